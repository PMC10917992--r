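#' Configuration of the observer-independent border detection
#'
#' @param block_sizes sweep of block sizes (profiles per block on each side
#'   of a candidate position).
#' @param alpha familywise significance level of the Bonferroni-corrected
#'   Hotelling tests.
#' @param position_tolerance maximal spread (profile indices) for candidates
#'   across block sizes/sections to count as the same border.
#' @param min_sections minimum number of adjacent sections that must support
#'   an accepted border.
#' @param min_block_sizes minimum number of distinct supporting block sizes
#'   per supporting section.
#' @param shrink covariance shrinkage: `"auto"` applies a diagonal-target
#'   (Ledoit-Wolf-style) shrinkage whenever the two blocks together provide
#'   at most 3x as many profiles as feature dimensions; `"never"` disables
#'   it; a number in \[0, 1\] fixes the intensity.
#' @param moments moment convention passed to [profile_features()].
#' @return a `border_config` list.
#' @export
border_config <- function(block_sizes = 12:30, alpha = 0.001,
                          position_tolerance = 3, min_sections = 3L,
                          min_block_sizes = 2L, shrink = "auto",
                          moments = "values") {
  if (alpha <= 0 || alpha >= 1) stop_glimap("alpha must lie in (0, 1)")
  if (min_sections < 1) stop_glimap("min_sections must be >= 1")
  if (any(block_sizes < 2)) stop_glimap("block sizes must be >= 2")
  structure(list(block_sizes = sort(unique(as.integer(block_sizes))),
                 alpha = alpha, position_tolerance = position_tolerance,
                 min_sections = as.integer(min_sections),
                 min_block_sizes = as.integer(min_block_sizes),
                 shrink = shrink, moments = moments),
            class = "border_config")
}

#' Squared Mahalanobis distance between two blocks of feature vectors
#'
#' \eqn{D^2 = (m_a - m_b)' C^{-1} (m_a - m_b)} with the block mean vectors
#' and a (typically pooled) covariance matrix.
#'
#' @param block_a,block_b numeric matrices, rows = feature vectors.
#' @param covariance symmetric positive-definite covariance matrix.
#' @return the scalar squared distance.
#' @export
mahalanobis_d2 <- function(block_a, block_b, covariance) {
  block_a <- as.matrix(block_a); block_b <- as.matrix(block_b)
  dm <- colMeans(block_a) - colMeans(block_b)
  R <- tryCatch(chol(covariance), error = function(e) NULL)
  if (is.null(R))
    stop_glimap("covariance is not positive definite (condition number %.3g); supply regularization",
                kappa(covariance))
  sum(backsolve(R, dm, transpose = TRUE)^2)
}

#' Hotelling's two-sample T-squared test from a Mahalanobis distance
#'
#' Converts \eqn{D^2} into \eqn{T^2 = n_a n_b / (n_a + n_b) D^2} and the
#' exact F statistic \eqn{F = T^2 (n_a + n_b - p - 1) / ((n_a + n_b - 2) p)}
#' with \eqn{(p, n_a + n_b - p - 1)} degrees of freedom.
#'
#' @param D2 squared Mahalanobis distance (>= 0).
#' @param n_a,n_b block sizes.
#' @param p_dim feature dimension (10 for the standard profile features).
#' @return `list(T2, F_stat, df1, df2, p_value)`.
#' @export
hotelling_p <- function(D2, n_a, n_b, p_dim = 10L) {
  if (D2 < 0) stop_glimap("D2 must be nonnegative")
  n <- n_a + n_b
  df2 <- n - p_dim - 1
  if (df2 < 1)
    stop_glimap("insufficient samples for the F conversion (n_a + n_b = %d, p = %d)",
                n, p_dim)
  T2 <- n_a * n_b / n * D2
  F_stat <- T2 * df2 / ((n - 2) * p_dim)
  list(T2 = T2, F_stat = F_stat, df1 = p_dim, df2 = df2,
       p_value = pf(F_stat, p_dim, df2, lower.tail = FALSE))
}

# Pooled within-block covariance with optional diagonal-target shrinkage
# (Schafer-Strimmer analytic intensity). Rows of A and B are observations.
pooled_covariance <- function(A, B, shrink = "auto") {
  na <- nrow(A); nb <- nrow(B); p <- ncol(A)
  X <- rbind(sweep(A, 2, colMeans(A)), sweep(B, 2, colMeans(B)))
  n <- na + nb
  S <- crossprod(X) / (n - 2)
  lambda <- 0
  if (identical(shrink, "auto")) {
    if (n <= 3 * p) lambda <- shrink_intensity(X, S, n)
  } else if (is.numeric(shrink)) {
    lambda <- min(max(shrink, 0), 1)
  }
  if (lambda > 0) {
    S_off <- S * (1 - lambda)
    diag(S_off) <- diag(S)
    S <- S_off
  }
  attr(S, "lambda") <- lambda
  S
}

# analytic shrinkage intensity toward the diagonal target
shrink_intensity <- function(X, S, n) {
  p <- ncol(X)
  num <- 0; den <- 0
  for (i in seq_len(p - 1L)) {
    for (j in (i + 1L):p) {
      w <- X[, i] * X[, j]
      num <- num + n / (n - 1)^3 * sum((w - mean(w))^2)
      den <- den + S[i, j]^2
    }
  }
  if (den <= 0) return(1)
  min(max(num / den, 0), 1)
}

#' Sliding-window Mahalanobis distance function along a profile sequence
#'
#' For every interior position the `b` profiles to the left are compared with
#' the `b` profiles to the right via the Mahalanobis distance between their
#' mean feature vectors (pooled covariance), Hotelling's T-squared and its F
#' conversion. Significance is Bonferroni-corrected over the number of
#' positions tested in this section at this block size.
#'
#' @param profiles a [gli_profiles()] or feature matrix; with
#'   `features = NULL` the 10-D profile features are computed first.
#' @param b block size (profiles per side).
#' @param config a [border_config()].
#' @param section section identifier carried into the output.
#' @param features optional precomputed feature matrix for `profiles`.
#' @return data.frame with one row per tested position: `section`,
#'   `block_size`, `position` (boundary between profiles `position` and
#'   `position + 1`), `D2`, `T2`, `F_stat`, `df1`, `df2`, `p_value`,
#'   `p_bonf`, `significant`. Zero rows (with a warning) when fewer than
#'   `2 b` profiles are available.
#' @export
distance_function <- function(profiles, b, config = border_config(),
                              section = 1L, features = NULL) {
  X <- features %||% profile_features(profiles, moments = config$moments)
  n <- nrow(X); p <- ncol(X)
  empty <- data.frame(section = integer(0), block_size = integer(0),
                      position = integer(0), D2 = numeric(0), T2 = numeric(0),
                      F_stat = numeric(0), df1 = integer(0), df2 = integer(0),
                      p_value = numeric(0), p_bonf = numeric(0),
                      significant = logical(0))
  if (n < 2 * b) {
    warning(sprintf("fewer than 2b = %d profiles (%d); no positions tested", 2 * b, n))
    return(empty)
  }
  pos <- b:(n - b)
  m <- length(pos)
  D2 <- T2 <- Fs <- pv <- numeric(m)
  for (k in seq_len(m)) {
    i <- pos[k]
    A <- X[(i - b + 1L):i, , drop = FALSE]
    B <- X[(i + 1L):(i + b), , drop = FALSE]
    C <- pooled_covariance(A, B, shrink = config$shrink)
    D2[k] <- mahalanobis_d2(A, B, C)
    ht <- hotelling_p(D2[k], b, b, p)
    T2[k] <- ht$T2; Fs[k] <- ht$F_stat; pv[k] <- ht$p_value
  }
  data.frame(section = section, block_size = b, position = pos,
             D2 = D2, T2 = T2, F_stat = Fs,
             df1 = p, df2 = 2 * b - p - 1,
             p_value = pv, p_bonf = pmin(pv * m, 1),
             significant = pv < config$alpha / m)
}

#' Significant local maxima of a distance function
#'
#' Candidate border positions: strict local maxima of \eqn{D^2} within a
#' window of half a block size on either side, restricted to positions whose
#' window lies fully inside the tested range (end-adjacent maxima are not
#' interior), and significant after Bonferroni correction.
#'
#' @param comparisons output of [distance_function()] for one section and
#'   one block size.
#' @return the subset of `comparisons` rows that are candidate borders.
#' @export
find_significant_maxima <- function(comparisons) {
  if (!nrow(comparisons)) return(comparisons[0, ])
  b <- comparisons$block_size[1]
  w <- floor(b / 2)
  pos <- comparisons$position
  lo <- min(pos); hi <- max(pos)
  keep <- logical(nrow(comparisons))
  for (k in seq_along(pos)) {
    if (!comparisons$significant[k]) next
    if (pos[k] - w < lo || pos[k] + w > hi) next   # truncated window: not interior
    nb <- which(abs(pos - pos[k]) <= w & seq_along(pos) != k)
    keep[k] <- all(comparisons$D2[k] > comparisons$D2[nb])
  }
  comparisons[keep, , drop = FALSE]
}

#' Accept borders consistent across block sizes and adjacent sections
#'
#' Candidates from all (section, block size) combinations are clustered by
#' position (single linkage, gaps larger than `position_tolerance` split
#' clusters). A cluster becomes an accepted border when at least
#' `min_sections` *adjacent* analyzed sections each support it with at least
#' `min_block_sizes` distinct block sizes. The consensus position is the
#' median candidate position (overall and per section); the summary p-value
#' is the largest Bonferroni-corrected p among the supporting candidates.
#'
#' @param candidates data.frame with columns `section`, `block_size`,
#'   `position`, `p_bonf` (e.g. row-bound [find_significant_maxima()]
#'   results).
#' @param config a [border_config()].
#' @param sections ordered vector of all analyzed section ids (adjacency is
#'   contiguity in this ordering); defaults to the sections present in
#'   `candidates`.
#' @return data.frame of class `border_calls`: `position`, `n_sections`,
#'   `n_block_sizes`, `sections` (comma-separated), `summary_p`; the
#'   per-section median positions are stored in
#'   `attr(, "section_positions")`.
#' @export
accept_borders <- function(candidates, config = border_config(), sections = NULL) {
  out <- data.frame(position = numeric(0), n_sections = integer(0),
                    n_block_sizes = integer(0), sections = character(0),
                    summary_p = numeric(0))
  attr(out, "section_positions") <- list()
  class(out) <- c("border_calls", "data.frame")
  if (is.null(candidates) || !nrow(candidates)) return(out)
  sections <- sections %||% sort(unique(candidates$section))
  ord <- order(candidates$position)
  cand <- candidates[ord, , drop = FALSE]
  gap <- c(FALSE, diff(cand$position) > config$position_tolerance)
  cl <- cumsum(gap) + 1L
  sec_pos_all <- list()
  rows <- list()
  for (g in unique(cl)) {
    cc <- cand[cl == g, , drop = FALSE]
    support <- tapply(cc$block_size, cc$section, function(z) length(unique(z)))
    qualified <- as.integer(names(support))[support >= config$min_block_sizes]
    if (!length(qualified)) next
    ranks <- match(qualified, sections)
    ranks <- sort(ranks[!is.na(ranks)])
    if (!length(ranks)) next
    runs <- split(ranks, cumsum(c(1L, diff(ranks) != 1L)))
    best <- runs[[which.max(lengths(runs))]]
    if (length(best) < config$min_sections) next
    keep_secs <- sections[best]
    cs <- cc[cc$section %in% keep_secs, , drop = FALSE]
    rows[[length(rows) + 1L]] <- data.frame(
      position = median(cs$position),
      n_sections = length(keep_secs),
      n_block_sizes = length(unique(cs$block_size)),
      sections = paste(keep_secs, collapse = ","),
      summary_p = max(cs$p_bonf))
    sec_pos_all[[length(sec_pos_all) + 1L]] <-
      tapply(cs$position, cs$section, median)
  }
  if (!length(rows)) return(out)
  res <- do.call(rbind, rows)
  res <- res[order(res$position), , drop = FALSE]
  attr(res, "section_positions") <- sec_pos_all[order(vapply(rows, `[[`, 0, "position"))]
  class(res) <- c("border_calls", "data.frame")
  res
}

#' Full observer-independent border detection pipeline
#'
#' Runs [distance_function()] and [find_significant_maxima()] for every
#' section and every block size in the sweep, then [accept_borders()] over
#' the pooled candidates.
#'
#' @param section_profiles list of [gli_profiles()] (or feature matrices),
#'   one per analyzed section, in anatomical order.
#' @param config a [border_config()].
#' @return list with `calls` (accepted [accept_borders()] result),
#'   `candidates` (all significant maxima) and `n_tests` (positions tested).
#' @export
detect_borders <- function(section_profiles, config = border_config()) {
  cands <- list(); n_tests <- 0L
  for (s in seq_along(section_profiles)) {
    X <- if (is.matrix(section_profiles[[s]])) section_profiles[[s]]
         else profile_features(section_profiles[[s]], moments = config$moments)
    for (b in config$block_sizes) {
      if (nrow(X) < 2 * b) next
      comp <- distance_function(X, b, config, section = s, features = X)
      n_tests <- n_tests + nrow(comp)
      mx <- find_significant_maxima(comp)
      if (nrow(mx)) cands[[length(cands) + 1L]] <- mx
    }
  }
  candidates <- if (length(cands)) do.call(rbind, cands) else NULL
  list(calls = accept_borders(candidates, config,
                              sections = seq_along(section_profiles)),
       candidates = candidates, n_tests = n_tests)
}
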