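test_that("Mahalanobis distance matches its definition and a brute-force oracle", {
  set.seed(1)
  A <- matrix(rnorm(30), 10, 3)
  expect_equal(mahalanobis_d2(A, A, diag(3)), 0)

  B <- matrix(rnorm(30, 1), 10, 3)
  dm <- colMeans(A) - colMeans(B)
  expect_equal(mahalanobis_d2(A, B, diag(3)), sum(dm^2), tolerance = 1e-12)

  for (k in 1:20) {
    A <- matrix(rnorm(24), 8, 3); B <- matrix(rnorm(24, 0.5), 8, 3)
    L <- matrix(rnorm(9), 3, 3); C <- crossprod(L) + diag(3) * 0.5
    expect_equal(mahalanobis_d2(A, B, C), oracle_d2(A, B, C), tolerance = 1e-10)
  }
  expect_error(mahalanobis_d2(A, B, matrix(0, 3, 3)), "positive definite")
})

test_that("Hotelling conversion is exact and degenerates correctly", {
  expect_equal(hotelling_p(0, 15, 15, 10)$p_value, 1)
  ht <- hotelling_p(2.3, 14, 17, 10)
  or <- oracle_hotelling(2.3, 14, 17, 10)
  expect_equal(ht$T2, or$T2, tolerance = 1e-12)
  expect_equal(ht$F_stat, or$F_stat, tolerance = 1e-12)
  expect_equal(ht$p_value, or$p_value, tolerance = 1e-9)
  expect_error(hotelling_p(1, 5, 5, 10), "insufficient")
})

test_that("null p-values are uniform when the F conversion is exact", {
  set.seed(303)
  p <- 3; na <- nb <- 15
  pv <- vapply(1:500, function(i) {
    A <- matrix(rnorm(na * p), na, p)
    B <- matrix(rnorm(nb * p), nb, p)
    C <- glimap:::pooled_covariance(A, B, shrink = "never")
    hotelling_p(mahalanobis_d2(A, B, C), na, nb, p)$p_value
  }, 0)
  expect_gt(ks.test(pv, "punif")$p.value, 0.01)
})

test_that("the distance function respects block preconditions and permutation invariance", {
  spec <- two_area_spec()
  sp <- sample_profiles(spec, 10, seed = 5)
  X <- profile_features(sp$profiles)
  expect_warning(out <- distance_function(X, b = 11, features = X), "fewer than")
  expect_equal(nrow(out), 0L)

  cfg <- border_config(block_sizes = 6)
  d1 <- distance_function(X, 6, cfg, features = X)
  # shuffling profiles *within* each compared block leaves statistics unchanged
  i <- 8   # boundary: left block rows 3..8, right rows 9..14
  Xs <- X
  Xs[3:8, ] <- X[sample(3:8), ]
  Xs[9:14, ] <- X[sample(9:14), ]
  d2 <- distance_function(Xs, 6, cfg, features = Xs)
  expect_equal(d2$D2[d2$position == i], d1$D2[d1$position == i], tolerance = 1e-12)
  expect_equal(d2$p_value[d2$position == i], d1$p_value[d1$position == i], tolerance = 1e-12)
})

test_that("significant maxima are strict interior local maxima", {
  base <- data.frame(section = 1L, block_size = 6L)
  mk <- function(D2, sig) cbind(base[rep(1, length(D2)), ],
                                position = seq_along(D2) + 5L, D2 = D2,
                                T2 = D2, F_stat = D2, df1 = 3, df2 = 8,
                                p_value = ifelse(sig, 1e-6, 0.5),
                                p_bonf = ifelse(sig, 1e-5, 1),
                                significant = sig)
  # monotone sequence: its only maximum is end-adjacent, hence not interior
  mono <- mk(seq(1, 12, length.out = 12), rep(TRUE, 12))
  expect_equal(nrow(find_significant_maxima(mono)), 0L)
  # flat sequence: no strict maxima
  flat <- mk(rep(2, 12), rep(TRUE, 12))
  expect_equal(nrow(find_significant_maxima(flat)), 0L)
  # interior peak
  peak <- mk(c(1, 1, 2, 3, 9, 3, 2, 1, 1, 1, 1, 1), rep(TRUE, 12))
  out <- find_significant_maxima(peak)
  expect_equal(out$position, 10L)  # 5th position, offset 5
  # insignificant peaks are not candidates
  peak$significant <- FALSE
  expect_equal(nrow(find_significant_maxima(peak)), 0L)
})

test_that("a planted border is recovered at the true position", {
  spec <- two_area_spec(noise_sd = 0.05, contrast = 0.5)
  secs <- lapply(1:3, function(s) sample_profiles(spec, 40, section_id = s,
                                                  seed = 400 + s)$profiles)
  cfg <- border_config()
  # the distance function's global maximum sits at the true border
  X <- profile_features(secs[[1]])
  d <- distance_function(X, 15, cfg, features = X)
  expect_lte(abs(d$position[which.max(d$D2)] - 40), 3)

  res <- detect_borders(secs, cfg)
  expect_equal(nrow(res$calls), 1L)
  expect_lte(abs(res$calls$position - 40), 3)
  expect_equal(res$calls$n_sections, 3L)
  expect_lt(res$calls$summary_p, cfg$alpha)
})

test_that("acceptance requires multi-section, position-stable support", {
  cfg <- border_config(position_tolerance = 3, min_sections = 3)
  cand <- function(section, position, b = c(12L, 14L))
    data.frame(section = section, block_size = b, position = position, p_bonf = 1e-5)
  # single section only: rejected
  one <- do.call(rbind, list(cand(2L, 40)))
  expect_equal(nrow(accept_borders(one, cfg, sections = 1:3)), 0L)
  # three adjacent sections, stable position: accepted
  three <- do.call(rbind, lapply(1:3, function(s) cand(s, 40 + s %% 2)))
  acc <- accept_borders(three, cfg, sections = 1:3)
  expect_equal(nrow(acc), 1L)
  expect_equal(acc$n_sections, 3L)
  # same support but positions drift by more than the tolerance: rejected
  drift <- do.call(rbind, lapply(1:3, function(s) cand(s, 40 + 5 * s)))
  expect_equal(nrow(accept_borders(drift, cfg, sections = 1:3)), 0L)
  # three sections but not adjacent (1, 3, 5): rejected
  gaps <- do.call(rbind, lapply(c(1L, 3L, 5L), function(s) cand(s, 40)))
  expect_equal(nrow(accept_borders(gaps, cfg, sections = 1:5)), 0L)
  # only one block size per section: rejected
  oneb <- do.call(rbind, lapply(1:3, function(s) cand(s, 40, b = 12L)))
  expect_equal(nrow(accept_borders(oneb, cfg, sections = 1:3)), 0L)
})

test_that("covariance shrinkage engages only in the small-sample regime and keeps PD", {
  set.seed(99)
  A <- matrix(rnorm(120), 12, 10); B <- matrix(rnorm(120), 12, 10)
  C <- glimap:::pooled_covariance(A, B, shrink = "auto")   # 2b = 24 <= 30
  expect_gt(attr(C, "lambda"), 0)
  expect_true(all(eigen(C, symmetric = TRUE, only.values = TRUE)$values > 0))
  A2 <- matrix(rnorm(400), 40, 10); B2 <- matrix(rnorm(400), 40, 10)
  C2 <- glimap:::pooled_covariance(A2, B2, shrink = "auto")  # 80 > 30
  expect_equal(attr(C2, "lambda"), 0)
  # unshrunk pooled covariance equals the textbook pooled estimator
  pooled <- ((nrow(A2) - 1) * cov(A2) + (nrow(B2) - 1) * cov(B2)) /
    (nrow(A2) + nrow(B2) - 2)
  expect_equal(unclass(C2), pooled, tolerance = 1e-12, ignore_attr = TRUE)
})
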