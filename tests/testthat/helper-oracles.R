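# Independent brute-force oracles and shared fixtures. Every oracle here is
# a direct transcription of the defining formula, kept free of the package's
# own computational paths.

# --- laminar fixtures -------------------------------------------------------

default_gli_levels <- c(0.10, 0.24, 0.16, 0.27, 0.17, 0.20)

granular_model <- function(soma_radius = 4, gli = default_gli_levels) {
  laminar_model(layer_intensities = intensity_for_gli(gli, soma_radius),
                soma_radius = soma_radius)
}

# area with layer IV cell density increased by `contrast` (e.g. 0.5 = +50%)
contrast_model <- function(contrast = 0.5, soma_radius = 4) {
  g <- default_gli_levels
  lam <- intensity_for_gli(g, soma_radius)
  lam[4] <- lam[4] * (1 + contrast)
  laminar_model(layer_intensities = lam, soma_radius = soma_radius)
}

one_area_spec <- function(noise_sd = 0.05, extent = 1000)
  ribbon_spec(list(list(extent = extent, model = granular_model())),
              noise_sd = noise_sd)

two_area_spec <- function(noise_sd = 0.05, contrast = 0.5)
  ribbon_spec(list(list(extent = 1000, model = granular_model()),
                   list(extent = 1000, model = contrast_model(contrast))),
              noise_sd = noise_sd)

# annulus-sector contour pair with analytic field ln(r/r_out)/ln(r_in/r_out)
annulus_contours <- function(r_out = 95, r_in = 35, cx = 100, cy = 10,
                             th = seq(pi / 4, 3 * pi / 4, length.out = 361)) {
  list(cp = contour_pair(cbind(cx + r_out * cos(th), cy + r_out * sin(th)),
                         cbind(cx + r_in * cos(th), cy + r_in * sin(th))),
       cx = cx, cy = cy, r_out = r_out, r_in = r_in)
}

# random smoothly wavy open ribbon for non-crossing property checks
wavy_contours <- function(seed) {
  set.seed(seed)
  x <- seq(0, 300, length.out = 121)
  a1 <- runif(1, 5, 20); f1 <- runif(1, 0.01, 0.04); p1 <- runif(1, 0, 2 * pi)
  a2 <- runif(1, 5, 20); f2 <- runif(1, 0.01, 0.04); p2 <- runif(1, 0, 2 * pi)
  gapmin <- 40
  outer <- cbind(x, 60 + a1 * sin(f1 * x + p1))
  inner <- cbind(x, 60 + gapmin + a1 * sin(f1 * x + p1) + a2 * (1 + sin(f2 * x + p2)))
  contour_pair(outer, inner)
}

# --- moment / statistics oracles -------------------------------------------

# ten feature components by direct summation (values convention)
oracle_features_values <- function(v, depth) {
  five <- function(z, d) {
    tot <- sum(z)
    cen <- if (tot > 0) sum(z * d) / tot else mean(d)
    m <- sum(z) / length(z)
    s <- sqrt(sum((z - m)^2) / length(z))
    sk <- if (s > 0) sum((z - m)^3) / length(z) / s^3 else 0
    ku <- if (s > 0) sum((z - m)^4) / length(z) / s^4 else 0
    c(m, cen, s, sk, ku)
  }
  a <- abs(v[-1] - v[-length(v)])
  dmid <- (depth[-1] + depth[-length(depth)]) / 2
  c(five(v, depth), five(a, dmid))
}

# depth-mass convention
oracle_features_mass <- function(v, depth) {
  five <- function(z, d) {
    tot <- sum(z)
    if (tot > 0) {
      w <- z / tot
      cen <- sum(w * d)
      s <- sqrt(sum(w * (d - cen)^2))
      sk <- if (s > 0) sum(w * (d - cen)^3) / s^3 else 0
      ku <- if (s > 0) sum(w * (d - cen)^4) / s^4 else 0
    } else { cen <- mean(d); s <- 0; sk <- 0; ku <- 0 }
    c(sum(z) / length(z), cen, s, sk, ku)
  }
  a <- abs(v[-1] - v[-length(v)])
  dmid <- (depth[-1] + depth[-length(depth)]) / 2
  c(five(v, depth), five(a, dmid))
}

# solve-then-dot Mahalanobis oracle
oracle_d2 <- function(A, B, C) {
  dm <- colMeans(A) - colMeans(B)
  as.numeric(t(dm) %*% solve(C) %*% dm)
}

# Hotelling conversion by the defining formulas, p-value by numerical
# integration of the F density
oracle_hotelling <- function(D2, na, nb, p) {
  T2 <- na * nb / (na + nb) * D2
  df2 <- na + nb - p - 1
  Fs <- T2 * df2 / ((na + nb - 2) * p)
  pv <- stats::integrate(function(q) stats::df(q, p, df2), Fs, Inf,
                         rel.tol = 1e-10)$value
  list(T2 = T2, F_stat = Fs, p_value = pv)
}

# exhaustive greedy Ward: at each step merge the pair with the smallest
# increase of the total error sum of squares, recomputed from scratch
oracle_ward_heights <- function(M) {
  ess <- function(idx) {
    X <- M[idx, , drop = FALSE]
    sum(sweep(X, 2, colMeans(X))^2)
  }
  clusters <- as.list(seq_len(nrow(M)))
  heights <- numeric(0)
  while (length(clusters) > 1L) {
    best <- Inf; bi <- bj <- NA
    for (i in seq_len(length(clusters) - 1L)) {
      for (j in (i + 1L):length(clusters)) {
        inc <- ess(c(clusters[[i]], clusters[[j]])) -
          ess(clusters[[i]]) - ess(clusters[[j]])
        if (inc < best) { best <- inc; bi <- i; bj <- j }
      }
    }
    heights <- c(heights, best)
    clusters[[bi]] <- c(clusters[[bi]], clusters[[bj]])
    clusters[[bj]] <- NULL
  }
  heights
}

# adjusted Rand index from the contingency table
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_comb <- function(x) sum(choose(x, 2))
  idx <- sum_comb(as.vector(tab))
  e1 <- sum_comb(rowSums(tab)); e2 <- sum_comb(colSums(tab))
  expected <- e1 * e2 / choose(n, 2)
  (idx - expected) / ((e1 + e2) / 2 - expected)
}

# random spatially-coherent binary mask (overlapping random rectangles)
random_mask <- function(seed, nr = 96, nc = 96, resolution = 1) {
  set.seed(seed)
  M <- matrix(0L, nr, nc)
  for (k in seq_len(sample(3:10, 1))) {
    r0 <- sample(nr, 1); c0 <- sample(nc, 1)
    r1 <- min(nr, r0 + sample(5:30, 1)); c1 <- min(nc, c0 + sample(5:30, 1))
    M[r0:r1, c0:c1] <- 1L
  }
  cell_mask(M, resolution)
}
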