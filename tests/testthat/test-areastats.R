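test_that("mean areal profiles are pointwise means", {
  p <- gli_profiles(matrix(rep(c(0.2, 0.4), each = 101), 2, 101, byrow = TRUE))
  m <- mean_area_profile(p)
  expect_equal(as.numeric(m$values), rep(0.3, 101), tolerance = 1e-12)
  expect_equal(attr(m, "mean_gli"), 0.3, tolerance = 1e-12)

  set.seed(3)
  X <- matrix(runif(15 * 101, 0, 1), 15, 101)
  m2 <- mean_area_profile(gli_profiles(X))
  expect_equal(m2$values[1, ], colSums(X) / 15, tolerance = 1e-12)
  # averaging order commutes: mean of per-section means (equal sizes)
  m_a <- colMeans(X[1:5, ]); m_b <- colMeans(X[6:10, ]); m_c <- colMeans(X[11:15, ])
  expect_equal(m2$values[1, ], (m_a + m_b + m_c) / 3, tolerance = 1e-12)
})

test_that("Ward merge heights equal the brute-force ESS oracle", {
  p1 <- matrix(0.3, 1, 101)
  lk0 <- cluster_areas(rbind(p1, p1), labels = c("a", "b"))
  expect_equal(lk0$height, 0)

  set.seed(42)
  for (k in 1:10) {
    n <- sample(4:6, 1)
    M <- matrix(runif(n * 12), n)
    lk <- cluster_areas(M)
    expect_equal(sort(lk$height), sort(oracle_ward_heights(M)), tolerance = 1e-9)
    expect_true(all(diff(lk$height) >= -1e-12))   # ultrametric monotonicity
  }
  expect_error(cluster_areas(matrix(runif(202), 2), labels = c("a", "a")), "duplicate")
})

test_that("well-separated profile groups are recovered with ARI 1", {
  set.seed(10)
  base1 <- laminar_curve(granular_model())
  base2 <- laminar_curve(contrast_model(1.0))
  for (s in 1:10) {
    set.seed(s)
    M <- rbind(t(replicate(4, pmin(pmax(base1 + rnorm(101, 0, 0.005), 0), 1))),
               t(replicate(4, pmin(pmax(base2 + rnorm(101, 0, 0.005), 0), 1))))
    lk <- cluster_areas(M)
    grp <- cutree(lk$hclust, k = 2)
    expect_equal(adjusted_rand(grp, rep(1:2, each = 4)), 1)
  }
})

test_that("discriminant projection separates classes and matches the eigen oracle", {
  set.seed(21)
  mk <- function(center) sweep(matrix(rnorm(20 * 4, 0, 0.2), 20, 4), 2, center, `+`)
  fs <- list(a = mk(c(0, 0, 0, 0)), b = mk(c(3, 0, 0, 0)), c = mk(c(0, 3, 0, 0)))
  pr <- discriminant_projection(fs)
  # centroid separation dwarfs the within-class spread in LD space
  dists <- as.matrix(dist(pr$centroids))
  within_sd <- max(tapply(pr$scores$LD1, pr$scores$area, sd),
                   tapply(pr$scores$LD2, pr$scores$area, sd))
  expect_gt(min(dists[upper.tri(dists)]), 5 * within_sd)
  # well-separated point clouds: no overlap of class projections in LD1/LD2
  ca <- pr$scores[pr$scores$area == "a", c("LD1", "LD2")]
  cb <- pr$scores[pr$scores$area == "b", c("LD1", "LD2")]
  gap <- min(as.matrix(dist(rbind(ca, cb)))[seq_len(nrow(ca)), -seq_len(nrow(ca))])
  expect_gt(gap, 0)

  # rotation invariance of pairwise projected distances
  Q <- qr.Q(qr(matrix(rnorm(16), 4, 4)))
  fs_rot <- lapply(fs, function(X) X %*% Q)
  pr2 <- discriminant_projection(fs_rot)
  d1 <- dist(as.matrix(pr$scores[, c("LD1", "LD2")]))
  d2 <- dist(as.matrix(pr2$scores[, c("LD1", "LD2")]))
  expect_equal(as.numeric(d1), as.numeric(d2), tolerance = 1e-6)

  # generalized eigenproblem oracle: scores correlate exactly up to sign
  X <- do.call(rbind, fs)
  grp <- rep(names(fs), each = 20)
  gm <- colMeans(X)
  Sw <- Reduce(`+`, lapply(unique(grp), function(g) {
    Xg <- X[grp == g, ]; crossprod(sweep(Xg, 2, colMeans(Xg)))
  }))
  Sb <- Reduce(`+`, lapply(unique(grp), function(g) {
    Xg <- X[grp == g, ]; nrow(Xg) * tcrossprod(colMeans(Xg) - gm)
  }))
  ev <- eigen(solve(Sw) %*% Sb)
  for (j in 1:2) {
    oracle_scores <- as.numeric(X %*% Re(ev$vectors[, j]))
    r <- abs(cor(oracle_scores, pr$scores[[paste0("LD", j)]]))
    expect_gt(r, 1 - 1e-8)
  }

  expect_error(discriminant_projection(fs[1:2]), "at least 3 areas")
})

test_that("the volume formula is exact arithmetic and linear in each factor", {
  vs <- volume_spec(s = 60, T = 0.02, x = 0.02116, y = 0.02116,
                    N_counts = rep(1e5, 10), F = 2)
  expect_equal(area_volume(vs), 60 * 0.02 * 0.02116 * 0.02116 * 1e6 * 2,
               tolerance = 1e-15)
  vs2 <- vs; vs2$F <- 4
  expect_equal(area_volume(vs2), 2 * area_volume(vs), tolerance = 1e-15)
  vs3 <- volume_spec(s = 60, N_counts = 0)
  expect_equal(area_volume(vs3), 0)

  set.seed(6)
  for (k in 1:30) {
    sp <- volume_spec(s = sample(30:90, 1), T = runif(1, 0.01, 0.05),
                      x = runif(1, 0.01, 0.05), y = runif(1, 0.01, 0.05),
                      N_counts = sample(0:1e6, sample(3:12, 1), replace = TRUE),
                      F = runif(1, 1, 3))
    direct <- sp$s * sp$T * sp$x * sp$y * sum(sp$N_counts) * sp$F
    expect_equal(area_volume(sp), direct, tolerance = 1e-12)
  }
})

test_that("volume normalization and tabulation behave", {
  expect_equal(normalize_volume(5711, 5711), 1)
  expect_equal(normalize_volume(0, 1234), 0)
  expect_error(normalize_volume(1, 0), "positive")

  counts <- data.frame(subject = rep(c("B01", "B04"), each = 4),
                       area = "SFG2", hemisphere = rep(c("L", "R"), 4),
                       section = rep(1:2, each = 2), pixels = c(1:8) * 1000)
  tab <- volume_table(counts, s = 60, shrinkage = c(B01 = 2, B04 = 1.5))
  expect_equal(nrow(tab), 4L)
  row <- tab[tab$subject == "B01" & tab$hemisphere == "L", ]
  expect_equal(row$volume, 60 * 0.02 * 0.02116^2 * (1000 + 3000) * 2, tolerance = 1e-12)
})
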