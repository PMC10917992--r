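make_subjects <- function() {
  # 10 subjects, two areas with jittered extents on a small grid
  base <- array(0L, c(10, 10, 6))
  base[2:5, 2:8, 2:5] <- 1L
  base[6:9, 2:8, 2:5] <- 2L
  make_label_volumes(10, base, jitter_sd = 0.8, seed = 17)
}

test_that("probability maps are exact subject fractions", {
  vols <- make_subjects()
  pm <- probability_map(vols, 1)
  # brute-force per-voxel count
  arr <- simplify2array(lapply(vols, function(v) v$voxels))
  expect_equal(pm$voxels, apply(arr == 1, 1:3, mean), tolerance = 0)
  expect_true(all(pm$voxels * 10 == round(pm$voxels * 10)))
  # full-agreement and no-support voxels
  all1 <- apply(arr == 1, 1:3, all)
  if (any(all1)) expect_true(all(pm$voxels[all1] == 1))
  expect_true(all(pm$voxels[apply(arr == 1, 1:3, sum) == 0] == 0))
})

test_that("per-voxel frequencies over all areas plus background sum to one", {
  vols <- make_subjects()
  ids <- 0:2
  # integer subject counts conserve exactly: every voxel is accounted for
  total <- Reduce(`+`, lapply(ids, function(a) probability_map(vols, a)$counts))
  expect_true(all(total == 10L))
  frac <- Reduce(`+`, lapply(ids, function(a) probability_map(vols, a)$voxels))
  expect_equal(frac, array(1, dim(frac)), tolerance = 1e-15)
})

test_that("the MPM is a partition attaining the per-voxel maximum", {
  vols <- make_subjects()
  maps <- lapply(1:2, function(a) probability_map(vols, a))
  mpm <- maximum_probability_map(maps)
  P <- simplify2array(lapply(maps, `[[`, "voxels"))
  pmaxv <- pmax(P[, , , 1], P[, , , 2])
  lab <- mpm$voxels
  # background exactly where no area has support
  expect_true(all((lab == 0) == (pmaxv == 0)))
  # assigned labels attain the maximum (brute force over the whole grid)
  for (a in 1:2)
    expect_true(all(P[, , , a][lab == a] == pmaxv[lab == a]))
  # partition: per-area masks recompose the nonzero support
  expect_equal(sum(lab == 1) + sum(lab == 2), sum(lab != 0))
  # single-area MPM equals its support
  m1 <- maximum_probability_map(maps[1])
  expect_true(all((m1$voxels == 1) == (maps[[1]]$voxels > 0)))
})

test_that("MPM tie-breaking is deterministic and neighborhood-driven", {
  dm <- c(5, 5, 3)
  v1 <- array(0, dm); v2 <- array(0, dm)
  v1[3, 3, 2] <- 0.5; v2[3, 3, 2] <- 0.5       # exact tie at the center
  v1[2:4, 2:4, 1:3] <- pmax(v1[2:4, 2:4, 1:3], 0.3)  # area 1 dominates around it
  mk <- function(v, id) structure(list(voxels = v, area_id = id, n_subjects = 10,
                                       voxel_mm = c(1, 1, 1), affine = diag(4)),
                                  class = "probability_map")
  maps <- list(mk(v1, 1L), mk(v2, 2L))
  m1 <- maximum_probability_map(maps)
  m2 <- maximum_probability_map(maps)
  expect_identical(m1$voxels, m2$voxels)
  expect_equal(m1$voxels[3, 3, 2], 1L)   # higher neighborhood support wins
  # symmetric tie falls back to the lower area index
  v1b <- array(0, dm); v2b <- array(0, dm)
  v1b[3, 3, 2] <- 0.4; v2b[3, 3, 2] <- 0.4
  mb <- maximum_probability_map(list(mk(v1b, 1L), mk(v2b, 2L)))
  expect_equal(mb$voxels[3, 3, 2], 1L)
})

test_that("centers of gravity match weighted-sum oracles through the affine", {
  dm <- c(8, 7, 6)
  v <- array(0, dm); v[4, 3, 2] <- 0.7
  mk <- structure(list(voxels = v, affine = diag(c(2, 2, 2, 1))),
                  class = "probability_map")
  expect_equal(center_of_gravity(mk), c(x = 6, y = 4, z = 2))  # (4-1,3-1,2-1)*2

  # uniform cube: geometric center
  v2 <- array(0, dm); v2[2:5, 2:5, 2:5] <- 0.5
  mk2 <- structure(list(voxels = v2, affine = diag(4)), class = "probability_map")
  expect_equal(center_of_gravity(mk2), c(x = 2.5, y = 2.5, z = 2.5))

  set.seed(31)
  v3 <- array(0, dm); v3[sample(length(v3), 40)] <- runif(40)
  aff <- diag(c(1.5, 2, 2.5, 1)); aff[1:3, 4] <- c(-10, 5, 3)
  mk3 <- structure(list(voxels = v3, affine = aff), class = "probability_map")
  idx <- arrayInd(seq_along(v3), dm) - 1
  oracle <- (aff %*% c(colSums(idx * as.numeric(v3)) / sum(v3), 1))[1:3]
  expect_equal(unname(center_of_gravity(mk3)), as.numeric(oracle), tolerance = 1e-9)

  expect_error(center_of_gravity(structure(list(voxels = array(0, dm), affine = diag(4)),
                                           class = "probability_map")), "zero mass")
})

test_that("population outputs are invariant under subject permutation", {
  vols <- make_subjects()
  perm <- vols[c(4, 1, 9, 2, 10, 3, 7, 5, 8, 6)]
  expect_identical(probability_map(vols, 1)$voxels, probability_map(perm, 1)$voxels)
  maps1 <- lapply(1:2, function(a) probability_map(vols, a))
  maps2 <- lapply(1:2, function(a) probability_map(perm, a))
  expect_identical(maximum_probability_map(maps1)$voxels,
                   maximum_probability_map(maps2)$voxels)
})

test_that("volumes with mismatched grids are rejected", {
  a <- label_volume(array(0L, c(4, 4, 4)))
  b <- label_volume(array(0L, c(4, 4, 5)))
  expect_error(probability_map(list(a, b), 1), "mismatched")
})
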