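test_that("tract binarization thresholds at >= and flags empty masks", {
  g <- c(4, 4, 4)
  expect_true(all(binarize_tract(array(0.6, g), 0.5)))
  expect_warning(m <- binarize_tract(array(0, g), 0.5), "empty")
  expect_false(any(m))
  v <- array(0, g); v[1:10] <- 0.5
  expect_equal(sum(binarize_tract(v, 0.5)), 10)
  expect_error(binarize_tract(v, 0), "strictly inside")
  expect_error(binarize_tract(v, 1), "strictly inside")
})

test_that("disconnection fraction equals the voxel-count ratio", {
  g <- c(6, 6, 6)
  tract <- array(FALSE, g); tract[1:10] <- TRUE
  lesion <- array(FALSE, g); lesion[1:3] <- TRUE
  expect_equal(disconnection_fraction(lesion, tract), 0.3)
  expect_equal(disconnection_fraction(array(FALSE, g), tract), 0)
  expect_equal(disconnection_fraction(array(TRUE, g), tract), 1)
  # disjoint lesion
  far <- array(FALSE, g); far[100:120] <- TRUE
  expect_equal(disconnection_fraction(far, tract), 0)
  expect_error(disconnection_fraction(lesion, array(FALSE, g)), "empty")
  expect_error(disconnection_fraction(array(FALSE, c(5, 5, 5)), tract),
               "grid")
})

test_that("rest-of-brain fraction uses the pool union minus player voxels", {
  g <- c(6, 6, 6)
  player <- cube_mask(g, c(1, 1, 1), c(3, 3, 3))
  pool1 <- cube_mask(g, c(4, 1, 1), c(6, 3, 3))
  pool2 <- cube_mask(g, c(4, 4, 1), c(6, 6, 3))
  # lesion confined to the player tract: RoB damage 0
  expect_equal(rob_fraction(player, list(player), list(pool1, pool2)), 0)
  # lesion covering the whole pool: 1
  expect_equal(rob_fraction(pool1 | pool2, list(player), list(pool1, pool2)), 1)
  # half of the pool union, disjoint from the player
  expect_equal(rob_fraction(pool1, list(player), list(pool1, pool2)), 0.5)
  # voxels shared between a player and a pool tract do not count against RoB
  overlap_pool <- player | pool1
  expect_equal(rob_fraction(player, list(player), list(overlap_pool, pool2)),
               0)
  expect_error(rob_fraction(player, list(player), list()), "empty")
})

test_that("patient profiles match brute-force voxel recounting exactly", {
  co <- tiny_cohort()
  atlas <- co$atlas
  thr <- 0.5
  for (i in c(1, 7, 20)) {
    les <- co$lesions[[i]]
    prof <- profile_patient(les, atlas, thr)
    for (k in seq_along(atlas$volumes)) {
      tr <- atlas$volumes[[k]] >= thr
      expect_identical(unname(prof$d[k]), sum(les & tr) / sum(tr))
    }
    poolU <- Reduce(`|`, lapply(atlas$pool, function(v) v >= thr))
    playU <- Reduce(`|`, lapply(atlas$volumes, function(v) v >= thr))
    rob_reg <- poolU & !playU
    expect_identical(unname(prof$d[["RoB"]]), sum(les & rob_reg) / sum(rob_reg))
    expect_equal(prof$intact, 1 - prof$d)
    expect_true(all(prof$d >= 0 & prof$d <= 1))
  }
  # empty and full lesions
  e <- profile_patient(array(FALSE, atlas$grid), atlas)
  expect_true(all(e$d == 0) && all(e$intact == 1))
  f <- profile_patient(array(TRUE, atlas$grid), atlas)
  expect_true(all(f$d == 1))
})

test_that("disconnection is monotone under lesion growth", {
  co <- tiny_cohort()
  atlas <- co$atlas
  set.seed(3)
  les <- generate_lesions(atlas, 1, size_dist = 60, seed = 3)[[1]]
  d_small <- profile_patient(les, atlas)$d
  grown <- les
  grown[which(!grown)[1:100]] <- TRUE   # add arbitrary voxels
  d_big <- profile_patient(grown, atlas)$d
  expect_true(all(d_big >= d_small))
})

test_that("lesion correlations match the closed-form Pearson formula", {
  d <- cbind(a = c(0.1, 0.4, 0.3, 0.9),
             b = c(0.2, 0.1, 0.5, 0.8),
             c = c(0.9, 0.6, 0.4, 0.1))
  cm <- lesion_correlation_matrix(d)
  # independent textbook computation
  pearson <- function(x, y) {
    n <- length(x)
    (sum(x * y) - n * mean(x) * mean(y)) /
      sqrt((sum(x^2) - n * mean(x)^2) * (sum(y^2) - n * mean(y)^2))
  }
  for (i in 1:3) for (j in 1:3)
    expect_equal(cm$r[i, j], pearson(d[, i], d[, j]))
  expect_equal(cm$r, t(cm$r))
  expect_equal(unname(diag(cm$r)), rep(1, 3))
  # duplicated column correlates at exactly 1
  cm2 <- lesion_correlation_matrix(cbind(d, a2 = d[, "a"]))
  expect_equal(cm2$r["a", "a2"], 1)
  # p-values agree with cor.test and masking follows the level
  pv <- cor.test(d[, 1], d[, 2])$p.value
  expect_equal(cm$p[1, 2], pv)
  expect_identical(unname(cm$masked[1, 2]), pv >= 0.05)
})

test_that("zero-variance tracts are flagged undefined, not zeroed", {
  d <- cbind(a = c(0.1, 0.4, 0.3, 0.9), flat = rep(0.2, 4))
  expect_warning(cm <- lesion_correlation_matrix(d), "zero-variance")
  expect_true(is.na(cm$r["a", "flat"]))
  expect_equal(cm$undefined, "flat")
  expect_error(lesion_correlation_matrix(d[1:2, ]), "at least 3")
})
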