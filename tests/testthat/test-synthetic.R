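test_that("generated atlases are normalized, deterministic, with distinct cores", {
  a1 <- generate_atlas(c(8, 8, 8), n_tracts = 3, n_pool = 2, seed = 1)
  expect_length(a1$volumes, 3)
  for (v in c(a1$volumes, a1$pool)) {
    expect_true(all(v >= 0 & v <= 1))
    expect_gt(sum(v >= 0.5), 0)          # supra-0.5 core non-empty
  }
  a2 <- generate_atlas(c(8, 8, 8), n_tracts = 3, n_pool = 2, seed = 1)
  expect_identical(a1$volumes, a2$volumes)

  # pairwise core overlap below one half on a crowded grid
  a <- generate_atlas(c(8, 8, 8), n_tracts = 12, n_pool = 2, seed = 7)
  cores <- lapply(a$volumes, function(v) v >= 0.5)
  for (i in 1:11) for (j in (i + 1):12) {
    ov <- sum(cores[[i]] & cores[[j]])
    expect_lt(ov / sum(cores[[i]]), 0.5)
    expect_lt(ov / sum(cores[[j]]), 0.5)
  }
})

test_that("degenerate atlas requests are rejected", {
  expect_error(generate_atlas(c(3, 8, 8), 3), "degenerate")
  expect_error(generate_atlas(c(8, 8, 8), 1), "at least 2")
})

test_that("lesions are contiguous blobs of the requested extent", {
  atlas <- generate_atlas(c(10, 10, 10), 3, seed = 2)
  empty <- generate_lesions(atlas, 5, size_dist = 0, seed = 3)
  expect_true(all(vapply(empty, function(m) sum(m) == 0, logical(1))))

  les <- generate_lesions(atlas, 25, size_dist = 40, seed = 3)
  expect_length(les, 25)
  for (m in les) {
    expect_identical(dim(m), atlas$grid)
    expect_equal(sum(m), 40)
    # contiguity: voxel count of the 6-connected component containing any
    # lesion voxel equals the lesion size
    idx <- which(m, arr.ind = TRUE)
    comp <- matrix(idx[1, ], 1)
    grown <- TRUE
    inc <- rbind(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0), c(0,0,1), c(0,0,-1))
    seen <- array(FALSE, dim(m)); seen[comp] <- TRUE
    frontier <- comp
    while (nrow(frontier) > 0) {
      nxt <- do.call(rbind, lapply(seq_len(nrow(frontier)), function(k)
        sweep(inc, 2, frontier[k, ], `+`)))
      ok <- nxt[, 1] >= 1 & nxt[, 1] <= 10 & nxt[, 2] >= 1 & nxt[, 2] <= 10 &
            nxt[, 3] >= 1 & nxt[, 3] <= 10
      nxt <- nxt[ok, , drop = FALSE]
      keep <- m[nxt] & !seen[nxt]
      frontier <- nxt[keep, , drop = FALSE]
      seen[frontier] <- TRUE
    }
    expect_equal(sum(seen & m), sum(m))
  }
  les2 <- generate_lesions(atlas, 25, size_dist = 40, seed = 3)
  expect_identical(les, les2)
})

test_that("a lesion covering a tract core gives d = 1 for that tract", {
  atlas <- generate_atlas(c(10, 10, 10), 3, seed = 4)
  core <- atlas$volumes[[2]] >= 0.5
  prof <- profile_patient(core, atlas, threshold = 0.5)
  expect_equal(unname(prof$d[2]), 1)
})

test_that("noiseless labels equal the hand-evaluated linear-threshold rule", {
  set.seed(9)
  intact <- matrix(runif(20 * 3), 20, 3)
  truth <- ground_truth(c(1, -0.5, 0.25), noise_sd = 0, threshold = 0.4,
                        seed = 2)
  lab <- generate_behavior(intact, truth)
  manual <- as.integer(intact %*% c(1, -0.5, 0.25) >= 0.4)
  expect_identical(lab$performance, manual)
  expect_identical(lab$deficit, 1L - manual)

  # all-intact with positive weights and low threshold: all normal
  all_int <- matrix(1, 5, 3)
  expect_true(all(generate_behavior(all_int, truth)$performance == 1))
  # all damaged: all pathological
  expect_true(all(generate_behavior(matrix(0, 5, 3), truth)$deficit == 1))
  # player-count mismatch rejected
  expect_error(generate_behavior(intact[, 1:2], truth), "player count")
})

test_that("synthetic cohorts reproduce bit-for-bit under the same seed", {
  c1 <- make_cohort(n_patients = 8, grid = c(8, 8, 8), n_tracts = 3,
                    n_pool = 2, missing = c(line_bisection = 1, bells = 1,
                                            letter = 2), seed = 21)
  c2 <- make_cohort(n_patients = 8, grid = c(8, 8, 8), n_tracts = 3,
                    n_pool = 2, missing = c(line_bisection = 1, bells = 1,
                                            letter = 2), seed = 21)
  expect_identical(c1$patient_table, c2$patient_table)
  expect_identical(c1$profiles, c2$profiles)
  expect_identical(c1$labels, c2$labels)
})

test_that("cohort tables honour the configured missingness and stay scorable", {
  co <- tiny_cohort()
  s <- summarize_cohort(co$patient_table)
  expect_equal(unname(s$n_complete),
               c(30 - 2, 30 - 1, 30 - 4))
  # no patient missing from every test
  tab <- co$patient_table
  all_miss <- is.na(tab$line_bisection_pct) & is.na(tab$bells_left) &
    is.na(tab$letter_left)
  expect_false(any(all_miss))
  # re-scoring the table reproduces the generated labels where observed
  sc <- score_cohort(tab)
  for (t in names(co$labels)) {
    s_t <- sc[sc$test == t, ]
    ok <- !is.na(s_t$deficit)
    expect_identical(s_t$deficit[ok], co$labels[[t]]$deficit[ok])
  }
})
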