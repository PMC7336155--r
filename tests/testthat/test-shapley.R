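test_that("exact Shapley values match brute-force ordering enumeration", {
  # 2-player game v(00)=0, v(10)=1, v(01)=0, v(11)=2:
  # ordering (1,2): marginals (1, 1); ordering (2,1): marginals (2, 0)
  # => phi = (1.5, 0.5), frozen from the hand enumeration
  v <- char_fun(function(cfg) ifelse(cfg[, 1] == 1 & cfg[, 2] == 1, 2,
                                     ifelse(cfg[, 1] == 1, 1, 0)), 2)
  expect_equal(unname(exact_shapley(v)), c(1.5, 0.5))

  # additive game: phi_i = w_i (dummy/additivity axiom)
  w <- c(0.3, -1.2, 2, 0.7)
  va <- char_fun(function(cfg) drop(cfg %*% w), 4)
  expect_equal(unname(exact_shapley(va)), w)

  # symmetric game v(S) = |S|: everyone gets 1
  vs <- char_fun(function(cfg) rowSums(cfg), 3)
  expect_equal(unname(exact_shapley(vs)), c(1, 1, 1))

  # general oracle: average marginal over all M! orderings, tiny M
  for (seed in 1:5) {
    M <- 4
    v_r <- random_game(M, seed)
    perms <- as.matrix(expand.grid(rep(list(1:M), M)))
    perms <- perms[apply(perms, 1, function(p) length(unique(p)) == M), ]
    pows <- 2^(0:(M - 1))
    phi_bf <- numeric(M)
    for (r in seq_len(nrow(perms))) {
      p <- perms[r, ]
      prev <- 0
      for (k in seq_len(M)) {
        cur <- prev + pows[p[k]]
        key2cfg <- function(key) matrix((key %/% pows) %% 2, 1)
        phi_bf[p[k]] <- phi_bf[p[k]] +
          v_r$evaluate(key2cfg(cur)) - v_r$evaluate(key2cfg(prev))
        prev <- cur
      }
    }
    phi_bf <- phi_bf / nrow(perms)
    expect_equal(unname(exact_shapley(v_r)), phi_bf)
  }
})

test_that("Shapley axioms hold exactly for exact_shapley on random games", {
  set.seed(99)
  for (rep in 1:50) {
    M <- sample(2:8, 1)
    v <- random_game(M, seed = 1000 + rep)
    phi <- exact_shapley(v)
    full <- matrix(1, 1, M); none <- matrix(0, 1, M)
    expect_equal(sum(phi), v$evaluate(full) - v$evaluate(none),
                 tolerance = 1e-12)
    # dummy: append a player that never changes the worth
    vd <- char_fun(function(cfg) v$evaluate(cfg[, 1:M, drop = FALSE]), M + 1)
    phid <- exact_shapley(vd)
    expect_equal(unname(phid[M + 1]), 0)
    expect_equal(unname(phid[1:M]), unname(phi))
    # symmetry: a game depending only on coalition size treats all equally
    vsym <- char_fun(function(cfg) sqrt(rowSums(cfg) + rep), M)
    expect_equal(diff(range(exact_shapley(vsym))), 0)
  }
  expect_error(exact_shapley(char_fun(function(cfg) rowSums(cfg), 21)),
               "M <= 20")
})

test_that("the permutation estimator is deterministic, unbiased and consistent", {
  v <- random_game(5, seed = 3)
  e1 <- estimated_shapley(v, 200, seed = 7)
  e2 <- estimated_shapley(v, 200, seed = 7)
  expect_identical(e1, e2)

  # full enumeration of orderings reproduces the exact values: average the
  # estimator over many seeds at small M instead (law of large numbers) and
  # check the exact value sits within 3 SE of a big sampled run
  ex <- exact_shapley(v)
  big <- estimated_shapley(v, 5000, seed = 11)
  expect_true(all(abs(big$value - ex) <= 3 * big$se))

  # error decreases in expectation with more sampled orderings
  err_at <- function(np) {
    mean(vapply(1:20, function(s)
      max(abs(estimated_shapley(v, np, seed = s)$value - ex)), numeric(1)))
  }
  errs <- c(err_at(10), err_at(100), err_at(1000))
  expect_true(all(diff(errs) < 0))
})

test_that("contribution normalization preserves sign and rank", {
  expect_equal(normalize_contributions(c(2, -1, 1)), c(0.5, -0.25, 0.25))
  expect_error(normalize_contributions(c(0, 0, 0)), "all-zero")
  set.seed(2)
  raw <- rnorm(8)
  nm <- normalize_contributions(raw)
  expect_equal(sum(abs(nm)), 1)
  expect_equal(sign(nm), sign(raw))
  expect_equal(order(abs(nm)), order(abs(raw)))
})

test_that("bootstrap significance flags follow the percentile interval", {
  boot <- cbind(all_pos = runif(100, 0.1, 0.5),
                sym = c(seq(-1, 1, length.out = 100)),
                mostly_pos = c(rep(-0.1, 2), runif(98, 0.05, 0.4)),
                three_pct = c(rep(-0.1, 3), runif(97, 0.05, 0.4)))
  sig <- flag_significance(boot, level = 0.05)
  expect_true(sig[["all_pos"]])
  expect_false(sig[["sym"]])
  # 2% of the mass below zero: the central 95% interval excludes 0
  expect_true(sig[["mostly_pos"]])
  # 3% below zero: the 2.5th percentile is negative, so 0 is inside
  expect_false(sig[["three_pct"]])
  expect_warning(flag_significance(boot[1:10, ]), "unreliable")
})

test_that("msa fits recover the generating weights on a noiseless cohort", {
  d <- separable_dataset(n = 120, M = 4, seed = 31)
  fit <- suppressMessages(
    msa(d$X, d$y, kernel = "linear", n_perms = 300, n_boot = 60, seed = 2))
  expect_s3_class(fit, "msa")
  # signs of the recovered contributions match the generating weights
  expect_equal(sign(coef(fit)), sign(d$w), ignore_attr = TRUE)
  expect_equal(sum(abs(fit$contributions$normalized)), 1)
  # dispersion strictly positive under resampling
  expect_true(all(fit$contributions$sd_boot > 0))
  # determinism of the whole fit
  fit2 <- suppressMessages(
    msa(d$X, d$y, kernel = "linear", n_perms = 300, n_boot = 60, seed = 2))
  expect_equal(coef(fit2), coef(fit))
  # methods behave
  expect_equal(dim(confint(fit)), c(4, 2))
  expect_output(print(fit), "Multiperturbation")
  expect_silent(grDevices::pdf(NULL)); plot(fit); grDevices::dev.off()
})

test_that("msa with one bootstrap reduces to a single estimated analysis", {
  d <- separable_dataset(n = 50, M = 4, seed = 40)
  fit <- suppressMessages(
    msa(d$X, d$y, kernel = "linear", n_perms = 100, n_boot = 1, seed = 9))
  set.seed(9L)
  idx <- lesionmsa:::.boot_index(d$y)
  ref <- train_predictor(d$X[idx, ], d$y[idx], predictor_spec("linear"))
  est <- estimated_shapley(predictor_char_fun(ref), 100)
  expect_equal(coef(fit), est$value)
  expect_true(all(is.na(fit$contributions$sd_boot)))
})

test_that("degenerate msa inputs are rejected", {
  d <- separable_dataset(n = 30, M = 3, seed = 44)
  expect_error(msa(d$X, rep(1, 30)), "single class")
  expect_error(msa(d$X * 2, d$y), "\\[0,1\\]")
})

test_that("contributors are classified task-invariant vs task-dependent", {
  mk <- function(values, sig) {
    structure(list(
      contributions = data.frame(player = names(values), value = values,
                                 significant = sig),
      players = names(values)), class = "msa")
  }
  players <- c("OR", "IFOF", "CA", "CP", "RoB")
  r1 <- mk(stats::setNames(c(0.3, 0.2, -0.1, 0.2, 0.05), players),
           c(TRUE, TRUE, TRUE, TRUE, TRUE))
  r2 <- mk(stats::setNames(c(0.25, 0.1, -0.2, -0.3, 0.01), players),
           c(TRUE, TRUE, TRUE, TRUE, FALSE))
  r3 <- mk(stats::setNames(c(0.4, 0.15, -0.05, -0.1, -0.02), players),
           c(TRUE, TRUE, TRUE, TRUE, TRUE))
  cl <- classify_contributors(list(bisection = r1, bells = r2, letter = r3))
  expect_equal(cl$classification[cl$player == "OR"], "task-invariant positive")
  expect_equal(cl$classification[cl$player == "IFOF"], "task-invariant positive")
  expect_equal(cl$classification[cl$player == "CA"], "task-invariant negative")
  expect_equal(cl$classification[cl$player == "CP"], "task-dependent")
  # RoB excluded by default, kept on request
  expect_false("RoB" %in% cl$player)
  cl2 <- classify_contributors(list(a = r1, b = r2, c = r3),
                               include_rob = TRUE)
  expect_true("RoB" %in% cl2$player)
  # mismatched player sets rejected
  r_bad <- mk(stats::setNames(1:3, c("X", "Y", "Z")), rep(TRUE, 3))
  expect_error(classify_contributors(list(r1, r_bad)), "identical player set")
})
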