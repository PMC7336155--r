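# Shared small fixtures, built in code at load time.

# tiny synthetic cohort reused across tests (30 patients, 4 tracts + RoB)
tiny_cohort <- function() {
  if (is.null(.fixture_env$tiny))
    .fixture_env$tiny <- make_cohort(
      n_patients = 30, grid = c(10, 10, 10), n_tracts = 4, n_pool = 2,
      noise_sd = 0.1, missing = c(line_bisection = 2, bells = 1, letter = 4),
      size_dist = function(n) round(stats::rlnorm(n, log(60), 0.6)),
      seed = 11)
  .fixture_env$tiny
}
.fixture_env <- new.env()

# linearly separable graded dataset with known weights and a real margin
# around the class boundary
separable_dataset <- function(n = 40, M = 4, seed = 5, noise_sd = 0,
                              margin = 0.15) {
  set.seed(seed)
  X <- matrix(runif(4 * n * M), 4 * n, M,
              dimnames = list(NULL, paste0("T", seq_len(M))))
  w <- c(1, 0.7, -0.5, 0.3)[seq_len(M)]
  latent <- drop(X %*% w) + rnorm(4 * n, 0, noise_sd)
  thr <- median(latent)
  keep <- which(abs(latent - thr) > margin)[seq_len(n)]
  X <- X[keep, , drop = FALSE]
  latent <- latent[keep]
  list(X = X, y = as.integer(latent >= thr), w = w, latent = latent)
}

# random coalition game as a lookup characteristic function; values are a
# reproducible function of the bitmask key
random_game <- function(M, seed) {
  set.seed(seed)
  vals <- rnorm(2^M)
  char_fun(function(cfg) vals[.bitkey(cfg) + 1], M)
}

.bitkey <- function(cfg) drop(cfg %*% 2^(seq_len(ncol(cfg)) - 1))

# cube-shaped binary mask helper
cube_mask <- function(grid, from, to) {
  m <- array(FALSE, grid)
  m[from[1]:to[1], from[2]:to[2], from[3]:to[3]] <- TRUE
  m
}
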