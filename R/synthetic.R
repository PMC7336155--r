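#' Construct a tract atlas object
#'
#' Container for a set of named probabilistic tract volumes on a shared
#' voxel grid, plus an optional pool of additional tract maps that are not
#' coalition players (they define the rest-of-brain region).
#'
#' @param volumes named list of 3D probability arrays (values in [0,1]).
#' @param pool named list of additional probability arrays on the same grid.
#' @return object of class \code{"tract_atlas"}.
#' @export
tract_atlas <- function(volumes, pool = list()) {
  stopifnot(is.list(volumes), length(volumes) >= 1)
  if (is.null(names(volumes)) || anyDuplicated(names(volumes)))
    stop("tract volumes must have unique names")
  grid <- dim(volumes[[1]])
  for (v in c(volumes, pool)) {
    if (!identical(dim(v), grid)) stop("all volumes must share the grid")
    if (any(v < 0 | v > 1)) stop("probabilities must lie in [0,1]")
  }
  structure(list(names = names(volumes), volumes = volumes, pool = pool,
                 grid = grid), class = "tract_atlas")
}

#' @export
print.tract_atlas <- function(x, ...) {
  cat(sprintf("Tract atlas: %d player tracts + %d pool tracts on a %s grid\n",
              length(x$volumes), length(x$pool),
              paste(x$grid, collapse = "x")))
  cat(" ", paste(x$names, collapse = ", "), "\n")
  invisible(x)
}

#' Default white-matter player names
#'
#' The 11 bundles forming the study's coalition (three branches of the
#' superior longitudinal fasciculus, inferior fronto-occipital and inferior
#' longitudinal fasciculi, corpus callosum, anterior thalamic projections,
#' optic radiations, posterior arcuate segment, anterior and posterior
#' cingulum).
#'
#' @param n number of names wanted; generic \code{Tract..} labels are
#'   appended beyond the 11 canonical ones.
#' @return character vector of length \code{n}.
#' @export
default_tract_names <- function(n = 11) {
  base <- c("SLF_I", "SLF_II", "SLF_III", "IFOF", "ILF", "CC", "ATP",
            "OR", "APS", "CA", "CP")
  if (n <= length(base)) base[seq_len(n)]
  else c(base, sprintf("Tract%02d", seq_len(n - length(base))))
}

#' Generate a synthetic probabilistic tract atlas
#'
#' Emulates a probabilistic atlas of white-matter fibers: each tract is a
#' compact Gaussian-profile blob (probability 1 at its core voxel, decaying
#' with distance) centred on a jittered lattice so cores are distinct and
#' supra-0.5 cores of different tracts overlap by less than half. Extra
#' blobs placed the same way form the non-player pool backing the
#' rest-of-brain region.
#'
#' @param grid_shape integer vector of 3 extents, each at least 4.
#' @param n_tracts number of player tracts (at least 2).
#' @param n_pool number of pool tracts (at least 1).
#' @param seed integer RNG seed; identical seeds give identical atlases.
#' @param names optional tract names; defaults to [default_tract_names()].
#' @return a [tract_atlas()].
#' @export
generate_atlas <- function(grid_shape = c(16, 16, 16), n_tracts = 11,
                           n_pool = 4, seed = 1, names = NULL) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3 || any(grid_shape < 4))
    stop("degenerate grid: each extent must be at least 4")
  if (n_tracts < 2) stop("at least 2 tracts are required")
  if (n_pool < 1) stop("at least 1 pool tract is required")
  set.seed(as.integer(seed))
  n_blob <- n_tracts + n_pool
  # lattice with at least twice as many cells as blobs, blob cells picked by
  # greedy farthest-point selection so tract cores stay well separated and
  # single lesions rarely co-damage several tracts
  k <- max(2L, ceiling((2 * n_blob)^(1 / 3)))
  cell <- grid_shape / k
  lattice <- as.matrix(expand.grid(seq_len(k), seq_len(k), seq_len(k)))
  scaled <- sweep(lattice, 2, cell, `*`)     # voxel-space cell centres
  chosen <- sample.int(nrow(lattice), 1)
  mind <- colSums((t(scaled) - scaled[chosen, ])^2)
  while (length(chosen) < n_blob) {
    nxt <- which.max(mind)
    chosen <- c(chosen, nxt)
    mind <- pmin(mind, colSums((t(scaled) - scaled[nxt, ])^2))
  }
  centers <- lattice[chosen, , drop = FALSE]
  ctr_vox <- sapply(1:3, function(a) {
    c0 <- (centers[, a] - 0.5) * cell[a] + 0.5
    j <- round(stats::runif(n_blob, -0.15, 0.15) * cell[a])
    pmin(pmax(round(c0) + j, 1), grid_shape[a])
  })
  sigma <- pmax(cell / 3, 0.45)
  coords <- list(x = slice.index(array(0, grid_shape), 1),
                 y = slice.index(array(0, grid_shape), 2),
                 z = slice.index(array(0, grid_shape), 3))
  blob <- function(i) {
    q <- ((coords$x - ctr_vox[i, 1]) / sigma[1])^2 +
         ((coords$y - ctr_vox[i, 2]) / sigma[2])^2 +
         ((coords$z - ctr_vox[i, 3]) / sigma[3])^2
    exp(-0.5 * q)
  }
  vols <- lapply(seq_len(n_tracts), blob)
  names(vols) <- names %||% default_tract_names(n_tracts)
  pool <- lapply(n_tracts + seq_len(n_pool), blob)
  names(pool) <- sprintf("pool%02d", seq_len(n_pool))
  tract_atlas(vols, pool)
}

# Contiguous blob of 'size' voxels grown by randomized 6-connected
# region growing from a uniformly drawn seed voxel.
.grow_blob <- function(grid, size) {
  mask <- array(FALSE, grid)
  size <- min(size, prod(grid))
  if (size <= 0) return(mask)
  nbr <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
               c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  start <- vapply(grid, function(g) sample.int(g, 1), integer(1))
  frontier <- matrix(start, 1, 3)
  seen <- array(FALSE, grid); seen[matrix(start, 1)] <- TRUE
  n_in <- 0L
  while (n_in < size && nrow(frontier) > 0) {
    pick <- sample.int(nrow(frontier), 1)
    vox <- frontier[pick, ]
    frontier <- frontier[-pick, , drop = FALSE]
    mask[matrix(vox, 1)] <- TRUE
    n_in <- n_in + 1L
    cand <- sweep(nbr, 2, vox, `+`)
    ok <- cand[, 1] >= 1 & cand[, 1] <= grid[1] &
          cand[, 2] >= 1 & cand[, 2] <= grid[2] &
          cand[, 3] >= 1 & cand[, 3] <= grid[3]
    cand <- cand[ok, , drop = FALSE]
    new <- !seen[cand]
    if (any(new)) {
      seen[cand[new, , drop = FALSE]] <- TRUE
      frontier <- rbind(frontier, cand[new, , drop = FALSE])
    }
  }
  mask
}

#' Generate synthetic lesion masks
#'
#' One binary mask per patient on the atlas grid: a spatially contiguous
#' blob grown by randomized region growing from a uniformly placed seed
#' voxel, with extent drawn from \code{size_dist}. A zero-extent draw gives
#' an empty mask.
#'
#' @param atlas a [tract_atlas()] (defines the grid).
#' @param n_patients number of masks.
#' @param size_dist lesion extent in voxels: a function of \code{n}
#'   returning \code{n} sizes, a single number (recycled) or a vector of
#'   length \code{n_patients}. Default: log-normal sizes with median 1.5% of
#'   the grid volume, which keeps pairwise inter-tract damage correlations
#'   low (below about 0.5) as observed in real stroke cohorts.
#' @param seed integer RNG seed.
#' @return named list of logical arrays (\code{patient01}, ...).
#' @export
generate_lesions <- function(atlas, n_patients, size_dist = NULL, seed = 1) {
  stopifnot(inherits(atlas, "tract_atlas"), n_patients >= 1)
  set.seed(as.integer(seed))
  V <- prod(atlas$grid)
  sizes <- if (is.function(size_dist)) size_dist(n_patients)
           else if (is.numeric(size_dist)) rep_len(size_dist, n_patients)
           else round(stats::rlnorm(n_patients, log(0.015 * V), 0.8))
  sizes <- as.integer(round(sizes))
  if (any(sizes < 0) || any(sizes > V))
    stop("lesion sizes must lie in [0, grid volume]")
  out <- lapply(sizes, function(s) .grow_blob(atlas$grid, s))
  names(out) <- sprintf("patient%02d", seq_len(n_patients))
  out
}

#' Ground truth of a synthetic lesion-behavior mapping
#'
#' Defines the linear-threshold generative model behind synthetic behavioral
#' labels: latent performance is the weighted sum of per-player intactness
#' plus Gaussian noise; the label is normal when the latent value reaches
#' the threshold. This is the minimal model under which the Shapley
#' contributions have known signs and ranks, making it the recovery target
#' for validation.
#'
#' @param weights signed per-player contribution weights.
#' @param noise_sd standard deviation (>= 0) of the latent noise.
#' @param threshold latent cut-point; \code{NULL} means "use the median
#'   noiseless latent of the cohort" (balancing the classes), resolved at
#'   generation time.
#' @param seed integer RNG seed for the noise draws.
#' @return object of class \code{"ground_truth"}.
#' @export
ground_truth <- function(weights, noise_sd = 0.25, threshold = NULL,
                         seed = 1) {
  stopifnot(is.numeric(weights), length(weights) >= 1,
            is.numeric(noise_sd), noise_sd >= 0)
  structure(list(weights = weights, noise_sd = noise_sd,
                 threshold = threshold, seed = as.integer(seed)),
            class = "ground_truth")
}

#' Default signed ground-truth weights
#'
#' Descending magnitudes with a mix of positive and negative contributors
#' and a small final weight for the rest-of-brain player.
#'
#' @param M number of players (tracts + rest of brain).
#' @return numeric vector of length \code{M}.
#' @export
default_weights <- function(M) {
  mag <- seq(1, 0.15, length.out = M - 1)
  sgn <- rep(c(1, 1, -1), length.out = M - 1)
  c(mag * sgn, 0.05)
}

#' Generate binary behavioral labels from disconnection profiles
#'
#' Latent performance for patient \eqn{p} is
#' \eqn{\sum_i w_i \, \mathrm{intact}_{p,i} + \epsilon_p},
#' \eqn{\epsilon_p \sim N(0, \sigma^2)}; the outcome is normal (deficit 0)
#' when the latent value is at least the threshold. With \code{noise_sd = 0}
#' the labels are an exact deterministic function of the profiles.
#'
#' @param intact patients-by-players intactness matrix (e.g. the
#'   \code{"intact"} attribute of [profile_cohort()]).
#' @param truth a [ground_truth()] whose weights match the player count.
#' @return data frame with \code{latent}, \code{deficit} (1 = pathological)
#'   and \code{performance} (1 = normal); the resolved threshold is attached
#'   as attribute \code{"threshold"}.
#' @export
generate_behavior <- function(intact, truth) {
  stopifnot(inherits(truth, "ground_truth"))
  intact <- as.matrix(intact)
  if (ncol(intact) != length(truth$weights))
    stop("profile player count (", ncol(intact),
         ") does not match ground-truth weights (", length(truth$weights), ")")
  base <- drop(intact %*% truth$weights)
  thr <- truth$threshold %||% stats::median(base)
  set.seed(truth$seed)
  latent <- base + stats::rnorm(length(base), 0, truth$noise_sd)
  normal <- as.integer(latent >= thr)
  structure(data.frame(latent = latent, deficit = 1L - normal,
                       performance = normal),
            threshold = thr)
}

# Raw test scores consistent with a given binary deficit under the clinical
# cut-off rules (so re-scoring the table reproduces the labels exactly).
.synth_bisection <- function(deficit) {
  vapply(deficit, function(d) {
    mm <- if (d == 1) {
      if (stats::runif(1) < 0.8) stats::runif(1, 6.7, 70)
      else stats::runif(1, -60, -7.5)
    } else stats::runif(1, -7.2, 6.4)
    round(mm / 2, 2)
  }, numeric(1))
}

.synth_bells <- function(deficit) {
  t(vapply(deficit, function(d) {
    if (d == 1) {
      raw <- sample(3:12, 1)
      r <- sample(raw:15, 1)
      c(left = r - raw, right = r)
    } else {
      raw <- sample(-2:2, 1)
      r <- sample(11:15, 1)
      c(left = min(r - raw, 15), right = r)
    }
  }, c(left = 0, right = 0)))
}

.synth_letter <- function(deficit) {
  t(vapply(deficit, function(d) {
    if (d == 1) {
      raw <- -sample(3:20, 1)             # more omissions on the left
      om_l <- sample(seq(-raw, min(30, -raw + 6)), 1)
      om_r <- om_l + raw
    } else {
      raw <- sample(-2:2, 1)
      om_l <- sample(max(0, -raw):3, 1)
      om_r <- om_l + raw
    }
    c(left = 30 - om_l, right = 30 - om_r)
  }, c(left = 0, right = 0)))
}

#' Generate a complete synthetic study cohort
#'
#' Builds a self-contained synthetic study with known ground truth: a
#' probabilistic tract atlas, per-patient contiguous lesion masks, the
#' disconnection profiles they induce, per-test binary outcomes generated by
#' the linear-threshold model, a patient table with raw test scores
#' consistent with those outcomes, and a per-test missingness pattern
#' (default 2/1/6 missing of 25, i.e. the 23/24/19 completion pattern).
#' Missingness is injected completely at random per test and never removes a
#' patient from all three tests at once.
#'
#' @param n_patients cohort size (default 25).
#' @param grid atlas grid extents.
#' @param n_tracts number of named player tracts (default 11, so 12 players
#'   with the rest of brain).
#' @param n_pool pool tracts behind the rest-of-brain region.
#' @param weights ground-truth weights over the \code{n_tracts + 1} players;
#'   default [default_weights()].
#' @param noise_sd latent noise SD shared by the three tests.
#' @param missing named integer vector: patients missing per test.
#' @param atlas_threshold binarization threshold for the atlas.
#' @param size_dist lesion-size distribution, see [generate_lesions()].
#' @param seed master integer seed; the whole cohort is a pure function of
#'   the arguments.
#' @return list of class \code{"synthetic_cohort"}: \code{atlas},
#'   \code{lesions}, \code{patient_table}, \code{profiles} (damage matrix,
#'   intactness in attribute), \code{labels} (per-test data frames before
#'   missingness), \code{truth} (per-test ground truths), \code{seed}.
#' @export
make_cohort <- function(n_patients = 25, grid = c(16, 16, 16),
                        n_tracts = 11, n_pool = 4, weights = NULL,
                        noise_sd = 0.25,
                        missing = c(line_bisection = 2, bells = 1, letter = 6),
                        atlas_threshold = 0.5, size_dist = NULL, seed = 1) {
  seed <- as.integer(seed)
  atlas <- generate_atlas(grid, n_tracts, n_pool, seed = seed)
  lesions <- generate_lesions(atlas, n_patients, size_dist, seed = seed + 1L)
  d <- profile_cohort(lesions, atlas, atlas_threshold)
  intact <- attr(d, "intact")
  weights <- weights %||% default_weights(n_tracts + 1L)
  tests <- c("line_bisection", "bells", "letter")
  truth <- lapply(seq_along(tests), function(i)
    ground_truth(weights, noise_sd, seed = seed + 10L + i))
  names(truth) <- tests
  labels <- lapply(truth, generate_behavior, intact = intact)

  set.seed(seed + 20L)
  tab <- data.frame(
    id = as.character(seq_len(n_patients)),
    sex = sample(c("M", "F"), n_patients, replace = TRUE, prob = c(.68, .32)),
    age = pmin(pmax(round(stats::rnorm(n_patients, 55.96, 10.63)), 18), 90),
    onset_days = pmax(round(stats::rlnorm(n_patients, log(170), 0.6)), 60),
    etiology = sample(c("Ischemic", "Hemorrhagic"), n_patients,
                      replace = TRUE, prob = c(.6, .4)),
    visual_field = sample(c("Normal", "Left extinction", "Left hemianopia"),
                          n_patients, replace = TRUE),
    stringsAsFactors = FALSE)
  tab$line_bisection_pct <- .synth_bisection(labels$line_bisection$deficit)
  bl <- .synth_bells(labels$bells$deficit)
  tab$bells_left <- as.integer(bl[, "left"])
  tab$bells_right <- as.integer(bl[, "right"])
  lt <- .synth_letter(labels$letter$deficit)
  tab$letter_left <- as.integer(lt[, "left"])
  tab$letter_right <- as.integer(lt[, "right"])

  stopifnot(all(names(missing) %in% tests), all(missing >= 0),
            all(missing <= n_patients))
  set.seed(seed + 30L)
  for (try in 1:200) {
    miss_idx <- lapply(tests, function(t) {
      m <- if (t %in% names(missing)) missing[[t]] else 0L
      if (m > 0) sample.int(n_patients, m) else integer(0)
    })
    names(miss_idx) <- tests
    all_missing <- Reduce(intersect, miss_idx)
    if (length(all_missing) == 0) break
    if (try == 200) stop("could not satisfy the missingness constraint")
  }
  tab$line_bisection_pct[miss_idx$line_bisection] <- NA
  tab$bells_left[miss_idx$bells] <- NA
  tab$bells_right[miss_idx$bells] <- NA
  tab$letter_left[miss_idx$letter] <- NA
  tab$letter_right[miss_idx$letter] <- NA
  class(tab) <- c("patient_table", "data.frame")

  structure(list(atlas = atlas, lesions = lesions, patient_table = tab,
                 profiles = d, labels = labels, truth = truth,
                 atlas_threshold = atlas_threshold, seed = seed),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d patients, %d players (+RoB), seed %d\n",
              nrow(x$patient_table), length(x$atlas$names), x$seed))
  print(x$atlas)
  invisible(x)
}
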