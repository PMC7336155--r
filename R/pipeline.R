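#' Configuration of an end-to-end MSA run
#'
#' Collects paths and parameters for [run_pipeline()]. Defaults reproduce
#' the study settings: 1,000 sampled permutations, 1,000 bootstrap samples,
#' box constraint 1, and the per-test kernels (linear for line bisection,
#' polynomial for bells cancellation, quadratic for letter cancellation).
#'
#' @param atlas_dir directory of player tract volumes (\code{<name>.nii.gz})
#'   with a \code{pool/} subdirectory of non-player volumes.
#' @param lesion_dir directory of per-patient lesion masks, one NIfTI per
#'   patient, sorted by file name.
#' @param patient_table CSV path, see [read_patient_table()].
#' @param out_dir output directory (created on run).
#' @param atlas_threshold tract binarization threshold in (0,1).
#' @param kernels named character vector: SVM kernel per test.
#' @param cost SVM box constraint.
#' @param n_perms,n_boot sampled orderings and bootstrap samples per test.
#' @param chance_reps label permutations for the chance level.
#' @param seed master integer seed.
#' @param level significance level for bootstrap intervals and correlation
#'   masking.
#' @param normalization contribution normalization mode, see [msa()].
#' @return list of class \code{"run_config"}.
#' @export
run_config <- function(atlas_dir, lesion_dir, patient_table, out_dir,
                       atlas_threshold = 0.5,
                       kernels = c(line_bisection = "linear",
                                   bells = "polynomial",
                                   letter = "quadratic"),
                       cost = 1, n_perms = 1000, n_boot = 1000,
                       chance_reps = 1000, seed = 1, level = 0.05,
                       normalization = "sum_abs") {
  cfg <- list(atlas_dir = atlas_dir, lesion_dir = lesion_dir,
              patient_table = patient_table, out_dir = out_dir,
              atlas_threshold = atlas_threshold, kernels = kernels,
              cost = cost, n_perms = n_perms, n_boot = n_boot,
              chance_reps = chance_reps, seed = as.integer(seed),
              level = level, normalization = normalization)
  class(cfg) <- "run_config"
  cfg
}

#' Validate a run configuration
#'
#' Checks that all referenced paths exist and numeric parameters are in
#' range, before any computation starts.
#'
#' @param config a [run_config()].
#' @return the config, invisibly; errors describe the offending field.
#' @export
validate_config <- function(config) {
  stopifnot(inherits(config, "run_config"))
  for (f in c("atlas_dir", "lesion_dir")) {
    if (!dir.exists(config[[f]]))
      stop("config: ", f, " does not exist: ", config[[f]])
  }
  if (!file.exists(config$patient_table))
    stop("config: patient_table does not exist: ", config$patient_table)
  tests <- c("line_bisection", "bells", "letter")
  if (!all(tests %in% names(config$kernels)))
    stop("config: kernels must name all of ", paste(tests, collapse = ", "))
  if (!all(config$kernels %in% c("linear", "polynomial", "quadratic")))
    stop("config: unknown kernel")
  with(config, stopifnot(atlas_threshold > 0, atlas_threshold < 1,
                         cost > 0, n_perms >= 1, n_boot >= 1,
                         chance_reps >= 1, level > 0, level < 1))
  invisible(config)
}

#' Read a run configuration from YAML
#' @param path YAML file with the [run_config()] fields.
#' @return a \code{"run_config"}.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  y$kernels <- unlist(y$kernels)
  do.call(run_config, y)
}

#' Write a run configuration as YAML
#' @param config a [run_config()].
#' @param path output path.
#' @export
write_run_config <- function(config, path) {
  cfg <- unclass(config)
  cfg$kernels <- as.list(cfg$kernels)   # yaml drops names of atomic vectors
  yaml::write_yaml(cfg, path)
  invisible(path)
}

.read_atlas_dir <- function(atlas_dir) {
  files <- sort(list.files(atlas_dir, pattern = "\\.nii(\\.gz)?$",
                           full.names = TRUE))
  if (!length(files)) stop("no tract volumes found in ", atlas_dir)
  vols <- lapply(files, function(f) {
    v <- RNifti::readNifti(f)
    array(as.numeric(v), dim = dim(v))
  })
  names(vols) <- sub("\\.nii(\\.gz)?$", "", basename(files))
  pool_dir <- file.path(atlas_dir, "pool")
  pool <- list()
  if (dir.exists(pool_dir)) {
    pf <- sort(list.files(pool_dir, pattern = "\\.nii(\\.gz)?$",
                          full.names = TRUE))
    pool <- lapply(pf, function(f) {
      v <- RNifti::readNifti(f)
      array(as.numeric(v), dim = dim(v))
    })
    names(pool) <- sub("\\.nii(\\.gz)?$", "", basename(pf))
  }
  tract_atlas(vols, pool)
}

.read_lesion_dir <- function(lesion_dir) {
  files <- sort(list.files(lesion_dir, pattern = "\\.nii(\\.gz)?$",
                           full.names = TRUE))
  if (!length(files)) stop("no lesion masks found in ", lesion_dir)
  out <- lapply(files, function(f) {
    v <- RNifti::readNifti(f)
    array(as.numeric(v) != 0, dim = dim(v))
  })
  names(out) <- sub("\\.nii(\\.gz)?$", "", basename(files))
  out
}

#' Write a synthetic study directory
#'
#' Emits a self-contained runnable study from [make_cohort()]: NIfTI tract
#' volumes (players plus a \code{pool/} subdirectory), per-patient NIfTI
#' lesion masks, the patient table CSV, and a JSON sidecar with the
#' generating ground truth. The directory is accepted unchanged by
#' [run_pipeline()] via the returned config.
#'
#' @param dir target directory (created).
#' @param ... passed to [make_cohort()] (e.g. \code{n_patients},
#'   \code{seed}, \code{missing}).
#' @param n_perms,n_boot,chance_reps analysis settings stored in the
#'   returned config.
#' @return a [run_config()] pointing at the new study, with the generated
#'   cohort attached as attribute \code{"cohort"}.
#' @export
make_fixture <- function(dir, ..., n_perms = 1000, n_boot = 1000,
                         chance_reps = 1000) {
  cohort <- make_cohort(...)
  atlas_dir <- file.path(dir, "atlas")
  lesion_dir <- file.path(dir, "lesions")
  dir.create(file.path(atlas_dir, "pool"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(lesion_dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(cohort$atlas$volumes))
    RNifti::writeNifti(cohort$atlas$volumes[[nm]],
                       file.path(atlas_dir, paste0(nm, ".nii.gz")))
  for (nm in names(cohort$atlas$pool))
    RNifti::writeNifti(cohort$atlas$pool[[nm]],
                       file.path(atlas_dir, "pool", paste0(nm, ".nii.gz")))
  for (nm in names(cohort$lesions))
    RNifti::writeNifti(cohort$lesions[[nm]] + 0,
                       file.path(lesion_dir, paste0(nm, ".nii.gz")))
  write_patient_table(cohort$patient_table, file.path(dir, "patient_table.csv"))
  truth <- lapply(cohort$truth, function(t)
    list(weights = t$weights, noise_sd = t$noise_sd,
         threshold = t$threshold, seed = t$seed))
  jsonlite::write_json(list(players = c(cohort$atlas$names, "RoB"),
                            truth = truth, seed = cohort$seed),
                       file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  cfg <- run_config(atlas_dir = atlas_dir, lesion_dir = lesion_dir,
                    patient_table = file.path(dir, "patient_table.csv"),
                    out_dir = file.path(dir, "results"),
                    atlas_threshold = cohort$atlas_threshold,
                    seed = cohort$seed, n_perms = n_perms, n_boot = n_boot,
                    chance_reps = chance_reps)
  attr(cfg, "cohort") <- cohort
  cfg
}

.stage <- function(name, expr) {
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
  message(sprintf("[%s] done in %.1fs", name,
                  proc.time()[["elapsed"]] - t0))
  res
}

#' Run the full lesion-inference pipeline
#'
#' Orchestrates the end-to-end analysis: disconnection profiles from lesions
#' and atlas, behavioral scoring and per-test graded datasets formed inside
#' the pipeline from missingness, lesion-pattern correlation diagnostics,
#' predictor validation, bootstrap MSA per test, contributor classification,
#' and a machine-readable run manifest. All tables are written as CSV with
#' named player/test headers; the manifest (JSON) records config, seed and
#' package version so a rerun regenerates identical outputs.
#'
#' @param config a validated [run_config()].
#' @return invisibly, a list with \code{profiles}, \code{summary},
#'   \code{correlations}, \code{validation}, \code{fits} (per-test
#'   \code{"msa"} objects), and \code{classification}.
#' @export
run_pipeline <- function(config) {
  validate_config(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  tests <- c("line_bisection", "bells", "letter")

  atlas <- .stage("read-atlas", .read_atlas_dir(config$atlas_dir))
  lesions <- .stage("read-lesions", .read_lesion_dir(config$lesion_dir))
  records <- .stage("read-table", read_patient_table(config$patient_table))
  if (length(lesions) != nrow(records))
    stop("lesion count (", length(lesions), ") does not match patient table (",
         nrow(records), ")")
  names(lesions) <- records$id

  d <- .stage("profiles", profile_cohort(lesions, atlas,
                                         config$atlas_threshold))
  utils::write.csv(data.frame(id = rownames(d), round(d, 6),
                              check.names = FALSE),
                   file.path(config$out_dir, "disconnection_fraction.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(id = rownames(d), round(100 * d, 4),
                              check.names = FALSE),
                   file.path(config$out_dir, "disconnection_percent.csv"),
                   row.names = FALSE)
  scores <- .stage("behavior", score_cohort(records))
  utils::write.csv(scores, file.path(config$out_dir, "behavior_scores.csv"),
                   row.names = FALSE)
  summary_tab <- summarize_cohort(records)
  jsonlite::write_json(unclass(summary_tab),
                       file.path(config$out_dir, "cohort_summary.json"),
                       auto_unbox = TRUE, digits = NA)

  intact <- attr(d, "intact")
  rownames(intact) <- records$id
  datasets <- lapply(tests, function(t)
    graded_dataset(intact, scores, t, ids = records$id))
  names(datasets) <- tests

  cors <- .stage("correlations", {
    lapply(datasets, function(ds) {
      sub <- d[ds$patient_ids, colnames(d) != "RoB", drop = FALSE]
      cm <- suppressWarnings(
        lesion_correlation_matrix(sub, level = config$level))
      utils::write.csv(round(cm$r, 4),
                       file.path(config$out_dir,
                                 paste0("lesion_correlation_", ds$test, ".csv")))
      cm
    })
  })

  validation <- .stage("validate", {
    out <- lapply(tests, function(t) {
      ds <- datasets[[t]]
      spec <- predictor_spec(config$kernels[[t]], cost = config$cost)
      validate_predictor(ds$X, ds$y, spec, reps = config$chance_reps,
                         seed = config$seed)
    })
    names(out) <- tests
    vtab <- do.call(rbind, lapply(tests, function(t) {
      v <- out[[t]]
      data.frame(test = t, n = v$n, kernel = config$kernels[[t]],
                 loo_accuracy = v$loo_accuracy,
                 chance_level = v$chance_level,
                 chance_level_exact = v$chance_level_exact,
                 youden = v$youden, sensitivity = v$sensitivity,
                 specificity = v$specificity)
    }))
    utils::write.csv(vtab, file.path(config$out_dir, "validation.csv"),
                     row.names = FALSE)
    out
  })

  fits <- .stage("msa", {
    out <- lapply(tests, function(t) {
      ds <- datasets[[t]]
      suppressMessages(msa(ds$X, ds$y, kernel = config$kernels[[t]],
                           cost = config$cost, n_perms = config$n_perms,
                           n_boot = config$n_boot, seed = config$seed,
                           level = config$level,
                           normalization = config$normalization, test = t))
    })
    names(out) <- tests
    ctab <- do.call(rbind, lapply(out, function(f)
      cbind(test = f$test, f$contributions)))
    utils::write.csv(ctab, file.path(config$out_dir, "contributions.csv"),
                     row.names = FALSE)
    out
  })

  classification <- .stage("classify", {
    cl <- classify_contributors(fits)
    utils::write.csv(as.data.frame(cl),
                     file.path(config$out_dir, "classification.csv"),
                     row.names = FALSE)
    cl
  })

  manifest <- list(
    config = unclass(config), seed = config$seed,
    package = "lesionmsa",
    version = as.character(utils::packageVersion("lesionmsa")),
    r_version = R.version.string,
    players = colnames(d), tests = tests,
    n_patients = nrow(records),
    subcohorts = as.list(vapply(datasets, function(x) nrow(x$X), integer(1))),
    redrawn_resamples = as.list(vapply(fits, `[[`, integer(1), "redraws")))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(profiles = d, summary = summary_tab, datasets = datasets,
                 correlations = cors, validation = validation, fits = fits,
                 classification = classification, manifest = manifest))
}
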