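#' Binarize a probabilistic tract map
#'
#' A voxel belongs to the binary tract mask when its probability of belonging
#' to the bundle is at least \code{threshold}.
#'
#' @param prob_volume 3D array of probabilities in [0,1].
#' @param threshold probability cut in (0,1); default 0.5.
#' @return logical array of the same dimensions; a warning is raised if the
#'   mask is empty.
#' @export
binarize_tract <- function(prob_volume, threshold = 0.5) {
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      threshold <= 0 || threshold >= 1)
    stop("'threshold' must lie strictly inside (0,1)")
  if (any(prob_volume < 0 | prob_volume > 1, na.rm = TRUE))
    stop("probability volume has values outside [0,1]")
  mask <- prob_volume >= threshold
  if (!any(mask)) warning("binarized tract mask is empty")
  mask
}

.check_same_grid <- function(a, b) {
  if (!identical(dim(a), dim(b)))
    stop("masks are not on the same voxel grid (",
         paste(dim(a), collapse = "x"), " vs ",
         paste(dim(b), collapse = "x"), ")")
}

#' Disconnection fraction of a tract
#'
#' The proportion of a tract's voxels intersected by a lesion mask,
#' \eqn{d(\mathrm{lesion}, \mathrm{bundle}) =
#' \#(\mathrm{lesion} \cap \mathrm{bundle}) / \#\mathrm{bundle}},
#' with voxels counted unweighted. Stored as a fraction in [0,1]; multiply by
#' 100 for the percent form.
#'
#' @param lesion,tract logical (or 0/1) arrays on the same grid; the tract
#'   must be non-empty.
#' @return fraction of damaged tract voxels.
#' @export
disconnection_fraction <- function(lesion, tract) {
  .check_same_grid(lesion, tract)
  nb <- sum(tract != 0)
  if (nb == 0) stop("tract mask is empty: disconnection fraction undefined")
  sum(lesion != 0 & tract != 0) / nb
}

#' Rest-of-brain damage fraction
#'
#' Damage to white matter not among the selected players: the lesioned share
#' of the union of the pool tracts, with voxels that also belong to a player
#' tract removed from the region (so they are not double-counted against the
#' rest of brain).
#'
#' @param lesion logical lesion mask.
#' @param players list of binary player-tract masks.
#' @param pool non-empty list of binary masks of the tracts not in the player
#'   set.
#' @return fraction in [0,1].
#' @export
rob_fraction <- function(lesion, players, pool) {
  if (length(pool) == 0) stop("pool of non-player tracts is empty")
  U <- Reduce(`|`, lapply(pool, function(m) m != 0))
  .check_same_grid(lesion, U)
  if (length(players)) {
    P <- Reduce(`|`, lapply(players, function(m) m != 0))
    U <- U & !P
  }
  if (!any(U)) stop("rest-of-brain region is empty after removing player voxels")
  sum(lesion != 0 & U) / sum(U)
}

#' Disconnection profile of one patient
#'
#' Applies the disconnection metric to every named tract of the atlas
#' (binarized at \code{threshold}) plus the rest-of-brain region, yielding
#' the damaged-fraction vector \code{d} and its complement \code{intact}
#' (1 = complete preservation, 0 = complete damage) that forms one row of the
#' graded dataset.
#'
#' @param lesion binary lesion mask on the atlas grid.
#' @param atlas a [tract_atlas()].
#' @param threshold atlas binarization threshold, see [binarize_tract()].
#' @param patient_id optional identifier carried along.
#' @return list of class \code{"disconnection_profile"} with named vectors
#'   \code{d} and \code{intact} (players = tracts + \code{"RoB"}).
#' @export
profile_patient <- function(lesion, atlas, threshold = 0.5,
                            patient_id = NULL) {
  stopifnot(inherits(atlas, "tract_atlas"))
  masks <- lapply(atlas$volumes, binarize_tract, threshold = threshold)
  d <- vapply(masks, function(m) disconnection_fraction(lesion, m),
              numeric(1))
  pool_masks <- lapply(atlas$pool, binarize_tract, threshold = threshold)
  d <- c(d, RoB = rob_fraction(lesion, masks, pool_masks))
  structure(list(patient_id = patient_id, d = d, intact = 1 - d),
            class = "disconnection_profile")
}

#' @export
print.disconnection_profile <- function(x, digits = 3, ...) {
  cat("Disconnection profile",
      if (!is.null(x$patient_id)) paste0("(", x$patient_id, ")"), "\n")
  print(round(x$d, digits))
  invisible(x)
}

#' Disconnection profiles for a whole cohort
#'
#' @param lesions list of binary lesion masks (one per patient; names become
#'   row names).
#' @param atlas a [tract_atlas()].
#' @inheritParams profile_patient
#' @return patients-by-players matrix of damaged fractions \code{d}; the
#'   intactness matrix \code{1 - d} is attached as attribute
#'   \code{"intact"}.
#' @export
profile_cohort <- function(lesions, atlas, threshold = 0.5) {
  profs <- lapply(seq_along(lesions), function(i)
    profile_patient(lesions[[i]], atlas, threshold,
                    patient_id = names(lesions)[i]))
  d <- do.call(rbind, lapply(profs, `[[`, "d"))
  rownames(d) <- names(lesions) %||% paste0("patient", seq_along(lesions))
  structure(d, intact = 1 - d)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Pairwise lesion-pattern correlations across tracts
#'
#' Pearson correlations, over patients, between the per-tract damage columns
#' of a cohort's disconnection profiles — the diagnostic for lesion
#' covariance induced by shared vascular territories. Entries whose
#' two-sided p-value is at or above \code{level} are flagged masked;
#' zero-variance tracts give NA rows/columns and are reported, not silently
#' zeroed.
#'
#' @param d patients-by-tracts matrix of damaged fractions (at least 3
#'   rows), e.g. from [profile_cohort()].
#' @param level significance level for masking (default 0.05).
#' @param reorder reorder tracts so strongly correlated pairs sit near the
#'   diagonal (average-linkage clustering of \code{1 - r})?
#' @return list of class \code{"lesion_cor"}: matrices \code{r}, \code{p},
#'   logical \code{masked}, the tract \code{order} used, and
#'   \code{undefined} (names of zero-variance tracts).
#' @export
lesion_correlation_matrix <- function(d, level = 0.05, reorder = FALSE) {
  d <- as.matrix(d)
  if (nrow(d) < 3) stop("at least 3 patients are required")
  k <- ncol(d)
  nm <- colnames(d) %||% paste0("T", seq_len(k))
  vars <- apply(d, 2, stats::var)
  undefined <- nm[vars == 0]
  if (length(undefined))
    warning("zero-variance tract(s): ", paste(undefined, collapse = ", "),
            "; correlation undefined")
  r <- suppressWarnings(stats::cor(d))
  p <- matrix(NA_real_, k, k, dimnames = list(nm, nm))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i == j) { p[i, j] <- 0; next }
    if (vars[i] == 0 || vars[j] == 0) next
    p[i, j] <- stats::cor.test(d[, i], d[, j])$p.value
  }
  dimnames(r) <- list(nm, nm)
  ord <- seq_len(k)
  if (reorder && k > 2) {
    ok <- which(vars > 0)
    if (length(ok) > 2) {
      h <- stats::hclust(stats::as.dist(1 - abs(r[ok, ok])), method = "average")
      ord <- c(ok[h$order], setdiff(seq_len(k), ok))
    }
    r <- r[ord, ord]; p <- p[ord, ord]
  }
  structure(list(r = r, p = p, masked = p >= level, level = level,
                 order = ord, undefined = undefined, n = nrow(d)),
            class = "lesion_cor")
}

#' @export
print.lesion_cor <- function(x, digits = 2, ...) {
  cat(sprintf("Pairwise lesion-pattern Pearson correlations (n = %d)\n", x$n))
  shown <- round(x$r, digits)
  shown[x$masked & !is.na(x$masked)] <- NA
  cat(sprintf("  (entries with p >= %.2f masked as NA)\n", x$level))
  print(shown)
  invisible(x)
}

#' Heatmap of the lesion correlation matrix
#'
#' Significant correlations in graded colors; non-significant entries
#' blacked out.
#'
#' @param x a [lesion_correlation_matrix()] result.
#' @param ... passed to [graphics::image()].
#' @export
plot.lesion_cor <- function(x, ...) {
  k <- ncol(x$r)
  z <- x$r
  z[x$masked & !is.na(x$masked)] <- NA
  pal <- grDevices::hcl.colors(64, "Blue-Red 3")
  graphics::image(seq_len(k), seq_len(k), t(z[k:1, , drop = FALSE]),
                  zlim = c(-1, 1), col = pal, axes = FALSE,
                  xlab = "", ylab = "", ...)
  na_idx <- which(is.na(t(z[k:1, , drop = FALSE])), arr.ind = TRUE)
  if (nrow(na_idx))
    graphics::rect(na_idx[, 1] - 0.5, na_idx[, 2] - 0.5,
                   na_idx[, 1] + 0.5, na_idx[, 2] + 0.5, col = "black")
  graphics::axis(1, seq_len(k), colnames(x$r), las = 2, cex.axis = 0.8)
  graphics::axis(2, seq_len(k), rev(rownames(x$r)), las = 2, cex.axis = 0.8)
  invisible(x)
}
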