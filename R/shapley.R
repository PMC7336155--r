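#' Characteristic function of a perturbation game
#'
#' Wraps a vectorized evaluator of perturbation configurations as the
#' characteristic function of a coalition game over \code{M} players.
#' A configuration is a binary vector with 0 meaning the player is perturbed
#' (fully damaged) and 1 meaning it is intact; the coalition is the set of
#' intact players.
#'
#' @param evaluate function taking an \code{n x M} 0/1 matrix of
#'   configurations (rows) and returning a numeric vector of length \code{n}
#'   of performance values. Must be deterministic.
#' @param M number of players.
#' @param players optional character vector of player names (length \code{M}).
#' @return An object of class \code{"char_fun"}.
#' @seealso [exact_shapley()], [estimated_shapley()], [predictor_char_fun()]
#' @export
#' @examples
#' v <- char_fun(function(cfg) rowSums(cfg), M = 3)
#' exact_shapley(v)  # additive game: each player gets its own weight
char_fun <- function(evaluate, M, players = NULL) {
  stopifnot(is.function(evaluate), length(M) == 1L, M >= 1)
  M <- as.integer(M)
  if (is.null(players)) players <- paste0("P", seq_len(M))
  if (length(players) != M) stop("'players' must have length M")
  structure(list(evaluate = evaluate, M = M, players = players),
            class = "char_fun")
}

#' @export
print.char_fun <- function(x, ...) {
  cat("Characteristic function over", x$M, "players:\n ",
      paste(x$players, collapse = ", "), "\n")
  invisible(x)
}

# Row-wise bitmask keys; exact in double up to M = 50.
.config_keys <- function(configs) {
  M <- ncol(configs)
  if (M > 50) stop("bitmask keying supports at most 50 players")
  drop(configs %*% 2^(seq_len(M) - 1))
}

# Decode bitmask keys back into a 0/1 configuration matrix.
.keys_to_configs <- function(keys, M) {
  pows <- 2^(seq_len(M) - 1)
  cfg <- outer(keys, pows, function(k, p) (k %/% p) %% 2)
  storage.mode(cfg) <- "integer"
  cfg
}

# Evaluate v on a key matrix, calling the evaluator once per unique
# configuration.  Returns a numeric object shaped like 'keys'.
.eval_keys <- function(v, keys) {
  uk <- unique(as.vector(keys))
  vals <- v$evaluate(.keys_to_configs(uk, v$M))
  if (length(vals) != length(uk) || anyNA(vals))
    stop("characteristic function returned invalid values")
  out <- vals[match(as.vector(keys), uk)]
  if (is.matrix(keys)) dim(out) <- dim(keys)
  out
}

#' Exact Shapley values by full coalition enumeration
#'
#' Computes the Shapley value of every player by enumerating all \code{2^M}
#' perturbation configurations, i.e. the coalition-based multiperturbation
#' analysis. For player \eqn{i},
#' \deqn{\phi_i = \sum_{S \not\ni i} \frac{|S|!\,(M-|S|-1)!}{M!}
#'   \left[v(S \cup \{i\}) - v(S)\right]}
#' where a coalition \eqn{S} is a set of intact players. The values satisfy
#' efficiency (\eqn{\sum_i \phi_i = v(\mathrm{all}) - v(\emptyset)}),
#' symmetry and the dummy axiom exactly.
#'
#' @param v a [char_fun()] object with \code{M <= 20} players.
#' @return Named numeric vector of Shapley values.
#' @export
exact_shapley <- function(v) {
  stopifnot(inherits(v, "char_fun"))
  M <- v$M
  if (M > 20)
    stop("exact enumeration is limited to M <= 20; use estimated_shapley()")
  n <- 2^M
  keys <- 0:(n - 1)
  vals <- v$evaluate(.keys_to_configs(keys, M))
  if (length(vals) != n) stop("characteristic function returned wrong length")
  pows <- 2^(seq_len(M) - 1)
  sizes <- rowSums(.keys_to_configs(keys, M))
  # w[s + 1] = s! (M - s - 1)! / M!  for coalition size s of the predecessors
  s <- 0:(M - 1)
  w <- exp(lfactorial(s) + lfactorial(M - s - 1) - lfactorial(M))
  phi <- numeric(M)
  for (i in seq_len(M)) {
    without <- which(keys %/% pows[i] %% 2 == 0)
    phi[i] <- sum(w[sizes[without] + 1] *
                    (vals[without + pows[i]] - vals[without]))
  }
  names(phi) <- v$players
  phi
}

#' Permutation-sampled (estimated) Shapley values
#'
#' Unbiased estimator of the Shapley values for games too large to enumerate:
#' player orderings are sampled uniformly; in each ordering every player
#' receives its marginal contribution \eqn{v(\mathrm{pred} \cup \{i\}) -
#' v(\mathrm{pred})}, all players not yet entered being perturbed. Estimates
#' are means over the sampled orderings; standard errors are the per-player
#' standard deviations of the marginals divided by \code{sqrt(n_perms)}.
#'
#' Configurations are memoised by bitmask, so the evaluator is called at most
#' once per distinct configuration (at most \code{2^M}).
#'
#' @param v a [char_fun()] object.
#' @param n_perms number of sampled player orderings (the study default is
#'   1,000).
#' @param seed optional integer seed; if \code{NULL} the current RNG state is
#'   used (so callers embedding this in a larger stochastic procedure keep a
#'   single reproducible stream).
#' @return A list of class \code{"shapley_estimate"} with components
#'   \code{value}, \code{se} (both named), \code{n_perms} and \code{M}.
#' @export
estimated_shapley <- function(v, n_perms = 1000, seed = NULL) {
  stopifnot(inherits(v, "char_fun"), n_perms >= 1)
  if (!is.null(seed)) set.seed(seed)
  M <- v$M
  pows <- 2^(seq_len(M) - 1)
  perms <- t(vapply(seq_len(n_perms), function(i) sample.int(M),
                    integer(M)))
  # cumulative coalition keys along each ordering
  keys <- t(apply(perms, 1L, function(p) cumsum(pows[p])))
  if (n_perms == 1L) keys <- matrix(keys, nrow = 1L)
  vmat <- .eval_keys(v, keys)
  v0 <- .eval_keys(v, matrix(0, 1, 1))[1]
  marg <- vmat - cbind(rep(v0, n_perms),
                       vmat[, -M, drop = FALSE])
  contrib <- matrix(NA_real_, n_perms, M)
  contrib[cbind(rep(seq_len(n_perms), M), as.vector(perms))] <-
    as.vector(marg)
  value <- colMeans(contrib)
  se <- if (n_perms > 1) apply(contrib, 2, stats::sd) / sqrt(n_perms)
        else rep(NA_real_, M)
  names(value) <- names(se) <- v$players
  structure(list(value = value, se = se, n_perms = n_perms, M = M),
            class = "shapley_estimate")
}

#' @export
print.shapley_estimate <- function(x, digits = 4, ...) {
  cat("Estimated Shapley values (", x$n_perms, " sampled orderings)\n",
      sep = "")
  print(round(rbind(value = x$value, se = x$se), digits))
  invisible(x)
}

#' Normalize signed contribution values
#'
#' Divides each contribution by the sum of absolute contributions, so signs
#' are preserved and the absolute normalized values sum to one — magnitudes
#' become comparable across tasks.
#'
#' @param raw numeric vector of contributions (not all zero).
#' @return numeric vector of the same length.
#' @export
normalize_contributions <- function(raw) {
  stopifnot(is.numeric(raw))
  tot <- sum(abs(raw))
  if (tot == 0) stop("cannot normalize an all-zero contribution vector")
  raw / tot
}

#' Flag players whose bootstrap interval excludes zero
#'
#' A player is flagged significant when the central \code{(1 - level)}
#' percentile interval of its bootstrap contribution distribution excludes 0.
#'
#' @param boot \code{n_boot x M} matrix of per-bootstrap contribution values,
#'   or an \code{"msa"} object (its stored bootstrap matrix is used).
#' @param level two-sided significance level (default 0.05).
#' @return logical vector of length \code{M} (with the interval bounds in
#'   attributes \code{"lower"}/\code{"upper"}), or the updated \code{"msa"}
#'   object when one was supplied.
#' @export
flag_significance <- function(boot, level = 0.05) {
  if (inherits(boot, "msa")) {
    obj <- boot
    sig <- flag_significance(obj$boot, level)
    obj$contributions$significant <- as.vector(sig)
    obj$level <- level
    return(obj)
  }
  stopifnot(is.matrix(boot), level > 0, level < 1)
  if (nrow(boot) < 20)
    warning("fewer than 20 bootstrap replicates: percentile intervals are unreliable")
  lo <- apply(boot, 2, stats::quantile, probs = level / 2, names = FALSE)
  hi <- apply(boot, 2, stats::quantile, probs = 1 - level / 2, names = FALSE)
  structure(lo > 0 | hi < 0, lower = lo, upper = hi)
}

# Draw a bootstrap index vector whose labels keep both classes.
.boot_index <- function(y, max_tries = 100) {
  n <- length(y)
  for (k in seq_len(max_tries)) {
    idx <- sample.int(n, n, replace = TRUE)
    if (length(unique(y[idx])) == 2L)
      return(structure(idx, redraws = k - 1L))
  }
  stop("could not draw a two-class bootstrap resample in ", max_tries,
       " attempts")
}

#' Bootstrap multiperturbation Shapley value analysis
#'
#' Fits the full MSA estimator to a graded lesion dataset: for each bootstrap
#' resample of patients (with replacement, original size) a support-vector
#' performance predictor is retrained and used as the characteristic function
#' of a perturbation game over the tracts, whose Shapley values are estimated
#' from sampled player orderings. Per-player contributions are averaged
#' across bootstrap samples; their bootstrap dispersion and percentile
#' intervals quantify uncertainty. Resamples whose labels collapse to a
#' single class are redrawn (the count is recorded).
#'
#' @param x patients-by-players matrix of tract intactness in \code{[0,1]}
#'   (1 = fully preserved, 0 = completely damaged). Column names become the
#'   player names.
#' @param y binary performance labels (1 = normal, 0 = pathological), one per
#'   row of \code{x}; both classes must be present.
#' @param kernel SVM kernel: \code{"linear"}, \code{"polynomial"} (degree 3)
#'   or \code{"quadratic"} (polynomial of degree 2).
#' @param cost SVM box constraint (default 1).
#' @param degree optional override of the polynomial degree.
#' @param n_perms sampled player orderings per Shapley estimation
#'   (study default 1,000).
#' @param n_boot bootstrap resamples (study default 1,000).
#' @param seed integer seed governing all randomness of the fit.
#' @param level two-sided level for the bootstrap significance flag.
#' @param normalization \code{"sum_abs"} divides contributions by the sum of
#'   their absolute values; \code{"grand"} divides by
#'   \eqn{v(\mathrm{all\ intact}) - v(\mathrm{none\ intact})} of the
#'   full-data predictor.
#' @param test optional label naming the behavioral test the dataset came
#'   from (carried into printouts and classification tables).
#' @return An object of class \code{"msa"}: a list with the per-player
#'   \code{contributions} data frame (value, bootstrap SD, mean permutation
#'   SE, normalized value, significance flag, sign), the \code{boot} matrix
#'   of per-resample values, the full-data \code{predictor}, and the call
#'   settings. Methods: \code{print}, \code{summary}, \code{coef},
#'   \code{confint}, \code{plot}.
#' @seealso [estimated_shapley()], [train_predictor()],
#'   [classify_contributors()]
#' @export
#' @examples
#' set.seed(1)
#' X <- matrix(runif(60 * 4), 60, 4,
#'             dimnames = list(NULL, c("SLF_II", "IFOF", "OR", "CA")))
#' y <- as.integer(X %*% c(1, 0.8, 0.6, -0.5) + rnorm(60, 0, 0.1) > 1.4)
#' fit <- msa(X, y, kernel = "linear", n_perms = 50, n_boot = 30, seed = 1)
#' coef(fit)
msa <- function(x, y, kernel = c("linear", "polynomial", "quadratic"),
                cost = 1, degree = NULL, n_perms = 1000, n_boot = 1000,
                seed = 1, level = 0.05,
                normalization = c("sum_abs", "grand"), test = NULL) {
  x <- as.matrix(x)
  normalization <- match.arg(normalization)
  spec <- predictor_spec(kernel, cost = cost, degree = degree)
  y <- .check_labels(y, nrow(x))
  if (any(x < 0 | x > 1)) stop("'x' must contain intactness values in [0,1]")
  stopifnot(n_perms >= 1, n_boot >= 1)
  players <- colnames(x)
  if (is.null(players)) players <- paste0("P", seq_len(ncol(x)))
  colnames(x) <- players
  M <- ncol(x)

  set.seed(as.integer(seed))
  boot_val <- matrix(NA_real_, n_boot, M, dimnames = list(NULL, players))
  boot_se <- boot_val
  redraws <- 0L
  for (b in seq_len(n_boot)) {
    idx <- .boot_index(y)
    redraws <- redraws + attr(idx, "redraws")
    fit_b <- train_predictor(x[idx, , drop = FALSE], y[idx], spec)
    est <- estimated_shapley(predictor_char_fun(fit_b), n_perms = n_perms)
    boot_val[b, ] <- est$value
    boot_se[b, ] <- est$se
  }
  if (redraws > 0)
    message(redraws, " single-class bootstrap resample(s) redrawn")

  value <- colMeans(boot_val)
  sd_boot <- if (n_boot > 1) apply(boot_val, 2, stats::sd)
             else rep(NA_real_, M)
  se_perm <- colMeans(boot_se)
  predictor <- train_predictor(x, y, spec)
  norm_den <- switch(normalization,
    sum_abs = sum(abs(value)),
    grand = {
      vg <- predict(predictor, rbind(rep(1, M), rep(0, M)))
      vg[1] - vg[2]
    })
  normalized <- if (isTRUE(norm_den != 0)) value / norm_den
                else rep(NA_real_, M)
  if (is.na(normalized[1]) && norm_den == 0)
    warning("normalization denominator is zero; normalized values are NA")
  sig <- if (n_boot >= 2) suppressWarnings(flag_significance(boot_val, level))
         else rep(NA, M)

  contributions <- data.frame(
    player = players,
    value = unname(value),
    sd_boot = unname(sd_boot),
    se_perm = unname(se_perm),
    normalized = unname(normalized),
    significant = unname(as.vector(sig)),
    sign = ifelse(value >= 0, "positive", "negative"),
    stringsAsFactors = FALSE)

  structure(list(contributions = contributions, boot = boot_val,
                 boot_se = boot_se, predictor = predictor, spec = spec,
                 players = players, n = nrow(x), n_perms = n_perms,
                 n_boot = n_boot, seed = seed, level = level,
                 normalization = normalization, redraws = redraws,
                 test = test, call = match.call()),
            class = "msa")
}

.check_labels <- function(y, n) {
  y <- as.integer(y)
  if (length(y) != n) stop("'y' must have one label per row of 'x'")
  if (anyNA(y) || !all(y %in% c(0L, 1L)))
    stop("'y' must be binary (0 = pathological, 1 = normal)")
  if (length(unique(y)) < 2L)
    stop("'y' contains a single class; the predictor cannot be trained")
  y
}

#' @export
print.msa <- function(x, digits = 4, ...) {
  cat("Multiperturbation Shapley value analysis",
      if (!is.null(x$test)) paste0(" [", x$test, "]"), "\n", sep = "")
  cat(sprintf("  %d patients, %d players, %s kernel (cost %g)\n",
              x$n, length(x$players), x$spec$kernel, x$spec$cost))
  cat(sprintf("  %d bootstrap samples x %d sampled orderings (seed %s)\n",
              x$n_boot, x$n_perms, format(x$seed)))
  tab <- x$contributions
  tab[c("value", "sd_boot", "se_perm", "normalized")] <-
    lapply(tab[c("value", "sd_boot", "se_perm", "normalized")], round,
           digits = digits)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' @export
coef.msa <- function(object, normalized = FALSE, ...) {
  out <- if (normalized) object$contributions$normalized
         else object$contributions$value
  names(out) <- object$players
  out
}

#' @export
confint.msa <- function(object, parm, level = 0.95, ...) {
  probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  ci <- t(apply(object$boot, 2, stats::quantile, probs = probs,
                names = FALSE))
  dimnames(ci) <- list(object$players, sprintf("%.1f %%", probs * 100))
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' @export
summary.msa <- function(object, ...) {
  ci <- confint(object, level = 1 - object$level)
  out <- cbind(object$contributions,
               lower = ci[, 1], upper = ci[, 2])
  structure(list(table = out, object = object), class = "summary.msa")
}

#' @export
print.summary.msa <- function(x, digits = 4, ...) {
  print(x$object, digits = digits)
  cat(sprintf("  %g%% bootstrap percentile intervals:\n",
              100 * (1 - x$object$level)))
  print(round(x$table[, c("lower", "upper")], digits))
  invisible(x)
}

#' Bar plot of normalized MSA contributions
#'
#' Draws the per-player normalized mean contributions with error bars (the
#' bootstrap SD, also normalized), positive bars meaning damage to the tract
#' predicts worse task performance.
#'
#' @param x an \code{"msa"} object.
#' @param ... passed to [graphics::barplot()].
#' @export
plot.msa <- function(x, ...) {
  tab <- x$contributions
  den <- if (x$normalization == "sum_abs") sum(abs(tab$value)) else {
    d <- tab$value / tab$normalized
    d[is.finite(d)][1]
  }
  err <- tab$sd_boot / den
  ylim <- range(0, tab$normalized - err, tab$normalized + err, na.rm = TRUE)
  mids <- graphics::barplot(tab$normalized, names.arg = tab$player,
                            las = 2, ylim = ylim * 1.1,
                            ylab = "normalized contribution",
                            main = if (!is.null(x$test)) x$test else "", ...)
  graphics::arrows(mids, tab$normalized - err, mids, tab$normalized + err,
                   angle = 90, code = 3, length = 0.03)
  graphics::abline(h = 0)
  invisible(mids)
}

#' Classify contributors as task-invariant or task-dependent
#'
#' Given MSA fits of the same player set on two or more behavioral tests,
#' labels each player \code{task-invariant positive} (significant positive
#' contribution in every test), \code{task-invariant negative} (significant
#' negative in every test) or \code{task-dependent} otherwise, reporting the
#' per-test signed pattern.
#'
#' @param results named list of \code{"msa"} objects (names = tests) over an
#'   identical player set.
#' @param include_rob keep the compound rest-of-brain player (\code{"RoB"})
#'   in the table? Default \code{FALSE}: it is a diagnostic guard against
#'   omitted contributors, not an anatomical tract.
#' @return data frame of class \code{"contributor_classification"} with one
#'   row per player: classification plus a signed pattern column per test
#'   (\code{"+"}/\code{"-"}, lower-case letters when not significant).
#' @export
classify_contributors <- function(results, include_rob = FALSE) {
  stopifnot(is.list(results), length(results) >= 2)
  if (is.null(names(results)) || any(names(results) == ""))
    names(results) <- paste0("test", seq_along(results))
  players <- results[[1]]$players
  for (r in results)
    if (!identical(r$players, players))
      stop("all results must share an identical player set")
  if (!include_rob) {
    keep <- players != "RoB"
    players <- players[keep]
  } else keep <- rep(TRUE, length(players))

  signs <- sapply(results, function(r) sign(r$contributions$value)[keep])
  sigs <- sapply(results, function(r) r$contributions$significant[keep])
  cls <- character(length(players))
  for (i in seq_along(players)) {
    if (all(sigs[i, ]) && all(signs[i, ] > 0)) cls[i] <- "task-invariant positive"
    else if (all(sigs[i, ]) && all(signs[i, ] < 0)) cls[i] <- "task-invariant negative"
    else cls[i] <- "task-dependent"
  }
  pat <- matrix(ifelse(signs > 0, ifelse(sigs, "+", "(+)"),
                       ifelse(sigs, "-", "(-)")),
                nrow = length(players),
                dimnames = list(NULL, names(results)))
  out <- data.frame(player = players, classification = cls, pat,
                    stringsAsFactors = FALSE, check.names = FALSE)
  class(out) <- c("contributor_classification", "data.frame")
  out
}

#' @export
print.contributor_classification <- function(x, ...) {
  cat("Contributor classification ((+)/(-) = not significant):\n")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}
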