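#' Specification of the SVM performance predictor
#'
#' The predictor backing the estimated MSA is a support vector machine
#' (C-classification, SMO-class solver) with box constraint \code{c = 1} by
#' default. "Quadratic" means a polynomial kernel of degree 2; "polynomial"
#' defaults to degree 3. Feature scaling is disabled: inputs are already
#' intactness values on a common [0,1] scale and binary perturbation
#' configurations must be mapped identically.
#'
#' @param kernel one of \code{"linear"}, \code{"polynomial"},
#'   \code{"quadratic"}.
#' @param cost positive box constraint.
#' @param degree optional polynomial degree override.
#' @return object of class \code{"predictor_spec"}.
#' @export
predictor_spec <- function(kernel = c("linear", "polynomial", "quadratic"),
                           cost = 1, degree = NULL) {
  kernel <- match.arg(kernel)
  stopifnot(is.numeric(cost), cost > 0)
  if (is.null(degree))
    degree <- switch(kernel, linear = 1L, polynomial = 3L, quadratic = 2L)
  stopifnot(degree >= 1)
  structure(list(kernel = kernel, cost = cost, degree = as.integer(degree)),
            class = "predictor_spec")
}

#' @export
print.predictor_spec <- function(x, ...) {
  cat(sprintf("SVM spec: %s kernel%s, cost %g\n", x$kernel,
              if (x$kernel != "linear") paste0(" (degree ", x$degree, ")")
              else "", x$cost))
  invisible(x)
}

#' Train the performance predictor on a graded dataset
#'
#' Fits the SVM on the patients-by-players intactness matrix and binary
#' performance labels. The fitted object maps any vector in \code{[0,1]^M} —
#' a patient's graded lesion pattern or a binary perturbation configuration —
#' to a predicted binary performance.
#'
#' @param x intactness matrix (values in [0,1]); columns are players.
#' @param y binary labels (1 = normal performance); both classes required.
#' @param spec a [predictor_spec()].
#' @return object of class \code{"msa_predictor"}.
#' @export
train_predictor <- function(x, y, spec = predictor_spec()) {
  x <- as.matrix(x)
  stopifnot(inherits(spec, "predictor_spec"))
  y <- .check_labels(y, nrow(x))
  if (anyNA(x)) stop("'x' must not contain missing values")
  svm_kernel <- if (spec$kernel == "linear") "linear" else "polynomial"
  fit <- e1071::svm(x, factor(y, levels = c(0, 1)),
                    type = "C-classification", kernel = svm_kernel,
                    degree = spec$degree, cost = spec$cost,
                    coef0 = if (svm_kernel == "polynomial") 1 else 0,
                    gamma = 1, scale = FALSE)
  structure(list(model = fit, spec = spec, M = ncol(x),
                 players = colnames(x)),
            class = "msa_predictor")
}

#' @export
print.msa_predictor <- function(x, ...) {
  cat("MSA performance predictor over", x$M, "players\n")
  print(x$spec)
  invisible(x)
}

#' @export
predict.msa_predictor <- function(object, newdata, ...) {
  if (is.vector(newdata)) newdata <- matrix(newdata, nrow = 1)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$M)
    stop("configuration length ", ncol(newdata), " does not match the ",
         object$M, " players of the predictor")
  as.integer(as.character(stats::predict(object$model, newdata)))
}

#' Predict performance of a binary perturbation configuration
#'
#' @param predictor a trained [train_predictor()] object.
#' @param config binary vector (or 0/1 matrix of row configurations);
#'   0 = player perturbed (fully damaged), 1 = intact.
#' @return integer 0/1 predicted performance per configuration.
#' @export
predict_configuration <- function(predictor, config) {
  stopifnot(inherits(predictor, "msa_predictor"))
  if (is.vector(config)) config <- matrix(config, nrow = 1)
  if (!all(config %in% c(0, 1)))
    stop("a perturbation configuration must be binary")
  predict(predictor, config)
}

#' Characteristic function backed by a trained predictor
#'
#' @param predictor a trained [train_predictor()] object.
#' @return a [char_fun()] whose value for a configuration is the predicted
#'   binary performance.
#' @export
predictor_char_fun <- function(predictor) {
  stopifnot(inherits(predictor, "msa_predictor"))
  char_fun(function(cfg) as.numeric(predict(predictor, cfg)),
           M = predictor$M, players = predictor$players)
}

#' Leave-one-out cross-validated accuracy
#'
#' Each patient in turn is held out, the predictor retrained on the rest and
#' the held-out label predicted; accuracy is the fraction predicted
#' correctly. A fold whose training labels collapse to one class predicts
#' the majority (training) class, with a warning.
#'
#' @inheritParams train_predictor
#' @return list of class \code{"loo_result"}: \code{accuracy},
#'   per-patient \code{predictions}, \code{labels}, \code{n},
#'   \code{degenerate_folds}.
#' @export
loo_accuracy <- function(x, y, spec = predictor_spec()) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 3) stop("leave-one-out validation requires at least 3 patients")
  y <- .check_labels(y, n)
  pred <- integer(n)
  degenerate <- 0L
  for (i in seq_len(n)) {
    ytr <- y[-i]
    if (length(unique(ytr)) < 2L) {
      degenerate <- degenerate + 1L
      pred[i] <- as.integer(names(which.max(table(ytr))))
    } else {
      fit <- train_predictor(x[-i, , drop = FALSE], ytr, spec)
      pred[i] <- predict(fit, x[i, , drop = FALSE])
    }
  }
  if (degenerate > 0)
    warning(degenerate, " degenerate single-class fold(s): majority class used")
  structure(list(accuracy = mean(pred == y), predictions = pred,
                 labels = y, n = n, degenerate_folds = degenerate),
            class = "loo_result")
}

#' @export
print.loo_result <- function(x, ...) {
  cat(sprintf("Leave-one-out accuracy: %.1f%% (%d of %d correct)\n",
              100 * x$accuracy, sum(x$predictions == x$labels), x$n))
  invisible(x)
}

#' Permutation chance level of classification accuracy
#'
#' The accuracy a predictor would achieve by chance, mirroring the
#' leave-one-out validation: on each repetition every held-out case is
#' scored against the randomly permuted label of another case (each case
#' receives the label of a uniformly drawn \emph{other} case), and the
#' agreement rates are averaged over repetitions. Converges to the closed
#' form \eqn{\sum_k n_k (n_k - 1) / (n (n - 1))} for class counts
#' \eqn{n_k} (see [chance_level_exact()]).
#'
#' @param labels binary label vector.
#' @param reps number of random permutations (study default 1,000).
#' @param seed optional integer seed.
#' @return mean agreement fraction.
#' @export
chance_level <- function(labels, reps = 1000, seed = NULL) {
  n <- length(labels)
  if (n == 0) stop("empty label vector")
  if (reps < 1) stop("'reps' must be >= 1")
  if (n == 1) return(1)
  if (!is.null(seed)) set.seed(seed)
  one_rep <- function(r) {
    # donor index: uniform over the n-1 cases other than i
    j <- (seq_len(n) - 1 + sample.int(n - 1, n, replace = TRUE)) %% n + 1
    mean(labels[j] == labels)
  }
  mean(vapply(seq_len(reps), one_rep, numeric(1)))
}

#' Closed-form permutation chance level
#'
#' @param labels label vector (any discrete coding).
#' @return \eqn{\sum_k n_k (n_k - 1) / (n (n - 1))}, the expected agreement
#'   between the labels and a uniformly random permutation of them.
#' @export
chance_level_exact <- function(labels) {
  if (length(labels) == 0) stop("empty label vector")
  n <- length(labels)
  if (n == 1) return(1)
  nk <- table(labels)
  sum(nk * (nk - 1)) / (n * (n - 1))
}

#' Youden index of a binary prediction
#'
#' Sensitivity + specificity − 1, in [−1, 1]; 1 means no false positives or
#' false negatives. The positive class is label 1.
#'
#' @param predictions,labels binary vectors of equal length; \code{labels}
#'   must contain both classes.
#' @return the Youden index, with \code{sensitivity} and \code{specificity}
#'   attached as attributes.
#' @export
youden <- function(predictions, labels) {
  stopifnot(length(predictions) == length(labels))
  predictions <- as.integer(predictions); labels <- as.integer(labels)
  if (!all(c(predictions, labels) %in% c(0L, 1L)))
    stop("predictions and labels must be binary")
  if (length(unique(labels)) < 2L)
    stop("labels contain a single class; sensitivity or specificity undefined")
  sens <- mean(predictions[labels == 1] == 1)
  spec <- mean(predictions[labels == 0] == 0)
  structure(sens + spec - 1, sensitivity = sens, specificity = spec)
}

#' Full validation report for a graded dataset
#'
#' Computes the leave-one-out accuracy, its permutation chance level (Monte
#' Carlo and closed form), and the Youden index with sensitivity and
#' specificity of the leave-one-out predictions.
#'
#' @inheritParams train_predictor
#' @param reps label permutations for the chance level.
#' @param seed optional integer seed for the chance permutations.
#' @return list of class \code{"validation_report"}.
#' @export
validate_predictor <- function(x, y, spec = predictor_spec(), reps = 1000,
                               seed = NULL) {
  loo <- loo_accuracy(x, y, spec)
  yj <- youden(loo$predictions, loo$labels)
  structure(list(
    loo_accuracy = loo$accuracy,
    chance_level = chance_level(y, reps = reps, seed = seed),
    chance_level_exact = chance_level_exact(y),
    youden = as.numeric(yj),
    sensitivity = attr(yj, "sensitivity"),
    specificity = attr(yj, "specificity"),
    n = loo$n, spec = spec, degenerate_folds = loo$degenerate_folds),
    class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf(paste0(
    "Predictor validation (n = %d, %s kernel):\n",
    "  LOO accuracy  %.1f%%  (chance %.1f%%, closed form %.1f%%)\n",
    "  Youden index  %.2f  (sensitivity %.2f, specificity %.2f)\n"),
    x$n, x$spec$kernel, 100 * x$loo_accuracy, 100 * x$chance_level,
    100 * x$chance_level_exact, x$youden, x$sensitivity, x$specificity))
  invisible(x)
}

#' Kernel sensitivity scan
#'
#' Leave-one-out accuracy of every candidate kernel on the same dataset, the
#' procedure used to pick one kernel per behavioral test.
#'
#' @inheritParams train_predictor
#' @param kernels character vector of kernels to scan.
#' @param cost box constraint shared by all candidates.
#' @return data frame with kernel, degree and LOO accuracy, sorted best
#'   first.
#' @export
kernel_scan <- function(x, y,
                        kernels = c("linear", "quadratic", "polynomial"),
                        cost = 1) {
  specs <- lapply(kernels, predictor_spec, cost = cost)
  acc <- vapply(specs, function(s) loo_accuracy(x, y, s)$accuracy,
                numeric(1))
  out <- data.frame(kernel = kernels,
                    degree = vapply(specs, `[[`, integer(1), "degree"),
                    loo_accuracy = acc, stringsAsFactors = FALSE)
  out[order(-out$loo_accuracy), ]
}
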