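# RBF-SVM classifier: training via the internal SMO solver, grid search
# over (C, gamma) by cross-validated MCC, the three operating thresholds
# on the decision score, and model persistence.

MODEL_FORMAT_VERSION <- "sumosite-model-1"

#' Three operating thresholds on the SVM decision score
#'
#' Named cutoffs on the raw SVM margin: `low` = -0.2, `medium` = 0,
#' `high` = +0.2. A site is called positive when its decision score is at
#' least the cutoff, so high-threshold calls are a subset of medium,
#' which are a subset of low.
#' @format Named numeric vector.
#' @export
THRESHOLD_LEVELS <- c(low = -0.2, medium = 0.0, high = 0.2)

#' Train an RBF-SVM classifier
#'
#' Fits a soft-margin support vector classifier with radial basis
#' function kernel `exp(-gamma * ||u - v||^2)` by sequential minimal
#' optimization. Deterministic: the same inputs always give the same
#' fitted machine.
#'
#' @param x Numeric feature matrix (rows = samples).
#' @param y Labels: 1 (positive) / 0 (negative), or a +1/-1 vector.
#' @param C Regularization parameter (> 0).
#' @param gamma RBF width parameter (> 0).
#' @param scheme Optional encoding-scheme name stored with the model.
#' @param eps SMO stopping tolerance on the KKT violation gap.
#' @return An object of class `sumo_svm` with the support vectors, dual
#'   coefficients, offset `rho`, and training metadata.
#' @export
train_model <- function(x, y, C, gamma, scheme = NA_character_, eps = 1e-3) {
  x <- as.matrix(x)
  if (!all(is.finite(x))) stop("non-finite feature values")
  if (C <= 0 || gamma <= 0) stop("C and gamma must be positive")
  ypm <- ifelse(y > 0, 1, -1)
  if (length(unique(ypm)) < 2L) stop("both classes must be present")
  if (length(ypm) != nrow(x)) stop("label/feature length mismatch")
  fit <- svc_smo_fit(x, as.numeric(ypm), C, gamma, eps = eps)
  structure(list(
    sv = fit$sv, coef = as.numeric(fit$coef), rho = fit$rho,
    C = C, gamma = gamma, scheme = scheme, dim = ncol(x),
    n_train = nrow(x), n_pos = sum(ypm > 0), n_sv = fit$n_sv,
    converged = fit$converged,
    format_version = MODEL_FORMAT_VERSION
  ), class = "sumo_svm")
}

#' @export
print.sumo_svm <- function(x, ...) {
  cat("RBF-SVM (", x$n_sv, " SVs, C = ", x$C, ", gamma = ",
      signif(x$gamma, 4), ", scheme = ", x$scheme, ")\n", sep = "")
  invisible(x)
}

#' Decision scores of a trained model
#'
#' Signed margins `f(x) = sum_s coef_s K(sv_s, x) - rho`; larger scores
#' are more sumoylation-like.
#'
#' @param model A `sumo_svm`.
#' @param x Feature matrix with the model's dimension.
#' @return Numeric score vector, one per row of `x`.
#' @export
decision_scores <- function(model, x) {
  stopifnot(inherits(model, "sumo_svm"))
  x <- as.matrix(x)
  if (ncol(x) != model$dim)
    stop("feature dimension ", ncol(x), " does not match model (", model$dim, ")")
  as.numeric(svc_decision(model$sv, model$coef, model$rho, model$gamma, x))
}

#' Threshold decision scores into calls
#'
#' @param scores Numeric decision scores.
#' @param level `"low"` (-0.2), `"medium"` (0) or `"high"` (+0.2), or a
#'   numeric cutoff.
#' @return Integer vector: 1 where `score >= cutoff`, else 0.
#' @export
classify <- function(scores, level = "medium") {
  cutoff <- if (is.numeric(level)) level
            else THRESHOLD_LEVELS[[match.arg(level, names(THRESHOLD_LEVELS))]]
  as.integer(scores >= cutoff)
}

#' Default libsvm-style parameter grids
#'
#' @return List with `C` (2^-5 .. 2^15) and `gamma` (2^-15 .. 2^3) grids.
#' @export
default_svm_grid <- function() {
  list(C = 2^seq(-5, 15, by = 2), gamma = 2^seq(-15, 3, by = 2))
}

#' Select (C, gamma) by cross-validated MCC
#'
#' Exhaustively evaluates every grid point with stratified k-fold
#' cross-validation and returns the pair maximizing the mean per-fold
#' MCC at decision cutoff 0. Ties are broken toward smaller `C`, then
#' smaller `gamma`. Fold assignment (hence the result) is deterministic
#' given the seed.
#'
#' @param x Feature matrix.
#' @param y 0/1 labels.
#' @param C_grid,gamma_grid Numeric grids (both non-empty, positive).
#' @param folds Number of CV folds.
#' @param seed Seed for fold assignment.
#' @return List with `C`, `gamma`, `mcc` (the winning mean CV MCC) and
#'   `table` (data frame of all grid evaluations).
#' @export
grid_search <- function(x, y, C_grid, gamma_grid, folds = 10L, seed = 1L) {
  x <- as.matrix(x)
  if (length(unique(y)) < 2L) stop("both classes must be present")
  if (!length(C_grid) || !length(gamma_grid) ||
      any(C_grid <= 0) || any(gamma_grid <= 0))
    stop("grids must be non-empty and positive")
  fold_id <- stratified_folds(y, folds, seed)
  C_grid <- sort(C_grid); gamma_grid <- sort(gamma_grid)
  grid <- expand.grid(gamma = gamma_grid, C = C_grid,
                      KEEP.OUT.ATTRS = FALSE)[, c("C", "gamma")]
  grid$mcc <- NA_real_
  best <- NULL
  for (g in seq_len(nrow(grid))) {
    mccs <- vapply(seq_len(folds), function(f) {
      tr <- fold_id != f; te <- !tr
      m <- train_model(x[tr, , drop = FALSE], y[tr], grid$C[g], grid$gamma[g])
      s <- decision_scores(m, x[te, , drop = FALSE])
      metrics(confusion(y[te], classify(s, 0)))$mcc
    }, numeric(1))
    grid$mcc[g] <- mean(mccs)
    if (is.null(best) || grid$mcc[g] > best$mcc + 1e-12)
      best <- list(C = grid$C[g], gamma = grid$gamma[g], mcc = grid$mcc[g])
  }
  best$table <- grid
  best
}

#' Save a trained model to a single-file archive
#'
#' @param model A `sumo_svm`.
#' @param path Output path.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "sumo_svm"))
  saveRDS(unclass(model), path)
  invisible(path)
}

#' Load a model archive
#'
#' @param path Path written by [save_model()].
#' @return The `sumo_svm` model.
#' @export
load_model <- function(path) {
  obj <- tryCatch(readRDS(path), error = function(e)
    stop("cannot read model archive ", path, ": ", conditionMessage(e)))
  if (!is.list(obj) || !identical(obj$format_version, MODEL_FORMAT_VERSION))
    stop("not a model archive (expected format ", MODEL_FORMAT_VERSION, ")")
  structure(obj, class = "sumo_svm")
}
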