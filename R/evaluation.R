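# Performance assessment: confusion counts, Sn/Sp/Ac/MCC, ROC/AUC, and
# the cross-validation protocols (stratified k-fold, leave-one-out,
# repeated negative resampling, class-ratio sweep).

#' Confusion counts
#'
#' @param truth True 0/1 labels.
#' @param predicted Predicted 0/1 labels.
#' @return List with integer `tp`, `fp`, `fn`, `tn`.
#' @export
confusion <- function(truth, predicted) {
  if (length(truth) != length(predicted))
    stop("label length mismatch: ", length(truth), " vs ", length(predicted))
  t1 <- truth == 1L; p1 <- predicted == 1L
  list(tp = sum(t1 & p1), fp = sum(!t1 & p1),
       fn = sum(t1 & !p1), tn = sum(!t1 & !p1))
}

#' Sensitivity, specificity, accuracy and Matthews correlation
#'
#' `Sn = TP/(TP+FN)`, `Sp = TN/(TN+FP)`, `Ac = (TP+TN)/total`,
#' `MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`.
#' If any factor of the MCC denominator is zero the MCC is reported as 0
#' and `degenerate` is set — the convention for tables that never hit
#' this case in practice.
#'
#' @param counts Confusion counts from [confusion()].
#' @return List with `sn`, `sp`, `ac`, `mcc`, `degenerate`.
#' @export
metrics <- function(counts) {
  tp <- as.numeric(counts$tp); fp <- as.numeric(counts$fp)
  fn <- as.numeric(counts$fn); tn <- as.numeric(counts$tn)
  total <- tp + fp + fn + tn
  if (total == 0) stop("empty confusion table")
  denom2 <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  degenerate <- denom2 == 0
  list(
    sn = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    sp = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    ac = (tp + tn) / total,
    mcc = if (degenerate) 0 else (tp * tn - fp * fn) / sqrt(denom2),
    degenerate = degenerate
  )
}

#' ROC curve and AUC
#'
#' Sweeps all distinct decision-score thresholds, yielding one
#' (false-positive-rate, true-positive-rate) point per threshold plus the
#' (0,0) and (1,1) endpoints; the AUC is the trapezoidal area, which
#' equals the fraction of (positive, negative) pairs ranked correctly
#' with ties counted half.
#'
#' @param truth True 0/1 labels (both classes required).
#' @param scores Decision scores (larger = more positive).
#' @return List with `points` (data frame `fpr`, `tpr`) and `auc`.
#' @export
roc <- function(truth, scores) {
  if (length(truth) != length(scores)) stop("length mismatch")
  np <- sum(truth == 1L); nn <- sum(truth == 0L)
  if (np == 0L || nn == 0L) stop("both classes must be present")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- truth[ord]
  # cumulative counts at each distinct threshold (predict positive if >= s)
  last <- which(c(diff(s) != 0, TRUE))
  ctp <- cumsum(y == 1L)[last]
  cfp <- cumsum(y == 0L)[last]
  pts <- data.frame(fpr = c(0, cfp / nn, 1), tpr = c(0, ctp / np, 1))
  pts <- pts[!duplicated(pts), , drop = FALSE]
  rownames(pts) <- NULL
  auc <- sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) + utils::tail(pts$tpr, -1)) / 2)
  list(points = pts, auc = auc)
}

#' Stratified fold assignment
#'
#' Assigns each sample to one of `k` folds so that the class ratio is
#' preserved within one sample per fold. Deterministic given the seed.
#'
#' @param y 0/1 labels.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return Integer fold ids (1..k) per sample.
#' @export
stratified_folds <- function(y, k, seed) {
  if (k < 2L) stop("k must be >= 2")
  if (min(table(y)) < k)
    stop("k = ", k, " exceeds the size of the smaller class")
  id <- integer(length(y))
  with_seed(seed, {
    for (cl in unique(y)) {
      idx <- which(y == cl)
      id[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  })
  id
}

# Encode train/test for one fold. For the KNN scheme the reference sets
# are the training fold only (test fragments are scored against them),
# avoiding label leakage; other schemes are fragment-local so the full
# precomputed matrix is subset.
.fold_encode <- function(dataset, tr, te, scheme, options, enc_full = NULL) {
  if (scheme != "knn") {
    list(xtr = enc_full$x[tr, , drop = FALSE], ytr = enc_full$y[tr],
         xte = enc_full$x[te, , drop = FALSE], yte = enc_full$y[te])
  } else {
    train_ds <- dataset[tr, , drop = FALSE]
    test_ds <- dataset[te, , drop = FALSE]
    ref <- list(positives = train_ds$fragment[train_ds$label == 1L],
                negatives = train_ds$fragment[train_ds$label == 0L],
                k_list = options$k_list)
    etr <- encode_dataset(.new_fragment_dataset(train_ds, attr(dataset, "window_n")),
                          "knn", options["k_list"])
    ete <- encode_dataset(.new_fragment_dataset(test_ds, attr(dataset, "window_n")),
                          "knn", ref)
    list(xtr = etr$x, ytr = etr$y, xte = ete$x, yte = ete$y)
  }
}

#' Stratified k-fold cross-validation
#'
#' Splits the dataset into stratified folds, trains an RBF-SVM on each
#' training fold and scores the held-out fold; the pooled out-of-fold
#' decision scores give the metrics (at cutoff 0) and the ROC curve.
#' KNN reference sets are restricted to the training fold.
#'
#' @param dataset A `fragment_dataset`.
#' @param scheme Encoding scheme name.
#' @param C,gamma SVM parameters.
#' @param folds Number of folds (default 10).
#' @param seed Seed for fold assignment.
#' @param options Encoding options (see [encode_dataset()]).
#' @return List with `metrics`, `roc`, `scores` and `labels` (pooled, in
#'   dataset order).
#' @export
kfold_cv <- function(dataset, scheme, C, gamma, folds = 10L, seed = 1L,
                     options = list()) {
  y <- dataset$label
  fold_id <- stratified_folds(y, folds, seed)
  enc_full <- if (scheme != "knn") encode_dataset(dataset, scheme, options)
  scores <- numeric(length(y))
  for (f in seq_len(folds)) {
    tr <- fold_id != f; te <- !tr
    e <- .fold_encode(dataset, tr, te, scheme, options, enc_full)
    m <- train_model(e$xtr, e$ytr, C, gamma, scheme = scheme)
    scores[te] <- decision_scores(m, e$xte)
  }
  list(metrics = metrics(confusion(y, classify(scores, 0))),
       roc = roc(y, scores), scores = scores, labels = y)
}

#' Leave-one-out cross-validation
#'
#' One round per sample, training on the remainder; pooled scores give
#' metrics at cutoff 0 and the ROC.
#'
#' @inheritParams kfold_cv
#' @return Same shape as [kfold_cv()].
#' @export
loo_cv <- function(dataset, scheme, C, gamma, options = list()) {
  y <- dataset$label
  if (length(y) < 2L) stop("dataset must contain at least 2 samples")
  enc_full <- if (scheme != "knn") encode_dataset(dataset, scheme, options)
  scores <- numeric(length(y))
  for (i in seq_along(y)) {
    tr <- rep(TRUE, length(y)); tr[i] <- FALSE
    e <- .fold_encode(dataset, tr, !tr, scheme, options, enc_full)
    m <- train_model(e$xtr, e$ytr, C, gamma, scheme = scheme)
    scores[i] <- decision_scores(m, e$xte)
  }
  list(metrics = metrics(confusion(y, classify(scores, 0))),
       roc = roc(y, scores), scores = scores, labels = y)
}

#' Repeated evaluation over fresh negative subsamples
#'
#' Resamples the negatives `repeats` times (seeds `seed + 1 .. seed + r`),
#' runs the chosen protocol on each resampled dataset, and reports the
#' mean and standard deviation of each metric — the repeat-level summary
#' used for benchmark tables.
#'
#' @param full_dataset The complete `fragment_dataset` (all negatives).
#' @param scheme Encoding scheme name.
#' @param C,gamma SVM parameters.
#' @param ratio Negatives per positive for each resample (default 10).
#' @param repeats Number of resamples (default 5).
#' @param protocol `"kfold"` or `"loo"`.
#' @param folds Folds for the k-fold protocol.
#' @param seed Master seed.
#' @param options Encoding options.
#' @return List with `summary` (data frame: metric, mean, sd) and
#'   `per_repeat` (data frame of sn/sp/ac/mcc/auc per repeat).
#' @export
repeated_eval <- function(full_dataset, scheme, C, gamma, ratio = 10,
                          repeats = 5L, protocol = c("kfold", "loo"),
                          folds = 10L, seed = 1L, options = list()) {
  protocol <- match.arg(protocol)
  rows <- lapply(seq_len(repeats), function(r) {
    ds <- sample_negatives(full_dataset, ratio, seed + r)
    res <- if (protocol == "kfold")
      kfold_cv(ds, scheme, C, gamma, folds = folds, seed = seed + r,
               options = options)
    else loo_cv(ds, scheme, C, gamma, options = options)
    with(res, data.frame(repeat_id = r, sn = metrics$sn, sp = metrics$sp,
                         ac = metrics$ac, mcc = metrics$mcc, auc = roc$auc))
  })
  per_repeat <- do.call(rbind, rows)
  mets <- c("sn", "sp", "ac", "mcc", "auc")
  summary <- data.frame(
    metric = mets,
    mean = vapply(mets, function(m) mean(per_repeat[[m]]), numeric(1)),
    sd = vapply(mets, function(m)
      if (repeats > 1L) stats::sd(per_repeat[[m]]) else 0, numeric(1)),
    row.names = NULL)
  list(summary = summary, per_repeat = per_repeat)
}

#' Class-ratio sweep
#'
#' For each positive:negative training ratio, subsamples the negatives,
#' runs stratified k-fold cross-validation on the resampled set, and in
#' addition scores every *unsampled* negative with the fold model of a
#' randomly assigned fold — so each fragment of the full dataset receives
#' exactly one out-of-fold score. Metrics are computed over the full
#' dataset, which is how an imbalance-selection curve is read.
#'
#' @param full_dataset The complete `fragment_dataset`.
#' @param scheme Encoding scheme name.
#' @param C,gamma SVM parameters.
#' @param ratios Integer vector of negatives-per-positive ratios.
#' @param folds CV folds per ratio.
#' @param seed Master seed.
#' @param options Encoding options.
#' @return Data frame: ratio, sn, sp, ac, mcc, auc (one row per ratio).
#' @export
ratio_sweep <- function(full_dataset, scheme, C, gamma, ratios = 1:25,
                        folds = 10L, seed = 1L, options = list()) {
  rows <- lapply(ratios, function(rt) {
    ds <- sample_negatives(full_dataset, rt, seed + rt)
    used <- paste(ds$protein_id, ds$position, ds$fragment)
    rest_idx <- which(!(paste(full_dataset$protein_id, full_dataset$position,
                              full_dataset$fragment) %in% used))
    rest <- full_dataset[rest_idx, , drop = FALSE]
    y <- ds$label
    fold_id <- stratified_folds(y, folds, seed + rt)
    rest_fold <- with_seed(seed + rt + 10000L,
                           sample(rep_len(seq_len(folds), nrow(rest))))
    enc_full <- if (scheme != "knn") encode_dataset(ds, scheme, options)
    enc_rest <- if (scheme != "knn" && nrow(rest))
      encode_dataset(.new_fragment_dataset(rest, attr(full_dataset, "window_n")),
                     scheme, options)
    sc_main <- numeric(length(y)); sc_rest <- numeric(nrow(rest))
    for (f in seq_len(folds)) {
      tr <- fold_id != f; te <- !tr
      e <- .fold_encode(ds, tr, te, scheme, options, enc_full)
      m <- train_model(e$xtr, e$ytr, C, gamma, scheme = scheme)
      sc_main[te] <- decision_scores(m, e$xte)
      ri <- rest_fold == f
      if (any(ri)) {
        xr <- if (scheme != "knn") enc_rest$x[ri, , drop = FALSE] else {
          train_ds <- ds[tr, , drop = FALSE]
          encode_dataset(
            .new_fragment_dataset(rest[ri, , drop = FALSE],
                                  attr(full_dataset, "window_n")),
            "knn", list(positives = train_ds$fragment[train_ds$label == 1L],
                        negatives = train_ds$fragment[train_ds$label == 0L],
                        k_list = options$k_list))$x
        }
        sc_rest[ri] <- decision_scores(m, xr)
      }
    }
    all_y <- c(y, rest$label)
    all_s <- c(sc_main, sc_rest)
    met <- metrics(confusion(all_y, classify(all_s, 0)))
    data.frame(ratio = rt, sn = met$sn, sp = met$sp, ac = met$ac,
               mcc = met$mcc, auc = roc(all_y, all_s)$auc)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
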