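#' Classification accuracy in percent
#'
#' Number of correctly classified samples over the total number of
#' samples, times 100.
#'
#' @param y_true True labels.
#' @param y_pred Predicted labels, same length.
#' @return Accuracy in percent.
#' @export
#' @examples
#' classification_accuracy(c("a", "b", "a", "a"), c("a", "b", "b", "a"))  # 75
classification_accuracy <- function(y_true, y_pred) {
  if (length(y_true) == 0) stop("empty label vectors", call. = FALSE)
  if (length(y_true) != length(y_pred))
    stop("label vectors differ in length", call. = FALSE)
  100 * mean(as.character(y_true) == as.character(y_pred))
}

# Partition n_reps repetition slots into n_folds contiguous blocks whose
# sizes differ by at most one, larger blocks first (30, 4 -> 8 8 7 7).
fold_blocks <- function(n_reps, n_folds) {
  sizes <- rep(n_reps %/% n_folds, n_folds)
  extra <- n_reps %% n_folds
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  ends <- cumsum(sizes)
  starts <- c(1L, head(ends, -1L) + 1L)
  lapply(seq_len(n_folds), function(f) seq.int(starts[f], ends[f]))
}

# Assign every window to a fold via its (class, repetition): repetitions
# are partitioned per class into contiguous blocks.
window_folds <- function(labels, rep_of_window, n_folds) {
  fold <- integer(length(labels))
  for (cl in levels(labels)) {
    in_cl <- labels == cl
    reps <- sort(unique(rep_of_window[in_cl]))
    if (length(reps) < n_folds)
      stop("class `", cl, "` has ", length(reps),
           " repetitions but ", n_folds, " folds were requested",
           call. = FALSE)
    blocks <- fold_blocks(length(reps), n_folds)
    for (f in seq_len(n_folds)) {
      fold[in_cl & rep_of_window %in% reps[blocks[[f]]]] <- f
    }
  }
  fold
}

# Core CV loop on a precomputed feature matrix (shared by cross_validate
# and the SFS / sweep drivers, which reuse one extraction).
cv_on_matrix <- function(values, labels, rep_of_window, spec, n_folds) {
  fold <- window_folds(labels, rep_of_window, n_folds)
  classes <- levels(labels)
  confusion <- matrix(0L, length(classes), length(classes),
                      dimnames = list(true = classes, predicted = classes))
  folds <- vector("list", n_folds)
  for (f in seq_len(n_folds)) {
    test <- fold == f
    model <- fit_classifier(spec, values[!test, , drop = FALSE],
                            labels[!test])
    pred <- predict(model, values[test, , drop = FALSE])
    truth <- labels[test]
    folds[[f]] <- list(fold = f, n_test = sum(test),
                       ca_pct = classification_accuracy(truth, pred))
    confusion <- confusion + unclass(table(factor(truth, classes),
                                           factor(pred, classes)))
  }
  fold_ca <- vapply(folds, function(x) x$ca_pct, numeric(1))
  confusion_pct <- 100 * confusion / rowSums(confusion)
  structure(
    list(ca_pct = 100 * sum(diag(confusion)) / sum(confusion),
         ca_sd_pct = sd(fold_ca),
         per_class_ca_pct = diag(confusion_pct),
         confusion_pct = confusion_pct,
         confusion_counts = confusion,
         folds = folds),
    class = "rsc_eval")
}

#' Repetition-blocked cross-validated accuracy
#'
#' Folds partition each class's repetition indices into `n_folds`
#' contiguous blocks (30 repetitions, 4 folds: 8/8/7/7); every analysis
#' window follows its source repetition, so near-duplicate windows from
#' one repetition never span the train/test split. Features are
#' standardised inside each training fold (see [fit_classifier()]).
#' `ca_pct` is the pooled accuracy over all folds, which equals the
#' label-frequency-weighted mean of the per-class accuracies;
#' `ca_sd_pct` is the standard deviation of the per-fold accuracies.
#'
#' @param ds An `rsc_windows` dataset.
#' @param ids Feature ids to extract and use.
#' @param spec An `rsc_classifier_spec`.
#' @param n_folds Number of folds (default 4).
#' @return An `rsc_eval` report: overall/per-class accuracy, row-normalised
#'   confusion matrix in percent, per-fold details and a config echo.
#' @export
cross_validate <- function(ds, ids, spec, n_folds = 4) {
  stopifnot(inherits(ds, "rsc_windows"))
  if (n_folds < 2) stop("`n_folds` must be >= 2", call. = FALSE)
  fm <- extract_features(ds, ids)
  rep <- cv_on_matrix(fm$values, fm$labels, fm$rep_of_window, spec, n_folds)
  rep$config_echo <- list(ids = fm$ids, classifier = unclass(spec),
                          n_folds = n_folds, window_ms = ds$window_ms,
                          increment_ms = ds$increment_ms, fs_hz = ds$fs_hz)
  rep
}

#' @export
print.rsc_eval <- function(x, digits = 1, ...) {
  cat(sprintf("Cross-validated accuracy: %.1f%% (fold sd %.1f%%)\n",
              x$ca_pct, x$ca_sd_pct))
  cat("Per-class accuracy (%):\n")
  print(round(x$per_class_ca_pct, digits))
  cat("Confusion matrix (row %):\n")
  print(round(x$confusion_pct, digits))
  invisible(x)
}

#' Sequential forward feature selection
#'
#' Greedy search over feature types (each evaluated jointly across all
#' channels): starting from the empty set, each step adds the feature that
#' maximises the cross-validated accuracy of the grown set, ties broken by
#' [feature_ids()] order. `best_set` is the smallest step whose accuracy
#' is within `parsimony_margin` points of the maximum over all steps, so
#' a compact set (e.g. RMS + WL) is preferred over a larger one that gains
#' a fraction of a point.
#'
#' @param ds An `rsc_windows` dataset.
#' @param spec Classifier specification used for every evaluation.
#' @param max_features Number of greedy steps (1..13).
#' @param n_folds CV folds per evaluation.
#' @param parsimony_margin Accuracy tolerance (points) for preferring a
#'   smaller set (default 1.0).
#' @param candidate_ids Feature pool (default all 13).
#' @return An `rsc_sfs` result: per-step table and the selected set.
#' @export
sfs_select <- function(ds, spec, max_features = 13, n_folds = 4,
                       parsimony_margin = 1.0,
                       candidate_ids = feature_ids()) {
  if (max_features < 1 || max_features > length(candidate_ids))
    stop("`max_features` must be in [1, ", length(candidate_ids), "]",
         call. = FALSE)
  fm <- extract_features(ds, candidate_ids)
  cols_of <- function(ids) {
    which(sub("^.*_", "", colnames(fm$values)) %in% ids)
  }
  chosen <- character(0)
  steps <- vector("list", max_features)
  for (step in seq_len(max_features)) {
    pool <- setdiff(fm$ids, chosen)  # fm$ids is in canonical order
    cas <- vapply(pool, function(f) {
      cv_on_matrix(fm$values[, cols_of(c(chosen, f)), drop = FALSE],
                   fm$labels, fm$rep_of_window, spec, n_folds)$ca_pct
    }, numeric(1))
    best <- pool[which.max(cas)]  # first max = FeatureId-order tie-break
    chosen <- c(chosen, best)
    rep <- cv_on_matrix(fm$values[, cols_of(chosen), drop = FALSE],
                        fm$labels, fm$rep_of_window, spec, n_folds)
    steps[[step]] <- list(added = best, set = chosen,
                          ca_pct = rep$ca_pct, ca_sd_pct = rep$ca_sd_pct)
  }
  ca_by_step <- vapply(steps, function(s) s$ca_pct, numeric(1))
  best_step <- which(ca_by_step >= max(ca_by_step) - parsimony_margin)[1]
  structure(list(steps = steps, best_set = steps[[best_step]]$set,
                 best_step = best_step,
                 parsimony_margin = parsimony_margin),
            class = "rsc_sfs")
}

#' @export
print.rsc_sfs <- function(x, ...) {
  cat("Sequential forward feature selection\n")
  for (s in x$steps)
    cat(sprintf("  +%-5s -> {%s}: %.1f%% (sd %.1f)\n", s$added,
                paste(s$set, collapse = ", "), s$ca_pct, s$ca_sd_pct))
  cat("Selected set (parsimony margin", x$parsimony_margin, "points):",
      paste(x$best_set, collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.data.frame.rsc_sfs <- function(x, ...) {
  data.frame(step = seq_along(x$steps),
             added = vapply(x$steps, function(s) s$added, character(1)),
             set = vapply(x$steps, function(s)
               paste(s$set, collapse = "+"), character(1)),
             ca_pct = vapply(x$steps, function(s) s$ca_pct, numeric(1)),
             ca_sd_pct = vapply(x$steps, function(s) s$ca_sd_pct,
                                numeric(1)))
}
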