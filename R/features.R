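#' The thirteen time-domain feature identifiers
#'
#' Canonical order used for feature-matrix columns and tie-breaking in
#' sequential forward selection: MAV (mean absolute value), WL (waveform
#' length), AAC (average amplitude change), SSI (simple square integral),
#' RMS (root mean square), VAR (variance), STD (standard deviation),
#' DASDV (difference absolute standard deviation value), TM3/TM4/TM5
#' (absolute third/fourth/fifth temporal moments), KURT (kurtosis-style
#' normalised moment) and LOGD (log detector).
#'
#' @return Character vector of the 13 feature ids.
#' @export
feature_ids <- function() {
  c("MAV", "WL", "AAC", "SSI", "RMS", "VAR", "STD", "DASDV",
    "TM3", "TM4", "TM5", "KURT", "LOGD")
}

#' Compute one time-domain feature of a window
#'
#' Implements the thirteen window statistics exactly as defined for RSC
#' pattern recognition:
#' \describe{
#'   \item{MAV}{mean of |x|}
#'   \item{WL}{sum of |successive differences| (cumulative waveform
#'     length)}
#'   \item{AAC}{WL / N (the N-1 difference terms divided by N, so
#'     AAC * N = WL exactly)}
#'   \item{SSI}{sum of squares}
#'   \item{RMS}{sqrt(SSI / N)}
#'   \item{VAR}{sum of squared deviations from the mean / (N - 1)}
#'   \item{STD}{sqrt(VAR)}
#'   \item{DASDV}{sqrt(sum of squared successive differences / (N - 1))}
#'   \item{TM3, TM4, TM5}{|mean of x^k|, k = 3, 4, 5}
#'   \item{KURT}{mean((|x| - mean(x))^2) / (mean(x^2))^4 — the
#'     normalised-moment form used in the RSC literature, which is not the
#'     conventional kurtosis; set `kurt_standard = TRUE` for the
#'     conventional m4 / m2^2 of the centred samples. The all-zero window
#'     is defined to have KURT 0.}
#'   \item{LOGD}{exp(mean(log(|x| + eps))), eps = machine epsilon, so the
#'     all-zero hold segments of transient RSC signals stay finite}
#' }
#'
#' @param id One of [feature_ids()].
#' @param x Finite numeric vector of length N >= 2.
#' @param kurt_standard Use conventional kurtosis (fourth central moment
#'   over squared second central moment) instead of the form above.
#' @return A single numeric value.
#' @export
#' @examples
#' compute_feature("MAV", c(1, -1, 2, -2))  # 1.5
#' compute_feature("WL", c(1, -1, 2, -2))   # 9
compute_feature <- function(id, x, kurt_standard = FALSE) {
  id <- match.arg(id, feature_ids())
  if (length(x) < 2) stop("window must have N >= 2 samples", call. = FALSE)
  if (!all(is.finite(x))) stop("window contains non-finite values",
                               call. = FALSE)
  n <- length(x)
  switch(id,
    MAV = mean(abs(x)),
    WL = sum(abs(diff(x))),
    AAC = sum(abs(diff(x))) / n,
    SSI = sum(x^2),
    RMS = sqrt(sum(x^2) / n),
    VAR = sum((x - mean(x))^2) / (n - 1),
    STD = sqrt(sum((x - mean(x))^2) / (n - 1)),
    DASDV = sqrt(sum(diff(x)^2) / (n - 1)),
    TM3 = abs(mean(x^3)),
    TM4 = abs(mean(x^4)),
    TM5 = abs(mean(x^5)),
    KURT = {
      if (kurt_standard) {
        m2 <- mean((x - mean(x))^2)
        if (m2 == 0) 0 else mean((x - mean(x))^4) / m2^2
      } else {
        den <- mean(x^2)^4
        if (den == 0) 0 else mean((abs(x) - mean(x))^2) / den
      }
    },
    LOGD = exp(mean(log(abs(x) + .Machine$double.eps))))
}

#' Extract a per-window feature matrix
#'
#' Computes the requested features for every channel of every window and
#' assembles them channel-major: columns `ch1_<f1> ... ch1_<fk>,
#' ch2_<f1> ...`, features in [feature_ids()] order within each channel.
#' Class labels and source repetitions are carried through unchanged.
#'
#' @param ds An `rsc_windows` dataset from [segment_windows()].
#' @param ids Distinct feature ids to compute (default all 13).
#' @param kurt_standard Passed to [compute_feature()].
#' @return An `rsc_features` object: `values` matrix (windows x
#'   channels*features), `labels`, `rep_of_window`.
#' @export
extract_features <- function(ds, ids = feature_ids(),
                             kurt_standard = FALSE) {
  stopifnot(inherits(ds, "rsc_windows"))
  if (length(ids) == 0) stop("`ids` must be non-empty", call. = FALSE)
  if (anyDuplicated(ids)) stop("`ids` must be distinct", call. = FALSE)
  ids <- feature_ids()[feature_ids() %in% ids]  # canonical order
  n_w <- dim(ds$windows)[1]
  n_ch <- dim(ds$windows)[3]
  values <- matrix(0, nrow = n_w, ncol = n_ch * length(ids))
  colnames(values) <- as.vector(vapply(
    seq_len(n_ch),
    function(ch) paste0(ds$channel_ids[ch], "_", ids),
    character(length(ids))))
  for (ch in seq_len(n_ch)) {
    mat <- ds$windows[, , ch, drop = FALSE]
    dim(mat) <- dim(ds$windows)[1:2]
    for (j in seq_along(ids)) {
      col <- (ch - 1L) * length(ids) + j
      for (w in seq_len(n_w))
        values[w, col] <- compute_feature(ids[j], mat[w, ],
                                          kurt_standard = kurt_standard)
    }
  }
  structure(list(values = values, labels = ds$labels,
                 rep_of_window = ds$rep_of_window, ids = ids,
                 channel_ids = ds$channel_ids),
            class = "rsc_features")
}

#' @export
print.rsc_features <- function(x, ...) {
  cat(sprintf("RSC feature matrix: %d windows x %d columns (%d channels x %d features)\n",
              nrow(x$values), ncol(x$values), length(x$channel_ids),
              length(x$ids)))
  cat("  features:", paste(x$ids, collapse = ", "), "\n")
  invisible(x)
}

#' Write / read a feature matrix as TSV
#'
#' One row per window; feature columns first, then `class` and
#' `repetition` label columns.
#'
#' @param fm An `rsc_features` object.
#' @param path TSV file path.
#' @return `write_features()` returns `path` invisibly; `read_features()`
#'   the `rsc_features`.
#' @export
write_features <- function(fm, path) {
  stopifnot(inherits(fm, "rsc_features"))
  df <- as.data.frame(format(fm$values, digits = 15, scientific = TRUE,
                             trim = TRUE), check.names = FALSE)
  df$class <- as.character(fm$labels)
  df$repetition <- fm$rep_of_window
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
  lab_cols <- c("class", "repetition")
  if (!all(lab_cols %in% names(df)))
    stop("feature TSV must contain `class` and `repetition` columns",
         call. = FALSE)
  vals <- as.matrix(df[, setdiff(names(df), lab_cols), drop = FALSE])
  rownames(vals) <- NULL
  ids <- unique(sub("^ch[0-9]+_", "", colnames(vals)))
  chs <- unique(sub("_[A-Z0-9]+$", "", colnames(vals)))
  structure(list(values = vals,
                 labels = factor(df$class, levels = unique(df$class)),
                 rep_of_window = as.integer(df$repetition),
                 ids = ids, channel_ids = chs),
            class = "rsc_features")
}
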