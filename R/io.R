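#' Construct a labelled multichannel recording
#'
#' @param samples Numeric matrix, rows = time samples, columns = channels
#'   (arbitrary pressure-rate units).
#' @param fs_hz Sampling rate in Hz (> 0).
#' @param class_id Motion class label.
#' @param rep_index 1-based repetition ordinal.
#' @param channel_ids Channel labels; defaults to `ch1..chC`.
#' @return An `rsc_recording` object.
#' @export
new_recording <- function(samples, fs_hz, class_id, rep_index = 1L,
                          channel_ids = NULL) {
  samples <- as.matrix(samples)
  if (nrow(samples) < 1) stop("recording must have >= 1 sample", call. = FALSE)
  if (!is.numeric(fs_hz) || fs_hz <= 0) stop("`fs_hz` must be > 0",
                                             call. = FALSE)
  if (is.null(channel_ids)) channel_ids <- paste0("ch", seq_len(ncol(samples)))
  if (length(channel_ids) != ncol(samples))
    stop("`channel_ids` length must match the channel count", call. = FALSE)
  colnames(samples) <- channel_ids
  structure(list(samples = samples, fs_hz = fs_hz,
                 class_id = as.character(class_id),
                 rep_index = as.integer(rep_index),
                 channel_ids = channel_ids),
            class = "rsc_recording")
}

#' @export
print.rsc_recording <- function(x, ...) {
  cat(sprintf("RSC recording: class %s, repetition %d\n",
              x$class_id, x$rep_index))
  cat(sprintf("  %d samples x %d channels at %g Hz (%.2f s)\n",
              nrow(x$samples), ncol(x$samples), x$fs_hz,
              nrow(x$samples) / x$fs_hz))
  invisible(x)
}

sidecar_path <- function(path) paste0(path, ".json")

#' Write / read a recording as TSV plus JSON sidecar
#'
#' The sample matrix is stored as tab-separated text (one row per time
#' sample, one column per channel, header = channel ids); the metadata
#' (sampling rate, class, repetition, channel ids) goes to a JSON sidecar
#' at `<path>.json`. Values are written with 15 significant digits so the
#' round trip is lossless at that precision.
#'
#' @param rec An `rsc_recording`.
#' @param path Path of the TSV data file; the sidecar is written next to it.
#' @return `write_recording()` returns `path` invisibly; `read_recording()`
#'   returns the `rsc_recording`.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "rsc_recording"))
  write.table(format(rec$samples, digits = 15, scientific = TRUE,
                     trim = TRUE),
              path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = rec$channel_ids)
  meta <- list(fs_hz = rec$fs_hz, class_id = rec$class_id,
               rep_index = rec$rep_index, channel_ids = rec$channel_ids)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  if (!file.exists(path)) stop("data file not found: ", path, call. = FALSE)
  side <- sidecar_path(path)
  if (!file.exists(side))
    stop("metadata sidecar not found: ", side,
         " (recordings are stored as TSV + JSON sidecar pairs)",
         call. = FALSE)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  for (f in c("fs_hz", "class_id", "rep_index", "channel_ids"))
    if (is.null(meta[[f]]))
      stop("sidecar ", side, " is missing field `", f, "`", call. = FALSE)
  raw <- tryCatch(
    read.table(path, header = TRUE, sep = "\t", colClasses = "numeric",
               check.names = FALSE),
    error = function(e)
      stop("failed to parse ", path, ": ", conditionMessage(e),
           call. = FALSE))
  if (nrow(raw) < 1) stop("empty data file: ", path, call. = FALSE)
  if (ncol(raw) != length(meta$channel_ids))
    stop("channel count mismatch: ", path, " has ", ncol(raw),
         " columns but sidecar lists ", length(meta$channel_ids),
         " channels", call. = FALSE)
  m <- as.matrix(raw)
  rownames(m) <- NULL
  new_recording(m, as.numeric(meta$fs_hz), meta$class_id,
                as.integer(meta$rep_index), meta$channel_ids)
}

#' Write / read a whole session directory
#'
#' One TSV + sidecar pair per recording, named
#' `<class>_rep<index>.tsv(.json)`.
#'
#' @param session List of `rsc_recording` objects.
#' @param dir Directory path (created if needed).
#' @return `write_session()` returns `dir` invisibly; `read_session()`
#'   returns the list of recordings sorted by class then repetition.
#' @export
write_session <- function(session, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (rec in session)
    write_recording(rec, file.path(dir, sprintf("%s_rep%03d.tsv",
                                                rec$class_id, rec$rep_index)))
  invisible(dir)
}

#' @rdname write_session
#' @export
read_session <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.tsv$", full.names = TRUE))
  if (length(files) == 0) stop("no .tsv recordings in ", dir, call. = FALSE)
  lapply(files, read_recording)
}

#' Concatenate repetitions into per-class analysis sets
#'
#' Joins every class's repetitions along time, in repetition order, and
#' records each repetition's start offset within the concatenation so any
#' sample index maps back to its source repetition (needed to attribute
#' analysis windows to repetitions for leak-free cross-validation).
#'
#' @param recordings List of `rsc_recording` objects sharing sampling rate
#'   and channel count.
#' @return An `rsc_concat` object: per class a samples matrix, 0-based
#'   repetition `boundaries`, and the ordered repetition indices.
#' @export
concatenate_recordings <- function(recordings) {
  stopifnot(length(recordings) >= 1)
  fs <- vapply(recordings, function(r) r$fs_hz, numeric(1))
  if (length(unique(fs)) != 1)
    stop("recordings have mixed sampling rates: ",
         paste(unique(fs), collapse = ", "), call. = FALSE)
  nch <- vapply(recordings, function(r) ncol(r$samples), integer(1))
  if (length(unique(nch)) != 1)
    stop("recordings have mixed channel counts", call. = FALSE)
  cls <- vapply(recordings, function(r) r$class_id, character(1))
  classes <- unique(cls)
  sets <- lapply(classes, function(cl) {
    recs <- recordings[cls == cl]
    recs <- recs[order(vapply(recs, function(r) r$rep_index, integer(1)))]
    lens <- vapply(recs, function(r) nrow(r$samples), integer(1))
    list(samples = do.call(rbind, lapply(recs, function(r) r$samples)),
         boundaries = cumsum(c(0L, lens[-length(lens)])),
         rep_index = vapply(recs, function(r) r$rep_index, integer(1)))
  })
  names(sets) <- classes
  structure(list(classes = sets, fs_hz = fs[1],
                 channel_ids = recordings[[1]]$channel_ids),
            class = "rsc_concat")
}

#' Map a sample index back to its source repetition
#'
#' @param concat An `rsc_concat`.
#' @param class_id Class whose concatenated signal is indexed.
#' @param sample_index 0-based sample index into the concatenation.
#' @return The repetition index owning that sample.
#' @export
sample_to_repetition <- function(concat, class_id, sample_index) {
  set <- concat$classes[[class_id]]
  if (is.null(set)) stop("unknown class: ", class_id, call. = FALSE)
  if (any(sample_index < 0 | sample_index >= nrow(set$samples)))
    stop("sample index out of range", call. = FALSE)
  set$rep_index[findInterval(sample_index, set$boundaries)]
}

#' @export
print.rsc_concat <- function(x, ...) {
  cat("Concatenated RSC analysis sets at", x$fs_hz, "Hz\n")
  for (cl in names(x$classes)) {
    set <- x$classes[[cl]]
    cat(sprintf("  %s: %d samples, %d repetitions\n", cl,
                nrow(set$samples), length(set$boundaries)))
  }
  invisible(x)
}
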