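#' Read one Bonn-format EEG segment
#'
#' The Bonn archive stores each single-channel EEG segment as plain ASCII text,
#' one sample per line (integers in the published files; any real number is
#' accepted here). The file is read verbatim: no resampling, scaling or
#' detrending is applied.
#'
#' @param path Path to a text file with one numeric sample per line.
#' @param fs Sampling rate in Hz. Defaults to the archive's 173.61 Hz.
#' @param label Optional class label, one of `"A"` (normal), `"D"`
#'   (interictal), `"E"` (ictal); `NA` for unlabelled data.
#' @param segment_id Identifier for the segment; defaults to the file name
#'   without extension.
#'
#' @return A one-row segment tibble with columns `segment_id`, `label`, `fs`
#'   and `samples` (a list-column holding the numeric sample vector).
#' @seealso [write_bonn_segment()], [generate_synthetic_dataset()]
#' @export
#' @examples
#' f <- tempfile(fileext = ".txt")
#' writeLines(c("12", "-5", "0"), f)
#' read_bonn_segment(f, label = "A")
read_bonn_segment <- function(path, fs = BONN_FS, label = NA_character_,
                              segment_id = NULL) {
  if (!file.exists(path)) {
    abort(paste0("cannot read Bonn segment: file not found: ", path),
          class = "selmeeg_io_error")
  }
  stopifnot(is.numeric(fs), length(fs) == 1, fs > 0)
  label <- check_label(label)
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines))
  lines <- lines[keep]
  if (length(lines) == 0) {
    abort(paste0("Bonn segment file is empty: ", path),
          class = "selmeeg_parse_error")
  }
  x <- suppressWarnings(as.numeric(trimws(lines)))
  if (anyNA(x)) {
    bad <- which(keep)[which(is.na(x))[1]]
    abort(sprintf("non-numeric sample at line %d of %s", bad, path),
          class = "selmeeg_parse_error")
  }
  segment_id <- segment_id %||% sub("\\.[^.]*$", "", basename(path))
  new_segment_tbl(segment_id, label, fs, list(x))
}

#' Write a segment to Bonn text format
#'
#' One sample per line, `format()`ed at full precision so that a write/read
#' round trip reproduces the samples exactly.
#'
#' @param samples Numeric vector of samples, or a one-row segment tibble as
#'   returned by [read_bonn_segment()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_bonn_segment <- function(samples, path) {
  if (is.data.frame(samples)) {
    stopifnot(nrow(samples) == 1, "samples" %in% names(samples))
    samples <- samples$samples[[1]]
  }
  stopifnot(is.numeric(samples), length(samples) >= 1)
  writeLines(format(samples, digits = 17, trim = TRUE, scientific = FALSE),
             path)
  invisible(path)
}

#' Read a whole directory or manifest of Bonn segments
#'
#' @param paths Character vector of file paths.
#' @param labels Class labels, recycled to `length(paths)`.
#' @param fs Sampling rate in Hz.
#' @return A segment tibble with one row per file.
#' @export
read_bonn_segments <- function(paths, labels = NA_character_, fs = BONN_FS) {
  labels <- rep_len(labels, length(paths))
  purrr::map2(paths, labels, read_bonn_segment, fs = fs) |>
    purrr::list_rbind()
}

check_label <- function(label) {
  if (length(label) != 1) {
    abort("label must be a single value", class = "selmeeg_validation_error")
  }
  if (is.na(label)) return(NA_character_)
  label <- as.character(label)
  if (!label %in% BONN_CLASSES) {
    abort(paste0("label must be one of ", paste(BONN_CLASSES, collapse = ", "),
                 " (got '", label, "')"),
          class = "selmeeg_validation_error")
  }
  label
}

new_segment_tbl <- function(segment_id, label, fs, samples) {
  tibble(segment_id = as.character(segment_id),
         label = as.character(label),
         fs = as.numeric(fs),
         samples = samples)
}

check_segments <- function(segments) {
  need <- c("segment_id", "label", "fs", "samples")
  if (!is.data.frame(segments) || !all(need %in% names(segments))) {
    abort(paste0("expected a segment tibble with columns ",
                 paste(need, collapse = ", ")),
          class = "selmeeg_validation_error")
  }
  invisible(segments)
}
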