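#' Slice segments into overlapping epochs
#'
#' Windows of `window` samples start every `hop` samples while the start lies
#' inside the segment; a final window running past the end is zero-padded to
#' full length. With the defaults (512/256) a 4096-sample segment yields 16
#' epochs, so 100 segments give 1600 epochs per class and 4800 over three
#' classes. `strict = TRUE` instead drops incomplete final windows (15 epochs
#' per 4096-sample segment).
#'
#' @param segments Segment tibble (`segment_id`, `label`, `fs`, `samples`).
#' @param window Epoch length in samples (default 512).
#' @param hop Hop between epoch starts (default 256, i.e. 50% overlap).
#' @param strict Drop zero-padded final windows? Default `FALSE`.
#' @return Epoch tibble: `epoch_id`, `segment_id`, `label`, `fs`,
#'   `start_index` (0-based sample offset) and `samples` (list-column of
#'   length-`window` vectors).
#' @export
make_epochs <- function(segments, window = 512L, hop = 256L, strict = FALSE) {
  check_segments(segments)
  if (window <= 0 || hop <= 0 || hop > window) {
    abort("need window > 0 and 0 < hop <= window",
          class = "selmeeg_validation_error")
  }
  purrr::pmap(segments[c("segment_id", "label", "fs", "samples")],
              function(segment_id, label, fs, samples) {
    L <- length(samples)
    starts <- seq(0L, L - 1L, by = hop)
    if (strict) starts <- starts[starts + window <= L]
    if (length(starts) == 0) return(NULL)
    sl <- purrr::map(starts, function(s0) {
      w <- samples[(s0 + 1):min(s0 + window, L)]
      if (length(w) < window) w <- c(w, numeric(window - length(w)))
      w
    })
    tibble(epoch_id = sprintf("%s_e%03d", segment_id, seq_along(starts)),
           segment_id = segment_id, label = label, fs = fs,
           start_index = as.integer(starts), samples = sl)
  }) |> purrr::list_rbind()
}

#' Eight-dimensional max/std feature vector of a subband set
#'
#' For each of the four subbands the signed maximum and the population
#' standard deviation (denominator `n`) of the raw coefficients are computed,
#' in the fixed order (max, std) for a3, d3, d2, d1. Set `abs_max = TRUE` for
#' the maximum of absolute coefficients, `sample_sd = TRUE` for the `n - 1`
#' denominator.
#'
#' @param subbands A `subband_set` from [decompose3()].
#' @param abs_max Use `max(|coef|)` instead of `max(coef)`? Default `FALSE`.
#' @param sample_sd Use the sample (n-1) standard deviation? Default `FALSE`.
#' @return A 1x8 tibble with columns `max_a3`, `std_a3`, `max_d3`, `std_d3`,
#'   `max_d2`, `std_d2`, `max_d1`, `std_d1`.
#' @export
extract_features <- function(subbands, abs_max = FALSE, sample_sd = FALSE) {
  bands <- subbands[c("a3", "d3", "d2", "d1")]
  if (any(lengths(bands) == 0)) {
    abort("cannot extract features from an empty subband",
          class = "selmeeg_validation_error")
  }
  feat <- purrr::map(bands, function(v) {
    mx <- if (abs_max) max(abs(v)) else max(v)
    s <- if (sample_sd) sd(v) else sqrt(mean((v - mean(v))^2))
    c(max = mx, std = s)
  })
  tibble(max_a3 = feat$a3[["max"]], std_a3 = feat$a3[["std"]],
         max_d3 = feat$d3[["max"]], std_d3 = feat$d3[["std"]],
         max_d2 = feat$d2[["max"]], std_d2 = feat$d2[["std"]],
         max_d1 = feat$d1[["max"]], std_d1 = feat$d1[["std"]])
}

#' Names of the eight feature columns, in canonical order
#' @export
feature_names <- function() {
  c("max_a3", "std_a3", "max_d3", "std_d3",
    "max_d2", "std_d2", "max_d1", "std_d1")
}

#' Full feature-extraction pipeline: segments to feature table
#'
#' Band-limits every segment to 0-32 Hz (zero phase), slices it into
#' overlapping epochs, decomposes each epoch with the three-level db4 lifting
#' transform, and summarises each subband by its maximum and standard
#' deviation. Deterministic: no randomness anywhere on this path.
#'
#' @param segments Segment tibble.
#' @param window,hop,strict Epoching parameters, see [make_epochs()].
#' @param bandpass Apply the 0-32 Hz filter first? Default `TRUE`.
#' @param require_labels Error on unlabelled segments (training mode)?
#'   Default `TRUE`.
#' @inheritParams extract_features
#' @return Feature tibble: `epoch_id`, `segment_id`, `label`, then the eight
#'   feature columns of [feature_names()].
#' @export
#' @examples
#' segs <- generate_synthetic_dataset(synth_spec(n_segments_per_class = 1,
#'                                               segment_length = 1024))
#' build_dataset(segs)
build_dataset <- function(segments, window = 512L, hop = 256L,
                          strict = FALSE, bandpass = TRUE,
                          require_labels = TRUE,
                          abs_max = FALSE, sample_sd = FALSE) {
  check_segments(segments)
  if (nrow(segments) == 0) {
    return(tibble(epoch_id = character(), segment_id = character(),
                  label = character()))
  }
  if (require_labels && anyNA(segments$label)) {
    abort("all segments must be labelled when building a training dataset",
          class = "selmeeg_validation_error")
  }
  if (bandpass) segments <- bandpass_0_32(segments)
  epochs <- make_epochs(segments, window = window, hop = hop, strict = strict)
  feats <- purrr::map(epochs$samples, function(x) {
    extract_features(decompose3(x), abs_max = abs_max, sample_sd = sample_sd)
  }) |> purrr::list_rbind()
  dplyr::bind_cols(epochs[c("epoch_id", "segment_id", "label")], feats)
}

#' Write / read a feature table as TSV
#'
#' @param features Feature tibble from [build_dataset()].
#' @param path File path.
#' @return `read_feature_table()` returns the feature tibble; the writer
#'   returns `path` invisibly.
#' @export
write_feature_table <- function(features, path) {
  utils::write.table(features, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  as_tibble(utils::read.table(path, sep = "\t", header = TRUE,
                              colClasses = c(epoch_id = "character",
                                             segment_id = "character",
                                             label = "character")))
}

# Extract the numeric feature matrix from a feature tibble.
feature_matrix <- function(features) {
  fn <- feature_names()
  missing <- setdiff(fn, names(features))
  if (length(missing) > 0) {
    abort(paste0("feature table is missing columns: ",
                 paste(missing, collapse = ", ")),
          class = "selmeeg_validation_error")
  }
  as.matrix(features[fn])
}
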