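#' Specification for a synthetic three-class EEG dataset
#'
#' Describes a generator that emulates the qualitative distinctions between
#' normal (A), interictal (D) and ictal (E) single-channel EEG: class A is a
#' low-amplitude alpha-band rhythm over coloured background noise, class D adds
#' sparse biphasic epileptiform spikes to that background, and class E is a
#' high-amplitude 3-7 Hz rhythmic spike-wave discharge. Amplitudes are in
#' microvolts on the scale typical of scalp/intracranial recordings (tens of
#' microvolts of background, hundreds during seizures).
#'
#' @param n_segments_per_class Number of segments generated for each of the
#'   three classes.
#' @param segment_length Samples per segment (default 4096).
#' @param fs Sampling rate in Hz (default 173.61).
#' @param seed Integer seed; the single source of randomness for the generator.
#' @param class_params Data frame with one row per class and columns `label`,
#'   `rhythm_amp` (uV), `rhythm_lo`/`rhythm_hi` (Hz, dominant-rhythm band),
#'   `spike_rate` (events/s), `spike_amp` (uV), `noise_sd` (uV).
#'
#' @return An object of class `synth_spec`.
#' @export
synth_spec <- function(n_segments_per_class = 100,
                       segment_length = 4096,
                       fs = BONN_FS,
                       seed = 1L,
                       class_params = default_class_params()) {
  stopifnot(is.numeric(n_segments_per_class), n_segments_per_class >= 0,
            n_segments_per_class == round(n_segments_per_class))
  stopifnot(is.numeric(segment_length), segment_length >= 1,
            segment_length == round(segment_length))
  stopifnot(is.numeric(fs), fs > 0)
  stopifnot(is.numeric(seed), length(seed) == 1)
  cp <- as_tibble(class_params)
  need <- c("label", "rhythm_amp", "rhythm_lo", "rhythm_hi",
            "spike_rate", "spike_amp", "noise_sd")
  if (!all(need %in% names(cp)) || !setequal(cp$label, BONN_CLASSES)) {
    abort("class_params must have one row per class A, D, E with columns:
rhythm_amp, rhythm_lo, rhythm_hi, spike_rate, spike_amp, noise_sd",
          class = "selmeeg_validation_error")
  }
  num <- c("rhythm_amp", "spike_rate", "spike_amp", "noise_sd")
  if (any(as.matrix(cp[num]) < 0)) {
    abort("class_params rates and scales must be non-negative",
          class = "selmeeg_validation_error")
  }
  if (any(cp$rhythm_lo <= 0 | cp$rhythm_hi >= fs / 2 |
          cp$rhythm_lo > cp$rhythm_hi)) {
    abort("rhythm bands must satisfy 0 < lo <= hi < fs/2",
          class = "selmeeg_validation_error")
  }
  structure(list(n_segments_per_class = as.integer(n_segments_per_class),
                 segment_length = as.integer(segment_length),
                 fs = fs, seed = as.integer(seed), class_params = cp),
            class = "synth_spec")
}

#' @rdname synth_spec
#' @export
default_class_params <- function() {
  tibble(label      = c("A", "D", "E"),
         rhythm_amp = c(20, 20, 200),
         rhythm_lo  = c(8, 8, 3),
         rhythm_hi  = c(12, 12, 7),
         spike_rate = c(0, 0.7, 3),
         spike_amp  = c(0, 120, 250),
         noise_sd   = c(15, 15, 40))
}

#' Generate a labelled synthetic three-class EEG dataset
#'
#' Deterministic given `(spec, spec$seed)`: the same spec produces bit-for-bit
#' identical samples on every call. The generator exists so that the full
#' band-pass / wavelet / feature / classifier pipeline can be exercised
#' without access to the Bonn archive.
#'
#' @param spec A [synth_spec()].
#' @return A segment tibble (`segment_id`, `label`, `fs`, `samples`) with
#'   `n_segments_per_class` rows per class.
#' @export
#' @examples
#' segs <- generate_synthetic_dataset(synth_spec(n_segments_per_class = 2,
#'                                               segment_length = 512))
#' segs
generate_synthetic_dataset <- function(spec) {
  if (!inherits(spec, "synth_spec")) {
    abort("spec must be a synth_spec object",
          class = "selmeeg_validation_error")
  }
  n <- spec$n_segments_per_class
  if (n == 0) {
    return(new_segment_tbl(character(), character(), numeric(), list()))
  }
  with_local_seed(spec$seed, {
    rows <- purrr::map(BONN_CLASSES, function(cl) {
      p <- spec$class_params[spec$class_params$label == cl, ]
      purrr::map(seq_len(n), function(i) {
        x <- synth_segment(spec$segment_length, spec$fs, p)
        new_segment_tbl(sprintf("%s%03d", cl, i), cl, spec$fs, list(x))
      }) |> purrr::list_rbind()
    })
    purrr::list_rbind(rows)
  })
}

# One synthetic segment: coloured background + dominant rhythm + optional
# biphasic spikes. Consumes RNG draws in a fixed order for reproducibility.
synth_segment <- function(len, fs, p) {
  t <- seq_len(len) / fs
  # AR(1)-coloured background (1/f-ish), rescaled to the requested sd
  w <- rnorm(len)
  bg <- as.numeric(stats::filter(w, 0.9, method = "recursive"))
  bg <- bg / sd(bg) * p$noise_sd
  # dominant rhythm at a random frequency in the class band, random phase
  f0 <- runif(1, p$rhythm_lo, p$rhythm_hi)
  ph <- runif(1, 0, 2 * pi)
  x <- bg + p$rhythm_amp * sin(2 * pi * f0 * t + ph)
  # sparse biphasic spikes (derivative-of-Gaussian, ~60 ms width)
  if (p$spike_rate > 0 && p$spike_amp > 0) {
    n_spk <- stats::rpois(1, p$spike_rate * len / fs)
    if (n_spk > 0) {
      centers <- sort(runif(n_spk, 0.05, 0.95)) * len
      tau <- 0.015 * fs                     # ~15 ms time constant
      half <- ceiling(4 * tau)
      for (c0 in centers) {
        idx <- max(1, floor(c0 - half)):min(len, ceiling(c0 + half))
        u <- (idx - c0) / tau
        x[idx] <- x[idx] + p$spike_amp * u * exp(0.5) * exp(-u^2 / 2)
      }
    }
  }
  x
}

# Evaluate `code` under a private RNG stream seeded with `seed`, restoring the
# caller's RNG state afterwards.
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Write a dataset manifest and per-segment Bonn files
#'
#' @param segments Segment tibble.
#' @param dir Output directory (created if needed).
#' @return Tibble (`segment_id`, `label`, `path`) — the manifest, also written
#'   to `manifest.tsv` in `dir`.
#' @export
write_bonn_dataset <- function(segments, dir) {
  check_segments(segments)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, paste0(segments$segment_id, ".txt"))
  purrr::walk2(segments$samples, paths, write_bonn_segment)
  manifest <- tibble(segment_id = segments$segment_id,
                     label = segments$label, path = paths)
  utils::write.table(manifest, file.path(dir, "manifest.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  manifest
}
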