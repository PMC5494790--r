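#' Daubechies-4 analysis filter pair
#'
#' Closed-form 4-tap orthonormal db4 filters. The low-pass taps are
#' \eqn{h_0=(1+\sqrt3)/(4\sqrt2)}, \eqn{h_1=(3+\sqrt3)/(4\sqrt2)},
#' \eqn{h_2=(3-\sqrt3)/(4\sqrt2)}, \eqn{h_3=(1-\sqrt3)/(4\sqrt2)}; the
#' high-pass filter is the quadrature mirror \eqn{(-h_3, h_2, -h_1, h_0)}.
#'
#' @return List with components `lowpass` and `highpass`, each length 4.
#' @export
#' @examples
#' f <- db4_filters()
#' sum(f$lowpass)   # sqrt(2)
#' sum(f$highpass)  # 0
db4_filters <- function() {
  s3 <- sqrt(3)
  h <- c(1 + s3, 3 + s3, 3 - s3, 1 - s3) / (4 * sqrt(2))
  list(lowpass = h, highpass = c(-h[4], h[3], -h[2], h[1]))
}

#' Band-limit an EEG segment to 0-32 Hz
#'
#' Zero-phase (forward-backward) Butterworth low-pass at 32 Hz. The nominal
#' band is 0-32 Hz; with a lower edge at DC this is a low-pass filter. The
#' forward-backward pass doubles the effective order and removes group delay,
#' so epochs cut from the filtered segment stay aligned with the raw signal.
#'
#' @param segments Segment tibble, or a bare numeric vector (then `fs` is
#'   required).
#' @param fs Sampling rate in Hz when `segments` is a numeric vector.
#' @param cutoff Cutoff frequency in Hz (default 32).
#' @param order Butterworth order of each pass (default 4).
#' @return Same shape as the input with filtered samples.
#' @export
bandpass_0_32 <- function(segments, fs = NULL, cutoff = 32, order = 4) {
  if (is.numeric(segments)) {
    stopifnot(!is.null(fs))
    return(bandpass_vec(segments, fs, cutoff, order))
  }
  check_segments(segments)
  dplyr::mutate(segments,
                samples = purrr::map2(.data$samples, .data$fs,
                                      bandpass_vec,
                                      cutoff = cutoff, order = order))
}

bandpass_vec <- function(x, fs, cutoff, order) {
  if (fs <= 2 * cutoff) {
    abort(sprintf(
      "sampling rate %.4g Hz too low: the %g Hz cutoff must lie below Nyquist",
      fs, cutoff), class = "selmeeg_config_error")
  }
  bf <- signal::butter(order, cutoff / (fs / 2), type = "low")
  as.numeric(signal::filtfilt(bf, x))
}

# --- lifting-scheme db4 ------------------------------------------------------

# One analysis level of the db4 lifting scheme on the even/odd polyphase
# components (periodic boundary). Steps, in order:
#   update:  s1 = even + sqrt(3) * odd
#   predict: d1 = odd - (sqrt(3)/4) s1 - ((sqrt(3)-2)/4) s1[l-1]
#   update:  s2 = s1 - d1[l+1]
#   scale:   a = ((sqrt(3)-1)/sqrt(2)) s2 ;  d = ((sqrt(3)+1)/sqrt(2)) d1
# Equivalent to circular convolution/decimation with the db4 filter pair:
#   a[l] = sum_m h[m] x[2l+m],  d[l] = sum_m hh[m] x[2l-2+m]  (0-based, mod L).

#' One level of db4 lifting analysis
#'
#' The caller performs the even/odd split; even-indexed samples (1st, 3rd, ...)
#' feed the approximation branch and odd-indexed the prediction branch.
#' Boundary handling is periodic, which keeps the transform orthonormal
#' (energy-preserving) and exactly invertible.
#'
#' @param even,odd Equal-length numeric vectors of polyphase components.
#' @return List with `approx` and `detail`, each `length(even)`.
#' @export
lifting_step <- function(even, odd) {
  if (length(even) != length(odd)) {
    abort("even and odd polyphase components must have equal length",
          class = "selmeeg_internal_error")
  }
  n <- length(even)
  s3 <- sqrt(3)
  prev <- c(n, seq_len(n - 1))   # l-1 (periodic)
  nxt <- c(seq_len(n - 1) + 1, 1) # l+1 (periodic)
  s1 <- even + s3 * odd
  d1 <- odd - (s3 / 4) * s1 - ((s3 - 2) / 4) * s1[prev]
  s2 <- s1 - d1[nxt]
  list(approx = (s3 - 1) / sqrt(2) * s2,
       detail = (s3 + 1) / sqrt(2) * d1)
}

#' Invert one level of db4 lifting
#'
#' @param approx,detail Equal-length coefficient vectors from [lifting_step()].
#' @return Numeric vector of length `2 * length(approx)`.
#' @export
lifting_step_inverse <- function(approx, detail) {
  if (length(approx) != length(detail)) {
    abort("approx and detail must have equal length",
          class = "selmeeg_internal_error")
  }
  n <- length(approx)
  s3 <- sqrt(3)
  prev <- c(n, seq_len(n - 1))
  nxt <- c(seq_len(n - 1) + 1, 1)
  s2 <- approx / ((s3 - 1) / sqrt(2))
  d1 <- detail / ((s3 + 1) / sqrt(2))
  s1 <- s2 + d1[nxt]
  odd <- d1 + (s3 / 4) * s1 + ((s3 - 2) / 4) * s1[prev]
  even <- s1 - s3 * odd
  x <- numeric(2 * n)
  x[seq(1, 2 * n, 2)] <- even
  x[seq(2, 2 * n, 2)] <- odd
  x
}

#' Three-level db4 wavelet decomposition of one epoch
#'
#' Recursively applies [lifting_step()] to the approximation branch, producing
#' the four subbands of the standard clinical decomposition at an effective
#' 64 Hz analysis rate: `a3` (approximation, nominally 0-4 Hz, delta), `d3`
#' (4-8 Hz, theta), `d2` (8-16 Hz, alpha), `d1` (16-32 Hz, beta).
#'
#' @param x Numeric vector whose length is divisible by 8 (512 in the standard
#'   pipeline).
#' @return A `subband_set`: list with `a3`, `d3`, `d2`, `d1` of lengths
#'   `L/8, L/8, L/4, L/2`.
#' @export
#' @examples
#' sb <- decompose3(sin(2 * pi * 5 * seq_len(512) / 173.61))
#' lengths(sb[c("a3", "d3", "d2", "d1")])
decompose3 <- function(x) {
  stopifnot(is.numeric(x))
  if (length(x) %% 8 != 0) {
    abort(sprintf(
      "epoch length must be divisible by 8 for a 3-level decomposition (got %d)",
      length(x)), class = "selmeeg_validation_error")
  }
  lvl <- function(v) lifting_step(v[seq(1, length(v), 2)],
                                  v[seq(2, length(v), 2)])
  l1 <- lvl(x)
  l2 <- lvl(l1$approx)
  l3 <- lvl(l2$approx)
  structure(list(a3 = l3$approx, d3 = l3$detail,
                 d2 = l2$detail, d1 = l1$detail),
            class = "subband_set")
}

#' Invert a three-level db4 decomposition
#'
#' Exact inverse of [decompose3()]: `reconstruct3(decompose3(x))` recovers `x`
#' to machine precision for any admissible `x`.
#'
#' @param subbands A `subband_set` (or plain list with `a3`, `d3`, `d2`, `d1`).
#' @return Numeric vector of length `8 * length(subbands$a3)`.
#' @export
reconstruct3 <- function(subbands) {
  sb <- subbands[c("a3", "d3", "d2", "d1")]
  if (any(vapply(sb, is.null, logical(1)))) {
    abort("subbands must contain a3, d3, d2, d1",
          class = "selmeeg_validation_error")
  }
  n <- length(sb$a3)
  if (length(sb$d3) != n || length(sb$d2) != 2 * n || length(sb$d1) != 4 * n) {
    abort("inconsistent subband lengths: need |d3|=|a3|, |d2|=2|a3|, |d1|=4|a3|",
          class = "selmeeg_validation_error")
  }
  a2 <- lifting_step_inverse(sb$a3, sb$d3)
  a1 <- lifting_step_inverse(a2, sb$d2)
  lifting_step_inverse(a1, sb$d1)
}

#' @export
print.subband_set <- function(x, ...) {
  cat("<subband_set>  a3/d3/d2/d1 lengths:",
      paste(lengths(x[c("a3", "d3", "d2", "d1")]), collapse = "/"), "\n")
  invisible(x)
}

#' Export subband coefficients as a long table
#'
#' @param subbands A `subband_set`.
#' @param epoch_id Optional provenance identifier.
#' @return Tibble with columns `epoch_id`, `subband`, `index`, `value`.
#' @export
tidy_subbands <- function(subbands, epoch_id = NA_character_) {
  purrr::imap(subbands[c("a3", "d3", "d2", "d1")], function(v, nm) {
    tibble(epoch_id = epoch_id, subband = nm,
           index = seq_along(v), value = as.numeric(v))
  }) |> purrr::list_rbind()
}
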