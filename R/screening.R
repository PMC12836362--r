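# MALDI candidate screening: mass-window filtering and paired
# derivatization-shift matching across native / reduced-alkylated /
# digested peak lists.

#' Construct a MALDI peak list
#'
#' @param mz Numeric vector of m/z values (Da), strictly positive.
#' @param intensity Numeric vector of non-negative intensities (defaults
#'   to 1 for presence-only lists).
#' @param label Optional sample label.
#' @param tolerance Assumed calibration tolerance (Da) carried as an
#'   attribute; matching functions use their own `tol` argument.
#' @return A data frame of class `peaklist` with columns `mz`, `intensity`,
#'   sorted ascending by `mz`.
#' @export
peaklist <- function(mz, intensity = rep(1, length(mz)), label = NULL,
                     tolerance = 0.5) {
  stopifnot(is.numeric(mz), is.numeric(intensity),
            length(mz) == length(intensity))
  if (any(mz <= 0)) stop("m/z values must be strictly positive", call. = FALSE)
  if (any(intensity < 0)) stop("intensities must be >= 0", call. = FALSE)
  ord <- order(mz)
  structure(data.frame(mz = mz[ord], intensity = intensity[ord]),
            class = c("peaklist", "data.frame"),
            label = label, tolerance = tolerance)
}

#' Retain peaks inside a mass window
#'
#' @param peaks A [peaklist()].
#' @param lo,hi Window bounds in Da (inclusive); `lo < hi`. The default
#'   2500-4000 Da is the MALDI detection range used for cyclotide
#'   screening; the narrower 2900-3900 Da observation window is available
#'   via [screen_config()].
#' @return A `peaklist` with only the in-window peaks, order and
#'   intensities preserved.
#' @export
window_filter <- function(peaks, lo = 2500, hi = 4000) {
  stopifnot(inherits(peaks, "peaklist"))
  if (!(lo < hi)) stop("window requires lo < hi", call. = FALSE)
  keep <- peaks$mz >= lo & peaks$mz <= hi
  out <- peaks[keep, , drop = FALSE]
  rownames(out) <- NULL
  attributes(out)[c("label", "tolerance")] <-
    attributes(peaks)[c("label", "tolerance")]
  class(out) <- c("peaklist", "data.frame")
  out
}

#' Match an expected mass shift between two peak lists
#'
#' Finds, for every native peak, the treated peak whose offset from
#' `native + expected_delta` is smallest; a match is emitted when that
#' offset is within `tol`. Each native peak is paired to at most one
#' treated peak (best = smallest absolute error, ties broken by lowest
#' treated m/z); the result is independent of input peak order.
#'
#' @param native,treated [peaklist()]s on the same calibration scale.
#' @param expected_delta Expected mass shift (Da), e.g.
#'   [derivatization_shift()] or [ring_opening_shift()].
#' @param tol Matching tolerance (Da), > 0.
#' @return Data frame with columns `native_mz`, `treated_mz`,
#'   `observed_delta`, `expected_delta`, `abs_error`, sorted by `native_mz`.
#' @export
match_shift <- function(native, treated, expected_delta, tol = 0.5) {
  stopifnot(inherits(native, "peaklist"), inherits(treated, "peaklist"))
  if (!(tol > 0)) stop("tol must be > 0", call. = FALSE)
  empty <- data.frame(native_mz = numeric(), treated_mz = numeric(),
                      observed_delta = numeric(), expected_delta = numeric(),
                      abs_error = numeric())
  if (nrow(native) == 0L || nrow(treated) == 0L) return(empty)
  rows <- lapply(sort(native$mz), function(n) {
    err <- abs(treated$mz - n - expected_delta)
    best <- which(err == min(err))
    best <- best[which.min(treated$mz[best])]  # deterministic tie-break
    if (err[best] > tol) return(NULL)
    data.frame(native_mz = n, treated_mz = treated$mz[best],
               observed_delta = treated$mz[best] - n,
               expected_delta = expected_delta, abs_error = err[best])
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Screening configuration
#'
#' @param window Mass window c(lo, hi) in Da; the 2900-3900 Da preset is the
#'   window in which cyclotide-like signals are typically observed.
#' @param tol Shift-matching tolerance in Da. The default 0.5 Da reflects
#'   MALDI calibration accuracy; `literature_mode` widens it to 2.5 Da to
#'   accommodate published peak annotations that deviate by up to ~2 Da.
#' @param nominal Use nominal (+348/+18) instead of exact shifts.
#' @param n_cys,n_disulfides Assumed cysteine scaffold for the
#'   derivatization shift (cyclotide default 6 Cys / 3 S-S).
#' @param require_ring_evidence If `TRUE`, the +18 digest shift is required
#'   before a peak is called a candidate; by default it is recorded as
#'   evidence only.
#' @param literature_mode Logical; widens `tol` to 2.5 Da.
#' @return A list of class `screen_config`.
#' @export
screen_config <- function(window = c(2500, 4000), tol = 0.5, nominal = FALSE,
                          n_cys = 6L, n_disulfides = 3L,
                          require_ring_evidence = FALSE,
                          literature_mode = FALSE) {
  if (literature_mode) tol <- 2.5
  structure(list(window = window, tol = tol, nominal = nominal,
                 n_cys = n_cys, n_disulfides = n_disulfides,
                 require_ring_evidence = require_ring_evidence),
            class = "screen_config")
}

#' Call cyclotide candidates from a native/RA/digest peak-list triple
#'
#' Implements the screening logic: a native peak is a cyclotide candidate
#' iff it lies in the mass window and shows the full derivatization shift
#' (+348 Da nominal for the 6-Cys/3-S-S scaffold) into the
#' reduced-alkylated (RA) list. A further ring-opening shift (+18 Da) from
#' the matched RA peak into the digested list is recorded as
#' cyclic-backbone evidence (`shift_18_after_digest`).
#'
#' @param native,reduced_alkylated [peaklist()]s; `reduced_alkylated` is
#'   required.
#' @param digested Optional digested-sample [peaklist()]; if `NULL` the
#'   ring-opening evidence flag is `NA`.
#' @param config A [screen_config()].
#' @return Data frame of class `cyclotide_candidates` with columns
#'   `native_mz`, `ra_mz`, `digest_mz`, `in_window`, `shift_348`,
#'   `shift_18_after_digest`, `shift_error`.
#' @export
call_candidates <- function(native, reduced_alkylated, digested = NULL,
                            config = screen_config()) {
  stopifnot(inherits(config, "screen_config"))
  if (missing(reduced_alkylated) || is.null(reduced_alkylated)) {
    stop("reduced/alkylated peak list is required to call candidates",
         call. = FALSE)
  }
  win <- window_filter(native, config$window[1], config$window[2])
  deriv <- derivatization_shift(config$n_cys, config$n_disulfides,
                                nominal = config$nominal)
  ring <- ring_opening_shift(nominal = config$nominal)
  m348 <- match_shift(win, reduced_alkylated, deriv, tol = config$tol)
  if (nrow(m348) == 0L) {
    out <- data.frame(native_mz = numeric(), ra_mz = numeric(),
                      digest_mz = numeric(), in_window = logical(),
                      shift_348 = logical(),
                      shift_18_after_digest = logical(),
                      shift_error = numeric())
    class(out) <- c("cyclotide_candidates", "data.frame")
    return(out)
  }
  digest_mz <- rep(NA_real_, nrow(m348))
  ring_flag <- rep(NA, nrow(m348))
  if (!is.null(digested)) {
    for (i in seq_len(nrow(m348))) {
      ra_one <- peaklist(m348$treated_mz[i])
      m18 <- match_shift(ra_one, digested, ring, tol = config$tol)
      ring_flag[i] <- nrow(m18) > 0L
      if (ring_flag[i]) digest_mz[i] <- m18$treated_mz[1]
    }
  }
  out <- data.frame(native_mz = m348$native_mz, ra_mz = m348$treated_mz,
                    digest_mz = digest_mz, in_window = TRUE,
                    shift_348 = TRUE, shift_18_after_digest = ring_flag,
                    shift_error = m348$abs_error)
  if (config$require_ring_evidence) {
    out <- out[!is.na(out$shift_18_after_digest) & out$shift_18_after_digest,
               , drop = FALSE]
    rownames(out) <- NULL
  }
  class(out) <- c("cyclotide_candidates", "data.frame")
  out
}
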