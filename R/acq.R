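#' Acquisition parameters for an edited MRS experiment
#'
#' Container for the acquisition settings shared by every FID of a scan. The
#' defaults reproduce the acquisition protocol the synthetic cohort emulates:
#' TR 2000 ms, 256 transients, 2.5 kHz spectral width and 2048 complex points,
#' with the carrier (and frequency reference) on water at 4.68 ppm. Phase
#' cycling is metadata only and is not simulated.
#'
#' @param transmitter_mhz Transmitter frequency in MHz (default 127.7, i.e. 3 T;
#'   the field strength is an assumption, flagged in the configuration).
#' @param center_ppm Chemical shift of the carrier, ppm.
#' @param sw_hz Spectral width in Hz.
#' @param n_points Number of complex points per FID.
#' @param te_ms,tr_ms Echo and repetition time, ms.
#' @param n_transients Total number of transients across all sub-experiments.
#' @param sequence_tag `"HERMES80"` or `"MEGA120"`.
#' @param editing_ppm Frequencies (ppm) of the editing pulses.
#' @return An object of class `acq_params`.
#' @export
acq_params <- function(transmitter_mhz = 127.7, center_ppm = 4.68,
                       sw_hz = 2500, n_points = 2048, te_ms = 80,
                       tr_ms = 2000, n_transients = 256,
                       sequence_tag = c("HERMES80", "MEGA120"),
                       editing_ppm = c(1.9, 4.56)) {
  sequence_tag <- match.arg(sequence_tag)
  stopifnot(sw_hz > 0, n_points >= 2, transmitter_mhz > 0, n_transients >= 1)
  structure(list(
    transmitter_mhz = transmitter_mhz, center_ppm = center_ppm, sw_hz = sw_hz,
    n_points = as.integer(n_points), te_ms = te_ms, tr_ms = tr_ms,
    n_transients = as.integer(n_transients), sequence_tag = sequence_tag,
    editing_ppm = editing_ppm
  ), class = "acq_params")
}

#' HERMES (TE 80 ms) acquisition defaults
#' @param n_transients Total transient count (divided over four sub-experiments).
#' @export
acq_hermes80 <- function(n_transients = 256) {
  acq_params(te_ms = 80, sequence_tag = "HERMES80",
             editing_ppm = c(1.9, 4.56), n_transients = n_transients)
}

#' MEGA-PRESS GSH (TE 120 ms) acquisition defaults
#' @param n_transients Total transient count (divided over ON/OFF).
#' @export
acq_mega120 <- function(n_transients = 256) {
  acq_params(te_ms = 120, sequence_tag = "MEGA120",
             editing_ppm = 4.56, n_transients = n_transients)
}

#' @export
print.acq_params <- function(x, ...) {
  cat(sprintf("<acq_params> %s: %.1f MHz, %.0f Hz / %d pts, TE %.0f ms, %d transients\n",
              x$sequence_tag, x$transmitter_mhz, x$sw_hz, x$n_points,
              x$te_ms, x$n_transients))
  invisible(x)
}

#' Dwell time in seconds
#' @param acq An `acq_params` object.
#' @export
dwell_time <- function(acq) 1 / acq$sw_hz

#' Time axis (s) for an FID of `n` points
#' @param acq An `acq_params` object.
#' @param n Number of points; defaults to `acq$n_points`.
#' @export
time_axis <- function(acq, n = acq$n_points) (seq_len(n) - 1) * dwell_time(acq)

#' Chemical-shift axis in ppm
#'
#' Returns a descending ppm axis of `n` points spanning
#' `center_ppm +/- sw_hz / (2 * transmitter_mhz)` inclusive, so the axis width
#' in Hz equals the spectral width for any `n`. Offset frequency f (Hz,
#' relative to the carrier) and ppm are related by
#' `ppm = center_ppm + f / transmitter_mhz`.
#'
#' @param acq An `acq_params` object.
#' @param n Number of axis points (>= 2).
#' @export
ppm_axis <- function(acq, n = acq$n_points) {
  if (!is.numeric(n) || length(n) != 1 || n < 2) {
    stop("`n` must be a single value >= 2")
  }
  half <- acq$sw_hz / (2 * acq$transmitter_mhz)
  seq(acq$center_ppm + half, acq$center_ppm - half, length.out = n)
}

#' Convert ppm to offset frequency (Hz relative to the carrier)
#' @param ppm Chemical shifts, ppm.
#' @param acq An `acq_params` object.
#' @export
ppm_to_hz <- function(ppm, acq) (ppm - acq$center_ppm) * acq$transmitter_mhz

#' Convert offset frequency (Hz) to ppm
#' @param hz Offset frequencies in Hz relative to the carrier.
#' @param acq An `acq_params` object.
#' @export
hz_to_ppm <- function(hz, acq) acq$center_ppm + hz / acq$transmitter_mhz
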