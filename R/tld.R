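#' Chip sensitivity calibration factors
#'
#' From a calibration irradiation in which every chip received the same dose,
#' the sensitivity calibration factor of chip i is
#' `SCF_i = mean(R - bkg) / (R_i - bkg)`, so that multiplying a net readout by
#' its SCF removes the chip-to-chip sensitivity spread.
#'
#' @param readings Raw calibration readouts (nC), one per chip.
#' @param background Background readout subtracted from every reading.
#' @return A tibble with `chip`, `net_reading`, `scf`.
#' @export
sensitivity_factors <- function(readings, background = 0) {
  net <- readings - background
  if (any(net <= 0)) stop("net calibration readings must be positive",
                          call. = FALSE)
  tibble::tibble(chip = seq_along(readings),
                 net_reading = net,
                 scf = mean(net) / net)
}

#' Batch correction factor
#'
#' `BCF = expected / mean(measured)`: rescales a readout session so the batch
#' mean matches the reference dose (or readout) expected from the calibration
#' conditions.
#'
#' @param expected Expected mean response under the calibration conditions.
#' @param measured Measured sensitivity-corrected responses of the batch.
#' @return The scalar batch correction factor.
#' @export
batch_correction <- function(expected, measured) {
  stopifnot(expected > 0, all(measured > 0))
  expected / mean(measured)
}

#' Corrected thermoluminescence signal
#'
#' `TL_i = (R_i - bkg) * SCF_i * BCF`.
#'
#' @param readings Raw readouts (nC).
#' @param scf Chip sensitivity factors, aligned with `readings`.
#' @param bcf Batch correction factor.
#' @param background Background readout.
#' @return Corrected TL signals, same length as `readings`.
#' @export
corrected_readout <- function(readings, scf, bcf = 1, background = 0) {
  stopifnot(length(scf) == length(readings), bcf > 0)
  net <- readings - background
  if (any(net <= 0)) stop("net readings must be positive", call. = FALSE)
  net * scf * bcf
}

#' Measured dose reduction factor from paired TLD sets
#'
#' Ratio of the mean corrected signal with contrast filling to the mean
#' corrected signal with saline filling, with a first-order propagated
#' standard error of the ratio of means.
#'
#' @param contrast_tl Corrected TL signals measured with contrast filling.
#' @param saline_tl Corrected TL signals measured with saline filling.
#' @return A one-row tibble with `drf`, `se`, `n_contrast`, `n_saline`.
#' @export
measured_drf <- function(contrast_tl, saline_tl) {
  stopifnot(length(contrast_tl) >= 1, length(saline_tl) >= 1,
            all(contrast_tl > 0), all(saline_tl > 0))
  mc <- mean(contrast_tl)
  ms <- mean(saline_tl)
  rel2 <- function(x) if (length(x) > 1) {
    stats::var(x) / length(x) / mean(x)^2
  } else 0
  tibble::tibble(drf = mc / ms,
                 se = mc / ms * sqrt(rel2(contrast_tl) + rel2(saline_tl)),
                 n_contrast = length(contrast_tl),
                 n_saline = length(saline_tl))
}

#' Simulate TLD chip readouts
#'
#' Generates raw readouts for chips with log-normally distributed individual
#' sensitivities (default coefficient of variation 1.3%, typical of a
#' hand-selected LiF chip set) plus optional readout noise and background.
#'
#' @param dose_gy True dose to each chip (recycled to `n_chips`).
#' @param n_chips Number of chips.
#' @param sensitivity_cv Coefficient of variation of chip sensitivity.
#' @param noise_cv Coefficient of variation of single-readout noise.
#' @param response_nc_per_gy Mean chip response in nC per Gy.
#' @param background Background readout added to every reading.
#' @return A tibble with `chip`, `dose_gy`, `sensitivity`, `reading`.
#' @export
simulate_tld_readings <- function(dose_gy, n_chips = length(dose_gy),
                                  sensitivity_cv = 0.013,
                                  noise_cv = 0.005,
                                  response_nc_per_gy = 100,
                                  background = 0) {
  stopifnot(all(dose_gy >= 0), n_chips >= 1,
            sensitivity_cv >= 0, noise_cv >= 0, response_nc_per_gy > 0)
  dose <- rep_len(dose_gy, n_chips)
  sdlog <- sqrt(log(1 + sensitivity_cv^2))
  sens <- stats::rlnorm(n_chips, meanlog = -sdlog^2 / 2, sdlog = sdlog)
  reading <- dose * sens * response_nc_per_gy *
    (1 + stats::rnorm(n_chips, 0, noise_cv)) + background
  tibble::tibble(chip = seq_len(n_chips), dose_gy = dose,
                 sensitivity = sens, reading = reading)
}
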