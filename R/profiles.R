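#' Measured spectroscopic inputs for the rsGreen constructs
#'
#' The measured per-protein inputs of the spectroscopic pipeline for EGFP,
#' rsGreen1, rsGreenF and their Enhancer-nanobody fusions: peak
#' excitation/emission wavelengths, pKa, fluorescence quantum yield and the
#' apparent extinction coefficient at pH 7.4, together with the relative
#' in-situ brightness readouts from colony plates (grown at 37 degrees C)
#' and live HeLa cells (both scaled to 100 for rsGreen1; `NA` where not
#' determined). Derived quantities — the deprotonated-state extinction
#' coefficient and the scaled molecular brightness — are computed by
#' [spectro_table()], not stored.
#'
#' @return Data frame with columns `name`, `lambda_ex`, `lambda_em`, `pKa`,
#'   `phi_fl`, `eps74` (L mol^-1 cm^-1), `ecoli_brightness`,
#'   `hela_brightness`.
#' @export
#' @examples
#' spectro_table(rsgreen_profiles())
rsgreen_profiles <- function() {
  path <- system.file("extdata", "rsgreen_profiles.csv", package = "rsfpfit",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
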