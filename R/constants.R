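# Molar extinction coefficients for oxy- and deoxyhemoglobin at the two
# device wavelengths, in cm^-1 mM^-1 on the decadic (base-10) convention
# (compiled values from the standard tabulation used throughout CW-NIRS).
# Rows: wavelength (nm); columns: HbO, HbR.
EXTINCTION <- matrix(
  c(0.5860, 1.5485,   # 760 nm
    1.0580, 0.6913),  # 850 nm
  nrow = 2, byrow = TRUE,
  dimnames = list(c("760", "850"), c("hbo", "hbr"))
)

WAVELENGTHS <- c(760, 850)

#' Default differential pathlength factor (device-unit calibration)
#'
#' Scales the geometric emitter-detector separation to the effective photon
#' path length through tissue. Applied identically at both wavelengths.
#' @keywords internal
DEFAULT_DPF <- 1.0

SUBREGIONS <- c("left_lateral", "lower_medial", "right_lateral")
CONDITIONS <- c("standard", "dnn")

# Sentence presentation time used by the session designer (s).
SENTENCE_DURATION_S <- 6
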