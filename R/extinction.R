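#' Hemoglobin extinction coefficients at the PAM excitation wavelengths
#'
#' Returns the bundled molar extinction coefficients (cm^-1/M) of oxy- and
#' deoxyhemoglobin at 532 and 559 nm, the dual-wavelength pair used for sO2
#' imaging. 532 nm is close to an isosbestic point (oxy and deoxy absorb
#' almost equally, so amplitude there reports total hemoglobin/structure),
#' while 559 nm sits near the deoxyhemoglobin peak and provides the
#' oxygenation contrast. The file header records the provenance of the
#' tabulation.
#'
#' @return A data.frame with columns `wavelength_nm`, `eps_hbo2`, `eps_hb`.
#' @examples
#' hb_extinction()
#' @export
hb_extinction <- function() {
  path <- system.file("extdata", "hb_extinction.csv", package = "mpam",
                      mustWork = TRUE)
  tab <- utils::read.csv(path, comment.char = "#",
                         colClasses = "numeric")
  stopifnot(all(c("wavelength_nm", "eps_hbo2", "eps_hb") %in% names(tab)))
  tab
}

# Look up one wavelength row; errors on wavelengths absent from the table.
extinction_at <- function(wavelength, extinction = hb_extinction()) {
  i <- match(wavelength, extinction$wavelength_nm)
  if (is.na(i))
    stop(sprintf("wavelength %s nm not in extinction table (have: %s)",
                 wavelength,
                 paste(extinction$wavelength_nm, collapse = ", ")),
         call. = FALSE)
  extinction[i, , drop = FALSE]
}

# Relative absorption coefficient of blood at `wavelength` for saturation
# `so2`, normalised by oxyhemoglobin extinction at 532 nm so simulated
# amplitudes are O(1).
blood_absorption <- function(so2, wavelength, extinction = hb_extinction()) {
  row <- extinction_at(wavelength, extinction)
  ref <- extinction_at(532, extinction)$eps_hbo2
  (so2 * row$eps_hbo2 + (1 - so2) * row$eps_hb) / ref
}
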