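#' Thermal energy conversion
#'
#' All estimator-internal quantities in this package are reduced
#' (dimensionless, energies divided by kT); user-facing free energies are in
#' kJ/mol. `kT_kJmol()` converts between the two conventions using the molar
#' gas constant R = 8.31446 J/(mol K), so at the default 300 K one kT is
#' 2.4943 kJ/mol.
#'
#' @param temperature Temperature in kelvin.
#' @return kT in kJ/mol.
#' @examples
#' kT_kJmol(300)  # 2.4943
#' @export
kT_kJmol <- function(temperature = 300) {
  stopifnot(is.numeric(temperature), length(temperature) == 1L,
            is.finite(temperature), temperature > 0)
  .gas_constant_kJ * temperature
}

# molar gas constant, kJ/(mol K)
.gas_constant_kJ <- 8.31446e-3
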