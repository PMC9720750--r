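#' Physical constants used throughout the package
#'
#' @description
#' `boltzmann_k_ev()` returns the Boltzmann constant in eV K^-1 used to form
#' the inverse thermal energy 1/kT.  The default is the physical (CODATA)
#' value 8.617333e-5 eV K^-1.  Some published analyses print the transposed
#' value 8.167e-5 eV K^-1; pass it explicitly wherever a `boltzmann_k`
#' argument is exposed to reproduce results computed with that constant
#' (activation energies rescale proportionally to k, p-values are unchanged).
#'
#' `oxyjoule_equivalent()` returns the energy released per unit oxygen
#' consumed, 0.45 J (umol O2)^-1, the standard oxycaloric value for a mixed
#' catabolic substrate in aquatic invertebrates.
#'
#' @return A numeric scalar.
#' @examples
#' boltzmann_k_ev()
#' oxyjoule_equivalent()
#' @export
boltzmann_k_ev <- function() 8.617333e-5

#' @rdname boltzmann_k_ev
#' @export
oxyjoule_equivalent <- function() 0.45

# standard atmosphere in torr and the mole fraction of O2 in dry air
.ATM_TORR <- 760
.O2_MOLE_FRACTION <- 0.20946
.ZERO_C_K <- 273.15
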