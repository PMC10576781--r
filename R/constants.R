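# Physical constants shared across the package.

#' Proton mass
#'
#' Mass of the proton in Da, used in every neutral-mass / m/z conversion.
#'
#' @format Length-one numeric.
#' @export
M_PROTON <- 1.007276466

#' Isotopologue spacing
#'
#' Fixed spacing between adjacent isotopologue centroids in Da. A single
#' averaged spacing is adequate at the +/- 10 ppm tolerances used for ion
#' matching throughout the package.
#'
#' @format Length-one numeric.
#' @export
ISOTOPE_SPACING <- 1.00235

# Monoisotopic masses and isotope abundance patterns (by neutron-number
# offset from the lightest isotope) for the elements of the averagine model.
.element_data <- list(
  C = list(mono = 12.0,           ab = c(0.9893, 0.0107)),
  H = list(mono = 1.00782503207,  ab = c(0.999885, 0.000115)),
  N = list(mono = 14.0030740048,  ab = c(0.99636, 0.00364)),
  O = list(mono = 15.99491461956, ab = c(0.99757, 0.00038, 0.00205)),
  S = list(mono = 31.97207100,    ab = c(0.9493, 0.0076, 0.0429, 0, 0.0002))
)

# Averagine monomer composition per 111.1254 Da of protein mass.
.averagine_unit <- c(C = 4.9384, H = 7.7583, N = 1.3577, O = 1.4773, S = 0.0417)
.averagine_unit_mass <- 111.1254
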