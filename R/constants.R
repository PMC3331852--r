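#' Mass constants used throughout the package
#'
#' Monoisotopic masses in Daltons: the proton, the water molecule lost on
#' peptide-bond formation, the heavy-isotope mass shifts used by label
#' schemes, and the 20 canonical amino-acid residue masses.
#'
#' @format A named list with elements `proton`, `water`, `d13C`, `d15N`
#'   and `residues` (a named numeric vector over the 20 canonical
#'   one-letter codes).
#' @export
MASS_CONSTANTS <- list(
  proton = 1.007276,
  water  = 18.010565,
  d13C   = 1.003355,
  d15N   = 0.997035,
  residues = c(
    G =  57.021464, A =  71.037114, S =  87.032028, P =  97.052764,
    V =  99.068414, T = 101.047679, C = 103.009185, L = 113.084064,
    I = 113.084064, N = 114.042927, D = 115.026943, Q = 128.058578,
    K = 128.094963, E = 129.042593, M = 131.040485, H = 137.058912,
    F = 147.068414, R = 156.101111, Y = 163.063329, W = 186.079313
  )
)

#' Named modification mass deltas
#'
#' The variable modifications accepted when building a native-peptide
#' spectral library: methionine (or other) oxidation, and pyroglutamate
#' formation from N-terminal Gln or Glu.
#'
#' @format Named numeric vector of mass deltas in Da.
#' @export
MOD_DELTAS <- c(
  "oxidation"    =  15.994915,
  "pyro-glu-Q"   = -17.026549,
  "pyro-glu-E"   = -18.010565
)
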