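# Mass discretization and the residue mass table.
#
# All graph arithmetic runs on scaled integers: floor(mass_Da * 274.335215).
# The scale factor maps monoisotopic residue masses close to integers so that
# integer dynamic programming over mass coordinates is possible.

MASS_SCALE <- 274.335215

#' Scale factor used for mass discretization
#'
#' All masses (peak masses, residue masses, modification masses) are converted
#' to integers as `floor(mass * mass_scale())` before any graph or alignment
#' arithmetic. One scaled unit corresponds to about 3.65 mDa.
#'
#' @return The scalar scale factor (274.335215).
#' @export
mass_scale <- function() MASS_SCALE

#' Convert a mass in Dalton to its scaled integer representation
#'
#' @param mass Numeric vector of non-negative masses in Da.
#' @return Integer-valued numeric vector `floor(mass * mass_scale())`.
#'   Monotone non-decreasing in `mass`.
#' @examples
#' discretize_mass(c(0, 1.00235, 57.02146))
#' @export
discretize_mass <- function(mass) {
  if (!is.numeric(mass)) stop("`mass` must be numeric", call. = FALSE)
  if (any(is.na(mass))) stop("`mass` must not contain NA", call. = FALSE)
  if (any(mass < 0)) stop("`mass` must be non-negative", call. = FALSE)
  floor(mass * MASS_SCALE)
}

#' Standard monoisotopic residue mass table
#'
#' Monoisotopic masses (Da) of the 20 standard amino-acid residues, i.e. the
#' mass each residue contributes to a peptide chain. Glycine is the smallest
#' entry; its scaled value (15642) is the default `m_small` in the tolerance
#' precondition check (see [dp_align()]).
#'
#' @return Named numeric vector of length 20 (names are one-letter codes).
#' @export
residue_masses <- function() {
  c(
    G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
    T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
    D = 115.02694, Q = 128.05858, E = 129.04259, K = 128.09496, M = 131.04049,
    H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
  )
}
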