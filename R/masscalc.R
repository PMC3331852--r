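#' Monoisotopic mass of a peptide
#'
#' Sum of residue masses plus one water, plus any modification and
#' stable-isotope-label mass deltas.
#'
#' @param pep A [peptide()] or a sequence string.
#' @return Neutral monoisotopic mass in Da.
#' @examples
#' monoisotopic_mass(peptide("G"))  # 75.03203
#' @export
monoisotopic_mass <- function(pep) {
  pep <- as_peptide(pep)
  sum(MASS_CONSTANTS$residues[pep$residues]) + MASS_CONSTANTS$water +
    sum(mod_deltas(pep)) + sum(label_deltas(pep))
}

as_peptide <- function(x) {
  if (inherits(x, "peptide")) x else peptide(x)
}

#' Precursor m/z
#'
#' `(M + z * proton) / z` for the protonated peptide.
#'
#' @inheritParams monoisotopic_mass
#' @param charge Positive integer charge state.
#' @return m/z (Th).
#' @examples
#' precursor_mz(peptide("DSGEGDFLAEGGGVR"), 2)  # 733.33
#' @export
precursor_mz <- function(pep, charge) {
  if (charge < 1) stop("charge must be >= 1")
  (monoisotopic_mass(pep) + charge * MASS_CONSTANTS$proton) / charge
}

#' Fragment ion m/z
#'
#' b- and y-series fragment m/z with 1-based indexing (y1 is the C-terminal
#' residue, b1 the N-terminal one). A modification or label contributes to a
#' fragment if and only if its residue position lies inside the fragment's
#' span: residues `1..k` for `b_k`, residues `n-k+1..n` for `y_k`.
#'
#' @inheritParams monoisotopic_mass
#' @param series `"y"` or `"b"`.
#' @param index Fragment length, `1 <= index <= length - 1`.
#' @param charge Positive integer fragment charge.
#' @return m/z (Th).
#' @examples
#' fragment_mz(peptide("DSGEGDFLAEGGGVR"), "y", 8, 1)  # 758.42
#' @export
fragment_mz <- function(pep, series, index, charge = 1L) {
  pep <- as_peptide(pep)
  n <- length(pep$residues)
  if (index < 1 || index > n - 1)
    stop(sprintf("fragment index %d outside 1..%d", index, n - 1L))
  if (charge < 1) stop("charge must be >= 1")
  series <- match.arg(series, c("y", "b"))
  span <- if (series == "b") seq_len(index) else seq.int(n - index + 1L, n)
  m <- sum(MASS_CONSTANTS$residues[pep$residues[span]]) +
    sum(mod_deltas(pep)[span]) + sum(label_deltas(pep)[span])
  if (series == "y") m <- m + MASS_CONSTANTS$water
  (m + charge * MASS_CONSTANTS$proton) / charge
}

#' Complementarity residual of a b/y fragment pair
#'
#' For any split point k, the singly charged b_k and y_(n-k) ions partition
#' the precursor: `b_k + y_(n-k) = M + 2 * proton`. The returned residual
#' should be zero to numerical precision; it is an internal-consistency
#' check of the fragment arithmetic (labels and modifications included).
#'
#' @inheritParams monoisotopic_mass
#' @param k Split point, `1 <= k <= length - 1`.
#' @return Residual in Da.
#' @export
complementary_check <- function(pep, k) {
  pep <- as_peptide(pep)
  n <- length(pep$residues)
  fragment_mz(pep, "b", k, 1L) + fragment_mz(pep, "y", n - k, 1L) -
    (monoisotopic_mass(pep) + 2 * MASS_CONSTANTS$proton)
}

#' Round m/z for display the way transition tables print it
#'
#' Half-even rounding to 2 decimals; internal arithmetic is always kept at
#' full precision.
#'
#' @param x Numeric.
#' @return Numeric rounded to 2 decimals.
#' @export
mz_round <- function(x) round(x, 2)
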