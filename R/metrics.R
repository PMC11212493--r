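# Alignment quality metrics.
#
# Errors are measured on the UNCORRECTED (observed) masses against the
# theoretical sub-path masses the alignment chose: for matched triples q < q'
# the observed mass difference is m_{i_q'} - m_{i_q} and the theoretical one
# is corrected_{q'} - corrected_q (the sum of chosen sub-path masses), so the
# pairwise error is the accumulated signed consecutive error between them.
# MME/AME are reported as absolute values; signed consecutive errors are kept
# for diagnostics.

#' Absolute mass errors over all pairs of matched peaks
#'
#' For every pair `q < q'` of matched triples, the absolute difference
#' between the observed mass gap and the theoretical (chosen sub-path) mass
#' between them.  The list has length \eqn{r(r-1)/2}.
#'
#' @param a An `mg_alignment` (should verify, see [verify_alignment()]).
#' @return Numeric vector of absolute errors in scaled units (empty for
#'   alignments of size < 2).
#' @export
pairwise_mass_errors <- function(a) {
  stopifnot(inherits(a, "mg_alignment"))
  tr <- a$triples
  r <- nrow(tr)
  if (r < 2) return(numeric(0))
  # cumulative signed error of each triple relative to the first
  s <- (tr$peak_mass - tr$corrected) - (tr$peak_mass[1] - tr$corrected[1])
  pairs <- which(upper.tri(diag(r)), arr.ind = TRUE)
  abs(s[pairs[, 2]] - s[pairs[, 1]])
}

#' Maximum mass error of an alignment
#'
#' @param errors Numeric vector from [pairwise_mass_errors()].
#' @return The maximum absolute pairwise error (0 for an empty list).
#' @export
mme <- function(errors) {
  if (length(errors) == 0) return(0)
  max(errors)
}

#' Average mass error of an alignment
#'
#' @inheritParams mme
#' @return The mean absolute pairwise error (0 for an empty list).
#' @export
ame <- function(errors) {
  if (length(errors) == 0) return(0)
  mean(errors)
}

#' Residue-match histogram
#'
#' Buckets each consecutive matched pair by the number of residues its
#' sub-path spans: 1, 2, or >= 3.  The counts sum to `r - 1`.
#'
#' @param a An `mg_alignment`.
#' @return Named integer vector `c(matches_1, matches_2, matches_3plus)`.
#' @export
residue_match_histogram <- function(a) {
  stopifnot(inherits(a, "mg_alignment"))
  span <- a$triples$span[-1]
  if (nrow(a$triples) < 2) span <- integer(0)
  c(matches_1 = sum(span == 1),
    matches_2 = sum(span == 2),
    matches_3plus = sum(span >= 3))
}

#' Summary metrics of an alignment
#'
#' @param a An `mg_alignment`.
#' @return A list with `score`, `mme`, `ame`, the residue-match counts
#'   `matches_1`/`matches_2`/`matches_3plus`, and the signed
#'   `consecutive_errors` (observed minus theoretical, one per step).
#' @export
alignment_metrics <- function(a) {
  stopifnot(inherits(a, "mg_alignment"))
  errors <- pairwise_mass_errors(a)
  hist <- residue_match_histogram(a)
  tr <- a$triples
  consec <- if (nrow(tr) >= 2) {
    diff(tr$peak_mass) - diff(tr$corrected)
  } else numeric(0)
  list(score = a$score, mme = mme(errors), ame = ame(errors),
       matches_1 = unname(hist["matches_1"]),
       matches_2 = unname(hist["matches_2"]),
       matches_3plus = unname(hist["matches_3plus"]),
       consecutive_errors = consec)
}
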