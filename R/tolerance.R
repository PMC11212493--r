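# Per-peak error tolerance models.
#
# Every peak y_i gets a symmetric tolerance delta_i plus asymmetric bounds
# (lower, upper) initialized to delta_i.  Dominated peaks (whose candidate
# corrected-position interval is contained in a neighbour's) are pruned, and
# remaining overlapping intervals are shrunk to be pairwise disjoint so that
# every candidate corrected position is examined exactly once by the DP.

new_tol_profile <- function(delta, lower, upper, disjoint = FALSE) {
  structure(list(delta = as.numeric(delta),
                 lower = as.numeric(lower),
                 upper = as.numeric(upper),
                 delta_max = if (length(delta) > 0) max(delta) else 0,
                 q = if (length(delta) > 0) max(lower + upper) else 0,
                 disjoint = disjoint),
            class = "tol_profile")
}

#' Fixed per-peak error tolerance
#'
#' Assigns the same symmetric tolerance `delta` (scaled units) to every peak
#' node; `y_0` always gets 0 because its mass is exact by construction.
#'
#' @param smg An `smg`.
#' @param delta Non-negative tolerance in scaled integer units (default 27,
#'   about 0.1 Da).
#' @return A `tol_profile` with fields `delta`, `lower`, `upper` (one entry
#'   per SMG node, `y_0` first), `delta_max` and `q`.
#' @export
fixed_tolerance <- function(smg, delta = 27) {
  stopifnot(inherits(smg, "smg"), delta >= 0)
  d <- c(0, rep(as.numeric(delta), smg$m))
  new_tol_profile(d, d, d)
}

#' Peak-dependent error tolerance
#'
#' Larger peaks carry larger absolute errors, so the tolerance grows with a
#' ppm term on top of a constant: for an original peak,
#' `delta_i = base + round(ppm * m_i / 1e6)`; for a complementary peak the
#' whole-protein mass contributes too,
#' `delta_i = base + round(ppm * (m_i + M) / 1e6)` with `M` the scaled
#' precursor mass.  Satellite peaks inherit the formula of the peak class
#' that spawned them.
#'
#' @param smg An `smg` whose nodes carry provenance.
#' @param ppm Parts-per-million coefficient (default 15).
#' @param base Constant term in scaled units (default 27).
#' @return A `tol_profile`.
#' @export
peak_dependent_tolerance <- function(smg, ppm = 15, base = 27) {
  stopifnot(inherits(smg, "smg"), ppm >= 0, base >= 0)
  is_comp <- smg$tol_class == "complementary"
  if (any(is_comp) && is.na(smg$precursor)) {
    stop("precursor mass required for complementary-peak tolerance",
         call. = FALSE)
  }
  eff_mass <- smg$mass + ifelse(is_comp, smg$precursor, 0)
  d <- base + round(ppm * eff_mass / 1e6)
  d[1] <- 0  # y_0
  new_tol_profile(d, d, d)
}

#' Prune peaks dominated by a neighbour's tolerance interval
#'
#' If a peak's interval `[m_i - lower_i, m_i + upper_i]` is completely
#' contained in a neighbouring peak's interval, the contained peak is
#' redundant (any corrected position it offers is offered by the neighbour
#' too) and is deleted.  Containment between consecutive peaks is iterated to
#' a fixpoint; on mutual containment (identical intervals) the later
#' (larger-mass) peak is kept.  `y_0` is never removed.
#'
#' @param smg An `smg`.
#' @param prof A `tol_profile` aligned with `smg`.
#' @return `list(smg = , profile = )` with consistent renumbering.
#' @export
prune_dominated_peaks <- function(smg, prof) {
  stopifnot(inherits(smg, "smg"), inherits(prof, "tol_profile"))
  stopifnot(length(prof$delta) == smg$m + 1L)
  mass <- smg$mass; lo <- prof$lower; up <- prof$upper
  # corrected masses must stay positive: position 0 belongs to y_0 alone
  lo <- pmin(lo, pmax(mass - 1, 0))
  keep <- rep(TRUE, length(mass))
  repeat {
    idx <- which(keep)
    if (length(idx) < 2) break
    a <- idx[-length(idx)]; b <- idx[-1]
    la <- mass[a] - lo[a]; ua <- mass[a] + up[a]
    lb <- mass[b] - lo[b]; ub <- mass[b] + up[b]
    a_in_b <- la >= lb & ua <= ub
    b_in_a <- lb >= la & ub <= ua
    drop_a <- a_in_b                      # mutual containment drops earlier
    drop_b <- b_in_a & !a_in_b
    victims <- unique(c(a[drop_a], b[drop_b]))
    victims <- setdiff(victims, 1L)       # y_0 immune
    if (length(victims) == 0) break
    keep[victims] <- FALSE
  }
  sub <- function(v) v[keep]
  smg2 <- structure(list(mass = sub(smg$mass), provenance = sub(smg$provenance),
                         tol_class = sub(smg$tol_class),
                         precursor = smg$precursor, m = sum(keep) - 1L),
                    class = "smg")
  prof2 <- new_tol_profile(sub(prof$delta), sub(prof$lower), sub(prof$upper),
                           disjoint = prof$disjoint)
  # delta_max keeps the original symmetric deltas' maximum over survivors
  list(smg = smg2, profile = prof2)
}

#' Delete overlaps between consecutive tolerance intervals
#'
#' Shrinks `upper_i` / `lower_{i+1}` of each overlapping consecutive pair so
#' the intervals become pairwise disjoint while the union of covered integer
#' positions is preserved exactly.  Overlapped positions are assigned to the
#' nearer peak (midpoint split, ties to the earlier peak).  Requires
#' dominated peaks to have been pruned first.
#'
#' @inheritParams prune_dominated_peaks
#' @return A `tol_profile` with `disjoint = TRUE`.
#' @export
disjointify_ranges <- function(smg, prof) {
  stopifnot(inherits(smg, "smg"), inherits(prof, "tol_profile"))
  stopifnot(length(prof$delta) == smg$m + 1L)
  mass <- smg$mass; lo <- prof$lower; up <- prof$upper
  nn <- length(mass)
  if (nn >= 2) {
    # containment must be gone before boundaries are moved; check the raw
    # intervals in one pass first
    a <- seq_len(nn - 1L); b <- a + 1L
    contained <-
      (mass[a] - lo[a] >= mass[b] - lo[b] & mass[a] + up[a] <= mass[b] + up[b]) |
      (mass[b] - lo[b] >= mass[a] - lo[a] & mass[b] + up[b] <= mass[a] + up[a])
    if (any(contained)) {
      stop("contained interval found; run prune_dominated_peaks() first",
           call. = FALSE)
    }
    for (i in seq_len(nn - 1L)) {
      if (mass[i] + up[i] >= mass[i + 1L] - lo[i + 1L]) {   # overlap
        bnd <- floor((mass[i] + mass[i + 1L]) / 2)
        up[i] <- min(up[i], bnd - mass[i])
        lo[i + 1L] <- min(lo[i + 1L], mass[i + 1L] - bnd - 1)
      }
    }
  }
  out <- new_tol_profile(prof$delta, lo, up, disjoint = TRUE)
  out
}

#' @export
print.tol_profile <- function(x, ...) {
  cat(sprintf("Tolerance profile: %d node(s), delta_max = %g, q = %g, %s\n",
              length(x$delta), x$delta_max, x$q,
              if (isTRUE(x$disjoint)) "ranges disjoint" else "raw ranges"))
  invisible(x)
}

#' Full tolerance preprocessing pipeline
#'
#' Convenience wrapper: compute the tolerance profile (fixed or
#' peak-dependent), prune dominated peaks, and disjointify the ranges.
#'
#' @param smg An `smg`.
#' @param mode `"fixed"` or `"peak_dependent"`.
#' @param delta Fixed tolerance (scaled units), used when `mode = "fixed"`.
#' @param ppm ppm coefficient, used when `mode = "peak_dependent"`.
#' @return `list(smg = , profile = )` ready for [dp_align()].
#' @export
prepare_tolerance <- function(smg, mode = c("fixed", "peak_dependent"),
                              delta = 27, ppm = 15) {
  mode <- match.arg(mode)
  prof <- switch(mode,
                 fixed = fixed_tolerance(smg, delta),
                 peak_dependent = peak_dependent_tolerance(smg, ppm))
  pd <- prune_dominated_peaks(smg, prof)
  pd$profile <- disjointify_ranges(pd$smg, pd$profile)
  pd
}
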