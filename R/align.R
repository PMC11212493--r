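# Error-correction alignment: DP wrappers, traceback, verification, oracles.
#
# The optimal alignment is a maximum-length sequence of triples
# (x_j, y_i, k): peak y_i, corrected by k scaled units, matches node x_j,
# and every consecutive corrected mass difference equals a sub-path mass of
# the proteoform mass graph EXACTLY.  The C++ core (align_core_cpp) fills
# the table over disjoint corrected-position ranges; the R oracles below
# (brute_force_align, dp_score_full_ranges) re-derive optima independently
# on small instances.

check_theorem1 <- function(pmg, prof) {
  edges <- c(pmg$black, pmg$red$mass)
  m_small <- min(edges)
  if (m_small <= 4 * prof$delta_max) {
    stop(errorCondition(
      sprintf(paste0("Theorem 1 precondition violated: smallest edge mass ",
                     "(%g) must exceed 4 * delta_max (%g); overlap deletion ",
                     "is not mass-preserving under this tolerance"),
              m_small, 4 * prof$delta_max),
      class = c("mgalign_theorem1_error", "error", "condition")))
  }
  invisible(TRUE)
}

# shared preprocessing: prune + disjointify unless already done
resolve_profile <- function(smg, prof) {
  if (isTRUE(prof$disjoint)) {
    return(list(smg = smg, profile = prof, kept = seq_along(smg$mass)))
  }
  pd <- prune_dominated_peaks(smg, prof)
  kept <- match(pd$smg$mass, smg$mass)
  pd$profile <- disjointify_ranges(pd$smg, pd$profile)
  list(smg = pd$smg, profile = pd$profile, kept = kept)
}

run_align_core <- function(pmg, smg, prof, caps, universe,
                           diagonal = FALSE, start_node = 0L,
                           start_peak = 0L, band = Inf) {
  stopifnot(inherits(pmg, "pmg"), inherits(smg, "smg"),
            inherits(prof, "tol_profile"), isTRUE(prof$disjoint))
  stopifnot(length(prof$delta) == smg$m + 1L)
  check_theorem1(pmg, prof)
  if (is.null(universe)) universe <- subpath_mass_universe(pmg, caps)
  lo <- smg$mass - prof$lower
  hi <- smg$mass + prof$upper
  lo[1] <- hi[1] <- 0  # y_0 exact
  if (max(c(smg$mass, hi, pmg$prefix_black)) >= 2^31 - 1) {
    stop("scaled masses exceed integer range", call. = FALSE)
  }
  band_num <- if (is.finite(band)) as.numeric(band) else
    .Machine$double.xmax / 2
  res <- align_core_cpp(as.integer(smg$mass), as.integer(lo), as.integer(hi),
                        as.integer(universe$s), as.integer(universe$j),
                        as.integer(universe$mass), as.integer(pmg$n),
                        diagonal, as.integer(start_node),
                        as.integer(start_peak), band_num,
                        as.integer(pmg$prefix_black))
  structure(list(score = res$score,
                 raw = data.frame(node = res$node, peak = res$peak,
                                  k = res$k, corrected = res$pos),
                 pmg = pmg, smg = smg, profile = prof, caps = caps,
                 mode = if (diagonal) "diagonal" else "global",
                 start = if (diagonal) c(node = start_node, peak = start_peak)
                         else NULL,
                 band = if (diagonal) band else NULL),
            class = "dp_state")
}

#' Global error-correction alignment (dynamic program)
#'
#' Fills the alignment table `T(i, j, k)` over the reduced (disjoint)
#' correction ranges and records the optimum.  Both alignment endpoints are
#' free: the score is the maximum over all table cells.  If `prof` has not
#' been disjointified yet, dominated peaks are pruned and overlapping ranges
#' are split automatically (see [prepare_tolerance()]).
#'
#' Refuses to run when the smallest (modified or unmodified) residue edge
#' mass does not exceed `4 * delta_max`, the precondition under which overlap
#' deletion provably preserves the optimum.
#'
#' @param pmg A `pmg`.
#' @param smg An `smg`.
#' @param prof A `tol_profile`; default is [fixed_tolerance()] with delta 27.
#' @param caps See [alignment_caps()].
#' @param universe Optional precomputed [subpath_mass_universe()] for `pmg`
#'   under `caps` (recompute is skipped when aligning one graph repeatedly).
#' @return A `dp_state` with the optimal `score`; pass to [traceback()].
#' @seealso [diagonal_align()], [brute_force_align()], [verify_alignment()]
#' @export
dp_align <- function(pmg, smg, prof = fixed_tolerance(smg),
                     caps = alignment_caps(), universe = NULL) {
  check_theorem1(pmg, prof)   # gate on the raw tolerances, before any pruning
  rp <- resolve_profile(smg, prof)
  run_align_core(pmg, rp$smg, rp$profile, caps, universe)
}

#' Recover the optimal alignment from a filled DP state
#'
#' Follows the arg-max chain back from the best cell (ties broken toward the
#' lexicographically smallest `(peak, node, k)`), yielding the sequence of
#' matched triples together with the sub-path mass and residue span of each
#' step.
#'
#' @param state A `dp_state` from [dp_align()] or [diagonal_align()].
#' @return An object of class `mg_alignment`: a list with `score`, `mode`,
#'   and `triples`, a data.frame with one row per matched triple and columns
#'   `node` (0-based PMG node), `peak` (0-based SMG node), `peak_mass`
#'   (observed scaled mass), `k` (correction), `corrected` (= peak_mass + k),
#'   `subpath_mass` and `span` (NA on the first row).
#' @export
traceback <- function(state) {
  stopifnot(inherits(state, "dp_state"))
  tr <- state$raw
  r <- nrow(tr)
  triples <- data.frame(
    node = tr$node, peak = tr$peak,
    peak_mass = state$smg$mass[tr$peak + 1L],
    k = tr$k, corrected = tr$corrected,
    subpath_mass = c(NA_real_, diff(tr$corrected))[seq_len(max(r, 0)) + 0],
    span = c(NA_integer_, diff(tr$node))[seq_len(max(r, 0)) + 0]
  )
  if (r == 0) triples <- triples[0, , drop = FALSE]
  structure(list(score = state$score, mode = state$mode, triples = triples,
                 pmg = state$pmg, smg = state$smg, profile = state$profile,
                 caps = state$caps),
            class = "mg_alignment")
}

#' @export
print.mg_alignment <- function(x, ...) {
  cat(sprintf("Error-correction alignment (%s): %d matched triple(s)\n",
              x$mode, x$score))
  if (nrow(x$triples) > 0) print(utils::head(x$triples, 10))
  invisible(x)
}

#' Diagonal (banded, local) error-correction alignment
#'
#' Computes the best alignment that starts at the given node/peak pair and
#' extends forward, with every matched pair staying inside a mass band around
#' the unmodified-residue diagonal: `|(m_i - m_i0) - (B_j - B_j0)| <= band`,
#' where `B` is the black-edge prefix mass.  Start positions typically come
#' from an upstream candidate filter.
#'
#' @inheritParams dp_align
#' @param start_node 0-based PMG node index of the alignment start.
#' @param start_peak 0-based SMG node index of the alignment start (indices
#'   refer to `smg` as passed; an error is raised if that peak is removed by
#'   dominated-peak pruning).
#' @param band Half-width of the mass band in scaled units; default
#'   `2 * delta_max + max single-edge mass`, wide enough that no optimal
#'   modification-free stretch is cut.
#' @return An `mg_alignment` (traceback is performed internally).
#' @export
diagonal_align <- function(pmg, smg, prof = fixed_tolerance(smg),
                           start_node, start_peak, band = NULL,
                           caps = alignment_caps(), universe = NULL) {
  stopifnot(inherits(pmg, "pmg"), inherits(smg, "smg"))
  if (start_node < 0 || start_node > pmg$n) {
    stop("`start_node` out of range", call. = FALSE)
  }
  if (start_peak < 0 || start_peak > smg$m) {
    stop("`start_peak` out of range", call. = FALSE)
  }
  check_theorem1(pmg, prof)
  rp <- resolve_profile(smg, prof)
  new_start <- match(start_peak + 1L, rp$kept) - 1L
  if (is.na(new_start)) {
    stop("start peak was removed by dominated-peak pruning", call. = FALSE)
  }
  if (is.null(band)) {
    band <- 2 * rp$profile$delta_max + max(c(pmg$black, pmg$red$mass))
  }
  st <- run_align_core(pmg, rp$smg, rp$profile, caps, universe,
                       diagonal = TRUE, start_node = start_node,
                       start_peak = new_start, band = band)
  traceback(st)
}

#' Verify an error-correction alignment
#'
#' Checks every invariant of a valid alignment: strictly increasing node and
#' peak indices, corrections within each peak's (asymmetric) tolerance
#' bounds, `k = 0` for `y_0`, and -- the defining property -- every
#' consecutive corrected mass difference equal to a member of the sub-path
#' mass set `d(j_{q-1}, j_q)` exactly.
#'
#' @param a An `mg_alignment`.
#' @param pmg,smg,prof,caps Structures the alignment refers to; default to
#'   the ones stored in `a`.
#' @return `TRUE` or `FALSE`, with attribute `diagnostics` naming the first
#'   violated step (empty string if valid).
#' @export
verify_alignment <- function(a, pmg = a$pmg, smg = a$smg, prof = a$profile,
                             caps = a$caps) {
  stopifnot(inherits(a, "mg_alignment"))
  tr <- a$triples
  fail <- function(msg) structure(FALSE, diagnostics = msg)
  if (nrow(tr) == 0) return(structure(TRUE, diagnostics = ""))
  if (any(tr$peak_mass != smg$mass[tr$peak + 1L])) {
    return(fail("peak masses do not match the spectrum mass graph"))
  }
  if (nrow(tr) > 1 &&
      (any(diff(tr$node) <= 0) || any(diff(tr$peak) <= 0))) {
    return(fail("node/peak indices not strictly increasing"))
  }
  lo <- prof$lower[tr$peak + 1L]
  up <- prof$upper[tr$peak + 1L]
  bad_k <- which(tr$k < -lo | tr$k > up)
  if (length(bad_k) > 0) {
    return(fail(sprintf("step %d: correction %g outside [-%g, %g]",
                        bad_k[1], tr$k[bad_k[1]], lo[bad_k[1]], up[bad_k[1]])))
  }
  if (any(tr$peak == 0 & tr$k != 0)) {
    return(fail("y_0 must have correction 0"))
  }
  if (any(tr$corrected != tr$peak_mass + tr$k)) {
    return(fail("corrected mass inconsistent with peak mass + k"))
  }
  if (nrow(tr) > 1) {
    for (q in 2:nrow(tr)) {
      dmass <- tr$corrected[q] - tr$corrected[q - 1]
      dset <- path_masses(pmg, tr$node[q - 1], tr$node[q], caps)
      if (!(dmass %in% dset)) {
        return(fail(sprintf(
          "step %d: corrected difference %g is not a sub-path mass of d(%d, %d)",
          q, dmass, tr$node[q - 1], tr$node[q])))
      }
    }
  }
  structure(TRUE, diagnostics = "")
}

# ---------------------------------------------------------------------------
# Independent oracles (small instances only)

#' Brute-force error-correction alignment (oracle)
#'
#' Exhaustively enumerates increasing (node, peak) triple sequences over the
#' full symmetric correction ranges `[-delta_i, +delta_i]` -- no dominated
#' -peak pruning, no overlap deletion -- and returns a maximum-size valid
#' alignment.  Exponential; guarded to `n <= 10`, `m <= 10`,
#' `delta_max <= 30`.
#'
#' @inheritParams dp_align
#' @return An `mg_alignment` (mode `"brute_force"`).
#' @export
brute_force_align <- function(pmg, smg, prof = fixed_tolerance(smg),
                              caps = alignment_caps()) {
  stopifnot(inherits(pmg, "pmg"), inherits(smg, "smg"))
  if (pmg$n > 10 || smg$m > 10 || prof$delta_max > 30) {
    stop("instance too large for the brute-force oracle", call. = FALSE)
  }
  n <- pmg$n
  mass <- smg$mass
  delta <- prof$delta
  npk <- length(mass)          # peaks incl. y_0, 1-based index
  dset <- new.env(parent = emptyenv())   # cache of path_masses
  get_d <- function(s, j) {
    key <- paste0(s, "_", j)
    if (!exists(key, envir = dset, inherits = FALSE)) {
      assign(key, path_masses(pmg, s, j, caps), envir = dset)
    }
    dset[[key]]
  }
  # best chain starting at (node j, peak index ip [1-based], corrected c)
  extend <- function(j, ip, c) {
    best_size <- 1
    best_path <- list(c(j, ip, c))
    if (j < n && ip < npk) {
      for (j2 in (j + 1):min(n, j + caps$max_gap_residues)) {
        for (mm in get_d(j, j2)) {
          c2 <- c + mm
          for (ip2 in (ip + 1):npk) {
            if (abs(c2 - mass[ip2]) <= delta[ip2]) {
              sub <- extend(j2, ip2, c2)
              if (sub$size + 1 > best_size) {
                best_size <- sub$size + 1
                best_path <- c(list(c(j, ip, c)), sub$path)
              }
            }
          }
        }
      }
    }
    list(size = best_size, path = best_path)
  }
  best <- list(size = 0, path = list())
  for (ip in seq_len(npk)) {
    ks <- (-delta[ip]):(delta[ip])
    for (k in ks) {
      for (j in 0:n) {
        cand <- extend(j, ip, mass[ip] + k)
        if (cand$size > best$size) best <- cand
      }
    }
  }
  steps <- do.call(rbind, best$path)
  triples <- data.frame(
    node = steps[, 1], peak = steps[, 2] - 1L,
    peak_mass = mass[steps[, 2]],
    k = steps[, 3] - mass[steps[, 2]], corrected = steps[, 3],
    subpath_mass = c(NA_real_, diff(steps[, 3])),
    span = c(NA_integer_, diff(steps[, 1]))
  )
  structure(list(score = best$size, mode = "brute_force", triples = triples,
                 pmg = pmg, smg = smg, profile = prof, caps = caps),
            class = "mg_alignment")
}

#' Full-range DP score without overlap deletion (oracle)
#'
#' Pure-R dynamic program over the full symmetric ranges
#' `[-delta_i, +delta_i]` with overlapping corrected positions allowed (each
#' `(peak, k)` cell kept separately) and the predecessor-peak condition
#' `i' < i` enforced explicitly.  Serves as the comparator demonstrating that
#' overlap deletion does not change the optimum.
#'
#' @inheritParams dp_align
#' @return The optimal alignment size (integer).
#' @export
dp_score_full_ranges <- function(pmg, smg, prof = fixed_tolerance(smg),
                                 caps = alignment_caps(), universe = NULL) {
  stopifnot(inherits(pmg, "pmg"), inherits(smg, "smg"))
  if (pmg$n > 30 || smg$m > 30 || prof$delta_max > 50) {
    stop("instance too large for the full-range DP comparator", call. = FALSE)
  }
  if (is.null(universe)) universe <- subpath_mass_universe(pmg, caps)
  mass <- smg$mass
  delta <- prof$delta
  cp <- integer(0); cc <- numeric(0)     # cell peak (1-based), cell position
  for (ip in seq_along(mass)) {
    ks <- (-delta[ip]):(delta[ip])
    cp <- c(cp, rep(ip, length(ks)))
    cc <- c(cc, mass[ip] + ks)
  }
  ncell <- length(cc)
  Tm <- matrix(1, nrow = pmg$n + 1L, ncol = ncell)
  for (j in seq_len(pmg$n)) {
    rows <- universe[universe$j == j, , drop = FALSE]
    for (rr in seq_len(nrow(rows))) {
      s <- rows$s[rr]; mm <- rows$mass[rr]
      for (t in seq_len(ncell)) {
        sel <- which(cc == cc[t] - mm & cp < cp[t])
        if (length(sel) > 0) {
          cand <- max(Tm[s + 1L, sel]) + 1
          if (cand > Tm[j + 1L, t]) Tm[j + 1L, t] <- cand
        }
      }
    }
  }
  as.integer(max(Tm))
}

# ---------------------------------------------------------------------------
# Sorted-index construction (the merge-pass data structures)

#' Index of pairwise peak mass differences
#'
#' All mass differences `m_i - m_i'` (`i' < i`) between spectrum nodes that
#' lie within `2 * delta_max` of some sub-path mass in the universe `D`;
#' pairs that can never satisfy the DP transition condition are omitted.
#'
#' @param smg An `smg`.
#' @param universe A [subpath_mass_universe()] table (or a sorted numeric
#'   vector of sub-path masses).
#' @param prof A `tol_profile`.
#' @return A data.frame with columns `mass` (the difference), `from`, `to`
#'   (0-based peak indices, `from < to`), sorted nondecreasing by `mass`.
#' @export
build_mass_difference_index <- function(smg, universe, prof) {
  stopifnot(inherits(smg, "smg"))
  D <- sort(unique(if (is.data.frame(universe)) universe$mass else universe))
  npk <- length(smg$mass)
  if (npk < 2 || length(D) == 0) {
    return(data.frame(mass = numeric(0), from = integer(0), to = integer(0)))
  }
  pairs <- which(upper.tri(matrix(0, npk, npk)), arr.ind = TRUE)
  d <- smg$mass[pairs[, 2]] - smg$mass[pairs[, 1]]
  # distance from each difference to the nearest universe mass
  idx <- findInterval(d, D)
  lo_d <- ifelse(idx >= 1, d - D[pmax(idx, 1)], Inf)
  hi_d <- ifelse(idx < length(D), D[pmin(idx + 1L, length(D))] - d, Inf)
  nearest <- pmin(abs(lo_d), abs(hi_d))
  keep <- nearest <= 2 * prof$delta_max
  out <- data.frame(mass = d[keep],
                    from = pairs[keep, 1] - 1L, to = pairs[keep, 2] - 1L)
  out <- out[order(out$mass, out$from, out$to), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Candidate predecessor lists for the DP transitions
#'
#' For each target peak `i`, node `j` and admissible sub-path mass `m`
#' ending at `j`, the sorted list of predecessor peaks whose mass difference
#' to `i` (taken from the mass-difference index) lies within the
#' `delta_max`-widened window implied by `i`'s reduced correction range
#' `[-lower_i, +upper_i]`.  Empty lists are omitted.
#'
#' @param smg An `smg`.
#' @param pmg A `pmg` (provides the node set).
#' @param universe A [subpath_mass_universe()] table.
#' @param mdi A [build_mass_difference_index()] table.
#' @param prof A `tol_profile`.
#' @return A data.frame with columns `peak`, `node`, `mass` and a list-column
#'   `preds` of 0-based predecessor peak indices sorted by mass.
#' @export
build_candidate_lists <- function(smg, pmg, universe, mdi, prof) {
  stopifnot(inherits(smg, "smg"), inherits(pmg, "pmg"))
  out <- list()
  dm <- prof$delta_max
  for (j in seq_len(pmg$n)) {
    masses <- sort(unique(universe$mass[universe$j == j]))
    for (i in seq_len(smg$m)) {             # 0-based peak index = i
      mi <- smg$mass[i + 1L]
      for (mm in masses) {
        # predecessor mass window widened by delta_max on both sides
        w_lo <- mi - prof$lower[i + 1L] - mm - dm
        w_hi <- mi + prof$upper[i + 1L] - mm + dm
        rows <- mdi[mdi$to == i & (mi - mdi$mass) >= w_lo &
                      (mi - mdi$mass) <= w_hi, , drop = FALSE]
        if (nrow(rows) > 0) {
          preds <- sort(unique(rows$from))
          out[[length(out) + 1L]] <- data.frame(
            peak = i, node = j, mass = mm, preds = I(list(preds)))
        }
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(peak = integer(0), node = integer(0),
                      mass = numeric(0), preds = I(list())))
  }
  do.call(rbind, out)
}

# ---------------------------------------------------------------------------
# One-call pipeline

#' Align a spectrum against a proteoform mass graph
#'
#' Convenience pipeline: tolerance profile, dominated-peak pruning, overlap
#' deletion, DP alignment (global or diagonal), traceback and quality
#' metrics.
#'
#' @inheritParams dp_align
#' @param tolerance Tolerance model, `"fixed"` or `"peak_dependent"`.
#' @param delta Fixed tolerance (scaled units).
#' @param ppm ppm coefficient for the peak-dependent model.
#' @param mode `"global"` (both endpoints free) or `"diagonal"` (banded,
#'   anchored at `start_node`/`start_peak`).
#' @param start_node,start_peak,band Diagonal-mode parameters, see
#'   [diagonal_align()].
#' @return `list(alignment = <mg_alignment>, metrics = <list>)`.
#' @export
align_spectrum <- function(pmg, smg, tolerance = c("fixed", "peak_dependent"),
                           delta = 27, ppm = 15, caps = alignment_caps(),
                           mode = c("global", "diagonal"),
                           start_node = 0L, start_peak = 0L, band = NULL,
                           universe = NULL) {
  tolerance <- match.arg(tolerance)
  mode <- match.arg(mode)
  prof <- switch(tolerance,
                 fixed = fixed_tolerance(smg, delta),
                 peak_dependent = peak_dependent_tolerance(smg, ppm))
  aln <- if (mode == "global") {
    traceback(dp_align(pmg, smg, prof, caps, universe))
  } else {
    diagonal_align(pmg, smg, prof, start_node, start_peak, band, caps,
                   universe)
  }
  list(alignment = aln, metrics = alignment_metrics(aln))
}
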