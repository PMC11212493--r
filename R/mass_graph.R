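# Mass graph construction.
#
# A proteoform mass graph (PMG) is a linear chain of n+1 bond nodes
# x_0 .. x_n.  Position p (1..n) carries exactly one black edge (the
# unmodified residue mass, scaled) plus zero or more red edges (modified
# masses).  A spectrum mass graph (SMG) is the ordered list of discretized
# peak masses y_0 .. y_m with y_0 = 0, so that the path length from y_0 to
# y_i equals the peak mass m_i.

#' Enumeration caps for sub-path masses
#'
#' The set of theoretical sub-path masses `d(s, j)` grows combinatorially with
#' the number of positions spanned and the number of red (modified) edges
#' chosen, so its enumeration is capped.  `max_gap_residues` bounds `j - s`
#' (how many residues a single alignment step may span); `max_red_edges`
#' bounds the number of modified residues inside one step.
#'
#' @param max_gap_residues Maximum residues per alignment step (default 10).
#' @param max_red_edges Maximum modified residues per step (default 2).
#' @return A list of class `alignment_caps`.
#' @export
alignment_caps <- function(max_gap_residues = 10L, max_red_edges = 2L) {
  max_gap_residues <- as.integer(max_gap_residues)
  max_red_edges <- as.integer(max_red_edges)
  stopifnot(max_gap_residues >= 1L, max_red_edges >= 0L)
  structure(list(max_gap_residues = max_gap_residues,
                 max_red_edges = max_red_edges),
            class = "alignment_caps")
}

#' Build a proteoform mass graph from a sequence and modification rules
#'
#' Every residue contributes one black edge with its scaled unmodified mass;
#' every rule matching a residue adds a parallel red edge with the scaled
#' modified mass.  Nodes are 0-based: `x_0` precedes the first residue and
#' `x_n` follows the last.
#'
#' @param sequence A single amino-acid string (one-letter codes).
#' @param rules A `mod_rules` table or `NULL` for no variable modifications.
#' @param table Residue mass table in Da, see [residue_masses()].
#' @return An object of class `pmg` with components `sequence`, `n`,
#'   `black` (integer vector of scaled edge masses, length `n`),
#'   `red` (data.frame `pos`, `mass`, `rule_id`, `label`) and
#'   `prefix_black` (cumulative black masses, length `n + 1`, starts at 0).
#' @examples
#' build_pmg("GG")
#' @export
build_pmg <- function(sequence, rules = NULL, table = residue_masses()) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (nchar(sequence) == 0L) stop("`sequence` must be non-empty", call. = FALSE)
  res <- strsplit(sequence, "")[[1]]
  unknown <- setdiff(res, names(table))
  if (length(unknown) > 0) {
    stop("unknown residue letter(s): ", paste(unique(unknown), collapse = ", "),
         call. = FALSE)
  }
  black <- as.numeric(discretize_mass(unname(table[res])))
  red <- data.frame(pos = integer(0), mass = numeric(0),
                    rule_id = character(0), label = character(0),
                    stringsAsFactors = FALSE)
  if (!is.null(rules)) {
    rules <- validate_rules(rules)
    absent <- setdiff(unique(rules$target), names(table))
    if (length(absent) > 0) {
      warning("rule target(s) not in residue table, skipped: ",
              paste(absent, collapse = ", "), call. = FALSE)
      rules <- rules[rules$target %in% names(table), , drop = FALSE]
    }
    mod_da <- modified_masses(rules, table)
    if (any(mod_da <= 0)) stop("modified mass must be positive", call. = FALSE)
    hit <- lapply(seq_len(nrow(rules)), function(r) {
      pos <- which(res == rules$target[r])
      if (length(pos) == 0) return(NULL)
      data.frame(pos = pos, mass = as.numeric(discretize_mass(mod_da[r])),
                 rule_id = rules$rule_id[r], label = rules$label[r],
                 stringsAsFactors = FALSE)
    })
    hit <- do.call(rbind, hit)
    if (!is.null(hit) && nrow(hit) > 0) {
      red <- hit[order(hit$pos, hit$mass), , drop = FALSE]
      rownames(red) <- NULL
    }
  }
  structure(list(sequence = sequence, n = length(res), black = black,
                 red = red, prefix_black = c(0, cumsum(black))),
            class = "pmg")
}

#' Low-level proteoform mass graph constructor from scaled edge masses
#'
#' Builds a `pmg` directly from integer edge masses, bypassing the residue
#' table.  Used for small hand-crafted alignment instances (tests, oracles).
#'
#' @param black Integer vector of scaled black edge masses (one per position).
#' @param red Optional data.frame with columns `pos` (1-based position) and
#'   `mass` (scaled integer), plus optional `rule_id`/`label`.
#' @return A `pmg` object; `sequence` is a placeholder of `X`s.
#' @export
pmg_from_masses <- function(black, red = NULL) {
  stopifnot(is.numeric(black), length(black) >= 1L, all(black > 0))
  black <- as.numeric(black)
  n <- length(black)
  if (is.null(red)) {
    red <- data.frame(pos = integer(0), mass = numeric(0),
                      rule_id = character(0), label = character(0),
                      stringsAsFactors = FALSE)
  } else {
    stopifnot(all(c("pos", "mass") %in% names(red)))
    if (is.null(red$rule_id)) red$rule_id <- paste0("red", seq_len(nrow(red)))
    if (is.null(red$label)) red$label <- NA_character_
    stopifnot(all(red$pos >= 1), all(red$pos <= n), all(red$mass > 0))
    red <- red[order(red$pos, red$mass), c("pos", "mass", "rule_id", "label")]
    rownames(red) <- NULL
  }
  structure(list(sequence = paste(rep("X", n), collapse = ""), n = n,
                 black = black, red = red,
                 prefix_black = c(0, cumsum(black))),
            class = "pmg")
}

#' @export
print.pmg <- function(x, ...) {
  cat(sprintf("Proteoform mass graph: %d positions (%d nodes), %d red edge(s)\n",
              x$n, x$n + 1L, nrow(x$red)))
  cat(sprintf("  total black mass (scaled): %d\n",
              as.integer(x$prefix_black[x$n + 1L])))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Spectrum mass graph

#' Build a spectrum mass graph from raw peak masses
#'
#' Preprocesses a deconvoluted prefix-mass peak list into an SMG:
#' complementary peaks (`precursor - m`) are added for every original peak,
#' satellite peaks at `m - 1.00235` and `m + 1.00235` are added for every peak
#' (original or complementary) heavier than `satellite_threshold` to absorb
#' +/-1 Da deconvolution errors, all masses are discretized, the zero-mass
#' node `y_0` is prepended, and exact scaled duplicates are merged (keeping
#' the provenance generated earliest: original before complementary before
#' satellite).
#'
#' @param peaks Numeric vector of raw peak masses in Da (possibly empty).
#' @param precursor_mass Precursor (whole proteoform) mass in Da. Required
#'   when `add_complementary = TRUE`.
#' @param add_complementary Add complementary peaks? Default `TRUE`.
#' @param satellite_threshold Mass (Da) above which satellite peaks are added
#'   (default 5000).
#' @return An object of class `smg` with components `mass` (scaled integer
#'   node masses incl. the 0 of `y_0`), `provenance`, `tol_class` (the
#'   provenance class a satellite inherits from its source peak), `precursor`
#'   (scaled, or `NA`) and `m` (number of peak nodes, excl. `y_0`).
#' @examples
#' build_smg(100.0, precursor_mass = 1000.0)
#' @export
build_smg <- function(peaks, precursor_mass = NULL, add_complementary = TRUE,
                      satellite_threshold = 5000) {
  stopifnot(is.numeric(peaks))
  if (any(peaks < 0)) stop("peak masses must be non-negative", call. = FALSE)
  if (add_complementary && is.null(precursor_mass)) {
    stop("`precursor_mass` is required when add_complementary = TRUE",
         call. = FALSE)
  }
  if (!is.null(precursor_mass) && length(peaks) > 0 &&
      precursor_mass < max(peaks)) {
    stop("`precursor_mass` must be at least the largest peak mass",
         call. = FALSE)
  }
  da <- as.numeric(peaks)
  prov <- rep("original", length(da))
  tolc <- prov
  if (add_complementary && length(da) > 0) {
    comp <- precursor_mass - da
    bad <- comp < 0
    if (any(bad)) {
      warning(sum(bad), " complementary peak(s) below zero skipped",
              call. = FALSE)
      comp <- comp[!bad]
    }
    da <- c(da, comp)
    prov <- c(prov, rep("complementary", length(comp)))
    tolc <- c(tolc, rep("complementary", length(comp)))
  }
  heavy <- which(da > satellite_threshold)
  if (length(heavy) > 0) {
    sat <- c(da[heavy] - 1.00235, da[heavy] + 1.00235)
    da <- c(da, sat)
    prov <- c(prov, rep("satellite", length(sat)))
    tolc <- c(tolc, rep(tolc[heavy], 2L))
  }
  scaled <- discretize_mass(da)
  # y_0 first so it wins duplicate merging at mass 0
  scaled <- c(0, scaled)
  prov <- c("origin", prov)
  tolc <- c("origin", tolc)
  ord <- order(scaled, seq_along(scaled))  # stable: earliest provenance first
  scaled <- scaled[ord]; prov <- prov[ord]; tolc <- tolc[ord]
  keep <- !duplicated(scaled)
  scaled <- scaled[keep]; prov <- prov[keep]; tolc <- tolc[keep]
  structure(list(mass = scaled, provenance = prov, tol_class = tolc,
                 precursor = if (is.null(precursor_mass)) NA_real_
                             else as.numeric(discretize_mass(precursor_mass)),
                 m = length(scaled) - 1L),
            class = "smg")
}

#' Low-level spectrum mass graph constructor from scaled masses
#'
#' Builds an `smg` directly from already-scaled integer peak masses, without
#' complementary/satellite preprocessing.  Used for hand-crafted instances.
#'
#' @param masses Integer vector of scaled peak masses (> 0); `y_0` is added.
#' @param precursor Scaled precursor mass or `NA`.
#' @param tol_class Tolerance class per peak (`"original"` or
#'   `"complementary"`), recycled.
#' @return An `smg` object.
#' @export
smg_from_scaled <- function(masses, precursor = NA_real_,
                            tol_class = "original") {
  stopifnot(is.numeric(masses), all(masses > 0))
  masses <- sort(unique(as.numeric(masses)))
  tol_class <- rep_len(tol_class, length(masses))
  structure(list(mass = c(0, masses),
                 provenance = c("origin", rep("original", length(masses))),
                 tol_class = c("origin", tol_class),
                 precursor = as.numeric(precursor),
                 m = length(masses)),
            class = "smg")
}

#' @export
print.smg <- function(x, ...) {
  cat(sprintf("Spectrum mass graph: %d peak node(s) + y_0; precursor (scaled): %s\n",
              x$m, ifelse(is.na(x$precursor), "NA",
                          format(x$precursor, scientific = FALSE))))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Sub-path mass enumeration

#' Distinct sub-path masses between two nodes of a proteoform mass graph
#'
#' Enumerates every distinct total mass obtainable by choosing one edge
#' (black or red) per position in `(s, j]`, using at most
#' `caps$max_red_edges` red edges.
#'
#' @param pmg A `pmg`.
#' @param s,j 0-based node indices with `0 <= s < j <= n` and
#'   `j - s <= caps$max_gap_residues`.
#' @param caps See [alignment_caps()].
#' @return Sorted numeric vector of distinct scaled masses.
#' @export
path_masses <- function(pmg, s, j, caps = alignment_caps()) {
  stopifnot(inherits(pmg, "pmg"))
  if (s >= j) stop("`s` must be strictly less than `j`", call. = FALSE)
  if (s < 0 || j > pmg$n) stop("node index out of range", call. = FALSE)
  if (j - s > caps$max_gap_residues) {
    stop("span exceeds caps$max_gap_residues", call. = FALSE)
  }
  # masses keyed by red-edge count; position-by-position extension
  acc <- list(`0` = 0)
  for (p in (s + 1L):j) {
    reds <- pmg$red$mass[pmg$red$pos == p]
    nxt <- list()
    for (nm in names(acc)) {
      r <- as.integer(nm)
      nxt[[nm]] <- c(nxt[[nm]], acc[[nm]] + pmg$black[p])
      if (length(reds) > 0 && r < caps$max_red_edges) {
        key <- as.character(r + 1L)
        nxt[[key]] <- c(nxt[[key]], as.vector(outer(acc[[nm]], reds, `+`)))
      }
    }
    acc <- lapply(nxt, unique)
  }
  sort(unique(unlist(acc, use.names = FALSE)))
}

#' Universe of sub-path masses of a proteoform mass graph
#'
#' The union over all node pairs `(s, j)` with `1 <= j - s <=
#' caps$max_gap_residues` of [path_masses()], as a mass-sorted table.  Its
#' row count is the quantity `L` in the alignment's complexity bound.
#'
#' @inheritParams path_masses
#' @return A data.frame with columns `mass`, `s`, `j`, sorted by `mass`
#'   (ties by `s`, `j`), with attribute `L` = number of rows.
#' @export
subpath_mass_universe <- function(pmg, caps = alignment_caps()) {
  stopifnot(inherits(pmg, "pmg"))
  out <- vector("list", pmg$n)
  for (j in seq_len(pmg$n)) {
    smin <- max(0L, j - caps$max_gap_residues)
    rows <- lapply(smin:(j - 1L), function(s) {
      data.frame(mass = path_masses(pmg, s, j, caps), s = s, j = j)
    })
    out[[j]] <- do.call(rbind, rows)
  }
  out <- do.call(rbind, out)
  out <- out[order(out$mass, out$s, out$j), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "L") <- nrow(out)
  out
}
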