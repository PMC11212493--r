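# Synthetic proteins, proteoforms and error-bearing spectra with ground
# truth.
#
# Spectra are simulated directly in the representation the aligner consumes:
# deconvoluted prefix masses.  Peaks are generated in the discretized domain
# -- a peak carrying true scaled prefix P and integer error k is written in
# Da as (P + k + 0.5) / mass_scale(), the centre of the scaled bin -- so that
# discretization recovers P + k exactly and the recorded ground truth is
# exact.  Fragments can be reported from either terminus; C-terminal
# fragments are written as precursor - prefix, which the complementary-peak
# preprocessing of build_smg() maps back onto prefix coordinates.

# sample n integers uniformly from lo:hi (safe for lo == hi)
sample_int_range <- function(lo, hi, n = 1L, replace = FALSE) {
  lo + sample.int(hi - lo + 1L, n, replace = replace) - 1L
}

with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Configuration of the synthetic-data generator
#'
#' Defaults describe the study conditions exercised throughout the package:
#' a 50-protein database of random 30-60-mers, five variable modifications
#' per proteoform, 80% fragment coverage, integer peak errors uniform in
#' `[-epsilon, +epsilon]` scaled units with `epsilon = 27` (the default
#' alignment tolerance), five uniform noise peaks, and fragments reported
#' from both termini in equal proportion.
#'
#' @param seed Integer seed; every generator function is deterministic in it.
#' @param db_size Number of database proteins.
#' @param length_range Protein length range (residues), inclusive.
#' @param n_mods Modifications per simulated proteoform.
#' @param coverage Fraction of internal prefix masses observed (0-1).
#' @param epsilon Half-width of the uniform integer peak error (scaled
#'   units). Instances are guaranteed recoverable when `epsilon <= delta`.
#' @param noise_peaks Number of uniform noise peaks added per spectrum.
#' @param cterm_fraction Fraction of fragments reported from the C terminus.
#' @param drop_terminal Drop the first and last covered internal prefix?
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, db_size = 50L, length_range = c(30L, 60L),
                       n_mods = 5L, coverage = 0.8, epsilon = 27L,
                       noise_peaks = 5L, cterm_fraction = 0.5,
                       drop_terminal = FALSE) {
  stopifnot(coverage >= 0, coverage <= 1, epsilon >= 0, noise_peaks >= 0,
            length_range[1] >= 1, length_range[2] >= length_range[1],
            cterm_fraction >= 0, cterm_fraction <= 1)
  structure(list(seed = as.integer(seed), db_size = as.integer(db_size),
                 length_range = as.integer(length_range),
                 n_mods = as.integer(n_mods), coverage = coverage,
                 epsilon = as.integer(epsilon),
                 noise_peaks = as.integer(noise_peaks),
                 cterm_fraction = cterm_fraction,
                 drop_terminal = isTRUE(drop_terminal)),
            class = "sim_config")
}

#' Random protein database
#'
#' Deterministic in `cfg$seed`: lengths uniform over `cfg$length_range`,
#' residues i.i.d. uniform over the 20 standard amino acids.
#'
#' @param cfg A [sim_config()].
#' @return Named character vector of sequences (names `SYNP0001`, ...),
#'   writable with [write_fasta()].
#' @export
random_protein_db <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  aa <- names(residue_masses())
  with_local_seed(cfg$seed, {
    lens <- sample_int_range(cfg$length_range[1], cfg$length_range[2],
                             cfg$db_size, replace = TRUE)
    seqs <- vapply(lens, function(L) {
      paste(sample(aa, L, replace = TRUE), collapse = "")
    }, character(1))
    names(seqs) <- sprintf("SYNP%04d", seq_along(seqs))
    seqs
  })
}

modifiable_positions <- function(sequence, rules) {
  res <- strsplit(sequence, "")[[1]]
  which(res %in% unique(rules$target))
}

#' Simulate an error-bearing spectrum from a sequence
#'
#' Chooses `cfg$n_mods` modification sites without replacement (one
#' applicable rule per site), computes the proteoform's scaled prefix masses,
#' keeps a coverage fraction of the internal prefixes, perturbs each kept
#' peak by a uniform integer error in `[-epsilon, +epsilon]` scaled units,
#' reports each fragment from the N or C terminus, appends uniform noise
#' peaks, and always emits the whole-proteoform mass (the precursor is always
#' known).  The ground-truth record holds the chosen sites/rules and every
#' kept peak's true scaled prefix and applied error.
#'
#' @param sequence Amino-acid string (a protein or a peptide).
#' @param rules A `mod_rules` table.
#' @param cfg A [sim_config()].
#' @param seed Seed for this spectrum (default `cfg$seed`).
#' @return A list with `peaks` (Da, sorted), `precursor` (Da), `truth`
#'   (list: `sites` data.frame `pos`/`rule_id`; `peaks` data.frame
#'   `prefix_index`/`true_scaled`/`k`/`terminal`), `total_scaled` and
#'   `sequence`.
#' @export
simulate_spectrum <- function(sequence, rules, cfg, seed = cfg$seed) {
  stopifnot(inherits(cfg, "sim_config"))
  rules <- validate_rules(rules)
  res <- strsplit(sequence, "")[[1]]
  L <- length(res)
  cand <- modifiable_positions(sequence, rules)
  if (length(cand) < cfg$n_mods) {
    stop(sprintf("only %d modifiable site(s) for %d requested modifications",
                 length(cand), cfg$n_mods), call. = FALSE)
  }
  table <- residue_masses()
  with_local_seed(seed, {
    sites <- sort(cand[sample.int(length(cand), cfg$n_mods)])
    rule_row <- vapply(sites, function(p) {
      hits <- which(rules$target == res[p])
      if (length(hits) == 1) hits else sample(hits, 1)
    }, integer(1))
    edge_da <- unname(table[res])
    mod_da <- modified_masses(rules, table)
    edge_scaled <- as.numeric(discretize_mass(edge_da))
    edge_scaled[sites] <- as.numeric(discretize_mass(mod_da[rule_row]))
    prefix <- cumsum(edge_scaled)
    total <- prefix[L]
    internal <- seq_len(L - 1L)
    n_keep <- round(cfg$coverage * (L - 1L))
    kept <- sort(internal[sample.int(L - 1L, n_keep)])
    if (cfg$drop_terminal && length(kept) > 0) {
      kept <- setdiff(kept, c(kept[1], kept[length(kept)]))
    }
    k <- if (length(kept) > 0) {
      sample.int(2L * cfg$epsilon + 1L, length(kept), replace = TRUE) -
        cfg$epsilon - 1L
    } else integer(0)
    cterm <- runif(length(kept)) < cfg$cterm_fraction
    scaled_obs <- prefix[kept] + k
    # C-terminal fragments are encoded so that their COMPLEMENT lands
    # mid-bin: precursor - written = (scaled_obs + 0.5) / scale exactly
    written <- ifelse(cterm, (total - scaled_obs) / MASS_SCALE,
                      (scaled_obs + 0.5) / MASS_SCALE)
    precursor_da <- (total + 0.5) / MASS_SCALE
    noise <- if (cfg$noise_peaks > 0) {
      runif(cfg$noise_peaks, 0, precursor_da)
    } else numeric(0)
    peaks <- sort(c(written, precursor_da, noise))
    list(peaks = peaks, precursor = precursor_da,
         truth = list(
           sites = data.frame(pos = sites, rule_id = rules$rule_id[rule_row]),
           peaks = data.frame(prefix_index = kept,
                              true_scaled = prefix[kept], k = k,
                              terminal = ifelse(cterm, "C", "N"))),
         total_scaled = total, sequence = sequence)
  })
}

#' Database-search recovery benchmark on simulated spectra
#'
#' Generates a seeded protein database, simulates one spectrum per selected
#' protein (whole-protein mode) or per random peptide of a selected protein
#' (peptide mode), aligns every spectrum against every database protein with
#' the free-endpoint global DP, and ranks proteins by alignment size (ties:
#' smaller average mass error, then database order).  Reports the fraction of
#' spectra whose true source protein ranks first.
#'
#' @param cfg A [sim_config()].
#' @param rules A `mod_rules` table used both for simulation and search.
#' @param n_spectra Number of spectra to simulate.
#' @param peptide Simulate peptide substrings instead of whole proteins?
#' @param peptide_length_range Peptide length bounds; lengths are drawn
#'   uniformly from `[min, min(max, protein length)]`.
#' @param tolerance,delta,ppm Tolerance model for the search, see
#'   [align_spectrum()].
#' @param caps See [alignment_caps()].
#' @param add_complementary,satellite_threshold Passed to [build_smg()].
#' @return A list with `results` (one row per spectrum: `spectrum`,
#'   `true_protein`, `top_protein`, `score`, `mme`, `ame`, `correct`) and
#'   `accuracy` (fraction correct).
#' @export
benchmark_recovery <- function(cfg, rules, n_spectra = 20L, peptide = FALSE,
                               peptide_length_range = c(23L, 154L),
                               tolerance = c("fixed", "peak_dependent"),
                               delta = 27, ppm = 15,
                               caps = alignment_caps(),
                               add_complementary = TRUE,
                               satellite_threshold = 5000) {
  stopifnot(inherits(cfg, "sim_config"))
  tolerance <- match.arg(tolerance)
  rules <- validate_rules(rules)
  db <- random_protein_db(cfg)
  pmgs <- lapply(db, build_pmg, rules = rules)
  universes <- lapply(pmgs, subpath_mass_universe, caps = caps)

  eligible <- vapply(db, function(s) {
    ok <- length(modifiable_positions(s, rules)) >= cfg$n_mods
    if (peptide) ok <- ok && nchar(s) >= peptide_length_range[1]
    ok
  }, logical(1))
  chosen <- names(db)[eligible]
  if (length(chosen) < n_spectra) {
    stop("not enough eligible proteins for the requested spectra",
         call. = FALSE)
  }
  chosen <- chosen[seq_len(n_spectra)]

  rows <- vector("list", n_spectra)
  for (si in seq_len(n_spectra)) {
    truth_name <- chosen[si]
    seq_full <- db[[truth_name]]
    seed_i <- (cfg$seed + 10007L * si) %% 2147483647L
    target_seq <- seq_full
    if (peptide) {
      target_seq <- with_local_seed(seed_i, {
        L <- nchar(seq_full)
        hi <- min(peptide_length_range[2], L)
        for (try in 1:50) {
          len <- sample_int_range(peptide_length_range[1], hi)
          start <- sample_int_range(1L, L - len + 1L)
          pep <- substr(seq_full, start, start + len - 1L)
          if (length(modifiable_positions(pep, rules)) >= cfg$n_mods) break
          pep <- NULL
        }
        if (is.null(pep)) {
          stop("could not place the requested modifications in a peptide",
               call. = FALSE)
        }
        pep
      })
    }
    sim <- simulate_spectrum(target_seq, rules, cfg, seed = seed_i)
    smg <- build_smg(sim$peaks, sim$precursor,
                     add_complementary = add_complementary,
                     satellite_threshold = satellite_threshold)
    pd <- prepare_tolerance(smg, mode = tolerance, delta = delta, ppm = ppm)

    scores <- numeric(length(db)); ames <- numeric(length(db))
    mmes <- numeric(length(db))
    for (pi in seq_along(db)) {
      st <- dp_align(pmgs[[pi]], pd$smg, pd$profile, caps,
                     universe = universes[[pi]])
      met <- alignment_metrics(traceback(st))
      scores[pi] <- met$score; ames[pi] <- met$ame; mmes[pi] <- met$mme
    }
    top <- order(-scores, ames, seq_along(db))[1]
    rows[[si]] <- data.frame(
      spectrum = si, true_protein = truth_name,
      top_protein = names(db)[top], score = scores[top],
      mme = mmes[top], ame = ames[top],
      correct = names(db)[top] == truth_name)
  }
  results <- do.call(rbind, rows)
  list(results = results, accuracy = mean(results$correct))
}
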