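# Shared fixtures: independent enumeration oracle for sub-path masses and a
# generator of small random alignment instances with scaled-integer edges.

# Exhaustive DFS over per-position edge choices; independent of path_masses().
enum_paths_oracle <- function(black, red, s, j, max_red = Inf) {
  masses <- numeric(0)
  recurse <- function(p, acc, nred) {
    if (p > j) {
      masses <<- c(masses, acc)
      return(invisible())
    }
    recurse(p + 1, acc + black[p], nred)
    for (rm in red$mass[red$pos == p]) {
      if (nred < max_red) recurse(p + 1, acc + rm, nred + 1)
    }
  }
  recurse(s + 1, 0, 0)
  sort(unique(masses))
}

# Random small instance: a PMG with edge masses in [60, 200] (so the overlap
# -deletion precondition m_small > 4*delta holds for delta <= 5) and a
# spectrum built from a true path with in-tolerance errors plus junk peaks.
random_small_instance <- function(seed, delta = 5, with_red = TRUE,
                                  n_max = 8, m_max = 8) {
  set.seed(seed)
  n <- sample(3:n_max, 1)
  black <- sample(60:200, n, replace = TRUE)
  red <- NULL
  if (with_red) {
    npos <- sample(0:2, 1)
    if (npos > 0) {
      red <- data.frame(pos = sample(n, npos),
                        mass = sample(60:200, npos, replace = TRUE))
    }
  }
  pmg <- pmg_from_masses(black, red)
  # a true path through a random node subset
  nodes <- sort(sample(0:n, sample(2:min(4, n + 1), 1)))
  caps <- alignment_caps(max_gap_residues = n, max_red_edges = 2)
  cmass <- 0
  true_peaks <- numeric(0)
  for (q in seq_along(nodes)[-1]) {
    opts <- path_masses(pmg, nodes[q - 1], nodes[q], caps)
    cmass <- cmass + sample(rep(opts, 2), 1)  # rep() defuses sample(n, 1)
    err <- sample((-delta):delta, 1)
    true_peaks <- c(true_peaks, cmass + err)
  }
  junk <- sample(30:max(31, cmass + 50), sample(1:3, 1), replace = TRUE)
  peaks <- unique(sort(c(true_peaks, junk)))
  peaks <- peaks[peaks > 0]
  if (length(peaks) > m_max) peaks <- sort(sample(peaks, m_max))
  smg <- smg_from_scaled(peaks)
  list(pmg = pmg, smg = smg, prof = fixed_tolerance(smg, delta), caps = caps)
}

# Simulated proteoform/spectrum pair aligned against its own protein.
simulate_and_align <- function(seed, n_mods = 2, epsilon = 27, coverage = 0.8,
                               noise_peaks = 5, delta = 27,
                               rules = builtin_rules("common_ptms")) {
  cfg <- sim_config(seed = seed, db_size = 1, length_range = c(30, 60),
                    n_mods = n_mods, coverage = coverage, epsilon = epsilon,
                    noise_peaks = noise_peaks)
  seqs <- random_protein_db(cfg)
  sim <- simulate_spectrum(seqs[[1]], rules, cfg)
  smg <- build_smg(sim$peaks, sim$precursor)
  pmg <- build_pmg(seqs[[1]], rules)
  st <- dp_align(pmg, smg, fixed_tolerance(smg, delta))
  list(alignment = traceback(st), sim = sim, pmg = pmg)
}
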