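# Synthetic proteins, proteoforms and spectra with ground truth.

common <- builtin_rules("common_ptms")

test_that("random protein database is deterministic in the seed", {
  cfg <- sim_config(seed = 1, db_size = 3, length_range = c(10, 10))
  db1 <- random_protein_db(cfg)
  db2 <- random_protein_db(cfg)
  expect_identical(db1, db2)
  expect_true(all(nchar(db1) == 10))
  expect_length(db1, 3)

  db3 <- random_protein_db(sim_config(seed = 2, db_size = 3,
                                      length_range = c(10, 10)))
  expect_false(identical(db1, db3))
})

test_that("simulate_spectrum is reproducible and honours the config", {
  cfg <- sim_config(seed = 7, db_size = 1, length_range = c(40, 40),
                    n_mods = 3, coverage = 0.8, epsilon = 27, noise_peaks = 5)
  seqs <- random_protein_db(cfg)
  s1 <- simulate_spectrum(seqs[[1]], common, cfg)
  s2 <- simulate_spectrum(seqs[[1]], common, cfg)
  expect_identical(s1, s2)
  expect_equal(nrow(s1$truth$sites), 3)
  expect_true(all(abs(s1$truth$peaks$k) <= 27))
  # ground truth discretizes back exactly
  smg <- build_smg(s1$peaks, s1$precursor)
  obs <- s1$truth$peaks$true_scaled + s1$truth$peaks$k
  expect_true(all(obs %in% smg$mass))

  expect_error(
    simulate_spectrum("GGGG", common, sim_config(seed = 1, n_mods = 2)),
    "modifiable site")
})

test_that("noise-free full-coverage spectra are recovered exactly", {
  cfg <- sim_config(seed = 12, db_size = 1, length_range = c(30, 40),
                    n_mods = 2, coverage = 1, epsilon = 0, noise_peaks = 0,
                    cterm_fraction = 0)
  seqs <- random_protein_db(cfg)
  sim <- simulate_spectrum(seqs[[1]], common, cfg)
  pmg <- build_pmg(seqs[[1]], common)
  smg <- build_smg(sim$peaks, sim$precursor, add_complementary = FALSE)
  expect_equal(smg$mass[-1], c(sim$truth$peaks$true_scaled, sim$total_scaled))
  a <- traceback(dp_align(pmg, smg))
  expect_equal(a$score, nchar(seqs[[1]]) + 1)
  expect_true(all(a$triples$k == 0))
  expect_true(verify_alignment(a))
})

test_that("coverage zero leaves only the precursor peak", {
  cfg <- sim_config(seed = 3, db_size = 1, length_range = c(30, 30),
                    n_mods = 1, coverage = 0, epsilon = 0, noise_peaks = 0)
  seqs <- random_protein_db(cfg)
  sim <- simulate_spectrum(seqs[[1]], common, cfg)
  expect_length(sim$peaks, 1)
  expect_equal(sim$peaks, sim$precursor)
})

test_that("in-tolerance errors keep alignments within the 2-delta MME bound", {
  for (seed in 1:5) {
    out <- simulate_and_align(seed, n_mods = 2, epsilon = 27, delta = 27)
    m <- alignment_metrics(out$alignment)
    expect_lte(m$mme, 54)
    expect_true(verify_alignment(out$alignment))
  }
})

test_that("C-terminal fragments are recovered through complementary peaks", {
  cfg <- sim_config(seed = 19, db_size = 1, length_range = c(30, 30),
                    n_mods = 2, coverage = 1, epsilon = 0, noise_peaks = 0,
                    cterm_fraction = 1)
  seqs <- random_protein_db(cfg)
  sim <- simulate_spectrum(seqs[[1]], common, cfg)
  pmg <- build_pmg(seqs[[1]], common)
  smg <- build_smg(sim$peaks, sim$precursor, add_complementary = TRUE)
  a <- traceback(dp_align(pmg, smg))
  expect_equal(a$score, nchar(seqs[[1]]) + 1)
})

test_that("small database searches rank the true protein first", {
  cfg <- sim_config(seed = 23, db_size = 10, length_range = c(30, 45),
                    n_mods = 2, coverage = 0.8, epsilon = 5, noise_peaks = 2)
  bench <- benchmark_recovery(cfg, common, n_spectra = 5)
  expect_equal(bench$accuracy, 1.0)
  expect_equal(nrow(bench$results), 5)
  expect_true(all(bench$results$correct))

  # truth absent from the database: every db protein scores far below the
  # true source, so a strict match can never be correct
  outsider <- random_protein_db(sim_config(seed = 99, db_size = 1,
                                           length_range = c(40, 40)))
  cfg2 <- sim_config(seed = 24, db_size = 5, length_range = c(30, 40),
                     n_mods = 2, coverage = 0.8, epsilon = 5, noise_peaks = 2)
  db <- random_protein_db(cfg2)
  sim <- simulate_spectrum(outsider[[1]], common, cfg2)
  smg <- build_smg(sim$peaks, sim$precursor)
  pd <- prepare_tolerance(smg, "fixed", delta = 27)
  db_scores <- vapply(db, function(s) {
    dp_align(build_pmg(s, common), pd$smg, pd$profile)$score
  }, numeric(1))
  true_score <- dp_align(build_pmg(outsider[[1]], common),
                         pd$smg, pd$profile)$score
  expect_lt(max(db_scores), true_score)

  # single-protein database: trivially correct
  cfg3 <- sim_config(seed = 25, db_size = 1, length_range = c(30, 40),
                     n_mods = 2, coverage = 0.8, epsilon = 5, noise_peaks = 2)
  bench3 <- benchmark_recovery(cfg3, common, n_spectra = 1)
  expect_equal(bench3$accuracy, 1.0)
})

test_that("peptide-mode spectra are searched with free endpoints", {
  cfg <- sim_config(seed = 31, db_size = 8, length_range = c(40, 60),
                    n_mods = 2, coverage = 0.9, epsilon = 5, noise_peaks = 1)
  bench <- benchmark_recovery(cfg, common, n_spectra = 3, peptide = TRUE,
                              peptide_length_range = c(23, 154))
  expect_equal(bench$accuracy, 1.0)
})

test_that("recovered corrections reproduce the simulated perturbations", {
  # epsilon <= delta, full coverage, no noise: every true peak is matched at
  # its exact true prefix coordinate (corrections undo the perturbation)
  cfg <- sim_config(seed = 41, db_size = 1, length_range = c(30, 40),
                    n_mods = 2, coverage = 1, epsilon = 10, noise_peaks = 0,
                    cterm_fraction = 0)
  seqs <- random_protein_db(cfg)
  sim <- simulate_spectrum(seqs[[1]], common, cfg)
  pmg <- build_pmg(seqs[[1]], common)
  smg <- build_smg(sim$peaks, sim$precursor, add_complementary = FALSE)
  a <- traceback(dp_align(pmg, smg, fixed_tolerance(smg, 10)))
  expect_equal(a$score, nchar(seqs[[1]]) + 1)
  matched <- a$triples[a$triples$peak > 0, ]
  truth_pos <- c(sim$truth$peaks$true_scaled, sim$total_scaled)
  expect_equal(sort(matched$corrected), sort(truth_pos))
})
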