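# The error-correction DP, traceback, diagonal mode and the oracles.

three_peak_instance <- function(delta = 2) {
  pmg <- pmg_from_masses(c(100, 150))
  smg <- smg_from_scaled(c(101, 249))
  list(pmg = pmg, smg = smg, prof = fixed_tolerance(smg, delta))
}

test_that("the reference instance aligns with corrections (0, -1, +1)", {
  inst <- three_peak_instance()
  st <- dp_align(inst$pmg, inst$smg, inst$prof)
  expect_equal(st$score, 3)
  a <- traceback(st)
  expect_equal(a$triples$node, c(0, 1, 2))
  expect_equal(a$triples$peak, c(0, 1, 2))
  expect_equal(a$triples$k, c(0, -1, 1))
  expect_equal(a$triples$corrected, c(0, 100, 250))
  expect_true(verify_alignment(a))

  # zero tolerance: no exact chain exists
  expect_equal(dp_align(inst$pmg, inst$smg,
                        fixed_tolerance(inst$smg, 0))$score, 1)
})

test_that("every DP table has optimum at least 1", {
  set.seed(5)
  for (rep in 1:5) {
    inst <- random_small_instance(rep + 100, delta = 2)
    expect_gte(dp_align(inst$pmg, inst$smg, inst$prof, inst$caps)$score, 1)
  }
  empty <- build_smg(numeric(0), precursor_mass = 500)
  expect_equal(dp_align(pmg_from_masses(c(100, 150)), empty,
                        fixed_tolerance(empty, 2))$score, 1)  # y_0 alone
})

test_that("DP equals brute force and full-range DP on random instances", {
  for (i in 1:40) {
    delta <- c(0, 2, 5)[(i %% 3) + 1]
    inst <- random_small_instance(i, delta = delta, with_red = (i %% 2 == 0))
    s_fast <- dp_align(inst$pmg, inst$smg, inst$prof, inst$caps)$score
    s_brute <- brute_force_align(inst$pmg, inst$smg, inst$prof, inst$caps)$score
    s_full <- dp_score_full_ranges(inst$pmg, inst$smg, inst$prof, inst$caps)
    expect_equal(s_fast, s_brute, info = paste("instance", i))
    expect_equal(s_fast, s_full, info = paste("instance", i))
  }
})

test_that("ties resolve to the lexicographically smallest (peak, node, k)", {
  # two symmetric single-step alignments of equal size
  pmg <- pmg_from_masses(c(100, 100))
  smg <- smg_from_scaled(c(100, 200))
  prof <- fixed_tolerance(smg, 0)
  a <- traceback(dp_align(pmg, smg, prof))
  expect_equal(a$score, 3)  # 0-100-200 chain is unique here
  # force a genuine tie: one peak, two equally good nodes
  smg2 <- smg_from_scaled(300)
  a2 <- traceback(dp_align(pmg, smg2, fixed_tolerance(smg2, 2)))
  expect_equal(a2$score, 1)
  expect_equal(a2$triples$peak, 0)   # smallest peak first
  expect_equal(a2$triples$node, 0)   # then smallest node
  expect_equal(a2$triples$k, 0)      # then smallest admissible k
})

test_that("monotonicity: adding a peak never decreases the optimum", {
  set.seed(9)
  for (rep in 1:10) {
    inst <- random_small_instance(rep + 300, delta = 5)
    base <- dp_align(inst$pmg, inst$smg, inst$prof, inst$caps)$score
    extra <- max(inst$smg$mass) + sample(40:120, 1)
    smg2 <- smg_from_scaled(c(inst$smg$mass[-1], extra))
    s2 <- dp_align(inst$pmg, smg2, fixed_tolerance(smg2, 5), inst$caps)$score
    expect_gte(s2, base)
  }
})

test_that("theorem precondition gate refuses over-wide tolerances", {
  inst <- three_peak_instance()
  wide <- fixed_tolerance(inst$smg, 5000)
  expect_error(dp_align(inst$pmg, inst$smg, wide),
               class = "mgalign_theorem1_error")
  expect_error(dp_align(inst$pmg, inst$smg, wide), "Theorem 1 precondition")
  # standard residue table with delta = 27: 15642 > 108, runs fine
  pmg <- build_pmg("GAS")
  smg <- smg_from_scaled(discretize_mass(c(57.02146, 128.05857)))
  expect_silent(dp_align(pmg, smg, fixed_tolerance(smg, 27)))
})

test_that("diagonal mode anchors at the start and respects the band", {
  inst <- three_peak_instance()
  # wide band from (0, 0): same result as global
  g <- traceback(dp_align(inst$pmg, inst$smg, inst$prof))
  d <- diagonal_align(inst$pmg, inst$smg, inst$prof, 0, 0)
  expect_equal(d$score, g$score)
  expect_equal(d$triples, g$triples)

  # nothing after the last positions
  dend <- diagonal_align(inst$pmg, inst$smg, inst$prof,
                         start_node = 2, start_peak = 2)
  expect_equal(dend$score, 1)
  expect_equal(dend$triples$node, 2)
  expect_equal(dend$triples$peak, 2)

  # exact spectrum, zero band, zero tolerance: full-length alignment
  pmg <- pmg_from_masses(c(100, 150, 120))
  smg <- smg_from_scaled(cumsum(c(100, 150, 120)))
  prof0 <- fixed_tolerance(smg, 0)
  dz <- diagonal_align(pmg, smg, prof0, 0, 0, band = 0)
  expect_equal(dz$score, 4)
  expect_true(all(dz$triples$k == 0))

  expect_error(diagonal_align(inst$pmg, inst$smg, inst$prof, 9, 0),
               "start_node")
  expect_error(diagonal_align(inst$pmg, inst$smg, inst$prof, 0, 9),
               "start_peak")
})

test_that("diagonal mode with a free-start-compatible instance matches global", {
  set.seed(123)
  for (rep in 1:5) {
    inst <- random_small_instance(rep + 500, delta = 2)
    g <- dp_align(inst$pmg, inst$smg, inst$prof, inst$caps)
    a <- traceback(g)
    if (nrow(a$triples) == 0) next
    first <- a$triples[1, ]
    d <- diagonal_align(inst$pmg, inst$smg, inst$prof,
                        start_node = first$node, start_peak = first$peak,
                        band = 10 * max(inst$smg$mass) + 1000,
                        caps = inst$caps)
    expect_equal(d$score, g$score)
  }
})

test_that("verify_alignment flags perturbed corrections with diagnostics", {
  inst <- three_peak_instance()
  a <- traceback(dp_align(inst$pmg, inst$smg, inst$prof))
  expect_true(verify_alignment(a))

  bad <- a
  bad$triples$k[2] <- bad$triples$k[2] + 1
  bad$triples$corrected[2] <- bad$triples$corrected[2] + 1
  ok <- verify_alignment(bad)
  expect_false(ok)
  expect_match(attr(ok, "diagnostics"), "step")

  empty <- a
  empty$triples <- empty$triples[0, ]
  expect_true(verify_alignment(empty))
})

test_that("mass difference index keeps only pairs near a sub-path mass", {
  smg <- smg_from_scaled(c(50, 100))
  prof <- fixed_tolerance(smg, 5)
  mdi <- build_mass_difference_index(smg, data.frame(mass = 50, s = 0, j = 1),
                                     prof)
  expect_equal(mdi$mass, c(50, 50))
  expect_equal(mdi$from, c(0, 1))
  expect_equal(mdi$to, c(1, 2))

  only_y0 <- build_smg(numeric(0), precursor_mass = 10)
  expect_equal(nrow(build_mass_difference_index(
    only_y0, data.frame(mass = 50, s = 0, j = 1),
    fixed_tolerance(only_y0, 5))), 0)

  near <- smg_from_scaled(49)
  prof1 <- fixed_tolerance(near, 1)
  mdi1 <- build_mass_difference_index(near, 50, prof1)
  expect_equal(nrow(mdi1), 1)   # |49 - 50| <= 2 * 1
  expect_equal(mdi1$mass, 49)
})

test_that("candidate lists collect in-window predecessors per (peak, node, mass)", {
  pmg <- pmg_from_masses(c(50, 50))
  smg <- smg_from_scaled(c(50, 100))
  prof <- disjointify_ranges(smg, fixed_tolerance(smg, 5))
  uni <- subpath_mass_universe(pmg)
  mdi <- build_mass_difference_index(smg, uni, prof)
  cl <- build_candidate_lists(smg, pmg, uni, mdi, prof)
  row <- cl[cl$peak == 2 & cl$node == 2 & cl$mass == 50, ]
  expect_equal(nrow(row), 1)
  expect_equal(row$preds[[1]], 1)

  empty_u <- uni[0, ]
  expect_equal(nrow(build_candidate_lists(smg, pmg, empty_u, mdi[0, ], prof)),
               0)

  # a peak pair in-window for two distinct sub-path masses appears under both
  pmg2 <- pmg_from_masses(50, red = data.frame(pos = 1, mass = 51))
  uni2 <- subpath_mass_universe(pmg2)
  smg2 <- smg_from_scaled(c(58, 110))
  prof2 <- disjointify_ranges(smg2, fixed_tolerance(smg2, 5))
  mdi2 <- build_mass_difference_index(smg2, uni2, prof2)
  cl2 <- build_candidate_lists(smg2, pmg2, uni2, mdi2, prof2)
  hit <- cl2[cl2$peak == 2 & cl2$node == 1, ]
  expect_setequal(hit$mass, c(50, 51))
  expect_true(all(vapply(hit$preds, function(p) 1 %in% p, logical(1))))
})
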