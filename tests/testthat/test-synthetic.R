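# Seeded synthetic generators: formula libraries, pathway databases,
# noisy measured features.

test_that("library generation honours its postconditions", {
  lib <- generate_library(1000, mass_min = 50, mass_max = 2000, seed = 42)
  expect_identical(nrow(lib), 1000L)
  expect_true(all(lib$mass >= 50 & lib$mass <= 2000))
  expect_false(anyDuplicated(lib[CHNOPS]) > 0)
  r <- element_ranges()
  for (e in CHNOPS) {
    expect_true(all(lib[[e]] >= r$min[e] & lib[[e]] <= r$max[e]))
  }
  expect_equal(lib$mass, monoisotopic_mass(lib), tolerance = 1e-12)
})

test_that("a single-point range box yields the single formula", {
  r <- element_ranges(C = c(6, 6), H = c(12, 12), N = c(0, 0), O = c(6, 6),
                      S = c(0, 0), P = c(0, 0))
  lib <- generate_library(1, ranges = r, mass_min = 100, mass_max = 300, seed = 1)
  expect_identical(lib$formula, "C6H12O6")
})

test_that("library draws are seed-deterministic", {
  a <- generate_library(200, mass_min = 100, mass_max = 900, seed = 7)
  b <- generate_library(200, mass_min = 100, mass_max = 900, seed = 7)
  c <- generate_library(200, mass_min = 100, mass_max = 900, seed = 8)
  expect_identical(a, b)
  expect_false(identical(a$formula, c$formula))
})

test_that("ppm mass-uniqueness holds for every pair", {
  lib <- generate_library(150, mass_min = 100, mass_max = 1200,
                          require_unique_masses_at_ppm = 10, seed = 33)
  m <- sort(lib$mass)
  rel <- diff(m) / m[-1] * 1e6
  expect_true(all(rel > 10))
})

test_that("infeasible library specs fail loudly", {
  r <- element_ranges(C = c(1, 2), H = c(1, 4), N = c(0, 0), O = c(0, 1),
                      S = c(0, 0), P = c(0, 0))
  expect_error(
    generate_library(1000, ranges = r, mass_min = 10, mass_max = 100,
                     seed = 1, max_batches = 3),
    "infeasible")
})

test_that("pathway generator plants recoverable ground truth", {
  for (k in c(0L, 3L)) {
    gen <- generate_pathway_db(n_pathways = 8, shared_compound_fraction = 0.3,
                               planted_unique_formula_pathways = k, seed = 5)
    rep <- uniqueness_analysis(gen$db)
    found <- rep$pathways$pathway[rep$pathways$n_unique_formulae > 0]
    expect_identical(sort(found), gen$ground_truth$formula_unique_pathways)
    found_met <- rep$pathways$pathway[rep$pathways$n_unique_metabolites > 0]
    expect_identical(sort(found_met), gen$ground_truth$metabolite_unique_pathways)
  }
  expect_error(generate_pathway_db(n_pathways = 2,
                                   planted_unique_formula_pathways = 5),
               "cannot plant")
})

test_that("no sharing and one compound per reaction makes all metabolites unique", {
  gen <- generate_pathway_db(n_pathways = 6, reactions_per_pathway = 2,
                             compounds_per_reaction = 1,
                             shared_compound_fraction = 0,
                             planted_unique_formula_pathways = 6, seed = 9)
  rep <- uniqueness_analysis(gen$db)
  expect_true(all(rep$metabolites$unique_metabolite[rep$metabolites$n_pathways == 1]))
  expect_true(all(rep$pathways$n_unique_metabolites > 0))
})

test_that("non-CHNOPS fraction is realized and removable", {
  gen <- generate_pathway_db(n_pathways = 15, non_chnops_fraction = 0.12,
                             seed = 23)
  frac <- mean(!gen$db$chnops_ok)
  expect_equal(frac, 0.12, tolerance = 0.02)
  clean <- restrict_to_chnops(gen$db)
  expect_true(all(clean$chnops_ok))
  expect_identical(attr(clean, "removed")[["compounds"]],
                   as.integer(gen$ground_truth$n_non_chnops))
})

test_that("super-pathway fraction is realized and removable", {
  gen <- generate_pathway_db(n_pathways = 10, super_pathway_fraction = 0.3,
                             seed = 31)
  n_super <- gen$ground_truth$n_super
  expect_equal(n_super / length(gen$db$pathways), 0.3, tolerance = 0.05)
  expect_identical(length(drop_super_pathways(gen$db)$pathways), 10L)
  all_super <- generate_pathway_db(n_pathways = 4, super_pathway_fraction = 1,
                                   planted_unique_formula_pathways = 0, seed = 2)
  expect_identical(length(drop_super_pathways(all_super$db)$pathways), 0L)
})

test_that("pathway databases are seed-deterministic", {
  a <- generate_pathway_db(n_pathways = 6, planted_unique_formula_pathways = 2,
                           seed = 77)
  b <- generate_pathway_db(n_pathways = 6, planted_unique_formula_pathways = 2,
                           seed = 77)
  expect_identical(a$db$compounds, b$db$compounds)
  expect_identical(a$ground_truth, b$ground_truth)
})

test_that("noise-free features reproduce the theoretical values exactly", {
  f <- generate_noisy_feature("C6H12O6", rel_error = 0, tolerance_ppm = 0,
                              label_mode = "both", seed = 11)
  expect_equal(f$mass, monoisotopic_mass("C6H12O6"), tolerance = 1e-12)
  truth <- predict_peak_ratios("C6H12O6")
  expect_equal(f$m1_over_m0, truth$m1_over_m0, tolerance = 1e-12)
  expect_equal(f$m2_over_m0, truth$m2_over_m0, tolerance = 1e-12)
  expect_identical(f$c_count, 6L)
  expect_identical(f$n_count, 0L)
  unlabeled <- generate_noisy_feature("C6H12O6", label_mode = "none", seed = 11)
  expect_true(is.na(unlabeled$c_count) && is.na(unlabeled$n_count))
})

test_that("uniform intensity noise stays inside its stated bound", {
  truth <- predict_peak_ratios("C19H19N7O6")
  for (seed in 1:1000) {
    f <- generate_noisy_feature("C19H19N7O6", rel_error = 0.10,
                                tolerance_ppm = 5, seed = seed)
    expect_lte(abs(f$m1_over_m0 / truth$m1_over_m0 - 1), 0.10)
    expect_lte(abs(f$m2_over_m0 / truth$m2_over_m0 - 1), 0.10)
    expect_lte(abs(f$mass / monoisotopic_mass("C19H19N7O6") - 1) * 1e6, 5)
  }
  g <- generate_noisy_feature("C19H19N7O6", rel_error = 0.10, dist = "gaussian",
                              seed = 1)
  expect_s3_class(g, "measured_feature")
})
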