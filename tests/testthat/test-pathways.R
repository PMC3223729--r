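# Pathway database model and the metabolite/formula uniqueness analysis.

test_that("constructor validates referential integrity", {
  expect_error(
    pathway_db(c(a = "C6H12O6"), list(r1 = c("a", "ghost")), list(p1 = "r1")),
    "unknown compounds")
  expect_error(
    pathway_db(c(a = "C6H12O6"), list(r1 = "a"), list(p1 = "missing_rxn")),
    "unknown reactions")
  expect_error(
    pathway_db(c(a = "C6H12O6"), list(r1 = "a"), list(p1 = "r1"),
               super_pathways = "nope"),
    "unknown pathway ids")
  expect_error(pathway_db(c("C6H12O6"), list(), list()), "named")
})

test_that("shared compounds are not unique; private ones are", {
  rep <- uniqueness_analysis(two_pathways_one_shared())
  met <- rep$metabolites
  expect_false(met$unique_metabolite[met$compound == "shared"])
  expect_true(met$unique_metabolite[met$compound == "a"])
  expect_true(met$unique_metabolite[met$compound == "b"])
  expect_identical(rep$pathways$n_unique_metabolites, c(1L, 1L))
  expect_identical(rep$pathways$n_unique_formulae, c(1L, 1L))
})

test_that("same formula private to two pathways is unique to neither", {
  db <- pathway_db(
    compounds = c(a = "C6H13NO2", b = "C6H13NO2", x = "C2H6O"),
    reactions = list(r1 = c("a", "x"), r2 = c("b", "x")),
    pathways = list(p1 = "r1", p2 = "r2")
  )
  rep <- uniqueness_analysis(db)
  expect_true(all(rep$metabolites$unique_metabolite[rep$metabolites$compound %in% c("a", "b")]))
  leu <- rep$formulae[rep$formulae$formula == "C6H13NO2", ]
  expect_identical(leu$n_compounds, 2L)
  expect_false(leu$unique_formula)
  expect_identical(rep$pathways$n_unique_formulae, c(0L, 0L))
  expect_identical(rep$pathways$n_unique_metabolites, c(1L, 1L))
})

test_that("occurrence in an orphan reaction disqualifies uniqueness", {
  db <- pathway_db(
    compounds = c(a = "C5H5N5", x = "C2H6O"),
    reactions = list(r1 = c("a", "x"), orphan = "a"),
    pathways = list(p1 = "r1")
  )
  rep <- uniqueness_analysis(db)
  expect_false(rep$metabolites$unique_metabolite[rep$metabolites$compound == "a"])
  expect_identical(rep$pathways$n_unique_metabolites[1], 1L)  # only x
})

test_that("formula matching is canonical over atom order", {
  db <- pathway_db(
    compounds = c(a = "C6H12O6", b = "H12C6O6"),
    reactions = list(r1 = "a", r2 = "b"),
    pathways = list(p1 = "r1", p2 = "r2")
  )
  rep <- uniqueness_analysis(db)
  expect_identical(nrow(rep$formulae), 1L)
  expect_false(rep$formulae$unique_formula[1])
})

test_that("CHNOPS restriction removes flagged compounds and prunes", {
  db <- pathway_db(
    compounds = c(a = "C6H12O6", b = "C6H5Cl", c = "C5H5N5"),
    reactions = list(r1 = c("a", "b"), r2 = "b", r3 = "c"),
    pathways = list(p1 = c("r1", "r2"), p2 = "r3")
  )
  out <- restrict_to_chnops(db)
  expect_identical(sort(names(out$compounds)), c("a", "c"))
  expect_false("r2" %in% names(out$reactions))  # emptied by the removal
  expect_identical(attr(out, "removed"),
                   c(compounds = 1L, reactions = 1L, pathways = 0L))
  # a fully CHNOPS database passes through unchanged
  clean <- two_pathways_one_shared()
  expect_identical(restrict_to_chnops(clean)$compounds, clean$compounds)
})

test_that("super-pathway removal keeps reactions and compounds", {
  db <- pathway_db(
    compounds = c(a = "C6H12O6", b = "C5H5N5"),
    reactions = list(r1 = "a", r2 = "b"),
    pathways = list(p1 = "r1", p2 = "r2", agg = c("r1", "r2")),
    super_pathways = "agg"
  )
  out <- drop_super_pathways(db)
  expect_identical(sort(names(out$pathways)), c("p1", "p2"))
  expect_identical(length(out$reactions), 2L)
  all_super <- pathway_db(
    compounds = c(a = "C6H12O6"), reactions = list(r1 = "a"),
    pathways = list(s1 = "r1"), super_pathways = "s1")
  expect_identical(length(drop_super_pathways(all_super)$pathways), 0L)
})

test_that("analysis refuses unclean databases", {
  dirty <- pathway_db(
    compounds = c(a = "C6H5Cl"), reactions = list(r1 = "a"),
    pathways = list(p1 = "r1"))
  expect_error(uniqueness_analysis(dirty), "CHNOPS")
  withsuper <- pathway_db(
    compounds = c(a = "C6H12O6"), reactions = list(r1 = "a"),
    pathways = list(p1 = "r1"), super_pathways = "p1")
  expect_error(uniqueness_analysis(withsuper), "super")
})

test_that("histograms conserve metabolite counts", {
  gen <- generate_pathway_db(n_pathways = 10, shared_compound_fraction = 0.3,
                             planted_unique_formula_pathways = 2, seed = 17)
  rep <- uniqueness_analysis(gen$db)
  expect_identical(sum(rep$reaction_occurrence), nrow(rep$metabolites))
  expect_identical(sum(rep$pathway_occurrence),
                   sum(rep$metabolites$n_pathways > 0))
})

test_that("formula-unique pathways are a subset of metabolite-unique ones", {
  for (seed in 1:5) {
    gen <- generate_pathway_db(n_pathways = 12, shared_compound_fraction = 0.4,
                               planted_unique_formula_pathways = seed %% 4,
                               seed = seed)
    rep <- uniqueness_analysis(gen$db)
    n_formula <- sum(rep$pathways$n_unique_formulae > 0)
    n_metab <- sum(rep$pathways$n_unique_metabolites > 0)
    expect_lte(n_formula, n_metab)
    # per-pathway implication, not just the aggregate counts
    expect_true(all(rep$pathways$n_unique_metabolites[rep$pathways$n_unique_formulae > 0] > 0))
  }
})

test_that("analysis is invariant to iteration order", {
  db <- two_pathways_one_shared()
  shuffled <- pathway_db(
    compounds = db$compounds[c(3, 1, 2)],
    reactions = rev(db$reactions),
    pathways = db$pathways
  )
  a <- uniqueness_analysis(db)
  b <- uniqueness_analysis(shuffled)
  expect_identical(a$metabolites, b$metabolites)
  expect_identical(a$formulae, b$formulae)
})

test_that("KEGG-style databases (no pathways) count reaction occurrences", {
  db <- pathway_db(
    compounds = c(a = "C6H12O6", b = "C5H5N5"),
    reactions = list(r1 = c("a", "b"), r2 = "a")
  )
  rep <- uniqueness_analysis(db)
  expect_identical(rep$metabolites$n_reactions[rep$metabolites$compound == "a"], 2L)
  expect_identical(rep$metabolites$n_reactions[rep$metabolites$compound == "b"], 1L)
  expect_true(all(!rep$metabolites$unique_metabolite))
  expect_identical(sum(rep$pathway_occurrence), 0L)
})

test_that("databases round-trip through JSON and the TSV trio", {
  db <- pathway_db(
    compounds = c(a = "C6H12O6", b = "C6H5Cl", c = "C5H5N5"),
    reactions = list(r1 = c("a", "b"), r2 = "c"),
    pathways = list(p1 = "r1", p2 = "r2", agg = c("r1", "r2")),
    super_pathways = "agg"
  )
  json <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(
    compounds = as.list(db$compounds),
    reactions = db$reactions,
    pathways = db$pathways,
    super_pathways = db$super_pathways
  ), json, auto_unbox = TRUE)
  back <- read_pathway_db(json = json)
  expect_identical(back$compounds, db$compounds)
  expect_identical(back$chnops_ok, db$chnops_ok)

  dir <- withr::local_tempdir()
  write.table(data.frame(id = names(db$compounds), formula = unname(db$compounds)),
              file.path(dir, "compounds.tsv"), sep = "\t", row.names = FALSE, quote = FALSE)
  rxn <- do.call(rbind, lapply(names(db$reactions), function(r)
    data.frame(reaction_id = r, compound_id = db$reactions[[r]])))
  write.table(rxn, file.path(dir, "reactions.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  pw <- do.call(rbind, lapply(names(db$pathways), function(p)
    data.frame(pathway_id = p, reaction_id = db$pathways[[p]],
               is_super = p %in% db$super_pathways)))
  write.table(pw, file.path(dir, "pathways.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  back2 <- read_pathway_db(compounds_tsv = file.path(dir, "compounds.tsv"),
                           reactions_tsv = file.path(dir, "reactions.tsv"),
                           pathways_tsv = file.path(dir, "pathways.tsv"))
  expect_identical(sort(names(back2$compounds)), sort(names(db$compounds)))
  expect_identical(back2$super_pathways, "agg")
  expect_identical(uniqueness_analysis(drop_super_pathways(restrict_to_chnops(back2)))$pathways,
                   uniqueness_analysis(drop_super_pathways(restrict_to_chnops(db)))$pathways)
})
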