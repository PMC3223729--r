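#' Pathway database of compounds, reactions, and pathways
#'
#' A minimal relational model of a metabolic-pathway database (the shape of
#' BioCyc/MetaCyc flat files or KEGG compound/reaction tables): compounds
#' carry formula strings; reactions reference sets of compounds; pathways
#' reference sets of reactions; pathways can be flagged as super-pathways
#' (aggregates of other pathways, excluded from uniqueness analysis).
#' Compounds whose formula cannot be parsed as pure CHNOPS (other elements,
#' missing or generic formulae) are flagged on ingest rather than rejected,
#' so that [restrict_to_chnops()] can report what it removes.
#'
#' A database with an empty pathway map is valid and models reaction-level
#' collections such as the KEGG compound/reaction tables.
#'
#' @param compounds Named character vector: compound id -> formula string.
#' @param reactions Named list: reaction id -> character vector of compound
#'   ids.
#' @param pathways Named list: pathway id -> character vector of reaction
#'   ids. May be empty.
#' @param super_pathways Character vector of pathway ids flagged as
#'   super-pathways.
#' @return An object of class `pathway_db`.
#' @examples
#' db <- pathway_db(
#'   compounds = c(glc = "C6H12O6", pyr = "C3H4O3"),
#'   reactions = list(r1 = c("glc", "pyr")),
#'   pathways = list(glycolysis = "r1")
#' )
#' @export
pathway_db <- function(compounds, reactions, pathways = list(),
                       super_pathways = character()) {
  if (is.null(names(compounds)) || anyDuplicated(names(compounds))) {
    stop("compounds must be uniquely named (id -> formula)")
  }
  if (length(reactions) && (is.null(names(reactions)) || anyDuplicated(names(reactions)))) {
    stop("reactions must be uniquely named")
  }
  if (length(pathways) && (is.null(names(pathways)) || anyDuplicated(names(pathways)))) {
    stop("pathways must be uniquely named")
  }
  ref_cpd <- unique(unlist(reactions, use.names = FALSE))
  if (!all(ref_cpd %in% names(compounds))) {
    stop("reactions reference unknown compounds: ",
         paste(utils::head(setdiff(ref_cpd, names(compounds))), collapse = ", "))
  }
  ref_rxn <- unique(unlist(pathways, use.names = FALSE))
  if (!all(ref_rxn %in% names(reactions))) {
    stop("pathways reference unknown reactions: ",
         paste(utils::head(setdiff(ref_rxn, names(reactions))), collapse = ", "))
  }
  if (!all(super_pathways %in% names(pathways))) {
    stop("super_pathways flags unknown pathway ids")
  }
  chnops_ok <- vapply(compounds, function(f) {
    !inherits(tryCatch(parse_formula(f), error = function(e) e), "error")
  }, logical(1))
  structure(
    list(
      compounds = compounds,
      chnops_ok = chnops_ok,
      reactions = lapply(reactions, unique),
      pathways = lapply(pathways, unique),
      super_pathways = super_pathways
    ),
    class = "pathway_db"
  )
}

#' @export
print.pathway_db <- function(x, ...) {
  cat(sprintf("pathway database: %d compounds (%d CHNOPS), %d reactions, %d pathways (%d super)\n",
              length(x$compounds), sum(x$chnops_ok), length(x$reactions),
              length(x$pathways), length(x$super_pathways)))
  invisible(x)
}

#' Read a pathway database from JSON or a TSV table trio
#'
#' JSON layout: an object with `compounds` (id -> formula), `reactions`
#' (id -> array of compound ids), `pathways` (id -> array of reaction ids)
#' and optional `super_pathways` (array of pathway ids). TSV layout: three
#' files — `compounds.tsv` (`id`, `formula`), `reactions.tsv`
#' (`reaction_id`, `compound_id`), `pathways.tsv` (`pathway_id`,
#' `reaction_id`, `is_super`).
#'
#' @param json Path to a JSON file, or
#' @param compounds_tsv,reactions_tsv,pathways_tsv Paths to the TSV trio.
#' @return A [pathway_db()].
#' @export
read_pathway_db <- function(json = NULL, compounds_tsv = NULL,
                            reactions_tsv = NULL, pathways_tsv = NULL) {
  if (!is.null(json)) {
    raw <- jsonlite::read_json(json, simplifyVector = TRUE)
    return(pathway_db(
      compounds = unlist(raw$compounds),
      reactions = lapply(raw$reactions, as.character),
      pathways = if (length(raw$pathways)) lapply(raw$pathways, as.character) else list(),
      super_pathways = as.character(raw$super_pathways %||% character())
    ))
  }
  cpd <- utils::read.delim(compounds_tsv, stringsAsFactors = FALSE)
  rxn <- utils::read.delim(reactions_tsv, stringsAsFactors = FALSE)
  pw <- if (!is.null(pathways_tsv)) {
    utils::read.delim(pathways_tsv, stringsAsFactors = FALSE)
  } else {
    data.frame(pathway_id = character(), reaction_id = character(),
               is_super = logical())
  }
  pathway_db(
    compounds = stats::setNames(cpd$formula, cpd$id),
    reactions = split(rxn$compound_id, rxn$reaction_id),
    pathways = if (nrow(pw)) split(pw$reaction_id, pw$pathway_id) else list(),
    super_pathways = unique(pw$pathway_id[as.logical(pw$is_super)])
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Restrict a pathway database to CHNOPS compounds
#'
#' Drops every compound whose formula is not pure C/H/N/O/S/P, then prunes
#' reactions left with no compounds and pathways left with no reactions.
#' The numbers removed at each step are attached as attribute `removed`.
#'
#' @param db A [pathway_db()].
#' @return The restricted `pathway_db`.
#' @export
restrict_to_chnops <- function(db) {
  stopifnot(inherits(db, "pathway_db"))
  keep_cpd <- names(db$compounds)[db$chnops_ok]
  reactions <- lapply(db$reactions, function(cpds) intersect(cpds, keep_cpd))
  empty_rxn <- names(reactions)[lengths(reactions) == 0L]
  reactions <- reactions[lengths(reactions) > 0L]
  pathways <- lapply(db$pathways, function(rxns) intersect(rxns, names(reactions)))
  empty_pw <- names(pathways)[lengths(pathways) == 0L]
  pathways <- pathways[lengths(pathways) > 0L]
  out <- pathway_db(
    compounds = db$compounds[keep_cpd],
    reactions = reactions,
    pathways = pathways,
    super_pathways = intersect(db$super_pathways, names(pathways))
  )
  attr(out, "removed") <- c(
    compounds = length(db$compounds) - length(keep_cpd),
    reactions = length(empty_rxn),
    pathways = length(empty_pw)
  )
  out
}

#' Remove super-pathways
#'
#' Drops pathways flagged as super-pathways (aggregates of other pathways).
#' Their reactions and compounds are retained, since other pathways may
#' reference them.
#'
#' @param db A [pathway_db()].
#' @return The `pathway_db` without super-pathways.
#' @export
drop_super_pathways <- function(db) {
  stopifnot(inherits(db, "pathway_db"))
  keep <- setdiff(names(db$pathways), db$super_pathways)
  pathway_db(
    compounds = db$compounds,
    reactions = db$reactions,
    pathways = db$pathways[keep],
    super_pathways = character()
  )
}

#' Pathway-uniqueness analysis of metabolites and chemical formulae
#'
#' Determines, for every metabolite, how many distinct reactions and
#' pathways contain it, and identifies pathway fingerprints: a metabolite is
#' pathway-unique iff it occurs in exactly one pathway and in no reaction
#' unlinked to any pathway; a chemical formula is pathway-unique iff every
#' compound bearing it is pathway-unique to the same single pathway. Such
#' formulae can serve as evidence for the presence of a pathway in
#' metabolomics-aided genome annotation.
#'
#' The database should already be CHNOPS-restricted and free of
#' super-pathways (see [restrict_to_chnops()], [drop_super_pathways()]).
#' With an empty pathway map the analysis degrades to reaction-level
#' occurrence counting (KEGG-style); pathway uniqueness is then vacuous.
#'
#' Occurrence histograms: `reaction_occurrence` counts metabolites by the
#' number of distinct reactions they appear in (all metabolites);
#' `pathway_occurrence` counts metabolites by the number of distinct
#' pathways, excluding metabolites that occur in no pathway at all.
#'
#' @param db A [pathway_db()].
#' @return An object of class `uniqueness_report`: a list with
#'   `$metabolites` (per-compound table with `n_reactions`, `n_pathways`,
#'   `in_orphan_reaction`, `unique_metabolite`, `unique_pathway`),
#'   `$formulae` (per-formula table with `unique_formula`),
#'   `$pathways` (per-pathway counts of unique metabolites and formulae),
#'   and the two occurrence histograms.
#' @examples
#' db <- pathway_db(
#'   compounds = c(a = "C3H7NO2", b = "C6H12O6", c = "C5H5N5"),
#'   reactions = list(r1 = c("a", "b"), r2 = c("b", "c")),
#'   pathways = list(p1 = "r1", p2 = "r2")
#' )
#' uniqueness_analysis(db)$pathways
#' @export
uniqueness_analysis <- function(db) {
  stopifnot(inherits(db, "pathway_db"))
  if (length(db$super_pathways)) {
    stop("drop super-pathways before the uniqueness analysis")
  }
  if (any(!db$chnops_ok)) {
    stop("restrict the database to CHNOPS compounds first")
  }

  # reaction -> pathways reverse index; orphan = reaction in no pathway
  rxn_ids <- names(db$reactions)
  rxn_pathways <- stats::setNames(vector("list", length(rxn_ids)), rxn_ids)
  for (pw in names(db$pathways)) {
    for (r in db$pathways[[pw]]) {
      rxn_pathways[[r]] <- c(rxn_pathways[[r]], pw)
    }
  }

  cpd_ids <- sort(unique(unlist(db$reactions, use.names = FALSE)))
  cpd_rxns <- stats::setNames(vector("list", length(cpd_ids)), cpd_ids)
  for (r in rxn_ids) {
    for (cpd in db$reactions[[r]]) {
      cpd_rxns[[cpd]] <- c(cpd_rxns[[cpd]], r)
    }
  }

  n_reactions <- lengths(cpd_rxns)
  pw_sets <- lapply(cpd_rxns, function(rs) {
    sort(unique(unlist(rxn_pathways[rs], use.names = FALSE)))
  })
  n_pathways <- lengths(pw_sets)
  in_orphan <- vapply(cpd_rxns, function(rs) {
    any(lengths(rxn_pathways[rs]) == 0L)
  }, logical(1))

  unique_metabolite <- n_pathways == 1L & !in_orphan
  unique_pathway <- ifelse(unique_metabolite,
                           vapply(pw_sets, function(s) if (length(s) == 1L) s else NA_character_,
                                  character(1)),
                           NA_character_)

  # canonical formula string so e.g. "H12C6O6" and "C6H12O6" collide
  formula_str <- vapply(db$compounds[cpd_ids],
                        function(f) format_formula(parse_formula(f)), character(1))
  metabolites <- data.frame(
    compound = cpd_ids,
    formula = unname(formula_str),
    n_reactions = unname(n_reactions),
    n_pathways = unname(n_pathways),
    in_orphan_reaction = unname(in_orphan),
    unique_metabolite = unname(unique_metabolite),
    unique_pathway = unname(unique_pathway),
    stringsAsFactors = FALSE
  )

  formulae <- do.call(rbind, lapply(split(metabolites, metabolites$formula), function(d) {
    pw <- unique(d$unique_pathway)
    uniq <- all(d$unique_metabolite) && length(pw) == 1L && !is.na(pw[1])
    data.frame(
      formula = d$formula[1],
      n_compounds = nrow(d),
      unique_formula = uniq,
      pathway = if (uniq) pw[1] else NA_character_,
      stringsAsFactors = FALSE
    )
  }))
  rownames(formulae) <- NULL

  pw_ids <- names(db$pathways)
  pathways <- data.frame(
    pathway = pw_ids,
    n_unique_metabolites = vapply(pw_ids, function(p) {
      sum(metabolites$unique_pathway == p, na.rm = TRUE)
    }, integer(1)),
    n_unique_formulae = vapply(pw_ids, function(p) {
      sum(formulae$pathway == p, na.rm = TRUE)
    }, integer(1)),
    stringsAsFactors = FALSE
  )
  rownames(pathways) <- NULL

  structure(
    list(
      metabolites = metabolites,
      formulae = formulae,
      pathways = pathways,
      reaction_occurrence = table(metabolites$n_reactions),
      pathway_occurrence = table(metabolites$n_pathways[metabolites$n_pathways > 0L])
    ),
    class = "uniqueness_report"
  )
}

#' @export
print.uniqueness_report <- function(x, ...) {
  cat(sprintf("uniqueness report: %d metabolites, %d formulae, %d pathways\n",
              nrow(x$metabolites), nrow(x$formulae), nrow(x$pathways)))
  cat(sprintf("  pathways with >= 1 unique metabolite: %d\n",
              sum(x$pathways$n_unique_metabolites > 0L)))
  cat(sprintf("  pathways with >= 1 unique formula:    %d\n",
              sum(x$pathways$n_unique_formulae > 0L)))
  invisible(x)
}
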