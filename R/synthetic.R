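#' Generate a synthetic formula library
#'
#' Stands in for a large compound-database snapshot (the role a filtered
#' PubChem export plays for the real analysis): distinct CHNOPS formulae
#' with atom counts sampled uniformly per element inside `ranges` and
#' rejection-filtered to a monoisotopic-mass band. Optionally enforces that
#' no two library masses lie within a ppm tolerance of each other, so each
#' library entry is a unique accurate mass. Sampling is uniform over the
#' count box, not matched to any empirical formula distribution.
#'
#' @param n_formulae Library size.
#' @param ranges [element_ranges()] box to sample from.
#' @param mass_min,mass_max Monoisotopic mass band in Da (default 50-2000).
#' @param require_unique_formulae Deduplicate identical formulae
#'   (default `TRUE`).
#' @param require_unique_masses_at_ppm If set, additionally drop formulae
#'   whose mass lies within this many ppm of an already-accepted mass.
#' @param seed Integer seed; equal seeds give identical libraries.
#' @param max_batches Rejection-sampling budget; an infeasible spec (more
#'   formulae requested than the box and band can supply) errors out.
#' @return A `formula_library` data.frame with columns `formula`,
#'   `C,H,N,O,S,P`, `mass`, sorted by mass.
#' @examples
#' lib <- generate_library(100, mass_min = 100, mass_max = 600, seed = 42)
#' range(lib$mass)
#' @export
generate_library <- function(n_formulae, ranges = element_ranges(),
                             mass_min = 50, mass_max = 2000,
                             require_unique_formulae = TRUE,
                             require_unique_masses_at_ppm = NULL,
                             seed = 1L, max_batches = 200L) {
  stopifnot(n_formulae >= 1, mass_min < mass_max)
  withr::with_seed(seed, {
    acc <- empty_count_matrix()
    acc_mass <- numeric(0)
    batch <- max(1000L, 4L * n_formulae)
    for (b in seq_len(max_batches)) {
      m <- vapply(CHNOPS, function(e) {
        lo <- ranges$min[e]
        hi <- ranges$max[e]
        if (hi > lo) sample(lo:hi, batch, replace = TRUE) else rep(lo, batch)
      }, integer(batch))
      mass <- as.numeric(m %*% .monoisotopic_masses)
      keep <- mass >= mass_min & mass <= mass_max & rowSums(m) >= 1L
      acc <- rbind(acc, m[keep, , drop = FALSE])
      acc_mass <- c(acc_mass, mass[keep])
      if (require_unique_formulae) {
        dup <- duplicated(acc)
        acc <- acc[!dup, , drop = FALSE]
        acc_mass <- acc_mass[!dup]
      }
      if (!is.null(require_unique_masses_at_ppm)) {
        sel <- select_unique_masses(acc_mass, require_unique_masses_at_ppm)
        acc <- acc[sel, , drop = FALSE]
        acc_mass <- acc_mass[sel]
      }
      if (nrow(acc) >= n_formulae) break
    }
    if (nrow(acc) < n_formulae) {
      stop("could not draw ", n_formulae, " formulae after ", max_batches,
           " rejection batches; the spec is likely infeasible")
    }
    acc <- acc[seq_len(n_formulae), , drop = FALSE]
    out <- data.frame(
      formula = format_formula(acc),
      acc,
      mass = acc_mass[seq_len(n_formulae)],
      stringsAsFactors = FALSE
    )
    out <- out[order(out$mass), , drop = FALSE]
    rownames(out) <- NULL
    class(out) <- c("formula_library", "data.frame")
    out
  })
}

# greedy pass over masses in original order: accept a mass only if it is
# farther than tol_ppm (relative to the larger mass) from every accepted one
select_unique_masses <- function(masses, tol_ppm) {
  ord <- order(masses)
  sorted <- masses[ord]
  keep_sorted <- logical(length(sorted))
  last <- -Inf
  for (i in seq_along(sorted)) {
    if ((sorted[i] - last) / sorted[i] * 1e6 > tol_ppm) {
      keep_sorted[i] <- TRUE
      last <- sorted[i]
    }
  }
  sort(ord[keep_sorted])
}

#' Generate a synthetic pathway database with planted ground truth
#'
#' Emulates the structure of a curated pathway database for testing the
#' uniqueness analysis: pathways built from reactions over a pool of
#' compounds with controlled compound sharing, plus (optionally) compounds
#' with non-CHNOPS formulae, super-pathway aggregates, and an exact number
#' of planted formula-unique pathways.
#'
#' Planting works in two directions: each planted pathway receives a
#' private compound with a globally unique formula; in every non-planted
#' pathway, each pathway-private compound gets a decoy compound with the
#' same formula attached to an orphan reaction (a reaction in no pathway),
#' which destroys formula uniqueness while leaving the metabolite itself
#' pathway-unique. The analysis must therefore recover exactly the planted
#' pathways as formula-unique.
#'
#' @param n_pathways Number of regular (non-super) pathways.
#' @param reactions_per_pathway,compounds_per_reaction Structure sizes.
#' @param shared_compound_fraction Probability that a compound slot reuses
#'   an existing compound from another pathway instead of minting a new one.
#' @param planted_unique_formula_pathways Number `k` of pathways that must
#'   end up with at least one pathway-unique formula (and no other pathway
#'   may).
#' @param non_chnops_fraction Fraction of all compounds that carry a
#'   non-CHNOPS formula (removable by [restrict_to_chnops()]).
#' @param super_pathway_fraction Fraction of all pathways that are
#'   super-pathway aggregates (removable by [drop_super_pathways()]).
#' @param seed Integer seed.
#' @return A list with `$db` (a [pathway_db()]) and `$ground_truth` (a list
#'   with `formula_unique_pathways`, `metabolite_unique_pathways`,
#'   `n_non_chnops`, `n_super`).
#' @examples
#' g <- generate_pathway_db(n_pathways = 6, planted_unique_formula_pathways = 2,
#'                          seed = 3)
#' rep <- uniqueness_analysis(g$db)
#' sum(rep$pathways$n_unique_formulae > 0)  # exactly 2
#' @export
generate_pathway_db <- function(n_pathways = 20L,
                                reactions_per_pathway = 4L,
                                compounds_per_reaction = 3L,
                                shared_compound_fraction = 0.2,
                                planted_unique_formula_pathways = 0L,
                                non_chnops_fraction = 0,
                                super_pathway_fraction = 0,
                                seed = 1L) {
  k <- planted_unique_formula_pathways
  n_super <- round(super_pathway_fraction / (1 - min(super_pathway_fraction, 0.999999)) *
                     n_pathways)
  if (super_pathway_fraction >= 1) {
    n_super <- max(n_pathways, 1L)
    n_pathways <- 0L
  }
  if (k > n_pathways) {
    stop("cannot plant ", k, " formula-unique pathways in ", n_pathways,
         " pathways")
  }
  withr::with_seed(seed, {
    # fresh unique formulae on demand
    pool <- generate_library(
      2L * n_pathways * reactions_per_pathway * compounds_per_reaction +
        2L * n_pathways + 10L,
      ranges = element_ranges(C = c(1, 40), H = c(1, 80)),
      mass_min = 60, mass_max = 700, seed = sample.int(2^30, 1)
    )
    pool_next <- 0L
    next_formula <- function() {
      pool_next <<- pool_next + 1L
      pool$formula[pool_next]
    }

    compounds <- character(0)
    reactions <- list()
    pathways <- list()
    cpd_pathways <- list()  # construction bookkeeping: compound -> pathways

    pw_ids <- if (n_pathways > 0L) sprintf("pw%03d", seq_len(n_pathways)) else character(0)
    planted <- if (k > 0L) sort(sample(pw_ids, k)) else character(0)

    for (pw in pw_ids) {
      rxns <- character(0)
      for (j in seq_len(reactions_per_pathway)) {
        rid <- sprintf("%s_r%02d", pw, j)
        members <- character(0)
        for (s in seq_len(compounds_per_reaction)) {
          foreign <- setdiff(names(compounds),
                             names(cpd_pathways)[vapply(cpd_pathways, function(p)
                               identical(p, pw), logical(1))])
          reuse <- length(foreign) > 0L &&
            stats::runif(1) < shared_compound_fraction
          if (reuse) {
            cid <- sample(foreign, 1L)
            cpd_pathways[[cid]] <- unique(c(cpd_pathways[[cid]], pw))
          } else {
            cid <- sprintf("c%04d", length(compounds) + 1L)
            compounds[cid] <- next_formula()
            cpd_pathways[[cid]] <- pw
          }
          members <- unique(c(members, cid))
        }
        reactions[[rid]] <- members
        rxns <- c(rxns, rid)
      }
      pathways[[pw]] <- rxns
    }

    # plant: a private compound with a fresh (globally unique) formula in
    # each planted pathway's first reaction
    for (pw in planted) {
      cid <- sprintf("uniq_%s", pw)
      compounds[cid] <- next_formula()
      cpd_pathways[[cid]] <- pw
      first_rxn <- pathways[[pw]][1L]
      reactions[[first_rxn]] <- c(reactions[[first_rxn]], cid)
    }

    # de-plant: every pathway-private compound of a non-planted pathway gets
    # a same-formula decoy compound in an orphan reaction
    orphan_members <- character(0)
    for (cid in names(cpd_pathways)) {
      pws <- cpd_pathways[[cid]]
      if (length(pws) == 1L && !pws %in% planted) {
        decoy <- sprintf("decoy_%s", cid)
        compounds[decoy] <- compounds[[cid]]
        orphan_members <- c(orphan_members, decoy)
      }
    }
    if (length(orphan_members)) {
      reactions[["orphan_r01"]] <- orphan_members
    }

    # non-CHNOPS decoys appended to random reactions
    n_non <- round(non_chnops_fraction / (1 - min(non_chnops_fraction, 0.999999)) *
                     length(compounds))
    if (n_non > 0L) {
      host_rxns <- sample(names(reactions), n_non, replace = TRUE)
      for (i in seq_len(n_non)) {
        cid <- sprintf("x%04d", i)
        compounds[cid] <- sprintf("C%dH%dCl%d", sample(3:20, 1),
                                  sample(4:30, 1), sample(1:3, 1))
        reactions[[host_rxns[i]]] <- c(reactions[[host_rxns[i]]], cid)
      }
    }

    # super-pathway aggregates over regular pathways' reactions
    super_ids <- character(0)
    if (n_super > 0L) {
      for (i in seq_len(n_super)) {
        sid <- sprintf("super%02d", i)
        if (length(pw_ids)) {
          parts <- sample(pw_ids, min(2L, length(pw_ids)))
          srxns <- unique(unlist(pathways[parts], use.names = FALSE))
        } else {
          rid <- sprintf("%s_r01", sid)
          cid <- sprintf("sc%03d", i)
          compounds[cid] <- next_formula()
          reactions[[rid]] <- cid
          srxns <- rid
        }
        pathways[[sid]] <- srxns
        super_ids <- c(super_ids, sid)
      }
    }

    db <- pathway_db(compounds, reactions, pathways, super_pathways = super_ids)
    met_unique_pw <- unique(unlist(
      cpd_pathways[vapply(cpd_pathways, function(p) length(p) == 1L, logical(1))],
      use.names = FALSE
    ))
    list(
      db = db,
      ground_truth = list(
        formula_unique_pathways = planted,
        metabolite_unique_pathways = sort(met_unique_pw),
        n_non_chnops = if (n_non > 0L) n_non else 0L,
        n_super = length(super_ids)
      )
    )
  })
}

#' Simulate a measured feature from a true formula
#'
#' Draws a noisy [measured_feature()] for a known compound: the mass is
#' perturbed uniformly within the stated ppm tolerance, the M1/M0 and M2/M0
#' ratios are the theoretical natural-abundance values times independent
#' multiplicative errors drawn uniformly from `[1 - rel_error, 1 +
#' rel_error]` (a bounded relative-error model matching the filter's
#' acceptance band; `dist = "gaussian"` instead uses a normal with sd =
#' `rel_error`). SIL counting is modeled as exact, so when a label mode is
#' requested the C and/or N counts equal the true formula's counts.
#'
#' @inheritParams monoisotopic_mass
#' @param true_formula The generating formula (any form accepted by
#'   [monoisotopic_mass()]; single formula).
#' @param rel_error Relative intensity-error bound (0.10 = 10 percent).
#' @param tolerance_ppm Mass tolerance; also the perturbation bound.
#' @param label_mode Which SIL counts are attached: `"none"`, `"c_count"`,
#'   `"n_count"` or `"both"`.
#' @param dist Error model for the ratios: bounded `"uniform"` (default) or
#'   `"gaussian"`.
#' @param seed Integer seed.
#' @return A [measured_feature()].
#' @examples
#' generate_noisy_feature("C6H12O6", rel_error = 0.1, tolerance_ppm = 5,
#'                        label_mode = "both", seed = 11)
#' @export
generate_noisy_feature <- function(true_formula, rel_error = 0,
                                   tolerance_ppm = 0,
                                   label_mode = c("none", "c_count", "n_count", "both"),
                                   dist = c("uniform", "gaussian"),
                                   seed = 1L) {
  label_mode <- match.arg(label_mode)
  dist <- match.arg(dist)
  stopifnot(rel_error >= 0, tolerance_ppm >= 0)
  counts <- as_count_matrix(true_formula)
  if (nrow(counts) != 1L) stop("one true formula at a time")
  mass0 <- monoisotopic_mass(counts)
  ratios <- predict_peak_ratios(counts)
  withr::with_seed(seed, {
    mass <- mass0 * (1 + stats::runif(1, -tolerance_ppm, tolerance_ppm) * 1e-6)
    eps <- if (dist == "uniform") {
      stats::runif(2, -rel_error, rel_error)
    } else {
      stats::rnorm(2, 0, rel_error)
    }
    measured_feature(
      mass = mass,
      tolerance_ppm = tolerance_ppm,
      c_count = if (label_mode %in% c("c_count", "both")) unname(counts[1, "C"]) else NA_integer_,
      n_count = if (label_mode %in% c("n_count", "both")) unname(counts[1, "N"]) else NA_integer_,
      m1_over_m0 = ratios$m1_over_m0 * (1 + eps[1]),
      m2_over_m0 = ratios$m2_over_m0 * (1 + eps[2]),
      ratio_rel_uncertainty = rel_error
    )
  })
}
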