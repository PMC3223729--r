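#' Restrict candidates by SIL-derived C and N atom counts
#'
#' Stable-isotope labeling (growth on uniformly 13C- or 15N-enriched media)
#' counts the carbon and nitrogen atoms of a feature exactly from the mass
#' shift between labeled and unlabeled forms. This filter keeps only
#' candidates with the stated C and N counts; when the set was built from
#' the true formula's own mass window, the true formula always survives.
#'
#' @param candidates A `candidate_set` from the enumerators.
#' @param c_count,n_count Known carbon and nitrogen atom counts (>= 0).
#' @return The filtered `candidate_set` (a subset of the input).
#' @examples
#' cs <- enumerate_brute_force(ppm_window(441.1397, 5))
#' nrow(filter_by_cn(cs, 19, 7))   # folate survives with few companions
#' @export
filter_by_cn <- function(candidates, c_count, n_count) {
  stopifnot(inherits(candidates, "candidate_set"))
  if (c_count < 0 || n_count < 0) {
    stop("c_count and n_count must be non-negative")
  }
  keep <- candidates$C == c_count & candidates$N == n_count
  subset_candidates(candidates, keep)
}

#' Restrict candidates by relative isotopic peak intensities
#'
#' The natural-abundance route: a candidate formula is retained iff both its
#' predicted M1/M0 and M2/M0 ratios lie within a stated relative deviation
#' of the observed ratios, i.e. `|predicted - observed| <=
#' rel_uncertainty * observed` for each ratio (the joint M1-and-M2 band of
#' the Seven Golden Rules isotope rule). An observed ratio of zero demands a
#' predicted ratio below an absolute floor of 1e-9.
#'
#' @param candidates A `candidate_set`.
#' @param observed Numeric length-2 vector `c(m1_over_m0, m2_over_m0)` (>= 0),
#'   e.g. from [relative_ratios()] or a `measured_feature`.
#' @param rel_uncertainty Relative half-width of the acceptance band
#'   (0.10 = 10 percent). At 0 the band degenerates to exact equality.
#' @param table The pinned [isotope_table()].
#' @return The filtered `candidate_set`.
#' @examples
#' cs <- enumerate_brute_force(ppm_window(441.1397, 5))
#' obs <- relative_ratios(molecular_pattern("C19H19N7O6"))
#' nrow(filter_by_ratios(cs, obs, 0.10))
#' @export
filter_by_ratios <- function(candidates, observed, rel_uncertainty,
                             table = isotope_table()) {
  stopifnot(inherits(candidates, "candidate_set"))
  observed <- as.numeric(observed)
  if (length(observed) != 2L || anyNA(observed) || any(observed < 0)) {
    stop("observed must be two non-negative ratios (M1/M0, M2/M0)")
  }
  if (rel_uncertainty < 0) {
    stop("rel_uncertainty must be >= 0")
  }
  if (nrow(candidates) == 0L) {
    return(candidates)
  }
  pred <- predict_peak_ratios(candidates)
  keep <- ratio_band_ok(pred$m1_over_m0, observed[1], rel_uncertainty) &
    ratio_band_ok(pred$m2_over_m0, observed[2], rel_uncertainty)
  subset_candidates(candidates, keep)
}

ratio_band_ok <- function(predicted, observed, rel_uncertainty, floor_abs = 1e-9) {
  if (observed == 0) {
    predicted <= floor_abs
  } else {
    abs(predicted - observed) <= rel_uncertainty * observed
  }
}

subset_candidates <- function(candidates, keep) {
  out <- as.data.frame(candidates)[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "window") <- attr(candidates, "window")
  attr(out, "ranges") <- attr(candidates, "ranges")
  attr(out, "filter") <- attr(candidates, "filter")
  class(out) <- c("candidate_set", "data.frame")
  out
}

#' A measured mass-spectral feature with optional constraints
#'
#' Container for the information attached to one untargeted-metabolomics
#' feature: accurate mass with its ppm tolerance, optionally SIL-derived C
#' and N atom counts, and optionally measured M1/M0 and M2/M0 intensity
#' ratios with their relative-uncertainty bound.
#'
#' @param mass Neutral monoisotopic mass, Da.
#' @param tolerance_ppm Mass tolerance, ppm.
#' @param c_count,n_count SIL atom counts, or `NA` when unlabeled.
#' @param m1_over_m0,m2_over_m0 Measured intensity ratios, or `NA`.
#' @param ratio_rel_uncertainty Relative uncertainty bound on the ratios.
#' @return An object of class `measured_feature`.
#' @export
measured_feature <- function(mass, tolerance_ppm,
                             c_count = NA_integer_, n_count = NA_integer_,
                             m1_over_m0 = NA_real_, m2_over_m0 = NA_real_,
                             ratio_rel_uncertainty = 0) {
  if (mass <= 0) stop("mass must be positive")
  if (ratio_rel_uncertainty < 0) stop("ratio_rel_uncertainty must be >= 0")
  if (!is.na(c_count) && c_count < 0) stop("c_count must be >= 0")
  if (!is.na(n_count) && n_count < 0) stop("n_count must be >= 0")
  structure(
    list(
      mass = mass, tolerance_ppm = tolerance_ppm,
      c_count = c_count, n_count = n_count,
      m1_over_m0 = m1_over_m0, m2_over_m0 = m2_over_m0,
      ratio_rel_uncertainty = ratio_rel_uncertainty
    ),
    class = "measured_feature"
  )
}

#' Compare the three constraint regimes over a formula library
#'
#' The head-to-head evaluation of mass-only, mass + SIL C/N counts, and
#' mass + natural-abundance intensity ratios. For each sampled library
#' formula the function builds its ppm window, enumerates all candidate
#' formulae, and counts the survivors under (i) no further constraint,
#' (ii) the true C and N counts (SIL regime), and (iii) the true formula's
#' noise-free theoretical M1/M0 and M2/M0 ratios at the stated relative
#' uncertainty (abundance regime). It reports, overall and per mass bin,
#' the fractions of masses where SIL leaves strictly fewer, equally many,
#' or strictly more survivors than the ratio filter, and the fractions of
#' masses with 0, 1, or >= 2 degeneracies under each regime.
#'
#' @param library A formula library: data.frame/matrix with `C,H,N,O,S,P`
#'   columns (e.g. from [generate_library()]), or a character vector of
#'   formula strings. Masses should be unique.
#' @param tolerance_ppm Mass tolerance (default 5 ppm).
#' @param rel_uncertainty Relative uncertainty of the intensity ratios
#'   (default 0.10).
#' @param ranges [element_ranges()] box for enumeration.
#' @param sample_size Number of library formulae to sample (default: all).
#' @param seed Integer seed for the sampling draw.
#' @param filter Optional [heuristic_filter()] applied to the enumeration
#'   (emulating a restricted generator); `NULL` for brute force.
#' @param mass_bin_width,mass_bin_range Reporting bins for the per-mass-bin
#'   table (default 100 Da bins over 50-2000 Da).
#' @return An object of class `regime_comparison`: a list with
#'   `$per_mass` (one row per sampled formula: `formula`, `mass`,
#'   `n_mass_only`, `n_sil`, `n_ratio`, `winner`),
#'   `$summary` (overall fractions), and `$by_mass_bin`.
#' @examples
#' lib <- generate_library(30, mass_min = 100, mass_max = 400, seed = 7)
#' cmp <- compare_regimes(lib, sample_size = 10, seed = 7)
#' cmp$summary
#' @export
compare_regimes <- function(library, tolerance_ppm = 5, rel_uncertainty = 0.10,
                            ranges = element_ranges(), sample_size = NULL,
                            seed = 1L, filter = NULL,
                            mass_bin_width = 100, mass_bin_range = c(50, 2000)) {
  counts <- as_count_matrix(library)
  if (nrow(counts) == 0L) {
    stop("library is empty")
  }
  if (is.null(sample_size)) {
    sample_size <- nrow(counts)
  }
  if (sample_size > nrow(counts)) {
    stop("sample_size exceeds library size")
  }
  picked <- withr::with_seed(seed, sample.int(nrow(counts), sample_size))
  counts <- counts[picked, , drop = FALSE]
  masses <- as.numeric(counts %*% .monoisotopic_masses)
  ratios <- predict_peak_ratios(counts)

  n_mass_only <- n_sil <- n_ratio <- integer(sample_size)
  truth_lost <- 0L
  for (i in seq_len(sample_size)) {
    w <- ppm_window(masses[i], tolerance_ppm)
    cs <- if (is.null(filter)) {
      enumerate_brute_force(w, ranges)
    } else {
      enumerate_filtered(w, ranges, filter)
    }
    truth <- format_formula(counts[i, , drop = FALSE])
    if (!truth %in% cs$formula) {
      # a restricted generator can fail to recapitulate the seed formula
      truth_lost <- truth_lost + 1L
    }
    n_mass_only[i] <- nrow(cs)
    n_sil[i] <- nrow(filter_by_cn(cs, counts[i, "C"], counts[i, "N"]))
    n_ratio[i] <- nrow(filter_by_ratios(
      cs, c(ratios$m1_over_m0[i], ratios$m2_over_m0[i]), rel_uncertainty))
  }

  winner <- ifelse(n_sil < n_ratio, "sil",
                   ifelse(n_ratio < n_sil, "ratio", "tie"))
  per_mass <- data.frame(
    formula = format_formula(counts),
    mass = masses,
    n_mass_only = n_mass_only,
    n_sil = n_sil,
    n_ratio = n_ratio,
    winner = winner,
    stringsAsFactors = FALSE
  )
  per_mass <- per_mass[order(per_mass$mass), , drop = FALSE]
  rownames(per_mass) <- NULL

  summary <- data.frame(
    n_masses = sample_size,
    frac_sil_better = mean(winner == "sil"),
    frac_ratio_better = mean(winner == "ratio"),
    frac_tie = mean(winner == "tie"),
    frac_unique_mass_only = mean(n_mass_only == 1L),
    frac_unique_sil = mean(n_sil == 1L),
    frac_unique_ratio = mean(n_ratio == 1L),
    frac_multi_mass_only = mean(n_mass_only >= 3L),
    truth_lost = truth_lost
  )

  breaks <- seq(mass_bin_range[1], mass_bin_range[2], by = mass_bin_width)
  if (max(masses) > max(breaks)) breaks <- c(breaks, Inf)
  bin <- cut(per_mass$mass, breaks, right = FALSE)
  by_bin <- do.call(rbind, lapply(split(per_mass, bin, drop = TRUE), function(d) {
    data.frame(
      mass_bin = NA_character_,
      n_masses = nrow(d),
      frac_sil_better = mean(d$winner == "sil"),
      frac_ratio_better = mean(d$winner == "ratio"),
      frac_tie = mean(d$winner == "tie"),
      frac_unique_sil = mean(d$n_sil == 1L),
      frac_unique_ratio = mean(d$n_ratio == 1L),
      stringsAsFactors = FALSE
    )
  }))
  if (!is.null(by_bin)) {
    by_bin$mass_bin <- names(split(per_mass, bin, drop = TRUE))
    rownames(by_bin) <- NULL
  }

  structure(
    list(per_mass = per_mass, summary = summary, by_mass_bin = by_bin,
         tolerance_ppm = tolerance_ppm, rel_uncertainty = rel_uncertainty,
         seed = seed),
    class = "regime_comparison"
  )
}

#' @export
print.regime_comparison <- function(x, ...) {
  s <- x$summary
  cat(sprintf("regime comparison over %d masses (%g ppm, %.0f%% ratio uncertainty)\n",
              s$n_masses, x$tolerance_ppm, 100 * x$rel_uncertainty))
  cat(sprintf("  SIL strictly better: %.1f%%   ratio strictly better: %.1f%%   tie: %.1f%%\n",
              100 * s$frac_sil_better, 100 * s$frac_ratio_better, 100 * s$frac_tie))
  cat(sprintf("  unique formula: mass-only %.1f%% | +C/N counts %.1f%% | +isotope ratios %.1f%%\n",
              100 * s$frac_unique_mass_only, 100 * s$frac_unique_sil,
              100 * s$frac_unique_ratio))
  invisible(x)
}
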