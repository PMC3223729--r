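#' Size of the formula search space
#'
#' Product over elements of the number of admissible atom counts,
#' `prod(max - min + 1)`.
#'
#' @param ranges An [element_ranges()] object.
#' @return The number of formulae in the box, as a numeric (the default box
#'   holds 288,120,000 formulae, beyond integer range safety).
#' @examples
#' search_space_size(element_ranges())  # 288,120,000
#' @export
search_space_size <- function(ranges = element_ranges()) {
  stopifnot(inherits(ranges, "element_ranges"))
  prod(as.numeric(ranges$max - ranges$min + 1L))
}

#' Heuristic plausibility filter for candidate formulae
#'
#' Configurable emulation of the element-ratio and valence heuristics used
#' by restricted formula generators (the Seven Golden Rules family). A
#' candidate passes when every enabled check passes:
#' element-ratio bounds on H/C, N/C, O/C, P/C, S/C; a lower bound on the
#' ring/double-bond equivalent `RDBE = C - H/2 + N/2 + P/2 + 1`; and
#' optionally the requirement that RDBE be an integer (a Senior-rule parity
#' condition). Defaults are the "common range" ratio bounds; note that such
#' defaults are known to exclude real metabolites (highly oxygenated species
#' such as ATP or malate fail O/C <= 1.2), which is why every bound is
#' exposed.
#'
#' @param enabled If `FALSE` the filter rejects nothing.
#' @param hc_min,hc_max,nc_max,oc_max,pc_max,sc_max Ratio bounds relative to
#'   the carbon count (dimensionless).
#' @param nc_min,oc_min,pc_min,sc_min Lower ratio bounds (default 0).
#' @param rdbe_min Lower bound on RDBE; set to `-Inf` to disable.
#' @param require_integer_rdbe Require RDBE to be a whole number.
#' @return An object of class `heuristic_filter`.
#' @examples
#' heuristic_filter()
#' heuristic_filter(oc_max = 3)  # liberal O/C keeps ATP-like formulae
#' @export
heuristic_filter <- function(enabled = TRUE,
                             hc_min = 0.2, hc_max = 3.1,
                             nc_min = 0, nc_max = 1.3,
                             oc_min = 0, oc_max = 1.2,
                             pc_min = 0, pc_max = 0.3,
                             sc_min = 0, sc_max = 0.8,
                             rdbe_min = 0,
                             require_integer_rdbe = FALSE) {
  structure(
    list(
      enabled = isTRUE(enabled),
      ratio_min = c(H = hc_min, N = nc_min, O = oc_min, P = pc_min, S = sc_min),
      ratio_max = c(H = hc_max, N = nc_max, O = oc_max, P = pc_max, S = sc_max),
      rdbe_min = rdbe_min,
      require_integer_rdbe = isTRUE(require_integer_rdbe)
    ),
    class = "heuristic_filter"
  )
}

# logical vector: which rows of an atom-count matrix pass the filter
passes_filter <- function(counts, filter) {
  n <- nrow(counts)
  if (is.null(filter) || !filter$enabled) {
    return(rep(TRUE, n))
  }
  cc <- counts[, "C"]
  ok <- rep(TRUE, n)
  for (e in c("H", "N", "O", "P", "S")) {
    ratio <- counts[, e] / cc
    ok <- ok & ratio >= filter$ratio_min[e] & ratio <= filter$ratio_max[e]
  }
  rdbe <- cc - counts[, "H"] / 2 + counts[, "N"] / 2 + counts[, "P"] / 2 + 1
  ok <- ok & rdbe >= filter$rdbe_min
  if (filter$require_integer_rdbe) {
    ok <- ok & (rdbe == floor(rdbe))
  }
  ok & !is.na(ok)
}

#' Ring/double-bond equivalents
#'
#' `RDBE = C - H/2 + N/2 + P/2 + 1`, the standard valence-based plausibility
#' score for CHNOPS formulae (N and P treated as trivalent).
#'
#' @inheritParams monoisotopic_mass
#' @return Numeric vector of RDBE values.
#' @export
rdbe <- function(formula) {
  m <- as_count_matrix(formula)
  m[, "C"] - m[, "H"] / 2 + m[, "N"] / 2 + m[, "P"] / 2 + 1
}

# Core enumerator. Iterates the (N,O,S,P) heteroatom sub-box (small under
# realistic ranges), then solves the remaining two-variable integer problem
# for (C,H) inside the residual mass interval. Candidate masses are
# recomputed exactly and filtered against [low, high], so the result is
# set-identical to naive six-nested-loop enumeration.
enumerate_counts <- function(low, high, ranges) {
  mm <- .monoisotopic_masses
  lo <- ranges$min
  hi <- ranges$max

  hetero <- expand.grid(
    N = lo["N"]:hi["N"], O = lo["O"]:hi["O"],
    S = lo["S"]:hi["S"], P = lo["P"]:hi["P"],
    KEEP.OUT.ATTRS = FALSE
  )
  m_het <- hetero$N * mm["N"] + hetero$O * mm["O"] +
    hetero$S * mm["S"] + hetero$P * mm["P"]

  # residual mass interval that C and H must fill
  res_lo <- low - m_het
  res_hi <- high - m_het
  feasible <- res_hi >= lo["C"] * mm["C"] + lo["H"] * mm["H"] - 1e-9
  if (!any(feasible)) {
    return(empty_count_matrix())
  }
  hetero <- hetero[feasible, , drop = FALSE]
  res_lo <- res_lo[feasible]
  res_hi <- res_hi[feasible]

  # admissible carbon counts per heteroatom combination (slack absorbs float
  # rounding; exact mass check below makes the final call)
  c_hi <- pmin(hi["C"], floor((res_hi - lo["H"] * mm["H"]) / mm["C"] + 1e-9))
  keep <- c_hi >= lo["C"]
  if (!any(keep)) {
    return(empty_count_matrix())
  }
  hetero <- hetero[keep, , drop = FALSE]
  res_lo <- res_lo[keep]
  res_hi <- res_hi[keep]
  c_hi <- c_hi[keep]

  n_c <- as.integer(c_hi - lo["C"] + 1L)
  idx <- rep.int(seq_along(n_c), n_c)
  c_val <- sequence(n_c) - 1L + lo["C"]

  rem_lo <- res_lo[idx] - c_val * mm["C"]
  rem_hi <- res_hi[idx] - c_val * mm["C"]
  h_lo <- pmax(lo["H"], ceiling(rem_lo / mm["H"] - 1e-9))
  h_hi <- pmin(hi["H"], floor(rem_hi / mm["H"] + 1e-9))
  keep2 <- h_hi >= h_lo
  if (!any(keep2)) {
    return(empty_count_matrix())
  }
  idx <- idx[keep2]
  c_val <- c_val[keep2]
  h_lo <- as.integer(h_lo[keep2])
  n_h <- as.integer(h_hi[keep2] - h_lo + 1L)

  idx3 <- rep.int(seq_along(n_h), n_h)
  h_val <- sequence(n_h) - 1L + h_lo[idx3]

  counts <- cbind(
    C = c_val[idx3], H = h_val,
    N = hetero$N[idx[idx3]], O = hetero$O[idx[idx3]],
    S = hetero$S[idx[idx3]], P = hetero$P[idx[idx3]]
  )
  storage.mode(counts) <- "integer"
  mass <- as.numeric(counts %*% mm)
  inwin <- mass >= low & mass <= high
  counts[inwin, , drop = FALSE]
}

empty_count_matrix <- function() {
  matrix(integer(0), ncol = 6L, dimnames = list(NULL, CHNOPS))
}

make_candidate_set <- function(counts, window, ranges, filter = NULL) {
  mass <- if (nrow(counts)) as.numeric(counts %*% .monoisotopic_masses) else numeric(0)
  error_ppm <- (mass - window$target_mass) / window$target_mass * 1e6
  df <- data.frame(
    formula = if (nrow(counts)) format_formula(counts) else character(0),
    counts,
    mass = mass,
    error_ppm = error_ppm,
    stringsAsFactors = FALSE
  )
  # deterministic order: |error| ascending, then lexicographic atom counts
  if (nrow(df)) {
    ord <- order(abs(df$error_ppm), df$C, df$H, df$N, df$O, df$S, df$P)
    df <- df[ord, , drop = FALSE]
    rownames(df) <- NULL
  }
  structure(df,
    window = window, ranges = ranges, filter = filter,
    class = c("candidate_set", "data.frame")
  )
}

#' Enumerate all formulae in a mass window (brute force)
#'
#' Returns every atom-count combination inside `ranges` whose neutral
#' monoisotopic mass falls in the window — the unfiltered ("brute force")
#' formula generator. The implementation iterates heteroatom combinations
#' and solves for feasible (C, H) pairs, but is exactly set-equivalent to
#' naive six-nested-loop enumeration.
#'
#' @param window A [ppm_window()] object.
#' @param ranges An [element_ranges()] box (default: the standard
#'   metabolite ranges).
#' @return A `candidate_set`: a data.frame with columns `formula`,
#'   `C,H,N,O,S,P`, `mass` (Da) and `error_ppm` (signed, relative to the
#'   window's target mass), sorted by `|error_ppm|` with lexicographic
#'   tie-break; the window, ranges and filter are carried as attributes.
#' @examples
#' cs <- enumerate_brute_force(ppm_window(441.1397, 5))
#' head(cs)
#' nrow(cs)   # mass degeneracy at 5 ppm around folate
#' @export
enumerate_brute_force <- function(window, ranges = element_ranges()) {
  stopifnot(inherits(window, "mass_window"), inherits(ranges, "element_ranges"))
  counts <- enumerate_counts(window$low, window$high, ranges)
  make_candidate_set(counts, window, ranges, filter = NULL)
}

#' Enumerate formulae in a mass window with heuristic filtering
#'
#' As [enumerate_brute_force()], then drops candidates failing any enabled
#' check of a [heuristic_filter()]. With the filter disabled the result is
#' identical to brute force.
#'
#' @inheritParams enumerate_brute_force
#' @param filter A [heuristic_filter()] configuration.
#' @return A `candidate_set` (see [enumerate_brute_force()]).
#' @examples
#' w <- ppm_window(506.9957, 5)  # ATP
#' nrow(enumerate_filtered(w, filter = heuristic_filter()))      # ATP excluded
#' nrow(enumerate_filtered(w, filter = heuristic_filter(oc_max = 3)))
#' @export
enumerate_filtered <- function(window, ranges = element_ranges(),
                               filter = heuristic_filter()) {
  stopifnot(inherits(filter, "heuristic_filter"))
  counts <- enumerate_counts(window$low, window$high, ranges)
  counts <- counts[passes_filter(counts, filter), , drop = FALSE]
  make_candidate_set(counts, window, ranges, filter = filter)
}

#' @export
print.candidate_set <- function(x, ...) {
  w <- attr(x, "window")
  cat(sprintf("candidate set: %d formulae in [%.6f, %.6f] Da (%.4f Da +/- %g ppm)\n",
              nrow(x), w$low, w$high, w$target_mass, w$tolerance_ppm))
  if (!is.null(attr(x, "filter")) && attr(x, "filter")$enabled) {
    cat("  heuristic filter: enabled\n")
  }
  print.data.frame(utils::head(as.data.frame(x), 10L))
  if (nrow(x) > 10L) cat("  ... and", nrow(x) - 10L, "more\n")
  invisible(x)
}

#' Mass degeneracy of a candidate set
#'
#' The number of chemical formulae other than the true one that are
#' indistinguishable from it at the window's mass tolerance. When the true
#' formula is supplied it must be present in the set (it always is when the
#' window was built from its own mass) and the count excludes it; otherwise
#' the plain candidate count is returned.
#'
#' @param candidate_set A `candidate_set` from the enumerators.
#' @param true_formula Optional `chem_formula` or formula string.
#' @return Integer degeneracy count (0 means the mass is unique).
#' @examples
#' w <- ppm_window(monoisotopic_mass("CH4"), 5)
#' degeneracy(enumerate_brute_force(w), "CH4")  # 0: methane is unique
#' @export
degeneracy <- function(candidate_set, true_formula = NULL) {
  stopifnot(inherits(candidate_set, "candidate_set"))
  if (is.null(true_formula)) {
    return(nrow(candidate_set))
  }
  key <- format_formula(as_count_matrix(true_formula))
  if (!key %in% candidate_set$formula) {
    stop("true formula ", key, " is not in the candidate set; ",
         "was the window built from its mass?")
  }
  nrow(candidate_set) - 1L
}
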