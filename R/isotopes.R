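#' Exact isotopologue distribution of a single element
#'
#' Probability of each neutron offset for `n` atoms of one element, computed
#' from the exact multinomial distribution over the element's stable
#' isotopes: the probability of offset `d` is the sum over isotope-count
#' vectors `k` (with `sum(k) = n` and total extra-neutron count `d`) of
#' `n! / prod(k!) * prod(p^k)`. Offsets beyond `max_offset` are truncated
#' (so probabilities sum to slightly less than 1).
#'
#' @param element Element symbol (one of C, H, N, O, S, P).
#' @param atom_count Number of atoms (>= 0; 0 gives a point mass at offset 0).
#' @param table The pinned [isotope_table()] (exposed for transparency; there
#'   is no alternative table).
#' @param max_offset Largest neutron offset retained.
#' @return An `isotope_pattern`: a data.frame with columns `neutron_offset`
#'   and `probability` (absolute normalization).
#' @examples
#' element_distribution("P", 5)        # monoisotopic: all mass at offset 0
#' element_distribution("C", 10)       # binomial in the 13C count
#' @export
element_distribution <- function(element, atom_count,
                                 table = isotope_table(), max_offset = 5L) {
  if (!element %in% CHNOPS) {
    stop("unknown element: ", element)
  }
  stopifnot(atom_count >= 0, max_offset >= 0)
  sub <- table[table$element == element, , drop = FALSE]
  probs <- element_offset_probs(sub$neutron_offset, sub$abundance,
                                atom_count, max_offset)
  new_isotope_pattern(probs, max_offset)
}

# exact multinomial over one element, returned as a numeric vector indexed
# by neutron offset 0..max_offset
element_offset_probs <- function(offsets, abundances, n, max_offset) {
  out <- numeric(max_offset + 1L)
  if (n == 0L) {
    out[1L] <- 1
    return(out)
  }
  heavy <- which(offsets > 0L)
  if (length(heavy) == 0L) {
    out[1L] <- 1  # single-isotope element: abundance 1 at offset 0
    return(out)
  }
  # heavy-isotope counts are bounded by the truncation offset, so the grid
  # of compositions is tiny even for 200 atoms
  kmax <- pmin(n, floor(max_offset / offsets[heavy]))
  grid <- expand.grid(lapply(kmax, function(k) 0:k), KEEP.OUT.ATTRS = FALSE)
  k_heavy <- as.matrix(grid)
  d <- as.vector(k_heavy %*% offsets[heavy])
  n_heavy <- rowSums(k_heavy)
  ok <- d <= max_offset & n_heavy <= n
  k_heavy <- k_heavy[ok, , drop = FALSE]
  d <- d[ok]
  k0 <- n - n_heavy[ok]
  logp <- lgamma(n + 1) - lgamma(k0 + 1) + k0 * log(abundances[offsets == 0L])
  for (j in seq_along(heavy)) {
    pj <- abundances[heavy[j]]
    kj <- k_heavy[, j]
    logp <- logp - lgamma(kj + 1) + ifelse(kj > 0, kj * log(pj), 0)
  }
  p <- exp(logp)
  for (i in seq_along(d)) {
    out[d[i] + 1L] <- out[d[i] + 1L] + p[i]
  }
  out
}

new_isotope_pattern <- function(probs, max_offset, normalization = "absolute") {
  structure(
    data.frame(neutron_offset = 0:max_offset, probability = probs),
    normalization = normalization,
    truncation_mass_shift = max_offset,
    class = c("isotope_pattern", "data.frame")
  )
}

#' @export
print.isotope_pattern <- function(x, ...) {
  cat("isotope pattern (", attr(x, "normalization"),
      " normalization, truncated at +", attr(x, "truncation_mass_shift"),
      "):\n", sep = "")
  print.data.frame(as.data.frame(x))
  invisible(x)
}

#' Molecular isotopologue pattern by multinomial convolution
#'
#' Builds the exact per-element multinomial isotopologue distributions and
#' convolves them across the six elements to give the molecular pattern —
#' the probabilities of the M0, M1, M2, ... peaks. The default mass axis
#' aggregates by integer neutron offset (unit resolution, the regime of
#' most metabolomics instruments); a fine mass axis with a configurable bin
#' width in Da is available for completeness, resolving e.g. the 13C vs 15N
#' contributions to M1.
#'
#' @inheritParams monoisotopic_mass
#' @param table The pinned [isotope_table()].
#' @param max_offset Largest neutron offset retained (default 5, ample for
#'   M2 work on CHNOPS molecules below 2000 Da).
#' @param bin `"unit"` for integer neutron-offset bins, or a numeric bin
#'   width in Da for a fine mass axis.
#' @return An `isotope_pattern` data.frame; in unit mode with columns
#'   `neutron_offset` and `probability`, in fine mode with `mass_shift`
#'   (bin center, Da relative to the monoisotopic mass) and `probability`.
#'   Probabilities are absolute (they sum to < 1 by the truncated tail only).
#' @examples
#' molecular_pattern("C19H19N7O6")
#' relative_ratios(molecular_pattern("C6H12O6"))
#' @export
molecular_pattern <- function(formula, table = isotope_table(),
                              max_offset = 5L, bin = "unit") {
  counts <- as_count_matrix(formula)
  if (nrow(counts) != 1L) {
    stop("molecular_pattern expects a single formula")
  }
  if (sum(counts) < 1L) {
    stop("invalid formula: all atom counts are zero")
  }
  if (identical(bin, "unit")) {
    acc <- c(1, numeric(max_offset))
    for (e in CHNOPS) {
      n <- counts[1L, e]
      if (n == 0L) next
      sub <- table[table$element == e, , drop = FALSE]
      vec <- element_offset_probs(sub$neutron_offset, sub$abundance, n, max_offset)
      acc <- convolve_truncated(acc, vec, max_offset)
    }
    return(new_isotope_pattern(acc, max_offset))
  }
  if (!is.numeric(bin) || length(bin) != 1L || bin <= 0) {
    stop("bin must be \"unit\" or a positive bin width in Da")
  }
  fine_mass_pattern(counts, table, max_offset, bin)
}

convolve_truncated <- function(a, b, max_offset) {
  out <- numeric(max_offset + 1L)
  for (d in 0:max_offset) {
    if (b[d + 1L] == 0) next
    out[(d + 1L):(max_offset + 1L)] <-
      out[(d + 1L):(max_offset + 1L)] + a[1:(max_offset + 1L - d)] * b[d + 1L]
  }
  out
}

# fine mass-axis mode: per-element compositions carry their exact mass shift
# relative to all-lightest; shifts are binned to a grid of width `bin` and
# convolved as sparse (bin index -> probability) maps
fine_mass_pattern <- function(counts, table, max_offset, bin, floor_prob = 1e-12) {
  acc <- c("0" = 1)
  for (e in CHNOPS) {
    n <- counts[1L, e]
    if (n == 0L) next
    sub <- table[table$element == e, , drop = FALSE]
    comp <- element_compositions(sub, n, max_offset)
    vec <- tapply(comp$prob, round(comp$shift / bin), sum)
    acc <- sparse_convolve(acc, vec)
    # total-shift truncation matching the unit mode's offset cap
    acc <- acc[as.numeric(names(acc)) * bin <= max_offset + 0.5]
  }
  acc <- acc[acc >= floor_prob]
  idx <- as.numeric(names(acc))
  ord <- order(idx)
  structure(
    data.frame(mass_shift = idx[ord] * bin, probability = as.numeric(acc)[ord]),
    normalization = "absolute",
    truncation_mass_shift = max_offset,
    bin_width = bin,
    class = c("isotope_pattern", "data.frame")
  )
}

# all isotope compositions of n atoms of one element with neutron offset
# <= max_offset, with exact probability and mass shift
element_compositions <- function(sub, n, max_offset) {
  offsets <- sub$neutron_offset
  masses <- sub$mass
  ab <- sub$abundance
  heavy <- which(offsets > 0L)
  if (length(heavy) == 0L) {
    return(data.frame(shift = 0, prob = 1))
  }
  kmax <- pmin(n, floor(max_offset / offsets[heavy]))
  grid <- expand.grid(lapply(kmax, function(k) 0:k), KEEP.OUT.ATTRS = FALSE)
  k_heavy <- as.matrix(grid)
  d <- as.vector(k_heavy %*% offsets[heavy])
  n_heavy <- rowSums(k_heavy)
  ok <- d <= max_offset & n_heavy <= n
  k_heavy <- k_heavy[ok, , drop = FALSE]
  k0 <- n - n_heavy[ok]
  logp <- lgamma(n + 1) - lgamma(k0 + 1) + k0 * log(ab[offsets == 0L])
  shift <- numeric(length(k0))
  for (j in seq_along(heavy)) {
    kj <- k_heavy[, j]
    logp <- logp - lgamma(kj + 1) + ifelse(kj > 0, kj * log(ab[heavy[j]]), 0)
    shift <- shift + kj * (masses[heavy[j]] - masses[offsets == 0L])
  }
  data.frame(shift = shift, prob = exp(logp))
}

sparse_convolve <- function(a, b) {
  ia <- as.numeric(names(a))
  ib <- as.numeric(names(b))
  idx <- outer(ia, ib, "+")
  val <- outer(as.numeric(a), as.numeric(b))
  tapply(as.vector(val), as.vector(idx), sum)
}

#' M1/M0 and M2/M0 relative peak intensities
#'
#' The two intensity ratios used for natural-abundance formula filtering:
#' the intensity of the one- and two-extra-neutron peaks relative to the
#' monoisotopic peak. Independent of whether the pattern is absolutely or
#' relatively normalized.
#'
#' @param pattern An `isotope_pattern` on the unit (neutron-offset) axis
#'   with offsets 0..2 present.
#' @return Named numeric vector `c(m1_over_m0, m2_over_m0)`.
#' @examples
#' relative_ratios(molecular_pattern("C19H19N7O6"))
#' @export
relative_ratios <- function(pattern) {
  stopifnot(inherits(pattern, "isotope_pattern"))
  if (is.null(pattern$neutron_offset)) {
    stop("relative_ratios requires a unit (neutron-offset) pattern")
  }
  p <- pattern$probability[match(0:2, pattern$neutron_offset)]
  if (anyNA(p)) {
    stop("pattern must contain offsets 0, 1 and 2")
  }
  if (p[1] == 0) {
    stop("cannot normalize: M0 probability is zero")
  }
  c(m1_over_m0 = p[2] / p[1], m2_over_m0 = p[3] / p[1])
}

#' Closed-form M1/M0 and M2/M0 for many formulae at once
#'
#' Exact vectorized predictor of the two relative peak intensities, used by
#' the ratio-based candidate filter. M1 arises only from single +1-isotope
#' substitutions, M2 from one +2 substitution or two +1 substitutions, so
#' with `q1,e = p(+1)/p(base)` and `q2,e = p(+2)/p(base)`:
#' `M1/M0 = sum_e n_e q1,e` and
#' `M2/M0 = (S1^2 - sum_e n_e q1,e^2)/2 + sum_e n_e q2,e` where
#' `S1 = M1/M0`. Agrees with [molecular_pattern()] to machine precision.
#'
#' @inheritParams monoisotopic_mass
#' @return A data.frame with columns `m1_over_m0`, `m2_over_m0`, one row per
#'   formula.
#' @examples
#' predict_peak_ratios(c("C6H12O6", "C19H19N7O6"))
#' @export
predict_peak_ratios <- function(formula) {
  m <- as_count_matrix(formula)
  q1 <- .q_ratios$q1
  q2 <- .q_ratios$q2
  s1 <- as.numeric(m %*% q1)
  sq <- as.numeric(m %*% (q1^2))
  s2 <- (s1^2 - sq) / 2 + as.numeric(m %*% q2)
  data.frame(m1_over_m0 = s1, m2_over_m0 = s2)
}
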