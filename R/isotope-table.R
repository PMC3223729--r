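#' Pinned stable-isotope table for C, H, N, O, S, P
#'
#' Exact isotope masses (Da) and natural abundances (fractions) for the six
#' biologically dominant elements, pinned as a versioned package constant so
#' that every mass and isotope-pattern computation in the package is
#' reproducible. Values are the NIST/IUPAC atomic masses and representative
#' isotopic compositions (the table distributed with pyteomics 5.0.1, itself
#' taken from the NIST compilation). Abundances per element sum to exactly 1.
#'
#' The `neutron_offset` column counts extra neutrons relative to the lightest
#' stable isotope of the element (0 for the lightest); note sulfur has no
#' stable isotope at offset 3, so its offsets are 0, 1, 2, 4.
#'
#' @param element Optional element symbol (`"C"`, `"H"`, `"N"`, `"O"`, `"S"`,
#'   `"P"`). If supplied, only that element's table is returned.
#' @return A data.frame with columns `element`, `neutron_offset`, `mass`,
#'   `abundance`, ordered by element then offset; or the subset for one
#'   element.
#' @examples
#' isotope_table("C")
#' @export
isotope_table <- function(element = NULL) {
  tab <- .silform_isotopes
  if (is.null(element)) {
    return(tab)
  }
  if (!element %in% CHNOPS) {
    stop("unknown element: ", element, " (supported: ", paste(CHNOPS, collapse = ", "), ")")
  }
  tab[tab$element == element, , drop = FALSE]
}

#' @rdname isotope_table
#' @format `CHNOPS` is the fixed element order `c("C","H","N","O","S","P")`
#'   used for all atom-count vectors in the package.
#' @export
CHNOPS <- c("C", "H", "N", "O", "S", "P")

# version tag recorded in provenance output
.isotope_table_version <- "nist-pyteomics-5.0.1"

.silform_isotopes <- data.frame(
  element = c(
    "C", "C",
    "H", "H",
    "N", "N",
    "O", "O", "O",
    "S", "S", "S", "S",
    "P"
  ),
  neutron_offset = c(
    0L, 1L,
    0L, 1L,
    0L, 1L,
    0L, 1L, 2L,
    0L, 1L, 2L, 4L,
    0L
  ),
  mass = c(
    12.0, 13.0033548378,
    1.00782503207, 2.0141017778,
    14.0030740048, 15.0001088982,
    15.99491461956, 16.9991317, 17.999161,
    31.972071, 32.97145876, 33.9678669, 35.96708076,
    30.97376163
  ),
  abundance = c(
    0.9893, 0.0107,
    0.999885, 0.000115,
    0.99636, 0.00364,
    0.99757, 0.00038, 0.00205,
    0.9499, 0.0075, 0.0425, 0.0001,
    1.0
  ),
  stringsAsFactors = FALSE
)

# lightest-isotope (monoisotopic) mass per element, in CHNOPS order
.monoisotopic_masses <- local({
  m <- vapply(CHNOPS, function(e) {
    sub <- .silform_isotopes[.silform_isotopes$element == e, ]
    sub$mass[sub$neutron_offset == 0L]
  }, numeric(1))
  names(m) <- CHNOPS
  m
})

# abundance ratios used by the closed-form M1/M2 predictor:
# q1 = p(+1 isotope)/p(base), q2 = p(+2 isotope)/p(base); 0 where absent
.q_ratios <- local({
  q1 <- q2 <- numeric(length(CHNOPS))
  names(q1) <- names(q2) <- CHNOPS
  for (e in CHNOPS) {
    sub <- .silform_isotopes[.silform_isotopes$element == e, ]
    p0 <- sub$abundance[sub$neutron_offset == 0L]
    if (any(sub$neutron_offset == 1L)) {
      q1[e] <- sub$abundance[sub$neutron_offset == 1L] / p0
    }
    if (any(sub$neutron_offset == 2L)) {
      q2[e] <- sub$abundance[sub$neutron_offset == 2L] / p0
    }
  }
  list(q1 = q1, q2 = q2)
})
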