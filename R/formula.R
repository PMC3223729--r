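#' Chemical formulae over C, H, N, O, S, P
#'
#' A chemical formula is an integer atom-count vector over the six elements
#' C, H, N, O, S, P (in that fixed order). All counts must be non-negative
#' and at least one atom must be present. Two formulae are equal iff all six
#' counts are equal.
#'
#' @param c_count,h_count,n_count,o_count,s_count,p_count Non-negative
#'   integer atom counts.
#' @return An object of class `chem_formula`: a named integer vector of
#'   length 6 with names `C,H,N,O,S,P`.
#' @examples
#' chem_formula(19, 19, 7, 6)          # folate
#' parse_formula("C19H19N7O6")
#' @seealso [parse_formula()], [monoisotopic_mass()]
#' @export
chem_formula <- function(c_count = 0, h_count = 0, n_count = 0,
                         o_count = 0, s_count = 0, p_count = 0) {
  counts <- c(c_count, h_count, n_count, o_count, s_count, p_count)
  if (length(counts) != 6L || anyNA(counts)) {
    stop("chem_formula requires six non-missing atom counts")
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("atom counts must be non-negative integers")
  }
  counts <- as.integer(round(counts))
  if (sum(counts) < 1L) {
    stop("a chemical formula must contain at least one atom")
  }
  names(counts) <- CHNOPS
  structure(counts, class = "chem_formula")
}

#' @export
print.chem_formula <- function(x, ...) {
  cat(format_formula(x), " (", format(monoisotopic_mass(x), nsmall = 4), " Da)\n", sep = "")
  invisible(x)
}

#' Parse and format formula strings
#'
#' Formula strings use Hill-like notation restricted to C, H, N, O, S, P
#' (e.g. `"C19H19N7O6"`). An omitted element means count 0; an omitted count
#' means 1 (so `"CH4"` is methane). `format_formula()` writes counts in
#' C, H, N, O, S, P order, omitting zero-count elements and the digit 1,
#' and round-trips: `parse_formula(format_formula(f))` equals `f`.
#'
#' @param text A formula string.
#' @param f A `chem_formula` (or a six-column atom-count matrix for the
#'   vectorized formatter).
#' @return `parse_formula()` returns a `chem_formula`; `format_formula()`
#'   a character vector.
#' @examples
#' parse_formula("CH4")
#' format_formula(chem_formula(6, 12, 0, 6))
#' @export
parse_formula <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text) || !nzchar(text)) {
    stop("formula must be a single non-empty string")
  }
  tokens <- gregexpr("[A-Z][a-z]?[0-9]*", text)[[1]]
  parts <- regmatches(text, gregexpr("[A-Z][a-z]?[0-9]*", text))[[1]]
  if (length(parts) == 0L || sum(nchar(parts)) != nchar(text)) {
    stop("malformed formula string: '", text, "'")
  }
  counts <- stats::setNames(integer(6L), CHNOPS)
  for (p in parts) {
    sym <- sub("[0-9]*$", "", p)
    num <- sub("^[A-Za-z]+", "", p)
    if (!sym %in% CHNOPS) {
      stop("element '", sym, "' is outside C,H,N,O,S,P in formula '", text, "'")
    }
    n <- if (nzchar(num)) as.integer(num) else 1L
    counts[sym] <- counts[sym] + n
  }
  chem_formula(counts["C"], counts["H"], counts["N"],
               counts["O"], counts["S"], counts["P"])
}

#' @rdname parse_formula
#' @export
format_formula <- function(f) {
  m <- as_count_matrix(f)
  apply(m, 1L, function(row) {
    keep <- row > 0L
    paste0(CHNOPS[keep], ifelse(row[keep] == 1L, "", row[keep]), collapse = "")
  })
}

# Coerce a chem_formula, formula string, count vector, or n x 6 matrix /
# data.frame with C,H,N,O,S,P columns to an integer count matrix.
as_count_matrix <- function(x) {
  if (inherits(x, "chem_formula")) {
    return(matrix(unclass(x), nrow = 1L, dimnames = list(NULL, CHNOPS)))
  }
  if (is.character(x)) {
    m <- t(vapply(x, function(s) unclass(parse_formula(s)), integer(6L)))
    dimnames(m) <- list(NULL, CHNOPS)
    return(m)
  }
  if (is.data.frame(x)) {
    if (!all(CHNOPS %in% names(x))) {
      stop("data.frame must carry columns ", paste(CHNOPS, collapse = ","))
    }
    m <- as.matrix(x[CHNOPS])
    storage.mode(m) <- "integer"
    return(m)
  }
  if (is.matrix(x)) {
    if (is.null(colnames(x))) {
      if (ncol(x) != 6L) stop("count matrix must have 6 columns (C,H,N,O,S,P)")
      colnames(x) <- CHNOPS
    }
    m <- x[, CHNOPS, drop = FALSE]
    storage.mode(m) <- "integer"
    return(m)
  }
  if (is.numeric(x) && length(x) == 6L) {
    return(matrix(as.integer(x), nrow = 1L, dimnames = list(NULL, CHNOPS)))
  }
  stop("cannot interpret object of class ", paste(class(x), collapse = "/"),
       " as chemical formulae")
}

#' Neutral monoisotopic mass
#'
#' Sum over elements of atom count times the lightest-isotope exact mass from
#' the pinned [isotope_table()]. Masses are neutral and uncharged; no adduct
#' or electron-mass handling.
#'
#' @param formula A `chem_formula`, a formula string (or character vector),
#'   or an atom-count matrix / data.frame with columns `C,H,N,O,S,P`.
#' @return Numeric vector of masses in Da, one per formula.
#' @examples
#' monoisotopic_mass("C19H19N7O6")   # folate, 441.1397 Da
#' monoisotopic_mass(chem_formula(1))  # 12 exactly: carbon-12 defines the scale
#' @export
monoisotopic_mass <- function(formula) {
  m <- as_count_matrix(formula)
  if (any(rowSums(m) < 1L)) {
    stop("invalid formula: all atom counts are zero")
  }
  as.numeric(m %*% .monoisotopic_masses)
}

#' Per-element atom-count ranges defining the formula search space
#'
#' The six-dimensional box of candidate atom counts. The default reproduces
#' the ranges commonly used for small-molecule metabolites: C and H from 1 to
#' 200, N 0-6, O 0-20, S 0-6, P 0-6, a search space of 288,120,000 formulae.
#'
#' @param C,H,N,O,S,P Length-2 integer vectors `c(min, max)` per element.
#' @return An object of class `element_ranges`: a list with integer vectors
#'   `$min` and `$max`, each named by element.
#' @examples
#' element_ranges()
#' element_ranges(C = c(1, 30), H = c(1, 60))
#' @export
element_ranges <- function(C = c(1L, 200L), H = c(1L, 200L), N = c(0L, 6L),
                           O = c(0L, 20L), S = c(0L, 6L), P = c(0L, 6L)) {
  rng <- list(C = C, H = H, N = N, O = O, S = S, P = P)
  lo <- hi <- stats::setNames(integer(6L), CHNOPS)
  for (e in CHNOPS) {
    r <- rng[[e]]
    if (length(r) != 2L || anyNA(r) || any(r < 0) || r[1] > r[2]) {
      stop("range for ", e, " must satisfy 0 <= min <= max")
    }
    lo[e] <- as.integer(r[1])
    hi[e] <- as.integer(r[2])
  }
  structure(list(min = lo, max = hi), class = "element_ranges")
}

#' @export
print.element_ranges <- function(x, ...) {
  cat("element ranges: ",
      paste0(CHNOPS, "[", x$min, ":", x$max, "]", collapse = " "),
      "\n  search space: ", format(search_space_size(x), big.mark = ","),
      " formulae\n", sep = "")
  invisible(x)
}

#' Relative (ppm) mass window around a target mass
#'
#' The symmetric window `[m (1 - ppm 1e-6), m (1 + ppm 1e-6)]` around a
#' neutral target mass, the standard accurate-mass tolerance model (relative
#' to the target, not the candidate).
#'
#' @param target_mass Target neutral monoisotopic mass in Da (> 0).
#' @param tolerance_ppm Half-width tolerance in parts per million (>= 0).
#' @return An object of class `mass_window`: a list with `target_mass`,
#'   `tolerance_ppm`, `low`, `high`.
#' @examples
#' ppm_window(441.1397, 5)
#' @export
ppm_window <- function(target_mass, tolerance_ppm) {
  if (!is.numeric(target_mass) || length(target_mass) != 1L ||
      is.na(target_mass) || target_mass <= 0) {
    stop("target_mass must be a single positive number")
  }
  if (!is.numeric(tolerance_ppm) || length(tolerance_ppm) != 1L ||
      is.na(tolerance_ppm) || tolerance_ppm < 0) {
    stop("tolerance_ppm must be a single non-negative number")
  }
  structure(
    list(
      target_mass = target_mass,
      tolerance_ppm = tolerance_ppm,
      low = target_mass * (1 - tolerance_ppm * 1e-6),
      high = target_mass * (1 + tolerance_ppm * 1e-6)
    ),
    class = "mass_window"
  )
}

#' @export
print.mass_window <- function(x, ...) {
  cat(sprintf("mass window: %.6f Da +/- %g ppm -> [%.6f, %.6f]\n",
              x$target_mass, x$tolerance_ppm, x$low, x$high))
  invisible(x)
}
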