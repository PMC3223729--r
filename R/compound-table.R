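#' Read a compound table with formula cross-checking
#'
#' Reads a TSV of compounds with columns `id`, `formula` and optionally
#' `monoisotopic_mass`. Masses are always recomputed from the formula with
#' the pinned isotope table; when the file also states a mass, any
#' discrepancy above 1e-3 Da triggers a warning naming the compound (a
#' guard against stale tables or a different mass convention).
#'
#' @param path Path to a tab-separated file.
#' @return A data.frame with columns `id`, `formula`, `C,H,N,O,S,P`, and
#'   `monoisotopic_mass` (recomputed).
#' @export
read_compound_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("id", "formula") %in% names(tab))) {
    stop("compound table needs columns 'id' and 'formula'")
  }
  counts <- as_count_matrix(tab$formula)
  mass <- monoisotopic_mass(counts)
  if ("monoisotopic_mass" %in% names(tab)) {
    off <- which(abs(tab$monoisotopic_mass - mass) > 1e-3)
    if (length(off)) {
      warning("stated mass differs from the recomputed mass by > 1e-3 Da for: ",
              paste(utils::head(tab$id[off], 5), collapse = ", "))
    }
  }
  data.frame(id = tab$id, formula = tab$formula, counts,
             monoisotopic_mass = mass, stringsAsFactors = FALSE)
}
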