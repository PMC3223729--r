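# Independent oracles and fixture builders shared across the suite.

# Naive six-nested-loop enumeration (materialized as a full grid): the
# reference implementation the optimized enumerator must match exactly.
naive_enumerate <- function(low, high, ranges) {
  tab <- isotope_table()
  mono <- vapply(CHNOPS, function(e) {
    sub <- tab[tab$element == e, ]
    sub$mass[sub$neutron_offset == 0]
  }, numeric(1))
  g <- expand.grid(
    C = ranges$min["C"]:ranges$max["C"],
    H = ranges$min["H"]:ranges$max["H"],
    N = ranges$min["N"]:ranges$max["N"],
    O = ranges$min["O"]:ranges$max["O"],
    S = ranges$min["S"]:ranges$max["S"],
    P = ranges$min["P"]:ranges$max["P"],
    KEEP.OUT.ATTRS = FALSE
  )
  m <- as.matrix(g) %*% mono[colnames(g)]
  g <- g[m >= low & m <= high & rowSums(g) >= 1, , drop = FALSE]
  g[order(g$C, g$H, g$N, g$O, g$S, g$P), , drop = FALSE]
}

# canonical sorted key set of a candidate collection, for set comparison
formula_key_set <- function(df) {
  sort(paste(df$C, df$H, df$N, df$O, df$S, df$P))
}

# random in-range atom-count matrices (plain formulae, no mass band)
random_counts <- function(n, cmax = 30, hmax = 60, hetmax = 5, seed = 1) {
  withr::with_seed(seed, {
    m <- cbind(
      C = sample(1:cmax, n, replace = TRUE),
      H = sample(1:hmax, n, replace = TRUE),
      N = sample(0:hetmax, n, replace = TRUE),
      O = sample(0:hetmax, n, replace = TRUE),
      S = sample(0:hetmax, n, replace = TRUE),
      P = sample(0:hetmax, n, replace = TRUE)
    )
    storage.mode(m) <- "integer"
    m
  })
}

# small hand-built pathway database fixtures
two_pathways_one_shared <- function() {
  pathway_db(
    compounds = c(shared = "C6H12O6", a = "C3H7NO2", b = "C5H5N5"),
    reactions = list(r1 = c("shared", "a"), r2 = c("shared", "b")),
    pathways = list(p1 = "r1", p2 = "r2")
  )
}
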