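---
title: "Methods: formula degeneracy, isotope patterns, and SIL constraints"
author: "silform"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: formula degeneracy, isotope patterns, and SIL constraints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(silform)
```

## The model

An uncharged CHNOPS molecule is a lattice point (a, b, c, x, y, z) in the
six-dimensional box of atom counts for C, H, N, O, S, P. The default box —
C and H from 1 to 200, N 0–6, O 0–20, S 0–6, P 0–6 — contains
`r format(search_space_size(), big.mark = ",")` formulae and is meant to
cover the overwhelming majority of biological metabolites below about
2000 Da. An accurate-mass measurement observes only the neutral
monoisotopic mass

$$ m(f) = \sum_e n_e \, m_e^{(0)} $$

(lightest-isotope masses $m_e^{(0)}$ from the pinned isotope table) to
within a symmetric relative window $[m(1-\mathrm{tol}),\, m(1+\mathrm{tol})]$,
tol in ppm and relative to the *target* mass. Everything downstream reduces
to counting lattice points inside that slab and intersecting the count with
additional constraints.

All masses are neutral and uncharged: no adducts, charges, or electron-mass
corrections. That keeps the analysis instrument-agnostic; translating a
measured ion m/z to a neutral mass is the caller's responsibility.

### Assumptions worth stating

* Compositions are natural-isotopic-abundance; isotopically enriched
  *inputs* are out of scope (SIL enters only as exact C/N counts, not as a
  predicted labeled pattern).
* SIL counting is modeled as error-free. In practice a fully labeled
  culture gives the C (or N) count from the mass shift between labeled and
  unlabeled features with essentially digital accuracy, but partial
  labeling efficiency and isotope effects are not modeled.
* The isotope-ratio filter evaluates a tolerance band, not a noise model:
  candidate f survives iff both predicted ratios lie within
  $u \cdot r_{\mathrm{obs}}$ of the observed M1/M0 and M2/M0 (joint AND).
  An observed ratio of exactly 0 demands a predicted ratio below an
  absolute floor of 1e-9.

## The pinned isotope table

The table (`isotope_table()`) pins NIST/IUPAC isotope masses (≥ 9 decimals)
and representative natural abundances (4–6 decimals) for C, H, N, O, S, P;
abundances per element sum to exactly 1. It is a versioned constant
(`nist-pyteomics-5.0.1`, i.e. the NIST compilation as distributed with the
pyteomics library), never fetched at run time, and recorded in every
provenance file. Fourth-decimal abundance differences between published
tables shift M1/M0 predictions by well under the 10% uncertainty regime
studied here, but pinning makes every number in the package reproducible
bit-for-bit.

## Enumeration

`enumerate_brute_force()` must equal naive six-nested-loop enumeration as a
set. Iterating 288 million points per window is wasteful, so the
implementation iterates only the heteroatom sub-box (N, O, S, P — at most
7·21·7·7 = 7203 combinations under the default ranges) and solves the
residual two-variable integer problem for (C, H) analytically: for each
heteroatom mass and each feasible carbon count, the admissible hydrogen
counts form a contiguous integer interval. Floating-point slack (1e-9 Da)
is added when converting interval endpoints to integers, and every
candidate's exact mass is then re-tested against the window with the same
comparison the naive loop would use — so boundary behaviour is identical
by construction, and the equivalence is enforced by randomized tests
against a materialized full-grid oracle over reduced ranges.

Candidates are ordered by |mass error in ppm|, ties broken
lexicographically on (C, H, N, O, S, P), so outputs diff cleanly.
`degeneracy()` reports |set| − 1 when the true formula is supplied
("degenerate" = at least one *other* formula exists) and errors if the true
formula is missing from its own self-window, which would indicate an
inconsistent call.

### Heuristic filters

`heuristic_filter()` emulates the restricted generators used in practice:
element-ratio bounds (defaults are the "common range" values: H/C 0.2–3.1,
N/C ≤ 1.3, O/C ≤ 1.2, P/C ≤ 0.3, S/C ≤ 0.8), an RDBE lower bound
(RDBE = C − H/2 + N/2 + P/2 + 1, default ≥ 0), and an optional
integer-RDBE parity rule (off by default). Every bound is configurable
because the defaults demonstrably misfire: ATP (O/C = 1.3), taurine, and
malate all fail O/C ≤ 1.2. The filter is only ever applied as a subset of
the brute-force result; when the seed formula itself is filtered out,
`compare_regimes()` counts it (`truth_lost`) rather than hiding it, and
`run_full_analysis()` escalates it to a warning.

## Isotopologue patterns

For n atoms of one element with isotope abundances $p_i$ and neutron
offsets $d_i$, the probability of total offset $d$ is the exact multinomial
sum over count vectors $k$ with $\sum k_i = n$, $\sum k_i d_i = d$:
$\frac{n!}{\prod k_i!} \prod p_i^{k_i}$. Because retained offsets are
capped, heavy-isotope counts are bounded by the cap and the composition
grid stays tiny even for 200 atoms; coefficients are evaluated in log space
(`lgamma`). The molecular pattern is the truncated discrete convolution of
the six element vectors.

Numerical choices:

* default truncation at neutron offset 5 — with all probability retained
  below the cap, total probability is conserved to better than 1e-9 for
  CHNOPS molecules in the ≤ 2000 Da range the package targets;
* default binning aggregates by integer neutron offset (unit resolution),
  because the downstream comparison uses only M1 and M2 and most
  metabolomics instruments do not resolve isotopic fine structure. A fine
  mass-axis mode (`bin = width` in Da) bins exact composition mass shifts
  instead, with a per-bin floor of 1e-12 and the same total-offset
  truncation; it resolves e.g. the ¹³C/¹⁵N/²H contributions to M1 but is
  not used in the headline analysis;
* no Gaussian or polynomial approximations anywhere — the multinomial is
  evaluated exactly, and tests pin the full patterns of five reference
  molecules against an independently computed truncated polynomial-power
  oracle.

For filtering thousands of candidates, `predict_peak_ratios()` uses the
exact closed forms (with $q_{1,e}, q_{2,e}$ the +1 and +2 abundance ratios
per atom): $M1/M0 = S_1 = \sum_e n_e q_{1,e}$ and
$M2/M0 = (S_1^2 - \sum_e n_e q_{1,e}^2)/2 + \sum_e n_e q_{2,e}$ — only
single and double substitutions reach offsets 1 and 2. The closed form and
the convolution generator are cross-checked against each other in the test
suite; the convolution remains the reference implementation.

## The regime comparison

`compare_regimes()` samples formulae from a library, builds each one's
window, enumerates candidates, and counts survivors under the true C/N
counts versus the true formula's noise-free theoretical ratios at the
stated uncertainty. "Observed" ratios are noise-free by design: the
comparison evaluates the tolerance band the ratio rule defines, not an
instrument noise draw (a noisy mode exists separately in
`generate_noisy_feature()` for robustness studies). At `rel_uncertainty =
0` the band degenerates to exact equality; the true formula still survives
because its observed ratios are produced by the same deterministic
predictor, and any other survivor is a genuine exact ratio collision —
empirically we observe none, but the code treats uniqueness as an empirical
outcome, not an axiom.

Reported fractions are disjoint (strictly-fewer / equal / strictly-more sum
to 1), with per-100 Da mass-bin tables over 50–2000 Da by default. All
sampling is governed by a caller seed.

Problem sizes: the packaged analyses and tests use libraries of 300
formulae (60–300 for unit tests), which gives stable two-digit fractions
for the directional conclusions while keeping a full run in tens of
seconds; the same machinery scales linearly to the 10⁴–10⁵ masses a
database-wide study would use.

## Synthetic data: what it does and does not emulate

`generate_library()` samples atom counts uniformly per element inside the
box and rejection-filters to a mass band, optionally enforcing pairwise
mass uniqueness at a ppm threshold. This reproduces the *structural*
features the analysis depends on — unique in-range formulae with known
ground truth spanning a mass band — but **not** the empirical formula
distribution of a real compound database: real libraries are strongly
concentrated around carbon-rich, chemically stable compositions, while
uniform sampling fills the box evenly (and hence over-weights H-rich,
heteroatom-rich corners). Consequently the package's percentages
characterize the method on a synthetic population; directional conclusions
(SIL dominates above ~500 Da; zero-uncertainty ratios are uniquely
localizing; C/N counts never reduce the unique fraction) transfer, exact
percentages do not.

`generate_pathway_db()` builds a compound/reaction/pathway graph with
controlled compound sharing and plants an exact number of formula-unique
pathways: each planted pathway receives a private compound with a globally
unique formula; every pathway-private compound of a non-planted pathway
gets a same-formula decoy compound attached to an orphan reaction, which
destroys formula uniqueness (the decoy is not pathway-unique) while leaving
metabolite uniqueness intact. Recovery of exactly the planted set is
therefore a sharp correctness check of the uniqueness analysis, including
its orphan-reaction exclusion clause. Non-CHNOPS compounds and
super-pathway aggregates are added at stated fractions to exercise the
ingest filters.

Intensity noise in `generate_noisy_feature()` is multiplicative uniform on
[−rel_error, +rel_error], chosen to match the bounded-relative-deviation
form of the ratio filter; a Gaussian option exists for sensitivity
analyses.

## Pathway uniqueness

A metabolite is pathway-unique iff it occurs in exactly one pathway and in
no reaction unlinked to any pathway; a formula is pathway-unique iff all
its bearer compounds are unique to the same pathway ("same formula" means
identical atom counts after canonicalization, so `H12C6O6` and `C6H12O6`
collide). Two consequences are asserted as invariants: a pathway with a
unique formula necessarily has a unique metabolite, and occurrence
histograms conserve the total metabolite count (metabolites occurring in no
pathway are excluded from the pathway histogram, mirroring how orphan
reactions are treated). Databases with an empty pathway map are supported
and degrade to reaction-level occurrence counting.

Ingest is deliberately database-agnostic: a small JSON schema or a TSV
trio, plus `read_compound_table()` for flat compound lists with mass
cross-checking. Parsing any specific BioCyc/KEGG flat-file dialect is out
of scope.

## Design notes and quirks

* **Folate and the N range.** The classic worked example, folate
  C19H19N7O6 (441.1397 Da), has 7 nitrogens — outside the standard N 0–6
  box. The worked example therefore enumerates with N opened to 0–9;
  everywhere else the default box stands. This is a real quirk of the
  standard ranges, not of the implementation: range boxes tight enough to
  be useful will exclude some real metabolites, which is the same
  trade-off the heuristic-filter discussion makes explicit.
* **Window convention.** The ppm tolerance is a half-width (±tol) relative
  to the target mass; generators differ on this and the choice is pinned
  and documented rather than configurable.
* **Degenerate inputs.** All-zero formulae are rejected; windows entirely
  above the box's maximum mass return empty sets (not errors); empty
  candidate sets pass through every filter unchanged.
* **Determinism.** Every stochastic entry point takes a seed and uses it
  via `withr::with_seed`, so reruns are byte-identical including CSV
  output; the provenance JSON records seed, configuration, package and
  isotope-table versions.

## Known limitations

* Uniform formula sampling (above) — percentages are
  population-dependent.
* Single-charge-free neutral masses only; adduct and charge handling, raw
  LC-MS feature detection, and retention-time or MS/MS evidence are out of
  scope.
* Isotopic fine structure is available only as the fine-binning mode of
  the pattern generator; the constraint analysis deliberately uses unit
  resolution.
* The heuristic filter emulates ratio/RDBE-style rules generically; it
  does not byte-replicate any specific released generator.
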