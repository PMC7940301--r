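---
title: "Methods: a calibrated seed-match screen for direct miRNA targets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a calibrated seed-match screen for direct miRNA targets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seedscreen)
```

## The screening model

A pSILAC overexpression experiment quantifies, for each protein `i`, a
heavy/medium intensity ratio `r_i` — the fold change in synthesis under a
miRNA mimic relative to a scrambled control. The screen combines two binary
pieces of evidence:

* **Downregulation**: `r_i <= c` for a cut-off `c`, boundary inclusive.
* **Sequence evidence**: the gene's 3'UTR contains a contiguous substring
  exactly complementary to a contiguous window of the miRNA seed of length
  at least `min_match` nucleotides.

A protein with both is classified *direct*; with only the first, *indirect*
(presumed downstream of direct targets); otherwise *unchanged*. Direct
candidates are ranked by summed MS intensity, the most robustly quantified
first, with deeper downregulation breaking ties, then gene name so output is
deterministic.

### The seed and its target k-mers

The seed is taken as mature positions 2–8 (1-based), the community
convention for the 7-nt seed. For a 7-nt seed the only contiguous windows of
length ≥ 6 are the full heptamer and its two 6-nt sub-windows, so the
scanner needs exactly three DNA k-mers: the reverse complement of the seed
(`complete7`) and of seed positions 1–6 (`partial6_5p`) and 2–7
(`partial6_3p`). A non-contiguous 6-of-7 match is **not** accepted:
"at least six matching nucleotides" is read as six *sequential* nucleotides,
consistent with complete sites being described as seven sequential
nucleotides. No A1-anchor, 8mer or context scoring is applied — the screen
is purely match-length based, which is what makes it auditable against an
exhaustive oracle.

### Scanning rules

Coordinates are 0-based half-open on the supplied UTR strand (UTRs are given
5'→3'; no strand arithmetic). All distinct start positions are reported,
including overlapping ones, but a 6-mer occurrence wholly contained in a
reported 7-mer occurrence is suppressed: every complete site contains both
partial k-mers, and without the rule each complete site would always count
as three sites. `N` bases never match; lower-case and `U` spellings are
normalized on input. For degenerate seeds whose two 6-mer k-mers are the
same string (e.g. homopolymers) a matching locus is reported once, classed
`partial6_5p` by convention. Matching is delegated to
`Biostrings::vmatchPattern` with `fixed = TRUE`; the test suite holds the
scanner to exact equality with an independent brute-force enumeration of
every substring.

### Cut-off calibration

The cut-off is not a free parameter: it is derived from an internal positive
control, a protein already validated as a target of the miRNA. The rule is
the one-decimal ceiling of the control's normalized ratio, capped at 1.0 —
a control at 0.773 yields 0.8. The rule is idempotent, and rejects a control
that is not downregulated (ratio ≥ 1) since such a control cannot calibrate
a downregulation screen. An explicit `cutoff` can be supplied instead; the
report records whether the value was derived or supplied.

### Ratio normalization

The upstream search engine's "normalized" ratios are accepted as-is
(`normalization = "none"`); for raw ratios, `median_log` divides all ratios
by the geometric-median factor so the median log ratio is zero. This encodes
the standard assumption that most of the proteome is unaffected by the
perturbation; it is a single global factor, so it preserves the ordering of
ratios and shifts the effective cut-off by the same factor for every
protein. Missing ratios are excluded from the statistic, kept in the output,
classified `unchanged` and flagged — never silently dropped — so that class
counts always reconcile with the input record count. Duplicate gene entries
keep the highest-intensity record, mirroring protein-group collapsing.

## What the simulator emulates

`simulate_experiment()` generates the statistical structure the screen
assumes, at the scale of a ~4569-protein screen:

| parameter | default | meaning |
|---|---|---|
| `n_proteins` | 4569 | quantified proteins (screen scale) |
| `frac_direct` | 0.01 | direct targets, seed sites planted |
| `frac_indirect` | 0.07 | repressed without sites |
| `direct_effect` | log2(0.7) | mean log2 ratio of direct genes |
| `indirect_effect` | log2(0.75) | mean log2 ratio of indirect genes |
| `noise_sd` | 0.1 | SD of log2 ratio noise (log-normal ratios) |
| `utr_length_range` | 200–2000 nt | uniform UTR lengths |
| `gc_content` | 0.5 | i.i.d. base composition |
| `planted_sites_per_direct` | 2 | complete sites inserted per direct gene |

The class fractions put roughly 8% of the proteome below the 0.8 cut-off,
echoing the regime of a real screen of this design; the effect sizes place
direct genes near the ratio range (0.7–0.8) where validated targets of this
kind of experiment are observed. Ratios are `2^(effect + N(0, noise_sd))` —
multiplicative log-normal noise, the standard error model for SILAC ratios;
the generator does not model peptide-level variance, missing-value
mechanisms correlated with intensity, isotope impurity, or ratio compression,
so passing recovery tests demonstrates the pipeline's logic, not performance
on real spectra. Sites are planted by substring replacement at non-overlapping
uniform positions (UTR length preserved), and chance complete sites in
non-planted UTRs are recorded by rescanning so false positives can be
audited. One global RNG stream makes outputs byte-identical for a given
`rng_seed`.

Under these conditions the attainable false-discovery proportion of the
screen is dictated by chance ≥ 6-nt matches: a random ~1 kb UTR has an
appreciable probability of containing one of the two 6-mers, so indirect
genes that pass the ratio cut-off and happen to carry a chance 6-mer are
declared direct. This is a property of the match-length-only design, not of
the implementation; the recovery tests check the observed FDP against the
closed-form expectation (normal tail probability of each class crossing the
cut-off, summed over genes carrying chance sites) rather than against an
aspirational constant. Raising `min_match` to 7 shrinks the direct set and
this error mode accordingly.

## Numerical and design choices

* **Analytic null for the scanner**: the expected number of occurrences of a
  fixed k-mer in a uniform i.i.d. sequence of length L is `(L−k+1)·4^−k`;
  Monte-Carlo means over random UTRs are required to agree within 3 standard
  errors.
* **Boundary inclusivity**: "0.8 or lower" is `<=`.
* **Tie-breaks** in ranking (ratio ascending, then gene name) are fixed so
  reruns are byte-identical.
* **Degenerate luciferase comparisons**: with zero pooled within-group
  variance the classic t statistic is undefined; the comparison returns
  p = 1 (equal means) or p = 0 with `degenerate_variance = TRUE` instead of
  erroring, because plate fixtures with identical wells are legitimate
  degenerate inputs.
* **Reporter normalization**: firefly/renilla per well, divided by the
  *mean* ratio of the reference group (means, not medians, because reporter
  data are conventionally summarized as mean ± SEM); the reference group is
  recorded in the output's metadata.
* **Problem sizes** in the shipped tests: oracle equivalence runs on 1000
  UTRs × 20 random seeds, the background-rate check on 10⁴ 300-nt UTRs, and
  recovery on 10 full-scale (n = 4569) replicates — sizes at which the
  binomial/Monte-Carlo standard errors are far below the tested tolerances.

## Interfaces

UTRs are read from multi-record FASTA (ID up to first whitespace = gene ID);
ratio tables from TSV with a configurable column map defaulting to
MaxQuant-style headers (`Ratio H/M normalized`, `Intensity`, `Gene names`),
with `REV__`/`CON__` rows dropped and counted. Sites export as TSV or BED6.
`run_full_screen()` writes candidates, sites, a JSON screen report and a
manifest (configuration snapshot, MD5 input digests, package version,
timestamp); `inst/cli/seedscreen.R` exposes `scan`, `screen`, `simulate`,
`evaluate` and `luciferase` subcommands over the same functions.

## Known limitations

* Match-length-only site calling: no pairing thermodynamics, conservation,
  context scores or 3'-supplementary pairing; 6-mer calls in particular are
  expected to include many non-functional sites.
* UTR annotation dependence: complete-site counts for a real gene depend on
  which UTR isoform is supplied; fetching UTRs is the user's responsibility.
* The simulator's i.i.d. UTR background understates the repeat structure and
  composition bias of real UTRs, so real chance-site rates will differ from
  the analytic null.
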