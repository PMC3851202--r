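---
title: "Methods: window statistics, conservation scoring and enrichment in phosmet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: window statistics, conservation scoring and enrichment in phosmet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phosmet)
```

## The question and the model

Methionine oxidation converts a hydrophobic side chain into a
hydrophilic one. If a Met residue sits inside the sequence window that
a kinase recognises around a Ser/Thr/Tyr phosphosite, oxidising it can
plausibly modulate phosphorylation — a crosstalk between two
posttranslational modifications. `phosmet` quantifies the sequence
preconditions for that crosstalk. Everything rests on one primitive:
the flanking window of a site, the 2k residues at signed offsets
−k…−1, +1…+k around position *p* (offset 0 is the site itself and is
never counted). The default k = 6 gives a 13-residue window, chosen
because most characterised phosphorylation motifs fit within 13
residues; `window_size_scan()` exposes the full k = 1…10 range so the
sensitivity of any proportion to the window length is visible.

Four window statistics are computed:

* **Met proximity**: a site "has Met" when at least one non-missing
  flank slot holds M. Proportions are tabulated per residue type and
  evidence class and compared between groups with a pooled
  two-proportion z-test.
* **Positional distribution**: per-offset occurrence percentages of a
  residue class, with per-offset denominators (below). A 2×12 table of
  Met/non-Met counts per offset feeds a Pearson χ² test of positional
  independence.
* **Composition**: percentages of the 20 standard residues over the
  proteome.
* **Hydropathy**: the arithmetic mean of Kyte-Doolittle values over
  the non-missing, non-ambiguous flank residues; the site itself is
  excluded, since its hydropathy is fixed by being S/T/Y.

### Amino-terminal discounting

Essentially every translated protein begins with Met, so windows of
sites near the N-terminus would count an initiator Met that says
nothing about Met availability inside a motif. The package therefore
discounts the residue at sequence position 1: it is never counted as
Met in composition, in Met-proximity, or in positional distributions
(`discount_nterm = TRUE` everywhere, switchable). The discount is
defined positionally — only position 1 is affected — so a Met at
position 2 still counts. Discounting can only remove counts, a
monotonicity the test suite asserts.

### Sites near termini

Sites closer than k residues to a terminus are kept, with the
out-of-range slots marked missing. Excluding them would silently bias
site counts against short proteins and N/C-terminal phosphorylation.
Consequences: Met-proximity denominators count sites, not slots;
positional percentages use per-offset denominators (the number of
sites whose position + d is inside the protein); and hydropathy is a
mean, not a sum, so truncated windows remain comparable. Whether a
published hydropathy aggregate is a mean or a sum is often
unspecified, so hydropathy scores here should be used comparatively,
not matched against external absolute values.

## Statistical procedures

All tests are computed locally, with no web services:

* **Two-proportion z-test**, pooled-variance form:
  z = (p̂₁ − p̂₂)/√(p̂(1 − p̂)(1/n₁ + 1/n₂)) with p̂ the pooled
  proportion; two-sided p from the standard normal. The pooled form is
  the standard choice under a null of equal proportions. When the
  pooled proportion is 0 or 1 there is no variability under the null;
  z is defined as 0 and p as 1.
* **Pearson χ² test of independence**, no continuity correction by
  default (counts in this application are large); a flag enables the
  Yates correction for 2×2 tables.
* **Hypergeometric enrichment**: exact upper tail P[X ≥ k], summed in
  log space (`lchoose`) for stability; one-sided because the question
  is enrichment, not depletion. The suite verifies it against direct
  summation for every valid configuration with N ≤ 25 and against an
  exhaustive enumeration of all C(20,5) draws.
* **Bonferroni correction**: adjusted p = min(1, m·p). The default m
  is the number of terms actually tested (those with k ≥ 1 in the
  test set), the convention of the common enrichment servers;
  `m_mode = "all"` uses every annotated term instead. Terms are tested
  jointly across the BP/MF/CC namespaces (a single m).
* **log₂ enrichment ratio** of test-set to background term
  proportions; `percent_increase()` converts it to a percentage
  (100·(2^r − 1), so r = 0.5 ↦ 41%).
* **Modification-state combinatorics**: `ptm_state_count(n, t)` =
  (t + 1)^n — each of n sites is unmodified or carries one of t
  modification types, giving 2ⁿ states for one type and 3ⁿ for two.

GO annotations are consumed as given, without ontology-graph ancestor
propagation; supply pre-propagated tables when rolled-up terms are
wanted. The background set defaults to all phosphoproteins (every
protein carrying a site), taken explicitly as an argument so other
universes can be substituted. The experimentally phosphorylated sites
remain part of the all-S/T/Y background (a superset comparison);
callers can subset if a disjoint background is preferred.

## Conservation scoring

Homolog information enters as a mapping table: per (query site, taxon)
one 13-character window aligned so its centre matches the query site,
the consumed product of an upstream profile search whose
coordinate-conversion conventions live with that tool. The query's own
taxon counts as one of the (up to 8) taxa, so a fully conserved Met
scores level 8. Gaps (`-`) count as neither Met nor V/I/L/F. When a
mapping lists several homologs for one taxon, the first row wins and
the rest are logged — best-hit selection belongs upstream.

The **conservation level** at a Met offset is the number of taxa whose
window holds M there; among the others, the **VILF fraction** measures
hydrophobic substitution. Scenario classification uses one threshold
(default 6 of 8, "high conservation"; the enrichment panels rerun at
≥ 7, 6, 5, 4):

| Met conserved (level ≥ T) | level + VILF ≥ T | centre S/T/Y in ≥ T taxa | scenario |
|---|---|---|---|
| yes | — | yes | regulatory candidate |
| no | yes | yes | structural hydrophobic |
| yes/partly | — | no | site not conserved |
| no | no | yes | Met not conserved |
| no | no | no | neither conserved |

A regulatory candidate is a site where evolution kept both partners of
the putative switch; a structural hydrophobic is one where any bulky
hydrophobic suffices, arguing against a Met-specific role.
`toy_homolog_matcher()` is a deliberately naive ungapped 13-mer
scanner used only to exercise this machinery in tests; it is not a
substitute for a real homology search on real data.

## The synthetic-data generator

The generator exists so that every stage has inputs with known truth.
Defaults were chosen once, as plausible study conditions:

* **Proteome**: 300 proteins, negative-binomial lengths (mean 350,
  dispersion 4, floored at 30), i.i.d. residues from a composition
  table with Met at 2.4% and Ser/Leu/Ala high, Cys/His/Trp low — a
  qualitative, synthetic stand-in for typical proteome composition
  (the package ships no measured frequencies). Every sequence starts
  with M.
* **Phosphosites**: 1000 sites sampled from S/T/Y positions subject to
  non-overlapping windows (candidates overlapping an accepted window
  are skipped and logged), then each window edited — plant one Met or
  remove all countable Mets — so the Met-containing fraction is
  exactly Binomial(n, p) with p = 0.14 by default, the planted
  phospho-vs-background effect size. Edits never touch site centres or
  position 1, and non-overlap makes edit collisions impossible.
* **Homolog families**: 7 member taxa per Met-containing site; for
  each Met offset a level L is drawn (default uniform over 1…8 — a
  neutral choice that exercises every level; the query always carries
  its own Met, so L ≥ 1 by construction), L − 1 members get M, and
  members without it get V/I/L/F with probability 0.5. Centres stay
  S/T/Y with probability 0.9; other positions mutate at rate 0.1,
  never to Met.
* **GO annotations**: 20 terms, background frequency 0.1 each,
  independent coin flips; planted terms multiply that probability (by
  fold ≥ 1) in a designated subpopulation.

Determinism is strict: the seed is mandatory, each generator reseeds
from it (with a fixed per-stage offset so stages draw from distinct
streams), and reruns are byte-identical. What the generator does *not*
emulate: kinase motif grammars, phylogenetic structure among taxa,
correlated annotations, length/composition covariation. Passing
recovery tests therefore demonstrate that the pipeline measures what
was planted — not that real proteomes behave like the simulation.

## Problem sizes and numerical choices

The recovery analyses run at 5000 sites (Met-in-window probability,
tolerance ±1.5 percentage points ≈ 3 binomial SD), ~8000 families
(level proportions, ±0.011 ≈ 3 multinomial SD), 100 replicates of a
1000-protein enrichment (planted-term top-hit rate), and 1000 null
replicates for the family-wise error rate — sizes at which the 3-SD
bands are tight enough to be informative while the whole suite runs in
minutes on one core. Tie-breaks are deterministic throughout
(enrichment sorted by adjusted p then term id; the toy matcher takes
the first best hit in (protein id, position) order). Degenerate inputs
have defined behaviour rather than NaNs: empty flanks yield an NA
hydropathy, zero positional denominators an undefined percentage,
zero counts an undefined log₂ ratio with a warning, and a pooled
proportion of 0 or 1 a z of 0 with p = 1.

## Known limitations

* Sequence-only: no structure, surface accessibility, or measured
  oxidation propensity; a "regulatory candidate" is a sequence-level
  hypothesis.
* Isoforms are not collapsed — every FASTA entry is an independent
  protein, so proteins with many isoforms are over-weighted in
  protein-level counts.
* Enrichment inherits whatever propagation convention the annotation
  table embodies.
* The χ² and z approximations assume large counts; for the small site
  sets typical of bacteria and archaea, treat those p-values with
  caution.
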