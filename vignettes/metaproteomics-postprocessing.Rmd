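---
title: "Methods: metaproteomics post-processing in calculomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: metaproteomics post-processing in calculomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(calculomics)
```

## The problem

Shotgun metaproteomics of dental calculus identifies peptides against a
database that mixes host, microbial and dietary proteins spanning wildly
different database sizes and degradation states. Three consequences shape
this package: (i) false-discovery control behaves differently in the human,
bacterial and "other" portions of the search space, so FDR must be
stratified; (ii) protein inference is ambiguous across closely related
taxa, so quantities must be aggregated at a taxonomic rank that the
evidence actually supports (lowest common ancestor, usually genus);
(iii) aged proteins accumulate chemical damage — in particular spontaneous
deamidation of asparagine to aspartate — that erases exactly the sequence
differences on which some species identifications rest.

## Stratified accumulation FDR

Within each stratum, forward and reverse (decoy) hits are pooled and sorted
by identification score, descending. Writing $R(k)$ and $F(k)$ for the
reverse and forward counts in the top-$k$ prefix, the package accepts the
**longest** prefix with $R(k)/F(k) \le q$ (default $q = 0.01$). Three
conventions, each of which an implementation must fix explicitly:

* **Longest vs first crossing.** The ratio is not monotone in $k$ (it drops
  every time a run of forward hits follows a decoy), so "accept until $q$
  has accumulated" is ambiguous. We take the longest qualifying prefix,
  which maximizes identifications at the controlled level and matches
  target-decoy practice. A prefix may therefore resume qualifying after a
  locally failing stretch.
* **Tie blocks.** Records sharing the boundary score enter or leave
  together, and a block is admitted only if the ratio including the whole
  block qualifies. This keeps the cutoff a pure score threshold — no
  secondary sort key is invented.
* **Degenerate ratios.** $0/0$ counts as 0 (an empty prefix qualifies
  trivially); a prefix with reverse hits but no forward hits never
  qualifies. All-decoy input yields zero accepted records, not an error.

The estimated FDR reported at the cutoff is $R/F$ of the accepted prefix;
it is $\le q$ by construction whenever anything is accepted. What the
estimate tracks in truth depends on the usual target-decoy assumption that
incorrect forward matches score like decoys; the generator builds that
assumption in (below), and a property test confirms the realized
false-accept fraction is of the order of $q$.

## QC filters and protein-group mapping

The filter chain is order-sensitive and the order is pinned by a test:
peptides whose leading razor protein is a decoy *and* whose `Proteins`
cell is valid are dropped **before** groups are mapped, otherwise a decoy
leading razor could rescue a group. Group-level filters:

* **Mapping**: keep a group iff some surviving leading-razor accession is a
  member of its protein IDs.
* **Minimum evidence**: "fewer than two razor + unique peptides per raw
  file" is read per raw file — the LFQ value of an under-supported raw file
  is masked to missing, and only groups masked everywhere are removed.
  The stricter whole-group reading (any raw file below threshold removes
  the group) is available via `whole_group = TRUE`; the masking default
  preserves per-sample quantitation in the samples that do have evidence.
* **Exclusions**: contaminant- and decoy-flagged groups, plus
  case-insensitive annotation substrings (default `collagen`, `keratin` —
  skeletal-matrix and skin proteins that would otherwise dominate calculus
  samples while carrying no microbiome signal).

All filters are idempotent, and retained groups shrink monotonically in the
evidence threshold; both properties are tested.

## Lowest common ancestor

For each group we select, among its majority protein IDs, the accessions
with the most peptide associations (a peptide is associated with every
accession in its `Proteins` list — the razor-only alternative is not used
because the razor choice is itself parsimony-driven and would hide genuine
ambiguity). Ties keep all maximal accessions. Their lineages are
intersected as sets of `(rank, taxon)` pairs — pairs, not bare names, so a
homonymous taxon at two ranks cannot create a false intersection — and the
deepest shared pair is the LCA. An empty intersection (possible only across
superkingdoms) yields `unassigned`.

The rank ladder is `superkingdom … species` with `parvorder` admitted
between order and family solely to house the primate override: assignments
landing on Catarrhini, and "other"-stratum groups containing a human
accession, are coerced to *Homo sapiens* at species rank. This reflects
how host peptides in ancient samples are shared with ape homologs from a
general-purpose protein database.

Unassigned-at-genus bacterial groups stay in the pipeline: they count in
the denominator of genus fractions but never in a numerator, so fractions
plus the unassigned remainder sum to exactly 1 (tested to $10^{-9}$).

## Quantitation and statistics

Genus fractions divide genus-summed LFQ by total bacterial LFQ per sample;
species-level assignments roll up to their genus (a species assignment
implies its genus — the rolled-up reading keeps the genus table consistent
with the species table produced by the same operation at `rank =
"species"`). Missing LFQ cells contribute nothing to sums but count as
missing for the presence filter and normalization — missingness means "not
quantified", and treating it as 0 would corrupt both fractions and medians.

For clustering, entries observed in at least `ceiling(n/2)` samples (11 of
22 at the default design; `ceil` is the stricter reading of "minimum half"
for odd $n$) are log2-transformed, median-centred per sample, and compared
by Pearson correlation distance $d = 1 - r$ over pairwise-present entries
with average linkage (the distance is the documented choice; linkage is
configurable). Sample pairs sharing fewer than 3 entries cannot support a
correlation; they are flagged and imputed at the maximum observed distance
rather than silently dropped.

The differential test is a two-tailed two-sample t-test per genus on log2
fractions (pooled variance by default, Welch by option), adjusted by
Benjamini–Hochberg across tested genera at $\alpha = 0.05$. BH is our
stand-in for an unspecified volcano significance curve; it is the most
common default and its calibration is itself checked by a null simulation.
Zero fractions become missing rather than receiving a pseudo-count —
fabricating $-\infty$ offsets would manufacture significance — and a genus
needs two present values per group to be tested; genera failing that are
reported untested rather than silently dropped.

Bray–Curtis dissimilarity is computed (via `vegan`) on percent abundances
multiplied by $10^6$ with decimals truncated toward zero — truncation, not
rounding, is the documented convention, and the integer scaling makes the
percent tables a valid count-like input.

## The synthetic-data generator

`simulate_dataset()` emulates the statistical structure the analysis
assumes, with full ground truth:

* **Design**: 16 vs 6 samples, matching the two archaeological groups the
  statistics are built for.
* **Community**: 14 genera with baseline fractions and log2 group effects
  mirroring a dysbiotic vs commensal oral community (periopathogens up in
  group 1, commensals in group 2, *Actinomyces* dominant and neutral).
  Per sample, log2 baselines are shifted by half the effect with the
  group's sign and renormalized; stochastic variation enters at the protein
  level (lognormal LFQ noise, log2 sd 0.8; completely-at-random missingness
  at 15%), not as an extra genus-level noise term — an optional
  `bio_log2_sd` extension adds one, off by default.
* **Identifications**: per stratum (3000/1500/1000 PSMs — uneven and
  bacteria-dominated), a 20% decoy share with decoy scores drawn from
  N(40, 10) and true-target scores from N(80, 15); one false forward match
  per decoy, drawn from the decoy distribution — the target-decoy symmetry
  assumption made explicit.
* **Taxonomy**: 10% of bacterial accessions have lineages truncated above
  genus, reproducing a ~90% genus-level assignment rate; a small primate /
  dietary / archaeal cast exercises the override and stratum logic.

What passing tests show — and what they do not. The generator's noise is
homoscedastic on the log scale, missingness is random, and decoys are
exchangeable with false targets by construction. Real calculus data violate
all three in degree (intensity-dependent missingness, genus-specific
variances, database-composition effects), so green tests demonstrate the
*algorithms* are correct under the stated model, not that the model
captures every property of archaeological samples.

## Synthetic dietary references

The shipped beta-lactoglobulin FASTA is a constructed stand-in, not a
database sequence set, and is labelled synthetic in its filename, headers
and documentation. It preserves the decision structure of the real bovine /
caprine / ovine comparison: an N/D polymorphism inside the
`PTPEGDLEILLQK` marker peptide (bovine D, caprine/ovine N) that
deamidation renders uninformative, and three further discriminating
tryptic peptide loci whose substitutions avoid N/D/Q/E entirely. The
marker peptide is placed at the mature N-terminus because, under the
classical trypsin rule (no cleavage before proline), a proline-initial
peptide can only be released at a terminus; `tryptic_digest()` also
offers `proline_rule = FALSE` for search engines that cleave regardless.
Peptide length reporting bounds (7–30 residues) reflect a typical LC–MS/MS
detectability window and are applied after the uniqueness logic so the
logic itself is length-agnostic.

## Problem sizes and numerical conventions

The test-suite and acceptance computations use datasets of roughly 5,500
PSMs, 140 protein groups and 22 samples per simulation — 20 seeds for FDR
control and clustering recovery, 50 for spike detection, 20 × 60 genera
for the type-I null — sizes the package's audience can rerun casually on a
laptop. Numerical conventions collected in one place: FDR ratio 0/0 → 0;
tie blocks move together; `ceiling(n/2)` presence threshold; correlation
on pairwise-complete entries with max-distance imputation below 3 shared
entries; no pseudo-counts anywhere; truncation (not rounding) in the
percent-to-count scaling; all randomness seeded through the simulation
config.

## Limitations

The package consumes the search engine's razor/unique assignments and LFQ
values as given — it does not re-run protein inference or re-normalize
intensities across runs. Lineages come from a user-supplied table, not a
taxonomy dump. Peptide-level FDR only (no posterior error probabilities,
no protein-level FDR). The dietary classifier operates on exact tryptic
peptides with an N↔D (optionally Q↔E) equivalence; it does not model
partial deamidation, other modifications, or spectrum-level evidence.
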