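---
title: "ERV antigen discovery: models, parameters and design choices"
author: "ervantigen maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ERV antigen discovery: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ervantigen)
```

# The problem

Clear cell renal cell carcinoma (ccRCC) almost universally loses pVHL, which
stabilizes the transcription factor HIF2α and constitutively activates the
hypoxia response. Among HIF2α's targets are endogenous retroviruses (ERVs) —
germline-integrated proviral sequences, a subset of which remain intact
enough to be transcribed, translated and presented as HLA class I peptides.
Such peptides are attractive tumor antigens: they are absent from normal
tissue (where the ERVs are silenced) and not subject to central tolerance.

Finding them computationally requires five linked analyses, each implemented
as a module of this package:

1. **ERV expression quantification** from reads that fail to map to the host
   transcriptome (`quantify_ervs()` and friends);
2. **HIF2 responsiveness calling** across isogenic high-vs-low HIF2
   comparisons, with candidate tiering (`call_responsive()`,
   `tier_and_union()`);
3. **peak-to-ERV proximity** against HIF2α ChIP binding sites
   (`annotate_peak_proximity()`);
4. **six-frame proteogenomic search-space construction** and
   peptide-to-source resolution (`six_frame_orfs()`, `build_search_db()`,
   `map_peptide_sources()`);
5. **immunopeptidomics PSM filtering**: target-decoy FDR, fixed score
   thresholds, three-metric strike classification and the terminal peptide
   filter chain (`estimate_fdr_threshold()`, `apply_fixed_thresholds()`,
   `strike_classify()`, `finalize_peptide_calls()`).

A sixth module (`sim_config()` and the `simulate_*()` generators) fabricates
ground-truthed inputs for all of the above, so the whole pipeline is testable
offline; `run_discovery()` chains everything and emits an audited report.

# Expression model

## Read retention

Only reads that fail to align to the host transcriptome are considered ERV
evidence. A read pair is retained when both mates hit a *common* ERV with
zero mismatches (PM) or with at most one mismatch summed across both mates
(1MM). A lone read is retained when it (i) perfectly matches an ERV, (ii) is
not part of a retained pair, and (iii) has no transcriptome match. "At most
one mismatch across both reads" is read here as a fragment-level budget
against a shared reference; a per-mate reading would also admit (1,1)
fragments, which the phrase "across both reads" argues against. Retained
fragments are deduplicated on the key *(ERV, leftmost fragment coordinate,
orientation)*, first record wins — a stand-in for coordinate-based duplicate
marking; the key is not stated by the upstream method and is therefore a
declared convention here.

## Counting and normalization

Raw expression is `2 × (PM + 1MM pairs) + single ends`: a retained pair
contributes two reads of evidence, a single end one. Normalization follows
the reads-per-kilobase-per-million convention,

$$\mathrm{norm} = \frac{\mathrm{raw}}{\mathrm{library\ size}/10^6 \cdot
\mathrm{ERV\ length}/10^3},$$

the upstream description names both normalizations without constants; RPKM
constants are chosen for familiarity. `library_size` should be the total
sequencing depth of the sample. In the synthetic world we pass a fixed
`library_size = 1e6`: simulated libraries contain only ERV fragments plus a
proportional background, so letting depth track ERV output would
compositionally damp every planted fold change, whereas real libraries are
dominated by host transcripts and their depth is effectively independent of
ERV expression.

## Multi-mapping

ERV families are highly homologous, so one fragment frequently matches many
catalog entries. The default policy counts a fragment toward **every** ERV it
matches at its achieved category (the retention rule says "at least one ERV"
and quantification is per-ERV downstream); `multimap = "first"` switches to
first-best. The package's own audit trail records which policy ran.

## Responsiveness and tiering

The upstream work never states its numeric per-comparison criterion for
"scored as HIF2α-dependent". The default rule here is declared, configurable,
and deliberately simple:

$$\log_2\mathrm{FC} = \log_2\frac{\bar{x}_\mathrm{high} + c}{\bar{x}_\mathrm{low} + c},
\qquad c = 1,$$

responsive iff log2FC ≥ 1 **and** the high-arm mean is ≥ 1 normalized unit
(the floor blocks near-zero ERVs from being called on ratio alone). Both
constants are exposed (`pseudocount`, `min_expr`, `log2fc_min`). Tiering then
counts, per cell line, how many of the three isogenic comparisons an ERV
scored in (`all_three` / `two_of_three` / `fewer`); an ERV is a candidate
when it reaches two of three or is polysome-responsive (translated,
pVHL-suppressible), and the cross-cell-line union is non-redundant with
provenance retained. On simulation with planted four-fold effects and two
replicates per arm, over 90% of planted-responsive ERVs reach
`two_of_three` under this rule (tested).

# Interval conventions

All interval I/O is BED-style 0-based half-open. Overlap is
`max(starts) < min(ends)`; peak extension by 1/5/10 kb precedes
intersection, so proximity is measured peak-edge to ERV-edge (the
extend-then-intersect procedure implies edge-to-edge; summit-to-edge is a
plausible alternative the data do not distinguish). The distance between
disjoint intervals is the gap in bases **plus one**: touching half-open
intervals have distance 1, not overlap, keeping the half-open algebra
consistent. Ties in nearest-peak distance resolve to the lexicographically
smallest peak id so output is deterministic. Minus-strand ERV sequences are
reverse-complemented on extraction; six-frame translation makes orientation
immaterial to the final ORF set, but the convention is fixed for
reproducibility.

# Search-space construction

Six-frame translation uses the standard genetic code, splits each frame at
stop codons, drops trailing partial codons and keeps stretches of at least 7
residues with no methionine-start requirement — short retroviral ORFs are
real antigen sources and an 80-residue floor (as some ERV protein databases
impose) would discard them. Codons containing N translate to `X`; `X` never
terminates an ORF but can never match a standard-residue peptide query, a
conservative choice that avoids phantom peptide hits.

ERV ORFs are appended to the reference proteome (plus optional contaminants)
with accessions `ERV|<erv_id>|<frame>|<aa_offset>`. Exact duplicate
sequences within a class collapse to one entry, first accession wins, and
the collapsed entry's description lists every contributing accession — this
is what lets a single detected peptide report all 2–128 homologous ERVs it
could derive from.

Unique 9-mer accounting collapses I/L (isobaric, indistinguishable by
fragment mass) and attributes each shared 9-mer to exactly one class by the
priority *reference > contaminant > ERV*, mirroring the downstream
elimination of any peptide that also maps to the reference proteome. The
same I/L collapse governs `map_peptide_sources()`, so a peptide differing
from a reference substring only by I↔L substitutions is *not* ERV-exclusive.

# PSM filtering

## Target-decoy FDR

$$\widehat{\mathrm{FDR}}(s) = \frac{\#\{\mathrm{decoys} \ge s\}}
{\max(1, \#\{\mathrm{targets} \ge s\})},$$

cutoff = the smallest score with estimate ≤ 1%; a PSM's q-value is the
minimum estimate over all thresholds that would accept it, which makes
q-values non-increasing in score and nested across levels. With
`scope = "run"` the estimator runs within each LC-MS/MS run first and the
aggregate check applies on top. Decoys arrive as flagged rows; decoy
*generation* lives in the simulator, since real search engines generate
decoys internally. With no decoys present the cutoff falls back to the
minimum target score with a warning (estimate 0). On simulated mixtures with
known correctness labels the realized false-discovery proportion at the 1%
cutoff matches the nominal level up to sampling noise; the mean over 50
seeds sits within two binomial standard errors of 1% (tested; the estimator
is unbiased only up to the slight selection effect of choosing the cutoff
where the decoy ratio just dips under the level).

## Fixed thresholds and strikes

The subset-specific fixed thresholds are inclusive: engine score ≥ 7, scored
peak intensity ≥ 50%, backbone cleavage score ≥ 5, charge 1–4, length 8–11.
The three rescoring checks are: spectral angle (pass strictly **above**
0.6), retention-time deviation (pass within ±10 min, **inclusive**), HLA
percentile rank (pass strictly **below** 2.0). Verdict: 0 strikes pass, 1
maybe, ≥2 fail. Note the deliberate boundary asymmetry: a rank of exactly
2.0 earns a strike yet is still a *weak binder* by the printed category
brackets (strong < 0.5 ≤ weak ≤ 2 < non); both readings are faithful to
their respective sentences and are kept side by side.

The spectral angle is the normalized spectral-contrast angle
$1 - \tfrac{2}{\pi}\arccos(\langle a,b\rangle / \lVert a\rVert\lVert
b\rVert)$ on L2-normalized non-negative b/y intensity vectors aligned on the
union of ion labels (missing label = 0, both-zero input = 0). The exact
formula and any intensity pre-transform are unstated upstream; no
square-root transform is applied here, and the choice is recorded.

RT-predictor calibration selects, within each of 50 equal-width segments of
the observed RT range, the top 15 reference-proteome PSMs by engine score.
The spectrum-quality sequence tag length is the longest chain of peaks
successively separated by residue masses (edge count; pass requires > 1),
computed by longest-path dynamic programming over the peak ladder.

## The terminal peptide chain

`finalize_peptide_calls()` runs, in order, with a per-stage audit: drop
reference-proteome collisions (I/L-aware); drop peptides seen in any
normal-tissue sample; collapse exact duplicate calls; drop
cysteine-containing peptides (cysteine chemistry makes synthetic validation
unreliable); drop peptides whose best PSM verdict is fail. Cysteine
detection is on the unmodified sequence; carbamidomethylation is metadata.
Audit counts are non-increasing by construction and the stage order is
tested, not assumed.

# Signature correlation

Expression is transformed as `log2(x + 1)` and z-scored per feature with the
sample (n−1) standard deviation (log base and pseudocount are unstated
upstream; these are the declared choices). Zero-variance features become
zero rows with a warning rather than NaNs. A signature score is the mean of
its member z-rows per sample. Pearson correlations between each ERV and each
target (signature or single gene) get two-sided p-values and
Benjamini–Hochberg adjustment **within each target family** (one family per
target, across ERVs); zero-variance rows are flagged and excluded from the
family. One caveat discovered while testing: the step-up BH adjustment is
not idempotent (re-adjusting adjusted values can only move them up), so the
tests assert order preservation, adjusted ≥ raw, and the true re-adjustment
direction.

# The synthetic world

The generators plant the conditions the analysis is meant to detect, and
every record is traceable to a ground-truth entry:

* **Catalog** (`make_erv_catalog()`): `n_ervs` ERVs of 600 bp in
  `n_families` homologous families; each family shares an identical,
  stop-free, codon-aligned block covering 30% of the ERV by default, so
  block-derived peptides genuinely map to every family member. Strands are
  random; the genome carries the reverse complement for minus-strand
  entries.
* **Alignments** (`simulate_alignments()`): fragment counts are Poisson
  around planted abundances (lognormal baseline around 50 fragments/ERV,
  responsive ERVs ×4 in the high-HIF2 arm — the canonical "clearly
  responsive" effect size with 2 replicates per arm); each mate carries a
  Bernoulli(0.1) mismatch; 10% of fragments divert to the single-end
  pathway (the lost mate surfaces as a transcriptome-mapped record); 10%
  acquire a PCR duplicate sharing the fragment key; fragments wholly inside
  the family block multi-map to all members. Background transcriptome reads
  are added at 20% of fragment volume.
* **PSMs** (`simulate_psm_table()`): correct targets score N(12, 2),
  incorrect targets and decoys N(5, 2) — not a claim about real engines,
  just a separable mixture for calibration testing; the rescoring metrics
  are drawn so correct PSMs predominantly pass all three checks and
  incorrect ones fail most; 10% of peptides also appear in normal tissue.
* **Expression matrix** (`simulate_expression_matrix()`): a latent HIF
  activity per sample; signature genes and responsive ERVs load on it with
  planted correlation 0.8 over 100 samples; housekeeping genes are
  independent. Values are `2^(5 + 2z)`, strictly positive, so the planted
  structure survives the log/z-score transform nearly unattenuated.

What the generators do **not** emulate: sequence-level read errors and
quality strings, realistic fragment-length distributions, engine-specific
score shapes, shared retention-time drift between runs, allele-specific
binding-rank structure. A green test therefore establishes that the
*procedures* are implemented correctly against their stated contracts and
recover planted truth at realistic effect sizes — not that the pipeline's
operating characteristics on real spectra or real libraries match the
synthetic ones.

One master seed drives every generator through a documented derivation
(`seed + 1000003 × offset`, one offset per sub-generator), so stages can be
re-simulated independently and identical configs give byte-identical
outputs.

# Numerical and degenerate-input choices

* FDR with score ties: all tied PSMs share the most inclusive
  decoy/target counts.
* `spectral_angle()` clips the cosine into [−1, 1] before `acos` and the
  result into [0, 1]; both-zero spectra give 0, not NaN.
* `unique_kmer_contribution()` with k longer than every sequence returns
  zero counts (not an error); fractions are 0 in that case.
* Empty peak lists give sequence tag length 0; a single peak cannot form an
  edge.
* `log_zscore()` zero-variance rows: all-zero output with one summary
  warning.
* Interval distance for an ERV with no peak on its chromosome is NA, with
  relation `none`.

# Known limitations

* The per-comparison responsiveness rule is a stand-in; with real replicate
  structure a shrinkage-based test would be preferable, and the module
  boundaries accommodate swapping one in.
* Polysome responsiveness is consumed as a precomputed flag (or called with
  the same rule on polysome-fraction counts); polysome read processing is
  out of scope.
* The FDR module tightens fixed thresholds for the rare-class subset rather
  than re-estimating a decoy FDR within the subset — the upstream text
  supports threshold-tightening, and subset decoy counts would be too
  sparse at desk scale to estimate stably.
* SAM/BAM ingestion is by conversion to the simplified alignment TSV; the
  package does not run aligners or parse BAM directly.
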