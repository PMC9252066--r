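---
title: "Methods: gene-family characterization with aldhfam"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gene-family characterization with aldhfam}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aldhfam)
library(dplyr)
```

`aldhfam` implements the quantitative core of a genome-wide gene-family
survey for plant aldehyde dehydrogenases (ALDHs): nomenclature by identity
thresholds, active-site detection, duplicate classification and molecular
dating, two-species copy-number evolution, promoter cis-element counting,
expression summarization, and protein physicochemistry. This vignette
documents the models, the parameters that matter, the numerical
conventions, and what the synthetic-data tests do and do not demonstrate.

## Nomenclature by identity thresholds

The ALDH Gene Nomenclature Committee (AGNC) convention groups proteins
that are more than 40% identical to a previously named ALDH into that
protein's family, proteins more than 60% identical into its subfamily, and
treats anything at or below 40% as a novel family. `assign_family()`
realizes this with pairwise global alignment against a labelled reference
panel:

* Alignment is affine-gap Needleman–Wunsch (BLOSUM62, gap open 10,
  extend 0.5 — standard global-alignment defaults), delegated to
  `Biostrings::pairwiseAlignment()`, which gives a deterministic traceback.
  At the 40/60 decision boundaries the planted-identity tests are
  insensitive to small scoring changes.
* Percent identity divides identical columns by the **full alignment
  length including gap columns**. This is the conservative reading of
  "X% identical"; `percent_identity(..., denominator = "shorter")` offers
  the common alternative. The published criteria use "identical" and
  "similar" interchangeably; identity (not similarity with positive
  substitution scores) is implemented.
* Threshold comparisons are strict (`>`): a query at exactly 60.0% falls
  to the family tier, exactly 40.0% to novel. Ties in the best hit break
  by lowest family number, then lexicographic reference ID.
* Gene symbols number genes within each (family, subfamily) by chromosome
  and start coordinate, and letter splice variants a, b, c… by
  lexicographic transcript ID — lettering is by rank, not by the numeric
  suffix of the transcript ID (the sorghum inventory starts some loci at
  `.2`). Single-transcript genes carry no letter. Novel families get
  `ALDHnovelK` symbols with a running index; this branch is exercised only
  by synthetic data.

## PROSITE active-site scanning

The ALDH cysteine (PS00070) and glutamic-acid (PS00687) active sites are
detected with a full PROSITE-syntax engine: `-`-separated elements,
`[..]` allowed sets, `{..}` forbidden sets, `x` wildcards, `(n)`/`(n,m)`
repetitions and `<`/`>` anchors. Repetition ranges match greedily with
full backtracking, so `x(n,m)` admits every length in `[n, m]`; the test
suite checks equivalence against a brute-force matcher on random patterns.
A site is called present when the pattern matches at least once
(presence/absence semantics, matching yes/no inventory columns).

Ambiguity handling is conservative so that presence calls never rest on
ambiguous residues: `X` satisfies only wildcards, and `B`/`Z` satisfy only
sets that name them explicitly.

The shipped pattern strings (`inst/extdata/prosite_patterns.cfg`) are
editable configuration transcribed from the PROSITE entries; verify them
against the current release before scanning real proteomes. No test
depends on their fidelity — planted windows are sampled from the shipped
patterns themselves.

## Duplication classification, Ka/Ks and dating

A pair of homologous loci is **tandem** when both lie on one chromosome
with an inter-gene gap (end of the upstream gene to the start of the
downstream one; zero when the spans overlap) of at most `tandem_window`
(default 100 kb). All other homologous pairs are **segmental**. A
published alternative labels segmental duplicates by >90% sequence
identity, but that rule contradicts the very pairs it is meant to label
(a pair with Ks ≈ 1.56 is far below 90% CDS identity), so the
coordinate rule takes precedence and the 90% criterion survives only as
`strict_segmental = TRUE`.

`kaks()` implements Nei–Gojobori (1986): per-codon synonymous site
fractions (stop-creating mutations removed from both numerator and
per-position denominator, so each codon still contributes exactly three
sites), pathway-averaged synonymous/nonsynonymous differences (1, 2 or 6
orderings; pathways through stops dropped, with a documented fallback if
every pathway is excluded), proportions corrected by Jukes–Cantor
d = −(3/4)·ln(1 − 4p/3), undefined at saturation p ≥ 3/4. The codon
alignment is obtained by back-threading a protein alignment and dropping
gap columns. NG86 variants differ in stop handling; at the divergences
relevant here the effect is below reporting precision.

Dating uses T = Ks/(2λ). The workflow's stated default is
λ = 6.1 × 10⁻⁹ substitutions/site/year, but the published duplicate
table's times are consistent with λ = 1.5 × 10⁻⁸ (0.7719/(2·1.5e-8)·1e-6
= 25.73 Mya); both are available through
`pipeline_config(substitution_rate = )` and the discrepancy is documented
rather than resolved. Reported Ka, Ks and Ka/Ks are **truncated** (not
rounded) to four decimals and times to two, reproducing printed values
such as 0.1664/2.5295 → 0.0657. The 0/0 pair renders its ratio as "∞" and
its time as "Not determinable"; internally both are carried as undefined
(`NA`), and `divergence_time(0)` alone is 0 Mya.

Selection regimes follow Ka/Ks > 1 positive, < 1 purifying, = 1 (within
1e-9) neutral, undefined → undetermined.

## Two-species expansion accounting

Family trees in a two-species comparison reduce, for counting purposes, to
orthogroups: `build_orthogroups()` seeds clusters with reciprocal best
hits, attaches remaining genes to their best hit's cluster when identity
reaches the threshold (default 60%), and leaves the rest as singletons.
The most-recent-common-ancestor copy number is the orthogroup count — a
deterministic stand-in for reading ancestral nodes off a phylogeny that
reproduces every published scenario; "at least five ancestral genes" is
reported as equality, with the lower-bound nuance noted here. Losses per
lineage are clusters without that species; gains are extant genes beyond
one per occupied cluster; the identity extant = ancestral − losses + gains
holds by construction and is property-tested on random cluster sets. A
neighbor-joining utility (`nj_tree()`, via `ape::nj`) supports tree-based
workflows; on additive distances it provably recovers the generating
topology, which the tests confirm on random 5-taxon trees.

## Promoter cis-elements

Promoters are the `promoter_length` (default 1000 bp) bases 5′ of the
annotated feature start — the gene start by default, the CDS start when
that is the supplied anchor — reverse-complemented for minus-strand genes
and truncated with a warning at chromosome ends. Scanning is IUPAC-aware
exact matching on both strands with positions on forward promoter
coordinates; `N` in a promoter matches nothing. All overlapping matches
are reported, since the reference database's overlap policy is not
published. Whether promoter units are genes or transcripts is left to the
caller (both work); summaries report genes-with-≥1-occurrence per element
and totals/types per gene.

The shipped catalog (`inst/extdata/plantcare_catalog.tsv`) carries
PlantCARE-style consensi (ABRE `ACGTG`, G-box `CACGTG`, MBS `CAACTG`,
LTR `CCGAAA`, CGTCA-motif `CGTCA`, …) as editable configuration. Because
the database's matrices are not published, no real-promoter count is
treated as ground truth; validation uses planted motifs instead. Note the
catalog is not prefix-free — the ABRE core nests inside the G-box — so a
planted G-box necessarily also creates ABRE occurrences; the generators
and tests therefore plant from the non-nesting elements and count distinct
sites (a palindromic consensus hits both strands at one site).

## Expression and qPCR

`percent_of_max()` rescales each gene to percent of its own maximum — an
approximation to the "percent of expression potential" of commercial
expression atlases whose exact sample semantics are unpublished, which is
why no published per-gene percentage is an acceptance value. All-zero rows
are flagged rather than divided. A gene is "highly expressed" in a tissue
when it exceeds `high_expression_threshold` (default 60%, strictly) in at
least one of the tissue's samples. Heatmap ordering uses Manhattan
distance with average (UPGMA-style, unweighted mean pairwise) linkage; the
reference tool's exact linkage default is unstated, and ties resolve by
`stats::hclust`'s deterministic ordering.

`ddct_fold_change()` computes, per gene, ΔCt = Cq(target) − Cq(reference)
per replicate, ΔΔCt of each treated replicate against the mean control
ΔCt, and fold change 2^−ΔΔCt. Mean ± standard error are taken over the
per-replicate fold changes (not over ΔΔCt and then transformed), matching
the "mean ± SE" reporting convention.

## Synthetic data: what it shows and what it does not

Each generator is a pure function of its parameters and an explicit seed
(`withr::with_seed`; no global RNG state), so regeneration is
byte-identical:

* `simulate_family_panel()` plants queries at 85/50/25% identity by
  substituting exactly the corresponding number of positions
  (substitution-only; realized ungapped identity is exact). Family
  assignment recovers 100% of planted tiers across seeded replicates.
* `simulate_duplication_set()` plants synonymous changes at fourfold
  degenerate third positions and nonsynonymous changes elsewhere
  (stop-free by rejection), with tandem/segmental layouts. At 300 codons
  and ~3% divergence, recovered Ka and Ks sit within a few percent of the
  planted per-site rates — well inside the 25% acceptance band.
* `simulate_promoters()` scrubs backgrounds free of catalog matches by
  iterative point mutation, plants non-overlapping instantiated consensi,
  and verifies the realized site counts equal the plan exactly.
* `simulate_expression()` builds group-mean × gene-effect matrices with
  lognormal noise, and Cq tables whose Gaussian cycle noise (default
  σ = 0.1 cycles) is applied to the target Cq so that σ is directly the
  ΔCt standard deviation. Recovered mean fold changes at planted
  0.25/1/4 are within 15%.

These tests demonstrate algorithmic correctness under the stated noise
models. They do not emulate indels or codon-usage bias in coding
evolution, alignment uncertainty at low identity, promoter base
composition, amplification-efficiency deviations from 2.0 in qPCR, or
cross-platform normalization of expression matrices — conclusions about
real data still require the usual upstream quality control.

## Problem sizes, numerics and limitations

The bundled fixtures are the 34-transcript/19-gene inventory and the
six-pair duplicate table; property tests use random patterns of ≤ 6
elements on sequences of ≤ 30 residues, tiny alignments enumerated by
brute force, 300-codon duplicate pairs, 300-bp planted promoters, and
20–50 seeded replicates per recovery property — everything runs in a few
minutes on one CPU. pI bisection targets |net charge| < 1e-4 on pH
[0, 14] (the Bjellqvist charge function is strictly decreasing, so the
root is unique) and agrees with a 10⁶-point grid search to two decimals.
Mean aggregates round half away from zero at reporting precision
(224.11/34 → 6.59); a published summary transposes the pI and MW labels in
its prose, and the implementation reports each statistic under its correct
column. Known limitations: PROSITE profile (weight-matrix) entries are not
supported, Ka/Ks is NG86 only (no maximum-likelihood models), orthogroup
clustering assumes two species, and domain coordinates are accepted as
input rather than recomputed by HMM search.
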