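---
title: "Methods: from MAE peptide lists to HLA-resolved binding motifs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from MAE peptide lists to HLA-resolved binding motifs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(maepitope)
```

This vignette documents the models, parameter choices and numerical
conventions behind `maepitope`, in the spirit of a methods supplement: what
each stage assumes, which knobs matter, and what the simulation-based tests
do and do not establish about real data.

## The analytical model

Mild acid elution recovers whatever peptides are associated with the cell
surface: genuine MHC I ligands (9–11-mers with anchor residues at core
positions 2 and 9), genuine MHC II ligands (nested, ragged 12–20-mers
sharing a 9-mer binding core, anchors typically at core positions 1, 4, 6
and 9), and non-specific contaminants. The pipeline's premise is that three
orthogonal structures separate signal from noise without any antibody or
knockdown:

- **Reproducibility**: true ligands recur across biological replicates;
  we require a positive spectral count in at least `min_reps = 2` of
  `total_reps = 3` replicates, per cell line independently.
- **Peptide geometry**: MHC I ligands are short and unique; MHC II ligands
  come in nested sets. After condensing overlapping peptides into maximal
  epitopes, 9–11-mers are class I candidates, 12–20-mers class II
  candidates only if at least 3 distinct peptides compose them, and
  epitopes with total spectral count ≤ 2 or length ≤ 8 are rejected.
- **Genetics**: an epitope presented by allele *a* can appear only in cell
  lines carrying *a*. Across a related panel this turns each epitope's E_i
  presence profile into a fingerprint of its presenting allele.

### Abundance indices

P_i is a **zero-inclusive mean**: the summed spectral count over a cell
line's replicates divided by `total_reps`, with absent replicates
contributing zero. The alternative (dividing by the number of replicates
where the peptide was seen) would inflate sporadically detected peptides;
zero-inclusion keeps P_i comparable across detection rates and makes
E_i = Σ P_i exactly linear in counts. The conservation identity
Σ_e E_i(e, c) = Σ_p P_i(p, c) holds exactly for every cell line because
condensation partitions peptides.

### Clustering

Centroid linkage with the **correlation distance** (1 − Pearson) is the
default: E_i profiles should be compared by shape (which lines present the
epitope, and in what proportion), not magnitude, since per-allele expression
differs widely. Euclidean distance is available via `metric =`. Centroids
are re-derived as member means at every step, which can produce
non-monotone merge heights; this is the accepted behaviour of classic
centroid linkage and is preserved (Newick export writes the resulting
negative branch lengths as computed). Ties in the minimal distance are
broken by the lexicographically smallest pair of cluster representatives so
the dendrogram is independent of input order. Zero-variance profiles get
correlation distance 0 to identical vectors and 1 to everything else.

Node extraction keeps every internal vertex with 9–100 leaves, nested nodes
included. The same defaults are applied to MHC I, since no separate class I
band is established; both bounds are arguments of `extract_nodes()`.

### Gapless offset alignment

At MHC ligand lengths, a prohibitive gap-open penalty makes progressive
alignment effectively gapless, so the package models alignment as integer
offsets directly: no internal gaps, terminal overhangs unpenalized, width
capped at 12 (MHC I) or 30 (MHC II). The seed is the sequence with the
highest total E_i (tie: longest, then lexicographic); each next sequence
maximizes its BLOSUM62 profile score, with ties resolved toward the smaller
width, then the smaller offset. This makes behaviour exactly specifiable
and testable — the suite verifies on random core-sharing nodes that the
progressive result attains the exhaustive-search sum-of-pairs optimum in
≥ 95% of cases and never exceeds it. A sequence longer than the width cap
should have been filtered upstream and raises an error; in the pipeline,
over-cap sequences are dropped from the node with a warning rather than
truncated, so reported motifs only ever come from fully aligned sequences.

### Logo statistics and consensus calling

Per column, the information content is
`E = max(0, log2(20) − H − e_n)` with Shannon entropy `H` of the residue
frequencies and the standard small-sample correction
`e_n = 19 / (2·ln 2·N_n)`, which compensates the upward compositional bias
of small columns. `L`, the lower bound of the 95% interval of `E`, is
estimated by a 200-replicate seeded multinomial bootstrap (2.5th
percentile, floored at 0 and clamped to ≤ E so that R = E − L ≥ 0 always).
These choices are explicit and deterministic under a fixed `seed`.

Significance uses the strict comparison `S > R`; S is capped at 1.0 only
for grayscale shading (floored at 0.2), never for selection. Residues that
fail individually can pass as a physicochemical group
({A,V,L,I,M}, {F,W,Y}, {K,R,H}, {D,E}, {S,T,N,Q}, {C}, {G,P};
overridable) when the group's summed S exceeds R and no member passes
alone — these render lowercase, individually significant residues
uppercase. The top-4 summary selects the four (position, residue) entries
with highest S across the whole line (a per-line reading of the summary
convention; a per-position reading would be ambiguous when one column
dominates).

### Deconvolution

Binarization uses `E_i > 0` exactly; a positive `floor` is available for
noisy data. Alleles are matched individually — cis/trans pairing of MHC II
heterodimers is out of scope, which is one reason class II deconvolution is
intrinsically weaker. Co-segregating alleles (identical presence profiles,
unavoidable under whole-haplotype inheritance) are all returned, preserving
the ambiguity rather than guessing. Uniqueness for
`traceable_allele_count()` is computed across all loci by default (the
stricter criterion); `per_locus = TRUE` relaxes it.

## The synthetic family generator

`simulate_family()` draws each parent's two multi-locus haplotypes without
replacement per locus (parents may share alleles, as real consanguineous
panels do — without some sharing, every allele would co-segregate perfectly
with its haplotype partners and allele-level deconvolution would be
impossible even in principle) and transmits one complete haplotype per
parent per child, with no recombination, mirroring HLA's tight linkage.
With five children and at most four parental haplotype combinations, at
least two children always carry identical genotypes — which is exactly what
the cell-line dendrogram should detect.

`simulate_peptidome()` gives every allele a position-weight matrix with
distinct anchor residues (probability 0.8 at anchor positions, uniform
elsewhere), embeds each epitope in its own synthetic protein, emits 1–2
peptides per MHC I epitope and 3–6 nested peptides per MHC II epitope, and
draws spectral counts as Poisson(λ = 5) per replicate with 10% dropout.
Contaminants are uniform random peptides of 9–20 residues present in every
line, at 20% of all emitted peptide sequences by default — the share of
non-MHC material suggested by knockdown-based estimates of MAE specificity.
Defaults were chosen once as plausible study conditions: 12 epitopes per
allele keeps single-allele clusters above the 9-member node floor while
keeping the panel small; λ = 5 makes the 2-of-3 replicate rule nearly
lossless at zero dropout, so noise-free runs isolate algorithmic rather
than sampling behaviour.

What the generator does **not** emulate: a realistic proteome background and
shared source proteins (each epitope lives in its own protein, so
coordinate-mode condensation is never confronted with paralogous mappings),
intensity structure beyond Poisson counts, allele-specific expression
levels, MHC II cis/trans dimer specificity, and sequence-dependent
detectability biases. Passing the recovery tests therefore demonstrates the
correctness of the algorithms under the stated model, not the field
performance of MAE itself.

## Numerical conventions and degenerate inputs

- Coordinates are 1-based inclusive throughout; conversion happens only at
  the table boundary.
- A spectral count of 0 means "not observed in that replicate".
- String-mode condensation requires end overlaps of ≥ 5 residues
  (`min_overlap`); shorter accidental overlaps would glue unrelated
  peptides. Components whose overlaps cannot be reconciled into one
  superstring raise an error naming the component. Peptides mapping to
  several proteins are assigned to the lexicographically smallest
  accession, logged.
- Condensed spans longer than the class II upper bound are rejected with a
  warning (`retain_long = TRUE` keeps them as `"unclassified"`); the class
  II upper bound itself is an argument (`mhc2_range`).
- All-gap alignment columns are null; empty peptide tables halt the
  pipeline at condensation with an explanatory error.
- Every stochastic step (simulation, bootstrap, random peptides) takes an
  explicit seed and restores the caller's RNG state.

## Problem sizes

The test suite exercises: exhaustive merge-order search on 200 nested
components of ≤ 6 peptides (20 permutations each); brute-force centroid
agglomeration on 100 matrices of ≤ 6 rows; exhaustive offset-alignment
search on 200 nodes of ≤ 4 sequences; 1,000 random panels of ≤ 32 alleles
for traceability; and one full seven-line family (≈ 8,000 observations,
≈ 230 true epitopes) end to end. These sizes make the oracles exact while
keeping the default test run to a few minutes.

## Known limitations

Length-21+ condensed spans are rejected rather than re-segmented; I/L mass
degeneracy is not disambiguated; binder predictions are ingested, never
computed; and on a purely consanguineous panel most alleles are not
uniquely traceable — `trace_panel()` exists precisely to plan panel
extensions that fix this.
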