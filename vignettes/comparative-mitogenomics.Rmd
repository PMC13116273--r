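---
title: "Comparative mitogenome architecture with mitocomp: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative mitogenome architecture with mitocomp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitocomp)
```

## Scope and scientific background

Animal mitochondrial genomes are small circular chromosomes, typically
14--20 kb, encoding 13 protein-coding genes (PCGs), two rRNAs and up to 22
tRNAs. Comparative studies of such genomes revolve around four largely
independent signals, and `mitocomp` implements one analysis stage for each:

1. **Compositional strand asymmetry.** AT skew $(A-T)/(A+T)$ and GC skew
   $(G-C)/(G+C)$ measure the excess of one base over its complement on the
   stored strand. Windowed along the genome, GC skew forms a *landscape*
   whose qualitative shape (globally positive, globally negative, or
   partitioned into positive and negative segments --- "bimodal") reflects
   strand-specific mutational pressure and can differ between lineages.
2. **Gene-order rearrangement.** Gene orders are modeled as circular signed
   permutations of canonical labels. Rearrangement is quantified by the
   breakpoint distance on signed adjacencies, and an ancestral order is
   inferred by adjacency parsimony rooted with an outgroup.
3. **tRNA repertoire.** Velvet worms and several other invertebrate groups
   lose or truncate mitochondrial tRNAs; presence/absence against the
   canonical 22 and conservation of consecutive tRNA *clusters* within
   taxonomic groups summarize this signal.
4. **Synonymous codon usage.** Relative synonymous codon usage (RSCU) under
   the invertebrate mitochondrial genetic code (NCBI transl_table 5),
   compared across species by PCA, measures how conserved the mutational
   pressures at synonymous sites are.

Everything operates on one container, the `mitogenome`: a sequence, a
topology flag and a feature list in 0-based half-open coordinates, with
GenBank, FASTA and feature-table I/O converting at the boundary. A feature
that spans the origin of a circular genome is stored once with a `wraps`
flag, so gene-order analyses always see exactly one entry per gene.

## Conventions that matter

**Canonical vocabulary.** All analyses run on normalized labels: 13 PCGs
(ND1--ND6, ND4L, COX1--COX3, CYTB, ATP6, ATP8), `rrnL`/`rrnS`, and 22 tRNAs
with leucine split into `trnL1` (CUN codons) / `trnL2` (UUR) and serine into
`trnS1` (AGN) / `trnS2` (UCN). `normalize_label()` maps the common dialects
("COI", "cytochrome c oxidase subunit I", "tRNA-Leu(UUR)", "16S ribosomal
RNA", ...). The leucine/serine isoacceptors are disambiguated from an
explicit 1/2 suffix, an anticodon triplet, or a codon-family token; when
none is available the gene is labeled `trnL?`/`trnS?` and *excluded* from
presence scoring rather than guessed. Unknown labels are carried with a
warning but excluded from gene-order and RSCU computations.

**COX1 anchoring.** Cross-species comparability requires a common
orientation, so windowed skew profiles and displayed gene orders are
computed after re-orienting each circular genome to start at COX1 on the
plus strand (`anchor_genome()`); if COX1 lies on the minus strand the whole
genome is reverse-complemented first. Skew antisymmetry under reverse
complement makes the choice of stored strand otherwise arbitrary.

**Windows.** `sliding_window_profile()` defaults to a 300 bp window moving
in 50 bp steps. These values are configurable: 300 bp is wide enough to
damp per-window sampling noise in a ~23% GC genome (the standard deviation
of a window's GC skew under no bias is roughly $1/\sqrt{n_{GC}} \approx
0.12$) while still resolving gene-scale sign changes; 50 bp gives a
smooth landscape at ~290 windows per genome. Windows with no G or C are
recorded as missing, never as zero --- a zero would fabricate a sign.

**Regime classification.** Let $f$ be the fraction of sign-carrying
(defined, nonzero) windows with positive GC skew. The regime is globally
positive if $f \ge 0.75$, globally negative if $f \le 0.25$, bimodal
otherwise. The thresholds separate the qualitative classes "predominantly
positive", "globally negative" and "partitioned almost equally", and are
exposed as parameters; the wide gap between the classes realized by the
synthetic generator (empirically $f \approx 0.9$, $0.1$ and $0.5$) makes
classification insensitive to their exact values.

**Breakpoint distance.** Two circular signed orders over the same $n$ genes
are compared through their adjacency sets; the distance is
$n - |A_1 \cap A_2|$. The signed adjacency $(a \to b)$ is identified with
its reading-direction mirror $(-b \to -a)$, which makes the distance
invariant to rotation *and* reflection --- both arbitrary for a circular
molecule. A strand flip of a single gene therefore counts as rearrangement;
a strand-blind variant (`signed = FALSE`) is available because published
figures do not always state whether pure strand flips were counted.
Inversion, DCJ and common-interval distances are deliberately out of scope:
breakpoints are the simplest statistic that supports "identical vs derived"
statements, which is the level at which the underlying comparisons are made.

**Rearranged segments.** For display (the dashed boxes of published
gene-order figures), `rearranged_segments()` anchors both orders at COX1
and reports maximal runs of genes whose (label, sign) differs from the
reference at the same position. This positional definition returns exactly
the inverted block for a single internal inversion and all non-anchor genes
for a full shuffle, and is empty precisely when the anchored orders
coincide. Note that it is intentionally *not* identical to "genes flanked
by a broken adjacency": the interior of an inverted block keeps its
(reflection-identified) adjacencies yet is certainly rearranged, while the
two genes flanking the block each lose one adjacency yet sit at their
ancestral positions.

**Ancestral inference.** `infer_ancestral_order()` resolves adjacency
presence over the rooted ingroup tree Fitch-style (intersection of child
sets when nonempty, else union) and assembles the root set greedily into a
single circular tour, preferring adjacencies in the Fitch root set, then
those shared with the outgroup, then higher ingroup support, with
lexicographic tie-breaking. Assembly uses the standard gene-extremity
matching (each gene contributes a head and a tail; an adjacency joins two
extremities; premature cycles are rejected), which enforces orientation
consistency by construction. If no complete tour exists the outgroup order
is returned flagged `fallback = TRUE` rather than failing the pipeline.
With an outgroup carrying the true ancestral arrangement and a minority of
rearranged ingroup lineages --- the configuration the method is designed
for --- recovery is exact (this is verified over 100 simulated replicates
in the test suite).

**tRNA clusters.** A cluster is a maximal block of at least two consecutive
tRNAs (no intervening PCG/rRNA) occurring with identical internal order and
signs in every genome of a group; reflection-equivalent blocks are merged,
and an `ignore_strand` option relaxes sign matching since published cluster
descriptions do not always state strand conventions. Truncated tRNAs are
treated as present if annotated; truncation and editing are out of scope.

**RSCU.** For codon $j$ of amino-acid family $i$ with family size $n_i$ and
counts $x$: $\mathrm{RSCU}_j = x_j / (X_i / n_i)$. Stops (TAA/TAG) are
excluded; start codons are counted as their table-5 amino acid (ATG/ATA are
both methionine), avoiding fragile start-codon heuristics. Codons of
unobserved amino acids are missing, not zero, so every *observed* family
sums exactly to its size --- an identity the tests enforce on every genome.
The log10 heatmap view masks zeros and missing cells instead of
pseudocounting; PCA runs on raw RSCU with column-mean imputation, centered
but not variance-scaled (all columns live on the common RSCU scale), with
component signs fixed by forcing the largest-magnitude loading positive.
transl_table 5 ships as a data file (`inst/extdata/transl_table_5.tsv`) so
other codes could be added without code changes.

## The synthetic-genome generator

Real onychophoran-scale analyses require assembled, annotated genomes that
cannot be bundled; the generator (`synth_config()`, `generate_genomes()`,
`generate_two_family_dataset()`) produces annotated genomes whose *truth*
(regime, inversions, tRNA losses, codon profile) is recorded, so every
analysis stage can be validated by parameter recovery. Its defaults are the
study conditions it emulates: ~14.4--14.9 kb circular genomes (emergent
from template gene lengths sampled within ±10%), A+T content 0.77, GC-skew
amplitude 0.15, and the 37-gene ancestral arthropod arrangement (the
*Limulus polyphemus* ground pattern, shipped as a documented fixture) as
the ancestral template.

Two design points deserve explanation:

* **Skew is imposed through sampling probabilities, never post-hoc
  editing**, so reading frames stay valid. Non-coding regions draw bases
  with $p_G : p_C = (1+s) : (1-s)$. Coding regions cannot be skewed that
  way without destroying codon-usage truth, so the regime instead tilts the
  *amino-acid* weights: weights are multiplied by
  $\exp(t\,\delta_{aa})$, where $\delta_{aa}$ is the expected per-codon
  $G-C$ of that amino acid under the codon profile, and $t$ is solved
  numerically (by `uniroot`) so the expected CDS skew equals the target
  amplitude. Because within-family synonymous codon probabilities are
  untouched, RSCU expectations are exactly preserved; because CDSs cover
  ~75% of the genome, this is what makes window-level regime recovery
  possible at all. The residual is absorbed by solving the non-coding
  skew per regime half so the whole-genome (or per-half) skew hits the
  target. Minus-strand genes flip the sign of their target, since their
  reverse complement is what lands on the major strand.
* **Bimodal regimes** assign $+s$ to genes and spacers whose midpoint falls
  in the first half of the laid-out genome and $-s$ to the second half,
  emulating landscapes partitioned into two contiguous segments.

The default codon profile weights each codon by the product of per-base
preferences (A 0.45, T 0.40, G 0.09, C 0.06) normalized within families;
this reproduces the two hallmarks of invertebrate mitochondrial codon
usage --- A/T-ending codons over-represented in essentially every family,
and A+T-rich coding sequences --- while remaining a pure within-family
(hence RSCU-defining) object. Default amino-acid weights favor the
hydrophobic, A/T-codon residues (Leu, Ile, Phe, Ser...) typical of
mitochondrial membrane proteins, landing whole-genome GC near 23%.

The two-family dataset encodes a family-level contrast: family A shares a
fixed two-inversion derived gene order, a globally positive regime and a
reduced (14-tRNA) complement; family B keeps the ancestral order, a bimodal
regime and 20 tRNAs; a single outgroup keeps the ancestral order with a
globally negative regime --- the configuration needed to demonstrate
outgroup-rooted ancestral reconstruction and group-exclusive clusters.

What the generator does **not** emulate: substitution processes along a
tree (genomes are independent draws, so phylogenetic covariance is absent),
tRNA truncation/editing, duplicated genes, and control-region repeats.
Passing recovery tests therefore demonstrates correctness of the analysis
machinery under the stated statistical structure, not robustness to every
messiness of real annotations.

Determinism is a contract: each genome's RNG stream is derived from
`(seed, genome_index)`, and identical configurations reproduce
byte-identical GenBank output.

## Numerical and degenerate-input choices

* Skews with a zero denominator return `NA` with a warning (whole-genome
  and per-window alike); regime classification errors only if *every*
  window is undefined.
* `extract_cds()` trims 1--2 trailing bases of incomplete stop codons and
  rejects CDSs shorter than 6 bases after trimming.
* Breakpoint comparisons require identical label sets and report the
  symmetric difference otherwise; duplicated labels are rejected at order
  construction.
* PCA with identical rows returns all-zero scores and zero explained
  variance (not an error); fewer than 3 rows is an error.
* Report TSVs print numerics with 4 decimal places --- wider than the 2--3
  used in typical summary tables, so round trips through files lose nothing
  at the precision the pipeline reports.

## Problem sizes used in validation

The shipped validation suite exercises the pipeline at the scale the
methods are designed for: single-genome operations on ~14.7 kb genomes;
regime recovery over 200 genomes per regime at window 300 / step 50;
breakpoint-distance equivalence against a brute-force positional oracle on
all signed circular permutations of 4--5 genes and 500 random 13-gene
permutation pairs, plus 10,000 inversion-bound trials; ancestral recovery
over 100 replicates of a 5-ingroup configuration with at most 2 rearranged
lineages; and PCA separation of two planted codon-bias profiles over 10
genomes each. All of these run from fixed seeds.

## Known limitations

* Duplicated genes are not modeled; orders with repeated labels are
  rejected rather than resolved.
* The ancestral assembler is greedy; with heavily conflicting ingroup
  signal and an uninformative outgroup it may fall back to the outgroup
  order (flagged) rather than search exhaustively.
* Only transl_table 5 is supported, matching the analysis domain.
* Linear genomes are supported throughout but never rotated, so profiles
  of unanchorable linear genomes are only comparable if digitized from a
  common convention.
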