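---
title: "Discovering podocyte-enriched lncRNAs: models and methods"
author: "podlnc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering podocyte-enriched lncRNAs: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(podlnc)
```

## The problem

Focal-segmental glomerulosclerosis (FSGS) is a podocytopathy: injury to the
post-mitotic epithelial cells of the glomerular filtration barrier leads to
proteinuria and scarring. Most transcriptomic work in this field has focused
on protein-coding genes, yet the majority of transcripts are non-coding, and
long non-coding RNAs (lncRNAs, transcripts of at least 200 nt without
protein-coding capacity) are strongly tissue- and context-specific. Finding
lncRNA candidates worth following up experimentally requires a chain of
evidence that coding-gene pipelines do not provide: a defensible exclusion
of coding potential, a measure of cell-type specificity across renal
compartments, conservation evidence that works for poorly conserved
transcripts, dysregulation across several disease models, and an independent
single-cell confirmation.

`podlnc` implements that chain downstream of read alignment and transcript
assembly. Its inputs are the standard interchange artifacts of such a
workflow: GTF annotations (a reference and an assembled set), transcript
FASTA, per-sample FPKM/TPM tables with compartment labels, BLAST tabular
(outfmt-6) homology and alignment tables, per-locus count matrices, and a
10x-style MTX triplet for single-cell data. Read QC, mapping, assembly and
Cell Ranger processing are out of scope by design.

## Known versus novel transcripts

An assembled multi-exon transcript is *known* if some reference transcript
on the same chromosome and strand has an identical **intron chain** — the
ordered set of intron intervals. Terminal exon boundaries are deliberately
ignored: assemblers place 5'/3' ends with much less precision than splice
junctions, so end jitter must never flip a label (a property test asserts
exactly this). Mono-exonic transcripts have no introns, so they are matched
by reciprocal overlap: a same-strand mono-exonic reference transcript must
cover at least 50% of each transcript's length. The 50% reciprocal rule is
this package's choice, in the spirit of the merge tools commonly used for
assembly comparison; it is symmetric and therefore cannot call a short
fragment "known" against a much longer reference model or vice versa.

Coordinates are 1-based closed everywhere, the native convention of GTF and
of the Bioconductor ranges stack this package is built on; converting to a
different internal convention would buy nothing in R and create boundary
bugs at every I/O edge.

## Candidate selection and coding potential

Candidates must have spliced length ≥ 200 nt and reach ≥ 1 FPKM in at least
one sample (both cutoffs inclusive). The coding-potential filter then works
on the transcript sequence:

1. **ORF discovery.** All ATG-initiated open reading frames in the three
   forward frames with at least 50 codons, reported with completeness
   status; an ORF that reaches the 3' end without a stop is kept as
   incomplete. When a downstream in-frame ATG shares the stop of an
   enclosing ORF, only the longest (outermost) ORF is reported. Codons
   containing N never match start or stop. The scanner is verified exactly
   against an independent brute-force scanner on hundreds of random
   sequences.

2. **Dynamic ORF-length cutoff.** A fixed ORF-length threshold misbehaves
   because long transcripts contain long chance ORFs. The cutoff used here
   is the smallest $n \ge 50$ such that the expected number of chance ORFs
   of $\ge n$ codons in an i.i.d. random sequence of the transcript's
   length $L$ falls below $\alpha = 0.05$:
   $$E(n, L) = \max(0, L - 3n)\; p_{\text{ATG}}\; (1 - p_{\text{stop}})^{n-1},$$
   with codon probabilities taken from the base composition. $E$ is an
   exact expectation (linearity over start positions), so the cutoff is a
   union-bound style control of chance ORFs and is monotone in $L$.
   One property is worth stating precisely: qualifying start positions
   cluster (nested in-frame ATGs inside one long stop-free run), so
   $P(\text{longest ORF} \ge n) < E(n, L)$ and the cutoff sits a handful of
   codons *above* the Monte-Carlo 95th percentile of the longest chance ORF
   (5–8 codons for $L$ between 500 and 5000 under uniform composition; the
   package's tests measure this). The expected-count form was retained
   deliberately: it errs on the conservative side — it never under-calls
   chance ORFs — and it has a closed form that is independently checkable.

3. **Scoring.** The longest complete ORF is scored with an in-frame hexamer
   log-odds model (coding vs background composition, pseudocounts applied)
   and a start-codon position-specific scoring matrix over offsets −6..+4
   around the ATG. The composite verdict is *coding* iff the longest
   complete ORF reaches the dynamic cutoff **and** a score favours coding
   (hexamer or PSSM log-odds > 0), **or** the transcript has a protein
   homology hit at ≥ 50 bits (inclusive boundary) in a BLASTX-style table.
   When no scoring model is supplied the score gate is open and length
   alone decides. No bundled organism model ships with the package; models
   are trained from data (the fixture generator trains them from its
   planted coding set).

## Tissue specificity

For each feature, expression is averaged per compartment (arithmetic mean
of FPKM — chosen so the sum decomposition of the index is exact), and the
tissue specificity index is the maximal compartment fraction:
$$\mathrm{TSI} = \frac{\max_c \bar{x}_c}{\sum_c \bar{x}_c} \in [1/N,\, 1].$$
TSI is 1/N for uniform expression, 1 for exclusive expression, invariant to
common rescaling, and strictly increases when mass moves into the top
compartment. A feature is podocyte-specific when TSI ≥ 0.8 (inclusive) *and*
the top compartment is the podocyte. High TSI = specific is the universal
semantics of this index; ties in the argmax break by the fixed priority
podocyte > glomerulus > kidney so results are deterministic. Ribo-depleted
and polyA podocyte libraries are averaged together within the podocyte
compartment unless the sample sheet separates them.

## Conservation in human

Two independent evidence routes, either of which marks a candidate
conserved:

**Sequence.** Alignments of mouse lncRNA transcripts against human
features, retained when identity is strictly above 80% and aligned length
strictly above 100 bp. Production-scale alignments arrive as outfmt-6
tables; an internal affine-gap Smith-Waterman (match +1, mismatch −1, gap
of length $k$ costs $2 + 0.5k$) serves small inputs and tests, with the
identical filter on both paths. The aligner is checked against an
independent three-state (Gotoh) dynamic program.

**Synteny.** Gene-order conservation transfers lncRNA identity through
protein-coding *anchors*. Both species' genes are ordered by midpoint per
chromosome; a Smith-Waterman-style local DP over the two anchor orders
scores an aligned anchor pair +1 when a BLASTP-like table links the genes
at ≥ 50 bits and −1 otherwise, with gaps at −0.5. Both orientations of the
second species are searched, so inversions are found, and all blocks with
score ≥ 3 are extracted greedily by descending score with each anchor used
at most once. A mouse lncRNA whose flanking anchor participates in a block
proposes every noncoding gene immediately flanking the matched human
anchor — within 100 kb of it — as a candidate ortholog. One aligned
flanking anchor suffices (both thresholds configurable). The scoring
scheme (±1/−0.5, minimum block score 3) is this package's default, chosen
to preserve the stated inputs (gene coordinates plus protein scores) and
local-alignment semantics; the DP is verified against exhaustive
enumeration on small instances.

Predicted orthologs are finally checked for expression in human kidney
samples (≥ 1 TPM in ≥ 1 sample by default; the thresholds are explicit
because no canonical value exists for this check).

## Differential expression

Candidate loci (noncoding transcripts bundled by same-strand exonic
overlap, single linkage, ≥ 1 bp; antisense transcripts form separate loci
because lncRNA biotypes are strand-defined) are tested per disease model:
a two-factor design (age + condition) for the two genetic models and a
one-factor design for the toxic model, with per-age one-factor contrasts
computed alongside and a locus counting as dysregulated when significant
in any contrast of its model.

The machinery is a per-locus negative-binomial log-linear model fitted by
IRLS at fixed dispersion, with median-of-ratios size factors as offsets and
the condition effect tested by a 1-df likelihood-ratio chi-square;
`log2fc` is the condition coefficient over $\ln 2$. Dispersion is the
per-locus method-of-moments estimate on normalized counts, shrunk toward a
common value with weight $n_{\text{prior}}/(n_{\text{prior}} + \mathrm{df})$
($n_{\text{prior}} = 10$) and floored at $10^{-6}$. The common value is the
mean of the per-locus estimates with the upper 5% winsorized: the
per-locus estimator is scale-free but right-skewed, so a symmetric trimmed
mean is biased low (which makes the LRT anti-conservative), while a pooled
ratio estimator is dominated by the few highest-expressed loci and
unstable; the upper-winsorized mean measured nearly unbiased and stable in
the package's calibration simulations. Significance is Benjamini-Hochberg
q < 0.05 within each model's testable loci. This module intentionally does
not reproduce any existing package's internals; an established NB-GLM
implementation is used as an independent cross-check in the test suite,
never as the implementation.

Calibration is asserted by simulation: null NB counts give approximately
uniform p (Kolmogorov-Smirnov distance < 0.05 at 2000 loci, n = 3 vs 3,
$\phi = 0.1$), realized FDR at q < 0.05 stays ≤ 0.1, and planted
$|\log_2\mathrm{FC}| = 2$ loci are recovered with ≥ 90% power.

## Single-cell validation

Cells expressing all four podocyte markers (*Wt1*, *Nphs1*, *Nphs2*,
*Mafb*) with raw count > 0 are labelled podocytes; everything else is
"other". "Express" = count > 0 is the natural reading for droplet data,
where any UMI is strong evidence of expression and the all-four conjunction
already controls specificity. Each gene is then tested podocytes vs other
cells with a two-sided Wilcoxon rank-sum test on log1p-CPM values (the test
is rank-based, so only per-cell scaling matters; the normalization choice
is recorded for reproducibility). Exact enumeration is used when both
groups have at most 8 cells; otherwise a normal approximation with tie and
continuity correction, which agrees with exact enumeration within 0.02
near the boundary. A gene is *detected* when nonzero in at least 3 cells —
an explicit decision, since no canonical cutoff exists. Clustering and
UMAP embeddings are visualization and out of scope; labelling is
marker-gated only.

## The candidate funnel

All flags combine into conjunctive tiers:
T1 expressed lncRNA → T2 podocyte-expressed → T3 TSI-specific →
T4 conserved (sequence or synteny) and free of protein homology →
T5 dysregulated in at least one disease model. Because tiers are
conjunctions, the final set does not depend on stage order. Upset-style
intersection counts over the flag combinations are emitted and partition
T1. Transcript evidence rolls up to loci by OR over members —
the permissive choice, made explicit — while DE flags are native to the
locus level.

## The synthetic study

`generate_fixture()` writes a complete toy two-species dataset with known
per-feature truth, so every stage is testable without downloads. Its
defaults are the package's study conditions, chosen once:

* 400 mouse lncRNA transcripts (70% present in the reference annotation),
  spliced lengths 300–2,800 nt, 1–3 exons, on toy ~1 Mb chromosomes; two
  "bulk" chromosomes carry most transcripts, one chromosome with
  human-colinear anchors hosts the 20 planted syntenic orthologs (one per
  anchor gap, so adjacency is unambiguous), and one chromosome with
  scrambled anchor homology (stride-8 permutation, which leaves no
  near-colinear run in either orientation) hosts 20 rearranged decoys.
* 40 coding contaminants with planted 150–250-aa ORFs built from a
  GC3-biased codon table (separable by the hexamer model) behind an
  in-frame stop guard, plus Swiss-Prot-style homology hits ≥ 50 bits.
* 40 sequence-conserved pairs generated by copying with per-base
  substitution at rate 0.15 (target identity 85%; the emitted outfmt-6
  table carries the realized identities).
* Compartment FPKM: specific features draw their profile from a
  concentrated Dirichlet tilted to the podocyte (TSI ≈ 0.9); non-specific
  features from Dirichlet(5,5,5), under which a chance TSI ≥ 0.8 is rare
  enough to keep the planted set separable; per-sample gamma noise at
  CV 0.2.
* Counts: NB with $\phi = 0.1$, n = 3 per design cell, baselines
  log-normal around 120, planted $\log_2\mathrm{FC} \in \{0, \pm 1, \pm 2\}$
  with a coherent up-regulated set shared by all three models; the
  two-factor models carry a 1.4× age effect.
* scRNA: 60 podocytes (markers at 1 + Poisson(3), so the gating truth is
  unambiguous) and 240 other cells (markers at Poisson(0.02)); 10 planted
  podocyte-exclusive genes, plus silent genes to exercise the detection
  cutoff.

Each file type draws from its own random stream derived from the master
seed, so adding a feature class does not shift unrelated outputs, and
regeneration with the same seed is byte-identical (asserted in tests).

What passing on this fixture does *not* show: real assemblies have
fragmented and overlapping isoforms, expression is not gamma-around-profile,
real conservation decays non-uniformly along transcripts, droplet data has
ambient RNA and doublets, and real dispersions are mean-dependent. The
fixture demonstrates correctness of the machinery under controlled truth,
not field performance.

## Numerical choices and degenerate inputs

* Cutoff boundaries: length ≥ 200, FPKM ≥ 1, TSI ≥ 0.8, 50 bits, q < 0.05
  are inclusive/exclusive exactly as written; sequence conservation uses
  strict > 80% and > 100 bp.
* All-zero features: TSI is NA and never specific; all-zero loci are
  untestable with p = 1 and log2fc = 0; NA p-values propagate through BH
  without counting toward the family size.
* Ties: TSI argmax by fixed compartment priority; DP traceback prefers
  diagonal over up over left; locus ids are content-addressed
  (`LOC_<chrom>_<start>_<strand>`) so they are stable under subsetting.
* Degenerate base compositions (zero mass on a base required by start or
  stop codons) are rejected rather than silently returning infinite
  cutoffs.
* IRLS runs at fixed dispersion with clamped linear predictors; the LRT
  statistic is floored at 0.

## Problem sizes in tests

The test-suite simulations use sizes that keep the default run in the
minutes range while leaving estimates sharp: 500 random 2-kb sequences for
the ORF oracle, 10,000 Monte-Carlo sequences per length for the cutoff
calibration, 200 random instances per DP oracle, 1,000 random vectors for
BH, 2,000 null + 200 planted loci for DE calibration, and the default
400-transcript fixture end-to-end. The acceptance script reruns the
pipeline and calibrations at the same sizes from a user-supplied seed.

## Known limitations

* The dynamic cutoff controls the *expected count* of chance ORFs, not the
  percentile of the longest chance ORF; the two differ by a few codons
  (see above) and the conservative side was chosen.
* Synteny adjacency can propose the ncRNA next to the *other* flanking
  anchor of the same gap as an additional ortholog candidate; candidates
  are proposals to be filtered by the human-expression check, not
  assertions of orthology.
* The NB machinery is deliberately simple (no mean-dispersion trend, no
  quasi-likelihood moderation); it is calibrated at the fixture's
  conditions but is not a drop-in replacement for mature DE packages on
  real data.
* Transcript-level quantification uncertainty (multi-mapping, isoform
  deconvolution) is upstream of this package and ignored.
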