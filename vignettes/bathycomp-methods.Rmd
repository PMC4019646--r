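---
title: "Methods: comparing bathytype genome pairs with bathycomp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparing bathytype genome pairs with bathycomp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and model of the data

`bathycomp` compares two closely related annotated bacterial genomes — the
motivating case is a shallow-water and a deep-water ecotype ("bathytype") of
one *Photobacterium* species, one genome a finished reference and the other
an 11-scaffold draft.  The package implements the complete comparative
workflow as composable functions: genome I/O and reference-guided
scaffolding, fragment-based average nucleotide identity (ANI), reciprocal
smallest distance (RSD) orthology, codon-level Ka/Ks with molecular-clock
dating, modal codon-usage screening for horizontal gene transfer (HGT), and
bootstrap comparison of functional-category profiles.  A codon-level
simulator with full ground truth stands in for downloadable assemblies, so
every stage is testable offline.

All coordinates are 1-based inclusive (GFF convention); translation uses the
bacterial genetic code (table 11) throughout.

# Pseudomolecule scaffolding

Draft scaffolds are anchored on the reference by their best local alignment
and concatenated in reference order, reverse-complemented when the anchor
lies on the minus strand, with the 34-nt spacer
`NNNNCACACACTTAATTAATTAAGTGTGTGNNNN` between consecutive scaffolds.  The
spacer's 26-nt core is its own reverse complement and carries a stop codon
in all three forward frames (hence all six frames across a join), so no
reading frame survives a junction; the test suite proves this property on
every junction it builds.

Anchoring uses BLASTN with match +1 / mismatch −1 / gap open −5 / gap
extend −2 and a minimum raw anchor score of 100 (scaffolds below it are
appended unplaced, in input order).  BLASTN restricts its gap-cost
combinations, so the same scoring scheme is used for anchoring as for the
ANI engine rather than a linear −2 gap; at the anchor scores involved
(hundreds to thousands) the placement decision is insensitive to this
choice.

Intergenic statistics are reported as the mean of strictly positive gaps
between consecutive gene spans within a scaffold (overlapping genes
contribute nothing); a "clip" mode that counts overlaps as zero-length gaps
is provided because published "mean intergenic size" figures rarely state
their convention.

# Fragment ANI and percent conserved DNA

The query genome is cut into consecutive 1020-bp fragments (trailing
partials retained) and each fragment is aligned to the full subject genome
with BLASTN (both strands, best hit only; match +1 / mismatch −1 / gap open
−5 / gap extend −2, identity denominator = all alignment columns including
gaps).  Fragments whose best hit reaches 30% identity over at least 714
aligned columns enter the ANI mean; aligned bases of fragments at ≥90%
identity count toward percent conserved DNA.  Two-way ANI averages the two
directions and reports the genome-level species verdict (same species iff
ANI > 95% and conserved DNA > 69%).

ANI at the second decimal depends on the alignment engine; the engine and
its parameters are fixed and recorded in the result (`engine = "blastn"`).
On indel-free simulated pairs the engine agrees with a direct per-column
identity count to well under half a percentage point, and self-comparison
is exactly 100%/100% by construction.

# RSD orthology

A pair (a, b) is orthologous iff b is a's smallest-distance hit and a is
b's.  Candidates are the top-3 BLASTP hits (BLOSUM62, gap −11/−1, raw score
≥ 50, no compositional adjustment for determinism); each candidate is then
globally aligned and scored by the corrected protein distance
d = −ln(1 − p − p²/5) on the proportion p of differing non-gap columns.
Distances beyond the correction's domain are set to a declared ceiling of
10 and flagged saturated.  Ties break by higher alignment score, then
lexicographic id.  The original RSD formulation uses maximum-likelihood
distances; the closed-form correction is used here for determinism and
speed, and makes no difference to mutual-best decisions at intra-species
divergences (recall ≥ 0.95, precision 1.0 on the default simulation).

# Ka/Ks, the omega census, and dating

`kaks_ng86()` is the pathway estimator: sites counted by enumerating the
nine single-nucleotide neighbours of each codon (stop-codon targets
excluded, each position contributing exactly one site, so S + N = 3 ×
codons), differences averaged over minimal mutational pathways with
stop-crossing paths discarded and the rest weighted equally, and both
proportions Jukes–Cantor corrected.  It doubles as the package's internal
oracle: the test suite re-derives its site and pathway counts from an
independent enumeration written in the tests.

`kaks_yn00()` follows the approximate method of Yang & Nielsen: codon
frequencies from the data (F3x4 with a small pseudocount), kappa estimated
by K80 on fourfold-degenerate and nondegenerate positions shared by both
codons (site-count-weighted average of the two classes, clamped to
[0.1, 99]), kappa- and frequency-weighted site counting iterated to
convergence of (S, N, kappa), pathway-classified synonymous/nonsynonymous
transitions and transversions, and separate K80 corrections for Ka and Ks.
Saturation or non-convergence falls back to the flagged NG86 result.  In
the uniform-usage, kappa = 1 limit the two estimators' site counts agree to
numerical precision, and their rates agree within 20% at intra-species
divergences — both are enforced by tests.

Each pair's omega is screened by a two-sided Fisher exact test on the
rounded 2×2 table [[Sd, S−Sd], [Nd, N−Nd]] (the KaKs-calculator
convention), with significance for the omega > 1 census at P < 0.01.  Pairs
with Ks = 0 have undefined omega and are excluded from the census rather
than counted as infinite.

Divergence time is tau = median(Ks) / (2λ) with λ = 8.3×10⁻⁷
substitutions/site/year, the SNP clock for closely related bacterial
isolates; saturated pairs are excluded from the median.  At the bathytype
pair's published median Ks of 0.210543 the formula dates the split to
~127,000 years, which the acceptance script recomputes.

# Modal codon usage and HGT detection

Per-gene usage counts the 59 informative codons (61 sense codons minus the
single-codon families ATG and TGG), excluding the initiator and terminal
stop, normalized within each synonymous family.  The genome-wide *mode* is
found by a deterministic fixed-point search: start from the pooled usage of
all eligible genes (≥ 60 informative codons), repeatedly re-pool over only
the genes matching the current mode (chi-square p ≥ 0.1), and keep the
usage that matched the most genes; the underlying literature leaves the
optimizer unspecified, so this seed-free iteration is the package's
declared choice.  A gene is atypical — an HGT candidate — when its
chi-square probability against the mode falls below 0.1.  Expected cells
below 1 are pooled into the family's largest cell (configurable off);
degrees of freedom are cells minus contributing families.

On two-table simulations the screen reaches island sensitivity ≥ 0.8 (in
practice 1.0 at the default table divergence), and on homogeneous genomes
flags 9–15% of genes at p < 0.1 — mildly above the nominal 10% is expected
because the chi-square approximation is rough at ~300-codon genes and the
mode is fitted to the same data.

Correspondence analysis of the gene × codon count matrix is computed
directly by SVD of the standardized residuals of the correspondence
matrix; row (gene) principal coordinates are returned with per-axis inertia
shares, and total inertia equals the table's chi-square over its grand
total (a test oracle).  Genes from different codon tables separate on the
first axis (silhouette > 0.5 on simulations).

# Category-profile comparison

Functional-category (COG-letter) profiles are compared XIPE-style: per
replicate, 4000 labels are drawn with replacement from each profile's
empirical distribution (a multinomial draw), and each category's proportion
difference is summarized over 10,000 replicates by its median and the
equal-tailed 98% percentile interval; a category is significant when the
interval excludes zero.  Each profile's bootstrap stream is keyed by the
seed and the profile's name, which makes the comparison exactly
antisymmetric under argument swap and bit-reproducible under a fixed seed.
Sampling without replacement is available as a variant (`replace = FALSE`),
since "subsample" is ambiguous in parts of the literature; genes with
several category letters contribute one label per letter.

Two null behaviours are worth distinguishing.  If the two *count vectors*
are literally identical, the resampled difference distribution is centred
and symmetric and the interval essentially never excludes zero.  The ~2%
per-category false-positive rate associated with a 98% interval is realized
under the proper sampling null — two profiles drawn independently from the
same multinomial, with the subsample size matching the profile totals —
and that is the experiment the acceptance checks run.

# The simulator

`simulate_pair()` builds an ancestor of `n_genes` protein-coding genes
(codons drawn from a host codon table, ATG start, weighted stop), lays them
on a chromosome with geometric intergenic spacers (mean 167 bp) and random
strands, and evolves two descendants independently: proposals follow an
HKY-like scheme (transition:transversion weight kappa = 2 by default),
synonymous changes are always accepted, nonsynonymous changes accepted with
the gene's omega, stops rejected.  The proposal intensity is calibrated in
closed form so the expected NG86-measured pairwise Ks equals the target:
with f_s the expected accepted-synonymous fraction per proposal under the
ancestral codon distribution and s the mean synonymous sites per nucleotide
position, the per-branch intensity is (Ks/2)·s/f_s proposals per site.
Intergenic sequence diverges neutrally at the same expected rate.  Start
and stop codons are held fixed; there are no indels within genes, so the
true codon homology is the identity alignment.

Genome A additionally receives a contiguous cluster of genes drawn from a
divergent (AT3-rich) island table — mirroring the clustered arrangement of
horizontally acquired genes such as a photolyase cassette — and genome B is
fragmented into 11 scaffolds at intergenic breakpoints, each flipped with
probability 1/2 and emitted in shuffled order.  Twenty genes are deleted
from each side.  Defaults (200 genes, ~300 codons, target Ks 0.21,
per-gene omega log-normal around 0.1, kappa 2) define the reference study
conditions used by the test suite and acceptance script.

What the simulator does **not** emulate — and hence what passing tests do
not certify on real data: indels and rearrangements within genes, gene
family expansion/paralogy, recombination, amelioration of transferred
genes, strand-specific mutational bias, and real annotation noise (wrong
starts, frameshifts).  ANI on real drafts also depends on repeat content
absent from the simulation.

# Numerical choices and problem sizes

Tolerances and degenerate-input rules: protein-distance saturation ceiling
10; Ka/Ks undefined (not infinite) past the Jukes–Cantor domain p ≥ 3/4;
YN00 falls back to NG86 with a flag; genes shorter than 60 informative
codons are computed but excluded from mode fitting and flagged untested;
empty genomes and empty Ks sets are errors, and a query with no retained
ANI fragments reports a missing ANI rather than zero.

The test suite and acceptance script run the simulator at 60–200 genes
(~0.2–0.25 Mb per genome) and use a 1-Mb indel-free pair for the ANI
calibration check; these sizes give stable statistics (e.g. binomial error
on a 160-pair recall is ~1.5%) while keeping a full run in minutes on one
CPU.

# Known limitations

ANI values at the second decimal are engine-specific; reproducing published
figures bit-for-bit may require matching the original BLAST version and
parameters.  The YN00 implementation follows the published approximate
scheme but is not codeml, and kappa estimates on short genes are noisy.
RSD here uses a fixed candidate depth (k = 3) and a closed-form distance;
deep paralogy could in principle mislead it.  GenBank flat files are not
parsed; genomes enter as FASTA + GFF3.
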