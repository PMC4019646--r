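# bathycomp

Intra-species comparative genomics for pairs of closely related bacterial
genomes — written around the analyses used to contrast the shallow- and
deep-water ecotypes ("bathytypes") of *Photobacterium profundum*, where a
finished reference genome is compared against an 11-scaffold draft of its
sister ecotype.

The package provides, as composable R functions plus a numbered analysis
workflow:

- **Genome I/O and scaffolding** — FASTA + GFF3 genomes; reference-guided
  pseudomolecule assembly that orders and orients draft scaffolds by their
  best BLASTN anchor and joins them with the 34-nt spacer
  `NNNNCACACACTTAATTAATTAAGTGTGTGNNNN`, whose palindromic core puts a stop
  codon in all six reading frames across every junction.
- **Fragment ANI** — Goris-style average nucleotide identity: 1020-bp
  fragments, best local alignment against the partner genome, filters at
  30% identity / 714 bp alignable; percent conserved DNA at ≥ 90% identity;
  two-way means and the species verdict (ANI > 95% and conserved DNA > 69%).
- **Orthology** — reciprocal smallest distance (RSD): top-3 BLASTP
  candidates, global alignment, corrected protein distance
  d = −ln(1 − p − p²/5), mutual-best pairing; shared/unique gene partition.
- **Selection and dating** — codon alignments via the protein alignment;
  Ka/Ks by Nei–Gojobori pathway counting (NG86) and by a YN00-style
  estimator (codon-frequency- and kappa-weighted sites, K80-corrected
  rates); Fisher exact screen of ω > 1 pairs (P < 0.01); divergence time
  τ = median(Ks)/(2λ) with λ = 8.3×10⁻⁷ substitutions/site/year.
- **HGT detection** — per-gene codon usage over the 59 informative codons,
  genome-wide *modal* usage by a deterministic fixed-point search,
  chi-square atypicality at p < 0.1, and correspondence analysis of the
  gene × codon matrix.
- **Category comparison** — XIPE-style bootstrap of COG-letter profiles
  (subsample 4000, 10,000 replicates, 98% equal-tailed intervals).
- **Simulator** — an ancestor genome evolved into two descendants under a
  selection-filtered HKY codon process calibrated to a target Ks, with an
  implanted alien-codon-usage island, per-side gene deletions and draft
  fragmentation, emitting FASTA/GFF plus a full ground-truth table.

## Worked example

The numbered scripts under `analysis/` run the whole study on the simulated
bathytype pair (seed 42 by default; pass `--seed N` to change it). Running
them in order prints, among other things:

```
$ Rscript analysis/01_simulate.R
Genome A: 190 genes, 208,452 bp (complete, carries the HGT island)
Genome B: 180 genes, 196,799 bp in 11 scaffolds (draft)
True ortholog pairs: 160; realized median Ks = 0.2115 (target 0.21)

$ Rscript analysis/03_ani.R
ANI 91.55% (a->b 91.54, b->a 91.55); conserved DNA 66.68%
species-boundary verdict (ANI>95%, conserved>69%): distinct

$ Rscript analysis/04_orthologs.R
160 orthologous pairs; 30 genes unique to A, 20 unique to B

$ Rscript analysis/05_selection.R
160 pairs analysed; 0 with omega > 1, 0 of them significant (P < 0.01)
median Ks = 0.200814 over 160 pairs; lambda = 8.3e-07 /site/year; tau = 120,972 years
tau recovery ratio (estimated / truth): 0.950
```

Reading the output: at a simulated synonymous divergence of Ks ≈ 0.21 the
pair sits below the genome-level species boundary (ANI ≈ 91.5% < 95%,
conserved DNA ≈ 67% < 69%) even though every gene is still confidently
orthologous — the same regime reported for the real bathytype pair. The
selection screen finds no credible positive selection (all genes simulated
under purifying ω), and the molecular clock converts the recovered median
Ks into a divergence date, here within 5% of the simulator's truth.
`analysis/06_codon_usage.R` flags the implanted 10-gene island with
sensitivity 1.0 while 162/190 genes match the genome's modal codon usage,
and `analysis/02_scaffold_stats.R` reassembles the draft into a
pseudomolecule with every scaffold placed and oriented correctly.

Per-table outputs land in `results/` as TSV.

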