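# Modal codon usage of genome A, chi-square atypicality calls (HGT
# candidates at p < 0.1), island-detection metrics against truth, and
# correspondence analysis of the gene x codon matrix.

source("analysis/00_setup.R")
seed <- cli_seed()
sim <- study_pair(seed)

genes <- genome_usage(sim$A)
scr <- hgt_screen(genes)
message(sprintf("mode fitted on %d eligible genes; %d match; %d genes atypical at p < 0.1",
                scr$mode$n_eligible, scr$mode$n_matching,
                sum(scr$calls$atypical[scr$calls$tested])))
ev <- truth_eval(sim$truth, hgt_calls = scr$calls)
print(ev)

m <- do.call(rbind, lapply(genes, `[[`, "counts"))
rownames(m) <- names(genes)
keep <- rowSums(m) >= 60
ca <- correspondence_analysis(m[keep, ])
message(sprintf("CA axes 1-2 carry %.1f%% + %.1f%% of total inertia",
                100 * ca$inertia[1], 100 * ca$inertia[2]))

dir <- results_dir()
write_tsv(scr$calls, file.path(dir, sprintf("hgt_calls_seed%d.tsv", seed)))
coords <- data.frame(gene_id = rownames(ca$coords), ca$coords,
                     island = rownames(ca$coords) %in% sim$truth$island_genes)
write_tsv(coords, file.path(dir, sprintf("ca_coords_seed%d.tsv", seed)))
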