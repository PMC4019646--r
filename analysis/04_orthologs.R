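# Reciprocal smallest distance orthologs between the two genomes, the
# shared/unique gene partition, and recovery metrics against simulator
# truth.

source("analysis/00_setup.R")
seed <- cli_seed()
sim <- study_pair(seed)

orth <- reciprocal_orthologs(sim$A, sim$B)
print(orth)
ev <- truth_eval(sim$truth, orthologs = orth)
print(ev)

dir <- results_dir()
write_tsv(orth$shared, file.path(dir, sprintf("orthologs_seed%d.tsv", seed)))
write_tsv(rbind(data.frame(genome = "A", gene_id = orth$unique_a),
                data.frame(genome = "B", gene_id = orth$unique_b)),
          file.path(dir, sprintf("unique_genes_seed%d.tsv", seed)))
write_tsv(ev, file.path(dir, sprintf("ortholog_recovery_seed%d.tsv", seed)))
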