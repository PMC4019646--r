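# Fragment-based two-way ANI and percent conserved DNA for the simulated
# pair, plus the species-boundary verdict (same species iff ANI > 95% and
# conserved DNA > 69%).

source("analysis/00_setup.R")
seed <- cli_seed()
sim <- study_pair(seed)

res <- two_way_ani(sim$A, sim$B)
print(res)
write_tsv(data.frame(ani_ab = res$ani_ab, ani_ba = res$ani_ba,
                     ani_mean = res$ani_mean,
                     conserved_ab = res$conserved_ab,
                     conserved_ba = res$conserved_ba,
                     conserved_mean = res$conserved_mean,
                     same_species = res$same_species),
          file.path(results_dir(), sprintf("ani_seed%d.tsv", seed)))
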