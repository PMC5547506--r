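#!/usr/bin/env Rscript

# Step 1 — simulate the locus and sequencing libraries.
#
# Builds a 2-Mb synthetic locus carrying NlaIII (CATG) and DpnII (GATC)
# sites at genomic densities, a viewpoint flanked by insulated sub-TADs
# with five enhancer-like islands, and a hub zone of correlated three-way
# contacts. From it, generates a 100-bp standard 4C library (20,000 reads)
# and a 250-bp multi-way library (5,000 reads; 20% PCR duplicates, 10%
# undigested products, 50% hub draws) with full planted ground truth.

suppressPackageStartupMessages(library(tricontact))

out <- "scratch/sim"   # bulky regenerable inputs live outside results/
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- sim_config(seed = 42L)
write_sim_config(cfg, file.path(out, "config.json"))

genome <- simulate_genome(cfg)
write_genome(genome, file.path(out, "genome.fa"))
map <- digest(genome)
write_fragments(map, file.path(out, "fragments.bed"))
message(sprintf("locus: %d bp, %d restriction fragments",
                cfg$chrom_length, nrow(map)))

model <- build_contact_model(map, genome, cfg)
vp <- sim_viewpoint(model, map)
jsonlite::write_json(unclass(vp), file.path(out, "viewpoint.json"),
                     auto_unbox = TRUE)
message(sprintf("viewpoint fragment %d [%d, %d); %d eligible fragments",
                model$viewpoint_index, vp$bait_start, vp$bait_end,
                sum(model$eligible)))

cfg_std <- cfg
cfg_std$n_reads <- 20000L
std <- simulate_standard_reads(model, map, genome, cfg_std)
write_fastq(std$reads, file.path(out, "standard_100bp.fq"))
write_truth(std$truth, file.path(out, "standard_truth.tsv"))

mw <- simulate_multiway_reads(model, map, genome, cfg)
write_fastq(mw$reads, file.path(out, "multiway_250bp.fq"))
write_truth(mw$truth, file.path(out, "multiway_truth.tsv"))

n_dup <- sum(!is.na(mw$truth$duplicate_of))
n_und <- sum(mw$truth$undigested)
message(sprintf(
  "libraries: %d standard reads; %d multiway reads (%d duplicates, %d undigested, %d planted unique pairs)",
  nrow(std$reads), nrow(mw$reads), n_dup, n_und,
  nrow(planted_unique_pairs(mw$truth))))
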