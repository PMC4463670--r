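#!/usr/bin/env Rscript
# Stage 1: generate the synthetic references and the two small-RNA
# libraries (A = intermuscular bone analogue, B = connective tissue
# analogue) with full ground truth.
#
# Usage: Rscript analysis/01_simulate.R [seed]

suppressMessages(library(mamiR))

seed <- suppressWarnings(as.integer(commandArgs(trailingOnly = TRUE)[1]))
if (is.na(seed)) seed <- 1L
out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cfg <- sim_config(seed = seed)
refs <- generate_references(cfg)
sim <- simulate_libraries(cfg, refs)

write_reference_bundle(refs, out)
write_fastq(sim$reads_A, file.path(out, "library_A.fastq"))
write_fastq(sim$reads_B, file.path(out, "library_B.fastq"))
write.table(sim$truth$mirna_counts, file.path(out, "truth_mirna_counts.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
yaml::write_yaml(unclass(cfg), file.path(out, "sim_config.yaml"))

tc <- sim$truth$mirna_counts
cat(sprintf("Simulated 2 x %d reads from %d hairpins (seed %d).\n",
            cfg$reads_per_library, cfg$n_hairpins, seed))
cat(sprintf("Truly differential hairpins: %d up, %d down (|log2fc| = %.1f).\n",
            sum(tc$de_label == "up" & !tc$is_star),
            sum(tc$de_label == "down" & !tc$is_star), cfg$de_log2fc))
cat(sprintf("Star-arm products simulated for %d hairpins.\n",
            sum(refs$arms$has_star)))
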