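#!/usr/bin/env Rscript
# Stage 2: clean the raw reads (quality -> adapter -> polyA -> length),
# collapse to unique tags, compare the libraries, map to the genome
# surrogate with one mismatch, and annotate/remove ncRNA classes.
#
# Usage: Rscript analysis/02_clean_annotate.R   (after 01_simulate.R)

suppressMessages(library(mamiR))

dat <- "results/data"
out <- "results/tables"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
cfg <- do.call(sim_config, lapply(yaml::read_yaml(file.path(dat, "sim_config.yaml")),
                                  function(x) if (is.list(x)) unlist(x) else x))

tags <- list()
summaries <- list()
for (lib in c("A", "B")) {
  cl <- clean_reads(file.path(dat, sprintf("library_%s.fastq", lib)),
                    cfg$adapter3)
  tags[[lib]] <- collapse_unique(cl$inserts)
  s <- cl$summary
  summaries[[lib]] <- data.frame(
    library = lib, raw_reads = s$raw_reads, clean_reads = s$clean_reads,
    clean_pct = round(100 * s$clean_fraction, 2),
    unique_tags = s$unique_tags, t(s$discards))
  cat(sprintf("Library %s: %d of %d reads clean (%.2f%%), %d unique tags.\n",
              lib, s$clean_reads, s$raw_reads, 100 * s$clean_fraction,
              s$unique_tags))
  write_tag_fasta(tags[[lib]], file.path(out, sprintf("tags_%s.fa", lib)))
  write.table(cbind(library = lib, length_distribution(tags[[lib]])),
              file.path(out, sprintf("length_distribution_%s.tsv", lib)),
              sep = "\t", quote = FALSE, row.names = FALSE)
}
write.table(do.call(rbind, summaries), file.path(out, "library_summary.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cs <- common_specific(tags$A, tags$B)
cat(sprintf("Unique tags: %d common, %d A-only, %d B-only.\n",
            cs$common, cs$A_only, cs$B_only))
write.table(data.frame(cs), file.path(out, "common_specific.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

merged <- merge_tag_counts(tags$A, tags$B)
genome <- setNames(
  toupper(as.character(Biostrings::readDNAStringSet(file.path(dat, "genome.fa")))),
  "chr1")
mp <- map_tags(merged, genome)
cat(sprintf("Mapping: %.2f%% of reads, %.2f%% of unique tags hit the genome (<=1 mismatch).\n",
            mp$summary$mapped_reads_pct, mp$summary$mapped_unique_pct))
write.table(data.frame(mp$summary), file.path(out, "mapping_summary.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(mp$hits, file.path(out, "mapping_hits.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

ncrna <- read_category_fasta(file.path(dat, "ncrna.fa"))
tx <- setNames(toupper(as.character(
  Biostrings::readDNAStringSet(file.path(dat, "transcripts.fa")))), NULL)
names(tx) <- names(Biostrings::readDNAStringSet(file.path(dat, "transcripts.fa")))
ann <- annotate_tags(merged, ncrna, tx)
summ <- annotation_summary(ann)
print(summ[, c("category", "unique_tags", "reads")], row.names = FALSE)
write.table(summ, file.path(out, "annotation_summary.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

retained <- merged[merged$seq %in% retain_for_mirna(ann)$seq, ]
cat(sprintf("Retained for miRNA analysis: %d tags, %d + %d reads.\n",
            nrow(retained), sum(retained$count_A), sum(retained$count_B)))
write.table(retained, file.path(out, "retained_tags.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(merged, file.path(out, "merged_tags.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
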