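#!/usr/bin/env Rscript
# Stage 3: identify conserved miRNAs against the mature/hairpin references,
# group families, rank abundances, profile base bias, detect miRNA:miRNA*
# duplexes, and decompose the supporting tags into isomiRs.
#
# Usage: Rscript analysis/03_identify_isomir.R   (after 02_clean_annotate.R)

suppressMessages(library(mamiR))

dat <- "results/data"
out <- "results/tables"
retained <- read.delim(file.path(out, "retained_tags.tsv"),
                       stringsAsFactors = FALSE)
mature <- setNames(
  toupper(as.character(Biostrings::readDNAStringSet(file.path(dat, "mature.fa")))),
  names(Biostrings::readDNAStringSet(file.path(dat, "mature.fa"))))
hairpins <- setNames(
  toupper(as.character(Biostrings::readDNAStringSet(file.path(dat, "hairpin.fa")))),
  names(Biostrings::readDNAStringSet(file.path(dat, "hairpin.fa"))))
arms <- read.delim(file.path(dat, "arms.tsv"), stringsAsFactors = FALSE)

ident <- identify_conserved(retained, mature, hairpins, arms = arms)
cat(sprintf("Identified %d miRNAs (%d in A, %d in B; %d families).\n",
            nrow(ident$catalog), sum(ident$catalog$count_A >= 1),
            sum(ident$catalog$count_B >= 1),
            length(group_families(ident$catalog))))
write.table(ident$catalog, file.path(out, "catalog.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(ident$support, file.path(out, "isomir_records.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

for (lib in c("A", "B")) {
  r <- rank_abundance(ident$catalog, lib, k = 10)
  cat(sprintf("Top-10 miRNAs carry %.2f%% of catalog reads in library %s.\n",
              100 * r$cumulative_fraction, lib))
}

bb <- base_bias(ident$support$tag[!duplicated(ident$support$tag)])
write.table(data.frame(length = rownames(bb$first_base), bb$first_base),
            file.path(out, "first_base_bias.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
u22 <- if ("22" %in% rownames(bb$first_base)) bb$first_base["22", "U"] else NA
cat(sprintf("First-base U fraction among 22-nt tags: %.2f.\n", u22))

dup <- detect_duplexes(ident$catalog, arms, hairpins)
cat(sprintf("miRNA:miRNA* duplex-like pairs detected: %d (3' overhangs %s).\n",
            nrow(dup),
            paste(unique(dup$overhang_mature3), collapse = "/")))
write.table(dup, file.path(out, "duplex_pairs.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

sp <- substitution_spectrum(ident$support)
cat("Seed-substitution spectrum (top 4):\n")
print(head(sp[order(-sp$count), ], 4), row.names = FALSE)
write.table(sp, file.path(out, "substitution_spectrum.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

prof <- nta_profile(ident$support)
if (nrow(prof)) {
  cat(sprintf("Non-templated 3' additions: %.0f%% start with U.\n",
              100 * prof$fraction[prof$base == "U"]))
}
write.table(prof, file.path(out, "nta_profile.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

# per-precursor isomiR detail for the most abundant miRNA, the tabular
# analogue of a let-7d-style isomiR figure
topm <- ident$catalog$name[which.max(ident$catalog$count_A +
                                       ident$catalog$count_B)]
tab <- isomir_table(topm, ident$support)
cat(sprintf("IsomiR variants of %s: %d (lengths %d-%d nt).\n",
            topm, nrow(tab), min(tab$length), max(tab$length)))
write.table(tab, file.path(out, "isomir_table_top.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
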