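#!/usr/bin/env Rscript
# Stage 5: stem-loop qPCR validation arithmetic (2^-ddCt against 5S rRNA,
# referenced to muscle) with hierarchical clustering of the miRNA x tissue
# matrix, and seed-match target scanning of the significant miRNAs
# against the transcript set.
#
# Usage: Rscript analysis/05_qpcr_targets.R [seed]   (after stage 04)

suppressMessages(library(mamiR))

seed <- suppressWarnings(as.integer(commandArgs(trailingOnly = TRUE)[1]))
if (is.na(seed)) seed <- 1L
dat <- "results/data"
out <- "results/tables"
de_tab <- read.delim(file.path(out, "de_table.tsv"), stringsAsFactors = FALSE)
catalog <- read.delim(file.path(out, "catalog.tsv"), stringsAsFactors = FALSE)

sig <- de_tab$name[grepl("^significant", de_tab$status)]
picks <- head(sig, 11)
if (length(picks) < 2) picks <- head(de_tab$name[de_tab$status != "filtered_low"], 11)

# a designed qPCR panel: tissue profiles consistent with the sequencing
# fold changes in the IB/CT columns, arbitrary in the other tissues
set.seed(seed)
tissues <- c("muscle", "brain", "liver", "spleen", "kidney", "gonad",
             "rib", "IB", "CT")
fc <- matrix(2^stats::rnorm(length(picks) * length(tissues), 0, 1.5),
             nrow = length(picks), dimnames = list(picks, tissues))
fc[, "muscle"] <- 1
fc[, "IB"] <- 2^pmax(pmin(de_tab$log2ratio[match(picks, de_tab$name)], 6), -6)
ct <- simulate_ct_table(fc, reference_tissue = "muscle")
mat <- relative_expression(ct, "muscle")
stopifnot(max(abs(mat[, "muscle"] - 1)) < 1e-12)
cl <- cluster_heatmap(mat)

write.table(ct, file.path(out, "qpcr_ct.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(data.frame(mirna = rownames(mat), unclass(mat),
                       check.names = FALSE),
            file.path(out, "qpcr_relative_expression.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
writeLines(c(cl$row_newick, cl$col_newick),
           file.path(out, "qpcr_dendrograms.nwk"))
cat(sprintf("qPCR panel: %d miRNAs x %d tissues; reference column == 1 exact.\n",
            nrow(mat), ncol(mat)))
cat("Tissue dendrogram leaf order:", paste(cl$col_order, collapse = " "),
    "\n")

tx_set <- Biostrings::readDNAStringSet(file.path(dat, "transcripts.fa"))
tx <- setNames(toupper(as.character(tx_set)), names(tx_set))
mir <- setNames(catalog$seq[match(picks, catalog$name)], picks)
mir <- mir[!is.na(mir)]
sites <- scan_targets(mir, tx)
stopifnot(all(verify_target_sites(sites, mir, tx)))
write.table(sites, file.path(out, "target_sites.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("Seed scan: %d candidate sites (%s) across %d transcripts for %d miRNAs.\n",
            nrow(sites),
            paste(names(table(sites$site_type)), table(sites$site_type),
                  sep = ":", collapse = ", "),
            length(unique(sites$transcript)), length(mir)))
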