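#!/usr/bin/env Rscript
# Stage 4: reads-per-million normalization, expression floors/filters, the
# exact conditional count test, and significance calls at |log2ratio| >= 1
# and p <= 0.01, scored against the simulator's truth.
#
# Usage: Rscript analysis/04_differential_expression.R  (after stage 03)

suppressMessages(library(mamiR))

dat <- "results/data"
out <- "results/tables"
catalog <- read.delim(file.path(out, "catalog.tsv"), stringsAsFactors = FALSE)
libsum <- read.delim(file.path(out, "library_summary.tsv"),
                     stringsAsFactors = FALSE)
totals <- setNames(libsum$clean_reads, libsum$library)

cfg <- de_config(p_threshold = 0.01)
tab <- expression_table(catalog, totals[["A"]], totals[["B"]])
res <- call_de(adjust_and_filter(tab, cfg), cfg)
write.table(res$table, file.path(out, "de_table.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(de_scatter_rows(res$table), file.path(out, "de_scatter.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
jsonlite::write_json(res$summary, file.path(out, "de_summary.json"),
                     auto_unbox = TRUE, pretty = TRUE)

cat(sprintf("Tested %d of %d miRNAs (%s).\n", res$summary$n_tested,
            res$summary$n_total, res$summary$orientation))
cat(sprintf("Significant at |log2ratio| >= %g, p <= %g: %d (%d up in B, %d up in A).\n",
            cfg$fc_threshold, cfg$p_threshold, res$summary$n_significant,
            res$summary$n_up_B, res$summary$n_up_A))

truth <- read.delim(file.path(dat, "truth_mirna_counts.tsv"),
                    stringsAsFactors = FALSE)
m <- merge(res$table, truth[, c("name", "de_label")], by = "name")
called <- grepl("^significant", m$status)
is_de <- m$de_label != "no"
open <- m$status != "filtered_low"
cat(sprintf("Against truth: sensitivity %.2f (%d/%d DE), FPR %.3f among tested.\n",
            sum(called & is_de) / sum(is_de), sum(called & is_de),
            sum(is_de), sum(called & !is_de) / max(1, sum(open & !is_de))))
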