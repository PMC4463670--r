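#' Ct difference against the reference gene
#'
#' `dCt = Ct_target - Ct_reference_gene` (5S rRNA in a stem-loop RT-PCR
#' assay).
#'
#' @param ct_mirna,ct_ref threshold-cycle values.
#' @return the difference.
#' @export
delta_ct <- function(ct_mirna, ct_ref) {
  ct_mirna - ct_ref
}

#' Relative expression matrix by the 2^-ddCt method
#'
#' Triplicate Ct values are averaged (arithmetic mean) per tissue and
#' target; each miRNA is normalized to the reference gene within tissue
#' (`dCt`), then referenced to the chosen baseline tissue
#' (`ddCt = dCt(tissue) - dCt(reference_tissue)`), giving
#' `2^-ddCt`. The reference-tissue column is identically 1 by construction.
#'
#' @param ct data.frame with columns `tissue`, `target`, `ct` and
#'   optionally `replicate`.
#' @param reference_tissue baseline tissue (default `"muscle"`).
#' @param reference_gene normalizer target name (default `"5S"`).
#' @return a `RelativeExpressionMatrix`: numeric matrix (miRNA x tissue)
#'   with attributes `reference_tissue` and `reference_gene`; missing Ct
#'   values propagate as NA.
#' @export
relative_expression <- function(ct, reference_tissue = "muscle",
                                reference_gene = "5S") {
  stopifnot(all(c("tissue", "target", "ct") %in% names(ct)))
  if (!reference_tissue %in% ct$tissue) {
    stop("reference tissue not present: ", reference_tissue)
  }
  if (!reference_gene %in% ct$target) {
    stop("reference gene not present: ", reference_gene)
  }
  bad <- is.finite(ct$ct) & ct$ct <= 0
  if (any(bad)) stop("Ct values must be positive")
  mean_ct <- tapply(ct$ct, list(ct$target, ct$tissue), mean, na.rm = TRUE)
  tissues <- colnames(mean_ct)
  targets <- setdiff(rownames(mean_ct), reference_gene)
  dct <- sweep(mean_ct[targets, , drop = FALSE], 2,
               mean_ct[reference_gene, ])
  ddct <- sweep(dct, 1, dct[, reference_tissue])
  mat <- 2^(-ddct)
  structure(mat, reference_tissue = reference_tissue,
            reference_gene = reference_gene,
            class = c("RelativeExpressionMatrix", class(mat)))
}

#' Hierarchical clustering of a relative-expression matrix
#'
#' Agglomerative clustering of miRNAs (rows) and tissues (columns) on the
#' log2-transformed values, Euclidean distance and average linkage (the
#' common heatmap defaults; both configurable). Rows and columns are sorted
#' lexicographically before clustering so the leaf order is deterministic
#' under ties; merge heights are invariant to input order. Entries with
#' missing values are excluded pairwise from the distances.
#'
#' @param mat matrix from [relative_expression()] (values > 0).
#' @param dist_method distance passed to [stats::dist()].
#' @param linkage linkage passed to [stats::hclust()].
#' @return list with `row_hclust`, `col_hclust`, `row_order`, `col_order`
#'   (leaf labels in dendrogram order) and `row_newick`, `col_newick`
#'   (Newick text for both dendrograms).
#' @export
cluster_heatmap <- function(mat, dist_method = "euclidean",
                            linkage = "average") {
  if (nrow(mat) < 2 || ncol(mat) < 2) {
    stop("clustering needs at least 2 rows and 2 columns")
  }
  lm <- log2(unclass(mat))
  lm <- lm[order(rownames(lm)), order(colnames(lm)), drop = FALSE]
  hr <- stats::hclust(stats::dist(lm, method = dist_method), method = linkage)
  hc <- stats::hclust(stats::dist(t(lm), method = dist_method),
                      method = linkage)
  list(row_hclust = hr, col_hclust = hc,
       row_order = hr$labels[hr$order],
       col_order = hc$labels[hc$order],
       row_newick = ape::write.tree(ape::as.phylo(hr)),
       col_newick = ape::write.tree(ape::as.phylo(hc)))
}

#' Synthetic Ct table with known relative expression
#'
#' Builds a stem-loop qPCR Ct table (triplicates plus the 5S normalizer per
#' tissue) whose 2^-ddCt values against the reference tissue equal a given
#' fold-change matrix exactly (up to optional replicate noise), for testing
#' the qPCR arithmetic and clustering.
#'
#' @param fold_changes numeric matrix (miRNA x tissue) of designed relative
#'   expression values; the reference tissue column should be 1.
#' @param reference_tissue baseline tissue name (must be a column).
#' @param base_ct 5S Ct level per tissue (recycled).
#' @param dct_ref miRNA dCt in the reference tissue (recycled over miRNAs).
#' @param noise_sd replicate-level Gaussian Ct noise (0 = exact design).
#' @param n_rep replicates per tissue x target.
#' @return Ct data.frame with `tissue`, `target`, `replicate`, `ct`.
#' @export
simulate_ct_table <- function(fold_changes, reference_tissue = "muscle",
                              base_ct = 15, dct_ref = 6, noise_sd = 0,
                              n_rep = 3) {
  stopifnot(reference_tissue %in% colnames(fold_changes))
  tissues <- colnames(fold_changes)
  mirnas <- rownames(fold_changes)
  base_ct <- rep_len(base_ct, length(tissues))
  dct_ref <- rep_len(dct_ref, length(mirnas))
  rows <- list()
  for (j in seq_along(tissues)) {
    rows[[length(rows) + 1L]] <- data.frame(
      tissue = tissues[j], target = "5S", replicate = seq_len(n_rep),
      ct = base_ct[j] + stats::rnorm(n_rep, 0, noise_sd))
    for (i in seq_along(mirnas)) {
      # value = 2^-(dct - dct_ref)  =>  dct = dct_ref - log2(value)
      dct <- dct_ref[i] - log2(fold_changes[i, j])
      rows[[length(rows) + 1L]] <- data.frame(
        tissue = tissues[j], target = mirnas[i], replicate = seq_len(n_rep),
        ct = base_ct[j] + dct + stats::rnorm(n_rep, 0, noise_sd))
    }
  }
  do.call(rbind, rows)
}
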