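SUBSTITUTION_TYPES <- {
  rna <- c("A", "C", "G", "U")
  x <- expand.grid(to = rna, from = rna, stringsAsFactors = FALSE)
  x <- x[x$from != x$to, c("from", "to")]
  x[order(x$from, x$to), ]
}

#' Seed-substitution spectrum over the 12 ordered base changes
#'
#' Aggregates single-nucleotide substitutions over unique tags (not
#' read-weighted, so one abundant variant cannot dominate), by default
#' restricted to the seed region (mature positions 2-8, 1-based).
#' Percentages are counts over the total substitution count times 100, and
#' 0 when no substitution exists.
#'
#' @param records support/isomiR records from [identify_conserved()] (the
#'   `support` element) or [classify_isomir()] rows.
#' @param seed_only restrict to seed-region substitutions (default TRUE).
#' @return data.frame of the 12 ordered substitution types (RNA alphabet)
#'   with `count` and `percentage`; percentages sum to 100 when any
#'   substitution exists.
#' @export
substitution_spectrum <- function(records, seed_only = TRUE) {
  keep <- !is.na(records$sub_pos)
  if (seed_only) keep <- keep & records$in_seed %in% TRUE
  sub <- records[keep, , drop = FALSE]
  sub <- sub[!duplicated(sub$tag), , drop = FALSE]  # unique tags
  from <- dna_to_rna(sub$sub_from)
  to <- dna_to_rna(sub$sub_to)
  out <- SUBSTITUTION_TYPES
  out$count <- vapply(seq_len(nrow(out)), function(i) {
    sum(from == out$from[i] & to == out$to[i])
  }, numeric(1))
  total <- sum(out$count)
  out$percentage <- if (total > 0) 100 * out$count / total else 0
  rownames(out) <- NULL
  out
}

#' Profile of the first non-templated 3' base
#'
#' Read-weighted by default (each tag contributes its read count), since
#' the question is which base the modifying enzymes add, and rare tails
#' would otherwise be over-represented after collapsing to unique tags.
#'
#' @param records support/isomiR records.
#' @param read_weighted weight tags by `count_A + count_B` (default TRUE);
#'   FALSE counts unique tags once.
#' @return data.frame with `base` (RNA alphabet), `count` and `fraction`
#'   over records with a non-empty tail; fractions sum to 1, empty profile
#'   if no tails exist.
#' @export
nta_profile <- function(records, read_weighted = TRUE) {
  tails <- records[nzchar(records$nta) & !duplicated(records$tag), ,
                   drop = FALSE]
  if (!nrow(tails)) {
    return(data.frame(base = character(0), count = numeric(0),
                      fraction = numeric(0)))
  }
  w <- if (read_weighted && all(c("count_A", "count_B") %in% names(tails))) {
    tails$count_A + tails$count_B
  } else rep(1, nrow(tails))
  first <- dna_to_rna(substr(tails$nta, 1, 1))
  cnt <- vapply(c("A", "C", "G", "U"), function(b) sum(w[first == b]),
                numeric(1))
  out <- data.frame(base = names(cnt), count = unname(cnt),
                    stringsAsFactors = FALSE)
  out$fraction <- out$count / sum(out$count)
  out
}

#' IsomiR variant table for one precursor
#'
#' All observed variants of one parent miRNA with their end annotations,
#' ordered by total read count (descending), the tabular analogue of a
#' per-precursor isomiR figure.
#'
#' @param parent parent miRNA name.
#' @param records support records from [identify_conserved()].
#' @return data.frame with `sequence` (RNA alphabet), `length`, per-library
#'   counts, total `count`, `offset5`, `offset3`, `nta`, `templated3`,
#'   `substitutions` (formatted `pos:X>Y`); row counts sum to the parent's
#'   supporting read count.
#' @export
isomir_table <- function(parent, records) {
  rec <- records[records$parent == parent, , drop = FALSE]
  subs <- ifelse(is.na(rec$sub_pos), "",
                 sprintf("%d:%s>%s", rec$sub_pos, dna_to_rna(rec$sub_from),
                         dna_to_rna(rec$sub_to)))
  out <- data.frame(sequence = dna_to_rna(rec$tag),
                    length = nchar(rec$tag),
                    count_A = rec$count_A, count_B = rec$count_B,
                    count = rec$count_A + rec$count_B,
                    offset5 = rec$offset5, offset3 = rec$offset3,
                    nta = dna_to_rna(rec$nta),
                    templated3 = rec$templated3,
                    substitutions = subs,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$count, out$sequence), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Round-trip check of isomiR records
#'
#' Re-applies each record's decomposition to its parent in the hairpin
#' context and compares the result with the tag; every classified record
#' must regenerate its tag byte-exactly.
#'
#' @param records support records.
#' @param mature named character vector of mature sequences (DNA alphabet).
#' @param hairpins named character vector of hairpin sequences.
#' @param arms arm sidecar data.frame.
#' @return logical vector, one element per record.
#' @export
isomir_roundtrip <- function(records, mature, hairpins, arms) {
  loc <- locate_matures(mature, hairpins, arms)
  vapply(seq_len(nrow(records)), function(i) {
    j <- match(records$parent[i], loc$name)
    placed <- !is.na(loc$hairpin_id[j])
    sub_pos <- records$sub_pos[i]
    rebuilt <- reconstruct_tag(
      loc$seq[j],
      hairpin = if (placed) hairpins[[loc$hairpin_id[j]]] else loc$seq[j],
      mature_start = if (placed) loc$start[j] else 0L,
      mature_end = if (placed) loc$end[j] else nchar(loc$seq[j]),
      offset5 = records$offset5[i], offset3 = records$offset3[i],
      nta = records$nta[i],
      sub_pos = if (is.na(sub_pos)) integer(0) else sub_pos,
      sub_to = if (is.na(sub_pos)) character(0) else records$sub_to[i])
    identical(rebuilt, records$tag[i])
  }, logical(1))
}
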