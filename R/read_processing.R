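#' Clean raw small-RNA reads
#'
#' Applies the standard small-RNA filter cascade in a fixed order — quality,
#' 3' adapter location/trimming, polyA, insert length — counting each
#' discarded read once under its first failing filter, so the discard ledger
#' partitions the raw reads exactly.
#'
#' Adapter detection finds the longest exact match (at least `min_adapter`
#' nt) of a prefix of `adapter3` anywhere in the read; the insert is
#' everything 5' of that match. Reads with no detectable adapter, or with an
#' empty insert (adapter at the first cycle), are discarded as
#' `adapter_only_or_missing`.
#'
#' @param fastq path to a FASTQ file (Sanger qualities) or an in-memory read
#'   list with `id`, `seq`, `qual`.
#' @param adapter3 3' adapter sequence.
#' @param min_len,max_len retained insert length window (defaults 18-30 nt).
#' @param max_below_q20 maximum tolerated number of bases below Q20 before a
#'   read is discarded as low-quality.
#' @param polya_frac insert A-fraction at or above which a read is discarded
#'   as polyA.
#' @param min_adapter minimum adapter prefix length for a match.
#' @return list with `inserts` (clean insert sequences) and `summary`
#'   (raw_reads, clean_reads, clean_fraction, and per-filter discard counts
#'   `low_quality`, `adapter_only_or_missing`, `polyA`,
#'   `length_out_of_range`).
#' @export
clean_reads <- function(fastq, adapter3, min_len = 18L, max_len = 30L,
                        max_below_q20 = 1L, polya_frac = 0.8,
                        min_adapter = 6L) {
  reads <- as_read_list(fastq)
  seqs <- toupper(reads$seq)
  quals <- reads$qual
  n <- length(seqs)

  # Q20 in Sanger encoding is '5' (ASCII 53); anything in [!-4] is below
  n_below <- nchar(quals) - nchar(gsub("[!-4]", "", quals))
  fail_q <- n_below > max_below_q20

  adapter3 <- toupper(adapter3)
  kmax <- min(nchar(adapter3), max(nchar(seqs)))
  pos <- rep(-1L, n)
  for (k in seq(kmax, min_adapter)) {
    idx <- which(pos < 0L)
    if (!length(idx)) break
    p <- regexpr(substr(adapter3, 1L, k), seqs[idx], fixed = TRUE)
    hit <- p > 0L
    pos[idx[hit]] <- p[hit]
  }
  insert <- ifelse(pos > 1L, substr(seqs, 1L, pos - 1L), "")
  fail_a <- !fail_q & pos < 2L

  len <- nchar(insert)
  n_a <- nchar(insert) - nchar(gsub("A", "", insert, fixed = TRUE))
  fail_p <- !fail_q & !fail_a & (n_a / pmax(len, 1L)) >= polya_frac
  fail_l <- !fail_q & !fail_a & !fail_p & (len < min_len | len > max_len)

  clean <- !(fail_q | fail_a | fail_p | fail_l)
  summary <- list(raw_reads = n,
                  clean_reads = sum(clean),
                  clean_fraction = if (n > 0) sum(clean) / n else NA_real_,
                  unique_tags = length(unique(insert[clean])),
                  discards = c(low_quality = sum(fail_q),
                               adapter_only_or_missing = sum(fail_a),
                               polyA = sum(fail_p),
                               length_out_of_range = sum(fail_l)))
  list(inserts = insert[clean], summary = summary)
}

# accept a FASTQ path or an in-memory read list; structural errors name the
# offending record index
as_read_list <- function(fastq) {
  if (is.list(fastq) && all(c("seq", "qual") %in% names(fastq))) {
    return(fastq)
  }
  if (!is.character(fastq) || length(fastq) != 1L) {
    stop("fastq must be a file path or a list with seq and qual")
  }
  lines <- readLines(fastq)
  if (length(lines) %% 4L != 0L) {
    stop(sprintf("malformed FASTQ record %d: truncated file",
                 length(lines) %/% 4L + 1L))
  }
  ids <- lines[seq(1, length(lines), by = 4)]
  seqs <- lines[seq(2, length(lines), by = 4)]
  plus <- lines[seq(3, length(lines), by = 4)]
  quals <- lines[seq(4, length(lines), by = 4)]
  bad <- which(!startsWith(ids, "@") | !startsWith(plus, "+") |
                 nchar(seqs) != nchar(quals))
  if (length(bad)) {
    stop(sprintf("malformed FASTQ record %d", bad[1]))
  }
  list(id = sub("^@", "", ids), seq = seqs, qual = quals)
}

#' Collapse clean inserts into unique tags
#'
#' One tag per distinct sequence with its read count, ordered by descending
#' count then lexicographically, so output order is deterministic.
#'
#' @param inserts character vector of clean insert sequences.
#' @return data.frame with columns `seq`, `count`; `sum(count)` equals
#'   `length(inserts)`.
#' @export
collapse_unique <- function(inserts) {
  if (!length(inserts)) {
    return(data.frame(seq = character(0), count = integer(0),
                      stringsAsFactors = FALSE))
  }
  tab <- table(inserts)
  out <- data.frame(seq = names(tab), count = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$count, out$seq), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read-length distribution of a tag set
#'
#' @param tags a tag data.frame from [collapse_unique()].
#' @return data.frame with `length`, `reads` and `fraction` (of total
#'   reads); fractions sum to 1.
#' @export
length_distribution <- function(tags) {
  if (!nrow(tags)) {
    return(data.frame(length = integer(0), reads = integer(0),
                      fraction = numeric(0)))
  }
  len <- nchar(tags$seq)
  reads <- tapply(tags$count, len, sum)
  out <- data.frame(length = as.integer(names(reads)),
                    reads = as.integer(reads))
  out$fraction <- out$reads / sum(out$reads)
  rownames(out) <- NULL
  out[order(out$length), , drop = FALSE]
}

#' Common and library-specific unique tags
#'
#' @param tags_A,tags_B tag data.frames from [collapse_unique()].
#' @return list with unique-tag counts `common`, `A_only`, `B_only`;
#'   `common + A_only` equals `nrow(tags_A)` and likewise for B.
#' @export
common_specific <- function(tags_A, tags_B) {
  common <- sum(tags_A$seq %in% tags_B$seq)
  list(common = common,
       A_only = nrow(tags_A) - common,
       B_only = nrow(tags_B) - common)
}

#' Write collapsed tags in the `>tag{i}_x{count}` FASTA dialect
#'
#' @param tags tag data.frame from [collapse_unique()].
#' @param path output FASTA path.
#' @return invisibly, the path.
#' @export
write_tag_fasta <- function(tags, path) {
  x <- stats::setNames(tags$seq,
                       sprintf("tag%d_x%d", seq_len(nrow(tags)), tags$count))
  write_fasta_chr(x, path)
}
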