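#' Scan transcripts for miRNA seed-match target sites
#'
#' Finds transcript sites complementary to the miRNA seed (positions 2-8,
#' 1-based) using the canonical seed-site taxonomy: a 6mer matches the
#' reverse complement of positions 2-7; 7mer-m8 additionally pairs position
#' 8 (one base upstream on the transcript); 7mer-A1 adds an A in the
#' transcript slot opposite position 1 (one base downstream); an 8mer has
#' both. Every 6mer core occurrence is reported once with its most specific
#' type. The whole transcript is scanned (the transcript set stands in for
#' unannotated UTRs).
#'
#' @param mirnas named character vector of mature miRNA sequences (DNA or
#'   RNA alphabet).
#' @param transcripts named character vector of transcript sequences, or a
#'   FASTA path.
#' @return data.frame of `TargetSite` rows: `mirna`, `transcript`,
#'   `site_start` (0-based start of the typed site), `site_type`,
#'   `core_start` (0-based start of the 6mer core, for set comparisons).
#' @export
scan_targets <- function(mirnas, transcripts) {
  if (is.character(transcripts) && is.null(names(transcripts)) &&
      length(transcripts) == 1) {
    transcripts <- read_fasta_chr(transcripts)
  }
  mirnas <- stats::setNames(rna_to_dna(toupper(mirnas)), names(mirnas))
  if (any(nchar(mirnas) < 8)) stop("miRNAs must be at least 8 nt")
  rows <- list()
  subjects <- lapply(transcripts, Biostrings::DNAString)
  for (mi in names(mirnas)) {
    m <- mirnas[[mi]]
    core <- revcomp(substr(m, 2, 7))   # transcript match, 5'->3'
    m8c <- revcomp(substr(m, 8, 8))    # pairs miRNA position 8, 5' of core
    for (tx in names(subjects)) {
      hits <- Biostrings::matchPattern(core, subjects[[tx]])
      if (!length(hits)) next
      s0 <- Biostrings::start(hits) - 1L  # 0-based core start
      txseq <- transcripts[[tx]]
      up <- ifelse(s0 >= 1L, substring(txseq, s0, s0), "")
      dn <- substring(txseq, s0 + 7L, s0 + 7L)
      has_m8 <- up == m8c
      has_a1 <- dn == "A"
      type <- ifelse(has_m8 & has_a1, "8mer",
                     ifelse(has_m8, "7mer-m8",
                            ifelse(has_a1, "7mer-A1", "6mer")))
      start <- ifelse(has_m8, s0 - 1L, s0)
      rows[[length(rows) + 1L]] <- data.frame(
        mirna = mi, transcript = tx, site_start = as.integer(start),
        site_type = type, core_start = as.integer(s0),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(mirna = character(0), transcript = character(0),
                      site_start = integer(0), site_type = character(0),
                      core_start = integer(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$mirna, out$transcript, out$core_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Re-verify reported target sites by direct complement comparison
#'
#' Independent check that each reported site's transcript slice is the
#' reverse complement of the required seed positions for its type.
#'
#' @param sites data.frame from [scan_targets()].
#' @param mirnas,transcripts the sequence sets used for the scan.
#' @return logical vector, one element per site.
#' @export
verify_target_sites <- function(sites, mirnas, transcripts) {
  mirnas <- stats::setNames(rna_to_dna(toupper(mirnas)), names(mirnas))
  vapply(seq_len(nrow(sites)), function(i) {
    m <- mirnas[[sites$mirna[i]]]
    tx <- transcripts[[sites$transcript[i]]]
    s0 <- sites$core_start[i]
    ok <- substr(tx, s0 + 1L, s0 + 6L) == revcomp(substr(m, 2, 7))
    type <- sites$site_type[i]
    if (type %in% c("7mer-m8", "8mer")) {
      ok <- ok && s0 >= 1L &&
        substr(tx, s0, s0) == revcomp(substr(m, 8, 8))
    }
    if (type %in% c("7mer-A1", "8mer")) {
      ok <- ok && substr(tx, s0 + 7L, s0 + 7L) == "A"
    }
    ok
  }, logical(1))
}
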