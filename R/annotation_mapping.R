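ANNOTATION_PRIORITY <- c("rRNA", "scRNA", "snRNA", "snoRNA", "tRNA",
                         "repeat", "exon", "intron")

#' Percentage summary of a mapping run
#'
#' Report-time arithmetic for the standard mapping summary: percentages are
#' numerator/denominator rounded to two decimals, computed nowhere else.
#'
#' @param mapped_reads,clean_reads read-level numerator and denominator.
#' @param mapped_unique,unique_tags unique-tag-level numerator and
#'   denominator.
#' @return list with `mapped_reads_pct` and `mapped_unique_pct`.
#' @export
mapping_summary <- function(mapped_reads, clean_reads, mapped_unique,
                            unique_tags) {
  list(mapped_reads_pct = round(100 * mapped_reads / clean_reads, 2),
       mapped_unique_pct = round(100 * mapped_unique / unique_tags, 2))
}

#' Map tags to a genome with at most one mismatch
#'
#' Reports every locus (both strands) where a tag aligns with at most
#' `max_mismatch` substitutions, using an exact substring scan
#' (Biostrings match engine). Unmapped tags are a result, not an error: a
#' tag counts as mapped if it has at least one hit.
#'
#' @param tags tag data.frame (`seq`, `count`) from [collapse_unique()].
#' @param genome named character vector of reference sequences, or a FASTA
#'   path.
#' @param max_mismatch maximum substitutions per hit (default 1).
#' @return list with `hits` (data.frame: tag, ref, start 0-based, strand,
#'   mismatches) and `summary` (mapped reads/unique counts plus the
#'   [mapping_summary()] percentages).
#' @export
map_tags <- function(tags, genome, max_mismatch = 1L) {
  if (is.character(genome) && is.null(names(genome)) && length(genome) == 1 &&
      file.exists(genome)) {
    genome <- read_fasta_chr(genome)
  }
  if (!length(genome) || !all(nzchar(genome))) stop("genome is empty")
  counts <- if ("count" %in% names(tags)) tags$count else
    tags$count_A + tags$count_B
  subjects <- lapply(genome, Biostrings::DNAString)

  res <- vector("list", nrow(tags))
  for (i in seq_len(nrow(tags))) {
    tag <- tags$seq[i]
    rows <- list()
    for (ref in names(subjects)) {
      for (strand in c("+", "-")) {
        pat <- if (strand == "+") tag else revcomp(tag)
        m <- Biostrings::matchPattern(pat, subjects[[ref]],
                                      max.mismatch = max_mismatch)
        m <- m[Biostrings::start(m) >= 1 &
                 Biostrings::end(m) <= length(subjects[[ref]])]
        if (length(m)) {
          nm <- vapply(as.character(m), function(s) hamming(pat, s),
                       numeric(1), USE.NAMES = FALSE)
          rows[[length(rows) + 1L]] <-
            data.frame(tag = tag, ref = ref,
                       start = Biostrings::start(m) - 1L,
                       strand = strand, mismatches = nm,
                       stringsAsFactors = FALSE)
        }
      }
    }
    if (length(rows)) res[[i]] <- do.call(rbind, rows)
  }
  hits <- do.call(rbind, res[!vapply(res, is.null, logical(1))])
  if (is.null(hits)) {
    hits <- data.frame(tag = character(0), ref = character(0),
                       start = integer(0), strand = character(0),
                       mismatches = integer(0), stringsAsFactors = FALSE)
  }
  mapped_tag <- tags$seq %in% hits$tag
  clean_reads <- sum(counts)
  summary <- c(list(mapped_reads = sum(counts[mapped_tag]),
                    clean_reads = clean_reads,
                    mapped_unique = sum(mapped_tag),
                    unique_tags = nrow(tags)),
               mapping_summary(sum(counts[mapped_tag]), clean_reads,
                               sum(mapped_tag), nrow(tags)))
  list(hits = hits, summary = summary)
}

#' Read category references from FASTA
#'
#' Category references carry their class as a `category=` key in the FASTA
#' description, e.g. `>rRNA_1 category=rRNA`.
#'
#' @param path FASTA path.
#' @return named character vector with a `category` attribute.
#' @export
read_category_fasta <- function(path) {
  x <- read_fasta_chr(path)
  cat <- sub(".*category=([^ ]+).*", "\\1", names(x))
  ids <- sub(" .*", "", names(x))
  bad <- setdiff(unique(cat), ANNOTATION_PRIORITY)
  if (length(bad)) {
    stop("unknown category label in reference: ", paste(bad, collapse = ", "))
  }
  names(x) <- ids
  attr(x, "category") <- cat
  x
}

# all references concatenated into one subject per strand; separator runs
# of N are longer than any tag so a match can never span two references,
# and the block boundaries recover the category of each hit
category_subjects <- function(refs, categories) {
  sep <- strrep("N", 40)
  starts <- cumsum(c(1L, utils::head(nchar(refs) + 40L, -1)))
  list(fwd = Biostrings::DNAString(paste(refs, collapse = sep)),
       rev = Biostrings::DNAString(paste(revcomp(refs), collapse = sep)),
       starts = starts, categories = categories)
}

#' Annotate tags into ncRNA and genomic categories
#'
#' Each tag is assigned exactly one category by a fixed priority order
#' (rRNA > scRNA > snRNA > snoRNA > tRNA > repeat > exon > intron), the
#' deterministic stand-in for a database search: a tag matches a category if
#' it occurs as a substring of one of its references on either strand with
#' at most `max_mismatch` substitutions. Strand resolves the sense/antisense
#' split for exon and intron classes (sense checked first). Tags matching
#' nothing are `unannotated` and are the ones retained for miRNA analysis.
#'
#' @param tags tag data.frame (`seq`, `count`).
#' @param references named character vector with a `category` attribute (see
#'   [read_category_fasta()]).
#' @param transcripts optional named character vector of transcript
#'   sequences, treated as `exon` references (the degraded-mRNA screen).
#' @param max_mismatch maximum substitutions for a category match.
#' @return data.frame with `tag`, `count`, `category`.
#' @export
annotate_tags <- function(tags, references = character(0), transcripts = NULL,
                          max_mismatch = 1L) {
  cat_labels <- attr(references, "category")
  if (length(references) && is.null(cat_labels)) {
    stop("references must carry a category attribute")
  }
  bad <- setdiff(unique(cat_labels), ANNOTATION_PRIORITY)
  if (length(bad)) {
    stop("unknown category label in reference: ", paste(bad, collapse = ", "))
  }
  refs <- as.character(references)
  if (length(transcripts)) {
    refs <- c(refs, as.character(transcripts))
    cat_labels <- c(cat_labels, rep("exon", length(transcripts)))
  }
  counts <- if ("count" %in% names(tags)) tags$count else
    tags$count_A + tags$count_B
  category <- rep("unannotated", nrow(tags))
  if (length(refs)) {
    subj <- category_subjects(refs, cat_labels)
    hit_cats <- function(tag, strand) {
      m <- Biostrings::matchPattern(
        tag, if (strand == "+") subj$fwd else subj$rev,
        max.mismatch = max_mismatch)
      if (!length(m)) return(character(0))
      blk <- findInterval(Biostrings::start(m), subj$starts)
      unique(subj$categories[blk])
    }
    for (i in seq_len(nrow(tags))) {
      sense <- hit_cats(tags$seq[i], "+")
      anti <- hit_cats(tags$seq[i], "-")
      for (cc in ANNOTATION_PRIORITY) {
        in_s <- cc %in% sense
        in_a <- cc %in% anti
        if (in_s || in_a) {
          category[i] <- if (cc %in% c("exon", "intron")) {
            paste0(cc, if (in_s) "_sense" else "_antisense")
          } else cc
          break
        }
      }
    }
  }
  data.frame(tag = tags$seq, count = counts, category = category,
             stringsAsFactors = FALSE)
}

#' Tags retained for miRNA analysis
#'
#' Exactly the unannotated tags pass through to miRNA identification; all
#' annotated ncRNA/genomic classes are removed.
#'
#' @param records annotation data.frame from [annotate_tags()].
#' @return tag data.frame (`seq`, `count`) of unannotated tags.
#' @export
retain_for_mirna <- function(records) {
  keep <- records$category == "unannotated"
  data.frame(seq = records$tag[keep], count = records$count[keep],
             stringsAsFactors = FALSE)
}

#' Per-category annotation summary (unique tags and reads)
#'
#' @param records annotation data.frame from [annotate_tags()].
#' @return data.frame with `category`, `unique_tags`, `reads`, and their
#'   fractions; both count columns sum to the input totals.
#' @export
annotation_summary <- function(records) {
  cats <- sort(unique(records$category))
  ut <- vapply(cats, function(cc) sum(records$category == cc), integer(1))
  rd <- vapply(cats, function(cc) sum(records$count[records$category == cc]),
               numeric(1))
  data.frame(category = cats, unique_tags = ut, reads = rd,
             unique_fraction = ut / sum(ut), read_fraction = rd / sum(rd),
             row.names = NULL, stringsAsFactors = FALSE)
}
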