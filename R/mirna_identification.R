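#' Merge per-library tag tables into one two-column count table
#'
#' @param tags_A,tags_B tag data.frames from [collapse_unique()].
#' @return data.frame with `seq`, `count_A`, `count_B` over the union of
#'   tags (0 where a tag is absent from a library), ordered by descending
#'   total count then sequence.
#' @export
merge_tag_counts <- function(tags_A, tags_B) {
  seqs <- union(tags_A$seq, tags_B$seq)
  a <- tags_A$count[match(seqs, tags_A$seq)]
  b <- tags_B$count[match(seqs, tags_B$seq)]
  out <- data.frame(seq = seqs,
                    count_A = ifelse(is.na(a), 0L, a),
                    count_B = ifelse(is.na(b), 0L, b),
                    stringsAsFactors = FALSE)
  out <- out[order(-(out$count_A + out$count_B), out$seq), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# locate every mature sequence on a hairpin: use the arm sidecar when
# given, fall back to exact substring search; unplaceable matures get
# arm "unknown" and are classified against themselves (no hairpin context)
locate_matures <- function(mature, hairpins, arms = NULL) {
  out <- data.frame(name = names(mature), seq = unname(mature),
                    hairpin_id = NA_character_, start = NA_integer_,
                    end = NA_integer_, arm = "unknown",
                    stringsAsFactors = FALSE)
  if (!is.null(arms)) {
    for (col in c("mature_name", "star_name")) {
      hit <- match(out$name, arms[[col]])
      ok <- !is.na(hit)
      pre <- if (col == "mature_name") "mature" else "star"
      out$hairpin_id[ok] <- arms$hairpin_id[hit[ok]]
      out$start[ok] <- arms[[paste0(pre, "_start")]][hit[ok]]
      out$end[ok] <- arms[[paste0(pre, "_end")]][hit[ok]]
    }
  }
  todo <- which(is.na(out$hairpin_id))
  for (i in todo) {
    for (h in names(hairpins)) {
      p <- regexpr(out$seq[i], hairpins[[h]], fixed = TRUE)
      if (p > 0) {
        out$hairpin_id[i] <- h
        out$start[i] <- p - 1L
        out$end[i] <- p - 1L + nchar(out$seq[i])
        break
      }
    }
  }
  miss <- is.na(out$hairpin_id)
  if (any(miss)) {
    warning("mature sequence(s) absent from every hairpin: ",
            paste(out$name[miss], collapse = ", "))
  }
  placed <- !miss
  H <- ifelse(placed, nchar(hairpins[out$hairpin_id]), nchar(out$seq))
  out$arm[placed] <- ifelse((out$start[placed] + out$end[placed]) / 2 <
                              H[placed] / 2, "5p", "3p")
  # sanity: the sidecar interval must reproduce the mature sequence
  chk <- placed & substr(hairpins[out$hairpin_id], out$start + 1L,
                         out$end) != out$seq
  if (any(chk, na.rm = TRUE)) {
    stop("arm sidecar interval does not match mature sequence for: ",
         paste(out$name[which(chk)], collapse = ", "))
  }
  out
}

#' Decompose a tag relative to its parent miRNA
#'
#' Finds the minimal-edit explanation of a tag as an isomiR of a mature
#' miRNA in its hairpin context: signed 5'/3' end offsets (negative =
#' trimmed, positive = extended), substitutions on mature coordinates, and a
#' non-templated 3' tail (the suffix of the 3' extension from its first
#' base that disagrees with the hairpin continuation). Competing
#' decompositions are ranked by `|offset5| + |offset3| + substitutions`,
#' ties broken by smaller `|offset5|`, then by the more 5'-trimmed
#' candidate, which makes classification deterministic. A 5' extension must
#' match the hairpin exactly.
#'
#' @param tag tag sequence (DNA alphabet).
#' @param mature parent mature sequence.
#' @param hairpin hairpin sequence (defaults to the mature itself when no
#'   hairpin context exists).
#' @param mature_start,mature_end 0-based half-open mature interval on the
#'   hairpin.
#' @param max_mismatch maximum substitutions (default 1).
#' @param max_shift maximum absolute end offset (default 4).
#' @return a one-row data.frame (`tag`, `parent`, `offset5`, `offset3`,
#'   `templated3`, `nta`, `sub_pos`, `sub_from`, `sub_to`, `in_seed`,
#'   `cost`) or NULL when no decomposition exists within the gate.
#' @export
classify_isomir <- function(tag, mature, hairpin = mature,
                            mature_start = 0L,
                            mature_end = nchar(mature),
                            max_mismatch = 1L, max_shift = 4L,
                            parent = NA_character_) {
  stopifnot(substr(hairpin, mature_start + 1L, mature_end) == mature)
  len <- nchar(tag)
  ml <- nchar(mature)
  H <- nchar(hairpin)
  tg <- strsplit(tag, "", fixed = TRUE)[[1]]
  hp <- strsplit(hairpin, "", fixed = TRUE)[[1]]

  best <- NULL
  for (o5 in seq(-max_shift, max_shift)) {
    # offsets are signed with negative = trimmed: tag start on hairpin is
    # mature_start - o5, so len = ml + o5 + o3
    o3 <- len - ml - o5
    if (abs(o3) > max_shift) next
    hstart <- mature_start - o5
    hend <- mature_end + o3
    if (hstart < 0 || hend > H || hend <= hstart) next
    ref <- hp[(hstart + 1L):hend]
    mm <- which(tg != ref)
    # hairpin coordinate (0-based) of each tag position
    coord <- hstart + (seq_len(len) - 1L)
    if (any(coord[mm] < mature_start)) next  # 5' extension must be templated
    ext_mm <- mm[coord[mm] >= mature_end]
    nta <- ""
    if (length(ext_mm)) {
      nta <- substr(tag, min(ext_mm), len)
    }
    core_mm <- mm[coord[mm] >= mature_start & coord[mm] < mature_end]
    if (length(core_mm) > max_mismatch) next
    cost <- abs(o5) + abs(o3) + length(core_mm)
    cand <- list(o5 = o5, o3 = o3, nta = nta, core_mm = core_mm, cost = cost)
    if (is.null(best) || cost < best$cost ||
        (cost == best$cost && abs(o5) < abs(best$o5)) ||
        (cost == best$cost && abs(o5) == abs(best$o5) && o5 < best$o5)) {
      best <- cand
    }
  }
  if (is.null(best)) return(NULL)
  # tag position k (1-based) sits at 1-based mature position k - offset5
  sub_pos1 <- as.integer(best$core_mm - best$o5)
  has_sub <- length(sub_pos1) > 0L
  data.frame(tag = tag, parent = parent,
             offset5 = as.integer(best$o5), offset3 = as.integer(best$o3),
             templated3 = best$o3 > 0L && !nzchar(best$nta),
             nta = best$nta,
             sub_pos = if (has_sub) sub_pos1[1] else NA_integer_,
             sub_from = if (has_sub) substr(mature, sub_pos1[1], sub_pos1[1]) else NA_character_,
             sub_to = if (has_sub) substr(tag, best$core_mm[1], best$core_mm[1]) else NA_character_,
             in_seed = if (has_sub) sub_pos1[1] >= 2L && sub_pos1[1] <= 8L else NA,
             cost = best$cost,
             stringsAsFactors = FALSE)
}

# vectorised coarse screen: for every (mature, 5'-offset, tag-length)
# combination, count raw mismatches of all tags of that length against the
# corresponding hairpin slice; survivors go to the exact classifier
support_candidates <- function(tags, loc, hairpins, max_mismatch, max_shift) {
  by_len <- split(seq_len(nrow(tags)), nchar(tags$seq))
  mats <- lapply(by_len, function(idx) {
    do.call(cbind, strsplit(tags$seq[idx], "", fixed = TRUE))
  })
  out <- list()
  for (j in seq_len(nrow(loc))) {
    ml <- nchar(loc$seq[j])
    placed <- !is.na(loc$hairpin_id[j])
    hseq <- if (placed) hairpins[[loc$hairpin_id[j]]] else loc$seq[j]
    ms <- if (placed) loc$start[j] else 0L
    me <- if (placed) loc$end[j] else ml
    H <- nchar(hseq)
    hp <- strsplit(hseq, "", fixed = TRUE)[[1]]
    cand <- integer(0)
    for (o5 in seq(-max_shift, max_shift)) {
      for (L in as.integer(names(by_len))) {
        o3 <- L - ml - o5
        if (abs(o3) > max_shift) next
        hstart <- ms - o5
        hend <- me + o3
        if (hstart < 0 || hend > H || hend <= hstart) next
        ref <- hp[(hstart + 1L):hend]
        mm <- colSums(mats[[as.character(L)]] != ref)
        ok <- mm <= max_mismatch + max(o3, 0L)
        if (any(ok)) cand <- c(cand, by_len[[as.character(L)]][ok])
      }
    }
    if (length(cand)) {
      out[[length(out) + 1L]] <- data.frame(tag_idx = unique(cand),
                                            mature_idx = j)
    }
  }
  if (!length(out)) {
    return(data.frame(tag_idx = integer(0), mature_idx = integer(0)))
  }
  do.call(rbind, out)
}

#' Identify conserved miRNAs from a tag table
#'
#' A tag supports a miRNA when it decomposes against the mature reference
#' (in its hairpin context) with at most `max_mismatch` substitutions and
#' 5'/3' end offsets each at most `max_shift` (see [classify_isomir()]).
#' Entry counts are the sums of supporting tag counts per library; a miRNA
#' counts as identified in a library when its count there is at least 1.
#' Tags supporting several mature references are attributed to each and
#' flagged `ambiguous`.
#'
#' @param tags merged tag table (`seq`, `count_A`, `count_B`), e.g. from
#'   [merge_tag_counts()]; a single-library table (`seq`, `count`) is
#'   accepted and treated as library A.
#' @param mature named character vector of mature (and star) sequences, or
#'   a FASTA path (RNA alphabet accepted).
#' @param hairpins named character vector of hairpin sequences or FASTA
#'   path.
#' @param arms optional arm sidecar data.frame (see
#'   [generate_references()]).
#' @param max_mismatch,max_shift identification gate (defaults 1 and 4).
#' @return list with `catalog` (name, family, arm, seq, count_A, count_B,
#'   n_tags) and `support` (one row per tag x miRNA assignment with the
#'   full isomiR decomposition).
#' @export
identify_conserved <- function(tags, mature, hairpins, arms = NULL,
                               max_mismatch = 1L, max_shift = 4L) {
  if (is.character(mature) && is.null(names(mature)) && length(mature) == 1) {
    mature <- read_fasta_chr(mature)
  }
  if (is.character(hairpins) && is.null(names(hairpins)) &&
      length(hairpins) == 1) {
    hairpins <- read_fasta_chr(hairpins)
  }
  mature <- stats::setNames(rna_to_dna(toupper(mature)), names(mature))
  hairpins <- stats::setNames(rna_to_dna(toupper(hairpins)), names(hairpins))
  if (!"count_A" %in% names(tags)) {
    tags <- data.frame(seq = tags$seq, count_A = tags$count, count_B = 0L,
                       stringsAsFactors = FALSE)
  }
  loc <- locate_matures(mature, hairpins, arms)

  support <- list()
  if (nrow(tags)) {
    cand <- support_candidates(tags, loc, as.list(hairpins),
                               max_mismatch, max_shift)
    for (r in seq_len(nrow(cand))) {
      i <- cand$tag_idx[r]; j <- cand$mature_idx[r]
      placed <- !is.na(loc$hairpin_id[j])
      rec <- classify_isomir(
        tags$seq[i], loc$seq[j],
        hairpin = if (placed) hairpins[[loc$hairpin_id[j]]] else loc$seq[j],
        mature_start = if (placed) loc$start[j] else 0L,
        mature_end = if (placed) loc$end[j] else nchar(loc$seq[j]),
        max_mismatch = max_mismatch, max_shift = max_shift,
        parent = loc$name[j])
      if (!is.null(rec)) {
        rec$count_A <- tags$count_A[i]
        rec$count_B <- tags$count_B[i]
        support[[length(support) + 1L]] <- rec
      }
    }
  }
  support <- if (length(support)) do.call(rbind, support) else
    data.frame(tag = character(0), parent = character(0),
               offset5 = integer(0), offset3 = integer(0),
               templated3 = logical(0), nta = character(0),
               sub_pos = integer(0), sub_from = character(0),
               sub_to = character(0), in_seed = logical(0),
               cost = numeric(0), count_A = integer(0), count_B = integer(0),
               stringsAsFactors = FALSE)
  support$ambiguous <- support$tag %in%
    support$tag[duplicated(support$tag)]
  support <- support[order(support$parent, -(support$count_A + support$count_B),
                           support$tag), , drop = FALSE]
  rownames(support) <- NULL

  count_A <- vapply(loc$name, function(nm) {
    sum(support$count_A[support$parent == nm])
  }, numeric(1))
  count_B <- vapply(loc$name, function(nm) {
    sum(support$count_B[support$parent == nm])
  }, numeric(1))
  n_tags <- vapply(loc$name, function(nm) sum(support$parent == nm),
                   numeric(1))
  catalog <- data.frame(name = loc$name,
                        family = mirna_family(loc$name),
                        arm = loc$arm,
                        seq = loc$seq,
                        count_A = as.integer(count_A),
                        count_B = as.integer(count_B),
                        n_tags = as.integer(n_tags),
                        stringsAsFactors = FALSE)
  catalog <- catalog[catalog$n_tags > 0L, , drop = FALSE]
  rownames(catalog) <- NULL
  list(catalog = catalog, support = support)
}

#' miRNA family from a miRBase-style name
#'
#' Grammar: strip the species prefix (e.g. `mam-`), any star mark, the
#' `-5p`/`-3p` arm suffix, a trailing duplicate-locus index (`-1`, `-2`,
#' ...), and trailing lowercase variant letters, so `mam-miR-199a-3p`,
#' `mam-miR-199-3p` and `miR-199b` all map to family `miR-199`, and the
#' let-7 variants collapse to `let-7`.
#'
#' @param names character vector of miRNA names.
#' @return character vector of family names.
#' @export
mirna_family <- function(names) {
  f <- sub("^[A-Za-z]{2,4}-(?=(miR|mir|let))", "", names, perl = TRUE)
  f <- sub("\\*$", "", f)
  f <- sub("-(5p|3p)$", "", f)
  # a duplicate-locus index only follows a variant letter (miR-199a-1);
  # a bare trailing number is the miRNA number itself and stays
  f <- sub("(?<=[a-z])-\\d+$", "", f, perl = TRUE)
  f <- sub("(?<=\\d)[a-z]+$", "", f, perl = TRUE)
  f
}

#' Group a catalog into miRNA families
#'
#' @param catalog catalog data.frame from [identify_conserved()].
#' @return named list mapping each family to its catalog rows; family sizes
#'   sum to the catalog size.
#' @export
group_families <- function(catalog) {
  split(catalog, catalog$family)
}

#' Most abundant miRNAs and their cumulative read share
#'
#' @param catalog catalog data.frame.
#' @param library `"A"` or `"B"`.
#' @param k number of top entries (default 10).
#' @return list with `top` (catalog rows, descending count, ties broken by
#'   name) and `cumulative_fraction` of all catalog reads in that library
#'   carried by the top `k`.
#' @export
rank_abundance <- function(catalog, library = c("A", "B"), k = 10L) {
  library <- match.arg(library)
  col <- paste0("count_", library)
  ord <- order(-catalog[[col]], catalog$name)
  top <- utils::head(catalog[ord, , drop = FALSE], k)
  total <- sum(catalog[[col]])
  list(top = top,
       cumulative_fraction = if (total > 0) sum(top[[col]]) / total else NA_real_)
}

#' First-base and per-position base composition of miRNA tags
#'
#' @param seqs character vector of (unique) miRNA-supporting tag sequences,
#'   DNA alphabet.
#' @return list of two matrices in the RNA alphabet (`A`,`C`,`G`,`U`):
#'   `first_base` (rows = tag length) and `positional` (rows = position);
#'   every row sums to 1.
#' @export
base_bias <- function(seqs) {
  rna <- c("A", "C", "G", "U")
  seqs <- dna_to_rna(toupper(seqs))
  lens <- sort(unique(nchar(seqs)))
  first <- substr(seqs, 1, 1)
  fb <- t(vapply(lens, function(L) {
    f <- first[nchar(seqs) == L]
    vapply(rna, function(b) mean(f == b), numeric(1))
  }, numeric(4)))
  rownames(fb) <- lens
  maxlen <- max(nchar(seqs))
  pos <- t(vapply(seq_len(maxlen), function(p) {
    ch <- substr(seqs[nchar(seqs) >= p], p, p)
    vapply(rna, function(b) mean(ch == b), numeric(1))
  }, numeric(4)))
  rownames(pos) <- seq_len(maxlen)
  list(first_base = fb, positional = pos)
}

#' Detect miRNA:miRNA* duplex-like pairs
#'
#' A pair is emitted for every hairpin whose mature and star arms both have
#' catalog entries with at least one read in either library. The 3'
#' overhang of each duplex end follows from the arm interval geometry under
#' the intramolecular pairing map `i <-> H - 1 - i`: the mature 3' overhang
#' is `star_start - (H - mature_end)` and the star 3' overhang is
#' `mature_start - (H - star_end)` (both 2 for a canonical Dicer duplex).
#'
#' @param catalog catalog data.frame from [identify_conserved()].
#' @param arms arm sidecar data.frame.
#' @param hairpins named character vector of hairpin sequences.
#' @return data.frame with one row per detected pair: `hairpin_id`,
#'   `mature_name`, `star_name`, per-library counts, and both 3' overhangs.
#' @export
detect_duplexes <- function(catalog, arms, hairpins) {
  rows <- list()
  for (j in seq_len(nrow(arms))) {
    mn <- arms$mature_name[j]; sn <- arms$star_name[j]
    if (is.na(sn)) next
    im <- match(mn, catalog$name); is <- match(sn, catalog$name)
    if (is.na(im) || is.na(is)) next
    if (catalog$count_A[im] + catalog$count_B[im] < 1 ||
        catalog$count_A[is] + catalog$count_B[is] < 1) next
    H <- nchar(hairpins[[arms$hairpin_id[j]]])
    rows[[length(rows) + 1L]] <- data.frame(
      hairpin_id = arms$hairpin_id[j],
      mature_name = mn, star_name = sn,
      mature_count_A = catalog$count_A[im],
      mature_count_B = catalog$count_B[im],
      star_count_A = catalog$count_A[is],
      star_count_B = catalog$count_B[is],
      overhang_mature3 = arms$star_start[j] - (H - arms$mature_end[j]),
      overhang_star3 = arms$mature_start[j] - (H - arms$star_end[j]),
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    return(data.frame(hairpin_id = character(0), mature_name = character(0),
                      star_name = character(0), mature_count_A = integer(0),
                      mature_count_B = integer(0), star_count_A = integer(0),
                      star_count_B = integer(0), overhang_mature3 = integer(0),
                      overhang_star3 = integer(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}
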