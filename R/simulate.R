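#' Simulation configuration for a two-library small-RNA experiment
#'
#' Builds and validates the parameter set for the synthetic read generator.
#' The generator emulates a pair of single-end small-RNA libraries (such as
#' the intermuscular-bone and connective-tissue libraries of a bone
#' development study): reads derive from known hairpin precursors with
#' configurable isomiR perturbation rates, a contaminant background of
#' rRNA/tRNA/snoRNA/mRNA fragments, and a known set of truly
#' differentially-expressed miRNAs.
#'
#' @param n_hairpins number of miRNA hairpin precursors to simulate.
#' @param hairpin_len hairpin length in nt.
#' @param mature_len_range integer range (min, max) of mature miRNA lengths.
#' @param reads_per_library reads simulated per library.
#' @param frac_contaminant named fractions of reads per contaminant category;
#'   names must be among `rRNA`, `tRNA`, `snoRNA`, `mRNA_fragment`.
#' @param isomir_rates named probabilities for the perturbation events
#'   `trim5`, `trim3`, `ext3_templated`, `nta3`, `seed_substitution`.
#'   The three 3'-length events are mutually exclusive per read; `trim5` and
#'   `seed_substitution` are applied independently.
#' @param nta_base_weights named base weights (DNA alphabet) for drawing
#'   non-templated 3' additions; uridine (written T) dominates by default.
#' @param de_fraction fraction of hairpins whose miRNAs are truly
#'   differential between the libraries.
#' @param de_log2fc true absolute log2 fold change of differential miRNAs
#'   (library B relative to library A).
#' @param star_fraction fraction of hairpins that also emit a detectable
#'   star-arm product.
#' @param star_expression star-arm abundance relative to its mature arm.
#' @param abundance_sdlog sd of the log-normal miRNA abundance distribution
#'   (large values give the strongly skewed abundance profile typical of
#'   muscle/bone small-RNA libraries, where a handful of miRNAs carry most
#'   reads).
#' @param adapter3 3' adapter ligated to every insert.
#' @param read_length raw read length (single-end).
#' @param low_quality_fraction fraction of reads rendered low-quality to
#'   exercise the quality filter.
#' @param seed integer RNG seed; all outputs are bit-reproducible given the
#'   seed.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(n_hairpins = 60,
                       hairpin_len = 80,
                       mature_len_range = c(20L, 23L),
                       reads_per_library = 50000,
                       frac_contaminant = c(rRNA = 0.015, tRNA = 0.010,
                                            snoRNA = 0.005, mRNA_fragment = 0.010),
                       isomir_rates = c(trim5 = 0.02, trim3 = 0.08,
                                        ext3_templated = 0.05, nta3 = 0.08,
                                        seed_substitution = 0.02),
                       nta_base_weights = c(A = 0.05, C = 0.05, G = 0.05, T = 0.85),
                       de_fraction = 0.10,
                       de_log2fc = 2.0,
                       star_fraction = 0.25,
                       star_expression = 0.05,
                       abundance_sdlog = 2.0,
                       adapter3 = "TGGAATTCTCGGGTGCCAAGG",
                       read_length = 50,
                       low_quality_fraction = 0.005,
                       seed = 1L) {
  cfg <- list(n_hairpins = as.integer(n_hairpins),
              hairpin_len = as.integer(hairpin_len),
              mature_len_range = as.integer(mature_len_range),
              reads_per_library = as.integer(reads_per_library),
              frac_contaminant = frac_contaminant,
              isomir_rates = isomir_rates,
              nta_base_weights = nta_base_weights,
              de_fraction = de_fraction,
              de_log2fc = de_log2fc,
              star_fraction = star_fraction,
              star_expression = star_expression,
              abundance_sdlog = abundance_sdlog,
              adapter3 = toupper(adapter3),
              read_length = as.integer(read_length),
              low_quality_fraction = low_quality_fraction,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  fr <- c(cfg$frac_contaminant, cfg$isomir_rates, cfg$de_fraction,
          cfg$star_fraction, cfg$low_quality_fraction)
  if (any(fr < 0 | fr > 1)) {
    stop("all fractions and rates must lie in [0, 1]")
  }
  if (sum(cfg$frac_contaminant) >= 1) {
    stop("contaminant fractions must sum to < 1")
  }
  if (cfg$reads_per_library <= 0) stop("reads_per_library must be > 0")
  if (cfg$n_hairpins <= 0) stop("n_hairpins must be > 0")
  bad <- setdiff(names(cfg$frac_contaminant),
                 c("rRNA", "tRNA", "snoRNA", "mRNA_fragment"))
  if (length(bad)) stop("unknown contaminant categories: ",
                        paste(bad, collapse = ", "))
  # the mature arm plus margins and a disjoint star arm must fit in the
  # hairpin: mature end <= (hairpin_len + 2) / 2 given a 5' margin of >= 2
  max_end <- 6L + max(cfg$mature_len_range)
  if (max_end > (cfg$hairpin_len + 2) %/% 2) {
    stop("mature interval exceeds hairpin bounds: increase hairpin_len")
  }
  if (max(cfg$mature_len_range) + 2L > 30L || min(cfg$mature_len_range) < 18L + 2L) {
    # trimming up to 2 nt must not push inserts below 18 nt, and extension
    # up to 2 nt must not exceed 30 nt
    stop("mature_len_range must lie within [20, 28]")
  }
  invisible(cfg)
}

#' Generate synthetic reference files for the simulator
#'
#' Produces a genome surrogate, per-category ncRNA references, a transcript
#' set, mature-miRNA and hairpin FASTA records in a miRBase-like dialect
#' (`mam-miR-N`, star arms `mam-miR-N*`), and a sidecar table of 0-based
#' half-open mature/star arm intervals on each hairpin. Each mature sequence
#' is an exact substring of its hairpin; the star interval is the duplex
#' partner region offset to give the canonical two-nucleotide 3' overhangs.
#'
#' @param config a [sim_config()].
#' @return a `ReferenceBundle` list with elements `genome`, `hairpins`,
#'   `mature`, `arms` (data.frame: hairpin_id, mature_name, star_name,
#'   mature_start, mature_end, star_start, star_end, mature_arm, has_star),
#'   `ncrna` (named character vector with a `category` attribute),
#'   `transcripts`, and the `config` used.
#' @export
generate_references <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  n <- config$n_hairpins
  H <- config$hairpin_len

  mature_len <- sample(seq(config$mature_len_range[1],
                           config$mature_len_range[2]), n, replace = TRUE)
  arm <- sample(c("5p", "3p"), n, replace = TRUE)
  # margin >= 4 keeps two templated continuation bases inside the hairpin
  # beyond both arms (star_end = hairpin_len - mature_start + 2)
  margin <- sample(4:6, n, replace = TRUE)
  # 0-based half-open intervals
  ms <- ifelse(arm == "5p", margin, H - margin - mature_len)
  me <- ms + mature_len
  star_start <- H - me + 2L
  star_end <- H - ms + 2L
  stopifnot(all(ms >= 0), all(me <= H), all(star_start >= 0),
            all(star_end <= H),
            all(pmax(ms, star_start) >= pmin(me, star_end)))  # disjoint

  hairpins <- random_dna(n, H)
  mature <- substr(hairpins, ms + 1L, me)
  while (anyDuplicated(mature)) {  # mature sequences must be unique
    dup <- which(duplicated(mature))
    hairpins[dup] <- random_dna(length(dup), H)
    mature[dup] <- substr(hairpins[dup], ms[dup] + 1L, me[dup])
  }
  # the templated base right after the mature 3' end never equals the
  # dominant non-templated addition base, so tailing events are always
  # identifiable against templated extension
  nta_top <- names(which.max(config$nta_base_weights))
  for (arm_end in list(me, star_end)) {
    clash <- which(substr(hairpins, arm_end + 1L, arm_end + 1L) == nta_top)
    if (length(clash)) {
      repl <- sample(setdiff(DNA_BASES, nta_top), length(clash),
                     replace = TRUE)
      substr(hairpins[clash], arm_end[clash] + 1L,
             arm_end[clash] + 1L) <- repl
    }
  }
  star <- substr(hairpins, star_start + 1L, star_end)

  hairpin_id <- sprintf("mam-mir-%d", seq_len(n))
  mature_name <- sprintf("mam-miR-%d", seq_len(n))
  star_name <- sprintf("mam-miR-%d*", seq_len(n))
  names(hairpins) <- hairpin_id

  has_star <- rep(FALSE, n)
  n_star <- round(config$star_fraction * n)
  if (n_star > 0) has_star[sample.int(n, n_star)] <- TRUE

  mature_set <- c(stats::setNames(mature, mature_name),
                  stats::setNames(star[has_star], star_name[has_star]))

  arms <- data.frame(hairpin_id = hairpin_id,
                     mature_name = mature_name,
                     star_name = ifelse(has_star, star_name, NA_character_),
                     mature_start = ms, mature_end = me,
                     star_start = star_start, star_end = star_end,
                     mature_arm = arm, has_star = has_star,
                     stringsAsFactors = FALSE)

  ncrna <- c(stats::setNames(random_dna(2, 400), sprintf("rRNA_%d", 1:2)),
             stats::setNames(random_dna(4, 75), sprintf("tRNA_%d", 1:4)),
             stats::setNames(random_dna(3, 130), sprintf("snoRNA_%d", 1:3)))
  attr(ncrna, "category") <- c(rep("rRNA", 2), rep("tRNA", 4),
                               rep("snoRNA", 3))
  transcripts <- stats::setNames(random_dna(8, 400),
                                 sprintf("transcript_%d", 1:8))

  # genome surrogate: every hairpin plus the ncRNA and transcript loci
  # (random strand for non-miRNA loci), separated by intergenic filler
  loci <- c(hairpins,
            vapply(seq_along(ncrna), function(i) {
              if (runif(1) < 0.5) revcomp(ncrna[i]) else ncrna[i]
            }, character(1)),
            vapply(seq_along(transcripts), function(i) {
              if (runif(1) < 0.5) revcomp(transcripts[i]) else transcripts[i]
            }, character(1)))
  filler <- random_dna(length(loci) + 1, 100)
  genome <- paste0(paste0(filler[seq_along(loci)], loci, collapse = ""),
                   filler[length(filler)])
  genome <- stats::setNames(genome, "chr1")

  structure(list(genome = genome, hairpins = hairpins, mature = mature_set,
                 arms = arms, ncrna = ncrna, transcripts = transcripts,
                 config = config),
            class = "ReferenceBundle")
}

#' Write a reference bundle to disk
#'
#' FASTA files for genome, hairpins, mature miRNAs, ncRNA categories
#' (category recorded as a `category=` key in the description) and
#' transcripts, plus the arm sidecar TSV.
#'
#' @param refs a `ReferenceBundle`.
#' @param dir output directory (created if absent).
#' @return invisibly, the directory.
#' @export
write_reference_bundle <- function(refs, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta_chr(refs$genome, file.path(dir, "genome.fa"))
  write_fasta_chr(refs$hairpins, file.path(dir, "hairpin.fa"))
  write_fasta_chr(refs$mature, file.path(dir, "mature.fa"))
  nc <- refs$ncrna
  names(nc) <- paste0(names(nc), " category=", attr(refs$ncrna, "category"))
  write_fasta_chr(nc, file.path(dir, "ncrna.fa"))
  write_fasta_chr(refs$transcripts, file.path(dir, "transcripts.fa"))
  write_tsv(refs$arms, file.path(dir, "arms.tsv"))
  invisible(dir)
}

# draw NTA strings: the first added base always differs from the templated
# hairpin continuation base, which keeps simulated events identifiable and
# matches the definition of a non-templated addition
draw_nta <- function(n, continuation, weights) {
  len <- 1L + stats::rbinom(n, 1L, 0.2)
  first <- sample(DNA_BASES, n, replace = TRUE,
                  prob = weights[DNA_BASES] / sum(weights[DNA_BASES]))
  for (b in DNA_BASES) {
    idx <- which(continuation == b)
    if (!length(idx)) next
    w <- weights[setdiff(DNA_BASES, b)]
    if (sum(w) == 0) w <- w + 1  # degenerate weights: uniform fallback
    first[idx] <- sample(setdiff(DNA_BASES, b), length(idx), replace = TRUE,
                         prob = w / sum(w))
  }
  second <- sample(DNA_BASES, n, replace = TRUE,
                   prob = weights[DNA_BASES] / sum(weights[DNA_BASES]))
  ifelse(len == 2L, paste0(first, second), first)
}

#' Simulate two small-RNA FASTQ libraries with full ground truth
#'
#' Draws reads from the mature (and star) miRNA set with the configured
#' isomiR perturbations and contaminant background, appends the 3' adapter,
#' pads to the read length and attaches Sanger-scale qualities. Library B
#' scales the truly differential miRNAs by `2^de_log2fc` (half up, half
#' down). Every read's generative events are logged so downstream stages can
#' be scored against the truth.
#'
#' @param config a [sim_config()]; must be the one used for `refs`.
#' @param refs a `ReferenceBundle` from [generate_references()].
#' @return a list with `reads_A`, `reads_B` (each a list of `id`, `seq`,
#'   `qual`) and `truth` (a `GroundTruth` list: `mirna_counts` per-miRNA
#'   realized counts and DE labels, `events` per-read event log, `config`).
#' @export
simulate_libraries <- function(config, refs) {
  if (!identical(refs$config$seed, config$seed)) {
    stop("references were generated with a different config")
  }
  if (!length(refs$mature)) stop("empty reference set")
  set.seed(config$seed + 1L)

  arms <- refs$arms
  mature_names <- names(refs$mature)
  n_m <- length(mature_names)
  is_star <- grepl("\\*$", mature_names)
  hp_index <- match(sub("\\*$", "", sub("miR", "mir", mature_names, fixed = TRUE)),
                    arms$hairpin_id)
  stopifnot(!anyNA(hp_index))

  # skewed abundance profile; stars at a fixed fraction of their mature arm
  w <- exp(stats::rnorm(nrow(arms), 0, config$abundance_sdlog))
  prop_A <- ifelse(is_star, config$star_expression, 1) * w[hp_index]
  prop_A <- prop_A / sum(prop_A)

  n_de <- round(config$de_fraction * nrow(arms))
  de_label <- rep("no", nrow(arms))
  if (n_de > 0) {
    de_hp <- sample.int(nrow(arms), n_de)
    de_label[de_hp] <- rep(c("up", "down"), length.out = n_de)
  }
  fc <- c(no = 1, up = 2^config$de_log2fc, down = 2^-config$de_log2fc)
  prop_B <- prop_A * fc[de_label[hp_index]]
  prop_B <- prop_B / sum(prop_B)

  sim_one <- function(lib, prop) {
    R <- config$reads_per_library
    cats <- c(miRNA = 1 - sum(config$frac_contaminant), config$frac_contaminant)
    cat_of_read <- sample(names(cats), R, replace = TRUE, prob = cats)
    n_mir <- sum(cat_of_read == "miRNA")
    parent_idx <- sample.int(n_m, n_mir, replace = TRUE, prob = prop)

    hp <- arms$hairpin_id[hp_index[parent_idx]]
    hp_seq <- refs$hairpins[hp]
    st <- ifelse(is_star[parent_idx],
                 arms$star_start[hp_index[parent_idx]],
                 arms$mature_start[hp_index[parent_idx]])
    en <- ifelse(is_star[parent_idx],
                 arms$star_end[hp_index[parent_idx]],
                 arms$mature_end[hp_index[parent_idx]])
    mat <- refs$mature[parent_idx]
    len <- nchar(mat)

    r <- config$isomir_rates
    t5 <- stats::rbinom(n_mir, 1L, r[["trim5"]]) *
      (1L + stats::rbinom(n_mir, 1L, 0.25))
    p3 <- c(r[["trim3"]], r[["ext3_templated"]], r[["nta3"]])
    ev3 <- sample(c("trim3", "ext3", "nta3", "none"), n_mir, replace = TRUE,
                  prob = c(p3, 1 - sum(p3)))
    amt3 <- (1L + stats::rbinom(n_mir, 1L, 0.25))
    # keep inserts within the 18-30 nt retention window
    over <- len - t5 - ifelse(ev3 == "trim3", amt3, 0L) < 18L
    t5[over] <- pmin(t5[over], 1L)
    amt3[over & ev3 == "trim3"] <- 1L

    has_sub <- stats::runif(n_mir) < r[["seed_substitution"]]
    sub_pos <- ifelse(has_sub, sample(2:8, n_mir, replace = TRUE), NA_integer_)
    sub_from <- ifelse(has_sub, substr(mat, sub_pos, sub_pos), NA_character_)
    sub_to <- NA_character_
    if (any(has_sub)) {
      sub_to <- vapply(seq_len(n_mir), function(i) {
        if (!has_sub[i]) return(NA_character_)
        sample(setdiff(DNA_BASES, sub_from[i]), 1)
      }, character(1))
    }

    seq_mut <- mat
    idx <- which(has_sub)
    if (length(idx)) {
      substr(seq_mut[idx], sub_pos[idx], sub_pos[idx]) <- sub_to[idx]
    }
    trim3 <- ifelse(ev3 == "trim3", amt3, 0L)
    core <- substr(seq_mut, 1L + t5, len - trim3)

    ext <- rep("", n_mir)
    i_ext <- which(ev3 == "ext3")
    if (length(i_ext)) {
      ext[i_ext] <- substr(hp_seq[i_ext], en[i_ext] + 1L,
                           en[i_ext] + amt3[i_ext])
    }
    nta <- rep("", n_mir)
    i_nta <- which(ev3 == "nta3")
    if (length(i_nta)) {
      continuation <- substr(hp_seq[i_nta], en[i_nta] + 1L, en[i_nta] + 1L)
      nta[i_nta] <- draw_nta(length(i_nta), continuation,
                             config$nta_base_weights)
    }
    insert_mir <- paste0(core, ext, nta)

    # contaminant inserts: random fragments of the category references
    n_con <- R - n_mir
    con_cat <- cat_of_read[cat_of_read != "miRNA"]
    con_insert <- character(n_con)
    con_src <- character(n_con)
    if (n_con > 0) {
      pool <- list(rRNA = refs$ncrna[attr(refs$ncrna, "category") == "rRNA"],
                   tRNA = refs$ncrna[attr(refs$ncrna, "category") == "tRNA"],
                   snoRNA = refs$ncrna[attr(refs$ncrna, "category") == "snoRNA"],
                   mRNA_fragment = refs$transcripts)
      for (cc in unique(con_cat)) {
        ii <- which(con_cat == cc)
        src <- sample(names(pool[[cc]]), length(ii), replace = TRUE)
        flen <- sample(18:30, length(ii), replace = TRUE)
        smax <- nchar(pool[[cc]][src]) - flen
        s0 <- floor(stats::runif(length(ii)) * (smax + 1))
        con_insert[ii] <- substr(pool[[cc]][src], s0 + 1L, s0 + flen)
        con_src[ii] <- src
      }
    }

    insert <- character(R)
    insert[cat_of_read == "miRNA"] <- insert_mir
    insert[cat_of_read != "miRNA"] <- con_insert
    low_q <- stats::runif(R) < config$low_quality_fraction

    id <- sprintf("%s_%06d", lib, seq_len(R))
    pad <- random_dna(R, config$read_length)
    seqs <- substr(paste0(insert, config$adapter3, pad), 1L,
                   config$read_length)
    qual <- strrep("I", config$read_length)
    quals <- rep(qual, R)
    if (any(low_q)) {
      # three early cycles dropped below Q20 ('#' = Q2)
      for (i in which(low_q)) {
        q <- quals[i]
        pos <- sample.int(config$read_length, 3)
        for (p in pos) substr(q, p, p) <- "#"
        quals[i] <- q
      }
    }

    off5 <- integer(R); off3 <- integer(R)
    templ3 <- logical(R); ntas <- rep("", R)
    parent <- rep(NA_character_, R)
    sp <- rep(NA_integer_, R); sf <- rep(NA_character_, R)
    stv <- rep(NA_character_, R)
    mi <- which(cat_of_read == "miRNA")
    parent[mi] <- mature_names[parent_idx]
    off5[mi] <- -t5
    off3[mi] <- ifelse(ev3 == "trim3", -amt3,
                       ifelse(ev3 == "ext3", amt3,
                              ifelse(ev3 == "nta3", nchar(nta), 0L)))
    templ3[mi] <- ev3 == "ext3"
    ntas[mi] <- nta
    sp[mi] <- sub_pos; sf[mi] <- sub_from; stv[mi] <- sub_to

    events <- data.frame(read_id = id, library = lib,
                         category = cat_of_read, parent = parent,
                         offset5 = off5, offset3 = off3,
                         templated3 = templ3, nta = ntas,
                         sub_pos = sp, sub_from = sf, sub_to = stv,
                         low_quality = low_q, insert = insert,
                         stringsAsFactors = FALSE)
    counts <- tabulate(parent_idx, nbins = n_m)
    list(reads = list(id = id, seq = unname(seqs), qual = quals),
         events = events, counts = counts)
  }

  A <- sim_one("A", prop_A)
  B <- sim_one("B", prop_B)

  mirna_counts <- data.frame(name = mature_names,
                             hairpin_id = arms$hairpin_id[hp_index],
                             is_star = is_star,
                             prop_A = prop_A, prop_B = prop_B,
                             count_A = A$counts, count_B = B$counts,
                             de_label = de_label[hp_index],
                             stringsAsFactors = FALSE)
  truth <- list(mirna_counts = mirna_counts,
                events = rbind(A$events, B$events),
                config = config)
  class(truth) <- "GroundTruth"
  list(reads_A = A$reads, reads_B = B$reads, truth = truth)
}

#' Reconstruct a read insert from its isomiR decomposition
#'
#' Applies a decomposition (end offsets, substitutions on mature
#' coordinates, non-templated 3' tail) to a mature sequence in its hairpin
#' context and returns the implied insert. Used both to verify the
#' simulator's event log and as the round-trip check for classified isomiR
#' records.
#'
#' @param mature mature (or star) arm sequence, DNA alphabet.
#' @param hairpin hairpin sequence containing `mature`.
#' @param mature_start,mature_end 0-based half-open arm interval on the
#'   hairpin.
#' @param offset5 signed 5' offset (negative = trimmed, positive = templated
#'   extension into the hairpin).
#' @param offset3 signed 3' offset (negative = trimmed; positive = extension,
#'   templated and/or non-templated).
#' @param nta non-templated 3' tail (suffix of the 3' extension), "" if none.
#' @param sub_pos,sub_to parallel vectors of substitution positions (1-based
#'   on the mature sequence) and replacement bases; empty if none.
#' @return the reconstructed insert string.
#' @export
reconstruct_tag <- function(mature, hairpin, mature_start, mature_end,
                            offset5 = 0L, offset3 = 0L, nta = "",
                            sub_pos = integer(0), sub_to = character(0)) {
  stopifnot(substr(hairpin, mature_start + 1L, mature_end) == mature)
  s <- mature
  for (k in seq_along(sub_pos)) {
    substr(s, sub_pos[k], sub_pos[k]) <- sub_to[k]
  }
  len <- nchar(mature)
  # 5' side
  if (offset5 < 0) {
    s <- substr(s, 1L - offset5, nchar(s))
  } else if (offset5 > 0) {
    s <- paste0(substr(hairpin, mature_start - offset5 + 1L, mature_start), s)
  }
  # 3' side: trimming, then templated extension, then the nta suffix
  if (offset3 < 0) {
    s <- substr(s, 1L, nchar(s) + offset3)
  } else if (offset3 > 0) {
    n_temp <- offset3 - nchar(nta)
    if (n_temp < 0) stop("nta longer than the 3' extension")
    if (n_temp > 0) {
      s <- paste0(s, substr(hairpin, mature_end + 1L, mature_end + n_temp))
    }
    s <- paste0(s, nta)
  } else if (nzchar(nta)) {
    stop("nta requires a positive 3' offset")
  }
  s
}

#' Write reads as a Sanger-quality FASTQ file
#'
#' @param reads a list with `id`, `seq`, `qual` (as produced by
#'   [simulate_libraries()]).
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_fastq <- function(reads, path) {
  out <- character(4L * length(reads$id))
  out[seq(1, length(out), by = 4)] <- paste0("@", reads$id)
  out[seq(2, length(out), by = 4)] <- reads$seq
  out[seq(3, length(out), by = 4)] <- "+"
  out[seq(4, length(out), by = 4)] <- reads$qual
  writeLines(out, path)
  invisible(path)
}
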