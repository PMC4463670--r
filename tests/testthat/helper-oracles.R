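# Independent oracles and hand-built fixtures shared across tests.

# brute-force <=k-mismatch mapper: slides every window of every reference
# on both strands and counts mismatches character-wise
brute_force_map <- function(tags, genome, max_mismatch = 1L) {
  rc_chr <- function(x) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", x), "")[[1]]), collapse = "")
  }
  rows <- list()
  for (ref in names(genome)) {
    g <- strsplit(genome[[ref]], "")[[1]]
    L <- length(g)
    for (tg in tags) {
      for (strand in c("+", "-")) {
        pat <- if (strand == "+") tg else rc_chr(tg)
        p <- strsplit(pat, "")[[1]]
        w <- length(p)
        if (w > L) next
        nwin <- L - w + 1L
        mm <- integer(nwin)
        for (j in seq_len(w)) {
          mm <- mm + (g[j:(nwin + j - 1L)] != p[j])
        }
        hit <- which(mm <= max_mismatch)
        if (length(hit)) {
          rows[[length(rows) + 1L]] <- data.frame(
            tag = tg, ref = ref, start = hit - 1L, strand = strand,
            mismatches = mm[hit], stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(tag = character(0), ref = character(0),
                      start = integer(0), strand = character(0),
                      mismatches = integer(0)))
  }
  out <- do.call(rbind, rows)
  out[order(out$tag, out$ref, out$start, out$strand), ]
}

# brute-force seed scanner: checks every transcript window directly by
# base-wise complementarity against miRNA positions 2-8 and the t1 slot
brute_force_seedscan <- function(mirnas, transcripts) {
  comp <- function(b) chartr("ACGT", "TGCA", b)
  rows <- list()
  for (mi in names(mirnas)) {
    m <- strsplit(mirnas[[mi]], "")[[1]]
    for (tx in names(transcripts)) {
      t <- strsplit(transcripts[[tx]], "")[[1]]
      L <- length(t)
      for (s0 in 0:(L - 6L)) {  # 0-based start of the 6mer core
        core_ok <- all(t[(s0 + 1):(s0 + 6)] == comp(m[7:2]))
        if (!core_ok) next
        has_m8 <- s0 >= 1 && t[s0] == comp(m[8])
        has_a1 <- s0 + 7 <= L && t[s0 + 7] == "A"
        type <- if (has_m8 && has_a1) "8mer" else if (has_m8) "7mer-m8"
          else if (has_a1) "7mer-A1" else "6mer"
        rows[[length(rows) + 1L]] <- data.frame(
          mirna = mi, transcript = tx, core_start = s0, site_type = type,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(mirna = character(0), transcript = character(0),
                      core_start = integer(0), site_type = character(0)))
  }
  out <- do.call(rbind, rows)
  out[order(out$mirna, out$transcript, out$core_start), ]
}

# direct-summation oracle for the exact conditional count test: the pmf
# p(y|x) = r^y (x+y)! / (x! y! (1+r)^(x+y+1)) with r = n_b/n_a, summed
# term by term via log-factorials; tails from cumulative sums in both
# conditioning orientations, smallest tail doubled and capped at 1
oracle_pvalue <- function(x, y, n_a, n_b) {
  tail_pair <- function(x, y, r) {
    ymax <- max(y + 50L, ceiling(5 * (x + 10) * r) + 50L)
    yy <- 0:ymax
    logpmf <- yy * log(r) + lgamma(x + yy + 1) - lgamma(x + 1) -
      lgamma(yy + 1) - (x + yy + 1) * log(1 + r)
    cdf <- cumsum(exp(logpmf))
    lo <- cdf[y + 1L]
    hi <- 1 - (if (y >= 1L) cdf[y] else 0)
    c(lo, hi)
  }
  t1 <- tail_pair(x, y, n_b / n_a)
  t2 <- tail_pair(y, x, n_a / n_b)
  min(1, 2 * min(c(t1, t2)))
}

# a hand-built hairpin fixture: 60 nt, mature on the 5' arm at [4, 26),
# star at the duplex-partner interval with canonical 2-nt 3' overhangs
make_hand_hairpin <- function() {
  set.seed(404)
  H <- 60L
  ms <- 4L; me <- 26L
  hairpin <- paste(sample(c("A", "C", "G", "T"), H, replace = TRUE),
                   collapse = "")
  star_start <- H - me + 2L  # 36
  star_end <- H - ms + 2L    # 58
  list(hairpin = c(`mam-mir-9` = hairpin),
       mature = substr(hairpin, ms + 1, me),
       star = substr(hairpin, star_start + 1, star_end),
       arms = data.frame(hairpin_id = "mam-mir-9",
                         mature_name = "mam-miR-9",
                         star_name = "mam-miR-9*",
                         mature_start = ms, mature_end = me,
                         star_start = star_start, star_end = star_end,
                         mature_arm = "5p", has_star = TRUE,
                         stringsAsFactors = FALSE))
}

# small default simulation shared by several tests
quiet_sim <- function(...) {
  cfg <- sim_config(...)
  refs <- generate_references(cfg)
  sim <- simulate_libraries(cfg, refs)
  list(cfg = cfg, refs = refs, sim = sim)
}
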