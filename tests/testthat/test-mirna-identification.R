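test_that("tags support miRNAs within the mismatch/shift gate only", {
  hh <- make_hand_hairpin()
  mature <- c(`mam-miR-9` = hh$mature)
  tags <- data.frame(seq = hh$mature, count_A = 10L, count_B = 5L)
  ident <- identify_conserved(tags, mature, hh$hairpin, arms = hh$arms)
  expect_equal(ident$catalog$name, "mam-miR-9")
  expect_equal(ident$catalog$count_A, 10L)
  expect_equal(ident$support$offset5, 0L)
  expect_equal(ident$support$offset3, 0L)

  two_mm <- hh$mature
  for (p in c(5, 12)) {
    substr(two_mm, p, p) <- setdiff(c("A", "C", "G", "T"),
                                    substr(two_mm, p, p))[1]
  }
  none <- identify_conserved(data.frame(seq = two_mm, count_A = 1L,
                                        count_B = 0L),
                             mature, hh$hairpin, arms = hh$arms)
  expect_equal(nrow(none$catalog), 0)

  shifted5 <- substr(hh$hairpin[[1]], 4 - 4 + 1, 26)  # 5' offset +4: in gate
  shifted6 <- paste0("ACGTAC", hh$mature)             # beyond gate
  in_gate <- identify_conserved(data.frame(seq = shifted5, count_A = 1L,
                                           count_B = 0L),
                                mature, hh$hairpin, arms = hh$arms)
  expect_equal(in_gate$support$offset5, 4L)
  out_gate <- identify_conserved(data.frame(seq = shifted6, count_A = 1L,
                                            count_B = 0L),
                                 mature, hh$hairpin, arms = hh$arms)
  expect_equal(nrow(out_gate$catalog), 0)
})

test_that("identification is order-independent and matches clean truth", {
  s <- quiet_sim(n_hairpins = 12, reads_per_library = 4000,
                 frac_contaminant = c(rRNA = 0, tRNA = 0, snoRNA = 0,
                                      mRNA_fragment = 0),
                 isomir_rates = c(trim5 = 0, trim3 = 0, ext3_templated = 0,
                                  nta3 = 0, seed_substitution = 0),
                 low_quality_fraction = 0, seed = 12)
  tags_A <- collapse_unique(clean_reads(s$sim$reads_A, s$cfg$adapter3)$inserts)
  tags_B <- collapse_unique(clean_reads(s$sim$reads_B, s$cfg$adapter3)$inserts)
  tags <- merge_tag_counts(tags_A, tags_B)
  ident <- identify_conserved(tags, s$refs$mature, s$refs$hairpins,
                              arms = s$refs$arms)
  truth <- s$sim$truth$mirna_counts
  m <- merge(ident$catalog, truth, by = "name", all = TRUE)
  m[is.na(m)] <- 0
  expect_equal(m$count_A.x, m$count_A.y)
  expect_equal(m$count_B.x, m$count_B.y)
  # shuffled input gives the identical catalog
  shuf <- tags[sample(nrow(tags)), ]
  ident2 <- identify_conserved(shuf, s$refs$mature, s$refs$hairpins,
                               arms = s$refs$arms)
  expect_identical(ident$catalog, ident2$catalog)
  # catalog counts can never exceed the retained read totals
  expect_lte(sum(ident$catalog$count_A), sum(tags$count_A))
})

test_that("a mature sequence absent from all hairpins warns, arm unknown", {
  hh <- make_hand_hairpin()
  mature <- c(`mam-miR-9` = hh$mature,
              `mam-miR-99` = "TTAAGGCCTTAAGGCCTTAAGG")
  tags <- data.frame(seq = c(hh$mature, "TTAAGGCCTTAAGGCCTTAAGG"),
                     count_A = c(2L, 3L), count_B = c(0L, 1L))
  expect_warning(
    ident <- identify_conserved(tags, mature, hh$hairpin, arms = hh$arms),
    "absent")
  expect_equal(ident$catalog$arm[ident$catalog$name == "mam-miR-99"],
               "unknown")
  expect_equal(ident$catalog$count_A[ident$catalog$name == "mam-miR-99"], 3L)
})

test_that("family grammar reproduces the canonical groupings", {
  expect_equal(unique(mirna_family(c("mam-let-7a", "mam-let-7b",
                                     "mam-let-7f"))), "let-7")
  expect_equal(unique(mirna_family(c("mam-miR-199-3p", "mam-miR-199a-3p"))),
               "miR-199")
  expect_equal(mirna_family("dre-miR-133a-1"), "miR-133")
  expect_equal(mirna_family("mam-miR-21*"), "miR-21")
  expect_equal(mirna_family("mam-miR-1"), "miR-1")
  cat <- data.frame(name = c("mam-let-7a", "mam-let-7b", "mam-miR-1",
                             "mam-miR-199a-3p"),
                    family = mirna_family(c("mam-let-7a", "mam-let-7b",
                                            "mam-miR-1", "mam-miR-199a-3p")))
  fams <- group_families(cat)
  expect_equal(sum(vapply(fams, nrow, integer(1))), nrow(cat))
  expect_equal(nrow(fams[["let-7"]]), 2)
})

test_that("abundance ranking orders and accumulates correctly", {
  cat1 <- data.frame(name = "m1", count_A = 7L, count_B = 0L)
  expect_equal(rank_abundance(cat1, "A", k = 1)$cumulative_fraction, 1)
  cat2 <- data.frame(name = c("m1", "m2"), count_A = c(90L, 10L),
                     count_B = c(0L, 0L))
  r <- rank_abundance(cat2, "A", k = 1)
  expect_equal(r$top$name, "m1")
  expect_equal(r$cumulative_fraction, 0.9)
  # a dominant miRNA keeps the top-10 share above its own share
  s <- quiet_sim(n_hairpins = 30, reads_per_library = 5000,
                 abundance_sdlog = 3, seed = 19)
  tags <- merge_tag_counts(
    collapse_unique(clean_reads(s$sim$reads_A, s$cfg$adapter3)$inserts),
    collapse_unique(clean_reads(s$sim$reads_B, s$cfg$adapter3)$inserts))
  ident <- identify_conserved(tags, s$refs$mature, s$refs$hairpins,
                              arms = s$refs$arms)
  top <- rank_abundance(ident$catalog, "A", k = 10)
  tr <- s$sim$truth$mirna_counts
  share10 <- sum(sort(tr$count_A, decreasing = TRUE)[1:10]) / sum(tr$count_A)
  expect_gt(top$cumulative_fraction, share10 - 0.05)
})

test_that("base-bias tables are row-normalized and detect a 5' U bias", {
  bb <- base_bias(c("TGAGGACTGACTGACTGACTGA"))
  expect_equal(unname(bb$first_base["22", "U"]), 1)
  expect_true(all(abs(rowSums(bb$first_base) - 1) < 1e-12))
  expect_true(all(abs(rowSums(bb$positional) - 1) < 1e-12))
  set.seed(33)
  seqs <- vapply(1:400, function(i) {
    paste(sample(c("A", "C", "G", "T"), 22, replace = TRUE), collapse = "")
  }, character(1))
  bb2 <- base_bias(seqs)
  expect_true(all(abs(bb2$first_base["22", ] - 0.25) < 3 * sqrt(0.25 * 0.75 / 400)))
})

test_that("duplex pairs require reads on both arms and match geometry", {
  hh <- make_hand_hairpin()
  mature <- c(`mam-miR-9` = hh$mature, `mam-miR-9*` = hh$star)
  only5p <- identify_conserved(data.frame(seq = hh$mature, count_A = 5L,
                                          count_B = 0L),
                               mature, hh$hairpin, arms = hh$arms)
  expect_equal(nrow(detect_duplexes(only5p$catalog, hh$arms, hh$hairpin)), 0)
  both <- identify_conserved(data.frame(seq = c(hh$mature, hh$star),
                                        count_A = c(5L, 1L),
                                        count_B = c(2L, 0L)),
                             mature, hh$hairpin, arms = hh$arms)
  dp <- detect_duplexes(both$catalog, hh$arms, hh$hairpin)
  expect_equal(nrow(dp), 1)
  expect_equal(dp$overhang_mature3, 2)
  expect_equal(dp$overhang_star3, 2)
  # forced stars: every expressed hairpin yields a pair
  s <- quiet_sim(n_hairpins = 10, reads_per_library = 20000,
                 star_fraction = 1, star_expression = 0.2,
                 abundance_sdlog = 0.3, seed = 23)
  tags <- merge_tag_counts(
    collapse_unique(clean_reads(s$sim$reads_A, s$cfg$adapter3)$inserts),
    collapse_unique(clean_reads(s$sim$reads_B, s$cfg$adapter3)$inserts))
  ident <- identify_conserved(tags, s$refs$mature, s$refs$hairpins,
                              arms = s$refs$arms)
  dps <- detect_duplexes(ident$catalog, s$refs$arms, s$refs$hairpins)
  tr <- s$sim$truth$mirna_counts
  expressed_both <- tapply(tr$count_A + tr$count_B, tr$hairpin_id,
                           function(x) all(x >= 1))
  expect_equal(sort(dps$hairpin_id),
               sort(names(expressed_both)[expressed_both]))
})
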