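test_that("config validation rejects out-of-range parameters", {
  expect_error(sim_config(de_fraction = 1.5), "fractions")
  expect_error(sim_config(reads_per_library = 0), "reads_per_library")
  expect_error(sim_config(frac_contaminant = c(rRNA = 0.6, tRNA = 0.5)),
               "sum")
  expect_error(sim_config(frac_contaminant = c(virus = 0.1)), "unknown")
  expect_error(sim_config(hairpin_len = 30), "hairpin")
})

test_that("references contain each mature arm and are seed-reproducible", {
  cfg <- sim_config(n_hairpins = 8, reads_per_library = 100, seed = 7)
  refs <- generate_references(cfg)
  expect_length(refs$hairpins, 8)
  for (j in seq_len(nrow(refs$arms))) {
    hp <- refs$hairpins[[refs$arms$hairpin_id[j]]]
    expect_identical(
      substr(hp, refs$arms$mature_start[j] + 1, refs$arms$mature_end[j]),
      unname(refs$mature[[refs$arms$mature_name[j]]]))
  }
  refs2 <- generate_references(cfg)
  expect_identical(refs$genome, refs2$genome)
  expect_identical(refs$mature, refs2$mature)
  td <- withr::local_tempdir()
  write_reference_bundle(refs, file.path(td, "r1"))
  write_reference_bundle(refs2, file.path(td, "r2"))
  for (f in list.files(file.path(td, "r1"))) {
    expect_identical(readLines(file.path(td, "r1", f)),
                     readLines(file.path(td, "r2", f)))
  }
})

test_that("star intervals are disjoint from mature with 2-nt 3' overhangs", {
  cfg <- sim_config(n_hairpins = 12, star_fraction = 1.0,
                    reads_per_library = 100, seed = 11)
  refs <- generate_references(cfg)
  a <- refs$arms
  expect_true(all(a$has_star))
  expect_true(all(pmax(a$mature_start, a$star_start) >=
                    pmin(a$mature_end, a$star_end)))
  H <- nchar(refs$hairpins[a$hairpin_id])
  expect_true(all(a$star_start - (H - a$mature_end) == 2))
  expect_true(all(a$mature_start - (H - a$star_end) == 2))
})

test_that("library simulation is seeded-deterministic and conserves reads", {
  s <- quiet_sim(n_hairpins = 10, reads_per_library = 2000, seed = 3)
  s2 <- quiet_sim(n_hairpins = 10, reads_per_library = 2000, seed = 3)
  expect_identical(s$sim$reads_A$seq, s2$sim$reads_A$seq)
  expect_identical(s$sim$truth$events, s2$sim$truth$events)
  ev <- s$sim$truth$events
  expect_equal(nrow(ev), 2 * 2000)
  # per-miRNA realized counts plus contaminants account for every read
  tc <- s$sim$truth$mirna_counts
  for (lib in c("A", "B")) {
    n_con <- sum(ev$category != "miRNA" & ev$library == lib)
    expect_equal(sum(tc[[paste0("count_", lib)]]) + n_con, 2000)
  }
})

test_that("every simulated miRNA event log reconstructs its read exactly", {
  s <- quiet_sim(n_hairpins = 15, reads_per_library = 4000, seed = 5)
  ev <- s$sim$truth$events
  mi <- which(ev$category == "miRNA")
  loc <- mamiR:::locate_matures(s$refs$mature, s$refs$hairpins, s$refs$arms)
  ok <- vapply(mi, function(i) {
    j <- match(ev$parent[i], loc$name)
    r <- reconstruct_tag(loc$seq[j], s$refs$hairpins[[loc$hairpin_id[j]]],
                         loc$start[j], loc$end[j],
                         ev$offset5[i], ev$offset3[i], ev$nta[i],
                         sub_pos = if (is.na(ev$sub_pos[i])) integer(0) else ev$sub_pos[i],
                         sub_to = if (is.na(ev$sub_pos[i])) character(0) else ev$sub_to[i])
    identical(r, ev$insert[i])
  }, logical(1))
  expect_true(all(ok))
})

test_that("contaminant category fractions match configuration within 3 SD", {
  frac <- c(rRNA = 0.05, tRNA = 0.03, snoRNA = 0.02, mRNA_fragment = 0.04)
  s <- quiet_sim(n_hairpins = 10, reads_per_library = 20000,
                 frac_contaminant = frac, seed = 8)
  ev <- s$sim$truth$events
  n <- sum(ev$library == "A")
  for (cc in names(frac)) {
    obs <- sum(ev$category == cc & ev$library == "A")
    sd <- sqrt(n * frac[[cc]] * (1 - frac[[cc]]))
    expect_lt(abs(obs - n * frac[[cc]]), 3 * sd + 1)
  }
})

test_that("unperturbed simulation emits pure mature+adapter reads", {
  s <- quiet_sim(n_hairpins = 6, reads_per_library = 500,
                 frac_contaminant = c(rRNA = 0, tRNA = 0, snoRNA = 0,
                                      mRNA_fragment = 0),
                 isomir_rates = c(trim5 = 0, trim3 = 0, ext3_templated = 0,
                                  nta3 = 0, seed_substitution = 0),
                 low_quality_fraction = 0, seed = 13)
  ev <- s$sim$truth$events
  expect_true(all(ev$category == "miRNA"))
  expect_true(all(ev$insert %in% s$refs$mature))
  pref <- paste0(ev$insert, substr(s$cfg$adapter3, 1,
                                   pmax(0, 50 - nchar(ev$insert))))
  reads <- c(s$sim$reads_A$seq, s$sim$reads_B$seq)
  expect_true(all(substr(reads, 1, nchar(pref)) == substr(pref, 1, 50)))
})

test_that("forced uridylation marks every miRNA read with a 3' U", {
  s <- quiet_sim(n_hairpins = 6, reads_per_library = 500,
                 frac_contaminant = c(rRNA = 0, tRNA = 0, snoRNA = 0,
                                      mRNA_fragment = 0),
                 isomir_rates = c(trim5 = 0, trim3 = 0, ext3_templated = 0,
                                  nta3 = 1, seed_substitution = 0),
                 nta_base_weights = c(A = 0, C = 0, G = 0, T = 1),
                 low_quality_fraction = 0, seed = 21)
  ev <- s$sim$truth$events
  expect_true(all(grepl("^T", ev$nta)))
  expect_true(all(substr(ev$insert, nchar(ev$insert) - nchar(ev$nta) + 1,
                         nchar(ev$insert)) == ev$nta))
})

test_that("equal-proportion libraries show no systematic count shift", {
  s <- quiet_sim(n_hairpins = 25, reads_per_library = 20000,
                 de_fraction = 0, abundance_sdlog = 0.5, seed = 17)
  tc <- s$sim$truth$mirna_counts
  expect_true(all(tc$de_label == "no"))
  # chi-square on realized counts against the shared proportions
  keep <- tc$count_A + tc$count_B > 10
  chi <- suppressWarnings(
    stats::chisq.test(cbind(tc$count_A[keep], tc$count_B[keep])))
  expect_gt(chi$p.value, 1e-4)
})
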