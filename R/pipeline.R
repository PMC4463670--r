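#' Pipeline configuration
#'
#' Bundles the stage parameters for an end-to-end run on simulated data:
#' the simulation settings, the identification gate, the DE thresholds and
#' the optional qPCR/target stages.
#'
#' @param sim a [sim_config()].
#' @param de a [de_config()].
#' @param max_mismatch mapping/annotation/identification mismatch
#'   tolerance.
#' @param max_shift identification end-offset gate.
#' @param run_qpcr,run_targets include the optional validation stages.
#' @param ct_table optional Ct data.frame for the qPCR stage (a synthetic
#'   one is generated when NULL and `run_qpcr` is TRUE).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(sim = sim_config(), de = de_config(),
                            max_mismatch = 1L, max_shift = 4L,
                            run_qpcr = TRUE, run_targets = TRUE,
                            ct_table = NULL) {
  structure(list(sim = sim, de = de, max_mismatch = max_mismatch,
                 max_shift = max_shift, run_qpcr = run_qpcr,
                 run_targets = run_targets, ct_table = ct_table),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys `sim` and `de` are passed as arguments to [sim_config()]
#' and [de_config()]; remaining keys go to [pipeline_config()].
#'
#' @param path YAML file path.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim <- do.call(sim_config, as_config_args(y$sim))
  de <- do.call(de_config, if (is.null(y$de)) list() else y$de)
  rest <- y[setdiff(names(y), c("sim", "de"))]
  do.call(pipeline_config, c(list(sim = sim, de = de), rest))
}

as_config_args <- function(x) {
  if (is.null(x)) return(list())
  for (nm in c("frac_contaminant", "isomir_rates", "nta_base_weights")) {
    if (!is.null(x[[nm]])) x[[nm]] <- unlist(x[[nm]])
  }
  if (!is.null(x$mature_len_range)) x$mature_len_range <- unlist(x$mature_len_range)
  x
}

#' Run the full small-RNA analysis pipeline
#'
#' Executes simulate -> clean -> collapse -> map -> annotate -> identify ->
#' isomiR -> differential expression (-> qPCR -> targets) on synthetic
#' libraries, writing every stage's tables under `out_dir` together with a
#' run manifest (package version, parameters, input file digests). Any
#' stage failure aborts with the stage name and cause.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory.
#' @return invisibly, a list with all in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  refs <- stage("simulate", generate_references(config$sim))
  sim <- stage("simulate", simulate_libraries(config$sim, refs))
  ref_dir <- file.path(out_dir, "references")
  write_reference_bundle(refs, ref_dir)
  write_fastq(sim$reads_A, file.path(out_dir, "library_A.fastq"))
  write_fastq(sim$reads_B, file.path(out_dir, "library_B.fastq"))

  clean_A <- stage("clean", clean_reads(sim$reads_A, config$sim$adapter3))
  clean_B <- stage("clean", clean_reads(sim$reads_B, config$sim$adapter3))
  tags_A <- collapse_unique(clean_A$inserts)
  tags_B <- collapse_unique(clean_B$inserts)
  tags <- merge_tag_counts(tags_A, tags_B)
  cs <- common_specific(tags_A, tags_B)

  map_res <- stage("map", map_tags(tags, refs$genome,
                                   max_mismatch = config$max_mismatch))
  ann <- stage("annotate",
               annotate_tags(tags, refs$ncrna, refs$transcripts,
                             max_mismatch = config$max_mismatch))
  retained <- retain_for_mirna(ann)
  retained2 <- tags[tags$seq %in% retained$seq, , drop = FALSE]

  ident <- stage("identify",
                 identify_conserved(retained2, refs$mature, refs$hairpins,
                                    arms = refs$arms,
                                    max_mismatch = config$max_mismatch,
                                    max_shift = config$max_shift))
  duplexes <- detect_duplexes(ident$catalog, refs$arms, refs$hairpins)
  spectrum <- stage("isomir", substitution_spectrum(ident$support))
  nta <- nta_profile(ident$support)

  expr <- expression_table(ident$catalog,
                           clean_A$summary$clean_reads,
                           clean_B$summary$clean_reads)
  de <- stage("de", call_de(adjust_and_filter(expr, config$de), config$de))

  qpcr <- NULL
  if (isTRUE(config$run_qpcr)) {
    qpcr <- stage("qpcr", {
      ct <- config$ct_table
      if (is.null(ct)) {
        sig <- de$table$name[grepl("^significant", de$table$status)]
        picks <- utils::head(sig, 4)
        if (length(picks) < 2) picks <- utils::head(de$table$name, 4)
        tissues <- c("muscle", "brain", "liver", "IB", "CT")
        fc <- matrix(2^stats::rnorm(length(picks) * length(tissues), 0, 2),
                     nrow = length(picks),
                     dimnames = list(picks, tissues))
        fc[, "muscle"] <- 1
        ct <- simulate_ct_table(fc, reference_tissue = "muscle")
      }
      mat <- relative_expression(ct, reference_tissue = "muscle")
      list(ct = ct, matrix = mat,
           clusters = if (nrow(mat) >= 2 && ncol(mat) >= 2)
             cluster_heatmap(mat) else NULL)
    })
  }
  targets <- NULL
  if (isTRUE(config$run_targets)) {
    targets <- stage("targets", {
      sig <- de$table$name[grepl("^significant", de$table$status)]
      mir <- ident$catalog$seq[match(sig, ident$catalog$name)]
      names(mir) <- sig
      if (length(mir)) scan_targets(mir, refs$transcripts) else
        scan_targets(refs$mature[1], refs$transcripts)[0, ]
    })
  }

  results <- list(refs = refs, truth = sim$truth,
                  clean_A = clean_A, clean_B = clean_B,
                  tags_A = tags_A, tags_B = tags_B, tags = tags,
                  common_specific = cs, mapping = map_res,
                  annotation = ann, retained = retained2,
                  catalog = ident$catalog, support = ident$support,
                  duplexes = duplexes, spectrum = spectrum,
                  nta_profile = nta, de = de, qpcr = qpcr,
                  targets = targets)

  write_pipeline_tables(results, out_dir)
  manifest <- list(
    package_version = as.character(utils::packageVersion("mamiR")),
    seed = config$sim$seed,
    parameters = list(sim = unclass(config$sim), de = unclass(config$de),
                      max_mismatch = config$max_mismatch,
                      max_shift = config$max_shift),
    input_digests = as.list(tools::md5sum(
      c(file.path(out_dir, c("library_A.fastq", "library_B.fastq")),
        file.path(ref_dir, c("genome.fa", "hairpin.fa", "mature.fa",
                             "ncrna.fa", "transcripts.fa", "arms.tsv"))))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  results$manifest <- manifest
  invisible(results)
}

write_pipeline_tables <- function(res, out_dir) {
  s <- summarize_run(res)
  for (nm in names(s)) {
    write_tsv(s[[nm]], file.path(out_dir, paste0(nm, ".tsv")))
  }
  write_tag_fasta(res$tags_A, file.path(out_dir, "tags_A.fa"))
  write_tag_fasta(res$tags_B, file.path(out_dir, "tags_B.fa"))
  write_tsv(res$mapping$hits, file.path(out_dir, "mapping_hits.tsv"))
  write_tsv(res$support, file.path(out_dir, "isomir_records.tsv"))
  write_tsv(res$duplexes, file.path(out_dir, "duplex_pairs.tsv"))
  if (!is.null(res$qpcr)) {
    write_tsv(res$qpcr$ct, file.path(out_dir, "qpcr_ct.tsv"))
    m <- data.frame(mirna = rownames(res$qpcr$matrix),
                    unclass(res$qpcr$matrix), check.names = FALSE)
    write_tsv(m, file.path(out_dir, "qpcr_relative_expression.tsv"))
    if (!is.null(res$qpcr$clusters)) {
      writeLines(c(res$qpcr$clusters$row_newick,
                   res$qpcr$clusters$col_newick),
                 file.path(out_dir, "qpcr_dendrograms.nwk"))
    }
  }
  if (!is.null(res$targets)) {
    write_tsv(res$targets, file.path(out_dir, "target_sites.tsv"))
  }
  invisible(out_dir)
}

#' Figure-style summary tables for a pipeline run
#'
#' Data tables behind the standard report figures: the read-length
#' histogram, the annotation category breakdown, the seed-substitution
#' spectrum, the DE scatter source, plus the library summary, catalog and
#' DE tables.
#'
#' @param res result list from [run_pipeline()].
#' @return named list of data.frames.
#' @export
summarize_run <- function(res) {
  lib_summary <- do.call(rbind, lapply(c("A", "B"), function(l) {
    s <- res[[paste0("clean_", l)]]$summary
    data.frame(library = l, raw_reads = s$raw_reads,
               clean_reads = s$clean_reads,
               clean_pct = round(100 * s$clean_fraction, 2),
               unique_tags = s$unique_tags,
               t(s$discards), stringsAsFactors = FALSE)
  }))
  list(library_summary = lib_summary,
       length_distribution = rbind(
         cbind(library = "A", length_distribution(res$tags_A)),
         cbind(library = "B", length_distribution(res$tags_B))),
       common_specific = data.frame(res$common_specific),
       mapping_summary = data.frame(res$mapping$summary),
       annotation_summary = annotation_summary(res$annotation),
       catalog = res$catalog,
       substitution_spectrum = res$spectrum,
       nta_profile = res$nta_profile,
       de_table = res$de$table,
       de_scatter = de_scatter_rows(res$de$table))
}
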