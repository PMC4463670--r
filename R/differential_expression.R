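#' Differential-expression configuration
#'
#' Thresholds for the two-library exact-test procedure: a minimum raw read
#' count (low-count miRNAs carry no usable signal), the floor substituted
#' for a normalized expression of exactly zero (so the log2 ratio is always
#' defined), removal of miRNAs below 1 read-per-million in both libraries,
#' and the fold-change/p-value significance gates. Both conventional
#' p-value gates (0.05 and the stricter 0.01) are supported; the default is
#' 0.01.
#'
#' @param min_reads minimum of `max(count_A, count_B)` to keep a miRNA.
#' @param ne_floor value substituted for a normalized expression of 0.
#' @param ne_min miRNAs below this NE in both libraries are filtered.
#' @param fc_threshold significance gate on `|log2ratio|`.
#' @param p_threshold significance gate on the p-value.
#' @param bh apply Benjamini-Hochberg correction to non-filtered rows
#'   before the p-value gate (off by default; the classical procedure uses
#'   raw p-values).
#' @return a `de_config` list.
#' @export
de_config <- function(min_reads = 100L, ne_floor = 0.01, ne_min = 1.0,
                      fc_threshold = 1.0, p_threshold = 0.01, bh = FALSE) {
  if (any(c(min_reads, ne_floor, ne_min, fc_threshold, p_threshold) <= 0)) {
    stop("all thresholds must be positive")
  }
  structure(list(min_reads = min_reads, ne_floor = ne_floor, ne_min = ne_min,
                 fc_threshold = fc_threshold, p_threshold = p_threshold,
                 bh = bh),
            class = "de_config")
}

#' Reads-per-million normalized expression
#'
#' `NE = count / total * 1e6`, the normalization of each miRNA's read count
#' by its library's total clean-read count.
#'
#' @param count raw read count(s), `0 <= count <= total`.
#' @param total library total clean-read count, `> 0`.
#' @return normalized expression value(s).
#' @export
normalize_expression <- function(count, total) {
  if (any(total <= 0)) stop("library total must be > 0")
  if (any(count < 0) || any(count > total)) {
    stop("counts must lie in [0, total]")
  }
  count / total * 1e6
}

#' Build the raw expression table for a catalog
#'
#' @param catalog catalog data.frame (`name`, `count_A`, `count_B`).
#' @param total_A,total_B library clean-read totals used as normalization
#'   denominators.
#' @return data.frame with raw counts, totals and per-library NE.
#' @export
expression_table <- function(catalog, total_A, total_B) {
  data.frame(name = catalog$name,
             count_A = catalog$count_A, count_B = catalog$count_B,
             total_A = total_A, total_B = total_B,
             NE_A = normalize_expression(catalog$count_A, total_A),
             NE_B = normalize_expression(catalog$count_B, total_B),
             stringsAsFactors = FALSE)
}

#' Apply expression floors and low-expression filters
#'
#' In order: a NE of exactly 0 becomes `ne_floor`; rows below `ne_min` in
#' both libraries are marked `filtered_low`; rows whose larger raw count is
#' below `min_reads` are marked `filtered_low`. The floor is applied first
#' so the log2 ratio is defined for every row.
#'
#' @param table expression table from [expression_table()].
#' @param config a [de_config()].
#' @return the table with adjusted `NE_A`/`NE_B`, `log2ratio` (B over A on
#'   adjusted NE) and a `status` column (`filtered_low` or pending).
#' @export
adjust_and_filter <- function(table, config = de_config()) {
  table$NE_A <- ifelse(table$NE_A == 0, config$ne_floor, table$NE_A)
  table$NE_B <- ifelse(table$NE_B == 0, config$ne_floor, table$NE_B)
  low_ne <- table$NE_A < config$ne_min & table$NE_B < config$ne_min
  low_reads <- pmax(table$count_A, table$count_B) < config$min_reads
  table$log2ratio <- log2(table$NE_B / table$NE_A)
  table$status <- ifelse(low_ne | low_reads, "filtered_low", "pending")
  table
}

#' Exact conditional p-value for a two-library count comparison
#'
#' The exact test for comparing one transcript's counts between two
#' sequencing libraries conditions on the observed count in one library:
#' given `x` counts among `N_A` reads, the count `y` among `N_B` reads
#' follows
#' \deqn{p(y|x) = (N_B/N_A)^y \frac{(x+y)!}{x!\,y!\,(1+N_B/N_A)^{x+y+1}}}
#' (a negative binomial with size `x+1` and success probability
#' `N_A/(N_A+N_B)`). The two-sided p-value doubles the smallest conditional
#' tail, evaluated in both conditioning orientations so the statistic is
#' symmetric in `(x, N_A) <-> (y, N_B)`, and is capped at 1.
#'
#' @param x,y raw counts in libraries A and B (vectorized).
#' @param n_a,n_b library totals.
#' @return two-sided p-values in (0, 1].
#' @export
count_pvalue <- function(x, y, n_a, n_b) {
  if (any(x < 0) || any(y < 0)) stop("counts must be non-negative")
  if (any(n_a <= 0) || any(n_b <= 0)) stop("library totals must be > 0")
  p_a <- n_a / (n_a + n_b)
  p_b <- n_b / (n_a + n_b)
  lo1 <- stats::pnbinom(y, size = x + 1, prob = p_a)
  hi1 <- 1 - stats::pnbinom(y - 1, size = x + 1, prob = p_a)
  lo2 <- stats::pnbinom(x, size = y + 1, prob = p_b)
  hi2 <- 1 - stats::pnbinom(x - 1, size = y + 1, prob = p_b)
  pmin(1, 2 * pmin(lo1, hi1, lo2, hi2))
}

#' Call differentially expressed miRNAs
#'
#' A non-filtered miRNA is significant when `|log2ratio| >= fc_threshold`
#' and `p <= p_threshold`; the direction follows the sign of the log2
#' ratio, which is oriented B over A (stated in every report header).
#'
#' @param table adjusted table from [adjust_and_filter()] (or a raw
#'   [expression_table()], adjusted on the fly).
#' @param config a [de_config()].
#' @return list with `table` (pvalue and status columns set) and `summary`
#'   (n tested, n significant, n up in each library).
#' @export
call_de <- function(table, config = de_config()) {
  if (!"status" %in% names(table)) {
    table <- adjust_and_filter(table, config)
  }
  table$pvalue <- count_pvalue(table$count_A, table$count_B,
                               table$total_A, table$total_B)
  p_gate <- table$pvalue
  open <- table$status != "filtered_low"
  if (isTRUE(config$bh)) {
    p_gate[open] <- stats::p.adjust(table$pvalue[open], method = "BH")
  }
  sig <- open & abs(table$log2ratio) >= config$fc_threshold &
    p_gate <= config$p_threshold
  table$status[open] <- "not_significant"
  table$status[sig & table$log2ratio > 0] <- "significant_up"
  table$status[sig & table$log2ratio < 0] <- "significant_down"
  summary <- list(n_total = nrow(table),
                  n_tested = sum(open),
                  n_significant = sum(sig),
                  n_up_B = sum(table$status == "significant_up"),
                  n_up_A = sum(table$status == "significant_down"),
                  orientation = "log2ratio = log2(NE_B / NE_A)")
  list(table = table, summary = summary)
}

#' Rows feeding a log2-ratio scatter report
#'
#' @param de_table the `table` element of [call_de()].
#' @return exactly the non-filtered rows.
#' @export
de_scatter_rows <- function(de_table) {
  de_table[de_table$status != "filtered_low", , drop = FALSE]
}
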