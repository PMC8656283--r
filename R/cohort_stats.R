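# Cohort-level summaries (counts/percentages per region and mutation type,
# coverage, allele fraction, mutation burden) and the Fisher exact
# region-enrichment test.

# half-up rounding, matching printed-table presentation (R's round() is
# round-half-even)
round_half_up <- function(x, digits = 1L) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Percentage as printed in summary tables
#'
#' `100 * count / total`, rounded half-up to `digits` decimals.
#'
#' @param count,total Numerator and denominator.
#' @param digits Decimal places (default 1).
#' @return Numeric percentage.
#' @export
#' @examples
#' pct(42380, 84571)   # 50.1
pct <- function(count, total, digits = 1L) {
  round_half_up(100 * count / total, digits)
}

#' Summarize a mutation cohort
#'
#' Builds a summary in the shape of a mutation-distribution table: one row
#' per region bucket (all, coding, noncoding, introns, 3'UTR, 5'UTR,
#' intergenic) with mutation counts, percentages of the cohort total,
#' unweighted mean coverage of mutated positions, mean alternate-allele
#' fraction (mutation-weighted), and counts/percentages of substitutions,
#' double substitutions and short (<4 nt) indels. Splice-site mutations are
#' counted as coding; deep-intronic records (not exome-covered) are
#' excluded from all tallies. Per-sample mutation burden is the
#' coding-region mutation count divided by the coding territory.
#'
#' @param records Annotated cohort mutation records (with `tumor_depth` and
#'   `tumor_af` carried through).
#' @param coding_territory_mbp Coding territory in Mbp (> 0) used as the
#'   burden denominator.
#' @return A list of class `CohortSummary`: `table` (data.frame as above),
#'   `burden` (data.frame sample, n_coding, mutations_per_mbp),
#'   `mean_coverage`, `mean_alt_fraction`.
#' @export
summarize_cohort <- function(records, coding_territory_mbp) {
  if (coding_territory_mbp <= 0) stop("coding_territory_mbp must be > 0")
  region <- as.character(records$region)
  keep <- region != "INTRON_DEEP"
  rec <- records[keep, , drop = FALSE]
  region <- region[keep]
  bucket <- ifelse(region %in% c("CODING", "SPLICE_SITE"), "coding",
            ifelse(region == "INTRON", "introns",
            ifelse(region == "UTR3", "3'UTR",
            ifelse(region == "UTR5", "5'UTR", "intergenic region"))))
  short_indel <- rec$mtype == "INDEL" & !rec$long_indel
  type <- ifelse(rec$mtype == "SNV", "sub",
          ifelse(rec$mtype == "DBS", "dbs",
          ifelse(short_indel, "indel", "other")))
  total <- nrow(rec)
  row_for <- function(name, sel) {
    n <- sum(sel)
    data.frame(
      region = name,
      n = n,
      pct = pct(n, total),
      mean_coverage = if (n) round_half_up(mean(rec$tumor_depth[sel]), 0) else NA,
      mean_alt_fraction = if (n) round_half_up(mean(rec$tumor_af[sel]), 2) else NA,
      n_sub = sum(sel & type == "sub"),
      pct_sub = pct(sum(sel & type == "sub"), max(n, 1L)),
      n_dbs = sum(sel & type == "dbs"),
      pct_dbs = pct(sum(sel & type == "dbs"), max(n, 1L)),
      n_indel = sum(sel & type == "indel"),
      pct_indel = pct(sum(sel & type == "indel"), max(n, 1L)),
      stringsAsFactors = FALSE)
  }
  tab <- rbind(
    row_for("all mutations", rep(TRUE, total)),
    row_for("coding", bucket == "coding"),
    row_for("noncoding", bucket != "coding"),
    row_for("introns", bucket == "introns"),
    row_for("3'UTR", bucket == "3'UTR"),
    row_for("5'UTR", bucket == "5'UTR"),
    row_for("intergenic region", bucket == "intergenic region")
  )
  cod <- rec[bucket == "coding", , drop = FALSE]
  samples <- sort(unique(records$sample_id))
  n_cod <- setNames(integer(length(samples)), samples)
  tt <- table(cod$sample_id)
  n_cod[names(tt)] <- as.integer(tt)
  burden <- data.frame(sample = samples, n_coding = as.integer(n_cod),
                       mutations_per_mbp =
                         round_half_up(n_cod / coding_territory_mbp, 1),
                       stringsAsFactors = FALSE, row.names = NULL)
  structure(list(table = tab, burden = burden,
                 mean_coverage = round_half_up(mean(rec$tumor_depth), 0),
                 mean_alt_fraction = round_half_up(mean(rec$tumor_af), 2)),
            class = "CohortSummary")
}

#' @export
print.CohortSummary <- function(x, ...) {
  print(x$table, row.names = FALSE)
  cat("mean coverage of mutated positions:", x$mean_coverage,
      "| mean alternate-allele fraction:", x$mean_alt_fraction, "\n")
  cat("mean burden:", round_half_up(mean(x$burden$mutations_per_mbp), 1),
      "mutations/Mbp (range",
      paste(range(x$burden$mutations_per_mbp), collapse = "-"), ")\n")
  invisible(x)
}

#' Fisher's exact test for a 2x2 table
#'
#' Exact two-sided p-value obtained by summing, over the hypergeometric
#' distribution with the observed margins, the probabilities of all tables
#' at most as probable as the observed one (probabilities equal to the
#' observed one within a 1e-7 relative tolerance count as ties, the
#' standard convention for this comparison in floating point); the odds
#' ratio is the sample odds ratio `(a*d)/(b*c)` (infinite when `b*c = 0`).
#'
#' @param tab 2x2 numeric matrix (or vector a, b, c, d filled by row) of
#'   nonnegative counts, at least one margin positive.
#' @return A list with `odds_ratio` and `p_value`.
#' @export
#' @examples
#' fisher_exact(matrix(c(10, 2, 3, 15), 2, byrow = TRUE))
fisher_exact <- function(tab) {
  if (!is.matrix(tab)) tab <- matrix(as.numeric(tab), 2L, 2L, byrow = TRUE)
  stopifnot(all(dim(tab) == 2L), all(tab >= 0))
  a <- tab[1, 1]; b <- tab[1, 2]; cc <- tab[2, 1]; d <- tab[2, 2]
  if (a + b + cc + d == 0) stop("all-zero table")
  m <- a + cc                      # first-column margin
  n <- b + d
  k <- a + b                       # first-row margin
  lo <- max(0, k - n); hi <- min(k, m)
  probs <- dhyper(lo:hi, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  or <- if (b * cc == 0) {
    if (a * d == 0) NaN else Inf
  } else (a * d) / (b * cc)
  list(odds_ratio = or, p_value = min(1, p))
}
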