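# Hotspot and frequently-mutated-gene detection.
#
# A hotspot is a genomic position mutated in at least `hotspot_min_samples`
# distinct samples; mutations in directly adjacent nucleotides are merged
# (transitively) into one hotspot whose sample count is the union of the
# member positions' carriers. A sample counts once per hotspot regardless
# of how many mutations it carries there.

#' Recurrence thresholds
#'
#' Defaults follow the frequently-mutated-gene definition of a 27-sample
#' cohort: hotspots at 3 samples (>10%), nonsynonymous coding mutations in
#' at least 5 samples, 5'UTR and 3'UTR mutations in at least 4, intronic
#' mutations (within `intron_recurrence_window` nt of an exon boundary) in
#' at least 5. Genes in `hypermutated_exclusion` are dropped before
#' thresholding.
#'
#' @param hotspot_min_samples,cds_min_samples,utr5_min_samples,utr3_min_samples,intron_min_samples
#'   Distinct-sample thresholds.
#' @param intron_recurrence_window Max distance (nt) from an exon boundary
#'   for an intronic mutation to count (default 40).
#' @param merge_distance Genomic adjacency distance for hotspot merging
#'   (default 1 = directly adjacent nucleotides).
#' @param hypermutated_exclusion Character vector of gene ids to exclude.
#' @return A list of class `RecurrenceParams`.
#' @export
recurrence_params <- function(hotspot_min_samples = 3L, cds_min_samples = 5L,
                              utr5_min_samples = 4L, utr3_min_samples = 4L,
                              intron_min_samples = 5L,
                              intron_recurrence_window = 40L,
                              merge_distance = 1L,
                              hypermutated_exclusion = character(0)) {
  stopifnot(hotspot_min_samples >= 1, cds_min_samples >= 1,
            utr5_min_samples >= 1, utr3_min_samples >= 1,
            intron_min_samples >= 1, intron_recurrence_window >= 0,
            merge_distance >= 1)
  structure(list(hotspot_min_samples = as.integer(hotspot_min_samples),
                 cds_min_samples = as.integer(cds_min_samples),
                 utr5_min_samples = as.integer(utr5_min_samples),
                 utr3_min_samples = as.integer(utr3_min_samples),
                 intron_min_samples = as.integer(intron_min_samples),
                 intron_recurrence_window = as.integer(intron_recurrence_window),
                 merge_distance = as.integer(merge_distance),
                 hypermutated_exclusion = hypermutated_exclusion),
            class = "RecurrenceParams")
}

#' Find mutation hotspots
#'
#' Groups mutations by genomic position (a double substitution contributes
#' its full two-base span; an indel its reference span), merges mutated
#' positions within `merge_distance` transitively, and returns merged
#' clusters whose distinct-sample union reaches `hotspot_min_samples`.
#'
#' @param records Cohort mutation records (filtered, merged).
#' @param params A [recurrence_params()] object.
#' @return data.frame with columns `chrom`, `start`, `end`, `n_positions`,
#'   `n_samples`, `n_mutations`, `samples` (comma-separated ids), ordered by
#'   (chrom, start).
#' @export
find_hotspots <- function(records, params = recurrence_params()) {
  if (!nrow(records))
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), n_positions = integer(),
                      n_samples = integer(), n_mutations = integer(),
                      samples = character(), stringsAsFactors = FALSE))
  span <- records$end - records$pos + 1L
  i <- rep.int(seq_len(nrow(records)), span)
  off <- sequence(span) - 1L
  ex <- data.frame(sample_id = records$sample_id[i],
                   chrom = records$chrom[i],
                   pos = records$pos[i] + off,
                   stringsAsFactors = FALSE)
  ex <- unique(ex)
  out <- list()
  for (ch in sort(unique(ex$chrom))) {
    e <- ex[ex$chrom == ch, , drop = FALSE]
    pos <- sort(unique(e$pos))
    cl <- cumsum(c(TRUE, diff(pos) > params$merge_distance))
    cl_of <- cl[match(e$pos, pos)]
    n_cl <- cl[length(cl)]
    n_positions <- tabulate(cl, n_cl)
    starts <- pos[!duplicated(cl)]
    ends <- pos[rev(!duplicated(rev(cl)))]
    n_mut <- tabulate(cl_of, n_cl)
    pair_dup <- duplicated(paste(cl_of, e$sample_id))
    n_smp <- tabulate(cl_of[!pair_dup], n_cl)
    keep <- which(n_smp >= params$hotspot_min_samples)
    if (!length(keep)) next
    smp_str <- vapply(keep, function(k)
      paste(sort(unique(e$sample_id[cl_of == k])), collapse = ","),
      character(1))
    out[[length(out) + 1L]] <- data.frame(
      chrom = ch, start = starts[keep], end = ends[keep],
      n_positions = n_positions[keep], n_samples = n_smp[keep],
      n_mutations = n_mut[keep], samples = smp_str,
      stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(), start = integer(), end = integer(),
               n_positions = integer(), n_samples = integer(),
               n_mutations = integer(), samples = character(),
               stringsAsFactors = FALSE)
  res[order(res$chrom, res$start), , drop = FALSE]
}

#' Find frequently mutated genes per region
#'
#' Counts distinct samples with qualifying mutations per gene and region:
#' coding counts nonsynonymous mutations only (missense, nonsense,
#' stop-loss, frameshift, inframe indel) plus splice-site mutations (introns
#' within +/-2 nt of exons, counted as coding); 5'UTR and 3'UTR count any
#' mutation; introns count only mutations within
#' `intron_recurrence_window` nt of an exon boundary. Genes on the
#' hypermutated exclusion list are dropped before thresholding.
#'
#' @param records Annotated cohort mutation records.
#' @param params A [recurrence_params()] object.
#' @return data.frame with columns `gene_id`, `region` (CODING/UTR5/UTR3/
#'   INTRON), `n_samples`, `n_mutations`, ordered by region then descending
#'   sample count.
#' @export
find_frequently_mutated_genes <- function(records,
                                          params = recurrence_params()) {
  region <- as.character(records$region)
  qual_region <- rep(NA_character_, nrow(records))
  nonsyn <- c("missense", "nonsense", "stop_loss", "frameshift",
              "inframe_indel")
  qual_region[region == "CODING" & records$effect %in% nonsyn] <- "CODING"
  qual_region[region == "SPLICE_SITE"] <- "CODING"
  qual_region[region == "UTR5"] <- "UTR5"
  qual_region[region == "UTR3"] <- "UTR3"
  qual_region[region == "INTRON" &
                !is.na(records$dist_to_exon) &
                records$dist_to_exon <= params$intron_recurrence_window] <-
    "INTRON"
  keep <- !is.na(qual_region) & !is.na(records$gene_id) &
    !(records$gene_id %in% params$hypermutated_exclusion)
  if (!any(keep))
    return(data.frame(gene_id = character(), region = character(),
                      n_samples = integer(), n_mutations = integer(),
                      stringsAsFactors = FALSE))
  df <- data.frame(gene_id = records$gene_id[keep],
                   region = qual_region[keep],
                   sample_id = records$sample_id[keep],
                   stringsAsFactors = FALSE)
  key <- paste(df$gene_id, df$region, sep = "\r")
  n_mut <- table(key)
  n_smp <- tapply(df$sample_id, key, function(x) length(unique(x)))
  parts <- strsplit(names(n_smp), "\r", fixed = TRUE)
  res <- data.frame(gene_id = vapply(parts, `[`, character(1), 1L),
                    region = vapply(parts, `[`, character(1), 2L),
                    n_samples = as.integer(n_smp),
                    n_mutations = as.integer(n_mut[names(n_smp)]),
                    stringsAsFactors = FALSE)
  thr <- c(CODING = params$cds_min_samples, UTR5 = params$utr5_min_samples,
           UTR3 = params$utr3_min_samples, INTRON = params$intron_min_samples)
  res <- res[res$n_samples >= thr[res$region], , drop = FALSE]
  res <- res[order(res$region, -res$n_samples, res$gene_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Write hotspots as BED (plus a TSV with sample lists)
#'
#' BED is 0-based half-open per the BED standard; the TSV keeps the 1-based
#' inclusive coordinates and carrier sample lists.
#'
#' @param hotspots Result of [find_hotspots()].
#' @param bed_path,tsv_path Output paths (either may be `NULL` to skip).
#' @export
write_hotspots <- function(hotspots, bed_path = NULL, tsv_path = NULL) {
  if (!is.null(bed_path)) {
    bed <- data.frame(hotspots$chrom, hotspots$start - 1L, hotspots$end,
                      paste0("hotspot_", seq_len(nrow(hotspots))),
                      hotspots$n_samples, ".")
    write.table(bed, bed_path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  if (!is.null(tsv_path))
    write.table(hotspots, tsv_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  invisible(NULL)
}
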