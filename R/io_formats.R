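# Readers/writers for the standard formats the pipeline touches and the
# in-memory containers they populate. Coordinates are 1-based inclusive at
# every interface (VCF/GTF convention).

REGION_LEVELS <- c("CODING", "SPLICE_SITE", "UTR5", "UTR3", "INTRON",
                   "INTRON_DEEP", "INTERGENIC")

MUTATION_TABLE_COLS <- c("sample", "chrom", "pos", "end", "ref", "alt",
                         "type", "region", "effect", "gene", "hgvs_c",
                         "context", "tumor_depth", "tumor_af")

#' Load somatic calls from a tumor/normal VCF
#'
#' Reads a VCF 4.x file and returns one call per alternate allele, carrying
#' tumor and normal allelic read support taken from the per-sample `AD`
#' FORMAT field. Depth is `sum(AD)` for self-consistency of allele-fraction
#' computation; `DP` is ignored. Multi-allelic records are decomposed into
#' one call per alternate allele.
#'
#' @param vcf_path Path to a VCF file (plain text or gzipped).
#' @param tumor_sample,normal_sample Sample column names in the VCF header.
#' @param sample_id Identifier stored in the `sample_id` column; defaults to
#'   `tumor_sample`.
#' @return A data.frame of somatic calls with columns `sample_id`, `chrom`,
#'   `pos`, `ref`, `alt`, `tumor_alt`, `tumor_depth`, `normal_alt`,
#'   `normal_depth`, `flags` (character, comma-separated, `""` if none).
#' @export
load_somatic_calls <- function(vcf_path, tumor_sample, normal_sample,
                               sample_id = tumor_sample) {
  if (!file.exists(vcf_path)) stop("no such VCF file: ", vcf_path)
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  smp <- colnames(v@gt)[-1]
  if (!tumor_sample %in% smp)
    stop("sample '", tumor_sample, "' absent from VCF header")
  if (!normal_sample %in% smp)
    stop("sample '", normal_sample, "' absent from VCF header")
  fix <- v@fix
  n <- nrow(fix)
  if (is.null(n) || n == 0L) {
    return(empty_calls())
  }
  ad <- vcfR::extract.gt(v, element = "AD")
  if (is.null(ad) || !all(c(tumor_sample, normal_sample) %in% colnames(ad)))
    stop("missing allelic depth (AD) in FORMAT")
  ad_t <- ad[, tumor_sample]
  ad_n <- ad[, normal_sample]
  if (anyNA(ad_t) || anyNA(ad_n))
    stop("missing allelic depth (AD) for one or more records")
  alts <- strsplit(fix[, "ALT"], ",", fixed = TRUE)
  n_alt <- lengths(alts)
  adt <- strsplit(ad_t, ",", fixed = TRUE)
  adn <- strsplit(ad_n, ",", fixed = TRUE)
  if (any(lengths(adt) != n_alt + 1L) || any(lengths(adn) != n_alt + 1L))
    stop("malformed AD: entry count must be 1 + number of ALT alleles")
  idx <- rep.int(seq_len(n), n_alt)
  alt_k <- sequence(n_alt)              # which alt within the record
  tum <- suppressWarnings(lapply(adt, as.numeric))
  nor <- suppressWarnings(lapply(adn, as.numeric))
  if (anyNA(unlist(tum)) || anyNA(unlist(nor)))
    stop("malformed AD: non-numeric allelic depth")
  tumor_depth <- vapply(tum, sum, numeric(1))[idx]
  normal_depth <- vapply(nor, sum, numeric(1))[idx]
  tumor_alt <- mapply(function(x, k) x[k + 1L], tum[idx], alt_k)
  normal_alt <- mapply(function(x, k) x[k + 1L], nor[idx], alt_k)
  calls <- data.frame(
    sample_id = sample_id,
    chrom = fix[idx, "CHROM"],
    pos = as.integer(fix[idx, "POS"]),
    ref = toupper(fix[idx, "REF"]),
    alt = toupper(unlist(alts)),
    tumor_alt = as.integer(round(tumor_alt)),
    tumor_depth = as.integer(round(tumor_depth)),
    normal_alt = as.integer(round(normal_alt)),
    normal_depth = as.integer(round(normal_depth)),
    flags = "",
    stringsAsFactors = FALSE
  )
  validate_calls(calls)
  calls
}

empty_calls <- function() {
  data.frame(sample_id = character(), chrom = character(), pos = integer(),
             ref = character(), alt = character(), tumor_alt = integer(),
             tumor_depth = integer(), normal_alt = integer(),
             normal_depth = integer(), flags = character(),
             stringsAsFactors = FALSE)
}

validate_calls <- function(calls) {
  stopifnot(all(calls$pos >= 1L),
            all(calls$tumor_alt >= 0L),
            all(calls$tumor_alt <= calls$tumor_depth),
            all(calls$normal_alt >= 0L),
            all(calls$normal_alt <= calls$normal_depth))
  if (any(calls$ref == calls$alt)) stop("ref and alt alleles must differ")
  if (any(!nzchar(calls$ref)) || any(!nzchar(calls$alt)))
    stop("empty allele string")
  invisible(calls)
}

#' Construct a gene model set
#'
#' Low-level constructor shared by [load_gene_models()] and the synthetic
#' generator. UTR intervals are derived as exon minus CDS, split into 5' and
#' 3' sides by strand. Transcripts whose total CDS length is not divisible
#' by 3 are flagged (`cds_ok = FALSE`), excluded from effect prediction, and
#' a warning is emitted. The canonical transcript of each gene is the one
#' with the longest CDS (ties broken by transcript id).
#'
#' @param exons,cds `GRanges` with metadata columns `transcript_id`,
#'   `gene_id` and optionally `gene_name`.
#' @return An object of class `GeneModelSet`: a list with elements
#'   `transcripts` (data.frame), `exons`, `cds`, `utr5`, `utr3` (GRanges).
#' @export
gene_model_set <- function(exons, cds) {
  stopifnot(is(exons, "GRanges"), is(cds, "GRanges"))
  for (gr in list(exons, cds)) {
    if (!all(c("transcript_id", "gene_id") %in% colnames(mcols(gr))))
      stop("exon/CDS ranges need transcript_id and gene_id metadata")
  }
  if (is.null(mcols(exons)$gene_name)) mcols(exons)$gene_name <- mcols(exons)$gene_id
  # plain-vector views (per-transcript S4 subsetting is too slow at scale)
  exd <- data.frame(chrom = as.character(seqnames(exons)),
                    start = start(exons), end = end(exons),
                    strand = as.character(strand(exons)),
                    tx = mcols(exons)$transcript_id,
                    gene = mcols(exons)$gene_id,
                    name = mcols(exons)$gene_name, stringsAsFactors = FALSE)
  cdd <- data.frame(start = start(cds), end = end(cds),
                    tx = mcols(cds)$transcript_id, stringsAsFactors = FALSE)
  ex_by <- split(seq_len(nrow(exd)), exd$tx)
  cds_by <- split(seq_len(nrow(cdd)), cdd$tx)
  tx_ids <- sort(names(ex_by))
  u5_rows <- list(); u3_rows <- list()
  meta <- vector("list", length(tx_ids))
  for (i in seq_along(tx_ids)) {
    tx <- tx_ids[i]
    e <- exd[ex_by[[tx]], , drop = FALSE]
    e <- e[order(e$start), , drop = FALSE]
    strand_tx <- e$strand[1]
    if (any(e$strand != strand_tx)) stop("mixed strand within transcript ", tx)
    if (nrow(e) > 1L && any(e$start[-1] <= e$end[-nrow(e)]))
      stop("overlapping exons within transcript ", tx)
    cd_idx <- cds_by[[tx]]
    cds_len <- 0L
    if (!is.null(cd_idx)) {
      cd <- cdd[cd_idx, , drop = FALSE]
      within <- vapply(seq_len(nrow(cd)), function(k)
        any(e$start <= cd$start[k] & cd$end[k] <= e$end), logical(1))
      if (!all(within)) stop("CDS feature outside any exon in transcript ", tx)
      cds_len <- sum(cd$end - cd$start + 1L)
      cmin <- min(cd$start); cmax <- max(cd$end)
      # exon minus CDS, split into the flank left/right of the CDS body
      ls <- e$start; le <- pmin(e$end, cmin - 1L)
      left <- which(ls <= le)
      rs <- pmax(e$start, cmax + 1L); re <- e$end
      right <- which(rs <= re)
      mk <- function(s, en, side) if (length(s))
        data.frame(chrom = e$chrom[1], start = s, end = en,
                   strand = strand_tx, tx = tx, gene = e$gene[1],
                   name = e$name[1], stringsAsFactors = FALSE) else NULL
      lf <- mk(ls[left], le[left]); rt <- mk(rs[right], re[right])
      if (strand_tx == "+") { u5_rows[[tx]] <- lf; u3_rows[[tx]] <- rt }
      else { u5_rows[[tx]] <- rt; u3_rows[[tx]] <- lf }
    }
    meta[[i]] <- data.frame(
      transcript_id = tx, gene_id = e$gene[1], gene_name = e$name[1],
      chrom = e$chrom[1], strand = strand_tx, n_exons = nrow(e),
      cds_len = cds_len, cds_ok = cds_len > 0L && cds_len %% 3L == 0L,
      stringsAsFactors = FALSE
    )
  }
  transcripts <- do.call(rbind, meta)
  utr_gr <- function(rows) {
    df <- do.call(rbind, rows)
    if (is.null(df)) return(GRanges())
    GRanges(df$chrom, IRanges(df$start, df$end), strand = df$strand,
            transcript_id = df$tx, gene_id = df$gene, gene_name = df$name)
  }
  bad <- transcripts$transcript_id[transcripts$cds_len > 0L & !transcripts$cds_ok]
  if (length(bad))
    warning("CDS length not divisible by 3; excluded from effect prediction: ",
            paste(bad, collapse = ", "))
  # canonical = longest (valid) CDS per gene, tie-break on transcript id
  ord <- order(transcripts$gene_id, -transcripts$cds_ok,
               -transcripts$cds_len, transcripts$transcript_id)
  tt <- transcripts[ord, ]
  canonical_ids <- tt$transcript_id[!duplicated(tt$gene_id)]
  transcripts$canonical <- transcripts$transcript_id %in% canonical_ids
  models <- list(
    transcripts = transcripts,
    exons = exons,
    cds = cds,
    utr5 = utr_gr(u5_rows),
    utr3 = utr_gr(u3_rows),
    .cache = new.env(parent = emptyenv())
  )
  class(models) <- "GeneModelSet"
  models
}

#' @export
print.GeneModelSet <- function(x, ...) {
  cat("GeneModelSet:", length(unique(x$transcripts$gene_id)), "genes,",
      nrow(x$transcripts), "transcripts,",
      sum(x$transcripts$cds_ok), "usable for effect prediction\n")
  invisible(x)
}

#' Load gene models from a GTF-like file
#'
#' Parses `exon` and `CDS` features (attributes `gene_id`, `transcript_id`,
#' optionally `gene_name`) and assembles a [gene_model_set()]. UTRs are
#' derived as exon minus CDS split by strand.
#'
#' @param path Path to a GTF file.
#' @return A `GeneModelSet`.
#' @export
load_gene_models <- function(path) {
  if (!file.exists(path)) stop("no such gene model file: ", path)
  gr <- rtracklayer::import(path, format = "gtf")
  keep <- mcols(gr)$type %in% c("exon", "CDS")
  gr <- gr[keep]
  if (!length(gr)) stop("no exon/CDS features in ", path)
  if (is.null(mcols(gr)$gene_name)) mcols(gr)$gene_name <- mcols(gr)$gene_id
  exons <- gr[mcols(gr)$type == "exon"]
  cds <- gr[mcols(gr)$type == "CDS"]
  mc_keep <- c("transcript_id", "gene_id", "gene_name")
  mcols(exons) <- mcols(exons)[, mc_keep]
  mcols(cds) <- mcols(cds)[, mc_keep]
  gene_model_set(exons, cds)
}

#' Write gene models as GTF
#'
#' Emits exon and CDS features of a `GeneModelSet` in GTF format, the format
#' [load_gene_models()] reads back.
#'
#' @param models A `GeneModelSet`.
#' @param path Output path.
#' @export
write_gtf <- function(models, path) {
  fmt <- function(gr, type) {
    if (!length(gr)) return(character())
    sprintf(paste0('%s\tuvsomatic\t%s\t%d\t%d\t.\t%s\t.\t',
                   'gene_id "%s"; transcript_id "%s"; gene_name "%s";'),
            as.character(seqnames(gr)), type, start(gr), end(gr),
            as.character(strand(gr)), mcols(gr)$gene_id,
            mcols(gr)$transcript_id, mcols(gr)$gene_name)
  }
  ex <- models$exons
  if (is.null(mcols(ex)$gene_name)) mcols(ex)$gene_name <- mcols(ex)$gene_id
  cd <- models$cds
  if (is.null(mcols(cd)$gene_name)) mcols(cd)$gene_name <- mcols(cd)$gene_id
  lines <- c(fmt(ex, "exon"), fmt(cd, "CDS"))
  ord <- order(sub(".*transcript_id \"([^\"]+)\".*", "\\1", lines),
               as.integer(sub("^[^\t]+\t[^\t]+\t[^\t]+\t([0-9]+)\t.*", "\\1", lines)))
  writeLines(lines[ord], path)
  invisible(path)
}

#' Write a mutation table
#'
#' Tab-separated, `"."` for missing, no quoting; deterministic row order
#' (chrom, pos, sample). [read_mutation_table()] round-trips the fields.
#'
#' @param records Annotated mutation records (data.frame).
#' @param path Output path.
#' @export
write_mutation_table <- function(records, path) {
  df <- as.data.frame(records, stringsAsFactors = FALSE)
  out <- data.frame(
    sample = df$sample_id %||% character(0),
    chrom = df$chrom %||% character(0),
    pos = df$pos %||% integer(0),
    end = df$end %||% integer(0),
    ref = df$ref %||% character(0),
    alt = df$alt %||% character(0),
    type = df$mtype %||% character(0),
    region = as.character(df$region %||% character(0)),
    effect = as.character(df$effect %||% character(0)),
    gene = df$gene_id %||% character(0),
    hgvs_c = df$hgvs_c %||% character(0),
    context = df$context_index %||% integer(0),
    tumor_depth = df$tumor_depth %||% integer(0),
    tumor_af = df$tumor_af %||% numeric(0),
    stringsAsFactors = FALSE
  )
  if (nrow(out)) {
    out <- out[order(out$chrom, out$pos, out$sample), , drop = FALSE]
    for (cc in names(out)) {
      v <- out[[cc]]
      if (is.numeric(v) && cc == "tumor_af") v <- format(v, digits = 6, trim = TRUE)
      v <- as.character(v)
      v[is.na(v) | v == "NA" | v == ""] <- "."
      out[[cc]] <- v
    }
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  invisible(path)
}

#' Read a mutation table written by [write_mutation_table()]
#'
#' @param path Path to the TSV.
#' @return A data.frame of mutation records with the in-memory column names
#'   (`sample_id`, `mtype`, `gene_id`, `context_index`, ...).
#' @export
read_mutation_table <- function(path) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                   colClasses = "character", na.strings = ".")
  data.frame(
    sample_id = df$sample, chrom = df$chrom,
    pos = as.integer(df$pos), end = as.integer(df$end),
    ref = df$ref, alt = df$alt, mtype = df$type,
    region = df$region, effect = df$effect, gene_id = df$gene,
    hgvs_c = df$hgvs_c, context_index = as.integer(df$context),
    tumor_depth = as.integer(df$tumor_depth),
    tumor_af = as.numeric(df$tumor_af),
    stringsAsFactors = FALSE
  )
}

#' Read a site list (germline or panel-of-normals)
#'
#' Accepts either a 4-column TSV (`chrom`, `pos`, `ref`, `alt`; header
#' optional) or a sites-only VCF (`.vcf`/`.vcf.gz` extension).
#'
#' @param path Path to the site list.
#' @return data.frame with columns `chrom`, `pos`, `ref`, `alt`; keys unique.
#' @export
read_site_list <- function(path) {
  if (!file.exists(path)) stop("no such site list: ", path)
  if (grepl("\\.vcf(\\.gz)?$", path)) {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- v@fix
    alts <- strsplit(fix[, "ALT"], ",", fixed = TRUE)
    idx <- rep.int(seq_len(nrow(fix)), lengths(alts))
    df <- data.frame(chrom = fix[idx, "CHROM"], pos = as.integer(fix[idx, "POS"]),
                     ref = fix[idx, "REF"], alt = unlist(alts),
                     stringsAsFactors = FALSE)
  } else {
    df <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
    if (!all(c("chrom", "pos") %in% names(df))) {
      df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                       colClasses = "character")
      names(df)[1:4] <- c("chrom", "pos", "ref", "alt")
    }
    df <- data.frame(chrom = df$chrom, pos = as.integer(df$pos),
                     ref = toupper(df$ref), alt = toupper(df$alt),
                     stringsAsFactors = FALSE)
  }
  unique(df)
}

#' Write per-sample tumor/normal VCFs
#'
#' Emits one minimal VCF 4.2 file per sample (FORMAT `AD:DP`, tumor and
#' normal columns), the format [load_somatic_calls()] reads. Used by the
#' synthetic generator; records are sorted by (chrom, pos, alt).
#'
#' @param calls Somatic call data.frame (see [load_somatic_calls()]).
#' @param dir Output directory (created if needed).
#' @param reference Optional `DNAStringSet` used to emit contig lengths.
#' @return Named character vector of file paths (one per sample).
#' @export
write_cohort_vcfs <- function(calls, dir, reference = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  samples <- sort(unique(calls$sample_id))
  paths <- setNames(character(length(samples)), samples)
  contigs <- ""
  if (!is.null(reference)) {
    contigs <- sprintf("##contig=<ID=%s,length=%d>", names(reference),
                       Biostrings::width(reference))
  }
  for (s in samples) {
    cs <- calls[calls$sample_id == s, , drop = FALSE]
    cs <- cs[order(cs$chrom, cs$pos, cs$alt), , drop = FALSE]
    hdr <- c(
      "##fileformat=VCFv4.2",
      "##source=uvsomatic-simulator",
      contigs[nzchar(contigs)],
      '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths">',
      '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
      paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
             s, "_T\t", s, "_N")
    )
    body <- sprintf(
      "%s\t%d\t.\t%s\t%s\t.\tPASS\t.\tAD:DP\t%d,%d:%d\t%d,%d:%d",
      cs$chrom, cs$pos, cs$ref, cs$alt,
      cs$tumor_depth - cs$tumor_alt, cs$tumor_alt, cs$tumor_depth,
      cs$normal_depth - cs$normal_alt, cs$normal_alt, cs$normal_depth
    )
    p <- file.path(dir, paste0(s, ".vcf"))
    writeLines(c(hdr, body), p)
    paths[s] <- p
  }
  paths
}

#' Assemble a multi-sample cohort from per-sample VCFs
#'
#' @param vcf_paths Named character vector of VCF paths; names are sample
#'   ids. Tumor/normal sample columns are assumed to be `<id>_T` / `<id>_N`
#'   unless given explicitly.
#' @param reference A `DNAStringSet` reference.
#' @param models A `GeneModelSet`.
#' @param tumor_suffix,normal_suffix Suffixes forming the VCF column names.
#' @return A list of class `Cohort` with elements `samples`, `calls`
#'   (one data.frame, all samples), `reference`, `models`.
#' @export
load_cohort <- function(vcf_paths, reference, models,
                        tumor_suffix = "_T", normal_suffix = "_N") {
  ids <- names(vcf_paths)
  if (is.null(ids) || any(!nzchar(ids))) stop("vcf_paths must be named by sample id")
  if (anyDuplicated(ids)) stop("duplicate sample ids")
  calls <- lapply(ids, function(s) {
    load_somatic_calls(vcf_paths[[s]], paste0(s, tumor_suffix),
                       paste0(s, normal_suffix), sample_id = s)
  })
  calls <- do.call(rbind, calls)
  if (nrow(calls) && !all(calls$chrom %in% names(reference)))
    stop("call on contig absent from the reference")
  structure(list(samples = ids, calls = calls, reference = reference,
                 models = models), class = "Cohort")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
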