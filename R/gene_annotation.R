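# Gene-subregion classification and coding-effect prediction.
#
# Classification priority when a position is ambiguous across genes:
# CODING > SPLICE_SITE > UTR5 > UTR3 > INTRON > INTRON_DEEP > INTERGENIC.
# SPLICE_SITE means intronic within `splice_window` nt of an exon boundary
# and is counted as coding in all downstream tallies. INTRON means intronic
# within `intron_prox_window` nt of a boundary; deeper intronic positions
# are classified INTRON_DEEP and excluded from all region tallies (they are
# not captured by exome sequencing). The full annotated 3'UTR is classified
# UTR3: proximal-window semantics of exome capture are a property of the
# data (and of the simulator's covered territory), not of the annotation.
#
# Internally an annotation index maps every genomic position of a contig to
# (region code, gene, transcript coordinate on the canonical transcript,
# nearest-exon anchor and distance for intronic positions), so cohort-scale
# annotation is vectorized lookups. Only canonical transcripts (longest
# valid CDS per gene) are used.

REGION_CODE <- c(CODING = 1L, SPLICE_SITE = 2L, UTR5 = 3L, UTR3 = 4L,
                 INTRON = 5L, INTRON_DEEP = 6L, INTERGENIC = 7L)

#' Annotation parameters
#'
#' @param splice_window Intronic distance (nt) from an exon boundary within
#'   which a position is a splice site, counted as coding (default 2).
#' @param intron_prox_window Intronic distance (nt) within which a position
#'   is classified INTRON; deeper positions are INTRON_DEEP and dropped from
#'   region tallies (default 100).
#' @param utr3_prox_window 3'UTR proximity window (nt); not a classification
#'   cutoff (the whole annotated 3'UTR is UTR3) but exposed for covered-
#'   territory computations (default 100).
#' @return A list of class `AnnotationParams`.
#' @export
annotation_params <- function(splice_window = 2L, intron_prox_window = 100L,
                              utr3_prox_window = 100L) {
  stopifnot(splice_window >= 0, intron_prox_window >= splice_window)
  structure(list(splice_window = as.integer(splice_window),
                 intron_prox_window = as.integer(intron_prox_window),
                 utr3_prox_window = as.integer(utr3_prox_window)),
            class = "AnnotationParams")
}

# transcript-order exon map: genomic position -> transcript coordinate
tx_exonic_map <- function(starts, ends, strand) {
  w <- ends - starts + 1L
  ord <- if (strand == "+") seq_along(starts) else rev(seq_along(starts))
  off <- cumsum(c(0L, w[ord]))[seq_along(ord)]
  pos <- integer(sum(w)); tpos <- integer(sum(w)); k <- 0L
  for (j in seq_along(ord)) {
    i <- ord[j]
    p <- starts[i]:ends[i]
    t <- if (strand == "+") off[j] + seq_len(w[i]) else off[j] + rev(seq_len(w[i]))
    pos[(k + 1L):(k + w[i])] <- p
    tpos[(k + 1L):(k + w[i])] <- t
    k <- k + w[i]
  }
  list(pos = pos, tpos = tpos)
}

# Build (and cache on the GeneModelSet) the annotation index.
annotation_index <- function(models, reference, params = annotation_params()) {
  stopifnot(inherits(models, "GeneModelSet"))
  key <- paste0("idx_", params$splice_window, "_", params$intron_prox_window)
  cached <- models$.cache[[key]]
  if (!is.null(cached)) return(cached)

  chroms <- names(reference)
  chrom_len <- setNames(Biostrings::width(reference), chroms)
  maps <- lapply(chroms, function(ch) list(
    region = rep.int(REGION_CODE[["INTERGENIC"]], chrom_len[[ch]]),
    gene = integer(chrom_len[[ch]]),
    tpos = rep.int(NA_integer_, chrom_len[[ch]]),
    anchor = rep.int(NA_integer_, chrom_len[[ch]]),
    dist = rep.int(NA_integer_, chrom_len[[ch]])
  ))
  names(maps) <- chroms

  tx_tab <- models$transcripts
  canon <- tx_tab[tx_tab$canonical & tx_tab$cds_ok, , drop = FALSE]
  skipped <- setdiff(unique(tx_tab$gene_id), canon$gene_id)
  if (length(skipped))
    message(length(skipped),
            " gene(s) without a valid canonical CDS ignored by annotation")
  gene_ids <- sort(unique(canon$gene_id))
  txinfo <- vector("list", nrow(canon))
  names(txinfo) <- canon$transcript_id

  # plain-vector exon/CDS tables; per-transcript S4 ops are too slow at scale
  exd <- data.frame(chrom = as.character(seqnames(models$exons)),
                    start = start(models$exons), end = end(models$exons),
                    tx = mcols(models$exons)$transcript_id,
                    stringsAsFactors = FALSE)
  cdd <- data.frame(start = start(models$cds), end = end(models$cds),
                    tx = mcols(models$cds)$transcript_id,
                    stringsAsFactors = FALSE)
  ex_by <- split(seq_len(nrow(exd)), exd$tx)
  cds_by <- split(seq_len(nrow(cdd)), cdd$tx)
  chr_seq <- lapply(chroms, function(ch) as.character(reference[[ch]]))
  names(chr_seq) <- chroms

  # per-class accumulators: positions + payloads, filled per transcript
  acc <- lapply(REGION_CODE, function(i) list())
  push <- function(class, ch, pos, gene, tpos = NULL, anchor = NULL, dist = NULL) {
    if (!length(pos)) return()
    acc[[class]][[length(acc[[class]]) + 1L]] <<- list(
      ch = ch, pos = pos, gene = rep.int(gene, length(pos)),
      tpos = tpos %||% rep.int(NA_integer_, length(pos)),
      anchor = anchor %||% rep.int(NA_integer_, length(pos)),
      dist = dist %||% rep.int(NA_integer_, length(pos)))
  }

  for (r in seq_len(nrow(canon))) {
    tx <- canon$transcript_id[r]
    gidx <- match(canon$gene_id[r], gene_ids)
    e <- exd[ex_by[[tx]], , drop = FALSE]
    e <- e[order(e$start), , drop = FALSE]
    cd <- cdd[cds_by[[tx]], , drop = FALSE]
    ch <- e$chrom[1]
    if (!ch %in% chroms) stop("unknown contig in gene models: ", ch)
    strand_tx <- canon$strand[r]
    emap <- tx_exonic_map(e$start, e$end, strand_tx)
    # transcript sequence in transcript order
    sense <- paste(substring(chr_seq[[ch]], e$start, e$end), collapse = "")
    tx_seq <- if (strand_tx == "+") sense else revcomp_chr(sense)
    in_cds <- rep.int(FALSE, length(emap$pos))
    for (k in seq_len(nrow(cd)))
      in_cds <- in_cds | (emap$pos >= cd$start[k] & emap$pos <= cd$end[k])
    cds_start_t <- min(emap$tpos[in_cds]); cds_end_t <- max(emap$tpos[in_cds])
    txinfo[[tx]] <- list(
      transcript_id = tx, gene_id = canon$gene_id[r], chrom = ch,
      strand = strand_tx, cds_start_t = cds_start_t, cds_end_t = cds_end_t,
      tx_len = length(emap$pos),
      cds_seq = substr(tx_seq, cds_start_t, cds_end_t)
    )
    push("CODING", ch, emap$pos[in_cds], gidx, tpos = emap$tpos[in_cds])
    u5 <- !in_cds & emap$tpos < cds_start_t
    u3 <- !in_cds & emap$tpos > cds_end_t
    push("UTR5", ch, emap$pos[u5], gidx, tpos = emap$tpos[u5])
    push("UTR3", ch, emap$pos[u3], gidx, tpos = emap$tpos[u3])
    # introns between genomically adjacent exons
    if (nrow(e) > 1L) {
      istart <- e$end[-nrow(e)] + 1L
      iend <- e$start[-1L] - 1L
      for (k in seq_along(istart)) {
        if (iend[k] < istart[k]) next
        ip <- istart[k]:iend[k]
        dl <- ip - istart[k] + 1L
        dr <- iend[k] - ip + 1L
        left <- dl <= dr
        d <- pmin(dl, dr)
        anch <- ifelse(left, istart[k] - 1L, iend[k] + 1L)
        push("INTRON_DEEP", ch, ip, gidx, anchor = anch, dist = d)
        sel <- d <= params$intron_prox_window
        push("INTRON", ch, ip[sel], gidx, anchor = anch[sel], dist = d[sel])
        sp <- d <= params$splice_window
        push("SPLICE_SITE", ch, ip[sp], gidx, anchor = anch[sp], dist = d[sp])
      }
    }
  }

  # write classes in ascending priority so higher priority overwrites;
  # one concatenated write per class per contig
  for (class in c("INTRON_DEEP", "INTRON", "UTR3", "UTR5", "SPLICE_SITE",
                  "CODING")) {
    blocks <- acc[[class]]
    if (!length(blocks)) next
    bch <- vapply(blocks, `[[`, character(1), "ch")
    for (ch in unique(bch)) {
      bl <- blocks[bch == ch]
      pos <- unlist(lapply(bl, `[[`, "pos"))
      m <- maps[[ch]]
      m$region[pos] <- REGION_CODE[[class]]
      m$gene[pos] <- unlist(lapply(bl, `[[`, "gene"))
      m$tpos[pos] <- unlist(lapply(bl, `[[`, "tpos"))
      m$anchor[pos] <- unlist(lapply(bl, `[[`, "anchor"))
      m$dist[pos] <- unlist(lapply(bl, `[[`, "dist"))
      maps[[ch]] <- m
    }
  }

  idx <- list(maps = maps, gene_ids = gene_ids, txinfo = txinfo,
              canonical_tx = setNames(canon$transcript_id, canon$gene_id),
              chrom_len = chrom_len, params = params)
  models$.cache[[key]] <- idx
  idx
}

idx_lookup <- function(idx, chrom, pos, what) {
  out <- rep.int(NA_integer_, length(pos))
  for (ch in unique(chrom)) {
    if (!ch %in% names(idx$maps)) stop("unknown contig: ", ch)
    sel <- chrom == ch
    if (any(pos[sel] < 1L | pos[sel] > idx$chrom_len[[ch]]))
      stop("position outside contig ", ch)
    out[sel] <- idx$maps[[ch]][[what]][pos[sel]]
  }
  out
}

#' Classify genomic positions into gene subregions
#'
#' Assigns each position exactly one region class with the fixed priority
#' CODING > SPLICE_SITE > UTR5 > UTR3 > INTRON > INTRON_DEEP > INTERGENIC
#' across overlapping genes, using canonical transcripts only. Splice sites
#' are intronic positions within `splice_window` nt of an exon boundary.
#'
#' @param chrom,pos Vectors of contig names and 1-based positions.
#' @param models A `GeneModelSet`.
#' @param reference A named `DNAStringSet`.
#' @param params An [annotation_params()] object.
#' @return data.frame with columns `region` (factor over the region levels),
#'   `gene_id` (NA when intergenic) and `dist_to_exon` (NA unless intronic).
#' @export
classify_region <- function(chrom, pos, models, reference,
                            params = annotation_params()) {
  idx <- annotation_index(models, reference, params)
  code <- idx_lookup(idx, chrom, pos, "region")
  g <- idx_lookup(idx, chrom, pos, "gene")
  d <- idx_lookup(idx, chrom, pos, "dist")
  data.frame(
    region = factor(names(REGION_CODE)[code], levels = REGION_LEVELS),
    gene_id = ifelse(g > 0L, idx$gene_ids[pmax(g, 1L)], NA_character_),
    dist_to_exon = d,
    stringsAsFactors = FALSE
  )
}

AA3 <- local({
  aa <- Biostrings::AMINO_ACID_CODE
  c(aa, "*" = "Ter")
})

codon_aa <- function(codons) {
  unname(Biostrings::GENETIC_CODE[codons])
}

#' Predict coding effects
#'
#' For substitutions in CDS the affected codon(s) are translated on the
#' coding strand with the standard genetic code; indels are frameshift when
#' the net length change is not divisible by 3 and inframe otherwise;
#' splice-site records get effect `splice`. Records outside CODING /
#' SPLICE_SITE regions get `NA`.
#'
#' @param records data.frame with columns `chrom`, `pos`, `ref`, `alt`,
#'   `mtype`, `region`, `gene_id` (as produced by [annotate_mutations()]
#'   internals, or any frame with those fields).
#' @param models A `GeneModelSet`.
#' @param reference A named `DNAStringSet`.
#' @param params An [annotation_params()] object.
#' @return A list with character vectors `effect` and `aa_change`.
#' @export
coding_effect <- function(records, models, reference,
                          params = annotation_params()) {
  idx <- annotation_index(models, reference, params)
  n <- nrow(records)
  effect <- rep(NA_character_, n)
  aa_change <- rep(NA_character_, n)
  region <- as.character(records$region)
  effect[region == "SPLICE_SITE"] <- "splice"

  is_cod <- region == "CODING" & !is.na(records$gene_id)
  if (!any(is_cod)) return(list(effect = effect, aa_change = aa_change))
  tx_of <- idx$canonical_tx[records$gene_id[is_cod]]
  strand_v <- vapply(idx$txinfo[tx_of], `[[`, character(1), "strand")
  cds_start <- vapply(idx$txinfo[tx_of], `[[`, integer(1), "cds_start_t")
  cds_seq <- vapply(idx$txinfo[tx_of], `[[`, character(1), "cds_seq")

  w <- which(is_cod)
  mtype <- records$mtype
  ref <- records$ref; alt <- records$alt
  # indels first (pure arithmetic)
  ind <- w[mtype[w] == "INDEL"]
  if (length(ind)) {
    net <- abs(nchar(ref[ind]) - nchar(alt[ind]))
    effect[ind] <- ifelse(net %% 3L == 0L, "inframe_indel", "frameshift")
  }

  # single-base substitutions, vectorized
  snv <- w[mtype[w] == "SNV"]
  if (length(snv)) {
    wi <- match(snv, w)
    refbase <- ref_bases(reference, records$chrom[snv], records$pos[snv])
    if (any(refbase != ref[snv])) stop("reference mismatch")
    tpos <- idx_lookup(idx, records$chrom[snv], records$pos[snv], "tpos")
    ci <- tpos - cds_start[wi] + 1L
    minus <- strand_v[wi] == "-"
    ref_c <- ifelse(minus, comp_base(ref[snv]), ref[snv])
    alt_c <- ifelse(minus, comp_base(alt[snv]), alt[snv])
    codon_num <- (ci - 1L) %/% 3L + 1L
    pos_in <- (ci - 1L) %% 3L + 1L
    ref_codon <- substr(cds_seq[wi], (codon_num - 1L) * 3L + 1L, codon_num * 3L)
    if (any(substr(ref_codon, pos_in, pos_in) != ref_c))
      stop("reference mismatch on coding strand")
    alt_codon <- ref_codon
    substr(alt_codon, pos_in, pos_in) <- alt_c
    aar <- codon_aa(ref_codon); aaa <- codon_aa(alt_codon)
    eff <- ifelse(aar == aaa, "synonymous",
           ifelse(aaa == "*", "nonsense",
           ifelse(aar == "*", "stop_loss", "missense")))
    effect[snv] <- eff
    aa_change[snv] <- paste0(AA3[aar], codon_num, AA3[aaa])
  }

  # multi-base substitutions (DBS and longer delins runs of equal length)
  mnv <- w[mtype[w] %in% c("DBS", "MNV") |
             (mtype[w] == "INDEL" & nchar(ref[w]) == nchar(alt[w]))]
  for (i in mnv) {
    tx <- idx$canonical_tx[records$gene_id[i]]
    info <- idx$txinfo[[tx]]
    span <- records$pos[i]:(records$pos[i] + nchar(ref[i]) - 1L)
    tp <- idx_lookup(idx, rep(records$chrom[i], length(span)), span, "tpos")
    reg <- idx_lookup(idx, rep(records$chrom[i], length(span)), span, "region")
    if (anyNA(tp) || any(reg != REGION_CODE[["CODING"]])) next  # spans boundary
    ci <- tp - info$cds_start_t + 1L
    minus <- info$strand == "-"
    refs <- strsplit(ref[i], "")[[1]]; alts <- strsplit(alt[i], "")[[1]]
    if (minus) { refs <- comp_base(refs); alts <- comp_base(alts) }
    cseq <- info$cds_seq
    mut <- cseq
    for (k in seq_along(ci)) substr(mut, ci[k], ci[k]) <- alts[k]
    cod_range <- unique((ci - 1L) %/% 3L + 1L)
    rc <- substring(cseq, (cod_range - 1L) * 3L + 1L, cod_range * 3L)
    mc <- substring(mut, (cod_range - 1L) * 3L + 1L, cod_range * 3L)
    aar <- codon_aa(rc); aaa <- codon_aa(mc)
    if (any(aaa == "*" & aar != "*")) effect[i] <- "nonsense"
    else if (any(aar == "*" & aaa != "*")) effect[i] <- "stop_loss"
    else if (any(aar != aaa)) effect[i] <- "missense"
    else effect[i] <- "synonymous"
    chg <- which(aar != aaa)
    k <- if (length(chg)) chg[1] else 1L
    aa_change[i] <- paste0(AA3[aar[k]], cod_range[k], AA3[aaa[k]])
  }
  list(effect = effect, aa_change = aa_change)
}

ref_bases <- function(reference, chrom, pos, len = 1L) {
  out <- character(length(pos))
  for (ch in unique(chrom)) {
    sel <- chrom == ch
    v <- Biostrings::extractAt(reference[[ch]],
                               IRanges(pos[sel], width = len))
    out[sel] <- as.character(v)
  }
  out
}

#' Annotate mutation records
#'
#' One-stop annotation: region class (at the highest-priority position of
#' the record's span), gene, intron boundary distance, coding effect,
#' protein descriptor, HGVS-like label and trinucleotide context index.
#'
#' @param records Mutation records from [merge_adjacent_snvs()].
#' @param models A `GeneModelSet`.
#' @param reference A named `DNAStringSet`.
#' @param params An [annotation_params()] object.
#' @return The records with columns `region`, `gene_id`, `dist_to_exon`,
#'   `effect`, `aa_change`, `hgvs_c`, `context_index` added.
#' @export
annotate_mutations <- function(records, models, reference,
                               params = annotation_params()) {
  idx <- annotation_index(models, reference, params)
  n <- nrow(records)
  # representative position: first changed base (indels are VCF-anchored)
  p1 <- ifelse(records$mtype == "INDEL" &
                 nchar(records$ref) > nchar(records$alt),
               records$pos + 1L, records$pos)
  cls1 <- classify_region(records$chrom, p1, models, reference, params)
  # substitutions spanning two bases: adopt the higher-priority end
  span2 <- records$mtype == "DBS"
  if (any(span2)) {
    cls2 <- classify_region(records$chrom[span2], records$pos[span2] + 1L,
                            models, reference, params)
    code1 <- REGION_CODE[as.character(cls1$region[span2])]
    code2 <- REGION_CODE[as.character(cls2$region)]
    take2 <- code2 < code1
    i2 <- which(span2)[take2]
    cls1$region[i2] <- cls2$region[take2]
    cls1$gene_id[i2] <- cls2$gene_id[take2]
    cls1$dist_to_exon[i2] <- cls2$dist_to_exon[take2]
  }
  records$region <- cls1$region
  records$gene_id <- cls1$gene_id
  records$dist_to_exon <- cls1$dist_to_exon
  eff <- coding_effect(records, models, reference, params)
  records$effect <- eff$effect
  records$aa_change <- eff$aa_change
  records$context_index <- rep(NA_integer_, n)
  snv <- records$mtype == "SNV"
  if (any(snv)) {
    records$context_index[snv] <- trinucleotide_context(
      records[snv, , drop = FALSE], reference)
  }
  records$hgvs_c <- hgvs_label(records, models, reference, params)
  records
}
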