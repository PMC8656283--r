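# Mutation typing: merging adjacent substitutions of one sample into
# double-substitution (delins) events, pyrimidine-normalized trinucleotide
# contexts, and HGVS-like coding-relative labels.

#' Merge adjacent same-sample substitutions
#'
#' Two single-base substitutions of one sample at directly adjacent
#' positions become one double substitution (DBS) with concatenated alleles,
#' the UV hallmark CC>TT (or its reverse-strand reading GG>AA) being flagged
#' `is_cc_tt`. Merging is transitive: runs of three or more consecutive
#' substitutions become a single multi-nucleotide delins record typed INDEL
#' (reported via `message()`). All other calls map 1:1 to records. Merging
#' is applied after filtering, so reported DBS counts sit next to
#' post-filter totals.
#'
#' @param calls Filtered somatic calls (any number of samples; merging is
#'   per sample). Must carry `tumor_af` (added by [apply_somatic_filters()]).
#' @return A data.frame of mutation records with columns `sample_id`,
#'   `chrom`, `pos`, `end`, `ref`, `alt`, `mtype` (SNV/DBS/INDEL),
#'   `is_cc_tt`, `long_indel`, `n_merged`, `tumor_depth`, `tumor_af`.
#' @export
merge_adjacent_snvs <- function(calls) {
  if (anyDuplicated(calls[, c("sample_id", "chrom", "pos", "alt")]))
    stop("duplicate (sample, chrom, pos, alt) call")
  if (is.null(calls$tumor_af))
    calls$tumor_af <- calls$tumor_alt / calls$tumor_depth
  is_sub <- nchar(calls$ref) == 1L & nchar(calls$alt) == 1L
  subs <- calls[is_sub, , drop = FALSE]
  inds <- calls[!is_sub, , drop = FALSE]

  rec <- function(sample_id, chrom, pos, end, ref, alt, mtype, depth, af,
                  n_merged) {
    data.frame(sample_id = sample_id, chrom = chrom, pos = as.integer(pos),
               end = as.integer(end), ref = ref, alt = alt, mtype = mtype,
               is_cc_tt = mtype == "DBS" &
                 ((ref == "CC" & alt == "TT") | (ref == "GG" & alt == "AA")),
               long_indel = mtype == "INDEL" &
                 pmax(nchar(ref), nchar(alt)) - 1L >= 4L,
               n_merged = as.integer(n_merged),
               tumor_depth = as.integer(round(depth)), tumor_af = af,
               stringsAsFactors = FALSE)
  }

  out <- list()
  if (nrow(subs)) {
    o <- order(subs$sample_id, subs$chrom, subs$pos)
    s <- subs[o, , drop = FALSE]
    new_run <- c(TRUE, s$sample_id[-1] != s$sample_id[-nrow(s)] |
                   s$chrom[-1] != s$chrom[-nrow(s)] |
                   s$pos[-1] != s$pos[-nrow(s)] + 1L)
    run <- cumsum(new_run)
    rl <- tabulate(run)
    first <- which(new_run)
    # fast path: singleton runs stay as-is; only merged runs need pasting
    ref_m <- s$ref[first]; alt_m <- s$alt[first]
    dep_m <- as.numeric(s$tumor_depth[first]); af_m <- s$tumor_af[first]
    multi <- which(rl > 1L)
    if (length(multi)) {
      in_multi <- run %in% multi
      r2 <- run[in_multi]
      ref_m[multi] <- vapply(split(s$ref[in_multi], r2), paste,
                             character(1), collapse = "")
      alt_m[multi] <- vapply(split(s$alt[in_multi], r2), paste,
                             character(1), collapse = "")
      dep_m[multi] <- vapply(split(s$tumor_depth[in_multi], r2), mean,
                             numeric(1))
      af_m[multi] <- vapply(split(s$tumor_af[in_multi], r2), mean,
                            numeric(1))
    }
    mtype <- ifelse(rl == 1L, "SNV", ifelse(rl == 2L, "DBS", "INDEL"))
    n_long <- sum(rl >= 3L)
    if (n_long)
      message(n_long, " run(s) of >=3 adjacent substitutions typed as ",
              "multi-nucleotide delins")
    out$subs <- rec(s$sample_id[first], s$chrom[first], s$pos[first],
                    s$pos[first] + rl - 1L, ref_m, alt_m, mtype,
                    dep_m, af_m, rl)
  }
  if (nrow(inds)) {
    out$inds <- rec(inds$sample_id, inds$chrom, inds$pos,
                    inds$pos + nchar(inds$ref) - 1L, inds$ref, inds$alt,
                    "INDEL", inds$tumor_depth, inds$tumor_af, 1L)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) res <- rec(character(0), character(0), integer(0),
                               integer(0), character(0), character(0),
                               character(0), numeric(0), numeric(0),
                               integer(0))
  rownames(res) <- NULL
  res[order(res$sample_id, res$chrom, res$pos), , drop = FALSE]
}

#' Pyrimidine-normalized trinucleotide context of single-base substitutions
#'
#' If the reference base is a purine the substitution and its flanks are
#' reverse-complemented so the reported channel has a pyrimidine reference.
#' Indices are 1-based positions into [trinucleotide_contexts()].
#'
#' @param records data.frame of SNV records (`chrom`, `pos`, `ref`, `alt`).
#'   Non-SNV rows raise an error.
#' @param reference A named `DNAStringSet`.
#' @return Integer vector of context indices (1-96).
#' @export
trinucleotide_context <- function(records, reference) {
  if (!is.null(records$mtype) && any(records$mtype != "SNV"))
    stop("trinucleotide context is defined for SNVs only")
  if (any(nchar(records$ref) != 1L | nchar(records$alt) != 1L))
    stop("trinucleotide context is defined for SNVs only")
  n <- nrow(records)
  if (!n) return(integer(0))
  lens <- setNames(Biostrings::width(reference), names(reference))
  if (any(records$pos <= 1L | records$pos >= lens[records$chrom]))
    stop("no flanking base: position at contig edge")
  tri <- ref_bases(reference, records$chrom, records$pos - 1L, len = 3L)
  up <- substr(tri, 1L, 1L); mid <- substr(tri, 2L, 2L); down <- substr(tri, 3L, 3L)
  if (any(mid != records$ref)) stop("reference mismatch")
  context_index_of(records$ref, records$alt, up, down)
}

# numeric c-position label relative to the CDS of the canonical transcript
cpos_label <- function(tpos, cds_start, cds_end) {
  ifelse(tpos < cds_start, paste0("-", cds_start - tpos),
         ifelse(tpos > cds_end, paste0("*", tpos - cds_end),
                as.character(tpos - cds_start + 1L)))
}

#' HGVS-like coding-relative labels
#'
#' Builds `c.` labels on the canonical transcript: `c.-N` in the 5'UTR
#' (N nt upstream of the ATG), `c.*N` in the 3'UTR (N nt downstream of the
#' stop), `c.N` in the CDS and `c.N+M` / `c.N-M` in introns; double and
#' longer multi-nucleotide substitutions are rendered `delins`; positions
#' and alleles are expressed on the coding strand. Not a full HGVS grammar
#' (no inversions, no protein-level HGVS beyond the simple descriptor
#' produced by [coding_effect()]).
#'
#' @param records Mutation records with `region` and `gene_id` columns.
#' @param models A `GeneModelSet`.
#' @param reference A named `DNAStringSet`.
#' @param params An [annotation_params()] object.
#' @param strict If `TRUE`, a record not associated with a gene raises an
#'   error; if `FALSE` (default) its label is `NA`.
#' @return Character vector of labels.
#' @export
hgvs_label <- function(records, models, reference,
                       params = annotation_params(), strict = FALSE) {
  idx <- annotation_index(models, reference, params)
  n <- nrow(records)
  out <- rep(NA_character_, n)
  has_gene <- !is.na(records$gene_id) &
    records$gene_id %in% names(idx$canonical_tx)
  if (strict && any(!has_gene)) stop("record not associated with a gene")
  if (!any(has_gene)) return(out)

  tx_of <- idx$canonical_tx[records$gene_id]
  info_of <- idx$txinfo[tx_of]
  strand_v <- rep(NA_character_, n)
  cs <- rep(NA_integer_, n); ce <- rep(NA_integer_, n)
  strand_v[has_gene] <- vapply(info_of[has_gene], `[[`, character(1), "strand")
  cs[has_gene] <- vapply(info_of[has_gene], `[[`, integer(1), "cds_start_t")
  ce[has_gene] <- vapply(info_of[has_gene], `[[`, integer(1), "cds_end_t")

  # label of one genomic point on its transcript
  point_lab <- function(i, p) {
    tp <- idx_lookup(idx, records$chrom[i], p, "tpos")
    if (!is.na(tp)) return(cpos_label(tp, cs[i], ce[i]))
    anch <- idx_lookup(idx, records$chrom[i], p, "anchor")
    if (is.na(anch)) return(NA_character_)
    atp <- idx_lookup(idx, records$chrom[i], anch, "tpos")
    if (is.na(atp)) return(NA_character_)
    plus_side <- (anch < p) == (strand_v[i] == "+")
    paste0(cpos_label(atp, cs[i], ce[i]),
           if (plus_side) "+" else "-", abs(p - anch))
  }

  mtype <- records$mtype
  snv <- which(has_gene & mtype == "SNV")
  # vectorized fast path: exonic SNVs
  if (length(snv)) {
    tp <- idx_lookup(idx, records$chrom[snv], records$pos[snv], "tpos")
    ex <- !is.na(tp)
    minus <- strand_v[snv] == "-"
    ref_c <- ifelse(minus, comp_base(records$ref[snv]), records$ref[snv])
    alt_c <- ifelse(minus, comp_base(records$alt[snv]), records$alt[snv])
    lab <- rep(NA_character_, length(snv))
    lab[ex] <- cpos_label(tp[ex], cs[snv][ex], ce[snv][ex])
    for (k in which(!ex)) lab[k] <- point_lab(snv[k], records$pos[snv[k]])
    out[snv] <- ifelse(is.na(lab), NA_character_,
                       paste0("c.", lab, ref_c, ">", alt_c))
  }

  other <- which(has_gene & mtype != "SNV")
  for (i in other) {
    p1 <- records$pos[i]
    strand_i <- strand_v[i]
    nref <- nchar(records$ref[i]); nalt <- nchar(records$alt[i])
    if (nref == nalt) {                       # DBS / MNV delins
      pA <- p1; pB <- p1 + nref - 1L
      ends <- if (strand_i == "+") c(pA, pB) else c(pB, pA)
      alt_c <- if (strand_i == "+") records$alt[i] else revcomp_chr(records$alt[i])
      l1 <- point_lab(i, ends[1]); l2 <- point_lab(i, ends[2])
      if (!is.na(l1) && !is.na(l2))
        out[i] <- paste0("c.", l1, "_", l2, "delins", alt_c)
    } else if (nref > nalt) {                 # deletion (anchored)
      s <- p1 + nalt; e <- p1 + nref - 1L
      ends <- if (strand_i == "+") c(s, e) else c(e, s)
      l1 <- point_lab(i, ends[1]); l2 <- point_lab(i, ends[2])
      if (is.na(l1) || is.na(l2)) next
      out[i] <- if (s == e) paste0("c.", l1, "del")
                else paste0("c.", l1, "_", l2, "del")
    } else {                                  # insertion (anchored)
      insseq <- substr(records$alt[i], nref + 1L, nalt)
      ends <- if (strand_i == "+") c(p1, p1 + 1L) else c(p1 + 1L, p1)
      if (strand_i == "-") insseq <- revcomp_chr(insseq)
      l1 <- point_lab(i, ends[1]); l2 <- point_lab(i, ends[2])
      if (!is.na(l1) && !is.na(l2))
        out[i] <- paste0("c.", l1, "_", l2, "ins", insseq)
    }
  }
  out
}
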