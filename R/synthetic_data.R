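# Seeded UV-mutagenesis simulator.
#
# Generates everything the pipeline consumes: a random genome with
# multi-exon genes on both strands, a 27-sample tumor cohort whose SNVs are
# drawn from per-sample mixtures of a UV-like signature (C>T at
# dipyrimidine sites, with CC>TT double substitutions), an alkylation-like
# signature and a flat background; short indels at low-complexity runs;
# planted hotspots, high-functional-score driver regions and chromosome-arm
# CNAs in MLPA signals; read supports built so true somatic calls pass the
# default filters while spiked artifacts fail them; and machine-readable
# truth tables for every planted entity.
#
# All randomness flows from `config$seed` through fixed per-stage offsets,
# so each product is deterministic under the seed.

#' Simulation configuration
#'
#' Defaults mirror the cohort shape of a UV-driven 27-sample exome study:
#' lognormal per-sample mutation counts averaging ~1900 (about 50,000
#' cohort-wide), substitution/double-substitution/indel fractions
#' 0.945/0.037/0.018, two near-empty samples (indices 14 and 21), one
#' alkylation-dominant sample (index 22), read depth around 180x and tumor
#' allele fraction centered at 0.35. The default planted structure is a
#' 2-position 3'UTR hotspot 142-143 nt downstream of the stop codon carried
#' by 8 samples, a 5'UTR hotspot at c.-5/-4 carried by 5, a coding hotspot
#' at c.71/72 carried by 3 (each including one double-substitution
#' carrier), and 11 driver regions (3 CDS, 6 5'UTR, 2 3'UTR) whose
#' mutations sit at high-functional-score positions.
#'
#' @param seed Integer master seed.
#' @param n_samples Cohort size (default 27).
#' @param n_genes Number of simulated genes (default 400).
#' @param genome_length Optional total genome length; an error is raised if
#'   the assembled genes do not fit, remaining sequence is random padding.
#' @param burden_meanlog,burden_sdlog Lognormal parameters of per-sample
#'   mutation counts.
#' @param low_burden_samples,low_burden_count Indices of near-empty samples
#'   and their Poisson mean mutation count.
#' @param alk_sample Index of the alkylation-dominant sample.
#' @param sig_weights,alk_weights,weight_jitter Signature mixture weights
#'   (UV, ALK, FLAT) for ordinary and for the alkylation-dominant sample,
#'   and the s.d. of per-sample jitter.
#' @param dbs_fraction,indel_fraction Fractions of mutation events emitted
#'   as CC>TT double substitutions and short indels.
#' @param intron_prox_window,utr3_cover_window,flank_window Covered
#'   territory: exons plus `intron_prox_window` nt of introns, the first
#'   `utr3_cover_window` nt of 3'UTRs, and `flank_window` nt of gene flanks
#'   (the intergenic spill-over of exome capture).
#' @param utr5_range,utr3_range,cds_codons_range,n_introns_range,intron_len_range,intergenic_range
#'   Gene geometry ranges (nt or codons).
#' @param hotspots,drivers Lists describing planted hotspots and driver
#'   regions (see Details in the package vignette); `NULL` keeps defaults,
#'   `list()` disables.
#' @param n_artifacts Named vector: spiked calls per class
#'   (`low_support`, `low_af`, `low_ratio`, `germline`, `pon`).
#' @param depth_mean,depth_size Negative-binomial read-depth model.
#' @param af_shape1,af_shape2 Beta model of tumor allele fraction.
#' @param score_shape,score_scale Gamma background of the functional score
#'   track (CADD-like scale); `driver_score_range` is the uniform range of
#'   planted driver-site scores.
#' @param mlpa_noise_sigma Lognormal sigma of MLPA signal noise.
#' @param mlpa_loss_samples,mlpa_gain_samples Numbers of samples with a
#'   planted 9q-arm single-copy loss / 9p-arm single-copy gain.
#' @return A list of class `SimulationConfig`.
#' @export
simulation_config <- function(seed = 1L,
                              n_samples = 27L,
                              n_genes = 400L,
                              genome_length = NULL,
                              burden_meanlog = log(1900),
                              burden_sdlog = 0.5,
                              low_burden_samples = c(14L, 21L),
                              low_burden_count = 8,
                              alk_sample = 22L,
                              sig_weights = c(UV = 0.7, ALK = 0.2, FLAT = 0.1),
                              alk_weights = c(UV = 0.3, ALK = 0.6, FLAT = 0.1),
                              weight_jitter = 0.04,
                              dbs_fraction = 0.037,
                              indel_fraction = 0.018,
                              intron_prox_window = 100L,
                              utr3_cover_window = 150L,
                              flank_window = 100L,
                              utr5_range = c(60L, 120L),
                              utr3_range = c(160L, 260L),
                              cds_codons_range = c(100L, 400L),
                              n_introns_range = c(2L, 4L),
                              intron_len_range = c(250L, 600L),
                              intergenic_range = c(300L, 800L),
                              hotspots = NULL,
                              drivers = NULL,
                              n_artifacts = c(low_support = 80L, low_af = 60L,
                                              low_ratio = 60L, germline = 80L,
                                              pon = 60L),
                              depth_mean = 180, depth_size = 12,
                              af_shape1 = 3.5, af_shape2 = 6.5,
                              score_shape = 2, score_scale = 2,
                              driver_score_range = c(25, 35),
                              mlpa_noise_sigma = 0.05,
                              mlpa_loss_samples = 9L,
                              mlpa_gain_samples = 5L) {
  stopifnot(n_samples >= 1, n_genes >= 1,
            dbs_fraction >= 0, indel_fraction >= 0,
            dbs_fraction + indel_fraction <= 1)
  if (is.null(hotspots)) {
    hotspots <- list(
      list(region = "UTR3", offset = 142L, width = 2L, n_carriers = 8L,
           dbs_carriers = 1L),
      list(region = "UTR5", offset = 5L, width = 2L, n_carriers = 5L,
           dbs_carriers = 1L),
      list(region = "CODING", offset = 71L, width = 2L, n_carriers = 3L,
           dbs_carriers = 1L))
  }
  if (is.null(drivers)) {
    drivers <- c(
      rep(list(list(region = "CODING", n_carriers = 6L)), 3),
      rep(list(list(region = "UTR5", n_carriers = 6L)), 6),
      rep(list(list(region = "UTR3", n_carriers = 6L)), 2))
  }
  structure(as.list(environment()), class = "SimulationConfig")
}

CODONS61 <- local({
  all <- apply(expand.grid(DNA_BASES, DNA_BASES, DNA_BASES), 1, paste,
               collapse = "")
  all[!all %in% c("TAA", "TAG", "TGA")]
})

rand_dna <- function(n) paste(sample(DNA_BASES, n, replace = TRUE),
                              collapse = "")

#' Generate a random genome and gene models
#'
#' Genes have 3-5 exons, a CDS starting with ATG, free of internal stops
#' and ending in a stop codon (so CDS length is divisible by 3), 5' and 3'
#' UTRs, and alternate between strands. Deterministic under the seed.
#'
#' @param config A [simulation_config()].
#' @return list with `reference` (named `DNAStringSet`, contig `chr1`) and
#'   `models` (`GeneModelSet`).
#' @export
generate_genome <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(config$seed + 101L)
  rint <- function(rg) if (rg[1] >= rg[2]) rg[1] else sample(rg[1]:rg[2], 1L)
  seq_parts <- list()
  ex_rows <- list(); cds_rows <- list()
  offset <- 0L
  for (g in seq_len(config$n_genes)) {
    gid <- sprintf("G%04d", g)
    strand_g <- if (g %% 2L == 1L) "+" else "-"
    u5 <- rint(config$utr5_range)
    u3 <- rint(config$utr3_range)
    ncod <- rint(config$cds_codons_range)
    nint <- rint(config$n_introns_range)
    cdslen <- 3L * ncod
    exlen <- u5 + cdslen + u3
    cds_tx <- c(u5 + 1L, u5 + cdslen)
    # exon cut points in transcript space; keep exons >= 20 nt
    cuts <- sort(sample(seq(20L, exlen - 20L), nint))
    while (any(diff(c(0L, cuts, exlen)) < 20L))
      cuts <- sort(sample(seq(20L, exlen - 20L), nint))
    ex_tx_start <- c(1L, cuts + 1L)
    ex_tx_end <- c(cuts, exlen)
    ilen <- vapply(seq_len(nint), function(i) rint(config$intron_len_range),
                   integer(1))
    # transcript sequence: UTR5 + ATG + internal codons + stop + UTR3
    cds_seq <- paste0("ATG",
                      paste(sample(CODONS61, ncod - 2L, replace = TRUE),
                            collapse = ""),
                      sample(c("TAA", "TAG", "TGA"), 1L))
    tx_seq <- paste0(rand_dna(u5), cds_seq, rand_dna(u3))
    # sense assembly: exons interleaved with introns
    ishift <- cumsum(c(0L, ilen))             # intron length before exon j
    A <- ex_tx_start + ishift                 # assembly start of exon j
    B <- ex_tx_end + ishift
    glen <- exlen + sum(ilen)
    pieces <- character(2L * nint + 1L)
    for (j in seq_len(nint + 1L)) {
      pieces[2L * j - 1L] <- substr(tx_seq, ex_tx_start[j], ex_tx_end[j])
      if (j <= nint) pieces[2L * j] <- rand_dna(ilen[j])
    }
    gseq <- paste(pieces, collapse = "")
    # CDS pieces per exon in assembly coordinates
    cA <- integer(0); cB <- integer(0)
    for (j in seq_len(nint + 1L)) {
      s <- max(ex_tx_start[j], cds_tx[1]); e <- min(ex_tx_end[j], cds_tx[2])
      if (s <= e) { cA <- c(cA, s + ishift[j]); cB <- c(cB, e + ishift[j]) }
    }
    if (strand_g == "-") {
      gseq <- revcomp_chr(gseq)
      mir <- function(s, e) c(glen - e + 1L, glen - s + 1L)
      tmp <- mapply(mir, A, B); A <- tmp[1, ]; B <- tmp[2, ]
      tmp <- mapply(mir, cA, cB); cA <- tmp[1, ]; cB <- tmp[2, ]
    }
    gap <- rint(config$intergenic_range)
    seq_parts[[length(seq_parts) + 1L]] <- rand_dna(gap)
    seq_parts[[length(seq_parts) + 1L]] <- gseq
    base <- offset + gap
    ex_rows[[g]] <- data.frame(start = base + A, end = base + B,
                               strand = strand_g, gene = gid,
                               stringsAsFactors = FALSE)
    cds_rows[[g]] <- data.frame(start = base + cA, end = base + cB,
                                strand = strand_g, gene = gid,
                                stringsAsFactors = FALSE)
    offset <- base + glen
  }
  tail_gap <- rint(config$intergenic_range)
  seq_parts[[length(seq_parts) + 1L]] <- rand_dna(tail_gap)
  total_len <- offset + tail_gap
  if (!is.null(config$genome_length)) {
    if (config$genome_length < total_len)
      stop("genome_length too small for n_genes (need ", total_len, ")")
    if (config$genome_length > total_len)
      seq_parts[[length(seq_parts) + 1L]] <-
        rand_dna(config$genome_length - total_len)
  }
  genome <- Biostrings::DNAStringSet(paste(unlist(seq_parts), collapse = ""))
  names(genome) <- "chr1"
  ex <- do.call(rbind, ex_rows); cd <- do.call(rbind, cds_rows)
  mk <- function(df) GRanges("chr1", IRanges(df$start, df$end),
                             strand = df$strand,
                             transcript_id = sub("^G", "T", df$gene),
                             gene_id = df$gene, gene_name = df$gene)
  models <- gene_model_set(mk(ex), mk(cd))
  list(reference = genome, models = models)
}

# --- internal helpers shared by the cohort / score-track simulators -------

transition_of <- function(b) chartr("ACGT", "GTAC", b)  # A<->G, C<->T

sim_index <- function(config, models, reference) {
  annotation_index(models, reference,
                   annotation_params(2L, config$intron_prox_window,
                                     config$utr3_cover_window))
}

# covered (exome-captured) positions of one contig, per the config windows
covered_positions <- function(config, models, reference, idx = NULL) {
  if (is.null(idx)) idx <- sim_index(config, models, reference)
  # cds end (transcript coords) per gene index, for the 3'UTR window
  ce_by_gene <- vapply(idx$txinfo[idx$canonical_tx[idx$gene_ids]], `[[`,
                       integer(1), "cds_end_t")
  ex_chrom <- as.character(seqnames(models$exons))
  ex_gene <- mcols(models$exons)$gene_id
  ex_start <- start(models$exons); ex_end <- end(models$exons)
  out <- list()
  for (ch in names(idx$maps)) {
    m <- idx$maps[[ch]]
    cov <- m$region %in% c(REGION_CODE[["CODING"]], REGION_CODE[["SPLICE_SITE"]],
                           REGION_CODE[["UTR5"]], REGION_CODE[["INTRON"]])
    # 3'UTR: only the proximal window downstream of the stop codon
    u3 <- which(m$region == REGION_CODE[["UTR3"]])
    if (length(u3)) {
      ce <- ce_by_gene[m$gene[u3]]
      cov[u3[m$tpos[u3] - ce <= config$utr3_cover_window]] <- TRUE
    }
    # gene flanks: intergenic spill-over of capture
    sel <- ex_chrom == ch
    gs <- tapply(ex_start[sel], ex_gene[sel], min)
    ge <- tapply(ex_end[sel], ex_gene[sel], max)
    L <- idx$chrom_len[[ch]]
    for (r in seq_along(gs)) {
      s <- gs[[r]]; e <- ge[[r]]
      lo <- max(2L, s - config$flank_window)
      hi <- min(L - 1L, e + config$flank_window)
      fl <- c(if (s - 1L >= lo) lo:(s - 1L) else integer(0),
              if (hi >= e + 1L) (e + 1L):hi else integer(0))
      cov[fl[m$region[fl] == REGION_CODE[["INTERGENIC"]]]] <- TRUE
    }
    cov[c(1L, L)] <- FALSE      # contexts need flanking bases
    out[[ch]] <- which(cov)
  }
  out
}

# genomic position of a transcript coordinate within one gene
tpos_to_genomic <- function(models, gene_id, tpos_wanted) {
  ex <- models$exons[mcols(models$exons)$gene_id == gene_id]
  ex <- sort(ex)
  emap <- tx_exonic_map(start(ex), end(ex), as.character(strand(ex))[1])
  emap$pos[match(tpos_wanted, emap$tpos)]
}

# deterministic placement of planted driver sites (shared by the cohort and
# score-track simulators via a dedicated derived seed)
planted_driver_sites <- function(config, models, reference) {
  if (!length(config$drivers)) {
    return(data.frame(driver_id = character(), gene_id = character(),
                      region = character(), chrom = character(),
                      pos = integer(), ref = character(), alt = character(),
                      carrier = character(), stringsAsFactors = FALSE))
  }
  set.seed(config$seed + 304L)
  idx <- sim_index(config, models, reference)
  n_hot <- length(config$hotspots)
  samples <- sprintf("S%02d", seq_len(config$n_samples))
  eligible <- setdiff(seq_len(config$n_samples), config$low_burden_samples)
  rows <- list()
  for (j in seq_along(config$drivers)) {
    d <- config$drivers[[j]]
    gene <- idx$gene_ids[n_hot + j]
    info <- idx$txinfo[[idx$canonical_tx[gene]]]
    tspan <- switch(d$region,
      CODING = seq(info$cds_start_t + 3L, info$cds_end_t - 3L),
      UTR5 = seq(1L, info$cds_start_t - 1L),
      UTR3 = seq(info$cds_end_t + 1L,
                 min(info$tx_len, info$cds_end_t + config$utr3_cover_window)))
    sites_t <- sample(tspan, d$n_carriers)
    pos <- tpos_to_genomic(models, gene, sites_t)
    ref <- ref_bases(reference, rep(info$chrom, length(pos)), pos)
    carriers <- samples[sample(eligible, d$n_carriers)]
    rows[[j]] <- data.frame(driver_id = sprintf("driver_%02d", j),
                            gene_id = gene, region = d$region,
                            chrom = info$chrom, pos = pos, ref = ref,
                            alt = transition_of(ref), carrier = carriers,
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

# --- cohort ----------------------------------------------------------------

#' Simulate a tumor/normal somatic-call cohort
#'
#' Draws per-sample SNVs from the sample's signature mixture over the
#' covered territory (the UV component only has mass at dipyrimidine C>T
#' channels), emits CC>TT double substitutions as pairs of adjacent calls,
#' short (<4 nt) indels at homopolymer runs, planted hotspot mutations in
#' exactly the configured carrier samples, planted driver mutations at the
#' shared driver sites, and spiked artifact/germline/panel-of-normals calls
#' engineered to fail filtering or flagging. Read support is drawn so true
#' somatic calls pass the default filters.
#'
#' @param config A [simulation_config()].
#' @param reference,models Output of [generate_genome()].
#' @return list with `calls` (somatic call data.frame, all samples) and
#'   `truth` (list of truth tables: `signatures`, `hotspots`, `drivers`,
#'   `germline_sites`, `pon_sites`, `artifacts`, `type_counts`).
#' @export
simulate_cohort <- function(config, reference, models) {
  stopifnot(inherits(config, "SimulationConfig"))
  idx <- sim_index(config, models, reference)
  drv <- planted_driver_sites(config, models, reference)
  set.seed(config$seed + 202L)
  samples <- sprintf("S%02d", seq_len(config$n_samples))
  sig <- uv_signature_matrix()

  # context-class index of covered positions (single pass over the genome)
  cov <- covered_positions(config, models, reference, idx)
  ch <- names(cov)[[1]]
  if (length(cov) > 1L) stop("simulator supports a single contig")
  code <- match(strsplit(as.character(reference[[ch]]), "")[[1]], DNA_BASES)
  cp <- cov[[ch]]
  cls <- context_class_of(DNA_BASES[code[cp]], DNA_BASES[code[cp - 1L]],
                          DNA_BASES[code[cp + 1L]])
  class_pos <- split(cp, cls)
  # CC / GG dinucleotides fully covered (for CC>TT events)
  covm <- logical(length(code)); covm[cp] <- TRUE
  di <- which((code[-length(code)] == 2L & code[-1L] == 2L) |
                (code[-length(code)] == 3L & code[-1L] == 3L))
  di <- di[covm[di] & covm[di + 1L]]
  # homopolymer runs >= 3 with a covered anchor base before the run
  r <- rle(code)
  run_end <- cumsum(r$lengths)
  run_start <- run_end - r$lengths + 1L
  runs <- which(r$lengths >= 3L & run_start > 1L)
  anchors <- run_start[runs] - 1L
  run_len <- r$lengths[runs]
  keep <- covm[anchors]
  anchors <- anchors[keep]; run_len <- run_len[keep]

  # per-sample burden and signature weights
  n_mut <- round(rlnorm(config$n_samples, config$burden_meanlog,
                        config$burden_sdlog))
  n_mut[config$low_burden_samples] <-
    rpois(length(config$low_burden_samples), config$low_burden_count)
  wts <- matrix(rep(config$sig_weights, each = config$n_samples),
                nrow = config$n_samples,
                dimnames = list(samples, names(config$sig_weights)))
  wts[config$alk_sample, ] <- config$alk_weights
  if (config$weight_jitter > 0)
    wts <- wts + matrix(rnorm(length(wts), 0, config$weight_jitter), nrow(wts))
  wts[wts < 0] <- 0                   # jitter must not create negative weights
  wts <- wts / rowSums(wts)

  support <- function(n) {
    depth <- rnbinom(n, mu = config$depth_mean - 30, size = config$depth_size) + 30L
    af <- rbeta(n, config$af_shape1, config$af_shape2)
    alt <- rbinom(n, depth, af)
    alt <- pmin(depth, pmax(alt, 5L, ceiling(0.05 * depth)))
    ndepth <- rnbinom(n, mu = config$depth_mean - 30, size = config$depth_size) + 30L
    list(depth = as.integer(depth), alt = as.integer(alt),
         ndepth = as.integer(ndepth), nalt = integer(n))
  }
  call_df <- function(sample_id, pos, ref, alt, sup, i = seq_along(pos)) {
    data.frame(sample_id = sample_id, chrom = ch, pos = as.integer(pos),
               ref = ref, alt = alt, tumor_alt = sup$alt[i],
               tumor_depth = sup$depth[i], normal_alt = sup$nalt[i],
               normal_depth = sup$ndepth[i], flags = "",
               stringsAsFactors = FALSE)
  }

  calls <- list(); type_counts <- list()
  for (si in seq_along(samples)) {
    s <- samples[si]
    n <- n_mut[si]
    if (n == 0L) { type_counts[[s]] <- c(0L, 0L, 0L); next }
    n_dbs <- rbinom(1L, n, config$dbs_fraction)
    n_ind <- rbinom(1L, n - n_dbs,
                    config$indel_fraction / max(1e-12, 1 - config$dbs_fraction))
    n_snv <- n - n_dbs - n_ind
    type_counts[[s]] <- as.integer(c(n_snv, n_dbs, n_ind))
    probs <- as.numeric(wts[si, ] %*% unclass(sig))
    if (n_snv > 0L) {
      chan <- rmultinom(1L, n_snv, probs)[, 1L]
      pos_l <- list(); alt_l <- list()
      for (k in which(chan > 0L)) {
        avail <- class_pos[[as.character(channel_class(k))]]
        if (is.null(avail)) next
        m <- min(chan[k], length(avail))
        p <- if (m == length(avail)) avail else sample(avail, m)
        rb <- DNA_BASES[code[p]]
        a <- ifelse(rb %in% c("C", "T"), channel_alt(k),
                    comp_base(channel_alt(k)))
        pos_l[[length(pos_l) + 1L]] <- p
        alt_l[[length(alt_l) + 1L]] <- a
      }
      p <- unlist(pos_l); a <- unlist(alt_l)
      sup <- support(length(p))
      calls[[length(calls) + 1L]] <-
        call_df(s, p, DNA_BASES[code[p]], a, sup)
    }
    if (n_dbs > 0L && length(di)) {
      p1 <- sample(di, min(n_dbs, length(di)))
      sup <- support(length(p1))
      refs <- DNA_BASES[code[p1]]                     # C or G
      alts <- ifelse(refs == "C", "T", "A")
      calls[[length(calls) + 1L]] <-
        rbind(call_df(s, p1, refs, alts, sup),
              call_df(s, p1 + 1L, DNA_BASES[code[p1 + 1L]],
                      ifelse(DNA_BASES[code[p1 + 1L]] == "C", "T", "A"), sup))
    }
    if (n_ind > 0L && length(anchors)) {
      ai <- sample(seq_along(anchors), min(n_ind, length(anchors)))
      p <- anchors[ai]
      d <- pmin(sample(1:3, length(ai), replace = TRUE), run_len[ai])
      is_del <- runif(length(ai)) < 0.5
      ref <- character(length(ai)); alt <- character(length(ai))
      for (q in seq_along(ai)) {
        anchor_b <- DNA_BASES[code[p[q]]]
        run_b <- DNA_BASES[code[p[q] + 1L]]
        if (is_del[q]) {
          ref[q] <- paste0(anchor_b, strrep(run_b, d[q])); alt[q] <- anchor_b
        } else {
          ref[q] <- anchor_b; alt[q] <- paste0(anchor_b, strrep(run_b, d[q]))
        }
      }
      sup <- support(length(p))
      calls[[length(calls) + 1L]] <- call_df(s, p, ref, alt, sup)
    }
  }

  # spiked artifacts and germline / panel-of-normals sites (added before the
  # planted structure so planted calls win any key collision in the dedup)
  art_rows <- list()
  spike <- function(class, n, tweak) {
    if (n == 0L) return(NULL)
    p <- sample(cp, n)
    ref <- DNA_BASES[code[p]]
    sup <- support(n)
    df <- call_df(samples[sample.int(config$n_samples, n, replace = TRUE)],
                  p, ref, transition_of(ref), sup)
    df <- tweak(df)
    art_rows[[length(art_rows) + 1L]] <<-
      data.frame(class = class, sample_id = df$sample_id, chrom = df$chrom,
                 pos = df$pos, ref = df$ref, alt = df$alt,
                 stringsAsFactors = FALSE)
    df
  }
  na <- config$n_artifacts
  calls[[length(calls) + 1L]] <- spike("low_support", na[["low_support"]],
    function(df) { df$tumor_alt <- sample(1:4, nrow(df), TRUE); df })
  calls[[length(calls) + 1L]] <- spike("low_af", na[["low_af"]],
    function(df) {
      df$tumor_depth <- as.integer(sample(150:300, nrow(df), TRUE))
      df$tumor_alt <- 5L; df })
  calls[[length(calls) + 1L]] <- spike("low_ratio", na[["low_ratio"]],
    function(df) {
      df$tumor_alt <- pmax(5L, as.integer(round(0.2 * df$tumor_depth)))
      df$normal_alt <- pmax(1L, as.integer(round(0.08 * df$normal_depth)))
      df })
  germ <- spike("germline", na[["germline"]], identity)
  calls[[length(calls) + 1L]] <- germ
  pon <- spike("pon", na[["pon"]], identity)
  calls[[length(calls) + 1L]] <- pon

  # planted hotspots: carriers fixed by config
  hot_rows <- list()
  eligible <- setdiff(seq_len(config$n_samples), config$low_burden_samples)
  for (h in seq_along(config$hotspots)) {
    hs <- config$hotspots[[h]]
    gene <- idx$gene_ids[h]
    info <- idx$txinfo[[idx$canonical_tx[gene]]]
    t0 <- switch(hs$region,
                 UTR3 = info$cds_end_t + hs$offset,
                 UTR5 = info$cds_start_t - hs$offset,
                 CODING = info$cds_start_t + hs$offset - 1L)
    tspan <- t0:(t0 + hs$width - 1L)
    pos <- sort(tpos_to_genomic(models, gene, tspan))
    carriers <- samples[sample(eligible, hs$n_carriers)]
    n_dbs_c <- min(hs$dbs_carriers %||% 0L, hs$n_carriers)
    for (ci in seq_along(carriers)) {
      sup <- support(2L)
      if (ci <= n_dbs_c && length(pos) >= 2L) {
        p <- pos[1:2]
      } else {
        p <- pos[(ci %% length(pos)) + 1L]
      }
      ref <- ref_bases(reference, rep(ch, length(p)), p)
      calls[[length(calls) + 1L]] <-
        call_df(carriers[ci], p, ref, transition_of(ref), sup,
                i = rep(1L, length(p)))
    }
    hot_rows[[h]] <- data.frame(
      hotspot_id = sprintf("hotspot_%02d", h), gene_id = gene,
      region = hs$region, chrom = ch,
      start = min(pos), end = max(pos),
      n_carriers = hs$n_carriers,
      carriers = paste(sort(carriers), collapse = ","),
      stringsAsFactors = FALSE)
  }

  # planted driver mutations at the shared high-score sites
  if (nrow(drv)) {
    sup <- support(nrow(drv))
    calls[[length(calls) + 1L]] <-
      call_df(drv$carrier, drv$pos, drv$ref, drv$alt, sup)
  }

  calls <- do.call(rbind, calls[!vapply(calls, is.null, logical(1))])
  # planted entries take precedence over random collisions at the same key
  calls <- calls[!duplicated(calls[, c("sample_id", "chrom", "pos", "alt")],
                             fromLast = TRUE), , drop = FALSE]
  calls <- calls[order(calls$sample_id, calls$chrom, calls$pos, calls$alt), ,
                 drop = FALSE]
  rownames(calls) <- NULL

  truth <- list(
    signatures = data.frame(sample = samples, wts,
                            n_mutations = n_mut, row.names = NULL),
    hotspots = if (length(hot_rows)) do.call(rbind, hot_rows) else NULL,
    drivers = drv,
    germline_sites = if (!is.null(germ))
      unique(germ[, c("chrom", "pos", "ref", "alt")]) else
        data.frame(chrom = character(), pos = integer(), ref = character(),
                   alt = character()),
    pon_sites = if (!is.null(pon))
      unique(pon[, c("chrom", "pos", "ref", "alt")]) else
        data.frame(chrom = character(), pos = integer(), ref = character(),
                   alt = character()),
    artifacts = if (length(art_rows)) do.call(rbind, art_rows) else NULL,
    type_counts = data.frame(sample = samples,
                             n_snv = vapply(type_counts, `[`, integer(1), 1L),
                             n_dbs = vapply(type_counts, `[`, integer(1), 2L),
                             n_indel = vapply(type_counts, `[`, integer(1), 3L),
                             row.names = NULL)
  )
  list(calls = calls, truth = truth)
}

#' Simulate a functional score track
#'
#' One score per (position, alternate allele) over the covered gene
#' territory: background scores i.i.d. Gamma (a CADD-like scale), planted
#' driver sites drawn uniformly from `driver_score_range`. Deterministic
#' under the seed; driver sites are the same ones [simulate_cohort()]
#' mutates.
#'
#' @param config A [simulation_config()].
#' @param models,reference Output of [generate_genome()].
#' @return Score-track data.frame (`chrom`, `pos`, `alt`, `score`).
#' @export
simulate_score_track <- function(config, models, reference) {
  idx <- sim_index(config, models, reference)
  drv <- planted_driver_sites(config, models, reference)
  set.seed(config$seed + 303L)
  cov <- covered_positions(config, models, reference, idx)
  ch <- names(cov)[[1]]
  m <- idx$maps[[ch]]
  p <- cov[[ch]]
  p <- p[m$region[p] != REGION_CODE[["INTERGENIC"]]]  # gene territory only
  ref <- ref_bases(reference, rep(ch, length(p)), p)
  # the three non-reference bases per position, position-major order
  base_m <- matrix(DNA_BASES, nrow = length(p), ncol = 4L, byrow = TRUE)
  keep <- base_m != ref
  track <- data.frame(chrom = ch, pos = rep(p, each = 3L),
                      alt = as.vector(t(base_m))[as.vector(t(keep))],
                      stringsAsFactors = FALSE)
  track$score <- rgamma(nrow(track), shape = config$score_shape,
                        scale = config$score_scale)
  if (nrow(drv)) {
    key <- paste(track$pos, track$alt)
    hit <- match(paste(drv$pos, drv$alt), key)
    track$score[hit[!is.na(hit)]] <-
      runif(sum(!is.na(hit)), config$driver_score_range[1],
            config$driver_score_range[2])
  }
  track
}

#' Simulate MLPA probe signals
#'
#' Tumor and normal signals per sample and probe:
#' `probe efficiency x run scale x copy-state factor x lognormal noise`.
#' Planted single-copy arm losses (factor 0.5) and gains (1.5) affect the
#' configured numbers of samples on the `9q` and `9p` arms respectively;
#' control probes are never affected.
#'
#' @param config A [simulation_config()].
#' @param probes An `MLPAProbeSet` with an `arm` column (default
#'   [chr9_probe_set()]).
#' @return list with matrices `tumor`, `normal` (samples x probes) and
#'   `truth` (data.frame sample, cna).
#' @export
simulate_mlpa <- function(config, probes = chr9_probe_set()) {
  set.seed(config$seed + 404L)
  samples <- sprintf("S%02d", seq_len(config$n_samples))
  np <- nrow(probes)
  eff <- rlnorm(np, 0, 0.3)
  loss_s <- sample(samples, min(config$mlpa_loss_samples, length(samples)))
  gain_s <- sample(setdiff(samples, loss_s),
                   min(config$mlpa_gain_samples,
                       length(samples) - length(loss_s)))
  arm <- probes$arm %||% rep("none", np)
  mk <- function() matrix(NA_real_, length(samples), np,
                          dimnames = list(samples, probes$probe_id))
  tumor <- mk(); normal <- mk()
  for (s in samples) {
    factor_t <- rep(1, np)
    if (s %in% loss_s) factor_t[arm == "9q"] <- 0.5
    if (s %in% gain_s) factor_t[arm == "9p"] <- 1.5
    tumor[s, ] <- eff * rlnorm(1, 0, 0.2) * factor_t *
      rlnorm(np, 0, config$mlpa_noise_sigma)
    normal[s, ] <- eff * rlnorm(1, 0, 0.2) *
      rlnorm(np, 0, config$mlpa_noise_sigma)
  }
  cna <- ifelse(samples %in% loss_s, "chr9q_loss",
                ifelse(samples %in% gain_s, "chr9p_gain", "none"))
  list(tumor = tumor, normal = normal,
       truth = data.frame(sample = samples, cna = cna,
                          stringsAsFactors = FALSE))
}

#' Driver-recovery benchmark for the FM-bias test
#'
#' Runs the full simulator-to-driver-test path on a compact configuration
#' tuned for statistical resolution: 60 genes, ~120 mutations per sample,
#' and 8 planted 5'UTR driver regions with 6 carriers each at
#' high-functional-score sites. With 1000 resampling iterations the
#' empirical p-value floor is 1/1001, so a compact region-class universe is
#' what makes q < 0.025 attainable; this benchmark measures the power of
#' the test to recover the planted drivers at that threshold.
#'
#' @param seed Integer seed.
#' @param n_iterations Null iterations (default 1000).
#' @return list with `results` (the [fm_bias_test()] table), `planted`
#'   (gene ids), `power` (fraction of planted drivers with q < 0.025).
#' @export
fm_driver_benchmark <- function(seed = 1L, n_iterations = 1000L) {
  config <- simulation_config(
    seed = seed, n_genes = 60L,
    burden_meanlog = log(120), burden_sdlog = 0.4,
    hotspots = list(),
    drivers = rep(list(list(region = "UTR5", n_carriers = 6L)), 8),
    n_artifacts = c(low_support = 0L, low_af = 0L, low_ratio = 0L,
                    germline = 0L, pon = 0L))
  gen <- generate_genome(config)
  sim <- simulate_cohort(config, gen$reference, gen$models)
  flt <- apply_somatic_filters(sim$calls)
  rec <- merge_adjacent_snvs(flt$passed)
  rec <- annotate_mutations(rec, gen$models, gen$reference)
  track <- simulate_score_track(config, gen$models, gen$reference)
  res <- fm_bias_test(rec, gen$models, gen$reference, track,
                      fm_bias_params(n_iterations = n_iterations,
                                     seed = seed + 505L))
  planted <- unique(sim$truth$drivers$gene_id)
  hit <- res$gene_id[res$region == "UTR5" & res$q_value < 0.025]
  list(results = res, planted = planted,
       power = mean(planted %in% hit))
}
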