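# Shared fixtures and independent oracles, built in code at test time.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(Biostrings)
})

# A hand-crafted single-gene genome with fully known geometry.
# Transcript layout (transcript coordinates):
#   5'UTR 1..12 | CDS 13..102 (30 codons: ATG, 28 internal, stop) | 3'UTR 103..252
# Two exons split at transcript position 60, one 80 nt intron.
# Codon 24 of the CDS is TCC (Ser), so c.71C>T gives TTC (Phe) = Ser24Phe.
# On the minus strand the same transcript is embedded reverse-complemented,
# producing a mirrored twin gene for strand-consistency checks.
toy_gene <- function(strand = "+", pad = 30L) {
  set.seed(42)
  internal <- c("AAA", "CCA", "GGA", "TTG", "CAT", "GAC", "TGG", "ATC",
                "GTT", "ACA", "CTG", "GAA", "TAC", "AGT", "CCG", "TCA",
                "GCT", "AAC", "GGT", "CAG", "TGC", "ATT", "TCC", "GAG",
                "CTT", "ACC", "GTA", "AGA")
  stopifnot(internal[23] == "TCC")   # codon 24 overall (after ATG)
  cds <- paste0("ATG", paste(internal, collapse = ""), "TAA")
  stopifnot(nchar(cds) == 90)
  u5 <- "GGCTAGCTAGCC"                               # 12 nt
  u3 <- paste(sample(c("A", "C", "G", "T"), 150, TRUE), collapse = "")
  tx <- paste0(u5, cds, u3)                          # 252 nt
  intron <- paste(sample(c("A", "C", "G", "T"), 80, TRUE), collapse = "")
  sense <- paste0(substr(tx, 1, 60), intron, substr(tx, 61, 252))
  gseq <- if (strand == "+") sense else as.character(
    reverseComplement(DNAString(sense)))
  left <- paste(sample(c("A", "C", "G", "T"), pad, TRUE), collapse = "")
  right <- paste(sample(c("A", "C", "G", "T"), pad, TRUE), collapse = "")
  genome <- DNAStringSet(paste0(left, gseq, right))
  names(genome) <- "chrT"
  off <- pad
  glen <- nchar(gseq)
  # sense-assembly coordinates
  ex_s <- c(1L, 141L); ex_e <- c(60L, 332L)          # exon2: 61..252 + 80
  cds_s <- c(13L, 141L); cds_e <- c(60L, 182L)       # CDS tx 13..102
  if (strand == "-") {
    mir <- function(s, e) c(glen - e + 1L, glen - s + 1L)
    t1 <- mapply(mir, ex_s, ex_e); ex_s <- t1[1, ]; ex_e <- t1[2, ]
    t2 <- mapply(mir, cds_s, cds_e); cds_s <- t2[1, ]; cds_e <- t2[2, ]
  }
  mk <- function(s, e) GRanges("chrT", IRanges(off + s, off + e),
                               strand = strand, transcript_id = "TX1",
                               gene_id = "GTOY", gene_name = "GTOY")
  models <- gene_model_set(c(mk(ex_s[1], ex_e[1]), mk(ex_s[2], ex_e[2])),
                           c(mk(cds_s[1], cds_e[1]), mk(cds_s[2], cds_e[2])))
  # genomic position of a transcript coordinate
  t2g <- function(tpos) {
    a <- ifelse(tpos <= 60, tpos, tpos + 80L)        # sense assembly coord
    if (strand == "-") a <- glen - a + 1L
    off + a
  }
  list(genome = genome, models = models, strand = strand, t2g = t2g,
       cds_start_t = 13L, cds_end_t = 102L, tx_len = 252L, tx_seq = tx)
}

# small simulated world shared by several integration tests
small_world <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    cfg <- simulation_config(
      seed = 11, n_genes = 15, n_samples = 8,
      burden_meanlog = log(180), burden_sdlog = 0.3,
      low_burden_samples = 4L, alk_sample = 5L,
      hotspots = list(list(region = "UTR3", offset = 142L, width = 2L,
                           n_carriers = 5L, dbs_carriers = 1L),
                      list(region = "CODING", offset = 31L, width = 1L,
                           n_carriers = 3L, dbs_carriers = 0L)),
      drivers = rep(list(list(region = "UTR5", n_carriers = 4L)), 2),
      n_artifacts = c(low_support = 12L, low_af = 12L, low_ratio = 12L,
                      germline = 12L, pon = 12L))
    gen <- generate_genome(cfg)
    sim <- simulate_cohort(cfg, gen$reference, gen$models)
    flt <- apply_somatic_filters(sim$calls)
    rec <- suppressMessages(merge_adjacent_snvs(flt$passed))
    rec <- annotate_mutations(rec, gen$models, gen$reference)
    cache <<- list(cfg = cfg, gen = gen, sim = sim, flt = flt, rec = rec)
    cache
  }
})

# --- independent oracles ---------------------------------------------------

# brute-force hotspot enumeration: scan every mutated position, merge
# adjacent ones transitively by repeated sweeps, count distinct samples
oracle_hotspots <- function(df, min_samples = 3L, merge_distance = 1L) {
  pos <- sort(unique(df$pos))
  if (!length(pos)) return(data.frame(start = integer(), end = integer(),
                                      n_samples = integer()))
  grp <- seq_along(pos)
  repeat {
    changed <- FALSE
    for (i in seq_along(pos)[-1]) {
      if (pos[i] - pos[i - 1] <= merge_distance && grp[i] != grp[i - 1]) {
        grp[grp == grp[i]] <- grp[i - 1]; changed <- TRUE
      }
    }
    if (!changed) break
  }
  out <- list()
  for (g in unique(grp)) {
    p <- pos[grp == g]
    smp <- unique(df$sample[df$pos %in% p])
    if (length(smp) >= min_samples)
      out[[length(out) + 1L]] <- data.frame(start = min(p), end = max(p),
                                            n_samples = length(smp))
  }
  if (!length(out)) return(data.frame(start = integer(), end = integer(),
                                      n_samples = integer()))
  res <- do.call(rbind, out)
  res[order(res$start), , drop = FALSE]
}

# exhaustive hypergeometric enumeration of the two-sided Fisher p-value,
# via log-binomial coefficients (independent of dhyper)
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + c; n <- b + d; k <- a + b
  lo <- max(0, k - n); hi <- min(k, m)
  lp <- vapply(lo:hi, function(x)
    lchoose(m, x) + lchoose(n, k - x) - lchoose(m + n, k), numeric(1))
  pr <- exp(lp)
  p_obs <- exp(lchoose(m, a) + lchoose(n, k - a) - lchoose(m + n, k))
  sum(pr[pr <= p_obs * (1 + 1e-7)])   # same tie convention as the package
}

# translate a full CDS with Biostrings, as an oracle for effect categories
oracle_effect_snv <- function(cds_seq, ci, alt_c) {
  mut <- cds_seq
  substr(mut, ci, ci) <- alt_c
  pr <- function(s) as.character(translate(DNAString(s), no.init.codon = TRUE))
  aa_ref <- pr(cds_seq); aa_mut <- pr(mut)
  d <- which(strsplit(aa_ref, "")[[1]] != strsplit(aa_mut, "")[[1]])
  if (!length(d)) return("synonymous")
  ch <- substr(aa_mut, d[1], d[1])
  if (ch == "*") return("nonsense")
  if (substr(aa_ref, d[1], d[1]) == "*") return("stop_loss")
  "missense"
}
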