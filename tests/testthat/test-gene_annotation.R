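# Region classification and coding-effect prediction on hand-crafted and
# simulated gene models.

test_that("splice window and intron proximity rules classify correctly", {
  g <- toy_gene("+")
  # exon1 ends at transcript pos 60; genomic end of exon1:
  ex1_end <- g$t2g(60L)
  probe <- function(p) as.character(
    classify_region("chrT", p, g$models, g$genome)$region)
  expect_equal(probe(ex1_end), "CODING")
  expect_equal(probe(ex1_end + 1L), "SPLICE_SITE")  # +1 nt into intron
  expect_equal(probe(ex1_end + 2L), "SPLICE_SITE")  # +/-2 rule boundary
  expect_equal(probe(ex1_end + 3L), "INTRON")       # just past the window
  expect_equal(probe(g$t2g(5L)), "UTR5")
  expect_equal(probe(g$t2g(102L + 142L)), "UTR3")   # 142 nt past the stop
  expect_equal(probe(3L), "INTERGENIC")
  expect_error(probe_chr <- classify_region("chrZ", 5L, g$models, g$genome),
               "unknown contig")
})

test_that("deep intronic positions are excluded from region tallies", {
  cfg <- simulation_config(seed = 3, n_genes = 4, n_samples = 2,
                           burden_meanlog = log(40), burden_sdlog = 0.2,
                           low_burden_samples = integer(0), alk_sample = 1L,
                           intron_len_range = c(400L, 500L),
                           hotspots = list(), drivers = list(),
                           n_artifacts = c(low_support = 0L, low_af = 0L,
                                           low_ratio = 0L, germline = 0L,
                                           pon = 0L))
  gen <- generate_genome(cfg)
  # positions at intron centers classify INTRON_DEEP
  idx <- uvsomatic:::annotation_index(gen$models, gen$reference,
                                      annotation_params())
  m <- idx$maps[[1]]
  deep <- which(m$region == uvsomatic:::REGION_CODE[["INTRON_DEEP"]])
  expect_gt(length(deep), 0)
  expect_true(all(m$dist[deep] > 100))
})

test_that("every simulated mutation gets exactly one region and tallies close", {
  w <- small_world()
  reg <- as.character(w$rec$region)
  expect_false(any(is.na(reg)))
  expect_true(all(reg %in% c("CODING", "SPLICE_SITE", "UTR5", "UTR3",
                             "INTRON", "INTRON_DEEP", "INTERGENIC")))
  expect_equal(sum(table(reg)), nrow(w$rec))
})

test_that("coding substitutions translate correctly incl. the Ser24Phe case", {
  for (strand in c("+", "-")) {
    g <- toy_gene(strand)
    p71 <- g$t2g(12L + 71L)                 # CDS position 71 (codon 24, TCC)
    ref <- as.character(Biostrings::subseq(g$genome[[1]], p71, p71))
    alt <- if (strand == "+") "T" else "A"  # C>T on the coding strand
    recs <- data.frame(sample_id = "S1", chrom = "chrT", pos = p71,
                       end = p71, ref = ref, alt = alt, mtype = "SNV",
                       region = "CODING", gene_id = "GTOY",
                       stringsAsFactors = FALSE)
    eff <- coding_effect(recs, g$models, g$genome)
    expect_equal(eff$effect, "missense", info = strand)
    expect_equal(eff$aa_change, "Ser24Phe", info = strand)
  }
})

test_that("stop gain, frameshift and inframe indels are typed by arithmetic", {
  g <- toy_gene("+")
  # codon 21 is CAG (Gln); C>T at its first base (c.61) gives TAG = stop
  p <- g$t2g(12L + 61L)
  ref <- as.character(Biostrings::subseq(g$genome[[1]], p, p))
  expect_equal(ref, "C")
  recs <- data.frame(sample_id = "S1", chrom = "chrT",
                     pos = c(p, p, p), end = c(p, p + 1L, p + 3L),
                     ref = c(ref, paste0(ref, "A"), paste0(ref, "AGG")),
                     alt = c("T", ref, ref),
                     mtype = c("SNV", "INDEL", "INDEL"),
                     region = "CODING", gene_id = "GTOY",
                     stringsAsFactors = FALSE)
  eff <- coding_effect(recs, g$models, g$genome)
  expect_equal(eff$effect, c("nonsense", "frameshift", "inframe_indel"))
})

test_that("effect prediction agrees with full-CDS translation on simulated SNVs", {
  w <- small_world()
  snv <- w$rec[w$rec$mtype == "SNV" & w$rec$region == "CODING", ]
  snv <- head(snv[order(snv$pos), ], 120)
  idx <- uvsomatic:::annotation_index(w$gen$models, w$gen$reference,
                                      annotation_params())
  for (i in seq_len(nrow(snv))) {
    tx <- idx$canonical_tx[snv$gene_id[i]]
    info <- idx$txinfo[[tx]]
    tp <- uvsomatic:::idx_lookup(idx, snv$chrom[i], snv$pos[i], "tpos")
    ci <- tp - info$cds_start_t + 1L
    alt_c <- if (info$strand == "-") chartr("ACGT", "TGCA", snv$alt[i]) else snv$alt[i]
    expect_equal(snv$effect[i], oracle_effect_snv(info$cds_seq, ci, alt_c),
                 info = paste(snv$gene_id[i], snv$pos[i]))
  }
})

test_that("a reference-mismatching call is rejected", {
  g <- toy_gene("+")
  p <- g$t2g(12L + 10L)
  ref <- as.character(Biostrings::subseq(g$genome[[1]], p, p))
  wrong <- setdiff(c("A", "C", "G", "T"), ref)[1]
  recs <- data.frame(sample_id = "S1", chrom = "chrT", pos = p, end = p,
                     ref = wrong, alt = ref, mtype = "SNV",
                     region = "CODING", gene_id = "GTOY",
                     stringsAsFactors = FALSE)
  expect_error(coding_effect(recs, g$models, g$genome), "reference mismatch")
})

test_that("classification of a minus-strand gene mirrors its plus-strand twin", {
  gp <- toy_gene("+"); gm <- toy_gene("-")
  tpts <- c(5L, 40L, 80L, 102L, 150L, 200L)   # spread over UTR5/CDS/UTR3
  for (tp in tpts) {
    rp <- classify_region("chrT", gp$t2g(tp), gp$models, gp$genome)
    rm <- classify_region("chrT", gm$t2g(tp), gm$models, gm$genome)
    expect_equal(as.character(rp$region), as.character(rm$region), info = tp)
  }
})
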