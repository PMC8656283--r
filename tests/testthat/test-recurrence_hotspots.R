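# Hotspot detection and frequently-mutated-gene thresholds.

mk_rec <- function(sample, pos, end = pos, mtype = "SNV", gene = "G1",
                   region = "CODING", effect = "missense", dist = NA) {
  data.frame(sample_id = sample, chrom = "chr1", pos = as.integer(pos),
             end = as.integer(end), ref = "C", alt = "T", mtype = mtype,
             region = region, effect = effect, gene_id = gene,
             dist_to_exon = dist, stringsAsFactors = FALSE)
}

test_that("hotspots count distinct samples and merge adjacent positions", {
  # one position mutated in 3 distinct samples
  r <- rbind(mk_rec("A", 100), mk_rec("B", 100), mk_rec("C", 100))
  hs <- find_hotspots(r)
  expect_equal(nrow(hs), 1L)
  expect_equal(hs$n_samples, 3L)
  # adjacent positions with 4 + 4 disjoint samples merge to n_samples = 8
  r2 <- rbind(mk_rec(paste0("S", 1:4), 200),
              mk_rec(paste0("S", 5:8), 201))
  hs2 <- find_hotspots(r2)
  expect_equal(nrow(hs2), 1L)
  expect_equal(c(hs2$start, hs2$end, hs2$n_samples), c(200L, 201L, 8L))
  # per-sample multiplicity is ignored: 2 distinct samples is no hotspot
  r3 <- rbind(mk_rec("A", 300), mk_rec("A", 300, end = 300), mk_rec("B", 300))
  r3$alt <- c("T", "G", "T")
  expect_equal(nrow(find_hotspots(r3)), 0L)
  # a double substitution contributes its full span
  r4 <- rbind(mk_rec("A", 400, end = 401, mtype = "DBS"),
              mk_rec("B", 401), mk_rec("C", 401))
  expect_equal(find_hotspots(r4)$n_samples, 3L)
})

test_that("hotspot detection equals brute-force enumeration on random cohorts", {
  set.seed(77)
  for (trial in 1:30) {
    n_s <- sample(2:10, 1); n_m <- sample(5:60, 1)
    df <- data.frame(sample = sample(paste0("S", 1:n_s), n_m, TRUE),
                     pos = sample(1:200, n_m, TRUE))
    df <- unique(df)
    rec <- mk_rec(df$sample, df$pos)
    rec$alt <- "T"
    got <- find_hotspots(rec)
    want <- oracle_hotspots(df)
    expect_equal(nrow(got), nrow(want), info = trial)
    if (nrow(want)) {
      expect_equal(got$start, want$start, info = trial)
      expect_equal(got$end, want$end, info = trial)
      expect_equal(got$n_samples, want$n_samples, info = trial)
    }
  }
})

test_that("raising thresholds never enlarges the hotspot set, and re-running
           on hotspot positions is idempotent", {
  w <- small_world()
  h3 <- find_hotspots(w$rec, recurrence_params(hotspot_min_samples = 3))
  h4 <- find_hotspots(w$rec, recurrence_params(hotspot_min_samples = 4))
  expect_lte(nrow(h4), nrow(h3))
  key3 <- paste(h3$chrom, h3$start, h3$end)
  expect_true(all(paste(h4$chrom, h4$start, h4$end) %in% key3))
  # idempotence: records restricted to hotspot spans reproduce the spans
  keep <- rep(FALSE, nrow(w$rec))
  for (i in seq_len(nrow(h3)))
    keep <- keep | (w$rec$pos >= h3$start[i] & w$rec$end <= h3$end[i])
  h_again <- find_hotspots(w$rec[keep, ], recurrence_params())
  expect_equal(h_again[, c("chrom", "start", "end", "n_samples")],
               h3[, c("chrom", "start", "end", "n_samples")],
               ignore_attr = TRUE)
})

test_that("planted hotspots are always recovered with their carrier counts", {
  w <- small_world()
  hs <- find_hotspots(w$rec)
  for (i in seq_len(nrow(w$sim$truth$hotspots))) {
    tr <- w$sim$truth$hotspots[i, ]
    hit <- hs[hs$start <= tr$start & hs$end >= tr$end, ]
    expect_gte(max(hit$n_samples, 0), tr$n_carriers)
  }
})

test_that("frequently mutated genes honor qualifiers, windows and exclusions", {
  base <- rbind(
    mk_rec(paste0("S", 1:5), 1:5),                                 # nonsyn CODING x5
    mk_rec(paste0("S", 1:5), 11:15, gene = "G2", effect = "synonymous"),
    mk_rec(paste0("S", 1:4), 21:24, gene = "G3", region = "UTR5", effect = NA),
    mk_rec(paste0("S", 1:5), 31:35, gene = "G4", region = "INTRON",
           effect = NA, dist = 45L),
    mk_rec(paste0("S", 1:5), 41:45, gene = "G5", region = "INTRON",
           effect = NA, dist = 35L),
    mk_rec(paste0("S", 1:5), 51:55, gene = "G6", region = "SPLICE_SITE",
           effect = "splice"))
  out <- find_frequently_mutated_genes(base)
  expect_true(all(c("G1", "G3", "G5", "G6") %in% out$gene_id))
  expect_false("G2" %in% out$gene_id)     # synonymous-only is not qualifying
  expect_false("G4" %in% out$gene_id)     # 45 nt > 40 nt intron window
  expect_equal(out$region[out$gene_id == "G6"], "CODING")  # splice counts coding
  # hypermutated exclusion list drops genes before thresholding
  out2 <- find_frequently_mutated_genes(
    base, recurrence_params(hypermutated_exclusion = "G1"))
  expect_false("G1" %in% out2$gene_id)
  # a 3'UTR gene with only 3 carriers misses the threshold of 4
  r3 <- mk_rec(paste0("S", 1:3), 61:63, gene = "G7", region = "UTR3",
               effect = NA)
  expect_false("G7" %in% find_frequently_mutated_genes(rbind(base, r3))$gene_id)
})
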