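# The UV-mutagenesis simulator: determinism, planted structure, realized
# mutation-type fractions and file round-trips.

test_that("generated genomes satisfy the gene-model invariants and are
           deterministic under the seed", {
  cfg <- simulation_config(seed = 13, n_genes = 10)
  g1 <- generate_genome(cfg)
  tx <- g1$models$transcripts
  expect_equal(nrow(tx), 10L)
  expect_true(all(tx$cds_ok))
  expect_true(all(tx$n_exons >= 2))
  expect_setequal(unique(tx$strand), c("+", "-"))
  # every canonical CDS translates ATG...stop with no internal stop
  idx <- uvsomatic:::annotation_index(g1$models, g1$reference,
                                      annotation_params())
  for (info in idx$txinfo) {
    aa <- as.character(Biostrings::translate(Biostrings::DNAString(info$cds_seq)))
    expect_equal(substr(aa, 1, 1), "M")
    expect_equal(substr(aa, nchar(aa), nchar(aa)), "*")
    expect_false(grepl("\\*", substr(aa, 1, nchar(aa) - 1)))
  }
  g2 <- generate_genome(cfg)
  expect_identical(as.character(g1$reference), as.character(g2$reference))
  expect_identical(g1$models$transcripts, g2$models$transcripts)
  expect_error(generate_genome(simulation_config(seed = 13, n_genes = 10,
                                                 genome_length = 1000L)),
               "genome_length too small")
})

test_that("switching off double substitutions removes DBS records", {
  # sparse cohort: accidental SNV adjacencies are then the only DBS source
  cfg <- simulation_config(seed = 14, n_genes = 10, n_samples = 4,
                           burden_meanlog = log(60), burden_sdlog = 0.2,
                           low_burden_samples = integer(0), alk_sample = 1L,
                           dbs_fraction = 0, hotspots = list(),
                           drivers = list(),
                           n_artifacts = c(low_support = 0L, low_af = 0L,
                                           low_ratio = 0L, germline = 0L,
                                           pon = 0L))
  gen <- generate_genome(cfg)
  sim <- simulate_cohort(cfg, gen$reference, gen$models)
  rec <- merge_adjacent_snvs(apply_somatic_filters(sim$calls)$passed)
  # no planted DBS: only rare accidental SNV adjacencies merge, far below
  # the default planted double-substitution fraction
  expect_lt(sum(rec$mtype == "DBS") / nrow(rec), 0.01)
})

test_that("realized type fractions match the configured fractions at 50k", {
  cfg <- simulation_config(seed = 15)        # defaults: 0.945/0.037/0.018
  gen <- generate_genome(cfg)
  sim <- simulate_cohort(cfg, gen$reference, gen$models)
  tc <- sim$truth$type_counts
  tot <- sum(tc$n_snv + tc$n_dbs + tc$n_indel)
  expect_gt(tot, 30000)
  expect_lt(abs(sum(tc$n_dbs) / tot - cfg$dbs_fraction), 0.01)
  expect_lt(abs(sum(tc$n_indel) / tot - cfg$indel_fraction), 0.01)
  expect_lt(abs(sum(tc$n_snv) / tot -
                  (1 - cfg$dbs_fraction - cfg$indel_fraction)), 0.01)
  # and the merged records reproduce them up to filtering accidents
  rec <- suppressMessages(
    merge_adjacent_snvs(apply_somatic_filters(sim$calls)$passed))
  expect_lt(abs(sum(rec$mtype == "DBS") / nrow(rec) - cfg$dbs_fraction), 0.01)
})

test_that("planted hotspots land where configured and carry their samples", {
  w <- small_world()
  tr <- w$sim$truth$hotspots
  expect_equal(nrow(tr), 2L)
  cls <- classify_region(tr$chrom, tr$start, w$gen$models, w$gen$reference)
  expect_equal(as.character(cls$region), tr$region)
  carriers <- strsplit(tr$carriers, ",")[[1]]
  hits <- w$rec[w$rec$pos >= tr$start[1] & w$rec$pos <= tr$end[1], ]
  expect_true(all(carriers %in% hits$sample_id))
})

test_that("true somatic calls pass filtering; spiked artifacts fail or flag", {
  w <- small_world()
  art <- w$sim$truth$artifacts
  flt <- w$flt
  rej_key <- paste(flt$rejected$sample_id, flt$rejected$pos, flt$rejected$alt)
  for (cl in c("low_support", "low_af", "low_ratio")) {
    a <- art[art$class == cl, ]
    expect_true(all(paste(a$sample_id, a$pos, a$alt) %in% rej_key),
                info = cl)
    expect_equal(flt$rejected$reason[match(paste(a$sample_id, a$pos, a$alt),
                                           rej_key)],
                 rep(cl, nrow(a)), info = cl)
  }
  # germline/PoN spikes are site-flagged, not read-support-rejected
  calls <- suppressMessages(flag_sites(w$sim$calls,
                                       w$sim$truth$germline_sites, "germline"))
  g <- art[art$class == "germline", ]
  flagged <- calls[nzchar(calls$flags), ]
  expect_true(all(paste(g$pos, g$alt) %in% paste(flagged$pos, flagged$alt)))
})

test_that("driver sites carry enriched scores and are shared across products", {
  w <- small_world()
  track <- simulate_score_track(w$cfg, w$gen$models, w$gen$reference)
  track2 <- simulate_score_track(w$cfg, w$gen$models, w$gen$reference)
  expect_identical(track, track2)                 # deterministic under seed
  drv <- w$sim$truth$drivers
  key <- paste(track$pos, track$alt)
  hit <- match(paste(drv$pos, drv$alt), key)
  expect_false(anyNA(hit))
  expect_gt(min(track$score[hit]), 20)            # planted high scores
  expect_lt(mean(track$score[-hit]), 6)           # background well below
  # the cohort mutates exactly those sites in the recorded carriers
  rk <- paste(w$rec$sample_id, w$rec$pos, w$rec$alt)
  expect_true(all(paste(drv$carrier, drv$pos, drv$alt) %in% rk))
})

test_that("every generated file parses back through the package readers", {
  w <- small_world()
  d <- tempfile(); dir.create(d)
  expect_no_warning({
    Biostrings::writeXStringSet(w$gen$reference, file.path(d, "ref.fa"))
    write_gtf(w$gen$models, file.path(d, "genes.gtf"))
    paths <- write_cohort_vcfs(w$sim$calls, file.path(d, "vcf"),
                               w$gen$reference)
    ref <- Biostrings::readDNAStringSet(file.path(d, "ref.fa"))
    models <- load_gene_models(file.path(d, "genes.gtf"))
    load_cohort(paths, setNames(ref, "chr1"), models)
  })
  m2 <- load_gene_models(file.path(d, "genes.gtf"))
  expect_equal(m2$transcripts$cds_len, w$gen$models$transcripts$cds_len)
  expect_equal(sort(as.integer(start(m2$utr5))),
               sort(as.integer(start(w$gen$models$utr5))))
})
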