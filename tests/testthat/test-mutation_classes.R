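# DBS merging, trinucleotide contexts and HGVS-like labels.

mk_sub <- function(sample, pos, ref, alt) {
  data.frame(sample_id = sample, chrom = "chr1", pos = as.integer(pos),
             ref = ref, alt = alt, tumor_alt = 20L, tumor_depth = 60L,
             normal_alt = 0L, normal_depth = 60L, flags = "",
             tumor_af = 20 / 60, stringsAsFactors = FALSE)
}

test_that("adjacent same-sample substitutions merge into CC>TT DBS records", {
  calls <- rbind(mk_sub("A", 100, "C", "T"), mk_sub("A", 101, "C", "T"))
  rec <- merge_adjacent_snvs(calls)
  expect_equal(rec$mtype, "DBS")
  expect_equal(rec$ref, "CC"); expect_equal(rec$alt, "TT")
  expect_true(rec$is_cc_tt)
  expect_equal(c(rec$pos, rec$end), c(100L, 101L))
  # reverse-strand reading GG>AA is the same event
  rec2 <- merge_adjacent_snvs(rbind(mk_sub("A", 10, "G", "A"),
                                    mk_sub("A", 11, "G", "A")))
  expect_true(rec2$is_cc_tt)
})

test_that("gaps, other samples and long runs are kept apart", {
  # gap of one position: two SNVs
  rec <- merge_adjacent_snvs(rbind(mk_sub("A", 100, "C", "T"),
                                   mk_sub("A", 102, "C", "T")))
  expect_equal(rec$mtype, c("SNV", "SNV"))
  # same positions, different samples: per-sample merging only
  rec <- merge_adjacent_snvs(rbind(mk_sub("A", 100, "C", "T"),
                                   mk_sub("B", 101, "C", "T")))
  expect_equal(rec$mtype, c("SNV", "SNV"))
  # a run of three adjacent substitutions becomes one multi-nucleotide record
  expect_message(
    rec <- merge_adjacent_snvs(rbind(mk_sub("A", 100, "C", "T"),
                                     mk_sub("A", 101, "C", "T"),
                                     mk_sub("A", 102, "G", "A"))),
    "multi-nucleotide")
  expect_equal(rec$mtype, "INDEL")
  expect_equal(rec$ref, "CCG")
  # duplicate keys are an input error
  expect_error(merge_adjacent_snvs(rbind(mk_sub("A", 100, "C", "T"),
                                         mk_sub("A", 100, "C", "T"))),
               "duplicate")
})

test_that("base-count conservation holds across merging", {
  w <- small_world()
  calls <- w$flt$passed
  rec <- w$rec
  is_sub <- nchar(calls$ref) == 1 & nchar(calls$alt) == 1
  spanned <- sum(rec$end - rec$pos + 1)
  expect_equal(spanned,
               sum(is_sub) + sum(nchar(calls$ref[!is_sub])))
})

test_that("contexts are pyrimidine-normalized with the fixed channel order", {
  ctx <- trinucleotide_contexts()
  expect_equal(length(ctx), 96L)
  expect_false(any(duplicated(ctx)))
  ref <- Biostrings::DNAStringSet(c(chrX = "AACGTCGCA"))
  # A[C>T]G at pos 3 stays A[C>T]G
  i1 <- trinucleotide_context(
    data.frame(chrom = "chrX", pos = 3L, ref = "C", alt = "T"), ref)
  expect_equal(ctx[i1], "A[C>T]G")
  # C[G>A]C at pos 7 reverse-complements to G[C>T]G
  i2 <- trinucleotide_context(
    data.frame(chrom = "chrX", pos = 7L, ref = "G", alt = "A"), ref)
  expect_equal(ctx[i2], "G[C>T]G")
  # contig edge has no flanking base
  expect_error(trinucleotide_context(
    data.frame(chrom = "chrX", pos = 1L, ref = "A", alt = "G"), ref),
    "no flanking base")
  # DBS records are outside the contract
  expect_error(trinucleotide_context(
    data.frame(chrom = "chrX", pos = 3L, ref = "CG", alt = "TT",
               mtype = "DBS"), ref),
    "SNVs only")
})

test_that("integer-code channel computation agrees with the string version", {
  b <- c("A", "C", "G", "T")
  grid <- expand.grid(ref = b, alt = b, up = b, down = b,
                      stringsAsFactors = FALSE)
  grid <- grid[grid$ref != grid$alt, ]
  i_str <- uvsomatic:::context_index_of(grid$ref, grid$alt, grid$up, grid$down)
  i_cod <- uvsomatic:::context_index_codes(match(grid$ref, b), match(grid$alt, b),
                                           match(grid$up, b), match(grid$down, b))
  expect_equal(i_str, i_cod)
  expect_true(all(i_str >= 1 & i_str <= 96))
})

test_that("HGVS labels cover UTR5, UTR3, CDS, introns and delins, both strands", {
  for (strand in c("+", "-")) {
    g <- toy_gene(strand)
    lab <- function(tpos, ref, alt, mtype = "SNV", width = 1L) {
      p <- g$t2g(tpos)
      if (width == 2L) p <- min(p, g$t2g(tpos + 1L))
      r <- data.frame(sample_id = "S", chrom = "chrT", pos = p,
                      end = p + width - 1L, ref = ref, alt = alt,
                      mtype = mtype, region = "x", gene_id = "GTOY",
                      stringsAsFactors = FALSE)
      hgvs_label(r, g$models, g$genome)
    }
    seqat <- function(tpos) substr(g$tx_seq, tpos, tpos)  # coding-strand base
    flip <- function(x) if (strand == "+") x else
      uvsomatic:::revcomp_chr(x)
    # 5'UTR substitution 5 nt upstream of the start codon
    r5 <- seqat(8L)   # tpos 8 = c.-5 (cds starts at 13)
    expect_equal(lab(8L, flip(r5), flip("A")), paste0("c.-5", r5, ">A"),
                 info = strand)
    # 3'UTR substitution 142 nt after the stop
    r3 <- seqat(102L + 142L)
    expect_equal(lab(102L + 142L, flip(r3), flip("A")),
                 paste0("c.*142", r3, ">A"), info = strand)
    # CDS substitution c.71C>T
    expect_equal(lab(12L + 71L, flip("C"), flip("T")), "c.71C>T",
                 info = strand)
    # adjacent double substitution at c.-5/-4 rendered as delins
    rr <- paste0(seqat(8L), seqat(9L))
    expect_equal(lab(8L, flip(rr), flip("AA"), mtype = "DBS", width = 2L),
                 "c.-5_-4delinsAA", info = strand)
  }
})

test_that("intronic labels anchor to the nearest exon boundary", {
  g <- toy_gene("+")
  ex1_end_t <- 60L                       # last exonic base of exon 1 = c.48
  p <- g$t2g(ex1_end_t) + 2L             # 2 nt into the intron
  r <- data.frame(sample_id = "S", chrom = "chrT", pos = p, end = p,
                  ref = as.character(Biostrings::subseq(g$genome[[1]], p, p)),
                  alt = "A", mtype = "SNV", region = "SPLICE_SITE",
                  gene_id = "GTOY", stringsAsFactors = FALSE)
  out <- hgvs_label(r, g$models, g$genome)
  expect_match(out, "^c\\.48\\+2")
  # strict mode demands gene association
  r$gene_id <- NA_character_
  expect_error(hgvs_label(r, g$models, g$genome, strict = TRUE),
               "not associated")
})

test_that("a pure-UV cohort concentrates all SNVs in C>T channels", {
  cfg <- simulation_config(seed = 21, n_genes = 6, n_samples = 3,
                           burden_meanlog = log(300), burden_sdlog = 0.1,
                           low_burden_samples = integer(0), alk_sample = 1L,
                           sig_weights = c(UV = 1, ALK = 0, FLAT = 0),
                           alk_weights = c(UV = 1, ALK = 0, FLAT = 0),
                           weight_jitter = 0, dbs_fraction = 0,
                           indel_fraction = 0, hotspots = list(),
                           drivers = list(),
                           n_artifacts = c(low_support = 0L, low_af = 0L,
                                           low_ratio = 0L, germline = 0L,
                                           pon = 0L))
  gen <- generate_genome(cfg)
  sim <- simulate_cohort(cfg, gen$reference, gen$models)
  rec <- merge_adjacent_snvs(apply_somatic_filters(sim$calls)$passed)
  rec <- annotate_mutations(rec, gen$models, gen$reference)
  idx <- rec$context_index[rec$mtype == "SNV"]
  # C>T block is channels 33..48; UV places only at pyrimidine-5' contexts
  expect_true(all(idx >= 33 & idx <= 48))
  labs <- trinucleotide_contexts()[idx]
  expect_true(all(substr(labs, 1, 1) %in% c("C", "T")))
})
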