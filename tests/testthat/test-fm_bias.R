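# Functional-mutation-bias statistic, resampling null and q-value tiers.

mk_track <- function(pos, score, alt = "T", chrom = "chr1") {
  data.frame(chrom = chrom, pos = as.integer(pos), alt = alt, score = score,
             stringsAsFactors = FALSE)
}

test_that("the observed statistic is the amean with max rules for DBS/indels", {
  track <- mk_track(1:9, c(0.2, 0.8, 1, 2, 3, 4, 5, 6, 7))
  snvs <- data.frame(sample_id = "S", chrom = "chr1", pos = c(1L, 2L),
                     end = c(1L, 2L), ref = "C", alt = "T", mtype = "SNV",
                     stringsAsFactors = FALSE)
  expect_equal(observed_statistic(snvs, track), 0.5)
  expect_equal(observed_statistic(snvs[1, ], track), 0.2)  # single SNV
  # indel at position 3: max over the 7-window scores 1..7 is 7
  indel <- data.frame(sample_id = "S", chrom = "chr1", pos = 3L, end = 4L,
                      ref = "CA", alt = "C", mtype = "INDEL",
                      stringsAsFactors = FALSE)
  expect_equal(observed_statistic(indel, track), 7)
  # DBS takes the max of its two positions
  dbs <- data.frame(sample_id = "S", chrom = "chr1", pos = 1L, end = 2L,
                    ref = "CC", alt = "TT", mtype = "DBS",
                    stringsAsFactors = FALSE)
  expect_equal(observed_statistic(dbs, track), 0.8)
  # unscored position is a hard error
  bad <- snvs; bad$pos <- c(50L, 51L)
  expect_error(observed_statistic(bad, track), "score gap")
})

test_that("null draws are degenerate, seeded and respect zero weights", {
  # n_mut equal to region size: every draw is the mean of all scores
  nulls <- null_distribution(1:10, rep(1, 10), 10,
                             fm_bias_params(n_iterations = 100, seed = 1))
  expect_true(all(nulls == mean(1:10)))
  # zero-weight pairs are unsampleable
  nulls2 <- null_distribution(c(5, 100, 100), c(1, 0, 0), 1,
                              fm_bias_params(n_iterations = 200, seed = 2))
  expect_true(all(nulls2 == 5))
  expect_error(null_distribution(1:3, c(0, 0, 0), 1, fm_bias_params()),
               "probabilities zero")
  # fixed seed reproduces the null vector exactly
  p <- fm_bias_params(n_iterations = 500, seed = 7)
  sc <- runif(50); wt <- runif(50)
  expect_identical(null_distribution(sc, wt, 5, p),
                   null_distribution(sc, wt, 5, p))
})

test_that("the compiled sampler draws with the law of sample(prob=)", {
  # n=3, k=2: identify each unordered pair by its mean; compare frequencies
  # against the successive-sampling law computed exactly by enumeration
  w <- c(0.5, 0.3, 0.2); s <- c(1, 10, 100)
  pair_mean <- c(`12` = mean(s[c(1, 2)]), `13` = mean(s[c(1, 3)]),
                 `23` = mean(s[c(2, 3)]))
  seq_p <- function(i, j) w[i] / sum(w) * w[j] / sum(w[-i])
  exact <- c(`12` = seq_p(1, 2) + seq_p(2, 1),
             `13` = seq_p(1, 3) + seq_p(3, 1),
             `23` = seq_p(2, 3) + seq_p(3, 2))
  set.seed(5)
  draws <- uvsomatic:::ppswor_null_means(w, s, 2L, 20000L)
  freq <- table(factor(draws, levels = pair_mean)) / 20000
  expect_lt(max(abs(as.numeric(freq) - exact)), 0.015)
  # the R-level sample(prob=) oracle agrees with the same exact law
  set.seed(6)
  rdraws <- replicate(20000, mean(s[sample.int(3, 2, prob = w)]))
  rfreq <- table(factor(rdraws, levels = pair_mean)) / 20000
  expect_lt(max(abs(as.numeric(rfreq) - exact)), 0.015)
})

test_that("empirical p-values use the +1 pseudocount and BH runs per class", {
  w <- small_world()
  cfg <- w$cfg
  track <- simulate_score_track(cfg, w$gen$models, w$gen$reference)
  res <- fm_bias_test(w$rec, w$gen$models, w$gen$reference, track,
                      fm_bias_params(n_iterations = 300, seed = 9))
  expect_true(all(res$p_value > 0 & res$p_value <= 1))
  expect_true(all(res$p_value >= 1 / 301))
  # q-values recompute as Benjamini-Hochberg within each region class
  for (cls in unique(res$region)) {
    sub <- res[res$region == cls, ]
    bh <- {
      p <- sub$p_value; n <- length(p); o <- order(p)
      q <- p[o] * n / seq_len(n)
      q <- rev(cummin(rev(q)))
      out <- numeric(n); out[o] <- pmin(q, 1); out
    }
    expect_equal(sub$q_value, bh, tolerance = 1e-12, info = cls)
  }
  # tiers follow the q thresholds
  expect_true(all(res$tier[res$q_value < 0.01] == "highly_significant"))
  expect_true(all(res$tier[res$q_value >= 0.025] == "none"))
  # planted 5'UTR drivers sit at the top of their class
  planted <- unique(w$sim$truth$drivers$gene_id)
  u5 <- res[res$region == "UTR5", ]
  expect_true(all(planted %in% u5$gene_id[seq_len(min(4, nrow(u5)))]))
})

test_that("cohort channel frequencies form the resampling weights", {
  w <- small_world()
  probs <- cohort_context_probs(w$rec)
  expect_equal(sum(probs), 1)
  expect_length(probs, 96)
  # UV-dominant cohort: C>T channels (33..48) carry most of the mass
  expect_gt(sum(probs[33:48]), 0.5)
})
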