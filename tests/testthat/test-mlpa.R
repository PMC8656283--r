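# MLPA geometric-mean normalization, CNA calling and simulator round-trip.

toy_probes <- function() {
  mlpa_probe_set(data.frame(
    probe_id = c("P1", "P2", "P3", "C1", "C2"),
    chrom = c("chr9", "chr9", "chr9", "chr2", "chr5"),
    pos = c(1e6, 2e6, 3e6, 1e6, 1e6),
    target = c("A", "B", "C", "control", "control"),
    is_control = c(FALSE, FALSE, FALSE, TRUE, TRUE),
    stringsAsFactors = FALSE))
}

test_that("identical tumor and normal signals give relative CN 2.0 exactly", {
  pr <- toy_probes()
  sig <- setNames(c(1.2, 0.8, 2.0, 1.0, 4.0), pr$probe_id)
  res <- normalize_mlpa(sig, sig, pr)
  expect_equal(res$relative_cn[1:3], rep(2, 3))
  expect_true(all(is.na(res$relative_cn[4:5])))  # controls are not reported
})

test_that("halved and 1.5x probes read 1.0 and 3.0; geometric mean is used", {
  pr <- toy_probes()
  nor <- setNames(c(1.2, 0.8, 2.0, 1.0, 4.0), pr$probe_id)
  tum <- nor; tum["P1"] <- tum["P1"] / 2; tum["P2"] <- tum["P2"] * 1.5
  res <- normalize_mlpa(tum, nor, pr)
  expect_equal(res$relative_cn[res$probe_id == "P1"], 1.0)
  expect_equal(res$relative_cn[res$probe_id == "P2"], 3.0)
  # control geometric mean: {1, 4} -> 2; doubling P3's tumor signal and
  # multiplying the controls by 4 (geomean 4x) halves its normalized value
  tum2 <- nor; tum2[c("C1", "C2")] <- tum2[c("C1", "C2")] * 4
  res2 <- normalize_mlpa(tum2, nor, pr)
  expect_equal(res2$relative_cn[1:3], rep(0.5, 3))
})

test_that("relative CN is invariant to rescaling either sample's signals", {
  pr <- toy_probes()
  set.seed(12)
  nor <- setNames(runif(5, 0.5, 2), pr$probe_id)
  tum <- setNames(runif(5, 0.5, 2), pr$probe_id)
  base <- normalize_mlpa(tum, nor, pr)$relative_cn
  for (c1 in c(0.01, 3, 170)) {
    expect_equal(normalize_mlpa(tum * c1, nor, pr)$relative_cn, base)
    expect_equal(normalize_mlpa(tum, nor * c1, pr)$relative_cn, base)
  }
})

test_that("input contracts: shared probes and positive control signals", {
  pr <- toy_probes()
  sig <- setNames(rep(1, 5), pr$probe_id)
  expect_error(normalize_mlpa(sig[-1], sig, pr), "missing probe")
  bad <- sig; bad["C1"] <- 0
  expect_error(normalize_mlpa(bad, sig, pr), "nonpositive control")
  expect_error(mlpa_probe_set(data.frame(probe_id = "P", chrom = "c", pos = 1,
                                         target = "t", is_control = FALSE)),
               "2 control")
})

test_that("CNA calls follow the loss/gain thresholds", {
  calls <- call_cna(c(1.0, 2.0, 3.0, 1.6, 2.4))
  expect_equal(calls, c("loss", "neutral", "gain", "loss", "gain"))
  expect_error(call_cna(2, loss_threshold = 2.1), "loss < 2 < gain")
})

test_that("noiseless planted arm CNAs round-trip to exactly 1.0 / 3.0", {
  cfg <- simulation_config(seed = 31, n_samples = 6, mlpa_noise_sigma = 0,
                           mlpa_loss_samples = 2L, mlpa_gain_samples = 2L)
  sim <- simulate_mlpa(cfg)
  pr <- chr9_probe_set()
  for (s in sim$truth$sample) {
    res <- normalize_mlpa(sim$tumor[s, ], sim$normal[s, ], pr)
    cna <- sim$truth$cna[sim$truth$sample == s]
    q <- res$relative_cn[pr$arm == "9q"]
    p <- res$relative_cn[pr$arm == "9p"]
    if (cna == "chr9q_loss") expect_equal(q, rep(1, length(q)))
    else if (cna == "chr9p_gain") expect_equal(p, rep(3, length(p)))
    else expect_equal(c(p, q), rep(2, length(p) + length(q)))
  }
})

test_that("planted CNAs are called correctly under 5% multiplicative noise", {
  cfg <- simulation_config(seed = 32)          # sigma = 0.05 default
  sim <- simulate_mlpa(cfg)
  pr <- chr9_probe_set()
  neut_ok <- 0L; neut_tot <- 0L
  for (s in sim$truth$sample) {
    res <- call_cna(normalize_mlpa(sim$tumor[s, ], sim$normal[s, ], pr))
    cna <- sim$truth$cna[sim$truth$sample == s]
    want <- ifelse(pr$is_control, NA,
            ifelse(pr$arm == "9q" & cna == "chr9q_loss", "loss",
            ifelse(pr$arm == "9p" & cna == "chr9p_gain", "gain", "neutral")))
    got <- res$call
    aff <- !is.na(want) & want != "neutral"
    # every probe on a planted-CNA arm is called correctly
    expect_equal(got[aff], want[aff], info = s)
    neut <- !is.na(want) & want == "neutral"
    neut_tot <- neut_tot + sum(neut)
    neut_ok <- neut_ok + sum(got[neut] == "neutral")
  }
  expect_gt(neut_ok / neut_tot, 0.95)   # rare noise-driven false calls only
})
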