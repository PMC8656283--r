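# MLPA relative copy number.
#
# Each probe's signal is divided by the geometric mean of the control-probe
# signals of the same run (normalizing run-to-run variation); the
# control-normalized tumor signal is then divided by the corresponding
# normal signal and multiplied by 2, so a diploid-neutral probe reads 2.0,
# a single-copy loss 1.0 and a single-copy gain 3.0.

#' Define an MLPA probe set
#'
#' @param df data.frame with columns `probe_id`, `chrom`, `pos`, `target`,
#'   `is_control` (logical). At least two control probes are required and
#'   probe ids must be unique.
#' @return The validated data.frame with class `MLPAProbeSet`.
#' @export
mlpa_probe_set <- function(df) {
  need <- c("probe_id", "chrom", "pos", "target", "is_control")
  stopifnot(all(need %in% names(df)))
  if (anyDuplicated(df$probe_id)) stop("duplicate probe ids")
  if (sum(df$is_control) < 2L) stop("need at least 2 control probes")
  class(df) <- c("MLPAProbeSet", class(df))
  df
}

#' Chromosome-9 style MLPA probe set
#'
#' A 20-probe layout emulating an assay targeting both arms of a
#' chromosome ("chr9"): arm-distributed probes plus probes in or near
#' genes of interest on 9p (a kinase and two immune-checkpoint ligand
#' genes) and 9q (a hedgehog-receptor tumor suppressor), and 5 control
#' probes on other chromosomes away from cancer-related regions.
#'
#' @return An `MLPAProbeSet` with an `arm` column (`9p`, `9q`, or `control`).
#' @export
chr9_probe_set <- function() {
  df <- data.frame(
    probe_id = c(sprintf("chr9p_arm_%d", 1:5), sprintf("chr9q_arm_%d", 1:2),
                 "JAK2_1", "JAK2_2", "PDL1_1", "PDL1_2", "PDL2_1", "PDL2_2",
                 "PTCH1_1", "PTCH1_2",
                 sprintf("ctrl_%d", 1:5)),
    chrom = c(rep("chr9", 15), c("chr2", "chr5", "chr7", "chr12", "chr17")),
    pos = c(seq(1e6, 30e6, length.out = 5), c(80e6, 120e6),
            5e6, 5.1e6, 5.45e6, 5.46e6, 5.51e6, 5.52e6, 95e6, 95.1e6,
            c(10e6, 20e6, 30e6, 40e6, 50e6)),
    target = c(rep("chr9p", 5), rep("chr9q", 2),
               "JAK2", "JAK2", "PDL1", "PDL1", "PDL2", "PDL2",
               "PTCH1", "PTCH1", rep("control", 5)),
    is_control = c(rep(FALSE, 15), rep(TRUE, 5)),
    stringsAsFactors = FALSE
  )
  df$arm <- ifelse(df$is_control, "control",
                   ifelse(df$target %in% c("chr9q", "PTCH1"), "9q", "9p"))
  mlpa_probe_set(df)
}

geomean <- function(x) exp(mean(log(x)))

#' Compute relative copy number from MLPA signals
#'
#' Per probe: `N_t = tumor / geomean(tumor controls)`,
#' `N_n = normal / geomean(normal controls)`, relative copy number
#' `2 * N_t / N_n`. The geometric-mean normalization makes the result
#' invariant to rescaling all tumor (or all normal) signals by any positive
#' constant.
#'
#' @param tumor_signals,normal_signals Named numeric vectors of probe
#'   intensities (names = probe ids; both must cover the probe set).
#' @param probes An `MLPAProbeSet`.
#' @return A data.frame of class `MLPAResult` with columns `probe_id`,
#'   `chrom`, `pos`, `target`, `relative_cn` (controls get `NA`).
#' @export
normalize_mlpa <- function(tumor_signals, normal_signals, probes) {
  stopifnot(inherits(probes, "MLPAProbeSet"))
  ids <- probes$probe_id
  if (!all(ids %in% names(tumor_signals)) ||
      !all(ids %in% names(normal_signals)))
    stop("missing probe signal in tumor or normal sample")
  tu <- tumor_signals[ids]; no <- normal_signals[ids]
  ctrl <- probes$is_control
  if (any(tu[ctrl] <= 0) || any(no[ctrl] <= 0))
    stop("nonpositive control-probe signal")
  nt <- tu / geomean(tu[ctrl])
  nn <- no / geomean(no[ctrl])
  cn <- 2 * nt / nn
  cn[ctrl] <- NA_real_
  res <- data.frame(probe_id = ids, chrom = probes$chrom, pos = probes$pos,
                    target = probes$target, relative_cn = unname(cn),
                    stringsAsFactors = FALSE)
  class(res) <- c("MLPAResult", class(res))
  res
}

#' Call copy-number state from relative copy number
#'
#' @param result An `MLPAResult` (or numeric vector of relative copy
#'   numbers).
#' @param loss_threshold Relative CN at or below which a probe is a loss
#'   (default 1.6).
#' @param gain_threshold Relative CN at or above which a probe is a gain
#'   (default 2.4). Must satisfy `loss_threshold < 2 < gain_threshold`.
#' @return For an `MLPAResult`, the data.frame with a `call` column
#'   (`loss`/`neutral`/`gain`, `NA` for controls); for a numeric vector, a
#'   character vector of calls.
#' @export
call_cna <- function(result, loss_threshold = 1.6, gain_threshold = 2.4) {
  if (!(loss_threshold < 2 && 2 < gain_threshold))
    stop("thresholds must satisfy loss < 2 < gain")
  cn <- if (is.data.frame(result)) result$relative_cn else result
  call <- ifelse(is.na(cn), NA_character_,
          ifelse(cn <= loss_threshold, "loss",
          ifelse(cn >= gain_threshold, "gain", "neutral")))
  if (is.data.frame(result)) { result$call <- call; result } else call
}
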