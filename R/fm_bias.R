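# Functional-mutation-bias driver test.
#
# Per gene-region, the observed statistic is the arithmetic mean functional
# score of its mutations ("amean"); the null resamples the same number of
# mutations from the region's scoreable position-allele pairs without
# replacement, with probability proportional to the cohort-wide probability
# of each pair's trinucleotide channel (the "signature/complement" idea:
# channel frequencies are collapsed to the pyrimidine reference, counting
# both strands). Indels enter the observed statistic through a max over
# `max_consecutive` positions; double substitutions through a max over
# their two positions. Empirical p-values use a +1 pseudocount and the
# inclusive tie rule (null >= observed); q-values are Benjamini-Hochberg
# within each region class (CDS, 5'UTR, 3'UTR, intron tested separately).
# This is a deliberately simplified reimplementation of the FM-bias
# analysis mode of OncodriveFML-style tools, not a clone.

#' FM-bias test parameters
#'
#' @param n_iterations Null resampling iterations (default 1000; >= 100).
#' @param max_consecutive Window (nt) for the indel max method (default 7).
#' @param seed Optional integer; when set, the RNG is seeded once at the
#'   start of [fm_bias_test()] / [null_distribution()].
#' @param q_significant,q_highly q-value thresholds for the `significant`
#'   (default 0.025) and `highly_significant` (default 0.01) tiers.
#' @return A list of class `FMBiasParams`.
#' @export
fm_bias_params <- function(n_iterations = 1000L, max_consecutive = 7L,
                           seed = NULL, q_significant = 0.025,
                           q_highly = 0.01) {
  stopifnot(n_iterations >= 100L, max_consecutive >= 1L)
  structure(list(n_iterations = as.integer(n_iterations),
                 max_consecutive = as.integer(max_consecutive),
                 seed = seed, q_significant = q_significant,
                 q_highly = q_highly),
            class = "FMBiasParams")
}

#' Read / write a functional score track
#'
#' TSV with columns `chrom`, `pos`, `alt`, `score`: one nonnegative
#' functional score per position and alternate allele (a generic stand-in
#' for CADD-like per-variant scores).
#'
#' @param path File path.
#' @return For the reader, a data.frame score track.
#' @export
read_score_track <- function(path) {
  df <- as.data.frame(data.table::fread(path, sep = "\t"))
  stopifnot(all(c("chrom", "pos", "alt", "score") %in% names(df)))
  if (any(!is.finite(df$score)) || any(df$score < 0))
    stop("scores must be finite and nonnegative")
  df
}

#' @rdname read_score_track
#' @param track A score-track data.frame.
#' @export
write_score_track <- function(track, path) {
  data.table::fwrite(track[, c("chrom", "pos", "alt", "score")], path,
                     sep = "\t")
  invisible(path)
}

#' Cohort mutation-channel frequencies
#'
#' Relative frequencies of the 96 pyrimidine-normalized substitution
#' channels over all cohort SNVs; used as resampling weights for the
#' FM-bias null.
#'
#' @param records Annotated cohort mutation records.
#' @return Numeric 96-vector summing to 1.
#' @export
cohort_context_probs <- function(records) {
  snv <- records[records$mtype == "SNV", , drop = FALSE]
  if (!nrow(snv) || anyNA(snv$context_index))
    stop("need annotated SNVs to estimate channel frequencies")
  counts <- tabulate(snv$context_index, nbins = 96L)
  setNames(counts / sum(counts), trinucleotide_contexts())
}

# numeric (chrom, pos, alt) keys: exact to 2^53, far beyond any contig
pair_key <- function(chrom_idx, pos, alt_code = 0) {
  (chrom_idx * 1e9 + pos) * 8 + alt_code
}

# per-record observed score contribution, given numeric lookup tables
obs_contribution <- function(records, chrom_levels, exact_key, exact_score,
                             track_poskey, params) {
  n <- nrow(records)
  out <- rep(NA_real_, n)
  rci <- match(records$chrom, chrom_levels)
  snv <- records$mtype == "SNV"
  if (any(snv)) {
    m <- match(pair_key(rci[snv], records$pos[snv],
                        match(records$alt[snv], DNA_BASES)), exact_key)
    if (anyNA(m)) stop("score gap: mutation at unscored position")
    out[snv] <- exact_score[m]
  }
  oth <- which(!snv)
  if (length(oth)) {
    wlen <- ifelse(records$mtype[oth] == "DBS", 2L, params$max_consecutive)
    rid <- rep.int(oth, wlen)
    wpos <- records$pos[rid] + (sequence(wlen) - 1L)
    wkey <- pair_key(rci[rid], wpos)
    # position-level max score, computed only over the needed windows
    tsel <- which(track_poskey %in% unique(wkey))
    pm <- tapply(exact_score[tsel], track_poskey[tsel], max)
    v <- as.numeric(pm)[match(wkey, as.numeric(names(pm)))]
    mx <- tapply(v, rid, function(x) if (all(is.na(x))) NA_real_
                 else max(x, na.rm = TRUE))
    got <- as.numeric(mx)[match(oth, as.integer(names(mx)))]
    if (anyNA(got)) stop("score gap: mutation at unscored position")
    out[oth] <- got
  }
  out
}

#' Observed FM-bias statistic of a gene region
#'
#' Arithmetic mean over the region's mutations of: the score at
#' (position, alt) for an SNV; the max of its two positions' scores for a
#' double substitution; the max score over `max_consecutive` positions
#' starting at the indel position for an indel.
#'
#' @param mutations Mutation records of one gene region (>= 1 row).
#' @param track Score track data.frame.
#' @param params An [fm_bias_params()] object.
#' @return The observed mean score (scalar).
#' @export
observed_statistic <- function(mutations, track,
                               params = fm_bias_params()) {
  stopifnot(nrow(mutations) >= 1L)
  chrom_levels <- unique(c(track$chrom, mutations$chrom))
  tci <- match(track$chrom, chrom_levels)
  exact_key <- pair_key(tci, track$pos, match(track$alt, DNA_BASES))
  poskey <- pair_key(tci, track$pos)
  mean(obs_contribution(mutations, chrom_levels, exact_key, track$score,
                        poskey, params))
}

#' Null distribution of the region mean score
#'
#' Draws `n_iterations` samples of `n_mut` position-allele pairs without
#' replacement, with probability proportional to `weights` (pairs with zero
#' weight are unsampleable), and returns the arithmetic mean score of each
#' draw. Sampling is successive weighted sampling (the law of R's
#' `sample(prob = )` without replacement), implemented over a Fenwick tree
#' in compiled code; reproducible under `params$seed`.
#'
#' @param scores Numeric vector of pair scores.
#' @param weights Nonnegative sampling weights (channel probabilities of
#'   each pair's trinucleotide change).
#' @param n_mut Number of pairs per draw.
#' @param params An [fm_bias_params()] object.
#' @return Numeric vector of length `n_iterations`.
#' @export
null_distribution <- function(scores, weights, n_mut,
                              params = fm_bias_params()) {
  stopifnot(length(scores) == length(weights))
  if (all(weights <= 0)) stop("all channel probabilities zero within region")
  if (!is.null(params$seed)) set.seed(params$seed)
  ppswor_null_means(as.numeric(weights), as.numeric(scores),
                    as.integer(n_mut), params$n_iterations)
}

# channel weight of every track pair under cohort channel frequencies;
# integer-code path over the whole genome at once
track_pair_weights <- function(track, reference, context_probs) {
  codes <- genome_codes(reference)
  w <- rep(0, nrow(track))
  altc <- match(track$alt, DNA_BASES)
  for (ch in unique(track$chrom)) {
    sel <- which(track$chrom == ch)
    cd <- codes[[ch]]
    p <- track$pos[sel]
    idx <- context_index_codes(cd[p], altc[sel], cd[p - 1L], cd[p + 1L])
    ok <- !is.na(idx)
    w[sel[ok]] <- context_probs[idx[ok]]
  }
  w
}

#' Functional-mutation-bias driver test across gene regions
#'
#' Tests every gene region (CDS including splice sites, 5'UTR, 3'UTR,
#' intron windows) that carries at least one mutation. Per region,
#' `p = (1 + #\{null >= observed\}) / (1 + n_iterations)`; q-values are
#' Benjamini-Hochberg within each region class; tiers follow the q
#' thresholds (`significant`, `highly_significant`).
#'
#' @param records Annotated cohort mutation records.
#' @param models A `GeneModelSet`.
#' @param reference A named `DNAStringSet`.
#' @param track Score track data.frame (see [read_score_track()]).
#' @param params An [fm_bias_params()] object.
#' @param context_probs Optional 96-vector of channel probabilities;
#'   defaults to [cohort_context_probs()] of `records`.
#' @param annot_params [annotation_params()] used for region footprints.
#' @return data.frame with columns `gene_id`, `region`, `n_mutations`,
#'   `observed_mean`, `p_value`, `q_value`, `tier`.
#' @export
fm_bias_test <- function(records, models, reference, track,
                         params = fm_bias_params(), context_probs = NULL,
                         annot_params = annotation_params()) {
  if (is.null(context_probs)) context_probs <- cohort_context_probs(records)
  if (!is.null(params$seed)) set.seed(params$seed)
  idx <- annotation_index(models, reference, annot_params)

  track_region <- idx_lookup(idx, track$chrom, track$pos, "region")
  track_gene <- idx_lookup(idx, track$chrom, track$pos, "gene")
  w <- track_pair_weights(track, reference, context_probs)

  chrom_levels <- names(reference)
  tci <- match(track$chrom, chrom_levels)
  exact_key <- pair_key(tci, track$pos, match(track$alt, DNA_BASES))
  poskey <- pair_key(tci, track$pos)

  rec_region <- as.character(records$region)
  class_of_rec <- ifelse(rec_region %in% c("CODING", "SPLICE_SITE"), "CODING",
                         rec_region)
  class_track_code <- c(CODING = 1L, UTR5 = 3L, UTR3 = 4L, INTRON = 5L)
  # observed score contributions, only for records entering some test
  rel <- which(class_of_rec %in% names(class_track_code) &
                 !is.na(records$gene_id))
  contrib <- rep(NA_real_, nrow(records))
  contrib[rel] <- obs_contribution(records[rel, , drop = FALSE],
                                   chrom_levels, exact_key, track$score,
                                   poskey, params)

  rows <- list()
  for (cls in names(class_track_code)) {
    rsel <- which(class_of_rec == cls & !is.na(records$gene_id))
    if (!length(rsel)) next
    tsel <- which(track_region == class_track_code[[cls]] & track_gene > 0L)
    t_gene <- idx$gene_ids[track_gene[tsel]]
    t_split <- split(tsel, t_gene)
    r_split <- split(rsel, records$gene_id[rsel])
    genes <- names(r_split)
    res <- vector("list", length(genes))
    for (gi in seq_along(genes)) {
      g <- genes[gi]
      ri <- r_split[[g]]
      ti <- t_split[[g]]
      k <- length(ri)
      obs <- mean(contrib[ri])
      if (is.null(ti) || sum(w[ti] > 0) < k) {
        warning("region ", g, "/", cls,
                " has fewer scoreable pairs than mutations; skipped")
        next
      }
      nulls <- ppswor_null_means(w[ti], track$score[ti], k,
                                 params$n_iterations)
      p <- (1 + sum(nulls >= obs)) / (1 + params$n_iterations)
      res[[gi]] <- data.frame(gene_id = g, region = cls, n_mutations = k,
                              observed_mean = obs, p_value = p,
                              stringsAsFactors = FALSE)
    }
    res <- do.call(rbind, res)
    if (is.null(res)) next
    res$q_value <- p.adjust(res$p_value, method = "BH")
    rows[[cls]] <- res
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(gene_id = character(), region = character(),
                      n_mutations = integer(), observed_mean = numeric(),
                      p_value = numeric(), q_value = numeric(),
                      tier = character(), stringsAsFactors = FALSE))
  out$tier <- ifelse(out$q_value < params$q_highly, "highly_significant",
                     ifelse(out$q_value < params$q_significant,
                            "significant", "none"))
  out <- out[order(out$region, out$p_value, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Null calibration of the FM-bias empirical p-value
#'
#' Builds synthetic regions with i.i.d. scores and draws the "observed"
#' mutation set by the same weighted without-replacement law the null uses
#' (via R's `sample(prob = )`, an implementation independent of the
#' compiled null sampler), then computes the empirical p-value per region.
#' Under this matched-law construction p-values are uniform up to the
#' 1/(n_iterations+1) discretization, which a Kolmogorov-Smirnov test can
#' check.
#'
#' @param n_regions Number of regions (default 200).
#' @param region_size Scoreable pairs per region (default 180).
#' @param mean_mutations Poisson mean of mutations per region (default 5,
#'   shifted by 1 so every region has at least one).
#' @param params An [fm_bias_params()] object.
#' @param seed Integer seed.
#' @return data.frame with one row per region: `n_mutations`, `p_value`.
#' @export
fm_null_calibration <- function(n_regions = 200L, region_size = 180L,
                                mean_mutations = 5, params = fm_bias_params(),
                                seed = 1L) {
  set.seed(seed)
  sig <- uv_signature_matrix()
  probs <- as.numeric(0.7 * sig["UV", ] + 0.2 * sig["ALK", ] +
                        0.1 * sig["FLAT", ])
  p_out <- numeric(n_regions)
  k_out <- integer(n_regions)
  for (r in seq_len(n_regions)) {
    channel <- sample.int(96L, region_size, replace = TRUE)
    wts <- probs[channel] + 1e-9      # keep every pair sampleable
    scores <- rgamma(region_size, shape = 2, scale = 2)
    k <- rpois(1, mean_mutations - 1) + 1L
    obs <- mean(scores[sample.int(region_size, k, prob = wts)])
    nulls <- ppswor_null_means(wts, scores, k, params$n_iterations)
    p_out[r] <- (1 + sum(nulls >= obs)) / (1 + params$n_iterations)
    k_out[r] <- k
  }
  data.frame(n_mutations = k_out, p_value = p_out)
}
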