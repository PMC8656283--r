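# Per-sample 96-context mutation profiles and refitting of predefined
# mutational signatures. The contribution of each signature (SC) is the
# nonnegative least-squares coefficient of the frequency-normalized profile
# on the signature rows, renormalized to sum to one; the fit is
# deterministic for fixed input.

#' Build a 96-context profile for one sample
#'
#' Counts single-base substitutions per pyrimidine-normalized trinucleotide
#' channel; double substitutions and indels are excluded.
#'
#' @param records Mutation records of one sample with `context_index`
#'   populated for SNVs (see [annotate_mutations()]).
#' @param sample_id Optional identifier stored on the result; defaults to
#'   the records' (unique) `sample_id`.
#' @return A list of class `SampleProfile` with fields `sample_id`,
#'   `counts` (integer 96-vector named by context label) and `total`.
#' @export
build_96_profile <- function(records, sample_id = NULL) {
  if (is.null(sample_id)) {
    sample_id <- unique(records$sample_id)
    if (length(sample_id) != 1L) sample_id <- NA_character_
  }
  snv <- records[records$mtype == "SNV", , drop = FALSE]
  if (nrow(snv) && anyNA(snv$context_index))
    stop("SNV records lack context_index; annotate first")
  counts <- tabulate(snv$context_index, nbins = 96L)
  names(counts) <- trinucleotide_contexts()
  structure(list(sample_id = sample_id, counts = counts,
                 total = sum(counts)),
            class = "SampleProfile")
}

#' @export
print.SampleProfile <- function(x, ...) {
  cat("SampleProfile", x$sample_id, "-", x$total, "SNVs\n")
  invisible(x)
}

#' Validate / construct a signature matrix
#'
#' A signature matrix has one row per signature and 96 columns in the order
#' of [trinucleotide_contexts()]; every row is a probability distribution.
#'
#' @param mat Numeric matrix (signatures x 96), rownames = signature labels.
#' @return The matrix, validated, with class `SignatureMatrix` attribute.
#' @export
signature_matrix <- function(mat) {
  stopifnot(is.matrix(mat), ncol(mat) == 96L, all(mat >= 0))
  if (any(abs(rowSums(mat) - 1) > 1e-6))
    stop("signature rows must sum to 1")
  if (is.null(rownames(mat)))
    rownames(mat) <- paste0("SIG", seq_len(nrow(mat)))
  colnames(mat) <- trinucleotide_contexts()
  class(mat) <- c("SignatureMatrix", class(mat))
  mat
}

#' Fixture signature matrix: UV-like, alkylation-like and flat rows
#'
#' A small built-in signature set for simulation and tests. The UV-like row
#' concentrates on C>T at dipyrimidine sites (pyrimidine 5' neighbor, the
#' hallmark context of UV-induced cyclobutane dimers, patterned on the
#' COSMIC signature-7 description); the alkylation-like row puts C>T mass at
#' purine-5' contexts (patterned on the signature-11 description, disjoint
#' in context from the UV row so mixtures are identifiable); the flat row is
#' uniform over all 96 channels. Real signature matrices are accepted as TSV
#' input ([read_signature_matrix()]) but never required.
#'
#' @return A `SignatureMatrix` with rows `UV`, `ALK`, `FLAT`.
#' @export
uv_signature_matrix <- function() {
  labs <- trinucleotide_contexts()
  up <- substr(labs, 1L, 1L)
  cls <- substr(labs, 3L, 5L)
  uv <- numeric(96)
  sel_uv <- cls == "C>T" & up %in% c("C", "T")
  uv[sel_uv] <- ifelse(up[sel_uv] == "T", 2, 1)   # TpC > CpC weighting
  alk <- numeric(96)
  sel_alk <- cls == "C>T" & up %in% c("A", "G")
  alk[sel_alk] <- 1
  flat <- rep(1, 96)
  m <- rbind(UV = uv / sum(uv), ALK = alk / sum(alk), FLAT = flat / 96)
  signature_matrix(m)
}

#' Read / write signature matrices as TSV
#'
#' The TSV has a first column of context labels (e.g. `A[C>T]G`) and one
#' column per signature, the transposed layout COSMIC distributes.
#'
#' @param path File path.
#' @return For the reader, a `SignatureMatrix`.
#' @export
read_signature_matrix <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  labs <- df[[1]]
  m <- t(as.matrix(df[, -1, drop = FALSE]))
  ord <- match(trinucleotide_contexts(), labs)
  if (anyNA(ord)) stop("signature TSV lacks some context labels")
  signature_matrix(m[, ord, drop = FALSE])
}

#' @rdname read_signature_matrix
#' @param mat A `SignatureMatrix`.
#' @export
write_signature_matrix <- function(mat, path) {
  df <- data.frame(context = trinucleotide_contexts(),
                   t(unclass(mat)[, , drop = FALSE]),
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Fit signature contributions to a sample profile
#'
#' Solves nonnegative least squares of the frequency-normalized profile
#' against the signature rows and renormalizes the coefficients to sum to
#' one; these are the per-sample signature contributions (SC). Samples with
#' fewer than `min_mutations` substitutions are excluded (returns `NULL`),
#' mirroring the exclusion of low-burden samples from signature analysis.
#'
#' @param profile A `SampleProfile` (or bare numeric 96-vector of counts).
#' @param signatures A `SignatureMatrix`.
#' @param min_mutations Minimum substitution count (default 30).
#' @return A list of class `SignatureFit` with `sample_id`, `contributions`
#'   (named, sums to 1), `reconstruction_error` (cosine distance between the
#'   observed and reconstructed profile), `n_mutations`; or `NULL` when the
#'   sample is excluded.
#' @export
fit_signatures <- function(profile, signatures, min_mutations = 30L) {
  if (is.numeric(profile))
    profile <- structure(list(sample_id = NA_character_,
                              counts = profile, total = sum(profile)),
                         class = "SampleProfile")
  stopifnot(inherits(profile, "SampleProfile"))
  if (nrow(signatures) == 0L) stop("signature matrix has zero rows")
  if (profile$total < min_mutations) return(NULL)
  y <- profile$counts / profile$total
  A <- t(unclass(signatures))               # 96 x S
  fit <- pracma::lsqnonneg(A, y)
  x <- fit$x
  if (sum(x) <= 0) stop("degenerate fit: all contributions zero")
  contributions <- setNames(x / sum(x), rownames(signatures))
  recon <- as.numeric(A %*% x)
  cosd <- 1 - sum(recon * y) / sqrt(sum(recon^2) * sum(y^2))
  structure(list(sample_id = profile$sample_id,
                 contributions = contributions,
                 reconstruction_error = cosd,
                 n_mutations = profile$total),
            class = "SignatureFit")
}

#' @export
print.SignatureFit <- function(x, ...) {
  cat("SignatureFit", x$sample_id, "(", x$n_mutations, "SNVs ):",
      paste(sprintf("%s=%.3f", names(x$contributions), x$contributions),
            collapse = " "),
      sprintf("[cos dist %.4f]\n", x$reconstruction_error))
  invisible(x)
}

#' Fit signatures across a cohort
#'
#' @param records Annotated cohort mutation records.
#' @param signatures A `SignatureMatrix`.
#' @param min_mutations Exclusion threshold passed to [fit_signatures()].
#' @return A list with `fits` (long data.frame: sample, signature, sc,
#'   n_mutations, reconstruction_error), `excluded` (character vector of
#'   excluded sample ids) and `profiles` (matrix samples x 96).
#' @export
fit_cohort_signatures <- function(records, signatures = uv_signature_matrix(),
                                  min_mutations = 30L) {
  samples <- sort(unique(records$sample_id))
  prof <- matrix(0L, nrow = length(samples), ncol = 96L,
                 dimnames = list(samples, trinucleotide_contexts()))
  rows <- list(); excluded <- character(0)
  for (s in samples) {
    p <- build_96_profile(records[records$sample_id == s, , drop = FALSE],
                          sample_id = s)
    prof[s, ] <- p$counts
    f <- fit_signatures(p, signatures, min_mutations)
    if (is.null(f)) { excluded <- c(excluded, s); next }
    rows[[s]] <- data.frame(sample = s,
                            signature = names(f$contributions),
                            sc = unname(f$contributions),
                            n_mutations = f$n_mutations,
                            reconstruction_error = f$reconstruction_error,
                            stringsAsFactors = FALSE)
  }
  if (length(excluded))
    message("excluded from signature analysis (fewer than ", min_mutations,
            " mutations): ", paste(excluded, collapse = ", "))
  list(fits = if (length(rows)) do.call(rbind, c(rows, make.row.names = FALSE))
       else data.frame(sample = character(), signature = character(),
                       sc = numeric(), n_mutations = integer(),
                       reconstruction_error = numeric()),
       excluded = excluded, profiles = prof)
}
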