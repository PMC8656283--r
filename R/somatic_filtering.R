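# Somatic-call retention criteria and site-list flagging.
#
# A call is retained iff (i) it has at least `min_tumor_alt` alternate-
# supporting reads in the tumor, (ii) the tumor alternate-allele fraction is
# at least `min_tumor_af`, and (iii) the tumor allele fraction is at least
# `min_tn_ratio` times the normal allele fraction. All thresholds are
# inclusive. Zero normal allele fraction (including an uncovered normal)
# satisfies the ratio criterion: absence of normal support is the strongest
# somatic evidence and the ratio rule targets contamination.

#' Somatic filter parameters
#'
#' @param min_tumor_alt Minimum tumor alternate-supporting reads (default 5).
#' @param min_tumor_af Minimum tumor alternate-allele fraction (default 0.05).
#' @param min_tn_ratio Minimum tumor/normal allele-fraction ratio (default 5).
#' @return A list of class `FilterParams`.
#' @export
filter_params <- function(min_tumor_alt = 5L, min_tumor_af = 0.05,
                          min_tn_ratio = 5.0) {
  stopifnot(min_tumor_alt >= 0, min_tumor_af >= 0, min_tumor_af <= 1,
            min_tn_ratio >= 1)
  structure(list(min_tumor_alt = as.integer(min_tumor_alt),
                 min_tumor_af = min_tumor_af,
                 min_tn_ratio = min_tn_ratio),
            class = "FilterParams")
}

#' Apply the somatic retention criteria
#'
#' Partitions calls into those passing all three retention criteria and
#' those rejected; each rejected call carries the first failing criterion in
#' the fixed order `low_support`, `low_af`, `low_ratio` so reason codes are
#' deterministic. Calls carrying any flag (germline / panel-of-normals, see
#' [flag_sites()]) must be excluded by the caller before counting; this
#' function filters purely on read support.
#'
#' @param calls Somatic call data.frame (see [load_somatic_calls()]).
#' @param params A [filter_params()] object.
#' @return A list with elements `passed` (data.frame) and `rejected`
#'   (data.frame with an additional `reason` column).
#' @export
apply_somatic_filters <- function(calls, params = filter_params()) {
  stopifnot(inherits(params, "FilterParams"))
  if (any(calls$tumor_depth == 0L)) stop("uncovered site: tumor_depth = 0")
  tumor_af <- calls$tumor_alt / calls$tumor_depth
  normal_af <- ifelse(calls$normal_depth == 0L, 0,
                      calls$normal_alt / calls$normal_depth)
  ok_support <- calls$tumor_alt >= params$min_tumor_alt
  ok_af <- tumor_af >= params$min_tumor_af
  ok_ratio <- normal_af == 0 | tumor_af / normal_af >= params$min_tn_ratio
  pass <- ok_support & ok_af & ok_ratio
  reason <- rep(NA_character_, nrow(calls))
  reason[!ok_ratio] <- "low_ratio"
  reason[!ok_af] <- "low_af"
  reason[!ok_support] <- "low_support"   # first failing criterion wins
  passed <- calls[pass, , drop = FALSE]
  passed$tumor_af <- tumor_af[pass]
  rejected <- calls[!pass, , drop = FALSE]
  rejected$reason <- reason[!pass]
  list(passed = passed, rejected = rejected)
}

#' Flag calls matching a site list
#'
#' Adds `flag_name` to the `flags` field of every call whose
#' (chrom, pos, ref, alt) key is in `sites`. Flagged calls are meant to be
#' excluded from all downstream counting (the pipeline drops them after
#' flagging); the number of newly flagged calls is reported via `message()`.
#'
#' @param calls Somatic call data.frame.
#' @param sites data.frame with columns `chrom`, `pos`, `ref`, `alt`
#'   (see [read_site_list()]).
#' @param flag_name Label to add (e.g. `"germline"`, `"pon"`).
#' @return The calls with updated `flags`.
#' @export
flag_sites <- function(calls, sites, flag_name) {
  stopifnot(is.character(flag_name), length(flag_name) == 1L)
  if (is.null(sites) || nrow(sites) == 0L) return(calls)
  key <- paste(calls$chrom, calls$pos, calls$ref, calls$alt, sep = ":")
  skey <- paste(sites$chrom, sites$pos, sites$ref, sites$alt, sep = ":")
  hit <- key %in% skey
  message(sum(hit), " call(s) flagged ", flag_name)
  calls$flags[hit] <- ifelse(nzchar(calls$flags[hit]),
                             paste(calls$flags[hit], flag_name, sep = ","),
                             flag_name)
  calls
}

# drop calls carrying any flag; used by the pipeline after flag_sites()
drop_flagged <- function(calls) {
  calls[!nzchar(calls$flags), , drop = FALSE]
}
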