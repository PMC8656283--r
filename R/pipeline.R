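# End-to-end pipeline orchestration: simulate (or load) inputs, flag and
# filter calls, merge double substitutions, annotate, fit signatures,
# summarize, find hotspots and recurrent genes, run the FM-bias driver
# test, compute MLPA copy number, and write a manifest with checksums.
# All stage logging goes to stderr via message(); data goes to files only.
# A rerun with the same inputs and seed reproduces byte-identical outputs.

#' Run the full analysis pipeline on synthetic or file inputs
#'
#' In `simulate = TRUE` mode (the default) the generator writes a complete
#' input set under `out_dir/inputs/` (FASTA reference, GTF gene models,
#' per-sample tumor/normal VCFs, score track, signature matrix, germline
#' and panel-of-normals site lists, MLPA signal tables, truth tables) and
#' the pipeline then runs from those files through the same readers a real
#' dataset would use. With `simulate = FALSE`, paths to the same file kinds
#' must be supplied via `inputs`.
#'
#' Stage order: flag -> filter -> merge -> annotate -> signatures ->
#' summarize -> hotspots -> recurrent genes -> FM-bias -> MLPA. Results are
#' written under `out_dir/results/`, and a `manifest.tsv` lists every
#' output with its MD5 checksum and the seed.
#'
#' @param out_dir Output directory (created).
#' @param seed Integer master seed; all stage seeds derive from it.
#' @param sim_config A [simulation_config()]; defaults to
#'   `simulation_config(seed = seed)`.
#' @param simulate Generate inputs (default) or read them from `inputs`.
#' @param inputs For `simulate = FALSE`: list with `fasta`, `gtf`,
#'   `vcfs` (named character vector), `score_track`, `signatures`,
#'   `germline_sites`, `pon_sites`, and optionally `mlpa_tumor`,
#'   `mlpa_normal`, `mlpa_probes` (TSV paths).
#' @param filter,annot,recur,fm Parameter objects ([filter_params()],
#'   [annotation_params()], [recurrence_params()], [fm_bias_params()]).
#' @param min_mutations Signature-analysis exclusion threshold.
#' @param coding_territory_mbp Burden denominator; default: total canonical
#'   CDS territory of the gene models.
#' @param run_mlpa Whether to run the MLPA stage (default TRUE).
#' @return (Invisibly) a list with the in-memory stage results and
#'   `manifest` (data.frame of output files and checksums).
#' @export
run_pipeline <- function(out_dir, seed = 1L,
                         sim_config = simulation_config(seed = seed),
                         simulate = TRUE, inputs = NULL,
                         filter = filter_params(),
                         annot = NULL,
                         recur = recurrence_params(),
                         fm = NULL,
                         min_mutations = 30L,
                         coding_territory_mbp = NULL,
                         run_mlpa = TRUE) {
  t0 <- Sys.time()
  res_dir <- file.path(out_dir, "results")
  dir.create(res_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(annot))
    annot <- annotation_params(
      intron_prox_window = if (simulate) sim_config$intron_prox_window else 100L)
  if (is.null(fm)) fm <- fm_bias_params(seed = seed + 606L)

  if (simulate) {
    in_dir <- file.path(out_dir, "inputs")
    truth_dir <- file.path(in_dir, "truth")
    dir.create(truth_dir, showWarnings = FALSE, recursive = TRUE)
    message("stage simulate: generating genome and cohort (seed ", seed, ")")
    gen <- generate_genome(sim_config)
    sim <- simulate_cohort(sim_config, gen$reference, gen$models)
    track0 <- simulate_score_track(sim_config, gen$models, gen$reference)
    fasta <- file.path(in_dir, "reference.fa")
    Biostrings::writeXStringSet(gen$reference, fasta)
    gtf <- file.path(in_dir, "genes.gtf")
    write_gtf(gen$models, gtf)
    vcfs <- write_cohort_vcfs(sim$calls, file.path(in_dir, "vcf"),
                              gen$reference)
    st_path <- file.path(in_dir, "score_track.tsv")
    write_score_track(track0, st_path)
    sig_path <- file.path(in_dir, "signatures.tsv")
    write_signature_matrix(uv_signature_matrix(), sig_path)
    germ_path <- file.path(in_dir, "germline_sites.tsv")
    write.table(sim$truth$germline_sites, germ_path, sep = "\t",
                quote = FALSE, row.names = FALSE)
    pon_path <- file.path(in_dir, "pon_sites.tsv")
    write.table(sim$truth$pon_sites, pon_path, sep = "\t",
                quote = FALSE, row.names = FALSE)
    mlpa_sim <- if (run_mlpa) simulate_mlpa(sim_config) else NULL
    for (nm in c("signatures", "hotspots", "drivers", "artifacts",
                 "type_counts")) {
      obj <- sim$truth[[nm]]
      if (!is.null(obj))
        write.table(obj, file.path(truth_dir, paste0(nm, ".tsv")),
                    sep = "\t", quote = FALSE, row.names = FALSE)
    }
    if (!is.null(mlpa_sim))
      write.table(mlpa_sim$truth, file.path(truth_dir, "mlpa_cna.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    inputs <- list(fasta = fasta, gtf = gtf, vcfs = vcfs,
                   score_track = st_path, signatures = sig_path,
                   germline_sites = germ_path, pon_sites = pon_path)
  } else if (is.null(inputs)) {
    stop("simulate = FALSE requires an 'inputs' list")
  }
  for (nm in c("fasta", "gtf", "vcfs", "signatures", "germline_sites",
               "pon_sites")) {
    if (is.null(inputs[[nm]]) || !all(file.exists(inputs[[nm]])))
      stop("stage load: missing input '", nm, "'")
  }
  if (is.null(inputs$score_track) || !file.exists(inputs$score_track))
    stop("stage drivers: score track not found")

  message("stage load: reading reference, gene models and ",
          length(inputs$vcfs), " VCF(s)")
  reference <- Biostrings::readDNAStringSet(inputs$fasta)
  names(reference) <- sub("\\s.*$", "", names(reference))
  models <- load_gene_models(inputs$gtf)
  cohort <- load_cohort(inputs$vcfs, reference, models)
  calls <- cohort$calls

  message("stage flag: germline and panel-of-normals site lists")
  calls <- flag_sites(calls, read_site_list(inputs$germline_sites), "germline")
  calls <- flag_sites(calls, read_site_list(inputs$pon_sites), "pon")
  n_flagged <- sum(nzchar(calls$flags))
  calls <- drop_flagged(calls)

  message("stage filter: somatic retention criteria")
  flt <- apply_somatic_filters(calls, filter)
  message("  ", nrow(flt$passed), " passed, ", nrow(flt$rejected),
          " rejected, ", n_flagged, " flagged")

  message("stage merge: adjacent substitutions")
  records <- merge_adjacent_snvs(flt$passed)

  message("stage annotate: regions, effects, HGVS, contexts")
  records <- annotate_mutations(records, models, reference, annot)
  write_mutation_table(records, file.path(res_dir, "mutations.tsv"))

  message("stage signatures: 96-context profiles and refitting")
  sig_mat <- read_signature_matrix(inputs$signatures)
  sig_fit <- fit_cohort_signatures(records, sig_mat, min_mutations)
  write.table(data.frame(sample = rownames(sig_fit$profiles),
                         sig_fit$profiles, check.names = FALSE),
              file.path(res_dir, "profiles_96.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(sig_fit$fits, file.path(res_dir, "signature_contributions.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  message("stage summarize: cohort summary and burden")
  if (is.null(coding_territory_mbp)) {
    canon <- models$transcripts$transcript_id[models$transcripts$canonical &
                                                models$transcripts$cds_ok]
    cds_c <- models$cds[mcols(models$cds)$transcript_id %in% canon]
    coding_territory_mbp <- sum(width(reduce(cds_c))) / 1e6
  }
  summ <- summarize_cohort(records, coding_territory_mbp)
  write.table(summ$table, file.path(res_dir, "cohort_summary.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(summ$burden, file.path(res_dir, "sample_burden.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  message("stage hotspots")
  hs <- find_hotspots(records, recur)
  write_hotspots(hs, file.path(res_dir, "hotspots.bed"),
                 file.path(res_dir, "hotspots.tsv"))

  message("stage recurrent genes")
  fmg <- find_frequently_mutated_genes(records, recur)
  write.table(fmg, file.path(res_dir, "recurrent_genes.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  message("stage drivers: FM-bias test")
  track <- read_score_track(inputs$score_track)
  fmb <- fm_bias_test(records, models, reference, track, fm,
                      annot_params = annot)
  write.table(fmb, file.path(res_dir, "fm_bias.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  mlpa_res <- NULL
  if (run_mlpa) {
    message("stage mlpa: relative copy number")
    probes <- chr9_probe_set()
    if (simulate) {
      tum <- mlpa_sim$tumor; nor <- mlpa_sim$normal
    } else if (!is.null(inputs$mlpa_tumor)) {
      tum <- as.matrix(read.delim(inputs$mlpa_tumor, row.names = 1,
                                  check.names = FALSE))
      nor <- as.matrix(read.delim(inputs$mlpa_normal, row.names = 1,
                                  check.names = FALSE))
      if (!is.null(inputs$mlpa_probes))
        probes <- mlpa_probe_set(read.delim(inputs$mlpa_probes))
    } else {
      tum <- NULL
    }
    if (!is.null(tum)) {
      rows <- lapply(rownames(tum), function(s) {
        r <- call_cna(normalize_mlpa(tum[s, ], nor[s, ], probes))
        cbind(sample = s, r)
      })
      mlpa_res <- do.call(rbind, rows)
      mlpa_res$relative_cn <- round(mlpa_res$relative_cn, 4)
      write.table(mlpa_res, file.path(res_dir, "mlpa_copynumber.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }

  files <- sort(list.files(res_dir, full.names = TRUE))
  files <- files[basename(files) != "manifest.tsv"]
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)),
                         seed = seed, stringsAsFactors = FALSE)
  write.table(manifest, file.path(res_dir, "manifest.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  message(sprintf("pipeline finished in %.1f s; %d output files",
                  as.numeric(difftime(Sys.time(), t0, units = "secs")),
                  nrow(manifest)))
  invisible(list(records = records, filter = flt, signatures = sig_fit,
                 summary = summ, hotspots = hs, recurrent_genes = fmg,
                 fm_bias = fmb, mlpa = mlpa_res, manifest = manifest,
                 models = models, reference = reference,
                 coding_territory_mbp = coding_territory_mbp,
                 truth = if (simulate) sim$truth else NULL))
}
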