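.CONFIG_DEFAULTS <- list(
  # array simulation
  n_genes = 1000L, spots_per_gene = 2L, n_replicate_pairs = 3L,
  de_fraction = 0.1, true_log2fc_magnitude = 1, noise_sd = 0.3,
  dye_bias_coeffs = c(4, -0.8, 0.04), gene_dye_bias_sd = 0,
  background_mean = 100, background_sd = 30, bg_correlation = 0,
  saturation_level = 65535, flag_fraction = 0.02,
  # qc / normalization
  sb_min = 1.5, bg_correlation_threshold = 0.5, lowess_span = 2 / 3,
  replicate_unit = "slide",
  # selection
  fc_min = 1.5, q_max = 0.05, min_replicates = 2L,
  # qpcr simulation
  qpcr_genes = c("Hif1a", "Mgp", "Sat1"),
  qpcr_true_fc = c(0.5, 2, 0.75), ct_noise_sd = 0.2, qpcr_replicates = 3L,
  # promoter simulation / scan
  promoter_length = 5000L, planted_offset = -2177L, planted_strand = "+",
  planted_spacer = 2L, substitution_rate = 0.1,
  conservation_window = 100L, conservation_min_identity = 0.7,
  spacers = c(1L, 2L, 5L), max_mismatches = 0L,
  seed = 1L)

#' Validate a pipeline run configuration
#'
#' A flat named list of parameters; unknown keys are rejected, known keys
#' override the documented defaults.
#'
#' @param config named list of overrides (may be empty).
#' @return the fully-resolved configuration (class `run_config`).
#' @export
run_config <- function(config = list()) {
  if (inherits(config, "run_config")) return(config)
  stopifnot(is.list(config))
  unknown <- setdiff(names(config), names(.CONFIG_DEFAULTS))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  structure(modifyList(.CONFIG_DEFAULTS, config), class = "run_config")
}

#' Run the full pipeline on synthetic data
#'
#' Executes simulate -> write/read slides -> normalize -> differential
#' expression -> qPCR quantification -> promoter scan, writing every
#' artifact (slides, design, truth sidecars, ratio matrix, DE table, qPCR
#' results, scan report, resolved configuration, provenance log) under
#' `out_dir` and finishing with a `manifest.json` listing each file with an
#' MD5 digest.  Identical configuration and seed give identical digests.
#'
#' @param config a [run_config()] or a plain named list of overrides.
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with the in-memory results (`truth`,
#'   `ratio_matrix`, `de`, `qpcr`, `scan`, `manifest`).
#' @export
run_pipeline <- function(config = list(), out_dir) {
  cfg <- run_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- "configure"
  written <- character(0)
  emit <- function(writer, path) {
    writer(file.path(out_dir, path))
    written <<- c(written, path)
  }
  result <- tryCatch({
    jsonlite::write_json(unclass(cfg), file.path(out_dir, "config.json"),
                         auto_unbox = TRUE, digits = NA)
    written <- c(written, "config.json")

    stage <- "simulate"
    sim <- simulate_two_color_experiment(array_sim_params(
      n_genes = cfg$n_genes, spots_per_gene = cfg$spots_per_gene,
      n_replicate_pairs = cfg$n_replicate_pairs,
      de_fraction = cfg$de_fraction,
      true_log2fc_magnitude = cfg$true_log2fc_magnitude,
      noise_sd = cfg$noise_sd, dye_bias_coeffs = cfg$dye_bias_coeffs,
      gene_dye_bias_sd = cfg$gene_dye_bias_sd,
      background_mean = cfg$background_mean,
      background_sd = cfg$background_sd,
      bg_correlation = cfg$bg_correlation,
      saturation_level = cfg$saturation_level,
      flag_fraction = cfg$flag_fraction, seed = cfg$seed))
    for (sl in sim$slides)
      emit(function(f) write_gpr(sl, f), paste0(sl$slide_id, ".gpr"))
    emit(function(f) write_design(sim$design, f), "design.tsv")
    emit(function(f) write.table(sim$truth$de_genes, f, sep = "\t",
                                 quote = FALSE, row.names = FALSE),
         "truth_de_genes.tsv")

    stage <- "normalize"
    qc <- qc_params(saturation_level = cfg$saturation_level,
                    sb_min = cfg$sb_min,
                    bg_correlation_threshold = cfg$bg_correlation_threshold,
                    lowess_span = cfg$lowess_span)
    rm_ <- normalize_experiment(sim$slides, sim$design, qc,
                                replicate_unit = cfg$replicate_unit)
    emit(function(f) write_ratio_matrix(rm_, f), "ratio_matrix.tsv")

    stage <- "differential-expression"
    de <- select_de_genes(gene_statistics(rm_, cfg$min_replicates),
                          fc_min = cfg$fc_min, q_max = cfg$q_max)
    emit(function(f) write.table(de, f, sep = "\t", quote = FALSE,
                                 row.names = FALSE), "de_results.tsv")

    stage <- "qpcr"
    qsim <- simulate_qpcr_experiment(
      cfg$qpcr_genes, setNames(cfg$qpcr_true_fc, cfg$qpcr_genes),
      ct_noise_sd = cfg$ct_noise_sd, n_replicates = cfg$qpcr_replicates,
      seed = cfg$seed)
    emit(function(f) write.table(qsim$table, f, sep = "\t", quote = FALSE,
                                 row.names = FALSE), "ct_table.tsv")
    qres <- relative_quantity(qsim$table, calibrator = "control")
    emit(function(f) write.table(qres, f, sep = "\t", quote = FALSE,
                                 row.names = FALSE), "qpcr_results.tsv")

    stage <- "rare-scan"
    psim <- simulate_promoter_pair(
      length = cfg$promoter_length,
      planted = data.frame(offset = cfg$planted_offset,
                           strand = cfg$planted_strand,
                           spacer = cfg$planted_spacer),
      substitution_rate = cfg$substitution_rate, seed = cfg$seed)
    emit(function(f) write_promoter_pair(psim$pair, f), "promoters.fasta")
    scan <- scan_promoter_pair(
      psim$pair, motif_params(spacers = cfg$spacers,
                              max_mismatches = cfg$max_mismatches),
      window = cfg$conservation_window,
      min_identity = cfg$conservation_min_identity)
    emit(function(f) write_scan_report(scan, f), "rare_hits.tsv")
    if (file.exists(file.path(out_dir, "rare_hits.tsv.bed")))
      written <- c(written, "rare_hits.tsv.bed")

    stage <- "provenance"
    prov <- list(
      stages = c("simulate", "normalize", "differential-expression",
                 "qpcr", "rare-scan"),
      qc_counts = lapply(rm_$provenance, `[[`, "qc_counts"),
      background = lapply(rm_$provenance, `[[`, "background"),
      de_counts = as.list(attr(de, "counts")),
      n_hits = nrow(scan$hits), n_conserved = sum(scan$hits$conserved))
    jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    written <- c(written, "provenance.json")

    manifest <- data.frame(
      file = written,
      md5 = unname(tools::md5sum(file.path(out_dir, written))),
      stringsAsFactors = FALSE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    list(truth = sim$truth, ratio_matrix = rm_, de = de, qpcr = qres,
         scan = scan, manifest = manifest)
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(result)
}
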