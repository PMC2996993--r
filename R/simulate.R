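#' Parameters for the two-colour array simulator
#'
#' The generator emulates the spot-level data of a dye-swapped two-colour
#' cDNA microarray experiment: per-gene latent log2 expression, a planted
#' log2 fold change for a fraction of genes, an intensity-dependent additive
#' dye bias in log-ratio space (polynomial in A, identical across the slides
#' of a pair so dye-swap averaging cancels it exactly), optional gene-wise
#' dye bias, per-channel Gaussian spot noise, additive log-normal local
#' background, clipping at the scanner ceiling, and uniformly sampled bad
#' flags.
#'
#' @param n_genes,spots_per_gene,n_replicate_pairs positive counts; each
#'   replicate pair is one forward and one dye-swapped slide.
#' @param de_fraction fraction of genes given a true fold change.
#' @param true_log2fc_magnitude absolute planted log2 fold change (random
#'   sign per gene).
#' @param noise_sd per-channel spot noise, log2 units.
#' @param dye_bias_coeffs polynomial coefficients (intercept first) of the
#'   additive dye-bias curve evaluated at the latent intensity; the default
#'   is a quadratic dishing up to ~0.8 log2 units at the intensity extremes.
#' @param gene_dye_bias_sd sd of an additional gene-specific additive dye
#'   bias (log2 units; default 0).
#' @param background_mean,background_sd mean and sd (counts) of the
#'   log-normal local background.
#' @param bg_correlation correlation (log scale) between background and
#'   foreground, to exercise the background-subtraction decision (default 0).
#' @param saturation_level scanner ceiling (default 65535).
#' @param flag_fraction fraction of spots flagged bad (code -100).
#' @param base_log2_mean,base_log2_sd latent log2 expression distribution.
#' @param seed integer RNG seed.
#' @return a list of class `array_sim_params`.
#' @export
array_sim_params <- function(n_genes = 1000L, spots_per_gene = 2L,
                             n_replicate_pairs = 3L, de_fraction = 0.1,
                             true_log2fc_magnitude = 1, noise_sd = 0.3,
                             dye_bias_coeffs = c(4, -0.8, 0.04),
                             gene_dye_bias_sd = 0,
                             background_mean = 100, background_sd = 30,
                             bg_correlation = 0,
                             saturation_level = 65535,
                             flag_fraction = 0.02,
                             base_log2_mean = 10, base_log2_sd = 1.5,
                             seed = 1L) {
  chk_count <- function(x, nm) {
    if (length(x) != 1L || !is.finite(x) || x < 1 || x != round(x))
      stop("invalid parameter: ", nm, " must be a positive integer",
           call. = FALSE)
    as.integer(x)
  }
  n_genes <- chk_count(n_genes, "n_genes")
  spots_per_gene <- chk_count(spots_per_gene, "spots_per_gene")
  n_replicate_pairs <- chk_count(n_replicate_pairs, "n_replicate_pairs")
  if (de_fraction < 0 || de_fraction > 1)
    stop("invalid parameter: de_fraction must be in [0, 1]", call. = FALSE)
  if (noise_sd < 0)
    stop("invalid parameter: noise_sd must be >= 0", call. = FALSE)
  if (saturation_level <= background_mean)
    stop("invalid parameter: saturation_level must exceed background_mean",
         call. = FALSE)
  structure(list(n_genes = n_genes, spots_per_gene = spots_per_gene,
                 n_replicate_pairs = n_replicate_pairs,
                 de_fraction = de_fraction,
                 true_log2fc_magnitude = true_log2fc_magnitude,
                 noise_sd = noise_sd, dye_bias_coeffs = dye_bias_coeffs,
                 gene_dye_bias_sd = gene_dye_bias_sd,
                 background_mean = background_mean,
                 background_sd = background_sd,
                 bg_correlation = bg_correlation,
                 saturation_level = saturation_level,
                 flag_fraction = flag_fraction,
                 base_log2_mean = base_log2_mean,
                 base_log2_sd = base_log2_sd,
                 seed = as.integer(seed)),
            class = "array_sim_params")
}

.polyval <- function(coeffs, x) {
  y <- 0
  for (k in seq_along(coeffs)) y <- y + coeffs[k] * x^(k - 1L)
  y
}

#' Simulate a dye-swapped two-colour array experiment
#'
#' Channel intensities are `2^latent` where the latent log2 intensity is the
#' gene's expression plus/minus half the true log2 fold change (depending on
#' which condition the channel carries), plus/minus half the dye-bias curve
#' evaluated at the gene's latent intensity, plus per-channel noise.  The
#' log-normal background is added to the foreground (the scanner's
#' foreground median includes the local background) and reported in the
#' background columns; both are clipped at the saturation ceiling.
#'
#' @param params an [array_sim_params()].
#' @return list with `slides` (list of [slide_assay()]), `design`
#'   (a [design_table()]) and `truth` (list with `de_genes` data frame
#'   `gene_id`, `true_log2fc`, and the latent `expression` table).
#' @export
simulate_two_color_experiment <- function(params = array_sim_params()) {
  stopifnot(inherits(params, "array_sim_params"))
  set.seed(params$seed)
  p <- params
  genes <- sprintf("gene_%05d", seq_len(p$n_genes))
  x <- rnorm(p$n_genes, p$base_log2_mean, p$base_log2_sd)
  n_de <- as.integer(round(p$de_fraction * p$n_genes))
  beta <- numeric(p$n_genes)
  de_idx <- if (n_de > 0L) sample.int(p$n_genes, n_de) else integer(0)
  beta[de_idx] <- sample(c(-1, 1), n_de, replace = TRUE) *
    p$true_log2fc_magnitude
  d_gene <- if (p$gene_dye_bias_sd > 0)
    rnorm(p$n_genes, 0, p$gene_dye_bias_sd) else numeric(p$n_genes)
  d_curve <- .polyval(p$dye_bias_coeffs, x)

  sdl2 <- sqrt(log(1 + (p$background_sd / p$background_mean)^2))
  mnl <- log(p$background_mean) - sdl2^2 / 2

  g_idx <- rep(seq_len(p$n_genes), each = p$spots_per_gene)
  n_spots <- length(g_idx)

  draw_bg <- function(fg) {
    if (p$background_mean == 0) return(numeric(length(fg)))
    if (p$background_sd == 0) return(rep(p$background_mean, length(fg)))
    z <- rnorm(length(fg))
    if (p$bg_correlation != 0) {
      zf <- as.numeric(scale(log(fg)))
      z <- p$bg_correlation * zf + sqrt(1 - p$bg_correlation^2) * z
    }
    exp(mnl + sdl2 * z)
  }

  make_slide <- function(slide_id, orientation) {
    sgn <- if (orientation == "forward") 1 else -1
    d_tot <- d_curve[g_idx] + d_gene[g_idx]
    l635 <- x[g_idx] + sgn * beta[g_idx] / 2 + d_tot / 2 +
      rnorm(n_spots, 0, p$noise_sd)
    l532 <- x[g_idx] - sgn * beta[g_idx] / 2 - d_tot / 2 +
      rnorm(n_spots, 0, p$noise_sd)
    fg635 <- 2^l635; fg532 <- 2^l532
    b635 <- draw_bg(fg635); b532 <- draw_bg(fg532)
    spots <- data.frame(
      spot_id = sprintf("%s_s%05d", slide_id, seq_len(n_spots)),
      gene_id = genes[g_idx],
      f635_median = pmin(fg635 + b635, p$saturation_level),
      b635_median = pmin(b635, p$saturation_level),
      f532_median = pmin(fg532 + b532, p$saturation_level),
      b532_median = pmin(b532, p$saturation_level),
      flag = ifelse(runif(n_spots) < p$flag_fraction, -100L, 0L),
      stringsAsFactors = FALSE)
    slide_assay(slide_id, spots, orientation)
  }

  slides <- list()
  pairs <- data.frame(forward_slide = character(), swapped_slide = character(),
                      comparison = character(), stringsAsFactors = FALSE)
  for (r in seq_len(p$n_replicate_pairs)) {
    fid <- sprintf("slide_%02d_fwd", r)
    sid <- sprintf("slide_%02d_swp", r)
    slides[[fid]] <- make_slide(fid, "forward")
    slides[[sid]] <- make_slide(sid, "swapped")
    pairs <- rbind(pairs, data.frame(
      forward_slide = fid, swapped_slide = sid,
      comparison = "treated_vs_control", stringsAsFactors = FALSE))
  }
  design <- design_table(
    comparisons = data.frame(name = "treated_vs_control",
                             numerator = "treated",
                             denominator = "control",
                             stringsAsFactors = FALSE),
    pairs = pairs)
  truth <- list(
    de_genes = data.frame(gene_id = genes[de_idx],
                          true_log2fc = beta[de_idx],
                          stringsAsFactors = FALSE),
    expression = data.frame(gene_id = genes, latent_log2 = x,
                            true_log2fc = beta, stringsAsFactors = FALSE))
  list(slides = slides, design = design, truth = truth)
}

#' Simulate an aligned promoter pair with planted direct repeats
#'
#' The first species' sequence is uniform random with each planted repeat
#' written in exactly (half-sites drawn from the PuG(G/T)TCA consensus,
#' random spacer bases); the second species is a copy mutated at
#' `substitution_rate` everywhere outside the planted footprints, so the
#' plants stay perfectly conserved and conservation filtering is testable.
#' The returned pair carries the identity (gap-free) alignment.
#'
#' @param length region length in bases (sequence ends at the anchor).
#' @param planted data frame (or list of lists) with columns `offset`
#'   (negative, in `[-length, -1]`, the 5'-most base of the repeat on the
#'   plus strand), `strand` (`"+"`/`"-"`), `spacer`.
#' @param substitution_rate per-base substitution probability for species 2.
#' @param seed integer RNG seed.
#' @param species_a,species_b labels.
#' @param consensus half-site consensus used for the plants.
#' @return list with `pair` (a [promoter_pair()]) and `truth` (list with
#'   `planted_motifs` data frame `offset`, `strand`, `spacer`, `dr_class`).
#' @export
simulate_promoter_pair <- function(length = 5000L, planted = NULL,
                                   substitution_rate = 0.1, seed = 1L,
                                   species_a = "mouse", species_b = "human",
                                   consensus = "RGKTCA") {
  set.seed(seed)
  L <- as.integer(length)
  if (is.null(planted))
    planted <- data.frame(offset = integer(), strand = character(),
                          spacer = integer())
  if (!is.data.frame(planted))
    planted <- do.call(rbind, lapply(planted, as.data.frame))
  w <- nchar(consensus)
  bases <- c("A", "C", "G", "T")
  draw_half <- function() {
    paste(vapply(strsplit(consensus, "")[[1]], function(cc)
      sample(.IUPAC[[cc]], 1L), character(1)), collapse = "")
  }
  fp <- 2L * w + planted$spacer
  if (any(planted$offset < -L) || any(planted$offset > -1L))
    stop("invalid parameter: planted offsets must lie in [-length, -1]",
         call. = FALSE)
  if (any(planted$offset + fp > 0L))
    stop("invalid parameter: planted footprint extends past the anchor",
         call. = FALSE)
  pos <- L + planted$offset + 1L
  if (nrow(planted) > 1L) {
    o <- order(pos)
    if (any(pos[o][-1L] <= (pos + fp - 1L)[o][-nrow(planted)]))
      stop("invalid parameter: planted motif footprints overlap",
           call. = FALSE)
  }
  seq_a <- sample(bases, L, replace = TRUE)
  footprint_mask <- logical(L)
  for (i in seq_len(nrow(planted))) {
    motif <- paste0(draw_half(),
                    paste(sample(bases, planted$spacer[i], replace = TRUE),
                          collapse = ""),
                    draw_half())
    if (planted$strand[i] == "-") motif <- .revcomp(motif)
    idx <- pos[i]:(pos[i] + fp[i] - 1L)
    seq_a[idx] <- strsplit(motif, "")[[1]]
    footprint_mask[idx] <- TRUE
  }
  seq_b <- seq_a
  mut <- which(!footprint_mask & runif(L) < substitution_rate)
  if (length(mut)) {
    seq_b[mut] <- vapply(seq_b[mut], function(bb)
      sample(setdiff(bases, bb), 1L), character(1), USE.NAMES = FALSE)
  }
  sa <- paste(seq_a, collapse = ""); sb <- paste(seq_b, collapse = "")
  pair <- promoter_pair(sa, sb, species_a, species_b,
                        aligned_a = sa, aligned_b = sb)
  truth <- list(planted_motifs = data.frame(
    species = rep(species_a, nrow(planted)),
    offset = planted$offset, strand = planted$strand,
    spacer = planted$spacer,
    dr_class = if (nrow(planted)) paste0("DR", planted$spacer)
               else character(0),
    stringsAsFactors = FALSE))
  list(pair = pair, truth = truth)
}

#' Simulate a qPCR Ct table with known fold changes
#'
#' Target-gene Ct values start from a per-gene baseline and decrease by
#' log2(true fold change) in each treated group (one PCR cycle is a factor
#' of two); the reference-gene Ct is independent of group.  Gaussian noise
#' of sd `ct_noise_sd` is added to every Ct value.
#'
#' @param genes character vector of gene identifiers.
#' @param true_fc named numeric vector of true fold changes (> 0) for the
#'   treated group, or a named list of such vectors for several treated
#'   groups (list names = group labels).
#' @param ct_noise_sd per-well Ct noise (cycles).
#' @param n_replicates replicates per (group, gene); at least 2.
#' @param seed integer RNG seed.
#' @param calibrator label of the baseline group (default "control").
#' @param baseline_target,baseline_reference mean Ct of target genes and of
#'   the endogenous reference (defaults 25 and 12 cycles).
#' @return list with `table` (Ct table data frame) and `truth`
#'   (`qpcr_truth` data frame `group`, `gene`, `true_fc`).
#' @export
simulate_qpcr_experiment <- function(genes, true_fc, ct_noise_sd = 0.2,
                                     n_replicates = 3L, seed = 1L,
                                     calibrator = "control",
                                     baseline_target = 25,
                                     baseline_reference = 12) {
  if (n_replicates < 2L)
    stop("invalid parameter: n_replicates must be >= 2", call. = FALSE)
  if (!is.list(true_fc)) true_fc <- list(treated = true_fc)
  for (g in names(true_fc)) {
    fc <- true_fc[[g]]
    if (any(!is.finite(fc)) || any(fc <= 0))
      stop("invalid parameter: fold changes must be positive", call. = FALSE)
    if (is.null(names(fc))) names(true_fc[[g]]) <- genes
  }
  set.seed(seed)
  groups <- c(calibrator, names(true_fc))
  rows <- list()
  for (grp in groups) {
    for (gene in genes) {
      shift <- if (grp == calibrator) 0
               else log2(true_fc[[grp]][[gene]])
      rows[[paste(grp, gene)]] <- data.frame(
        group = grp, gene = gene, replicate = seq_len(n_replicates),
        ct_target = baseline_target - shift +
          rnorm(n_replicates, 0, ct_noise_sd),
        ct_reference = baseline_reference +
          rnorm(n_replicates, 0, ct_noise_sd),
        stringsAsFactors = FALSE)
    }
  }
  table <- do.call(rbind, rows)
  row.names(table) <- NULL
  truth <- do.call(rbind, lapply(names(true_fc), function(grp)
    data.frame(group = grp, gene = genes,
               true_fc = unname(true_fc[[grp]][genes]),
               stringsAsFactors = FALSE)))
  list(table = table, truth = list(qpcr_truth = truth))
}
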