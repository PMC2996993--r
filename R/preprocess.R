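#' Quality-control and normalization parameters
#'
#' @param saturation_level scanner ceiling in fluorescence counts; spots with
#'   either channel's foreground median at this value are excluded as
#'   saturated (default 65535, the 16-bit ceiling).
#' @param sb_min minimum signal-to-background ratio; a spot is excluded when
#'   *either* channel's foreground/background ratio is strictly below this
#'   (default 1.5).
#' @param bad_flag_codes integer flag codes treated as "bad spot"; defaults
#'   to the negative GenePix codes.
#' @param bg_correlation_threshold Pearson correlation (of log2 foreground vs
#'   log2 background over retained spots) at or above which local background
#'   is subtracted (default 0.5).
#' @param lowess_span smoother span for the intensity-dependent lowess
#'   correction of M on A (default 2/3).
#' @return a list of class `qc_params`.
#' @export
qc_params <- function(saturation_level = 65535, sb_min = 1.5,
                      bad_flag_codes = c(-25L, -50L, -75L, -100L),
                      bg_correlation_threshold = 0.5,
                      lowess_span = 2 / 3) {
  stopifnot(sb_min > 0, lowess_span > 0, lowess_span <= 1,
            saturation_level > 0)
  structure(list(saturation_level = saturation_level, sb_min = sb_min,
                 bad_flag_codes = as.integer(bad_flag_codes),
                 bg_correlation_threshold = bg_correlation_threshold,
                 lowess_span = lowess_span),
            class = "qc_params")
}

#' Flag, saturation and signal-to-background filtering
#'
#' Annotates every spot with a QC status.  Exclusion reasons are assigned in
#' priority order: bad flag, then saturation (either foreground median equal
#' to the ceiling), then signal-to-background.  S/B is computed per channel
#' as foreground median / background median; a zero background with positive
#' foreground counts as infinite S/B; the spot is excluded when either
#' channel is strictly below `sb_min` (a ratio of exactly `sb_min` is kept).
#'
#' @param slide a [slide_assay()].
#' @param params a [qc_params()].
#' @return the slide with `spots$qc_status` set to one of `retained`,
#'   `excluded_flag`, `excluded_saturated`, `excluded_sb`.
#' @export
apply_qc_mask <- function(slide, params = qc_params()) {
  stopifnot(inherits(slide, "slide_assay"), inherits(params, "qc_params"))
  sp <- slide$spots
  sb <- function(f, b) ifelse(b > 0, f / b, ifelse(f > 0, Inf, 0))
  bad_flag <- sp$flag %in% params$bad_flag_codes
  saturated <- sp$f635_median >= params$saturation_level |
               sp$f532_median >= params$saturation_level
  low_sb <- sb(sp$f635_median, sp$b635_median) < params$sb_min |
            sb(sp$f532_median, sp$b532_median) < params$sb_min
  status <- rep("retained", nrow(sp))
  status[low_sb] <- "excluded_sb"
  status[saturated] <- "excluded_saturated"
  status[bad_flag] <- "excluded_flag"
  slide$spots$qc_status <- status
  slide
}

#' Decide per channel whether to subtract local background
#'
#' Following the correlation-based rule, background is subtracted from a
#' channel's foreground only when the log-scale foreground and background
#' intensities correlate across retained spots (Pearson correlation at or
#' above the configured threshold).  An undefined correlation (constant
#' background or foreground) yields a no-subtract decision.
#'
#' @param slide a QC-annotated [slide_assay()].
#' @param params a [qc_params()].
#' @return data frame with one row per channel: `channel`, `correlation`,
#'   `subtract`.
#' @export
background_policy <- function(slide, params = qc_params()) {
  stopifnot(inherits(slide, "slide_assay"))
  sp <- slide$spots[slide$spots$qc_status == "retained", , drop = FALSE]
  if (nrow(sp) < 3L)
    stop("insufficient data: fewer than 3 retained spots on slide '",
         slide$slide_id, "'", call. = FALSE)
  one <- function(f, b) {
    lf <- log2(pmax(f, 1)); lb <- log2(pmax(b, 1))
    r <- if (sd(lf) == 0 || sd(lb) == 0) NA_real_ else cor(lf, lb)
    data.frame(correlation = r,
               subtract = !is.na(r) && r >= params$bg_correlation_threshold)
  }
  res <- rbind(one(sp$f635_median, sp$b635_median),
               one(sp$f532_median, sp$b532_median))
  cbind(channel = c("635", "532"), res)
}

#' Per-spot M and A values
#'
#' For each retained spot the channel signal is the foreground median, minus
#' the background median when that channel's policy says subtract, floored at
#' 1 count (floored spots are annotated via `clipped`).  M is the log2 ratio
#' with the *treated* condition in the numerator — resolved from the slide's
#' dye orientation — and A is the mean log2 intensity of the two channels.
#'
#' @param slide a QC-annotated [slide_assay()].
#' @param policy decision record from [background_policy()]; when `NULL` no
#'   background is subtracted.
#' @return data frame `spot_id`, `gene_id`, `M`, `A`, `clipped` with one row
#'   per retained spot.
#' @export
compute_ma <- function(slide, policy = NULL) {
  stopifnot(inherits(slide, "slide_assay"))
  sp <- slide$spots[slide$spots$qc_status == "retained", , drop = FALSE]
  sub635 <- FALSE; sub532 <- FALSE
  if (!is.null(policy)) {
    sub635 <- policy$subtract[policy$channel == "635"]
    sub532 <- policy$subtract[policy$channel == "532"]
  }
  s635 <- if (sub635) sp$f635_median - sp$b635_median else sp$f635_median
  s532 <- if (sub532) sp$f532_median - sp$b532_median else sp$f532_median
  clipped <- s635 < 1 | s532 < 1
  s635 <- pmax(s635, 1); s532 <- pmax(s532, 1)
  m_raw <- log2(s635) - log2(s532)
  M <- if (slide$orientation == "forward") m_raw else -m_raw
  A <- 0.5 * (log2(s635) + log2(s532))
  data.frame(spot_id = sp$spot_id, gene_id = sp$gene_id,
             M = M, A = A, clipped = clipped, stringsAsFactors = FALSE)
}

#' Remove the intensity-dependent trend of M on A
#'
#' Fits a robust lowess curve (3 robustifying iterations) of M against A
#' with the given smoother span and returns M minus the fitted trend.
#'
#' @param ma data frame with columns `M` and `A` (as from [compute_ma()]).
#' @param span smoother span (fraction of points in each local fit),
#'   default 2/3.
#' @return `ma` with `M` replaced by the corrected values.
#' @export
lowess_correct <- function(ma, span = 2 / 3) {
  if (nrow(ma) < 10L)
    stop("insufficient data: lowess correction needs at least 10 spots",
         call. = FALSE)
  fit <- lowess(ma$A, ma$M, f = span, iter = 3L)
  trend <- approx(fit$x, fit$y, xout = ma$A, rule = 2, ties = "ordered")$y
  ma$M <- ma$M - trend
  ma
}

#' Combine a dye-swapped slide pair into per-gene replicate values
#'
#' Duplicate spots of a gene are collapsed by median within each slide, then
#' the two per-slide gene values (both already sign-resolved so that the
#' treated condition is the ratio numerator) are averaged.  Because any
#' additive log-scale dye bias enters the forward and swapped M with equal
#' size, the average is exactly bias-free.  Genes measured on only one slide
#' keep that slide's value and are flagged.
#'
#' @param forward_ma,swapped_ma per-spot M/A data frames from the forward
#'   and swapped slides of one replicate pair.
#' @return data frame `gene_id`, `M`, `A`, `n_spots_used`, `single_slide`.
#' @export
dye_swap_combine <- function(forward_ma, swapped_ma) {
  per_gene <- function(ma) {
    if (nrow(ma) == 0L)
      return(data.frame(gene_id = character(), M = numeric(),
                        A = numeric(), n = integer()))
    g <- split(seq_len(nrow(ma)), ma$gene_id)
    data.frame(gene_id = names(g),
               M = vapply(g, function(i) median(ma$M[i]), numeric(1)),
               A = vapply(g, function(i) median(ma$A[i]), numeric(1)),
               n = lengths(g), stringsAsFactors = FALSE, row.names = NULL)
  }
  fw <- per_gene(forward_ma); sw <- per_gene(swapped_ma)
  genes <- union(fw$gene_id, sw$gene_id)
  if (length(genes) == 0L)
    stop("design error: no genes on either slide of the pair", call. = FALSE)
  if (length(intersect(fw$gene_id, sw$gene_id)) == 0L &&
      nrow(fw) > 0L && nrow(sw) > 0L)
    stop("design error: slides of a pair share no genes", call. = FALSE)
  mf <- match(genes, fw$gene_id); ms <- match(genes, sw$gene_id)
  Mf <- fw$M[mf]; Ms <- sw$M[ms]
  Af <- fw$A[mf]; As <- sw$A[ms]
  M <- rowMeans(cbind(Mf, Ms), na.rm = TRUE)
  A <- rowMeans(cbind(Af, As), na.rm = TRUE)
  n <- rowSums(cbind(fw$n[mf], sw$n[ms]), na.rm = TRUE)
  data.frame(gene_id = genes, M = M, A = A, n_spots_used = as.integer(n),
             single_slide = is.na(Mf) | is.na(Ms),
             stringsAsFactors = FALSE, row.names = NULL)
}

.per_gene_slide <- function(ma) {
  g <- split(seq_len(nrow(ma)), ma$gene_id)
  data.frame(gene_id = names(g),
             M = vapply(g, function(i) median(ma$M[i]), numeric(1)),
             A = vapply(g, function(i) median(ma$A[i]), numeric(1)),
             n = lengths(g), stringsAsFactors = FALSE, row.names = NULL)
}

#' Normalize a whole two-colour experiment to a ratio matrix
#'
#' Runs the per-slide pipeline — QC mask, background-subtraction decision,
#' M/A computation, robust lowess correction — and assembles per-gene
#' normalized log2 ratios over the union of genes.
#'
#' With `replicate_unit = "slide"` (the default) every sign-resolved,
#' lowess-corrected slide contributes one replicate column (so a design with
#' `k` dye-swap pairs yields `2k` replicates; the intensity-dependent dye
#' bias is removed per slide by lowess, and dye-swap balance makes the
#' *mean* across columns free of any residual additive dye bias).  With
#' `replicate_unit = "pair"` each dye-swap pair is first combined by
#' [dye_swap_combine()] and contributes a single column; this cancels even
#' gene-specific dye bias exactly, at the cost of halving the degrees of
#' freedom available to downstream tests.
#'
#' @param slides list of [slide_assay()] objects.
#' @param design a [design_table()]; slide orientations are taken from the
#'   design (forward/swapped column membership).
#' @param params a [qc_params()].
#' @param comparison name of the comparison to assemble; default the first.
#' @param replicate_unit `"slide"` or `"pair"` (see Details).
#' @param lowess logical; set `FALSE` to skip the intensity-dependent
#'   correction (e.g. for algebraic checks on noiseless data).
#' @return an object of class `ratio_matrix`: list with `M`, `A`,
#'   `n_spots_used` (genes x replicates matrices), `genes`, `replicates`,
#'   `replicate_unit`, and a `provenance` list of per-slide QC counts and
#'   background decisions.
#' @export
normalize_experiment <- function(slides, design, params = qc_params(),
                                 comparison = NULL,
                                 replicate_unit = c("slide", "pair"),
                                 lowess = TRUE) {
  replicate_unit <- match.arg(replicate_unit)
  stopifnot(inherits(design, "design_table"))
  ids <- vapply(slides, function(s) s$slide_id, character(1))
  names(slides) <- ids
  if (is.null(comparison)) comparison <- design$comparisons$name[1L]
  pairs <- design$pairs[design$pairs$comparison == comparison, , drop = FALSE]
  if (nrow(pairs) == 0L)
    stop("no replicate pairs for comparison '", comparison, "'",
         call. = FALSE)
  provenance <- list()

  process_slide <- function(id, orientation) {
    if (!id %in% ids)
      stop("slide '", id, "' referenced by design but not supplied",
           call. = FALSE)
    sl <- slides[[id]]
    sl$orientation <- orientation
    sl <- apply_qc_mask(sl, params)
    pol <- tryCatch(background_policy(sl, params),
                    error = function(e) stop("slide '", id, "': ",
                                             conditionMessage(e),
                                             call. = FALSE))
    ma <- compute_ma(sl, pol)
    if (lowess) ma <- lowess_correct(ma, span = params$lowess_span)
    provenance[[id]] <<- list(
      qc_counts = as.list(table(sl$spots$qc_status)),
      background = pol)
    ma
  }

  cols <- list()
  for (i in seq_len(nrow(pairs))) {
    fw_ma <- process_slide(pairs$forward_slide[i], "forward")
    sw_ma <- process_slide(pairs$swapped_slide[i], "swapped")
    if (replicate_unit == "pair") {
      comb <- dye_swap_combine(fw_ma, sw_ma)
      cols[[sprintf("pair_%d", i)]] <-
        comb[c("gene_id", "M", "A", "n_spots_used")]
    } else {
      cols[[pairs$forward_slide[i]]] <- .per_gene_slide(fw_ma)
      cols[[pairs$swapped_slide[i]]] <- .per_gene_slide(sw_ma)
    }
  }
  genes <- sort(unique(unlist(lapply(cols, `[[`, "gene_id"))))
  k <- length(cols)
  M <- A <- matrix(NA_real_, length(genes), k,
                   dimnames = list(genes, names(cols)))
  N <- matrix(0L, length(genes), k, dimnames = list(genes, names(cols)))
  for (j in seq_len(k)) {
    cj <- cols[[j]]
    m <- match(cj$gene_id, genes)
    M[m, j] <- cj$M
    A[m, j] <- cj$A
    N[m, j] <- as.integer(cj[[4L]])
  }
  structure(list(M = M, A = A, n_spots_used = N, genes = genes,
                 replicates = names(cols), replicate_unit = replicate_unit,
                 comparison = comparison, provenance = provenance),
            class = "ratio_matrix")
}

#' @export
print.ratio_matrix <- function(x, ...) {
  cat("ratio_matrix: ", length(x$genes), " genes x ", length(x$replicates),
      " replicates (", x$replicate_unit, "-level), comparison '",
      x$comparison, "'\n", sep = "")
  invisible(x)
}

#' Write a ratio matrix as tab-delimited text
#' @param rm a `ratio_matrix`.
#' @param file output path; M, A and spot-count columns are suffixed per
#'   replicate.
#' @return `file`, invisibly.
#' @export
write_ratio_matrix <- function(rm, file) {
  stopifnot(inherits(rm, "ratio_matrix"))
  out <- data.frame(gene_id = rm$genes, stringsAsFactors = FALSE)
  for (j in seq_along(rm$replicates)) {
    r <- rm$replicates[j]
    out[[paste0("M.", r)]] <- rm$M[, j]
    out[[paste0("A.", r)]] <- rm$A[, j]
    out[[paste0("n.", r)]] <- rm$n_spots_used[, j]
  }
  write.table(out, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
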