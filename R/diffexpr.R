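#' Per-gene one-sample t statistics on a ratio matrix
#'
#' Tests, per gene, whether the mean normalized log2 ratio differs from 0
#' (two-sided one-sample t-test with n - 1 degrees of freedom, n being the
#' number of replicates with an observed value).  Genes with fewer than
#' `min_replicates` observations or with zero variance across replicates get
#' `NA` statistics and are never selected downstream.
#'
#' @param rm a `ratio_matrix` from [normalize_experiment()].
#' @param min_replicates minimum observed replicates per gene (default 2).
#' @return data frame `gene_id`, `n`, `mean_M`, `t_stat`, `p`.
#' @export
gene_statistics <- function(rm, min_replicates = 2L) {
  stopifnot(inherits(rm, "ratio_matrix"), min_replicates >= 2L)
  M <- rm$M
  if (length(M) == 0L || nrow(M) == 0L)
    stop("insufficient data: empty ratio matrix", call. = FALSE)
  n <- rowSums(!is.na(M))
  mean_M <- rowMeans(M, na.rm = TRUE)
  dev <- M - mean_M
  s2 <- rowSums(dev * dev, na.rm = TRUE) / pmax(n - 1L, 1L)
  sdv <- sqrt(s2)
  ok <- n >= min_replicates & sdv > 0
  t_stat <- ifelse(ok, mean_M / (sdv / sqrt(n)), NA_real_)
  p <- ifelse(ok, 2 * pt(-abs(t_stat), df = n - 1L), NA_real_)
  data.frame(gene_id = rm$genes, n = as.integer(n),
             mean_M = ifelse(n > 0, mean_M, NA_real_),
             t_stat = t_stat, p = p,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' Implements the step-up definition directly: with the m non-missing
#' p-values sorted increasingly, `q_(i) = min_{j >= i} p_(j) * m / j`,
#' capped at 1, returned in the original input order.  `NA` entries are
#' passed through and do not count towards m.
#'
#' @param p numeric vector of p-values in \[0, 1\] (NAs allowed).
#' @return vector of FDR-adjusted values, same length and order as `p`.
#' @export
fdr_adjust <- function(p) {
  if (!is.numeric(p)) stop("p must be numeric", call. = FALSE)
  obs <- !is.na(p)
  if (any(p[obs] < 0 | p[obs] > 1))
    stop("invalid input: p-values must lie in [0, 1]", call. = FALSE)
  q <- rep(NA_real_, length(p))
  m <- sum(obs)
  if (m == 0L) return(q)
  ord <- order(p[obs])
  ps <- p[obs][ord]
  qs <- rev(cummin(rev(ps * m / seq_len(m))))
  qs <- pmin(qs, 1)
  qobs <- numeric(m)
  qobs[ord] <- qs
  q[obs] <- qobs
  q
}

#' Signed fold change with the FC* convention
#'
#' Converts a mean log2 ratio to a fold change `FC = 2^mean_M` and maps
#' fold changes below 1 onto the symmetric signed scale `FC* = -1/FC`, so
#' that a halving is reported as -2 rather than 0.5 and `|fc| >= 1` always.
#'
#' @param mean_M numeric vector of mean log2 ratios.
#' @return numeric vector of signed fold changes (`mean_M = 0` gives +1).
#' @export
fold_change <- function(mean_M) {
  fc <- 2^mean_M
  ifelse(fc >= 1, fc, -1 / fc)
}

#' Select differentially expressed genes
#'
#' Computes FDR-adjusted q-values and signed fold changes and classifies
#' each gene as `up` (fc_signed >= +fc_min), `down` (fc_signed <= -fc_min)
#' or `not_selected`.  The fold-change boundary is inclusive.  When `q_max`
#' is given, selection additionally requires `q <= q_max`; by default
#' selection is on fold change alone, with q reported for every gene.
#'
#' @param stats data frame from [gene_statistics()].
#' @param fc_min minimum absolute signed fold change (default 1.5).
#' @param q_max optional FDR threshold; `NULL` (default) for no
#'   significance requirement.
#' @return data frame `gene_id`, `n`, `mean_M`, `fc_signed`, `t_stat`, `p`,
#'   `q`, `status`, with attribute `counts` = c(up, down).
#' @export
select_de_genes <- function(stats, fc_min = 1.5, q_max = NULL) {
  stopifnot(fc_min >= 1)
  q <- fdr_adjust(stats$p)
  fc <- fold_change(stats$mean_M)
  pass_q <- if (is.null(q_max)) !is.na(stats$p) else (!is.na(q) & q <= q_max)
  testable <- !is.na(stats$mean_M)
  up <- testable & pass_q & fc >= fc_min
  down <- testable & pass_q & fc <= -fc_min
  status <- rep("not_selected", nrow(stats))
  status[up] <- "up"; status[down] <- "down"
  out <- data.frame(gene_id = stats$gene_id, n = stats$n,
                    mean_M = stats$mean_M, fc_signed = fc,
                    t_stat = stats$t_stat, p = stats$p, q = q,
                    status = status, stringsAsFactors = FALSE)
  attr(out, "counts") <- c(up = sum(up, na.rm = TRUE),
                           down = sum(down, na.rm = TRUE))
  out
}

#' Intersect two differential-expression selections
#'
#' Genes selected (status `up` or `down`) in both comparisons, classified by
#' sign agreement of their signed fold changes: `concordant` when the two
#' comparisons move the gene the same way, `discordant` otherwise.
#'
#' @param res1,res2 results from [select_de_genes()].
#' @return data frame `gene_id`, `fc_comparison1`, `fc_comparison2`,
#'   `pattern`, with attribute `counts` per pattern.
#' @export
intersect_comparisons <- function(res1, res2) {
  s1 <- res1[res1$status != "not_selected", , drop = FALSE]
  s2 <- res2[res2$status != "not_selected", , drop = FALSE]
  genes <- intersect(s1$gene_id, s2$gene_id)
  fc1 <- s1$fc_signed[match(genes, s1$gene_id)]
  fc2 <- s2$fc_signed[match(genes, s2$gene_id)]
  pattern <- ifelse(sign(fc1) == sign(fc2), "concordant", "discordant")
  out <- data.frame(gene_id = genes, fc_comparison1 = fc1,
                    fc_comparison2 = fc2,
                    pattern = if (length(genes)) pattern else character(0),
                    stringsAsFactors = FALSE)
  attr(out, "counts") <- c(total = length(genes),
                           concordant = sum(pattern == "concordant"),
                           discordant = sum(pattern == "discordant"))
  out
}

#' Summarize a gene list by annotation category
#'
#' Counts genes per category of a gene-to-category map; genes absent from
#' the map are reported under `"unknown"`.  Percentages are relative to the
#' full input list, so they sum to 100 up to rounding.
#'
#' @param genes character vector of gene identifiers.
#' @param annotation data frame with columns `gene_id` and `category` (one
#'   category per gene; the first mapping wins if duplicated).
#' @return data frame `category`, `count`, `percentage`, sorted by
#'   decreasing count.
#' @export
summarize_go <- function(genes, annotation) {
  stopifnot(is.data.frame(annotation),
            all(c("gene_id", "category") %in% names(annotation)))
  if (length(genes) == 0L)
    return(data.frame(category = character(), count = integer(),
                      percentage = numeric()))
  cat_of <- annotation$category[match(genes, annotation$gene_id)]
  cat_of[is.na(cat_of)] <- "unknown"
  tab <- sort(table(cat_of), decreasing = TRUE)
  data.frame(category = names(tab), count = as.integer(tab),
             percentage = 100 * as.integer(tab) / length(genes),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Read a gene-to-category annotation map
#' @param file tab-delimited file with header columns `gene_id`, `category`.
#' @return data frame.
#' @export
read_annotation <- function(file) {
  df <- read.delim(file, stringsAsFactors = FALSE)
  if (!all(c("gene_id", "category") %in% names(df)))
    stop("annotation file needs columns gene_id and category", call. = FALSE)
  df
}
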