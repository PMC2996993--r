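#' Read a Ct table
#'
#' @param file tab-delimited file with header columns `group`, `gene`,
#'   `replicate`, `ct_target`, `ct_reference`.
#' @return validated data frame.
#' @export
read_ct_table <- function(file) {
  df <- read.delim(file, stringsAsFactors = FALSE)
  validate_ct_table(df)
}

#' @rdname read_ct_table
#' @param table a data frame in the Ct-table layout.
#' @export
validate_ct_table <- function(table) {
  need <- c("group", "gene", "replicate", "ct_target", "ct_reference")
  missing <- setdiff(need, names(table))
  if (length(missing))
    stop("Ct table missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  ct <- c(table$ct_target, table$ct_reference)
  if (any(!is.finite(ct)) || any(ct <= 0))
    stop("Ct values must be positive and finite", call. = FALSE)
  table
}

#' Relative quantification by the delta-delta-Ct method
#'
#' Per (group, gene): the target Ct is normalized against the reference-gene
#' Ct (`dCt = mean(ct_target) - mean(ct_reference)`), expressed relative to
#' the calibrator group (`ddCt = dCt - dCt_calibrator`) and converted to a
#' relative quantity `rq = 2^-ddCt`.  Dispersion is taken over per-replicate
#' dCt values: `sem` is the standard error of dCt mapped through the
#' exponential at the point estimate (`rq * ln 2 * se(dCt)`).
#'
#' @param table a Ct table (see [read_ct_table()]).
#' @param calibrator group label used as the 1x reference; must carry every
#'   gene present in the table.
#' @return data frame `group`, `gene`, `n`, `delta_ct`, `delta_delta_ct`,
#'   `rq`, `sem`, `fc_signed` (the signed fold-change convention of
#'   [fold_change()], for comparability with microarray fold changes).
#' @export
relative_quantity <- function(table, calibrator) {
  table <- validate_ct_table(table)
  if (!calibrator %in% table$group)
    stop("configuration error: calibrator group '", calibrator,
         "' not present", call. = FALSE)
  key <- interaction(table$group, table$gene, drop = TRUE)
  rows <- split(seq_len(nrow(table)), key)
  agg <- do.call(rbind, lapply(rows, function(i) {
    dct_reps <- table$ct_target[i] - table$ct_reference[i]
    data.frame(group = table$group[i][1L], gene = table$gene[i][1L],
               n = length(i),
               delta_ct = mean(table$ct_target[i]) -
                          mean(table$ct_reference[i]),
               sd_dct = if (length(i) >= 2L) sd(dct_reps) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  row.names(agg) <- NULL
  cal <- agg[agg$group == calibrator, , drop = FALSE]
  miss <- setdiff(unique(agg$gene), cal$gene)
  if (length(miss))
    stop("configuration error: calibrator lacks gene(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  ddct <- agg$delta_ct - cal$delta_ct[match(agg$gene, cal$gene)]
  rq <- 2^(-ddct)
  if (any(agg$n < 2L))
    warning("single-replicate (group, gene) cells: rq computed, SEM absent")
  sem <- rq * log(2) * agg$sd_dct / sqrt(agg$n)
  data.frame(group = agg$group, gene = agg$gene, n = agg$n,
             delta_ct = agg$delta_ct, delta_delta_ct = ddct, rq = rq,
             sem = sem, fc_signed = fold_change(-ddct),
             stringsAsFactors = FALSE)
}

#' Group comparison of qPCR expression levels
#'
#' For one gene, compares per-replicate dCt values (`ct_target -
#' ct_reference`) across condition groups with a one-way ANOVA and all
#' pairwise two-sided t-tests.  Degenerate inputs (zero variance everywhere)
#' yield `NA` p-values with a warning.
#'
#' @param table a Ct table.
#' @param gene gene to test.
#' @param alpha significance level for the `significant` flags
#'   (default 0.05).
#' @param var_equal passed to [stats::t.test()]; default `TRUE` (pooled
#'   variance, matching the ANOVA model).
#' @return list with `gene`, `anova_p`, and data frame `pairwise`
#'   (`group1`, `group2`, `p`, `significant`).
#' @export
group_comparison <- function(table, gene, alpha = 0.05, var_equal = TRUE) {
  table <- validate_ct_table(table)
  tb <- table[table$gene == gene, , drop = FALSE]
  if (nrow(tb) == 0L)
    stop("gene '", gene, "' not in table", call. = FALSE)
  groups <- unique(tb$group)
  if (length(groups) < 2L)
    stop("insufficient data: need at least 2 groups", call. = FALSE)
  dct <- tb$ct_target - tb$ct_reference
  ns <- table(tb$group)
  if (any(ns < 2L))
    stop("insufficient data: every group needs >= 2 replicates",
         call. = FALSE)
  if (sd(dct) == 0) {
    warning("zero variance in dCt; p-values undefined")
    return(list(gene = gene, anova_p = NA_real_,
                pairwise = data.frame(group1 = character(),
                                      group2 = character(),
                                      p = numeric(),
                                      significant = logical())))
  }
  fit <- aov(dct ~ factor(tb$group))
  anova_p <- anova(fit)[["Pr(>F)"]][1L]
  combs <- utils::combn(groups, 2L)
  pw <- apply(combs, 2L, function(gg) {
    x <- dct[tb$group == gg[1L]]; y <- dct[tb$group == gg[2L]]
    if (sd(c(x - mean(x), y - mean(y))) == 0) NA_real_
    else t.test(x, y, var.equal = var_equal)$p.value
  })
  list(gene = gene, anova_p = anova_p,
       pairwise = data.frame(group1 = combs[1L, ], group2 = combs[2L, ],
                             p = pw, significant = !is.na(pw) & pw < alpha,
                             stringsAsFactors = FALSE))
}
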