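#' @title GenePix-results-style spot tables and experiment design tables
#' @name gpr_io
#' @description Readers and writers for the tab-delimited spot-level dialect
#'   used throughout the package: one header row, one row per spot, with at
#'   least the columns `ID`, `F635 Median`, `B635 Median`, `F532 Median`,
#'   `B532 Median` and `Flags`.  An ATF-style preamble (quoted lines or lines
#'   starting with "ATF" before the header) is tolerated and skipped.
NULL

.GPR_REQUIRED <- c("ID", "F635 Median", "B635 Median", "F532 Median",
                   "B532 Median", "Flags")

#' Construct a slide assay
#'
#' A `slide_assay` bundles the per-spot two-channel fluorescence medians of
#' one hybridisation with its identity and dye orientation.  `orientation`
#' states which biological condition was labelled with the 635 nm dye:
#' `"forward"` means the treated/numerator condition is in the 635 channel,
#' `"swapped"` means it is in the 532 channel.
#'
#' @param slide_id single string identifying the slide.
#' @param spots data frame with columns `spot_id`, `gene_id`, `f635_median`,
#'   `b635_median`, `f532_median`, `b532_median`, `flag`; a `qc_status`
#'   column is added (all `"retained"`) if absent.
#' @param orientation `"forward"` or `"swapped"`.
#' @param channel_meta named list of pass-through metadata (e.g. unknown
#'   columns retained from a file).
#' @return an object of class `slide_assay`.
#' @export
slide_assay <- function(slide_id, spots, orientation = c("forward", "swapped"),
                        channel_meta = list()) {
  orientation <- match.arg(orientation)
  stopifnot(is.character(slide_id), length(slide_id) == 1L)
  if (!is.data.frame(spots) || nrow(spots) < 1L)
    stop("a slide_assay needs at least one spot", call. = FALSE)
  needed <- c("spot_id", "gene_id", "f635_median", "b635_median",
              "f532_median", "b532_median", "flag")
  missing <- setdiff(needed, names(spots))
  if (length(missing))
    stop("spots is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  num <- c("f635_median", "b635_median", "f532_median", "b532_median")
  for (cl in num) {
    if (!is.numeric(spots[[cl]]) || any(!is.finite(spots[[cl]])) ||
        any(spots[[cl]] < 0))
      stop("column ", cl, " must be finite non-negative", call. = FALSE)
  }
  if (is.null(spots$qc_status)) spots$qc_status <- "retained"
  structure(
    list(slide_id = slide_id, orientation = orientation,
         spots = spots, channel_meta = channel_meta),
    class = "slide_assay")
}

#' @export
print.slide_assay <- function(x, ...) {
  cat("slide_assay '", x$slide_id, "' (", x$orientation, "), ",
      nrow(x$spots), " spots\n", sep = "")
  tab <- table(x$spots$qc_status)
  cat("  qc: ", paste(names(tab), tab, sep = "=", collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

#' Read a spot table in the GenePix-results dialect
#'
#' @param file path to a tab-delimited file.  Lines before the header that
#'   start with a double quote or with `ATF` are skipped.
#' @param slide_id identifier for the slide; defaults to the file name
#'   without extension.
#' @param orientation dye orientation of the slide (see [slide_assay()]);
#'   normally overridden by the design table downstream.
#' @return a [slide_assay()].  Columns beyond the six required ones are kept
#'   in `channel_meta$extra_columns`.
#' @export
read_gpr <- function(file, slide_id = NULL,
                     orientation = c("forward", "swapped")) {
  orientation <- match.arg(orientation)
  if (is.null(slide_id))
    slide_id <- sub("\\.[^.]*$", "", basename(file))
  lines <- readLines(file)
  skip <- 0L
  while (skip < length(lines) &&
         (startsWith(lines[skip + 1L], "\"") ||
          startsWith(lines[skip + 1L], "ATF")) &&
         !grepl("\tF635 Median\t", paste0(lines[skip + 1L], "\t")))
    skip <- skip + 1L
  df <- read.delim(file, skip = skip, check.names = FALSE,
                   stringsAsFactors = FALSE, quote = "\"")
  missing <- setdiff(.GPR_REQUIRED, names(df))
  if (length(missing))
    stop("GPR file '", file, "' is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  num_cols <- c("F635 Median", "B635 Median", "F532 Median", "B532 Median")
  for (cl in num_cols) {
    v <- df[[cl]]
    if (!is.numeric(v)) {
      conv <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(conv) & !is.na(v))
      if (length(bad))
        stop("non-numeric value in column '", cl, "' at data row ",
             bad[1L], " (file line ", bad[1L] + skip + 1L, ") of '",
             file, "'", call. = FALSE)
      df[[cl]] <- conv
    }
    df[[cl]] <- as.numeric(df[[cl]])
  }
  spots <- data.frame(
    spot_id = if ("Spot" %in% names(df)) as.character(df[["Spot"]])
              else sprintf("spot_%05d", seq_len(nrow(df))),
    gene_id = as.character(df[["ID"]]),
    f635_median = df[["F635 Median"]],
    b635_median = df[["B635 Median"]],
    f532_median = df[["F532 Median"]],
    b532_median = df[["B532 Median"]],
    flag = as.integer(df[["Flags"]]),
    stringsAsFactors = FALSE)
  extra <- setdiff(names(df), c(.GPR_REQUIRED, "Spot"))
  meta <- if (length(extra)) list(extra_columns = df[extra]) else list()
  slide_assay(slide_id, spots, orientation, channel_meta = meta)
}

#' Write a slide assay in the GenePix-results dialect
#'
#' Writes a single header row and one row per spot, tab-delimited, in a
#' stable column order so that `write -> read -> write` is byte-identical.
#'
#' @param slide a [slide_assay()].
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_gpr <- function(slide, file) {
  stopifnot(inherits(slide, "slide_assay"))
  sp <- slide$spots
  out <- data.frame(
    Spot = sp$spot_id, ID = sp$gene_id,
    `F635 Median` = sp$f635_median, `B635 Median` = sp$b635_median,
    `F532 Median` = sp$f532_median, `B532 Median` = sp$b532_median,
    Flags = sp$flag, check.names = FALSE, stringsAsFactors = FALSE)
  extra <- slide$channel_meta$extra_columns
  if (!is.null(extra)) out <- cbind(out, extra)
  write.table(out, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Construct / validate an experiment design table
#'
#' A design table lists the comparisons of an experiment and, per comparison,
#' the dye-swapped replicate slide pairs: each pair names one slide hybridised
#' in forward orientation (treated condition in the 635 channel) and one
#' swapped.
#'
#' @param comparisons data frame with columns `name`, `numerator`,
#'   `denominator` (condition labels; the numerator is the treated condition).
#' @param pairs data frame with columns `forward_slide`, `swapped_slide`,
#'   `comparison`.
#' @return an object of class `design_table`.
#' @export
design_table <- function(comparisons, pairs) {
  stopifnot(is.data.frame(comparisons), is.data.frame(pairs))
  need_c <- c("name", "numerator", "denominator")
  need_p <- c("forward_slide", "swapped_slide", "comparison")
  if (length(setdiff(need_c, names(comparisons))))
    stop("comparisons needs columns: ", paste(need_c, collapse = ", "),
         call. = FALSE)
  if (length(setdiff(need_p, names(pairs))))
    stop("pairs needs columns: ", paste(need_p, collapse = ", "),
         call. = FALSE)
  if (any(pairs$forward_slide == pairs$swapped_slide))
    stop("design error: a pair references the same slide twice ",
         "(orientations within a pair must be opposite)", call. = FALSE)
  ids <- c(pairs$forward_slide, pairs$swapped_slide)
  if (anyDuplicated(ids))
    stop("design error: slide '", ids[duplicated(ids)][1L],
         "' is referenced more than once", call. = FALSE)
  if (!all(pairs$comparison %in% comparisons$name))
    stop("design error: pair references unknown comparison", call. = FALSE)
  structure(list(comparisons = comparisons, pairs = pairs),
            class = "design_table")
}

#' Read a design table
#'
#' Expects a tab-delimited file with header
#' `comparison, numerator, denominator, forward_slide, swapped_slide`
#' and one row per replicate pair.  When `slides` is supplied, the declared
#' orientations are checked against the slides (a pair whose two slides have
#' the same recorded orientation is a design error).
#'
#' @param file path.
#' @param slides optional named list of [slide_assay()] objects keyed (or
#'   named) by slide id, used to cross-check orientations.
#' @return a [design_table()].
#' @export
read_design <- function(file, slides = NULL) {
  df <- read.delim(file, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("comparison", "numerator", "denominator",
            "forward_slide", "swapped_slide")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("design file missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  comparisons <- unique(df[c("comparison", "numerator", "denominator")])
  names(comparisons) <- c("name", "numerator", "denominator")
  pairs <- df[c("forward_slide", "swapped_slide", "comparison")]
  des <- design_table(comparisons, pairs)
  if (!is.null(slides)) validate_design(des, slides)
  des
}

#' Write a design table
#' @param design a [design_table()].
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_design <- function(design, file) {
  stopifnot(inherits(design, "design_table"))
  comp <- design$comparisons
  m <- match(design$pairs$comparison, comp$name)
  out <- data.frame(comparison = design$pairs$comparison,
                    numerator = comp$numerator[m],
                    denominator = comp$denominator[m],
                    forward_slide = design$pairs$forward_slide,
                    swapped_slide = design$pairs$swapped_slide,
                    stringsAsFactors = FALSE)
  write.table(out, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Check a design table against a set of slides
#'
#' @param design a [design_table()].
#' @param slides list of [slide_assay()] objects.
#' @return the design, invisibly; errors on inconsistency.
#' @export
validate_design <- function(design, slides) {
  ids <- vapply(slides, function(s) s$slide_id, character(1))
  names(slides) <- ids
  for (i in seq_len(nrow(design$pairs))) {
    fw <- design$pairs$forward_slide[i]
    sw <- design$pairs$swapped_slide[i]
    for (id in c(fw, sw)) {
      if (!id %in% ids)
        stop("design error: slide '", id, "' not found", call. = FALSE)
    }
    if (slides[[fw]]$orientation == slides[[sw]]$orientation)
      stop("design error: pair (", fw, ", ", sw,
           ") has two slides with orientation '",
           slides[[fw]]$orientation, "'", call. = FALSE)
  }
  invisible(design)
}
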