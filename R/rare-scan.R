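.IUPAC <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

.revcomp <- function(seq) {
  map <- c(A = "T", C = "G", G = "C", T = "A", N = "N", `-` = "-")
  paste(rev(map[strsplit(seq, "")[[1]]]), collapse = "")
}

.check_alphabet <- function(seq, allow_gap = FALSE) {
  chars <- strsplit(toupper(seq), "")[[1]]
  ok <- c("A", "C", "G", "T", "N", if (allow_gap) "-")
  bad <- which(!chars %in% ok)
  if (length(bad))
    stop("invalid character(s) in sequence at position(s): ",
         paste(head(bad, 10L), collapse = ", "),
         if (length(bad) > 10L) " ..." else "", call. = FALSE)
  chars
}

#' Motif-scan parameters for RARE-like direct repeats
#'
#' Retinoic acid response elements are direct repeats of the nuclear-receptor
#' half-site PuG(G/T)TCA (IUPAC `RGKTCA`; Pu = purine) separated by a short
#' spacer — classically 1, 2 or 5 intervening bases (DR1/DR2/DR5).
#'
#' @param half_site_consensus IUPAC-degenerate half-site (default `RGKTCA`).
#' @param spacers integer set of admissible spacer lengths (default 1, 2, 5).
#' @param max_mismatches maximum mismatches tolerated per half-site
#'   (default 0).
#' @param strands `"both"` (default) or `"forward"`.
#' @return a list of class `motif_params`.
#' @export
motif_params <- function(half_site_consensus = "RGKTCA",
                         spacers = c(1L, 2L, 5L),
                         max_mismatches = 0L,
                         strands = c("both", "forward")) {
  strands <- match.arg(strands)
  half_site_consensus <- toupper(half_site_consensus)
  if (nchar(half_site_consensus) < 4L)
    stop("half-site consensus must be at least 4 bases", call. = FALSE)
  if (!all(strsplit(half_site_consensus, "")[[1]] %in% names(.IUPAC)))
    stop("consensus contains non-IUPAC characters", call. = FALSE)
  spacers <- sort(unique(as.integer(spacers)))
  if (any(spacers < 0L)) stop("spacers must be non-negative", call. = FALSE)
  structure(list(half_site_consensus = half_site_consensus,
                 spacers = spacers,
                 max_mismatches = as.integer(max_mismatches),
                 strands = strands),
            class = "motif_params")
}

# mismatch count of every window of the consensus against a char vector;
# N in the sequence never matches
.window_mismatches <- function(chars, consensus) {
  w <- nchar(consensus)
  L <- length(chars)
  if (L < w) return(integer(0))
  cons <- strsplit(consensus, "")[[1]]
  n_win <- L - w + 1L
  mism <- integer(n_win)
  for (k in seq_len(w)) {
    allowed <- .IUPAC[[cons[k]]]
    mism <- mism + !(chars[k:(n_win + k - 1L)] %in% allowed)
  }
  mism
}

#' Find half-site matches in a promoter sequence
#'
#' Reports every window matching the degenerate half-site consensus within
#' `max_mismatches`, on the requested strands.  Minus-strand matches are
#' consensus matches on the reverse complement, reported at the window's
#' plus-strand position (1-based coordinate of the window's leftmost base on
#' the given sequence) with strand `"-"`.
#'
#' @param seq nucleotide sequence (A/C/G/T/N; N never matches).
#' @param params a [motif_params()].
#' @return data frame `position`, `strand`, `site` (observed window, read
#'   5'->3' on the matching strand), `mismatches`.
#' @export
find_half_sites <- function(seq, params = motif_params()) {
  chars <- .check_alphabet(seq)
  seq <- paste(chars, collapse = "")
  w <- nchar(params$half_site_consensus)
  L <- length(chars)
  out <- list()
  mism <- .window_mismatches(chars, params$half_site_consensus)
  hit <- which(mism <= params$max_mismatches)
  if (length(hit))
    out$plus <- data.frame(
      position = hit, strand = "+",
      site = substring(seq, hit, hit + w - 1L),
      mismatches = mism[hit], stringsAsFactors = FALSE)
  if (params$strands == "both") {
    rc <- .revcomp(seq)
    rchars <- strsplit(rc, "")[[1]]
    mism_rc <- .window_mismatches(rchars, params$half_site_consensus)
    hit_rc <- which(mism_rc <= params$max_mismatches)
    if (length(hit_rc))
      out$minus <- data.frame(
        position = L - hit_rc - w + 2L, strand = "-",
        site = substring(rc, hit_rc, hit_rc + w - 1L),
        mismatches = mism_rc[hit_rc], stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out)
         else data.frame(position = integer(), strand = character(),
                         site = character(), mismatches = integer())
  res <- res[order(res$position, res$strand), , drop = FALSE]
  row.names(res) <- NULL
  res
}

#' Find direct repeats of the half-site (DR elements)
#'
#' Pairs of same-strand half-site matches whose gap equals one of the
#' admissible spacers form a direct-repeat hit; on the minus strand the
#' repeat geometry is evaluated on the reverse complement and mapped back to
#' plus-strand coordinates.  Overlapping qualifying pairs each produce a hit
#' (no greedy de-duplication), so a chained triple repeat yields two hits.
#'
#' Offsets follow the upstream-promoter convention: the sequence is assumed
#' to end at the anchor (TSS or ATG), and a hit's offset is the negative
#' 1-based distance of its 5'-most base (plus strand) from the anchor, so
#' the last base of the sequence has offset -1.
#'
#' @param seq nucleotide sequence ending at the anchor.
#' @param params a [motif_params()].
#' @return data frame `position`, `offset`, `strand`, `half_site_1`,
#'   `half_site_2`, `spacer`, `dr_class`.
#' @export
find_direct_repeats <- function(seq, params = motif_params()) {
  chars <- .check_alphabet(seq)
  seq <- paste(chars, collapse = "")
  w <- nchar(params$half_site_consensus)
  L <- length(chars)

  pair_up <- function(s, scanned) {
    # scanned: char string actually scanned (seq or its revcomp)
    ch <- strsplit(scanned, "")[[1]]
    mism <- .window_mismatches(ch, params$half_site_consensus)
    pos <- which(mism <= params$max_mismatches)
    res <- list()
    for (sp in params$spacers) {
      p1 <- pos[(pos + w + sp) %in% pos]
      if (!length(p1)) next
      res[[as.character(sp)]] <- data.frame(
        start_scanned = p1,
        half_site_1 = substring(scanned, p1, p1 + w - 1L),
        half_site_2 = substring(scanned, p1 + w + sp,
                                p1 + 2L * w + sp - 1L),
        spacer = sp, stringsAsFactors = FALSE)
    }
    if (!length(res)) return(NULL)
    out <- do.call(rbind, res)
    out$strand <- s
    out
  }

  plus <- pair_up("+", seq)
  minus <- NULL
  if (params$strands == "both") {
    minus <- pair_up("-", .revcomp(seq))
    if (!is.null(minus)) {
      fp <- 2L * w + minus$spacer
      minus$start_scanned <- L - minus$start_scanned - fp + 2L
    }
  }
  res <- rbind(plus, minus)
  if (is.null(res))
    return(data.frame(position = integer(), offset = integer(),
                      strand = character(), half_site_1 = character(),
                      half_site_2 = character(), spacer = integer(),
                      dr_class = character(), stringsAsFactors = FALSE))
  out <- data.frame(position = res$start_scanned,
                    offset = res$start_scanned - L - 1L,
                    strand = res$strand,
                    half_site_1 = res$half_site_1,
                    half_site_2 = res$half_site_2,
                    spacer = as.integer(res$spacer),
                    dr_class = paste0("DR", res$spacer),
                    stringsAsFactors = FALSE)
  out <- out[order(out$position, out$strand, out$spacer), , drop = FALSE]
  row.names(out) <- NULL
  out
}

#' Construct a promoter pair
#'
#' Holds the upstream regions of a gene in two species, 5'->3', ending at
#' the anchor (transcription start site or translation start), optionally
#' with a gapped pairwise alignment.
#'
#' @param seq_a,seq_b ungapped upstream sequences.
#' @param species_a,species_b labels.
#' @param aligned_a,aligned_b optional gapped sequences of equal length whose
#'   ungapped content equals `seq_a`/`seq_b`.
#' @param anchor `"TSS"` (default) or `"ATG"`.
#' @return an object of class `promoter_pair`.
#' @export
promoter_pair <- function(seq_a, seq_b, species_a = "species_a",
                          species_b = "species_b",
                          aligned_a = NULL, aligned_b = NULL,
                          anchor = c("TSS", "ATG")) {
  anchor <- match.arg(anchor)
  seq_a <- paste(.check_alphabet(seq_a), collapse = "")
  seq_b <- paste(.check_alphabet(seq_b), collapse = "")
  if (nchar(seq_a) == 0L || nchar(seq_b) == 0L)
    stop("empty sequence", call. = FALSE)
  if (!is.null(aligned_a)) {
    aligned_a <- paste(.check_alphabet(aligned_a, allow_gap = TRUE),
                       collapse = "")
    aligned_b <- paste(.check_alphabet(aligned_b, allow_gap = TRUE),
                       collapse = "")
    if (nchar(aligned_a) != nchar(aligned_b))
      stop("aligned sequences must have equal length", call. = FALSE)
    if (gsub("-", "", aligned_a) != seq_a ||
        gsub("-", "", aligned_b) != seq_b)
      stop("ungapped alignment does not match the sequences", call. = FALSE)
  }
  structure(list(species_a = species_a, species_b = species_b,
                 seq_a = seq_a, seq_b = seq_b,
                 aligned_a = aligned_a, aligned_b = aligned_b,
                 anchor = anchor,
                 region_length = max(nchar(seq_a), nchar(seq_b))),
            class = "promoter_pair")
}

#' @export
print.promoter_pair <- function(x, ...) {
  cat("promoter_pair (anchor ", x$anchor, "): ", x$species_a, " ",
      nchar(x$seq_a), " nt / ", x$species_b, " ", nchar(x$seq_b), " nt",
      if (!is.null(x$aligned_a)) paste0("; aligned (", nchar(x$aligned_a),
                                        " columns)"),
      "\n", sep = "")
  invisible(x)
}

#' Read a promoter pair from FASTA
#'
#' A two-record FASTA; records containing `-` are taken as a gapped
#' alignment (ungapped versions are derived).
#'
#' @param file FASTA path.
#' @param anchor anchor convention of the regions.
#' @return a [promoter_pair()].
#' @export
read_promoter_pair <- function(file, anchor = c("TSS", "ATG")) {
  anchor <- match.arg(anchor)
  ss <- Biostrings::readBStringSet(file)
  if (length(ss) != 2L)
    stop("expected exactly 2 FASTA records, got ", length(ss),
         call. = FALSE)
  s <- toupper(as.character(ss))
  gapped <- grepl("-", s[1L], fixed = TRUE) ||
            grepl("-", s[2L], fixed = TRUE)
  promoter_pair(gsub("-", "", s[1L]), gsub("-", "", s[2L]),
                species_a = names(ss)[1L], species_b = names(ss)[2L],
                aligned_a = if (gapped) s[1L], aligned_b = if (gapped) s[2L],
                anchor = anchor)
}

#' Write a promoter pair as FASTA
#' @param pair a [promoter_pair()].
#' @param file output path.
#' @param aligned write the gapped alignment (if present) instead of the
#'   ungapped sequences.
#' @return `file`, invisibly.
#' @export
write_promoter_pair <- function(pair, file, aligned = FALSE) {
  stopifnot(inherits(pair, "promoter_pair"))
  s <- if (aligned) {
    if (is.null(pair$aligned_a)) stop("pair has no alignment", call. = FALSE)
    c(pair$aligned_a, pair$aligned_b)
  } else c(pair$seq_a, pair$seq_b)
  ss <- Biostrings::BStringSet(setNames(s, c(pair$species_a, pair$species_b)))
  Biostrings::writeXStringSet(ss, file)
  invisible(file)
}

#' Globally align the two promoter sequences
#'
#' Needleman-Wunsch global alignment with affine gap costs.  A gap of length
#' L costs `gap_open + (L - 1) * gap_extend` (both negative).
#'
#' @param pair a [promoter_pair()].
#' @param match,mismatch substitution scores (defaults +1 / -1).
#' @param gap_open,gap_extend affine gap scores (defaults -5 / -1).
#' @return the pair with `aligned_a`/`aligned_b` set and attribute
#'   `alignment_score`.
#' @export
align_promoters <- function(pair, match = 1, mismatch = -1,
                            gap_open = -5, gap_extend = -1) {
  stopifnot(inherits(pair, "promoter_pair"))
  if (nchar(pair$seq_a) == 0L || nchar(pair$seq_b) == 0L)
    stop("empty sequence", call. = FALSE)
  mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = match, mismatch = mismatch, baseOnly = FALSE)
  aln <- Biostrings::pairwiseAlignment(
    pattern = pair$seq_a, subject = pair$seq_b, type = "global",
    substitutionMatrix = mat,
    gapOpening = -(gap_open - gap_extend), gapExtension = -gap_extend)
  pair$aligned_a <- as.character(Biostrings::alignedPattern(aln))
  pair$aligned_b <- as.character(Biostrings::alignedSubject(aln))
  attr(pair, "alignment_score") <- Biostrings::score(aln)
  pair
}

#' Cross-species conserved blocks of an aligned promoter pair
#'
#' Slides a window over alignment columns; columns where both species carry
#' the same unambiguous base count as matches (gaps and N count as
#' mismatches).  All columns covered by at least one window meeting
#' `min_identity` are merged into maximal non-overlapping blocks, and each
#' block's identity is recomputed over its full span.
#'
#' @param pair an aligned [promoter_pair()].
#' @param window window width in alignment columns (default 100).
#' @param min_identity minimum windowed identity (default 0.7).
#' @return data frame `start_col`, `end_col`, `length`, `identity`
#'   (1-based, inclusive alignment-column coordinates).
#' @export
conserved_blocks <- function(pair, window = 100L, min_identity = 0.7) {
  stopifnot(inherits(pair, "promoter_pair"))
  if (is.null(pair$aligned_a))
    stop("pair has no alignment; run align_promoters() first", call. = FALSE)
  a <- strsplit(pair$aligned_a, "")[[1]]
  b <- strsplit(pair$aligned_b, "")[[1]]
  L <- length(a)
  if (window > L)
    stop("window (", window, ") exceeds alignment length (", L, ")",
         call. = FALSE)
  m <- as.integer(a == b & a %in% c("A", "C", "G", "T"))
  cs <- c(0L, cumsum(m))
  starts <- seq_len(L - window + 1L)
  win_id <- (cs[starts + window] - cs[starts]) / window
  good <- win_id >= min_identity - 1e-12
  if (!any(good))
    return(data.frame(start_col = integer(), end_col = integer(),
                      length = integer(), identity = numeric()))
  covered <- logical(L)
  for (s in starts[good]) covered[s:(s + window - 1L)] <- TRUE
  r <- rle(covered)
  ends <- cumsum(r$lengths)
  begs <- ends - r$lengths + 1L
  keep <- r$values
  blocks <- data.frame(start_col = begs[keep], end_col = ends[keep])
  blocks$length <- blocks$end_col - blocks$start_col + 1L
  blocks$identity <- vapply(seq_len(nrow(blocks)), function(i) {
    (cs[blocks$end_col[i] + 1L] - cs[blocks$start_col[i]]) /
      blocks$length[i]
  }, numeric(1))
  blocks
}

#' Scan an aligned promoter pair for conserved RARE direct repeats
#'
#' Direct-repeat hits are computed per species on the ungapped sequences;
#' a hit is *conserved* when every alignment column of its footprint lies
#' inside one conserved block, in which case the partner species' offset of
#' the hit's 5' base is reported.
#'
#' @param pair a [promoter_pair()]; aligned with default scores if needed.
#' @param motif a [motif_params()].
#' @param window,min_identity conservation parameters
#'   (see [conserved_blocks()]).
#' @return list of class `rare_scan_report`: `hits` (per-species
#'   [find_direct_repeats()] table with `species`, `conserved`,
#'   `partner_offset`), `blocks`, `pair`, `params`.
#' @export
scan_promoter_pair <- function(pair, motif = motif_params(),
                               window = 100L, min_identity = 0.7) {
  stopifnot(inherits(pair, "promoter_pair"))
  if (is.null(pair$aligned_a)) pair <- align_promoters(pair)
  blocks <- conserved_blocks(pair, window, min_identity)
  a <- strsplit(pair$aligned_a, "")[[1]]
  b <- strsplit(pair$aligned_b, "")[[1]]
  col_of_a <- which(a != "-")   # ungapped pos -> alignment column
  col_of_b <- which(b != "-")
  ung_b <- cumsum(b != "-")     # alignment column -> ungapped pos (if base)
  ung_a <- cumsum(a != "-")
  w <- nchar(motif$half_site_consensus)

  annotate <- function(hits, col_of, partner_ung, partner_gap, L_partner,
                       species) {
    if (nrow(hits) == 0L) {
      hits$species <- character(0)
      hits$conserved <- logical(0)
      hits$partner_offset <- integer(0)
      return(hits)
    }
    fp <- 2L * w + hits$spacer
    hits$species <- species
    hits$conserved <- FALSE
    hits$partner_offset <- NA_integer_
    for (i in seq_len(nrow(hits))) {
      c1 <- col_of[hits$position[i]]
      c2 <- col_of[hits$position[i] + fp[i] - 1L]
      inside <- which(blocks$start_col <= c1 & blocks$end_col >= c2)
      if (length(inside) == 1L) {
        hits$conserved[i] <- TRUE
        if (!partner_gap[c1])
          hits$partner_offset[i] <- partner_ung[c1] - L_partner - 1L
      }
    }
    hits
  }

  hits_a <- annotate(find_direct_repeats(pair$seq_a, motif), col_of_a,
                     ung_b, b == "-", nchar(pair$seq_b), pair$species_a)
  hits_b <- annotate(find_direct_repeats(pair$seq_b, motif), col_of_b,
                     ung_a, a == "-", nchar(pair$seq_a), pair$species_b)
  structure(list(hits = rbind(hits_a, hits_b), blocks = blocks,
                 pair = pair,
                 params = list(motif = motif, window = window,
                               min_identity = min_identity)),
            class = "rare_scan_report")
}

#' @export
print.rare_scan_report <- function(x, ...) {
  cat("rare_scan_report: ", nrow(x$hits), " direct-repeat hit(s), ",
      sum(x$hits$conserved), " conserved; ", nrow(x$blocks),
      " conserved block(s)\n", sep = "")
  if (nrow(x$hits)) print(x$hits)
  invisible(x)
}

#' Write a scan report as tab-delimited hit table (+ BED intervals)
#'
#' @param report a `rare_scan_report`.
#' @param file path for the hit table; a companion `<file>.bed` with
#'   promoter-local 0-based intervals is written alongside.
#' @return `file`, invisibly.
#' @export
write_scan_report <- function(report, file) {
  stopifnot(inherits(report, "rare_scan_report"))
  write.table(report$hits, file, sep = "\t", quote = FALSE,
              row.names = FALSE)
  h <- report$hits
  if (nrow(h)) {
    w <- nchar(report$params$motif$half_site_consensus)
    bed <- data.frame(chrom = h$species, start = h$position - 1L,
                      end = h$position + 2L * w + h$spacer - 1L,
                      name = h$dr_class, score = 0L, strand = h$strand)
    write.table(bed, paste0(file, ".bed"), sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  invisible(file)
}
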