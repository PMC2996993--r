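# Independent oracles used across tests.  These deliberately avoid the
# package's own code paths.

# literal Benjamini-Hochberg step-up definition:
# q_(i) = min over j with p_(j) >= p_(i) of p_(j) * m / j, capped at 1
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  q <- numeric(m)
  for (i in seq_len(m)) {
    cand <- Inf
    for (j in seq_len(m)) {
      if (ps[j] >= ps[i]) cand <- min(cand, ps[j] * m / j)
    }
    q[ord[i]] <- min(1, cand)
  }
  q
}

# regex-based brute-force enumeration of direct repeats of [AG]G[GT]TCA
rc_oracle <- function(seq) {
  chartr("ACGTN", "TGCAN",
         paste(rev(strsplit(seq, "")[[1]]), collapse = ""))
}

brute_force_dr <- function(seq, spacers = c(1, 2, 5)) {
  L <- nchar(seq)
  one_strand <- function(s, strand) {
    if (L < 12) return(NULL)
    wins <- substring(s, seq_len(L - 5), seq_len(L - 5) + 5)
    is_half <- grepl("^[AG]G[GT]TCA$", wins)
    out <- NULL
    for (sp in spacers) {
      for (p in seq_len(max(L - 12 - sp + 1, 0))) {
        if (is_half[p] && is_half[p + 6 + sp]) {
          pos_scanned <- p
          pos_plus <- if (strand == "+") pos_scanned
                      else L - pos_scanned - (12 + sp) + 2
          out <- rbind(out, data.frame(position = as.integer(pos_plus),
                                       strand = strand,
                                       spacer = as.integer(sp)))
        }
      }
    }
    out
  }
  res <- rbind(one_strand(seq, "+"), one_strand(rc_oracle(seq), "-"))
  if (is.null(res))
    return(data.frame(position = integer(), strand = character(),
                      spacer = integer()))
  res <- res[order(res$position, res$strand, res$spacer), , drop = FALSE]
  row.names(res) <- NULL
  res
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

# tiny hand-built slide for unit tests
tiny_slide <- function(f635 = c(2000, 1500, 65535),
                       b635 = c(1000, 1000, 100),
                       f532 = c(1000, 1500, 2000),
                       b532 = c(100, 1000, 100),
                       flag = c(0L, 0L, 0L),
                       gene = c("g1", "g2", "g3"),
                       orientation = "forward") {
  slide_assay("s1",
              data.frame(spot_id = paste0("sp", seq_along(gene)),
                         gene_id = gene,
                         f635_median = f635, b635_median = b635,
                         f532_median = f532, b532_median = b532,
                         flag = flag, stringsAsFactors = FALSE),
              orientation)
}
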