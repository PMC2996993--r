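test_that("half-site matching expands the PuG(G/T)TCA consensus", {
  h <- find_half_sites("AGGTCA", motif_params(strands = "forward"))
  expect_equal(h$position, 1L)
  expect_equal(h$strand, "+")
  expect_equal(h$mismatches, 0L)
  expect_equal(nrow(find_half_sites("GGTTCA",
                                    motif_params(strands = "forward"))), 1L)
  # all 8 expansions match, near-misses do not, N never matches
  expansions <- as.vector(outer(c("A", "G"), c("G", "T"), function(a, k)
    paste0(a, "G", k, "TCA")))
  for (s in expansions)
    expect_equal(nrow(find_half_sites(s, motif_params())), 1L)
  expect_equal(nrow(find_half_sites("CGGTCA",
                                    motif_params(strands = "forward"))), 0L)
  expect_equal(nrow(find_half_sites("NGGTCA",
                                    motif_params(strands = "forward"))), 0L)
  # minus-strand matches are reported at the plus-strand window position
  h2 <- find_half_sites(rc_oracle("AGGTCA"), motif_params())
  expect_equal(h2$strand, "-")
  expect_equal(h2$position, 1L)
  expect_error(find_half_sites("AGGXCA"), "invalid character")
})

test_that("direct repeats pair same-strand half-sites at admissible spacers", {
  # DR2 on the plus strand, offset relative to the sequence end
  h <- find_direct_repeats("AGGTCAGGAGGTCA", motif_params(spacers = 2))
  expect_equal(nrow(h), 1L)
  expect_equal(h$position, 1L)
  expect_equal(h$offset, -14L)
  expect_equal(h$dr_class, "DR2")
  expect_equal(h$half_site_1, "AGGTCA")
  # a lone half-site is not a repeat
  expect_equal(nrow(find_direct_repeats("AGGTCA", motif_params())), 0L)
  # chained repeats: one hit per qualifying ordered pair
  h3 <- find_direct_repeats("AGGTCATTAGGTCATTAGGTCA",
                            motif_params(spacers = 2,
                                         strands = "forward"))
  expect_equal(nrow(h3), 2L)
  # minus-strand geometry maps back to plus-strand coordinates
  m <- find_direct_repeats(rc_oracle("AGGTCAGGAGGTCA"),
                           motif_params(spacers = 2))
  expect_equal(m$strand, "-")
  expect_equal(m$position, 1L)
})

test_that("hit sets equal brute-force enumeration on random sequences", {
  set.seed(31)
  for (i in 1:20) {
    s <- random_dna(sample(200:1500, 1))
    got <- find_direct_repeats(s, motif_params())
    expect_identical(got[c("position", "strand", "spacer")],
                     brute_force_dr(s))
  }
})

test_that("strand symmetry and monotonicity hold", {
  set.seed(77)
  s <- random_dna(3000)
  L <- nchar(s)
  fwd_only <- motif_params(strands = "forward")
  minus <- find_direct_repeats(s, motif_params())
  minus <- minus[minus$strand == "-", ]
  mirror <- find_direct_repeats(rc_oracle(s), fwd_only)
  expect_setequal(L - minus$position - (12L + minus$spacer) + 2L,
                  mirror$position)
  # enlarging the spacer set or mismatch budget never removes a hit
  base <- find_direct_repeats(s, motif_params(spacers = c(2, 5)))
  wider <- find_direct_repeats(s, motif_params(spacers = c(1, 2, 3, 5)))
  looser <- find_direct_repeats(s, motif_params(spacers = c(2, 5),
                                                max_mismatches = 1))
  key <- function(h) paste(h$position, h$strand, h$spacer)
  expect_true(all(key(base) %in% key(wider)))
  expect_true(all(key(base) %in% key(looser)))
})

test_that("global alignment scores and degenerate cases are right", {
  p <- align_promoters(promoter_pair("ACGT", "ACT"))
  expect_equal(attr(p, "alignment_score"), 3 * 1 + (-5))
  expect_equal(nchar(p$aligned_a), 4L)
  expect_equal(gsub("-", "", p$aligned_b), "ACT")
  ident <- align_promoters(promoter_pair("ACGTACGT", "ACGTACGT"))
  expect_equal(ident$aligned_a, ident$aligned_b)
  expect_false(grepl("-", ident$aligned_a))
  expect_error(promoter_pair("", "ACGT"), "invalid|empty")
})

test_that("substitution-only simulated pairs align gap-free at high identity", {
  sim <- simulate_promoter_pair(1000, substitution_rate = 0.1, seed = 41)
  pair <- promoter_pair(sim$pair$seq_a, sim$pair$seq_b)  # drop identity aln
  pair <- align_promoters(pair)
  a <- strsplit(pair$aligned_a, "")[[1]]
  b <- strsplit(pair$aligned_b, "")[[1]]
  expect_gte(mean(a == b), 0.85)
})

test_that("conserved blocks cover a high-identity core with window slack", {
  # identical pair: one block, full length, identity 1
  s <- random_dna(400)
  pair <- promoter_pair(s, s, aligned_a = s, aligned_b = s)
  b <- conserved_blocks(pair, window = 100, min_identity = 0.7)
  expect_equal(nrow(b), 1L)
  expect_equal(b$start_col, 1L)
  expect_equal(b$end_col, 400L)
  expect_equal(b$identity, 1)
  # 60%-identity flanks around a 95%-identity core
  set.seed(55)
  mutate_at <- function(x, rate) {
    ch <- strsplit(x, "")[[1]]
    idx <- which(runif(length(ch)) < rate)
    ch[idx] <- vapply(ch[idx], function(bb)
      sample(setdiff(c("A", "C", "G", "T"), bb), 1), "", USE.NAMES = FALSE)
    paste(ch, collapse = "")
  }
  core_a <- random_dna(500); flank1 <- random_dna(300); flank2 <- random_dna(300)
  a <- paste0(flank1, core_a, flank2)
  bseq <- paste0(mutate_at(flank1, 0.4), mutate_at(core_a, 0.05),
                 mutate_at(flank2, 0.4))
  pr <- promoter_pair(a, bseq, aligned_a = a, aligned_b = bseq)
  blk <- conserved_blocks(pr, window = 100, min_identity = 0.8)
  expect_equal(nrow(blk), 1L)
  expect_lte(abs(blk$start_col - 301L), 99L)   # core +/- (window - 1) slack
  expect_lte(abs(blk$end_col - 800L), 99L)
  # no block when nothing reaches the identity floor
  a_div <- mutate_at(a, 0.6)
  lo <- promoter_pair(a, a_div, aligned_a = a, aligned_b = a_div)
  expect_equal(nrow(conserved_blocks(lo, 100, 0.9)), 0L)
  expect_error(conserved_blocks(pr, window = 5000), "window")
})

test_that("planted repeats are recovered and conservation-annotated", {
  plants <- data.frame(offset = c(-2177L, -900L, -300L),
                       strand = c("+", "-", "+"),
                       spacer = c(2L, 5L, 1L))
  sim <- simulate_promoter_pair(3000, plants, substitution_rate = 0.05,
                                seed = 8)
  rep <- scan_promoter_pair(sim$pair)
  mouse <- rep$hits[rep$hits$species == "mouse", ]
  for (i in seq_len(nrow(plants))) {
    hit <- mouse[mouse$offset == plants$offset[i], ]
    expect_equal(nrow(hit), 1L)
    expect_equal(hit$strand, plants$strand[i])
    expect_equal(hit$dr_class, paste0("DR", plants$spacer[i]))
    expect_true(hit$conserved)
    expect_equal(hit$partner_offset, plants$offset[i])
  }
  # heavy divergence keeps the hit but destroys its conserved status
  sim2 <- simulate_promoter_pair(3000,
                                 data.frame(offset = -2177L, strand = "+",
                                            spacer = 2L),
                                 substitution_rate = 0.5, seed = 8)
  rep2 <- scan_promoter_pair(sim2$pair)
  hit2 <- rep2$hits[rep2$hits$species == "mouse" & rep2$hits$offset == -2177, ]
  expect_equal(nrow(hit2), 1L)
  expect_false(hit2$conserved)
})

test_that("promoter pairs round-trip through FASTA, gapped and ungapped", {
  sim <- simulate_promoter_pair(300, substitution_rate = 0.1, seed = 4)
  f <- withr::local_tempfile(fileext = ".fasta")
  write_promoter_pair(sim$pair, f)
  back <- read_promoter_pair(f)
  expect_equal(back$seq_a, sim$pair$seq_a)
  expect_equal(back$seq_b, sim$pair$seq_b)
  expect_null(back$aligned_a)
  aligned <- align_promoters(promoter_pair("ACGTAC", "ACTAC"))
  fa <- withr::local_tempfile(fileext = ".fasta")
  write_promoter_pair(aligned, fa, aligned = TRUE)
  back2 <- read_promoter_pair(fa)
  expect_equal(back2$aligned_a, aligned$aligned_a)
  expect_equal(back2$seq_b, "ACTAC")
})
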