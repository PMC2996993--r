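test_that("QC mask applies saturation, S/B and flag rules in priority order", {
  sl <- tiny_slide(
    f635 = c(65535, 1500, 65535, 1400, 3000),
    b635 = c(100, 1000, 100, 1000, 0),
    f532 = c(2000, 1500, 2000, 1500, 3000),
    b532 = c(100, 1000, 100, 1000, 0),
    flag = c(0L, 0L, -100L, 0L, 0L),
    gene = paste0("g", 1:5))
  m <- apply_qc_mask(sl)$spots$qc_status
  expect_equal(m[1], "excluded_saturated")     # F635 at the ceiling
  expect_equal(m[2], "retained")               # S/B exactly 1.5 is kept
  expect_equal(m[3], "excluded_flag")          # flag wins over saturation
  expect_equal(m[4], "excluded_sb")            # 1.4 < 1.5 in one channel
  expect_equal(m[5], "retained")               # zero background => S/B Inf
})

test_that("filtering is monotone in the S/B threshold", {
  sim <- simulate_two_color_experiment(
    array_sim_params(n_genes = 200, seed = 21, background_sd = 60))
  sl <- sim$slides[[1]]
  retained <- function(sb) {
    apply_qc_mask(sl, qc_params(sb_min = sb))$spots$qc_status == "retained"
  }
  r_strict <- retained(2.0)
  r_loose <- retained(1.2)
  expect_true(all(r_loose[r_strict]))  # loosening never drops a spot
})

test_that("background decision follows the foreground/background correlation", {
  # constant background: correlation undefined -> no subtraction
  sl <- tiny_slide(f635 = c(1000, 2000, 4000), b635 = c(50, 50, 50),
                   f532 = c(1000, 2000, 4000), b532 = c(50, 50, 50))
  pol <- background_policy(sl)
  expect_true(all(is.na(pol$correlation)))
  expect_false(any(pol$subtract))
  # background proportional to foreground: perfect log-linear, r = 1
  f <- c(1000, 2000, 4000, 8000)
  sl2 <- tiny_slide(f635 = f, b635 = 0.5 * f, f532 = f, b532 = 0.5 * f,
                    flag = rep(0L, 4), gene = paste0("g", 1:4))
  pol2 <- background_policy(sl2)
  expect_equal(pol2$correlation, c(1, 1))
  expect_true(all(pol2$subtract))
  # independent background by construction -> no subtraction
  sim <- simulate_two_color_experiment(
    array_sim_params(n_genes = 500, seed = 3, bg_correlation = 0))
  pol3 <- background_policy(apply_qc_mask(sim$slides[[1]]))
  expect_true(all(abs(pol3$correlation) < 0.3))
  expect_false(any(pol3$subtract))
  # strongly correlated background -> subtraction on both channels
  sim2 <- simulate_two_color_experiment(
    array_sim_params(n_genes = 500, seed = 3, bg_correlation = 0.9))
  pol4 <- background_policy(apply_qc_mask(sim2$slides[[1]]))
  expect_true(all(pol4$subtract))
  # fewer than 3 retained spots is an error
  expect_error(
    background_policy(apply_qc_mask(tiny_slide(flag = c(-100L, -100L, 0L)))),
    "insufficient")
})

test_that("M and A follow the orientation and floor rules", {
  sl <- tiny_slide(f635 = c(2000, 100), b635 = c(0, 200),
                   f532 = c(1000, 1000), b532 = c(0, 100),
                   flag = c(0L, 0L), gene = c("g1", "g2"))
  pol <- data.frame(channel = c("635", "532"), correlation = c(1, 1),
                    subtract = c(TRUE, TRUE))
  ma <- compute_ma(sl, pol)
  expect_equal(ma$M[1], 1)                  # log2(2000/1000)
  expect_equal(ma$A[1], 0.5 * log2(2000 * 1000))
  expect_true(ma$clipped[2])                # 100 - 200 floored at 1
  expect_equal(ma$M[2], log2(1 / 900))
  # same signals on a swapped slide flip the ratio
  sl$orientation <- "swapped"
  expect_equal(compute_ma(sl, pol)$M[1], -1)
})

test_that("lowess correction removes a planted intensity-dependent trend", {
  expect_error(lowess_correct(data.frame(M = 1:5, A = 1:5)), "at least 10")
  A <- seq(6, 14, length.out = 50)
  # flat zero input stays zero; a constant offset is absorbed
  expect_equal(lowess_correct(data.frame(M = rep(0, 50), A = A))$M,
               rep(0, 50))
  expect_equal(lowess_correct(data.frame(M = rep(0.8, 50), A = A))$M,
               rep(0, 50), tolerance = 1e-10)
  # realistic quadratic bias (amplitude 0.3 log2 units across the A range)
  # + noise: residual trend and median both near zero
  set.seed(42)
  A <- runif(2000, 6, 14)
  M <- 0.3 * ((A - 10) / 4)^2 - 0.15 + rnorm(2000, 0, 0.1)
  corr <- lowess_correct(data.frame(M = M, A = A))
  expect_lt(abs(median(corr$M)), 0.02)
  expect_lt(abs(unname(coef(lm(corr$M ~ A))[2])), 0.02)
})

test_that("lowess with a shared bias curve preserves the gene ranking", {
  set.seed(7)
  n <- 300
  A <- runif(n, 6, 14)
  M_true <- rnorm(n, 0, 0.5)
  bias <- 0.04 * (A - 10)^2
  corr <- lowess_correct(data.frame(M = M_true + bias, A = A))
  expect_gt(cor(rank(corr$M), rank(M_true)), 0.98)
})

test_that("dye-swap combination averages slides and cancels gene-wise bias", {
  fwd <- data.frame(spot_id = "a", gene_id = "g1", M = 1.2, A = 10,
                    clipped = FALSE)
  swp <- data.frame(spot_id = "b", gene_id = "g1", M = 0.8, A = 10,
                    clipped = FALSE)
  comb <- dye_swap_combine(fwd, swp)
  expect_equal(comb$M, 1.0)
  expect_false(comb$single_slide)
  # a gene on only one slide keeps that value, flagged
  fwd2 <- rbind(fwd, data.frame(spot_id = "c", gene_id = "g2", M = 0.5,
                                A = 9, clipped = FALSE))
  comb2 <- dye_swap_combine(fwd2, swp)
  expect_true(comb2$single_slide[comb2$gene_id == "g2"])
  expect_equal(comb2$M[comb2$gene_id == "g2"], 0.5)
  # duplicate spots collapse by median before averaging
  fwd3 <- data.frame(spot_id = c("a", "b", "c"), gene_id = "g1",
                     M = c(1, 1.1, 9), A = 10, clipped = FALSE)
  comb3 <- dye_swap_combine(fwd3, swp)
  expect_equal(comb3$M, (1.1 + 0.8) / 2)
  expect_error(
    dye_swap_combine(fwd, data.frame(spot_id = "z", gene_id = "zz",
                                     M = 0, A = 1, clipped = FALSE)),
    "design error")
})

test_that("noiseless gene-wise dye bias cancels exactly in a combined pair", {
  sim <- simulate_two_color_experiment(array_sim_params(
    n_genes = 100, spots_per_gene = 1, n_replicate_pairs = 1,
    de_fraction = 0.3, true_log2fc_magnitude = 0.8, noise_sd = 0,
    dye_bias_coeffs = 0, gene_dye_bias_sd = 0.6,
    background_mean = 0, flag_fraction = 0, seed = 5))
  fwd <- compute_ma(apply_qc_mask(sim$slides[[1]]))
  swp <- compute_ma(apply_qc_mask(sim$slides[[2]]))
  # each single slide is contaminated by the gene-wise bias
  expect_gt(max(abs(fwd$M - sim$truth$expression$true_log2fc)), 0.1)
  comb <- dye_swap_combine(fwd, swp)
  truth <- sim$truth$expression
  expect_equal(comb$M[match(truth$gene_id, comb$gene_id)],
               truth$true_log2fc, tolerance = 1e-12)
})

test_that("normalize_experiment is deterministic and recovers planted effects", {
  prm <- array_sim_params(n_genes = 300, seed = 7)
  sim <- simulate_two_color_experiment(prm)
  rm1 <- normalize_experiment(sim$slides, sim$design)
  rm2 <- normalize_experiment(sim$slides, sim$design)
  expect_identical(rm1$M, rm2$M)
  expect_equal(dim(rm1$M), c(length(rm1$genes), 6L))
  # with correlated background (subtract branch) recovery is unbiased
  simc <- simulate_two_color_experiment(
    array_sim_params(n_genes = 300, seed = 7, bg_correlation = 0.9))
  rmc <- normalize_experiment(simc$slides, simc$design)
  trc <- simc$truth$de_genes
  mmc <- rowMeans(rmc$M[trc$gene_id, ], na.rm = TRUE)
  expect_lt(abs(mean(mmc * sign(trc$true_log2fc)) - 1), 0.1)
  # with independent, unsubtracted background the additive offset
  # compresses ratios at low intensity: recovery is attenuated but bounded
  truth <- sim$truth$de_genes
  mm <- rowMeans(rm1$M[truth$gene_id, ], na.rm = TRUE)
  rec <- mean(mm * sign(truth$true_log2fc))
  expect_gt(rec, 0.8)
  expect_lt(rec, 1.0)
  # pair-level variant halves the columns and agrees on the means
  rmp <- normalize_experiment(sim$slides, sim$design,
                              replicate_unit = "pair")
  expect_equal(ncol(rmp$M), 3L)
  common <- intersect(rownames(rm1$M), rownames(rmp$M))
  expect_equal(rowMeans(rmp$M[common, ], na.rm = TRUE),
               rowMeans(rm1$M[common, ], na.rm = TRUE), tolerance = 0.05)
  # provenance records QC counts and background decisions per slide
  expect_setequal(names(rm1$provenance),
                  unname(vapply(sim$slides, `[[`, "", "slide_id")))
})
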