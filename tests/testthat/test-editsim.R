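test_that("invalid model parameters are rejected", {
  expect_error(outcome_model(p_transfect = 1.2), "probability")
  expect_error(outcome_model(p_inv = 0.5, p_del = 0.4, p_perfect = 0.2),
               "must not exceed 1")
  expect_error(outcome_model(indel_size_dist = c("-3" = 0.5, "-6" = 0.6)),
               "sum to 1")
  expect_error(outcome_model(junction_insert_dist = c("-1" = 1)), "sizes")
  lp <- test_locus()
  expect_error(simulate_sample(lp, outcome_model(), n_cells = 0, seed = 1),
               "n_cells")
})

test_that("rearrangements require both active gRNAs and delivery", {
  lp <- test_locus()
  # variable gRNA inactive: inversion and deletion channels are structurally 0
  m_var0 <- outcome_model(p_cut_var = 0, p_inv = 0.3, p_del = 0.3)
  m_fix0 <- outcome_model(p_cut_fixed = 0, p_inv = 0.3, p_del = 0.3)
  for (s in 1:10) {
    tr <- simulate_sample(lp, m_var0, n_cells = 2000, seed = s)
    expect_identical(tr$counts[["inversion"]], 0L)
    expect_identical(tr$counts[["deletion"]], 0L)
    tr <- simulate_sample(lp, m_fix0, n_cells = 2000, seed = s)
    expect_identical(tr$counts[["inversion"]], 0L)
    expect_identical(tr$counts[["deletion"]], 0L)
  }
  # no delivery, no editing of any kind
  tr <- simulate_sample(lp, outcome_model(p_transfect = 0), 3000, seed = 4)
  expect_identical(tr$counts[["wild_type"]], 6000L)
  expect_identical(sum(tr$counts), 6000L)
})

test_that("class counts are conserved and match the generative closed form", {
  lp <- test_locus()
  m <- outcome_model(p_transfect = 0.5, p_cut_fixed = 0.5, p_cut_var = 0.5,
                     p_inv = 0.05)
  n_cells <- 100000L
  n_alleles <- 2L * n_cells
  fracs <- vapply(1:10, function(s) {
    tr <- simulate_sample(lp, m, n_cells, seed = s)
    expect_identical(sum(tr$counts), n_alleles)
    tr$counts[["inversion"]] / n_alleles
  }, numeric(1))
  # P(inversion) = p_transfect * p_cut_fixed * p_cut_var * p_inv = 6.25e-3
  expected <- 0.5 * 0.5 * 0.5 * 0.05
  mc_se <- sd(fracs) / sqrt(length(fracs))
  expect_lt(abs(mean(fracs) - expected), 3 * mc_se + 1e-12)
})

test_that("halving transfection efficiency halves expected edited fractions", {
  lp <- test_locus()
  edited_frac <- function(p_t, s) {
    tr <- simulate_sample(lp, outcome_model(p_transfect = p_t), 20000, seed = s)
    1 - tr$counts[["wild_type"]] / sum(tr$counts)
  }
  hi <- vapply(1:10, function(s) edited_frac(0.6, s), numeric(1))
  lo <- vapply(1:10, function(s) edited_frac(0.3, 100 + s), numeric(1))
  diff <- mean(hi) - 2 * mean(lo)
  se <- sqrt(var(hi) / 10 + 4 * var(lo) / 10)
  expect_lt(abs(diff), 3 * se)
})

test_that("identical seeds give byte-identical outputs", {
  lp <- test_locus()
  m <- outcome_model()
  expect_identical(simulate_sample(lp, m, 500, seed = 7),
                   simulate_sample(lp, m, 500, seed = 7))
  tr <- simulate_sample(lp, m, 500, seed = 7)
  cfg <- read_sim_config(coverage = 50, seed = 3)
  expect_identical(emit_long_reads(tr, lp, m, cfg),
                   emit_long_reads(tr, lp, m, cfg))
  expect_identical(emit_amplicon_reads(tr, lp, "fixed", cfg),
                   emit_amplicon_reads(tr, lp, "fixed", cfg))
  expect_identical(
    emit_droplet_panel(tr, mass_for_copies(1e4), n_droplets = 1000, seed = 5),
    emit_droplet_panel(tr, mass_for_copies(1e4), n_droplets = 1000, seed = 5))
})

test_that("amplicon reads reflect the allele composition at the cut site", {
  lp <- test_locus()
  # all wild type, zero error: every read equals the reference amplicon
  wt <- manual_truth(rep("wild_type", 200))
  out <- emit_amplicon_reads(wt, lp, "fixed", exact_read_cfg(100, seed = 2))
  expect_true(all(out$reads == out$amplicon))

  # 30% of alleles carry a -3 indel at the fixed site
  classes <- rep(c("indel_fixed_only", "wild_type"), c(600, 1400))
  tr <- manual_truth(classes,
                     indel_fixed = rep(c(-3L, NA_integer_), c(600, 1400)))
  out <- emit_amplicon_reads(tr, lp, "fixed", exact_read_cfg(4000, seed = 5))
  frac <- mean(nchar(out$reads) < nchar(out$amplicon))
  se <- sqrt(0.3 * 0.7 / 4000)
  expect_lt(abs(frac - 0.3), 4 * se)
  # a -3 bp allele read is shorter than the reference by exactly 3
  short <- out$reads[nchar(out$reads) != nchar(out$amplicon)]
  expect_true(all(nchar(short) == nchar(out$amplicon) - 3L))
})

test_that("long reads carry the expected junction structure", {
  lp <- test_locus()
  pr <- locus_products(lp)
  m0 <- outcome_model(junction_insert_dist = c("0" = 1))  # clean junctions
  inv_truth <- manual_truth(rep("inversion", 10))
  out <- emit_long_reads(inv_truth, lp, m0, exact_read_cfg(20, seed = 8))
  norm <- vapply(out$reads, function(r) {
    if (grepl(substr(pr$wt, 1, 30), r, fixed = TRUE)) r
    else as.character(Biostrings::reverseComplement(Biostrings::DNAString(r)))
  }, character(1), USE.NAMES = FALSE)
  expect_true(all(norm == pr$inversion))

  del_truth <- manual_truth(rep("deletion", 10))
  out <- emit_long_reads(del_truth, lp, m0, exact_read_cfg(20, seed = 9))
  expect_true(all(nchar(out$reads) == nchar(pr$wt) - lp$interval_bp))

  # amplicon ceiling: intervals beyond it are refused explicitly
  big <- simulate_locus_pair(6000, seed = 1)
  expect_error(emit_long_reads(inv_truth, big, m0, exact_read_cfg(5)),
               "unsupported for this interval")
})

test_that("droplet panels reflect the junction-carrier fraction", {
  # no inversion alleles: no double positives at any sensible threshold
  tr0 <- allele_truth(c(wild_type = 20000))
  p <- emit_droplet_panel(tr0, mass_for_copies(2e4), n_droplets = 5000, seed = 3)
  cls <- classify_droplets(p, cdpcr_run_config())
  expect_identical(cls$n_double_positive, 0L)

  # one inversion genome, one droplet spanning the whole loaded volume,
  # zero invalid fraction: that droplet is double positive
  tr1 <- allele_truth(c(inversion = 2))
  p1 <- emit_droplet_panel(tr1, mass_for_copies(1),
                           loaded_vol_uL = 0.59e-3, droplet_vol_nL = 0.59,
                           n_droplets = 1,
                           noise_cfg = droplet_noise_config(frac_invalid = 0),
                           seed = 1)
  cls1 <- classify_droplets(p1, cdpcr_run_config())
  expect_identical(cls1$n_double_positive, 1L)

  # double-positive rate follows the per-droplet occupancy formula
  # 1 - exp(-lambda * f) across seeds
  copies <- 1e5; f <- 0.02; n_drop <- 20000L
  tr <- allele_truth(c(wild_type = 49000, inversion = 1000))
  lam <- copies * 0.59 / 25000
  expected <- 1 - exp(-lam * f)
  obs <- vapply(1:10, function(s) {
    pan <- emit_droplet_panel(tr, mass_for_copies(copies), n_droplets = n_drop,
                              noise_cfg = droplet_noise_config(frac_invalid = 0),
                              seed = s)
    attr(pan, "panel_truth")$n_positive_droplets / n_drop
  }, numeric(1))
  mc_se <- sd(obs) / sqrt(10)
  expect_lt(abs(mean(obs) - expected), 3 * mc_se + 1e-6)

  # volumes are checked
  expect_error(
    emit_droplet_panel(tr0, mass_for_copies(100), loaded_vol_uL = 1,
                       n_droplets = 2000), "exceeds the loaded volume")
  expect_error(emit_droplet_panel(tr0, -1e-9), "non-negative")
})
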