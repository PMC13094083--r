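ref100 <- local({
  set.seed(42)
  paste(sample(c("A", "C", "G", "T"), 100, replace = TRUE), collapse = "")
})
cut100 <- 50L  # blunt cut between positions 50 and 51

test_that("alignment of identical sequences yields no events and full score", {
  al <- align_to_reference(ref100, ref100)
  expect_identical(nrow(al$events), 0L)
  expect_equal(al$score, 100 * 2)  # match score +2 per base
  expect_error(align_to_reference("", ref100), "non-empty")
})

test_that("indel events carry correct reference coordinates", {
  # 3-nt excision spanning the cut: single deletion event of size 3 there
  read <- paste0(substr(ref100, 1, cut100 - 1), substr(ref100, cut100 + 3, 100))
  al <- align_to_reference(read, ref100)
  ev <- al$events[al$events$type == "deletion", ]
  expect_identical(nrow(ev), 1L)
  expect_identical(ev$size, 3L)
  expect_true(ev$start <= cut100 + 1L && ev$end >= cut100 - 2L)

  # insertion reported at the reference base 5' of the inserted sequence;
  # use a base differing from both neighbours so gap placement is unambiguous
  b <- setdiff(c("A", "C", "G", "T"),
               c(substr(ref100, cut100, cut100),
                 substr(ref100, cut100 + 1, cut100 + 1)))[1]
  read <- paste0(substr(ref100, 1, cut100), strrep(b, 4),
                 substr(ref100, cut100 + 1, 100))
  al <- align_to_reference(read, ref100)
  ev <- al$events[al$events$type == "insertion", ]
  expect_identical(nrow(ev), 1L)
  expect_identical(ev$size, 4L)
  expect_identical(ev$start, cut100)

  # reads shorter than 30% of the reference are flagged discarded
  al <- align_to_reference(substr(ref100, 1, 20), ref100)
  expect_true(al$discarded)
})

test_that("the cut window rule counts only intersecting indels", {
  # deletion spanning the cut coordinate: counted
  del_read <- paste0(substr(ref100, 1, cut100 - 2), substr(ref100, cut100 + 2, 100))
  call <- site_mutation_frequency(rep(del_read, 10), ref100, cut100,
                                  indel_call_config(min_reads = 1))
  expect_equal(call$raw_frequency, 1)

  # 1-bp insertion 5 bp outside the window edge (window is [46, 55]): not counted
  far <- cut100 + 5L + 5L
  ins_read <- paste0(substr(ref100, 1, far), "A", substr(ref100, far + 1, 100))
  call <- site_mutation_frequency(rep(ins_read, 10), ref100, cut100,
                                  indel_call_config(min_reads = 1))
  expect_equal(call$raw_frequency, 0)

  # substitutions never count
  sub_read <- ref100
  substr(sub_read, cut100, cut100) <- setdiff(c("A", "C", "G", "T"),
                                              substr(ref100, cut100, cut100))[1]
  call <- site_mutation_frequency(rep(sub_read, 10), ref100, cut100,
                                  indel_call_config(min_reads = 1))
  expect_equal(call$raw_frequency, 0)

  # QC flag on read depth
  expect_false(site_mutation_frequency(del_read, ref100, cut100)$qc_pass)
})

test_that("enlarging the buffer never decreases the raw frequency", {
  set.seed(7)
  cfg0 <- indel_call_config(min_reads = 1)
  for (rep_i in 1:5) {
    # random reads: some with indels at random positions, some clean
    reads <- vapply(1:30, function(i) {
      if (runif(1) < 0.5) return(ref100)
      pos <- sample(10:90, 1)
      if (runif(1) < 0.5) {
        paste0(substr(ref100, 1, pos - 1), substr(ref100, pos + sample(1:6, 1), 100))
      } else {
        paste0(substr(ref100, 1, pos), random_bases(sample(1:4, 1)),
               substr(ref100, pos + 1, 100))
      }
    }, character(1))
    freqs <- vapply(c(0L, 2L, 4L, 10L, 40L), function(b) {
      site_mutation_frequency(reads, ref100, cut100,
                              indel_call_config(cut_buffer_bp = b,
                                                min_reads = 1))$raw_frequency
    }, numeric(1))
    expect_true(all(diff(freqs) >= 0))
    expect_true(all(freqs >= 0 & freqs <= 1))
  }
})

test_that("control subtraction removes shared event classes only", {
  cfg <- indel_call_config(min_reads = 1)
  del_read <- paste0(substr(ref100, 1, cut100 - 2), substr(ref100, cut100 + 2, 100))
  ins_read <- paste0(substr(ref100, 1, cut100), "G", substr(ref100, cut100 + 1, 100))

  # event present only in the sample: retained
  samp <- site_mutation_frequency(c(rep(del_read, 5), rep(ref100, 5)),
                                  ref100, cut100, cfg)
  ctrl <- site_mutation_frequency(rep(ref100, 10), ref100, cut100, cfg)
  adj <- control_subtract(samp, list(ctrl))
  expect_equal(adj$control_adjusted_frequency, samp$raw_frequency)

  # event at equal frequency in sample and controls: removed
  ctrl2 <- site_mutation_frequency(c(rep(del_read, 5), rep(ref100, 5)),
                                   ref100, cut100, cfg)
  adj <- control_subtract(samp, list(ctrl2))
  expect_equal(adj$control_adjusted_frequency, 0)
  expect_identical(nrow(adj$events), 0L)

  # mixed: sample-specific insertion survives, shared deletion is removed
  samp2 <- site_mutation_frequency(c(rep(del_read, 4), rep(ins_read, 4),
                                     rep(ref100, 2)), ref100, cut100, cfg)
  adj2 <- control_subtract(samp2, list(ctrl2))
  expect_equal(adj2$control_adjusted_frequency, 0.4)

  # zero-edit sample with noisy controls stays at 0, never negative
  clean <- site_mutation_frequency(rep(ref100, 10), ref100, cut100, cfg)
  adj <- control_subtract(clean, list(ctrl2))
  expect_equal(adj$control_adjusted_frequency, 0)

  # empty control list: pass-through with a warning
  expect_warning(out <- control_subtract(samp, list()), "no negative controls")
  expect_identical(out$control_flag, "no_controls")
  expect_equal(out$control_adjusted_frequency, samp$raw_frequency)
})

test_that("estimated frequency recovers the generative indel fraction", {
  lp <- test_locus()
  m <- outcome_model(p_transfect = 0.6, p_cut_fixed = 0.6, p_cut_var = 0.3)
  tr <- simulate_sample(lp, m, n_cells = 3000, seed = 21)
  # generative truth: fraction of amplifiable alleles with a fixed-site indel
  amp <- tr$alleles[!tr$alleles$class %in% c("inversion", "deletion"), ]
  f_true <- mean(!is.na(amp$indel_fixed))

  # zero sequencing error: the estimate equals the sampled-read fraction exactly
  out <- emit_amplicon_reads(tr, lp, "fixed", exact_read_cfg(800, seed = 22))
  call <- site_mutation_frequency(out$reads, out$amplicon, out$cut_pos)
  expect_equal(call$raw_frequency, mean(!is.na(out$labels$indel_size)))
  expect_lt(abs(call$raw_frequency - f_true), 4 * sqrt(f_true * (1 - f_true) / 800))

  # with default sequencing error rates, still within binomial error
  out <- emit_amplicon_reads(tr, lp, "fixed",
                             read_sim_config(coverage = 800, seed = 23))
  call <- site_mutation_frequency(out$reads, out$amplicon, out$cut_pos)
  expect_lt(abs(call$raw_frequency - f_true), 4 * sqrt(f_true * (1 - f_true) / 800))
})
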