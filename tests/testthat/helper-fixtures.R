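# Shared fixtures: a small dual-cut locus and handy model/config builders.
# Everything is generated in code; no stored data files.

test_locus <- function(interval_bp = 300L, seed = 11L) {
  simulate_locus_pair(interval_bp, margin_bp = 150L, seed = seed)
}

# zero-noise read config for construction-level checks
exact_read_cfg <- function(coverage, seed = 1L, read_length = 150L) {
  read_sim_config(coverage = coverage, read_length = read_length,
                  substitution_error_rate = 0, indel_error_rate = 0,
                  seed = seed)
}

# an allele_truth with an explicit per-allele table (deterministic composition)
manual_truth <- function(classes, indel_fixed = NA_integer_,
                         indel_var = NA_integer_, ploidy = 2L) {
  alleles <- data.frame(class = classes,
                        indel_fixed = rep_len(indel_fixed, length(classes)),
                        indel_var = rep_len(indel_var, length(classes)),
                        stringsAsFactors = FALSE)
  counts <- table(factor(classes, levels = c("wild_type", "indel_fixed_only",
                                             "indel_var_only", "indel_both",
                                             "inversion", "deletion")))
  allele_truth(stats::setNames(as.integer(counts), names(counts)),
               ploidy = ploidy, alleles = alleles)
}

# expected junction-caller label for each generative allele class on
# full-interval zero-error reads
truth_to_call <- c(wild_type = "wild_type",
                   indel_fixed_only = "wild_type",
                   indel_var_only = "wild_type",
                   indel_both = "wild_type",
                   inversion = "complete_inversion",
                   deletion = "deletion")

# expected rearrangement products of a locus (zero junction inserts)
locus_products <- function(lp) {
  seg <- lp$ref_segment
  cut_l <- min(lp$fixed_cut_pos, lp$variable_cut_pos)
  cut_r <- max(lp$fixed_cut_pos, lp$variable_cut_pos)
  left <- substr(seg, 1L, cut_l)
  mid <- substr(seg, cut_l + 1L, cut_r)
  right <- substr(seg, cut_r + 1L, nchar(seg))
  rc <- function(x) as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
  list(wt = seg,
       inversion = paste0(left, rc(mid), right),
       deletion = paste0(left, right),
       left = left, mid = mid, right = right,
       cut_l = cut_l, cut_r = cut_r)
}

random_bases <- function(n, seed = NULL) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
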