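#' Genome model for converting DNA mass to genome copy number
#'
#' Defaults describe the tomato nuclear genome: 1,179 Mbp at an average
#' base-pair weight of 659.928 Da.
#'
#' @param genome_size_bp haploid genome size in base pairs.
#' @param avg_bp_weight_Da average molecular weight of one base pair (Da).
#' @param avogadro Avogadro's number.
#' @return an object of class `genome_model`.
#' @export
genome_model <- function(genome_size_bp = 1.179e9,
                         avg_bp_weight_Da = 659.928,
                         avogadro = 6.022e23) {
  if (genome_size_bp <= 0 || avg_bp_weight_Da <= 0 || avogadro <= 0) {
    stop("all genome-model constants must be strictly positive", call. = FALSE)
  }
  structure(list(genome_size_bp = genome_size_bp,
                 avg_bp_weight_Da = avg_bp_weight_Da,
                 avogadro = avogadro),
            class = "genome_model")
}

#' Genome copies contained in a DNA mass
#'
#' copies = mass (g) x Avogadro / (genome size (bp) x average bp weight (Da)).
#' Linear in mass; with the tomato defaults, 1 ng of DNA corresponds to
#' roughly 774 genome copies.
#'
#' @param dna_mass_g DNA mass in grams (>= 0).
#' @param gm a [genome_model()].
#' @return genome copy number (numeric, not rounded).
#' @examples
#' genome_copies(1e-9)  # ~774 tomato genomes per ng
#' @export
genome_copies <- function(dna_mass_g, gm = genome_model()) {
  if (any(dna_mass_g < 0)) stop("`dna_mass_g` must be >= 0", call. = FALSE)
  dna_mass_g * gm$avogadro / (gm$genome_size_bp * gm$avg_bp_weight_Da)
}

#' DNA mass yielding a target genome copy number
#'
#' Inverse of [genome_copies()]; convenient when constructing synthetic
#' panels with a prescribed number of loaded genomes.
#'
#' @param copies target genome copy number (>= 0).
#' @param gm a [genome_model()].
#' @return DNA mass in grams.
#' @export
mass_for_copies <- function(copies, gm = genome_model()) {
  if (any(copies < 0)) stop("`copies` must be >= 0", call. = FALSE)
  copies * gm$genome_size_bp * gm$avg_bp_weight_Da / gm$avogadro
}

#' Run configuration for crystal digital PCR quantification
#'
#' @param droplet_vol_nL expected droplet volume (default 0.59 nL); droplets
#'   not matching it are excluded upstream via the validity flag.
#' @param loaded_vol_uL total reaction volume loaded on the chip (default
#'   25 uL).
#' @param min_partitions minimum number of valid partitions for a sample to
#'   pass QC (default 18,000).
#' @param ch1_threshold,ch2_threshold fluorescence thresholds above which a
#'   channel is scored positive.
#' @param poisson_corrected replace the direct double-positive count with a
#'   Poisson occupancy-corrected event estimate
#'   `-ln(1 - p) * n_valid` (p = double-positive fraction)? Off by default:
#'   the standard workflow divides counts directly, which is accurate at low
#'   junction occupancy but biased downward when positive copies co-occur in
#'   droplets.
#' @return an object of class `cdpcr_run_config`.
#' @export
cdpcr_run_config <- function(droplet_vol_nL = 0.59, loaded_vol_uL = 25,
                             min_partitions = 18000L,
                             ch1_threshold = 500, ch2_threshold = 500,
                             poisson_corrected = FALSE) {
  if (droplet_vol_nL <= 0) stop("`droplet_vol_nL` must be > 0", call. = FALSE)
  if (loaded_vol_uL <= 0) stop("`loaded_vol_uL` must be > 0", call. = FALSE)
  if (min_partitions < 0) stop("`min_partitions` must be >= 0", call. = FALSE)
  if (!is.finite(ch1_threshold) || !is.finite(ch2_threshold)) {
    stop("channel thresholds must be finite", call. = FALSE)
  }
  structure(list(droplet_vol_nL = droplet_vol_nL, loaded_vol_uL = loaded_vol_uL,
                 min_partitions = as.integer(min_partitions),
                 ch1_threshold = ch1_threshold, ch2_threshold = ch2_threshold,
                 poisson_corrected = isTRUE(poisson_corrected)),
            class = "cdpcr_run_config")
}

#' Classify droplets of a cdPCR panel
#'
#' Volume-invalid droplets are excluded entirely (they count neither as valid
#' partitions nor as events, even if both channels are high). Among valid
#' droplets, a double positive requires *both* channels above their
#' thresholds — the two probes target opposite borders of the inversion
#' junction, so a single-channel signal is not scored.
#'
#' @param panel a droplet panel: data frame with columns `ch1`, `ch2`,
#'   `valid` (and typically `droplet_id`, `volume_nl`).
#' @param cfg a [cdpcr_run_config()].
#' @return list with `n_valid`, `n_double_positive`, `n_excluded`.
#' @export
classify_droplets <- function(panel, cfg = cdpcr_run_config()) {
  needed <- c("ch1", "ch2", "valid")
  if (!is.data.frame(panel) || !all(needed %in% names(panel))) {
    stop("`panel` must be a data frame with columns ch1, ch2, valid",
         call. = FALSE)
  }
  if (nrow(panel) == 0L) stop("`panel` is empty", call. = FALSE)
  valid <- as.logical(panel$valid)
  dp <- valid & panel$ch1 > cfg$ch1_threshold & panel$ch2 > cfg$ch2_threshold
  list(n_valid = sum(valid),
       n_double_positive = sum(dp),
       n_excluded = sum(!valid))
}

#' Quantify inversion frequency per analysed genome from a cdPCR panel
#'
#' Composes the full quantification: genome copies loaded from DNA mass, the
#' analysed volume fraction (valid droplets x droplet volume / loaded
#' volume), droplet classification, and the frequency
#' `double positives / analysed genomes`. A sample passes QC only with at
#' least `min_partitions` valid partitions; the frequency is still computed
#' for diagnostics when QC fails. With `poisson_corrected = TRUE` in `cfg`,
#' the double-positive count is replaced by the Poisson occupancy-corrected
#' event estimate, which removes the downward bias arising when several
#' junction copies share a droplet.
#'
#' @param panel a droplet panel (see [classify_droplets()]).
#' @param dna_mass_g DNA mass loaded (grams).
#' @param gm a [genome_model()].
#' @param cfg a [cdpcr_run_config()].
#' @return an object of class `cdpcr_result` with fields `n_valid_droplets`,
#'   `n_double_positive`, `n_events` (corrected count actually used),
#'   `genome_copies_loaded`, `analysed_fraction`, `analysed_genomes`,
#'   `inversion_frequency`, `qc_pass`.
#' @examples
#' lp_truth <- allele_truth(c(wild_type = 99000, inversion = 1000))
#' panel <- emit_droplet_panel(lp_truth, dna_mass_g = mass_for_copies(1e5),
#'                             n_droplets = 20000, seed = 7)
#' quantify_cdpcr(panel, dna_mass_g = mass_for_copies(1e5))
#' @export
quantify_cdpcr <- function(panel, dna_mass_g, gm = genome_model(),
                           cfg = cdpcr_run_config()) {
  cls <- classify_droplets(panel, cfg)
  copies <- genome_copies(dna_mass_g, gm)
  analysed_fraction <- cls$n_valid * cfg$droplet_vol_nL / (cfg$loaded_vol_uL * 1000)
  if (analysed_fraction > 1 + 1e-9) {
    stop("analysed volume exceeds loaded volume; check droplet counts/volumes",
         call. = FALSE)
  }
  analysed_fraction <- min(analysed_fraction, 1)
  analysed_genomes <- copies * analysed_fraction
  if (analysed_genomes <= 0) {
    stop("no analysed genomes; inversion frequency is undefined", call. = FALSE)
  }
  n_events <- cls$n_double_positive
  if (cfg$poisson_corrected && cls$n_valid > 0L) {
    p_hat <- cls$n_double_positive / cls$n_valid
    if (p_hat >= 1) stop("all valid droplets positive; Poisson correction undefined",
                         call. = FALSE)
    n_events <- -log(1 - p_hat) * cls$n_valid
  }
  structure(
    list(n_valid_droplets = cls$n_valid,
         n_double_positive = cls$n_double_positive,
         n_excluded = cls$n_excluded,
         n_events = n_events,
         genome_copies_loaded = copies,
         analysed_fraction = analysed_fraction,
         analysed_genomes = analysed_genomes,
         inversion_frequency = n_events / analysed_genomes,
         qc_pass = cls$n_valid >= cfg$min_partitions,
         poisson_corrected = cfg$poisson_corrected),
    class = "cdpcr_result"
  )
}

#' @export
print.cdpcr_result <- function(x, ...) {
  cat("cdPCR inversion quantification\n")
  cat(sprintf("  valid droplets:    %d (excluded: %d) — QC %s\n",
              x$n_valid_droplets, x$n_excluded,
              if (x$qc_pass) "pass" else "FAIL (frequency reported for diagnostics only)"))
  cat(sprintf("  double positives:  %d%s\n", x$n_double_positive,
              if (x$poisson_corrected)
                sprintf(" (Poisson-corrected events: %.1f)", x$n_events) else ""))
  cat(sprintf("  genomes loaded:    %.0f; analysed fraction %.3f -> %.0f analysed genomes\n",
              x$genome_copies_loaded, x$analysed_fraction, x$analysed_genomes))
  cat(sprintf("  inversion frequency: %.4g (%.3g%% of analysed genomes)\n",
              x$inversion_frequency, 100 * x$inversion_frequency))
  invisible(x)
}
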