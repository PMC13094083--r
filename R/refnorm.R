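#' Reference-gRNA normalisation factor for one sample
#'
#' The fixed gRNA targets the same site in every construct, so its mutation
#' frequency tracks the sample's transfection and expression efficiency. The
#' factor `mean_fixed / sample_fixed` rescales each sample onto the shared
#' average-efficiency scale.
#'
#' @param mean_fixed mean fixed-site mutation frequency across all non-control
#'   experimental samples.
#' @param sample_fixed this sample's fixed-site mutation frequency (> 0).
#' @return the multiplicative normalisation factor.
#' @examples
#' normalisation_factor(0.1274, 0.0637)  # 2
#' @export
normalisation_factor <- function(mean_fixed, sample_fixed) {
  if (sample_fixed <= 0) {
    stop("sample fixed-site frequency is 0; sample is non-normalisable ",
         "(inactive reference gRNA)", call. = FALSE)
  }
  mean_fixed / sample_fixed
}

#' Normalise a table of samples by the fixed-gRNA internal reference
#'
#' Computes the arithmetic mean fixed-site frequency over non-control samples
#' (equal replicate weighting), derives each sample's
#' [normalisation_factor()] and applies it multiplicatively to the variable-
#' site and inversion frequencies. After normalisation every normalisable
#' sample's fixed-site frequency equals the raw mean exactly, and all
#' within-sample frequency ratios are preserved. Samples with a zero
#' fixed-site frequency (inactive reference gRNA) are flagged
#' non-normalisable, excluded from the mean, and their normalised columns set
#' to `NA`.
#'
#' @param records data frame with columns `sample_id`, `fixed_freq`,
#'   `variable_freq`, `inversion_freq` and optionally `construct`,
#'   `interval_bp`, `replicate`, `is_control` (controls default to `FALSE`).
#'   All frequencies must lie in [0, 1].
#' @return an object of class `normalised_samples`: the input data frame with
#'   added columns `normalisable`, `norm_factor`, `norm_fixed`,
#'   `norm_variable`, `norm_inversion`; the reference mean is stored in
#'   attribute `mean_fixed`. Normalised values may exceed 1 for samples whose
#'   reference activity was far below average; they are reported unclamped
#'   (the scale is relative) with a warning.
#' @export
normalise_samples <- function(records) {
  needed <- c("sample_id", "fixed_freq", "variable_freq", "inversion_freq")
  if (!is.data.frame(records) || !all(needed %in% names(records))) {
    stop("`records` must be a data frame with columns ",
         paste(needed, collapse = ", "), call. = FALSE)
  }
  if (!"is_control" %in% names(records)) records$is_control <- FALSE
  freq_cols <- c("fixed_freq", "variable_freq", "inversion_freq")
  for (cn in freq_cols) {
    v <- records[[cn]]
    if (any(!is.na(v) & (v < 0 | v > 1))) {
      stop(sprintf("`%s` must lie in [0, 1]", cn), call. = FALSE)
    }
  }
  experimental <- !records$is_control
  normalisable <- experimental & !is.na(records$fixed_freq) & records$fixed_freq > 0
  if (!any(normalisable)) {
    stop("no non-control sample with a positive fixed-site frequency; ",
         "the reference mean is undefined", call. = FALSE)
  }
  mean_fixed <- mean(records$fixed_freq[normalisable])
  out <- records
  out$normalisable <- normalisable
  out$norm_factor <- ifelse(normalisable, mean_fixed / records$fixed_freq, NA_real_)
  out$norm_fixed <- out$norm_factor * records$fixed_freq
  out$norm_variable <- out$norm_factor * records$variable_freq
  out$norm_inversion <- out$norm_factor * records$inversion_freq
  if (any(stats::na.omit(c(out$norm_variable, out$norm_inversion)) > 1)) {
    warning("some normalised frequencies exceed 1; values reported unclamped ",
            "(the normalised scale is relative)")
  }
  attr(out, "mean_fixed") <- mean_fixed
  class(out) <- c("normalised_samples", "data.frame")
  out
}

#' @export
print.normalised_samples <- function(x, ...) {
  cat(sprintf(
    "Reference-normalised samples (n = %d, %d normalisable; mean fixed-site frequency %.4g)\n",
    nrow(x), sum(x$normalisable), attr(x, "mean_fixed")))
  print.data.frame(x, digits = 4)
  invisible(x)
}

#' Bar panels of raw vs normalised variable-site frequencies
#'
#' Two base-graphics panels showing each sample's variable-site mutation
#' frequency before and after reference normalisation, with the reference
#' mean marked on the normalised panel.
#'
#' @param x a [normalise_samples()] result.
#' @param ... passed to [graphics::barplot()].
#' @return `x`, invisibly.
#' @export
plot.normalised_samples <- function(x, ...) {
  old <- graphics::par(mfrow = c(1, 2), mar = c(6, 4, 2, 1))
  on.exit(graphics::par(old))
  ok <- x$normalisable
  graphics::barplot(x$variable_freq[ok], names.arg = x$sample_id[ok],
                    las = 2, main = "raw", ylab = "variable-site frequency", ...)
  graphics::barplot(x$norm_variable[ok], names.arg = x$sample_id[ok],
                    las = 2, main = "normalised", ylab = "", ...)
  graphics::abline(h = attr(x, "mean_fixed"), col = "red", lty = 2)
  invisible(x)
}

#' Experiment-level report across constructs and detection methods
#'
#' Aggregates normalised per-sample tables into the standard experiment
#' summaries: normalised inversion frequency versus interval size; inversion
#' frequency versus variable-site cutting efficiency (with the reference mean
#' marked as the saturation threshold above which the fixed site becomes
#' limiting); the deletion:inversion ratio per construct when long-read
#' calls are supplied; per-construct concordance between the droplet-count
#' and long-read estimates; and, when generative truth is supplied,
#' per-stage recovery errors. Constructs in which no inversion was detected
#' in any sample are excluded from the normalised panels and listed in
#' `excluded_constructs`.
#'
#' @param cdpcr a [normalise_samples()] result for the droplet-count pipeline
#'   (must carry a `construct` column; `interval_bp` recommended).
#' @param longread optional [normalise_samples()] result for the long-read
#'   pipeline; may carry a `deletion_freq` column for the ratio table.
#' @param truth optional data frame with columns `construct` and
#'   `true_inversion_freq`.
#' @return an object of class `dualcut_report`: list of data frames
#'   `freq_vs_size`, `freq_vs_efficiency`, `del_inv_ratio`, `concordance`,
#'   `recovery`, plus `excluded_constructs` and `saturation_threshold` (the
#'   reference mean).
#' @export
experiment_report <- function(cdpcr, longread = NULL, truth = NULL) {
  stopifnot(inherits(cdpcr, "normalised_samples"))
  if (!"construct" %in% names(cdpcr)) {
    stop("`cdpcr` must carry a `construct` column", call. = FALSE)
  }
  d <- cdpcr[cdpcr$normalisable, , drop = FALSE]
  inv_by_construct <- tapply(d$inversion_freq, d$construct, sum)
  excluded <- names(inv_by_construct)[inv_by_construct == 0]
  kept <- d[!d$construct %in% excluded, , drop = FALSE]

  freq_vs_size <- do.call(rbind, lapply(split(kept, kept$construct), function(g) {
    data.frame(construct = g$construct[1L],
               interval_bp = if ("interval_bp" %in% names(g)) g$interval_bp[1L] else NA,
               n = nrow(g),
               mean_norm_inversion = mean(g$norm_inversion),
               sd_norm_inversion = stats::sd(g$norm_inversion),
               stringsAsFactors = FALSE)
  }))
  if (!is.null(freq_vs_size) && "interval_bp" %in% names(freq_vs_size)) {
    freq_vs_size <- freq_vs_size[order(freq_vs_size$interval_bp), , drop = FALSE]
  }
  rownames(freq_vs_size) <- NULL

  freq_vs_efficiency <- kept[, intersect(
    c("sample_id", "construct", "interval_bp", "norm_variable", "norm_inversion"),
    names(kept)), drop = FALSE]
  rownames(freq_vs_efficiency) <- NULL

  del_inv_ratio <- NULL
  if (!is.null(longread) && "deletion_freq" %in% names(longread)) {
    lr <- longread[longread$normalisable, , drop = FALSE]
    del_inv_ratio <- do.call(rbind, lapply(split(lr, lr$construct), function(g) {
      inv <- sum(g$inversion_freq)
      data.frame(construct = g$construct[1L],
                 mean_deletion_freq = mean(g$deletion_freq),
                 mean_inversion_freq = mean(g$inversion_freq),
                 ratio = if (inv > 0) mean(g$deletion_freq) / mean(g$inversion_freq)
                         else NA_real_,
                 stringsAsFactors = FALSE)
    }))
    rownames(del_inv_ratio) <- NULL
  }

  concordance <- NULL
  if (!is.null(longread)) {
    stopifnot(inherits(longread, "normalised_samples"))
    if (!"construct" %in% names(longread)) {
      stop("`longread` must carry a `construct` column", call. = FALSE)
    }
    cd_mean <- tapply(kept$norm_inversion, kept$construct, mean)
    lr_ok <- longread[longread$normalisable, , drop = FALSE]
    lr_mean <- tapply(lr_ok$norm_inversion, lr_ok$construct, mean)
    shared <- intersect(names(cd_mean), names(lr_mean))
    if (!length(shared)) {
      stop("no shared constructs between cdPCR and long-read tables; ",
           "offending constructs: ",
           paste(union(names(cd_mean), names(lr_mean)), collapse = ", "),
           call. = FALSE)
    }
    concordance <- data.frame(
      construct = shared,
      cdpcr_norm_inversion = as.numeric(cd_mean[shared]),
      longread_norm_inversion = as.numeric(lr_mean[shared]),
      ratio = as.numeric(cd_mean[shared] / lr_mean[shared]),
      abs_diff = abs(as.numeric(cd_mean[shared]) - as.numeric(lr_mean[shared])),
      stringsAsFactors = FALSE
    )
    rownames(concordance) <- NULL
  }

  recovery <- NULL
  if (!is.null(truth)) {
    est <- tapply(kept$norm_inversion, kept$construct, mean)
    shared <- intersect(names(est), as.character(truth$construct))
    tr <- truth$true_inversion_freq[match(shared, truth$construct)]
    recovery <- data.frame(construct = shared,
                           true_inversion_freq = tr,
                           est_norm_inversion = as.numeric(est[shared]),
                           abs_error = abs(as.numeric(est[shared]) - tr),
                           stringsAsFactors = FALSE)
    rownames(recovery) <- NULL
  }

  structure(
    list(freq_vs_size = freq_vs_size,
         freq_vs_efficiency = freq_vs_efficiency,
         del_inv_ratio = del_inv_ratio,
         concordance = concordance,
         recovery = recovery,
         excluded_constructs = excluded,
         saturation_threshold = attr(cdpcr, "mean_fixed")),
    class = "dualcut_report"
  )
}

#' @export
print.dualcut_report <- function(x, ...) {
  cat("Dual-cut experiment report\n")
  cat(sprintf("  saturation threshold (mean fixed-site frequency): %.4g\n",
              x$saturation_threshold))
  if (length(x$excluded_constructs)) {
    cat("  constructs excluded (no detected inversions): ",
        paste(x$excluded_constructs, collapse = ", "), "\n")
  }
  cat("-- normalised inversion frequency vs interval size --\n")
  print(x$freq_vs_size, digits = 4)
  if (!is.null(x$del_inv_ratio)) {
    cat("-- deletion:inversion ratio per construct --\n")
    print(x$del_inv_ratio, digits = 4)
  }
  if (!is.null(x$concordance)) {
    cat("-- cdPCR vs long-read concordance --\n")
    print(x$concordance, digits = 4)
  }
  if (!is.null(x$recovery)) {
    cat("-- recovery vs generative truth --\n")
    print(x$recovery, digits = 4)
  }
  invisible(x)
}
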