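#' Generative model of dual-cut editing outcomes in a transfected sample
#'
#' Parameters of the per-allele editing process in a protoplast transfection:
#' delivery, per-site cleavage, and repair-outcome channels conditional on
#' cutting. Inversions and deletions can only arise on alleles where *both*
#' sites are cut; this zero-inflation structure is enforced by construction in
#' [simulate_sample()].
#'
#' @param p_transfect probability that an allele's cell received the construct.
#' @param p_cut_fixed,p_cut_var per-allele cleavage probability at the fixed /
#'   variable site, conditional on transfection.
#' @param p_inv,p_del,p_perfect outcome probabilities conditional on both sites
#'   being cut: inversion of the intervening segment, deletion of it, or
#'   perfect re-ligation; `p_inv + p_del + p_perfect` must be <= 1 and the
#'   remainder is re-ligation with small indels at one or both junctions.
#' @param p_indel probability that a repaired single cut carries an indel
#'   (rather than restoring the wild-type sequence); also used to split the
#'   both-cut re-ligation remainder across the one-site/both-site indel
#'   classes.
#' @param indel_size_dist named numeric vector over signed indel sizes
#'   (negative = deletion, positive = insertion). The default places point
#'   masses on -3/-6/-9 bp deletions, the classes seen in Sanger traces at
#'   these junctions, plus a geometric tail of insertions up to +80 bp.
#' @param junction_insert_dist named numeric vector over 0..200 bp of random
#'   sequence inserted at each rearrangement junction. The default supports
#'   0..80 bp (point mass at 0, geometric tail), the insert range the
#'   flank-matching junction scan is designed to tolerate; larger inserts can
#'   be configured but escape flank detection.
#' @param ploidy copies of the locus per cell (default 2; tomato is diploid).
#' @return an object of class `outcome_model`.
#' @export
outcome_model <- function(p_transfect = 0.5,
                          p_cut_fixed = 0.5, p_cut_var = 0.5,
                          p_inv = 0.05, p_del = 0.2, p_perfect = 0.25,
                          p_indel = 0.9,
                          indel_size_dist = default_indel_sizes(),
                          junction_insert_dist = default_junction_inserts(),
                          ploidy = 2L) {
  check_prob(p_transfect, "p_transfect")
  check_prob(p_cut_fixed, "p_cut_fixed")
  check_prob(p_cut_var, "p_cut_var")
  check_prob(p_inv, "p_inv")
  check_prob(p_del, "p_del")
  check_prob(p_perfect, "p_perfect")
  check_prob(p_indel, "p_indel")
  if (p_inv + p_del + p_perfect > 1 + 1e-12) {
    stop("`p_inv + p_del + p_perfect` must not exceed 1", call. = FALSE)
  }
  check_size_dist(indel_size_dist, "indel_size_dist")
  check_size_dist(junction_insert_dist, "junction_insert_dist", min_size = 0)
  ploidy <- as.integer(ploidy)
  if (is.na(ploidy) || ploidy < 1L) stop("`ploidy` must be a positive integer", call. = FALSE)
  structure(
    list(p_transfect = p_transfect,
         p_cut_fixed = p_cut_fixed, p_cut_var = p_cut_var,
         p_inv = p_inv, p_del = p_del, p_perfect = p_perfect,
         p_indel = p_indel,
         indel_size_dist = indel_size_dist,
         junction_insert_dist = junction_insert_dist,
         ploidy = ploidy),
    class = "outcome_model"
  )
}

#' Default indel-size distribution at repaired cut sites
#'
#' Point masses at -3, -6 and -9 bp (in-frame deletion classes recurrently
#' observed at these junctions) plus a geometric tail of insertions from
#' +1 to +80 bp.
#' @return named numeric probability vector (names = signed sizes).
#' @export
default_indel_sizes <- function() {
  del <- c("-3" = 0.30, "-6" = 0.20, "-9" = 0.10)
  ins_sizes <- 1:80
  ins <- stats::dgeom(ins_sizes - 1L, prob = 0.30)
  ins <- 0.40 * ins / sum(ins)
  names(ins) <- as.character(ins_sizes)
  c(del, ins)
}

#' Default junction-insert size distribution for rearrangement junctions
#'
#' Mass 0.6 on a clean junction (0 bp inserted) and a geometric tail over
#' 1..80 bp of random inserted sequence.
#' @return named numeric probability vector.
#' @export
default_junction_inserts <- function() {
  sizes <- 1:80
  tail <- stats::dgeom(sizes - 1L, prob = 0.10)
  tail <- 0.40 * tail / sum(tail)
  names(tail) <- as.character(sizes)
  c("0" = 0.60, tail)
}

allele_classes <- c("wild_type", "indel_fixed_only", "indel_var_only",
                    "indel_both", "inversion", "deletion")

#' Construct an allele-truth object from class counts
#'
#' Low-level constructor used when the exact allele composition should be
#' fixed rather than simulated (e.g. to build a droplet panel whose true
#' junction-carrier fraction is an exact target value). [simulate_sample()]
#' is the generative counterpart.
#'
#' @param counts named integer vector over (a subset of) the allele classes
#'   `wild_type`, `indel_fixed_only`, `indel_var_only`, `indel_both`,
#'   `inversion`, `deletion`.
#' @param ploidy,n_cells optional; if omitted, `n_cells` is inferred from the
#'   total count and `ploidy` (total must be divisible by `ploidy`).
#' @param alleles optional per-allele data frame (columns `class`,
#'   `indel_fixed`, `indel_var`) carrying drawn indel sizes for read emission.
#' @param seed seed recorded for provenance (default `NA`).
#' @return an object of class `allele_truth`.
#' @export
allele_truth <- function(counts, ploidy = 2L, n_cells = NULL, alleles = NULL,
                         seed = NA_integer_) {
  full <- stats::setNames(integer(length(allele_classes)), allele_classes)
  if (is.null(names(counts)) || !all(names(counts) %in% allele_classes)) {
    stop("`counts` must be named with allele classes: ",
         paste(allele_classes, collapse = ", "), call. = FALSE)
  }
  if (any(counts < 0)) stop("allele counts must be non-negative", call. = FALSE)
  full[names(counts)] <- as.integer(counts)
  total <- sum(full)
  if (is.null(n_cells)) {
    if (total %% ploidy != 0L) {
      stop("total allele count must be divisible by `ploidy`", call. = FALSE)
    }
    n_cells <- total %/% ploidy
  } else if (total != ploidy * n_cells) {
    stop("allele counts must sum to ploidy * n_cells", call. = FALSE)
  }
  structure(
    list(counts = full, ploidy = as.integer(ploidy),
         n_cells = as.integer(n_cells), seed = seed, alleles = alleles),
    class = "allele_truth"
  )
}

#' @export
print.allele_truth <- function(x, ...) {
  cat(sprintf("Allele truth: %d cells x ploidy %d = %d alleles\n",
              x$n_cells, x$ploidy, sum(x$counts)))
  print(x$counts)
  inv <- x$counts[["inversion"]]
  cat(sprintf("  inversion-junction carrier fraction: %.4g\n", inv / sum(x$counts)))
  invisible(x)
}

#' Simulate the allele population of one transfected sample
#'
#' Each of the `ploidy * n_cells` alleles is processed independently:
#' untransfected alleles stay wild type; transfected alleles draw Bernoulli
#' cleavage events at each site; alleles cut at both sites draw an outcome
#' among inversion / deletion / perfect re-ligation / re-ligation with
#' junction indels; alleles cut at a single site draw indel-vs-perfect
#' repair. Inversions and deletions therefore cannot occur unless both gRNAs
#' are active. Deterministic given `seed`.
#'
#' @param locus a [locus_pair()] (recorded; sizes drawn here are interpreted
#'   relative to its cut sites by the read emitters).
#' @param model an [outcome_model()].
#' @param n_cells number of cells in the sample (> 0).
#' @param seed integer seed.
#' @return an [allele_truth()] with class counts and a per-allele table of
#'   drawn indel sizes.
#' @examples
#' lp <- simulate_locus_pair(200, seed = 1)
#' m <- outcome_model(p_transfect = 0.5, p_inv = 0.05)
#' truth <- simulate_sample(lp, m, n_cells = 1000, seed = 42)
#' truth
#' @export
simulate_sample <- function(locus, model, n_cells, seed) {
  stopifnot(inherits(locus, "locus_pair"), inherits(model, "outcome_model"))
  n_cells <- as.integer(n_cells)
  if (is.na(n_cells) || n_cells <= 0L) stop("`n_cells` must be > 0", call. = FALSE)
  n <- model$ploidy * n_cells
  with_seed(seed, {
    transfected <- stats::runif(n) < model$p_transfect
    cut_f <- transfected & (stats::runif(n) < model$p_cut_fixed)
    cut_v <- transfected & (stats::runif(n) < model$p_cut_var)

    cls <- rep("wild_type", n)
    indel_f <- rep(NA_integer_, n)
    indel_v <- rep(NA_integer_, n)

    both <- which(cut_f & cut_v)
    if (length(both)) {
      p_rem <- 1 - model$p_inv - model$p_del - model$p_perfect
      outc <- sample(c("inversion", "deletion", "perfect", "relig_indel"),
                     length(both), replace = TRUE,
                     prob = c(model$p_inv, model$p_del, model$p_perfect, p_rem))
      cls[both[outc == "inversion"]] <- "inversion"
      cls[both[outc == "deletion"]] <- "deletion"
      # perfect re-ligation is indistinguishable from wild type
      rel <- both[outc == "relig_indel"]
      if (length(rel)) {
        # each junction carries an indel with prob p_indel, conditioned on
        # at least one (otherwise it would be the perfect channel)
        f_has <- stats::runif(length(rel)) < model$p_indel
        v_has <- stats::runif(length(rel)) < model$p_indel
        neither <- !f_has & !v_has
        f_has[neither] <- stats::runif(sum(neither)) < 0.5
        v_has[neither] <- !f_has[neither]
        cls[rel[f_has & v_has]] <- "indel_both"
        cls[rel[f_has & !v_has]] <- "indel_fixed_only"
        cls[rel[!f_has & v_has]] <- "indel_var_only"
        indel_f[rel[f_has]] <- draw_sizes(model$indel_size_dist, sum(f_has))
        indel_v[rel[v_has]] <- draw_sizes(model$indel_size_dist, sum(v_has))
      }
    }

    only_f <- which(cut_f & !cut_v)
    if (length(only_f)) {
      has <- stats::runif(length(only_f)) < model$p_indel
      cls[only_f[has]] <- "indel_fixed_only"
      indel_f[only_f[has]] <- draw_sizes(model$indel_size_dist, sum(has))
    }
    only_v <- which(!cut_f & cut_v)
    if (length(only_v)) {
      has <- stats::runif(length(only_v)) < model$p_indel
      cls[only_v[has]] <- "indel_var_only"
      indel_v[only_v[has]] <- draw_sizes(model$indel_size_dist, sum(has))
    }

    counts <- stats::setNames(
      as.integer(table(factor(cls, levels = allele_classes))), allele_classes)
    alleles <- data.frame(class = cls, indel_fixed = indel_f,
                          indel_var = indel_v, stringsAsFactors = FALSE)
    allele_truth(counts, ploidy = model$ploidy, n_cells = n_cells,
                 alleles = alleles, seed = as.integer(seed))
  })
}

#' Read-simulation configuration
#'
#' @param coverage number of reads to emit.
#' @param read_length target read length for short amplicon reads; the
#'   amplicon window is `read_length` bases centred on the cut site (long
#'   reads always span the full reference segment).
#' @param substitution_error_rate,indel_error_rate per-base sequencing error
#'   rates, each in [0, 0.2].
#' @param seed integer seed.
#' @return an object of class `read_sim_config`.
#' @export
read_sim_config <- function(coverage = 1000L, read_length = 150L,
                            substitution_error_rate = 0.001,
                            indel_error_rate = 0.0001, seed = 1L) {
  for (r in c(substitution_error_rate, indel_error_rate)) {
    if (r < 0 || r > 0.2) stop("error rates must lie in [0, 0.2]", call. = FALSE)
  }
  if (coverage <= 0) stop("`coverage` must be > 0", call. = FALSE)
  structure(
    list(coverage = as.integer(coverage), read_length = as.integer(read_length),
         substitution_error_rate = substitution_error_rate,
         indel_error_rate = indel_error_rate, seed = as.integer(seed)),
    class = "read_sim_config"
  )
}

# Apply a signed indel of size s at cut position `cut` (cut between cut and
# cut+1) to sequence `seq`. Deletions remove |s| bases spanning the cut;
# insertions add s random bases at the cut. Returns the modified sequence.
apply_cut_indel <- function(seq, cut, s) {
  if (is.na(s) || s == 0L) return(seq)
  if (s < 0L) {
    k <- -s
    start <- max(1L, cut - k %/% 2L)
    paste0(substr(seq, 1L, start - 1L), substr(seq, start + k, nchar(seq)))
  } else {
    paste0(substr(seq, 1L, cut), random_dna(s), substr(seq, cut + 1L, nchar(seq)))
  }
}

#' Emit short amplicon reads around one cut site
#'
#' Draws `cfg$coverage` reads from the sample's allele population, each read
#' being the (possibly indel-carrying) amplicon sequence centred on the
#' requested cut site, with sequencing errors applied. Alleles carrying an
#' inversion or deletion yield no product for the wild-type-orientation primer
#' pair spanning the cut, so by default they drop out of the amplifiable pool
#' (`rearrangement_dropout = FALSE` keeps them in as wild-type-like template
#' truncations are not modelled).
#'
#' @param truth an [allele_truth()] carrying the per-allele table (i.e. from
#'   [simulate_sample()]).
#' @param locus the [locus_pair()] the truth was simulated on.
#' @param site `"fixed"` or `"variable"`.
#' @param cfg a [read_sim_config()].
#' @param rearrangement_dropout should inversion/deletion alleles be excluded
#'   from the amplifiable pool (default `TRUE`)?
#' @return a list with `reads` (character vector), `labels` (data frame:
#'   `read_id`, `class`, `indel_size`), the reference `amplicon` sequence and
#'   its local `cut_pos`.
#' @export
emit_amplicon_reads <- function(truth, locus, site = c("fixed", "variable"),
                                cfg = read_sim_config(),
                                rearrangement_dropout = TRUE) {
  site <- match.arg(site)
  stopifnot(inherits(truth, "allele_truth"), inherits(locus, "locus_pair"))
  if (is.null(truth$alleles)) {
    stop("`truth` lacks a per-allele table; use simulate_sample()", call. = FALSE)
  }
  cut <- if (site == "fixed") locus$fixed_cut_pos else locus$variable_cut_pos
  hw <- cfg$read_length %/% 2L
  a_start <- max(1L, cut - hw + 1L)
  a_end <- min(nchar(locus$ref_segment), cut + hw)
  amplicon <- substr(locus$ref_segment, a_start, a_end)
  local_cut <- cut - a_start + 1L
  if (local_cut < 10L || local_cut > nchar(amplicon) - 10L) {
    stop("cut site too close to the segment end for this read length", call. = FALSE)
  }
  alleles <- truth$alleles
  pool <- if (rearrangement_dropout) {
    which(!alleles$class %in% c("inversion", "deletion"))
  } else {
    seq_len(nrow(alleles))
  }
  if (!length(pool)) stop("no amplifiable alleles in `truth`", call. = FALSE)
  with_seed(cfg$seed, {
    pick <- pool[sample.int(length(pool), cfg$coverage, replace = TRUE)]
    sizes <- if (site == "fixed") alleles$indel_fixed[pick] else alleles$indel_var[pick]
    sizes[alleles$class[pick] %in% c("inversion", "deletion")] <- NA_integer_
    reads <- vapply(sizes, function(s) apply_cut_indel(amplicon, local_cut, s),
                    character(1))
    reads <- apply_seq_errors(reads, cfg$substitution_error_rate, cfg$indel_error_rate)
    list(
      reads = reads,
      labels = data.frame(read_id = sprintf("read_%06d", seq_along(pick)),
                          class = alleles$class[pick],
                          indel_size = sizes, stringsAsFactors = FALSE),
      amplicon = amplicon,
      cut_pos = local_cut
    )
  })
}

#' Emit full-interval long amplicon reads
#'
#' Simulates amplicon long reads spanning the whole reference segment (both
#' cut sites and the intervening interval), one read per sampled allele:
#' wild-type order (with any junction indels), the internal segment
#' reverse-complemented for inversion alleles, or the fused outer product for
#' deletion alleles. Rearrangement junctions receive random inserts drawn
#' from the model's junction-insert distribution. Read orientation is random,
#' as in single-molecule sequencing.
#'
#' @inheritParams emit_amplicon_reads
#' @param model the [outcome_model()] supplying `junction_insert_dist`.
#' @param max_interval_bp amplicon ceiling (default 5000 bp); intervals above
#'   it cannot be spanned by amplicon long-read sequencing and raise an error.
#' @return a list with `reads` (character vector) and `labels` (data frame:
#'   `read_id`, `class`, `orientation`).
#' @export
emit_long_reads <- function(truth, locus, model, cfg = read_sim_config(),
                            max_interval_bp = 5000L) {
  stopifnot(inherits(truth, "allele_truth"), inherits(locus, "locus_pair"),
            inherits(model, "outcome_model"))
  if (locus$interval_bp > max_interval_bp) {
    stop(sprintf(
      "long-read simulation unsupported for this interval (%d bp > ceiling %d bp)",
      locus$interval_bp, max_interval_bp), call. = FALSE)
  }
  seg <- locus$ref_segment
  cut_l <- min(locus$fixed_cut_pos, locus$variable_cut_pos)
  cut_r <- max(locus$fixed_cut_pos, locus$variable_cut_pos)
  left <- substr(seg, 1L, cut_l)
  mid <- substr(seg, cut_l + 1L, cut_r)
  right <- substr(seg, cut_r + 1L, nchar(seg))
  fixed_is_left <- locus$fixed_cut_pos <= locus$variable_cut_pos

  with_seed(cfg$seed, {
    if (!is.null(truth$alleles)) {
      pick <- sample.int(nrow(truth$alleles), cfg$coverage, replace = TRUE)
      cls <- truth$alleles$class[pick]
      ind_f <- truth$alleles$indel_fixed[pick]
      ind_v <- truth$alleles$indel_var[pick]
    } else {
      cls <- sample(allele_classes, cfg$coverage, replace = TRUE,
                    prob = truth$counts / sum(truth$counts))
      ind_f <- ind_v <- rep(NA_integer_, cfg$coverage)
    }
    reads <- character(cfg$coverage)
    for (i in seq_len(cfg$coverage)) {
      ci <- cls[i]
      if (ci == "inversion") {
        insL <- random_dna(draw_sizes(model$junction_insert_dist, 1L))
        insR <- random_dna(draw_sizes(model$junction_insert_dist, 1L))
        reads[i] <- paste0(left, insL, revcomp(mid), insR, right)
      } else if (ci == "deletion") {
        ins <- random_dna(draw_sizes(model$junction_insert_dist, 1L))
        reads[i] <- paste0(left, ins, right)
      } else {
        r <- seg
        # apply the rightmost cut first so coordinates stay valid
        sz_l <- if (fixed_is_left) ind_f[i] else ind_v[i]
        sz_r <- if (fixed_is_left) ind_v[i] else ind_f[i]
        r <- apply_cut_indel(r, cut_r, sz_r)
        r <- apply_cut_indel(r, cut_l, sz_l)
        reads[i] <- r
      }
    }
    flip <- stats::runif(cfg$coverage) < 0.5
    if (any(flip)) reads[flip] <- revcomp(reads[flip])
    reads <- apply_seq_errors(reads, cfg$substitution_error_rate, cfg$indel_error_rate)
    list(
      reads = reads,
      labels = data.frame(read_id = sprintf("lread_%06d", seq_len(cfg$coverage)),
                          class = cls,
                          orientation = ifelse(flip, "-", "+"),
                          stringsAsFactors = FALSE)
    )
  })
}

#' Noise configuration for simulated droplet fluorescence
#'
#' @param background_mean,background_sd Gaussian background signal per channel.
#' @param positive_mean,positive_sd Gaussian signal of droplets containing at
#'   least one inversion-junction genome (emitted in both channels).
#' @param frac_invalid fraction of droplets flagged volume-invalid by the
#'   reader and excluded from analysis.
#' @return a list used by [emit_droplet_panel()].
#' @export
droplet_noise_config <- function(background_mean = 100, background_sd = 15,
                                 positive_mean = 1000, positive_sd = 60,
                                 frac_invalid = 0.02) {
  check_prob(frac_invalid, "frac_invalid")
  if (background_sd < 0 || positive_sd < 0) stop("noise sds must be >= 0", call. = FALSE)
  list(background_mean = background_mean, background_sd = background_sd,
       positive_mean = positive_mean, positive_sd = positive_sd,
       frac_invalid = frac_invalid)
}

#' Simulate a crystal digital PCR droplet panel from an allele population
#'
#' The genome copies implied by the loaded DNA mass are partitioned over the
#' droplets: each copy lands in droplet j with probability
#' `droplet_vol / loaded_vol` (multinomial partitioning over the loaded
#' volume, which converges to independent Poisson occupancy at the usual
#' volume fractions). Copies carrying the inversion junction are drawn
#' binomially from the truth's carrier fraction; a droplet holding at least
#' one junction copy fluoresces high in both probe channels (FAM and Cy-5
#' analogues), all others emit background. A configurable fraction of
#' droplets is flagged volume-invalid.
#'
#' @param truth an [allele_truth()]; only the inversion-carrier fraction is
#'   used.
#' @param dna_mass_g DNA mass loaded (grams).
#' @param loaded_vol_uL total reaction volume loaded on the chip (default
#'   25 uL, the standard master-mix volume).
#' @param droplet_vol_nL droplet volume (default 0.59 nL).
#' @param n_droplets number of droplets formed; their total volume must not
#'   exceed the loaded volume.
#' @param noise_cfg a [droplet_noise_config()].
#' @param seed integer seed.
#' @param gm a [genome_model()] converting mass to copies.
#' @return a `droplet_panel`: data frame with columns `droplet_id`,
#'   `volume_nl`, `ch1`, `ch2`, `valid`, plus attributes `panel_truth` (list:
#'   loaded copies, junction copies loaded/captured, carrier fraction) for
#'   estimator-recovery checks.
#' @export
emit_droplet_panel <- function(truth, dna_mass_g,
                               loaded_vol_uL = 25, droplet_vol_nL = 0.59,
                               n_droplets = 25000L,
                               noise_cfg = droplet_noise_config(),
                               seed = 1L,
                               gm = genome_model()) {
  stopifnot(inherits(truth, "allele_truth"))
  if (dna_mass_g < 0 || loaded_vol_uL <= 0 || droplet_vol_nL <= 0) {
    stop("mass and volumes must be non-negative (volumes strictly positive)",
         call. = FALSE)
  }
  loaded_vol_nL <- loaded_vol_uL * 1000
  if (droplet_vol_nL * n_droplets > loaded_vol_nL + 1e-9) {
    stop("total droplet volume exceeds the loaded volume", call. = FALSE)
  }
  copies <- round(genome_copies(dna_mass_g, gm))
  f <- truth$counts[["inversion"]] / sum(truth$counts)
  with_seed(seed, {
    n_junction <- stats::rbinom(1L, copies, f)
    capture_frac <- droplet_vol_nL * n_droplets / loaded_vol_nL
    n_captured <- stats::rbinom(1L, n_junction, capture_frac)
    per_droplet <- if (n_captured > 0L) {
      as.integer(stats::rmultinom(1L, n_captured, rep(1, n_droplets)))
    } else {
      integer(n_droplets)
    }
    positive <- per_droplet > 0L
    ch <- function() {
      s <- stats::rnorm(n_droplets, noise_cfg$background_mean, noise_cfg$background_sd)
      s[positive] <- stats::rnorm(sum(positive), noise_cfg$positive_mean,
                                  noise_cfg$positive_sd)
      s
    }
    panel <- data.frame(
      droplet_id = sprintf("d%06d", seq_len(n_droplets)),
      volume_nl = droplet_vol_nL,
      ch1 = ch(), ch2 = ch(),
      valid = stats::runif(n_droplets) >= noise_cfg$frac_invalid,
      stringsAsFactors = FALSE
    )
    attr(panel, "panel_truth") <- list(
      genome_copies_loaded = copies,
      junction_copies_loaded = n_junction,
      junction_copies_captured = n_captured,
      carrier_fraction = f,
      n_positive_droplets = sum(positive)
    )
    class(panel) <- c("droplet_panel", "data.frame")
    panel
  })
}
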