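#' Describe a pair of Cas9 cut sites on one chromosome
#'
#' A locus pair holds the reference sequence spanning two SpCas9 target sites —
#' a "fixed" (internal reference) site and a "variable" (interval-defining)
#' site — together with their protospacers, PAMs, strands and blunt-cut
#' positions. All junction coordinates used by the simulator and the junction
#' caller derive from this object.
#'
#' Cut positions use the SpCas9 blunt-cut convention: the enzyme cuts between
#' protospacer positions 17 and 18, i.e. 3 bp 5' of the PAM on the protospacer
#' strand. `fixed_cut_pos` is the 1-based position of the base immediately 5'
#' of the cut on the plus strand of `ref_segment` (the cut falls between
#' `cut_pos` and `cut_pos + 1`).
#'
#' @param chrom_name chromosome label.
#' @param ref_segment plus-strand reference sequence covering both sites
#'   (character scalar, A/C/G/T).
#' @param fixed_cut_pos,variable_cut_pos 1-based blunt-cut positions within
#'   `ref_segment`; must be distinct and interior.
#' @param fixed_protospacer,variable_protospacer lists with elements `seq`
#'   (20-nt protospacer), `pam` (3-nt PAM) and `strand` (`"+"` or `"-"`),
#'   given on the protospacer strand. Validated against `ref_segment`.
#' @return an object of class `locus_pair` with an `interval_bp` field equal to
#'   the distance between the two cuts.
#' @seealso [simulate_locus_pair()] to generate a synthetic locus,
#'   [build_queries()] for junction-flank extraction.
#' @export
locus_pair <- function(chrom_name, ref_segment, fixed_cut_pos, variable_cut_pos,
                       fixed_protospacer, variable_protospacer) {
  ref_segment <- toupper(as.character(ref_segment))
  n <- nchar(ref_segment)
  if (n < 40L) stop("`ref_segment` is too short to host two cut sites", call. = FALSE)
  if (!grepl("^[ACGT]+$", ref_segment)) {
    stop("`ref_segment` must contain only A/C/G/T", call. = FALSE)
  }
  for (p in c(fixed_cut_pos, variable_cut_pos)) {
    if (p < 1L || p >= n) stop("cut positions must lie inside `ref_segment`", call. = FALSE)
  }
  if (fixed_cut_pos == variable_cut_pos) {
    stop("cut positions must be distinct", call. = FALSE)
  }
  validate_protospacer(ref_segment, fixed_cut_pos, fixed_protospacer, "fixed")
  validate_protospacer(ref_segment, variable_cut_pos, variable_protospacer, "variable")
  structure(
    list(
      chrom_name = chrom_name,
      ref_segment = ref_segment,
      fixed_cut_pos = as.integer(fixed_cut_pos),
      variable_cut_pos = as.integer(variable_cut_pos),
      fixed_protospacer = fixed_protospacer,
      variable_protospacer = variable_protospacer,
      interval_bp = abs(as.integer(variable_cut_pos) - as.integer(fixed_cut_pos))
    ),
    class = "locus_pair"
  )
}

# Check that a protospacer + PAM + strand is consistent with the stated
# blunt-cut position (3 bp 5' of the PAM on the protospacer strand).
validate_protospacer <- function(ref_segment, cut_pos, ps, label) {
  if (!is.list(ps) || !all(c("seq", "pam", "strand") %in% names(ps))) {
    stop(sprintf("`%s_protospacer` must list `seq`, `pam` and `strand`", label),
         call. = FALSE)
  }
  ps$seq <- toupper(ps$seq); ps$pam <- toupper(ps$pam)
  if (nchar(ps$seq) != 20L) stop(sprintf("%s protospacer must be 20 nt", label), call. = FALSE)
  if (nchar(ps$pam) != 3L) stop(sprintf("%s PAM must be 3 nt", label), call. = FALSE)
  if (!ps$strand %in% c("+", "-")) stop(sprintf("%s strand must be '+' or '-'", label), call. = FALSE)
  expected <- paste0(ps$seq, ps$pam)
  if (ps$strand == "+") {
    # protospacer occupies cut_pos-16 .. cut_pos+3, PAM cut_pos+4 .. cut_pos+6
    start <- cut_pos - 16L
    if (start < 1L || cut_pos + 6L > nchar(ref_segment)) {
      stop(sprintf("%s protospacer/PAM extends beyond `ref_segment`", label), call. = FALSE)
    }
    found <- substr(ref_segment, start, cut_pos + 6L)
  } else {
    # on the minus strand the PAM sits at cut_pos-5 .. cut_pos-3 (genomic),
    # protospacer at cut_pos-2 .. cut_pos+17; cut between cut_pos and cut_pos+1
    start <- cut_pos - 5L
    if (start < 1L || cut_pos + 17L > nchar(ref_segment)) {
      stop(sprintf("%s protospacer/PAM extends beyond `ref_segment`", label), call. = FALSE)
    }
    found <- revcomp(substr(ref_segment, start, cut_pos + 17L))
  }
  if (!identical(found, expected)) {
    stop(sprintf(
      "%s protospacer+PAM does not match `ref_segment` at the stated cut position (cut must be 3 bp 5' of the PAM)",
      label), call. = FALSE)
  }
  invisible(TRUE)
}

#' Generate a synthetic locus pair with a given inter-cut distance
#'
#' Builds a random reference segment with two plus-strand SpCas9 sites
#' (NGG PAMs planted at the required offsets) separated by `interval_bp`.
#' Useful as the substrate for read and droplet simulation.
#'
#' @param interval_bp distance between the two blunt cuts (bp, > 0).
#' @param margin_bp reference sequence retained on the outer side of each cut
#'   (default 150 bp; must be at least 30 to leave room for protospacer,
#'   PAM and junction flanks).
#' @param seed integer seed for the random sequence.
#' @param chrom_name chromosome label (default `"chr6"`, the chromosome
#'   targeted in the tomato experiments this package models).
#' @return a [locus_pair()] whose fixed cut sits at `margin_bp` and variable
#'   cut at `margin_bp + interval_bp`.
#' @examples
#' lp <- simulate_locus_pair(1000, seed = 1)
#' lp$interval_bp
#' @export
simulate_locus_pair <- function(interval_bp, margin_bp = 150L, seed = 1L,
                                chrom_name = "chr6") {
  interval_bp <- as.integer(interval_bp)
  margin_bp <- as.integer(margin_bp)
  if (interval_bp < 40L) stop("`interval_bp` must be at least 40", call. = FALSE)
  if (margin_bp < 30L) stop("`margin_bp` must be at least 30", call. = FALSE)
  with_seed(seed, {
    len <- 2L * margin_bp + interval_bp
    seg <- strsplit(random_dna(len), "", fixed = TRUE)[[1L]]
    cut_f <- margin_bp
    cut_v <- margin_bp + interval_bp
    # plant NGG PAMs 3 bp 3' of each cut on the plus strand
    seg[cut_f + 5L] <- "G"; seg[cut_f + 6L] <- "G"
    seg[cut_v + 5L] <- "G"; seg[cut_v + 6L] <- "G"
    seg <- paste(seg, collapse = "")
    proto <- function(cut) {
      list(seq = substr(seg, cut - 16L, cut + 3L),
           pam = substr(seg, cut + 4L, cut + 6L),
           strand = "+")
    }
    locus_pair(chrom_name, seg, cut_f, cut_v, proto(cut_f), proto(cut_v))
  })
}

#' @export
print.locus_pair <- function(x, ...) {
  cat("Dual-gRNA locus pair on", x$chrom_name, "\n")
  cat(sprintf("  segment: %d bp; fixed cut @ %d, variable cut @ %d (interval %d bp)\n",
              nchar(x$ref_segment), x$fixed_cut_pos, x$variable_cut_pos, x$interval_bp))
  cat(sprintf("  fixed gRNA:    %s %s (%s)\n", x$fixed_protospacer$seq,
              x$fixed_protospacer$pam, x$fixed_protospacer$strand))
  cat(sprintf("  variable gRNA: %s %s (%s)\n", x$variable_protospacer$seq,
              x$variable_protospacer$pam, x$variable_protospacer$strand))
  invisible(x)
}
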