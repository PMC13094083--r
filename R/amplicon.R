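#' Configuration for windowed indel calling at a cut site
#'
#' The quantification window is the two nucleotides flanking the blunt cut,
#' extended on both sides by a buffer: a read counts as mutated when it
#' carries at least one insertion or deletion intersecting
#' `[cut_pos - cut_buffer_bp, cut_pos + 1 + cut_buffer_bp]` (1-based, closed).
#' Substitutions never count.
#'
#' @param cut_window_nt width of the core cut window (default 2 nt, the bases
#'   either side of the blunt cut).
#' @param cut_buffer_bp buffer added on each side of the core window
#'   (default 4 bp).
#' @param min_reads minimum reads for the call to pass QC (default 100).
#' @param match,mismatch,gap_open,gap_extend global-alignment scoring
#'   (defaults +2/-2/-6/-1; gap penalties given as positive costs).
#' @return an object of class `indel_call_config`.
#' @export
indel_call_config <- function(cut_window_nt = 2L, cut_buffer_bp = 4L,
                              min_reads = 100L,
                              match = 2, mismatch = -2,
                              gap_open = 6, gap_extend = 1) {
  if (cut_window_nt < 1L) stop("`cut_window_nt` must be >= 1", call. = FALSE)
  if (cut_buffer_bp < 0L) stop("`cut_buffer_bp` must be >= 0", call. = FALSE)
  structure(list(cut_window_nt = as.integer(cut_window_nt),
                 cut_buffer_bp = as.integer(cut_buffer_bp),
                 min_reads = as.integer(min_reads),
                 match = match, mismatch = mismatch,
                 gap_open = gap_open, gap_extend = gap_extend),
            class = "indel_call_config")
}

#' Globally align a read to its reference amplicon and list indel events
#'
#' Needleman-Wunsch alignment with affine gap costs (via
#' \code{Biostrings::pairwiseAlignment}), followed by extraction of an ordered
#' event list in 1-based reference coordinates. Deletions report the deleted
#' reference span; insertions report the reference position immediately 5' of
#' the inserted bases. Reads shorter than 30% of the reference are flagged
#' discarded rather than aligned.
#'
#' @param read,ref_amplicon DNA sequences (character scalars).
#' @param cfg an [indel_call_config()].
#' @return a list with `score`, `discarded`, and `events`: a data frame with
#'   columns `type` (`"insertion"`/`"deletion"`/`"substitution"`), `start`,
#'   `end` (reference span), `size`.
#' @export
align_to_reference <- function(read, ref_amplicon, cfg = indel_call_config()) {
  if (!nzchar(read) || !nzchar(ref_amplicon)) {
    stop("`read` and `ref_amplicon` must be non-empty", call. = FALSE)
  }
  if (nchar(read) < 0.3 * nchar(ref_amplicon)) {
    return(list(score = NA_real_, discarded = TRUE,
                events = empty_events()))
  }
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = cfg$match,
                                                  mismatch = cfg$mismatch,
                                                  baseOnly = TRUE)
  aln <- Biostrings::pairwiseAlignment(pattern = read, subject = ref_amplicon,
                                       type = "global",
                                       substitutionMatrix = mat,
                                       gapOpening = cfg$gap_open,
                                       gapExtension = cfg$gap_extend)
  p <- strsplit(as.character(Biostrings::alignedPattern(aln)), "", fixed = TRUE)[[1L]]
  s <- strsplit(as.character(Biostrings::alignedSubject(aln)), "", fixed = TRUE)[[1L]]
  list(score = Biostrings::score(aln), discarded = FALSE,
       events = gapped_events(p, s))
}

empty_events <- function() {
  data.frame(type = character(0), start = integer(0), end = integer(0),
             size = integer(0), stringsAsFactors = FALSE)
}

# Walk a pair of gapped alignment strings (pattern = read, subject = ref) and
# emit substitution/insertion/deletion events in reference coordinates.
gapped_events <- function(p, s) {
  state <- ifelse(p == "-", "D", ifelse(s == "-", "I", ifelse(p == s, "M", "S")))
  refpos <- cumsum(s != "-")          # reference coordinate at each column
  r <- rle(state)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values != "M"
  if (!any(keep)) return(empty_events())
  out <- lapply(which(keep), function(i) {
    cols <- starts[i]:ends[i]
    v <- r$values[i]
    if (v == "D") {
      data.frame(type = "deletion", start = refpos[starts[i]],
                 end = refpos[ends[i]], size = length(cols),
                 stringsAsFactors = FALSE)
    } else if (v == "I") {
      # inserted between ref positions pos and pos+1
      pos <- if (starts[i] == 1L) 0L else refpos[starts[i] - 1L]
      data.frame(type = "insertion", start = pos, end = pos + 1L,
                 size = length(cols), stringsAsFactors = FALSE)
    } else {
      data.frame(type = "substitution", start = refpos[starts[i]],
                 end = refpos[ends[i]], size = length(cols),
                 stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, out)
}

#' Per-site mutation frequency from amplicon reads
#'
#' Aligns every read to the reference amplicon and scores it as mutated when
#' it carries at least one insertion or deletion whose reference span
#' intersects the cut window (see [indel_call_config()]). Identical reads are
#' aligned once and weighted by multiplicity. Returns the raw frequency
#' `mutated / aligned` together with a table of qualifying indel events.
#'
#' @param reads character vector of reads (or `DNAStringSet`).
#' @param ref_amplicon reference amplicon sequence.
#' @param cut_pos 1-based position of the base immediately 5' of the blunt
#'   cut in `ref_amplicon`.
#' @param cfg an [indel_call_config()].
#' @param site optional site label carried through to the result.
#' @return an object of class `site_mutation_call` with fields `site`,
#'   `n_reads`, `n_discarded`, `n_reads_with_qualifying_indel`,
#'   `raw_frequency`, `control_adjusted_frequency` (`NA` until
#'   [control_subtract()]), `events` (type/position/size/count) and `qc_pass`.
#' @export
site_mutation_frequency <- function(reads, ref_amplicon, cut_pos,
                                    cfg = indel_call_config(), site = "site") {
  reads <- as.character(reads)
  if (length(reads) < 1L) stop("need at least one read", call. = FALSE)
  cut_pos <- as.integer(cut_pos)
  if (cut_pos < 1L || cut_pos >= nchar(ref_amplicon)) {
    stop("`cut_pos` must lie inside the reference amplicon", call. = FALSE)
  }
  win_lo <- cut_pos - cfg$cut_buffer_bp
  win_hi <- cut_pos + 1L + cfg$cut_buffer_bp

  tab <- table(reads)
  uniq <- names(tab)
  counts <- as.integer(tab)
  keys_per_read <- vector("list", length(uniq))
  discarded <- logical(length(uniq))
  for (i in seq_along(uniq)) {
    al <- align_to_reference(uniq[i], ref_amplicon, cfg)
    if (al$discarded) { discarded[i] <- TRUE; next }
    ev <- al$events
    ev <- ev[ev$type %in% c("insertion", "deletion") &
               ev$start <= win_hi & ev$end >= win_lo, , drop = FALSE]
    if (nrow(ev)) {
      sz <- ifelse(ev$type == "deletion", -ev$size, ev$size)
      keys_per_read[[i]] <- sprintf("%s:%d:%+d", ev$type, ev$start, sz)
    } else {
      keys_per_read[[i]] <- character(0)
    }
  }
  n_disc <- sum(counts[discarded])
  n_aligned <- sum(counts) - n_disc
  if (n_aligned == 0L) stop("all reads discarded (too short to align)", call. = FALSE)
  mutated <- !discarded & lengths(keys_per_read) > 0L
  n_mut <- sum(counts[mutated])

  key_counts <- tapply(
    rep(counts, lengths(keys_per_read)),
    unlist(keys_per_read),
    sum
  )
  events <- if (length(key_counts)) {
    parts <- strsplit(names(key_counts), ":", fixed = TRUE)
    data.frame(type = vapply(parts, `[`, "", 1L),
               position = as.integer(vapply(parts, `[`, "", 2L)),
               size = as.integer(vapply(parts, `[`, "", 3L)),
               count = as.integer(key_counts),
               stringsAsFactors = FALSE)
  } else {
    data.frame(type = character(0), position = integer(0), size = integer(0),
               count = integer(0), stringsAsFactors = FALSE)
  }

  structure(
    list(site = site,
         n_reads = n_aligned,
         n_discarded = n_disc,
         n_reads_with_qualifying_indel = n_mut,
         raw_frequency = n_mut / n_aligned,
         control_adjusted_frequency = NA_real_,
         events = events[order(events$position, events$type, events$size), ,
                         drop = FALSE],
         qc_pass = n_aligned >= cfg$min_reads,
         window = c(win_lo, win_hi),
         .unique = list(keys = keys_per_read[!discarded],
                        counts = counts[!discarded])),
    class = "site_mutation_call"
  )
}

#' Subtract background events observed in negative controls
#'
#' Event classes (type, position, size) whose pooled frequency in the
#' negative controls reaches `threshold` times their frequency in the sample
#' are treated as background (PCR/sequencing artefacts or pre-existing
#' variants) and removed before the mutated-read fraction is recomputed over
#' the surviving event classes. The adjusted frequency is clamped to [0, 1];
#' it can exceed the raw frequency only in degenerate configurations, never
#' drop below 0.
#'
#' @param sample a `site_mutation_call` for the edited sample.
#' @param controls list of `site_mutation_call`s from negative-control
#'   samples computed on the same reference window.
#' @param threshold control-to-sample frequency ratio at which an event class
#'   is removed (default 0.5).
#' @return the sample call with `control_adjusted_frequency` filled in,
#'   `events` reduced to retained classes, and a `control_flag` field
#'   (`"ok"`, or `"no_controls"` when `controls` is empty).
#' @export
control_subtract <- function(sample, controls, threshold = 0.5) {
  stopifnot(inherits(sample, "site_mutation_call"))
  if (length(controls) == 0L) {
    warning("no negative controls supplied; frequencies passed through unadjusted")
    sample$control_adjusted_frequency <- sample$raw_frequency
    sample$control_flag <- "no_controls"
    return(sample)
  }
  ctrl_reads <- sum(vapply(controls, function(c) c$n_reads, numeric(1)))
  ctrl_events <- do.call(rbind, lapply(controls, function(c) c$events))
  ctrl_freq <- if (!is.null(ctrl_events) && nrow(ctrl_events)) {
    tapply(ctrl_events$count,
           sprintf("%s:%d:%+d", ctrl_events$type, ctrl_events$position,
                   ctrl_events$size),
           sum) / ctrl_reads
  } else {
    numeric(0)
  }
  ev <- sample$events
  if (nrow(ev)) {
    keys <- sprintf("%s:%d:%+d", ev$type, ev$position, ev$size)
    samp_freq <- ev$count / sample$n_reads
    cf <- ifelse(keys %in% names(ctrl_freq), ctrl_freq[keys], 0)
    drop_keys <- keys[cf >= threshold * samp_freq]
  } else {
    drop_keys <- character(0)
  }
  retained <- lapply(sample$.unique$keys, setdiff, y = drop_keys)
  n_mut <- sum(sample$.unique$counts[lengths(retained) > 0L])
  adj <- max(0, min(1, n_mut / sample$n_reads))
  sample$control_adjusted_frequency <- adj
  if (nrow(ev)) {
    keep <- !(sprintf("%s:%d:%+d", ev$type, ev$position, ev$size) %in% drop_keys)
    sample$events <- ev[keep, , drop = FALSE]
  }
  sample$control_flag <- "ok"
  sample
}

#' @export
print.site_mutation_call <- function(x, ...) {
  cat(sprintf("Site mutation call [%s]\n", x$site))
  cat(sprintf("  reads: %d aligned (%d discarded) — QC %s\n",
              x$n_reads, x$n_discarded, if (x$qc_pass) "pass" else "FAIL"))
  cat(sprintf("  reads with qualifying indel: %d (raw frequency %.4g)\n",
              x$n_reads_with_qualifying_indel, x$raw_frequency))
  if (!is.na(x$control_adjusted_frequency)) {
    cat(sprintf("  control-adjusted frequency: %.4g\n",
                x$control_adjusted_frequency))
  }
  cat(sprintf("  %d distinct indel event classes in window [%d, %d]\n",
              nrow(x$events), x$window[1], x$window[2]))
  invisible(x)
}
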