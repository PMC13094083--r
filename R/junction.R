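#' Build junction flank queries for a dual-cut locus
#'
#' For each double-strand break the scan targets two short flanks (default
#' 16 bp) spaced `spacing` bp apart with the cut centred between them, so
#' that small deletions at the cut shrink — and insertions grow — the
#' inter-flank gap without touching the flanks themselves. Five queries are
#' emitted: the two wild-type junctions, the two inversion junctions (outer
#' flank joined to the reverse complement of the interval-side flank at each
#' border), and the single fused deletion junction joining the two outer
#' flanks.
#'
#' A read matches a query when its left flank is followed by its right flank
#' separated by any `gap_min`..`gap_max` bases, where
#' `gap_max = (spacing - 2 * flank_len) + max_insert`: an insertion of
#' exactly `max_insert` bp at the cut is still matched, one base more is not.
#'
#' @param locus a [locus_pair()].
#' @param flank_len flank length (default 16 bp).
#' @param spacing outer-edge to outer-edge distance between the two flanks of
#'   one junction (default 60 bp, cut centred).
#' @param max_insert largest insertion tolerated at a junction (default
#'   80 bp).
#' @return an object of class `junction_queries`: data frame with columns
#'   `label` (`wt_left`, `wt_right`, `inv_left`, `inv_right`, `del`),
#'   `left_flank`, `right_flank`, `gap_min`, `gap_max`.
#' @export
build_queries <- function(locus, flank_len = 16L, spacing = 60L,
                          max_insert = 80L) {
  stopifnot(inherits(locus, "locus_pair"))
  flank_len <- as.integer(flank_len); spacing <- as.integer(spacing)
  max_insert <- as.integer(max_insert)
  if (2L * flank_len > spacing) {
    stop("`spacing` must be at least twice `flank_len`", call. = FALSE)
  }
  half <- spacing %/% 2L
  nominal_gap <- spacing - 2L * flank_len
  seg <- locus$ref_segment
  cut_l <- min(locus$fixed_cut_pos, locus$variable_cut_pos)
  cut_r <- max(locus$fixed_cut_pos, locus$variable_cut_pos)
  if (cut_l - half < 0L || cut_r + half > nchar(seg)) {
    stop("cut site too close to the segment end to extract junction flanks",
         call. = FALSE)
  }
  if (locus$interval_bp <= nominal_gap + max_insert) {
    warning("interval is within the scan's gap tolerance; the deletion query ",
            "cannot be distinguished from wild type")
  }
  left <- substr(seg, 1L, cut_l)
  mid <- substr(seg, cut_l + 1L, cut_r)
  right <- substr(seg, cut_r + 1L, nchar(seg))
  inv_product <- paste0(left, revcomp(mid), right)
  del_product <- paste0(left, right)

  flanks <- function(product, j) {
    c(left_flank = substr(product, j - half + 1L, j - half + flank_len),
      right_flank = substr(product, j + half - flank_len + 1L, j + half))
  }
  rows <- rbind(
    c(label = "wt_left", flanks(seg, cut_l)),
    c(label = "wt_right", flanks(seg, cut_r)),
    c(label = "inv_left", flanks(inv_product, cut_l)),
    c(label = "inv_right", flanks(inv_product, cut_l + nchar(mid))),
    c(label = "del", flanks(del_product, cut_l))
  )
  q <- as.data.frame(rows, stringsAsFactors = FALSE)
  q$gap_min <- 0L
  q$gap_max <- nominal_gap + max_insert
  attr(q, "flank_len") <- flank_len
  attr(q, "spacing") <- spacing
  attr(q, "max_insert") <- max_insert
  attr(q, "nominal_gap") <- nominal_gap
  class(q) <- c("junction_queries", "data.frame")
  q
}

# Vectorised query matching: returns a logical matrix reads x queries, where
# a hit on either strand counts (long-read orientation is random).
match_queries <- function(reads, queries) {
  rc <- revcomp(reads)
  m <- matrix(FALSE, nrow = length(reads), ncol = nrow(queries),
              dimnames = list(NULL, queries$label))
  for (j in seq_len(nrow(queries))) {
    pat <- sprintf("%s[ACGTN]{%d,%d}%s",
                   queries$left_flank[j], queries$gap_min[j],
                   queries$gap_max[j], queries$right_flank[j])
    m[, j] <- grepl(pat, reads, perl = TRUE) | grepl(pat, rc, perl = TRUE)
  }
  m
}

# Precedence rules turning a row of query hits into one label.
label_from_hits <- function(hits) {
  inv_any <- hits["inv_left"] | hits["inv_right"]
  if (inv_any && hits["del"]) return("other")        # chimeric
  if (hits["inv_left"] && hits["inv_right"]) return("complete_inversion")
  if (inv_any) return("inversion")
  if (hits["del"]) return("deletion")
  if (hits["wt_left"] && hits["wt_right"]) return("wild_type")
  "other"
}

#' Classify a single long read against the junction queries
#'
#' Scans the read and its reverse complement for each query's flank pair and
#' applies the label precedence: `complete_inversion` (both inversion
#' junctions) > `inversion` (one) > `deletion` > `wild_type` (both wild-type
#' junctions) > `other`. Reads matching both inversion and deletion queries
#' are chimeric and labelled `other`. The call is strand-symmetric by
#' construction.
#'
#' @param read DNA sequence (character scalar), at least two flank lengths
#'   long.
#' @param queries a [build_queries()] object.
#' @return an object of class `read_call`: list with `label`, `matched`
#'   (labels of all matching queries) and `signature` (inter-flank junction
#'   sequence(s), used for unique-event deduplication; `NA` for
#'   non-rearranged reads).
#' @export
scan_read <- function(read, queries) {
  stopifnot(inherits(queries, "junction_queries"))
  if (nchar(read) < 2L * attr(queries, "flank_len")) {
    stop("read shorter than two flank lengths", call. = FALSE)
  }
  hits <- match_queries(read, queries)[1L, ]
  label <- label_from_hits(hits)
  structure(list(label = label,
                 matched = queries$label[hits],
                 signature = junction_signature(read, queries, label)),
            class = "read_call")
}

# Junction signature: concatenated inter-flank sequences of the matched
# rearrangement queries (inversion borders or the deletion junction),
# extracted from whichever strand matches. NA for non-rearranged labels.
junction_signature <- function(read, queries, label) {
  idx <- switch(label,
                complete_inversion = ,
                inversion = which(queries$label %in% c("inv_left", "inv_right")),
                deletion = which(queries$label == "del"),
                return(NA_character_))
  sigs <- character(0)
  for (j in idx) {
    pat <- sprintf("%s([ACGTN]{%d,%d})%s",
                   queries$left_flank[j], queries$gap_min[j],
                   queries$gap_max[j], queries$right_flank[j])
    for (x in c(read, revcomp(read))) {
      m <- regmatches(x, regexec(pat, x, perl = TRUE))[[1L]]
      if (length(m) == 2L) { sigs <- c(sigs, paste0(queries$label[j], "=", m[2L])); break }
    }
  }
  if (!length(sigs)) NA_character_ else paste(sigs, collapse = ";")
}

read_call_levels <- c("wild_type", "inversion", "complete_inversion",
                      "deletion", "other")

#' Classify a set of long reads and summarise rearrangement frequencies
#'
#' Applies [scan_read()] logic to every read (vectorised), then tabulates
#' per-label counts and frequencies, deduplicates rearranged reads into
#' unique junction events by their exact inter-flank sequence, and reports
#' the deletion:inversion read ratio (deletions over inversion-junction
#' reads, complete or single-border) when inversions were observed.
#'
#' @param reads character vector (or `DNAStringSet`) of long reads.
#' @param queries a [build_queries()] object.
#' @return an object of class `junction_calls`: list with `calls` (data frame
#'   `read_id`, `label`, `signature`), `counts`, `frequencies`,
#'   `unique_events` (data frame `label`, `signature`, `n_reads`),
#'   `del_inv_ratio` (`NA` with `ratio_defined = FALSE` when no inversion
#'   reads were seen) and `n_reads`.
#' @examples
#' lp <- simulate_locus_pair(300, seed = 2)
#' q <- build_queries(lp)
#' truth <- allele_truth(c(wild_type = 1800, inversion = 100, deletion = 100))
#' lr <- emit_long_reads(truth, lp, outcome_model(),
#'                       read_sim_config(coverage = 500, seed = 3,
#'                                       substitution_error_rate = 0,
#'                                       indel_error_rate = 0))
#' classify_readset(lr$reads, q)
#' @export
classify_readset <- function(reads, queries) {
  stopifnot(inherits(queries, "junction_queries"))
  reads <- as.character(reads)
  if (length(reads) < 1L) stop("empty read set", call. = FALSE)
  hits <- match_queries(reads, queries)
  labels <- apply(hits, 1L, label_from_hits)
  rearranged <- which(labels %in% c("inversion", "complete_inversion", "deletion"))
  sigs <- rep(NA_character_, length(reads))
  for (i in rearranged) {
    sigs[i] <- junction_signature(reads[i], queries, labels[i])
  }
  counts <- table(factor(labels, levels = read_call_levels))
  counts <- stats::setNames(as.integer(counts), read_call_levels)
  n <- length(reads)
  inv_reads <- counts[["inversion"]] + counts[["complete_inversion"]]
  ratio_defined <- inv_reads > 0L
  uniq <- if (length(rearranged)) {
    key <- paste(labels[rearranged], sigs[rearranged], sep = "|")
    agg <- table(key)
    parts <- strsplit(names(agg), "|", fixed = TRUE)
    data.frame(label = vapply(parts, `[`, "", 1L),
               signature = vapply(parts, `[`, "", 2L),
               n_reads = as.integer(agg), stringsAsFactors = FALSE)
  } else {
    data.frame(label = character(0), signature = character(0),
               n_reads = integer(0), stringsAsFactors = FALSE)
  }
  structure(
    list(calls = data.frame(read_id = sprintf("r%06d", seq_len(n)),
                            label = labels, signature = sigs,
                            stringsAsFactors = FALSE),
         counts = counts,
         frequencies = counts / n,
         unique_events = uniq,
         del_inv_ratio = if (ratio_defined) counts[["deletion"]] / inv_reads
                         else NA_real_,
         ratio_defined = ratio_defined,
         n_reads = n),
    class = "junction_calls"
  )
}

#' @export
print.junction_calls <- function(x, ...) {
  cat(sprintf("Junction calls over %d long reads\n", x$n_reads))
  for (l in read_call_levels) {
    cat(sprintf("  %-19s %8d  (%.4g%%)\n", l, x$counts[[l]],
                100 * x$frequencies[[l]]))
  }
  cat(sprintf("  unique rearrangement events: %d\n", nrow(x$unique_events)))
  if (x$ratio_defined) {
    cat(sprintf("  deletion:inversion read ratio: %.3g\n", x$del_inv_ratio))
  } else {
    cat("  deletion:inversion ratio undefined (no inversion reads)\n")
  }
  invisible(x)
}
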