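# Internal helpers shared across modules.

#' Evaluate an expression under a fixed RNG seed without touching global state
#'
#' All stochastic operations in the package take an explicit seed; the caller's
#' `.Random.seed` is saved and restored so no function leaks random state.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Reverse complement of a character vector of DNA strings.
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# n random bases (character scalar); uses the current RNG stream.
random_dna <- function(n) {
  if (n <= 0) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Draw k sizes from a categorical size distribution given as a named numeric
# vector (names = integer sizes, values = probabilities).
draw_sizes <- function(dist, k) {
  if (k == 0L) return(integer(0))
  sizes <- as.integer(names(dist))
  sizes[sample.int(length(sizes), k, replace = TRUE, prob = as.numeric(dist))]
}

check_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop(sprintf("`%s` must be a single probability in [0, 1]", name),
         call. = FALSE)
  }
  invisible(x)
}

check_size_dist <- function(dist, name, min_size = -Inf, max_size = Inf) {
  if (is.null(names(dist)) || anyNA(suppressWarnings(as.integer(names(dist))))) {
    stop(sprintf("`%s` must be a named numeric vector with integer-size names", name),
         call. = FALSE)
  }
  sizes <- as.integer(names(dist))
  if (any(sizes < min_size) || any(sizes > max_size)) {
    stop(sprintf("`%s` sizes must lie in [%s, %s]", name, min_size, max_size),
         call. = FALSE)
  }
  if (any(dist < 0) || abs(sum(dist) - 1) > 1e-8) {
    stop(sprintf("`%s` probabilities must be non-negative and sum to 1", name),
         call. = FALSE)
  }
  invisible(dist)
}

# Apply per-base substitution and 1-bp indel sequencing errors to a character
# vector of reads. Vectorised over reads; uses the current RNG stream.
apply_seq_errors <- function(reads, substitution_rate, indel_rate) {
  if (substitution_rate <= 0 && indel_rate <= 0) return(reads)
  bases <- c("A", "C", "G", "T")
  vapply(reads, function(r) {
    chars <- strsplit(r, "", fixed = TRUE)[[1L]]
    n <- length(chars)
    if (substitution_rate > 0) {
      hit <- which(stats::runif(n) < substitution_rate)
      for (i in hit) chars[i] <- sample(setdiff(bases, chars[i]), 1L)
    }
    if (indel_rate > 0) {
      hit <- which(stats::runif(length(chars)) < indel_rate)
      if (length(hit)) {
        # half insertions, half deletions, applied right-to-left so earlier
        # positions stay valid
        for (i in rev(hit)) {
          if (stats::runif(1) < 0.5) {
            chars <- append(chars, sample(bases, 1L), after = i)
          } else {
            chars <- chars[-i]
          }
        }
      }
    }
    paste(chars, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}
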