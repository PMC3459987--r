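# Internal helpers shared across modules.  All genomic coordinates inside the
# package are 0-based, half-open; conversion to 1-based happens only at file
# format boundaries (wiggle, SAM) and when talking to IRanges (1-based closed).

#' @importFrom rlang abort warn .data
#' @importFrom tibble tibble as_tibble
NULL

#' Run code with a temporary RNG state
#'
#' Seeds the RNG from `seed`, runs `code`, and restores the caller's
#' `.Random.seed` afterwards, so simulation functions neither perturb nor
#' depend on the session RNG.  A `NULL` seed runs the code unchanged.
#'
#' @param seed Integer seed or `NULL`.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @export
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

# tibble(chrom, start, end) [0-based half-open] -> named list of IRanges
# (1-based closed), split by chromosome.
as_iranges_list <- function(x) {
  stopifnot(all(c("chrom", "start", "end") %in% names(x)))
  split_idx <- split(seq_len(nrow(x)), x$chrom)
  lapply(split_idx, function(i) {
    IRanges::IRanges(start = x$start[i] + 1L, end = x$end[i])
  })
}

#' Reverse complement of DNA strings
#'
#' Vectorised reverse complement for plain character DNA (IUPAC ambiguity
#' codes are complemented too).
#'
#' @param x Character vector of DNA strings (uppercase).
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  chartr(
    "ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN",
    vapply(strsplit(x, "", fixed = TRUE), function(ch) {
      paste(rev(ch), collapse = "")
    }, character(1))
  )
}

#' Hamming distance between two equal-length DNA strings
#'
#' Any position involving a non-ACGT character counts as a mismatch.
#'
#' @param a,b Equal-length DNA strings.
#' @return Integer mismatch count.
#' @export
hamming <- function(a, b) {
  va <- strsplit(a, "", fixed = TRUE)[[1]]
  vb <- strsplit(b, "", fixed = TRUE)[[1]]
  stopifnot(length(va) == length(vb))
  acgt <- c("A", "C", "G", "T")
  sum(va != vb | !(va %in% acgt) | !(vb %in% acgt))
}

# Coerce a DNAStringSet / named character vector to a named uppercase
# character vector of sequences.
as_seq_vector <- function(seqs) {
  if (methods::is(seqs, "DNAStringSet")) {
    out <- as.character(seqs)
  } else if (is.character(seqs)) {
    out <- toupper(seqs)
  } else {
    abort("`seqs` must be a DNAStringSet or a named character vector")
  }
  if (is.null(names(out)) || anyNA(names(out))) {
    abort("sequences must be named by chromosome")
  }
  out
}

# Standardise a summit table: accepts a peak tibble carrying `summit`, or a
# site tibble carrying `pos`.  Returns tibble(chrom, pos).
summit_positions <- function(x) {
  if (!"chrom" %in% names(x)) abort("expected a `chrom` column")
  if ("summit" %in% names(x)) {
    tibble(chrom = x$chrom, pos = as.integer(x$summit))
  } else if ("pos" %in% names(x)) {
    tibble(chrom = x$chrom, pos = as.integer(x$pos))
  } else {
    abort("expected a `summit` or `pos` column")
  }
}

validate_genome_lengths <- function(genome_lengths) {
  if (is.null(names(genome_lengths)) || !is.numeric(genome_lengths) ||
      length(genome_lengths) == 0 || any(genome_lengths <= 0)) {
    abort("`genome_lengths` must be a named numeric vector of positive lengths")
  }
  invisible(genome_lengths)
}
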