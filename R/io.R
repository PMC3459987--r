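#' Read a BED file into a tibble
#'
#' Parses BED3/BED6 records into 0-based half-open intervals.  `track`,
#' `browser` and `#` comment lines are skipped.  A strand of `"."` is read as
#' `NA`.
#'
#' @param path Path to a BED file.
#' @return A tibble with columns `chrom`, `start`, `end` and, when present in
#'   the file, `name`, `score`, `strand`.
#' @export
read_bed <- function(path) {
  lines <- readr::read_lines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3)) {
    bad <- lineno[which(nf < 3)[1]]
    abort(sprintf("malformed BED record (fewer than 3 fields) at line %d", bad))
  }
  ncol <- min(nf)
  get <- function(i) vapply(fields, `[[`, character(1), i)
  out <- tibble(
    chrom = get(1),
    start = suppressWarnings(as.integer(get(2))),
    end   = suppressWarnings(as.integer(get(3)))
  )
  if (anyNA(out$start) || anyNA(out$end)) {
    bad <- lineno[which(is.na(out$start) | is.na(out$end))[1]]
    abort(sprintf("non-numeric BED coordinate at line %d", bad))
  }
  if (any(out$start >= out$end)) {
    bad <- lineno[which(out$start >= out$end)[1]]
    abort(sprintf("BED interval with start >= end at line %d", bad))
  }
  if (ncol >= 4) out$name <- get(4)
  if (ncol >= 5) out$score <- suppressWarnings(as.numeric(get(5)))
  if (ncol >= 6) {
    strand <- get(6)
    strand[strand == "."] <- NA_character_
    out$strand <- strand
  }
  out
}

#' Write intervals to a BED file
#'
#' @param x A tibble with `chrom`, `start`, `end` and optionally `name`,
#'   `score`, `strand` columns (0-based half-open).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  cols <- c("chrom", "start", "end")
  stopifnot(all(cols %in% names(x)))
  out <- x[cols]
  if ("strand" %in% names(x)) {
    out$name <- if ("name" %in% names(x)) x$name else "."
    out$score <- if ("score" %in% names(x)) x$score else 0
    out$strand <- ifelse(is.na(x$strand), ".", x$strand)
    out <- out[c("chrom", "start", "end", "name", "score", "strand")]
  } else if ("name" %in% names(x)) {
    out$name <- x$name
    if ("score" %in% names(x)) out$score <- x$score
  }
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}

#' Read DNA sequences from FASTA
#'
#' Thin wrapper over [Biostrings::readDNAStringSet()]; sequences are
#' uppercased on read.
#'
#' @param path Path to a FASTA file.
#' @return A `DNAStringSet` named by sequence id (first word of the header).
#' @export
read_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  Biostrings::DNAStringSet(toupper(seqs))
}

#' Write DNA sequences to FASTA
#'
#' @param seqs A `DNAStringSet` or named character vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (!methods::is(seqs, "DNAStringSet")) {
    seqs <- Biostrings::DNAStringSet(as_seq_vector(seqs))
  }
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read paired-end alignment records from BEDPE
#'
#' @param path Path to a BEDPE file (chrom1 start1 end1 chrom2 start2 end2
#'   name score strand1 strand2; 0-based half-open).
#' @return A tibble of mate pairs.
#' @export
read_bedpe <- function(path) {
  x <- readr::read_tsv(
    path,
    col_names = c("chrom1", "start1", "end1", "chrom2", "start2", "end2",
                  "name", "score", "strand1", "strand2"),
    col_types = "ciiciicdcc",
    comment = "#"
  )
  as_tibble(x)
}

#' Write paired-end alignment records as BEDPE
#'
#' @param pairs A tibble with columns `chrom1`, `start1`, `end1`, `chrom2`,
#'   `start2`, `end2`, `strand1`, `strand2` and optionally `name`, `score`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedpe <- function(pairs, path) {
  out <- tibble(
    chrom1 = pairs$chrom1, start1 = pairs$start1, end1 = pairs$end1,
    chrom2 = pairs$chrom2, start2 = pairs$start2, end2 = pairs$end2,
    name = if ("name" %in% names(pairs)) pairs$name else ".",
    score = if ("score" %in% names(pairs)) pairs$score else 0,
    strand1 = pairs$strand1, strand2 = pairs$strand2
  )
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}

#' Read proper pairs from a minimal SAM text file
#'
#' Parses the eleven mandatory SAM columns and pairs mates by QNAME.  Only
#' primary, mapped, properly paired records are used.  Mates whose RNEXT does
#' not point back at each other's reference are an error.
#'
#' @param path Path to a SAM text file.
#' @return A tibble of mate pairs in the same layout as [read_bedpe()].
#' @export
read_sam_pairs <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[!startsWith(lines, "@") & nzchar(lines)]
  if (length(lines) == 0) return(read_bedpe_empty())
  f <- strsplit(lines, "\t", fixed = TRUE)
  qname <- vapply(f, `[[`, character(1), 1)
  flag <- as.integer(vapply(f, `[[`, character(1), 2))
  rname <- vapply(f, `[[`, character(1), 3)
  pos <- as.integer(vapply(f, `[[`, character(1), 4))
  rnext <- vapply(f, `[[`, character(1), 7)
  seq <- vapply(f, `[[`, character(1), 10)
  len <- nchar(seq)
  strand <- ifelse(bitwAnd(flag, 16L) > 0L, "-", "+")
  keep <- bitwAnd(flag, 4L) == 0L & bitwAnd(flag, 256L) == 0L
  idx <- split(which(keep), qname[keep])
  idx <- idx[lengths(idx) == 2]
  if (length(idx) == 0) return(read_bedpe_empty())
  rows <- lapply(names(idx), function(q) {
    i <- idx[[q]]
    r1 <- i[1]; r2 <- i[2]
    ok1 <- rnext[r1] == "=" || rnext[r1] == rname[r2]
    ok2 <- rnext[r2] == "=" || rnext[r2] == rname[r1]
    if (!ok1 || !ok2) {
      abort(sprintf("SAM pair '%s' has inconsistent RNEXT fields", q))
    }
    tibble(
      chrom1 = rname[r1], start1 = pos[r1] - 1L, end1 = pos[r1] - 1L + len[r1],
      chrom2 = rname[r2], start2 = pos[r2] - 1L, end2 = pos[r2] - 1L + len[r2],
      name = q, score = 0,
      strand1 = strand[r1], strand2 = strand[r2]
    )
  })
  dplyr::bind_rows(rows)
}

read_bedpe_empty <- function() {
  tibble(
    chrom1 = character(), start1 = integer(), end1 = integer(),
    chrom2 = character(), start2 = integer(), end2 = integer(),
    name = character(), score = numeric(),
    strand1 = character(), strand2 = character()
  )
}

#' Write a fragment coverage track as wiggle
#'
#' Each run of constant non-zero coverage is emitted as its own `fixedStep`
#' block (`step=1`).  Wiggle positions are 1-based, so a run covering the
#' 0-based half-open interval `[5, 10)` starts at wiggle position 6.
#'
#' @param track A coverage track tibble (`chrom`, `start`, `end`, `count`),
#'   as produced by [coverage_track()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_wig <- function(track, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("track type=wiggle_0", con)
  if (nrow(track) == 0) return(invisible(path))
  for (i in seq_len(nrow(track))) {
    writeLines(sprintf("fixedStep chrom=%s start=%d step=1",
                       track$chrom[i], track$start[i] + 1L), con)
    writeLines(rep(format(track$count[i]), track$end[i] - track$start[i]), con)
  }
  invisible(path)
}

#' Read a fixedStep wiggle file into a coverage track
#'
#' Inverse of [write_wig()]: adjacent equal values are merged back into runs
#' and positions are converted to 0-based half-open intervals.
#'
#' @param path Path to a wiggle file written by [write_wig()].
#' @return A coverage track tibble (`chrom`, `start`, `end`, `count`).
#' @export
read_wig <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[!grepl("^track", lines) & nzchar(lines)]
  chrom <- NULL
  cur_vals <- numeric(0); cur_start <- NA_integer_
  out <- list()
  push <- function(chrom, start0, values) {
    if (length(values) == 0) return()
    r <- rle(values)
    ends <- cumsum(r$lengths)
    starts <- c(0L, utils::head(ends, -1L))
    out[[length(out) + 1L]] <<- tibble(
      chrom = chrom,
      start = start0 + starts,
      end = start0 + ends,
      count = r$values
    )
  }
  for (ln in lines) {
    if (startsWith(ln, "fixedStep")) {
      push(chrom, cur_start, cur_vals)
      chrom <- sub(".*chrom=(\\S+).*", "\\1", ln)
      cur_start <- as.integer(sub(".*start=(\\d+).*", "\\1", ln)) - 1L
      cur_vals <- numeric(0)
    } else {
      cur_vals <- c(cur_vals, as.numeric(ln))
    }
  }
  push(chrom, cur_start, cur_vals)
  if (length(out) == 0) {
    return(tibble(chrom = character(), start = integer(),
                  end = integer(), count = numeric()))
  }
  res <- dplyr::arrange(dplyr::bind_rows(out), .data$chrom, .data$start)
  res
}
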