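# IUPAC consensus motif scanning, summit-window assignment of peaks to
# motif categories, and motif-centered average binding profiles.

iupac_code_table <- function() {
  list(A = "A", C = "C", G = "G", T = "T",
       R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC",
       B = "CGT", D = "AGT", H = "ACT", V = "ACG", N = "ACGT")
}

#' Built-in transcription-factor consensus patterns
#'
#' The three consensus motifs enriched near non-MER85 peak summits: the
#' AP-1 binding TRE (`TGANTCA`), the TEAD1 site (`WGGAATK`, i.e.
#' `[AT]GGAAT[GT]`) and the CTCF site (`CCASYAGRKGGC`, i.e.
#' `CCA[CG][CT]AG[AG][GT]GGC`).
#'
#' @return A tibble with columns `name` and `iupac`.
#' @export
motif_patterns <- function() {
  tibble(
    name = c("TRE", "TEAD1", "CTCF"),
    iupac = c("TGANTCA", "WGGAATK", "CCASYAGRKGGC")
  )
}

# Translate an IUPAC string to a regular expression; errors name the first
# invalid character.
iupac_to_regex <- function(pattern) {
  codes <- iupac_code_table()
  chars <- strsplit(toupper(pattern), "", fixed = TRUE)[[1]]
  bad <- setdiff(chars, names(codes))
  if (length(bad) > 0) {
    abort(sprintf("invalid IUPAC code '%s' in pattern", bad[1]))
  }
  paste(vapply(chars, function(ch) {
    opts <- codes[[ch]]
    if (nchar(opts) == 1) opts else paste0("[", opts, "]")
  }, character(1)), collapse = "")
}

#' Scan a sequence for exact IUPAC consensus matches
#'
#' Finds all (possibly overlapping) matches of an IUPAC pattern.  With
#' `both_strands`, the reverse complement of the pattern is also scanned
#' and its matches reported in plus-strand coordinates with strand `"-"`;
#' a self-reverse-complementary pattern therefore yields one hit per strand
#' at the same position.  Ambiguous bases in the subject never match.
#'
#' @param seq A DNA string.
#' @param pattern An IUPAC consensus string (length >= 4) or a name from
#'   [motif_patterns()].
#' @param both_strands Scan the minus strand too (default `TRUE`).
#' @return A tibble with `start`, `end` (0-based half-open), `strand`,
#'   `pattern`.
#' @export
scan_iupac <- function(seq, pattern, both_strands = TRUE) {
  pats <- motif_patterns()
  pat_name <- pattern
  if (pattern %in% pats$name) {
    pattern <- pats$iupac[match(pattern, pats$name)]
  }
  if (nchar(pattern) < 4) abort("pattern length must be at least 4")
  seq <- toupper(seq)
  w <- nchar(pattern)
  scan_one <- function(p, strand) {
    rx <- paste0("(?=", iupac_to_regex(p), ")")
    m <- gregexpr(rx, seq, perl = TRUE)[[1]]
    if (m[1] == -1) return(NULL)
    tibble(start = as.integer(m) - 1L, end = as.integer(m) - 1L + w,
           strand = strand, pattern = pat_name)
  }
  fwd <- scan_one(pattern, "+")
  rev <- if (both_strands) scan_one(revcomp(pattern), "-") else NULL
  out <- dplyr::bind_rows(fwd, rev)
  if (nrow(out) == 0) {
    return(tibble(start = integer(), end = integer(),
                  strand = character(), pattern = character()))
  }
  dplyr::arrange(out, .data$start, .data$strand)
}

#' Scan genome sequences for motif occurrences
#'
#' Applies [scan_iupac()] to every chromosome and every requested pattern.
#'
#' @param seqs Genome sequences (`DNAStringSet` or named character).
#' @param patterns Character vector of pattern names from
#'   [motif_patterns()], or a tibble with `name` and `iupac` columns.
#' @param both_strands Scan both strands (default `TRUE`).
#' @return A tibble with `chrom`, `start`, `end`, `strand`, `pattern`.
#' @export
scan_motifs <- function(seqs, patterns = motif_patterns()$name,
                        both_strands = TRUE) {
  sv <- as_seq_vector(seqs)
  if (is.character(patterns)) {
    pats <- motif_patterns()
    pats <- pats[pats$name %in% patterns, , drop = FALSE]
  } else {
    pats <- patterns
  }
  out <- list()
  for (chr in names(sv)) {
    for (i in seq_len(nrow(pats))) {
      hits <- scan_iupac(sv[[chr]], pats$iupac[i], both_strands)
      if (nrow(hits) > 0) {
        hits$pattern <- pats$name[i]
        hits$chrom <- chr
        out[[length(out) + 1L]] <- hits
      }
    }
  }
  if (length(out) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  strand = character(), pattern = character()))
  }
  res <- dplyr::bind_rows(out)
  dplyr::arrange(res[, c("chrom", "start", "end", "strand", "pattern")],
                 .data$chrom, .data$start)
}

#' Build summit windows around peaks
#'
#' The window for a summit at position `s` is `[s - flank, s + flank)`
#' (100 bp for the default flank of 50), clipped at chromosome ends.  A
#' zero flank degenerates to the 1-bp window `[s, s + 1)`.
#'
#' @param peaks Tibble with `chrom` and `summit` columns (and optionally
#'   `peak_id`).
#' @param flank Half-width in bp (default 50).
#' @param genome_lengths Optional named chromosome lengths for right-edge
#'   clipping.
#' @return A tibble with `peak_id`, `chrom`, `start`, `end`, `clipped`.
#' @export
summit_windows <- function(peaks, flank = 50L, genome_lengths = NULL) {
  stopifnot("summit" %in% names(peaks))
  peak_id <- if ("peak_id" %in% names(peaks)) peaks$peak_id else {
    sprintf("peak_%05d", seq_len(nrow(peaks)))
  }
  if (flank <= 0) {
    start <- peaks$summit
    end <- peaks$summit + 1L
  } else {
    start <- peaks$summit - as.integer(flank)
    end <- peaks$summit + as.integer(flank)
  }
  clipped <- start < 0
  start <- pmax(start, 0L)
  if (!is.null(genome_lengths)) {
    lim <- genome_lengths[peaks$chrom]
    clipped <- clipped | end > lim
    end <- pmin(end, lim)
  }
  tibble(peak_id = peak_id, chrom = peaks$chrom,
         start = as.integer(start), end = as.integer(end),
         clipped = unname(clipped))
}

#' Assign consensus peaks to element and motif categories
#'
#' A peak overlapping a MER85 or PGBD3 element takes that element category
#' (element categories have precedence: the motif search was defined on
#' non-element peaks).  Otherwise the peak is labelled with every motif
#' pattern that has at least one occurrence fully contained in its summit
#' window — a peak with both TRE and TEAD1 hits is counted as a member of
#' both peak sets.  Peaks with no element and no motif get `"none"`.
#' Motif hits over element peaks are still recorded in `motif_hits` for
#' audit.
#'
#' @param peaks Consensus peaks with `peak_id`, `chrom`, `start`, `end`,
#'   `summit`.
#' @param elements Element tibble with `chrom`, `start`, `end`, `kind`.
#' @param occurrences Motif occurrences ([scan_motifs()]).
#' @param flank Summit-window half-width (default 50).
#' @param genome_lengths Optional chromosome lengths for window clipping.
#' @return `peaks` with added `categories` (list of character vectors) and
#'   `motif_hits` (list column) plus a convenience `category` string
#'   (semicolon-joined).
#' @export
categorize_peaks <- function(peaks, elements, occurrences, flank = 50L,
                             genome_lengths = NULL) {
  n <- nrow(peaks)
  cats <- vector("list", n)
  motif_hits <- vector("list", n)
  wins <- summit_windows(peaks, flank, genome_lengths)
  for (i in seq_len(n)) {
    chr <- peaks$chrom[i]
    el <- elements[elements$chrom == chr &
                     elements$start < peaks$end[i] &
                     elements$end > peaks$start[i], , drop = FALSE]
    occ <- occurrences[occurrences$chrom == chr &
                         occurrences$start >= wins$start[i] &
                         occurrences$end <= wins$end[i], , drop = FALSE]
    motif_hits[[i]] <- sort(unique(occ$pattern))
    if (nrow(el) > 0) {
      cats[[i]] <- sort(unique(el$kind))
    } else if (length(motif_hits[[i]]) > 0) {
      cats[[i]] <- motif_hits[[i]]
    } else {
      cats[[i]] <- "none"
    }
  }
  peaks$categories <- cats
  peaks$motif_hits <- motif_hits
  peaks$category <- vapply(cats, paste, character(1), collapse = ";")
  peaks
}

#' Average binding profile centered on motif occurrences
#'
#' Extracts the coverage window around each occurrence midpoint
#' (`floor((start + end) / 2)`), oriented by strand, zero-padded at
#' chromosome edges, and averages across occurrences.
#'
#' @param track Coverage track ([coverage_track()]).
#' @param occurrences Motif occurrences with `chrom`, `start`, `end`,
#'   `strand`.
#' @param window Integer `c(from, to)` of offsets relative to the midpoint.
#' @param genome_lengths Optional chromosome lengths.
#' @return A tibble with `offset`, `total`, `mean`, `n_sites`.
#' @export
motif_profile <- function(track, occurrences, window = c(-100L, 100L),
                          genome_lengths = NULL) {
  if (nrow(occurrences) == 0) abort("no motif occurrences supplied")
  mid <- occurrences$start + (occurrences$end - occurrences$start) %/% 2L
  anchors <- tibble(
    chrom = occurrences$chrom,
    # reuse the element-profile engine: a plus-strand anchor at the
    # midpoint, or a minus-strand 1-bp "element" ending at the midpoint
    start = mid, end = mid + 1L,
    strand = occurrences$strand
  )
  prof <- element_profile(track, anchors, window, genome_lengths)
  names(prof)[names(prof) == "n_elements"] <- "n_sites"
  prof
}
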