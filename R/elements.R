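# Annotation of piggyBac-derived repeat elements: target-site duplications,
# terminal inverted repeats, the internal 16-bp palindrome, completeness
# classes, bound/unbound status, and orientation-corrected binding profiles.

#' Scan a sequence for (near-)matches to the palindrome consensus
#'
#' Reports every offset, on either strand, where the Hamming distance to the
#' consensus is at most `max_mismatch`.  Minus-strand hits (matches to the
#' reverse complement of the consensus) are reported in plus-strand
#' coordinates.  Ambiguity characters always count as mismatches.
#'
#' @param seq A DNA string (character).
#' @param consensus The consensus to match; default the 16-bp internal
#'   palindrome `GTTCCATTATTGGAAC`.
#' @param max_mismatch Maximum Hamming distance.
#' @return A tibble with `position` (0-based), `strand`, `mismatches`,
#'   sorted by position.
#' @export
match_palindrome <- function(seq, consensus = PALINDROME_CONSENSUS,
                             max_mismatch = 0L) {
  seq <- toupper(seq)
  if (nchar(consensus) > nchar(seq)) {
    return(tibble(position = integer(), strand = character(),
                  mismatches = integer()))
  }
  subject <- Biostrings::DNAString(seq)
  scan_one <- function(pat, strand) {
    m <- Biostrings::matchPattern(pat, subject,
                                  max.mismatch = max_mismatch,
                                  with.indels = FALSE, fixed = TRUE)
    if (length(m) == 0) {
      return(NULL)
    }
    mm <- Biostrings::neditStartingAt(Biostrings::DNAString(pat), subject,
                                      starting.at = IRanges::start(m),
                                      with.indels = FALSE, fixed = TRUE)
    tibble(position = IRanges::start(m) - 1L, strand = strand,
           mismatches = as.integer(mm))
  }
  fwd <- scan_one(consensus, "+")
  rcp <- revcomp(consensus)
  rev <- if (rcp == consensus) NULL else scan_one(rcp, "-")
  out <- dplyr::bind_rows(fwd, rev)
  if (nrow(out) == 0) {
    return(tibble(position = integer(), strand = character(),
                  mismatches = integer()))
  }
  dplyr::arrange(out, .data$position, .data$strand)
}

#' Flag sequence variants of a 16-bp palindrome
#'
#' Compares a 16-bp sequence to the palindrome consensus and flags the
#' characteristic C>T substitution at the final position, which turns the
#' 3' arm `TGGAAC` into `TGGAAT` (a TEAD1-like site once the downstream
#' base is included).  All other deviations are listed as generic
#' substitutions by position.
#'
#' @param seq A 16-character DNA string.
#' @param consensus The 16-bp consensus.
#' @return A list with `c_to_t` (logical), `substitutions` (integer vector
#'   of mismatching 1-based positions) and `matches_consensus` (logical).
#' @export
detect_palindrome_variant <- function(seq, consensus = PALINDROME_CONSENSUS) {
  seq <- toupper(seq)
  if (nchar(seq) != nchar(consensus)) {
    abort(sprintf("expected a %d-bp sequence", nchar(consensus)))
  }
  vs <- strsplit(seq, "", fixed = TRUE)[[1]]
  vc <- strsplit(consensus, "", fixed = TRUE)[[1]]
  if (!any(vs %in% c("A", "C", "G", "T"))) {
    abort("sequence contains no unambiguous bases")
  }
  mism <- which(vs != vc | !(vs %in% c("A", "C", "G", "T")))
  n <- length(vc)
  c_to_t <- vc[n] == "C" && vs[n] == "T" &&
    identical(vs[(n - 5):(n - 1)], vc[(n - 5):(n - 1)])
  list(
    c_to_t = c_to_t,
    substitutions = setdiff(mism, if (c_to_t) n else integer(0)),
    matches_consensus = length(mism) == 0
  )
}

#' Find imperfect palindromes in a sequence
#'
#' Scans for positions where a left arm of `arm_length` bp equals the
#' reverse complement of the right arm within `max_arm_mismatch`
#' mismatches, for every loop length in `loop_range`.  For each hit the
#' Hamming distance of the full span to its own reverse complement is also
#' reported.
#'
#' @param seq A DNA string.
#' @param arm_length Arm length in bp (at least 3).
#' @param loop_range Integer vector of loop lengths to try (e.g. `4` or
#'   `0:8`).
#' @param max_arm_mismatch Maximum arm-vs-arm mismatches.
#' @return A tibble with `position`, `arm_length`, `loop_length`,
#'   `arm_mismatches`, `full_self_revcomp_mismatches`.
#' @export
find_imperfect_palindromes <- function(seq, arm_length, loop_range,
                                       max_arm_mismatch = 0L) {
  stopifnot(arm_length >= 3)
  seq <- toupper(seq)
  n <- nchar(seq)
  hits <- list()
  for (loop in loop_range) {
    span <- 2L * arm_length + loop
    if (span > n) next
    starts <- 0:(n - span)
    left <- substring(seq, starts + 1L, starts + arm_length)
    right <- substring(seq, starts + arm_length + loop + 1L, starts + span)
    mm <- mapply(function(l, r) hamming(l, revcomp(r)), left, right,
                 USE.NAMES = FALSE)
    keep <- which(mm <= max_arm_mismatch)
    if (length(keep) == 0) next
    full <- substring(seq, starts[keep] + 1L, starts[keep] + span)
    full_mm <- vapply(full, function(s) hamming(s, revcomp(s)), numeric(1),
                      USE.NAMES = FALSE)
    hits[[length(hits) + 1L]] <- tibble(
      position = starts[keep],
      arm_length = as.integer(arm_length),
      loop_length = as.integer(loop),
      arm_mismatches = as.integer(mm[keep]),
      full_self_revcomp_mismatches = as.integer(full_mm)
    )
  }
  if (length(hits) == 0) {
    return(tibble(position = integer(), arm_length = integer(),
                  loop_length = integer(), arm_mismatches = integer(),
                  full_self_revcomp_mismatches = integer()))
  }
  dplyr::arrange(dplyr::bind_rows(hits), .data$position, .data$loop_length)
}

#' Annotate one element sequence
#'
#' Locates the TTAA target-site duplication, the 5'/3' terminal inverted
#' repeats and the internal palindrome in an element-oriented sequence, and
#' assigns a completeness class.  TIR detection first aligns the first and
#' last `tir_length` bases against each other's reverse complement
#' (`max_tir_mismatch` allowed); if that mutual test fails, each edge is
#' compared to the model TIR consensus to decide which side is broken.
#'
#' @param seq Element sequence (element orientation, starting at the 5'
#'   TSD when present).
#' @param model An [element_model()].
#' @param max_tir_mismatch Mismatches tolerated in a TIR.
#' @param max_palindrome_mismatch Mismatches tolerated when locating the
#'   palindrome in the 5' region.
#' @param reference_length Reference element length for the
#'   expanded/deleted calls (default the 140-bp MER85 length).
#' @return A list with `tsd`, `tir5`, `tir3`, `palindrome` (each `NULL` or
#'   a list with 0-based `start`/`end` and, for the palindrome,
#'   `mismatches` and variant `flags`), plus `completeness` (one of
#'   `intact`, `incomplete_5p`, `incomplete_3p`, `no_tirs`, `expanded`,
#'   `deleted`) and `length`.
#' @export
annotate_element <- function(seq, model = element_model(),
                             max_tir_mismatch = 2L,
                             max_palindrome_mismatch = 3L,
                             reference_length = model$mer85_length) {
  seq <- toupper(seq)
  n <- nchar(seq)
  tl <- model$tir_length
  if (n < 2L * tl) {
    return(list(tsd = NULL, tir5 = NULL, tir3 = NULL, palindrome = NULL,
                completeness = "no_tirs", length = n))
  }
  tsd <- NULL
  off5 <- 0L
  if (substr(seq, 1, nchar(model$tsd_seq)) == model$tsd_seq) {
    tsd <- list(start = 0L, end = nchar(model$tsd_seq))
    off5 <- nchar(model$tsd_seq)
  }
  cand5 <- substr(seq, off5 + 1L, off5 + tl)
  cand3 <- substr(seq, n - tl + 1L, n)
  tir5 <- tir3 <- NULL
  if (hamming(cand5, revcomp(cand3)) <= max_tir_mismatch) {
    tir5 <- list(start = off5, end = off5 + tl)
    tir3 <- list(start = n - tl, end = n)
  } else {
    if (hamming(cand5, model$tir5) <= max_tir_mismatch) {
      tir5 <- list(start = off5, end = off5 + tl)
    }
    if (hamming(cand3, model$tir3) <= max_tir_mismatch) {
      tir3 <- list(start = n - tl, end = n)
    }
  }
  completeness <- if (!is.null(tir5) && !is.null(tir3)) {
    if (n > reference_length + 20L) {
      "expanded"
    } else if (n < reference_length) {
      "deleted"
    } else {
      "intact"
    }
  } else if (is.null(tir5) && is.null(tir3)) {
    "no_tirs"
  } else if (is.null(tir5)) {
    "incomplete_5p"
  } else {
    "incomplete_3p"
  }
  palindrome <- NULL
  window5 <- substr(seq, 1, min(n, 60L))
  hits <- match_palindrome(window5, model$palindrome,
                           max_mismatch = max_palindrome_mismatch)
  hits <- hits[hits$strand == "+", , drop = FALSE]
  if (nrow(hits) > 0) {
    best <- hits[order(hits$mismatches, hits$position), ][1, ]
    pal_seq <- substr(seq, best$position + 1L,
                      best$position + nchar(model$palindrome))
    palindrome <- list(
      start = best$position, end = best$position + nchar(model$palindrome),
      mismatches = best$mismatches,
      flags = detect_palindrome_variant(pal_seq, model$palindrome)
    )
  }
  list(tsd = tsd, tir5 = tir5, tir3 = tir3, palindrome = palindrome,
       completeness = completeness, length = n)
}

#' Annotate a table of elements from genome sequence
#'
#' Extracts each element's sequence (reverse-complemented for minus-strand
#' elements, so annotation runs in element orientation) and applies
#' [annotate_element()].
#'
#' @param elements Tibble with `chrom`, `start`, `end`, `strand`.
#' @param seqs Genome sequences (`DNAStringSet` or named character).
#' @param ... Passed to [annotate_element()].
#' @return The input tibble with added columns `completeness`,
#'   `tsd_start`, `tir5_start`, `tir3_start`, `palindrome_start`,
#'   `palindrome_mismatches`, `palindrome_c_to_t` (element-oriented 0-based
#'   offsets; `NA` where a feature is absent).
#' @export
annotate_elements <- function(elements, seqs, ...) {
  sv <- as_seq_vector(seqs)
  ann <- lapply(seq_len(nrow(elements)), function(i) {
    s <- substr(sv[[elements$chrom[i]]], elements$start[i] + 1L,
                elements$end[i])
    if (identical(elements$strand[i], "-")) s <- revcomp(s)
    a <- annotate_element(s, ...)
    tibble(
      completeness = a$completeness,
      tsd_start = if (is.null(a$tsd)) NA_integer_ else a$tsd$start,
      tir5_start = if (is.null(a$tir5)) NA_integer_ else a$tir5$start,
      tir3_start = if (is.null(a$tir3)) NA_integer_ else a$tir3$start,
      palindrome_start = if (is.null(a$palindrome)) NA_integer_ else {
        a$palindrome$start
      },
      palindrome_mismatches = if (is.null(a$palindrome)) NA_integer_ else {
        as.integer(a$palindrome$mismatches)
      },
      palindrome_c_to_t = if (is.null(a$palindrome)) NA else {
        a$palindrome$flags$c_to_t
      }
    )
  })
  ann <- dplyr::bind_rows(ann)
  # annotation columns replace any same-named planted-truth columns
  keep <- setdiff(names(elements), names(ann))
  dplyr::bind_cols(elements[keep], ann)
}

#' Classify elements as bound or unbound by peaks
#'
#' An element is bound when it overlaps any peak by at least 1 bp
#' (half-open semantics).  The leftmost overlapping peak's id is recorded.
#'
#' @param elements Tibble with `chrom`, `start`, `end`.
#' @param peaks Tibble with `chrom`, `start`, `end` and optionally
#'   `peak_id`.
#' @return `elements` with added `bound` (logical) and `bound_peak_id`
#'   columns.
#' @export
classify_bound <- function(elements, peaks) {
  elements$bound <- FALSE
  elements$bound_peak_id <- NA_character_
  if (nrow(elements) == 0 || nrow(peaks) == 0) return(elements)
  if (!"peak_id" %in% names(peaks)) {
    peaks$peak_id <- sprintf("peak_%05d", seq_len(nrow(peaks)))
  }
  for (chr in unique(elements$chrom)) {
    ei <- which(elements$chrom == chr)
    pk <- peaks[peaks$chrom == chr, , drop = FALSE]
    if (nrow(pk) == 0) next
    hits <- IRanges::findOverlaps(
      IRanges::IRanges(elements$start[ei] + 1L, elements$end[ei]),
      IRanges::IRanges(pk$start + 1L, pk$end)
    )
    if (length(hits) == 0) next
    qh <- S4Vectors::queryHits(hits)
    sh <- S4Vectors::subjectHits(hits)
    # leftmost overlapping peak per element
    ord <- order(qh, pk$start[sh])
    first <- !duplicated(qh[ord])
    elements$bound[ei[qh[ord][first]]] <- TRUE
    elements$bound_peak_id[ei[qh[ord][first]]] <- pk$peak_id[sh[ord][first]]
  }
  elements
}

#' Orientation-corrected cumulative binding profile over elements
#'
#' For each element, extracts coverage at offsets relative to the first base
#' of its 5' TSD in element orientation (minus-strand windows run leftward
#' along the genome), then sums position-wise across elements.  Offsets that
#' fall outside a chromosome contribute zero and set the `clipped` flag.
#'
#' @param track Coverage track ([coverage_track()]).
#' @param elements Tibble with `chrom`, `start`, `end`, `strand`.
#' @param window Integer vector `c(from, to)` of offsets relative to the
#'   5' TSD (inclusive), e.g. `c(-100, 239)`.
#' @param genome_lengths Optional named chromosome lengths for clip
#'   detection at the right edge.
#' @return A tibble with `offset`, `total`, `mean`, `n_elements` and a
#'   `clipped` attribute.
#' @export
element_profile <- function(track, elements, window = c(-100L, 239L),
                            genome_lengths = NULL) {
  stopifnot(nrow(elements) > 0)
  offsets <- window[1]:window[2]
  total <- numeric(length(offsets))
  clipped <- FALSE
  for (i in seq_len(nrow(elements))) {
    chr <- elements$chrom[i]
    if (identical(elements$strand[i], "-")) {
      anchor <- elements$end[i] - 1L
      pos <- anchor - offsets
    } else {
      anchor <- elements$start[i]
      pos <- anchor + offsets
    }
    out_of_range <- pos < 0
    if (!is.null(genome_lengths) && chr %in% names(genome_lengths)) {
      out_of_range <- out_of_range | pos >= genome_lengths[[chr]]
    }
    if (any(out_of_range)) clipped <- TRUE
    v <- track_values(track, chr, pos)
    v[out_of_range] <- 0L
    total <- total + v
  }
  out <- tibble(offset = offsets, total = total,
                mean = total / nrow(elements),
                n_elements = nrow(elements))
  attr(out, "clipped") <- clipped
  out
}

#' Summit offset of a binding profile
#'
#' The profile summit is the center of the deepest run of the profile —
#' the same "center of the deepest fragment overlap" rule used for peak
#' summits by [find_summit()].  Among several maximal runs the leftmost is
#' used; the center is the floor midpoint.
#'
#' @param profile A profile tibble from [element_profile()] or
#'   [motif_profile()].
#' @param stat Column to use (`"total"` or `"mean"`).
#' @return The summit `offset` value.
#' @export
profile_summit <- function(profile, stat = "total") {
  v <- profile[[stat]]
  r <- rle(v == max(v))
  ends <- cumsum(r$lengths)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  i <- which(r$values)[1]
  mid <- starts[i] + (ends[i] - starts[i]) %/% 2L
  profile$offset[mid]
}

#' Normalise EMSA band-shift intensities to controls
#'
#' For each probe the binding signal is the difference in shifted-band
#' intensity with and without protein; percent affinity rescales that
#' difference between the scrambled-sequence control (0%) and the consensus
#' control (100%).
#'
#' @param intensities Tibble with columns `sample`, `with_protein`,
#'   `without_protein`.
#' @param scrambled,consensus Names of the control rows in `sample`.
#' @return The input tibble with added `delta` and `percent` columns.
#' @export
emsa_normalize <- function(intensities, scrambled = "scrambled",
                           consensus = "consensus") {
  stopifnot(all(c("sample", "with_protein", "without_protein") %in%
                  names(intensities)))
  d <- intensities$with_protein - intensities$without_protein
  d_scr <- d[match(scrambled, intensities$sample)]
  d_con <- d[match(consensus, intensities$sample)]
  if (is.na(d_scr) || is.na(d_con)) {
    abort("control samples not found in `sample` column")
  }
  if (d_con == d_scr) abort("degenerate controls")
  dplyr::mutate(intensities, delta = d,
                percent = 100 * (d - d_scr) / (d_con - d_scr))
}
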