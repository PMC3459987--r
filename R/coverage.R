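# Fragment-coverage processing: paired reads -> fragments -> per-position
# fragment-overlap tracks -> fragment clusters with summits -> consensus
# peaks across callers.

#' Convert mate pairs to sequenced-fragment intervals
#'
#' Each properly oriented mate pair delimits one sequenced fragment:
#' `[min(mate starts), max(mate ends))` on the shared chromosome.  Pairs
#' with mates on different chromosomes or on the same strand are rejected
#' (tallied in the `"rejected"` attribute, not fatal).
#'
#' @param pairs A tibble of mate pairs in BEDPE layout (see [read_bedpe()]).
#' @return A tibble of fragments (`chrom`, `start`, `end`), sorted by
#'   (`chrom`, `start`, `end`), with attribute `rejected` giving the number
#'   of dropped pairs.
#' @export
pairs_to_fragments <- function(pairs) {
  ok <- pairs$chrom1 == pairs$chrom2 & pairs$strand1 != pairs$strand2
  rejected <- sum(!ok)
  kept <- pairs[ok, , drop = FALSE]
  out <- tibble(
    chrom = kept$chrom1,
    start = pmin(kept$start1, kept$start2),
    end = pmax(kept$end1, kept$end2)
  )
  out <- dplyr::arrange(out, .data$chrom, .data$start, .data$end)
  attr(out, "rejected") <- rejected
  out
}

#' Compute a fragment-overlap coverage track
#'
#' Counts the number of fragments overlapping each genomic position and
#' returns the result as sparse runs of constant coverage (zero-coverage
#' positions are omitted).  The sum of `count * (end - start)` over all runs
#' equals the sum of fragment lengths.
#'
#' @param fragments A tibble of intervals (`chrom`, `start`, `end`,
#'   0-based half-open), e.g. from [pairs_to_fragments()].
#' @return A tibble with columns `chrom`, `start`, `end`, `count`; runs are
#'   non-overlapping, sorted, and maximal.
#' @export
coverage_track <- function(fragments) {
  if (nrow(fragments) == 0) {
    return(tibble(chrom = character(), start = integer(),
                  end = integer(), count = integer()))
  }
  ir <- as_iranges_list(fragments)
  out <- lapply(names(ir), function(chr) {
    cov <- IRanges::coverage(ir[[chr]])
    ends <- cumsum(S4Vectors::runLength(cov))
    starts <- c(0L, utils::head(ends, -1L))
    vals <- S4Vectors::runValue(cov)
    keep <- vals > 0
    tibble(chrom = chr, start = starts[keep], end = ends[keep],
           count = as.integer(vals[keep]))
  })
  dplyr::arrange(dplyr::bind_rows(out), .data$chrom, .data$start)
}

#' Coverage values at arbitrary positions
#'
#' Looks up the fragment-overlap count of a track at 0-based positions;
#' positions outside recorded runs return 0.
#'
#' @param track A coverage track ([coverage_track()]).
#' @param chrom Chromosome name.
#' @param positions Integer vector of 0-based positions.
#' @return Integer vector of counts.
#' @export
track_values <- function(track, chrom, positions) {
  t <- track[track$chrom == chrom, , drop = FALSE]
  if (nrow(t) == 0) return(rep(0L, length(positions)))
  idx <- findInterval(positions, t$start)
  val <- rep(0L, length(positions))
  hit <- idx >= 1
  hit[hit] <- positions[hit] < t$end[idx[hit]]
  val[hit] <- t$count[idx[hit]]
  val
}

# Restrict a single-chromosome run table to [start, end), clipping runs.
clip_runs <- function(t, start, end) {
  t <- t[t$end > start & t$start < end, , drop = FALSE]
  if (nrow(t) == 0) return(t)
  t$start <- pmax(t$start, start)
  t$end <- pmin(t$end, end)
  t
}

#' Locate the summit of a region
#'
#' The summit is the center of the deepest fragment-overlap run within the
#' region.  Among several runs attaining the maximal count, the leftmost run
#' is used; its center is `start + floor((width - 1) / 2)`.
#'
#' @param track A coverage track ([coverage_track()]).
#' @param chrom Chromosome name.
#' @param start,end Region bounds (0-based half-open).
#' @return Integer summit position.
#' @export
find_summit <- function(track, chrom, start, end) {
  t <- clip_runs(track[track$chrom == chrom, , drop = FALSE], start, end)
  t <- t[t$count > 0, , drop = FALSE]
  if (nrow(t) == 0) abort("no coverage in region")
  # merge adjacent clipped runs of equal count so the deepest run is maximal
  i <- which.max(t$count)
  j <- i
  while (j < nrow(t) && t$start[j + 1] == t$end[j] &&
         t$count[j + 1] == t$count[i]) {
    j <- j + 1
  }
  run_start <- t$start[i]
  run_end <- t$end[j]
  as.integer(run_start + (run_end - run_start - 1L) %/% 2L)
}

#' Call fragment clusters against an input control
#'
#' Finds maximal runs where the ChIP fragment-overlap count is at least
#' `min_fragments` (default 5 overlapping fragments), then retains runs
#' whose mean ChIP count is at least `min_fold` times the mean input count
#' over the same span.  The input mean is floored at `pseudocount` so that
#' zero-coverage input never divides by zero.  Each retained cluster gets a
#' summit via [find_summit()].
#'
#' @param track ChIP coverage track ([coverage_track()]).
#' @param input_track Input-control coverage track, or `NULL` to skip the
#'   fold filter (the input mean is then the pseudocount).
#' @param min_fragments Minimum fragment-overlap depth for a position to
#'   enter a cluster.
#' @param min_fold Minimum fold enrichment of the mean ChIP count over the
#'   mean input count.
#' @param min_span Minimum cluster width in bp.
#' @param pseudocount Floor for the mean input count.
#' @return A tibble of candidate peaks: `chrom`, `start`, `end`, `summit`,
#'   `max_count`, `mean_count`, `mean_input`, `fold`.
#' @export
call_clusters <- function(track, input_track = NULL, min_fragments = 5L,
                          min_fold = 2, min_span = 1L, pseudocount = 1) {
  stopifnot(min_fragments >= 1, min_fold >= 1)
  t <- track[track$count >= min_fragments, , drop = FALSE]
  if (nrow(t) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  summit = integer(), max_count = integer(),
                  mean_count = numeric(), mean_input = numeric(),
                  fold = numeric()))
  }
  ir <- as_iranges_list(t)
  clusters <- dplyr::bind_rows(lapply(names(ir), function(chr) {
    red <- IRanges::reduce(ir[[chr]], min.gapwidth = 1L)
    tibble(chrom = chr, start = IRanges::start(red) - 1L,
           end = IRanges::end(red))
  }))
  clusters <- clusters[clusters$end - clusters$start >= min_span, ,
                       drop = FALSE]
  rows <- lapply(seq_len(nrow(clusters)), function(i) {
    chr <- clusters$chrom[i]; s <- clusters$start[i]; e <- clusters$end[i]
    span <- e - s
    chip <- clip_runs(track[track$chrom == chr, , drop = FALSE], s, e)
    mean_chip <- sum(chip$count * (chip$end - chip$start)) / span
    mean_input <- pseudocount
    if (!is.null(input_track)) {
      inp <- clip_runs(input_track[input_track$chrom == chr, ,
                                   drop = FALSE], s, e)
      mean_input <- max(sum(inp$count * (inp$end - inp$start)) / span,
                        pseudocount)
    }
    fold <- mean_chip / mean_input
    if (fold < min_fold) return(NULL)
    tibble(chrom = chr, start = s, end = e,
           summit = find_summit(track, chr, s, e),
           max_count = max(chip$count),
           mean_count = mean_chip, mean_input = mean_input, fold = fold)
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  summit = integer(), max_count = integer(),
                  mean_count = numeric(), mean_input = numeric(),
                  fold = numeric()))
  }
  dplyr::arrange(out, .data$chrom, .data$start)
}

#' Intersect peak sets from multiple callers into consensus peaks
#'
#' A consensus ("combined") peak is emitted for every maximal genomic region
#' in which intervals form a transitive overlap chain that touches every
#' input set.  The combined peak's boundaries are the outermost boundaries
#' of the contributing intervals; its summit is computed from the coverage
#' track with [find_summit()].
#'
#' @param peak_sets A named list of at least two peak tibbles
#'   (`chrom`, `start`, `end`).
#' @param track Optional coverage track for summit computation; without it,
#'   summits are `NA`.
#' @return A tibble of consensus peaks: `peak_id`, `chrom`, `start`, `end`,
#'   `summit`, `n_callers`, `callers`.
#' @export
consensus_peaks <- function(peak_sets, track = NULL) {
  if (length(peak_sets) < 2) {
    abort("need at least 2 peak sets for a consensus")
  }
  if (is.null(names(peak_sets)) || any(!nzchar(names(peak_sets)))) {
    names(peak_sets) <- paste0("caller", seq_along(peak_sets))
  }
  all_iv <- dplyr::bind_rows(lapply(names(peak_sets), function(nm) {
    x <- peak_sets[[nm]]
    tibble(chrom = x$chrom, start = x$start, end = x$end, caller = nm)
  }))
  if (nrow(all_iv) == 0) {
    return(tibble(peak_id = character(), chrom = character(),
                  start = integer(), end = integer(), summit = integer(),
                  n_callers = integer(), callers = character()))
  }
  out <- lapply(split(all_iv, all_iv$chrom), function(x) {
    ir <- IRanges::IRanges(x$start + 1L, x$end)
    # components of the transitive overlap graph (strictly overlapping,
    # not merely abutting)
    comp <- IRanges::reduce(ir, min.gapwidth = 0L)
    hits <- IRanges::findOverlaps(ir, comp)
    member <- S4Vectors::subjectHits(hits)
    sets_per_comp <- tapply(x$caller, member,
                            function(cl) sort(unique(cl)))
    keep <- vapply(sets_per_comp, function(cl) {
      length(cl) == length(peak_sets)
    }, logical(1))
    idx <- as.integer(names(sets_per_comp))[keep]
    if (length(idx) == 0) return(NULL)
    tibble(chrom = x$chrom[1],
           start = IRanges::start(comp)[idx] - 1L,
           end = IRanges::end(comp)[idx],
           n_callers = length(peak_sets),
           callers = paste(names(peak_sets), collapse = ";"))
  })
  out <- dplyr::bind_rows(out)
  if (nrow(out) == 0) {
    return(tibble(peak_id = character(), chrom = character(),
                  start = integer(), end = integer(), summit = integer(),
                  n_callers = integer(), callers = character()))
  }
  out <- dplyr::arrange(out, .data$chrom, .data$start)
  out$summit <- if (is.null(track)) {
    NA_integer_
  } else {
    vapply(seq_len(nrow(out)), function(i) {
      find_summit(track, out$chrom[i], out$start[i], out$end[i])
    }, integer(1))
  }
  out$peak_id <- sprintf("peak_%05d", seq_len(nrow(out)))
  out[, c("peak_id", "chrom", "start", "end", "summit",
          "n_callers", "callers")]
}
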