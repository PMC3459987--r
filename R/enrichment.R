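# GREAT-style association statistics: regulatory domains anchored on gene or
# probe start sites, binomial enrichment of peak summits in domain unions,
# empirical FDR from randomised summit sets, proximity enrichment around
# anchor elements, and multi-dataset overlap support.

#' Extract 5' start sites from stranded probe/gene intervals
#'
#' Plus-strand intervals start at their left edge; minus-strand intervals at
#' `end - 1`.  Input order is preserved.
#'
#' @param probes Tibble with `chrom`, `strand`, and either `start`/`end`
#'   intervals or a precomputed `tss` position column (any id columns are
#'   carried through).
#' @return The input tibble with an added `site` column (0-based position).
#' @export
probe_start_sites <- function(probes) {
  if (!"strand" %in% names(probes) || anyNA(probes$strand)) {
    abort("probe intervals must carry a strand")
  }
  if ("tss" %in% names(probes)) {
    return(dplyr::mutate(probes, site = as.integer(.data$tss)))
  }
  dplyr::mutate(probes,
                site = ifelse(.data$strand == "+", .data$start,
                              .data$end - 1L))
}

#' Build regulatory domains around start sites
#'
#' Two modes are provided.  `"basal"` follows the GREAT basal-plus-extension
#' rule: each site gets a strand-oriented basal region
#' `[site - basal_up, site + basal_down)`, then extends on each side up to
#' `max_extension` bp from the site but not into a neighbouring site's basal
#' region (a site's own basal region is always kept).  `"extension"` is the
#' pure-extension rule: `[site - max_extension, site + max_extension)`
#' truncated at the midpoint between neighbouring sites.  Both are clipped
#' to chromosome bounds.
#'
#' @param sites Tibble with `chrom`, `site`, `strand` and an id column
#'   (`gene_id` or `probe_id`; carried through as `id`).
#' @param max_extension Maximum extension from the site in bp (the study's
#'   settings are 100 kb, 250 kb and 1 Mb).
#' @param genome_lengths Named chromosome lengths.
#' @param mode `"basal"` (default) or `"extension"`.
#' @param basal_up,basal_down Strand-oriented basal region sizes in bp.
#' @return A tibble with `id`, `chrom`, `start`, `end`, `site`,
#'   `max_extension`, `mode`.
#' @export
regulatory_domains <- function(sites, max_extension, genome_lengths,
                               mode = c("basal", "extension"),
                               basal_up = 5000L, basal_down = 1000L) {
  mode <- match.arg(mode)
  validate_genome_lengths(genome_lengths)
  id_col <- intersect(c("gene_id", "probe_id", "id"), names(sites))[1]
  if (is.na(id_col)) abort("`sites` must carry gene_id, probe_id or id")
  x <- tibble(id = sites[[id_col]], chrom = sites$chrom,
              site = as.integer(sites$site),
              strand = if ("strand" %in% names(sites)) sites$strand else "+")
  out <- lapply(split(x, x$chrom), function(g) {
    g <- dplyr::arrange(g, .data$site)
    len <- genome_lengths[[g$chrom[1]]]
    n <- nrow(g)
    if (mode == "basal") {
      b_start <- ifelse(g$strand == "+", g$site - basal_up,
                        g$site - basal_down)
      b_end <- ifelse(g$strand == "+", g$site + basal_down,
                      g$site + basal_up)
      b_start <- pmax(b_start, 0L)
      b_end <- pmin(b_end, len)
      prev_end <- c(0L, utils::head(b_end, -1L))
      next_start <- c(utils::tail(b_start, -1L), len)
      start <- pmin(b_start, pmax(g$site - max_extension,
                                  cummax(prev_end)))
      # extension rightward stops at the next basal start; use running
      # minimum from the right so out-of-order basal bounds are respected
      next_min <- rev(cummin(rev(next_start)))
      end <- pmax(b_end, pmin(g$site + max_extension, next_min))
    } else {
      mid_prev <- c(0L, floor((utils::head(g$site, -1L) +
                                 utils::tail(g$site, -1L)) / 2))
      mid_next <- c(floor((utils::head(g$site, -1L) +
                             utils::tail(g$site, -1L)) / 2), len)
      start <- pmax(g$site - max_extension, mid_prev)
      end <- pmin(g$site + max_extension, mid_next)
    }
    tibble(id = g$id, chrom = g$chrom,
           start = as.integer(pmax(start, 0L)),
           end = as.integer(pmin(end, len)),
           site = g$site)
  })
  res <- dplyr::bind_rows(out)
  res$max_extension <- as.integer(max_extension)
  res$mode <- mode
  dplyr::arrange(res, .data$chrom, .data$start)
}

#' Fraction of the genome covered by a domain union
#'
#' @param domains Tibble with `chrom`, `start`, `end`.
#' @param genome_lengths Named chromosome lengths.
#' @return The scalar fraction `p` of genome bp inside the merged union.
#' @export
domain_union_fraction <- function(domains, genome_lengths) {
  validate_genome_lengths(genome_lengths)
  total <- sum(as.numeric(genome_lengths))
  if (total == 0) abort("empty genome")
  if (nrow(domains) == 0) return(0)
  ir <- as_iranges_list(domains)
  covered <- sum(vapply(ir, function(r) {
    sum(as.numeric(IRanges::width(IRanges::reduce(r))))
  }, numeric(1)))
  covered / total
}

# Count summits falling inside the union of domains (half-open containment).
count_summits_in <- function(pos_tbl, domains) {
  if (nrow(pos_tbl) == 0 || nrow(domains) == 0) return(0L)
  k <- 0L
  dl <- split(domains, domains$chrom)
  for (chr in names(dl)) {
    p <- pos_tbl$pos[pos_tbl$chrom == chr]
    if (length(p) == 0) next
    d <- dl[[chr]]
    hits <- IRanges::findOverlaps(
      IRanges::IRanges(p + 1L, p + 1L),
      IRanges::reduce(IRanges::IRanges(d$start + 1L, d$end))
    )
    k <- k + length(unique(S4Vectors::queryHits(hits)))
  }
  k
}

#' Binomial enrichment of summits in a domain set
#'
#' Tests whether more of the `n` summits fall inside the merged regulatory
#' domains than expected if summits landed uniformly: with `p` the fraction
#' of the genome covered by the domain union and `k` the observed count,
#' the P-value is the upper binomial tail `P(X >= k)`, `X ~ Bin(n, p)`.
#'
#' @param summits Tibble of test positions (`chrom` plus `summit` or `pos`).
#' @param domains Regulatory domains ([regulatory_domains()]) or any
#'   interval tibble.
#' @param genome_lengths Named chromosome lengths.
#' @param name Label for the comparison.
#' @return An object of class `enrichment_test` with fields `name`, `n`,
#'   `k`, `p`, `p_value` (and `empirical_fdr = NA` until
#'   [empirical_fdr()] is run).
#' @export
binomial_enrichment <- function(summits, domains, genome_lengths,
                                name = "enrichment") {
  pos <- summit_positions(summits)
  n <- nrow(pos)
  if (n < 1) abort("need at least one summit")
  p <- domain_union_fraction(domains, genome_lengths)
  k <- count_summits_in(pos, domains)
  degenerate <- FALSE
  if (p == 0) {
    p_value <- if (k > 0) 0 else 1
    degenerate <- k > 0
  } else if (p >= 1) {
    p_value <- 1
  } else if (k == 0) {
    p_value <- 1
  } else {
    p_value <- stats::pbinom(k - 1L, n, p, lower.tail = FALSE)
  }
  structure(
    list(name = name, n = n, k = k, p = p, p_value = p_value,
         degenerate = degenerate, empirical_fdr = NA_real_,
         fdr_label = NA_character_, n_random_sets = NA_integer_),
    class = "enrichment_test"
  )
}

#' @export
print.enrichment_test <- function(x, ...) {
  cat(sprintf("<enrichment_test> %s\n", x$name))
  cat(sprintf("  k/n = %d/%d, genome fraction p = %.4g, P = %.4g\n",
              x$k, x$n, x$p, x$p_value))
  if (!is.na(x$empirical_fdr)) {
    cat(sprintf("  empirical FDR = %s (%d random sets)\n",
                x$fdr_label, x$n_random_sets))
  }
  invisible(x)
}

# Draw one random summit set: chromosome proportional to length, position
# uniform within the chromosome.
random_summits <- function(n, genome_lengths) {
  chrom <- sample(names(genome_lengths), n, replace = TRUE,
                  prob = genome_lengths / sum(genome_lengths))
  tibble(chrom = chrom,
         pos = as.integer(floor(stats::runif(n, 0, genome_lengths[chrom]))))
}

# Precompute the merged (reduced) domain intervals per chromosome so that
# repeated containment counting does not re-split and re-reduce.
domain_index <- function(domains) {
  lapply(split(domains, domains$chrom), function(d) {
    r <- IRanges::reduce(IRanges::IRanges(d$start + 1L, d$end))
    list(start = IRanges::start(r) - 1L, end = IRanges::end(r))
  })
}

# Count 0-based positions falling inside an index built by domain_index().
count_in_index <- function(chrom, pos, index) {
  k <- 0L
  for (chr in unique(chrom)) {
    ix <- index[[chr]]
    if (is.null(ix)) next
    p <- pos[chrom == chr]
    i <- findInterval(p, ix$start)
    hit <- i >= 1L
    hit[hit] <- p[hit] < ix$end[i[hit]]
    k <- k + sum(hit)
  }
  k
}

#' Empirical FDR from randomised summit sets
#'
#' Draws `n_sets` random summit sets of the same size as the observed set,
#' uniformly over the genome, recomputes the binomial P-value for each, and
#' reports the fraction of random sets achieving a P-value at least as
#' small as the observed one.  A zero count is reported as `"<1/R"`.
#'
#' @param test An `enrichment_test` from [binomial_enrichment()] or
#'   [proximity_enrichment()].
#' @param domains The domain set the test was computed against.
#' @param genome_lengths Named chromosome lengths.
#' @param n_sets Number of random sets `R` (default 100).
#' @param seed Optional integer seed.
#' @return The test with `empirical_fdr`, `fdr_label`, `n_random_sets` and
#'   `random_p_values` filled in.
#' @export
empirical_fdr <- function(test, domains, genome_lengths, n_sets = 100L,
                          seed = NULL) {
  stopifnot(inherits(test, "enrichment_test"), n_sets >= 1)
  p <- test$p
  index <- domain_index(domains)
  chroms <- names(genome_lengths)
  prob <- genome_lengths / sum(genome_lengths)
  with_seed(seed, {
    p_rand <- vapply(seq_len(n_sets), function(r) {
      chrom <- sample(chroms, test$n, replace = TRUE, prob = prob)
      pos <- as.integer(floor(stats::runif(test$n, 0,
                                           genome_lengths[chrom])))
      k <- count_in_index(chrom, pos, index)
      if (k == 0) 1 else {
        stats::pbinom(k - 1L, test$n, p, lower.tail = FALSE)
      }
    }, numeric(1))
    hits <- sum(p_rand <= test$p_value)
    test$empirical_fdr <- hits / n_sets
    test$fdr_label <- if (hits == 0) {
      sprintf("<%g", 1 / n_sets)
    } else {
      format(hits / n_sets)
    }
    test$n_random_sets <- as.integer(n_sets)
    test$random_p_values <- p_rand
    test
  })
}

#' Proximity enrichment of summits near anchor elements
#'
#' Builds merged windows of `+/- window` bp around anchor midpoints and
#' tests, with the binomial model, whether more test summits fall inside
#' the windows than expected from their genomic footprint.
#'
#' @param anchors Tibble of anchor intervals (`chrom`, `start`, `end`).
#' @param summits Tibble of test positions (`chrom` plus `summit`/`pos`).
#' @param genome_lengths Named chromosome lengths.
#' @param window Half-width in bp (default 100 kb).
#' @param name Label for the comparison.
#' @return An `enrichment_test`; its `domains` attribute holds the merged
#'   windows so [empirical_fdr()] can be applied.
#' @export
proximity_enrichment <- function(anchors, summits, genome_lengths,
                                 window = 100000L, name = "proximity") {
  if (nrow(anchors) == 0) abort("no anchor elements")
  mid <- anchors$start + (anchors$end - anchors$start) %/% 2L
  wins <- tibble(
    chrom = anchors$chrom,
    start = pmax(mid - as.integer(window), 0L),
    end = pmin(mid + as.integer(window),
               as.integer(genome_lengths[anchors$chrom]))
  )
  test <- binomial_enrichment(summits, wins, genome_lengths, name = name)
  attr(test, "domains") <- wins
  test
}

#' Count support of query peaks across reference peak sets
#'
#' For each query peak, counts how many reference sets contain at least one
#' interval overlapping the query after widening it by `slop` bp on each
#' side ("regions within 50 bp" semantics).  Returns the 0/1 support matrix
#' and the queries reaching `min_support`.
#'
#' @param query Tibble of query peaks with `peak_id`, `chrom`, `start`,
#'   `end`.
#' @param ref_sets Named list of reference interval tibbles.
#' @param min_support Minimum number of supporting sets.
#' @param slop Widening in bp applied to the query before overlap (default
#'   50).
#' @return A list with `matrix` (tibble: `peak_id` plus one 0/1 column per
#'   reference set and `support`), and `supported` (the query rows with
#'   `support >= min_support`).
#' @export
count_multi_support <- function(query, ref_sets, min_support = 10L,
                                slop = 50L) {
  if (length(ref_sets) < 1) abort("need at least one reference set")
  if (is.null(names(ref_sets))) {
    names(ref_sets) <- paste0("ref", seq_along(ref_sets))
  }
  if (!"peak_id" %in% names(query)) {
    query$peak_id <- sprintf("peak_%05d", seq_len(nrow(query)))
  }
  qs <- pmax(query$start - as.integer(slop), 0L)
  qe <- query$end + as.integer(slop)
  mat <- matrix(0L, nrow = nrow(query), ncol = length(ref_sets),
                dimnames = list(NULL, names(ref_sets)))
  for (j in seq_along(ref_sets)) {
    ref <- ref_sets[[j]]
    for (chr in unique(query$chrom)) {
      qi <- which(query$chrom == chr)
      r <- ref[ref$chrom == chr, , drop = FALSE]
      if (nrow(r) == 0) next
      hits <- IRanges::findOverlaps(
        IRanges::IRanges(qs[qi] + 1L, qe[qi]),
        IRanges::IRanges(r$start + 1L, r$end)
      )
      mat[qi[unique(S4Vectors::queryHits(hits))], j] <- 1L
    }
  }
  support <- as.integer(rowSums(mat))
  matrix_tbl <- dplyr::bind_cols(tibble(peak_id = query$peak_id),
                                 as_tibble(mat))
  matrix_tbl$support <- support
  query$support <- support
  list(matrix = matrix_tbl,
       supported = query[support >= min_support, , drop = FALSE])
}

#' Map genes to the peak summits inside their regulatory domains
#'
#' @param domains Regulatory domains ([regulatory_domains()]).
#' @param summits Tibble of summits (`chrom` plus `summit`/`pos`, and
#'   optionally `peak_id`).
#' @return A tibble with one row per (gene, summit) containment:
#'   `id`, `chrom`, `pos`, `peak_id`.
#' @export
genes_near_peaks <- function(domains, summits) {
  pos <- summit_positions(summits)
  pos$peak_id <- if ("peak_id" %in% names(summits)) summits$peak_id else {
    sprintf("summit_%05d", seq_len(nrow(pos)))
  }
  out <- list()
  for (chr in unique(domains$chrom)) {
    d <- domains[domains$chrom == chr, , drop = FALSE]
    s <- pos[pos$chrom == chr, , drop = FALSE]
    if (nrow(s) == 0) next
    hits <- IRanges::findOverlaps(
      IRanges::IRanges(s$pos + 1L, s$pos + 1L),
      IRanges::IRanges(d$start + 1L, d$end)
    )
    if (length(hits) == 0) next
    out[[length(out) + 1L]] <- tibble(
      id = d$id[S4Vectors::subjectHits(hits)],
      chrom = chr,
      pos = s$pos[S4Vectors::queryHits(hits)],
      peak_id = s$peak_id[S4Vectors::queryHits(hits)]
    )
  }
  if (length(out) == 0) {
    return(tibble(id = character(), chrom = character(),
                  pos = integer(), peak_id = character()))
  }
  dplyr::arrange(dplyr::bind_rows(out), .data$id, .data$chrom, .data$pos)
}
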