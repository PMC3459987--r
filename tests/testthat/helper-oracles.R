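# Brute-force reference implementations used to cross-check the package's
# interval and sequence primitives, plus small scenario builders.

# Per-base fragment-overlap counts over [0, len) for one chromosome.
oracle_coverage_vector <- function(fragments, len) {
  v <- integer(len)
  for (i in seq_len(nrow(fragments))) {
    s <- fragments$start[i] + 1L
    e <- fragments$end[i]
    if (e >= s) v[s:e] <- v[s:e] + 1L
  }
  v
}

# Expand a run-encoded track for one chromosome to a per-base vector.
track_to_vector <- function(track, chrom, len) {
  t <- track[track$chrom == chrom, , drop = FALSE]
  v <- integer(len)
  for (i in seq_len(nrow(t))) {
    v[(t$start[i] + 1L):t$end[i]] <- t$count[i]
  }
  v
}

# Summit oracle: leftmost maximal run of the per-base vector restricted to
# [start, end); center = run_start + floor((width - 1) / 2).
oracle_summit <- function(v, start, end) {
  w <- v[(start + 1L):end]
  r <- rle(w == max(w))
  ends <- cumsum(r$lengths)
  starts <- c(0L, utils::head(ends, -1L))
  i <- which(r$values)[1]
  run_start <- start + starts[i]
  run_end <- start + ends[i]
  as.integer(run_start + (run_end - run_start - 1L) %/% 2L)
}

# Consensus-peak oracle: transitive-overlap components via repeated
# merging, kept only when every caller contributes.
oracle_consensus <- function(peak_sets) {
  all_iv <- do.call(rbind, lapply(names(peak_sets), function(nm) {
    x <- peak_sets[[nm]]
    data.frame(chrom = x$chrom, start = x$start, end = x$end, caller = nm,
               stringsAsFactors = FALSE)
  }))
  res <- list()
  for (chr in sort(unique(all_iv$chrom))) {
    x <- all_iv[all_iv$chrom == chr, , drop = FALSE]
    n <- nrow(x)
    comp <- seq_len(n)
    repeat {
      changed <- FALSE
      for (i in seq_len(n)) for (j in seq_len(n)) {
        if (comp[i] != comp[j] &&
            x$start[i] < x$end[j] && x$start[j] < x$end[i]) {
          comp[comp == comp[j]] <- comp[i]
          changed <- TRUE
        }
      }
      if (!changed) break
    }
    for (cid in unique(comp)) {
      m <- comp == cid
      if (length(unique(x$caller[m])) == length(peak_sets)) {
        res[[length(res) + 1L]] <- data.frame(
          chrom = chr, start = min(x$start[m]), end = max(x$end[m]))
      }
    }
  }
  if (length(res) == 0) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer()))
  }
  out <- do.call(rbind, res)
  out[order(out$chrom, out$start), , drop = FALSE]
}

# IUPAC scan oracle via Biostrings with pattern ambiguity codes.
oracle_scan_iupac <- function(seq, pattern, both_strands = TRUE) {
  subject <- Biostrings::DNAString(seq)
  hit_starts <- function(p) {
    m <- Biostrings::matchPattern(p, subject, fixed = "subject")
    IRanges::start(m) - 1L
  }
  w <- nchar(pattern)
  fwd <- hit_starts(pattern)
  out <- data.frame(start = fwd, strand = rep("+", length(fwd)))
  if (both_strands) {
    rev <- hit_starts(as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(pattern))))
    out <- rbind(out, data.frame(start = rev,
                                 strand = rep("-", length(rev))))
  }
  out$end <- out$start + w
  out <- out[order(out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Hamming-scan oracle for the palindrome matcher.
oracle_match_palindrome <- function(seq, consensus, max_mismatch) {
  seq <- toupper(seq)
  w <- nchar(consensus)
  n <- nchar(seq)
  res <- list()
  pats <- list(`+` = consensus, `-` = revcomp(consensus))
  if (pats[["+"]] == pats[["-"]]) pats <- pats["+"]
  for (strand in names(pats)) {
    pat <- pats[[strand]]
    for (pos in 0:(n - w)) {
      mm <- hamming_chr(substr(seq, pos + 1L, pos + w), pat)
      if (mm <= max_mismatch) {
        res[[length(res) + 1L]] <- data.frame(
          position = pos, strand = strand, mismatches = mm)
      }
    }
  }
  if (length(res) == 0) {
    return(data.frame(position = integer(), strand = character(),
                      mismatches = integer()))
  }
  out <- do.call(rbind, res)
  out[order(out$position, out$strand), , drop = FALSE]
}

hamming_chr <- function(a, b) {
  va <- strsplit(a, "", fixed = TRUE)[[1]]
  vb <- strsplit(b, "", fixed = TRUE)[[1]]
  acgt <- c("A", "C", "G", "T")
  sum(va != vb | !(va %in% acgt) | !(vb %in% acgt))
}

revcomp_chr <- function(x) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", toupper(x)), "",
                     fixed = TRUE)[[1]]), collapse = "")
}

# Per-base genome-fraction oracle.
oracle_union_fraction <- function(domains, genome_lengths) {
  covered <- 0
  for (chr in names(genome_lengths)) {
    v <- logical(genome_lengths[[chr]])
    d <- domains[domains$chrom == chr, , drop = FALSE]
    for (i in seq_len(nrow(d))) {
      if (d$end[i] > d$start[i]) v[(d$start[i] + 1L):d$end[i]] <- TRUE
    }
    covered <- covered + sum(v)
  }
  covered / sum(as.numeric(genome_lengths))
}

# Binomial upper-tail oracle by pmf summation.
oracle_binom_upper <- function(k, n, p) {
  if (k <= 0) return(1)
  sum(stats::dbinom(k:n, n, p))
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# A small reusable genome scenario with planted elements, motifs and genes.
small_scenario <- function(seed = 42L) {
  spec <- random_genome_spec(
    chrom_lengths = c(chr1 = 3e5, chr2 = 3e5),
    n_mer85 = 6, n_bound_mer85 = 3, n_tre = 6, n_bound_tre = 3,
    n_tead1 = 2, n_ctcf = 2, n_genes = 8, genes_near_tre = 0,
    seed = seed
  )
  generate_genome(spec)
}
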