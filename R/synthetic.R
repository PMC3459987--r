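# Synthetic data generator: toy genomes with planted piggyBac-derived
# elements, transcription-factor motif sites and gene models, plus simulated
# paired-end ChIP fragments and expression tables with known truth labels.

#' Specify a synthetic genome
#'
#' Collects the layout of a toy genome: chromosome lengths, planted
#' MER85/PGBD3-like elements, planted motif sites, and gene models.  All
#' coordinates are 0-based half-open.  The constructor validates that every
#' planted feature lies inside its chromosome and that no two planted
#' features overlap.
#'
#' @param chrom_lengths Named integer vector of chromosome lengths (bp).
#' @param elements Tibble of planted elements with columns `kind`
#'   (`"MER85"` or `"PGBD3"`), `chrom`, `start`, `strand`, `bound` and
#'   optionally `palindrome_mismatches` (default 0), `tir5_intact`,
#'   `tir3_intact` (default `TRUE`).
#' @param motifs Tibble of planted motif sites with columns `chrom`, `pos`,
#'   `pattern` (a name from [motif_patterns()]), `strand` and optionally
#'   `bound` (default `TRUE`).
#' @param genes Tibble of gene models with columns `gene_id`, `chrom`,
#'   `tss`, `strand`.
#' @param seed Integer RNG seed controlling background sequence and all
#'   downstream simulation randomness.
#' @return A list of class `genome_spec`.
#' @export
synthetic_genome_spec <- function(chrom_lengths, elements = NULL,
                                  motifs = NULL, genes = NULL, seed = 1L) {
  validate_genome_lengths(chrom_lengths)
  chrom_lengths <- stats::setNames(as.integer(chrom_lengths),
                                   names(chrom_lengths))
  model <- element_model()

  if (is.null(elements)) {
    elements <- tibble(kind = character(), chrom = character(),
                       start = integer(), strand = character(),
                       bound = logical())
  }
  elements <- as_tibble(elements)
  if (nrow(elements) > 0) {
    if (!"palindrome_mismatches" %in% names(elements)) {
      elements$palindrome_mismatches <- 0L
    }
    if (!"tir5_intact" %in% names(elements)) elements$tir5_intact <- TRUE
    if (!"tir3_intact" %in% names(elements)) elements$tir3_intact <- TRUE
    if (!all(elements$kind %in% c("MER85", "PGBD3"))) {
      abort("element kind must be 'MER85' or 'PGBD3'")
    }
  }
  elements$length <- ifelse(elements$kind == "MER85",
                            model$mer85_length, 2500L)
  elements$end <- as.integer(elements$start + elements$length)

  if (is.null(motifs)) {
    motifs <- tibble(chrom = character(), pos = integer(),
                     pattern = character(), strand = character(),
                     bound = logical())
  }
  motifs <- as_tibble(motifs)
  if (nrow(motifs) > 0) {
    if (!"bound" %in% names(motifs)) motifs$bound <- TRUE
    pat <- motif_patterns()
    if (!all(motifs$pattern %in% pat$name)) {
      abort("unknown motif pattern name in `motifs`")
    }
    motifs$width <- nchar(pat$iupac[match(motifs$pattern, pat$name)])
  } else {
    motifs$width <- integer()
  }

  if (is.null(genes)) {
    genes <- tibble(gene_id = character(), chrom = character(),
                    tss = integer(), strand = character())
  }
  genes <- as_tibble(genes)

  # range checks
  check_inside <- function(chrom, start, end, what) {
    bad <- !(chrom %in% names(chrom_lengths)) | start < 0 |
      end > chrom_lengths[chrom]
    if (any(bad)) {
      abort(sprintf("%s #%d lies outside its chromosome",
                    what, which(bad)[1]))
    }
  }
  if (nrow(elements) > 0) {
    check_inside(elements$chrom, elements$start, elements$end, "element")
  }
  if (nrow(motifs) > 0) {
    check_inside(motifs$chrom, motifs$pos, motifs$pos + motifs$width, "motif")
  }
  if (nrow(genes) > 0) {
    check_inside(genes$chrom, genes$tss, genes$tss + 1L, "gene TSS")
  }

  # planted features must not overlap one another
  planted <- dplyr::bind_rows(
    if (nrow(elements) > 0) {
      tibble(chrom = elements$chrom, start = elements$start,
             end = elements$end,
             label = paste0(elements$kind, "_", seq_len(nrow(elements))))
    },
    if (nrow(motifs) > 0) {
      tibble(chrom = motifs$chrom, start = motifs$pos,
             end = motifs$pos + motifs$width,
             label = paste0(motifs$pattern, "_", seq_len(nrow(motifs))))
    }
  )
  if (!is.null(planted) && nrow(planted) > 1) {
    ir <- as_iranges_list(planted)
    lab <- split(planted$label, planted$chrom)
    for (chr in names(ir)) {
      hits <- IRanges::findOverlaps(ir[[chr]], ir[[chr]])
      hits <- hits[S4Vectors::queryHits(hits) < S4Vectors::subjectHits(hits)]
      if (length(hits) > 0) {
        abort(sprintf("planted features overlap on %s: %s and %s", chr,
                      lab[[chr]][S4Vectors::queryHits(hits)[1]],
                      lab[[chr]][S4Vectors::subjectHits(hits)[1]]))
      }
    }
  }

  structure(
    list(chrom_lengths = chrom_lengths, elements = elements,
         motifs = motifs, genes = genes, seed = as.integer(seed),
         model = model),
    class = "genome_spec"
  )
}

#' Simulation parameters for fragments and expression
#'
#' @param n_fragments_signal Number of signal (enriched) ChIP fragment pairs.
#' @param n_fragments_background Number of background ChIP fragment pairs.
#' @param n_input_reads Number of single-end input-control reads
#'   (defaults to `n_fragments_background`).
#' @param fragment_length_range Sonicated fragment size-selection window in
#'   bp; the default `c(300, 600)` mirrors a typical paired-end ChIP library.
#' @param read_length Read length in bp (default 36).
#' @param binding_offset Offset in bp from the element 5' TSD where signal
#'   fragment centers concentrate; the default 25 is the middle of the
#'   internal palindrome.
#' @param enrichment_sd Standard deviation (bp) of fragment centers around
#'   the binding position; models shearing spread.  Because fragments are
#'   constrained to contain their binding site, the coverage peak is only
#'   sharply anchored at the site when the spread is comparable to the
#'   minimum half fragment length (so that an appreciable number of
#'   fragment boundaries are clamped at the site); the default 100 vs the
#'   default minimum half-length 150 yields roughly 2% clamped fragments
#'   per side.
#' @param up_slr,down_slr Planted expression effects (log2 signal ratios)
#'   for genes near bound TRE sites.
#' @param slr_noise_sd Standard deviation of SLR noise for all genes.
#' @param regulatory_distance Maximum TSS distance (bp) from a bound TRE
#'   site for a gene to receive a planted expression effect.
#' @param seed Integer RNG seed.
#' @return A list of class `sim_config`.
#' @export
simulation_config <- function(n_fragments_signal = 5000L,
                              n_fragments_background = 5000L,
                              n_input_reads = n_fragments_background,
                              fragment_length_range = c(300L, 600L),
                              read_length = 36L,
                              binding_offset = 25L,
                              enrichment_sd = 100,
                              up_slr = 2, down_slr = -2,
                              slr_noise_sd = 0.3,
                              regulatory_distance = 50000L,
                              seed = 1L) {
  if (fragment_length_range[1] < 2 * read_length) {
    abort("minimum fragment length must be at least twice the read length")
  }
  if (!all(is.finite(c(up_slr, down_slr, slr_noise_sd)))) {
    abort("SLR effects must be finite")
  }
  structure(
    list(n_fragments_signal = as.integer(n_fragments_signal),
         n_fragments_background = as.integer(n_fragments_background),
         n_input_reads = as.integer(n_input_reads),
         fragment_length_range = as.integer(fragment_length_range),
         read_length = as.integer(read_length),
         binding_offset = as.integer(binding_offset),
         enrichment_sd = enrichment_sd,
         up_slr = up_slr, down_slr = down_slr,
         slr_noise_sd = slr_noise_sd,
         regulatory_distance = as.integer(regulatory_distance),
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

# Build the concrete planted sequence for one element row.
element_sequence <- function(row, model) {
  base <- if (row$kind == "MER85") mer85_consensus(model) else {
    pgbd3_consensus(model)
  }
  chars <- strsplit(base, "", fixed = TRUE)[[1]]
  off <- mer85_truth_offsets(model)
  if (row$kind == "PGBD3") {
    off$tir3 <- c(length(chars) - model$tir_length, length(chars))
  }
  mutate_at <- function(idx) {
    for (i in idx) {
      chars[i] <<- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1)
    }
  }
  if (row$palindrome_mismatches > 0) {
    pal_idx <- (off$palindrome[1] + 1L):off$palindrome[2]
    mutate_at(sample(pal_idx, row$palindrome_mismatches))
  }
  if (!row$tir5_intact) {
    tir_idx <- (off$tir5[1] + 1L):off$tir5[2]
    mutate_at(sample(tir_idx, 6))
  }
  if (!row$tir3_intact) {
    tir_idx <- (off$tir3[1] + 1L):off$tir3[2]
    mutate_at(sample(tir_idx, 6))
  }
  paste(chars, collapse = "")
}

# Choose one concrete instantiation of an IUPAC pattern.
instantiate_iupac <- function(iupac) {
  codes <- iupac_code_table()
  chars <- strsplit(iupac, "", fixed = TRUE)[[1]]
  paste(vapply(chars, function(ch) {
    opts <- strsplit(codes[[ch]], "", fixed = TRUE)[[1]]
    if (length(opts) == 1) opts else sample(opts, 1)
  }, character(1)), collapse = "")
}

#' Generate a synthetic genome with planted features
#'
#' Draws uniform-ACGT background sequence and writes the planted elements,
#' motif instances and (implicitly, as coordinates only) gene TSSs declared
#' in the spec.  Elements are written in their declared orientation; a
#' second TTAA target-site copy is written immediately 3' of each element.
#' Fully deterministic given `spec$seed`.
#'
#' @param spec A [synthetic_genome_spec()].
#' @return A list of class `synthetic_genome` with components `sequences`
#'   (a named `DNAStringSet`), `elements`, `motifs`, `genes` (truth tibbles
#'   with exact planted coordinates) and `chrom_lengths`.
#' @export
generate_genome <- function(spec) {
  stopifnot(inherits(spec, "genome_spec"))
  model <- spec$model
  with_seed(spec$seed, {
    seqs <- lapply(spec$chrom_lengths, function(len) {
      sample(c("A", "C", "G", "T"), len, replace = TRUE)
    })

    elements <- spec$elements
    if (nrow(elements) > 0) {
      elements$element_id <- sprintf("%s_%03d", elements$kind,
                                     seq_len(nrow(elements)))
      off <- mer85_truth_offsets(model)
      truth <- lapply(seq_len(nrow(elements)), function(i) {
        row <- elements[i, ]
        eseq <- element_sequence(row, model)
        oriented <- if (row$strand == "-") revcomp(eseq) else eseq
        chars <- strsplit(oriented, "", fixed = TRUE)[[1]]
        idx <- (row$start + 1L):(row$start + row$length)
        seqs[[row$chrom]][idx] <<- chars
        # second TSD copy in the 3' flank (element orientation)
        if (row$strand == "+") {
          if (row$end + 4L <= spec$chrom_lengths[row$chrom]) {
            seqs[[row$chrom]][(row$end + 1L):(row$end + 4L)] <<-
              strsplit(model$tsd_seq, "")[[1]]
          }
        } else if (row$start >= 4L) {
          seqs[[row$chrom]][(row$start - 3L):row$start] <<-
            strsplit(revcomp(model$tsd_seq), "")[[1]]
        }
        o3 <- if (row$kind == "PGBD3") {
          c(row$length - model$tir_length, row$length)
        } else {
          off$tir3
        }
        tibble(
          tsd_offset = off$tsd[1], tir5_offset = off$tir5[1],
          palindrome_offset = off$palindrome[1], tir3_offset = o3[1],
          sequence = eseq
        )
      })
      elements <- dplyr::bind_cols(elements, dplyr::bind_rows(truth))
    }

    motifs <- spec$motifs
    if (nrow(motifs) > 0) {
      pat <- motif_patterns()
      motifs$site_id <- sprintf("%s_%03d", motifs$pattern,
                                seq_len(nrow(motifs)))
      for (i in seq_len(nrow(motifs))) {
        iupac <- pat$iupac[match(motifs$pattern[i], pat$name)]
        inst <- instantiate_iupac(iupac)
        if (motifs$strand[i] == "-") inst <- revcomp(inst)
        idx <- (motifs$pos[i] + 1L):(motifs$pos[i] + nchar(inst))
        seqs[[motifs$chrom[i]]][idx] <- strsplit(inst, "")[[1]]
      }
    }

    sequences <- Biostrings::DNAStringSet(
      vapply(seqs, paste, character(1), collapse = "")
    )
    structure(
      list(sequences = sequences, elements = elements, motifs = motifs,
           genes = spec$genes, chrom_lengths = spec$chrom_lengths,
           model = model, seed = spec$seed),
      class = "synthetic_genome"
    )
  })
}

# Genomic position of the binding site for each bound feature: elements bind
# at `binding_offset` bp from the 5' TSD (element-oriented); motif sites bind
# at the motif midpoint.
binding_positions <- function(genome, config) {
  el <- genome$elements
  mo <- genome$motifs
  out <- dplyr::bind_rows(
    if (nrow(el) > 0 && any(el$bound)) {
      b <- el[el$bound, ]
      tibble(
        chrom = b$chrom,
        pos = ifelse(b$strand == "+",
                     b$start + config$binding_offset,
                     b$end - 1L - config$binding_offset)
      )
    },
    if (nrow(mo) > 0 && any(mo$bound)) {
      b <- mo[mo$bound, ]
      tibble(chrom = b$chrom, pos = b$pos + b$width %/% 2L)
    }
  )
  if (is.null(out)) tibble(chrom = character(), pos = integer()) else out
}

#' Simulate paired-end ChIP fragments and input-control reads
#'
#' Signal fragment centers are drawn Normal around the binding position of a
#' uniformly chosen bound feature (truncated to the chromosome); background
#' fragment centers are uniform over the genome with chromosomes chosen
#' proportional to length.  Fragment lengths are uniform over
#' `fragment_length_range`.  Each fragment is emitted as two reads of
#' `read_length` bp at its ends, on opposite strands.  Input records are
#' single-end uniform background reads.
#'
#' @param genome A [generate_genome()] result.
#' @param config A [simulation_config()].
#' @return A list with `pairs` (BEDPE-layout tibble of ChIP mate pairs) and
#'   `input` (tibble of single-end input reads: `chrom`, `start`, `end`,
#'   `strand`).
#' @export
simulate_fragments <- function(genome, config = simulation_config()) {
  stopifnot(inherits(genome, "synthetic_genome"))
  lens <- genome$chrom_lengths
  if (length(lens) == 0) abort("empty genome")
  sites <- binding_positions(genome, config)
  if (config$n_fragments_signal > 0 && nrow(sites) == 0) {
    abort("no bound elements or motif sites to place signal fragments on")
  }
  with_seed(config$seed, {
    flr <- config$fragment_length_range
    # background: center anywhere, clipped to the chromosome
    draw_frag <- function(chrom, center) {
      len <- sample(seq(flr[1], flr[2]), length(center), replace = TRUE)
      start <- as.integer(round(center - len / 2))
      end <- start + len
      # truncate to chromosome bounds, preserving length where possible
      shift <- pmax(0L, -start) - pmax(0L, end - lens[chrom])
      tibble(chrom = chrom, start = start + shift, end = end + shift)
    }

    n_sig <- config$n_fragments_signal
    sig <- NULL
    if (n_sig > 0) {
      pick <- sample.int(nrow(sites), n_sig, replace = TRUE)
      center <- stats::rnorm(n_sig, mean = sites$pos[pick],
                             sd = config$enrichment_sd)
      len <- sample(seq(flr[1], flr[2]), n_sig, replace = TRUE)
      # an immunoprecipitated fragment contains the crosslinked binding
      # site: truncate the center so the fragment spans it
      center <- pmin(pmax(center, sites$pos[pick] - len / 2 + 1),
                     sites$pos[pick] + len / 2 - 1)
      start <- as.integer(round(center - len / 2))
      end <- start + len
      shift <- pmax(0L, -start) -
        pmax(0L, end - lens[sites$chrom[pick]])
      sig <- tibble(chrom = sites$chrom[pick],
                    start = start + shift, end = end + shift)
    }

    n_bg <- config$n_fragments_background
    bg <- NULL
    if (n_bg > 0) {
      chrom <- sample(names(lens), n_bg, replace = TRUE,
                      prob = lens / sum(lens))
      center <- floor(stats::runif(n_bg, 0, lens[chrom]))
      bg <- draw_frag(chrom, center)
    }

    frags <- dplyr::bind_rows(sig, bg)
    rl <- config$read_length
    pairs <- tibble(
      chrom1 = frags$chrom, start1 = frags$start,
      end1 = frags$start + rl,
      chrom2 = frags$chrom, start2 = frags$end - rl, end2 = frags$end,
      name = sprintf("frag_%06d", seq_len(nrow(frags))),
      score = 0,
      strand1 = "+", strand2 = "-"
    )

    n_in <- config$n_input_reads
    input <- if (n_in > 0) {
      chrom <- sample(names(lens), n_in, replace = TRUE,
                      prob = lens / sum(lens))
      start <- floor(stats::runif(n_in, 0, lens[chrom] - rl))
      tibble(chrom = chrom, start = as.integer(start),
             end = as.integer(start) + rl,
             strand = sample(c("+", "-"), n_in, replace = TRUE))
    } else {
      tibble(chrom = character(), start = integer(), end = integer(),
             strand = character())
    }
    list(pairs = pairs, input = input)
  })
}

#' Simulate an expression table with planted regulation near bound TRE sites
#'
#' Genes whose TSS lies within `regulatory_distance` of a bound TRE motif
#' site receive a signal log ratio drawn around `up_slr` or `down_slr`
#' (direction assigned at random per gene); all other genes — including
#' genes near MER85 elements — receive SLR ~ Normal(0, `slr_noise_sd`).
#' Truth labels are recorded so recovery can be checked against the planted
#' ground truth.
#'
#' @param genome A [generate_genome()] result.
#' @param config A [simulation_config()].
#' @return A tibble with `probe_id`, `gene_id`, `slr` and a `truth` column
#'   (`"up"`, `"down"` or `"null"`).
#' @export
simulate_expression <- function(genome, config = simulation_config()) {
  stopifnot(inherits(genome, "synthetic_genome"))
  genes <- genome$genes
  if (nrow(genes) == 0) abort("no gene models in the genome")
  tre <- genome$motifs[genome$motifs$pattern == "TRE" & genome$motifs$bound, ]
  near_tre <- rep(FALSE, nrow(genes))
  if (nrow(tre) > 0) {
    for (i in seq_len(nrow(genes))) {
      same <- tre$chrom == genes$chrom[i]
      if (any(same)) {
        d <- abs(tre$pos[same] + tre$width[same] %/% 2 - genes$tss[i])
        near_tre[i] <- min(d) <= config$regulatory_distance
      }
    }
  }
  with_seed(config$seed + 1L, {
    direction <- ifelse(near_tre,
                        sample(c("up", "down"), nrow(genes), replace = TRUE),
                        "null")
    effect <- dplyr::case_when(
      direction == "up" ~ config$up_slr,
      direction == "down" ~ config$down_slr,
      TRUE ~ 0
    )
    noise <- if (config$slr_noise_sd > 0) {
      stats::rnorm(nrow(genes), 0, config$slr_noise_sd)
    } else {
      rep(0, nrow(genes))
    }
    tibble(
      probe_id = paste0(genes$gene_id, "_at"),
      gene_id = genes$gene_id,
      chrom = genes$chrom, tss = genes$tss, strand = genes$strand,
      slr = effect + noise,
      truth = direction
    )
  })
}

#' Randomly lay out a synthetic binding study
#'
#' Convenience constructor that places non-overlapping MER85 elements, TRE /
#' TEAD1 / CTCF motif sites and gene TSSs uniformly at random over a toy
#' genome, then returns the validated [synthetic_genome_spec()].  Genes are
#' placed independently of elements, so gene-to-feature proximity arises by
#' chance unless `genes_near_tre` is set, in which case that many genes are
#' placed within 10-50 kb of distinct bound TRE sites (creating a planted
#' regulatory association for enrichment tests).
#'
#' @param chrom_lengths Named vector of chromosome lengths.
#' @param n_mer85,n_bound_mer85 Number of MER85 elements and how many of
#'   them are bound.
#' @param n_tre,n_bound_tre Number of TRE sites and how many are bound.
#' @param n_tead1,n_ctcf Numbers of TEAD1 and CTCF sites (all bound).
#' @param n_genes Number of gene models.
#' @param genes_near_tre Number of genes placed near bound TRE sites.
#' @param seed Integer RNG seed.
#' @return A `genome_spec`.
#' @export
random_genome_spec <- function(chrom_lengths = c(chr1 = 2e6, chr2 = 2e6),
                               n_mer85 = 20, n_bound_mer85 = 10,
                               n_tre = 20, n_bound_tre = 10,
                               n_tead1 = 5, n_ctcf = 5,
                               n_genes = 50, genes_near_tre = 0,
                               seed = 1L) {
  validate_genome_lengths(chrom_lengths)
  chrom_lengths <- stats::setNames(as.integer(chrom_lengths),
                                   names(chrom_lengths))
  stopifnot(n_bound_mer85 <= n_mer85, n_bound_tre <= n_tre,
            genes_near_tre <= n_genes,
            genes_near_tre == 0 || n_bound_tre > 0)
  with_seed(seed, {
    taken <- lapply(chrom_lengths, function(l) IRanges::IRanges())
    # keep planted features min_gap apart so fragment pileups and profile
    # windows of neighbouring features never overlap
    place <- function(n, width, margin = 1000L, min_gap = 2000L) {
      out <- vector("list", n)
      for (i in seq_len(n)) {
        repeat {
          chrom <- sample(names(chrom_lengths), 1,
                          prob = chrom_lengths / sum(chrom_lengths))
          start <- floor(stats::runif(1, margin,
                                      chrom_lengths[chrom] - width - margin))
          cand <- IRanges::IRanges(start + 1L - min_gap,
                                   start + width + min_gap)
          if (length(IRanges::findOverlaps(cand, taken[[chrom]])) == 0) {
            taken[[chrom]] <<- c(taken[[chrom]], cand)
            out[[i]] <- tibble(chrom = chrom, start = as.integer(start))
            break
          }
        }
      }
      dplyr::bind_rows(out)
    }
    elements <- NULL
    if (n_mer85 > 0) {
      pos <- place(n_mer85, MER85_LENGTH + 8L)
      elements <- tibble(
        kind = "MER85", chrom = pos$chrom, start = pos$start,
        strand = sample(c("+", "-"), n_mer85, replace = TRUE),
        bound = seq_len(n_mer85) <= n_bound_mer85
      )
    }
    motif_rows <- list()
    add_motifs <- function(pattern, n, n_bound) {
      if (n == 0) return()
      w <- nchar(motif_patterns()$iupac[motif_patterns()$name == pattern])
      pos <- place(n, w + 4L)
      motif_rows[[length(motif_rows) + 1L]] <<- tibble(
        chrom = pos$chrom, pos = pos$start, pattern = pattern,
        strand = sample(c("+", "-"), n, replace = TRUE),
        bound = seq_len(n) <= n_bound
      )
    }
    add_motifs("TRE", n_tre, n_bound_tre)
    add_motifs("TEAD1", n_tead1, n_tead1)
    add_motifs("CTCF", n_ctcf, n_ctcf)
    motifs <- if (length(motif_rows)) dplyr::bind_rows(motif_rows) else NULL

    genes <- NULL
    if (n_genes > 0) {
      near <- NULL
      if (genes_near_tre > 0) {
        tre_bound <- motifs[motifs$pattern == "TRE" & motifs$bound, ,
                            drop = FALSE]
        anchor <- tre_bound[
          sample.int(nrow(tre_bound), genes_near_tre, replace = TRUE), ]
        offset <- sample(10000:50000, genes_near_tre, replace = TRUE) *
          sample(c(-1L, 1L), genes_near_tre, replace = TRUE)
        tss <- pmin(pmax(anchor$pos + offset, 0L),
                    chrom_lengths[anchor$chrom] - 1L)
        near <- tibble(chrom = anchor$chrom, tss = as.integer(tss))
      }
      n_far <- n_genes - genes_near_tre
      far <- if (n_far > 0) {
        chrom <- sample(names(chrom_lengths), n_far, replace = TRUE,
                        prob = chrom_lengths / sum(chrom_lengths))
        tibble(chrom = chrom,
               tss = as.integer(floor(stats::runif(n_far, 0,
                                                   chrom_lengths[chrom]))))
      } else {
        NULL
      }
      gpos <- dplyr::bind_rows(near, far)
      genes <- tibble(
        gene_id = sprintf("gene_%03d", seq_len(n_genes)),
        chrom = gpos$chrom, tss = gpos$tss,
        strand = sample(c("+", "-"), n_genes, replace = TRUE)
      )
    }
    synthetic_genome_spec(chrom_lengths, elements, motifs, genes, seed = seed)
  })
}
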