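test_that("probe_start_sites picks the stranded 5' end", {
  probes <- tibble::tibble(chrom = "chr1", start = c(100L, 100L),
                           end = c(200L, 200L), strand = c("+", "-"),
                           gene_id = c("g1", "g2"))
  s <- probe_start_sites(probes)
  expect_equal(s$site, c(100L, 199L))
  expect_error(probe_start_sites(dplyr::select(probes, -strand)), "strand")
  tss <- probe_start_sites(tibble::tibble(chrom = "chr1", tss = 5L,
                                          strand = "+", gene_id = "g"))
  expect_equal(tss$site, 5L)
})

test_that("basal regulatory domains extend but respect neighbours", {
  gl <- c(chr1 = 1e6)
  sites <- tibble::tibble(gene_id = c("a", "b"), chrom = "chr1",
                          site = c(100000L, 130000L), strand = "+")
  d <- regulatory_domains(probe_start_sites(
    tibble::tibble(gene_id = sites$gene_id, chrom = sites$chrom,
                   tss = sites$site, strand = sites$strand)),
    max_extension = 100000L, genome_lengths = gl)
  # left gene: free extension left, right extension stops at b's basal start
  expect_equal(d$start[d$id == "a"], 0L)
  expect_equal(d$end[d$id == "a"], 125000L)   # b's basal = 130000 - 5000
  # right gene: left extension stops at a's basal end (100000 + 1000)
  expect_equal(d$start[d$id == "b"], 101000L)
  expect_equal(d$end[d$id == "b"], 230000L)
  # a site always keeps its own basal region even when neighbours are close
  near <- tibble::tibble(gene_id = c("x", "y"), chrom = "chr1",
                         tss = c(50000L, 50100L), strand = "+")
  dn <- regulatory_domains(probe_start_sites(near), 100000L, gl)
  expect_true(all(dn$end > dn$start))
  expect_true(dn$end[dn$id == "x"] >= 51000L)   # own basal_down
  expect_true(dn$start[dn$id == "y"] <= 45100L) # own basal_up
})

test_that("extension-mode domains truncate at site midpoints", {
  gl <- c(chr1 = 1e6)
  sites <- tibble::tibble(gene_id = c("a", "b"), chrom = "chr1",
                          tss = c(100000L, 150000L), strand = "+")
  d <- regulatory_domains(probe_start_sites(sites), 100000L, gl,
                          mode = "extension")
  expect_equal(d$end[d$id == "a"], 125000L)
  expect_equal(d$start[d$id == "b"], 125000L)
  expect_equal(d$start[d$id == "a"], 0L)
  expect_equal(d$end[d$id == "b"], 250000L)
})

test_that("domain_union_fraction equals a per-base oracle", {
  gl <- c(c1 = 400L, c2 = 300L)
  with_seed(909, {
    for (rep in 1:100) {
      n <- sample(1:10, 1)
      chrom <- sample(names(gl), n, replace = TRUE)
      start <- vapply(chrom, function(ch) {
        sample(0:(gl[[ch]] - 2L), 1)
      }, integer(1))
      d <- tibble::tibble(chrom = chrom, start = start,
                          end = pmin(start + sample(5:80, n, TRUE),
                                     gl[chrom]))
      expect_equal(domain_union_fraction(d, gl),
                   oracle_union_fraction(d, gl))
    }
  })
  # idempotence under duplication: union, not sum
  d <- tibble::tibble(chrom = "c1", start = c(0L, 0L), end = c(100L, 100L))
  expect_equal(domain_union_fraction(d, gl), 100 / 700)
})

test_that("binomial_enrichment reproduces exact closed-form tails", {
  # P(X >= 8), X ~ Bin(10, 0.5) = 56/1024
  gl <- c(c1 = 1000L)
  domains <- tibble::tibble(chrom = "c1", start = 0L, end = 500L)
  summits <- tibble::tibble(chrom = "c1",
                            pos = c(seq(0L, 350L, by = 50L),
                                    c(600L, 700L)))
  t <- binomial_enrichment(summits, domains, gl)
  expect_equal(t$n, 10L)
  expect_equal(t$k, 8L)
  expect_equal(t$p, 0.5)
  expect_equal(t$p_value, 56 / 1024)
})

test_that("binomial p-values equal pmf summation on random cases", {
  gl <- c(c1 = 2000L)
  with_seed(1010, {
    for (rep in 1:100) {
      w <- sample(100:1500, 1)
      domains <- tibble::tibble(chrom = "c1", start = 0L, end = w)
      n <- sample(2:40, 1)
      pos <- sample(0:1999, n, replace = TRUE)
      t <- binomial_enrichment(tibble::tibble(chrom = "c1", pos = pos),
                               domains, gl)
      expect_equal(t$k, sum(pos < w))
      expect_equal(t$p_value, oracle_binom_upper(t$k, n, w / 2000),
                   tolerance = 1e-12)
    }
  })
})

test_that("degenerate domain fractions are handled explicitly", {
  gl <- c(c1 = 100L)
  s <- tibble::tibble(chrom = "c1", pos = 50L)
  all_dom <- tibble::tibble(chrom = "c1", start = 0L, end = 100L)
  expect_equal(binomial_enrichment(s, all_dom, gl)$p_value, 1)
  none <- all_dom[0, ]
  t0 <- binomial_enrichment(s, none, gl)
  expect_equal(t0$p, 0)
  expect_equal(t0$p_value, 1)
  expect_error(binomial_enrichment(s[0, ], all_dom, gl), "at least one")
})

test_that("empirical_fdr is deterministic under a seed and labels <1/R", {
  gl <- c(c1 = 1e5, c2 = 1e5)
  domains <- tibble::tibble(chrom = "c1", start = 0L, end = 2000L)
  summits <- tibble::tibble(chrom = "c1", pos = seq(100L, 1900L, by = 200L))
  t <- binomial_enrichment(summits, domains, gl)
  f1 <- empirical_fdr(t, domains, gl, n_sets = 50L, seed = 12L)
  f2 <- empirical_fdr(t, domains, gl, n_sets = 50L, seed = 12L)
  expect_identical(f1$random_p_values, f2$random_p_values)
  # all 10 observed summits inside a 1% footprint: no random set matches
  expect_equal(f1$empirical_fdr, 0)
  expect_equal(f1$fdr_label, "<0.02")
  expect_equal(f1$n_random_sets, 50L)
})

test_that("proximity_enrichment counts summits near anchor midpoints", {
  gl <- c(c1 = 1e6)
  anchors <- tibble::tibble(chrom = "c1", start = 500000L, end = 500140L)
  summits <- tibble::tibble(chrom = "c1", pos = c(450000L, 700000L))
  t <- proximity_enrichment(anchors, summits, gl, window = 100000L)
  expect_equal(t$k, 1L)
  expect_equal(t$n, 2L)
  expect_equal(t$p, 200000 / 1e6, tolerance = 1e-4)
  expect_s3_class(attr(t, "domains"), "tbl_df")
})

test_that("count_multi_support applies the slop and threshold rules", {
  query <- tibble::tibble(peak_id = c("q1", "q2"), chrom = "c1",
                          start = c(1000L, 5000L), end = c(1100L, 5100L))
  mk_ref <- function(s) tibble::tibble(chrom = "c1", start = s, end = s + 10L)
  refs <- c(
    replicate(10, mk_ref(1140L), simplify = FALSE),   # within 50 bp of q1
    replicate(8, mk_ref(900000L), simplify = FALSE)
  )
  names(refs) <- paste0("set", seq_along(refs))
  out <- count_multi_support(query, refs, min_support = 10L, slop = 50L)
  expect_equal(out$matrix$support, c(10L, 0L))
  expect_equal(out$supported$peak_id, "q1")
  # 51 bp away: no longer counted
  refs2 <- replicate(10, mk_ref(1151L), simplify = FALSE)
  names(refs2) <- paste0("far", 1:10)
  out2 <- count_multi_support(query, refs2, min_support = 10L, slop = 50L)
  expect_equal(out2$matrix$support, c(0L, 0L))
})

test_that("genes_near_peaks lists each (gene, summit) containment", {
  gl <- c(c1 = 1e6)
  genes <- tibble::tibble(gene_id = c("g1", "g2"), chrom = "c1",
                          tss = c(100000L, 600000L), strand = "+")
  domains <- regulatory_domains(probe_start_sites(genes), 50000L, gl)
  summits <- tibble::tibble(chrom = "c1", pos = c(120000L, 130000L,
                                                  900000L),
                            peak_id = c("p1", "p2", "p3"))
  near <- genes_near_peaks(domains, summits)
  expect_equal(near$id, c("g1", "g1"))
  expect_setequal(near$peak_id, c("p1", "p2"))
})
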