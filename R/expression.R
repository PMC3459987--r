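# Regulated-gene classification from signal-log-ratio tables, QPCR
# delta-delta-Ct signal log ratios, and gene-set intersections.

#' Classify regulated genes from signal log ratios
#'
#' Partitions records into `up` (SLR strictly greater than
#' `up_threshold`), `down` (SLR strictly less than `down_threshold`) and
#' `unchanged` (inclusive interval in between); the defaults implement the
#' 2-fold rule SLR > 1 / SLR < -1.  Records with non-finite SLR are
#' rejected and tallied in the `"rejected"` attribute.
#'
#' @param records Tibble with an `slr` column (plus any id columns).
#' @param up_threshold,down_threshold Strict thresholds, `down < up`.
#' @return The finite-SLR records with an added `direction` factor
#'   (`up` / `down` / `unchanged`).
#' @export
classify_regulated <- function(records, up_threshold = 1,
                               down_threshold = -1) {
  stopifnot(down_threshold < up_threshold)
  finite <- is.finite(records$slr)
  out <- records[finite, , drop = FALSE]
  out$direction <- factor(
    dplyr::case_when(
      out$slr > up_threshold ~ "up",
      out$slr < down_threshold ~ "down",
      TRUE ~ "unchanged"
    ),
    levels = c("up", "down", "unchanged")
  )
  attr(out, "rejected") <- sum(!finite)
  out
}

#' Signal log ratio from QPCR Ct values
#'
#' Delta-delta-Ct with assumed amplification efficiency 2:
#' `SLR = (Ct_target,control - Ct_ref,control) -
#' (Ct_target,sample - Ct_ref,sample)`, i.e. the log2 fold change of the
#' target in the sample relative to the control, normalised to the
#' reference gene.
#'
#' @param ct_target_sample,ct_ref_sample Ct values in the sample condition.
#' @param ct_target_control,ct_ref_control Ct values in the control
#'   condition.
#' @return Numeric SLR (vectorised).
#' @export
qpcr_slr <- function(ct_target_sample, ct_ref_sample,
                     ct_target_control, ct_ref_control) {
  (ct_target_control - ct_ref_control) -
    (ct_target_sample - ct_ref_sample)
}

#' Intersect two regulated gene sets
#'
#' Returns the exact id intersection.  When regulatory `domains` and peak
#' `summits` are supplied, each shared gene is additionally flagged for
#' having at least one peak summit inside its domain (the "binding site
#' within 100 kb of the TSS" report style).
#'
#' @param set_a,set_b Character vectors of gene ids (or tibbles with a
#'   `gene_id` column).
#' @param domains Optional [regulatory_domains()] table (ids matching the
#'   gene ids).
#' @param summits Optional summit tibble for [genes_near_peaks()].
#' @return A tibble with `gene_id` and, when domains/summits are given,
#'   `has_nearby_peak`.
#' @export
gene_set_overlap <- function(set_a, set_b, domains = NULL, summits = NULL) {
  ids_a <- if (is.data.frame(set_a)) set_a$gene_id else set_a
  ids_b <- if (is.data.frame(set_b)) set_b$gene_id else set_b
  shared <- intersect(ids_a, ids_b)
  out <- tibble(gene_id = shared)
  if (!is.null(domains) && !is.null(summits) && length(shared) > 0) {
    near <- genes_near_peaks(domains, summits)
    out$has_nearby_peak <- out$gene_id %in% near$id
  }
  out
}
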