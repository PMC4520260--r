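# Per-method acceptance filters.

#' Default pipeline thresholds
#'
#' All thresholds are boundary-inclusive contracts evaluated exactly (no
#' epsilon): an E-value of exactly 0.001, a Z-score of exactly 7.5 or a
#' P-value of exactly 1e-5 passes.
#'
#' * `evalue` (0.001): full-sequence E-value cutoff for the HMM-based
#'   searches (nrichd, superfamily_db, hhsearch).
#' * `zscore` (7.5): profile-profile Z-score cutoff (supfam_plus).
#' * `pvalue` (1e-5): threading P-value cutoff (pdomthreader), required
#'   jointly with the `CERTAIN` confidence tag.
#' * `coverage` (0.60): minimum query-length coverage, applied to nrichd and
#'   supfam_plus hits.
#' * `link_zscore` (9) / `link_coverage` (0.80): cutoffs for family-family
#'   links used to derive indirect superfamily mappings (both families'
#'   coverages must qualify).
#' * `evalue_margin` (10): in the E-value decision tree, a fold-or-class
#'   heterogeneous region is resolved only when the top superfamily has
#'   strictly more than this many hits over the runner-up.
#' * `z_fold_margin` (4) / `z_class_margin` (6): inclusive best-Z margins in
#'   the Z-score decision tree for cross-fold and cross-class regions.
#' * `overlap` (0.60): two regions are the same domain when their overlap
#'   covers at least this fraction of either region.
#' * `ic` (1.5): minimum information content for transferred GO terms.
#'
#' @return named list of thresholds.
#' @export
default_thresholds <- function() {
  list(evalue = 1e-3, zscore = 7.5, pvalue = 1e-5, coverage = 0.60,
       link_zscore = 9, link_coverage = 0.80,
       evalue_margin = 10, z_fold_margin = 4, z_class_margin = 6,
       overlap = 0.60, ic = 1.5)
}

#' Query coverage of hits
#'
#' @param hits `domain_hits` table.
#' @return numeric vector `(end - start + 1) / query_length`, in (0, 1].
#' @export
query_coverage <- function(hits) {
  (hits$end - hits$start + 1) / hits$query_length
}

#' Which hits pass their method's acceptance filter?
#'
#' E-value methods require full-sequence E <= `thresholds$evalue`; nrichd
#' additionally requires coverage >= `thresholds$coverage`. supfam_plus
#' requires Z >= `thresholds$zscore` and coverage >= `thresholds$coverage`.
#' pdomthreader requires P <= `thresholds$pvalue` and the `CERTAIN` tag.
#' All comparisons are boundary-inclusive.
#'
#' @param hits `domain_hits` table.
#' @param thresholds see [default_thresholds()].
#' @return logical vector.
#' @export
passes_filter <- function(hits, thresholds = default_thresholds()) {
  if (nrow(hits) == 0L) return(logical())
  cov <- query_coverage(hits)
  vapply(seq_len(nrow(hits)), function(i) {
    switch(hits$method[i],
      nrichd = hits$evalue[i] <= thresholds$evalue &&
               cov[i] >= thresholds$coverage,
      superfamily_db = , hhsearch = hits$evalue[i] <= thresholds$evalue,
      supfam_plus = hits$zscore[i] >= thresholds$zscore &&
                    cov[i] >= thresholds$coverage,
      pdomthreader = hits$pvalue[i] <= thresholds$pvalue &&
                     hits$source_pass[i] == "CERTAIN",
      stop("unknown method '", hits$method[i], "'"))
  }, NA)
}

#' Apply the per-method acceptance filters
#'
#' @inheritParams passes_filter
#' @return the passing subset of `hits`.
#' @export
filter_hits <- function(hits, thresholds = default_thresholds()) {
  out <- hits[passes_filter(hits, thresholds), , drop = FALSE]
  rownames(out) <- NULL
  out
}
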