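# The common hit model shared by all five search strategies.

#' Method tags for the five remote-similarity search strategies
#'
#' `nrichd`: profile/sequence searches against the linker-enriched and natural
#' SCOP sequence databases (HMMER hmmsearch/jackhmmer, E-value scored).
#' `supfam_plus`: profile-profile alignment against SCOP family profiles
#' (Z-score scored). `superfamily_db`: hmmscan against the SUPERFAMILY HMM
#' library (E-value scored). `pdomthreader`: threading against a fold library
#' (P-value scored, confidence-tagged). `hhsearch`: HMM-HMM search against a
#' SCOP HMM library (E-value scored).
#' @export
FC_METHODS <- c("nrichd", "supfam_plus", "superfamily_db",
                "pdomthreader", "hhsearch")

#' Score kind used by a method
#'
#' @param method one of [FC_METHODS].
#' @return `"evalue"`, `"zscore"` or `"pvalue"`.
#' @export
method_score_kind <- function(method) {
  switch(match.arg(method, FC_METHODS),
         nrichd = , superfamily_db = , hhsearch = "evalue",
         supfam_plus = "zscore",
         pdomthreader = "pvalue")
}

#' Construct a table of domain hits
#'
#' One row per filtered-search hit: the query family, the method that found
#' it, the hit's structural-domain identifier and SCOP lineage, the aligned
#' region on the query (1-based inclusive) and exactly one score field
#' matching the method's score kind.
#'
#' @param query_id character, query family identifiers.
#' @param method single method tag (see [FC_METHODS]).
#' @param hit_id character, structural-domain identifiers.
#' @param sccs character, sccs codes of the hits (3 or 4 fields).
#' @param start,end integer, aligned region on the query, 1-based inclusive.
#' @param query_length integer, query lengths in residues.
#' @param evalue,zscore,pvalue numeric score vectors; exactly the one
#'   matching `method_score_kind(method)` must be non-`NA`.
#' @param source_pass character tag recording which search program / pass
#'   produced each hit.
#' @return data.frame of class `domain_hits`.
#' @export
domain_hits <- function(query_id, method, hit_id, sccs, start, end,
                        query_length, evalue = NA_real_, zscore = NA_real_,
                        pvalue = NA_real_, source_pass = "") {
  method <- match.arg(method, FC_METHODS)
  n <- length(query_id)
  h <- data.frame(query_id = as.character(query_id),
                  method = rep_len(method, n),
                  hit_id = as.character(hit_id),
                  sccs = as.character(sccs),
                  start = as.integer(start),
                  end = as.integer(end),
                  query_length = as.integer(query_length),
                  evalue = rep_len(as.numeric(evalue), if (n) n else 0L),
                  zscore = rep_len(as.numeric(zscore), if (n) n else 0L),
                  pvalue = rep_len(as.numeric(pvalue), if (n) n else 0L),
                  source_pass = rep_len(as.character(source_pass), if (n) n else 0L),
                  stringsAsFactors = FALSE)
  h <- cbind(h, sccs_fields(h$sccs))
  validate_hits(h)
}

empty_hits <- function() {
  h <- data.frame(query_id = character(), method = character(),
                  hit_id = character(), sccs = character(),
                  start = integer(), end = integer(),
                  query_length = integer(), evalue = numeric(),
                  zscore = numeric(), pvalue = numeric(),
                  source_pass = character(), stringsAsFactors = FALSE)
  h <- cbind(h, sccs_fields(character()))
  class(h) <- c("domain_hits", "data.frame")
  h
}

validate_hits <- function(h) {
  if (nrow(h)) {
    bad <- !(h$start >= 1L & h$start <= h$end & h$end <= h$query_length)
    if (any(bad))
      stop("invalid hit region (need 1 <= start <= end <= query_length) for query ",
           h$query_id[bad][1L])
    kind <- vapply(h$method, method_score_kind, "")
    score_na <- cbind(evalue = is.na(h$evalue), zscore = is.na(h$zscore),
                      pvalue = is.na(h$pvalue))
    for (i in seq_len(nrow(h))) {
      want <- kind[i]
      if (score_na[i, want])
        stop("hit for query ", h$query_id[i], " (method ", h$method[i],
             ") is missing its ", want)
      if (sum(!score_na[i, ]) != 1L)
        stop("hit for query ", h$query_id[i],
             " must carry exactly one score kind")
    }
    if (any(h$evalue < 0, na.rm = TRUE))
      stop("negative E-value")
    if (any(h$pvalue <= 0 | h$pvalue > 1, na.rm = TRUE))
      stop("P-value outside (0, 1]")
  }
  if (!inherits(h, "domain_hits")) class(h) <- c("domain_hits", "data.frame")
  h
}

bind_hits <- function(lst) {
  lst <- lst[vapply(lst, nrow, 0L) > 0L]
  if (length(lst) == 0L) return(empty_hits())
  h <- do.call(rbind, lapply(lst, as.data.frame))
  rownames(h) <- NULL
  class(h) <- c("domain_hits", "data.frame")
  h
}

#' Pool hit tables from several search passes of one method
#'
#' Pooling concatenates; it never deduplicates, because the downstream
#' decision trees count hit frequencies over the pooled list (a hit found by
#' both the profile and the iterative sequence search legitimately counts
#' twice).
#'
#' @param ... `domain_hits` tables, all carrying the same method tag.
#' @return one `domain_hits` table, input order preserved, `source_pass`
#'   kept per hit.
#' @export
pool_hits <- function(...) {
  bundles <- list(...)
  if (length(bundles) == 1L && is.list(bundles[[1L]]) &&
      !is.data.frame(bundles[[1L]]))
    bundles <- bundles[[1L]]
  methods <- unique(unlist(lapply(bundles, function(b) unique(b$method))))
  if (length(methods) > 1L)
    stop("cannot pool hits from different methods: ",
         paste(methods, collapse = ", "))
  bind_hits(bundles)
}
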