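# Merge per-method assignments per query by region overlap, exclude
# ambiguous regions, tier confidence by method agreement.

#' Confidence tier from the number of agreeing methods
#'
#' At least four agreeing methods: `high`; two or three: `medium`; a single
#' method: `low`.
#'
#' @param n_methods integer in 1..5.
#' @return `"high"`, `"medium"` or `"low"` (vectorised).
#' @export
tier <- function(n_methods) {
  if (any(is.na(n_methods)) || any(n_methods < 1L | n_methods > 5L))
    stop("n_methods must lie in 1..5")
  ifelse(n_methods >= 4L, "high", ifelse(n_methods >= 2L, "medium", "low"))
}

empty_records <- function() {
  data.frame(query_id = character(), start = integer(), end = integer(),
             superfamily_id = character(), methods = character(),
             n_methods = integer(), confidence = character(),
             outvoted_method = character(), stringsAsFactors = FALSE)
}

empty_exclusions <- function() {
  data.frame(query_id = character(), start = integer(), end = integer(),
             superfamilies = character(), same_fold = logical(),
             stringsAsFactors = FALSE)
}

#' Combine per-method assignments into consensus and exclusion records
#'
#' Assigned verdicts for each query are clustered into region groups by
#' single-linkage overlap (at least `overlap` of either region). Per group:
#' all methods agreeing on one superfamily yield a `ConsensusRecord`;
#' exactly four agreeing with one dissenter yield a record for the majority
#' superfamily with the dissenter recorded as `outvoted_method` (this is the
#' only tolerated disagreement); any other disagreement excludes the region,
#' with `same_fold` flagging conflicts whose superfamilies share a SCOP
#' fold. Groups on different regions produce independent records. Agreement
#' is tested at superfamily level; fold-level agreement is not sufficient
#' for retention.
#'
#' @param assignments data.frame from [resolve_assignments()] (unresolved
#'   rows are ignored); at most one verdict per method per region group,
#'   otherwise an error is raised.
#' @param overlap region-identity fraction (default 0.6).
#' @return list with elements
#'   `records` (query_id, start, end, superfamily_id, methods
#'   (semicolon-joined), n_methods, confidence, outvoted_method),
#'   `exclusions` (query_id, start, end, superfamilies, same_fold), and
#'   `assignments` (the assigned input rows with added `disposition`
#'   (`consensus`/`outvoted`/`excluded`) and `region_group` columns).
#' @export
combine_assignments <- function(assignments, overlap = 0.6) {
  asg <- assignments[assignments$status == "assigned", , drop = FALSE]
  if (nrow(asg) == 0L)
    return(list(records = empty_records(), exclusions = empty_exclusions(),
                assignments = cbind(asg,
                  data.frame(disposition = character(),
                             region_group = integer()))))
  asg$disposition <- NA_character_
  asg$region_group <- NA_integer_
  records <- list(); exclusions <- list()
  nr <- 0L; nx <- 0L; gid <- 0L
  for (q in unique(asg$query_id)) {
    qi <- which(asg$query_id == q)
    grp <- group_regions(asg$start[qi], asg$end[qi], overlap)
    for (g in unique(grp)) {
      gi <- qi[grp == g]
      gid <- gid + 1L
      asg$region_group[gi] <- gid
      meth <- asg$method[gi]
      if (anyDuplicated(meth))
        stop("query ", q, ": method ", meth[duplicated(meth)][1L],
             " contributes two verdicts to one region group; ",
             "per-method resolution must yield one verdict per region")
      sfs <- asg$superfamily_id[gi]
      counts <- sort(table(sfs), decreasing = TRUE)
      if (length(counts) == 1L) {
        asg$disposition[gi] <- "consensus"
        m <- sort(factor(meth, levels = FC_METHODS))
        records[[nr <- nr + 1L]] <- data.frame(
          query_id = q, start = min(asg$start[gi]), end = max(asg$end[gi]),
          superfamily_id = sfs[1L],
          methods = paste(as.character(m), collapse = ";"),
          n_methods = length(gi), confidence = tier(length(gi)),
          outvoted_method = NA_character_, stringsAsFactors = FALSE)
      } else if (length(gi) == 5L && length(counts) == 2L &&
                 counts[1L] == 4L) {
        maj_sf <- names(counts)[1L]
        maj <- gi[sfs == maj_sf]
        dis <- gi[sfs != maj_sf]
        asg$disposition[maj] <- "consensus"
        asg$disposition[dis] <- "outvoted"
        m <- sort(factor(asg$method[maj], levels = FC_METHODS))
        records[[nr <- nr + 1L]] <- data.frame(
          query_id = q, start = min(asg$start[maj]), end = max(asg$end[maj]),
          superfamily_id = maj_sf,
          methods = paste(as.character(m), collapse = ";"),
          n_methods = 4L, confidence = tier(4L),
          outvoted_method = asg$method[dis], stringsAsFactors = FALSE)
      } else {
        asg$disposition[gi] <- "excluded"
        usf <- sort(unique(sfs))
        exclusions[[nx <- nx + 1L]] <- data.frame(
          query_id = q, start = min(asg$start[gi]), end = max(asg$end[gi]),
          superfamilies = paste(usf, collapse = ";"),
          same_fold = length(unique(sf_fold(usf))) == 1L,
          stringsAsFactors = FALSE)
      }
    }
  }
  records <- if (nr) do.call(rbind, records) else empty_records()
  exclusions <- if (nx) do.call(rbind, exclusions) else empty_exclusions()
  rownames(records) <- NULL; rownames(exclusions) <- NULL
  list(records = records, exclusions = exclusions, assignments = asg)
}

#' Summarise a consensus run
#'
#' @param combined list returned by [combine_assignments()].
#' @return list with components:
#'   `n_records` (consensus region records), `n_families` (distinct
#'   annotated queries), `tier_counts` (high/medium/low),
#'   `tier_histogram` (records per n_methods 1..5),
#'   `per_method` data.frame (method, n_assigned pre-consensus,
#'   n_discarded_as_ambiguous incl. outvoted verdicts, n_retained,
#'   n_unique single-method records), `n_excluded_regions`,
#'   `n_excluded_families`, `n_superfamilies`, `n_folds`.
#' @export
tally <- function(combined) {
  records <- combined$records
  exclusions <- combined$exclusions
  asg <- combined$assignments
  tier_counts <- vapply(c("high", "medium", "low"),
                        function(t) sum(records$confidence == t), 0L)
  hist5 <- vapply(1:5, function(k) sum(records$n_methods == k), 0L)
  names(hist5) <- as.character(1:5)
  per_method <- do.call(rbind, lapply(FC_METHODS, function(m) {
    mi <- asg$method == m
    n_assigned <- sum(mi)
    n_retained <- sum(mi & asg$disposition == "consensus")
    n_unique <- sum(records$n_methods == 1L & records$methods == m)
    data.frame(method = m, n_assigned = n_assigned,
               n_discarded = n_assigned - n_retained,
               n_retained = n_retained, n_unique = n_unique,
               stringsAsFactors = FALSE)
  }))
  list(n_records = nrow(records),
       n_families = length(unique(records$query_id)),
       tier_counts = as.list(tier_counts),
       tier_histogram = as.list(hist5),
       per_method = per_method,
       n_excluded_regions = nrow(exclusions),
       n_excluded_families = length(unique(exclusions$query_id)),
       n_superfamilies = length(unique(records$superfamily_id)),
       n_folds = length(unique(sf_fold(records$superfamily_id))))
}
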