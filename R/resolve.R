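# Collapse one method's surviving hits to per-region superfamily verdicts.
#
# Hits for a query that fall on different domain regions are kept as
# independent predictions; hits on the same region are reconciled by a
# method-specific decision tree. Region identity (here and in the
# cross-method consensus) means an overlap covering at least 60 % of either
# region's length, extended transitively (single linkage).

#' Overlap fractions of two regions
#'
#' @param r1,r2 integer length-2 vectors `(start, end)`, 1-based inclusive.
#' @return numeric length-2: overlap length divided by each region's length.
#' @export
region_overlap_frac <- function(r1, r2) {
  ov <- max(0L, min(r1[2L], r2[2L]) - max(r1[1L], r2[1L]) + 1L)
  c(ov / (r1[2L] - r1[1L] + 1L), ov / (r2[2L] - r2[1L] + 1L))
}

#' Do two regions describe the same domain?
#'
#' True when the overlap covers at least `min_frac` of either region.
#'
#' @inheritParams region_overlap_frac
#' @param min_frac minimum fraction (default 0.6).
#' @export
regions_overlap <- function(r1, r2, min_frac = 0.6) {
  any(region_overlap_frac(r1, r2) >= min_frac)
}

#' Cluster regions into domain groups by single-linkage overlap
#'
#' @param start,end integer vectors of equal length.
#' @param min_frac overlap fraction linking two regions.
#' @return integer group labels (1-based, in order of first appearance).
#' @export
group_regions <- function(start, end, min_frac = 0.6) {
  n <- length(start)
  if (n == 0L) return(integer())
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    if (regions_overlap(c(start[i], end[i]), c(start[j], end[j]), min_frac)) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  }
  roots <- vapply(seq_len(n), find, 0L)
  match(roots, unique(roots))
}

# One resolved (or unresolved) verdict as a one-row data.frame.
assignment_row <- function(query_id, method, start, end, superfamily_id,
                           n_support, best_score, status, provenance,
                           origin = "direct") {
  data.frame(query_id = query_id, method = method,
             start = as.integer(start), end = as.integer(end),
             superfamily_id = superfamily_id,
             n_support = as.integer(n_support),
             best_score = as.numeric(best_score),
             status = status,
             provenance = provenance, origin = origin,
             stringsAsFactors = FALSE)
}

empty_assignments <- function() {
  assignment_row(character(), character(), integer(), integer(),
                 character(), integer(), numeric(), character(),
                 character(), character())
}

# Shared bookkeeping once a winning superfamily is known (or not).
finish_assignment <- function(hits, winner, score_col, decreasing) {
  if (is.na(winner)) {
    return(assignment_row(hits$query_id[1L], hits$method[1L],
                          min(hits$start), max(hits$end),
                          NA_character_, 0L, NA_real_, "unresolved", ""))
  }
  sup <- hits[hits$superfamily_id == winner, , drop = FALSE]
  cov <- query_coverage(sup)
  key <- if (decreasing) -sup[[score_col]] else sup[[score_col]]
  rep_i <- order(key, -cov, sup$hit_id)[1L]
  assignment_row(hits$query_id[1L], hits$method[1L],
                 min(sup$start), max(sup$end), winner, nrow(sup),
                 sup[[score_col]][rep_i], "assigned",
                 paste(sup$hit_id, collapse = ";"))
}

check_group <- function(hits, score_col) {
  if (nrow(hits) == 0L) stop("cannot resolve an empty hit group")
  if (length(unique(hits$query_id)) != 1L ||
      length(unique(hits$method)) != 1L)
    stop("a hit group must contain a single query and method")
  if (anyNA(hits[[score_col]]))
    stop("hit group is missing ", score_col, " scores")
}

# Modal superfamily; NA on a tie for the mode.
modal_superfamily <- function(sfs) {
  counts <- sort(table(sfs), decreasing = TRUE)
  if (length(counts) > 1L && counts[1L] == counts[2L]) return(NA_character_)
  names(counts)[1L]
}

#' Resolve a same-region hit group by the E-value decision tree
#'
#' Cascade: (i) all hits in one superfamily: pick it, represented by the
#' lowest-E-value hit (ties: larger query coverage, then lexicographic hit
#' id); (ii) several superfamilies within one fold: the most frequent
#' superfamily (a tie leaves the region unresolved); (iii) several folds or
#' classes: the most frequent superfamily, but only when it has strictly
#' more than `margin` hits over the second most frequent; otherwise the
#' region is unresolved. Used by the nrichd, superfamily_db and hhsearch
#' methods.
#'
#' @param hits `domain_hits` for one query, one method, one region group;
#'   E-value scored.
#' @param margin frequency margin for rule (iii), exclusive (default 10).
#' @return one-row assignment data.frame (`status` = `"assigned"` or
#'   `"unresolved"`).
#' @export
resolve_evalue_tree <- function(hits, margin = 10) {
  check_group(hits, "evalue")
  sfs <- unique(hits$superfamily_id)
  winner <-
    if (length(sfs) == 1L) sfs
    else if (length(unique(hits$fold_id)) == 1L) modal_superfamily(hits$superfamily_id)
    else {
      counts <- sort(table(hits$superfamily_id), decreasing = TRUE)
      if (counts[1L] - counts[2L] > margin) names(counts)[1L]
      else NA_character_
    }
  finish_assignment(hits, winner, "evalue", decreasing = FALSE)
}

#' Resolve a same-region hit group by the Z-score decision tree
#'
#' Cascade: (1) all hits in one superfamily: pick it, represented by the
#' highest Z-score; (2) several superfamilies within one fold: the most
#' frequent superfamily (a tie leaves the region unresolved); (3) several
#' folds within one class: the superfamily with the highest best-Z, provided
#' the best-Z margin over the runner-up superfamily is at least
#' `fold_margin`; (4) several classes: same, with margin at least
#' `class_margin`. Margin tests are boundary-inclusive; a failed margin
#' leaves the region unresolved. Used by the supfam_plus method. Any
#' cross-class pair of hits routes the group to rule (4).
#'
#' @param hits `domain_hits` for one query, one method, one region group;
#'   Z-score scored.
#' @param fold_margin,class_margin inclusive best-Z margins (defaults 4, 6).
#' @return one-row assignment data.frame.
#' @export
resolve_zscore_tree <- function(hits, fold_margin = 4, class_margin = 6) {
  check_group(hits, "zscore")
  sfs <- unique(hits$superfamily_id)
  winner <-
    if (length(sfs) == 1L) sfs
    else if (length(unique(hits$fold_id)) == 1L) modal_superfamily(hits$superfamily_id)
    else {
      best_z <- vapply(split(hits$zscore, hits$superfamily_id), max, 0)
      best_z <- sort(best_z, decreasing = TRUE)
      need <- if (length(unique(hits$class_id)) == 1L) fold_margin else class_margin
      if (best_z[1L] - best_z[2L] >= need) names(best_z)[1L] else NA_character_
    }
  finish_assignment(hits, winner, "zscore", decreasing = TRUE)
}

#' Resolve a same-region hit group by superfamily frequency
#'
#' The most frequent superfamily wins outright; a tie for the mode leaves
#' the region unresolved. The representative hit is the lowest P-value hit
#' of the winning superfamily. Used by the pdomthreader method.
#'
#' @param hits `domain_hits` for one query, one method, one region group;
#'   P-value scored.
#' @return one-row assignment data.frame.
#' @export
resolve_frequency <- function(hits) {
  check_group(hits, "pvalue")
  finish_assignment(hits, modal_superfamily(hits$superfamily_id),
                    "pvalue", decreasing = FALSE)
}

resolve_group <- function(hits, thresholds = default_thresholds()) {
  switch(method_score_kind(hits$method[1L]),
         evalue = resolve_evalue_tree(hits, margin = thresholds$evalue_margin),
         zscore = resolve_zscore_tree(hits,
                                      fold_margin = thresholds$z_fold_margin,
                                      class_margin = thresholds$z_class_margin),
         pvalue = resolve_frequency(hits))
}

#' Resolve filtered hits to per-region method assignments
#'
#' For every (query, method) the hits are clustered into region groups by
#' single-linkage overlap (`thresholds$overlap`), then each group is
#' collapsed by the method's decision tree: E-value tree for nrichd,
#' superfamily_db and hhsearch; Z-score tree for supfam_plus; frequency rule
#' for pdomthreader. Groups on different domain regions yield independent
#' assignments.
#'
#' @param hits filtered `domain_hits` (any mix of queries and methods).
#' @param thresholds see [default_thresholds()].
#' @return data.frame of assignments: `query_id`, `method`, `start`, `end`
#'   (envelope of the supporting hits), `superfamily_id`, `n_support`,
#'   `best_score`, `status` (`assigned`/`unresolved`), `provenance`
#'   (semicolon-joined supporting hit ids), `origin` (`direct`).
#' @export
resolve_assignments <- function(hits, thresholds = default_thresholds()) {
  if (nrow(hits) == 0L) return(empty_assignments())
  pieces <- split(seq_len(nrow(hits)),
                  paste(hits$query_id, hits$method, sep = "\r"))
  out <- lapply(pieces, function(idx) {
    h <- hits[idx, , drop = FALSE]
    grp <- group_regions(h$start, h$end, thresholds$overlap)
    do.call(rbind, lapply(split(seq_len(nrow(h)), grp), function(gidx)
      resolve_group(h[gidx, , drop = FALSE], thresholds)))
  })
  out <- do.call(rbind, out)
  out <- out[order(out$query_id, out$method, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Derive indirect family-to-superfamily assignments through family links
#'
#' A family without a direct superfamily mapping inherits one through
#' qualifying family-family links (Z-score >= `link_zscore` and both
#' families covered to at least `link_coverage`): when all directly mapped
#' link partners agree on a single superfamily, the family is assigned to it
#' (flagged `indirect`); conflicting partner superfamilies yield no
#' assignment. Inheritance is one hop only; indirect assignments never seed
#' further ones.
#'
#' @param direct data.frame with columns `family_id`, `superfamily_id`
#'   (direct mappings).
#' @param links data.frame from [read_links()].
#' @param link_zscore,link_coverage link qualification cutoffs (defaults 9
#'   and 0.80, boundary-inclusive).
#' @return data.frame with columns `family_id`, `superfamily_id`, `origin`
#'   (`"indirect"`), `via` (semicolon-joined partner families).
#' @export
derive_indirect <- function(direct, links, link_zscore = 9,
                            link_coverage = 0.80) {
  ok <- links$zscore >= link_zscore &
    links$coverage_a >= link_coverage & links$coverage_b >= link_coverage
  links <- links[ok, , drop = FALSE]
  edges <- rbind(
    data.frame(from = links$family_a, to = links$family_b,
               stringsAsFactors = FALSE),
    data.frame(from = links$family_b, to = links$family_a,
               stringsAsFactors = FALSE))
  edges <- edges[!(edges$from %in% direct$family_id), , drop = FALSE]
  part_sf <- direct$superfamily_id[match(edges$to, direct$family_id)]
  edges <- edges[!is.na(part_sf), , drop = FALSE]
  part_sf <- part_sf[!is.na(part_sf)]
  if (nrow(edges) == 0L)
    return(data.frame(family_id = character(), superfamily_id = character(),
                      origin = character(), via = character(),
                      stringsAsFactors = FALSE))
  by_fam <- split(seq_len(nrow(edges)), edges$from)
  rows <- lapply(names(by_fam), function(f) {
    idx <- by_fam[[f]]
    sfs <- unique(part_sf[idx])
    if (length(sfs) != 1L) return(NULL)
    data.frame(family_id = f, superfamily_id = sfs, origin = "indirect",
               via = paste(sort(unique(edges$to[idx])), collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(family_id = character(), superfamily_id = character(),
                      origin = character(), via = character(),
                      stringsAsFactors = FALSE))
  out <- out[order(out$family_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
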