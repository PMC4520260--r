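# Independent brute-force oracles used to cross-check the decision trees,
# region clustering and consensus adjudication.

# Build a minimal hit table directly (bypassing the reader path) with the
# columns the resolvers consume.
make_hits <- function(sf, score, method = "nrichd", query = "Q1",
                      start = 1L, end = 90L, qlen = 100L,
                      hit_id = sprintf("h%03d", seq_along(sf)),
                      tag = "CERTAIN") {
  kind <- method_score_kind(method)
  n <- length(sf)
  parts <- strsplit(sf, ".", fixed = TRUE)
  data.frame(
    query_id = rep_len(query, n), method = rep_len(method, n),
    hit_id = hit_id, sccs = paste0(sf, ".1"),
    start = as.integer(rep_len(start, n)), end = as.integer(rep_len(end, n)),
    query_length = as.integer(rep_len(qlen, n)),
    evalue = if (kind == "evalue") score else NA_real_,
    zscore = if (kind == "zscore") score else NA_real_,
    pvalue = if (kind == "pvalue") score else NA_real_,
    source_pass = rep_len(tag, n),
    class_id = vapply(parts, `[`, "", 1L),
    fold_id = vapply(parts, function(p) paste(p[1:2], collapse = "."), ""),
    superfamily_id = sf,
    family_id = paste0(sf, ".1"),
    stringsAsFactors = FALSE)
}

# Literal per-rule interpreter of the three resolution cascades; returns the
# winning superfamily or NA (unresolved).
oracle_winner <- function(sf, fold, cls, score, kind,
                          e_margin = 10, zf_margin = 4, zc_margin = 6) {
  modal <- function() {
    tb <- table(sf)
    top <- names(tb)[tb == max(tb)]
    if (length(top) == 1L) top else NA_character_
  }
  if (length(unique(sf)) == 1L) return(sf[1L])
  if (kind == "pvalue") return(modal())
  if (length(unique(fold)) == 1L) return(modal())
  if (kind == "evalue") {
    tb <- sort(table(sf), decreasing = TRUE)
    if (as.integer(tb[1L]) - as.integer(tb[2L]) > e_margin)
      return(names(tb)[1L])
    return(NA_character_)
  }
  # zscore, heterogeneous folds
  best <- sort(tapply(score, sf, max), decreasing = TRUE)
  need <- if (length(unique(cls)) == 1L) zf_margin else zc_margin
  if (best[1L] - best[2L] >= need) names(best)[1L] else NA_character_
}

oracle_resolve <- function(hits) {
  kind <- method_score_kind(hits$method[1L])
  oracle_winner(hits$superfamily_id, hits$fold_id, hits$class_id,
                hits[[kind]], kind)
}

# Brute-force connected components of the pairwise region-overlap graph.
oracle_components <- function(start, end, min_frac = 0.6) {
  n <- length(start)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    adj[i, j] <- regions_overlap(c(start[i], end[i]), c(start[j], end[j]),
                                 min_frac)
  comp <- rep(NA_integer_, n)
  cid <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cid <- cid + 1L
    frontier <- s
    while (length(frontier)) {
      comp[frontier] <- cid
      frontier <- setdiff(which(apply(adj[frontier, , drop = FALSE], 2, any)),
                          which(!is.na(comp)))
    }
  }
  comp
}

# Independent adjudicator of cross-method agreement patterns: given one
# superfamily label per method, what should the consensus stage do?
consensus_oracle <- function(sf_by_method) {
  tb <- sort(table(sf_by_method), decreasing = TRUE)
  if (length(tb) == 1L)
    return(list(outcome = "consensus", sf = names(tb)[1L],
                n = length(sf_by_method), outvoted = NA_character_))
  if (length(sf_by_method) == 5L && tb[1L] == 4L)
    return(list(outcome = "consensus", sf = names(tb)[1L], n = 4L,
                outvoted = names(sf_by_method)[sf_by_method != names(tb)[1L]]))
  list(outcome = "excluded", sf = NA_character_, n = 0L,
       outvoted = NA_character_)
}

# All positive integer k-compositions of n.
compositions <- function(n, k) {
  if (k == 1L) return(list(n))
  out <- list()
  for (first in seq_len(n - k + 1L))
    for (rest in compositions(n - first, k - 1L))
      out[[length(out) + 1L]] <- c(first, rest)
  out
}

# Superfamily layouts covering every lineage-relation pattern with <= 3
# superfamilies.
sf_layouts <- list(
  c("a.1.1"),
  c("a.1.1", "a.1.2"),               # same fold
  c("a.1.1", "a.2.1"),               # same class, different folds
  c("a.1.1", "b.1.1"),               # different classes
  c("a.1.1", "a.1.2", "a.1.3"),      # one fold, three superfamilies
  c("a.1.1", "a.1.2", "a.2.1"),      # mixed: shared fold + foreign fold
  c("a.1.1", "a.2.1", "a.3.1"),      # three folds, one class
  c("a.1.1", "a.1.2", "b.1.1"),      # mixed across classes
  c("a.1.1", "b.1.1", "c.1.1"))      # three classes
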