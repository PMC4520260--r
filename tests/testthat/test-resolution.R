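test_that("query coverage is the aligned fraction of the query", {
  h <- make_hits(rep("a.1.1", 3), score = c(1e-9, 1e-9, 1e-9),
                 start = c(1L, 41L, 1L), end = c(60L, 100L, 100L),
                 qlen = 100L)
  expect_equal(query_coverage(h), c(0.60, 0.60, 1.00))
})

test_that("acceptance filters are boundary-inclusive and method-specific", {
  thr <- default_thresholds()
  # E-value methods: boundary E passes; nrichd also needs 60 % coverage
  h <- make_hits("a.1.1", 1e-3, method = "nrichd", start = 1L, end = 60L,
                 qlen = 100L)
  expect_true(passes_filter(h, thr))
  h$end <- 59L
  expect_false(passes_filter(h, thr))
  expect_false(passes_filter(make_hits("a.1.1", 0.01, method = "nrichd",
                                       end = 99L, qlen = 100L), thr))
  # superfamily_db / hhsearch: E-value only, no coverage requirement
  expect_true(passes_filter(make_hits("a.1.1", 1e-3, method = "hhsearch",
                                      start = 1L, end = 10L, qlen = 100L), thr))
  # supfam_plus: boundary Z and coverage pass
  expect_true(passes_filter(make_hits("a.1.1", 7.5, method = "supfam_plus",
                                      start = 1L, end = 60L, qlen = 100L), thr))
  expect_false(passes_filter(make_hits("a.1.1", 7.4, method = "supfam_plus",
                                       end = 90L), thr))
  # pdomthreader: P and tag are conjunctive
  expect_true(passes_filter(make_hits("a.1.1", 1e-5, method = "pdomthreader"),
                            thr))
  expect_false(passes_filter(make_hits("a.1.1", 1e-6, method = "pdomthreader",
                                       tag = "HIGH"), thr))
  expect_false(passes_filter(make_hits("a.1.1", 2e-5, method = "pdomthreader"),
                             thr))
})

test_that("tightening any threshold never admits new hits", {
  set.seed(19)
  for (rep in 1:30) {
    m <- sample(FC_METHODS, 1)
    kind <- method_score_kind(m)
    n <- sample(1:12, 1)
    score <- switch(kind, evalue = 10^-runif(n, 0, 8),
                    zscore = runif(n, 4, 12), pvalue = 10^-runif(n, 2, 8))
    start <- sample(1:40, n, replace = TRUE)
    h <- make_hits(sample(c("a.1.1", "b.1.1"), n, replace = TRUE), score,
                   method = m, start = start,
                   end = pmin(start + sample(20:90, n, replace = TRUE), 100L),
                   tag = sample(c("CERTAIN", "HIGH"), n, replace = TRUE))
    base <- default_thresholds()
    loose <- utils::modifyList(base, list(evalue = 1, zscore = 5,
                                          pvalue = 1e-2, coverage = 0.3))
    tight <- utils::modifyList(base, list(evalue = 1e-6, zscore = 10,
                                          pvalue = 1e-7, coverage = 0.8))
    pl <- passes_filter(h, loose); pb <- passes_filter(h, base)
    pt <- passes_filter(h, tight)
    expect_true(all(pb <= pl))
    expect_true(all(pt <= pb))
  }
})

test_that("region grouping matches brute-force connected components", {
  expect_equal(group_regions(c(1L, 30L), c(100L, 90L)), c(1L, 1L))
  expect_equal(group_regions(c(1L, 120L), c(100L, 200L)), c(1L, 2L))
  # chained overlap joins transitively even when the outer regions share
  # only 20 residues (each adjacent pair covers 60 % of a region)
  expect_equal(group_regions(c(1L, 41L, 81L), c(100L, 140L, 180L)),
               c(1L, 1L, 1L))
  set.seed(23)
  for (rep in 1:40) {
    n <- sample(2:9, 1)
    start <- sample(1:300, n, replace = TRUE)
    end <- start + sample(10:120, n, replace = TRUE)
    got <- group_regions(start, end)
    want <- oracle_components(start, end)
    # same partition (labels may differ)
    expect_equal(outer(got, got, "=="), outer(want, want, "=="))
  }
})

test_that("E-value tree rule (i): representative is best E, then coverage", {
  h <- make_hits(c("a.1.1", "a.1.1"), c(1e-10, 1e-5),
                 start = c(11L, 1L), end = c(90L, 90L))
  a <- resolve_evalue_tree(h)
  expect_equal(a$status, "assigned")
  expect_equal(a$superfamily_id, "a.1.1")
  expect_equal(a$best_score, 1e-10)
  expect_equal(a$n_support, 2L)
  expect_equal(c(a$start, a$end), c(1L, 90L))   # envelope of support
  # equal E: larger coverage wins, then lexicographic hit id
  h2 <- make_hits(c("a.1.1", "a.1.1"), c(1e-8, 1e-8),
                  start = c(21L, 1L), end = c(100L, 100L),
                  hit_id = c("hB", "hA"))
  expect_equal(resolve_evalue_tree(h2)$best_score, 1e-8)
  h3 <- make_hits(c("a.1.1", "a.1.1"), c(1e-8, 1e-8), hit_id = c("hB", "hA"))
  expect_equal(strsplit(resolve_evalue_tree(h3)$provenance, ";")[[1]][1], "hB")
})

test_that("E-value tree rules (ii)/(iii): modal superfamily and the >10 margin", {
  # same fold, modal superfamily wins regardless of scores
  h <- make_hits(c(rep("a.1.1", 3), "a.1.2"), c(1e-4, 1e-4, 1e-4, 1e-30))
  expect_equal(resolve_evalue_tree(h)$superfamily_id, "a.1.1")
  # same fold, tied mode is unresolved
  tie <- make_hits(c("a.1.1", "a.1.2"), c(1e-9, 1e-4))
  expect_equal(resolve_evalue_tree(tie)$status, "unresolved")
  # different folds: margin of 11 > 10 resolves, margin of 2 does not
  big <- make_hits(c(rep("a.1.1", 12), "b.1.1"), 10^-(1:13))
  a <- resolve_evalue_tree(big)
  expect_equal(a$superfamily_id, "a.1.1")
  expect_equal(a$n_support, 12L)
  small <- make_hits(c(rep("a.1.1", 5), rep("b.1.1", 3)), 10^-(1:8))
  expect_equal(resolve_evalue_tree(small)$status, "unresolved")
  # boundary: a margin of exactly 10 is not enough (strict, as printed)
  edge <- make_hits(c(rep("a.1.1", 11), "b.1.1"), 10^-(1:12))
  expect_equal(resolve_evalue_tree(edge)$status, "unresolved")
  expect_error(resolve_evalue_tree(make_hits("a.1.1", 1e-9)[0, ]), "empty")
})

test_that("Z-score tree margins are inclusive and class-dependent", {
  h <- make_hits(c("a.1.1", "a.1.1"), c(9, 11), method = "supfam_plus")
  a <- resolve_zscore_tree(h)
  expect_equal(a$best_score, 11)
  # different classes: margin 6.4 >= 6 resolves
  cl <- make_hits(c("a.1.1", "b.1.1"), c(14.0, 7.6), method = "supfam_plus")
  expect_equal(resolve_zscore_tree(cl)$superfamily_id, "a.1.1")
  # different classes: margin 4.4 < 6 stays unresolved
  cl2 <- make_hits(c("a.1.1", "b.1.1"), c(12.0, 7.6), method = "supfam_plus")
  expect_equal(resolve_zscore_tree(cl2)$status, "unresolved")
  # same class, different folds: margin 4 suffices (inclusive)
  fl <- make_hits(c("a.1.1", "a.2.1"), c(11.6, 7.6), method = "supfam_plus")
  expect_equal(resolve_zscore_tree(fl)$superfamily_id, "a.1.1")
  # any cross-class pair routes to the class margin
  mix <- make_hits(c("a.1.1", "a.2.1", "b.1.1"), c(12.0, 7.6, 7.0),
                   method = "supfam_plus")
  expect_equal(resolve_zscore_tree(mix)$status, "unresolved")
  # same fold: frequency, not Z, decides
  fr <- make_hits(c("a.1.1", "a.1.2", "a.1.2"), c(15, 8, 8),
                  method = "supfam_plus")
  expect_equal(resolve_zscore_tree(fr)$superfamily_id, "a.1.2")
})

test_that("frequency rule takes the mode and refuses ties", {
  h <- make_hits(c("a.1.1", "a.1.1", "b.1.1"), c(1e-6, 1e-7, 1e-9),
                 method = "pdomthreader")
  a <- resolve_frequency(h)
  expect_equal(a$superfamily_id, "a.1.1")
  expect_equal(a$best_score, 1e-7)
  single <- make_hits("a.1.1", 1e-6, method = "pdomthreader")
  expect_equal(resolve_frequency(single)$superfamily_id, "a.1.1")
  tie <- make_hits(c("a.1.1", "a.1.1", "b.1.1", "b.1.1"),
                   c(1e-6, 1e-6, 1e-9, 1e-9), method = "pdomthreader")
  expect_equal(resolve_frequency(tie)$status, "unresolved")
})

test_that("all three trees agree with the brute-force rule interpreter", {
  set.seed(31)
  n_cases <- 0L
  for (layout in sf_layouts) {
    k <- length(layout)
    for (n in seq(k, 13, by = 2)) {
      for (comp in compositions(n, k)) {
        sfs <- rep(layout, comp)
        for (draw in 1:2) {
          z <- round(runif(n, 7.5, 16), 1)
          ev <- 10^-sample(3:40, n, replace = TRUE)
          pv <- 10^-sample(5:12, n, replace = TRUE)
          he <- make_hits(sfs, ev, method = "nrichd")
          hz <- make_hits(sfs, z, method = "supfam_plus")
          hp <- make_hits(sfs, pv, method = "pdomthreader")
          for (h in list(he, hz, hp)) {
            got <- resolve_group(h)
            want <- oracle_resolve(h)
            n_cases <- n_cases + 1L
            if (is.na(want)) expect_equal(got$status, "unresolved")
            else {
              expect_equal(got$status, "assigned")
              expect_equal(got$superfamily_id, want)
              # no invented labels, and support comes from that superfamily
              expect_true(want %in% h$superfamily_id)
              expect_equal(got$n_support, sum(h$superfamily_id == want))
            }
          }
        }
      }
    }
  }
  expect_gt(n_cases, 3000)
})

test_that("resolution outcomes are invariant to hit order", {
  set.seed(37)
  for (rep in 1:25) {
    layout <- sf_layouts[[sample(length(sf_layouts), 1)]]
    n <- sample(length(layout):10, 1)
    sfs <- c(layout, sample(layout, n - length(layout), replace = TRUE))
    m <- sample(FC_METHODS, 1)
    kind <- method_score_kind(m)
    sc <- switch(kind, evalue = 10^-sample(3:30, n, replace = TRUE),
                 zscore = round(runif(n, 8, 15), 1),
                 pvalue = 10^-sample(5:12, n, replace = TRUE))
    h <- make_hits(sfs, sc, method = m)
    ref <- resolve_group(h)
    perm <- sample(n)
    got <- resolve_group(h[perm, ])
    expect_equal(got$status, ref$status)
    expect_equal(got$superfamily_id, ref$superfamily_id)
    expect_equal(got$best_score, ref$best_score)
    expect_equal(got$n_support, ref$n_support)
  }
})

test_that("per-query resolution keeps distinct regions as separate verdicts", {
  h <- rbind(make_hits(c("a.1.1", "a.1.1"), c(1e-9, 1e-8),
                       start = 1L, end = 100L, qlen = 300L),
             make_hits("b.1.1", 1e-12, start = 181L, end = 300L,
                       qlen = 300L, hit_id = "h900"))
  asg <- resolve_assignments(h)
  expect_equal(nrow(asg), 2L)
  expect_setequal(asg$superfamily_id, c("a.1.1", "b.1.1"))
})

test_that("indirect mappings require one unambiguous qualifying link", {
  direct <- data.frame(family_id = c("B", "C"),
                       superfamily_id = c("a.1.1", "b.1.1"),
                       stringsAsFactors = FALSE)
  links1 <- data.frame(family_a = "A", family_b = "B", zscore = 9.5,
                       coverage_a = 0.9, coverage_b = 0.85,
                       stringsAsFactors = FALSE)
  got <- derive_indirect(direct, links1)
  expect_equal(got$family_id, "A")
  expect_equal(got$superfamily_id, "a.1.1")
  expect_equal(got$origin, "indirect")
  # sub-threshold links produce nothing
  weak <- links1; weak$zscore <- 8.9
  expect_equal(nrow(derive_indirect(direct, weak)), 0L)
  lowcov <- links1; lowcov$coverage_b <- 0.79
  expect_equal(nrow(derive_indirect(direct, lowcov)), 0L)
  # conflicting partner superfamilies leave the family unassigned
  links2 <- rbind(links1,
                  data.frame(family_a = "A", family_b = "C", zscore = 10,
                             coverage_a = 0.9, coverage_b = 0.9,
                             stringsAsFactors = FALSE))
  expect_equal(nrow(derive_indirect(direct, links2)), 0L)
})

test_that("indirect derivation matches enumeration over 3-node link graphs", {
  # A is unassigned; B and C carry all combinations of direct mappings;
  # links A-B and A-C are present/absent/qualifying in all combinations
  sf_opts <- list(NULL, "a.1.1", "b.1.1")
  link_opts <- list(NULL, TRUE, FALSE)   # absent / qualifying / sub-threshold
  for (sfB in sf_opts) for (sfC in sf_opts)
    for (lB in link_opts) for (lC in link_opts) {
      direct <- data.frame(family_id = character(),
                           superfamily_id = character(),
                           stringsAsFactors = FALSE)
      if (!is.null(sfB)) direct <- rbind(direct, data.frame(
        family_id = "B", superfamily_id = sfB, stringsAsFactors = FALSE))
      if (!is.null(sfC)) direct <- rbind(direct, data.frame(
        family_id = "C", superfamily_id = sfC, stringsAsFactors = FALSE))
      links <- data.frame(family_a = character(), family_b = character(),
                          zscore = numeric(), coverage_a = numeric(),
                          coverage_b = numeric(), stringsAsFactors = FALSE)
      add <- function(b, ok) data.frame(
        family_a = "A", family_b = b, zscore = if (ok) 9 else 8,
        coverage_a = 0.9, coverage_b = 0.9, stringsAsFactors = FALSE)
      if (!is.null(lB)) links <- rbind(links, add("B", lB))
      if (!is.null(lC)) links <- rbind(links, add("C", lC))
      got <- derive_indirect(direct, links)
      # expected: superfamilies reachable over qualifying links to mapped fams
      reach <- c(if (isTRUE(lB) && !is.null(sfB)) sfB,
                 if (isTRUE(lC) && !is.null(sfC)) sfC)
      if (length(unique(reach)) == 1L) {
        expect_equal(got$family_id, "A")
        expect_equal(got$superfamily_id, unique(reach))
      } else {
        expect_equal(nrow(got), 0L)
      }
    }
})
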