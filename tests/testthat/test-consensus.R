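# Build a method-assignment table from a named per-method superfamily map.
asg_from_map <- function(sf_by_method, query = "Q1", start = 1L, end = 100L) {
  ms <- names(sf_by_method)
  data.frame(query_id = query, method = ms,
             start = rep_len(start, length(ms)),
             end = rep_len(end, length(ms)),
             superfamily_id = as.character(sf_by_method),
             n_support = 1L, best_score = 1e-9, status = "assigned",
             provenance = "h1", origin = "direct", stringsAsFactors = FALSE)
}

test_that("the 60 % overlap rule follows the shorter-region arithmetic", {
  expect_true(regions_overlap(c(1, 100), c(30, 90)))    # containment
  expect_true(regions_overlap(c(1, 100), c(1, 100)))    # identity
  # overlap 51 covers 51 % of (1,100) and ~50.5 % of (50,150): not the same domain
  expect_false(regions_overlap(c(1, 100), c(50, 150)))
  expect_equal(region_overlap_frac(c(1, 100), c(50, 150)),
               c(51 / 100, 51 / 101))
  # 60 % of the shorter region is enough even when the longer is barely covered
  expect_true(regions_overlap(c(1, 300), c(1, 60)))
})

test_that("confidence tiers map method counts as published", {
  expect_equal(tier(5L), "high")
  expect_equal(tier(4L), "high")
  expect_equal(tier(3L), "medium")
  expect_equal(tier(2L), "medium")
  expect_equal(tier(1L), "low")
  expect_error(tier(0L), "1..5")
  expect_error(tier(6L), "1..5")
})

test_that("full agreement and the 4-of-5 exception are retained, all else excluded", {
  # five methods, one superfamily
  all5 <- asg_from_map(stats::setNames(rep("a.1.1", 5), FC_METHODS))
  got <- combine_assignments(all5)
  expect_equal(nrow(got$records), 1L)
  expect_equal(got$records$n_methods, 5L)
  expect_equal(got$records$confidence, "high")
  expect_true(is.na(got$records$outvoted_method))
  # four agree, one dissents: retained for the majority, dissenter recorded
  v41 <- asg_from_map(stats::setNames(c(rep("a.1.1", 4), "b.1.1"), FC_METHODS))
  got <- combine_assignments(v41)
  expect_equal(got$records$superfamily_id, "a.1.1")
  expect_equal(got$records$n_methods, 4L)
  expect_equal(got$records$confidence, "high")
  expect_equal(got$records$outvoted_method, FC_METHODS[5])
  expect_equal(sum(got$assignments$disposition == "outvoted"), 1L)
  expect_equal(nrow(got$exclusions), 0L)
  # a two-method conflict is excluded; same-fold conflicts are flagged
  c2 <- asg_from_map(c(nrichd = "a.1.1", hhsearch = "a.1.2"))
  got <- combine_assignments(c2)
  expect_equal(nrow(got$records), 0L)
  expect_equal(nrow(got$exclusions), 1L)
  expect_true(got$exclusions$same_fold)
  expect_equal(got$exclusions$superfamilies, "a.1.1;a.1.2")
  c2b <- asg_from_map(c(nrichd = "a.1.1", hhsearch = "b.1.1"))
  expect_false(combine_assignments(c2b)$exclusions$same_fold)
  # 3-vs-1 is NOT the tolerated exception
  v31 <- asg_from_map(stats::setNames(c(rep("a.1.1", 3), "b.1.1"),
                                      FC_METHODS[1:4]))
  got <- combine_assignments(v31)
  expect_equal(nrow(got$records), 0L)
  expect_equal(nrow(got$exclusions), 1L)
})

test_that("consensus adjudication matches the pattern oracle for all method subsets", {
  sf_sets <- list(c("a.1.1"), c("a.1.1", "a.1.2"), c("a.1.1", "b.1.1"),
                  c("a.1.1", "a.1.2", "b.1.1"))
  n_checked <- 0L
  for (k in 1:5) {
    subsets <- utils::combn(FC_METHODS, k, simplify = FALSE)
    for (ms in subsets) for (sfs in sf_sets) {
      n_lab <- length(sfs)
      for (code in seq_len(n_lab^k) - 1L) {
        lab <- (code %/% n_lab^(seq_len(k) - 1L)) %% n_lab + 1L
        sf_by_method <- stats::setNames(sfs[lab], ms)
        got <- combine_assignments(asg_from_map(sf_by_method))
        want <- consensus_oracle(sf_by_method)
        n_checked <- n_checked + 1L
        if (want$outcome == "consensus") {
          expect_equal(nrow(got$records), 1L)
          expect_equal(got$records$superfamily_id, want$sf)
          expect_equal(got$records$n_methods, want$n)
          if (!is.na(want$outvoted))
            expect_equal(got$records$outvoted_method, want$outvoted)
        } else {
          expect_equal(nrow(got$records), 0L)
          expect_equal(nrow(got$exclusions), 1L)
        }
        # partition: every assignment lands in exactly one disposition
        expect_false(anyNA(got$assignments$disposition))
      }
    }
  }
  expect_gt(n_checked, 1500)
})

test_that("non-overlapping regions yield independent records", {
  a <- rbind(asg_from_map(c(nrichd = "a.1.1", hhsearch = "a.1.1"),
                          start = 1L, end = 100L),
             asg_from_map(c(supfam_plus = "b.1.1"), start = 150L, end = 260L))
  got <- combine_assignments(a)
  expect_equal(nrow(got$records), 2L)
  expect_setequal(got$records$superfamily_id, c("a.1.1", "b.1.1"))
  expect_setequal(got$records$n_methods, c(2L, 1L))
})

test_that("two verdicts from one method in one region group are an error", {
  a <- rbind(asg_from_map(c(nrichd = "a.1.1")),
             asg_from_map(c(nrichd = "a.1.1"), start = 5L, end = 95L))
  expect_error(combine_assignments(a), "two verdicts")
})

test_that("combination is invariant to method input order", {
  set.seed(43)
  for (rep in 1:20) {
    k <- sample(1:5, 1)
    ms <- sample(FC_METHODS, k)
    sfs <- sample(c("a.1.1", "a.1.2", "b.1.1"), k, replace = TRUE)
    a <- asg_from_map(stats::setNames(sfs, ms))
    ref <- combine_assignments(a)
    per <- combine_assignments(a[sample(k), , drop = FALSE])
    expect_equal(per$records$superfamily_id, ref$records$superfamily_id)
    expect_equal(per$records$methods, ref$records$methods)
    expect_equal(per$exclusions$superfamilies, ref$exclusions$superfamilies)
  }
})

test_that("removing a method never raises agreement, and 4v1 flips to excluded", {
  v41 <- stats::setNames(c(rep("a.1.1", 4), "b.1.1"), FC_METHODS)
  full <- combine_assignments(asg_from_map(v41))
  expect_equal(full$records$n_methods, 4L)
  # dropping one agreeing method leaves 3v1, which is an exclusion
  drop1 <- combine_assignments(asg_from_map(v41[-1]))
  expect_equal(nrow(drop1$records), 0L)
  expect_equal(nrow(drop1$exclusions), 1L)
  # dropping the dissenter leaves clean 4-way agreement
  drop_dis <- combine_assignments(asg_from_map(v41[1:4]))
  expect_equal(drop_dis$records$n_methods, 4L)
  expect_equal(nrow(drop_dis$exclusions), 0L)
  # for agreeing sets, removal only lowers n_methods
  agree <- stats::setNames(rep("a.1.1", 4), FC_METHODS[1:4])
  for (i in 1:4) {
    red <- combine_assignments(asg_from_map(agree[-i]))
    expect_equal(red$records$n_methods, 3L)
    expect_equal(nrow(red$exclusions), 0L)
  }
})

test_that("tallies account for every assignment and tier", {
  a <- rbind(asg_from_map(stats::setNames(rep("a.1.1", 5), FC_METHODS), "Q1"),
             asg_from_map(c(nrichd = "a.1.2", hhsearch = "a.1.2"), "Q2"),
             asg_from_map(c(supfam_plus = "b.1.1"), "Q3"),
             asg_from_map(c(nrichd = "a.1.1", supfam_plus = "b.2.1"), "Q4"))
  got <- combine_assignments(a)
  s <- tally(got)
  expect_equal(s$n_records, 3L)
  expect_equal(s$n_families, 3L)
  expect_equal(s$tier_counts, list(high = 1L, medium = 1L, low = 1L))
  expect_equal(unlist(s$tier_histogram), c("1" = 1L, "2" = 1L, "3" = 0L,
                                           "4" = 0L, "5" = 1L))
  pm <- s$per_method
  expect_equal(pm$n_assigned[pm$method == "nrichd"], 3L)
  expect_equal(pm$n_discarded[pm$method == "nrichd"], 1L)
  expect_equal(pm$n_retained[pm$method == "nrichd"], 2L)
  expect_equal(pm$n_unique[pm$method == "supfam_plus"], 1L)
  expect_equal(pm$n_retained, pm$n_assigned - pm$n_discarded)
  expect_equal(s$n_excluded_regions, 1L)
  expect_equal(s$n_superfamilies, 3L)   # a.1.1, a.1.2, b.1.1
  expect_equal(s$n_folds, 2L)           # a.1, b.1
  # empty input tallies to zero
  e <- tally(combine_assignments(a[0, , drop = FALSE]))
  expect_equal(e$n_records, 0L)
  expect_equal(sum(unlist(e$tier_counts)), 0L)
})
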