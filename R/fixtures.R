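# Deterministic synthetic input bundles.
#
# The generator emits a complete, internally consistent input bundle -- hit
# files in every supported dialect, SCOP catalog, family table, link and
# annotation tables -- together with a ground-truth manifest stating the
# consensus outcome the pipeline must reproduce for every family. Scores and
# regions are sampled to pass or fail the acceptance filters exactly as the
# manifest dictates. One pseudo-random stream is derived per (seed, label)
# so regenerating with the same seed is byte-identical and adding a file
# never shifts the content of others.

# -- deterministic streams ---------------------------------------------------

stream_seed <- function(seed, label) {
  h <- as.numeric(seed) %% 2147483647
  for (ch in utf8ToInt(label)) h <- (h * 31 + ch) %% 2147483647
  as.integer(h)
}

with_stream <- function(seed, label, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
          else assign(".Random.seed", old, envir = globalenv()))
  set.seed(stream_seed(seed, label))
  force(expr)
}

# scores as shortest 3-significant-digit decimals so write -> read -> write
# is byte-stable
num3 <- function(x) as.numeric(sprintf("%.3g", x))

# -- fixture specification ---------------------------------------------------

#' Specify a synthetic input bundle
#'
#' The specification fixes, per method, how many families that method
#' assigns before consensus and how many of those are discarded as
#' cross-method conflicts, and/or a histogram of method-agreement tiers.
#' The generator then plans one hit per (family, method) whose scores and
#' regions pass the acceptance filters, so per-method pre-filter hit counts
#' equal the assigned counts exactly.
#'
#' @param seed integer; drives every pseudo-random choice.
#' @param n_families total families in the bundle (`NULL`: as many as the
#'   plan needs; extra families beyond the plan receive no hits).
#' @param scop_catalog_size minimum number of catalog domains (default 72;
#'   at least two domains per generated superfamily).
#' @param per_method_assigned named integer vector (names from
#'   [FC_METHODS]): pre-consensus assignment counts per listed method.
#' @param per_method_conflicting named integer vector: how many of each
#'   listed method's assignments end in cross-method conflicts. Conflict
#'   families pair methods with remaining conflict quotas; when only one
#'   listed method has quota left its partner is drawn from the remaining
#'   methods (adding one assignment and one conflict to that partner, so
#'   retained counts are unaffected).
#' @param tier_histogram named vector (`"1"`..`"5"` -> family counts):
#'   agreement families by number of supporting methods. When combined with
#'   `per_method_assigned` the totals must be consistent.
#' @param n_outvoted families where four methods agree and a fifth dissents
#'   (retained with the dissenter outvoted). Only available when
#'   `per_method_assigned` is not given.
#' @param link_spec integer pair `c(n_direct, n_indirect)`: size of the
#'   direct family-to-superfamily mapping table and number of additional
#'   families assignable only through qualifying family-family links.
#' @param kingdom_mix optional named vector (kingdom-set label such as
#'   `"Bacteria"` or `"Bacteria+Eukaryota"` -> family count) controlling
#'   member-taxon sampling; default: one or two kingdoms per family at
#'   random.
#' @return validated `fixture_spec` object.
#' @export
fixture_spec <- function(seed, n_families = NULL, scop_catalog_size = 72,
                         per_method_assigned = NULL,
                         per_method_conflicting = NULL,
                         tier_histogram = NULL, n_outvoted = 0L,
                         link_spec = c(n_direct = 0L, n_indirect = 0L),
                         kingdom_mix = NULL) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  chk_map <- function(x, what, allowed) {
    if (is.null(x)) return(NULL)
    x <- round(unlist(x))
    if (is.null(names(x)) || !all(names(x) %in% allowed))
      stop(what, " must be named by ", paste(allowed, collapse = "/"))
    if (any(x < 0)) stop(what, " counts must be >= 0")
    x[x > 0]
  }
  per_method_assigned <- chk_map(per_method_assigned,
                                 "per_method_assigned", FC_METHODS)
  per_method_conflicting <- chk_map(per_method_conflicting,
                                    "per_method_conflicting", FC_METHODS)
  tier_histogram <- chk_map(tier_histogram, "tier_histogram",
                            as.character(1:5))
  if (!is.null(per_method_assigned) && !is.null(per_method_conflicting)) {
    for (m in names(per_method_conflicting)) {
      a <- if (m %in% names(per_method_assigned)) per_method_assigned[[m]] else 0L
      if (per_method_conflicting[[m]] > a)
        stop("per-method conflicting count exceeds assigned count for ", m)
    }
  }
  if (n_outvoted > 0L && !is.null(per_method_assigned))
    stop("n_outvoted cannot be combined with per_method_assigned")
  link_spec <- round(unlist(link_spec))
  if (length(link_spec) != 2L || any(link_spec < 0))
    stop("link_spec must be two non-negative counts (n_direct, n_indirect)")
  names(link_spec) <- c("n_direct", "n_indirect")
  if (link_spec[["n_indirect"]] > 0L && link_spec[["n_direct"]] == 0L)
    stop("indirect links need at least one direct mapping")
  spec <- structure(
    list(seed = as.integer(seed), n_families = n_families,
         scop_catalog_size = as.integer(scop_catalog_size),
         per_method_assigned = per_method_assigned,
         per_method_conflicting = per_method_conflicting,
         tier_histogram = tier_histogram, n_outvoted = as.integer(n_outvoted),
         link_spec = link_spec, kingdom_mix = kingdom_mix),
    class = "fixture_spec")
  plan <- plan_families(spec)     # validates joint consistency
  if (!is.null(n_families)) {
    if (n_families < length(plan))
      stop("n_families (", n_families, ") is smaller than the ",
           length(plan), " families the specification requires")
    spec$n_families <- as.integer(n_families)
  } else {
    spec$n_families <- length(plan)
  }
  spec
}

# Allocate methods to agreement / conflict / outvoted / indirect families.
# Returns a list of family plans: list(type, methods, dissenter).
plan_families <- function(spec) {
  fams <- list()
  agree_quota <- NULL
  if (!is.null(spec$per_method_assigned)) {
    agree_quota <- spec$per_method_assigned
    for (m in names(spec$per_method_conflicting)) {
      if (m %in% names(agree_quota))
        agree_quota[[m]] <- agree_quota[[m]] - spec$per_method_conflicting[[m]]
    }
    agree_quota <- agree_quota[agree_quota > 0]
  }
  # agreement families
  if (!is.null(spec$tier_histogram)) {
    sizes <- rep(as.integer(names(spec$tier_histogram)), spec$tier_histogram)
    sizes <- sort(sizes, decreasing = TRUE)
    if (!is.null(agree_quota) &&
        sum(agree_quota) != sum(sizes))
      stop("tier_histogram methods total (", sum(sizes),
           ") does not match per-method agreement total (",
           sum(agree_quota), ")")
    for (j in seq_along(sizes)) {
      k <- sizes[j]
      if (is.null(agree_quota)) {
        meth <- FC_METHODS[((j - 1L + 0:(k - 1L)) %% 5L) + 1L]
      } else {
        avail <- names(agree_quota)[agree_quota > 0]
        if (length(avail) < k)
          stop("tier_histogram incompatible with per-method counts: ",
               "a family of ", k, " methods cannot be filled")
        avail <- avail[order(-agree_quota[avail], avail)]
        meth <- avail[seq_len(k)]
        agree_quota[meth] <- agree_quota[meth] - 1L
      }
      fams[[length(fams) + 1L]] <- list(type = "agree", methods = meth)
    }
  } else if (!is.null(agree_quota)) {
    for (m in names(agree_quota)) for (i in seq_len(agree_quota[[m]]))
      fams[[length(fams) + 1L]] <- list(type = "agree", methods = m)
  }
  # outvoted families (4 agree + 1 dissent)
  if (spec$n_outvoted > 0L) for (j in seq_len(spec$n_outvoted)) {
    dis <- FC_METHODS[((j - 1L) %% 5L) + 1L]
    fams[[length(fams) + 1L]] <-
      list(type = "outvoted", methods = FC_METHODS, dissenter = dis)
  }
  # conflict families
  quota <- spec$per_method_conflicting
  if (!is.null(quota) && sum(quota) > 0) {
    filler <- 0L
    while (sum(quota) > 0) {
      act <- names(quota)[quota > 0]
      act <- act[order(-quota[act], act)]
      m1 <- act[1L]
      if (length(act) >= 2L) {
        m2 <- act[2L]
        quota[m2] <- quota[m2] - 1L
      } else {
        others <- setdiff(FC_METHODS, m1)
        m2 <- others[(filler %% length(others)) + 1L]
        filler <- filler + 1L
      }
      quota[m1] <- quota[m1] - 1L
      fams[[length(fams) + 1L]] <- list(type = "conflict",
                                        methods = sort(c(m1, m2)))
    }
  }
  # indirect families
  n_ind <- spec$link_spec[["n_indirect"]]
  if (n_ind > 0L) for (j in seq_len(n_ind))
    fams[[length(fams) + 1L]] <- list(type = "indirect",
                                      methods = "supfam_plus")
  fams
}

# -- bundle components -------------------------------------------------------

# Catalog of synthetic structural domains: 4 classes x 3 folds x 3
# superfamilies so every lineage relation needed by the decision trees is
# represented; at least two domains per superfamily.
make_catalog <- function(scop_catalog_size) {
  sfs <- character()
  for (cl in c("a", "b", "c", "d")) for (f in 1:3) for (s in 1:3)
    sfs <- c(sfs, paste(cl, f, s, sep = "."))
  per_sf <- max(2L, ceiling(scop_catalog_size / length(sfs)))
  rows <- list()
  k <- 0L
  for (sf in sfs) for (d in seq_len(per_sf)) {
    k <- k + 1L
    rows[[k]] <- data.frame(
      domain_sid = sprintf("d%04d%s_", k, letters[d]),
      pdb_id = sprintf("%04d", 1000L + k),
      chain_region = "A:", sccs = paste0(sf, ".1"),
      stringsAsFactors = FALSE)
  }
  cat_df <- do.call(rbind, rows)
  cat_df <- cbind(cat_df, sccs_fields(cat_df$sccs))
  class(cat_df) <- c("scop_catalog", "data.frame")
  cat_df
}

# Minimal four-kingdom taxonomy with three species leaves per kingdom.
fixture_taxonomy_tables <- function() {
  sk <- data.frame(
    taxid = c(2L, 2157L, 2759L, 10239L),
    name = c("Bacteria", "Archaea", "Eukaryota", "Viruses"),
    stringsAsFactors = FALSE)
  species <- data.frame(
    taxid = c(562L, 1280L, 287L, 2190L, 2287L, 2261L,
              9606L, 4932L, 7227L, 10665L, 11676L, 10298L),
    parent = rep(sk$taxid, each = 3L),
    name = c("Escherichia coli", "Staphylococcus aureus",
             "Pseudomonas aeruginosa", "Methanocaldococcus jannaschii",
             "Sulfolobus acidocaldarius", "Pyrococcus furiosus",
             "Homo sapiens", "Saccharomyces cerevisiae",
             "Drosophila melanogaster", "Escherichia virus T4",
             "HIV-1", "Human alphaherpesvirus 1"),
    stringsAsFactors = FALSE)
  nodes <- rbind(
    data.frame(taxid = 1L, parent_taxid = 1L, rank = "no rank",
               name = "root", stringsAsFactors = FALSE),
    data.frame(taxid = sk$taxid, parent_taxid = 1L, rank = "superkingdom",
               name = sk$name, stringsAsFactors = FALSE),
    data.frame(taxid = species$taxid, parent_taxid = species$parent,
               rank = "species", name = species$name,
               stringsAsFactors = FALSE))
  nodes
}

species_by_kingdom <- function(taxonomy) {
  sp <- taxonomy[taxonomy$rank == "species", , drop = FALSE]
  kingdom <- taxonomy$name[match(sp$parent_taxid, taxonomy$taxid)]
  split(sp$taxid, kingdom)
}

# -- file writers ------------------------------------------------------------

fmt_num <- function(x) sprintf("%.6g", x)

#' Write hits as a HMMER3 per-domain tabular file
#'
#' @param hits `domain_hits` (E-value scored).
#' @param path output file.
#' @export
write_domtbl <- function(hits, path) {
  header <- c(
    "# target name        accession   tlen query name           accession   qlen   E-value  score  bias   #  of  c-Evalue  i-Evalue  score  bias  from    to  from    to  from    to  acc description of target",
    "#------------------- ---------- ----- -------------------- ---------- ----- --------- ------ ----- --- --- --------- --------- ------ ----- ----- ----- ----- ----- ----- ----- ---- ---------------------")
  rows <- character(nrow(hits))
  for (i in seq_len(nrow(hits))) {
    rows[i] <- paste(
      hits$hit_id[i], "-", hits$end[i] - hits$start[i] + 1L,
      hits$query_id[i], "-", hits$query_length[i],
      fmt_num(hits$evalue[i]), "100.0", "0.1", "1", "1",
      fmt_num(hits$evalue[i]), fmt_num(hits$evalue[i]), "100.0", "0.1",
      hits$start[i], hits$end[i], hits$start[i], hits$end[i],
      hits$start[i], hits$end[i], "0.95", "-")
  }
  writeLines(c(header, rows, "#"), path)
}

#' Write hits as an HHsearch-style result file
#'
#' One query block per distinct query, each with a header and summary
#' table; several blocks are concatenated in one file.
#'
#' @param hits `domain_hits` (E-value scored).
#' @param path output file.
#' @export
write_hhr <- function(hits, path) {
  out <- character()
  for (q in unique(hits$query_id)) {
    h <- hits[hits$query_id == q, , drop = FALSE]
    out <- c(out,
      paste0("Query         ", q),
      paste0("Match_columns ", h$query_length[1L]),
      "No_of_seqs    1 out of 1",
      "",
      " No Hit                             Prob E-value P-value  Score    SS Cols Query HMM  Template HMM")
    for (i in seq_len(nrow(h))) {
      tlen <- h$end[i] - h$start[i] + 1L
      out <- c(out, sprintf(
        "%3d %-30s %5.1f %7s %7s %6.1f %5.1f %4d %9s %9s (%d)",
        i, h$hit_id[i], 99.9, fmt_num(h$evalue[i]),
        fmt_num(h$evalue[i] / 10), 210.0, 0.0, tlen,
        paste0(h$start[i], "-", h$end[i]), paste0(1L, "-", tlen), tlen))
    }
    out <- c(out, "")
  }
  writeLines(out, path)
}

#' Write hits as a tab-delimited score table
#'
#' Columns: query_id, hit_id, score (Z or P by method), qstart, qend, tag.
#'
#' @param hits `domain_hits` (Z- or P-value scored).
#' @param path output file.
#' @export
write_score_table <- function(hits, path) {
  kind <- if (nrow(hits)) method_score_kind(hits$method[1L]) else "zscore"
  score <- if (kind == "zscore") hits$zscore else hits$pvalue
  writeLines(c("# query_id\thit_id\tscore\tqstart\tqend\ttag",
               sprintf("%s\t%s\t%s\t%d\t%d\t%s",
                       hits$query_id, hits$hit_id, fmt_num(score),
                       hits$start, hits$end, hits$source_pass)), path)
}

write_catalog_file <- function(cat_df, path) {
  writeLines(c("# domain_sid\tpdb_id\tchain:range\tsccs",
               sprintf("%s\t%s\t%s\t%s", cat_df$domain_sid, cat_df$pdb_id,
                       cat_df$chain_region, cat_df$sccs)), path)
}

write_family_file <- function(fam, path) {
  taxa <- vapply(fam$member_taxa, function(t) paste(t, collapse = ","), "")
  writeLines(c("# family_id\tquery_length\tclan_id\tmember_taxa",
               sprintf("%s\t%d\t%s\t%s", fam$family_id, fam$query_length,
                       fam$clan_id, taxa)), path)
}

write_taxonomy_files <- function(taxonomy, nodes_path, names_path) {
  writeLines(sprintf("%d\t|\t%d\t|\t%s\t|", taxonomy$taxid,
                     taxonomy$parent_taxid, taxonomy$rank), nodes_path)
  writeLines(sprintf("%d\t|\t%s\t|\t\t|\tscientific name\t|",
                     taxonomy$taxid, taxonomy$name), names_path)
}

# -- the generator -----------------------------------------------------------

#' Generate a synthetic input bundle
#'
#' Writes, under `outdir`: per-method hit files (`nrichd_hmmsearch.domtbl`,
#' `nrichd_jackhmmer.domtbl`, `superfamily.domtbl`, `hhsearch.hhr`,
#' `supfam_plus.tsv`, `pdomthreader.tsv`), `scop_cla.tsv`, `families.tsv`,
#' `links.tsv`, `direct_map.tsv`, annotation tables (`dcgo.tsv`,
#' `pdb_ec.tsv`, `pdb_scop.tsv`, `taxonomy_nodes.dmp`,
#' `taxonomy_names.dmp`) and the ground-truth `manifest.tsv` /
#' `manifest.json`. Regenerating with the same spec and seed is
#' byte-identical.
#'
#' @param spec a [fixture_spec()].
#' @param outdir output directory (created if missing).
#' @return the manifest data.frame, invisibly: per family its type,
#'   methods, intended superfamily, intended consensus `outcome`
#'   (`consensus`/`excluded`/`none`), `n_methods`, `confidence`,
#'   `same_fold`, intended region and origin.
#' @export
generate_fixture <- function(spec, outdir) {
  stopifnot(inherits(spec, "fixture_spec"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  seed <- spec$seed
  plans <- plan_families(spec)
  n_plan <- length(plans)
  n_fam <- spec$n_families
  cat_df <- make_catalog(spec$scop_catalog_size)
  sf_pool <- unique(cat_df$superfamily_id)
  doms_by_sf <- split(cat_df$domain_sid, cat_df$superfamily_id)
  taxonomy <- fixture_taxonomy_tables()
  sp_by_k <- species_by_kingdom(taxonomy)

  fam_ids <- sprintf("DUF%04d", seq_len(n_fam))
  qlen <- with_stream(seed, "plan:qlen", sample(120:400, n_fam, replace = TRUE))
  shift <- with_stream(seed, "plan:shift", sample(0:4, n_fam, replace = TRUE))

  # kingdoms per family
  kmix <- spec$kingdom_mix
  fam_kingdoms <- vector("list", n_fam)
  if (!is.null(kmix)) {
    labels <- rep(names(kmix), unlist(kmix))
    if (length(labels) > n_fam)
      stop("kingdom_mix total exceeds n_families")
    labels <- c(labels, rep("Bacteria", n_fam - length(labels)))
    fam_kingdoms <- strsplit(labels, "+", fixed = TRUE)
  } else {
    fam_kingdoms <- with_stream(seed, "plan:kingdoms", lapply(seq_len(n_fam),
      function(i) sample(KINGDOMS, sample(1:2, 1L))))
  }
  member_taxa <- with_stream(seed, "plan:taxa", lapply(fam_kingdoms,
    function(ks) unlist(lapply(ks, function(k) sample(sp_by_k[[k]], 2L)))))

  # intended superfamilies and per-method hit plan
  folds <- unique(sf_fold(sf_pool))
  hit_rows <- list(); nh <- 0L
  manifest <- list()
  sf_rr <- 0L; fold_rr <- 0L; conf_i <- 0L; ind_rr <- 0L
  # indirect families inherit through the direct table, so their intended
  # superfamily must be one the direct table covers
  n_direct_sf <- min(spec$link_spec[["n_direct"]], length(sf_pool))
  dom_pick <- function(sf, j) {
    d <- doms_by_sf[[sf]]
    d[((j - 1L) %% length(d)) + 1L]
  }
  for (i in seq_len(n_fam)) {
    fp <- if (i <= n_plan) plans[[i]] else list(type = "background",
                                                methods = character())
    s <- 1L + shift[i]
    e <- min(s + as.integer(ceiling(0.85 * qlen[i])) - 1L, qlen[i])
    sf_by_method <- character(0)
    if (fp$type == "agree") {
      sf_rr <- sf_rr + 1L
      sf <- sf_pool[((sf_rr - 1L) %% length(sf_pool)) + 1L]
      sf_by_method <- stats::setNames(rep(sf, length(fp$methods)), fp$methods)
    } else if (fp$type == "indirect") {
      ind_rr <- ind_rr + 1L
      sf <- sf_pool[((ind_rr - 1L) %% n_direct_sf) + 1L]
      sf_by_method <- stats::setNames(rep(sf, length(fp$methods)), fp$methods)
      s <- 1L; e <- qlen[i]   # indirect assignments span the whole query
    } else if (fp$type == "outvoted") {
      sf_rr <- sf_rr + 1L
      sf <- sf_pool[((sf_rr - 1L) %% length(sf_pool)) + 1L]
      dis_sf <- sf_pool[sf_class(sf_pool) != sf_class(sf)][1L]
      sf_by_method <- stats::setNames(
        ifelse(fp$methods == fp$dissenter, dis_sf, sf), fp$methods)
    } else if (fp$type == "conflict") {
      conf_i <- conf_i + 1L
      if (conf_i %% 2L == 1L) {    # same-fold conflict
        fold_rr <- fold_rr + 1L
        fold <- folds[((fold_rr - 1L) %% length(folds)) + 1L]
        in_fold <- sf_pool[sf_fold(sf_pool) == fold]
        sfs <- in_fold[seq_along(fp$methods)]
      } else {                     # cross-fold conflict
        fold_rr <- fold_rr + 1L
        pick <- (fold_rr - 1L + seq_along(fp$methods)) %% length(folds) + 1L
        sfs <- vapply(folds[pick], function(f)
          sf_pool[sf_fold(sf_pool) == f][1L], "")
      }
      sf_by_method <- stats::setNames(sfs, fp$methods)
    }
    for (m in fp$methods) {
      if (fp$type == "indirect") next   # reached through the link tables
      nh <- nh + 1L
      ms <- max(1L, s + ((nh %% 3L) - 1L))   # small per-method jitter
      me <- min(ms + (e - s), qlen[i])
      hit_rows[[nh]] <- data.frame(
        family = fam_ids[i], method = m, sf = sf_by_method[[m]],
        hit_id = dom_pick(sf_by_method[[m]], i), start = ms, end = me,
        qlen = qlen[i], stringsAsFactors = FALSE)
    }
    out <- intended_outcome(sf_by_method)
    manifest[[i]] <- data.frame(
      family_id = fam_ids[i], type = fp$type,
      methods = paste(sort(factor(fp$methods, levels = FC_METHODS)),
                      collapse = ";"),
      superfamily_id = out$superfamily_id, outcome = out$outcome,
      n_methods = out$n_methods, confidence = out$confidence,
      same_fold = out$same_fold,
      start = if (length(fp$methods)) s else NA_integer_,
      end = if (length(fp$methods)) e else NA_integer_,
      origin = if (fp$type == "indirect") "indirect" else "direct",
      query_length = qlen[i], stringsAsFactors = FALSE)
  }
  plan_df <- if (nh) do.call(rbind, hit_rows) else
    data.frame(family = character(), method = character(), sf = character(),
               hit_id = character(), start = integer(), end = integer(),
               qlen = integer(), stringsAsFactors = FALSE)
  manifest <- do.call(rbind, manifest)
  if (is.null(manifest))
    manifest <- data.frame(family_id = character(), type = character(),
                           methods = character(), superfamily_id = character(),
                           outcome = character(), n_methods = integer(),
                           confidence = character(), same_fold = logical(),
                           start = integer(), end = integer(),
                           origin = character(), query_length = integer(),
                           stringsAsFactors = FALSE)

  # family table
  fam <- data.frame(family_id = fam_ids,
                    query_length = qlen,
                    clan_id = ifelse(seq_len(n_fam) %% 4L == 0L,
                                     sprintf("CL%04d", seq_len(n_fam)), ""),
                    stringsAsFactors = FALSE)
  fam$member_taxa <- I(member_taxa)
  write_family_file(fam, file.path(outdir, "families.tsv"))
  write_catalog_file(cat_df, file.path(outdir, "scop_cla.tsv"))

  # per-method hit files
  method_hits <- function(m, score_fun) {
    p <- plan_df[plan_df$method == m, , drop = FALSE]
    if (nrow(p) == 0L) return(empty_hits())
    kind <- method_score_kind(m)
    sc <- score_fun(nrow(p))
    domain_hits(query_id = p$family, method = m, hit_id = p$hit_id,
                sccs = paste0(p$sf, ".1"), start = p$start, end = p$end,
                query_length = p$qlen,
                evalue = if (kind == "evalue") sc else NA_real_,
                zscore = if (kind == "zscore") sc else NA_real_,
                pvalue = if (kind == "pvalue") sc else NA_real_,
                source_pass = if (m == "pdomthreader") "CERTAIN" else m)
  }
  ev_fun <- function(lbl) function(n)
    with_stream(seed, lbl, num3(10^(-stats::runif(n, 5, 50))))
  nrichd <- method_hits("nrichd", ev_fun("scores:nrichd"))
  half <- seq_len(nrow(nrichd)) %% 2L == 1L
  write_domtbl(nrichd[half, , drop = FALSE],
               file.path(outdir, "nrichd_hmmsearch.domtbl"))
  write_domtbl(nrichd[!half, , drop = FALSE],
               file.path(outdir, "nrichd_jackhmmer.domtbl"))
  write_domtbl(method_hits("superfamily_db", ev_fun("scores:superfamily_db")),
               file.path(outdir, "superfamily.domtbl"))
  write_hhr(method_hits("hhsearch", ev_fun("scores:hhsearch")),
            file.path(outdir, "hhsearch.hhr"))
  write_score_table(method_hits("supfam_plus", function(n)
    with_stream(seed, "scores:supfam_plus", num3(stats::runif(n, 8, 15)))),
    file.path(outdir, "supfam_plus.tsv"))
  write_score_table(method_hits("pdomthreader", function(n)
    with_stream(seed, "scores:pdomthreader", num3(10^(-stats::runif(n, 6, 12))))),
    file.path(outdir, "pdomthreader.tsv"))

  # direct mapping and link tables
  n_direct <- spec$link_spec[["n_direct"]]
  direct <- data.frame(
    family_id = sprintf("PF%05d", seq_len(n_direct)),
    superfamily_id = sf_pool[((seq_len(n_direct) - 1L) %% length(sf_pool)) + 1L],
    stringsAsFactors = FALSE)
  ind_rows <- manifest[manifest$type == "indirect", , drop = FALSE]
  links <- data.frame(family_a = character(), family_b = character(),
                      zscore = numeric(), coverage_a = numeric(),
                      coverage_b = numeric(), stringsAsFactors = FALSE)
  if (nrow(ind_rows) > 0L) {
    # give every indirect family a qualifying link to a direct partner of
    # its intended superfamily
    partner <- vapply(ind_rows$superfamily_id, function(sf) {
      cand <- direct$family_id[direct$superfamily_id == sf]
      if (length(cand) == 0L)
        stop("no direct mapping available for superfamily ", sf)
      cand[1L]
    }, "")
    zl <- with_stream(seed, "links:z",
                      num3(stats::runif(nrow(ind_rows), 9, 14)))
    cv <- with_stream(seed, "links:cov",
                      num3(stats::runif(2L * nrow(ind_rows), 0.82, 0.98)))
    links <- data.frame(family_a = ind_rows$family_id, family_b = partner,
                        zscore = zl,
                        coverage_a = cv[seq_len(nrow(ind_rows))],
                        coverage_b = cv[nrow(ind_rows) + seq_len(nrow(ind_rows))],
                        stringsAsFactors = FALSE)
    # sub-threshold decoy links: must not create mappings
    decoy <- data.frame(family_a = ind_rows$family_id[1L],
                        family_b = direct$family_id[nrow(direct)],
                        zscore = 8.5, coverage_a = 0.5, coverage_b = 0.9,
                        stringsAsFactors = FALSE)
    links <- rbind(links, decoy)
  }
  writeLines(c("# family_id\tsuperfamily_id",
               sprintf("%s\t%s", direct$family_id, direct$superfamily_id)),
             file.path(outdir, "direct_map.tsv"))
  writeLines(c("# family_a\tfamily_b\tzscore\tcoverage_a\tcoverage_b",
               sprintf("%s\t%s\t%s\t%s\t%s", links$family_a, links$family_b,
                       fmt_num(links$zscore), fmt_num(links$coverage_a),
                       fmt_num(links$coverage_b))),
             file.path(outdir, "links.tsv"))

  # annotation tables
  go_ns <- c("molecular_function", "biological_process", "cellular_component")
  dcgo <- do.call(rbind, lapply(seq_along(sf_pool), function(k)
    data.frame(superfamily_id = sf_pool[k],
               go_id = sprintf("GO:%07d", 1000L + 10L * k + 0:2),
               namespace = go_ns[(k + 0:2) %% 3L + 1L],
               information_content = c(2.5, 1.5, 0.8) + 0.01 * (k %% 7),
               stringsAsFactors = FALSE)))
  writeLines(c("# superfamily_id\tgo_id\tnamespace\tinformation_content",
               sprintf("%s\t%s\t%s\t%s", dcgo$superfamily_id, dcgo$go_id,
                       dcgo$namespace, fmt_num(dcgo$information_content))),
             file.path(outdir, "dcgo.tsv"))
  pdb_scop <- do.call(rbind, lapply(seq_along(sf_pool), function(k) rbind(
    data.frame(pdb_chain = sprintf("%04dA", 3000L + k),
               domain_sid = sprintf("e%04da_", k),
               sccs = paste0(sf_pool[k], ".1"), stringsAsFactors = FALSE),
    # a two-domain chain: contributes no EC transfer
    data.frame(pdb_chain = sprintf("%04dB", 3000L + k),
               domain_sid = sprintf("e%04d%s_", k, c("b", "c")),
               sccs = c(paste0(sf_pool[k], ".1"),
                        paste0(sf_pool[(k %% length(sf_pool)) + 1L], ".1")),
               stringsAsFactors = FALSE))))
  writeLines(c("# pdb_chain\tdomain_sid\tsccs",
               sprintf("%s\t%s\t%s", pdb_scop$pdb_chain, pdb_scop$domain_sid,
                       pdb_scop$sccs)),
             file.path(outdir, "pdb_scop.tsv"))
  ec <- sprintf("%d.%d.%d.%d", (seq_along(sf_pool) - 1L) %% 6L + 1L,
                seq_along(sf_pool) %% 9L + 1L, 1L, seq_along(sf_pool))
  writeLines(c("# pdb_chain\tec_number",
               sprintf("%04dA\t%s", 3000L + seq_along(sf_pool), ec),
               sprintf("%04dB\t%s", 3000L + seq_along(sf_pool), ec)),
             file.path(outdir, "pdb_ec.tsv"))
  write_taxonomy_files(taxonomy, file.path(outdir, "taxonomy_nodes.dmp"),
                       file.path(outdir, "taxonomy_names.dmp"))

  write_manifest(manifest, outdir)
  invisible(manifest)
}

# Intended cross-method outcome from a named per-method superfamily map.
intended_outcome <- function(sf_by_method) {
  if (length(sf_by_method) == 0L)
    return(list(outcome = "none", superfamily_id = NA_character_,
                n_methods = 0L, confidence = NA_character_, same_fold = NA))
  counts <- sort(table(sf_by_method), decreasing = TRUE)
  if (length(counts) == 1L)
    return(list(outcome = "consensus", superfamily_id = names(counts)[1L],
                n_methods = length(sf_by_method),
                confidence = tier(length(sf_by_method)), same_fold = NA))
  if (length(sf_by_method) == 5L && length(counts) == 2L && counts[1L] == 4L)
    return(list(outcome = "consensus", superfamily_id = names(counts)[1L],
                n_methods = 4L, confidence = tier(4L), same_fold = NA))
  usf <- unique(as.character(sf_by_method))
  list(outcome = "excluded", superfamily_id = NA_character_,
       n_methods = length(sf_by_method), confidence = NA_character_,
       same_fold = length(unique(sf_fold(usf))) == 1L)
}

write_manifest <- function(manifest, outdir) {
  sf <- ifelse(is.na(manifest$same_fold), "NA",
               ifelse(manifest$same_fold, "TRUE", "FALSE"))
  writeLines(c(paste0("# ", paste(names(manifest), collapse = "\t")),
               sprintf("%s\t%s\t%s\t%s\t%s\t%d\t%s\t%s\t%s\t%s\t%s\t%d",
                       manifest$family_id, manifest$type, manifest$methods,
                       ifelse(is.na(manifest$superfamily_id), "NA",
                              manifest$superfamily_id),
                       manifest$outcome, manifest$n_methods,
                       ifelse(is.na(manifest$confidence), "NA",
                              manifest$confidence), sf,
                       ifelse(is.na(manifest$start), "NA",
                              as.character(manifest$start)),
                       ifelse(is.na(manifest$end), "NA",
                              as.character(manifest$end)),
                       manifest$origin, manifest$query_length)),
             file.path(outdir, "manifest.tsv"))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       dataframe = "rows", na = "null", digits = NA,
                       pretty = TRUE)
}

#' Read a bundle manifest
#'
#' @param dir bundle directory.
#' @return manifest data.frame (see [generate_fixture()]).
#' @export
read_manifest <- function(dir) {
  lines <- readLines(file.path(dir, "manifest.tsv"))
  lines <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  if (length(lines) == 0L)
    return(data.frame(family_id = character(), type = character(),
                      methods = character(), superfamily_id = character(),
                      outcome = character(), n_methods = integer(),
                      confidence = character(), same_fold = logical(),
                      start = integer(), end = integer(),
                      origin = character(), query_length = integer(),
                      stringsAsFactors = FALSE))
  p <- strsplit(lines, "\t", fixed = TRUE)
  g <- function(i) vapply(p, `[`, "", i)
  na_chr <- function(x) ifelse(x == "NA", NA_character_, x)
  data.frame(family_id = g(1L), type = g(2L), methods = g(3L),
             superfamily_id = na_chr(g(4L)), outcome = g(5L),
             n_methods = as.integer(g(6L)), confidence = na_chr(g(7L)),
             same_fold = as.logical(na_chr(g(8L))),
             start = as.integer(na_chr(g(9L))),
             end = as.integer(na_chr(g(10L))),
             origin = g(11L), query_length = as.integer(g(12L)),
             stringsAsFactors = FALSE)
}

# -- targeted corruption -----------------------------------------------------

#' Perturb a generated bundle
#'
#' Applies a documented, targeted corruption to a fraction of families and
#' rewrites the bundle with an updated manifest reflecting the expected
#' downstream effect:
#'
#' * `flip_superfamily`: dissenting hits of families whose methods disagree
#'   are rewritten to the majority superfamily (ties: the first method's
#'   superfamily), turning conflicts into full agreement.
#' * `shrink_region`: hit regions are shortened to half the query length,
#'   so coverage-filtered methods (nrichd, supfam_plus) lose their hits.
#' * `inflate_evalue`: E-values of E-value-scored hits are set to 0.01, so
#'   nrichd, superfamily_db and hhsearch lose their hits.
#'
#' @param dir bundle directory produced by [generate_fixture()].
#' @param kind one of `"flip_superfamily"`, `"shrink_region"`,
#'   `"inflate_evalue"`.
#' @param fraction fraction of families to perturb (families are drawn
#'   deterministically from `seed`); 0 leaves the bundle unchanged.
#' @param seed integer driving the family draw.
#' @param outdir output bundle directory.
#' @return the updated manifest, invisibly.
#' @export
perturb_fixture <- function(dir, kind, fraction, seed, outdir) {
  kind <- match.arg(kind, c("flip_superfamily", "shrink_region",
                            "inflate_evalue"))
  stopifnot(fraction >= 0, fraction <= 1)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  manifest <- read_manifest(dir)
  catalog <- read_scop_catalog(file.path(dir, "scop_cla.tsv"))
  families <- read_family_table(file.path(dir, "families.tsv"))
  doms_by_sf <- split(catalog$domain_sid, catalog$superfamily_id)
  hits <- read_bundle_hits(dir, families, catalog)
  cand <- manifest$family_id[manifest$type != "background"]
  n_sel <- ceiling(fraction * length(cand))
  sel <- if (n_sel > 0L)
    with_stream(seed, paste0("perturb:", kind),
                sort(sample(cand, n_sel))) else character()

  for (m in FC_METHODS) {
    h <- hits[[m]]
    if (nrow(h) == 0L) next
    in_sel <- h$query_id %in% sel
    if (kind == "inflate_evalue" &&
        method_score_kind(m) == "evalue") {
      h$evalue[in_sel] <- 0.01
    } else if (kind == "shrink_region") {
      span <- pmax(1L, as.integer(floor(0.5 * h$query_length[in_sel])))
      h$end[in_sel] <- pmin(h$start[in_sel] + span - 1L,
                            h$query_length[in_sel])
    }
    hits[[m]] <- h
  }
  if (kind == "flip_superfamily") {
    for (f in sel) {
      sfm <- family_sf_map(hits, f)
      if (length(unique(sfm)) < 2L) next
      counts <- sort(table(sfm), decreasing = TRUE)
      maj <- names(counts)[1L]
      for (m in names(sfm)[sfm != maj]) {
        h <- hits[[m]]
        at <- h$query_id == f
        h$hit_id[at] <- doms_by_sf[[maj]][1L]
        h$sccs[at] <- catalog$sccs[match(h$hit_id[at], catalog$domain_sid)]
        h[at, c("class_id", "fold_id", "superfamily_id", "family_id")] <-
          sccs_fields(h$sccs[at])
        hits[[m]] <- h
      }
    }
  }

  # recompute the intended outcome of every family from the surviving,
  # filter-passing hits
  thr <- default_thresholds()
  for (i in seq_len(nrow(manifest))) {
    f <- manifest$family_id[i]
    if (manifest$type[i] == "background") next
    sfm <- character()
    for (m in FC_METHODS) {
      h <- hits[[m]]
      h <- h[h$query_id == f, , drop = FALSE]
      h <- h[passes_filter(h, thr), , drop = FALSE]
      if (nrow(h)) sfm[m] <- h$superfamily_id[1L]
    }
    if (manifest$origin[i] == "indirect") sfm["supfam_plus"] <-
      manifest$superfamily_id[i]
    out <- intended_outcome(sfm)
    manifest$methods[i] <- paste(sort(factor(names(sfm),
                                             levels = FC_METHODS)),
                                 collapse = ";")
    manifest$superfamily_id[i] <- out$superfamily_id
    manifest$outcome[i] <- out$outcome
    manifest$n_methods[i] <- out$n_methods
    manifest$confidence[i] <- out$confidence
    manifest$same_fold[i] <- out$same_fold
  }

  # rewrite hit files; copy everything else verbatim
  nr <- hits$nrichd
  by_pass <- nr$source_pass == "nrichd_hmmsearch"
  write_domtbl(nr[by_pass, , drop = FALSE],
               file.path(outdir, "nrichd_hmmsearch.domtbl"))
  write_domtbl(nr[!by_pass, , drop = FALSE],
               file.path(outdir, "nrichd_jackhmmer.domtbl"))
  write_domtbl(hits$superfamily_db, file.path(outdir, "superfamily.domtbl"))
  write_hhr(hits$hhsearch, file.path(outdir, "hhsearch.hhr"))
  write_score_table(hits$supfam_plus, file.path(outdir, "supfam_plus.tsv"))
  write_score_table(hits$pdomthreader, file.path(outdir, "pdomthreader.tsv"))
  for (f in c("scop_cla.tsv", "families.tsv", "links.tsv", "direct_map.tsv",
              "dcgo.tsv", "pdb_ec.tsv", "pdb_scop.tsv",
              "taxonomy_nodes.dmp", "taxonomy_names.dmp"))
    file.copy(file.path(dir, f), file.path(outdir, f), overwrite = TRUE)
  write_manifest(manifest, outdir)
  invisible(manifest)
}

# per-method hit tables of a bundle, as a named list
read_bundle_hits <- function(dir, families, catalog) {
  list(
    nrichd = pool_hits(
      read_domtbl(file.path(dir, "nrichd_hmmsearch.domtbl"), "nrichd",
                  families, catalog, source_pass = "nrichd_hmmsearch"),
      read_domtbl(file.path(dir, "nrichd_jackhmmer.domtbl"), "nrichd",
                  families, catalog, source_pass = "nrichd_jackhmmer")),
    supfam_plus = read_score_table(file.path(dir, "supfam_plus.tsv"),
                                   "supfam_plus", families, catalog),
    superfamily_db = read_domtbl(file.path(dir, "superfamily.domtbl"),
                                 "superfamily_db", families, catalog,
                                 source_pass = "hmmscan"),
    pdomthreader = read_score_table(file.path(dir, "pdomthreader.tsv"),
                                    "pdomthreader", families, catalog),
    hhsearch = read_hhr(file.path(dir, "hhsearch.hhr"), families, catalog))
}

family_sf_map <- function(hits, family_id) {
  sfm <- character()
  for (m in FC_METHODS) {
    h <- hits[[m]]
    at <- h$query_id == family_id
    if (any(at)) sfm[m] <- h$superfamily_id[at][1L]
  }
  sfm
}
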