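# End-to-end orchestration: read -> filter -> resolve -> indirect ->
# combine -> annotate -> tally, with per-stage logging and TSV/JSON outputs.

cfg_stop <- function(...) {
  stop(errorCondition(paste0(...), class = c("fc_config_error", "error")))
}

fc_log <- function(...) message("foldcons: ", ...)

#' Build a run configuration
#'
#' @param inputs named list of input hit files per method: `nrichd`,
#'   `superfamily_db` (character vectors of domtblout paths; several files
#'   per method are pooled), `hhsearch` (.hhr paths), `supfam_plus`,
#'   `pdomthreader` (score-table paths). Missing methods are simply absent
#'   from the run.
#' @param catalog path to the SCOP classification flat file.
#' @param families path to the family metadata table.
#' @param links,direct_map optional paths enabling indirect
#'   family-to-superfamily assignments for the supfam_plus method.
#' @param dcgo,pdb_ec,pdb_scop,tax_nodes,tax_names optional annotation
#'   table paths.
#' @param outdir output directory.
#' @param thresholds threshold list (see [default_thresholds()]); partial
#'   lists are completed with the defaults.
#' @return a `run_config` list.
#' @export
run_config <- function(inputs, catalog, families, links = NULL,
                       direct_map = NULL, dcgo = NULL, pdb_ec = NULL,
                       pdb_scop = NULL, tax_nodes = NULL, tax_names = NULL,
                       outdir, thresholds = list()) {
  thr <- utils::modifyList(default_thresholds(), thresholds)
  if (any(vapply(thr, function(x) !is.numeric(x) || x <= 0, NA)))
    cfg_stop("all thresholds must be positive numbers")
  if (thr$overlap > 1 || thr$coverage > 1 || thr$link_coverage > 1)
    cfg_stop("overlap and coverage thresholds must lie in (0, 1]")
  structure(list(inputs = inputs, catalog = catalog, families = families,
                 links = links, direct_map = direct_map, dcgo = dcgo,
                 pdb_ec = pdb_ec, pdb_scop = pdb_scop,
                 tax_nodes = tax_nodes, tax_names = tax_names,
                 outdir = outdir, thresholds = thr),
            class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Top-level keys mirror the arguments of [run_config()]; relative paths
#' are resolved against the YAML file's directory.
#'
#' @param path YAML file.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  fix <- function(p) {
    if (is.null(p)) return(NULL)
    vapply(p, function(x)
      if (grepl("^(/|[A-Za-z]:)", x)) x else file.path(base, x), "")
  }
  run_config(inputs = lapply(y$inputs, fix), catalog = fix(y$catalog),
             families = fix(y$families), links = fix(y$links),
             direct_map = fix(y$direct_map), dcgo = fix(y$dcgo),
             pdb_ec = fix(y$pdb_ec), pdb_scop = fix(y$pdb_scop),
             tax_nodes = fix(y$tax_nodes), tax_names = fix(y$tax_names),
             outdir = if (is.null(y$outdir)) file.path(base, "out")
                      else fix(y$outdir),
             thresholds = if (is.null(y$thresholds)) list() else y$thresholds)
}

#' Configuration for a generated bundle directory
#'
#' Maps the conventional file names written by [generate_fixture()] to a
#' [run_config()].
#'
#' @param dir bundle directory.
#' @param outdir output directory (default `file.path(dir, "out")`).
#' @param thresholds threshold overrides.
#' @return a `run_config`.
#' @export
bundle_config <- function(dir, outdir = file.path(dir, "out"),
                          thresholds = list()) {
  run_config(
    inputs = list(
      nrichd = file.path(dir, c("nrichd_hmmsearch.domtbl",
                                "nrichd_jackhmmer.domtbl")),
      superfamily_db = file.path(dir, "superfamily.domtbl"),
      hhsearch = file.path(dir, "hhsearch.hhr"),
      supfam_plus = file.path(dir, "supfam_plus.tsv"),
      pdomthreader = file.path(dir, "pdomthreader.tsv")),
    catalog = file.path(dir, "scop_cla.tsv"),
    families = file.path(dir, "families.tsv"),
    links = file.path(dir, "links.tsv"),
    direct_map = file.path(dir, "direct_map.tsv"),
    dcgo = file.path(dir, "dcgo.tsv"),
    pdb_ec = file.path(dir, "pdb_ec.tsv"),
    pdb_scop = file.path(dir, "pdb_scop.tsv"),
    tax_nodes = file.path(dir, "taxonomy_nodes.dmp"),
    tax_names = file.path(dir, "taxonomy_names.dmp"),
    outdir = outdir, thresholds = thresholds)
}

check_paths <- function(config) {
  paths <- c(unlist(config$inputs), config$catalog, config$families,
             config$links, config$direct_map, config$dcgo, config$pdb_ec,
             config$pdb_scop, config$tax_nodes, config$tax_names)
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    cfg_stop("missing input file(s): ", paste(missing, collapse = ", "))
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
}

#' Run the full consensus pipeline
#'
#' Stages: read the per-method hit files (pooling multiple passes of one
#' method), apply the acceptance filters, resolve per-method region
#' verdicts, add indirect supfam_plus assignments through family links,
#' combine methods into consensus/exclusion records, annotate, and tally.
#' Per-stage counts are logged to stderr; `assignments.tsv`,
#' `consensus.tsv`, `exclusions.tsv` and `summary.json` are written to the
#' configured output directory. Rerunning on identical inputs writes
#' identical outputs.
#'
#' @param config a `run_config`, a bundle directory, or a YAML path.
#' @return invisibly, a list: `records`, `exclusions`, `assignments`,
#'   `summary` (the [tally()]), `n_unmapped` per input file.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    config <- if (dir.exists(config)) bundle_config(config)
              else read_run_config(config)
  }
  stopifnot(inherits(config, "run_config"))
  check_paths(config)
  thr <- config$thresholds
  fc_log("thresholds: ", paste(names(thr), unlist(thr), sep = "=",
                               collapse = " "))
  catalog <- read_scop_catalog(config$catalog)
  families <- read_family_table(config$families)
  fc_log("read ", nrow(catalog), " catalog domains, ", nrow(families),
         " query families")

  unmapped <- integer()
  read_method <- function(m, paths) {
    bundles <- lapply(paths, function(p) {
      h <- switch(method_score_kind(m),
                  evalue = if (m == "hhsearch")
                             read_hhr(p, families, catalog)
                           else read_domtbl(p, m, families, catalog,
                                            source_pass =
                                              tools::file_path_sans_ext(basename(p))),
                  read_score_table(p, m, families, catalog))
      unmapped[basename(p)] <<- attr(h, "n_unmapped")
      h
    })
    pool_hits(bundles)
  }
  hits <- bind_hits(lapply(names(config$inputs), function(m)
    read_method(m, config$inputs[[m]])))
  fc_log("read ", nrow(hits), " hits (", sum(unmapped),
         " dropped as unmapped)")

  filtered <- filter_hits(hits, thr)
  fc_log(nrow(filtered), " hits pass the per-method filters")
  assignments <- resolve_assignments(filtered, thr)
  fc_log(sum(assignments$status == "assigned"), " region verdicts assigned, ",
         sum(assignments$status == "unresolved"), " unresolved")

  if (!is.null(config$links) && !is.null(config$direct_map)) {
    direct <- read_direct_map(config$direct_map)
    links <- read_links(config$links)
    ind <- derive_indirect(direct, links, thr$link_zscore, thr$link_coverage)
    ind <- ind[ind$family_id %in% families$family_id, , drop = FALSE]
    has_sp <- unique(assignments$query_id[
      assignments$method == "supfam_plus" & assignments$status == "assigned"])
    ind <- ind[!ind$family_id %in% has_sp, , drop = FALSE]
    if (nrow(ind)) {
      qlen <- families$query_length[match(ind$family_id, families$family_id)]
      n_via <- lengths(strsplit(ind$via, ";", fixed = TRUE))
      assignments <- rbind(assignments, assignment_row(
        ind$family_id, "supfam_plus", 1L, qlen, ind$superfamily_id,
        n_via, NA_real_, "assigned", ind$via, origin = "indirect"))
    }
    fc_log(nrow(ind), " indirect supfam_plus assignments added")
  }

  combined <- combine_assignments(assignments, thr$overlap)
  summary <- tally(combined)
  fc_log(summary$n_records, " consensus records for ", summary$n_families,
         " families (high ", summary$tier_counts$high, ", medium ",
         summary$tier_counts$medium, ", low ", summary$tier_counts$low,
         "); ", summary$n_excluded_regions, " ambiguous regions excluded")

  records <- combined$records
  records <- annotate_consensus(
    records, families,
    dcgo = if (!is.null(config$dcgo)) read_dcgo(config$dcgo),
    pdb_ec = if (!is.null(config$pdb_ec)) read_pdb_ec(config$pdb_ec),
    pdb_scop = if (!is.null(config$pdb_scop)) read_pdb_scop(config$pdb_scop),
    taxonomy = if (!is.null(config$tax_nodes) && !is.null(config$tax_names))
      read_taxonomy(config$tax_nodes, config$tax_names),
    ic_threshold = thr$ic)

  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  write_tsv(combined$assignments, file.path(config$outdir, "assignments.tsv"))
  write_tsv(records, file.path(config$outdir, "consensus.tsv"))
  write_tsv(combined$exclusions, file.path(config$outdir, "exclusions.tsv"))
  summary_out <- summary
  summary_out$unmapped_dropped <- sum(unmapped)
  jsonlite::write_json(summary_out, file.path(config$outdir, "summary.json"),
                       auto_unbox = TRUE, dataframe = "rows", na = "null",
                       digits = NA, pretty = TRUE)
  invisible(list(records = records, exclusions = combined$exclusions,
                 assignments = combined$assignments, summary = summary,
                 n_unmapped = unmapped))
}
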