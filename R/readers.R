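# Readers for the five methods' hit-file dialects and the run's flat tables.
#
# Readers are total and order-preserving on well-formed input and apply no
# score thresholds: the number of hits returned equals the number of data
# rows minus hits whose target is absent from the SCOP catalog (those are
# dropped and counted in the "n_unmapped" attribute, mirroring the exclusion
# of threading templates without a SCOP mapping).

#' Read the query-family metadata table
#'
#' Tab-delimited columns: family_id, query_length, clan_id (may be empty),
#' comma-separated member taxonomy ids (may be empty). Lines starting with
#' `#` are comments.
#'
#' @param path file path.
#' @return data.frame with columns `family_id`, `query_length`, `clan_id`
#'   and list-column `member_taxa` (integer vectors).
#' @export
read_family_table <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  if (length(lines) == 0L)
    return(data.frame(family_id = character(), query_length = integer(),
                      clan_id = character(),
                      member_taxa = I(list()), stringsAsFactors = FALSE))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  get <- function(i) vapply(parts, function(p)
    if (length(p) >= i) p[i] else "", "")
  qlen <- suppressWarnings(as.integer(get(2L)))
  if (anyNA(qlen) || any(qlen <= 0L))
    stop("family table '", path, "': non-positive or non-integer query_length at line ",
         which(is.na(qlen) | qlen <= 0L)[1L])
  fam <- data.frame(family_id = get(1L), query_length = qlen,
                    clan_id = get(3L), stringsAsFactors = FALSE)
  if (anyDuplicated(fam$family_id))
    stop("family table '", path, "': duplicated family_id '",
         fam$family_id[duplicated(fam$family_id)][1L], "'")
  taxa <- lapply(get(4L), function(s) {
    if (!nzchar(s)) return(integer())
    as.integer(strsplit(s, ",", fixed = TRUE)[[1L]])
  })
  fam$member_taxa <- I(taxa)
  fam
}

# Resolve hit target ids against the catalog; drop + count unmapped ones.
map_targets <- function(h_raw, catalog, path) {
  idx <- match(h_raw$hit_id, catalog$domain_sid)
  n_unmapped <- sum(is.na(idx))
  if (n_unmapped > 0L)
    message("foldcons: ", n_unmapped, " hit(s) in '", basename(path),
            "' dropped: target not in SCOP catalog")
  kept <- h_raw[!is.na(idx), , drop = FALSE]
  kept$sccs <- catalog$sccs[idx[!is.na(idx)]]
  kept
}

check_known_queries <- function(query_id, families, path) {
  unknown <- setdiff(unique(query_id), families$family_id)
  if (length(unknown))
    stop("'", path, "': unknown query id(s): ",
         paste(utils::head(unknown, 3L), collapse = ", "))
}

#' Read a HMMER3 per-domain tabular output file (domtblout)
#'
#' One `DomainHit` per domain line. The filtering score is the full-sequence
#' E-value column (not the per-domain conditional/independent E-values); the
#' query region is taken from the alignment coordinate columns; the query
#' length from the qlen column. Hits whose target identifier is not in the
#' SCOP catalog are dropped and counted (attribute `n_unmapped`).
#'
#' @param path domtblout file.
#' @param method `"nrichd"` or `"superfamily_db"` (both E-value scored).
#' @param families family table from [read_family_table()]; every query id
#'   in the file must resolve, otherwise an error is raised.
#' @param catalog `scop_catalog` used to resolve target lineages.
#' @param source_pass tag recorded per hit (e.g. `"hmmsearch"`,
#'   `"jackhmmer"`); defaults to the file name.
#' @return `domain_hits` table with attribute `n_unmapped`.
#' @export
read_domtbl <- function(path, method, families, catalog,
                        source_pass = basename(path)) {
  method <- match.arg(method, FC_METHODS)
  if (method_score_kind(method) != "evalue")
    stop("read_domtbl: method '", method, "' is not E-value scored")
  lines <- readLines(path)
  keep <- !startsWith(lines, "#") & nzchar(trimws(lines))
  data_lines <- which(keep)
  if (length(data_lines) == 0L) {
    out <- empty_hits()
    attr(out, "n_unmapped") <- 0L
    return(out)
  }
  parts <- strsplit(trimws(lines[data_lines]), "[[:space:]]+")
  nf <- lengths(parts)
  if (any(nf < 22L))
    stop("'", path, "': line ", data_lines[nf < 22L][1L],
         " has ", nf[nf < 22L][1L], " columns; domtblout needs at least 22")
  col <- function(i) vapply(parts, `[`, "", i)
  num <- function(i, what) {
    x <- suppressWarnings(as.numeric(col(i)))
    if (anyNA(x))
      stop("'", path, "': unparseable ", what, " at line ",
           data_lines[is.na(x)][1L])
    x
  }
  raw <- data.frame(hit_id = col(1L), query_id = col(4L),
                    query_length = as.integer(num(6L, "qlen")),
                    evalue = num(7L, "full-sequence E-value"),
                    start = as.integer(num(18L, "ali from")),
                    end = as.integer(num(19L, "ali to")),
                    stringsAsFactors = FALSE)
  check_known_queries(raw$query_id, families, path)
  raw <- map_targets(raw, catalog, path)
  out <- domain_hits(query_id = raw$query_id, method = method,
                     hit_id = raw$hit_id, sccs = raw$sccs,
                     start = raw$start, end = raw$end,
                     query_length = raw$query_length,
                     evalue = raw$evalue, source_pass = source_pass)
  attr(out, "n_unmapped") <- length(data_lines) - nrow(out)
  out
}

#' Read an HHsearch result file (.hhr)
#'
#' Parses the summary table of one or more query blocks (a block starts at a
#' `Query` header line); one hit per summary row, in file order. The E-value
#' column is the score; the query region comes from the Query-HMM column.
#' Alignment blocks after the summary are ignored. Hits are taken per row,
#' not best-per-template.
#'
#' @param path .hhr file (may concatenate several query blocks).
#' @param families family table; resolves query lengths.
#' @param catalog `scop_catalog`; unmapped targets dropped and counted.
#' @return `domain_hits` table (method `"hhsearch"`) with attribute
#'   `n_unmapped`.
#' @export
read_hhr <- function(path, families, catalog) {
  lines <- readLines(path)
  q_starts <- which(startsWith(lines, "Query "))
  rows <- list(); n_rows <- 0L
  for (qi in seq_along(q_starts)) {
    block <- lines[q_starts[qi]:(if (qi < length(q_starts))
      q_starts[qi + 1L] - 1L else length(lines))]
    query_id <- strsplit(trimws(sub("^Query", "", block[1L])),
                         "[[:space:]]+")[[1L]][1L]
    hdr <- grep("^ *No Hit", block)
    if (length(hdr) == 0L)
      stop("'", path, "': query block '", query_id,
           "' has no summary table header")
    i <- hdr[1L] + 1L
    while (i <= length(block) && nzchar(trimws(block[i])) &&
           !startsWith(block[i], "No ")) {
      tok <- strsplit(trimws(block[i]), "[[:space:]]+")[[1L]]
      # from the right: (tlen) template-HMM query-HMM cols SS score pval eval prob
      if (length(tok) < 11L)
        stop("'", path, "': truncated summary row at block '", query_id,
             "' line ", i)
      nt <- length(tok)
      qcols <- tok[nt - 2L]
      ev <- suppressWarnings(as.numeric(tok[nt - 7L]))
      se <- suppressWarnings(as.integer(strsplit(qcols, "-", fixed = TRUE)[[1L]]))
      if (is.na(ev) || length(se) != 2L || anyNA(se))
        stop("'", path, "': unparseable summary row at block '", query_id,
             "' line ", i)
      rows[[n_rows <- n_rows + 1L]] <-
        list(query_id = query_id, hit_id = tok[2L], evalue = ev,
             start = se[1L], end = se[2L])
      i <- i + 1L
    }
  }
  if (n_rows == 0L) {
    out <- empty_hits()
    attr(out, "n_unmapped") <- 0L
    return(out)
  }
  raw <- data.frame(query_id = vapply(rows, `[[`, "", "query_id"),
                    hit_id = vapply(rows, `[[`, "", "hit_id"),
                    evalue = vapply(rows, `[[`, 0, "evalue"),
                    start = vapply(rows, `[[`, 0L, "start"),
                    end = vapply(rows, `[[`, 0L, "end"),
                    stringsAsFactors = FALSE)
  check_known_queries(raw$query_id, families, path)
  raw$query_length <-
    families$query_length[match(raw$query_id, families$family_id)]
  raw <- map_targets(raw, catalog, path)
  out <- domain_hits(query_id = raw$query_id, method = "hhsearch",
                     hit_id = raw$hit_id, sccs = raw$sccs,
                     start = raw$start, end = raw$end,
                     query_length = raw$query_length,
                     evalue = raw$evalue, source_pass = "hhsearch")
  attr(out, "n_unmapped") <- n_rows - nrow(out)
  out
}

#' Read a tab-delimited score table (profile-profile or threading hits)
#'
#' Columns: query_id, hit_id, score, qstart, qend, and (optional) a
#' confidence tag. The score is a Z-score for `supfam_plus` and a P-value
#' for `pdomthreader`; the tag (e.g. `CERTAIN`) is retained in
#' `source_pass`.
#'
#' @param path TSV file; `#`-lines are comments.
#' @param method `"supfam_plus"` or `"pdomthreader"`.
#' @param families family table; resolves query lengths.
#' @param catalog `scop_catalog`; unmapped targets dropped and counted.
#' @return `domain_hits` table with attribute `n_unmapped`.
#' @export
read_score_table <- function(path, method, families, catalog) {
  method <- match.arg(method, c("supfam_plus", "pdomthreader"))
  lines <- readLines(path)
  keep <- !startsWith(lines, "#") & nzchar(trimws(lines))
  data_lines <- which(keep)
  if (length(data_lines) == 0L) {
    out <- empty_hits()
    attr(out, "n_unmapped") <- 0L
    return(out)
  }
  parts <- strsplit(lines[data_lines], "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 5L))
    stop("'", path, "': row at line ", data_lines[nf < 5L][1L],
         " has ", nf[nf < 5L][1L], " columns; need query, hit, score, qstart, qend")
  col <- function(i) vapply(parts, `[`, "", i)
  num <- function(i, what) {
    x <- suppressWarnings(as.numeric(col(i)))
    if (anyNA(x))
      stop("'", path, "': non-numeric ", what, " at line ",
           data_lines[is.na(x)][1L])
    x
  }
  raw <- data.frame(query_id = col(1L), hit_id = col(2L),
                    score = num(3L, "score"),
                    start = as.integer(num(4L, "qstart")),
                    end = as.integer(num(5L, "qend")),
                    tag = vapply(parts, function(p)
                      if (length(p) >= 6L) p[6L] else "", ""),
                    stringsAsFactors = FALSE)
  check_known_queries(raw$query_id, families, path)
  raw$query_length <-
    families$query_length[match(raw$query_id, families$family_id)]
  raw <- map_targets(raw, catalog, path)
  out <- domain_hits(query_id = raw$query_id, method = method,
                     hit_id = raw$hit_id, sccs = raw$sccs,
                     start = raw$start, end = raw$end,
                     query_length = raw$query_length,
                     zscore = if (method == "supfam_plus") raw$score else NA_real_,
                     pvalue = if (method == "pdomthreader") raw$score else NA_real_,
                     source_pass = raw$tag)
  attr(out, "n_unmapped") <- length(data_lines) - nrow(out)
  out
}

#' Read a family-family link table
#'
#' TSV columns: family_a, family_b, zscore, coverage_a, coverage_b. Links are
#' undirected; each row is stored once and treated symmetrically.
#'
#' @param path TSV file.
#' @return data.frame with those five columns.
#' @export
read_links <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  if (length(lines) == 0L)
    return(data.frame(family_a = character(), family_b = character(),
                      zscore = numeric(), coverage_a = numeric(),
                      coverage_b = numeric(), stringsAsFactors = FALSE))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 5L))
    stop("link table '", path, "': row with fewer than 5 columns")
  out <- data.frame(
    family_a = vapply(parts, `[`, "", 1L),
    family_b = vapply(parts, `[`, "", 2L),
    zscore = as.numeric(vapply(parts, `[`, "", 3L)),
    coverage_a = as.numeric(vapply(parts, `[`, "", 4L)),
    coverage_b = as.numeric(vapply(parts, `[`, "", 5L)),
    stringsAsFactors = FALSE)
  if (anyNA(out$zscore) || anyNA(out$coverage_a) || anyNA(out$coverage_b))
    stop("link table '", path, "': non-numeric score or coverage")
  if (any(out$coverage_a < 0 | out$coverage_a > 1 |
          out$coverage_b < 0 | out$coverage_b > 1))
    stop("link table '", path, "': coverages must lie in [0, 1]")
  out
}

#' Read a direct family-to-superfamily mapping table
#'
#' TSV columns: family_id, superfamily_id (dotted `x.N.M` code).
#'
#' @param path TSV file.
#' @return data.frame with columns `family_id`, `superfamily_id`.
#' @export
read_direct_map <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  if (length(lines) == 0L)
    return(data.frame(family_id = character(), superfamily_id = character(),
                      stringsAsFactors = FALSE))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 2L))
    stop("direct-mapping table '", path, "': row with fewer than 2 columns")
  data.frame(family_id = vapply(parts, `[`, "", 1L),
             superfamily_id = vapply(parts, `[`, "", 2L),
             stringsAsFactors = FALSE)
}
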