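# GO, EC and taxonomic-kingdom annotation of consensus assignments.

#' Read a domain-centric GO flat table
#'
#' TSV columns: superfamily_id, go_id, namespace (molecular_function /
#' biological_process / cellular_component), information_content.
#'
#' @param path TSV file.
#' @return data.frame with those four columns.
#' @export
read_dcgo <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  if (length(lines) == 0L)
    return(data.frame(superfamily_id = character(), go_id = character(),
                      namespace = character(),
                      information_content = numeric(),
                      stringsAsFactors = FALSE))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 4L))
    stop("dcGO table '", path, "': row with fewer than 4 columns")
  ic <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 4L)))
  if (anyNA(ic) || any(!is.finite(ic)))
    stop("dcGO table '", path, "': non-finite information content")
  ns <- vapply(parts, `[`, "", 3L)
  bad <- !ns %in% c("molecular_function", "biological_process",
                    "cellular_component")
  if (any(bad))
    stop("dcGO table '", path, "': unknown namespace '", ns[bad][1L], "'")
  data.frame(superfamily_id = vapply(parts, `[`, "", 1L),
             go_id = vapply(parts, `[`, "", 2L),
             namespace = ns, information_content = ic,
             stringsAsFactors = FALSE)
}

#' GO terms transferred to a superfamily
#'
#' Keeps terms whose information content reaches the threshold (boundary
#' inclusive; the default keeps only informative terms, IC >= 1.5), sorted
#' by decreasing information content.
#'
#' @param sf superfamily identifier.
#' @param dcgo table from [read_dcgo()].
#' @param ic_threshold minimum information content (default 1.5).
#' @return subset of `dcgo` for `sf`; empty for an unknown superfamily.
#' @export
go_for_superfamily <- function(sf, dcgo, ic_threshold = 1.5) {
  out <- dcgo[dcgo$superfamily_id == sf &
              dcgo$information_content >= ic_threshold, , drop = FALSE]
  out <- out[order(-out$information_content, out$go_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a PDB-chain to EC table
#'
#' TSV columns: pdb_chain, ec_number (partial EC codes allowed, e.g.
#' `"3.2.1.-"`; the top-level class must be 1..7).
#'
#' @param path TSV file.
#' @return data.frame with columns `pdb_chain`, `ec_number`.
#' @export
read_pdb_ec <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  if (length(lines) == 0L)
    return(data.frame(pdb_chain = character(), ec_number = character(),
                      stringsAsFactors = FALSE))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 2L))
    stop("PDB-EC table '", path, "': row with fewer than 2 columns")
  ec <- vapply(parts, `[`, "", 2L)
  bad <- !grepl("^[1-7](\\.([0-9]+|-)){0,3}$", ec)
  if (any(bad))
    stop("PDB-EC table '", path, "': malformed EC number '", ec[bad][1L], "'")
  data.frame(pdb_chain = vapply(parts, `[`, "", 1L), ec_number = ec,
             stringsAsFactors = FALSE)
}

#' Read a PDB-chain to SCOP domain table
#'
#' TSV columns: pdb_chain, domain_sid, sccs. A chain may carry several
#' domains (one row each).
#'
#' @param path TSV file.
#' @return data.frame with columns `pdb_chain`, `domain_sid`, `sccs`,
#'   `superfamily_id`.
#' @export
read_pdb_scop <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  if (length(lines) == 0L)
    return(data.frame(pdb_chain = character(), domain_sid = character(),
                      sccs = character(), superfamily_id = character(),
                      stringsAsFactors = FALSE))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 3L))
    stop("PDB-SCOP table '", path, "': row with fewer than 3 columns")
  out <- data.frame(pdb_chain = vapply(parts, `[`, "", 1L),
                    domain_sid = vapply(parts, `[`, "", 2L),
                    sccs = vapply(parts, `[`, "", 3L),
                    stringsAsFactors = FALSE)
  out$superfamily_id <- sccs_fields(out$sccs)$superfamily_id
  out
}

#' Candidate EC numbers for a superfamily
#'
#' EC numbers are transferred only from PDB chains that carry exactly one
#' SCOP domain, and only when that domain's superfamily is `sf`; chains
#' with several domains contribute nothing because the enzyme activity
#' cannot be attributed to one domain. Results are deduplicated and sorted.
#'
#' @param sf superfamily identifier.
#' @param pdb_ec table from [read_pdb_ec()].
#' @param pdb_scop table from [read_pdb_scop()].
#' @return character vector of EC numbers (possibly empty).
#' @export
ec_for_superfamily <- function(sf, pdb_ec, pdb_scop) {
  dom_per_chain <- table(pdb_scop$pdb_chain)
  single <- pdb_scop[pdb_scop$pdb_chain %in%
                       names(dom_per_chain)[dom_per_chain == 1L] &
                     pdb_scop$superfamily_id == sf, , drop = FALSE]
  sort(unique(pdb_ec$ec_number[pdb_ec$pdb_chain %in% single$pdb_chain]))
}

#' Read a taxonomy from nodes/names dump files
#'
#' Dialect of the NCBI taxonomy dumps: fields separated by `\\t|\\t`, lines
#' terminated by `\\t|`. Nodes: taxid, parent taxid, rank. Names: taxid,
#' name (only `scientific name` rows are kept when a fourth name-class
#' field is present). The taxonomy must have a single root (its own parent)
#' and an acyclic parent chain; a cycle is an error at load time.
#'
#' @param nodes_path,names_path dump files.
#' @return data.frame with columns `taxid`, `parent_taxid`, `rank`, `name`.
#' @export
read_taxonomy <- function(nodes_path, names_path) {
  parse_dump <- function(path) {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    lines <- sub("\t\\|$", "", lines)
    strsplit(lines, "\t|\t", fixed = TRUE)
  }
  np <- parse_dump(nodes_path)
  nodes <- data.frame(
    taxid = as.integer(vapply(np, `[`, "", 1L)),
    parent_taxid = as.integer(vapply(np, `[`, "", 2L)),
    rank = vapply(np, `[`, "", 3L), stringsAsFactors = FALSE)
  if (anyNA(nodes$taxid) || anyNA(nodes$parent_taxid))
    stop("taxonomy nodes '", nodes_path, "': non-integer taxid")
  if (anyDuplicated(nodes$taxid))
    stop("taxonomy nodes '", nodes_path, "': duplicated taxid")
  mp <- parse_dump(names_path)
  keep <- vapply(mp, function(p)
    length(p) < 4L || p[4L] == "scientific name", NA)
  nm <- data.frame(taxid = as.integer(vapply(mp[keep], `[`, "", 1L)),
                   name = vapply(mp[keep], `[`, "", 2L),
                   stringsAsFactors = FALSE)
  nodes$name <- nm$name[match(nodes$taxid, nm$taxid)]
  roots <- nodes$taxid[nodes$taxid == nodes$parent_taxid]
  if (length(roots) != 1L)
    stop("taxonomy must have exactly one root node (found ",
         length(roots), ")")
  # acyclic check: every node must reach the root within n steps
  parent_of <- stats::setNames(nodes$parent_taxid, nodes$taxid)
  n <- nrow(nodes)
  for (t in nodes$taxid) {
    cur <- t
    for (step in seq_len(n + 1L)) {
      if (cur == roots) break
      cur <- parent_of[[as.character(cur)]]
      if (is.null(cur) || step > n)
        stop("taxonomy parent chain is cyclic or broken at taxid ", t)
    }
  }
  nodes
}

KINGDOMS <- c("Archaea", "Bacteria", "Eukaryota", "Viruses")

#' Kingdoms represented among a family's members
#'
#' Each member taxid is climbed to its superkingdom-rank ancestor (the four
#' labels Archaea, Bacteria, Eukaryota, Viruses); the family's kingdom set
#' is the union over members. Taxids absent from the taxonomy are skipped
#' and counted in the `n_skipped` attribute.
#'
#' @param taxids integer vector of member taxonomy ids.
#' @param taxonomy data.frame from [read_taxonomy()].
#' @return sorted character vector of kingdom names with attribute
#'   `n_skipped`.
#' @export
kingdoms_for_family <- function(taxids, taxonomy) {
  skipped <- 0L
  kingdoms <- character()
  for (t in taxids) {
    i <- match(t, taxonomy$taxid)
    if (is.na(i)) { skipped <- skipped + 1L; next }
    repeat {
      if (taxonomy$rank[i] == "superkingdom") {
        kingdoms <- c(kingdoms, taxonomy$name[i]); break
      }
      if (taxonomy$taxid[i] == taxonomy$parent_taxid[i]) break
      i <- match(taxonomy$parent_taxid[i], taxonomy$taxid)
      if (is.na(i)) { skipped <- skipped + 1L; break }
    }
  }
  out <- sort(unique(kingdoms))
  attr(out, "n_skipped") <- skipped
  out
}

#' Annotate consensus records with GO, EC and kingdom information
#'
#' @param records consensus records from [combine_assignments()].
#' @param families family table (for member taxids).
#' @param dcgo,pdb_ec,pdb_scop,taxonomy annotation tables (any may be
#'   `NULL` to skip that annotation).
#' @param ic_threshold GO information-content cutoff (default 1.5).
#' @return `records` with added character columns `go_ids`, `ec_numbers`,
#'   `kingdoms` (semicolon-joined; empty string when no annotation).
#' @export
annotate_consensus <- function(records, families, dcgo = NULL,
                               pdb_ec = NULL, pdb_scop = NULL,
                               taxonomy = NULL, ic_threshold = 1.5) {
  n <- nrow(records)
  records$go_ids <- rep("", n)
  records$ec_numbers <- rep("", n)
  records$kingdoms <- rep("", n)
  if (n == 0L) return(records)
  if (!is.null(dcgo))
    records$go_ids <- vapply(records$superfamily_id, function(sf)
      paste(go_for_superfamily(sf, dcgo, ic_threshold)$go_id,
            collapse = ";"), "")
  if (!is.null(pdb_ec) && !is.null(pdb_scop))
    records$ec_numbers <- vapply(records$superfamily_id, function(sf)
      paste(ec_for_superfamily(sf, pdb_ec, pdb_scop), collapse = ";"), "")
  if (!is.null(taxonomy)) {
    taxa <- families$member_taxa[match(records$query_id, families$family_id)]
    records$kingdoms <- vapply(taxa, function(t)
      paste(kingdoms_for_family(t, taxonomy), collapse = ";"), "")
  }
  records
}
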