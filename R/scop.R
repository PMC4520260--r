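# SCOP hierarchy: sccs identifiers, lineage comparison, domain catalog.

#' Relations two SCOP lineages can stand in
#'
#' Ordered from finest to coarsest shared level.
#' @export
SCOP_RELATIONS <- c("same_superfamily", "same_fold_diff_superfamily",
                    "same_class_diff_fold", "diff_class")

sccs_regex <- "^[A-Za-z]\\.[1-9][0-9]*\\.[1-9][0-9]*(\\.[1-9][0-9]*)?$"

#' Parse a SCOP concise classification string
#'
#' An sccs code such as `"a.1.1.1"` encodes the SCOP hierarchy
#' class > fold > superfamily > family as dot-separated fields; the family
#' field may be absent when a hit is resolved only to superfamily level.
#'
#' @param code character scalar, e.g. `"a.1.1.1"` or `"b.1.1"`.
#' @return An object of class `scop_lineage` with elements `class_id`,
#'   `fold_id`, `superfamily_id` and `family_id` (`NA` when absent). Each
#'   level's identifier is a prefix-extension of the level above, so equality
#'   tests at any level are plain string comparisons.
#' @examples
#' parse_sccs("a.1.1.1")
#' parse_sccs("b.1.1")$family_id  # NA
#' @export
parse_sccs <- function(code) {
  if (!is.character(code) || length(code) != 1L || is.na(code))
    stop("sccs code must be a single character string")
  fields <- strsplit(code, ".", fixed = TRUE)[[1L]]
  if (!(length(fields) %in% c(3L, 4L)))
    stop("malformed sccs '", code, "': expected 3 or 4 dot-separated fields, got ",
         length(fields))
  if (!grepl("^[A-Za-z]$", fields[1L]))
    stop("malformed sccs '", code, "': class field '", fields[1L],
         "' must be a single alphabetic character")
  for (i in 2:length(fields)) {
    if (!grepl("^[1-9][0-9]*$", fields[i]))
      stop("malformed sccs '", code, "': field '", fields[i],
           "' (position ", i, ") is not a positive integer")
  }
  structure(
    list(class_id       = fields[1L],
         fold_id        = paste(fields[1:2], collapse = "."),
         superfamily_id = paste(fields[1:3], collapse = "."),
         family_id      = if (length(fields) == 4L)
                            paste(fields, collapse = ".") else NA_character_),
    class = "scop_lineage")
}

#' @export
format.scop_lineage <- function(x, ...) {
  if (is.na(x$family_id)) x$superfamily_id else x$family_id
}

#' @export
as.character.scop_lineage <- function(x, ...) format(x)

#' @export
print.scop_lineage <- function(x, ...) {
  cat("<scop_lineage> ", format(x),
      "  (class ", x$class_id,
      ", fold ", x$fold_id,
      ", superfamily ", x$superfamily_id,
      if (!is.na(x$family_id)) paste0(", family ", x$family_id) else "",
      ")\n", sep = "")
  invisible(x)
}

as_lineage <- function(x) {
  if (inherits(x, "scop_lineage")) return(x)
  parse_sccs(x)
}

#' Split a vector of sccs codes into hierarchy-level columns
#'
#' Vectorised companion of [parse_sccs()] used by the file readers.
#'
#' @param codes character vector of sccs codes (3 or 4 fields each).
#' @return data.frame with columns `class_id`, `fold_id`, `superfamily_id`,
#'   `family_id` (`NA` for 3-field codes), one row per input code.
#' @export
sccs_fields <- function(codes) {
  if (length(codes) == 0L)
    return(data.frame(class_id = character(), fold_id = character(),
                      superfamily_id = character(), family_id = character(),
                      stringsAsFactors = FALSE))
  bad <- !grepl(sccs_regex, codes)
  if (any(bad))
    stop("malformed sccs code(s): ",
         paste(utils::head(unique(codes[bad]), 3L), collapse = ", "))
  parts <- strsplit(codes, ".", fixed = TRUE)
  data.frame(
    class_id       = vapply(parts, `[`, "", 1L),
    fold_id        = vapply(parts, function(p) paste(p[1:2], collapse = "."), ""),
    superfamily_id = vapply(parts, function(p) paste(p[1:3], collapse = "."), ""),
    family_id      = vapply(parts, function(p)
                       if (length(p) == 4L) paste(p, collapse = ".") else NA_character_, ""),
    stringsAsFactors = FALSE)
}

#' Finest shared level of two SCOP lineages
#'
#' @param a,b `scop_lineage` objects or sccs strings.
#' @return One of `"same_superfamily"`, `"same_fold_diff_superfamily"`,
#'   `"same_class_diff_fold"`, `"diff_class"`. Symmetric in its arguments.
#' @examples
#' lineage_relation("a.1.1.1", "a.1.2.1")  # same_fold_diff_superfamily
#' @export
lineage_relation <- function(a, b) {
  a <- as_lineage(a); b <- as_lineage(b)
  if (identical(a$superfamily_id, b$superfamily_id)) "same_superfamily"
  else if (identical(a$fold_id, b$fold_id))          "same_fold_diff_superfamily"
  else if (identical(a$class_id, b$class_id))        "same_class_diff_fold"
  else                                               "diff_class"
}

# Fold / class of a dotted superfamily identifier ("a.1.1" -> "a.1" -> "a").
sf_fold  <- function(sf) sub("\\.[0-9]+$", "", sf)
sf_class <- function(sf) sub("\\..*$", "", sf)

#' Read a SCOP classification flat file
#'
#' Tab-delimited dir.cla-style dialect: columns
#' (domain_sid, pdb_id, chain:range, sccs); lines starting with `#` are
#' comments.
#'
#' @param path file path.
#' @return data.frame of class `scop_catalog` with columns `domain_sid`,
#'   `pdb_id`, `chain_region`, `sccs` plus the split hierarchy columns from
#'   [sccs_fields()]. Domain identifiers are unique.
#' @export
read_scop_catalog <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    cat0 <- data.frame(domain_sid = character(), pdb_id = character(),
                       chain_region = character(), sccs = character(),
                       stringsAsFactors = FALSE)
    cat0 <- cbind(cat0, sccs_fields(character()))
    class(cat0) <- c("scop_catalog", "data.frame")
    return(cat0)
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 4L))
    stop("SCOP catalog '", path, "': line ", which(nf < 4L)[1L],
         " has fewer than 4 tab-separated columns")
  out <- data.frame(
    domain_sid   = vapply(parts, `[`, "", 1L),
    pdb_id       = vapply(parts, `[`, "", 2L),
    chain_region = vapply(parts, `[`, "", 3L),
    sccs         = vapply(parts, `[`, "", 4L),
    stringsAsFactors = FALSE)
  if (anyDuplicated(out$domain_sid))
    stop("SCOP catalog '", path, "': duplicated domain identifier '",
         out$domain_sid[duplicated(out$domain_sid)][1L], "'")
  out <- cbind(out, sccs_fields(out$sccs))
  class(out) <- c("scop_catalog", "data.frame")
  out
}

#' Look up the SCOP lineage of a structural domain
#'
#' Unmapped identifiers are an expected outcome, not an error: the readers
#' drop such hits upstream and report how many were dropped.
#'
#' @param catalog a `scop_catalog` from [read_scop_catalog()].
#' @param domain_id domain identifier (e.g. a 7-character sid or PDB chain).
#' @return A `scop_lineage`, or `NULL` when the identifier is not in the
#'   catalog.
#' @export
lookup_lineage <- function(catalog, domain_id) {
  i <- match(domain_id, catalog$domain_sid)
  if (is.na(i)) return(NULL)
  parse_sccs(catalog$sccs[i])
}
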