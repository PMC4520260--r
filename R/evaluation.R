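# Benchmark predicted fold assignments against families of known structure.

#' Score one predicted lineage against a known one
#'
#' Correctness is judged at SCOP fold level: a prediction in the same fold
#' as the known structure is correct even when the superfamilies differ.
#'
#' @param prediction,truth `scop_lineage` objects or sccs strings.
#' @return `"correct"` or `"wrong"`.
#' @export
score_fold <- function(prediction, truth) {
  p <- as_lineage(prediction); t <- as_lineage(truth)
  if (identical(p$fold_id, t$fold_id)) "correct" else "wrong"
}

#' Evaluate fold predictions against a reference set
#'
#' Three statistics: success rate = TP / N_total x 100,
#' precision = TP / (TP + FP) x 100, error rate = FP / (TP + FP) x 100,
#' where TP counts correct fold assignments, FP wrong ones, and N_total all
#' reference queries. Queries without a prediction are misses: they lower
#' the success rate but not the precision. A reference family mapping to
#' several SCOP folds (multi-domain structures) counts a prediction correct
#' when it matches any of them. With no predictions at all, precision and
#' error rate are undefined (`NA`), not zero.
#'
#' @param predictions data.frame with columns `family_id`, `sccs` (at most
#'   one row per family); a prediction for a family absent from `truth` is
#'   an error.
#' @param truth data.frame with columns `family_id`, `sccs`; several rows
#'   per family allowed.
#' @return list of class `fold_eval`: `tp`, `fp`, `n_total`,
#'   `success_rate`, `precision`, `error_rate` (percentages; the latter two
#'   `NA` when tp + fp = 0), `n_unpredicted`.
#' @export
evaluate_predictions <- function(predictions, truth) {
  if (nrow(truth) > 0 && anyNA(truth$sccs)) stop("truth sccs must not be NA")
  truth_fold <- sf_fold(sccs_fields(truth$sccs)$superfamily_id)
  folds_by_family <- split(truth_fold, truth$family_id)
  n_total <- length(folds_by_family)
  if (anyDuplicated(predictions$family_id))
    stop("duplicated prediction for family ",
         predictions$family_id[duplicated(predictions$family_id)][1L])
  unknown <- setdiff(predictions$family_id, names(folds_by_family))
  if (length(unknown))
    stop("prediction for famil(ies) absent from the reference set: ",
         paste(utils::head(unknown, 3L), collapse = ", "))
  tp <- 0L; fp <- 0L
  if (nrow(predictions)) {
    pred_fold <- sf_fold(sccs_fields(predictions$sccs)$superfamily_id)
    for (i in seq_len(nrow(predictions))) {
      if (pred_fold[i] %in% folds_by_family[[predictions$family_id[i]]])
        tp <- tp + 1L else fp <- fp + 1L
    }
  }
  res <- list(tp = tp, fp = fp, n_total = n_total,
              success_rate = if (n_total > 0) 100 * tp / n_total else NA_real_,
              precision = if (tp + fp > 0) 100 * tp / (tp + fp) else NA_real_,
              error_rate = if (tp + fp > 0) 100 * fp / (tp + fp) else NA_real_,
              n_unpredicted = n_total - nrow(predictions))
  class(res) <- "fold_eval"
  res
}

#' @export
print.fold_eval <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "N/A" else sprintf("%.1f", v)
  cat(sprintf("TP %d  FP %d  N %d  |  success %s  precision %s  error %s\n",
              x$tp, x$fp, x$n_total, fmt(x$success_rate),
              fmt(x$precision), fmt(x$error_rate)))
  invisible(x)
}

#' Evaluate prediction and reference TSV files
#'
#' Predictions: TSV (family_id, sccs); reference: TSV (family_id, sccs,
#' sccs, ...) with one or more known lineages per row.
#'
#' @param predictions_path,truth_path file paths.
#' @return a `fold_eval` (see [evaluate_predictions()]).
#' @export
evaluate_files <- function(predictions_path, truth_path) {
  read2 <- function(path, multi) {
    lines <- readLines(path)
    lines <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
    if (length(lines) == 0L)
      return(data.frame(family_id = character(), sccs = character(),
                        stringsAsFactors = FALSE))
    parts <- strsplit(lines, "\t", fixed = TRUE)
    if (any(lengths(parts) < 2L))
      stop("'", path, "': row with fewer than 2 columns")
    if (!multi)
      return(data.frame(family_id = vapply(parts, `[`, "", 1L),
                        sccs = vapply(parts, `[`, "", 2L),
                        stringsAsFactors = FALSE))
    do.call(rbind, lapply(parts, function(p)
      data.frame(family_id = p[1L], sccs = p[-1L], stringsAsFactors = FALSE)))
  }
  evaluate_predictions(read2(predictions_path, multi = FALSE),
                       read2(truth_path, multi = TRUE))
}
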