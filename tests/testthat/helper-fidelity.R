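# Compare a pipeline result against a bundle's ground-truth manifest.
# Returns the family ids whose consensus outcome deviates from the intent.
manifest_mismatches <- function(res, manifest) {
  bad <- character()
  for (i in seq_len(nrow(manifest))) {
    f <- manifest$family_id[i]
    r <- res$records[res$records$query_id == f, , drop = FALSE]
    x <- res$exclusions[res$exclusions$query_id == f, , drop = FALSE]
    ok <- switch(manifest$outcome[i],
      consensus = nrow(r) == 1L && nrow(x) == 0L &&
        r$superfamily_id == manifest$superfamily_id[i] &&
        r$n_methods == manifest$n_methods[i] &&
        r$confidence == manifest$confidence[i],
      excluded = nrow(r) == 0L && nrow(x) == 1L &&
        x$same_fold == manifest$same_fold[i],
      none = nrow(r) == 0L && nrow(x) == 0L)
    if (!isTRUE(ok)) bad <- c(bad, f)
  }
  bad
}

run_bundle <- function(dir) {
  suppressMessages(run_pipeline(bundle_config(dir)))
}

bundle_checksums <- function(dir) {
  files <- sort(list.files(dir, recursive = TRUE, full.names = TRUE))
  files <- files[!dir.exists(files)]
  stats::setNames(tools::md5sum(files), sub(paste0("^", dir, "/?"), "", files))
}
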