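#' On-disk store archives (snapshots)
#'
#' External releases of a connectome are static, versioned snapshots.
#' An archive directory holds the exported raw bundle plus a
#' `meta.json` recording the dataset name, version, site totals, the
#' promotion predicate in force, and the last applied edit sequence.
#' Loading an archive re-ingests the bundle, rebuilds every aggregate,
#' and re-applies the recorded predicate, reproducing the archived
#' store exactly. Multiple datasets live in separate archives selected
#' by path (the moral equivalent of per-dataset node-label prefixes).
#'
#' @param store a consistent [graph_store].
#' @param path archive directory.
#' @return `path` (write) / the restored store (load).
#' @export
write_store_archive <- function(store, path) {
  export_bundle(store, path)
  pred <- store$predicate
  meta <- list(
    dataset = store$dataset,
    version = store$meta$version,
    total_pre = store$meta$total_pre,
    total_post = store$meta$total_post,
    last_sequence = store$meta$last_sequence,
    predicate = if (is.null(pred)) NULL else list(
      min_size = if (is.finite(pred$min_size)) pred$min_size else NULL,
      min_pre = if (is.finite(pred$min_pre)) pred$min_pre else NULL,
      min_post = if (is.finite(pred$min_post)) pred$min_post else NULL,
      status_qualifies = pred$status_qualifies
    )
  )
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_store_archive
#' @export
load_store_archive <- function(path) {
  meta_path <- file.path(path, "meta.json")
  if (!file.exists(meta_path))
    cg_stop("cg_not_found", "'%s' is not a store archive (no meta.json)", path)
  meta <- jsonlite::fromJSON(meta_path, simplifyVector = TRUE)
  # an archive always carries both membership sources (boxes + explicit
  # table), so the explicit-table-precedence warning is expected here
  bundle <- suppressWarnings(load_bundle(path))
  store <- suppressWarnings(
    build_aggregates(bundle, dataset = meta$dataset, version = meta$version))
  if (!is.null(meta$predicate)) {
    pr <- meta$predicate
    val <- function(v) if (is.null(v)) Inf else v
    store <- promote_neurons(store, promotion_predicate(
      min_size = val(pr$min_size), min_pre = val(pr$min_pre),
      min_post = val(pr$min_post),
      status_qualifies = isTRUE(pr$status_qualifies)))
  }
  store$meta$last_sequence <- if (is.null(meta$last_sequence)) 0L
                              else as.integer(meta$last_sequence)
  store
}
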