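#' Incremental maintenance from reconstruction edit events
#'
#' Proofreading continuously merges and splits bodies. Rather than
#' rebuilding the store from raw data after every edit, these operations
#' apply each event *incrementally*: only the aggregates touching the
#' affected bodies (site counts, per-ROI tallies, connections and their
#' ROI breakdowns) are recomputed; everything else is untouched. The
#' result is always field-for-field identical to a full rebuild from the
#' correspondingly edited raw data -- the module's defining property.
#'
#' Events are consumed from a JSON-lines log (one object per line) with
#' strictly increasing `sequence` numbers:
#' \preformatted{
#' {"action":"merge","sequence":1,"target":200,"source":300}
#' {"action":"split","sequence":2,"body":200,"new_body":400,
#'  "moved_site_ids":[8],"new_size":10000}
#' {"action":"set_property","sequence":3,"body":400,"key":"status",
#'  "value":"Traced"}
#' }
#'
#' @name update_log
NULL

# Recompute counts, seg_roi, connections, and conn_roi rows touching any
# body in `bodies`; all other rows are preserved verbatim.
recompute_for_bodies <- function(store, bodies) {
  s <- store$sites
  cnt <- s[body_id %in% bodies, .N, by = .(body_id, kind)]
  for (b in bodies) {
    if (!b %in% store$segments$body_id) next
    npre <- cnt[body_id == b & kind == "pre", sum(N)]
    npost <- cnt[body_id == b & kind == "post", sum(N)]
    store$segments[J(b), on = "body_id",
                   `:=`(pre_count = as.integer(npre),
                        post_count = as.integer(npost))]
  }

  seg_tal <- s[body_id %in% bodies][store$site_rois, on = "site_id",
                                    nomatch = NULL, allow.cartesian = TRUE]
  seg_new <- if (nrow(seg_tal) > 0L) {
    wide <- dcast(seg_tal[, .N, by = .(body_id, roi, kind)],
                  body_id + roi ~ kind, value.var = "N", fill = 0L)
    for (col in c("pre", "post"))
      if (!col %in% names(wide)) wide[, (col) := 0L]
    wide[, .(body_id, roi, pre = as.integer(pre), post = as.integer(post))]
  } else data.table(body_id = numeric(), roi = character(),
                    pre = integer(), post = integer())
  store$seg_roi <- rbind(store$seg_roi[!body_id %in% bodies], seg_new)
  setkey(store$seg_roi, body_id, roi)

  # connections touching the bodies
  lf <- link_frame(store)
  touched <- lf[pre_body %in% bodies | post_body %in% bodies]
  conn_new <- touched[, .(weight = .N), by = .(pre_body, post_body)]
  store$connections <- rbind(
    store$connections[!(pre_body %in% bodies | post_body %in% bodies)],
    conn_new)
  setkey(store$connections, pre_body, post_body)

  post_tal <- touched[store$site_rois, on = c(post_site = "site_id"),
                      nomatch = NULL, allow.cartesian = TRUE][
    , .(post = .N), by = .(pre_body, post_body, roi)]
  pre_tal <- unique(touched[, .(pre_body, post_body, pre_site)])[
    store$site_rois, on = c(pre_site = "site_id"),
    nomatch = NULL, allow.cartesian = TRUE][
    , .(pre = .N), by = .(pre_body, post_body, roi)]
  cr_new <- merge(pre_tal, post_tal, by = c("pre_body", "post_body", "roi"),
                  all = TRUE)
  for (col in c("pre", "post"))
    set(cr_new, which(is.na(cr_new[[col]])), col, 0L)
  cr_new <- cr_new[, .(pre_body, post_body, roi,
                       pre = as.integer(pre), post = as.integer(post))]
  store$conn_roi <- rbind(
    store$conn_roi[!(pre_body %in% bodies | post_body %in% bodies)],
    cr_new)
  setkey(store$conn_roi, pre_body, post_body, roi)

  store$meta$last_modified <- Sys.time()
  store
}

#' Merge one body into another
#'
#' All of the source's sites become the target's, sizes add, the source
#' disappears, and every affected aggregate is updated incrementally.
#' Links between the two former bodies become autapse contributions on
#' the target (autapses are stored like any other connection). The
#' target keeps its properties and its neuron flag (merging only adds
#' material, so designation is monotone); batch application re-evaluates
#' flags at the end.
#'
#' @param store a [graph_store].
#' @param target,source distinct existing body ids.
#' @return the updated store.
#' @export
apply_merge <- function(store, target, source) {
  require_body(store, target, "target body")
  require_body(store, source, "source body")
  if (target == source)
    cg_stop("cg_input_error", "cannot merge a body into itself")

  store$segments <- copy(store$segments)
  store$sites <- copy(store$sites)
  src_size <- store$segments[J(source), on = "body_id", size]
  store$segments[J(target), on = "body_id", size := size + src_size]
  store$segments <- store$segments[body_id != source]
  setkey(store$segments, body_id)
  store$sites[body_id == source, body_id := target]
  recompute_for_bodies(store, c(target, source))
}

#' Split sites off a body into a new one
#'
#' The moved sites are re-owned by `new_body`, created with no instance,
#' type, or status and `new_size` voxels (transferred from the original
#' body; raw site coordinates do not carry volume, so the caller states
#' the split's size). Splitting off nothing just creates an empty body.
#'
#' @param store a [graph_store].
#' @param body existing body id.
#' @param new_body unused body id for the split-off part.
#' @param moved_site_ids sites currently owned by `body` to move.
#' @param new_size voxel count transferred to the new body (default 0).
#' @return the updated store.
#' @export
apply_split <- function(store, body, new_body, moved_site_ids,
                        new_size = 0) {
  require_body(store, body)
  if (new_body %in% store$segments$body_id)
    cg_stop("cg_input_error", "new body id %s already exists",
            format(new_body, scientific = FALSE))
  moved_site_ids <- as.integer(moved_site_ids)
  owner <- store$sites[J(moved_site_ids), on = "site_id", body_id]
  if (anyNA(owner) || any(owner != body))
    cg_stop("cg_input_error",
            "moved sites must all be owned by body %s at split time",
            format(body, scientific = FALSE))
  old_size <- store$segments[J(body), on = "body_id", size]
  if (new_size < 0 || new_size > old_size)
    cg_stop("cg_input_error", "new_size must be between 0 and the body's size")

  store$segments <- copy(store$segments)
  store$sites <- copy(store$sites)
  store$segments[J(body), on = "body_id", size := size - new_size]
  store$segments <- rbind(store$segments, data.table(
    body_id = as.numeric(new_body), instance = NA_character_,
    type = NA_character_, status = NA_character_, size = as.numeric(new_size),
    pre_count = 0L, post_count = 0L, is_neuron = FALSE))
  setkey(store$segments, body_id)
  if (length(moved_site_ids))
    store$sites[J(moved_site_ids), on = "site_id", body_id := as.numeric(new_body)]
  recompute_for_bodies(store, c(body, new_body))
}

#' Change a body's annotation
#'
#' Only the free-form annotation keys may be edited this way:
#' `instance`, `type`, or `status`. `NA` (JSON `null`) clears the value.
#'
#' @param store a [graph_store].
#' @param body existing body id.
#' @param key one of `"instance"`, `"type"`, `"status"`.
#' @param value character or `NA`.
#' @return the updated store.
#' @export
apply_set_property <- function(store, body, key, value) {
  require_body(store, body)
  if (!key %in% c("instance", "type", "status"))
    cg_stop("cg_input_error",
            "set_property key must be instance, type, or status (got '%s')", key)
  if (is.null(value) || length(value) == 0L) value <- NA_character_
  store$segments <- copy(store$segments)
  store$segments[J(as.numeric(body)), on = "body_id",
                 (key) := as.character(value)]
  store$meta$last_modified <- Sys.time()
  store
}

#' Read / write a JSON-lines edit log
#'
#' @param path file path.
#' @return `read_edit_log`: a list of event lists, in file order.
#' @export
read_edit_log <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  lapply(lines, function(l) jsonlite::fromJSON(l, simplifyVector = TRUE))
}

#' @rdname read_edit_log
#' @param events list of event lists (each with `action`, `sequence`, and
#'   the action's fields).
#' @export
write_edit_log <- function(events, path) {
  lines <- vapply(events, function(e)
    as.character(jsonlite::toJSON(e, auto_unbox = TRUE, null = "null", digits = NA)),
    "")
  writeLines(lines, path)
  invisible(path)
}

apply_one_event <- function(store, e) {
  action <- e$action
  if (is.null(action))
    cg_stop("cg_input_error", "edit event has no action")
  switch(action,
    merge = apply_merge(store, e$target, e$source),
    split = apply_split(store, e$body, e$new_body,
                        moved_site_ids = unlist(e$moved_site_ids),
                        new_size = if (is.null(e$new_size)) 0 else e$new_size),
    set_property = apply_set_property(store, e$body, e$key, e$value),
    cg_stop("cg_input_error", "unknown edit action '%s'", action)
  )
}

#' Apply an ordered edit log to a store
#'
#' Folds the per-event operations over the store. Sequence numbers must
#' be strictly increasing within the log; events whose sequence number
#' has already been applied to this store are skipped with a warning
#' (idempotence guard). If an event fails, application stops with a
#' `cg_log_error` whose `data` field carries the store as of the last
#' successfully applied event and that event's sequence number -- never a
#' silently partial result. After the batch, neuron designation is
#' re-evaluated under the store's recorded promotion predicate
#' (snapshot-style consistency: per batch, not per event).
#'
#' @param store a [graph_store].
#' @param events list of events, e.g. from [read_edit_log()].
#' @return the updated store.
#' @export
apply_edit_log <- function(store, events) {
  if (length(events) == 0L) return(store)
  seqs <- vapply(events, function(e)
    if (is.null(e$sequence)) NA_real_ else as.numeric(e$sequence), 0)
  if (anyNA(seqs))
    cg_stop("cg_input_error", "every edit event needs a sequence number")
  if (any(diff(seqs) <= 0))
    cg_stop("cg_input_error",
            "edit log sequence numbers must be strictly increasing")

  last_ok <- store$meta$last_sequence
  for (i in seq_along(events)) {
    e <- events[[i]]
    if (seqs[i] <= store$meta$last_sequence) {
      warning(sprintf("event with sequence %s already applied; skipping",
                      format(seqs[i])), call. = FALSE)
      next
    }
    store <- tryCatch(apply_one_event(store, e), cg_error = function(err) {
      cg_stop("cg_log_error",
              "edit log failed at sequence %s (%s); last applied sequence: %s",
              format(seqs[i]), conditionMessage(err), format(last_ok),
              data = list(store = store, last_sequence = last_ok))
    })
    store$meta$last_sequence <- seqs[i]
    last_ok <- seqs[i]
  }
  if (!is.null(store$predicate))
    store <- promote_neurons(store, store$predicate)
  store
}
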