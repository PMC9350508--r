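#' Assemble and validate a raw connectome bundle
#'
#' A raw bundle is the exchange form of a connectome: four tables plus an
#' ROI hierarchy, mirroring the CSV-first ingestion path of large
#' reconstruction pipelines.
#'
#' * `bodies`: `body_id, instance, type, status, size` (empty string =
#'   absent optional value)
#' * `sites`: `site_id, body_id, kind, x, y, z, confidence`, `kind` in
#'   `{pre, post}`
#' * `links`: `pre_site_id, post_site_id`, one row per pre-to-post pairing
#'   (a pre site may drive many post sites -- polyadic synapses -- but each
#'   post site has at most one pre partner)
#' * `rois`: an [roi_spec()]
#' * `site_rois` (optional): explicit leaf memberships `site_id, roi_name`
#'
#' Every referential-integrity violation is reported with its data row
#' number (1-based, header excluded).
#'
#' @param bodies,sites,links data.frames per the schemas above.
#' @param rois an [roi_spec()] (or data.frame coercible to one).
#' @param site_rois optional explicit membership table.
#' @param skeletons optional named list of [read_swc()] skeletons keyed by
#'   body id.
#' @return an object of class `raw_bundle`.
#' @export
raw_bundle <- function(bodies, sites, links, rois, site_rois = NULL,
                       skeletons = NULL) {
  bodies <- copy(as.data.table(bodies)); sites <- copy(as.data.table(sites))
  links <- copy(as.data.table(links))
  if (!inherits(rois, "roi_spec")) rois <- roi_spec(rois)
  problems <- character()
  need <- function(dt, cols, label) {
    miss <- setdiff(cols, names(dt))
    if (length(miss))
      problems <<- c(problems, sprintf("%s: missing column(s) %s", label,
                                       paste(miss, collapse = ", ")))
    length(miss) == 0L
  }

  if (need(bodies, c("body_id", "instance", "type", "status", "size"), "bodies")) {
    bodies[, body_id := as.numeric(body_id)]
    bodies[, size := as.numeric(size)]
    for (col in c("instance", "type", "status")) {
      v <- as.character(bodies[[col]])
      v[!is.na(v) & v == ""] <- NA_character_
      bodies[, (col) := v]
    }
    dup <- which(duplicated(bodies$body_id))
    if (length(dup))
      problems <- c(problems, sprintf("bodies row %d: duplicate body_id %s",
                                      dup[1], bodies$body_id[dup[1]]))
  }
  if (need(sites, c("site_id", "body_id", "kind", "x", "y", "z", "confidence"),
           "synapses")) {
    sites[, site_id := as.integer(site_id)]
    sites[, body_id := as.numeric(body_id)]
    sites[, kind := as.character(kind)]
    for (col in c("x", "y", "z")) sites[, (col) := as.integer(get(col))]
    sites[, confidence := as.numeric(confidence)]
    dup <- which(duplicated(sites$site_id))
    if (length(dup))
      problems <- c(problems, sprintf("synapses row %d: duplicate site_id %d",
                                      dup[1], sites$site_id[dup[1]]))
    badk <- which(!sites$kind %in% c("pre", "post"))
    for (i in head(badk, 3L))
      problems <- c(problems, sprintf("synapses row %d: kind must be pre/post", i))
    badc <- which(is.na(sites$confidence) | sites$confidence < 0 | sites$confidence > 1)
    for (i in head(badc, 3L))
      problems <- c(problems, sprintf("synapses row %d: confidence outside [0,1]", i))
    if ("body_id" %in% names(bodies)) {
      orphan <- which(!sites$body_id %in% bodies$body_id)
      for (i in head(orphan, 3L))
        problems <- c(problems, sprintf(
          "synapses row %d: unknown body %s", i,
          format(sites$body_id[i], scientific = FALSE)))
    }
  }
  if (need(links, c("pre_site_id", "post_site_id"), "links")) {
    links <- links[, .(pre_site = as.integer(pre_site_id),
                       post_site = as.integer(post_site_id))]
    if ("site_id" %in% names(sites)) {
      pre_kind <- sites$kind[match(links$pre_site, sites$site_id)]
      post_kind <- sites$kind[match(links$post_site, sites$site_id)]
      for (i in head(which(is.na(pre_kind)), 3L))
        problems <- c(problems, sprintf("links row %d: unknown site %d", i, links$pre_site[i]))
      for (i in head(which(!is.na(pre_kind) & pre_kind != "pre"), 3L))
        problems <- c(problems, sprintf("links row %d: site %d is not a pre site", i, links$pre_site[i]))
      for (i in head(which(is.na(post_kind)), 3L))
        problems <- c(problems, sprintf("links row %d: unknown site %d", i, links$post_site[i]))
      for (i in head(which(!is.na(post_kind) & post_kind != "post"), 3L))
        problems <- c(problems, sprintf("links row %d: site %d is not a post site", i, links$post_site[i]))
      dup <- which(duplicated(links$post_site))
      if (length(dup))
        problems <- c(problems, sprintf(
          "links row %d: post site %d already has a pre partner",
          dup[1], links$post_site[dup[1]]))
    }
  } else {
    links <- data.table(pre_site = integer(), post_site = integer())
  }
  if (!is.null(site_rois)) {
    site_rois <- as.data.table(site_rois)
    if (need(site_rois, c("site_id", "roi_name"), "synapse_rois")) {
      site_rois[, site_id := as.integer(site_id)]
      site_rois[, roi_name := as.character(roi_name)]
      bad <- which(!site_rois$roi_name %in% rois$name)
      for (i in head(bad, 3L))
        problems <- c(problems, sprintf("synapse_rois row %d: unknown ROI '%s'",
                                        i, site_rois$roi_name[i]))
      if ("site_id" %in% names(sites)) {
        bad <- which(!site_rois$site_id %in% sites$site_id)
        for (i in head(bad, 3L))
          problems <- c(problems, sprintf("synapse_rois row %d: unknown site %d",
                                          i, site_rois$site_id[i]))
      }
    }
  }
  if (length(problems))
    cg_stop("cg_ingest_error", "raw bundle failed validation:\n%s",
            paste(head(problems, 20L), collapse = "\n"))

  structure(list(bodies = bodies[], sites = sites[], links = links[],
                 rois = rois, site_rois = site_rois,
                 skeletons = skeletons),
            class = "raw_bundle")
}

#' @export
print.raw_bundle <- function(x, ...) {
  cat(sprintf("<raw_bundle> %d bodies, %d sites, %d links, %d ROIs%s\n",
              nrow(x$bodies), nrow(x$sites), nrow(x$links), nrow(x$rois),
              if (is.null(x$skeletons)) "" else
                sprintf(", %d skeletons", length(x$skeletons))))
  invisible(x)
}

#' Load a raw bundle from disk
#'
#' Reads `bodies.csv`, `synapses.csv`, `links.csv`, `rois.json`, and, when
#' present, `synapse_rois.csv` and a `skeletons/` directory of
#' `<body_id>.swc` files, from a bundle directory. CSV files are RFC-4180
#' comma-separated UTF-8 with a header row.
#'
#' @param path directory containing the bundle files.
#' @return a validated [raw_bundle()].
#' @export
load_bundle <- function(path) {
  if (!dir.exists(path))
    cg_stop("cg_ingest_error", "bundle directory '%s' does not exist", path)
  fp <- function(f) file.path(path, f)
  for (f in c("bodies.csv", "synapses.csv", "links.csv", "rois.json"))
    if (!file.exists(fp(f)))
      cg_stop("cg_ingest_error", "bundle is missing %s", f)
  read_csv <- function(f, coltypes)
    fread(fp(f), colClasses = coltypes, na.strings = NULL, sep = ",",
          header = TRUE, encoding = "UTF-8")
  bodies <- read_csv("bodies.csv",
                     list(numeric = c("body_id", "size"),
                          character = c("instance", "type", "status")))
  sites <- read_csv("synapses.csv",
                    list(integer = c("site_id", "x", "y", "z"),
                         numeric = c("body_id", "confidence"),
                         character = "kind"))
  links <- read_csv("links.csv",
                    list(integer = c("pre_site_id", "post_site_id")))
  rois <- read_rois_json(fp("rois.json"))
  site_rois <- if (file.exists(fp("synapse_rois.csv")))
    read_csv("synapse_rois.csv",
             list(integer = "site_id", character = "roi_name")) else NULL

  skeletons <- NULL
  skel_dir <- fp("skeletons")
  if (dir.exists(skel_dir)) {
    files <- list.files(skel_dir, pattern = "\\.swc$", full.names = TRUE)
    skeletons <- lapply(files, function(f)
      read_swc(f, body_id = as.integer(sub("\\.swc$", "", basename(f)))))
    names(skeletons) <- sub("\\.swc$", "", basename(files))
  }
  raw_bundle(bodies, sites, links, rois, site_rois, skeletons)
}

# Recompute every redundant aggregate from primary state. Used by
# build_aggregates, store_check, and the incremental-update repair path.
derive_aggregates <- function(bodies, sites, links, site_rois) {
  counts <- if (nrow(sites) > 0L)
    dcast(sites[, .N, by = .(body_id, kind)], body_id ~ kind,
          value.var = "N", fill = 0L) else data.table(body_id = numeric())
  for (col in c("pre", "post")) if (!col %in% names(counts)) counts[, (col) := 0L]
  counts <- counts[, .(body_id, pre_count = as.integer(pre),
                       post_count = as.integer(post))]
  counts <- merge(data.table(body_id = bodies$body_id), counts,
                  by = "body_id", all.x = TRUE)
  for (col in c("pre_count", "post_count"))
    set(counts, which(is.na(counts[[col]])), col, 0L)
  setkey(counts, body_id)

  lf <- copy(links)
  if (nrow(lf) > 0L) {
    lf[sites, on = c(pre_site = "site_id"), pre_body := i.body_id]
    lf[sites, on = c(post_site = "site_id"), post_body := i.body_id]
  } else {
    lf[, `:=`(pre_body = numeric(), post_body = numeric())]
  }
  connections <- lf[, .(weight = .N), by = .(pre_body, post_body)]
  setkey(connections, pre_body, post_body)

  # connection ROI tallies: post by post-site location, pre by distinct
  # participating pre sites, both ancestor-inclusive
  post_tal <- lf[site_rois, on = c(post_site = "site_id"), nomatch = NULL,
                 allow.cartesian = TRUE][, .(post = .N), by = .(pre_body, post_body, roi)]
  pre_sites <- unique(lf[, .(pre_body, post_body, pre_site)])
  pre_tal <- pre_sites[site_rois, on = c(pre_site = "site_id"), nomatch = NULL,
                       allow.cartesian = TRUE][, .(pre = .N), by = .(pre_body, post_body, roi)]
  conn_roi <- merge(pre_tal, post_tal, by = c("pre_body", "post_body", "roi"),
                    all = TRUE)
  for (col in c("pre", "post"))
    set(conn_roi, which(is.na(conn_roi[[col]])), col, 0L)
  conn_roi <- conn_roi[, .(pre_body, post_body, roi,
                           pre = as.integer(pre), post = as.integer(post))]
  setkey(conn_roi, pre_body, post_body, roi)

  seg_tal <- sites[site_rois, on = "site_id", nomatch = NULL,
                   allow.cartesian = TRUE][, .N, by = .(body_id, roi, kind)]
  seg_roi <- if (nrow(seg_tal) > 0L)
    dcast(seg_tal, body_id + roi ~ kind, value.var = "N", fill = 0L)
  else data.table(body_id = numeric(), roi = character())
  for (col in c("pre", "post"))
    if (!col %in% names(seg_roi)) seg_roi[, (col) := 0L]
  seg_roi <- seg_roi[, .(body_id, roi, pre = as.integer(pre),
                         post = as.integer(post))]
  setkey(seg_roi, body_id, roi)

  list(counts = counts, connections = connections, conn_roi = conn_roi,
       seg_roi = seg_roi,
       total_pre = sum(sites$kind == "pre"),
       total_post = sum(sites$kind == "post"))
}

#' Build a consistent graph store from a raw bundle
#'
#' Materializes the redundant representation that the query suite relies
#' on: per-pair connection weights, connection- and segment-level per-ROI
#' synapse tallies (ancestor ROIs included), per-body site counts, and
#' store-wide totals, all derived from the bundle's sites and links.
#' Building is idempotent: rebuilding from the same bundle yields an
#' identical store. Bodies start out undesignated; call
#' [promote_neurons()] to mark neurons.
#'
#' @param bundle a [raw_bundle()].
#' @param dataset dataset name (plays the role of a node-label prefix
#'   when several datasets coexist as separate stores).
#' @param version snapshot version string.
#' @return a consistent [graph_store].
#' @export
build_aggregates <- function(bundle, dataset = "default", version = "1.0") {
  sites <- copy(bundle$sites)
  setkey(sites, site_id)
  site_rois <- assign_rois(sites, bundle$rois, bundle$site_rois)
  d <- derive_aggregates(bundle$bodies, sites, bundle$links, site_rois)

  segments <- copy(bundle$bodies)
  segments <- segments[d$counts, on = "body_id"]
  segments[, is_neuron := FALSE]
  setcolorder(segments, c("body_id", "instance", "type", "status", "size",
                          "pre_count", "post_count", "is_neuron"))
  setkey(segments, body_id)

  meta <- list(dataset = dataset, version = version,
               total_pre = d$total_pre, total_post = d$total_post,
               last_modified = Sys.time(), last_sequence = 0L)
  new_graph_store(dataset, segments, sites, site_rois, copy(bundle$links),
                  d$connections, d$conn_roi, d$seg_roi, bundle$rois, meta)
}

#' Neuron promotion predicates
#'
#' Automatic segmentation leaves a bimodal population: a few large bodies
#' that are real neurons and a long tail of tiny fragments. A promotion
#' predicate designates the large bodies as neurons -- the default scope of
#' every query. The predicate is a *disjunction*: a body is promoted when
#' its size, pre-site count, or post-site count reaches the corresponding
#' threshold, or (when `status_qualifies`) when it carries any
#' reconstruction status. Each disjunct is monotone, so adding synapses or
#' volume to a body can never demote it under a fixed predicate.
#'
#' The default (`size >= 1e7` voxels, `pre >= 2`, `post >= 10`, or any
#' status) cleanly separates the two modes of the synthetic worlds and is
#' deliberately permissive on the size axis.
#'
#' @param min_size,min_pre,min_post thresholds; `Inf` disables a disjunct.
#' @param status_qualifies should a present status alone promote a body?
#' @return an object of class `promotion_predicate`.
#' @export
promotion_predicate <- function(min_size = Inf, min_pre = Inf, min_post = Inf,
                                status_qualifies = FALSE) {
  structure(list(min_size = min_size, min_pre = min_pre, min_post = min_post,
                 status_qualifies = isTRUE(status_qualifies)),
            class = "promotion_predicate")
}

#' @rdname promotion_predicate
#' @export
default_promotion_predicate <- function() {
  promotion_predicate(min_size = 1e7, min_pre = 2, min_post = 10,
                      status_qualifies = TRUE)
}

predicate_holds <- function(pred, segments) {
  segments$size >= pred$min_size |
    segments$pre_count >= pred$min_pre |
    segments$post_count >= pred$min_post |
    (pred$status_qualifies & !is.na(segments$status) & segments$status != "")
}

#' Designate neurons
#'
#' Sets the neuron flag on exactly the segments satisfying the predicate
#' and records the predicate on the store (incremental updates re-apply it
#' after each edit batch). The number of designated neurons is
#' `sum(store$segments$is_neuron)` on the returned store.
#'
#' @param store a [graph_store].
#' @param predicate a [promotion_predicate()].
#' @return the updated store.
#' @export
promote_neurons <- function(store, predicate = default_promotion_predicate()) {
  store$segments <- copy(store$segments)
  store$segments[, is_neuron := predicate_holds(predicate, store$segments)]
  store$predicate <- predicate
  store$meta$last_modified <- Sys.time()
  store
}

#' Export a store as a raw bundle directory
#'
#' Writes the five exchange files (`bodies.csv`, `synapses.csv`,
#' `links.csv`, `rois.json`, `synapse_rois.csv` with the leaf
#' memberships), plus a derived `connections.csv` in which each
#' connection's per-ROI tallies are serialized as a JSON string -- the
#' on-disk encoding of the `roiInfo` aggregate. Reloading the directory
#' with [load_bundle()] and rebuilding with [build_aggregates()]
#' reproduces the store exactly; the derived file is informational and is
#' not re-ingested.
#'
#' @param store a [graph_store].
#' @param path output directory (created if needed).
#' @return `path`, invisibly.
#' @export
export_bundle <- function(store, path) {
  ok <- dir.exists(path) || dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!ok || file.access(path, 2L) != 0L)
    cg_stop("cg_io_error", "cannot write to '%s'", path)
  out <- function(f) file.path(path, f)

  bodies <- store$segments[, .(body_id = format(body_id, scientific = FALSE, trim = TRUE),
                               instance, type, status,
                               size = format(size, scientific = FALSE, trim = TRUE))]
  fwrite(bodies, out("bodies.csv"), na = "", quote = "auto")
  fwrite(store$sites[order(site_id),
                     .(site_id, body_id = format(body_id, scientific = FALSE, trim = TRUE),
                       kind, x, y, z, confidence)],
         out("synapses.csv"), na = "", quote = "auto")
  fwrite(store$links[order(pre_site, post_site),
                     .(pre_site_id = pre_site, post_site_id = post_site)],
         out("links.csv"), na = "", quote = "auto")
  write_rois_json(store$rois, out("rois.json"))

  leaves <- roi_leaves(store$rois)
  leafm <- store$site_rois[roi %in% leaves][order(site_id, roi)]
  fwrite(leafm[, .(site_id, roi_name = roi)], out("synapse_rois.csv"),
         na = "", quote = "auto")

  conns <- store$connections[order(pre_body, post_body)]
  roi_json <- vapply(seq_len(nrow(conns)), function(i) {
    tal <- store$conn_roi[J(conns$pre_body[i], conns$post_body[i]),
                          on = c("pre_body", "post_body"), nomatch = NULL]
    as.character(jsonlite::toJSON(roi_info_list(tal), auto_unbox = TRUE))
  }, "")
  fwrite(data.table(pre_body = format(conns$pre_body, scientific = FALSE, trim = TRUE),
                    post_body = format(conns$post_body, scientific = FALSE, trim = TRUE),
                    weight = conns$weight, roi_info = roi_json),
         out("connections.csv"), quote = TRUE)
  invisible(path)
}
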