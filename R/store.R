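#' The connectome graph store
#'
#' A `graph_store` is an in-memory property graph for one connectome
#' dataset. It holds the raw reconstruction state -- segments (bodies),
#' synaptic sites, and the pre-to-post links between sites -- together with
#' the *redundant* aggregates that make the common circuit queries cheap:
#'
#' * `connections`: one row per ordered body pair with at least one link;
#'   `weight` is the number of pre-to-post links between the pair
#'   (equivalently, the number of the target's postsynaptic densities
#'   driven by the source, since each post site has at most one
#'   presynaptic partner).
#' * `conn_roi`: the per-ROI breakdown of each connection. `post` counts
#'   the connection's post sites inside the ROI; `pre` counts the distinct
#'   participating pre sites inside it. Ancestor ROIs are included, so the
#'   conservation law (tallies sum to the weight) holds over leaf ROIs.
#' * `seg_roi`: per-body, per-ROI pre/post site tallies (ancestors
#'   included; all-zero rows absent).
#' * per-body `pre_count` / `post_count` and store-wide meta totals.
#' * a uniform spatial grid over site coordinates for box queries.
#'
#' Stores are ordinary R values: operations that modify a store return the
#' updated copy, so any store a caller holds is a consistent snapshot
#' (single-writer semantics). Use [build_aggregates()] to create one from a
#' raw bundle, and [store_check()] to verify every aggregate invariant.
#'
#' @name graph_store
NULL

new_graph_store <- function(dataset, segments, sites, site_rois, links,
                            connections, conn_roi, seg_roi, rois, meta,
                            predicate = NULL, extra_nodes = list()) {
  store <- list(
    dataset = dataset, segments = segments, sites = sites,
    site_rois = site_rois, links = links, connections = connections,
    conn_roi = conn_roi, seg_roi = seg_roi, rois = rois, meta = meta,
    predicate = predicate, extra_nodes = extra_nodes,
    grid = build_site_grid(sites)
  )
  class(store) <- "graph_store"
  store
}

GRID_CELL <- 128L

build_site_grid <- function(sites) {
  g <- sites[, .(site_id, cx = x %/% GRID_CELL, cy = y %/% GRID_CELL,
                 cz = z %/% GRID_CELL)]
  setkey(g, cx, cy, cz)
  g
}

#' @export
print.graph_store <- function(x, ...) {
  cat(sprintf(paste0(
    "<graph_store '%s' v%s>\n",
    "  %d segments (%d designated neurons)\n",
    "  %d synaptic sites (%d pre, %d post), %d links\n",
    "  %d connections, %d ROIs\n"),
    x$dataset, x$meta$version,
    nrow(x$segments), sum(x$segments$is_neuron),
    nrow(x$sites), x$meta$total_pre, x$meta$total_post, nrow(x$links),
    nrow(x$connections), nrow(x$rois)))
  invisible(x)
}

require_body <- function(store, body_id, what = "body") {
  if (!is.numeric(body_id) || length(body_id) != 1L || is.na(body_id))
    cg_stop("cg_input_error", "%s id must be a single number", what)
  if (!body_id %in% store$segments$body_id)
    cg_stop("cg_not_found", "%s %s not found in dataset '%s'",
            what, format(body_id, scientific = FALSE), store$dataset)
  invisible(TRUE)
}

require_roi <- function(store, roi) {
  if (!roi %in% store$rois$name)
    cg_stop("cg_input_error", "unknown ROI '%s'", roi)
  invisible(TRUE)
}

# named list  roi -> list(pre=, post=)  from a long tally table
roi_info_list <- function(tally) {
  if (nrow(tally) == 0L) return(structure(list(), names = character()))
  tally <- tally[order(roi)]
  out <- lapply(seq_len(nrow(tally)), function(i)
    list(pre = tally$pre[i], post = tally$post[i]))
  names(out) <- tally$roi
  out
}

#' Fetch one segment record
#'
#' @param store a [graph_store].
#' @param body_id numeric body id.
#' @return a list with the segment's properties (`body_id`, `instance`,
#'   `type`, `status`, `size`, `pre_count`, `post_count`, `is_neuron`) and
#'   `roi_info`, a named list `roi -> list(pre, post)` of its synapse
#'   tallies per region.
#' @export
get_body <- function(store, body_id) {
  require_body(store, body_id)
  bid <- as.numeric(body_id)
  row <- store$segments[J(bid), on = "body_id"]
  rec <- as.list(row)
  rec$dataset <- store$dataset
  rec$roi_info <- roi_info_list(store$seg_roi[J(bid), on = "body_id", nomatch = NULL])
  rec
}

#' Find neurons (or segments) by property filters
#'
#' All supplied criteria must hold. Regular expressions match the whole
#' string unless explicitly anchored; status comparison is
#' case-insensitive. `roi_any` keeps bodies with a nonzero synapse tally in
#' at least one of the named ROIs (ancestor ROIs are valid here).
#'
#' @param store a [graph_store].
#' @param name_regex,type_regex optional patterns against `instance` / `type`.
#' @param status optional exact (case-insensitive) reconstruction status.
#' @param roi_any optional character vector of ROI names.
#' @param min_size,min_pre,min_post optional lower bounds.
#' @param scope `"neurons"` (default) restricts to designated neurons;
#'   `"segments"` searches everything.
#' @return data.table of matching segment rows, body_id ascending.
#' @export
neurons_matching <- function(store, name_regex = NULL, type_regex = NULL,
                             status = NULL, roi_any = NULL,
                             min_size = NULL, min_pre = NULL, min_post = NULL,
                             scope = c("neurons", "segments")) {
  scope <- match.arg(scope)
  seg <- store$segments
  keep <- rep(TRUE, nrow(seg))
  if (scope == "neurons") keep <- keep & seg$is_neuron
  if (!is.null(name_regex)) keep <- keep & cg_regex_match(name_regex, seg$instance)
  if (!is.null(type_regex)) keep <- keep & cg_regex_match(type_regex, seg$type)
  if (!is.null(status))
    keep <- keep & !is.na(seg$status) & tolower(seg$status) == tolower(status)
  if (!is.null(min_size)) keep <- keep & seg$size >= min_size
  if (!is.null(min_pre)) keep <- keep & seg$pre_count >= min_pre
  if (!is.null(min_post)) keep <- keep & seg$post_count >= min_post
  if (!is.null(roi_any)) {
    for (r in roi_any) require_roi(store, r)
    hit <- unique(store$seg_roi[roi %in% roi_any & (pre + post) > 0, body_id])
    keep <- keep & seg$body_id %in% hit
  }
  out <- seg[keep]
  setorder(out, body_id)
  out[]
}

#' Synaptic sites inside an axis-aligned box
#'
#' The box is half-open: a site at coordinate `c` is inside iff
#' `min <= c < max` on every axis. Served from the store's spatial grid
#' index; equivalent to a linear scan over all sites.
#'
#' @param store a [graph_store].
#' @param min_corner,max_corner numeric xyz triples, `min_corner <= max_corner`.
#' @return data.table of site rows in `site_id` order.
#' @export
synapses_in_box <- function(store, min_corner, max_corner) {
  if (length(min_corner) != 3L || length(max_corner) != 3L)
    cg_stop("cg_input_error", "box corners must be xyz triples")
  if (any(min_corner > max_corner))
    cg_stop("cg_input_error", "box min corner exceeds max corner")
  if (any(min_corner == max_corner))  # empty half-open box
    return(store$sites[0L])
  lo <- floor(min_corner / GRID_CELL)
  hi <- floor((max_corner - 1) / GRID_CELL)
  n_cells <- prod(hi - lo + 1)
  if (is.finite(n_cells) && n_cells <= nrow(store$sites) + 1) {
    cells <- CJ(cx = lo[1]:hi[1], cy = lo[2]:hi[2], cz = lo[3]:hi[3])
    cand <- store$grid[cells, on = c("cx", "cy", "cz"), nomatch = NULL, site_id]
    s <- store$sites[J(sort(cand)), on = "site_id", nomatch = NULL]
  } else {
    s <- store$sites
  }
  out <- s[x >= min_corner[1] & x < max_corner[1] &
           y >= min_corner[2] & y < max_corner[2] &
           z >= min_corner[3] & z < max_corner[3]]
  setorder(out, site_id)
  out[]
}

#' Fetch the aggregated connection between two bodies
#'
#' @param store a [graph_store].
#' @param pre_body,post_body body ids (both must exist).
#' @return a list `(pre_body, post_body, weight, roi_info)` where
#'   `roi_info` maps ROI name to `list(pre, post)` tallies, or `NULL`
#'   when no link exists in that direction.
#' @export
get_connection <- function(store, pre_body, post_body) {
  require_body(store, pre_body, "pre body")
  require_body(store, post_body, "post body")
  pb <- as.numeric(pre_body); qb <- as.numeric(post_body)
  row <- store$connections[J(pb, qb),
                           on = c("pre_body", "post_body"), nomatch = NULL]
  if (nrow(row) == 0L) return(NULL)
  tal <- store$conn_roi[J(pb, qb),
                        on = c("pre_body", "post_body"), nomatch = NULL]
  list(pre_body = pb, post_body = qb,
       weight = row$weight, roi_info = roi_info_list(tal))
}

# links annotated with endpoint bodies and confidences
link_frame <- function(store) {
  lf <- copy(store$links)
  s <- store$sites
  lf[s, on = c(pre_site = "site_id"),
     `:=`(pre_body = i.body_id, pre_conf = i.confidence)]
  lf[s, on = c(post_site = "site_id"),
     `:=`(post_body = i.body_id, post_conf = i.confidence)]
  lf
}

#' Synapse sets: a connection's sites grouped per endpoint
#'
#' For each directed connection A->B the *outgoing* set of A lists A's pre
#' sites participating in the connection and the *incoming* set of B lists
#' B's post sites; together the two sets cover exactly the links between
#' the pair. Sets are derived on demand from the link table.
#'
#' @param store a [graph_store].
#' @param owner optional owner body id filter.
#' @param partner optional partner body id filter.
#' @param direction optional `"outgoing"` or `"incoming"` filter.
#' @return data.table `(owner_body, partner_body, direction, site_ids)`
#'   where `site_ids` is a list column of sorted site ids.
#' @export
synapse_sets <- function(store, owner = NULL, partner = NULL, direction = NULL) {
  lf <- link_frame(store)
  out_sets <- lf[, .(direction = "outgoing",
                     site_ids = list(sort(unique(pre_site)))),
                 by = .(owner_body = pre_body, partner_body = post_body)]
  in_sets <- lf[, .(direction = "incoming",
                    site_ids = list(sort(unique(post_site)))),
                by = .(owner_body = post_body, partner_body = pre_body)]
  sets <- rbind(out_sets, in_sets)
  if (!is.null(owner)) sets <- sets[owner_body == owner]
  if (!is.null(partner)) sets <- sets[partner_body == partner]
  if (!is.null(direction)) {
    dir <- direction
    sets <- sets[sets$direction == dir]
  }
  setorder(sets, owner_body, partner_body, direction)
  sets[]
}

#' Verify every store invariant
#'
#' Recomputes all redundant aggregates from the primary state
#' (sites + links + ROI memberships) and checks them against the stored
#' ones, along with referential integrity, link polarity, the
#' one-pre-partner-per-post-site rule, confidence bounds, ancestor closure
#' of ROI memberships, leaf-ROI conservation, and meta totals.
#'
#' @param store a [graph_store].
#' @return `TRUE` invisibly, or an error describing the first violation.
#' @export
store_check <- function(store) {
  seg <- store$segments; s <- store$sites; lf <- link_frame(store)
  fail <- function(...) cg_stop("cg_input_error", ...)

  if (anyDuplicated(seg$body_id)) fail("duplicate body ids")
  if (anyDuplicated(s$site_id)) fail("duplicate site ids")
  if (!all(s$body_id %in% seg$body_id)) fail("site with unknown owner body")
  if (any(s$confidence < 0 | s$confidence > 1)) fail("confidence outside [0,1]")
  if (nrow(lf) > 0L) {
    kinds <- s[J(lf$pre_site), on = "site_id", kind]
    if (!all(kinds == "pre")) fail("link pre endpoint is not a pre site")
    kinds <- s[J(lf$post_site), on = "site_id", kind]
    if (!all(kinds == "post")) fail("link post endpoint is not a post site")
    if (anyDuplicated(lf$post_site)) fail("post site with multiple pre partners")
  }

  # ancestor closure of site memberships
  clo <- roi_closure(store$rois)
  closed <- unique(store$site_rois[clo, on = "roi", nomatch = NULL,
                                   allow.cartesian = TRUE,
                                   .(site_id = x.site_id, roi = i.anc)])
  if (!identical(nrow(closed), nrow(store$site_rois)))
    fail("site ROI memberships not closed under the hierarchy")

  d <- derive_aggregates(seg[, .(body_id, instance, type, status, size)],
                         s, store$links, store$site_rois)
  cmp <- function(a, b, what) {
    if (!isTRUE(all.equal(canon_dt(a), canon_dt(b), check.attributes = FALSE)))
      fail("stored %s disagree with recomputation from sites+links", what)
  }
  cmp(store$connections, d$connections, "connection weights")
  cmp(store$conn_roi, d$conn_roi, "connection ROI tallies")
  cmp(store$seg_roi, d$seg_roi, "segment ROI tallies")
  cmp(seg[, .(body_id, pre_count, post_count)],
      d$counts, "segment pre/post counts")
  if (store$meta$total_pre != d$total_pre || store$meta$total_post != d$total_post)
    fail("meta totals disagree with site counts")

  # leaf-ROI conservation for connections
  leaves <- roi_leaves(store$rois)
  if (nrow(store$connections) > 0L) {
    leaf_post <- store$conn_roi[roi %in% leaves,
                                .(in_leaf = sum(post)), by = .(pre_body, post_body)]
    post_roi_n <- store$site_rois[roi %in% leaves, unique(site_id)]
    outside <- lf[!post_site %in% post_roi_n,
                  .(outside = .N), by = .(pre_body, post_body)]
    chk <- merge(store$connections, leaf_post,
                 by = c("pre_body", "post_body"), all.x = TRUE)
    chk <- merge(chk, outside, by = c("pre_body", "post_body"), all.x = TRUE)
    for (cc in c("in_leaf", "outside"))
      set(chk, which(is.na(chk[[cc]])), cc, 0L)
    if (chk[, any(in_leaf + outside != weight)])
      fail("leaf-ROI conservation violated on a connection")
  }
  invisible(TRUE)
}

canon_dt <- function(dt) {
  dt <- as.data.table(dt)
  setorderv(dt, names(dt))
  setattr(dt, "sorted", NULL)
  setattr(dt, "index", NULL)
  as.data.frame(dt)
}

#' Compare two stores field by field
#'
#' Row order, keys, and the `last_modified` timestamp are ignored; all
#' primary state and all aggregates must agree. Set
#' `ignore_neuron_flags = TRUE` to compare up to re-evaluation of the
#' neuron designation (useful around merge/split round trips, where
#' designation is deliberately re-derived per batch).
#'
#' @param a,b graph stores.
#' @param ignore_neuron_flags drop `is_neuron` from the comparison.
#' @return `TRUE` or `FALSE`.
#' @export
store_equal <- function(a, b, ignore_neuron_flags = FALSE) {
  seg_cols <- c("body_id", "instance", "type", "status", "size",
                "pre_count", "post_count", if (!ignore_neuron_flags) "is_neuron")
  same <- function(x, y) isTRUE(all.equal(canon_dt(x), canon_dt(y),
                                          check.attributes = FALSE))
  identical(a$dataset, b$dataset) &&
    same(a$segments[, seg_cols, with = FALSE], b$segments[, seg_cols, with = FALSE]) &&
    same(a$sites, b$sites) &&
    same(a$site_rois, b$site_rois) &&
    same(a$links, b$links) &&
    same(a$rois[, .(name, parent, xmin, ymin, zmin, xmax, ymax, zmax)],
         b$rois[, .(name, parent, xmin, ymin, zmin, xmax, ymax, zmax)]) &&
    same(a$connections, b$connections) &&
    same(a$conn_roi, b$conn_roi) &&
    same(a$seg_roi, b$seg_roi) &&
    a$meta$total_pre == b$meta$total_pre &&
    a$meta$total_post == b$meta$total_post
}
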