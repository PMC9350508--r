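#' Reconstruction-quality metrics
#'
#' At the current state of the art it is too costly to attach every
#' synapse to a proofread neuron, so a reconstruction's usefulness is
#' summarized by graph-level completeness: what share of a neuron's
#' synaptic partners are real, designated neurons rather than anonymous
#' fragments, what share of a region's synapses belong to traced bodies,
#' and how many bodies one must consider to cover a region's synapses.
#' Only graph-level metrics live here; geometric checks (synapse-to-
#' skeleton distances and the like) belong to upstream pipelines.
#'
#' @name qc_metrics
NULL

#' Partner completeness of one body
#'
#' Partitions the body's links in the given direction by the partner
#' body's reconstruction status (absent status pooled as `"(none)"`).
#' `fraction_complete` is the share of links whose partner is "complete":
#' by default a designated neuron (any status); set
#' `complete_when = "traced"` to require a traced status instead.
#'
#' @param store a [graph_store].
#' @param body body id with at least one link in the direction.
#' @param direction `"outgoing"` or `"incoming"`.
#' @param complete_when `"neuron"` (default) or `"traced"`.
#' @return list `(body, direction, total_links, fraction_complete,
#'   status_breakdown)`; the breakdown is a named integer vector whose
#'   counts sum to `total_links`.
#' @export
partner_completeness <- function(store, body,
                                 direction = c("outgoing", "incoming"),
                                 complete_when = c("neuron", "traced")) {
  direction <- dir_arg(direction)
  complete_when <- match.arg(complete_when)
  require_body(store, body)
  lf <- link_frame(store)
  partner <- if (direction == "outgoing") lf[pre_body == body, post_body]
             else lf[post_body == body, pre_body]
  if (length(partner) == 0L)
    cg_stop("cg_undefined", "body %s has no %s links; completeness undefined",
            format(body, scientific = FALSE), direction)

  idx <- match(partner, store$segments$body_id)
  st <- store$segments$status[idx]
  st[is.na(st)] <- "(none)"
  breakdown <- table(st)
  breakdown <- setNames(as.integer(breakdown), names(breakdown))
  complete <- if (complete_when == "neuron") store$segments$is_neuron[idx]
              else !is.na(store$segments$status[idx]) &
                   tolower(store$segments$status[idx]) == "traced"
  list(body = body, direction = direction,
       total_links = length(partner),
       fraction_complete = sum(complete) / length(partner),
       status_breakdown = breakdown)
}

#' Completeness of a brain region
#'
#' The share of the region's synaptic sites owned by traced bodies
#' (status "traced", case-insensitive; `complete_when = "neuron"` counts
#' designated neurons instead). Pre and post sites are pooled by default;
#' `kind` restricts to one polarity. Because the interactive plugin this
#' mirrors is phrased over *segments* while the underlying metric is
#' phrased over *synapses*, both readings are reported:
#' `fraction_complete` (site-weighted, the primary value) and
#' `segment_fraction` (share of bodies with sites in the region that are
#' complete).
#'
#' @param store a [graph_store].
#' @param roi ROI name containing at least one site.
#' @param complete_when `"traced"` (default) or `"neuron"`.
#' @param kind `"both"` (default), `"pre"`, or `"post"`.
#' @return list `(roi, total_sites, fraction_complete, segment_fraction,
#'   status_breakdown)`.
#' @export
roi_completeness <- function(store, roi, complete_when = c("traced", "neuron"),
                             kind = c("both", "pre", "post")) {
  complete_when <- match.arg(complete_when)
  kind <- match.arg(kind)
  require_roi(store, roi)
  roi_q <- roi
  ids <- store$site_rois[roi == roi_q, site_id]
  s <- store$sites[J(ids), on = "site_id", nomatch = NULL]
  if (kind != "both") s <- s[s$kind == kind]
  if (nrow(s) == 0L)
    cg_stop("cg_undefined", "ROI '%s' contains no %s sites; completeness undefined",
            roi, if (kind == "both") "" else kind)

  idx <- match(s$body_id, store$segments$body_id)
  st <- store$segments$status[idx]
  is_complete_body <- function(i)
    if (complete_when == "neuron") store$segments$is_neuron[i]
    else !is.na(store$segments$status[i]) &
         tolower(store$segments$status[i]) == "traced"
  complete <- is_complete_body(idx)
  st[is.na(st)] <- "(none)"
  breakdown <- table(st)

  owners <- unique(s$body_id)
  owner_complete <- is_complete_body(match(owners, store$segments$body_id))
  list(roi = roi, total_sites = nrow(s),
       fraction_complete = sum(complete) / nrow(s),
       segment_fraction = sum(owner_complete) / length(owners),
       status_breakdown = setNames(as.integer(breakdown), names(breakdown)))
}

#' Segment coverage curve for a region
#'
#' How many bodies must be considered to account for a given share of a
#' region's synapses? Bodies are ranked by their site count of the given
#' kind inside the ROI (descending, ties by body id ascending); entry
#' `k` of the curve is the fraction of the region's sites of that kind
#' covered by the top `k` bodies. The curve is non-decreasing and its
#' final entry is exactly 1.
#'
#' @param store a [graph_store].
#' @param roi ROI name.
#' @param kind `"pre"` or `"post"`.
#' @return data.table `(rank, body_id, n_sites, cumulative_fraction)`.
#' @export
coverage_curve <- function(store, roi, kind = c("pre", "post")) {
  kind <- match.arg(kind)
  require_roi(store, roi)
  roi_q <- roi; kind_q <- kind
  ids <- store$site_rois[roi == roi_q, site_id]
  s <- store$sites[J(ids), on = "site_id", nomatch = NULL]
  s <- s[s$kind == kind_q]
  if (nrow(s) == 0L)
    cg_stop("cg_undefined", "ROI '%s' contains no %s sites; curve undefined",
            roi, kind)
  per <- s[, .(n_sites = .N), by = body_id]
  setorder(per, -n_sites, body_id)
  per[, rank := seq_len(.N)]
  per[, cumulative_fraction := cumsum(n_sites) / sum(n_sites)]
  per[, .(rank, body_id, n_sites, cumulative_fraction)]
}
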