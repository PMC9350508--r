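#' Build and validate an ROI hierarchy specification
#'
#' Brain regions of interest (ROIs) form a forest: each ROI has at most one
#' parent and any number of children. A leaf ROI may carry an axis-aligned
#' box (integer voxels, half-open on every axis) used for geometric synapse
#' membership tests. A synaptic site that lies inside a leaf's box is a
#' member of that leaf *and of every ancestor* up to the root, mirroring the
#' per-synapse boolean region flags of the underlying data model.
#'
#' @param x a data.frame with columns `name` and `parent` (`NA` for roots)
#'   and, optionally, box columns `xmin,ymin,zmin,xmax,ymax,zmax` (`NA` when
#'   the ROI has no geometry).
#' @return a keyed `data.table` of class `roi_spec`.
#' @export
roi_spec <- function(x) {
  x <- as.data.table(x)
  if (!all(c("name", "parent") %in% names(x)))
    cg_stop("cg_input_error", "ROI spec needs 'name' and 'parent' columns")
  box_cols <- c("xmin", "ymin", "zmin", "xmax", "ymax", "zmax")
  for (col in box_cols) if (!col %in% names(x)) x[, (col) := NA_real_]
  spec <- x[, c("name", "parent", box_cols), with = FALSE]
  spec[, name := as.character(name)]
  spec[, parent := as.character(parent)]
  for (col in box_cols) spec[, (col) := as.numeric(get(col))]

  if (anyDuplicated(spec$name))
    cg_stop("cg_input_error", "duplicate ROI name(s): %s",
            paste(unique(spec$name[duplicated(spec$name)]), collapse = ", "))
  bad_parent <- setdiff(spec$parent[!is.na(spec$parent)], spec$name)
  if (length(bad_parent))
    cg_stop("cg_input_error", "ROI parent(s) not defined: %s",
            paste(bad_parent, collapse = ", "))

  # forest check: walking parents from any node must reach a root
  parent_of <- setNames(spec$parent, spec$name)
  for (nm in spec$name) {
    seen <- character(); cur <- nm
    while (!is.na(cur)) {
      if (cur %in% seen)
        cg_stop("cg_input_error", "ROI hierarchy contains a cycle at '%s'", cur)
      seen <- c(seen, cur)
      cur <- parent_of[[cur]]
    }
  }

  has_box <- !is.na(spec$xmin)
  if (any(has_box)) {
    b <- spec[has_box]
    if (anyNA(b[, box_cols, with = FALSE]))
      cg_stop("cg_input_error", "ROI boxes must supply all six coordinates")
    if (b[, any(xmin >= xmax | ymin >= ymax | zmin >= zmax)])
      cg_stop("cg_input_error", "ROI box(es) are empty (min must be < max)")
  }
  setkey(spec, name)
  setattr(spec, "class", c("roi_spec", class(spec)))
  spec[]
}

#' @export
print.roi_spec <- function(x, ...) {
  cat(sprintf("ROI hierarchy: %d regions (%d leaves, %d with geometry)\n",
              nrow(x), length(roi_leaves(x)), sum(!is.na(x$xmin))))
  NextMethod()
}

#' Leaf ROIs of a hierarchy
#'
#' A leaf is an ROI that is not the parent of any other ROI.
#' @param spec an [roi_spec()].
#' @return character vector of leaf names, sorted.
#' @export
roi_leaves <- function(spec) {
  sort(setdiff(spec$name, spec$parent[!is.na(spec$parent)]))
}

# long table (roi, anc) of every ROI paired with itself and all ancestors
roi_closure <- function(spec) {
  parent_of <- setNames(spec$parent, spec$name)
  rows <- lapply(spec$name, function(nm) {
    chain <- nm; cur <- parent_of[[nm]]
    while (!is.na(cur)) { chain <- c(chain, cur); cur <- parent_of[[cur]] }
    data.table(roi = nm, anc = chain)
  })
  rbindlist(rows)
}

#' Assign ROI memberships to synaptic sites
#'
#' Each site receives the set of all ROIs it belongs to: its leaf
#' memberships plus every ancestor of those leaves (closure under the
#' hierarchy). Membership comes from exactly one source per call:
#' either leaf box geometry in `spec` (a site is inside a leaf iff
#' `min <= coord < max` on every axis), or an explicit leaf-membership
#' table. When both are available the explicit table wins, with a warning.
#' Overlapping leaf boxes are permitted; a site in the overlap belongs to
#' all of them. A site inside no leaf gets no memberships.
#'
#' @param sites data.frame/data.table with `site_id`, `x`, `y`, `z`.
#' @param spec an [roi_spec()].
#' @param site_roi_table optional data.frame with columns `site_id`,
#'   `roi_name` listing leaf memberships explicitly.
#' @return data.table `(site_id, roi)`, ancestor-closed, sorted, unique.
#' @export
assign_rois <- function(sites, spec, site_roi_table = NULL) {
  sites <- as.data.table(sites)
  leaves <- roi_leaves(spec)
  boxed <- spec[!is.na(xmin) & name %in% leaves]

  if (!is.null(site_roi_table)) {
    tab <- as.data.table(site_roi_table)
    if (!all(c("site_id", "roi_name") %in% names(tab)))
      cg_stop("cg_input_error",
              "site_roi_table needs 'site_id' and 'roi_name' columns")
    if (nrow(boxed) > 0L && nrow(tab) >= 0L)
      warning("explicit synapse ROI table supplied; ROI box geometry ignored",
              call. = FALSE)
    unknown <- setdiff(tab$roi_name, spec$name)
    if (length(unknown))
      cg_stop("cg_input_error", "unknown ROI name(s) in membership table: %s",
              paste(unknown, collapse = ", "))
    foreign <- setdiff(tab$site_id, sites$site_id)
    if (length(foreign))
      cg_stop("cg_input_error", "membership table names unknown site(s): %s",
              paste(head(foreign, 5L), collapse = ", "))
    leafm <- tab[, .(site_id = as.integer(site_id), roi = as.character(roi_name))]
  } else {
    if (nrow(boxed) == 0L) {
      leafm <- data.table(site_id = integer(), roi = character())
    } else {
      pieces <- lapply(seq_len(nrow(boxed)), function(i) {
        b <- boxed[i]
        inside <- sites$x >= b$xmin & sites$x < b$xmax &
                  sites$y >= b$ymin & sites$y < b$ymax &
                  sites$z >= b$zmin & sites$z < b$zmax
        data.table(site_id = sites$site_id[inside], roi = b$name)
      })
      leafm <- rbindlist(pieces)
    }
  }

  if (nrow(leafm) == 0L)
    return(data.table(site_id = integer(), roi = character(), key = c("site_id", "roi")))
  clo <- roi_closure(spec)
  out <- unique(leafm[clo, on = "roi", nomatch = NULL, allow.cartesian = TRUE,
                      .(site_id = x.site_id, roi = i.anc)])
  setkey(out, site_id, roi)
  out[]
}

read_rois_json <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  rows <- lapply(raw, function(r) {
    box <- r$box
    data.table(
      name = r$name,
      parent = if (is.null(r$parent)) NA_character_ else r$parent,
      xmin = if (is.null(box)) NA_real_ else box$min[[1]],
      ymin = if (is.null(box)) NA_real_ else box$min[[2]],
      zmin = if (is.null(box)) NA_real_ else box$min[[3]],
      xmax = if (is.null(box)) NA_real_ else box$max[[1]],
      ymax = if (is.null(box)) NA_real_ else box$max[[2]],
      zmax = if (is.null(box)) NA_real_ else box$max[[3]]
    )
  })
  roi_spec(rbindlist(rows))
}

write_rois_json <- function(spec, path) {
  items <- lapply(seq_len(nrow(spec)), function(i) {
    r <- spec[i]
    item <- list(name = r$name,
                 parent = if (is.na(r$parent)) NULL else r$parent)
    if (!is.na(r$xmin))
      item$box <- list(min = c(r$xmin, r$ymin, r$zmin),
                       max = c(r$xmax, r$ymax, r$zmax))
    item
  })
  jsonlite::write_json(items, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
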