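#' Connectivity query suite
#'
#' Deterministic re-implementations of the standard interactive circuit
#' queries over a consistent [graph_store]: partner tables, bounded path
#' search, reciprocity, region projections, common partners, similarity
#' rankings, and region-to-region connectivity. All list-returning
#' operations have a deterministic order and default to *neuron scope* --
#' users rarely want a query to return a long list of tiny unnamed
#' fragments -- with segment scope available as an explicit opt-in.
#'
#' @name query_suite
NULL

scope_mask <- function(store, scope) {
  if (scope == "neurons") store$segments$is_neuron
  else rep(TRUE, nrow(store$segments))
}

dir_arg <- function(direction) {
  direction <- match.arg(direction, c("outgoing", "incoming"))
  direction
}

#' Synaptic partners of a body, ordered by connection strength
#'
#' With the default `min_confidence = 0` the table is served straight from
#' the stored connection aggregates. A positive confidence threshold
#' instead recomputes effective weights from the individual links, keeping
#' only links whose pre *and* post site confidences reach the threshold.
#'
#' @param store a [graph_store].
#' @param body body id whose partners are wanted.
#' @param direction `"outgoing"` (downstream) or `"incoming"` (upstream).
#' @param min_weight minimum (effective) connection weight.
#' @param scope `"neurons"` (default) or `"segments"` for the partners.
#' @param min_confidence per-site confidence threshold in `[0, 1]`.
#' @return data.table `(partner_body, weight, partner_type,
#'   partner_instance, partner_status, direction)` sorted by weight
#'   descending then partner id ascending.
#' @export
partners <- function(store, body, direction = c("outgoing", "incoming"),
                     min_weight = 1, scope = c("neurons", "segments"),
                     min_confidence = 0) {
  direction <- dir_arg(direction)
  scope <- match.arg(scope)
  require_body(store, body)

  if (min_confidence > 0) {
    lf <- link_frame(store)
    lf <- lf[pre_conf >= min_confidence & post_conf >= min_confidence]
    conns <- lf[, .(weight = .N), by = .(pre_body, post_body)]
  } else {
    conns <- store$connections
  }
  rows <- if (direction == "outgoing")
    conns[pre_body == body, .(partner_body = post_body, weight)]
  else
    conns[post_body == body, .(partner_body = pre_body, weight)]

  in_scope <- store$segments[scope_mask(store, scope), body_id]
  rows <- rows[partner_body %in% in_scope & weight >= min_weight]
  rows[store$segments, on = c(partner_body = "body_id"),
       `:=`(partner_type = i.type, partner_instance = i.instance,
            partner_status = i.status)]
  rows[, direction := direction]
  setorder(rows, -weight, partner_body)
  rows[]
}

#' Total connection weight to traced partners
#'
#' Sums the connection weights from `body` (in the given direction) over
#' all partners whose reconstruction status is "traced"
#' (case-insensitive), regardless of partner scope.
#'
#' @inheritParams partners
#' @return a single integer weight.
#' @export
traced_partner_weight <- function(store, body,
                                  direction = c("outgoing", "incoming")) {
  direction <- dir_arg(direction)
  require_body(store, body)
  rows <- if (direction == "outgoing")
    store$connections[pre_body == body, .(partner_body = post_body, weight)]
  else
    store$connections[post_body == body, .(partner_body = pre_body, weight)]
  st <- store$segments[match(rows$partner_body, body_id), status]
  sum(rows$weight[!is.na(st) & tolower(st) == "traced"])
}

# adjacency restricted to weight >= min_weight and allowed bodies;
# named list body -> sorted integer vector of successors
filtered_adjacency <- function(store, min_weight, allowed) {
  conns <- store$connections[weight >= min_weight &
                             pre_body %in% allowed & post_body %in% allowed]
  wkey <- paste(conns$pre_body, conns$post_body)
  list(
    succ = lapply(split(conns$post_body, conns$pre_body), sort),
    weight_of = setNames(conns$weight, wkey)
  )
}

path_sort <- function(found) {
  if (length(found) == 0L) return(found)
  len <- vapply(found, function(p) length(p$bodies) - 1L, 0L)
  key <- vapply(found, function(p)
    paste(sprintf("%025.0f", p$bodies), collapse = "/"), "")
  found[order(len, key)]
}

attach_weights <- function(found, adj) {
  lapply(found, function(bodies) {
    w <- vapply(seq_len(length(bodies) - 1L), function(i)
      unname(adj$weight_of[[paste(bodies[i], bodies[i + 1L])]]), 0)
    list(bodies = bodies, weights = as.integer(w))
  })
}

#' All simple directed paths between two bodies, up to a length bound
#'
#' Enumerates every simple path from `source` to `target` of at most
#' `max_len` hops using only connections of weight at least `min_weight`.
#' Intermediate bodies are restricted to the chosen scope; the endpoints
#' are always admissible. When `source == target` the only admissible
#' "path" is a direct autapse hop. The search is depth-first with a
#' deterministic node-expansion budget: exceeding `expansion_cap` raises a
#' budget error rather than returning a silent partial answer.
#'
#' @param store a [graph_store].
#' @param source,target body ids.
#' @param max_len maximum number of hops (>= 1).
#' @param min_weight minimum weight of every connection on the path.
#' @param scope `"neurons"` (default) or `"segments"` for intermediate hops.
#' @param expansion_cap maximum number of node expansions.
#' @return list of paths, each `list(bodies, weights)`, sorted by length
#'   then lexicographically by body sequence.
#' @export
find_paths <- function(store, source, target, max_len, min_weight = 1,
                       scope = c("neurons", "segments"),
                       expansion_cap = 1e5) {
  scope <- match.arg(scope)
  source <- as.numeric(source); target <- as.numeric(target)
  require_body(store, source, "source body")
  require_body(store, target, "target body")
  if (!is.numeric(max_len) || max_len < 1)
    cg_stop("cg_input_error", "max_len must be >= 1")

  allowed <- unique(c(store$segments[scope_mask(store, scope), body_id],
                      source, target))
  adj <- filtered_adjacency(store, min_weight, allowed)

  if (source == target) {
    auto <- adj$weight_of[paste(source, source)]
    found <- if (!is.na(auto)) list(c(source, source)) else list()
    return(path_sort(attach_weights(found, adj)))
  }

  env <- new.env(parent = emptyenv())
  env$expansions <- 0L
  env$found <- list()
  dfs <- function(node, path) {
    env$expansions <- env$expansions + 1L
    if (env$expansions > expansion_cap)
      cg_stop("cg_budget_error",
              "path search exceeded its expansion budget of %d nodes",
              expansion_cap)
    if (node == target && length(path) > 1L) {
      env$found[[length(env$found) + 1L]] <- path
      return(invisible())  # simple paths cannot extend beyond the target
    }
    if (length(path) - 1L >= max_len) return(invisible())
    for (nb in adj$succ[[as.character(node)]]) {
      if (nb %in% path) next  # simple path: no revisits (target never in path)
      dfs(nb, c(path, nb))
    }
    invisible()
  }
  dfs(source, source)
  path_sort(attach_weights(env$found, adj))
}

#' All shortest directed paths between two bodies
#'
#' Breadth-first variant of [find_paths()]: returns only the paths of
#' minimum feasible hop count (empty when the target is unreachable).
#' The same deterministic expansion budget applies, standing in for the
#' wall-clock timeout an interactive service would use.
#'
#' @inheritParams find_paths
#' @export
find_shortest_paths <- function(store, source, target, min_weight = 1,
                                scope = c("neurons", "segments"),
                                expansion_cap = 1e5) {
  scope <- match.arg(scope)
  source <- as.numeric(source); target <- as.numeric(target)
  require_body(store, source, "source body")
  require_body(store, target, "target body")
  allowed <- unique(c(store$segments[scope_mask(store, scope), body_id],
                      source, target))
  adj <- filtered_adjacency(store, min_weight, allowed)

  if (source == target) {
    auto <- adj$weight_of[paste(source, source)]
    found <- if (!is.na(auto)) list(c(source, source)) else list()
    return(path_sort(attach_weights(found, adj)))
  }

  # BFS distances from source
  dist <- new.env(parent = emptyenv())
  assign(as.character(source), 0L, envir = dist)
  frontier <- source
  expansions <- 0L
  target_dist <- NA_integer_
  d <- 0L
  while (length(frontier) > 0L && is.na(target_dist)) {
    d <- d + 1L
    nxt <- numeric()
    for (node in frontier) {
      expansions <- expansions + 1L
      if (expansions > expansion_cap)
        cg_stop("cg_budget_error",
                "shortest-path search exceeded its expansion budget of %d nodes",
                expansion_cap)
      for (nb in adj$succ[[as.character(node)]]) {
        key <- as.character(nb)
        if (!exists(key, envir = dist, inherits = FALSE)) {
          assign(key, d, envir = dist)
          nxt <- c(nxt, nb)
        }
      }
    }
    if (exists(as.character(target), envir = dist, inherits = FALSE))
      target_dist <- get(as.character(target), envir = dist)
    frontier <- unique(nxt)
  }
  if (is.na(target_dist)) return(list())

  # enumerate paths through the BFS level DAG, backwards from the target
  pred <- function(node, lvl) {
    cand <- numeric()
    for (p in names(adj$succ)) {
      pn <- as.numeric(p)
      pk <- as.character(pn)
      if (exists(pk, envir = dist, inherits = FALSE) &&
          get(pk, envir = dist) == lvl - 1L &&
          node %in% adj$succ[[p]])
        cand <- c(cand, pn)
    }
    sort(cand)
  }
  paths <- list(c(target))
  for (lvl in seq(target_dist, 1L)) {
    nxt <- list()
    for (p in paths) {
      for (pr in pred(p[1L], lvl)) nxt[[length(nxt) + 1L]] <- c(pr, p)
    }
    paths <- nxt
    if (length(paths) == 0L) break
  }
  paths <- Filter(function(p) p[1L] == source, paths)
  path_sort(attach_weights(paths, adj))
}

#' Does a reciprocal connection exist between two bodies?
#'
#' @param store a [graph_store].
#' @param a,b body ids.
#' @param min_weight minimum weight required in *each* direction.
#' @return `TRUE` iff `weight(a->b) >= min_weight` and
#'   `weight(b->a) >= min_weight`.
#' @export
is_reciprocal <- function(store, a, b, min_weight = 1) {
  require_body(store, a); require_body(store, b)
  w <- function(p, q) {
    row <- store$connections[J(p, q), on = c("pre_body", "post_body"),
                             nomatch = NULL]
    if (nrow(row) == 0L) 0L else row$weight
  }
  w(a, b) >= min_weight && w(b, a) >= min_weight
}

#' Neurons projecting from one region to another
#'
#' A neuron "projects" from `roi_from` to `roi_to` when it receives at
#' least `min_in` postsynaptic sites in the source region and places at
#' least `min_out` presynaptic sites in the target region (inputs in the
#' source, outputs in the target).
#'
#' @param store a [graph_store].
#' @param roi_from,roi_to ROI names.
#' @param min_in,min_out tally thresholds.
#' @return sorted numeric vector of neuron body ids (its length is the
#'   projection count).
#' @export
roi_projection_neurons <- function(store, roi_from, roi_to,
                                   min_in = 1, min_out = 1) {
  require_roi(store, roi_from); require_roi(store, roi_to)
  neu <- store$segments[is_neuron == TRUE, body_id]
  inn <- store$seg_roi[roi == roi_from & post >= min_in, body_id]
  out <- store$seg_roi[roi == roi_to & pre >= min_out, body_id]
  sort(intersect(intersect(neu, inn), out))
}

#' Partners common to a set of bodies
#'
#' Finds the partners connected, in the stated direction and at weight at
#' least `min_weight`, to *every* body in the set, and reports the
#' per-body weights.
#'
#' @param store a [graph_store].
#' @param bodies numeric vector of body ids (length >= 1).
#' @param direction `"outgoing"` or `"incoming"` (shared partners
#'   downstream or upstream of the set).
#' @param min_weight per-connection weight threshold.
#' @param scope partner scope, `"neurons"` (default) or `"segments"`.
#' @return data.table with `partner_body` and one `weight_<body>` column
#'   per queried body, partner id ascending.
#' @export
common_partners <- function(store, bodies, direction = c("outgoing", "incoming"),
                            min_weight = 1, scope = c("neurons", "segments")) {
  direction <- dir_arg(direction)
  scope <- match.arg(scope)
  if (length(bodies) < 1L)
    cg_stop("cg_input_error", "need at least one body")
  per <- lapply(bodies, function(b)
    partners(store, b, direction, min_weight, scope)[, .(partner_body, weight)])
  shared <- Reduce(intersect, lapply(per, `[[`, "partner_body"))
  out <- data.table(partner_body = sort(shared))
  for (i in seq_along(bodies)) {
    w <- per[[i]][match(out$partner_body, partner_body), weight]
    out[, (sprintf("weight_%s", format(bodies[i], scientific = FALSE))) := w]
  }
  out[]
}

# L2-normalized leaf-ROI profile vectors (pre then post tallies)
roi_profile_matrix <- function(store, body_ids) {
  leaves <- roi_leaves(store$rois)
  m <- matrix(0, nrow = length(body_ids), ncol = 2L * length(leaves),
              dimnames = list(as.character(body_ids),
                              c(paste0("pre:", leaves), paste0("post:", leaves))))
  tal <- store$seg_roi[body_id %in% body_ids & roi %in% leaves]
  if (nrow(tal) > 0L) {
    ri <- match(as.character(tal$body_id), rownames(m))
    m[cbind(ri, match(paste0("pre:", tal$roi), colnames(m)))] <- tal$pre
    m[cbind(ri, match(paste0("post:", tal$roi), colnames(m)))] <- tal$post
  }
  m
}

cosine_rows <- function(v, m) {
  nv <- sqrt(sum(v^2)); nm <- sqrt(rowSums(m^2))
  num <- as.numeric(m %*% v)
  ifelse(nm > 0 & nv > 0, num / (nm * nv), 0)
}

#' Neurons with similar region input/output profiles
#'
#' Ranks neurons by cosine similarity between leaf-ROI profile vectors
#' (the concatenated per-leaf pre and post synapse tallies,
#' L2-normalized). Scale-invariant: two neurons with proportional
#' profiles score 1; disjoint region support scores 0. The query body is
#' excluded from its own ranking.
#'
#' @param store a [graph_store].
#' @param body a designated neuron with at least one synapse.
#' @param top_k number of neighbours to return.
#' @return data.table `(body_id, similarity)` sorted by similarity
#'   descending, ties by body id.
#' @export
similar_by_roi_profile <- function(store, body, top_k = 10L) {
  require_body(store, body)
  if (!store$segments[J(body), on = "body_id", is_neuron])
    cg_stop("cg_input_error", "body %s is not a designated neuron",
            format(body, scientific = FALSE))
  if (top_k < 1L) cg_stop("cg_input_error", "top_k must be >= 1")
  others <- store$segments[is_neuron == TRUE & body_id != body, body_id]
  prof <- roi_profile_matrix(store, c(body, others))
  v <- prof[1L, ]
  if (sum(v) == 0)
    cg_stop("cg_undefined",
            "body %s has no synapses in any leaf ROI; profile undefined",
            format(body, scientific = FALSE))
  if (length(others) == 0L)
    return(data.table(body_id = numeric(), similarity = numeric()))
  sim <- cosine_rows(v, prof[-1L, , drop = FALSE])
  out <- data.table(body_id = others, similarity = sim)
  setorder(out, -similarity, body_id)
  head(out, top_k)[]
}

#' Connectivity similarity within a cell type
#'
#' Lists the designated neurons of a cell type and scores every pair by
#' the cosine similarity of their connectivity fingerprints: for each
#' member, outgoing and incoming connection weights are accumulated into
#' a vector indexed by partner *type* (absent types pooled as `"(none)"`),
#' outgoing and incoming halves concatenated. The matrix is symmetric
#' with a unit diagonal.
#'
#' @param store a [graph_store].
#' @param type exact cell type string.
#' @return list with `type`, `members` (sorted ids), and `similarity`
#'   (members x members matrix).
#' @export
cell_type_summary <- function(store, type) {
  seg <- store$segments
  members <- sort(seg$body_id[seg$is_neuron & !is.na(seg$type) & seg$type == type])
  if (length(members) == 0L)
    cg_stop("cg_not_found", "no designated neuron has type '%s'", type)

  type_of <- function(ids) {
    tt <- store$segments$type[match(ids, store$segments$body_id)]
    ifelse(is.na(tt), "(none)", tt)
  }
  conns <- store$connections
  out_f <- conns[pre_body %in% members,
                 .(member = pre_body, key = paste0("out:", type_of(post_body)), weight)]
  in_f <- conns[post_body %in% members,
                .(member = post_body, key = paste0("in:", type_of(pre_body)), weight)]
  feat <- rbind(out_f, in_f)[, .(w = sum(weight)), by = .(member, key)]
  keys <- sort(unique(feat$key))
  m <- matrix(0, nrow = length(members), ncol = max(length(keys), 1L),
              dimnames = list(as.character(members),
                              if (length(keys)) keys else "none"))
  if (nrow(feat) > 0L)
    m[cbind(match(as.character(feat$member), rownames(m)),
            match(feat$key, colnames(m)))] <- feat$w

  k <- length(members)
  sim <- diag(1, k)
  dimnames(sim) <- list(as.character(members), as.character(members))
  if (k > 1L) {
    for (i in seq_len(k - 1L)) {
      sim[i, (i + 1L):k] <- cosine_rows(m[i, ], m[(i + 1L):k, , drop = FALSE])
      sim[(i + 1L):k, i] <- sim[i, (i + 1L):k]
    }
  }
  list(type = type, members = members, similarity = sim)
}

#' Region-to-region connectivity matrix
#'
#' Summarizes how brain regions connect through the neurons that project
#' between them, over leaf ROIs only. In `"count"` mode, entry
#' `(from, to)` is the number of neurons with at least one input in
#' `from` and one output in `to` (the projection count). In `"weighted"`
#' mode each neuron contributes its input share
#' `post(from) / total_post` multiplied by its output tally `pre(to)`;
#' neurons with no postsynaptic sites are skipped.
#'
#' @param store a [graph_store].
#' @param mode `"count"` or `"weighted"`.
#' @return numeric matrix, rows = source leaf ROI, cols = target leaf ROI.
#' @export
roi_connectivity_matrix <- function(store, mode = c("count", "weighted")) {
  mode <- match.arg(mode)
  leaves <- roi_leaves(store$rois)
  m <- matrix(0, length(leaves), length(leaves), dimnames = list(leaves, leaves))
  if (length(leaves) == 0L) return(m)
  neu <- store$segments[is_neuron == TRUE]
  tal <- store$seg_roi[body_id %in% neu$body_id & roi %in% leaves]
  if (nrow(tal) == 0L) return(m)
  for (n in neu$body_id) {
    t_n <- tal[body_id == n]
    if (nrow(t_n) == 0L) next
    ins <- t_n[post > 0]
    outs <- t_n[pre > 0]
    if (mode == "count") {
      for (rf in ins$roi) for (rt in outs$roi) m[rf, rt] <- m[rf, rt] + 1
    } else {
      total_post <- neu[body_id == n, post_count]
      if (total_post == 0L) next
      for (i in seq_len(nrow(ins))) for (j in seq_len(nrow(outs)))
        m[ins$roi[i], outs$roi[j]] <- m[ins$roi[i], outs$roi[j]] +
          (ins$post[i] / total_post) * outs$pre[j]
    }
  }
  m
}

#' Count neurons whose cell type matches a pattern
#'
#' @param store a [graph_store].
#' @param pattern regular expression (full-match unless anchored).
#' @return integer count of designated neurons with a matching type.
#' @export
count_types_matching <- function(store, pattern) {
  neu <- store$segments[is_neuron == TRUE]
  sum(cg_regex_match(pattern, neu$type))
}
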