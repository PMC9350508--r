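# Fixture builders shared across test files.

# a small random world; sizes vary with the seed so the oracle suite sees
# a spread of shapes
small_world <- function(seed, ...) {
  set.seed(seed * 7 + 1)
  defaults <- list(
    n_neurons = sample(3:12, 1), n_fragments = sample(150:250, 1),
    synapses_per_neuron = sample(5:20, 1),
    traced_fraction = runif(1, 0.5, 0.95),
    roi_grid = if (seed %% 2 == 0) c(2L, 2L) else c(3L, 2L),
    seed = seed
  )
  args <- modifyList(defaults, list(...))
  generate_world(do.call(world_config, args))
}

world_store <- function(w, promote = TRUE) {
  st <- build_aggregates(w$bundle, dataset = "synthetic")
  if (promote) st <- promote_neurons(st)
  st
}

# a store realizing an arbitrary weighted digraph: edge (from, to, w) gets
# w pre sites on `from`, w post sites on `to`, and w links; every body is
# promoted via its status, so neuron scope covers the whole graph
edge_store <- function(n_bodies, edges) {
  body_ids <- 100 * seq_len(n_bodies)
  bodies <- data.frame(body_id = body_ids,
                       instance = sprintf("n%02d", seq_len(n_bodies)),
                       type = "T", status = "Traced", size = 1000)
  rois <- data.frame(name = "root", parent = NA)
  total <- sum(edges$w)
  if (total == 0) {
    sites <- data.frame(site_id = integer(), body_id = numeric(),
                        kind = character(), x = integer(), y = integer(),
                        z = integer(), confidence = numeric())
    links <- data.frame(pre_site_id = integer(), post_site_id = integer())
  } else {
    pre_ids <- seq_len(total)
    post_ids <- total + seq_len(total)
    from_rep <- rep(body_ids[edges$from], edges$w)
    to_rep <- rep(body_ids[edges$to], edges$w)
    sites <- data.frame(
      site_id = c(pre_ids, post_ids),
      body_id = c(from_rep, to_rep),
      kind = rep(c("pre", "post"), each = total),
      x = 0L, y = 0L, z = 0L, confidence = 0.9)
    links <- data.frame(pre_site_id = pre_ids, post_site_id = post_ids)
  }
  st <- build_aggregates(raw_bundle(bodies, sites, links, rois), dataset = "digraph")
  promote_neurons(st, promotion_predicate(status_qualifies = TRUE))
}

# random digraph spec: <= 12 bodies, <= 30 distinct ordered pairs
# (occasional autapses), weights 1..3
random_digraph <- function(seed) {
  set.seed(seed * 13 + 5)
  n <- sample(2:12, 1)
  all_pairs <- expand.grid(from = seq_len(n), to = seq_len(n))
  if (runif(1) < 0.7) all_pairs <- all_pairs[all_pairs$from != all_pairs$to, ]
  k <- min(nrow(all_pairs), sample(1:30, 1))
  sel <- all_pairs[sample.int(nrow(all_pairs), k), ]
  sel$w <- sample(1:3, k, replace = TRUE)
  list(n = n, edges = sel)
}

# ---- igraph path oracles -----------------------------------------------

path_key <- function(bodies) paste(format(bodies, scientific = FALSE, trim = TRUE),
                                   collapse = "->")

# all simple paths source -> target with <= max_len hops on connections of
# weight >= min_weight, via igraph; source == target handled like the
# implementation's contract (direct autapse only)
oracle_paths <- function(n_bodies, edges, source, target, max_len, min_weight) {
  body_ids <- 100 * seq_len(n_bodies)
  e <- edges[edges$w >= min_weight, , drop = FALSE]
  if (source == target) {
    has_autapse <- any(body_ids[e$from] == source & body_ids[e$to] == source)
    return(if (has_autapse) path_key(c(source, source)) else character())
  }
  if (nrow(e) == 0L) return(character())
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(body_ids[e$from]),
               to = as.character(body_ids[e$to])),
    directed = TRUE, vertices = as.character(body_ids))
  ps <- igraph::all_simple_paths(g, from = as.character(source),
                                 to = as.character(target), mode = "out",
                                 cutoff = max_len)
  sort(vapply(ps, function(p) path_key(as.numeric(names(p))), ""))
}

sort_paths_keys <- function(keys) {
  if (length(keys) == 0L) return(keys)
  hops <- lengths(regmatches(keys, gregexpr("->", keys)))
  pad <- vapply(strsplit(keys, "->", fixed = TRUE), function(b)
    paste(sprintf("%025.0f", as.numeric(b)), collapse = "/"), "")
  keys[order(hops, pad)]
}

oracle_shortest <- function(n_bodies, edges, source, target, min_weight) {
  all_keys <- oracle_paths(n_bodies, edges, source, target,
                           max_len = n_bodies, min_weight = min_weight)
  if (length(all_keys) == 0L) return(character())
  hops <- lengths(regmatches(all_keys, gregexpr("->", all_keys)))
  sort(all_keys[hops == min(hops)])
}

# ---- raw-bundle editing (rebuild oracle for the update log) -------------

edit_bundle_raw <- function(bundle, events) {
  bodies <- as.data.frame(bundle$bodies)
  sites <- as.data.frame(bundle$sites)
  for (e in events) {
    if (e$action == "merge") {
      bodies$size[bodies$body_id == e$target] <-
        bodies$size[bodies$body_id == e$target] +
        bodies$size[bodies$body_id == e$source]
      bodies <- bodies[bodies$body_id != e$source, ]
      sites$body_id[sites$body_id == e$source] <- e$target
    } else if (e$action == "split") {
      ns <- if (is.null(e$new_size)) 0 else e$new_size
      bodies$size[bodies$body_id == e$body] <-
        bodies$size[bodies$body_id == e$body] - ns
      bodies <- rbind(bodies, data.frame(
        body_id = e$new_body, instance = NA_character_, type = NA_character_,
        status = NA_character_, size = ns))
      sites$body_id[sites$site_id %in% unlist(e$moved_site_ids)] <- e$new_body
    } else if (e$action == "set_property") {
      v <- if (is.null(e$value)) NA_character_ else as.character(e$value)
      bodies[[e$key]][bodies$body_id == e$body] <- v
    }
  }
  links <- as.data.frame(bundle$links)
  names(links) <- c("pre_site_id", "post_site_id")
  raw_bundle(bodies, sites, links, bundle$rois, bundle$site_rois)
}

# generate a valid random edit log against a store, tracking ownership so
# every event is applicable at its position
random_edit_log <- function(store, n_events, seed) {
  set.seed(seed * 31 + 7)
  bodies <- as.data.frame(store$segments)[, c("body_id", "size")]
  sites <- as.data.frame(store$sites)[, c("site_id", "body_id")]
  events <- list()
  next_id <- max(bodies$body_id) + 1000
  for (k in seq_len(n_events)) {
    kind <- sample(c("merge", "split", "set_property"), 1,
                   prob = c(0.4, 0.35, 0.25))
    if (kind == "merge" && nrow(bodies) >= 2) {
      pick <- sample(nrow(bodies), 2)
      tgt <- bodies$body_id[pick[1]]; src <- bodies$body_id[pick[2]]
      bodies$size[pick[1]] <- bodies$size[pick[1]] + bodies$size[pick[2]]
      bodies <- bodies[-pick[2], ]
      sites$body_id[sites$body_id == src] <- tgt
      events[[length(events) + 1L]] <-
        list(action = "merge", sequence = k, target = tgt, source = src)
    } else if (kind == "split") {
      owned <- table(sites$body_id)
      cand <- as.numeric(names(owned)[owned > 0])
      if (length(cand) == 0L) next
      b <- cand[sample.int(length(cand), 1)]
      own_sites <- sites$site_id[sites$body_id == b]
      take <- sample.int(length(own_sites), 1)
      moved <- sort(own_sites[sample.int(length(own_sites), take)])
      sz <- floor(bodies$size[bodies$body_id == b] / 3)
      nb <- next_id; next_id <- next_id + 1
      bodies$size[bodies$body_id == b] <- bodies$size[bodies$body_id == b] - sz
      bodies <- rbind(bodies, data.frame(body_id = nb, size = sz))
      sites$body_id[sites$site_id %in% moved] <- nb
      events[[length(events) + 1L]] <-
        list(action = "split", sequence = k, body = b, new_body = nb,
             moved_site_ids = as.list(moved), new_size = sz)
    } else {
      b <- bodies$body_id[sample.int(nrow(bodies), 1)]
      key <- sample(c("instance", "type", "status"), 1)
      val <- sample(c("Traced", "Anchor", "edited", NA), 1)
      events[[length(events) + 1L]] <-
        list(action = "set_property", sequence = k, body = b, key = key,
             value = if (is.na(val)) NULL else val)
    }
  }
  events
}

withr_tempdir <- function() {
  d <- tempfile("cg_")
  dir.create(d)
  d
}

link_df <- function(b) {
  l <- as.data.frame(b$links)
  names(l) <- c("pre_site_id", "post_site_id")
  l
}

# write the TOY bundle files to a directory (for CLI tests)
write_toy_dir <- function(dir) {
  st <- toy_store(promote = FALSE)
  suppressWarnings(export_bundle(st, dir))
  dir
}

cli_csv <- function(args) {
  res <- run_cli_capture(args)
  testthat::expect_equal(res$status, 0L)
  data.table::fread(text = paste(res$stdout, collapse = "\n"))
}

run_cli_capture <- function(args) {
  out <- character()
  status <- suppressWarnings(
    withCallingHandlers(
      {
        out <- capture.output(st <- cg_cli(args))
        st
      },
      message = function(m) invokeRestart("muffleMessage")
    )
  )
  list(status = status, stdout = out)
}
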