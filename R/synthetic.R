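#' Configuration for a synthetic connectome world
#'
#' The generator emulates the statistical shape of an automatically
#' segmented, partially proofread EM reconstruction:
#'
#' * a *bimodal* body-size distribution -- a few large bodies that are real
#'   neurons (typed, named, status "Traced") and a much larger number of
#'   tiny anonymous fragments with only a few synapses;
#' * *polyadic* synapses -- each presynaptic T-bar drives a fan-out of
#'   postsynaptic densities drawn from a truncated geometric distribution,
#'   each post site placed within a couple of voxels of its pre site;
#' * a *hierarchical ROI layout* -- a grid of leaf boxes tiling the volume
#'   under a single root, so ancestor-closure logic is always exercised;
#' * a planted *completeness level*: every pre and every post site is
#'   independently owned by a (traced, designated) neuron with probability
#'   `traced_fraction`, otherwise by a fragment. Site-level independence
#'   makes the completeness metrics exactly binomial, so their sampling
#'   error is known in closed form.
#'
#' Fragments are capped at 1 pre and 9 post sites and sized below `1e6`
#' voxels, strictly under every default promotion threshold; neuron sizes
#' start at `2e7`, above the size threshold. The planted neuron set is
#' therefore exactly recoverable by [promote_neurons()] with the default
#' predicate.
#'
#' @param n_neurons number of planted neurons (> 0 when there are synapses).
#' @param n_fragments number of fragment bodies.
#' @param synapses_per_neuron mean presynaptic sites per neuron; total
#'   T-bar count is drawn as negative binomial with this mean.
#' @param dispersion negative-binomial size parameter for the T-bar count
#'   (larger = closer to Poisson).
#' @param fanout_prob geometric parameter of the polyadic fan-out
#'   (`1 + rgeom(fanout_prob)`, truncated at `max_fanout`).
#' @param max_fanout largest allowed fan-out per pre site.
#' @param traced_fraction probability a site belongs to a traced neuron.
#' @param roi_grid integer `c(nx, ny)` leaf-box grid under the root.
#' @param cell_edge edge length of each leaf box in voxels.
#' @param types cell type labels cycled over the neurons.
#' @param type_preference optional square matrix (rows/cols = `types`)
#'   weighting which presynaptic type connects to which postsynaptic
#'   type; default uniform.
#' @param seed integer seed; identical `(config, seed)` yields an
#'   identical bundle, byte for byte.
#' @return a `world_config` list.
#' @export
world_config <- function(n_neurons = 30L, n_fragments = 300L,
                         synapses_per_neuron = 30, dispersion = 10,
                         fanout_prob = 0.6, max_fanout = 5L,
                         traced_fraction = 0.9,
                         roi_grid = c(2L, 2L), cell_edge = 512L,
                         types = c("KC", "PN", "MBON", "LHN"),
                         type_preference = NULL, seed = 1L) {
  cfg <- list(n_neurons = as.integer(n_neurons),
              n_fragments = as.integer(n_fragments),
              synapses_per_neuron = synapses_per_neuron,
              dispersion = dispersion,
              fanout_prob = fanout_prob, max_fanout = as.integer(max_fanout),
              traced_fraction = traced_fraction,
              roi_grid = as.integer(roi_grid), cell_edge = as.integer(cell_edge),
              types = types, type_preference = type_preference,
              seed = as.integer(seed))
  if (cfg$n_neurons < 0L || cfg$n_fragments < 0L)
    cg_stop("cg_input_error", "counts must be non-negative")
  if (cfg$n_neurons == 0L && cfg$synapses_per_neuron > 0)
    cg_stop("cg_input_error", "cannot place synapses in a world with no neurons")
  if (cfg$traced_fraction < 0 || cfg$traced_fraction > 1)
    cg_stop("cg_input_error", "traced_fraction must be in [0,1]")
  if (cfg$n_fragments == 0L && cfg$traced_fraction < 1)
    cg_stop("cg_input_error",
            "traced_fraction < 1 needs fragments to own the untraced sites")
  if (!is.null(type_preference) &&
      (!is.matrix(type_preference) ||
       any(dim(type_preference) != length(types)) || any(type_preference < 0)))
    cg_stop("cg_input_error",
            "type_preference must be a non-negative types x types matrix")
  structure(cfg, class = "world_config")
}

#' Generate a synthetic connectome world
#'
#' Emits a [raw_bundle()] conforming to the ingestion schemas together
#' with its ground truth (brute-force connection weights, totals, the
#' planted neuron ids and traced fraction), and optionally writes the
#' bundle files to a directory. Deterministic under `config$seed`.
#'
#' @param config a [world_config()].
#' @param path optional directory to write the bundle files into.
#' @return list with `bundle`, `truth`, and (when written) `path`.
#' @export
generate_world <- function(config, path = NULL) {
  if (!inherits(config, "world_config")) config <- do.call(world_config, config)
  set.seed(config$seed)

  nx <- config$roi_grid[1]; ny <- config$roi_grid[2]; edge <- config$cell_edge
  vol <- c(nx * edge, ny * edge, edge)
  leaf_rows <- CJ(i = seq_len(nx), j = seq_len(ny))
  rois <- roi_spec(rbind(
    data.table(name = "brain", parent = NA_character_,
               xmin = NA_real_, ymin = NA_real_, zmin = NA_real_,
               xmax = NA_real_, ymax = NA_real_, zmax = NA_real_),
    leaf_rows[, .(name = sprintf("cell_%d_%d", i, j), parent = "brain",
                  xmin = (i - 1) * edge, ymin = (j - 1) * edge, zmin = 0,
                  xmax = i * edge, ymax = j * edge, zmax = edge)]
  ))

  n <- config$n_neurons; m <- config$n_fragments
  neuron_ids <- if (n > 0) 1000 + seq_len(n) else numeric()
  frag_ids <- if (m > 0) 500000 + seq_len(m) else numeric()
  neuron_types <- if (n > 0) config$types[(seq_len(n) - 1L) %% length(config$types) + 1L]
                  else character()
  pref <- config$type_preference
  if (is.null(pref)) {
    k <- length(config$types)
    pref <- matrix(1, k, k)
  }
  dimnames(pref) <- list(config$types, config$types)

  bodies <- rbind(
    data.table(body_id = neuron_ids,
               instance = if (n > 0) sprintf("%s_%03d", neuron_types, seq_len(n)) else character(),
               type = neuron_types,
               status = rep("Traced", n),
               size = if (n > 0) round(runif(n, 2e7, 2e8)) else numeric()),
    data.table(body_id = frag_ids, instance = NA_character_,
               type = NA_character_, status = NA_character_,
               size = if (m > 0) round(runif(m, 1e3, 1e5)) else numeric())
  )

  n_syn <- if (n > 0) sum(rnbinom(1, size = config$dispersion,
                                  mu = n * config$synapses_per_neuron)) else 0L
  p <- config$traced_fraction

  # fragment capacity slots keep every fragment under the promotion bar
  frag_pre_slots <- frag_ids                       # <=1 pre site each
  frag_post_slots <- rep(frag_ids, each = 9L)      # <=9 post sites each

  pre_owner <- numeric(n_syn)
  if (n_syn > 0) {
    on_neuron <- runif(n_syn) < p
    pre_owner[on_neuron] <- neuron_ids[sample.int(n, sum(on_neuron), replace = TRUE)]
    n_frag_pre <- sum(!on_neuron)
    if (n_frag_pre > length(frag_pre_slots))
      cg_stop("cg_input_error",
              "not enough fragments for the requested untraced pre sites")
    if (n_frag_pre > 0)
      pre_owner[!on_neuron] <-
        frag_pre_slots[sample.int(length(frag_pre_slots), n_frag_pre)]
  }

  pre_x <- if (n_syn > 0) sample.int(vol[1], n_syn, replace = TRUE) - 1L else integer()
  pre_y <- if (n_syn > 0) sample.int(vol[2], n_syn, replace = TRUE) - 1L else integer()
  pre_z <- if (n_syn > 0) sample.int(vol[3], n_syn, replace = TRUE) - 1L else integer()

  fanout <- if (n_syn > 0)
    1L + pmin(rgeom(n_syn, config$fanout_prob), config$max_fanout - 1L)
  else integer()
  n_post <- sum(fanout)
  post_of_pre <- rep(seq_len(n_syn), fanout)

  post_owner <- numeric(n_post)
  if (n_post > 0) {
    on_neuron <- runif(n_post) < p
    idx_n <- which(on_neuron)
    if (length(idx_n)) {
      # postsynaptic neuron chosen by the pre owner's type preference
      pre_t <- rep(NA_character_, n_syn)
      is_neu_pre <- pre_owner %in% neuron_ids
      pre_t[is_neu_pre] <- neuron_types[match(pre_owner[is_neu_pre], neuron_ids)]
      for (i in idx_n) {
        t_pre <- pre_t[post_of_pre[i]]
        w <- if (is.na(t_pre)) rep(1, n) else pref[t_pre, neuron_types]
        post_owner[i] <- neuron_ids[sample.int(n, 1L, prob = w)]
      }
    }
    n_frag_post <- sum(!on_neuron)
    if (n_frag_post > length(frag_post_slots))
      cg_stop("cg_input_error",
              "not enough fragments for the requested untraced post sites")
    if (n_frag_post > 0)
      post_owner[!on_neuron] <-
        frag_post_slots[sample.int(length(frag_post_slots), n_frag_post)]
  }

  jit <- function(v, lim) pmin(pmax(v + sample(-2:2, length(v), replace = TRUE), 0L),
                               lim - 1L)
  post_x <- jit(pre_x[post_of_pre], vol[1])
  post_y <- jit(pre_y[post_of_pre], vol[2])
  post_z <- jit(pre_z[post_of_pre], vol[3])

  pre_ids <- seq_len(n_syn)
  post_ids <- n_syn + seq_len(n_post)
  sites <- rbind(
    data.table(site_id = pre_ids, body_id = pre_owner, kind = "pre",
               x = pre_x, y = pre_y, z = pre_z,
               confidence = round(rbeta(n_syn, 6, 2), 3)),
    data.table(site_id = post_ids, body_id = post_owner, kind = "post",
               x = post_x, y = post_y, z = post_z,
               confidence = round(rbeta(n_post, 6, 2), 3))
  )
  links <- data.table(pre_site_id = pre_ids[post_of_pre],
                      post_site_id = post_ids)

  bundle <- raw_bundle(bodies, sites, links, rois)

  # ground truth by direct tabulation of the emitted links
  truth_w <- if (n_post > 0) {
    pair <- data.frame(pre_body = pre_owner[post_of_pre], post_body = post_owner)
    agg <- aggregate(list(weight = rep(1L, nrow(pair))),
                     by = pair[c("pre_body", "post_body")], FUN = sum)
    agg[order(agg$pre_body, agg$post_body), ]
  } else data.frame(pre_body = numeric(), post_body = numeric(),
                    weight = integer())
  truth <- list(
    connection_weights = as.data.table(truth_w),
    total_pre = n_syn, total_post = n_post,
    neuron_ids = neuron_ids, fragment_ids = frag_ids,
    traced_fraction = p,
    types = setNames(neuron_types, as.character(neuron_ids))
  )

  out <- list(bundle = bundle, truth = truth)
  if (!is.null(path)) {
    dir.create(path, recursive = TRUE, showWarnings = FALSE)
    fwrite(bodies[, .(body_id = format(body_id, scientific = FALSE, trim = TRUE),
                      instance, type, status,
                      size = format(size, scientific = FALSE, trim = TRUE))],
           file.path(path, "bodies.csv"), na = "", quote = "auto")
    fwrite(sites[, .(site_id, body_id = format(body_id, scientific = FALSE, trim = TRUE),
                     kind, x, y, z, confidence)],
           file.path(path, "synapses.csv"), na = "", quote = "auto")
    fwrite(links, file.path(path, "links.csv"), quote = "auto")
    write_rois_json(rois, file.path(path, "rois.json"))
    out$path <- path
  }
  out
}

#' The TOY worked-example fixture
#'
#' A three-body, nine-site, five-link micro-connectome used throughout
#' the documentation and tests, small enough that every aggregate can be
#' verified by hand. Bodies: 100 (type "KCa", status "Traced"), 200
#' (type "PN1", status "Traced"), and the anonymous fragment 300. Two
#' leaf ROIs, `alpha` and `beta`, tile the root `brain`. Site ids 1-4
#' are the pre sites (p1, p2, p3 on body 100; t1 on body 200) and 5-9
#' the post sites (r1, r2, r3 on 200; s1 on 300; q1 on 100); the links
#' are p1->r1, p2->r2, p2->s1, p3->r3, t1->q1, giving connection weights
#' 100->200 = 3, 100->300 = 1, 200->100 = 1.
#'
#' @return a [raw_bundle()].
#' @export
toy_bundle <- function() {
  bodies <- data.table(
    body_id = c(100, 200, 300),
    instance = c("KCa-1", "PN1-1", NA),
    type = c("KCa", "PN1", NA),
    status = c("Traced", "Traced", NA),
    size = c(2e7, 3e7, 1e4)
  )
  #              p1   p2   p3   t1   r1   r2   r3   s1   q1
  sites <- data.table(
    site_id = 1:9,
    body_id = c(100, 100, 100, 200, 200, 200, 200, 300, 100),
    kind = c(rep("pre", 4), rep("post", 5)),
    x = c(10, 20, 110, 150, 12, 120, 130, 121, 160),
    y = c(10, 10, 10, 50, 10, 10, 10, 12, 50),
    z = c(10, 10, 10, 10, 10, 10, 10, 10, 10),
    confidence = c(0.9, 0.7, 0.4, 0.9, 0.9, 0.8, 0.6, 0.5, 0.9)
  )
  links <- data.table(pre_site_id = c(1L, 2L, 2L, 3L, 4L),
                      post_site_id = c(5L, 6L, 8L, 7L, 9L))
  rois <- roi_spec(data.table(
    name = c("brain", "alpha", "beta"),
    parent = c(NA, "brain", "brain"),
    xmin = c(NA, 0, 100), ymin = c(NA, 0, 0), zmin = c(NA, 0, 0),
    xmax = c(NA, 100, 200), ymax = c(NA, 100, 100), zmax = c(NA, 100, 100)
  ))
  raw_bundle(bodies, sites, links, rois)
}

#' @rdname toy_bundle
#' @param promote designate neurons with the default predicate.
#' @return `toy_store`: the TOY fixture ingested into a [graph_store].
#' @export
toy_store <- function(promote = TRUE) {
  store <- build_aggregates(toy_bundle(), dataset = "toy", version = "1.0")
  if (promote) store <- promote_neurons(store)
  store
}
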