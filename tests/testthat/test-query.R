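toyq <- toy_store()

test_that("partner tables match the hand enumeration, with thresholds", {
  p <- partners(toyq, 100, "outgoing", min_weight = 2, scope = "segments")
  expect_equal(p$partner_body, 200)
  expect_equal(p$weight, 3L)
  p <- partners(toyq, 100, "outgoing", scope = "segments")
  expect_equal(p$partner_body, c(200, 300))
  expect_equal(p$weight, c(3L, 1L))
  # confidence filtering recomputes from links: only p1->r1 has both >= 0.8
  p <- partners(toyq, 100, "outgoing", min_confidence = 0.8)
  expect_equal(p$partner_body, 200)
  expect_equal(p$weight, 1L)
  expect_error(partners(toyq, 5, "outgoing"), class = "cg_not_found")
})

test_that("partner weights from aggregates equal recomputation from links", {
  for (seed in 1:10) {
    st <- world_store(small_world(seed))
    lf <- circuitgraph:::link_frame(st)
    for (b in utils::head(st$segments$body_id[st$segments$is_neuron], 4)) {
      got <- partners(st, b, "outgoing", scope = "segments")
      raw <- table(lf$post_body[lf$pre_body == b])
      expect_equal(nrow(got), length(raw))
      expect_equal(got$weight[order(got$partner_body)],
                   as.integer(raw[order(as.numeric(names(raw)))]))
      # flow conservation: summed outgoing weights = body's pre-side links
      expect_equal(sum(got$weight), sum(lf$pre_body == b))
      got_in <- partners(st, b, "incoming", scope = "segments")
      expect_equal(sum(got_in$weight), sum(lf$post_body == b))
    }
  }
})

test_that("traced-partner weight sums case-insensitively over statuses", {
  expect_equal(traced_partner_weight(toyq, 100, "outgoing"), 3L)
  expect_equal(traced_partner_weight(toyq, 300, "outgoing"), 0L)
  for (seed in 1:5) {
    st <- world_store(small_world(seed))
    conns <- as.data.frame(st$connections)
    seg <- as.data.frame(st$segments)
    for (b in utils::head(seg$body_id, 3)) {
      rows <- conns[conns$pre_body == b, ]
      stt <- seg$status[match(rows$post_body, seg$body_id)]
      want <- sum(rows$weight[!is.na(stt) & tolower(stt) == "traced"])
      expect_equal(traced_partner_weight(st, b, "outgoing"), want)
    }
  }
})

test_that("path enumeration matches the TOY enumeration and its contracts", {
  p <- find_paths(toyq, 100, 300, max_len = 2, scope = "segments")
  expect_length(p, 1L)
  expect_equal(p[[1]]$bodies, c(100, 300))
  expect_equal(p[[1]]$weights, 1L)
  # no autapse on 100, so no source==target path
  expect_length(find_paths(toyq, 100, 100, max_len = 3, scope = "segments"), 0L)
  sp <- find_shortest_paths(toyq, 100, 300, scope = "segments")
  expect_length(sp, 1L)
  expect_equal(sp[[1]]$bodies, c(100, 300))
  expect_length(find_shortest_paths(toyq, 300, 200, scope = "segments"), 0L)
  expect_error(find_paths(toyq, 100, 999, max_len = 2), class = "cg_not_found")
})

test_that("path search agrees with exhaustive igraph enumeration", {
  skip_if_not_installed("igraph")
  for (seed in 1:40) {
    dg <- random_digraph(seed)
    st <- edge_store(dg$n, dg$edges)
    set.seed(seed + 999)
    for (rep in 1:3) {
      src <- 100 * sample.int(dg$n, 1)
      tgt <- 100 * sample.int(dg$n, 1)
      max_len <- sample(1:4, 1)
      min_w <- sample(1:2, 1)
      got <- find_paths(st, src, tgt, max_len, min_weight = min_w)
      got_keys <- vapply(got, function(p) path_key(p$bodies), "")
      want_keys <- oracle_paths(dg$n, dg$edges, src, tgt, max_len, min_w)
      expect_identical(sort(got_keys), sort(want_keys))
      expect_identical(got_keys, sort_paths_keys(got_keys))

      got_s <- find_shortest_paths(st, src, tgt, min_weight = min_w)
      got_s_keys <- sort(vapply(got_s, function(p) path_key(p$bodies), ""))
      expect_identical(got_s_keys,
                       oracle_shortest(dg$n, dg$edges, src, tgt, min_w))
    }
  }
})

test_that("path weights report the traversed connection strengths", {
  edges <- data.frame(from = c(1, 2, 1), to = c(2, 3, 3), w = c(5, 2, 7))
  st <- edge_store(3, edges)
  p <- find_paths(st, 100, 300, max_len = 2)
  expect_equal(lapply(p, `[[`, "bodies"),
               list(c(100, 300), c(100, 200, 300)))
  expect_equal(lapply(p, `[[`, "weights"), list(7L, c(5L, 2L)))
})

test_that("the expansion budget raises rather than truncating silently", {
  # complete digraph on 9 bodies has huge simple-path counts
  pairs <- expand.grid(from = 1:9, to = 1:9)
  pairs <- pairs[pairs$from != pairs$to, ]
  pairs$w <- 1L
  st <- edge_store(9, pairs)
  expect_error(find_paths(st, 100, 900, max_len = 8, expansion_cap = 50),
               class = "cg_budget_error")
  expect_length(find_paths(st, 100, 900, max_len = 1, expansion_cap = 1e5), 1L)
})

test_that("reciprocity is symmetric and threshold-aware", {
  expect_true(is_reciprocal(toyq, 100, 200))
  expect_false(is_reciprocal(toyq, 100, 300))
  expect_false(is_reciprocal(toyq, 100, 200, min_weight = 2))
  for (seed in 1:5) {
    st <- world_store(small_world(seed))
    ids <- utils::head(st$segments$body_id, 6)
    for (a in ids) for (b in ids)
      expect_identical(is_reciprocal(st, a, b), is_reciprocal(st, b, a))
  }
})

test_that("region projections pick neurons with inputs here, outputs there", {
  expect_equal(roi_projection_neurons(toyq, "alpha", "beta"), 200)
  expect_equal(roi_projection_neurons(toyq, "beta", "alpha"), 100)
  expect_error(roi_projection_neurons(toyq, "gamma", "beta"),
               class = "cg_input_error")
})

test_that("common partners intersect over the whole query set", {
  got <- common_partners(toyq, c(200, 300), "incoming", scope = "segments")
  expect_equal(got$partner_body, 100)
  expect_equal(got$weight_200, 3L)
  expect_equal(got$weight_300, 1L)
  expect_equal(nrow(common_partners(toyq, c(100, 200), "outgoing",
                                    scope = "segments")), 0L)
  # a singleton set degenerates to the plain partner table
  one <- common_partners(toyq, 100, "outgoing", scope = "segments")
  tab <- partners(toyq, 100, "outgoing", scope = "segments")
  expect_setequal(one$partner_body, tab$partner_body)
})

test_that("ROI-profile similarity is scale-invariant cosine", {
  # two neurons with proportional profiles across the same leaves
  bodies <- data.frame(body_id = c(1, 2, 3), instance = NA, type = "T",
                       status = "Traced", size = 1e8)
  mk_site <- function(id, body, kind, x) data.frame(
    site_id = id, body_id = body, kind = kind, x = x, y = 5L, z = 5L,
    confidence = 0.9)
  # body 1: 2 pre in A, 4 pre in B; body 2: 1 pre in A, 2 pre in B
  # body 3: pre only in C (disjoint support)
  sites <- rbind(
    mk_site(1:2, 1, "pre", 5L), mk_site(3:6, 1, "pre", 15L),
    mk_site(7, 2, "pre", 5L), mk_site(8:9, 2, "pre", 15L),
    mk_site(10, 3, "pre", 25L))
  rois <- data.frame(name = c("root", "A", "B", "C"),
                     parent = c(NA, "root", "root", "root"),
                     xmin = c(NA, 0, 10, 20), ymin = c(NA, 0, 0, 0),
                     zmin = c(NA, 0, 0, 0), xmax = c(NA, 10, 20, 30),
                     ymax = c(NA, 10, 10, 10), zmax = c(NA, 10, 10, 10))
  links <- data.frame(pre_site_id = integer(), post_site_id = integer())
  st <- promote_neurons(build_aggregates(raw_bundle(bodies, sites, links, rois)))
  sim <- similar_by_roi_profile(st, 1, top_k = 5)
  expect_equal(sim$body_id, c(2, 3))
  expect_equal(sim$similarity, c(1, 0), tolerance = 1e-12)

  zero <- promote_neurons(build_aggregates(raw_bundle(
    rbind(bodies, data.frame(body_id = 4, instance = NA, type = "T",
                             status = "Traced", size = 1e8)),
    sites, links, rois)))
  expect_error(similar_by_roi_profile(zero, 4), class = "cg_undefined")
})

test_that("cell-type summaries score connectivity fingerprints", {
  res <- cell_type_summary(toyq, "KCa")
  expect_equal(res$members, 100)
  expect_equal(unname(res$similarity), matrix(1))
  expect_error(cell_type_summary(toyq, "nope"), class = "cg_not_found")

  # two members with identical partners -> 1; partners of disjoint types -> 0
  edges <- data.frame(from = c(1, 2, 3), to = c(5, 5, 6), w = c(2, 2, 3))
  st <- edge_store(6, edges)
  st$segments[st$segments$body_id %in% c(100, 200, 300), "type"] <- "twin"
  st$segments[st$segments$body_id == 600, "type"] <- "other"
  sim <- cell_type_summary(st, "twin")$similarity
  expect_equal(sim["100", "200"], 1)
  expect_equal(sim["100", "300"], 0)
  expect_true(isSymmetric(sim))
  expect_equal(diag(sim), setNames(rep(1, 3), c("100", "200", "300")))
})

test_that("region connectivity matrices follow their two definitions", {
  cm <- roi_connectivity_matrix(toyq, "count")
  expect_equal(cm["alpha", "beta"], 1)
  expect_equal(cm["beta", "alpha"], 1)
  expect_equal(cm["alpha", "alpha"], 0)
  # every neuron with inputs in `from` and outputs in `to` counts: both
  # 100 (q1 in, p3 out) and 200 (r2/r3 in, t1 out) project beta -> beta
  expect_equal(cm["beta", "beta"], 2)
  # count mode is the projection count, everywhere
  for (rf in rownames(cm)) for (rt in colnames(cm))
    expect_equal(cm[rf, rt],
                 length(roi_projection_neurons(toyq, rf, rt)))

  wm <- roi_connectivity_matrix(toyq, "weighted")
  # 200's contribution to (alpha, beta): input share 1/3 times 1 output
  expect_equal(wm["alpha", "beta"], 1 / 3, tolerance = 1e-12)
})

test_that("type counting respects the full-match regex convention", {
  expect_equal(count_types_matching(toyq, "KC.*"), 1L)
  expect_equal(count_types_matching(toyq, ".*"), 2L)
  expect_equal(count_types_matching(toyq, "ZZZ"), 0L)
  expect_error(count_types_matching(toyq, "("), class = "cg_input_error")
})
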