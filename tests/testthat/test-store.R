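toy <- toy_store()

test_that("segment records carry counts, flags, and per-ROI tallies", {
  rec <- get_body(toy, 100)
  expect_equal(rec$pre_count, 3L)
  expect_equal(rec$post_count, 1L)
  expect_true(rec$is_neuron)
  expect_equal(rec$roi_info$alpha, list(pre = 2L, post = 0L))
  expect_equal(rec$roi_info$beta, list(pre = 1L, post = 1L))
  expect_equal(rec$roi_info$brain, list(pre = 3L, post = 1L))

  expect_error(get_body(toy, 999), class = "cg_not_found")
  empty <- build_aggregates(raw_bundle(
    data.frame(body_id = numeric(), instance = character(), type = character(),
               status = character(), size = numeric()),
    data.frame(site_id = integer(), body_id = numeric(), kind = character(),
               x = integer(), y = integer(), z = integer(),
               confidence = numeric()),
    data.frame(pre_site_id = integer(), post_site_id = integer()),
    data.frame(name = "root", parent = NA)))
  expect_error(get_body(empty, 1), class = "cg_not_found")
})

test_that("neuron search applies all criteria conjunctively", {
  expect_equal(neurons_matching(toy, type_regex = "KC.*")$body_id, 100)
  expect_equal(neurons_matching(toy, roi_any = "alpha")$body_id, c(100, 200))
  expect_equal(nrow(neurons_matching(toy, min_size = 1e12,
                                     scope = "segments")), 0L)
  # unanchored patterns are full matches; anchored ones keep their meaning
  expect_equal(nrow(neurons_matching(toy, type_regex = "KC")), 0L)
  expect_equal(neurons_matching(toy, type_regex = "^KC")$body_id, 100)
  # status comparison is case-insensitive
  expect_equal(neurons_matching(toy, status = "traced")$body_id, c(100, 200))
  expect_error(neurons_matching(toy, type_regex = "("), class = "cg_input_error")
  expect_error(neurons_matching(toy, roi_any = "gamma"), class = "cg_input_error")
})

test_that("neuron scope equals segment scope filtered to designated neurons", {
  for (seed in 1:8) {
    st <- world_store(small_world(seed))
    for (r in roi_leaves(st$rois)[1:2]) {
      a <- neurons_matching(st, roi_any = r, scope = "neurons")
      b <- neurons_matching(st, roi_any = r, scope = "segments")
      expect_identical(a$body_id, b$body_id[b$is_neuron])
    }
    a <- neurons_matching(st, min_size = 1e7, scope = "neurons")
    b <- neurons_matching(st, min_size = 1e7, scope = "segments")
    expect_identical(a$body_id, b$body_id[b$is_neuron])
  }
})

test_that("box queries are half-open and agree with a linear scan", {
  expect_equal(synapses_in_box(toy, c(0, 0, 0), c(100, 100, 100))$site_id,
               c(1L, 2L, 5L))
  expect_equal(nrow(synapses_in_box(toy, c(0, 0, 0), c(0, 0, 0))), 0L)
  expect_error(synapses_in_box(toy, c(10, 0, 0), c(0, 0, 0)),
               class = "cg_input_error")

  for (seed in 1:10) {
    w <- small_world(seed)
    st <- world_store(w)
    set.seed(seed)
    for (rep in 1:5) {
      lo <- sapply(c(2048, 1024, 512), function(m) sample.int(m, 1) - 1)
      hi <- lo + sapply(c(600, 600, 600), function(m) sample.int(m, 1))
      got <- synapses_in_box(st, lo, hi)
      s <- as.data.frame(st$sites)
      want <- s[s$x >= lo[1] & s$x < hi[1] & s$y >= lo[2] & s$y < hi[2] &
                s$z >= lo[3] & s$z < hi[3], ]
      expect_identical(got$site_id, sort(want$site_id))
    }
  }
})

test_that("connection lookups return stored aggregates or absence", {
  conn <- get_connection(toy, 100, 200)
  expect_equal(conn$weight, 3L)
  expect_equal(conn$roi_info$alpha$post, 1L)
  expect_equal(conn$roi_info$beta$post, 2L)
  expect_equal(conn$roi_info$brain$post, 3L)
  expect_null(get_connection(toy, 300, 100))
  expect_equal(get_connection(toy, 200, 100)$weight, 1L)
  expect_error(get_connection(toy, 1, 200), class = "cg_not_found")
})

test_that("synapse sets cover the links between a pair exactly", {
  out_set <- synapse_sets(toy, owner = 100, partner = 200,
                          direction = "outgoing")
  expect_equal(out_set$site_ids[[1]], c(1L, 2L, 3L))
  in_set <- synapse_sets(toy, owner = 200, partner = 100,
                         direction = "incoming")
  expect_equal(in_set$site_ids[[1]], c(5L, 6L, 7L))

  # weight(A->B) equals the size of B's incoming set w.r.t. A, everywhere
  for (seed in 1:5) {
    st <- world_store(small_world(seed))
    sets <- synapse_sets(st)
    inc <- sets[sets$direction == "incoming", ]
    conns <- as.data.frame(st$connections)
    expect_equal(nrow(inc), nrow(conns))
    m <- merge(conns,
               data.frame(pre_body = inc$partner_body,
                          post_body = inc$owner_body,
                          n = lengths(inc$site_ids)),
               by = c("pre_body", "post_body"))
    expect_true(all(m$weight == m$n))
  }
})

test_that("every owned site belongs to its synapse-set owner", {
  st <- world_store(small_world(3))
  sets <- synapse_sets(st)
  owner_of <- setNames(st$sites$body_id, as.character(st$sites$site_id))
  for (i in seq_len(nrow(sets)))
    expect_true(all(owner_of[as.character(sets$site_ids[[i]])] ==
                    sets$owner_body[i]))
})

test_that("stores pass the full consistency check and equality is exact", {
  expect_true(store_check(toy))
  expect_true(store_equal(toy, toy_store()))
  other <- toy_store()
  other$connections <- data.table::copy(other$connections)
  other$connections[1, weight := 99L]
  expect_false(store_equal(toy, other))
  expect_error(store_check(other), class = "cg_input_error")
})
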