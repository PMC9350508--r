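test_that("the TOY bundle loads with the expected cardinalities", {
  b <- toy_bundle()
  expect_equal(nrow(b$bodies), 3L)
  expect_equal(nrow(b$sites), 9L)
  expect_equal(nrow(b$links), 5L)

  dir <- withr_tempdir()
  write_toy_dir(dir)
  b2 <- suppressWarnings(load_bundle(dir))
  expect_equal(nrow(b2$bodies), 3L)
  expect_equal(nrow(b2$sites), 9L)
  expect_equal(nrow(b2$links), 5L)
})

test_that("referential-integrity violations are reported with row numbers", {
  b <- toy_bundle()
  bad_links <- rbind(as.data.frame(b$links),
                     data.frame(pre_site = 1L, post_site = 777L))
  names(bad_links) <- c("pre_site_id", "post_site_id")
  err <- expect_error(
    raw_bundle(b$bodies, b$sites, bad_links, b$rois),
    class = "cg_ingest_error")
  expect_match(conditionMessage(err), "links row 6")
  expect_match(conditionMessage(err), "777")

  # duplicate ids, dangling body, wrong polarity, double-parented post site
  dup_bodies <- rbind(as.data.frame(b$bodies), as.data.frame(b$bodies)[1, ])
  expect_error(raw_bundle(dup_bodies, b$sites, link_df(b), b$rois),
               class = "cg_ingest_error")
  orphan <- as.data.frame(b$sites); orphan$body_id[1] <- 12345
  expect_error(raw_bundle(b$bodies, orphan, link_df(b), b$rois),
               class = "cg_ingest_error")
  swapped <- link_df(b); swapped$pre_site_id[1] <- 5L
  expect_error(raw_bundle(b$bodies, b$sites, swapped, b$rois),
               class = "cg_ingest_error")
  doubled <- rbind(link_df(b), data.frame(pre_site_id = 3L, post_site_id = 5L))
  expect_error(raw_bundle(b$bodies, b$sites, doubled, b$rois),
               class = "cg_ingest_error")
})

test_that("header-only tables yield an empty bundle and an empty store", {
  b <- raw_bundle(
    data.frame(body_id = numeric(), instance = character(), type = character(),
               status = character(), size = numeric()),
    data.frame(site_id = integer(), body_id = numeric(), kind = character(),
               x = integer(), y = integer(), z = integer(),
               confidence = numeric()),
    data.frame(pre_site_id = integer(), post_site_id = integer()),
    data.frame(name = "root", parent = NA))
  st <- build_aggregates(b)
  expect_equal(nrow(st$segments), 0L)
  expect_equal(nrow(st$connections), 0L)
  expect_equal(st$meta$total_pre, 0L)
  expect_true(store_check(st))
})

test_that("ROI assignment closes memberships over the hierarchy", {
  b <- toy_bundle()
  memb <- assign_rois(b$sites, b$rois)
  expect_setequal(memb[memb$site_id == 1, roi], c("alpha", "brain"))  # p1
  expect_setequal(memb[memb$site_id == 3, roi], c("beta", "brain"))   # p3

  # a site outside every leaf box has no memberships
  outside <- data.frame(site_id = 99L, body_id = 100, kind = "pre",
                        x = 250L, y = 10L, z = 10L, confidence = 0.5)
  memb2 <- assign_rois(rbind(as.data.frame(b$sites), outside), b$rois)
  expect_equal(nrow(memb2[memb2$site_id == 99]), 0L)

  # explicit table wins over geometry (with a warning) and is closed too
  tab <- data.frame(site_id = 3L, roi_name = "beta")
  expect_warning(memb3 <- assign_rois(b$sites, b$rois, tab),
                 "geometry ignored")
  expect_setequal(memb3$roi, c("beta", "brain"))
  expect_error(
    suppressWarnings(assign_rois(b$sites, b$rois,
                                 data.frame(site_id = 3L, roi_name = "nope"))),
    class = "cg_input_error")
})

test_that("building aggregates reproduces the hand-enumerated TOY values", {
  st <- toy_store(promote = FALSE)
  conns <- as.data.frame(st$connections)
  expect_equal(conns[order(conns$pre_body, conns$post_body), "weight"],
               c(3L, 1L, 1L))  # 100->200, 100->300, 200->100
  expect_equal(st$meta$total_pre, 4L)
  expect_equal(st$meta$total_post, 5L)
  expect_store_matches_oracle(st, toy_bundle())

  # idempotence: rebuilding yields an identical store
  expect_true(store_equal(st, build_aggregates(toy_bundle(), dataset = "toy")))
})

test_that("promotion designates exactly the predicate's segments", {
  st <- toy_store(promote = FALSE)
  st <- promote_neurons(st, promotion_predicate(min_pre = 2, min_post = 3,
                                                status_qualifies = TRUE))
  expect_equal(st$segments[st$segments$is_neuron == TRUE, body_id], c(100, 200))
  expect_equal(sum(st$segments$is_neuron), 2L)

  st0 <- promote_neurons(st, promotion_predicate(min_size = Inf))
  expect_equal(sum(st0$segments$is_neuron), 0L)

  # predicate-scan oracle on bimodal synthetic worlds
  for (seed in 1:6) {
    w <- small_world(seed)
    stw <- promote_neurons(world_store(w, promote = FALSE))
    seg <- as.data.frame(stw$segments)
    want <- seg$size >= 1e7 | seg$pre_count >= 2 | seg$post_count >= 10 |
      (!is.na(seg$status) & seg$status != "")
    expect_identical(seg$is_neuron, want)
    expect_setequal(seg$body_id[seg$is_neuron], w$truth$neuron_ids)
  }
})

test_that("promotion is monotone: adding sites never demotes", {
  st <- world_store(small_world(2))
  pred <- default_promotion_predicate()
  before <- st$segments$body_id[st$segments$is_neuron]
  # graft extra synapses onto every neuron via a merge from a fragment
  frag <- st$segments$body_id[!st$segments$is_neuron][1]
  target <- before[1]
  st2 <- promote_neurons(apply_merge(st, target, frag), pred)
  after <- st2$segments$body_id[st2$segments$is_neuron]
  expect_true(all(setdiff(before, frag) %in% after))
})

test_that("export -> load -> rebuild is the identity on the TOY store", {
  st <- toy_store()
  dir <- withr_tempdir()
  export_bundle(st, dir)
  for (f in c("bodies.csv", "synapses.csv", "links.csv", "rois.json",
              "synapse_rois.csv", "connections.csv"))
    expect_true(file.exists(file.path(dir, f)))
  st2 <- promote_neurons(suppressWarnings(
    build_aggregates(load_bundle(dir), dataset = "toy")))
  expect_true(store_equal(st, st2))

  # the derived connections.csv serializes roi_info as a JSON string
  cc <- read.csv(file.path(dir, "connections.csv"), stringsAsFactors = FALSE)
  info <- jsonlite::fromJSON(cc$roi_info[cc$pre_body == 100 & cc$post_body == 200])
  expect_equal(info$beta$post, 2L)
})

test_that("an empty store exports header-only tables", {
  b <- raw_bundle(
    data.frame(body_id = numeric(), instance = character(), type = character(),
               status = character(), size = numeric()),
    data.frame(site_id = integer(), body_id = numeric(), kind = character(),
               x = integer(), y = integer(), z = integer(),
               confidence = numeric()),
    data.frame(pre_site_id = integer(), post_site_id = integer()),
    data.frame(name = "root", parent = NA))
  dir <- withr_tempdir()
  export_bundle(build_aggregates(b), dir)
  expect_equal(nrow(read.csv(file.path(dir, "bodies.csv"))), 0L)
  expect_equal(nrow(read.csv(file.path(dir, "links.csv"))), 0L)
})
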