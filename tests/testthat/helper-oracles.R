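# Independent brute-force oracles, written in plain base R on the raw
# bundle tables so they share no code with the data.table aggregation
# pipeline they check.

orc_owner <- function(bundle, site_ids) {
  bundle$sites$body_id[match(site_ids, bundle$sites$site_id)]
}

# connection weights by direct tabulation of the link list
orc_weights <- function(bundle) {
  l <- as.data.frame(bundle$links)
  if (nrow(l) == 0L)
    return(data.frame(pre_body = numeric(), post_body = numeric(),
                      weight = integer()))
  pre_b <- orc_owner(bundle, l$pre_site)
  post_b <- orc_owner(bundle, l$post_site)
  agg <- aggregate(list(weight = rep(1L, length(pre_b))),
                   by = list(pre_body = pre_b, post_body = post_b), FUN = sum)
  agg[order(agg$pre_body, agg$post_body), ]
}

# site -> ROI memberships (leaf geometry or explicit table, ancestor-closed)
orc_site_rois <- function(bundle) {
  spec <- as.data.frame(bundle$rois)
  parent_of <- setNames(spec$parent, spec$name)
  ancestors <- function(nm) {
    chain <- nm
    while (!is.na(parent_of[[chain[length(chain)]]]))
      chain <- c(chain, parent_of[[chain[length(chain)]]])
    chain
  }
  s <- as.data.frame(bundle$sites)
  leaf_names <- setdiff(spec$name, spec$parent[!is.na(spec$parent)])
  rows <- list()
  if (!is.null(bundle$site_rois)) {
    tab <- as.data.frame(bundle$site_rois)
    for (i in seq_len(nrow(tab)))
      for (a in ancestors(tab$roi_name[i]))
        rows[[length(rows) + 1L]] <- c(tab$site_id[i], a)
  } else {
    for (ln in leaf_names) {
      b <- spec[spec$name == ln, ]
      if (is.na(b$xmin)) next
      inside <- s$x >= b$xmin & s$x < b$xmax & s$y >= b$ymin & s$y < b$ymax &
                s$z >= b$zmin & s$z < b$zmax
      for (sid in s$site_id[inside])
        for (a in ancestors(ln))
          rows[[length(rows) + 1L]] <- c(sid, a)
    }
  }
  if (length(rows) == 0L)
    return(data.frame(site_id = integer(), roi = character()))
  df <- unique(data.frame(site_id = as.integer(sapply(rows, `[`, 1)),
                          roi = sapply(rows, `[`, 2)))
  df[order(df$site_id, df$roi), ]
}

# per-body per-ROI pre/post tallies
orc_seg_tallies <- function(bundle, memb = orc_site_rois(bundle)) {
  s <- as.data.frame(bundle$sites)
  if (nrow(memb) == 0L)
    return(data.frame(body_id = numeric(), roi = character(),
                      pre = integer(), post = integer()))
  m <- merge(memb, s[, c("site_id", "body_id", "kind")], by = "site_id")
  pre <- aggregate(list(pre = as.integer(m$kind == "pre")),
                   by = list(body_id = m$body_id, roi = m$roi), FUN = sum)
  post <- aggregate(list(post = as.integer(m$kind == "post")),
                    by = list(body_id = m$body_id, roi = m$roi), FUN = sum)
  out <- merge(pre, post, by = c("body_id", "roi"))
  out <- out[out$pre + out$post > 0, ]
  out[order(out$body_id, out$roi), ]
}

# connection-level ROI tallies: post sites by location, distinct pre sites
orc_conn_tallies <- function(bundle, memb = orc_site_rois(bundle)) {
  l <- as.data.frame(bundle$links)
  empty <- data.frame(pre_body = numeric(), post_body = numeric(),
                      roi = character(), pre = integer(), post = integer())
  if (nrow(l) == 0L) return(empty)
  l$pre_body <- orc_owner(bundle, l$pre_site)
  l$post_body <- orc_owner(bundle, l$post_site)
  post_m <- merge(l, memb, by.x = "post_site", by.y = "site_id")
  post_t <- if (nrow(post_m)) aggregate(
    list(post = rep(1L, nrow(post_m))),
    by = list(pre_body = post_m$pre_body, post_body = post_m$post_body,
              roi = post_m$roi), FUN = sum) else empty[, c(1:3, 5)]
  upre <- unique(l[, c("pre_body", "post_body", "pre_site")])
  pre_m <- merge(upre, memb, by.x = "pre_site", by.y = "site_id")
  pre_t <- if (nrow(pre_m)) aggregate(
    list(pre = rep(1L, nrow(pre_m))),
    by = list(pre_body = pre_m$pre_body, post_body = pre_m$post_body,
              roi = pre_m$roi), FUN = sum) else empty[, 1:4]
  out <- merge(pre_t, post_t, by = c("pre_body", "post_body", "roi"), all = TRUE)
  out$pre[is.na(out$pre)] <- 0L
  out$post[is.na(out$post)] <- 0L
  out[order(out$pre_body, out$post_body, out$roi), ]
}

orc_totals <- function(bundle) {
  list(pre = sum(bundle$sites$kind == "pre"),
       post = sum(bundle$sites$kind == "post"))
}

# ---- comparison helper -------------------------------------------------

expect_same_table <- function(got, want, ...) {
  got <- as.data.frame(got); want <- as.data.frame(want)
  want <- want[, names(got), drop = FALSE]
  sort_all <- function(d) {
    if (nrow(d)) d <- d[do.call(order, d), , drop = FALSE]
    rownames(d) <- NULL
    d
  }
  g <- sort_all(got); w <- sort_all(want)
  for (cn in names(g)) if (is.numeric(g[[cn]])) {
    g[[cn]] <- as.numeric(g[[cn]]); w[[cn]] <- as.numeric(w[[cn]])
  }
  expect_equal(g, w, ignore_attr = TRUE, ...)
}

# full aggregate check of a store against the oracle recomputation
expect_store_matches_oracle <- function(store, bundle) {
  expect_same_table(store$connections, orc_weights(bundle))
  memb <- orc_site_rois(bundle)
  expect_same_table(store$seg_roi, orc_seg_tallies(bundle, memb))
  expect_same_table(store$conn_roi, orc_conn_tallies(bundle, memb))
  tot <- orc_totals(bundle)
  expect_identical(store$meta$total_pre, tot$pre)
  expect_identical(store$meta$total_post, tot$post)
  cnt <- table(factor(bundle$sites$kind, c("pre", "post")),
               dnn = NULL)
  expect_identical(sum(store$segments$pre_count), as.integer(cnt[["pre"]]))
  expect_identical(sum(store$segments$post_count), as.integer(cnt[["post"]]))
}
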