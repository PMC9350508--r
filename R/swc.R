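#' Read a neuron skeleton in SWC format
#'
#' SWC is the field-standard ball-and-stick morphology format: one node per
#' line with seven whitespace-separated columns
#' `node_id structure x y z radius parent_id`, `#` comment lines, and
#' `parent_id = -1` marking roots. Parent references may point forwards;
#' the node order of the file is preserved. The structure code is carried
#' opaquely (no soma/axon semantics are enforced).
#'
#' @param x path to an `.swc` file, or SWC text (a single string with
#'   newlines, or a character vector of lines).
#' @param body_id optional body id to attach to the skeleton.
#' @return an object of class `swc_skeleton`: a list with `nodes`
#'   (data.table `node_id, structure, x, y, z, radius, parent_id`) and
#'   `body_id`.
#' @export
read_swc <- function(x, body_id = NA_integer_) {
  lines <- if (length(x) == 1L && !grepl("\n", x, fixed = TRUE) && file.exists(x))
    readLines(x) else unlist(strsplit(x, "\n", fixed = TRUE))
  lineno <- seq_along(lines)
  keep <- !grepl("^\\s*(#|$)", lines)
  lines <- lines[keep]; lineno <- lineno[keep]

  if (length(lines) == 0L)
    return(swc_skeleton(data.table(
      node_id = integer(), structure = integer(), x = numeric(), y = numeric(),
      z = numeric(), radius = numeric(), parent_id = integer()), body_id))

  toks <- strsplit(trimws(lines), "\\s+")
  nfield <- lengths(toks)
  if (any(nfield != 7L))
    cg_stop("cg_format_error", "SWC line %d: expected 7 columns, found %d",
            lineno[which(nfield != 7L)[1]], nfield[nfield != 7L][1])
  m <- matrix(suppressWarnings(as.numeric(unlist(toks))), ncol = 7L, byrow = TRUE)
  if (anyNA(m))
    cg_stop("cg_format_error", "SWC line %d: non-numeric field",
            lineno[which(rowSums(is.na(m)) > 0)[1]])

  nodes <- data.table(
    node_id = as.integer(m[, 1]), structure = as.integer(m[, 2]),
    x = m[, 3], y = m[, 4], z = m[, 5], radius = m[, 6],
    parent_id = as.integer(m[, 7])
  )
  if (anyDuplicated(nodes$node_id))
    cg_stop("cg_format_error", "SWC line %d: duplicate node id %d",
            lineno[which(duplicated(nodes$node_id))[1]],
            nodes$node_id[duplicated(nodes$node_id)][1])
  dangling <- !(nodes$parent_id == -1L | nodes$parent_id %in% nodes$node_id)
  if (any(dangling))
    cg_stop("cg_format_error", "SWC line %d: parent %d does not exist",
            lineno[which(dangling)[1]], nodes$parent_id[dangling][1])

  # cycle check: follow parent chains; any chain longer than n nodes loops
  parent_of <- setNames(nodes$parent_id, as.character(nodes$node_id))
  n <- nrow(nodes)
  for (start in nodes$node_id) {
    cur <- start; steps <- 0L
    while (cur != -1L) {
      steps <- steps + 1L
      if (steps > n)
        cg_stop("cg_format_error", "SWC skeleton contains a cycle through node %d", start)
      cur <- parent_of[[as.character(cur)]]
    }
  }
  swc_skeleton(nodes, body_id)
}

swc_skeleton <- function(nodes, body_id = NA_integer_) {
  structure(list(nodes = as.data.table(nodes), body_id = as.integer(body_id)),
            class = "swc_skeleton")
}

#' @export
print.swc_skeleton <- function(x, ...) {
  cat(sprintf("SWC skeleton: %d nodes, %d root(s)%s\n",
              nrow(x$nodes), sum(x$nodes$parent_id == -1L),
              if (is.na(x$body_id)) "" else sprintf(" (body %d)", x$body_id)))
  invisible(x)
}

#' Write a skeleton as SWC text
#'
#' Inverse of [read_swc()]: `read_swc(write_swc(s))` reproduces `s` exactly
#' (comments and surplus whitespace are not representable and are dropped
#' on read).
#'
#' @param skeleton an `swc_skeleton`.
#' @param path optional file path; when given the text is also written there.
#' @return the SWC text as a character vector of lines, invisibly when
#'   `path` is supplied.
#' @export
write_swc <- function(skeleton, path = NULL) {
  n <- skeleton$nodes
  num <- function(v) vapply(v, function(e) format(e, scientific = FALSE, trim = TRUE), "")
  lines <- paste(n$node_id, n$structure, num(n$x), num(n$y), num(n$z),
                 num(n$radius), n$parent_id)
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}
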