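#' Neuron skeletons
#'
#' A skeleton is a rooted tree of 3-D treenodes with radii, the standard
#' representation of a traced neuron. Internally every coordinate is in
#' nanometres (the FAFB convention). The node table is a tibble with columns
#' `node_id`, `parent_id` (`NA` for the root), `x`, `y`, `z`, `radius`;
#' identifiers are opaque strings.
#'
#' @param nodes data frame with columns `node_id`, `parent_id`, `x`, `y`, `z`,
#'   `radius`. `parent_id` is `NA` for the single root.
#' @param skeleton_id identifier for the neuron.
#' @param soma_node node id of the soma, or `NULL`.
#' @param validate check tree invariants (single root, resolving parents,
#'   acyclic connectivity, finite coordinates). Internal bulk constructors may
#'   disable this after building by construction.
#' @return A `consat_skeleton`: the node tibble with `skeleton_id` and
#'   `soma_node` attributes.
#' @examples
#' sk <- skeleton(
#'   tibble::tibble(
#'     node_id = c("1", "2"), parent_id = c(NA, "1"),
#'     x = c(0, 3000), y = c(0, 4000), z = c(0, 0), radius = 40
#'   ),
#'   skeleton_id = "n1"
#' )
#' cable_length(sk)
#' @export
skeleton <- function(nodes, skeleton_id, soma_node = NULL, validate = TRUE) {
  nodes <- as_tibble(nodes)[, c("node_id", "parent_id", "x", "y", "z", "radius")]
  nodes$node_id <- as.character(nodes$node_id)
  nodes$parent_id <- as.character(nodes$parent_id)
  if (validate) validate_skeleton_nodes(nodes, skeleton_id, soma_node)
  structure(nodes,
    class = c("consat_skeleton", class(tibble())),
    skeleton_id = as.character(skeleton_id),
    soma_node = if (is.null(soma_node)) NULL else as.character(soma_node)
  )
}

validate_skeleton_nodes <- function(nodes, skeleton_id, soma_node) {
  check_that(nrow(nodes) >= 1, "skeleton has no nodes", "malformed_skeleton")
  check_that(!anyDuplicated(nodes$node_id),
    "duplicated node ids in skeleton", "malformed_skeleton")
  check_that(all(is.finite(nodes$x)) && all(is.finite(nodes$y)) && all(is.finite(nodes$z)),
    "non-finite skeleton coordinates", "malformed_skeleton")
  root <- is.na(nodes$parent_id)
  check_that(sum(root) == 1,
    sprintf("skeleton '%s' must have exactly one root, found %d", skeleton_id, sum(root)),
    "malformed_skeleton")
  known <- nodes$parent_id %in% nodes$node_id | root
  check_that(all(known),
    sprintf("skeleton '%s' has unresolved parent references", skeleton_id),
    "malformed_skeleton")
  # single root + resolving unique parents: connected (hence acyclic) iff
  # every node reaches the root by parent chasing
  idx <- match(nodes$parent_id, nodes$node_id)
  reach <- root
  frontier <- which(root)
  while (length(frontier)) {
    frontier <- which(!reach & idx %in% frontier)
    reach[frontier] <- TRUE
  }
  check_that(all(reach),
    sprintf("skeleton '%s' is not a connected tree", skeleton_id),
    "malformed_skeleton")
  if (!is.null(soma_node)) {
    check_that(as.character(soma_node) %in% nodes$node_id,
      "soma_node not in node table", "malformed_skeleton")
  }
  invisible(TRUE)
}

#' @export
print.consat_skeleton <- function(x, ...) {
  cat(sprintf(
    "<skeleton %s: %d nodes, cable %.0f nm%s>\n",
    skeleton_id(x), nrow(x), cable_length(x),
    if (is.null(soma_node(x))) "" else paste0(", soma at node ", soma_node(x))
  ))
  NextMethod()
}

#' @rdname skeleton
#' @param x a `consat_skeleton`.
#' @export
skeleton_id <- function(x) attr(x, "skeleton_id")

#' @rdname skeleton
#' @export
soma_node <- function(x) attr(x, "soma_node")

#' @rdname skeleton
#' @export
root_node <- function(x) x$node_id[is.na(x$parent_id)]

#' Read and write SWC skeleton files
#'
#' SWC is the 7-column whitespace-delimited skeleton format
#' (`id structure x y z radius parent`, `#` comments, parent `-1` for the
#' root). File coordinates are multiplied by `unit_scale` on reading so that
#' skeletons are always held in nanometres; SWC files are conventionally in
#' micrometres, hence the default of 1000. A node with structure code 1 is
#' taken as the soma.
#'
#' @param path file path.
#' @param unit_scale nanometres per file coordinate unit.
#' @param skeleton_id identifier to give the skeleton; defaults to the file
#'   name without extension.
#' @return `read_swc()` returns a [skeleton()]; `write_swc()` returns `path`
#'   invisibly.
#' @export
read_swc <- function(path, unit_scale = 1000, skeleton_id = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) consat_abort(sprintf("empty SWC file: %s", path), "malformed_skeleton")
  fields <- strsplit(lines, "[[:space:]]+")
  bad <- lengths(fields) != 7L
  if (any(bad)) {
    consat_abort(sprintf("SWC line without 7 columns: '%s'", lines[which(bad)[1]]),
      "malformed_skeleton")
  }
  m <- do.call(rbind, fields)
  num <- apply(m[, 3:6, drop = FALSE], 2, as.numeric)
  if (!is.matrix(num)) num <- matrix(num, nrow = 1)
  if (anyNA(num)) consat_abort("non-numeric coordinates in SWC", "malformed_skeleton")
  parent <- m[, 7]
  nodes <- tibble(
    node_id = m[, 1],
    parent_id = ifelse(parent == "-1", NA_character_, parent),
    x = num[, 1] * unit_scale,
    y = num[, 2] * unit_scale,
    z = num[, 3] * unit_scale,
    radius = num[, 4] * unit_scale
  )
  soma <- nodes$node_id[m[, 2] == "1"]
  skeleton(nodes,
    skeleton_id = skeleton_id %||% sub("\\.[sS][wW][cC]$", "", basename(path)),
    soma_node = if (length(soma)) soma[1] else NULL
  )
}

#' @rdname read_swc
#' @param x a [skeleton()].
#' @export
write_swc <- function(x, path, unit_scale = 1) {
  struct <- rep(0L, nrow(x))
  if (!is.null(soma_node(x))) struct[x$node_id == soma_node(x)] <- 1L
  fmt <- function(v) formatC(v / unit_scale, format = "g", digits = 17)
  lines <- paste(x$node_id, struct, fmt(x$x), fmt(x$y), fmt(x$z), fmt(x$radius),
    ifelse(is.na(x$parent_id), "-1", x$parent_id))
  writeLines(c(paste0("# skeleton ", skeleton_id(x)), lines), path)
  invisible(path)
}

skeleton_edges <- function(x) {
  child <- which(!is.na(x$parent_id))
  parent <- match(x$parent_id[child], x$node_id)
  list(child = child, parent = parent)
}

#' Cable length of a skeleton, optionally restricted to a volume
#'
#' Sums parent-child Euclidean edge lengths. With a volume, an edge
#' contributes only when both endpoints fall inside it (edges are never
#' clipped); this matches the node-resolution bookkeeping of traced
#' skeletons.
#'
#' @param x a [skeleton()].
#' @param volume a volume (see [box_volume()]) or `NULL` for total cable.
#' @return length in nanometres.
#' @export
cable_length <- function(x, volume = NULL) {
  e <- skeleton_edges(x)
  if (!length(e$child)) return(0)
  keep <- rep(TRUE, length(e$child))
  if (!is.null(volume)) {
    inside <- point_in_volume(cbind(x$x, x$y, x$z), volume)
    keep <- inside[e$child] & inside[e$parent]
  }
  dx <- x$x[e$child] - x$x[e$parent]
  dy <- x$y[e$child] - x$y[e$parent]
  dz <- x$z[e$child] - x$z[e$parent]
  sum(sqrt(dx^2 + dy^2 + dz^2)[keep])
}
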