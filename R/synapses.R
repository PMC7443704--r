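#' Polyadic synapse tables
#'
#' Synapses are stored connector-centric, following the EM annotation model:
#' one presynaptic site (a continuous synaptic cleft scored once) with one or
#' more postsynaptic links (each opposing membrane in contact with that
#' cleft). The tidy representation is one row per (connector, postsynaptic
#' link):
#'
#' `connector_id, x, y, z, pre_skeleton, pre_node, post_skeleton, post_node`
#'
#' Coordinates are nanometres. Per-edge synapse counts are always derived
#' from this table, never stored.
#'
#' @param x data frame with the columns above.
#' @return a validated tibble of class `consat_synapses`.
#' @export
synapse_table <- function(x) {
  cols <- c("connector_id", "x", "y", "z", "pre_skeleton", "pre_node",
    "post_skeleton", "post_node")
  check_that(all(cols %in% names(x)),
    paste("synapse table needs columns:", paste(cols, collapse = ", ")),
    "malformed_synapse")
  x <- as_tibble(x)[, cols]
  for (col in c("connector_id", "pre_skeleton", "pre_node", "post_skeleton", "post_node")) {
    x[[col]] <- as.character(x[[col]])
  }
  check_that(all(is.finite(x$x)) && all(is.finite(x$y)) && all(is.finite(x$z)),
    "non-finite connector coordinates", "malformed_synapse")
  # one presynaptic site per connector: pre fields and location must agree
  # across the rows that share a connector_id
  pre_key <- paste(x$pre_skeleton, x$pre_node, x$x, x$y, x$z, sep = "\r")
  n_pre <- tapply(pre_key, x$connector_id, function(k) length(unique(k)))
  if (any(n_pre > 1L)) {
    bad <- names(n_pre)[n_pre > 1L][1]
    consat_abort(sprintf(
      "connector '%s' has conflicting presynaptic links across rows", bad),
      "malformed_synapse")
  }
  post_key <- paste(x$connector_id, x$post_skeleton, x$post_node, sep = "\r")
  if (anyDuplicated(post_key)) {
    consat_abort(
      "duplicated (skeleton, node) postsynaptic link within one connector",
      "malformed_synapse")
  }
  class(x) <- c("consat_synapses", class(tibble()))
  x
}

#' Read and write the delimited synapse table
#'
#' Plain UTF-8 delimited text with a header row; one row per (connector,
#' postsynaptic link). Rows sharing a `connector_id` form one polyadic
#' connector and must agree on the presynaptic fields.
#'
#' @param path file path.
#' @param delim field delimiter.
#' @return `read_synapse_table()` returns a validated [synapse_table()].
#' @export
read_synapse_table <- function(path, delim = "\t") {
  x <- readr::read_delim(path, delim = delim, col_types = readr::cols(
    connector_id = "c", x = "d", y = "d", z = "d",
    pre_skeleton = "c", pre_node = "c", post_skeleton = "c", post_node = "c"
  ), progress = FALSE)
  synapse_table(x)
}

#' @rdname read_synapse_table
#' @param x a synapse table.
#' @export
write_synapse_table <- function(x, path, delim = "\t") {
  readr::write_delim(as_tibble(x), path, delim = delim)
  invisible(path)
}

#' Collapse a synapse table to one row per connector
#'
#' @param x a synapse table.
#' @return tibble with `connector_id`, location, presynaptic link and the
#'   number of postsynaptic links (`n_post`).
#' @export
connectors <- function(x) {
  dplyr::summarise(
    dplyr::group_by(as_tibble(x), .data$connector_id),
    x = .data$x[1], y = .data$y[1], z = .data$z[1],
    pre_skeleton = .data$pre_skeleton[1], pre_node = .data$pre_node[1],
    n_post = dplyr::n(), .groups = "drop"
  )
}
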