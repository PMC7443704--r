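#' Build a synaptic adjacency table
#'
#' Counts (connector, postsynaptic link) pairs from each source to each
#' target — one polyadic connector contributes once per postsynaptic link,
#' the only reading consistent with the connector-centric data model.
#' Optionally restricted to connectors inside a volume, and to presynaptic
#' and/or postsynaptic nodes within per-neuron compartments (e.g. the
#' dendrite node sets returned by [split_dendrites()], or a neuron's axon).
#'
#' @param x a [connectome()].
#' @param sources,targets character vectors of skeleton ids.
#' @param volume a volume, a volume name in `x$volumes`, or `NULL`.
#' @param pre_nodes,post_nodes optional named lists (skeleton id -> allowed
#'   node ids) restricting the presynaptic / postsynaptic side of flagged
#'   neurons; unflagged neurons are unrestricted.
#' @return a long tibble of class `consat_adjacency`: `source`, `target`,
#'   `n` (all source x target combinations, zeros included).
#' @export
build_adjacency <- function(x, sources, targets, volume = NULL,
                            pre_nodes = NULL, post_nodes = NULL) {
  check_that(all(c(sources, targets) %in% names(x$skeletons)),
    "unknown skeleton id in sources/targets", "unknown_id")
  if (is.character(volume)) volume <- x$volumes[[volume]]
  syn <- dplyr::filter(as_tibble(x$synapses),
    .data$pre_skeleton %in% sources, .data$post_skeleton %in% targets)
  if (!is.null(volume) && nrow(syn)) syn <- syn[point_in_volume(syn, volume), ]
  keep_side <- function(tbl, flags, skel_col, node_col) {
    if (is.null(flags) || !nrow(tbl)) return(tbl)
    drop <- rep(FALSE, nrow(tbl))
    for (id in names(flags)) {
      hit <- tbl[[skel_col]] == id
      drop[hit & !(tbl[[node_col]] %in% flags[[id]])] <- TRUE
    }
    tbl[!drop, ]
  }
  syn <- keep_side(syn, pre_nodes, "pre_skeleton", "pre_node")
  syn <- keep_side(syn, post_nodes, "post_skeleton", "post_node")
  counts <- dplyr::count(syn, source = .data$pre_skeleton,
    target = .data$post_skeleton)
  grid <- tidyr::expand_grid(source = sources, target = targets)
  adj <- dplyr::left_join(grid, counts, by = c("source", "target"))
  adj$n <- as.integer(ifelse(is.na(adj$n), 0L, adj$n))
  class(adj) <- c("consat_adjacency", class(tibble()))
  attr(adj, "volume") <- if (is.null(volume)) NA_character_ else volume$name
  adj
}

#' Pool adjacency rows/columns by type
#'
#' Summing member cells within each source/target group; pooling then
#' summing equals summing then pooling for any partition.
#'
#' @param adj a [build_adjacency()] table.
#' @param source_groups,target_groups optional named vectors mapping
#'   skeleton id -> group label; unmapped ids keep their own id.
#' @return pooled adjacency tibble (`source`, `target`, `n`).
#' @export
pool_adjacency <- function(adj, source_groups = NULL, target_groups = NULL) {
  relabel <- function(ids, groups) {
    if (is.null(groups)) return(ids)
    out <- groups[ids]
    ifelse(is.na(out), ids, out)
  }
  out <- dplyr::summarise(dplyr::group_by(as_tibble(adj),
    source = relabel(.data$source, source_groups),
    target = relabel(.data$target, target_groups)),
    n = sum(.data$n), .groups = "drop")
  class(out) <- c("consat_adjacency", class(tibble()))
  out
}

#' Widen an adjacency table into a numeric matrix
#' @param adj adjacency tibble.
#' @return matrix with sources as rows, targets as columns.
#' @export
adjacency_matrix <- function(adj) {
  w <- tidyr::pivot_wider(as_tibble(adj), names_from = "target",
    values_from = "n", values_fill = 0L)
  m <- as.matrix(w[, -1])
  rownames(m) <- w$source
  m
}

#' Read/write adjacency tables as labelled delimited text
#' @param adj adjacency tibble.
#' @param path file path.
#' @export
write_adjacency <- function(adj, path) {
  utils::write.table(adjacency_matrix(adj), path, sep = "\t", quote = FALSE,
    col.names = NA)
  invisible(path)
}

#' @rdname write_adjacency
#' @export
read_adjacency <- function(path) {
  m <- as.matrix(utils::read.table(path, sep = "\t", header = TRUE,
    row.names = 1, check.names = FALSE))
  adj <- tidyr::pivot_longer(
    dplyr::mutate(as_tibble(m, rownames = "source")),
    -"source", names_to = "target", values_to = "n")
  adj$n <- as.integer(adj$n)
  class(adj) <- c("consat_adjacency", class(tibble()))
  adj
}

#' Export an adjacency table as a GraphML edge list
#' @param adj adjacency tibble.
#' @param path output file.
#' @export
write_graphml <- function(adj, path) {
  edges <- dplyr::filter(as_tibble(adj), .data$n > 0)
  g <- igraph::graph_from_data_frame(
    edges[, c("source", "target", "n")], directed = TRUE)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Threshold-based circuit membership
#'
#' Targets whose summed input from the query set reaches `threshold`
#' (inclusive: "at least 5 connections" designates membership).
#'
#' @param adj adjacency table from the query neurons, volume-restricted to
#'   the circuit's neuropil.
#' @param threshold minimum summed input (default 5, inclusive).
#' @return character vector of member target ids.
#' @export
circuit_members <- function(adj, threshold = 5) {
  tot <- dplyr::summarise(dplyr::group_by(as_tibble(adj), .data$target),
    n = sum(.data$n), .groups = "drop")
  sort(tot$target[tot$n >= threshold])
}

#' Most strongly connected downstream targets
#'
#' Targets with summed input strictly above `threshold` (exclusive: "more
#' than 150 inputs"). Note the deliberate asymmetry with [circuit_members()],
#' which is inclusive.
#'
#' @param adj brain-wide adjacency table from the full query population.
#' @param threshold strict lower bound on summed input (default 150).
#' @return character vector of target ids.
#' @export
strong_targets <- function(adj, threshold = 150) {
  tot <- dplyr::summarise(dplyr::group_by(as_tibble(adj), .data$target),
    n = sum(.data$n), .groups = "drop")
  sort(tot$target[tot$n > threshold])
}

#' Normalized input budget of one target neuron
#'
#' Mode `"vp"`: raw per-source cells at or below `heat_threshold` synapses
#' are zeroed out (the heatmap convention "thresholded >2 synapses"), then
#' the retained cells are renormalized so total VP-PN input sums to 1. Mode
#' `"identified"`: sources are first grouped into identified input
#' categories via `category_map` and fractions are taken over total
#' identified input (no heatmap threshold). Retained fractions sum to 1 in
#' both modes.
#'
#' @param adj adjacency table whose targets include `target`.
#' @param target target skeleton id (or pooled label).
#' @param mode `"vp"` or `"identified"`.
#' @param category_map named vector source id/label -> category (mode
#'   `"identified"`).
#' @param heat_threshold strict raw-count threshold for mode `"vp"`
#'   (default 2: cells of 2 or fewer synapses are dropped).
#' @return tibble `source` (or `category`), `n`, `fraction`.
#' @export
input_budget <- function(adj, target, mode = c("vp", "identified"),
                         category_map = NULL, heat_threshold = 2) {
  mode <- match.arg(mode)
  col <- dplyr::filter(as_tibble(adj), .data$target == !!target)
  check_that(nrow(col) > 0, "target not present in adjacency", "unknown_id")
  if (mode == "vp") {
    keep <- col[col$n > heat_threshold, ]
    check_that(sum(keep$n) > 0, "no retained input: undefined budget",
      "undefined_budget")
    return(tibble(source = keep$source, n = keep$n,
      fraction = keep$n / sum(keep$n)))
  }
  check_that(!is.null(category_map), "mode 'identified' needs a category_map",
    "config")
  cat <- category_map[col$source]
  cat <- ifelse(is.na(cat), "unidentified", cat)
  grp <- dplyr::summarise(dplyr::group_by(
    tibble(category = cat, n = col$n), .data$category),
    n = sum(.data$n), .groups = "drop")
  grp <- grp[grp$category != "unidentified", ]
  check_that(sum(grp$n) > 0, "no identified input: undefined budget",
    "undefined_budget")
  tibble(category = grp$category, n = grp$n, fraction = grp$n / sum(grp$n))
}

#' Census bookkeeping for the VP-glomeruli survey
#'
#' Implements the arithmetic used to summarise the reconstruction census:
#'
#' * pooled PN total across hemispheres (sum of per-side counts);
#' * novel type count = total types − previously described − previously
#'   reported but misassociated;
#' * percent fully reconstructed = 100 * complete / sampled, one decimal;
#' * sacculus chamber assignment by the triad-cohabitation rule: VP4, VP5
#'   and VP1d receptor neurons cohabit triad sensilla in chamber II, so the
#'   chamber-II VP4 count per side equals that side's VP5 RN count, the
#'   remainder sit in chamber I, and the VP1d count per side also equals the
#'   VP5 count — hence VP1d + VP4 total = VP4 total + VP5 count.
#'
#' @param pn_per_side numeric vector of per-hemisphere VP PN counts.
#' @param types_total,types_described,types_misassociated type-level counts.
#' @param n_complete,n_sampled neurons fully reconstructed / sampled.
#' @param vp4_total,vp5_count per-side VP4 RN total and VP5 RN count.
#' @return tibble `quantity`, `value`.
#' @export
vp_census <- function(pn_per_side, types_total, types_described,
                      types_misassociated, n_complete, n_sampled,
                      vp4_total, vp5_count) {
  vals <- c(
    pn_total = census_pooled_total(pn_per_side),
    novel_types = census_novel_types(types_total, types_described,
      types_misassociated),
    pct_complete = census_percent_complete(n_complete, n_sampled),
    vp4_chamber2 = census_chamber2_vp4(vp4_total, vp5_count),
    vp4_chamber1 = vp4_total - census_chamber2_vp4(vp4_total, vp5_count),
    vp1d_vp4_total = census_vp1d_vp4_total(vp4_total, vp5_count)
  )
  tibble(quantity = names(vals), value = unname(vals))
}

#' @rdname vp_census
#' @export
census_pooled_total <- function(pn_per_side) {
  check_that(all(pn_per_side >= 0), "negative count", "config")
  sum(pn_per_side)
}

#' @rdname vp_census
#' @export
census_novel_types <- function(types_total, types_described, types_misassociated) {
  out <- types_total - types_described - types_misassociated
  check_that(out >= 0, "negative novel-type count", "config")
  out
}

#' @rdname vp_census
#' @export
census_percent_complete <- function(n_complete, n_sampled) {
  check_that(n_sampled > 0 && n_complete >= 0 && n_complete <= n_sampled,
    "invalid completion counts", "config")
  round(100 * n_complete / n_sampled, 1)
}

#' @rdname vp_census
#' @export
census_chamber2_vp4 <- function(vp4_total, vp5_count) {
  check_that(vp5_count <= vp4_total, "more VP5 RNs than VP4 RNs", "config")
  vp5_count
}

#' @rdname vp_census
#' @export
census_vp1d_vp4_total <- function(vp4_total, vp5_count) {
  check_that(vp4_total >= 0 && vp5_count >= 0, "negative count", "config")
  vp4_total + vp5_count
}
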