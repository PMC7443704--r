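#' Enumerate the downstream postsynapse pool of query neurons
#'
#' All (connector, postsynaptic link) pairs whose presynaptic skeleton is a
#' query neuron and whose connector lies inside `volume` (or anywhere when
#' `volume` is `NULL`). Order is deterministic: sorted by connector id then
#' postsynaptic skeleton and node.
#'
#' @param x a [connectome()].
#' @param query_ids character vector of presynaptic skeleton ids.
#' @param volume a volume, a volume name in `x$volumes`, or `NULL`.
#' @return tibble: the rows of the synapse table forming the pool.
#' @export
enumerate_postsynapses <- function(x, query_ids, volume = NULL) {
  check_that(all(query_ids %in% names(x$skeletons)),
    "unknown query skeleton id", "unknown_id")
  if (is.character(volume)) volume <- x$volumes[[volume]]
  pool <- dplyr::filter(as_tibble(x$synapses), .data$pre_skeleton %in% query_ids)
  if (!is.null(volume)) {
    pool <- pool[point_in_volume(pool, volume), ]
  }
  dplyr::arrange(pool, .data$connector_id, .data$post_skeleton, .data$post_node)
}

#' Randomized downstream sampling with a saturation stopping rule
#'
#' Draws postsynapses uniformly without replacement from the pool. Each draw
#' whose postsynaptic skeleton has not been seen before is a "novel hit" and
#' is recorded together with that partner's true total number of connections
#' to the query (within the sampled scope). After each novel hit, once at
#' least `window` novel hits exist, sampling stops if the last `window` of
#' them all have fewer than `weak_threshold` connections — the saturation
#' criterion: recent discoveries are all weak partners, so the strong ones
#' have been found. If the pool is exhausted first, the state is flagged
#' `"exhausted"`.
#'
#' @param pool postsynapse pool from [enumerate_postsynapses()].
#' @param truth named numeric vector: skeleton id -> total connections to the
#'   query within scope (see [partner_truth_from_pool()] for the live mode
#'   that recomputes it from the connectome).
#' @param window number of most recent novel hits inspected (default 10).
#' @param weak_threshold connection count below which a partner is "weak"
#'   (default 5).
#' @param stop_rule set `FALSE` to disable the rule and consume the pool.
#' @return a `consat_sampling_state` list: `pool`, `sampled` (ordered draws),
#'   `partner_tally` (tibble `skeleton_id`, `hits`), `novel_history` (tibble
#'   `skeleton_id`, `connections`), `stopped` (`"saturated"` or
#'   `"exhausted"`), `fraction_sampled`.
#' @export
sample_to_saturation <- function(pool, truth, window = 10, weak_threshold = 5,
                                 stop_rule = TRUE) {
  check_that(nrow(pool) > 0, "empty postsynapse pool", "config")
  missing <- setdiff(unique(pool$post_skeleton), names(truth))
  if (length(missing)) {
    consat_abort(sprintf("truth is missing %d partner id(s), e.g. '%s'",
      length(missing), missing[1]), "unknown_id")
  }
  ord <- sample.int(nrow(pool))
  skel <- pool$post_skeleton[ord]
  novel <- !duplicated(skel)
  stop_at <- nrow(pool)
  reason <- "exhausted"
  if (stop_rule) {
    nov_conn <- unname(truth[skel[novel]])
    nov_draw <- which(novel)
    if (length(nov_conn) >= window) {
      weak <- nov_conn < weak_threshold
      # rolling all-weak over the trailing window of novel hits
      run <- stats::filter(as.numeric(weak), rep(1, window), sides = 1)
      fire <- which(!is.na(run) & run == window)
      if (length(fire)) {
        stop_at <- nov_draw[fire[1]]
        reason <- "saturated"
      }
    }
  }
  idx <- ord[seq_len(stop_at)]
  sampled <- pool[idx, ]
  sampled$draw <- seq_len(stop_at)
  tally <- dplyr::count(sampled, .data$post_skeleton, name = "hits")
  names(tally)[1] <- "skeleton_id"
  nh <- skel[seq_len(stop_at)]
  nh <- nh[!duplicated(nh)]
  structure(list(
    pool = pool,
    sampled = sampled,
    partner_tally = tally,
    novel_history = tibble(skeleton_id = nh, connections = unname(truth[nh])),
    stopped = reason,
    fraction_sampled = stop_at / nrow(pool)
  ), class = "consat_sampling_state")
}

#' @export
print.consat_sampling_state <- function(x, ...) {
  cat(sprintf(
    "<sampling: %d/%d postsynapses drawn (%.1f%%), %d partners, stopped: %s>\n",
    nrow(x$sampled), nrow(x$pool), 100 * x$fraction_sampled,
    nrow(x$partner_tally), x$stopped))
  invisible(x)
}

#' True per-partner connection totals for a pool
#'
#' The "live" mode of the stopping rule: recomputes each partner's total
#' connections to the query from the connectome itself, either within the
#' same volume scope as the pool (the default workflow) or brain-wide.
#'
#' @param x a [connectome()].
#' @param query_ids presynaptic skeleton ids.
#' @param volume volume restriction, or `NULL` for brain-wide counts.
#' @return named numeric vector, skeleton id -> connections.
#' @export
partner_truth_from_pool <- function(x, query_ids, volume = NULL) {
  pool <- enumerate_postsynapses(x, query_ids, volume)
  tab <- table(pool$post_skeleton)
  stats::setNames(as.numeric(tab), names(tab))
}

#' Partner discovery curve of a sampling run
#'
#' @param state a [sample_to_saturation()] result.
#' @return tibble `draw`, `unique_partners` (cumulative, monotone
#'   non-decreasing; final value equals the partner tally size).
#' @export
discovery_curve <- function(state) {
  check_that(nrow(state$sampled) > 0, "empty sampling state", "config")
  tibble(
    draw = state$sampled$draw,
    unique_partners = cumsum(!duplicated(state$sampled$post_skeleton))
  )
}
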