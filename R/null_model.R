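#' Observed Kenyon-cell claw inputs
#'
#' Builds the binary claw-input table: one row per (KC, claw branch), one
#' column per PN class, cell 1 when that class contributed at least
#' `min_syn` synapses to the claw (inputs are weighted equally above the
#' threshold). Synapses from the lACA-associated query PNs lying inside the
#' lACA volume are omitted — the claw analysis concerns calyx bouton inputs,
#' not the accessory-calyx circuit itself.
#'
#' @param x a [connectome()] with a claw annotation table.
#' @param kc_ids KC skeleton ids to tabulate; KCs without claw annotations
#'   are skipped with a warning.
#' @param min_syn observation threshold in synapses (default 5).
#' @param class_of named vector skeleton id -> PN class; defaults to each
#'   PN's primary glomerulus from the metadata table.
#' @param laca_pn_ids skeleton ids of the lACA-associated PNs whose
#'   lACA-volume inputs are excluded.
#' @param laca_volume the lACA volume (or its name in `x$volumes`).
#' @return tibble of class `consat_claw_inputs`: `skeleton_id`, `branch_id`,
#'   then one 0/1 column per class; attribute `min_syn`.
#' @export
observed_inputs <- function(x, kc_ids, min_syn = 5, class_of = NULL,
                            laca_pn_ids = NULL, laca_volume = NULL) {
  check_that(!is.null(x$claws), "connectome has no claw annotation table",
    "config")
  if (is.character(laca_volume)) laca_volume <- x$volumes[[laca_volume]]
  if (is.null(class_of)) {
    pn <- x$meta[x$meta$neuron_class == "PN", ]
    class_of <- stats::setNames(primary_glomerulus(pn), pn$skeleton_id)
  }
  missing <- setdiff(kc_ids, unique(x$claws$skeleton_id))
  if (length(missing)) {
    consat_warn(sprintf("%d KC(s) without flagged dendrites skipped",
      length(missing)), "unflagged_kc")
    kc_ids <- setdiff(kc_ids, missing)
  }
  claws <- dplyr::filter(as_tibble(x$claws), .data$skeleton_id %in% kc_ids)
  all_rows <- dplyr::distinct(claws, .data$skeleton_id, .data$branch_id)
  if (!nrow(all_rows)) {
    out <- tibble(skeleton_id = character(), branch_id = character())
    attr(out, "min_syn") <- min_syn
    class(out) <- c("consat_claw_inputs", class(tibble()))
    return(out)
  }
  syn <- dplyr::filter(as_tibble(x$synapses), .data$post_skeleton %in% kc_ids,
    .data$pre_skeleton %in% names(class_of))
  if (!is.null(laca_pn_ids) && !is.null(laca_volume) && nrow(syn)) {
    excl <- syn$pre_skeleton %in% laca_pn_ids & point_in_volume(syn, laca_volume)
    syn <- syn[!excl, ]
  }
  hits <- dplyr::inner_join(syn, claws,
    by = c(post_skeleton = "skeleton_id", post_node = "node_id"))
  hits$class_label <- unname(class_of[hits$pre_skeleton])
  counts <- dplyr::count(hits, skeleton_id = .data$post_skeleton,
    .data$branch_id, .data$class_label)
  counts$observed <- as.integer(counts$n >= min_syn)
  wide <- tidyr::pivot_wider(counts[, c("skeleton_id", "branch_id",
      "class_label", "observed")],
    names_from = "class_label", values_from = "observed", values_fill = 0L)
  out <- dplyr::left_join(all_rows, wide, by = c("skeleton_id", "branch_id"))
  out[is.na(out)] <- 0L
  out <- dplyr::arrange(out, .data$skeleton_id, .data$branch_id)
  attr(out, "min_syn") <- min_syn
  class(out) <- c("consat_claw_inputs", class(tibble()))
  out
}

#' Bouton-share probability vector
#'
#' The null model's input probabilities: each PN class's share of the total
#' calyx bouton count.
#'
#' @param bouton_counts named non-negative vector, class -> bouton count
#'   (not all zero), or a bouton annotation tibble with `class_label`,
#'   `n_boutons`.
#' @return tibble `class_label`, `share` (sums to 1).
#' @export
bouton_shares <- function(bouton_counts) {
  if (is.data.frame(bouton_counts)) {
    agg <- dplyr::summarise(dplyr::group_by(bouton_counts, .data$class_label),
      n = sum(.data$n_boutons), .groups = "drop")
    bouton_counts <- stats::setNames(agg$n, agg$class_label)
  }
  check_that(all(bouton_counts >= 0), "negative bouton count", "config")
  check_that(sum(bouton_counts) > 0, "all-zero bouton counts", "config")
  cls <- sort(names(bouton_counts))
  tibble(class_label = cls, share = unname(bouton_counts[cls] / sum(bouton_counts)))
}

#' Monte Carlo expected claw inputs under the bouton-share null
#'
#' A virtual KC population with the same number of claws and inputs is
#' created by random draw: every replicate draws, for each claw row,
#' `inputs_per_row` class labels independently with the share probabilities;
#' per-class totals are averaged over replicates (with their Monte Carlo
#' standard errors). `inputs_per_row` may be a constant or the observed
#' per-row totals; holding the observed totals fixed honours "the same
#' number of KCs and PN inputs".
#'
#' @param n_rows number of claw rows.
#' @param inputs_per_row scalar or length-`n_rows` vector of inputs per row.
#' @param shares a [bouton_shares()] tibble (or named probability vector).
#' @param reps Monte Carlo replicates (default 1000).
#' @return list of class `consat_expected`: `summary` (tibble `class_label`,
#'   `expected`, `se`), `replicates` (reps x classes matrix of per-class
#'   totals), `total_inputs`.
#' @export
expected_inputs <- function(n_rows, inputs_per_row, shares, reps = 1000) {
  check_that(reps >= 1, "reps must be >= 1", "config")
  if (!is.data.frame(shares)) {
    shares <- tibble(class_label = names(shares), share = unname(shares))
  }
  check_that(abs(sum(shares$share) - 1) < 1e-9 && all(shares$share >= 0),
    "shares must be a probability vector", "config")
  total <- if (length(inputs_per_row) == 1) n_rows * inputs_per_row
           else sum(inputs_per_row)
  check_that(total > 0, "no inputs to draw", "config")
  # rows draw independently with identical probabilities, so the per-class
  # population total in one replicate is multinomial(total, shares)
  m <- t(stats::rmultinom(reps, size = total, prob = shares$share))
  colnames(m) <- shares$class_label
  mu <- colMeans(m)
  se <- apply(m, 2, stats::sd) / sqrt(reps)
  structure(list(
    summary = tibble(class_label = shares$class_label, expected = unname(mu),
      se = unname(se)),
    replicates = m,
    total_inputs = total
  ), class = "consat_expected")
}

# Two-sided empirical Monte Carlo p-value (mid-p, add-one corrected).
# The replicate distribution is discrete, so plain tail doubling is
# conservative; mid-p halves the weight of ties, keeping the null
# calibration close to nominal.
mc_pvalue <- function(replicates, observed) {
  n <- length(replicates)
  lo <- (sum(replicates < observed) + 0.5 * sum(replicates == observed) + 1) / (n + 1)
  hi <- (sum(replicates > observed) + 0.5 * sum(replicates == observed) + 1) / (n + 1)
  min(1, 2 * min(lo, hi))
}

#' Observed versus expected claw inputs, with valence roll-up
#'
#' Per class: observed input count (column sums of the binary claw table),
#' null expectation, observed/expected ratio, and a two-sided empirical
#' Monte Carlo p-value from the replicate distribution. The same statistics
#' are reported per putative valence after summing classes within each
#' valence group. Classes missing from the valence map are assigned
#' `"unknown"` with a warning.
#'
#' @param observed a [observed_inputs()] table (or any tibble with
#'   `skeleton_id`, `branch_id` and 0/1 class columns).
#' @param expected an [expected_inputs()] result whose classes cover the
#'   observed columns.
#' @param valence_map named vector class -> one of `"attractive"`,
#'   `"aversive"`, `"unknown"`.
#' @return list of class `consat_enrichment`: `by_class` and `by_valence`
#'   tibbles (`observed`, `expected`, `ratio`, `p_value`).
#' @export
enrichment_report <- function(observed, expected, valence_map = NULL) {
  cls <- setdiff(colnames(observed), c("skeleton_id", "branch_id"))
  exp_cls <- expected$summary$class_label
  check_that(all(cls %in% exp_cls),
    "observed classes missing from the expected table", "config")
  obs <- vapply(exp_cls, function(cl) {
    if (cl %in% cls) sum(observed[[cl]]) else 0
  }, numeric(1))
  reps <- expected$replicates
  exp_mu <- expected$summary$expected
  by_class <- tibble(
    class_label = exp_cls,
    observed = unname(obs),
    expected = exp_mu,
    ratio = unname(obs) / exp_mu,
    p_value = vapply(seq_along(exp_cls), function(j)
      mc_pvalue(reps[, j], obs[j]), numeric(1))
  )
  if (is.null(valence_map)) valence_map <- character(0)
  val <- valence_map[exp_cls]
  if (anyNA(val)) {
    consat_warn(sprintf("%d class(es) missing from valence map set to 'unknown'",
      sum(is.na(val))), "unmapped_valence")
    val[is.na(val)] <- "unknown"
  }
  groups <- split(seq_along(exp_cls), val)
  by_valence <- dplyr::bind_rows(lapply(names(groups), function(v) {
    j <- groups[[v]]
    o <- sum(obs[j])
    r <- rowSums(reps[, j, drop = FALSE])
    tibble(valence = v, observed = o, expected = mean(r), ratio = o / mean(r),
      p_value = mc_pvalue(r, o))
  }))
  structure(list(by_class = by_class, by_valence = by_valence),
    class = "consat_enrichment")
}

#' @export
print.consat_enrichment <- function(x, ...) {
  cat("<claw-input enrichment report>\n")
  print(x$by_class)
  invisible(x)
}
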