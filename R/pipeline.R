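#' Run the full analysis pipeline on a synthetic or loaded connectome
#'
#' Orchestrates the stages end to end: simulate (or load) a connectome,
#' type neurons by morphology similarity, sample downstream of the query
#' PNs with the saturation stopping rule, extract the threshold-defined
#' circuit, run the Kenyon-cell bouton-share null model, and fit the
#' cable-versus-input regression. Every intermediate table is written to
#' `out_dir` as delimited text, together with a YAML run manifest recording
#' the seed, the stage parameters and a configuration hash. Output is
#' deterministic for a fixed seed.
#'
#' @param config either a [synth_config()] (the connectome is generated) or
#'   a directory path readable by [read_connectome()].
#' @param out_dir output directory, or `NULL` to skip writing.
#' @param seed master seed for the sampling and null-model stages (defaults
#'   to the synthetic config's seed, or 1).
#' @param params list of stage parameters; missing entries take the
#'   defaults `list(window = 10, weak_threshold = 5, circuit_threshold = 5,
#'   strong_threshold = 150, heat_threshold = 2, cut_height = 0.8,
#'   sigma = 3000, reps = 1000, min_syn = 5, spacing = 1000, k = 5)`.
#' @param census_counts optional named list passed to [vp_census()]
#'   (defaults to the reconstruction census of the VP survey this package
#'   models).
#' @return list of class `consat_run`: `connectome`, `truth` (if
#'   synthetic), `typing`, `sampling`, `adjacency`, `circuit`,
#'   `claw_inputs`, `expected`, `enrichment`, `regression`, `census`,
#'   `manifest`.
#' @export
run_pipeline <- function(config, out_dir = NULL, seed = NULL, params = list(),
                         census_counts = NULL) {
  p <- utils::modifyList(list(
    window = 10, weak_threshold = 5, circuit_threshold = 5,
    strong_threshold = 150, heat_threshold = 2, cut_height = 0.8,
    sigma = 3000, reps = 1000, min_syn = 5, spacing = 1000, k = 5
  ), params)

  truth <- NULL
  if (inherits(config, "consat_synth_config")) {
    seed <- seed %||% config$seed
    synth <- generate_connectome(config)
    cx <- synth$connectome
    truth <- synth$truth
  } else if (is.character(config) && dir.exists(config)) {
    seed <- seed %||% 1L
    cx <- read_connectome(config)
  } else {
    consat_abort("config must be a synth_config or an existing directory",
      "config")
  }

  # --- morphology typing of the PNs -----------------------------------------
  pn_ids <- cx$meta$skeleton_id[cx$meta$neuron_class == "PN" &
    cx$meta$hemisphere == "R"]
  dps <- lapply(cx$skeletons[pn_ids], to_dotprops, spacing = p$spacing, k = p$k)
  S <- score_matrix(dps, sigma = p$sigma)
  typing <- cluster_types(S, cut_height = p$cut_height)

  # --- saturation sampling downstream of the query PNs ----------------------
  query_ids <- if (!is.null(truth)) {
    unique(truth$partners$query_id)
  } else {
    grep("^PN_", pn_ids, value = TRUE)[1:2]
  }
  laca_name <- grep("^lACA", names(cx$volumes), value = TRUE)[1]
  pool <- enumerate_postsynapses(cx, query_ids, laca_name)
  tr <- partner_truth_from_pool(cx, query_ids, laca_name)
  sampling <- with_stage_seed(seed, "pipeline_sampling",
    sample_to_saturation(pool, tr, window = p$window,
      weak_threshold = p$weak_threshold))

  # --- circuit extraction ----------------------------------------------------
  targets <- sort(unique(pool$post_skeleton))
  adj <- build_adjacency(cx, query_ids, targets, volume = laca_name)
  members <- circuit_members(adj, threshold = p$circuit_threshold)

  # --- Kenyon-cell claw-input null model -------------------------------------
  kc_ids <- cx$meta$skeleton_id[cx$meta$neuron_class == "KC" &
    cx$meta$hemisphere == "R"]
  if (!is.null(cx$claws)) kc_ids <- intersect(kc_ids, unique(cx$claws$skeleton_id))
  claw_inputs <- NULL; expected <- NULL; enrichment <- NULL
  if (length(kc_ids) && !is.null(cx$claws) && !is.null(cx$boutons)) {
    # every PN with presynapses inside the lACA counts as lACA-associated
    laca_pns <- unique(enumerate_postsynapses(cx,
      intersect(pn_ids, unique(cx$synapses$pre_skeleton)),
      laca_name)$pre_skeleton)
    claw_inputs <- observed_inputs(cx, kc_ids, min_syn = p$min_syn,
      laca_pn_ids = laca_pns, laca_volume = laca_name)
    shares <- bouton_shares(cx$boutons)
    cls <- setdiff(colnames(claw_inputs), c("skeleton_id", "branch_id"))
    per_row <- rowSums(claw_inputs[, cls, drop = FALSE])
    expected <- with_stage_seed(seed, "pipeline_null",
      expected_inputs(nrow(claw_inputs), per_row, shares, reps = p$reps))
    enrichment <- enrichment_report(claw_inputs, expected)
  }

  # --- cable-vs-input regression ---------------------------------------------
  regression <- NULL
  samples <- if (!is.null(truth)) truth$rn_inputs else NULL
  if (!is.null(samples) && nrow(samples) >= 3 && stats::sd(samples$cable_nm) > 0) {
    regression <- fit_cable_vs_input(samples)
  }

  # --- census ----------------------------------------------------------------
  census_counts <- census_counts %||% list(
    pn_per_side = c(52, 36), types_total = 38, types_described = 9,
    types_misassociated = 6, n_complete = 20, n_sampled = 42,
    vp4_total = 14, vp5_count = 9
  )
  census <- do.call(vp_census, census_counts)

  manifest <- list(
    seed = as.integer(seed),
    params = p,
    config_hash = rlang::hash(list(config, p, seed)),
    stop_reason = sampling$stopped,
    fraction_sampled = sampling$fraction_sampled,
    n_circuit_members = length(members)
  )

  res <- structure(list(
    connectome = cx, truth = truth, typing = typing, score_matrix = S,
    sampling = sampling, adjacency = adj, circuit = members,
    claw_inputs = claw_inputs, expected = expected, enrichment = enrichment,
    regression = regression, census = census, manifest = manifest
  ), class = "consat_run")

  if (!is.null(out_dir)) write_run(res, out_dir)
  res
}

write_run <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(res$typing$labels, file.path(out_dir, "typing.tsv"))
  write_score_matrix(res$score_matrix, file.path(out_dir, "score_matrix.tsv"))
  readr::write_tsv(res$sampling$partner_tally, file.path(out_dir, "partner_tally.tsv"))
  readr::write_tsv(discovery_curve(res$sampling), file.path(out_dir, "discovery_curve.tsv"))
  write_adjacency(res$adjacency, file.path(out_dir, "adjacency.tsv"))
  writeLines(res$circuit, file.path(out_dir, "circuit_members.txt"))
  if (!is.null(res$claw_inputs)) {
    readr::write_tsv(as_tibble(res$claw_inputs), file.path(out_dir, "claw_inputs.tsv"))
    readr::write_tsv(res$enrichment$by_class, file.path(out_dir, "enrichment_by_class.tsv"))
    readr::write_tsv(res$enrichment$by_valence, file.path(out_dir, "enrichment_by_valence.tsv"))
  }
  if (!is.null(res$regression)) {
    readr::write_tsv(glance(res$regression), file.path(out_dir, "regression_glance.tsv"))
  }
  readr::write_tsv(res$census, file.path(out_dir, "census.tsv"))
  yaml::write_yaml(res$manifest, file.path(out_dir, "manifest.yaml"))
  invisible(out_dir)
}

#' @export
print.consat_run <- function(x, ...) {
  cat("<pipeline run>\n")
  print(x$sampling)
  cat(sprintf("  circuit members (>= threshold): %d\n", length(x$circuit)))
  cat(sprintf("  typing groups: %d\n", length(unique(x$typing$labels$group))))
  if (!is.null(x$enrichment)) {
    cat(sprintf("  claw-input classes: %d\n", nrow(x$enrichment$by_class)))
  }
  invisible(x)
}
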