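test_that("claw inputs are observed at the synapse threshold", {
  # one KC with one claw: 6 synapses from a VP3 PN, 4 from a VP2 PN
  kc_nodes <- tibble::tibble(node_id = as.character(1:6),
    parent_id = c(NA, as.character(1:5)),
    x = seq(0, 5000, by = 1000), y = 0, z = 0, radius = 40)
  sks <- list(
    KC1 = skeleton(kc_nodes, "KC1"),
    PNA = path_skeleton(cbind(c(0, 1000), 10e3, 0), "PNA"),
    PNB = path_skeleton(cbind(c(0, 1000), 20e3, 0), "PNB"))
  syn <- synapse_table(tibble::tibble(
    connector_id = sprintf("c%d", 1:10), x = 0, y = 0, z = 0,
    pre_skeleton = rep(c("PNA", "PNB"), c(6, 4)), pre_node = "1",
    post_skeleton = "KC1",
    post_node = as.character(c(3:6, 3, 4, 3:6))))
  meta <- neuron_meta(tibble::tibble(
    skeleton_id = c("KC1", "PNA", "PNB"), neuron_class = c("KC", "PN", "PN"),
    type_label = c("KC", "VP3 vPN", "VP2 adPN"), hemisphere = "R",
    glomeruli = c(NA, "VP3", "VP2")))
  claws <- tibble::tibble(skeleton_id = "KC1", branch_id = "KC1.claw1",
    node_id = as.character(3:6))
  cx <- connectome(sks, syn, meta, claws = claws)
  obs <- observed_inputs(cx, "KC1", min_syn = 5)
  expect_equal(nrow(obs), 1)
  expect_equal(obs$VP3, 1L)
  expect_equal(obs$VP2, 0L)
})

test_that("observed claw inputs equal the generator's thresholded draws", {
  synth <- generate_connectome(small_config(seed = 18))
  cx <- synth$connectome
  kc <- sort(intersect(cx$meta$skeleton_id[cx$meta$neuron_class == "KC"],
    unique(cx$claws$skeleton_id)))
  pn <- cx$meta$skeleton_id[cx$meta$neuron_class == "PN"]
  laca_pns <- unique(enumerate_postsynapses(cx,
    intersect(pn, unique(cx$synapses$pre_skeleton)), "lACA_R")$pre_skeleton)
  obs <- observed_inputs(cx, kc, laca_pn_ids = laca_pns,
    laca_volume = "lACA_R")
  truth_wide <- tidyr::pivot_wider(
    dplyr::mutate(synth$truth$claw_draws, v = 1L),
    names_from = class_label, values_from = v, values_fill = 0L)
  j <- dplyr::left_join(obs, truth_wide, by = c("skeleton_id", "branch_id"),
    suffix = c("_obs", "_tru"))
  for (cl in setdiff(colnames(obs), c("skeleton_id", "branch_id"))) {
    oc <- if (paste0(cl, "_obs") %in% names(j)) j[[paste0(cl, "_obs")]] else j[[cl]]
    tc <- if (paste0(cl, "_tru") %in% names(j)) j[[paste0(cl, "_tru")]] else
      rep(0L, nrow(j))
    tc[is.na(tc)] <- 0L
    expect_equal(oc, tc)
  }
  # the lACA claws exist as rows but their excluded inputs leave them empty
  lrows <- grepl("lclaw", obs$branch_id)
  expect_true(any(lrows))
  cls <- setdiff(colnames(obs), c("skeleton_id", "branch_id"))
  expect_true(all(rowSums(obs[lrows, cls]) == 0))
})

test_that("empty KC sets and unflagged KCs degrade gracefully", {
  synth <- generate_connectome(small_config(seed = 19))
  cx <- synth$connectome
  obs <- observed_inputs(cx, character(0))
  expect_equal(nrow(obs), 0)
  expect_warning(obs2 <- observed_inputs(cx, c("PN_VP3.vPN_R_1")),
    class = "consat_warning_unflagged_kc")
  expect_equal(nrow(obs2), 0)
})

test_that("bouton shares normalize counts", {
  sh <- bouton_shares(c(A = 30, B = 70))
  expect_equal(stats::setNames(sh$share, sh$class_label), c(A = 0.3, B = 0.7))
  expect_equal(bouton_shares(c(X = 5))$share, 1.0)
  set.seed(4)
  r <- stats::setNames(stats::rpois(6, 20) + 1, letters[1:6])
  expect_equal(sum(bouton_shares(r)$share), 1, tolerance = 1e-12)
  expect_error(bouton_shares(c(A = 0, B = 0)), class = "consat_error_config")
  tbl <- tibble::tibble(class_label = c("A", "A", "B"), n_boutons = c(10, 20, 70))
  expect_equal(bouton_shares(tbl)$share, c(0.3, 0.7))
})

test_that("expected inputs match the multinomial mean and concentrate", {
  sh <- bouton_shares(c(A = 50, B = 50))
  ex <- withr::with_seed(1, expected_inputs(50, 2, sh, reps = 1000))
  expect_equal(ex$total_inputs, 100)
  a <- ex$summary[ex$summary$class_label == "A", ]
  expect_lt(abs(a$expected - 50), 3 * max(a$se, 1e-12))
  # degenerate single class
  ex1 <- expected_inputs(10, 3, bouton_shares(c(X = 4)), reps = 100)
  expect_equal(ex1$summary$expected, 30)
  expect_equal(ex1$summary$se, 0)
  expect_error(expected_inputs(10, 1, sh, reps = 0),
    class = "consat_error_config")
  # Monte Carlo SE shrinks as replicates grow
  ses <- vapply(c(10, 100, 1000), function(r)
    withr::with_seed(2, expected_inputs(100, 1, sh, reps = r))$summary$se[1],
    numeric(1))
  expect_true(all(diff(ses) < 0))
})

test_that("Monte Carlo means sit within 4 SE of n*p for a random share vector", {
  set.seed(6)
  w <- stats::runif(5) + 0.1
  sh <- bouton_shares(stats::setNames(w, letters[1:5]))
  n <- 400
  ex <- withr::with_seed(3, expected_inputs(n, 1, sh, reps = 1000))
  for (i in 1:5) {
    expect_lt(abs(ex$summary$expected[i] - n * sh$share[i]),
      4 * ex$summary$se[i])
  }
})

test_that("valence roll-up conserves class sums and flags unmapped classes", {
  sh <- bouton_shares(c(A = 30, B = 30, C = 40))
  ex <- withr::with_seed(4, expected_inputs(100, 1, sh, reps = 500))
  obs <- tibble::tibble(skeleton_id = sprintf("k%d", 1:100),
    branch_id = sprintf("k%d.c1", 1:100),
    A = as.integer(stats::runif(100) < 0.3),
    B = as.integer(stats::runif(100) < 0.3),
    C = as.integer(stats::runif(100) < 0.4))
  expect_warning(
    rep1 <- enrichment_report(obs, ex, c(A = "attractive", B = "aversive")),
    class = "consat_warning_unmapped_valence")
  expect_setequal(rep1$by_valence$valence, c("attractive", "aversive", "unknown"))
  for (v in rep1$by_valence$valence) {
    cls_in_v <- switch(v, attractive = "A", aversive = "B", unknown = "C")
    expect_equal(
      rep1$by_valence$observed[rep1$by_valence$valence == v],
      sum(rep1$by_class$observed[rep1$by_class$class_label %in% cls_in_v]))
  }
})

test_that("a planted bouton-share bias is detected as enrichment", {
  base <- c(VP1d = 3, VP1l = 2, VP1m = 6, VP2 = 8, VP3 = 10, VP4 = 4, VP5 = 5)
  cfg <- synth_config(seed = 33,
    kc_spec = list(n_kc = 250, claws_min = 4, claws_max = 4,
      inputs_per_claw = 1, syn_per_input = 6, n_laca_kc = 0,
      weak_frac = 0, weak_syn = 2),
    bouton_counts = base, bias = c(VP1l = 2))
  pop <- generate_kc_population(cfg)
  obs_wide <- tidyr::pivot_wider(dplyr::mutate(pop$draws, v = 1L),
    names_from = class_label, values_from = v, values_fill = 0L)
  ex <- withr::with_seed(34,
    expected_inputs(nrow(pop$draws), 1, bouton_shares(base), reps = 1000))
  rep1 <- enrichment_report(obs_wide, ex,
    stats::setNames(rep("unknown", 7), names(base)))
  biased <- rep1$by_class[rep1$by_class$class_label == "VP1l", ]
  expect_gt(biased$ratio, 1.5)
  expect_lt(biased$p_value, 0.01)
})

test_that("planted bias factors are recovered with monotone ratios", {
  base <- c(A = 20, B = 20, C = 20, D = 40)
  mean_ratio <- vapply(c(1.5, 2, 3), function(bf) {
    rr <- vapply(1:5, function(s) {
      cfg <- synth_config(seed = 100 + s * 7 + round(bf * 10),
        kc_spec = list(n_kc = 250, claws_min = 4, claws_max = 4,
          inputs_per_claw = 1, syn_per_input = 6, n_laca_kc = 0,
          weak_frac = 0, weak_syn = 2),
        bouton_counts = base, bias = c(A = bf))
      pop <- generate_kc_population(cfg)
      mean(pop$draws$class_label == "A") / 0.2
    }, numeric(1))
    mean(rr)
  }, numeric(1))
  expect_true(all(diff(mean_ratio) > 0))
})
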