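test_that("dotprops resampling spaces points along a straight segment", {
  sk <- path_skeleton(rbind(c(0, 0, 0), c(4000, 0, 0)))
  dp <- to_dotprops(sk, spacing = 1000, k = 3)
  expect_equal(nrow(dp$points), 5)
  expect_equal(sort(dp$points[, 1]), seq(0, 4000, by = 1000))
  expect_true(all(abs(abs(dp$vect[, 1]) - 1) < 1e-9))
})

test_that("tangents are unit vectors, also at corners and for large k", {
  sk <- path_skeleton(rbind(c(0, 0, 0), c(5000, 0, 0), c(5000, 5000, 0)))
  dp <- to_dotprops(sk, spacing = 1000, k = 4)
  expect_equal(sqrt(rowSums(dp$vect^2)), rep(1, nrow(dp$vect)),
    tolerance = 1e-6)
  dp2 <- to_dotprops(sk, spacing = 2500, k = 50)  # k larger than N: clamped
  expect_equal(sqrt(rowSums(dp2$vect^2)), rep(1, nrow(dp2$vect)),
    tolerance = 1e-6)
})

test_that("single-node skeletons cannot become dotprops", {
  one <- skeleton(tibble::tibble(node_id = "1", parent_id = NA_character_,
    x = 0, y = 0, z = 0, radius = 1), "one")
  expect_error(to_dotprops(one), class = "consat_error_degenerate_morphology")
})

test_that("similarity kernel evaluates exactly on hand-checkable clouds", {
  dp <- raw_dotprops(rbind(c(0, 0, 0), c(1000, 0, 0)), rbind(c(1, 0, 0), c(1, 0, 0)))
  expect_equal(nblast_similarity(dp, dp), 2)
  # one point at distance sigma, parallel tangents
  q <- raw_dotprops(cbind(0, 0, 0), cbind(1, 0, 0))
  t1 <- raw_dotprops(cbind(3000, 0, 0), cbind(1, 0, 0))
  expect_equal(nblast_similarity(q, t1), exp(-1))
  # orthogonal tangents at distance 0
  t2 <- raw_dotprops(cbind(0, 0, 0), cbind(0, 1, 0))
  expect_equal(nblast_similarity(q, t2), 0)
})

test_that("similarity matches the brute-force nearest-neighbour oracle", {
  set.seed(31)
  for (trial in 1:5) {
    n1 <- sample(5:50, 1); n2 <- sample(5:50, 1)
    q <- raw_dotprops(matrix(stats::runif(3 * n1, 0, 10e3), ncol = 3),
      matrix(stats::rnorm(3 * n1), ncol = 3))
    t <- raw_dotprops(matrix(stats::runif(3 * n2, 0, 10e3), ncol = 3),
      matrix(stats::rnorm(3 * n2), ncol = 3))
    expect_equal(nblast_similarity(q, t), brute_similarity(q, t),
      tolerance = 1e-9)
  }
})

test_that("mean normalized score is 1 on self, symmetric, near 0 when far", {
  set.seed(5)
  q <- raw_dotprops(matrix(stats::runif(60, 0, 5e3), ncol = 3),
    matrix(stats::rnorm(60), ncol = 3))
  t <- raw_dotprops(matrix(stats::runif(45, 0, 5e3), ncol = 3),
    matrix(stats::rnorm(45), ncol = 3))
  expect_equal(nblast_mean(q, q), 1)
  expect_equal(nblast_mean(q, t), nblast_mean(t, q))
  far <- raw_dotprops(matrix(stats::runif(45, 1e6, 1.005e6), ncol = 3),
    matrix(stats::rnorm(45), ncol = 3))
  # min separation ~1e6 - 5e3 nm >> sigma: each term at most exp(-d/sigma)
  expect_lt(nblast_mean(q, far), 0.01)
})

test_that("a tabulated score table overrides the default kernel", {
  st <- score_table(c(0, 1000, Inf), c(0, 0.5, 1),
    rbind(c(1, 2), c(3, 4)))
  q <- raw_dotprops(cbind(0, 0, 0), cbind(1, 0, 0))
  near_par <- raw_dotprops(cbind(500, 0, 0), cbind(1, 0, 0))
  far_orth <- raw_dotprops(cbind(5000, 0, 0), cbind(0, 1, 0))
  expect_equal(nblast_similarity(q, near_par, score_table = st), 2)
  expect_equal(nblast_similarity(q, far_orth, score_table = st), 3)
})

test_that("score matrices have unit diagonal and survive text roundtrip", {
  pop <- generate_type_population(n_types = 2, n_per_type = 2, seed = 4)
  dps <- lapply(pop$skeletons, to_dotprops)
  S <- score_matrix(dps)
  expect_equal(diag(S), rep(1, 4), ignore_attr = TRUE)
  expect_equal(S, t(S))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_score_matrix(S, f)
  expect_equal(read_score_matrix(f), S, tolerance = 1e-12)
})

test_that("clustering at the cut height groups duplicates and splits strangers", {
  S <- matrix(c(1, 1, 0.01, 1, 1, 0.01, 0.01, 0.01, 1), 3, 3,
    dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  ty <- cluster_types(S, cut_height = 0.8)
  expect_equal(length(unique(ty$labels$group)), 2)
  expect_equal(ty$labels$group[1], ty$labels$group[2])
  S2 <- S; S2[1, 2] <- S2[2, 1] <- 0.9  # distinct neurons: merge heights > 0
  ty0 <- cluster_types(S2, cut_height = 0)
  expect_equal(length(unique(ty0$labels$group)), 3)
  S[1, 2] <- NaN
  expect_error(cluster_types(S), class = "consat_error_config")
})

test_that("clustering recovers planted types from separated envelopes", {
  pop <- generate_type_population(n_types = 2, n_per_type = 3, seed = 17)
  dps <- lapply(pop$skeletons, to_dotprops)
  ty <- cluster_types(score_matrix(dps), cut_height = 0.8)
  got <- ty$labels$group[match(pop$labels$skeleton_id, ty$labels$skeleton_id)]
  expect_equal(mclust::adjustedRandIndex(got, pop$labels$type), 1)
  f <- withr::local_tempfile(fileext = ".nwk")
  write_typing_newick(ty, f)
  expect_equal(length(ape::read.tree(f)$tip.label), 6)
})

test_that("contralateral matching pairs mirrored neurons", {
  pop <- generate_type_population(n_types = 5, n_per_type = 1, seed = 23)
  sks <- pop$skeletons
  meta_rows <- list()
  for (id in names(pop$skeletons)) {
    lid <- paste0(id, "_L")
    sks[[lid]] <- consat:::mirror_skeleton(pop$skeletons[[id]], lid,
      midline_x = -10e3, jitter_sd = 0)
    meta_rows[[id]] <- tibble::tibble(skeleton_id = id, neuron_class = "PN",
      type_label = id, hemisphere = "R", contralateral_partner = lid)
    meta_rows[[lid]] <- tibble::tibble(skeleton_id = lid, neuron_class = "PN",
      type_label = id, hemisphere = "L", contralateral_partner = id)
  }
  meta <- neuron_meta(dplyr::bind_rows(meta_rows))
  dps <- lapply(sks, to_dotprops)
  res <- match_contralateral(dps, meta, midline_x = -10e3)
  expect_equal(res$count, 10)
  expect_equal(res$n_eligible, 10)
})

test_that("jittered bilateral populations still pair overwhelmingly", {
  specs <- tibble::tibble(
    type_label = paste0("VP", c("3 vPN", "2 adPN", "1m l2PN", "4 vPN",
      "5 l2PN", "1d il2PN", "1l lvPN", "2+ l2PN", "3+ smPN", "1m+ lvPN")),
    glomeruli = c("VP3", "VP2", "VP1m", "VP4", "VP5", "VP1d", "VP1l",
      "VP2", "VP3", "VP1m"),
    volumes = c("lACA;CA", "lACA;CA", rep("CA;LH", 8)),
    n = 1, query = c(TRUE, TRUE, rep(FALSE, 8)))
  cfg <- synth_config(seed = 29, pn_specs = specs, hemispheres = c("R", "L"),
    noise = 500,
    kc_spec = list(n_kc = 0, claws_min = 2, claws_max = 4, inputs_per_claw = 1,
      syn_per_input = 6, n_laca_kc = 0, weak_frac = 0, weak_syn = 2))
  synth <- generate_connectome(cfg)
  cx <- synth$connectome
  pn <- cx$meta$skeleton_id[cx$meta$neuron_class == "PN"]
  dps <- lapply(cx$skeletons[pn], to_dotprops)
  res <- match_contralateral(dps, cx$meta, midline_x = 0)
  expect_equal(res$n_eligible, 20)
  expect_gte(res$count, 18)
})

test_that("single-hemisphere input yields zero contralateral pairs", {
  pop <- generate_type_population(n_types = 2, n_per_type = 1, seed = 2)
  meta <- neuron_meta(tibble::tibble(
    skeleton_id = names(pop$skeletons), neuron_class = "PN",
    type_label = names(pop$skeletons), hemisphere = "R"))
  res <- match_contralateral(lapply(pop$skeletons, to_dotprops), meta)
  expect_equal(res$count, 0)
})

test_that("dendrite splitting flags exactly the planted claw branches", {
  synth <- generate_connectome(small_config(seed = 12))
  cx <- synth$connectome
  kc <- intersect(cx$meta$skeleton_id[cx$meta$neuron_class == "KC"],
    unique(cx$claws$skeleton_id))
  for (id in kc[1:3]) {
    flagged <- split_dendrites(cx$skeletons[[id]], cx$volumes$CA_R)
    planted <- cx$claws$node_id[cx$claws$skeleton_id == id &
      !grepl("lclaw", cx$claws$branch_id)]
    expect_setequal(flagged, planted)
    # the lACA claws are flagged against the lACA volume instead
    lflag <- split_dendrites(cx$skeletons[[id]], cx$volumes$lACA_R)
    lplant <- cx$claws$node_id[cx$claws$skeleton_id == id &
      grepl("lclaw", cx$claws$branch_id)]
    expect_setequal(lflag, lplant)
  }
})

test_that("dendrite splitting degenerates gracefully", {
  far <- box_volume("far", c(1e6, 1e6, 1e6), c(2e6, 2e6, 2e6))
  sk <- path_skeleton(rbind(c(0, 0, 0), c(1000, 0, 0), c(2000, 0, 0)))
  expect_warning(out <- split_dendrites(sk, far),
    class = "consat_warning_no_calyx_overlap")
  expect_length(out, 0)
  # unbranched path through the volume: no side branches, empty set
  through <- box_volume("t", c(500, -10, -10), c(1500, 10, 10))
  expect_length(split_dendrites(sk, through), 0)
})
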