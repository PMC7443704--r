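test_that("polyadic connectors count once per postsynaptic link", {
  cx <- toy_connectome()
  adj <- build_adjacency(cx, c("A", "B"), c("T1", "T2"))
  m <- adjacency_matrix(adj)
  expect_equal(m["A", "T1"], 2)   # one connector, two post links
  expect_equal(m["B", "T1"], 1)
  expect_equal(m["A", "T2"], 1)
  adj_v <- build_adjacency(cx, c("A", "B"), c("T1", "T2"),
    volume = cx$volumes$box)
  expect_equal(adjacency_matrix(adj_v)["A", "T2"], 0)  # c3 lies outside
  expect_error(build_adjacency(cx, "ghost", "T1"),
    class = "consat_error_unknown_id")
})

test_that("compartment flags restrict the counted nodes per side", {
  cx <- toy_connectome()
  adj <- build_adjacency(cx, "A", "T1", post_nodes = list(T1 = "1"))
  expect_equal(adjacency_matrix(adj)["A", "T1"], 1)
  adj2 <- build_adjacency(cx, "A", "T1", pre_nodes = list(A = "2"))
  expect_equal(adjacency_matrix(adj2)["A", "T1"], 0)
})

test_that("adjacency equals a brute-force triple loop over connectors", {
  synth <- generate_connectome(small_config(seed = 14))
  cx <- synth$connectome
  sources <- sort(unique(cx$synapses$pre_skeleton))[1:5]
  targets <- sort(unique(cx$synapses$post_skeleton))[1:8]
  vol <- cx$volumes$lACA_R
  adj <- build_adjacency(cx, sources, targets, volume = vol)
  syn <- as.data.frame(cx$synapses)
  ref <- matrix(0L, length(sources), length(targets),
    dimnames = list(sources, targets))
  for (r in seq_len(nrow(syn))) {
    s <- syn$pre_skeleton[r]; t <- syn$post_skeleton[r]
    if (!(s %in% sources) || !(t %in% targets)) next
    p <- c(syn$x[r], syn$y[r], syn$z[r])
    if (all(p >= vol$min & p <= vol$max)) ref[s, t] <- ref[s, t] + 1L
  }
  expect_equal(adjacency_matrix(adj)[sources, targets], ref)
})

test_that("exhaustive sampling and adjacency construction agree", {
  synth <- generate_connectome(small_config(seed = 15))
  cx <- synth$connectome
  q <- sort(unique(synth$truth$partners$query_id))
  pool <- enumerate_postsynapses(cx, q, "lACA_R")
  st <- withr::with_seed(3,
    sample_to_saturation(pool, truth_vector(synth), stop_rule = FALSE))
  adj <- build_adjacency(cx, q, sort(unique(pool$post_skeleton)),
    volume = "lACA_R")
  col_tot <- dplyr::count(tibble::as_tibble(adj), target, wt = n, name = "n")
  tally <- st$partner_tally[order(st$partner_tally$skeleton_id), ]
  expect_equal(col_tot$n[match(tally$skeleton_id, col_tot$target)],
    tally$hits)
})

test_that("circuit membership is inclusive at the threshold", {
  adj <- tibble::tibble(
    source = "Q", target = c("a", "b", "c"), n = c(7L, 5L, 4L))
  expect_equal(circuit_members(adj, 5), c("a", "b"))
  empty <- tibble::tibble(source = character(), target = character(),
    n = integer())
  expect_equal(circuit_members(empty), character(0))
})

test_that("strong-target selection is strict at the threshold", {
  adj <- tibble::tibble(source = "Q", target = c("a", "b"), n = c(151L, 150L))
  expect_equal(strong_targets(adj, 150), "a")
  expect_equal(strong_targets(tibble::tibble(source = "Q", target = "a",
    n = 10L), 150), character(0))
})

test_that("membership is monotone in the threshold", {
  set.seed(20)
  adj <- tibble::tibble(source = "Q", target = sprintf("t%02d", 1:30),
    n = as.integer(rpois(30, 6)))
  prev <- circuit_members(adj, 1)
  for (th in 2:12) {
    cur <- circuit_members(adj, th)
    expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("planted heavy partners are recovered as strong targets", {
  synth <- generate_connectome(small_config(seed = 16,
    partner_degrees = tibble::tibble(n_partners = c(1, 5, 20),
      connections_each = c(200, 10, 1))))
  cx <- synth$connectome
  q <- sort(unique(synth$truth$partners$query_id))
  targets <- sort(unique(synth$truth$partners$partner_id))
  adj <- build_adjacency(cx, q, targets)
  heavy <- synth$truth$partners$partner_id[synth$truth$partners$connections > 150]
  expect_setequal(strong_targets(adj, 150), heavy)
  # and the >=5 circuit members are exactly the planted partners of degree >= 5
  adj_l <- build_adjacency(cx, q, targets, volume = "lACA_R")
  deg <- dplyr::count(synth$truth$partners, partner_id, wt = connections)
  expect_setequal(circuit_members(adj_l, 5), deg$partner_id[deg$n >= 5])
})

test_that("pooling commutes with summation", {
  set.seed(21)
  adj <- tidyr::expand_grid(source = sprintf("s%d", 1:6),
    target = sprintf("t%d", 1:4))
  adj$n <- as.integer(rpois(nrow(adj), 3))
  groups <- stats::setNames(rep(c("g1", "g2"), each = 3), sprintf("s%d", 1:6))
  pooled <- pool_adjacency(adj, source_groups = groups)
  manual <- dplyr::count(
    dplyr::mutate(adj, source = groups[source]), source, target, wt = n)
  expect_equal(
    dplyr::arrange(tibble::as_tibble(pooled), source, target)$n,
    dplyr::arrange(manual, source, target)$n)
  expect_equal(sum(pooled$n), sum(adj$n))
})

test_that("input budgets threshold raw cells then renormalize", {
  adj <- tibble::tibble(source = c("A", "B", "C"), target = "T",
    n = c(8L, 2L, 2L))
  b <- input_budget(adj, "T", mode = "vp")
  expect_equal(b$source, "A")
  expect_equal(b$fraction, 1.0)
  cat_adj <- tibble::tibble(source = c("v1", "o1"), target = "T",
    n = c(70L, 30L))
  b2 <- input_budget(cat_adj, "T", mode = "identified",
    category_map = c(v1 = "VP", o1 = "olfactory"))
  expect_equal(stats::setNames(b2$fraction, b2$category),
    c(VP = 0.7, olfactory = 0.3))
  # fractions always renormalize to 1 over retained cells
  set.seed(3)
  for (i in 1:20) {
    r <- tibble::tibble(source = sprintf("s%d", 1:6), target = "T",
      n = as.integer(rpois(6, 4)))
    if (all(r$n <= 2)) next
    expect_equal(sum(input_budget(r, "T", mode = "vp")$fraction), 1,
      tolerance = 1e-12)
  }
  all_small <- tibble::tibble(source = "A", target = "T", n = 2L)
  expect_error(input_budget(all_small, "T", mode = "vp"),
    class = "consat_error_undefined_budget")
})

test_that("census arithmetic reproduces the reconstruction bookkeeping", {
  expect_equal(census_pooled_total(c(52, 36)), 88)
  expect_equal(census_novel_types(38, 9, 6), 23)
  expect_equal(census_percent_complete(20, 42), 47.6)
  expect_equal(census_chamber2_vp4(14, 9), 9)
  expect_equal(14 - census_chamber2_vp4(14, 9), 5)
  expect_equal(census_vp1d_vp4_total(14, 9), 23)
  expect_error(census_novel_types(10, 9, 6), class = "consat_error_config")
  expect_error(census_percent_complete(43, 42), class = "consat_error_config")
  cen <- vp_census(c(52, 36), 38, 9, 6, 20, 42, 14, 9)
  expect_equal(stats::setNames(cen$value, cen$quantity)[
    c("pn_total", "novel_types", "pct_complete", "vp4_chamber2",
      "vp1d_vp4_total")],
    c(pn_total = 88, novel_types = 23, pct_complete = 47.6,
      vp4_chamber2 = 9, vp1d_vp4_total = 23))
})

test_that("adjacency tables roundtrip through text and GraphML", {
  cx <- toy_connectome()
  adj <- build_adjacency(cx, c("A", "B"), c("T1", "T2"))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_adjacency(adj, f)
  back <- read_adjacency(f)
  expect_equal(adjacency_matrix(back)[c("A", "B"), c("T1", "T2")],
    adjacency_matrix(adj)[c("A", "B"), c("T1", "T2")])
  g <- withr::local_tempfile(fileext = ".graphml")
  write_graphml(adj, g)
  gr <- igraph::read_graph(g, format = "graphml")
  expect_equal(igraph::ecount(gr), sum(adj$n > 0))
})
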