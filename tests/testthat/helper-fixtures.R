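# Fixtures are built in code; nothing is read from disk except files the
# tests themselves write to tempdir().

path_skeleton <- function(coords, id = "sk", ...) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  skeleton(tibble::tibble(
    node_id = as.character(seq_len(n)),
    parent_id = c(NA, as.character(seq_len(n - 1))),
    x = coords[, 1], y = coords[, 2], z = coords[, 3], radius = 40
  ), skeleton_id = id, ...)
}

# a dotprops object built directly from points/tangents (unit-normalised)
raw_dotprops <- function(points, vect, id = "dp") {
  points <- as.matrix(points)
  vect <- as.matrix(vect)
  vect <- vect / sqrt(rowSums(vect^2))
  structure(list(points = points, vect = vect, skeleton_id = id,
    spacing = NA_real_), class = "consat_dotprops")
}

# independent brute-force oracle for the raw similarity score: explicit
# all-pairs loops, no vectorisation shared with the implementation
brute_similarity <- function(query, target, sigma = 3000) {
  total <- 0
  for (i in seq_len(nrow(query$points))) {
    best_d <- Inf
    best_j <- NA
    for (j in seq_len(nrow(target$points))) {
      d <- sqrt(sum((query$points[i, ] - target$points[j, ])^2))
      if (d < best_d) {
        best_d <- d
        best_j <- j
      }
    }
    a <- abs(sum(query$vect[i, ] * target$vect[best_j, ]))
    total <- total + exp(-best_d / sigma) * min(a, 1)
  }
  total
}

# tiny hand-wired connectome: two sources, two targets, one polyadic
# connector, one connector outside the volume
toy_connectome <- function() {
  mk <- function(id, x0) path_skeleton(cbind(x0 + c(0, 1000), 0, 0), id)
  sk <- list(mk("A", 0), mk("B", 2000), mk("T1", 4000), mk("T2", 6000))
  names(sk) <- c("A", "B", "T1", "T2")
  syn <- synapse_table(tibble::tibble(
    connector_id = c("c1", "c1", "c2", "c3"),
    x = c(500, 500, 800, 50000),
    y = 0, z = 0,
    pre_skeleton = c("A", "A", "B", "A"),
    pre_node = "1",
    post_skeleton = c("T1", "T1", "T1", "T2"),
    post_node = c("1", "2", "1", "1")
  ))
  meta <- neuron_meta(tibble::tibble(
    skeleton_id = c("A", "B", "T1", "T2"),
    neuron_class = c("PN", "PN", "KC", "LHN"),
    type_label = c("qA", "qB", "t1", "t2"),
    hemisphere = "R"
  ))
  connectome(sk, syn, meta,
    volumes = list(box = box_volume("box", c(0, -1e3, -1e3), c(10e3, 1e3, 1e3))))
}

# small synthetic config that keeps generator-backed tests fast
small_config <- function(seed = 1, ...) {
  defaults <- list(
    seed = seed,
    laca_dominance = 0.8,
    rn_counts = c(VP2 = 2, VP3 = 3, VP1m = 2),
    pn_specs = tibble::tibble(
      type_label = c("VP3 vPN", "VP2 adPN", "VP1m l2PN"),
      glomeruli = c("VP3", "VP2", "VP1m"),
      volumes = c("lACA;CA", "lACA;CA", "lACA;CA"),
      n = c(1, 1, 2),
      query = c(TRUE, TRUE, FALSE)
    ),
    partner_degrees = tibble::tibble(n_partners = c(2, 20),
      connections_each = c(8, 1)),
    kc_spec = list(n_kc = 6, claws_min = 2, claws_max = 4, inputs_per_claw = 1,
      syn_per_input = 6, n_laca_kc = 2, weak_frac = 0.3, weak_syn = 2),
    bouton_counts = c(VP1m = 4, VP2 = 6, VP3 = 10)
  )
  dots <- list(...)
  for (nm in names(dots)) defaults[[nm]] <- dots[[nm]]
  do.call(synth_config, defaults)
}

# ground-truth per-partner totals as a named vector
truth_vector <- function(synth) {
  agg <- dplyr::count(synth$truth$partners, partner_id, wt = connections,
    name = "n")
  stats::setNames(as.numeric(agg$n), agg$partner_id)
}
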