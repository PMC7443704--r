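#' Configuration for the synthetic connectome generator
#'
#' The generator emulates the data structures of a sparsely reconstructed
#' EM connectome of the fly thermo/hygrosensory system: seven
#' ventroposterior (VP) glomeruli with realistic per-hemisphere receptor
#' neuron (RN) counts, projection neuron (PN) types with axons in several
#' neuropil volumes, a lateral accessory calyx (lACA) in which two query PNs
#' dominate the PN presynapse supply, Kenyon cells (KCs) with claw-structured
#' dendrites whose calyx inputs are drawn from PN bouton shares, and a
#' long-tailed partner-degree distribution downstream of the query PNs.
#' Ground-truth tables are emitted alongside so every downstream analysis can
#' be tested as parameter recovery.
#'
#' @param seed integer master seed; every stage draws from its own stream
#'   derived from it, so output is reproducible byte for byte.
#' @param rn_counts named vector, glomerulus -> per-hemisphere RN count.
#'   Defaults follow the right-hemisphere census scale of the system
#'   (VP4 = 14, VP5 = 9, VP1d = 9, ...).
#' @param pn_specs tibble with columns `type_label`, `glomeruli`
#'   (";"-separated, first = primary), `volumes` (";"-separated axon target
#'   volumes), `n` (instances per hemisphere), `query` (logical: one of the
#'   two lACA-dominating PNs).
#' @param laca_dominance fraction of lACA PN presynapses supplied by the two
#'   query PNs (default 0.92, i.e. ">90%").
#' @param partner_degrees tibble `n_partners`, `connections_each` defining
#'   the downstream degree multiset of each query PN. The default
#'   (3 x 20, 2 x 8, 200 x 1) is a long-tailed profile: a few strong
#'   partners over a sea of singletons.
#' @param kc_spec list: `n_kc` Kenyon cells, `claws_min`/`claws_max` claws
#'   per KC, `inputs_per_claw`, `syn_per_input` synapses realising one claw
#'   input (default 6, above the 5-synapse observation threshold),
#'   `n_laca_kc` KCs given an additional claw inside the lACA (wired from a
#'   query PN, to exercise the lACA-exclusion rule), `weak_frac`/`weak_syn`
#'   fraction of claws receiving a sub-threshold contaminating input and its
#'   synapse count.
#' @param bouton_counts named vector, PN class (primary glomerulus) ->
#'   calyx bouton count; defines the null-model share vector.
#' @param bias optional named vector, PN class -> multiplicative
#'   overrepresentation factor for planted-bias tests; shares are
#'   renormalised after multiplication.
#' @param noise coordinate jitter standard deviation in nanometres applied to
#'   type archetypes (instances) and mirrored skeletons.
#' @param hemispheres `"R"` or `c("R", "L")`; the left hemisphere is a
#'   mirrored, jittered copy of the right with contralateral partners
#'   annotated.
#' @param rn_syn_per_um expected RN inputs per micrometre of PN dendritic
#'   cable within a glomerulus (drives the cable-vs-input regression signal).
#' @return a `consat_synth_config` list.
#' @export
synth_config <- function(seed = 1L,
                         rn_counts = c(VP1d = 9, VP1l = 7, VP1m = 7, VP2 = 3,
                                       VP3 = 4, VP4 = 14, VP5 = 9),
                         pn_specs = default_pn_specs(),
                         laca_dominance = 0.92,
                         partner_degrees = tibble(
                           n_partners = c(3, 2, 200),
                           connections_each = c(20, 8, 1)
                         ),
                         kc_spec = list(n_kc = 40, claws_min = 3, claws_max = 6,
                                        inputs_per_claw = 1, syn_per_input = 6,
                                        n_laca_kc = 4, weak_frac = 0.3,
                                        weak_syn = 2),
                         bouton_counts = c(VP1d = 3, VP1l = 2, VP1m = 6,
                                           VP2 = 8, VP3 = 10, VP4 = 4, VP5 = 5),
                         bias = NULL,
                         noise = 150,
                         hemispheres = "R",
                         rn_syn_per_um = 1.5) {
  cfg <- list(
    seed = as.integer(seed), rn_counts = rn_counts, pn_specs = as_tibble(pn_specs),
    laca_dominance = laca_dominance, partner_degrees = as_tibble(partner_degrees),
    kc_spec = kc_spec, bouton_counts = bouton_counts, bias = bias, noise = noise,
    hemispheres = hemispheres, rn_syn_per_um = rn_syn_per_um
  )
  check_that(laca_dominance > 0 && laca_dominance <= 1,
    "laca_dominance must be in (0, 1]", "config")
  check_that(all(rn_counts >= 0) && all(cfg$partner_degrees$n_partners >= 0) &&
    all(cfg$partner_degrees$connections_each >= 0),
    "counts must be non-negative", "config")
  check_that(sum(cfg$pn_specs$query) == 2,
    "exactly two query PN types are required", "config")
  check_that(kc_spec$n_kc >= 0 && kc_spec$inputs_per_claw >= 0,
    "KC counts must be non-negative", "config")
  check_that(all(bouton_counts >= 0), "bouton counts must be non-negative", "config")
  structure(cfg, class = "consat_synth_config")
}

#' @rdname synth_config
#' @export
default_pn_specs <- function() {
  tibble(
    type_label = c("VP3 vPN", "VP2 adPN", "VP1m l2PN", "VP4 vPN", "VP5 l2PN",
                   "VP1d il2PN", "VP1l+VP3 ilPN"),
    glomeruli  = c("VP3", "VP2", "VP1m", "VP4", "VP5", "VP1d", "VP1l;VP3"),
    volumes    = c("lACA;CA", "lACA;CA", "lACA;CA;LH", "CA;LH", "CA;LH",
                   "CA;LH", "CA;LH"),
    n          = c(1, 1, 2, 2, 2, 2, 2),
    query      = c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE)
  )
}

# ---- geometry ---------------------------------------------------------------

glom_names <- function(cfg) sort(names(cfg$rn_counts))

# Axis-aligned neuropil layout (nanometres), right hemisphere at x > 0;
# the sagittal midline is the plane x = 0.
synth_volumes <- function(cfg, hemi = "R") {
  gl <- glom_names(cfg)
  vols <- list(
    AL  = box_volume("AL",  c(5e3, 0, 0),       c(35e3, 30e3, 30e3)),
    lACA = box_volume("lACA", c(45e3, 0, 0),     c(55e3, 10e3, 20e3)),
    CA  = box_volume("CA",  c(45e3, 15e3, 0),    c(65e3, 35e3, 20e3)),
    LH  = box_volume("LH",  c(70e3, 0, 0),       c(90e3, 20e3, 20e3))
  )
  xs <- c(6e3, 13.5e3, 21e3, 28.5e3)
  ys <- c(2e3, 12e3, 22e3)
  for (i in seq_along(gl)) {
    cx <- xs[(i - 1) %% 4 + 1]
    cy <- ys[(i - 1) %/% 4 + 1]
    vols[[gl[i]]] <- box_volume(gl[i], c(cx, cy, 5e3), c(cx + 6e3, cy + 6e3, 25e3))
  }
  names(vols) <- paste0(names(vols), "_", hemi)
  for (nm in names(vols)) {
    vols[[nm]]$name <- nm
    if (hemi == "L") {
      x0 <- vols[[nm]]$min[1]; x1 <- vols[[nm]]$max[1]
      vols[[nm]]$min[1] <- -x1; vols[[nm]]$max[1] <- -x0
    }
  }
  vols
}

# uniform integers in [lo, hi], safe when lo == hi (no scalar-sample trap)
sample_range <- function(lo, hi, n) {
  if (lo == hi) rep(as.integer(lo), n) else sample(seq.int(lo, hi), n, replace = TRUE)
}

# reflect coordinates into [lo, hi] (triangular folding)
fold_into <- function(v, lo, hi) {
  L <- hi - lo
  w <- (v - lo) %% (2 * L)
  lo + ifelse(w > L, 2 * L - w, w)
}

# biased random-walk path inside a box
walk_in_box <- function(n, box, step = 800, start = NULL) {
  lo <- box$min; hi <- box$max
  if (is.null(start)) start <- lo + stats::runif(3) * (hi - lo)
  d <- matrix(stats::rnorm(3 * n, sd = step), ncol = 3)
  d[1, ] <- 0
  p <- apply(d, 2, cumsum)
  if (n == 1) p <- matrix(p, ncol = 3)
  p <- sweep(p, 2, start, "+")
  for (j in 1:3) p[, j] <- fold_into(p[, j], lo[j], hi[j])
  p
}

path_nodes <- function(points, id_offset = 0, parent_of_first = NA_character_) {
  n <- nrow(points)
  ids <- as.character(id_offset + seq_len(n))
  tibble(
    node_id = ids,
    parent_id = c(parent_of_first, ids[-n]),
    x = points[, 1], y = points[, 2], z = points[, 3],
    radius = 40
  )
}

# one skeleton made of chained path segments, one per box
chained_walk_skeleton <- function(id, boxes, n_per_seg, step = 800) {
  nodes <- NULL
  offset <- 0
  for (i in seq_along(boxes)) {
    pts <- walk_in_box(n_per_seg[i], boxes[[i]], step)
    parent <- if (is.null(nodes)) NA_character_ else nodes$node_id[nrow(nodes)]
    nodes <- dplyr::bind_rows(nodes, path_nodes(pts, offset, parent))
    offset <- offset + n_per_seg[i]
  }
  skeleton(nodes, id, soma_node = nodes$node_id[1], validate = FALSE)
}

jitter_skeleton <- function(sk, sd) {
  if (sd <= 0) return(sk)
  n <- nrow(sk)
  sk$x <- sk$x + stats::rnorm(n, sd = sd)
  sk$y <- sk$y + stats::rnorm(n, sd = sd)
  sk$z <- sk$z + stats::rnorm(n, sd = sd)
  sk
}

mirror_skeleton <- function(sk, new_id, midline_x = 0, jitter_sd = 0) {
  sk$x <- 2 * midline_x - sk$x
  out <- skeleton(as_tibble(sk), new_id, soma_node = soma_node(sk), validate = FALSE)
  if (jitter_sd > 0) out <- jitter_skeleton(out, jitter_sd)
  out
}

# ---- generator --------------------------------------------------------------

#' Generate a synthetic connectome with ground truth
#'
#' Builds skeletons (biased random walks seeded in type-specific spatial
#' envelopes), wires the polyadic synapse table so that (a) each query PN's
#' downstream partner multiset matches `partner_degrees` exactly, (b) the two
#' query PNs jointly supply at least `laca_dominance` of PN presynapses
#' inside the lACA volume, and (c) KC claw inputs are drawn from
#' (bias-adjusted, renormalised) bouton shares. Metadata, volumes, bouton and
#' claw annotation tables, and ground-truth tables are returned alongside.
#'
#' @param config a [synth_config()].
#' @return list of class `consat_synth` with elements `connectome` (a
#'   [connectome()]) and `truth` (list of tibbles: `partners`, `claw_draws`,
#'   `shares`, `rn_inputs`, `types`).
#' @export
generate_connectome <- function(config) {
  stopifnot(inherits(config, "consat_synth_config"))
  cfg <- config
  vols_R <- synth_volumes(cfg, "R")
  vols <- vols_R
  if ("L" %in% cfg$hemispheres) vols <- c(vols, synth_volumes(cfg, "L"))

  built <- with_stage_seed(cfg$seed, "skeletons", build_neurons(cfg, vols_R))
  wiring <- with_stage_seed(cfg$seed, "wiring", wire_synapses(cfg, built, vols_R))
  kc <- with_stage_seed(cfg$seed, "kc", wire_kc_claws(cfg, built, wiring$next_cid))

  skeletons <- built$skeletons
  meta <- built$meta
  if ("L" %in% cfg$hemispheres) {
    mir <- with_stage_seed(cfg$seed, "mirror", mirror_hemisphere(cfg, built))
    skeletons <- c(skeletons, mir$skeletons)
    meta <- dplyr::rows_update(
      dplyr::bind_rows(meta, mir$meta),
      mir$partner_links, by = "skeleton_id")
  }

  syn <- synapse_table(dplyr::bind_rows(wiring$synapses, kc$synapses))
  cx <- connectome(
    skeletons = skeletons, synapses = syn, meta = neuron_meta(meta),
    volumes = vols, boutons = built$boutons, claws = built$claws
  )
  structure(list(
    connectome = cx,
    truth = list(
      partners = wiring$partner_truth,
      claw_draws = kc$claw_draws,
      shares = effective_shares(cfg$bouton_counts, cfg$bias),
      rn_inputs = wiring$rn_truth,
      types = built$meta[, c("skeleton_id", "type_label")]
    )
  ), class = "consat_synth")
}

#' Effective input-share vector after planted bias
#'
#' Multiplies bouton-derived shares by per-class bias factors and
#' renormalises; with no bias this is simply counts / total.
#'
#' @param bouton_counts named vector, class -> bouton count.
#' @param bias optional named vector of multiplicative factors.
#' @return tibble `class_label`, `share` (bouton share), `effective_share`.
#' @export
effective_shares <- function(bouton_counts, bias = NULL) {
  check_that(sum(bouton_counts) > 0, "all-zero bouton counts", "config")
  cls <- sort(names(bouton_counts))
  share <- bouton_counts[cls] / sum(bouton_counts)
  w <- share
  if (!is.null(bias)) {
    f <- rep(1, length(cls)); names(f) <- cls
    f[names(bias)] <- bias
    w <- share * f[cls]
  }
  tibble(class_label = cls, share = unname(share),
    effective_share = unname(w / sum(w)))
}

build_neurons <- function(cfg, vols) {
  skeletons <- list()
  meta <- list()
  gl <- glom_names(cfg)

  # receptor neurons, per glomerulus
  for (g in gl) {
    for (i in seq_len(cfg$rn_counts[[g]])) {
      id <- sprintf("RN_%s_R_%02d", g, i)
      skeletons[[id]] <- chained_walk_skeleton(id, vols[paste0(g, "_R")], 15)
      meta[[id]] <- tibble(skeleton_id = id, neuron_class = "RN",
        type_label = paste(g, "RN"), hemisphere = "R", glomeruli = g,
        lineage = NA_character_, contralateral_partner = NA_character_)
    }
  }

  # projection neurons: one archetype per type, instances = archetype + jitter
  pn_layout <- list()   # per PN: node index ranges per segment
  for (r in seq_len(nrow(cfg$pn_specs))) {
    spec <- cfg$pn_specs[r, ]
    gls <- strsplit(spec$glomeruli, ";")[[1]]
    tvols <- strsplit(spec$volumes, ";")[[1]]
    boxes <- c(vols[paste0(gls, "_R")], vols[paste0(tvols, "_R")])
    seg_names <- c(gls, tvols)
    for (i in seq_len(spec$n)) {
      # dendritic segment length varies per instance so glomerular cable (and
      # hence RN input) spans a useful range for the regression stage
      n_seg <- c(sample(8:25, length(gls), replace = TRUE),
                 rep(14, length(tvols)))
      id <- sprintf("PN_%s_R_%d", gsub("[^A-Za-z0-9]+", ".", spec$type_label), i)
      sk <- chained_walk_skeleton(id, boxes, n_seg)
      skeletons[[id]] <- sk
      ends <- cumsum(n_seg)
      pn_layout[[id]] <- list(
        segments = tibble(name = seg_names, from = c(1, utils::head(ends, -1) + 1),
          to = ends, kind = rep(c("glom", "axon"), c(length(gls), length(tvols)))),
        type = spec$type_label, query = spec$query, glomeruli = gls
      )
      meta[[id]] <- tibble(skeleton_id = id, neuron_class = "PN",
        type_label = spec$type_label, hemisphere = "R",
        glomeruli = spec$glomeruli, lineage = NA_character_,
        contralateral_partner = NA_character_)
    }
  }

  # downstream partners of each query PN, per the degree distribution
  query_ids <- names(Filter(function(p) p$query, pn_layout))
  pd <- cfg$partner_degrees
  partner_ids <- list()
  partner_classes <- c("KC", "LHN", "other")
  for (qi in seq_along(query_ids)) {
    degs <- rep(pd$connections_each, pd$n_partners)
    ids <- sprintf("TGT_q%d_R_%04d", qi, seq_along(degs))
    cls <- ifelse(degs >= 5, partner_classes[(seq_along(degs) %% 2) + 1], "other")
    pts <- walk_in_box(6 * length(ids), vols$lACA_R, step = 600)
    for (j in seq_along(ids)) {
      nodes <- path_nodes(pts[(6 * j - 5):(6 * j), , drop = FALSE])
      skeletons[[ids[j]]] <- skeleton(nodes, ids[j], validate = FALSE)
    }
    meta_part <- tibble(skeleton_id = ids, neuron_class = cls,
      type_label = sprintf("lACA target %s q%d-%d", cls, qi, seq_along(ids)),
      hemisphere = "R", glomeruli = NA_character_, lineage = NA_character_,
      contralateral_partner = NA_character_)
    meta[[paste0("partners_q", qi)]] <- meta_part
    partner_ids[[query_ids[qi]]] <- tibble(partner_id = ids, connections = degs)
  }

  # Kenyon cells: main tract from below the calyx up through it, with claw
  # side-branches; optionally an extra claw inside the lACA
  ks <- cfg$kc_spec
  claws <- list()
  if (ks$n_kc > 0) {
    for (i in seq_len(ks$n_kc)) {
      id <- sprintf("KC_R_%03d", i)
      z0 <- stats::runif(1, 2e3, 18e3)
      x0 <- stats::runif(1, 46e3, 54e3)
      ty <- seq(-6e3, 34e3, by = 800)
      tract <- cbind(fold_into(x0 + cumsum(stats::rnorm(length(ty), sd = 200)), 46e3, 54e3),
                     ty,
                     fold_into(z0 + cumsum(stats::rnorm(length(ty), sd = 200)), 1e3, 19e3))
      nodes <- path_nodes(tract)
      n_claw <- sample_range(ks$claws_min, ks$claws_max, 1)
      attach_at <- sample(which(ty > 16e3 & ty < 28e3), n_claw)
      claw_rows <- list()
      offset <- nrow(nodes)
      for (cidx in seq_len(n_claw)) {
        cpts <- tract[attach_at[cidx], , drop = FALSE][rep(1, 4), ] +
          matrix(cumsum(stats::rnorm(12, sd = 500)), ncol = 3)
        # claws must sit fully inside the calyx box
        cpts[, 1] <- pmin(pmax(cpts[, 1], 45.2e3), 64.8e3)
        cpts[, 2] <- pmin(pmax(cpts[, 2], 15.2e3), 34.8e3)
        cpts[, 3] <- pmin(pmax(cpts[, 3], 0.2e3), 19.8e3)
        cn <- path_nodes(cpts, offset, parent_of_first = nodes$node_id[attach_at[cidx]])
        nodes <- dplyr::bind_rows(nodes, cn)
        claw_rows[[cidx]] <- tibble(skeleton_id = id,
          branch_id = sprintf("%s.claw%d", id, cidx), node_id = cn$node_id)
        offset <- offset + 4
      }
      if (i <= ks$n_laca_kc) {
        at <- which(ty > 2e3 & ty < 8e3)[3]   # tract node inside the lACA
        cpts <- tract[at, , drop = FALSE][rep(1, 4), ] +
          matrix(cumsum(stats::rnorm(12, sd = 400)), ncol = 3)
        cpts[, 1] <- pmin(pmax(cpts[, 1], 45.2e3), 54.8e3)
        cpts[, 2] <- pmin(pmax(cpts[, 2], 0.2e3), 9.8e3)
        cpts[, 3] <- pmin(pmax(cpts[, 3], 0.2e3), 19.8e3)
        cn <- path_nodes(cpts, offset, parent_of_first = nodes$node_id[at])
        nodes <- dplyr::bind_rows(nodes, cn)
        claw_rows[["laca"]] <- tibble(skeleton_id = id,
          branch_id = paste0(id, ".lclaw"), node_id = cn$node_id)
        offset <- offset + 4
      }
      skeletons[[id]] <- skeleton(nodes, id, soma_node = nodes$node_id[1],
        validate = FALSE)
      claws[[id]] <- dplyr::bind_rows(claw_rows)
      meta[[id]] <- tibble(skeleton_id = id, neuron_class = "KC",
        type_label = "KC a'b'", hemisphere = "R", glomeruli = NA_character_,
        lineage = NA_character_, contralateral_partner = NA_character_)
    }
  }

  # calyx bouton annotations: class totals split over instances of the class
  pn_by_class <- split(names(pn_layout),
    vapply(pn_layout, function(p) p$glomeruli[1], character(1)))
  bout <- list()
  for (cls in sort(names(cfg$bouton_counts))) {
    inst <- pn_by_class[[cls]]
    if (is.null(inst)) next
    tot <- cfg$bouton_counts[[cls]]
    per <- rep(tot %/% length(inst), length(inst))
    per[seq_len(tot %% length(inst))] <- per[seq_len(tot %% length(inst))] + 1
    bout[[cls]] <- tibble(skeleton_id = inst, class_label = cls, n_boutons = per)
  }

  list(
    skeletons = skeletons,
    meta = dplyr::bind_rows(meta),
    pn_layout = pn_layout,
    query_ids = query_ids,
    partner_ids = partner_ids,
    claws = if (length(claws)) dplyr::bind_rows(claws) else NULL,
    boutons = if (length(bout)) dplyr::bind_rows(bout) else NULL
  )
}

wire_synapses <- function(cfg, built, vols) {
  syn <- list()
  cid <- 0L
  pick_nodes <- function(sk, seg = NULL, n) {
    rows <- if (is.null(seg)) seq_len(nrow(sk)) else seg$from:seg$to
    rows[(seq_len(n) - 1L) %% length(rows) + 1L]
  }

  # RN -> PN within each glomerulus; counts scale with dendritic cable
  rn_truth <- list()
  gl <- glom_names(cfg)
  rn_of <- lapply(gl, function(g) grep(paste0("^RN_", g, "_R"), names(built$skeletons),
    value = TRUE))
  names(rn_of) <- gl
  for (pid in names(built$pn_layout)) {
    lay <- built$pn_layout[[pid]]
    sk <- built$skeletons[[pid]]
    for (g in lay$glomeruli) {
      seg <- lay$segments[lay$segments$name == g & lay$segments$kind == "glom", ][1, ]
      cab <- cable_length(sk, vols[[paste0(g, "_R")]])
      k <- stats::rpois(1, cfg$rn_syn_per_um * cab / 1000)
      rn_truth[[paste(pid, g)]] <- tibble(skeleton_id = pid, glomerulus = g,
        cable_nm = cab, rn_count = k)
      if (k == 0 || !length(rn_of[[g]])) next
      rns <- rn_of[[g]][(seq_len(k) - 1L) %% length(rn_of[[g]]) + 1L]
      post_rows <- pick_nodes(sk, seg, k)
      pre_nodes <- vapply(rns, function(r) {
        rsk <- built$skeletons[[r]]
        rsk$node_id[sample.int(nrow(rsk), 1)]
      }, character(1))
      syn[[length(syn) + 1L]] <- tibble(
        connector_id = sprintf("c%07d", cid + seq_len(k)),
        x = sk$x[post_rows], y = sk$y[post_rows], z = sk$z[post_rows],
        pre_skeleton = rns, pre_node = pre_nodes,
        post_skeleton = pid, post_node = sk$node_id[post_rows]
      )
      cid <- cid + k
    }
  }

  # query PN -> downstream partners inside the lACA, grouped into polyadic
  # connectors; per-partner connection counts are exact by construction
  partner_truth <- list()
  for (qid in built$query_ids) {
    pt <- built$partner_ids[[qid]]
    partner_truth[[qid]] <- tibble(query_id = qid, partner_id = pt$partner_id,
      connections = pt$connections)
    links <- rep(pt$partner_id, pt$connections)
    if (!length(links)) next
    links <- links[sample.int(length(links))]
    # per-partner node assignment cycles through that partner's six nodes
    ord <- stats::ave(seq_along(links), links, FUN = seq_along)
    node_of <- as.character(((ord - 1L) %% 6L) + 1L)
    # group shuffled links into connectors of size 1-3
    sizes <- sample(c(1L, 1L, 1L, 2L, 3L), length(links), replace = TRUE)
    grp <- rep(seq_along(sizes), sizes)[seq_along(links)]
    qsk <- built$skeletons[[qid]]
    qlay <- built$pn_layout[[qid]]
    qseg <- qlay$segments[qlay$segments$name == "lACA", ][1, ]
    n_conn <- max(grp)
    pre_rows <- pick_nodes(qsk, qseg, n_conn)
    syn[[length(syn) + 1L]] <- tibble(
      connector_id = sprintf("c%07d", cid + grp),
      x = qsk$x[pre_rows][grp], y = qsk$y[pre_rows][grp], z = qsk$z[pre_rows][grp],
      pre_skeleton = qid, pre_node = qsk$node_id[pre_rows][grp],
      post_skeleton = links, post_node = node_of
    )
    cid <- cid + n_conn
  }

  # remaining lACA PN presynapses from non-query lACA PNs, sized so the two
  # query PNs own >= laca_dominance of the lACA PN presynapse total; part of
  # this budget is reserved for the lACA-claw inputs wired later
  q_total <- 2 * sum(cfg$partner_degrees$n_partners * cfg$partner_degrees$connections_each)
  other_total <- floor(q_total * (1 - cfg$laca_dominance) / cfg$laca_dominance)
  ks <- cfg$kc_spec
  laca_claw_budget <- min(ks$n_kc, ks$n_laca_kc) * ks$syn_per_input
  others <- sort(names(Filter(function(p) !p$query &&
    "lACA" %in% p$segments$name, built$pn_layout)))
  if (laca_claw_budget > 0 && !length(others)) {
    consat_abort("lACA claws requested but no non-query lACA PN type to supply them",
      "config")
  }
  check_that(laca_claw_budget <= other_total, paste(
    "infeasible config: lACA-claw synapse budget exceeds the non-query",
    "lACA presynapse allowance implied by laca_dominance"), "config")
  other_total <- other_total - laca_claw_budget
  if (length(others) && other_total > 0) {
    per <- rep(other_total %/% length(others), length(others))
    per[seq_len(other_total %% length(others))] <-
      per[seq_len(other_total %% length(others))] + 1
    all_partners <- unlist(lapply(built$partner_ids, function(p) p$partner_id),
      use.names = FALSE)
    for (oi in seq_along(others)) {
      k <- per[oi]
      if (k == 0) next
      osk <- built$skeletons[[others[oi]]]
      olay <- built$pn_layout[[others[oi]]]
      oseg <- olay$segments[olay$segments$name == "lACA", ][1, ]
      pre_rows <- pick_nodes(osk, oseg, k)
      posts <- all_partners[sample.int(length(all_partners), k, replace = TRUE)]
      pord <- stats::ave(seq_len(k), posts, FUN = seq_along)
      syn[[length(syn) + 1L]] <- tibble(
        connector_id = sprintf("c%07d", cid + seq_len(k)),
        x = osk$x[pre_rows], y = osk$y[pre_rows], z = osk$z[pre_rows],
        pre_skeleton = others[oi], pre_node = osk$node_id[pre_rows],
        post_skeleton = posts, post_node = as.character(((pord - 1L) %% 6L) + 1L)
      )
      cid <- cid + k
    }
  }

  list(
    synapses = dplyr::bind_rows(syn),
    partner_truth = dplyr::bind_rows(partner_truth),
    rn_truth = dplyr::bind_rows(rn_truth),
    next_cid = cid
  )
}

wire_kc_claws <- function(cfg, built, cid) {
  ks <- cfg$kc_spec
  empty <- list(synapses = NULL, claw_draws = tibble(
    skeleton_id = character(), branch_id = character(), class_label = character()))
  if (ks$n_kc == 0 || is.null(built$claws)) return(empty)

  shares <- effective_shares(cfg$bouton_counts, cfg$bias)
  pn_class_of <- vapply(built$pn_layout, function(p) p$glomeruli[1], character(1))
  pn_by_class <- split(names(pn_class_of), pn_class_of)
  ca_seg <- lapply(built$pn_layout, function(p)
    p$segments[p$segments$name == "CA", ][1, ])

  claw_tbl <- built$claws
  ca_claws <- unique(claw_tbl[!grepl("\\.lclaw$", claw_tbl$branch_id),
    c("skeleton_id", "branch_id")])
  syn <- list()
  draws <- list()
  wire_input <- function(kc_id, branch, cls, n_syn) {
    pn_pool <- pn_by_class[[cls]]
    pn <- pn_pool[sample.int(length(pn_pool), 1)]
    psk <- built$skeletons[[pn]]
    seg <- ca_seg[[pn]]
    pre_rows <- seg$from + (seq_len(n_syn) - 1L) %% (seg$to - seg$from + 1L)
    claw_nodes <- claw_tbl$node_id[claw_tbl$branch_id == branch]
    post_nodes <- claw_nodes[(seq_len(n_syn) - 1L) %% length(claw_nodes) + 1L]
    ksk <- built$skeletons[[kc_id]]
    post_rows <- match(post_nodes, ksk$node_id)
    out <- tibble(
      connector_id = sprintf("c%07d", cid + seq_len(n_syn)),
      x = ksk$x[post_rows], y = ksk$y[post_rows], z = ksk$z[post_rows],
      pre_skeleton = pn, pre_node = psk$node_id[pre_rows],
      post_skeleton = kc_id, post_node = post_nodes
    )
    cid <<- cid + n_syn
    out
  }

  for (r in seq_len(nrow(ca_claws))) {
    kc_id <- ca_claws$skeleton_id[r]; branch <- ca_claws$branch_id[r]
    for (k in seq_len(ks$inputs_per_claw)) {
      cls <- sample(shares$class_label, 1, prob = shares$effective_share)
      if (!length(pn_by_class[[cls]])) next
      syn[[length(syn) + 1L]] <- wire_input(kc_id, branch, cls, ks$syn_per_input)
      draws[[length(draws) + 1L]] <- tibble(skeleton_id = kc_id,
        branch_id = branch, class_label = cls)
    }
    # sub-threshold contamination from a different class
    if (stats::runif(1) < ks$weak_frac && ks$weak_syn > 0) {
      cls2 <- sample(shares$class_label, 1)
      if (length(pn_by_class[[cls2]])) {
        syn[[length(syn) + 1L]] <- wire_input(kc_id, branch, cls2, ks$weak_syn)
      }
    }
  }

  # lACA claws: wired from a non-query lACA PN inside the lACA; these inputs
  # must be excluded by the claw-input observation rule
  laca_claws <- unique(claw_tbl[grepl("\\.lclaw$", claw_tbl$branch_id),
    c("skeleton_id", "branch_id")])
  if (nrow(laca_claws)) {
    qid <- sort(names(Filter(function(p) !p$query &&
      "lACA" %in% p$segments$name, built$pn_layout)))[1]
    qsk <- built$skeletons[[qid]]
    qlay <- built$pn_layout[[qid]]
    qseg <- qlay$segments[qlay$segments$name == "lACA", ][1, ]
    for (r in seq_len(nrow(laca_claws))) {
      kc_id <- laca_claws$skeleton_id[r]; branch <- laca_claws$branch_id[r]
      n_syn <- ks$syn_per_input
      pre_rows <- qseg$from + (seq_len(n_syn) - 1L) %% (qseg$to - qseg$from + 1L)
      claw_nodes <- claw_tbl$node_id[claw_tbl$branch_id == branch]
      post_nodes <- claw_nodes[(seq_len(n_syn) - 1L) %% length(claw_nodes) + 1L]
      ksk <- built$skeletons[[kc_id]]
      post_rows <- match(post_nodes, ksk$node_id)
      syn[[length(syn) + 1L]] <- tibble(
        connector_id = sprintf("c%07d", cid + seq_len(n_syn)),
        x = ksk$x[post_rows], y = ksk$y[post_rows], z = ksk$z[post_rows],
        pre_skeleton = qid, pre_node = qsk$node_id[pre_rows],
        post_skeleton = kc_id, post_node = post_nodes
      )
      cid <- cid + n_syn
    }
  }

  list(synapses = dplyr::bind_rows(syn), claw_draws = dplyr::bind_rows(draws))
}

mirror_hemisphere <- function(cfg, built) {
  skeletons <- list()
  rows <- list()
  links <- list()
  rhs <- built$meta[built$meta$hemisphere == "R", ]
  for (i in seq_len(nrow(rhs))) {
    rid <- rhs$skeleton_id[i]
    lid <- sub("_R", "_L", rid, fixed = TRUE)
    skeletons[[lid]] <- mirror_skeleton(built$skeletons[[rid]], lid,
      midline_x = 0, jitter_sd = cfg$noise)
    rows[[lid]] <- tibble(skeleton_id = lid, neuron_class = rhs$neuron_class[i],
      type_label = rhs$type_label[i], hemisphere = "L",
      glomeruli = rhs$glomeruli[i], lineage = rhs$lineage[i],
      contralateral_partner = rid)
    links[[lid]] <- tibble(skeleton_id = rid, contralateral_partner = lid)
  }
  list(skeletons = skeletons, meta = dplyr::bind_rows(rows),
    partner_links = dplyr::bind_rows(links))
}

#' Draw a virtual Kenyon-cell claw-input population from bouton shares
#'
#' Standalone draw of the claw-input table the null model reasons about,
#' without building skeletons: each claw input is one class label drawn from
#' the (bias-adjusted) bouton share vector. The ground-truth share vector is
#' returned alongside.
#'
#' @param config a [synth_config()]; uses `kc_spec`, `bouton_counts`, `bias`
#'   and `seed`.
#' @return list with `draws` (tibble `skeleton_id`, `branch_id`,
#'   `class_label`, one row per claw input) and `shares` (the
#'   [effective_shares()] table).
#' @export
generate_kc_population <- function(config) {
  stopifnot(inherits(config, "consat_synth_config"))
  ks <- config$kc_spec
  shares <- effective_shares(config$bouton_counts, config$bias)
  if (ks$n_kc == 0) {
    return(list(draws = tibble(skeleton_id = character(), branch_id = character(),
      class_label = character()), shares = shares))
  }
  with_stage_seed(config$seed, "kc_population", {
    n_claws <- sample_range(ks$claws_min, ks$claws_max, ks$n_kc)
    kc <- rep(sprintf("KC_%03d", seq_len(ks$n_kc)), n_claws)
    claw <- unlist(lapply(n_claws, seq_len), use.names = FALSE)
    kc <- rep(kc, each = ks$inputs_per_claw)
    claw <- rep(claw, each = ks$inputs_per_claw)
    cls <- sample(shares$class_label, length(kc), replace = TRUE,
      prob = shares$effective_share)
    list(draws = tibble(skeleton_id = kc,
      branch_id = sprintf("%s.claw%d", kc, claw), class_label = cls),
      shares = shares)
  })
}

#' Generate well-separated synthetic neuron types for morphology tests
#'
#' Each type is a random-walk archetype seeded in its own spatial envelope;
#' instances are jittered copies of the archetype. Used to exercise the
#' similarity-scoring and clustering stages against known type labels.
#'
#' @param n_types number of types.
#' @param n_per_type instances per type.
#' @param seed integer seed.
#' @param jitter per-instance coordinate jitter sd (nm).
#' @param envelope_gap spacing between type envelopes (nm).
#' @param n_nodes nodes per archetype walk.
#' @return list with `skeletons` (named list) and `labels` (tibble
#'   `skeleton_id`, `type`).
#' @export
generate_type_population <- function(n_types = 2, n_per_type = 3, seed = 1,
                                     jitter = 300, envelope_gap = 60e3,
                                     n_nodes = 40) {
  withr::with_seed(as.integer(seed), {
    skeletons <- list()
    labels <- list()
    for (t in seq_len(n_types)) {
      box <- box_volume(paste0("env", t),
        c((t - 1) * envelope_gap, 0, 0),
        c((t - 1) * envelope_gap + 20e3, 20e3, 20e3))
      arch <- walk_in_box(n_nodes, box, step = 1000)
      for (i in seq_len(n_per_type)) {
        id <- sprintf("T%d_n%d", t, i)
        pts <- arch + matrix(stats::rnorm(3 * n_nodes, sd = jitter), ncol = 3)
        skeletons[[id]] <- skeleton(path_nodes(pts), id, validate = FALSE)
        labels[[id]] <- tibble(skeleton_id = id, type = paste0("T", t))
      }
    }
    list(skeletons = skeletons, labels = dplyr::bind_rows(labels))
  })
}
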