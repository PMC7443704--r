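#' Dotprops: resampled point/tangent clouds for morphology comparison
#'
#' Converts a skeleton into the point-cloud-with-tangents representation
#' used for NBLAST-style similarity scoring: arclength resampling of every
#' unbranched segment at `spacing`, with the tangent at each point taken as
#' the first principal axis of its `k` nearest resampled neighbours. Tangent
#' sign is irrelevant downstream (only absolute dot products are used).
#'
#' @param x a [skeleton()] with at least one edge.
#' @param spacing resample spacing in nanometres.
#' @param k neighbourhood size for tangent estimation (clamped to the number
#'   of points).
#' @return a `consat_dotprops`: list with `points` (N x 3), `vect` (N x 3
#'   unit tangents), `skeleton_id`, `spacing`.
#' @export
to_dotprops <- function(x, spacing = 1000, k = 5) {
  check_that(spacing > 0 && k >= 2, "spacing must be > 0 and k >= 2", "config")
  e <- skeleton_edges(x)
  if (!length(e$child)) {
    consat_abort("cannot build dotprops from a single-node skeleton",
      "degenerate_morphology")
  }
  pts <- resample_segments(x, spacing)
  n <- nrow(pts)
  kk <- min(k, n)
  vect <- matrix(0, n, 3)
  d2 <- as.matrix(stats::dist(pts))^2
  for (i in seq_len(n)) {
    nb <- order(d2[i, ])[seq_len(kk)]
    p <- pts[nb, , drop = FALSE]
    if (nrow(p) < 2) {
      vect[i, ] <- c(1, 0, 0)
      next
    }
    pc <- stats::prcomp(p, center = TRUE, scale. = FALSE)
    vect[i, ] <- pc$rotation[, 1]
  }
  vect <- vect / sqrt(rowSums(vect^2))
  structure(list(points = pts, vect = vect, skeleton_id = skeleton_id(x),
    spacing = spacing), class = "consat_dotprops")
}

#' @export
print.consat_dotprops <- function(x, ...) {
  cat(sprintf("<dotprops %s: %d points, spacing %g nm>\n",
    x$skeleton_id, nrow(x$points), x$spacing))
  invisible(x)
}

# split the tree into unbranched segments and resample each by arclength
resample_segments <- function(x, spacing) {
  parent <- match(x$parent_id, x$node_id)
  n_children <- tabulate(parent[!is.na(parent)], nbins = nrow(x))
  # a node starts a new segment if it is the root, or its parent is a
  # branchpoint (>= 2 children)
  starts_new <- is.na(parent) | n_children[ifelse(is.na(parent), 1L, parent)] > 1
  pts_list <- list()
  # walk each leaf-to-start path; collect segments between breakpoints
  coords <- cbind(x$x, x$y, x$z)
  children <- split(seq_len(nrow(x)), factor(parent, levels = seq_len(nrow(x))))
  seg_from <- which(starts_new)
  for (s in seg_from) {
    seg <- s
    cur <- s
    repeat {
      kids <- children[[cur]]
      if (length(kids) != 1) break
      if (starts_new[kids]) break
      seg <- c(seg, kids)
      cur <- kids
    }
    # prepend the parent so segments connect through branchpoints
    if (!is.na(parent[s])) seg <- c(parent[s], seg)
    if (length(seg) < 2) next
    pts_list[[length(pts_list) + 1L]] <- resample_path(coords[seg, , drop = FALSE],
      spacing)
  }
  if (!length(pts_list)) {
    # unbranched skeleton: a single path root -> leaf
    ord <- path_order(x)
    pts_list[[1]] <- resample_path(coords[ord, , drop = FALSE], spacing)
  }
  do.call(rbind, pts_list)
}

path_order <- function(x) {
  parent <- match(x$parent_id, x$node_id)
  ord <- integer(0)
  cur <- which(is.na(parent))
  children <- split(seq_len(nrow(x)), factor(parent, levels = seq_len(nrow(x))))
  while (length(cur)) {
    ord <- c(ord, cur[1])
    cur <- children[[cur[1]]]
  }
  ord
}

resample_path <- function(p, spacing) {
  if (nrow(p) < 2) return(p)
  seglen <- sqrt(rowSums(diff(p)^2))
  s <- c(0, cumsum(seglen))
  L <- s[length(s)]
  if (L == 0) return(p[1, , drop = FALSE])
  at <- seq(0, L, by = spacing)
  if (at[length(at)] < L) at <- c(at, L)
  cbind(stats::approx(s, p[, 1], xout = at)$y,
        stats::approx(s, p[, 2], xout = at)$y,
        stats::approx(s, p[, 3], xout = at)$y)
}

#' Raw NBLAST-style similarity of two dotprops clouds
#'
#' For every query point, find the nearest target point (distance `d`,
#' absolute tangent dot product `a`) and sum a score kernel over query
#' points. The default kernel is `exp(-d / sigma) * a` with `sigma =
#' 3000` nm, which rewards nearby, parallel cable. A tabulated
#' distance-bin x dot-product-bin score table ([score_table()]) may be
#' supplied instead and overrides the kernel. Nearest-neighbour ties break
#' to the lowest target point index.
#'
#' @param query,target `consat_dotprops` objects.
#' @param sigma kernel length scale in nanometres.
#' @param score_table optional [score_table()].
#' @return raw similarity score (a sum over query points).
#' @export
nblast_similarity <- function(query, target, sigma = 3000, score_table = NULL) {
  stopifnot(inherits(query, "consat_dotprops"), inherits(target, "consat_dotprops"))
  q <- query$points; t <- target$points
  # squared cross-distances, vectorised
  d2 <- outer(rowSums(q^2), rowSums(t^2), "+") - 2 * tcrossprod(q, t)
  nn <- max.col(-d2, ties.method = "first")
  d <- sqrt(pmax(d2[cbind(seq_len(nrow(q)), nn)], 0))
  a <- abs(rowSums(query$vect * target$vect[nn, , drop = FALSE]))
  a <- pmin(a, 1)
  if (is.null(score_table)) {
    sum(exp(-d / sigma) * a)
  } else {
    sum(score_table_lookup(score_table, d, a))
  }
}

#' Tabulated NBLAST score table
#'
#' A (distance bin x |dot product| bin) matrix of scores, compatible with
#' published score tables. Values outside the given breaks fall into the
#' nearest boundary bin.
#'
#' @param dist_breaks increasing distance bin boundaries (nm), length B+1.
#' @param dot_breaks increasing |dot| bin boundaries in `[0, 1]`, length D+1.
#' @param scores B x D numeric matrix.
#' @return a `consat_score_table`.
#' @export
score_table <- function(dist_breaks, dot_breaks, scores) {
  scores <- as.matrix(scores)
  stopifnot(length(dist_breaks) == nrow(scores) + 1,
            length(dot_breaks) == ncol(scores) + 1)
  structure(list(dist_breaks = dist_breaks, dot_breaks = dot_breaks,
    scores = scores), class = "consat_score_table")
}

score_table_lookup <- function(st, d, a) {
  bi <- pmin(pmax(findInterval(d, st$dist_breaks, all.inside = TRUE), 1),
    nrow(st$scores))
  bj <- pmin(pmax(findInterval(a, st$dot_breaks, all.inside = TRUE), 1),
    ncol(st$scores))
  st$scores[cbind(bi, bj)]
}

#' Mean normalized similarity score
#'
#' Normalizes the raw similarity by self-similarity and averages the forward
#' and reverse directions: `(S(q,t)/S(q,q) + S(t,q)/S(t,t)) / 2`. Equal
#' clouds score exactly 1; the value is symmetric in its arguments.
#'
#' @inheritParams nblast_similarity
#' @return mean normalized score in `[-Inf, 1]`.
#' @export
nblast_mean <- function(query, target, sigma = 3000, score_table = NULL) {
  sqq <- nblast_similarity(query, query, sigma, score_table)
  stt <- nblast_similarity(target, target, sigma, score_table)
  if (sqq == 0 || stt == 0) {
    consat_abort("zero self-similarity: degenerate dotprops", "degenerate_morphology")
  }
  (nblast_similarity(query, target, sigma, score_table) / sqq +
   nblast_similarity(target, query, sigma, score_table) / stt) / 2
}

#' All-pairs mean normalized score matrix
#'
#' @param dotprops_list named list of `consat_dotprops`.
#' @inheritParams nblast_similarity
#' @return square numeric matrix (diagonal exactly 1) with neuron ids as
#'   dimnames.
#' @export
score_matrix <- function(dotprops_list, sigma = 3000, score_table = NULL) {
  n <- length(dotprops_list)
  ids <- names(dotprops_list) %||%
    vapply(dotprops_list, function(d) d$skeleton_id, character(1))
  self <- vapply(dotprops_list, function(d)
    nblast_similarity(d, d, sigma, score_table), numeric(1))
  S <- diag(1, n)
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        fij <- nblast_similarity(dotprops_list[[i]], dotprops_list[[j]],
          sigma, score_table) / self[i]
        fji <- nblast_similarity(dotprops_list[[j]], dotprops_list[[i]],
          sigma, score_table) / self[j]
        S[i, j] <- S[j, i] <- (fij + fji) / 2
      }
    }
  }
  dimnames(S) <- list(ids, ids)
  S
}

#' Read/write a score matrix as labelled delimited text
#' @param x square score matrix with dimnames.
#' @param path file path.
#' @export
write_score_matrix <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, col.names = NA)
  invisible(path)
}

#' @rdname write_score_matrix
#' @export
read_score_matrix <- function(path) {
  as.matrix(utils::read.table(path, sep = "\t", header = TRUE, row.names = 1,
    check.names = FALSE))
}

#' Cluster neurons into types from a score matrix
#'
#' Agglomerates on the dissimilarity `1 - score` (clipped below at 0) with
#' Ward linkage and cuts the dendrogram at `cut_height`; the convention used
#' throughout the NBLAST typing literature.
#'
#' @param S square mean-normalized score matrix with dimnames.
#' @param cut_height dendrogram cut height (default 0.8).
#' @return list of class `consat_typing`: `labels` (tibble `skeleton_id`,
#'   `group`), `hclust` (the dendrogram), `cut_height`.
#' @export
cluster_types <- function(S, cut_height = 0.8) {
  check_that(all(is.finite(S)), "non-finite scores in score matrix", "config")
  d <- stats::as.dist(pmax(1 - S, 0))
  hc <- stats::hclust(d, method = "ward.D2")
  grp <- stats::cutree(hc, h = cut_height)
  structure(list(
    labels = tibble(skeleton_id = names(grp), group = unname(grp)),
    hclust = hc, cut_height = cut_height
  ), class = "consat_typing")
}

#' @export
print.consat_typing <- function(x, ...) {
  cat(sprintf("<typing: %d neurons in %d groups at cut height %g>\n",
    nrow(x$labels), length(unique(x$labels$group)), x$cut_height))
  invisible(x)
}

#' Export a typing dendrogram as Newick
#' @param typing a [cluster_types()] result.
#' @param path output file.
#' @export
write_typing_newick <- function(typing, path) {
  ape::write.tree(ape::as.phylo(typing$hclust), file = path)
  invisible(path)
}

#' Match neurons to their contralateral partners by mirrored similarity
#'
#' Reflects one hemisphere's dotprops about the sagittal plane
#' `x = midline_x` (a rigid reflection; no nonrigid registration), scores
#' all pairs, and counts the neurons whose highest-scoring partner (highest
#' off-diagonal mean normalized score) is their annotated contralateral
#' partner. Neurons without a hemisphere annotation are excluded with a
#' warning.
#'
#' @param dotprops_list named list of `consat_dotprops`.
#' @param meta a [neuron_meta()] table with `hemisphere` and
#'   `contralateral_partner`.
#' @param midline_x x coordinate of the sagittal midline plane (nm).
#' @inheritParams nblast_similarity
#' @return list: `count` (number of neurons that paired), `n_eligible`,
#'   `pairs` (tibble `skeleton_id`, `best_match`, `annotated_partner`,
#'   `paired`).
#' @export
match_contralateral <- function(dotprops_list, meta, midline_x = 0,
                                sigma = 3000, score_table = NULL) {
  ids <- names(dotprops_list)
  hemi <- meta$hemisphere[match(ids, meta$skeleton_id)]
  if (anyNA(hemi)) {
    consat_warn(sprintf("%d neurons without hemisphere excluded from matching",
      sum(is.na(hemi))), "missing_hemisphere")
    dotprops_list <- dotprops_list[!is.na(hemi)]
    ids <- ids[!is.na(hemi)]
    hemi <- hemi[!is.na(hemi)]
  }
  if (length(unique(hemi)) < 2) {
    return(list(count = 0L, n_eligible = 0L,
      pairs = tibble(skeleton_id = character(), best_match = character(),
        annotated_partner = character(), paired = logical())))
  }
  mirrored <- dotprops_list
  for (i in which(hemi == "L")) {
    mirrored[[i]]$points[, 1] <- 2 * midline_x - mirrored[[i]]$points[, 1]
    mirrored[[i]]$vect[, 1] <- -mirrored[[i]]$vect[, 1]
  }
  S <- score_matrix(mirrored, sigma = sigma, score_table = score_table)
  partner <- meta$contralateral_partner[match(ids, meta$skeleton_id)]
  eligible <- which(!is.na(partner) & partner %in% ids)
  best <- character(length(ids))
  for (i in seq_along(ids)) {
    s <- S[i, ]
    s[i] <- -Inf
    best[i] <- ids[which.max(s)]
  }
  pairs <- tibble(
    skeleton_id = ids[eligible],
    best_match = best[eligible],
    annotated_partner = partner[eligible],
    paired = best[eligible] == partner[eligible]
  )
  list(count = sum(pairs$paired), n_eligible = length(eligible), pairs = pairs)
}

#' Flag the dendritic (claw-bearing) nodes of a Kenyon cell in the calyx
#'
#' The main tract is taken as the root-to-tip path of maximal cable length;
#' dendrite nodes are nodes inside `calyx_volume` lying on side branches off
#' that path. A KC that does not intersect the calyx yields an empty set
#' with a warning.
#'
#' @param x a KC [skeleton()].
#' @param calyx_volume a volume.
#' @return character vector of dendrite-flagged node ids.
#' @export
split_dendrites <- function(x, calyx_volume) {
  inside <- point_in_volume(cbind(x$x, x$y, x$z), calyx_volume)
  if (!any(inside)) {
    consat_warn(sprintf("skeleton %s does not intersect volume %s",
      skeleton_id(x), calyx_volume$name), "no_calyx_overlap")
    return(character(0))
  }
  parent <- match(x$parent_id, x$node_id)
  e <- skeleton_edges(x)
  elen <- sqrt((x$x[e$child] - x$x[e$parent])^2 +
               (x$y[e$child] - x$y[e$parent])^2 +
               (x$z[e$child] - x$z[e$parent])^2)
  # distance from root along the tree, by parent chasing in topological order
  dist_root <- rep(NA_real_, nrow(x))
  dist_root[is.na(parent)] <- 0
  edge_len <- rep(NA_real_, nrow(x))
  edge_len[e$child] <- elen
  todo <- which(!is.na(parent))
  while (length(todo)) {
    ready <- todo[!is.na(dist_root[parent[todo]])]
    if (!length(ready)) break
    dist_root[ready] <- dist_root[parent[ready]] + edge_len[ready]
    todo <- setdiff(todo, ready)
  }
  tip <- which.max(dist_root)
  main <- logical(nrow(x))
  cur <- tip
  while (!is.na(cur)) {
    main[cur] <- TRUE
    cur <- parent[cur]
  }
  x$node_id[inside & !main]
}
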