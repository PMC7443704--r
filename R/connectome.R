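#' Neuron metadata tables
#'
#' One row per neuron: class (`RN`, `PN`, `KC`, `LHN`, `DN`, `other`), a free
#' type label (e.g. `"VP3 vPN"`), hemisphere (`R`/`L`), innervated glomeruli
#' (semicolon-separated, first = primary), neuroblast lineage, and the
#' annotated contralateral partner when one exists.
#'
#' @param x data frame with columns `skeleton_id`, `neuron_class`,
#'   `type_label`, `hemisphere`, `glomeruli`, `lineage`,
#'   `contralateral_partner` (the last three may be `NA`).
#' @return validated tibble of class `consat_meta`.
#' @export
neuron_meta <- function(x) {
  cols <- c("skeleton_id", "neuron_class", "type_label", "hemisphere",
    "glomeruli", "lineage", "contralateral_partner")
  x <- as_tibble(x)
  for (col in setdiff(cols, names(x))) x[[col]] <- NA_character_
  x <- x[, cols]
  for (col in cols) x[[col]] <- as.character(x[[col]])
  check_that(!anyDuplicated(x$skeleton_id),
    "duplicated skeleton_id in metadata table", "malformed_meta")
  known <- c("RN", "PN", "KC", "LHN", "DN", "other")
  check_that(all(x$neuron_class %in% known),
    paste("neuron_class must be one of:", paste(known, collapse = ", ")),
    "malformed_meta")
  check_that(all(is.na(x$hemisphere) | x$hemisphere %in% c("R", "L")),
    "hemisphere must be R or L", "malformed_meta")
  class(x) <- c("consat_meta", class(tibble()))
  x
}

#' @rdname neuron_meta
#' @param path file path.
#' @param delim field delimiter.
#' @export
read_neuron_meta <- function(path, delim = "\t") {
  neuron_meta(readr::read_delim(path, delim = delim,
    col_types = readr::cols(.default = "c"), progress = FALSE))
}

#' @rdname neuron_meta
#' @export
write_neuron_meta <- function(x, path, delim = "\t") {
  readr::write_delim(as_tibble(x), path, delim = delim)
  invisible(path)
}

#' Primary glomerulus of each neuron in a metadata table
#' @param meta a [neuron_meta()] table.
#' @return character vector (NA where none annotated).
#' @export
primary_glomerulus <- function(meta) {
  vapply(strsplit(meta$glomeruli, ";"), function(g) {
    if (!length(g) || all(is.na(g))) NA_character_ else g[1]
  }, character(1))
}

#' Assemble a connectome
#'
#' The container every analysis consumes: skeletons, the polyadic synapse
#' table, neuron metadata, named neuropil volumes, and optional annotation
#' tables (per-PN calyx bouton counts; per-KC claw membership mapping claw
#' branch ids to skeleton nodes).
#'
#' @param skeletons named list of [skeleton()] objects (names = skeleton ids).
#' @param synapses a [synapse_table()].
#' @param meta a [neuron_meta()] table.
#' @param volumes named list of volumes ([box_volume()] / [mesh_volume()]).
#' @param boutons optional tibble `skeleton_id`, `class_label`, `n_boutons`.
#' @param claws optional tibble `skeleton_id`, `branch_id`, `node_id`
#'   (one row per claw node).
#' @param validate check cross-references.
#' @return a `consat_connectome` list.
#' @export
connectome <- function(skeletons, synapses, meta, volumes = list(),
                       boutons = NULL, claws = NULL, validate = TRUE) {
  if (is.null(names(skeletons)) && length(skeletons)) {
    names(skeletons) <- vapply(skeletons, skeleton_id, character(1))
  }
  x <- structure(list(
    skeletons = skeletons,
    synapses = synapses,
    meta = meta,
    volumes = volumes,
    boutons = if (is.null(boutons)) NULL else as_tibble(boutons),
    claws = if (is.null(claws)) NULL else as_tibble(claws)
  ), class = "consat_connectome")
  if (validate) validate_connectome(x)
  x
}

#' @rdname connectome
#' @param x a connectome.
#' @export
validate_connectome <- function(x) {
  ids <- names(x$skeletons)
  syn <- x$synapses
  check_that(all(syn$pre_skeleton %in% ids) && all(syn$post_skeleton %in% ids),
    "synapse table references unknown skeletons", "malformed_connectome")
  if (!is.null(x$boutons)) {
    check_that(all(x$boutons$skeleton_id %in% ids),
      "bouton table references unknown skeletons", "malformed_connectome")
  }
  if (!is.null(x$claws)) {
    check_that(all(x$claws$skeleton_id %in% ids),
      "claw table references unknown skeletons", "malformed_connectome")
  }
  invisible(x)
}

#' @export
print.consat_connectome <- function(x, ...) {
  cat(sprintf(
    "<connectome: %d skeletons, %d connectors (%d postsynaptic links), %d volumes>\n",
    length(x$skeletons), length(unique(x$synapses$connector_id)),
    nrow(x$synapses), length(x$volumes)))
  invisible(x)
}

#' Write every table of a connectome to a directory as delimited text
#'
#' Skeletons go to `swc/<id>.swc` (nanometre units), synapses to
#' `synapses.tsv`, metadata to `meta.tsv`, bouton and claw annotations to
#' `boutons.tsv` / `claws.tsv`, box volumes to `volumes.tsv`.
#'
#' @param x a connectome.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_connectome <- function(x, dir) {
  dir.create(file.path(dir, "swc"), recursive = TRUE, showWarnings = FALSE)
  for (sk in x$skeletons) {
    write_swc(sk, file.path(dir, "swc", paste0(skeleton_id(sk), ".swc")))
  }
  write_synapse_table(x$synapses, file.path(dir, "synapses.tsv"))
  write_neuron_meta(x$meta, file.path(dir, "meta.tsv"))
  if (!is.null(x$boutons)) readr::write_tsv(x$boutons, file.path(dir, "boutons.tsv"))
  if (!is.null(x$claws)) readr::write_tsv(x$claws, file.path(dir, "claws.tsv"))
  boxes <- Filter(function(v) v$kind == "box", x$volumes)
  if (length(boxes)) {
    readr::write_tsv(dplyr::bind_rows(lapply(boxes, function(v) {
      tibble(name = v$name, xmin = v$min[1], ymin = v$min[2], zmin = v$min[3],
        xmax = v$max[1], ymax = v$max[2], zmax = v$max[3])
    })), file.path(dir, "volumes.tsv"))
  }
  invisible(dir)
}

#' Read a connectome written by [write_connectome()]
#' @param dir directory path.
#' @return a connectome.
#' @export
read_connectome <- function(dir) {
  swc <- list.files(file.path(dir, "swc"), pattern = "\\.swc$", full.names = TRUE)
  skeletons <- lapply(swc, read_swc, unit_scale = 1)
  names(skeletons) <- vapply(skeletons, skeleton_id, character(1))
  volumes <- list()
  vp <- file.path(dir, "volumes.tsv")
  if (file.exists(vp)) {
    vt <- readr::read_tsv(vp, col_types = "cdddddd", progress = FALSE)
    volumes <- lapply(seq_len(nrow(vt)), function(i) {
      box_volume(vt$name[i], c(vt$xmin[i], vt$ymin[i], vt$zmin[i]),
        c(vt$xmax[i], vt$ymax[i], vt$zmax[i]))
    })
    names(volumes) <- vt$name
  }
  bp <- file.path(dir, "boutons.tsv")
  cp <- file.path(dir, "claws.tsv")
  connectome(
    skeletons = skeletons,
    synapses = read_synapse_table(file.path(dir, "synapses.tsv")),
    meta = read_neuron_meta(file.path(dir, "meta.tsv")),
    volumes = volumes,
    boutons = if (file.exists(bp)) readr::read_tsv(bp, col_types = "ccd", progress = FALSE),
    claws = if (file.exists(cp)) readr::read_tsv(cp, col_types = "ccc", progress = FALSE)
  )
}
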