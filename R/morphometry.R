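#' Extract the histomorphometry region of interest
#'
#' The BIC (bone-implant contact) ROI is the implant-callus interface
#' restricted to the upper flanks, lower flanks and roots of all threads —
#' crest faces, the collar, the apex and the tip are excluded. The BA
#' (bone area) ROI is the set of callus elements lying inside the healing
#' chambers, i.e. between the threads (radially inside the crest radius
#' within the threaded band).
#'
#' @param mesh an `oh_mesh` built from an implant layout.
#' @param profile optional override of the implant profile (defaults to the
#'   one stored in the mesh layout).
#' @return A list of class `oh_roi`: `edges` (interface edge tibble with
#'   `from`, `to`, `type`, `length`, `thread`, `adj_element`), `elements`
#'   (tibble `element`, `area`, `thread`), `length_total`, `area_total`.
#' @export
extract_roi <- function(mesh, profile = NULL) {
  if (is.null(mesh$interface)) {
    rlang::abort("mesh carries no implant-callus interface tag")
  }
  prof <- if (is.null(profile)) mesh$layout$profile else profile
  edges <- mesh$interface[
    mesh$interface$type %in% c("upper_flank", "root", "lower_flank"), ,
    drop = FALSE]
  z_hi <- prof$z_threads[2]
  pitch <- prof$params$pitch
  thread_of <- function(z) {
    pmin(pmax(ceiling((z_hi - z) / pitch + 1e-9), 1L),
         prof$params$n_threads)
  }
  cal <- mesh$elements[mesh$elements$region == "callus", , drop = FALSE]
  conn <- as.matrix(cal[, c("n1", "n2", "n3", "n4")])
  if (nrow(edges) > 0) {
    # adjacent callus element: the callus quad sharing both edge nodes
    key <- paste(pmin(edges$from, edges$to), pmax(edges$from, edges$to))
    pair_keys <- c(
      paste(pmin(conn[, 1], conn[, 2]), pmax(conn[, 1], conn[, 2])),
      paste(pmin(conn[, 2], conn[, 3]), pmax(conn[, 2], conn[, 3])),
      paste(pmin(conn[, 3], conn[, 4]), pmax(conn[, 3], conn[, 4])),
      paste(pmin(conn[, 4], conn[, 1]), pmax(conn[, 4], conn[, 1])))
    pair_elem <- rep(cal$element, 4)
    hit <- match(key, pair_keys)
    if (anyNA(hit)) {
      rlang::abort("some ROI interface edges adjoin no callus element")
    }
    edges$adj_element <- pair_elem[hit]
    zmid <- (mesh$nodes$z[edges$from] + mesh$nodes$z[edges$to]) / 2
    edges$thread <- thread_of(zmid)
  } else {
    edges$adj_element <- integer(0)
    edges$thread <- integer(0)
  }
  cen_r <- rowMeans(matrix(mesh$nodes$r[conn], ncol = 4))
  cen_z <- rowMeans(matrix(mesh$nodes$z[conn], ncol = 4))
  in_band <- cen_z > prof$z_threads[1] & cen_z < prof$z_threads[2]
  in_chamber <- in_band & cen_r < prof$outer_radius - 1e-9
  elements <- tibble::tibble(element = cal$element[in_chamber],
                             area = cal$area[in_chamber],
                             thread = thread_of(cen_z[in_chamber]))
  structure(list(edges = edges, elements = elements,
                 length_total = sum(edges$length),
                 area_total = sum(elements$area)),
            class = "oh_roi")
}

bone_classes <- c("mature_bone", "immature_bone")

phenotype_of <- function(phenotypes, elements) {
  if (is.data.frame(phenotypes)) {
    as.character(phenotypes$phenotype)[match(elements, phenotypes$element)]
  } else {
    as.character(phenotypes[elements])
  }
}

#' Bone-implant contact (BIC)
#'
#' Percentage of the ROI interface length whose adjacent callus element is
#' mature or immature bone.
#'
#' @param phenotypes data frame with `element` and `phenotype` (or a vector
#'   indexed by element id).
#' @param roi an [extract_roi()] result.
#' @param mesh the mesh.
#' @return One-row tibble `bic_percent`, `bic_mature`, `bic_immature`.
#' @export
bone_implant_contact <- function(phenotypes, roi, mesh) {
  if (nrow(roi$edges) == 0 || roi$length_total == 0) {
    return(tibble::tibble(bic_percent = 0, bic_mature = 0,
                          bic_immature = 0))
  }
  phen <- phenotype_of(phenotypes, roi$edges$adj_element)
  if (anyNA(phen)) {
    rlang::abort("phenotypes missing for some ROI-adjacent elements")
  }
  tot <- roi$length_total
  tibble::tibble(
    bic_percent = 100 * sum(roi$edges$length[phen %in% bone_classes]) / tot,
    bic_mature = 100 * sum(roi$edges$length[phen == "mature_bone"]) / tot,
    bic_immature = 100 *
      sum(roi$edges$length[phen == "immature_bone"]) / tot)
}

#' Bone area (BA)
#'
#' Percentage of the ROI (inter-thread) area occupied by mature or immature
#' bone elements; in-plane element areas mimic a histology section.
#'
#' @inheritParams bone_implant_contact
#' @return One-row tibble `ba_percent`, `ba_mature`, `ba_immature`.
#' @export
bone_area <- function(phenotypes, roi, mesh) {
  if (nrow(roi$elements) == 0 || roi$area_total == 0) {
    return(tibble::tibble(ba_percent = 0, ba_mature = 0, ba_immature = 0))
  }
  phen <- phenotype_of(phenotypes, roi$elements$element)
  if (anyNA(phen)) {
    rlang::abort("phenotypes missing for some ROI elements")
  }
  tot <- roi$area_total
  tibble::tibble(
    ba_percent = 100 * sum(roi$elements$area[phen %in% bone_classes]) / tot,
    ba_mature = 100 * sum(roi$elements$area[phen == "mature_bone"]) / tot,
    ba_immature = 100 *
      sum(roi$elements$area[phen == "immature_bone"]) / tot)
}

#' Combined morphometry scores
#'
#' @inheritParams bone_implant_contact
#' @return One-row tibble with BIC and BA totals and their mature/immature
#'   splits.
#' @export
morphometry <- function(phenotypes, roi, mesh) {
  dplyr::bind_cols(bone_implant_contact(phenotypes, roi, mesh),
                   bone_area(phenotypes, roi, mesh))
}

#' Mean callus Young's modulus per healing day
#'
#' Area-weighted average of the element Young's modulus over the callus,
#' tracking the overall stiffening of the healing tissue.
#'
#' @param history an `oh_healing` run.
#' @return Tibble `day`, `mean_modulus` (MPa).
#' @export
mean_modulus_history <- function(history) {
  stopifnot(inherits(history, "oh_healing"))
  history$daily[, c("day", "mean_modulus")]
}

#' Histogram of callus element Young's moduli
#'
#' @param field tibble with `element` and `young_modulus` (e.g. one entry
#'   of an `oh_healing` `fields` list, or its `final_materials` restricted
#'   to the callus).
#' @param bin_edges histogram bin edges (MPa) covering all values.
#' @return Tibble `bin_lo`, `bin_hi`, `count`.
#' @export
modulus_histogram <- function(field, bin_edges) {
  x <- field$young_modulus
  if (any(x < bin_edges[1] | x > bin_edges[length(bin_edges)])) {
    rlang::abort("bin_edges do not cover all modulus values")
  }
  ct <- graphics::hist(x, breaks = bin_edges, plot = FALSE)$counts
  tibble::tibble(bin_lo = bin_edges[-length(bin_edges)],
                 bin_hi = bin_edges[-1], count = as.integer(ct))
}
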