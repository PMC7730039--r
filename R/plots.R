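# ggplot2 views of meshes and healing runs.

element_polygons <- function(mesh, values = NULL) {
  conn <- mesh_conn(mesh)
  df <- tibble::tibble(
    element = rep(mesh$elements$element, each = 4),
    r = as.vector(t(matrix(mesh$nodes$r[conn], ncol = 4))),
    z = as.vector(t(matrix(mesh$nodes$z[conn], ncol = 4))))
  if (!is.null(values)) df$value <- rep(values, each = 4)
  df
}

#' Plot the tissue phenotype map of one healing day
#'
#' @param history an `oh_healing` run.
#' @param day healing day to show (default: last).
#' @return A ggplot object.
#' @export
plot_phenotype_map <- function(history, day = history$days) {
  fld <- history$fields[[day]]
  mesh <- history$mesh
  phen <- rep("fixed bone/implant", nrow(mesh$elements))
  phen[fld$element] <- as.character(fld$phenotype)
  df <- element_polygons(mesh, phen)
  pal <- c(fibrous_tissue = "#c7a26b", cartilage = "#7fbf7b",
           immature_bone = "#92c5de", mature_bone = "#2166ac",
           resorption = "#b2182b", granulation = "#f7f4ef",
           `fixed bone/implant` = "grey85")
  ggplot2::ggplot(df, ggplot2::aes(.data$r, .data$z, group = .data$element,
                                   fill = .data$value)) +
    ggplot2::geom_polygon(colour = NA) +
    ggplot2::scale_fill_manual(values = pal, name = NULL) +
    ggplot2::coord_equal() +
    ggplot2::labs(title = paste("Tissue phenotypes, day", day),
                  x = "r (mm)", y = "z (mm)") +
    ggplot2::theme_minimal()
}

#' Plot the callus-mean Young's modulus evolution
#'
#' @param object an `oh_healing` run.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.oh_healing <- function(object, ...) {
  ggplot2::ggplot(object$daily,
                  ggplot2::aes(.data$day, .data$mean_modulus)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "healing day",
                  y = "mean callus Young's modulus (MPa)") +
    ggplot2::theme_minimal()
}

#' Histogram of callus element Young's moduli on one day
#'
#' @param history an `oh_healing` run.
#' @param day healing day (default: last).
#' @param binwidth bin width in MPa.
#' @return A ggplot object.
#' @export
plot_modulus_histogram <- function(history, day = history$days,
                                   binwidth = 250) {
  fld <- history$fields[[day]]
  ggplot2::ggplot(fld, ggplot2::aes(.data$young_modulus)) +
    ggplot2::geom_histogram(binwidth = binwidth, boundary = 0,
                            fill = "#2166ac", colour = "white") +
    ggplot2::labs(x = "element Young's modulus (MPa)", y = "elements",
                  title = paste("Callus modulus distribution, day", day)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
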