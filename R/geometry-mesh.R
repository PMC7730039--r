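#' Generate a quadrilateral mesh for a domain layout
#'
#' Builds a boundary-fitted structured quadrilateral mesh. Horizontal mesh
#' lines are placed at every geometric breakpoint (profile vertices, callus
#' and cortical interfaces) and refined to the target element size; within
#' each row the radial nodes are graded in three bands — implant interior,
#' callus band, outer bone — whose limits follow the implant outline. Every
#' element therefore has two exactly horizontal edges (a trapezoid), which
#' guarantees positive Jacobians, and every region boundary lies on mesh
#' lines, so region areas are conserved exactly. Element regions are
#' assigned by polygon containment of element centroids.
#'
#' @param layout an [build_domain()] or [rectangle_layout()] result.
#' @param element_size target element edge length (mm).
#' @return A list of class `oh_mesh` with `nodes` (tibble `node`, `r`, `z`),
#'   `elements` (tibble `element`, `n1`..`n4` counter-clockwise, `region`,
#'   `area`), `boundaries` (named lists of node indices), `interface`
#'   (tibble of implant-callus interface edges with `from`, `to`, `type`,
#'   `length`), `layout` and `element_size_target`.
#' @export
generate_mesh <- function(layout, element_size = 0.05) {
  stopifnot(inherits(layout, "oh_layout"), element_size > 0)
  h <- element_size
  W <- layout$extent[["width"]]
  H <- layout$extent[["height"]]
  prof <- layout$profile
  tol <- 1e-9

  if (is.null(prof)) {
    z_break <- c(0, H)
  } else {
    m <- layout$callus_margin
    z_tip <- layout$z_tip
    z_break <- sort(unique(c(0, z_tip - m, z_tip,
                             prof$outline$z,
                             if (layout$cortical_thickness > 0)
                               H - layout$cortical_thickness,
                             H)))
    z_break <- z_break[!duplicated(round(z_break / tol))]
  }

  refine <- function(breaks, target) {
    out <- numeric(0)
    for (i in seq_len(length(breaks) - 1)) {
      n <- max(1, ceiling((breaks[i + 1] - breaks[i]) / target - 1e-9))
      out <- c(out, seq(breaks[i], breaks[i + 1],
                        length.out = n + 1)[-(n + 1)])
    }
    c(out, breaks[length(breaks)])
  }
  z_levels <- refine(z_break, h)
  nz <- length(z_levels)

  if (is.null(prof)) {
    r0 <- if (is.null(layout$r0)) 0 else layout$r0
    nr_seg <- max(1, ceiling(W / h - 1e-9))
    r_rows <- matrix(rep(seq(r0, r0 + W, length.out = nr_seg + 1),
                         each = nz), nrow = nz)
  } else {
    m <- layout$callus_margin
    z_tip <- layout$z_tip
    f_ext <- function(z) {
      fz <- profile_radius(prof, pmax(z, z_tip))
      fz
    }
    fz <- f_ext(z_levels)
    n1 <- max(1, ceiling(prof$outer_radius / h - 1e-9))
    n2 <- max(1, ceiling(m / h - 1e-9))
    n3 <- max(1, ceiling((W - prof$core_radius - m) / h - 1e-9))
    r_rows <- t(vapply(seq_len(nz), function(k) {
      c(seq(0, fz[k], length.out = n1 + 1),
        seq(fz[k], fz[k] + m, length.out = n2 + 1)[-1],
        seq(fz[k] + m, W, length.out = n3 + 1)[-1])
    }, numeric(n1 + n2 + n3 + 1)))
  }
  nr <- ncol(r_rows)

  nodes <- tibble::tibble(
    node = seq_len(nz * nr),
    r = as.vector(t(r_rows)),
    z = rep(z_levels, each = nr))
  nid <- function(k, j) (k - 1L) * nr + j
  k <- rep(seq_len(nz - 1), each = nr - 1)
  j <- rep(seq_len(nr - 1), times = nz - 1)
  elements <- tibble::tibble(
    element = seq_along(k),
    n1 = nid(k, j), n2 = nid(k, j + 1),
    n3 = nid(k + 1, j + 1), n4 = nid(k + 1, j))

  conn <- as.matrix(elements[, c("n1", "n2", "n3", "n4")])
  coords <- cbind(nodes$r, nodes$z)
  minJ <- .element_min_jacobian(coords, conn)
  if (any(minJ <= 0)) {
    rlang::abort(paste0(sum(minJ <= 0),
                        " mesh elements have non-positive Jacobians"))
  }
  cen_r <- rowMeans(matrix(nodes$r[conn], ncol = 4))
  cen_z <- rowMeans(matrix(nodes$z[conn], ncol = 4))
  region <- rep(NA_character_, nrow(elements))
  for (nm in names(layout$regions)) {
    hit <- is.na(region) &
      points_in_polygon(cen_r, cen_z, layout$regions[[nm]])
    region[hit] <- nm
  }
  if (anyNA(region)) {
    rlang::abort("some element centroids fall in no layout region")
  }
  elements$region <- region
  # in-plane area of each trapezoid element
  r1 <- nodes$r[conn[, 1]]; z1 <- nodes$z[conn[, 1]]
  r2 <- nodes$r[conn[, 2]]; z2 <- nodes$z[conn[, 2]]
  r3 <- nodes$r[conn[, 3]]; z3 <- nodes$z[conn[, 3]]
  r4 <- nodes$r[conn[, 4]]; z4 <- nodes$z[conn[, 4]]
  elements$area <- abs((r1 * z2 - r2 * z1) + (r2 * z3 - r3 * z2) +
                         (r3 * z4 - r4 * z3) + (r4 * z1 - r1 * z4)) / 2

  near <- function(a, b) abs(a - b) < 1e-7
  boundaries <- list(
    axis = nodes$node[near(nodes$r, 0)],
    fixed_base = nodes$node[near(nodes$z, 0)],
    inner_wall = nodes$node[near(nodes$r, min(nodes$r))],
    outer_wall = nodes$node[near(nodes$r, max(nodes$r))],
    top_surface = nodes$node[near(nodes$z, H)])

  interface <- NULL
  if (!is.null(prof)) {
    fH <- profile_radius(prof, H)
    boundaries$load_surface <-
      nodes$node[near(nodes$z, H) & nodes$r <= fH + 1e-7]
    f_tip_r <- profile_radius(prof, z_tip)
    on_origin <-
      (near(nodes$r, f_ext(nodes$z) + m) & nodes$z >= z_tip - m - 1e-7) |
      (near(nodes$z, z_tip - m) & nodes$r <= f_tip_r + m + 1e-7)
    boundaries$cells_origin <- nodes$node[on_origin]
    # drained exterior: outer wall, base, and the top bone/callus surface
    boundaries$drained <- sort(unique(c(
      boundaries$fixed_base, boundaries$outer_wall,
      nodes$node[near(nodes$z, H) & nodes$r >= fH - 1e-7])))
    # implant-callus interface edges: along the outline and under the tip
    icol <- n1 + 1L # radial index of the outline column
    rows_above <- which(z_levels >= z_tip - 1e-9)
    col_nodes <- nid(rows_above, rep(icol, length(rows_above)))
    seg_type <- function(zm) {
      s <- prof$segments
      i <- findInterval(-zm, -s$z_hi) # segments ordered z decreasing
      i <- pmin(pmax(i, 1L), nrow(s))
      s$type[i]
    }
    e_from <- col_nodes[-length(col_nodes)]
    e_to <- col_nodes[-1]
    zmid <- (nodes$z[e_from] + nodes$z[e_to]) / 2
    iface1 <- tibble::tibble(
      from = e_from, to = e_to, type = seg_type(zmid),
      length = sqrt((nodes$r[e_to] - nodes$r[e_from])^2 +
                      (nodes$z[e_to] - nodes$z[e_from])^2))
    ktip <- which(near(z_levels, z_tip))[1]
    tip_nodes <- nid(rep(ktip, icol), seq_len(icol))
    iface2 <- tibble::tibble(
      from = tip_nodes[-icol], to = tip_nodes[-1], type = "tip",
      length = abs(nodes$r[tip_nodes[-1]] - nodes$r[tip_nodes[-icol]]))
    interface <- rbind(iface1, iface2)
    boundaries$implant_callus_interface <-
      sort(unique(c(interface$from, interface$to)))
  } else {
    boundaries$drained <- sort(unique(c(boundaries$fixed_base,
                                        boundaries$outer_wall,
                                        boundaries$top_surface)))
  }

  structure(list(nodes = nodes, elements = elements,
                 boundaries = boundaries, interface = interface,
                 layout = layout, element_size_target = h),
            class = "oh_mesh")
}

#' @export
#' @method print oh_mesh
print.oh_mesh <- function(x, ...) {
  cat("<oh_mesh> ", nrow(x$nodes), " nodes, ", nrow(x$elements),
      " quads; regions: ",
      paste(names(table(x$elements$region)), collapse = ", "),
      "; target h = ", x$element_size_target, " mm\n", sep = "")
  invisible(x)
}

#' Summed element areas per region
#'
#' @param mesh an `oh_mesh`.
#' @return Tibble with `region` and `area` (mm^2).
#' @export
mesh_region_areas <- function(mesh) {
  dplyr::summarise(dplyr::group_by(mesh$elements, .data$region),
                   area = sum(.data$area), .groups = "drop")
}

# connectivity matrix helper used by the solvers
mesh_conn <- function(mesh) {
  as.matrix(mesh$elements[, c("n1", "n2", "n3", "n4")])
}

mesh_coords <- function(mesh) {
  cbind(mesh$nodes$r, mesh$nodes$z)
}
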