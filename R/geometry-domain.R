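#' Lay out the simulation domain around an implant
#'
#' Places the implant in a rectangular half-plane domain `[0, width] x
#' [0, height]` with the implant top face flush with the top of the domain
#' (z = height) and the tip at `z = height - length_total`. The healing
#' callus is a band of width `callus_margin` offset radially from the
#' implant outline, wrapping under the tip; a cortical stratum of the given
#' thickness spans the top of the bone; the remainder is cancellous bone.
#' All region boundaries are polygons whose union tiles the domain
#' rectangle exactly.
#'
#' @param profile an [build_chamber_profile()] result.
#' @param cortical_thickness thickness of the top cortical stratum (mm);
#'   0 suppresses the cortical region.
#' @param callus_margin radial width of the healing callus band (mm), > 0.
#' @param domain_extent numeric `c(width, height)` of the domain (mm).
#' @return A list of class `oh_layout` with `regions` (named list of closed
#'   polygons: implant, callus, cortical, cancellous), `boundaries` (named
#'   polylines: axis, load_surface, fixed_base, cells_origin,
#'   implant_callus_interface), the shifted `profile`, `z_tip`, `extent`,
#'   `callus_margin` and `cortical_thickness`.
#' @export
build_domain <- function(profile, cortical_thickness = 1.5,
                         callus_margin = 0.5,
                         domain_extent = c(5, 12)) {
  stopifnot(inherits(profile, "oh_profile"), callus_margin > 0,
            length(domain_extent) == 2)
  W <- domain_extent[1]
  H <- domain_extent[2]
  m <- callus_margin
  tc <- cortical_thickness
  L <- profile$length_total
  if (H <= L) rlang::abort("domain height must exceed the implant length")
  if (profile$outer_radius + m >= W) {
    rlang::abort(paste0(
      "callus band extends outside the domain: outer radius + margin = ",
      profile$outer_radius + m, " mm >= domain width ", W, " mm"))
  }
  if (tc < 0 || tc >= L) {
    rlang::abort("cortical thickness must be in [0, implant length)")
  }
  z_tip <- H - L
  if (z_tip - m <= 0) {
    rlang::abort("callus band extends below the domain: increase height")
  }
  shift <- function(df) {
    df$z <- df$z + z_tip
    df
  }
  prof <- profile
  prof$outline <- shift(profile$outline)
  prof$segments <- within_shift(profile$segments, z_tip)
  prof$polyline <- shift(profile$polyline)
  prof$z_threads <- profile$z_threads + z_tip

  o <- prof$outline # z decreasing from H to z_tip
  f_tip <- o$r[nrow(o)]
  # implant region polygon (closed across tip, axis, top)
  implant <- tibble::tibble(
    r = c(o$r, 0, 0, o$r[1]),
    z = c(o$z, z_tip, H, o$z[1]))
  # callus: implant outline down, under the tip, back up the offset outline
  callus <- tibble::tibble(
    r = c(o$r, 0, 0, f_tip + m, rev(o$r) + m, o$r[1]),
    z = c(o$z, z_tip, z_tip - m, z_tip - m, rev(o$z), o$z[1]))
  regions <- list(implant = implant, callus = callus)
  z_cort <- H - tc
  if (tc > 0) {
    oc <- o[o$z >= z_cort - 1e-12, ]
    if (abs(oc$z[nrow(oc)] - z_cort) > 1e-12) {
      oc <- rbind(oc, tibble::tibble(z = z_cort,
                                     r = profile_radius(prof, z_cort)))
    }
    regions$cortical <- tibble::tibble(
      r = c(oc$r + m, W, W, oc$r[1] + m),
      z = c(oc$z, z_cort, H, oc$z[1]))
  }
  # cancellous: everything else, one simple polygon
  ob <- o[o$z <= z_cort + 1e-12, ]
  if (nrow(ob) == 0 || abs(ob$z[1] - z_cort) > 1e-12) {
    ob <- rbind(tibble::tibble(z = z_cort,
                               r = profile_radius(prof, z_cort)), ob)
  }
  regions$cancellous <- tibble::tibble(
    r = c(W, ob$r + m, f_tip + m, 0, 0, W, W),
    z = c(z_cort, ob$z, z_tip - m, z_tip - m, 0, 0, z_cort))

  boundaries <- list(
    axis = tibble::tibble(r = c(0, 0), z = c(0, H)),
    load_surface = tibble::tibble(r = c(0, o$r[1]), z = c(H, H)),
    fixed_base = tibble::tibble(r = c(0, W), z = c(0, 0)),
    cells_origin = tibble::tibble(
      r = c(o$r + m, f_tip + m, 0),
      z = c(o$z, z_tip - m, z_tip - m)),
    implant_callus_interface = tibble::tibble(
      r = c(o$r, 0), z = c(o$z, z_tip)))

  structure(list(regions = regions, boundaries = boundaries,
                 profile = prof, z_tip = z_tip,
                 extent = c(width = W, height = H),
                 callus_margin = m, cortical_thickness = tc),
            class = "oh_layout")
}

within_shift <- function(seg, dz) {
  seg$z_hi <- seg$z_hi + dz
  seg$z_lo <- seg$z_lo + dz
  seg
}

#' Plain rectangular layout (no implant)
#'
#' A single-region rectangle used by verification fixtures (consolidation
#' columns, diffusion strips, pressurized cylinders) and by the structured
#' path of [generate_mesh()].
#'
#' @param width,height rectangle extents (mm).
#' @param r0 radial offset of the left edge (mm); the rectangle spans
#'   `[r0, r0 + width]`.
#' @param region region tag for all elements.
#' @return An `oh_layout` without an implant.
#' @export
rectangle_layout <- function(width, height, r0 = 0, region = "domain") {
  poly <- tibble::tibble(r = r0 + c(0, width, width, 0),
                         z = c(0, 0, height, height))
  regions <- stats::setNames(list(poly), region)
  structure(list(regions = regions,
                 boundaries = list(
                   fixed_base = tibble::tibble(r = r0 + c(0, width),
                                               z = c(0, 0))),
                 profile = NULL, z_tip = NA_real_,
                 extent = c(width = width, height = height), r0 = r0,
                 callus_margin = NA_real_, cortical_thickness = NA_real_),
            class = "oh_layout")
}

#' Areas of the layout regions
#'
#' @param layout an `oh_layout`.
#' @return Tibble with `region` and `area` (shoelace, in-plane mm^2).
#' @export
layout_areas <- function(layout) {
  tibble::tibble(
    region = names(layout$regions),
    area = vapply(layout$regions, polygon_area, numeric(1)))
}
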