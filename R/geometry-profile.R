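#' Healing-chamber (thread) parameters
#'
#' Describes one repeating thread unit of an implant in the axisymmetric
#' half-plane. The chamber is the notch between adjacent threads: a crest at
#' the outer radius, an upper flank descending into the chamber, a root at
#' depth `depth_d`, and a lower flank returning to the outer radius. Flank
#' angles are measured between the flank orientation and the direction of
#' the applied (axial) force, so 90 degrees is a flat (horizontal) flank and
#' smaller angles are steeper flanks. The axial extent of a flank of depth
#' `d` at angle `phi` is `d / tan(phi)`.
#'
#' For the beak-shaped styles `depth_d` is the depth of the deepened half of
#' the chamber and `beak_ratio * depth_d` the depth of the shallow half:
#' `eagle_beak` deepens the lower half, `inverse_eagle_beak` the upper half.
#'
#' @param depth_d chamber depth (mm), >= 0.
#' @param upper_flank_angle_phi,lower_flank_angle flank angles (degrees,
#'   0 < angle <= 90).
#' @param root_length_r,crest_length_c axial root and crest lengths (mm).
#' @param pitch axial length of one thread unit (mm).
#' @param n_threads number of thread units.
#' @param profile_style one of `"v_thread"`, `"trapezoid"`, `"eagle_beak"`,
#'   `"inverse_eagle_beak"`.
#' @param outer_radius implant outer (crest) radius (mm).
#' @param collar_length,apex_length straight lengths above and below the
#'   threaded section (mm).
#' @param beak_ratio shallow-half depth as a fraction of `depth_d` for the
#'   beak styles.
#' @return A list of class `oh_chamber_params`.
#' @export
chamber_params <- function(depth_d, upper_flank_angle_phi, lower_flank_angle,
                           root_length_r = 0, crest_length_c = 0,
                           pitch = 0.8, n_threads = 8,
                           profile_style = c("trapezoid", "v_thread",
                                             "eagle_beak",
                                             "inverse_eagle_beak"),
                           outer_radius = 2, collar_length = 1,
                           apex_length = 0.6, beak_ratio = 0.6) {
  profile_style <- match.arg(profile_style)
  stopifnot(depth_d >= 0, pitch > 0, n_threads >= 1,
            root_length_r >= 0, crest_length_c >= 0,
            upper_flank_angle_phi > 0, upper_flank_angle_phi <= 90,
            lower_flank_angle > 0, lower_flank_angle <= 90,
            outer_radius > depth_d, beak_ratio > 0, beak_ratio <= 1)
  if (profile_style == "v_thread" &&
      (root_length_r > 0)) {
    rlang::abort("v_thread style has no root segment; set root_length_r = 0")
  }
  p <- list(depth_d = depth_d,
            upper_flank_angle_phi = upper_flank_angle_phi,
            lower_flank_angle = lower_flank_angle,
            root_length_r = root_length_r,
            crest_length_c = crest_length_c,
            pitch = pitch, n_threads = as.integer(n_threads),
            profile_style = profile_style,
            outer_radius = outer_radius,
            collar_length = collar_length, apex_length = apex_length,
            beak_ratio = beak_ratio)
  class(p) <- "oh_chamber_params"
  # closure check happens here so invalid parameter sets fail early
  chamber_segments(p)
  p
}

# Axial/radial increments of one thread unit, top to bottom.
# Returns a tibble with columns dz (axial extent, > 0 rows only kept),
# r_end (radius at the end of the segment) and type.
chamber_segments <- function(p) {
  d <- p$depth_d
  tu <- tanpi(p$upper_flank_angle_phi / 180)
  tl <- tanpi(p$lower_flank_angle / 180)
  ro <- p$outer_radius
  if (d == 0) {
    # degenerate chamber: a straight cylindrical thread unit
    return(tibble::tibble(dz = p$pitch, r_end = ro, type = "crest"))
  }
  seg <- switch(
    p$profile_style,
    v_thread = ,
    trapezoid = {
      dz_up <- d / tu
      dz_lo <- d / tl
      used <- p$crest_length_c + dz_up + p$root_length_r + dz_lo
      if (used > p$pitch + 1e-12) {
        rlang::abort(paste0(
          "chamber does not close within one pitch: crest + flank axial ",
          "extents + root = ", signif(used, 6), " mm > pitch = ", p$pitch,
          " mm"))
      }
      tibble::tibble(
        dz = c(p$crest_length_c + (p$pitch - used), dz_up,
               p$root_length_r, dz_lo),
        r_end = c(ro, ro - d, ro - d, ro),
        type = c("crest", "upper_flank", "root", "lower_flank"))
    },
    eagle_beak = {
      d_sh <- p$beak_ratio * d       # shallow (upper) half depth
      dz_up <- d_sh / tu
      dz_lo <- d / tl
      step <- d - d_sh               # 45-degree step between root levels
      used <- p$crest_length_c + dz_up + p$root_length_r + step + dz_lo
      if (used > p$pitch + 1e-12) {
        rlang::abort(paste0(
          "beak chamber does not close within one pitch (", signif(used, 6),
          " mm > ", p$pitch, " mm)"))
      }
      tibble::tibble(
        dz = c(p$crest_length_c + (p$pitch - used), dz_up,
               p$root_length_r / 2, step, p$root_length_r / 2, dz_lo),
        r_end = c(ro, ro - d_sh, ro - d_sh, ro - d, ro - d, ro),
        type = c("crest", "upper_flank", "root", "root", "root",
                 "lower_flank"))
    },
    inverse_eagle_beak = {
      d_sh <- p$beak_ratio * d       # shallow (lower) half depth
      dz_up <- d / tu
      dz_lo <- d_sh / tl
      step <- d - d_sh
      used <- p$crest_length_c + dz_up + p$root_length_r + step + dz_lo
      if (used > p$pitch + 1e-12) {
        rlang::abort(paste0(
          "beak chamber does not close within one pitch (", signif(used, 6),
          " mm > ", p$pitch, " mm)"))
      }
      tibble::tibble(
        dz = c(p$crest_length_c + (p$pitch - used), dz_up,
               p$root_length_r / 2, step, p$root_length_r / 2, dz_lo),
        r_end = c(ro, ro - d, ro - d, ro - d_sh, ro - d_sh, ro),
        type = c("crest", "upper_flank", "root", "root", "root",
                 "lower_flank"))
    })
  seg[seg$dz > 1e-12 | c(abs(diff(c(ro, seg$r_end))) > 1e-12), ]
}

#' Build the axisymmetric implant profile
#'
#' Generates the outer boundary of the implant in the half-plane (radial
#' coordinate r >= 0, axial coordinate z, axis of symmetry at r = 0). The
#' outline is single-valued in z (no overhangs), which the mesher exploits;
#' the full boundary polyline closes across the flat tip, the symmetry axis
#' and the top face. z runs from 0 at the implant tip to `length_total` at
#' the top.
#'
#' @param params an [chamber_params()] object.
#' @return A list of class `oh_profile` with elements `outline` (tibble
#'   `z`, `r` of the single-valued outer boundary, z decreasing from top to
#'   tip), `segments` (tibble `z_hi`, `z_lo`, `r_hi`, `r_lo`, `type`),
#'   `polyline` (closed boundary tibble `r`, `z`), `core_radius`,
#'   `outer_radius`, `length_total` and the originating `params`.
#' @examples
#' pr <- build_chamber_profile(chamber_params(0.3, 60, 60, 0.1, 0.1))
#' head(pr$outline)
#' @export
build_chamber_profile <- function(params) {
  stopifnot(inherits(params, "oh_chamber_params"))
  seg <- chamber_segments(params)
  L <- params$collar_length + params$n_threads * params$pitch +
    params$apex_length
  ro <- params$outer_radius
  z <- L
  r <- ro
  zs <- z
  rs <- r
  types <- character(0)
  add_seg <- function(dz, r_end, type) {
    z2 <- z - dz
    if (dz > 1e-12 || abs(r_end - r) > 1e-12) {
      zs <<- c(zs, z2)
      rs <<- c(rs, r_end)
      types <<- c(types, type)
      z <<- z2
      r <<- r_end
    }
  }
  if (params$collar_length > 0) add_seg(params$collar_length, ro, "collar")
  for (k in seq_len(params$n_threads)) {
    for (i in seq_len(nrow(seg))) add_seg(seg$dz[i], seg$r_end[i], seg$type[i])
  }
  if (params$apex_length > 0) add_seg(params$apex_length, ro, "apex")
  # merge collinear vertices so degenerate chambers give clean outlines
  keep <- rep(TRUE, length(zs))
  for (i in seq_len(length(zs) - 2) + 1) {
    dr1 <- rs[i] - rs[i - 1]; dz1 <- zs[i] - zs[i - 1]
    dr2 <- rs[i + 1] - rs[i]; dz2 <- zs[i + 1] - zs[i]
    if (abs(dr1 * dz2 - dr2 * dz1) < 1e-12 &&
        types[i - 1] == types[i]) keep[i] <- FALSE
  }
  seg_keep <- keep[-1]
  outline <- tibble::tibble(z = zs[keep], r = rs[keep])
  segments <- tibble::tibble(
    z_hi = zs[-length(zs)], z_lo = zs[-1],
    r_hi = rs[-length(rs)], r_lo = rs[-1], type = types)
  segments <- segments[segments$z_hi - segments$z_lo > 1e-12, ]
  polyline <- tibble::tibble(
    r = c(outline$r, 0, 0, outline$r[1]),
    z = c(outline$z, 0, L, outline$z[1]))
  if (any(polyline$r < -1e-12)) {
    rlang::abort("profile has negative radial coordinates")
  }
  structure(list(outline = outline, segments = segments,
                 polyline = polyline,
                 core_radius = min(outline$r),
                 outer_radius = ro, length_total = L,
                 z_threads = c(params$apex_length,
                               params$apex_length +
                                 params$n_threads * params$pitch),
                 params = params),
            class = "oh_profile")
}

# Single-valued implant outer radius at axial position z (vector), with the
# tip radius continued below the tip so the callus offset is well defined.
profile_radius <- function(profile, z) {
  o <- profile$outline[rev(seq_len(nrow(profile$outline))), ]
  zz <- pmin(pmax(z, min(o$z)), max(o$z))
  stats::approx(o$z, o$r, xout = zz, ties = "ordered")$y
}

#' Polygon area by the shoelace formula
#'
#' @param poly data frame with columns `r` and `z` (closed or open ring).
#' @return Absolute enclosed area.
#' @export
polygon_area <- function(poly) {
  r <- poly$r
  z <- poly$z
  n <- length(r)
  if (abs(r[1] - r[n]) < 1e-15 && abs(z[1] - z[n]) < 1e-15) {
    r <- r[-n]; z <- z[-n]; n <- n - 1
  }
  j <- c(n, seq_len(n - 1))
  abs(sum(r[j] * z - r * z[j])) / 2
}

# Vectorized ray-casting point-in-polygon test.
points_in_polygon <- function(px, pz, poly) {
  r <- poly$r
  z <- poly$z
  n <- length(r)
  if (abs(r[1] - r[n]) < 1e-15 && abs(z[1] - z[n]) < 1e-15) {
    r <- r[-n]; z <- z[-n]; n <- n - 1
  }
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    cross <- ((z[i] > pz) != (z[j] > pz)) &
      (px < (r[j] - r[i]) * (pz - z[i]) / (z[j] - z[i]) + r[i])
    inside <- xor(inside, cross & !is.na(cross))
    j <- i
  }
  inside
}
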