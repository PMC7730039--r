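#' Catalog of the eight healing-chamber designs
#'
#' Parametric stand-ins for the eight implant designs (labelled A-H)
#' compared by the healing-pattern study. Only the ordering relations
#' between the designs are published, so absolute dimensions here are
#' documented approximations (4 mm outer diameter, 0.8 mm pitch, 8 mm
#' embedded length by default). The orderings honoured are: within the
#' flank-angle group, phi_A > phi_E > phi_F (E has equal upper and lower
#' flank slopes, F a steeper upper flank); within the root/crest group,
#' r_B < r_G and c_B < c_G at equal depth; within the depth group,
#' d_C < d_H, with D the eagle-beak modification of C (deepened lower
#' chamber half) and H its inverse (deepened upper half).
#'
#' @param n_threads number of thread units per implant.
#' @param pitch thread pitch (mm).
#' @param outer_radius implant outer radius (mm).
#' @param scale multiplies all chamber depths and root/crest lengths
#'   (useful for scaled-down analog studies); flank angles are preserved.
#' @return Named list (labels `A`-`H`); each entry has `params`
#'   (a [chamber_params()]) and `domain` (arguments for [build_domain()]).
#' @examples
#' cat8 <- catalog_implants()
#' cat8$A$params$upper_flank_angle_phi
#' @export
catalog_implants <- function(n_threads = 8, pitch = 0.8, outer_radius = 2,
                             scale = 1) {
  base <- function(depth, phi_up, phi_lo, r_len, c_len, style = "trapezoid") {
    chamber_params(
      depth_d = depth * scale,
      upper_flank_angle_phi = phi_up, lower_flank_angle = phi_lo,
      root_length_r = r_len * scale, crest_length_c = c_len * scale,
      pitch = pitch, n_threads = n_threads, profile_style = style,
      outer_radius = outer_radius,
      collar_length = 1 * pitch / 0.8, apex_length = 0.6 * pitch / 0.8)
  }
  specs <- list(
    A = base(0.30, 70, 60, 0.10, 0.10),
    B = base(0.35, 55, 55, 0.05, 0.05),
    C = base(0.15, 60, 60, 0.10, 0.10),
    D = base(0.25, 60, 60, 0.10, 0.10, style = "eagle_beak"),
    E = base(0.30, 60, 60, 0.10, 0.10),
    F = base(0.30, 45, 60, 0.10, 0.10),
    G = base(0.35, 60, 60, 0.15, 0.15),
    H = base(0.25, 60, 60, 0.10, 0.10, style = "inverse_eagle_beak"))
  L <- specs$A$collar_length + n_threads * pitch + specs$A$apex_length
  dom <- list(cortical_thickness = 1.5, callus_margin = 0.5,
              domain_extent = c(outer_radius + 3, L + 4))
  lapply(specs, function(p) list(params = p, domain = dom))
}
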