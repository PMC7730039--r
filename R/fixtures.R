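#' Deterministic verification fixtures
#'
#' Small meshes with analytic metadata attached, used by the test-suite and
#' the verification command. All are generated in code; none exceeds 2,000
#' elements.
#'
#' * `strip_1d` — a tall thin column for one-dimensional diffusion; carries
#'   the half-space complementary-error-function solution for invasion from
#'   the top boundary and the first-mode slab estimate of the calibrated
#'   diffusivity.
#' * `terzaghi_column` — an oedometer (laterally confined) consolidation
#'   column, drained at the top, step-loaded by a vertical traction;
#'   carries the classical Terzaghi series solution for excess pore
#'   pressure.
#' * `lame_cylinder` — a thick-walled cylinder under internal pressure in
#'   plane strain; carries the closed-form radial displacement.
#' * `single_chamber` — a one-thread implant with its callus, cortical and
#'   cancellous surroundings; the reference geometry for toy healing runs
#'   and diffusivity calibration.
#'
#' @param kind fixture name.
#' @param element_size target element size (mm); fixture-specific default.
#' @return A list with `mesh`, `materials` and (per kind) `analytic`
#'   functions, `load` descriptions and geometric metadata.
#' @export
make_fixture <- function(kind = c("strip_1d", "single_chamber",
                                  "lame_cylinder", "terzaghi_column"),
                         element_size = NULL) {
  kind <- match.arg(kind)
  tab <- material_table()
  gran <- tab[tab$phenotype == "granulation", ]
  switch(kind,
    strip_1d = {
      h <- element_size %||% 0.05
      height <- 5
      mesh <- generate_mesh(rectangle_layout(2 * h, height), h)
      analytic <- list(
        # semi-infinite solution for unit boundary concentration at z = H
        halfspace = function(z, t, D) {
          pracma_erfc((height - z) / (2 * sqrt(D * t)))
        },
        # first-mode slab estimate of D saturating at `days`
        calibrated_D = function(days = 35, threshold = 0.99) {
          height^2 * 4 * log((4 / pi) / (1 - threshold)) /
            (pi^2 * days)
        })
      list(mesh = mesh, height = height, analytic = analytic)
    },
    terzaghi_column = {
      h <- element_size %||% 0.1
      height <- 5
      mesh <- generate_mesh(rectangle_layout(2 * h, height), h)
      materials <- tibble::tibble(
        element = mesh$elements$element, region = "domain",
        phenotype = "granulation",
        young_modulus = gran$young_modulus,
        poisson_ratio = gran$poisson_ratio,
        permeability = gran$permeability, is_solid_only = FALSE)
      E <- gran$young_modulus
      nuv <- gran$poisson_ratio
      E_oed <- E * (1 - nuv) / ((1 + nuv) * (1 - 2 * nuv))
      cv <- perm_to_solver(gran$permeability) * E_oed # mm^2/s
      sigma0 <- 0.01 # MPa
      analytic <- list(
        cv = cv, sigma0 = sigma0, height = height,
        # excess pore pressure p(z, Tv)/sigma0; drainage at z = height
        pressure = function(z, Tv, n_terms = 60) {
          Z <- (height - z) / height
          out <- 0
          for (m in 0:(n_terms - 1)) {
            M <- pi * (2 * m + 1) / 2
            out <- out + (2 / M) * sin(M * Z) * exp(-M^2 * Tv)
          }
          sigma0 * out
        },
        time_of = function(Tv) Tv * height^2 / cv)
      list(mesh = mesh, materials = materials, analytic = analytic)
    },
    lame_cylinder = {
      h <- element_size %||% 0.25
      a <- 5
      b <- 10
      height <- 1
      mesh <- generate_mesh(rectangle_layout(b - a, height, r0 = a), h)
      E <- 1000
      nuv <- 0.3
      materials <- tibble::tibble(
        element = mesh$elements$element, region = "domain",
        phenotype = "elastic",
        young_modulus = E, poisson_ratio = nuv,
        permeability = gran$permeability, is_solid_only = FALSE)
      P <- 1 # MPa internal pressure
      analytic <- list(
        a = a, b = b, P = P, E = E, nu = nuv,
        # plane-strain radial displacement of a pressurized cylinder
        u_r = function(r) {
          P * a^2 / (E * (b^2 - a^2)) *
            ((1 + nuv) * (1 - 2 * nuv) * r + (1 + nuv) * b^2 / r)
        })
      list(mesh = mesh, materials = materials, analytic = analytic)
    },
    single_chamber = {
      h <- element_size %||% 0.1
      params <- chamber_params(
        depth_d = 0.3, upper_flank_angle_phi = 60, lower_flank_angle = 60,
        root_length_r = 0.1, crest_length_c = 0.1, pitch = 0.8,
        n_threads = 1, profile_style = "trapezoid", outer_radius = 1.2,
        collar_length = 0.8, apex_length = 1.2)
      profile <- build_chamber_profile(params)
      layout <- build_domain(profile, cortical_thickness = 0.8,
                             callus_margin = 0.5,
                             domain_extent = c(2.5, 4.4))
      mesh <- generate_mesh(layout, h)
      list(mesh = mesh, materials = region_materials(mesh),
           params = params, layout = layout, load = load_case())
    })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# erfc without extra dependencies
pracma_erfc <- function(x) 2 * stats::pnorm(-sqrt(2) * x)

#' Consistent nodal forces for a boundary traction
#'
#' Integrates a constant traction over the boundary segments joining the
#' given nodes (which must lie on a straight axis-aligned boundary line),
#' with the same axisymmetric weighting as the assembler.
#'
#' @param mesh an `oh_mesh`.
#' @param nodes node ids along one boundary line.
#' @param traction `c(t_r, t_z)` in MPa.
#' @param axisym weighting flag.
#' @return Numeric force vector of length `2 * n_nodes(mesh)`.
#' @export
boundary_forces <- function(mesh, nodes, traction, axisym = TRUE) {
  r <- mesh$nodes$r[nodes]
  z <- mesh$nodes$z[nodes]
  ord <- order(if (stats::sd(r) > stats::sd(z)) r else z)
  nodes <- nodes[ord]
  r <- r[ord]
  z <- z[ord]
  f <- numeric(2 * nrow(mesh$nodes))
  for (i in seq_len(length(nodes) - 1)) {
    L <- sqrt((r[i + 1] - r[i])^2 + (z[i + 1] - z[i])^2)
    if (axisym) {
      w1 <- L * (2 * r[i] + r[i + 1]) / 6
      w2 <- L * (r[i] + 2 * r[i + 1]) / 6
    } else {
      w1 <- w2 <- L / 2
    }
    d1 <- 2 * (nodes[i] - 1)
    d2 <- 2 * (nodes[i + 1] - 1)
    f[d1 + 1] <- f[d1 + 1] + traction[1] * w1
    f[d1 + 2] <- f[d1 + 2] + traction[2] * w1
    f[d2 + 1] <- f[d2 + 1] + traction[1] * w2
    f[d2 + 2] <- f[d2 + 2] + traction[2] * w2
  }
  f
}
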