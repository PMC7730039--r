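#' Per-element materials from region tags
#'
#' Maps every mesh element to the material properties of its region
#' (implant, cortical, cancellous) with the callus initialized to
#' granulation tissue — the state of the wound space before cell invasion.
#'
#' @param mesh an `oh_mesh`.
#' @param table a [material_table()].
#' @return Tibble with one row per element: `element`, `region`,
#'   `phenotype`, `young_modulus` (MPa), `poisson_ratio`, `permeability`
#'   (m^4/(N s)), `is_solid_only`.
#' @export
region_materials <- function(mesh, table = material_table()) {
  map <- c(implant = "implant", cortical = "cortical",
           cancellous = "cancellous", callus = "granulation",
           domain = "granulation")
  phen <- map[mesh$elements$region]
  if (anyNA(phen)) {
    rlang::abort(paste0("no default material for region(s): ",
                        paste(unique(mesh$elements$region[is.na(phen)]),
                              collapse = ", ")))
  }
  idx <- match(phen, table$phenotype)
  tibble::tibble(
    element = mesh$elements$element,
    region = mesh$elements$region,
    phenotype = unname(phen),
    young_modulus = table$young_modulus[idx],
    poisson_ratio = table$poisson_ratio[idx],
    permeability = table$permeability[idx],
    is_solid_only = table$is_solid_only[idx])
}

#' Assemble the coupled displacement/pore-pressure system
#'
#' Builds the monolithic symmetric system of one backward-Euler step of
#' axisymmetric Biot consolidation with Biot coefficient 1 and
#' incompressible constituents (zero storativity):
#' \deqn{\begin{bmatrix} K & -Q \\ -Q^T & -\Delta t\, H \end{bmatrix}
#'   \begin{bmatrix} u \\ p \end{bmatrix} =
#'   \begin{bmatrix} f \\ -Q^T u_{prev} \end{bmatrix}}
#' where `K` is the drained elastic stiffness, `Q` the volumetric
#' displacement-pressure coupling and `H` the permeability (Darcy) matrix.
#' Solid-only elements (the implant) contribute elasticity only; pressure
#' unknowns exist only on nodes of poroelastic elements.
#'
#' @param mesh an `oh_mesh`.
#' @param materials per-element tibble as from [region_materials()].
#' @param dt time-step length (s), > 0.
#' @param axisym logical; `FALSE` switches to planar (unit-thickness)
#'   weighting, used by verification fixtures.
#' @return List with sparse `A` (the block matrix), `K`, `Q`, `H`
#'   (Matrix objects), `pnodes` (nodes carrying a pressure unknown),
#'   `n_unodes`, and the per-element `area`.
#' @export
assemble_poroelastic_system <- function(mesh, materials, dt = 0.1,
                                        axisym = TRUE) {
  stopifnot(dt > 0)
  n <- nrow(mesh$nodes)
  mm <- materials[order(materials$element), ]
  if (nrow(mm) != nrow(mesh$elements)) {
    rlang::abort("materials must have one row per mesh element")
  }
  poro <- !mm$is_solid_only
  if (any(poro & (is.na(mm$permeability) | mm$permeability <= 0))) {
    rlang::abort("poroelastic elements require positive permeability")
  }
  k_mm <- ifelse(poro, perm_to_solver(mm$permeability), 0)
  tr <- .assemble_axisym(mesh_coords(mesh), mesh_conn(mesh),
                         mm$young_modulus, mm$poisson_ratio, k_mm,
                         poro, axisym)
  K <- Matrix::sparseMatrix(i = tr$Ki, j = tr$Kj, x = tr$Kx,
                            dims = c(2 * n, 2 * n))
  Qfull <- Matrix::sparseMatrix(i = tr$Qi, j = tr$Qj, x = tr$Qx,
                                dims = c(2 * n, n))
  Hfull <- Matrix::sparseMatrix(i = tr$Hi, j = tr$Hj, x = tr$Hx,
                                dims = c(n, n))
  pnodes <- sort(unique(as.vector(mesh_conn(mesh)[poro, , drop = FALSE])))
  Q <- Qfull[, pnodes, drop = FALSE]
  H <- Hfull[pnodes, pnodes, drop = FALSE]
  A <- rbind(cbind(K, -Q), cbind(-Matrix::t(Q), -dt * H))
  list(A = A, K = K, Q = Q, H = H, pnodes = pnodes, n_unodes = n,
       area = tr$area)
}

# Solve a linear system with Dirichlet constraints. The `factor` cache
# holds the LU factorization of the free block and the free-fixed coupling
# so repeated solves with new right-hand sides avoid submatrix extraction.
solve_constrained <- function(A, b, fixed, xfix, factor = NULL) {
  n <- length(b)
  if (is.null(factor)) {
    free <- setdiff(seq_len(n), fixed)
    Aff <- A[free, free, drop = FALSE]
    lu <- tryCatch(Matrix::lu(Aff), error = function(e) {
      rlang::abort(paste0("singular system (missing constraints?): ",
                          conditionMessage(e)))
    })
    factor <- list(lu = lu, Afx = A[free, fixed, drop = FALSE],
                   free = free)
  }
  free <- factor$free
  rhs <- b[free] - as.vector(factor$Afx %*% xfix)
  x <- numeric(n)
  x[fixed] <- xfix
  x[free] <- as.vector(Matrix::solve(factor$lu, rhs))
  list(x = x, factor = factor, free = free)
}

#' Time-stepped poroelastic solve with explicit boundary conditions
#'
#' Low-level driver used by [solve_loadstep()] and the verification
#' fixtures. Prescribed displacements and external forces are scaled by a
#' per-step schedule (a linear ramp by default); pore pressure is fixed
#' (usually to zero, drained) on the given node set; all other hydraulic
#' boundaries are natural no-flux.
#'
#' @param mesh an `oh_mesh`.
#' @param materials per-element material tibble.
#' @param dirichlet_u tibble with `node`, `dof` ("r" or "z") and `value`
#'   (mm) of prescribed displacement at full load.
#' @param forces optional numeric vector of nodal forces (length 2 * nodes,
#'   interleaved ur, uz) at full load.
#' @param drained_nodes nodes with prescribed zero pore pressure.
#' @param dt either a single step length or a vector of step lengths (s).
#' @param n_steps number of steps when `dt` is scalar.
#' @param schedule numeric vector of load scale factors per step; defaults
#'   to a linear ramp ending at 1.
#' @param axisym weighting flag passed to the assembler.
#' @param u0 optional initial displacement (2 * nodes).
#' @param keep_history keep per-step displacement/pressure matrices.
#' @return A list of class `oh_solution`: `u` (2n, mm), `pressure` tibble
#'   (`node`, `p` in MPa, `NA` on solid-only nodes), `p_full` (n), `times`,
#'   and optionally `u_hist`, `p_hist` (columns = steps).
#' @export
poro_solve <- function(mesh, materials, dirichlet_u,
                       forces = NULL, drained_nodes = integer(0),
                       dt = 0.1, n_steps = 10, schedule = NULL,
                       axisym = TRUE, u0 = NULL, keep_history = FALSE) {
  n <- nrow(mesh$nodes)
  dts <- if (length(dt) > 1) dt else rep(dt, n_steps)
  ns <- length(dts)
  if (is.null(schedule)) schedule <- seq_len(ns) / ns
  stopifnot(length(schedule) == ns)

  sys <- assemble_poroelastic_system(mesh, materials, dt = dts[1],
                                     axisym = axisym)
  np <- length(sys$pnodes)
  pmap <- match(seq_len(n), sys$pnodes)

  dof_u <- 2 * (dirichlet_u$node - 1) + ifelse(dirichlet_u$dof == "r", 1, 2)
  pfix <- 2 * n + pmap[intersect(drained_nodes, sys$pnodes)]
  fixed <- c(dof_u, pfix)
  if (anyDuplicated(dof_u)) {
    rlang::abort("duplicate prescribed displacement dofs")
  }
  f_ext <- if (is.null(forces)) numeric(2 * n) else forces
  stopifnot(length(f_ext) == 2 * n)

  u <- if (is.null(u0)) numeric(2 * n) else u0
  p <- numeric(np)
  u_hist <- if (keep_history) matrix(NA_real_, 2 * n, ns) else NULL
  p_hist <- if (keep_history) matrix(NA_real_, n, ns) else NULL
  factor <- NULL
  A <- sys$A
  dt_last <- dts[1]
  for (s in seq_len(ns)) {
    if (abs(dts[s] - dt_last) > 1e-15) {
      # only the H block scales with dt
      A <- rbind(cbind(sys$K, -sys$Q),
                 cbind(-Matrix::t(sys$Q), -dts[s] * sys$H))
      factor <- NULL
      dt_last <- dts[s]
    }
    b <- c(f_ext * schedule[s], -as.vector(Matrix::t(sys$Q) %*% u))
    xfix <- c(dirichlet_u$value * schedule[s], rep(0, length(pfix)))
    sol <- solve_constrained(A, b, fixed, xfix, factor)
    factor <- sol$factor
    u <- sol$x[seq_len(2 * n)]
    p <- sol$x[2 * n + seq_len(np)]
    if (keep_history) {
      u_hist[, s] <- u
      p_hist[, s] <- ifelse(is.na(pmap), NA_real_, p[pmap])
    }
  }
  structure(list(
    u = u,
    p_full = ifelse(is.na(pmap), NA_real_, p[pmap]),
    pressure = tibble::tibble(node = seq_len(n),
                              p = ifelse(is.na(pmap), NA_real_, p[pmap])),
    times = cumsum(dts), u_hist = u_hist, p_hist = p_hist,
    axisym = axisym), class = "oh_solution")
}

#' Solve one healing-day load step
#'
#' Applies the daily functional load — a uniform prescribed axial
#' displacement on the implant top surface, ramped over `ramp_duration` in
#' `n_time_steps` implicit steps — with the standard boundary conditions:
#' axial displacement fixed on the base, radial displacement fixed on the
#' symmetry axis and at the bottom-left corner, drained (zero pore
#' pressure) exterior boundary, no-flux on the axis and the implant
#' interface. Stimuli are evaluated at the step of peak load (end of ramp).
#'
#' @param mesh an `oh_mesh` with an implant.
#' @param materials per-element material tibble.
#' @param load a [load_case()].
#' @param interface an [interface_spec()]; mode "coulomb_penalty" (default)
#'   duplicates the interface nodes and allows Coulomb frictional sliding,
#'   "tied" shares the mesh across the implant-callus interface.
#' @return An `oh_solution` (see [poro_solve()]).
#' @export
solve_loadstep <- function(mesh, materials, load = load_case(),
                           interface = interface_spec()) {
  b <- mesh$boundaries
  if (is.null(b$load_surface)) {
    rlang::abort("mesh has no load_surface boundary set (no implant?)")
  }
  uz_mm <- -load$top_displacement * 1e-3
  diri <- dplyr::bind_rows(
    tibble::tibble(node = b$load_surface, dof = "z", value = uz_mm),
    tibble::tibble(node = b$axis, dof = "r", value = 0),
    tibble::tibble(node = b$fixed_base, dof = "z", value = 0))
  diri <- diri[!duplicated(paste(diri$node, diri$dof)), ]
  dt <- load$ramp_duration / load$n_time_steps
  if (interface$mode == "coulomb_penalty") {
    return(solve_contact(mesh, materials, diri, b$drained, dt,
                         load$n_time_steps, interface))
  }
  poro_solve(mesh, materials, diri, drained_nodes = b$drained,
             dt = dt, n_steps = load$n_time_steps)
}

#' Daily load case
#'
#' @param top_displacement magnitude of the prescribed axial displacement
#'   on the implant top surface, in micrometres (applied along -z).
#' @param ramp_duration loading ramp duration (s).
#' @param n_time_steps number of implicit time steps over the ramp.
#' @return A list of class `oh_load_case`.
#' @export
load_case <- function(top_displacement = 8, ramp_duration = 1,
                      n_time_steps = 10) {
  stopifnot(top_displacement >= 0, ramp_duration > 0, n_time_steps >= 1)
  structure(list(top_displacement = top_displacement,
                 ramp_duration = ramp_duration,
                 n_time_steps = as.integer(n_time_steps)),
            class = "oh_load_case")
}

#' Implant-callus interface treatment
#'
#' @param mode "coulomb_penalty" (duplicated interface nodes joined by
#'   normal penalty springs with Coulomb frictional sliding; the default,
#'   matching the frictional implant-bone interface the model assumes) or
#'   "tied" (shared mesh, no sliding; faster, and the right limit for a
#'   fully osseointegrated interface).
#' @param friction_coefficient Coulomb friction coefficient (>= 0).
#' @param penalty_stiffness spring stiffness per unit interface area
#'   (N/mm^3).
#' @param max_iterations contact fixed-point iteration budget.
#' @return A list of class `oh_interface_spec`.
#' @export
interface_spec <- function(mode = c("coulomb_penalty", "tied"),
                           friction_coefficient = 0.3,
                           penalty_stiffness = 1e7,
                           max_iterations = 80) {
  mode <- match.arg(mode)
  stopifnot(friction_coefficient >= 0, penalty_stiffness > 0)
  structure(list(mode = mode,
                 friction_coefficient = friction_coefficient,
                 penalty_stiffness = penalty_stiffness,
                 max_iterations = as.integer(max_iterations)),
            class = "oh_interface_spec")
}

#' Element strains at centroids
#'
#' Axisymmetric strain components evaluated at each element centroid
#' (single-point evaluation) from the displacement field at peak load.
#'
#' @param solution an `oh_solution`.
#' @param mesh the mesh the solution was computed on.
#' @return Tibble `element`, `e_rr`, `e_zz`, `e_tt`, `g_rz` (engineering
#'   shear).
#' @export
element_strains <- function(solution, mesh) {
  u <- solution$u
  if (length(u) != 2 * nrow(mesh$nodes)) {
    rlang::abort("solution and mesh sizes do not match")
  }
  s <- .element_strain_centroid(mesh_coords(mesh), mesh_conn(mesh), u,
                                isTRUE(solution$axisym))
  tibble::tibble(element = mesh$elements$element,
                 e_rr = s[, 1], e_zz = s[, 2], e_tt = s[, 3], g_rz = s[, 4])
}

#' Octahedral shear strain
#'
#' \eqn{\gamma = (2/3)\sqrt{(\epsilon_1-\epsilon_2)^2 +
#' (\epsilon_2-\epsilon_3)^2 + (\epsilon_3-\epsilon_1)^2}} from the
#' principal strains of the full 3D tensor: the in-plane eigenvalues of
#' [[e_rr, e_rz], [e_rz, e_zz]] (tensor shear e_rz = g_rz / 2) together
#' with the hoop strain e_tt as the third principal direction.
#'
#' @param strains tibble from [element_strains()] (columns `e_rr`, `e_zz`,
#'   `e_tt`, `g_rz`), or a numeric matrix with those four columns.
#' @return Numeric vector of octahedral shear strains (dimensionless, >= 0).
#' @export
octahedral_shear_strain <- function(strains) {
  if (is.data.frame(strains)) {
    err <- strains$e_rr; ezz <- strains$e_zz
    ett <- strains$e_tt; grz <- strains$g_rz
  } else {
    err <- strains[, 1]; ezz <- strains[, 2]
    ett <- strains[, 3]; grz <- strains[, 4]
  }
  erz <- grz / 2
  mean2 <- (err + ezz) / 2
  rad <- sqrt(((err - ezz) / 2)^2 + erz^2)
  e1 <- mean2 + rad
  e2 <- mean2 - rad
  e3 <- ett
  (2 / 3) * sqrt((e1 - e2)^2 + (e2 - e3)^2 + (e3 - e1)^2)
}

#' Darcy (interstitial) fluid velocity at element centroids
#'
#' `v = -k grad(p)` with the tabulated hydraulic mobility, evaluated at the
#' step of peak load and reported in micrometres per second.
#'
#' @param solution an `oh_solution` with a pore-pressure field.
#' @param materials per-element material tibble.
#' @param mesh the mesh.
#' @return Tibble `element`, `nu_r`, `nu_z`, `nu` (um/s) for poroelastic
#'   elements; requesting implant (solid-only) elements is an error.
#' @param elements optional element ids to evaluate (default: all
#'   poroelastic elements).
#' @export
darcy_velocity <- function(solution, materials, mesh, elements = NULL) {
  mm <- materials[order(materials$element), ]
  if (is.null(elements)) {
    elements <- mm$element[!mm$is_solid_only]
  } else if (any(mm$is_solid_only[match(elements, mm$element)])) {
    rlang::abort("fluid velocity requested on solid-only (implant) elements")
  }
  p <- solution$p_full
  p[is.na(p)] <- 0 # values on solid-only nodes are never referenced
  idx <- match(elements, mm$element)
  conn <- mesh_conn(mesh)[idx, , drop = FALSE]
  g <- .element_grad_centroid(mesh_coords(mesh), conn, p)
  k_mm <- perm_to_solver(mm$permeability[idx])
  nu_r <- speed_to_um_s(-k_mm * g[, 1])
  nu_z <- speed_to_um_s(-k_mm * g[, 2])
  tibble::tibble(element = elements, nu_r = nu_r, nu_z = nu_z,
                 nu = sqrt(nu_r^2 + nu_z^2))
}

#' Per-element mechanical stimuli for one solve
#'
#' Combines [element_strains()], [octahedral_shear_strain()] and
#' [darcy_velocity()] into the per-element stimulus table used by the
#' healing loop.
#'
#' @inheritParams darcy_velocity
#' @return Tibble `element`, `region`, `gamma_oct`, `nu_r`, `nu_z`, `nu`
#'   (um/s); `nu` is `NA` on solid-only elements.
#' @export
compute_stimuli <- function(solution, materials, mesh) {
  st <- element_strains(solution, mesh)
  gam <- octahedral_shear_strain(st)
  dv <- darcy_velocity(solution, materials, mesh)
  out <- tibble::tibble(element = mesh$elements$element,
                        region = mesh$elements$region,
                        gamma_oct = gam)
  dplyr::left_join(out, dv, by = "element")
}
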