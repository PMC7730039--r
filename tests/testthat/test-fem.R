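# Uniform-strain material tibble for verification meshes.
uniform_materials <- function(mesh, E = 10, nu = 0.25, k = 1e-14) {
  tibble::tibble(element = mesh$elements$element, region = "domain",
                 phenotype = "test", young_modulus = E, poisson_ratio = nu,
                 permeability = k, is_solid_only = FALSE)
}

test_that("constant-strain patch states are reproduced exactly", {
  msh <- generate_mesh(rectangle_layout(1, 1, r0 = 2), 0.5)
  mats <- uniform_materials(msh)
  nd <- msh$nodes
  # axial stretch
  alpha <- 1e-3
  diri <- dplyr::bind_rows(
    tibble::tibble(node = nd$node, dof = "z", value = alpha * nd$z),
    tibble::tibble(node = nd$node, dof = "r", value = 0))
  sol <- poro_solve(msh, mats, diri, drained_nodes = nd$node,
                    dt = 1, n_steps = 1, schedule = 1)
  st <- element_strains(sol, msh)
  expect_true(all(abs(st$e_zz - alpha) < 1e-14))
  expect_true(all(abs(st$e_rr) < 1e-14))
  expect_true(all(abs(st$g_rz) < 1e-14))
  # radial state u_r = c * r gives e_rr = e_tt = c on interior nodes too
  cc <- 2e-3
  diri2 <- dplyr::bind_rows(
    tibble::tibble(node = nd$node, dof = "r", value = cc * nd$r),
    tibble::tibble(node = nd$node, dof = "z", value = 0))
  bnd <- unique(c(msh$boundaries$fixed_base, msh$boundaries$top_surface,
                  msh$boundaries$inner_wall, msh$boundaries$outer_wall))
  sol2 <- poro_solve(msh, mats, diri2[diri2$node %in% bnd |
                                        diri2$dof == "z", ],
                     drained_nodes = nd$node, dt = 1, n_steps = 1,
                     schedule = 1)
  st2 <- element_strains(sol2, msh)
  expect_true(all(abs(st2$e_rr - cc) < 1e-12))
  expect_true(all(abs(st2$e_tt - cc) < 1e-12))
})

test_that("rigid axial translation produces zero strain and zero
           stimulus", {
  msh <- toy_mesh()
  u <- rep(c(0, -0.008), nrow(msh$nodes))
  sol <- structure(list(u = u, axisym = TRUE), class = "oh_solution")
  st <- element_strains(sol, msh)
  expect_true(all(abs(as.matrix(st[, -1])) < 1e-15))
  expect_true(all(octahedral_shear_strain(st) < 1e-15))
})

test_that("implant-interior nodes carry no pressure unknowns", {
  msh <- toy_mesh()
  mats <- region_materials(msh)
  sys <- assemble_poroelastic_system(msh, mats, dt = 0.1)
  conn <- as.matrix(msh$elements[, c("n1", "n2", "n3", "n4")])
  poro_nodes <- sort(unique(as.vector(
    conn[msh$elements$region != "implant", ])))
  expect_identical(sys$pnodes, poro_nodes)
  imp_only <- setdiff(unique(as.vector(
    conn[msh$elements$region == "implant", ])), poro_nodes)
  expect_true(length(imp_only) > 0)
  expect_true(all(!imp_only %in% sys$pnodes))
})

test_that("the assembled coupled operator is symmetric", {
  msh <- generate_mesh(rectangle_layout(1, 2, r0 = 1), 0.5)
  sys <- assemble_poroelastic_system(msh, uniform_materials(msh), dt = 0.3)
  asym <- max(abs(sys$A - Matrix::t(sys$A))) / max(abs(sys$A))
  expect_lt(asym, 1e-12)
})

terzaghi_solve <- function(fx, Tv, n_sub = 40) {
  msh <- fx$mesh
  an <- fx$analytic
  f <- boundary_forces(msh, msh$boundaries$top_surface, c(0, -an$sigma0))
  diri <- dplyr::bind_rows(
    tibble::tibble(node = msh$nodes$node, dof = "r", value = 0),
    tibble::tibble(node = msh$boundaries$fixed_base, dof = "z", value = 0))
  tend <- an$time_of(Tv)
  dts <- diff(c(0, tend * (seq_len(n_sub) / n_sub)^2))
  poro_solve(msh, fx$materials, diri, forces = f,
             drained_nodes = msh$boundaries$top_surface, dt = dts,
             schedule = rep(1, length(dts)))
}

test_that("Terzaghi consolidation matches the series solution within 2%
           at Tv = 0.1 and 0.5", {
  fx <- make_fixture("terzaghi_column")
  for (Tv in c(0.1, 0.5)) {
    sol <- terzaghi_solve(fx, Tv, n_sub = 60)
    pa <- fx$analytic$pressure(fx$mesh$nodes$z, Tv)
    rel <- sqrt(sum((sol$p_full - pa)^2) / sum(pa^2))
    expect_lt(rel, 0.02, label = paste("Tv =", Tv))
  }
})

test_that("pore pressure decays monotonically towards the drained state", {
  fx <- make_fixture("terzaghi_column")
  msh <- fx$mesh
  an <- fx$analytic
  f <- boundary_forces(msh, msh$boundaries$top_surface, c(0, -an$sigma0))
  diri <- dplyr::bind_rows(
    tibble::tibble(node = msh$nodes$node, dof = "r", value = 0),
    tibble::tibble(node = msh$boundaries$fixed_base, dof = "z", value = 0))
  dts <- rep(an$time_of(0.05), 20)
  sol <- poro_solve(msh, fx$materials, diri, forces = f,
                    drained_nodes = msh$boundaries$top_surface, dt = dts,
                    schedule = rep(1, length(dts)), keep_history = TRUE)
  base_node <- msh$boundaries$fixed_base[1]
  p_base <- sol$p_hist[base_node, ]
  expect_true(all(diff(p_base) < 1e-12))
  # analytic first-mode decay puts the base pressure near 0.11 * sigma0
  # at Tv = 1; the discrete solution should be at or below that level
  expect_lt(p_base[length(p_base)], 0.15 * an$sigma0)
})

lame_error <- function(element_size) {
  fx <- make_fixture("lame_cylinder", element_size = element_size)
  msh <- fx$mesh
  f <- boundary_forces(msh, msh$boundaries$inner_wall, c(fx$analytic$P, 0))
  diri <- tibble::tibble(node = msh$nodes$node, dof = "z", value = 0)
  sol <- poro_solve(msh, fx$materials, diri, forces = f,
                    drained_nodes = msh$nodes$node, dt = 1, n_steps = 1,
                    schedule = 1)
  ur <- sol$u[2 * msh$nodes$node - 1]
  ua <- fx$analytic$u_r(msh$nodes$r)
  sqrt(sum((ur - ua)^2) / sum(ua^2))
}

test_that("Lame pressurized cylinder matches the closed form within 1%
           and converges at the expected rate", {
  e1 <- lame_error(0.5)
  e2 <- lame_error(0.25)
  expect_lt(e2, 0.01)
  rate <- log2(e1 / e2)
  expect_gt(rate, 1.8)
})

test_that("zero applied displacement yields the zero solution", {
  msh <- toy_mesh()
  mats <- region_materials(msh)
  sol <- solve_loadstep(msh, mats, load_case(top_displacement = 0),
                        interface_spec("tied"))
  expect_lt(max(abs(sol$u)), 1e-14)
  expect_lt(max(abs(sol$p_full), na.rm = TRUE), 1e-14)
})

test_that("octahedral shear strain formula matches closed forms and a
           dense eigenvalue oracle", {
  # hydrostatic: deviatoric measure vanishes
  hyd <- tibble::tibble(e_rr = 1e-3, e_zz = 1e-3, e_tt = 1e-3, g_rz = 0)
  expect_equal(octahedral_shear_strain(hyd), 0)
  # uniaxial e1 = e: gamma = 2*sqrt(2)/3 * e
  e <- 4e-3
  uni <- tibble::tibble(e_rr = e, e_zz = 0, e_tt = 0, g_rz = 0)
  expect_equal(octahedral_shear_strain(uni), 2 * sqrt(2) / 3 * e,
               tolerance = 1e-12)
  # random states against an explicit eigen-decomposition
  set.seed(42)
  for (i in 1:20) {
    s <- stats::rnorm(4, sd = 1e-3)
    tens3 <- matrix(c(s[1], s[4] / 2, 0,
                      s[4] / 2, s[2], 0,
                      0, 0, s[3]), 3, 3)
    ev <- eigen(tens3, symmetric = TRUE, only.values = TRUE)$values
    oracle <- (2 / 3) * sqrt((ev[1] - ev[2])^2 + (ev[2] - ev[3])^2 +
                               (ev[3] - ev[1])^2)
    mine <- octahedral_shear_strain(
      tibble::tibble(e_rr = s[1], e_zz = s[2], e_tt = s[3], g_rz = s[4]))
    expect_equal(mine, oracle, tolerance = 1e-10)
  }
})

test_that("Darcy velocity reproduces uniform and linear pressure fields", {
  msh <- generate_mesh(rectangle_layout(1, 1, r0 = 1), 0.25)
  mats <- uniform_materials(msh, k = 1e-14)
  # uniform pressure: zero velocity
  sol <- structure(list(u = numeric(2 * nrow(msh$nodes)),
                        p_full = rep(0.5, nrow(msh$nodes)),
                        axisym = TRUE), class = "oh_solution")
  dv <- darcy_velocity(sol, mats, msh)
  expect_lt(max(dv$nu), 1e-12)
  # linear p = beta * z: nu_z = -k * beta (in um/s), nu_r = 0
  beta <- 0.2 # MPa / mm
  sol$p_full <- beta * msh$nodes$z
  dv2 <- darcy_velocity(sol, mats, msh)
  k_mm <- 1e-14 * 1e12
  expect_true(all(abs(dv2$nu_z - (-k_mm * beta * 1e3)) < 1e-9))
  expect_true(all(abs(dv2$nu_r) < 1e-9))
  # implant elements have no pore field
  toy <- toy_mesh()
  tmats <- region_materials(toy)
  imp <- tmats$element[tmats$is_solid_only][1]
  sol3 <- structure(list(u = numeric(2 * nrow(toy$nodes)),
                         p_full = rep(0, nrow(toy$nodes)), axisym = TRUE),
                    class = "oh_solution")
  expect_error(darcy_velocity(sol3, tmats, toy, elements = imp),
               "solid-only")
})

test_that("centroid strains match numerical differentiation of a smooth
           displacement field", {
  msh <- generate_mesh(rectangle_layout(1, 1, r0 = 2), 0.25)
  ur_f <- function(r, z) 1e-3 * r^2 + 5e-4 * z^2
  uz_f <- function(r, z) -2e-3 * r * z
  u <- numeric(2 * nrow(msh$nodes))
  u[2 * msh$nodes$node - 1] <- ur_f(msh$nodes$r, msh$nodes$z)
  u[2 * msh$nodes$node] <- uz_f(msh$nodes$r, msh$nodes$z)
  sol <- structure(list(u = u, axisym = TRUE), class = "oh_solution")
  st <- element_strains(sol, msh)
  conn <- as.matrix(msh$elements[, c("n1", "n2", "n3", "n4")])
  cr <- rowMeans(matrix(msh$nodes$r[conn], ncol = 4))
  cz <- rowMeans(matrix(msh$nodes$z[conn], ncol = 4))
  hfd <- 1e-6
  d_err <- (ur_f(cr + hfd, cz) - ur_f(cr - hfd, cz)) / (2 * hfd)
  d_ezz <- (uz_f(cr, cz + hfd) - uz_f(cr, cz - hfd)) / (2 * hfd)
  # bilinear interpolation of a quadratic: centroid derivative error is
  # O(h^2); compare against the analytic derivative accordingly
  expect_lt(max(abs(st$e_rr - d_err)), 1e-6)
  expect_lt(max(abs(st$e_zz - d_ezz)), 1e-6)
})

test_that("coulomb contact releases collar shear and approaches tied
           behaviour under the implant tip", {
  fx <- make_fixture("single_chamber")
  msh <- fx$mesh
  sol_t <- solve_loadstep(msh, fx$materials, load_case(),
                          interface_spec("tied"))
  sol_c <- solve_loadstep(msh, fx$materials, load_case(),
                          interface_spec("coulomb_penalty"))
  # sliding at the smooth collar: slip comparable to the applied 8 um
  iu <- sol_c$u_ext
  slip_z <- iu[2 * sol_c$dup] - iu[2 * sol_c$dup_of]
  expect_gt(max(abs(slip_z)), 0.0 + 0.5 * 0.008)
  # stimuli: contact lowers the crestal (top-callus) stimulus
  cc <- callus_centroids(msh)
  S_t <- with(compute_stimuli(sol_t, fx$materials, msh)[cc$idx, ],
              stimulus(gamma_oct, nu))
  S_c <- with(compute_stimuli(sol_c, fx$materials, msh)[cc$idx, ],
              stimulus(gamma_oct, nu))
  top <- cc$z > max(cc$z) - 0.3
  expect_lt(mean(S_c[top]), 0.5 * mean(S_t[top]))
  # both modes agree on the order of magnitude of the peak displacement
  expect_equal(max(abs(sol_c$u)), max(abs(sol_t$u)), tolerance = 0.3)
})
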