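test_that("degenerate (zero-depth) chamber gives a cylindrical profile", {
  pr <- build_chamber_profile(chamber_params(0, 60, 60, 0, 0,
                                             n_threads = 4))
  thread_part <- pr$outline[pr$outline$z >= pr$z_threads[1] &
                              pr$outline$z <= pr$z_threads[2], ]
  expect_true(all(abs(thread_part$r - pr$outer_radius) < 1e-12))
})

test_that("sawtooth (v-thread, no root/crest) vertex count follows the
           construction formula", {
  for (n in c(1, 3, 6)) {
    # pick angles so the two flanks exactly fill one pitch
    d <- 0.3
    phi <- atan(2 * d / 0.8) * 180 / pi # dz_up = dz_lo = pitch/2
    pr <- build_chamber_profile(chamber_params(
      d, phi, phi, 0, 0, pitch = 0.8, n_threads = n,
      profile_style = "v_thread", collar_length = 0.5, apex_length = 0.5))
    # outline: top, collar end, then 2 vertices per sawtooth, apex end
    expect_equal(nrow(pr$outline), 2 * n + 3)
  }
})

test_that("trapezoid chambers contribute 4 vertices each and the enclosed
           area matches the analytic value", {
  d <- 0.25
  r_len <- 0.12
  c_len <- 0.1
  phi_u <- 55
  phi_l <- 65
  n <- 3
  pitch <- 0.8
  ro <- 2
  p <- chamber_params(d, phi_u, phi_l, r_len, c_len, pitch = pitch,
                      n_threads = n, outer_radius = ro,
                      collar_length = 0.7, apex_length = 0.5)
  pr <- build_chamber_profile(p)
  dz_up <- d / tan(phi_u * pi / 180)
  dz_lo <- d / tan(phi_l * pi / 180)
  # shoelace area = full cylinder minus n trapezoidal notches
  notch <- d * (r_len + (r_len + dz_up + dz_lo)) / 2
  analytic <- ro * pr$length_total - n * notch
  expect_equal(polygon_area(pr$polyline), analytic, tolerance = 1e-9)
  # 4 genuine vertices per chamber (crest end, root start/end, flank end);
  # the last flank end coincides with the thread-band boundary
  thread_v <- pr$outline[pr$outline$z > pr$z_threads[1] + 1e-9 &
                           pr$outline$z < pr$z_threads[2] - 1e-9, ]
  expect_equal(nrow(thread_v), 4 * n - 1)
})

test_that("self-intersecting chamber parameters are rejected with the
           closure constraint named", {
  expect_error(chamber_params(0.5, 30, 30, 0.3, 0.3, pitch = 0.8),
               "pitch")
})

test_that("profile generation is deterministic", {
  p <- chamber_params(0.3, 60, 55, 0.1, 0.1, n_threads = 5)
  a <- build_chamber_profile(p)
  b <- build_chamber_profile(p)
  expect_identical(a$polyline, b$polyline)
})

test_that("cylindrical-profile callus band area matches the closed form", {
  a <- 1.5
  m <- 0.5
  pr <- build_chamber_profile(chamber_params(0, 60, 60, 0, 0,
                                             n_threads = 4,
                                             outer_radius = a))
  L <- pr$length_total
  lay <- build_domain(pr, cortical_thickness = 1, callus_margin = m,
                      domain_extent = c(4, L + 2))
  # band along the shank plus the wrap under the tip
  analytic <- m * L + (a + m) * m
  expect_equal(polygon_area(lay$regions$callus), analytic,
               tolerance = 1e-6)
})

test_that("zero cortical thickness removes the cortical region only", {
  pr <- build_chamber_profile(chamber_params(0.3, 60, 60, 0.1, 0.1,
                                             n_threads = 2))
  lay0 <- build_domain(pr, cortical_thickness = 0, callus_margin = 0.5,
                       domain_extent = c(5, 6))
  lay1 <- build_domain(pr, cortical_thickness = 1, callus_margin = 0.5,
                       domain_extent = c(5, 6))
  expect_false("cortical" %in% names(lay0$regions))
  expect_identical(lay0$regions$implant, lay1$regions$implant)
  expect_identical(lay0$regions$callus, lay1$regions$callus)
})

test_that("region polygons tile the domain rectangle", {
  pr <- build_chamber_profile(chamber_params(0.35, 55, 55, 0.05, 0.05,
                                             n_threads = 3))
  lay <- build_domain(pr, cortical_thickness = 1.2, callus_margin = 0.4,
                      domain_extent = c(4.5, 7))
  expect_equal(sum(layout_areas(lay)$area), 4.5 * 7, tolerance = 1e-9)
})

test_that("callus band outside the domain raises", {
  pr <- build_chamber_profile(chamber_params(0.3, 60, 60, 0.1, 0.1))
  expect_error(build_domain(pr, 1, callus_margin = 2,
                            domain_extent = c(3.5, 12)),
               "callus band")
})

test_that("unit square at element size 0.25 gives 16 structured quads", {
  msh <- generate_mesh(rectangle_layout(1, 1), 0.25)
  expect_identical(nrow(msh$elements), 16L)
  expect_true(all(abs(msh$elements$area - 0.0625) < 1e-12))
})

test_that("mesh conserves total and per-region areas on the toy implant", {
  fx <- make_fixture("single_chamber", element_size = 0.05)
  msh <- fx$mesh
  la <- layout_areas(fx$layout)
  ma <- mesh_region_areas(msh)
  tot_layout <- sum(la$area)
  expect_equal(sum(ma$area), tot_layout, tolerance = 0.005)
  for (rg in la$region) {
    expect_equal(ma$area[ma$region == rg], unname(la$area[la$region == rg]),
                 tolerance = 0.005)
  }
})

test_that("all element Jacobians are positive and median edge length is
           within 25% of the target", {
  msh <- toy_mesh()
  conn <- as.matrix(msh$elements[, c("n1", "n2", "n3", "n4")])
  expect_true(all(msh$elements$area > 0))
  # horizontal edge lengths of the trapezoid elements
  e1 <- abs(msh$nodes$r[conn[, 2]] - msh$nodes$r[conn[, 1]])
  e2 <- abs(msh$nodes$z[conn[, 4]] - msh$nodes$z[conn[, 1]])
  med <- stats::median(c(e1, e2))
  expect_lt(abs(med - msh$element_size_target),
            0.25 * msh$element_size_target)
})

test_that("mesh generation is deterministic", {
  a <- make_fixture("single_chamber")$mesh
  b <- make_fixture("single_chamber")$mesh
  expect_identical(a$nodes, b$nodes)
  expect_identical(a$elements, b$elements)
})

test_that("the eight catalog designs satisfy the printed ordering
           relations simultaneously", {
  cat8 <- catalog_implants()
  expect_named(cat8, LETTERS[1:8])
  p <- lapply(cat8, `[[`, "params")
  expect_gt(p$A$upper_flank_angle_phi, p$E$upper_flank_angle_phi)
  expect_gt(p$E$upper_flank_angle_phi, p$F$upper_flank_angle_phi)
  expect_identical(p$E$upper_flank_angle_phi, p$E$lower_flank_angle)
  expect_lt(p$F$upper_flank_angle_phi, p$F$lower_flank_angle)
  expect_lt(p$B$root_length_r, p$G$root_length_r)
  expect_lt(p$B$crest_length_c, p$G$crest_length_c)
  expect_lt(p$C$depth_d, p$H$depth_d)
  expect_identical(p$D$profile_style, "eagle_beak")
  expect_identical(p$H$profile_style, "inverse_eagle_beak")
  # every catalog entry builds a valid, meshable profile
  for (lab in names(cat8)) {
    pr <- build_chamber_profile(cat8[[lab]]$params)
    expect_true(all(diff(pr$outline$z) < 1e-12), label = lab)
  }
})
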