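test_that("stimulus combines solid and fluid terms with the standard
           constants", {
  expect_identical(stimulus(0, 0), 0)
  expect_equal(stimulus(0.0375, 0), 1)
  expect_equal(stimulus(0.0375, 3), 2)
  expect_equal(stimulus(0.1125, 0), 3)
  expect_equal(stimulus(0, 0.03), 0.01)
  expect_error(stimulus(-0.1, 0), "non-negative")
  expect_error(stimulus(0, -1), "non-negative")
  # custom constants rescale linearly
  k <- stimulus_constants(a = 0.075, b = 6)
  expect_equal(stimulus(0.075, 6, k), 2)
})

test_that("classification honours the printed boundary semantics", {
  expect_identical(as.character(classify_phenotype(5)), "fibrous_tissue")
  expect_identical(as.character(classify_phenotype(3)), "cartilage")
  expect_identical(as.character(classify_phenotype(1)), "immature_bone")
  expect_identical(as.character(classify_phenotype(0.266)), "mature_bone")
  expect_identical(as.character(classify_phenotype(0.010)), "resorption")
  expect_identical(as.character(classify_phenotype(0.005)), "resorption")
  expect_identical(as.character(classify_phenotype(0)), "resorption")
  expect_error(classify_phenotype(-0.1), "non-negative")
})

test_that("classification agrees with a brute-force interval lookup over
           a million random stimuli", {
  oracle <- function(S) {
    br <- c(0.010, 0.266, 1, 3)
    lab <- c("resorption", "mature_bone", "immature_bone", "cartilage",
             "fibrous_tissue")
    lab[findInterval(S, br, left.open = TRUE) + 1]
  }
  set.seed(1)
  S <- c(10^stats::runif(1e6, -4, 1),
         0.010, 0.266, 1, 3, 0,
         0.010 + 1e-12, 0.266 + 1e-12, 1 + 1e-12, 3 + 1e-12)
  mine <- as.character(classify_phenotype(S))
  orc <- oracle(S)
  expect_identical(mine, orc)
  # each value falls in exactly one class
  expect_false(anyNA(mine))
})

test_that("mixing endpoints reproduce the material table exactly for all
           phenotypes and properties", {
  tab <- material_table()
  for (ph in c("fibrous_tissue", "cartilage", "immature_bone",
               "mature_bone")) {
    lo <- mixed_properties(ph, 0, 1, tab)
    hi <- mixed_properties(ph, 1, 1, tab)
    row <- tab[tab$phenotype == ph, ]
    g <- tab[tab$phenotype == "granulation", ]
    for (col in c("young_modulus", "poisson_ratio", "permeability")) {
      expect_identical(lo[[col]], g[[col]], label = paste(ph, col, "lo"))
      expect_identical(hi[[col]], row[[col]], label = paste(ph, col, "hi"))
    }
  }
  # half concentration: arithmetic midpoint (immature bone E -> 500.5)
  mid <- mixed_properties("immature_bone", 0.5, 1, tab)
  expect_equal(mid$young_modulus, (1 + 1000) / 2)
  # resorption maps to granulation at any concentration
  res <- mixed_properties("resorption", 1, 1, tab)
  expect_identical(res$young_modulus,
                   tab$young_modulus[tab$phenotype == "granulation"])
  expect_error(mixed_properties("enamel", 0.5, 1, tab), "enamel")
})

test_that("temporal smoothing has the constant fixed point and truncates
           the early window correctly", {
  X <- function(E) tibble::tibble(young_modulus = E, poisson_ratio = 0.2,
                                  permeability = 1e-14)
  # constant input is a fixed point
  hist <- list()
  for (i in 1:12) {
    Xi <- smooth_properties(X(7), hist, i = i, N = 10)
    expect_equal(Xi$young_modulus, 7)
    hist <- c(list(Xi), hist)
    if (length(hist) > 9) hist <- hist[1:9]
  }
  # empty history: X_1 = X_mix
  expect_equal(smooth_properties(X(42), list(), i = 1)$young_modulus, 42)
  # i = 3: mean of the three available values
  X3 <- smooth_properties(X(9), list(X(6), X(3)), i = 3, N = 10)
  expect_equal(X3$young_modulus, (9 + 6 + 3) / 3)
  # direct-summation oracle for a ramp input over 15 iterations
  hist <- list()
  vals <- numeric(0)
  for (i in 1:15) {
    Xi <- smooth_properties(X(i), hist, i = i, N = 10)
    nwin <- min(i - 1, 9)
    prior <- if (nwin > 0) vals[seq(length(vals), by = -1,
                                    length.out = nwin)] else numeric(0)
    expect_equal(Xi$young_modulus, mean(c(i, prior)), label = paste("i =", i))
    vals <- c(vals, Xi$young_modulus)
    hist <- c(list(Xi), hist)
    if (length(hist) > 9) hist <- hist[1:9]
  }
  # over-long history raises
  expect_error(smooth_properties(X(1), rep(list(X(1)), 10), i = 20, N = 10),
               "at most")
})

test_that("zero load drives the whole callus to resorption by day 2 with
           zero bone area", {
  msh <- toy_mesh()
  h <- run_healing(msh, days = 2, load = load_case(top_displacement = 0),
                   interface = interface_spec("tied"), D = 0.05)
  f2 <- h$fields[[2]]
  expect_true(all(f2$phenotype == "resorption"))
  expect_identical(h$daily$ba_percent[2], 0)
  expect_identical(h$daily$bic_percent[2], 0)
})

test_that("the healing pipeline is deterministic", {
  fx <- make_fixture("single_chamber")
  h1 <- run_healing(fx$mesh, days = 3, D = 0.05)
  h2 <- run_healing(fx$mesh, days = 3, D = 0.05)
  expect_identical(h1$daily, h2$daily)
  expect_identical(h1$fields, h2$fields)
})

test_that("smoothed callus modulus stays within the granulation-to-mature
           bracket and matures monotonically at saturated concentration", {
  h <- toy_healing_run()
  for (d in c(1, 10, 35)) {
    E <- h$fields[[d]]$young_modulus
    expect_true(all(E >= 1 - 1e-9 & E <= 6000 + 1e-9))
  }
  # elements that stay mature bone with non-decreasing concentration
  # stiffen monotonically
  phen <- sapply(h$fields, function(f) as.character(f$phenotype))
  always_mature <- which(apply(phen[, 10:35], 1, function(x)
    all(x == "mature_bone")))
  if (length(always_mature) > 0) {
    Emat <- sapply(h$fields[10:35], function(f)
      f$young_modulus[always_mature[1]])
    expect_true(all(diff(Emat) > -1e-9))
  }
})

test_that("daily summaries track the per-element fields", {
  h <- toy_healing_run()
  f <- h$fields[[35]]
  areas <- h$mesh$elements$area[match(f$element, h$mesh$elements$element)]
  expect_equal(h$daily$mean_S[35], sum(f$S * areas) / sum(areas))
  expect_identical(h$daily$resorption[35],
                   sum(f$phenotype == "resorption"))
  expect_s3_class(tidy(h), "tbl_df")
  expect_identical(nrow(tidy(h)), 35L)
  g <- glance(h)
  expect_equal(g$days, 35)
  expect_equal(g$ba_percent, h$daily$ba_percent[35])
})
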