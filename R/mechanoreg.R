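#' Mechano-regulatory stimulus
#'
#' The scalar cell stimulus `S = gamma/a + nu/b` combining the solid
#' (octahedral shear strain) and fluid (interstitial fluid speed) stimuli.
#'
#' @param gamma_oct octahedral shear strain (dimensionless, >= 0);
#'   vectorized.
#' @param nu interstitial fluid speed (um/s, >= 0); vectorized.
#' @param constants a [stimulus_constants()] list.
#' @return Numeric vector of stimulus values.
#' @examples
#' stimulus(0.0375, 0)   # 1: the cartilage / immature-bone boundary
#' stimulus(0.0375, 3)   # 2
#' @export
stimulus <- function(gamma_oct, nu, constants = stimulus_constants()) {
  if (any(gamma_oct < 0, na.rm = TRUE)) {
    rlang::abort("octahedral shear strain must be non-negative")
  }
  if (any(nu < 0, na.rm = TRUE)) {
    rlang::abort("fluid speed must be non-negative")
  }
  gamma_oct / constants$a + nu / constants$b
}

#' Phenotype levels in maturation order
#' @export
phenotype_levels <- function() {
  c("fibrous_tissue", "cartilage", "immature_bone", "mature_bone",
    "resorption", "granulation")
}

#' Classify the stimulus into a tissue phenotype
#'
#' Boundary semantics follow the printed ranges exactly: fibrous tissue for
#' S > 3, cartilage for 3 >= S > 1, immature bone for 1 >= S > 0.266,
#' mature bone for 0.266 >= S > 0.010, resorption for 0.010 >= S. Each
#' upper end is closed, so S = 3 is cartilage, S = 1 immature bone,
#' S = 0.266 mature bone, S = 0.010 (and S = 0, as at zero load)
#' resorption.
#'
#' @param S stimulus values (>= 0); vectorized.
#' @param thresholds named numeric vector of the class lower bounds
#'   `c(fibrous, cartilage, immature, mature)`.
#' @return Factor with levels [phenotype_levels()].
#' @export
classify_phenotype <- function(S, thresholds = c(fibrous = 3, cartilage = 1,
                                                 immature = 0.266,
                                                 mature = 0.010)) {
  if (any(S < 0, na.rm = TRUE)) {
    rlang::abort("stimulus must be non-negative")
  }
  out <- ifelse(S > thresholds[["fibrous"]], "fibrous_tissue",
         ifelse(S > thresholds[["cartilage"]], "cartilage",
         ifelse(S > thresholds[["immature"]], "immature_bone",
         ifelse(S > thresholds[["mature"]], "mature_bone", "resorption"))))
  factor(out, levels = phenotype_levels())
}

#' Concentration-weighted material mixing
#'
#' Blends granulation-tissue properties with the differentiated phenotype's
#' properties by the local stem-cell concentration:
#' `X_mix = (n_max - n_i)/n_max * X_g + n_i/n_max * X_d`
#' for each scalar property (Young's modulus, Poisson ratio, permeability).
#' Resorption maps to granulation properties (softest state).
#'
#' @param phenotype character or factor vector of differentiated phenotypes.
#' @param n_i local stem-cell concentration (0..n_max); vectorized.
#' @param n_max maximal concentration.
#' @param table a [material_table()].
#' @return Tibble `phenotype`, `young_modulus`, `poisson_ratio`,
#'   `permeability` of the mixed state.
#' @export
mixed_properties <- function(phenotype, n_i, n_max = 1,
                             table = material_table()) {
  if (any(n_i < -1e-12 | n_i > n_max + 1e-12)) {
    rlang::abort("concentration must lie in [0, n_max]")
  }
  phen <- as.character(phenotype)
  target <- ifelse(phen == "resorption", "granulation", phen)
  idx <- match(target, table$phenotype)
  if (anyNA(idx)) {
    rlang::abort(paste0("no material table entry for phenotype(s): ",
                        paste(unique(phen[is.na(idx)]), collapse = ", ")))
  }
  g <- match("granulation", table$phenotype)
  wd <- pmin(pmax(n_i / n_max, 0), 1)
  wg <- 1 - wd
  tibble::tibble(
    phenotype = phen,
    young_modulus = wg * table$young_modulus[g] +
      wd * table$young_modulus[idx],
    poisson_ratio = wg * table$poisson_ratio[g] +
      wd * table$poisson_ratio[idx],
    permeability = wg * table$permeability[g] + wd * table$permeability[idx])
}

#' Temporal smoothing of material properties
#'
#' Averages the freshly mixed properties with the smoothed properties of up
#' to the previous `N - 1` iterations,
#' `X_i = (X_mix + X_{i-1} + ... + X_{i-(N-1)}) / N`,
#' which damps day-to-day jumps in element stiffness. For early iterations
#' (`i < N`) the window is truncated to the available history and the
#' denominator is the number of summed terms.
#'
#' @param X_mix data frame of mixed properties (columns `young_modulus`,
#'   `poisson_ratio`, `permeability`), one row per element.
#' @param history list of prior smoothed property data frames, most recent
#'   first; length at most `N - 1`.
#' @param i iteration (day) index, >= 1.
#' @param N smoothing window (current value plus `N - 1` previous).
#' @return Data frame of smoothed properties, same shape as `X_mix`.
#' @export
smooth_properties <- function(X_mix, history = list(), i = 1, N = 10) {
  if (length(history) > N - 1) {
    rlang::abort(paste0("history holds ", length(history),
                        " sets; at most N - 1 = ", N - 1, " allowed"))
  }
  if (length(history) > min(i - 1, N - 1)) {
    rlang::abort("history longer than the iteration index allows")
  }
  cols <- c("young_modulus", "poisson_ratio", "permeability")
  acc <- as.data.frame(X_mix)[, cols]
  for (hset in history) acc <- acc + as.data.frame(hset)[, cols]
  out <- acc / (1 + length(history))
  tibble::as_tibble(out)
}

#' Run the iterative healing simulation
#'
#' One iteration per healing day, each consisting of: (1) a poroelastic
#' load-step solve with the current material field; (2) per-element
#' stimulus and phenotype classification for the next day; (3) one
#' stem-cell diffusion step; (4) concentration-weighted property mixing;
#' (5) temporal smoothing. The callus starts as granulation tissue at zero
#' cell concentration; implant, cortical and cancellous regions keep their
#' fixed properties.
#'
#' @param mesh an `oh_mesh` with an implant (or any mesh with a callus
#'   region and load/boundary sets).
#' @param days number of healing days (iterations).
#' @param load a [load_case()].
#' @param interface an [interface_spec()].
#' @param constants a [stimulus_constants()].
#' @param table a [material_table()].
#' @param D stem-cell diffusivity (mm^2/day) or `"calibrate"` to calibrate
#'   so the callus saturates at `days`.
#' @param N smoothing window.
#' @param saturation_threshold saturation criterion for calibration.
#' @param thresholds classification thresholds, see [classify_phenotype()].
#' @param verbose print a per-day summary line.
#' @return A list of class `oh_healing`: `daily` (tibble with per-day class
#'   counts, mean stimulus, mean callus modulus, BIC and BA), `fields`
#'   (list of per-day callus element tibbles), `final_materials`, `roi`,
#'   `mesh`, `D` and the run settings.
#' @export
run_healing <- function(mesh, days = 35, load = load_case(),
                        interface = interface_spec(),
                        constants = stimulus_constants(),
                        table = material_table(),
                        D = "calibrate", N = 10,
                        saturation_threshold = 0.99,
                        thresholds = c(fibrous = 3, cartilage = 1,
                                       immature = 0.266, mature = 0.010),
                        verbose = FALSE) {
  if (identical(D, "calibrate")) {
    D <- calibrate_diffusivity(mesh, horizon_days = days,
                               saturation_threshold = saturation_threshold)
  }
  mat <- region_materials(mesh, table)
  cal <- which(mat$region == "callus")
  if (length(cal) == 0) rlang::abort("mesh has no callus elements")
  conc <- concentration_field(mesh, D)
  conn_cal <- mesh_conn(mesh)[cal, , drop = FALSE]
  conc_of_elements <- function(field) {
    nn <- numeric(nrow(mesh$nodes))
    nn[field$nodes] <- field$n
    rowMeans(matrix(nn[conn_cal], ncol = 4))
  }
  roi <- extract_roi(mesh)
  history <- list()
  fields <- vector("list", days)
  daily <- vector("list", days)
  phen_present <- factor(rep("granulation", length(cal)),
                         levels = phenotype_levels())
  areas <- mesh$elements$area[cal]

  for (day in seq_len(days)) {
    sol <- tryCatch(
      solve_loadstep(mesh, mat, load, interface),
      error = function(e) {
        rlang::abort(paste0("healing day ", day, ": ",
                            conditionMessage(e)))
      })
    sti <- compute_stimuli(sol, mat, mesh)
    sti_cal <- sti[cal, ]
    S <- stimulus(sti_cal$gamma_oct, sti_cal$nu, constants)
    phen_next <- classify_phenotype(S, thresholds)

    conc <- advance_concentration(conc, dt = 1)
    n_e <- conc_of_elements(conc)
    X_mix <- mixed_properties(phen_next, n_e, n_max = conc$n_max, table)
    X_i <- smooth_properties(X_mix, history, i = day, N = N)
    history <- c(list(X_i), history)
    if (length(history) > N - 1) history <- history[seq_len(N - 1)]

    mat$young_modulus[cal] <- X_i$young_modulus
    mat$poisson_ratio[cal] <- X_i$poisson_ratio
    mat$permeability[cal] <- X_i$permeability
    mat$phenotype[cal] <- as.character(phen_next)

    fields[[day]] <- tibble::tibble(
      element = mat$element[cal],
      phenotype = phen_present,
      S = S, gamma_oct = sti_cal$gamma_oct, nu = sti_cal$nu,
      concentration = n_e,
      young_modulus = X_i$young_modulus)
    phen_tab <- table(phen_present)
    mor <- morphometry(fields[[day]], roi, mesh)
    daily[[day]] <- tibble::tibble(
      day = day,
      fibrous_tissue = as.integer(phen_tab[["fibrous_tissue"]]),
      cartilage = as.integer(phen_tab[["cartilage"]]),
      immature_bone = as.integer(phen_tab[["immature_bone"]]),
      mature_bone = as.integer(phen_tab[["mature_bone"]]),
      resorption = as.integer(phen_tab[["resorption"]]),
      granulation = as.integer(phen_tab[["granulation"]]),
      mean_S = sum(S * areas) / sum(areas),
      mean_modulus = sum(X_i$young_modulus * areas) / sum(areas),
      n_min = min(conc$n), n_mean = mean(conc$n),
      bic_percent = mor$bic_percent, ba_percent = mor$ba_percent)
    if (verbose) {
      message(sprintf(
        "day %2d: mean S %.3f, mean E %.1f MPa, BIC %.1f%%, BA %.1f%%",
        day, daily[[day]]$mean_S, daily[[day]]$mean_modulus,
        mor$bic_percent, mor$ba_percent))
    }
    phen_present <- phen_next
  }
  structure(list(
    daily = dplyr::bind_rows(daily), fields = fields,
    final_materials = mat, roi = roi, mesh = mesh, D = D, days = days,
    load = load, interface = interface, constants = constants,
    table = table, N = N), class = "oh_healing")
}

#' @export
#' @method print oh_healing
print.oh_healing <- function(x, ...) {
  last <- x$daily[nrow(x$daily), ]
  cat("<oh_healing> ", x$days, " days, ",
      sum(x$final_materials$region == "callus"), " callus elements\n",
      "  final BIC ", round(last$bic_percent, 1), "%, BA ",
      round(last$ba_percent, 1), "%, mean callus modulus ",
      round(last$mean_modulus, 1), " MPa (D = ", signif(x$D, 3),
      " mm^2/day)\n", sep = "")
  invisible(x)
}
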