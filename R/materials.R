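#' Tissue and implant material property catalog
#'
#' Poroelastic material properties for each tissue phenotype and for the
#' non-differentiating regions (cortical bone, cancellous bone, Ti-6Al-4V
#' implant). Young's modulus is the drained modulus in MPa; permeability is
#' the hydraulic mobility (intrinsic permeability already divided by fluid
#' viscosity) in m^4/(N s), the unit in which these constants are usually
#' tabulated in the bone mechanobiology literature. The implant carries no
#' pore fluid (`is_solid_only = TRUE`); resorbed elements take granulation
#' tissue properties (the model's softest state) and are counted as
#' non-bone by the histomorphometry.
#'
#' @param overrides optional data frame with columns `phenotype` and any of
#'   `young_modulus`, `poisson_ratio`, `permeability` to replace defaults.
#' @return A tibble with columns `phenotype`, `young_modulus` (MPa),
#'   `poisson_ratio`, `permeability` (m^4/(N s)), `is_solid_only`.
#' @examples
#' material_table()
#' @export
material_table <- function(overrides = NULL) {
  tab <- tibble::tibble(
    phenotype = c("granulation", "fibrous_tissue", "cartilage",
                  "immature_bone", "mature_bone", "resorption",
                  "cortical", "cancellous", "implant"),
    young_modulus = c(1, 2, 10, 1000, 6000, 1, 20000, 6000, 113000),
    poisson_ratio = c(0.17, 0.17, 0.17, 0.30, 0.30, 0.17, 0.30, 0.30, 0.30),
    permeability = c(1e-14, 1e-14, 5e-15, 1e-13, 3.7e-13, 1e-14,
                     1e-17, 3.7e-13, NA_real_),
    is_solid_only = c(rep(FALSE, 8), TRUE)
  )
  if (!is.null(overrides)) {
    stopifnot(is.data.frame(overrides), "phenotype" %in% names(overrides))
    for (i in seq_len(nrow(overrides))) {
      row <- match(overrides$phenotype[i], tab$phenotype)
      if (is.na(row)) {
        rlang::abort(paste0("unknown phenotype in overrides: '",
                            overrides$phenotype[i], "'"))
      }
      for (col in intersect(names(overrides),
                            c("young_modulus", "poisson_ratio",
                              "permeability"))) {
        tab[[col]][row] <- overrides[[col]][i]
      }
    }
  }
  bad <- !tab$is_solid_only &
    (tab$young_modulus <= 0 | tab$poisson_ratio < 0 |
       tab$poisson_ratio >= 0.5 | is.na(tab$permeability) |
       tab$permeability <= 0)
  if (any(bad)) {
    rlang::abort(paste0("invalid material properties for: ",
                        paste(tab$phenotype[bad], collapse = ", ")))
  }
  tab
}

# Unit conversions kept in one place: permeability catalog unit m^4/(N s)
# to the solver unit mm^4/(N s); solver fluid speed mm/s to um/s.
perm_to_solver <- function(k_m4) k_m4 * 1e12
speed_to_um_s <- function(v_mm_s) v_mm_s * 1e3

#' Mechano-regulatory stimulus constants
#'
#' The scalar stimulus is `S = gamma/a + nu/b` with `gamma` the octahedral
#' shear strain (dimensionless) and `nu` the interstitial fluid speed in
#' um/s. The defaults `a = 0.0375` and `b = 3` um/s are the standard
#' constants of the Prendergast-type mechano-regulation rule.
#'
#' @param a solid (strain) stimulus constant, dimensionless.
#' @param b fluid (velocity) stimulus constant, um/s.
#' @return A list with elements `a` and `b`.
#' @export
stimulus_constants <- function(a = 0.0375, b = 3) {
  if (!(is.numeric(a) && length(a) == 1 && a > 0)) {
    rlang::abort("stimulus constant `a` must be a single positive number")
  }
  if (!(is.numeric(b) && length(b) == 1 && b > 0)) {
    rlang::abort("stimulus constant `b` must be a single positive number")
  }
  list(a = a, b = b)
}
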