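#' Stem-cell concentration field on the healing callus
#'
#' Mesenchymal stem cells invade the callus from its outer boundary (the
#' cells-origin line, held at the maximal concentration `n_max`) and spread
#' by Fickian diffusion, `dn/dt = D lap(n)`. The field lives on the callus
#' sub-mesh only; all other callus boundaries (implant interface, bone
#' interfaces when not part of the origin) are natural no-flux. One
#' implicit (backward Euler) step per healing day is taken with a lumped
#' mass matrix, which preserves the discrete maximum principle on this
#' mesh family.
#'
#' @param mesh an `oh_mesh`.
#' @param D diffusivity (mm^2/day).
#' @param n_max maximal (boundary) concentration; concentrations are
#'   fractions of it.
#' @param region region tag carrying the field (default `"callus"`).
#' @param dirichlet_nodes nodes held at `n_max`; defaults to the mesh's
#'   `cells_origin` boundary set.
#' @param n0 initial concentration (scalar or per-callus-node vector);
#'   defaults to 0 everywhere (granulation tissue before invasion).
#' @return A list of class `oh_concentration`: `nodes` (mesh node ids of
#'   the sub-mesh), `n` (their concentrations), `day`, `D`, `n_max`, plus
#'   cached operators.
#' @export
concentration_field <- function(mesh, D, n_max = 1, region = "callus",
                                dirichlet_nodes = NULL, n0 = 0) {
  stopifnot(D > 0, n_max > 0)
  sel <- mesh$elements$region == region
  if (!any(sel)) rlang::abort(paste0("mesh has no '", region, "' elements"))
  conn <- mesh_conn(mesh)[sel, , drop = FALSE]
  cn <- sort(unique(as.vector(conn)))
  lmap <- match(seq_len(nrow(mesh$nodes)), cn)
  conn_l <- matrix(lmap[conn], ncol = 4)
  coords <- mesh_coords(mesh)[cn, , drop = FALSE]
  sc <- .assemble_scalar(coords, conn_l, TRUE)
  Kd <- Matrix::sparseMatrix(i = sc$Ai, j = sc$Aj, x = sc$Ax,
                             dims = c(length(cn), length(cn)))
  if (is.null(dirichlet_nodes)) dirichlet_nodes <- mesh$boundaries$cells_origin
  fix_l <- lmap[intersect(dirichlet_nodes, cn)]
  if (length(fix_l) == 0) {
    rlang::abort("no cells-origin nodes lie on the field region")
  }
  n <- rep_len(n0, length(cn))
  n[fix_l] <- n_max
  structure(list(nodes = cn, n = n, day = 0L, D = D, n_max = n_max,
                 K = Kd, Mlump = sc$Mlump, fixed = fix_l,
                 region = region),
            class = "oh_concentration")
}

#' Advance the concentration by one implicit diffusion step
#'
#' @param field an [concentration_field()].
#' @param mesh the mesh the field was built on (shape check only; the
#'   operators are cached in the field).
#' @param dt step length in days.
#' @return The updated field (`day` incremented by `dt`).
#' @export
advance_concentration <- function(field, mesh = NULL, dt = 1) {
  stopifnot(inherits(field, "oh_concentration"), dt > 0)
  if (!is.null(mesh) && nrow(mesh$nodes) < max(field$nodes)) {
    rlang::abort("field does not belong to this mesh")
  }
  Mdt <- field$Mlump / dt
  b <- Mdt * field$n
  if (is.null(field$solver) || !identical(field$solver_dt, dt)) {
    A <- Matrix::Diagonal(x = Mdt) + field$D * field$K
    sol <- solve_constrained(A, b, field$fixed,
                             rep(field$n_max, length(field$fixed)))
    field$solver <- sol$factor
    field$solver_dt <- dt
  } else {
    sol <- solve_constrained(NULL, b, field$fixed,
                             rep(field$n_max, length(field$fixed)),
                             factor = field$solver)
  }
  n_new <- sol$x
  # bilinear quads are not strictly monotone: sharp boundary layers (small
  # dt*D relative to h^2) undershoot at the per-mille level and are
  # clamped; larger excursions signal a genuine loss of the maximum
  # principle (mesh / step misconfiguration)
  tol <- 5e-3 * field$n_max
  lo <- min(field$n)
  if (min(n_new) < lo - tol || max(n_new) > field$n_max + tol) {
    rlang::abort(paste0(
      "diffusion step violates the discrete maximum principle ",
      "(range ", signif(min(n_new), 4), " .. ", signif(max(n_new), 4),
      "); check mesh quality / step size"))
  }
  field$n <- pmin(pmax(n_new, lo), field$n_max)
  field$day <- field$day + dt
  field
}

#' Simulate the concentration history over a healing horizon
#'
#' @inheritParams concentration_field
#' @param days number of daily steps.
#' @return Tibble with `day`, `n_min`, `n_mean` over the sub-mesh, and the
#'   final field as attribute `"field"`.
#' @export
simulate_concentration <- function(mesh, D, days = 35, n_max = 1,
                                   region = "callus",
                                   dirichlet_nodes = NULL) {
  f <- concentration_field(mesh, D, n_max, region, dirichlet_nodes)
  out <- tibble::tibble(day = seq_len(days), n_min = NA_real_,
                        n_mean = NA_real_)
  for (d in seq_len(days)) {
    f <- advance_concentration(f, dt = 1)
    out$n_min[d] <- min(f$n)
    out$n_mean[d] <- mean(f$n)
  }
  attr(out, "field") <- f
  out
}

#' Calibrate the stem-cell diffusivity
#'
#' Finds the smallest diffusivity `D` (bisection to 1 % relative) for which
#' the minimum concentration over the callus reaches
#' `saturation_threshold * n_max` by `horizon_days` daily steps — the
#' calibration that makes the whole callus saturate at the end of the
#' healing period.
#'
#' @inheritParams simulate_concentration
#' @param horizon_days the healing horizon (days).
#' @param saturation_threshold saturation criterion as a fraction of
#'   `n_max`.
#' @param bounds search bracket for `D` (mm^2/day); the upper end is grown
#'   by doubling if needed.
#' @return The calibrated diffusivity (mm^2/day).
#' @export
calibrate_diffusivity <- function(mesh, horizon_days = 35,
                                  saturation_threshold = 0.99,
                                  n_max = 1, region = "callus",
                                  dirichlet_nodes = NULL,
                                  bounds = c(1e-4, 10)) {
  reaches <- function(D) {
    sim <- simulate_concentration(mesh, D, horizon_days, n_max, region,
                                  dirichlet_nodes)
    sim$n_min[horizon_days] >= saturation_threshold * n_max
  }
  lo <- bounds[1]
  hi <- bounds[2]
  if (reaches(lo)) {
    rlang::abort("lower diffusivity bound already saturates the callus")
  }
  tries <- 0
  while (!reaches(hi)) {
    hi <- hi * 2
    tries <- tries + 1
    if (tries > 20) {
      rlang::abort("failed to bracket the calibrated diffusivity")
    }
  }
  while ((hi - lo) / hi > 0.01) {
    mid <- sqrt(lo * hi)
    if (reaches(mid)) hi <- mid else lo <- mid
  }
  hi
}

#' First day the callus saturates
#'
#' @inheritParams simulate_concentration
#' @param saturation_threshold saturation criterion as a fraction of
#'   `n_max`.
#' @param max_days simulation horizon.
#' @return Integer day of first crossing (or `NA` if never within
#'   `max_days`).
#' @export
saturation_day <- function(mesh, D, saturation_threshold = 0.99,
                           n_max = 1, region = "callus",
                           dirichlet_nodes = NULL, max_days = 100) {
  sim <- simulate_concentration(mesh, D, max_days, n_max, region,
                                dirichlet_nodes)
  hit <- which(sim$n_min >= saturation_threshold * n_max)
  if (length(hit) == 0) NA_integer_ else hit[1]
}
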