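# Coulomb penalty contact at the implant-callus interface.
#
# The interface nodes are duplicated (implant-side copies). The two sides
# are joined by bilateral normal penalty springs (preventing
# interpenetration and mesh separation). Tangential interaction is imposed
# by equal-and-opposite pair forces q determined by a projected Newton
# iteration: sticking pairs drive their tangential slip to zero, and |q|
# is capped at mu * (compressive normal force), which is the Coulomb
# slider. The per-pair tangential compliances used by the Newton update
# are probed once from the factorized operator, so the system is
# factorized a single time per solve. Loading is monotone within a day, so
# total slip stands in for the slip rate (deformation-theory friction).

solve_contact <- function(mesh, materials, diri, drained_nodes, dt,
                          n_steps, interface) {
  n <- nrow(mesh$nodes)
  inodes <- mesh$boundaries$implant_callus_interface
  nd <- length(inodes)
  dup <- n + seq_len(nd)

  conn <- mesh_conn(mesh)
  imp <- mesh$elements$region == "implant"
  conn_ext <- conn
  remap <- seq_len(n)
  remap[inodes] <- dup
  conn_ext[imp, ] <- matrix(remap[conn[imp, ]], ncol = 4)
  coords_ext <- rbind(mesh_coords(mesh),
                      mesh_coords(mesh)[inodes, , drop = FALSE])
  n_ext <- n + nd

  mm <- materials[order(materials$element), ]
  poro <- !mm$is_solid_only
  k_mm <- ifelse(poro, perm_to_solver(mm$permeability), 0)
  tr <- .assemble_axisym(coords_ext, conn_ext, mm$young_modulus,
                         mm$poisson_ratio, k_mm, poro, TRUE)
  K <- Matrix::sparseMatrix(i = tr$Ki, j = tr$Kj, x = tr$Kx,
                            dims = c(2 * n_ext, 2 * n_ext))
  Qfull <- Matrix::sparseMatrix(i = tr$Qi, j = tr$Qj, x = tr$Qx,
                                dims = c(2 * n_ext, n_ext))
  Hfull <- Matrix::sparseMatrix(i = tr$Hi, j = tr$Hj, x = tr$Hx,
                                dims = c(n_ext, n_ext))
  pnodes <- sort(unique(as.vector(conn_ext[poro, , drop = FALSE])))
  Q <- Qfull[, pnodes, drop = FALSE]
  H <- Hfull[pnodes, pnodes, drop = FALSE]
  np <- length(pnodes)
  pmap <- match(seq_len(n), pnodes)

  # per-pair outward (from implant) normals and penalty weights
  edges <- mesh$interface
  tan_r <- (mesh$nodes$r[edges$to] - mesh$nodes$r[edges$from]) / edges$length
  tan_z <- (mesh$nodes$z[edges$to] - mesh$nodes$z[edges$from]) / edges$length
  acc_n <- matrix(0, nd, 2)
  acc_w <- numeric(nd)
  for (i in seq_len(nrow(edges))) {
    for (nodei in c(edges$from[i], edges$to[i])) {
      j <- match(nodei, inodes)
      acc_n[j, ] <- acc_n[j, ] + edges$length[i] * c(tan_z[i], -tan_r[i])
      acc_w[j] <- acc_w[j] + edges$length[i] / 2
    }
  }
  nlen <- sqrt(rowSums(acc_n^2))
  normals <- acc_n / pmax(nlen, 1e-30)
  tangents <- cbind(-normals[, 2], normals[, 1])
  wn <- interface$penalty_stiffness * acc_w *
    pmax(mesh$nodes$r[inodes], mesh$element_size_target / 4)

  # Dirichlet handling on the extended mesh: load-surface constraints on
  # interface nodes move to the implant-side copy; axis constraints apply
  # to both sides.
  H_top <- max(mesh$nodes$z)
  on_load <- diri$node %in% inodes & diri$dof == "z" &
    abs(mesh$nodes$z[diri$node] - H_top) < 1e-7 & diri$value != 0
  diri2 <- diri
  diri2$node[on_load] <- dup[match(diri$node[on_load], inodes)]
  on_axis <- diri$node %in% inodes & diri$dof == "r"
  if (any(on_axis)) {
    diri2 <- rbind(diri2, tibble::tibble(
      node = dup[match(diri$node[on_axis], inodes)],
      dof = "r", value = 0))
  }
  dof_u <- 2 * (diri2$node - 1) + ifelse(diri2$dof == "r", 1, 2)
  pfix <- 2 * n_ext + pmap[intersect(drained_nodes, pnodes)]
  fixed <- c(dof_u, pfix)

  odof_r <- 2 * inodes - 1
  odof_z <- 2 * inodes
  ddof_r <- 2 * dup - 1
  ddof_z <- 2 * dup
  # normal springs only; tangential action is by pair forces
  nn_rr <- wn * normals[, 1]^2
  nn_zz <- wn * normals[, 2]^2
  nn_rz <- wn * normals[, 1] * normals[, 2]
  ii <- c(odof_r, odof_z, ddof_r, ddof_z,
          odof_r, odof_z, ddof_r, ddof_z,
          odof_r, ddof_r, odof_z, ddof_z,
          odof_r, ddof_r, odof_z, ddof_z)
  jj <- c(odof_r, odof_z, ddof_r, ddof_z,
          odof_z, odof_r, ddof_z, ddof_r,
          ddof_r, odof_r, ddof_z, odof_z,
          ddof_z, odof_z, ddof_r, odof_r)
  xx <- c(nn_rr, nn_zz, nn_rr, nn_zz,
          nn_rz, nn_rz, nn_rz, nn_rz,
          -nn_rr, -nn_rr, -nn_zz, -nn_zz,
          -nn_rz, -nn_rz, -nn_rz, -nn_rz)
  Ks <- K + Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                                 dims = c(2 * n_ext, 2 * n_ext))
  A <- rbind(cbind(Ks, -Q), cbind(-Matrix::t(Q), -dt * H))
  ntot <- 2 * n_ext + np

  pair_force <- function(q) {
    f <- numeric(2 * n_ext)
    f[ddof_r] <- f[ddof_r] + q * tangents[, 1]
    f[ddof_z] <- f[ddof_z] + q * tangents[, 2]
    f[odof_r] <- f[odof_r] - q * tangents[, 1]
    f[odof_z] <- f[odof_z] - q * tangents[, 2]
    f
  }
  slip_of <- function(x) {
    rel_r <- x[ddof_r] - x[odof_r]
    rel_z <- x[ddof_z] - x[odof_z]
    list(slip = rel_r * tangents[, 1] + rel_z * tangents[, 2],
         gap = rel_r * normals[, 1] + rel_z * normals[, 2])
  }

  # factorize once, then probe the diagonal tangential compliances
  zero_fix <- rep(0, length(fixed))
  sol0 <- solve_constrained(A, numeric(ntot), fixed, zero_fix)
  factor <- sol0$factor
  comp <- numeric(nd)
  for (j in seq_len(nd)) {
    e <- numeric(nd)
    e[j] <- 1
    xj <- solve_constrained(A, c(pair_force(e), numeric(np)),
                            fixed, zero_fix, factor)$x
    comp[j] <- slip_of(xj)$slip[j]
  }
  # pairs whose tangential motion is fully constrained (e.g. the axis node
  # under the tip) cannot slide; they carry no slider force
  active <- comp > 1e-12 * max(comp)
  comp[!active] <- Inf

  mu <- interface$friction_coefficient
  u <- numeric(2 * n_ext)
  p <- numeric(np)
  q <- numeric(nd)
  u_scale <- max(abs(diri2$value), 1e-9)
  schedule <- seq_len(n_steps) / n_steps
  for (s in seq_len(n_steps)) {
    converged <- FALSE
    relax <- 1
    moved_prev <- Inf
    x_prev <- NULL
    for (it in seq_len(interface$max_iterations)) {
      b <- c(pair_force(q), -as.vector(Matrix::t(Q) %*% u))
      xfix <- c(diri2$value * schedule[s], rep(0, length(pfix)))
      sol <- solve_constrained(A, b, fixed, xfix, factor)
      x <- sol$x
      sg <- slip_of(x)
      # after a generous budget of full updates, freeze the Coulomb caps
      # (lag the normal force) so cap chattering at marginal-contact pairs
      # cannot block the contraction of the slip iteration
      if (it <= 40) {
        fn_comp <- pmax(0, -wn * sg$gap)
        cap <- mu * fn_comp
      }
      q_new <- pmin(pmax(q - relax * sg$slip / comp, -cap), cap)
      q_new[!active] <- 0
      stick <- (abs(q_new) < cap - 1e-30 | cap == 0) & active
      resid <- max(abs(sg$slip[stick & cap > 0]), 0) / u_scale
      moved <- max(abs(q_new - q)) /
        max(max(abs(q_new)), 1e-30)
      # damp when the force update stops contracting (cap-state cycling)
      if (moved > 0.7 * moved_prev) relax <- max(0.25, relax * 0.7)
      moved_prev <- moved
      q <- q_new
      # primary test: stick slips closed and slider forces settled;
      # secondary: the displacement field itself has stopped moving
      # (residual force chatter at near-zero normal force pairs does not
      # affect the reported fields)
      du <- if (is.null(x_prev)) Inf else
        max(abs(x[seq_len(2 * n_ext)] - x_prev)) / u_scale
      x_prev <- x[seq_len(2 * n_ext)]
      if ((resid < 1e-5 && moved < 1e-3 && it > 1) || du < 1e-6) {
        u <- x[seq_len(2 * n_ext)]
        p <- x[2 * n_ext + seq_len(np)]
        converged <- TRUE
        break
      }
    }
    if (!converged) {
      rlang::abort(paste0("contact iteration failed to converge in ",
                          interface$max_iterations, " iterations at step ",
                          s))
    }
  }
  p_out <- ifelse(is.na(pmap), NA_real_, p[pmap])
  structure(list(
    u = u[seq_len(2 * n)], u_ext = u, dup = dup, dup_of = inodes,
    p_full = p_out,
    pressure = tibble::tibble(node = seq_len(n), p = p_out),
    times = dt * seq_len(n_steps), u_hist = NULL, p_hist = NULL,
    axisym = TRUE), class = "oh_solution")
}
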