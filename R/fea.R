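#' Define a prescribed-displacement compression load case
#'
#' The stack is compressed by imposing a -z displacement of `magnitude` mm
#' on the loaded node set while the constrained set is held fixed,
#' emulating the fully constrained lower endplate of the lowest vertebra.
#' For the linear model the quasi-static staircase of `n_steps` equal
#' increments is recovered exactly by scaling a single solve.
#'
#' @param magnitude Prescribed compression in mm, positive.
#' @param n_steps Number of quasi-static load steps (default 10).
#' @param constrained,loaded Names of node sets in the mesh (defaults
#'   `"bottom"` and `"top"`).
#' @param constraint_mode `"fixed"` clamps all translations of the
#'   constrained set; `"rollers_z"` fixes only the axial component and pins
#'   two nodes minimally against in-plane rigid motion (the laterally
#'   unconstrained uniaxial variant).
#' @param loaded_mode `"uz_only"` prescribes only the axial displacement of
#'   the loaded set (lateral expansion free); `"fixed_lateral"` also clamps
#'   its in-plane motion.
#' @return An object of class `load_case`.
#' @export
load_case <- function(magnitude, n_steps = 10L, constrained = "bottom",
                      loaded = "top",
                      constraint_mode = c("fixed", "rollers_z"),
                      loaded_mode = c("uz_only", "fixed_lateral")) {
  if (magnitude <= 0) stop("magnitude must be positive")
  if (n_steps < 1L) stop("n_steps must be >= 1")
  structure(list(magnitude = magnitude, n_steps = as.integer(n_steps),
                 constrained = constrained, loaded = loaded,
                 constraint_mode = match.arg(constraint_mode),
                 loaded_mode = match.arg(loaded_mode)),
            class = "load_case")
}

# Elasticity matrices in Voigt order (xx, yy, zz, xy, yz, xz) with
# engineering shear strains: D = lambda * D_LAM + mu * D_MU.
D_LAM <- {
  m <- matrix(0, 6, 6); m[1:3, 1:3] <- 1; m
}
D_MU <- diag(c(2, 2, 2, 1, 1, 1))

#' Precompute element operators for a labeled tetrahedral mesh
#'
#' Builds, once per mesh, the per-element strain-displacement operators and
#' the four global stiffness components `K_lam_bone`, `K_mu_bone`,
#' `K_lam_disc`, `K_mu_disc`, so that the stiffness matrix for any material
#' pair is the sparse combination
#' `K = lambda_b K_lam_bone + mu_b K_mu_bone + lambda_d K_lam_disc + mu_d K_mu_disc`.
#' This makes material sweeps (dataset generation, calibration loops) cheap:
#' no re-assembly, only a sparse linear combination and one factorisation.
#'
#' Geometry is converted from mm to metres here; all solver quantities are
#' SI (m, Pa, N).
#'
#' @param mesh A `labeled_tet_mesh` (coordinates in mm).
#' @return An object of class `fea_operator` (cached inside the mesh-free
#'   solver path); users normally call [assemble_and_solve()] directly.
#' @export
precompute_operator <- function(mesh) {
  nodes <- mesh$nodes * 1e-3
  tets <- mesh$tets
  nel <- nrow(tets)
  vol <- tet_volumes(nodes, tets)
  if (any(vol <= 0)) stop("mesh error: non-positive tetrahedron volume")

  B <- array(0, dim = c(6L, 12L, nel))
  dofmat <- matrix(0L, 12L, nel)
  Ke_lam <- array(0, dim = c(12L, 12L, nel))
  Ke_mu <- array(0, dim = c(12L, 12L, nel))
  for (e in seq_len(nel)) {
    nd <- tets[e, ]
    X <- nodes[nd, , drop = FALSE]
    M <- X[2:4, ] - matrix(X[1, ], 3, 3, byrow = TRUE)
    G <- solve(M)                      # columns: grad N2, N3, N4
    grads <- cbind(-rowSums(G), G)     # 3 x 4, column i = grad N_i
    Be <- matrix(0, 6, 12)
    for (i in 1:4) {
      c0 <- 3 * (i - 1)
      g <- grads[, i]
      Be[1, c0 + 1] <- g[1]
      Be[2, c0 + 2] <- g[2]
      Be[3, c0 + 3] <- g[3]
      Be[4, c0 + 1] <- g[2]; Be[4, c0 + 2] <- g[1]
      Be[5, c0 + 2] <- g[3]; Be[5, c0 + 3] <- g[2]
      Be[6, c0 + 1] <- g[3]; Be[6, c0 + 3] <- g[1]
    }
    B[, , e] <- Be
    dofmat[, e] <- as.integer(rbind(3 * nd - 2, 3 * nd - 1, 3 * nd))
    Ke_lam[, , e] <- vol[e] * crossprod(Be, D_LAM %*% Be)
    Ke_mu[, , e] <- vol[e] * crossprod(Be, D_MU %*% Be)
  }

  ii <- dofmat[rep(1:12, times = 12), , drop = FALSE]
  jj <- dofmat[rep(1:12, each = 12), , drop = FALSE]
  part <- function(which_type, Ke) {
    sel <- mesh$region_type == which_type
    if (!any(sel)) return(NULL)
    Matrix::sparseMatrix(i = as.vector(ii[, sel]), j = as.vector(jj[, sel]),
                         x = as.vector(Ke[, , sel]),
                         dims = c(3L * nrow(nodes), 3L * nrow(nodes)))
  }
  structure(list(
    K_lam_bone = part("bone", Ke_lam), K_mu_bone = part("bone", Ke_mu),
    K_lam_disc = part("disc", Ke_lam), K_mu_disc = part("disc", Ke_mu),
    B = B, dofmat = dofmat, vol = vol, n_nodes = nrow(nodes),
    nodes_m = nodes
  ), class = "fea_operator")
}

# Prescribed DOFs and values for a load case; returns list(dofs, values,
# reaction_dofs) with reaction_dofs = axial dofs of the constrained set.
dirichlet_dofs <- function(mesh, load) {
  ns <- mesh$node_sets
  if (is.null(ns[[load$constrained]]) || is.null(ns[[load$loaded]]))
    stop("unknown node set in load case")
  cset <- ns[[load$constrained]]
  lset <- ns[[load$loaded]]
  if (length(cset) == 0L || length(lset) == 0L)
    stop("constrained and loaded sets must be non-empty")
  if (length(intersect(cset, lset)) > 0L)
    stop("constrained and loaded sets must be disjoint")
  u_mag <- -load$magnitude * 1e-3

  dofs <- integer(0); vals <- numeric(0)
  if (load$constraint_mode == "fixed") {
    dofs <- c(dofs, as.vector(rbind(3 * cset - 2, 3 * cset - 1, 3 * cset)))
    vals <- c(vals, numeric(3 * length(cset)))
  } else {
    dofs <- c(dofs, 3 * cset)
    vals <- c(vals, numeric(length(cset)))
    # 3-2-1 style pinning of the in-plane rigid modes
    xy <- mesh$nodes[cset, 1:2, drop = FALSE]
    cen <- colMeans(xy)
    pin1 <- cset[which.min((xy[, 1] - cen[1])^2 + (xy[, 2] - cen[2])^2)]
    pin2 <- cset[which.max(abs(mesh$nodes[cset, 1] - mesh$nodes[pin1, 1]))]
    dofs <- c(dofs, 3 * pin1 - 2, 3 * pin1 - 1, 3 * pin2 - 1)
    vals <- c(vals, 0, 0, 0)
  }
  if (load$loaded_mode == "fixed_lateral") {
    dofs <- c(dofs, as.vector(rbind(3 * lset - 2, 3 * lset - 1, 3 * lset)))
    vals <- c(vals, as.vector(rbind(numeric(length(lset)),
                                    numeric(length(lset)),
                                    rep(u_mag, length(lset)))))
  } else {
    dofs <- c(dofs, 3 * lset)
    vals <- c(vals, rep(u_mag, length(lset)))
  }
  keep <- !duplicated(dofs)
  list(dofs = dofs[keep], values = vals[keep],
       reaction_dofs = 3 * cset, loaded_zdofs = 3 * lset,
       cset = cset, lset = lset)
}

#' Assemble and solve the linear-elastic compression problem
#'
#' Linear four-node tetrahedron formulation with Dirichlet conditions
#' imposed exactly by partitioning. Both material regions are isotropic
#' linear elastic; the reduced system is symmetric positive definite and is
#' factorised with a sparse Cholesky decomposition. For the linear model
#' the quasi-static staircase is exact scaling: step `s` of `n_steps`
#' carries `s / n_steps` of the full solution (a per-step re-solve is
#' available with `rescale_steps = FALSE` for future nonlinear materials).
#'
#' @param mesh A `labeled_tet_mesh`.
#' @param mat A [material_properties()] object.
#' @param load A [load_case()].
#' @param op Optional precomputed [precompute_operator()] result for `mesh`
#'   (pass it when solving many material draws on the same mesh).
#' @param rescale_steps Scale one solve across steps (default) or re-solve
#'   every step.
#' @return An object of class `field_solution`: nodal displacements `u`
#'   (n x 3, metres) at the final step, per-element strain and stress in
#'   Voigt order (engineering shear strains), `F_ext` (N, total axial
#'   reaction transmitted to the constrained set, positive in compression),
#'   a per-step summary table, and the stored strain energy.
#' @export
assemble_and_solve <- function(mesh, mat, load, op = NULL,
                               rescale_steps = TRUE) {
  stopifnot(inherits(mat, "material_properties"), inherits(load, "load_case"))
  if (is.null(op)) op <- precompute_operator(mesh)
  lb <- lame_parameters(mat$E_bone, mat$nu_bone)
  ld <- lame_parameters(mat$E_disc, mat$nu_disc)
  K <- NULL
  addK <- function(K, M, a) if (is.null(M)) K else if (is.null(K)) a * M else K + a * M
  K <- addK(K, op$K_lam_bone, lb$lambda)
  K <- addK(K, op$K_mu_bone, lb$mu)
  K <- addK(K, op$K_lam_disc, ld$lambda)
  K <- addK(K, op$K_mu_disc, ld$mu)

  bc <- dirichlet_dofs(mesh, load)
  ndof <- 3L * op$n_nodes
  free <- setdiff(seq_len(ndof), bc$dofs)
  Kff <- K[free, free, drop = FALSE]
  rhs <- -K[free, bc$dofs, drop = FALSE] %*% bc$values
  uf <- tryCatch(
    as.vector(Matrix::solve(Kff, rhs, sparse = TRUE)),
    error = function(e)
      stop("singular reduced system (unconstrained rigid-body modes?): ",
           conditionMessage(e))
  )
  u <- numeric(ndof)
  u[free] <- uf
  u[bc$dofs] <- bc$values

  fr <- as.vector(K %*% u)            # nodal forces; nonzero only at Dirichlet dofs
  F_ext <- sum(fr[bc$reaction_dofs])  # axial reaction on the constrained set
  F_top <- sum(fr[bc$loaded_zdofs])

  U12 <- matrix(u[op$dofmat], nrow = 12L)
  eps <- sapply(seq_len(6L), function(r)
    colSums(matrix(op$B[r, , ], nrow = 12L) * U12))
  if (is.null(dim(eps))) eps <- matrix(eps, ncol = 6L)
  lam_e <- ifelse(mesh$region_type == "bone", lb$lambda, ld$lambda)
  mu_e <- ifelse(mesh$region_type == "bone", lb$mu, ld$mu)
  tr_eps <- rowSums(eps[, 1:3, drop = FALSE])
  sig <- cbind(lam_e * tr_eps + 2 * mu_e * eps[, 1],
               lam_e * tr_eps + 2 * mu_e * eps[, 2],
               lam_e * tr_eps + 2 * mu_e * eps[, 3],
               mu_e * eps[, 4], mu_e * eps[, 5], mu_e * eps[, 6])
  energy <- 0.5 * sum(op$vol * rowSums(sig * eps))

  steps <- seq_len(load$n_steps) / load$n_steps
  if (!rescale_steps) {
    # re-solve each step: identical up to solver round-off for the linear model
    Fs <- vapply(steps, function(s) {
      sub <- load; sub$magnitude <- load$magnitude * s
      sol <- assemble_and_solve(mesh, mat, structure(sub, class = "load_case"),
                                op = op, rescale_steps = TRUE)
      sol$F_ext
    }, numeric(1))
  } else {
    Fs <- F_ext * steps
  }
  step_table <- data.frame(step = seq_len(load$n_steps),
                           magnitude_mm = load$magnitude * steps,
                           F_ext_N = Fs)

  structure(list(
    u = matrix(u, ncol = 3L, byrow = TRUE),
    strain = eps, stress = sig,
    F_ext = F_ext, F_top = F_top,
    energy = energy, steps = step_table,
    load = load, mat = mat, bc = bc, vol = op$vol
  ), class = "field_solution")
}

#' @export
print.field_solution <- function(x, ...) {
  cat(sprintf("field_solution: F_ext = %.4g N at %.2f mm, energy = %.4g J\n",
              x$F_ext, x$load$magnitude, x$energy))
  invisible(x)
}

#' Extract the 16 mechanical-response features
#'
#' Condenses a solved field into the fixed 16-scalar response vector used
#' as network input: applied load `F_ext` (N); displacement `u_x, u_y, u_z`
#' (m) of the loaded-endplate centroid node (default) or the
#' volume-weighted mean nodal displacement; the three normal and three
#' independent shear stresses (Pa) and strains (dimensionless, tensor
#' shears) as volume-weighted element averages over the whole model.
#'
#' @param sol A [assemble_and_solve()] result (final load step).
#' @param mesh The mesh the solution was computed on.
#' @param aggregation `"centroid"` or `"volume_mean"` for the displacement
#'   components.
#' @return Named numeric vector of length 16 in the canonical column order
#'   `F_ext, u_x, u_y, u_z, sigma_x, sigma_y, sigma_z, sigma_xy, sigma_yz,
#'   sigma_xz, eps_x, eps_y, eps_z, eps_xy, eps_yz, eps_xz`.
#' @export
extract_features <- function(sol, mesh,
                             aggregation = c("centroid", "volume_mean")) {
  aggregation <- match.arg(aggregation)
  lset <- mesh$node_sets[[sol$load$loaded]]
  if (aggregation == "centroid") {
    xy <- mesh$nodes[lset, , drop = FALSE]
    cen <- colMeans(xy)
    node <- lset[which.min(rowSums(sweep(xy, 2, cen)^2))]
    uvec <- sol$u[node, ]
  } else {
    w <- node_volume_weights(mesh, sol$vol)
    uvec <- colSums(sol$u * w) / sum(w)
  }
  w <- sol$vol / sum(sol$vol)
  sbar <- colSums(sol$stress * w)
  ebar <- colSums(sol$strain * w)
  ebar[4:6] <- ebar[4:6] / 2   # engineering -> tensor shear strain
  out <- c(sol$F_ext, uvec, sbar, ebar)
  names(out) <- feature_names()
  out
}

node_volume_weights <- function(mesh, vol) {
  w <- numeric(nrow(mesh$nodes))
  for (j in 1:4) {
    t <- tapply(vol / 4, mesh$tets[, j], sum)
    w[as.integer(names(t))] <- w[as.integer(names(t))] + t
  }
  w
}

#' Canonical feature and target column names
#'
#' @return Character vector of the 16 feature names or the 10 target names
#'   (targets carry their unit suffix: bone moduli in GPa, disc moduli in
#'   MPa, densities in kg/m^3).
#' @export
feature_names <- function() {
  c("F_ext", "u_x", "u_y", "u_z",
    "sigma_x", "sigma_y", "sigma_z", "sigma_xy", "sigma_yz", "sigma_xz",
    "eps_x", "eps_y", "eps_z", "eps_xy", "eps_yz", "eps_xz")
}

#' @rdname feature_names
#' @export
target_names <- function() {
  c("E_bone_GPa", "E_disc_MPa", "nu_bone", "nu_disc",
    "k_bone_GPa", "k_disc_MPa", "mu_bone_GPa", "mu_disc_MPa",
    "rho_bone", "rho_disc")
}

# material_properties -> named 10-vector in natural column units
properties_to_targets <- function(mat) {
  out <- c(mat$E_bone / 1e9, mat$E_disc / 1e6, mat$nu_bone, mat$nu_disc,
           mat$k_bone / 1e9, mat$k_disc / 1e6, mat$mu_bone / 1e9,
           mat$mu_disc / 1e6, mat$rho_bone, mat$rho_disc)
  names(out) <- target_names()
  out
}

# named 10-vector (natural units) -> material_properties for re-simulation;
# nu outside the admissible open interval is clamped and reported
targets_to_properties <- function(x, clamp_log = NULL) {
  clamp <- function(v, lo, hi, nm) {
    if (v < lo || v > hi) {
      if (!is.null(clamp_log)) clamp_log(sprintf("%s clamped from %.4g", nm, v))
      v <- min(max(v, lo), hi)
    }
    v
  }
  E_b <- clamp(x[["E_bone_GPa"]], 1e-6, Inf, "E_bone") * 1e9
  E_d <- clamp(x[["E_disc_MPa"]], 1e-6, Inf, "E_disc") * 1e6
  nu_b <- clamp(x[["nu_bone"]], -0.95, 0.499, "nu_bone")
  nu_d <- clamp(x[["nu_disc"]], -0.95, 0.499, "nu_disc")
  rho_b <- clamp(x[["rho_bone"]], 1e-6, Inf, "rho_bone")
  rho_d <- clamp(x[["rho_disc"]], 1e-6, Inf, "rho_disc")
  material_properties(E_b, nu_b, E_d, nu_d, rho_b, rho_d)
}
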