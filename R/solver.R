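## P1 finite-element assembly and solution of the (non)linear
## Poisson-Boltzmann equation in dimensionless form u = e_c beta phi:
##
##   -div(eps grad u) - s_c sum_i z_i c_i exp(-z_i u) [solvent only]
##       = s_q sum_j q_j delta(r - r_j)
##
## with s_q = 4 pi k_e beta and s_c = s_q * (molar -> A^-3). Dirichlet
## values on the top/bottom (or all) box faces, optional lateral periodic
## folding of x/y faces, damped Newton for the ionic term, and the
## singular/harmonic/regular decomposition solver for cross-validation.

## 4-point tetrahedral quadrature (degree-2 exact), barycentric rows
.tet_quad <- list(
  lambda = {
    a <- 0.5854101966249685; b <- 0.1381966011250105
    rbind(c(a, b, b, b), c(b, a, b, b), c(b, b, a, b), c(b, b, b, a))
  },
  w = rep(0.25, 4))

## per-element P1 basis gradients and volumes
.grad_parts <- function(mesh) {
  v <- mesh$vertices; tt <- mesh$tets
  a <- v[tt[, 1], , drop = FALSE]
  B <- v[tt[, 2], , drop = FALSE] - a
  C <- v[tt[, 3], , drop = FALSE] - a
  D <- v[tt[, 4], , drop = FALSE] - a
  cross <- function(u, w) cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
                                u[, 3] * w[, 1] - u[, 1] * w[, 3],
                                u[, 1] * w[, 2] - u[, 2] * w[, 1])
  cxd <- cross(C, D); dxb <- cross(D, B); bxc <- cross(B, C)
  six_v <- rowSums(B * cxd)
  g2 <- cxd / six_v; g3 <- dxb / six_v; g4 <- bxc / six_v
  g1 <- -(g2 + g3 + g4)
  list(g = list(g1, g2, g3, g4), vol = six_v / 6)
}

#' Assemble the P1 stiffness matrix
#'
#' \eqn{A_{jl} = \int \epsilon \nabla\Phi_j \cdot \nabla\Phi_l} with an
#' elementwise-constant dielectric. Rows sum to zero before boundary
#' conditions; the matrix is symmetric.
#'
#' @param mesh a `pb_mesh`
#' @param eps either a scalar, or a per-tet vector, or a named vector of
#'   region dielectrics like `c(SOLUTE = 2, SOLVENT = 80, MEMBRANE = 2)`
#' @return a sparse symmetric matrix (`Matrix::dgCMatrix`)
#' @export
assemble_stiffness <- function(mesh, eps) {
  if (!is.null(names(eps))) eps <- unname(eps[mesh$region])
  if (length(eps) == 1) eps <- rep(eps, nrow(mesh$tets))
  if (anyNA(eps)) stop("missing dielectric for some region")
  gp <- .grad_parts(mesh)
  if (any(gp$vol <= 0)) stop("degenerate element: tet ",
                             which(gp$vol <= 0)[1])
  tt <- mesh$tets
  n <- nrow(mesh$vertices)
  m <- nrow(tt)
  ii <- integer(16 * m); jj <- integer(16 * m); xx <- numeric(16 * m)
  pos <- 0L
  for (k in 1:4) for (l in 1:4) {
    idx <- pos + seq_len(m)
    ii[idx] <- tt[, k]; jj[idx] <- tt[, l]
    xx[idx] <- eps * gp$vol * rowSums(gp$g[[k]] * gp$g[[l]])
    pos <- pos + m
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n))
}

## elementwise dielectric for a solve state
.eps_field <- function(mesh, params, state) {
  if (state == "REFERENCE") rep(params$eps_m, nrow(mesh$tets))
  else unname(c(SOLUTE = params$eps_m, SOLVENT = params$eps_s,
                MEMBRANE = params$eps_mem)[mesh$region])
}

#' Dirichlet boundary values (screened Coulomb superposition)
#'
#' \eqn{u(r) = \beta \sum_i k_e q_i e^{-\kappa d_i} / (\epsilon d_i)} with
#' \eqn{d_i = |r - r_i|}. The exterior dielectric and screening follow the
#' solve state: \eqn{\epsilon_s} and the Debye \eqn{\kappa} for the
#' solvated state, \eqn{\epsilon_m} and no screening for the reference
#' state (uniform dielectric, no ions). With `lateral_minimage`, distances
#' use the minimum-image convention in x/y so the data are covariant under
#' lattice translations of the molecule (used in periodic mode).
#'
#' @param mol a `pb_molecule`
#' @param params a `pb_params`
#' @param pts k x 3 evaluation points (must not coincide with atoms)
#' @param state `"SOLVATED"` or `"REFERENCE"`
#' @param box box list for the minimum-image convention
#' @param lateral_minimage logical
#' @return dimensionless potential values u at `pts`
#' @export
dirichlet_values <- function(mol, params, pts, state = "SOLVATED",
                             box = NULL, lateral_minimage = FALSE) {
  pts <- matrix(pts, ncol = 3)
  eps <- if (state == "REFERENCE") params$eps_m else params$eps_s
  kap <- if (state == "REFERENCE") 0 else params$kappa
  ke <- .pb_constants$k_coulomb
  L <- if (lateral_minimage) box$upper - box$lower else NULL
  u <- numeric(nrow(pts))
  for (a in seq_len(nrow(mol$positions))) {
    d <- sweep(pts, 2, mol$positions[a, ])
    if (lateral_minimage)
      for (k in 1:2) d[, k] <- d[, k] - L[k] * round(d[, k] / L[k])
    dist <- sqrt(rowSums(d^2))
    if (any(dist < 1e-9))
      stop("boundary point coincides with atom ", a)
    u <- u + params$beta * ke * mol$charges[a] * exp(-kap * dist) /
      (eps * dist)
  }
  u
}

## Dirichlet vertex set by boundary-condition mode
.dirichlet_vertices <- function(mesh, bc_mode) {
  if (is.null(mesh$boundary_faces)) stop("mesh has no boundary faces")
  mk <- mesh$boundary_marker
  keep <- if (is.null(mesh$box) || bc_mode == "dirichlet")
    mk != "INTERFACE"
  else mk %in% c("TOP", "BOTTOM")   # periodic: x/y faces are folded
  sort(unique(as.vector(mesh$boundary_faces[keep, , drop = FALSE])))
}

## Jacobi-preconditioned conjugate gradient for large SPD systems
.pcg <- function(A, b, tol = 1e-10, max_iter = 50000, x0 = NULL) {
  n <- length(b)
  d <- Matrix::diag(A)
  if (any(d <= 0)) stop("non-positive diagonal in PCG")
  x <- if (is.null(x0)) numeric(n) else x0
  r <- b - as.numeric(A %*% x)
  nb <- sqrt(sum(b^2))
  if (nb == 0) return(numeric(n))
  z <- r / d; p <- z; rz <- sum(r * z)
  for (it in seq_len(max_iter)) {
    Ap <- as.numeric(A %*% p)
    alpha <- rz / sum(p * Ap)
    x <- x + alpha * p
    r <- r - alpha * Ap
    if (sqrt(sum(r^2)) <= tol * nb) return(x)
    z <- r / d
    rz2 <- sum(r * z)
    p <- z + (rz2 / rz) * p
    rz <- rz2
  }
  stop("PCG did not converge: final relative residual ",
       signif(sqrt(sum(r^2)) / nb, 4))
}

## sparse SPD solve: supernodal Cholesky for moderate sizes (memory
## permitting), Jacobi-PCG beyond, with PCG as the universal fallback
.solve_sym <- function(A, b, tol = 1e-10) {
  if (nrow(A) <= 60000) {
    res <- tryCatch({
      ch <- Matrix::Cholesky(Matrix::forceSymmetric(A), LDL = FALSE,
                             super = TRUE)
      as.numeric(Matrix::solve(ch, b))
    }, error = function(e) NULL)
    if (!is.null(res)) return(res)
  }
  .pcg(A, b, tol = tol)
}

## ionic residual vector n_j(u) = s_c sum_i z_i c_i int_solv e^{-z_i u} Phi_j
.ionic_residual <- function(u, st, vol_s, species, s_c, n) {
  Q <- .tet_quad$lambda; w <- .tet_quad$w
  U4 <- matrix(u[st], ncol = 4)
  uq <- U4 %*% t(Q)                              # ms x 4 quadrature values
  S <- 0
  for (i in seq_len(nrow(species))) {
    z <- species$z[i]; c0 <- species$molar[i]
    S <- S + z * c0 * exp(pmin(-z * uq, 40))
  }
  contrib <- s_c * vol_s * (S %*% (w * Q))       # ms x 4, per-vertex slot
  out <- numeric(n)
  for (k in 1:4) {
    s <- rowsum(contrib[, k], st[, k])
    ids <- as.integer(rownames(s))
    out[ids] <- out[ids] + s[, 1]
  }
  out
}

## ionic Jacobian M(u)_{jl} = s_c sum_i z_i^2 c_i int_solv e^{-z_i u} Phi_j Phi_l
.ionic_jacobian <- function(u, st, vol_s, species, s_c, n) {
  Q <- .tet_quad$lambda; w <- .tet_quad$w
  U4 <- matrix(u[st], ncol = 4)
  uq <- U4 %*% t(Q)
  W <- 0
  for (i in seq_len(nrow(species))) {
    z <- species$z[i]; c0 <- species$molar[i]
    W <- W + z^2 * c0 * exp(pmin(-z * uq, 40))
  }
  ms <- nrow(st)
  ii <- integer(16 * ms); jj <- integer(16 * ms); xx <- numeric(16 * ms)
  pos <- 0L
  for (k in 1:4) for (l in 1:4) {
    idx <- pos + seq_len(ms)
    ii[idx] <- st[, k]; jj[idx] <- st[, l]
    xx[idx] <- s_c * vol_s * as.numeric(W %*% (w * Q[, k] * Q[, l]))
    pos <- pos + ms
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n))
}

.mesh_sig <- function(mesh)
  c(nrow(mesh$vertices), nrow(mesh$tets), sum(mesh$vertices), sum(mesh$tets))

#' Solve one dielectric state of the PB problem
#'
#' Core driver shared by the linear Poisson solves (reference state, or
#' solvated at zero ionic strength), the linearized PB operator and the
#' damped-Newton nonlinear PB solve. Most users want
#' [electrostatic_solvation()] instead.
#'
#' @param mesh labelled `pb_mesh`
#' @param mol `pb_molecule` (for boundary values and potential readout)
#' @param load per-vertex fixed-charge load in e units (see [charge_load()]),
#'   or NULL with `load_scaled` given
#' @param params a `pb_params`
#' @param state `"SOLVATED"` (region dielectrics, ions on) or
#'   `"REFERENCE"` (uniform `eps_m`, no ions)
#' @param bc_mode `"dirichlet"` or `"periodic"`
#' @param pmap a [build_periodic_map()] result (built on demand if NULL and
#'   `bc_mode = "periodic"`)
#' @param cfg a [newton_config()]
#' @param ionic `"auto"` (nonlinear Newton when the solvated state has
#'   ions), `"off"`, or `"linearized"` (Debye-Hueckel operator)
#' @param load_scaled optional per-vertex right-hand side already on the
#'   dimensionless scale (overrides `load`; used by the decomposition
#'   solver's surface source)
#' @return a `pb_solution`: nodal dimensionless potential `u`, the state,
#'   per-atom potentials `phi_atoms` in kcal/mol/e, and Newton iteration
#'   history if applicable
#' @export
solve_state <- function(mesh, mol, load, params, state = "SOLVATED",
                        bc_mode = "dirichlet", pmap = NULL,
                        cfg = newton_config(), ionic = "auto",
                        load_scaled = NULL) {
  stopifnot(state %in% c("SOLVATED", "REFERENCE"),
            bc_mode %in% c("dirichlet", "periodic"))
  n <- nrow(mesh$vertices)
  s_q <- 4 * pi * .pb_constants$k_coulomb * params$beta
  s_c <- s_q * .pb_constants$molar_to_A3
  b <- if (!is.null(load_scaled)) load_scaled else s_q * load

  A <- assemble_stiffness(mesh, .eps_field(mesh, params, state))

  use_ions <- state == "SOLVATED" && params$ionic_strength > 0 &&
    ionic != "off"
  if (use_ions) .check_electroneutral(params)

  ## boundary handling
  periodic <- bc_mode == "periodic"
  if (periodic && is.null(pmap)) pmap <- build_periodic_map(mesh)
  P <- if (periodic) .fold_matrix(pmap, n) else NULL
  dv <- .dirichlet_vertices(mesh, bc_mode)
  uD <- dirichlet_values(mol, params, mesh$vertices[dv, , drop = FALSE],
                         state, box = mesh$box, lateral_minimage = periodic)
  red <- function(vec) if (periodic) as.numeric(Matrix::crossprod(P, vec))
                       else vec
  redM <- function(M) if (periodic) Matrix::crossprod(P, M %*% P) else M
  dof_of <- if (periodic) pmap$reduced_dof else seq_len(n)
  nred <- if (periodic) pmap$n_reduced else n

  dir_red <- dof_of[dv]
  keep <- !duplicated(dir_red)
  dir_red <- dir_red[keep]; uD_red <- uD[keep]
  free <- setdiff(seq_len(nred), dir_red)

  full_of_red <- function(ur) {          # expand reduced -> full
    if (periodic) as.numeric(P %*% ur) else ur
  }
  Ar <- redM(A); br <- red(b)

  u_red <- numeric(nred)
  u_red[dir_red] <- uD_red
  iter_hist <- NULL

  solvent <- mesh$region == "SOLVENT"
  st <- mesh$tets[solvent, , drop = FALSE]
  vol_s <- tet_volumes(mesh)[solvent]

  if (!use_ions) {
    rhs <- br[free] - as.numeric(Ar[free, dir_red, drop = FALSE] %*% uD_red)
    u_red[free] <- .solve_sym(Ar[free, free], rhs)
  } else if (ionic == "linearized") {
    M0 <- .ionic_jacobian(numeric(n), st, vol_s, params$species, s_c, n)
    Kr <- redM(A + M0)
    rhs <- br[free] - as.numeric(Kr[free, dir_red, drop = FALSE] %*% uD_red)
    u_red[free] <- .solve_sym(Kr[free, free], rhs)
    Ar <- Kr
  } else {
    ## damped Newton
    resid <- function(ur) {
      uf <- full_of_red(ur)
      Fv <- as.numeric(A %*% uf) -
        .ionic_residual(uf, st, vol_s, params$species, s_c, n) - b
      red(Fv)
    }
    scale0 <- max(1, sqrt(sum(br[free]^2)))
    Fv <- resid(u_red)
    omega <- cfg$relaxation
    it <- 0
    iter_hist <- numeric(0)
    repeat {
      rnorm_ <- sqrt(sum(Fv[free]^2))
      iter_hist <- c(iter_hist, rnorm_)
      if (rnorm_ <= cfg$residual_tol * scale0) break
      if (it >= cfg$max_iter)
        stop("Newton did not converge in ", cfg$max_iter,
             " iterations; residual history: ",
             paste(signif(iter_hist, 4), collapse = " "))
      uf <- full_of_red(u_red)
      J <- A + .ionic_jacobian(uf, st, vol_s, params$species, s_c, n)
      Jr <- redM(J)
      delta <- numeric(nred)
      delta[free] <- .solve_sym(Jr[free, free], -Fv[free])
      ## damping with backtracking
      accepted <- FALSE
      for (try in 1:12) {
        u_try <- u_red + omega * delta
        F_try <- resid(u_try)
        if (sqrt(sum(F_try[free]^2)) < rnorm_) {
          u_red <- u_try; Fv <- F_try
          omega <- min(1, 2 * omega)
          accepted <- TRUE
          break
        }
        omega <- omega / 2
      }
      if (!accepted)
        stop("Newton line search failed at residual ", signif(rnorm_, 6))
      it <- it + 1
    }
  }

  u <- full_of_red(u_red)
  phi <- interpolate_nodal(mesh, u, mol$positions) / params$beta
  structure(list(u = u, state = state, phi_atoms = phi,
                 mesh_sig = .mesh_sig(mesh), newton_residuals = iter_hist),
            class = "pb_solution")
}

#' @export
print.pb_solution <- function(x, ...) {
  cat("pb_solution (", x$state, "): ", length(x$u), " nodal values, u in [",
      signif(min(x$u), 4), ", ", signif(max(x$u), 4), "]\n", sep = "")
  invisible(x)
}

#' Linear Poisson / Poisson-Boltzmann solve
#'
#' Convenience wrappers around [solve_state()]: `solve_linear` drops the
#' ionic term, `solve_pb_newton` runs the damped Newton iteration for the
#' full nonlinear equation, `solve_linearized` uses the Debye-Hueckel
#' (linearized) operator.
#'
#' @inheritParams solve_state
#' @return a `pb_solution`
#' @export
solve_linear <- function(mesh, mol, load, params, state = "SOLVATED",
                         bc_mode = "dirichlet", pmap = NULL)
  solve_state(mesh, mol, load, params, state, bc_mode, pmap, ionic = "off")

#' @rdname solve_linear
#' @export
solve_pb_newton <- function(mesh, mol, load, params,
                            cfg = newton_config(),
                            bc_mode = "dirichlet", pmap = NULL)
  solve_state(mesh, mol, load, params, "SOLVATED", bc_mode, pmap, cfg,
              ionic = "auto")

#' @rdname solve_linear
#' @export
solve_linearized <- function(mesh, mol, load, params,
                             bc_mode = "dirichlet", pmap = NULL)
  solve_state(mesh, mol, load, params, "SOLVATED", bc_mode, pmap,
              ionic = "linearized")
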