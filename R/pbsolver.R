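#' @include AllGenerics.R
NULL

# cubic B-spline weights for fractional offset t in [0,1): support 4 nodes
# at floor(u)-1 .. floor(u)+2; partition of unity by construction.
.bspline_w <- function(t) {
  cbind((1 - t)^3 / 6,
        (3 * t^3 - 6 * t^2 + 4) / 6,
        (-3 * t^3 + 3 * t^2 + 3 * t + 1) / 6,
        t^3 / 6)
}

.spread_indices <- function(xyz, origin, h, dims) {
  u <- sweep(xyz, 2, origin) / h        # grid units, 0-based
  i0 <- floor(u)
  t <- u - i0
  if (any(i0 < 1) || any(i0 > matrix(dims - 3, nrow(u), 3, byrow = TRUE)))
    stop("focusing/extent error: atom within 2 spacings of the grid boundary")
  list(i0 = i0, wx = .bspline_w(t[, 1]), wy = .bspline_w(t[, 2]),
       wz = .bspline_w(t[, 3]))
}

#' Spread point charges onto a grid with cubic B-splines
#'
#' Each charge is distributed over the nearest and next-nearest grid nodes
#' (a 4-point cubic B-spline stencil per axis); total grid charge equals
#' total atomic charge to machine precision.
#'
#' @param xyz n x 3 coordinates (Angstrom)
#' @param q charges (e)
#' @param origin,spacing,dims grid geometry (node \code{[1,1,1]} at origin)
#' @return 3-D array of node charges (e)
#' @export
spreadCharges <- function(xyz, q, origin, spacing, dims) {
  rho <- array(0, dims)
  if (!nrow(xyz)) return(rho)
  s <- .spread_indices(xyz, origin, spacing, dims)
  for (a in seq_len(nrow(xyz))) {
    if (q[a] == 0) next
    ix <- s$i0[a, 1] + (0:3); iy <- s$i0[a, 2] + (0:3); iz <- s$i0[a, 3] + (0:3)
    w <- outer(outer(s$wx[a, ], s$wy[a, ]), s$wz[a, ])
    rho[ix, iy, iz] <- rho[ix, iy, iz] + q[a] * w
  }
  rho
}

# potential at atom positions using the same B-spline weights as spreading
.interp_atoms <- function(phi, xyz, origin, h, dims) {
  s <- .spread_indices(xyz, origin, h, dims)
  vapply(seq_len(nrow(xyz)), function(a) {
    ix <- s$i0[a, 1] + (0:3); iy <- s$i0[a, 2] + (0:3); iz <- s$i0[a, 3] + (0:3)
    w <- outer(outer(s$wx[a, ], s$wy[a, ]), s$wz[a, ])
    sum(phi[ix, iy, iz] * w)
  }, 1)
}

# trilinear interpolation of a coarse solution at arbitrary points
# (vectorised: gathers the 8 cell corners with flat indices)
.interp_trilinear <- function(phi, origin, h, dims, pts) {
  u <- sweep(pts, 2, origin) / h
  i0 <- pmin(pmax(floor(u), 0), matrix(dims - 2, nrow(u), 3, byrow = TRUE))
  t <- u - i0
  nx <- dims[1]; nxy <- dims[1] * dims[2]
  base <- 1 + i0[, 1] + nx * i0[, 2] + nxy * i0[, 3]
  g <- function(dx, dy, dz) phi[base + dx + nx * dy + nxy * dz]
  tx <- t[, 1]; ty <- t[, 2]; tz <- t[, 3]
  c00 <- g(0, 0, 0) * (1 - tx) + g(1, 0, 0) * tx
  c10 <- g(0, 1, 0) * (1 - tx) + g(1, 1, 0) * tx
  c01 <- g(0, 0, 1) * (1 - tx) + g(1, 0, 1) * tx
  c11 <- g(0, 1, 1) * (1 - tx) + g(1, 1, 1) * tx
  c0 <- c00 * (1 - ty) + c10 * ty
  c1 <- c01 * (1 - ty) + c11 * ty
  c0 * (1 - tz) + c1 * tz
}

#' Edge-centred dielectric maps for a structure
#'
#' Solute dielectric inside the union of atom spheres, solvent outside,
#' with a cubic-spline transition of half-width \code{smoothWindow} across
#' the boundary.  Values are stored on the x-, y- and z-edges used by the
#' finite-difference stencil.
#'
#' @param xyz heavy-atom coordinates (n x 3)
#' @param radii cavity radii (A)
#' @param origin,spacing,dims grid geometry
#' @param epsIn,epsOut dielectric constants
#' @param smoothWindow spline half-width, A
#' @return list of three 3-D arrays \code{epsx, epsy, epsz}
#' @export
dielectricMap <- function(xyz, radii, origin, spacing, dims, epsIn = 1,
                          epsOut = 78.54, smoothWindow = 0.3) {
  e <- .edge_dielectric(as.matrix(xyz), as.numeric(radii),
                        as.numeric(origin), spacing, as.integer(dims),
                        epsIn, epsOut, smoothWindow)
  lapply(e, array, dim = dims)
}

# one focusing ladder for a fixed charge set; eps_maps NULL means uniform
# eps_in (the reference/homogeneous solve).  Returns phi at atoms plus the
# finest grid.
.pb_ladder <- function(xyz, q, radii, config, eps_uniform = NULL,
                       center = NULL) {
  dime <- config@dime
  dims <- rep(dime, 3L)
  if (is.null(center)) center <- colMeans(xyz)
  kappa <- 0
  if (config@ionicStrength > 0)  # Debye kappa in 1/A at 298 K
    kappa <- sqrt(config@ionicStrength / 0.0107) / 3.047
  prev <- NULL
  for (h in config@spacings) {
    origin <- center - (dime - 1) / 2 * h
    rho <- spreadCharges(xyz, q, origin, h, dims)
    src <- as.numeric(4 * pi * KE_COULOMB * rho / h)
    if (is.null(eps_uniform)) {
      em <- dielectricMap(xyz, radii, origin, h, dims, config@epsIn,
                          config@epsOut, config@smoothWindow)
      bc_eps <- config@epsOut
    } else {
      em <- NULL
      bc_eps <- eps_uniform
    }
    phi <- array(0, dims)
    if (!is.null(prev)) {
      # initialise interior and boundary from the coarser solution
      nodes <- as.matrix(expand.grid(x = origin[1] + h * (0:(dime - 1)),
                                     y = origin[2] + h * (0:(dime - 1)),
                                     z = origin[3] + h * (0:(dime - 1))))
      phi <- array(.interp_trilinear(prev$phi, prev$origin, prev$h,
                                     dims, nodes), dims)
    }
    phi <- array(.coulomb_boundary(as.numeric(phi), as.integer(dims),
                                   as.numeric(origin), h, as.matrix(xyz),
                                   as.numeric(q), KE_COULOMB, bc_eps,
                                   if (is.null(eps_uniform)) kappa else 0),
                 dims)
    kap2 <- numeric(length(phi))
    if (kappa > 0 && is.null(eps_uniform)) {
      solv <- as.numeric(em$epsx) > (config@epsIn + config@epsOut) / 2
      kap2[solv] <- config@epsOut * kappa^2 * h^2
    }
    omega <- 2 / (1 + sin(pi / dime))
    if (is.null(em)) {
      u <- rep(eps_uniform, length(phi))
      res <- .sor_solve(as.numeric(phi), as.integer(dims), u, u, u,
                        src, kap2, omega, config@tol, config@maxit)
    } else {
      res <- .sor_solve(as.numeric(phi), as.integer(dims),
                        as.numeric(em$epsx), as.numeric(em$epsy),
                        as.numeric(em$epsz), src, kap2, omega,
                        config@tol, config@maxit)
    }
    if (!res$converged)
      stop(sprintf("PB solver did not converge (relative residual %.2e)",
                   res$residual))
    prev <- list(phi = array(res$phi, dims), origin = origin, h = h,
                 iterations = res$iterations)
  }
  phiAtoms <- .interp_atoms(prev$phi, xyz, prev$origin, prev$h, dims)
  list(phi = prev$phi, origin = prev$origin, h = prev$h,
       phiAtoms = phiAtoms, iterations = prev$iterations)
}

#' Electrostatic solvation free energy by finite-difference LPBE
#'
#' Successive-focusing finite-difference solution of the (linearized)
#' Poisson-Boltzmann equation.  The outermost grid takes analytic
#' Debye-Hueckel/Coulombic boundary values; each finer grid is focused with
#' boundary values interpolated from the coarser solution.  The grid
#' self-energy is removed by a matched homogeneous reference solve
#' (\code{epsOut = epsIn} on identical grids), so
#' \deqn{G^{elec}_{solv} = \tfrac12 \sum_j q_j\,[\phi_{solv}(r_j) -
#'   \phi_{ref}(r_j)].}
#'
#' @param xyz n x 3 coordinates, or a \code{PDBStructure} (heavy atoms used
#'   for the cavity, all charged atoms as sources)
#' @param q per-atom charges (e); taken from \code{params} for structures
#' @param radii per-atom PB cavity radii (A)
#' @param config a \code{\link{pbConfig}}
#' @param params \code{ParameterSet} used when \code{xyz} is a structure
#' @param center optional grid centre (defaults to the charge centroid);
#'   pass a common centre when differencing solves across systems
#' @return list with \code{Gsolv} (kcal/mol), \code{potential}
#'   (finest-focus \code{PotentialGrid} of the solvated solve),
#'   \code{phiAtoms} (reaction-field potential at the charge sites,
#'   kcal/mol/e) and \code{iterations}
#' @export
solveLPBE <- function(xyz, q = NULL, radii = NULL, config = pbConfig(),
                      params = NULL, center = NULL) {
  if (is(xyz, "PDBStructure")) {
    stopifnot(!is.null(params))
    p <- attachParameters(xyz, params)
    q <- p$charge
    radii <- p$pb_radius
    xyz <- coords(xyz)
  }
  if (!is.matrix(xyz)) xyz <- matrix(xyz, ncol = 3)
  if (all(q == 0))
    return(list(Gsolv = 0,
                potential = new("PotentialGrid", origin = c(0, 0, 0),
                                spacing = config@spacings[length(config@spacings)],
                                values = array(0, rep(config@dime, 3))),
                phiAtoms = rep(0, nrow(xyz)), iterations = 0L))
  if (is.null(center)) center <- colMeans(xyz)
  solv <- .pb_ladder(xyz, q, radii, config, eps_uniform = NULL,
                     center = center)
  ref <- .pb_ladder(xyz, q, radii, config, eps_uniform = config@epsIn,
                    center = center)
  rf <- solv$phiAtoms - ref$phiAtoms
  list(Gsolv = 0.5 * sum(q * rf),
       potential = new("PotentialGrid", origin = solv$origin,
                       spacing = solv$h, values = solv$phi),
       phiAtoms = rf, iterations = solv$iterations)
}

#' Nonpolar solvation free energy from surface area
#'
#' \eqn{\gamma \cdot SASA / 1000} kcal/mol with \eqn{\gamma} in
#' cal/mol/A^2 (default 8).
#' @param sasa solvent-accessible surface area, A^2 (>= 0)
#' @param gamma surface-tension coefficient, cal/mol/A^2
#' @return kcal/mol
#' @export
nonpolarSolvation <- function(sasa, gamma = 8) {
  if (any(sasa < 0)) stop("negative SASA")
  gamma * sasa / 1000
}

#' Per-residue electrostatic solvation contributions
#'
#' For each residue \eqn{i}, the reaction-field potential sourced only by
#' residue \eqn{i}'s charges is computed on the same dielectric maps as the
#' full solve, and the contribution is
#' \eqn{\tfrac12 \sum_{all\,charges} q\,\phi_{(i)}(r)}.  The 1/2 factor
#' makes the contributions sum exactly (by LPBE linearity) to the total
#' electrostatic solvation energy.
#'
#' @param x a \code{PDBStructure}
#' @param params a \code{ParameterSet}
#' @param config a \code{\link{pbConfig}}
#' @param residues optional subset of residue keys (default all)
#' @param center optional common grid centre
#' @return named numeric vector of contributions (kcal/mol) per residue
#' @export
residueSolvation <- function(x, params, config = pbConfig(),
                             residues = NULL, center = NULL) {
  p <- attachParameters(x, params)
  xyz <- coords(x)
  ridx <- residueIndex(x)
  keys <- residueKeys(x)
  if (is.null(residues)) residues <- keys
  unknown <- setdiff(residues, keys)
  if (length(unknown)) stop("unknown residue(s): ", paste(unknown, collapse = ", "))
  if (is.null(center)) center <- colMeans(xyz)
  out <- setNames(numeric(length(residues)), residues)
  for (k in residues) {
    m <- ridx == match(k, keys)
    qi <- ifelse(m, p$charge, 0)
    if (all(qi == 0)) next
    solv <- .pb_ladder(xyz, qi, p$pb_radius, config, NULL, center)
    ref <- .pb_ladder(xyz, qi, p$pb_radius, config, config@epsIn, center)
    rf <- solv$phiAtoms - ref$phiAtoms
    out[k] <- 0.5 * sum(p$charge * rf)
  }
  out
}

#' Write a scalar grid in OpenDX format
#' @param grid a \code{ScalarGrid}
#' @param file output path
#' @export
writeOpenDX <- function(grid, file) {
  d <- dim(grid@values)
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("object 1 class gridpositions counts %d %d %d", d[1], d[2], d[3]),
    sprintf("origin %g %g %g", grid@origin[1], grid@origin[2], grid@origin[3]),
    sprintf("delta %g 0 0", grid@spacing),
    sprintf("delta 0 %g 0", grid@spacing),
    sprintf("delta 0 0 %g", grid@spacing),
    sprintf("object 2 class gridconnections counts %d %d %d", d[1], d[2], d[3]),
    sprintf("object 3 class array type double rank 0 items %d data follows",
            prod(d))), con)
  # OpenDX order: z fastest
  v <- aperm(grid@values, c(3, 2, 1))
  writeLines(apply(matrix(c(as.numeric(v),
                            rep(NA, (3 - prod(d) %% 3) %% 3)),
                          nrow = 3),
                   2, function(r) paste(r[!is.na(r)], collapse = " ")), con)
  writeLines('attribute "dep" string "positions"', con)
  invisible(file)
}
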