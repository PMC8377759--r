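#' @useDynLib fdpb, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

# Physical constants. The electrostatic coupling constant is derived at run
# time from fundamentals rather than hard-coded: e^2 / (4 pi eps0 * 1 A)
# converted to kcal/mol, divided by kT = R_gas * T.
.const <- list(
  R_gas = 1.9872e-3,        # kcal / (mol K)
  e_C = 1.602176634e-19,    # C
  eps0 = 8.8541878128e-12,  # F / m
  N_A = 6.02214076e23,
  J_per_kcal = 4184
)

# kcal/mol for two unit charges 1 A apart in vacuum (~332.06)
coulomb_kcal_A <- function() {
  with(.const, e_C^2 / (4 * pi * eps0 * 1e-10) * N_A / J_per_kcal)
}

# Coupling constant in kT * A / e^2 at temperature T (~557 at 300 K)
celec <- function(temperature = 300) {
  coulomb_kcal_A() / (.const$R_gas * temperature)
}

# Bulk kappa^2 in A^-2 for a 1:1 salt: 8 pi * celec * I / eps_out with the
# ionic strength I in particles / A^3.
kappa2_bulk <- function(salt, eps_out, temperature = 300) {
  if (salt < 0) stop("salt concentration must be >= 0")
  n_A3 <- salt * .const$N_A / 1e27
  8 * pi * celec(temperature) * n_A3 / eps_out
}

#' Poisson-Boltzmann solver configuration
#'
#' Defaults follow the study parameterization: 2.0 grid points per Angstrom
#' (0.5 A spacing), solute/solvent dielectrics 2.0/80.0, probe radius 1.4 A,
#' 0.15 M salt, 300 K, dipole-level ("dipolar") or per-atom Debye-Hueckel
#' boundary conditions. The Stern ion-exclusion layer (2.0 A) and the solver
#' tolerances are standard continuum-electrostatics practice.
#'
#' @param spacing grid spacing, Angstrom.
#' @param eps_in,eps_out relative dielectrics of solute interior and solvent.
#' @param salt 1:1 salt concentration, mol/L.
#' @param probe_radius solvent probe used to inflate atom spheres when
#'   building the dielectric map, Angstrom.
#' @param stern ion-exclusion layer thickness, Angstrom.
#' @param temperature Kelvin.
#' @param boundary `"atom"` (per-atom Debye-Hueckel sum, default),
#'   `"dipolar"` (monopole + dipole only) or `"zero"`.
#' @param mode `"linear"` (default) or `"nonlinear"` (full sinh term via
#'   under-relaxed Picard iteration).
#' @param tol convergence tolerance: maximum relative potential change per
#'   sweep.
#' @param maxit maximum SOR sweeps.
#' @param omega over-relaxation factor; `NULL` picks 2/(1+sin(pi/N)).
#' @param padding grid padding beyond the solute bounding box, Angstrom.
#' @param max_dim largest permitted grid dimension.
#' @param spreading charge-assignment scheme: `"tsc"` (quadratic B-spline
#'   over 27 nodes, default) or `"cic"` (trilinear over 8 nodes).
#' @return A `pbe_config` list.
#' @export
pbe_config <- function(spacing = 0.5, eps_in = 2.0, eps_out = 80.0,
                       salt = 0.15, probe_radius = 1.4, stern = 2.0,
                       temperature = 300, boundary = c("atom", "dipolar", "zero"),
                       mode = c("linear", "nonlinear"), tol = 1e-8,
                       maxit = 5000, omega = NULL, padding = 10,
                       max_dim = 301, spreading = c("tsc", "cic")) {
  stopifnot(spacing > 0, eps_in > 0, eps_out > 0, salt >= 0, tol > 0,
            maxit >= 1, probe_radius >= 0, stern >= 0, temperature > 0)
  structure(list(spacing = spacing, eps_in = eps_in, eps_out = eps_out,
                 salt = salt, probe_radius = probe_radius, stern = stern,
                 temperature = temperature, boundary = match.arg(boundary),
                 mode = match.arg(mode), tol = tol, maxit = maxit,
                 omega = omega, padding = padding, max_dim = max_dim,
                 spreading = match.arg(spreading)),
            class = "pbe_config")
}

#' @export
print.pbe_config <- function(x, ...) {
  cat(sprintf(paste0("pbe_config: spacing %.2f A (%.1f grids/A), eps %g/%g, ",
                     "salt %.3g M, probe %.2f A, stern %.1f A, T %g K\n"),
              x$spacing, 1 / x$spacing, x$eps_in, x$eps_out, x$salt,
              x$probe_radius, x$stern, x$temperature))
  cat(sprintf("  boundary %s, mode %s, tol %g, maxit %d\n",
              x$boundary, x$mode, x$tol, x$maxit))
  invisible(x)
}

#' Build a regular grid enclosing a structure
#'
#' The grid covers every atom sphere plus `padding` on all sides; dimensions
#' are rounded up to odd values so a center node exists, and the box is
#' centered on the solute.
#'
#' @param structure a [pqr_structure()].
#' @param spacing grid spacing, Angstrom.
#' @param padding clearance beyond the atom spheres, Angstrom (>= 5).
#' @param max_dim resource cap on each dimension.
#' @return A `grid_spec` with `origin`, `spacing`, `dims`.
#' @export
build_grid <- function(structure, spacing = 0.5, padding = 10,
                       max_dim = 301) {
  a <- structure$atoms
  if (!nrow(a)) stop("cannot build a grid around an empty structure")
  if (padding < 5) stop("padding must be >= 5 A")
  lo <- c(min(a$x - a$radius), min(a$y - a$radius), min(a$z - a$radius)) - padding
  hi <- c(max(a$x + a$radius), max(a$y + a$radius), max(a$z + a$radius)) + padding
  extent <- hi - lo
  dims <- ceiling(extent / spacing) + 1L
  dims <- ifelse(dims %% 2 == 0, dims + 1L, dims)
  dims <- pmax(dims, 9L)
  if (any(dims > max_dim))
    stop(sprintf("grid of %d x %d x %d nodes exceeds the cap of %d; use a coarser spacing",
                 dims[1], dims[2], dims[3], max_dim))
  center <- (lo + hi) / 2
  origin <- center - (dims - 1L) / 2 * spacing
  bbox <- extent - 2 * padding  # solute bounding box incl. atom radii
  structure(list(origin = origin, spacing = spacing, dims = as.integer(dims),
                 fill_ratio = max(bbox) / (max(dims - 1L) * spacing)),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("grid_spec: %d x %d x %d nodes, spacing %.3f A, origin (%.2f, %.2f, %.2f)\n",
              x$dims[1], x$dims[2], x$dims[3], x$spacing,
              x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

grid_axes <- function(grid) {
  lapply(1:3, function(d) grid$origin[d] + grid$spacing * (seq_len(grid$dims[d]) - 1))
}

atom_xyz <- function(structure) {
  as.matrix(structure$atoms[, c("x", "y", "z"), drop = FALSE])
}

#' Edge-based dielectric map
#'
#' Assigns `eps_in` to grid edges whose midpoint falls inside any
#' probe-inflated atom sphere (radius + probe), `eps_out` elsewhere: a
#' van-der-Waals-union approximation of the molecular surface (no reentrant
#' surface). With no atoms the map is uniform `eps_out`.
#'
#' @param structure a [pqr_structure()] (may be empty).
#' @param grid a `grid_spec`.
#' @param config a [pbe_config()].
#' @return List of three arrays `ex`, `ey`, `ez` (edge dielectrics).
#' @export
map_dielectric <- function(structure, grid, config = pbe_config()) {
  m <- cpp_dielectric_maps(grid$origin, grid$spacing, grid$dims,
                           atom_xyz(structure), structure$atoms$radius,
                           config$probe_radius, config$eps_in, config$eps_out)
  d <- grid$dims
  dim(m$ex) <- c(d[1] - 1L, d[2], d[3])
  dim(m$ey) <- c(d[1], d[2] - 1L, d[3])
  dim(m$ez) <- c(d[1], d[2], d[3] - 1L)
  m
}

#' Node-based ion-screening map
#'
#' kappa^2 (A^-2) is the bulk Debye-Hueckel value outside the solute and zero
#' at nodes inside any atom sphere inflated by the Stern layer. With
#' `salt = 0` the map is identically zero.
#'
#' @inheritParams map_dielectric
#' @return 3-D array of kappa^2 values.
#' @export
map_kappa <- function(structure, grid, config = pbe_config()) {
  k2 <- kappa2_bulk(config$salt, config$eps_out, config$temperature)
  m <- cpp_kappa_map(grid$origin, grid$spacing, grid$dims,
                     atom_xyz(structure), structure$atoms$radius,
                     config$stern, k2)
  dim(m) <- grid$dims
  m
}

boundary_node_coords <- function(grid) {
  d <- grid$dims
  ax <- grid_axes(grid)
  idx <- expand.grid(i = seq_len(d[1]), j = seq_len(d[2]), k = seq_len(d[3]))
  onb <- idx$i == 1 | idx$i == d[1] | idx$j == 1 | idx$j == d[2] |
    idx$k == 1 | idx$k == d[3]
  idx <- idx[onb, ]
  cbind(ax[[1]][idx$i], ax[[2]][idx$j], ax[[3]][idx$k])
}

#' Boundary potential on the grid faces
#'
#' `"atom"` mode sums screened Coulomb contributions of every atom at each
#' face node; `"dipolar"` keeps only the solute's monopole and dipole (about
#' the mean atom position) under Debye-Hueckel screening; `"zero"` imposes
#' zero. Values are in kT/e.
#'
#' @inheritParams map_dielectric
#' @return 3-D array, zero in the interior, boundary faces filled.
#' @export
boundary_potential <- function(structure, grid, config = pbe_config()) {
  d <- grid$dims
  mode <- config$boundary
  kap <- sqrt(kappa2_bulk(config$salt, config$eps_out, config$temperature))
  ce <- celec(config$temperature)
  if (mode == "zero" || nrow(structure$atoms) == 0)
    return(array(0, dim = d))
  if (mode == "atom") {
    u <- cpp_boundary_peratom(grid$origin, grid$spacing, d,
                              atom_xyz(structure), structure$atoms$charge,
                              kap, config$eps_out, ce)
    dim(u) <- d
    return(u)
  }
  # dipolar: monopole + dipole about the mean atom position
  a <- structure$atoms
  ref <- c(mean(a$x), mean(a$y), mean(a$z))
  Q <- sum(a$charge)
  p <- c(sum(a$charge * (a$x - ref[1])), sum(a$charge * (a$y - ref[2])),
         sum(a$charge * (a$z - ref[3])))
  u <- array(0, dim = d)
  bc <- boundary_node_coords(grid)
  rv <- sweep(bc, 2, ref)
  r <- pmax(sqrt(rowSums(rv^2)), 1e-6)
  phi <- ce / config$eps_out *
    (Q * exp(-kap * r) / r +
       (rv %*% p)[, 1] / r^3 * (1 + kap * r) * exp(-kap * r))
  # boundary_node_coords enumerates boundary nodes in ascending column-major
  # order, matching which(mask)
  mask <- array(FALSE, d)
  mask[1, , ] <- TRUE; mask[d[1], , ] <- TRUE
  mask[, 1, ] <- TRUE; mask[, d[2], ] <- TRUE
  mask[, , 1] <- TRUE; mask[, , d[3]] <- TRUE
  u[which(mask)] <- phi
  u
}

# Spread atom partial charges to grid nodes and return the SOR source array
# b = 4 pi celec q / h. "tsc" (triangular-shaped cloud, quadratic B-spline
# over 3 nodes per dimension) is the default: it roughly halves the
# near-source lattice-anisotropy error relative to plain trilinear ("cic")
# assignment, which is kept as an option.
spread_charges <- function(structure, grid, config) {
  d <- grid$dims
  b <- array(0, dim = d)
  a <- structure$atoms
  if (!nrow(a)) return(b)
  h <- grid$spacing
  f <- sweep(atom_xyz(structure), 2, grid$origin) / h  # fractional indices
  scale <- 4 * pi * celec(config$temperature) / h
  tsc <- identical(config$spreading, "tsc")
  guard <- if (tsc) 2 else 1
  if (any(f < guard) || any(f[, 1] > d[1] - 1 - guard) ||
      any(f[, 2] > d[2] - 1 - guard) || any(f[, 3] > d[3] - 1 - guard))
    stop("charged atom too close to the grid boundary; increase padding")
  for (n in seq_len(nrow(a))) {
    if (a$charge[n] == 0) next
    if (tsc) {
      nn <- round(f[n, ])
      t <- f[n, ] - nn
      wx <- rbind(0.5 * (0.5 - t)^2, 0.75 - t^2, 0.5 * (0.5 + t)^2)
      for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
        wt <- wx[dx + 2, 1] * wx[dy + 2, 2] * wx[dz + 2, 3]
        i <- nn[1] + 1 + dx; j <- nn[2] + 1 + dy; k <- nn[3] + 1 + dz
        b[i, j, k] <- b[i, j, k] + wt * scale * a$charge[n]
      }
    } else {
      i0 <- floor(f[n, ])
      w <- f[n, ] - i0
      for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
        wt <- (if (dx) w[1] else 1 - w[1]) *
          (if (dy) w[2] else 1 - w[2]) *
          (if (dz) w[3] else 1 - w[3])
        if (wt == 0) next
        i <- i0[1] + 1 + dx; j <- i0[2] + 1 + dy; k <- i0[3] + 1 + dz
        b[i, j, k] <- b[i, j, k] + wt * scale * a$charge[n]
      }
    }
  }
  b
}

#' Solve the Poisson-Boltzmann equation by finite differences
#'
#' Seven-point-stencil successive over-relaxation on the linearized PBE
#' (default), with charges spread trilinearly to grid nodes, edge-harmonic
#' dielectric boundaries handled by the edge-based dielectric map, and
#' Dirichlet boundary values from [boundary_potential()]. `mode =
#' "nonlinear"` wraps the linear solve in an under-relaxed Picard iteration
#' on the sinh screening term. Potentials are in kT/e.
#'
#' @param structure the charged structure (source of the field).
#' @param grid a `grid_spec`; `NULL` builds one from `config`.
#' @param config a [pbe_config()].
#' @param cavity optional uncharged [pqr_structure()] whose atoms contribute
#'   to the dielectric/ion-exclusion maps but carry no source charge (e.g. a
#'   probe molecule's cavity).
#' @return A `potential_grid`: `phi` (3-D array, kT/e), grid metadata, and a
#'   convergence report (`iterations`, `residual`, `history`).
#' @export
solve_pbe <- function(structure, grid = NULL, config = pbe_config(),
                      cavity = NULL) {
  if (is.null(grid)) {
    solute <- if (is.null(cavity)) structure else combine_structures(structure, cavity)
    grid <- build_grid(solute, config$spacing, config$padding, config$max_dim)
  }
  mapsrc <- if (is.null(cavity)) structure else combine_structures(structure, cavity)
  eps <- map_dielectric(mapsrc, grid, config)
  kap2 <- map_kappa(mapsrc, grid, config)
  u0 <- boundary_potential(structure, grid, config)
  b <- spread_charges(structure, grid, config)
  omega <- config$omega
  if (is.null(omega)) omega <- 2 / (1 + sin(pi / max(grid$dims)))
  run_linear <- function(bsrc, ustart) {
    cpp_sor(ustart, eps$ex, eps$ey, eps$ez, as.numeric(kap2),
            config$eps_out, grid$spacing, as.numeric(bsrc), omega,
            config$tol, config$maxit)
  }
  if (config$mode == "linear") {
    res <- run_linear(b, u0)
    conv <- list(iterations = res$iterations, residual = res$residual,
                 history = res$history, mode = "linear")
    u <- res$u
    if (!res$converged)
      stop(structure(class = c("fdpb_convergence_error", "error", "condition"),
                     list(message = sprintf(
                       "PBE solver did not converge in %d sweeps (residual %.3g)",
                       res$iterations, res$residual),
                       call = sys.call(), history = res$history)))
  } else {
    # Picard on the sinh term: keep the linear part implicit, move the
    # remainder eps_out * kappa2 * (sinh(u) - u) * h^2 to the source.
    h2 <- grid$spacing^2
    u <- u0
    alpha <- 0.5
    total_it <- 0L
    hist <- numeric()
    for (outer in 1:40) {
      uc <- pmin(pmax(u, -30), 30)
      b_nl <- b - config$eps_out * as.numeric(kap2) * (sinh(uc) - uc) * h2
      dim(b_nl) <- grid$dims
      res <- run_linear(b_nl, u)
      unew <- (1 - alpha) * u + alpha * res$u
      change <- max(abs(unew - u)) / max(max(abs(unew)), 1e-12)
      u <- unew
      total_it <- total_it + res$iterations
      hist <- c(hist, change)
      if (change < 10 * config$tol) break
    }
    conv <- list(iterations = total_it, residual = hist[length(hist)],
                 history = hist, mode = "nonlinear", picard_iterations = outer)
  }
  structure(list(phi = u, origin = grid$origin, spacing = grid$spacing,
                 dims = grid$dims, convergence = conv, config = config),
            class = "potential_grid")
}

#' @export
print.potential_grid <- function(x, ...) {
  cat(sprintf("potential_grid: %d x %d x %d nodes, spacing %.3f A\n",
              x$dims[1], x$dims[2], x$dims[3], x$spacing))
  cat(sprintf("  phi range [%.4g, %.4g] kT/e; %s solve, %d sweeps, residual %.3g\n",
              min(x$phi), max(x$phi), x$convergence$mode,
              x$convergence$iterations, x$convergence$residual))
  invisible(x)
}

#' Write a potential grid in OpenDX scalar-field format
#'
#' Chimera/VMD-compatible regular-grid export (z varies fastest).
#'
#' @param grid a `potential_grid`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_dx <- function(grid, path) {
  d <- grid$dims
  h <- grid$spacing
  o <- grid$origin
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c(
    "# OpenDX scalar field written by fdpb",
    sprintf("object 1 class gridpositions counts %d %d %d", d[1], d[2], d[3]),
    sprintf("origin %.6f %.6f %.6f", o[1], o[2], o[3]),
    sprintf("delta %.6f 0.000000 0.000000", h),
    sprintf("delta 0.000000 %.6f 0.000000", h),
    sprintf("delta 0.000000 0.000000 %.6f", h),
    sprintf("object 2 class gridconnections counts %d %d %d", d[1], d[2], d[3]),
    sprintf("object 3 class array type double rank 0 items %d data follows",
            prod(d))), con)
  v <- as.numeric(aperm(grid$phi, c(3, 2, 1)))  # z fastest
  n <- length(v)
  pad <- (3 - n %% 3) %% 3
  if (pad) v <- c(v, rep(NA_real_, pad))
  m <- matrix(v, ncol = 3, byrow = TRUE)
  lines <- apply(m, 1, function(r)
    paste(sprintf("%.6e", r[!is.na(r)]), collapse = " "))
  writeLines(lines, con)
  writeLines(c('attribute "dep" string "positions"',
               'object "regular positions regular connections" class field',
               'component "positions" value 1',
               'component "connections" value 2',
               'component "data" value 3'), con)
  invisible(path)
}

#' Read an OpenDX scalar field written by [write_dx()]
#'
#' @param path OpenDX file.
#' @return A `potential_grid` (without a convergence report).
#' @export
read_dx <- function(path) {
  lines <- readLines(path, warn = FALSE)
  cl <- grep("class gridpositions counts", lines, value = TRUE)[1]
  d <- as.integer(strsplit(trimws(sub(".*counts", "", cl)), "\\s+")[[1]])
  o <- as.numeric(strsplit(trimws(sub("origin", "", grep("^origin", lines, value = TRUE)[1])), "\\s+")[[1]])
  deltas <- grep("^delta", lines, value = TRUE)
  h <- as.numeric(strsplit(trimws(sub("delta", "", deltas[1])), "\\s+")[[1]])[1]
  start <- grep("data follows", lines)[1] + 1
  end <- grep("attribute", lines)[1] - 1
  v <- as.numeric(unlist(strsplit(trimws(lines[start:end]), "\\s+")))
  phi <- aperm(array(v, dim = rev(d)), c(3, 2, 1))
  structure(list(phi = phi, origin = o, spacing = h, dims = d,
                 convergence = NULL, config = NULL),
            class = "potential_grid")
}
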