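#' Trilinear interpolation of the potential
#'
#' @param grid a `potential_grid`.
#' @param points numeric length-3 vector or n x 3 matrix of coordinates
#'   (Angstrom), strictly inside the grid.
#' @return Potential value(s) in kT/e.
#' @export
potential_at <- function(grid, points) {
  p <- if (is.matrix(points)) points else matrix(points, ncol = 3)
  d <- grid$dims
  f <- sweep(p, 2, grid$origin) / grid$spacing
  if (any(f < 0) || any(f[, 1] > d[1] - 1) || any(f[, 2] > d[2] - 1) ||
      any(f[, 3] > d[3] - 1))
    stop("point outside the potential grid")
  i0 <- pmin(floor(f), matrix(rep(d - 2, each = nrow(f)), ncol = 3))
  w <- f - i0
  phi <- grid$phi
  val <- numeric(nrow(p))
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    wt <- (if (dx) w[, 1] else 1 - w[, 1]) *
      (if (dy) w[, 2] else 1 - w[, 2]) *
      (if (dz) w[, 3] else 1 - w[, 3])
    val <- val + wt * phi[cbind(i0[, 1] + 1 + dx, i0[, 2] + 1 + dy,
                                i0[, 3] + 1 + dz)]
  }
  val
}

#' Electric field E = -grad(phi) by central differences
#'
#' Central differences (one grid spacing) of the interpolated potential,
#' negated; exact for globally linear potentials. Points must lie at least
#' one node inside the grid boundary.
#'
#' @inheritParams potential_at
#' @return n x 3 matrix (or length-3 vector for a single point) in
#'   kT/(e Angstrom).
#' @export
field_at <- function(grid, points) {
  p <- if (is.matrix(points)) points else matrix(points, ncol = 3)
  h <- grid$spacing
  d <- grid$dims
  f <- sweep(p, 2, grid$origin) / h
  if (any(f < 1) || any(f[, 1] > d[1] - 2) || any(f[, 2] > d[2] - 2) ||
      any(f[, 3] > d[3] - 2))
    stop("point too close to the grid boundary for a central-difference field")
  E <- matrix(0, nrow(p), 3)
  for (ax in 1:3) {
    dp <- dm <- p
    dp[, ax] <- dp[, ax] + h
    dm[, ax] <- dm[, ax] - h
    E[, ax] <- -(potential_at(grid, dp) - potential_at(grid, dm)) / (2 * h)
  }
  if (!is.matrix(points)) E[1, ] else E
}

# Deterministic quasi-uniform directions on the unit sphere (Fibonacci
# lattice).
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  ga <- pi * (3 - sqrt(5))
  th <- ga * (seq_len(n) - 1)
  cbind(r * cos(th), r * sin(th), z)
}

#' Sample the potential on atom surfaces
#'
#' Potential is sampled at quasi-uniform dots on each atom's probe-inflated
#' sphere; per-atom means and a structure-level summary (overall mean,
#' fraction of positive samples) are returned.
#'
#' @param structure the structure whose surface is probed.
#' @param grid a solved `potential_grid` covering every atom sphere.
#' @param config a [pbe_config()] (for the probe radius).
#' @param n_dots sphere dots per atom.
#' @return A `surface_potential` object: `per_atom` data.frame and `summary`
#'   list.
#' @export
surface_potential <- function(structure, grid, config = pbe_config(),
                              n_dots = 50) {
  a <- structure$atoms
  if (!nrow(a)) stop("surface_potential of an empty structure")
  dirs <- fibonacci_sphere(n_dots)
  means <- numeric(nrow(a))
  allvals <- vector("list", nrow(a))
  for (i in seq_len(nrow(a))) {
    dots <- sweep(dirs * (a$radius[i] + config$probe_radius), 2,
                  c(a$x[i], a$y[i], a$z[i]), "+")
    vals <- potential_at(grid, dots)  # errors if the sphere leaves the grid
    means[i] <- mean(vals)
    allvals[[i]] <- vals
  }
  v <- unlist(allvals)
  structure(list(
    per_atom = data.frame(chain = a$chain, resid = a$resid, name = a$name,
                          mean_potential = means, stringsAsFactors = FALSE),
    summary = list(mean = mean(v), fraction_positive = mean(v > 0),
                   n_dots = n_dots)),
    class = "surface_potential")
}

#' @export
print.surface_potential <- function(x, ...) {
  cat(sprintf("surface_potential: %d atoms, mean %.4f kT/e, %.1f%% positive\n",
              nrow(x$per_atom), x$summary$mean,
              100 * x$summary$fraction_positive))
  invisible(x)
}

#' Field-line selection filter
#'
#' Defaults follow the study's display filter: keep lines with arc length in
#' [4.12, 35.31] Angstrom, seed only where the local gradient magnitude
#' reaches 3.64 kT/(e A), and integrate with a 0.25 A step.
#'
#' @param min_length,max_length arc-length window, Angstrom.
#' @param grad_threshold minimum |grad phi| at a seed, kT/(e A).
#' @param step integration step, Angstrom.
#' @return A `line_filter` list.
#' @export
line_filter <- function(min_length = 4.12, max_length = 35.31,
                        grad_threshold = 3.64, step = 0.25) {
  stopifnot(min_length > 0, max_length > min_length, step > 0,
            grad_threshold >= 0)
  structure(list(min_length = min_length, max_length = max_length,
                 grad_threshold = grad_threshold, step = step),
            class = "line_filter")
}

# Fast scalar trilinear interpolator and central-difference field for the
# tracer: plain arithmetic, no matrix plumbing, NULL when out of range.
make_field_fn <- function(grid) {
  phi <- grid$phi
  o <- grid$origin
  h <- grid$spacing
  d <- grid$dims
  interp <- function(x, y, z) {
    fx <- (x - o[1]) / h; fy <- (y - o[2]) / h; fz <- (z - o[3]) / h
    if (fx < 0 || fy < 0 || fz < 0 || fx > d[1] - 1 || fy > d[2] - 1 ||
        fz > d[3] - 1) return(NULL)
    i <- min(floor(fx), d[1] - 2); j <- min(floor(fy), d[2] - 2)
    k <- min(floor(fz), d[3] - 2)
    wx <- fx - i; wy <- fy - j; wz <- fz - k
    i <- i + 1; j <- j + 1; k <- k + 1
    c00 <- phi[i, j, k] * (1 - wx) + phi[i + 1, j, k] * wx
    c10 <- phi[i, j + 1, k] * (1 - wx) + phi[i + 1, j + 1, k] * wx
    c01 <- phi[i, j, k + 1] * (1 - wx) + phi[i + 1, j, k + 1] * wx
    c11 <- phi[i, j + 1, k + 1] * (1 - wx) + phi[i + 1, j + 1, k + 1] * wx
    (c00 * (1 - wy) + c10 * wy) * (1 - wz) +
      (c01 * (1 - wy) + c11 * wy) * wz
  }
  field <- function(p) {
    xp <- interp(p[1] + h, p[2], p[3]); xm <- interp(p[1] - h, p[2], p[3])
    yp <- interp(p[1], p[2] + h, p[3]); ym <- interp(p[1], p[2] - h, p[3])
    zp <- interp(p[1], p[2], p[3] + h); zm <- interp(p[1], p[2], p[3] - h)
    if (is.null(xp) || is.null(xm) || is.null(yp) || is.null(ym) ||
        is.null(zp) || is.null(zm)) return(NULL)
    -c(xp - xm, yp - ym, zp - zm) / (2 * h)
  }
  field
}

# One-directional RK4 streamline from `start` along sign * E.
trace_one_direction <- function(field_fn, start, sign, filter,
                                max_steps = 10000L, min_field = 1e-6) {
  h <- filter$step
  pts <- matrix(NA_real_, max_steps + 1L, 3)
  pts[1, ] <- start
  len <- 0
  reason <- "max steps"
  np <- 1L
  unitE <- function(p) {
    E <- field_fn(p)
    if (is.null(E)) return(NULL)
    nrm <- sqrt(sum(E * E))
    if (nrm < min_field) return(FALSE)
    sign * E / nrm
  }
  p <- start
  for (s in seq_len(max_steps)) {
    ks <- vector("list", 4)
    stage_pts <- function(i) switch(i, p, p + (h / 2) * ks[[1]],
                                    p + (h / 2) * ks[[2]], p + h * ks[[3]])
    bad <- FALSE
    for (i in 1:4) {
      v <- unitE(stage_pts(i))
      if (!is.numeric(v)) {
        reason <- if (is.null(v)) "left grid" else "low field"
        bad <- TRUE
        break
      }
      ks[[i]] <- v
    }
    if (bad) break
    p <- p + (h / 6) * (ks[[1]] + 2 * ks[[2]] + 2 * ks[[3]] + ks[[4]])
    np <- np + 1L
    pts[np, ] <- p
    len <- len + h
    # capture by a point source/sink: the normalized-step integrator
    # oscillates across the singular node instead of advancing
    if (np >= 3 && sum((p - pts[np - 2L, ])^2) < (0.5 * h)^2) {
      reason <- "stagnated"
      break
    }
    if (len >= filter$max_length) { reason <- "max length"; break }
  }
  list(points = pts[seq_len(np), , drop = FALSE], length = len,
       reason = reason)
}

#' Trace electric field lines
#'
#' Fixed-step 4th-order Runge-Kutta streamline integration along the
#' normalized field from each seed whose local gradient magnitude reaches
#' the filter threshold. `direction = "both"` (default) traces along +E and
#' -E and joins the halves through the seed. Lines whose arc length falls
#' outside the filter window are discarded; tracing stops on leaving the
#' grid, field collapse (|E| < 1e-6), capture by a point source/sink
#' (stagnation), the step cap, or the length cap. Deterministic given the
#' seeds.
#'
#' @param grid a `potential_grid`.
#' @param seeds n x 3 matrix of seed points inside the grid.
#' @param filter a [line_filter()].
#' @param direction `"both"`, `"forward"` (+E) or `"backward"` (-E).
#' @return A `field_lines` list; each element has `points`, `length`,
#'   `seed`, `reason`.
#' @export
trace_field_lines <- function(grid, seeds, filter = line_filter(),
                              direction = c("both", "forward", "backward")) {
  direction <- match.arg(direction)
  seeds <- if (is.matrix(seeds)) seeds else matrix(seeds, ncol = 3)
  field_fn <- make_field_fn(grid)
  lines <- list()
  for (s in seq_len(nrow(seeds))) {
    seed <- seeds[s, ]
    E0 <- field_fn(seed)
    if (is.null(E0) || sqrt(sum(E0 * E0)) < filter$grad_threshold) next
    fw <- if (direction %in% c("both", "forward"))
      trace_one_direction(field_fn, seed, +1, filter) else NULL
    bw <- if (direction %in% c("both", "backward"))
      trace_one_direction(field_fn, seed, -1, filter) else NULL
    if (is.null(bw)) {
      pts <- fw$points; len <- fw$length; reason <- fw$reason
    } else if (is.null(fw)) {
      pts <- bw$points; len <- bw$length; reason <- bw$reason
    } else {
      pts <- rbind(bw$points[rev(seq_len(nrow(bw$points))[-1]), , drop = FALSE],
                   fw$points)
      len <- fw$length + bw$length
      reason <- fw$reason
    }
    if (len < filter$min_length || len > filter$max_length) next
    lines[[length(lines) + 1L]] <- list(points = pts, length = len,
                                        seed = seed, reason = reason)
  }
  structure(lines, class = "field_lines", filter = filter)
}

#' @export
print.field_lines <- function(x, ...) {
  cat(sprintf("field_lines: %d lines", length(x)))
  if (length(x))
    cat(sprintf(", arc length %.2f-%.2f A",
                min(vapply(x, `[[`, 0, "length")),
                max(vapply(x, `[[`, 0, "length"))))
  cat("\n")
  invisible(x)
}

#' Flatten field lines to a polyline table
#'
#' @param x a `field_lines` object.
#' @param grid optional `potential_grid` to annotate each vertex with phi.
#' @param ... unused.
#' @return data.frame with columns line, idx, x, y, z (and phi if `grid`).
#' @export
as.data.frame.field_lines <- function(x, grid = NULL, ...) {
  if (!length(x))
    return(data.frame(line = integer(), idx = integer(), x = numeric(),
                      y = numeric(), z = numeric()))
  out <- do.call(rbind, lapply(seq_along(x), function(i) {
    p <- x[[i]]$points
    data.frame(line = i, idx = seq_len(nrow(p)), x = p[, 1], y = p[, 2],
               z = p[, 3])
  }))
  if (!is.null(grid))
    out$phi <- potential_at(grid, as.matrix(out[, c("x", "y", "z")]))
  out
}

#' Seed points on a structure's probe-inflated surface
#'
#' @param structure a [pqr_structure()].
#' @param config a [pbe_config()] (probe radius).
#' @param n_dots dots per atom.
#' @return Matrix of candidate seed coordinates.
#' @export
surface_seeds <- function(structure, config = pbe_config(), n_dots = 12) {
  a <- structure$atoms
  dirs <- fibonacci_sphere(n_dots)
  do.call(rbind, lapply(seq_len(nrow(a)), function(i)
    sweep(dirs * (a$radius[i] + config$probe_radius), 2,
          c(a$x[i], a$y[i], a$z[i]), "+")))
}
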