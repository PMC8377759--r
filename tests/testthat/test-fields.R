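# A synthetic grid holding an exactly linear potential phi = a.x + b.y + c.z
linear_grid <- function(a = 0.7, b = -0.3, c = 0.2, n = 21, h = 1) {
  ax <- (seq_len(n) - (n + 1) / 2) * h
  phi <- outer(outer(a * ax, b * ax, "+"), c * ax, "+")
  structure(list(phi = phi, origin = rep(ax[1], 3), spacing = h,
                 dims = rep(as.integer(n), 3)),
            class = "potential_grid")
}

test_that("trilinear sampling is exact on nodes and linear fields", {
  g <- linear_grid()
  expect_equal(potential_at(g, c(3, -2, 5)), 0.7 * 3 - 0.3 * -2 + 0.2 * 5)
  # random interior points reproduce the linear field exactly
  rng <- fdpb:::lcg_new(5)
  pts <- matrix(fdpb:::lcg_unif(rng, 30, -8, 8), ncol = 3)
  expect_equal(potential_at(g, pts),
               pts %*% c(0.7, -0.3, 0.2), ignore_attr = TRUE,
               tolerance = 1e-12)
  # midpoint of two nodes on an axis is the mean of the node values
  expect_equal(potential_at(g, c(0.5, 0, 0)),
               mean(c(potential_at(g, c(0, 0, 0)), potential_at(g, c(1, 0, 0)))))
  expect_error(potential_at(g, c(100, 0, 0)), "outside")
})

test_that("central-difference field is exact on linear potentials", {
  g <- linear_grid()
  expect_equal(field_at(g, c(1.3, 0.2, -4)), -c(0.7, -0.3, 0.2),
               tolerance = 1e-12)
  gu <- linear_grid(0, 0, 0)
  expect_equal(field_at(gu, c(2, 2, 2)), c(0, 0, 0))
  expect_error(field_at(g, c(9.99, 0, 0)), "boundary")
})

test_that("field of a point charge is radial", {
  s <- point_charge_structure()
  pg <- solve_pbe(s, build_grid(s, 1, 12), uniform_config(padding = 12))
  rng <- fdpb:::lcg_new(8)
  dirs <- fdpb:::fibonacci_sphere(20)
  for (r in c(4, 6, 8)) {
    E <- field_at(pg, dirs * r)
    En <- E / sqrt(rowSums(E^2))
    ang <- acos(pmin(1, rowSums(En * dirs))) * 180 / pi
    expect_lt(max(ang), 5)
  }
})

test_that("surface potential resolves the polarity of the synthetic enzyme", {
  en <- make_polar_enzyme(60)
  cfg <- pbe_config(spacing = 1)
  pg <- solve_pbe(en, config = cfg)
  sp <- surface_potential(en, pg, cfg)
  face_mean <- function(gr)
    mean(sp$per_atom$mean_potential[fdpb:::resolve_selection(en, gr)])
  expect_gt(face_mean("interface"), face_mean("backside"))
  expect_gt(face_mean("interface"), 0)
  expect_lt(face_mean("backside"), 0)
  # doubling the charges doubles every sample in linear mode
  en2 <- en
  en2$atoms$charge <- 2 * en2$atoms$charge
  pg2 <- solve_pbe(en2, config = cfg)
  sp2 <- surface_potential(en2, pg2, cfg)
  expect_equal(sp2$per_atom$mean_potential, 2 * sp$per_atom$mean_potential,
               tolerance = 1e-4)
  # positive monopole: every per-atom mean positive
  s <- point_charge_structure(q = 1, radius = 1.5)
  pgm <- solve_pbe(s, build_grid(s, 1, 10), uniform_config(padding = 10))
  spm <- surface_potential(s, pgm, uniform_config())
  expect_true(all(spm$per_atom$mean_potential > 0))
})

test_that("field lines run radially off a point charge with falling
           potential and respect the length filters", {
  s <- point_charge_structure(q = 2, radius = 1.5)
  cfg <- uniform_config(padding = 20)
  pg <- solve_pbe(s, build_grid(s, 1, 20), cfg)
  seeds <- fdpb:::fibonacci_sphere(16) * 3.5
  filt <- line_filter(min_length = 4.12, max_length = 35.31,
                      grad_threshold = 0.5)
  fl <- trace_field_lines(pg, seeds, filt, direction = "forward")
  expect_gt(length(fl), 0)
  for (l in fl) {
    expect_gte(l$length, 4.12)
    expect_lte(l$length, 35.31)
    # radial within 5 degrees, monotone decreasing potential
    p <- l$points
    dirs <- p / sqrt(rowSums(p^2))
    steps <- diff(p)
    sd <- steps / sqrt(rowSums(steps^2))
    ang <- acos(pmin(1, rowSums(sd * dirs[-nrow(dirs), ]))) * 180 / pi
    expect_lt(max(ang), 5)
    expect_true(all(diff(potential_at(pg, p)) < 1e-9))
    # consecutive points closer than 2x step; arc length consistent
    expect_true(all(sqrt(rowSums(steps^2)) < 2 * filt$step))
    expect_equal(l$length, filt$step * (nrow(p) - 1), tolerance = 1e-9)
    expect_true(l$reason %in% c("left grid", "low field", "max steps",
                                "max length", "stagnated"))
  }
  # uniform potential -> no seeds pass the threshold
  gu <- linear_grid(0, 0, 0)
  expect_length(trace_field_lines(gu, matrix(c(0, 0, 0), 1), filt), 0)
  # min-length filter is strict
  short_filter <- line_filter(min_length = 30, max_length = 35,
                              grad_threshold = 0.5)
  fls <- trace_field_lines(pg, seeds, short_filter, direction = "forward")
  for (l in fls) expect_gte(l$length, 30)
})

test_that("lines between opposite charges land on the sink more often than
           they leave the grid", {
  d <- make_dimer(1, -1, 10)
  cfg <- uniform_config(padding = 15)
  pg <- solve_pbe(d, build_grid(d, 1, 15), cfg)
  seeds <- fdpb:::fibonacci_sphere(30) * 3.0
  fl <- trace_field_lines(pg, seeds,
                          line_filter(min_length = 1, max_length = 40,
                                      grad_threshold = 0.2),
                          direction = "forward")
  reach <- vapply(fl, function(l)
    min(sqrt(rowSums(sweep(l$points, 2, c(10, 0, 0))^2))) < 2, TRUE)
  left <- vapply(fl, function(l) l$reason == "left grid", TRUE)
  expect_gt(sum(reach), sum(left))
})

test_that("field lines export as polyline tables", {
  s <- point_charge_structure(q = 2, radius = 1.5)
  cfg <- uniform_config(padding = 12)
  pg <- solve_pbe(s, build_grid(s, 1, 12), cfg)
  fl <- trace_field_lines(pg, fdpb:::fibonacci_sphere(6) * 3.5,
                          line_filter(grad_threshold = 0.5, min_length = 2,
                                      max_length = 20),
                          direction = "forward")
  df <- as.data.frame(fl, grid = pg)
  expect_true(all(c("line", "idx", "x", "y", "z", "phi") %in% names(df)))
  expect_equal(length(unique(df$line)), length(fl))
})
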