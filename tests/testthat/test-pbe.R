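test_that("grids enclose the solute with odd dimensions", {
  s <- point_charge_structure(radius = 2)
  g <- build_grid(s, spacing = 1, padding = 10)
  expect_equal(g$dims, c(25L, 25L, 25L))     # 2*(2+10)/1 + 1
  g2 <- build_grid(s, spacing = 0.5, padding = 10)
  expect_equal(g2$dims, c(49L, 49L, 49L))    # spacing halved ~ doubled, odd
  expect_true(all(g$dims %% 2 == 1))
  expect_error(build_grid(s, spacing = 0.1, padding = 10, max_dim = 51),
               "coarser")
  expect_error(build_grid(s, spacing = 1, padding = 2), "padding")
})

test_that("dielectric maps mark probe-inflated spheres on edge midpoints", {
  cfg <- pbe_config(spacing = 1, probe_radius = 1.4)
  s <- point_charge_structure(radius = 2)
  g <- build_grid(s, 1, 10)
  # empty structure: uniform solvent dielectric
  m0 <- map_dielectric(pqr_structure(fdpb:::empty_atoms()), g, cfg)
  expect_true(all(m0$ex == cfg$eps_out) && all(m0$ey == cfg$eps_out))
  m <- map_dielectric(s, g, cfg)
  # x-edge midpoint at (0.5, 0, 0): distance 0.5 < 3.4 -> eps_in
  ctr <- (g$dims - 1) / 2
  expect_equal(m$ex[ctr[1] + 1, ctr[2] + 1, ctr[3] + 1], cfg$eps_in)
  # an edge midpoint far outside stays eps_out
  expect_equal(m$ex[2, 2, 2], cfg$eps_out)
  # interior fraction grows monotonically with the probe radius
  fr <- vapply(seq(0, 3, 0.5), function(p) {
    mm <- map_dielectric(s, g, pbe_config(spacing = 1, probe_radius = p))
    mean(c(mm$ex, mm$ey, mm$ez) == cfg$eps_in)
  }, 0)
  expect_true(all(diff(fr) >= 0))
  expect_gt(fr[7], fr[1])
})

test_that("ion-exclusion map is zero in the solute and Stern layer only", {
  s <- point_charge_structure(radius = 2)
  g <- build_grid(s, 1, 10)
  cfg <- pbe_config(spacing = 1, salt = 0.15, stern = 2)
  k <- map_kappa(s, g, cfg)
  ctr <- (g$dims - 1) / 2 + 1
  expect_equal(k[ctr[1], ctr[2], ctr[3]], 0)           # inside solute
  expect_equal(k[ctr[1] + 3, ctr[2], ctr[3]], 0)       # r=3 < radius+stern=4
  expect_gt(k[ctr[1] + 5, ctr[2], ctr[3]], 0)          # r=5 outside
  expect_true(all(map_kappa(s, g, pbe_config(spacing = 1, salt = 0)) == 0))
  expect_error(map_kappa(s, g, pbe_config(spacing = 1, salt = -1)))
  # bulk value reproduces the Debye length from SI constants
  lam <- 1 / sqrt(max(k))
  expect_rel(lam, debye_length_oracle(0.15), 0.005)
  expect_equal(round(lam, 1), 8.0, tolerance = 0.11)   # ~7.9 A
})

test_that("boundary conditions match their closed forms", {
  s <- point_charge_structure(q = 1)
  g <- build_grid(s, 2, 16)
  cfg <- uniform_config(spacing = 2, padding = 16)
  u <- boundary_potential(s, g, cfg)
  # single +1 charge, no salt: faces carry the Coulomb potential
  ce <- celec_oracle()
  i <- 1; j <- (g$dims[2] + 1) / 2; k <- (g$dims[3] + 1) / 2
  r <- abs(g$origin[1])
  expect_rel(u[i, j, k], ce / (80 * r), 1e-6)
  expect_true(all(u[2:(g$dims[1] - 1), 2:(g$dims[2] - 1), 2:(g$dims[3] - 1)] == 0))
  # zero mode
  cfg0 <- uniform_config(spacing = 2, padding = 16, boundary = "zero")
  expect_true(all(boundary_potential(s, g, cfg0) == 0))
  # neutral dimer: dipolar mode has no monopole contribution (decays as r^-2)
  d <- make_dimer(1, -1, 4)
  gd <- build_grid(d, 2, 30)
  cfgd <- uniform_config(spacing = 2, padding = 30, boundary = "dipolar")
  ud <- boundary_potential(d, gd, cfgd)
  ua <- boundary_potential(d, gd, uniform_config(spacing = 2, padding = 30))
  # per-atom and dipolar modes agree for a compact source at >= 20 A
  face <- cbind(as.numeric(ud[1, , ]), as.numeric(ua[1, , ]))
  expect_lt(max(abs(face[, 1] - face[, 2])) / max(abs(face[, 2])), 0.05)
})

test_that("solver reproduces Coulomb and Yukawa closed forms", {
  s <- point_charge_structure()
  g <- build_grid(s, 1, 20)
  ax <- seq(g$origin[1], -g$origin[1], 1)
  nodes <- as.matrix(expand.grid(ax, ax, ax))
  r <- sqrt(rowSums(nodes^2))
  keep <- r >= 3 & r <= 8
  ce <- celec_oracle()
  pg <- solve_pbe(s, g, uniform_config(spacing = 1, padding = 20))
  rel <- (as.numeric(pg$phi)[keep] - ce / (80 * r[keep])) /
    (ce / (80 * r[keep]))
  expect_lt(max(abs(rel)), 0.05)
  # screened form
  cfg2 <- uniform_config(spacing = 1, salt = 0.15, padding = 20)
  pg2 <- solve_pbe(s, g, cfg2)
  kap <- 1 / debye_length_oracle(0.15)
  oracle <- ce * exp(-kap * r[keep]) / (80 * r[keep])
  expect_lt(max(abs(as.numeric(pg2$phi)[keep] - oracle) / oracle), 0.05)
  # no charges + zero boundary -> identically zero
  s0 <- point_charge_structure(q = 0)
  pg0 <- solve_pbe(s0, g, uniform_config(spacing = 1, padding = 20,
                                         boundary = "zero"))
  expect_equal(max(abs(pg0$phi)), 0)
})

test_that("linear-mode solutions superpose and scale", {
  cfg <- uniform_config(spacing = 1, padding = 10)
  q1 <- pqr_structure(data.frame(name = "C1", resname = "ION", resid = 1L,
                                 chain = "A", x = -3, y = 0, z = 0,
                                 charge = 1, radius = 0))
  q2 <- pqr_structure(data.frame(name = "C1", resname = "ION", resid = 1L,
                                 chain = "B", x = 3, y = 1, z = 0,
                                 charge = -0.5, radius = 0))
  both <- fdpb:::combine_structures(q1, q2)
  g <- build_grid(both, 1, 10)
  p1 <- solve_pbe(q1, g, cfg)$phi
  p2 <- solve_pbe(q2, g, cfg)$phi
  p12 <- solve_pbe(both, g, cfg)$phi
  expect_lt(max(abs(p12 - (p1 + p2))), 2 * max(abs(p12)) * 1e-6)
  # doubling the charges doubles the potential
  dbl <- both
  dbl$atoms$charge <- 2 * dbl$atoms$charge
  pd <- solve_pbe(dbl, g, cfg)$phi
  expect_lt(max(abs(pd - 2 * p12)), max(abs(pd)) * 1e-5)
})

test_that("a centered charge yields an axis-permutation-symmetric field", {
  s <- point_charge_structure()
  g <- build_grid(s, 1, 10)
  pg <- solve_pbe(s, g, uniform_config(spacing = 1, padding = 10))
  expect_lt(max(abs(pg$phi - aperm(pg$phi, c(2, 3, 1)))), 1e-6 * max(pg$phi))
  expect_lt(max(abs(pg$phi - pg$phi[rev(seq_len(dim(pg$phi)[1])), , ])),
            1e-6 * max(pg$phi))
})

test_that("grid refinement reduces the Coulomb error", {
  s <- point_charge_structure()
  err_at <- function(h) {
    cfg <- uniform_config(spacing = h, padding = 10)
    g <- build_grid(s, h, 10)
    pg <- solve_pbe(s, g, cfg)
    pts <- rbind(c(4, 0, 0), c(0, 4, 0), c(0, 0, 4), c(3, 3, 3))
    r <- sqrt(rowSums(pts^2))
    max(abs(potential_at(pg, pts) - celec_oracle() / (80 * r)) /
          (celec_oracle() / (80 * r)))
  }
  expect_lt(err_at(0.5), err_at(1.0))
})

test_that("nonlinear mode damps high potentials and matches linear at low", {
  s <- point_charge_structure(q = 5)
  cfg_l <- uniform_config(spacing = 1, salt = 0.5, padding = 10)
  cfg_n <- uniform_config(spacing = 1, salt = 0.5, padding = 10,
                          mode = "nonlinear")
  g <- build_grid(s, 1, 10)
  pl <- solve_pbe(s, g, cfg_l)
  pn <- solve_pbe(s, g, cfg_n)
  ctr <- (g$dims + 1) / 2
  # in the high-potential region the sinh term screens harder
  expect_lt(pn$phi[ctr[1] + 3, ctr[2], ctr[3]],
            pl$phi[ctr[1] + 3, ctr[2], ctr[3]])
  # at small charge the two modes agree
  s2 <- point_charge_structure(q = 0.01)
  pl2 <- solve_pbe(s2, g, cfg_l)
  pn2 <- solve_pbe(s2, g, cfg_n)
  expect_lt(max(abs(pn2$phi - pl2$phi)), 1e-3 * max(abs(pl2$phi)))
})

test_that("convergence failures surface as a typed error with history", {
  s <- point_charge_structure()
  g <- build_grid(s, 1, 10)
  cfg <- uniform_config(spacing = 1, padding = 10, maxit = 3, tol = 1e-12)
  err <- tryCatch(solve_pbe(s, g, cfg), error = function(e) e)
  expect_s3_class(err, "fdpb_convergence_error")
  expect_length(err$history, 3)
})

test_that("OpenDX files round-trip the potential grid", {
  s <- point_charge_structure()
  g <- build_grid(s, 2, 10)
  pg <- solve_pbe(s, g, uniform_config(spacing = 2, padding = 10))
  f <- withr::local_tempfile(fileext = ".dx")
  write_dx(pg, f)
  back <- read_dx(f)
  expect_equal(back$dims, pg$dims)
  expect_equal(back$origin, pg$origin, tolerance = 1e-6)
  expect_equal(back$phi, pg$phi, tolerance = 1e-5)
})
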