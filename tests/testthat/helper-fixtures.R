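# Shared fixtures and analytic oracles for the test suite.

# Uniform-solvent solver configuration (no cavity, no Stern layer): the
# setting in which Coulomb / Yukawa closed forms are exact.
uniform_config <- function(spacing = 1, salt = 0, padding = 12, ...) {
  pbe_config(spacing = spacing, eps_in = 80, eps_out = 80, salt = salt,
             stern = 0, probe_radius = 0, padding = padding, ...)
}

# Electrostatic coupling constant in kT*A/e^2, derived independently of the
# package internals from CODATA constants.
celec_oracle <- function(temperature = 300) {
  e <- 1.602176634e-19; eps0 <- 8.8541878128e-12; NA_ <- 6.02214076e23
  kcal <- e^2 / (4 * pi * eps0 * 1e-10) * NA_ / 4184
  kcal / (1.9872e-3 * temperature)
}

# Debye length (A) for a 1:1 salt from SI constants.
debye_length_oracle <- function(salt, eps_r = 80, temperature = 300) {
  e <- 1.602176634e-19; eps0 <- 8.8541878128e-12
  kB <- 1.380649e-23; NA_ <- 6.02214076e23
  sqrt(eps0 * eps_r * kB * temperature /
         (2 * NA_ * e^2 * salt * 1000)) * 1e10
}

point_charge_structure <- function(q = 1, radius = 0) {
  pqr_structure(data.frame(name = "C1", resname = "ION", resid = 1L,
                           chain = "A", x = 0, y = 0, z = 0, charge = q,
                           radius = radius, stringsAsFactors = FALSE))
}

# A small hand-built pseudo-nucleotide matching the packaged RU template.
ru_fixture <- function() {
  tmpl <- read_charge_template()
  a <- data.frame(name = c("P", "O1", "C1", "N1", "B1", "B2"),
                  resname = "RU", resid = 5L, chain = "B",
                  x = c(0, 1.2, 2.1, 3.0, 4.1, 5.2),
                  y = c(0, 0.4, -0.3, 0.2, 0.5, -0.1),
                  z = c(0, -0.2, 0.4, 0.1, -0.4, 0.3),
                  charge = 0, radius = 1.7, stringsAsFactors = FALSE)
  assign_charges(pqr_structure(a), tmpl)
}

expect_rel <- function(value, oracle, tol) {
  expect_lt(abs(value - oracle) / abs(oracle), tol)
}
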