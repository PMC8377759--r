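# Minimal-standard (Lehmer/MINSTD) linear congruential generator, used for
# all fixture randomness so generated structures are pure functions of
# (parameters, seed) without touching R's global RNG state.
lcg_new <- function(seed) {
  stopifnot(is.finite(seed))
  env <- new.env(parent = emptyenv())
  # map any integer onto the generator's valid state range [1, m - 1]
  env$state <- (abs(as.double(seed)) %% 2147483646) + 1
  env
}

lcg_unif <- function(rng, n, min = 0, max = 1) {
  out <- numeric(n)
  for (i in seq_len(n)) {
    rng$state <- (16807 * rng$state) %% 2147483647
    out[i] <- rng$state / 2147483647
  }
  min + out * (max - min)
}

#' Two-point-charge fixture
#'
#' Two atoms on the x axis with unit-scale charges and 2.0 A radii: the
#' analytic-oracle fixture for Coulomb/Yukawa potential and force checks.
#'
#' @param q1,q2 charges (e) of the atoms at the origin and at `distance`.
#' @param distance separation along x, Angstrom (> 0).
#' @return A [pqr_structure()] with chains "A" and "B".
#' @export
make_dimer <- function(q1 = 1, q2 = -1, distance = 10) {
  stopifnot(distance > 0)
  a <- data.frame(name = c("C1", "C1"), resname = c("ION", "ION"),
                  resid = c(1L, 1L), chain = c("A", "B"),
                  x = c(0, distance), y = 0, z = 0,
                  charge = c(q1, q2), radius = 2.0,
                  stringsAsFactors = FALSE)
  pqr_structure(a, provenance = sprintf("make_dimer(%g, %g, %g)", q1, q2,
                                        distance),
                groups = list(source = list(chain = "A"),
                              probe = list(chain = "B")))
}

helix_backbone_offsets <- data.frame(
  name = c("P", "O1", "C1", "N1", "B1"),
  r = c(9.5, 8.6, 7.6, 6.6, 5.4),
  dth = c(0, 5, 10, 15, 20) * pi / 180,
  dz = c(0, 0.4, 0, -0.4, 0),
  stringsAsFactors = FALSE)

#' Synthetic DNA-like double helix with one flipped-out base
#'
#' Two antiparallel strands of pseudo-nucleotides (residue `DN`: one -1 e
#' "phosphate" plus neutral sugar/base sites), carrying net charge
#' -1 e per residue like B-DNA at the continuum level. Residue `base_index`
#' of chain "B" is typed `RU` and its base atoms are displaced radially
#' outward (the flipped-out target-base analog); the packaged template also
#' provides a `C` entry so the base can be mutated cytosine-like while
#' keeping the same -1 e net charge.
#'
#' @param n_residues residues per strand (>= 4).
#' @param rise helical rise per residue, Angstrom.
#' @param twist helical twist per residue, degrees.
#' @param base_index which residue of chain "B" carries the flipped base.
#' @param template charge template (default: packaged).
#' @return A [pqr_structure()] with groups `flipped_base` and `dna`.
#' @export
make_helix <- function(n_residues = 10, rise = 3.4, twist = 36,
                       base_index = 5, template = NULL) {
  stopifnot(n_residues >= 4, base_index >= 1, base_index <= n_residues)
  if (is.null(template)) template <- read_charge_template()
  rows <- list()
  for (strand in 1:2) {
    chain <- c("A", "B")[strand]
    for (i in seq_len(n_residues)) {
      th0 <- (i - 1) * twist * pi / 180 + if (strand == 2) pi * 5 / 6 else 0
      z0 <- if (strand == 1) (i - 1) * rise else (n_residues - i) * rise
      flipped <- strand == 2 && i == base_index
      resname <- if (flipped) "RU" else "DN"
      off <- helix_backbone_offsets
      if (flipped) {
        # backbone stays on the strand; base atoms are flung radially out
        off <- data.frame(name = c("P", "O1", "C1", "N1", "B1", "B2"),
                          r = c(9.5, 8.6, 7.6, 12.5, 15.0, 17.5),
                          dth = c(0, 5, 10, 0, 0, 0) * pi / 180,
                          dz = c(0, 0.4, 0, 0, 0, 0),
                          stringsAsFactors = FALSE)
      }
      th <- th0 + off$dth
      rows[[length(rows) + 1L]] <- data.frame(
        name = off$name, resname = resname, resid = i, chain = chain,
        x = off$r * cos(th), y = off$r * sin(th), z = z0 + off$dz,
        charge = 0, radius = 1.7, stringsAsFactors = FALSE)
    }
  }
  s <- pqr_structure(do.call(rbind, rows),
                     provenance = sprintf(
                       "make_helix(n=%d, rise=%g, twist=%g, base_index=%d)",
                       n_residues, rise, twist, base_index),
                     groups = list(
                       flipped_base = list(chain = "B", resid = base_index),
                       dna = list(chain = c("A", "B"))))
  assign_charges(s, template)
}

#' Synthetic polar enzyme with a ringed binding face
#'
#' A spherical shell of neutral atoms with: one negatively charged pocket
#' site (ASP analog) recessed at the +x pole; a ring of positive sites
#' (ARG/LYS analogs) around the binding face; and negative sites on the
#' back face. This reproduces, by construction, the polar charge pattern of
#' a base-excision enzyme: positively ringed binding interface, single
#' negative pocket residue, negative non-pocket side.
#'
#' @param n_shell number of neutral shell atoms (>= 50).
#' @param pocket_spec list with `n_ring` (positive interface sites) and
#'   `n_back` (negative back-face sites).
#' @param radius shell radius, Angstrom.
#' @param seed integer seed for the documented MINSTD LCG radial jitter.
#' @param template charge template (default: packaged).
#' @return A [pqr_structure()] (chain "E") with groups `pocket`,
#'   `interface`, `backside`.
#' @export
make_polar_enzyme <- function(n_shell = 80,
                              pocket_spec = list(n_ring = 8, n_back = 4),
                              radius = 12, seed = 1, template = NULL) {
  stopifnot(n_shell >= 50, pocket_spec$n_ring >= 4, pocket_spec$n_back >= 1)
  if (is.null(template)) template <- read_charge_template()
  rng <- lcg_new(seed)
  dirs <- fibonacci_sphere(n_shell)
  rr <- radius + lcg_unif(rng, n_shell, -0.3, 0.3)
  shell <- data.frame(name = "CA", resname = "GLY", resid = seq_len(n_shell),
                      chain = "E", x = rr * dirs[, 1], y = rr * dirs[, 2],
                      z = rr * dirs[, 3], charge = 0, radius = 1.8,
                      stringsAsFactors = FALSE)
  nextid <- n_shell
  # recessed pocket site at the +x pole
  nextid <- nextid + 1L
  pocket <- data.frame(name = "OD1", resname = "ASP", resid = nextid,
                       chain = "E", x = radius - 2.5, y = 0, z = 0,
                       charge = 0, radius = 1.8, stringsAsFactors = FALSE)
  pocket_id <- nextid
  # positive ring around the binding face
  nr <- pocket_spec$n_ring
  polar <- 28 * pi / 180
  az <- 2 * pi * (seq_len(nr) - 1) / nr
  ringres <- rep(c("ARG", "LYS"), length.out = nr)
  ring <- data.frame(name = ifelse(ringres == "ARG", "NH1", "NZ"),
                     resname = ringres, resid = nextid + seq_len(nr),
                     chain = "E",
                     x = (radius + 0.5) * cos(polar),
                     y = (radius + 0.5) * sin(polar) * cos(az),
                     z = (radius + 0.5) * sin(polar) * sin(az),
                     charge = 0, radius = 2.0, stringsAsFactors = FALSE)
  ring_ids <- nextid + seq_len(nr)
  nextid <- nextid + nr
  # negative back face
  nb <- pocket_spec$n_back
  polarb <- 150 * pi / 180
  azb <- 2 * pi * (seq_len(nb) - 1) / nb + 0.3
  backres <- rep(c("ASP", "GLU"), length.out = nb)
  back <- data.frame(name = ifelse(backres == "ASP", "OD1", "OE1"),
                     resname = backres, resid = nextid + seq_len(nb),
                     chain = "E",
                     x = radius * cos(polarb),
                     y = radius * sin(polarb) * cos(azb),
                     z = radius * sin(polarb) * sin(azb),
                     charge = 0, radius = 1.8, stringsAsFactors = FALSE)
  back_ids <- nextid + seq_len(nb)
  s <- pqr_structure(rbind(shell, pocket, ring, back),
                     provenance = sprintf(
                       "make_polar_enzyme(n_shell=%d, n_ring=%d, n_back=%d, seed=%d)",
                       n_shell, nr, nb, seed),
                     groups = list(
                       pocket = list(chain = "E", resid = pocket_id),
                       interface = list(chain = "E",
                                        resid = c(pocket_id, ring_ids)),
                       backside = list(chain = "E", resid = back_ids),
                       enzyme = list(chain = "E")))
  assign_charges(s, template)
}

#' Bound enzyme-DNA complex fixture
#'
#' Places the helix so its flipped-out base aims at the enzyme pocket center
#' along -x, with the closest interatomic approach equal to `gap`. Chains
#' distinguish the molecules (helix "A"/"B", enzyme "E").
#'
#' @param enzyme a [make_polar_enzyme()] structure (or `NULL` for defaults).
#' @param helix a [make_helix()] structure (or `NULL` for defaults).
#' @param gap closest approach between the molecules, Angstrom (>= 0).
#' @return A [pqr_structure()] carrying both molecules and all groups.
#' @export
make_complex <- function(enzyme = NULL, helix = NULL, gap = 3) {
  if (gap < 0) stop("gap must be >= 0")
  if (is.null(enzyme)) enzyme <- make_polar_enzyme()
  if (is.null(helix)) helix <- make_helix()
  ha <- helix$atoms
  flip <- resolve_selection(helix, "flipped_base")
  tip <- ha[flip & ha$name == "B2", c("x", "y", "z")]
  if (!nrow(tip)) stop("helix has no flipped base tip (B2)")
  # rotate about z so the base tip azimuth points to -x
  thb <- atan2(tip$y[1], tip$x[1])
  al <- pi - thb
  rot <- matrix(c(cos(al), sin(al), 0, -sin(al), cos(al), 0, 0, 0, 1), 3, 3)
  xyz <- as.matrix(ha[, c("x", "y", "z")]) %*% t(rot)
  # base tip at z = 0, then slide in along +x until closest approach = gap
  xyz[, 3] <- xyz[, 3] - xyz[flip & ha$name == "B2", 3][1]
  xoff <- max(enzyme$atoms$x) - min(xyz[, 1]) + gap + 20
  xyz[, 1] <- xyz[, 1] + xoff
  ea <- as.matrix(enzyme$atoms[, c("x", "y", "z")])
  min_cross <- function(xyz) {
    d2 <- outer(rowSums(xyz^2), rowSums(ea^2), "+") - 2 * xyz %*% t(ea)
    sqrt(max(min(d2), 0))
  }
  for (it in 1:60) {
    D <- min_cross(xyz)
    if (D >= gap && D <= gap + 0.5) break
    xyz[, 1] <- xyz[, 1] - (D - (gap + 0.25))
  }
  D <- min_cross(xyz)
  if (D < gap - 1e-6)
    stop(sprintf("geometry error: molecules overlap (min distance %.2f < gap %.2f)",
                 D, gap))
  ha[, c("x", "y", "z")] <- xyz
  helix$atoms <- ha
  helix$provenance <- c(helix$provenance,
                        sprintf("docked to enzyme pocket, gap %.2f A", gap))
  combine_structures(enzyme, helix)
}

#' Synthetic titratable-site set
#'
#' Unfolded pKas cycle through the packaged model-compound table; folded
#' pKas are offset according to `shift_profile`:
#' \describe{
#'   \item{null}{folded = unfolded (flat zero folding-energy curve).}
#'   \item{udg_like}{acidic sites with model pKa <= 5 are shifted down by
#'     2.5 units on folding and basic sites with model pKa >= 10 up by 2.5,
#'     producing a folding-energy curve that falls at low pH, is flat over
#'     the mid-range, and rises at high pH.}
#'   \item{random}{folded = unfolded + MINSTD-LCG uniform offsets in
#'     [-2, 2].}
#' }
#'
#' @param n_acids,n_bases site counts (total >= 1).
#' @param shift_profile `"udg_like"`, `"null"` or `"random"`.
#' @param seed integer LCG seed (used by `"random"`).
#' @return A [titratable_sites()] table.
#' @export
make_titration_set <- function(n_acids = 6, n_bases = 6,
                               shift_profile = c("udg_like", "null", "random"),
                               seed = 1) {
  shift_profile <- match.arg(shift_profile)
  stopifnot(n_acids + n_bases >= 1, n_acids >= 0, n_bases >= 0)
  mp <- model_pkas()
  acids <- mp[mp$type == "acid", ]
  bases <- mp[mp$type == "base", ]
  pick <- function(tab, n) tab[((seq_len(n) - 1) %% nrow(tab)) + 1, ]
  sel <- rbind(if (n_acids) pick(acids, n_acids),
               if (n_bases) pick(bases, n_bases))
  pka_u <- sel$pka
  pka_f <- switch(shift_profile,
    null = pka_u,
    udg_like = ifelse(sel$type == "acid" & pka_u <= 5, pka_u - 2.5,
                      ifelse(sel$type == "base" & pka_u >= 10, pka_u + 2.5,
                             pka_u)),
    random = pka_u + lcg_unif(lcg_new(seed), nrow(sel), -2, 2))
  titratable_sites(paste0(sel$residue, seq_len(nrow(sel))), sel$type,
                   pka_u, pka_f)
}
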