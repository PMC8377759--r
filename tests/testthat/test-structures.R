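test_that("PQR records parse field-by-field, with and without a chain id", {
  f <- withr::local_tempfile(fileext = ".pqr")
  writeLines(c("REMARK test",
               "ATOM 1 P DU B 5 1.0 2.0 3.0 -1.0000 1.9000",
               "ATOM 2 O1 DU 6 1.0 2.0 3.5 0.2500 1.5000"), f)
  s <- read_pqr(f)
  expect_equal(nrow(s$atoms), 2)
  expect_equal(s$atoms$charge[1], -1.0)
  expect_equal(s$atoms$radius[1], 1.9)
  expect_equal(s$atoms$chain, c("B", ""))  # blank chain column permitted
  expect_equal(s$atoms$resid, c(5L, 6L))
  expect_equal(s$atoms$name, c("P", "O1"))
})

test_that("malformed records fail with the offending line number", {
  f <- withr::local_tempfile(fileext = ".pqr")
  writeLines(c("ATOM 1 P DU B 5 1.0 2.0 3.0 -1.0 1.9",
               "ATOM 2 O1 DU B x 1.0 2.0 3.5 0.25 1.5"), f)
  expect_error(read_pqr(f), "line 2")
  writeLines("ATOM 1 P DU", f)
  expect_error(read_pqr(f), "line 1")
  expect_error(read_pqr(file.path(tempdir(), "no-such-file.pqr")),
               "not found")
})

test_that("HETATM and waters are dropped unless asked for", {
  f <- withr::local_tempfile(fileext = ".pqr")
  writeLines(c("ATOM 1 P DU B 5 1.0 2.0 3.0 -1.0 1.9",
               "HETATM 2 ZN ZN A 9 0.0 0.0 0.0 2.0 1.2",
               "ATOM 3 O HOH A 10 5.0 5.0 5.0 -0.8 1.5"), f)
  expect_equal(nrow(read_pqr(f)$atoms), 1)
  expect_equal(nrow(read_pqr(f, keep_hetatm = TRUE)$atoms), 3)
})

test_that("PQR round-trip is the identity and byte-stable", {
  s <- make_helix(5, base_index = 2)
  f1 <- withr::local_tempfile(fileext = ".pqr")
  f2 <- withr::local_tempfile(fileext = ".pqr")
  write_pqr(s, f1)
  r1 <- read_pqr(f1)
  expect_equal(r1$atoms[c("name", "resname", "resid", "chain")],
               s$atoms[c("name", "resname", "resid", "chain")])
  expect_equal(as.matrix(r1$atoms[c("x", "y", "z", "charge", "radius")]),
               as.matrix(s$atoms[c("x", "y", "z", "charge", "radius")]),
               tolerance = 1e-4)
  # fixed point after the first serialization: 3 cycles, identical bytes
  write_pqr(r1, f2)
  expect_identical(readLines(f1), readLines(f2))
  write_pqr(read_pqr(f2), f2)
  expect_identical(readLines(f1), readLines(f2))
  # formatting contract for unit charges
  expect_match(readLines(f1)[1], "-1\\.0000")
  expect_error(write_pqr(pqr_structure(fdpb:::empty_atoms()), f1), "empty")
})

test_that("PDB coordinates load with empty charges, agreeing with bio3d", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    sprintf("ATOM  %5d  CA  GLY A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
            1:3, 1:3, c(0, 3.8, 7.6), c(0, 0.5, -0.5), c(0, 1, 2)),
    "HETATM    4  O   HOH A   9      10.000  10.000  10.000  1.00  0.00           O",
    "END"), f)
  s <- read_pdb(f)
  expect_equal(nrow(s$atoms), 3)           # water dropped
  expect_true(all(s$atoms$charge == 0) && all(s$atoms$radius == 0))
  ref <- bio3d::read.pdb(f)
  expect_equal(s$atoms$x, ref$atom$x[ref$atom$type == "ATOM"])
  expect_equal(nrow(read_pdb(f, keep_hetatm = TRUE)$atoms), 4)
})

test_that("assign_charges recharges from the template and is idempotent", {
  s <- ru_fixture()
  expect_equal(net_charge(s), -1.0, tolerance = 1e-12)
  tmpl <- read_charge_template()
  expect_equal(assign_charges(s, tmpl)$atoms, s$atoms)
  # template net-charge bookkeeping matches its members
  for (rn in names(tmpl$net))
    expect_equal(tmpl$net[[rn]],
                 sum(tmpl$table$charge[tmpl$table$resname == rn]),
                 tolerance = 1e-6)
  # unknown residue/atom names are reported
  bad <- s
  bad$atoms$name[2] <- "XX"
  expect_error(assign_charges(bad, tmpl), "RU:XX")
})

test_that("residue mutation swaps charges in place and is an involution", {
  tmpl <- read_charge_template()
  s <- ru_fixture()
  m <- mutate_residue(s, "B", 5L, "C", tmpl)
  expect_equal(m$atoms$resname, rep("C", 6))
  expect_equal(m$atoms[c("x", "y", "z")], s$atoms[c("x", "y", "z")])
  expect_equal(net_charge(m), -1.0, tolerance = 1e-12)  # same net charge
  expect_false(isTRUE(all.equal(m$atoms$charge, s$atoms$charge)))
  expect_match(m$provenance[length(m$provenance)], "RU -> C")
  # back-mutation restores the original charges
  back <- mutate_residue(m, "B", 5L, "RU", tmpl)
  expect_equal(back$atoms$charge, s$atoms$charge, tolerance = 1e-6)
  # identity mutation only touches provenance
  idm <- mutate_residue(s, "B", 5L, "RU", tmpl)
  expect_equal(idm$atoms, s$atoms)
  # too small a common scaffold is refused
  tiny <- select_group(s, list(name = c("P", "O1")))
  expect_error(mutate_residue(tiny, "B", 5L, "C", tmpl), "matched")
})

test_that("selections subset, complement and partition the structure", {
  s <- make_helix(6, base_index = 3)
  pocketless <- select_group(s, "flipped_base", invert = TRUE)
  flip <- select_group(s, "flipped_base")
  expect_equal(nrow(flip$atoms) + nrow(pocketless$atoms), nrow(s$atoms))
  expect_equal(rbind(flip$atoms, pocketless$atoms)[order(c(
    which(fdpb:::resolve_selection(s, "flipped_base")),
    which(!fdpb:::resolve_selection(s, "flipped_base")))), ],
    s$atoms, ignore_attr = TRUE)
  # residue-id range query agrees with a brute-force filter
  sel <- select_group(s, list(chain = "A", resid = 2:4))
  brute <- s$atoms[s$atoms$chain == "A" & s$atoms$resid %in% 2:4, ]
  expect_equal(sel$atoms, brute, ignore_attr = TRUE)
  # empty selection is allowed
  expect_equal(nrow(select_group(s, list(chain = "Z"))$atoms), 0)
})

test_that("mass centers are mass-weighted with element fallbacks", {
  two <- pqr_structure(data.frame(name = c("C1", "C2"), resname = "ION",
                                  resid = 1:2, chain = "A",
                                  x = c(-1, 1), y = 0, z = 0,
                                  charge = 0, radius = 1))
  expect_equal(mass_center(two), c(0, 0, 0))
  one <- select_group(two, list(resid = 1L))
  expect_equal(mass_center(one), c(-1, 0, 0))
  co <- pqr_structure(data.frame(name = c("C1", "O1"), resname = "ION",
                                 resid = 1:2, chain = "A",
                                 x = c(0, 2), y = 0, z = 0,
                                 charge = 0, radius = 1))
  expect_equal(mass_center(co)[1], 2 * 15.999 / (12.011 + 15.999),
               tolerance = 1e-6)
  expect_equal(mass_center(co)[1], 2 * 16 / (12 + 16), tolerance = 1e-3)
  expect_equal(mass_center(co, geometric = TRUE)[1], 1)
  expect_error(mass_center(select_group(co, list(chain = "Z"))), "empty")
})

test_that("net charge sums and is additive over disjoint selections", {
  s <- make_helix(6, base_index = 3)
  parts <- lapply(c("A", "B"), function(ch) select_group(s, list(chain = ch)))
  expect_equal(sum(vapply(parts, net_charge, 0)), net_charge(s))
  expect_equal(net_charge(select_group(s, list(chain = "Z"))), 0)
  dimer <- make_dimer(1, -1, 5)
  expect_equal(net_charge(dimer), 0)
})

test_that("translations are exact, reversible and charge/shape preserving", {
  s <- make_helix(5, base_index = 2)
  v <- c(3.5, -2.25, 11)
  t1 <- translate_group(s, list(chain = "B"), v)
  expect_equal(translate_group(t1, list(chain = "B"), -v)$atoms[c("x", "y", "z")],
               s$atoms[c("x", "y", "z")], tolerance = 1e-9)
  expect_equal(net_charge(t1), net_charge(s))
  # mass center of the moved group shifts by exactly v
  mc0 <- mass_center(select_group(s, list(chain = "B")))
  mc1 <- mass_center(select_group(t1, list(chain = "B")))
  expect_equal(mc1 - mc0, v, tolerance = 1e-12)
  # intra-group pairwise distances are preserved
  p0 <- as.matrix(select_group(s, list(chain = "B"))$atoms[, c("x", "y", "z")])
  p1 <- as.matrix(select_group(t1, list(chain = "B"))$atoms[, c("x", "y", "z")])
  expect_equal(as.numeric(dist(p0)), as.numeric(dist(p1)), tolerance = 1e-12)
  # zero translation is the identity on coordinates
  expect_equal(translate_group(s, NULL, c(0, 0, 0))$atoms, s$atoms)
})
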