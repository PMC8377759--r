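#' Atomic structure with partial charges and radii
#'
#' Constructs a `pqr_structure`, the package's container for an ordered set
#' of atoms carrying coordinates (Angstrom), partial charges (e) and radii
#' (Angstrom), grouped by chain and residue. The (chain, residue id, atom
#' name) triple must be unique and iteration order is the row order of
#' `atoms`.
#'
#' @param atoms data.frame with columns `name`, `resname`, `resid`, `chain`,
#'   `x`, `y`, `z`, `charge`, `radius`.
#' @param provenance character vector recording edits (mutations,
#'   translations) applied to the structure.
#' @param groups named list of selections (each a list with any of `chain`,
#'   `resid`, `resname`, `name` fields) labelling functional groups such as a
#'   binding pocket; used by [select_group()].
#' @return An object of class `pqr_structure`.
#' @export
pqr_structure <- function(atoms, provenance = character(), groups = list()) {
  req <- c("name", "resname", "resid", "chain", "x", "y", "z", "charge", "radius")
  missing_cols <- setdiff(req, names(atoms))
  if (length(missing_cols))
    stop("atoms is missing columns: ", paste(missing_cols, collapse = ", "))
  atoms <- as.data.frame(atoms)[req]
  atoms$name <- as.character(atoms$name)
  atoms$resname <- as.character(atoms$resname)
  atoms$chain <- as.character(atoms$chain)
  atoms$resid <- as.integer(atoms$resid)
  for (cc in c("x", "y", "z", "charge", "radius"))
    atoms[[cc]] <- as.numeric(atoms[[cc]])
  if (nrow(atoms)) {
    if (any(!is.finite(as.matrix(atoms[c("x", "y", "z")]))))
      stop("atom coordinates must be finite")
    if (any(atoms$radius < 0)) stop("atom radii must be >= 0")
    key <- paste(atoms$chain, atoms$resid, atoms$name, sep = "\r")
    if (anyDuplicated(key))
      stop("duplicate (chain, residue_id, atom name) triples: ",
           paste(unique(key[duplicated(key)]), collapse = "; "))
  }
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, provenance = as.character(provenance),
                 groups = groups),
            class = "pqr_structure")
}

#' @export
print.pqr_structure <- function(x, ...) {
  a <- x$atoms
  cat(sprintf("pqr_structure: %d atoms, %d residues, net charge %+0.4f e\n",
              nrow(a), n_residues(x), net_charge(x)))
  if (nrow(a)) {
    ch <- sort(unique(a$chain))
    cat("  chains: ", paste(ifelse(ch == "", "(blank)", ch), collapse = ", "),
        "\n", sep = "")
  }
  if (length(x$groups))
    cat("  groups: ", paste(names(x$groups), collapse = ", "), "\n", sep = "")
  if (length(x$provenance))
    cat("  provenance:\n", paste("   -", x$provenance, collapse = "\n"), "\n")
  invisible(x)
}

n_residues <- function(structure) {
  a <- structure$atoms
  if (!nrow(a)) return(0L)
  length(unique(paste(a$chain, a$resid, sep = "\r")))
}

#' @export
as.data.frame.pqr_structure <- function(x, ...) x$atoms

water_resnames <- c("HOH", "WAT", "TIP3", "TIP", "SOL", "H2O")

#' Read a whitespace-delimited PQR file
#'
#' Parses the PDB2PQR whitespace dialect: each ATOM/HETATM record holds
#' record type, serial, atom name, residue name, an optional chain id,
#' residue id, x, y, z, charge, radius. The chain column may be absent
#' (blank chain); charges and radii are taken from the last two fields.
#' HETATM records and water residues are dropped by default, mirroring the
#' usual implicit-solvent preparation step.
#'
#' @param path file to read.
#' @param keep_hetatm keep HETATM records and water residues (default FALSE).
#' @return A [pqr_structure()].
#' @export
read_pqr <- function(path, keep_hetatm = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  isrec <- grepl("^(ATOM|HETATM)", lines)
  recs <- lines[isrec]
  lineno <- which(isrec)
  if (!length(recs))
    return(pqr_structure(empty_atoms()))
  parse_one <- function(ln, no) {
    tok <- strsplit(trimws(ln), "[[:space:]]+")[[1]]
    if (length(tok) < 10)
      stop(sprintf("malformed PQR record at line %d: expected >= 10 fields, got %d",
                   no, length(tok)))
    n <- length(tok)
    num <- suppressWarnings(as.numeric(tok[(n - 4):n]))
    resid <- suppressWarnings(as.integer(tok[n - 5]))
    if (any(is.na(num)) || is.na(resid))
      stop(sprintf("malformed PQR record at line %d: non-numeric field", no))
    chain <- if (n - 6 >= 5) tok[5] else ""
    list(rec = tok[1], name = tok[3], resname = tok[4], chain = chain,
         resid = resid, x = num[1], y = num[2], z = num[3],
         charge = num[4], radius = num[5])
  }
  parsed <- mapply(parse_one, recs, lineno, SIMPLIFY = FALSE)
  a <- data.frame(
    name = vapply(parsed, `[[`, "", "name"),
    resname = vapply(parsed, `[[`, "", "resname"),
    resid = vapply(parsed, `[[`, 0L, "resid"),
    chain = vapply(parsed, `[[`, "", "chain"),
    x = vapply(parsed, `[[`, 0, "x"),
    y = vapply(parsed, `[[`, 0, "y"),
    z = vapply(parsed, `[[`, 0, "z"),
    charge = vapply(parsed, `[[`, 0, "charge"),
    radius = vapply(parsed, `[[`, 0, "radius"),
    stringsAsFactors = FALSE)
  rectype <- vapply(parsed, `[[`, "", "rec")
  if (!keep_hetatm) {
    drop <- rectype == "HETATM" | toupper(a$resname) %in% water_resnames
    a <- a[!drop, , drop = FALSE]
  }
  pqr_structure(a)
}

empty_atoms <- function() {
  data.frame(name = character(), resname = character(), resid = integer(),
             chain = character(), x = numeric(), y = numeric(), z = numeric(),
             charge = numeric(), radius = numeric(), stringsAsFactors = FALSE)
}

#' Write a structure as a whitespace-delimited PQR file
#'
#' Serializes with charge then radius as the final fields, four decimals on
#' all numeric fields; formatting is deterministic so a write/read/write
#' cycle is byte-stable after the first write.
#'
#' @param structure a [pqr_structure()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_pqr <- function(structure, path) {
  a <- structure$atoms
  if (!nrow(a)) stop("refusing to write an empty structure")
  lines <- sprintf("ATOM  %5d %-4s %-4s %s %4d %11.4f %11.4f %11.4f %8.4f %8.4f",
                   seq_len(nrow(a)), a$name, a$resname,
                   ifelse(a$chain == "", " ", a$chain),
                   a$resid, a$x, a$y, a$z, a$charge, a$radius)
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Read atom coordinates from a PDB file
#'
#' Reads ATOM/HETATM coordinates only (via bio3d); charges and radii are set
#' to 0 and are expected to be filled in with [assign_charges()] from a
#' charge template. Waters/HETATM are dropped by default.
#'
#' @inheritParams read_pqr
#' @return A [pqr_structure()] with zero charges and radii.
#' @export
read_pdb <- function(path, keep_hetatm = FALSE) {
  if (!requireNamespace("bio3d", quietly = TRUE))
    stop("read_pdb requires the bio3d package")
  pdb <- bio3d::read.pdb(path)
  at <- pdb$atom  # bio3d names: elety = atom name, resid = residue name
  if (!keep_hetatm) {
    drop <- at$type == "HETATM" | toupper(at$resid) %in% water_resnames
    at <- at[!drop, , drop = FALSE]
  }
  n <- nrow(at)
  a <- data.frame(name = at$elety, resname = at$resid,
                  resid = as.integer(at$resno),
                  chain = ifelse(is.na(at$chain), "", at$chain),
                  x = at$x, y = at$y, z = at$z,
                  charge = rep(0, n), radius = rep(0, n),
                  stringsAsFactors = FALSE)
  pqr_structure(a, provenance = paste("read coordinates from", basename(path)))
}

#' Read a charge/radius template table
#'
#' A template maps (residue name, atom name) to (partial charge, radius) and
#' records each residue's net charge. The packaged template
#' (`system.file("extdata", "charge_templates.tsv", package = "fdpb")`)
#' covers the synthetic pseudo-nucleotides (`DN`, `RU`, `C`) and single-atom
#' charged amino-acid sites.
#'
#' @param path tab/whitespace separated file with columns
#'   `resname atom charge radius`; `NULL` loads the packaged template.
#' @return A `charge_template` object.
#' @export
read_charge_template <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "charge_templates.tsv", package = "fdpb")
  tab <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
  req <- c("resname", "atom", "charge", "radius")
  if (!all(req %in% names(tab)))
    stop("template must have columns: ", paste(req, collapse = ", "))
  net <- tapply(tab$charge, tab$resname, sum)
  structure(list(table = tab, net = net), class = "charge_template")
}

#' @export
print.charge_template <- function(x, ...) {
  cat("charge_template:", length(x$net), "residues\n")
  for (rn in names(x$net))
    cat(sprintf("  %-4s net %+0.4f e (%d atoms)\n", rn, x$net[[rn]],
                sum(x$table$resname == rn)))
  invisible(x)
}

template_lookup <- function(template, resname, atom) {
  i <- match(paste(resname, atom, sep = "\r"),
             paste(template$table$resname, template$table$atom, sep = "\r"))
  i
}

#' Assign charges and radii from a template
#'
#' Overwrites every atom's charge and radius by (residue name, atom name)
#' lookup. The operation is idempotent.
#'
#' @param structure a [pqr_structure()].
#' @param template a `charge_template` from [read_charge_template()].
#' @return The recharged structure.
#' @export
assign_charges <- function(structure, template) {
  a <- structure$atoms
  if (!nrow(a)) return(structure)
  i <- template_lookup(template, a$resname, a$name)
  if (anyNA(i)) {
    bad <- unique(paste0(a$resname, ":", a$name)[is.na(i)])
    stop("template has no entry for: ", paste(bad, collapse = ", "))
  }
  a$charge <- template$table$charge[i]
  a$radius <- template$table$radius[i]
  structure$atoms <- a
  structure
}

#' Mutate a residue by charge-template swap
#'
#' Retypes a residue to `new_resname`: atoms whose names exist in the new
#' template keep their coordinates and take the template's charges/radii;
#' residue atoms absent from the new template are dropped with a warning.
#' Only charges enter the Poisson-Boltzmann source term, so no geometry is
#' rebuilt. The mutation is recorded in the provenance.
#'
#' @param structure a [pqr_structure()].
#' @param chain,resid identify the target residue.
#' @param new_resname residue name to mutate to (must exist in `template`).
#' @param template a `charge_template`.
#' @return The mutated structure.
#' @export
mutate_residue <- function(structure, chain, resid, new_resname, template) {
  a <- structure$atoms
  sel <- a$chain == chain & a$resid == resid
  if (!any(sel)) stop(sprintf("no residue %s/%d in structure", chain, resid))
  if (!new_resname %in% template$table$resname)
    stop("template has no residue ", new_resname)
  tmpl_atoms <- template$table$atom[template$table$resname == new_resname]
  res_atoms <- a$name[sel]
  matched <- intersect(res_atoms, tmpl_atoms)
  if (length(matched) < 3)
    stop(sprintf("cannot mutate %s/%d to %s: only %d matched atom names (need >= 3)",
                 chain, resid, new_resname, length(matched)))
  unmatched <- setdiff(res_atoms, tmpl_atoms)
  if (length(unmatched)) {
    warning(sprintf("mutation %s/%d -> %s drops unmatched atoms: %s",
                    chain, resid, new_resname,
                    paste(unmatched, collapse = ", ")))
    a <- a[!(sel & a$name %in% unmatched), , drop = FALSE]
    sel <- a$chain == chain & a$resid == resid
  }
  old_resname <- a$resname[sel][1]
  a$resname[sel] <- new_resname
  i <- template_lookup(template, a$resname[sel], a$name[sel])
  a$charge[sel] <- template$table$charge[i]
  a$radius[sel] <- template$table$radius[i]
  structure$atoms <- a
  structure$provenance <- c(structure$provenance,
                            sprintf("mutated %s/%d %s -> %s", chain, resid,
                                    old_resname, new_resname))
  structure
}

resolve_selection <- function(structure, selection) {
  a <- structure$atoms
  if (is.null(selection)) return(rep(TRUE, nrow(a)))
  if (is.character(selection) && length(selection) == 1 &&
      selection %in% names(structure$groups))
    selection <- structure$groups[[selection]]
  if (is.logical(selection)) {
    stopifnot(length(selection) == nrow(a))
    return(selection)
  }
  if (is.numeric(selection)) {
    keep <- rep(FALSE, nrow(a))
    keep[as.integer(selection)] <- TRUE
    return(keep)
  }
  if (!is.list(selection))
    stop("selection must be a group name, index vector, logical mask or list")
  keep <- rep(TRUE, nrow(a))
  if (!is.null(selection$chain)) keep <- keep & a$chain %in% selection$chain
  if (!is.null(selection$resid)) keep <- keep & a$resid %in% selection$resid
  if (!is.null(selection$resname)) keep <- keep & a$resname %in% selection$resname
  if (!is.null(selection$name)) keep <- keep & a$name %in% selection$name
  keep
}

#' Select a subset of atoms
#'
#' `selection` may be a named group recorded on the structure (e.g. the
#' generator-labelled `"pocket"`), a list of predicates over chain /
#' residue id / residue name / atom name, an explicit index vector, or a
#' logical mask. Order is preserved; an empty result is allowed.
#'
#' @param structure a [pqr_structure()].
#' @param selection see Details.
#' @param invert select the complement.
#' @return A [pqr_structure()] view of the selected atoms.
#' @export
select_group <- function(structure, selection, invert = FALSE) {
  keep <- resolve_selection(structure, selection)
  if (invert) keep <- !keep
  pqr_structure(structure$atoms[keep, , drop = FALSE],
                provenance = structure$provenance,
                groups = structure$groups)
}

element_masses <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                    P = 30.97376, S = 32.06)

atom_masses <- function(names) {
  el <- toupper(substr(gsub("[^A-Za-z].*$", "", names), 1, 1))
  m <- element_masses[el]
  m[is.na(m)] <- 12.0
  unname(m)
}

#' Mass center of an atom group
#'
#' Mass-weighted mean position; element masses are inferred from the first
#' alphabetic character of each atom name (H, C, N, O, P, S; anything else
#' counts 12.0). `geometric = TRUE` gives the unweighted centroid.
#'
#' @param group a [pqr_structure()] (typically from [select_group()]).
#' @param geometric use unit weights instead of masses.
#' @return Numeric length-3 vector (Angstrom).
#' @export
mass_center <- function(group, geometric = FALSE) {
  a <- group$atoms
  if (!nrow(a)) stop("mass_center of an empty group is undefined")
  w <- if (geometric) rep(1, nrow(a)) else atom_masses(a$name)
  c(sum(w * a$x), sum(w * a$y), sum(w * a$z)) / sum(w)
}

#' Net charge of an atom group
#'
#' @param group a [pqr_structure()].
#' @return Sum of partial charges (e); 0 for an empty group.
#' @export
net_charge <- function(group) {
  sum(group$atoms$charge)
}

#' Rigidly translate a selected atom group
#'
#' @param structure a [pqr_structure()].
#' @param selection as in [select_group()]; `NULL` moves every atom.
#' @param vector length-3 displacement (Angstrom).
#' @return The translated structure, with provenance updated.
#' @export
translate_group <- function(structure, selection, vector) {
  stopifnot(length(vector) == 3, all(is.finite(vector)))
  keep <- resolve_selection(structure, selection)
  a <- structure$atoms
  a$x[keep] <- a$x[keep] + vector[1]
  a$y[keep] <- a$y[keep] + vector[2]
  a$z[keep] <- a$z[keep] + vector[3]
  structure$atoms <- a
  structure$provenance <- c(structure$provenance,
                            sprintf("translated %d atoms by (%.3f, %.3f, %.3f)",
                                    sum(keep), vector[1], vector[2], vector[3]))
  structure
}

# Concatenate two structures (distinct chains expected).
combine_structures <- function(a, b) {
  pqr_structure(rbind(a$atoms, b$atoms),
                provenance = c(a$provenance, b$provenance),
                groups = c(a$groups, b$groups))
}
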