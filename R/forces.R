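#' Net electrostatic force of a source molecule on a probe group
#'
#' Solves the PBE with the source charges only (the probe is uncharged; by
#' default its cavity is also removed, i.e. the source sits in pure
#' solvent), then accumulates F_i = q_i E(r_i) over the probe atoms. This is
#' the qE approximation: dielectric-boundary and ionic pressure terms are
#' omitted, which is adequate at the >= 20 A separations probed here where
#' the qE term dominates.
#'
#' The axial component is the projection of the net force on the unit vector
#' from the source mass center to the probe mass center; a negative axial
#' component (force pointing back toward the source) is attractive.
#'
#' @param source charged [pqr_structure()] generating the field.
#' @param probe [pqr_structure()] whose atoms feel the field; must be
#'   disjoint from `source`.
#' @param config a [pbe_config()].
#' @param separation optional scalar recorded in the result (Angstrom).
#' @param keep_cavity include the probe's uncharged cavity in the
#'   dielectric/ion maps of the source solve.
#' @param grid optional `grid_spec`; by default one is built around
#'   source + probe.
#' @return A `force_record`: net force vector, magnitude, axial component
#'   (kT/(e A) acting on unit charges, i.e. kT/A), and an
#'   attractive/repulsive/none label.
#' @export
force_on_group <- function(source, probe, config = pbe_config(),
                           separation = NA_real_, keep_cavity = FALSE,
                           grid = NULL) {
  key <- function(s) paste(s$atoms$chain, s$atoms$resid, s$atoms$name)
  if (length(intersect(key(source), key(probe))))
    stop("source and probe atom sets must be disjoint")
  if (is.null(grid))
    grid <- build_grid(combine_structures(source, probe), config$spacing,
                       config$padding, config$max_dim)
  pg <- solve_pbe(source, grid, config,
                  cavity = if (keep_cavity) uncharged(probe) else NULL)
  E <- tryCatch(field_at(pg, atom_xyz(probe)), error = function(e)
    stop("probe atom in the boundary guard zone; increase the grid padding"))
  Fi <- E * probe$atoms$charge
  Fnet <- colSums(Fi)
  axis_vec <- mass_center(probe) - mass_center(source)
  axis_vec <- axis_vec / sqrt(sum(axis_vec^2))
  axial <- sum(Fnet * axis_vec)
  structure(list(separation = separation, force = Fnet,
                 magnitude = sqrt(sum(Fnet^2)), axial = axial,
                 label = classify_axial(axial), axis = axis_vec,
                 convergence = pg$convergence),
            class = "force_record")
}

uncharged <- function(structure) {
  structure$atoms$charge <- 0
  structure
}

classify_axial <- function(axial, dead_zone = 1e-9) {
  if (abs(axial) < dead_zone) "none"
  else if (axial < 0) "attractive"
  else "repulsive"
}

#' Classify a force record as attractive, repulsive or none
#'
#' Sign test on the axial force component with a dead zone of 1e-9:
#' attractive when the net force on the probe points back toward the source.
#'
#' @param record a `force_record`.
#' @return `"attractive"`, `"repulsive"` or `"none"`.
#' @export
classify_interaction <- function(record) {
  classify_axial(record$axial)
}

#' @export
print.force_record <- function(x, ...) {
  cat(sprintf("force_record: |F| %.4g kT/A, axial %+.4g (%s)",
              x$magnitude, x$axial, x$label))
  if (!is.na(x$separation)) cat(sprintf(" at +%.4g A", x$separation))
  cat("\n")
  invisible(x)
}

#' Separation-scan protocol
#'
#' Default distances follow the study protocol: 20 to 40 Angstrom in 4 A
#' steps, applied as displacement added to the bound pose along the
#' source-to-probe mass-center axis (so 0 is the bound pose itself).
#'
#' @param distances strictly increasing positive displacements, Angstrom.
#' @return A `scan_protocol` list.
#' @export
scan_protocol <- function(distances = seq(20, 40, by = 4)) {
  stopifnot(length(distances) >= 1, all(distances > 0),
            all(diff(distances) > 0))
  structure(list(distances = distances), class = "scan_protocol")
}

#' Mass-center separation scan
#'
#' Rigidly displaces the probe selection from its bound pose along the
#' source-to-probe mass-center axis by each protocol distance and evaluates
#' [force_on_group()] at every step. A failing distance is recorded as an
#' error entry and the scan continues.
#'
#' @param complex a [pqr_structure()] holding both molecules.
#' @param source_sel,probe_sel disjoint selections (see [select_group()]).
#' @param protocol a [scan_protocol()].
#' @param config a [pbe_config()].
#' @param keep_cavity passed to [force_on_group()].
#' @return A `force_scan`: list of `force_record`s (or error entries), with
#'   the axis and protocol attached.
#' @export
separation_scan <- function(complex, source_sel, probe_sel,
                            protocol = scan_protocol(),
                            config = pbe_config(), keep_cavity = FALSE) {
  source <- select_group(complex, source_sel)
  probe <- select_group(complex, probe_sel)
  if (!nrow(source$atoms) || !nrow(probe$atoms))
    stop("source and probe selections must be non-empty")
  axis_vec <- mass_center(probe) - mass_center(source)
  nrm <- sqrt(sum(axis_vec^2))
  if (nrm < 1e-9) stop("mass-center axis is degenerate")
  axis_vec <- axis_vec / nrm
  records <- lapply(protocol$distances, function(d) {
    probe_d <- translate_group(probe, NULL, d * axis_vec)
    tryCatch(force_on_group(source, probe_d, config, separation = d,
                            keep_cavity = keep_cavity),
             error = function(e) structure(list(separation = d,
                                                error = conditionMessage(e)),
                                           class = "force_record_error"))
  })
  structure(records, class = "force_scan", axis = axis_vec,
            protocol = protocol)
}

#' @export
print.force_scan <- function(x, ...) {
  cat(sprintf("force_scan: %d distances\n", length(x)))
  print(as.data.frame(x), row.names = FALSE)
  invisible(x)
}

#' Tabulate a force scan
#'
#' @param x a `force_scan`.
#' @param ... unused.
#' @return data.frame with columns distance_A, Fx, Fy, Fz, magnitude, axial,
#'   label (failed distances carry NA and label "error").
#' @export
as.data.frame.force_scan <- function(x, ...) {
  do.call(rbind, lapply(x, function(r) {
    if (inherits(r, "force_record_error"))
      data.frame(distance_A = r$separation, Fx = NA_real_, Fy = NA_real_,
                 Fz = NA_real_, magnitude = NA_real_, axial = NA_real_,
                 label = "error", stringsAsFactors = FALSE)
    else
      data.frame(distance_A = r$separation, Fx = r$force[1], Fy = r$force[2],
                 Fz = r$force[3], magnitude = r$magnitude, axial = r$axial,
                 label = r$label, stringsAsFactors = FALSE)
  }))
}

#' @export
plot.force_scan <- function(x, ...) {
  df <- as.data.frame(x)
  graphics::plot(df$distance_A, df$magnitude, type = "b", pch = 16,
                 xlab = "added separation (A)",
                 ylab = "|F| (kT/A)", ...)
  invisible(df)
}
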