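#' Titratable-site table
#'
#' Builds/validates a table of ionizable groups: a label, the acid/base sign
#' y (-1 for acids, +1 for bases), and the pKas of the unfolded and folded
#' states.
#'
#' @param label character identifiers.
#' @param type `"acid"` or `"base"` per site.
#' @param pka_unfolded,pka_folded pKa values (pH units).
#' @return data.frame of class `titratable_sites`.
#' @export
titratable_sites <- function(label, type, pka_unfolded, pka_folded) {
  type <- as.character(type)
  if (!all(type %in% c("acid", "base")))
    stop("site type must be \"acid\" or \"base\"")
  stopifnot(all(is.finite(pka_unfolded)), all(is.finite(pka_folded)))
  out <- data.frame(label = as.character(label), type = type,
                    y = ifelse(type == "acid", -1, +1),
                    pka_unfolded = pka_unfolded, pka_folded = pka_folded,
                    stringsAsFactors = FALSE)
  class(out) <- c("titratable_sites", "data.frame")
  out
}

#' Read a titratable-site table from CSV/TSV
#'
#' Expected columns: `label`, `type` (acid|base), `pka_unfolded`,
#' `pka_folded`.
#'
#' @param path file path.
#' @return A [titratable_sites()] table.
#' @export
read_sites <- function(path) {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  titratable_sites(tab$label, tab$type, tab$pka_unfolded, tab$pka_folded)
}

#' Model-compound pKa table
#'
#' Standard solution pKas used as unfolded-state defaults by the generators.
#'
#' @return data.frame with columns residue, type, pka.
#' @export
model_pkas <- function() {
  utils::read.csv(system.file("extdata", "model_pkas.csv", package = "fdpb"),
                  stringsAsFactors = FALSE)
}

site_charge_one <- function(y, pka, pH, form) {
  if (form == "standard") {
    x <- 10^(y * (pka - pH))
    y * x / (1 + x)
  } else {
    # literal printed form: always-positive term with an extra 2.3 factor
    # inside the base-10 exponent
    x <- 10^(-2.3 * y * (pH - pka))
    x / (1 + x)
  }
}

#' Charge of one titratable site at a given pH
#'
#' The default `"standard"` form is Henderson-Hasselbalch: charge = sign x
#' charged fraction, i.e. y * 10^(y (pKa - pH)) / (1 + 10^(y (pKa - pH))),
#' giving -0.5 e for an acid at pH = pKa. The `"as-printed"` form evaluates
#' the always-positive literal term with the extra 2.3 factor in the
#' exponent; it is provided for comparison because it contradicts the
#' acid/base sign convention (see the methods vignette).
#'
#' @param site one row of a [titratable_sites()] table (or a list with `y`
#'   and the relevant pKa fields).
#' @param pH pH value(s).
#' @param state `"unfolded"` or `"folded"` (selects the pKa).
#' @param form `"standard"` or `"as-printed"`.
#' @return Charge(s), e.
#' @export
site_charge <- function(site, pH, state = c("unfolded", "folded"),
                        form = c("standard", "as-printed")) {
  state <- match.arg(state)
  form <- match.arg(form)
  pka <- if (state == "folded") site$pka_folded else site$pka_unfolded
  site_charge_one(site$y, pka, pH, form)
}

#' Net-charge titration curve
#'
#' Pointwise sum of [site_charge()] over all sites on a pH grid.
#'
#' @param sites a [titratable_sites()] table (possibly empty).
#' @param state `"unfolded"` or `"folded"`.
#' @param grid strictly increasing pH grid (default 0 to 14, step 0.5).
#' @param form see [site_charge()].
#' @return A `titration_curve`: data.frame (pH, Q) with the state attached.
#' @export
net_charge_curve <- function(sites, state = c("unfolded", "folded"),
                             grid = seq(0, 14, by = 0.5),
                             form = c("standard", "as-printed")) {
  state <- match.arg(state)
  form <- match.arg(form)
  stopifnot(all(diff(grid) > 0))
  Q <- rep(0, length(grid))
  if (nrow(sites)) {
    pka <- if (state == "folded") sites$pka_folded else sites$pka_unfolded
    for (i in seq_len(nrow(sites)))
      Q <- Q + site_charge_one(sites$y[i], pka[i], grid, form)
  }
  structure(data.frame(pH = grid, Q = Q), state = state, form = form,
            class = c("titration_curve", "data.frame"))
}

#' pH-dependent relative folding energy
#'
#' Integrates the folded-minus-unfolded net-charge difference over pH
#' (trapezoidal rule on the grid):
#' Delta G(pH) = ln(10) R T  integral_0^pH (Q_f - Q_u) d pH,
#' with R = 1.9872e-3 kcal/(mol K) and T = 300 K, referenced to 0 kcal/mol
#' at pH 0. Lower values mean higher stability at that pH.
#'
#' @param sites a [titratable_sites()] table.
#' @param grid pH grid starting at 0 (default 0 to 14, step 0.5).
#' @param form see [site_charge()].
#' @param temperature Kelvin.
#' @return A `folding_energy` data.frame (pH, dG) with constants attached.
#' @export
folding_energy_curve <- function(sites, grid = seq(0, 14, by = 0.5),
                                 form = c("standard", "as-printed"),
                                 temperature = 300) {
  form <- match.arg(form)
  if (abs(grid[1]) > 1e-12)
    stop("pH grid must start at 0: the reference energy is defined there")
  qf <- net_charge_curve(sites, "folded", grid, form)$Q
  qu <- net_charge_curve(sites, "unfolded", grid, form)$Q
  dq <- qf - qu
  n <- length(grid)
  integral <- c(0, cumsum((dq[-1] + dq[-n]) / 2 * diff(grid)))
  dG <- log(10) * .const$R_gas * temperature * integral
  structure(data.frame(pH = grid, dG = dG),
            R = .const$R_gas, temperature = temperature, form = form,
            class = c("folding_energy", "data.frame"))
}

#' @export
plot.folding_energy <- function(x, ...) {
  graphics::plot(x$pH, x$dG, type = "l", xlab = "pH",
                 ylab = expression(Delta * G ~ "(kcal/mol)"), ...)
  invisible(x)
}

#' Detect the pH stability range of a folding-energy curve
#'
#' Returns the widest contiguous grid interval on which the relative folding
#' energy stays within `tolerance` of its minimum; ties break toward the
#' wider interval, then the lower pH.
#'
#' @param curve a `folding_energy` (or data.frame with pH, dG).
#' @param tolerance allowed excess over the minimum, kcal/mol (> 0).
#' @return Named numeric vector `c(pH_low, pH_high)`.
#' @export
stability_range <- function(curve, tolerance = 0.5) {
  stopifnot(tolerance > 0)
  ok <- curve$dG <= min(curve$dG) + tolerance
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  runs <- which(r$values)
  widths <- curve$pH[ends[runs]] - curve$pH[starts[runs]]
  best <- runs[order(-widths, curve$pH[starts[runs]])][1]
  c(pH_low = curve$pH[starts[best]], pH_high = curve$pH[ends[best]])
}
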