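# Boltzmann aggregation of per-pose free energies into binding-mode
# free energies and mode probabilities.
#
# A landscape is a long-format data.frame (class "dualbind_landscape")
# with columns k (structure replica index), z (A), phi (degrees in
# [-180, 180)), dG (kcal/mol) and allowed (logical; sterically
# forbidden or missing cells are allowed = FALSE). The mode free energy
# is
#   F_mode = -kB T log( sum_k sum_Z sum_{phi in mode}
#                       exp(-dG_k(Z, phi) / kB T) * [dG_k < E_c] )
# with mode I the phi interval (-90, 90) and mode II (90, 270),
# boundaries excluded. The ratio of mode probabilities is
#   p_I / p_II = exp(-(F_I - F_II) / kB T).

new_landscape <- function(df) {
  need <- c("k", "z", "phi", "dG", "allowed")
  stopifnot(all(need %in% names(df)))
  df <- as.data.frame(df)[, need]
  if (any(!is.finite(df$dG[df$allowed])))
    stop("non-finite dG on allowed cells")
  if (anyDuplicated(df[, c("k", "z", "phi")]))
    stop("duplicate (k, z, phi) grid cells")
  class(df) <- c("dualbind_landscape", "data.frame")
  df
}

#' Assemble an energy landscape from grid values
#'
#' @param k replica index (scalar or per-row vector)
#' @param z,phi grid coordinates (A, degrees in [-180, 180))
#' @param dG free energy per cell, kcal/mol
#' @param allowed logical mask (default all TRUE)
#' @return a `dualbind_landscape` data.frame
#' @export
energy_landscape <- function(k, z, phi, dG, allowed = TRUE) {
  new_landscape(data.frame(k = k, z = z, phi = phi, dG = dG,
                           allowed = allowed))
}

#' Read per-pose free-energy landscapes from a TSV file
#'
#' Expects columns k, z, phi, dG and optionally allowed (0/1 or
#' TRUE/FALSE; missing means all allowed).
#'
#' @param file path to a tab-separated table
#' @return a `dualbind_landscape`
#' @export
read_landscape <- function(file) {
  df <- read.table(file, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE)
  need <- c("k", "z", "phi", "dG")
  if (!all(need %in% names(df)))
    stop("landscape table must have columns k, z, phi, dG (missing: ",
         paste(setdiff(need, names(df)), collapse = ", "), ")")
  for (cn in need)
    if (!is.numeric(df[[cn]]))
      stop("non-numeric values in column '", cn, "'")
  if (!"allowed" %in% names(df)) df$allowed <- TRUE
  df$allowed <- as.logical(df$allowed)
  new_landscape(df)
}

#' Write a landscape to TSV
#'
#' @param x a `dualbind_landscape`
#' @param file output path
#' @return invisibly, the path
#' @export
write_landscape <- function(x, file) {
  write.table(as.data.frame(x), file, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(file)
}

#' Binding-mode phi intervals
#'
#' Mode I covers phi in (-90, 90) degrees and mode II the complementary
#' half-circle (90, 270); the boundaries belong to neither mode.
#'
#' @param phi angles in degrees (any wrap)
#' @param mode "I" or "II"
#' @return logical vector: phi strictly inside the mode interval
#' @export
in_mode <- function(phi, mode = c("I", "II")) {
  mode <- match.arg(mode)
  w <- ((phi + 180) %% 360) - 180  # wrap to [-180, 180)
  if (mode == "I") w > -90 & w < 90 else w > 90 | w < -90
}

# log(sum(exp(x))) without overflow; exact to machine precision
logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

#' Boltzmann mode free energy from per-pose landscapes
#'
#' Aggregates all replicas k, all Z values and all phi cells strictly
#' inside the mode interval, keeping only allowed cells with dG < E_c,
#' into F = -kB T log sum exp(-dG / kB T). Evaluated with a shifted
#' (log-sum-exp) sum so that deeply negative dG (|dG|/kBT ~ 65) cannot
#' overflow.
#'
#' @param landscape a `dualbind_landscape`
#' @param mode "I" or "II"
#' @param E_c energy cutoff in kcal/mol (states with dG >= E_c are
#'   excluded); default Inf keeps every allowed state
#' @param T temperature in kelvin
#' @return free energy in kcal/mol
#' @export
mode_free_energy <- function(landscape, mode = c("I", "II"), E_c = Inf,
                             T = 298) {
  mode <- match.arg(mode)
  g <- landscape$dG[landscape$allowed & in_mode(landscape$phi, mode) &
                      landscape$dG < E_c]
  if (length(g) == 0L)
    stop("no allowed states in mode ", mode, " below E_c = ", E_c)
  kT <- kB_kcal * T
  -kT * logsumexp(-g / kT)
}

#' Scan the mode free energy over energy cutoffs
#'
#' Evaluates F(E_c) over a cutoff grid and locates the saturation
#' plateau: the smallest E_c beyond which F changes by less than `tol`
#' over a `window`-wide stretch of cutoffs. The saturation value is F at
#' the largest cutoff.
#'
#' @param landscape a `dualbind_landscape`
#' @param mode "I" or "II"
#' @param E_c_values increasing cutoff grid (kcal/mol)
#' @param T temperature in kelvin
#' @param tol plateau tolerance, kcal/mol (default 0.05)
#' @param window width of the plateau test window, kcal/mol (default 5)
#' @return list with `curve` (data.frame E_c, F; F is NA where no state
#'   passes the cutoff), `saturation` (F at max E_c) and
#'   `plateau_onset` (smallest plateau E_c, or NA)
#' @export
saturation_scan <- function(landscape, mode = c("I", "II"), E_c_values,
                            T = 298, tol = 0.05, window = 5) {
  mode <- match.arg(mode)
  if (length(E_c_values) == 0L) stop("empty E_c grid")
  E_c_values <- sort(E_c_values)
  F_vals <- vapply(E_c_values, function(ec) {
    tryCatch(mode_free_energy(landscape, mode, ec, T), error = function(e) NA_real_)
  }, numeric(1))
  curve <- data.frame(E_c = E_c_values, F = F_vals)
  sat <- F_vals[length(F_vals)]
  onset <- NA_real_
  ok <- which(!is.na(F_vals))
  for (i in ok) {
    idx <- which(E_c_values >= E_c_values[i] &
                   E_c_values <= E_c_values[i] + window)
    if (all(!is.na(F_vals[idx])) &&
        max(abs(diff(F_vals[idx])), 0) < tol &&
        abs(F_vals[i] - sat) < tol) {
      onset <- E_c_values[i]
      break
    }
  }
  list(curve = curve, saturation = sat, plateau_onset = onset)
}

#' Mode probabilities from the two binding free energies
#'
#' p_I / p_II = exp(-(F_I - F_II) / kB T), normalized so that
#' p_I + p_II = 1.
#'
#' @param F_I,F_II mode free energies in kcal/mol
#' @param T temperature in kelvin
#' @return list with `ratio`, `p_I`, `p_II`
#' @export
probability_ratio <- function(F_I, F_II, T = 298) {
  stopifnot(is.finite(F_I), is.finite(F_II), T > 0)
  ratio <- exp(-(F_I - F_II) / (kB_kcal * T))
  list(ratio = ratio, p_I = ratio / (1 + ratio), p_II = 1 / (1 + ratio))
}

#' Per-mode landscape minima
#'
#' Minimum dG and its (z, phi) location over the allowed cells of a
#' mode, reported per replica k and pooled.
#'
#' @param landscape a `dualbind_landscape`
#' @param mode "I" or "II"
#' @return list with `overall` (dG_min, z, phi, k) and `per_k`
#'   (data.frame, one row per replica)
#' @export
minimum_report <- function(landscape, mode = c("I", "II")) {
  mode <- match.arg(mode)
  sub <- landscape[landscape$allowed & in_mode(landscape$phi, mode), ,
                   drop = FALSE]
  if (nrow(sub) == 0L) stop("no allowed states in mode ", mode)
  per_k <- do.call(rbind, lapply(split(sub, sub$k), function(d) {
    i <- which.min(d$dG)
    data.frame(k = d$k[i], dG_min = d$dG[i], z = d$z[i], phi = d$phi[i])
  }))
  rownames(per_k) <- NULL
  i <- which.min(sub$dG)
  list(overall = data.frame(k = sub$k[i], dG_min = sub$dG[i],
                            z = sub$z[i], phi = sub$phi[i]),
       per_k = per_k)
}

#' Reported saturation binding free energies of the cohesin-dockerin systems
#'
#' Literature-reported saturation values of the mode free energies
#' F_I and F_II (kcal/mol, T = 298 K) for the type-I cohesin-dockerin
#' complex of *C. thermocellum*: the wild-type and the S45A/T46A
#' double-mutant dockerin, each without the terminal tails (residues
#' 1-56) and with them (residues -5 through 64 modeled). These are
#' external reference inputs for the mode-probability analysis, not
#' values computed by this package.
#'
#' @return data.frame with columns system, tails, F_I, F_II (kcal/mol)
#' @export
reported_free_energies <- function() {
  data.frame(
    system = c("WT", "mutant", "WT", "mutant"),
    tails = c(FALSE, FALSE, TRUE, TRUE),
    F_I = c(-38.5, -35.9, -29.2, -29.6),
    F_II = c(-35.3, -34.0, -30.2, -32.4),
    stringsAsFactors = FALSE)
}
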