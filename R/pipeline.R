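# End-to-end composition of the analysis stages with a reproducible
# run manifest. All randomness flows from one root seed through
# per-stage derived seeds, recorded in the manifest.

#' Run the dual-binding landscape analysis
#'
#' Composes landscape input (a TSV file or a synthetic landscape spec),
#' the per-mode cutoff saturation scan, and the mode-probability report
#' at the requested temperatures.
#'
#' @param landscape a `dualbind_landscape`, or a path to a landscape TSV
#' @param T_values temperatures in kelvin (default c(298, 308))
#' @param E_c_values cutoff scan grid (default -45 to -5 by 0.5)
#' @param seed root seed (recorded; the stage itself is deterministic)
#' @param out_dir optional output directory (JSON summary + TSV curves)
#' @return list of class `dualbind_run_manifest`: config, per-T results
#'   (F_I, F_II, ratio, p_I, plateau onsets, minima) and file paths
#' @export
run_dual_binding_analysis <- function(landscape,
                                      T_values = c(298, 308),
                                      E_c_values = seq(-45, -5, by = 0.5),
                                      seed = 1L, out_dir = NULL) {
  if (is.character(landscape)) landscape <- read_landscape(landscape)
  stopifnot(inherits(landscape, "dualbind_landscape"))
  results <- lapply(T_values, function(Tk) {
    scan_I <- saturation_scan(landscape, "I", E_c_values, T = Tk)
    scan_II <- saturation_scan(landscape, "II", E_c_values, T = Tk)
    if (is.na(scan_I$saturation))
      stop("empty mode I region: no allowed states under any cutoff")
    if (is.na(scan_II$saturation))
      stop("empty mode II region: no allowed states under any cutoff")
    pr <- probability_ratio(scan_I$saturation, scan_II$saturation, T = Tk)
    list(T = Tk, F_I = scan_I$saturation, F_II = scan_II$saturation,
         plateau_onset_I = scan_I$plateau_onset,
         plateau_onset_II = scan_II$plateau_onset,
         ratio = pr$ratio, p_I = pr$p_I, p_II = pr$p_II,
         curve_I = scan_I$curve, curve_II = scan_II$curve)
  })
  names(results) <- paste0("T", T_values)
  minima <- list(I = minimum_report(landscape, "I"),
                 II = minimum_report(landscape, "II"))
  manifest <- structure(list(
    stage = "dual_binding_analysis",
    config = list(T_values = T_values, E_c_range = range(E_c_values),
                  seed = seed, n_cells = nrow(landscape),
                  k_set = sort(unique(landscape$k))),
    package_version = as.character(utils::packageVersion("dualbind")),
    results = results, minima = minima),
    class = "dualbind_run_manifest")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    summary <- lapply(results, function(r) {
      r[c("T", "F_I", "F_II", "ratio", "p_I", "p_II",
          "plateau_onset_I", "plateau_onset_II")]
    })
    jsonlite::write_json(summary, file.path(out_dir, "binding_report.json"),
                         auto_unbox = TRUE, digits = NA)
    for (nm in names(results)) {
      write.table(results[[nm]]$curve_I,
                  file.path(out_dir, paste0("curve_I_", nm, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      write.table(results[[nm]]$curve_II,
                  file.path(out_dir, paste0("curve_II_", nm, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
    manifest$files <- list.files(out_dir)
  }
  manifest
}

#' Run the coarse-grained mechanics suite on a structure
#'
#' Thermal stability (P0, Q over temperatures), thermal unfolding
#' (median t_u), and a pulling ensemble with long/short classification.
#' Scaled-down defaults suitable for toy systems; raise the counts for
#' production runs.
#'
#' @param structure a `dualbind_structure`
#' @param thermal_T,unfold_T temperature grids (eps/k_B)
#' @param n_traj trajectories per protocol stage
#' @param pull_n pulling trajectories
#' @param pull_v_p pulling speed (A/tau)
#' @param pull_max_d pulling displacement limit (A)
#' @param steps sampling steps per thermal trajectory
#' @param max_time unfolding time limit (tau)
#' @param seed root seed
#' @return list of class `dualbind_run_manifest` with thermal,
#'   unfolding, and pulling results
#' @export
run_mechanics_suite <- function(structure,
                                thermal_T = c(0.1, 0.3, 0.6, 0.9, 1.2),
                                unfold_T = c(1.2, 1.6, 2.0),
                                n_traj = 11L, pull_n = 5L,
                                pull_v_p = 5e-3, pull_max_d = 80,
                                steps = 20000L, max_time = 500,
                                seed = 1L) {
  map <- native_contacts(structure)
  topo <- build_topology(structure, map)
  thermal <- native_state_stats(topo, thermal_T, n_traj = n_traj,
                                steps = steps, seed = derive_seed(seed, 1L))
  unfold <- unfolding_times(topo, unfold_T, n_traj = n_traj,
                            max_time = max_time,
                            seed = derive_seed(seed, 2L))
  has_interface <- any(topo$contact_class == "interface")
  pulling <- NULL
  if (has_interface && pull_n > 0) {
    curves <- lapply(seq_len(pull_n), function(i) {
      pull(topo, v_p = pull_v_p, max_d = pull_max_d,
           seed = derive_seed(seed, 100L + i))
    })
    pulling <- scenario_report(curves)
    pulling$curves <- curves
  }
  structure(list(
    stage = "mechanics_suite",
    config = list(thermal_T = thermal_T, unfold_T = unfold_T,
                  n_traj = n_traj, pull_n = pull_n, pull_v_p = pull_v_p,
                  seed = seed,
                  n_contacts = length(topo$contact_i)),
    package_version = as.character(utils::packageVersion("dualbind")),
    contact_counts = contact_classes(map),
    thermal = thermal, T0 = attr(thermal, "T0"),
    unfolding = unfold, pulling = pulling),
    class = "dualbind_run_manifest")
}

#' @export
print.dualbind_run_manifest <- function(x, ...) {
  cat("dualbind run manifest:", x$stage, "\n")
  if (x$stage == "dual_binding_analysis") {
    for (r in x$results) {
      cat(sprintf(
        "  T = %g K: F_I = %.2f, F_II = %.2f kcal/mol, p_I/p_II = %.3g, p_I = %.3f\n",
        r$T, r$F_I, r$F_II, r$ratio, r$p_I))
    }
  } else {
    cat(sprintf("  %d native contacts; T0 = %s eps/k_B\n",
                x$config$n_contacts,
                ifelse(is.na(x$T0), "NA", sprintf("%.2f", x$T0))))
    if (!is.null(x$pulling))
      cat(sprintf("  pulling: %d curves, fraction long = %.2f\n",
                  x$pulling$n, x$pulling$fraction_long))
  }
  invisible(x)
}
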