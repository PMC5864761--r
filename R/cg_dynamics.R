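# Langevin dynamics protocols: equilibrium thermal stability (P0, Q),
# thermal unfolding times, and constant-speed pulling with
# force-extension analysis.
#
# Temperatures are in eps/k_B. The equations of motion
# m r'' = F - gamma r' + Gamma are integrated by the fifth-order Gear
# predictor-corrector with time step dt; the thermal noise has per-step
# standard deviation sqrt(2 gamma k_B T / dt) (the standard
# discretization of a noise process of dispersion sqrt(2 gamma k_B T)).

#' Langevin integration of a coarse-grained topology
#'
#' Runs `steps` integration steps from `start` (default: native
#' coordinates) and returns frames sampled every `stride` steps together
#' with kinetic and total energy and the native-contact fraction Q per
#' frame. Bit-reproducible for a fixed seed.
#'
#' @param topology a `dualbind_topology`
#' @param T temperature in eps/k_B
#' @param steps number of steps
#' @param stride sampling stride (steps)
#' @param start starting coordinates (n x 3)
#' @param seed RNG seed (set with [set.seed()] internally)
#' @param tethers optional harmonic restraints: list with `bead`
#'   (1-based indices), `anchor` (m x 3), `k` (spring constants)
#' @param gamma,dt override the topology's damping / time step
#' @return list of class `dualbind_trajectory`: frames (frames x 3n),
#'   kinetic, total_energy, q, time
#' @export
integrate_langevin <- function(topology, T = 0.3, steps = 10000L,
                               stride = 100L, start = topology$coords,
                               seed = NULL, tethers = NULL,
                               gamma = topology$params$gamma,
                               dt = topology$params$dt) {
  if (!is.null(seed)) set.seed(seed)
  out <- integrate_cpp(unclass(topology), as.matrix(start), T, gamma, dt,
                       as.integer(steps), as.integer(stride), tethers)
  out$n_beads <- nrow(topology$coords)
  class(out) <- "dualbind_trajectory"
  out
}

#' Equilibrium native-state statistics (P0 and Q)
#'
#' For each temperature runs `n_traj` independent trajectories
#' (equilibration followed by sampling) and pools frames across time and
#' trajectories. P0 is the fraction of frames in which every native
#' contact is present (r_ij < 1.5 sigma_ij) and Q the mean fraction of
#' native contacts present. Always P0 <= Q.
#'
#' @param topology a `dualbind_topology`
#' @param T_values temperatures in eps/k_B
#' @param n_traj trajectories per temperature
#' @param steps sampling steps per trajectory
#' @param equil_steps equilibration steps (not sampled)
#' @param stride frame sampling stride
#' @param seed root seed; trajectory seeds are derived from it
#' @return data.frame of class `dualbind_thermal`: T, P0, Q,
#'   mean_ke_per_dof, n_frames, n_traj; plus `T0` attribute (first
#'   linear-interpolated crossing of P0 = 1/2, NA if not bracketed)
#' @export
native_state_stats <- function(topology, T_values, n_traj = 21L,
                               steps = 20000L, equil_steps = 2000L,
                               stride = 100L, seed = 1L) {
  stopifnot(n_traj >= 1L)
  rows <- lapply(seq_along(T_values), function(ti) {
    acc <- c(n_frames = 0, n_all = 0, sum_q = 0, sum_ke = 0)
    for (tr in seq_len(n_traj)) {
      set.seed(derive_seed(seed, ti * 1000L + tr))
      r <- run_thermal_cpp(unclass(topology), T_values[ti],
                           topology$params$gamma, topology$params$dt,
                           as.integer(equil_steps), as.integer(steps),
                           as.integer(stride))
      acc <- acc + c(r$n_frames, r$n_all_present, r$sum_q,
                     r$mean_ke_per_dof * r$n_frames)
    }
    data.frame(T = T_values[ti], P0 = acc[["n_all"]] / acc[["n_frames"]],
               Q = acc[["sum_q"]] / acc[["n_frames"]],
               mean_ke_per_dof = acc[["sum_ke"]] / acc[["n_frames"]],
               n_frames = acc[["n_frames"]], n_traj = n_traj)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("dualbind_thermal", "data.frame")
  attr(out, "T0") <- crossing_half(out$T, out$P0)
  out
}

# first downward crossing of y = 1/2, linearly interpolated
crossing_half <- function(x, y) {
  ord <- order(x)
  x <- x[ord]; y <- y[ord]
  for (i in seq_len(length(x) - 1L)) {
    if (y[i] >= 0.5 && y[i + 1] < 0.5) {
      return(x[i] + (0.5 - y[i]) / (y[i + 1] - y[i]) * (x[i + 1] - x[i]))
    }
  }
  NA_real_
}

derive_seed <- function(root, k) {
  as.integer((as.numeric(root) * 7919 + as.numeric(k) * 104729) %% 2147483629)
}

#' Thermal unfolding times
#'
#' Unfolding trajectories start from the native state and end when all
#' nonlocal native contacts (sequence separation |i-j| > 4; ion contacts
#' count as nonlocal) are simultaneously broken, defining t_unf. The
#' characteristic time t_u is the median over trajectories, with
#' censored (never-unfolded) runs entering as +Inf -- the median is
#' finite only when more than half the runs unfold.
#'
#' @param topology a `dualbind_topology`
#' @param T_values temperatures in eps/k_B
#' @param n_traj trajectories per temperature
#' @param max_time trajectory length in tau
#' @param check_stride steps between unfolding checks
#' @param seed root seed
#' @return data.frame: T, t_u (tau), unfolded_fraction, n_traj; raw
#'   times in `attr(, "times")` (list per temperature)
#' @export
unfolding_times <- function(topology, T_values, n_traj = 31L,
                            max_time = 1000, check_stride = 20L, seed = 1L) {
  if (!any(as.logical(topology$contact_nonlocal)))
    warning("topology has no nonlocal contacts: unfolding is immediate")
  max_steps <- ceiling(max_time / topology$params$dt)
  all_times <- list()
  rows <- lapply(seq_along(T_values), function(ti) {
    tu <- vapply(seq_len(n_traj), function(tr) {
      set.seed(derive_seed(seed, ti * 100000L + tr))
      r <- run_unfold_cpp(unclass(topology), T_values[ti],
                          topology$params$gamma, topology$params$dt,
                          max_steps, as.integer(check_stride))
      if (r$unfolded) r$t_unf else Inf
    }, numeric(1))
    all_times[[ti]] <<- tu
    data.frame(T = T_values[ti], t_u = median(tu),
               unfolded_fraction = mean(is.finite(tu)), n_traj = n_traj)
  })
  out <- do.call(rbind, rows)
  attr(out, "times") <- all_times
  out
}

#' Constant-speed pulling of a complex
#'
#' Attaches harmonic springs (stiffness K) to the two attachment beads:
#' one spring is fixed in space, the other moves at constant speed v_p
#' along the line from the fixed to the pulled attachment. Starts from
#' the native state. The spring force is averaged over windows of 0.5 A
#' of spring displacement d = v_p t. A native contact is broken when
#' r_ij > 1.5 sigma_ij (re-formation allowed; the last break is what is
#' recorded). The run ends when all interface contacts have stayed
#' broken for `sustain` = 1 A of further displacement (dissociation), or
#' at `max_d`.
#'
#' @param topology a `dualbind_topology`
#' @param pulled_bead,fixed_bead 1-based bead indices of the attachment
#'   points; defaults: N-terminal beads of the last and first chain.
#'   `fixed_bead = NA` pulls with a single spring.
#' @param K spring constant (default 0.12 eps/A^2)
#' @param v_p pulling speed (default 5e-5 A/tau)
#' @param T temperature (default 0.3 eps/k_B)
#' @param max_d displacement limit (A)
#' @param window force-averaging window (A of spring displacement)
#' @param sustain sustained-breakage displacement defining dissociation
#' @param seed RNG seed
#' @return list of class `dualbind_force_extension`: d, F (windowed),
#'   F_max, last_break (data.frame contact, class, d), dissociation_d,
#'   final_d
#' @export
pull <- function(topology, pulled_bead = NULL, fixed_bead = NULL, K = 0.12,
                 v_p = 5e-5, T = 0.3, max_d = 100, window = 0.5,
                 sustain = 1, seed = 1L) {
  beads <- topology$beads
  chains <- unique(beads$chain[!beads$ion])
  if (is.null(fixed_bead))
    fixed_bead <- which(beads$chain == chains[1] & !beads$ion &
                          beads$seq_idx == 1L)[1]
  if (is.null(pulled_bead))
    pulled_bead <- which(beads$chain == chains[length(chains)] & !beads$ion &
                           beads$seq_idx == 1L)[1]
  if (!is.na(fixed_bead) && fixed_bead == pulled_bead)
    stop("pulling springs attached to the same bead")
  set.seed(seed)
  r <- run_pull_cpp(unclass(topology),
                    if (is.na(fixed_bead)) -1L else as.integer(fixed_bead - 1L),
                    as.integer(pulled_bead - 1L), K, v_p, T,
                    topology$params$gamma, topology$params$dt,
                    window, max_d, sustain)
  lb <- data.frame(contact = seq_along(topology$contact_i),
                   class = topology$contact_class,
                   d = r$last_break_d, first_d = r$first_break_d,
                   n_breaks = r$n_breaks)
  structure(list(d = r$window_d, F = r$window_F, F_max = r$F_max,
                 last_break = lb, dissociation_d = r$dissociation_d,
                 final_d = r$final_d,
                 K = K, v_p = v_p, T = T),
            class = "dualbind_force_extension")
}

#' @export
print.dualbind_force_extension <- function(x, ...) {
  cat(sprintf(paste0("dualbind force-extension curve: %d windows, ",
                     "F_max = %.3f eps/A, dissociation at %s A\n"),
              length(x$d), x$F_max,
              ifelse(is.na(x$dissociation_d), "NA",
                     sprintf("%.1f", x$dissociation_d))))
  invisible(x)
}

#' Classify a pulling trajectory as long or short
#'
#' Long trajectories extend past `threshold_d` of spring displacement
#' before final dissociation; short ones dissociate earlier.
#'
#' @param curve a `dualbind_force_extension` (or a bare dissociation
#'   displacement)
#' @param threshold_d classification threshold (A)
#' @return "long" or "short"
#' @export
classify_trajectory <- function(curve, threshold_d) {
  d <- if (inherits(curve, "dualbind_force_extension")) {
    if (is.na(curve$dissociation_d))
      stop("incomplete curve: dissociation not reached")
    curve$dissociation_d
  } else curve
  if (d >= threshold_d) "long" else "short"
}

#' Ensemble report for a set of pulling trajectories
#'
#' Classifies each curve long/short and reports the class fractions with
#' a binomial (Wilson) confidence interval, the F_max distribution, and
#' the median last-break displacement per contact class. When
#' `threshold_d` is NULL it is placed midway between the two modes of
#' the dissociation-displacement distribution (univariate 2-means).
#'
#' @param curves list of `dualbind_force_extension` objects
#' @param threshold_d long/short threshold (A), or NULL to derive it
#' @param conf confidence level for the fraction interval
#' @return list: n, threshold_d, fraction_long, ci_long (length 2),
#'   labels, F_max, break_table (data.frame class, median_last_break_d)
#' @export
scenario_report <- function(curves, threshold_d = NULL, conf = 0.95) {
  stopifnot(length(curves) >= 1L)
  dd <- vapply(curves, function(cu) {
    if (is.na(cu$dissociation_d)) cu$final_d else cu$dissociation_d
  }, numeric(1))
  if (is.null(threshold_d)) {
    threshold_d <- if (length(unique(dd)) >= 2L) {
      km <- tryCatch(kmeans(dd, centers = matrix(range(dd), 2, 1)),
                     error = function(e) NULL)
      if (is.null(km)) mean(range(dd)) else mean(km$centers)
    } else dd[1]
  }
  labels <- ifelse(dd >= threshold_d, "long", "short")
  n <- length(labels)
  p <- mean(labels == "long")
  zq <- stats::qnorm(1 - (1 - conf) / 2)
  ci <- (p + zq^2 / (2 * n) + c(-1, 1) * zq *
           sqrt(p * (1 - p) / n + zq^2 / (4 * n^2))) / (1 + zq^2 / n)
  breaks <- do.call(rbind, lapply(curves, function(cu) cu$last_break))
  bt <- if (!is.null(breaks) && nrow(breaks)) {
    agg <- stats::aggregate(d ~ class, data = breaks, FUN = median,
                            na.action = stats::na.omit)
    names(agg) <- c("class", "median_last_break_d")
    agg
  } else data.frame(class = character(0), median_last_break_d = numeric(0))
  list(n = n, threshold_d = threshold_d, fraction_long = p,
       ci_long = pmin(pmax(ci, 0), 1), labels = labels,
       F_max = vapply(curves, function(cu) cu$F_max, numeric(1)),
       dissociation_d = dd, break_table = bt)
}
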