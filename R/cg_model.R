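# The structure-based C-alpha Hamiltonian.
#
# Beads sit on the Calpha atoms (plus one bead per bound calcium ion).
# Sequence neighbors are tethered by stiff harmonic bonds; native
# contacts interact through 12-6 Lennard-Jones wells minimal at the
# native separation; all remaining pairs feel a truncated-shifted
# repulsion; and a harmonic term on the local chirality of each chain
# keeps the backbone right-handed. Reduced units: energy eps, length
# Angstrom, time tau, mass m = 1, k_B = 1.

#' Coarse-grained model parameters
#'
#' Defaults: bond constant 100 eps/A^2, repulsion range r0 = 4 A (so the
#' repulsive sigma is 4/2^(1/6)), chirality strength 1 eps, mass 1,
#' damping gamma = 2 m/tau (overdamped), time step 0.005 tau. `epsilon`
#' is the physical value of the energy unit (pN*A) used only for unit
#' conversion; internally all energies are in eps.
#'
#' @param k_bond bond spring constant, eps/A^2
#' @param r0_rep repulsion cutoff r0, A
#' @param chirality_strength chirality spring constant, eps
#' @param mass bead mass, m
#' @param gamma Langevin damping, m/tau
#' @param dt integration time step, tau
#' @param epsilon physical energy unit, pN*A
#' @return list of class `dualbind_cg_parameters`
#' @export
cg_parameters <- function(k_bond = 100, r0_rep = 4, chirality_strength = 1,
                          mass = 1, gamma = 2, dt = 0.005,
                          epsilon = eps_pN_A) {
  stopifnot(k_bond > 0, r0_rep > 0, chirality_strength >= 0, mass > 0,
            gamma >= 0, dt > 0)
  structure(list(k_bond = k_bond, epsilon_model = 1, r0_rep = r0_rep,
                 chirality_strength = chirality_strength, mass = mass,
                 gamma = gamma, dt = dt, epsilon = epsilon),
            class = "dualbind_cg_parameters")
}

#' Build a coarse-grained topology from a structure and its contact map
#'
#' One bead per residue at the Calpha position; calcium ions become
#' extra beads held only by their native contacts (no bonds, no
#' chirality). Bonds take their native lengths; contacts carry
#' sigma = r_native / 2^(1/6); chirality references are the native
#' scalar triple products of successive bond vectors, normalized by the
#' cube of the chain's mean native bond length.
#'
#' @param s a `dualbind_structure`
#' @param map contact map from [native_contacts()] on the same structure
#'   (default: computed here)
#' @param params a `dualbind_cg_parameters`
#' @param allow_breaks tolerate sequence-neighbor Calpha gaps > 4.5 A by
#'   splitting the chain there (default FALSE: error)
#' @return list of class `dualbind_topology`
#' @export
build_topology <- function(s, map = NULL, params = cg_parameters(),
                           allow_breaks = FALSE) {
  if (is.null(map)) map <- native_contacts(s)
  beads <- attr(map, "beads")
  if (is.null(beads)) beads <- bead_table(s)
  n <- nrow(beads)
  coords <- as.matrix(beads[, c("x", "y", "z")])
  bond_i <- integer(0); bond_j <- integer(0); bond_r0 <- numeric(0)
  q0 <- q1 <- q2 <- q3 <- integer(0)
  cnat <- d0 <- numeric(0)
  for (ch in unique(beads$chain[!beads$ion])) {
    idx <- which(beads$chain == ch & !beads$ion)
    idx <- idx[order(beads$seq_idx[idx])]
    if (length(idx) < 2L) next
    dvec <- sqrt(rowSums((coords[idx[-1], , drop = FALSE] -
                            coords[idx[-length(idx)], , drop = FALSE])^2))
    segs <- split_segments(idx, dvec, allow_breaks)
    for (seg in segs) {
      m <- length(seg)
      if (m < 2L) next
      bi <- seg[-m]; bj <- seg[-1]
      r0s <- sqrt(rowSums((coords[bj, , drop = FALSE] -
                             coords[bi, , drop = FALSE])^2))
      bond_i <- c(bond_i, bi); bond_j <- c(bond_j, bj)
      bond_r0 <- c(bond_r0, r0s)
      if (m >= 4L) {
        d0_seg <- mean(r0s)
        for (q in seq_len(m - 3L)) {
          a <- seg[q]; b <- seg[q + 1L]; cc <- seg[q + 2L]; dd <- seg[q + 3L]
          C <- triple_product(coords[b, ] - coords[a, ],
                              coords[cc, ] - coords[b, ],
                              coords[dd, ] - coords[cc, ]) / d0_seg^3
          q0 <- c(q0, a); q1 <- c(q1, b); q2 <- c(q2, cc); q3 <- c(q3, dd)
          cnat <- c(cnat, C); d0 <- c(d0, d0_seg)
        }
      }
    }
  }
  nonlocal <- map$class == "ion" |
    !(map$chain_i == map$chain_j &
        abs(beads$seq_idx[map$i] - beads$seq_idx[map$j]) <= 4 &
        !beads$ion[map$i] & !beads$ion[map$j])
  topo <- structure(list(
    coords = coords, beads = beads,
    bond_i = as.integer(bond_i - 1L), bond_j = as.integer(bond_j - 1L),
    bond_r0 = bond_r0,
    contact_i = as.integer(map$i - 1L), contact_j = as.integer(map$j - 1L),
    contact_sigma = map$sigma,
    contact_nonlocal = as.integer(nonlocal),
    contact_interface = as.integer(map$class == "interface"),
    contact_class = map$class,
    chir_q0 = as.integer(q0 - 1L), chir_q1 = as.integer(q1 - 1L),
    chir_q2 = as.integer(q2 - 1L), chir_q3 = as.integer(q3 - 1L),
    chir_native = cnat, chir_d0 = d0,
    params = unclass(params)),
    class = "dualbind_topology")
  topo
}

split_segments <- function(idx, dvec, allow_breaks) {
  breaks <- which(dvec > 4.5)
  if (length(breaks) && !allow_breaks)
    stop("chain break: consecutive Calpha distance ",
         sprintf("%.2f", max(dvec[breaks])),
         " A > 4.5 A (set allow_breaks = TRUE to split)")
  bounds <- c(0L, breaks, length(idx))
  lapply(seq_len(length(bounds) - 1L), function(k) {
    idx[(bounds[k] + 1L):bounds[k + 1L]]
  })
}

triple_product <- function(v1, v2, v3) {
  sum(c(v1[2] * v2[3] - v1[3] * v2[2],
        v1[3] * v2[1] - v1[1] * v2[3],
        v1[1] * v2[2] - v1[2] * v2[1]) * v3)
}

#' @export
print.dualbind_topology <- function(x, ...) {
  cat(sprintf(paste0("dualbind CG topology: %d beads, %d bonds, ",
                     "%d native contacts, %d chirality terms\n"),
              nrow(x$coords), length(x$bond_i), length(x$contact_i),
              length(x$chir_q0)))
  invisible(x)
}

#' Native-contact Lennard-Jones potential and force
#'
#' V(r) = 4 eps [ (sigma/r)^12 - (sigma/r)^6 ]; the minimum -eps sits at
#' r = 2^(1/6) sigma.
#'
#' @param r separation (A)
#' @param sigma contact length parameter (A)
#' @param epsilon well depth (eps units)
#' @return list with `energy` and `force` (-dV/dr), vectorized over r
#' @export
native_lj_energy <- function(r, sigma, epsilon = 1) {
  stopifnot(all(r > 0))
  s6 <- (sigma / r)^6
  list(energy = 4 * epsilon * (s6^2 - s6),
       force = 24 * epsilon * (2 * s6^2 - s6) / r)
}

#' Truncated-shifted repulsive potential
#'
#' The 12-6 potential with sigma = r0/2^(1/6), shifted up by eps and cut
#' at r0, so it is purely repulsive, zero at and beyond r0, and
#' continuous there.
#'
#' @param r separation (A)
#' @param r0 cutoff (default 4 A)
#' @param epsilon energy scale
#' @return energy (eps units), vectorized over r
#' @export
repulsive_energy <- function(r, r0 = 4, epsilon = 1) {
  stopifnot(all(r > 0))
  s6 <- (r0 / 2^(1/6) / r)^6
  ifelse(r < r0, 4 * epsilon * (s6^2 - s6) + epsilon, 0)
}

#' Chirality energy of a bead chain
#'
#' Sum over quadruplets of (kappa/2)(C_i - C_i^native)^2 with
#' C_i = [(v_i x v_{i+1}) . v_{i+2}] / d0^3 for successive bond vectors
#' v and native bond length d0.
#'
#' @param coords n x 3 coordinates of the chain beads (sequence order)
#' @param references native C values (default: recompute from `native`)
#' @param native native coordinates (used when `references` is NULL)
#' @param strength kappa (eps units)
#' @param d0 native bond length; default mean native bond length
#' @return total chirality energy
#' @export
chirality_energy <- function(coords, references = NULL, native = NULL,
                             strength = 1, d0 = NULL) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (n < 4L) stop("need at least 4 consecutive beads")
  if (is.null(references)) {
    if (is.null(native)) stop("supply either references or native coords")
    native <- as.matrix(native)
    if (is.null(d0))
      d0 <- mean(sqrt(rowSums((native[-1, ] - native[-n, ])^2)))
    references <- chain_chirality(native, d0)
  } else if (is.null(d0)) {
    d0 <- mean(sqrt(rowSums((coords[-1, ] - coords[-n, ])^2)))
  }
  C <- chain_chirality(coords, d0)
  sum(0.5 * strength * (C - references)^2)
}

chain_chirality <- function(coords, d0) {
  n <- nrow(coords)
  v <- coords[-1, , drop = FALSE] - coords[-n, , drop = FALSE]
  vapply(seq_len(n - 3L), function(i) {
    triple_product(v[i, ], v[i + 1, ], v[i + 2, ]) / d0^3
  }, numeric(1))
}

#' Total energy decomposition of a configuration
#'
#' @param topology a `dualbind_topology`
#' @param coords n x 3 coordinates (default: native)
#' @return list with bond, native, repulsive, chirality, total (eps)
#' @export
total_energy <- function(topology, coords = topology$coords) {
  out <- cg_eval_cpp(unclass(topology), as.matrix(coords), forces = FALSE)
  out[c("bond", "native", "repulsive", "chirality", "total")]
}

#' Analytic forces on every bead
#'
#' Negative gradient of the full Hamiltonian.
#'
#' @param topology a `dualbind_topology`
#' @param coords n x 3 coordinates (default: native)
#' @return n x 3 matrix of forces (eps/A)
#' @export
total_force <- function(topology, coords = topology$coords) {
  cg_eval_cpp(unclass(topology), as.matrix(coords), forces = TRUE)$forces
}

#' Serialize / read a topology as TSV sections
#'
#' Writes beads, bonds, contacts and chirality terms as tab-separated
#' blocks separated by `#` section headers.
#'
#' @param topology a `dualbind_topology`
#' @param file path
#' @return invisibly, the path
#' @export
write_topology <- function(topology, file) {
  con <- file(file, "w")
  on.exit(close(con))
  wt <- function(tag, df) {
    writeLines(paste0("# ", tag), con)
    write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  b <- topology$beads
  wt("beads", data.frame(chain = b$chain, resno = b$resno, ion = b$ion,
                         x = topology$coords[, 1], y = topology$coords[, 2],
                         z = topology$coords[, 3]))
  wt("bonds", data.frame(i = topology$bond_i + 1L, j = topology$bond_j + 1L,
                         r0 = topology$bond_r0))
  wt("contacts", data.frame(i = topology$contact_i + 1L,
                            j = topology$contact_j + 1L,
                            sigma = topology$contact_sigma,
                            class = topology$contact_class,
                            nonlocal = topology$contact_nonlocal))
  wt("chirality", data.frame(q0 = topology$chir_q0 + 1L,
                             q1 = topology$chir_q1 + 1L,
                             q2 = topology$chir_q2 + 1L,
                             q3 = topology$chir_q3 + 1L,
                             c_native = topology$chir_native,
                             d0 = topology$chir_d0))
  invisible(file)
}
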