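# Synthetic inputs: two-basin (Z, phi) free-energy landscapes with
# analytically known structure, toy helical proteins and two-body
# complexes with heavy-atom decorations (so the overlap criterion and
# the pulling protocol are exercised end to end), and known-rotation
# structure pairs for the symmetry-axis machinery.

#' Specify a Gaussian basin of a synthetic landscape
#'
#' @param z0,phi0 basin center (A, degrees)
#' @param depth basin depth in kcal/mol (negative)
#' @param sigma_z,sigma_phi basin widths (A, degrees)
#' @return list of class `dualbind_basin_spec`
#' @export
basin_spec <- function(z0, phi0, depth, sigma_z = 1.5, sigma_phi = 15) {
  stopifnot(depth < 0, sigma_z > 0, sigma_phi > 0)
  structure(list(z0 = z0, phi0 = phi0, depth = depth, sigma_z = sigma_z,
                 sigma_phi = sigma_phi), class = "dualbind_basin_spec")
}

# circular angular difference in degrees, in [-180, 180)
circ_diff <- function(a, b) ((a - b + 180) %% 360) - 180

#' Generate synthetic two-basin free-energy landscapes
#'
#' dG(z, phi) = baseline + sum_b depth_b *
#'   exp(-(z - z0)^2 / (2 sigma_z^2) - dphi^2 / (2 sigma_phi^2))
#' with circular dphi, plus independent Gaussian jitter per replica k.
#' The default basin pair mimics the two binding-mode minima of the
#' cohesin-dockerin landscape: depths -38.2 and -28.7 kcal/mol at
#' phi = 3 and 173 degrees. The manifest stores the analytic ground
#' truth: per-mode minima and the dense-quadrature mode ratio at the
#' requested temperature.
#'
#' @param basins list of [basin_spec()] objects
#' @param replicas number of k replicas
#' @param jitter per-replica Gaussian jitter amplitude (kcal/mol; the
#'   reported per-k minima scatter over roughly this scale)
#' @param baseline unbound-level free energy (kcal/mol)
#' @param z_values,phi_values grid axes
#' @param T temperature (K) used for the manifest's quadrature ratio
#' @param seed RNG seed
#' @return a `dualbind_landscape` with the manifest in
#'   `attr(, "manifest")`
#' @export
make_landscape <- function(basins = list(basin_spec(0, 3, -38.2 - (-10)),
                                         basin_spec(0, 173, -28.7 - (-10))),
                           replicas = 1L, jitter = 0, baseline = -10,
                           z_values = seq(-4, 4, by = 0.5),
                           phi_values = seq(-180, 178, by = 2),
                           T = 298, seed = 1L) {
  stopifnot(length(basins) >= 1L, replicas >= 1L)
  set.seed(seed)
  grid <- expand.grid(z = z_values, phi = phi_values)
  clean <- baseline
  for (b in basins) {
    clean <- clean + b$depth *
      exp(-(grid$z - b$z0)^2 / (2 * b$sigma_z^2) -
            circ_diff(grid$phi, b$phi0)^2 / (2 * b$sigma_phi^2))
  }
  dfs <- lapply(seq_len(replicas), function(k) {
    data.frame(k = k, z = grid$z, phi = grid$phi,
               dG = clean + if (jitter > 0) rnorm(nrow(grid), 0, jitter)
                    else 0,
               allowed = TRUE)
  })
  out <- new_landscape(do.call(rbind, dfs))
  # analytic ground truth on a dense quadrature grid (clean surface)
  dz <- seq(min(z_values), max(z_values), length.out = 201)
  dphi <- seq(-180, 180 - 360 / 1441, length.out = 1441)
  dg <- expand.grid(z = dz, phi = dphi)
  gq <- baseline
  for (b in basins) {
    gq <- gq + b$depth * exp(-(dg$z - b$z0)^2 / (2 * b$sigma_z^2) -
                               circ_diff(dg$phi, b$phi0)^2 /
                                 (2 * b$sigma_phi^2))
  }
  kT <- kB_kcal * T
  lI <- logsumexp(-gq[in_mode(dg$phi, "I")] / kT)
  lII <- logsumexp(-gq[in_mode(dg$phi, "II")] / kT)
  manifest <- list(
    basins = basins, replicas = replicas, jitter = jitter,
    baseline = baseline, seed = seed, T = T,
    true_minima = data.frame(
      z0 = vapply(basins, `[[`, numeric(1), "z0"),
      phi0 = vapply(basins, `[[`, numeric(1), "phi0"),
      depth_total = baseline + vapply(basins, `[[`, numeric(1), "depth")),
    quadrature_ratio = exp(lI - lII))
  attr(out, "manifest") <- manifest
  out
}

# ---- toy structures via ideal peptide geometry (NeRF construction) ----

# place atom D given A-B-C with bond |CD|, angle B-C-D (deg) and
# torsion A-B-C-D (deg)
nerf_place <- function(A, B, C, bond, angle, torsion) {
  ang <- angle * pi / 180
  tor <- torsion * pi / 180
  bc <- C - B
  bc <- bc / sqrt(sum(bc^2))
  ab <- B - A
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m2 <- c(n[2] * bc[3] - n[3] * bc[2],
          n[3] * bc[1] - n[1] * bc[3],
          n[1] * bc[2] - n[2] * bc[1])
  d <- c(-bond * cos(ang), bond * sin(ang) * cos(tor),
         bond * sin(ang) * sin(tor))
  C + d[1] * bc + d[2] * m2 + d[3] * n
}

# ideal backbone geometry (lengths A, angles deg)
PEP <- list(b_NCa = 1.458, b_CaC = 1.525, b_CN = 1.329, b_CO = 1.231,
            b_CaCb = 1.530,
            a_NCaC = 111.2, a_CaCN = 116.2, a_CNCa = 121.7,
            a_CaCO = 120.8, a_NCaCb = 110.6)

# build a poly-alanine chain from per-residue (phi, psi); returns the
# atom data.frame rows
build_peptide <- function(phi_psi, chain = "A", resno_start = 1L) {
  n <- nrow(phi_psi)
  atoms <- list()
  # seed atoms of residue 1
  N <- c(0, 0, 0)
  CA <- c(PEP$b_NCa, 0, 0)
  ang <- PEP$a_NCaC * pi / 180
  C <- CA + PEP$b_CaC * c(-cos(ang), sin(ang), 0)
  for (i in seq_len(n)) {
    resno <- resno_start + i - 1L
    psi <- phi_psi$psi[i]
    O <- nerf_place(N, CA, C, PEP$b_CO, PEP$a_CaCO, psi + 180)
    CB <- nerf_place(C, N, CA, PEP$b_CaCb, PEP$a_NCaCb, -122.6)
    atoms[[i]] <- data.frame(
      name = c("N", "CA", "C", "O", "CB"),
      element = c("N", "C", "C", "O", "C"),
      resid = "ALA", chain = chain, resno = resno, insert = "",
      x = c(N[1], CA[1], C[1], O[1], CB[1]),
      y = c(N[2], CA[2], C[2], O[2], CB[2]),
      z = c(N[3], CA[3], C[3], O[3], CB[3]),
      stringsAsFactors = FALSE)
    if (i < n) {
      phi_next <- phi_psi$phi[i + 1]
      N2 <- nerf_place(N, CA, C, PEP$b_CN, PEP$a_CaCN, psi)
      CA2 <- nerf_place(CA, C, N2, PEP$b_NCa, PEP$a_CNCa, 180)
      C2 <- nerf_place(C, N2, CA2, PEP$b_CaC, PEP$a_NCaC, phi_next)
      N <- N2; CA <- CA2; C <- C2
    }
  }
  out <- do.call(rbind, atoms)
  out$serial <- seq_len(nrow(out))
  out$occupancy <- 1
  out$het <- FALSE
  out$ion <- FALSE
  out
}

#' Generate an ideal alpha-helix with backbone heavy atoms
#'
#' Builds a poly-alanine helix (phi = -57, psi = -47) with N, CA, C, O
#' and CB heavy atoms from ideal peptide geometry, centered at the
#' origin with the helix axis along +z. Consecutive Calpha distances
#' are 3.8 +/- 0.1 A and the overlap criterion recovers the
#' (i, i+3)/(i, i+4) helical contact pattern.
#'
#' @param n number of residues (>= 4)
#' @param chain chain id
#' @param resno_start first residue number
#' @param phi,psi backbone dihedrals in degrees
#' @return a `dualbind_structure`
#' @export
make_helix <- function(n, chain = "A", resno_start = 1L, phi = -57,
                       psi = -47) {
  stopifnot(n >= 4L)
  atoms <- build_peptide(data.frame(phi = rep(phi, n), psi = rep(psi, n)),
                         chain = chain, resno_start = resno_start)
  s <- new_structure(atoms)
  align_principal_axis(s)
}

# center a structure and rotate its Calpha principal axis onto +z
align_principal_axis <- function(s) {
  ca <- as.matrix(calpha_coords(s)[, c("x", "y", "z")])
  ctr <- colMeans(ca)
  P <- sweep(ca, 2L, ctr)
  ev <- eigen(crossprod(P), symmetric = TRUE)
  ax <- ev$vectors[, 1]
  if (sum(ax * (P[nrow(P), ] - P[1, ])) < 0) ax <- -ax
  z <- c(0, 0, 1)
  v <- c(ax[2] * z[3] - ax[3] * z[2], ax[3] * z[1] - ax[1] * z[3],
         ax[1] * z[2] - ax[2] * z[1])
  sv <- sqrt(sum(v^2))
  R <- if (sv < 1e-12) diag(3) else
    rotation_matrix(v / sv, acos(max(-1, min(1, sum(ax * z)))) * 180 / pi)
  transform_structure(s, R, -as.numeric(R %*% ctr))
}

#' Generate a two-chain helix-helix complex
#'
#' Two ideal helices packed side by side (antiparallel by default) at a
#' typical helix-packing distance, as a toy stand-in for a two-domain
#' complex: it exercises the interface contact classes, the steric
#' mask of the pose scan, and the pulling protocol. The manifest
#' records the interface contacts found by the overlap criterion at
#' build time.
#'
#' @param n_a,n_b residues per chain
#' @param separation inter-axis distance (A; 8.5 is a typical
#'   helix-packing distance)
#' @param twist rotation of the second helix about its own axis
#'   (degrees); the default interdigitates the side chains so the
#'   closest interatomic approach (~2.9 A) is that of a packed
#'   interface rather than a clash
#' @param antiparallel flip the second helix (default TRUE)
#' @return a `dualbind_structure` with `attr(, "manifest")` listing the
#'   interface pairs
#' @export
make_two_body_complex <- function(n_a = 14L, n_b = 12L, separation = 8.5,
                                  twist = 90, antiparallel = TRUE) {
  ha <- make_helix(n_a, chain = "A")
  hb <- make_helix(n_b, chain = "B")
  hb <- transform_structure(hb, rotation_matrix(c(0, 0, 1), twist))
  if (antiparallel)
    hb <- transform_structure(hb, rotation_matrix(c(1, 0, 0), 180))
  hb <- transform_structure(hb, diag(3), c(separation, 0, 0))
  s <- new_structure(rbind(as.data.frame(ha), as.data.frame(hb)))
  s$serial <- seq_len(nrow(s))
  s <- new_structure(s)
  map <- native_contacts(s)
  iface <- map[map$class == "interface", c("chain_i", "res_i", "chain_j",
                                           "res_j")]
  attr(s, "manifest") <- list(n_a = n_a, n_b = n_b,
                              separation = separation,
                              interface = iface,
                              n_interface = nrow(iface))
  s
}

#' Generate a single-chain helical hairpin
#'
#' Two packed antiparallel helices joined by a short loop in one chain:
#' the smallest topology with nonlocal (|i-j| > 4) contacts, used for
#' thermal-unfolding tests. Loop Calpha positions are interpolated at
#' bonded spacing with small heavy-atom decorations.
#'
#' @param n_helix residues per helix arm
#' @param n_loop loop residues
#' @param separation inter-helix distance (A)
#' @param twist rotation of the second helix about its own axis (degrees)
#' @return a `dualbind_structure`
#' @export
make_hairpin <- function(n_helix = 10L, n_loop = 3L, separation = 8.5,
                         twist = 90) {
  ha <- make_helix(n_helix, chain = "A", resno_start = 1L)
  hb <- make_helix(n_helix, chain = "A",
                   resno_start = n_helix + n_loop + 1L)
  hb <- transform_structure(hb, rotation_matrix(c(0, 0, 1), twist))
  hb <- transform_structure(hb, rotation_matrix(c(1, 0, 0), 180))
  hb <- transform_structure(hb, diag(3), c(separation, 0, 0))
  # connect the top of helix A to the top of helix B through loop beads
  ca_a <- calpha_coords(ha)
  ca_b <- calpha_coords(hb)
  p_from <- as.numeric(ca_a[which.max(ca_a$z), c("x", "y", "z")])
  p_to <- as.numeric(ca_b[which.max(ca_b$z), c("x", "y", "z")])
  # helix B must begin (lowest resno) at its highest point so the loop
  # connects the two helix tops; mirror the numbering if it does not
  if (ca_b$resno[which.max(ca_b$z)] != n_helix + n_loop + 1L)
    hb$resno <- max(hb$resno) + min(hb$resno) - hb$resno
  loop <- lapply(seq_len(n_loop), function(i) {
    frac <- i / (n_loop + 1)
    p <- p_from + frac * (p_to - p_from)
    # arch high enough that no (i, i+2) pair enters the 4 A repulsion
    # range, keeping the native state an exact stationary point
    bulge <- 3.5 * sin(pi * frac)
    p[3] <- p[3] + bulge  # arch above the helices
    data.frame(name = c("N", "CA", "C", "O"),
               element = c("N", "C", "C", "O"),
               resid = "GLY", chain = "A", resno = n_helix + i, insert = "",
               x = p[1] + c(-0.6, 0, 0.6, 0.9),
               y = p[2] + c(0.4, 0, -0.4, 0.5),
               z = p[3] + c(-0.3, 0, 0.3, 0.9),
               serial = 0L, occupancy = 1, het = FALSE, ion = FALSE,
               stringsAsFactors = FALSE)
  })
  df <- rbind(as.data.frame(ha), do.call(rbind, loop), as.data.frame(hb))
  df$serial <- seq_len(nrow(df))
  ord <- order(df$resno, df$serial)
  new_structure(df[ord, ])
}

#' Generate a structure pair related by a known rotation
#'
#' Returns the base structure and a copy rotated by `angle` about
#' `axis` through `origin`, with optional isotropic coordinate noise --
#' the ground truth for symmetry-axis and mode-angle recovery tests.
#'
#' @param base a `dualbind_structure`
#' @param axis rotation axis (length-3, need not be unit)
#' @param angle rotation angle in degrees
#' @param origin point on the axis (default: Calpha centroid)
#' @param noise per-coordinate Gaussian noise sd (A)
#' @param seed RNG seed
#' @return list: a, b, ground_truth (axis, angle, origin)
#' @export
make_rotated_pair <- function(base, axis = c(0, 0, 1), angle = 174,
                              origin = NULL, noise = 0, seed = 1L) {
  set.seed(seed)
  if (is.null(origin)) {
    ca <- calpha_coords(base)
    origin <- colMeans(as.matrix(ca[, c("x", "y", "z")]))
  }
  axis <- axis / sqrt(sum(axis^2))
  R <- rotation_matrix(axis, angle)
  tvec <- as.numeric(origin - R %*% origin)
  b <- transform_structure(base, R, tvec)
  if (noise > 0) {
    b$x <- b$x + rnorm(nrow(b), 0, noise)
    b$y <- b$y + rnorm(nrow(b), 0, noise)
    b$z <- b$z + rnorm(nrow(b), 0, noise)
    b <- new_structure(b)
  }
  list(a = base, b = b,
       ground_truth = list(axis = axis, angle = angle %% 360,
                           origin = as.numeric(origin)))
}
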