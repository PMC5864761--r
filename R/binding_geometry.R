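# Symmetry-axis derivation and rigid (Z, phi) posing of the dockerin.
#
# The two binding modes are related by a rotation about an axis (the
# Z-axis) that is derived from the two crystal structures: after
# superposing the cohesins, the displacement vectors between equivalent
# helix Calpha atoms of the two dockerins all lie (nearly) in a plane;
# the plane normal is the symmetry axis.

#' Dockerin helix definitions
#'
#' Residue ranges of the three dockerin alpha-helices. Only the first
#' and third helices couple to the cohesin, so the symmetry axis is
#' derived from those two.
#'
#' @return named list of integer ranges (alpha1 = 11:23, alpha2 = 28:36,
#'   alpha3 = 45:56)
#' @export
doc_helices <- function() {
  list(alpha1 = 11:23, alpha2 = 28:36, alpha3 = 45:56)
}

#' Displacement vectors between equivalent helix C-alpha atoms
#'
#' Both dockerins must already be expressed in the common frame in which
#' the cohesins are superposed. One vector per residue shared by both
#' structures within the requested helices, pointing from the mode-I
#' position to the mode-II position.
#'
#' @param doc_a,doc_b dockerin structures in the common (cohesin) frame
#' @param helices list of residue-number vectors (default: alpha1 and
#'   alpha3 of [doc_helices()])
#' @param chain_a,chain_b dockerin chain ids (default: first chain)
#' @return n x 3 matrix of vectors, with the paired mode-I coordinates in
#'   `attr(, "from")` and mode-II coordinates in `attr(, "to")`
#' @export
difference_vectors <- function(doc_a, doc_b,
                               helices = doc_helices()[c("alpha1", "alpha3")],
                               chain_a = NULL, chain_b = NULL) {
  if (is.null(chain_a)) chain_a <- doc_a$chain[!doc_a$ion][1]
  if (is.null(chain_b)) chain_b <- doc_b$chain[!doc_b$ion][1]
  wanted <- sort(unique(unlist(helices)))
  ca_a <- calpha_coords(doc_a, chain_a)
  ca_b <- calpha_coords(doc_b, chain_b)
  in_a <- wanted %in% ca_a$resno
  in_b <- wanted %in% ca_b$resno
  shared <- wanted[in_a & in_b]
  if (length(shared) == 0L)
    stop("no helix residues shared by the two structures; missing: ",
         paste(wanted[!(in_a & in_b)], collapse = ", "))
  A <- as.matrix(ca_a[match(shared, ca_a$resno), c("x", "y", "z")])
  B <- as.matrix(ca_b[match(shared, ca_b$resno), c("x", "y", "z")])
  v <- B - A
  rownames(v) <- shared
  attr(v, "from") <- A
  attr(v, "to") <- B
  v
}

new_symmetry_frame <- function(origin, axes) {
  stopifnot(length(origin) == 3L, all(dim(axes) == c(3L, 3L)))
  if (max(abs(axes %*% t(axes) - diag(3))) > 1e-8 || det(axes) < 0)
    stop("frame axes must be a proper orthonormal matrix (rows)")
  structure(list(origin = as.numeric(origin), axes = axes),
            class = "dualbind_symmetry_frame")
}

#' @export
print.dualbind_symmetry_frame <- function(x, ...) {
  cat("dualbind symmetry frame\n  origin:",
      paste(sprintf("%.3f", x$origin), collapse = ", "),
      "\n  Z-axis:", paste(sprintf("%.4f", x$axes[3, ]), collapse = ", "), "\n")
  invisible(x)
}

# residual = sum of squared projections of the vectors on the frame Z-axis
axis_residual <- function(vectors, z) sum((vectors %*% z)^2)

#' Derive the binding-mode symmetry axis from displacement vectors
#'
#' Iteratively rotates the coordinate frame so that the Z-components of
#' the displacement vectors are driven to zero: at each step the small
#' rotation about the in-plane frame axes minimizing the linearized sum
#' of squared Z-components is solved in closed form and applied, until
#' the residual change drops below `tol` (or `max_iter` is hit, which is
#' an error). The Z-axis of the converged frame is the symmetry axis.
#'
#' @param vectors n x 3 matrix from [difference_vectors()], n >= 3
#' @param origin frame origin; default is the centroid of the paired
#'   "from"/"to" coordinates when present, else the origin
#' @param tol convergence threshold on the residual change (A^2)
#' @param max_iter iteration cap
#' @return a `dualbind_symmetry_frame`; the per-iteration residuals are
#'   in `attr(, "residuals")`
#' @export
find_symmetry_axis <- function(vectors, origin = NULL, tol = 1e-9,
                               max_iter = 500L) {
  V <- as.matrix(vectors)
  V <- V[rowSums(V^2) > 0, , drop = FALSE]
  if (nrow(V) < 3L) stop("need at least 3 non-zero vectors")
  if (is.null(origin)) {
    A <- attr(vectors, "from"); B <- attr(vectors, "to")
    origin <- if (!is.null(A) && !is.null(B)) colMeans(rbind(A, B)) else c(0, 0, 0)
  }
  axes <- diag(3)
  res <- axis_residual(V, axes[3, ])
  trace <- res
  for (it in seq_len(max_iter)) {
    e1 <- axes[1, ]; e2 <- axes[2, ]; z <- axes[3, ]
    d <- as.numeric(V %*% z)
    # linearize z' = z + omega x z with omega = a*e1 + b*e2:
    # (z' . v_i) = d_i + a * (e1 . (z x v_i)) + b * (e2 . (z x v_i))
    cx <- cbind(V[, 2] * z[3] - V[, 3] * z[2],
                V[, 3] * z[1] - V[, 1] * z[3],
                V[, 1] * z[2] - V[, 2] * z[1])  # z x v_i (row-wise, negated sign folded below)
    Zx <- -cx  # z x v_i
    M <- cbind(as.numeric(Zx %*% e1), as.numeric(Zx %*% e2))
    ab <- tryCatch(qr.solve(crossprod(M) + 1e-14 * diag(2), -crossprod(M, d)),
                   error = function(e) c(0, 0))
    omega <- ab[1] * e1 + ab[2] * e2
    # linearization can overshoot far from the minimum: damp until downhill
    scale <- 1
    repeat {
      axes_new <- rotate_rows(axes, scale * omega)
      res_new <- axis_residual(V, axes_new[3, ])
      if (res_new <= res || scale < 1e-6) break
      scale <- scale / 2
    }
    if (res_new > res) {  # stuck at a stationary point: converged
      frame <- new_symmetry_frame(origin, axes)
      attr(frame, "residuals") <- trace
      attr(frame, "rms_z") <- sqrt(res / nrow(V))
      return(frame)
    }
    axes <- axes_new
    trace <- c(trace, res_new)
    if (res - res_new < tol) {
      res <- res_new
      frame <- new_symmetry_frame(origin, axes)
      attr(frame, "residuals") <- trace
      attr(frame, "rms_z") <- sqrt(res / nrow(V))
      return(frame)
    }
    res <- res_new
  }
  if (length(trace) > 1L && abs(diff(utils::tail(trace, 2))) < tol) {
    frame <- new_symmetry_frame(origin, axes)
    attr(frame, "residuals") <- trace
    attr(frame, "rms_z") <- sqrt(res / nrow(V))
    return(frame)
  }
  stop(sprintf("symmetry-axis iteration did not converge (residual %.3e A^2)",
               res))
}

# rotate the rows of an orthonormal frame by the rotation vector omega
rotate_rows <- function(axes, omega) {
  R <- rotation_matrix(omega)
  out <- axes %*% t(R)
  # re-orthonormalize against drift
  qr_d <- qr(t(out))
  Q <- qr.Q(qr_d)
  Q <- Q %*% diag(sign(diag(qr.R(qr_d))))
  t(Q)
}

#' Rotation matrix from an axis-angle (Rodrigues) vector or axis + angle
#'
#' @param axis rotation axis (length-3; if `angle` is missing, the norm
#'   of `axis` is the angle in radians)
#' @param angle rotation angle in degrees (optional)
#' @return 3x3 proper rotation matrix
#' @export
rotation_matrix <- function(axis, angle = NULL) {
  axis <- as.numeric(axis)
  if (is.null(angle)) {
    theta <- sqrt(sum(axis^2))
    if (theta < 1e-15) return(diag(3))
    u <- axis / theta
  } else {
    theta <- angle * pi / 180
    n <- sqrt(sum(axis^2))
    if (n < 1e-15) stop("zero-length rotation axis")
    u <- axis / n
  }
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

#' Orient a symmetry frame so +Z points from the dockerin to the cohesin
#'
#' The sign of the derived axis is arbitrary; the posing convention is
#' that positive Z shifts move the dockerin toward the cohesin.
#'
#' @param frame a `dualbind_symmetry_frame`
#' @param coh,doc structures fixing the orientation
#' @return the (possibly flipped) frame
#' @export
orient_frame <- function(frame, coh, doc) {
  ccoh <- colMeans(as.matrix(coh[, c("x", "y", "z")]))
  cdoc <- colMeans(as.matrix(doc[, c("x", "y", "z")]))
  if (sum((ccoh - cdoc) * frame$axes[3, ]) < 0) {
    # flip Z and one in-plane axis to stay proper
    frame$axes[3, ] <- -frame$axes[3, ]
    frame$axes[2, ] <- -frame$axes[2, ]
  }
  frame
}

#' Derive the full symmetry frame from a mode-I / mode-II structure pair
#'
#' Convenience wrapper: superposes the cohesins, forms the helix
#' displacement vectors, finds the axis, and orients +Z toward the
#' cohesin.
#'
#' @param complex_a,complex_b two-chain complexes (cohesin + dockerin)
#'   exemplifying the two binding modes
#' @param chain_coh,chain_doc chain ids of the cohesin and dockerin in
#'   both complexes
#' @param helices helix residue sets for the vectors
#' @return list with `frame`, `angle` (mode-switch rotation, degrees),
#'   and `doc_b_fitted` (complex_b's dockerin in the common frame)
#' @export
derive_symmetry_frame <- function(complex_a, complex_b, chain_coh, chain_doc,
                                  helices = doc_helices()[c("alpha1", "alpha3")]) {
  b_fit <- superpose_structures(complex_b, complex_a,
                                chain_mobile = chain_coh,
                                chain_reference = chain_coh)
  doc_a <- subset_chain(complex_a, chain_doc)
  doc_b <- subset_chain(b_fit, chain_doc)
  v <- difference_vectors(doc_a, doc_b, helices)
  frame <- find_symmetry_axis(v)
  frame <- orient_frame(frame, subset_chain(complex_a, chain_coh), doc_a)
  ang <- mode_rotation_angle(doc_a, doc_b, frame, helices)
  list(frame = frame, angle = ang, doc_b_fitted = doc_b)
}

subset_chain <- function(s, chain) {
  out <- s[s$chain %in% chain, , drop = FALSE]
  new_structure(out)
}

#' Rotation angle about the symmetry axis switching mode I to mode II
#'
#' Least-squares in-plane rotation about the frame Z-axis that carries
#' the helix C-alpha atoms of `doc_a` onto those of `doc_b`.
#'
#' @param doc_a,doc_b dockerin structures in the common frame
#' @param frame a `dualbind_symmetry_frame`
#' @param helices helix residue sets used for the pairing
#' @return angle in degrees in [0, 360)
#' @export
mode_rotation_angle <- function(doc_a, doc_b, frame,
                                helices = doc_helices()[c("alpha1", "alpha3")]) {
  v <- difference_vectors(doc_a, doc_b, helices)
  A <- attr(v, "from"); B <- attr(v, "to")
  la <- sweep(A, 2L, frame$origin) %*% t(frame$axes)
  lb <- sweep(B, 2L, frame$origin) %*% t(frame$axes)
  # centered in-plane Procrustes: the frame origin need not lie exactly
  # on the rotation axis, so fit rotation + in-plane translation
  la[, 1] <- la[, 1] - mean(la[, 1]); la[, 2] <- la[, 2] - mean(la[, 2])
  lb[, 1] <- lb[, 1] - mean(lb[, 1]); lb[, 2] <- lb[, 2] - mean(lb[, 2])
  num <- sum(la[, 1] * lb[, 2] - la[, 2] * lb[, 1])
  den <- sum(la[, 1] * lb[, 1] + la[, 2] * lb[, 2])
  if (abs(num) < 1e-12 && abs(den) < 1e-12)
    stop("degenerate input: helix atoms lie on the symmetry axis")
  ang <- atan2(num, den) * 180 / pi
  ang %% 360
}

#' Construct a rigid pose
#'
#' @param z_shift translation along the frame +Z axis in Angstrom
#'   (positive moves the dockerin toward the cohesin)
#' @param phi rotation about the Z-axis in degrees; wrapped to
#'   [-180, 180)
#' @return list of class `dualbind_pose`
#' @export
rigid_pose <- function(z_shift = 0, phi = 0) {
  stopifnot(is.finite(z_shift), is.finite(phi))
  phi <- ((phi + 180) %% 360) - 180
  structure(list(z_shift = z_shift, phi = phi), class = "dualbind_pose")
}

#' Apply a rigid (Z, phi) pose to a dockerin
#'
#' Rotates the structure by `phi` about the frame Z-axis through the
#' frame origin, then translates it by `z_shift` along +Z. The identity
#' pose (0, 0) leaves the mode-I structure in place.
#'
#' @param doc a `dualbind_structure`
#' @param frame a `dualbind_symmetry_frame`
#' @param pose a `dualbind_pose` (or list with z_shift, phi)
#' @return the posed structure
#' @export
apply_pose <- function(doc, frame, pose) {
  z <- frame$axes[3, ]
  R <- rotation_matrix(z, pose$phi)
  t_vec <- as.numeric(frame$origin - R %*% frame$origin) + pose$z_shift * z
  transform_structure(doc, R, t_vec)
}

#' Steric admissibility of a posed complex
#'
#' A pose is allowed when no inter-molecular heavy-atom pair comes
#' closer than `min_dist` (clash distance; default 2 A, below any bonded
#' or contact separation).
#'
#' @param coh,doc_posed structures of the two partners
#' @param min_dist clash threshold in Angstrom
#' @return TRUE if sterically allowed
#' @export
steric_allowed <- function(coh, doc_posed, min_dist = 2.0) {
  a <- as.matrix(coh[, c("x", "y", "z")])
  b <- as.matrix(doc_posed[, c("x", "y", "z")])
  min_pair_dist(a, b) >= min_dist
}

# minimum inter-set distance, chunked to bound memory
min_pair_dist <- function(a, b) {
  best <- Inf
  step <- max(1L, floor(2e6 / nrow(b)))
  for (i0 in seq(1L, nrow(a), by = step)) {
    ii <- i0:min(i0 + step - 1L, nrow(a))
    d2 <- outer(rowSums(a[ii, , drop = FALSE]^2), rowSums(b^2), "+") -
      2 * tcrossprod(a[ii, , drop = FALSE], b)
    best <- min(best, min(d2))
  }
  sqrt(max(best, 0))
}

#' Generate a (Z, phi) pose grid with steric mask
#'
#' Scans the rigid poses of the dockerin over a rectangular (Z, phi)
#' grid, marking each pose allowed or sterically forbidden. Posed
#' structures can be exported as PDB files (one per allowed pose) plus a
#' TSV manifest for an external per-pose energy backend.
#'
#' @param coh,doc the two partners (dockerin in its mode-I position)
#' @param frame a `dualbind_symmetry_frame`
#' @param z_values,phi_values grid axes (A, degrees); defaults
#'   z from -10 to 4 by 0.5 and phi from -180 to 178 by 2
#' @param min_dist steric clash threshold (A)
#' @param out_dir optional directory for pose PDBs + manifest.tsv
#' @return list of class `dualbind_pose_grid`: z_values, phi_values,
#'   allowed (matrix z x phi), and manifest (data.frame)
#' @export
generate_pose_grid <- function(coh, doc, frame,
                               z_values = seq(-10, 4, by = 0.5),
                               phi_values = seq(-180, 178, by = 2),
                               min_dist = 2.0, out_dir = NULL) {
  if (length(z_values) == 0L || length(phi_values) == 0L)
    stop("empty pose grid")
  stopifnot(!is.unsorted(z_values), !is.unsorted(phi_values))
  allowed <- matrix(NA, length(z_values), length(phi_values),
                    dimnames = list(z_values, phi_values))
  rows <- vector("list", length(z_values) * length(phi_values))
  n <- 0L
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE,
                                    recursive = TRUE)
  for (j in seq_along(phi_values)) {
    rotated <- apply_pose(doc, frame, rigid_pose(0, phi_values[j]))
    z_axis <- frame$axes[3, ]
    for (i in seq_along(z_values)) {
      posed <- transform_structure(rotated, diag(3), z_values[i] * z_axis)
      ok <- steric_allowed(coh, posed, min_dist)
      allowed[i, j] <- ok
      n <- n + 1L
      fname <- sprintf("pose_z%+.2f_phi%+.1f.pdb", z_values[i], phi_values[j])
      rows[[n]] <- data.frame(z = z_values[i], phi = phi_values[j],
                              allowed = ok, filename = fname)
      if (!is.null(out_dir) && ok) write_pdb(posed, file.path(out_dir, fname))
    }
  }
  manifest <- do.call(rbind, rows[seq_len(n)])
  if (!is.null(out_dir))
    write.table(manifest, file.path(out_dir, "manifest.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  structure(list(z_values = z_values, phi_values = phi_values,
                 allowed = allowed, manifest = manifest),
            class = "dualbind_pose_grid")
}
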