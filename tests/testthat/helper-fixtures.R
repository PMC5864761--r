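# Shared fixtures and independent brute-force oracles.

# --- tiny PDB text fixtures (written at test time) ---

pdb_line <- function(type, serial, name, resid, chain, resno, x, y, z,
                     element) {
  sprintf("%-6s%5d %-4s%3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          type, serial, name, resid, chain, resno, x, y, z, 1, 0, element)
}

write_mini_pdb <- function(lines) {
  f <- tempfile(fileext = ".pdb")
  writeLines(c(lines, "END"), f)
  f
}

# three-atom, one-residue fixture
mini_pdb_file <- function() {
  write_mini_pdb(c(
    pdb_line("ATOM", 1, "N", "GLY", "A", 1, 0, 0, 0, "N"),
    pdb_line("ATOM", 2, "CA", "GLY", "A", 1, 1.45, 0, 0, "C"),
    pdb_line("ATOM", 3, "C", "GLY", "A", 1, 2.0, 1.4, 0, "C")))
}

# residues numbered -5..-3 (terminal-tail numbering convention)
negative_resno_pdb_file <- function() {
  write_mini_pdb(unlist(lapply(-5:-3, function(r) {
    i <- (r + 5) * 2
    c(pdb_line("ATOM", i + 1, "N", "ALA", "A", r, 3.8 * (r + 5), 0, 0, "N"),
      pdb_line("ATOM", i + 2, "CA", "ALA", "A", r, 3.8 * (r + 5) + 1.4, 0.5,
               0, "C"))
  })))
}

# helix plus one calcium ion at a given gap from a chosen oxygen,
# placed radially outward so it sits away from the rest of the chain
helix_with_ion <- function(n = 10, gap = 2.4) {
  h <- make_helix(n)
  o <- h[h$name == "O" & h$resno == 5, ]
  rad <- c(o$x, o$y, 0)
  rad <- rad / sqrt(sum(rad^2))
  ion <- data.frame(serial = max(h$serial) + 1L, name = "CA",
                    element = "CA", resid = "CA", chain = "A",
                    resno = 200L, insert = "",
                    x = o$x + gap * rad[1], y = o$y + gap * rad[2],
                    z = o$z, occupancy = 1,
                    het = TRUE, ion = TRUE, stringsAsFactors = FALSE)
  dualbind:::new_structure(rbind(as.data.frame(h), ion))
}

# --- brute-force contact oracle: plain nested loops over residue pairs ---

bf_contact_pairs <- function(s, radii = default_vdw_radii(), scale = 1.24) {
  cls <- atom_class(s$name, s$element, s$resid, s$ion)
  r <- radii[cls]
  key <- paste(s$chain, s$resno, s$insert)
  beads <- unique(key)
  # residue-level sequence index per chain (ions get NA)
  info <- do.call(rbind, lapply(beads, function(k) {
    rows <- which(key == k)
    data.frame(key = k, chain = s$chain[rows[1]], ion = s$ion[rows[1]],
               resno = s$resno[rows[1]], stringsAsFactors = FALSE)
  }))
  info$seq <- NA_integer_
  for (ch in unique(info$chain)) {
    sel <- which(info$chain == ch & !info$ion)
    info$seq[sel[order(info$resno[sel])]] <- seq_along(sel)
  }
  out <- list()
  for (a in seq_len(nrow(info) - 1L)) {
    for (b in (a + 1L):nrow(info)) {
      same <- info$chain[a] == info$chain[b] && !info$ion[a] && !info$ion[b]
      if (same && abs(info$seq[a] - info$seq[b]) <= 2) next
      ia <- which(key == info$key[a])
      ib <- which(key == info$key[b])
      hit <- FALSE
      for (p in ia) {
        for (q in ib) {
          d <- sqrt((s$x[p] - s$x[q])^2 + (s$y[p] - s$y[q])^2 +
                      (s$z[p] - s$z[q])^2)
          if (d <= scale * (r[p] + r[q])) {
            hit <- TRUE
            break
          }
        }
        if (hit) break
      }
      if (hit) out[[length(out) + 1L]] <- c(info$key[a], info$key[b])
    }
  }
  if (!length(out)) return(character(0))
  sort(vapply(out, function(p) paste(sort(p), collapse = "|"), character(1)))
}

contact_map_keys <- function(map) {
  beads <- attr(map, "beads")
  k1 <- paste(beads$chain[map$i], beads$resno[map$i], beads$insert[map$i])
  k2 <- paste(beads$chain[map$j], beads$resno[map$j], beads$insert[map$j])
  sort(vapply(seq_along(k1), function(i) {
    paste(sort(c(k1[i], k2[i])), collapse = "|")
  }, character(1)))
}

# --- brute-force Boltzmann sum with a fixed (not max-based) shift ---

bf_mode_free_energy <- function(landscape, mode, E_c, T, shift = -40) {
  g <- landscape$dG[landscape$allowed & in_mode(landscape$phi, mode) &
                      landscape$dG < E_c]
  kT <- dualbind::kB_kcal * T
  s <- sum(exp(-(g - shift) / kT))
  -kT * log(s) + shift
}

# --- brute-force rotation search for the Kabsch oracle ---

bf_min_rmsd <- function(mobile, reference) {
  P <- sweep(mobile, 2, colMeans(mobile))
  Q <- sweep(reference, 2, colMeans(reference))
  obj <- function(w) {
    R <- rotation_matrix(w)
    sqrt(mean(rowSums((P %*% t(R) - Q)^2)))
  }
  best <- Inf
  for (st in list(c(0, 0, 0), c(pi, 0, 0), c(0, pi, 0), c(0, 0, pi))) {
    o <- stats::optim(st, obj, method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-14))
    o <- stats::optim(o$par, obj, method = "BFGS",
                      control = list(maxit = 2000, reltol = 1e-14))
    best <- min(best, o$value)
  }
  best
}

# --- minimal hand-built two-bead topology (one interface contact) ---

two_bead_topology <- function(r0 = 3.8, params = cg_parameters()) {
  beads <- data.frame(chain = c("A", "B"), resno = c(1L, 1L),
                      insert = "", x = c(0, r0), y = 0, z = 0,
                      ion = FALSE, seq_idx = 1L,
                      stringsAsFactors = FALSE)
  structure(list(
    coords = as.matrix(beads[, c("x", "y", "z")]),
    beads = beads,
    bond_i = integer(0), bond_j = integer(0), bond_r0 = numeric(0),
    contact_i = 0L, contact_j = 1L,
    contact_sigma = r0 / 2^(1/6),
    contact_nonlocal = 1L, contact_interface = 1L,
    contact_class = "interface",
    chir_q0 = integer(0), chir_q1 = integer(0), chir_q2 = integer(0),
    chir_q3 = integer(0), chir_native = numeric(0), chir_d0 = numeric(0),
    params = unclass(params)), class = "dualbind_topology")
}

single_bead_topology <- function(params = cg_parameters()) {
  beads <- data.frame(chain = "A", resno = 1L, insert = "", x = 0, y = 0,
                      z = 0, ion = FALSE, seq_idx = 1L,
                      stringsAsFactors = FALSE)
  structure(list(
    coords = as.matrix(beads[, c("x", "y", "z")]),
    beads = beads,
    bond_i = integer(0), bond_j = integer(0), bond_r0 = numeric(0),
    contact_i = integer(0), contact_j = integer(0),
    contact_sigma = numeric(0),
    contact_nonlocal = integer(0), contact_interface = integer(0),
    contact_class = character(0),
    chir_q0 = integer(0), chir_q1 = integer(0), chir_q2 = integer(0),
    chir_q3 = integer(0), chir_native = numeric(0), chir_d0 = numeric(0),
    params = unclass(params)), class = "dualbind_topology")
}

random_rigid_transform <- function(seed) {
  set.seed(seed)
  w <- rnorm(3)
  R <- rotation_matrix(w / sqrt(sum(w^2)), runif(1, 10, 350))
  list(R = R, t = rnorm(3, sd = 20))
}
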