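# Native contact determination by the atomic overlap criterion.
#
# Two residues are in native contact when any pair of their heavy atoms
# (a, b) satisfies dist(a, b) <= scale * (r_vdw(a) + r_vdw(b)) with
# scale = 1.24 (the inflection point of the Lennard-Jones potential).
# Sequential neighbors (i, i+1) and (i, i+2) within a chain are
# excluded; inter-chain pairs never are. Calcium ions are treated as
# single spheres of van der Waals radius 1.53 A and their contacts are
# never sequence-excluded.

#' Default van der Waals radii by atom class
#'
#' A Tsai/Taylor/Chothia-style heavy-atom radii set, keyed by a coarse
#' atom class: sp3 carbon 1.88, sp2/aromatic carbon 1.76, nitrogen 1.64,
#' carbonyl-type oxygen 1.42, hydroxyl/carboxylate oxygen 1.46, sulfur
#' 1.77, phosphorus 1.80 and the calcium ion 1.53 A. Overridable by any
#' named vector or a two-column text file via [read_radii()].
#'
#' @return named numeric vector of radii in Angstrom
#' @export
default_vdw_radii <- function() {
  c(C_sp3 = 1.88, C_sp2 = 1.76, N = 1.64, O_carbonyl = 1.42,
    O_hydroxyl = 1.46, S = 1.77, P = 1.80, CA_ion = 1.53)
}

#' Read a radii table from a two-column text file
#'
#' @param file whitespace-separated file with columns atom-class, radius
#' @return named numeric vector
#' @export
read_radii <- function(file) {
  df <- read.table(file, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L || !is.numeric(df[[2]]))
    stop("radii file must have two columns: atom-class, radius")
  setNames(df[[2]], df[[1]])
}

# sp2 side-chain carbons of the standard residues (aromatic rings,
# carboxylate / amide / guanidinium carbons); backbone C is sp2.
SP2_SIDE <- list(
  ARG = "CZ", ASN = "CG", ASP = "CG", GLN = "CD", GLU = "CD",
  HIS = c("CG", "CD2", "CE1"),
  PHE = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TRP = c("CG", "CD1", "CD2", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
  TYR = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"))

# hydroxyl / carboxylate / terminal oxygens
O_HYDROXYL <- c("OG", "OG1", "OH", "OD2", "OE2", "OXT")

#' Atom class used for radius lookup
#'
#' @param name atom name (e.g. "CB", "OD1")
#' @param element element symbol
#' @param resid 3-letter residue code
#' @param is_ion whether the atom is a calcium ion
#' @return character vector of classes matching [default_vdw_radii()]
#' @export
atom_class <- function(name, element, resid, is_ion = FALSE) {
  cls <- rep(NA_character_, length(name))
  cls[is_ion] <- "CA_ion"
  idx <- !is_ion
  el <- element[idx]; nm <- name[idx]; rs <- toupper(resid[idx])
  out <- rep(NA_character_, sum(idx))
  out[el == "N"] <- "N"
  out[el == "S"] <- "S"
  out[el == "P"] <- "P"
  out[el == "O"] <- ifelse(nm[el == "O"] %in% O_HYDROXYL,
                           "O_hydroxyl", "O_carbonyl")
  isC <- el == "C"
  sp2 <- nm == "C" | mapply(function(n, r) {
    n %in% (SP2_SIDE[[r]] %||% character(0))
  }, nm, rs)
  out[isC] <- ifelse(sp2[isC], "C_sp2", "C_sp3")
  cls[idx] <- out
  cls
}

`%||%` <- function(a, b) if (is.null(a)) b else a

new_contact_map <- function(contacts) {
  need <- c("i", "j", "chain_i", "res_i", "chain_j", "res_j", "sigma",
            "class")
  contacts <- as.data.frame(contacts)
  stopifnot(all(need %in% names(contacts)))
  if (nrow(contacts) && any(contacts$i >= contacts$j))
    stop("contacts must be stored canonically with i < j")
  class(contacts) <- c("dualbind_contact_map", "data.frame")
  contacts
}

#' @export
print.dualbind_contact_map <- function(x, ...) {
  cat(sprintf("dualbind contact map: %d contacts\n", nrow(x)))
  if (nrow(x)) print(table(x$class))
  invisible(x)
}

# bead table: one bead per residue (Calpha position) plus one per ion
bead_table <- function(s) {
  ca <- calpha_coords(s)
  beads <- data.frame(chain = ca$chain, resno = ca$resno, insert = ca$insert,
                      x = ca$x, y = ca$y, z = ca$z, ion = FALSE,
                      stringsAsFactors = FALSE)
  ions <- s[s$ion, , drop = FALSE]
  if (nrow(ions)) {
    beads <- rbind(beads, data.frame(chain = ions$chain, resno = ions$resno,
                                     insert = ions$insert, x = ions$x,
                                     y = ions$y, z = ions$z, ion = TRUE))
  }
  # sequence index within each chain for the |i-j| exclusion
  beads$seq_idx <- NA_integer_
  for (ch in unique(beads$chain[!beads$ion])) {
    sel <- which(beads$chain == ch & !beads$ion)
    ord <- order(beads$resno[sel], beads$insert[sel])
    beads$seq_idx[sel[ord]] <- seq_along(sel)
  }
  beads
}

#' Native contact map by the atomic overlap criterion
#'
#' Residue-level contacts: residues i < j are in contact when any
#' heavy-atom pair overlaps after inflating the van der Waals radii by
#' `scale`. Same-chain pairs with sequence separation <= 2 are excluded.
#' Calcium ions are included as single-sphere beads (radius from the
#' `CA_ion` class) unless `include_ions = FALSE`; ion contacts are never
#' sequence-excluded. Each contact carries sigma = r_native / 2^(1/6)
#' where r_native is the native bead (Calpha or ion) distance, placing
#' the Lennard-Jones minimum at the native separation.
#'
#' @param s a `dualbind_structure`
#' @param radii named radii vector (default [default_vdw_radii()])
#' @param scale overlap inflation factor (default 1.24)
#' @param include_ions include calcium-ion contacts (default TRUE)
#' @return a `dualbind_contact_map`; bead table in `attr(, "beads")`
#' @export
native_contacts <- function(s, radii = default_vdw_radii(), scale = 1.24,
                            include_ions = TRUE) {
  atoms <- s[!s$ion | include_ions, , drop = FALSE]
  cls <- atom_class(atoms$name, atoms$element, atoms$resid, atoms$ion)
  unknown <- is.na(cls) | !(cls %in% names(radii))
  if (any(unknown))
    stop("no van der Waals radius for atom(s): ",
         paste(unique(paste0(atoms$resid[unknown], "/", atoms$name[unknown])),
               collapse = ", "))
  r <- radii[cls]
  beads <- bead_table(s)
  if (!include_ions) beads <- beads[!beads$ion, , drop = FALSE]
  bead_key <- paste(beads$chain, beads$resno, beads$insert)
  atom_bead <- match(paste(atoms$chain, atoms$resno, atoms$insert), bead_key)
  if (anyNA(atom_bead)) {
    # atoms of residues without a Calpha (e.g. stray hetero groups) are
    # not part of the bead model
    keep <- !is.na(atom_bead)
    atoms <- atoms[keep, , drop = FALSE]
    r <- r[keep]
    atom_bead <- atom_bead[keep]
  }
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  n <- nrow(xyz)
  maxcut <- scale * 2 * max(r)
  hits <- overlap_pairs_cpp(xyz, as.numeric(r), as.integer(atom_bead),
                            scale, maxcut)
  pairs <- unique(data.frame(bi = pmin(hits[, 1], hits[, 2]),
                             bj = pmax(hits[, 1], hits[, 2])))
  pairs <- pairs[pairs$bi != pairs$bj, , drop = FALSE]
  # sequence exclusion within a chain; never for ions or across chains
  bi <- pairs$bi; bj <- pairs$bj
  same_chain <- beads$chain[bi] == beads$chain[bj] &
    !beads$ion[bi] & !beads$ion[bj]
  seqsep <- abs(beads$seq_idx[bi] - beads$seq_idx[bj])
  keep <- !(same_chain & seqsep <= 2)
  pairs <- pairs[keep, , drop = FALSE]
  bi <- pairs$bi; bj <- pairs$bj
  rn <- unname(sqrt(rowSums((beads[bi, c("x", "y", "z")] -
                               beads[bj, c("x", "y", "z")])^2)))
  cls_pair <- contact_class_label(beads, bi, bj)
  ord <- order(bi, bj)
  out <- new_contact_map(data.frame(
    i = bi, j = bj,
    chain_i = beads$chain[bi], res_i = beads$resno[bi],
    chain_j = beads$chain[bj], res_j = beads$resno[bj],
    sigma = rn / 2^(1/6), class = cls_pair,
    stringsAsFactors = FALSE)[ord, ])
  rownames(out) <- NULL
  attr(out, "beads") <- beads
  out
}

contact_class_label <- function(beads, bi, bj) {
  ifelse(beads$ion[bi] | beads$ion[bj], "ion",
         ifelse(beads$chain[bi] != beads$chain[bj], "interface",
                paste0("intra_", beads$chain[bi])))
}

#' Calcium-ion contacts by the overlap criterion
#'
#' Ion-residue contacts only, with the ion treated as one sphere of
#' radius `ca_radius`. An ion-free structure yields an empty map.
#'
#' @param s a `dualbind_structure`
#' @param ca_radius calcium van der Waals radius (default 1.53 A)
#' @param radii protein radii table
#' @param scale overlap inflation factor
#' @return a `dualbind_contact_map` of class "ion" contacts
#' @export
calcium_contacts <- function(s, ca_radius = 1.53,
                             radii = default_vdw_radii(), scale = 1.24) {
  radii["CA_ion"] <- ca_radius
  if (!any(s$ion)) {
    return(new_contact_map(data.frame(
      i = integer(0), j = integer(0), chain_i = character(0),
      res_i = integer(0), chain_j = character(0), res_j = integer(0),
      sigma = numeric(0), class = character(0))))
  }
  m <- native_contacts(s, radii, scale, include_ions = TRUE)
  out <- m[m$class == "ion", , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "beads") <- attr(m, "beads")
  new_contact_map(out)
}

#' Per-contact sigma from native distances
#'
#' sigma = r_native / 2^(1/6), so the 12-6 potential is minimal exactly
#' at the native separation.
#'
#' @param r_native native distances (A)
#' @return sigma values (A)
#' @export
sigma_from_native <- function(r_native) {
  stopifnot(all(r_native > 0))
  r_native / 2^(1/6)
}

#' Contact counts by class
#'
#' @param map a `dualbind_contact_map`
#' @return named integer vector (one entry per class, plus `total`)
#' @export
contact_classes <- function(map) {
  cl <- table(map$class)
  out <- c(as.integer(cl), nrow(map))
  names(out) <- c(names(cl), "total")
  out
}

#' Write / read contact maps as TSV
#'
#' @param map a `dualbind_contact_map`
#' @param file path
#' @return the path (write) or the map (read)
#' @export
write_contact_map <- function(map, file) {
  write.table(as.data.frame(map), file, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(file)
}

#' @rdname write_contact_map
#' @export
read_contact_map <- function(file) {
  df <- read.table(file, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  new_contact_map(df)
}

# TRUE if the single-row ion structure overlaps any heavy atom of `prot`
ion_contacts_any <- function(ion_row, prot, radii = default_vdw_radii(),
                             scale = 1.24) {
  cls <- atom_class(prot$name, prot$element, prot$resid, prot$ion)
  cls[is.na(cls)] <- "C_sp3"
  r <- radii[cls]
  r[is.na(r)] <- 1.88
  d <- sqrt((prot$x - ion_row$x)^2 + (prot$y - ion_row$y)^2 +
              (prot$z - ion_row$z)^2)
  any(d <= scale * (r + radii[["CA_ion"]]))
}
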