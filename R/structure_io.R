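# Structure ingestion, residue selection and superposition.
#
# A structure is a plain data.frame of atom records (class "dualbind_structure")
# with one row per heavy atom: serial, name, element, resid (3-letter code),
# chain, resno (may be negative), insert, x, y, z, occupancy, het, ion.
# Hydrogens are dropped on input: every downstream criterion (atomic overlap,
# Calpha beads) is defined on heavy atoms only.

STRUCT_COLS <- c("serial", "name", "element", "resid", "chain", "resno",
                 "insert", "x", "y", "z", "occupancy", "het", "ion")

new_structure <- function(atoms) {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  stopifnot(all(STRUCT_COLS %in% names(atoms)))
  if (nrow(atoms) == 0L) stop("structure contains no atoms")
  if (!all(is.finite(c(atoms$x, atoms$y, atoms$z))))
    stop("non-finite atom coordinates")
  rownames(atoms) <- NULL
  class(atoms) <- c("dualbind_structure", "data.frame")
  atoms
}

#' @export
print.dualbind_structure <- function(x, ...) {
  ch <- table(x$chain[!x$ion])
  cat(sprintf("dualbind structure: %d heavy atoms, %d residues, %d ion(s)\n",
              nrow(x), nrow(unique(x[!x$ion, c("chain", "resno", "insert")])),
              sum(x$ion)))
  cat("chains:", paste(sprintf("%s (%d atoms)", names(ch), ch), collapse = ", "),
      "\n")
  invisible(x)
}

infer_element <- function(name, resid) {
  # PDB atom-name convention: element is the first alphabetic character,
  # except two-letter ions/metals (CA calcium vs CA alpha-carbon is
  # disambiguated by the residue name).
  el <- toupper(sub("^[0-9]*", "", name))
  ifelse(toupper(resid) == "CA" & el == "CA", "CA", substr(el, 1L, 1L))
}

#' Read a protein structure from a PDB file
#'
#' Reads ATOM and HETATM records, keeping the original residue numbering
#' (negative numbers included) and insertion codes. Hydrogens are
#' discarded. For alternate locations the highest-occupancy conformer is
#' kept (ties resolved by file order). Calcium HETATM records are flagged
#' as ions and kept as single-sphere entities.
#'
#' @param file path to a PDB file
#' @return an object of class `dualbind_structure` (a data.frame of atoms)
#' @examples
#' h <- make_helix(8)
#' f <- tempfile(fileext = ".pdb")
#' write_pdb(h, f)
#' s <- read_pdb(f)
#' @export
read_pdb <- function(file) {
  if (!file.exists(file)) stop("no such file: ", file)
  pdb <- tryCatch(bio3d::read.pdb(file, verbose = FALSE, rm.alt = FALSE),
                  error = function(e) stop("failed to parse PDB '", file,
                                           "': ", conditionMessage(e)))
  a <- pdb$atom
  if (is.null(a) || nrow(a) == 0L) stop("empty structure: ", file)
  el <- a$elesy
  miss <- is.na(el) | el == ""
  el[miss] <- infer_element(a$elety[miss], a$resid[miss])
  el <- toupper(trimws(el))
  keep <- el != "H" & el != "D"
  a <- a[keep, , drop = FALSE]
  el <- el[keep]
  if (nrow(a) == 0L) stop("structure has no heavy atoms: ", file)
  chain <- ifelse(is.na(a$chain), " ", a$chain)
  insert <- ifelse(is.na(a$insert), "", a$insert)
  occ <- ifelse(is.na(a$o), 1, a$o)
  atoms <- data.frame(
    serial = a$eleno, name = a$elety, element = el, resid = a$resid,
    chain = chain, resno = a$resno, insert = insert,
    x = a$x, y = a$y, z = a$z, occupancy = occ,
    het = a$type == "HETATM",
    ion = a$type == "HETATM" & el == "CA",
    altloc = ifelse(is.na(a$alt), "", a$alt),
    stringsAsFactors = FALSE)
  atoms <- resolve_altloc(atoms)
  atoms$altloc <- NULL
  new_structure(atoms)
}

# keep the highest-occupancy alternate conformer per atom site
resolve_altloc <- function(atoms) {
  if (all(atoms$altloc == "")) return(atoms)
  key <- paste(atoms$chain, atoms$resno, atoms$insert, atoms$name, sep = "\r")
  ord <- order(key, -atoms$occupancy, seq_len(nrow(atoms)))
  atoms <- atoms[ord, , drop = FALSE]
  atoms <- atoms[!duplicated(key[ord]), , drop = FALSE]
  atoms[order(atoms$serial), , drop = FALSE]
}

#' Write a structure to a PDB file
#'
#' @param s a `dualbind_structure`
#' @param file output path
#' @return invisibly, the file path
#' @export
write_pdb <- function(s, file) {
  stopifnot(inherits(s, "dualbind_structure"))
  xyz <- as.vector(t(as.matrix(s[, c("x", "y", "z")])))
  bio3d::write.pdb(file = file, xyz = xyz,
                   type = ifelse(s$het, "HETATM", "ATOM"),
                   resno = s$resno, resid = s$resid,
                   eleno = seq_len(nrow(s)), elety = s$name,
                   chain = ifelse(s$chain == " ", "", s$chain),
                   insert = ifelse(s$insert == "", NA, s$insert),
                   o = s$occupancy, elesy = s$element)
  invisible(file)
}

#' Select a residue range from one chain
#'
#' Keeps the residues with `first <= resno <= last` in the given chain
#' (other chains are untouched). Hetero ions are kept only while they
#' remain in contact (by the atomic overlap criterion) with at least one
#' retained residue, so truncating away a calcium-binding segment also
#' drops its calcium.
#'
#' @param s a `dualbind_structure`
#' @param chain chain identifier
#' @param first,last inclusive residue-number bounds
#' @param prune_ions drop ions no longer in contact with the retained
#'   residues (default TRUE)
#' @return the truncated structure
#' @export
select_residues <- function(s, chain, first, last, prune_ions = TRUE) {
  stopifnot(inherits(s, "dualbind_structure"), first <= last)
  if (!chain %in% s$chain) stop("chain '", chain, "' not present")
  drop <- s$chain == chain & !s$ion & (s$resno < first | s$resno > last)
  out <- s[!drop, , drop = FALSE]
  if (!any(out$chain == chain & !out$ion))
    stop("empty selection: no residues of chain '", chain, "' in [",
         first, ", ", last, "]")
  if (prune_ions && any(out$ion)) {
    keep_ion <- vapply(which(out$ion), function(i) {
      ion_contacts_any(out[i, , drop = FALSE], out[!out$ion, , drop = FALSE])
    }, logical(1))
    idx <- which(out$ion)[!keep_ion]
    if (length(idx)) out <- out[-idx, , drop = FALSE]
  }
  new_structure(out)
}

#' Extract C-alpha coordinates of a chain
#'
#' @param s a `dualbind_structure`
#' @param chain chain id (default: all chains)
#' @return data.frame with chain, resno, insert, x, y, z, one row per residue
#' @export
calpha_coords <- function(s, chain = NULL) {
  a <- s[!s$ion & s$name == "CA" & s$element == "C", , drop = FALSE]
  if (!is.null(chain)) a <- a[a$chain %in% chain, , drop = FALSE]
  key <- paste(a$chain, a$resno, a$insert)
  if (anyDuplicated(key)) stop("duplicate C-alpha atoms for a residue")
  a[, c("chain", "resno", "insert", "x", "y", "z")]
}

#' Kabsch least-squares superposition
#'
#' Finds the proper rotation and translation minimizing the RMSD between
#' two equal-length coordinate sets (`mobile` onto `reference`).
#'
#' @param mobile,reference n x 3 coordinate matrices, n >= 3
#' @return list with `rotation` (3x3, det +1), `translation` (length 3),
#'   and `rmsd` (Angstrom); the fit is
#'   `mobile %*% t(rotation) + translation`.
#' @export
kabsch_superpose <- function(mobile, reference) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (!all(dim(mobile) == dim(reference)) || ncol(mobile) != 3L)
    stop("coordinate sets must be equal-size n x 3 matrices")
  n <- nrow(mobile)
  if (n < 3L) stop("need at least 3 points")
  cm <- colMeans(mobile); cr <- colMeans(reference)
  P <- sweep(mobile, 2L, cm); Q <- sweep(reference, 2L, cr)
  H <- crossprod(P, Q)
  sv <- svd(H)
  # collinear/degenerate sets leave the rotation under-determined
  scale <- max(sv$d[1], sqrt(sum(P^2) * sum(Q^2)) / n, 1e-12)
  if (sv$d[2] / scale < 1e-8)
    stop("degenerate (collinear) point set: superposition is ill-defined")
  d <- sign(det(tcrossprod(sv$v, sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  fitted <- P %*% t(R)
  rmsd <- sqrt(mean(rowSums((fitted - Q)^2)))
  list(rotation = R, translation = as.numeric(cr - cm %*% t(R)), rmsd = rmsd)
}

#' Apply a rigid transform to a structure
#'
#' @param s a `dualbind_structure`
#' @param rotation 3x3 rotation matrix
#' @param translation length-3 vector
#' @return the transformed structure (`x' = R x + t`)
#' @export
transform_structure <- function(s, rotation = diag(3), translation = c(0, 0, 0)) {
  xyz <- as.matrix(s[, c("x", "y", "z")]) %*% t(rotation)
  xyz <- sweep(xyz, 2L, -translation)
  s$x <- xyz[, 1]; s$y <- xyz[, 2]; s$z <- xyz[, 3]
  new_structure(s)
}

#' Paired C-alpha RMSD between two structures
#'
#' Pairs residues of the two chains by the intersection of their
#' (residue number, insertion code) labels -- residue names are ignored,
#' so point mutants pair with their wild type -- and reports the minimal
#' RMSD over the paired C-alpha atoms after Kabsch superposition.
#'
#' @param a,b `dualbind_structure` objects
#' @param chain_a,chain_b chains to compare (default: first chain of each)
#' @param range optional c(first, last) residue-number window applied to
#'   both before pairing
#' @return RMSD in Angstrom
#' @export
paired_calpha_rmsd <- function(a, b, chain_a = NULL, chain_b = NULL,
                               range = NULL) {
  if (is.null(chain_a)) chain_a <- a$chain[!a$ion][1]
  if (is.null(chain_b)) chain_b <- b$chain[!b$ion][1]
  ca_a <- calpha_coords(a, chain_a)
  ca_b <- calpha_coords(b, chain_b)
  if (!is.null(range)) {
    ca_a <- ca_a[ca_a$resno >= range[1] & ca_a$resno <= range[2], ]
    ca_b <- ca_b[ca_b$resno >= range[1] & ca_b$resno <= range[2], ]
  }
  key_a <- paste(ca_a$resno, ca_a$insert)
  key_b <- paste(ca_b$resno, ca_b$insert)
  common <- intersect(key_a, key_b)
  if (length(common) < 3L)
    stop("fewer than 3 shared residues between the chains")
  ma <- as.matrix(ca_a[match(common, key_a), c("x", "y", "z")])
  mb <- as.matrix(ca_b[match(common, key_b), c("x", "y", "z")])
  kabsch_superpose(ma, mb)$rmsd
}

#' Superpose one structure onto another by shared C-alpha atoms
#'
#' Computes the Kabsch fit on paired C-alpha atoms of the given chains
#' and applies it to the whole mobile structure.
#'
#' @inheritParams paired_calpha_rmsd
#' @param mobile,reference `dualbind_structure` objects
#' @param chain_mobile,chain_reference chains anchoring the fit
#' @return the transformed mobile structure, with the fit in
#'   `attr(, "fit")`
#' @export
superpose_structures <- function(mobile, reference,
                                 chain_mobile = NULL, chain_reference = NULL,
                                 range = NULL) {
  if (is.null(chain_mobile)) chain_mobile <- mobile$chain[!mobile$ion][1]
  if (is.null(chain_reference))
    chain_reference <- reference$chain[!reference$ion][1]
  ca_m <- calpha_coords(mobile, chain_mobile)
  ca_r <- calpha_coords(reference, chain_reference)
  if (!is.null(range)) {
    ca_m <- ca_m[ca_m$resno >= range[1] & ca_m$resno <= range[2], ]
    ca_r <- ca_r[ca_r$resno >= range[1] & ca_r$resno <= range[2], ]
  }
  key_m <- paste(ca_m$resno, ca_m$insert)
  key_r <- paste(ca_r$resno, ca_r$insert)
  common <- intersect(key_m, key_r)
  if (length(common) < 3L) stop("fewer than 3 shared residues for the fit")
  fit <- kabsch_superpose(
    as.matrix(ca_m[match(common, key_m), c("x", "y", "z")]),
    as.matrix(ca_r[match(common, key_r), c("x", "y", "z")]))
  out <- transform_structure(mobile, fit$rotation, fit$translation)
  attr(out, "fit") <- fit
  out
}
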