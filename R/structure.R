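# Atomic-structure handling: a light data-frame structure model, PDB
# read/write (parsing via bio3d), CA-CA distances and Shrake-Rupley
# solvent-accessible surface area.

# van der Waals radii (Angstrom) for elements that occur in protein
# structures; unknown elements are an error, never silently defaulted.
VDW_RADII <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80,
               P = 1.80, SE = 1.90)

#' Build a structure model from atom records
#'
#' The in-memory structure representation is a plain `data.frame` with one
#' row per atom: `chain`, `resno` (author numbering, 1-based), `resname`,
#' `elety` (atom name, e.g. "CA"), `element`, `x`, `y`, `z` (Angstrom).
#'
#' @param atoms `data.frame` with the columns above.
#' @return the validated `data.frame` with class `structure_model`.
#' @export
structure_model <- function(atoms) {
  need <- c("chain", "resno", "resname", "elety", "element", "x", "y", "z")
  stopifnot(all(need %in% names(atoms)),
            all(is.finite(atoms$x)), all(is.finite(atoms$y)),
            all(is.finite(atoms$z)))
  atoms <- as.data.frame(atoms)[, need]
  class(atoms) <- c("structure_model", "data.frame")
  atoms
}

#' Parse a PDB file into a structure model
#'
#' Reads ATOM/HETATM records through [bio3d::read.pdb()], keeps the first
#' model of multi-model files, and reduces alternate locations to a single
#' conformer per atom (highest occupancy, ties broken by altloc label
#' order).  Author chain and residue numbering are preserved.
#'
#' @param path path to a PDB file.
#' @return a [structure_model()].
#' @export
parse_structure <- function(path) {
  pdb <- bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE, verbose = FALSE)
  a <- pdb$atom
  if (nrow(a) == 0) stop("no ATOM records in ", path, call. = FALSE)
  a$alt[is.na(a$alt)] <- ""
  a$o[is.na(a$o)] <- 1
  # one conformer per (chain, resno, insert, atom name)
  key <- paste(a$chain, a$resno, a$insert, a$elety, sep = "\r")
  ord <- order(key, -a$o, a$alt)
  a <- a[ord, ]
  a <- a[!duplicated(key[ord]), ]
  a <- a[order(as.integer(rownames(a))), ]
  elem <- toupper(a$elesy)
  guess <- is.na(elem) | elem == ""
  # fall back on the first letter of the atom name when the element column
  # is absent (common in minimal CA-only files)
  elem[guess] <- toupper(substr(trimws(a$elety[guess]), 1, 1))
  structure_model(data.frame(
    chain = a$chain, resno = a$resno, resname = a$resid, elety = a$elety,
    element = elem, x = a$x, y = a$y, z = a$z))
}

#' Write a structure model as minimal PDB ATOM records
#'
#' @param model a [structure_model()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_structure_pdb <- function(model, path) {
  lines <- vapply(seq_len(nrow(model)), function(i) {
    sprintf("ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            i, ifelse(nchar(model$elety[i]) < 4,
                      paste0(" ", model$elety[i]), model$elety[i]),
            model$resname[i], model$chain[i], model$resno[i],
            model$x[i], model$y[i], model$z[i], 1, 0,
            model$element[i])
  }, character(1))
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' CA-CA distance between two residues
#'
#' @param model a [structure_model()].
#' @param a,b length-2 vectors `c(chain, resno)`.
#' @return Euclidean distance in Angstrom (symmetric in its arguments).
#' @export
ca_distance <- function(model, a, b) {
  get_ca <- function(sel) {
    i <- which(model$chain == sel[1] & model$resno == as.integer(sel[2]) &
                 trimws(model$elety) == "CA")
    if (length(i) == 0) {
      stop(sprintf("residue %s:%s has no CA atom", sel[1], sel[2]),
           call. = FALSE)
    }
    c(model$x[i[1]], model$y[i[1]], model$z[i[1]])
  }
  sqrt(sum((get_ca(a) - get_ca(b))^2))
}

# Deterministic quasi-uniform points on the unit sphere (golden-section
# spiral), the classic point set for Shrake-Rupley.
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' For each atom, test points are placed quasi-uniformly on a sphere of
#' radius `r_vdw + probe`; the accessible fraction (points inside no
#' neighboring expanded sphere) times the sphere area `4*pi*(r+probe)^2`
#' is the atom's SASA.  Per-residue SASA sums all of a residue's atoms
#' (side chains included when present).
#'
#' @param model a [structure_model()].
#' @param probe probe radius in Angstrom (water, 1.4).
#' @param n_points number of test points per atom.
#' @param radii named per-element radius table (Angstrom); elements missing
#'   from it are an error.
#' @return list with `atom` (the model plus a `sasa` column) and `residue`
#'   (`data.frame`: `chain`, `resno`, `resname`, `sasa`).
#' @export
#' @examples
#' one_c <- structure_model(data.frame(chain = "A", resno = 1,
#'   resname = "ALA", elety = "CA", element = "C", x = 0, y = 0, z = 0))
#' sasa(one_c)$residue$sasa  # 4 * pi * (1.7 + 1.4)^2
sasa <- function(model, probe = 1.4, n_points = 960L, radii = VDW_RADII) {
  elem <- toupper(model$element)
  unknown <- setdiff(unique(elem), names(radii))
  if (length(unknown) > 0) {
    stop("no van der Waals radius for element(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  r <- unname(radii[elem]) + probe
  xyz <- as.matrix(model[, c("x", "y", "z")])
  n <- nrow(xyz)
  pts <- sphere_points(n_points)
  atom_sasa <- numeric(n)
  for (i in seq_len(n)) {
    d2 <- rowSums(sweep(xyz, 2, xyz[i, ])^2)
    nb <- which(d2 < (r[i] + r)^2 & seq_len(n) != i)
    test <- sweep(pts * r[i], 2, xyz[i, ], "+")
    acc <- rep(TRUE, n_points)
    for (j in nb) {
      dj2 <- (test[, 1] - xyz[j, 1])^2 + (test[, 2] - xyz[j, 2])^2 +
        (test[, 3] - xyz[j, 3])^2
      acc <- acc & dj2 > r[j]^2
      if (!any(acc)) break
    }
    atom_sasa[i] <- mean(acc) * 4 * pi * r[i]^2
  }
  atom <- cbind(as.data.frame(model), sasa = atom_sasa)
  key <- paste(model$chain, model$resno)
  residue <- stats::aggregate(atom_sasa,
                              by = list(chain = model$chain,
                                        resno = model$resno),
                              FUN = sum)
  names(residue)[3] <- "sasa"
  residue$resname <- model$resname[match(paste(residue$chain,
                                               residue$resno), key)]
  residue <- residue[order(residue$chain, residue$resno),
                     c("chain", "resno", "resname", "sasa")]
  rownames(residue) <- NULL
  list(atom = atom, residue = residue)
}
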