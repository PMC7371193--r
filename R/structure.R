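#' Representative-atom set
#'
#' One weighted 3D point per residue: the Calpha for amino acids, the
#' backbone phosphate for nucleotides.  This point set is the input to the
#' whole descriptor pipeline.
#'
#' @param coords numeric matrix (n x 3), Angstrom.
#' @param mass per-point residue masses in Daltons (recycled; default from
#'   \code{\link{residue_mass}} applied to \code{resid}).
#' @param resid per-point residue codes (recycled, default "UNK").
#' @param chain per-point chain identifiers (recycled, default "A").
#' @param source_id free-text provenance tag.
#' @return object of class \code{zs_atoms}.
#' @export
representative_atoms <- function(coords, mass = NULL, resid = "UNK",
                                 chain = "A", source_id = "") {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3 || nrow(coords) < 1)
    stop("coords must be an n x 3 matrix with n >= 1")
  if (!all(is.finite(coords))) stop("coordinates must be finite")
  n <- nrow(coords)
  resid <- rep_len(as.character(resid), n)
  if (is.null(mass)) mass <- residue_mass(resid)
  mass <- rep_len(as.numeric(mass), n)
  if (any(!is.finite(mass)) || any(mass <= 0))
    stop("masses must be finite and strictly positive")
  chain <- rep_len(as.character(chain), n)
  dimnames(coords) <- NULL
  structure(list(coords = coords, mass = mass, resid = resid,
                 chain = chain, source_id = source_id),
            class = "zs_atoms")
}

#' @export
print.zs_atoms <- function(x, ...) {
  cat(sprintf("representative atoms: %d points, %d chain(s), %.1f kDa%s\n",
              nrow(x$coords), length(unique(x$chain)), sum(x$mass) / 1000,
              if (nzchar(x$source_id)) paste0(" [", x$source_id, "]") else ""))
  invisible(x)
}

.aa_codes <- names(.aa_mass)
.nt_codes <- names(.nt_mass)

#' Load representative atoms from a structure file
#'
#' Parses a PDB or mmCIF file and reduces polymer residues to one point
#' each: the Calpha coordinate for amino acids (including mapped modified
#' residues such as MSE) and the backbone phosphate for nucleotides.
#' Waters, ligands and ions are excluded.  Alternate locations keep the
#' highest-occupancy conformer; among equal keys the first occurrence wins.
#' Residues lacking their representative atom are skipped with a warning.
#'
#' @param path structure file.
#' @param format "pdb", "mmcif" or "auto" (by file extension).
#' @param selector optional character vector of chain identifiers; default
#'   all polymer chains of the deposited coordinates.
#' @return a \code{zs_atoms} object.
#' @export
load_representative_atoms <- function(path, format = c("auto", "pdb", "mmcif"),
                                      selector = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.cif(\\.gz)?$", path, ignore.case = TRUE))
      "mmcif" else "pdb"
  }
  parsed <- tryCatch(
    if (format == "pdb") bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE)
    else bio3d::read.cif(path, rm.alt = FALSE, verbose = FALSE),
    error = function(e) stop("cannot parse ", path, " as ", format, ": ",
                             conditionMessage(e), call. = FALSE))
  at <- parsed$atom
  is_aa <- at$resid %in% c(.aa_codes, names(.res_parent), "UNK")
  is_nt <- at$resid %in% .nt_codes
  polymer <- (is_aa | is_nt) & at$type %in% c("ATOM", "HETATM")
  # restrict HETATM records to mapped modified residues (drops free ligands
  # that happen to share a code)
  polymer[at$type == "HETATM" & !(at$resid %in% names(.res_parent))] <- FALSE
  if (!is.null(selector)) polymer <- polymer & at$chain %in% selector
  if (!any(polymer)) stop("selector matches no polymer residues")
  at <- at[polymer, , drop = FALSE]
  rep_atom <- (at$resid %in% c(.aa_codes, names(.res_parent), "UNK") & at$elety == "CA") |
    (at$resid %in% .nt_codes & at$elety == "P")
  ins <- if ("insert" %in% names(at)) ifelse(is.na(at$insert), "", at$insert) else ""
  key_all <- paste(at$chain, at$resno, ins, sep = "|")
  sel <- at[rep_atom, , drop = FALSE]
  key <- key_all[rep_atom]
  if (nrow(sel) == 0) stop("selector matches no residues with representative atoms")
  # altloc: highest occupancy wins, then first occurrence
  occ <- if ("o" %in% names(sel)) ifelse(is.na(sel$o), 1, sel$o) else rep(1, nrow(sel))
  ord <- order(match(key, unique(key)), -occ)
  sel <- sel[ord, , drop = FALSE]
  keep <- !duplicated(key[ord])
  sel <- sel[keep, , drop = FALSE]
  n_missing <- length(unique(key_all)) - nrow(sel)
  if (n_missing > 0)
    warning(n_missing, " polymer residue(s) lack a representative atom; skipped")
  representative_atoms(
    coords = cbind(sel$x, sel$y, sel$z),
    mass = residue_mass(sel$resid),
    resid = sel$resid,
    chain = sel$chain,
    source_id = basename(path))
}

#' Write representative atoms as a minimal PDB file
#'
#' One CA (or P) record per point; used by the fixtures module to exercise
#' parser round trips.  Coordinates are written at PDB precision (0.001 A).
#'
#' @param atoms a \code{zs_atoms} object.
#' @param path output file.
#' @export
write_atoms_pdb <- function(atoms, path) {
  stopifnot(inherits(atoms, "zs_atoms"))
  elety <- ifelse(atoms$resid %in% .nt_codes, "P", "CA")
  bio3d::write.pdb(file = path,
                   xyz = as.vector(t(atoms$coords)),
                   resno = seq_len(nrow(atoms$coords)),
                   resid = atoms$resid,
                   chain = atoms$chain,
                   elety = elety)
  invisible(path)
}
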