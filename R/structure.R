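#' Labelled pseudo-atom structure frame
#'
#' A light container for one coordinate frame: an N x 3 matrix of positions
#' (Angstrom) plus per-atom labels and the membrane-slab geometry. Atoms are
#' grouped into molecules (protein domains, lipids, antibody chains) by
#' `molecule_id`; `molecule_class` distinguishes protein-domain names (e.g.
#' MpD, DD, CrD, StD, TmD, IcD), lipid species (POPC, POPS) and Fab chains.
#'
#' @param coords N x 3 numeric matrix, Angstrom.
#' @param atoms data.frame with columns `residue_id`, `residue_name`,
#'   `molecule_id`, `molecule_class` (one row per atom).
#' @param slab optional list `list(z_lo =, z_hi =, half_width =)` describing
#'   the membrane slab as a z-interval with lateral extent.
#' @return object of class `structure_frame`.
#' @export
structure_frame <- function(coords, atoms, slab = NULL) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3L) stop("coords must be N x 3")
  need <- c("residue_id", "residue_name", "molecule_id", "molecule_class")
  if (!all(need %in% names(atoms))) {
    stop("atoms must have columns residue_id, residue_name, molecule_id, molecule_class")
  }
  if (nrow(atoms) != nrow(coords)) stop("coords and atoms row counts differ")
  if (!is.null(slab)) {
    if (slab$z_lo >= slab$z_hi) stop("inverted slab bounds: z_lo must be < z_hi")
  }
  structure(list(coords = coords, atoms = atoms, slab = slab),
            class = "structure_frame")
}

#' @export
print.structure_frame <- function(x, ...) {
  cat(sprintf("structure_frame: %d atoms, %d molecules (%s)\n",
              nrow(x$coords), length(unique(x$atoms$molecule_id)),
              paste(unique(x$atoms$molecule_class), collapse = ", ")))
  if (!is.null(x$slab)) {
    cat(sprintf("  membrane slab z in [%.1f, %.1f] A\n", x$slab$z_lo, x$slab$z_hi))
  }
  invisible(x)
}

# Internal: atom indices of a domain / molecule class / residue selection.
select_atoms <- function(frame, domain = NULL, residues = NULL, class = NULL) {
  keep <- rep(TRUE, nrow(frame$atoms))
  if (!is.null(domain)) keep <- keep & frame$atoms$molecule_class == domain
  if (!is.null(class)) keep <- keep & frame$atoms$molecule_class %in% class
  if (!is.null(residues)) keep <- keep & frame$atoms$residue_id %in% residues
  which(keep)
}
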