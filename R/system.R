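#' Build an atom table
#'
#' The atom table is the tabular core of a [molecular_system()]: one row per
#' atom, with identity columns (name, element, residue, chain), the
#' enzyme/ligand tag used to split interaction energies, and the per-atom
#' nonbonded and solvation parameters.
#'
#' @param atom_id integer ids, unique; stable keys referenced by topology and
#'   exclusions (row order may change, ids do not).
#' @param name atom names (PDB-style, e.g. "CA", "O6").
#' @param element element symbols.
#' @param residue_id 1-based residue numbers.
#' @param residue_name residue names ("GLY", "LIG", ...).
#' @param chain chain identifiers (single characters).
#' @param molecule_tag one of "enzyme", "ligand", "other" per atom.
#' @param charge partial charges, elementary charges.
#' @param lj_epsilon Lennard-Jones well depth, kJ/mol (>= 0).
#' @param lj_rmin_half half the LJ minimum-energy distance, angstrom (> 0).
#' @param born_radius generalized-Born radius, angstrom (> 0).
#' @param sasa_coefficient nonpolar surface coefficient, kJ/(mol A^2).
#' @param vdw_radius van der Waals radius for surface-area evaluation,
#'   angstrom (> 0).
#' @return a tibble with one row per atom.
#' @export
atom_table <- function(atom_id, name, element, residue_id, residue_name,
                       chain, molecule_tag, charge,
                       lj_epsilon, lj_rmin_half, born_radius,
                       sasa_coefficient, vdw_radius) {
  tb <- tibble::tibble(
    atom_id = as.integer(atom_id), name = as.character(name),
    element = as.character(element), residue_id = as.integer(residue_id),
    residue_name = as.character(residue_name), chain = as.character(chain),
    molecule_tag = as.character(molecule_tag), charge = as.numeric(charge),
    lj_epsilon = as.numeric(lj_epsilon),
    lj_rmin_half = as.numeric(lj_rmin_half),
    born_radius = as.numeric(born_radius),
    sasa_coefficient = as.numeric(sasa_coefficient),
    vdw_radius = as.numeric(vdw_radius)
  )
  validate_atom_table(tb)
  tb
}

validate_atom_table <- function(tb) {
  stopifnot(is.data.frame(tb))
  if (anyDuplicated(tb$atom_id)) stop("atom_id values must be unique")
  if (!all(tb$molecule_tag %in% c("enzyme", "ligand", "other")))
    stop("molecule_tag must be one of 'enzyme', 'ligand', 'other'")
  if (any(tb$lj_epsilon < 0)) stop("lj_epsilon must be >= 0")
  bad <- tb$lj_rmin_half <= 0 | tb$born_radius <= 0 | tb$vdw_radius <= 0
  if (any(bad)) stop("all radii (lj_rmin_half, born_radius, vdw_radius) must be > 0")
  invisible(tb)
}

#' Build a bonded topology
#'
#' Harmonic terms follow the k (x - x0)^2 convention (the force constant
#' absorbs the conventional 1/2); torsions are k (1 + cos(n phi - delta)).
#' All indices are `atom_id` keys into the atom table.
#'
#' @param bonds tibble/data frame with columns i, j, k_b (kJ/(mol A^2)), r0 (A).
#' @param angles columns i, j, k, k_theta (kJ/(mol rad^2)), theta0 (rad); j is
#'   the vertex.
#' @param urey_bradley columns i, k, k_ub (kJ/(mol A^2)), s0 (A) for 1-3
#'   distances.
#' @param dihedrals columns i, j, k, l, k_phi (kJ/mol), n (integer >= 1),
#'   delta (rad).
#' @param impropers columns i, j, k, l, k_psi (kJ/(mol rad^2)), psi0 (rad).
#' @return a list of the five term tables, class "mm_topology".
#' @export
mm_topology <- function(bonds = NULL, angles = NULL, urey_bradley = NULL,
                        dihedrals = NULL, impropers = NULL) {
  empty <- function(cols) {
    tb <- tibble::as_tibble(stats::setNames(
      rep(list(numeric(0)), length(cols)), cols))
    tb
  }
  top <- list(
    bonds = if (is.null(bonds)) empty(c("i", "j", "k_b", "r0"))
            else tibble::as_tibble(bonds),
    angles = if (is.null(angles)) empty(c("i", "j", "k", "k_theta", "theta0"))
             else tibble::as_tibble(angles),
    urey_bradley = if (is.null(urey_bradley)) empty(c("i", "k", "k_ub", "s0"))
                   else tibble::as_tibble(urey_bradley),
    dihedrals = if (is.null(dihedrals))
                  empty(c("i", "j", "k", "l", "k_phi", "n", "delta"))
                else tibble::as_tibble(dihedrals),
    impropers = if (is.null(impropers))
                  empty(c("i", "j", "k", "l", "k_psi", "psi0"))
                else tibble::as_tibble(impropers)
  )
  if (nrow(top$dihedrals) && any(top$dihedrals$n < 1))
    stop("dihedral periodicity n must be >= 1")
  if (nrow(top$bonds)) {
    key <- paste(pmin(top$bonds$i, top$bonds$j), pmax(top$bonds$i, top$bonds$j))
    if (anyDuplicated(key)) stop("duplicate bond pairs in topology")
  }
  top <- structure(top, class = "mm_topology")
  # cache the 1-2/1-3 exclusions so systems sharing a topology do not
  # re-derive them
  attr(top, "derived_exclusions") <- derive_exclusions(top)
  top
}

#' Assemble a molecular system
#'
#' A molecular system bundles the atom table, an n x 3 coordinate matrix
#' (angstrom), the bonded topology and the nonbonded exclusion list. Pairs
#' separated by one (1-2) or two (1-3) bonds are always excluded from
#' nonbonded evaluation and are added automatically; 1-4 pairs interact at
#' full strength. Extra exclusions (e.g. intra-residue pairs for rigid
#' rotamers) may be supplied as a two-column matrix of atom ids.
#'
#' @param atoms an [atom_table()].
#' @param coords numeric matrix, nrow(atoms) x 3, angstrom.
#' @param topology an [mm_topology()].
#' @param exclusions optional two-column integer matrix of atom-id pairs.
#' @return an object of class "molecular_system".
#' @export
molecular_system <- function(atoms, coords, topology = mm_topology(),
                             exclusions = NULL) {
  validate_atom_table(atoms)
  coords <- as.matrix(coords)
  if (nrow(atoms) > 0 && (nrow(coords) != nrow(atoms) || ncol(coords) != 3))
    stop("coords must be an nrow(atoms) x 3 matrix")
  ids <- atoms$atom_id
  for (tab in topology[c("bonds", "angles", "urey_bradley",
                         "dihedrals", "impropers")]) {
    idx_cols <- intersect(c("i", "j", "k", "l"), names(tab))
    for (cl in idx_cols) {
      if (nrow(tab) && !all(tab[[cl]] %in% ids))
        stop("topology refers to atom ids absent from the atom table")
    }
  }
  excl <- attr(topology, "derived_exclusions")
  if (is.null(excl)) excl <- derive_exclusions(topology)
  if (!is.null(exclusions) && nrow(exclusions)) {
    exclusions <- cbind(pmin(exclusions[, 1], exclusions[, 2]),
                        pmax(exclusions[, 1], exclusions[, 2]))
    excl <- rbind(excl, exclusions)
  }
  excl <- unique(excl)
  structure(list(atoms = atoms, coords = coords, topology = topology,
                 exclusions = excl),
            class = "molecular_system")
}

# 1-2 and 1-3 pairs from the bond list, as a sorted two-column id matrix
derive_exclusions <- function(topology) {
  b <- topology$bonds
  if (!nrow(b)) return(matrix(integer(0), ncol = 2))
  p12 <- cbind(pmin(b$i, b$j), pmax(b$i, b$j))
  # 1-3: two bonds sharing an atom
  adj <- split(c(b$j, b$i), c(b$i, b$j))
  p13 <- list()
  for (centre in names(adj)) {
    nb <- unique(adj[[centre]])
    if (length(nb) >= 2) {
      cmb <- utils::combn(sort(nb), 2)
      p13[[centre]] <- t(cmb)
    }
  }
  p13 <- if (length(p13)) do.call(rbind, p13) else matrix(integer(0), ncol = 2)
  unique(rbind(p12, p13))
}

#' @export
print.molecular_system <- function(x, ...) {
  cat("<molecular_system> ", nrow(x$atoms), " atoms (",
      sum(x$atoms$molecule_tag == "enzyme"), " enzyme, ",
      sum(x$atoms$molecule_tag == "ligand"), " ligand); ",
      nrow(x$topology$bonds), " bonds\n", sep = "")
  invisible(x)
}

#' Number of atoms in a system
#' @param system a [molecular_system()].
#' @return integer atom count.
#' @export
n_atoms <- function(system) nrow(system$atoms)

# row positions for a vector of atom ids
id_to_row <- function(system, ids) {
  pos <- match(ids, system$atoms$atom_id)
  if (anyNA(pos)) stop("atom id not present in system")
  pos
}

#' Extract the subsystem carrying a molecule tag
#'
#' Keeps the atoms whose `molecule_tag` is in `tags`, together with the
#' bonded terms and exclusions fully contained in that selection. Coordinates
#' are retained as-is (no re-minimization).
#'
#' @param system a [molecular_system()].
#' @param tags character vector of tags to keep.
#' @return a [molecular_system()].
#' @export
subsystem <- function(system, tags) {
  keep <- system$atoms$molecule_tag %in% tags
  if (!any(keep)) stop("no atoms carry molecule tag(s): ",
                       paste(tags, collapse = ", "))
  ids <- system$atoms$atom_id[keep]
  filt <- function(tab) {
    idx_cols <- intersect(c("i", "j", "k", "l"), names(tab))
    if (!nrow(tab)) return(tab)
    ok <- rep(TRUE, nrow(tab))
    for (cl in idx_cols) ok <- ok & tab[[cl]] %in% ids
    tab[ok, , drop = FALSE]
  }
  top <- mm_topology(
    bonds = filt(system$topology$bonds),
    angles = filt(system$topology$angles),
    urey_bradley = filt(system$topology$urey_bradley),
    dihedrals = filt(system$topology$dihedrals),
    impropers = filt(system$topology$impropers)
  )
  excl <- system$exclusions
  if (nrow(excl)) excl <- excl[excl[, 1] %in% ids & excl[, 2] %in% ids, ,
                               drop = FALSE]
  molecular_system(system$atoms[keep, , drop = FALSE],
                   system$coords[keep, , drop = FALSE], top, excl)
}
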