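BACKBONE_ATOMS <- c("N", "CA", "C", "O", "H", "HA", "OXT")

# orthonormal local frame at a residue: origin CA, x along CA->N,
# z normal to the N-CA-C plane, y completing the right-handed set
backbone_frame <- function(system, position, chain = NULL) {
  at <- system$atoms
  sel <- at$residue_id == position & at$molecule_tag == "enzyme"
  if (!is.null(chain)) sel <- sel & at$chain == chain
  need <- c("N", "CA", "C")
  rows <- vapply(need, function(nm) {
    hit <- which(sel & at$name == nm)
    if (length(hit) != 1)
      stop("backbone atom ", nm, " missing or ambiguous at position ", position)
    hit
  }, 0L)
  N <- system$coords[rows["N"], ]; CA <- system$coords[rows["CA"], ]
  C <- system$coords[rows["C"], ]
  ex <- N - CA; ex <- ex / sqrt(sum(ex^2))
  ez <- cross3(ex, C - CA); ez <- ez / sqrt(sum(ez^2))
  ey <- cross3(ez, ex)
  list(origin = CA, R = cbind(ex, ey, ez))
}

#' Place a rotamer at a design position
#'
#' Replaces the side-chain atoms of the residue (everything beyond the
#' backbone set N/CA/C/O/H/HA/OXT) with the rotamer's atoms, mapped rigidly
#' through the local backbone frame (origin CA, x toward N, z normal to the
#' N-CA-C plane). Backbone atoms are untouched; the residue name is updated
#' to the rotamer type; side-chain nonbonded parameters are looked up in
#' `params$atoms` by (residue type, atom name) with "*" wildcards.
#'
#' Side chains are rigid bodies: they carry no bonded terms, and all
#' intra-residue pairs involving a side-chain atom are excluded from
#' nonbonded evaluation.
#'
#' @param system a [molecular_system()].
#' @param position enzyme residue id.
#' @param rotamer a rotamer (element of a [read_rotamer_library()] list).
#' @param params parameter list with an `atoms` table (see
#'   [read_parameters()]).
#' @return the modified [molecular_system()].
#' @export
place_rotamer <- function(system, position, rotamer, params) {
  fr <- backbone_frame(system, position)
  at <- system$atoms
  in_res <- at$residue_id == position & at$molecule_tag == "enzyme"
  side <- in_res & !(at$name %in% BACKBONE_ATOMS)
  keep <- !side
  atoms <- at[keep, , drop = FALSE]
  coords <- system$coords[keep, , drop = FALSE]
  res3 <- rotamer$residue_type
  atoms$residue_name[atoms$residue_id == position &
                       atoms$molecule_tag == "enzyme"] <- res3
  if (nrow(rotamer$atoms)) {
    pt <- params$atoms
    look <- function(atm, col) {
      for (cand in list(c(res3, atm), c(res3, "*"), c("*", atm), c("*", "*"))) {
        hit <- which(pt$residue_name == cand[1] & pt$atom_name == cand[2])
        if (length(hit)) return(pt[[col]][hit[1]])
      }
      stop("no parameters for side-chain atom ", res3, "/", atm)
    }
    tmpl_chain <- at$chain[which(in_res & at$name == "CA")][1]
    nr <- nrow(rotamer$atoms)
    new_ids <- max(at$atom_id) + seq_len(nr)
    new_atoms <- list(
      atom_id = as.integer(new_ids),
      name = rotamer$atoms$name,
      element = substr(gsub("[0-9]", "", rotamer$atoms$name), 1, 1),
      residue_id = rep(as.integer(position), nr),
      residue_name = rep(res3, nr),
      chain = rep(tmpl_chain, nr),
      molecule_tag = rep("enzyme", nr),
      charge = vapply(rotamer$atoms$name, look, 0, col = "charge"),
      lj_epsilon = vapply(rotamer$atoms$name, look, 0, col = "lj_epsilon"),
      lj_rmin_half = vapply(rotamer$atoms$name, look, 0, col = "lj_rmin_half"),
      born_radius = vapply(rotamer$atoms$name, look, 0, col = "born_radius"),
      sasa_coefficient = vapply(rotamer$atoms$name, look, 0,
                                col = "sasa_coefficient"),
      vdw_radius = vapply(rotamer$atoms$name, look, 0, col = "vdw_radius")
    )
    local <- as.matrix(rotamer$atoms[, c("x", "y", "z")])
    glob <- sweep(local %*% t(fr$R), 2, fr$origin, "+")
    # insert after the residue's backbone block to keep residues contiguous
    last_bb <- max(which(atoms$residue_id == position &
                           atoms$molecule_tag == "enzyme"))
    head_idx <- seq_len(last_bb)
    tail_idx <- if (last_bb < nrow(atoms)) (last_bb + 1):nrow(atoms)
                else integer(0)
    atoms <- tibble::new_tibble(lapply(stats::setNames(names(atoms),
                                                       names(atoms)),
      function(cl) c(atoms[[cl]][head_idx], unname(new_atoms[[cl]]),
                     atoms[[cl]][tail_idx])),
      nrow = nrow(atoms) + nr)
    coords <- rbind(coords[head_idx, , drop = FALSE], glob,
                    coords[tail_idx, , drop = FALSE])
  }
  molecular_system(atoms, coords, system$topology,
                   exclusions = sidechain_exclusions(atoms))
}

# intra-residue pairs involving at least one side-chain atom (enzyme only)
sidechain_exclusions <- function(atoms) {
  out <- list()
  enz <- atoms$molecule_tag == "enzyme"
  for (res in unique(atoms$residue_id[enz])) {
    ids <- atoms$atom_id[enz & atoms$residue_id == res]
    side <- atoms$atom_id[enz & atoms$residue_id == res &
                            !(atoms$name %in% BACKBONE_ATOMS)]
    if (!length(side) || length(ids) < 2) next
    pairs <- expand.grid(i = side, j = ids)
    pairs <- pairs[pairs$i != pairs$j, , drop = FALSE]
    out[[as.character(res)]] <- cbind(pmin(pairs$i, pairs$j),
                                      pmax(pairs$i, pairs$j))
  }
  if (!length(out)) return(NULL)
  unique(do.call(rbind, out))
}

#' Optimal rotamer assignment at design positions
#'
#' For design spaces of at most `exhaustive_limit` combinations the full
#' Cartesian product of candidate rotamers is enumerated and the combination
#' minimizing the total energy (including restraints) is returned; ties go to
#' the first combination in deterministic order (positions ascending,
#' candidates sorted by amino acid and library index). Larger spaces are
#' optimized greedily position-by-position in a seeded random order.
#'
#' @param system a [molecular_system()].
#' @param positions integer residue ids to repack.
#' @param library rotamer library ([read_rotamer_library()]).
#' @param permitted named list: position (character) -> allowed one-letter
#'   amino acids.
#' @param params parameter list (see [place_rotamer()]).
#' @param restraints optional [noe_restraints()] table.
#' @param exhaustive_limit switch-over to greedy search.
#' @return list with `system` (rotamers placed), `assignment` (tibble:
#'   position, residue_type one-letter, rotamer_index), `energy` (total, kJ/mol).
#' @export
assign_rotamers <- function(system, positions, library, permitted, params,
                            restraints = NULL, exhaustive_limit = 10000) {
  positions <- sort(as.integer(positions))
  cands <- lapply(positions, function(p) {
    allowed <- permitted[[as.character(p)]]
    if (is.null(allowed)) stop("no permitted set for position ", p)
    allowed3 <- aa_one_to_three(allowed)
    avail <- intersect(sort(allowed3), names(library))
    if (!length(avail))
      stop("permitted set and rotamer library do not intersect at position ", p)
    out <- list()
    for (rt in avail) {
      for (ri in seq_along(library[[rt]]))
        out[[length(out) + 1]] <- list(rt = rt, idx = ri,
                                       rot = library[[rt]][[ri]])
    }
    out
  })
  n_cands <- vapply(cands, length, 0L)
  n_comb <- prod(n_cands)
  eval_combo <- function(sys, combo) {
    for (p in seq_along(positions))
      sys <- place_rotamer(sys, positions[p], cands[[p]][[combo[p]]]$rot,
                           params)
    list(system = sys, e = sum(total_energy_vec(sys, restraints)))
  }
  if (n_comb <= exhaustive_limit) {
    grid <- as.matrix(expand.grid(lapply(rev(n_cands), seq_len)))
    grid <- grid[, rev(seq_len(ncol(grid))), drop = FALSE]  # pos-major order
    best <- NULL
    for (r in seq_len(nrow(grid))) {
      res <- eval_combo(system, grid[r, ])
      if (is.null(best) || res$e < best$e)
        best <- c(res, list(combo = grid[r, ]))
    }
  } else {
    order_pos <- sample(seq_along(positions))
    combo <- rep(1L, length(positions))
    cur <- eval_combo(system, combo)
    for (p in order_pos) {
      for (ci in seq_len(n_cands[p])) {
        if (ci == combo[p]) next
        trial <- combo; trial[p] <- ci
        res <- eval_combo(system, trial)
        if (res$e < cur$e) { combo <- trial; cur <- res }
      }
    }
    best <- c(cur, list(combo = combo))
  }
  assignment <- tibble::tibble(
    position = positions,
    residue_type = vapply(seq_along(positions), function(p)
      aa_three_to_one(cands[[p]][[best$combo[p]]]$rt), ""),
    rotamer_index = vapply(seq_along(positions), function(p)
      cands[[p]][[best$combo[p]]]$idx, 0L)
  )
  list(system = best$system, assignment = assignment, energy = best$e)
}

#' Randomly perturb backbone dihedrals
#'
#' Draws independent phi/psi changes uniformly in +/- `magnitude` degrees for
#' every residue in `window` and applies them as rigid rotations about the
#' N-CA (phi) and CA-C (psi) axes: downstream atoms (and, for phi, the
#' residue's own side chain and carbonyl) rotate rigidly, so bond lengths and
#' angles are preserved exactly. Uses the current RNG state; seed beforehand
#' for reproducibility.
#'
#' @param system a [molecular_system()].
#' @param window integer vector of enzyme residue ids (contiguous).
#' @param magnitude maximum |change| per dihedral, degrees (>= 0).
#' @return the perturbed [molecular_system()].
#' @export
perturb_backbone <- function(system, window, magnitude) {
  stopifnot(magnitude >= 0)
  at <- system$atoms
  enz <- at$molecule_tag == "enzyme"
  if (!all(window %in% at$residue_id[enz]))
    stop("window residues outside the enzyme chain")
  coords <- system$coords
  rot_about <- function(coords, p0, axis, ang, rows) {
    if (!length(rows) || ang == 0) return(coords)
    u <- axis / sqrt(sum(axis^2))
    x <- sweep(coords[rows, , drop = FALSE], 2, p0, "-")
    ct <- cos(ang); st <- sin(ang)
    xr <- x * ct +
      t(apply(x, 1, function(v) cross3(u, v))) * st +
      outer(drop(x %*% u) * (1 - ct), u)
    coords[rows, ] <- sweep(xr, 2, p0, "+")
    coords
  }
  find1 <- function(res, nm) {
    hit <- which(enz & at$residue_id == res & at$name == nm)
    if (length(hit) != 1)
      stop("backbone atom ", nm, " missing at residue ", res)
    hit
  }
  for (res in sort(window)) {
    dphi <- stats::runif(1, -magnitude, magnitude) * pi / 180
    dpsi <- stats::runif(1, -magnitude, magnitude) * pi / 180
    iN <- find1(res, "N"); iCA <- find1(res, "CA"); iC <- find1(res, "C")
    # phi: rotate C-side of CA (carbonyl, side chain, later residues)
    rows_phi <- which(enz & ((at$residue_id == res &
                                !(at$name %in% c("N", "CA", "H"))) |
                               at$residue_id > res))
    coords <- rot_about(coords, coords[iN, ], coords[iCA, ] - coords[iN, ],
                        dphi, rows_phi)
    # psi: rotate the carbonyl oxygen and later residues about CA->C
    rows_psi <- which(enz & ((at$residue_id == res & at$name == "O") |
                               at$residue_id > res))
    coords <- rot_about(coords, coords[iCA, ], coords[iC, ] - coords[iCA, ],
                        dpsi, rows_psi)
  }
  out <- system
  out$coords <- coords
  out
}
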