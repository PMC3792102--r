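# internal-coordinate (NeRF) placement: position d given a-b-c and
# bond |cd|, angle b-c-d, torsion a-b-c-d
place_internal <- function(a, b, c, bond, angle, torsion) {
  bc <- c - b; bc <- bc / sqrt(sum(bc^2))
  n <- cross3(b - a, bc); n <- n / sqrt(sum(n^2))
  m <- cross3(n, bc)
  d2 <- bond * c(-cos(angle), sin(angle) * cos(torsion),
                 sin(angle) * sin(torsion))
  c + cbind(bc, m, n) %*% d2
}

# deterministic nonbonded/solvation parameter set for toy systems: backbone
# and ligand entries plus one wildcard row per amino acid so any library
# side chain can be placed. Side-chain charges are graded by chemistry
# (acidic negative, basic positive, polar slightly negative, apolar zero).
toy_parameters <- function(lj_epsilon = 0.3, sasa_coefficient = 0.0226,
                           charge_pattern = "complementary",
                           ligand_charge = -0.25) {
  bb <- tibble::tibble(
    residue_name = "GLY", atom_name = c("N", "CA", "C", "O"),
    charge = c(-0.30, 0.07, 0.51, -0.28),
    lj_epsilon = lj_epsilon, lj_rmin_half = 1.8,
    born_radius = 1.7, vdw_radius = 1.6,
    sasa_coefficient = sasa_coefficient
  )
  if (charge_pattern == "neutral") bb$charge <- 0
  if (charge_pattern == "repulsive") bb$charge <- abs(bb$charge)
  side_charge <- c(ALA = 0, VAL = 0, LEU = 0, ILE = 0, MET = 0, PHE = 0,
                   TRP = 0, PRO = 0, GLY = 0,
                   SER = -0.1, THR = -0.1, ASN = -0.1, GLN = -0.1,
                   CYS = -0.1, TYR = -0.1,
                   ASP = -0.4, GLU = -0.4, LYS = 0.4, ARG = 0.4, HIS = 0.1)
  if (charge_pattern == "neutral") side_charge[] <- 0
  sc <- tibble::tibble(
    residue_name = names(side_charge), atom_name = "*",
    charge = unname(side_charge),
    lj_epsilon = 0.25, lj_rmin_half = 1.9, born_radius = 1.8,
    vdw_radius = 1.8, sasa_coefficient = sasa_coefficient
  )
  lig <- tibble::tibble(
    residue_name = "LIG", atom_name = "*",
    charge = switch(charge_pattern, neutral = 0, repulsive = -ligand_charge,
                    ligand_charge),
    lj_epsilon = lj_epsilon, lj_rmin_half = 1.8, born_radius = 1.7,
    vdw_radius = 1.6, sasa_coefficient = sasa_coefficient
  )
  fallback <- tibble::tibble(
    residue_name = "*", atom_name = "*", charge = 0,
    lj_epsilon = 0.25, lj_rmin_half = 1.8, born_radius = 1.7,
    vdw_radius = 1.7, sasa_coefficient = sasa_coefficient
  )
  list(atoms = dplyr::bind_rows(bb, sc, lig, fallback))
}

#' Generate a pair of toy enzyme-ligand complexes
#'
#' Desk-scale stand-in for a real active-site complex: a short polyglycine
#' enzyme (N/CA/C/O backbone built from ideal internal coordinates, bonded
#' terms set to the built geometry) and a small chain ligand. The
#' transition-state-analogue complex shares the enzyme and carries a
#' flattened, re-charged copy of the substrate ligand (mimicking the more
#' planar ring geometry and increased polarity of a lactone analogue). One
#' flat-bottom NOE restraint links the central residue's CA to the first
#' ligand atom. Byte-identical output for a fixed seed.
#'
#' Charge patterns: "complementary" (negative ligand, basic side chains
#' attract), "neutral" (all charges zero; with LJ epsilon 0 the interaction
#' energy is exactly zero), "repulsive" (like charges).
#'
#' @param n_enzyme_residues 2-10 residues.
#' @param ligand_n_atoms 2-10 atoms.
#' @param charge_pattern "complementary", "neutral" or "repulsive".
#' @param seed integer seed (coordinates get a small deterministic jitter).
#' @param lj_epsilon backbone/ligand LJ well depth, kJ/mol.
#' @param sasa_coefficient nonpolar surface coefficient, kJ/(mol A^2)
#'   (0 disables the surface term).
#' @param separation initial gap between ligand and enzyme, angstrom
#'   (defaults: 4 for charged patterns, 10 for neutral so that surface areas
#'   stay additive).
#' @return list with `substrate`, `tsa` (both [molecular_system()]),
#'   `restraints` ([noe_restraints()]), `params` (parameter list).
#' @export
generate_toy_complex <- function(n_enzyme_residues = 3, ligand_n_atoms = 4,
                                 charge_pattern = c("complementary",
                                                    "neutral", "repulsive"),
                                 seed = 1, lj_epsilon = 0.3,
                                 sasa_coefficient = 0.0226,
                                 separation = NULL) {
  charge_pattern <- match.arg(charge_pattern)
  if (n_enzyme_residues < 2 || n_enzyme_residues > 10)
    stop("n_enzyme_residues must be in 2..10")
  if (ligand_n_atoms < 2 || ligand_n_atoms > 10)
    stop("ligand_n_atoms must be in 2..10")
  if (is.null(separation))
    separation <- if (charge_pattern == "neutral") 10 else 4
  set.seed(seed)
  deg <- pi / 180
  # backbone chain
  nres <- n_enzyme_residues
  coords <- matrix(0, 0, 3)
  names_ <- character(0); resids <- integer(0)
  add <- function(p, nm, res) {
    coords <<- rbind(coords, as.numeric(p))
    names_ <<- c(names_, nm); resids <<- c(resids, res)
  }
  add(c(0, 0, 0), "N", 1L)
  add(c(1.46, 0, 0), "CA", 1L)
  add(place_internal(c(-1, 1, 0), c(0, 0, 0), c(1.46, 0, 0),
                     1.52, 111 * deg, 150 * deg), "C", 1L)
  row_of <- function(res, nm) which(resids == res & names_ == nm)
  add(place_internal(coords[row_of(1, "N"), ], coords[row_of(1, "CA"), ],
                     coords[row_of(1, "C"), ], 1.23, 121 * deg, -40 * deg),
      "O", 1L)
  for (r in 2:nres) {
    pN <- place_internal(coords[row_of(r - 1, "N"), ],
                         coords[row_of(r - 1, "CA"), ],
                         coords[row_of(r - 1, "C"), ],
                         1.33, 116 * deg, 140 * deg)       # psi(prev)
    add(pN, "N", r)
    pCA <- place_internal(coords[row_of(r - 1, "CA"), ],
                          coords[row_of(r - 1, "C"), ], pN,
                          1.46, 122 * deg, 180 * deg)      # omega
    add(pCA, "CA", r)
    pC <- place_internal(coords[row_of(r - 1, "C"), ], pN, pCA,
                         1.52, 111 * deg, -120 * deg)      # phi
    add(pC, "C", r)
    add(place_internal(pN, pCA, pC, 1.23, 121 * deg, -40 * deg), "O", r)
  }
  n_enz <- nrow(coords)
  # ligand: zig-zag chain in the xz plane, offset along +y
  lig <- matrix(0, ligand_n_atoms, 3)
  for (k in seq_len(ligand_n_atoms)) {
    lig[k, ] <- c(1.2 * (k - 1), 0, 0.5 * ((k - 1) %% 2))
  }
  lig <- sweep(lig, 2, colMeans(lig), "-")
  centre <- colMeans(coords)
  lig <- sweep(lig, 2, centre, "+")
  lig[, 2] <- lig[, 2] + 1
  gap <- function(L) {
    dmin <- Inf
    for (k in seq_len(nrow(L)))
      dmin <- min(dmin, sqrt(min(rowSums(sweep(coords, 2, L[k, ], "-")^2))))
    dmin
  }
  while (gap(lig) < separation) lig[, 2] <- lig[, 2] + 0.25
  all_coords <- rbind(coords, lig)
  all_coords <- all_coords + matrix(stats::runif(length(all_coords),
                                                 -0.02, 0.02),
                                    nrow(all_coords), 3)
  atoms <- tibble::tibble(
    atom_id = seq_len(n_enz + ligand_n_atoms),
    name = c(names_, paste0("L", seq_len(ligand_n_atoms))),
    element = c(substr(names_, 1, 1), rep("C", ligand_n_atoms)),
    residue_id = c(resids, rep(1L, ligand_n_atoms)),
    residue_name = c(rep("GLY", n_enz), rep("LIG", ligand_n_atoms)),
    chain = c(rep("A", n_enz), rep("B", ligand_n_atoms)),
    molecule_tag = c(rep("enzyme", n_enz), rep("ligand", ligand_n_atoms))
  )
  params <- toy_parameters(lj_epsilon, sasa_coefficient, charge_pattern)
  build_system <- function(all_coords, ligand_charges) {
    pt <- params$atoms
    look <- function(res, atm, col) {
      for (cand in list(c(res, atm), c(res, "*"), c("*", atm), c("*", "*"))) {
        hit <- which(pt$residue_name == cand[1] & pt$atom_name == cand[2])
        if (length(hit)) return(pt[[col]][hit[1]])
      }
      stop("missing toy parameter")
    }
    full <- atoms
    for (cl in c("charge", "lj_epsilon", "lj_rmin_half", "born_radius",
                 "vdw_radius", "sasa_coefficient"))
      full[[cl]] <- unname(mapply(look, full$residue_name, full$name,
                                  MoreArgs = list(col = cl)))
    full$charge[full$molecule_tag == "ligand"] <- ligand_charges
    id <- function(res, nm) atoms$atom_id[row_of(res, nm)]
    dist0 <- function(i, j) sqrt(sum((all_coords[i, ] - all_coords[j, ])^2))
    ang0 <- function(i, j, k) vertex_angle(all_coords, i, j, k)
    bonds <- list(); angles <- list(); ub <- list(); imps <- list()
    dihs <- list()
    for (r in seq_len(nres)) {
      bonds[[length(bonds) + 1]] <- c(id(r, "N"), id(r, "CA"))
      bonds[[length(bonds) + 1]] <- c(id(r, "CA"), id(r, "C"))
      bonds[[length(bonds) + 1]] <- c(id(r, "C"), id(r, "O"))
      if (r < nres) bonds[[length(bonds) + 1]] <- c(id(r, "C"), id(r + 1, "N"))
      angles[[length(angles) + 1]] <- c(id(r, "N"), id(r, "CA"), id(r, "C"))
      angles[[length(angles) + 1]] <- c(id(r, "CA"), id(r, "C"), id(r, "O"))
      ub[[length(ub) + 1]] <- c(id(r, "N"), id(r, "C"))
      if (r < nres) {
        angles[[length(angles) + 1]] <- c(id(r, "CA"), id(r, "C"),
                                          id(r + 1, "N"))
        angles[[length(angles) + 1]] <- c(id(r, "C"), id(r + 1, "N"),
                                          id(r + 1, "CA"))
        imps[[length(imps) + 1]] <- c(id(r, "CA"), id(r + 1, "N"),
                                      id(r, "C"), id(r, "O"))
        dihs[[length(dihs) + 1]] <- c(id(r, "N"), id(r, "CA"), id(r, "C"),
                                      id(r + 1, "N"))
      }
    }
    lig_ids <- atoms$atom_id[atoms$molecule_tag == "ligand"]
    for (k in seq_len(ligand_n_atoms - 1))
      bonds[[length(bonds) + 1]] <- c(lig_ids[k], lig_ids[k + 1])
    if (ligand_n_atoms >= 3)
      for (k in seq_len(ligand_n_atoms - 2))
        angles[[length(angles) + 1]] <- c(lig_ids[k], lig_ids[k + 1],
                                          lig_ids[k + 2])
    bm <- do.call(rbind, bonds); am <- do.call(rbind, angles)
    um <- do.call(rbind, ub); im <- do.call(rbind, imps)
    dm <- do.call(rbind, dihs)
    pos_of <- function(ids) match(ids, atoms$atom_id)
    top <- mm_topology(
      bonds = tibble::tibble(i = bm[, 1], j = bm[, 2], k_b = 1200,
                             r0 = mapply(dist0, pos_of(bm[, 1]),
                                         pos_of(bm[, 2]))),
      angles = tibble::tibble(i = am[, 1], j = am[, 2], k = am[, 3],
                              k_theta = 150,
                              theta0 = mapply(function(i, j, k)
                                ang0(i, j, k), pos_of(am[, 1]),
                                pos_of(am[, 2]), pos_of(am[, 3]))),
      urey_bradley = tibble::tibble(i = um[, 1], k = um[, 2], k_ub = 40,
                                    s0 = mapply(dist0, pos_of(um[, 1]),
                                                pos_of(um[, 2]))),
      dihedrals = if (is.null(dm)) NULL else
        tibble::tibble(i = dm[, 1], j = dm[, 2], k = dm[, 3], l = dm[, 4],
                       k_phi = 1, n = 3L, delta = 0),
      impropers = if (is.null(im)) NULL else
        tibble::tibble(i = im[, 1], j = im[, 2], k = im[, 3], l = im[, 4],
                       k_psi = 40,
                       psi0 = mapply(function(i, j, k, l)
                         torsion_angle(all_coords, i, j, k, l),
                         pos_of(im[, 1]), pos_of(im[, 2]),
                         pos_of(im[, 3]), pos_of(im[, 4])))
    )
    molecular_system(full, all_coords, top,
                     exclusions = sidechain_exclusions(full))
  }
  lig_q <- rep(switch(charge_pattern, neutral = 0, repulsive = 0.25, -0.25),
               ligand_n_atoms)
  substrate <- build_system(all_coords, lig_q)
  # analogue: flattened, re-charged ligand copy
  tsa_coords <- all_coords
  lrows <- n_enz + seq_len(ligand_n_atoms)
  zc <- mean(tsa_coords[lrows, 3])
  tsa_coords[lrows, 3] <- zc + 0.4 * (tsa_coords[lrows, 3] - zc)
  tsa_q <- lig_q * 1.3
  if (charge_pattern != "neutral") tsa_q[1] <- tsa_q[1] + 0.1
  tsa <- build_system(tsa_coords, tsa_q)
  mid <- ceiling(nres / 2)
  d0 <- sqrt(sum((all_coords[row_of(mid, "CA"), ] -
                    all_coords[n_enz + 1, ])^2))
  restraints <- noe_restraints("A", mid, "CA", "B", 1L, "L1",
                               max(0.5, d0 - 0.5), d0 + 0.5, 75, 100)
  list(substrate = substrate, tsa = tsa, restraints = restraints,
       params = params)
}

#' A small synthetic rotamer library
#'
#' Two rotamers for each of the 20 standard amino acids: a CB atom at the
#' canonical tetrahedral position in the local backbone frame plus (for all
#' but alanine and glycine) a distal CG atom at one of two chi-like
#' orientations. Glycine carries two empty rotamers. This is a synthetic
#' stand-in sized for tests and examples, not a statistical rotamer library;
#' real backbone-dependent libraries can be supplied through
#' [read_rotamer_library()].
#'
#' @return a rotamer library list (see [read_rotamer_library()]).
#' @export
toy_rotamer_library <- function() {
  cb <- c(-0.57, -1.21, 0.95)          # ~1.6 A from CA, off the N-CA-C plane
  dir1 <- c(0.2, -0.9, 0.6); dir1 <- dir1 / sqrt(sum(dir1^2))
  dir2 <- c(-0.9, -0.2, 0.6); dir2 <- dir2 / sqrt(sum(dir2^2))
  lib <- list()
  for (rt in AA3) {
    if (rt == "GLY") {
      rot <- function(p) list(residue_type = "GLY", probability = p,
                              atoms = tibble::tibble(name = character(0),
                                                     x = numeric(0),
                                                     y = numeric(0),
                                                     z = numeric(0)))
      lib[[rt]] <- list(rot(0.5), rot(0.5))
      next
    }
    mk <- function(d, p) {
      atoms <- tibble::tibble(name = "CB", x = cb[1], y = cb[2], z = cb[3])
      if (rt != "ALA") {
        cg <- cb + 1.5 * d
        atoms <- dplyr::bind_rows(atoms, tibble::tibble(
          name = "CG", x = cg[1], y = cg[2], z = cg[3]))
      }
      list(residue_type = rt, probability = p, atoms = atoms)
    }
    lib[[rt]] <- list(mk(dir1, 0.6), mk(dir2, 0.4))
  }
  lib
}

#' Generate synthetic kinetics obeying the correlating equations
#'
#' Draws interaction energies uniformly from [-1600, -100] kJ/mol (the span
#' of the redesign libraries) and builds kinetic parameters exactly from the
#' correlating model: ln K_M = IE_S/(RT)_S + c1 (+ noise),
#' ln(k_cat/K_M) = -IE_TSA/(RT)_TSA + c2 (+ noise), k_cat by product.
#' With zero noise the three correlation fits recover the RT constants
#' exactly.
#'
#' @param n_variants number of variants (>= 3).
#' @param rt_s,rt_tsa effective RT constants, kJ/mol.
#' @param intercepts numeric pair (c1 for ln K_M in mM, c2 for
#'   ln k_cat/K_M in 1/(mM s)).
#' @param noise_sd_ln Gaussian noise SD on the ln scale (>= 0).
#' @param seed integer seed.
#' @param ie_range interaction-energy range sampled, kJ/mol.
#' @return list with `ie` (variant_id, ie_s, ie_tsa) and `kinetics`
#'   (variant_id, km, kcat, kcat_over_km) tibbles.
#' @export
generate_synthetic_kinetics <- function(n_variants = 100, rt_s = 386.7,
                                        rt_tsa = 15.3,
                                        intercepts = c(2.5, -3),
                                        noise_sd_ln = 0, seed = 1,
                                        ie_range = c(-1600, -100)) {
  stopifnot(n_variants >= 3, noise_sd_ln >= 0)
  set.seed(seed)
  ie_s <- stats::runif(n_variants, ie_range[1], ie_range[2])
  ie_tsa <- stats::runif(n_variants, ie_range[1], ie_range[2])
  ln_km <- ie_s / rt_s + intercepts[1] +
    stats::rnorm(n_variants, 0, noise_sd_ln)
  ln_eff <- -ie_tsa / rt_tsa + intercepts[2] +
    stats::rnorm(n_variants, 0, noise_sd_ln)
  id <- sprintf("V%03d", seq_len(n_variants))
  list(
    ie = tibble::tibble(variant_id = id, ie_s = ie_s, ie_tsa = ie_tsa),
    kinetics = tibble::tibble(variant_id = id, km = exp(ln_km),
                              kcat = exp(ln_km + ln_eff),
                              kcat_over_km = exp(ln_eff))
  )
}
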