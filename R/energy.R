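#' Energy breakdown of a molecular system
#'
#' All components in kJ/mol. `total` always equals the sum of the nine
#' components.
#'
#' @name energy_breakdown
#' @keywords internal
NULL

energy_breakdown <- function(bond = 0, angle = 0, urey_bradley = 0,
                             dihedral = 0, improper = 0, vdw = 0,
                             electrostatic = 0, gb_polar = 0,
                             asa_nonpolar = 0, noe = 0) {
  tb <- tibble::tibble(
    bond = bond, angle = angle, urey_bradley = urey_bradley,
    dihedral = dihedral, improper = improper, vdw = vdw,
    electrostatic = electrostatic, gb_polar = gb_polar,
    asa_nonpolar = asa_nonpolar, noe = noe
  )
  tb$total <- rowSums(tb)
  class(tb) <- c("energy_breakdown", class(tb))
  tb
}

pair_dist <- function(coords, i, j) {
  d <- coords[i, , drop = FALSE] - coords[j, , drop = FALSE]
  sqrt(rowSums(d * d))
}

# angle at vertex j (radians); errors on zero-length arms
vertex_angle <- function(coords, i, j, k) {
  u <- coords[i, , drop = FALSE] - coords[j, , drop = FALSE]
  v <- coords[k, , drop = FALSE] - coords[j, , drop = FALSE]
  nu <- sqrt(rowSums(u * u)); nv <- sqrt(rowSums(v * v))
  if (any(nu == 0) || any(nv == 0))
    stop("zero-length bond vector in angle evaluation")
  cosang <- rowSums(u * v) / (nu * nv)
  acos(pmin(1, pmax(-1, cosang)))
}

# signed torsion i-j-k-l (radians)
torsion_angle <- function(coords, i, j, k, l) {
  b1 <- coords[j, , drop = FALSE] - coords[i, , drop = FALSE]
  b2 <- coords[k, , drop = FALSE] - coords[j, , drop = FALSE]
  b3 <- coords[l, , drop = FALSE] - coords[k, , drop = FALSE]
  n1 <- row_cross(b1, b2); n2 <- row_cross(b2, b3)
  nb2 <- sqrt(rowSums(b2 * b2))
  if (any(nb2 == 0) || any(rowSums(n1 * n1) == 0) || any(rowSums(n2 * n2) == 0))
    stop("degenerate geometry in torsion evaluation")
  x <- rowSums(n1 * n2)
  y <- rowSums(row_cross(n1, n2) * (b2 / nb2))
  atan2(y, x)
}

row_cross <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

#' Bonded energy terms
#'
#' Harmonic bond, angle, Urey-Bradley (1-3 distance) and improper terms use
#' E = k (x - x0)^2; proper torsions use E = k_phi (1 + cos(n phi - delta)).
#'
#' @param system a [molecular_system()].
#' @return one-row tibble with columns bond, angle, urey_bradley, dihedral,
#'   improper (kJ/mol).
#' @export
bonded_energy <- function(system) {
  tibble::as_tibble(as.list(bonded_energy_vec(system)))
}

bonded_energy_vec <- function(system) {
  top <- system$topology; X <- system$coords
  e <- c(bond = 0, angle = 0, urey_bradley = 0, dihedral = 0, improper = 0)
  if (nrow(top$bonds)) {
    r <- pair_dist(X, id_to_row(system, top$bonds$i),
                   id_to_row(system, top$bonds$j))
    e["bond"] <- sum(top$bonds$k_b * (r - top$bonds$r0)^2)
  }
  if (nrow(top$angles)) {
    th <- vertex_angle(X, id_to_row(system, top$angles$i),
                       id_to_row(system, top$angles$j),
                       id_to_row(system, top$angles$k))
    e["angle"] <- sum(top$angles$k_theta * (th - top$angles$theta0)^2)
  }
  if (nrow(top$urey_bradley)) {
    s <- pair_dist(X, id_to_row(system, top$urey_bradley$i),
                   id_to_row(system, top$urey_bradley$k))
    e["urey_bradley"] <- sum(top$urey_bradley$k_ub * (s - top$urey_bradley$s0)^2)
  }
  if (nrow(top$dihedrals)) {
    phi <- torsion_angle(X, id_to_row(system, top$dihedrals$i),
                         id_to_row(system, top$dihedrals$j),
                         id_to_row(system, top$dihedrals$k),
                         id_to_row(system, top$dihedrals$l))
    e["dihedral"] <- sum(top$dihedrals$k_phi *
                           (1 + cos(top$dihedrals$n * phi - top$dihedrals$delta)))
  }
  if (nrow(top$impropers)) {
    psi <- torsion_angle(X, id_to_row(system, top$impropers$i),
                         id_to_row(system, top$impropers$j),
                         id_to_row(system, top$impropers$k),
                         id_to_row(system, top$impropers$l))
    dpsi <- wrap_angle(psi - top$impropers$psi0)
    e["improper"] <- sum(top$impropers$k_psi * dpsi^2)
  }
  e
}

# wrap to (-pi, pi]
wrap_angle <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  y[y == -pi] <- pi
  y
}

# nonbonded pair list: row indices (i < j), honoring exclusions and scope
nonbonded_pairs <- function(system, pair_scope = c("all", "cross_molecule")) {
  pair_scope <- match.arg(pair_scope)
  n <- n_atoms(system)
  if (n < 2) return(matrix(integer(0), ncol = 2))
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  ids <- system$atoms$atom_id
  if (nrow(system$exclusions)) {
    # numeric pair codes are much cheaper than string keys
    key <- pmin(ids[idx[, 1]], ids[idx[, 2]]) * 2^20 +
      pmax(ids[idx[, 1]], ids[idx[, 2]])
    exkey <- system$exclusions[, 1] * 2^20 + system$exclusions[, 2]
    idx <- idx[!(key %in% exkey), , drop = FALSE]
  }
  if (pair_scope == "cross_molecule") {
    tag <- system$atoms$molecule_tag
    idx <- idx[tag[idx[, 1]] != tag[idx[, 2]], , drop = FALSE]
  }
  idx
}

#' Nonbonded (Lennard-Jones and Coulomb) energy
#'
#' Lennard-Jones uses the rmin convention
#' E = eps_ij ((rmin_ij/r)^12 - 2 (rmin_ij/r)^6) with Lorentz-Berthelot-style
#' combination eps_ij = sqrt(eps_i eps_j), rmin_ij = rmin_half_i + rmin_half_j.
#' Coulomb is K_e q_i q_j / r in vacuum dielectric. 1-2 and 1-3 pairs are
#' excluded; 1-4 pairs interact at full strength. No distance cutoff is
#' applied.
#'
#' @param system a [molecular_system()].
#' @param pair_scope "all" (every included pair) or "cross_molecule" (only
#'   pairs whose atoms carry different molecule tags).
#' @return one-row tibble with columns vdw and electrostatic (kJ/mol).
#' @export
nonbonded_energy <- function(system, pair_scope = c("all", "cross_molecule")) {
  v <- nonbonded_energy_vec(system, match.arg(pair_scope))
  tibble::tibble(vdw = v[["vdw"]], electrostatic = v[["electrostatic"]])
}

nonbonded_energy_vec <- function(system, pair_scope) {
  idx <- nonbonded_pairs(system, pair_scope)
  if (!nrow(idx)) return(c(vdw = 0, electrostatic = 0))
  at <- system$atoms
  r <- pair_dist(system$coords, idx[, 1], idx[, 2])
  if (any(r == 0)) stop("coincident atoms in nonbonded pair (r = 0)")
  epsij <- sqrt(at$lj_epsilon[idx[, 1]] * at$lj_epsilon[idx[, 2]])
  rmin <- at$lj_rmin_half[idx[, 1]] + at$lj_rmin_half[idx[, 2]]
  sr6 <- (rmin / r)^6
  vdw <- sum(epsij * (sr6^2 - 2 * sr6))
  elec <- sum(mm_constants$KE * at$charge[idx[, 1]] * at$charge[idx[, 2]] / r)
  c(vdw = vdw, electrostatic = elec)
}

# Still-form generalized Born with fixed input Born radii; includes
# self-terms. eps_in = 1, eps_out = 80.
gb_energy <- function(system) {
  at <- system$atoms
  if (any(at$born_radius <= 0)) stop("nonpositive Born radius")
  q <- at$charge
  if (all(q == 0)) return(0)
  a <- at$born_radius
  n <- length(q)
  pref <- -mm_constants$KE / 2 *
    (1 / mm_constants$EPS_IN - 1 / mm_constants$EPS_OUT)
  self <- sum(q^2 / a)
  cross <- 0
  if (n >= 2) {
    idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    r2 <- rowSums((system$coords[idx[, 1], , drop = FALSE] -
                     system$coords[idx[, 2], , drop = FALSE])^2)
    ab <- a[idx[, 1]] * a[idx[, 2]]
    fgb <- sqrt(r2 + ab * exp(-r2 / (4 * ab)))
    cross <- 2 * sum(q[idx[, 1]] * q[idx[, 2]] / fgb)
  }
  pref * (self + cross)
}

# deterministic golden-spiral unit sphere points
sphere_points <- function(n = 256) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Deterministic 256-point golden-spiral sphere per atom, probe radius 1.4 A.
#'
#' @param system a [molecular_system()].
#' @param probe probe radius, angstrom.
#' @param n_points points per atom sphere.
#' @return numeric vector of per-atom areas (A^2).
#' @export
sasa <- function(system, probe = 1.4, n_points = 256) {
  at <- system$atoms; X <- system$coords
  n <- nrow(at)
  pts <- sphere_points(n_points)
  radii <- at$vdw_radius + probe
  out <- numeric(n)
  for (i in seq_len(n)) {
    ri <- radii[i]
    surf <- sweep(pts * ri, 2, X[i, ], "+")
    # candidate occluders: spheres that can reach atom i's surface
    d2 <- rowSums(sweep(X, 2, X[i, ], "-")^2)
    nb <- which(d2 < (ri + radii)^2 & seq_len(n) != i)
    if (!length(nb)) { out[i] <- 4 * pi * ri^2; next }
    acc <- rep(TRUE, n_points)
    for (jj in nb) {
      dd <- sweep(surf, 2, X[jj, ], "-")
      acc <- acc & (rowSums(dd * dd) > radii[jj]^2)
      if (!any(acc)) break
    }
    out[i] <- 4 * pi * ri^2 * mean(acc)
  }
  out
}

#' Implicit-solvation energy
#'
#' Polar part: pairwise Still-form generalized Born,
#' f_GB = sqrt(r^2 + a_i a_j exp(-r^2 / (4 a_i a_j))), with user-supplied Born
#' radii (interior dielectric 1, exterior 80), including self-terms. Nonpolar
#' part: per-atom accessible-surface-area model,
#' sum_i sasa_coefficient_i * SASA_i.
#'
#' @param system a [molecular_system()].
#' @return one-row tibble with columns gb_polar and asa_nonpolar (kJ/mol).
#' @export
solvation_energy <- function(system) {
  v <- solvation_energy_vec(system)
  tibble::tibble(gb_polar = v[["gb_polar"]], asa_nonpolar = v[["asa_nonpolar"]])
}

solvation_energy_vec <- function(system) {
  gb <- gb_energy(system)
  asa <- if (all(system$atoms$sasa_coefficient == 0)) 0 else
    sum(system$atoms$sasa_coefficient * sasa(system))
  c(gb_polar = gb, asa_nonpolar = asa)
}

#' Flat-bottom NOE restraint table
#'
#' One row per restraint; atoms are selected by chain + residue id + atom
#' name. Distances below `d_min` are penalized with the softer constant
#' `k_min`, distances above `d_max` with the stiffer `k_max` (catalytic
#' contacts stay intact at small distances, hence k_min < k_max is typical).
#'
#' @param chain_a,res_a,atom_a selector of the first atom.
#' @param chain_b,res_b,atom_b selector of the second atom.
#' @param d_min,d_max flat-bottom window, angstrom (d_min <= d_max).
#' @param k_min,k_max harmonic constants, kJ/(mol A^2) (k_min <= k_max).
#' @return a tibble of class "noe_restraints".
#' @export
noe_restraints <- function(chain_a, res_a, atom_a, chain_b, res_b, atom_b,
                           d_min, d_max, k_min, k_max) {
  tb <- tibble::tibble(
    chain_a = as.character(chain_a), res_a = as.integer(res_a),
    atom_a = as.character(atom_a),
    chain_b = as.character(chain_b), res_b = as.integer(res_b),
    atom_b = as.character(atom_b),
    d_min = as.numeric(d_min), d_max = as.numeric(d_max),
    k_min = as.numeric(k_min), k_max = as.numeric(k_max)
  )
  if (any(tb$d_min > tb$d_max)) stop("d_min must be <= d_max")
  if (any(tb$k_min > tb$k_max)) stop("k_min must be <= k_max")
  class(tb) <- c("noe_restraints", class(tb))
  tb
}

# resolve restraint selectors to row indices; errors if not unique
resolve_restraints <- function(system, restraints) {
  at <- system$atoms
  find1 <- function(ch, rs, nm) {
    hit <- which(at$chain == ch & at$residue_id == rs & at$name == nm)
    if (length(hit) != 1)
      stop(sprintf("restraint selector %s/%d/%s resolves to %d atoms",
                   ch, rs, nm, length(hit)))
    hit
  }
  ia <- mapply(find1, restraints$chain_a, restraints$res_a, restraints$atom_a)
  ib <- mapply(find1, restraints$chain_b, restraints$res_b, restraints$atom_b)
  cbind(ia, ib)
}

#' NOE restraint energy
#'
#' Per restraint: k_min (d - d_min)^2 below the window, 0 inside,
#' k_max (d - d_max)^2 above; continuous (and zero) at both walls.
#'
#' @param system a [molecular_system()].
#' @param restraints a [noe_restraints()] table (NULL for none).
#' @return total restraint energy, kJ/mol.
#' @export
noe_energy <- function(system, restraints) {
  if (is.null(restraints) || !nrow(restraints)) return(0)
  rows <- resolve_restraints(system, restraints)
  d <- pair_dist(system$coords, rows[, 1], rows[, 2])
  e <- ifelse(d < restraints$d_min,
              restraints$k_min * (d - restraints$d_min)^2,
              ifelse(d > restraints$d_max,
                     restraints$k_max * (d - restraints$d_max)^2, 0))
  sum(e)
}

#' Total molecular-mechanics energy with breakdown
#'
#' Sums bonded (bond, angle, Urey-Bradley, dihedral, improper), nonbonded
#' (Lennard-Jones, Coulomb), implicit-solvation (generalized Born polar,
#' accessible-area nonpolar) and NOE restraint terms.
#'
#' @param system a [molecular_system()].
#' @param restraints optional [noe_restraints()] table.
#' @param solvation if FALSE, skip both solvation terms (vacuum evaluation).
#' @return a one-row "energy_breakdown" tibble; `total` is the component sum.
#' @export
total_energy <- function(system, restraints = NULL, solvation = TRUE) {
  v <- total_energy_vec(system, restraints, solvation)
  energy_breakdown(
    bond = v[["bond"]], angle = v[["angle"]],
    urey_bradley = v[["urey_bradley"]], dihedral = v[["dihedral"]],
    improper = v[["improper"]], vdw = v[["vdw"]],
    electrostatic = v[["electrostatic"]], gb_polar = v[["gb_polar"]],
    asa_nonpolar = v[["asa_nonpolar"]], noe = v[["noe"]]
  )
}

# tibble-free evaluation used by the minimizer and search loops
total_energy_vec <- function(system, restraints = NULL, solvation = TRUE) {
  zero <- c(bond = 0, angle = 0, urey_bradley = 0, dihedral = 0,
            improper = 0, vdw = 0, electrostatic = 0, gb_polar = 0,
            asa_nonpolar = 0, noe = 0)
  if (n_atoms(system) == 0) return(zero)
  sv <- if (solvation) solvation_energy_vec(system) else
    c(gb_polar = 0, asa_nonpolar = 0)
  c(bonded_energy_vec(system), nonbonded_energy_vec(system, "all"), sv,
    noe = noe_energy(system, restraints))
}
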