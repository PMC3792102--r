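# shared builders for tiny molecular systems used across the suite

# a bare n-atom system with uniform parameters and no topology
bare_system <- function(coords, charge = 0, lj_epsilon = 0, lj_rmin_half = 1.8,
                        born_radius = 2, sasa_coefficient = 0,
                        vdw_radius = 1.6, tag = "enzyme",
                        topology = mm_topology(), names = NULL,
                        chain = "A", residue_id = NULL) {
  coords <- matrix(coords, ncol = 3)
  n <- nrow(coords)
  molecular_system(
    atom_table(seq_len(n),
               if (is.null(names)) paste0("X", seq_len(n)) else names,
               "C",
               if (is.null(residue_id)) rep(1L, n) else residue_id,
               "RES", chain,
               rep_len(tag, n), rep_len(charge, n),
               rep_len(lj_epsilon, n), rep_len(lj_rmin_half, n),
               rep_len(born_radius, n), rep_len(sasa_coefficient, n),
               rep_len(vdw_radius, n)),
    coords, topology)
}

# a diatomic with one harmonic bond
diatomic <- function(r, k_b = 100, r0 = 1.5, ...) {
  bare_system(rbind(c(0, 0, 0), c(r, 0, 0)),
              topology = mm_topology(bonds = data.frame(i = 1, j = 2,
                                                        k_b = k_b, r0 = r0)),
              ...)
}

# a random charged cluster with some bonded terms, for gradient checks
random_system <- function(n, seed, sasa_coefficient = 0) {
  set.seed(seed)
  top <- mm_topology(
    bonds = data.frame(i = 1, j = 2, k_b = 300, r0 = 1.5),
    angles = data.frame(i = 1, j = 2, k = 3, k_theta = 80, theta0 = 1.9),
    dihedrals = data.frame(i = 1, j = 2, k = 3, l = 4, k_phi = 4, n = 2,
                           delta = 0.4),
    impropers = data.frame(i = 1, j = 2, k = 3, l = 4, k_psi = 25,
                           psi0 = 0.3),
    urey_bradley = data.frame(i = 1, k = 3, k_ub = 30, s0 = 2.4)
  )
  bare_system(matrix(stats::rnorm(3 * n, sd = 2.5), n, 3),
              charge = stats::runif(n, -0.4, 0.4), lj_epsilon = 0.25,
              sasa_coefficient = sasa_coefficient, topology = top)
}

# finite-difference gradient of the total energy
fd_gradient <- function(system, restraints = NULL, h = 1e-6) {
  G <- matrix(0, n_atoms(system), 3)
  for (i in seq_len(n_atoms(system))) for (k in 1:3) {
    cp <- system; cm <- system
    cp$coords[i, k] <- cp$coords[i, k] + h
    cm$coords[i, k] <- cm$coords[i, k] - h
    G[i, k] <- (total_energy(cp, restraints)$total -
                  total_energy(cm, restraints)$total) / (2 * h)
  }
  G
}

# cached toy complex shared by the slower redesign tests
toy_cached <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generate_toy_complex(4, 4, "complementary", seed = 1,
                                     sasa_coefficient = 0)
    cache
  }
})

toy_library <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- toy_rotamer_library()
    cache
  }
})
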