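test_that("harmonic bonded terms follow the k(x - x0)^2 convention", {
  expect_equal(bonded_energy(diatomic(1.5))$bond, 0)
  # k = 100 kJ/(mol A^2), displacement 0.1 A -> 1.0 kJ/mol, no 1/2 prefactor
  expect_equal(bonded_energy(diatomic(1.6))$bond, 1.0, tolerance = 1e-12)
  expect_equal(bonded_energy(diatomic(1.4))$bond, 1.0, tolerance = 1e-12)
})

test_that("torsion energy is k(1 + cos(n phi - delta))", {
  # planar zig-zag with phi = 180 degrees
  X <- rbind(c(0, 1, 0), c(0, 0, 0), c(1.5, 0, 0), c(1.5, -1, 0))
  top <- mm_topology(dihedrals = data.frame(i = 1, j = 2, k = 3, l = 4,
                                            k_phi = 5, n = 1, delta = 0))
  sys <- bare_system(X, topology = top)
  expect_equal(bonded_energy(sys)$dihedral, 0, tolerance = 1e-12)
  # each term is bounded by [0, 2 k_phi]
  for (seed in 1:5) {
    s <- random_system(4, seed)
    expect_gte(bonded_energy(s)$dihedral, 0)
    expect_lte(bonded_energy(s)$dihedral, 2 * 4)
  }
})

test_that("Lennard-Jones reaches -sqrt(eps_i eps_j) at the combined rmin", {
  sys <- bare_system(rbind(c(0, 0, 0), c(3.6, 0, 0)), lj_epsilon = c(0.4, 0.9))
  nb <- nonbonded_energy(sys)
  expect_equal(nb$vdw, -sqrt(0.4 * 0.9), tolerance = 1e-12)
  expect_equal(nb$electrostatic, 0)
})

test_that("Coulomb energy uses K_e = 1389.354 kJ A/(mol e^2)", {
  sys <- bare_system(rbind(c(0, 0, 0), c(3, 0, 0)), charge = c(1, -1))
  expect_equal(nonbonded_energy(sys)$electrostatic, -1389.354 / 3,
               tolerance = 1e-12)
  expect_equal(nonbonded_energy(sys)$electrostatic, -463.118,
               tolerance = 1e-4)
})

test_that("nonbonded terms decay to zero at large separation", {
  sys <- bare_system(rbind(c(0, 0, 0), c(1e6, 0, 0)), charge = c(1e-5, -1e-5),
                     lj_epsilon = 0.5)
  nb <- nonbonded_energy(sys)
  expect_lt(abs(nb$vdw), 1e-12)
  expect_lt(abs(nb$electrostatic), 1e-12)
  expect_error(nonbonded_energy(bare_system(rbind(c(0, 0, 0), c(0, 0, 0)))),
               "coincident")
})

test_that("excluded and cross-molecule pair scopes are honored", {
  sys <- bare_system(rbind(c(0, 0, 0), c(1.5, 0, 0), c(10, 0, 0)),
                     charge = c(0.5, -0.5, 0.3),
                     tag = c("enzyme", "enzyme", "ligand"),
                     topology = mm_topology(bonds = data.frame(
                       i = 1, j = 2, k_b = 100, r0 = 1.5)))
  # bonded 1-2 pair excluded: only pairs 1-3 and 2-3 remain
  all_e <- nonbonded_energy(sys, "all")$electrostatic
  manual <- 1389.354 * (0.5 * 0.3 / 10 + (-0.5) * 0.3 / 8.5)
  expect_equal(all_e, manual, tolerance = 1e-10)
  # cross scope drops nothing here (both remaining pairs are cross)
  expect_equal(nonbonded_energy(sys, "cross_molecule")$electrostatic, all_e)
})

test_that("generalized Born reproduces the Born self-energy closed form", {
  ion <- bare_system(c(0, 0, 0), charge = 1, born_radius = 2)
  gb <- solvation_energy(ion)$gb_polar
  expect_equal(gb, -(1389.354 / 2) * (1 - 1 / 80) / 2, tolerance = 1e-10)
  expect_equal(gb, -342.99, tolerance = 1e-2)
  # zero charges -> zero polar term
  expect_equal(solvation_energy(bare_system(matrix(rnorm(9), 3, 3)))$gb_polar,
               0)
})

test_that("surface-area term vanishes for a buried atom", {
  # central atom enclosed by an octahedron of large spheres
  d <- 2.2
  shell <- rbind(c(d, 0, 0), c(-d, 0, 0), c(0, d, 0), c(0, -d, 0),
                 c(0, 0, d), c(0, 0, -d))
  sys <- bare_system(rbind(c(0, 0, 0), shell), vdw_radius = c(1, rep(2.5, 6)),
                     sasa_coefficient = c(1, rep(0, 6)))
  expect_equal(solvation_energy(sys)$asa_nonpolar, 0)
  # an isolated atom is fully exposed: 4 pi (r + probe)^2
  lone <- bare_system(c(0, 0, 0), vdw_radius = 1.6, sasa_coefficient = 1)
  expect_equal(solvation_energy(lone)$asa_nonpolar, 4 * pi * 3^2,
               tolerance = 1e-6)
})

test_that("NOE flat-bottom restraint matches hand-evaluated walls", {
  mk <- function(d) bare_system(rbind(c(0, 0, 0), c(d, 0, 0)),
                                names = c("HE2", "O6"),
                                residue_id = c(413L, 1L),
                                chain = c("A", "B"),
                                tag = c("enzyme", "ligand"))
  rst <- noe_restraints("A", 413, "HE2", "B", 1, "O6", 1.7, 1.8, 75, 100)
  expect_equal(noe_energy(mk(1.75), rst), 0)
  expect_equal(noe_energy(mk(1.6), rst), 75 * 0.1^2, tolerance = 1e-12)
  expect_equal(noe_energy(mk(1.9), rst), 100 * 0.1^2, tolerance = 1e-12)
  # continuity: zero at both walls
  expect_equal(noe_energy(mk(1.7), rst), 0)
  expect_equal(noe_energy(mk(1.8), rst), 0)
  expect_error(noe_restraints("A", 1, "X", "B", 1, "Y", 2, 1, 75, 100),
               "d_min")
  expect_error(noe_restraints("A", 1, "X", "B", 1, "Y", 1, 2, 100, 75),
               "k_min")
})

test_that("total energy equals the component sum on varied fixtures", {
  for (seed in 1:5) {
    s <- random_system(6, seed, sasa_coefficient = 0.0226)
    e <- total_energy(s)
    comp <- e$bond + e$angle + e$urey_bradley + e$dihedral + e$improper +
      e$vdw + e$electrostatic + e$gb_polar + e$asa_nonpolar + e$noe
    expect_equal(e$total, comp, tolerance = 1e-9)
  }
  # empty system
  e0 <- total_energy(molecular_system(
    atom_table(integer(0), character(0), character(0), integer(0),
               character(0), character(0), character(0), numeric(0),
               numeric(0), numeric(0), numeric(0), numeric(0), numeric(0)),
    matrix(numeric(0), 0, 3)))
  expect_equal(e0$total, 0)
})

test_that("energies are invariant under rigid rotation and translation", {
  s <- random_system(8, 11)
  rot <- function(th) rbind(c(cos(th), -sin(th), 0),
                            c(sin(th), cos(th), 0), c(0, 0, 1))
  s2 <- s
  s2$coords <- sweep(s$coords %*% rot(0.83), 2, c(5, -3, 2), "+")
  e1 <- total_energy(s); e2 <- total_energy(s2)
  for (cl in c("bond", "angle", "urey_bradley", "dihedral", "improper",
               "vdw", "electrostatic", "gb_polar"))
    expect_equal(e2[[cl]], e1[[cl]], tolerance = 1e-6)
  # the point-sampled surface area is exactly translation-invariant and
  # rotation-invariant to sampling resolution
  s3 <- random_system(8, 11, sasa_coefficient = 0.0226)
  s4 <- s3; s4$coords <- sweep(s3$coords, 2, c(7, 1, -4), "+")
  expect_equal(total_energy(s4)$asa_nonpolar, total_energy(s3)$asa_nonpolar,
               tolerance = 1e-9)
  s5 <- s3; s5$coords <- s3$coords %*% rot(0.83)
  expect_equal(total_energy(s5)$asa_nonpolar, total_energy(s3)$asa_nonpolar,
               tolerance = 0.1)
})

test_that("analytic gradient matches finite differences on random systems", {
  for (seed in c(2, 5, 9)) {
    s <- random_system(6, seed)
    G <- energy_gradient(s)
    expect_lt(max(abs(G - fd_gradient(s))) / max(abs(G)), 1e-4)
  }
  # including restraints
  s <- random_system(4, 3)
  s$atoms$name <- c("HE2", "O6", "A3", "A4")
  s$atoms$residue_id <- c(413L, 1L, 2L, 3L)
  s$atoms$chain <- c("A", "B", "A", "A")
  rst <- noe_restraints("A", 413, "HE2", "B", 1, "O6", 1.0, 1.4, 75, 100)
  G <- energy_gradient(s, rst)
  expect_lt(max(abs(G - fd_gradient(s, rst))) / max(abs(G)), 1e-4)
})

test_that("minimization is monotone and solves the diatomic analytically", {
  # already at the stationary point: coordinates unchanged
  s0 <- diatomic(1.5)
  m0 <- minimize(s0, max_steps = 50)
  expect_lt(max(abs(m0$system$coords - s0$coords)), 1e-8)
  # unique analytic minimum at r0 = 1.5
  m <- minimize(diatomic(2.0), max_steps = 500, grad_tol = 1e-5)
  r <- sqrt(sum((m$system$coords[1, ] - m$system$coords[2, ])^2))
  expect_lt(abs(r - 1.5), 1e-4)
  expect_true(all(diff(m$trace) <= 1e-9))
  # monotone on a messy system too
  mm <- minimize(random_system(6, 4, sasa_coefficient = 0.0226),
                 max_steps = 80)
  expect_true(all(diff(mm$trace) <= 1e-9))
  expect_lte(utils::tail(mm$trace, 1), mm$trace[1])
})

test_that("interaction energy is zero without cross terms", {
  tc <- generate_toy_complex(3, 4, "neutral", seed = 2, lj_epsilon = 0)
  expect_lt(abs(interaction_energy(tc$substrate, NULL, max_steps = 30)),
            1e-10)
})

test_that("interaction energy equals the cross-pair oracle without solvation", {
  for (seed in 1:3) {
    tc <- generate_toy_complex(3, 4, "complementary", seed = seed,
                               sasa_coefficient = 0)
    d <- interaction_energy(tc$substrate, NULL, max_steps = 60,
                            detail = TRUE, solvation = FALSE)
    # brute force: loop over every cross-molecule pair at the minimized
    # geometry, no shared code with the pair-scope implementation
    sys <- d$complex
    at <- sys$atoms
    excl_key <- sys$exclusions[, 1] * 1e6 + sys$exclusions[, 2]
    acc <- 0
    for (i in seq_len(n_atoms(sys) - 1)) for (j in (i + 1):n_atoms(sys)) {
      if (at$molecule_tag[i] == at$molecule_tag[j]) next
      ids <- sort(c(at$atom_id[i], at$atom_id[j]))
      if ((ids[1] * 1e6 + ids[2]) %in% excl_key) next
      r <- sqrt(sum((sys$coords[i, ] - sys$coords[j, ])^2))
      eps <- sqrt(at$lj_epsilon[i] * at$lj_epsilon[j])
      rmin <- at$lj_rmin_half[i] + at$lj_rmin_half[j]
      acc <- acc + eps * ((rmin / r)^12 - 2 * (rmin / r)^6) +
        1389.354 * at$charge[i] * at$charge[j] / r
    }
    expect_equal(d$ie, acc, tolerance = 1e-8)
  }
})

test_that("complementary charges give a favorable interaction energy", {
  tc <- generate_toy_complex(3, 4, "complementary", seed = 1)
  expect_lt(interaction_energy(tc$substrate, tc$restraints, max_steps = 120),
            0)
})

test_that("binding energy equals IE for rigid (single-atom) partners", {
  sys <- bare_system(rbind(c(0, 0, 0), c(3, 0, 0)), charge = c(0.5, -0.5),
                     lj_epsilon = 0.3, tag = c("enzyme", "ligand"))
  ie <- interaction_energy(sys, max_steps = 100)
  be <- binding_energy(sys, max_steps = 100)
  expect_equal(be, ie, tolerance = 1e-8)
})

test_that("binding energy matches an explicit three-minimization oracle", {
  tc <- generate_toy_complex(3, 3, "complementary", seed = 4,
                             sasa_coefficient = 0)
  be <- binding_energy(tc$substrate, tc$restraints, max_steps = 80)
  e_cx <- minimize(tc$substrate, tc$restraints, max_steps = 80)$energy$total
  e_en <- minimize(subsystem(tc$substrate, "enzyme"), max_steps = 80)$energy$total
  e_li <- minimize(subsystem(tc$substrate, "ligand"), max_steps = 80)$energy$total
  expect_equal(be, e_cx - e_en - e_li, tolerance = 1e-9)
  # relaxing the separated parts can only lower their energies, so BE <= IE
  ie <- interaction_energy(tc$substrate, tc$restraints, max_steps = 80)
  expect_lte(be, ie + 1e-6)
})
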