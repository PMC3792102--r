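test_that("Metropolis acceptance reproduces the annealing calibration", {
  # downhill moves always accepted
  expect_equal(metropolis_acceptance(-5, 300), 1)
  expect_equal(metropolis_acceptance(0, 300), 1)
  # a 10 kcal/mol (41.9 kJ/mol) increase at 7268 K is accepted ~half the time
  expect_equal(metropolis_acceptance(41.9, 7268), 0.5, tolerance = 2e-3)
  # analytic half-acceptance point at any temperature
  for (temp in c(10, 300, 7268))
    expect_equal(metropolis_acceptance(mm_constants$R * temp * log(2), temp),
                 0.5, tolerance = 1e-12)
  expect_error(metropolis_acceptance(1, 0), "temperature")
})

test_that("acceptance probability is monotone in energy and temperature", {
  de <- seq(1, 100, by = 1)
  p <- metropolis_acceptance(de, 500)
  expect_true(all(diff(p) < 0))
  temps <- seq(100, 5000, by = 100)
  pt <- vapply(temps, function(tt) metropolis_acceptance(20, tt), 0)
  expect_true(all(diff(pt) > 0))
  # the T -> 0 limit is greedy descent: no uphill acceptance in practice
  expect_lt(metropolis_acceptance(1e-6, 1e-12), 1e-300)
})

test_that("objective values follow the three correlating targets", {
  expect_equal(objective_value(-489.4, -100, "KM"), -489.4)
  expect_equal(objective_value(-10, 7.7, "KCAT_OVER_KM"), 7.7)
  expect_equal(objective_value(-100, -100, "KCAT", rt_s = 386.7,
                               rt_tsa = 15.3),
               -100 / 15.3 + 100 / 386.7, tolerance = 1e-12)
  expect_equal(objective_value(-100, -100, "KCAT", rt_s = 386.7,
                               rt_tsa = 15.3), -6.277, tolerance = 1e-3)
  expect_error(objective_value(-1, -1, "KCAT"), "rt_s")
})

test_that("feasibility enforces binding signs, glycine cap and permitted sets", {
  cfg <- redesign_config(
    design_positions = c(162, 163, 164, 355, 356, 361, 362, 549, 550),
    permitted = read_permitted_sets(system.file("extdata",
                                                "permitted_sets.txt",
                                                package = "tsadesign")),
    objective = "KM", iterations = 0)
  wt <- c(`162` = "H", `163` = "D", `164` = "F", `355` = "V", `356` = "G",
          `361` = "L", `362` = "G", `549` = "W", `550` = "N")
  ok <- check_feasibility(list(assignment = wt, ie_s = -489.4,
                               ie_tsa = -377.8), cfg)
  expect_true(ok$feasible)      # WT carries exactly 2 glycines = cap
  bad_g <- wt; bad_g[c("162", "163", "164")] <- "G"
  r <- check_feasibility(list(assignment = bad_g, ie_s = -1, ie_tsa = -1), cfg)
  expect_false(r$feasible)
  expect_true("glycine_cap" %in% r$reasons)
  # a positive analogue interaction energy is infeasible
  r2 <- check_feasibility(list(assignment = wt, ie_s = -70.7, ie_tsa = 90.1),
                          cfg)
  expect_false(r2$feasible)
  expect_true("ie_tsa_nonnegative" %in% r2$reasons)
  bad_aa <- wt; bad_aa[["164"]] <- "P"   # P not permitted at 164
  r3 <- check_feasibility(list(assignment = bad_aa, ie_s = -1, ie_tsa = -1),
                          cfg)
  expect_true("not_permitted" %in% r3$reasons)
})

test_that("backbone perturbation is seeded and preserves internal geometry", {
  tc <- toy_cached()
  sys <- tc$substrate
  expect_identical({set.seed(5); perturb_backbone(sys, 2, 0)$coords},
                   sys$coords)
  set.seed(5); p1 <- perturb_backbone(sys, 2:3, 2)
  set.seed(5); p2 <- perturb_backbone(sys, 2:3, 2)
  expect_identical(p1$coords, p2$coords)
  expect_gt(max(abs(p1$coords - sys$coords)), 0)
  # pure dihedral rotations: bond lengths and angles unchanged
  b <- sys$topology$bonds
  pos <- function(s, id) match(id, s$atoms$atom_id)
  r0 <- sqrt(rowSums((sys$coords[pos(sys, b$i), ] -
                        sys$coords[pos(sys, b$j), ])^2))
  r1 <- sqrt(rowSums((p1$coords[pos(p1, b$i), ] -
                        p1$coords[pos(p1, b$j), ])^2))
  expect_lt(max(abs(r0 - r1)), 1e-8)
  a <- sys$topology$angles
  th0 <- vapply(seq_len(nrow(a)), function(t)
    as.numeric(tsadesign:::vertex_angle(sys$coords, pos(sys, a$i[t]), pos(sys, a$j[t]),
                            pos(sys, a$k[t]))), 0)
  th1 <- vapply(seq_len(nrow(a)), function(t)
    as.numeric(tsadesign:::vertex_angle(p1$coords, pos(p1, a$i[t]), pos(p1, a$j[t]),
                            pos(p1, a$k[t]))), 0)
  expect_lt(max(abs(th0 - th1)), 1e-8)
  expect_error(perturb_backbone(sys, 99, 2), "outside")
})

test_that("rotamer placement is rigid, idempotent and glycine-aware", {
  tc <- toy_cached(); lib <- toy_library()
  s1 <- place_rotamer(tc$substrate, 2, lib$LYS[[1]], tc$params)
  s2 <- place_rotamer(s1, 2, lib$LYS[[1]], tc$params)
  expect_equal(s1$coords, s2$coords, tolerance = 1e-12)
  rot <- lib$LYS[[1]]
  rows <- which(s1$atoms$residue_id == 2 & s1$atoms$molecule_tag == "enzyme" &
                  s1$atoms$name %in% rot$atoms$name)
  d_local <- dist(as.matrix(rot$atoms[, c("x", "y", "z")]))
  d_global <- dist(s1$coords[rows, , drop = FALSE])
  expect_lt(max(abs(d_local - d_global)), 1e-8)
  # glycine strips the side chain back to the backbone
  s3 <- place_rotamer(s1, 2, lib$GLY[[1]], tc$params)
  expect_equal(n_atoms(s3), n_atoms(tc$substrate))
  expect_equal(
    unique(s3$atoms$residue_name[s3$atoms$residue_id == 2 &
                                   s3$atoms$molecule_tag == "enzyme"]),
    "GLY")
})

test_that("rotamer assignment picks the clash-free candidate", {
  tc <- toy_cached()
  # two fake rotamers: one buried in the ligand (clash), one pointing away
  lig_local <- c(0, 8, 0)   # far from everything in the local frame
  clash_local <- local({
    fr <- tsadesign:::backbone_frame(tc$substrate, 2)
    lig_row <- which(tc$substrate$atoms$molecule_tag == "ligand")[1]
    lig_xyz <- tc$substrate$coords[lig_row, ]
    as.numeric(t(fr$R) %*% (lig_xyz - fr$origin))
  })
  lib <- list(ALA = list(
    list(residue_type = "ALA", probability = 0.5,
         atoms = tibble::tibble(name = "CB", x = clash_local[1],
                                y = clash_local[2], z = clash_local[3])),
    list(residue_type = "ALA", probability = 0.5,
         atoms = tibble::tibble(name = "CB", x = lig_local[1],
                                y = lig_local[2], z = lig_local[3]))))
  res <- assign_rotamers(tc$substrate, 2, lib, list(`2` = "A"), tc$params)
  expect_equal(res$assignment$rotamer_index, 2L)
})

test_that("exhaustive rotamer assignment equals a brute-force enumeration", {
  tc <- toy_cached(); lib <- toy_library()
  perm <- list(`2` = c("D", "K", "S"), `3` = c("A", "R", "G"))
  res <- assign_rotamers(tc$substrate, c(2, 3), lib, perm, tc$params,
                         tc$restraints)
  # independent enumeration over every (rotamer, rotamer) combination
  best_e <- Inf; best <- NULL
  for (a1 in sort(aa_one_to_three(perm$`2`))) for (i1 in seq_along(lib[[a1]]))
    for (a2 in sort(aa_one_to_three(perm$`3`))) for (i2 in seq_along(lib[[a2]])) {
      s <- place_rotamer(tc$substrate, 2, lib[[a1]][[i1]], tc$params)
      s <- place_rotamer(s, 3, lib[[a2]][[i2]], tc$params)
      e <- total_energy(s, tc$restraints)$total
      if (e < best_e) { best_e <- e; best <- c(a1, i1, a2, i2) }
    }
  expect_equal(res$energy, best_e, tolerance = 1e-10)
  expect_equal(aa_one_to_three(res$assignment$residue_type), best[c(1, 3)])
  # a single-candidate space returns that assignment
  one <- assign_rotamers(tc$substrate, 2,
                         list(TRP = lib$TRP[1]), list(`2` = "W"), tc$params)
  expect_equal(one$assignment$residue_type, "W")
})

test_that("a trajectory with zero iterations reports the wild type", {
  tc <- toy_cached(); lib <- toy_library()
  cfg <- redesign_config(c(2, 3), list(`2` = c("G", "K"), `3` = c("G", "R")),
                         "KM", iterations = 0, minimize_steps = 10)
  r <- run_trajectory(tc$substrate, tc$tsa, cfg, lib, tc$params,
                      tc$restraints, tc$restraints, seed = 1)
  expect_equal(unname(r$best_state$assignment), c("G", "G"))
  expect_true(r$found)              # the toy wild type binds both ligands
  expect_length(r$best_trace, 0)
})

test_that("trajectories are deterministic and track a monotone best trace", {
  tc <- toy_cached(); lib <- toy_library()
  cfg <- redesign_config(c(2, 3), list(`2` = c("G", "D", "K"),
                                       `3` = c("G", "S", "R")),
                         "KM", iterations = 8, sa_start_iteration = 5,
                         minimize_steps = 8)
  r1 <- run_trajectory(tc$substrate, tc$tsa, cfg, lib, tc$params,
                       tc$restraints, tc$restraints, seed = 7)
  r2 <- run_trajectory(tc$substrate, tc$tsa, cfg, lib, tc$params,
                       tc$restraints, tc$restraints, seed = 7)
  expect_identical(r1$best_state, r2$best_state)
  expect_identical(r1$best_trace, r2$best_trace)
  tr <- r1$best_trace[!is.na(r1$best_trace)]
  expect_true(all(diff(tr) <= 1e-9))
  # the reported best state satisfies the feasibility constraints
  expect_true(check_feasibility(r1$best_state, cfg)$feasible)
})

test_that("trajectory-best interaction energies aggregate by the mean", {
  mk <- function(ie_s, found = TRUE)
    structure(list(best_state = list(ie_s = ie_s, ie_tsa = ie_s - 1),
                   found = found), class = "trajectory_result")
  expect_equal(aggregate_best_ie(list(mk(-1), mk(-3)), "ie_s")$mean, -2)
  same <- replicate(25, mk(-7), simplify = FALSE)
  expect_equal(aggregate_best_ie(same, "ie_s")$mean, -7)
  # synthetic draws: mean matches direct recomputation, empties are counted
  set.seed(3)
  vals <- -stats::runif(25, 10, 100)
  res <- lapply(vals, mk)
  res[[5]] <- mk(0, found = FALSE)
  agg <- aggregate_best_ie(res, "ie_s")
  expect_equal(agg$mean, mean(vals[-5]))
  expect_equal(agg$n_empty, 1)
  expect_error(aggregate_best_ie(list(mk(0, FALSE)), "ie_s"), "feasible")
})
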