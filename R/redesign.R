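#' Metropolis acceptance probability
#'
#' min(1, exp(-deltaE / (R T))) with R = 8.3145e-3 kJ/(mol K). At the default
#' annealing temperature of 7268 K an objective increase of 41.9 kJ/mol
#' (10 kcal/mol) is accepted about half the time.
#'
#' @param delta_e objective-energy change, kJ/mol (may be a vector).
#' @param temperature annealing temperature, K (> 0).
#' @return acceptance probability in [0, 1].
#' @examples
#' metropolis_acceptance(41.9, 7268)   # ~0.5
#' @export
metropolis_acceptance <- function(delta_e, temperature) {
  if (any(temperature <= 0)) stop("temperature must be > 0")
  pmin(1, exp(-delta_e / (mm_constants$R * temperature)))
}

#' Redesign objective from the two interaction energies
#'
#' All objectives are minimized. "KM" minimizes the substrate interaction
#' energy (lower IE_S implies lower K_M); "KCAT_OVER_KM" minimizes the
#' analogue interaction energy (lower IE_TSA implies higher k_cat/K_M);
#' "KCAT" minimizes the weighted combination
#' IE_TSA/(RT)_TSA - IE_S/(RT)_S whose decrease raises the turnover number.
#'
#' @param ie_s substrate interaction energy, kJ/mol.
#' @param ie_tsa transition-state-analogue interaction energy, kJ/mol.
#' @param objective "KM", "KCAT_OVER_KM" or "KCAT".
#' @param rt_s,rt_tsa effective RT constants, kJ/mol (required for "KCAT").
#' @return objective value (kJ/mol, or dimensionless for "KCAT").
#' @export
objective_value <- function(ie_s, ie_tsa,
                            objective = c("KM", "KCAT_OVER_KM", "KCAT"),
                            rt_s = NULL, rt_tsa = NULL) {
  objective <- match.arg(objective)
  switch(objective,
    KM = ie_s,
    KCAT_OVER_KM = ie_tsa,
    KCAT = {
      if (is.null(rt_s) || is.null(rt_tsa) || rt_s <= 0 || rt_tsa <= 0)
        stop("objective 'KCAT' requires positive rt_s and rt_tsa")
      ie_tsa / rt_tsa - ie_s / rt_s
    })
}

#' Redesign run configuration
#'
#' Defaults mirror the study conditions of the glucuronidase redesign: nine
#' active-site design positions, 5000 iterations per trajectory with greedy
#' acceptance for the first 100 and constant-temperature (7268 K) simulated
#' annealing afterwards, at most two glycines across the design positions,
#' and 25 trajectories averaged for interaction-energy estimation (50 for
#' library design).
#'
#' @param design_positions integer residue ids allowed to mutate.
#' @param permitted named list: position -> allowed one-letter codes.
#' @param objective "KM", "KCAT_OVER_KM" or "KCAT".
#' @param glycine_cap maximum glycines across design positions.
#' @param n_trajectories number of independent trajectories.
#' @param iterations iterations per trajectory.
#' @param sa_start_iteration first iteration of the annealing phase.
#' @param temperature annealing temperature, K.
#' @param rt_s,rt_tsa effective RT constants, kJ/mol (used by "KCAT").
#' @param seed base seed; trajectory i uses seed + i.
#' @param minimize_steps relaxation steps per interaction-energy evaluation.
#' @param mutation_prob probability that a move is a mutation (otherwise a
#'   backbone perturbation with rotamer reassignment).
#' @param perturb_magnitude backbone perturbation amplitude, degrees.
#' @return list of class "redesign_config".
#' @export
redesign_config <- function(design_positions, permitted,
                            objective = c("KM", "KCAT_OVER_KM", "KCAT"),
                            glycine_cap = 2, n_trajectories = 25,
                            iterations = 5000, sa_start_iteration = 100,
                            temperature = 7268, rt_s = 386.7, rt_tsa = 15.3,
                            seed = 1, minimize_steps = 30,
                            mutation_prob = 0.5, perturb_magnitude = 2) {
  objective <- match.arg(objective)
  stopifnot(temperature > 0, iterations >= 0, sa_start_iteration >= 0,
            glycine_cap >= 0, mutation_prob >= 0, mutation_prob <= 1)
  if (!all(as.character(design_positions) %in% names(permitted)))
    stop("every design position needs a permitted set")
  if (any(lengths(permitted[as.character(design_positions)]) == 0))
    stop("permitted sets must be non-empty")
  structure(list(
    design_positions = as.integer(design_positions), permitted = permitted,
    objective = objective, glycine_cap = glycine_cap,
    n_trajectories = n_trajectories, iterations = iterations,
    sa_start_iteration = sa_start_iteration, temperature = temperature,
    rt_s = rt_s, rt_tsa = rt_tsa, seed = seed,
    minimize_steps = minimize_steps, mutation_prob = mutation_prob,
    perturb_magnitude = perturb_magnitude
  ), class = "redesign_config")
}

#' Number of glycines in an assignment
#'
#' @param assignment character vector of one-letter codes, named by position.
#' @param design_positions positions to count over (default: all of
#'   `assignment`).
#' @return integer glycine count.
#' @examples
#' glycine_count(c(`361` = "G", `362` = "G", `549` = "W"))
#' @export
glycine_count <- function(assignment, design_positions = names(assignment)) {
  if (!length(design_positions)) return(0L)
  sum(assignment[as.character(design_positions)] == "G")
}

#' Feasibility of a candidate mutant
#'
#' A mutant is feasible when both ligands bind favorably (IE_S < 0 and
#' IE_TSA < 0), the glycine count over the design positions does not exceed
#' the cap, and every assigned amino acid is in its permitted set.
#'
#' @param state list with elements `assignment` (named one-letter vector over
#'   the design positions), `ie_s` and `ie_tsa` (kJ/mol).
#' @param config a [redesign_config()].
#' @return list with `feasible` (logical) and `reasons` (character vector of
#'   codes: "ie_s_nonnegative", "ie_tsa_nonnegative", "glycine_cap",
#'   "not_permitted").
#' @export
check_feasibility <- function(state, config) {
  pos <- as.character(config$design_positions)
  if (!all(pos %in% names(state$assignment)))
    stop("assignment does not cover all design positions")
  reasons <- character(0)
  if (!is.finite(state$ie_s) || state$ie_s >= 0)
    reasons <- c(reasons, "ie_s_nonnegative")
  if (!is.finite(state$ie_tsa) || state$ie_tsa >= 0)
    reasons <- c(reasons, "ie_tsa_nonnegative")
  if (glycine_count(state$assignment, pos) > config$glycine_cap)
    reasons <- c(reasons, "glycine_cap")
  ok <- vapply(pos, function(p)
    state$assignment[[p]] %in% config$permitted[[p]], TRUE)
  if (!all(ok)) reasons <- c(reasons, "not_permitted")
  list(feasible = length(reasons) == 0, reasons = reasons)
}

# current one-letter assignment at the design positions of a system
current_assignment <- function(system, positions) {
  at <- system$atoms
  out <- vapply(positions, function(p) {
    nm <- unique(at$residue_name[at$residue_id == p &
                                   at$molecule_tag == "enzyme"])
    aa_three_to_one(nm[1])
  }, "")
  names(out) <- as.character(positions)
  out
}

#' Run one stochastic redesign trajectory
#'
#' Iterates the redesign loop on the paired substrate and
#' transition-state-analogue complexes: each iteration proposes either a
#' mutation at a random design position (probability `mutation_prob`) or a
#' backbone perturbation around the design positions followed by rotamer
#' reassignment; both complexes receive identical sequence changes and are
#' relaxed before the two interaction energies are evaluated. Moves are
#' accepted greedily before `sa_start_iteration` and by the Metropolis
#' criterion at constant temperature afterwards. Infeasible proposals are
#' rejected outright. Deterministic for a fixed seed.
#'
#' @param substrate_complex,tsa_complex paired [molecular_system()]s sharing
#'   the enzyme.
#' @param config a [redesign_config()].
#' @param library rotamer library.
#' @param params parameter list (for side-chain placement).
#' @param restraints_substrate,restraints_tsa optional restraint tables.
#' @param seed trajectory seed.
#' @return list of class "trajectory_result" with `best_state` (assignment,
#'   ie_s, ie_tsa, objective_value, feasible), `best_trace` (per-iteration
#'   best objective, non-increasing), `found` (any feasible state seen),
#'   `seed`.
#' @export
run_trajectory <- function(substrate_complex, tsa_complex, config,
                           library, params,
                           restraints_substrate = NULL,
                           restraints_tsa = NULL, seed = config$seed) {
  set.seed(seed)
  pos <- config$design_positions
  eval_state <- function(sys_s, sys_t, assignment) {
    d_s <- interaction_energy(sys_s, restraints_substrate,
                              max_steps = config$minimize_steps, detail = TRUE)
    d_t <- interaction_energy(sys_t, restraints_tsa,
                              max_steps = config$minimize_steps, detail = TRUE)
    state <- list(assignment = assignment, ie_s = d_s$ie, ie_tsa = d_t$ie)
    state$objective_value <- objective_value(d_s$ie, d_t$ie, config$objective,
                                             config$rt_s, config$rt_tsa)
    state$feasible <- check_feasibility(state, config)$feasible
    list(state = state, sys_s = d_s$complex, sys_t = d_t$complex)
  }
  cur <- eval_state(substrate_complex, tsa_complex,
                    current_assignment(substrate_complex, pos))
  wt_state <- cur$state
  best <- if (cur$state$feasible) cur$state else NULL
  trace <- numeric(0)
  repack_permitted <- function(assignment)
    stats::setNames(as.list(assignment), names(assignment))
  for (it in seq_len(config$iterations)) {
    if (stats::runif(1) < config$mutation_prob) {
      p <- pos[sample.int(length(pos), 1)]
      choices <- sort(config$permitted[[as.character(p)]])
      aa <- choices[sample.int(length(choices), 1)]
      new_assignment <- cur$state$assignment
      new_assignment[[as.character(p)]] <- aa
      perm1 <- repack_permitted(new_assignment[as.character(p)])
      cand_s <- assign_rotamers(cur$sys_s, p, library, perm1, params,
                                restraints_substrate)$system
      cand_t <- assign_rotamers(cur$sys_t, p, library, perm1, params,
                                restraints_tsa)$system
    } else {
      enz_res <- range(cur$sys_s$atoms$residue_id[
        cur$sys_s$atoms$molecule_tag == "enzyme"])
      window <- unique(pmax(enz_res[1], pmin(enz_res[2],
                                             c(pos - 1L, pos, pos + 1L))))
      new_assignment <- cur$state$assignment
      cand_s <- perturb_backbone(cur$sys_s, window, config$perturb_magnitude)
      cand_t <- perturb_backbone(cur$sys_t, window, config$perturb_magnitude)
      permc <- repack_permitted(new_assignment)
      cand_s <- assign_rotamers(cand_s, pos, library, permc, params,
                                restraints_substrate)$system
      cand_t <- assign_rotamers(cand_t, pos, library, permc, params,
                                restraints_tsa)$system
    }
    cand <- eval_state(cand_s, cand_t, new_assignment)
    accept <- FALSE
    if (cand$state$feasible) {
      delta <- cand$state$objective_value - cur$state$objective_value
      accept <- if (it < config$sa_start_iteration) delta < 0
                else stats::runif(1) < metropolis_acceptance(
                  delta, config$temperature)
    }
    if (accept) {
      cur <- cand
      if (cand$state$feasible &&
          (is.null(best) ||
             cand$state$objective_value < best$objective_value))
        best <- cand$state
    }
    trace <- c(trace, if (is.null(best)) NA_real_ else best$objective_value)
  }
  structure(list(best_state = if (is.null(best)) wt_state else best,
                 best_trace = trace, found = !is.null(best), seed = seed),
            class = "trajectory_result")
}

#' Aggregate trajectory-best interaction energies
#'
#' The interaction energy reported for a variant is the arithmetic mean of
#' the best value from each trajectory (trajectories that never reached a
#' feasible state are excluded and counted).
#'
#' @param results list of "trajectory_result" objects.
#' @param field "ie_s" or "ie_tsa".
#' @return list with `mean` (kJ/mol), `n_used`, `n_empty`.
#' @export
aggregate_best_ie <- function(results, field = c("ie_s", "ie_tsa")) {
  field <- match.arg(field)
  ok <- vapply(results, function(r) isTRUE(r$found), TRUE)
  if (!any(ok)) stop("no trajectory produced a feasible state")
  vals <- vapply(results[ok], function(r) r$best_state[[field]], 0)
  list(mean = mean(vals), n_used = sum(ok), n_empty = sum(!ok))
}

#' Run a multi-trajectory redesign
#'
#' Runs `config$n_trajectories` independent trajectories (seeds
#' `config$seed + 1 .. config$seed + n`) and assembles the per-trajectory
#' best mutants into a ranked [design_library()].
#'
#' @inheritParams run_trajectory
#' @param name library name.
#' @return list with `trajectories` (list of trajectory results), `library`
#'   (a [design_library()] of the feasible trajectory bests, ranked by
#'   objective), `ie_s`, `ie_tsa` (aggregated means over trajectory bests).
#' @export
run_redesign <- function(substrate_complex, tsa_complex, config,
                         library, params,
                         restraints_substrate = NULL, restraints_tsa = NULL,
                         name = "redesign") {
  results <- lapply(seq_len(config$n_trajectories), function(i)
    run_trajectory(substrate_complex, tsa_complex, config, library, params,
                   restraints_substrate, restraints_tsa,
                   seed = config$seed + i))
  ok <- vapply(results, function(r) isTRUE(r$found), TRUE)
  best <- results[ok]
  ord <- order(vapply(best, function(r) r$best_state$objective_value, 0))
  best <- best[ord]
  pos <- config$design_positions
  mutants <- tibble::tibble(
    rank = seq_along(best),
    energy = vapply(best, function(r) r$best_state$objective_value, 0),
    sequence = vapply(best, function(r)
      paste(r$best_state$assignment[as.character(pos)], collapse = ""), "")
  )
  wt <- paste(current_assignment(substrate_complex, pos), collapse = "")
  lib <- design_library(name = name, objective = config$objective,
                        positions = pos, mutants = mutants, wildtype = wt,
                        wildtype_energy = NA_real_)
  list(trajectories = results, library = lib,
       ie_s = if (any(ok)) aggregate_best_ie(results, "ie_s")$mean else NA_real_,
       ie_tsa = if (any(ok)) aggregate_best_ie(results, "ie_tsa")$mean
                else NA_real_)
}
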