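#' Analytic gradient of the molecular-mechanics energy
#'
#' Returns d(total energy)/d(coords) for every term except the
#' accessible-area nonpolar contribution, which is piecewise-constant under
#' the point-sphere approximation and therefore carries no analytic gradient;
#' the minimizer guards against it by testing the full energy (including the
#' surface term) at every trial step.
#'
#' @param system a [molecular_system()].
#' @param restraints optional [noe_restraints()] table.
#' @param solvation if FALSE, skip the generalized-Born contribution.
#' @return n x 3 matrix of gradients, kJ/(mol A).
#' @export
energy_gradient <- function(system, restraints = NULL, solvation = TRUE) {
  X <- system$coords
  n <- nrow(X)
  G <- matrix(0, n, 3)
  if (n == 0) return(G)
  at <- system$atoms
  top <- system$topology

  add_pair_force <- function(G, i, j, dEdr) {
    # dE/dr along the i->j axis; i, j row indices (vectors)
    d <- X[i, , drop = FALSE] - X[j, , drop = FALSE]
    r <- sqrt(rowSums(d * d))
    f <- d * (dEdr / r)
    for (k in 1:3) {
      G[, k] <- G[, k] + tabulate2(i, f[, k], n) - tabulate2(j, f[, k], n)
    }
    G
  }

  if (nrow(top$bonds)) {
    i <- id_to_row(system, top$bonds$i); j <- id_to_row(system, top$bonds$j)
    r <- pair_dist(X, i, j)
    G <- add_pair_force(G, i, j, 2 * top$bonds$k_b * (r - top$bonds$r0))
  }
  if (nrow(top$urey_bradley)) {
    i <- id_to_row(system, top$urey_bradley$i)
    k <- id_to_row(system, top$urey_bradley$k)
    s <- pair_dist(X, i, k)
    G <- add_pair_force(G, i, k, 2 * top$urey_bradley$k_ub * (s - top$urey_bradley$s0))
  }
  if (nrow(top$angles)) {
    ai <- id_to_row(system, top$angles$i)
    aj <- id_to_row(system, top$angles$j)
    ak <- id_to_row(system, top$angles$k)
    for (t in seq_len(nrow(top$angles))) {
      i <- ai[t]; j <- aj[t]; k <- ak[t]
      u <- X[i, ] - X[j, ]; v <- X[k, ] - X[j, ]
      nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
      ct <- sum(u * v) / (nu * nv)
      ct <- min(1, max(-1, ct))
      st <- sqrt(max(1 - ct^2, 1e-12))
      th <- acos(ct)
      dEdth <- 2 * top$angles$k_theta[t] * (th - top$angles$theta0[t])
      dthdi <- (ct * u / nu - v / nv) / (nu * st)
      dthdk <- (ct * v / nv - u / nu) / (nv * st)
      G[i, ] <- G[i, ] + dEdth * dthdi
      G[k, ] <- G[k, ] + dEdth * dthdk
      G[j, ] <- G[j, ] - dEdth * (dthdi + dthdk)
    }
  }
  torsion_grad <- function(i, j, k, l, dEdphi) {
    # Blondel-Karplus style torsion derivatives
    b1 <- X[j, ] - X[i, ]; b2 <- X[k, ] - X[j, ]; b3 <- X[l, ] - X[k, ]
    n1 <- cross3(b1, b2); n2 <- cross3(b2, b3)
    nb2 <- sqrt(sum(b2^2))
    gi <- -nb2 / sum(n1^2) * n1
    gl <- nb2 / sum(n2^2) * n2
    s1 <- sum(b1 * b2) / sum(b2^2)
    s2 <- sum(b3 * b2) / sum(b2^2)
    gj <- -(1 + s1) * gi + s2 * gl
    gk <- s1 * gi - (1 + s2) * gl
    list(i = dEdphi * gi, j = dEdphi * gj, k = dEdphi * gk, l = dEdphi * gl)
  }
  if (nrow(top$dihedrals)) {
    di <- id_to_row(system, top$dihedrals$i)
    dj <- id_to_row(system, top$dihedrals$j)
    dk <- id_to_row(system, top$dihedrals$k)
    dl <- id_to_row(system, top$dihedrals$l)
    phi <- torsion_angle(X, di, dj, dk, dl)
    dEdphi <- -top$dihedrals$k_phi * top$dihedrals$n *
      sin(top$dihedrals$n * phi - top$dihedrals$delta)
    for (t in seq_len(nrow(top$dihedrals))) {
      g <- torsion_grad(di[t], dj[t], dk[t], dl[t], dEdphi[t])
      G[di[t], ] <- G[di[t], ] + g$i; G[dj[t], ] <- G[dj[t], ] + g$j
      G[dk[t], ] <- G[dk[t], ] + g$k; G[dl[t], ] <- G[dl[t], ] + g$l
    }
  }
  if (nrow(top$impropers)) {
    di <- id_to_row(system, top$impropers$i)
    dj <- id_to_row(system, top$impropers$j)
    dk <- id_to_row(system, top$impropers$k)
    dl <- id_to_row(system, top$impropers$l)
    psi <- torsion_angle(X, di, dj, dk, dl)
    dpsi <- wrap_angle(psi - top$impropers$psi0)
    dEdpsi <- 2 * top$impropers$k_psi * dpsi
    for (t in seq_len(nrow(top$impropers))) {
      g <- torsion_grad(di[t], dj[t], dk[t], dl[t], dEdpsi[t])
      G[di[t], ] <- G[di[t], ] + g$i; G[dj[t], ] <- G[dj[t], ] + g$j
      G[dk[t], ] <- G[dk[t], ] + g$k; G[dl[t], ] <- G[dl[t], ] + g$l
    }
  }

  idx <- nonbonded_pairs(system, "all")
  if (nrow(idx)) {
    i <- idx[, 1]; j <- idx[, 2]
    r <- pair_dist(X, i, j)
    epsij <- sqrt(at$lj_epsilon[i] * at$lj_epsilon[j])
    rmin <- at$lj_rmin_half[i] + at$lj_rmin_half[j]
    sr6 <- (rmin / r)^6
    dvdw <- -12 * epsij / r * (sr6^2 - sr6)
    delec <- -mm_constants$KE * at$charge[i] * at$charge[j] / r^2
    G <- add_pair_force(G, i, j, dvdw + delec)
  }

  # generalized Born (cross terms only; self-terms are coordinate-free)
  if (solvation && any(at$charge != 0) && n >= 2) {
    pref <- -mm_constants$KE *
      (1 / mm_constants$EPS_IN - 1 / mm_constants$EPS_OUT)
    idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    i <- idx[, 1]; j <- idx[, 2]
    qq <- at$charge[i] * at$charge[j]
    keep <- qq != 0
    if (any(keep)) {
      i <- i[keep]; j <- j[keep]; qq <- qq[keep]
      r <- pair_dist(X, i, j)
      ab <- at$born_radius[i] * at$born_radius[j]
      ex <- exp(-r^2 / (4 * ab))
      fgb <- sqrt(r^2 + ab * ex)
      dfdr <- r * (1 - ex / 4) / fgb
      dEdr <- -pref * qq / fgb^2 * dfdr
      G <- add_pair_force(G, i, j, dEdr)
    }
  }

  if (!is.null(restraints) && nrow(restraints)) {
    rows <- resolve_restraints(system, restraints)
    i <- rows[, 1]; j <- rows[, 2]
    d <- pair_dist(X, i, j)
    dEdr <- ifelse(d < restraints$d_min,
                   2 * restraints$k_min * (d - restraints$d_min),
                   ifelse(d > restraints$d_max,
                          2 * restraints$k_max * (d - restraints$d_max), 0))
    G <- add_pair_force(G, i, j, dEdr)
  }
  G
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# sum values v at integer positions idx into a length-n vector
tabulate2 <- function(idx, v, n) {
  out <- numeric(n)
  agg <- rowsum(v, idx)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}

#' Minimize a molecular system
#'
#' Steepest descent with a backtracking (halving) Armijo line search. The
#' search direction comes from the analytic gradient of the smooth terms; the
#' Armijo acceptance test evaluates the full energy (including the nonpolar
#' surface term), so the energy trace is non-increasing by construction.
#' Deterministic for a fixed input.
#'
#' @param system a [molecular_system()].
#' @param restraints optional [noe_restraints()] table.
#' @param max_steps maximum number of descent iterations (>= 0).
#' @param grad_tol convergence threshold on the largest per-atom gradient
#'   norm, kJ/(mol A).
#' @param step0 initial maximum per-atom displacement, angstrom.
#' @param solvation if FALSE, evaluate and minimize without solvation terms.
#' @return list with elements `system` (minimized), `energy` (final
#'   [total_energy()] breakdown), `trace` (energy after each accepted step),
#'   `converged` (logical).
#' @export
minimize <- function(system, restraints = NULL, max_steps = 500,
                     grad_tol = 0.1, step0 = 0.01, solvation = TRUE) {
  stopifnot(max_steps >= 0)
  e_tot <- sum(total_energy_vec(system, restraints, solvation))
  if (!is.finite(e_tot)) stop("non-finite energy at minimization start")
  trace <- e_tot
  converged <- FALSE
  if (n_atoms(system) == 0)
    return(list(system = system, energy = total_energy(system, restraints,
                                                       solvation),
                trace = trace, converged = TRUE))
  step <- step0
  for (it in seq_len(max_steps)) {
    G <- energy_gradient(system, restraints, solvation)
    gmax <- max(sqrt(rowSums(G * G)))
    if (gmax <= grad_tol) { converged <- TRUE; break }
    dir <- -G / gmax            # largest atom moves by `alpha` angstrom
    g2 <- sum(G * dir)          # directional derivative (negative)
    alpha <- step
    accepted <- FALSE
    while (alpha > 1e-12) {
      cand <- system
      cand$coords <- system$coords + alpha * dir
      e_new <- tryCatch(sum(total_energy_vec(cand, restraints, solvation)),
                        error = function(c) NULL)
      if (!is.null(e_new) && is.finite(e_new) &&
          e_new <= e_tot + 1e-4 * alpha * g2) {
        system <- cand; e_tot <- e_new; accepted <- TRUE
        break
      }
      alpha <- alpha / 2
    }
    if (!accepted) { converged <- TRUE; break }
    trace <- c(trace, e_tot)
    step <- min(max(alpha * 2, 1e-6), 0.5)
  }
  if (!is.finite(e_tot)) stop("minimization diverged to non-finite energy")
  list(system = system, energy = total_energy(system, restraints, solvation),
       trace = trace, converged = converged)
}
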