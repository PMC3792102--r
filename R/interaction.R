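#' Enzyme-ligand interaction energy
#'
#' One minimization of the complex, then
#' IE = E(complex) - E(enzyme alone) - E(ligand alone), with both subsystem
#' energies evaluated at the complex coordinates (no re-relaxation). NOE
#' restraints couple enzyme and ligand atoms and are therefore charged to the
#' complex evaluation only. A negative IE means favorable binding.
#'
#' @param complex a [molecular_system()] containing atoms tagged "enzyme" and
#'   atoms tagged "ligand".
#' @param restraints optional [noe_restraints()] table.
#' @param max_steps,grad_tol minimization controls (see [minimize()]);
#'   `max_steps = 0` evaluates at the input coordinates.
#' @param detail if TRUE, return the component energies and the minimized
#'   complex alongside the IE.
#' @param solvation if FALSE, evaluate in vacuum (used e.g. to compare with
#'   the exact cross-pair decomposition, which only holds without the
#'   non-additive solvation terms).
#' @return the interaction energy (kJ/mol), or a list when `detail = TRUE`
#'   with elements ie, e_complex, e_enzyme, e_ligand, complex.
#' @export
interaction_energy <- function(complex, restraints = NULL, max_steps = 500,
                               grad_tol = 0.1, detail = FALSE,
                               solvation = TRUE) {
  tags <- unique(complex$atoms$molecule_tag)
  if (!all(c("enzyme", "ligand") %in% tags))
    stop("complex must contain atoms tagged both 'enzyme' and 'ligand'")
  mz <- minimize(complex, restraints, max_steps = max_steps,
                 grad_tol = grad_tol, solvation = solvation)
  e_complex <- mz$energy
  enz <- subsystem(mz$system, "enzyme")
  lig <- subsystem(mz$system, "ligand")
  e_enz <- total_energy(enz, solvation = solvation)
  e_lig <- total_energy(lig, solvation = solvation)
  ie <- e_complex$total - e_enz$total - e_lig$total
  if (!detail) return(ie)
  list(ie = ie, e_complex = e_complex, e_enzyme = e_enz, e_ligand = e_lig,
       complex = mz$system)
}

#' Enzyme-ligand binding energy
#'
#' BE = E_min(complex) - E_min(enzyme) - E_min(ligand), each term from an
#' independent minimization of that (sub)system. Differs from
#' [interaction_energy()] in that the separated enzyme and ligand are allowed
#' to relax. Restraints apply to the complex only.
#'
#' @inheritParams interaction_energy
#' @return the binding energy (kJ/mol), or a detail list with elements be,
#'   e_complex, e_enzyme, e_ligand.
#' @export
binding_energy <- function(complex, restraints = NULL, max_steps = 500,
                           grad_tol = 0.1, detail = FALSE,
                           solvation = TRUE) {
  tags <- unique(complex$atoms$molecule_tag)
  if (!all(c("enzyme", "ligand") %in% tags))
    stop("complex must contain atoms tagged both 'enzyme' and 'ligand'")
  e_complex <- minimize(complex, restraints, max_steps = max_steps,
                        grad_tol = grad_tol, solvation = solvation)$energy
  e_enz <- minimize(subsystem(complex, "enzyme"), NULL, max_steps = max_steps,
                    grad_tol = grad_tol, solvation = solvation)$energy
  e_lig <- minimize(subsystem(complex, "ligand"), NULL, max_steps = max_steps,
                    grad_tol = grad_tol, solvation = solvation)$energy
  be <- e_complex$total - e_enz$total - e_lig$total
  if (!detail) return(be)
  list(be = be, e_complex = e_complex, e_enzyme = e_enz, e_ligand = e_lig)
}
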