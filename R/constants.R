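#' Physical constants used throughout the package
#'
#' All energies are kJ/mol internally; distances are angstroms; charges are
#' elementary charges. Inputs in kcal/mol are converted at the I/O layer.
#'
#' @format A named list with elements:
#' \describe{
#'   \item{R}{Gas constant, 8.3145e-3 kJ/(mol K).}
#'   \item{KE}{Electrostatic (Coulomb) constant, 1389.354 kJ A/(mol e^2).}
#'   \item{KB}{Boltzmann constant, J/K.}
#'   \item{H}{Planck constant, J s.}
#'   \item{KJ_PER_KCAL}{4.184 kJ per kcal.}
#'   \item{EPS_IN}{Interior (solute) dielectric for generalized Born.}
#'   \item{EPS_OUT}{Exterior (solvent) dielectric for generalized Born.}
#' }
#' @export
mm_constants <- list(
  R           = 8.3145e-3,
  KE          = 1389.354,
  KB          = 1.380649e-23,
  H           = 6.62607015e-34,
  KJ_PER_KCAL = 4.184,
  EPS_IN      = 1,
  EPS_OUT     = 80
)

# one-letter <-> three-letter amino acid tables (20 standard)
AA1 <- c("A","R","N","D","C","Q","E","G","H","I",
         "L","K","M","F","P","S","T","W","Y","V")
AA3 <- c("ALA","ARG","ASN","ASP","CYS","GLN","GLU","GLY","HIS","ILE",
         "LEU","LYS","MET","PHE","PRO","SER","THR","TRP","TYR","VAL")

#' Convert between one- and three-letter amino acid codes
#'
#' @param x character vector of codes.
#' @return character vector of the converted codes.
#' @examples
#' aa_three_to_one("GLY")
#' aa_one_to_three("W")
#' @export
aa_three_to_one <- function(x) {
  out <- AA1[match(toupper(x), AA3)]
  if (anyNA(out)) stop("unknown three-letter amino acid code: ",
                       paste(x[is.na(out)], collapse = ", "))
  out
}

#' @rdname aa_three_to_one
#' @export
aa_one_to_three <- function(x) {
  out <- AA3[match(toupper(x), AA1)]
  if (anyNA(out)) stop("unknown one-letter amino acid code: ",
                       paste(x[is.na(out)], collapse = ", "))
  out
}
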