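#' Amino-acid profile of an alignment column
#'
#' Counts the 20 standard amino acids in one column of an aligned set of
#' sequences. Gaps ('-', '.') are excluded from the counts and from the
#' frequency denominator; letters are uppercased; ambiguity/non-standard
#' codes (B, J, O, U, X, Z) are ignored and reported in `n_nonstandard`.
#'
#' @param alignment character matrix from [read_alignment()] (rows =
#'   sequences) or a character vector of equal-length sequences.
#' @param column 1-based column index.
#' @return list of class "column_profile": `counts` (named integer vector
#'   over observed standard amino acids), `n_ungapped`, `n_sequences`,
#'   `n_nonstandard`, `column`.
#' @export
column_profile <- function(alignment, column) {
  if (!is.matrix(alignment)) {
    lens <- nchar(alignment)
    if (length(unique(lens)) > 1) stop("ragged alignment")
    alignment <- do.call(rbind, strsplit(alignment, ""))
  }
  if (column < 1 || column > ncol(alignment))
    stop("column out of range")
  letters_ <- toupper(alignment[, column])
  gap <- letters_ %in% c("-", ".")
  std <- letters_ %in% AA1
  counts <- table(factor(letters_[std], levels = AA1))
  counts <- counts[counts > 0]
  structure(list(
    counts = stats::setNames(as.integer(counts), names(counts)),
    n_ungapped = sum(!gap),
    n_sequences = length(letters_),
    n_nonstandard = sum(!gap & !std),
    column = column
  ), class = "column_profile")
}

#' Column frequency of an amino acid (gap-excluded denominator)
#'
#' @param profile a [column_profile()].
#' @param aa one-letter code.
#' @return fraction of ungapped rows carrying `aa`.
#' @export
profile_freq <- function(profile, aa) {
  if (profile$n_ungapped == 0) return(0)
  cnt <- profile$counts[aa]
  if (is.na(cnt)) 0 else unname(cnt) / profile$n_ungapped
}

#' Permitted amino acids at a design position
#'
#' The union rule over two alignment profiles: an amino acid is permitted if
#' it is observed at least `min_count_family` times in the family alignment
#' (natural close homologs) OR in at least `min_freq_superfamily` of the
#' ungapped rows of the superfamily alignment. Both thresholds are inclusive
#' ("at least"). The two profiles must refer to the same design position via
#' a user-supplied column mapping.
#'
#' @param profile_family [column_profile()] of the family alignment column.
#' @param profile_superfamily [column_profile()] of the superfamily column.
#' @param min_count_family minimum family count (default 1).
#' @param min_freq_superfamily minimum superfamily frequency (default 0.05).
#' @return sorted character vector of permitted one-letter codes (possibly
#'   empty, with a warning when both profiles are empty).
#' @export
permitted_amino_acids <- function(profile_family, profile_superfamily,
                                  min_count_family = 1,
                                  min_freq_superfamily = 0.05) {
  stopifnot(min_count_family >= 1,
            min_freq_superfamily > 0, min_freq_superfamily <= 1)
  fam <- names(profile_family$counts)[
    profile_family$counts >= min_count_family]
  sup <- character(0)
  if (profile_superfamily$n_ungapped > 0) {
    fr <- profile_superfamily$counts / profile_superfamily$n_ungapped
    sup <- names(fr)[fr >= min_freq_superfamily]
  } else if (!length(fam)) {
    warning("both profiles empty: permitted set is empty")
  }
  sort(union(fam, sup))
}

#' Derive permitted sets for a set of design positions
#'
#' Applies [permitted_amino_acids()] across a column mapping table.
#'
#' @param family,superfamily alignment matrices ([read_alignment()]).
#' @param column_map data frame with columns `position` (structure residue
#'   id), `family_column`, `superfamily_column`.
#' @param min_count_family,min_freq_superfamily thresholds.
#' @return named list position -> permitted one-letter codes.
#' @export
derive_permitted_sets <- function(family, superfamily, column_map,
                                  min_count_family = 1,
                                  min_freq_superfamily = 0.05) {
  out <- list()
  for (r in seq_len(nrow(column_map))) {
    pf <- column_profile(family, column_map$family_column[r])
    ps <- column_profile(superfamily, column_map$superfamily_column[r])
    out[[as.character(column_map$position[r])]] <-
      permitted_amino_acids(pf, ps, min_count_family, min_freq_superfamily)
  }
  out
}
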