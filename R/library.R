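#' A ranked design library
#'
#' An ordered set of mutant sequences over a fixed set of design positions,
#' as produced by a redesign run (or transcribed from a published table),
#' with the wild-type sequence for reference.
#'
#' @param name library label.
#' @param objective "KM", "KCAT_OVER_KM" or "KCAT".
#' @param positions ordered integer residue ids.
#' @param mutants tibble with columns rank (unique), energy (kJ/mol) and
#'   sequence (one-letter string over `positions`).
#' @param wildtype one-letter wild-type sequence over `positions`.
#' @param wildtype_energy wild-type objective energy, kJ/mol (may be NA).
#' @return list of class "design_library".
#' @export
design_library <- function(name, objective, positions, mutants, wildtype,
                           wildtype_energy = NA_real_) {
  mutants <- tibble::as_tibble(mutants)
  stopifnot(all(c("rank", "energy", "sequence") %in% names(mutants)))
  if (anyDuplicated(mutants$rank)) stop("ranks must be unique")
  if (nrow(mutants) &&
      any(nchar(mutants$sequence) != length(positions)))
    stop("every mutant sequence must cover all design positions")
  if (nchar(wildtype) != length(positions))
    stop("wildtype sequence must cover all design positions")
  structure(list(name = name, objective = objective,
                 positions = as.integer(positions), mutants = mutants,
                 wildtype = wildtype, wildtype_energy = wildtype_energy),
            class = "design_library")
}

#' @export
print.design_library <- function(x, ...) {
  cat("<design_library '", x$name, "'> objective ", x$objective, ", ",
      nrow(x$mutants), " mutants over positions ",
      paste(x$positions, collapse = "/"), "; WT ", x$wildtype, "\n", sep = "")
  invisible(x)
}

# mutants of one or more libraries as a long (mutant x position) tibble
library_long <- function(libraries) {
  if (inherits(libraries, "design_library")) libraries <- list(libraries)
  pos <- libraries[[1]]$positions
  for (l in libraries) {
    if (!identical(l$positions, pos))
      stop("libraries do not share design positions")
  }
  purrr::map_dfr(libraries, function(l) {
    if (!nrow(l$mutants)) return(NULL)
    chars <- strsplit(l$mutants$sequence, "")
    tibble::tibble(
      library = l$name,
      rank = rep(l$mutants$rank, each = length(pos)),
      position = rep(pos, nrow(l$mutants)),
      aa = unlist(chars)
    )
  })
}

#' Per-position amino-acid frequencies of a design library
#'
#' Fraction of mutants carrying each amino acid at each design position.
#' Passing a list of libraries pools their mutant lists (the wild type is
#' never counted). Per position the fractions sum to 1.
#'
#' @param libraries a [design_library()] or list of them (pooled).
#' @return tibble of class "frequency_table" with columns position, aa,
#'   count, freq; attribute `n_mutants`.
#' @export
frequency_table <- function(libraries) {
  long <- library_long(libraries)
  if (is.null(long) || !nrow(long)) stop("empty library")
  n <- length(unique(paste(long$library, long$rank)))
  out <- long |>
    dplyr::count(.data$position, .data$aa, name = "count") |>
    dplyr::mutate(freq = .data$count / n) |>
    dplyr::arrange(.data$position, dplyr::desc(.data$freq), .data$aa)
  attr(out, "n_mutants") <- n
  class(out) <- c("frequency_table", class(out))
  out
}

# guard for inclusive threshold comparisons on k/n fractions
FREQ_EPS <- 1e-9

freq_lookup <- function(ft, position, aa) {
  hit <- ft$freq[ft$position == position & ft$aa == aa]
  if (length(hit)) hit else 0
}

#' Mutations representative of one library
#'
#' A (position, amino acid) pair is representative of the target library
#' when it occurs in at least `min_frequency` of its mutants AND at least
#' `margin` more frequently than in the comparison libraries (both
#' thresholds inclusive; comparison is against the maximum over the other
#' libraries by default, or their mean with `compare = "mean"`). Wild-type
#' residues are excluded: a representative *mutation* differs from wild
#' type.
#'
#' @param target a [design_library()].
#' @param others list of comparison [design_library()]s (same positions).
#' @param min_frequency minimum in-library frequency (default 0.15).
#' @param margin minimum frequency advantage (default 0.10).
#' @param compare "max" (strictest) or "mean" over the other libraries.
#' @return tibble with columns position, aa, freq, freq_others.
#' @export
representative_mutations <- function(target, others, min_frequency = 0.15,
                                     margin = 0.10,
                                     compare = c("max", "mean")) {
  compare <- match.arg(compare)
  ft <- frequency_table(target)
  fo <- lapply(others, frequency_table)
  wt <- strsplit(target$wildtype, "")[[1]]
  names(wt) <- as.character(target$positions)
  out <- ft |>
    dplyr::rowwise() |>
    dplyr::mutate(freq_others = {
      vals <- vapply(fo, freq_lookup, 0, position = .data$position,
                     aa = .data$aa)
      if (compare == "max") max(vals) else mean(vals)
    }) |>
    dplyr::ungroup() |>
    dplyr::filter(.data$aa != wt[as.character(.data$position)],
                  .data$freq >= min_frequency - FREQ_EPS,
                  .data$freq - .data$freq_others >= margin - FREQ_EPS) |>
    dplyr::select("position", "aa", "freq", "freq_others")
  out
}

#' Mutations enriched in one group of libraries and absent from another
#'
#' A (position, amino acid) pair qualifies when its frequency is at least
#' `present_threshold` in EVERY library of group A and at most
#' `absent_threshold` in EVERY library of group B. Wild-type residues are
#' excluded. The thresholds are exposed as parameters (no canonical values
#' exist for "enriched" and "largely absent").
#'
#' @param group_a,group_b lists of [design_library()]s sharing positions.
#' @param present_threshold minimum frequency in each group-A library.
#' @param absent_threshold maximum frequency in each group-B library.
#' @return tibble with columns position, aa, min_freq_a, max_freq_b.
#' @export
enriched_in_group_absent_in_group <- function(group_a, group_b,
                                              present_threshold = 0.10,
                                              absent_threshold = 0.05) {
  fa <- lapply(group_a, frequency_table)
  fb <- lapply(group_b, frequency_table)
  pos <- group_a[[1]]$positions
  for (l in c(group_a, group_b))
    if (!identical(l$positions, pos)) stop("libraries do not share positions")
  wt <- strsplit(group_a[[1]]$wildtype, "")[[1]]
  names(wt) <- as.character(pos)
  cand <- dplyr::distinct(dplyr::bind_rows(lapply(fa, function(f)
    f[, c("position", "aa")])))
  rows <- purrr::pmap_dfr(cand, function(position, aa) {
    if (aa == wt[as.character(position)]) return(NULL)
    va <- vapply(fa, freq_lookup, 0, position = position, aa = aa)
    vb <- vapply(fb, freq_lookup, 0, position = position, aa = aa)
    if (all(va >= present_threshold - FREQ_EPS) &&
        all(vb <= absent_threshold + FREQ_EPS))
      tibble::tibble(position = position, aa = aa,
                     min_freq_a = min(va), max_freq_b = max(vb))
    else NULL
  })
  if (!nrow(rows))
    return(tibble::tibble(position = integer(0), aa = character(0),
                          min_freq_a = numeric(0), max_freq_b = numeric(0)))
  dplyr::arrange(rows, .data$position, .data$aa)
}

#' Read and write design-library tables
#'
#' TSV layout mirroring published mutant tables: two comment-style header
#' lines (`# name:`, `# objective:`), a column header
#' `rank energy <position...>`, a wild-type row with rank "WT", then one row
#' per mutant with its rank, objective energy and one amino acid letter per
#' design position. Round-trips bit-exactly.
#'
#' @param path TSV file.
#' @return a [design_library()].
#' @export
read_design_library <- function(path) {
  lines <- readLines(path)
  meta <- list(name = NA_character_, objective = NA_character_)
  body <- character(0)
  for (ln in lines) {
    if (startsWith(ln, "# name:")) meta$name <- trimws(sub("# name:", "", ln))
    else if (startsWith(ln, "# objective:"))
      meta$objective <- trimws(sub("# objective:", "", ln))
    else if (!startsWith(ln, "#") && nzchar(trimws(ln)))
      body <- c(body, ln)
  }
  toks <- strsplit(body, "\t")
  hdr <- toks[[1]]
  if (hdr[1] != "rank" || hdr[2] != "energy")
    stop("malformed library header at line 1: expected 'rank\tenergy\t<positions>'")
  positions <- as.integer(hdr[-(1:2)])
  wt <- NULL; wt_energy <- NA_real_
  rows <- list()
  for (i in seq_along(toks)[-1]) {
    tk <- toks[[i]]
    if (length(tk) != length(hdr))
      stop("malformed library row at line ", i, ": expected ",
           length(hdr), " fields")
    if (tk[1] == "WT") {
      wt <- paste(tk[-(1:2)], collapse = "")
      wt_energy <- as.numeric(tk[2])
    } else {
      rows[[length(rows) + 1]] <- tibble::tibble(
        rank = as.integer(tk[1]), energy = as.numeric(tk[2]),
        sequence = paste(tk[-(1:2)], collapse = ""))
    }
  }
  if (is.null(wt)) stop("library table has no WT row")
  design_library(meta$name, meta$objective, positions,
                 dplyr::bind_rows(rows), wt, wt_energy)
}

#' @rdname read_design_library
#' @param library a [design_library()].
#' @export
write_design_library <- function(library, path) {
  hdr <- paste(c("rank", "energy", library$positions), collapse = "\t")
  wt_row <- paste(c("WT", format_energy(library$wildtype_energy),
                    strsplit(library$wildtype, "")[[1]]), collapse = "\t")
  rows <- vapply(seq_len(nrow(library$mutants)), function(i)
    paste(c(library$mutants$rank[i],
            format_energy(library$mutants$energy[i]),
            strsplit(library$mutants$sequence[i], "")[[1]]),
          collapse = "\t"), "")
  writeLines(c(paste("# name:", library$name),
               paste("# objective:", library$objective),
               hdr, wt_row, rows), path)
  invisible(path)
}

format_energy <- function(x) {
  ifelse(is.na(x), "NA", sprintf("%.10g", x))
}

#' Load the packaged published-mutant-library fixtures
#'
#' Transcriptions of the two published top-10 mutant tables for the
#' glucuronidase redesign: three libraries (K_M-, k_cat/K_M- and
#' k_cat-optimized) for the native-like glucuronide substrate and three for
#' the galactoside target substrate, each with its wild-type row.
#'
#' @param substrate "glucuronide" or "galactoside".
#' @return named list of three [design_library()]s (km, efficiency, kcat).
#' @export
published_libraries <- function(substrate = c("glucuronide", "galactoside")) {
  substrate <- match.arg(substrate)
  stem <- if (substrate == "glucuronide") "glu" else "gal"
  objs <- c(km = "km", efficiency = "efficiency", kcat = "kcat")
  lapply(objs, function(o)
    read_design_library(system.file("extdata",
                                    paste0("library_", stem, "_", o, ".tsv"),
                                    package = "tsadesign")))
}

#' Bar chart of per-position amino-acid frequencies
#'
#' @param object a [frequency_table()].
#' @param ... unused.
#' @return a ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.frequency_table <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$aa, y = .data$freq)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~position, scales = "free_x") +
    ggplot2::labs(x = "amino acid", y = "frequency") +
    ggplot2::theme_minimal()
}
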