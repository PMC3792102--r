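#' Read a PDB file into an atom-record tibble
#'
#' Only ATOM/HETATM/TER/END records are interpreted (via bio3d). HETATM
#' records are tagged "ligand", ATOM records "enzyme". A missing chain
#' identifier defaults to "A" with a warning.
#'
#' @param path PDB file.
#' @return tibble with columns record, atom_id, name, element, residue_id,
#'   residue_name, chain, molecule_tag, x, y, z.
#' @export
read_pdb <- function(path) {
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  ch <- as.character(at$chain)
  if (any(is.na(ch) | ch == "")) {
    warning("PDB records without a chain id: defaulting to chain 'A'")
    ch[is.na(ch) | ch == ""] <- "A"
  }
  tibble::tibble(
    record = as.character(at$type),
    atom_id = as.integer(at$eleno),
    name = as.character(at$elety),
    element = ifelse(is.na(at$elesy) | at$elesy == "",
                     substr(gsub("[0-9]", "", at$elety), 1, 1),
                     as.character(at$elesy)),
    residue_id = as.integer(at$resno),
    residue_name = as.character(at$resid),
    chain = ch,
    molecule_tag = ifelse(at$type == "HETATM", "ligand", "enzyme"),
    x = at$x, y = at$y, z = at$z
  )
}

#' Write a molecular system to a PDB file
#'
#' Ligand-tagged atoms are written as HETATM, everything else as ATOM;
#' occupancy/B-factor are 1.00/0.00; coordinates are written at PDB precision
#' (3 decimals). Output is deterministic for a given system.
#'
#' @param system a [molecular_system()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(system, path) {
  at <- system$atoms
  bio3d::write.pdb(
    file = path,
    type = ifelse(at$molecule_tag == "ligand", "HETATM", "ATOM"),
    xyz = as.vector(t(system$coords)),
    resno = at$residue_id, resid = at$residue_name,
    eleno = at$atom_id, elety = at$name, chain = at$chain,
    o = rep(1, nrow(at)), b = rep(0, nrow(at)),
    elesy = at$element
  )
  invisible(path)
}

fmt_num <- function(x) sprintf("%.17g", x)

#' Read and write nonbonded/solvation parameter files
#'
#' A documented whitespace-delimited text format. The `[atoms]` section maps
#' (residue_name, atom_name) to charge, lj_epsilon, lj_rmin_half,
#' born_radius, vdw_radius and sasa_coefficient; "*" acts as a wildcard
#' fallback (most specific match wins). Optional bonded sections `[bonds]`,
#' `[angles]`, `[urey_bradley]`, `[dihedrals]`, `[impropers]` list terms by
#' chain/residue-id/atom-name selectors. Harmonic constants use the
#' k (x - x0)^2 convention; energies are kJ/mol (convert kcal inputs with
#' [mm_constants]$KJ_PER_KCAL before writing). Numbers round-trip bit-exactly.
#'
#' @param path parameter file.
#' @return a list with element `atoms` (tibble) and one tibble per bonded
#'   section present.
#' @export
read_parameters <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[lines != "" & !startsWith(lines, "#")]
  sec <- cumsum(grepl("^\\[", lines))
  out <- list()
  for (s in split(lines, sec)) {
    header <- sub("\\]$", "", sub("^\\[", "", s[1]))
    body <- s[-1]
    if (!length(body)) next
    toks <- strsplit(body, "[ \t]+")
    out[[header]] <- switch(header,
      atoms = tibble::tibble(
        residue_name = vapply(toks, `[`, "", 1),
        atom_name = vapply(toks, `[`, "", 2),
        charge = as.numeric(vapply(toks, `[`, "", 3)),
        lj_epsilon = as.numeric(vapply(toks, `[`, "", 4)),
        lj_rmin_half = as.numeric(vapply(toks, `[`, "", 5)),
        born_radius = as.numeric(vapply(toks, `[`, "", 6)),
        vdw_radius = as.numeric(vapply(toks, `[`, "", 7)),
        sasa_coefficient = as.numeric(vapply(toks, `[`, "", 8))
      ),
      bonds = selector_block(toks, 2, c("k_b", "r0")),
      urey_bradley = selector_block(toks, 2, c("k_ub", "s0")),
      angles = selector_block(toks, 3, c("k_theta", "theta0")),
      dihedrals = selector_block(toks, 4, c("k_phi", "n", "delta")),
      impropers = selector_block(toks, 4, c("k_psi", "psi0")),
      stop("unknown parameter section [", header, "]")
    )
  }
  out
}

selector_block <- function(toks, n_sel, value_cols) {
  cols <- list()
  for (a in seq_len(n_sel)) {
    off <- (a - 1) * 3
    cols[[paste0("chain_", a)]] <- vapply(toks, `[`, "", off + 1)
    cols[[paste0("res_", a)]] <- as.integer(vapply(toks, `[`, "", off + 2))
    cols[[paste0("atom_", a)]] <- vapply(toks, `[`, "", off + 3)
  }
  for (v in seq_along(value_cols)) {
    cols[[value_cols[v]]] <-
      as.numeric(vapply(toks, `[`, "", n_sel * 3 + v))
  }
  tibble::as_tibble(cols)
}

#' @rdname read_parameters
#' @param params a parameter list as returned by [read_parameters()].
#' @export
write_parameters <- function(params, path) {
  out <- character(0)
  if (!is.null(params$atoms)) {
    a <- params$atoms
    out <- c(out, "[atoms]",
             paste(a$residue_name, a$atom_name, fmt_num(a$charge),
                   fmt_num(a$lj_epsilon), fmt_num(a$lj_rmin_half),
                   fmt_num(a$born_radius), fmt_num(a$vdw_radius),
                   fmt_num(a$sasa_coefficient)))
  }
  wsel <- function(tab, n_sel, value_cols) {
    parts <- list()
    for (a in seq_len(n_sel)) {
      parts[[length(parts) + 1]] <- tab[[paste0("chain_", a)]]
      parts[[length(parts) + 1]] <- tab[[paste0("res_", a)]]
      parts[[length(parts) + 1]] <- tab[[paste0("atom_", a)]]
    }
    for (v in value_cols) {
      col <- tab[[v]]
      parts[[length(parts) + 1]] <-
        if (v == "n") as.character(as.integer(col)) else fmt_num(col)
    }
    do.call(paste, parts)
  }
  spec <- list(bonds = list(2, c("k_b", "r0")),
               urey_bradley = list(2, c("k_ub", "s0")),
               angles = list(3, c("k_theta", "theta0")),
               dihedrals = list(4, c("k_phi", "n", "delta")),
               impropers = list(4, c("k_psi", "psi0")))
  for (nm in names(spec)) {
    if (!is.null(params[[nm]]) && nrow(params[[nm]])) {
      out <- c(out, paste0("[", nm, "]"),
               wsel(params[[nm]], spec[[nm]][[1]], spec[[nm]][[2]]))
    }
  }
  writeLines(out, path)
  invisible(path)
}

#' Assemble a molecular system from a PDB file and parameters
#'
#' Atom parameters are looked up by (residue_name, atom_name) in the
#' `[atoms]` section, falling back to (residue, *), (*, atom) and (*, *)
#' wildcards in that order. Bonded sections are resolved by their
#' chain/residue/atom selectors.
#'
#' @param path PDB file.
#' @param params list from [read_parameters()].
#' @return a [molecular_system()].
#' @export
system_from_pdb <- function(path, params) {
  rec <- read_pdb(path)
  pt <- params$atoms
  look <- function(res, atm, col) {
    for (cand in list(c(res, atm), c(res, "*"), c("*", atm), c("*", "*"))) {
      hit <- which(pt$residue_name == cand[1] & pt$atom_name == cand[2])
      if (length(hit)) return(pt[[col]][hit[1]])
    }
    stop("no parameters for atom ", res, "/", atm)
  }
  cols <- c("charge", "lj_epsilon", "lj_rmin_half", "born_radius",
            "vdw_radius", "sasa_coefficient")
  vals <- lapply(cols, function(cl)
    unname(mapply(look, rec$residue_name, rec$name,
                  MoreArgs = list(col = cl))))
  names(vals) <- cols
  atoms <- atom_table(rec$atom_id, rec$name, rec$element, rec$residue_id,
                      rec$residue_name, rec$chain, rec$molecule_tag,
                      vals$charge, vals$lj_epsilon, vals$lj_rmin_half,
                      vals$born_radius, vals$sasa_coefficient,
                      vals$vdw_radius)
  coords <- cbind(rec$x, rec$y, rec$z)
  res_id <- function(ch, rs, nm) {
    hit <- which(rec$chain == ch & rec$residue_id == rs & rec$name == nm)
    if (length(hit) != 1)
      stop("bonded-term selector ", ch, "/", rs, "/", nm, " is not unique")
    rec$atom_id[hit]
  }
  conv <- function(tab, n_sel, idx_names) {
    if (is.null(tab) || !nrow(tab)) return(NULL)
    out <- tab
    for (a in seq_len(n_sel)) {
      out[[idx_names[a]]] <- mapply(res_id, tab[[paste0("chain_", a)]],
                                    tab[[paste0("res_", a)]],
                                    tab[[paste0("atom_", a)]])
    }
    out[, c(idx_names,
            setdiff(names(tab), grep("^(chain|res|atom)_", names(tab),
                                     value = TRUE))), drop = FALSE]
  }
  top <- mm_topology(
    bonds = conv(params$bonds, 2, c("i", "j")),
    angles = conv(params$angles, 3, c("i", "j", "k")),
    urey_bradley = conv(params$urey_bradley, 2, c("i", "k")),
    dihedrals = conv(params$dihedrals, 4, c("i", "j", "k", "l")),
    impropers = conv(params$impropers, 4, c("i", "j", "k", "l"))
  )
  molecular_system(atoms, coords, top)
}

#' Read and write NOE restraint files
#'
#' One restraint per line: chainA resA atomA chainB resB atomB d_min d_max
#' k_min k_max (whitespace-delimited; "#" comments). The packaged catalytic
#' restraint set for the glucuronidase active site ships at
#' `system.file("extdata", "catalytic_restraints.tsv", package = "tsadesign")`.
#'
#' @param path restraint file.
#' @return a [noe_restraints()] tibble.
#' @export
read_restraints <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[lines != "" & !startsWith(lines, "#")]
  toks <- strsplit(lines, "[ \t]+")
  bad <- which(lengths(toks) != 10)
  if (length(bad))
    stop("malformed restraint line ", bad[1], ": expected 10 fields")
  g <- function(k) vapply(toks, `[`, "", k)
  noe_restraints(g(1), as.integer(g(2)), g(3), g(4), as.integer(g(5)), g(6),
                 as.numeric(g(7)), as.numeric(g(8)),
                 as.numeric(g(9)), as.numeric(g(10)))
}

#' @rdname read_restraints
#' @param restraints a [noe_restraints()] tibble.
#' @export
write_restraints <- function(restraints, path) {
  writeLines(paste(restraints$chain_a, restraints$res_a, restraints$atom_a,
                   restraints$chain_b, restraints$res_b, restraints$atom_b,
                   fmt_num(restraints$d_min), fmt_num(restraints$d_max),
                   fmt_num(restraints$k_min), fmt_num(restraints$k_max)),
             path)
  invisible(path)
}

#' Export a system's bonded topology as parameter-file selector blocks
#'
#' Converts the atom-id-indexed topology of a [molecular_system()] into the
#' chain/residue/atom-name selector form used by parameter files, so that
#' [write_parameters()] + [system_from_pdb()] reproduce the full system.
#'
#' @param system a [molecular_system()].
#' @param params optional parameter list whose `atoms` section is carried
#'   over.
#' @return a parameter list with `atoms` (if supplied) and bonded sections.
#' @export
parameters_from_system <- function(system, params = NULL) {
  at <- system$atoms
  sel <- function(ids, k) {
    rows <- match(ids, at$atom_id)
    stats::setNames(list(at$chain[rows], at$residue_id[rows],
                         at$name[rows]),
                    paste0(c("chain_", "res_", "atom_"), k))
  }
  conv <- function(tab, idx_names, value_cols) {
    if (is.null(tab) || !nrow(tab)) return(NULL)
    cols <- list()
    for (k in seq_along(idx_names))
      cols <- c(cols, sel(tab[[idx_names[k]]], k))
    for (v in value_cols) cols[[v]] <- tab[[v]]
    tibble::as_tibble(cols)
  }
  out <- list(atoms = params$atoms)
  out$bonds <- conv(system$topology$bonds, c("i", "j"), c("k_b", "r0"))
  out$urey_bradley <- conv(system$topology$urey_bradley, c("i", "k"),
                           c("k_ub", "s0"))
  out$angles <- conv(system$topology$angles, c("i", "j", "k"),
                     c("k_theta", "theta0"))
  out$dihedrals <- conv(system$topology$dihedrals, c("i", "j", "k", "l"),
                        c("k_phi", "n", "delta"))
  out$impropers <- conv(system$topology$impropers, c("i", "j", "k", "l"),
                        c("k_psi", "psi0"))
  out[!vapply(out, is.null, TRUE)]
}

#' Read a rotamer library
#'
#' Text format: for each rotamer a header line
#' `ROT <residue_type> <n_atoms> <probability>` followed by `n_atoms` lines
#' `name x y z` giving side-chain atom coordinates in the local backbone
#' frame (origin at CA, x along CA->N, z along the N-CA-C plane normal).
#' Glycine rotamers have zero atoms. Probabilities per residue type must sum
#' to at most 1.
#'
#' @param path library file.
#' @return named list: residue type -> list of rotamers, each a list with
#'   residue_type, probability and an atoms tibble (name, x, y, z).
#' @export
read_rotamer_library <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[lines != "" & !startsWith(lines, "#")]
  lib <- list()
  i <- 1
  while (i <= length(lines)) {
    tok <- strsplit(lines[i], "[ \t]+")[[1]]
    if (tok[1] != "ROT") stop("expected ROT header at line: ", lines[i])
    rt <- tok[2]; na <- as.integer(tok[3]); p <- as.numeric(tok[4])
    atoms <- tibble::tibble(name = character(0), x = numeric(0),
                            y = numeric(0), z = numeric(0))
    if (na > 0) {
      block <- strsplit(lines[i + seq_len(na)], "[ \t]+")
      atoms <- tibble::tibble(
        name = vapply(block, `[`, "", 1),
        x = as.numeric(vapply(block, `[`, "", 2)),
        y = as.numeric(vapply(block, `[`, "", 3)),
        z = as.numeric(vapply(block, `[`, "", 4))
      )
    }
    lib[[rt]] <- c(lib[[rt]], list(list(residue_type = rt, probability = p,
                                        atoms = atoms)))
    i <- i + 1 + na
  }
  for (rt in names(lib)) {
    ps <- sum(vapply(lib[[rt]], `[[`, 0, "probability"))
    if (ps > 1 + 1e-6)
      stop("rotamer probabilities for ", rt, " sum to ", ps, " > 1")
  }
  lib
}

#' @rdname read_rotamer_library
#' @param library a rotamer library list.
#' @export
write_rotamer_library <- function(library, path) {
  out <- character(0)
  for (rt in names(library)) {
    for (rot in library[[rt]]) {
      out <- c(out, paste("ROT", rt, nrow(rot$atoms),
                          fmt_num(rot$probability)))
      if (nrow(rot$atoms))
        out <- c(out, paste(rot$atoms$name, fmt_num(rot$atoms$x),
                            fmt_num(rot$atoms$y), fmt_num(rot$atoms$z)))
    }
  }
  writeLines(out, path)
  invisible(path)
}

#' Read an aligned FASTA file
#'
#' @param path aligned FASTA (all sequences equal length).
#' @return a character matrix, one row per sequence, one column per
#'   alignment column.
#' @export
read_alignment <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  w <- Biostrings::width(ss)
  if (length(unique(w)) > 1)
    stop("ragged alignment: sequence lengths ", paste(unique(w), collapse = ", "))
  mat <- do.call(rbind, strsplit(unname(as.character(ss)), ""))
  rownames(mat) <- names(ss)
  mat
}

#' Read and write permitted-amino-acid set files
#'
#' One line per design position: `<position>: <comma-separated one-letter
#' codes>`. The alignment-derived permitted sets for the nine glucuronidase
#' design positions ship as `permitted_sets.txt` in `extdata`.
#'
#' @param path permitted-set file.
#' @return named list: position (as character) -> character vector of
#'   one-letter codes.
#' @export
read_permitted_sets <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[lines != "" & !startsWith(lines, "#")]
  out <- list()
  for (ln in lines) {
    parts <- strsplit(ln, ":")[[1]]
    pos <- trimws(parts[1])
    out[[pos]] <- trimws(strsplit(parts[2], ",")[[1]])
  }
  out
}

#' @rdname read_permitted_sets
#' @param sets named list of permitted sets.
#' @export
write_permitted_sets <- function(sets, path) {
  writeLines(vapply(names(sets), function(p)
    paste0(p, ": ", paste(sets[[p]], collapse = ", ")), ""), path)
  invisible(path)
}
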