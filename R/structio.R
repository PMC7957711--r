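# PDB reading/writing and the molecular data model.
#
# A Structure is a list with class "Structure":
#   $atoms      data.frame, one row per atom, file order preserved
#   $model_id   integer MODEL number (1 for single-model files)
#   $provenance list(path, model_index)
#   $typed      logical, TRUE once assign_atom_types() has run
#
# Residue identity throughout the package is (chain, number, insertion code),
# encoded as the key "<chain>:<resno><ins>". Numbering follows the source file.

#' Default glycan residue names
#'
#' HETATM residues with these names are flagged as glycans and kept as
#' standalone residues, so that sugar contacts (e.g. the N-linked NAG chain of
#' a channel) can be reported separately from amino-acid contacts.
#' @return character vector of 3-letter residue names
#' @export
glycan_residue_names <- function() c("NAG", "BMA", "MAN")

STANDARD_AA <- c(
  "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
  "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL"
)

#' Residue keys for each atom of a Structure
#' @param s Structure
#' @return character vector, one key "<chain>:<resno><ins>" per atom
#' @export
residue_keys <- function(s) {
  a <- s$atoms
  paste0(a$chain, ":", a$resno, a$ins)
}

#' Residue-level table of a Structure
#' @param s Structure
#' @return data.frame with key, chain, resno, ins, resname, is_glycan,
#'   is_het, n_atoms in file order
#' @export
residue_table <- function(s) {
  a <- s$atoms
  key <- residue_keys(s)
  first <- !duplicated(key)
  data.frame(
    key = key[first],
    chain = a$chain[first],
    resno = a$resno[first],
    ins = a$ins[first],
    resname = a$resname[first],
    is_glycan = a$is_glycan[first],
    is_het = a$is_het[first],
    n_atoms = as.integer(table(factor(key, levels = key[first]))),
    stringsAsFactors = FALSE
  )
}

new_structure <- function(atoms, model_id = 1L, provenance = list(), typed = FALSE) {
  structure(
    list(atoms = atoms, model_id = as.integer(model_id),
         provenance = provenance, typed = typed),
    class = "Structure"
  )
}

#' @export
print.Structure <- function(x, ...) {
  rt <- residue_table(x)
  cat(sprintf(
    "Structure (model %d): %d atoms, %d residues, chains [%s]%s\n",
    x$model_id, nrow(x$atoms), nrow(rt),
    paste(unique(x$atoms$chain), collapse = ","),
    if (isTRUE(x$typed)) ", typed" else ""
  ))
  invisible(x)
}

#' Coordinates of a Structure as a matrix
#' @param s Structure
#' @param heavy restrict to heavy (non-hydrogen) atoms
#' @return n x 3 matrix
#' @export
coords <- function(s, heavy = FALSE) {
  a <- s$atoms
  if (heavy) a <- a[!a$is_hydrogen, , drop = FALSE]
  as.matrix(a[, c("x", "y", "z")])
}

#' Replace the coordinates of a Structure
#' @param s Structure
#' @param xyz n x 3 matrix matching all atoms of s
#' @return Structure with new coordinates
#' @export
set_coords <- function(s, xyz) {
  stopifnot(nrow(xyz) == nrow(s$atoms), ncol(xyz) == 3)
  s$atoms$x <- xyz[, 1]
  s$atoms$y <- xyz[, 2]
  s$atoms$z <- xyz[, 3]
  s
}

# Element inference when columns 77-78 are blank: strip digits, take the
# PDB convention that column 13 non-blank means a two-letter element for
# common hetero atoms; for standard atom names the first letter suffices.
infer_element <- function(name) {
  nm <- gsub("[0-9']", "", trimws(name))
  two <- toupper(substr(nm, 1, 2))
  ifelse(two %in% c("CL", "BR", "FE", "ZN", "MG", "NA", "SE"),
         substr(paste0(substr(two, 1, 1), tolower(substr(two, 2, 2))), 1, 2),
         substr(nm, 1, 1))
}

#' Read a PDB file
#'
#' Parses ATOM/HETATM/MODEL/ENDMDL records into Structure objects. Multi-model
#' files (NMR ensembles) yield a list of Structures unless a single
#' \code{model_index} is requested. Alternate locations are resolved to the
#' highest-occupancy conformer (ties: first in file). HETATM residues whose
#' name is in \code{glycan_names} are flagged \code{is_glycan}.
#'
#' @param path PDB file path
#' @param model_index optional 1-based model index to extract
#' @param glycan_names residue names treated as glycans
#' @return a Structure (single model or \code{model_index} given) or a list of
#'   Structures, one per MODEL
#' @export
read_pdb <- function(path, model_index = NULL, glycan_names = glycan_residue_names()) {
  if (!file.exists(path)) stop("PDB file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  is_model <- rec == "MODEL "
  is_endmdl <- rec == "ENDMDL"
  if (!any(is_atom)) stop("no ATOM/HETATM records in ", path)

  # model id per line: cumulative count of MODEL records (0 => implicit model 1)
  model_no <- cumsum(is_model)
  if (max(model_no) == 0) model_no <- model_no + 1L

  idx <- which(is_atom)
  al <- lines[idx]
  # pad short lines so substr on fixed columns is safe
  short <- nchar(al) < 80
  if (any(short)) al[short] <- formatC(al[short], width = -80)

  num <- function(x) suppressWarnings(as.numeric(x))
  atoms <- data.frame(
    record = trimws(substr(al, 1, 6)),
    serial = suppressWarnings(as.integer(substr(al, 7, 11))),
    name = trimws(substr(al, 13, 16)),
    altloc = substr(al, 17, 17),
    resname = trimws(substr(al, 18, 20)),
    chain = substr(al, 22, 22),
    resno = suppressWarnings(as.integer(substr(al, 23, 26))),
    ins = trimws(substr(al, 27, 27)),
    x = num(substr(al, 31, 38)),
    y = num(substr(al, 39, 46)),
    z = num(substr(al, 47, 54)),
    occ = num(substr(al, 55, 60)),
    bfac = num(substr(al, 61, 66)),
    element = trimws(substr(al, 77, 78)),
    stringsAsFactors = FALSE
  )
  bad <- which(is.na(atoms$x) | is.na(atoms$y) | is.na(atoms$z) | is.na(atoms$resno))
  if (length(bad)) {
    stop(sprintf("unparseable PDB record at line %d of %s", idx[bad[1]], path))
  }
  atoms$occ[is.na(atoms$occ)] <- 1.0
  atoms$bfac[is.na(atoms$bfac)] <- 0.0
  blank_el <- atoms$element == ""
  atoms$element[blank_el] <- infer_element(atoms$name[blank_el])
  atoms$element <- paste0(
    toupper(substr(atoms$element, 1, 1)),
    tolower(substr(atoms$element, 2, 2))
  )
  atoms$is_hydrogen <- atoms$element %in% c("H", "D")
  atoms$is_het <- atoms$record == "HETATM"
  atoms$is_glycan <- atoms$is_het & atoms$resname %in% glycan_names
  atoms$model <- model_no[idx]

  models <- sort(unique(atoms$model))
  build_one <- function(m, i) {
    a <- atoms[atoms$model == m, setdiff(names(atoms), "model"), drop = FALSE]
    # altloc resolution: for each (residue, atom name), keep highest occupancy,
    # tie broken by file order (stable order of which.max on the first max)
    if (any(a$altloc != " ")) {
      grp <- paste(a$chain, a$resno, a$ins, a$name, sep = "\r")
      keep <- unlist(lapply(split(seq_len(nrow(a)), factor(grp, levels = unique(grp))),
                            function(ii) ii[which.max(a$occ[ii])]),
                     use.names = FALSE)
      a <- a[sort(keep), , drop = FALSE]
      a$altloc <- " "
    }
    rownames(a) <- NULL
    if (anyDuplicated(a$serial)) a$serial <- seq_len(nrow(a))
    new_structure(a, model_id = i, provenance = list(path = path, model_index = i))
  }
  out <- lapply(seq_along(models), function(i) build_one(models[i], i))
  if (!is.null(model_index)) {
    if (model_index < 1 || model_index > length(out)) {
      stop(sprintf("model_index %d out of range [1, %d]", model_index, length(out)))
    }
    return(out[[model_index]])
  }
  if (length(out) == 1) out[[1]] else out
}

#' Write one or more Structures to a PDB file
#'
#' Emits standard fixed-column ATOM/HETATM records; a list of Structures (or a
#' multi-model request) is wrapped in MODEL/ENDMDL blocks. TER records close
#' each chain of non-HETATM residues.
#'
#' @param s Structure or list of Structures
#' @param path output file path
#' @return invisibly, the path
#' @export
write_pdb <- function(s, path) {
  models <- if (inherits(s, "Structure")) list(s) else s
  stopifnot(all(vapply(models, inherits, logical(1), "Structure")))
  multi <- length(models) > 1
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(models)) {
    if (multi) writeLines(sprintf("MODEL     %4d", i), con)
    a <- models[[i]]$atoms
    fmt_name <- ifelse(nchar(a$name) < 4 & nchar(a$element) < 2,
                       sprintf(" %-3s", a$name), sprintf("%-4s", a$name))
    lines <- sprintf(
      "%-6s%5d %s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      a$record, a$serial %% 100000L, fmt_name, " ", a$resname, a$chain,
      a$resno %% 10000L, ifelse(a$ins == "", " ", a$ins),
      a$x, a$y, a$z, a$occ, a$bfac, toupper(a$element)
    )
    writeLines(lines, con)
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Define a region of residues
#'
#' A RegionSpec selects residues by explicit (chain, number, insertion code)
#' membership and/or by residue name (e.g. all NAG glycans). A chain of NA
#' matches any chain.
#'
#' @param name region label (e.g. "site3", "S4")
#' @param members data.frame with columns chain, resno and optionally ins, or a
#'   list of c(chain, resno) pairs; may be NULL
#' @param resnames residue names selected wholesale (e.g. "NAG"); may be NULL
#' @return RegionSpec object
#' @export
region_spec <- function(name, members = NULL, resnames = NULL) {
  if (!is.null(members)) {
    if (is.list(members) && !is.data.frame(members)) {
      members <- do.call(rbind, lapply(members, function(m) {
        data.frame(chain = as.character(m[1]), resno = as.integer(m[2]),
                   ins = if (length(m) > 2) as.character(m[3]) else "",
                   stringsAsFactors = FALSE)
      }))
    }
    members <- as.data.frame(members)
    if (is.null(members$ins)) members$ins <- ""
    if (is.null(members$chain)) members$chain <- NA_character_
    members$chain <- as.character(members$chain)
    members$resno <- as.integer(members$resno)
    members$ins <- as.character(members$ins)
  }
  if (is.null(members) && is.null(resnames)) {
    stop("region '", name, "' needs members and/or resnames")
  }
  structure(list(name = name, members = members, resnames = resnames),
            class = "RegionSpec")
}

#' @export
print.RegionSpec <- function(x, ...) {
  cat(sprintf("RegionSpec '%s': %d explicit members%s\n", x$name,
              if (is.null(x$members)) 0L else nrow(x$members),
              if (is.null(x$resnames)) "" else
                paste0(", resnames [", paste(x$resnames, collapse = ","), "]")))
  invisible(x)
}

# Logical mask over the residues of residue_table(s) selected by region r
region_residue_mask <- function(rt, r) {
  stopifnot(inherits(r, "RegionSpec"))
  sel <- rep(FALSE, nrow(rt))
  if (!is.null(r$members)) {
    for (i in seq_len(nrow(r$members))) {
      m <- r$members[i, ]
      hit <- rt$resno == m$resno & rt$ins == m$ins
      if (!is.na(m$chain) && m$chain != "") hit <- hit & rt$chain == m$chain
      sel <- sel | hit
    }
  }
  if (!is.null(r$resnames)) sel <- sel | rt$resname %in% r$resnames
  sel
}

#' Resolve a RegionSpec against a Structure
#'
#' @param s Structure
#' @param r RegionSpec
#' @return data.frame of selected residues (subset of
#'   \code{residue_table(s)}) in file order; may be empty
#' @export
select_region <- function(s, r) {
  rt <- residue_table(s)
  rt[region_residue_mask(rt, r), , drop = FALSE]
}

# Atom index mask for residues selected by a region (or a chain id string)
region_atom_mask <- function(s, selector) {
  if (is.character(selector) && length(selector) == 1 &&
      !inherits(selector, "RegionSpec")) {
    return(s$atoms$chain == selector)
  }
  rt <- residue_table(s)
  keys <- rt$key[region_residue_mask(rt, selector)]
  residue_keys(s) %in% keys
}

#' Remove selected residues from a Structure
#'
#' Used e.g. to delete a co-crystallised ligand chain from a receptor before
#' docking. All other records are untouched.
#'
#' @param s Structure
#' @param selector RegionSpec, or a single chain id string
#' @return Structure without the selected residues
#' @export
strip_residues <- function(s, selector) {
  mask <- region_atom_mask(s, selector)
  if (!any(mask)) stop("strip_residues: selector matched no residues")
  s$atoms <- s$atoms[!mask, , drop = FALSE]
  rownames(s$atoms) <- NULL
  s
}

#' Heavy-atom RMSD between two placements of the same molecule
#'
#' No superposition is performed: the two structures are assumed to share the
#' receptor coordinate frame (two poses of one ligand).
#'
#' @param a,b Structures with identical heavy-atom names and order
#' @return RMSD in Angstrom
#' @export
ligand_rmsd <- function(a, b) {
  aa <- a$atoms[!a$atoms$is_hydrogen, , drop = FALSE]
  bb <- b$atoms[!b$atoms$is_hydrogen, , drop = FALSE]
  if (nrow(aa) != nrow(bb) || !all(aa$name == bb$name) ||
      !all(aa$resno == bb$resno)) {
    stop("ligand_rmsd: atom topology mismatch")
  }
  d2 <- (aa$x - bb$x)^2 + (aa$y - bb$y)^2 + (aa$z - bb$z)^2
  sqrt(mean(d2))
}

#' Combine two Structures into one complex
#'
#' Atoms are concatenated (receptor first); serials are renumbered. Chain ids
#' must not collide between the two molecules.
#' @param receptor,ligand Structures
#' @return Structure holding both molecules
#' @export
merge_structures <- function(receptor, ligand) {
  overlap <- intersect(unique(receptor$atoms$chain), unique(ligand$atoms$chain))
  if (length(overlap)) {
    stop("merge_structures: chain id collision: ", paste(overlap, collapse = ","))
  }
  a <- rbind(receptor$atoms, ligand$atoms)
  a$serial <- seq_len(nrow(a))
  rownames(a) <- NULL
  new_structure(a, model_id = receptor$model_id,
                provenance = list(path = NA_character_, model_index = NA_integer_),
                typed = isTRUE(receptor$typed) && isTRUE(ligand$typed))
}
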