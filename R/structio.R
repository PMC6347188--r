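# Structure I/O: PDB / PDBQT atom tables, heavy-atom selection, pose RMSD,
# generic residue numbering.

#' Read a molecular structure from a PDB or PDBQT file
#'
#' Parses all `ATOM`/`HETATM` records into an atom table. A structure is a
#' tibble with one row per atom and attributes `id` and `source_format`;
#' it flows through the rest of the package (grids, RMSD, docking poses).
#'
#' PDBQT is the AutoDock dialect of PDB: the element columns carry AutoDock
#' atom types (e.g. `OA`, `NA`, `HD`) and files may contain `REMARK VINA
#' RESULT`, `ROOT`/`BRANCH` and `TORSDOF` records, which are ignored here
#' (scores are extracted by [parse_scores()]).
#'
#' When a residue has alternate locations, only the highest-occupancy
#' altloc is kept, so downstream grids see a single conformer.
#'
#' @param path Path to the file.
#' @param format `"pdb"`, `"pdbqt"`, or `"auto"` (default; decided by file
#'   extension, falling back to PDB).
#' @param id Model identifier; defaults to the file name without extension.
#'
#' @return A `structure_model`: a tibble with columns `serial`, `name`,
#'   `element`, `residue_name`, `residue_number`, `chain`, `x`, `y`, `z`,
#'   `is_heavy`, `record` and `occupancy`.
#' @examples
#' pdb <- tempfile(fileext = ".pdb")
#' writeLines("ATOM      1  CA  ALA A   1       1.000   2.000   3.000  1.00  0.00           C",
#'            pdb)
#' read_structure(pdb)
#' @export
read_structure <- function(path, format = c("auto", "pdb", "pdbqt"),
                           id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    abort(paste0("Cannot read structure: file not found: ", path))
  }
  if (format == "auto") {
    format <- if (grepl("\\.pdbqt$", path, ignore.case = TRUE)) "pdbqt" else "pdb"
  }
  if (is.null(id)) id <- sub("\\.[^.]*$", "", basename(path))

  atoms <- if (format == "pdbqt") {
    parse_pdbqt_atoms(readLines(path, warn = FALSE))
  } else {
    parse_pdb_atoms(path)
  }
  if (nrow(atoms) == 0L) {
    abort(paste0("No ATOM/HETATM records in ", path))
  }
  atoms <- collapse_altlocs(atoms)
  new_structure_model(atoms, id = id, source_format = toupper(format))
}

new_structure_model <- function(atoms, id, source_format = "PDB") {
  atoms <- as_tibble(atoms)
  stopifnot(all(c("serial", "name", "element", "residue_name",
                  "residue_number", "chain", "x", "y", "z") %in% names(atoms)))
  if (anyDuplicated(atoms$serial)) {
    abort("Atom serial numbers must be unique within a model")
  }
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z))) {
    abort("Atom coordinates must be finite")
  }
  if (!"is_heavy" %in% names(atoms)) {
    atoms$is_heavy <- toupper(atoms$element) != "H"
  }
  structure(atoms,
            class = c("structure_model", class(tibble())),
            id = id, source_format = source_format)
}

# PDB parsing is delegated to bio3d; only the column normalisation is ours.
parse_pdb_atoms <- function(path) {
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE)),
    error = function(e) abort(paste0("Unreadable PDB file ", path, ": ",
                                     conditionMessage(e)))
  )
  a <- pdb$atom
  if (is.null(a) || nrow(a) == 0L) return(tibble())
  elem <- infer_element(a$elesy, a$elety)
  tibble(
    serial = as.integer(a$eleno),
    name = as.character(a$elety),
    element = elem,
    residue_name = as.character(a$resid),
    residue_number = as.integer(a$resno),
    chain = ifelse(is.na(a$chain), "", as.character(a$chain)),
    x = a$x, y = a$y, z = a$z,
    record = as.character(a$type),
    occupancy = ifelse(is.na(a$o), 1, a$o),
    altloc = ifelse(is.na(a$alt), "", as.character(a$alt))
  ) %>% mutate(is_heavy = toupper(.data$element) != "H")
}

# Fixed-column reader for the AutoDock PDBQT dialect (bio3d mis-reads its
# charge/type columns). Branch/torsion records are skipped by design.
parse_pdbqt_atoms <- function(lines) {
  rec <- substr(lines, 1, 6)
  keep <- grepl("^(ATOM|HETATM)", rec)
  lines <- lines[keep]
  if (length(lines) == 0L) return(tibble())
  fx <- function(l, from, to) trimws(substr(l, from, to))
  adtype <- fx(lines, 78, 79)
  tibble(
    serial = as.integer(fx(lines, 7, 11)),
    name = fx(lines, 13, 16),
    element = autodock_type_to_element(adtype, fx(lines, 13, 16)),
    residue_name = fx(lines, 18, 21),
    residue_number = as.integer(fx(lines, 23, 26)),
    chain = fx(lines, 22, 22),
    x = as.numeric(fx(lines, 31, 38)),
    y = as.numeric(fx(lines, 39, 46)),
    z = as.numeric(fx(lines, 47, 54)),
    record = trimws(fx(lines, 1, 6)),
    occupancy = {
      o <- suppressWarnings(as.numeric(fx(lines, 55, 60)))
      ifelse(is.na(o), 1, o)
    },
    altloc = fx(lines, 17, 17)
  ) %>% mutate(is_heavy = toupper(.data$element) != "H")
}

# AutoDock atom types: hydrogens are H/HD/HS; A is aromatic carbon; types
# like OA/NA/SA keep their first letter as the element.
autodock_type_to_element <- function(type, atom_name) {
  type <- toupper(type)
  el <- ifelse(type %in% c("H", "HD", "HS"), "H",
        ifelse(type == "A", "C",
        ifelse(type %in% c("OA", "NA", "SA", "N", "O", "S", "C", "P",
                           "F", "CL", "BR", "I", "ZN", "MG", "MN", "CA",
                           "FE"),
               sub("A$", "", type), NA_character_)))
  el <- ifelse(type %in% c("CL", "BR", "ZN", "MG", "MN", "CA", "FE"),
               type, el)
  fallback <- infer_element(rep(NA_character_, length(atom_name)), atom_name)
  ifelse(is.na(el) | el == "", fallback, el)
}

# Hydrogen/element detection: use the element column when present, otherwise
# the first alphabetic character of the atom name (many files in the wild
# omit element columns).
infer_element <- function(elesy, elety) {
  elesy <- as.character(elesy)
  elety <- as.character(elety)
  missing <- is.na(elesy) | trimws(elesy) == ""
  out <- trimws(elesy)
  first_alpha <- vapply(elety, function(nm) {
    ch <- regmatches(nm, regexpr("[A-Za-z]", nm))
    if (length(ch) == 0L) "X" else toupper(ch)
  }, character(1), USE.NAMES = FALSE)
  out[missing] <- first_alpha[missing]
  out
}

collapse_altlocs <- function(atoms) {
  if (!"altloc" %in% names(atoms) || all(atoms$altloc %in% c("", "A"))) {
    return(atoms)
  }
  atoms %>%
    group_by(.data$chain, .data$residue_number, .data$residue_name,
             .data$name) %>%
    slice_max(.data$occupancy, n = 1, with_ties = FALSE) %>%
    ungroup() %>%
    arrange(.data$serial)
}

#' Write a structure as a PDB file
#'
#' Emits standard fixed-column `ATOM`/`HETATM` records (coordinates at
#' 3-decimal precision, the PDB record resolution).
#'
#' @param structure A `structure_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(structure, path) {
  stopifnot(inherits(structure, "structure_model"))
  a <- structure
  name4 <- ifelse(nchar(a$name) < 4, paste0(" ", a$name), a$name)
  name4 <- formatC(name4, width = -4)
  lines <- sprintf(
    "%-6s%5d %-4s%1s%-4s%1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    ifelse(a$record %in% "HETATM", "HETATM", "ATOM"),
    a$serial %% 100000L, name4, "", substr(a$residue_name, 1, 4),
    substr(paste0(a$chain, " "), 1, 1), a$residue_number %% 10000L, "",
    a$x, a$y, a$z, a$occupancy, 0, substr(a$element, 1, 2))
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Select the heavy (non-hydrogen) atoms of a structure
#'
#' @param structure A `structure_model`.
#' @return A `structure_model` containing only heavy atoms, order preserved.
#' @export
heavy_atoms <- function(structure) {
  stopifnot(inherits(structure, "structure_model"))
  out <- structure[structure$is_heavy, , drop = FALSE]
  attributes(out)$id <- attr(structure, "id")
  attributes(out)$source_format <- attr(structure, "source_format")
  class(out) <- class(structure)
  out
}

coords_matrix <- function(structure) {
  cbind(x = structure$x, y = structure$y, z = structure$z)
}

#' Heavy-atom RMSD between two ligand poses
#'
#' Root-mean-square deviation over heavy atoms with positional
#' correspondence (the i-th heavy atom of one pose is matched to the i-th of
#' the other). No superposition is applied: poses are assumed to share the
#' receptor coordinate frame, as in re-docking against a fixed receptor.
#'
#' @param pose_a,pose_b `structure_model` objects with the same number of
#'   heavy atoms.
#' @return RMSD in Angstroms (non-negative scalar).
#' @export
pose_rmsd <- function(pose_a, pose_b) {
  ha <- heavy_atoms(pose_a)
  hb <- heavy_atoms(pose_b)
  if (nrow(ha) != nrow(hb)) {
    abort(sprintf(
      "Heavy-atom counts differ (%d vs %d): no positional correspondence",
      nrow(ha), nrow(hb)))
  }
  if (nrow(ha) == 0L) abort("Poses contain no heavy atoms")
  d <- coords_matrix(ha) - coords_matrix(hb)
  sqrt(mean(rowSums(d^2)))
}

#' Read a generic residue-number map
#'
#' The map is a whitespace- or tab-separated key-value file with columns
#' `chain`, `residue_number`, `label`, where labels follow the class B GPCR
#' generic numbering pattern `"<helix>.<position>"` (e.g. `"6.41"`). Within a
#' chain each label may be used once.
#'
#' @param path Path to the map file. Lines starting with `#` are comments.
#' @return A tibble with columns `chain`, `residue_number`, `label`.
#' @export
read_generic_number_map <- function(path) {
  raw <- readLines(path, warn = FALSE)
  raw <- trimws(raw)
  raw <- raw[raw != "" & !startsWith(raw, "#")]
  parts <- strsplit(raw, "[[:space:]]+")
  bad <- lengths(parts) != 3L
  if (any(bad)) {
    abort(paste0("Malformed map line(s): ", paste(raw[bad], collapse = "; ")))
  }
  map <- tibble(
    chain = vapply(parts, `[[`, "", 1),
    residue_number = as.integer(vapply(parts, `[[`, "", 2)),
    label = vapply(parts, `[[`, "", 3)
  )
  validate_generic_map(map)
}

validate_generic_map <- function(map) {
  map <- as_tibble(map)
  stopifnot(all(c("chain", "residue_number", "label") %in% names(map)))
  ok <- grepl("^[0-9]+\\.[0-9]+$", map$label)
  if (!all(ok)) {
    abort(paste0("Generic labels must match '<digits>.<digits>'; offending: ",
                 paste(unique(map$label[!ok]), collapse = ", ")))
  }
  dup <- map %>% dplyr::count(.data$chain, .data$label) %>% filter(n > 1)
  if (nrow(dup) > 0) {
    abort(paste0("Duplicate generic label within a chain: ",
                 paste(unique(dup$label), collapse = ", ")))
  }
  dup2 <- map %>% dplyr::count(.data$chain, .data$residue_number) %>%
    filter(n > 1)
  if (nrow(dup2) > 0) {
    abort("A residue may carry at most one generic label")
  }
  map
}

#' Attach generic residue numbers to a structure
#'
#' Adds a `generic_number` column mapping `(chain, residue_number)` pairs to
#' labels such as `"6.41"`. Unmapped residues get `NA`; the structure is
#' otherwise unchanged.
#'
#' @param structure A `structure_model`.
#' @param map A tibble with columns `chain`, `residue_number`, `label` (see
#'   [read_generic_number_map()]), or an empty tibble / `NULL` for no-op.
#' @return The structure with a `generic_number` column.
#' @export
assign_generic_numbers <- function(structure, map) {
  stopifnot(inherits(structure, "structure_model"))
  id <- attr(structure, "id"); fmt <- attr(structure, "source_format")
  if (is.null(map) || nrow(map) == 0L) {
    out <- structure
    if (!"generic_number" %in% names(out)) out$generic_number <- NA_character_
    return(new_structure_model(out, id = id, source_format = fmt))
  }
  map <- validate_generic_map(map)
  out <- as_tibble(structure) %>%
    select(-dplyr::any_of("generic_number")) %>%
    left_join(map %>% rename(generic_number = "label"),
              by = c("chain", "residue_number"))
  new_structure_model(out, id = id, source_format = fmt)
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("<structure_model> id=%s format=%s atoms=%d heavy=%d\n",
              attr(x, "id"), attr(x, "source_format"),
              nrow(x), sum(x$is_heavy)))
  NextMethod()
}
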