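# Adapter around an external AutoDock-VINA-compatible docking executable:
# box configuration, invocation, score parsing, best-receptor selection.
# No docking engine is implemented here; everything downstream consumes
# score tables, so the suite runs against a stub executable.

#' Docking box specification
#'
#' A per-receptor, per-site axis-aligned search box in the receptor frame.
#'
#' @param receptor_id Receptor model identifier.
#' @param site `"orthosteric"` or `"allosteric"`.
#' @param center Numeric length-3 box center, Angstroms.
#' @param size Numeric length-3 box edge lengths, Angstroms (all > 0).
#' @return A `box_spec` list.
#' @export
box_spec <- function(receptor_id, site, center, size) {
  site <- match.arg(site, binding_sites())
  stopifnot(is.numeric(center), length(center) == 3L,
            is.numeric(size), length(size) == 3L)
  if (any(size <= 0)) abort("All box size components must be positive")
  structure(list(receptor_id = receptor_id, site = site,
                 center = as.numeric(center), size = as.numeric(size)),
            class = "box_spec")
}

#' @export
print.box_spec <- function(x, ...) {
  cat(sprintf("<box_spec> %s/%s center=(%.2f, %.2f, %.2f) size=(%.2f, %.2f, %.2f) A\n",
              x$receptor_id, x$site, x$center[1], x$center[2], x$center[3],
              x$size[1], x$size[2], x$size[3]))
  invisible(x)
}

#' Parse scores from AutoDock-VINA-style output text
#'
#' Extracts the score of every `REMARK VINA RESULT: <score> <rmsd_lb>
#' <rmsd_ub>` line, in file order.
#'
#' @param output_text Character vector of lines, or a single string with
#'   embedded newlines.
#' @return Numeric vector of scores (kcal/mol, lower = stronger).
#' @export
parse_scores <- function(output_text) {
  lines <- unlist(strsplit(output_text, "\n", fixed = TRUE))
  hit <- grep("^REMARK VINA RESULT", lines)
  if (length(hit) == 0L) {
    abort("No 'REMARK VINA RESULT' lines found in engine output")
  }
  vals <- numeric(length(hit))
  for (i in seq_along(hit)) {
    ln <- lines[hit[i]]
    m <- regmatches(ln, regexec(
      "^REMARK VINA RESULT:\\s+(-?[0-9.]+)\\s+(-?[0-9.]+)\\s+(-?[0-9.]+)", ln))[[1]]
    if (length(m) != 4L || is.na(suppressWarnings(as.numeric(m[2])))) {
      abort(sprintf("Malformed VINA result line %d: '%s'", hit[i], ln))
    }
    vals[i] <- as.numeric(m[2])
  }
  vals
}

#' Run an external VINA-compatible docking engine
#'
#' Invokes `executable` with the conventional flag set (`--receptor`,
#' `--ligand`, `--center_x/y/z`, `--size_x/y/z`, `--out`, optionally
#' `--seed`), captures its log, and parses the multi-pose PDBQT output into
#' a `docking_result`. Poses are re-sorted by score if the engine emitted
#' them out of order, so the result invariant (non-decreasing scores, ranks
#' contiguous from 1) always holds.
#'
#' @param executable Path to the engine binary (or a stub script).
#' @param receptor_file,ligand_file Paths to PDBQT inputs.
#' @param box A [box_spec()].
#' @param seed Optional integer engine seed for deterministic runs.
#' @param out_file Where the engine writes poses (default: tempfile).
#' @param extra_args Additional command-line arguments.
#' @return A `docking_result`: list with `scores` (numeric, sorted),
#'   `ranks`, `poses` (list of `structure_model`, may be empty if the output
#'   carried no atoms), `log` (captured engine output) and `box`.
#' @export
run_docking <- function(executable, receptor_file, ligand_file, box,
                        seed = NULL, out_file = tempfile(fileext = ".pdbqt"),
                        extra_args = character()) {
  stopifnot(inherits(box, "box_spec"))
  if (!file.exists(executable) && Sys.which(executable) == "") {
    abort(paste0("Docking executable not found: ", executable))
  }
  for (f in c(receptor_file, ligand_file)) {
    if (!file.exists(f)) abort(paste0("Input file not found: ", f))
  }
  args <- c("--receptor", receptor_file, "--ligand", ligand_file,
            "--center_x", box$center[1], "--center_y", box$center[2],
            "--center_z", box$center[3],
            "--size_x", box$size[1], "--size_y", box$size[2],
            "--size_z", box$size[3],
            "--out", out_file)
  if (!is.null(seed)) args <- c(args, "--seed", as.integer(seed))
  args <- c(args, extra_args)
  log <- suppressWarnings(system2(executable, args = as.character(args),
                                  stdout = TRUE, stderr = TRUE))
  status <- attr(log, "status") %||% 0L
  if (status != 0L) {
    abort(paste0("Docking engine exited with status ", status, ":\n",
                 paste(log, collapse = "\n")))
  }
  if (!file.exists(out_file)) {
    abort("Docking engine produced no output file")
  }
  parse_docking_output(readLines(out_file, warn = FALSE), log = log,
                       box = box)
}

# Split a multi-MODEL PDBQT into poses; sort by score; build the result.
parse_docking_output <- function(lines, log = character(), box = NULL) {
  starts <- grep("^MODEL", lines)
  blocks <- if (length(starts) == 0L) list(lines) else {
    ends <- c(starts[-1] - 1L, length(lines))
    purrr::map2(starts, ends, function(s, e) lines[s:e])
  }
  scores <- vapply(blocks, function(b) parse_scores(b)[1], numeric(1))
  poses <- lapply(seq_along(blocks), function(i) {
    atoms <- parse_pdbqt_atoms(blocks[[i]])
    if (nrow(atoms) == 0L) return(NULL)
    new_structure_model(atoms, id = paste0("pose_", i),
                        source_format = "PDBQT")
  })
  ord <- order(scores)
  structure(list(scores = scores[ord],
                 ranks = seq_along(ord),
                 poses = poses[ord],
                 log = log, box = box),
            class = "docking_result")
}

#' @export
print.docking_result <- function(x, ...) {
  cat(sprintf("<docking_result> %d poses, best score %.2f kcal/mol\n",
              length(x$scores), x$scores[1]))
  invisible(x)
}

#' Pick the best receptor for a ligand from per-receptor scores
#'
#' Given each receptor's best docking score, returns the receptor with the
#' minimum (strongest) score together with the margin to the runner-up.
#' Equal minima are resolved alphabetically and flagged ambiguous.
#'
#' @param query_scores Named numeric vector (receptor -> best score), or a
#'   tibble with columns `receptor`, `score`; at least 2 receptors.
#' @return A one-row tibble: `receptor`, `score`, `runner_up`, `margin`,
#'   `ambiguous`.
#' @export
best_receptor <- function(query_scores) {
  if (is.data.frame(query_scores)) {
    stopifnot(all(c("receptor", "score") %in% names(query_scores)))
    query_scores <- setNames(query_scores$score, query_scores$receptor)
  }
  if (length(query_scores) < 2L) {
    abort("Need scores for at least 2 receptors")
  }
  ord <- order(query_scores, names(query_scores))
  s <- query_scores[ord]
  tibble(receptor = names(s)[1], score = unname(s[1]),
         runner_up = names(s)[2], margin = unname(s[2] - s[1]),
         ambiguous = unname(s[2] == s[1]))
}

#' Read or write a long-format docking score table
#'
#' Tab-separated with columns `drug`, `receptor`, `site`, `replicate`,
#' `score` (the adapter's on-disk exchange format).
#'
#' @param path File path.
#' @return `read_score_table()`: a tibble; `write_score_table()`: `path`,
#'   invisibly.
#' @export
read_score_table <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    drug = readr::col_character(), receptor = readr::col_character(),
    site = readr::col_character(), replicate = readr::col_integer(),
    score = readr::col_double()))
}

#' @rdname read_score_table
#' @param scores Tibble with the table columns.
#' @export
write_score_table <- function(scores, path) {
  validate_score_matrix(scores)
  if (!"replicate" %in% names(scores)) scores$replicate <- 1L
  readr::write_tsv(scores[, c("drug", "receptor", "site", "replicate",
                              "score")], path)
  invisible(path)
}
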