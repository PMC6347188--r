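# Ligand-density occupancy grid over a binding pocket and steric-intrusion
# scoring of receptor models.

#' Build a ligand-density grid over a binding site
#'
#' Lays a regular Cartesian grid over the axis-aligned bounding box of all
#' ligand heavy atoms (expanded by `padding` on every side) and counts, per
#' cell, the ligand heavy atoms whose coordinates fall in that cell. Every
#' atom carries the same weight, so the per-cell count is the ligand density
#' accumulated over the pose ensemble. Poses must already share one
#' coordinate frame; no superposition is performed.
#'
#' Cells are half-open boxes `[origin + i*s, origin + (i+1)*s)` per axis, so
#' every point maps to exactly one cell; atoms landing exactly on the upper
#' grid boundary are binned into the last cell so that no atom is lost.
#'
#' @param ligand_poses A `structure_model` or a list of them (e.g. a
#'   superposed ensemble of endogenous-peptide poses).
#' @param spacing Grid spacing in Angstroms (default 1).
#' @param padding Extra margin added around the ligand bounding box in
#'   Angstroms (default 2, so that a shell of empty cells exists in-bounds).
#' @return A `density_grid`: list with `origin` (Å), `spacing` (Å), `dims`
#'   (3 integers), `counts` (3-D integer array) and `n_ligand_atoms_binned`.
#' @export
build_density_grid <- function(ligand_poses, spacing = 1, padding = 2) {
  if (inherits(ligand_poses, "structure_model")) {
    ligand_poses <- list(ligand_poses)
  }
  if (length(ligand_poses) == 0L) abort("At least one ligand pose is required")
  if (!is.numeric(spacing) || length(spacing) != 1L || spacing <= 0) {
    abort("`spacing` must be a positive scalar (Angstroms)")
  }
  if (padding < 0) abort("`padding` must be non-negative")

  xyz <- do.call(rbind, lapply(ligand_poses, function(p) {
    coords_matrix(heavy_atoms(p))
  }))
  if (nrow(xyz) == 0L) abort("Ligand poses contain no heavy atoms")

  origin <- apply(xyz, 2, min) - padding
  upper <- apply(xyz, 2, max) + padding
  dims <- pmax(1L, as.integer(ceiling((upper - origin) / spacing - 1e-9)))

  idx <- bin_indices(xyz, origin, spacing, dims, clamp_upper = TRUE)
  lin <- linear_index(idx, dims)
  counts <- array(0L, dim = dims)
  tab <- tabulate(lin, nbins = prod(dims))
  counts[] <- as.integer(tab)

  structure(
    list(origin = unname(origin), spacing = spacing, dims = dims,
         counts = counts, n_ligand_atoms_binned = nrow(xyz)),
    class = "density_grid")
}

# 1-based cell indices per axis; rows outside the grid get NA unless clamped.
bin_indices <- function(xyz, origin, spacing, dims, clamp_upper = FALSE) {
  idx <- floor(sweep(xyz, 2, origin) / spacing) + 1
  storage.mode(idx) <- "integer"
  for (k in 1:3) {
    if (clamp_upper) {
      # atoms exactly on the upper boundary belong to the last cell
      at_edge <- idx[, k] == dims[k] + 1L &
        abs((xyz[, k] - origin[k]) / spacing - dims[k]) < 1e-9
      idx[at_edge, k] <- dims[k]
    }
    idx[idx[, k] < 1L | idx[, k] > dims[k], k] <- NA_integer_
  }
  idx
}

linear_index <- function(idx, dims) {
  idx[, 1] + dims[1] * (idx[, 2] - 1L) + dims[1] * dims[2] * (idx[, 3] - 1L)
}

#' @export
print.density_grid <- function(x, ...) {
  cat(sprintf(
    "<density_grid> dims=%s spacing=%.3g A, %d atoms binned, %d occupied cells\n",
    paste(x$dims, collapse = "x"), x$spacing,
    x$n_ligand_atoms_binned, sum(x$counts > 0)))
  invisible(x)
}

neighbor_offsets <- function(connectivity = 26) {
  g <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  g <- g[!(g$dx == 0 & g$dy == 0 & g$dz == 0), ]
  cheb <- pmax(abs(g$dx), abs(g$dy), abs(g$dz))
  manh <- abs(g$dx) + abs(g$dy) + abs(g$dz)
  keep <- switch(as.character(connectivity),
                 "6" = manh == 1,
                 "18" = manh <= 2 & cheb == 1,
                 "26" = cheb == 1,
                 abort("`connectivity` must be one of 6, 18, 26"))
  as.matrix(g[keep, , drop = FALSE])
}

#' Partition a density grid into core and shell regions
#'
#' The core is the set of cells with nonzero ligand density (the space the
#' endogenous peptide actually occupies). The shell is the set of zero-count
#' cells adjacent to at least one core cell — a one-cell-thick surface around
#' the occupied space, relevant when screening small-molecule ligands rather
#' than peptides.
#'
#' @param grid A `density_grid`.
#' @param connectivity Neighborhood used for the shell: 6 (faces), 18
#'   (faces+edges) or 26 (faces+edges+corners, the default).
#' @return A list with elements `core` and `shell`, each a `grid_region`
#'   (integer cell-index matrix with attributes `kind` and `dims`).
#' @export
grid_regions <- function(grid, connectivity = 26) {
  stopifnot(inherits(grid, "density_grid"))
  core_idx <- which(grid$counts > 0, arr.ind = TRUE)
  colnames(core_idx) <- c("i", "j", "k")
  dims <- grid$dims
  if (nrow(core_idx) == 0L) {
    empty <- matrix(integer(0), ncol = 3,
                    dimnames = list(NULL, c("i", "j", "k")))
    return(list(core = new_grid_region(empty, "core", dims, connectivity),
                shell = new_grid_region(empty, "shell", dims, connectivity)))
  }
  off <- neighbor_offsets(connectivity)
  nb <- do.call(rbind, lapply(seq_len(nrow(off)), function(r) {
    sweep(core_idx, 2, -off[r, ])
  }))
  inb <- nb[, 1] >= 1 & nb[, 1] <= dims[1] &
         nb[, 2] >= 1 & nb[, 2] <= dims[2] &
         nb[, 3] >= 1 & nb[, 3] <= dims[3]
  nb <- nb[inb, , drop = FALSE]
  lin <- unique(linear_index(nb, dims))
  core_lin <- linear_index(core_idx, dims)
  shell_lin <- setdiff(lin, core_lin)
  shell_idx <- arr_index(shell_lin, dims)
  list(core = new_grid_region(core_idx, "core", dims, connectivity),
       shell = new_grid_region(shell_idx, "shell", dims, connectivity))
}

arr_index <- function(lin, dims) {
  lin0 <- lin - 1L
  i <- lin0 %% dims[1] + 1L
  j <- (lin0 %/% dims[1]) %% dims[2] + 1L
  k <- lin0 %/% (dims[1] * dims[2]) + 1L
  m <- cbind(i = i, j = j, k = k)
  storage.mode(m) <- "integer"
  m
}

new_grid_region <- function(cells, kind, dims, connectivity) {
  structure(cells, kind = kind, dims = dims, connectivity = connectivity,
            class = c("grid_region", "matrix", "array"))
}

#' @export
print.grid_region <- function(x, ...) {
  cat(sprintf("<grid_region> kind=%s cells=%d (grid %s)\n",
              attr(x, "kind"), nrow(x),
              paste(attr(x, "dims"), collapse = "x")))
  invisible(x)
}

#' Steric-intrusion score of a receptor model
#'
#' Counts the region cells (by default the nonzero-density core) that contain
#' at least one receptor heavy-atom center. A high score flags receptor
#' models whose extracellular loops collapse into the peptide-occupied
#' orthosteric pocket. Cells are counted, not atoms: a cell covered by three
#' receptor atoms contributes 1.
#'
#' @param grid A `density_grid`.
#' @param receptor A `structure_model` of the receptor (TMD and loops).
#' @param region A `grid_region` from [grid_regions()] on the same grid;
#'   defaults to the core region.
#' @return A one-row tibble with `model_id`, `score` and `n_region_cells`
#'   (class `steric_score`).
#' @export
steric_score <- function(grid, receptor, region = NULL) {
  stopifnot(inherits(grid, "density_grid"),
            inherits(receptor, "structure_model"))
  if (is.null(region)) region <- grid_regions(grid)$core
  if (!inherits(region, "grid_region") ||
      !identical(as.integer(attr(region, "dims")), as.integer(grid$dims))) {
    abort("`region` was not derived from this grid (dimension mismatch)")
  }
  if (nrow(receptor) == 0L) abort("Receptor structure is empty")
  xyz <- coords_matrix(heavy_atoms(receptor))
  idx <- bin_indices(xyz, grid$origin, grid$spacing, grid$dims)
  idx <- idx[stats::complete.cases(idx), , drop = FALSE]
  occupied <- unique(linear_index(idx, grid$dims))
  region_lin <- if (nrow(region) == 0L) integer(0) else {
    linear_index(region, grid$dims)
  }
  score <- length(intersect(region_lin, occupied))
  out <- tibble(model_id = attr(receptor, "id") %||% NA_character_,
                score = as.integer(score),
                n_region_cells = nrow(region))
  class(out) <- c("steric_score", class(out))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Score a collection of receptor models against one density grid
#'
#' @param grid A `density_grid`.
#' @param receptors A list of `structure_model` receptors.
#' @param region Optional `grid_region`; defaults to the core.
#' @return A tibble with one row per model: `model_id`, `steric`,
#'   `n_region_cells`.
#' @export
steric_scores <- function(grid, receptors, region = NULL) {
  if (inherits(receptors, "structure_model")) receptors <- list(receptors)
  if (is.null(region)) region <- grid_regions(grid)$core
  purrr::map_dfr(receptors, function(r) {
    s <- steric_score(grid, r, region)
    tibble(model_id = s$model_id, steric = s$score,
           n_region_cells = s$n_region_cells)
  })
}

#' Derive a docking box from a density grid
#'
#' Centers the box on the centroid of the occupied (core) cell centers and
#' sizes it to the core bounding box plus a margin on every side — a
#' convenient way to produce per-site docking boxes from a ligand-pose
#' ensemble.
#'
#' @param grid A `density_grid` with at least one occupied cell.
#' @param margin Margin added per side, Angstroms (default 2).
#' @param receptor_id,site Passed through to the resulting [box_spec()].
#' @return A `box_spec`.
#' @export
derive_box <- function(grid, margin = 2, receptor_id = "receptor",
                       site = "orthosteric") {
  stopifnot(inherits(grid, "density_grid"))
  core <- grid_regions(grid)$core
  if (nrow(core) == 0L) abort("Grid has no occupied cells; cannot derive a box")
  centers <- sweep((core - 0.5) * grid$spacing, 2, grid$origin, `+`)
  center <- colMeans(centers)
  extent <- apply(centers, 2, max) - apply(centers, 2, min)
  size <- extent + grid$spacing + 2 * margin
  box_spec(receptor_id = receptor_id, site = site,
           center = unname(center), size = unname(size))
}
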