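# Seeded synthetic-data generators. Every stage of the pipeline is testable
# against constructions with known ground truth: a toy pocket/receptor
# complex with a planted steric score, score libraries with planted
# enrichment, and drug-by-receptor score matrices with a planted rank-score
# correlation.

make_structure <- function(xyz, id, elements = NULL, record = "ATOM",
                           residue_name = "LIG", chain = "A") {
  n <- nrow(xyz)
  if (is.null(elements)) elements <- rep("C", n)
  new_structure_model(tibble(
    serial = seq_len(n),
    name = paste0(elements, seq_len(n) %% 100),
    element = elements,
    residue_name = residue_name,
    residue_number = rep(1L, n),
    chain = chain,
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    record = record, occupancy = 1, altloc = "",
    is_heavy = toupper(elements) != "H"
  ), id = id, source_format = "PDB")
}

#' Generate a toy binding-pocket complex with a planted steric score
#'
#' Emulates a superposed ensemble of peptide poses occupying a binding
#' pocket plus a receptor model with controlled pocket intrusion: pose atoms
#' are Gaussian clouds around the pocket center; receptor atoms sit on a
#' sphere well outside the ligand grid, except for exactly
#' `receptor_intrusion` atoms placed into distinct occupied (nonzero-density)
#' grid cells. The true steric score of the generated receptor against the
#' generated grid therefore equals `receptor_intrusion` by construction.
#'
#' @param n_poses Number of ligand poses (default 5).
#' @param n_atoms_per_pose Atoms per pose (default 30; roughly every fifth
#'   is a hydrogen so heavy-atom selection is exercised).
#' @param pocket_center Pocket center, Angstroms (default origin).
#' @param pocket_radius Pocket radius, Angstroms (default 6); pose atoms are
#'   drawn with standard deviation `pocket_radius / 2` per axis.
#' @param receptor_intrusion Number of receptor atoms planted inside
#'   occupied grid cells (default 0).
#' @param n_receptor_atoms Total receptor atoms (default 120).
#' @param spacing,padding Grid parameters used for the planted construction
#'   (defaults 1 and 2 Angstroms).
#' @param seed Mandatory integer seed; the generator is a pure function of
#'   its arguments.
#' @return A list: `poses` (list of `structure_model`), `receptor`
#'   (`structure_model`), `grid` (the `density_grid` the construction used)
#'   and `true_score` (= `receptor_intrusion`).
#' @export
gen_toy_complex <- function(n_poses = 5, n_atoms_per_pose = 30,
                            pocket_center = c(0, 0, 0), pocket_radius = 6,
                            receptor_intrusion = 0, n_receptor_atoms = 120,
                            spacing = 1, padding = 2, seed) {
  stopifnot(n_poses >= 1, n_atoms_per_pose >= 1, pocket_radius > 0,
            receptor_intrusion >= 0, n_receptor_atoms >= receptor_intrusion)
  if (missing(seed)) abort("`seed` is mandatory for synthetic generation")
  withr::with_seed(seed, {
    poses <- lapply(seq_len(n_poses), function(p) {
      xyz <- matrix(rnorm(3 * n_atoms_per_pose, sd = pocket_radius / 2),
                    ncol = 3, byrow = TRUE)
      xyz <- sweep(xyz, 2, pocket_center, `+`)
      el <- ifelse(seq_len(n_atoms_per_pose) %% 5 == 0, "H", "C")
      make_structure(xyz, id = sprintf("pose_%02d", p), elements = el)
    })
    grid <- build_density_grid(poses, spacing = spacing, padding = padding)
    core <- grid_regions(grid)$core
    if (receptor_intrusion > nrow(core)) {
      abort(sprintf(
        "receptor_intrusion (%d) exceeds the %d occupied grid cells",
        receptor_intrusion, nrow(core)))
    }
    # intruding atoms: centers of distinct occupied cells
    pick <- if (receptor_intrusion > 0) {
      core[sample.int(nrow(core), receptor_intrusion), , drop = FALSE]
    } else {
      core[integer(0), , drop = FALSE]
    }
    intrude <- sweep((pick - 0.5) * grid$spacing, 2, grid$origin, `+`)
    # remaining atoms: sphere strictly outside the grid bounding box
    n_out <- n_receptor_atoms - receptor_intrusion
    r_out <- max(abs(c(grid$origin - pocket_center,
                       grid$origin + grid$dims * grid$spacing -
                         pocket_center))) + 3
    dir <- matrix(rnorm(3 * n_out), ncol = 3)
    dir <- dir / sqrt(rowSums(dir^2))
    outer_xyz <- sweep(dir * r_out, 2, pocket_center, `+`)
    rec_xyz <- rbind(as.matrix(intrude), outer_xyz)
    receptor <- make_structure(rec_xyz, id = "receptor",
                               elements = rep("C", nrow(rec_xyz)),
                               residue_name = "ALA", chain = "R")
    list(poses = poses, receptor = receptor, grid = grid,
         true_score = as.integer(receptor_intrusion))
  })
}

#' Generate a scored library with planted enrichment
#'
#' Emulates an active/decoy virtual-screening score list: active scores are
#' drawn from `N(-separation * sigma, sigma)` and decoy scores from
#' `N(0, sigma)` with lower = better, so `separation` is the active/decoy
#' mean gap in noise units. Defaults mirror a screening set of 10 known
#' actives against 500 property-matched decoys (50 per active).
#'
#' @param n_actives Number of actives (default 10).
#' @param n_decoys Number of decoys (default 500).
#' @param separation Mean score gap in units of `sigma` (default 2).
#' @param sigma Score noise standard deviation (default 1).
#' @param seed Mandatory integer seed.
#' @return A tibble `compound_id`, `score`, `is_active` of `n_actives +
#'   n_decoys` rows (lower score = better).
#' @export
gen_scored_library <- function(n_actives = 10, n_decoys = 500,
                               separation = 2, sigma = 1, seed) {
  stopifnot(n_actives >= 1, n_decoys >= 1, sigma > 0)
  if (missing(seed)) abort("`seed` is mandatory for synthetic generation")
  withr::with_seed(seed, {
    tibble(
      compound_id = c(sprintf("act_%03d", seq_len(n_actives)),
                      sprintf("dec_%03d", seq_len(n_decoys))),
      score = c(rnorm(n_actives, mean = -separation * sigma, sd = sigma),
                rnorm(n_decoys, mean = 0, sd = sigma)),
      is_active = rep(c(TRUE, FALSE), c(n_actives, n_decoys)))
  })
}

# Expected sample Pearson r for y = c*z + e (fixed standardized design z of
# size n, unit Gaussian noise), via nested quadrature over the normal score
# component and the chi-square residual component.
expected_pearson_fixed_design <- function(cc, n) {
  mu <- cc * sqrt(n)
  df <- n - 2
  f_outer <- function(t) {
    vapply(t, function(ti) {
      u <- mu + ti
      inner <- integrate(function(w) u / sqrt(u^2 + w) * dchisq(w, df),
                         0, Inf, rel.tol = 1e-9)$value
      inner * dnorm(ti)
    }, numeric(1))
  }
  integrate(f_outer, -Inf, Inf, rel.tol = 1e-8)$value
}

# Signal-to-noise c such that E[sample pearson r] equals rho at size n.
# Memoized: the root-find involves nested quadrature and is reused across
# replicate matrices.
.calibration_cache <- new.env(parent = emptyenv())
calibrate_signal <- function(rho, n) {
  if (abs(rho) < 1e-12) return(0)
  s <- sign(rho); rho <- abs(rho)
  if (rho >= 0.9999) return(s * Inf)
  key <- sprintf("%.12g_%d", rho, as.integer(n))
  if (!is.null(.calibration_cache[[key]])) return(s * .calibration_cache[[key]])
  root <- uniroot(function(cc) expected_pearson_fixed_design(cc, n) - rho,
                  interval = c(1e-8, 200), tol = 1e-9)$root
  .calibration_cache[[key]] <- root
  s * root
}

#' Generate a drug-by-receptor score matrix with planted rank correlation
#'
#' Emulates the reference-drug docking table: for every (receptor, site)
#' pair, scores are linear in the clinical rank plus Gaussian noise, with
#' the signal-to-noise ratio calibrated (by numerical integration over the
#' fixed rank design) so that the expected sample Pearson coefficient
#' between rank and score equals `rho`. Clinical ranks are 1..`n_drugs`.
#'
#' @param n_drugs Number of ranked drugs (default 5).
#' @param rho Target expected Pearson correlation, |rho| <= 1 (default 0.9).
#' @param base_score Mean score level, kcal/mol (default -8).
#' @param spread Score scale in kcal/mol (default 0.8).
#' @param n_replicates Replicate docking runs per key (default 1; replicates
#'   redraw the noise, not the planted signal).
#' @param receptors,sites Key sets (defaults [gut_receptors()],
#'   [binding_sites()]).
#' @param drugs Drug names (default `drug_1` ... `drug_n`).
#' @param seed Mandatory integer seed.
#' @return A list: `scores` (tibble `drug`, `receptor`, `site`, `replicate`,
#'   `score`) and `ranks` (tibble `drug`, `rank`).
#' @export
gen_score_matrix <- function(n_drugs = 5, rho = 0.9, base_score = -8,
                             spread = 0.8, n_replicates = 1,
                             receptors = gut_receptors(),
                             sites = binding_sites(), drugs = NULL, seed) {
  stopifnot(n_drugs >= 3, abs(rho) <= 1, spread > 0, n_replicates >= 1)
  if (missing(seed)) abort("`seed` is mandatory for synthetic generation")
  if (is.null(drugs)) drugs <- sprintf("drug_%d", seq_len(n_drugs))
  stopifnot(length(drugs) == n_drugs)
  rk <- seq_len(n_drugs)
  z <- (rk - mean(rk)) / sqrt((n_drugs^2 - 1) / 12)
  cc <- calibrate_signal(rho, n_drugs)
  noiseless <- is.infinite(cc)
  withr::with_seed(seed, {
    grid <- tidyr::expand_grid(receptor = receptors, site = sites,
                               replicate = seq_len(n_replicates))
    scores <- purrr::pmap_dfr(grid, function(receptor, site, replicate) {
      y <- if (noiseless) sign(cc) * z else cc * z + rnorm(n_drugs)
      yn <- if (noiseless) y else y / sqrt(cc^2 + 1)
      tibble(drug = drugs, receptor = receptor, site = site,
             replicate = as.integer(replicate),
             score = base_score + spread * yn)
    })
    list(scores = scores, ranks = tibble(drug = drugs, rank = rk))
  })
}
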