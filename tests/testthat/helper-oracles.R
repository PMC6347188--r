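# Independent brute-force oracles and small fixture builders. These are kept
# deliberately naive (triple loops, pairwise enumeration, direct formulas on
# explicitly computed ranks) so they cannot share a defect with the
# vectorized implementations they check.

# --- structures ------------------------------------------------------------

toy_structure <- function(xyz, elements = NULL, id = "toy") {
  n <- nrow(xyz)
  if (is.null(elements)) elements <- rep("C", n)
  tb <- tibble::tibble(
    serial = seq_len(n), name = paste0(elements, seq_len(n)),
    element = elements, residue_name = "LIG", residue_number = 1L,
    chain = "A", x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    record = "ATOM", occupancy = 1, altloc = "",
    is_heavy = toupper(elements) != "H")
  dockscreen:::new_structure_model(tb, id = id, source_format = "PDB")
}

write_mini_pdb <- function(path, xyz, elements = rep("C", nrow(xyz)),
                           record = "ATOM") {
  lines <- sprintf(
    "%-6s%5d  %-3s LIG A   1    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
    record, seq_len(nrow(xyz)), paste0(elements, seq_len(nrow(xyz))),
    xyz[, 1], xyz[, 2], xyz[, 3], elements)
  writeLines(c(lines, "END"), path)
  path
}

# --- steric grid -----------------------------------------------------------

# cell membership by explicit half-open interval comparison per axis
oracle_cell_of <- function(p, origin, spacing, dims) {
  idx <- integer(3)
  for (k in 1:3) {
    found <- NA_integer_
    for (i in seq_len(dims[k])) {
      lo <- origin[k] + (i - 1) * spacing
      hi <- origin[k] + i * spacing
      on_upper_edge <- i == dims[k] && abs(p[k] - hi) < 1e-9
      if ((p[k] >= lo && p[k] < hi) || on_upper_edge) { found <- i; break }
    }
    if (is.na(found)) return(NULL)
    idx[k] <- found
  }
  idx
}

oracle_grid_counts <- function(xyz, origin, spacing, dims) {
  counts <- array(0L, dim = dims)
  for (r in seq_len(nrow(xyz))) {
    idx <- oracle_cell_of(xyz[r, ], origin, spacing, dims)
    if (!is.null(idx)) counts[idx[1], idx[2], idx[3]] <-
        counts[idx[1], idx[2], idx[3]] + 1L
  }
  counts
}

oracle_regions <- function(counts, connectivity = 26) {
  dims <- dim(counts)
  core <- list(); shell <- list()
  for (i in seq_len(dims[1])) for (j in seq_len(dims[2]))
    for (k in seq_len(dims[3])) {
      if (counts[i, j, k] > 0) {
        core[[length(core) + 1]] <- c(i, j, k)
      } else {
        touches <- FALSE
        for (di in -1:1) for (dj in -1:1) for (dk in -1:1) {
          if (di == 0 && dj == 0 && dk == 0) next
          manh <- abs(di) + abs(dj) + abs(dk)
          if (connectivity == 6 && manh != 1) next
          if (connectivity == 18 && manh > 2) next
          ii <- i + di; jj <- j + dj; kk <- k + dk
          if (ii >= 1 && ii <= dims[1] && jj >= 1 && jj <= dims[2] &&
              kk >= 1 && kk <= dims[3] && counts[ii, jj, kk] > 0) {
            touches <- TRUE
          }
        }
        if (touches) shell[[length(shell) + 1]] <- c(i, j, k)
      }
    }
  list(core = do.call(rbind, core), shell = do.call(rbind, shell))
}

oracle_steric_score <- function(region_cells, receptor_xyz, origin, spacing,
                                dims) {
  if (is.null(region_cells) || nrow(region_cells) == 0L) return(0L)
  hits <- 0L
  for (r in seq_len(nrow(region_cells))) {
    cell <- region_cells[r, ]
    covered <- FALSE
    for (a in seq_len(nrow(receptor_xyz))) {
      idx <- oracle_cell_of(receptor_xyz[a, ], origin, spacing, dims)
      if (!is.null(idx) && all(idx == cell)) { covered <- TRUE; break }
    }
    if (covered) hits <- hits + 1L
  }
  hits
}

sort_cells <- function(m) {
  if (is.null(m) || nrow(m) == 0L) {
    return(matrix(integer(0), ncol = 3))
  }
  m <- unname(as.matrix(m))
  m[order(m[, 1], m[, 2], m[, 3]), , drop = FALSE]
}

# --- enrichment metrics ----------------------------------------------------

# EF by explicit sort (score ascending = better for lower_better), ties by id
oracle_ef <- function(lib, fraction) {
  N <- nrow(lib); A <- sum(lib$is_active)
  n <- max(1, floor(fraction * N))
  ord <- order(lib$score, lib$compound_id)
  a <- sum(lib$is_active[ord][seq_len(n)])
  (a / n) / (A / N)
}

# AUC by pairwise enumeration over all active-decoy pairs, ties = 1/2
oracle_auc <- function(lib) {
  act <- lib$score[lib$is_active]
  dec <- lib$score[!lib$is_active]
  tot <- 0
  for (sa in act) for (sd_ in dec) {
    tot <- tot + (if (sa < sd_) 1 else if (sa == sd_) 0.5 else 0)
  }
  tot / (length(act) * length(dec))
}

# BEDROC from ranks computed by explicit counting (average ties), lower
# score = better
oracle_bedroc <- function(lib, alpha = 20) {
  N <- nrow(lib); A <- sum(lib$is_active); Ra <- A / N
  ranks <- vapply(seq_len(N), function(i) {
    better <- sum(lib$score < lib$score[i])
    tied <- sum(lib$score == lib$score[i])
    better + (1 + tied) / 2
  }, numeric(1))
  s <- sum(exp(-alpha * ranks[lib$is_active] / N))
  rie <- s / (Ra * (1 - exp(-alpha)) / (exp(alpha / N) - 1))
  rie * Ra * sinh(alpha / 2) /
    (cosh(alpha / 2) - cosh(alpha / 2 - alpha * Ra)) +
    1 / (1 - exp(alpha * (1 - Ra)))
}

# random library with occasional score ties and guaranteed 0 < A < N
random_library <- function(n_max = 100) {
  N <- sample(5:n_max, 1)
  A <- sample(seq_len(N - 1), 1)
  score <- if (runif(1) < 0.4) {
    sample(round(rnorm(N), 1), N, replace = TRUE)  # coarse: forces ties
  } else {
    rnorm(N)
  }
  tibble::tibble(
    compound_id = sprintf("c%04d", seq_len(N)),
    score = score,
    is_active = sample(rep(c(TRUE, FALSE), c(A, N - A))))
}

# --- docking stub ----------------------------------------------------------

# stub engine: validates flag count, copies a canned output to --out
make_stub_engine <- function(canned_output,
                             path = tempfile(fileext = ".sh"),
                             unsorted = FALSE) {
  script <- c(
    "#!/bin/sh",
    'out=""',
    'while [ $# -gt 0 ]; do',
    '  if [ "$1" = "--out" ]; then out="$2"; shift; fi',
    "  shift",
    "done",
    'if [ -z "$out" ]; then echo "no --out flag" >&2; exit 2; fi',
    paste0('cp "', canned_output, '" "$out"'),
    'echo "stub engine done"')
  writeLines(script, path)
  Sys.chmod(path, "0755")
  path
}

canned_vina_output <- function() {
  system.file("extdata", "synthetic_vina_output_9mode.pdbqt",
              package = "dockscreen", mustWork = TRUE)
}
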