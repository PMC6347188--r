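# Model-ensemble bookkeeping: steric-hindrance filtering and
# cluster-representative selection. Cluster labels and knowledge-based
# energies are inputs (produced upstream by clustering / scoring tools);
# only the selection logic lives here.

validate_model_records <- function(models, need_energy = FALSE,
                                   need_cluster = FALSE) {
  models <- as_tibble(models)
  if (nrow(models) == 0L) abort("Empty model ensemble")
  if (!all(c("model_id", "steric") %in% names(models)) && !need_energy) {
    abort("Model records need `model_id` and `steric` columns")
  }
  if (anyDuplicated(models$model_id)) abort("Duplicate model_id values")
  if (need_energy) {
    if (!"energy" %in% names(models) || !all(is.finite(models$energy))) {
      abort("Every model needs a finite `energy`")
    }
  }
  if (need_cluster && (!"cluster" %in% names(models) ||
                       anyNA(models$cluster))) {
    abort("Every model needs a `cluster` label")
  }
  models
}

#' Retain the least sterically intruding fraction of a model ensemble
#'
#' Keeps the `floor(keep_fraction * N)` models with the lowest steric
#' scores — the models whose loops intrude least into the ligand-occupied
#' pocket — and discards the rest. Ties at the cutoff are broken by
#' `model_id` in lexicographic order so reruns are deterministic. The
#' retained models keep their original row order.
#'
#' @param models A tibble of model records with columns `model_id` and
#'   `steric` (integer steric-intrusion score; see [steric_score()]).
#' @param keep_fraction Fraction in (0, 1] of models to retain (default 0.5,
#'   i.e. half the ensemble is discarded).
#' @return The retained subset of `models`, original order preserved.
#' @export
filter_by_steric <- function(models, keep_fraction = 0.5) {
  models <- validate_model_records(models)
  if (!is.numeric(keep_fraction) || keep_fraction <= 0 || keep_fraction > 1) {
    abort("`keep_fraction` must be in (0, 1]")
  }
  n_keep <- floor(keep_fraction * nrow(models))
  if (n_keep == 0L) abort("keep_fraction retains zero models")
  ord <- order(models$steric, models$model_id)
  keep_ids <- models$model_id[ord[seq_len(n_keep)]]
  models[models$model_id %in% keep_ids, , drop = FALSE]
}

#' Select per-cluster lowest-energy representatives
#'
#' Identifies the `k` largest clusters by member count and returns, from
#' each, its single lowest-energy member — the "best model from each of the
#' k largest clusters" rule used to pick ensemble representatives for
#' virtual screening. Cluster-size ties are broken toward the cluster with
#' the lower mean energy, then by label; energy ties within a cluster by
#' `model_id`.
#'
#' @param models A tibble with columns `model_id`, `energy` (knowledge-based
#'   potential, lower = better) and `cluster` (integer label).
#' @param k Number of representatives (default 5).
#' @return A tibble of `k` rows (fewer, with a warning, if the ensemble has
#'   fewer than `k` clusters), ordered by cluster size rank, with an added
#'   `cluster_size` column.
#' @export
select_representatives <- function(models, k = 5) {
  models <- validate_model_records(models, need_energy = TRUE,
                                   need_cluster = TRUE)
  stopifnot(is.numeric(k), k >= 1)
  sizes <- models %>%
    group_by(.data$cluster) %>%
    summarise(cluster_size = dplyr::n(),
              mean_energy = mean(.data$energy), .groups = "drop") %>%
    arrange(dplyr::desc(.data$cluster_size), .data$mean_energy,
            .data$cluster)
  if (nrow(sizes) < k) {
    warn(sprintf("Only %d clusters available; returning %d representatives",
                 nrow(sizes), nrow(sizes)))
  }
  top <- head(sizes, k)
  models %>%
    filter(.data$cluster %in% top$cluster) %>%
    group_by(.data$cluster) %>%
    arrange(.data$energy, .data$model_id, .by_group = TRUE) %>%
    dplyr::slice(1) %>%
    ungroup() %>%
    left_join(top, by = "cluster") %>%
    arrange(dplyr::desc(.data$cluster_size), .data$mean_energy,
            .data$cluster) %>%
    select(-"mean_energy")
}
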