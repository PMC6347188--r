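# Off-target analysis: correlate per-receptor/per-site docking scores of
# drugs with a clinical risk ranking, combine both into one ranking, and
# place a query compound among precomputed references.

#' Class B gut-hormone receptor panel and binding sites
#'
#' The five secretin-family GPCRs screened for off-target interactions, and
#' the two binding sites considered per receptor (the orthosteric peptide
#' pocket and the allosteric TMH6/TMH7 site).
#'
#' @return Character vector of receptor (site) names.
#' @export
gut_receptors <- function() c("GCGR", "GIPR", "GLP1R", "VIPR1", "PAC1R")

#' @rdname gut_receptors
#' @export
binding_sites <- function() c("orthosteric", "allosteric")

#' Clinical T2DM-risk ranking of reference beta-blockers
#'
#' Integer ranking of five well-studied beta-blockers by their reported
#' propensity to disturb glucose homeostasis (rank 1 = least disturbing;
#' rank 0 = no clinical data yet, used for the recently discovered negative
#' allosteric modulator "compound 15"). Two published assignments exist that
#' swap nebivolol and carvedilol; both ship as fixtures:
#' `"figure"` (carvedilol = 1, nebivolol = 2; the default, used for the
#' published correlation analysis) and `"table"` (nebivolol = 1,
#' carvedilol = 2).
#'
#' @param assignment `"figure"` (default) or `"table"`.
#' @return A tibble with columns `drug` and `rank`.
#' @export
clinical_ranks <- function(assignment = c("figure", "table")) {
  assignment <- match.arg(assignment)
  path <- system.file("extdata",
                      sprintf("clinical_ranks_%s.tsv", assignment),
                      package = "dockscreen", mustWork = TRUE)
  readr::read_tsv(path, col_types = readr::cols(
    drug = readr::col_character(), rank = readr::col_integer()))
}

#' IUPAC name of the "compound 15" query beta-blocker
#' @return A string.
#' @export
compound15_name <- function() {
  paste0("4-((2S)-3-(((S)-3-(3-bromophenyl)-1-(methylamino)-1-oxopropan-2-",
         "yl)amino)-2-(2-cyclohexyl-2-phenylacetamido)-3-oxopropyl)benzamide")
}

validate_score_matrix <- function(scores, allow_replicates = TRUE) {
  scores <- as_tibble(scores)
  need <- c("drug", "receptor", "site", "score")
  if (!all(need %in% names(scores))) {
    abort(paste0("Score table needs columns: ", paste(need, collapse = ", ")))
  }
  if (!all(is.finite(scores$score))) abort("Docking scores must be finite")
  key <- scores %>% dplyr::count(.data$drug, .data$receptor, .data$site)
  if (!allow_replicates && any(key$n > 1)) {
    abort("Duplicated (drug, receptor, site) keys in score table")
  }
  scores
}

# Collapse replicates to one mean score per (drug, receptor, site).
mean_scores <- function(scores) {
  scores %>%
    group_by(.data$drug, .data$receptor, .data$site) %>%
    summarise(score = mean(.data$score), .groups = "drop")
}

#' Correlate docking scores with a clinical risk ranking
#'
#' For every (receptor, site) pair, computes the correlation between the
#' clinical rank (1 = least disturbing to glucose homeostasis) and the
#' docking score (more negative = stronger predicted binding) over the drugs
#' shared by both tables. Drugs with rank 0 (no clinical data) are excluded.
#' A strong positive coefficient means the least-risky drugs have the
#' strongest predicted off-target binding — the compensating-incretin-effect
#' signature.
#'
#' @param scores Tibble with columns `drug`, `receptor`, `site`, `score`
#'   (a `replicate` column, if present, is averaged out first).
#' @param ranks Tibble with columns `drug`, `rank` (see [clinical_ranks()]).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return An `offtarget_correlation` tibble: one row per (receptor, site)
#'   with `coefficient`, `n_drugs` and `method`.
#' @export
rank_score_correlation <- function(scores, ranks,
                                   method = c("pearson", "spearman")) {
  method <- match.arg(method)
  scores <- validate_score_matrix(scores) %>% mean_scores()
  ranks <- as_tibble(ranks)
  stopifnot(all(c("drug", "rank") %in% names(ranks)))
  joined <- scores %>%
    dplyr::inner_join(ranks, by = "drug") %>%
    filter(.data$rank > 0)
  if (nrow(joined) == 0L) abort("No ranked drugs shared between tables")
  sizes <- joined %>% dplyr::count(.data$receptor, .data$site)
  if (any(sizes$n < 3)) {
    abort("Fewer than 3 ranked drugs for at least one (receptor, site)")
  }
  out <- joined %>%
    group_by(.data$receptor, .data$site) %>%
    summarise(coefficient = cor(.data$rank, .data$score, method = method),
              n_drugs = dplyr::n(), .groups = "drop") %>%
    mutate(method = method)
  class(out) <- c("offtarget_correlation", class(out))
  out
}

#' @export
print.offtarget_correlation <- function(x, ...) {
  cat(sprintf("<offtarget_correlation> method=%s\n", x$method[1]))
  NextMethod()
}

#' @rdname rank_score_correlation
#' @param x,object An `offtarget_correlation`.
#' @param ... Unused.
#' @method tidy offtarget_correlation
#' @export
tidy.offtarget_correlation <- function(x, ...) as_tibble(x)

#' @rdname rank_score_correlation
#' @method glance offtarget_correlation
#' @export
glance.offtarget_correlation <- function(x, ...) {
  tibble(mean_coefficient = mean(x$coefficient),
         min_coefficient = min(x$coefficient),
         max_coefficient = max(x$coefficient),
         n_pairs = nrow(x), method = x$method[1])
}

#' Combine a clinical ranking with docking results for a query compound
#'
#' Reference drugs keep their clinical ordering; the query compound is
#' inserted by its mean docking score across all (receptor, site) keys. A
#' query that out-scores every reference is assigned rank 0 (the slot for a
#' compound with no clinical data that the docking places ahead of all
#' references); otherwise ranks are renumbered sequentially down the
#' combined list. Score ties are broken toward the reference.
#'
#' @param scores Reference score table (`drug`, `receptor`, `site`, `score`).
#' @param ranks Clinical ranking (`drug`, `rank`); rank-0 entries are
#'   ignored as references.
#' @param query One-compound score table (`receptor`, `site`, `score`),
#'   covering the same (receptor, site) keys as `scores`; or `NULL` to rank
#'   the references alone.
#' @param query_name Name used for the query row (default `"query"`).
#' @return A tibble `drug`, `combined_rank`, `mean_score`, `clinical_rank`,
#'   `is_query`, ordered by `combined_rank`.
#' @export
combined_ranking <- function(scores, ranks, query = NULL,
                             query_name = "query") {
  scores <- validate_score_matrix(scores) %>% mean_scores()
  ranks <- as_tibble(ranks) %>% filter(.data$rank > 0)
  refs <- scores %>%
    group_by(.data$drug) %>%
    summarise(mean_score = mean(.data$score), .groups = "drop") %>%
    dplyr::inner_join(ranks, by = "drug") %>%
    arrange(.data$rank, .data$mean_score, .data$drug)
  if (nrow(refs) == 0L) abort("No ranked reference drugs in the score table")

  if (is.null(query)) {
    return(tibble(drug = refs$drug,
                  combined_rank = seq_len(nrow(refs)),
                  mean_score = refs$mean_score,
                  clinical_rank = refs$rank,
                  is_query = FALSE))
  }
  query <- as_tibble(query)
  stopifnot(all(c("receptor", "site", "score") %in% names(query)))
  ref_keys <- scores %>% distinct(.data$receptor, .data$site)
  missing <- dplyr::anti_join(ref_keys, query, by = c("receptor", "site"))
  if (nrow(missing) > 0L) {
    abort(paste0("Query is missing (receptor, site) keys: ",
                 paste(paste(missing$receptor, missing$site, sep = "/"),
                       collapse = ", ")))
  }
  q_mean <- mean((query %>%
                    dplyr::semi_join(ref_keys,
                                     by = c("receptor", "site")))$score)
  # ties toward the reference: references at the same mean score stay ahead
  pos <- sum(refs$mean_score <= q_mean)
  drugs <- append(refs$drug, query_name, after = pos)
  means <- append(refs$mean_score, q_mean, after = pos)
  clin <- append(refs$rank, NA_integer_, after = pos)
  rank0 <- pos == 0L  # query beats every reference: reserved rank 0
  combined <- if (rank0) {
    c(0L, seq_len(nrow(refs)))
  } else {
    seq_len(nrow(refs) + 1L)
  }
  tibble(drug = drugs, combined_rank = combined, mean_score = means,
         clinical_rank = clin,
         is_query = drugs == query_name & is.na(clin))
}

#' Compare a query compound against precomputed reference scores
#'
#' Summarises, per (receptor, site), the reference drugs as mean docking
#' score (with the standard deviation across replicate runs as dispersion)
#' against their clinical rank, and the query compound as a rank-free
#' horizontal marker — the content of the web-service comparison plot,
#' emitted as plain tabular data.
#'
#' @param reference Score table with replicates: `drug`, `receptor`, `site`,
#'   `score` and optionally `replicate`.
#' @param query_scores Query replicate scores: `receptor`, `site`, `score`.
#' @param ranks Clinical ranking (default [clinical_ranks()]).
#' @param query_name Label for the query compound.
#' @return A `query_comparison` tibble: `receptor`, `site`, `drug`,
#'   `clinical_rank`, `mean_score`, `sd_score`, `n_replicates`, `is_query`.
#' @export
compare_query <- function(reference, query_scores,
                          ranks = clinical_ranks(), query_name = "query") {
  reference <- validate_score_matrix(reference)
  query_scores <- as_tibble(query_scores)
  stopifnot(all(c("receptor", "site", "score") %in% names(query_scores)))
  if (nrow(query_scores) == 0L) abort("Query has no replicate scores")

  summarize_block <- function(df, drug_col) {
    df %>%
      group_by(dplyr::across(dplyr::all_of(c("receptor", "site", drug_col)))) %>%
      summarise(mean_score = mean(.data$score),
                sd_score = if (dplyr::n() > 1) sd(.data$score) else 0,
                n_replicates = dplyr::n(), .groups = "drop")
  }
  ref <- reference %>%
    summarize_block("drug") %>%
    left_join(as_tibble(ranks), by = "drug") %>%
    rename(clinical_rank = "rank") %>%
    mutate(is_query = FALSE)
  qry <- query_scores %>%
    mutate(drug = query_name) %>%
    summarize_block("drug") %>%
    mutate(clinical_rank = NA_integer_, is_query = TRUE)
  out <- bind_rows(ref, qry) %>%
    select("receptor", "site", "drug", "clinical_rank", "mean_score",
           "sd_score", "n_replicates", "is_query") %>%
    arrange(.data$receptor, .data$site, .data$is_query, .data$clinical_rank)
  class(out) <- c("query_comparison", class(out))
  out
}

#' @rdname compare_query
#' @param object A `query_comparison`.
#' @param ... Unused.
#' @method autoplot query_comparison
#' @export
autoplot.query_comparison <- function(object, ...) {
  refs <- dplyr::filter(object, !.data$is_query, !is.na(.data$clinical_rank))
  qry <- dplyr::filter(object, .data$is_query)
  ggplot2::ggplot(refs, ggplot2::aes(x = .data$clinical_rank,
                                     y = .data$mean_score)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean_score - .data$sd_score,
                                        ymax = .data$mean_score + .data$sd_score),
                           width = 0.15, color = "grey50") +
    ggplot2::geom_step(color = "grey40") +
    ggplot2::geom_point(size = 2, color = "#2166ac") +
    ggplot2::geom_hline(data = qry,
                        ggplot2::aes(yintercept = .data$mean_score),
                        linetype = "dashed", color = "#b2182b") +
    ggplot2::facet_grid(site ~ receptor) +
    ggplot2::labs(x = "Clinical T2DM-risk rank (1 = least disturbing)",
                  y = "Docking score (kcal/mol, lower = stronger)",
                  title = "Query compound vs. reference beta-blockers") +
    ggplot2::theme_minimal()
}

#' @rdname rank_score_correlation
#' @method autoplot offtarget_correlation
#' @export
autoplot.offtarget_correlation <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$receptor, y = .data$coefficient,
                               fill = .data$site)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_hline(yintercept = 0, color = "grey30") +
    ggplot2::ylim(-1, 1) +
    ggplot2::labs(y = sprintf("%s correlation (clinical rank vs. score)",
                              object$method[1]),
                  x = NULL, fill = "site") +
    ggplot2::theme_minimal()
}
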