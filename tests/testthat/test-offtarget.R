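score_table <- function(drugs, scores_by_key) {
  # scores_by_key: function(receptor, site) -> numeric vector over drugs
  out <- tidyr::expand_grid(receptor = gut_receptors(),
                            site = binding_sites())
  purrr::pmap_dfr(out, function(receptor, site) {
    tibble::tibble(drug = drugs, receptor = receptor, site = site,
                   score = scores_by_key(receptor, site))
  })
}

test_that("perfectly linear scores give pearson 1 everywhere", {
  ranks <- tibble::tibble(drug = sprintf("d%d", 1:5), rank = 1:5)
  tbl <- score_table(ranks$drug, function(r, s) -10 + 0.5 * (1:5))
  res <- rank_score_correlation(tbl, ranks)
  expect_equal(nrow(res), 10L)
  expect_true(all(abs(res$coefficient - 1) < 1e-12))
  expect_true(all(res$n_drugs == 5L))
})

test_that("pearson matches a covariance/sigma-sigma oracle", {
  ranks <- tibble::tibble(drug = sprintf("d%d", 1:5), rank = 1:5)
  sc <- c(-9.0, -8.1, -8.4, -7.2, -7.0)
  tbl <- score_table(ranks$drug, function(r, s) sc)
  res <- rank_score_correlation(tbl, ranks)
  rk <- 1:5
  oracle <- sum((rk - mean(rk)) * (sc - mean(sc))) /
    sqrt(sum((rk - mean(rk))^2) * sum((sc - mean(sc))^2))
  expect_equal(unique(res$coefficient), oracle, tolerance = 1e-12)

  # spearman on the same data equals pearson of the score ranks
  res_s <- rank_score_correlation(tbl, ranks, method = "spearman")
  expect_equal(unique(res_s$coefficient), cor(rk, rank(sc)),
               tolerance = 1e-12)
})

test_that("rank-0 drugs are excluded and small overlaps error", {
  ranks <- tibble::tibble(drug = c("q", sprintf("d%d", 1:5)), rank = 0:5)
  tbl <- score_table(ranks$drug, function(r, s) rnorm(6))
  res <- rank_score_correlation(tbl, ranks)
  expect_true(all(res$n_drugs == 5L))  # "q" dropped

  tiny <- tibble::tibble(drug = c("a", "b"), rank = 1:2)
  tbl2 <- score_table(tiny$drug, function(r, s) rnorm(2))
  expect_error(rank_score_correlation(tbl2, tiny), "Fewer than 3")
})

test_that("correlation is invariant to affine (pearson) / monotone (spearman) transforms", {
  m <- gen_score_matrix(rho = 0.6, seed = 12)
  base <- rank_score_correlation(m$scores, m$ranks)
  aff <- m$scores
  aff$score <- 3 * aff$score + 7
  expect_equal(rank_score_correlation(aff, m$ranks)$coefficient,
               base$coefficient, tolerance = 1e-12)
  mono <- m$scores
  mono$score <- exp(mono$score)
  base_s <- rank_score_correlation(m$scores, m$ranks, method = "spearman")
  expect_equal(rank_score_correlation(mono, m$ranks,
                                      method = "spearman")$coefficient,
               base_s$coefficient, tolerance = 1e-12)
})

test_that("planted correlations are recovered in expectation (rho 0.3, 0.6)", {
  for (rho in c(0.3, 0.6)) {
    est <- vapply(1:120, function(i) {
      m <- gen_score_matrix(n_drugs = 5, rho = rho,
                            receptors = "GCGR", sites = "orthosteric",
                            seed = 5000 + i)
      rank_score_correlation(m$scores, m$ranks)$coefficient
    }, numeric(1))
    se <- stats::sd(est) / sqrt(length(est))
    expect_lt(abs(mean(est) - rho), 3 * se)
  }
})

test_that("combined ranking preserves clinical order and places the query by score", {
  m <- gen_score_matrix(rho = 0.9, seed = 8,
                        drugs = c("nebivolol", "carvedilol", "labetalol",
                                  "atenolol", "metoprolol"))
  ranks <- tibble::tibble(drug = m$ranks$drug, rank = 1:5)

  # restriction to references reproduces the clinical order exactly
  refs_only <- combined_ranking(m$scores, ranks)
  expect_equal(refs_only$drug, ranks$drug)
  expect_equal(refs_only$combined_rank, 1:5)

  # an out-scoring query with no clinical data takes rank 0
  keys <- dplyr::distinct(m$scores, receptor, site)
  best_query <- dplyr::mutate(keys, score = -20)
  cr <- combined_ranking(m$scores, ranks, best_query,
                         query_name = "compound 15")
  expect_equal(cr$combined_rank[cr$is_query], 0L)
  expect_equal(cr$drug[1], "compound 15")
  expect_equal(cr$drug[-1], ranks$drug)
  expect_equal(cr$combined_rank[-1], 1:5)

  # a query tied with an existing drug sits just behind it
  ref_means <- m$scores %>%
    dplyr::group_by(drug) %>%
    dplyr::summarise(ms = mean(score))
  tie_with <- ref_means$ms[ref_means$drug == "labetalol"]
  tied_query <- dplyr::mutate(keys, score = tie_with)
  cr2 <- combined_ranking(m$scores, ranks, tied_query)
  pos_ref <- which(cr2$drug == "labetalol")
  pos_q <- which(cr2$is_query)
  expect_equal(pos_q, pos_ref + 1L)
  expect_equal(cr2$combined_rank, 1:6)

  # missing keys are an input error
  expect_error(combined_ranking(m$scores, ranks, best_query[-1, ]),
               "missing")
})

test_that("query insertion matches an exhaustive placement oracle", {
  set.seed(661)
  for (i in 1:20) {
    m <- gen_score_matrix(rho = runif(1, -0.5, 0.95), seed = 700 + i)
    keys <- dplyr::distinct(m$scores, receptor, site)
    q <- dplyr::mutate(keys, score = rnorm(nrow(keys), -8, 1.5))
    cr <- combined_ranking(m$scores, m$ranks, q)
    q_mean <- mean(q$score)
    ref_means <- m$scores %>%
      dplyr::group_by(drug) %>%
      dplyr::summarise(ms = mean(score), .groups = "drop")
    n_better_or_tied <- sum(ref_means$ms <= q_mean)
    expect_equal(which(cr$is_query), n_better_or_tied + 1L)
  }
})

test_that("compare_query reports means and replicate dispersion per key", {
  m <- gen_score_matrix(rho = 0.9, n_replicates = 3, seed = 77)
  keys <- tidyr::expand_grid(receptor = gut_receptors(),
                             site = binding_sites())
  q <- purrr::pmap_dfr(keys, function(receptor, site) {
    tibble::tibble(receptor = receptor, site = site,
                   score = c(-8.0, -8.4, -8.2))
  })
  rep <- compare_query(m$scores, q, ranks = m$ranks)
  qrows <- dplyr::filter(rep, is_query)
  expect_equal(nrow(qrows), 10L)  # 5 receptors x 2 sites
  expect_equal(unique(qrows$mean_score), -8.2)
  expect_equal(unique(qrows$sd_score), sd(c(-8.0, -8.4, -8.2)))
  expect_equal(unique(qrows$n_replicates), 3L)

  # single replicate everywhere -> zero-width dispersion
  m1 <- gen_score_matrix(rho = 0.9, n_replicates = 1, seed = 78)
  q1 <- dplyr::mutate(keys, score = -8)
  rep1 <- compare_query(m1$scores, q1, ranks = m1$ranks)
  expect_true(all(rep1$sd_score == 0))

  # full key coverage for references too
  expect_equal(nrow(dplyr::distinct(rep, receptor, site)), 10L)
  p <- autoplot(rep)
  expect_s3_class(p, "ggplot")
})

test_that("both published clinical rank assignments ship and differ as documented", {
  fig <- clinical_ranks("figure")
  tab <- clinical_ranks("table")
  expect_equal(fig$rank[fig$drug == "carvedilol"], 1L)
  expect_equal(fig$rank[fig$drug == "nebivolol"], 2L)
  expect_equal(tab$rank[tab$drug == "nebivolol"], 1L)
  expect_equal(tab$rank[tab$drug == "carvedilol"], 2L)
  expect_equal(fig$rank[fig$drug == "compound 15"], 0L)
  # identical beyond the swapped pair
  expect_equal(fig$rank[fig$drug %in% c("labetalol", "atenolol", "metoprolol")],
               tab$rank[tab$drug %in% c("labetalol", "atenolol", "metoprolol")])
})
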