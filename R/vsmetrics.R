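# Virtual-screening enrichment metrics: EF at a fraction, ROC curve, AUC
# (Mann-Whitney, ties counted 1/2) and BEDROC (Truchon & Bayly early
# recognition metric).

validate_library <- function(lib) {
  lib <- as_tibble(lib)
  need <- c("compound_id", "score", "is_active")
  if (!all(need %in% names(lib))) {
    abort(paste0("A scored library needs columns: ",
                 paste(need, collapse = ", ")))
  }
  if (anyDuplicated(lib$compound_id)) abort("compound_id values must be unique")
  if (!all(is.finite(lib$score))) abort("Scores must be finite")
  A <- sum(lib$is_active)
  if (A == 0L || A == nrow(lib)) {
    abort("Enrichment metrics are undefined when all or none are active")
  }
  lib
}

# "Goodness" orientation: larger is better regardless of score direction.
goodness <- function(lib, score_direction) {
  score_direction <- match.arg(score_direction,
                               c("lower_better", "higher_better"))
  if (score_direction == "lower_better") -lib$score else lib$score
}

#' Enrichment factor at a fraction of a ranked library
#'
#' With `n = max(1, floor(fraction * N))` top-ranked compounds of which `a`
#' are active, the concentration-form enrichment factor is
#' `EF = (a/n) / (A/N)` — how much more concentrated actives are at the top
#' of the list than overall. The recall form `(a/A) / fraction` is available
#' via `convention`. Score ties at the cutoff are resolved by score order
#' then compound id, so results are deterministic.
#'
#' @param lib Tibble with columns `compound_id`, `score`, `is_active`.
#' @param fraction Fraction of the ranked list to inspect, in (0, 1].
#' @param score_direction `"lower_better"` (docking scores, default) or
#'   `"higher_better"`.
#' @param convention `"concentration"` (default) or `"recall"`.
#' @return The enrichment factor (scalar, >= 0; at most `N/A`).
#' @export
enrichment_factor <- function(lib, fraction,
                              score_direction = "lower_better",
                              convention = c("concentration", "recall")) {
  lib <- validate_library(lib)
  convention <- match.arg(convention)
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 1) {
    abort("`fraction` must be in (0, 1]")
  }
  g <- goodness(lib, score_direction)
  N <- nrow(lib); A <- sum(lib$is_active)
  n <- max(1L, floor(fraction * N))
  top <- order(-g, lib$compound_id)[seq_len(n)]
  a <- sum(lib$is_active[top])
  switch(convention,
         concentration = (a / n) / (A / N),
         recall = (a / A) / fraction)
}

#' ROC curve and AUC of an active/decoy score list
#'
#' The AUC is the probability that a randomly chosen active outranks a
#' randomly chosen decoy, with score ties counted 1/2 (the normalized
#' Mann-Whitney U statistic). ROC points traverse score thresholds from
#' strictest to loosest, grouping tied scores, so the trapezoidal area under
#' the returned points equals the AUC exactly.
#'
#' @inheritParams enrichment_factor
#' @return A list with `roc_points` (tibble of `fpr`, `tpr` from (0,0) to
#'   (1,1)) and `auc` (scalar in \[0, 1\]).
#' @export
roc_auc <- function(lib, score_direction = "lower_better") {
  lib <- validate_library(lib)
  g <- goodness(lib, score_direction)
  N <- nrow(lib); A <- sum(lib$is_active); D <- N - A
  r <- rank(g, ties.method = "average")  # larger rank = better
  u <- sum(r[lib$is_active]) - A * (A + 1) / 2
  auc <- u / (A * D)

  ord <- order(-g)
  gs <- g[ord]; act <- lib$is_active[ord]
  grp <- cumsum(!duplicated(gs))
  tp <- cumsum(act); fp <- cumsum(!act)
  last <- !duplicated(grp, fromLast = TRUE)  # last entry of each tie group
  roc <- tibble(fpr = c(0, fp[last] / D), tpr = c(0, tp[last] / A))
  list(roc_points = roc, auc = auc)
}

#' BEDROC early-recognition metric
#'
#' Boltzmann-enhanced discrimination of ROC (Truchon & Bayly). With
#' 1-based ranks `r_i` of the `A` actives in a list of `N`, `Ra = A/N` and
#' exponent `alpha`:
#' \deqn{RIE = \frac{\sum_i e^{-\alpha r_i/N}}{R_a \,
#'   \frac{1-e^{-\alpha}}{e^{\alpha/N}-1}}}
#' \deqn{BEDROC = RIE \cdot \frac{R_a \sinh(\alpha/2)}{\cosh(\alpha/2) -
#'   \cosh(\alpha/2 - \alpha R_a)} + \frac{1}{1 - e^{\alpha(1-R_a)}}}
#' Values lie in \[0, 1\]; `alpha = 20` (the default) concentrates weight on
#' roughly the first 8% of the list. Tied scores share their average rank.
#'
#' @inheritParams enrichment_factor
#' @param alpha Early-recognition exponent (> 0), default 20.
#' @return BEDROC value in \[0, 1\].
#' @export
bedroc <- function(lib, alpha = 20, score_direction = "lower_better") {
  lib <- validate_library(lib)
  stopifnot(is.numeric(alpha), alpha > 0)
  g <- goodness(lib, score_direction)
  N <- nrow(lib); A <- sum(lib$is_active); Ra <- A / N
  r <- N + 1 - rank(g, ties.method = "average")  # 1 = best
  rie <- sum(exp(-alpha * r[lib$is_active] / N)) /
    (Ra * (1 - exp(-alpha)) / (exp(alpha / N) - 1))
  rie * Ra * sinh(alpha / 2) /
    (cosh(alpha / 2) - cosh(alpha / 2 - alpha * Ra)) +
    1 / (1 - exp(alpha * (1 - Ra)))
}

#' Closed-form BEDROC of a perfectly front-loaded library
#'
#' The value [bedroc()] attains when all `A` actives precede all decoys,
#' useful as a reference maximum.
#'
#' @param n_total,n_active Library size and number of actives.
#' @param alpha Early-recognition exponent.
#' @return The maximal BEDROC for the given composition.
#' @export
bedroc_max <- function(n_total, n_active, alpha = 20) {
  N <- n_total; A <- n_active; Ra <- A / N
  rie <- sum(exp(-alpha * seq_len(A) / N)) /
    (Ra * (1 - exp(-alpha)) / (exp(alpha / N) - 1))
  rie * Ra * sinh(alpha / 2) /
    (cosh(alpha / 2) - cosh(alpha / 2 - alpha * Ra)) +
    1 / (1 - exp(alpha * (1 - Ra)))
}

#' Expected BEDROC of a random ranking
#'
#' Under a uniformly random permutation of the list the expected RIE is
#' exactly 1, so the expected BEDROC has a closed form; useful as the null
#' reference in calibration checks.
#'
#' @inheritParams bedroc_max
#' @return Expected BEDROC under random ranking.
#' @export
bedroc_random <- function(n_total, n_active, alpha = 20) {
  Ra <- n_active / n_total
  Ra * sinh(alpha / 2) / (cosh(alpha / 2) - cosh(alpha / 2 - alpha * Ra)) +
    1 / (1 - exp(alpha * (1 - Ra)))
}

#' Full enrichment report for a scored library
#'
#' Computes the standard virtual-screening evaluation panel in one pass:
#' BEDROC(alpha), AUC with the ROC curve, and enrichment factors at 1%, 5%
#' and 10% of the list.
#'
#' @inheritParams enrichment_factor
#' @param alpha BEDROC exponent (default 20).
#' @param fractions EF fractions (default `c(0.01, 0.05, 0.10)`).
#' @return An `enrichment_report`: list with a one-row `metrics` tibble
#'   (`bedroc`, `auc`, `ef1`, `ef5`, `ef10`, `n`, `n_active`, `alpha`) and
#'   the `roc_points` tibble. Has [tidy()], [glance()] and [autoplot()]
#'   methods.
#' @examples
#' lib <- gen_scored_library(separation = 2, seed = 7)
#' rep <- enrichment_report(lib)
#' glance(rep)
#' @export
enrichment_report <- function(lib, score_direction = "lower_better",
                              alpha = 20, fractions = c(0.01, 0.05, 0.10),
                              convention = "concentration") {
  lib <- validate_library(lib)
  stopifnot(length(fractions) == 3L)
  roc <- roc_auc(lib, score_direction)
  efs <- vapply(fractions, enrichment_factor, numeric(1), lib = lib,
                score_direction = score_direction, convention = convention)
  metrics <- tibble(
    bedroc = bedroc(lib, alpha, score_direction),
    auc = roc$auc,
    ef1 = efs[1], ef5 = efs[2], ef10 = efs[3],
    n = nrow(lib), n_active = sum(lib$is_active), alpha = alpha)
  structure(list(metrics = metrics, roc_points = roc$roc_points),
            class = "enrichment_report")
}

#' @export
print.enrichment_report <- function(x, ...) {
  m <- x$metrics
  cat(sprintf(
    "<enrichment_report> N=%d (A=%d)\n  BEDROC(alpha=%g)=%.3f AUC=%.3f EF1%%=%.3g EF5%%=%.3g EF10%%=%.3g\n",
    m$n, m$n_active, m$alpha, m$bedroc, m$auc, m$ef1, m$ef5, m$ef10))
  invisible(x)
}

#' @rdname enrichment_report
#' @param x An `enrichment_report`.
#' @param ... Unused.
#' @method tidy enrichment_report
#' @export
tidy.enrichment_report <- function(x, ...) {
  m <- x$metrics
  tibble(metric = c(sprintf("bedroc_alpha%g", m$alpha), "auc",
                    "ef1", "ef5", "ef10"),
         value = c(m$bedroc, m$auc, m$ef1, m$ef5, m$ef10))
}

#' @rdname enrichment_report
#' @method glance enrichment_report
#' @export
glance.enrichment_report <- function(x, ...) x$metrics

#' @rdname enrichment_report
#' @param object An `enrichment_report`.
#' @method autoplot enrichment_report
#' @export
autoplot.enrichment_report <- function(object, ...) {
  ggplot2::ggplot(object$roc_points,
                  ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         color = "grey60") +
    ggplot2::geom_path(linewidth = 0.8, color = "#2166ac") +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "False positive rate", y = "True positive rate",
      title = sprintf("ROC (AUC = %.3f, BEDROC = %.3f)",
                      object$metrics$auc, object$metrics$bedroc)) +
    ggplot2::theme_minimal()
}
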