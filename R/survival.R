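#' Split samples into high/low expression groups at the median
#'
#' Values strictly above the median are `high`; values at or below the
#' median are `low` (ties go to `low`). A constant vector yields all-`low`
#' with a warning.
#'
#' @param x Named numeric vector of per-sample expression values (>= 2).
#' @return Character vector of labels `high`/`low`, names preserved.
#' @export
median_split <- function(x) {
  if (length(x) < 2) stop("need at least 2 samples")
  med <- stats::median(x)
  out <- ifelse(x > med, "high", "low")
  if (all(out == "low")) warning("constant (or tie-dominated) expression; all samples labeled low")
  out
}

#' Kaplan-Meier product-limit survival estimate
#'
#' Standard product-limit estimator
#' `S(t) = prod over event times u <= t of (1 - d_u / n_u)`, fitted via the
#' survival package; the returned table keeps the ordered distinct event
#' times only (censoring times affect the at-risk counts but add no rows).
#'
#' @param time Nonnegative follow-up times.
#' @param event Event indicators (1 = event, 0 = censored).
#' @return Data.frame of class `km_fit`: time, n_risk, n_event, surv.
#'   Estimates start at 1, are non-increasing and lie in \[0,1\].
#' @export
km_estimate <- function(time, event) {
  if (!length(time)) stop("empty input")
  if (any(time < 0)) stop("times must be nonnegative")
  if (!all(event %in% c(0, 1))) stop("events must be 0/1")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  keep <- fit$n.event > 0
  out <- data.frame(time = fit$time[keep], n_risk = fit$n.risk[keep],
                    n_event = fit$n.event[keep], surv = fit$surv[keep])
  class(out) <- c("km_fit", class(out))
  out
}

#' Two-group log-rank test
#'
#' The standard 1-degree-of-freedom log-rank statistic
#' `(sum(O - E))^2 / V` pooled over event times, with a two-sided chi-square
#' p-value, fitted via the survival package.
#'
#' @param time Nonnegative follow-up times.
#' @param event Event indicators (1 = event, 0 = censored).
#' @param group Two-level grouping vector (e.g. from [median_split()]).
#' @return List: `statistic` (chi-square), `p_value`, `n` (per-group sizes).
#' @export
logrank_test <- function(time, event, group) {
  group <- as.factor(group)
  if (nlevels(droplevels(group)) != 2) stop("need exactly two nonempty groups")
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  stat <- unname(sd$chisq)
  list(statistic = stat,
       p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
       n = table(droplevels(group)))
}

#' Median-split survival analysis for one gene
#'
#' Convenience wrapper: splits the given samples at the gene's median
#' expression, fits per-group Kaplan-Meier curves and runs the log-rank
#' test.
#'
#' @param gene Gene id.
#' @param expr Expression matrix (genes x samples).
#' @param samples Sample table with `sample_id`, `time`, `event`.
#' @return List: gene, labels, fits (per-group `km_fit`), statistic,
#'   p_value.
#' @export
survival_by_expression <- function(gene, expr, samples) {
  if (!gene %in% rownames(expr)) stop("gene not in expression matrix: ", gene)
  ids <- intersect(samples$sample_id, colnames(expr))
  s <- samples[match(ids, samples$sample_id), ]
  labels <- median_split(expr[gene, ids])
  fits <- lapply(split(seq_along(ids), labels), function(i)
    km_estimate(s$time[i], s$event[i]))
  lr <- logrank_test(s$time, s$event, labels)
  list(gene = gene, labels = labels, fits = fits,
       statistic = lr$statistic, p_value = lr$p_value)
}
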