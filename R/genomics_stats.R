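#' @title Tumor-genomics alteration, enrichment and survival statistics
#' @name genomics_stats
#' @description
#' Statistics over binary sample-by-gene alteration matrices (alteration
#' frequencies, co-occurrence enrichment relative to an index gene with
#' Fisher tests and Benjamini-Hochberg correction), expression group
#' comparison (Wilcoxon rank-sum, median split), and survival analysis
#' (Kaplan-Meier curves, Mantel-Cox log-rank test with an O/E hazard
#' ratio). Standard machinery is delegated to `stats` and `survival`;
#' this module fixes the conventions (two-sided Fisher by point-probability
#' summation, log2 ratios of group percentages, median ties to the low
#' group) so printed-table semantics are reproducible.
NULL

#' Construct an alteration matrix
#'
#' @param calls binary matrix, samples in rows (rownames = sample ids),
#'   genes in columns.
#' @param cancer_type character/factor of per-sample cancer-type labels.
#' @return Object of class `alteration_matrix`.
#' @export
alteration_matrix <- function(calls, cancer_type) {
  calls <- as.matrix(calls)
  stopifnot(all(calls %in% c(0, 1)), length(cancer_type) == nrow(calls),
            !is.null(colnames(calls)))
  structure(list(calls = calls, cancer_type = as.character(cancer_type)),
            class = "alteration_matrix")
}

#' @export
print.alteration_matrix <- function(x, ...) {
  cat("<alteration_matrix>", nrow(x$calls), "samples x", ncol(x$calls),
      "genes,", length(unique(x$cancer_type)), "cancer types\n")
  invisible(x)
}

#' Alteration frequency of a gene
#'
#' @param m an [alteration_matrix()].
#' @param gene gene symbol.
#' @param by_cancer_type also report per-cancer-type percentages.
#' @return List with `altered` (count), `total`, `pct` (overall percentage
#'   rounded to the nearest integer) and, if requested, `by_type`
#'   (data.frame with per-type percentages to 2 decimals).
#' @export
alteration_frequency <- function(m, gene, by_cancer_type = FALSE) {
  stopifnot(inherits(m, "alteration_matrix"))
  if (!gene %in% colnames(m$calls)) stop("unknown gene: ", gene)
  v <- m$calls[, gene]
  out <- list(altered = sum(v), total = length(v),
              pct = round(100 * sum(v) / length(v)))
  if (by_cancer_type) {
    tab <- lapply(split(v, m$cancer_type), function(g)
      data.frame(n = length(g), altered = sum(g),
                 pct = round(100 * sum(g) / length(g), 2)))
    bt <- do.call(rbind, tab)
    bt <- cbind(cancer_type = rownames(bt), bt)
    rownames(bt) <- NULL
    out$by_type <- bt[order(-bt$pct), ]
  }
  out
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Two-sided p-value by summing hypergeometric point probabilities not
#' exceeding the observed table's probability (with a relative tolerance
#' of 1e-7), the convention of common implementations. The all-zero table
#' returns p = 1.
#'
#' @param a,b,c,d the 2x2 counts (row-wise).
#' @return Two-sided p-value.
#' @export
fisher_exact <- function(a, b, c, d) {
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0,
            a == round(a), b == round(b), c == round(c), d == round(d))
  if (a + b + c + d == 0) return(1)
  stats::fisher.test(matrix(c(a, c, b, d), 2))$p.value
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement;
#' each q lies in `[p, 1]`.
#'
#' @param pvals vector of p-values in `[0, 1]`.
#' @return Vector of q-values, same order as input.
#' @export
bh_fdr <- function(pvals) {
  stopifnot(all(pvals >= 0 & pvals <= 1, na.rm = TRUE))
  stats::p.adjust(pvals, method = "BH")
}

#' Co-occurrence enrichment relative to an index gene
#'
#' Samples are split by index-gene alteration status; every other gene is
#' tested for differential alteration frequency between the two groups.
#' The log ratio is `log2(altered-group pct / unaltered-group pct)`
#' computed from the group percentages (the printed-table convention),
#' reported to 2 decimals; genes altered in only one group get an
#' infinite log ratio and are flagged. p-values are two-sided Fisher,
#' q-values Benjamini-Hochberg across all tested genes.
#'
#' @param m an [alteration_matrix()].
#' @param index_gene the gene defining the split.
#' @return data.frame with one row per non-index gene: counts and
#'   percentages per group, `log_ratio`, `p`, `q`, `enriched_in`
#'   (`"altered"`/`"unaltered"`/`"neither"`) and `degenerate` (zero
#'   percentage in one group).
#' @export
cooccurrence_enrichment <- function(m, index_gene) {
  stopifnot(inherits(m, "alteration_matrix"))
  if (!index_gene %in% colnames(m$calls)) stop("unknown index gene: ", index_gene)
  idx <- m$calls[, index_gene] == 1
  if (!any(idx) || all(idx))
    stop("both index-altered and index-unaltered groups must be non-empty")
  genes <- setdiff(colnames(m$calls), index_gene)
  nA <- sum(idx); nU <- sum(!idx)
  rows <- lapply(genes, function(g) {
    aA <- sum(m$calls[idx, g]); aU <- sum(m$calls[!idx, g])
    pA <- 100 * aA / nA; pU <- 100 * aU / nU
    lr <- if (pA > 0 && pU > 0) round(log2(pA / pU), 2)
          else if (pA == 0 && pU == 0) 0
          else if (pU == 0) Inf else -Inf
    data.frame(gene = g,
               altered_count = aA, altered_pct = round(pA, 2),
               unaltered_count = aU, unaltered_pct = round(pU, 2),
               log_ratio = lr,
               p = fisher_exact(aA, nA - aA, aU, nU - aU),
               degenerate = xor(pA == 0, pU == 0))
  })
  d <- do.call(rbind, rows)
  d$q <- bh_fdr(d$p)
  d$enriched_in <- ifelse(d$log_ratio > 0, "altered",
                          ifelse(d$log_ratio < 0, "unaltered", "neither"))
  d[order(d$p), ]
}

#' Log ratio of two printed group percentages
#'
#' The printed-table semantics: `log2(altered pct / unaltered pct)` to
#' 2 decimals.
#'
#' @param altered_pct,unaltered_pct group percentages.
#' @return log2 ratio, 2 decimals.
#' @export
log_ratio_pct <- function(altered_pct, unaltered_pct) {
  round(log2(altered_pct / unaltered_pct), 2)
}

#' Wilcoxon rank-sum comparison of two groups
#'
#' Exact enumeration for small samples (combined n <= 12 and no ties),
#' otherwise the normal approximation with tie-corrected midranks.
#'
#' @param a,b numeric vectors.
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`.
#' @return List with `statistic` (rank-sum W for the first group) and `p`.
#' @export
wilcoxon_ranksum <- function(a, b, alternative = "two.sided") {
  stopifnot(length(a) >= 1, length(b) >= 1)
  exact <- (length(a) + length(b) <= 12) && !anyDuplicated(c(a, b))
  w <- suppressWarnings(
    stats::wilcox.test(a, b, alternative = alternative, exact = exact,
                       correct = !exact))
  list(statistic = unname(w$statistic), p = w$p.value)
}

#' Median split into high/low expression groups
#'
#' High = strictly above the median; samples tied at the median go to the
#' low group (deterministic and stated). A constant vector yields an empty
#' high group with a warning.
#'
#' @param expression named numeric vector, sample -> expression.
#' @return List with `high` and `low` (character vectors of sample names)
#'   and `threshold` (the median).
#' @export
median_split <- function(expression) {
  stopifnot(length(expression) >= 2, !is.null(names(expression)))
  med <- stats::median(expression)
  hi <- names(expression)[expression > med]
  if (!length(hi)) warning("degenerate median split: no sample above the median")
  list(high = hi, low = setdiff(names(expression), hi), threshold = med)
}

#' Kaplan-Meier product-limit curve
#'
#' @param time follow-up times (months, >= 0).
#' @param event 1 = event (death/progression), 0 = censored.
#' @return Object of class `km_fit`: event `times`, `n_risk`, `n_event`,
#'   `surv` (step-function survival probabilities) and `median` survival
#'   (NA when the curve never falls to 0.5).
#' @export
km_curve <- function(time, event) {
  stopifnot(length(time) >= 1, length(time) == length(event))
  if (any(time < 0)) stop("negative survival time")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  med <- unname(summary(fit)$table["median"])
  structure(list(times = fit$time, n_risk = fit$n.risk,
                 n_event = fit$n.event, surv = fit$surv, median = med),
            class = "km_fit")
}

#' @export
print.km_fit <- function(x, ...) {
  cat("<km_fit>", length(x$times), "time points; median survival:",
      if (is.na(x$median)) "not reached" else format(x$median), "\n")
  invisible(x)
}

#' Survival probability at given times
#'
#' @param fit a [km_curve()] result.
#' @param t times at which to evaluate the step function.
#' @return Survival probabilities (1 before the first event).
#' @export
km_surv_at <- function(fit, t) {
  vapply(t, function(ti) {
    i <- which(fit$times <= ti)
    if (!length(i)) 1 else fit$surv[max(i)]
  }, 1)
}

#' Mantel-Cox log-rank test with an O/E hazard ratio
#'
#' Chi-square (1 df) log-rank test between two groups, with the hazard
#' ratio estimated as `(OA/EA)/(OB/EB)` from observed and expected event
#' counts and a log-scale 95% CI `exp(log HR +/- 1.96 sqrt(1/EA + 1/EB))`.
#'
#' @param time,event survival data for all samples.
#' @param group two-level grouping (the first level in sort order is the
#'   numerator of the hazard ratio).
#' @return List with `chi2`, `p`, `hr`, `hr_ci` (length-2), `obs`, `exp`.
#' @export
logrank_test <- function(time, event, group) {
  stopifnot(length(unique(group)) == 2)
  if (sum(event) == 0) stop("no events in either group: log-rank undefined")
  group <- factor(group)
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  O <- sd$obs; E <- sd$exp
  hr <- (O[1] / E[1]) / (O[2] / E[2])
  se <- sqrt(1 / E[1] + 1 / E[2])
  list(chi2 = sd$chisq,
       p = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE),
       hr = unname(hr),
       hr_ci = unname(exp(log(hr) + c(-1.96, 1.96) * se)),
       obs = unname(O), exp = unname(E))
}

#' Read an alteration matrix from TSV
#'
#' Columns: `sample_id`, `cancer_type`, then one 0/1 column per gene.
#'
#' @param path TSV path.
#' @return An [alteration_matrix()].
#' @export
read_alteration_tsv <- function(path) {
  d <- utils::read.delim(path, check.names = FALSE)
  stopifnot(all(c("sample_id", "cancer_type") %in% names(d)))
  calls <- as.matrix(d[, setdiff(names(d), c("sample_id", "cancer_type")),
                       drop = FALSE])
  rownames(calls) <- d$sample_id
  alteration_matrix(calls, d$cancer_type)
}

#' Read survival records from TSV
#'
#' Columns: `sample_id`, `time_months`, `event`, `group`.
#'
#' @param path TSV path.
#' @return data.frame of survival records.
#' @export
read_survival_tsv <- function(path) {
  d <- utils::read.delim(path)
  stopifnot(all(c("sample_id", "time_months", "event", "group") %in% names(d)))
  d
}
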