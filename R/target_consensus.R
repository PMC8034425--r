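#' @title Multi-predictor target consensus
#' @name target_consensus
#' @description
#' Target-prediction web tools report incommensurable scores: Pa/Pi
#' activity probabilities, plain probabilities, or pharmacophore fit
#' scores with z-scores. This module normalizes entries to a within-
#' predictor ranking, computes Venn membership across predictors, and
#' aggregates by mean reciprocal rank into a consensus target list.
NULL

#' Comparable score for one predictor entry
#'
#' `pa_pi` entries score as `pa - pi`; `probability` entries as the
#' probability; `pharmacophore` entries as the normalized fit score
#' (the z-score is used only for tie-breaking downstream).
#'
#' @param e list or one-row data.frame with `score_kind` and the fields
#'   that kind requires (`pa`/`pi`, `probability`, or `fit_score`).
#' @return Numeric score, larger = stronger prediction.
#' @export
score_entry <- function(e) {
  kind <- match.arg(e$score_kind, c("pa_pi", "probability", "pharmacophore"))
  need <- function(f) {
    v <- e[[f]]
    if (is.null(v) || length(v) != 1 || is.na(v))
      stop("score_kind '", kind, "' requires field '", f, "'")
    v
  }
  switch(kind,
         pa_pi = {
           pa <- need("pa"); pi <- need("pi")
           stopifnot(pa >= 0, pa <= 1, pi >= 0, pi <= 1)
           pa - pi
         },
         probability = {
           p <- need("probability"); stopifnot(p >= 0, p <= 1); p
         },
         pharmacophore = need("fit_score"))
}

.clean_symbol <- function(x) toupper(trimws(x))

#' Venn membership of per-predictor target lists
#'
#' @param lists named list (one element per predictor) of gene-symbol
#'   character vectors. Symbols are uppercased and whitespace-trimmed; no
#'   alias resolution is attempted.
#' @return List with `membership` (named list: target -> character vector
#'   of predictors), `by_count` (targets grouped by number of predictors)
#'   and `subset_sizes` (named integer vector over non-empty predictor
#'   combinations; sums to the union size).
#' @export
venn_membership <- function(lists) {
  stopifnot(length(lists) >= 2, !is.null(names(lists)))
  lists <- lapply(lists, function(x) unique(.clean_symbol(x)))
  union_all <- sort(unique(unlist(lists)))
  membership <- lapply(union_all, function(g)
    names(lists)[vapply(lists, function(l) g %in% l, TRUE)])
  names(membership) <- union_all
  combo <- vapply(membership, function(p) paste(sort(p), collapse = "&"), "")
  subset_sizes <- table(combo)
  by_count <- split(union_all, lengths(membership))
  list(membership = membership,
       by_count = by_count,
       subset_sizes = stats::setNames(as.integer(subset_sizes),
                                      names(subset_sizes)))
}

#' Consensus ranking of predicted targets
#'
#' Within each predictor, entries are ranked by [score_entry()] descending
#' (average ranks on ties, pharmacophore z-score as tie-break where
#' present). Targets predicted by at least `min_predictors` predictors are
#' ordered by predictor count descending, then mean reciprocal rank
#' descending, then symbol.
#'
#' @param entries data.frame with columns `predictor`, `target`,
#'   `score_kind` and the score fields that kind requires.
#' @param min_predictors minimum number of predictors naming the target.
#' @return data.frame: target, n_predictors, consensus_score (mean
#'   reciprocal rank over the predictors that named it), and one
#'   `rank_<predictor>` column per predictor.
#' @export
consensus_rank <- function(entries, min_predictors = 1) {
  stopifnot(is.data.frame(entries),
            all(c("predictor", "target", "score_kind") %in% names(entries)))
  entries$target <- .clean_symbol(entries$target)
  entries$.score <- vapply(seq_len(nrow(entries)), function(i)
    score_entry(as.list(entries[i, ])), 1)
  entries$.tie <- if ("z" %in% names(entries))
    ifelse(is.na(entries$z), 0, entries$z) else 0
  preds <- sort(unique(entries$predictor))
  ranked <- do.call(rbind, lapply(preds, function(p) {
    d <- entries[entries$predictor == p, ]
    # average-rank ties on the primary score; z breaks exact ties first
    ord_score <- -(d$.score + d$.tie * 1e-9)
    d$.rank <- rank(ord_score, ties.method = "average")
    d[, c("predictor", "target", ".rank")]
  }))
  targets <- sort(unique(ranked$target))
  rows <- lapply(targets, function(g) {
    d <- ranked[ranked$target == g, ]
    out <- data.frame(target = g, n_predictors = nrow(d),
                      consensus_score = mean(1 / d$.rank))
    for (p in preds)
      out[[paste0("rank_", p)]] <-
        if (p %in% d$predictor) d$.rank[d$predictor == p] else NA_real_
    out
  })
  res <- do.call(rbind, rows)
  res <- res[res$n_predictors >= min_predictors, , drop = FALSE]
  res <- res[order(-res$n_predictors, -res$consensus_score, res$target), ,
             drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Read predictor output CSV files
#'
#' One CSV per predictor with columns `predictor`, `target`, `score_kind`
#' and the relevant score columns (`pa`, `pi`, `probability`,
#' `fit_score`, `z`).
#'
#' @param paths character vector of CSV paths.
#' @return Combined data.frame suitable for [consensus_rank()].
#' @export
read_predictor_csvs <- function(paths) {
  all_cols <- c("predictor", "target", "score_kind", "pa", "pi",
                "probability", "fit_score", "z")
  do.call(rbind, lapply(paths, function(p) {
    d <- utils::read.csv(p)
    for (col in setdiff(all_cols, names(d))) d[[col]] <- NA_real_
    d[, all_cols]
  }))
}
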