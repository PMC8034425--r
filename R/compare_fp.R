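#' @title COMPARE-style activity fingerprint correlation
#' @name compare_fp
#' @description
#' A compound's anticancer fingerprint is its vector of per-cell-line
#' potencies (-log10 of the molar endpoint concentration) at one endpoint
#' (GI50, TGI or LC50). Fingerprints of a seed compound are correlated
#' against a library by Pearson correlation over the common cell lines,
#' guarded by a minimum common-cell-line count (CCLC).
NULL

.fp_endpoints <- c("GI50", "TGI", "LC50")

#' Construct an activity fingerprint
#'
#' @param compound_id compound identifier.
#' @param endpoint one of `"GI50"`, `"TGI"`, `"LC50"`.
#' @param values named numeric vector, cell line -> potency
#'   (-log10 molar); `NA` marks missing cell lines.
#' @return Object of class `fingerprint`.
#' @export
fingerprint <- function(compound_id, endpoint, values) {
  endpoint <- match.arg(endpoint, .fp_endpoints)
  stopifnot(!is.null(names(values)), all(nzchar(names(values))))
  if (any(is.infinite(values), na.rm = TRUE))
    stop("fingerprint values must be finite where present")
  structure(list(compound_id = compound_id, endpoint = endpoint,
                 values = values), class = "fingerprint")
}

#' Fingerprint from a screen summary
#'
#' Converts one endpoint column of [summarize_screen()] output into a
#' potency fingerprint: `-log10(concentration in molar)`. Censored
#' endpoints become missing cells.
#'
#' @param params the `params` data.frame of a `screen_summary` (or the
#'   summary object itself).
#' @param endpoint `"GI50"`, `"TGI"` or `"LC50"`.
#' @param compound_id identifier for the screened compound.
#' @return A [fingerprint()].
#' @export
to_fingerprint <- function(params, endpoint, compound_id = "seed") {
  if (inherits(params, "screen_summary")) params <- params$params
  endpoint <- match.arg(endpoint, .fp_endpoints)
  col <- paste0(tolower(endpoint), "_uM")
  v <- -log10(params[[col]] * 1e-6)
  names(v) <- params$cell_line
  fingerprint(compound_id, endpoint, v)
}

#' Correlate two fingerprints (COMPARE step)
#'
#' Pearson correlation over the cell lines present in both fingerprints.
#' Too-small overlap or a constant restricted vector is a rejection, not
#' an error.
#'
#' @param seed,other [fingerprint()] objects on the same endpoint.
#' @param min_common minimum common-cell-line count (default 25, guarding
#'   against spuriously high correlations on tiny overlaps).
#' @return List with `compound_id`, `r`, `n_common`, or `NULL` when the
#'   pair is rejected.
#' @export
pairwise_correlation <- function(seed, other, min_common = 25) {
  stopifnot(inherits(seed, "fingerprint"), inherits(other, "fingerprint"))
  if (seed$endpoint != other$endpoint)
    stop("endpoint mismatch: ", seed$endpoint, " vs ", other$endpoint)
  common <- intersect(names(seed$values)[!is.na(seed$values)],
                      names(other$values)[!is.na(other$values)])
  if (length(common) < min_common) return(NULL)
  x <- seed$values[common]; y <- other$values[common]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NULL)
  list(compound_id = other$compound_id,
       r = stats::cor(x, y), n_common = length(common))
}

#' Rank a compound library against a seed fingerprint
#'
#' @param seed seed [fingerprint()].
#' @param library list of [fingerprint()] objects.
#' @param min_common minimum common-cell-line count.
#' @param top_k maximum number of rows returned.
#' @return data.frame (rank, compound_id, r, n_common) sorted by `r`
#'   descending, ties broken by `n_common` descending then compound id;
#'   zero rows when every pair is rejected.
#' @export
rank_library <- function(seed, library, min_common = 25, top_k = Inf) {
  stopifnot(length(library) >= 1)
  hits <- Filter(Negate(is.null),
                 lapply(library, pairwise_correlation, seed = seed,
                        min_common = min_common))
  if (!length(hits))
    return(data.frame(rank = integer(), compound_id = character(),
                      r = numeric(), n_common = integer()))
  d <- data.frame(compound_id = vapply(hits, `[[`, "", "compound_id"),
                  r = vapply(hits, `[[`, 1, "r"),
                  n_common = vapply(hits, `[[`, 1L, "n_common"))
  d <- d[order(-d$r, -d$n_common, d$compound_id), ]
  d <- utils::head(d, top_k)
  d <- cbind(rank = seq_len(nrow(d)), d)
  rownames(d) <- NULL
  d
}

#' Read a fingerprint library from a CSV matrix
#'
#' Rows are compounds (first column = compound id), columns are cell
#' lines; blank cells are missing.
#'
#' @param path CSV path.
#' @param endpoint endpoint label to attach to every fingerprint.
#' @return List of [fingerprint()] objects.
#' @export
read_fingerprint_csv <- function(path, endpoint = "GI50") {
  d <- utils::read.csv(path, check.names = FALSE)
  ids <- d[[1]]
  m <- as.matrix(d[, -1, drop = FALSE])
  lapply(seq_along(ids), function(i)
    fingerprint(as.character(ids[i]), endpoint,
                stats::setNames(as.numeric(m[i, ]), colnames(m))))
}
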