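#' @title PPI-graph summaries and gene-set enrichment
#' @name network_enrich
#' @description
#' Summary statistics of confidence-weighted protein-protein-interaction
#' graphs (node/edge counts, average degree, average local clustering
#' coefficient, hub nodes) and hypergeometric gene-set over-representation
#' with the STRING-style filtering rule (p below a cutoff, minimum overlap
#' count, minimum strength = log10 observed/expected).
NULL

#' Construct a PPI graph from an edge table
#'
#' @param edges data.frame with columns `gene_a`, `gene_b`, `confidence`
#'   (in `[0, 1]`). Self-edges and duplicate pairs are rejected.
#' @return An `igraph` undirected graph with a `confidence` edge attribute.
#' @export
ppi_graph <- function(edges) {
  stopifnot(all(c("gene_a", "gene_b", "confidence") %in% names(edges)))
  if (any(edges$confidence < 0 | edges$confidence > 1))
    stop("confidence must lie in [0, 1]")
  if (any(edges$gene_a == edges$gene_b)) stop("self-edges not allowed")
  key <- paste(pmin(edges$gene_a, edges$gene_b),
               pmax(edges$gene_a, edges$gene_b))
  if (anyDuplicated(key)) stop("duplicate edges not allowed")
  g <- igraph::graph_from_data_frame(
    edges[, c("gene_a", "gene_b")], directed = FALSE)
  igraph::E(g)$confidence <- edges$confidence
  g
}

#' Summarize a PPI graph
#'
#' Edges below `confidence_min` are dropped (nodes left isolated are
#' dropped with them). Average degree is `2E/N` rounded half-up to one
#' decimal; the average local clustering coefficient is the mean over
#' nodes of triangles through the node divided by `deg(deg-1)/2`, with 0
#' for nodes of degree < 2.
#'
#' @param g a [ppi_graph()].
#' @param confidence_min minimum edge confidence retained.
#' @return List: `n_nodes`, `n_edges`, `avg_degree`, `avg_local_clustering`.
#' @export
graph_summary <- function(g, confidence_min = 0) {
  g <- igraph::delete_edges(g, which(igraph::E(g)$confidence < confidence_min))
  g <- igraph::delete_vertices(g, which(igraph::degree(g) == 0))
  n <- igraph::vcount(g); e <- igraph::ecount(g)
  if (n == 0) stop("graph empty after confidence filtering")
  cl <- igraph::transitivity(g, type = "local", isolates = "zero")
  cl[igraph::degree(g) < 2] <- 0
  p <- 10
  list(n_nodes = n, n_edges = e,
       avg_degree = floor(2 * e / n * p + 0.5) / p,
       avg_local_clustering = mean(cl))
}

#' Top-k hub nodes by degree
#'
#' Degrees are computed in the full (confidence-filtered) graph; the
#' ranking can be restricted to a candidate gene list via `among` -- the
#' usual question is which of the query genes are hubs of their
#' interaction neighborhood, not which neighbor has most edges.
#'
#' @param g a [ppi_graph()].
#' @param k number of hubs (all nodes when `k` exceeds the node count).
#' @param among optional character vector restricting the ranking.
#' @param confidence_min minimum edge confidence retained.
#' @return data.frame (gene, degree) sorted by degree descending, ties
#'   alphabetical.
#' @export
hub_nodes <- function(g, k, among = NULL, confidence_min = 0) {
  stopifnot(k >= 1)
  g <- igraph::delete_edges(g, which(igraph::E(g)$confidence < confidence_min))
  deg <- igraph::degree(g)
  if (!is.null(among)) deg <- deg[names(deg) %in% among]
  d <- data.frame(gene = names(deg), degree = as.integer(deg))
  d <- d[order(-d$degree, d$gene), ]
  d <- utils::head(d, k)
  rownames(d) <- NULL
  d
}

#' Hypergeometric gene-set enrichment with filtering
#'
#' For each named set, the upper-tail hypergeometric p-value of the
#' query/set overlap against a background of `background_size` genes,
#' Benjamini-Hochberg q-values across all sets, and strength =
#' `log10(observed overlap / expected overlap)` where expected =
#' `|set| * |query| / background`. Rows failing any filter (p, overlap
#' count, strength) are dropped; thresholds are configurable.
#'
#' @param query character vector of query genes.
#' @param sets named list of gene sets.
#' @param background_size background gene universe size (must be at least
#'   as large as every set and the query).
#' @param p_max,min_count,min_strength the retention filters
#'   (defaults: 1e-5, 3, 2).
#' @return data.frame: set_name, set_size, overlap_count, expected, p, q,
#'   strength; only rows passing all filters, sorted by p.
#' @export
set_enrichment <- function(query, sets, background_size,
                           p_max = 1e-5, min_count = 3, min_strength = 2) {
  stopifnot(length(query) >= 1, length(sets) >= 1, !is.null(names(sets)))
  query <- unique(query)
  if (background_size < length(unique(unlist(sets))) ||
      background_size < length(query))
    stop("background_size smaller than the gene universe it must contain")
  n_q <- length(query)
  rows <- lapply(names(sets), function(nm) {
    s <- unique(sets[[nm]])
    k <- length(intersect(query, s))
    expected <- length(s) * n_q / background_size
    p <- stats::phyper(k - 1, length(s), background_size - length(s), n_q,
                       lower.tail = FALSE)
    data.frame(set_name = nm, set_size = length(s), overlap_count = k,
               expected = expected, p = p,
               strength = if (k > 0) log10(k / expected) else -Inf)
  })
  d <- do.call(rbind, rows)
  d$q <- bh_fdr(d$p)
  keep <- d$p < p_max & d$overlap_count >= min_count & d$strength >= min_strength
  d <- d[keep, , drop = FALSE]
  d <- d[order(d$p), ]
  rownames(d) <- NULL
  d
}

#' Read a PPI edge list from TSV
#'
#' Columns: `gene_a`, `gene_b`, `confidence`.
#'
#' @param path TSV path.
#' @return A [ppi_graph()].
#' @export
read_edges_tsv <- function(path) {
  ppi_graph(utils::read.delim(path))
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' then member genes.
#'
#' @param path GMT path.
#' @return Named list of gene-symbol vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) stop("malformed GMT line: ", substr(l, 1, 60))
    f[-(1:2)]
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], "")
  sets
}

#' Construct the packaged hub-structure demonstration network
#'
#' A synthetic 26-node, 176-edge interaction network built so that the six
#' candidate target genes carry the reported degrees of the second-order
#' clustering: MTOR 23, MAP2K1 14, EGFR 13, FGFR1 4, TGFB1 4, NOS2 1.
#' The true database edges are not published, so the remaining edges are
#' filled in deterministically (a circulant pattern) among the 20 partner
#' nodes; edge confidences are all 0.95.
#'
#' @return A [ppi_graph()].
#' @export
demo_ppi_network <- function() {
  cand <- c("MTOR", "MAP2K1", "EGFR", "FGFR1", "TGFB1", "NOS2")
  partners <- c("RPS6KB1", "RHEB", "LAMTOR1", "LAMTOR2", "LAMTOR4",
                "LAMTOR5", "EIF4EBP1", "MAPKAP1", "RICTOR", "RPTOR",
                "GRB2", "EGF", "BRAF", "AKT1", "PIK3CA", "PTEN",
                "KRAS", "HRAS", "MAPK1", "MAPK3")
  stopifnot(length(c(cand, partners)) == 26)
  ea <- character(0); eb <- character(0)
  add <- function(a, b) { ea <<- c(ea, a); eb <<- c(eb, b) }
  # candidate degrees: MTOR 23, MAP2K1 14, EGFR 13, FGFR1 4, TGFB1 4, NOS2 1
  add("MTOR", "MAP2K1"); add("MTOR", "EGFR"); add("MTOR", "FGFR1")
  add("MAP2K1", "EGFR")
  for (p in partners) add("MTOR", p)          # MTOR: 3 + 20 = 23
  for (p in partners[1:12]) add("MAP2K1", p)  # MAP2K1: 2 + 12 = 14
  for (p in partners[1:11]) add("EGFR", p)    # EGFR: 2 + 11 = 13
  for (p in partners[1:3]) add("FGFR1", p)    # FGFR1: 1 + 3 = 4
  for (p in partners[1:4]) add("TGFB1", p)    # TGFB1: 4
  add("NOS2", partners[1])                    # NOS2: 1
  # 55 edges so far; fill 121 partner-partner edges by circulant offsets
  n <- length(partners)
  for (off in 1:7) {
    for (i in seq_len(n)) {
      if (length(ea) >= 176) break
      add(partners[i], partners[(i - 1 + off) %% n + 1])
    }
    if (length(ea) >= 176) break
  }
  stopifnot(length(ea) == 176)
  ppi_graph(data.frame(gene_a = ea, gene_b = eb, confidence = 0.95))
}
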