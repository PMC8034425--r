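#' @title Molecular graphs from molfiles and formulas
#' @name molgraph
#' @description
#' A minimal molecular-graph layer sufficient for graph-derivable
#' drug-likeness descriptors: V2000 molfile/SDF input, Hill-notation formula
#' parsing, implicit-hydrogen assignment from default valences, ring
#' perception via a minimum cycle basis, and benzenoid aromaticity.
NULL

# Elements the graph layer knows about (organic subset + halogens).
.mg_elements <- c("C", "N", "O", "F", "S", "P", "Cl", "Br", "I", "H")

# Default valences used for implicit-H assignment.
.mg_valence <- c(C = 4, N = 3, O = 2, F = 1, S = 2, P = 3,
                 Cl = 1, Br = 1, I = 1, H = 1)

#' Construct a molecular graph
#'
#' @param atoms data.frame with columns `element` (symbol) and `charge`
#'   (integer formal charge; defaults to 0).
#' @param bonds data.frame with columns `a`, `b` (1-based atom indices) and
#'   `order` (1, 2 or 3). May have zero rows.
#' @param name molecule name.
#' @return An object of class `molgraph`: a list with `name`, `atoms`
#'   (element, charge, implicit_h, aromatic, in_ring) and `bonds`
#'   (a, b, order, in_ring). Derived columns are `NA`/`FALSE` until
#'   [assign_implicit_h()], [perceive_rings()] and [perceive_aromatic()]
#'   have been applied.
#' @export
molgraph <- function(atoms, bonds = NULL, name = "") {
  stopifnot(is.data.frame(atoms), "element" %in% names(atoms))
  if (is.null(atoms$charge)) atoms$charge <- 0L
  bad <- setdiff(unique(atoms$element), .mg_elements)
  if (length(bad))
    stop("unknown element symbol(s): ", paste(bad, collapse = ", "))
  if (is.null(bonds))
    bonds <- data.frame(a = integer(), b = integer(), order = integer())
  n <- nrow(atoms)
  if (nrow(bonds)) {
    if (any(bonds$a < 1 | bonds$a > n | bonds$b < 1 | bonds$b > n))
      stop("bond endpoint out of range")
    if (any(bonds$a == bonds$b)) stop("self-bond not allowed")
    key <- paste(pmin(bonds$a, bonds$b), pmax(bonds$a, bonds$b))
    if (anyDuplicated(key)) stop("duplicate bond between the same atom pair")
    if (!all(bonds$order %in% 1:3)) stop("bond order must be 1, 2 or 3")
  }
  structure(list(
    name  = name,
    atoms = data.frame(element = atoms$element,
                       charge = as.integer(atoms$charge),
                       implicit_h = NA_integer_,
                       aromatic = FALSE, in_ring = FALSE),
    bonds = data.frame(a = as.integer(bonds$a), b = as.integer(bonds$b),
                       order = as.integer(bonds$order),
                       in_ring = logical(nrow(bonds))),
    rings = list()
  ), class = "molgraph")
}

#' @export
print.molgraph <- function(x, ...) {
  cat("<molgraph>", if (nzchar(x$name)) x$name else "(unnamed)", "\n")
  cat("  atoms:", nrow(x$atoms), " bonds:", nrow(x$bonds), "\n")
  if (length(x$rings)) cat("  rings:", length(x$rings),
                           paste0("(sizes ", paste(lengths(x$rings), collapse = ","), ")"), "\n")
  invisible(x)
}

#' Parse a Hill-notation molecular formula
#'
#' @param text formula string such as `"C19H11F4NO2"`; a missing count means 1.
#' @return Named integer vector of element counts (class `formula_counts`).
#' @examples
#' parse_formula("C19H11F4NO2")
#' @export
parse_formula <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  if (!nzchar(text)) stop("empty formula string")
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", text)[[1]]
  toks <- regmatches(text, gregexpr("([A-Z][a-z]?)([0-9]*)", text))[[1]]
  if (sum(nchar(toks)) != nchar(text))
    stop("formula does not parse as element/count pairs: ", text)
  counts <- integer(0)
  for (tok in toks) {
    el <- sub("[0-9]*$", "", tok)
    if (!el %in% .mg_elements)
      stop("unknown element symbol '", el, "' in formula ", text)
    nstr <- sub("^[A-Za-z]+", "", tok)
    n <- if (nzchar(nstr)) as.integer(nstr) else 1L
    counts[el] <- (if (el %in% names(counts)) counts[[el]] else 0L) + n
  }
  structure(counts, class = "formula_counts")
}

#' Format element counts as a canonical Hill-order formula
#'
#' Carbon first, then hydrogen, then all other elements alphabetically
#' (plain alphabetical order when no carbon is present).
#'
#' @param fc named integer vector of element counts.
#' @return Formula string.
#' @export
format_formula <- function(fc) {
  fc <- fc[fc > 0]
  els <- names(fc)
  ord <- if ("C" %in% els) {
    c(intersect(c("C", "H"), els), sort(setdiff(els, c("C", "H"))))
  } else sort(els)
  paste0(vapply(ord, function(e)
    paste0(e, if (fc[[e]] > 1) fc[[e]] else ""), ""), collapse = "")
}

#' Element counts of a molecular graph
#'
#' Includes implicit hydrogens, so the result round-trips against
#' [parse_formula()] on the molecule's molecular formula.
#'
#' @param mol a `molgraph` with implicit hydrogens assigned.
#' @return Named integer vector (class `formula_counts`).
#' @export
formula_counts <- function(mol) {
  stopifnot(inherits(mol, "molgraph"))
  if (anyNA(mol$atoms$implicit_h))
    stop("assign_implicit_h() must be applied first")
  tab <- table(mol$atoms$element)
  counts <- stats::setNames(as.integer(tab), names(tab))
  h <- sum(mol$atoms$implicit_h) + sum(counts["H"], na.rm = TRUE)
  if (h > 0) counts["H"] <- h
  structure(counts[counts > 0], class = "formula_counts")
}

.mol_lines <- function(text) {
  if (length(text) == 1 && !grepl("\n", text) && file.exists(text))
    text <- readLines(text, warn = FALSE)
  if (length(text) == 1) text <- strsplit(text, "\n", fixed = TRUE)[[1]]
  text
}

.parse_one_mol <- function(lines, offset = 0L) {
  ln <- function(i) offset + i
  if (length(lines) < 4)
    stop("molfile truncated before counts line (line ", ln(length(lines)), ")")
  counts_line <- lines[4]
  if (grepl("V3000", counts_line))
    stop("V3000 molfiles are not supported; supply V2000")
  n_atoms <- suppressWarnings(as.integer(substr(counts_line, 1, 3)))
  n_bonds <- suppressWarnings(as.integer(substr(counts_line, 4, 6)))
  if (is.na(n_atoms) || is.na(n_bonds))
    stop("cannot parse counts line (line ", ln(4), "): ", counts_line)
  if (length(lines) < 4 + n_atoms)
    stop("atom block truncated: declared ", n_atoms, " atoms, file ends at line ",
         ln(length(lines)))
  atoms <- data.frame(element = character(n_atoms), charge = 0L)
  for (i in seq_len(n_atoms)) {
    l <- lines[4 + i]
    el <- trimws(substr(l, 32, 34))
    if (!nzchar(el)) {
      # tolerate whitespace-collapsed atom lines (x y z element ...)
      f <- strsplit(trimws(l), "[[:space:]]+")[[1]]
      el <- if (length(f) >= 4) f[4] else ""
    }
    if (!el %in% .mg_elements)
      stop("unknown or missing element '", el, "' at line ", ln(4 + i))
    atoms$element[i] <- el
  }
  if (length(lines) < 4 + n_atoms + n_bonds)
    stop("bond block truncated: declared ", n_bonds, " bonds, file ends at line ",
         ln(length(lines)))
  bonds <- data.frame(a = integer(n_bonds), b = integer(n_bonds),
                      order = integer(n_bonds))
  for (i in seq_len(n_bonds)) {
    l <- lines[4 + n_atoms + i]
    a <- suppressWarnings(as.integer(substr(l, 1, 3)))
    b <- suppressWarnings(as.integer(substr(l, 4, 6)))
    o <- suppressWarnings(as.integer(substr(l, 7, 9)))
    if (anyNA(c(a, b, o))) {
      f <- suppressWarnings(as.integer(strsplit(trimws(l), "[[:space:]]+")[[1]]))
      if (length(f) >= 3 && !anyNA(f[1:3])) { a <- f[1]; b <- f[2]; o <- f[3] }
      else stop("cannot parse bond line ", ln(4 + n_atoms + i), ": ", l)
    }
    bonds$a[i] <- a; bonds$b[i] <- b; bonds$order[i] <- o
  }
  # property block: formal charges
  rest <- lines[seq.int(4 + n_atoms + n_bonds + 1, length.out =
                          max(0, length(lines) - 4 - n_atoms - n_bonds))]
  for (l in rest) {
    if (startsWith(l, "M  CHG")) {
      f <- as.integer(strsplit(trimws(substr(l, 7, nchar(l))), "[[:space:]]+")[[1]])
      k <- f[1]
      for (j in seq_len(k)) {
        idx <- f[2 * j]; chg <- f[2 * j + 1]
        if (idx < 1 || idx > n_atoms)
          stop("M  CHG references atom ", idx, " outside the atom block")
        atoms$charge[idx] <- chg
      }
    }
    if (startsWith(l, "M  END")) break
  }
  molgraph(atoms, bonds, name = trimws(lines[1]))
}

#' Read an MDL V2000 molfile
#'
#' @param text path to a `.mol` file, or the molfile contents as a single
#'   string or character vector of lines. Only the first record is read;
#'   see [read_sdf()] for multi-record files.
#' @return A `molgraph` with implicit hydrogens, rings and aromaticity
#'   perceived (coordinates are discarded; `M  CHG` blocks are applied).
#' @export
read_molfile <- function(text) {
  lines <- .mol_lines(text)
  end <- which(lines == "$$$$")
  if (length(end)) lines <- lines[seq_len(end[1] - 1)]
  mol <- .parse_one_mol(lines)
  perceive_aromatic(perceive_rings(assign_implicit_h(mol)))
}

#' Read a multi-record SDF file
#'
#' @param text path or contents as for [read_molfile()].
#' @return List of `molgraph` objects, in file order.
#' @export
read_sdf <- function(text) {
  lines <- .mol_lines(text)
  breaks <- which(lines == "$$$$")
  starts <- c(1L, head(breaks, -1) + 1L)
  ends <- if (length(breaks)) breaks - 1L else length(lines)
  if (!length(breaks)) starts <- 1L
  out <- vector("list", length(starts))
  for (i in seq_along(starts)) {
    rec <- lines[starts[i]:ends[i]]
    # drop SDF data fields after M  END
    e <- which(startsWith(rec, "M  END"))
    if (length(e)) rec <- rec[seq_len(e[1])]
    mol <- .parse_one_mol(rec, offset = starts[i] - 1L)
    out[[i]] <- perceive_aromatic(perceive_rings(assign_implicit_h(mol)))
  }
  out
}

#' Assign implicit hydrogens from default valences
#'
#' Each atom receives `default valence - sum of incident bond orders`,
#' adjusted by formal charge (cationic N/O gain a bond slot, anionic lose
#' one; charged carbon loses one), floored at zero. Over-valent atoms get
#' zero implicit hydrogens with a warning.
#'
#' @param mol a `molgraph`.
#' @return The graph with the `implicit_h` atom column filled in.
#' @export
assign_implicit_h <- function(mol) {
  stopifnot(inherits(mol, "molgraph"))
  n <- nrow(mol$atoms)
  bsum <- numeric(n)
  if (nrow(mol$bonds)) {
    for (i in seq_len(nrow(mol$bonds))) {
      bsum[mol$bonds$a[i]] <- bsum[mol$bonds$a[i]] + mol$bonds$order[i]
      bsum[mol$bonds$b[i]] <- bsum[mol$bonds$b[i]] + mol$bonds$order[i]
    }
  }
  for (i in seq_len(n)) {
    el <- mol$atoms$element[i]
    chg <- mol$atoms$charge[i]
    val <- .mg_valence[[el]]
    eff <- if (el %in% c("N", "O", "P", "S")) val + chg else val - abs(chg)
    h <- eff - bsum[i]
    if (h < 0) {
      warning("atom ", i, " (", el, ") is over-valent; implicit_h set to 0")
      h <- 0
    }
    mol$atoms$implicit_h[i] <- as.integer(h)
  }
  mol
}

# --- minimum cycle basis -----------------------------------------------------

# Fundamental cycles from a BFS spanning forest, then pairwise GF(2)
# reduction so the basis cycles are as small as possible. Cycles are kept
# as edge-index sets; deterministic (BFS from lowest atom index, ties by
# smallest ring size then lowest atom index).
.cycle_basis <- function(n, bonds) {
  m <- nrow(bonds)
  if (m == 0 || n == 0) return(list())
  adj <- vector("list", n)
  for (i in seq_len(m)) {
    adj[[bonds$a[i]]] <- rbind(adj[[bonds$a[i]]], c(bonds$b[i], i))
    adj[[bonds$b[i]]] <- rbind(adj[[bonds$b[i]]], c(bonds$a[i], i))
  }
  parent <- rep(NA_integer_, n); parent_edge <- rep(NA_integer_, n)
  visited <- logical(n); tree_edge <- logical(m)
  for (root in seq_len(n)) {
    if (visited[root]) next
    visited[root] <- TRUE
    queue <- root
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      nb <- adj[[v]]
      if (is.null(nb)) next
      for (k in order(nb[, 1])) {
        w <- nb[k, 1]; e <- nb[k, 2]
        if (!visited[w]) {
          visited[w] <- TRUE; parent[w] <- v; parent_edge[w] <- e
          tree_edge[e] <- TRUE
          queue <- c(queue, w)
        }
      }
    }
  }
  path_to_root <- function(v) {
    edges <- integer(0); nodes <- v
    while (!is.na(parent[v])) { edges <- c(edges, parent_edge[v]); v <- parent[v]; nodes <- c(nodes, v) }
    list(edges = edges, nodes = nodes)
  }
  fund <- list()
  for (e in which(!tree_edge)) {
    pa <- path_to_root(bonds$a[e]); pb <- path_to_root(bonds$b[e])
    common <- intersect(pa$edges, pb$edges)
    fund[[length(fund) + 1]] <- c(e, setdiff(pa$edges, common), setdiff(pb$edges, common))
  }
  if (!length(fund)) return(list())
  # pairwise reduction: replace a cycle by its symmetric difference with
  # another whenever that is strictly smaller; iterate to a fixed point
  repeat {
    changed <- FALSE
    for (i in seq_along(fund)) for (j in seq_along(fund)) {
      if (i == j) next
      xr <- union(setdiff(fund[[i]], fund[[j]]), setdiff(fund[[j]], fund[[i]]))
      if (length(xr) > 0 && length(xr) < length(fund[[i]])) {
        fund[[i]] <- xr; changed <- TRUE
      }
    }
    if (!changed) break
  }
  # deterministic order: by size, then lowest involved edge index
  ord <- order(lengths(fund), vapply(fund, min, 1))
  fund[ord]
}

# Order a cycle's edge set into a closed atom walk; NULL if it is not a
# single simple cycle.
.order_cycle <- function(edge_set, bonds) {
  ends <- cbind(bonds$a[edge_set], bonds$b[edge_set])
  verts <- sort(unique(as.vector(ends)))
  if (length(verts) != length(edge_set)) return(NULL)
  adj <- lapply(verts, function(v) edge_set[ends[, 1] == v | ends[, 2] == v])
  names(adj) <- verts
  if (any(lengths(adj) != 2)) return(NULL)
  start <- verts[1]; walk <- start; prev_e <- NA
  v <- start
  repeat {
    es <- adj[[as.character(v)]]
    e <- if (is.na(prev_e)) es[1] else setdiff(es, prev_e)[1]
    w <- if (bonds$a[e] == v) bonds$b[e] else bonds$a[e]
    if (w == start) return(walk)
    walk <- c(walk, w); v <- w; prev_e <- e
    if (length(walk) > length(verts)) return(NULL)
  }
}

#' Perceive rings (minimum cycle basis)
#'
#' Flags every atom and bond lying on a cycle of a minimum cycle basis
#' (spanning-tree fundamental cycles with pairwise reduction). The ordered
#' rings are stored on the graph for aromaticity perception.
#'
#' @param mol a `molgraph`.
#' @return The graph with `in_ring` flags set and `rings` populated
#'   (each ring an ordered vector of atom indices).
#' @export
perceive_rings <- function(mol) {
  stopifnot(inherits(mol, "molgraph"))
  basis <- .cycle_basis(nrow(mol$atoms), mol$bonds)
  mol$atoms$in_ring <- FALSE
  mol$bonds$in_ring <- FALSE
  rings <- list()
  for (cyc in basis) {
    mol$bonds$in_ring[cyc] <- TRUE
    mol$atoms$in_ring[unique(c(mol$bonds$a[cyc], mol$bonds$b[cyc]))] <- TRUE
    w <- .order_cycle(cyc, mol$bonds)
    if (!is.null(w)) rings[[length(rings) + 1]] <- w
  }
  mol$rings <- rings
  mol
}

#' Perceive benzenoid aromaticity
#'
#' Flags the atoms of every six-membered ring whose members are all carbon
#' or nitrogen and whose bond orders alternate single/double around the ring
#' (a Kekulé benzenoid). Five-membered heteroaromatics and fused
#' electron-counting cases are deliberately out of scope.
#'
#' @param mol a `molgraph` with rings perceived.
#' @return The graph with the `aromatic` atom flag set.
#' @export
perceive_aromatic <- function(mol) {
  stopifnot(inherits(mol, "molgraph"))
  bond_order <- function(a, b) {
    hit <- which((mol$bonds$a == a & mol$bonds$b == b) |
                 (mol$bonds$a == b & mol$bonds$b == a))
    mol$bonds$order[hit[1]]
  }
  mol$atoms$aromatic <- FALSE
  for (ring in mol$rings) {
    if (length(ring) != 6) next
    if (!all(mol$atoms$element[ring] %in% c("C", "N"))) next
    ords <- vapply(seq_along(ring), function(i)
      bond_order(ring[i], ring[if (i == 6) 1 else i + 1]), 1)
    if (all(ords %in% c(1, 2)) && sum(ords == 2) == 3 &&
        all(abs(diff(ords)) == 1))
      mol$atoms$aromatic[ring] <- TRUE
  }
  mol
}
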