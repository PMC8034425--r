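#' @title Graph-derivable drug-likeness descriptors
#' @name descriptors
#' @description
#' Molecular weight, Lipinski H-bond donor/acceptor counts, Ertl topological
#' polar surface area (TPSA), fraction of sp3 carbons, rotatable-bond count,
#' and the Lipinski rule-of-five verdict. logP and molar refractivity are
#' consumed as external inputs, never computed: their standard predictors are
#' proprietary models.
NULL

# IUPAC standard atomic weights, 3 decimal places.
.atomic_mass <- c(C = 12.011, H = 1.008, N = 14.007, O = 15.999, F = 18.998,
                  S = 32.06, P = 30.974, Cl = 35.45, Br = 79.904, I = 126.904)

.round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  # small epsilon so decimal halves stored just below .5 still round up
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' Molecular weight from element counts
#'
#' @param fc named integer vector of element counts (see [parse_formula()]
#'   or [formula_counts()]).
#' @return Molecular weight in g/mol, rounded half-up to 2 decimals.
#' @examples
#' molecular_weight(parse_formula("C19H11F4NO2"))  # 361.29
#' @export
molecular_weight <- function(fc) {
  if (length(fc) == 0) return(0)
  missing <- setdiff(names(fc), names(.atomic_mass))
  if (length(missing))
    stop("no atomic mass for element(s): ", paste(missing, collapse = ", "))
  .round_half_up(sum(.atomic_mass[names(fc)] * as.numeric(fc)), 2)
}

#' Count Lipinski hydrogen-bond donors
#'
#' Hydrogens attached to nitrogen or oxygen (sum of implicit hydrogens over
#' N and O atoms).
#'
#' @param mol a `molgraph` with implicit hydrogens assigned.
#' @return Integer donor count.
#' @export
count_hbd <- function(mol) {
  stopifnot(inherits(mol, "molgraph"))
  if (anyNA(mol$atoms$implicit_h)) stop("assign_implicit_h() required")
  sum(mol$atoms$implicit_h[mol$atoms$element %in% c("N", "O")])
}

#' Count Lipinski hydrogen-bond acceptors
#'
#' The Lipinski convention: number of N plus number of O atoms; halogens are
#' excluded (fluorine is not an acceptor under this rule).
#'
#' @param mol a `molgraph`.
#' @return Integer acceptor count.
#' @export
count_hba <- function(mol) {
  stopifnot(inherits(mol, "molgraph"))
  sum(mol$atoms$element %in% c("N", "O"))
}

# Ertl fragment contributions (A^2) for N/O environments, keyed by
# element | H count | sorted incident bond orders, with aromatic N and
# small-ring ether O special-cased. Polar atoms matching no class raise an
# error rather than silently contributing zero.
.tpsa_contrib <- function(el, n_h, orders, aromatic, in_ring3) {
  key <- paste(sort(orders), collapse = ",")
  if (el == "N") {
    if (aromatic && n_h == 0 && key %in% c("1,2", "1,1,2")) return(12.89)
    if (n_h == 0) switch(key,
      "1,1,1" = return(3.24),
      "1,2"   = return(12.36),
      "3"     = return(23.79),
      "1,1,2" = , "2,2" = return(11.68),       # nitro-type N
      "1,1,1,1" = return(0.00))                # quaternary N+
    if (n_h == 1) switch(key,
      "1,1" = return(12.03),
      "2"   = return(23.85),
      "1,1,1" = return(4.44))                  # protonated tertiary N+
    if (n_h == 2) switch(key,
      "1" = return(26.02),
      "1,1" = return(16.61))                   # protonated secondary N+
    if (n_h == 3 && key == "1") return(27.64)  # primary N+
  }
  if (el == "O") {
    if (n_h == 0) switch(key,
      "1,1" = return(if (in_ring3) 12.53 else 9.23),
      "2"   = return(17.07),
      "1"   = return(23.06))                   # O-
    if (n_h == 1 && key == "1") return(20.23)
  }
  stop("no TPSA fragment class for atom environment: ", el,
       " H", n_h, " bonds(", key, ")",
       if (aromatic) " aromatic" else "")
}

#' Ertl topological polar surface area
#'
#' Sum of published polar-fragment surface contributions over N and O atoms,
#' classified by element, attached hydrogens, incident bond-order pattern and
#' aromatic/ring context. An N or O environment outside the packaged table is
#' an error, never a silent zero.
#'
#' @param mol a `molgraph` with implicit hydrogens and rings perceived.
#' @return TPSA in square Angstroms, rounded half-up to 2 decimals.
#' @export
tpsa <- function(mol) {
  stopifnot(inherits(mol, "molgraph"))
  if (anyNA(mol$atoms$implicit_h)) stop("assign_implicit_h() required")
  total <- 0
  ring3_atoms <- unique(unlist(mol$rings[lengths(mol$rings) == 3]))
  for (i in seq_len(nrow(mol$atoms))) {
    el <- mol$atoms$element[i]
    if (!el %in% c("N", "O")) next
    sel <- mol$bonds$a == i | mol$bonds$b == i
    total <- total + .tpsa_contrib(
      el, mol$atoms$implicit_h[i], mol$bonds$order[sel],
      mol$atoms$aromatic[i], i %in% ring3_atoms)
  }
  .round_half_up(total, 2)
}

#' Fraction of sp3-hybridized carbons
#'
#' Carbons participating only in single bonds and carrying no aromatic flag,
#' divided by the total carbon count (0 for carbon-free molecules).
#'
#' @param mol a `molgraph` with aromaticity perceived.
#' @return Fraction in `[0, 1]`.
#' @export
fraction_csp3 <- function(mol) {
  stopifnot(inherits(mol, "molgraph"))
  is_c <- mol$atoms$element == "C"
  if (!any(is_c)) return(0)
  sp3 <- vapply(which(is_c), function(i) {
    sel <- mol$bonds$a == i | mol$bonds$b == i
    all(mol$bonds$order[sel] == 1) && !mol$atoms$aromatic[i]
  }, TRUE)
  sum(sp3) / sum(is_c)
}

#' Count rotatable bonds
#'
#' Acyclic single bonds whose two endpoints are both non-terminal heavy
#' atoms (degree >= 2 in the heavy-atom graph). Amide C-N bonds are counted
#' as rotatable under this definition.
#'
#' @param mol a `molgraph` with rings perceived.
#' @return Integer rotatable-bond count.
#' @export
rotatable_bonds <- function(mol) {
  stopifnot(inherits(mol, "molgraph"))
  if (!nrow(mol$bonds)) return(0L)
  deg <- tabulate(c(mol$bonds$a, mol$bonds$b), nbins = nrow(mol$atoms))
  sum(mol$bonds$order == 1 & !mol$bonds$in_ring &
        deg[mol$bonds$a] >= 2 & deg[mol$bonds$b] >= 2)
}

#' Lipinski rule-of-five verdict
#'
#' Collects violations of: molecular weight >= 500 g/mol, H-bond donors >= 5,
#' H-bond acceptors >= 10, logP >= 5, molar refractivity outside `[40, 130]`.
#' logP and molar refractivity are external inputs; when absent those rules
#' are skipped with a message.
#'
#' @param mw molecular weight (g/mol).
#' @param n_hbd,n_hba H-bond donor and acceptor counts.
#' @param logp octanol/water partition coefficient (optional).
#' @param molar_refractivity molar refractivity (optional).
#' @return List with `violations` (character vector, possibly empty),
#'   `skipped` (rules not evaluable) and `pass` (no violations).
#' @export
lipinski <- function(mw, n_hbd, n_hba, logp = NA, molar_refractivity = NA) {
  v <- character(0); skipped <- character(0)
  if (mw >= 500) v <- c(v, "molecular weight >= 500")
  if (n_hbd >= 5) v <- c(v, "H-bond donors >= 5")
  if (n_hba >= 10) v <- c(v, "H-bond acceptors >= 10")
  if (is.na(logp)) skipped <- c(skipped, "logP") else
    if (logp >= 5) v <- c(v, "logP >= 5")
  if (is.na(molar_refractivity)) skipped <- c(skipped, "molar refractivity") else
    if (molar_refractivity < 40 || molar_refractivity > 130)
      v <- c(v, "molar refractivity outside [40, 130]")
  if (length(skipped))
    message("Lipinski rules skipped (value not supplied): ",
            paste(skipped, collapse = ", "))
  list(violations = v, skipped = skipped, pass = length(v) == 0)
}

#' Compute the full descriptor set for a molecule
#'
#' @param mol a `molgraph` (implicit H, rings, aromaticity perceived, as
#'   returned by [read_molfile()]).
#' @param logp,molar_refractivity externally supplied values (optional).
#' @return One-row data.frame: name, formula, mw, n_hbd, n_hba, tpsa,
#'   frac_csp3, n_rotatable, logp, molar_refractivity, lipinski_pass,
#'   lipinski_violations.
#' @export
descriptor_set <- function(mol, logp = NA, molar_refractivity = NA) {
  fc <- formula_counts(mol)
  mw <- molecular_weight(fc)
  hbd <- count_hbd(mol); hba <- count_hba(mol)
  lip <- suppressMessages(lipinski(mw, hbd, hba, logp, molar_refractivity))
  data.frame(
    name = mol$name, formula = format_formula(fc), mw = mw,
    n_hbd = hbd, n_hba = hba, tpsa = tpsa(mol),
    frac_csp3 = fraction_csp3(mol), n_rotatable = rotatable_bonds(mol),
    logp = logp, molar_refractivity = molar_refractivity,
    lipinski_pass = lip$pass,
    lipinski_violations = paste(lip$violations, collapse = "; "))
}
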