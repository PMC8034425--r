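#' @title Synthetic-data generators with known ground truth
#' @name synthetic_data
#' @description
#' Generators for every input class of the pipeline: Hill-shaped dose
#' plates, correlated fingerprint libraries with missing cells, alteration
#' matrices with planted co-occurrence odds ratios, exponential survival
#' cohorts with a group hazard ratio, and noisy predictor score lists with
#' planted true targets. Every generator is a pure function of its
#' configuration and seed, and emits a machine-readable truth table
#' alongside the data so downstream recovery tests never peek at
#' internals.
NULL

# Child seeds fan out from one root seed by fixed offsets so stages use
# independent, reproducible streams. Kept below 2^31 - 1.
#' Derive a per-stage child seed from a root seed
#'
#' @param seed root seed (integer).
#' @param offset fixed per-generator offset.
#' @return Integer child seed.
#' @export
child_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset) %% 2147483629)
}

.with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}

# Growth model behind the plate generator: percent growth falls from 100
# to `floor` as a Hill function of concentration,
#   PG(c) = floor + (100 - floor) / (1 + (c/m)^h).
# The analytic endpoint for level L (when L > floor) is
#   c = m * ((100 - L)/(L - floor))^(1/h).
.hill_pg <- function(conc, m, h, floor) {
  floor + (100 - floor) / (1 + (conc / m)^h)
}

.hill_endpoint <- function(level, m, h, floor) {
  if (level <= floor) return(NA_real_)
  m * ((100 - level) / (level - floor))^(1 / h)
}

#' Generate synthetic five-dose plates
#'
#' Treated signals follow a Hill-shaped growth model spanning 100%
#' (control growth) down to a per-line floor; a configurable fraction of
#' lines is lethal (floor below -50, so an exact LC50 exists). The default
#' concentration grid is the five-dose design read as 0.01-100 micromolar
#' in 10-fold steps, and default GI50s span the low-micromolar potencies
#' typical of an active screen.
#'
#' @param n_lines number of cell lines.
#' @param conc_grid tested concentrations in molar (log-spaced).
#' @param gi50_range range (molar) from which true GI50s are drawn
#'   log-uniformly.
#' @param hill_range range of Hill slopes.
#' @param lethality_fraction fraction of lines with floor below -50.
#' @param noise_sd additive noise on percent growth, in points.
#' @param panels panel labels cycled over the lines.
#' @param seed RNG seed.
#' @return List with `plates` (list of [dose_plate()]) and `truth`
#'   (data.frame: cell_line, panel, floor, hill, gi50_M, tgi_M, lc50_M --
#'   analytic endpoint concentrations, NA where the curve never reaches
#'   the level).
#' @export
gen_dose_plates <- function(n_lines = 60,
                            conc_grid = 10^seq(-8, -4),
                            gi50_range = c(1e-6, 5e-6),
                            hill_range = c(0.5, 3),
                            lethality_fraction = 0.3,
                            noise_sd = 3,
                            panels = c("NSCLC", "Leukemia", "Melanoma",
                                       "Renal", "Colon", "Breast",
                                       "Ovarian", "CNS", "Prostate"),
                            seed = 1) {
  stopifnot(length(conc_grid) >= 2, all(diff(conc_grid) > 0),
            gi50_range[1] > 0, diff(gi50_range) >= 0)
  .with_seed(seed, {
    gi50 <- 10^stats::runif(n_lines, log10(gi50_range[1]), log10(gi50_range[2]))
    h <- stats::runif(n_lines, hill_range[1], hill_range[2])
    lethal <- stats::runif(n_lines) < lethality_fraction
    floor <- ifelse(lethal, stats::runif(n_lines, -100, -60),
                    stats::runif(n_lines, -40, -10))
    # place the Hill midpoint so the analytic GI50 equals the drawn value
    m <- gi50 / ((100 - 50) / (50 - floor))^(1 / h)
    tz <- 0.25; c0 <- 1.0
    plates <- vector("list", n_lines)
    truth <- data.frame(cell_line = sprintf("SYN-%03d", seq_len(n_lines)),
                        panel = rep_len(panels, n_lines),
                        floor = floor, hill = h,
                        gi50_M = NA_real_, tgi_M = NA_real_, lc50_M = NA_real_)
    for (i in seq_len(n_lines)) {
      pg <- .hill_pg(conc_grid, m[i], h[i], floor[i]) +
        stats::rnorm(length(conc_grid), 0, noise_sd)
      ti <- ifelse(pg >= 0, tz + pg / 100 * (c0 - tz), tz * (1 + pg / 100))
      ti <- pmax(ti, 0)
      plates[[i]] <- dose_plate(truth$cell_line[i], truth$panel[i],
                                tz, c0, conc_grid, ti)
      truth$gi50_M[i] <- .hill_endpoint(50, m[i], h[i], floor[i])
      truth$tgi_M[i]  <- .hill_endpoint(0, m[i], h[i], floor[i])
      truth$lc50_M[i] <- .hill_endpoint(-50, m[i], h[i], floor[i])
    }
    list(plates = plates, truth = truth)
  })
}

#' Generate a synthetic fingerprint library
#'
#' The first `n_correlated` compounds are the seed fingerprint plus
#' Gaussian noise (sd = `correlation_noise_sd` times the seed's sd);
#' the rest are independent draws. Cells are dropped uniformly at random
#' at `missing_rate`.
#'
#' @param n_compounds library size.
#' @param n_lines number of cell lines.
#' @param n_correlated number of planted look-alike compounds.
#' @param correlation_noise_sd noise sd as a multiple of the seed sd.
#' @param missing_rate probability a cell is missing.
#' @param endpoint endpoint label.
#' @param seed RNG seed.
#' @return List with `seed_fp` ([fingerprint()]), `library` (list of
#'   fingerprints) and `truth` (data.frame: compound_id, planted flag).
#' @export
gen_fingerprint_library <- function(n_compounds = 100, n_lines = 50,
                                    n_correlated = 5,
                                    correlation_noise_sd = 0.1,
                                    missing_rate = 0.1,
                                    endpoint = "GI50", seed = 1) {
  stopifnot(n_correlated <= n_compounds)
  .with_seed(seed, {
    lines <- sprintf("CL-%02d", seq_len(n_lines))
    base <- stats::rnorm(n_lines, mean = 5.7, sd = 0.5)  # -log10 molar
    names(base) <- lines
    seed_fp <- fingerprint("SEED", endpoint, base)
    sd_sig <- stats::sd(base)
    lib <- vector("list", n_compounds)
    for (j in seq_len(n_compounds)) {
      v <- if (j <= n_correlated)
        base + stats::rnorm(n_lines, 0, correlation_noise_sd * sd_sig)
      else stats::rnorm(n_lines, 5.7, 0.5)
      v[stats::runif(n_lines) < missing_rate] <- NA
      names(v) <- lines
      lib[[j]] <- fingerprint(sprintf("CMPD-%03d", j), endpoint, v)
    }
    truth <- data.frame(compound_id = sprintf("CMPD-%03d", seq_len(n_compounds)),
                        planted = seq_len(n_compounds) <= n_correlated)
    list(seed_fp = seed_fp, library = lib, truth = truth)
  })
}

#' Generate a synthetic alteration matrix with planted co-occurrence
#'
#' The index gene is Bernoulli at its base rate; genes with a planted odds
#' ratio have their alteration odds multiplied by that ratio in
#' index-altered samples. Other genes are independent of the index.
#'
#' @param n_samples cohort size.
#' @param gene_base_rates named vector of per-gene baseline alteration
#'   probabilities (must include `index_gene`).
#' @param index_gene the index gene symbol.
#' @param planted_odds_ratios named vector of odds ratios (subset of the
#'   genes; 1 = no planted signal).
#' @param cancer_type_mix named probability vector of cancer-type labels.
#' @param seed RNG seed.
#' @return List with `matrix` (an [alteration_matrix()]) and `truth`
#'   (data.frame: gene, base_rate, planted_or).
#' @export
gen_alteration_matrix <- function(n_samples = 10000,
                                  gene_base_rates = c(EGFR = 0.07,
                                                      RICTOR = 0.02,
                                                      UGGT1 = 0.015,
                                                      KRAS = 0.07,
                                                      TP53 = 0.37,
                                                      TTN = 0.30),
                                  index_gene = "EGFR",
                                  planted_odds_ratios = c(RICTOR = 8,
                                                          UGGT1 = 8),
                                  cancer_type_mix = c(GBM = 0.1, LUAD = 0.2,
                                                      HNSC = 0.2, BRCA = 0.25,
                                                      COAD = 0.25),
                                  seed = 1) {
  stopifnot(index_gene %in% names(gene_base_rates),
            all(gene_base_rates > 0 & gene_base_rates < 1),
            all(names(planted_odds_ratios) %in% names(gene_base_rates)))
  .with_seed(seed, {
    genes <- names(gene_base_rates)
    idx <- stats::rbinom(n_samples, 1, gene_base_rates[[index_gene]])
    calls <- matrix(0L, n_samples, length(genes),
                    dimnames = list(sprintf("S%05d", seq_len(n_samples)), genes))
    calls[, index_gene] <- idx
    for (g in setdiff(genes, index_gene)) {
      base <- gene_base_rates[[g]]
      or <- if (g %in% names(planted_odds_ratios)) planted_odds_ratios[[g]] else 1
      odds <- base / (1 - base)
      p_alt <- (odds * or) / (1 + odds * or)
      p <- ifelse(idx == 1, p_alt, base)
      calls[, g] <- stats::rbinom(n_samples, 1, p)
    }
    ct <- sample(names(cancer_type_mix), n_samples, replace = TRUE,
                 prob = cancer_type_mix)
    truth <- data.frame(
      gene = genes,
      base_rate = as.numeric(gene_base_rates),
      planted_or = vapply(genes, function(g)
        if (g %in% names(planted_odds_ratios)) planted_odds_ratios[[g]] else 1, 1))
    list(matrix = alteration_matrix(calls, ct), truth = truth)
  })
}

#' Generate synthetic two-group survival data
#'
#' Exponential event times (group B at `baseline_rate`, group A at
#' `baseline_rate * hazard_ratio`) with independent exponential censoring.
#'
#' @param n_per_group samples per group.
#' @param baseline_rate events per month in the reference group.
#' @param hazard_ratio true hazard ratio of group A versus group B.
#' @param censor_rate rate of the independent censoring process (0 = no
#'   censoring).
#' @param seed RNG seed.
#' @return List with `records` (data.frame: sample_id, time_months, event,
#'   group) and `truth` (hazard_ratio, baseline_rate, median months of the
#'   reference group).
#' @export
gen_survival <- function(n_per_group = 300, baseline_rate = 0.02,
                         hazard_ratio = 2, censor_rate = 0.005, seed = 1) {
  .with_seed(seed, {
    n <- 2 * n_per_group
    group <- rep(c("A", "B"), each = n_per_group)
    rate <- ifelse(group == "A", baseline_rate * hazard_ratio, baseline_rate)
    t_event <- stats::rexp(n, rate)
    t_cens <- if (censor_rate > 0) stats::rexp(n, censor_rate) else rep(Inf, n)
    records <- data.frame(sample_id = sprintf("P%04d", seq_len(n)),
                          time_months = pmin(t_event, t_cens),
                          event = as.integer(t_event <= t_cens),
                          group = group)
    list(records = records,
         truth = list(hazard_ratio = hazard_ratio,
                      baseline_rate = baseline_rate,
                      median_B = log(2) / baseline_rate))
  })
}

#' Generate synthetic target-predictor outputs
#'
#' Three predictors (Pa/Pi, probability, pharmacophore kinds) score a pool
#' of true targets and decoys: true targets get high scores, decoys low,
#' plus Gaussian noise; each predictor drops a random subset of targets so
#' the Venn structure is nontrivial. With `fixture = TRUE` the generator
#' instead returns the deterministic three-list structure with six
#' triple-predicted genes and two double-predicted genes (STAT, MTOR),
#' twenty targets per predictor.
#'
#' @param true_targets character vector of planted true targets.
#' @param n_decoys decoys per predictor.
#' @param score_noise sd of score noise.
#' @param drop_rate probability a predictor drops a given true target.
#' @param fixture return the deterministic published-structure fixture.
#' @param seed RNG seed.
#' @return List with `entries` (data.frame for [consensus_rank()] /
#'   [venn_membership()]) and `truth` (the planted target list).
#' @export
gen_predictor_outputs <- function(true_targets = c("EGFR", "MTOR", "NOS2",
                                                   "TGFB1", "MAP2K1", "FGFR1"),
                                  n_decoys = 14, score_noise = 0.05,
                                  drop_rate = 0.2, fixture = FALSE, seed = 1) {
  preds <- data.frame(
    predictor = c("PASS", "SwissTarget", "PharmMapper"),
    score_kind = c("pa_pi", "probability", "pharmacophore"))
  if (fixture) return(.predictor_fixture(preds))
  .with_seed(seed, {
    rows <- list()
    for (i in seq_len(nrow(preds))) {
      decoys <- sprintf("DECOY%s%02d", substr(preds$predictor[i], 1, 2),
                        seq_len(n_decoys))
      keep <- true_targets[stats::runif(length(true_targets)) >= drop_rate]
      targets <- c(keep, decoys)
      strength <- c(stats::runif(length(keep), 0.7, 0.95),
                    stats::runif(length(decoys), 0.05, 0.45)) +
        stats::rnorm(length(targets), 0, score_noise)
      strength <- pmin(pmax(strength, 0), 0.999)
      d <- data.frame(predictor = preds$predictor[i], target = targets,
                      score_kind = preds$score_kind[i],
                      pa = NA_real_, pi = NA_real_, probability = NA_real_,
                      fit_score = NA_real_, z = NA_real_)
      if (preds$score_kind[i] == "pa_pi") {
        d$pa <- strength; d$pi <- stats::runif(nrow(d), 0, 0.05)
      } else if (preds$score_kind[i] == "probability") {
        d$probability <- strength
      } else {
        d$fit_score <- strength; d$z <- stats::runif(nrow(d), 0.1, 0.65)
      }
      rows[[i]] <- d
    }
    list(entries = do.call(rbind, rows), truth = true_targets)
  })
}

# Deterministic fixture mirroring the published Venn structure: six genes
# named by all three predictors, STAT and MTOR by exactly two, and
# predictor-specific singles filling each list to 20.
.predictor_fixture <- function(preds) {
  triple <- c("NOS2", "TGFB1", "KDR", "FGFR1", "EGFR", "MAP2K1")
  double <- c("STAT", "MTOR")
  lists <- list(
    PASS        = c(triple, double, sprintf("PASSONLY%02d", 1:12)),
    SwissTarget = c(triple, double, sprintf("SWISSONLY%02d", 1:12)),
    PharmMapper = c(triple, sprintf("PHARMONLY%02d", 1:14)))
  rows <- list()
  for (i in seq_len(nrow(preds))) {
    p <- preds$predictor[i]
    targets <- lists[[p]]
    n <- length(targets)
    strength <- seq(0.95, 0.30, length.out = n)  # rank order = list order
    d <- data.frame(predictor = p, target = targets,
                    score_kind = preds$score_kind[i],
                    pa = NA_real_, pi = NA_real_, probability = NA_real_,
                    fit_score = NA_real_, z = NA_real_)
    if (preds$score_kind[i] == "pa_pi") { d$pa <- strength; d$pi <- 0.01 }
    else if (preds$score_kind[i] == "probability") d$probability <- strength
    else { d$fit_score <- strength; d$z <- seq(0.64, 0.11, length.out = n) }
    rows[[i]] <- d
  }
  list(entries = do.call(rbind, rows),
       truth = list(triple = triple, double = double))
}
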