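# Independent oracles used across tests. These deliberately avoid the code
# paths they check: brute-force enumeration and closed forms only.

# Two-sided Fisher p by full enumeration over all 2x2 tables with the
# observed margins: sum point probabilities <= observed (1 + 1e-7 slack).
oracle_fisher2 <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  lo <- max(0, r1 + c1 - n); hi <- min(r1, c1)
  pt <- function(x) dhyper(x, c1, n - c1, r1)
  p_obs <- pt(a)
  sum(vapply(lo:hi, pt, 1)[vapply(lo:hi, pt, 1) <= p_obs * (1 + 1e-7)])
}

# Upper-tail hypergeometric by direct summation.
oracle_hyper_tail <- function(k, set_size, bg, query_size) {
  kk <- k:min(set_size, query_size)
  sum(choose(set_size, kk) * choose(bg - set_size, query_size - kk)) /
    choose(bg, query_size)
}

# Step-up BH by hand.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q_sorted <- p[o] * n / seq_len(n)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(n)
  q[o] <- pmin(q_sorted, 1)
  q
}

# Product-limit estimator by hand (right-censored data).
oracle_km <- function(time, event) {
  ts <- sort(unique(time[event == 1]))
  s <- 1; out <- numeric(length(ts))
  for (i in seq_along(ts)) {
    at_risk <- sum(time >= ts[i])
    d <- sum(time == ts[i] & event == 1)
    s <- s * (1 - d / at_risk)
    out[i] <- s
  }
  list(times = ts, surv = out)
}

# Textbook Pearson correlation.
oracle_pearson <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}

# Locate the percent-growth level crossing of a Hill curve on a dense
# log-spaced grid (numerical truth for endpoint-recovery checks).
oracle_hill_crossing <- function(level, m, h, floor,
                                 lo = 1e-10, hi = 1e-2, n = 1e5) {
  conc <- 10^seq(log10(lo), log10(hi), length.out = n)
  pg <- floor + (100 - floor) / (1 + (conc / m)^h)
  i <- which(pg <= level)[1]
  if (is.na(i) || i == 1) return(NA_real_)
  conc[i]
}

fixture_mol <- function(name = "nsc765598.mol") {
  read_molfile(system.file("extdata", name, package = "screenkit"))
}
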