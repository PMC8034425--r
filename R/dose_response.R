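#' @title NCI60-style dose-response endpoint analysis
#' @name dose_response
#' @description
#' The five-dose screening mathematics: piecewise percent growth from
#' time-zero (Tz), control (C) and treated (Ti) signals, the three endpoint
#' concentrations GI50 (percent growth = 50), TGI (= 0) and LC50 (= -50)
#' by interpolation in log10 concentration with censoring at the tested
#' range, and per-panel screen summaries.
NULL

#' Percent growth from plate signals
#'
#' `(Ti - Tz)/(C - Tz) * 100` when `Ti >= Tz` (net growth relative to
#' control growth), `(Ti - Tz)/Tz * 100` when `Ti < Tz` (net cell loss
#' relative to the starting population). Continuous at `Ti = Tz` (both
#' branches give 0).
#'
#' @param ti treated signal(s) at one or more concentrations.
#' @param tz time-zero signal.
#' @param c0 control growth signal.
#' @return Percent growth, same length as `ti`; 100 means control-level
#'   growth, 0 no net growth, -100 complete kill.
#' @export
percent_growth <- function(ti, tz, c0) {
  if (c0 == tz) stop("control equals time-zero signal: percent growth undefined")
  ifelse(ti >= tz, (ti - tz) / (c0 - tz) * 100, (ti - tz) / tz * 100)
}

#' Growth inhibition from a single-dose growth value
#'
#' A growth value of 60 means 40% growth inhibition. Negative growth values
#' indicate net lethality and are returned unchanged, flagged via the
#' `lethal` attribute.
#'
#' @param growth_value percent growth value(s).
#' @return Percent growth inhibition (or the unchanged negative value),
#'   with a logical attribute `lethal`.
#' @export
growth_inhibition <- function(growth_value) {
  out <- ifelse(growth_value >= 0, 100 - growth_value, growth_value)
  attr(out, "lethal") <- growth_value < 0
  out
}

#' Construct a dose plate
#'
#' @param cell_line cell-line identifier.
#' @param panel tissue panel label.
#' @param tz time-zero signal.
#' @param c0 control growth signal.
#' @param conc ascending vector of tested concentrations (molar, > 0).
#' @param ti treated signals, one per concentration.
#' @return Object of class `dose_plate`.
#' @export
dose_plate <- function(cell_line, panel, tz, c0, conc, ti) {
  stopifnot(length(conc) >= 2, length(ti) == length(conc))
  if (any(conc <= 0) || any(diff(conc) <= 0))
    stop("concentrations must be positive and strictly increasing")
  if (tz < 0 || c0 < 0 || any(ti < 0)) stop("signals must be non-negative")
  if (c0 == tz) stop("control equals time-zero signal")
  structure(list(cell_line = cell_line, panel = panel, tz = tz, c0 = c0,
                 conc = conc, ti = ti), class = "dose_plate")
}

#' Endpoint concentration by log-linear interpolation
#'
#' Finds the lowest concentration at which percent growth crosses `level`,
#' interpolating linearly in percent growth versus log10(concentration)
#' between the bracketing doses. Exact grid hits are returned as-is. When
#' the curve never reaches the level the endpoint is censored at the tested
#' range.
#'
#' @param conc ascending concentrations (molar).
#' @param pg percent growth at each concentration.
#' @param level target percent-growth level (50 for GI50, 0 for TGI,
#'   -50 for LC50).
#' @return List with `value` (molar; the range boundary when censored) and
#'   `censor` (`"exact"`, `"above_max"` or `"below_min"`).
#' @export
endpoint_concentration <- function(conc, pg, level) {
  stopifnot(length(conc) == length(pg), length(conc) >= 1)
  if (any(!is.finite(pg))) stop("non-finite percent-growth values")
  if (pg[1] == level)
    return(list(value = conc[1], censor = "exact"))
  if (pg[1] < level)
    return(list(value = conc[1], censor = "below_min"))
  for (i in seq_along(pg)[-1]) {
    if (pg[i] == level)
      return(list(value = conc[i], censor = "exact"))
    if (pg[i - 1] > level && pg[i] < level) {
      lx <- log10(conc[c(i - 1, i)])
      f <- (pg[i - 1] - level) / (pg[i - 1] - pg[i])
      return(list(value = 10^(lx[1] + f * (lx[2] - lx[1])), censor = "exact"))
    }
  }
  list(value = conc[length(conc)], censor = "above_max")
}

#' Analyze one dose plate
#'
#' Computes percent growth at every tested concentration, then the GI50,
#' TGI and LC50 endpoint concentrations with censor flags.
#'
#' @param plate a [dose_plate()].
#' @return Object of class `response_params`: cell_line, panel, the percent
#'   growth curve, and per-endpoint `value` (molar) + `censor`.
#' @export
analyze_plate <- function(plate) {
  stopifnot(inherits(plate, "dose_plate"))
  pg <- percent_growth(plate$ti, plate$tz, plate$c0)
  eps <- list(gi50 = endpoint_concentration(plate$conc, pg, 50),
              tgi  = endpoint_concentration(plate$conc, pg, 0),
              lc50 = endpoint_concentration(plate$conc, pg, -50))
  structure(c(list(cell_line = plate$cell_line, panel = plate$panel,
                   conc = plate$conc, pg = pg), eps),
            class = "response_params")
}

#' @export
print.response_params <- function(x, ...) {
  cat("<response_params>", x$cell_line, "/", x$panel, "\n")
  for (ep in c("gi50", "tgi", "lc50"))
    cat(" ", toupper(ep), "=", format_endpoint_uM(x[[ep]], x$conc), "uM\n")
  invisible(x)
}

#' Format an endpoint in micromolar
#'
#' Exact endpoints print with 2 significant figures; censored endpoints
#' serialize as `"> max"` / `"< min"` of the tested range in micromolar.
#'
#' @param ep list with `value` (molar) and `censor`.
#' @param conc tested concentrations (molar), used for the censoring bounds.
#' @return Character scalar.
#' @export
format_endpoint_uM <- function(ep, conc) {
  uM <- function(x) format(signif(x * 1e6, 2), trim = TRUE, scientific = FALSE)
  switch(ep$censor,
         exact = uM(ep$value),
         above_max = paste(">", uM(max(conc))),
         below_min = paste("<", uM(min(conc))))
}

#' Summarize a screen over many plates
#'
#' @param plates list of [dose_plate()] objects.
#' @return List of class `screen_summary` with `params` (one row per cell
#'   line: endpoint values in micromolar, censor flags, formatted strings)
#'   and `panel_ranges` (per panel and endpoint: `[min, max]` over exact
#'   values in micromolar, with censored counts reported separately).
#' @export
summarize_screen <- function(plates) {
  stopifnot(length(plates) >= 1)
  res <- lapply(plates, analyze_plate)
  row1 <- function(r) {
    out <- data.frame(cell_line = r$cell_line, panel = r$panel)
    for (ep in c("gi50", "tgi", "lc50")) {
      e <- r[[ep]]
      out[[paste0(ep, "_uM")]] <- if (e$censor == "exact") e$value * 1e6 else NA_real_
      out[[paste0(ep, "_censor")]] <- e$censor
      out[[paste0(ep, "_label")]] <- format_endpoint_uM(e, r$conc)
    }
    out
  }
  params <- do.call(rbind, lapply(res, row1))
  ranges <- do.call(rbind, lapply(split(params, params$panel), function(d) {
    do.call(rbind, lapply(c("gi50", "tgi", "lc50"), function(ep) {
      v <- d[[paste0(ep, "_uM")]]
      data.frame(panel = d$panel[1], endpoint = toupper(ep),
                 n = nrow(d), n_censored = sum(is.na(v)),
                 min_uM = if (any(!is.na(v))) min(v, na.rm = TRUE) else NA_real_,
                 max_uM = if (any(!is.na(v))) max(v, na.rm = TRUE) else NA_real_)
    }))
  }))
  rownames(ranges) <- NULL
  structure(list(params = params, panel_ranges = ranges),
            class = "screen_summary")
}

#' @export
print.screen_summary <- function(x, ...) {
  cat("<screen_summary>", nrow(x$params), "cell lines,",
      length(unique(x$params$panel)), "panels\n")
  print(utils::head(x$params[, c("cell_line", "panel", "gi50_label",
                                 "tgi_label", "lc50_label")], 10))
  invisible(x)
}

#' Read dose plates from long-format TSV
#'
#' Expected columns: `cell_line`, `panel`, `tz`, `c`, `conc_M`, `ti`
#' (one row per tested concentration).
#'
#' @param path TSV file path.
#' @return List of [dose_plate()] objects.
#' @export
read_plates_tsv <- function(path) {
  d <- utils::read.delim(path, check.names = FALSE)
  need <- c("cell_line", "panel", "tz", "c", "conc_M", "ti")
  if (!all(need %in% names(d)))
    stop("plate TSV must have columns: ", paste(need, collapse = ", "))
  lapply(split(d, d$cell_line), function(g) {
    g <- g[order(g$conc_M), ]
    dose_plate(g$cell_line[1], g$panel[1], g$tz[1], g$c[1], g$conc_M, g$ti)
  })
}

#' Write dose plates to long-format TSV
#'
#' @param plates list of [dose_plate()] objects.
#' @param path output TSV path.
#' @export
write_plates_tsv <- function(plates, path) {
  d <- do.call(rbind, lapply(plates, function(p)
    data.frame(cell_line = p$cell_line, panel = p$panel, tz = p$tz,
               c = p$c0, conc_M = p$conc, ti = p$ti)))
  utils::write.table(d, path, sep = "\t", row.names = FALSE, quote = FALSE)
}
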