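#' Fortification / supplementation risk scenario
#'
#' @param name Scenario label.
#' @param fortification Staple-food fortificant dose in mg/d (default 10).
#' @param supplementation Daily-equivalent supplement dose in mg/d (default
#'   14, i.e. roughly a 100 mg weekly tablet).
#' @param tul Tolerable upper level of intake in mg/d (default 45).
#' @return An object of class `risk_scenario`.
#' @export
risk_scenario <- function(name = "fortification+supplementation",
                          fortification = 10, supplementation = 14,
                          tul = 45) {
  stopifnot(fortification >= 0, supplementation >= 0, tul >= 0)
  structure(list(name = name, fortification = fortification,
                 supplementation = supplementation, tul = tul),
            class = "risk_scenario")
}

#' Population risk of inadequate intake (probability approach)
#'
#' The probability approach evaluates the requirement survival function
#' `rho(x) = 1 - F(x)` at each individual's usual intake and averages over
#' the intake distribution.  Here the expectation is taken by Monte Carlo:
#' intakes are simulated from the fitted usual-intake distribution and
#' `rho` is evaluated against the requirement CDF (fitted lognormal by
#' default, empirical Monte Carlo CDF optionally; the two agree within Monte
#' Carlo error when the lognormal summary is adequate).
#'
#' @param intake An [intake_distribution].
#' @param requirement A `requirement_distribution` (see
#'   [derive_requirement]).
#' @param n_sim Number of simulated intakes; at least 1e5.
#' @param seed Integer seed for the intake draws.
#' @param req_cdf `"fitted"` (default) or `"empirical"`.
#' @return Risk in percent, with attribute `mc_se` (Monte Carlo standard
#'   error, percent).
#' @export
risk_of_inadequacy <- function(intake, requirement, n_sim = 1e5, seed = 1L,
                               req_cdf = c("fitted", "empirical")) {
  req_cdf <- match.arg(req_cdf)
  stopifnot(inherits(intake, "intake_distribution"),
            inherits(requirement, "requirement_distribution"))
  if (n_sim < 1e5) stop("'n_sim' must be >= 1e5")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  x <- intake_draws(intake, n_sim)
  rho <- if (req_cdf == "fitted") {
    1 - stats::plnorm(x, requirement$fitted$mu, requirement$fitted$sigma)
  } else {
    1 - stats::ecdf(requirement$samples)(x)
  }
  structure(100 * mean(rho),
            mc_se = 100 * stats::sd(rho) / sqrt(n_sim))
}

#' Population risk of inadequate intake (EAR cut-point method)
#'
#' The cut-point method approximates the probability approach by the
#' proportion of the population with usual intake below the EAR.  It is
#' accurate when requirement and intake are symmetric, independent, and the
#' intake variance dominates the requirement variance; it is provided for
#' comparison with [risk_of_inadequacy].
#'
#' @param intake An [intake_distribution].
#' @param ear EAR in mg/d (> 0).
#' @return Risk in percent.
#' @export
risk_of_inadequacy_cutpoint <- function(intake, ear) {
  stopifnot(inherits(intake, "intake_distribution"))
  if (ear <= 0) stop("'ear' must be positive")
  100 * intake_cdf(intake, ear)
}

#' Population risk of exceeding the tolerable upper level
#'
#' Probability that usual intake plus the scenario's fortification and
#' supplementation doses exceeds the TUL, computed in closed form from the
#' shifted CDF: `P(X + doses > TUL) = 1 - F_X(TUL - doses)`.
#'
#' @param intake An [intake_distribution] (baseline, before scenario doses).
#' @param scenario A [risk_scenario].
#' @return Risk in percent.
#' @export
risk_of_excess <- function(intake, scenario = risk_scenario()) {
  stopifnot(inherits(intake, "intake_distribution"),
            inherits(scenario, "risk_scenario"))
  if (scenario$tul <= 0) stop("'tul' must be positive")
  shifted <- shift_intake(intake, scenario$fortification +
                            scenario$supplementation)
  100 * (1 - intake_cdf(shifted, scenario$tul))
}

#' Per-group risk table under baseline and intervention scenarios
#'
#' For each population group: baseline risk of inadequacy (probability
#' approach against the supplied requirement distribution, plus an optional
#' cut-point comparison against a reference EAR such as the earlier 21 mg/d
#' recommendation), risk of inadequacy after each scenario's dose is added to
#' intake, and risk of exceeding the TUL under each scenario.  A summary of
#' the cross-group median and IQR of each risk column is attached (linear
#' interpolation quantiles, so with 35 groups the median is the 18th order
#' statistic).
#'
#' @param intakes List of [intake_distribution] objects.
#' @param requirement A `requirement_distribution`.
#' @param scenarios List of [risk_scenario] objects; defaults to fortification
#'   alone (10 mg/d) and fortification plus supplementation (10 + 14 mg/d).
#' @param n_sim,seed Monte Carlo controls for the probability approach; each
#'   group/scenario cell uses an independent substream derived from `seed`.
#' @param reference_ear Optional reference EAR (mg/d) for a cut-point
#'   comparison column (`NA` to omit); default 21.
#' @param req_cdf Passed to [risk_of_inadequacy].
#' @return A data frame of class `risk_table` with one row per group and a
#'   `"summary"` attribute (data frame of median, q25, q75 per risk column,
#'   both raw and rounded to integer percent).
#' @export
scenario_table <- function(intakes, requirement,
                           scenarios = list(
                             risk_scenario("fortification", 10, 0),
                             risk_scenario("fortification+supplementation",
                                           10, 14)),
                           n_sim = 1e5, seed = 1L, reference_ear = 21,
                           req_cdf = c("fitted", "empirical")) {
  req_cdf <- match.arg(req_cdf)
  if (length(intakes) < 1L) stop("need at least one intake group")
  stopifnot(all(vapply(intakes, inherits, logical(1), "intake_distribution")))
  scen_names <- vapply(scenarios, `[[`, character(1), "name")
  rows <- vector("list", length(intakes))
  for (i in seq_along(intakes)) {
    g <- intakes[[i]]
    # independent, reproducible substream per cell
    cell_seed <- function(j) (as.integer(seed) + 7919L * i + 104729L * j) %%
      .Machine$integer.max
    row <- list(group_id = g$group_id)
    if (!is.na(reference_ear)) {
      row$risk_cutpoint_ref <- risk_of_inadequacy_cutpoint(g, reference_ear)
    }
    row$risk_inadequate_baseline <- as.numeric(
      risk_of_inadequacy(g, requirement, n_sim, cell_seed(0L), req_cdf))
    for (j in seq_along(scenarios)) {
      sc <- scenarios[[j]]
      dosed <- shift_intake(g, sc$fortification + sc$supplementation)
      row[[paste0("risk_inadequate_", scen_names[j])]] <- as.numeric(
        risk_of_inadequacy(dosed, requirement, n_sim, cell_seed(j), req_cdf))
      row[[paste0("risk_excess_", scen_names[j])]] <- risk_of_excess(g, sc)
    }
    rows[[i]] <- as.data.frame(row, stringsAsFactors = FALSE,
                               check.names = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "summary") <- summarize_risk_table(out)
  class(out) <- c("risk_table", "data.frame")
  out
}

#' Cross-group median and IQR of each risk column
#'
#' @param table A risk table (any data frame whose numeric columns are
#'   per-group risks in percent).
#' @return Data frame with columns `column, median, q25, q75` (linear
#'   interpolation quantiles).
#' @export
summarize_risk_table <- function(table) {
  num <- vapply(table, is.numeric, logical(1))
  cols <- names(table)[num]
  do.call(rbind, lapply(cols, function(cn) {
    q <- stats::quantile(table[[cn]], c(0.5, 0.25, 0.75), names = FALSE,
                         type = 7)
    data.frame(column = cn, median = q[1], q25 = q[2], q75 = q[3],
               stringsAsFactors = FALSE)
  }))
}

#' @export
print.risk_table <- function(x, digits = 0, ...) {
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], round, digits = digits)
  print(df, ...)
  cat("\nCross-group summary (percent):\n")
  s <- attr(x, "summary")
  s[-1] <- lapply(s[-1], round, digits = digits)
  print(s, row.names = FALSE)
  invisible(x)
}

#' Published state-level risk estimates for India
#'
#' Returns the packaged table of previously published state/union-territory
#' risk estimates (integer percent): risk of inadequate intake under the
#' earlier 21 mg/d reference and under the newer EAR, after fortification
#' (10 mg/d) and after fortification plus supplementation (24 mg/d), and risk
#' of exceeding the 45 mg/d TUL under both interventions.  Useful as worked
#' input data for [summarize_risk_table] and for benchmarking synthetic
#' surveys.
#'
#' @return A data frame with 35 rows.
#' @examples
#' summarize_risk_table(state_risk_estimates())
#' @export
state_risk_estimates <- function() {
  utils::read.csv(system.file("extdata", "state_risk_estimates.csv",
                              package = "ironear"),
                  stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write a risk table (rounded to integer percent) as CSV
#'
#' @param table A `risk_table`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_risk_table <- function(table, path) {
  df <- as.data.frame(table)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) round(v))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
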