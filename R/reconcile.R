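#' Wealth-relative temptation
#'
#' The classic temptation parameter is the ratio of the unilateral
#' defection payoff to the mutual-cooperation payoff.  Its wealth-relative
#' form divides additionally by a wealth weighting `w` (a player's initial
#' wealth divided by 10), so the same payoff pair tempts a poor player
#' more than a wealthy one: `b = defect_payoff / (cooperate_payoff * w)`.
#'
#' @param defect_payoff Defector-vs-cooperator payoff (D|C), tokens.
#' @param cooperate_payoff Mutual cooperation payoff (C|C), tokens (> 0).
#' @param w Wealth weighting (> 0); 1 for the wealthy (initial wealth 10),
#'   0.4 for the poor (initial wealth 4).
#' @return The dimensionless temptation `b`.
#' @examples
#' wealth_relative_temptation(2.2, 1.1, 1)    # 2.0
#' wealth_relative_temptation(1.2, 1.1, 0.4)  # 2.73: poor players are
#'                                            # tempted even by mild payoffs
#' @export
wealth_relative_temptation <- function(defect_payoff, cooperate_payoff, w) {
  if (any(cooperate_payoff <= 0) || any(w <= 0)) {
    stop("cooperate_payoff and w must be positive")
  }
  defect_payoff / (cooperate_payoff * w)
}

#' Temptation-response curve
#'
#' A mapping from the temptation parameter `b` to the equilibrium density
#' of cooperators, as produced by spatial Prisoner's Dilemma simulations on
#' a given network model.  Curves are consumed from two-column tables
#' (`b`, `density`); the package never embeds digitised third-party curve
#' data — supply curves from the original source, or generate synthetic
#' ones with [generate_curve_fixture()].
#'
#' @param b Strictly increasing temptation knots.
#' @param density Cooperator densities in \[0, 1\] at the knots.
#' @param name Curve label (e.g. the network model it came from).
#' @return An object of class `farmers_curve`.
#' @seealso [predict_density()], [read_curve()]
#' @export
temptation_curve <- function(b, density, name = "curve") {
  b <- as.numeric(b); density <- as.numeric(density)
  if (length(b) != length(density)) stop("b and density lengths differ")
  if (length(b) < 2L) stop("a curve needs at least 2 points")
  if (any(diff(b) <= 0)) stop("b knots must be strictly increasing")
  if (any(density < 0 | density > 1)) stop("densities must lie in [0, 1]")
  structure(list(b = b, density = density, name = as.character(name)),
            class = "farmers_curve")
}

#' @export
print.farmers_curve <- function(x, ...) {
  cat(sprintf("Temptation curve '%s': %d knots, b in [%.3g, %.3g], density %.3g..%.3g\n",
              x$name, length(x$b), min(x$b), max(x$b),
              x$density[[1]], x$density[[length(x$density)]]))
  invisible(x)
}

#' Read / write a temptation curve as CSV
#'
#' CSV schema: columns `b`, `density`; one file per network model.
#'
#' @param path File path.
#' @param name Curve label; defaults to the file name.
#' @return [read_curve()] returns a `farmers_curve`.
#' @export
read_curve <- function(path, name = NULL) {
  df <- utils::read.csv(path)
  if (!all(c("b", "density") %in% names(df))) {
    stop("curve CSV needs columns: b, density")
  }
  temptation_curve(df$b, df$density,
                   name = if (is.null(name)) {
                     sub("\\.csv$", "", basename(path))
                   } else name)
}

#' @rdname read_curve
#' @param curve A `farmers_curve`.
#' @export
write_curve <- function(curve, path) {
  stopifnot(inherits(curve, "farmers_curve"))
  utils::write.csv(data.frame(b = curve$b, density = curve$density),
                   path, row.names = FALSE)
  invisible(path)
}

#' Predict cooperator density from a temptation value
#'
#' Piecewise-linear interpolation of the curve at `b`.  Outside the knot
#' range the prediction clamps to the terminal densities rather than
#' extrapolating: the curves are bounded and extrapolating through a
#' near-discontinuity would be meaningless.
#'
#' @param curve A [temptation_curve()].
#' @param b Temptation value(s).
#' @return Predicted cooperator density, a fraction in \[0, 1\].
#' @examples
#' crv <- temptation_curve(c(1, 1.2, 2), c(0.95, 0.85, 0.2))
#' predict_density(crv, 1.1)  # 0.90, the linear midpoint
#' @export
predict_density <- function(curve, b) {
  stopifnot(inherits(curve, "farmers_curve"))
  stats::approx(curve$b, curve$density, xout = b, method = "linear",
                rule = 2, ties = "ordered")$y
}

#' Country records for the reconciliation pipeline
#'
#' Validates a country table: one row per country with the per-capita
#' wealth basis (USD per year, e.g. per-capita GDP of the year preceding
#' the experiment), the monetary stake at risk, the days-per-year divisor
#' used to express the wealth basis as a daily wage (250 working days, or
#' 365 calendar days), and the observed fraction of the stake invested in
#' non-individual accounts.
#'
#' @param df A data frame with columns `name`, `wealth_basis_usd`,
#'   `stake_usd`, `divisor`, `observed_fraction`.
#' @param strict_divisor Require divisor in \{250, 365\} (default).
#' @return The validated data frame, classed `farmers_countries`.
#' @seealso [normalized_temptation()], [correlate_predictions()]
#' @export
country_records <- function(df, strict_divisor = TRUE) {
  need <- c("name", "wealth_basis_usd", "stake_usd", "divisor",
            "observed_fraction")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("country table missing columns: ",
                         paste(miss, collapse = ", "))
  if (any(df$wealth_basis_usd <= 0)) stop("wealth_basis_usd must be positive")
  if (any(df$stake_usd < 0)) stop("stake_usd must be nonnegative")
  if (strict_divisor && !all(df$divisor %in% c(250, 365))) {
    stop("divisor must be 250 (workdays) or 365 (calendar days)")
  }
  if (any(df$observed_fraction < 0 | df$observed_fraction > 1)) {
    stop("observed_fraction must lie in [0, 1]")
  }
  class(df) <- c("farmers_countries", class(df))
  df
}

#' GDP-normalised temptation of a monetary stake
#'
#' Expresses the temptation to keep a sure monetary stake relative to a
#' country's wealth: the per-capita wealth basis divided by `divisor` days
#' gives a daily wage, and `b = 1 + stake / daily_wage`.  A zero stake
#' gives `b = 1`, the no-temptation limit; the same stake is a greater
#' temptation in a poorer country.
#'
#' @param wealth_basis Per-capita wealth basis, USD per year (or a
#'   [country_records()] table as first argument).
#' @param stake Stake at risk, USD.
#' @param divisor Days per year: 250 (workdays, the default basis) or 365.
#' @return Temptation value(s) `b >= 1`.
#' @examples
#' normalized_temptation(3750, stake = 15, divisor = 250)  # 2: a full day's wage
#' @export
normalized_temptation <- function(wealth_basis, stake = 15, divisor = 250) {
  if (inherits(wealth_basis, "farmers_countries") ||
      (is.data.frame(wealth_basis) && "wealth_basis_usd" %in% names(wealth_basis))) {
    df <- wealth_basis
    return(normalized_temptation(df$wealth_basis_usd, df$stake_usd,
                                 df$divisor))
  }
  if (any(wealth_basis <= 0) || any(divisor <= 0)) {
    stop("wealth_basis and divisor must be positive")
  }
  if (any(stake < 0)) stop("stake must be nonnegative")
  1 + stake / (wealth_basis / divisor)
}

#' Correlate curve predictions with observed cooperation
#'
#' The reconciliation pipeline: each country's stake is normalised to a
#' temptation value ([normalized_temptation()]), the curve predicts a
#' cooperator density at that temptation ([predict_density()]), and the
#' predictions are compared with the observed other-investment fractions.
#' Reported are the Pearson correlation `r` between predicted and observed
#' series and the displacement constant, the mean of observed minus
#' predicted — the systematic gap between curve predictions and behaviour,
#' whether over-prediction of cooperation or an amount withheld by
#' cooperators.
#'
#' @param curve A [temptation_curve()].
#' @param countries A [country_records()] table (>= 3 rows).
#' @return A list of class `farmers_reconciliation`: `table` (per country:
#'   `name`, `b`, `predicted`, `observed`, `residual`), `r`,
#'   `displacement`, `curve`.
#' @examples
#' fx <- generate_curve_fixture(seed = 1, noise_sd = 0)
#' rec <- correlate_predictions(fx$curve, fx$countries)
#' rec$r  # 1 at zero noise
#' @export
correlate_predictions <- function(curve, countries) {
  stopifnot(inherits(curve, "farmers_curve"))
  countries <- country_records(as.data.frame(countries))
  if (nrow(countries) < 3L) stop("need at least 3 countries")
  b <- normalized_temptation(countries)
  predicted <- predict_density(curve, b)
  observed <- countries$observed_fraction
  if (stats::sd(predicted) == 0 || stats::sd(observed) == 0) {
    stop("zero variance in predicted or observed series")
  }
  tab <- data.frame(name = countries$name, b = b, predicted = predicted,
                    observed = observed, residual = observed - predicted)
  structure(list(table = tab,
                 r = stats::cor(predicted, observed),
                 displacement = mean(observed - predicted),
                 curve = curve$name),
            class = "farmers_reconciliation")
}

#' @export
print.farmers_reconciliation <- function(x, ...) {
  cat(sprintf("Reconciliation vs curve '%s': r = %.3f, displacement = %.3f\n",
              x$curve, x$r, x$displacement))
  print(x$table, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Reconcile a set of curves against one country table
#'
#' @param curves A list of [temptation_curve()]s.
#' @param countries A [country_records()] table.
#' @return A data frame, one row per curve, with columns `curve` and `r`
#'   (and `displacement`) — the correlation-summary table shape.
#' @export
reconcile_curves <- function(curves, countries) {
  rows <- lapply(curves, function(crv) {
    rec <- correlate_predictions(crv, countries)
    data.frame(curve = rec$curve, r = rec$r, displacement = rec$displacement)
  })
  do.call(rbind, rows)
}
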