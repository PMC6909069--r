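#' Generate a synthetic temptation curve and country table
#'
#' Builds a strictly decreasing synthetic cooperator-density curve over
#' temptation `b` in \[1, 2\] together with a synthetic country table whose
#' observed other-investment fractions are the curve's own predictions
#' plus a known displacement constant and seeded Gaussian noise.  The
#' fixture makes the whole reconciliation pipeline testable offline: at
#' zero noise [correlate_predictions()] must recover a Pearson r of 1 and the
#' injected displacement exactly, and increasing noise degrades `r` in
#' expectation.
#'
#' Country wealth bases are drawn so that every normalised temptation
#' falls strictly inside the curve's knot range (no clamping), mirroring
#' the published range of roughly 1.06-1.55 for a day's-wage stake across
#' six countries.
#'
#' @param seed Integer seed; the fixture is a pure function of its
#'   arguments.
#' @param knots Number of curve knots (>= 2).
#' @param n_countries Number of synthetic countries (>= 3).
#' @param noise_sd Standard deviation of the observation noise.
#' @param displacement Constant added to predictions to form observations
#'   (negative: behaviour falls short of prediction).
#' @return A list with `curve` (a [temptation_curve()]), `countries`
#'   (a [country_records()] table) and `displacement` (the injected
#'   constant).
#' @examples
#' fx <- generate_curve_fixture(seed = 7, noise_sd = 0)
#' correlate_predictions(fx$curve, fx$countries)$displacement  # -0.1
#' @export
generate_curve_fixture <- function(seed = 1, knots = 6, n_countries = 6,
                                   noise_sd = 0, displacement = -0.1) {
  knots <- as.integer(knots); n_countries <- as.integer(n_countries)
  if (knots < 2L) stop("need at least 2 knots")
  if (n_countries < 3L) stop("need at least 3 countries")
  set.seed(as.integer(seed))
  b <- seq(1, 2, length.out = knots)
  # strictly decreasing from ~0.95 toward ~0.2, random step sizes
  steps <- stats::runif(knots - 1L, 0.5, 1.5)
  density <- 0.95 - cumsum(c(0, steps)) / sum(steps) * 0.75
  curve <- temptation_curve(b, density, name = sprintf("synthetic-%d", seed))

  # wealth bases chosen so b = 1 + stake/(basis/divisor) stays inside (1, 2)
  basis <- exp(stats::runif(n_countries, log(3800), log(40000)))
  countries <- data.frame(
    name = sprintf("country%02d", seq_len(n_countries)),
    wealth_basis_usd = basis,
    stake_usd = 15,
    divisor = 250,
    observed_fraction = NA_real_)
  predicted <- predict_density(curve, normalized_temptation(countries))
  obs <- predicted + displacement + stats::rnorm(n_countries, 0, noise_sd)
  countries$observed_fraction <- pmin(1, pmax(0, obs))
  list(curve = curve, countries = country_records(countries),
       displacement = displacement)
}

#' Write the synthetic reconciliation fixture to CSV
#'
#' @param dir Output directory.
#' @inheritParams generate_curve_fixture
#' @return Invisibly, the paths of the two files written
#'   (`curve_synthetic.csv`, `countries_synthetic.csv`).
#' @export
write_curve_fixture <- function(dir, seed = 1, knots = 6, n_countries = 6,
                                noise_sd = 0, displacement = -0.1) {
  fx <- generate_curve_fixture(seed, knots, n_countries, noise_sd,
                               displacement)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  curve_path <- file.path(dir, "curve_synthetic.csv")
  countries_path <- file.path(dir, "countries_synthetic.csv")
  write_curve(fx$curve, curve_path)
  utils::write.csv(as.data.frame(fx$countries)[, c(
    "name", "wealth_basis_usd", "stake_usd", "divisor", "observed_fraction")],
    countries_path, row.names = FALSE)
  invisible(list(curve = curve_path, countries = countries_path))
}
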