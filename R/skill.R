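#' Paired model-observation series
#'
#' @param model,obs numeric vectors of matched model values `M_i` and
#'   observations `O_i` (no missing values inside pairs; pairs with an `NA`
#'   on either side are dropped).
#' @param time optional timestamps.
#' @param variable optional variable name carried through reports.
#' @param units optional unit string.
#' @return data.frame of class `paired_series` with columns `time`,
#'   `model`, `obs`.
#' @export
paired_series <- function(model, obs, time = seq_along(model),
                          variable = NA_character_, units = NA_character_) {
  stopifnot(length(model) == length(obs), length(time) == length(model))
  keep <- is.finite(model) & is.finite(obs)
  out <- data.frame(time = time[keep], model = as.numeric(model[keep]),
                    obs = as.numeric(obs[keep]))
  structure(out, class = c("paired_series", "data.frame"),
            variable = variable, units = units)
}

.sd_obs <- function(x, population = FALSE) {
  if (population) sqrt(mean((x - mean(x))^2)) else stats::sd(x)
}

#' Percentage model bias
#'
#' `PB = 100 * sum(O - M) / sum(O)`: the model error normalized by the
#' observations, in percent. The sign convention makes overestimation
#' negative (model above the observations gives PB < 0).
#'
#' @param p a [paired_series()].
#' @return PB in percent.
#' @export
percentage_bias <- function(p) {
  so <- sum(p$obs)
  if (so == 0) stop("percentage bias undefined: observations sum to zero",
                    call. = FALSE)
  100 * sum(p$obs - p$model) / so
}

#' Cost function (goodness of fit)
#'
#' `CF = mean(|M - O|) / sd(O)`: the mean absolute error normalized by the
#' observations' standard deviation. Non-dimensional, zero only for a
#' perfect fit, and invariant to scaling both series by a common factor.
#'
#' @param p a [paired_series()].
#' @param population use the population (1/n) standard deviation instead of
#'   the sample (1/(n-1)) default.
#' @return CF (dimensionless, >= 0).
#' @export
cost_function <- function(p, population = FALSE) {
  s <- .sd_obs(p$obs, population)
  if (!is.finite(s) || s == 0) {
    stop("cost function undefined: zero observation variance", call. = FALSE)
  }
  mean(abs(p$model - p$obs)) / s
}

#' OSPAR rating of a cost function
#'
#' Model results are rated very good (cost function in \[0, 1\]), good
#' ((1, 2\]), reasonable ((2, 3\]) and poor (above 3); bin edges belong to
#' the lower class.
#'
#' @param CF cost function value(s), >= 0.
#' @return factor with levels `very good`, `good`, `reasonable`, `poor`.
#' @examples
#' classify_ospar(0.27)  # "very good"
#' @export
classify_ospar <- function(CF) {
  if (any(!is.finite(CF)) || any(CF < 0)) {
    stop("CF must be finite and >= 0", call. = FALSE)
  }
  cut(CF, breaks = c(-Inf, 1, 2, 3, Inf),
      labels = c("very good", "good", "reasonable", "poor"), right = TRUE)
}

#' Average absolute error
#'
#' `AAE = mean(|M - O|)`: the mean magnitude of the discrepancies,
#' regardless of their direction, in the units of the variable.
#'
#' @param p a [paired_series()].
#' @return AAE (variable units).
#' @export
aae <- function(p) mean(abs(p$model - p$obs))

#' Root mean square deviation
#'
#' `RMSD = sqrt(mean((M - O)^2))`, in the units of the variable. Always at
#' least as large as the AAE.
#'
#' @param p a [paired_series()].
#' @return RMSD (variable units).
#' @export
rmsd <- function(p) sqrt(mean((p$model - p$obs)^2))

#' Pearson correlation between model and observations
#'
#' @param p a [paired_series()] with at least two pairs and non-constant
#'   series.
#' @return R in `[-1, 1]`.
#' @export
correlation <- function(p) {
  if (nrow(p) < 2L) stop("correlation needs n >= 2", call. = FALSE)
  if (stats::sd(p$model) == 0 || stats::sd(p$obs) == 0) {
    stop("correlation undefined for constant series", call. = FALSE)
  }
  stats::cor(p$model, p$obs)
}

#' Target-diagram coordinates
#'
#' Normalized statistics for a target diagram: the ordinate is the
#' normalized bias `Bias* = (mean(M) - mean(O)) / sd(O)` (overestimating
#' models plot above the origin) and the abscissa is the signed normalized
#' unbiased RMSD `uRMSD* = sign(sd(M) - sd(O)) * uRMSD / sd(O)`, where
#' `uRMSD` is the centred (bias-removed) RMSD; models with more variance
#' than the observations plot to the right. The distance from the origin is
#' the total normalized RMSD: `Bias*^2 + uRMSD*^2 = (RMSD / sd(O))^2`.
#'
#' @param p a [paired_series()].
#' @param population use population standard deviations.
#' @return named numeric `c(uRMSD_star, Bias_star)`.
#' @export
target_diagram_coords <- function(p, population = FALSE) {
  s_o <- .sd_obs(p$obs, population)
  if (!is.finite(s_o) || s_o == 0) {
    stop("target coordinates undefined: zero observation variance",
         call. = FALSE)
  }
  bias <- mean(p$model) - mean(p$obs)
  urmsd <- sqrt(mean(((p$model - mean(p$model)) -
                        (p$obs - mean(p$obs)))^2))
  s_m <- .sd_obs(p$model, population)
  c(uRMSD_star = sign(s_m - s_o) * urmsd / s_o, Bias_star = bias / s_o)
}

#' Full skill report for one paired series
#'
#' Assembles means, standard deviations, cost function with OSPAR rating,
#' percentage bias, AAE, RMSD, correlation and the normalized
#' target-diagram coordinates from shared intermediate statistics. The
#' decomposition `RMSD^2 = bias^2 + uRMSD^2` (and its normalized form)
#' holds to numerical precision.
#'
#' @param p a [paired_series()].
#' @param population use population standard deviations.
#' @return list of class `skill_report`.
#' @export
skill_report <- function(p, population = FALSE) {
  stopifnot(inherits(p, "paired_series"))
  cf <- cost_function(p, population)
  tg <- target_diagram_coords(p, population)
  r <- tryCatch(correlation(p), error = function(e) NA_real_)
  structure(list(
    variable = attr(p, "variable"), units = attr(p, "units"),
    n = nrow(p),
    mean_obs = mean(p$obs), mean_model = mean(p$model),
    std_obs = .sd_obs(p$obs, population),
    std_model = .sd_obs(p$model, population),
    CF = cf, PB = percentage_bias(p), AAE = aae(p), RMSD = rmsd(p),
    R = r,
    Bias_star = tg[["Bias_star"]], uRMSD_star = tg[["uRMSD_star"]],
    ospar_rating = as.character(classify_ospar(cf))
  ), class = "skill_report")
}

#' @export
print.skill_report <- function(x, digits = 3, ...) {
  cat("<skill_report>", if (!is.na(x$variable)) x$variable, "n =", x$n, "\n")
  nums <- unlist(x[c("mean_obs", "mean_model", "std_obs", "std_model",
                     "CF", "PB", "AAE", "RMSD", "R",
                     "Bias_star", "uRMSD_star")])
  print(round(nums, digits))
  cat("OSPAR rating:", x$ospar_rating, "\n")
  invisible(x)
}

#' @rdname skill_report
#' @export
as.data.frame.skill_report <- function(x, ...) {
  data.frame(x[!vapply(x, is.null, TRUE)], stringsAsFactors = FALSE)
}

#' Monthly climatology of a time series
#'
#' Groups a dated series by calendar month and reports the monthly mean and
#' the within-month standard deviation (the error bar of climatology
#' plots).
#'
#' @param date dates (coercible with [as.Date()]).
#' @param value numeric values.
#' @return data.frame `month` (1-12), `n`, `mean`, `sd` (0 for months with
#'   a single value; `NA` row absent for empty months).
#' @export
monthly_climatology <- function(date, value) {
  stopifnot(length(date) == length(value))
  m <- as.integer(format(as.Date(date), "%m"))
  keep <- is.finite(value)
  m <- m[keep]; value <- value[keep]
  months <- sort(unique(m))
  out <- data.frame(
    month = months,
    n = vapply(months, function(k) sum(m == k), 0L),
    mean = vapply(months, function(k) mean(value[m == k]), 0),
    sd = vapply(months, function(k) {
      v <- value[m == k]
      if (length(v) < 2L) 0 else stats::sd(v)
    }, 0))
  out
}

#' Match model and observation files into paired series
#'
#' Reads two CSV files with `timestamp, variable, value` columns and pairs
#' each observation with the nearest-in-time model value within a
#' tolerance.
#'
#' @param model_file,obs_file CSV paths.
#' @param vars variables to pair (default: all shared).
#' @param tolerance_days maximum |model time - obs time| for a match.
#' @return named list of [paired_series()].
#' @export
match_series <- function(model_file, obs_file, vars = NULL,
                         tolerance_days = 1) {
  rd <- function(f) {
    df <- utils::read.csv(f, stringsAsFactors = FALSE)
    need <- c("timestamp", "variable", "value")
    if (!all(need %in% names(df))) {
      stop(f, " must have columns ", paste(need, collapse = ", "),
           call. = FALSE)
    }
    df$timestamp <- as.numeric(as.Date(df$timestamp))
    df
  }
  mod <- rd(model_file)
  obs <- rd(obs_file)
  if (is.null(vars)) vars <- intersect(unique(mod$variable),
                                       unique(obs$variable))
  out <- list()
  for (v in vars) {
    mo <- mod[mod$variable == v, ]
    ob <- obs[obs$variable == v, ]
    if (!nrow(mo) || !nrow(ob)) next
    idx <- vapply(ob$timestamp, function(tt) which.min(abs(mo$timestamp - tt)),
                  0L)
    keep <- abs(mo$timestamp[idx] - ob$timestamp) <= tolerance_days
    if (!any(keep)) next
    out[[v]] <- paired_series(mo$value[idx[keep]], ob$value[keep],
                              time = ob$timestamp[keep], variable = v)
  }
  out
}
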