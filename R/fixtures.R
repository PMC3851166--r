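# Synthetic fixture generators: small, seeded, text-only datasets shaped
# like the monitoring inputs the forcing loaders expect, plus synthetic
# observation series for exercising the skill statistics.

#' Generate a synthetic river monitoring fixture
#'
#' Seeded daily series shaped like the raw monitoring files consumed by
#' [load_river_series()].
#' \describe{
#'   \item{rhone}{`date`, `discharge` and the nine raw chemistry columns.
#'     Discharge follows a seasonal cycle (winter-high, around a 1700 m3/s
#'     mean) with lognormal day-to-day variability and occasional flood
#'     spikes. Nutrients covary weakly (negatively) with discharge
#'     (dilution), and the NO3:PO4 ratio stays in the strongly P-deficient
#'     65-80 range characteristic of the river.}
#'   \item{wwtp}{`date`, `discharge` (around 1.9 m3/s), daily `NO3`, `NH4`.}
#'   \item{urban}{`date`, `discharge`: a small stream that is near-dry most
#'     of the year and flashes during rain events.}
#' }
#'
#' @param seed integer RNG seed.
#' @param n_days number of daily rows.
#' @param type `"rhone"`, `"wwtp"` or `"urban"`.
#' @param start first date.
#' @param file optional path; when given the fixture is written as CSV and
#'   the path returned invisibly.
#' @return data.frame (invisibly, if `file` is given).
#' @export
make_river_fixture <- function(seed, n_days = 365,
                               type = c("rhone", "wwtp", "urban"),
                               start = as.Date("2008-01-01"), file = NULL) {
  type <- match.arg(type)
  stopifnot(n_days >= 2)
  df <- .with_seed(seed, {
    date <- seq(as.Date(start), by = "day", length.out = n_days)
    doy <- as.integer(format(date, "%j"))
    phase <- cos(2 * pi * (doy - 15) / 365)  # +1 in mid-January
    if (type == "rhone") {
      # winter-high discharge with lognormal noise and a few flood spikes
      q <- (1700 + 600 * phase) * exp(stats::rnorm(n_days, 0, 0.18))
      n_fl <- max(1L, round(n_days / 180))
      at <- sample.int(n_days, n_fl)
      for (i in at) {
        sel <- i:min(n_days, i + 5L)
        q[sel] <- q[sel] * (3.5 * exp(-(seq_along(sel) - 1) / 2) + 1)
      }
      dil <- (1700 / q)^0.3   # mild dilution of nutrients at high flow
      no3 <- 110 * dil * exp(stats::rnorm(n_days, 0, 0.10))
      po4 <- no3 / stats::runif(n_days, 65, 80)
      data.frame(
        date = date,
        discharge = round(q, 1),
        NO3 = round(no3, 2),
        NH4 = round(3.0 * dil * exp(stats::rnorm(n_days, 0, 0.2)), 3),
        PO4 = round(po4, 4),
        DOC = round(190 * exp(stats::rnorm(n_days, 0, 0.12)), 1),
        DON = round(9.5 * exp(stats::rnorm(n_days, 0, 0.12)), 2),
        DOP = round(0.16 * exp(stats::rnorm(n_days, 0, 0.15)), 4),
        POC = round(95 * (q / 1700)^0.8 * exp(stats::rnorm(n_days, 0, 0.2)), 1),
        PON = round(11 * (q / 1700)^0.8 * exp(stats::rnorm(n_days, 0, 0.2)), 2),
        POP = round(0.9 * (q / 1700)^0.8 * exp(stats::rnorm(n_days, 0, 0.2)), 3)
      )
    } else if (type == "wwtp") {
      data.frame(
        date = date,
        discharge = round(1.9 * exp(stats::rnorm(n_days, 0, 0.08)), 3),
        NO3 = round(120 * exp(stats::rnorm(n_days, 0, 0.15)), 1),
        NH4 = round(1500 * exp(stats::rnorm(n_days, 0, 0.20)), 0)
      )
    } else {
      # near-dry base flow with rain-driven flashes
      q <- rep(0.02, n_days)
      wet <- stats::rbinom(n_days, 1, 0.08) == 1
      q[wet] <- q[wet] + stats::rlnorm(sum(wet), log(0.8), 0.6)
      data.frame(date = date, discharge = round(q, 3))
    }
  })
  if (!is.null(file)) {
    utils::write.csv(df, file, row.names = FALSE, quote = FALSE)
    return(invisible(df))
  }
  df
}

#' Generate a synthetic atmospheric deposition fixture
#'
#' Seeded collector data shaped for [atmospheric_deposition_flux()]: a dry
#' series of roughly fortnightly accumulated totals (first row marks
#' deployment), a wet series of per-event rain concentrations, and a daily
#' rainfall series with autumn/spring-weighted wet days.
#'
#' @param seed integer RNG seed.
#' @param n_days covered period (days).
#' @param start first date.
#' @return list `dry`, `wet`, `rainfall` (data.frames).
#' @export
make_deposition_fixture <- function(seed, n_days = 180,
                                    start = as.Date("2008-03-01")) {
  stopifnot(n_days >= 30)
  .with_seed(seed, {
    date <- seq(as.Date(start), by = "day", length.out = n_days)
    doy <- as.integer(format(date, "%j"))
    # sample roughly every 14 d with a little jitter
    picks <- unique(pmin(cumsum(c(1, pmax(10, round(14 + stats::rnorm(
      ceiling(n_days / 10), 0, 2))))), n_days))
    dd <- date[picks]
    span <- c(NA, diff(as.numeric(dd)))
    dry <- data.frame(
      date = dd,
      NO3 = round(c(0, span[-1] * 16 * exp(stats::rnorm(length(dd) - 1,
                                                        0, 0.3))), 1),
      NH4 = round(c(0, span[-1] * 21 * exp(stats::rnorm(length(dd) - 1,
                                                        0, 0.3))), 1),
      PO4 = round(c(0, span[-1] * 0.5 * exp(stats::rnorm(length(dd) - 1,
                                                         0, 0.4))), 2)
    )
    wet_p <- 0.10 + 0.08 * abs(cos(2 * pi * (doy - 120) / 365))
    rain_day <- stats::rbinom(n_days, 1, wet_p) == 1
    rainfall <- data.frame(
      date = date,
      rain_mm = ifelse(rain_day,
                       round(stats::rlnorm(n_days, log(6), 0.8), 1), 0)
    )
    ev <- which(rain_day)
    ev <- ev[seq(1, length(ev), by = max(1L, length(ev) %/% 12L))]
    wet <- data.frame(
      date = date[ev],
      NO3 = round(20 * exp(stats::rnorm(length(ev), 0, 0.4)), 1),
      NH4 = round(25 * exp(stats::rnorm(length(ev), 0, 0.4)), 1),
      PO4 = round(0.4 * exp(stats::rnorm(length(ev), 0, 0.5)), 3)
    )
    list(dry = dry, wet = wet, rainfall = rainfall)
  })
}

#' Generate a synthetic observation fixture from a model run
#'
#' Produces a monitoring-shaped observation table (`timestamp`, `depth_m`,
#' `variable`, `value`, `below_detection`) by sampling a model trajectory
#' at a sparse station schedule and perturbing it:
#' \itemize{
#'   \item sampling at fortnightly (or custom) intervals and up to three
#'     nominal depths (for box runs all depths see the same water);
#'   \item multiplicative lognormal noise of standard deviation `noise_cv`
#'     (zero gives an exact closed loop: the skill statistics then report a
#'     perfect fit);
#'   \item left-censoring of phosphate at the detection limit: values below
#'     `po4_detection` are reported at the limit with
#'     `below_detection = TRUE`.
#' }
#'
#' @param traj a [run_box()] trajectory.
#' @param seed integer RNG seed.
#' @param vars variables to observe.
#' @param every_days sampling interval.
#' @param depths_m nominal sampling depths.
#' @param noise_cv lognormal noise coefficient of variation (0 = none).
#' @param po4_detection phosphate detection limit (umol/L).
#' @param start_date calendar date mapped to trajectory time 0.
#' @param file optional CSV path.
#' @return data.frame (invisibly, if `file` is given).
#' @export
make_obs_fixture <- function(traj, seed, vars = c("Chla", "NO3", "PO4"),
                             every_days = 14, depths_m = c(1, 10, 20),
                             noise_cv = 0.25, po4_detection = 0.02,
                             start_date = as.Date("2008-01-01"),
                             file = NULL) {
  stopifnot(inherits(traj, "bgc_trajectory"))
  vars <- intersect(vars, colnames(traj$state))
  if (!length(vars)) stop("no requested variable in the trajectory",
                          call. = FALSE)
  df <- .with_seed(seed, {
    tt <- traj$time
    want <- seq(min(tt), max(tt), by = every_days)
    idx <- vapply(want, function(w) which.min(abs(tt - w)), 0L)
    rows <- expand.grid(i = idx, depth_m = depths_m, variable = vars,
                        stringsAsFactors = FALSE)
    truth <- traj$state[cbind(rows$i, match(rows$variable,
                                            colnames(traj$state)))]
    noise <- if (noise_cv > 0) {
      sdl <- sqrt(log(1 + noise_cv^2))
      exp(stats::rnorm(nrow(rows), -sdl^2 / 2, sdl))  # mean-1 lognormal
    } else 1
    value <- truth * noise
    below <- rows$variable == "PO4" & value < po4_detection
    value[below] <- po4_detection
    data.frame(
      timestamp = format(start_date + tt[rows$i]),
      depth_m = rows$depth_m,
      variable = rows$variable,
      value = signif(value, 6),
      below_detection = below
    )
  })
  df <- df[order(df$timestamp, df$depth_m, df$variable), ]
  rownames(df) <- NULL
  if (!is.null(file)) {
    utils::write.csv(df, file, row.names = FALSE, quote = FALSE)
    return(invisible(df))
  }
  df
}

#' Write a trajectory in long observation-like CSV form
#'
#' `timestamp, variable, value` rows suitable for [match_series()].
#'
#' @param traj a [run_box()] trajectory.
#' @param file CSV path.
#' @param vars variables to include (default: all).
#' @param start_date calendar date mapped to trajectory time 0.
#' @return the file path, invisibly.
#' @export
write_model_long_csv <- function(traj, file, vars = NULL,
                                 start_date = as.Date("2008-01-01")) {
  stopifnot(inherits(traj, "bgc_trajectory"))
  if (is.null(vars)) vars <- colnames(traj$state)
  vars <- intersect(vars, colnames(traj$state))
  long <- do.call(rbind, lapply(vars, function(v) {
    data.frame(timestamp = format(start_date + round(traj$time)),
               variable = v, value = signif(traj$state[, v], 8))
  }))
  utils::write.csv(long, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}
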