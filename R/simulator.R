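# Pools belonging to each conserved element (oxygen handled separately).
.element_pools <- list(
  N = c("Nb", "Nba", "DPON", "LDON", "NO3", "NH4"),
  P = c("Pb", "Pba", "DPOP", "LDOP", "PO4"),
  C = c("Cb", "Cba", "DPOC", "LDOC")
)

#' Advance a state by one forward-Euler step
#'
#' `state + dt * (SMS + boundary + entrainment)`, with positivity preserved
#' by flux limiting: if the sinks of a pool would overdraw it within the
#' step, every outgoing transfer of that pool is scaled down so the pool
#' lands exactly at zero. Because whole transfers (source and destination
#' together) are scaled, element conservation is preserved by limiting;
#' clipping is never used.
#'
#' @param state a [bgc_state()].
#' @param forcing named list: `temp` (deg C), `E` (W/m2), optional
#'   `dilution` (1/d), `deep` (named vector of reservoir concentrations for
#'   the entrainment term) and `boundary` (named vector of boundary mass
#'   fluxes, umol/L/d).
#' @param params a [default_params()] parameter set.
#' @param dt time step (days); the default is 20 minutes.
#' @param version model version.
#' @return the updated [bgc_state()].
#' @export
step_box <- function(state, forcing, params, dt = 20 / 1440,
                     version = attr(state, "version")) {
  stopifnot(dt > 0)
  machine <- make_sms(params, version)
  y <- as.numeric(state[machine$vars])
  dil <- if (!is.null(forcing$dilution)) forcing$dilution else 0
  deep <- .expand_named(forcing$deep, machine$vars)
  bnd <- .expand_named(forcing$boundary, machine$vars)
  y2 <- .euler_step(y, machine, unname(forcing[["temp"]]),
                    unname(forcing[["E"]]), dil, deep, bnd, dt)$y
  bgc_state(stats::setNames(y2, machine$vars), version)
}

# named vector (possibly partial / NULL) -> full-length vector in vars order
.expand_named <- function(x, vars) {
  out <- numeric(length(vars))
  if (!is.null(x)) {
    idx <- match(names(x), vars)
    if (anyNA(idx)) {
      stop("unknown variable(s) in forcing: ",
           paste(names(x)[is.na(idx)], collapse = ", "), call. = FALSE)
    }
    out[idx] <- as.numeric(x)
  }
  out
}

# One limited Euler step on the plain numeric state. Returns the new state,
# the scaled flux vector and the boundary tendency actually applied.
.euler_step <- function(y, machine, temp, E, dil, deep, bnd, dt) {
  if (!is.finite(temp) || !is.finite(E) || E < 0) {
    stop("forcing must provide finite temp and non-negative E (got temp=",
         format(temp), ", E=", format(E), ")", call. = FALSE)
  }
  res <- machine$fun(y, temp, E)
  fl <- res$fl
  src <- machine$src
  # outflow per pool (internal sinks + dilution)
  outflow <- dil * y
  for (j in seq_along(fl)) {
    if (!is.na(src[j])) outflow[src[j]] <- outflow[src[j]] + fl[j]
  }
  need <- outflow > 0 & dt * outflow > y
  if (any(need)) {
    s <- rep(1, length(y))
    s[need] <- pmax(0, y[need]) / (dt * outflow[need])
    sf <- ifelse(is.na(src), 1, s[src])
    fl <- fl * sf
    dil_out <- dil * y * s
  } else {
    dil_out <- dil * y
  }
  tend <- drop(machine$inc %*% fl)
  btend <- bnd + dil * deep - dil_out
  y2 <- y + dt * (tend + btend)
  # round-off guard only; the limiter keeps pools non-negative analytically
  tiny <- y2 < 0 & y2 > -1e-12
  if (any(tiny)) y2[tiny] <- 0
  if (any(!is.finite(y2)) || any(y2 < 0)) {
    bad <- machine$vars[!is.finite(y2) | y2 < 0]
    stop("integration failure: non-finite or negative state for ",
         paste(bad, collapse = ", "), " (temp=", format(temp),
         ", E=", format(E), ", dt=", format(dt), ")", call. = FALSE)
  }
  list(y = y2, fl = fl, btend = btend, diag = res$diag)
}

#' Run a zero-dimensional box simulation
#'
#' Integrates the model with forward Euler at the configured step (default
#' 20 minutes), applying boundary mass fluxes and mixed-layer entrainment
#' from the physical forcing, and accumulating process fluxes per save
#' interval.
#'
#' @param config list with entries:
#'   \describe{
#'     \item{version}{`"noP"` or `"P"`.}
#'     \item{params}{a [default_params()] set (default used if absent).}
#'     \item{state}{initial [bgc_state()] or a preset name.}
#'     \item{forcing}{a [synthetic_forcing()] / [physical_forcing()] object,
#'       or a named list of constants (`temp`, `E`, optional `dilution`,
#'       `deep`, `boundary`) for a time-invariant run.}
#'     \item{duration}{run length (days).}
#'     \item{dt}{step (days), default `20/1440`.}
#'     \item{save_every}{saving cadence (days), default 1.}
#'   }
#' @return a `bgc_trajectory`: list with `time` (days), `state` (matrix of
#'   saved states), `diag` (per-save diagnostics), `fluxes` and `boundary`
#'   (per-interval integrated process fluxes and boundary inputs), plus the
#'   configuration. Deterministic: identical configs give identical
#'   trajectories.
#' @export
run_box <- function(config) {
  cf <- .check_config(config)
  machine <- make_sms(cf$params, cf$version)
  vars <- machine$vars
  nv <- length(vars)
  nf <- machine$nf
  y <- as.numeric(cf$state[vars])
  nsteps <- ceiling(cf$duration / cf$dt - 1e-9)
  save_steps <- max(1L, round(cf$save_every / cf$dt))
  nsave <- floor(nsteps / save_steps)

  fc <- .forcing_at(cf$forcing, (seq_len(nsteps) - 1) * cf$dt, vars)

  state_m <- matrix(NA_real_, nsave + 1L, nv, dimnames = list(NULL, vars))
  diag0 <- machine$fun(y, fc$temp[1L], fc$E[1L])$diag
  diag_m <- matrix(NA_real_, nsave + 1L, length(diag0),
                   dimnames = list(NULL, names(diag0)))
  flux_m <- matrix(0, nsave + 1L, nf, dimnames = list(NULL, machine$flux_names))
  bnd_m <- matrix(0, nsave + 1L, nv, dimnames = list(NULL, vars))
  time_v <- numeric(nsave + 1L)
  state_m[1L, ] <- y
  diag_m[1L, ] <- diag0

  facc <- numeric(nf)
  bacc <- numeric(nv)
  row <- 1L
  for (k in seq_len(nsteps)) {
    st <- .euler_step(y, machine, fc$temp[k], fc$E[k], fc$dil[k],
                      fc$deep[k, ], fc$bnd[k, ], cf$dt)
    y <- st$y
    facc <- facc + st$fl * cf$dt
    bacc <- bacc + st$btend * cf$dt
    if (k %% save_steps == 0L && row <= nsave) {
      row <- row + 1L
      time_v[row] <- k * cf$dt
      state_m[row, ] <- y
      diag_m[row, ] <- st$diag
      flux_m[row, ] <- facc
      bnd_m[row, ] <- bacc
      facc <- numeric(nf)
      bacc <- numeric(nv)
    }
  }
  structure(list(time = time_v, state = state_m, diag = diag_m,
                 fluxes = flux_m, boundary = bnd_m,
                 version = cf$version, params = cf$params, dt = cf$dt,
                 mode = "box"),
            class = "bgc_trajectory")
}

.check_config <- function(config) {
  stopifnot(is.list(config))
  version <- config$version %||% "P"
  check_version(version)
  params <- config$params %||% default_params()
  validate_params(params)
  state <- config$state %||% "oligotrophic-summer"
  if (is.character(state)) state <- make_initial_state(version, state)
  if (!identical(attr(state, "version"), version)) {
    stop("initial state version does not match config version", call. = FALSE)
  }
  viol <- validate_state(state, params, version)
  if (length(viol)) {
    stop("invalid initial state: ", paste(viol, collapse = "; "),
         call. = FALSE)
  }
  duration <- config$duration
  if (is.null(duration) && inherits(config$forcing, "physical_forcing")) {
    duration <- max(config$forcing$time)
  }
  stopifnot(is.numeric(duration), duration > 0)
  dt <- config$dt %||% (20 / 1440)
  stopifnot(dt > 0)
  list(version = version, params = params, state = state,
       forcing = config$forcing, duration = duration, dt = dt,
       save_every = config$save_every %||% 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate forcing at the step times. Returns vectors temp, E, dil and
# matrices deep, bnd (nsteps x nv).
.forcing_at <- function(forcing, times, vars) {
  n <- length(times)
  nv <- length(vars)
  if (inherits(forcing, "physical_forcing")) {
    ap <- function(y) stats::approx(forcing$time, y, xout = times,
                                    rule = 2)$y
    deep <- matrix(rep(.expand_named(forcing$deep, vars), each = n), n, nv)
    bnd <- matrix(0, n, nv)
    if (!is.null(forcing$boundary)) {
      # columns for pools absent from this version (e.g. P inputs under
      # noP) are simply not delivered
      keep <- which(colnames(forcing$boundary) %in% vars)
      idx <- match(colnames(forcing$boundary)[keep], vars)
      for (j in seq_along(keep)) {
        bnd[, idx[j]] <- ap(forcing$boundary[, keep[j]])
      }
    }
    list(temp = ap(forcing$temp), E = ap(forcing$E0),
         dil = if (!is.null(forcing$dilution)) ap(forcing$dilution)
               else numeric(n),
         deep = deep, bnd = bnd)
  } else if (is.list(forcing)) {
    list(temp = rep(unname(forcing$temp), n), E = rep(unname(forcing$E), n),
         dil = rep(forcing$dilution %||% 0, n),
         deep = matrix(rep(.expand_named(forcing$deep, vars), each = n),
                       n, nv),
         bnd = matrix(rep(.expand_named(forcing$boundary, vars), each = n),
                      n, nv))
  } else {
    stop("unsupported forcing object", call. = FALSE)
  }
}

#' @export
print.bgc_trajectory <- function(x, ...) {
  cat("<bgc_trajectory>", x$mode, "run, version", x$version, "-",
      length(x$time), "saves over", format(max(x$time)), "days\n")
  invisible(x)
}

#' Run a one-dimensional column simulation
#'
#' Per-level source-minus-sink dynamics coupled through (i) light, computed
#' from surface irradiance attenuated by water and the simulated chlorophyll
#' profile (see [light_extinction()]), and (ii) explicit vertical diffusion
#' in conservative flux form. An optional bottom boundary relaxes the
#' deepest level toward reservoir concentrations. The explicit scheme
#' requires `dt * Kz / dz^2 <= 0.5` at every interface; a violation raises
#' an error instructing a smaller step.
#'
#' @param config as for [run_box()] plus
#'   \describe{
#'     \item{grid}{list with `dz` (level thicknesses, m, surface first) and
#'       `Kz` (interface diffusivities, m2/s, length `nlev - 1`).}
#'     \item{bottom}{optional list `conc` (named concentrations) and `rate`
#'       (1/d) relaxing the bottom level.}
#'   }
#'   The initial `state` is replicated over levels unless a matrix
#'   (levels x variables) is supplied.
#' @return a `bgc_trajectory` with `mode = "column"`; `state` is a 3-d array
#'   (save x level x variable).
#' @export
run_column <- function(config) {
  grid <- config$grid
  stopifnot(is.list(grid), all(grid$dz > 0), all(grid$Kz >= 0),
            length(grid$Kz) == length(grid$dz) - 1L)
  cf <- .check_config(config)
  machine <- make_sms(cf$params, cf$version)
  vars <- machine$vars
  nv <- length(vars)
  dz <- grid$dz
  nlev <- length(dz)
  kz_d <- grid$Kz * 86400  # m2/s -> m2/d
  dz_int <- (dz[-nlev] + dz[-1L]) / 2
  # explicit diffusion stability
  if (nlev > 1L && any(cf$dt * kz_d / (dz_int * pmin(dz[-nlev], dz[-1L])) >
                       0.5)) {
    stop("explicit diffusion unstable: dt * Kz / dz^2 > 0.5; ",
         "reduce dt or Kz, or thicken levels", call. = FALSE)
  }
  Y <- if (is.matrix(config$state_profile %||% NULL)) {
    config$state_profile[, vars, drop = FALSE]
  } else {
    matrix(rep(as.numeric(cf$state[vars]), each = nlev), nlev, nv,
           dimnames = list(NULL, vars))
  }
  nsteps <- ceiling(cf$duration / cf$dt - 1e-9)
  save_steps <- max(1L, round(cf$save_every / cf$dt))
  nsave <- floor(nsteps / save_steps)
  fc <- .forcing_at(cf$forcing, (seq_len(nsteps) - 1) * cf$dt, vars)
  bottom <- config$bottom
  bconc <- if (!is.null(bottom)) .expand_named(bottom$conc, vars)
  brate <- if (!is.null(bottom)) bottom$rate else 0

  arr <- array(NA_real_, c(nsave + 1L, nlev, nv),
               dimnames = list(NULL, NULL, vars))
  gpp_m <- matrix(NA_real_, nsave + 1L, nlev)
  time_v <- numeric(nsave + 1L)
  arr[1L, , ] <- Y
  chla_col <- match("Chla", vars)
  row <- 1L
  zero_deep <- numeric(nv)
  for (k in seq_len(nsteps)) {
    prof <- light_extinction(Y[, chla_col], cf$params, dz = dz,
                             E0 = fc$E[k])
    gpp_k <- numeric(nlev)
    newY <- Y
    for (l in seq_len(nlev)) {
      st <- .euler_step(Y[l, ], machine, fc$temp[k], prof$E[l], 0,
                        zero_deep, fc$bnd[k, ] * (l == 1L), cf$dt)
      newY[l, ] <- st$y
      gpp_k[l] <- st$diag[["gpp"]]
    }
    # conservative explicit diffusion between levels
    if (nlev > 1L) {
      flx <- kz_d * (newY[-nlev, , drop = FALSE] -
                     newY[-1L, , drop = FALSE]) / dz_int  # umol/L * m/d
      newY[-nlev, ] <- newY[-nlev, ] - cf$dt * flx / dz[-nlev]
      newY[-1L, ] <- newY[-1L, ] + cf$dt * flx / dz[-1L]
    }
    if (!is.null(bottom) && brate > 0) {
      newY[nlev, ] <- newY[nlev, ] +
        cf$dt * brate * (bconc - newY[nlev, ])
    }
    if (any(newY < 0)) newY[newY < 0 & newY > -1e-12] <- 0
    Y <- newY
    if (k %% save_steps == 0L && row <= nsave) {
      row <- row + 1L
      time_v[row] <- k * cf$dt
      arr[row, , ] <- Y
      gpp_m[row, ] <- gpp_k
    }
  }
  structure(list(time = time_v, state = arr, gpp = gpp_m,
                 grid = grid, version = cf$version, params = cf$params,
                 dt = cf$dt, mode = "column"),
            class = "bgc_trajectory")
}

#' Days until two runs converge (spin-up detection)
#'
#' The spin-up period is complete at the first saved time from which the
#' two trajectories agree - maximum over state variables of the relative
#' difference below `tol` - and stay in agreement for the rest of the run.
#' Runs that never converge return `Inf`.
#'
#' @param run_a,run_b `bgc_trajectory` box runs on the same time grid and
#'   variable set (typically identical configurations started from
#'   different initial conditions).
#' @param tol relative tolerance.
#' @param floor scale floor in the relative difference denominator.
#' @return convergence time in days (0 when the runs are identical), or
#'   `Inf`.
#' @export
detect_spinup <- function(run_a, run_b, tol = 1e-3, floor = 1e-10) {
  if (!identical(dim(run_a$state), dim(run_b$state)) ||
      !isTRUE(all.equal(run_a$time, run_b$time))) {
    stop("trajectories are not on the same grid / variable set",
         call. = FALSE)
  }
  a <- run_a$state
  b <- run_b$state
  scale <- pmax(abs(a), abs(b), floor)
  rel <- abs(a - b) / scale
  worst <- apply(rel, 1L, max)
  ok_from <- rev(cummax(rev(worst))) < tol  # below tol, sustained thereafter
  if (!any(ok_from)) return(Inf)
  run_a$time[which(ok_from)[1L]]
}

#' Element budgets of a box trajectory
#'
#' For every conserved element: change in stock minus net boundary delivery
#' minus internal source/sink must vanish. N and P have no internal source;
#' carbon's internal term is gross primary production minus total
#' respiration (there is no inorganic carbon pool); oxygen's is the
#' stoichiometric sum of production, respiration and nitrification.
#'
#' @param traj a `bgc_trajectory` from [run_box()].
#' @return data.frame with one row per element: `dstock`, `boundary`,
#'   `internal`, `residual` (umol/L over the run) and `residual_rel`
#'   (residual over mean stock).
#' @export
compute_budgets <- function(traj) {
  stopifnot(inherits(traj, "bgc_trajectory"), traj$mode == "box")
  vars <- colnames(traj$state)
  fl <- traj$fluxes
  fsum <- colSums(fl)
  n <- nrow(traj$state)
  elems <- c("N", if ("PO4" %in% vars) "P", "C", "O")
  resp_names <- c("resp_phy", "graz_phy_c_dim", "resp_ba", "excess_c",
                  "graz_bac_c_dim", "remin_c")
  rows <- lapply(elems, function(el) {
    if (el == "O") {
      pools <- "O"
      internal <- fsum[["o_prod"]] - fsum[["o_resp"]] - fsum[["o_nitrif"]]
    } else {
      pools <- intersect(.element_pools[[el]], vars)
      internal <- if (el == "C") {
        fsum[["gpp"]] - sum(fsum[resp_names])
      } else 0
    }
    stock <- rowSums(traj$state[, pools, drop = FALSE])
    bnd <- sum(traj$boundary[, pools, drop = FALSE])
    dstock <- stock[n] - stock[1L]
    res <- dstock - bnd - internal
    data.frame(element = el, dstock = dstock, boundary = bnd,
               internal = internal, residual = res,
               residual_rel = abs(res) / max(mean(stock), 1e-300))
  })
  do.call(rbind, rows)
}

#' Write a box trajectory to CSV
#'
#' Plain-text station-style output: a commented metadata header (variable
#' long names and units) followed by `time` plus one column per state
#' variable and diagnostic.
#'
#' @param traj a `bgc_trajectory` from [run_box()].
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_trajectory_csv <- function(traj, file) {
  stopifnot(inherits(traj, "bgc_trajectory"), traj$mode == "box")
  vars <- colnames(traj$state)
  units <- state_units(traj$version)
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("# planktonbox trajectory, version=", traj$version,
           ", dt_days=", format(traj$dt)),
    paste0("# ", vars, ": ",
           .var_table$long_name[match(vars, .var_table$name)],
           " [", units[vars], "]")), con)
  df <- data.frame(time = traj$time, traj$state, traj$diag,
                   check.names = FALSE)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(file)
}
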