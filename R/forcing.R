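# Raw river chemistry columns (umol/L) expected from daily monitoring files.
.raw_river_vars <- c("NO3", "NH4", "PO4", "DOC", "DON", "DOP",
                     "POC", "PON", "POP")
# Model-side boundary variables produced by the loaders.
.model_river_vars <- c("NO3", "NH4", "PO4", "LDOC", "LDON", "LDOP",
                       "DPOC", "DPON", "DPOP")

#' Labile-fraction rules for riverine organic matter
#'
#' Only the biologically labile fraction of riverine organic matter enters
#' the model: 20% of DOC and DON, 88% of DOP, 18% of POC, and the same
#' dissolved percentages applied to PON (20%) and POP (88%). An alternative
#' reading of the particulate-nitrogen rule, deriving the labile PON from
#' POC (`pon_from_poc = TRUE`, fraction 0.2 of POC), is available.
#'
#' @param doc,don,dop,poc,pon,pop labile fractions in `[0, 1]`.
#' @param pon_from_poc logical; derive labile PON as `pon * POC` instead of
#'   `pon * PON`.
#' @return list of class `lability_rules`.
#' @export
lability_rules <- function(doc = 0.20, don = 0.20, dop = 0.88,
                           poc = 0.18, pon = 0.20, pop = 0.88,
                           pon_from_poc = FALSE) {
  fr <- c(doc = doc, don = don, dop = dop, poc = poc, pon = pon, pop = pop)
  if (any(fr < 0 | fr > 1)) {
    stop("labile fractions must lie in [0, 1]", call. = FALSE)
  }
  structure(list(doc = doc, don = don, dop = dop, poc = poc, pon = pon,
                 pop = pop, pon_from_poc = pon_from_poc),
            class = "lability_rules")
}

#' Apply lability rules to raw river concentrations
#'
#' Maps measured bulk organic concentrations to the model's labile pools:
#' `LDOC = doc * DOC`, `LDON = don * DON`, `LDOP = dop * DOP`,
#' `DPOC = poc * POC`, `DPON = pon * PON` (or `pon * POC`, see
#' [lability_rules()]), `DPOP = pop * POP`. Nutrients (NO3, NH4, PO4) pass
#' through unchanged. Inputs that already carry labile variables (LDOC,
#' DPOC, ...) are rejected rather than silently re-scaled.
#'
#' @param raw named vector, list or single-row data.frame with the raw
#'   columns `NO3, NH4, PO4, DOC, DON, DOP, POC, PON, POP` (a data.frame
#'   with several rows is processed rowwise).
#' @param rules a [lability_rules()] object.
#' @return same shape as the input with the model columns
#'   `NO3, NH4, PO4, LDOC, LDON, LDOP, DPOC, DPON, DPOP`.
#' @examples
#' apply_lability(c(NO3 = 100, NH4 = 5, PO4 = 1.5, DOC = 100, DON = 10,
#'                  DOP = 10, POC = 50, PON = 6, POP = 0.5))
#' @export
apply_lability <- function(raw, rules = lability_rules()) {
  stopifnot(inherits(rules, "lability_rules"))
  nm <- if (is.data.frame(raw)) names(raw) else names(raw)
  already <- intersect(nm, c("LDOC", "LDON", "LDOP", "DPOC", "DPON", "DPOP"))
  if (length(already)) {
    stop("input already contains labile variables (",
         paste(already, collapse = ", "),
         "); lability rules must not be re-applied", call. = FALSE)
  }
  miss <- setdiff(.raw_river_vars, nm)
  if (length(miss)) {
    stop("missing raw concentration column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  g <- function(v) if (is.data.frame(raw)) raw[[v]] else as.numeric(raw[[v]])
  out <- list(
    NO3 = g("NO3"), NH4 = g("NH4"), PO4 = g("PO4"),
    LDOC = rules$doc * g("DOC"),
    LDON = rules$don * g("DON"),
    LDOP = rules$dop * g("DOP"),
    DPOC = rules$poc * g("POC"),
    DPON = if (rules$pon_from_poc) rules$pon * g("POC")
           else rules$pon * g("PON"),
    DPOP = rules$pop * g("POP")
  )
  if (is.data.frame(raw)) as.data.frame(out) else unlist(out)
}

# Constant-source registry (umol/L): long-term mean concentrations for the
# Berre lagoon outlet (Caronte channel, constant 20 m3/s) and the urban
# sources; the wastewater plant carries fixed PO4 and organics with daily
# measured NO3/NH4. Organic columns are already labile. Urban-river
# particulate columns tied to discharge in the source material are not
# reconstructible from concentrations alone and are set to 0 here.
.river_constants <- list(
  caronte = c(NO3 = 0.75, NH4 = 2.72, PO4 = 0.4, LDOC = 45, LDON = 3.73,
              LDOP = 0.11, DPOC = 1.8, DPON = 1.36, DPOP = 0.078),
  wwtp = c(NO3 = NA, NH4 = NA, PO4 = 13.4, LDOC = 135, LDON = 17,
           LDOP = 3, DPOC = 8403, DPON = 864, DPOP = 372),
  bonneveine = c(NO3 = NA, NH4 = NA, PO4 = NA, LDOC = 52.4, LDON = 6.62,
                 LDOP = 1.17, DPOC = 667, DPON = 68.60, DPOP = 29.6),
  huveaune = c(NO3 = NA, NH4 = NA, PO4 = NA, LDOC = 38.5, LDON = 4.86,
               LDOP = 0.86, DPOC = 869, DPON = 89.4, DPOP = 38.57),
  aygalade = c(NO3 = NA, NH4 = NA, PO4 = NA, LDOC = 52.4, LDON = 6.62,
               LDOP = 1.17, DPOC = 0, DPON = 0, DPOP = 0),
  belvedere = c(NO3 = NA, NH4 = NA, PO4 = NA, LDOC = 52.4, LDON = 6.62,
                LDOP = 1.17, DPOC = 0, DPON = 0, DPOP = 0)
)

#' Registered boundary sources
#' @return character vector of river/source names known to
#'   [load_river_series()].
#' @export
river_registry <- function() c("rhone", names(.river_constants))

#' Load a river / WWTP boundary time series
#'
#' Applies the source-specific construction rules:
#' \describe{
#'   \item{rhone}{daily file with `date`, `discharge` (m3/s, total river)
#'     and the raw chemistry columns; lability rules are applied and the
#'     discharge is multiplied by 0.90 (the branch entering the model domain
#'     carries 90% of the total discharge).}
#'   \item{caronte}{constant concentrations and a constant 20 m3/s
#'     discharge; no file needed.}
#'   \item{wwtp}{daily file with `date`, `discharge`, `NO3`, `NH4`; PO4 is
#'     fixed at 13.4 umol/L and the organic concentrations are fixed.}
#'   \item{urban rivers}{daily file with `date`, `discharge`; nutrient
#'     concentrations are taken from the Rhone series (`rhone_nutrients`)
#'     and organics from the constant table.}
#' }
#' Marine plankton variables are absent (zero) from all boundary inputs.
#' Gaps in daily series are forward-filled with a warning.
#'
#' @param file CSV path (ignored for `caronte`).
#' @param river one of [river_registry()].
#' @param rules a [lability_rules()] (used for the Rhone).
#' @param rhone_nutrients data.frame `date, NO3, NH4, PO4` used for the
#'   urban rivers.
#' @param dates date vector for constant sources (default: a single row).
#' @return data.frame of class `river_series`: `date`, `discharge` (m3/s)
#'   and the model boundary concentrations (umol/L).
#' @export
load_river_series <- function(file = NULL, river, rules = lability_rules(),
                              rhone_nutrients = NULL, dates = NULL) {
  river <- match.arg(river, river_registry())
  if (river == "caronte") {
    if (is.null(dates)) dates <- as.Date("2000-01-01")
    cc <- .river_constants$caronte
    out <- data.frame(date = dates, discharge = 20,
                      as.list(cc), check.names = FALSE)
    return(structure(out, class = c("river_series", "data.frame")))
  }
  stopifnot(!is.null(file))
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  if (!all(c("date", "discharge") %in% names(df))) {
    stop("river file must have `date` and `discharge` columns",
         call. = FALSE)
  }
  df$date <- as.Date(df$date)
  if (is.unsorted(df$date)) df <- df[order(df$date), ]
  df <- .fill_daily_gaps(df, river)
  if (river == "rhone") {
    lab <- apply_lability(df[.raw_river_vars], rules)
    out <- data.frame(date = df$date,
                      discharge = 0.90 * df$discharge,  # 90% enters the domain
                      lab, check.names = FALSE)
  } else if (river == "wwtp") {
    if (!all(c("NO3", "NH4") %in% names(df))) {
      stop("wwtp file must have daily NO3 and NH4 columns", call. = FALSE)
    }
    cc <- .river_constants$wwtp
    out <- data.frame(date = df$date, discharge = df$discharge,
                      NO3 = df$NO3, NH4 = df$NH4, PO4 = cc[["PO4"]],
                      LDOC = cc[["LDOC"]], LDON = cc[["LDON"]],
                      LDOP = cc[["LDOP"]], DPOC = cc[["DPOC"]],
                      DPON = cc[["DPON"]], DPOP = cc[["DPOP"]])
  } else {
    if (is.null(rhone_nutrients)) {
      stop("urban rivers need `rhone_nutrients` (date, NO3, NH4, PO4): ",
           "their nutrient concentrations follow the Rhone", call. = FALSE)
    }
    idx <- match(df$date, as.Date(rhone_nutrients$date))
    if (anyNA(idx)) {
      stop("rhone_nutrients does not cover all dates of ", river,
           call. = FALSE)
    }
    cc <- .river_constants[[river]]
    out <- data.frame(date = df$date, discharge = df$discharge,
                      NO3 = rhone_nutrients$NO3[idx],
                      NH4 = rhone_nutrients$NH4[idx],
                      PO4 = rhone_nutrients$PO4[idx],
                      LDOC = cc[["LDOC"]], LDON = cc[["LDON"]],
                      LDOP = cc[["LDOP"]], DPOC = cc[["DPOC"]],
                      DPON = cc[["DPON"]], DPOP = cc[["DPOP"]])
  }
  structure(out, class = c("river_series", "data.frame"))
}

# forward-fill missing calendar days (daily data expected)
.fill_daily_gaps <- function(df, what) {
  full <- seq(min(df$date), max(df$date), by = "day")
  if (length(full) == nrow(df)) return(df)
  idx <- findInterval(as.numeric(full), as.numeric(df$date))
  warning(length(full) - nrow(df), " missing day(s) in ", what,
          " series forward-filled", call. = FALSE)
  out <- df[idx, , drop = FALSE]
  out$date <- full
  rownames(out) <- NULL
  out
}

#' Convert a river series to box boundary mass fluxes
#'
#' Concentration tendencies for a well-mixed receiving box:
#' `flux = conc * discharge * 86400 / volume` in umol/L/d.
#'
#' @param series a [load_river_series()] result.
#' @param volume_m3 receiving box volume.
#' @return data.frame `date` plus one flux column per boundary variable.
#' @export
river_boundary_flux <- function(series, volume_m3) {
  stopifnot(volume_m3 > 0)
  fac <- series$discharge * 86400 / volume_m3
  out <- data.frame(date = series$date)
  for (v in .model_river_vars) out[[v]] <- series[[v]] * fac
  out
}

#' Atmospheric deposition fluxes
#'
#' Dry deposition: each sample reports the mass accumulated since the
#' previous sample date; it is applied as the mean flux over that interval
#' (piecewise constant), so the delivered mass reproduces the measurement
#' exactly. Wet deposition: event concentrations are applied to the
#' rainfall (last-observation-carried-forward between events); the flux is
#' `concentration x rainfall`, zero on rainless days. Per-area fluxes are
#' converted to mixed-layer concentration tendencies by dividing by the
#' mixed-layer depth.
#'
#' @param dry data.frame `date` plus per-variable accumulated totals
#'   (umol/m2 since the previous row; the first row marks deployment and
#'   carries no flux). Dates must be strictly increasing.
#' @param wet data.frame `date` plus per-variable concentrations (umol/L)
#'   of rain, or `NULL`.
#' @param rainfall data.frame `date`, `rain_mm` (mm/d), or `NULL`.
#' @param mld_m mixed-layer depth (m) for the concentration conversion.
#' @return data.frame: `date`, per-variable `<var>_flux` (umol/m2/d) and
#'   `<var>_tend` (umol/L/d).
#' @export
atmospheric_deposition_flux <- function(dry, wet = NULL, rainfall = NULL,
                                        mld_m = 10) {
  stopifnot(mld_m > 0)
  dry$date <- as.Date(dry$date)
  if (is.unsorted(dry$date, strictly = TRUE)) {
    stop("dry samples must be sorted by strictly increasing date",
         call. = FALSE)
  }
  vars <- setdiff(names(dry), "date")
  days <- seq(min(dry$date), max(dry$date) - 1, by = "day")
  out <- data.frame(date = days)
  for (v in vars) out[[paste0(v, "_flux")]] <- 0
  for (i in seq_len(nrow(dry))[-1L]) {
    span <- as.numeric(dry$date[i] - dry$date[i - 1L])
    sel <- out$date >= dry$date[i - 1L] & out$date < dry$date[i]
    for (v in vars) {
      out[[paste0(v, "_flux")]][sel] <- out[[paste0(v, "_flux")]][sel] +
        dry[[v]][i] / span
    }
  }
  if (!is.null(rainfall) && !is.null(wet)) {
    rainfall$date <- as.Date(rainfall$date)
    wet$date <- as.Date(wet$date)
    if (is.unsorted(wet$date, strictly = TRUE)) {
      stop("wet samples must be sorted by strictly increasing date",
           call. = FALSE)
    }
    rain <- rainfall$rain_mm[match(out$date, rainfall$date)]
    rain[is.na(rain)] <- 0
    wvars <- setdiff(names(wet), "date")
    pos <- findInterval(as.numeric(out$date), as.numeric(wet$date))
    for (v in wvars) {
      conc <- ifelse(pos >= 1L, wet[[v]][pmax(pos, 1L)], 0)
      col <- paste0(v, "_flux")
      if (is.null(out[[col]])) out[[col]] <- 0
      # 1 mm rain = 1 L/m2, so conc (umol/L) * rain (mm/d) = umol/m2/d
      out[[col]] <- out[[col]] + conc * rain
    }
  }
  for (col in grep("_flux$", names(out), value = TRUE)) {
    out[[sub("_flux$", "_tend", col)]] <- out[[col]] / (1000 * mld_m)
  }
  out
}

#' Light extinction and irradiance profile
#'
#' The extinction coefficient at each level is
#' `k(z) = k_w + k_chl * Chla(z)`: the simulated chlorophyll feeds back on
#' the light field. Irradiance decays exponentially through the cumulative
#' optical depth; by default it is evaluated at level centres (what the
#' growth model uses), optionally at level bottoms.
#'
#' @param chla per-level chlorophyll (ug/L), surface first.
#' @param params a [default_params()] parameter set (optics group).
#' @param dz level thicknesses (m), recycled to `length(chla)`.
#' @param E0 surface irradiance.
#' @param at `"center"` or `"bottom"`.
#' @return list `k` (1/m per level) and `E` (same units as `E0`).
#' @examples
#' light_extinction(2, default_params(), dz = 10, E0 = 1, at = "bottom")$E
#' # exp(-1) = 0.368: k = 0.04 + 0.03 * 2 = 0.1 over 10 m
#' @export
light_extinction <- function(chla, params, dz, E0 = 1,
                             at = c("center", "bottom")) {
  at <- match.arg(at)
  if (any(chla < 0)) stop("Chla must be >= 0", call. = FALSE)
  if (any(dz <= 0)) stop("level thicknesses must be > 0", call. = FALSE)
  dz <- rep_len(dz, length(chla))
  k <- params$optics$k_w + params$optics$k_chl * chla
  tau_bottom <- cumsum(k * dz)
  tau <- if (at == "center") tau_bottom - k * dz / 2 else tau_bottom
  list(k = k, E = E0 * exp(-tau))
}

#' Construct a physical-forcing object
#'
#' Time-stamped physical drivers and boundary mass inputs for [run_box()]:
#' temperature, surface irradiance, salinity (event flagging only),
#' mixed-layer dilution/entrainment and per-variable boundary
#' concentration tendencies.
#'
#' @param time strictly increasing times (days).
#' @param temp temperature (deg C).
#' @param E0 surface irradiance (W/m2).
#' @param salinity optional salinity trace.
#' @param dilution optional entrainment/dilution rate (1/d, >= 0).
#' @param deep optional named constant reservoir concentrations paired with
#'   `dilution` (inflow `dilution * deep`); time-varying reservoirs are
#'   expressed through `boundary`.
#' @param boundary optional matrix (time x variable, named columns) of
#'   boundary mass fluxes (umol/L/d, >= 0).
#' @return list of class `physical_forcing`.
#' @export
physical_forcing <- function(time, temp, E0, salinity = NULL,
                             dilution = NULL, deep = NULL, boundary = NULL) {
  stopifnot(length(time) > 1L, !is.unsorted(time, strictly = TRUE),
            length(temp) == length(time), length(E0) == length(time),
            all(E0 >= 0))
  if (!is.null(dilution)) {
    stopifnot(length(dilution) == length(time), all(dilution >= 0))
  }
  if (!is.null(boundary)) {
    stopifnot(is.matrix(boundary), nrow(boundary) == length(time),
              !is.null(colnames(boundary)), all(boundary >= 0))
  }
  structure(list(time = time, temp = temp, E0 = E0, salinity = salinity,
                 dilution = dilution, deep = deep, boundary = boundary),
            class = "physical_forcing")
}

#' @export
print.physical_forcing <- function(x, ...) {
  cat("<physical_forcing>", length(x$time), "samples over",
      format(max(x$time)), "days",
      if (!is.null(attr(x, "scenario"))) paste0("(", attr(x, "scenario"), ")"),
      "\n")
  invisible(x)
}
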