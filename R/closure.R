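#' Temperature limitation of grazing
#'
#' Zooplankton are not a state variable; their grazing pressure is an
#' explicit function whose rate is modulated by temperature with a
#' Q10 exponential normalized to 1 at the reference temperature and capped
#' at 1: `f(T) = min(1, Q10^((T - T_ref)/10))`. Over the regional range
#' (about 10-26 deg C with `T_ref = 24`) this makes grazing weak in winter
#' and strong in summer.
#'
#' @param T_c water temperature (deg C); must lie in (-2, 40).
#' @param params a [default_params()] parameter set.
#' @return dimensionless factor in `[0, 1]`.
#' @examples
#' grazing_temperature_limitation(24, default_params())  # 1 at T_ref
#' @export
grazing_temperature_limitation <- function(T_c, params) {
  if (any(!is.finite(T_c)) || any(T_c < -2) || any(T_c > 40)) {
    stop("temperature out of the admissible range (-2..40 deg C): ",
         paste(format(T_c[!is.finite(T_c) | T_c < -2 | T_c > 40]),
               collapse = ", "), call. = FALSE)
  }
  cl <- params$closure
  pmin(1, cl$Q10 ^ ((T_c - cl$T_ref) / 10))
}

#' Grazing fluxes on phytoplankton and bacteria
#'
#' The specific grazing rate on each prey is `g_max * f(T)`, optionally
#' saturating in prey carbon (Holling II, `closure$K_prey`; linear when
#' `Inf`). Element fluxes follow prey stoichiometry exactly: grazed N equals
#' grazed C times the prey N:C quota, and chlorophyll is removed at the same
#' specific rate as phytoplankton carbon.
#'
#' @param state a [bgc_state()].
#' @param T_c temperature (deg C).
#' @param params a [default_params()] parameter set.
#' @param version model version.
#' @return list of class `bgc_grazing` with per-prey element fluxes
#'   (umol/L/d; Chla in ug/L/d): `phy = c(C, N, P, Chla)`,
#'   `bac = c(C, N, P)` (P entries `NA` under `noP`), and the realized
#'   specific rates `rate_phy`, `rate_bac` (1/d).
#' @export
grazing_fluxes <- function(state, T_c, params,
                           version = attr(state, "version")) {
  check_version(version)
  cl <- params$closure
  fT <- grazing_temperature_limitation(T_c, params)
  holl <- function(prey_c) {
    if (is.finite(cl$K_prey)) prey_c / (prey_c + cl$K_prey) else 1
  }
  cb <- unname(state[["Cb"]])
  cba <- unname(state[["Cba"]])
  g_phy <- cl$g_phy * fT * holl(cb)
  g_bac <- cl$g_bac * fT * holl(cba)
  isP <- version == "P"
  phy <- c(C = g_phy * cb,
           N = g_phy * unname(state[["Nb"]]),
           P = if (isP) g_phy * unname(state[["Pb"]]) else NA_real_,
           Chla = g_phy * unname(state[["Chla"]]))
  bac <- c(C = g_bac * cba,
           N = g_bac * unname(state[["Nba"]]),
           P = if (isP) g_bac * unname(state[["Pba"]]) else NA_real_)
  structure(list(phy = phy, bac = bac, rate_phy = g_phy, rate_bac = g_bac,
                 fT = fT),
            class = "bgc_grazing")
}

#' Redistribution of grazed matter (implicit closure)
#'
#' Everything grazed by zooplankton and higher trophic levels is returned to
#' the organic and inorganic pools: a fraction `frac_pom` to detrital
#' particulate matter (sloppy feeding/egestion), `frac_dom` to labile
#' dissolved matter, and `frac_dim` to the inorganic pools (excretion:
#' NH4 for N, PO4 for P). The inorganic fraction of grazed carbon is
#' zooplankton respiration: it leaves the modelled carbon pools and consumes
#' oxygen stoichiometrically. Mass closure is exact per element.
#'
#' @param g a [grazing_fluxes()] result.
#' @param params a [default_params()] parameter set.
#' @param version model version.
#' @return named numeric tendency contribution over the destination pools
#'   plus `zoo_respiration` (umol C/L/d, reported, not a pool).
#' @export
closure_redistribution <- function(g, params, version) {
  check_version(version)
  cl <- params$closure
  fr <- c(cl$frac_pom, cl$frac_dom, cl$frac_dim)
  if (any(fr < 0) || abs(sum(fr) - 1) > 1e-12) {
    stop("closure redistribution fractions must be >= 0 and sum to 1",
         call. = FALSE)
  }
  gC <- g$phy[["C"]] + g$bac[["C"]]
  gN <- g$phy[["N"]] + g$bac[["N"]]
  out <- c(
    DPOC = cl$frac_pom * gC, LDOC = cl$frac_dom * gC,
    DPON = cl$frac_pom * gN, LDON = cl$frac_dom * gN,
    NH4 = cl$frac_dim * gN,
    zoo_respiration = cl$frac_dim * gC
  )
  if (version == "P") {
    gP <- g$phy[["P"]] + g$bac[["P"]]
    out <- c(out, DPOP = cl$frac_pom * gP, LDOP = cl$frac_dom * gP,
             PO4 = cl$frac_dim * gP)
  }
  out
}

#' Remineralization of organic matter
#'
#' First-order hydrolysis of detrital particulate matter to the labile
#' dissolved pools and first-order remineralization of dissolved organic
#' matter to the inorganic pools, element-parallel for C, N and P (the P
#' chain mirrors the N chain with its own rate). Dissolved organic carbon is
#' oxidized (oxygen consumed per mol C). An optional Q10 factor
#' (`remin$Q10`, 1 = off) scales all rates with temperature.
#'
#' @param state a [bgc_state()].
#' @param T_c temperature (deg C).
#' @param params a [default_params()] parameter set.
#' @param version model version.
#' @return named numeric tendency contribution over
#'   `DPOC, DPON, (DPOP), LDOC, LDON, (LDOP), NH4, (PO4), O`.
#' @export
remineralization <- function(state, T_c, params,
                             version = attr(state, "version")) {
  check_version(version)
  rm <- params$remin
  tf <- if (rm$Q10 == 1) 1 else rm$Q10 ^ ((T_c - rm$T_ref) / 10)
  s <- function(v) unname(state[[v]])
  hyd_c <- rm$hydrolysis * tf * s("DPOC")
  hyd_n <- rm$hydrolysis * tf * s("DPON")
  rem_c <- rm$remin_c * tf * s("LDOC")
  rem_n <- rm$remin_n * tf * s("LDON")
  out <- c(
    DPOC = -hyd_c, DPON = -hyd_n,
    LDOC = hyd_c - rem_c, LDON = hyd_n - rem_n,
    NH4 = rem_n,
    O = -params$oxygen$gamma_OC * rem_c
  )
  if (version == "P") {
    hyd_p <- rm$hydrolysis * tf * s("DPOP")
    rem_p <- rm$remin_p * tf * s("LDOP")
    out <- c(out, DPOP = -hyd_p, LDOP = hyd_p - rem_p, PO4 = rem_p)
  }
  out
}

#' Nitrification
#'
#' First-order oxidation of ammonium to nitrate, `flux = k_nitrif * NH4`,
#' conserving total nitrogen and consuming oxygen stoichiometrically
#' (`oxygen$gamma_ON` mol O2 per mol N). Set `remin$k_nitrif = 0` to disable.
#'
#' @param state a [bgc_state()].
#' @param params a [default_params()] parameter set.
#' @return named numeric tendency contribution over `NH4`, `NO3`, `O`.
#' @export
nitrification <- function(state, params) {
  nh4 <- unname(state[["NH4"]])
  if (nh4 < 0) stop("NH4 must be >= 0", call. = FALSE)
  fl <- params$remin$k_nitrif * nh4
  c(NH4 = -fl, NO3 = fl, O = -params$oxygen$gamma_ON * fl)
}
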