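#' Phytoplankton nutrient limitation (Liebig co-limitation)
#'
#' Per-element limitation is the normalized internal quota
#' `(Q - Q_min) / (Q_max - Q_min)` clamped to `[0, 1]`; the realized
#' limitation `Qstar` is the Liebig minimum over the elements carried by the
#' model version (N only under `noP`, N and P under `P`). The reported
#' `limiting_element` is the argmin; ties are reported as `"N"`, and a fully
#' satiated cell (`Qstar = 1`) reports `"none"`.
#'
#' @param q a [compute_quotas()] result.
#' @param params a [default_params()] parameter set.
#' @param version model version; defaults to the version the quotas were
#'   computed under.
#' @return list of class `bgc_limitation`: `limN`, `limP` (NA under `noP`),
#'   `Qstar`, `limiting_element`.
#' @export
nutrient_limitation <- function(q, params, version = q$version) {
  check_version(version)
  pp <- params$phyto
  limN <- .clamp01((q$QN - pp$QN_min) / (pp$QN_max - pp$QN_min))
  if (version == "P") {
    limP <- .clamp01((q$QP - pp$QP_min) / (pp$QP_max - pp$QP_min))
    Qstar <- min(limN, limP)
    elem <- if (Qstar >= 1) "none" else if (limN <= limP) "N" else "P"
  } else {
    limP <- NA_real_
    Qstar <- limN
    elem <- if (Qstar >= 1) "none" else "N"
  }
  structure(list(limN = limN, limP = limP, Qstar = Qstar,
                 limiting_element = elem),
            class = "bgc_limitation")
}

# Specific photosynthesis rate (1/d): saturating P-E curve with nutrient
# co-limitation of the light-saturated plateau. The Qstar -> 0 limit is
# taken analytically (rate -> 0), avoiding 0/0.
.photo_rate <- function(theta, E, Qstar, PCm, alpha_chl) {
  if (E < 0) stop("irradiance must be >= 0", call. = FALSE)
  if (Qstar <= 0 || PCm <= 0) return(0)
  sat <- PCm * Qstar
  sat * (1 - exp(-alpha_chl * theta * E / sat))
}

#' Gross primary production
#'
#' `GPP = Cb * PCm * Qstar * (1 - exp(-alpha_chl * theta * E / (PCm * Qstar)))`
#' in umol C/L/d: a saturating photosynthesis-irradiance curve whose
#' light-saturated plateau is down-regulated by the most limiting internal
#' quota. GPP is 0 at `E = 0`, tends to `Cb * PCm * Qstar` as `E` grows, and
#' goes continuously to 0 as `Qstar` goes to 0.
#'
#' @param state a [bgc_state()].
#' @param q a [compute_quotas()] result.
#' @param E scalar irradiance (W/m2, photosynthetically available).
#' @inheritParams nutrient_limitation
#' @return carbon flux (umol C/L/d).
#' @export
gross_primary_production <- function(state, q, E, params,
                                     version = attr(state, "version")) {
  lim <- nutrient_limitation(q, params, version)
  unname(state[["Cb"]]) *
    .photo_rate(q$theta, E, lim$Qstar, params$phyto$PCm, params$phyto$alpha_chl)
}

#' Phytoplankton nutrient uptake
#'
#' Each uptake is `Cb * Vmax * S / (S + K) * hunger`, where `hunger` is the
#' normalized quota head-room `(Q_max - Q) / (Q_max - Q_min)` clamped to
#' `[0, 1]`: uptake shuts down as the cell approaches satiation. An optional
#' ammonium inhibition of nitrate uptake (`phyto$nh4_inhib`, off by default)
#' multiplies the NO3 term by `K_i / (K_i + NH4)`.
#'
#' @inheritParams gross_primary_production
#' @return named numeric: `NO3`, `NH4` and (version `P`) `PO4` uptake fluxes
#'   into phytoplankton biomass (umol/L/d).
#' @export
nutrient_uptake <- function(state, q, params,
                            version = attr(state, "version")) {
  check_version(version)
  pp <- params$phyto
  cb <- unname(state[["Cb"]])
  no3 <- unname(state[["NO3"]])
  nh4 <- unname(state[["NH4"]])
  hungerN <- .clamp01((pp$QN_max - q$QN) / (pp$QN_max - pp$QN_min))
  inhib <- if (is.finite(pp$nh4_inhib)) {
    pp$nh4_inhib / (pp$nh4_inhib + nh4)
  } else 1
  out <- c(
    NO3 = cb * pp$V_NO3 * no3 / (no3 + pp$K_NO3) * hungerN * inhib,
    NH4 = cb * pp$V_NH4 * nh4 / (nh4 + pp$K_NH4) * hungerN
  )
  if (version == "P") {
    po4 <- unname(state[["PO4"]])
    hungerP <- .clamp01((pp$QP_max - q$QP) / (pp$QP_max - pp$QP_min))
    out <- c(out, PO4 = cb * pp$V_PO4 * po4 / (po4 + pp$K_PO4) * hungerP)
  }
  pmax(out, 0)
}

# Chlorophyll synthesis ratio rho (ug Chl per umol C of gross production):
# photoacclimation target. rho tracks theta_max scaled by (i) the nutrient
# co-limitation Qstar, so that P (or N) starvation also caps pigment
# synthesis, and (ii) the ratio of realized photosynthesis to light capture
# (low light -> rho near theta_max, high light -> pigment dilution). Clamped
# into [theta_min, theta_max] so theta relaxes within its bounds.
.rho_chl <- function(theta, E, Qstar, pp) {
  capture <- pp$alpha_chl * theta * E
  photo <- .photo_rate(theta, E, Qstar, pp$PCm, pp$alpha_chl)
  accl <- if (capture > 0) min(1, photo / capture) else 1
  min(pp$theta_max, max(pp$theta_min, pp$theta_max * Qstar * accl))
}

#' Chlorophyll-a tendency
#'
#' Synthesis is `rho_chl * GPP` where `rho_chl` is the photoacclimation
#' target ratio (see Details); all specific carbon losses (respiration,
#' exudation, mortality, grazing) remove chlorophyll at the same specific
#' rate, so `theta = Chla/Cb` relaxes toward `rho_chl` at the rate of gross
#' growth. As `Qstar` decreases toward zero, so do `rho_chl` and hence
#' `theta`; at `Qstar = 0` synthesis vanishes.
#'
#' @inheritParams gross_primary_production
#' @param grazing_specific specific grazing loss rate applied to the
#'   phytoplankton pool (1/d); defaults to 0 (chlorophyll physiology only).
#' @return chlorophyll flux (ug/L/d).
#' @export
chlorophyll_tendency <- function(state, q, E, params,
                                 version = attr(state, "version"),
                                 grazing_specific = 0) {
  if (E < 0) stop("irradiance must be >= 0", call. = FALSE)
  lim <- nutrient_limitation(q, params, version)
  pp <- params$phyto
  gpp <- unname(state[["Cb"]]) *
    .photo_rate(q$theta, E, lim$Qstar, pp$PCm, pp$alpha_chl)
  rho <- .rho_chl(q$theta, E, lim$Qstar, pp)
  loss_specific <- pp$resp + pp$exud + pp$mort + grazing_specific
  rho * gpp - loss_specific * unname(state[["Chla"]])
}

#' Phytoplankton source-minus-sink terms
#'
#' Tendencies for `Cb`, `Nb`, (`Pb` under version `P`) and `Chla`:
#' carbon gains gross primary production and loses respiration, exudation,
#' mortality and grazing; nitrogen gains NO3+NH4 uptake and loses mortality
#' and grazing; phosphorus mirrors nitrogen with PO4 uptake; chlorophyll per
#' [chlorophyll_tendency()].
#'
#' @param state a [bgc_state()].
#' @param forcing named list or vector with at least `temp` (deg C) and `E`
#'   (W/m2).
#' @param params a [default_params()] parameter set.
#' @param version model version.
#' @return named numeric tendency for the phytoplankton pools (per day).
#' @export
phyto_sms <- function(state, forcing, params,
                      version = attr(state, "version")) {
  sms <- total_sms(state, forcing, params, version)
  vars <- intersect(c("Cb", "Nb", "Pb", "Chla"), names(sms))
  sms[vars]
}
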