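#' Bacterial co-limitation of production
#'
#' Bacterial growth is co-limited by the intracellular C, N and P status.
#' For each element X the stress ratio is `r_X = Q_X_min / Q_X`; it rises
#' toward 1 as the cell is starved of X, and the most restrictive element is
#' the one with the highest ratio (ties broken in the fixed order C, N, P).
#' The per-element limitation term is
#' `l_X = clamp01((1 - r_X) / (1 - r_X_sat))` with `r_X_sat = Q_X_min /
#' Q_X_max` (so `l_X = 1` at full satiation and 0 at the minimum quota), and
#' the realized co-limitation is the Liebig minimum `f = min_X l_X`.
#' Phosphorus is excluded from the competition under the `noP` version.
#'
#' The carbon quota is carried per unit nitrogen (`Q_C = Cba/Nba`), so
#' carbon limitation expresses a low cellular C:N ratio (carbon-starved
#' cells); N and P quotas are per unit carbon.
#'
#' @param q a [compute_quotas()] result.
#' @param params a [default_params()] parameter set.
#' @param version model version.
#' @return list of class `bgc_bact_limitation`: `f` in `[0,1]`, stress
#'   ratios `r_C`, `r_N`, `r_P` (NA under `noP`) and `limiting_element`.
#' @export
bacterial_limitation <- function(q, params, version = q$version) {
  check_version(version)
  pb <- params$bacteria
  lim_term <- function(Q, Qmin, Qmax) {
    r <- Qmin / Q
    rsat <- Qmin / Qmax
    list(r = r, l = .clamp01((1 - r) / (1 - rsat)))
  }
  C <- lim_term(q$QC_ba, pb$QC_min, pb$QC_max)
  N <- lim_term(q$QN_ba, pb$QN_min, pb$QN_max)
  if (version == "P") {
    P <- lim_term(q$QP_ba, pb$QP_min, pb$QP_max)
    r <- c(C = C$r, N = N$r, P = P$r)
    f <- min(C$l, N$l, P$l)
  } else {
    P <- list(r = NA_real_, l = NA_real_)
    r <- c(C = C$r, N = N$r)
    f <- min(C$l, N$l)
  }
  # highest stress ratio wins; which.max keeps the first maximum -> C, N, P
  structure(list(f = f, r_C = C$r, r_N = N$r, r_P = P$r,
                 l_C = C$l, l_N = N$l, l_P = P$l,
                 limiting_element = names(r)[which.max(r)]),
            class = "bgc_bact_limitation")
}

#' Bacterial production
#'
#' `BP = Cba * mu_max * f`: the carbon-specific production capped by the
#' maximum growth rate and scaled by the quota co-limitation.
#'
#' @param state a [bgc_state()].
#' @param lim a [bacterial_limitation()] result.
#' @param params a [default_params()] parameter set.
#' @return production (umol C/L/d).
#' @export
bacterial_production <- function(state, lim, params) {
  unname(state[["Cba"]]) * params$bacteria$mu_max * lim$f
}

# Shared uptake kinetics helper: Michaelis-Menten in the substrate,
# down-regulated by the quota head-room of the element the substrate carries.
.bact_hunger <- function(q, pb, version) {
  list(
    C = .clamp01((pb$QC_max - q$QC_ba) / (pb$QC_max - pb$QC_min)),
    N = .clamp01((pb$QN_max - q$QN_ba) / (pb$QN_max - pb$QN_min)),
    P = if (version == "P") {
      .clamp01((pb$QP_max - q$QP_ba) / (pb$QP_max - pb$QP_min))
    } else NA_real_
  )
}

#' Bacterial substrate uptake
#'
#' Saturating uptake of labile dissolved and detrital particulate organic
#' matter plus the mineral nutrients NH4 and PO4, per substrate:
#' `Cba * Vmax * S / (S + K) * hunger`, with `hunger` the quota head-room of
#' the element carried by the substrate. Detrital uptake is an effective
#' hydrolysis-then-uptake pathway with a single rate (no intermediate pool).
#' With `bacteria$mineral_uptake = "deficit"` (default), NH4 and PO4 are
#' taken only while the corresponding quota is unsatiated, which is already
#' expressed by the hunger factor. Organic-carbon uptake is additionally
#' capped so that assimilated carbon (`GE * uptake_C`) cannot exceed the
#' nutrient-limited production capacity `Cba * mu_max * min(l_N, l_P)`; the
#' cap deliberately excludes the carbon term of the co-limitation, because
#' carbon uptake is itself the route out of carbon starvation. The cap
#' scales LDOC and DPOC uptake proportionally.
#'
#' @param state a [bgc_state()].
#' @param q a [compute_quotas()] result.
#' @param params a [default_params()] parameter set.
#' @param version model version.
#' @return named numeric fluxes (umol/L/d) out of `LDOC`, `DPOC`, `LDON`,
#'   `DPON`, `NH4` and, under version `P`, `LDOP`, `DPOP`, `PO4`, into the
#'   corresponding bacterial element pools.
#' @export
bacterial_uptake <- function(state, q, params,
                             version = attr(state, "version")) {
  check_version(version)
  pb <- params$bacteria
  cba <- unname(state[["Cba"]])
  h <- .bact_hunger(q, pb, version)
  mm <- function(S, V, K, hunger) cba * V * S / (S + K) * hunger
  s <- function(v) unname(state[[v]])
  up_ldoc <- mm(s("LDOC"), pb$V_LDOC, pb$K_LDOC, h$C)
  up_dpoc <- mm(s("DPOC"), pb$V_DPOC, pb$K_DPOC, h$C)
  # acquisition cap on carbon assimilation: nutrient-only limitation, since
  # carbon uptake is itself the source of the carbon quota (capping it by
  # carbon-limited production would lock starved cells in place)
  lim <- bacterial_limitation(q, params, version)
  f_nut <- if (version == "P") min(lim$l_N, lim$l_P) else lim$l_N
  tot_c <- up_ldoc + up_dpoc
  allowed <- if (pb$GE > 0) cba * pb$mu_max * f_nut / pb$GE else Inf
  if (tot_c > allowed && tot_c > 0) {
    scale <- allowed / tot_c
    up_ldoc <- up_ldoc * scale
    up_dpoc <- up_dpoc * scale
  }
  deficit <- identical(pb$mineral_uptake, "deficit")
  out <- c(
    LDOC = up_ldoc, DPOC = up_dpoc,
    LDON = mm(s("LDON"), pb$V_LDON, pb$K_LDON, h$N),
    DPON = mm(s("DPON"), pb$V_DPON, pb$K_DPON, h$N),
    NH4 = mm(s("NH4"), pb$V_NH4, pb$K_NH4, if (deficit) h$N else 1)
  )
  if (version == "P") {
    out <- c(out,
      LDOP = mm(s("LDOP"), pb$V_LDOP, pb$K_LDOP, h$P),
      DPOP = mm(s("DPOP"), pb$V_DPOP, pb$K_DPOP, h$P),
      PO4 = mm(s("PO4"), pb$V_PO4, pb$K_PO4, if (deficit) h$P else 1)
    )
  }
  pmax(out, 0)
}

#' Bacterial source-minus-sink terms
#'
#' Tendencies for `Cba`, `Nba` and (version `P`) `Pba`: element pools gain
#' substrate uptake and lose respiration (carbon, per the growth
#' efficiency), quota-overflow release to the inorganic pools
#' (remineralization by bacteria), mortality to detritus, and grazing.
#'
#' @inheritParams phyto_sms
#' @return named numeric tendency for the bacterial pools (per day).
#' @export
bacteria_sms <- function(state, forcing, params,
                         version = attr(state, "version")) {
  sms <- total_sms(state, forcing, params, version)
  vars <- intersect(c("Cba", "Nba", "Pba"), names(sms))
  sms[vars]
}
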