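# Flux-based assembly of the full source-minus-sink (SMS) vector.
#
# Every biogeochemical process is an elementary transfer between a source
# pool and a destination pool (0 = outside the modelled pools, e.g. CO2 for
# respiration or light for chlorophyll synthesis). The tendency vector is
# the incidence matrix times the flux vector, which makes element
# conservation structural: a transfer always debits its source exactly as
# much as it credits its destination. The positivity limiter in the
# integrator scales whole transfers (never one end), so conservation
# survives limiting.

# Build the flux topology + evaluation closure for one (params, version).
make_sms <- function(params, version) {
  check_version(version)
  validate_params(params)
  vars <- state_vars(version)
  nv <- length(vars)
  isP <- version == "P"

  # --- topology ------------------------------------------------------------
  def <- list(
    # name                src      dst
    c("gpp",              "ext",   "Cb"),
    c("resp_phy",         "Cb",    "ext"),
    c("exud",             "Cb",    "LDOC"),
    c("mort_phy_c",       "Cb",    "DPOC"),
    c("graz_phy_c_pom",   "Cb",    "DPOC"),
    c("graz_phy_c_dom",   "Cb",    "LDOC"),
    c("graz_phy_c_dim",   "Cb",    "ext"),
    c("upt_no3",          "NO3",   "Nb"),
    c("upt_nh4",          "NH4",   "Nb"),
    c("mort_phy_n",       "Nb",    "DPON"),
    c("graz_phy_n_pom",   "Nb",    "DPON"),
    c("graz_phy_n_dom",   "Nb",    "LDON"),
    c("graz_phy_n_dim",   "Nb",    "NH4"),
    c("chl_synth",        "ext",   "Chla"),
    c("chl_loss",         "Chla",  "ext"),
    c("upt_ldoc",         "LDOC",  "Cba"),
    c("upt_dpoc",         "DPOC",  "Cba"),
    c("resp_ba",          "Cba",   "ext"),
    c("excess_c",         "Cba",   "ext"),
    c("mort_ba_c",        "Cba",   "DPOC"),
    c("graz_bac_c_pom",   "Cba",   "DPOC"),
    c("graz_bac_c_dom",   "Cba",   "LDOC"),
    c("graz_bac_c_dim",   "Cba",   "ext"),
    c("upt_ldon",         "LDON",  "Nba"),
    c("upt_dpon",         "DPON",  "Nba"),
    c("upt_nh4_ba",       "NH4",   "Nba"),
    c("rel_nh4",          "Nba",   "NH4"),
    c("mort_ba_n",        "Nba",   "DPON"),
    c("graz_bac_n_pom",   "Nba",   "DPON"),
    c("graz_bac_n_dom",   "Nba",   "LDON"),
    c("graz_bac_n_dim",   "Nba",   "NH4"),
    c("hyd_c",            "DPOC",  "LDOC"),
    c("hyd_n",            "DPON",  "LDON"),
    c("remin_c",          "LDOC",  "ext"),
    c("remin_n",          "LDON",  "NH4"),
    c("nitrif",           "NH4",   "NO3"),
    c("o_prod",           "ext",   "O"),
    c("o_resp",           "O",     "ext"),
    c("o_nitrif",         "O",     "ext")
  )
  if (isP) {
    def <- c(def, list(
      c("upt_po4",        "PO4",   "Pb"),
      c("mort_phy_p",     "Pb",    "DPOP"),
      c("graz_phy_p_pom", "Pb",    "DPOP"),
      c("graz_phy_p_dom", "Pb",    "LDOP"),
      c("graz_phy_p_dim", "Pb",    "PO4"),
      c("upt_ldop",       "LDOP",  "Pba"),
      c("upt_dpop",       "DPOP",  "Pba"),
      c("upt_po4_ba",     "PO4",   "Pba"),
      c("rel_po4",        "Pba",   "PO4"),
      c("mort_ba_p",      "Pba",   "DPOP"),
      c("graz_bac_p_pom", "Pba",   "DPOP"),
      c("graz_bac_p_dom", "Pba",   "LDOP"),
      c("graz_bac_p_dim", "Pba",   "PO4"),
      c("hyd_p",          "DPOP",  "LDOP"),
      c("remin_p",        "LDOP",  "PO4")
    ))
  }
  flux_names <- vapply(def, `[`, "", 1L)
  src <- match(vapply(def, `[`, "", 2L), vars)  # NA for "ext"
  dst <- match(vapply(def, `[`, "", 3L), vars)
  nf <- length(flux_names)
  inc <- matrix(0, nv, nf, dimnames = list(vars, flux_names))
  for (j in seq_len(nf)) {
    if (!is.na(src[j])) inc[src[j], j] <- inc[src[j], j] - 1
    if (!is.na(dst[j])) inc[dst[j], j] <- inc[dst[j], j] + 1
  }
  fi <- stats::setNames(seq_len(nf), flux_names)  # name -> index
  vi <- stats::setNames(seq_len(nv), vars)

  # --- parameter locals (extracted once for speed) -------------------------
  pp <- params$phyto; pb <- params$bacteria; cl <- params$closure
  rm_ <- params$remin; ox <- params$oxygen
  floor_ <- params$numerics$biomass_floor
  chl_elems <- if (isP) c("C", "N", "P") else c("C", "N")
  deficit <- identical(pb$mineral_uptake, "deficit")
  nh4_inhib <- pp$nh4_inhib

  # --- evaluation ----------------------------------------------------------
  # y: plain numeric vector in `vars` order; temp in deg C; E in W/m2.
  fun <- function(y, temp, E) {
    fl <- numeric(nf)
    fT <- min(1, cl$Q10 ^ ((temp - cl$T_ref) / 10))
    cb <- y[1L]; nb <- y[2L]; chla <- y[3L]; cba <- y[4L]; nba <- y[5L]
    dpoc <- y[6L]; dpon <- y[7L]; ldoc <- y[8L]; ldon <- y[9L]
    no3 <- y[10L]; nh4 <- y[11L]
    if (isP) {
      pbm <- y[13L]; pba <- y[14L]; dpop <- y[15L]; ldop <- y[16L]
      po4 <- y[17L]
    }
    Qstar <- NA_real_; limN <- NA_real_; limP <- NA_real_
    f_ba <- NA_real_; bp <- 0

    # phytoplankton -------------------------------------------------------
    if (cb >= floor_) {
      QN <- nb / cb; theta <- chla / cb
      limN <- min(1, max(0, (QN - pp$QN_min) / (pp$QN_max - pp$QN_min)))
      if (isP) {
        QP <- pbm / cb
        limP <- min(1, max(0, (QP - pp$QP_min) / (pp$QP_max - pp$QP_min)))
        Qstar <- min(limN, limP)
      } else {
        Qstar <- limN
      }
      photo <- .photo_rate(theta, E, Qstar, pp$PCm, pp$alpha_chl)
      gpp <- cb * photo
      fl[1L] <- gpp
      fl[2L] <- pp$resp * cb
      fl[3L] <- pp$exud * cb
      fl[4L] <- pp$mort * cb
      g_phy <- cl$g_phy * fT *
        (if (is.finite(cl$K_prey)) cb / (cb + cl$K_prey) else 1)
      gc <- g_phy * cb
      fl[5L] <- cl$frac_pom * gc
      fl[6L] <- cl$frac_dom * gc
      fl[7L] <- cl$frac_dim * gc
      hungerN <- min(1, max(0, (pp$QN_max - QN) / (pp$QN_max - pp$QN_min)))
      inhib <- if (is.finite(nh4_inhib)) nh4_inhib / (nh4_inhib + nh4) else 1
      fl[8L] <- cb * pp$V_NO3 * no3 / (no3 + pp$K_NO3) * hungerN * inhib
      fl[9L] <- cb * pp$V_NH4 * nh4 / (nh4 + pp$K_NH4) * hungerN
      gn <- g_phy * nb
      fl[10L] <- pp$mort * nb
      fl[11L] <- cl$frac_pom * gn
      fl[12L] <- cl$frac_dom * gn
      fl[13L] <- cl$frac_dim * gn
      rho <- .rho_chl(theta, E, Qstar, pp)
      fl[14L] <- rho * gpp
      fl[15L] <- (pp$resp + pp$exud + pp$mort + g_phy) * chla
      if (isP) {
        hungerP <- min(1, max(0, (pp$QP_max - QP) / (pp$QP_max - pp$QP_min)))
        fl[fi[["upt_po4"]]] <- cb * pp$V_PO4 * po4 / (po4 + pp$K_PO4) * hungerP
        gp <- g_phy * pbm
        fl[fi[["mort_phy_p"]]] <- pp$mort * pbm
        fl[fi[["graz_phy_p_pom"]]] <- cl$frac_pom * gp
        fl[fi[["graz_phy_p_dom"]]] <- cl$frac_dom * gp
        fl[fi[["graz_phy_p_dim"]]] <- cl$frac_dim * gp
      }
    }

    # bacteria ------------------------------------------------------------
    if (cba >= floor_ && nba >= floor_ * pb$QN_min) {
      QC <- cba / nba; QNb <- nba / cba
      lterm <- function(Q, qmin, qmax) {
        r <- qmin / Q
        min(1, max(0, (1 - r) / (1 - qmin / qmax)))
      }
      lC <- lterm(QC, pb$QC_min, pb$QC_max)
      lN <- lterm(QNb, pb$QN_min, pb$QN_max)
      if (isP) {
        QPb <- pba / cba
        lP <- lterm(QPb, pb$QP_min, pb$QP_max)
        f_ba <- min(lC, lN, lP)
      } else {
        f_ba <- min(lC, lN)
      }
      hC <- min(1, max(0, (pb$QC_max - QC) / (pb$QC_max - pb$QC_min)))
      hN <- min(1, max(0, (pb$QN_max - QNb) / (pb$QN_max - pb$QN_min)))
      up_ldoc <- cba * pb$V_LDOC * ldoc / (ldoc + pb$K_LDOC) * hC
      up_dpoc <- cba * pb$V_DPOC * dpoc / (dpoc + pb$K_DPOC) * hC
      # the acquisition cap uses the nutrient-only limitation: carbon
      # uptake is itself the source of the carbon quota, so capping it by
      # carbon-limited production would lock starved cells in place
      f_nut <- if (isP) min(lN, lP) else lN
      bp_cap <- cba * pb$mu_max * f_nut
      tot_c <- up_ldoc + up_dpoc
      allowed <- if (pb$GE > 0) bp_cap / pb$GE else Inf
      if (tot_c > allowed && tot_c > 0) {
        sc <- allowed / tot_c
        up_ldoc <- up_ldoc * sc
        up_dpoc <- up_dpoc * sc
        tot_c <- allowed
      }
      fl[16L] <- up_ldoc
      fl[17L] <- up_dpoc
      fl[18L] <- (1 - pb$GE) * tot_c        # respiration per growth efficiency
      bp <- pb$GE * tot_c
      fl[19L] <- pb$k_excess * max(0, QC - pb$QC_max) * nba  # excess C (per N)
      fl[20L] <- pb$mort * cba
      g_bac <- cl$g_bac * fT *
        (if (is.finite(cl$K_prey)) cba / (cba + cl$K_prey) else 1)
      gc <- g_bac * cba
      fl[21L] <- cl$frac_pom * gc
      fl[22L] <- cl$frac_dom * gc
      fl[23L] <- cl$frac_dim * gc
      fl[24L] <- cba * pb$V_LDON * ldon / (ldon + pb$K_LDON) * hN
      fl[25L] <- cba * pb$V_DPON * dpon / (dpon + pb$K_DPON) * hN
      fl[26L] <- cba * pb$V_NH4 * nh4 / (nh4 + pb$K_NH4) *
        (if (deficit) hN else 1)
      fl[27L] <- pb$k_excess * max(0, QNb - pb$QN_max) * cba
      fl[28L] <- pb$mort * nba
      gn <- g_bac * nba
      fl[29L] <- cl$frac_pom * gn
      fl[30L] <- cl$frac_dom * gn
      fl[31L] <- cl$frac_dim * gn
      if (isP) {
        hP <- min(1, max(0, (pb$QP_max - QPb) / (pb$QP_max - pb$QP_min)))
        fl[fi[["upt_ldop"]]] <- cba * pb$V_LDOP * ldop / (ldop + pb$K_LDOP) * hP
        fl[fi[["upt_dpop"]]] <- cba * pb$V_DPOP * dpop / (dpop + pb$K_DPOP) * hP
        fl[fi[["upt_po4_ba"]]] <- cba * pb$V_PO4 * po4 / (po4 + pb$K_PO4) *
          (if (deficit) hP else 1)
        fl[fi[["rel_po4"]]] <- pb$k_excess * max(0, QPb - pb$QP_max) * cba
        fl[fi[["mort_ba_p"]]] <- pb$mort * pba
        gp <- g_bac * pba
        fl[fi[["graz_bac_p_pom"]]] <- cl$frac_pom * gp
        fl[fi[["graz_bac_p_dom"]]] <- cl$frac_dom * gp
        fl[fi[["graz_bac_p_dim"]]] <- cl$frac_dim * gp
      }
    }

    # remineralization + nitrification ------------------------------------
    tf <- if (rm_$Q10 == 1) 1 else rm_$Q10 ^ ((temp - rm_$T_ref) / 10)
    fl[32L] <- rm_$hydrolysis * tf * dpoc
    fl[33L] <- rm_$hydrolysis * tf * dpon
    fl[34L] <- rm_$remin_c * tf * ldoc
    fl[35L] <- rm_$remin_n * tf * ldon
    fl[36L] <- rm_$k_nitrif * nh4
    if (isP) {
      fl[fi[["hyd_p"]]] <- rm_$hydrolysis * tf * dpop
      fl[fi[["remin_p"]]] <- rm_$remin_p * tf * ldop
    }

    # oxygen ---------------------------------------------------------------
    resp_total <- fl[2L] + fl[7L] + fl[18L] + fl[19L] + fl[23L] + fl[34L]
    fl[37L] <- ox$gamma_OC * fl[1L]
    fl[38L] <- ox$gamma_OC * resp_total
    fl[39L] <- ox$gamma_ON * fl[36L]

    list(fl = fl,
         diag = c(Qstar = Qstar, limN = limN, limP = limP, f_ba = f_ba,
                  fT = fT, gpp = fl[1L], bp = bp, resp = resp_total,
                  nitrif = fl[36L]))
  }

  list(fun = fun, inc = inc, src = src, dst = dst,
       flux_names = flux_names, fi = fi, vi = vi, vars = vars, nf = nf,
       version = version)
}

#' Full source-minus-sink tendency vector
#'
#' Assembles the tendencies of all state variables from the process modules:
#' phytoplankton growth and losses, bacterial dynamics, the implicit grazing
#' closure with its redistribution, remineralization, nitrification and the
#' stoichiometric oxygen terms. In a closed box the assembly conserves total
#' N (and total P under version `P`) exactly, and the summed carbon-pool
#' tendency equals gross primary production minus total respiration
#' (there is no dissolved inorganic carbon pool).
#'
#' @param state a [bgc_state()].
#' @param forcing named list/vector with `temp` (deg C) and `E` (W/m2).
#' @param params a [default_params()] parameter set.
#' @param version model version.
#' @return named numeric tendency (umol/L/d; Chla in ug/L/d), with
#'   attributes `fluxes` (named elementary fluxes) and `diag` (named
#'   diagnostics: `Qstar`, `limN`, `limP`, `f_ba`, `fT`, `gpp`, `bp`,
#'   `resp`, `nitrif`).
#' @export
total_sms <- function(state, forcing, params,
                      version = attr(state, "version")) {
  machine <- make_sms(params, version)
  y <- as.numeric(state[machine$vars])
  if (any(!is.finite(y))) stop("non-finite state", call. = FALSE)
  temp <- unname(forcing[["temp"]])
  E <- unname(forcing[["E"]])
  if (!is.finite(temp) || !is.finite(E)) {
    stop("forcing sample must provide finite `temp` and `E`", call. = FALSE)
  }
  if (E < 0) stop("irradiance must be >= 0", call. = FALSE)
  res <- machine$fun(y, temp, E)
  tend <- drop(machine$inc %*% res$fl)
  names(tend) <- machine$vars
  attr(tend, "fluxes") <- stats::setNames(res$fl, machine$flux_names)
  attr(tend, "diag") <- res$diag
  tend
}
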