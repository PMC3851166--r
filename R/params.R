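#' Default parameter set
#'
#' All rate constants, quota bounds, stoichiometric and optical constants of
#' the model, grouped by process. Values are a coherent default set for a
#' diatom-dominated, oligotrophic NW-Mediterranean coastal system; every
#' entry can be overridden via `...` using `group.name` keys (e.g.
#' `phyto.PCm = 1.5`) or by editing the returned list. Internal units are
#' micromol/L, micrograms of chlorophyll per L, days and degrees Celsius.
#'
#' Groups:
#' \describe{
#'   \item{phyto}{`PCm` maximum C-specific growth rate (1/d); `alpha_chl`
#'     initial slope of the P-E curve (umol C (ug Chl)^-1 (W m^-2)^-1 d^-1);
#'     `theta_min`/`theta_max` chlorophyll:carbon bounds (ug Chl / umol C);
#'     `QN_min`/`QN_max`, `QP_min`/`QP_max` quota bounds (mol:mol); uptake
#'     maxima `V*` (mol per mol C per d) and half-saturations `K*` (umol/L);
#'     linear loss rates `resp`, `exud`, `mort` (1/d); `nh4_inhib` optional
#'     ammonium inhibition constant for NO3 uptake (umol/L; `Inf` = off).}
#'   \item{bacteria}{`mu_max` maximum growth rate (1/d); `GE` growth
#'     efficiency (dimensionless); quota bounds `QC_*` (mol C per mol N,
#'     the carbon cell quota is carried per unit nitrogen), `QN_*`, `QP_*`
#'     (mol per mol C); Michaelis-Menten uptake kinetics per substrate;
#'     `k_excess` relaxation rate for quota overflow release (1/d); `mort`
#'     linear mortality to detritus (1/d); `mineral_uptake` `"deficit"`
#'     (NH4/PO4 taken only while the quota is unsatiated) or `"always"`.}
#'   \item{closure}{`g_phy`, `g_bac` maximum specific grazing rates (1/d);
#'     `Q10`, `T_ref` temperature limitation of grazing; `K_prey` optional
#'     Holling-II half saturation (umol C/L; `Inf` = linear response);
#'     `frac_pom`, `frac_dom`, `frac_dim` redistribution of grazed matter to
#'     particulate, dissolved-organic and inorganic pools (sum to 1; the
#'     inorganic carbon fraction is zooplankton respiration).}
#'   \item{remin}{`hydrolysis` POM to DOM rate (1/d); `remin_n`, `remin_p`,
#'     `remin_c` DOM to inorganic rates (1/d); `k_nitrif` nitrification rate
#'     (1/d); `Q10`, `T_ref` optional temperature scaling (`Q10 = 1` = off).}
#'   \item{optics}{`k_w` background light extinction (1/m); `k_chl`
#'     chlorophyll-specific extinction (1/m per ug Chl/L).}
#'   \item{oxygen}{`gamma_OC` mol O2 per mol C fixed or respired (138/106);
#'     `gamma_ON` mol O2 per mol N nitrified.}
#'   \item{numerics}{`biomass_floor` (umol C/L) below which quotas are
#'     frozen rather than divided.}
#' }
#'
#' @param ... overrides as `group.name = value`.
#' @return nested list of class `bgc_params`.
#' @examples
#' p <- default_params(phyto.PCm = 1.5)
#' p$phyto$PCm
#' @export
default_params <- function(...) {
  p <- list(
    phyto = list(
      PCm = 2.0, alpha_chl = 0.30,
      theta_min = 0.05, theta_max = 0.6,
      QN_min = 0.05, QN_max = 0.20,
      QP_min = 0.002, QP_max = 0.012,
      V_NO3 = 0.28, K_NO3 = 0.5,
      V_NH4 = 0.14, K_NH4 = 0.1,
      V_PO4 = 0.02, K_PO4 = 0.05,
      resp = 0.05, exud = 0.05, mort = 0.05,
      nh4_inhib = Inf
    ),
    bacteria = list(
      mu_max = 2.0, GE = 0.3,
      QC_min = 3.3, QC_max = 6.7,
      QN_min = 0.15, QN_max = 0.30,
      QP_min = 0.005, QP_max = 0.030,
      V_LDOC = 6.0, K_LDOC = 10,
      V_DPOC = 0.5, K_DPOC = 10,
      V_LDON = 1.0, K_LDON = 1,
      V_DPON = 0.1, K_DPON = 1,
      V_LDOP = 0.06, K_LDOP = 0.1,
      V_DPOP = 0.01, K_DPOP = 0.1,
      V_NH4 = 0.30, K_NH4 = 0.5,
      V_PO4 = 0.02, K_PO4 = 0.05,
      k_excess = 1.0, mort = 0.05,
      mineral_uptake = "deficit"
    ),
    closure = list(
      g_phy = 0.8, g_bac = 0.5,
      Q10 = 2.0, T_ref = 24, K_prey = Inf,
      frac_pom = 1 / 3, frac_dom = 1 / 3, frac_dim = 1 / 3
    ),
    remin = list(
      hydrolysis = 0.05,
      remin_n = 0.1, remin_p = 0.1, remin_c = 0.05,
      k_nitrif = 0.05,
      Q10 = 1.0, T_ref = 20
    ),
    optics = list(k_w = 0.04, k_chl = 0.03),
    oxygen = list(gamma_OC = 138 / 106, gamma_ON = 2.0),
    numerics = list(biomass_floor = 1e-8)
  )
  ov <- list(...)
  for (key in names(ov)) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    if (length(parts) != 2L || is.null(p[[parts[1]]]) ||
        is.null(p[[parts[1]]][[parts[2]]])) {
      stop("unknown parameter override: ", key, call. = FALSE)
    }
    p[[parts[1]]][[parts[2]]] <- ov[[key]]
  }
  class(p) <- "bgc_params"
  validate_params(p)
  p
}

#' Validate a parameter set
#'
#' Checks that rates are non-negative, that every `*_min` is strictly below
#' its `*_max`, and that the closure redistribution fractions sum to 1.
#'
#' @param p a `bgc_params` list.
#' @return `p` invisibly; errors on violation.
#' @export
validate_params <- function(p) {
  stopifnot(is.list(p))
  num <- unlist(lapply(p[c("phyto", "bacteria", "closure", "remin",
                           "optics", "oxygen")], function(g) {
    Filter(is.numeric, g)
  }))
  bad <- names(num)[!is.na(num) & num < 0]
  if (length(bad)) {
    stop("negative parameter value(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  pairs <- list(
    c("phyto", "theta_min", "theta_max"),
    c("phyto", "QN_min", "QN_max"), c("phyto", "QP_min", "QP_max"),
    c("bacteria", "QC_min", "QC_max"), c("bacteria", "QN_min", "QN_max"),
    c("bacteria", "QP_min", "QP_max"))
  for (pr in pairs) {
    if (p[[pr[1]]][[pr[2]]] >= p[[pr[1]]][[pr[3]]]) {
      stop(pr[1], "$", pr[2], " must be < ", pr[1], "$", pr[3], call. = FALSE)
    }
  }
  fr <- p$closure$frac_pom + p$closure$frac_dom + p$closure$frac_dim
  if (abs(fr - 1) > 1e-12) {
    stop("closure redistribution fractions must sum to 1 (got ", fr, ")",
         call. = FALSE)
  }
  invisible(p)
}

#' Read / write a parameter set as a flat key-value YAML file
#'
#' The on-disk schema is flat: one `group.name: value` entry per parameter,
#' so a file is both diffable and hand-editable. Missing keys fall back to
#' [default_params()].
#'
#' @param file path to a YAML file.
#' @param p a `bgc_params` list (for writing).
#' @return `read_params()` returns a validated `bgc_params`;
#'   `write_params()` returns `file` invisibly.
#' @export
read_params <- function(file) {
  kv <- yaml::read_yaml(file)
  if (length(kv) == 0) return(default_params())
  do.call(default_params, kv)
}

#' @rdname read_params
#' @export
write_params <- function(p, file) {
  validate_params(p)
  flat <- list()
  for (g in c("phyto", "bacteria", "closure", "remin", "optics", "oxygen",
              "numerics")) {
    for (nm in names(p[[g]])) {
      flat[[paste(g, nm, sep = ".")]] <- p[[g]][[nm]]
    }
  }
  yaml::write_yaml(flat, file, precision = 17)  # lossless double round-trip
  invisible(file)
}

#' @export
print.bgc_params <- function(x, ...) {
  cat("<bgc_params> groups:", paste(names(x), collapse = ", "), "\n")
  invisible(x)
}
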