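#' Intracellular quotas
#'
#' Computes the phytoplankton quotas QN = Nb/Cb, QP = Pb/Cb (mol:mol) and
#' theta = Chla/Cb (ug Chl per umol C), and the bacterial quotas
#' Q_C = Cba/Nba (mol C per mol N), Q_N = Nba/Cba and Q_P = Pba/Cba.
#' Quotas are ratios, so they are invariant to scaling the biomass pools by
#' any positive factor. When a denominator biomass is below the configured
#' floor (`params$numerics$biomass_floor`) the quota is undefined and an
#' error naming the pool is raised; the integrator handles that case by
#' freezing quotas instead (see [run_box()]).
#'
#' @param state a [bgc_state()].
#' @param params a [default_params()] parameter set.
#' @return list of class `bgc_quotas` with entries `QN`, `QP`, `theta`,
#'   `QC_ba`, `QN_ba`, `QP_ba` and `version`. Phosphorus quotas are `NA`
#'   under the `noP` version.
#' @examples
#' p <- default_params()
#' q <- compute_quotas(make_initial_state("P", "oligotrophic-summer"), p)
#' q$QN   # mol N per mol C
#' @export
compute_quotas <- function(state, params) {
  version <- attr(state, "version")
  check_version(version)
  floor <- params$numerics$biomass_floor
  cb <- unname(state[["Cb"]])
  cba <- unname(state[["Cba"]])
  nba <- unname(state[["Nba"]])
  if (!is.finite(cb) || cb < floor) {
    stop("degenerate state: Cb (", format(cb), ") below biomass floor ",
         format(floor), call. = FALSE)
  }
  if (!is.finite(cba) || cba < floor) {
    stop("degenerate state: Cba (", format(cba), ") below biomass floor ",
         format(floor), call. = FALSE)
  }
  if (!is.finite(nba) || nba < floor * params$bacteria$QN_min) {
    stop("degenerate state: Nba (", format(nba), ") below biomass floor",
         call. = FALSE)
  }
  isP <- version == "P"
  q <- list(
    QN = unname(state[["Nb"]]) / cb,
    QP = if (isP) unname(state[["Pb"]]) / cb else NA_real_,
    theta = unname(state[["Chla"]]) / cb,
    QC_ba = cba / nba,
    QN_ba = nba / cba,
    QP_ba = if (isP) unname(state[["Pba"]]) / cba else NA_real_,
    version = version
  )
  structure(q, class = "bgc_quotas")
}

# clamp to [0, 1]
.clamp01 <- function(x) pmin(1, pmax(0, x))
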