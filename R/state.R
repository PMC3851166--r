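# Variable registry. Order matters: the C/N ("noP") configuration is exactly
# the first 12 entries; the C/N/P ("P") configuration appends the 5 phosphorus
# pools. Units are micromol/L except chlorophyll-a (microgram/L).
.var_table <- data.frame(
  name = c("Cb", "Nb", "Chla", "Cba", "Nba", "DPOC", "DPON", "LDOC", "LDON",
           "NO3", "NH4", "O", "Pb", "Pba", "DPOP", "LDOP", "PO4"),
  long_name = c(
    "Phytoplankton carbon", "Phytoplankton nitrogen",
    "Phytoplankton chlorophyll-a", "Bacterial carbon", "Bacterial nitrogen",
    "Detrital particulate organic carbon",
    "Detrital particulate organic nitrogen",
    "Labile dissolved organic carbon", "Labile dissolved organic nitrogen",
    "Nitrate", "Ammonium", "Dissolved oxygen",
    "Phytoplankton phosphorus", "Bacterial phosphorus",
    "Detrital particulate organic phosphorus",
    "Labile dissolved organic phosphorus", "Phosphate"),
  units = c(rep("umol/L", 2), "ug/L", rep("umol/L", 14)),
  stringsAsFactors = FALSE
)

#' Model version tags
#'
#' Two nested configurations are supported: `"noP"`, the carbon/nitrogen
#' model with 12 state variables, and `"P"`, the carbon/nitrogen/phosphorus
#' model with 17 state variables (the 12 shared pools plus phytoplankton P,
#' bacterial P, detrital particulate organic P, labile dissolved organic P
#' and phosphate).
#'
#' @param version character, `"noP"` or `"P"`.
#' @return `model_versions()` returns the vector of valid tags;
#'   `check_version()` returns `version` invisibly or errors.
#' @export
model_versions <- function() c("noP", "P")

#' @rdname model_versions
#' @export
check_version <- function(version) {
  if (!(is.character(version) && length(version) == 1L &&
        version %in% model_versions())) {
    stop("unknown model version: ", paste(version, collapse = ", "),
         " (expected \"noP\" or \"P\")", call. = FALSE)
  }
  invisible(version)
}

#' State-variable names for a model version
#'
#' @inheritParams model_versions
#' @param long logical; return long names instead of symbols.
#' @return character vector of variable names (12 for `"noP"`, 17 for `"P"`).
#' @export
state_vars <- function(version, long = FALSE) {
  check_version(version)
  n <- if (version == "noP") 12L else 17L
  if (long) .var_table$long_name[seq_len(n)] else .var_table$name[seq_len(n)]
}

#' Units of the state variables
#' @inheritParams state_vars
#' @return named character vector of units.
#' @export
state_units <- function(version) {
  v <- state_vars(version)
  stats::setNames(.var_table$units[match(v, .var_table$name)], v)
}

#' Construct a state vector
#'
#' @param values named numeric vector covering exactly the variables of the
#'   version (see [state_vars()]).
#' @inheritParams model_versions
#' @return a named numeric vector of class `bgc_state` with a `version`
#'   attribute.
#' @export
bgc_state <- function(values, version) {
  check_version(version)
  vars <- state_vars(version)
  if (is.null(names(values)) || !setequal(names(values), vars)) {
    extra <- setdiff(names(values), vars)
    miss <- setdiff(vars, names(values))
    stop("state variables do not match version ", version,
         if (length(miss)) paste0("; missing: ", paste(miss, collapse = ", ")),
         if (length(extra)) paste0("; not in version: ",
                                   paste(extra, collapse = ", ")),
         call. = FALSE)
  }
  x <- as.numeric(values[vars])
  names(x) <- vars
  if (any(!is.finite(x))) {
    stop("non-finite state value(s): ",
         paste(vars[!is.finite(x)], collapse = ", "), call. = FALSE)
  }
  if (any(x < 0)) {
    stop("concentrations must be non-negative; negative: ",
         paste(vars[x < 0], collapse = ", "), call. = FALSE)
  }
  structure(x, class = "bgc_state", version = version)
}

#' @export
print.bgc_state <- function(x, ...) {
  cat("<bgc_state> version", attr(x, "version"), "-", length(x), "variables\n")
  print(stats::setNames(as.numeric(x), names(x)))
  invisible(x)
}

#' Read a state variable, enforcing version membership
#'
#' Querying a phosphorus-only pool (e.g. `PO4`) on a `noP` state is an error,
#' not an `NA`.
#'
#' @param state a [bgc_state()].
#' @param var variable name.
#' @return the scalar concentration.
#' @export
state_get <- function(state, var) {
  vars <- names(state)
  if (!var %in% vars) {
    if (var %in% .var_table$name) {
      stop("variable ", var, " is not part of version ",
           attr(state, "version"), call. = FALSE)
    }
    stop("unknown state variable: ", var, call. = FALSE)
  }
  unname(state[[var]])
}

# Registered initial-condition presets. Concentrations are typical of the
# study region: the oligotrophic-summer preset matches the observed mean
# surface concentrations (chlorophyll-a 0.4 ug/L, PO4 0.03 umol/L and
# DIN 1 umol/L); winter-mixed carries the high-nutrient, cooler mixed-layer
# signature with nitrate near 3 umol/L.
.presets <- list(
  "oligotrophic-summer" = c(
    Cb = 1.6667, Nb = 0.2, Chla = 0.4, Cba = 0.8, Nba = 0.16,
    DPOC = 2, DPON = 0.25, LDOC = 40, LDON = 1.5,
    NO3 = 0.8, NH4 = 0.2, O = 230,
    Pb = 0.010, Pba = 0.008, DPOP = 0.010, LDOP = 0.02, PO4 = 0.03),
  "winter-mixed" = c(
    Cb = 1.0, Nb = 0.16, Chla = 0.35, Cba = 0.5, Nba = 0.11,
    DPOC = 1.5, DPON = 0.2, LDOC = 45, LDON = 1.8,
    NO3 = 3.0, NH4 = 0.3, O = 255,
    Pb = 0.008, Pba = 0.006, DPOP = 0.008, LDOP = 0.03, PO4 = 0.15),
  "abiotic" = c(
    Cb = 0, Nb = 0, Chla = 0, Cba = 0, Nba = 0,
    DPOC = 0, DPON = 0, LDOC = 0, LDON = 0,
    NO3 = 0, NH4 = 0, O = 230,
    Pb = 0, Pba = 0, DPOP = 0, LDOP = 0, PO4 = 0)
)

#' Named initial-condition presets
#' @return character vector of registered preset names.
#' @export
state_presets <- function() names(.presets)

#' Build an initial state from a named preset
#'
#' @inheritParams model_versions
#' @param preset one of [state_presets()].
#' @return a [bgc_state()] for the requested version; phosphorus pools are
#'   absent under `"noP"`.
#' @examples
#' s <- make_initial_state("P", "oligotrophic-summer")
#' s["Chla"]                      # 0.4 ug/L
#' s["NO3"] + s["NH4"]            # DIN = 1 umol/L
#' @export
make_initial_state <- function(version, preset = "oligotrophic-summer") {
  check_version(version)
  if (!(is.character(preset) && length(preset) == 1L &&
        preset %in% names(.presets))) {
    stop("unknown preset: ", paste(preset, collapse = ", "),
         "; registered presets: ", paste(names(.presets), collapse = ", "),
         call. = FALSE)
  }
  bgc_state(.presets[[preset]][state_vars(version)], version)
}

#' Validate a state vector against the type invariants
#'
#' Reports (does not throw): negative concentrations, a chlorophyll-to-carbon
#' ratio outside the parameter bounds, and variables foreign to the version.
#'
#' @param state a [bgc_state()] (or named numeric vector plus `version`).
#' @param params a [default_params()] parameter set.
#' @param version optional override of the state's version attribute.
#' @param tol numeric slack applied to the theta bounds (integrator round-off).
#' @return character vector of violations; `character(0)` when valid.
#' @export
validate_state <- function(state, params, version = attr(state, "version"),
                           tol = 1e-9) {
  check_version(version)
  vars <- state_vars(version)
  out <- character(0)
  foreign <- setdiff(names(state), vars)
  for (v in foreign) {
    out <- c(out, paste0(v, ": variable not in version ", version))
  }
  known <- intersect(names(state), vars)
  for (v in known) {
    val <- unname(state[[v]])
    if (!is.finite(val)) out <- c(out, paste0(v, ": non-finite value"))
    else if (val < 0) out <- c(out, paste0(v, ": negative (", format(val), ")"))
  }
  cb <- if ("Cb" %in% known) unname(state[["Cb"]]) else NA_real_
  ch <- if ("Chla" %in% known) unname(state[["Chla"]]) else NA_real_
  if (is.finite(cb) && is.finite(ch) && cb > params$numerics$biomass_floor) {
    th <- ch / cb
    if (th < params$phyto$theta_min - tol ||
        th > params$phyto$theta_max + tol) {
      out <- c(out, paste0("Chla/Cb: theta ", format(th),
                           " outside [", params$phyto$theta_min, ", ",
                           params$phyto$theta_max, "]"))
    }
  }
  out
}
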