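# Shared builders for fast test runs.

# A short constant-forcing box configuration.
quick_config <- function(version = "P", duration = 5, dt = 0.01,
                         state = "oligotrophic-summer",
                         params = default_params(), temp = 20, E0 = 80,
                         save_every = 1) {
  list(version = version, params = params, state = state,
       forcing = list(temp = temp, E = E0),
       duration = duration, dt = dt, save_every = save_every)
}

# Element pool membership (mirrors the conservation accounting).
pools_of <- function(element, version = "P") {
  p <- switch(element,
    N = c("Nb", "Nba", "DPON", "LDON", "NO3", "NH4"),
    P = c("Pb", "Pba", "DPOP", "LDOP", "PO4"),
    C = c("Cb", "Cba", "DPOC", "LDOC"),
    stop("unknown element"))
  intersect(p, state_vars(version))
}

element_total <- function(state_row, element, version = "P") {
  sum(state_row[pools_of(element, version)])
}

# A forcing sample as total_sms() expects it.
sample_forcing <- function(temp = 20, E = 80) list(temp = temp, E = E)
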