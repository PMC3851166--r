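---
title: "Model formulation and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model formulation and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(planktonbox)
```

`planktonbox` is a desk-scale simulator for the plankton ecosystem of an
oligotrophic, river-influenced coastal sea, built around three ideas:

1. **Variable internal stoichiometry.** Phytoplankton and heterotrophic
   bacteria are represented by separate carbon, nitrogen and (optionally)
   phosphorus pools, so their elemental composition is a dynamical quantity
   rather than a fixed Redfield ratio. Growth is controlled by internal
   quotas (Droop kinetics), not directly by external concentrations.
2. **Nested model versions.** The `"noP"` configuration integrates 12 state
   variables (C and N cycles); the `"P"` configuration adds five phosphorus
   pools for a total of 17. The two versions share every C/N process, which
   lets the effect of resolving the P cycle be isolated cleanly.
3. **Structural conservation.** All biogeochemical tendencies are assembled
   from elementary transfers between pools through an incidence matrix, so
   closed-system conservation of N and P is a property of the data
   structure, not of careful bookkeeping in each process routine.

# State variables

```{r}
data.frame(variable = state_vars("P"),
           long_name = state_vars("P", long = TRUE),
           units = unname(state_units("P")))
```

The first 12 rows are the `"noP"` configuration. Concentrations are
micromolar; chlorophyll-a is in µg L⁻¹.

# Phytoplankton

**Quotas and limitation.** The internal quotas are $Q_N = N_b/C_b$ and
$Q_P = P_b/C_b$. Each element limits growth through its normalized quota,

$$\mathrm{lim}_X = \mathrm{clamp}_{[0,1]}
\frac{Q_X - Q_X^{min}}{Q_X^{max} - Q_X^{min}},$$

and the realized limitation is Liebig's minimum,
$Q^* = \min(\mathrm{lim}_N, \mathrm{lim}_P)$ (N only under `"noP"`). The
reported limiting element is the argument of the minimum.

**Photosynthesis.** Gross primary production follows a saturating
photosynthesis–irradiance curve whose plateau is down-regulated by $Q^*$:

$$\mathrm{GPP} = C_b \, P^C_m \, Q^* \left(1 -
\exp\!\frac{-\alpha^{chl}\,\theta\,E}{P^C_m\,Q^*}\right),$$

with $\theta = \mathrm{Chl}a/C_b$ the chlorophyll-to-carbon ratio and $E$
the irradiance. The $Q^* \to 0$ limit is taken analytically (GPP → 0), so
there is no removable singularity in code.

**Photoacclimation.** Chlorophyll synthesis is a fraction $\rho^{chl}$ of
GPP, where $\rho^{chl}$ tracks $\theta_{max}$ scaled by $Q^*$ and by the
ratio of realized photosynthesis to light capture (Geider-style pigment
dilution under high light), clamped into $[\theta_{min}, \theta_{max}]$.
All specific carbon losses remove chlorophyll at the same specific rate, so
$\theta$ relaxes toward $\rho^{chl}$ at the gross growth rate and can never
leave its bounds — an invariant the test suite checks at both ends.

**Uptake.** Nutrient uptake is Michaelis–Menten in the external substrate,
multiplied by the quota head-room
$(Q^{max}-Q)/(Q^{max}-Q^{min})$, so uptake shuts down smoothly at
satiation. An optional ammonium inhibition of nitrate uptake is off by
default.

# Heterotrophic bacteria

Bacteria carry C, N and P pools. Because only the three pools exist, the
carbon quota is expressed per unit nitrogen ($Q_C = C_{ba}/N_{ba}$, the
cellular C:N ratio) while N and P quotas are per unit carbon. For each
element the stress ratio $r_X = Q_X^{min}/Q_X$ rises toward 1 under
starvation; the co-limitation is

$$f = \min_X \; \mathrm{clamp}_{[0,1]}
\frac{1 - r_X}{1 - Q_X^{min}/Q_X^{max}},$$

and bacterial production is $BP = C_{ba}\,\mu_{max}\,f$. Organic C, N and P
(labile dissolved and detrital particulate) and the mineral nutrients NH₄
and PO₄ are taken up with Michaelis–Menten kinetics scaled by quota
head-room. Carbon acquisition is capped by the *nutrient-only* production
capacity $C_{ba}\,\mu_{max}\min(l_N, l_P)/GE$: the cap deliberately
excludes the carbon limitation term, because carbon uptake is itself the
only route out of carbon starvation — capping it by carbon-limited
production would lock a starved cell in a self-reinforcing collapse. A
fraction $(1-GE)$ of the carbon taken up is respired; quota overflow beyond
$Q^{max}$ is released to the inorganic pools (ammonium, phosphate, respired
C), which is how bacteria act as remineralizers when C-rich substrate is
abundant.

# Implicit zooplankton closure

Zooplankton are not a state variable. Grazing on phytoplankton and
bacteria is an explicit function with specific rate $g_{max} f(T)$, where
$f(T) = \min(1, Q_{10}^{(T - T_{ref})/10})$ with $Q_{10} = 2$ and
$T_{ref} = 24$ °C — weak in winter, saturating in summer. Element fluxes
follow prey stoichiometry exactly. Grazed matter is redistributed in fixed
fractions to detrital particulate, labile dissolved and inorganic pools;
the inorganic fraction of grazed carbon is the implicit zooplankton
respiration and consumes oxygen. An optional Holling-II prey saturation is
available (`closure$K_prey`), linear by default.

# Remineralization, nitrification, oxygen

Detrital particulate matter hydrolyses to the labile dissolved pools, and
dissolved organic matter remineralizes to NH₄ and PO₄, each at first order
(optionally Q10-scaled). Nitrification oxidizes NH₄ to NO₃ at first order.
Oxygen follows the photosynthetic quotient $\gamma_{OC} = 138/106$ mol O₂
per mol C for production and all respiration, and $\gamma_{ON} = 2$ mol O₂
per mol N nitrified. There is no inorganic carbon pool, so respired C
leaves the system; the carbon budget is closed diagnostically against the
accumulated GPP and respiration fluxes.

# Numerical scheme

Tendencies are integrated with forward Euler at a default step of 20
minutes. Positivity is enforced by *flux limiting*: when the sinks of a
pool would overdraw it within one step, every outgoing transfer of that
pool is scaled so that it lands exactly at zero. Because whole transfers
(source and destination together) are scaled, the limiter preserves element
conservation exactly — clipping is never used. The scheme is first-order
accurate; the test suite verifies the error halves when the step is halved
against a fine-step reference, and the acceptance suite verifies N and P
closed-box drift below $10^{-8}$ relative over five simulated years.

The 1-D column couples per-level biogeochemistry through (i) light,
attenuated as $k(z) = k_w + k_{chl}\,\mathrm{Chl}a(z)$ through the
simulated chlorophyll profile, and (ii) conservative explicit vertical
diffusion, with the usual stability bound $\Delta t\, K_z/\Delta z^2 \le
1/2$ enforced with a clear error message.

# Forcing construction

River and point sources enter a box as concentration tendencies
$c\,Q\,86400/V$. The loaders encode the source-specific rules: only the
labile fraction of riverine organic matter enters the model (20% of DOC
and DON, 88% of DOP and POP, 18% of POC, 20% of PON), the branch of the
river entering the domain carries 90% of the measured total discharge, the
lagoon outlet is a constant source (20 m³ s⁻¹ with a fixed concentration
row), the wastewater plant has daily measured NO₃/NH₄ with fixed PO₄
(13.4 µmol L⁻¹) and organics, and small urban rivers borrow their nutrient
concentrations from the main river. Atmospheric deposition converts
collector totals to mean fluxes between sample dates (dry) and
concentration × rainfall (wet), divided by the mixed-layer depth.

# Synthetic scenarios

`synthetic_forcing()` generates seeded, bitwise-reproducible forcing at
daily resolution: a seasonal cycle (temperature 13–25 °C, irradiance
30–180 W m⁻², winter-strong entrainment of an N-rich deep reservoir,
N:P ≈ 21, which leaves the stratified summer surface P-limited), plus two
event types. *Upwelling pulses* cool the box by 5 °C and entrain deep
water with low N:P (≈ 11, reflecting preferential P regeneration at
depth), driving a transient bloom and a switch of the limiting element to
nitrogen. *River intrusions* deliver low-salinity plume water whose
NO₃:PO₄ ratio is drawn in [65, 80] — strongly P-deficient relative to
planktonic demand — so the bloom response is much weaker when the P cycle
is resolved than in the C/N-only version. These problem sizes (one box,
daily forcing, 1–5 year runs) are this package's own choice of a
desk-scale analogue; they are not a reproduction of any 3-D hindcast.

# Skill statistics

For matched model–observation pairs the package computes percentage bias,
the cost function $CF = \overline{|M-O|}/\sigma_O$ with its OSPAR rating
(very good ≤ 1 < good ≤ 2 < reasonable ≤ 3 < poor), average absolute
error, RMSD, Pearson correlation and normalized target-diagram coordinates
$(\mathrm{uRMSD}^*, \mathrm{Bias}^*)$. With $1/n$ variances throughout, the
decomposition $\mathrm{RMSD}^2 = \mathrm{bias}^2 + \mathrm{uRMSD}^2$ holds
to machine precision; observation-normalized statistics use the sample
standard deviation by default (`population = FALSE`).

# Worked example

```{r example}
forcing <- synthetic_forcing(seed = 1, duration = 365,
                             scenario = "seasonal")
traj <- run_box(list(version = "P", state = "winter-mixed",
                     forcing = forcing, duration = 365, dt = 20 / 1440))
summary(traj$state[, "Chla"])
compute_budgets(traj)
```

Mean chlorophyll sits in the few-tenths µg L⁻¹ range typical of an
oligotrophic coastal surface layer, and the N/P budget residuals are at
round-off level.

```{r skill}
obs <- make_obs_fixture(traj, seed = 2, vars = "Chla", every_days = 14,
                        depths_m = 1, noise_cv = 0.25)
days <- as.numeric(as.Date(obs$timestamp) - as.Date("2008-01-01"))
idx <- vapply(days, function(d) which.min(abs(traj$time - d)), 0L)
skill_report(paired_series(traj$state[idx, "Chla"], obs$value,
                           variable = "Chla"))
```

# Parameter rationale

Defaults (`default_params()`) are a coherent set for a warm, oligotrophic
coastal system rather than a fit to any dataset: maximum phytoplankton
growth 2 d⁻¹ with N quota 0.05–0.20 and P quota 0.002–0.012 mol:mol
(internal N:P spanning Redfield), chlorophyll-to-carbon 0.05–0.6
µg µmol⁻¹, bacterial growth efficiency 0.3, grazing rates chosen so summer
top-down control roughly balances growth, and first-order
remineralization/nitrification rates of a few percent per day. Every value
can be overridden per call (`default_params(phyto.PCm = 1.5)`) or stored
in a flat YAML file (`write_params()`/`read_params()`).

# Limitations

* No inorganic carbon pool: respired C leaves the system, so pH/carbonate
  questions are out of scope and the C budget is closed diagnostically.
* The zooplankton closure has no biomass memory; prey removal responds
  instantaneously to temperature and prey.
* The 1-D column uses explicit diffusion, so strong mixing requires small
  steps; there is no sediment layer and no sinking velocity for detritus.
* Synthetic scenarios are statistical analogues for testing mechanisms,
  not reconstructions of observed years.
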