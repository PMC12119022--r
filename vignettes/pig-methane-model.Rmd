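---
title: "From pig diets to methane: the estimation chain in pigch4"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From pig diets to methane: the estimation chain in pigch4}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pigch4)
```

# The problem

Pig production emits methane from two places: the hindgut of the animal
(enteric fermentation) and the slurry — the mix of faeces, urine, washing
water and spilled feed handled as a liquid in pits beneath the barn floor
and later in an outdoor storage tank. Both sources feed on the same
upstream quantity: the fermentable organic matter that the diet supplies
and the animal does not digest. `pigch4` implements that causal chain as a
set of composable, testable stages for four pig categories (weaned pigs,
grower-finisher pigs, gestating sows, lactating sows):

1. **Diet mixing** — whole-diet nutrient concentrations from ingredient
   inclusions.
2. **Intake** — daily feed and nutrient intake at equal net-energy (feed
   unit) supply.
3. **Excretion** — digestibility-based faeces and urine flows, with the
   residual-fibre partition that drives everything downstream.
4. **Enteric methane** — published regressions on fermentable substrate
   intake.
5. **Slurry simulation** — a dynamic model of hydrolysis, methanogenesis
   and management events in the barn pit and the outdoor store.

# Diet mixing and the fibre bookkeeping

Each diet is a list of as-fed inclusion proportions over a feedstuff table
(per-ingredient DM in g/kg as-fed and nutrients in g/kg DM). Mixing works
on a DM basis: the DM proportion of ingredient $j$ is
$a_j = p_j d_j / \sum_k p_k d_k$, and every diet concentration is
$X_i = \sum_j a_j x_{ij}$. The central fibre quantity is **residual fibre**
(RF), a by-difference fraction:

$$\mathrm{RF} = \mathrm{OM} - \mathrm{CP} - \mathrm{CF} - \mathrm{starch} - \mathrm{sugar}
\quad (\mathrm{g/kg\ DM}).$$

RF splits further using indigestible NDF: iNDF passes both the pig and the
slurry untouched (it becomes the inert pool of the manure model), while
RF − iNDF is potentially degradable. Diet-level RF is computed both by
mixing ingredient RF values (the canonical route) and by difference on the
mixed proximate fractions; the two differ only through the rounding of
printed ingredient tables, and the package asserts they stay within
2 g/kg DM of each other on the built-in diets.

Two bookkeeping decisions deserve a note:

* **As-fed interpretation of the built-in formulations.** The source
  formulation tables are headed as DM percentages, but only the as-fed
  reading reproduces the published whole-diet DM values (e.g. 861 g/kg for
  the gestating-sow diet); the package therefore treats inclusion
  proportions as as-fed mass fractions throughout.
* **Mineral and amino-acid closure.** Pure minerals carry no organic
  matter; crystalline amino acids are assigned a crude-protein equivalent
  (N × 6.25 from the molecular formula, scaled by declared purity) with
  the non-protein mass in the ash closure term, so they contribute protein
  but no fibre. These rows are fixture choices, documented and editable —
  whether the original calculation used N × 6.25 or product declarations
  is not stated in the source.

A known discrepancy: the published diet-level RF values (e.g. 237 g/kg DM
for the gestating average diet) sit roughly 25 g/kg below any
reconstruction from the published ingredient tables by either route. The
supplementary formulations evidently differ slightly from the printed
ones; the package exposes both routes and does not chase the printed
diet-level RF.

# Feed intake at equal energy

Growing pigs are fed to a batch-cycle gain target:
$\text{intake} = \text{gain} \times \text{FE} / (\text{FU/kg}) / \text{days}$,
with gain in kg per cycle and feed efficiency FE in feed units per kg
gain. Sows get an annual feed-unit budget split over production stages,
divided by the days they actually spend in the section — 285 d/year in
gestation, 80 d/year in farrowing. The feeding-day denominator (rather
than 365) is what reproduces the published daily intakes from the
published stage budgets, e.g. $973.2/285/0.99 = 3.449$ kg/d for gestating
sows against a printed 3452 g/d.

Because all diets within a category are compared at equal FU intake,
fibre-rich diets (lower FU/kg) always raise as-fed intake — the dominant
mechanism behind every downstream diet effect.

Constants not printed in the source are fixture values calibrated once to
the published intakes and then frozen: weaned pigs 21 kg gain / 2.09 FU
per kg / 54 feeding days; grower-finishers 84 kg / 2.648 FU per kg / 84
feeding days. The energy densities of the fibre-substituted diet variants
are likewise not printed anywhere and cannot be reconstructed from any
per-ingredient FU table (the gestating soy-hull variant would need a
negative soy-hull energy density); each variant therefore carries its own
calibrated FU/kg, stored to three decimals in the package.

# Digestion and excretion

Apparent total-tract digestibility coefficients are applied per
ingredient and nutrient (OM, CP, CF, and starch+sugar as one pool with one
shared coefficient); intake = digested + excreted holds exactly by
construction. Derived quantities:

* **Fermentable fibre** (FF) = digested OM − digested CP − digested CF −
  digested starch+sugar, per kg feed DM — the substrate term of the sow
  enteric regression. FF can never exceed diet RF as long as the
  starch+sugar coefficient dominates, which the test suite checks on all
  built-in diets.
* **Urine**: 2.0 kg per kg DM intake (growing pigs) or 2.5 (sows); urine N
  from the linear prediction
  $-21.20 + 0.134\,\mathrm{CP} + 10.15\,\mathrm{DMI}$, except weaned pigs,
  where a nitrogen balance (intake − faecal − retained) is used with a
  configurable 25.6 g body N per kg gain (16% body protein).
* **Faeces mass**: $5.405 - 6.31\,d_{OM} + 0.505\,\mathrm{DMI}$ kg/d for
  all but weaned pigs, which use faecal DM / 0.25. The whole-diet $d_{OM}$
  is the intake-weighted mean of ingredient coefficients.
* **Faecal ash** closes faecal DM (excreted OM + unabsorbed ash) with a
  default apparent mineral absorption of 0.45 — chosen once so that faecal
  DM and its ash complement sit in the published range for all four
  categories.
* **Faecal VFA** is 2.87 g per kg fresh faeces; **urea** is 75% of urine N.

The digestibility table itself is the one deliberately *synthetic* input:
the source cites national normative tables without printing them, so the
package ships documented plausible values (cereal OM digestibility around
0.87–0.92, hulls and bran 0.64–0.77, a shared starch+sugar coefficient of
0.99, sow-class values slightly above growing-class). They reproduce the
published *orderings* of faecal DM across diets and the published
magnitude of faecal output, and they are plainly editable CSV.

# Enteric methane

Two regressions, chosen by category:

* growing pigs: $\mathrm{CH_4\,(L/d)} = -0.62 + 0.032 \times \mathrm{sNSP\ intake\ (g/d)} + 0.025 \times \mathrm{BW\ (kg)}$,
  clamped at zero;
* sows: $\mathrm{CH_4\,(L/d)} = 0.440 + 0.0206 \times \mathrm{FF\ intake\ (g/d)}$.

Litres convert to grams with a configurable density, default 0.716 g/L
(0 °C, 1 atm; 0.654 g/L at 25 °C is selectable). The source never states
its conversion convention and its printed g/d values cannot be matched
from the regression inputs at either density, so the package treats the
published enteric g/d values as reporting inputs rather than targets; the
derived reporting arithmetic (g per kg feed, annualisation by ×365/1000)
reproduces the published derived columns exactly. What *is* asserted is
structure: emissions rank with sNSP (or FF) intake across diets, sugar
beet pulp highest and wheat lowest, and lactating sows out-emit gestating
sows daily while the ranking reverses per kg of feed.

# The slurry model

The manure simulation is a compartment model in chemical oxygen demand
(COD), the common currency of anaerobic degradation. Excreted nutrients
map to COD pools once, at influent construction: carbohydrate-like pools
(residual fibre, starch+sugar) at 1.19 g COD/g, protein 1.42, fat 2.90,
VFA (as acetate) 1.07. Faecal iNDF enters an inert pool; faecal VFA seeds
the VFA pool; urine, faecal water and the water in spilled feed carry the
slurry mass.

Each degradable pool $P$ follows

$$\frac{dP}{dt} = P_{in} - \alpha(T)\,P - R(T)\,P,$$

with first-order hydrolysis $\alpha(T) = \alpha_{20} e^{0.08 (T - 20)}$
per pool (fast starch+sugar pool 0.30 d⁻¹ at 20 °C; protein 0.020; fat
0.005; degradable RF 0.008) and a slow aerobic surface respiration
$R(T)$ (0.008 d⁻¹ at 20 °C, same temperature form) that burns pool COD to
CO₂. Hydrolysed COD enters the VFA pool, which three methanogen
populations consume at

$$u_i = B_i\, u_{max,i}\, f_i(T)\, \frac{S}{K_{S,i} + S}\, \frac{1}{1 + (S/k_I)^2},$$

with $S$ the VFA concentration in g per kg slurry, half-saturation
constants 0.30 / 0.45 / 0.60 g/kg (the range quoted for slurry
methanogens), maximum uptakes 3 / 5 / 8 g COD per g biomass DM per day,
Gaussian temperature optima at 22 / 32 / 42 °C (width 8 °C), and a shared
VFA inhibition constant $k_I = 14$ g/kg. Consumed VFA COD splits into
emitted CH₄ COD and biomass growth by a yield of 0.05 g DM per g COD
(biomass C₅H₇O₂N at 1.42 g COD/g DM); biomass decays at 0.01 d⁻¹ back
into the protein pool; 4 g of CH₄-COD equal 1 g of CH₄. Fresh excreta
carry a methanogen inoculum of 9.5 g biomass DM per kg influent solids —
without it, a pit emptied weekly would wash the community out entirely,
which is not what field measurements show.

These kinetic constants are the package's own parameter set. The source
computed its manure emissions with an external model whose constants are
not printed; the defaults here were calibrated once against the published
*behaviour* — the ordering of diets and categories, the barn-versus-store
split as a function of removal interval, the seasonal storage dynamics,
and the spillage response including methanogen inhibition — and against
the published magnitudes within roughly ±50%. Absolute barn and storage
values are therefore checked as properties (COD conservation,
monotonicities, orderings, convergence, parameter recovery), not as
numbers.

## Management events

The barn pit runs at the category's constant in-barn temperature.
Influent flows while the section is occupied and pauses during the empty
days of each production cycle — that pause *is* the occupancy correction,
applied to influent rather than to emissions, which continue between
batches. Washing water arrives on the first empty day. At every removal
interval, and at each cycle end, all but a residual 5% of the pit
(configurable; the source is silent on the heel) transfers as a batch to
the outdoor store. The store follows a monthly temperature series, is
covered (no rain, no evaporation), and is emptied for field application
on the Danish pattern — 80% on day 105, 20% on day 288 — giving a mean
retention near 4.5 months. The packaged monthly temperature series is a
synthetic Danish-seasonality stand-in (the measured series lives in an
unavailable supplement) with a winter minimum of 1.8 °C and an
August-adjacent maximum of 17.4 °C.

## Numerics

Integration is fixed-step explicit Euler at `dt = 0.05` day with
non-negativity guards (transfers are scaled, never allowed to drive a
pool negative) and event handling at day boundaries: batch arrivals at
the start of a day, removals at its end. Halving the step changes annual
totals by well under 0.5% on the built-in scenarios. Every simulation
carries a full COD ledger — influent, CH₄, respiration, removals,
standing stock, biomass — and `cod_balance()` closes to machine precision
(the acceptance checks use 0.1% as the hard gate). Scenario runs simulate
two calendar years and report the second, so year one serves as spin-up
for methanogen biomass and store filling; this horizon is the package's
reporting choice and is configurable.

## Feed spillage

Spilled feed enters the pit uneaten: 2% of intake is the baseline
production condition, and the sweep covers 0–8%. Spillage is rich in
rapidly degradable starch and sugar, so it loads the fast pool. In sow
barns (long retention, large methanogen stocks) barn emission rises
monotonically with spillage across the swept range. In the
grower-finisher barn (7-day removal, small stocks) the fast pool
hydrolyses to more VFA than the community can take up, the inhibition
factor drops below 1, and barn emission plateaus and then falls — the
package reproduces this asymmetry, and the spillage sweep reports the
minimum inhibition factor alongside the emissions.

# The synthetic-data generator

`gen_feed_table()`, `gen_diet()`, `gen_temperature_series()` and
`gen_scenario()` generate random but invariant-true inputs from a single
integer seed: ingredient compositions are sampled so the by-difference RF
closure holds exactly (RF targeted into a configurable range, iNDF a
fraction of RF, sNSP a fraction of NSP), diets are two-ingredient blends
solved exactly for a target RF on the DM basis, and temperature series
are closed-form sinusoids. The generator emulates the *structure* of real
feed tables — not the Danish feed market's statistical distributions, nor
correlations between nutrients and digestibility. Passing pipeline tests
on generated data therefore demonstrates contract correctness (mass and
COD balances, invariant preservation, parameter recoverability), not
predictive accuracy for any real farm.

The test suite runs the full chain on 100 generated seeds (balance checks
at one-cycle horizon) plus multi-year runs on the built-in scenarios, and
recovers a known hydrolysis constant from a simulated emission ledger by
grid search to within 5%. Problem sizes in the suite (90–180-day property
windows, two-year scenario runs) are the package's own choices, sized so
the whole suite stays quick while every claim is still exercised end to
end.

# Known limitations

* The digestibility table and the manure kinetic constants are documented
  plausible/calibrated values, not normative data; absolute emission
  levels inherit that uncertainty, the orderings and balances much less so.
* Enteric predictions are linear regressions with all their fragility
  outside the calibration range; the growing-pig form clamps at zero for
  very small pigs on fibre-free diets.
* The slurry model ignores pH and sulfide chemistry, crust formation,
  N₂O and NH₃, and diet-dependent hydrolysis rates of a given pool.
* One animal place is simulated in isolation; farm-scale storage mixes
  manure of different ages and categories.
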