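# nanotwin

An in-silico manufacturing thread (digital twin) for a solidified drug
nanosuspension produced by wet media milling and spray drying. The package
covers four linked stages:

1. **Stabilizer screening** — rank stabilizer candidates by their
   interfacial Gibbs energy contribution, computed from segment-level pair
   potentials combined by the Berthelot–Lorentz rules.
2. **Wet media milling** — simulate comminution as a discrete breakage
   population balance and fit the tuning parameters of three nested kernel
   families (de Vegt, Kapur, Austin) to median-size D50(t) data.
3. **Data augmentation** — turn sparse milling experiments into dense
   reference profiles with a small feed-forward neural network (trained by
   hand-rolled backpropagation) or polynomial regression.
4. **Spray drying** — dry the milled suspension through coupled
   droplet/gas mass and energy balances advanced by the package's
   fixed-step BDF integrator, including a two-factor design-space sweep.

## The models in brief

Milling evolves the mass fractions $w_i$ on a descending geometric size
grid by the batch grinding balance

$$\frac{dw_i}{dt} \;=\; \sum_{j<i} S_j\,w_j\,b_{ij} \;-\; S_i\,w_i ,$$

where the breakage rate $S$ and fragment distribution $b$ come from one of
three nested kernels: de Vegt ($S \propto c\,x^{3/4}$, one parameter),
Kapur ($B = (x_i/x_j)^e$, $S = A x^k$, three parameters) or Austin
($B = \varphi r^\gamma + (1-\varphi) r^\beta$, $S = a (x/x_{crit})^d$ with
a hard stop below the critical size, five parameters). The discretization
conserves mass exactly by construction, and the finest bin is a sink.

Spray drying advances, per droplet class, the dry-basis moisture and
particle temperature, coupled to a well-mixed gas zone through the
evaporation rate $N = f\,(h/\lambda) A (T_v - T_{wb})$ with a falling-rate
factor $f = \min(1, x/x_{crit})$ and a wet-bulb temperature from the
adiabatic-saturation balance. The enthalpy bookkeeping is exact by design:
both water and energy closures sit at machine precision (~1e-15).

See the methods vignette (`vignettes/methods.Rmd`) for the full equations,
parameter conventions, numerical choices and known limitations.

## Worked example

```r
library(nanotwin)

## 1. pick the stabilizer
rank_stabilizers(stabilizer_table()[, c("name", "gmi")])
#>            name    gmi selected
#> 1 Poloxamer-188 0.0056     TRUE
#> 2 Poloxamer-407 0.0039    FALSE
#> 3        HPC-SL 0.0019    FALSE

## 2. augment the 18 experimental D50 points into a dense profile
data <- milling_experiments()
poly <- polyfit_profile(data, order = 2)
poly
#> poly_surrogate: order-2 fit, training MSE 1.13 %
ann <- train_ann(data)           # ~4 s
ann
#> ann_surrogate: 1-8-8-1 network, sigmoid hidden / ReLU output
#>   trained 20000 epochs (lr 0.05, seed 42); training MSE 1.11 %
ref <- augment_profile(poly, seq(0, 3600, length.out = 61), extrapolate = TRUE)

## 3. fit and compare the three breakage families (~40 s)
psd0 <- psd_lognormal(size_grid(), 1.5e-6, 1.5)
cmp <- compare_breakage(ref, psd0, n_starts = 8, seed = 42)
cmp
#> Breakage family comparison (relative MSE, %):
#>    family n_tuning_parameters mse_percent
#> 1  austin                   5  0.02089325
#> 2   kapur                   3  0.02089343
#> 3 de_vegt                   1  0.05168299

## 4. simulate milling with the best family
sim <- simulate_milling(psd0, cmp$fits$austin$model, t_end = 3600)
sim
#> milling_result: austin kernel, 61 output times over 3600 s
#>   D50: 1.497 -> 0.316 um (max |mass error| 4.4e-16)

## 5. spray-dry the milled suspension
w_end <- sim$w[nrow(sim$w), ]
dry <- simulate_spraydry(dryer_config(), psd = psd(size_grid(), w_end / sum(w_end)))
dry
#> spraydry_result: 5 solids x 5 droplet classes, bdf solver
#>   mean final moisture 0.002009 kg/kg; outlet gas 370.5 K
#>   closure: water 1.1e-15, enthalpy 4.3e-15 (relative)
```

The same thread runs end to end from one configuration:

```r
thread <- run_thread(load_run_config())   # or via the CLI:
# Rscript inst/cli/nanotwin.R run-thread --out results/
```

## Package layout

- `R/properties.R` — Gibbs-energy stabilizer screening
- `R/grid.R`, `R/breakage.R`, `R/milling.R` — population-balance milling
- `R/fit.R` — breakage-kernel fitting and family comparison
- `R/surrogate.R` — ANN and polynomial D50(t) surrogates
- `R/numerics.R` — fixed-step BDF integrator for implicit residual systems
- `R/spraydry.R` — droplet/gas drying balances and design space
- `R/config.R`, `R/fixtures.R`, `inst/cli/nanotwin.R` — orchestration,
  bundled reference tables, command-line front end
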