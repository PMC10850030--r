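# indoorheat

Workplace-specific indoor heat-stress projections from neural surrogates of
building thermal response.

## The problem

Occupational heat exposure happens indoors, but climate projections describe
the outdoors. Every room filters the outdoor signal differently — thermal
mass, solar gains, internal gains, heating — so two workplaces in the same
city can differ by thousands of annual heat-stress hours. `indoorheat`
implements a data-driven workflow for projecting indoor conditions at
individual workplaces:

1. **Learn the room.** A small neural network (one hidden layer, 16 sigmoid
   units, linear output) is trained per workplace and per target to map
   outdoor weather onto the indoor observable. Inputs are the six outdoor
   driver variables at time *t* — air temperature *T*ₐ, dew point *T*_d,
   wind *v*, pressure *p*, global irradiance *G*, long-wave downwelling
   *A*_G — plus *T*ₐ, *G* and *A*_G at *t* − 3, 6, 12 and 24 h (18 features;
   the lags let the network represent thermal inertia). Two targets: indoor
   air temperature *T*ᵢ and indoor physiologically equivalent temperature
   PETᵢ. Training: Adam (learning rate 10⁻⁴), batch size 8, random
   80/10/10 train/validation/test split, early stopping on validation loss.
2. **PET from first principles.** PETᵢ is computed from sensor-like
   channels (*T*ᵢ, RH, globe temperature, air speed) via a two-node MEMI
   heat-balance model for a standardized person: *T*_mrt from the globe
   thermometer (ISO 7726 forced-convection relation), then the
   reference-environment air temperature (*T*_mrt = *T*ₐ, *v* = 0.1 m s⁻¹,
   VP = 12 hPa) that reproduces the body's core/skin state.
3. **Bias-correct the scenarios.** Projection members are adjusted against
   the historical reference by quantile delta mapping (QDM): each future
   value is mapped through matched observed/model historical quantile
   functions, preserving the model's projected change at every quantile.
   Additive transfer for temperature-like variables, multiplicative (with a
   trace threshold) for the zero-bounded *G* and *v*.
4. **Count the exposure.** On a 365-day ("noleap") calendar: exceedance
   hours/year (*T*ᵢ ≥ 26, 30, 35 °C; PETᵢ ≥ 23, 29, 35, 41 °C; a 3-h step
   counts as three hours), heat days (daily maximum ≥ threshold), mean
   consecutive heat-day runs, and stress-class frequencies stratified by
   season and working hours (09:00–18:00 UTC), aggregated across ensemble
   members as mean (min–max).

Because real sensor records and reanalysis/projection archives are
proprietary or huge, the package ships a **synthetic-data module** with
known ground truth: an outdoor weather generator (seasonal + diurnal
cycles, AR(1) noise, physically consistent couplings), scenario variants
with a configurable imposed change, and a single-node building model
*dT*ᵢ/*dt* = (*T*ₐ − *T*ᵢ)/τ + *aG* + *q*(*t*) + max(0, *k*(*T*_set − *T*ᵢ)).
Every pipeline stage is validated against brute-force or closed-form
oracles on this synthetic world.

## Worked example

```r
library(indoorheat)

# PET: reference identity, warm room, warm room with high radiant load
round(pet(T_a = c(21, 30, 30), T_mrt = c(21, 30, 55),
          VP  = c(12, 21, 21), v = c(0.1, 0.5, 0.5)), 1)
#> [1] 21.0 28.4 41.3
```

21 °C in the reference environment maps to PET = 21 °C by definition; the
humid 30 °C room is moderate heat stress (28.4); adding a 55 °C radiant
load pushes it to extreme heat stress (41.3).

```r
# end-to-end projection for one heated synthetic office, +3 K scenario
cfg <- workplace_config("office-01", type = "office",
                        building = building_parameters(T_set = 21),
                        targets = "T_i", seed = 42)
scen <- list(scenario_config("RCP8.5", member = 1,
                             offset = c(T_a = 3, T_d = 3)))
rep <- run_workplace_projection(cfg, scen)
d <- rep$members[[1]]$deltas$T_i
subset(d, metric %in% c("mean_overall", "mean_DJF", "mean_JJA"))
#>        metric  hist   fut delta
#>  mean_overall 20.85 21.26  0.41
#>      mean_DJF 20.21 20.39  0.18
#>      mean_JJA 21.89 22.63  0.75
```

Under a uniform +3 K outdoor warming this heated, thermally heavy office
warms by only +0.41 K indoors — +0.18 K in winter (the heating pins the
indoor temperature) and +0.75 K in summer. That indoor damping, strongest
in the heating season, is the central mechanism the workflow is built to
resolve; an uninsulated pass-through building instead recovers the full
+3 K (see `tests/testthat/test-acceptance.R`). The stage log records the
surrogate quality and QDM repairs:

```
[data] simulated 2920 training steps (tau=40 h)
[train] T_i: test MAE 0.268 K, best epoch 420/440
[qdm] RCP8.5 member 1: repairs T_d=55 G=0 v=0 A_G=0
```

A test MAE of 0.268 K is consistent with the 0.39–2.76 K range this
architecture reaches on real workplace records — slightly better, as the
synthetic building is cleaner than a real room.

## Command line

`inst/cli/indoorheat.R` exposes the stages as subcommands:

```sh
CLI=$(Rscript -e 'cat(system.file("cli/indoorheat.R", package="indoorheat"))')
Rscript $CLI simulate     --outdoor o.csv --indoor i.csv --seed 3
Rscript $CLI pet          --indoor i.csv --out i_pet.csv
Rscript $CLI train        --outdoor o.csv --indoor i_pet.csv --target PET_i --model m.json
Rscript $CLI bias-correct --obs obs.csv --mod-hist mh.csv --mod-fut mf.csv --out corr.csv
Rscript $CLI project      --experiment experiment.json --out-dir results/
Rscript $CLI report       --series pred.csv --variable T_i --out metrics.csv
```

File schemas: series CSVs have an ISO-8601 UTC `timestamp` column plus one
column per variable (`T_a,T_d,v,p,G,A_G` outdoors; `T_i,RH,T_g,v_i,PET_i`
indoors). Models serialize to a documented JSON (weights, scalers,
hyperparameters, metadata); the per-epoch training log is written as CSV.
The experiment JSON for `project` holds `id`, `type`, `building`,
`outdoor`, `targets`, period lengths, `hyper`, `seed` and a `scenarios`
table (`label`, `member`, `bias`, `offset`, `trend`).

## Documentation

The methods vignette (`vignettes/methods.Rmd`) describes the models, the
numerical choices, what the synthetic generator does and does not emulate,
and known limitations.
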