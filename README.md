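# hyphasim

Event-driven simulation of single fungal hypha growth as a chain of
well-mixed tanks in series.

A growing hypha is modelled as `n` cubic tanks of side `dx` attached to a
source tank that represents the vegetative mycelium. Dissolved nutrient
moves towards the tip by cytoplasmic streaming (convection at velocity `v`)
and diffusion (`D`). In at most `NV` tanks immediately behind the tip,
nutrient is converted into wall-building vesicles with Michaelis–Menten
kinetics; vesicles are actively transported tip-wards at velocity `psi`
and consumed in the tip-tank, whose wall-extension rate is a
Michaelis–Menten function of its vesicle concentration. The tip-tank grows
from `dx` to `2*dx`, then splits into two tanks and the ODE system is
re-dimensioned — so growth proceeds through a sequence of stiff ODE
integrations separated by discrete division events.

## Quick start

```r
library(hyphasim)

# calibrated preset for a reproductive aerial hypha
sc <- hypha_preset("rhizopus_oligosporus")
traj <- simulate_hypha(sc$params, init = sc$init, t_end = 24)
traj
#> Hypha trajectory: 24 h, 249 division events
#>   final: 252 tanks, total length 2528 um, extension 2498 um
#>   extension-rate audit: passed (max rate / v = 0.477)

tail(traj$series, 1)[, c("t_h", "n_tanks", "extension_um")]

# spatial concentration profile at 24 h
pr <- spatial_profile(traj, 24)
head(pr)

# where are the vesicles? (bin 1 = the tip-tank)
fr <- tip_vesicle_fractions(traj)
range(fr$fraction[fr$bin == 1])
#> [1] 0.4098... 0.5931...

# one-at-a-time sensitivity of 24 h extension to the source concentration
sensitivity_F(sc, "omega0", low = 1, high = 15)
```

Three calibrated presets ship with the package:

| preset | tanks | source | horizon |
|---|---|---|---|
| `rhizopus_oligosporus` | 10 µm | constant | 24 h |
| `aspergillus_giganteus` | 40 µm | constant | 21 h |
| `phycomyces_blakesleeanus` | 150 µm | depleting | 110 h |

Presets are plain-text config files under
`system.file("extdata", package = "hyphasim")`; `read_hypha_config()` /
`write_hypha_config()` handle user-defined scenarios in the same format.

## Command-line interface

The launcher script (installed at
`system.file("exec", "hyphasim", package = "hyphasim")`) exposes four
subcommands:

```sh
hyphasim run --scenario rhizopus_oligosporus --t-end 24 --out-dir out/
hyphasim sensitivity --parameter kp --low 10 --high 2000 --out-dir out/
hyphasim sweep --parameter omega0 --values 1,5,10,15 --out-dir out/
hyphasim profile --time 24 --out-dir out/
```

`run` writes `timeseries.csv`, `profiles.csv` and a `manifest.json`
recording the scenario, settings, division count, the extension-rate audit
and wall time. All CSV numbers are formatted at 10 significant digits, so
repeated runs with identical inputs are bitwise identical.

If the launcher is not on your `PATH`, call the same entry point from R:

```r
hyphasim_main(c("run", "--scenario", "rhizopus_oligosporus",
                "--out-dir", "out"))
```

## Units

All computation uses the dm / h / g unit system of the calibrated
parameter sets; reported lengths are converted to micrometres
(1 dm = 1e5 µm). Concentrations are g dm⁻³.

## Verification

`tests/testthat` contains unit, property and acceptance tests, including
a fixed-step Runge–Kutta verification integrator that is compared against
the adaptive production solver, exact mass/length-conservation checks at
division events, and a cross-check of the compiled C right-hand side
against a pure-R reference implementation. Run them with:

```r
testthat::test_dir("tests/testthat", package = "hyphasim",
                   load_package = "installed")
```

`scripts/acceptance.R` reproduces the headline numbers of the calibrated
scenario and writes them as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out acceptance.json
```

The methods vignette (`vignettes/tanks-in-series-model.Rmd`) documents the
model equations, the division-event scheme, the solver configuration and
the analysis definitions.
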