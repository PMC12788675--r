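# nanodosim

Track-structure nanodosimetry in R: event-by-event Monte Carlo transport of
low-energy electrons (tens of eV to keV) in liquid water, driven by
*interchangeable total interaction cross-section datasets*, with scoring of
ionization cluster size distributions (ICSDs) in nanometric spheres and a
statistics layer to quantify how much of the disagreement between
cross-section datasets propagates into nanodosimetric predictions.

## The problem

Different Monte Carlo track-structure codes, all "validated", predict
strikingly different ICSDs for the same electron energy and target —
especially below ~300 eV, where their total interaction cross sections
disagree most.  A clean way to dissect this is a *harmonization
experiment*: run every dataset as-is ("initial" phase), then substitute one
*common* dataset — the channel-wise arithmetic mean over all members —
into every run ("final" phase) while leaving everything else (differential
models, binding energies, cutoffs) untouched.  The variability that
disappears is attributable to the total cross sections; the residue to
everything else.

`nanodosim` implements that entire pipeline: dataset template I/O and
validation, averaging, transport, scoring, statistics, and the experiment
driver — plus a synthetic-data module so the machinery is fully testable
without access to any production code's proprietary tables.

## Quantities and statistics

For an ICSD with probabilities $P_\nu$ of $\nu$ ionizations in the sphere,
estimated from $N$ histories:

- moments $M_k = \sum_\nu \nu^k P_\nu$ (mean cluster size $M_1$) and
  cumulative probabilities $F_k = \sum_{\nu \ge k} P_\nu$ ($F_2$: at least
  one ionization *cluster*; $F_3$: a complex cluster);
- binomial uncertainties $u(x) = \sqrt{x(1-x)/N}$ for probabilities and
  $u(M_1) = \sqrt{(M_2 - M_1^2)/N}$ by GUM error propagation;
- across a family of datasets: mean value MV, sample standard deviation SD
  (n−1 denominator), relative standard deviation RSD = SD/MV, with
  $u(\mathrm{MV}) = \sqrt{\tfrac1{n_c}\sum_k u(x_k)^2 + \mathrm{SD}^2/(n_c-1)}$;
- between whole distributions: the discrete Wasserstein-1 (earth-mover)
  distance $W_1 = \sum_i |\delta_i|$, $\delta_{i+1} = \delta_i + x_i - y_i$,
  of each member to the per-bin mean ICSD, also reported as $W_1/M_1$ so
  energies with different numbers of occupied bins are comparable.

## Worked example

Desk-scale first: the published seven-code 20 eV mean cluster sizes
(shipped under `inst/extdata/`) fully determine each code's ICSD at that
energy (only 0 or 1 ionizations are possible, so the ICSD is
$\{1-M_1, M_1\}$):

```r
library(nanodosim)
t2 <- intercomparison_table("m1_original")
m1_20 <- t2$value[t2$energy_eV == 20]
variability_record(two_bin_icsds(m1_20), flavor = "initial")
#> <variability_record> initial: mean W1 = 0.1919, mean M1 = 0.5171, W1/M1 = 0.371
dispersion(m1_20, t2$u[t2$energy_eV == 20])
#> <dispersion> n = 7: MV = 0.5171 +/- 0.095, SD = 0.2338, RSD = 0.4521
```

These are the published 20 eV cells (mean $W_1$ = 0.19, $W_1/M_1$ = 0.37,
SD = 0.2338, RSD = 0.4521, MV = 0.52 ± 0.10).

Now the simulation side, on a synthetic 7-member family whose spread
emulates the inter-code situation (factor-~2 disagreement at 20 eV,
percent-level at 10 keV):

```r
base <- base_dataset()
fam  <- perturbed_family(base, 7, spread_profile(seed = 1))
rep  <- harmonization_experiment(fam, energies = c(20, 100),
                                 n_histories = 2000, master_seed = 1)
rep
#> <harmonization_report> 7 members x 2 energies, 2000 histories/run
#>      20 eV: RSD(M1) initial 0.2733 -> final 0.0180; mean W1 0.09971 -> 0.005367
#>     100 eV: RSD(M1) initial 0.1150 -> final 0.0111; mean W1 0.3395 -> 0.03794
```

Substituting the common dataset removes ~93% of the RSD of $M_1$ at 20 eV
in this synthetic world — the same qualitative collapse reported for the
real codes (0.45 → 0.01).  The residual final-phase spread here is purely
statistical, because the synthetic members share one set of differential
models; real codes retain code-specific differential behaviour, which is
why their residual variability grows with energy.

## Command line

```sh
Rscript inst/cli/nanodosim-cli.R synth      --out fam/ --members 7 --seed 1
Rscript inst/cli/nanodosim-cli.R average    --family-dir fam/ --out common.tsv
Rscript inst/cli/nanodosim-cli.R simulate   --xsec common.tsv --energy 20 \
        --histories 100000 --diameter 8 --seed 5 --out icsd_20.tsv
Rscript inst/cli/nanodosim-cli.R experiment --config config.json --out report/
```

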