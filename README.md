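# neurofitr

Fitting the parameters of neuronal models to electrophysiological traces.

## The problem

Conductance-based and reduced neuron models have parameters (channel
densities, synaptic kinetics, adaptation constants) that are rarely measured
directly; they must be inferred by making the model's simulated response
match a recorded one. `neurofitr` is a modular tool for that task, aimed at
electrophysiologists and modellers: it compares simulated and target trace
sets through a library of normalized cost functions, and minimizes the
weighted combination with bound-constrained global and local optimizers.

Given a target trace set \(x\) and a candidate parameter vector
\(\theta\), the backend simulates \(s(\theta)\) and the objective is

\[ F(\theta) \;=\; \sum_f w_f \sum_{\text{trace pairs}} C_f\big(s(\theta), x\big), \qquad \sum_f w_f = 1, \]

where each cost function \(C_f\) is normalized toward \([0,1]\): the
point-by-point mean squared error divided by the squared target range, its
sub-threshold variant that excludes windows around detected spikes, the
squared difference of temporal derivatives, spike-count error
\(|n_s-n_x|/(n_s+n_x+1)\), spike count during the stimulus, inter-spike
interval differences, latency to first spike, action-potential overshoot,
half-amplitude spike width, after-hyperpolarization depth, and a
phase-plane trajectory-density distance. Optimization runs on parameters
normalized to \([0,1]^d\) (bounds are mandatory) with a choice of an
evolutionary algorithm with generational replacement and weak elitism
(blend crossover + annealed Gaussian mutation), simulated annealing,
Nelder–Mead, and L-BFGS-B.

Built-in backends: a single-compartment Hodgkin–Huxley neuron under current
clamp (NEURON-compatible staggered implicit integration), a
double-exponential conductance synapse under ideal voltage clamp, and the
adaptive exponential integrate-and-fire model; any external simulator can
be attached as a file-based black box. Surrogate-data generators with known
ground truth make the whole pipeline testable without recordings.

## Worked example: recovering synaptic parameters

A voltage-clamped compartment receives four synaptic inputs 100 ms apart
through a double-exponential conductance synapse (rise 0.3 ms, decay 3 ms,
peak 10 nS, delay 2 ms). We generate that target, then ask the evolutionary
algorithm to recover the four synaptic parameters from the clamp current:

```r
library(neurofitr)

sur <- make_surrogate("uc2_synapse_vc")   # target + ready-to-run config
fit <- neurofit(sur$target,
                get_backend("synaptic_vc", sur$config$backend$fixed),
                sur$config$parameters, sur$config$protocol, sur$config$cost,
                optimizer = list(algorithm = "EO", seed = 1,
                                 pop_size = 100, generations = 100))
print(fit)
#> Neuronal model fit (synaptic_vc backend, EO optimizer)
#>   1 traces, 10100 evaluations, seed 1
#>   best fitness: 3.82152e-12
#>   best parameters:
#>       tau1       tau2     weight      delay
#> 0.30002200 3.00000000 0.00999984 1.99999000

signif(coef(fit) / sur$true_params - 1, 2)   # relative recovery error
#>     tau1     tau2   weight    delay
#>  7.4e-05  3.7e-07 -1.6e-05 -7.3e-06
```

The best fitness is the normalized mean squared error of the clamp current
(dimensionless); every recovered parameter is within 0.01 % of the
generating value. `plot(fit)` overlays target and best trace,
`plot(fit, "generations")` shows the cost across generations, and
`summary(fit)` adds the per-feature error breakdown and final-population
statistics.

The same run can be driven entirely from an XML configuration:

```r
dir <- tempdir()
sur <- make_surrogate(surrogate_case("uc2_synapse_vc"), dir = dir)
fit <- run_session(file.path(dir, "config_uc2_synapse_vc.xml"), seed = 1)
```

which also writes the result artifacts (best-trace text file, PNG figure,
HTML report, reproducing config, `key = value` summary) into the configured
output directory. A thin command-line front end ships in
`inst/scripts/fit.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("scripts/fit.R", package="neurofitr"))')" \
  -c config.xml --seed 1 --out results/
```

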