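# ergnet

Topology inference and noise analysis for the ERα–GATA3 gene regulatory
network.

ERα (estrogen receptor alpha) and GATA3 jointly control luminal cell fate
in the mammary gland, and ERα status defines the major clinical subtypes of
breast cancer. The two factors regulate each other and possibly themselves,
but slow siRNA perturbations cannot separate autoregulation from
cross-regulation. `ergnet` implements the modeling strategy that can: fit a
small mechanistic ODE model to *depletion* and *cycloheximide-recovery*
protein time courses under every candidate sign topology, rank topologies
by fit error, and interrogate the surviving candidates with
logarithmic-gain, link-elimination, dose–response and stochastic-noise
analyses. A calibrated synthetic-data generator emulates the measurements,
so the entire pipeline is exercised and tested without external data.

## The model

Normalized protein levels $e$ (ERα) and $g$ (GATA3) follow

$$\frac{de}{dt} = s_e b_e F_1(e) F_2(g) - k_e e,
\qquad
\frac{dg}{dt} = s_g b_g F_3(e) F_4(g) - k_g g,
\qquad
F_j(x) = \frac{1 + f_j (x/K_j)^{n_j}}{1 + (x/K_j)^{n_j}},$$

with multiplicative Hill regulation and first-order turnover. Each link's
fold change $f_j$ encodes its sign ($f_j>1$ activation, $f_j<1$ repression,
$f_j=1$ absent), so the network has $3^4 = 81$ sign topologies, reduced to
$3^2 = 9$ once the cross-links are fixed by knockdown endpoints. Basal
rates are eliminated by wild-type normalization (the unperturbed steady
state is exactly $(1,1)$). Perturbations: siRNA scales a synthesis rate by
$1-\text{efficiency}$; cycloheximide zeroes both synthesis rates inside its
window; the ER degrader ICI 182,780 reduces *active* ERα and adds an ERα
loss term. Intrinsic noise is computed by the Linear Noise Approximation
(Lyapunov equation at the stable fixed point, CV $=\sigma/\mu$), validated
against exact Gillespie simulation; extrinsic noise by lognormal parameter
ensembles.

## Worked example

Generate synthetic perturbation data from the inferred network and refit
all nine autoregulation topologies:

```r
library(ergnet)

data <- generate_timecourses(generator_config(seed = 42))
rk <- rank_topologies(data, n_starts = 40, seed = 42)
rk
#> Topology ranking (9 candidates, tolerance 2x best):
#>   er_auto gata3_to_er er_to_gata3 gata3_auto label best_error rel_error pass
#> 1 0       +           -           +          0+-+        10.9      1    TRUE
#> 2 +       +           -           +          ++-+        11.0      1.01 TRUE
#> 3 -       +           -           +          -+-+        11.1      1.01 TRUE
#> 4 0       +           -           0          0+-0       138.      12.7  FALSE
#> ...
```

Only the three topologies with positive GATA3 autoregulation (`label`
ending in `+`) capture the data — their errors sit ~13× below the rest —
while the sign of ERα autoregulation is not decided by the time courses
(the top three errors are within 1%). The labels spell the four link signs
in order: ERα auto, GATA3→ERα, ERα→GATA3, GATA3 auto.

The ICI dose–response settles the remaining question. Under the
no-autoregulation hypothesis the steady-state ERα mRNA proxy *rises* with
dose (GATA3 derepression), under positive autoregulation it *falls*:

```r
ici_dose_response(default_ground_truth("0")$params)
#>    rank dose_nM branch proxy label
#> 1     1     0        1  1    increasing
#> 2     1     0.1      1  1.23 increasing
#> 3     1     1        1  1.29 increasing
#> ...
```

Finally, the noise analysis shows what the negative feedback buys. At
system size ω = 500, breaking the ERα→GATA3 repression (means held fixed by
a controlled comparison) raises ERα noise by ~35%:

```r
sys <- stochastic_system(default_ground_truth()$params, omega = 500)
lna_noise(sys)
#> Noise summary (lna): mean e = 1, g = 1; CV e = 0.03649, g = 0.05059
lna_noise(remove_link_controlled(sys, "er_to_gata3"))
#> Noise summary (lna): mean e = 1, g = 1; CV e = 0.04927, g = 0.04847
```

`run_pipeline(pipeline_config(...))` chains all stages (generation, sign
fixing, 9-topology fit, gain/elimination, dose–response, selection, noise)
with recorded seeds and writes CSV/JSON reports; `autoplot()` methods and
`plot_dose_response()` / `plot_noise()` draw the standard diagnostics, and
`tidy()` / `glance()` turn fitted objects into tibbles.

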