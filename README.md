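# rescuedip

Survival probabilities for populations facing an abrupt environmental
change — and the counterintuitive *dip*: intermediate-sized populations can
be at **greater** risk of extinction than smaller ones.

## The problem

After a sudden environmental change (a new pathogen, an antibiotic, a step
change in climate), a haploid population of size $N$ declines at rate
$\delta$ per generation unless a *survival allele* — beneficial after the
change ($s_b > \delta$), mildly deleterious before it (cost $s_d$) — rescues
it, either from standing variation or by de novo mutation (symmetric rate
$\mu$). Each allele copy founds a surviving lineage with the
branching-process establishment probability $\pi(s_r)$,
$s_r = s_b - \delta$, the larger root of $\pi = 1 - e^{-(1+s)\pi}$. The
initial allele frequency follows Wright's stationary distribution
$\phi(p) \propto e^{-2Ns_d p}(p(1-p))^{2N\mu-1}$, and the marginal survival
probability has the closed form

$$P_{\mathrm{survival}} = 1 - e^{-N\pi(s_r)\mu/\delta}\,
\frac{{}_1F_1\!\big(2N\mu,\,4N\mu,\,-2N\tilde s\big)}
     {{}_1F_1\!\big(2N\mu,\,4N\mu,\,-2Ns_d\big)},
\qquad \tilde s = s_d + (1 - \mu/\delta)\,\pi(s_r)/2 .$$

Because drift keeps a mildly deleterious allele common in populations below
$N_{\mathrm{neut}} = 1/s_d$ while mutation supply only guarantees rescue near
$N_{\mathrm{mut}} = 1/\mu$, $P_{\mathrm{survival}}$ is **non-monotone** in
$N$ whenever $N_{\mathrm{neut}} \ll N_{\mathrm{mut}}$: there is a local
minimum at an intermediate, most-vulnerable population size. The package is
for population geneticists, conservation modellers and AMR researchers who
want these quantities — closed forms, quadrature oracles, decomposition into
standing/de-novo routes, the vulnerable-size finder, and the stochastic
simulators that validate them.

## Worked example

```r
library(rescuedip)
params <- model_params()   # s_b = 0.05, delta = 0.01, s_d = 0.001, mu = 1e-5
survival_table(c(100, 1000, 3000, 1e4, 1e5), params)
```

```
      N p_survival p_stand p_de_novo p_total   p_mean p_at_least_one_copy
1 1e+02     0.4568  0.4526  0.007564  0.4568 0.450364              0.4552
2 1e+03     0.2489  0.1897  0.073113  0.2490 0.129439              0.2216
3 3e+03     0.3698  0.2086  0.203694  0.3698 0.014996              0.2993
4 1e+04     0.7768  0.5232  0.531978  0.7769 0.010448              0.6885
5 1e+05     1.0000  0.9993  0.999496  1.0000 0.009949              1.0000
```

Survival *falls* from 46% at $N=100$ to 25% at $N=1000$ before recovering:
the mean stationary frequency (`p_mean`) collapses from 0.45 to 0.01 as
selection starts to see the cost, while the de novo route (`p_de_novo`) is
still weak. The most vulnerable size and the Monte Carlo cross-check:

```r
find_vulnerable_N(params, 10, 1e6)
#> Vulnerable population size: N* = 1240.5 (survival = 0.242185) in [10, 1e+06]

estimate_survival(1000, params, sim_config(seed = 42, replicates = 1000))
#> Survival estimate at N = 1000: 0.2570 (SE 0.0138; 257/1000 survived, 0 censored)
```

The simulated fraction (0.257 ± 0.014) brackets the closed form (0.2489).
A command-line wrapper is installed as `exec/rescuedip`
(`rescuedip simulate --N 1000 --reps 1000 --seed 1 --out out.csv`, plus
`wright`, `curve`, `components`, `minimum`, `ricker` subcommands); see
`?rescuedip_cli`. The methods vignette (`vignettes/rescue-dip.Rmd`) documents
the model, the numerics and the simulators' scope.

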