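# allocbias

Quantifies the impact of third-order allocation bias on test decisions in
randomized two-arm parallel-group clinical trials with multiple continuous
endpoints, as a function of the randomization procedure (RP). It is aimed at
trial statisticians choosing an RP at the design stage — particularly for
small trials (e.g. in rare diseases) where multiple primary or co-primary
endpoints are attractive and allocation bias bites hardest.

## The model

In an unmasked but allocation-concealed trial, an investigator applying the
*convergence strategy* guesses that the next patient goes to the currently
under-represented arm and enrols accordingly: a better responder (response
shift `+eta_k` on endpoint `k`) when the control arm leads, a worse one
(`-eta_k`) when the experimental arm leads, neutral at balance. Patient `j`'s
response is

    X_j = mu_E t_j + mu_C (1 - t_j) + tau_j + eps_j,   eps_j ~ N_m(0, Sigma)

with `tau_{j,k} ∈ {-eta_k, 0, +eta_k}` determined by the imbalance
`D_{j-1} = N_E(j-1) - N_C(j-1)` of the allocation sequence. Under the
component null, the pooled two-sample t statistic for endpoint `k` is then
*doubly non-central t* distributed with `N - 2` degrees of freedom and
parameters

    delta_k  = sqrt(n_E n_C / N) (tau_bar_Ek - tau_bar_Ck) / sigma_k
    lambda_k = [ sum_E (tau_jk - tau_bar_Ek)^2 + sum_C (tau_jk - tau_bar_Ck)^2 ] / sigma_k^2

which yields, per randomization list, a closed-form

* **family-wise error rate of the Šidák procedure** (multiple primary
  endpoints, two-sided tests at level `1 - (1-alpha)^(1/m)`), with a
  principal-component transform handling correlated endpoints, and a
* **type I error rate of the all-or-none / intersection-union procedure**
  (co-primary endpoints, one-sided tests at `alpha`), computed at the least
  favourable configuration of the union null.

A Monte-Carlo driver scores `r` lists per candidate RP (seven are
implemented: CR, EBC(p), BSD(b), CHEN(p,b), MP(b), RAR, PBR(k), each with
its exact sampling distribution) and reports the mean rate and
`P_RP(rate <= alpha)`, the probability that a drawn list keeps the nominal
level. A brute-force simulation oracle (`empirical_rate()`) validates the
closed forms by actually running the t-tests on simulated responses.

## Worked example

Impact of a bias effect of 10% of the anticipated effect size
(`eta = 0.1 * 1.024`) on the Šidák FWER in a trial with `N = 32` patients and
`m = 2` independent standard-normal endpoints, over 100 000 randomization
lists per RP:

```r
library(allocbias)
design <- trial_design(N = 32, m = 2, alpha = 0.05)
policy <- effect_size_eta(0.1, 1.024, m = 2)
rps <- list(rp_spec("CR"), rp_spec("BSD", b = 3), rp_spec("MP", b = 3),
            rp_spec("PBR", block_size = 4), rp_spec("RAR"),
            rp_spec("EBC", p = 0.67), rp_spec("CHEN", p = 0.67, b = 2))
assess_allocation_bias(design, policy, rps, "sidak", r = 100000, seed = 20240930)
#> Allocation-bias assessment: FWER (Sidak), N = 32, m = 2, alpha = 0.05
#>   eta: 0.1024, 0.1024 | r = 100000 lists per RP | seed = 20240930
#>            rp mean_rate p_controlled n_degenerate      r
#>            CR    0.0502       0.5501            0 100000
#>        BSD(3)    0.0506       0.3392            0 100000
#>         MP(3)    0.0527       0.0365            0 100000
#>        PBR(4)    0.0572       0.0000            0 100000
#>           RAR    0.0513       0.1878            0 100000
#>     EBC(0.67)    0.0526       0.1155            0 100000
#>  CHEN(2,0.67)    0.0541       0.0050            0 100000
```

Reading: under this bias magnitude the mean FWER is inflated above the
nominal 5% for every RP, least for complete randomization (5.02%, and 55% of
its lists still control the level) and most for permuted blocks of four
(5.72%, with essentially no list controlling the level) — the price of PBR's
frequent returns to balance, which make its assignments predictable. The
all-or-none procedure (`procedure = "all_or_none"`) is markedly more
sensitive. `plot()` on the returned object draws per-RP boxplots of the
per-list rates; `summary()` adds quartiles.

Study settings can also be read from YAML (see
`system.file("extdata", package = "allocbias")` for the shipped
configurations) and run with `run_study_config()`, or from the shell via the
thin CLI at `inst/cli/allocbias` (`allocbias run --config cfg.yaml --out
results.csv`; `allocbias lists --rp BSD --b 3 --N 32 --r 100 --seed 1 --out
lists.csv`).

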