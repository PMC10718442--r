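# crashdecluster

Secondary crashes — collisions that happen in the congestion wake of an
earlier ("primary") crash — are among the most dangerous highway incidents,
because they strike queued traffic, crash victims and first responders.
Crash databases record *when* and *where* collisions occurred but not
*whether* one collision caused another. `crashdecluster` answers that
question statistically: it fits a temporal self-exciting (Hawkes) point
process to a crash catalog and declusters it into background (primary) and
triggered (secondary) events, for traffic-safety analysts working with
state-DOT crash exports and for anyone studying clustered event sequences
on a time axis.

## The model

Crash times t₁ < t₂ < … < t_N on a window [0, T] are modeled with the
conditional intensity

    λ(t) = μ(t) + A Σ_{tᵢ < t} α e^{−α (t − tᵢ)}

where μ(t) is the background (primary) rate in events/day, A is the
branching ratio (expected directly triggered offspring per event) and α is
the decay rate of the excitation. The background can be

* **stationary** — constant μ;
* **piecewise** — a step function over calendar bins (one rate per day of
  the week, or morning-rush / non-rush / evening-rush periods);
* **sinusoidal** — μ₀ {P·wave(Q·x + R) + S} with x the position within the
  week or the day, capturing smooth weekly/daily periodicity.

Parameters are estimated by exact maximum likelihood

    ℓ = Σᵢ log λ(tᵢ) − ∫₀ᵀ μ(t) dt − A Σᵢ (1 − e^{−α (T − tᵢ)})

with a quasi-Newton search, analytic gradients and an O(N) recursion for
the event sum. Families are ranked by AIC = 2k − 2ℓ. Declustering assigns
each pair the triggering probability p_ij = A α e^{−α(t_j−t_i)} / λ(t_j);
p_j = Σ_i p_ij is the probability that event j is secondary, and
1 − p_j = μ(t_j)/λ(t_j) that it is primary. The fitted decay rate yields
the **queue time** 1440/α in minutes — the window after a primary crash
within which triggered crashes are expected — and the post-processing rule
labels event j secondary when its gap to the preceding event is below the
queue time and p_j reaches a probability threshold (default 0.5). Two exact
simulators (Ogata thinning and the cluster/branching construction) provide
ground-truth catalogs for validation.

## Worked example

Simulate three years of crashes from a known model, refit, and decluster:

```r
library(crashdecluster)

model <- hawkes_model(stationary_background(0.4),   # 0.4 primaries/day
                      triggering_params(0.25, 12))  # A = 0.25, alpha = 12/day
syn  <- simulate_branching(model, T = 1095, seed = 2015)
cat_ <- syn$catalog

fit <- fit_mle(cat_, family = "stationary")
print(fit)
#> <fit_result: stationary> N = 529, T = 1095.0 days
#> <hawkes_model>
#>   <background: stationary> mu = 0.3659 /day
#>   trigger: A = 0.2427, alpha = 12.33 /day (queue time 116.8 min)
#>   loglik = -789.856, k = 3, AIC = 1585.71, converged = TRUE (|grad| = 1.1e-06, 36 evals)

dec <- triggering_probabilities(fit$model, cat_)
cls <- classify_secondary(cat_, dec,
                          classification_config(queue_time(fit), 0.5))
print(cls)
#> <classification> 99 of 529 events secondary (18.71%), mean p_j = 0.86
```

The fit recovers the generating parameters (μ̂ = 0.366 vs 0.4, Â = 0.243 vs
0.25, α̂ = 12.3 vs 12); the queue time 1440/α̂ = 116.8 minutes says triggered
crashes are expected within roughly two hours of their parent, and 18.7% of
the events are labeled secondary. Because the simulator records true parent
links, the labels can be scored: `match_against_reference(cls$secondary,
syn$parent != -1)` reports the fraction of true secondaries flagged.

Real catalogs enter through `load_catalog("crashes.csv")` (FDOT-style CSV
with date/time and coordinate columns), can be restricted to a 2-mile
corridor window with `filter_corridor()` or scanned along a highway with
`sliding_windows()`, and compared across background families with
`compare_models()`. The same workflow is scriptable from a shell via
`inst/scripts/crashdecluster` (`fit`, `decluster`, `classify`, `simulate`,
`compare` subcommands).

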