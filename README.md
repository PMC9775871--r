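# bilexnet

Tools for characterising a bilingual (or bidialectal) mental lexicon from
two complementary kinds of behavioural data:

* **Semantic-fluency responses** → word-correlation lexical networks.
  Participants name members of a category (animals, colours) in each of
  their two languages; bilexnet builds the participants × words incidence
  matrix, correlates word-production profiles (phi coefficients on binary
  data), and analyses the resulting weighted graph: clustering coefficient
  (CC), average shortest path length (ASPL), the small-world index
  *S* = (CC/CC<sub>ran</sub>)/(ASPL/ASPL<sub>ran</sub>) against matched
  Erdős–Rényi ensembles, modularity *Q* with Louvain (or exhaustive)
  community detection, and spanning-tree backbones.
* **Long-term repetition-priming reaction times** → mixed-effects priming
  analysis.  Subjects study words in one language and are tested in the
  other; bilexnet applies the standard filter chain (exclude subjects below
  80% accuracy, keep correct trials, trim ±2.5 SD outliers, natural-log
  transform), summarises the priming effect (mean RT unlearned − learned,
  in ms), and fits `log RT ~ stimulus type` per language condition with
  by-subject and by-item random effects, selecting the random structure by
  backward stepwise likelihood-ratio tests from the maximal model
  (lme4/lmerTest, Satterthwaite df).

Raw data from such studies are rarely deposited, so the package also ships
seeded synthetic generators — a planted-cluster Bernoulli model for fluency
matrices and a lognormal crossed random-effects model for trial tables —
that reproduce the statistical structure the analyses assume.  Every
pipeline stage is therefore testable end to end, including brute-force
oracle checks of all graph statistics and simulation-based calibration of
the mixed model.  See `vignettes/bilexnet-methods.Rmd` for the models,
parameter defaults, and design decisions.

## Worked example

```r
library(bilexnet)

# --- fluency arm -------------------------------------------------------
d <- simulate_fluency(fluency_sim_spec(n_participants = 32, seed = 5))
d
#> <fluency_dataset> 32 participants x 45 words (D1 / animal)
#>   words produced per participant: median 26, range 22-32

net <- build_network(word_correlations(d))            # phi-weighted graph
ens <- null_ensemble(n = 45, p = 0.5, reps = 1000, seed = 5)
network_metrics(net, null = ens)
#>    n cc aspl     q n_communities ccran asplran    s    cc_mode aspl_mode
#> 1 45  1    1 0.684             5 0.499     1.5 3.01 unweighted      hops

compare_to_null(1.0, ens, "cc")    # z = 29.2: far outside the ER(0.5) null
detect_communities(net, seed = 2)
#> <community_partition> 5 communities over 45 nodes, Q = 0.6842 (louvain)
```

The default simulated lexicon plants five semantic clusters; the detected
partition recovers that block structure (Q ≈ 0.68 on the positive-weight
graph), and the correlation network is far denser and more clustered than a
size-matched random graph — the same qualitative signature (high CC, short
paths, S > 1, substantial Q) reported for real fluency lexicons.

```r
# --- priming arm -------------------------------------------------------
trials <- simulate_rt(rt_sim_spec(n_subjects = 32, n_items_per_cell = 20,
                                  priming_beta = -0.12, seed = 2))
fit <- trials |>
  filter_participants(threshold = 0.80) |>
  preprocess_rt(k = 2.5, scope = "cell") |>
  fit_priming_model(condition = "D1-D2")
tidy(fit)
#> # A tibble: 2 x 7
#>   condition term                  estimate     se    df      t        p
#> 1 D1-D2     (Intercept)              6.03  0.0459  52.0 131.   2.81e-67
#> 2 D1-D2     stimulus_type_learned   -0.104 0.0365  37.8  -2.83 7.33e- 3
fit$structure
#> [1] "(1 | subject) + (1 | item)"
```

The stimulus-type coefficient is the learned-item shift on the log-ms
scale: the generating value was −0.12, this draw recovers −0.104
(SE 0.037), i.e. learned items are ~10% faster — a significant
cross-language priming effect, 48.3 ms in `fit$means$priming_effect`.
The backward selection correctly pruned the random slopes (the generator
has none) down to by-subject and by-item intercepts; `fit$selection`
records each step.

Both arms are also available as one-call pipelines writing GraphML / TSV /
JSON reports (`run_fluency_pipeline()`, `run_priming_pipeline()`), and as
shell verbs via `Rscript inst/cli/bilexnet.R <verb> ...`.

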