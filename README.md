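# semgkit

Feature extraction and classification strategies for multichannel surface
electromyography (sEMG) gesture recognition — the signals recorded over
forearm muscles that drive finger-movement decoding in neural prosthetics.
The reference recording geometry is 15 finger-movement classes, 24 trials
per class, 8 channels sampled at 4 kHz.

The package implements four independent routes from a raw trial (an
`n_samples x n_channels` matrix with a class label) to a movement label:

1. **Dynamic causality graphs + graph entropy.** Per time interval, every
   channel pair is Granger-tested (`F = ((SSR_r - SSR_u)/L)/(SSR_u/(n-2L-1))`,
   lag by BIC, alpha = 0.05) and the edge weight is the spurious correlation
   coefficient: `R = 1` if no causality, else `1 - |PCC|`. Features are the
   vertex entropies `e(v_i) = -sum_j R_ij ln R_ij` and their graph sums.
2. **Manifold reduction + belief-network/ELM hybrid.** Trial summary vectors
   are reduced by local tangent space alignment (LTSA) or local linear
   coordination (LLC, a mixture of probabilistic PCA models aligned through
   LLE weights), then classified by a stack of CD-1-trained restricted
   Boltzmann machines with an extreme-learning-machine output layer
   (`beta = H^+ T`), optionally fine-tuned by backpropagation, with particle
   swarm search over topologies.
3. **EWT + differential entropy + high-order fuzzy cognitive maps.** Each
   channel is decomposed by a Meyer-type empirical wavelet bank over detected
   spectral segments; windowed differential entropy per band
   (`h = 0.5 ln(2 pi e sigma^2)`) feeds an order-`h` fuzzy cognitive map
   `S_i(t+1) = tanh(sum_l sum_j W_ij^l S_j(t-l+1) + b_i)` whose fitted
   weights become features.
4. **LMD + fuzzy C-means + hybrid-kernel LS-SVM.** Local mean decomposition
   splits each channel into envelope x FM product functions; energy,
   envelope and instantaneous-frequency summaries (optionally re-encoded by
   fuzzy C-means memberships) are classified by a least-squares SVM with the
   convex kernel `K = a K_rbf + (1 - a) K_poly`, its parameters
   `(a, sigma^2, gamma, O)` tuned by particle swarm.

A synthetic generator (`generate_semg()`) emulates the recording geometry
with controllable class-dependent channel masks, directed lag-1 coupling
(true Granger structure), and 2–5 Hz amplitude envelopes, so every stage is
testable without any data download. A benchmarking harness
(`run_benchmark()`) reports cross-validated sensitivity, specificity,
accuracy and macro detection rate per (method, classifier) pair.

## Worked example

```r
library(semgkit)

# a reduced synthetic set: 5 classes x 12 trials, 8 channels at 1 kHz
cfg <- synth_config(n_classes = 5, trials_per_class = 12, fs = 1000, seed = 42)
ts <- generate_semg(cfg)
print(ts)
#> <semg_trialset> 60 trials, 5 classes, 8 channels @ 1000 Hz

# a single causality test: y is driven by lag-1 x with coefficient 0.9
p <- generate_pair_causal(500, beta = 0.9, seed = 1)
g <- granger_causal(p$x, p$y, max_lag = 4)
cat(sprintf("C = %d, p = %.3g, lag = %d\n", g$C, g$prob, g$lag))
#> C = 1, p = 1.07e-54, lag = 1

# strategy 1 end to end: dynamic graph entropy features + SVM, 5-fold CV
fm <- graph_entropy_features(ts, max_lag = 4)
print(fm)
#> <feature_matrix> 60 trials x 36 features, 5 classes
round(crossval(fm, "svm", folds = 5, seed = 1), 2)
#>     sen   spe   acc   gdr sen_sd spe_sd acc_sd gdr_sd
#> 1 94.67 98.67 94.67 94.67   5.06   1.26   5.06   5.06
```

The columns are percentages over held-out folds: macro one-vs-rest
sensitivity and specificity, overall accuracy, and the macro detection rate
(per-class recall). Here the causality-graph features alone recover the
5-class movement labels at ~95% accuracy against a 20% chance rate, because
the generator plants class-specific directed coupling that the Granger
stage is designed to detect.

`run_benchmark(ts, methods = c("strategy1", "strategy4"))` produces the
full table layout (feature variant x classifier), and the `semgkit` script
under `exec/` exposes `synth`, `features` and `bench` subcommands for shell
use.

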