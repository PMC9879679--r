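# saetm — stacked-autoencoder topographic maps for emotional EEG

Conventional quantitative-EEG brain mapping draws one scalp map per
feature: an alpha-power map, an entropy map, and so on — ten maps for a
ten-feature analysis. `saetm` compresses, per channel, ten linear and
nonlinear features of every 2-s analysis window into a **single abstracted
scalar**, supervised by emotion labels, so that one topographic map
summarizes all of them. It is aimed at researchers studying valence/arousal
emotion correlates in multichannel EEG who want one interpretable map per
trial or condition instead of a panel.

## Method in brief

For a 32-channel recording (10–20 montage, resampled to 128 Hz, band-passed
0.05–47 Hz) each 2-s window with 50% overlap yields, per channel, the
feature vector

> *P*<sub>θ</sub>, *P*<sub>α</sub>, *P*<sub>β</sub>, *P*<sub>γ</sub>
> (mean Welch PSD over 4–8, 8–12, 12–30, 30–45 Hz), μ, σ, ZCR,
> Higuchi *D*, ApEn(*m* = 2, *r* = 0.2σ), correlation dimension
> (embedding 5),

min–max normalized against the 5-s pre-stimulus baseline. One stacked
autoencoder per channel (tied weights, *h* = σ(*xW* + *b*),
*x*′ = σ(*hW*ᵀ + *c*); three hidden layers) compresses the ten features;
each hidden width is chosen by the structural loss

> SLF = ω₁ (1 − ρ₁)² + (1 − ω₁)(1 − ρ₂)², ω₁ = 0.5,

with ρ₁/ρ₂ the Pearson/Spearman correlations between input and
reconstruction — the smallest width statistically tied with the minimum
wins. A one-neuron head per channel (*Uᵢ* = σ(μ·*h* + ∂)) and a two-neuron
output (*y* = σ(β*U* + α), one-hot low/high) are fine-tuned by
backpropagation through all parameters, one binary model per emotion
dimension. The 32 per-channel head means are interpolated
(piecewise-linear over the Delaunay triangulation of the electrode
positions) into a scalp map, and a small CNN (two 3×3 conv/max-pool
blocks, RMSprop, 10 epochs) quantifies how distinguishable the map classes
are.

Because the study corpus this design targets (DEAP) is licensed, the
package ships a synthetic generator producing DEAP-shaped corpora with
planted, class-dependent effects: left-frontal alpha scaling for high
valence (hemispheric valence hypothesis) and posterior beta/gamma scaling
for high arousal.

## Worked example

```r
library(saetm)

## a small planted-effect corpus: 1 participant, 8 trials
spec <- synth_spec(n_participants = 1,
                   trials_per_quadrant = c(HAHV = 2, LAHV = 2,
                                           HALV = 2, LALV = 2),
                   valence_effect = 3, arousal_effect = 3, seed = 7)
corpus <- generate_dataset(spec)
tensors <- lapply(corpus, function(it)
  extract_feature_tensor(preprocess(it$recording), label = it$label))

tensors[[1]]
#> feature tensor: 59 windows x 32 channels x 10 features
#>   label: HAHV (valence high, arousal high)

## pretrain + fine-tune a valence model (small config for the example)
cfg <- saetm_config(epochs = 20, seed = 1, max_rows = 500)
model <- train_saetm(tensors, "valence", cfg, finetune_epochs = 10)

vals <- channel_map_values(model, tensors[[1]])
round(vals[c("F3", "F4", "Oz")], 3)
#>    F3    F4    Oz
#> 0.557 0.503 0.397

render_png(interpolate_topo(vals), "map.png")
```

The three numbers are the abstracted map scalars (baseline-referenced, so
0.5 means "no change from rest"): on this high-valence trial the
left-frontal channel F3 sits above its right homolog F4 — the planted
frontal alpha asymmetry surviving compression — and `map.png` shows that
contrast over the head outline (dark red = highest, dark blue = lowest).

A command-line wrapper for the same steps lives at `inst/cli/saetm.R`
(subcommands `synth`, `features`, `train`, `mapvals`, `topomap`,
`evaluate`).

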