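# mirtroncnn

Nucleotide-level convolutional neural networks for classifying human
pre-miRNA hairpins as **canonical miRNAs** (Drosha/DGCR8-processed) or
**mirtrons** (released by intron splicing, bypassing Drosha) — directly from
the raw sequence, with no hand-crafted features and no secondary-structure
prediction.

## Who this is for

Small-RNA researchers and tool builders who have labeled hairpin sequences
(e.g. miRBase-derived FASTA plus a mirtron/canonical annotation) and want a
feature-free baseline classifier, plus everything around it: encoding,
stratified splitting, training with early stopping, confusion-matrix metrics,
and a seeded synthetic benchmark that exercises the whole pipeline offline.

## The model

Each sequence is one-hot encoded base-by-base with the fixed map
A→(1,0,0,0), T/U→(0,1,0,0), G→(0,0,1,0), C→(0,0,0,1), N→(0,0,0,0), and
zero-padded at the end to a common length *L* (164 nt for the curated human
corpus), giving an *L* × 4 matrix per record. A single convolution layer
(filter height *h* ∈ {3,…,6}, width 4, stride 1, valid padding, relu)
produces feature maps of length *L − h + 1*; **global max-pooling** keeps one
value per filter; pooled features feed a 128-unit relu dense layer with
dropout and a 2-class softmax. Training minimizes the mean cross-entropy
−Σᵢ yᵢ log sᵢ by back-propagation (Adam), with early stopping on a held-out
loss.

Five architecture variants: `filter3` … `filter6` (one filter height, 128
filters) and `concat` (heights 3–6 at 32 filters each, pooled features
concatenated to the same 128-long vector; 19,202 trainable parameters).

Evaluation reports sensitivity, specificity, F1, MCC and accuracy with
**mirtron as the positive class**.

## Worked example

Everything runs offline: the built-in generator emulates the pre-miRNA input
(two classes, 40–164 nt, RNA alphabet) with a planted 6-mer as the
class-discriminating signal.

```r
library(mirtroncnn)

hairpins <- generate_dataset(150, 150, signal_model(plant_probability = 1),
                             seed = 42)
sp <- stratified_split(hairpins, test_fraction = 0.30, seed = 42)
sp
#> Stratified split (test_fraction = 0.3 , seed = 42 )
#> train: 210 records; test: 90 records

spec <- build_concat_spec(input_length = dataset_max_length(hairpins))
fit <- train_cnn(spec, sp$train, config = training_config(seed = 42))
fit
#> Trained CNN-concat-filters - 800 steps on 178 records
#> best held-out loss 0.09443 at step 300 (early stop)

evaluate_model(fit, sp$test)
#> # A tibble: 1 × 5
#>   sensitivity specificity    f1   mcc accuracy
#>         <dbl>       <dbl> <dbl> <dbl>    <dbl>
#> 1           1       0.933 0.968 0.935    0.967

predict(fit, sp$test[1:3, ], type = "class")
#> # A tibble: 3 × 4
#>   id               p_canonical p_mirtron .pred_class
#>   <chr>                  <dbl>     <dbl> <fct>
#> 1 syn_mirtron_0001     0.0142      0.986 mirtron
#> 2 syn_mirtron_0002     0.0306      0.969 mirtron
#> 3 syn_mirtron_0003     0.00286     0.997 mirtron
```

Reading: the fit trained 800 steps (a stratified 15% of the training
partition is carved out automatically to monitor early stopping — hence 178
training records) and kept the weights from step 300, where the held-out
loss was best. On the untouched 90-record test partition all 45 mirtrons are
recovered (sensitivity 1.00) and 42/45 canonical records are correctly
rejected (specificity 0.933); MCC 0.935 summarizes the agreement. Per-record
softmax probabilities sum to 1.

`count_parameters(build_concat_spec())` prints the per-layer accounting of
the mixed model (416/544/672/800 for the four convolution branches, 16512
and 258 for the dense layers, 19,202 total), `tidy(fit)` returns the same as
a tibble, and `autoplot(fit)` draws the training/held-out loss curves.

With real data the same pipeline is:

```r
mirtrons  <- read_labeled_fasta("mirtrons.fa",  label = "mirtron")
canonical <- read_labeled_fasta("canonical.fa", label = "canonical")
corpus <- merge_datasets(mirtrons, canonical)
sp <- stratified_split(corpus, test_fraction = 0.30, seed = 1)
fit <- train_cnn(build_concat_spec(input_length = dataset_max_length(corpus)),
                 sp$train)
evaluate_model(fit, sp$test)
```

## Command line

A thin wrapper over the same functions is installed with the package:

```sh
Rscript "$(R -e 'cat(system.file("scripts/mirtroncnn.R", package="mirtroncnn"))' -s)" \
  train --fasta corpus.fa --labels labels.tsv --variant concat --out run/
```

Subcommands: `split`, `train`, `evaluate`, `predict`, `simulate`, `params`.
Logs go to stderr; machine-readable outputs (split manifests, loss TSV,
metrics TSV/JSON, checkpoints) go only to `--out`.

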