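# sranet

Person identification and verification from chest radiographs by deep
metric learning. The package implements an attention-augmented
convolutional embedding generator — self-residual attention blocks
combining channel and spatial gates, an attention block, and a reverse
attention block on top of a residual-network backbone — trained as a
three-branch Siamese network with the triplet hinge loss

```
L(A, P, N) = max(0, ||f(A) − f(P)|| − ||f(A) − f(N)|| + margin)
```

where `f(·)` is the shared embedding generator, `A`/`P` are two images of
one patient and `N` an image of a different patient. Identification ranks
a gallery of stored embeddings by Euclidean distance to a query (top-k);
verification thresholds the distance of a single pair, with the threshold
calibrated on labelled pairs. Enrolling new patients never requires
retraining: images are embedded once and appended to the gallery.

The intended audience is researchers in radiograph-based biometrics and
forensic identification who want a fully self-contained, CPU-reproducible
reference implementation: the entire network stack (convolutions via
im2col + BLAS, batch normalisation, the attention gates, backpropagation
and Adam) lives in plain R, every layer gradient is verified against
finite differences in the test suite, and a synthetic radiograph phantom
generator makes the complete train → embed → identify/verify pipeline
runnable with no external data.

## Worked example

Train the CPU-scale model on a synthetic cohort and evaluate it:

```r
library(sranet)

bench <- benchmark_reid(n_identities = 20, images_per_identity = 5, seed = 1)
print(bench$trained)
#> Identification: top-1 1.000, top-5 hit rate 1.000 (100 queries)
#> Verification:   accuracy 0.950, precision 0.940, recall 0.959 (threshold 5.711, 100 held-out pairs)
print(bench$untrained)
#> Identification: top-1 0.520, top-5 hit rate 0.800 (100 queries)
#> Verification:   accuracy 0.760, precision 0.755, recall 0.755 (threshold 0.038, 100 held-out pairs)
```

The cohort is 20 synthetic identities × 5 images (identity-stable anatomy
plus per-acquisition noise and jitter). After ~3 minutes of triplet
training on one CPU, the trained embedding ranks the correct patient first
for every query and verifies held-out pairs at 95% accuracy, while the
identically initialised untrained architecture manages 52% top-1 and 76%
verification — the separation the attention-based embedding is designed to
produce. `bench$history` holds the per-epoch mean triplet loss.

Individual pieces compose the same way outside the benchmark:

```r
ds    <- generate_dataset(10, 3, size = 64, seed = 7)
index <- index_patients(ds$metadata)          # keeps patients with >= 2 images
imgs  <- lapply(ds$images, preprocess_image, size = 64)
model <- build_siamese_triplet_model(tiny_network_config(seed = 7))
tri   <- sample_triplets(index, 100, seed = 7)
fit   <- train_triplet_model(model, tri, images = imgs, epochs = 10, lr = 1e-3)
store <- embed_collection(model, index, images = imgs)
identify_topk(store$emb[1, ], store, k = 5)
```

A command-line interface covering the same pipeline is installed as
`exec/sranet` (subcommands `synth`, `train`, `embed`, `identify`,
`verify`, `evaluate`); run it with `--help` for usage.

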