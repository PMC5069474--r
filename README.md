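# mlphvg

Multiscale limited penetrable horizontal visibility graphs (MLPHVG) for
nonlinear time-series analysis in R — with the network statistics and
cross-validated classification pipeline used for graph-based seizure
detection from EEG segments.

## What it does

Physiological signals such as EEG carry diagnostic information in their
*nonlinear temporal structure*, which classical spectral features miss.
The MLPHVG method turns a series $\{x(i)\}_{i=1}^N$ into networks and reads
that structure off their topology:

1. **Coarse-grain** at scale factor $s$:
   $y^{(s)}(j) = \tfrac1s \sum_{i=(j-1)s+1}^{js} x(i)$,
   giving $\lfloor N/s\rfloor$ points per scale.
2. **Limited penetrable horizontal visibility.** Samples become
   time-ordered nodes; $i$ and $j$ are linked iff at most $L$ in-between
   samples reach the height $\min\{y(i), y(j)\}$ (such samples "block" the
   horizontal sight line). $L = 0$ is the classical horizontal visibility
   graph; $L = 1$ — the default — tolerates one blocker per link, making
   the topology robust to noise.
3. **Network features per scale:** the average clustering coefficient
   $\bar C = \tfrac1M\sum_i C_i$ and the clustering coefficient entropy
   $E_C = -\sum p_i \ln p_i$, $p_i = C_i/\sum_j C_j$ over nodes with
   $C_i > 0$.
4. **Classification** of two signal classes from the $(\bar C, E_C)$ pair
   at a chosen scale with an SVM, scored by leave-one-out and by
   10×-repeated stratified 10-fold cross-validation.

The package is aimed at researchers analyzing biomedical or other nonlinear
signals who want visibility-graph features with a verified, reproducible
construction: a fast C++ builder checked edge-for-edge against a literal
reference implementation, exact structural invariants under test, and
seed-deterministic synthetic benchmarks.

## Worked example

```r
library(mlphvg)

# a chaotic logistic-map trajectory, 1000 samples
x <- gen_logistic(1000, r = 4, x0 = 0.3, burn_in = 100)

build_mlphvg(x, scales = 1:3, L = 1)
#> Multiscale LPHVG: series of length 1000 | L = 1
#>   scale 1: 1000 nodes, 3964 edges
#>   scale 2: 500 nodes, 1959 edges
#>   scale 3: 333 nodes, 1301 edges

extract_features(x, scales = 1:3, L = 1, signal_id = "chaos")
#>   signal_id scale avg_clustering clustering_entropy
#> 1     chaos     1         0.6602              6.852
#> 2     chaos     2         0.6536              6.164
#> 3     chaos     3         0.6525              5.759
```

Each row summarizes the network at one scale: about two thirds of every
node's neighbour pairs are themselves connected (`avg_clustering`), and the
entropy measures how evenly that clustering is spread over nodes — it
shrinks with scale here because coarse-graining shortens the series.

The end-to-end surrogate experiment — 100 background-like AR(1) signals vs
100 chaotic logistic-map signals, 4096 samples each, variance-matched so
only temporal structure distinguishes them:

```r
ds    <- gen_two_class_dataset(n_per_class = 100, length = 4096, seed = 1)
feats <- features_table(ds$series, scales = 2, L = 1)
X <- as.matrix(feats[, c("avg_clustering", "clustering_entropy")])
y <- unname(ds$labels[feats$signal_id])

loocv(X, y)
#> protocol=loo accuracy=1.0000 (n_fits=200)
repeated_kfold(X, y, k = 10, repeats = 10, seed = 2)
#> protocol=kfold accuracy=1.0000 (n_fits=100)
#> per-repeat accuracies: 1.0000 1.0000 1.0000 1.0000 1.0000 1.0000 1.0000 1.0000 1.0000 1.0000
```

Both protocols separate the classes perfectly at scale 2 — the per-class
feature clouds are several within-class standard deviations apart even
though the raw gaps are small in absolute terms.

## Command line

A thin script over the same functions, installed with the package:

```sh
MLPHVG=$(Rscript -e 'cat(system.file("scripts", "mlphvg.R", package = "mlphvg"))')
Rscript "$MLPHVG" simulate  --generator two_class --n-per-class 100 --length 4096 --seed 1 --output-dir signals
Rscript "$MLPHVG" features  --manifest signals/manifest.csv --scales 1,2,3,4,5 -L 1 --output feats.csv
Rscript "$MLPHVG" classify  --features feats.csv --labels labels.csv --protocol kfold --scale 2 --seed 1
Rscript "$MLPHVG" transform --input signals/bg_001.txt --scale 2 -L 1 --output edges.txt
```

Series files are single-column text/CSV (optional header auto-detected);
edge lists are 1-based, `i < j`, lexicographically sorted; GraphML export is
available via `--graphml`.

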