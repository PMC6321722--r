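# mhcforest

Random-forest prediction of peptide presentation by MHC class I.

## The problem

Cytotoxic T cells survey cells through short peptides displayed on MHC
class I molecules. Predicting which peptides an HLA allele will present —
from nothing but the peptide sequence — is central to neoantigen
prioritisation in cancer immunotherapy. Mass-spectrometry immunopeptidomics
yields large catalogues of peptides that were *actually presented* in
vivo, which makes them better training material than in vitro binding
affinities: presentation depends on proteasomal processing, source-protein
abundance and transport, not affinity alone.

`mhcforest` trains one random-forest classifier per HLA allele to separate
presented 9-mer peptides (the dominant MHC-I ligand length) from random
nonamers drawn from a background proteome. It is aimed at computational
immunologists who have per-allele peptide lists (monoallelic data or the
output of an external deconvolution tool) and want trainable, inspectable
per-allele models plus the standard decoy-excess evaluation around them.

## The method

* **Encoding.** A 9-mer is encoded position-wise with any subset of six
  features: hydropathy (Kyte–Doolittle), aromatic-ring indicator, formal
  charge at pH 7.4, residue mass (9 coordinates each), one-hot ("sparse")
  encoding and BLOSUM62 rows (180 coordinates each). The default
  combination `HASM` (hydropathy, aromatic, sparse, mass) gives a
  207-dimensional vector.
* **Training.** For each allele, binders are mixed 1:1 with random decoy
  nonamers sampled from proteome windows, and a forest of 1000 trees is
  grown with Gini-impurity splits, `sqrt(p)` candidate features per node
  and bootstrap resampling. The model score is the ensemble's
  positive-class probability in [0, 1].
* **Evaluation.** Test binders are mixed with a 99-fold excess of fresh
  decoys and scored; the headline metric is **Prec1%**, the precision
  among the top 1% of ranked peptides (1.0 for a perfect classifier, 0.01
  for a random one at this class ratio), with AUPRC (average precision)
  and AUROC as companions, over five decoy replicates and repeated 75/25
  train/holdout splits.
* **Feature search.** All 63 non-empty subsets of the six features can be
  evaluated exhaustively; the selection rule takes the smallest subset
  whose mean Prec1% and AUPRC both sit within 1% of the respective maxima.
* **Interpretation.** Per-coordinate Gini-impurity importances are
  normalised per model, averaged across models, and aggregated by peptide
  position — recovering the canonical anchor positions 2 and 9.
* **Downstream statistics.** Spearman/Pearson correlation of model scores
  with IC50 binding affinities (per allele, entry-weighted means), and
  Cliff's delta for the expression of presented-vs-non-presented genes
  (per sample, gene-count-weighted means).

A motif simulator (position weight matrices with anchor preferences,
synthetic proteomes, affinities monotone in motif match, expression
up-shifted for presented genes) makes the full pipeline runnable without
any external data.

## Worked example

```r
library(mhcforest)

# simulate a study: one allele, anchored motif, background proteome
proteome <- synth_proteome(n_proteins = 100, mean_length = 300, seed = 42)
motif <- make_motif(seed = 42)            # anchors at positions 2 and 9
motif
#> <motif: anchors 2,9 (T,F) at weight 0.90>

binders <- sample_binders(motif, 300, seed = 43)
dataset <- allele_dataset("A0201", binders)
dataset
#> <allele A0201: 300 unique binders, trainable>

model <- train_allele_model(dataset, proteome,
                            train_config(n_trees = 300, seed = 44))
res <- evaluate_with_decoys(model, sample_binders(motif, 80, seed = 45),
                            proteome, excess = 99, n_decoy_sets = 5, seed = 46,
                            exclude = binders)
attr(res, "summary")
#>   metric      mean           sd
#> 1  prec1 0.7850000 0.0285043856
#> 2  auprc 0.7590547 0.0381316573
#> 3  auroc 0.9927781 0.0003335584

imp <- model_importance(model)
subset(imp$per_position_feature, feature == "S")
#>    feature position  importance
#> 28       S        1 0.010215608
#> 29       S        2 0.210537825
#> 30       S        3 0.009658177
#> 31       S        4 0.009803920
#> 32       S        5 0.010248434
#> 33       S        6 0.010570110
#> 34       S        7 0.010395098
#> 35       S        8 0.011415335
#> 36       S        9 0.190371522
```

Held-out binders are retrieved with ~0.79 precision in the top 1% of a
1:99 binder:decoy mixture (a random scorer would get 0.01), and the
one-hot importance concentrates on the planted anchor positions 2 and 9 —
about 20-fold above the non-anchor positions. At these simulator settings
(anchor weight 0.9, uniform background) Prec1% is capped below 1: see the
methods vignette for the exchangeability argument that puts the ceiling
near 0.77.

The same pipeline is scriptable from a shell via the bundled launcher:

```sh
mhcforest simulate --outdir sim --alleles 1 --binders 300 --seed 42
mhcforest train --allele A0101 --binders sim/binders_A0101.txt \
          --proteome sim/proteome.fasta --outdir run --trees 1000 --seed 1
mhcforest evaluate --model run/model_A0101 --binders holdout.txt \
          --proteome sim/proteome.fasta --outdir eval --excess 99
```

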