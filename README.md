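# spatlink

Cross-modal analysis tools for spatial transcriptomics (ST) built around one
idea: represent both a capture spot's transcriptome and its tissue-image
patch as vectors in a shared embedding space, then solve the field's
recurring tasks — aligning adjacent sections, annotating histology from bulk
RNA-seq or marker genes, decomposing spots into cell types against a
single-cell reference, retrieving transcriptomes for image queries, and
predicting spot-level expression from images — as geometry in that space.

The package is aimed at computational biologists who want these algorithms
as composable, deterministic R functions with a full evaluation-metric suite
and seeded synthetic cohorts, so every pipeline stage can be developed and
validated at desk scale without downloads or GPUs.

## What is inside

**Gene sentences.** A profile becomes the ordered, space-joined list of its
top-50 expressed gene symbols ("`SNAP25 ENO2 CKB ...`"); ranking is
invariant to monotone normalization, ties break by input order.

**Reference dual encoder.** A deterministic text/image encoder pair over a
shared per-token Gaussian basis: the text encoder weights the gene at rank
*r* by 1/log2(r+1); the image encoder maps named feature channels linearly
onto the same basis. The symmetric contrastive (InfoNCE) objective

    L = -(1/N) [ Σ_i log softmax_j(x_i·y_j/σ)_i + Σ_i log softmax_j(y_i·x_j/σ)_i ]

(temperature σ = 0.07) drives linear adapter fine-tuning.

**Alignment.** Nonrigid coherent point drift on points augmented with the
first two principal components of the spot embeddings (one PCA jointly over
both sections), EM with log-sum-exp posteriors, displacement restricted to
the spatial coordinates, and a final rigid rotation + translation projection
that suppresses distortion.

**Annotation.** Cosine-similarity maps and zero-shot classification against
bulk-profile or marker-gene reference embeddings, with dual-model fusion by
per-image min-max normalization and summation.

**Decomposition.** A spots x references probability matrix, parameterized as
a columnwise softmax and optimized by gradient descent on the sum over
embedding dimensions of cosine distance between projected reference
embeddings and spot embeddings; per-spot type fractions with optional
non-maximum-suppression refinement.

**Retrieval / prediction.** Cosine top-k retrieval scored by Recall@K over
quantile ranks; expression prediction as the similarity-weighted average of
training-spot expression with a 10-fold cross-validation harness.

**Metrics.** Calinski-Harabasz, Pearson, Kendall tau-b, Jensen-Shannon
divergence (base-2), single-window SSIM, MSE, and the impact score
(mean of the SSIM z-score and sign-inverted JS z-score across methods).

**Synthetic data.** Seeded generators for paired expression/image cohorts
with known cell-type fractions, rigidly perturbed and jittered sections with
the exact inverse transform, depth downsampling by binomial thinning, and
pseudo-spot binning of single cells.

## Worked example

```r
library(spatlink)

# simulate a paired cohort and score decomposition + retrieval
cohort <- simulate_paired_cohort(cohort_spec(n_spots = 200, n_genes = 200,
                                             n_types = 4, seed = 1))
cfg <- encoder_config(embed_dim = 256, seed = 1)

corpus <- build_corpus(cohort$spots, k = 50)
substr(corpus$sentence[1], 1, 60)
#> "G178 G017 G081 G001 G038 G123 G049 G025 G192 G096 G084 G158"

spot_embs <- encode_corpus(corpus, cfg)
refs <- t(sapply(colnames(cohort$fractions), function(ty) {
  v <- cohort$loadings[, ty]; names(v) <- rownames(cohort$loadings)
  encode_text(build_sentence(v, 50), cfg)
}))
mapping <- map_cells(mapping_problem(refs, spot_embs, rownames(refs)),
                     seed = 1)
fractions <- fractions_from_mapping(mapping)
scores <- evaluate_decomposition(fractions, cohort$fractions)
scores$per_type
#>   type         js      ssim
#> 1   T1 0.01309762 0.9232102
#> 2   T2 0.01876953 0.8257955
#> 3   T3 0.01844583 0.9161409
#> 4   T4 0.01491116 0.8510655

image_embs <- encode_features(cohort$features, cfg)
bank <- retrieval_bank(spot_embs, cohort$spots$barcodes)
hits <- lapply(seq_len(nrow(image_embs)), function(i)
  retrieve_topk(image_embs[i, ], bank, truth_id = cohort$spots$barcodes[i]))
recall_at_k(hits, 0.05)
#> 0.65   # chance level is 0.05
```

The decomposition recovers the planted type fractions nearly exactly
(per-type JS divergence ~0.02, SSIM 0.83-0.92), and image queries retrieve
their paired transcriptome within the top 5% of the bank 65% of the time,
thirteen times the chance rate.

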