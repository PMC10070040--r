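# scMultiClust

Fusion of paired single-cell multi-omics data (scRNA-seq + scATAC) into
an informative co-embedding, with imputation of dropout events and the
mining of **multiple diverse clusterings** — e.g. a cell-*type*
partition and an orthogonal cell-*state* partition — from the same
cells.

## Who this is for

Anyone with cell-matched RNA counts (cells × genes, non-negative
integers) and peak accessibility (cells × peaks, binary or binarizable)
who wants (a) a fused low-dimensional representation that respects both
what the omics layers share and what is specific to each, (b)
model-based imputation, and (c) more than one meaningful way of
partitioning the cells.

## The model in brief

**Stage 1 — fusion.** Omics-specific encoders produce latents
$Z^X, Z^Y$; cell-by-cell self-attention $A=\mathrm{softmax}(ZZ^\top/d)$
with a cooperative omics-label discriminator extracts individuality
$Z^{gX}, Z^{gY}$; a contrastive mutual-information objective over a
shared MLP extracts commonality $Z^{XY}$; the co-embedding is
$Z^I = Z^{XY} + \lambda_x Z^{gX} + \lambda_y Z^{gY}$. Generative
decoders tie $Z^I$ to the data: a zero-inflated negative binomial
(ZINB) likelihood on the raw RNA counts (heads $\Pi, \bar M^X, \Theta$)
and a Bernoulli cross-entropy on the binary ATAC matrix
($\bar M^Y$). Training minimizes
$L_1 = L_{ZINB} + \alpha_1 L_{Ber} + \alpha_2 L_{dis} + \alpha_3 L_{cl}$
with full-batch Adam. Imputed matrices are the decoder means.

**Stage 2 — multiple clusterings.** $Z^I$ is projected into $L$
attention-head subspaces $O_l$; a reconstruction loss keeps them
faithful, an HSIC-based redundancy penalty makes them non-redundant,
and a per-head KL target-distribution loss (Student-t soft assignments
sharpened toward $r_{ij} \propto p_{ij}^2/f_j$) yields $L$ hard
partitions: $L_2 = L_{rec} + \beta_1 L_{red} + \beta_2 L_{clu}$.
$L = 1$ reduces to single-clustering refinement.

Evaluation helpers: NMI, ARI, pair-counting Jaccard, silhouette, Dunn
index, diversity (1−NMI, 1−JI), and the seeded k-means single-
clustering protocol on $Z^I$.

All gradients come from a small reverse-mode automatic-differentiation
engine included in the package (finite-difference tested); there is no
deep-learning framework dependency.

## Worked example

Simulated paired data with two planted orthogonal partitions (4 cell
types, 2 cell states), fused and clustered:

```r
library(scMultiClust)

sim  <- simulate_pair(sim_config(seed = 1))    # 300 cells, 200 genes, 300 peaks
sim$omics
#> omics_pair: 300 cells, 200 genes (RNA), 300 peaks (ATAC)
#>   RNA zero fraction 0.579 | ATAC open fraction 0.143

st1 <- train_stage1(sim$omics, fusion_config(epochs = 250, seed = 2))
kmlab <- kmeans_single_clustering(st1$latents$ZI, k = 4, seed = 2)
ari(kmlab, sim$type_labels)
#> [1] 1

imp <- impute(st1)
cor(as.vector(imp$imputed_rna), as.vector(sim$true_rna_mean))   # imputed
#> [1] 0.578
cor(as.vector(sim$omics$rna_counts), as.vector(sim$true_rna_mean)) # raw
#> [1] 0.560

st2 <- train_stage2(st1$latents$ZI,
                    multiclust_config(L = 2, cluster_counts = c(4, 2), seed = 2))
C1 <- st2$clusters$labels[[1]]; C2 <- st2$clusters$labels[[2]]
round(c(C1_vs_types  = nmi(C1, sim$type_labels),
        C2_vs_states = nmi(C2, sim$state_labels),
        diversity    = 1 - nmi(C1, C2)), 2)
#>  C1_vs_types C2_vs_states    diversity
#>         1.00         0.94         1.00
```

The first clustering recovers the planted cell types (ARI = 1 against
the type labels), the second recovers the planted cell states from its
own subspace (NMI 0.94), and the two partitions are nearly
non-overlapping (diversity 1−NMI ≈ 1). Imputation pulls the observed
counts toward the true dropout-free means: the imputed matrix
correlates better with the simulator's ground-truth means than the raw
counts do (0.578 vs 0.560 here; the margin varies with the seed).

A command-line interface wrapping the same functions lives at
`inst/cli/scmc.R` (subcommands `simulate`, `fuse`, `multicluster`,
`impute`, `evaluate`, `run`), and `run_pipeline()` executes the whole
chain from a YAML/JSON config with a reproducibility manifest.

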