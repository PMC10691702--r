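# mlcoexp

Multilayer community detection for gene co-expression **correlation
matrices**.

Gene co-expression differs between tissues: some gene sets are co-regulated
everywhere (housekeeping programs), others only in one tissue (secretory or
epidermal programs). `mlcoexp` finds both kinds at once by treating each
tissue's co-expression matrix as one layer of a multiplex network and
partitioning all (gene, tissue) nodes jointly. It is written for analysts of
tissue-resolved expression panels (e.g. GTEx-style TPM tables) who want
communities with attached significance, tissue-specialization scores, and
genomic follow-up statistics, without thresholding correlations into a graph
first.

## The model

For tissue (layer) α with S samples, co-expression is the Pearson correlation
of log-transformed abundance,

    ρ_ijα = corr( log(x_i,α,s + 1), log(x_j,α,s + 1) ),   s = 1..S,

and the same-gene interlayer coupling ω_iαβ is the correlation of gene i's
log expression between tissues α and β across their shared donors, clipped at
zero. The partition g is scored by the multilayer modularity

    Q = (1/C_norm) Σ_{ijαβ} [ (ρ_ijα − γ_α ⟨ρ_ijα⟩) δ_αβ + ω_iαβ δ_ij ] δ(g_iα, g_jβ),

where ⟨ρ_ijα⟩ is the **configuration model for correlation matrices**: the
maximum-entropy multivariate normal whose correlation matrix preserves every
node's strength (row sum). `mlcoexp` fits that null itself (damped Newton on
the dual), maximizes Q with an iterated generalized Louvain engine, selects
the resolution γ by the 1-D CHAMP upper envelope over a sweep (default 15
values on [1, 4]), and stabilizes the partition by consensus clustering of
200 stochastic runs.

Each community then gets:

* an analytic Z score for its total intralayer weight under the null
  (Wishart moments of the null sample covariance);
* a **specialist fraction** — genes unique to the dominant tissue divided by
  community nodes — classifying it as specialist (> 0.5) or generalist;
* optional chromosome-localization randomization tests (same-chromosome pair
  fraction, mean base-pair distances, 100 shuffles, Bonferroni per group) and
  a shared cis-eQTL screen for strongly co-expressed gene pairs.

## Worked example

Everything below is synthetic: the built-in generator plants one *generalist*
block (six genes co-expressed in both layers, with donor-linked factors, so
the layers are coupled) and one *specialist* block (six genes co-expressed in
tissue 1 only) among background genes.

```r
library(mlcoexp)

design <- planted_design(N = 40, S = 300, n_generalist = 6, n_specialist = 6)
layers <- generate_expression(design, seed = 11)
fit <- multilayer_communities(layers, genes = design$gene_ids,
                              n_consensus = 50, seed = 1)
fit
#> Multilayer co-expression community fit
#>   40 genes x 2 layers (tissue1, tissue2)
#>   CHAMP domains on [1, 4]: 6; selected gamma: 3.53, 1.79
#>   gamma = 3.53: 12 communities, Q = -0.5857
#>   gamma = 1.79: 3 communities, Q = 0.0784

s <- summary(fit)
head(as.data.frame(s)[s$n_pairs > 0,
     c("gamma", "community", "n_nodes", "z",
       "specialist_fraction", "specialist_tissue", "class")])
#>     gamma community n_nodes         z specialist_fraction specialist_tissue      class
#>  3.525674         1      36  7.463294          0.88888889           tissue2 specialist
#>  3.525674         2      28 10.099008          1.00000000           tissue1 specialist
#>  1.787035         1      62 11.433714          0.09677419           tissue2 generalist
#>  1.787035         2      12 16.389814          0.00000000               N/A generalist
#>  1.787035         3       6 16.301126          1.00000000           tissue1 specialist
```

At the lower selected resolution (γ ≈ 1.79) the method reports exactly the
planted structure: community 2 is the generalist block — twelve nodes, the
six planted genes present in *both* layers, so no gene is unique to a tissue
and the specialist fraction is 0.000 — and community 3 is the specialist
block, six nodes confined to tissue 1 (fraction 1.000). Both are far from the
configuration-model expectation (z ≈ 16). The Z column is the deviation of
the community's total intralayer correlation from its null expectation in
null standard deviations; `plot(fit)` draws the CHAMP envelope the γ values
were selected from.

Genomic follow-up runs from the same objects:

```r
ann <- generate_annotation(design)
localization_test(c("G001", "G002", "G003"), ann,
                  universe = design$gene_ids, n_rand = 100, seed = 1)
shared_eqtl_pairs(fit$mlc$rho[[1]], generate_eqtl(design), threshold = 0.5)
```

A command-line wrapper with `simulate | build | sweep | detect | localize |
eqtl` subcommands is installed at `inst/cli/mlcoexp.R`.

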