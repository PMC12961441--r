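# ptv2fr

Semantic segmentation of sorghum seedling point clouds and downstream
phenotypic trait extraction, in pure R.

Seedling trays ("pots") carrying 15–25 sorghum plants are reconstructed from
multi-view imagery into colored 3-D point clouds. This package labels every
point as **leaf**, **stem** or **pot** with a U-shaped point-transformer
network and then turns the labeled cloud into the phenotypes breeders use at
the seedling stage: per-plant stem length and basal diameter, per-leaf
length, width and surface area, and the tray-level leaf area index
(LAI = total leaf area / 625 cm²).

The network's attention blocks are **multi-radius dual-coordinate attention**
(MRDCA): three parallel KNN branches (K = 8/16/24) whose scalar attention
logits combine a scaled query–key product, an MLP of the relative offset and
feature difference, an MLP of min–max-normalized absolute coordinates, and a
learnably gated MLP of neighborhood-pooled channel statistics,

w_ij = softmax_j( q_i·k_j/√d + ψ_rel(Δp_ij, Δf_ij) + ψ_abs(p_i^norm) + α·ψ_pool(Δf_i·) ).

Before the segmentation head, **PG-InvFR** refines the decoder features with
involution-style dynamic kernels over a k-NN point graph, scaled per point
by an uncertainty gate α_i = σ(−Σ_c p_ic log p_ic) derived from an auxiliary
classifier, so ambiguous boundary points (stem–leaf junctions) are refined
hardest. Training minimizes the composite loss

L = α·L_wCE + β·L_Lovász,

inverse-frequency weighted cross-entropy (w_c = N/(C·N_c), mean-normalized)
plus the multiclass Lovász-softmax surrogate of 1 − IoU, which counters the
severe stem-class imbalance.

Trait extraction follows the segmentation: DBSCAN on the xy projection
(ε = 3 cm, minPts = 80) instances the stems; RANSAC line consensus (120
iterations) plus SVD fits each stem axis (sign-fixed to a_z ≥ 0); leaf
points join the nearest stem centroid; per-plant 3-D DBSCAN separates
leaves; PCA extents give leaf length/width; Delaunay triangulation of the
PCA-plane projection with 3-D triangle areas gives leaf area.

Because no public labeled dataset of this kind is available, the package
includes a procedural generator of labeled pots whose stems and
cylinder-section leaf ribbons have closed-form traits — every training and
trait benchmark in the test suite runs against that analytic ground truth.
The network itself (including reverse-mode gradients) runs on a compact
tape-based autodiff engine written for this package; KNN, FPS, DBSCAN and
Delaunay are compiled (Rcpp) primitives.

## Worked example

```r
library(ptv2fr)

# a labeled synthetic pot with analytic ground truth
g  <- generate_pot(pot_spec(n_plants = 12, noise_sigma = 0, stem_curvature = 0,
                            density_scale = 2, density_gradient = 0,
                            occlusion_sectors = 0, grid_jitter = 5e-4,
                            leaf_arc_range = c(0.02, 0.032),
                            leaf_bend_angle_range = c(0.3, 0.7)), seed = 11)
g$cloud
#> <labeled_cloud> 26488 points, pot 'pot11'
#>   labels: ignore=0 leaf=12568 stem=1920 pot=12000

rec <- extract_traits(g$cloud)
nrow(rec$plants); rec$pot$lai
#> [1] 12
#> [1] 0.1066415
g$traits$pot$lai          # analytic truth for the same pot
#> [1] 0.1070037

head(rec$plants[, c("plant", "stem_length_cm", "stem_diameter_mm")], 3)
#>   plant stem_length_cm stem_diameter_mm
#> 1     1       2.916658         2.886283
#> 2     2       4.130944         2.662263
#> 3     3       4.061993         2.380742
```

Twelve plants are found (matching the layout), the recovered LAI of 0.1066
sits within half a percent of the analytic 0.1070, and per-plant rows give
stem length in cm and basal diameter in mm.

Training and inference at desk scale:

```r
clouds <- lapply(1:17, function(i)
  fps_downsample(generate_pot(pot_spec(), seed = i)$cloud, 1024, seed = i))
cfg   <- ptv2fr_config(channels = c(16, 32),
                       mrdca = mrdca_config(k = c(4, 8, 12), branch_channels = 8),
                       pg = pg_config(k = 8, hidden = 16))
model <- build_model(cfg, seed = 1)
fit   <- train(model, clouds, train_config(batch_size = 4, epochs = 12,
                                           lr = 5e-3, milestones = 8, gamma = 0.2))
out   <- predict_cloud(fit$model, clouds[[1]])
table(out$labels)
```

A thin command-line front end (`inst/cli/ptv2fr`) wraps the same functions:
`ptv2fr generate`, `split`, `fps`, `train`, `segment`, `evaluate`, `traits`.

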