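# netskel

Quantitative mesoscopic analysis of particulate network structures —
colloidal gels, fibre networks, aggregated suspensions — from 3D microscopy
image stacks or particle coordinate sets.

Microscopy and particle-based simulation both resolve aggregated matter
across many length scales, but most structural analyses stop at the local
particle arrangement (pair correlations, coordination numbers). `netskel`
targets the mesoscopic scale: it reduces the imaged material to a
single-voxel-thin backbone, converts that backbone into a graph of **nodes**
(strand end points and branch points) and **links** (strand segments with
physical path lengths Λ), cleans discretization artefacts, and reports
network descriptors:

- node and link counts N_N, N_L and the branching ratio N_L/N_N;
- number densities ρ_N, ρ_L in µm⁻³ and σ⁻³ (σ = particle diameter), with a
  margin-based box-edge correction;
- the normalized link-length distribution Ñ(Λ);
- the tortuosity ξ = ⟨λ/λ_Euc⟩, the mean ratio of along-backbone path length
  to Euclidean end-to-end distance over all paths spanning the box.

Because coordinate sets are rendered to images through an optional
point-spread-function model, the same pipeline applies to experiments and
simulations, enabling direct quantitative comparison — including data in
which individual particles cannot be resolved.

## Pipeline

1. **Preprocess** — Gaussian blur; per-slice binarization, either Otsu or the
   percentile rule I_T = I_10 + V_u (I_90 − I_10) (per-slice thresholds
   compensate depth-dependent intensity drift); morphological closing with a
   physical ellipsoidal element; removal of small unconnected clusters;
   filling of 3D-enclosed holes.
2. **Skeletonize** — topology-preserving 3D thinning: border voxels are
   deleted only if they are not end points, leave the Euler characteristic
   unchanged, and are simple points; components and χ of the input are
   provably preserved.
3. **Graph + clean** — voxel classification by 3×3×3 material counts
   (2 = end, 3 = link, >3 = branch), branch clumping, link-path tracing;
   then iterative cleaning: side chains shorter than 1.5σ pruned, canal
   (degree-2) nodes merged, nodes closer than 0.9σ collected.
4. **Analyze** — counts, densities, Ñ(Λ), ξ, per-component and pooled,
   with diagnostic overlay TIFFs at every stage.

A phantom generator (`makeTube`, `makeArc`, `makeJunction`, `makeTorus`,
`makeBeadNetwork`, `corruptStack`) produces synthetic volumes and
beads-on-a-graph gel images with known ground-truth topology for validation.

## Worked example

```r
library(netskel)

# a synthetic gel: 50 strand junctions in a 20 sigma box, beads of
# diameter sigma laid along the strands, cropped by the imaging window
bn  <- makeBeadNetwork(seed = 1)
geom <- VoxelGeometry(0.25, 0.25, 0.25, "sigma")
img <- projectParticles(bn$particles, geom, pad = 0)

pre <- preprocessVolume(img, sigma = 1, method = "otsu")
sk  <- thinVolume(pre$volume)
gr  <- cleanGraph(extractGraph(sk, sigma = 1))
rep <- analyzeNetwork(gr, graphToSkeleton(gr, stackDim(sk)), margin = 0)
rep
#> Network summary (margin 0 sigma):
#>   N_N = 28, N_L = 33, N_L/N_N = 1.179
#>   rho_N = 0.0035 sigma^-3 (0.0035 sigma^-3)
#>   rho_L = 0.004125 sigma^-3 (0.004125 sigma^-3)
#> Tortuosity: xi = 2.029 +/- 0.425 over 6 spanning paths
#>   2 connected component(s)
```

The phantom's cropped ground truth contains 30 nodes and 35 links inside the
box; the pipeline recovers 28 and 33 (two nodes short: a stub clipped at a
box face falls below the 1.5σ side-chain threshold once rendered), a
branching ratio of 1.18, densities of a dilute gel (ρ_N ≈ 3.5·10⁻³ σ⁻³), and
a tortuosity ξ ≈ 2 typical of strand networks.

The same run is available from the shell:

```sh
Rscript inst/scripts/netskel.R phantom beads --out demo
Rscript inst/scripts/netskel.R run --input demo/beads.txt --kind coordinates \
    --voxel "0.25 0.25 0.25" --sigma 1 --out demo/run
```

which writes `nodes.csv`, `links.csv`, `report.json`, `histogram.csv`, the
cleaned-skeleton TIFF, the binarization/preprocessing/skeleton overlay TIFFs
and an audit log of every parameter used.

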