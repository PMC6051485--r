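# boxseg

Interactive bounding-box segmentation for 2D images and 3D volumes, with
image-specific fine-tuning.

## Who this is for

Anyone who needs to extract one object from a medical (or medical-like)
image with minimal interaction: draw a bounding box, get a segmentation,
optionally correct it with a few scribbles. The twist is that the
segmentation network answers a *generic* question — "extract the salient
object inside this box" — so it can be applied to object classes that were
never annotated for training (zero-shot use), and it is re-adapted to every
single test image on the fly.

## The method

A compact resolution-preserving dilated CNN (five feature blocks, dilations
1/2/4/8/16 in 2D, receptive field 181×181; an anisotropic 3D variant with
receptive field 85×85×9 and per-block 1×1×1 feature compression) maps the
normalized box content to a per-pixel foreground probability `p_i`. The
labelling `Ŷ` and the network parameters `θ` then alternately minimize

    E(Ŷ, θ) = Σ_i φ(ŷ_i | X̂, θ) + λ Σ_{i,j} ψ(ŷ_i, ŷ_j | X̂)
    subject to ŷ_i = s_i on scribbles S,

with unaries `φ = −(ŷ log p + (1−ŷ) log(1−p))` and contrast-sensitive
pairwise terms `ψ = [ŷ_i≠ŷ_j] exp(−(X̂(i)−X̂(j))²/2σ²)/d_ij`:

* **label update** — exact global minimization by max-flow/min-cut (the
  binary pairwise energy is submodular); scribbles are hard constraints;
* **network update** — a few gradient steps on the classifier block only
  (features are cached once per image), using the weighted cross-entropy
  `−Σ w(i) (ŷ_i log p_i + (1−ŷ_i) log(1−p_i))` where `w = ω` on scribbles,
  `w = 0` on uncertain pixels (softmax probability inside (t0, t1), or
  geodesically close to a scribble with the opposite label), `w = 1`
  elsewhere.

Everything is testable without external data: a synthetic "multi-organ"
scene generator produces bright shape classes that share saliency and
contrast but differ in geometry, a seen/unseen class split exercises the
zero-shot path, and a robot user draws corrective scribbles only inside
mis-segmented regions.

## Worked example

Train a compact 2D network on two synthetic shape classes, then segment an
instance of a class it has never seen:

```r
library(boxseg)

bm  <- make_benchmark(seen = c("ellipse", "blob"), unseen = c("lobed", "bumpy"),
                      n_train = 60, n_test = 8, seed = 11)
net <- build_network(pnet_spec(), seed = 21)
tr  <- train_network(net, bm$train, train_config(max_iterations = 500, seed = 3))

inst <- bm$test[[which(!sapply(bm$test, `[[`, "seen"))[1]]]   # an unseen-class instance
p0   <- forward_probability(tr$net, inst$region)
cat("initial Dice:", dice_score(p0 > 0.5, inst$mask), "\n")

st <- refine(tr$net, inst$region, cfg = finetune_config(), reference = inst$mask)
print(st$history[, c("round", "energy_before", "energy_after", "dice")])
cat("refined Dice:", dice_score(st$labeling, inst$mask), "\n")

scr <- robot_scribbles(st$initial_labeling, inst$mask)
st2 <- refine(tr$net, inst$region, scr, finetune_config(), reference = inst$mask)
cat("scribble-supervised Dice:", dice_score(st2$labeling, inst$mask), "\n")
```

```
initial Dice: 0.9763932
  round energy_before energy_after      dice
1     1      600.6738     523.1113 0.9807018
2     2      477.6082     455.2513 0.9810303
3     3      440.8847     432.7319 0.9796484
4     4      428.7537     425.0583 0.9803041
refined Dice: 0.9803041
scribble-supervised Dice: 0.9816831
```

The Dice score measures overlap with the reference mask (1 = perfect). The
initial zero-shot guess on a never-seen shape class is already at 0.976;
unsupervised fine-tuning lifts it to 0.980, and three robot scribbles on the
largest residual errors to 0.982.

The energy drops (or stays) at every label update — the graph cut is an
exact minimizer — and the scribble-supervised pass recovers detail that the
unsupervised pass cannot. `segment_box()` wraps the same pipeline
end-to-end (crop → normalize → resize → refine → restore) for a full image
and a `bounding_box()`, and `inst/cli/boxseg` exposes `train`, `segment`
and `simulate` subcommands for shell use.

## Package layout

| file | contents |
|---|---|
| `R/network_spec.R`, `R/network.R` | dilated network specs, receptive-field arithmetic, forward pass, feature cache |
| `R/instance_prep.R` | instance extraction, cropping, normalization, resizing, back-mapping |
| `R/crf.R` | CRF energy, exact graph-cut label update, brute-force oracle |
| `R/uncertainty.R` | uncertainty sets, geodesic transforms, weight maps |
| `R/finetune.R` | weighted loss, classifier updates, `refine()`, `segment_box()` |
| `R/trainer.R` | SGD training, Dice evaluation |
| `R/synthetic.R` | scene generator, benchmark bundles, robot user |
| `R/io.R` | PNG/TIFF/NIfTI readers and writers, YAML configs, checkpoints |
| `src/ops.cpp` | dilated convolution (im2col + BLAS), Dinic max-flow, Dijkstra, components, resampling |

See the vignette (`vignettes/interactive-box-segmentation.Rmd`) for the
model, parameter meanings, numerical choices and limitations.
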