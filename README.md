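# jointchange

Joint deformable registration and focal change detection for
longitudinal 3D brain MRI.

## The problem

Quantifying lesion evolution (new, growing, shrinking lesions — the
bread and butter of multiple sclerosis monitoring) from a baseline scan
`I1` and a follow-up scan `I2` requires compensating brain atrophy, a
smooth geometric change that affine registration cannot capture.  But an
unconstrained deformable registration does not stop at atrophy: it also
deforms tissue to "explain away" appearing lesions, erasing the change
signal before the detector sees it.  `jointchange` resolves this tension
by estimating the dense displacement field `w` and the binary change map
`c` **jointly**, as the minimizer of one coupled energy:

    E(w, c) = sum_x [ (1 - c(x)) * rho(I1, I2, w, x) + lambda2 * c(x) ]
              + lambda1 * Psi(w) + lambda3 * Phi(c)

where `rho` is the squared intensity residual of the backward warp
`I2(x - w(x))` normalized by the MAD scale `sigma`, `Psi` is first-order
Tikhonov smoothness of the field and `Phi` a binary Potts boundary
penalty on the change map.  Detected changes (`c = 1`) cancel the data
term, so the field cannot contract a lesion away; a good field removes
atrophy residuals so the detector does not flag them.

The energy is minimized by alternation: the field subproblem
(linearized, convex) is solved by ADMM proximal splitting — a closed-form
voxelwise prox for the data term and an exact DCT-domain solve for the
Tikhonov prox — inside a coarse-to-fine pyramid; the change-map
subproblem is solved **exactly** by graph cut (max-flow/min-cut).  The
package also ships the *sequential* baseline (register once, then
detect) and the *affine* baseline (no deformable registration), the
preprocessing chain (median-100 intensity scaling, 1 mm resampling,
differential bias-field correction), detection post-processing,
voxel- and lesion-wise evaluation metrics, and a seeded synthetic
longitudinal-pair generator with known ground truth.

Default hyperparameters follow the published setting: `lambda1 = 70`,
`(lambda2, lambda3) = (16, 5)` (preset `"lesjakdb"`) or `(25, 3)`
(preset `"msseg2"`); ADMM stops at relative change `2e-3` (cap 300),
the outer alternation at `1e-3` (cap 5).

## Worked example

```r
library(jointchange)

## a seeded synthetic pair: 3 appearing lesions + atrophy-like deformation
spec <- scenarioSpec("appearance", atrophy = TRUE,
                     shape = c(40, 40, 40), seed = 101)
pair <- makePair(spec)

## preprocess: median-100 scaling + differential bias correction
I1 <- normalizeMedianIntensity(pair$baseline, pair$mask)$volume
I2 <- normalizeMedianIntensity(pair$followup, pair$mask)$volume
I2 <- differentialBiasCorrection(I1, I2, pair$mask, kernel = 11L)

## the three pipelines
cfg   <- solverConfig()          # lesjakdb preset, lambda1 = 70
joint <- runJoint(I1, I2, pair$mask, cfg)
seq_  <- runSequential(I1, I2, pair$mask, cfg)
aff   <- runAffine(I1, I2, pair$mask, cfg)

## post-process and score against the ground truth
parenchyma <- BinaryMask(pair$labels == 1 | pair$labels == 2)
score <- function(run) {
    cm <- applyParenchymaMask(filterSmallComponents(changeMap(run)),
                              parenchyma)
    voxelMetrics(cm, pair$truth$change, pair$mask)[c("dsc", "ppv", "tpr")]
}
rbind(joint = score(joint), sequential = score(seq_), affine = score(aff))
```

On this seed the comparison prints

               dsc       ppv       tpr
    joint      0.8372093 0.9782609 0.7317073
    sequential 0.8096    0.9882812 0.6856369
    affine     0.7413127 0.7058824 0.7804878

which is the mechanism in numbers: *affine* detects sensitively
(TPR 0.78) but admits atrophy-induced false positives (PPV 0.71);
*sequential* registration removes those false positives (PPV 0.99) but
partially erases lesions (TPR 0.69); *joint* keeps the compensation
while protecting the lesions (TPR 0.73 at PPV 0.98, the best DSC of
the three).  The energy trace (`energyTrace(joint)` prints 52908.6
50877.5 50787.0 50787.0) decreases across the outer iterations.

A command-line interface wraps the same functions:

```sh
Rscript inst/cli/jointchange.R simulate --scenario appearance_atrophy \
        --seed 7 --out sim/
Rscript inst/cli/jointchange.R preprocess --baseline sim/baseline.nii.gz \
        --followup sim/followup.nii.gz --mask sim/mask.nii.gz --out pp/
Rscript inst/cli/jointchange.R run --method joint \
        --baseline pp/baseline_pp.nii.gz --followup pp/followup_pp.nii.gz \
        --mask pp/mask_pp.nii.gz --out out/
Rscript inst/cli/jointchange.R eval --pred out/change_map.nii.gz \
        --truth sim/truth_change.nii.gz --out eval/
```

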