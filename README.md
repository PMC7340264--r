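# xtalcut

Paired-refinement analysis of the high-resolution cutoff of macromolecular
diffraction data.

## The problem

Diffraction intensities fade into noise at high resolution, and the data
are conventionally truncated where indicators such as mean I/sigma or the
half-set correlation CC1/2 drop below a chosen level. Those indicators
describe the data, not the model: weak shells can still improve a refined
structure. Paired refinement tests each shell directly — refine the model
with the shell included, then compare the new and old models **against
the same lower-resolution data**, where their R values are comparable.
`xtalcut` automates the full protocol for crystallographers and methods
developers:

* reflection containers and plain-text I/O (merged amplitudes/intensities
  with CCP4-style free flags; unmerged XDS-ASCII-style intensities);
* merging statistics per resolution shell: multiplicity, completeness,
  mean I/sigma, Rmerge, Rmeas, Rpim, CC1/2 (with 1:1000-level
  significance) and CC* = sqrt(2 CC1/2 / (1 + CC1/2));
* model agreement: Rwork, Rfree, Rgap = Rfree − Rwork, CCwork/CCfree on
  intensities, with R = Σ| |Fo| − k|Fc| | / Σ|Fo| and the work-set scale
  k = Σ|Fo||Fc| / Σ|Fc|²;
* the paired-refinement ladder (`runLadder`) with matched-resolution
  delta-R values, and complete k-fold cross-validation over the free-flag
  sets (`runCompleteCV`) with per-step mean/SD/SEM and rise/fall counts;
* a deterministic built-in least-squares refinement backend (point-atom
  structure factors, global scale + ADP shift + coordinates by
  Levenberg–Marquardt), plus an adapter contract for external refinement
  programs;
* a synthetic-data generator with a planted information limit, the test
  substrate for the whole protocol.

The package reports; the cutoff decision stays with the user.

## Worked example

Generate a synthetic study with information to 1.5 A inside data extending
to 1.2 A, refine a degraded model at 1.65 A, and run the ladder:

```r
library(xtalcut)

cfg   <- generatorConfig(cell = unitCellNew(15, 16, 17), nAtoms = 60,
                         dMin = 1.2, multiplicity = 4, noiseRel = 0.2,
                         noiseShell = 1.0, dInfo = 1.5, transition = 0,
                         nFlagSets = 4L, seed = 4)
truth <- generateTruth(cfg)
dat   <- generateData(truth, cfg)
start <- degradeModel(truth, cfg, perturb = 0.1, resetAdp = NULL)

resA <- refineModel(start, dat$merged, 1.65, nCycles = 150)
lad  <- runLadder(resA, dat$merged, 1.65,
                  cutoffs = seq(1.60, 1.35, by = -0.05),
                  unmerged = dat$unmerged, nCycles = 80, seed = 1)
ladderSteps(lad)[, c("from", "to", "dRwork", "dRfree", "rGapA")]
```

```
  from   to        dRwork       dRfree      rGapA
1 1.65 1.60 -0.0002349946 -0.002383542 0.09015843
2 1.60 1.55 -0.0001228188 -0.005832911 0.08427167
3 1.55 1.50 -0.0005135431 -0.002755371 0.08158169
4 1.50 1.45  0.0013645678  0.001157207 0.08113884
5 1.45 1.40  0.0007509516  0.002660524 0.08332508
6 1.40 1.35  0.0007286863  0.001710166 0.08426918
```

Delta-Rfree is negative for every shell that carries information and
first turns positive at the 1.50 to 1.45 A step: the ladder recovers the
planted 1.5 A information boundary. `writeReports(lad, "out")`
writes `steps.csv`, `shells.csv`, `merging.csv`, per-step PDB models and a
single-page `report.html`. A thin command-line front end over the same
functions lives at `inst/cli/xtalcut.R` (`run` and `simulate`
subcommands, flags `--xyzin --hklin --hklin-unmerged -i -r`).

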