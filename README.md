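# jointsuv

Joint-level quantification of PET tracer uptake (FDG and NaF) in large
joints — knee, hip and sacroiliac — on coregistered PET/CT, with the
cohort statistics used in small-sample imaging studies of inflammatory
joint disease.

## The scientific problem

Semiquantitative reads of joint PET are hard to compare across patients
and tracers. The pipeline implemented here measures, for each joint and
side, the **global SUVmean**: bone belonging to the joint is segmented on
the CT, the PET is converted to body-weight standardized uptake values,
and the mean SUV over the segmented region is reported. Formally

    SUV(v) = C(v) / (D(t) / W),   D(t) = D * 2^(-Δt / 109.77 min)

with `C` the activity concentration (Bq/mL), `D` the injected dose (Bq)
decay-corrected over the uptake interval `Δt`, and `W` the body weight in
grams.

Per joint and side the stages are:

1. **ROI**: a landmark-driven rectangular region — knee: axial slab ±4 cm
   around the intercondylar eminence; hip: head–neck junction to 2 mm
   lateral of the pelvic brim, ±10 mm past the neck edge; sacroiliac:
   ±20 mm around the articulation line.
2. **Segmentation**: CT voxels in the inclusive 150–1500 HU bone window
   (optionally only components connected to ≥300 HU seeds).
3. **Closing**: morphological closing with a 20-voxel disk per axial
   slice, so the marrow space enclosed by the cortical shell is included.
4. **Resampling**: trilinear interpolation of the PET onto the CT grid in
   world coordinates.
5. **SUV conversion and SUVmean**, left and right separately; cohort
   statistics use the side average.

Cohort-level analysis reports Pearson correlations (pairwise deletion,
two-sided p from `t = r·sqrt(n−2)/sqrt(1−r²)`) of uptake against clinical
covariates, paired right-minus-left laterality t-tests, and the design
arithmetic `min_detectable_r(n, power, alpha)` solving the Fisher-z
relation `n = ((z_{1−α/2}+z_power)/atanh r)² + 3` for r.

Because patient imaging data of this kind are not publicly deposited,
validation is built around **digital joint phantoms** (geometric bone
with a cortical shell inside the HU window, PET constructed so the
designed SUV field is recovered exactly) and **synthetic cohorts**
(Gaussian copula with range-truncated normal marginals and a designed,
positive-semi-definite correlation matrix). See the vignette
`vignettes/joint-uptake-methods.Rmd` for the modeling choices and their
limits.

## Worked example

```r
library(jointsuv)

# a digital hip phantom with designed bone SUV 3.73 (NaF)
ph <- make_joint_phantom(phantom_spec("hip", tracer = "NaF", bone_suv = 3.73))
left  <- quantify_joint(ph$ct, ph$pet, ph$meta, ph$landmarks, "hip", "left")
right <- quantify_joint(ph$ct, ph$pet, ph$meta, ph$landmarks, "hip", "right")
print(left)
print(right)
cat("side-averaged SUVmean:", average_sides(left, right), "\n")

# design arithmetic and a headline significance bound
cat("minimal detectable r at n = 18:", round(min_detectable_r(18), 2), "\n")
cat("p-value of r = 0.77 at n = 18:", signif(corr_pvalue(0.77, 18), 3), "\n")

# a synthetic 18-subject cohort with the default designed correlations
cohort <- make_cohort(cohort_spec(n = 18,
                                  correlations = default_correlations(),
                                  sides = TRUE, seed = 1))
rep <- cohort_analysis(cohort)
print(rep)
correlation_matrix(rep, "knee")[1:4, c("variable", "FDG_r", "FDG_p",
                                       "NaF_r", "NaF_p")]
```

Output:

```
<joint_uptake> subject hip left NaF: SUVmean 3.7300 over 7064 voxels
<joint_uptake> subject hip right NaF: SUVmean 3.7300 over 7064 voxels
side-averaged SUVmean: 3.73
minimal detectable r at n = 18: 0.62
p-value of r = 0.77 at n = 18: 0.000186
<cohort_report> 18 subjects, 84 correlation cells, 6 laterality tests
     variable       FDG_r        FDG_p       NaF_r      NaF_p
1         age  0.09047472 7.210708e-01  0.12348994 0.62541803
2      height -0.34169112 1.652003e-01 -0.03577730 0.88791949
3         bmi  0.82790480 2.220187e-05  0.58277236 0.01114449
4 ra_duration -0.15214985 5.467078e-01 -0.04541264 0.85799350
```

The disk-based full pipeline is also scriptable: `run_simulate()` writes
a phantom cohort to a data directory, `run_quantify()` produces
`results.csv` with provenance and a run log, and `run_stats()` writes
correlation and laterality tables plus scatter plots. The same verbs are
exposed on the command line via `inst/cli/jointsuv`
(`Rscript $(Rscript -e 'cat(system.file("cli","jointsuv",package="jointsuv"))') simulate --out data ...`).

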