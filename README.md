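# bonemri

CT-like bone imaging from multi-echo MRI, as a fully simulated and tested
analysis pipeline.

## The problem

Stress fractures of the pars interarticularis (isthmic spondylolysis) are a
common cause of low back pain in adolescent athletes. Conventional MRI often
misses the fracture line, so a CT scan — with its ionizing radiation — is
frequently needed to confirm the diagnosis. Bone-oriented MRI offers a
radiation-free alternative: acquire a multi-echo series with either an
ultrashort echo time (UTE) sequence, whose first echo (TE ≈ 0.1 ms) still
contains signal from short-T2\* cortical bone, or a conventional field echo
(FE) sequence in which bone is a signal void, and post-process the echoes so
bone appears bright on a dark background, as in CT.

`bonemri` implements that post-processing and its quantitative evaluation,
driven by a digital lumbar-spine phantom so every stage is testable without
patient data:

1. **Phantom** — a voxelized slab-and-plate spine-like object (cortical bone
   plate, muscle, marrow core, air) with an optional pars-defect gap of
   configurable width.
2. **Acquisition** — mono-exponential T2\* decay
   `SI = ρ · exp(−TE / T2*)` per tissue, plus complex Gaussian noise taken in
   magnitude (Rician; Rayleigh in air), for 3-echo UTE
   (TE = 0.1, 2.7, 5.3 ms) and FE (TE = 4, 8.6, 13.2 ms) protocols.
3. **CT-like processing** — first-echo inversion `1 / SI₁`, or multi-echo
   averaging then inversion `n / Σᵢ SIᵢ` (with an epsilon clamp on signal
   voids; a linear `max − SI` inversion is available behind a flag).
4. **Metrics** — ROI statistics on bone, muscle and background air;
   `SNR = SI_mean / SI_SD(air)`, `CNR = (SI_mean,1 − SI_mean,2) / SI_SD(air)`;
   slice-to-slice coefficient of variation; defect width as the full width at
   half maximum (FWHM) of a signal profile across the gap.
5. **Statistics** — a balanced two-way factorial ANOVA of sequence
   (UTE vs FE) × processing (first echo vs multi-echo) on each measure, with
   broom-style `tidy()`/`glance()` methods.

Everything tabular is a tibble; results have `autoplot()` methods.

## Worked example

```r
library(bonemri)

spec <- phantom_spec(defect_width = 2.5)        # 64x64x32 @ 1 mm, 2.5 mm gap
cfg  <- pipeline_config(spec, seeds = 101:104)  # four simulated subjects
res  <- run_pipeline(cfg)
res
```

```
<pipeline_result> 16 records (4 subjects)
Mean (+/- SD) values for each sequence and processing
         measure   FE first_echo   FE multi_echo   UTE first_echo
        Bone SNR   0.892 (0.227)   2.71 (0.0978)   0.109 (0.0116)
      Muscle SNR 0.0255 (0.0026) 0.124 (0.00175) 0.0204 (0.00246)
 Bone-Muscle CNR   0.867 (0.225)   2.59 (0.0991) 0.0887 (0.00923)
   UTE multi_echo
    1.06 (0.0595)
 0.0986 (0.00359)
   0.965 (0.0561)

Two-way ANOVA p-values (alpha = 0.05)
         measure sequence processing interaction
        Bone SNR 2.39e-10   5.14e-11    1.93e-05
      Muscle SNR 9.26e-08   1.02e-16    7.20e-06
 Bone-Muscle CNR 2.50e-10   1.00e-10    2.23e-05

Defect FWHM (mm) on multi-echo images
 subject_id sequence     fwhm
     subj01      UTE 2.000014
     subj01       FE 2.246691
     ...
```

Reading the output: each row of the top table is one image-quality measure on
the processed CT-like images, mean (SD) across the four simulated subjects.
Multi-echo processing raises bone–muscle CNR for both sequences (0.089 → 0.97
for UTE-like, 0.87 → 2.59 for FE-like) because echo averaging suppresses the
air-noise SD in the denominator before the inversion amplifies it — the ANOVA
flags that processing effect at p ≈ 1e-10 here. The FWHM table recovers the
2.5 mm gap (2 voxel columns after rounding to the 1 mm grid) to within one
voxel on every subject. Drill in with:

```r
tidy(two_way_anova(res$records, "bone_muscle_cnr", "sequence", "processing"))
autoplot(res$report)
```

A thin command-line wrapper over the same functions ships in
`inst/cli/bonemri` (`simulate`, `process`, `metrics`, `profile`, `anova`,
`run-all`, `fixtures` subcommands).

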