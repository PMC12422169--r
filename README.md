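# osteoload

Inverse determination of the internal loads carried by a plate
osteosynthesis bridging a 3 mm metacarpal shaft osteotomy during
non-weight-bearing rehabilitation exercises — fingertip-to-palm finger
flexion and wrist flexion — and a safety-margin assessment of an adhesive
composite fixation patch against those loads.

The package is aimed at orthopaedic biomechanics researchers who want the
whole displacement-driven pipeline runnable and testable on a desk, with a
synthetic construct and cohort standing in for the cadaveric experiment:

- a parametric bone–plate–screw construct: two hollow-tube fragments
  (cortical shell, trabecular lining, open medullary canal), a 3 mm gap, a
  24.25 × 4.25 mm plate, four bicortical screws at ±5 and ±10 mm;
- a deterministic quadratic-tetrahedral (tet10) mesher with a refinement
  region around the plate and named node sets;
- a small-strain linear-elastic FE solver with rigid screw-tie
  condensation and Dirichlet boundary conditions;
- free-body extraction of the six section loads at a cut plane through the
  plate, with special focus on the out-of-plane bending moment

  `Mz = Σ_i [ r_i × f_i ]_z ,  f_i = Σ_{e ∈ side} (k_e u_e)_i`

  summed over the cut-interface nodes of one side's elements, about the
  plate cross-section centroid (N mm);
- normalized-trajectory processing: travel → `s ∈ [0, 1]`, the
  first-half analysis window for wrist flexion, linear resampling onto the
  reporting grid {0, 0.2, …, 1}, retention of trials 3–5, per-trial maxima;
- the statistics chain: Shapiro–Wilk (report only), Levene's gate, classic
  or Welch ANOVA `F = Σ w_i (m_i − m̄_w)² / (k−1) / [1 + 2(k−2)/(k²−1) Σ (1−w_i/Σw)²/(n_i−1)]`
  with Games–Howell post hoc, and the paired t comparison of the two
  exercises;
- safety factors `capacity / demand` against the adhesive patch's published
  failure moments (lowest 728 N mm, mean 1220 ± 300 N mm) and a flexural
  stress check `σ = M c / I` vs. its 69 MPa flexural strength.

## Worked example

One forward solve of the default construct parametrizes the whole linear
study; the seeded synthetic cohort (5 hands × digits 2–4 × trials 3–5,
with one excluded digit, n = 15/15/12 per exercise) is then pushed through
trajectory processing, statistics and the safety assessment:

```r
library(osteoload)
study <- simulate_study(seed = 42)
print(study)
```

```
Synthetic internal-load study (seed 42)
unit bending moment: 2.482 N mm per degree of flexion

Cohort summary (bending moments, N mm)

Per-digit maxima:
 test digit  n max_mean max_sd degenerate
    1     2 15     9.38  1.026      FALSE
    1     3 15     5.09  0.729      FALSE
    1     4 12     5.21  0.357      FALSE
    2     2 15     5.22  0.900      FALSE
    2     3 15     3.59  1.268      FALSE
    2     4 12     2.50  0.728      FALSE

Pooled maxima per test:
 test  n mean   sd
    1 42 6.66 2.19
    2 42 3.86 1.49

Pooled weighted maxima: test 1 = 6.66, test 2 = 3.86 N mm

Paired exercise comparison: paired t: statistic = 11.542, df = 41, p = 1.854e-14 (significant at 0.05)

Digits comparison, test 1: branch = welch, p = 8.369e-13

Digits comparison, test 2: branch = classic, p = 1.003e-07

Safety factor: 109.3 (capacity 728 N mm [lowest] / demand 6.659 N mm) -> PASS
note: capacity measured in an ovine phalanx four-point-bending model
```

Reading the output: one degree of fragment flexion at the osteotomy loads
the gap-center plate section with 2.48 N mm of out-of-plane bending moment,
so the calibrated fingertip-to-palm peaks (≈ 8.6 N mm in the index digit)
correspond to ≈ 3.5° of flexion. Fingertip-to-palm loads the fixation
roughly twice as hard as wrist flexion (pooled maxima 6.7 vs. 3.9 N mm;
paired p ≪ 0.001), the index digit carries distinctly more than digits 3–4,
and the adhesive patch's weakest published failure moment still exceeds the
pooled demand more than 100-fold.

Lower-level entry points (`mesh_construct()`, `solve_fe()`,
`section_loads()`, `check_convergence()`, `games_howell()`, …) are
documented individually; the methods vignette
(`vignettes/internal-loads-methods.Rmd`) explains the model, the
calibration, the generator's scatter structure and every numerical choice.

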