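# brachyqa

Patient-specific quality assurance (QA) tools for high-dose-rate (HDR)
Ir-192 brachytherapy with a solid plastic phantom.

## What problem this solves

Pretreatment QA of an HDR plan means delivering it into a phantom holding a
radiochromic film and checking that the measured planar dose matches an
independent calculation. Treatment planning systems follow the AAPM TG-43
formalism, which assumes all dose is deposited in **water**; a practical
phantom is made of ABS plastic, which scatters and attenuates differently.
`brachyqa` closes that gap with a radial medium conversion factor and
provides the whole verification chain for medical physicists:

* **TG-43 line-source dose engine** — dwell-time superposition of
  $\dot D(r,\theta) = S_K \Lambda \,
  \frac{G_L(r,\theta)}{G_L(r_0,\theta_0)} g_L(r) F(r,\theta)\, CF(r)$
  onto planar grids 1 cm below the catheter, with
  $G_L = \beta/(L r \sin\theta)$ and tabulated $g_L$, $F$ from a
  source-characterization file.
* **Medium conversion** — $CF(r) = D_\mathrm{ABS}/D_\mathrm{water}$,
  a Monte-Carlo-derived anchor curve (0.88 at 0.5 cm, unity at 2.1 cm,
  1.08 at 6 cm, 1.04 at 8 cm, exactly 1 beyond), applied per dwell
  contribution.
* **Film dosimetry** — netOD calibration
  $D = b\,\mathrm{netOD} + c\,\mathrm{netOD}^n$ per colour channel (red
  below 10 Gy, green above), scan-to-dose conversion, synthetic-scan
  generation.
* **Gamma analysis** — Low et al. gamma index (default 3%/3 mm, global
  normalization, 10% threshold) plus an independent exhaustive-search
  oracle for validating the fast search.
* **Workflow** — the standard single-dwell / elliptical / concave test
  cases, a synthetic measurement generator (rigid shift + multiplicative
  noise), an end-to-end `run_verification()` report, and a thin CLI
  (`inst/cli/brachyqa.R`).

## Worked example

```r
library(brachyqa)

cv <- abs_conversion_curve()
cf_at(cv, c(0.5, 1, 2.1, 6, 8))
#> [1] 0.880 0.932 1.000 1.080 1.040

plan <- make_case("single_dwell", 400)   # 400 cGy water dose at (1 cm, 90 deg)
plan
#> HDR plan: single_dwell_400cGy
#>   S_K = 40700.0 U, source 'mHDR-v2 (synthetic tables)', 1 dwell(s)
#>  position_cm   time_s
#>            0 31.90337

rep <- run_verification(plan, cf = cv,
                        noise_sd_fraction = 0.01, shift = c(1, 0), seed = 7)
rep
#> Dosimetric verification: single_dwell_400cGy
#>   point dose 1 cm below source: water 400.00 / phantom-corrected 372.80 / measured 372.02 cGy
#>   gamma (3%/3 mm, global): water-calc vs measured 100.00%, corrected-calc vs measured 100.00%
#>   verdict: PASS (threshold 95.0% on the corrected calculation)
```

Reading the numbers: the plan delivers 400 cGy in the water formalism at
the reference point 1 cm below the dwell; inside the ABS phantom the same
point receives 400 × CF(1 cm) = 372.80 cGy, and the synthetic "film"
measurement (1% noise, 1 mm registration shift) reads 372.02 cGy. Both the
water-only and the medium-corrected calculations pass the 3%/3 mm gamma
comparison against this measurement; the verification verdict is driven by
the corrected calculation.

The same chain is scriptable from a shell:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "brachyqa.R", package = "brachyqa"))')
Rscript $CLI make-case --case single_dwell --dose 400 --out plan.txt
Rscript $CLI verify --plan plan.txt --out report.txt --artifacts
```

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes, from the installed package, the packaged conversion-factor
values at 6 and 8 cm, the ABS percentage dose at the 1 cm normalization
point, and the phantom-corrected point dose of the 400 cGy single-dwell
plan (via the full planar dose engine), and writes them as JSON.

## Layout

* `R/` — dose engine, source model, medium conversion, film dosimetry,
  gamma analysis, workflow.
* `inst/extdata/` — packaged source characterization (synthetic tables,
  mHDR-v2 geometry) and the ABS/water conversion curve.
* `inst/cli/brachyqa.R` — command-line front end.
* `vignettes/brachyqa-methods.Rmd` — model, assumptions, numerical
  choices, and what the synthetic tests do and do not establish.
* `tests/testthat/` — unit, property and acceptance tests.
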