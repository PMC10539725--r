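# jdeconv — scalar coupling extraction by multiplet structure deconvolution

`jdeconv` determines scalar coupling constants (J, in Hz) from first-order
multiplets in 1D NMR spectra, including the cases that defeat visual
analysis: highly degenerate structures ("dqd" and worse), partially
overlapping multiplets, couplings smaller than the linewidth, partners
with spin above 1/2 (the 1:1:1 triplets of deuterium, 1:1:1:1 quartets of
boron), and mildly second-order "roofed" doublets — from which it also
estimates the coupling partner's chemical shift. It is aimed at
spectroscopists and at metabolomics / natural-product pipelines that need
validated coupling lists rather than a bare "m".

## The method

A multiplet is the convolution of a line shape with one stick pattern
F(J) per coupling; a spin-S partner contributes 2S+1 equal lines spaced J.
Convolution with the alternating-sign inverse series M(J\*) — for spin 1/2
a comb at ±(2k+1)J\*/2 with signs (−1)^k — collapses a splitting exactly
when the trial value J\* matches a true J. The package implements this as
the O(n) side-to-side recursion

    out[i] = in[i] − Σ_{m=1..2S} ρ^m · out[i − m·J*/step]

run from both ends of the region. A quality function (the normalized
scalar product of the two aligned sub-multiplets, or a half-integral
criterion for one-sided analyses) scanned over J\* peaks at the couplings;
the analyzer takes the largest splitting first, deconvolves, and recurses,
then groups degenerate couplings (0.5 Hz tolerance), validates the result
by rebuilding the multiplet from the extracted data (scalar product
≥ 0.99 against the source), and repairs under-counted multiplicities by a
post-analysis degeneracy search. Roofed doublets with amplitude ratio
r = (1 − sin θ)/(1 + sin θ), θ = atan(J/Δδ), yield the partner position
δ_partner = δ_ref + J/tan θ with a propagated error.

## A worked example

A double double doublet with J = 9.9, 6.32 and 4.22 Hz at a 2.7 Hz
linewidth — transitions overlap and the naked eye sees a pseudo-triplet:

```r
library(jdeconv)
s <- synth_multiplet(list(coupling_spec(9.9), coupling_spec(6.32),
                          coupling_spec(4.22)),
                     center_hz = 1200, ls = lineshape(fwhm_hz = 2.7),
                     step_hz = 0.1, width_hz = 70, spectrometer_mhz = 400)
extract_couplings(s)
#> δ 3.000, ddd, J = 9.88, 6.32, 4.22 Hz (score 1.000)
```

The line reads: chemical shift 3.000 ppm, a ddd with the three couplings
recovered within the grid resolution, and a reconstruction that matches
the input with a normalized scalar product of 1.000 (0.99 is the pass
mark; anything below is reported as "m"). The roof-effect closed forms are
available directly:

```r
round(amplitude_ratio(atan(1 / 6.6)), 2)   # amplitude ratio of the tilted doublet
#> 0.74
```

Batch work goes through `run_analysis()` (strategy search over
symmetrization and extremum-choice policies, JSON or text reports) or the
command line:

```sh
Rscript inst/cli/jdeconv.R simulate --out dd.jdx --j 9.9,6.32,4.22 \
        --fwhm 2.7 --step 0.1 --width 70 --center 1200 --mhz 400
Rscript inst/cli/jdeconv.R analyze --input dd.jdx --region 1170:1230
```

Spectra are read from JCAMP-DX (AFFN and SQZ/DIF/DUP tables) or
two-column text; see the vignette in `vignettes/` for the algorithm,
parameter and design details.

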