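---
title: "Multiplet structure deconvolution: model, algorithm and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiplet structure deconvolution: model, algorithm and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(jdeconv)
```

## The convolution model of a multiplet

In a weakly coupled spin system, the multiplet a nucleus shows in a 1D NMR
spectrum is the convolution of several contributions: its resonance
position, the Lorentzian of transverse relaxation, the (often
Gaussian-modelled) B0-inhomogeneity broadening, and one stick pattern
$F(J_i)$ per scalar coupling. A single spin-1/2 partner contributes a pair
of delta functions at $\pm J/2$; a partner of spin $S$ contributes $2S+1$
equal lines spaced $J$ (the 1:1:1 triplet of deuterium, the 1:1:1:1 quartet
of $^{11}$B, ...); $n$ equivalent partners apply their pattern $n$ times,
giving the binomial 1:2:1, 1:3:3:1, ... intensities for spin 1/2. In
`jdeconv` these objects are `lineshape`, `coupling_spec` and
`stick_pattern`; `coupling_pattern()` builds $F$ for a coupling list and
`synth_multiplet()` convolves it with a line shape on a uniform grid,
optionally adding a constant baseline and seeded Gaussian noise.

Patterns are normalized to unit total weight, so the spectrum's integral is
carried by the line shape alone and is invariant under the coupling list.
Sticks closer than $10^{-6}$ Hz are merged by weight addition, which keeps
commensurate coupling sets (degenerate triplets, quartets, ...) free of
near-duplicate lines.

## The inverse series M(J*) and the side-to-side recursion

Deconvolution of a splitting is the convolution with an inverse of $F$.
For a trial splitting $J^*$ and a spin-$S$ partner ($n = 2S+1$ lines),
`m_series()` builds the doubly infinite alternating series $M(J^*)$: a core
of $n$ unit sticks spaced $J^*$, flanked on both sides by repeating blocks
of one stick of weight $-(n-1)$ followed by $n-1$ unit sticks. By
construction the sum of any $n$ consecutive weights vanishes except over
the central window, so $F_S(J) \otimes M_S(J^*) $ collapses to a single
line exactly when $J^* = J$. For spin 1/2 this is the familiar comb at
$\pm(2k+1)J^*/2$ with signs $(-1)^k$. The series is truncated at the
region width; the truncation residue is confined to marginal zones of one
arm ($2S \cdot J^*$) per side.

Because convolution with $M$ telescopes, it is equivalent to a running
cursor that walks the amplitude vector and subtracts, at $2S$ arm distances
$J^*$ behind, the output already accumulated:

$$\mathrm{out}[i] = \mathrm{in}[i] - \sum_{m=1}^{2S} \rho^m\,
\mathrm{out}[i - m\,d], \qquad d = J^*/\mathrm{step}.$$

Each output point costs two reads instead of the $W/J^*$ of the full
convolution. Run left-to-right and right-to-left this yields the two
sub-multiplets $S_L$ and $S_R$; for spin 1/2 and even integer arms their
margin-aligned sum is *numerically identical* to the convolution with the
truncated two-sided $M$, a property the test suite asserts at $10^{-9}$.
For fractional arms the recursion reads its own output by linear
interpolation (nearest-bin reading would quantize the quality curve and
shift its extrema), which makes the two routes differ by interpolation
error only. The right-to-left run is implemented by reversing the vector,
running the same code path, and reversing back.

The recursion is implemented in C++: it is inherently sequential and is
executed roughly a thousand times per quality scan.

## Quality functions and the J* scan

`scan_quality()` measures the degree of simplification as a function of
$J^*$, scanned from half the region width down to a floor (default 1 Hz)
in steps of half the grid spacing:

* **symmetry** — the normalized scalar product of $S_L$ and $S_R$ after
  shifting them one arm onto each other so the two copies of the
  simplified sub-multiplet superpose. The artifact margins (one arm per
  side, where uncancelled residue lands) are chopped off by the alignment
  itself. Values near 1 mark successful simplification.
* **half-integral** — $1 - 2\,\lvert \sum \lvert S_\mathrm{side}\rvert /
  \sum\lvert \mathrm{in}\rvert - 1/2 \rvert$: a successful one-sided
  simplification leaves exactly half the absolute sum. Only one side is
  needed, which is what partially overlapping multiplets require.

Local maxima above a relative prominence (default 0.02) are reported in
scan order and refined by three-point parabolic interpolation. Two classes
of spurious extrema exist and shape the whole strategy: odd fractions
$J/(2n+1)$ of a true coupling produce artifact-free but unsimplified
structures (the reason to aim at the *largest* coupling first and recurse),
and combinations such as $J_1 + J_2$ can score moderately well in richly
degenerate multiplets.

## The recursive analyzer

`extract_couplings()` repeats: scan, accept an extremum, deconvolve at it,
and continue on the simplified multiplet with the scan ceiling lowered to
the accepted splitting. Four safeguards, all part of the package's design,
make the loop robust:

1. **Halving gate.** A genuine spin-$S$ splitting collapses $2S+1$ equal
   lines into one, so the absolute sum must drop to $1/(2S+1)$ of its
   previous value (ratio window 0.5–1.3 after spin scaling). The sums are
   soft-thresholded at twice the point-to-point noise (median absolute
   successive difference), so accumulated noise does not drown the
   criterion late in the recursion. A rejected extremum resumes the scan
   just below it.
2. **Sharpened localization.** Two couplings closer than the linewidth
   share one broad extremum. After the plain scan picks a candidate, a
   narrow window around it is re-scanned on a resolution-enhanced copy
   (negated second derivative of a Gaussian-smoothed copy, $\sigma =$
   fwhm/5); its much narrower extrema split merged candidates. The
   deconvolution itself always runs on the unenhanced data. (A raw
   grid-resolution second derivative is available in `preprocess()`, but
   without smoothing it is unusable at realistic noise levels.)
3. **Degeneracy confirmation and ghost pruning.** Extracted values within
   0.5 Hz are grouped as degenerate; when the grouped values are spread
   wider than the grid, the grouped and ungrouped variants are compared by
   synthetic reconstruction and parsimony wins ties. Couplings below the
   residual linewidth are kept only when the reconstruction is genuinely
   better with them than without them — a noise-born ghost's removal
   leaves the match unchanged. Such couplings are flagged
   "unresolved — use with care" in any case.
4. **Final polish.** Each accepted splitting inherits a small bias from
   the artifacts of the previous steps, so every $J$ is re-fitted on the
   source region by maximizing the synthetic-Lorentzian reconstruction
   match (engaged only when that model credibly fits, score $\ge 0.97$).

Between steps the two sub-multiplets are re-centred and combined according
to `direction_policy`: their average (`both_sum`, default), one side only,
or the cleaner half of each (`best_half`, not default since it can leave a
discontinuity in the middle). Symmetrization after each step averages out
noise and artifacts but is wrong for dispersive (misphased) line shapes,
which is why it is a strategy dimension rather than a constant.

`validate_by_reconstruction()` rebuilds the multiplet from the extracted
data — the final singlet shape with all couplings reintroduced — and
scores the normalized scalar product against the source; 0.99 is the pass
mark. The residual-shape policy is a self-consistency check and cannot see
under-counted multiplicities (their leftover structure hides inside the
residual); the `"lorentzian"` policy instead simulates the multiplet with
a synthetic line whose width is fitted per candidate, and is what
`post_degeneracy_search()` uses to test higher degeneracy levels (raising
by one *and* two, since even and odd multiplicities place their lines on
combs shifted by half a splitting) and to merge near-equal couplings.

`strategy_search()` runs the extraction over a grid of option sets —
symmetrize the input or not, symmetrize each step or not, take the first
extremum above threshold or only within a slack of the scan's best — and
ranks the validated results, ties broken by fewer couplings, then by the
larger smallest $J$. The post-degeneracy search is applied to results that
fail validation or end with unexplained structure.

## Partners with spin above 1/2

With `spin_map = list(list(spin = 3/2))` the first extraction step uses
the general-spin series, turning the 1:1:1:1 borohydride quartet into a
one-step analysis. Left to the spin-1/2 default, the same quartet is
consistently (mis)read as a double doublet whose larger splitting is
exactly twice the smaller — a useful diagnostic that the partner has
higher spin.

## Mild second-order effects

The roof effect tilts a doublet's amplitudes by
$r = (1-\sin\theta)/(1+\sin\theta)$ with $\theta = \arctan(J/\Delta\delta)$
($\Delta\delta$ in Hz). The tilted inverse series scales consecutive
weights by $1/r$ towards the stronger line (artifacts grow on that side),
and $\theta$ is only optimized at trial values that are extrema of the
$\theta = 0$ curve, avoiding a two-variable search (default grid
0–20° in 0.25° steps, both signs; the sign says which side the partner is
on). The partner's shift follows from
$\delta_\mathrm{partner} = \delta_\mathrm{ref} + J/\tan\theta$; the
doublet midpoint $\delta_\mathrm{ref}$ is obtained from the intensity
centroid corrected by $(J/2)\sin\theta$. First-order error propagation
through $\sin\theta = (1-r)/(1+r)$ gives the quoted uncertainty, which
grows as $1/\theta^2$, and estimates outside $3 < \Delta\delta/J < 20$ are
flagged unreliable. On an exact AB system the estimate's error has the
closed form $(D-\Delta\nu)/2 \approx J^2/4\Delta\nu$ — the test suite
checks this identity to $10^{-9}$.

A note on conventions: the tilt angle is defined here so that the closed
form above yields $r = 0.74$ at $\Delta\delta/J = 6.6$, the only
self-consistent reading of the ratio formula, and the symmetry score is
used to fit it.

## Partially overlapping multiplets

When two multiplets overlap over a distance smaller than the largest
coupling of the analysed one, the analysis runs one-sided from the
non-overlapped edge. The half-integral criterion is restricted to the
analysed multiplet's integral share $f$ (which the user supplies from
ordinary integration): the collapsed sub-multiplet must hold $f/2$ of the
region's absolute sum, with the bookkeeping stopped at 80 % of the share so
the zone where the neighbour is being subtracted stays out of the measure.
After the first splitting is removed the walk is truncated where the
running absolute integral reaches $f/2$ of the total; the remaining,
now isolated sub-multiplet is analysed recursively. The result is
validated against the leading quarter (by integral) of the multiplet's
share — clean by assumption — with a synthetic-Lorentzian reconstruction;
failure raises an explicit "overlap too severe" error rather than
fabricating couplings. `overlap_fraction = 1` reduces exactly to the
standard path. Sequential subtraction of more than two overlapping
multiplets is not part of the validated surface.

## What the synthetic generator emulates — and what it does not

`synth_multiplet()` reproduces the features the method is sensitive to:
arbitrary first-order coupling structures for spins 1/2 to 3, Lorentzian /
Gaussian / Voigt / empirical line shapes, zero-order phase error (the
dispersive partner is obtained analytically for the Lorentzian and by FFT
Hilbert transform otherwise), roof tilt, baseline offset and white
Gaussian noise. It does not emulate curved baselines, solvent or spike
artifacts, field-inhomogeneity asymmetry, $t_1$-noise, or the
second-order line *shifts* and extra transitions of strongly coupled
systems. Passing tests on this generator therefore demonstrates the
correctness and the noise behaviour of the algorithm, not its robustness
to every pathology of experimental spectra; the quality thresholds
(`success_threshold`, `validation_threshold`) are the intended handles in
such cases.

The package's recovery suite analyses 200 random multiplets with 1–4
couplings drawn uniformly in 1.5–20 Hz (pairwise gaps above 0.5 Hz, the
degeneracy tolerance), linewidths 0.5–3 Hz, and peak signal-to-noise drawn
uniformly in 50–200, on a 0.1 Hz grid with regions wide enough for the
symmetric window at the largest coupling (2.3 times the largest $J$ plus
ten linewidths, or the pattern span plus margins if larger). Every
coupling must come back within 0.1 Hz with no spurious extras; results
whose synthetic-lineshape validation fails fall back on the strategy
search. These problem sizes keep the whole suite within a few minutes.

## Numerical choices

* Stick merge tolerance $10^{-6}$ Hz; pattern weights sum to 1.
* $J^*$ grid: region width / 2 down to 1 Hz in steps of step/2 (finer than
  the data grid so extrema are not aliased); trial splittings below twice
  the grid step are refused as sub-resolution.
* Fractional arms are read by linear interpolation everywhere.
* $M$ truncated at the region width; symmetry scores computed on the
  margin-aligned overlap, which discards one arm per side.
* Extremum picker: local maxima at relative prominence 0.02 with 3-point
  parabolic refinement; quality curves are oriented so that better
  simplification means a larger score.
* Noise is seeded and the seed recorded in the simulated spectrum.
* ppm increases right-to-left per NMR convention; all internal computation
  is in Hz, conversion happens at the I/O boundary. JCAMP-DX is written as
  uncompressed AFFN (exponent-free, since "E" is ambiguous with the SQZ
  digit +5 inside tables) and read in AFFN, SQZ, DIF and DUP forms, with
  DUP counts as the total number of adjacent equal items.

## Known limitations

* Two couplings separated by roughly a fifth of the linewidth or less are
  at the information limit; the sharpened scan resolves most such pairs,
  but expect occasional merges into a degenerate group near a 0.5 Hz gap
  at 2–3 Hz linewidths.
* The residual-shape validation is blind to under-counted degeneracy; use
  the `"lorentzian"` policy (as the strategy search does) when that
  matters.
* Very wide regions dilute the symmetry criterion with accumulated noise;
  select regions a few couplings wide, as one would visually.
* The overlap path handles two multiplets; deeper pile-ups need the
  (unimplemented) sequential subtraction.
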