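---
title: "Methods: isotopic-envelope deconvolution and uptake kinetics for MALDI HDX"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: isotopic-envelope deconvolution and uptake kinetics for MALDI HDX}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(maldiHDX)
```

# The measurement and the model

An HDX reaction mixture contains, for each peptic fragment, molecules that
have incorporated different numbers of backbone-amide deuteriums. On a
MALDI-TOF instrument each fragment appears as a singly protonated ion whose
isotopic envelope is the superposition of the envelopes of those
subpopulations, each shifted up in mass by one deuterium unit per
incorporated atom. `maldiHDX` models an observed envelope as the
non-negative mixture

$$ y \approx \sum_{k=0}^{N} f_k\, a_k, \qquad f_k \ge 0,\ \sum_k f_k = 1, $$

where $N$ is the number of exchangeable backbone amide hydrogens, $a_k$ is
the theoretical envelope of the species carrying exactly $k$ amide
deuteriums, and $f_k$ is the fraction of molecules in that state — the
composition profile. The two summary statistics derive from the profile:
the average number of exchanged atoms $\sum_k k f_k$ and the average
deuteration ratio $100 \sum_k k f_k / N$ (percent).

Assumptions: singly charged ions only (the MALDI regime; multiply charged
ions are out of scope); 20 standard residues with no modifications; natural
isotopic abundances for C, H, N, O, S; and complete re-equilibration of
side-chain/terminal labile hydrogens with the quench solvent.

## Exchangeable-site bookkeeping

Backbone amides follow the standard counting rule:
$N = L - 1 - \#\{\text{prolines at position} \ge 2\}$ — the N-terminal
residue carries a free amine rather than an amide, and proline has no amide
hydrogen. For angiotensin II (DRVYIHPF) this gives $N = 6$; for the
adenylate kinase fragment 107–117 (FERRIGQPTLL), $N = 9$.

Fast-exchanging side-chain and terminal hydrogens are counted from a fixed
per-residue table (neutral forms: Arg 4, Lys 2, His 1, Asp 1, Glu 1, Ser 1,
Thr 1, Asn 2, Gln 2, Tyr 1, Trp 1, Cys 1; others 0) plus two for the
N-terminal amine and one for the C-terminal carboxyl. The exact labile
table is not standardized across software; these are the counts in common
HDX use, and because every mixture component is convolved with the *same*
side-chain distribution, a miscount of one labile site biases all
components identically and cancels in the profile to first order. Cysteine
is counted as a free thiol; modified residues are not supported.

## Theoretical envelopes

The natural-abundance envelope is computed by iterative convolution of
elemental isotope patterns (IUPAC masses and representative abundances,
hard-coded in one constants table), using exponentiation-by-squaring over
atom counts. Isotopologues are aggregated by neutron count into
nominal-mass bins; each bin's reported m/z is the abundance-weighted mean
mass of its members. This aggregation is exact in total probability and
mass, and reflects what a reflectron TOF actually resolves: the fine
structure of ¹³C vs ¹⁵N vs ²H substitutions inside one nominal bin is never
separated, and the ±0.3 Da quantification window spans the whole bin. The
engine is verified in the test suite against exhaustive isotopologue
enumeration for small formulas (agreement to 1e−10 in abundance, 1e−6 Da in
bin mass).

The component-$k$ envelope is built from the all-protium base envelope of
the ion by

1. computing the base on the elemental formula with the $n_{side}$ labile
   hydrogens removed from the natural-abundance convolution and re-added as
   fixed protium mass (so natural deuterium is not double counted on sites
   whose occupancy is modeled explicitly),
2. a rigid shift by $k \cdot \Delta m$, with $\Delta m = m(\mathrm{D}) -
   m(\mathrm{H}) = 1.006277$ Da (the exact isotope mass difference; an
   averaged isotope spacing would misplace high-$k$ components by several
   mDa per deuterium), and
3. convolution with a Binomial($n_{side}$, $p_D$) side-chain occupancy at
   the quench-solvent deuterium fraction $p_D$ (default 0.9, the H:D = 1:9
   exchange condition). Binomial occupancy is the standard physical model
   for sites that fully re-equilibrate with solvent before measurement;
   because it is common to all $k$, the fit "removes" side-chain deuterium
   computationally.

The ionizing proton is added once as a fixed, non-exchanging mass of
1.007276 Da. All $N+1$ envelopes are aligned on the union of their
nominal-mass bins (zero-padded), and the shared grid centers are the
abundance-weighted means across components; within-bin centers of different
components differ by at most a few mDa, far below the window half-width.

## Peak quantification

Observed spectra are two-column ASCII (m/z, intensity; `#` comments;
whitespace or comma delimited), the common vendor export. Each theoretical
peak is quantified as the trapezoidal integral of the intensity over
[center − h, center + h] with linear interpolation at the window edges;
the default half-width h = 0.3 Da is the conventional "theoretical mass
± 0.3 Da" rule and cannot overlap at the ~1 Da isotopic spacing. Trapezoidal
integration with edge interpolation is exact for piecewise-linear signals,
additive over sub-windows, and invariant to resampling density — so profile
data and centroided sticks are handled by the same contract. No baseline is
subtracted by default. Peptides whose isotopic peaks are not resolved
(linear-mode data) are summarized by the intensity-weighted average mass
over a window instead, and feed only the kinetics layer.

## The mixture fit

The observed area vector is scaled to unit sum (removing the arbitrary
intensity scale) and the profile solved by Lawson–Hanson non-negative least
squares (`pracma::lsqnonneg`), then renormalized to unit sum.
Non-negativity is essential: the components are heavily overlapping
(adjacent columns differ by one ~1 Da shift), and unconstrained least
squares produces oscillating signed weights with no physical meaning. Exact
zeros in reported profiles arise naturally from the NNLS active set; no
sparsity penalty is used. A numerically rank-deficient basis (possible only
for degenerate inputs, e.g. a one-bin grid) is still solved but the result
is flagged `degenerate`. An all-zero observation — the fragment is absent
from the spectrum — is an error, which batch processing logs per pair and
skips without aborting.

## Uptake kinetics

Time courses of the deuteration ratio are fitted with

$$ D(t) = D_\infty - A e^{-k_{obs} t}, $$

the single-exponential form consistent with its parameter meanings:
$D_\infty$ the asymptotic uptake, $A$ the amplitude of the fraction
exchanging on the observable time scale, $k_{obs}$ the apparent first-order
rate constant averaging the individual amide rates, and the derived
zero-time uptake $D_0 = D_\infty - A$, governed by sites that exchange
faster than the first time point. The fit is bounded
($0 \le D_\infty \le 100$, $A \ge 0$, $k_{obs} \ge 0$) Levenberg–Marquardt
(`minpack.lm::nls.lm`, ftol = ptol = 1e−15), weighted by $1/sd^2$ when
replicate SDs are given, with initialization $D_\infty = \max D$,
$A = \max D - \min D$, $k = 1/\mathrm{median}(t)$ plus ten multiplicatively
jittered restarts drawn from a private, fixed-seed RNG stream — the fit is
deterministic and never perturbs the caller's random seed; the lowest
weighted RSS wins. At least four time points are required for the three
parameters. Two degenerate regimes are handled explicitly: an exactly flat
series short-circuits to $D_\infty = \bar D$, $A = 0$; and a converged
amplitude below 1e−3 percentage points is reported as $A = 0$ with
$k_{obs}$ undefined, since the rate is unidentifiable when nothing is seen
to exchange. Standard errors come from $\hat\sigma^2 (J^\top J)^{-1}$ at
the optimum.

Region-specific uptake between overlapping peptic fragments uses the
amide-weighted difference
$D_{region} = (D_p n_p - D_c n_c)/(n_p - n_c)$ on matching time grids, with
SDs propagated in quadrature. Noise can push derived points slightly past
the physical 0–100% bounds; such points are flagged, not clamped
(clamping would bias subsequent fits), and the container type tolerates
[−5, 105].

# The simulator: what it emulates and what it does not

`renderSpectrum` draws each nominal-mass peak of each mixture component as
a Gaussian of FWHM = m/z / resolution (default resolution 10 000,
reflectron-TOF scale), samples at 0.01 Da steps, and adds seeded Gaussian
noise scaled to the maximum signal, clipped at zero intensity.
`renderTimeSeries` evaluates the exponential model at the conventional
1, 3, 5, 7, 10, 20, 40 min sampling and adds seeded noise. Defaults
(solvent D fraction 0.9, resolution 10 000, seven time points, 1% kinetic
noise in the property tests) mirror the measurement conditions the method
targets.

The simulator is deliberately idealized: Gaussian, isotope-independent peak
shapes; no matrix cluster peaks, chemical background, detector saturation,
baseline drift or m/z miscalibration; noise that is white and additive.
Passing round-trip tests therefore demonstrates that the deconvolution
inverts its own forward model correctly and degrades gracefully under
additive noise — it does not certify accuracy against instrument artifacts
(calibration error in particular shifts windows off the true peaks and must
be handled upstream).

# Tested problem sizes and observed accuracy

The test suite exercises: exact recovery of noiseless mixtures
(≤ 1e−6 per fraction); recovery of a bimodal 6-amide composition
(93.7%/6.3%) from a rendered spectrum within 0.5 percentage points at zero
noise; mean absolute error of the average exchanged-atom count below 0.1
atoms over 100 random profiles at signal-to-noise 50; noiseless kinetics
recovery to 1e−4 relative across realistic parameter sets
($D_\infty$ 66–93%, $A$ 3–21%, $k_{obs}$ 0.07–0.42 min⁻¹) and median
$|\Delta D_\infty| < 1$ percentage point over 200 replicates at 1% noise;
and envelope-engine agreement with exhaustive enumeration for formulas of
up to 8 atoms. These sizes keep the full suite in the tens of seconds while
covering every code path; all quantitative claims above are computed by the
suite itself.

# Known limitations

* Singly charged, unmodified peptides of the 20 standard residues only.
* No bimodality significance testing and no automatic assignment of
  populations to conformers; multimodal profiles are reported as fitted.
* No smoothing, recalibration, or vendor binary format support; input is
  ASCII profile or stick data.
* The labile-hydrogen side-chain table follows common HDX practice; other
  software may count individual residues differently (see above for why
  this largely cancels).
* Back-exchange during workup is not corrected beyond the side-chain
  model; it appears as a uniform depression of the deuteration ratio.
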