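---
title: "Pixel-size calibration from polycrystalline diffraction rings: models and methods"
author: "magcal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pixel-size calibration from polycrystalline diffraction rings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(magcal)
```

## The measurement model

One detector pixel corresponds to a specimen-plane distance $P$ (Å), the
magnified pixel size, set by the projection-lens system and typically known
only nominally. A crystalline support film provides an absolute internal
reference: crystallites diffract at their lattice spacing $d$, and in the
power spectrum of an $L$-wide micrograph the corresponding ring sits at
radius $r$ pixels with

$$ q \;=\; \frac{1}{d} \;=\; \frac{r}{L\,P} \qquad\Longrightarrow\qquad
   P \;=\; \frac{r\,d}{L}. $$

Everything in `calibrate()` serves the accurate measurement of $r$, and the
crystallography module serves the accurate knowledge of $d$.

### Lattice constants and temperature

For fcc gold $d_{hkl} = a/\sqrt{h^2+k^2+l^2}$. The lattice constant
contracts on cooling; we use the linear law
$a(T) = 4.0611\,\text{Å} + 5.67075\times10^{-5}\,\text{Å/K}\; T$,
valid down to 43 K. Below that the contraction levels off approaching
absolute zero, and the constant is held at the measured 13 K value,
4.0636 Å. The clamp is a deliberate hard switch — the smooth roll-off is
not parametrised — leaving a documented discontinuity of order
$10^{-4}$ Å at 43 K, i.e. $\sim 2.5\times10^{-5}$ relative, far below the
method's precision. At the common cryo-stage temperature of 81 K the (111)
spacing is `r round(dSpacing(reflectionFor("gold_fcc", c(1,1,1), 81)), 4)` Å.

hcp gold ($a = 2.88$ Å, $c = 4.96$ Å, three-index convention
$1/d^2 = \tfrac43(h^2{+}hk{+}k^2)/a^2 + l^2/c^2$) carries no thermal model;
none is established for the metastable phase. Graphitized carbon is
parametrised as a cubic lattice with $a = 5.92$ Å so that its (111) spacing
reproduces the 3.42 Å calibration peak; it was only characterised at 81 K,
so temperature is ignored. The catalogue is a plain CSV
(`inst/extdata/materials.csv`) users can extend.

Negative Miller indices are accepted throughout. Note that under the
three-index hexagonal form the basal indices matter:
$(1,\bar1,\bar1)$ and $(\bar1,1,1)$ coincide (full sign flip), but
$(\bar1,\bar1,1)$ is a different reflection.

## Measuring the ring radius

### Power spectra

`powerSpectrum()` takes $|\mathrm{FFT}|^2$ of the mean-subtracted image,
DC-centred (bin $L/2+1$ for even $L$; radii are measured from that bin
centre). The whole frame is transformed rather than periodogram tiles:
whole-frame transforms maximise the ring-radius resolution, which is the
quantity of interest. Apodization is off by default — edge tapers broaden
Bragg peaks — and exposed as a flag for images with severe edge
discontinuities. Zero-padding is available but not needed for sub-pixel
work, since interpolation happens in the radial domain.

### Noise whitening

The spectral background falls steeply with frequency (detector MTF plus
low-angle scattering). On a falling background the apparent maximum of a
finite-width peak is displaced toward the centre; for weak rings the bias
reaches pixels, i.e. tenths of a percent in $P$. `whiten()` therefore fits
a degree-5 polynomial to log mean intensity versus radius — with the known
Bragg annuli excluded — exponentiates, and divides. The model is
parameter-light and exact for exponential-type envelopes (log-linear);
degree 5 absorbs the gentle curvature of real envelopes. Radii below 2 px
and above 97.5% of Nyquist are excluded as unusable; if exclusion windows
cover more than 80% of usable annuli the fit refuses.

Whitening by *division* slightly tilts the line shape the other way
(multiplying a symmetric peak by a rising $1/B(r)$), so the whitened
spectrum carries its background model along, and the wedge measurement
below undoes the tilt.

### Peak detection

`findRingPeak()` searches the annulus $r_\mathrm{exp}(1\pm t)$,
$r_\mathrm{exp} = L P_\mathrm{nom}/d$, default tolerance $t = 0.05$: wide
enough for a 2% magnification error, narrow enough that the hcp gold (002)
ring 5.5% away falls outside. It takes the most prominent *interior local
maximum* — the raw argmax could be the shoulder of a neighbouring ring
leaking over the window edge — interpolates it with a 3-point parabola, and
requires the height over the flanking annuli (baseline: median; scatter:
MAD of the half-window bands either side) to exceed `minProminence` (5)
scatters. Failing that, the micrograph is rejected with a reason, never
silently used. Ties between equal maxima resolve to the larger radius (the
fcc ring is the outer of the gold pair).

### Azimuthal wedges and the ellipse

Anisotropic magnification turns the ring into an ellipse (fractions of a
percent in practice, but resolution-limiting). `azimuthalPeaks()` measures
the radius in 36 wedges (10°). Detection per wedge uses the same
local-maximum-plus-prominence rule; the sub-pixel position, however, uses
an iteratively recentred, background-subtracted radial power **centroid**
rather than a parabolic argmax. The reason is speckle: each wedge contains
a handful of crystallite reflections whose complex amplitudes interfere,
so the wedge profile is a jagged superposition and its argmax scatters by
$\sim$1.5 px between seeds; the centroid averages the speckle to
$\sim$0.4 px. Two measure corrections keep the centroid unbiased: weights
are divided by $r$ (annulus area grows $\propto r$) and multiplied back by
the whitening background model (undoing the division tilt). Four
recentring iterations suffice; the window equals the search annulus.

Wedges without a significant peak are dropped; fewer than 2/3 surviving
raises an incomplete-ring error, since anisotropy cannot be measured from a
partial ring. `fitEllipse()` then fits the centred conic
$Ax^2 + Bxy + Cy^2 = 1$ by linear least squares — three parameters, centre
fixed at DC because Friedel symmetry makes diffraction rings
centro-symmetric (a free-centre fit exists as a diagnostic only). The
scalar pixel size uses the geometric-mean radius
$\sqrt{ab}$, which preserves area scaling under anisotropy; per-axis pixel
sizes and the anisotropy $100(a-b)/\bar r$ are reported. With radial noise
$\sigma$ on $n$ wedge radii the spurious anisotropy of a true circle is
Rayleigh-distributed with scale $2\sigma\sqrt{2/n}/r$ — about 0.09% mean at
$\sigma = 0.3$ px, $r = 200$, $n = 36$ — a positivity bias worth keeping in
mind when interpreting small reported anisotropies.

### Aggregation and the mixed-lattice flag

Per-micrograph estimates are combined with an unweighted mean; the standard
deviation $\sigma$ and standard error $\sigma/\sqrt n$ are reported
(prominence weighting is a config option; equal weighting matches how such
tables are usually reported). An accumulated-spectrum mode (average all
spectra, fit once) exists for weak-signal datasets.

Gold foils can contain hcp domains whose (002) ring at 2.48 Å would be
mis-read as the fcc (111) ring with a >5% pixel-size error. For gold,
`calibrate()` also probes the hcp annulus: a micrograph is flagged when the
hcp-position peak is stronger than the expected-reflection peak **and**
lies more than half the expected fcc–hcp separation from it. The second
condition matters: the two search annuli overlap, so with a mis-set nominal
pixel size both windows can latch onto the same physical ring, which is no
evidence of hcp gold. Flagged micrographs stay in the report with their
flag; they are never silently recalibrated to the other spacing.

## The Cs-refinement estimator

Aberration refinement balances spherical aberration against defocus to
minimise CTF error. With the standard phase
$\chi(q) = \pi\lambda\Delta z\,q^2 + \tfrac{\pi}{2}\lambda^3 C_s q^4$ and
$\mathrm{CTF} = \sqrt{1-W^2}\sin\chi - W\cos\chi$, a fractional pixel-size
error $\epsilon$ rescales $q$ by $(1{+}\epsilon)$; defocus (a $q^2$ term)
can absorb it only at low frequency, and the residual is soaked up by the
$q^4$ term as an *apparent* Cs shift. Refinement reports that shift as the
primary-spherical Zernike coefficient $Z_{40}$ of the normalised polynomial
$6\rho^4 - 6\rho^2 + 1$, $\rho = q/q_\mathrm{max}$ (the lower-order parts
cancel against lower even coefficients). Matching $q^4$ phase coefficients
gives

$$ \Delta C_s = \frac{12\,Z_{40}}{\pi \lambda^3 q_\mathrm{max}^4},
   \qquad
   P_\mathrm{true} = P_\mathrm{nom}
   \left(\frac{C_s^\mathrm{true}}{C_s^\mathrm{apparent}}\right)^{1/4}. $$

The normalisation radius $q_\mathrm{max}$ is convention-dependent upstream;
it defaults to the Nyquist frequency $1/(2P_\mathrm{nom})$ of the optics
group and is exposed as a knob. Validation is by round-trip
self-consistency (inject $\Delta C_s$, recover the pixel error to
$10^{-10}$), not by reproducing any particular external program's
convention. `ctfErrorCurve()` visualises the compensation: with defocus
refitted (a dense grid scan brackets the oscillatory RMS objective before
local refinement), the CTF error is near zero at low $q$ and grows with
$q$, for pixel errors of 1–5%.

Units follow microscopy convention at the interface — kV, mm, µm, Å,
underfocus negative — with all internal computation in Å and radians; the
conversions are tested explicitly.

## The synthetic scene generator

`generateMicrograph()` emulates the features of a foil image that the
estimators consume, and only those:

- crystallites are nearest-seed (Voronoi) regions of a seeded uniform point
  set; each carries an additive cosine fringe at one configured spacing
  with random orientation and phase. Cosines reproduce Bragg-peak positions
  exactly, which is all the estimators use — there is no dynamical
  diffraction, grain-boundary, bending or multiple-scattering contrast;
- a background field of coloured Gaussian noise with an exponentially
  decaying spectral envelope (decay length 100 px, amplitude 0.15 of the
  mean) stands in for detector MTF and low-angle scattering;
- counting noise is Poisson with 50 counts per pixel by default, a typical
  integrated exposure; Gaussian and noiseless modes exist;
- anisotropic magnification is applied as an exact analytic affine of the
  scene coordinates — area-preserving factors $\sqrt s$, $1/\sqrt s$ along
  the stretch axes — so the configured `truePixelSize` remains the
  geometric-mean ground truth and no raster interpolation artefacts enter;
- fringe periods below 2 px are refused (aliasing is a separate concern,
  off by default: high-pixel-size regimes would be generated at 2×
  resolution and decimated without low-pass).

`generateDataset()` writes MRC2014 files whose headers deliberately carry a
*nominal* pixel size (optionally a decoy, e.g. 0.669 Å against a 0.6484 Å
truth, emulating a mis-set microscope) and a JSON sidecar holding the
truth; the calibration code never reads the sidecar, which a test enforces
by deleting it.

Passing tests on these scenes demonstrates correct geometry, noise
handling and statistical behaviour of the estimators; they do not
demonstrate robustness to foil bending, crystalline texture, drift or beam
damage, which real data can exhibit.

## Problem sizes, defaults and numerical choices

The default study conditions are 1024² micrographs with 200 crystallites,
fringe contrast 0.1, Poisson noise at 50 counts, fcc gold (111) at 81 K,
truth 0.6484 Å; ten micrographs per dataset (at least ten is the sensible
recommendation for real work too). At these sizes one micrograph generates
in ~4 s and calibrates in ~2 s; unit tests mostly use 512²/80-crystallite
scenes. The per-micrograph error at default noise is dominated by
crystallite-spot speckle, not counting noise; it shrinks with the number of
reflections per wedge and with $\sqrt n$ over micrographs.

Other choices worth recording: ring searches need at least 3 annulus bins
and an interior maximum; degenerate ellipse inputs (points spanning <240°
of azimuth, <8 points, non-elliptical conics) raise errors rather than
returning garbage; the material catalogue validates positivity and crystal
system; blank or featureless micrographs are rejected per file with the
reason in the report; identical seeds produce bitwise-identical synthetic
files.

## Known limitations

- The whitening background is radially symmetric; strongly astigmatic
  envelopes are not modelled (they mainly affect peak *height*, not the
  centroid position, per wedge).
- The mixed-lattice check needs the two rings resolved: at small transform
  sizes (≲512 px at gold spacings) the fcc and hcp rings blur together and
  neither a reliable flag nor an unbiased measurement is possible.
- The Cs-refinement estimator interprets upstream aberration output; it
  does not perform aberration refinement, and its absolute scale depends on
  the upstream Zernike normalisation through $q_\mathrm{max}$.
- Aggregation assumes per-micrograph independence; beam-induced
  magnification drift within a session would appear as excess $\sigma$, not
  as a trend.
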