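---
title: "Opponent-channel modelling and grey-card simulation for stomatopod colour vision"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Opponent-channel modelling and grey-card simulation for stomatopod colour vision}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stomaspec)
```

## The scientific problem

Stomatopods (mantis shrimps) sample colour with up to 12 photoreceptor
classes housed in four specialised ommatidial rows of the eye's midband.
Two processing schemes have been proposed for this unusually polychromatic
retina. Under the *multi-dichromatic* (opponent) scheme, each midband row
acts as an independent two-receptor colour channel: the distal and proximal
tiers of its R1–R7 rhabdom feed an interneuron that compares their signals.
Under the *binning* (barcode) scheme, colour is encoded by the activation
pattern across all 12 channels, dominated by whichever channel responds most
strongly, with no fine within-row comparison.

The von Frisch grey-card paradigm separates these hypotheses behaviourally:
an animal that can pick a trained colour out of a series of greys of varying
brightness — especially under coloured illumination that flattens the
spectral differences — must be comparing receptor outputs, because intensity
alone carries no usable signal. `stomaspec` implements the computational
side of that argument: the quantum-catch and opponent-contrast model, its
binning competitor, a synthetic spectral world standing in for the
unpublished measured spectra, a simulator of the staged three-choice
experiment, and the choice statistics used to analyse it.

## The model

For a receptor with spectral sensitivity $S_\lambda$, a stimulus with
reflectance $R_\lambda$ and an illuminant with photon irradiance
$I_\lambda$, the quantum catch is

$$Q = \int S_\lambda\, R_\lambda\, I_\lambda \, d\lambda,$$

evaluated by the trapezoid rule on a common 300–750 nm, 1 nm session grid
(the species' stated sensitivity span). Receptor potential is approximated
by the natural log of the catch, so the opponent output of row $n$ viewing
stimulus $X$ — the *activity profile* — is

$$A_n^X = \ln Q_{\mathrm{distal},n}^X - \ln Q_{\mathrm{proximal},n}^X,$$

and the *contrast difference* between stimuli $X$ and $Y$ seen under the
same illuminant is

$$\mathrm{CD}_n = A_n^X - A_n^Y.$$

Three consequences follow immediately and are enforced as tests. First,
scaling the illuminant by any constant cancels in the log-ratio, so
intensity is invisible to every activity profile and every CD — the formal
content of the grey-card logic. Second, two spectrally flat greys differing
only in optical density differ by a wavelength-independent factor, which
likewise cancels: flat greys are exact metamers (CD $= 0$ in every row, and
identical binning patterns). Only spectrally structured reflectance
produces contrast. Third, CD is antisymmetric in $X$ and $Y$.

The binning readout is the channel-ordered catch vector rescaled to unit
maximum; two patterns are called discriminable when their maximum absolute
channelwise difference exceeds a tolerance (default 0.1). It shares the
intensity-invariance and grey-metamer properties, which is why the paradigm
cannot be solved by either readout through brightness alone.

### Row activation

Narrowband tents can drive every photon a row's receptors would absorb to
numerically nothing. A row whose opponent channels catch essentially no
light still has a formally defined log-ratio, but the animal cannot use it.
We therefore gate contrasts by *row activation*: a row counts as active only
when both of its opponent channels' normalised catches (relative to the
experiment's reference entry, channel R2P viewing the ND 0.15 grey under
natural daylight) exceed a threshold, default 0.05. The threshold is a
modelling choice — the original analysis marks such rows qualitatively
("not activated") without stating a criterion — and is exposed as a
parameter. Catches below $10^{-12}$ of the reference are treated as
undefined rather than producing $-\infty$ in the log.

## The synthetic world

None of the measured spectra (site irradiance, filter transmittances,
stimulus reflectances) or intracellular sensitivities are published as
tables, so the package states a synthetic world once and holds it fixed:

* **Daylight**: a log-normal hump peaking at 490 nm with log-width 0.28 —
  smooth, strictly positive, broad, blue-green peaked, as appropriate for
  shallow reef water. Unit peak; the intensity scale is irrelevant by the
  invariance above.
* **Filters**: band-pass transmittances built from logistic edges (edge
  width 10 nm; ≥ 0.9 deep inside the passband, ≤ 0.01 three widths
  outside), at the stated passbands — stimulus filters blue 360–550 nm,
  green 500–560 nm, red > 610 nm; illumination tents blue 360–590 nm,
  green 450–600 nm, red > 590 nm. Double tents square the single-tent
  transmittance (Beer–Lambert stacking).
* **Neutral densities**: flat transmittance $10^{-\mathrm{OD}}$ for OD
  0.15/0.3/0.6/0.9, with an optional logistic leak above 680 nm (ceiling
  0.7) reproducing the real gels' far-red failure.
* **Stimuli**: a flat white base of reflectance 0.9 behind the stimulus
  filter (colours) or ND filter (greys).

### The retina placeholder

The true sensitivities exist only as figures, so `default_retina_config()`
ships a **non-authoritative** λmax table built from A1 Govardovskii-type
α-band templates: R8 cells at 315/330/340/380 nm, and R1–R7 opponent pairs
row 1 = 400/440, row 4 = 470/550, row 2 = 560/630, row 3 = 630/690 nm. The
arrangement follows the reported qualitative structure — rows 1 and 4
sample short/middle wavelengths and fall silent under a red tent, row 2
spans the middle/long range, row 3 is far-red only and falls silent under
blue and green tents — with distal below proximal in every row, spanning
roughly 400–700 nm as in gonodactyloid stomatopods. With these choices the
model reproduces the contrast pattern that explains the behavioural
results: under its own tent the blue target's largest active-row |CD|
against any grey stays below the 0.5 "high-contrast" mark (about 0.46),
while the green and red targets each retain at least one active row above
0.5. Users wanting species fidelity should supply digitised sensitivity
curves via `sensitivity_file`; every downstream computation is agnostic to
the source.

Real stomatopod sensitivities are considerably narrower than α-band
templates (serial tier filtering, which this package deliberately does not
model), so template-based rows overlap more than the animal's. One visible
consequence: row 3's template shoulder keeps it weakly active under the
green tent here, where the animal's row 3 is described as silent. The
high-CD structure above does not depend on this.

## The simulated experiment

The chooser is a Luce/softmax rule on similarity scores. An animal's
memory of its target is the target's activity profile under the natural
training light; a presented stimulus's score is minus the largest absolute
per-row difference between its profile under the test illumination and
that memory, over the stimulus's active rows. This models memory without
assuming colour constancy. The softmax sensitivity defaults to
$\beta = 2\ln 6 \approx 3.58$, a calibration constant (not a measured
value) chosen so that a stimulus set whose two distractors sit one row of
$|\mathrm{CD}| = 0.5$ from the target is answered correctly 75% of the
time, the plateau seen in well-trained animals. Lapses (default 0.02) make
a uniform choice; no-choice events (default 0.05) model the five-minute
timeout and never enter success-rate denominators. If every row is
inactive for some presented stimulus, the chromatic signal is lost and the
whole choice collapses to a uniform guess.

One stated consequence of this calibration: because the blue target's
active-row contrast under the blue tent (≈ 0.46) sits just below 0.5, the
simulated blue group performs at roughly 70% there — degraded relative to
its distractor-rich conditions but far above the animals' observed
collapse to chance. The simulator demonstrates the *direction* of the
contrast explanation, not the animals' exact rates, which likely involve
steeper psychometrics or the innate blue-avoidance the original study
discusses and this package deliberately leaves unmodelled.

Stage progression follows the protocol: priming promotes at an 80%
participation rate over the last five consecutive trials and removes below
50% overall; training (three natural-light trials a day, evaluated from
nine recorded choices) promotes above 80% success over the last six
consecutive trials, removes below 30% overall, and continues in between;
testing runs three trials a day — all natural on day one, then one natural
and two coloured per day in random order — with a flagged reinforcement
trial after every six testing trials, excluded from every statistic.
Individuals whose natural-light testing success is not strictly above 50%
are excluded from analysis. The five-trial priming window follows the
protocol text where a figure caption instead says five consecutive trials
of 80% *success* for training; the window lengths are configurable and the
discrepancy is noted here once.

Scheduling is pseudo-randomised under the stated constraints (no target
position and no distractor combination more than twice consecutively, six
OD combinations 0.15/0.3, 0.15/0.6, 0.15/0.9, 0.3/0.6, 0.3/0.9, 0.6/0.9).
All randomness flows from one master seed with per-individual substreams,
so a dataset is reproducible from design + seed alone.

## The statistics

Success rates are percentages of correct first choices among
non-reinforcement trials with a recorded choice, reported to two decimals
with half-up rounding; empty cells are reported as absent, never as 0%.
Discrimination against chance uses a Pearson goodness-of-fit test of
(correct, incorrect) counts against the (1/3, 2/3) three-choice
expectation, one degree of freedom, no continuity correction — the
expected-count construction stated in the protocol. We note, without
reverse-engineering it, that the printed p-value for the blue group's 8/20
under blue illumination (0.3291) does not match this Pearson statistic
(p ≈ 0.53); the original exact variant is unknown, and this package
reports the Pearson form consistently. The choice regression is a binomial
logit mixed model (delegated to `lme4::glmer()` behind the package
interface) with fixed effects for illumination condition, distractor
combination and choice position, and a random intercept per individual;
sex is accepted as an optional grouping but excluded from default models,
mirroring the original analysis. Non-convergence and suspected complete
separation are flagged, never silently reported.

## What a green test establishes

The test suite verifies the analytic invariants exactly (metamerism,
intensity invariance, antisymmetry, ND stacking, trapezoid accuracy
against a 100× finer Riemann oracle), the printed-count arithmetic, the
null chooser's 1/3 calibration and the chi-square test's size, the
qualitative high-CD structure under coloured tents, and parameter recovery
of the mixed model on data simulated from its own generative form. It does
*not* establish that the synthetic spectra or the placeholder retina match
the animal: measured spectra, narrow real sensitivities, innate colour
preferences, learning dynamics and receptor noise are all outside this
package's stated world.

## Worked example

```{r example, eval = FALSE}
world <- grey_card_world()
design <- experiment_design(groups = c(blue = 8, green = 8, red = 8))
trials <- simulate_experiment(design, chooser_params(), seed = 1,
                              world = world)
report <- summarize_experiment(trials)
report$group_summaries
report$inclusion_ledger
```
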