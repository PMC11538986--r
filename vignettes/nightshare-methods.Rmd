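---
title: "Night and day: methods behind the nightshare pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Night and day: methods behind the nightshare pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nightshare)
options(nightshare.quiet = TRUE)
```

## The problem

Groups of social primates such as olive baboons sleep at a small number of
discrete refuges -- cliff faces and tree groves -- and occasionally two
groups end up at the same refuge on the same night. `nightshare` implements
a complete analysis chain for asking what such sharing does to the animals:
whether neighbouring groups attract or avoid one another by day, at what
distance they begin to respond to each other, whether their sleeping-site
choices are coordinated, whether days that follow a shared night look
different from ordinary days, and what sharing a site costs in sleep. The
inputs are the two data streams a modern tracking collar produces: GPS
fixes at regular (nominally 15-min) intervals and short tri-axial
accelerometer bursts (about 3 s per minute at ~10.5 Hz per axis).

Because the questions are about *dependence between trajectories*, almost
every inference in the package is phrased against a day-shift permutation
null rather than a parametric model.

## Preprocessing

Raw fixes are snapped to a common global grid (nearest grid point within
half an interval), gaps of up to `max_gap` = 4 intervals are linearly
interpolated, and longer gaps are left missing. Two artefact filters
follow:

* **Spike correction.** A fix is treated as anomalous when both legs
  around it imply speeds above 3 m/s while its neighbours sit within one
  interval's travel of each other -- the out-and-back signature of a bad
  fix. We deliberately use this pattern rule rather than a pure speed
  filter, which would also delete genuine rapid flights. Spikes are
  replaced by the neighbour midpoint.
* **Jitter removal.** While a group occupies its sleeping site the collar
  is essentially stationary and the scatter in its fixes is GPS noise.
  Within the site-occupancy window (return to departure; the pipeline
  exposes the window as a parameter) fixes within 20 m of the night's
  median location snap to that median. This matters downstream: without
  it, the sub-metre random jitter at a shared site produces hundreds of
  spurious "movement" headings at near-zero intergroup distances, which
  would contaminate the lowest distance bins of the response-radius
  analysis with pure noise.

Every point carries a provenance flag (`observed`, `interpolated`,
`corrected`, `missing`), and the count of observed points can only
decrease through the chain.

When a group carries more than one collar, one member represents the group
at each timestamp; where members overlap, the member with the longest
total data duration wins. All coordinates are planar metres (lon/lat
inputs are projected with a local tangent-plane projection centred on the
data -- adequate over the tens of kilometres a study population spans, and
chosen because every threshold in the pipeline is metric).

## Sleeping sites

A nightly centroid is the mean of an individual's fixes between 20:00 and
04:00 (at least 8 of the 32 possible fixes). Centroids are clustered with
hierarchical agglomerative clustering and the tree is cut at 500 m.
Complete linkage is the default because it bounds the within-site
diameter; with refuges spaced kilometres apart and nightly centroids
scattered by metres, any cut between roughly 100 m and the inter-site
spacing yields the same partition, so the exact cut height is not
delicate. A night is *shared* when two or more distinct groups are
assigned to the same site on the same night date.

## Home ranges

Utilization distributions are Gaussian-kernel densities on cell-aligned
50 m grids (reference "href" bandwidth by default), converted to
cell-integrated mass. The 95% home range is the smallest set of
highest-density cells reaching that mass; overlap is computed on the
shared cell lattice, and Bhattacharyya's affinity is
$BA = \sum_c \sqrt{p_a(c)\,p_b(c)} \in [0,1]$. For two isotropic
unit-variance Gaussians offset by $d$ the affinity is exactly
$e^{-d^2/8}$, which the test suite uses as a closed-form oracle.

## The day-shift permutation engine

To ask whether two groups move interdependently we rotate one group's
trajectory by a whole number of days (uniformly drawn from 1 to
$n_{days}-1$; without replacement across permutations when possible) and
recompute the statistic of interest. The rotation preserves each track's
space use, daily routine and within-day structure exactly -- only the
concurrency of the two tracks is destroyed -- so attraction to fixed
resources, travel corridors and topography is held constant under the
null. Five dyadic movement metrics are built in: mean dyadic distance,
proportion of time in association (within the response radius), and the
within-radius mean distance, heading difference and step-length
difference.

Significance is reported two ways, and both are exposed: the empirical
value falling outside the 90% inter-quantile band of the null (the
decision rule used throughout), and one-sided permutation proportions with
the add-one correction $p = (1+k)/(n+1)$, which keeps p-values in
$[1/(n+1), 1]$ and well-defined under ties.

Which member of a dyad is shifted is arbitrary under the null; we shift
the member with fewer tracking days (deterministic, and it maximizes the
offsets available).

## Response radius

The response radius is the distance at which intergroup proximity stops
mattering. All dyad timestamps are pooled and binned by intergroup
distance in 100 m bins ascending from zero; in each bin the mean heading
difference (the default coordination metric; step-length difference and
within-bin distance are pluggable) is compared with the 5th--95th
percentile band of the same binned quantity under day-shift permutations.
The radius is the lower edge of the first evaluated bin whose empirical
value lies inside the band; if the first evaluated bin is already inside,
the radius is 0. Bins with fewer than 50 empirical observations are
skipped.

Two numerical choices deserve a note:

* Heading and step are properties of the *step into* a fix, computed
  within calendar days (so whole-day rotations leave them untouched), and
  undefined below a 1 m step. Step-based metrics are binned by the
  intergroup distance at the *start* of the step -- the distance at which
  the behavioural decision was made. Binning by the end-point distance
  instead smears genuinely coupled steps one step-length outward across
  the radius boundary and biases the recovered radius upward.
* Under a true null every bin has, by exchangeability, roughly a 10%
  chance of falling outside a 90% band, so the radius is 0 (no evaluated
  bin outside) in about 90% of null datasets. The specificity experiment
  below measures exactly this rate; values far above it would indicate a
  calibration bug, and a rate near it is expected behaviour, not noise to
  be suppressed.

## Interactions

Within the daytime window 08:30--17:30 (median departure/arrival times at
sleeping sites), an interaction is a maximal run of fixes with intergroup
distance at or below the response radius; runs on the same day separated
by less than 75 min merge, and runs never span a night (continuous
overnight proximity counts as one interaction per day, with the shared
night between them flagged). An interaction is *cohesive* when some
contiguous stretch keeps the dyad within the 80% quantile of within-group
daytime dyadic distances while either group travels at least 100 m --
i.e. the two groups are as close as group-mates while actually going
somewhere. Front/behind scores compare each group's distance to the dyad
centroid one step ahead; the sign says who leads, and the score negates
exactly under dyad swap.

## Sleep

Each accelerometer burst yields a posture angle
$\theta = \operatorname{atan2}(\bar a_z, \sqrt{\bar a_x^2 + \bar a_y^2})$.
A minute is classified as sleep when it lies inside a run of at least 5
consecutive minutes whose successive angle changes all stay below 5
degrees -- a run-length formulation of the angle-stability family of
actigraphy algorithms. Both parameters are exposed; the classifier is
validated against the simulator's known labels rather than against video.
Per night (sleep period fixed at 21:00--05:00):

* **TST** -- sleep minutes in the period;
* **efficiency** -- TST over non-missing period minutes (missing minutes
  leave the denominator);
* **fragmentation** -- maximal wake bouts of >= 2 min per hour of sleep,
  undefined (NA, never infinite) when TST is 0;
* **onset / offset** -- the ends of the first/last sleep run of >= 5 min
  inside a 19:00--07:00 search window, wide enough to bracket typical
  onsets (~19:30) and wakings (~06:00);
* **synchronization** -- the fraction of jointly classified minutes two
  individuals spend in the same state.

Nights covering less than half the sleep period are flagged unusable and
excluded from effect tables. Sharing contrasts (shared minus unshared
nights) come with percentile CIs from an individual-level block bootstrap;
the full hierarchical regressions such data ultimately deserve are out of
scope here, but the effect tables are written in model-ready form (metric,
sharing flag, group/individual/date/site identifiers) for any mixed-model
package.

## The simulator

`simulate_gps()` generates the study conditions every experiment runs on:
4 groups carrying 6 collars by default, 24 sleeping sites laid out with a
guaranteed >= 3 km minimum spacing (a jittered grid), a daily routine of
departure at 08:30 and return by 17:30 via a random foraging waypoint
(target-seeking steps with Gaussian noise), ~5 m GPS scatter at the site,
and within-group AR(1) offsets tuned so collared group-mates average
roughly 40--80 m apart by day. Nightly site choice is either *controlled*
(a dyad is forced onto one site with probability `p_share`, 0.03 by
default -- the few-percent sharing rate typical of such populations --
otherwise all groups sleep apart) or *independent* (every group draws its
site each night; sharing arises by chance), the latter providing exact
exchangeability for calibration experiments. After a shared night a dyad
can be *attracted* for a set number of days: while within the true
response radius, the follower's step is a mixture of its own
target-seeking step and the leader's concurrent step plus a weak
positional pull -- giving a coordination signal that is strictly
distance-gated, which is what response-radius recovery needs.

Sleep is an alternating renewal process (exponential bout durations, mean
25 min asleep / 3 min awake) bracketed by a Gaussian onset near 19:32 and
waking near 05:55; shared nights multiply the wake-bout initiation rate by
1.5. Accelerometry gives each sleep bout a fixed random gravity
orientation with 0.02 g noise and each wake minute a fresh orientation
with 0.25 g noise.

Scenario presets pin down the conditions of the validation experiments:
`null_independent` (two independent groups, 120 days),
`attraction_after_sharing` (recurrent sharing, `p_share` = 0.15, with
3-day coupling -- sharing made frequent enough that a power experiment has
signal to find), `radius_600` (coupling strictly inside 600 m;
`p_share` = 0.2, 180 days, home-range centres 2 km apart so that distance
bins on both sides of 600 m are well populated), and `sleep_disruption`
(four groups, frequent sharing, the 1.5x wake-rate multiplier).

What the simulator does *not* emulate: terrain and vegetation, predators,
seasonal range shifts, collar failure patterns beyond simple gaps,
demography, or any feedback from sleep to next-day movement. Passing the
validation experiments therefore shows that the estimators recover known
structure from data with realistic geometry and noise -- not that real
baboon data satisfy the generative assumptions.

## Validation experiments and their sizes

The experiments behind `test-acceptance.R` and `scripts/acceptance.R`,
with the problem sizes the package uses as its standard design:

| experiment | design | expectation |
|---|---|---|
| type-I calibration | 100 datasets x 200 permutations, 120 days | rejection rate near the 10% band mass (accepted: 0.05--0.16) |
| attraction power | 20 seeds x 200 permutations | empirical mean distance below the 5th null percentile in >= 90% |
| radius recovery | 20 seeds x 200 permutations | within +/- 100 m of 600 m in >= 90%; radius 0 under the null in >= 90% |
| site recovery | 10 seeds, 90 days | exactly 24 sites, 100% night assignment |
| sharing null | 20 seeds x 200 permutations | calibrated under independence; detects forced sharing always |
| sleep classifier | 20 seeds | >= 90% minute accuracy (typically ~98%) |
| effect signs | 20 seeds, 400 bootstrap draws | negative TST contrast with CI below 0; positive fragmentation contrast |

Permutation counts of 200 are used in the replicated experiments (the
engine's default for a single analysis is 1000): the band quantiles are
then estimated from 200 draws, which is ample for a 5th/95th percentile
decision, and it keeps hundred-replicate designs affordable.

## Known limitations

* The day-shift null assumes approximate day-to-day stationarity; strong
  trends (range shift, seasonality) would leak into the null band.
* Response-radius inference needs data in the distance bins around the
  true radius; with < 50 observations per 100 m bin those bins are
  skipped, and the reported radius can jump to the next covered bin.
* The group track uses a single collar at a time; within-group spread is
  only represented when a group carries two collars.
* The sleep classifier sees only posture stability; behaviours that are
  still but awake (resting vigilance) are its intrinsic confusion class,
  as for all actigraphy-style algorithms.
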