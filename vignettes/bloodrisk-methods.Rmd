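---
title: "Methods: self-supervised risk scoring of blood panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: self-supervised risk scoring of blood panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

A complete blood count panel gives five numbers per subject — hematocrit
(HTC, %), hemoglobin (HGB, g/dL), white blood cells (WBC, 10⁹/L),
platelets (PLT, 10⁹/L) and mean platelet volume (MPV, fL) — and no label.
Most panels are normal. The pipeline in this package turns such an
unlabelled table into a supervised regression problem by (i) discarding
records that are normal in *every* dimension, (ii) scoring the remaining
records on a signed percentage scale derived from the data itself, and
(iii) fitting a fixed nonlinear basis model to predict that score.

This vignette records the model, the assumptions, and the design choices
that were genuinely open, so a maintainer can tell deliberate decisions
from accidents.

# Preprocessing model

**Normalization.** Each analyte column is min-max scaled,
$x' = (x - \min)/(\max - \min)$, onto $[0, 1]$. The $(\min, \max)$ pairs
are retained and reused for held-out data; held-out values beyond the
training range deliberately fall outside $[0,1]$ rather than being
clipped, because the labeller needs the size of the deviation. A constant
column is a hard error (zero range), not a silent NaN.

**Statistics.** Per-analyte mean and standard deviation of the
normalized data use the population convention (divisor $N$, not $N-1$).
This matters only for consistency: the elimination band and the error
spread reported by the evaluator use the same convention.

**Elimination.** With band half-width $\beta_j = a \cdot s_j$ per analyte
$j$ (multiplier $a$, default 1), a record is eliminated iff all five
values satisfy $|x_{ij} - m_j| \le \beta_j$ (inclusive). The inclusive
boundary pairs with the weighting rule below: a value exactly at the band
edge has weight zero, and a record of five such values carries no signal.
Widening $a$ eliminates weakly more records; the eliminated sets are
nested (tested over seeded cohorts).

**Self-weighting.** For a retained record, each analyte maps to

$$
w_{ij} =
\begin{cases}
0 & |x_{ij}-m_j| \le \beta_j\\[2pt]
100\,\mathrm{sign}(x_{ij}-m_j)\,
\dfrac{|x_{ij}-m_j|-\beta_j}{D_j^{\pm}-\beta_j} & \text{otherwise,}
\end{cases}
$$

where $D_j^{+} = \max_j - m_j$ and $D_j^{-} = m_j - \min_j$ are the
side-specific distances to the observed extremes. The map is the simplest
one that is (a) zero across the whole normal band, (b) continuous at the
band edge, and (c) exactly $\pm 100$ at the observed worst-case values.
Because it is anchored to observed extremes, the scale is cohort-relative,
not physiologic — that is a property of the method, not a bug. Held-out
values beyond the training extremes would map past $\pm100$ and are
saturated at the scale ends.

**Label reduction.** A record's scalar label is its largest-magnitude
analyte weight: risk is driven by the most abnormal analyte. Magnitude
ties are broken by the fixed priority HTC > HGB > WBC > PLT > MPV. Any
fixed priority would do; fixing one makes the pipeline deterministic. A
retained record cannot have an all-zero weight vector, so the label is
never exactly 0.

**Interval selection.** Labels are binned into signed 10 % intervals —
$(k-10, k]$ for positive labels, $[-k, -k+10)$ for negative, $k = 10,
\dots, 100$ — so every nonzero label falls in exactly one bin. Each
bin-sign cell keeps $\min(\text{existing}, i_t)$ records, default
$i_t = 300$, ranked by label magnitude (ties by original row index). The
magnitude ranking favours extreme, information-rich cases and needs no
randomness. The 75/25 train/test split is stratified within bins and
seeded; the pipeline never specifies an unseeded random step.

# Prediction model

The basis expands each normalized analyte $x$ through seven maps
$\{1, |x|^{1/2}, |x|, |x|^{1.2}, |x|^2, |x|^3, |x|^4\}$, analyte-major,
giving $7 \times 5 = 35$ columns. Two consequences are accepted
deliberately:

* the five bias columns are identical, so $b^\top b$ is rank-deficient —
  every solver must (and does) tolerate that;
* absolute values keep the fractional powers real for held-out inputs
  below 0 on the training scale; the odd powers therefore lose the sign
  of such inputs, which only affects out-of-range held-out values.

Labels are rescaled from percent to $[-1, 1]$ before fitting and all
reported errors are on that unit scale; this conditions the optimization
and makes error magnitudes comparable across learners.

## Learners

**BLS.** The minimum-norm least-squares solution via SVD, with singular
values below $\max(M,35)\,\varepsilon\,\sigma_1$ treated as zero. A
literal inverse of $b^\top b$ does not exist here (duplicate bias
columns); the pseudo-inverse is the standard resolution and is
cross-checked in the tests against an independent pseudo-inverse
implementation and against residual-orthogonality
($\|b^\top e\|_\infty$).

**INN.** Per-sample descent $w \leftarrow w + \eta e_k b_k$, $w_0 = 0$,
default $\eta = 0.05$, one pass in label-ascending order. The *descent*
sign is used: the update is derived from the gradient of the squared
error, and only the descent direction can reduce it. Ordering by label
makes the rule's recency effect visible — late near-normal samples
overwrite early extreme ones — which is exactly the qualitative behaviour
the method is known for. Divergence ($\|w\| > 10^6$) is flagged
`converged = FALSE` rather than thrown, so a comparison run survives a
reckless learning rate.

**LSLC.** Per-sample update
$w \leftarrow w + \eta^c\, b_k\, y_k / (b_k^\top b_k + \lambda_k)$ with
the multiplier solved in closed form per sample,
$\lambda_k = \max(0, \|b_k y_k\|_2 / (p\|\alpha\|_2) - b_k^\top b_k)$,
followed by projection onto the ball $\|w\|_2 \le p\|\alpha\|_2$
(defaults $\alpha = \mathbf{1}$, $p = 10$). The projection is what makes
the constraint hold at *every* iteration; the raw update alone does not
guarantee it. Note the update feeds back $y_k$, not the prediction error
$e_k$: the weights accumulate until the ball binds. That is a property of
this update rule, reproduced faithfully; its prediction error on the
synthetic cohorts is correspondingly large, and the constraint — not
convergence — is what the tests verify (plus exact agreement with an
unconstrained per-sample oracle when $p$ is effectively infinite).

**SCE.** Shuffled complex evolution over a box, defaults $n = 10$ points
per complex, $A = 4$ complexes, subcomplex size $q = 5$, $\alpha = 3$
evolution steps, $\beta = 5$ subcomplex draws, $\Omega = 100$ shuffling
iterations, stop target $f_q = 0$. The scheme is the standard one:
uniform seeded initialization, rank striping into complexes, triangular
rank-weighted subcomplex selection, then reflection → contraction →
random replacement of the subcomplex's worst point. Non-finite objective
values cause resampling inside the box. The fit objective is the squared
training error; each of the 35 weights is searched in $[-10, 10]$.
Forty points in a 35-dimensional box is a coarse search by construction;
SCE is included as the gradient-free baseline, not as the most accurate
learner, and its optimizer quality is tested where it can be measured
exactly (a 2-D quadratic, against equal-budget random search).

# Evaluation

"Mean error" is the mean *absolute* prediction error on unit-scaled
labels (a signed-mean alternative sits behind `metric = "signed"`), and
the spread is the population sd of the error, matching the preprocessing
convention. The 4 × 2 algorithm/partition report tolerates a failing
fitter by reporting `NA` for its cells.

One documented subtlety: the claim "scarce positive data degrades the
fit on the positive side" is a statement about imbalance acting through
a misspecified model. After interval selection has capped the dense bins,
the default synthetic cohort is balanced enough that the effect is within
noise for BLS. The test for this property therefore constructs the
condition it speaks about: ~95 % negative-label rows and a label map
(tanh plus a sine term) outside the basis span, under which the global
least-squares fit consistently favours the dense negative range.

# The synthetic cohort

`generate_panels()` emulates the structure of a real screening cohort:
~8.6 % female records; analytes drawn from per-analyte normal components
at standard adult reference magnitudes (HTC ≈ 42 %, HGB ≈ 14 g/dL,
WBC ≈ 7, PLT ≈ 250 × 10⁹/L, MPV ≈ 10 fL), so PLT dominates raw
magnitudes; 45 % of records get one or two analytes redrawn from a tail
shifted 4 sd away, low-side with probability 0.85 — high-side
abnormalities are scarce, which propagates to scarce positive labels
downstream; ages from weighted bins (18–40 dominant, a second mode past
65). Values truncate at zero, which concentrates extreme platelet lows at
the scale end — severe thrombocytopenia behaves the same way.

What the generator does **not** emulate: cross-analyte correlation
(independent draws by default; real HTC/HGB are strongly coupled),
laboratory measurement error structure, missing data, or any
cohort-specific age/gender effects. Passing tests therefore demonstrate
the pipeline's mechanics and invariants on realistic magnitudes — not
clinical validity on real panels.

# Numerical choices and degenerate inputs

* SVD cutoff for the pseudo-inverse: `max(dim) * eps * d[1]` (the usual
  rank tolerance).
* Band boundaries inclusive; weight exactly 0 at the band edge.
* A side whose observed extreme lies inside the band while out-of-band
  values exist on that side is a degenerate-scale error (division by a
  non-positive range) rather than an Inf weight.
* Constant analyte columns: error at normalization; constant inputs to
  the correlation: explicit undefined-correlation error.
* Per-bin train counts round to nearest (`round(0.75 n)`), so a 4-record
  bin splits 3/1.
* All seeded code paths save and restore the caller's RNG state.

# Problem sizes in the test suite

The suite runs cohorts of 200–6,000 records (10,000 in the acceptance
script), 100-trial optimizer comparisons on a 2-D quadratic, 100 random
50 × 5 least-squares instances, and one full 5,000-record pipeline
determinism check — sizes at which every property being asserted is
already stable across seeds while the whole suite stays fast.

# Known limitations

* The risk scale is cohort-relative: retraining on a different cohort
  moves the band and the extremes, hence every label.
* The label reduction keeps only the dominant analyte; a record with two
  moderately abnormal analytes scores the same as one with a single such
  analyte.
* LSLC as specified does not converge to a least-squares solution (see
  above); it is included for fidelity and comparison, not as a
  recommended estimator.
* With five duplicate bias columns the individual weights are not
  identifiable — only predictions are; interpret `w` accordingly.
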