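---
title: "Gaussian entanglement and structure-based folding: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gaussian entanglement and structure-based folding: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(entfold)
```

This vignette is the package's account of the science it implements: the
entanglement descriptors, the coarse-grained energy function and its
integrator, the histogram thermodynamics, the ensemble definitions, and the
numerical and design choices behind each. It states no empirical result that
the test suite or `scripts/acceptance.R` does not itself compute.

## 1. Gaussian entanglement of open chains

The linking number of two closed oriented curves is the Gauss double
integral, an integer topological invariant. Protein chains are open, so we
use its discrete, real-valued analogue. For a chain of N Cα positions
$r_1,\dots,r_N$, let $R_i = (r_{i+1}+r_i)/2$ be the bond midpoints and
$\Delta R_i = r_{i+1}-r_i$ the bond vectors. For a *loop*
$\gamma_i = (i_1,\dots,i_2)$ — a chain portion closed by a native contact
between $i_1$ and $i_2$ — and a *thread* $\gamma_j = (j_1,\dots,j_2)$
sharing no bond with the loop,

$$G'(\gamma_i, \gamma_j) = \frac{1}{4\pi}
  \sum_{i=i_1}^{i_2-1}\sum_{j=j_1}^{j_2-1}
  \frac{R_i - R_j}{|R_i - R_j|^3}\cdot(\Delta R_i \times \Delta R_j).$$

$|G'|\approx 1$ indicates a single threading event; the sign encodes
chirality. Minimal lengths $i_2-i_1 \ge 4$ and $j_2-j_1 \ge 10$ exclude
degenerate loops and trivially short threads. For each loop, the thread is
chosen to maximize $|G'|$ over all admissible contiguous segments on either
side of the loop.

**Algorithmic note.** The Gauss kernel for all bond pairs is computed once
per snapshot ($O(N^2)$, `gauss_pair_matrix()`). For a given loop, the sum
over thread intervals is a difference of prefix sums of per-column loop-row
sums, so the scan over all $(j_1, j_2)$ intervals is linear after the prefix
pass. The suite verifies exact agreement with exhaustive enumeration on 100
random 60-bead coils. Ties (equal $|G'|$) resolve to the smaller $j_1$, then
the smaller $j_2$; with continuous coordinates ties have measure zero.

**Thread admissibility.** Threads may share the loop's endpoint *residue*
but no bond ($j_2 \le i_1$ or $j_1 \ge i_2$): the double sum runs over
bonds, and this is the loosest convention that never counts a bond pair
twice. The alternative (strict residue disjointness) shifts reported values
of extremal loops in the second decimal at most.

**The whole-chain indicator.** Per-configuration entanglement is the
Hill-weighted average over the loops of the contacts *formed in that
snapshot*:

$$\langle G'\rangle = \frac{1}{H}\sum_{\gamma_i} G'\, h(|G'|),\qquad
  h(g) = \frac{1}{1 + (g_0/g)^m},\qquad H = \sum_{\gamma_i} h(|G'|),$$

with threshold $g_0 = 0.5$ (halfway between the unentangled $|G'|\approx 0$
and singly-threaded $|G'|\approx 1$ regimes; $h(g_0) = 1/2$ exactly) and
cooperativity $m = 3$, soft enough that $\langle G'\rangle$ remains a
usable reaction coordinate near threshold. Conventions for degenerate
cases: $h(0) = 0$ (the limit of the Hill form); a snapshot with no formed
contact, or all weights zero, has $\langle G'\rangle = 0$ and is flagged —
0 matches the "non-entangled" reading of the landscape plots. Loops whose
complement is too short for any thread contribute $G' = 0$ (hence
near-zero weight) rather than being dropped, keeping $H$ consistent with
an average over all formed loops. During trajectory analysis the maximal
thread is re-searched on every analyzed frame rather than frozen to the
native thread: misfolded configurations can be entangled by non-native
threads, including with chirality opposite to the native one, and a frozen
thread would miss them. The indicator is evaluated at every recorded frame
(1 MD step), the same cadence as Q, so both reaction coordinates share one
time base.

## 2. The structure-based model

One bead per residue at the Cα position. The potential is

$$V = \sum \epsilon_r (r - r_0)^2 + \sum \epsilon_\theta (\theta-\theta_0)^2
 + \sum \epsilon_\phi\left[(1-\cos\Delta\phi) + \tfrac12(1-\cos 3\Delta\phi)\right]
 + V_\text{native} + V_\text{rep},$$

with uniform amplitudes $\epsilon_r = 100\,\epsilon$,
$\epsilon_\theta = 20\,\epsilon$, and
$\epsilon_\phi = \epsilon_C = \epsilon_{NN} = \epsilon$; all "0" reference
values come from the input structure. $\Delta\phi$ uses signed dihedrals in
$(-\pi,\pi]$; the periodic cosine form needs no wrapping. Native contacts
attract through 12/6 Lennard-Jones with $\sigma_{ij} = 2^{-1/6} r_0^{ij}$
(minimum $-\epsilon_C$ exactly at the native distance), truncated — not
shifted — beyond $2.5\,\sigma_{ij}$, with no tail correction. All other
pairs with $j \ge i+2$ repel through a 12/6 term with $\sigma_{NN} = 4$ Å,
cut at $2^{1/6}\sigma_{NN}$ and shifted to zero there (a purely repulsive
excluded volume).

**Contact definition.** A native contact is a residue pair with any two
heavy (non-hydrogen) atoms closer than 4.5 Å and $j - i \ge 4$ — the
sequence-separation rule that simultaneously enforces "not in the same
pseudo-bond or pseudo-dihedral" and the $i+3 < j$ restriction of the
contact sum, and guarantees every contact defines a valid loop. The contact
equilibrium length $r_0^{ij}$ is the Cα–Cα distance. In simulation a
contact is *formed* when $r < g\, r_0$ with $g = 1.2$ (strict inequality at
the boundary).

**12/10 flavour.** For robustness comparisons an alternative native term
$\epsilon_C [5 (r_0/r)^{12} - 6 (r_0/r)^{10}]$ is available — the standard
form of this family of models, same minimum $-\epsilon_C$ at $r_0$ — with a
plain cut at $3\,r_0$ (a configurable choice recorded in run metadata;
there is no canonical truncation for this flavour).

**Forces.** All gradients are analytic, including the four-body dihedral
decomposition (evaluated trig-free from cross- and dot-products with
precomputed $\cos\phi_0,\sin\phi_0$). Near-collinear angles are regularized
by clamping $\cos\theta$ to $\pm(1-10^{-10})$; exactly collinear dihedral
frames contribute no torque. Truncation discontinuities are accepted, as is
standard for plainly cut potentials. The suite checks analytic forces
against central finite differences ($h = 10^{-6}$ Å) to a relative
component error below $10^{-5}$ for both flavours.

## 3. Langevin dynamics

The equation of motion $m\ddot r = -\gamma\dot r - \nabla V + R(t)$ with
white noise $\langle R(t)R(t')\rangle = 2 k_B T \gamma\,\delta(t-t')$ is
integrated in reduced units ($m = 1$, $\epsilon = 1$, 1 Å, $k_B = 1$),
$m/\gamma = 0.1$ and $\Delta t = 0.001$. The discretization is the
Grønbech-Jensen–Farago velocity-Verlet scheme, chosen because it samples
the configurational Boltzmann distribution essentially without time-step
bias at this $\Delta t$; the scheme name is recorded in run metadata since
barrier heights can shift slightly between thermostat discretizations. One
*MD step* — the package's time unit — is 24000 integrations; observables
(Q, $\langle G'\rangle$, E, RMSD) are recorded every MD step by default.
Velocities initialize from Maxwell–Boltzmann at the run temperature unless
supplied. The Langevin thermostat acts on all degrees of freedom; the
center of mass diffuses, which is documented rather than removed (RMSD is
computed after optimal superposition, so recorded observables are
unaffected).

Noise comes from an internal xoshiro256++ stream (polar-method normals)
whose per-chunk seed is drawn from R's RNG, so `set.seed()` — or the seed
field of `integrator_settings()` — fixes trajectories bit-for-bit on a
given build while keeping the inner loop fast. Equipartition is verified
statistically in the suite: $\langle v^2\rangle = T/m$ on free beads and
$\langle V\rangle = \frac32 k_B T$ on a three-bead bonded chain (2 bonds +
1 angle), each within three standard errors over $10^4$ MD steps.

## 4. WHAM on the native-contact coordinate

Equilibrium runs at R temperatures are combined on the fraction of native
contacts Q, which bins naturally by the integer formed-contact count. With
$N_i(Q)$ the per-run histograms (first 10% of each series discarded as
burn-in) and $\langle E\rangle_Q$ the run-average of per-run bin means, the
self-consistent equations

$$S(Q) = \ln\frac{\sum_i N_i(Q)}{\sum_j n_j\, e^{-\beta_j \langle E\rangle_Q + f_j}},
\qquad e^{-f_k} = \sum_Q e^{-\beta_k\langle E\rangle_Q + S(Q)}$$

are iterated from $f = 0$, $S = 0$ until the mean absolute change of each,
over its own domain, drops below $10^{-14}$. All exponentials are evaluated
in log space (log-sum-exp), so $|\beta E|$ up to $10^4$ causes no overflow.
Two numerical points: (i) bins never visited by any run are excluded from
both sums; (ii) the equations are invariant under the gauge
$(S+c,\, f-c)$, along which the plain iteration is marginally stable — the
implementation anchors $f_1 = 0$ each sweep, and reports S shifted to
$\max S = 0$. Free-energy *differences* are gauge-invariant and tested as
such (single-run identity $F = -T\ln N(Q) + \text{const}$ to $10^{-10}$;
invariance under duplicating a run and under shifting all energies).

Thermal averages reweight the bin means,
$\langle E^n\rangle_T \propto \sum_Q \langle E\rangle_Q^n\, e^{S(Q)-\langle E\rangle_Q/T}$
— the intra-bin energy variance is ignored (bin-mean approximation), which
slightly smooths Cv but leaves peak positions accurate at these system
sizes. $C_v(T) = (\langle E^2\rangle_T - \langle E\rangle_T^2)/(T^2 N)$ per
residue; $T_f$ is the grid argmax refined by a quadratic fit through the
three surrounding points (default grid spacing 0.005). Profiles evaluated
well outside the sampled temperature range trigger a warning. The barrier
$\Delta F$ is the saddle between the two lowest minima of $F(Q;T_f)$
measured from the lower-Q (unfolded) minimum, after 3-bin smoothing on
profiles with at least 9 bins (short constructed profiles are used raw).

## 5. Landscapes, regions and pathway classification

Two-dimensional $(Q,\langle G'\rangle)$ surfaces are the negative log of a
Gaussian product-kernel density estimate of the sample cloud, with
per-dimension Scott bandwidths $\hat\sigma\, n^{-1/6}$, shifted so the
minimum is 0; contour levels of 0.4 log-units correspond to $0.4\,k_BT$ for
equilibrium data. The wording "KDE of the negative log-scale histogram" is
resolved as KDE on the raw points followed by the negative log — what the
standard KDE tooling computes; the alternative (smoothing a pre-binned
log-histogram) differs only in the far tails. Equilibrium and refolding
landscapes share this code path; only the sample source differs.

Ensemble regions are closed-form predicates: U is
$Q\in[0,0.375],\ \langle G'\rangle\in[-0.25,0.25]$; F is
$Q\in[0.75,1],\ \langle G'\rangle\in[-1,-0.5]$; the transition-state band
is $Q\in[Q_{TSE}\pm\delta Q]$ with $Q_{TSE}=0.5,\ \delta Q = 0.03$; the
rhomboidal intermediates are IT: $Q\in[0.5,0.75]$,
$-0.2Q < \langle G'\rangle < -0.2Q+0.2$ (near-native contacts, no
entanglement — the kinetic trap) and IE−: $Q\in[0.32,0.46]$,
$-1.07Q-0.26 < \langle G'\rangle < -1.07Q-0.11$ (near-unfolded but natively
entangled — the fast-channel gateway). Bracketed interval bounds are
closed; the rhomboid inequalities are strict, exactly as defined.

Classification smooths both coordinates with a centered 555-MD-step rolling
mean (shrunken windows at the ends — centered to avoid biasing state
timing), labels each point, drops unlabeled points and merges consecutive
duplicates into the visited sequence. Rules: reaching F without visiting IT
is *fast folding*; otherwise the decision is made on the most recent
decision state among {IT, U} before F — IT means *threading*, U means
*backtracking* (the transient IE− is crossed on the fast channel of either
escape route, so it does not carry the decision); never reaching F while
ending in IT is *trapped*; a series with no labeled state reports
*unclassified* rather than being dropped. Folding times block-average Q and
$\langle G'\rangle$ over 250 MD steps and return the first block satisfying
the mode's criterion — $Q \ge 0.75$ *and* $\langle G'\rangle \le -0.5$ for
an entangled protein (both the structure and its topology must be native),
$Q \ge 0.7$ alone for a non-entangled one.

Ensemble contact maps are per-contact formation fractions; Z-scores
$z_i = (p_i - \bar p)/\sigma_p$ use the population standard deviation (no
Bessel correction), so they average to zero over the contact list.
"Trap-avoiding" contacts have $z^{IE-} > 1$ and $z^{IT} < 1$;
"first-entangling" contacts have $z^{IE-} > 0$ and belong to the supplied
set of natively entangled contacts.

## 6. Contact kinetics

Per-contact binary formation indicators are averaged across refolding
trajectories (optionally a pathway-selected subset, driven by the
classifier's labels rather than hard-coded counts), block-averaged
(non-overlapping blocks, center timestamps, trailing partial block kept),
and fitted with $A - B e^{-kt}$ by bounded Levenberg–Marquardt least
squares ($A, B \in [0, 1.2]$, $k > 0$; unweighted, as the plain
nonlinear-least-squares reading). Initialization: A from the final block, B
from the rise, $k$ from a third of the time span. Flat or non-convergent
curves are flagged "no-kinetics" ($A$ = mean, $B = 0$, $k$ undefined)
rather than reported with meaningless parameters. Parameter standard
deviations come from the fit covariance. Center-of-block timestamps matter
at coarse windows: the suite checks exact recovery on noiseless curves,
$k \to k/s$ consistency under time rescaling, and 10% recovery of $k$ on a
stochastic Bernoulli fixture (100 trajectories). Unfolded-state formation
probabilities $p_U$ are simple fractions over unfolded samples with
binomial standard errors.

## 7. Synthetic fixtures: what they emulate and what they do not

The generators provide ground truth without downloads:

* `make_linked_rings()` — polygonal circles with analytic linking number 0,
  ±1 (Hopf) or ±2 (double wind); the discrete Gauss sum converges to the
  integer as segments double.
* `make_open_lasso()` — a near-closed planar loop plus a straight terminal
  thread through (or beside) its center; the smooth-geometry Gauss integral
  is the oracle, and chirality mirrors exactly.
* `make_toy_native()` — hairpin (paired strands, CB beads pointing into the
  gap provide the heavy-atom contacts while Cα–Cα non-native pairs stay
  outside the repulsion cutoff, so the native state is an exact stationary
  point), helix (compressed pitch, i → i+4 contacts through axial pseudo
  side chains), and lasso (an 11-residue thread down the z axis, a
  connector, and a loop closed by a Cα contact with |G′| ≈ 0.87). Bond
  lengths are near 3.8 Å; no attempt is made to mimic Ramachandran
  statistics, side-chain packing or realistic contact-order distributions.
* `make_synthetic_kinetics()` — independent Bernoulli draws with
  $p(t) = A - Be^{-kt}$; `make_scripted_series()` — reaction-coordinate
  series sitting at region centroids with 0.02 jitter (small against the
  region sizes).

Passing tests on these fixtures demonstrates the correctness of the
descriptors, the integrator's statistics, the estimators and the
classifiers — not that any particular real protein folds through a given
mechanism. Real-structure analyses additionally depend on experimental
coordinates (altloc and occupancy handling can shift extremal G′ values in
the second decimal; the reader keeps the highest-occupancy altloc, ties to
the first listed).

## 8. Study conditions and problem sizes

The desk-scale study conditions used by the test suite and
`scripts/acceptance.R`: rings with 200 segments (convergence ladder 50–400);
a 30-residue lasso and 12-residue hairpin; thermostat checks over $10^4$ MD
steps; a hairpin equilibrium ladder of 8 temperatures spanning 1.3–2.1
$\epsilon/k_B$ at 250 MD steps each (the hairpin's Cv peak lies near 1.4,
with a few-percent seed-to-seed spread at this sampling); a refolding batch
of 20 trajectories of 150 MD steps at $0.9\,T_f$ from unfolded starts
sampled at $1.3\,T_f$ (burn-in 30 MD steps, decorrelation 10); kinetics
fixtures with 100 trajectories of $5\times10^4$ steps. These sizes were
chosen so the full analysis chain — including the two-temperature ladder
protocol, unfolded-state sampling above $T_f$ and refolding below it —
runs end to end in minutes on one CPU while every statistical tolerance
stated above is meaningful. Production analyses of real proteins use the
same code paths with longer ladders (e.g. $8\times10^4$ MD steps) and
100-trajectory refolding batches.

## 9. Known limitations

* The Go-model bias means non-native interactions are purely repulsive:
  kinetic traps of non-native origin are invisible by construction; the IT
  trap studied here is a *native-contact* topological trap.
* WHAM uses the bin-mean energy approximation; for very small systems the
  Cv peak is broad and its position carries sampling noise.
* $\langle G'\rangle$ is chirality-signed but scalar: configurations with
  coexisting opposite-chirality entanglements partially cancel.
* The maximal-thread search considers contiguous threads only; multi-segment
  or knotted threading (knot invariants, minimal-surface variants) is out of
  scope.
* Time units are reduced; mapping MD steps to seconds is model-dependent
  and intentionally not provided.
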