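---
title: "Models and methods behind serpens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind serpens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`serpens` simulates a closed sensorimotor loop — a network of
Bonhoeffer–van der Pol (BVP) oscillators driving and driven by a planar
snake-like body — and analyses the movement patterns that the loop
produces. This vignette documents the models, the numerical conventions,
and the design decisions taken where the problem was genuinely open, so
that every default can be traced to a reason.

## The oscillator network

Each of the 200 neurons follows the BVP equations

$$\tau \dot x = c\!\left(x - \tfrac{x^3}{3} - y + z\right) + \delta (S_f - x),
\qquad
\tau \dot y = \tfrac{1}{c}(x - b y + a) + \epsilon S_f,$$

with `a = 0.7`, `b = -0.2`, `c = 2.0`, excitatory gain `delta = 0.01`,
inhibitory gain `eps = 0.015`, and tonic input `z` on the grid
0.4/0.45/0.5/0.55. At these values an uncoupled neuron sits on a stable
limit cycle with a period near 10 s; the coupling gains are two orders of
magnitude below the intrinsic dynamics, so all interaction effects
accumulate on a 100 s time scale — which is exactly the scale of the
movement-pattern episodes the analysis chain measures.

The coupling input is
$S_f = \frac{1}{K_i}\sum_{j \ne i} w_{ji}\, x_j$
for hidden neurons, where $K_i$ counts the incoming connections; the 26
interface neurons blend this network term with the sensory feedback $I$ of
their muscle through the sensor ratio $\alpha$. Two conventions deserve
note:

* The $1/K$ factor is applied even under the random-weight scheme, whose
  per-node normalization already makes $\sum_j |w_{ji}| = 1$; the double
  normalization is deliberate and follows the model equations as stated.
* The transmitted signal is the activation $x$ itself, not a transformed
  firing rate.

The time constant $\tau$ defaults to 1 s so that simulated durations are in
seconds. Integration is classical RK4 at `dt = 0.01` s (an explicit Euler
option exists for cross-checks), with the sensory input held constant
within a step; states are sampled every 0.1 s for analysis. Initial states
are i.i.d. uniform on $[-0.1, 0.1]$. With these choices a 2000 s,
200-neuron closed-loop run takes about two seconds of wall time.

### Wired topologies

Four generators are provided. The ring-regular network connects each node
to its `m = 2` nearest neighbors per side. The small-world network rewires
each ring edge with probability `p` (0.01 or 0.05 in the standard
conditions); `p = 1` is the random network. The scale-free network grows
from `m0 = 2` initially unconnected seed nodes by attaching each new node
to `m = 1` existing node with probability proportional to degree + 1 — the
+1 smoothing makes the empty seed graph well defined, so no ad-hoc seed
clique is needed. All generated graphs are undirected and stored
bidirectionally, because the coupling sum runs over all connected
neighbors. Interface neurons are placed uniformly at random (placement is
configurable: `random`, `hubs`, `spread`), since nothing in the model pins
their location.

Network measures operate on $|W|$: the weighted directed clustering
coefficient in the Fagiolo form
$C_i = [\hat W^{[1/3]} + (\hat W^T)^{[1/3]}]^3_{ii} /
\left(2[k^{tot}_i(k^{tot}_i - 1) - 2k^\leftrightarrow_i]\right)$
with $\hat W = |W| / \max |W|$ so that $C_i \le 1$; shortest paths with
edge length $1/|w|$, averaging over reachable ordered pairs and reporting
the unreachable count separately (keeping the average finite on fragmented
information networks); and node degree $\sum_j |w_{ji}|$. Both measures are
verified in the test suite against brute-force triad enumeration and
Floyd–Warshall oracles at $10^{-9}$ tolerance.

## The body surrogate

The body is a deliberately simplified planar stand-in for a physics-engine
snake: 15 links (0.1 m cubes, 0.6 kg, 0.02 m gaps) joined by 14 hinge
joints, actuated by 26 two-joint muscles (one left and one right per
adjacent joint pair). Geometry is abstracted into the muscle rest length
`L0 = 0.24` m and a factor `kappa = 0.4` per radian of mean spanned bend:
$L = L_0(1 - s\,\kappa\,(\theta_q + \theta_{q+1})/2)$, which makes left and
right muscle lengths exact mirror images.

Muscles are linear spring-dampers (`k_s = 200` N/m, `k_d = 2` N·s/m) whose
rest length is commanded by the interface neurons through
$L_{rest} = L_0 (1 + g \tanh x)$ with motor gain `g = 0.4`. Joints are
overdamped (`b_visc = 0.5` N·m·s/rad, limits ±π/3): the articulated chain
has no inertia, so it is unconditionally stable and acts as a mechanical
low-pass with a response time of ~0.3 s, fast relative to the 10 s gait
period. Net motion comes from viscous resistive-force theory: each link
feels anisotropic ground drag (tangential 0.1, normal 10 N·s/m), and the
3-dof rigid-body velocity that balances total force and torque is solved
exactly each step, so traveling waves propel the body (≈0.7 body lengths
in 50 s under a reference wave) while standing flexion does not.

Sensory feedback is proportional muscle stretch,
$I = \sigma (L - L_0)/L_0$ clipped to $[-2, 2]$. The gain `sigma = 1.5` is
the one deliberately *calibrated* constant of the surrogate: it makes the
standard-deviation of $I$ match the standard deviation of the network
coupling term at intermediate sensor ratio, so that $\alpha$ genuinely
interpolates between network-dominated and body-dominated drive rather
than letting one side swamp the other. Muscle-to-neuron routing is muscle
index order (left chain then right chain) against interface index order,
configurable by permutation.

What the surrogate does **not** reproduce: contact impulses, inertia,
slipping, and the resulting mechanical instabilities of a rigid-body
physics engine. This matters for one family of results (see *Known
limitations*).

## Behavior analysis

Joint-angle series (burn-in of 50 s removed, since early motion is
dominated by the arbitrary initial state) are summarized per 10 s window,
shifted by 0.5 s (1 s in the large parameter sweeps), as the 91 Pearson
correlations of all joint pairs — windows with a zero-variance joint get
correlation 0 and are counted. Window length and shift are not dictated by
the model; 10 s covers one gait period and the shift keeps ~3.9k windows
per 2000 s run, which matches the 350-nearest-neighbor embedding scale.

The embedding is a Laplacian eigenmap: a binary symmetrized k-NN graph
(ties at the k-th distance all included, so duplicate windows are treated
symmetrically), normalized graph Laplacian, and the three non-trivial
eigenvectors with smallest eigenvalues, sign-fixed (first nonzero
coordinate positive) for determinism. Two conventions turn the embedding
into a space where a *fixed* clustering radius is meaningful:

* **Diffusion weighting** (`t_diff = 14`): coordinate $d$ is weighted by
  $\lambda_d^{t}$, the eigenvalue of the normalized adjacency. Cluster
  separations have eigenvalues near 1 and are kept; localized modes (e.g.
  an internal mode of one dense dwell region) decay and are suppressed.
  This is the diffusion-map distance at time $t$, chosen at the smallest
  value that removes localized modes on the planted-pattern fixtures.
* **Resolution convention** (`scale_rms = 3.2`): the geometric-mean RMS of
  the coordinates is fixed, placing the DBSCAN radius 0.16 at about 1/20
  of the coordinate spread — the regime in which dwell regions separate
  from transition paths. An embedding's absolute scale is arbitrary; a
  fixed convention makes the radius comparable across runs. A run whose
  feature cloud has no structure (global spread within ~5–20× of the
  median window-to-window step, e.g. a single unbroken gait) is compressed
  proportionally, so it reports one pattern rather than noise fragments.

DBSCAN (ε = 0.16, minimum 10 points) labels windows; label 0 is noise and
is reported as the unstable movement pattern. Maximal runs of one label
are episodes; a pattern is *stable* when its longest episode reaches the
Otsu threshold of the episode-duration histogram (256 bins; when the
between-class variance plateaus across an empty histogram gap the plateau
midpoint is taken). The threshold can be pooled over a whole experiment
batch (the default in `run_grid()`) or computed per run.

## Information networks

Transfer entropy with history lengths 1,
$T_{j \to i} = I(x^{(i)}_{t+1}; x^{(j)}_t \mid x^{(i)}_t)$,
is estimated with the KSG conditional estimator (max-norm, `k = 4`
neighbors, natural log — units are nats) over the union of all episodes of
one movement-pattern label; mutual information uses KSG algorithm 1.
Estimates are exact-brute-force and deterministic; small negative values,
a finite-sample property, are kept in the matrix but clamped at zero for
network measures. Closed-form Gaussian oracles (stationary covariance
algebra of an autoregressive pair, written before and independently of the
estimator) bound the estimator error below 0.05 nats at $n = 10^4$ in the
acceptance checks.

For block discovery the MI matrix is Otsu-binarized (the TE matrix is an
option) and fed to an infinite relational model: CRP prior with
concentration γ = 1 over partitions, Beta(1, β)–Bernoulli link model with
β = 7 — the single printed noise hyper-parameter is mapped to the second
Beta pseudo-count, penalizing dense spurious blocks. Inference is
collapsed Gibbs sampling started from singleton blocks (an all-merged
start cannot escape through single-node moves), followed by a greedy
maximum-a-posteriori sweep; the highest-posterior partition is returned
with blocks in first-appearance order. Planted 3-block graphs (30 nodes,
within-density 0.9, between 0.05) are recovered with adjusted Rand ≥ 0.9
in ≥ 90% of seeds.

Body–network influence is the mean TE over hidden→interface ordered pairs
and over interface→hidden pairs. In our simulations the two directions are
nearly equal, and both fall with pattern duration.

## Synthetic validation fixtures

Every analysis stage is testable without the simulator:

* `gaussian_var_pair()` — an AR pair with analytic transfer entropy from
  its stationary covariance ($\tfrac12\log(1 + c_y^2)$ for unit noise),
  the oracle for the KSG estimators.
* `planted_blockmodel()` — stochastic block models for the IRM.
* `switching_traj()` — joint-angle records switching between well-separated
  traveling-wave configurations, the oracle for the behavior chain. Dwells
  above twice the window length are recoverable; shorter dwells may be
  missed, and windows straddling a switch limit boundary precision to one
  window length.
* `driven_panel()` — a lag-one driver panel for directedness checks.

Passing these fixtures shows the chain recovers *planted, well-separated*
structure; it does not show that real dwell regions are as cleanly
separated, which is why the coupled-run checks (pattern counts, duration
correlations) are kept separate and stochastic.

## Problem sizes used in tests and the acceptance script

Full-length (2000 s) runs are used throughout, matching the reference
conditions; the parameter sweep uses 5 seeded repeats per sensor ratio at
a 1 s window shift, the information-network batches use 6–8 runs with
40-neuron subsets (all 26 interface neurons plus a seeded hidden sample)
and ≤ 600 samples per pattern, and the reference-condition check uses 3–4
seeds at the full 0.5 s shift. These sizes keep the whole suite inside a
desk-scale compute budget while leaving every qualitative check
unambiguous at its observed effect size.

## Known limitations

* **High-sensor-ratio stabilization is not reproduced.** In our surrogate,
  movement patterns live longest at intermediate sensor ratio and the
  pattern count is *highest* at the extremes — the body, being
  unconditionally stable and memoryless, acts at high α as a second weak
  drive rather than as the stabilizer that contact-rich rigid-body
  dynamics provides. The package reports this shape honestly; reproducing
  the monotone duration growth with α likely requires a body with inertia
  and contact.
* Transfer entropy is pairwise with history length 1; conditional or
  multivariate variants are out of scope.
* The IRM β mapping (single printed value onto a two-parameter Beta prior)
  is a convention; both hyper-parameters are exposed.
* DBSCAN's radius is meaningful only through the embedding resolution
  convention described above; comparing labelings across different
  conventions is not supported.
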