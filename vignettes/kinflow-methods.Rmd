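---
title: "State-space kinetic Ising models and time-varying entropy flow"
author: "kinflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{State-space kinetic Ising models and time-varying entropy flow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinflow)
```

## The model

`kinflow` analyzes binarized population spike trains: the activity of $N$
neurons is reduced to 0/1 indicators in bins of width $\Delta$ (10 ms by
default), over $T+1$ bins and $L$ repeated trials. The generative model is a
kinetic Ising model with time-varying natural parameters. Given the
population pattern $\mathbf{x}_{t-1}$ at the previous bin, neurons are
conditionally independent and neuron $i$ spikes with logistic probability

$$p(x_{i,t}=1 \mid \mathbf{x}_{t-1}) = r\!\left(\theta_{i,t} +
\textstyle\sum_j \theta_{ij,t}\, x_{j,t-1}\right), \qquad
r(h) = \frac{1}{1+e^{-h}},$$

where $\theta_{i,t}$ is a time-dependent field (bias) and $\theta_{ij,t}$ a
*causal* coupling from neuron $j$'s state at $t-1$ to neuron $i$ at $t$. The
diagonal $\theta_{ii,t}$ is a self-coupling (burstiness/refractoriness).
Couplings need not be symmetric, so the chain need not obey detailed
balance: the model is a nonequilibrium Markov chain, and its time asymmetry
is exactly what the entropy-flow estimators quantify. The initial pattern
$\mathbf{x}_0$ is conditioned on throughout; it contributes no likelihood
term.

Parameters evolve under a Gaussian random-walk state model, independently
per neuron: $\boldsymbol\theta^i_t \sim
N(\boldsymbol\theta^i_{t-1}, \mathbf{Q}^i)$, with an initial density
$N(\boldsymbol\mu^i, \boldsymbol\Sigma^i)$. The per-neuron factorization is
what makes the method scale: filtering, smoothing and hyperparameter updates
decompose into independent $(N{+}1)$-dimensional problems, and results do
not depend on the order in which neurons are processed.

## Inference

The E-step is a sequential Laplace filter: at each bin the per-neuron filter
density (a logistic log-likelihood over trials plus the Gaussian one-step
prediction prior) is concave, its mode is found by damped Newton–Raphson
with step-halving, and its covariance is the inverse of the Fisher
information plus prior precision at the mode. A fixed-interval (RTS)
smoother then runs backward, with the innovation taken against the one-step
*predicted* moments and gain
$\mathbf{A}_{t-1} = \mathbf{W}_{t-1|t-1}\mathbf{W}_{t|t-1}^{-1}$. Lag-one
smoothing cross-covariances
$\mathrm{Cov}(\boldsymbol\theta_{t-1},\boldsymbol\theta_t \mid
\mathbf{x}_{0:T}) = \mathbf{A}_{t-1}\mathbf{W}_{t|T}$ feed the M-step. We
verified the whole E-step against a brute-force joint-Gaussian oracle in the
linear-Gaussian limit, where it is exact to machine precision.

The M-step updates $\mathbf{Q}^i$ as the posterior mean of squared parameter
increments averaged over bins; `q_structure` restricts it to its diagonal or
to a scalar multiple of the identity ("full" is the default). The initial
mean is set to the smoothed mean at bin 1 — the joint maximizer with the
initial covariance, which then collapses to the smoothed covariance at
bin 1 — with `optimize_initial = FALSE` available to hold the initial
density fixed. Convergence is monitored through the Laplace approximation of
the marginal log-likelihood; iteration stops when its relative change drops
below `em_rel_tol` (1e-6). Defaults: Newton tolerance 1e-8 on the max-abs
gradient, at most 100 Newton iterations with up to 30 step halvings, at most
200 EM iterations, initial $\mathbf{Q} = 10^{-3}\mathbf{I}$,
$\boldsymbol\Sigma = \mathbf{I}$, and initial fields at the logit of each
neuron's mean rate (clamped to $[1/(TL+2), 1-1/(TL+2)]$). All covariance
inverses go through Cholesky factorizations and every updated covariance is
symmetrized.

Two numerical facts worth knowing. First, the single-pass Laplace smoother
approximates the *mode* of the joint path posterior only up to the skewness
of the per-bin logistic posteriors; with ten trials per bin the discrepancy
is at the percent level, vanishing in the linear-Gaussian limit and as $L$
grows. Second, Laplace-EM monotonicity of the approximate marginal
likelihood is itself approximate; in all our simulated regimes the trace is
non-decreasing within 1e-6 relative slack, and the test suite asserts this.

With `freeze_q = TRUE` the state noise is pinned at zero and a single E-step
is run: the posterior then converges to constant parameters across bins,
which is the stationary mode used for fitting time-homogeneous data.

## Entropy flow

The entropy flow at bin $t$ is the expected log-ratio of the forward
transition probability to the same kernel evaluated on the time-swapped
pair,
$\sigma^{\mathrm{flow}}_t = \sum p(\mathbf{x}_t,\mathbf{x}_{t-1})
\log\left[p(\mathbf{x}_t|\mathbf{x}_{t-1})/p(\mathbf{x}_{t-1}|\mathbf{x}_t)\right]$,
in nats; it decomposes as $-\sigma^{\mathrm{forward}}_t +
\sigma^{\mathrm{backward}}_t$ into forward and time-reversed conditional
entropies, an identity every estimator in the package satisfies to 1e-12.
Together with the system-entropy change it forms the (non-negative) entropy
production. Three estimators are provided:

* **Exact enumeration** (`entropy_flow_exact`, $N \le 12$): builds the
  $2^N \times 2^N$ transition matrix, propagates the state marginal from an
  independent-Bernoulli start, and evaluates flow, production and system
  entropy exactly. This is the oracle the others are tested against; it also
  verifies the second law and the detailed-balance zeroes (independent
  stationary units; symmetric couplings at stationarity) in the suite.
* **Sampling** (`entropy_flow_sampling`): averages the per-transition
  log-ratio over `n_s` independent chains (10,000 by default). Because both
  conditionals are model kernels, each term is computable directly and the
  estimator is unbiased; a per-bin Monte-Carlo standard error is returned.
* **Dynamic mean field** (`entropy_flow_meanfield`): treats each neuron's
  summed input as Gaussian with mean $g_{i,t,s} = \theta_{i,t} + \sum_j
  \theta_{ij,t} m_{j,s}$ and variance $\Delta_{i,t,s} = \sum_j
  \theta_{ij,t}^2 m_{j,s}(1-m_{j,s})$, propagating rates $m_{i,t}$
  recursively. The forward entropy integrates the Bernoulli entropy
  $\chi(h) = -r(h)h + \psi(h)$ against the previous-bin input statistics;
  the time-reversed entropy integrates $\phi_{i,t}(h) = -(m_{i,t-1}h -
  \psi(h))$ against same-bin statistics. Per-neuron contributions are
  returned, enabling the per-spike normalizations. On data, initialize
  $m_{i,0}$ with each neuron's session-averaged spiking probability
  (`mean_rates`).

Gaussian integrals use Gauss–Hermite quadrature with 100 nodes (via
`pracma`); at the input variances that arise in practice ($\Delta \lesssim
4$) the rule agrees with a 201-node rule to better than 1e-10, which the
suite checks. When $\Delta < 10^{-12}$ the integrand is evaluated at its
mean. A steady-state variant (`entropy_flow_steady`) iterates the rate
recursion to a fixed point and evaluates the stationary flow as the
covariance between rate deviations and input fluctuations.

When estimating flow from a fitted model, the smoothed posterior means are
plugged in; posterior uncertainty is not propagated into the flow estimate.
The mean-field approximation is accurate for weak couplings (the suite
requires per-bin agreement with enumeration within $\max(0.02N,\,10\%)$ on a
weakly coupled 6-neuron system) and degrades gracefully as couplings
strengthen; it is also insensitive to coupling asymmetry per se, so
asymmetry-driven comparisons should lean on the shuffle-subtraction design
rather than raw mean-field values.

## Simulators and surrogates

`sample_param_trajectories` draws ground-truth fields and couplings from
Gaussian processes with a squared-exponential kernel. The standard settings
(`default_gp_configs`): couplings with mean $5/N$, variance $10/N$ and
length scale $30/\sqrt{N}$ bins — the Sherrington–Kirkpatrick scaling that
keeps recurrent input $O(1)$ as $N$ grows — and fields with mean $-3$,
variance 1 and length scale 50 bins, producing the sparse firing typical of
cortex. Every series draws from its own stream keyed by (seed, series
identity), so the parameters for a population of size $N$ are exactly the
leading block of those for a larger population under the same seed — useful
for system-size sweeps. Cholesky factorization adds jitter starting at
$10^{-10} k_0$, escalating tenfold to at most $10^{-4} k_0$.

`trial_shuffle` permutes trial labels independently per neuron. This
preserves each neuron's within-trial dynamics (hence self-couplings) and
its per-bin trial-averaged rate bit-exactly, while destroying same-trial
cross-neuron alignment. Fitting shuffled data therefore retains rate
dynamics and estimation noise but not cross-couplings, so subtracting the
shuffled-fit entropy flow isolates the coupling-driven component; on truly
independent neurons the subtraction is statistically zero, which the suite
verifies.

What the simulator does *not* emulate: refractory structure beyond one bin,
slow drifts across trials, non-Markov history dependence, and unobserved
common input. Passing tests on these synthetic conditions demonstrates
correctness of the estimators under the model's own assumptions, not that
real recordings satisfy those assumptions.

## The higher-order interaction testbed

To probe what the pairwise, synchronously updated model *cannot* represent,
the package includes an alternating-shrinking higher-order interaction (HOI)
model: a homogeneous exponential-family law over binary patterns with
interactions of all orders, alternating in sign with geometrically shrinking
weights $C_j = \tau^j$, a sparsity parameter $f$, and a base measure
$1/\binom{N}{n}$ that cancels the pattern multiplicity. Its spike-count
distribution is sparse (mode at zero) yet widespread (heavy upper tail), and
its single-unit conditional log-odds accelerates supra-linearly at high peer
counts. A Gibbs sampler (fresh random permutation per sweep; consecutive
sweeps become consecutive bins, trial boundaries breaking the chain;
burn-in defaulting to 10% of sweeps, no thinning since the bin-to-bin
dependence is the point) generates data whose count histogram matches the
exact law to TV < 0.02 at the suite's scale. Fitting the kinetic Ising
model in stationary mode to these data and resampling from the fit
reproduces the count histogram an order of magnitude worse than a matched
kinetic-Ising control, with an exactly affine fitted log-odds against the
supra-linear truth — the documented failure mode.

## Downstream analyses

`analyze`-side helpers compute the summary statistics used when comparing
behavioral conditions: the coefficient of variation of rates (population
convention, divisor $n$; a `population = FALSE` switch gives the sample
convention), the skewness of per-neuron rate differences (same convention
switch), coupling asymmetry as the mean over unordered pairs of
$|\bar\theta_{ij}-\bar\theta_{ji}|$ (ordered-pair averaging would differ by
a constant factor that cancels in comparisons), credible-interval screening
of couplings (retained if the interval excludes zero in at least one window
bin — a union rule that is anti-conservative relative to the per-bin level,
which the false-positive test documents), the $\beta$-rescaling scan
$\boldsymbol\theta \to \beta\boldsymbol\theta$ with forward/backward
surfaces and low-gain range averaging, shuffle subtraction and per-spike
normalization of flow (per-neuron mean of contribution/rate by default; a
population-level alternative is exposed), and the behavioral sensitivity
index $d' = \Phi^{-1}(\mathrm{hit}) - \Phi^{-1}(\mathrm{fa})$ with rates
clamped to $[1/(2n), 1-1/(2n)]$.

Group-level significance testing across subjects (e.g. Wilcoxon signed-rank
comparisons) is left to base R's `wilcox.test` in user scripts; the package
computes the per-subject quantities.

## Problem sizes and known limitations

The test suite and the reproduction script run at desk scale, chosen so the
full suite completes in minutes on one core: two-neuron EM at $T=100$,
$L=200$; recovery sweeps at $N=5$, $T=50$, $L \in \{50, 200, 800\}$;
enumeration oracles at $N \le 6$; the HOI study at $N=30$ with
$\sim 3\times10^4$ sweeps. Larger problems scale linearly in $L$ and $T$ and
cubically in $N$ per neuron-bin update.

Known limitations, measured rather than assumed:

* Credible-interval calibration depends on the regime. With a
  well-specified random-walk truth, 95% intervals cover at 0.94; at the
  two-neuron showcase conditions ($T = 400$, $L = 200$) at 0.97. But when a
  smooth GP truth is tracked with only $T = 50$ bins and six parameters per
  neuron ($N = 5$), coverage drops to ~0.74 — smoothing bias of the
  random-walk working model, not an estimation defect (fixing the
  state-noise at the true GP increment variance makes it worse, not
  better). Treat short-series bands as optimistic.
* The single-pass smoother mean is not the exact joint posterior mode for
  logistic likelihoods (see above).
* The mean-field flow estimator's error grows with coupling strength and
  does not see coupling asymmetry directly.
* Entropy-flow estimates are quantities *of the fitted pairwise,
  synchronous-update model*; the HOI study shows how far that can sit from
  a population with genuine higher-order structure.
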