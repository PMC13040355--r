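---
title: "Methods: Bayesian anti-scalping detection for hospital registration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Bayesian anti-scalping detection for hospital registration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scalpguard)
```

## The problem

Online appointment registration concentrates demand for scarce specialist
slots into short release windows. Scalper operations exploit this with
scripted clients: they register many accounts, bind many medical cards to
few devices, seize slots within seconds of release, and hold or churn them
(cancel/rebook) for resale. The observable damage is a depressed completion
rate — a large share of booked appointments ends in cancelation or no-show —
and displaced legitimate patients.

`scalpguard` packages an end-to-end, fully synthetic study of a
countermeasure: recognise abnormal accounts from behavioural traces with a
Bayesian classifier, modulate its vigilance with clinic congestion, apply
graduated interventions, and quantify the effect with standard
epidemiological and ML statistics.

## The detector

### Class-conditional Gaussian model

Each account is summarised by 12 behavioural variables (13 numeric columns,
since booking hour-of-day is circular and enters as a sin/cos pair; see
`feature_names()`). Features are z-scored with training-set parameters that
are stored and replayed at scoring time.

For class $c \in \{\text{abnormal}, \text{normal}\}$ we fit a multivariate
Gaussian $g_c = N(\mu_c, \Sigma_c)$ and score accounts by

$$P(\text{abnormal} \mid x) =
  \frac{\pi\, g_s(x)}{\pi\, g_s(x) + (1 - \pi)\, g_l(x)},$$

computed entirely in log space (Cholesky factorization,
log-sum-exp). Accounts with posterior $\ge \tau$ are flagged, boundary
included.

Two parameters are deliberately **fixed rather than estimated**:

- the prior $\pi = 0.05$ encodes an audited baseline prevalence of
  violative accounts and is decoupled from the training-sample prevalence,
  which is an artifact of how the training window was drawn;
- the threshold $\tau = 0.75$ is the chosen operating point of the
  sensitivity–specificity trade-off (`calibrate_threshold()` reproduces the
  sweep). At $\pi = 0.05$, a posterior of exactly 0.75 corresponds to a
  class likelihood ratio of 57.

### Regularization

The abnormal class is small, so its MLE covariance can be near-singular.
Two standard devices are combined (`scalper_bayes()`):

- diagonal shrinkage $\Sigma \leftarrow (1-\lambda)\Sigma +
  \lambda\,\mathrm{diag}(\Sigma)$ with $\lambda = 0.1$;
- a small ridge $10^{-4} I$ on the standardized scale. This keeps the
  density proper when a behaviour is *constant within a class* — e.g. when
  every abnormal account books online only, shrinkage toward the diagonal
  cannot repair the zero variance, but the ridge can.

### Dynamic prior

Queue congestion modulates vigilance on the log-odds scale:

$$\mathrm{logit}(\pi') = \mathrm{logit}(\pi) + \gamma\,(\kappa - 0.5),$$

where $\kappa \in [0,1]$ is the congestion index from the queuing model and
$\gamma = 2$ by default. Congestion 0.5 is neutral; the mapping is strictly
increasing, so higher congestion never lowers a posterior.

### Sequential updating

Detection outcomes feed back into training. Two modes
(`sequential_update()`):

- **window**: refit on the most recent $W$ batches. Simple, fully
  forgetting, and the default for drift tracking.
- **conjugate**: a normal–inverse-Wishart update of each class with the
  current parameters as prior and pseudo-counts `kappa0`/`nu0`; infinite
  pseudo-counts freeze the model. This gives a tunable memory without
  storing past batches.

### Bayesian-network variant

`bn_fit_naive()` provides a discrete Bayesian-network reading of the same
problem: features discretized at training quartiles, class as sole parent
of each feature, CPTs estimated with Laplace smoothing ($\alpha = 1$), and
posteriors computed by exact enumeration over the class node. The naive
structure is a deliberate commitment: no dependency structure among the
behavioural variables is assumed, but `bn_spec()` accepts arbitrary DAGs
with long-format CPTs (validated for row-sums and acyclicity) for
experimentation.

## Ground-truth labeling

An account is labeled abnormal when at least **two of three** criteria
fire (`label_accounts()`):

1. more than 3 cancelations inside some sliding 48-hour window (strict:
   4+). Windows are duration-based, not calendar-based, so time-zone and
   DST issues cannot arise; the maximum is found by anchoring a window at
   each cancel event, which enumerates all attainable counts;
2. a device associated with more than 5 distinct medical cards (strict:
   6+). The flag is device-level and marks **every** account that used the
   device — card fan-out is evidence about the device, not about one login;
3. any user-initiated operation faster than the speed threshold. The
   default is the documented fixed 2 s automation signature;
   alternatively, the threshold is the boundary of the fastest 1% tail of
   reference manual operations (`speed_threshold()`).

Requiring two criteria makes single-signal false positives (an indecisive
patient who cancels often; a caregiver booking for a family) structurally
impossible.

## The queuing model

Patient flow is an M/M/c queue (`simulate_queue()`): Poisson arrivals,
exponential service, FIFO, infinite waiting room. The discrete-event
simulator uses the server-free-time recursion; the first 10% of the horizon
is discarded as burn-in and the mean number in system $L$ is a
time-average of the queue-length step function. Exact analytic
counterparts (`analytic_mm1()`, Erlang-C `analytic_mmc()`) serve as
oracles: $L = \rho/(1-\rho)$ and $W = 1/(\mu - \lambda)$ for M/M/1, and
Little's law $L = \lambda W$ as an internal consistency check. The
congestion index coupling the queue to the detector is the utilization
clamped to $[0, 1]$ (an occupancy transform $L/(1+L)$ is also offered).

A practical note from validation: single sample paths at horizon $10^4$
hours carry sizeable autocorrelated noise (relative SD of $L$ roughly 6% at
$\rho = 0.5$, growing with load), so convergence tests average a handful of
independent replications rather than trusting one path.

## The synthetic generator

### Design

`sim_config()` fixes the study conditions; `simulate_cohort()` and
`simulate_events()` generate the data. The defaults — 2,000 accounts, 5%
scalpers, 15 bookings/day over a four-year window with the intervention at
the midpoint — are this package's own choice of problem size, picked so the
full experiment runs in seconds on one CPU while keeping several hundred
events per class.

Scalper signatures are generated mechanistically, not by sampling labels:

- **release-window bursts**: scalper bookings cluster in the 30 minutes
  after the daily 00:00 slot release, in bursts of ~6 bookings seconds
  apart;
- **scripted speed**: operation durations are lognormal with median 0.8 s
  (legitimate: median 25 s, heavier tail), so scalpers routinely break the
  2 s signature;
- **card fan-out**: each scalper operates one device with 6–12 medical
  cards and several rotating IPs; legitimate accounts have 1–2 cards;
- **churn**: scalpers cancel 75% of bookings and complete 5%; legitimate
  accounts cancel 12% and complete 75%. Scalper activity is weighted 8× per
  account.

Every booking resolves to exactly one of cancel/complete/no-show with a
back-reference, so outcome accounting is conservative by construction.

### Realism and limitations

The generator reproduces the *signatures the detector uses* and the
*outcome gap the intervention targets*, which is what a validation study
needs; it is not a behavioural digital twin. Known simplifications:

- legitimate daytime activity follows a smooth beta-shaped diurnal curve;
  there are no weekday/weekend or holiday effects;
- scalper tactics are stationary — no adversarial adaptation to the
  detector (the drift tests in the suite emulate this exogenously);
- departments are sampled independently of clinical need, and no-shows are
  independent across bookings;
- with the default signature strengths the classes are strongly separated,
  so cross-validated AUC is near 1 — the evaluation machinery, not the
  difficulty of the frontier, is the object under test. Signature strength
  is fully configurable for harder scenarios (e.g. slower scalpers,
  `label_noise > 0`).

## The intervention experiment

`run_experiment()` wires the closed loop: simulate → label (pre period) →
fit → queue congestion → score the post period under the dynamic prior →
graduated policy → outcome accounting → evaluation. Flagged accounts with
posterior in $[0.75, 0.90)$ receive a verification challenge (pass
probability 0.98 for legitimate users, 0.05 for scalpers); posteriors in
$[0.90, 1]$ get a temporary restriction; a concurrent-open-booking cap of 3
models card binding and quotas. Blocked bookings and their resolutions
leave the materialized stream, so the completion rate is computed over
completed + no-show appointments — the dichotomy actually observed at the
clinic.

The evaluation reports: pre/post χ² and Katz relative risk on completion,
the completion change in percentage points with a percentile-bootstrap CI,
confusion metrics and rank-AUC of the detector against post-period rule
labels, an Equal Opportunity TPR-gap fairness report by age and
socioeconomic band, monthly interrupted time-series (segmented regression
with Durbin–Watson diagnostic), the drop in flagged-account bookings, and
the share of wrongly flagged legitimate accounts.

Every stage draws from its own seed stream derived from one master seed
(`derive_seeds()`), so the entire experiment is a pure function of
(configuration, seed).

## Numerical choices

- All density arithmetic in log space; posteriors via log-sum-exp; Gaussian
  log-density via Cholesky + triangular solve (validated against
  `mvtnorm::dmvnorm` to $10^{-9}$).
- Hand-rolled statistics are cross-checked against reference
  implementations in the test suite: `stats::chisq.test(correct = FALSE)`,
  `stats::prop.trend.test`, `pROC::auc`, `lmtest::dwtest`, plus brute-force
  oracles (pairwise AUC counting, quadratic sliding-window enumeration,
  hand-multiplied CPTs). They are reimplemented only where the package
  needs a specific convention exposed (signed trend Z, Katz log-Wald CI,
  ties-at-half AUC); the ITS model itself is an ordinary `stats::lm` fit.
- The sliding-window maximum uses a sorted two-pointer `findInterval` scan,
  $O(n \log n)$, with a $10^{-9}$ s guard so a window closed on the left
  and open on the right never double-counts boundary events.
- Degenerate feature cases are resolved totally (single operation → capped
  inter-operation interval; one-event session → its own duration) so the
  Gaussian model never sees missing values.

## Limitations

Beyond the generator simplifications above: the fixed prior and threshold
are policy inputs, not estimates, and should be recalibrated against an
audited prevalence before any real deployment; the fairness report checks
Equal Opportunity only (group-conditional TPR), not calibration or demographic
parity; and the queuing model is stationary M/M/c — release-window demand
spikes are visible in the event stream but not fed back into the queue.
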