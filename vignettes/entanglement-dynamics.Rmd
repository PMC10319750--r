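---
title: "Modelling DNA-mRNA entanglement decay under tautomeric decoherence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling DNA-mRNA entanglement decay under tautomeric decoherence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tautodyn)
```

## The model

Proton tunneling across a hydrogen bond can hold a DNA base in a coherent
superposition of its normal and tautomeric forms. When such a template is
transcribed and replicated, the mRNA transcript and the daughter DNA strand
inherit *correlated* incorporation errors: either both polymerases read the
tautomer (an R-error together with a D-error) or neither does. The pair is
therefore modelled as two qubits prepared in the entangled state

$$|\psi(0)\rangle = \alpha\,|0\rangle_1|0\rangle_2 + \beta\,|1\rangle_1|1\rangle_2,
\qquad \alpha^2 + \beta^2 = 1,$$

after which each qubit couples to its own bosonic reservoir (nucleoplasm for
the DNA, cytoplasm for the mRNA), both starting in their vacuum. The
computational levels are the symmetric/antisymmetric combinations of the
biologically legible outcomes, e.g.
$|0\rangle_1 = (|D_{cor}\rangle - |D_{er}\rangle)/\sqrt2$;
`error_basis_populations()` rotates any two-qubit state back to the
correct/error basis and exposes the R-D error correlation directly.

Each channel $i \in \{1, 2\}$ is characterised by two dimensionless numbers:
a tunnel splitting $\Delta_i \ge 0$ (the level spacing in units of the
quasi-classical $\tilde h$; see below) and a decay rate $\Gamma_i \ge 0$.
Treating the system-reservoir coupling to second order in time-dependent
perturbation theory, a parity rule splits the propagator into a
vacuum-preserving branch (diagonal, pure phases, carrying principal-value
shifts $F_\pm(t)$) and a one-quantum branch (off-diagonal); tracing out both
reservoirs leaves an X-shaped reduced density matrix whose non-zero elements
are the closed forms implemented in `lambda_elements()`:

$$\Lambda_{14} = \alpha\beta\, e^{-(\Gamma_1+\Gamma_2)t/2} e^{i(\Delta_1+\Delta_2)t},
\quad \Lambda_{22} = \beta^2(1 - e^{-\Gamma_1 t})e^{-\Gamma_2 t},
\quad \Lambda_{33} = \beta^2 e^{-\Gamma_1 t}(1 - e^{-\Gamma_2 t}),
\quad \Lambda_{44} = \beta^2 e^{-(\Gamma_1+\Gamma_2)t}.$$

The survival probability of the initial state,

$$P(t) = \alpha^4 + \beta^4 e^{-(\Gamma_1+\Gamma_2)t}
  + 2\alpha^2\beta^2 e^{-(\Gamma_1+\Gamma_2)t/2}\cos\big((\Delta_1+\Delta_2)t\big),$$

oscillates at the combined splitting inside an envelope set by the combined
decay rate, and entanglement is quantified by the Wootters concurrence, which
for this family reduces to

$$C(t) = \max\Big\{0,\; 2\alpha\beta\, e^{-(\Gamma_1+\Gamma_2)t/2}
  - 2\beta^2 e^{-(\Gamma_1+\Gamma_2)t/2}
  \sqrt{(1-e^{-\Gamma_1 t})(1-e^{-\Gamma_2 t})}\Big\}.$$

When $\beta > \alpha$ the bracket crosses zero at a finite time while the
$|11\rangle$ population is still positive — entanglement sudden death.
`sudden_death_time()` locates that root by bracketed bisection to 1e-10;
analytically it satisfies
$\sqrt{(1-e^{-\Gamma_1 t^*})(1-e^{-\Gamma_2 t^*})} = \alpha/\beta$.

```{r}
ed <- entanglement_dynamics(alpha = 0.6, beta = 0.8, delta1 = 1, delta2 = 1,
                            gamma1 = 1, gamma2 = 1, t_max = 6, n_steps = 121)
ed
```

## Sign conventions in the population factors

Taken literally, factors of the form $(1 - e^{+\Gamma t})$ in the grown
populations and under the square root of the concurrence would be negative
(or imaginary) for $\Gamma, t > 0$, which contradicts the decaying
exponentials carried by $\Lambda_{44}$, $\Lambda_{14}$ and by the survival
probability, and would break $0 \le \Lambda_{ii} \le 1$. This package
therefore reads every such factor as $(1 - e^{-\Gamma t})$ — the standard
amplitude-damping population growth. The choice is not merely cosmetic: it is
validated by a dedicated dual-route test in which the closed-form concurrence
above is compared, over thousands of parameter/time points, with the general
spin-flip eigenvalue procedure applied to the assembled density matrix; the
two agree to better than 1e-8 (in practice to machine precision). Similarly,
the closed form is clamped at zero because the Wootters definition carries a
`max{0, .}`; a test demonstrates that the unclamped expression goes negative
exactly where the eigenvalue procedure returns 0.

The two diagonal growth terms are assigned symmetrically, $\Lambda_{22}$
growing with channel 1's decay while still decaying under channel 2 and vice
versa for $\Lambda_{33}$, matching the X-matrix layout under the exchange
$1 \leftrightarrow 2$.

## Two density-matrix modes

The truncated perturbative trace is not automatically trace-preserving: with
$\Lambda_{11} = \alpha^2$ held fixed the trace decays to
$\alpha^2 + \beta^2(e^{-\Gamma_1 t} + e^{-\Gamma_2 t} -
e^{-(\Gamma_1+\Gamma_2)t})$. Both conventions are exposed:

* `mode = "paper"` keeps $\Lambda_{11} = \alpha^2$ (the trace leaks, and the
  leak is asserted against the closed form above);
* `mode = "trace_preserving"` (default) feeds the doubly decayed population
  back, $\Lambda_{11} = \alpha^2 + \beta^2(1-e^{-\Gamma_1 t})
  (1-e^{-\Gamma_2 t})$, which is the completely positive amplitude-damping
  result with unit trace.

The concurrence is identical in both modes, because the branch of the X-state
concurrence that involves $\Lambda_{11}$ (namely
$|\Lambda_{23}| - \sqrt{\Lambda_{11}\Lambda_{44}}$) is never the positive
one here; a test asserts the equality. One subtlety follows: the closed form
is derived from the raw matrix elements, so `entanglement_dynamics()`
evaluates its numeric cross-check *without* renormalising by the trace. The
standalone `wootters_concurrence()` defaults to renormalising, since the
definition presumes a density operator; `normalize = FALSE` recovers the raw
convention.

## Numerical evaluation of the concurrence

`wootters_concurrence()` needs the descending square roots $\sqrt{\lambda_i}$
of the eigenvalues of
$\rho(\sigma_y\otimes\sigma_y)\rho^*(\sigma_y\otimes\sigma_y)$. Taking the
square root after a general eigendecomposition loses half the working
precision when $\lambda_i$ underflows toward zero (an absolute error of
1e-15 in $\lambda$ becomes ~3e-8 in $\sqrt\lambda$), so the implementation
computes the $\sqrt{\lambda_i}$ directly as the singular values of
$\sqrt{\tilde\rho}\sqrt{\rho}$, which has the same spectrum in exact
arithmetic and keeps the dual-route comparison at machine precision. A test
checks the SVD route against the plain eigendecomposition route. The
closed-form eigenvalues of the X state,
$\lambda_1 = \lambda_2 = \Lambda_{22}\Lambda_{33}$ and
$\lambda_{3,4} = (\sqrt{\Lambda_{11}\Lambda_{44}} \mp |\Lambda_{14}|)^2$,
are exposed by `xstate_eigenvalues()` and validated against a brute-force
eigensolver; published shorthand for $\lambda_{3,4}$ that differs from this
standard form is deliberately not reproduced symbol-by-symbol — only through
the concurrence equivalence, which both routes must (and do) satisfy.

Entanglement of formation is the closed two-qubit function
$E(C) = h\big((1+\sqrt{1-C^2})/2\big)$ with $h$ the binary entropy
(`binary_entropy()`, with $0\log 0 := 0$).

## Bath spectra and quadrature

The reservoirs belong to the Ohmic family,
$J(\omega) = \eta\,\omega(\omega/\omega_c)^{s-1}e^{-\omega/\omega_c}$
(`ohmic_spectrum()`; $s = 1$ Ohmic, $s<1$ sub-Ohmic, $s>1$ super-Ohmic), and
the second-order kernel concentrating the bath response is the mode density
$D(\omega, t) = \frac{1}{2\pi t}\{\sin(\omega t/2)/(\omega/2)\}^2$, with
removable-singularity value $t/(2\pi)$ at $\omega = 0$ and total mass 1/2 on
$[0,\infty)$ for every $t > 0$ (asserted against the analytic value).

The decay rate is the weighted overlap

$$\Gamma(t) = \frac{|f_{01}|^2\eta}{\pi\tilde h}\int_0^\infty
\Big(\frac{\omega}{\omega_c}\Big)^{s-1}\omega\, e^{-\omega/\omega_c}\,
\frac{1}{t}\Big\{\frac{\sin(\omega t/2)}{\omega/2}\Big\}^2 d\omega,$$

evaluated by adaptive quadrature truncated at $50\,\omega_c$; the
exponential cutoff makes the discarded tail certifiable (the code checks it
is below 1e-12 of the integral) and the result is asserted against an
independent dense Simpson oracle. The rates $\Gamma_i$ used by the dynamics
may be taken from this profile or supplied directly; the closed forms of the
dynamics treat them as constants, so the profile is a diagnostic for choosing
a plateau value rather than a time-dependent input. Likewise the splittings
$\Delta_i$ are always direct inputs — they are properties of the double-well,
not of the spectrum.

The phase shifts
$F_\pm(t) = -\pi^{-1}\mathcal{P}\int_0^\infty J(\omega)
\frac{\sin((\omega\pm\Delta)t)}{(\omega\pm\Delta)^2}\,d\omega$
are regular for the $+$ branch but carry a simple pole at $\omega = \Delta$
for the $-$ branch. The principal value is computed by symmetric-window
subtraction: on $[\Delta-h, \Delta+h]$ the paired combination
$\{J(\Delta+u) - J(\Delta-u)\}\sin(ut)/u^2$ is regular at $u = 0$ (limit
$2J'(\Delta)t$) and is integrated as an ordinary integral, with plain
adaptive quadrature on the two tails. The scheme is validated against a
paired-sample brute-force oracle on both box and Ohmic spectra. These shifts
only enter the diagnostic propagator phases (`propagator_elements()`); they
cancel from every reported observable, which is why the dynamics itself needs
no quadrature at all.

## Units and the decoherence-time estimator

`units_system()` constructs the dimensionless Planck constant
$\tilde h = \hbar/(U_0\tau_0)$ from the characteristic length, energy and
mass of the double-well; all three algebraically equivalent forms are
evaluated and must agree to 1e-12, so unit mistakes surface immediately. All
model-level quantities (times, splittings, rates) are dimensionless in these
units; $\tilde h$ defaults to 1 in `decay_rate()`.

The order-of-magnitude estimator $t_D \simeq t_R\,\lambda_T/\Delta x$ is
provided with two conventions for the thermal de Broglie wavelength. The
default is the standard $\lambda_T = \hbar/\sqrt{2mk_BT}$, which is the form
with units of length that the ratio requires; the variant
$\hbar\sqrt{2mk_BT}$ appears in some published statements of the estimate but
is dimensionally anomalous, and is kept only behind
`convention = "as_printed"`. No reference parameter values are bundled, so
the estimator is a tool, not a reproduction of any particular printed number.

## Sweeps, defaults and what the tests do (and do not) show

The exact parameter values behind the published figure panels are not
available in the main text, so `run_sweep()` uses documented defaults chosen
once: coupling ratios $\kappa = \Gamma_i/\Delta_i \in \{0.05, 0.1, 0.3\}$
(weak to moderate damping, below the overdamped regime), splittings
$\Delta \in \{0.2, 1, 5\}$ spanning slow to fast tunneling around the
fully quantum point $\Delta = 1$, the maximally entangled initial state, and
$t \in [0, 20]$ with 400 steps (several coherence times at the weakest
damping). Only the qualitative caption claims are asserted: the survival
envelope is ordered inversely in the total decay rate; the time for the
concurrence to fall below 0.01 is non-increasing in $\kappa$; and for a
fixed total rate $\Gamma_1 + \Gamma_2$ the symmetric split
$\Gamma_1 = \Gamma_2$ maximises $(1-e^{-\Gamma_1 t})(1-e^{-\Gamma_2 t})$ and
hence destroys entanglement fastest — environments with similar properties
decohere the pair most efficiently. Passing these tests shows the
implemented closed forms have the claimed orderings; it does not certify any
quantitative correspondence with the published curves, nor anything about
real cellular environments, which are neither vacuum-state bosonic baths nor
weakly coupled.

Degenerate inputs are handled explicitly: $t = 0$ returns the exact initial
state, $\Gamma_i = 0$ freezes the populations, $\eta = 0$ or $f_{01} = 0$
silences a channel, $\Delta = 0$ leaves an integrable endpoint singularity
in $F_-$ that the quadrature treats without principal-value machinery, and
$\omega = 0$ evaluates all spectral kernels by their limits.

## Known limitations

* Second-order perturbation theory: the closed forms are trustworthy for
  weak coupling ($\kappa \lesssim$ a few tenths) and do not resum higher
  orders; the intermediate short-time linearisations that a derivation
  passes through are not exposed, only the resummed exponential forms.
* Zero-temperature reservoirs only; no thermal occupation, no non-Ohmic
  structure beyond the $(s, \omega_c)$ family.
* The level shifts $\delta E_{0,i}, \delta E_{1,i}$ have no closed form at
  this order in the implemented model and default to 0; they affect only the
  diagnostic propagator phases.
* Entanglement measures beyond concurrence/EoF (negativity, discord) and
  initial states outside the $\alpha|00\rangle + \beta|11\rangle$ family are
  out of scope; the random-density-matrix generator exists for testing, not
  as model surface.
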