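Package: nessflow
Title: Helmholtz Decomposition of Stochastic Flows and Nonequilibrium
    Steady-State Densities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Turns stochastic equations of motion into an explicit
    nonequilibrium steady-state (NESS) density via a polynomial-parameterised
    generalised Helmholtz decomposition f = (Q - Gamma) grad(I) - Lambda, with
    the Lorenz and coupled-Lorenz systems as built-in worked examples. Under a
    quadratic (Laplace) truncation the steady state is Gaussian, and the
    package reads off conditional independencies, Markov boundaries and
    particular partitions (external, sensory, active, internal states) from
    the precision matrix; estimates expected Lyapunov exponents and the
    Kaplan-Yorke dimension under the fitted density; integrates the
    Fokker-Planck equation in surprisal form on a grid, with information
    length; and exposes the Bayesian-mechanics layer: synchronisation maps,
    variational free energy and its gradient flows.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
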