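# ibflow

Joint collective-variable learning and equilibrium-density generation for
molecular trajectories, in one fitted model.

`ibflow` is for researchers who have time-ordered molecular descriptor
trajectories (or want to generate benchmark ones) and need, from a single
fit: low-dimensional collective variables (CVs) that capture the slow
dynamics, a metastable-state decomposition, an exact density estimate over
the CVs, equilibrium samples at training and unseen temperatures, and
physically sensible transition-path interpolations.

## The model

A time-lagged variational information bottleneck is trained jointly with a
RealNVP normalizing flow under an exponentially tilted Gaussian prior:

- an encoder maps descriptors $X_t$ to a 2D latent mean $\mu_\theta(X_t)$;
  the Gaussian posterior is $u = \mu_\theta + \sigma_\theta\,\varepsilon$
  with one learnable global scale $\sigma_\theta$;
- a decoder predicts the metastable state occupied after a lag $\Delta t$,
  with labels refined iteratively (short-lived states get absorbed);
- an invertible coupling flow $f_\theta$ maps the latent distribution onto
  the prior $r_{T}(z,\tau) \propto \exp\!\big(-\lVert z\rVert^2/2T +
  \tau\lVert z\rVert\big)$, whose density peaks on the shell
  $\lVert z\rVert = \tau T$ and whose variance and peak radius scale
  linearly with the steerable temperature $T$.

The unified objective is the future-state cross-entropy plus
$\beta\,[\log q(u\mid X_t) - \log r(f(u)) - \log|\det J_f(u)|]$. Exact
per-frame likelihoods come from the change of variables; generation samples
the prior at any temperature and pulls back through the inverse flow.

Everything is base R plus a small amount of compiled code for the Langevin
simulators; the coupling-network gradients are hand-derived reverse-mode.

## Worked example

Three-hole model potential: simulate, fit, inspect, generate.

```r
library(ibflow)

traj <- simulate_langevin(sim_protocol("three_hole", n_steps = 5e6), seed = 7)
fit  <- ibflow(traj, lag = 10, tau = 2.5, k_init = 6, seed = 11,
               control = ibflow_control(epochs_stage1 = 6, max_refine = 15,
                                        epochs_stage2 = 40,
                                        max_pairs_per_epoch = 20000,
                                        epochs_polish = 60))
print(fit)
#> latent-flow bottleneck model
#>   features: 2, latent dim: 2, lag: 10 frames
#>   prior: tilted Gaussian, tau = 2.5; flow: 6 blocks
#>   states: 3, populations: 0.418 0.479 0.104
#>   posterior scale sigma = 0.1892, beta = 0.01
```

The fit resolves the potential's three basins (two deep wells plus the
upper-channel shallow minimum; the ~10% state is the upper basin). From
here:

```r
samples <- simulate(fit, nsim = 1e5, seed = 3, temperature = 1)  # generation
ll      <- score_frames(fit, traj$frames)      # exact log-likelihood per frame
reps    <- state_representatives(fit, traj$frames)  # most likely frame per state
msm     <- build_msm(fit$labels$labels, lag = 10)   # decoded-label MSM
```

`generation_kl()` measures the symmetric KL divergence between generated
samples and the latent distribution of held-out data (on the fit above,
about 0.06-0.13 depending on the refinement budget; the acceptance script prints the exact value it measures); `select_tau()` screens tilting
factors by exactly this criterion, and `cv_benchmark()` compares the full
model against the vanilla VampPrior baseline (`type = "spib"`) fold by
fold, reporting generation KL and the GMRQ score of the decoded states.

For multi-temperature work, pass a list of trajectories whose
`temperature` fields hold the physical temperatures; generation then takes
any steerable temperature (1 = the lowest training temperature):

```r
lj <- list(simulate_langevin(sim_protocol("lj7", kT = 0.2), seed = 21),
           simulate_langevin(sim_protocol("lj7", kT = 0.5), seed = 22))
fit <- ibflow(lj, lag = 2, tau = 2, k_init = 10, init_space = "moments",
              seed = 31)
hot <- simulate(fit, nsim = 5e4, temperature = 3.5, seed = 1)  # kT = 0.7
```

A thin command-line wrapper over these functions is at
`inst/scripts/ibflow-cli.R` (subcommands `simulate`, `train`, `generate`,
`evaluate`).

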