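# Shared fixtures: baseline parameters and small perturbed draws.

baseline <- signalling_params()

# log-uniform perturbation of the baseline rates around their defaults
random_params <- function(seed, spread = 3) {
  withr::with_seed(seed, {
    lu <- function(x) x * exp(stats::runif(1, -log(spread), log(spread)))
    signalling_params(
      bD = lu(100), bJ = lu(100), bN = lu(500), bR = lu(800),
      beta = lu(0.1), betaS = lu(0.5), kho = lu(1e-4), khe = lu(1e-3),
      kt = lu(5e-5), kci = lu(6e-4), kv = lu(5e-5), alpha = 1e-4)
  })
}

# steady free-ligand levels by direct long-time RK4 on the decoupled
# (D, J) subsystem -- the integration oracle for the cubic solver
integrate_ligands <- function(params, Next = 0, t_end = 3000) {
  p <- params
  pp <- p$beta + p$kt * Next
  qq <- p$beta + p$alpha * p$kt * Next
  rhs <- function(s) {
    c(D = p$bD - pp * s[["D"]] - 2 * p$kho * s[["D"]]^2 -
        p$khe * s[["J"]] * s[["D"]],
      J = p$bJ - qq * s[["J"]] - p$khe * s[["D"]] * s[["J"]])
  }
  tol <- 1e-7 * max(p$bD, p$bJ, 1)
  rk4_integrate(rhs, c(D = 0, J = 0), h = 0.01, t_end = t_end,
                steady_tol = tol, check_every = 200L,
                record_every = 1e6)$final_state
}
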