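# Shared fixtures, built in code.

# n draws from a standard bivariate normal with correlation rho
make_bvn <- function(n, rho, seed) {
  set.seed(seed)
  z <- matrix(rnorm(2 * n), ncol = 2)
  cbind(z[, 1], rho * z[, 1] + sqrt(1 - rho^2) * z[, 2])
}

# independent numerical oracle for P(X <= h, Y <= k)
pbvn_oracle <- function(h, k, r) {
  if (h == Inf && k == Inf) return(1)
  if (h == -Inf || k == -Inf) return(0)
  if (h == Inf) return(pnorm(k))
  if (k == Inf) return(pnorm(h))
  integrate(function(x) dnorm(x) * pnorm((k - r * x) / sqrt(1 - r^2)),
            -Inf, h, rel.tol = 1e-12, abs.tol = 1e-14)$value
}

# short sampler settings for tests where chain conventions are not the point
quick_mcmc <- function(seed) {
  mcmc_config(chain_length = 2500, estimate_window = 1000, seed = seed)
}
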