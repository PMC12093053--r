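# Shared helpers: random simplex points and small scenario fixtures.

random_simplex <- function(n = 1) {
  x <- matrix(stats::rexp(3 * n), ncol = 3)
  x / rowSums(x)
}

# Independent numerical integration of the two-hit chain (oracle for the
# closed-form solution). Uses a high-accuracy adaptive integrator.
ode_chain <- function(x0, mu1, mu2, t) {
  rhs <- function(time, y, parms) {
    list(c(-parms[1] * y[1],
           parms[1] * y[1] - parms[2] * y[2],
           parms[2] * y[2]))
  }
  out <- deSolve::ode(y = as.numeric(x0), times = c(0, t), func = rhs,
                      parms = c(mu1, mu2), method = "lsoda",
                      rtol = 1e-12, atol = 1e-14)
  as.numeric(out[nrow(out), -1])
}

# Power iteration on the composed fragmentation operator: the iterative
# oracle for the closed-form dominant eigenvector.
power_limit <- function(f, mu1, mu2, TF, iters = 2000L) {
  M <- transfer_operator(mu1, mu2, TF) %*% diag(as.numeric(f))
  x <- c(1, 1, 1) / 3
  for (i in seq_len(iters)) x <- as.vector(M %*% x) / sum(M %*% x)
  x
}

# Tiny scenario for fast population tests.
small_config <- function(...) {
  args <- list(name = "test", phi = 0.5, I = 0.5, theta = 0.3, s = 1.25,
               f = c(5, 1, 0.5), TU = 35, TF = 15,
               fitness = fitness_params(epsilon = 2, tau = 0.5,
                                        delta = 0.4, b0 = 0.5))
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(scenario_config, args)
}
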