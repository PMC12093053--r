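test_that("baseline rate is positive, decreasing in suppression, and matches its closed form", {
  expect_equal(eta_rate(0.5), 0.05 * exp(-1.5))
  I <- seq(0.05, 0.95, by = 0.05)
  r <- eta_rate(I)
  expect_true(all(r > 0))
  expect_true(all(diff(r) < 0))
  expect_error(eta_rate(0), "0, 1")
  expect_error(eta_rate(1), "0, 1")
})

test_that("rate construction follows the fidelity-bias and APSC-surcharge rules", {
  eta <- eta_rate(0.4)
  r <- make_rates(0.4, s = 1, theta = 0)
  expect_equal(r$mu1, eta)
  expect_equal(r$k1, eta)

  r <- make_rates(0.4, s = 0.5, theta = 0)
  expect_equal(r$mu1, 1.5 * eta)
  expect_equal(r$k1, 0.5 * eta)

  # germline-protected strategy with proliferative APSCs
  r <- make_rates(0.4, s = 1.5, theta = 0.7)
  expect_equal(r$mu1, 1.7 * 0.5 * eta)
  expect_equal(r$k1, 1.5 * eta)

  # second hits always 1.5x first hits
  for (s in c(0.5, 0.75, 1, 1.25, 1.5)) {
    r <- make_rates(0.3, s, theta = 0.2)
    expect_identical(r$mu2, 1.5 * r$mu1)
    expect_identical(r$k2, 1.5 * r$k1)
  }
  expect_error(make_rates(0.4, s = 2), "\\(0, 2\\)")
  expect_error(make_rates(0.4, s = 1, theta = 1), "\\[0, 1\\)")
})

test_that("closed-form propagation matches its analytic structure", {
  x0 <- cell_composition(c(0.6, 0.3, 0.1))
  expect_equal(unclass(propagate(x0, 0.02, 0.03, 0))[1:3],
               unclass(x0)[1:3])
  x <- propagate(c(1, 0, 0), 0.02, 0.03, 35)
  expect_equal(x[["normal"]], exp(-0.7))
  expect_equal(sum(x), 1)
  # defective ancestors never regain normal cells
  x <- propagate(c(0, 1, 0), 0.05, 0.02, 40)
  expect_identical(x[["normal"]], 0)
  expect_error(propagate(c(1, 0, 0), 0.02, 0.03, -1), "non-negative")
})

test_that("propagation agrees with an adaptive ODE integration", {
  skip_if_not_installed("deSolve")
  set.seed(11)
  for (i in 1:25) {
    x0 <- random_simplex()
    mu <- runif(2, 0, 0.2)
    t <- runif(1, 0, 100)
    got <- unclass(propagate(x0, mu[1], mu[2], t))[1:3]
    ref <- ode_chain(x0, mu[1], mu[2], t)
    expect_lt(max(abs(got - ref)), 1e-9)
  }
})

test_that("propagation conserves the simplex and is monotone in time", {
  set.seed(21)
  for (i in 1:50) {
    x0 <- random_simplex()
    mu <- runif(2, 0, 0.2)
    ts <- sort(runif(5, 0, 80))
    xs <- t(vapply(ts, function(t) unclass(propagate(x0, mu[1], mu[2], t))[1:3],
                   numeric(3)))
    expect_true(all(xs >= 0 & xs <= 1))
    expect_equal(rowSums(xs), rep(1, 5))
    expect_true(all(diff(xs[, 1]) <= 1e-14))   # normal non-increasing
    expect_true(all(diff(xs[, 3]) >= -1e-14))  # cancerous non-decreasing
  }
})

test_that("the equal-rate branch joins the generic branch continuously", {
  x0 <- c(0.5, 0.4, 0.1)
  mu <- 0.05
  at_limit <- unclass(propagate(x0, mu, mu, 20))[1:3]
  for (eps in c(1e-6, 1e-8, 1e-10)) {
    near <- unclass(propagate(x0, mu, mu + eps, 20))[1:3]
    expect_lt(max(abs(near - at_limit)), 1e-5)
  }
  near <- unclass(propagate(x0, mu, mu + 1e-11, 20))[1:3]
  expect_lt(max(abs(near - at_limit)), 1e-8)
})

test_that("the transfer operator is the linear form of propagation", {
  expect_equal(transfer_operator(0.1, 0.2, 0), diag(3))
  set.seed(31)
  for (i in 1:20) {
    mu <- runif(2, 0, 0.2)
    t <- runif(1, 0, 60)
    M <- transfer_operator(mu[1], mu[2], t)
    expect_true(all(M >= 0))
    expect_equal(colSums(M), rep(1, 3))
    expect_equal(M[upper.tri(M)], rep(0, 3))
    expect_equal(diag(M), c(exp(-mu[1] * t), exp(-mu[2] * t), 1))
    x0 <- random_simplex()
    expect_equal(as.vector(M %*% as.numeric(x0)),
                 unname(unclass(propagate(x0, mu[1], mu[2], t))[1:3]),
                 tolerance = 1e-12)
    # semigroup property M(t1 + t2) = M(t2) M(t1)
    t2 <- runif(1, 0, 60)
    expect_equal(transfer_operator(mu[1], mu[2], t + t2),
                 transfer_operator(mu[1], mu[2], t2) %*% M,
                 tolerance = 1e-12)
  }
})

test_that("APSC coupling blends compositions convexly", {
  expect_equal(unclass(couple_somatic(c(1, 0, 0), c(0.8, 0.2, 0), 0.5))[1:3],
               c(normal = 0.9, defective = 0.1, cancerous = 0))
  s <- cell_composition(c(0.7, 0.2, 0.1), role = "somatic")
  expect_equal(unclass(couple_somatic(c(1, 0, 0), s, 0))[1:3],
               unclass(s)[1:3])
  # fixed point when both compartments agree
  expect_equal(unclass(couple_somatic(c(0.5, 0.3, 0.2), c(0.5, 0.3, 0.2), 0.8))[1:3],
               c(normal = 0.5, defective = 0.3, cancerous = 0.2))
  expect_error(couple_somatic(c(1, 0, 0), c(1, 0, 0), 1), "\\[0, 1\\)")
})

test_that("log2 replication counts reproduce the zygote/fragment comparison", {
  expect_identical(replications_to_maturity(1024), 10)
  expect_identical(replications_to_maturity(1024, 128), 3)
  expect_error(replications_to_maturity(64, 128), "exceeds")
})
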