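test_that("the composition term reproduces the normal-vs-cancer comparison", {
  p1 <- fitness_params(alphaN = 1, alphaD = 0, alphaC = 0, epsilon = 1)
  p2 <- fitness_params(alphaN = 1, alphaD = 0, alphaC = 0, epsilon = 2)
  expect_equal(composition_term(c(1, 0, 0), p1), 1)
  expect_equal(composition_term(c(0.9, 0, 0.1), p1), 0.9)
  expect_equal(composition_term(c(1, 0, 0), p2), 1)
  expect_equal(composition_term(c(0.9, 0, 0.1), p2), 0.81)
  # equal coefficients at epsilon = 1 collapse to the common value
  pa <- fitness_params(alphaN = 0.37, alphaD = 0.37, alphaC = 0.37, epsilon = 1)
  set.seed(81)
  for (i in 1:10) expect_equal(composition_term(random_simplex(), pa), 0.37)
})

test_that("a steeper fatality exponent penalizes cancer increments more", {
  set.seed(91)
  for (i in 1:30) {
    # normal/cancerous mixtures, as in the pure-to-10%-cancer comparison
    N <- runif(1, 0.5, 1)
    x <- c(N, 0, 1 - N)
    shift <- runif(1, 0.01, 0.5) * N
    y <- x + c(-shift, 0, shift)  # move mass from normal to cancerous
    p1 <- fitness_params(alphaN = 1, alphaD = 0.5, alphaC = 0, epsilon = 1)
    p2 <- fitness_params(alphaN = 1, alphaD = 0.5, alphaC = 0, epsilon = 2)
    drop1 <- composition_term(x, p1) - composition_term(y, p1)
    drop2 <- composition_term(x, p2) - composition_term(y, p2)
    # relative to the starting value, epsilon = 2 loses strictly more
    expect_gt(drop2 / composition_term(x, p2),
              drop1 / composition_term(x, p1))
  }
})

test_that("damage cost declines with regeneration capability", {
  expect_equal(damage_cost(0.5, 0.4, 0), 0.2)
  expect_equal(damage_cost(0, 0.9, 0.5), 0)
  expect_equal(damage_cost(0.3, 0.1, 0.7), 0.03 * (1 - 0.49))
  th <- seq(0, 0.95, by = 0.05)
  expect_true(all(diff(damage_cost(0.3, 0.2, th)) < 0))
  # alternative exponent placement is also monotone decreasing
  alt <- vapply(th, damage_cost, numeric(1), tau = 0.3, delta = 0.2,
                chi_form = "sq_one_minus_theta")
  expect_true(all(diff(alt) < 0))
  expect_equal(damage_cost(0.3, 0.2, 0.5, "sq_one_minus_theta"), 0.06 * 0.25)
})

test_that("suppression cost is quadratic in capability", {
  expect_equal(suppression_cost(0, 0.8), 0)
  expect_equal(suppression_cost(2, 0.3), 2 * 0.09)
  set.seed(101)
  I <- runif(10, 0.05, 0.45)
  expect_equal(suppression_cost(1.3, 2 * I), 4 * suppression_cost(1.3, I))
})

test_that("organism fitness assembles its pieces and never goes negative", {
  p <- fitness_params(omega0 = 0.5, alphaN = 1, alphaD = 0.5, alphaC = 0,
                      epsilon = 2, tau = 0, delta = 0, c0 = 0)
  expect_equal(organism_fitness(c(1, 0, 0), theta = 0, I = 0.5, p), 1.5)
  # costs exceeding the benefit clamp to zero
  p2 <- fitness_params(omega0 = 0.1, alphaN = 0.1, alphaD = 0, alphaC = 0,
                       epsilon = 1, tau = 1, delta = 1, c0 = 5)
  expect_identical(organism_fitness(c(1, 0, 0), theta = 0, I = 0.9, p2), 0)
  # moving mass into cancer never raises fitness
  set.seed(111)
  for (i in 1:25) {
    x <- random_simplex()
    shift <- runif(1, 0, x[1])
    y <- x + c(-shift, 0, shift)
    pr <- fitness_params(alphaN = 1, alphaD = runif(1, 0, 1), alphaC = 0,
                         epsilon = runif(1, 1, 2))
    expect_lte(organism_fitness(y, 0.2, 0.5, pr),
               organism_fitness(x, 0.2, 0.5, pr) + 1e-12)
  }
})

test_that("the diversity coefficient has the stated boundary values and shape", {
  expect_equal(diversity_coefficient(0, 0.25), 1)
  expect_equal(diversity_coefficient(1, 0.25), 0.25)
  expect_equal(diversity_coefficient(0.5, 0.7), 0.7 + 0.3 * 0.5^(1 / 4))
  for (b0 in c(0.1, 0.5, 0.9)) {
    rho <- seq(0, 1, length.out = 201)
    H <- diversity_coefficient(rho, b0)
    expect_true(all(H >= b0 - 1e-12 & H <= 1 + 1e-12))
    expect_true(all(diff(H) < 0))
    expect_true(all(diff(diff(H)) < 1e-12))  # concave
  }
  # quartic alternative shares boundaries and monotonicity
  Hq <- diversity_coefficient(seq(0, 1, 0.01), 0.3, H_form = "quartic")
  expect_equal(Hq[1], 1)
  expect_equal(Hq[101], 0.3)
  expect_true(all(diff(Hq) < 0))
  expect_error(diversity_coefficient(1.2, 0.5), "\\[0, 1\\]")
})
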