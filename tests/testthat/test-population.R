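test_that("zygote probabilities weight the germline by gamete functionality", {
  u <- zygote_probabilities(c(0.5, 0.3, 0.2), 1, 0.5, 0.1)
  expect_equal(u$U1, 0.5 / 0.67)
  expect_equal(u$U2, 0.15 / 0.67)
  expect_lte(u$U1 + u$U2, 1)
  # no normal germ cells -> no normal zygotes, ever
  u <- zygote_probabilities(c(0, 0.8, 0.2), 1, 0.5, 0.1)
  expect_identical(u$U1, 0)
  # cancer-free germline with uniform weights is the identity
  u <- zygote_probabilities(c(0.7, 0.3, 0), 1, 1, 0.4)
  expect_equal(u$U1, 0.7)
  expect_equal(u$U2, 0.3)
  expect_error(zygote_probabilities(c(0, 0, 1), 1, 1, 0), "viable")
})

test_that("the regulation transform is bounded, monotone and neutral at 1", {
  expect_equal(theta_transform(1), 1)
  x <- exp(seq(log(1e-3), log(1e3), length.out = 2001))
  th <- theta_transform(x)
  expect_true(all(th >= 0.9391 & th <= 1.08))
  expect_true(all(diff(th) >= 0))
  expect_error(theta_transform(0), "positive")
  # steepness changes the shape, not the anchor or the bounds
  for (k in c(2, 20, 100)) {
    expect_equal(theta_transform(1, k = k), 1)
    expect_true(all(theta_transform(x, k = k) >= 0.9391 &
                      theta_transform(x, k = k) <= 1.08))
  }
})

test_that("maturity states follow the zygote and fragment development paths", {
  rates <- make_rates(0.5, 1.25, 0.4)
  fp <- fitness_params(epsilon = 2, tau = 0.3, delta = 0.2)
  nu <- maturity_state("NU", rates, 0.4, 35, 15, fp, I = 0.5)
  du <- maturity_state("DU", rates, 0.4, 35, 15, fp, I = 0.5)
  # defective ancestors have no normal cells in either compartment
  expect_identical(du$germline[["normal"]], 0)
  expect_identical(du$somatic[["normal"]], 0)
  expect_equal(nu$germline[["normal"]], exp(-rates$mu1 * 35))
  # theta = 0: somatic compartment is the pure somatic chain
  nu0 <- maturity_state("NU", make_rates(0.5, 1.25, 0), 0, 35, 15, fp, I = 0.5)
  expect_equal(unclass(nu0$somatic)[1:3],
               unclass(propagate(c(1, 0, 0), rates$k1, rates$k2, 35))[1:3])
  # equal inheritance from an all-normal-ish parent: NF1 == fragment aged TF
  rates1 <- make_rates(0.5, 1, 0)
  nu1 <- maturity_state("NU", rates1, 0, 35, 15, fp, I = 0.5)
  nf1 <- maturity_state("NF", rates1, 0, 35, 15, fp, I = 0.5,
                        parent = nu1, f = c(1, 1, 1))
  expect_equal(unclass(nf1$germline)[1:3],
               unclass(propagate(nu1$germline, rates1$mu1, rates1$mu2, 15))[1:3])
  expect_identical(nf1$depth, 1L)
  expect_error(maturity_state("NF", rates, 0.4, 35, 15, fp, I = 0.5),
               "parent")
})

test_that("one generation step matches hand evaluation of the recursion", {
  cfg <- small_config()
  tab <- fragevo:::lineage_table(cfg, 5L)
  state <- list(V = 1, W = 0, Z = numeric(5), Q = numeric(5), P = 1,
                rho = 0, H = 1)
  nxt <- fragevo:::step_generation(state, tab, cfg)
  # hand evaluation of the inflow equations for a pure founder population
  omega_v <- tab$omega$V
  u <- zygote_probabilities(tab$NU$germline, cfg$r1, cfg$r2, cfg$r3)
  V_star <- cfg$deltaV * (1 - cfg$phi) * omega_v * u$U1
  W_star <- cfg$deltaW * (1 - cfg$phi) * omega_v * u$U2
  Z1_star <- cfg$phi * omega_v
  P_star <- V_star + W_star + Z1_star
  th <- theta_transform(P_star / 1, k = cfg$theta_k)
  scale <- th / P_star  # realized total is Theta(ratio) * P_j
  expect_equal(nxt$V, V_star * scale)
  expect_equal(nxt$W, W_star * scale)
  expect_equal(nxt$Z[1], Z1_star * scale)
  expect_equal(sum(nxt$Q), 0)
  expect_equal(nxt$P, th)
})

test_that("fragmentation switches route the offspring as expected", {
  # phi = 0: no clones ever arise
  cfg <- small_config(phi = 0, theta = 0)
  r <- run_pedigree(cfg, 12)
  expect_true(all(r$trajectory$Ztot == 0))
  expect_true(all(r$trajectory$Qtot == 0))
  expect_true(all(r$trajectory$rho == 0))
  # phi = 1: no sexual offspring after the founders
  cfg <- small_config(phi = 1)
  r <- run_pedigree(cfg, 12)
  expect_true(all(r$trajectory$V[-1] == 0))
  expect_true(all(r$trajectory$W == 0))
})

test_that("defective lineages never generate normal ones", {
  cfg <- small_config()
  tab <- fragevo:::lineage_table(cfg, 4L)
  state <- list(V = 0, W = 1, Z = numeric(4), Q = numeric(4), P = 1,
                rho = 0, H = 1)
  for (i in 1:6) {
    state <- fragevo:::step_generation(state, tab, cfg)
    expect_identical(state$V, 0)
    expect_identical(sum(state$Z), 0)
  }
})

test_that("realized growth ratios respect the regulation bounds", {
  for (seed in c(3, 17, 29)) {
    cfg <- generate_fixture(seed)
    r <- run_pedigree(cfg, 20)
    ratios <- r$trajectory$P[-1] / r$trajectory$P[-nrow(r$trajectory)]
    expect_true(all(ratios >= 0.9391 - 1e-12 & ratios <= 1.08 + 1e-12))
  }
})

test_that("depth support grows by at most one fragmentation level per generation", {
  cfg <- small_config()
  depth_cap <- 14L
  tab <- fragevo:::lineage_table(cfg, depth_cap)
  state <- list(V = 1, W = 0, Z = numeric(depth_cap), Q = numeric(depth_cap),
                P = 1, rho = 0, H = 1)
  for (j in 1:14) {
    state <- fragevo:::step_generation(state, tab, cfg)
    gen <- j + 1
    if (gen >= 2) expect_true(all(state$Z[seq_len(depth_cap) > gen - 1] == 0))
    if (gen >= 3) expect_true(all(state$Q[seq_len(depth_cap) > gen - 2] == 0))
  }
})

test_that("with no fragmentation the model reduces to a two-type recursion", {
  cfg <- small_config(phi = 0, theta = 0)
  r <- run_pedigree(cfg, 25)
  # independent two-type (NU/DU) reimplementation
  rates <- make_rates(cfg$I, cfg$s, 0)
  fp <- cfg$fitness
  gV <- propagate(c(1, 0, 0), rates$mu1, rates$mu2, cfg$TU)
  sV <- propagate(c(1, 0, 0), rates$k1, rates$k2, cfg$TU)
  gW <- propagate(c(0, 1, 0), rates$mu1, rates$mu2, cfg$TU)
  sW <- propagate(c(0, 1, 0), rates$k1, rates$k2, cfg$TU)
  wV <- organism_fitness(sV, 0, cfg$I, fp)
  wW <- organism_fitness(sW, 0, cfg$I, fp)
  uV <- zygote_probabilities(gV, cfg$r1, cfg$r2, cfg$r3)
  uW <- zygote_probabilities(gW, cfg$r1, cfg$r2, cfg$r3)
  V <- 1; W <- 0
  for (j in 2:25) {
    Vs <- cfg$deltaV * V * wV * uV$U1
    Ws <- cfg$deltaW * (V * wV * uV$U2 + W * wW * uW$U2)
    th <- theta_transform((Vs + Ws) / (V + W), k = cfg$theta_k)
    sc <- th * (V + W) / (Vs + Ws)
    V <- Vs * sc; W <- Ws * sc
    expect_equal(r$trajectory$V[j], V, tolerance = 1e-12)
    expect_equal(r$trajectory$W[j], W, tolerance = 1e-12)
  }
})

test_that("prevalence is the size-weighted mean somatic cancer share", {
  st <- list(V = 3, W = 0, Z = 1, Q = 0, P = 4)
  C <- list(V = 0.1, W = 0, Z = 0.3, Q = 0)
  expect_equal(cancer_prevalence(st, C), 0.15)
  st <- list(V = 0, W = 2, Z = numeric(0), Q = numeric(0), P = 2)
  C <- list(V = 0.1, W = 0.25, Z = numeric(0), Q = numeric(0))
  expect_equal(cancer_prevalence(st, C), 0.25)
  expect_error(cancer_prevalence(list(V = 0, W = 0, Z = 0, Q = 0, P = 0), C),
               "extinct")
})
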