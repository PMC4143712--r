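# independent term-by-term prior density calculator
oracle_log_prior <- function(params, a = 20, b = 20, beta0_sd = 10) {
  lam <- params$lambda
  dlap <- function(x) log(lam / 2) - lam * abs(x)
  f <- params$freq$f
  lo <- max(-f[f < 1] / (1 - f[f < 1]))
  if (params$freq$d < lo || params$freq$d >= 1) return(-Inf)
  total <- sum(vapply(as.numeric(params$B), dlap, 0)) +
    dlap(params$betaE) + sum(vapply(params$betaEh, dlap, 0)) +
    dlap(params$betaS) +
    ((a) * log(b) - lgamma(a) + (a - 1) * log(lam) - b * lam) +
    (-0.5 * log(2 * pi) - log(beta0_sd) -
       params$beta0^2 / (2 * beta0_sd^2)) +
    lgamma(length(f)) - log(1 - lo)
  total
}

test_that("log prior matches an independent density calculator", {
  basis <- spline_basis()
  haps <- c("AA", "AB", "BB", "BA")
  # Laplace density at the mode is log(lambda / 2)
  p0 <- lbl_params(haps, basis, lambda = 3)
  p_shift <- p0; p_shift$betaE <- 0.7
  p_neg <- p0; p_neg$betaE <- -0.7
  expect_equal(log_prior(p_shift), log_prior(p_neg))  # symmetry
  expect_equal(log_prior(p0) - log_prior(p_shift), 3 * 0.7)
  for (s in 1:10) {
    pr <- random_params(haps, basis, seed = 300 + s)
    expect_equal(log_prior(pr), oracle_log_prior(pr), tolerance = 1e-12)
  }
  bad <- random_params(haps, basis, seed = 311)
  bad$freq$d <- -0.999
  expect_identical(log_prior(bad), -Inf)
})

test_that("diplotype Gibbs weights match the exact full conditional", {
  # 20 identical individuals, each ambiguous between two diplotypes
  n <- 20
  a1 <- matrix(rep(c("A", "A"), each = n), n, 2)
  a2 <- matrix(rep(c("G", "G"), each = n), n, 2)
  g <- make_genotypes(a1, a2)
  phe <- as_phenotypes(data.frame(id = sprintf("i%d", 1:n), exam = 1,
                                  y = 1, smoke = 0, age = 60, sex = 0))
  co <- join_cohort(g, phe)
  cl <- haplotype_closure(co$genotypes)
  expect_equal(vapply(cl$supports, nrow, 1L), rep(2L, n))
  basis <- spline_basis()
  freq <- hap_freq_model(cl$haplotypes, c(0.4, 0.3, 0.2, 0.1), d = 0.1)
  m <- length(cl$haplotypes)
  pr <- lbl_params(cl$haplotypes, basis,
                   beta0 = -0.5,
                   B = matrix(seq(-0.6, 0.6, length.out = (m - 1) * 6),
                              m - 1, 6),
                   freq = freq)
  # exact full-conditional weights by enumeration for one individual
  sp <- cl$supports[[1]]
  lw <- vapply(1:2, function(q) {
    pair <- sp[q, ]
    w <- log(diplotype_probability(freq, pair))
    row <- build_design_row(pair, phe[1, ], pr$haplotypes)
    eta <- log_odds(pr, row)
    w + 1 * eta - log(1 + exp(eta))
  }, 0)
  w_exact <- exp(lw - max(lw)); w_exact <- w_exact / sum(w_exact)
  set.seed(99)
  sweeps <- 500
  hits <- 0
  for (s in seq_len(sweeps)) {
    draws <- gibbs_update_diplotypes(pr, co, cl$supports)
    hits <- hits + sum(vapply(draws, function(z)
      all(sort(z) == sp[1, ]), TRUE))
  }
  N <- sweeps * n
  p_hat <- hits / N
  mcse <- sqrt(w_exact[1] * (1 - w_exact[1]) / N)
  expect_lt(abs(p_hat - w_exact[1]), 3 * mcse + 1e-9)

  # flat likelihood: weights reduce to the frequency-model probabilities
  pr_flat <- lbl_params(cl$haplotypes, basis, freq = freq)
  lw0 <- vapply(1:2, function(q)
    log(diplotype_probability(freq, sp[q, ])), 0)
  w0 <- exp(lw0 - max(lw0)); w0 <- w0 / sum(w0)
  set.seed(100)
  hits0 <- 0
  for (s in seq_len(sweeps)) {
    draws <- gibbs_update_diplotypes(pr_flat, co, cl$supports)
    hits0 <- hits0 + sum(vapply(draws, function(z)
      all(sort(z) == sp[1, ]), TRUE))
  }
  p0_hat <- hits0 / N
  mcse0 <- sqrt(w0[1] * (1 - w0[1]) / N)
  expect_lt(abs(p0_hat - w0[1]), 3 * mcse0 + 1e-9)

  # support of size 1 is returned with probability 1
  hom <- make_genotypes(matrix("A", 2, 2), matrix("A", 2, 2))
  phe2 <- as_phenotypes(data.frame(id = c("i1", "i2"), exam = 1, y = 0,
                                   smoke = 0, age = 50, sex = 0))
  co2 <- join_cohort(hom, phe2)
  cl2 <- haplotype_closure(co2$genotypes)
  pr2 <- lbl_params(cl2$haplotypes, spline_basis())
  expect_equal(gibbs_update_diplotypes(pr2, co2, cl2$supports),
               list(c("AA", "AA"), c("AA", "AA")))
})

test_that("chains are bitwise reproducible under a fixed seed", {
  sc <- sim_scenario(n = 40)
  dat <- simulate_dataset(sc, seed = 5)
  co <- join_cohort(dat$genotypes, dat$phenotypes)
  cfg <- lbl_config(n_iter = 400, burnin = 100, thin = 2, seed = 17)
  ch1 <- run_chain(co, config = cfg)
  ch2 <- run_chain(co, config = cfg)
  for (el in c("beta0", "B", "betaE", "betaEh", "betaS", "f", "d",
               "lambda", "fitted"))
    expect_identical(ch1[[el]], ch2[[el]])
  cfg2 <- cfg; cfg2$seed <- 18
  ch3 <- run_chain(co, config = cfg2)
  expect_false(identical(ch1$beta0, ch3$beta0))
})

test_that("posterior means on a tiny instance match grid quadrature", {
  # 2 haplotypes over a single SNP: no phase ambiguity, d fixed at 0,
  # lambda fixed, constant (order-1) basis => a 2-parameter posterior
  a1 <- matrix(c("A", "A", "A", "G", "G", "A", "A", "G"), 8, 1)
  a2 <- matrix(c("A", "G", "G", "G", "G", "A", "G", "G"), 8, 1)
  g <- make_genotypes(a1, a2)
  y <- c(1, 1, 0, 1, 0, 0, 1, 1)
  phe <- as_phenotypes(data.frame(id = sprintf("i%d", 1:8), exam = 1, y = y,
                                  smoke = 0, age = 50, sex = 0))
  co <- join_cohort(g, phe)
  lam_star <- 1
  cfg <- lbl_config(interior_knots = numeric(0), boundary_knots = c(20, 100),
                    spline_order = 1, n_iter = 60000, burnin = 5000,
                    thin = 5, fix_f = TRUE, fix_d = TRUE,
                    fix_lambda = lam_star, seed = 4)
  ch <- run_chain(co, config = cfg)
  expect_equal(length(ch$haplotypes), 2L)
  expect_equal(ch$basis$n_basis, 1L)
  # dosage of the non-reference haplotype per individual
  nonref <- ch$haplotypes[2]
  dose <- (a1[, 1] == nonref) + (a2[, 1] == nonref)
  # quadrature oracle over (beta0, bh)
  gr <- seq(-6, 6, by = 0.02)
  G <- expand.grid(b0 = gr, bh = gr)
  ll <- numeric(nrow(G))
  for (i in 1:8) {
    eta <- G$b0 + dose[i] * G$bh
    ll <- ll + y[i] * eta - log1p(exp(eta))
  }
  lp <- ll + dnorm(G$b0, 0, 10, log = TRUE) - lam_star * abs(G$bh)
  w <- exp(lp - max(lp)); w <- w / sum(w)
  mean_b0 <- sum(w * G$b0)
  mean_bh <- sum(w * G$bh)
  se <- function(x) sd(x) / sqrt(lbltvc:::.ess(x))
  expect_lt(abs(mean(ch$beta0) - mean_b0), 3 * se(ch$beta0) + 0.01)
  expect_lt(abs(mean(ch$B[, 1]) - mean_bh), 3 * se(ch$B[, 1]) + 0.01)
})

test_that("prior-only sampling recovers the Laplace and Dirichlet priors", {
  sc <- sim_scenario(n = 40)
  dat <- simulate_dataset(sc, seed = 23)
  co <- join_cohort(dat$genotypes, dat$phenotypes)
  lam_star <- 2
  cfg <- lbl_config(n_iter = 42000, burnin = 2000, thin = 4,
                    use_likelihood = FALSE, sample_z = FALSE,
                    fix_d = TRUE, fix_lambda = lam_star, seed = 31)
  ch <- run_chain(co, config = cfg)
  # |beta| under a Laplace(lam) prior is Exponential(lam)
  for (draws in list(ch$betaE, ch$B[, 3])) {
    absd <- abs(draws)
    for (q in c(0.25, 0.5, 0.75)) {
      expected <- -log(1 - q) / lam_star
      expect_lt(abs(quantile(absd, q) - expected), 0.12)
    }
  }
  # intercept prior: diffuse normal, sd 10
  expect_lt(abs(sd(ch$beta0) - 10) / 10, 0.15)
  # frequencies: Dirichlet(1,...,1) => mean 1/m for every component
  # (checks the stick-breaking walk and its Jacobian)
  m <- length(ch$haplotypes)
  expect_lt(max(abs(colMeans(ch$f) - 1 / m)), 0.035)
  # marginal of each component is Beta(1, m - 1)
  expect_lt(abs(mean(ch$f[, 1] < 0.2) - (1 - (1 - 0.2)^(m - 1))), 0.05)
})

test_that("acceptance rates land in a usable band after adaptation", {
  sc <- sim_scenario(n = 60)
  dat <- simulate_dataset(sc, seed = 41)
  co <- join_cohort(dat$genotypes, dat$phenotypes)
  cfg <- lbl_config(n_iter = 3000, burnin = 1500, thin = 3, seed = 8)
  ch <- run_chain(co, config = cfg)
  mh <- ch$acceptance[ch$acceptance$attempts > 0, ]
  expect_true(all(mh$acceptance >= 0.1 & mh$acceptance <= 0.6))
  # every stored frequency draw is a strictly positive point on the simplex
  expect_true(all(ch$f > 0))
  expect_lt(max(abs(rowSums(ch$f) - 1)), 1e-9)
  # inbreeding coefficient stays in its valid range
  lo <- apply(ch$f, 1, function(f) max(-f / (1 - f)))
  expect_true(all(ch$d >= lo & ch$d < 1))
  # diagnostics are finite and informative
  expect_true(all(is.finite(ch$diagnostics$ess)))
  expect_true(all(ch$diagnostics$ess >= 1))
})
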