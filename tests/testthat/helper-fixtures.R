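# Shared fixtures and independent oracles, built in code at test time.

# -- small genotype/phenotype tables -------------------------------------

make_genotypes <- function(a1, a2, ids = sprintf("i%d", seq_len(nrow(a1))),
                           snps = sprintf("snp%d", seq_len(ncol(a1))),
                           positions = seq_len(ncol(a1)) * 100L) {
  lbltvc:::.new_genotypes(ids, snps, as.integer(positions), a1, a2)
}

# n individuals drawn from given haplotype strings (phase known, emitted
# unphased); returns the genotype object plus the generating diplotypes
random_genotypes <- function(n, haplotypes, freqs, seed = 1) {
  set.seed(seed)
  m <- length(haplotypes)
  chars <- do.call(rbind, strsplit(haplotypes, ""))
  h1 <- sample.int(m, n, TRUE, prob = freqs)
  h2 <- sample.int(m, n, TRUE, prob = freqs)
  g <- make_genotypes(chars[h1, , drop = FALSE], chars[h2, , drop = FALSE])
  list(genotypes = g, h1 = h1, h2 = h2)
}

make_phenotypes <- function(df) as_phenotypes(df)

tiny_cohort <- function(n = 6, seed = 1, n_exams = 2,
                        haplotypes = c("AC", "AG", "TC"),
                        freqs = c(0.5, 0.3, 0.2)) {
  rg <- random_genotypes(n, haplotypes, freqs, seed = seed)
  set.seed(seed + 1000)
  rows <- do.call(rbind, lapply(seq_len(n), function(i) {
    ages <- sort(runif(n_exams, 30, 80))
    while (any(diff(ages) <= 0)) ages <- sort(runif(n_exams, 30, 80))
    data.frame(id = sprintf("i%d", i), exam = seq_len(n_exams),
               y = rbinom(n_exams, 1, 0.5),
               smoke = rbinom(n_exams, 1, 0.4),
               age = ages, sex = rep(rbinom(1, 1, 0.5), n_exams))
  }))
  join_cohort(rg$genotypes, make_phenotypes(rows))
}

# -- independent oracles --------------------------------------------------

# Cox-de Boor recursion, written directly from the recurrence (independent
# of splines::splineDesign)
coxdeboor_basis <- function(knots, order, t) {
  nb <- length(knots) - order
  B <- matrix(0, length(t), nb + order - 1)
  # order-1 (piecewise constant) functions
  for (j in seq_len(length(knots) - 1)) {
    lo <- knots[j]; hi <- knots[j + 1]
    B[, j] <- as.numeric(t >= lo & t < hi)
  }
  # right-closure: include the right boundary in the last nonempty interval
  last <- max(which(knots < max(knots)))
  B[t == max(knots), last] <- 1
  for (k in 2:order) {
    Bn <- matrix(0, length(t), length(knots) - k)
    for (j in seq_len(length(knots) - k)) {
      d1 <- knots[j + k - 1] - knots[j]
      d2 <- knots[j + k] - knots[j + 1]
      a <- if (d1 > 0) (t - knots[j]) / d1 * B[, j] else 0
      b <- if (d2 > 0) (knots[j + k] - t) / d2 * B[, j + 1] else 0
      Bn[, j] <- a + b
    }
    B <- Bn
  }
  B
}

# direct evaluation of the diplotype distribution
oracle_dip_prob <- function(f, d, k, kp) {
  if (k == kp) d * f[k] + (1 - d) * f[k]^2 else 2 * (1 - d) * f[k] * f[kp]
}

# naive per-record Bernoulli + frequency-model evaluation of the
# complete-data log-likelihood (fully independent expression evaluator)
oracle_loglik <- function(params, cohort, assignment) {
  phe <- cohort$phenotypes
  haps <- params$haplotypes
  total <- 0
  for (r in seq_len(nrow(phe))) {
    pair <- assignment[[phe$id_idx[r]]]
    bb <- splines::splineDesign(params$basis$knots, phe$age[r],
                                ord = params$basis$order)[1, ]
    eta <- params$beta0 + params$betaE * phe$smoke[r] +
      params$betaS * phe$sex[r]
    for (hp in pair) {
      h <- match(hp, haps) - 1L
      if (h >= 1L) {
        eta <- eta + sum(params$B[h, ] * bb) +
          params$betaEh[h] * phe$smoke[r]
      }
    }
    p <- 1 / (1 + exp(-eta))
    total <- total + ifelse(phe$y[r] == 1, log(p), log(1 - p))
  }
  f <- params$freq$f; d <- params$freq$d
  for (i in seq_along(assignment)) {
    pair <- match(assignment[[i]], params$freq$haplotypes)
    total <- total + log(oracle_dip_prob(f, d, pair[1], pair[2]))
  }
  total
}

# random valid parameter state over a haplotype list
random_params <- function(haplotypes, basis, seed = 1) {
  set.seed(seed)
  m <- length(haplotypes)
  f <- as.numeric(stats::rgamma(m, 2, 1)); f <- f / sum(f)
  lo <- d_lower_bound(f)
  d <- runif(1, lo + 1e-6, 0.9)
  lbl_params(haplotypes, basis,
             beta0 = rnorm(1),
             B = matrix(rnorm((m - 1) * basis$n_basis, sd = 0.7),
                        m - 1, basis$n_basis),
             betaE = rnorm(1, sd = 0.5),
             betaEh = rnorm(m - 1, sd = 0.5),
             betaS = rnorm(1, sd = 0.5),
             freq = hap_freq_model(haplotypes, f, d),
             lambda = stats::rgamma(1, 20, 20))
}

# random valid frequency model of size m
random_freq_model <- function(m, seed) {
  set.seed(seed)
  f <- as.numeric(stats::rgamma(m, 1.5, 1)) + 1e-4
  f <- f / sum(f)
  d <- runif(1, d_lower_bound(f) + 1e-9, 1 - 1e-9)
  hap_freq_model(sprintf("H%02d", seq_len(m)), f, d)
}
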