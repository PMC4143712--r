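# build a synthetic chain with known draws for a 2-haplotype model
synthetic_chain <- function(Bdraws, basis = spline_basis(),
                            haplotypes = c("REF00", "ALT11")) {
  n <- nrow(Bdraws)
  structure(list(
    beta0 = rep(0, n), B = Bdraws,
    betaE = rnorm(n, 0, 0.1),
    betaEh = matrix(rnorm(n, 0, 0.1), n, 1,
                    dimnames = list(NULL, haplotypes[2])),
    betaS = rnorm(n, 0, 0.1),
    f = matrix(0.5, n, 2, dimnames = list(NULL, haplotypes)),
    d = rep(0, n), lambda = rep(1, n), fitted = numeric(0),
    haplotypes = haplotypes, basis = basis, f_start = c(0.5, 0.5),
    rare = c(FALSE, FALSE),
    acceptance = data.frame(block = "beta0", acceptance = 0.3,
                            attempts = 10, scale = 0.1),
    diagnostics = data.frame(parameter = "beta0", ess = n, geweke_z = 0),
    n_kept = n, z_last = integer(0), config = lbl_config()),
    class = "lbl_chain")
}

test_that("OR curves follow the draws: constants, zeros and equivariance", {
  basis <- spline_basis()
  set.seed(1)
  # all-zero coefficients: OR identically 1
  ch0 <- synthetic_chain(matrix(0, 200, 6))
  oc0 <- or_curve(ch0, "ALT11")
  expect_equal(oc0$summary$or, rep(1, 15))
  expect_equal(oc0$summary$lower, rep(1, 15))
  expect_equal(oc0$summary$upper, rep(1, 15))
  expect_false(any(oc0$summary$significant))

  # constant coefficients c: OR = exp(c) at every age (partition of unity)
  chc <- synthetic_chain(matrix(0.7, 100, 6))
  occ <- or_curve(chc, "ALT11")
  expect_equal(occ$summary$or, rep(exp(0.7), 15))

  # adding c to every coefficient multiplies OR(t) by exp(c)
  B1 <- matrix(rnorm(300 * 6, sd = 0.5), 300, 6)
  ch1 <- synthetic_chain(B1)
  ch2 <- synthetic_chain(B1 + 0.4)
  o1 <- or_curve(ch1, "ALT11")$summary
  o2 <- or_curve(ch2, "ALT11")$summary
  expect_equal(o2$or, o1$or * exp(0.4), tolerance = 1e-12)
  expect_equal(o2$lower, o1$lower * exp(0.4), tolerance = 1e-12)

  expect_error(or_curve(ch1, "REF00"), "reference")
  expect_error(or_curve(ch1, "NOPE"), "not in the model")
})

test_that("percentile summaries match a sort-based percentile oracle", {
  # independent type-7 percentile computation from sorted draws
  oracle_pct <- function(x, p) {
    s <- sort(x)
    n <- length(s)
    h <- (n - 1) * p + 1
    lo <- floor(h); hi <- ceiling(h)
    s[lo] + (h - lo) * (s[hi] - s[lo])
  }
  set.seed(2)
  B <- matrix(rnorm(1000 * 6, sd = 0.8), 1000, 6)
  ch <- synthetic_chain(B)
  oc <- or_curve(ch, "ALT11", age_grid = c(30, 60, 90))
  for (j in 1:3) {
    dr <- oc$draws[, j]
    expect_equal(oc$summary$lower[j], oracle_pct(dr, 0.025), tolerance = 1e-14)
    expect_equal(oc$summary$or[j], oracle_pct(dr, 0.5), tolerance = 1e-14)
    expect_equal(oc$summary$upper[j], oracle_pct(dr, 0.975), tolerance = 1e-14)
  }
  # percentile summaries are monotone under stochastic ordering
  oc_shift <- or_curve(synthetic_chain(B + 0.3), "ALT11",
                       age_grid = c(30, 60, 90))
  expect_true(all(oc_shift$summary$or > oc$summary$or))
  expect_true(all(oc_shift$summary$upper > oc$summary$upper))
})

test_that("significance uses strict exclusion of 1", {
  tab <- data.frame(age = c(55, 60, 65),
                    lower = c(0.94, 1.01, 1.0),
                    upper = c(2.55, 2.60, 2.0))
  sig <- call_significance(tab)
  expect_equal(sig$per_age, c(FALSE, TRUE, FALSE))  # bound at 1 not significant
  expect_true(sig$overall)
  # window restriction
  expect_false(call_significance(tab, ages = c(62, 70))$overall)
  expect_true(call_significance(tab, ages = c(58, 62))$overall)
  # intervals below 1 count too
  expect_true(call_significance(data.frame(age = 40, lower = 0.2,
                                           upper = 0.9))$overall)
})

test_that("report tables mirror the standard layout and round-trip", {
  set.seed(3)
  B <- matrix(rnorm(400 * 6, 0.5, 0.3), 400, 6)
  ch <- synthetic_chain(B)
  out <- withr::local_tempdir()
  report_tables(ch, out, plots = TRUE)
  tab <- read.delim(file.path(out, "summary.tsv"))
  expect_equal(nrow(tab), 15L)                 # ages 25..95 by 5
  expect_equal(tab$age, seq(25, 95, 5))
  expect_named(tab, c("haplotype", "age", "or", "lower", "upper",
                      "significant"))
  # round-trip: the TSV reproduces the computed summaries
  oc <- or_curve(ch, "ALT11")
  expect_equal(tab$or, oc$summary$or, tolerance = 1e-12)
  expect_equal(tab$lower, oc$summary$lower, tolerance = 1e-12)
  expect_equal(tab$upper, oc$summary$upper, tolerance = 1e-12)
  expect_true(file.exists(file.path(out, "curves", "ALT11.csv")))
  expect_true(file.exists(file.path(out, "scalar_effects.tsv")))
  expect_true(file.exists(file.path(out, "frequencies.tsv")))
  expect_true(file.exists(file.path(out, "run_manifest.json")))
  manifest <- jsonlite::read_json(file.path(out, "run_manifest.json"))
  expect_equal(manifest$reference, "REF00")

  # all-zero draws: nothing significant, tables still written, no plots
  out2 <- withr::local_tempdir()
  report_tables(synthetic_chain(matrix(0, 50, 6)), out2, plots = TRUE)
  expect_true(file.exists(file.path(out2, "summary.tsv")))
  expect_equal(length(list.files(file.path(out2, "plots"))), 0L)
})

test_that("fit methods expose coherent summaries", {
  sc <- sim_scenario(n = 50)
  dat <- simulate_dataset(sc, seed = 71)
  co <- join_cohort(dat$genotypes, dat$phenotypes)
  cfg <- lbl_config(n_iter = 600, burnin = 200, thin = 2, seed = 2)
  fit <- lbl_tvc(co, config = cfg)
  expect_s3_class(fit, "lbl_tvc")
  s <- summary(fit)
  expect_s3_class(s, "summary.lbl_tvc")
  expect_true(all(s$or_table$lower <= s$or_table$or + 1e-12))
  expect_true(all(s$or_table$or <= s$or_table$upper + 1e-12))
  expect_true(all(s$or_table$or > 0))
  expect_equal(sum(s$or_table$haplotype == s$or_table$haplotype[1]), 15L)
  co_names <- names(coef(fit))
  expect_true("beta0" %in% co_names)
  p <- predict(fit, haplotype = fit$haplotypes[2], ages = c(50, 70))
  expect_equal(p$age, c(50, 70))
  expect_true(all(p$lower <= p$or & p$or <= p$upper))
  fv <- fitted(fit)
  expect_equal(length(fv), fit$n_records)
  expect_true(all(fv > 0 & fv < 1))
  rr <- residuals(fit)
  expect_equal(length(rr), fit$n_records)
  sim <- simulate(fit, nsim = 2, seed = 9)
  expect_length(sim, 2L)
  expect_s3_class(sim[[1]], "lbl_phenotypes")
  expect_equal(nrow(sim[[1]]), fit$n_records)
  # print methods run quietly
  expect_output(print(fit), "haplotypes")
  expect_output(print(s), "Odds ratios")
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})
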