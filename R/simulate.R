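#' Default age-varying log-odds-ratio curve for a causal haplotype
#'
#' A smooth effect trajectory typical of late-onset hypertension risk:
#' protective at young ages, crossing OR = 1 shortly after age 50, peaking
#' around 2.5 at ages 65 to 70, and decaying toward the null by the mid
#' 90s. Constructed as the natural cubic spline interpolant through
#' per-copy (age, log OR) anchors
#' `OR = 0.13, 0.10, 0.14, 0.26, 0.51, 0.93, 1.53, 2.15, 2.52, 2.52,
#' 2.26, 1.88, 1.53, 1.27, 1.12` at ages 25 to 95 by 5.
#'
#' @return A function `f(age)` returning the per-copy log odds ratio.
#' @export
default_effect_curve <- function() {
  ages <- seq(25, 95, by = 5)
  or <- c(0.13, 0.10, 0.14, 0.26, 0.51, 0.93, 1.53, 2.15, 2.52, 2.52,
          2.26, 1.88, 1.53, 1.27, 1.12)
  splinefun(ages, log(or), method = "natural")
}

#' Simulation scenario for the haplotype block design
#'
#' Describes the generating model of the simulation study: a 5-SNP
#' haplotype block carrying 5 common and 2 rare haplotypes, one causal
#' haplotype of each class with an age-varying per-copy log-odds-ratio
#' curve, a 2-state Markov smoking process observed at up to 4
#' examinations, and a time-constant interaction between smoking and the
#' common risk haplotype. Diplotypes are drawn under Hardy-Weinberg
#' equilibrium (`d = 0`) and emitted unphased.
#'
#' Defaults: 250 individuals with 4 exams each; common haplotype
#' frequencies 0.30, 0.25, 0.20, 0.13, 0.06 and rare frequencies 0.035,
#' 0.025 (rare means frequency below 0.05); the causal common haplotype is
#' the 0.20 one (`GGTCC`) and the causal rare haplotype the 0.035 one
#' (`ACGTG`), both following [default_effect_curve()]; smoking initial
#' prevalence 0.3 with persistence 0.8 per exam; interaction effect
#' `log(2)` between smoking and the causal common haplotype; intercept set
#' so the null prevalence is about 0.35; first-exam age uniform on
#' (22, 75) with inter-exam gaps uniform on (3, 6) years, capped at 90.
#'
#' @param n Number of individuals.
#' @param n_exams Examinations per individual (1 to 4).
#' @param haplotypes Character vector of haplotype strings.
#' @param frequencies Haplotype frequencies (sum to 1).
#' @param causal_common,causal_rare Causal haplotype strings (set to `NA`
#'   for a null scenario with no haplotype effect).
#' @param effect_curve Function age -> per-copy log OR shared by the
#'   causal haplotypes, or `NULL` for no haplotype effect.
#' @param betaE Smoking main effect (log OR).
#' @param interaction Smoking-by-causal-common-haplotype effect (log OR).
#' @param betaS Sex effect (log OR).
#' @param seed_prevalence Null prevalence fixing the intercept via its
#'   logit.
#' @param smoking_init,smoking_persist Initial smoking prevalence and the
#'   per-exam probability of keeping the previous smoking state.
#' @param age_first Range of the first-exam age (uniform).
#' @param age_gap Range of inter-exam gaps in years (uniform).
#' @param age_cap Maximum age (later exams are capped here).
#' @return A list of class `"lbl_scenario"`.
#' @export
sim_scenario <- function(n = 250L, n_exams = 4L,
                         haplotypes = c("ACGCC", "GCGCC", "GGTCC", "AGTTC",
                                        "GCTTG", "ACGTG", "GGGCG"),
                         frequencies = c(0.30, 0.25, 0.20, 0.13, 0.06,
                                         0.035, 0.025),
                         causal_common = "GGTCC", causal_rare = "ACGTG",
                         effect_curve = default_effect_curve(),
                         betaE = 0, interaction = log(2), betaS = 0,
                         seed_prevalence = 0.35,
                         smoking_init = 0.3, smoking_persist = 0.8,
                         age_first = c(22, 75), age_gap = c(3, 6),
                         age_cap = 90) {
  stopifnot(length(haplotypes) == length(frequencies),
            n_exams >= 1L, n_exams <= 4L)
  if (any(frequencies <= 0) || abs(sum(frequencies) - 1) > 1e-8)
    .stopf("scenario frequencies must be positive and sum to 1")
  if (!is.na(causal_common) && !causal_common %in% haplotypes)
    .stopf("causal_common not among the scenario haplotypes")
  if (!is.na(causal_rare) && !causal_rare %in% haplotypes)
    .stopf("causal_rare not among the scenario haplotypes")
  if (!is.na(causal_rare) &&
      frequencies[match(causal_rare, haplotypes)] >= 0.05)
    .stopf("the causal rare haplotype must have frequency < 0.05")
  structure(list(
    n = as.integer(n), n_exams = as.integer(n_exams),
    haplotypes = haplotypes, frequencies = frequencies,
    causal_common = causal_common, causal_rare = causal_rare,
    effect_curve = effect_curve, betaE = betaE, interaction = interaction,
    betaS = betaS, beta0 = qlogis(seed_prevalence),
    smoking_init = smoking_init, smoking_persist = smoking_persist,
    age_first = age_first, age_gap = age_gap, age_cap = age_cap),
    class = "lbl_scenario")
}

#' Null version of a scenario
#'
#' Same block and design, all effects (haplotype, interaction, smoking,
#' sex) set to zero; used for type-I-error calibration.
#'
#' @param scenario An `"lbl_scenario"`.
#' @return The modified scenario.
#' @export
null_scenario <- function(scenario = sim_scenario()) {
  scenario$effect_curve <- NULL
  scenario$interaction <- 0
  scenario$betaE <- 0
  scenario$betaS <- 0
  scenario
}

#' Generate one synthetic dataset
#'
#' Draws each individual's diplotype from the scenario frequencies under
#' Hardy-Weinberg equilibrium, emits the unphased block genotypes (phase
#' is discarded), simulates the smoking process as a 2-state Markov chain
#' across exams, and draws affection statuses from the logistic model
#' with the scenario's age-varying haplotype effects and time-constant
#' smoking/interaction/sex effects.
#'
#' @param scenario An `"lbl_scenario"`.
#' @param seed Integer seed (`NULL` to use the current RNG state).
#' @return A list: `genotypes` (`"lbl_genotypes"`), `phenotypes`
#'   (`"lbl_phenotypes"`), and `truth` (generating diplotypes, per-record
#'   linear predictors, and all generating parameter values).
#' @export
simulate_dataset <- function(scenario, seed = NULL) {
  stopifnot(inherits(scenario, "lbl_scenario"))
  if (!is.null(seed)) set.seed(seed)
  sc <- scenario
  n <- sc$n
  m <- length(sc$haplotypes)
  hap_chars <- do.call(rbind, strsplit(sc$haplotypes, ""))
  S <- ncol(hap_chars)
  h1 <- sample.int(m, n, replace = TRUE, prob = sc$frequencies)
  h2 <- sample.int(m, n, replace = TRUE, prob = sc$frequencies)
  sex <- rbinom(n, 1L, 0.5)
  ids <- sprintf("ind%03d", seq_len(n))
  a1 <- hap_chars[h1, , drop = FALSE]
  a2 <- hap_chars[h2, , drop = FALSE]
  geno <- .new_genotypes(ids, sprintf("snp%d", seq_len(S)),
                         as.integer(seq_len(S) * 1000L), a1, a2)
  i_cc <- if (is.na(sc$causal_common)) 0L else match(sc$causal_common, sc$haplotypes)
  i_cr <- if (is.na(sc$causal_rare)) 0L else match(sc$causal_rare, sc$haplotypes)
  rows <- vector("list", n)
  eta_all <- numeric(0)
  for (i in seq_len(n)) {
    J <- sc$n_exams
    ages <- numeric(J)
    ages[1L] <- runif(1L, sc$age_first[1L], sc$age_first[2L])
    if (J > 1L)
      for (j in 2:J)
        ages[j] <- min(ages[j - 1L] + runif(1L, sc$age_gap[1L], sc$age_gap[2L]),
                       sc$age_cap)
    # the cap can create ties at age_cap; nudge to keep ages strictly increasing
    for (j in seq_len(J)[-1L])
      if (ages[j] <= ages[j - 1L]) ages[j] <- ages[j - 1L] + 0.1
    smoke <- integer(J)
    smoke[1L] <- rbinom(1L, 1L, sc$smoking_init)
    if (J > 1L)
      for (j in 2:J)
        smoke[j] <- if (runif(1L) < sc$smoking_persist) smoke[j - 1L]
                    else 1L - smoke[j - 1L]
    x_cc <- (h1[i] == i_cc) + (h2[i] == i_cc)
    x_cr <- (h1[i] == i_cr) + (h2[i] == i_cr)
    eff <- if (is.null(sc$effect_curve)) rep(0, J) else sc$effect_curve(ages)
    eta <- sc$beta0 + (x_cc + x_cr) * eff + sc$betaE * smoke +
           sc$interaction * x_cc * smoke + sc$betaS * sex[i]
    y <- rbinom(J, 1L, plogis(eta))
    eta_all <- c(eta_all, eta)
    rows[[i]] <- data.frame(id = ids[i], exam = seq_len(J), y = y,
                            smoke = smoke, age = ages, sex = sex[i])
  }
  phe <- as_phenotypes(do.call(rbind, rows))
  truth <- list(haplotypes = sc$haplotypes, frequencies = sc$frequencies,
                diplotypes = cbind(sc$haplotypes[h1], sc$haplotypes[h2]),
                causal_common = sc$causal_common,
                causal_rare = sc$causal_rare,
                beta0 = sc$beta0, betaE = sc$betaE,
                interaction = sc$interaction, betaS = sc$betaS,
                eta = eta_all, scenario = sc)
  list(genotypes = geno, phenotypes = phe, truth = truth)
}

#' Type-I-error / power study over simulation replicates
#'
#' For each replicate: generate a dataset from the scenario, fit the
#' model, and record whether each monitored effect is detected. A
#' haplotype is detected when its 95% credible interval for OR(t)
#' strictly excludes 1 at one or more reporting-grid ages inside the
#' mid-age window (default 55 to 85); the interaction is detected when
#' the 95% interval of its scalar OR excludes 1. Monitored effects: the
#' causal common haplotype, the causal rare haplotype, the
#' smoking-by-common-haplotype interaction, and a designated null
#' haplotype (giving the empirical type-I error). Under a null scenario
#' only the null haplotype and interaction are meaningful.
#'
#' @param scenario An `"lbl_scenario"`.
#' @param replicates Number of replicates (the reference study size is
#'   100).
#' @param config An [lbl_config()]; replicate analyses typically use
#'   shortened chains (a few thousand iterations).
#' @param seed Integer base seed; replicate r uses `seed + r`.
#' @param null_haplotype Haplotype monitored for type-I error (default
#'   `"GCGCC"`, the most frequent non-reference, non-causal haplotype of
#'   the default block).
#' @return A list of class `"lbl_power"`: `results` (data frame with one
#'   row per monitored effect: rejections, usable replicates, rejection
#'   `proportion`, Monte Carlo standard error `mcse = sqrt(p(1-p)/R)`),
#'   `detail` (replicate-by-effect logical matrix), `failed` (count of
#'   replicate fits that errored; excluded from denominators with a
#'   warning).
#' @export
run_power_study <- function(scenario, replicates = 100L,
                            config = lbl_config(n_iter = 5000L,
                                                burnin = 1000L, thin = 5L),
                            seed = 1L, null_haplotype = "GCGCC") {
  stopifnot(inherits(scenario, "lbl_scenario"), replicates >= 1L)
  effects <- c("common", "rare", "interaction", "null")
  detail <- matrix(NA, replicates, length(effects),
                   dimnames = list(NULL, effects))
  failed <- 0L
  for (r in seq_len(replicates)) {
    res <- tryCatch(
      .power_one_replicate(scenario, config, seed + r, null_haplotype),
      error = function(e) e)
    if (inherits(res, "error")) {
      failed <- failed + 1L
      .warnf("replicate %d failed: %s", r, conditionMessage(res))
      next
    }
    detail[r, ] <- res
  }
  results <- do.call(rbind, lapply(effects, function(ef) {
    v <- detail[, ef]
    v <- v[!is.na(v)]
    R <- length(v)
    p <- if (R) mean(v) else NA_real_
    data.frame(effect = ef, rejections = sum(v), replicates = R,
               proportion = p,
               mcse = if (R) sqrt(p * (1 - p) / R) else NA_real_)
  }))
  structure(list(results = results, detail = detail, failed = failed,
                 scenario = scenario, config = config, seed = seed),
            class = "lbl_power")
}

.power_one_replicate <- function(scenario, config, seed, null_haplotype) {
  dat <- simulate_dataset(scenario, seed = seed)
  cohort <- join_cohort(dat$genotypes, dat$phenotypes)
  cfg <- config
  cfg$seed <- seed
  fit <- lbl_tvc(cohort, config = cfg)
  win <- cfg$sig_window
  detect_hap <- function(hp) {
    if (is.na(hp) || !hp %in% fit$haplotypes ||
        hp == fit$haplotypes[1L]) return(NA)
    call_significance(fit$or_curves[[hp]], ages = win)$overall
  }
  sc_int <- NA
  cc <- scenario$causal_common
  if (!is.na(cc) && cc %in% fit$haplotypes[-1L]) {
    h <- match(cc, fit$haplotypes[-1L])
    sc_int <- .scalar_or_summary(fit$chain$betaEh[, h])$significant
  }
  c(common = detect_hap(scenario$causal_common),
    rare = detect_hap(scenario$causal_rare),
    interaction = sc_int,
    null = detect_hap(null_haplotype))
}

#' @export
print.lbl_power <- function(x, ...) {
  cat(sprintf("Simulation study: %d replicates (%d failed)\n",
              nrow(x$detail), x$failed))
  tab <- x$results
  tab$proportion <- round(tab$proportion, 3)
  tab$mcse <- round(tab$mcse, 3)
  print(tab, row.names = FALSE)
  invisible(x)
}
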