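#' Fit the time-varying haplotype association model
#'
#' The main entry point. Takes unphased genotypes for a SNP block and
#' longitudinal binary phenotypes, treats phase as latent, and fits a
#' logistic model in which each non-reference haplotype's per-copy
#' log-odds effect is a cubic B-spline function of age, with smoking,
#' haplotype-by-smoking and sex terms. Regression coefficients carry
#' double-exponential (Bayesian LASSO) shrinkage priors whose shared
#' intensity has a gamma hyperprior; haplotype frequencies and an
#' inbreeding coefficient parameterize the diplotype distribution.
#' Estimation is by MCMC: Gibbs draws for the latent diplotypes and the
#' shrinkage intensity, random-walk Metropolis for the remaining blocks.
#' Starting frequencies come from a Hardy-Weinberg EM fit; the most
#' frequent haplotype is the reference (baseline).
#'
#' @param genotypes An `"lbl_genotypes"` object ([read_genotypes()]), or
#'   an `"lbl_cohort"` (in which case `phenotypes` is ignored).
#' @param phenotypes An `"lbl_phenotypes"` data frame
#'   ([read_phenotypes()]).
#' @param snps Optional character vector naming the block SNPs (default:
#'   all SNPs in the genotype table). Use [build_block()] to construct
#'   5-SNP blocks around prescreen anchors.
#' @param config An [lbl_config()].
#' @return An object of class `"lbl_tvc"` with components `call`,
#'   `chain` (the `"lbl_chain"`), `haplotypes`, `rare`, `or_curves`
#'   (per non-reference haplotype, on the config's age grid),
#'   `scalar_effects` (smoking, sex, interactions), `n`, `n_records`,
#'   `config`. Methods: `print`, `summary`, `coef`, `plot`, `predict`,
#'   `fitted`, `residuals`, `simulate`.
#'
#' @examples
#' sc <- sim_scenario(n = 60, seed_prevalence = 0.35)
#' dat <- simulate_dataset(sc, seed = 7)
#' cohort <- join_cohort(dat$genotypes, dat$phenotypes)
#' cfg <- lbl_config(n_iter = 600, burnin = 200, thin = 2, seed = 1)
#' fit <- lbl_tvc(cohort, config = cfg)
#' print(fit)
#' @export
lbl_tvc <- function(genotypes, phenotypes = NULL, snps = NULL,
                    config = lbl_config()) {
  cohort <- if (inherits(genotypes, "lbl_cohort")) genotypes
            else join_cohort(genotypes, phenotypes)
  md <- .prepare_model_data(cohort, snps, config)
  chain <- run_chain_prepared(md, config)
  nonref <- chain$haplotypes[-1L]
  ocs <- lapply(nonref, function(hp) or_curve(chain, hp))
  names(ocs) <- nonref
  sc <- rbind(
    cbind(effect = "smoking", .scalar_or_summary(chain$betaE)),
    cbind(effect = "sex", .scalar_or_summary(chain$betaS)),
    do.call(rbind, lapply(seq_along(nonref), function(h)
      cbind(effect = paste0("smoking:", nonref[h]),
            .scalar_or_summary(chain$betaEh[, h])))))
  rownames(sc) <- NULL
  structure(
    list(call = match.call(), chain = chain,
         haplotypes = chain$haplotypes, rare = chain$rare,
         f_start = chain$f_start, or_curves = ocs, scalar_effects = sc,
         n = length(cohort$ids), n_records = nrow(cohort$phenotypes),
         cohort = cohort, config = config),
    class = "lbl_tvc")
}

#' @export
print.lbl_tvc <- function(x, ...) {
  cat("Time-varying haplotype association fit (logistic Bayesian LASSO)\n")
  cat(sprintf("  %d individuals, %d examination records\n", x$n, x$n_records))
  cat(sprintf("  %d haplotypes (reference %s; %d rare, frequency < 0.05)\n",
              length(x$haplotypes), x$haplotypes[1L], sum(x$rare)))
  cat(sprintf("  %d stored posterior draws\n", x$chain$n_kept))
  sig <- vapply(x$or_curves, function(oc) any(oc$summary$significant), TRUE)
  if (any(sig))
    cat("  significant haplotypes (95% CI excludes OR = 1 at >= 1 grid age):",
        paste(names(sig)[sig], collapse = ", "), "\n")
  else cat("  no haplotype significant on the reporting grid\n")
  invisible(x)
}

#' Summarize a fitted time-varying haplotype model
#'
#' @param object An `"lbl_tvc"` fit.
#' @param ... Unused.
#' @return A `"summary.lbl_tvc"`: the per-haplotype OR table over the age
#'   grid (posterior median with 95% credible bounds), scalar effect ORs,
#'   haplotype frequencies, and convergence diagnostics.
#' @export
summary.lbl_tvc <- function(object, ...) {
  tab <- do.call(rbind, lapply(names(object$or_curves), function(hp) {
    s <- object$or_curves[[hp]]$summary
    data.frame(haplotype = hp, rare = object$rare[match(hp, object$haplotypes)],
               s[c("age", "or", "lower", "upper", "significant")])
  }))
  rownames(tab) <- NULL
  freq <- data.frame(haplotype = object$haplotypes,
                     em_start = object$f_start,
                     posterior_mean = colMeans(object$chain$f),
                     rare = object$rare)
  structure(list(call = object$call, n = object$n,
                 n_records = object$n_records, or_table = tab,
                 scalar_effects = object$scalar_effects,
                 frequencies = freq,
                 d = quantile(object$chain$d, c(0.025, 0.5, 0.975)),
                 diagnostics = object$chain$diagnostics,
                 acceptance = object$chain$acceptance),
            class = "summary.lbl_tvc")
}

#' @export
print.summary.lbl_tvc <- function(x, digits = 3L, ...) {
  cat("Time-varying haplotype association fit\n")
  cat(sprintf("%d individuals, %d records\n\n", x$n, x$n_records))
  cat("Haplotype frequencies (reference first):\n")
  fr <- x$frequencies
  fr$em_start <- signif(fr$em_start, digits)
  fr$posterior_mean <- signif(fr$posterior_mean, digits)
  print(fr, row.names = FALSE)
  cat(sprintf("\nInbreeding coefficient d: %.3f (95%% CI %.3f, %.3f)\n",
              x$d[2L], x$d[1L], x$d[3L]))
  cat("\nOdds ratios by age (posterior median, 95% credible bounds):\n")
  tab <- x$or_table
  for (cc in c("or", "lower", "upper")) tab[[cc]] <- signif(tab[[cc]], digits)
  print(tab, row.names = FALSE)
  cat("\nScalar effects:\n")
  sc <- x$scalar_effects
  for (cc in c("or", "mean", "lower", "upper")) sc[[cc]] <- signif(sc[[cc]], digits)
  print(sc, row.names = FALSE)
  cat(sprintf("\nDiagnostics: min ESS %.0f, max |Geweke z| %.2f\n",
              min(x$diagnostics$ess), max(abs(x$diagnostics$geweke_z))))
  invisible(x)
}

#' @export
coef.lbl_tvc <- function(object, ...) {
  ch <- object$chain
  draws <- cbind(beta0 = ch$beta0, ch$B, betaE = ch$betaE,
                 `colnames<-`(ch$betaEh, paste0("betaEh.", colnames(ch$betaEh))),
                 betaS = ch$betaS,
                 `colnames<-`(ch$f, paste0("f.", colnames(ch$f))),
                 d = ch$d, lambda = ch$lambda)
  apply(draws, 2L, stats::median)
}

#' Plot odds-ratio curves of a fit
#'
#' Posterior-median OR(t) with dotted 95% credible bounds, one panel per
#' requested haplotype (default: all significant haplotypes, or the first
#' non-reference haplotype if none is significant).
#'
#' @param x An `"lbl_tvc"` fit.
#' @param haplotypes Character vector of haplotypes to plot.
#' @param ages Optional finer age grid for the curves.
#' @param ... Unused.
#' @export
plot.lbl_tvc <- function(x, haplotypes = NULL, ages = NULL, ...) {
  if (is.null(haplotypes)) {
    sig <- names(x$or_curves)[vapply(x$or_curves,
                                     function(oc) any(oc$summary$significant),
                                     TRUE)]
    haplotypes <- if (length(sig)) sig else names(x$or_curves)[1L]
  }
  if (length(haplotypes) > 1L) {
    op <- graphics::par(mfrow = c(1L, length(haplotypes)))
    on.exit(graphics::par(op))
  }
  for (hp in haplotypes) {
    oc <- if (is.null(ages)) x$or_curves[[hp]] else or_curve(x, hp, ages)
    .plot_or_curve(oc)
  }
  invisible(x)
}

#' Predicted odds ratios at new ages
#'
#' @param object An `"lbl_tvc"` fit.
#' @param haplotype Haplotype string (non-reference).
#' @param ages Ages at which to predict (default the config grid).
#' @param type `"or"` for the per-copy odds-ratio summary, `"link"` for
#'   the log-odds-ratio summary.
#' @param ... Unused.
#' @return Data frame with `age`, point estimate (`or` or `effect`,
#'   posterior median), `lower`, `upper`.
#' @export
predict.lbl_tvc <- function(object, haplotype, ages = NULL,
                            type = c("or", "link"), ...) {
  type <- match.arg(type)
  oc <- or_curve(object, haplotype, ages)
  s <- oc$summary
  if (type == "or") return(s[c("age", "or", "lower", "upper")])
  data.frame(age = s$age, effect = log(s$or),
             lower = log(s$lower), upper = log(s$upper))
}

#' @export
fitted.lbl_tvc <- function(object, ...) object$chain$fitted

#' @export
residuals.lbl_tvc <- function(object, type = c("response", "pearson"), ...) {
  type <- match.arg(type)
  p <- object$chain$fitted
  y <- object$cohort$phenotypes$y
  r <- y - p
  if (type == "pearson") r <- r / sqrt(pmax(p * (1 - p), 1e-12))
  r
}

#' Simulate phenotype tables from a fitted model
#'
#' Holds the observed design fixed (individuals, exam ages, smoking, sex),
#' draws each individual's diplotype from its posterior full conditional
#' at the posterior-median parameters, and simulates new affection
#' statuses from the fitted logistic model. Useful for posterior
#' predictive checks.
#'
#' @param object An `"lbl_tvc"` fit.
#' @param nsim Number of simulated datasets.
#' @param seed Optional integer seed.
#' @param ... Unused.
#' @return A list of `nsim` `"lbl_phenotypes"` data frames.
#' @export
simulate.lbl_tvc <- function(object, nsim = 1L, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  ch <- object$chain
  phe <- object$cohort$phenotypes
  n <- length(object$cohort$ids)
  nb <- ch$basis$n_basis
  m <- length(ch$haplotypes)
  med <- function(x) apply(as.matrix(x), 2L, stats::median)
  Bc <- matrix(med(ch$B), m - 1L, nb, byrow = TRUE)
  fmed <- med(ch$f); fmed <- fmed / sum(fmed)
  params <- lbl_params(ch$haplotypes, ch$basis,
                       beta0 = stats::median(ch$beta0), B = Bc,
                       betaE = stats::median(ch$betaE),
                       betaEh = med(ch$betaEh),
                       betaS = stats::median(ch$betaS),
                       freq = hap_freq_model(ch$haplotypes, fmed,
                                             max(stats::median(ch$d),
                                                 d_lower_bound(fmed) + 1e-8)),
                       lambda = stats::median(ch$lambda))
  md_sup <- .prepare_model_data(object$cohort, NULL, object$config)$supports_str
  out <- vector("list", nsim)
  for (s in seq_len(nsim)) {
    assign <- gibbs_update_diplotypes(params, object$cohort, md_sup)
    newy <- integer(nrow(phe))
    for (r in seq_len(nrow(phe))) {
      row <- build_design_row(assign[[phe$id_idx[r]]], phe[r, ],
                              params$haplotypes)
      newy[r] <- rbinom(1L, 1L, plogis(log_odds(params, row)))
    }
    sim <- phe
    sim$y <- newy
    sim$id_idx <- NULL
    out[[s]] <- as_phenotypes(sim)
  }
  out
}
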