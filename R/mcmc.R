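#' Analysis configuration
#'
#' Collects every tunable of the model and sampler. Defaults follow the
#' method's conventions: cubic B-splines with interior knots (40, 60) and
#' boundary knots (20, 100) over adult ages; Laplace (double-exponential)
#' shrinkage on all regression coefficients except the intercept, with a
#' shared intensity given a Gamma(a = 20, b = 20) hyperprior; a diffuse
#' normal prior (sd 10) on the intercept; Dirichlet(1,...,1) on haplotype
#' frequencies and a flat prior on the inbreeding coefficient over its
#' valid range; 50,000 MCMC iterations with 10,000 burn-in and thinning 10;
#' reporting odds ratios on the age grid 25, 30, ..., 95.
#'
#' @param interior_knots,boundary_knots,spline_order Passed to
#'   [spline_basis()].
#' @param n_iter,burnin,thin Chain length, burn-in, thinning interval.
#' @param a,b Gamma hyperprior shape and rate for the Laplace intensity.
#' @param beta0_sd Normal prior sd for the intercept (not shrunk).
#' @param age_grid Ages at which odds-ratio curves are reported.
#' @param sig_window Age window (inclusive) used by the power/type-I
#'   drivers when declaring a haplotype detected; default `c(55, 85)`.
#' @param min_hap_freq Haplotypes with EM frequency below this are pruned
#'   from the universe when every individual keeps a nonempty diplotype
#'   support (default 1e-6; set 0 to keep the full closure).
#' @param adapt Adapt proposal scales during burn-in (frozen afterwards).
#' @param adapt_interval,target_acc,init_scale Adaptation controls.
#' @param fix_f,fix_d Hold frequencies / inbreeding coefficient at their
#'   starting values (no MH updates).
#' @param fix_lambda `NULL` (sample the intensity) or a fixed value.
#' @param sample_z Sample latent diplotypes (default TRUE).
#' @param use_likelihood Set `FALSE` to sample from the prior only
#'   (validation tool).
#' @param seed Integer seed; `NULL` leaves the RNG state alone.
#' @return A list of class `"lbl_config"`.
#' @export
lbl_config <- function(interior_knots = c(40, 60),
                       boundary_knots = c(20, 100),
                       spline_order = 4L,
                       n_iter = 50000L, burnin = 10000L, thin = 10L,
                       a = 20, b = 20, beta0_sd = 10,
                       age_grid = seq(25, 95, by = 5),
                       sig_window = c(55, 85),
                       min_hap_freq = 1e-6,
                       adapt = TRUE, adapt_interval = 50L,
                       target_acc = 0.35, init_scale = 0.25,
                       fix_f = FALSE, fix_d = FALSE, fix_lambda = NULL,
                       sample_z = TRUE, use_likelihood = TRUE,
                       seed = NULL) {
  stopifnot(n_iter > burnin, thin >= 1L, a > 0, b > 0, beta0_sd > 0)
  structure(list(
    interior_knots = interior_knots, boundary_knots = boundary_knots,
    spline_order = as.integer(spline_order),
    n_iter = as.integer(n_iter), burnin = as.integer(burnin),
    thin = as.integer(thin), a = a, b = b, beta0_sd = beta0_sd,
    age_grid = age_grid, sig_window = sig_window,
    min_hap_freq = min_hap_freq, adapt = adapt,
    adapt_interval = as.integer(adapt_interval), target_acc = target_acc,
    init_scale = init_scale, fix_f = fix_f, fix_d = fix_d,
    fix_lambda = fix_lambda, sample_z = sample_z,
    use_likelihood = use_likelihood, seed = seed),
    class = "lbl_config")
}

#' Log prior density of a parameter state
#'
#' Laplace (double-exponential, mean 0) log densities with the state's
#' intensity for every shrunk coefficient (spline coefficients, smoking,
#' interactions, sex), the gamma log density of the intensity, a normal
#' log density for the intercept, the Dirichlet(1,...,1) density on the
#' frequency simplex and a flat density for the inbreeding coefficient
#' over its valid range. An inbreeding coefficient outside its valid range
#' yields `-Inf`.
#'
#' @param params An `"lbl_params"` state.
#' @param a,b Gamma hyperprior shape and rate for the intensity.
#' @param beta0_sd Normal prior sd for the intercept.
#' @return The log prior density (a scalar, possibly `-Inf`).
#' @export
log_prior <- function(params, a = 20, b = 20, beta0_sd = 10) {
  stopifnot(inherits(params, "lbl_params"))
  f <- params$freq$f
  d <- params$freq$d
  lo <- d_lower_bound(f)
  if (d < lo || d >= 1) return(-Inf)
  lam <- params$lambda
  shrunk <- c(as.numeric(params$B), params$betaE, params$betaEh, params$betaS)
  sum(log(lam / 2) - lam * abs(shrunk)) +
    stats::dgamma(lam, shape = a, rate = b, log = TRUE) +
    stats::dnorm(params$beta0, 0, beta0_sd, log = TRUE) +
    lgamma(length(f)) +             # Dirichlet(1,...,1) on the simplex
    -log(1 - lo)                    # flat on the valid d range
}

#' One Gibbs sweep over the latent diplotypes
#'
#' Draws each individual's diplotype from its exact full conditional,
#' proportional to the product of the individual's Bernoulli likelihood
#' terms and the diplotype probability under the frequency model,
#' normalized over the individual's compatible pairs. With a flat
#' likelihood (all coefficients zero) the sampling weights reduce to the
#' frequency-model probabilities alone.
#'
#' @param params An `"lbl_params"` state.
#' @param cohort An `"lbl_cohort"`.
#' @param supports List of compatible-pair matrices per individual (from
#'   [enumerate_diplotypes()] / [haplotype_closure()]).
#' @return List of length-2 character vectors: the sampled diplotypes.
#' @export
gibbs_update_diplotypes <- function(params, cohort, supports) {
  stopifnot(inherits(params, "lbl_params"), inherits(cohort, "lbl_cohort"))
  phe <- cohort$phenotypes
  recs <- split(seq_len(nrow(phe)), phe$id_idx)
  out <- vector("list", length(cohort$ids))
  for (i in seq_along(out)) {
    sp <- supports[[i]]
    k <- nrow(sp)
    if (k == 1L) { out[[i]] <- sp[1L, ]; next }
    lw <- numeric(k)
    for (q in seq_len(k)) {
      w <- log(diplotype_probability(params$freq, sp[q, ]))
      for (r in recs[[as.character(i)]]) {
        row <- build_design_row(sp[q, ], phe[r, ], params$haplotypes)
        eta <- log_odds(params, row)
        w <- w + phe$y[r] * eta - .log1pexp(eta)
      }
      lw[q] <- w
    }
    p <- exp(lw - max(lw))
    out[[i]] <- sp[sample.int(k, 1L, prob = p), ]
  }
  out
}

# ---- model-data preparation --------------------------------------------

# EM core over integer-pair supports; returns frequencies + loglik trace
.em_core <- function(sup_idx, m, tol = 1e-8, max_iter = 500L) {
  n <- length(sup_idx)
  f <- rep(1 / m, m)
  ll_trace <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    counts <- numeric(m)
    ll <- 0
    for (i in seq_len(n)) {
      sp <- sup_idx[[i]]
      w <- ifelse(sp[, 1L] == sp[, 2L], f[sp[, 1L]]^2,
                  2 * f[sp[, 1L]] * f[sp[, 2L]])
      tot <- sum(w)
      ll <- ll + log(tot)
      w <- w / tot
      # homozygous pairs contribute both copies; repeated haplotype indices
      # across pairs must accumulate, so sum per index
      idx <- c(sp[, 1L], sp[, 2L])
      ww <- c(w, w)
      for (u in seq_along(idx)) counts[idx[u]] <- counts[idx[u]] + ww[u]
    }
    f_new <- counts / (2 * n)
    ll_trace <- c(ll_trace, ll)
    if (it > 1L && abs(ll - ll_trace[it - 1L]) <=
        tol * (abs(ll_trace[it - 1L]) + 1e-12)) {
      converged <- TRUE
      f <- f_new
      break
    }
    f <- f_new
  }
  list(f = f / sum(f), loglik = ll_trace, converged = converged)
}

# Build everything the sampler needs from a cohort and a SNP block.
# Haplotypes are ordered by descending EM frequency; the first (most
# frequent) is the reference. Haplotypes with EM frequency < min_hap_freq
# are pruned one at a time provided every individual keeps a nonempty
# support, and frequencies are re-estimated on the pruned universe.
.prepare_model_data <- function(cohort, snps = NULL, config = lbl_config()) {
  stopifnot(inherits(cohort, "lbl_cohort"))
  basis <- spline_basis(config$interior_knots, config$boundary_knots,
                        config$spline_order)
  phe <- cohort$phenotypes
  bad_age <- phe$age < basis$boundary_knots[1L] |
             phe$age > basis$boundary_knots[2L]
  if (any(bad_age))
    .stopf("%d phenotype record(s) have ages outside the boundary knots [%g, %g]",
           sum(bad_age), basis$boundary_knots[1L], basis$boundary_knots[2L])
  cl <- haplotype_closure(cohort$genotypes, snps)
  haps <- cl$haplotypes
  sup_str <- cl$supports
  to_idx <- function(sup, universe) lapply(sup, function(p) {
    keep <- p[, 1L] %in% universe & p[, 2L] %in% universe
    q <- p[keep, , drop = FALSE]
    cbind(match(q[, 1L], universe), match(q[, 2L], universe))
  })
  em <- .em_core(to_idx(sup_str, haps), length(haps))
  f <- em$f
  # prune near-zero-frequency haplotypes while keeping supports nonempty
  repeat {
    cand <- which(f < config$min_hap_freq)
    if (!length(cand) || length(haps) <= 2L) break
    drop_k <- cand[which.min(f[cand])]
    trial <- haps[-drop_k]
    tsup <- to_idx(sup_str, trial)
    if (any(vapply(tsup, nrow, 1L) == 0L)) break
    haps <- trial
    em <- .em_core(tsup, length(haps))
    f <- em$f
  }
  ord <- order(-f, haps)
  haps <- haps[ord]
  em <- .em_core(to_idx(sup_str, haps), length(haps))
  f <- em$f
  sup_idx <- to_idx(sup_str, haps)
  # initial assignment: most probable pair under the EM frequencies
  z_init <- vapply(sup_idx, function(sp) {
    w <- ifelse(sp[, 1L] == sp[, 2L], f[sp[, 1L]]^2,
                2 * f[sp[, 1L]] * f[sp[, 2L]])
    which.max(w)
  }, 1L)
  list(cohort = cohort, basis = basis, haplotypes = haps, f_start = f,
       em_loglik = em$loglik, supports = sup_idx,
       supports_str = lapply(sup_idx, function(sp)
         cbind(haps[sp[, 1L]], haps[sp[, 2L]])),
       B = evaluate_basis(basis, phe$age), z_init = z_init,
       rare = f < 0.05)
}

# ---- chain runner ------------------------------------------------------

#' Run the posterior sampling chain
#'
#' Low-level driver behind [lbl_tvc()]: prepares the haplotype universe,
#' EM starting frequencies and latent-diplotype supports from the cohort,
#' then runs the compiled Metropolis-within-Gibbs sampler. Exposed for
#' validation work (fixed-frequency runs, prior-only sampling, custom
#' blocks); most users should call [lbl_tvc()].
#'
#' @param cohort An `"lbl_cohort"`.
#' @param snps Optional character vector of block SNP ids (default: all
#'   SNPs in the cohort).
#' @param config An [lbl_config()].
#' @param init Optional named list overriding initial values (`beta0`,
#'   `B`, `betaE`, `betaEh`, `betaS`, `f`, `d`, `lambda`).
#' @return A list of class `"lbl_chain"`: post-burn-in draws (`beta0`,
#'   `B` as draws x (m-1)*n_basis, `betaE`, `betaEh`, `betaS`, `f`, `d`,
#'   `lambda`), `haplotypes` (reference first), `basis`, `f_start`,
#'   `rare`, `fitted` (posterior-mean per-record probabilities),
#'   `acceptance` (per-block rates after adaptation), `diagnostics`
#'   (effective sample size and Geweke z per stored scalar), `config`.
#' @export
run_chain <- function(cohort, snps = NULL, config = lbl_config(),
                      init = NULL) {
  md <- .prepare_model_data(cohort, snps, config)
  run_chain_prepared(md, config, init)
}

# chain on prepared model data (shared by run_chain and lbl_tvc)
run_chain_prepared <- function(md, config, init = NULL) {
  if (!is.null(config$seed)) set.seed(config$seed)
  m <- length(md$haplotypes)
  nb <- md$basis$n_basis
  phe <- md$cohort$phenotypes
  prev <- max(min(mean(phe$y[!duplicated(phe$id_idx)]), 0.99), 0.01)
  ini <- list(beta0 = qlogis(prev),
              B = matrix(0, max(m - 1L, 0L), nb),
              betaE = 0, betaEh = rep(0, max(m - 1L, 0L)), betaS = 0,
              f = md$f_start, d = 0,
              lambda = if (is.null(config$fix_lambda)) config$a / config$b
                       else config$fix_lambda)
  if (!is.null(init)) for (nm in names(init)) ini[[nm]] <- init[[nm]]
  ini$B <- matrix(ini$B, max(m - 1L, 0L), nb)
  ini$z <- md$z_init - 1L
  sup0 <- lapply(md$supports, function(sp) {
    storage.mode(sp) <- "integer"
    sp - 1L
  })
  ctl <- list(n_iter = config$n_iter, burnin = config$burnin,
              thin = config$thin, adapt = config$adapt,
              adapt_interval = config$adapt_interval,
              target_acc = config$target_acc, init_scale = config$init_scale,
              fix_f = config$fix_f, fix_d = config$fix_d,
              fix_lambda = !is.null(config$fix_lambda),
              sample_z = config$sample_z,
              use_likelihood = config$use_likelihood)
  res <- .run_chain_cpp(as.integer(phe$y), as.integer(phe$smoke),
                        as.integer(phe$sex),
                        as.integer(phe$id_idx) - 1L, md$B,
                        length(md$cohort$ids), sup0, m,
                        list(a = config$a, b = config$b,
                             beta0_sd = config$beta0_sd),
                        ini, ctl)
  nonref <- if (m > 1L) md$haplotypes[-1L] else character(0)
  colnames(res$B) <- if (m > 1L)
    paste0(rep(nonref, each = nb), ".b", rep(seq_len(nb), m - 1L)) else NULL
  colnames(res$betaEh) <- nonref
  colnames(res$f) <- md$haplotypes
  block_names <- c("beta0",
                   if (m > 1L) paste0("spline.", colnames(res$B)),
                   "betaE", if (m > 1L) paste0("betaEh.", nonref),
                   "betaS", "f", "d")
  acc <- data.frame(block = block_names,
                    acceptance = res$acceptance,
                    attempts = res$attempts,
                    scale = res$scales, stringsAsFactors = FALSE)
  draws <- cbind(beta0 = res$beta0, res$B, betaE = res$betaE,
                 res$betaEh, betaS = res$betaS, res$f,
                 d = res$d, lambda = res$lambda)
  diag <- data.frame(
    parameter = colnames(draws),
    ess = apply(draws, 2L, .ess),
    geweke_z = apply(draws, 2L, .geweke_z))
  rownames(diag) <- NULL
  structure(
    list(beta0 = res$beta0, B = res$B, betaE = res$betaE,
         betaEh = res$betaEh, betaS = res$betaS, f = res$f, d = res$d,
         lambda = res$lambda, fitted = res$fitted,
         haplotypes = md$haplotypes, basis = md$basis,
         f_start = md$f_start, rare = md$rare,
         acceptance = acc, diagnostics = diag, n_kept = res$n_kept,
         z_last = res$z_last + 1L, config = config),
    class = "lbl_chain")
}

#' @export
print.lbl_chain <- function(x, ...) {
  cat(sprintf("lbl_chain: %d stored draws, %d haplotypes (reference %s)\n",
              x$n_kept, length(x$haplotypes), x$haplotypes[1L]))
  mh <- x$acceptance[x$acceptance$attempts > 0, , drop = FALSE]
  cat(sprintf("MH acceptance (post-adaptation): min %.2f, median %.2f, max %.2f\n",
              min(mh$acceptance), stats::median(mh$acceptance),
              max(mh$acceptance)))
  invisible(x)
}

# effective sample size by Geyer's initial positive sequence
.ess <- function(x) {
  n <- length(x)
  if (n < 10L || stats::var(x) == 0) return(n)
  x <- x - mean(x)
  max_lag <- min(n - 1L, 200L)
  ac <- stats::acf(x, lag.max = max_lag, plot = FALSE,
                   demean = FALSE)$acf[, 1L, 1L]
  s <- 0
  k <- 1L
  while (k + 1L <= max_lag) {
    pair <- ac[k + 1L] + ac[k + 2L - (k + 1L > max_lag)]
    if (is.na(pair) || pair < 0) break
    s <- s + pair
    k <- k + 2L
  }
  max(1, n / (1 + 2 * s))
}

# Geweke convergence z-score (first 10% vs last 50%), batch-means variances
.geweke_z <- function(x) {
  n <- length(x)
  if (n < 40L || stats::var(x) == 0) return(0)
  a <- x[seq_len(max(4L, floor(0.1 * n)))]
  b <- x[seq(floor(0.5 * n) + 1L, n)]
  se2 <- function(v) {
    nb <- max(2L, floor(sqrt(length(v))))
    bs <- floor(length(v) / nb)
    bm <- vapply(seq_len(nb), function(k) mean(v[((k - 1L) * bs + 1L):(k * bs)]), 0)
    stats::var(bm) / nb
  }
  (mean(a) - mean(b)) / sqrt(se2(a) + se2(b))
}
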