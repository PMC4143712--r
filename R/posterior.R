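#' Odds-ratio curve of a haplotype over an age grid
#'
#' For every stored draw of a haplotype's spline coefficients, evaluates
#' the per-copy odds ratio \eqn{OR(t) = \exp(\sum_l \beta_{hl} B_l(t))} on
#' the age grid, and summarizes by the empirical 2.5th, 50th and 97.5th
#' percentiles (plus the mean). The point estimate is the posterior
#' median, which is robust under the strongly asymmetric intervals typical
#' of rare haplotypes.
#'
#' @param chain An `"lbl_chain"` (or an `"lbl_tvc"` fit, whose chain is
#'   used).
#' @param haplotype Haplotype string; must be a non-reference haplotype of
#'   the model.
#' @param age_grid Ages at which to evaluate; default the chain config's
#'   grid (25 to 95 by 5).
#' @return A list of class `"lbl_or_curve"`: `haplotype`, `age`,
#'   `summary` (data frame with `age`, `or` (median), `mean`, `lower`,
#'   `upper`, `significant`), and `draws` (draws x ages matrix of OR
#'   values).
#' @export
or_curve <- function(chain, haplotype, age_grid = NULL) {
  if (inherits(chain, "lbl_tvc")) chain <- chain$chain
  stopifnot(inherits(chain, "lbl_chain"))
  if (is.null(age_grid)) age_grid <- chain$config$age_grid
  nonref <- chain$haplotypes[-1L]
  h <- match(haplotype, nonref)
  if (is.na(h)) {
    if (haplotype == chain$haplotypes[1L])
      .stopf("'%s' is the reference haplotype; it has no effect curve", haplotype)
    .stopf("haplotype '%s' is not in the model", haplotype)
  }
  nb <- chain$basis$n_basis
  cols <- ((h - 1L) * nb + 1L):(h * nb)
  Bg <- evaluate_basis(chain$basis, age_grid)          # ages x nb
  draws <- exp(chain$B[, cols, drop = FALSE] %*% t(Bg))  # draws x ages
  colnames(draws) <- as.character(age_grid)
  qs <- apply(draws, 2L, quantile, probs = c(0.025, 0.5, 0.975),
              names = FALSE)
  summary <- data.frame(
    age = age_grid, or = qs[2L, ], mean = colMeans(draws),
    lower = qs[1L, ], upper = qs[3L, ])
  summary$significant <- summary$lower > 1 | summary$upper < 1
  structure(list(haplotype = haplotype, age = age_grid,
                 summary = summary, draws = draws),
            class = "lbl_or_curve")
}

#' @export
print.lbl_or_curve <- function(x, digits = 3L, ...) {
  cat(sprintf("OR(t) for haplotype %s (posterior median and 95%% credible bounds)\n",
              x$haplotype))
  tab <- x$summary
  tab[c("or", "mean", "lower", "upper")] <-
    lapply(tab[c("or", "mean", "lower", "upper")], signif, digits)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Significance calls from posterior summaries
#'
#' A haplotype is significant at age `t` when its 95% credible interval
#' for `OR(t)` strictly excludes 1 (an interval with a bound exactly at 1
#' is not significant), and significant overall when this holds at one or
#' more grid ages; an `ages` window restricts which grid ages count.
#' Scalar effects (smoking, sex, interactions) use the same
#' exclusion-of-1 rule.
#'
#' @param summary An `"lbl_or_curve"`, or a data frame with columns
#'   `lower` and `upper` (and optionally `age`).
#' @param ages Optional length-2 window `c(lo, hi)`; only grid ages inside
#'   it count toward the overall call.
#' @return A list: `per_age` (logical vector over the grid) and `overall`
#'   (logical scalar).
#' @export
call_significance <- function(summary, ages = NULL) {
  if (inherits(summary, "lbl_or_curve")) summary <- summary$summary
  stopifnot(all(c("lower", "upper") %in% colnames(summary)))
  per_age <- summary$lower > 1 | summary$upper < 1
  sel <- rep(TRUE, length(per_age))
  if (!is.null(ages) && "age" %in% colnames(summary))
    sel <- summary$age >= ages[1L] & summary$age <= ages[2L]
  list(per_age = per_age, overall = any(per_age & sel))
}

# scalar OR summary for one column of draws
.scalar_or_summary <- function(draws) {
  ord <- exp(draws)
  q <- quantile(ord, c(0.025, 0.5, 0.975), names = FALSE)
  data.frame(or = q[2L], mean = mean(ord), lower = q[1L], upper = q[3L],
             significant = q[1L] > 1 | q[3L] < 1)
}

#' Write report tables, curves and plots for a fit
#'
#' Writes to `out_dir`:
#' \itemize{
#'   \item `summary.tsv` — one row per non-reference haplotype per grid
#'     age with OR (posterior median), L and U (95% credible bounds) and
#'     the significance flag, mirroring the method's standard report
#'     layout (ages 25 to 95 by 5 gives 15 rows per haplotype);
#'   \item `scalar_effects.tsv` — smoking, sex and per-haplotype
#'     interaction ORs with bounds;
#'   \item `frequencies.tsv` — haplotype frequencies with rare flags;
#'   \item `curves/<hap>.csv` — the full curve per haplotype;
#'   \item `plots/<hap>.png` — an OR-vs-age plot for each significant
#'     haplotype;
#'   \item `run_manifest.json` — seed, settings, acceptance rates,
#'     diagnostics summary.
#' }
#'
#' @param fit An `"lbl_tvc"` fit (or `"lbl_chain"`).
#' @param out_dir Output directory (created if missing).
#' @param plots Write per-haplotype plots for significant haplotypes
#'   (default TRUE).
#' @return Invisibly, the paths written.
#' @export
report_tables <- function(fit, out_dir, plots = TRUE) {
  chain <- if (inherits(fit, "lbl_tvc")) fit$chain else fit
  stopifnot(inherits(chain, "lbl_chain"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) .stopf("cannot create output directory %s", out_dir)
  dir.create(file.path(out_dir, "curves"), showWarnings = FALSE)
  nonref <- chain$haplotypes[-1L]
  paths <- character(0)
  rows <- list()
  for (hp in nonref) {
    oc <- or_curve(chain, hp)
    s <- oc$summary
    rows[[hp]] <- data.frame(haplotype = hp, age = s$age, or = s$or,
                             lower = s$lower, upper = s$upper,
                             significant = as.integer(s$significant))
    cpath <- file.path(out_dir, "curves", paste0(hp, ".csv"))
    utils::write.csv(s, cpath, row.names = FALSE)
    paths <- c(paths, cpath)
  }
  summary_tab <- do.call(rbind, rows)
  if (is.null(summary_tab))
    summary_tab <- data.frame(haplotype = character(0), age = numeric(0),
                              or = numeric(0), lower = numeric(0),
                              upper = numeric(0), significant = integer(0))
  rownames(summary_tab) <- NULL
  spath <- file.path(out_dir, "summary.tsv")
  write.table(summary_tab, spath, sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- c(paths, spath)

  sc <- rbind(
    cbind(effect = "smoking", .scalar_or_summary(chain$betaE)),
    cbind(effect = "sex", .scalar_or_summary(chain$betaS)),
    do.call(rbind, lapply(seq_along(nonref), function(h)
      cbind(effect = paste0("smoking:", nonref[h]),
            .scalar_or_summary(chain$betaEh[, h])))))
  epath <- file.path(out_dir, "scalar_effects.tsv")
  write.table(sc, epath, sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- c(paths, epath)

  fpath <- file.path(out_dir, "frequencies.tsv")
  write_frequencies(hap_freq_model(chain$haplotypes,
                                   colMeans(chain$f),
                                   mean(chain$d)), fpath)
  paths <- c(paths, fpath)

  if (plots) {
    dir.create(file.path(out_dir, "plots"), showWarnings = FALSE)
    for (hp in nonref) {
      oc <- or_curve(chain, hp)
      if (!any(oc$summary$significant)) next
      ppath <- file.path(out_dir, "plots", paste0(hp, ".png"))
      grDevices::png(ppath, width = 700, height = 500)
      .plot_or_curve(oc)
      grDevices::dev.off()
      paths <- c(paths, ppath)
    }
  }

  manifest <- list(
    seed = chain$config$seed,
    n_iter = chain$config$n_iter, burnin = chain$config$burnin,
    thin = chain$config$thin, n_kept = chain$n_kept,
    haplotypes = chain$haplotypes, reference = chain$haplotypes[1L],
    acceptance = chain$acceptance,
    diagnostics = list(min_ess = min(chain$diagnostics$ess),
                       max_abs_geweke = max(abs(chain$diagnostics$geweke_z))))
  mpath <- file.path(out_dir, "run_manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(c(paths, mpath))
}

.plot_or_curve <- function(oc, n_fine = 200L, basis = NULL, chain = NULL) {
  s <- oc$summary
  ylim <- range(c(s$lower, s$upper, 1))
  plot(s$age, s$or, type = "l", lwd = 2, ylim = ylim, log = "y",
       xlab = "Age (years)", ylab = "Odds ratio",
       main = sprintf("Haplotype %s", oc$haplotype))
  graphics::lines(s$age, s$lower, lty = 3, col = "red")
  graphics::lines(s$age, s$upper, lty = 3, col = "red")
  graphics::abline(h = 1, col = "grey60")
}
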