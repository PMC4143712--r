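#' Single-SNP logistic prescreen at the first examination
#'
#' For one SNP, fits the first-examination logistic model
#' \deqn{logit P(Y_1 = 1) = \beta_0 + \beta_1 SNP_k + \beta_2 SMOKE_1 +
#'   \beta_3 AGE_1 + \beta_4 SEX}
#' with the SNP coded additively (0/1/2 copies of the minor allele), and
#' tests the SNP term by the 1-df likelihood-ratio chi-square (the
#' `anova(..., test = "Chisq")` comparison of the model with and without
#' the SNP). This is a screen used to pick anchor SNPs for haplotype
#' blocks, not an inference: no multiplicity correction is applied.
#'
#' Monomorphic SNPs are skipped with `p = 1` and a warning. If the fit
#' shows complete or quasi-complete separation, the p-value is recomputed
#' from a Firth (Jeffreys-prior) penalized likelihood-ratio test and the
#' fit is flagged.
#'
#' @param cohort An `"lbl_cohort"` from [join_cohort()].
#' @param snp_id SNP identifier present in the cohort's genotype table.
#' @return A list of class `"lbl_prescreen_fit"`: `snp_id`, `coefficients`
#'   (named `beta0..beta4`), `lrt` (likelihood-ratio statistic), `df`,
#'   `p_value`, `skipped` (monomorphic), `separation` (penalized refit used),
#'   `minor_allele`.
#' @seealso [prescreen_snps()], [select_anchors()], [build_block()]
#' @export
fit_single_snp <- function(cohort, snp_id) {
  stopifnot(inherits(cohort, "lbl_cohort"))
  j <- match(snp_id, cohort$genotypes$snps)
  if (is.na(j)) .stopf("SNP '%s' not found in cohort", snp_id)
  first <- .first_exam(cohort)
  g <- .additive_dosage(cohort$genotypes, j)[first$id_idx]
  dat <- data.frame(y = first$y, snp = g, smoke = first$smoke,
                    age = first$age, sex = first$sex)
  out <- list(snp_id = snp_id, df = 1L, skipped = FALSE, separation = FALSE,
              minor_allele = attr(g, "minor"))
  if (length(unique(g)) < 2L) {
    .warnf("SNP '%s' is monomorphic at the first examination; skipped", snp_id)
    out$skipped <- TRUE
    out$lrt <- 0
    out$p_value <- 1
    out$coefficients <- c(beta0 = NA_real_, beta1 = NA_real_, beta2 = NA_real_,
                          beta3 = NA_real_, beta4 = NA_real_)
    class(out) <- "lbl_prescreen_fit"
    return(out)
  }
  full <- suppressWarnings(glm(y ~ snp + smoke + age + sex, family = binomial(),
                               data = dat))
  null <- suppressWarnings(glm(y ~ smoke + age + sex, family = binomial(),
                               data = dat))
  sep <- .detect_separation(full)
  if (sep) {
    out$separation <- TRUE
    X_full <- stats::model.matrix(~ snp + smoke + age + sex, dat)
    X_null <- stats::model.matrix(~ smoke + age + sex, dat)
    f_full <- .firth_logistic(X_full, dat$y)
    f_null <- .firth_logistic(X_null, dat$y)
    out$lrt <- max(0, 2 * (f_full$loglik_pen - f_null$loglik_pen))
    out$coefficients <- setNames(as.numeric(f_full$beta), paste0("beta", 0:4))
  } else {
    out$lrt <- max(0, null$deviance - full$deviance)
    out$coefficients <- setNames(as.numeric(coef(full)), paste0("beta", 0:4))
  }
  out$p_value <- stats::pchisq(out$lrt, df = 1L, lower.tail = FALSE)
  class(out) <- "lbl_prescreen_fit"
  out
}

#' @export
print.lbl_prescreen_fit <- function(x, ...) {
  cat(sprintf("SNP %s: LRT = %.4f (df = %d), p = %.4g%s%s\n",
              x$snp_id, x$lrt, x$df, x$p_value,
              if (x$skipped) " [monomorphic, skipped]" else "",
              if (x$separation) " [separation; Firth refit]" else ""))
  invisible(x)
}

.first_exam <- function(cohort) {
  phe <- cohort$phenotypes
  phe[!duplicated(phe$id_idx), , drop = FALSE]
}

# 0/1/2 copies of the minor allele (minor at that SNP among cohort alleles)
.additive_dosage <- function(genotypes, j) {
  al <- c(genotypes$a1[, j], genotypes$a2[, j])
  tab <- sort(table(al))
  minor <- names(tab)[1L]
  g <- (genotypes$a1[, j] == minor) + (genotypes$a2[, j] == minor)
  attr(g, "minor") <- minor
  g
}

.detect_separation <- function(fit) {
  p <- fitted(fit)
  eps <- 1e-8
  big <- any(abs(coef(fit)[-1L]) > 12, na.rm = TRUE)
  boundary <- any(p < eps | p > 1 - eps)
  (!fit$converged) || big || (boundary && big)
}

# Firth (Jeffreys-prior) penalized logistic regression by Newton iteration.
# Penalized log-likelihood: l(b) + 0.5 * log det(X'WX).
.firth_logistic <- function(X, y, max_iter = 100, tol = 1e-8) {
  b <- rep(0, ncol(X))
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% b)
    p <- plogis(eta)
    w <- p * (1 - p)
    XtW <- t(X * w)
    I <- XtW %*% X
    # hat values of the weighted design
    U <- chol(I + diag(1e-10, ncol(X)))
    h <- w * rowSums((X %*% chol2inv(U)) * X)
    score <- drop(t(X) %*% (y - p + h * (0.5 - p)))
    step <- solve(I + diag(1e-10, ncol(X)), score)
    b <- b + step
    if (max(abs(step)) < tol) break
  }
  eta <- drop(X %*% b)
  p <- plogis(eta)
  ll <- sum(y * eta - log1p(exp(eta)))
  w <- p * (1 - p)
  I <- t(X * w) %*% X
  list(beta = b, loglik = ll,
       loglik_pen = ll + 0.5 * determinant(I, logarithm = TRUE)$modulus)
}

#' Prescreen all (or a subset of) SNPs
#'
#' Runs [fit_single_snp()] across SNPs and collects the results in a table.
#'
#' @param cohort An `"lbl_cohort"`.
#' @param snp_ids SNPs to screen; default all SNPs in the cohort.
#' @return A `data.frame` with columns `snp`, `position` (NA if unknown),
#'   `beta`, `lrt`, `p`, `skipped`, `separation`, ordered as the input SNPs.
#' @export
prescreen_snps <- function(cohort, snp_ids = cohort$genotypes$snps) {
  fits <- lapply(snp_ids, function(s) fit_single_snp(cohort, s))
  pos <- if (is.null(cohort$genotypes$positions)) rep(NA_integer_, length(snp_ids))
         else cohort$genotypes$positions[match(snp_ids, cohort$genotypes$snps)]
  data.frame(
    snp = snp_ids,
    position = pos,
    beta = vapply(fits, function(f) unname(f$coefficients["beta1"]), 0),
    lrt = vapply(fits, function(f) f$lrt, 0),
    p = vapply(fits, function(f) f$p_value, 0),
    skipped = vapply(fits, function(f) f$skipped, TRUE),
    separation = vapply(fits, function(f) f$separation, TRUE),
    stringsAsFactors = FALSE)
}

#' Select anchor SNPs by smallest prescreen p-value
#'
#' Picks the `k` SNPs with the smallest p-values; ties at the selection
#' boundary are broken in favour of the smaller bp position (input order
#' when positions are unknown).
#'
#' @param fits Data frame from [prescreen_snps()].
#' @param k Number of anchors (default 4).
#' @return Character vector of `k` SNP ids, ordered by ascending p.
#' @export
select_anchors <- function(fits, k = 4L) {
  stopifnot(is.data.frame(fits), nrow(fits) >= 1L, k >= 1L)
  if (k > nrow(fits))
    .stopf("k = %d exceeds the number of prescreen fits (%d)", k, nrow(fits))
  tie <- if (all(is.na(fits$position))) seq_len(nrow(fits)) else fits$position
  ord <- order(fits$p, tie)
  fits$snp[ord[seq_len(k)]]
}

#' Build a 5-SNP haplotype block around an anchor SNP
#'
#' The block is the anchor plus its `flank` adjacent SNPs on each side in
#' map order. When the anchor sits within `flank` SNPs of either end of the
#' map, the window shifts inward so the block keeps its full width.
#'
#' @param snp_list Ordered character vector of all SNP ids (map order).
#' @param anchor Anchor SNP id, present in `snp_list`.
#' @param flank SNPs on each side (default 2, giving 5-SNP blocks).
#' @param positions Optional bp positions parallel to `snp_list`.
#' @return A list of class `"lbl_block"`: `anchor`, `snps` (length
#'   `2 * flank + 1`), `span` (bp range or `NULL`).
#' @export
build_block <- function(snp_list, anchor, flank = 2L, positions = NULL) {
  width <- 2L * flank + 1L
  if (length(snp_list) < width)
    .stopf("need at least %d SNPs to build a block; have %d",
           width, length(snp_list))
  i <- match(anchor, snp_list)
  if (is.na(i)) .stopf("anchor SNP '%s' not in snp_list", anchor)
  lo <- max(1L, min(i - flank, length(snp_list) - width + 1L))
  idx <- seq(lo, lo + width - 1L)
  span <- if (!is.null(positions)) range(positions[idx]) else NULL
  structure(list(anchor = anchor, snps = snp_list[idx], span = span),
            class = "lbl_block")
}

#' @export
print.lbl_block <- function(x, ...) {
  cat(sprintf("lbl_block: anchor %s; SNPs: %s%s\n", x$anchor,
              paste(x$snps, collapse = ", "),
              if (is.null(x$span)) ""
              else sprintf(" (span %d-%d bp)", x$span[1L], x$span[2L])))
  invisible(x)
}
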