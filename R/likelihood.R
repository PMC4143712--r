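# numerically stable log(1 + exp(x)); safe over |x| <= 700 and beyond
.log1pexp <- function(x) {
  out <- numeric(length(x))
  lo <- x <= -37
  hi <- x >= 34
  mid <- !lo & !hi
  out[lo] <- exp(x[lo])
  out[mid] <- log1p(exp(x[mid]))
  out[hi] <- x[hi] + exp(-x[hi])
  out
}

#' Parameter state of the time-varying haplotype model
#'
#' Collects every parameter of the logistic model
#' \deqn{\log \theta_{Z,E}(t) = \beta_0 + \sum_h X_h \sum_l \beta_{hl} B_l(t)
#'   + \beta_E X_E(t) + \sum_h \beta_{E,h} X_{E,h}(t) + \beta_s X_s}
#' together with the haplotype frequency model (frequencies and inbreeding
#' coefficient) and the shared Laplace shrinkage intensity. Spline
#' coefficients exist for every non-reference haplotype; the reference
#' (baseline) haplotype is the first element of `haplotypes`.
#'
#' @param haplotypes Character vector of all m haplotypes; the first is the
#'   reference.
#' @param basis An `"lbl_spline_basis"`.
#' @param beta0 Intercept.
#' @param B (m-1) x `n_basis` matrix of spline coefficients (rows follow
#'   `haplotypes[-1]`). Scalars are recycled.
#' @param betaE Smoking main effect (time-constant coefficient on the
#'   time-varying smoking status).
#' @param betaEh Length m-1 vector of haplotype-by-smoking interaction
#'   effects (time-constant).
#' @param betaS Sex effect.
#' @param freq A `"hap_freq_model"` over the same haplotypes (any order
#'   permitted; matched by name).
#' @param lambda Laplace shrinkage intensity (default 1).
#' @return A list of class `"lbl_params"`.
#' @export
lbl_params <- function(haplotypes, basis, beta0 = 0, B = 0, betaE = 0,
                       betaEh = 0, betaS = 0, freq = NULL, lambda = 1) {
  stopifnot(inherits(basis, "lbl_spline_basis"), length(haplotypes) >= 1L)
  m <- length(haplotypes)
  nb <- basis$n_basis
  if (length(B) == 1L) B <- matrix(B, max(m - 1L, 0L), nb)
  B <- as.matrix(B)
  if (m > 1L && (nrow(B) != m - 1L || ncol(B) != nb))
    .stopf("B must be (m-1) x n_basis = %d x %d", m - 1L, nb)
  rownames(B) <- if (m > 1L) haplotypes[-1L] else NULL
  if (length(betaEh) == 1L) betaEh <- rep(betaEh, max(m - 1L, 0L))
  if (length(betaEh) != max(m - 1L, 0L))
    .stopf("betaEh must have length m-1 = %d", m - 1L)
  if (is.null(freq)) freq <- hap_freq_model(haplotypes, rep(1 / m, m), 0)
  stopifnot(inherits(freq, "hap_freq_model"))
  if (!setequal(freq$haplotypes, haplotypes))
    .stopf("freq model haplotypes differ from the parameter state's")
  structure(
    list(haplotypes = haplotypes, basis = basis, beta0 = beta0, B = B,
         betaE = betaE, betaEh = setNames(betaEh, rownames(B)),
         betaS = betaS, freq = freq, lambda = lambda),
    class = "lbl_params")
}

#' Build the design row for one examination record
#'
#' `X_h` counts copies (0/1/2) of each non-reference haplotype in the
#' diplotype; copies over all haplotypes including the reference always sum
#' to 2, so a reference homozygote has `X_h = 0`. `X_E(t)` is the smoking
#' status at the exam, `X_Eh = X_h * X_E` the interaction design, `X_s`
#' the sex.
#'
#' @param diplotype Length-2 character vector (the haplotype pair).
#' @param exam_record List or one-row data frame with elements `smoke`,
#'   `age`, `sex`.
#' @param haplotypes Character vector of all haplotypes, reference first.
#' @return List of class `"lbl_design_row"`: `Xh` (named, non-reference),
#'   `XE`, `XEh`, `Xs`, `t`.
#' @export
build_design_row <- function(diplotype, exam_record, haplotypes) {
  stopifnot(length(diplotype) == 2L)
  if (!all(diplotype %in% haplotypes))
    .stopf("diplotype contains haplotype(s) outside the model")
  nonref <- haplotypes[-1L]
  Xh <- setNames(numeric(length(nonref)), nonref)
  for (hp in diplotype) if (hp %in% nonref) Xh[hp] <- Xh[hp] + 1
  XE <- as.numeric(exam_record$smoke)
  structure(list(Xh = Xh, XE = XE, XEh = Xh * XE,
                 Xs = as.numeric(exam_record$sex),
                 t = as.numeric(exam_record$age)),
            class = "lbl_design_row")
}

#' Log odds of affection for one design row
#'
#' Evaluates the linear predictor
#' \eqn{\beta_0 + \sum_h X_h \beta_h(t) + \beta_E X_E + \sum_h \beta_{E,h}
#' X_{E,h} + \beta_s X_s}, with each \eqn{\beta_h(t)} expanded in the
#' spline basis at the record's age.
#'
#' @param params An `"lbl_params"` state.
#' @param design_row An `"lbl_design_row"` from [build_design_row()].
#' @return The log odds (a scalar).
#' @export
log_odds <- function(params, design_row) {
  stopifnot(inherits(params, "lbl_params"),
            inherits(design_row, "lbl_design_row"))
  b <- evaluate_basis(params$basis, design_row$t)[1L, ]
  hap_eff <- if (nrow(params$B)) drop(params$B %*% b) else numeric(0)
  params$beta0 +
    sum(design_row$Xh * hap_eff) +
    params$betaE * design_row$XE +
    sum(params$betaEh * design_row$XEh) +
    params$betaS * design_row$Xs
}

#' Complete-data prospective log-likelihood
#'
#' Given a diplotype assignment for every individual, evaluates
#' \deqn{\sum_{i,j} [Y_{ij} \eta_{ij} - \log(1 + e^{\eta_{ij}})] +
#'   \sum_i \log P(Z_i | f, d),}
#' where \eqn{\eta_{ij}} is the record's log odds and disease statuses are
#' conditionally independent across examinations given the exam-specific
#' mean. The smoking-process and sex factors of the full complete-data
#' likelihood carry no model parameters and are omitted as multiplicative
#' constants.
#'
#' @param params An `"lbl_params"` state.
#' @param cohort An `"lbl_cohort"`.
#' @param assignment List (one element per cohort individual, in cohort id
#'   order) of length-2 character vectors: the assigned diplotype.
#' @param supports Optional list of compatible-pair matrices (from
#'   [enumerate_diplotypes()]); when given, each assignment is checked to
#'   lie in the individual's support.
#' @return The log-likelihood (a scalar).
#' @export
complete_data_loglik <- function(params, cohort, assignment, supports = NULL) {
  stopifnot(inherits(params, "lbl_params"), inherits(cohort, "lbl_cohort"))
  n <- length(cohort$ids)
  if (length(assignment) != n)
    .stopf("assignment must have one diplotype per individual (%d)", n)
  if (!is.null(supports)) {
    for (i in seq_len(n)) {
      z <- sort(assignment[[i]])
      ok <- any(supports[[i]][, 1L] == z[1L] & supports[[i]][, 2L] == z[2L])
      if (!ok) .stopf("assigned diplotype for individual %d not in its support", i)
    }
  }
  phe <- cohort$phenotypes
  ll <- 0
  for (r in seq_len(nrow(phe))) {
    i <- phe$id_idx[r]
    row <- build_design_row(assignment[[i]], phe[r, ], params$haplotypes)
    eta <- log_odds(params, row)
    ll <- ll + phe$y[r] * eta - .log1pexp(eta)
  }
  for (i in seq_len(n))
    ll <- ll + log(diplotype_probability(params$freq, assignment[[i]]))
  ll
}
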