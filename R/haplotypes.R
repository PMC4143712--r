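#' Enumerate diplotypes compatible with an unphased genotype
#'
#' A diplotype is an unordered pair of haplotypes whose site-wise union
#' reproduces the unphased multilocus genotype exactly. With `h`
#' heterozygous sites and an unrestricted universe there are
#' `2^(h-1)` compatible pairs for `h >= 1` and exactly one for `h = 0`.
#' Restricting to a haplotype universe filters pairs whose members are not
#' both in the universe; an empty result after filtering is an error (the
#' caller must extend the universe).
#'
#' @param genotype A 2 x S character matrix: the two (unordered) alleles at
#'   each of the S block SNPs, no missing values.
#' @param universe Optional character vector of allowed haplotype strings;
#'   `NULL` means unrestricted.
#' @return A k x 2 character matrix of haplotype strings, one row per
#'   compatible unordered pair (row-wise lexicographically sorted).
#' @export
enumerate_diplotypes <- function(genotype, universe = NULL) {
  stopifnot(is.matrix(genotype), nrow(genotype) == 2L)
  if (anyNA(genotype))
    .stopf("genotype must be complete at all block SNPs")
  S <- ncol(genotype)
  het <- which(genotype[1L, ] != genotype[2L, ])
  h <- length(het)
  base1 <- genotype[1L, ]
  base2 <- genotype[2L, ]
  if (h == 0L) {
    pairs <- matrix(paste(base1, collapse = ""), 1L, 2L)
  } else {
    # fix the orientation of the first heterozygous site; vary the rest
    nfree <- h - 1L
    k <- 2L ^ nfree
    pairs <- matrix("", k, 2L)
    for (c in seq_len(k)) {
      hap1 <- base1
      hap2 <- base2
      if (nfree > 0L) {
        bits <- as.integer(intToBits(c - 1L))[seq_len(nfree)]
        flip <- het[-1L][bits == 1L]
        tmp <- hap1[flip]
        hap1[flip] <- hap2[flip]
        hap2[flip] <- tmp
      }
      s1 <- paste(hap1, collapse = "")
      s2 <- paste(hap2, collapse = "")
      pairs[c, ] <- if (s1 <= s2) c(s1, s2) else c(s2, s1)
    }
  }
  pairs <- unique(pairs)
  if (!is.null(universe)) {
    keep <- pairs[, 1L] %in% universe & pairs[, 2L] %in% universe
    pairs <- pairs[keep, , drop = FALSE]
    if (nrow(pairs) == 0L)
      .stopf("no diplotype in the universe is compatible with the genotype; extend the universe")
  }
  pairs[order(pairs[, 1L], pairs[, 2L]), , drop = FALSE]
}

#' Haplotype frequency model with inbreeding coefficient
#'
#' Frequencies `f` over `m` haplotypes together with an inbreeding
#' coefficient `d` define the diplotype distribution
#' \deqn{P(z_k/z_{k'}) = \delta_{kk'} d f_k + (2 - \delta_{kk'}) (1 - d) f_k f_{k'},}
#' where \eqn{\delta_{kk'} = 1} if \eqn{k = k'}. `d > 0` captures excess
#' homozygosity, `d < 0` a deficit; `d = 0` is Hardy-Weinberg equilibrium.
#' Validity requires `d < 1` and `d >= max_k(-f_k / (1 - f_k))` so every
#' diplotype probability is nonnegative.
#'
#' @param haplotypes Character vector of m haplotype strings.
#' @param f Numeric vector of m frequencies (nonnegative, summing to 1).
#' @param d Inbreeding coefficient in (-1, 1), within the valid range for `f`.
#' @return A list of class `"hap_freq_model"` with elements `haplotypes`,
#'   `f`, `d`.
#' @export
hap_freq_model <- function(haplotypes, f, d = 0) {
  haplotypes <- as.character(haplotypes)
  f <- as.numeric(f)
  if (length(f) != length(haplotypes))
    .stopf("length(f) != number of haplotypes")
  if (anyDuplicated(haplotypes)) .stopf("duplicated haplotypes")
  if (any(f < 0) || abs(sum(f) - 1) > 1e-8)
    .stopf("frequencies must be nonnegative and sum to 1")
  if (d <= -1 || d >= 1) .stopf("d must lie in (-1, 1)")
  if (d < d_lower_bound(f) - 1e-12)
    .stopf("d = %.4f below the validity bound %.4f for these frequencies",
           d, d_lower_bound(f))
  structure(list(haplotypes = haplotypes, f = f, d = d),
            class = "hap_freq_model")
}

#' Lower validity bound for the inbreeding coefficient
#'
#' Smallest `d` for which every diplotype probability under frequencies `f`
#' is nonnegative: `max_k(-f_k / (1 - f_k))`.
#'
#' @param f Numeric frequency vector.
#' @return The bound (a nonpositive number).
#' @export
d_lower_bound <- function(f) {
  f <- f[f < 1]
  if (!length(f)) return(-1)
  max(-f / (1 - f))
}

#' Diplotype probability under a frequency model
#'
#' Evaluates the diplotype distribution of [hap_freq_model()]:
#' homozygote `k/k` has probability `d f_k + (1 - d) f_k^2`; heterozygote
#' `k/k'` has probability `2 (1 - d) f_k f_k'`. Probabilities over all
#' unordered pairs sum to 1.
#'
#' @param model A `"hap_freq_model"`.
#' @param pair Length-2 vector: haplotype indices (integer) or haplotype
#'   strings naming an unordered pair.
#' @return The probability of the pair.
#' @export
diplotype_probability <- function(model, pair) {
  stopifnot(inherits(model, "hap_freq_model"), length(pair) == 2L)
  if (is.character(pair)) {
    idx <- match(pair, model$haplotypes)
    if (anyNA(idx)) .stopf("haplotype(s) not in the model: %s",
                           paste(pair[is.na(idx)], collapse = ", "))
  } else {
    idx <- as.integer(pair)
    if (any(idx < 1L | idx > length(model$f)))
      .stopf("pair indices outside the model")
  }
  f <- model$f; d <- model$d
  k <- idx[1L]; kp <- idx[2L]
  if (k == kp) d * f[k] + (1 - d) * f[k]^2
  else 2 * (1 - d) * f[k] * f[kp]
}

# all unordered pairs (matrix 2 x n_pairs of indices)
.all_pairs <- function(m) {
  idx <- which(upper.tri(matrix(0, m, m), diag = TRUE), arr.ind = TRUE)
  t(idx[, c(2L, 1L), drop = FALSE])  # row <= col
}

#' Haplotype universe implied by a set of unphased genotypes
#'
#' The closure of the data: every haplotype that appears in at least one
#' compatible phasing of at least one individual. This keeps the model's
#' haplotype list at the data-supported set without pooling rare
#' haplotypes.
#'
#' @param genotypes An `"lbl_genotypes"` object (complete genotypes).
#' @param snps Optional SNP subset (character ids), default all.
#' @return List with `haplotypes` (sorted character vector) and `supports`
#'   (per individual, the k x 2 matrix from [enumerate_diplotypes()]).
#' @export
haplotype_closure <- function(genotypes, snps = NULL) {
  g <- .block_genotypes(genotypes, snps)
  supports <- lapply(seq_along(g$ids), function(i)
    enumerate_diplotypes(rbind(g$a1[i, ], g$a2[i, ])))
  haps <- sort(unique(unlist(supports)))
  list(haplotypes = haps, supports = supports)
}

.block_genotypes <- function(genotypes, snps = NULL) {
  stopifnot(inherits(genotypes, "lbl_genotypes"))
  if (is.null(snps)) snps <- genotypes$snps
  j <- match(snps, genotypes$snps)
  if (anyNA(j)) .stopf("SNP(s) not in genotype table: %s",
                       paste(snps[is.na(j)], collapse = ", "))
  a1 <- genotypes$a1[, j, drop = FALSE]
  a2 <- genotypes$a2[, j, drop = FALSE]
  if (anyNA(a1) || anyNA(a2))
    .stopf("block genotypes must be complete; flagged individuals should have been dropped")
  list(ids = genotypes$ids, a1 = a1, a2 = a2)
}

#' Haplotype frequencies by EM under Hardy-Weinberg equilibrium
#'
#' Standard multinomial haplotype-frequency EM over the unphased block
#' genotypes: the E-step distributes each individual over its compatible
#' diplotypes proportionally to the HWE pair probabilities; the M-step
#' re-estimates frequencies from expected haplotype counts. The
#' observed-data log-likelihood is nondecreasing across iterations. The
#' result (with `d = 0`) is used as the starting value of the MCMC
#' frequency block. Haplotypes with fitted frequency below 0.05 are
#' labelled rare for reporting.
#'
#' @param genotypes An `"lbl_genotypes"` object, or an `"lbl_cohort"`.
#' @param snps Optional SNP subset defining the block (default all SNPs).
#' @param tol Relative log-likelihood convergence tolerance (default 1e-8).
#' @param max_iter Maximum EM iterations (default 500); hitting it returns
#'   the last iterate with a warning.
#' @return A `"hap_freq_model"` with extra attributes: `loglik` (trace of
#'   observed-data log-likelihood), `converged`, `rare` (logical vector,
#'   frequency < 0.05), `supports` (per-individual compatible pairs).
#' @export
em_haplotype_frequencies <- function(genotypes, snps = NULL, tol = 1e-8,
                                     max_iter = 500L) {
  if (inherits(genotypes, "lbl_cohort")) genotypes <- genotypes$genotypes
  cl <- haplotype_closure(genotypes, snps)
  haps <- cl$haplotypes
  sup_idx <- lapply(cl$supports, function(p)
    cbind(match(p[, 1L], haps), match(p[, 2L], haps)))
  em <- .em_core(sup_idx, length(haps), tol = tol, max_iter = max_iter)
  if (!em$converged)
    .warnf("haplotype-frequency EM did not converge in %d iterations", max_iter)
  model <- hap_freq_model(haps, em$f, d = 0)
  attr(model, "loglik") <- em$loglik
  attr(model, "converged") <- em$converged
  attr(model, "rare") <- em$f < 0.05
  attr(model, "supports") <- cl$supports
  model
}

#' @export
print.hap_freq_model <- function(x, ...) {
  rare <- attr(x, "rare")
  cat(sprintf("hap_freq_model: %d haplotypes, d = %.4f\n", length(x$f), x$d))
  tab <- data.frame(haplotype = x$haplotypes, frequency = round(x$f, 4))
  if (!is.null(rare)) tab$rare <- ifelse(rare, "*", "")
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Write haplotype frequencies as TSV
#'
#' Columns: haplotype, frequency, rare flag (frequency < 0.05).
#'
#' @param model A `"hap_freq_model"`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_frequencies <- function(model, path) {
  stopifnot(inherits(model, "hap_freq_model"))
  tab <- data.frame(haplotype = model$haplotypes, frequency = model$f,
                    rare = as.integer(model$f < 0.05))
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
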