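test_that("diplotype enumeration matches the exhaustive-pairs oracle", {
  # oracle: try all unordered pairs over the full 2^S universe
  oracle_enumerate <- function(genotype) {
    S <- ncol(genotype)
    universe <- apply(expand.grid(rep(list(c("A", "G")), S)), 1, paste,
                      collapse = "")
    pairs <- t(combn(c(universe, universe), 2))  # with replacement below
    pairs <- unique(rbind(t(combn(universe, 2)), cbind(universe, universe)))
    keep <- apply(pairs, 1, function(pr) {
      g1 <- strsplit(pr[1], "")[[1]]
      g2 <- strsplit(pr[2], "")[[1]]
      all(vapply(seq_len(S), function(k)
        setequal(c(g1[k], g2[k]), genotype[, k]) ||
          (g1[k] == g2[k] && genotype[1, k] == genotype[2, k] &&
           g1[k] == genotype[1, k]), TRUE))
    })
    out <- pairs[keep, , drop = FALSE]
    out <- t(apply(out, 1, sort))
    out[order(out[, 1], out[, 2]), , drop = FALSE]
  }
  set.seed(3)
  for (S in c(2, 3, 5)) {
    for (rep in 1:5) {
      a1 <- sample(c("A", "G"), S, TRUE)
      a2 <- sample(c("A", "G"), S, TRUE)
      geno <- rbind(a1, a2)
      got <- enumerate_diplotypes(geno)
      expect_equal(unname(got), unname(oracle_enumerate(geno)))
      h <- sum(a1 != a2)
      expect_equal(nrow(got), if (h == 0) 1 else 2^(h - 1))
    }
  }
})

test_that("enumeration respects the universe and errors on empty support", {
  geno <- rbind(c("A", "A", "G", "C", "C"),
                c("A", "G", "G", "C", "C"))  # heterozygous at site 2 only
  full <- enumerate_diplotypes(geno)
  expect_equal(nrow(full), 1L)
  expect_setequal(full[1, ], c("AAGCC", "AGGCC"))
  expect_error(enumerate_diplotypes(geno, universe = c("AAGCC", "CCCCC")),
               "extend the universe")
  # three heterozygous sites: 4 pairs
  geno3 <- rbind(c("A", "A", "G", "C", "C"),
                 c("G", "G", "G", "C", "G"))
  expect_equal(nrow(enumerate_diplotypes(geno3)), 4L)
})

test_that("diplotype probabilities follow the inbreeding-coefficient model", {
  m <- hap_freq_model(c("A", "B", "C"), c(0.3, 0.2, 0.5), d = 0)
  expect_equal(diplotype_probability(m, c("A", "A")), 0.09)   # HWE square
  expect_equal(diplotype_probability(m, c("A", "B")), 0.12)   # 2 f1 f2
  m2 <- hap_freq_model(c("A", "B"), c(0.5, 0.5), d = 0.2)
  expect_equal(diplotype_probability(m2, c(1, 1)), 0.2 * 0.5 + 0.8 * 0.25)
  expect_equal(diplotype_probability(m2, c(2, 2)), 0.3)
  expect_equal(diplotype_probability(m2, c(1, 2)), 0.8 * 2 * 0.25)
  expect_equal(diplotype_probability(m2, c(1, 1)) +
               diplotype_probability(m2, c(2, 2)) +
               diplotype_probability(m2, c(1, 2)), 1.0)
  expect_error(diplotype_probability(m, c(1, 4)), "outside")
})

test_that("diplotype probabilities sum to 1 for random valid (f, d)", {
  for (s in 1:40) {
    m <- random_freq_model(sample(2:8, 1), seed = s)
    pairs <- lbltvc:::.all_pairs(length(m$f))
    tot <- sum(apply(pairs, 2, function(pr) diplotype_probability(m, pr)))
    expect_equal(tot, 1, tolerance = 1e-12)
  }
})

test_that("d = 0 reduces exactly to Hardy-Weinberg products", {
  m <- random_freq_model(5, seed = 99)
  m0 <- hap_freq_model(m$haplotypes, m$f, d = 0)
  for (k in 1:5) for (kp in k:5) {
    hwe <- if (k == kp) m$f[k]^2 else 2 * m$f[k] * m$f[kp]
    expect_identical(diplotype_probability(m0, c(k, kp)), hwe)
  }
})

test_that("invalid frequency models are rejected", {
  expect_error(hap_freq_model(c("A", "B"), c(0.6, 0.6)), "sum to 1")
  expect_error(hap_freq_model(c("A", "B"), c(0.5, 0.5), d = 1), "in \\(-1, 1\\)")
  # d below the nonnegativity bound for these frequencies
  expect_error(hap_freq_model(c("A", "B"), c(0.9, 0.1), d = -0.5), "bound")
})

test_that("EM frequencies equal direct counts when phase is unambiguous", {
  # all individuals fully homozygous
  haps <- c("AC", "GT")
  rg <- random_genotypes(20, haps, c(0.5, 0.5), seed = 4)
  g <- rg$genotypes
  a1 <- g$a1
  hom <- make_genotypes(a1, a1, ids = g$ids)  # force homozygosity
  em <- em_haplotype_frequencies(hom)
  counted <- table(factor(apply(a1, 1, paste, collapse = ""),
                          levels = em$haplotypes))
  expect_equal(em$f, as.numeric(counted / sum(counted)), tolerance = 1e-9)

  # single-SNP block: frequencies are allele counts / 2n
  one <- make_genotypes(matrix(c("A", "A", "G"), 3, 1),
                        matrix(c("G", "A", "G"), 3, 1))
  em1 <- em_haplotype_frequencies(one)
  expect_equal(em1$f[em1$haplotypes == "A"], 3 / 6, tolerance = 1e-9)
  expect_equal(em1$f[em1$haplotypes == "G"], 3 / 6, tolerance = 1e-9)
})

test_that("EM matches a grid-search maximizer of the observed likelihood", {
  # 6 individuals, 2 SNPs, with genuine phase ambiguity
  a1 <- rbind(c("A", "C"), c("A", "G"), c("A", "C"),
              c("G", "C"), c("A", "C"), c("G", "G"))
  a2 <- rbind(c("G", "G"), c("A", "G"), c("A", "G"),
              c("G", "G"), c("G", "G"), c("G", "G"))
  g <- make_genotypes(a1, a2)
  em <- em_haplotype_frequencies(g)
  supports <- attr(em, "supports")
  obs_ll <- function(f) {
    sum(vapply(supports, function(sp) {
      idx1 <- match(sp[, 1], em$haplotypes)
      idx2 <- match(sp[, 2], em$haplotypes)
      log(sum(ifelse(idx1 == idx2, f[idx1]^2, 2 * f[idx1] * f[idx2])))
    }, 0))
  }
  m <- length(em$f)
  # vectorized likelihood over a matrix of candidate frequency vectors
  sup_idx <- lapply(supports, function(sp)
    cbind(match(sp[, 1], em$haplotypes), match(sp[, 2], em$haplotypes)))
  grid_ll <- function(F) {
    ll <- numeric(nrow(F))
    for (sp in sup_idx) {
      tot <- 0
      for (r in seq_len(nrow(sp))) {
        k <- sp[r, 1]; kp <- sp[r, 2]
        tot <- tot + if (k == kp) F[, k]^2 else 2 * F[, k] * F[, kp]
      }
      ll <- ll + log(tot)
    }
    ll
  }
  simplex_grid <- function(step, center = NULL, half = NULL) {
    ax <- lapply(seq_len(m - 1), function(k) {
      if (is.null(center)) seq(0, 1, by = step)
      else seq(max(0, center[k] - half), min(1, center[k] + half), by = step)
    })
    F <- as.matrix(expand.grid(ax))
    last <- 1 - rowSums(F)
    F <- cbind(F, last)[last >= 0, , drop = FALSE]
    unname(F)
  }
  Fc <- simplex_grid(0.04)
  coarse <- Fc[which.max(grid_ll(Fc)), ]
  Ff <- simplex_grid(0.001, center = coarse[seq_len(m - 1)], half = 0.05)
  llf <- grid_ll(Ff)
  best <- Ff[which.max(llf), ]
  expect_lt(max(abs(em$f - best)), 1.5e-3)
  expect_gte(obs_ll(em$f), max(llf) - 1e-6)  # EM at least as good as the grid
})

test_that("EM observed-data log-likelihood is monotone nondecreasing", {
  rg <- random_genotypes(30, c("ACG", "AGG", "TCG", "TGC"),
                         c(0.4, 0.3, 0.2, 0.1), seed = 12)
  em <- em_haplotype_frequencies(rg$genotypes)
  ll <- attr(em, "loglik")
  expect_true(all(diff(ll) >= -1e-9))
  expect_true(attr(em, "converged"))
})

test_that("the haplotype closure contains every generating haplotype", {
  haps <- c("ACGCC", "GCGCC", "GGTCC", "AGTTC", "GCTTG", "ACGTG", "GGGCG")
  rg <- random_genotypes(60, haps, c(0.3, 0.25, 0.2, 0.13, 0.06, 0.035, 0.025),
                         seed = 8)
  cl <- haplotype_closure(rg$genotypes)
  used <- unique(haps[c(rg$h1, rg$h2)])
  expect_true(all(used %in% cl$haplotypes))
  # every support contains the generating diplotype
  for (i in seq_along(cl$supports)) {
    pair <- sort(haps[c(rg$h1[i], rg$h2[i])])
    hit <- any(cl$supports[[i]][, 1] == pair[1] &
               cl$supports[[i]][, 2] == pair[2])
    expect_true(hit)
  }
})
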