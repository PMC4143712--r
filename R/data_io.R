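#' Read an unphased genotype table
#'
#' Reads SNP genotypes for unrelated individuals, either from the package's
#' tab-separated dialect (one row per individual, two allele columns per SNP)
#' or from a VCF restricted to biallelic SNPs. Phase information in a VCF is
#' discarded: the model treats phase as latent. Individuals with any fully
#' missing genotype among the requested SNPs are flagged for exclusion;
#' half-calls (one allele present, one missing) are rejected outright.
#'
#' The TSV dialect is: a header line `id <snp>_1 <snp>_2 ...`, one row per
#' individual, alleles in `A`,`C`,`G`,`T`, missing coded as `0` in both
#' columns of a SNP. An optional leading comment line
#' `#positions <tab> p1 <tab> p2 ...` carries 1-based bp positions.
#'
#' @param path Path to the genotype file.
#' @param dialect Either `"tsv"` (default) or `"vcf"`.
#' @return An object of class `"lbl_genotypes"`: a list with `ids`
#'   (character), `snps` (character SNP ids), `positions` (integer bp or
#'   `NULL`), `a1`/`a2` (character matrices, individuals x SNPs; `NA` for
#'   missing) and `flagged` (logical, `TRUE` for individuals with missing
#'   genotype data, to be excluded when joined into a cohort).
#' @seealso [read_phenotypes()], [join_cohort()], [write_genotypes()]
#' @export
read_genotypes <- function(path, dialect = c("tsv", "vcf")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) .stopf("genotype file not found: %s", path)
  if (dialect == "tsv") .read_genotypes_tsv(path) else .read_genotypes_vcf(path)
}

.new_genotypes <- function(ids, snps, positions, a1, a2) {
  ids <- as.character(ids)
  if (anyDuplicated(ids)) .stopf("duplicated individual ids in genotype table")
  dimnames(a1) <- dimnames(a2) <- list(ids, snps)
  if (!is.null(positions)) {
    if (length(positions) != length(snps))
      .stopf("positions length (%d) != number of SNPs (%d)",
             length(positions), length(snps))
    if (!.is_strictly_increasing(positions))
      .stopf("SNP positions must be strictly increasing")
  }
  miss1 <- is.na(a1)
  miss2 <- is.na(a2)
  if (any(miss1 != miss2)) {
    bad <- which(miss1 != miss2, arr.ind = TRUE)[1L, ]
    .stopf("half-called genotype for individual '%s' at SNP '%s'",
           ids[bad[1L]], snps[bad[2L]])
  }
  allowed <- c("A", "C", "G", "T")
  vals <- c(a1[!miss1], a2[!miss2])
  if (length(vals) && !all(vals %in% allowed))
    .stopf("invalid allele code(s): %s",
           paste(unique(setdiff(vals, allowed)), collapse = ", "))
  structure(
    list(ids = ids, snps = as.character(snps), positions = positions,
         a1 = a1, a2 = a2, flagged = rowSums(miss1) > 0L),
    class = "lbl_genotypes")
}

.read_genotypes_tsv <- function(path) {
  lines <- readLines(path)
  positions <- NULL
  if (length(lines) && startsWith(lines[1L], "#positions")) {
    positions <- as.integer(strsplit(lines[1L], "\t", fixed = TRUE)[[1L]][-1L])
    lines <- lines[-1L]
  }
  if (length(lines) < 2L) .stopf("genotype TSV has no data rows: %s", path)
  nfield <- vapply(strsplit(lines, "\t", fixed = TRUE), length, 1L)
  bad <- which(nfield != nfield[1L])
  if (length(bad))
    .stopf("malformed genotype row at line %d: expected %d fields, found %d",
           bad[1L] + (!is.null(positions)), nfield[1L], nfield[bad[1L]])
  tab <- tryCatch(
    read.table(text = lines, header = TRUE, sep = "\t",
               colClasses = "character", check.names = FALSE),
    error = function(e) .stopf("malformed genotype TSV (%s): %s",
                               path, conditionMessage(e)))
  ncols <- ncol(tab) - 1L
  if (ncols < 2L || ncols %% 2L != 0L)
    .stopf("genotype TSV must have an id column plus two columns per SNP")
  hdr <- colnames(tab)[-1L]
  s1 <- hdr[seq(1L, ncols, by = 2L)]
  s2 <- hdr[seq(2L, ncols, by = 2L)]
  snps <- sub("_1$", "", s1)
  if (!identical(paste0(snps, "_1"), s1) || !identical(paste0(snps, "_2"), s2))
    .stopf("genotype TSV header must pair columns as <snp>_1, <snp>_2")
  a1 <- as.matrix(tab[, seq(2L, ncol(tab), by = 2L), drop = FALSE])
  a2 <- as.matrix(tab[, seq(3L, ncol(tab), by = 2L), drop = FALSE])
  a1[a1 == "0"] <- NA_character_
  a2[a2 == "0"] <- NA_character_
  .new_genotypes(tab[[1L]], snps, positions, a1, a2)
}

.read_genotypes_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    .stopf("reading VCF requires the 'vcfR' package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1L,
                                       dimnames = list(NULL, names(fix)))
  alt <- fix[, "ALT"]
  if (any(grepl(",", alt, fixed = TRUE)))
    .stopf("multi-allelic records are not supported; filter the VCF first")
  if (any(nchar(fix[, "REF"]) != 1L | nchar(alt) != 1L))
    .stopf("only biallelic SNPs are supported (indel record found)")
  ids <- fix[, "ID"]
  noid <- is.na(ids) | ids == "."
  ids[noid] <- paste0(fix[noid, "CHROM"], "_", fix[noid, "POS"])
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(gt)) .stopf("VCF has no GT field")
  samples <- colnames(gt)
  n <- length(samples); s <- nrow(gt)
  a1 <- matrix(NA_character_, n, s)
  a2 <- matrix(NA_character_, n, s)
  for (k in seq_len(s)) {
    alleles <- c(fix[k, "REF"], alt[k])
    parts <- strsplit(gt[k, ], "[/|]")
    for (i in seq_len(n)) {
      p <- parts[[i]]
      if (length(p) != 2L || any(p == ".") || anyNA(p)) next
      a1[i, k] <- alleles[as.integer(p[1L]) + 1L]
      a2[i, k] <- alleles[as.integer(p[2L]) + 1L]
    }
  }
  pos <- as.integer(fix[, "POS"])
  ord <- order(pos)
  .new_genotypes(samples, ids[ord], pos[ord],
                 a1[, ord, drop = FALSE], a2[, ord, drop = FALSE])
}

#' Write a genotype table in the package's TSV dialect
#'
#' Inverse of [read_genotypes()] for `dialect = "tsv"`; `read(write(x))`
#' round-trips exactly.
#'
#' @param genotypes An `"lbl_genotypes"` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(genotypes, path) {
  stopifnot(inherits(genotypes, "lbl_genotypes"))
  g <- genotypes
  s <- length(g$snps)
  out <- matrix("", length(g$ids), 2L * s)
  a1 <- g$a1; a2 <- g$a2
  a1[is.na(a1)] <- "0"; a2[is.na(a2)] <- "0"
  out[, seq(1L, 2L * s, by = 2L)] <- a1
  out[, seq(2L, 2L * s, by = 2L)] <- a2
  hdr <- character(2L * s)
  hdr[seq(1L, 2L * s, by = 2L)] <- paste0(g$snps, "_1")
  hdr[seq(2L, 2L * s, by = 2L)] <- paste0(g$snps, "_2")
  con <- file(path, "w"); on.exit(close(con))
  if (!is.null(g$positions))
    writeLines(paste(c("#positions", g$positions), collapse = "\t"), con)
  writeLines(paste(c("id", hdr), collapse = "\t"), con)
  writeLines(apply(cbind(g$ids, out), 1L, paste, collapse = "\t"), con)
  invisible(path)
}

#' Read a longitudinal phenotype table
#'
#' Long-format TSV with columns `id`, `exam`, `y` (binary affection status,
#' e.g. hypertensive at that examination), `smoke` (binary smoking status at
#' that examination), `age` (years at examination) and `sex` (0 = female,
#' 1 = male by default, constant across an individual's rows). Individuals
#' may have between 1 and 4 examinations; all are retained — the model
#' accommodates incomplete follow-up. Ages must be strictly increasing
#' within an individual.
#'
#' @param path Path to the phenotype TSV.
#' @param sex_codes Length-2 vector mapping the file's sex codes to
#'   `c(female, male)`; default `c(0, 1)`.
#' @return A `data.frame` of class `"lbl_phenotypes"` with columns
#'   `id`, `exam`, `y`, `smoke`, `age`, `sex`, sorted by id then exam.
#' @export
read_phenotypes <- function(path, sex_codes = c(0, 1)) {
  if (!file.exists(path)) .stopf("phenotype file not found: %s", path)
  tab <- read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
  need <- c("id", "exam", "y", "smoke", "age", "sex")
  if (!all(need %in% colnames(tab)))
    .stopf("phenotype table must have columns: %s", paste(need, collapse = ", "))
  tab <- tab[need]
  tab$id <- as.character(tab$id)
  as_phenotypes(tab, sex_codes = sex_codes)
}

#' Validate a long-format phenotype data frame
#'
#' Applies the same validation as [read_phenotypes()] to an in-memory data
#' frame: 1-4 exams per individual, strictly increasing ages, constant sex,
#' binary `y`/`smoke`.
#'
#' @param df Data frame with columns `id`, `exam`, `y`, `smoke`, `age`, `sex`.
#' @param sex_codes Length-2 vector mapping sex codes to `c(female, male)`.
#' @return A validated `"lbl_phenotypes"` data frame.
#' @export
as_phenotypes <- function(df, sex_codes = c(0, 1)) {
  need <- c("id", "exam", "y", "smoke", "age", "sex")
  stopifnot(all(need %in% colnames(df)))
  tab <- as.data.frame(df)[need]
  tab$id <- as.character(tab$id)
  tab$exam <- as.integer(tab$exam)
  for (cc in c("y", "smoke")) {
    v <- tab[[cc]]
    if (!all(v %in% c(0, 1))) .stopf("column '%s' must be binary 0/1", cc)
    tab[[cc]] <- as.integer(v)
  }
  if (!all(tab$sex %in% sex_codes))
    .stopf("column 'sex' contains codes outside sex_codes")
  tab$sex <- as.integer(match(tab$sex, sex_codes) - 1L)
  tab$age <- as.numeric(tab$age)
  tab <- tab[order(tab$id, tab$exam), , drop = FALSE]
  rownames(tab) <- NULL
  for (pieces in split(tab, tab$id)) {
    id <- pieces$id[1L]
    if (nrow(pieces) > 4L)
      .stopf("individual '%s' has %d exams; at most 4 are supported",
             id, nrow(pieces))
    if (anyDuplicated(pieces$exam))
      .stopf("individual '%s' has duplicated exam indices", id)
    if (!.is_strictly_increasing(pieces$age))
      .stopf("ages must be strictly increasing across exams (individual '%s')",
             id)
    if (length(unique(pieces$sex)) != 1L)
      .stopf("sex must be constant within an individual ('%s')", id)
  }
  class(tab) <- c("lbl_phenotypes", "data.frame")
  tab
}

#' Write a phenotype table
#'
#' @param phenotypes An `"lbl_phenotypes"` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(phenotypes, path) {
  stopifnot(inherits(phenotypes, "lbl_phenotypes"))
  write.table(phenotypes, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Join genotypes and phenotypes into an analysis cohort
#'
#' Inner join on individual id. Individuals flagged at genotype reading
#' (missing genotype data) are dropped — this is the only row-dropping rule
#' applied at I/O time — and the number dropped is reported via `message()`.
#'
#' @param genotypes An `"lbl_genotypes"` object.
#' @param phenotypes An `"lbl_phenotypes"` data frame.
#' @return An object of class `"lbl_cohort"`: list with `ids`, `genotypes`
#'   (subset, no flagged individuals), `phenotypes` (subset, with an
#'   `id_idx` column indexing into `ids`), and drop counts.
#' @export
join_cohort <- function(genotypes, phenotypes) {
  stopifnot(inherits(genotypes, "lbl_genotypes"),
            inherits(phenotypes, "lbl_phenotypes"))
  common <- intersect(genotypes$ids, unique(phenotypes$id))
  if (length(common) == 0L)
    .stopf("genotype and phenotype tables share no individual ids")
  keep <- common[!genotypes$flagged[match(common, genotypes$ids)]]
  n_flagged <- length(common) - length(keep)
  if (length(keep) == 0L)
    .stopf("all overlapping individuals are flagged for missing genotypes")
  if (n_flagged > 0L)
    message(sprintf("join_cohort: dropped %d individual(s) with missing genotype data",
                    n_flagged))
  sel <- match(keep, genotypes$ids)
  geno <- structure(
    list(ids = keep, snps = genotypes$snps, positions = genotypes$positions,
         a1 = genotypes$a1[sel, , drop = FALSE],
         a2 = genotypes$a2[sel, , drop = FALSE],
         flagged = rep(FALSE, length(keep))),
    class = "lbl_genotypes")
  phe <- phenotypes[phenotypes$id %in% keep, , drop = FALSE]
  phe <- phe[order(match(phe$id, keep), phe$exam), , drop = FALSE]
  rownames(phe) <- NULL
  phe$id_idx <- match(phe$id, keep)
  structure(
    list(ids = keep, genotypes = geno, phenotypes = phe,
         n_genotyped = length(genotypes$ids),
         n_phenotyped = length(unique(phenotypes$id)),
         n_flagged_dropped = n_flagged),
    class = "lbl_cohort")
}

#' @export
print.lbl_cohort <- function(x, ...) {
  cat(sprintf("lbl_cohort: %d individuals, %d SNPs, %d phenotype records\n",
              length(x$ids), length(x$genotypes$snps), nrow(x$phenotypes)))
  invisible(x)
}

#' @export
print.lbl_genotypes <- function(x, ...) {
  cat(sprintf("lbl_genotypes: %d individuals x %d SNPs (%d flagged for missing data)\n",
              length(x$ids), length(x$snps), sum(x$flagged)))
  invisible(x)
}
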