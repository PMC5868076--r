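#' Construct a genotype matrix object
#'
#' Container for allele-count genotypes: a matrix of 0/1/2 codes (NA for
#' missing) with individuals in rows and SNPs in columns, plus per-SNP map
#' information. Codes count copies of the *counted allele* (for PLINK input
#' this is the bim A1, conventionally the minor allele); all downstream
#' frequencies refer to that allele. Association results are invariant to
#' which allele is counted.
#'
#' @param codes Integer/numeric matrix `n_individuals x n_snps` with entries
#'   in `{0, 1, 2, NA}`.
#' @param snp_meta `data.frame` with columns `id`, `chromosome`, `position`,
#'   `allele1`, `allele2` (allele1 is the counted allele). If omitted,
#'   placeholder metadata is created from column names.
#' @param individual_ids Character vector of unique individual ids; defaults
#'   to row names or `ind1..indN`.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(codes, snp_meta = NULL, individual_ids = NULL) {
  codes <- as.matrix(codes)
  storage.mode(codes) <- "double"
  ok <- is.na(codes) | codes == 0 | codes == 1 | codes == 2
  if (!all(ok))
    stop("genotype codes must be 0, 1, 2 or NA; offending value(s): ",
         paste(utils::head(unique(codes[!ok]), 5L), collapse = ", "))
  n_snp <- ncol(codes)
  if (is.null(snp_meta)) {
    ids <- colnames(codes)
    if (is.null(ids)) ids <- paste0("snp", seq_len(n_snp))
    snp_meta <- data.frame(id = ids, chromosome = "1",
                           position = seq_len(n_snp),
                           allele1 = "A", allele2 = "B",
                           stringsAsFactors = FALSE)
  }
  snp_meta <- as.data.frame(snp_meta, stringsAsFactors = FALSE)
  need <- c("id", "chromosome", "position", "allele1", "allele2")
  miss <- setdiff(need, names(snp_meta))
  if (length(miss)) stop("snp_meta lacks column(s): ", paste(miss, collapse = ", "))
  if (nrow(snp_meta) != n_snp)
    stop(sprintf("snp_meta has %d rows but codes has %d SNP columns",
                 nrow(snp_meta), n_snp))
  if (anyDuplicated(snp_meta$id))
    stop("duplicate SNP ids: ",
         paste(utils::head(unique(snp_meta$id[duplicated(snp_meta$id)]), 5L),
               collapse = ", "))
  if (is.null(individual_ids)) {
    individual_ids <- rownames(codes)
    if (is.null(individual_ids)) individual_ids <- paste0("ind", seq_len(nrow(codes)))
  }
  individual_ids <- as.character(individual_ids)
  if (length(individual_ids) != nrow(codes))
    stop("individual_ids length does not match number of genotype rows")
  if (anyDuplicated(individual_ids))
    stop("duplicate individual ids")
  dimnames(codes) <- list(individual_ids, snp_meta$id)
  structure(list(codes = codes, snp_meta = snp_meta,
                 individual_ids = individual_ids),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d individuals x %d SNPs (%.2f%% missing)\n",
              nrow(x$codes), ncol(x$codes), 100 * mean(is.na(x$codes))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$codes)

#' Subset a genotype matrix by SNPs and/or individuals
#' @param geno A [genotype_matrix()].
#' @param snps SNP index/logical/id selector.
#' @param individuals Individual index/logical/id selector.
#' @return A `genotype_matrix` restricted to the selection.
#' @export
subset_genotypes <- function(geno, snps = NULL, individuals = NULL) {
  codes <- geno$codes; meta <- geno$snp_meta; ids <- geno$individual_ids
  if (!is.null(snps)) {
    if (is.character(snps)) snps <- match(snps, meta$id)
    codes <- codes[, snps, drop = FALSE]
    meta <- meta[snps, , drop = FALSE]
  }
  if (!is.null(individuals)) {
    if (is.character(individuals)) individuals <- match(individuals, ids)
    codes <- codes[individuals, , drop = FALSE]
    ids <- ids[individuals]
  }
  genotype_matrix(codes, meta, ids)
}

#' Allele frequencies of the counted allele
#'
#' \eqn{p_i} = (sum of codes at SNP i over non-missing individuals) /
#' (2 x number of non-missing calls).
#'
#' @param geno A [genotype_matrix()].
#' @return Numeric vector of frequencies in \eqn{[0, 1]}, named by SNP id.
#' @export
allele_frequencies <- function(geno) {
  n_called <- colSums(!is.na(geno$codes))
  if (any(n_called == 0L))
    stop("SNP(s) with no non-missing calls: ",
         paste(utils::head(geno$snp_meta$id[n_called == 0L], 5L), collapse = ", "))
  p <- colSums(geno$codes, na.rm = TRUE) / (2 * n_called)
  names(p) <- geno$snp_meta$id
  p
}

#' Hardy-Weinberg equilibrium chi-squared test
#'
#' One-degree-of-freedom goodness-of-fit test of observed genotype counts
#' against expected proportions \eqn{((1-\hat p)^2, 2\hat p(1-\hat p),
#' \hat p^2)} with \eqn{\hat p} from the allele counts. Monomorphic SNPs
#' fit their expectation exactly and return p = 1.
#'
#' @param n_aa,n_Aa,n_AA Genotype counts (codes 0, 1, 2). Vectorized.
#' @return Numeric vector of p-values.
#' @export
hwe_test <- function(n_aa, n_Aa, n_AA) {
  if (any(c(n_aa, n_Aa, n_AA) < 0)) stop("genotype counts must be non-negative")
  n <- n_aa + n_Aa + n_AA
  if (any(n == 0)) stop("total genotype count must be positive")
  p <- (n_Aa + 2 * n_AA) / (2 * n)
  e_aa <- n * (1 - p)^2
  e_Aa <- n * 2 * p * (1 - p)
  e_AA <- n * p^2
  stat <- ifelse(e_aa > 0, (n_aa - e_aa)^2 / e_aa, 0) +
    ifelse(e_Aa > 0, (n_Aa - e_Aa)^2 / e_Aa, 0) +
    ifelse(e_AA > 0, (n_AA - e_AA)^2 / e_AA, 0)
  out <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  out[p == 0 | p == 1] <- 1
  out
}

#' Filter SNPs on minor allele frequency and Hardy-Weinberg equilibrium
#'
#' Retains SNPs with MAF >= `maf_min` and HWE p-value >= `hwe_p_min`
#' (the standard pre-GWAS filters; defaults match routine dairy-panel QC).
#'
#' @param geno A [genotype_matrix()].
#' @param maf_min Minimum minor allele frequency (default 0.03).
#' @param hwe_p_min Minimum HWE p-value (default 1e-6).
#' @return The filtered `genotype_matrix`, with attribute `"filter_report"`:
#'   a `data.frame` of removed SNPs with columns `snp_id`, `reason` (`"MAF"`
#'   or `"HWE"`; MAF checked first), `value`.
#' @export
filter_snps <- function(geno, maf_min = 0.03, hwe_p_min = 1e-6) {
  p <- allele_frequencies(geno)
  maf <- pmin(p, 1 - p)
  n_aa <- colSums(geno$codes == 0, na.rm = TRUE)
  n_Aa <- colSums(geno$codes == 1, na.rm = TRUE)
  n_AA <- colSums(geno$codes == 2, na.rm = TRUE)
  hwe_p <- hwe_test(n_aa, n_Aa, n_AA)
  fail_maf <- maf < maf_min
  fail_hwe <- !fail_maf & hwe_p < hwe_p_min
  keep <- !fail_maf & !fail_hwe
  report <- data.frame(
    snp_id = geno$snp_meta$id[!keep],
    reason = ifelse(fail_maf[!keep], "MAF", "HWE"),
    value = ifelse(fail_maf[!keep], maf[!keep], hwe_p[!keep]),
    stringsAsFactors = FALSE)
  if (!any(keep)) warning("all SNPs removed by MAF/HWE filters")
  out <- subset_genotypes(geno, snps = which(keep))
  attr(out, "filter_report") <- report
  out
}

#' VanRaden genomic relationship matrix
#'
#' \eqn{K = M M' / (2 \sum_i p_i (1 - p_i))} where column i of M holds the
#' genotype codes centered by twice the allele frequency
#' (\eqn{2 - 2p_i}, \eqn{1 - 2p_i}, \eqn{0 - 2p_i}). Missing codes are
#' mean-imputed, i.e. set to 0 after centering.
#'
#' @param geno A [genotype_matrix()].
#' @param freqs Allele frequencies of the counted allele, aligned with the
#'   SNP columns; computed from `geno` when omitted.
#' @return An object of class `kinship_matrix`: list with `values`
#'   (symmetric `n x n` matrix) and `individual_ids`.
#' @export
vanraden_kinship <- function(geno, freqs = allele_frequencies(geno)) {
  if (length(freqs) != ncol(geno$codes))
    stop(sprintf("freqs length %d does not match %d SNP columns",
                 length(freqs), ncol(geno$codes)))
  denom <- 2 * sum(freqs * (1 - freqs))
  if (denom <= 0)
    stop("all SNPs monomorphic: VanRaden denominator 2*sum(p(1-p)) is zero")
  M <- sweep(geno$codes, 2L, 2 * freqs, `-`)
  M[is.na(M)] <- 0
  K <- tcrossprod(M) / denom
  K <- (K + t(K)) / 2
  structure(list(values = K, individual_ids = geno$individual_ids),
            class = "kinship_matrix")
}

#' @export
print.kinship_matrix <- function(x, ...) {
  cat(sprintf("<kinship_matrix> %d individuals, mean diagonal %.3f\n",
              nrow(x$values), mean(diag(x$values))))
  invisible(x)
}

#' Squared correlation (r2) between two SNPs' allele counts
#'
#' Pearson correlation over pairwise-complete individuals, squared. A SNP
#' with zero variance among the complete pairs yields r2 = 0 with a warning.
#'
#' @param a,b Genotype code vectors of equal length.
#' @return r2 in \eqn{[0, 1]}.
#' @export
ld_r2 <- function(a, b) {
  if (length(a) != length(b)) stop("genotype vectors differ in length")
  ok <- !is.na(a) & !is.na(b)
  if (sum(ok) < 2L) stop("fewer than 2 pairwise-complete genotype pairs")
  a <- a[ok]; b <- b[ok]
  if (stats::var(a) == 0 || stats::var(b) == 0) {
    warning("zero genotype variance; r2 defined as 0")
    return(0)
  }
  stats::cor(a, b)^2
}

#' Windowed greedy LD pruning (indep-pairwise style)
#'
#' Slides a window of `window` SNPs in steps of `step` along each
#' chromosome (SNPs must be sorted by chromosome and position). Within a
#' window, while any retained pair has r2 > `r2_max`, the member of the
#' worst pair with the lower MAF is removed (tie: the SNP at the later
#' position). The retained set approximates a panel of independent markers
#' whose count serves as the effective number of tests.
#'
#' @param geno A [genotype_matrix()].
#' @param window Window size in SNPs (default 50).
#' @param step Window shift in SNPs (default 5).
#' @param r2_max Pruning threshold on pairwise r2 (default 0.5).
#' @return Character vector of retained SNP ids, in input order.
#' @export
ld_prune <- function(geno, window = 50L, step = 5L, r2_max = 0.5) {
  meta <- geno$snp_meta
  chr_rle <- rle(as.character(meta$chromosome))
  pos_ok <- all(unlist(tapply(meta$position, factor(meta$chromosome,
                                                    levels = chr_rle$values),
                              function(x) !is.unsorted(x))))
  if (anyDuplicated(chr_rle$values) || !pos_ok)
    stop("SNPs must be sorted by (chromosome, position); sort the input first")
  p <- allele_frequencies(geno)
  maf <- pmin(p, 1 - p)
  keep <- rep(TRUE, ncol(geno$codes))
  for (chr in unique(meta$chromosome)) {
    idx <- which(meta$chromosome == chr)
    start <- 1L
    repeat {
      win <- idx[start:min(start + window - 1L, length(idx))]
      win <- win[keep[win]]
      if (length(win) >= 2L) {
        repeat {
          # recompute r2 among currently retained SNPs in this window
          cc <- geno$codes[, win, drop = FALSE]
          r2 <- suppressWarnings(stats::cor(cc, use = "pairwise.complete.obs"))^2
          r2[is.na(r2)] <- 0
          diag(r2) <- 0
          if (max(r2) <= r2_max) break
          worst <- which(r2 == max(r2), arr.ind = TRUE)[1L, ]
          i <- win[worst[[1L]]]; j <- win[worst[[2L]]]
          drop_snp <- if (maf[i] < maf[j]) i
                      else if (maf[j] < maf[i]) j
                      else if (meta$position[i] >= meta$position[j]) i else j
          keep[drop_snp] <- FALSE
          win <- win[win != drop_snp]
          if (length(win) < 2L) break
        }
      }
      if (start + window - 1L >= length(idx)) break
      start <- start + step
    }
  }
  meta$id[keep]
}

#' Bonferroni genome-wide significance threshold
#'
#' `alpha / m_eff`, with `m_eff` the effective number of independent tests
#' (e.g. the SNP count retained by [ld_prune()]).
#'
#' @param alpha Family-wise error rate (default 0.05).
#' @param m_eff Effective number of tests (>= 1).
#' @return The per-test p-value threshold.
#' @export
bonferroni_threshold <- function(alpha = 0.05, m_eff) {
  if (length(m_eff) != 1L || is.na(m_eff) || m_eff < 1)
    stop("m_eff must be a positive count")
  alpha / m_eff
}
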