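#' Validate a longitudinal phenotype table
#'
#' One row per animal x test day, long format. Required columns:
#' `animal_id`, `t` (days in milk), `htd_id` (herd-test-date level),
#' `group_id` (mean-curve group), `y` (trait value); `parity` is optional
#' and defaults to 1. Duplicate (animal, t) rows within a parity are errors.
#'
#' @param df A data.frame with the columns above.
#' @param domain Optional length-2 time domain used to validate `t`.
#' @return The table with class `phenotype_table` prepended.
#' @export
phenotype_table <- function(df, domain = NULL) {
  need <- c("animal_id", "t", "htd_id", "group_id", "y")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("phenotype table lacks column(s): ",
                         paste(miss, collapse = ", "))
  if (!nrow(df)) stop("phenotype table is empty")
  if (is.null(df$parity)) df$parity <- 1L
  df$animal_id <- as.character(df$animal_id)
  df$htd_id <- as.character(df$htd_id)
  df$group_id <- as.character(df$group_id)
  key <- paste(df$parity, df$animal_id, df$t, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- df[duplicated(key), c("animal_id", "t"), drop = FALSE]
    stop("duplicate (animal, t) record(s): ",
         paste(utils::head(paste0(dup$animal_id, "@", dup$t), 5L),
               collapse = ", "))
  }
  if (!is.null(domain)) standardize_time(df$t, domain)
  if (anyNA(df$y)) stop("phenotype table contains missing y; drop them first")
  class(df) <- unique(c("phenotype_table", class(df)))
  df
}

#' Build the random-regression design for the test-day model
#'
#' Assembles the fixed design X = \[HTD indicators (first level dropped) |
#' per-group fixed-regression basis blocks\] and the per-record basis rows
#' used by the additive-genetic (Q) and permanent-environmental (Z) random
#' regressions. Q and Z are block structured: record r contributes the
#' basis row evaluated at its time, placed in the block of its owning
#' individual; they are kept in factored form (`Phi_add`/`Phi_perm` plus
#' the record-to-individual index) and can be materialized with
#' [design_Q()]/[design_Z()].
#'
#' The group blocks absorb the intercept (no separate global mean), and the
#' first HTD level is dropped, which makes X full column rank in
#' non-degenerate designs; rank is verified and confounded columns are
#' reported.
#'
#' @param pheno A [phenotype_table()].
#' @param individual_ids Ids of the genotyped panel, in kinship order. Every
#'   phenotyped animal must be present.
#' @param mean_spec,add_spec,perm_spec [basis_spec()]s for the group mean
#'   curves, additive-genetic and permanent-environmental regressions.
#' @return An object of class `rrm_design`.
#' @export
build_design <- function(pheno, individual_ids, mean_spec, add_spec,
                         perm_spec = add_spec) {
  pheno <- phenotype_table(pheno, domain = c(mean_spec$t_min, mean_spec$t_max))
  missing_ids <- setdiff(unique(pheno$animal_id), individual_ids)
  if (length(missing_ids))
    stop("animal(s) with records but absent from the genotype panel: ",
         paste(utils::head(missing_ids, 10L), collapse = ", "))
  record_ind <- match(pheno$animal_id, individual_ids)
  t <- pheno$t
  N <- nrow(pheno)

  htd <- factor(pheno$htd_id)
  htd_cols <- NULL
  htd_names <- character(0)
  if (nlevels(htd) > 1L) {
    htd_cols <- stats::model.matrix(~ htd)[, -1L, drop = FALSE]
    htd_names <- paste0("htd:", levels(htd)[-1L])
  }

  Phi_mean <- basis_matrix(t, mean_spec)
  grp <- factor(pheno$group_id)
  q_mean <- n_basis(mean_spec)
  grp_block <- matrix(0, N, nlevels(grp) * q_mean)
  grp_names <- character(nlevels(grp) * q_mean)
  for (g in seq_len(nlevels(grp))) {
    sel <- grp == levels(grp)[g]
    cols <- (g - 1L) * q_mean + seq_len(q_mean)
    grp_block[sel, cols] <- Phi_mean[sel, , drop = FALSE]
    grp_names[cols] <- paste0("group:", levels(grp)[g], ":phi", seq_len(q_mean) - 1L)
  }

  X <- cbind(htd_cols, grp_block)
  colnames(X) <- c(htd_names, grp_names)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("fixed design is rank deficient; confounded column(s): ",
         paste(bad, collapse = ", "))
  }

  structure(list(
    X = X,
    record_ind = record_ind,
    individual_ids = individual_ids,
    n_ind = length(individual_ids),
    t = t,
    y = pheno$y,
    Phi_add = basis_matrix(t, add_spec),
    Phi_perm = basis_matrix(t, perm_spec),
    mean_spec = mean_spec, add_spec = add_spec, perm_spec = perm_spec,
    col_map = data.frame(name = colnames(X),
                         type = c(rep("htd", length(htd_names)),
                                  rep("group_curve", length(grp_names))),
                         stringsAsFactors = FALSE)),
    class = "rrm_design")
}

#' @export
print.rrm_design <- function(x, ...) {
  cat(sprintf("<rrm_design> %d records, %d individuals, %d fixed columns\n",
              length(x$t), x$n_ind, ncol(x$X)))
  invisible(x)
}

#' Materialize the additive-genetic design matrix Q
#'
#' Dense `N_rec x (n_ind * n_basis)` matrix whose row r carries the
#' additive basis evaluated at t_r inside individual n(r)'s block
#' (individual-major column order). Intended for verification and small
#' problems; the engine itself never forms it.
#' @param design An `rrm_design`.
#' @return Dense matrix.
#' @export
design_Q <- function(design) expand_block(design$Phi_add, design$record_ind, design$n_ind)

#' Materialize the permanent-environment design matrix Z
#' @rdname design_Q
#' @export
design_Z <- function(design) expand_block(design$Phi_perm, design$record_ind, design$n_ind)

expand_block <- function(Phi, record_ind, n_ind) {
  q <- ncol(Phi); N <- nrow(Phi)
  out <- matrix(0, N, n_ind * q)
  for (r in seq_len(N)) {
    cols <- (record_ind[r] - 1L) * q + seq_len(q)
    out[r, cols] <- Phi[r, ]
  }
  out
}

#' Variance components of the random regression model
#'
#' @param G Symmetric PSD covariance of the additive-genetic regression
#'   coefficients, `(nr1+1) x (nr1+1)`.
#' @param P Symmetric PSD covariance of the permanent-environmental
#'   coefficients, `(nr2+1) x (nr2+1)`.
#' @param sigma2_e Positive residual variance.
#' @return Object of class `variance_components`.
#' @export
variance_components <- function(G, P, sigma2_e) {
  G <- as.matrix(G); P <- as.matrix(P)
  check_psd <- function(M, label) {
    if (nrow(M) != ncol(M)) stop(label, " must be square")
    if (max(abs(M - t(M))) > 1e-10 * max(1, max(abs(M))))
      stop(label, " must be symmetric")
    ev <- eigen((M + t(M)) / 2, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8 * max(sum(diag(M)), 1))
      stop(label, " must be positive semi-definite (min eigenvalue ",
           signif(min(ev), 3), ")")
  }
  check_psd(G, "G"); check_psd(P, "P")
  if (length(sigma2_e) != 1L || !is.finite(sigma2_e) || sigma2_e <= 0)
    stop("sigma2_e must be a positive real")
  structure(list(G = G, P = P, sigma2_e = as.numeric(sigma2_e)),
            class = "variance_components")
}

#' @export
print.variance_components <- function(x, ...) {
  cat(sprintf("<variance_components> G %dx%d, P %dx%d, sigma2_e = %.4g\n",
              nrow(x$G), ncol(x$G), nrow(x$P), ncol(x$P), x$sigma2_e))
  invisible(x)
}

#' Non-residual phenotypic covariance W of the test-day records
#'
#' \eqn{W = Q (K \otimes G) Q' + Z (I \otimes P) Z'}. Exploits the block
#' structure: entry (r, s) equals
#' \eqn{K_{n(r)n(s)} \phi_r' G \phi_s + [n(r)=n(s)] \psi_r' P \psi_s},
#' so no Kronecker product is ever formed.
#'
#' @param design An `rrm_design` from [build_design()].
#' @param K A `kinship_matrix` covering (at least) the design's panel.
#' @param vc A [variance_components()]. Dimensions must match the design's
#'   basis orders.
#' @param with_polygenic If `FALSE`, the additive-genetic term is dropped
#'   (the "no-polygenic" comparator model).
#' @return Symmetric `N_rec x N_rec` matrix.
#' @export
build_covariance_W <- function(design, K, vc, with_polygenic = TRUE) {
  q1 <- ncol(design$Phi_add); q2 <- ncol(design$Phi_perm)
  if (with_polygenic && (nrow(vc$G) != q1))
    stop(sprintf("G is %dx%d but the additive basis has %d functions",
                 nrow(vc$G), ncol(vc$G), q1))
  if (nrow(vc$P) != q2)
    stop(sprintf("P is %dx%d but the permanent-environment basis has %d functions",
                 nrow(vc$P), ncol(vc$P), q2))
  idx <- design$record_ind
  same <- outer(idx, idx, `==`)
  W <- (design$Phi_perm %*% vc$P %*% t(design$Phi_perm)) * same
  if (with_polygenic) {
    kk <- match(design$individual_ids, K$individual_ids)
    if (anyNA(kk))
      stop("kinship matrix is missing individual(s): ",
           paste(utils::head(design$individual_ids[is.na(kk)], 5L), collapse = ", "))
    Ksub <- K$values[kk, kk, drop = FALSE]
    W <- W + (design$Phi_add %*% vc$G %*% t(design$Phi_add)) * Ksub[idx, idx]
  }
  (W + t(W)) / 2
}

#' One-time eigen rotation of the test-day system
#'
#' Diagonalizes \eqn{W = U D U'} so that the rotated records
#' \eqn{y^* = U'y} have diagonal covariance \eqn{S = D + \sigma_e^2 I},
#' turning every subsequent SNP fit into weighted least squares. Also
#' precomputes, for each SNP-basis function k, the projector
#' \eqn{B_k = U' \,\mathrm{diag}(\varphi_k(t_r))\, Z_{ind}} mapping a
#' genotype vector over individuals straight to its rotated covariate
#' column, so a genome scan never touches U again.
#'
#' @param W Symmetric covariance from [build_covariance_W()].
#' @param design The `rrm_design` the covariance was built from.
#' @param sigma2_e Residual variance.
#' @param snp_spec [basis_spec()] of the per-SNP effect curve.
#' @return Object of class `rotated_system` with fields `U`, `D`, `S`,
#'   `y_star`, `X_star_base`, `projectors` (list over k).
#' @export
rotate_system <- function(W, design, sigma2_e, snp_spec) {
  N <- length(design$t)
  if (!isTRUE(all.equal(dim(W), c(N, N))))
    stop(sprintf("W is %dx%d but the design has %d records",
                 nrow(W), ncol(W), N))
  asym <- max(abs(W - t(W)))
  if (asym > 1e-8 * max(1, max(abs(W))))
    stop("W is not symmetric (max asymmetry ", signif(asym, 3), ")")
  eg <- eigen((W + t(W)) / 2, symmetric = TRUE)
  D <- eg$values
  dmax <- max(D, 0)
  neg <- D < 0
  if (any(D < -1e-8 * max(dmax, 1)))
    warning("W has eigenvalues below the PSD tolerance; clamped to 0")
  D[neg] <- 0
  S <- D + sigma2_e
  U <- eg$vectors
  Phi_snp <- basis_matrix(design$t, snp_spec)
  # B_k = U' diag(phi_k) Z_ind, computed by grouping U's rows by individual;
  # rowsum only covers individuals with records, so re-embed at full width
  have <- sort(unique(design$record_ind))
  projectors <- lapply(seq_len(ncol(Phi_snp)), function(k) {
    B <- matrix(0, N, design$n_ind)
    Bhave <- t(rowsum(U * Phi_snp[, k], group = design$record_ind, reorder = TRUE))
    B[, have] <- Bhave
    B
  })
  structure(list(
    U = U, D = D, S = S,
    y_star = drop(crossprod(U, design$y)),
    X_star_base = crossprod(U, design$X),
    projectors = projectors,
    snp_spec = snp_spec,
    sigma2_e = sigma2_e,
    record_ind = design$record_ind,
    individual_ids = design$individual_ids,
    n_ind = design$n_ind),
    class = "rotated_system")
}

#' @export
print.rotated_system <- function(x, ...) {
  cat(sprintf("<rotated_system> %d records, %d SNP-basis projector(s), sigma2_e = %.4g\n",
              length(x$S), length(x$projectors), x$sigma2_e))
  invisible(x)
}

#' Weighted least squares with diagonal weights
#'
#' Solves \eqn{\hat b = (X'S^{-1}X)^{-1} X'S^{-1} y} with
#' \eqn{cov(\hat b) = (X'S^{-1}X)^{-1}} via a QR factorization of the
#' row-scaled design (no explicit inverse of the cross-product).
#'
#' @param X_star Design matrix (rotated).
#' @param y_star Response vector (rotated).
#' @param S Positive weights: the diagonal of the residual covariance.
#' @return List with `b_hat` and `b_cov`.
#' @export
wls_solve <- function(X_star, y_star, S) {
  if (any(S <= 0)) stop("weights S must be strictly positive")
  w <- 1 / sqrt(S)
  Xw <- X_star * w
  qrX <- qr(Xw)
  if (qrX$rank < ncol(Xw)) {
    nm <- colnames(Xw)
    if (is.null(nm)) nm <- paste0("col", seq_len(ncol(Xw)))
    stop("rank-deficient weighted design; dependent column(s): ",
         paste(nm[qrX$pivot[(qrX$rank + 1L):ncol(Xw)]], collapse = ", "))
  }
  b_hat <- qr.coef(qrX, y_star * w)
  R <- qr.R(qrX)
  Rinv <- backsolve(R, diag(ncol(Xw)))
  cov_p <- tcrossprod(Rinv)
  piv <- qrX$pivot
  b_cov <- matrix(0, ncol(Xw), ncol(Xw))
  b_cov[piv, piv] <- cov_p
  dimnames(b_cov) <- list(colnames(X_star), colnames(X_star))
  list(b_hat = b_hat, b_cov = b_cov)
}

#' Wald chi-squared test of a time-varying SNP effect
#'
#' \eqn{\chi^2 = \hat\alpha' [cov(\hat\alpha)]^{-1} \hat\alpha} on
#' `length(alpha_hat)` degrees of freedom (the number of SNP basis
#' coefficients, nf2 + 1).
#'
#' @param alpha_hat SNP regression-coefficient vector.
#' @param alpha_cov Its covariance (symmetric positive definite).
#' @return List with `wald_stat`, `df`, `p_value`.
#' @export
wald_test <- function(alpha_hat, alpha_cov) {
  alpha_cov <- as.matrix(alpha_cov)
  ch <- tryCatch(chol(alpha_cov), error = function(e) NULL)
  if (is.null(ch))
    stop("singular coefficient covariance: SNP covariates are confounded ",
         "(e.g. monomorphic within the used records)")
  z <- backsolve(ch, alpha_hat, transpose = TRUE)
  stat <- sum(z^2)
  df <- length(alpha_hat)
  list(wald_stat = stat, df = df,
       p_value = stats::pchisq(stat, df = df, lower.tail = FALSE))
}

#' Genome scan: per-SNP weighted least squares on the rotated system
#'
#' For every SNP the genotype vector (missing imputed with 2p) is expanded
#' through the precomputed projectors into `nf2 + 1` rotated covariate
#' columns, the SNP block is fitted jointly with the base fixed effects by
#' WLS, and the time-varying effect is tested by the Wald chi-squared
#' statistic. The base design's cross-products are factored once, so the
#' per-SNP cost is a handful of matrix-vector products.
#'
#' SNPs that are monomorphic among the scanned individuals are emitted with
#' `flag = "monomorphic"` and a missing p-value rather than dropped.
#'
#' @param rot A `rotated_system` from [rotate_system()].
#' @param geno A [genotype_matrix()] covering all phenotyped individuals.
#' @param freqs Allele frequencies used for missing-genotype imputation;
#'   computed from `geno` when omitted.
#' @param snp_ids Optional subset of SNP ids to scan (default: all).
#' @param keep_cov Keep each SNP's coefficient covariance (list attribute
#'   `"alpha_cov"`)? Default off to keep scans light.
#' @return A `data.frame` (class `scan_result`) with one row per SNP:
#'   `snp_id`, `chromosome`, `position`, `allele1`, `allele2`, `maf`,
#'   `n_used`, `alpha_0..`, `wald_stat`, `df`, `p_value`, `flag`.
#' @export
scan_snps <- function(rot, geno, freqs = allele_frequencies(geno),
                      snp_ids = NULL, keep_cov = FALSE) {
  stopifnot(inherits(rot, "rotated_system"))
  gidx <- match(rot$individual_ids, geno$individual_ids)
  if (anyNA(gidx))
    stop("genotype matrix is missing scanned individual(s): ",
         paste(utils::head(rot$individual_ids[is.na(gidx)], 5L), collapse = ", "))
  if (is.null(snp_ids)) snp_ids <- geno$snp_meta$id
  midx <- match(snp_ids, geno$snp_meta$id)
  if (anyNA(midx)) stop("unknown SNP id(s): ",
                        paste(utils::head(snp_ids[is.na(midx)], 5L), collapse = ", "))

  S <- rot$S; sw <- 1 / S
  Xb <- rot$X_star_base
  q <- length(rot$projectors)
  XbW <- Xb * sw                       # S^-1 X, N x p
  A <- crossprod(Xb, XbW)              # X'S^-1X
  cholA <- chol(A)
  rb <- drop(crossprod(XbW, rot$y_star))
  yW <- rot$y_star * sw

  n <- length(midx)
  alpha <- matrix(NA_real_, n, q)
  wald <- rep(NA_real_, n); pval <- rep(NA_real_, n)
  n_used <- rep(length(rot$individual_ids), n)
  flag <- rep("", n)
  covs <- if (keep_cov) vector("list", n) else NULL

  for (i in seq_len(n)) {
    m <- midx[i]
    g <- geno$codes[gidx, m]
    na <- is.na(g)
    if (any(na)) g[na] <- 2 * freqs[m]
    if (stats::var(g) == 0) { flag[i] <- "monomorphic"; next }
    Gs <- vapply(rot$projectors, function(B) drop(B %*% g),
                 numeric(length(S)))
    Cm <- crossprod(XbW, Gs)                       # p x q
    Dm <- crossprod(Gs, Gs * sw)                   # q x q
    rg <- drop(crossprod(Gs, yW))
    AiC <- backsolve(cholA, backsolve(cholA, Cm, transpose = TRUE))
    Scov <- Dm - crossprod(Cm, AiC)                # alpha information matrix
    Scov <- (Scov + t(Scov)) / 2
    chS <- tryCatch(chol(Scov), error = function(e) NULL)
    if (is.null(chS)) { flag[i] <- "singular"; next }
    rhs <- rg - drop(crossprod(AiC, rb))
    a <- backsolve(chS, backsolve(chS, rhs, transpose = TRUE))
    alpha[i, ] <- a
    wald[i] <- sum(a * drop(Scov %*% a))
    pval[i] <- stats::pchisq(wald[i], df = q, lower.tail = FALSE)
    if (keep_cov) covs[[i]] <- chol2inv(chS)
  }

  meta <- geno$snp_meta[midx, , drop = FALSE]
  p_all <- freqs[midx]
  out <- data.frame(snp_id = meta$id, chromosome = meta$chromosome,
                    position = meta$position, allele1 = meta$allele1,
                    allele2 = meta$allele2, maf = pmin(p_all, 1 - p_all),
                    n_used = n_used, stringsAsFactors = FALSE)
  colnames(alpha) <- paste0("alpha_", seq_len(q) - 1L)
  out <- cbind(out, alpha)
  out$wald_stat <- wald
  out$df <- q
  out$p_value <- pval
  out$flag <- flag
  class(out) <- c("scan_result", class(out))
  if (keep_cov) attr(out, "alpha_cov") <- covs
  out
}

#' Time-dependent additive, permanent-environmental and phenotypic variance
#'
#' \eqn{add(t) = \phi(t)' G \phi(t)}, \eqn{perm(t) = \psi(t)' P \psi(t)},
#' \eqn{phe(t) = add(t) + perm(t) + \sigma_e^2}.
#'
#' @param vc A [variance_components()].
#' @param add_spec,perm_spec Basis specs of the two random regressions.
#' @param times Days at which to evaluate the curves.
#' @return `data.frame` with columns `t`, `add`, `perm`, `phe`.
#' @export
variance_curves <- function(vc, add_spec, perm_spec, times) {
  Pa <- basis_matrix(times, add_spec)
  Pp <- basis_matrix(times, perm_spec)
  add <- rowSums((Pa %*% vc$G) * Pa)
  perm <- rowSums((Pp %*% vc$P) * Pp)
  data.frame(t = times, add = add, perm = perm,
             phe = add + perm + vc$sigma2_e)
}

#' Genotypic value curve of a SNP over time
#'
#' \eqn{effect(t) = code \times \sum_k \hat\alpha_k \varphi_k(t)}: the
#' estimated time-varying genotypic value relative to the code-0 genotype.
#'
#' @param alpha_hat SNP regression coefficients (length nf2 + 1).
#' @param snp_spec The SNP [basis_spec()].
#' @param times Days at which to evaluate.
#' @param genotype_code 0, 1 or 2 copies of the counted allele.
#' @return Numeric vector of effects.
#' @export
snp_effect_curve <- function(alpha_hat, snp_spec, times, genotype_code = 1) {
  if (length(alpha_hat) != n_basis(snp_spec))
    stop(sprintf("alpha_hat has %d coefficients but the basis has %d functions",
                 length(alpha_hat), n_basis(snp_spec)))
  genotype_code * drop(basis_matrix(times, snp_spec) %*% alpha_hat)
}
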