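test_that("design matrices place basis rows in the owning individual's block", {
  sp1 <- basis_spec("legendre", 1)
  pheno <- data.frame(animal_id = c("a", "a", "a"), t = c(10, 150, 290),
                      htd_id = "h1", group_id = "g1", y = rnorm(3))
  des <- build_design(pheno, "a", mean_spec = sp1, add_spec = sp1)
  Q <- design_Q(des)
  expect_equal(dim(Q), c(3L, 2L))
  for (r in 1:3) expect_equal(Q[r, ], evaluate_basis(pheno$t[r], sp1))

  # two groups with an order-0 mean: indicator columns scaled by phi0
  sp0 <- basis_spec("legendre", 0)
  ph2 <- data.frame(animal_id = c("a", "a", "b", "b"), t = c(10, 100, 10, 100),
                    htd_id = "h1", group_id = c("g1", "g1", "g2", "g2"),
                    y = rnorm(4))
  des2 <- build_design(ph2, c("a", "b"), mean_spec = sp0, add_spec = sp1)
  expect_equal(ncol(des2$X), 2L)
  expect_equal(des2$X[, 1], c(sqrt(0.5), sqrt(0.5), 0, 0))
  expect_equal(des2$X[, 2], c(0, 0, sqrt(0.5), sqrt(0.5)))

  # multi-animal Q verified entry-by-entry against evaluate_basis
  ph3 <- data.frame(animal_id = c("a", "b", "a", "b"), t = c(20, 40, 160, 280),
                    htd_id = c("h1", "h1", "h2", "h2"), group_id = "g1",
                    y = rnorm(4))
  des3 <- build_design(ph3, c("b", "a"), mean_spec = sp1, add_spec = sp1)
  Q3 <- design_Q(des3)
  for (r in 1:4) {
    blk <- if (ph3$animal_id[r] == "b") 1:2 else 3:4
    expect_equal(Q3[r, blk], evaluate_basis(ph3$t[r], sp1))
    expect_equal(Q3[r, -blk], c(0, 0))
  }

  expect_error(build_design(ph3, c("a"), mean_spec = sp1, add_spec = sp1),
               "absent from the genotype panel")
})

test_that("confounded fixed designs are rejected with column names", {
  sp0 <- basis_spec("legendre", 0)
  # all of group g2's records sit in htd h2 at a single day: the htd column
  # equals the g2 mean-curve column up to scale
  ph <- data.frame(animal_id = c("a", "a", "b", "b"),
                   t = c(100, 150, 100, 200),
                   htd_id = c("h1", "h1", "h2", "h2"),
                   group_id = c("g1", "g1", "g2", "g2"), y = rnorm(4))
  expect_error(build_design(ph, c("a", "b"), mean_spec = sp0,
                            add_spec = sp0),
               "rank deficient")
})

test_that("record covariance equals the Kronecker assembly", {
  st <- small_study()
  vc <- st$cfg$true_vc
  Q <- design_Q(st$des); Z <- design_Z(st$des)
  n <- st$des$n_ind
  kk <- match(st$des$individual_ids, st$pop$kinship$individual_ids)
  Wo <- Q %*% kronecker(st$pop$kinship$values[kk, kk], vc$G) %*% t(Q) +
    Z %*% kronecker(diag(n), vc$P) %*% t(Z)
  expect_lt(max(abs(st$W - Wo)), 1e-10)

  # zero components give a zero covariance
  vc0 <- variance_components(matrix(0, 3, 3), matrix(0, 3, 3), 1)
  W0 <- build_covariance_W(st$des, st$pop$kinship, vc0)
  expect_equal(max(abs(W0)), 0)

  # order-0 closed form: (g00 + p00) phi0^2 on same-individual pairs, K = I
  sp0 <- basis_spec("legendre", 0, normalized = FALSE)
  ph <- data.frame(animal_id = c("a", "a", "b"), t = c(10, 200, 100),
                   htd_id = "h1", group_id = "g1", y = rnorm(3))
  des0 <- build_design(ph, c("a", "b"), mean_spec = sp0, add_spec = sp0,
                       perm_spec = sp0)
  Kid <- structure(list(values = diag(2), individual_ids = c("a", "b")),
                   class = "kinship_matrix")
  vc00 <- variance_components(matrix(2), matrix(3), 1)
  W00 <- build_covariance_W(des0, Kid, vc00)
  A <- outer(ph$animal_id, ph$animal_id, `==`) * 1
  expect_equal(W00, 5 * A, tolerance = 1e-12)
})

test_that("eigen rotation diagonalizes the record covariance", {
  st <- small_study()
  rot <- st$rot
  D <- crossprod(rot$U, st$W %*% rot$U)
  expect_lt(max(abs(D - diag(rot$D))), 1e-8 * max(rot$D))
  Vstar <- crossprod(rot$U, (st$W + diag(st$cfg$true_vc$sigma2_e, nrow(st$W))) %*% rot$U)
  expect_lt(max(abs(Vstar - diag(rot$S))), 1e-8 * max(rot$S))

  # W = 0: D = 0 and all weights equal the residual variance
  N <- 6
  ph <- data.frame(animal_id = rep(c("a", "b"), each = 3),
                   t = rep(c(10, 100, 250), 2), htd_id = "h1",
                   group_id = "g1", y = rnorm(N))
  des <- build_design(ph, c("a", "b"), mean_spec = basis_spec("legendre", 1),
                      add_spec = basis_spec("legendre", 1))
  rot0 <- rotate_system(matrix(0, N, N), des, 2.5, basis_spec("legendre", 1))
  expect_equal(rot0$D, rep(0, N))
  expect_equal(rot0$S, rep(2.5, N))

  expect_error(rotate_system(matrix(rnorm(36), 6, 6), des, 1,
                             basis_spec("legendre", 1)), "symmetric")
})

test_that("weighted least squares matches the textbook formula", {
  set.seed(2)
  X <- matrix(rnorm(120), 30, 4)
  y <- rnorm(30)
  S <- runif(30, 0.5, 3)
  fit <- wls_solve(X, y, S)
  XtSiX <- t(X) %*% (X / S)
  b_ref <- solve(XtSiX, t(X) %*% (y / S))
  expect_equal(fit$b_hat, drop(b_ref), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(fit$b_cov, solve(XtSiX), tolerance = 1e-10,
               ignore_attr = TRUE)

  # unit weights and orthonormal design reduce to a projection
  Qo <- qr.Q(qr(matrix(rnorm(100), 20, 5)))
  yo <- rnorm(20)
  fo <- wls_solve(Qo, yo, rep(1, 20))
  expect_equal(fo$b_hat, drop(crossprod(Qo, yo)), tolerance = 1e-10)

  # duplicating rows while doubling the weights leaves the fit unchanged
  f2 <- wls_solve(rbind(X, X), c(y, y), c(2 * S, 2 * S))
  expect_equal(f2$b_hat, fit$b_hat, tolerance = 1e-10)

  expect_error(wls_solve(cbind(X, X[, 1]), y, S), "dependent")
  expect_error(wls_solve(X, y, c(-1, S[-1])), "positive")
})

test_that("Wald test follows the chi-squared distribution rules", {
  expect_equal(wald_test(c(0, 0), diag(2))$p_value, 1)
  w <- wald_test(2, matrix(1))
  expect_equal(w$wald_stat, 4)
  expect_equal(w$df, 1L)
  expect_equal(w$p_value, pchisq(4, 1, lower.tail = FALSE), tolerance = 1e-12)
  # df always equals the number of SNP basis coefficients
  w5 <- wald_test(rep(0.1, 5), diag(5))
  expect_equal(w5$df, 5L)
  expect_error(wald_test(c(1, 1), matrix(1, 2, 2)), "singular|confounded")
})

test_that("rotated WLS scan equals direct GLS with the full covariance", {
  st <- small_study()
  scan <- scan_snps(st$rot, st$pop$geno)
  freqs <- allele_frequencies(st$pop$geno)
  for (m in c(2, 19, 44)) {
    g <- st$pop$geno$codes[, m]
    g[is.na(g)] <- 2 * freqs[m]
    ref <- gls_oracle_snp(st$des, st$W, st$cfg$true_vc$sigma2_e,
                          st$cfg$mean_spec, g)
    expect_equal(scan$wald_stat[m], ref$wald, tolerance = 1e-8)
    expect_equal(scan$p_value[m], ref$p, tolerance = 1e-8)
  }
})

test_that("monomorphic SNPs are flagged rather than dropped", {
  st <- small_study()
  g <- st$pop$geno
  g$codes[, 5] <- 1
  g <- genotype_matrix(g$codes, g$snp_meta, g$individual_ids)
  scan <- scan_snps(st$rot, g, freqs = allele_frequencies(g))
  expect_equal(scan$flag[5], "monomorphic")
  expect_true(is.na(scan$p_value[5]))
  expect_equal(nrow(scan), ncol(g$codes))
})

test_that("Wald p-values are invariant to genotype recoding and basis normalization", {
  st <- small_study()
  scan <- scan_snps(st$rot, st$pop$geno)

  # affine recoding: count the other allele (g -> 2 - g)
  g2 <- st$pop$geno
  codes2 <- 2 - g2$codes           # allele swap keeps codes in {0,1,2}
  g2 <- genotype_matrix(codes2, g2$snp_meta, g2$individual_ids)
  scan2 <- scan_snps(st$rot, g2)
  expect_equal(scan2$p_value, scan$p_value, tolerance = 1e-8)

  # unnormalized Legendre bases with G, P transformed accordingly give the
  # same record covariance and identical p-values
  lam <- diag(sqrt((2 * (0:2) + 1) / 2))
  cfg <- st$cfg
  vc_u <- variance_components(lam %*% cfg$true_vc$G %*% lam,
                              lam %*% cfg$true_vc$P %*% lam,
                              cfg$true_vc$sigma2_e)
  spu <- basis_spec("legendre", 2, normalized = FALSE)
  des_u <- build_design(st$phe$pheno, st$pop$geno$individual_ids,
                        spu, spu, spu)
  W_u <- build_covariance_W(des_u, st$pop$kinship, vc_u)
  expect_lt(max(abs(W_u - st$W)), 1e-8)
  rot_u <- rotate_system(W_u, des_u, vc_u$sigma2_e, spu)
  scan_u <- scan_snps(rot_u, st$pop$geno)
  expect_equal(scan_u$p_value, scan$p_value, tolerance = 1e-6)
  expect_equal(scan_u$wald_stat, scan$wald_stat, tolerance = 1e-6)
})

test_that("permuting genotype labels of a SNP yields uniform p-values", {
  st <- small_study()
  g <- st$pop$geno
  m <- 12
  set.seed(31)
  pv <- replicate(500, {
    codes <- g$codes
    codes[, m] <- codes[sample.int(nrow(codes)), m]
    gp <- genotype_matrix(codes, g$snp_meta, g$individual_ids)
    scan_snps(st$rot, gp, snp_ids = g$snp_meta$id[m])$p_value
  })
  expect_gt(ks.test(pv, "punif")$p.value, 0.01)
})

test_that("variance curves satisfy the decomposition identity", {
  sp1 <- basis_spec("legendre", 1)
  vc <- variance_components(matrix(c(2, 0.3, 0.3, 1), 2),
                            matrix(c(3, 0.2, 0.2, 0.5), 2), 1.5)
  tt <- seq(5, 305, by = 50)
  cv <- variance_curves(vc, sp1, sp1, tt)
  expect_equal(cv$phe - cv$add - cv$perm, rep(1.5, length(tt)))

  # order-0 unnormalized: constant additive variance G00
  sp0 <- basis_spec("legendre", 0, normalized = FALSE)
  cv0 <- variance_curves(variance_components(matrix(2), matrix(1), 1),
                         sp0, sp0, tt)
  expect_equal(cv0$add, rep(2, length(tt)))

  # G = I with normalized order-1 basis at the upper endpoint: 1/2 + 3/2
  cvI <- variance_curves(variance_components(diag(2), matrix(0, 2, 2), 1),
                         sp1, sp1, 305)
  expect_equal(cvI$add, 2)
})

test_that("SNP effect curves scale additively with the genotype code", {
  sp <- basis_spec("legendre", 2)
  a <- c(0.5, -0.2, 0.1)
  tt <- seq(5, 305, by = 25)
  expect_equal(snp_effect_curve(a, sp, tt, 0), rep(0, length(tt)))
  expect_equal(snp_effect_curve(a, sp, tt, 2),
               2 * snp_effect_curve(a, sp, tt, 1))
  # intercept-only coefficients with an unnormalized basis: constant curve
  sp0 <- basis_spec("legendre", 2, normalized = FALSE)
  expect_equal(snp_effect_curve(c(1, 0, 0), sp0, tt, 1), rep(1, length(tt)))
  expect_error(snp_effect_curve(c(1, 2), sp, tt, 1), "coefficients")
})
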