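test_that("variance component files round-trip exactly", {
  set.seed(8)
  A <- crossprod(matrix(rnorm(9), 3))
  B <- crossprod(matrix(rnorm(4), 2))
  vc <- variance_components(A, B, 1.234567890123)
  f <- tempfile()
  write_varcomp(vc, f)
  vc2 <- read_varcomp(f)
  expect_identical(vc2$G, vc$G)
  expect_identical(vc2$P, vc$P)
  expect_identical(vc2$sigma2_e, vc$sigma2_e)
  expect_error(read_varcomp(f, add_order = 4), "configured additive order")
})

test_that("hand-written variance component file parses to known matrices", {
  vc <- read_varcomp(test_path("vc_order1.txt"), add_order = 1, perm_order = 1)
  expect_equal(vc$G, matrix(c(1.5, 0.25, 0.25, 0.75), 2))
  expect_equal(vc$P, matrix(c(2.5, -0.5, -0.5, 1.25), 2))
  expect_equal(vc$sigma2_e, 0.8)
})

test_that("EM-REML is monotone in the restricted log-likelihood", {
  cfg <- sim_config(n_individuals = 40, n_families = 8, n_snps = 200, seed = 15,
                    add_spec = basis_spec("legendre", 1),
                    perm_spec = basis_spec("legendre", 1))
  pop <- simulate_population(cfg)
  phe <- simulate_phenotypes(pop, cfg)
  vc <- suppressWarnings(suppressMessages(
    reml_estimate(phe$pheno, pop$kinship, cfg$mean_spec, cfg$add_spec,
                  cfg$perm_spec, method = "em", max_iter = 40)))
  tr <- attr(vc, "convergence")$logl
  expect_true(all(diff(tr) > -1e-8))
})

test_that("pure-noise data yields near-zero G and P and the right residual", {
  q <- 2
  cfg <- sim_config(n_individuals = 200, n_families = 20, n_snps = 400,
                    seed = 21, htd_sd = 0,
                    add_spec = basis_spec("legendre", 1),
                    perm_spec = basis_spec("legendre", 1),
                    true_vc = variance_components(matrix(0, q, q),
                                                  matrix(0, q, q), 4))
  pop <- simulate_population(cfg)
  phe <- simulate_phenotypes(pop, cfg, include_htd = FALSE)
  vc <- suppressWarnings(suppressMessages(
    reml_estimate(phe$pheno, pop$kinship, cfg$mean_spec, cfg$add_spec,
                  cfg$perm_spec)))
  expect_equal(vc$sigma2_e, 4, tolerance = 0.05)
  expect_lt(max(eigen(vc$G, only.values = TRUE)$values), 0.05 * vc$sigma2_e)
  expect_lt(max(eigen(vc$P, only.values = TRUE)$values), 0.05 * vc$sigma2_e)
})

test_that("order-0 fit with identity kinship matches an lme4 repeatability model", {
  skip_if_not_installed("lme4")
  set.seed(33)
  n <- 120; reps <- 6
  id <- rep(sprintf("a%03d", 1:n), each = reps)
  tt <- rep(round(seq(5, 305, length.out = reps)), n)
  htd <- rep(sprintf("h%d", 1:reps), n)
  a <- rep(rnorm(n, 0, sqrt(2.5)), each = reps)
  y <- a + rnorm(n * reps, 0, sqrt(1.8))
  ph <- data.frame(animal_id = id, t = tt, htd_id = htd, group_id = "g1",
                   y = y)
  sp0 <- basis_spec("legendre", 0, normalized = FALSE)
  Kid <- structure(list(values = diag(n), individual_ids = sprintf("a%03d", 1:n)),
                   class = "kinship_matrix")
  vc <- suppressWarnings(suppressMessages(
    reml_estimate(ph, Kid, mean_spec = sp0, add_spec = sp0, perm_spec = sp0,
                  tol = 1e-9, max_iter = 500)))
  fit <- lme4::lmer(y ~ htd_id + (1 | animal_id), data = ph, REML = TRUE)
  vc_ref <- as.data.frame(lme4::VarCorr(fit))
  ind_var_ref <- vc_ref$vcov[vc_ref$grp == "animal_id"]
  res_var_ref <- vc_ref$vcov[vc_ref$grp == "Residual"]
  # with K = I the additive and permanent order-0 variances are only
  # identified through their sum
  expect_equal(vc$G[1, 1] + vc$P[1, 1], ind_var_ref, tolerance = 1e-4)
  expect_equal(vc$sigma2_e, res_var_ref, tolerance = 1e-4)
})

test_that("REML estimates are invariant to individual reordering", {
  cfg <- sim_config(n_individuals = 40, n_families = 8, n_snps = 200, seed = 27,
                    add_spec = basis_spec("legendre", 1),
                    perm_spec = basis_spec("legendre", 1))
  pop <- simulate_population(cfg)
  phe <- simulate_phenotypes(pop, cfg)
  v1 <- suppressWarnings(suppressMessages(
    reml_estimate(phe$pheno, pop$kinship, cfg$mean_spec, cfg$add_spec,
                  cfg$perm_spec, tol = 1e-8)))
  perm <- sample(seq_len(cfg$n_individuals))
  K2 <- structure(list(values = pop$kinship$values[perm, perm],
                       individual_ids = pop$kinship$individual_ids[perm]),
                  class = "kinship_matrix")
  ph2 <- phe$pheno[rev(seq_len(nrow(phe$pheno))), , drop = FALSE]
  v2 <- suppressWarnings(suppressMessages(
    reml_estimate(phenotype_table(as.data.frame(ph2)), K2, cfg$mean_spec,
                  cfg$add_spec, cfg$perm_spec, tol = 1e-8)))
  expect_equal(v2$G, v1$G, tolerance = 1e-4)
  expect_equal(v2$P, v1$P, tolerance = 1e-4)
  expect_equal(v2$sigma2_e, v1$sigma2_e, tolerance = 1e-5)
})

test_that("non-PSD initial values are rejected", {
  cfg <- sim_config(n_individuals = 20, n_families = 4, n_snps = 100, seed = 2,
                    add_spec = basis_spec("legendre", 1),
                    perm_spec = basis_spec("legendre", 1))
  pop <- simulate_population(cfg)
  phe <- simulate_phenotypes(pop, cfg)
  bad <- matrix(c(1, 2, 2, 1), 2)  # eigenvalues 3 and -1
  expect_error(variance_components(bad, diag(2), 1), "positive semi-definite")
})
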