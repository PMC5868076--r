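# Shared fixtures, built once per test run and cached.
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures)) assign(name, builder(), envir = .fixtures)
  get(name, envir = .fixtures)
}

# small half-sib study used across engine tests: 50 cows, order-2 bases
small_study <- function() fixture("small_study", function() {
  cfg <- sim_config(n_individuals = 50, n_families = 10, n_snps = 60, seed = 3)
  pop <- simulate_population(cfg)
  phe <- simulate_phenotypes(pop, cfg)
  des <- build_design(phe$pheno, pop$geno$individual_ids,
                      cfg$mean_spec, cfg$add_spec, cfg$perm_spec)
  W <- build_covariance_W(des, pop$kinship, cfg$true_vc)
  rot <- rotate_system(W, des, cfg$true_vc$sigma2_e, cfg$mean_spec)
  list(cfg = cfg, pop = pop, phe = phe, des = des, W = W, rot = rot)
})

# study at the defaults (300 cows), shared by the calibration/power tests
default_study <- function() fixture("default_study", function() {
  cfg <- sim_config(seed = 1)
  pop <- simulate_population(cfg)
  phe <- simulate_phenotypes(pop, cfg)
  list(cfg = cfg, pop = pop, phe = phe)
})

# null scan on the default study with the polygenic term (reused for power)
default_null <- function() fixture("default_null", function() {
  st <- default_study()
  null_scan_study(st$pop, st$phe, st$cfg)
})

# dense GLS fit of one SNP: the from-scratch oracle the rotated path must match
gls_oracle_snp <- function(des, W, sigma2_e, snp_spec, g) {
  V <- W + diag(sigma2_e, nrow(W))
  Vi <- solve(V)
  Phi_snp <- basis_matrix(des$t, snp_spec)
  Xs <- cbind(des$X, Phi_snp * g[des$record_ind])
  XtVi <- t(Xs) %*% Vi
  b <- solve(XtVi %*% Xs, XtVi %*% des$y)
  covb <- solve(XtVi %*% Xs)
  q <- ncol(Phi_snp)
  idx <- (ncol(Xs) - q + 1):ncol(Xs)
  stat <- drop(t(b[idx]) %*% solve(covb[idx, idx], b[idx]))
  list(wald = stat, p = pchisq(stat, df = q, lower.tail = FALSE))
}
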