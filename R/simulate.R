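#' Configuration of the synthetic test-day study
#'
#' Captures the study conditions the simulator emulates: a half-sib
#' structured cow population genotyped at independent SNPs, unbalanced
#' monthly test-day records over days in milk 5-305, herd-test-date
#' effects, group-specific lactation mean curves, and random regression
#' genetic / permanent-environmental (co)variances.
#'
#' Defaults describe a desk-scale population: 300 cows in 30 paternal
#' half-sib families, 1000 SNPs with frequencies U(0.05, 0.5), 10
#' scheduled monthly tests with +-10-day jitter and 10% record dropout,
#' herd-test-date effects of SD 2 across 10 herds, two mean-curve groups,
#' and order-2 normalized Legendre bases with mildly correlated G and P
#' giving a lactation-average heritability around 0.25.
#'
#' @param n_individuals Number of cows.
#' @param n_families Number of paternal half-sib families (`<=`
#'   `n_individuals`); `n_families == n_individuals` gives an unrelated
#'   population.
#' @param n_snps Number of simulated SNPs.
#' @param maf_low,maf_high Allele-frequency law U(maf_low, maf_high).
#' @param record_schedule Scheduled days in milk (default 10 monthly tests
#'   spanning 5-305).
#' @param schedule_jitter Max uniform day jitter around each scheduled
#'   test (integer days).
#' @param dropout Probability that a scheduled record is missing.
#' @param n_herds Number of herds; HTD levels are herd x scheduled test.
#' @param htd_sd SD of herd-test-date effects (trait units).
#' @param group_labels Number of mean-curve groups.
#' @param group_curves Matrix of fixed regression coefficients (groups x
#'   n_basis of `mean_spec`) for the group mean curves; default built in.
#' @param true_vc A [variance_components()]; default matches the order-2
#'   bases.
#' @param mean_spec,add_spec,perm_spec [basis_spec()]s of the generative
#'   model.
#' @param seed Integer seed; the whole stack is reproducible under it.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_individuals = 300L, n_families = 30L,
                       n_snps = 1000L, maf_low = 0.05, maf_high = 0.5,
                       record_schedule = round(seq(5, 305, length.out = 10)),
                       schedule_jitter = 10L, dropout = 0.1,
                       n_herds = 10L, htd_sd = 2,
                       group_labels = 2L, group_curves = NULL,
                       true_vc = NULL,
                       mean_spec = basis_spec("legendre", order = 2),
                       add_spec = basis_spec("legendre", order = 2),
                       perm_spec = basis_spec("legendre", order = 2),
                       seed = 1L) {
  if (n_families > n_individuals)
    stop("n_families must not exceed n_individuals")
  standardize_time(record_schedule, c(mean_spec$t_min, mean_spec$t_max))
  if (is.null(true_vc)) {
    q1 <- n_basis(add_spec); q2 <- n_basis(perm_spec)
    G <- 3.0 * stats::toeplitz(0.3^(0:(q1 - 1))) * tcrossprod(c(1, rep(0.5, q1 - 1)))
    P <- 6.0 * stats::toeplitz(0.3^(0:(q2 - 1))) * tcrossprod(c(1, rep(0.5, q2 - 1)))
    true_vc <- variance_components(G, P, sigma2_e = 4)
  }
  if (is.null(group_curves)) {
    qm <- n_basis(mean_spec)
    # a typical declining lactation shape plus a level offset per group
    base <- c(30, -4, 1.5, rep(0, max(0, qm - 3)))[seq_len(qm)]
    group_curves <- t(vapply(seq_len(group_labels),
                             function(g) base + c(2 * (g - 1), rep(0, qm - 1)),
                             numeric(qm)))
  }
  structure(list(
    n_individuals = as.integer(n_individuals),
    n_families = as.integer(n_families),
    n_snps = as.integer(n_snps),
    maf_low = maf_low, maf_high = maf_high,
    record_schedule = as.numeric(record_schedule),
    schedule_jitter = as.integer(schedule_jitter),
    dropout = dropout,
    n_herds = as.integer(n_herds), htd_sd = htd_sd,
    group_labels = as.integer(group_labels),
    group_curves = group_curves,
    true_vc = true_vc,
    mean_spec = mean_spec, add_spec = add_spec, perm_spec = perm_spec,
    seed = as.integer(seed)),
    class = "sim_config")
}

#' Simulate a half-sib genotyped population
#'
#' Per SNP, an allele frequency p is drawn from the configured uniform
#' law; each sire receives Binomial(2, p) allele counts; each daughter
#' inherits one allele sampled from her sire's two and one from the
#' population (Bernoulli p). Daughters of one sire form a paternal
#' half-sib family with elevated expected kinship, supplying the
#' population structure and cryptic relatedness the association model
#' must absorb.
#'
#' @param cfg A [sim_config()].
#' @return List with `geno` ([genotype_matrix()]), `kinship` (VanRaden
#'   [vanraden_kinship()] from the simulated SNPs), and `family` (integer
#'   family index per individual).
#' @export
simulate_population <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n_individuals; fam_n <- cfg$n_families; m <- cfg$n_snps
  p <- stats::runif(m, cfg$maf_low, cfg$maf_high)
  family <- rep(seq_len(fam_n), length.out = n)
  sire <- matrix(stats::rbinom(fam_n * m, 2L, rep(p, each = fam_n)),
                 nrow = fam_n, ncol = m)
  # paternal allele: for het sires a fair coin, else the homozygous allele
  sire_of <- sire[family, , drop = FALSE]
  pat <- matrix(0L, n, m)
  pat[sire_of == 2L] <- 1L
  het <- sire_of == 1L
  pat[het] <- stats::rbinom(sum(het), 1L, 0.5)
  mat <- matrix(stats::rbinom(n * m, 1L, rep(p, each = n)), n, m)
  codes <- pat + mat
  meta <- data.frame(id = sprintf("snp%04d", seq_len(m)),
                     chromosome = "1", position = seq_len(m) * 1000L,
                     allele1 = "A", allele2 = "B", stringsAsFactors = FALSE)
  geno <- genotype_matrix(codes, meta,
                          individual_ids = sprintf("cow%04d", seq_len(n)))
  K <- vanraden_kinship(geno)
  list(geno = geno, kinship = K, family = family, true_freqs = p)
}

#' Simulate unbalanced test-day phenotypes from the random regression model
#'
#' Draws \eqn{u \sim N(0, K \otimes G)}, \eqn{p \sim N(0, I \otimes P)},
#' herd-test-date effects \eqn{N(0, htd\_sd^2)} and iid residuals, then
#' assembles records at jittered, thinned schedule days:
#' \eqn{y = \mu_{group}(t) + htd + \phi(t)'u_n + \psi(t)'p_n + e}.
#' No SNP effect enters: every simulated SNP is null, as in a type-I
#' error study. QTN effects are injected afterwards with
#' [inject_qtn_effect()].
#'
#' @param pop Output of [simulate_population()].
#' @param cfg The same [sim_config()].
#' @param include_htd,include_groups Disable the herd-test-date block or
#'   the group curves (both active by default).
#' @return List with `pheno` (a [phenotype_table()]) and `truth` (list of
#'   the drawn `u`, `p`, `htd_effects`).
#' @export
simulate_phenotypes <- function(pop, cfg, include_htd = TRUE,
                                include_groups = TRUE) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 1L)
  n <- cfg$n_individuals
  vc <- cfg$true_vc
  K <- pop$kinship$values
  eg <- eigen((K + t(K)) / 2, symmetric = TRUE)
  Lk <- eg$vectors %*% (sqrt(pmax(eg$values, 0)) * t(eg$vectors))
  Lg <- chol_psd(vc$G)
  Lp <- chol_psd(vc$P)
  q1 <- nrow(vc$G); q2 <- nrow(vc$P)
  Um <- Lk %*% matrix(stats::rnorm(n * q1), n, q1) %*% t(Lg)
  Pm <- matrix(stats::rnorm(n * q2), n, q2) %*% t(Lp)

  herd <- rep(seq_len(cfg$n_herds), length.out = n)
  sched <- cfg$record_schedule
  htd_levels <- expand.grid(herd = seq_len(cfg$n_herds),
                            test = seq_along(sched))
  htd_eff <- stats::rnorm(nrow(htd_levels), 0, cfg$htd_sd)
  names(htd_eff) <- paste0("h", htd_levels$herd, ".t", htd_levels$test)
  # groups (calving season / age class) cut across herds, so assignment is
  # randomized; a deterministic herd-aligned assignment would confound the
  # group curves with the herd-test-date block
  group <- sample(rep(seq_len(cfg$group_labels), length.out = n))

  rows <- vector("list", n)
  dom <- c(cfg$mean_spec$t_min, cfg$mean_spec$t_max)
  for (i in seq_len(n)) {
    keep <- stats::runif(length(sched)) >= cfg$dropout
    if (sum(keep) < 2L) keep[sample.int(length(sched), 2L)] <- TRUE
    tt <- sched[keep] + sample(seq(-cfg$schedule_jitter, cfg$schedule_jitter),
                               sum(keep), replace = TRUE)
    tt <- pmin(pmax(tt, dom[1]), dom[2])
    tt <- sort(unique(tt))
    rows[[i]] <- data.frame(
      animal_id = pop$geno$individual_ids[i],
      parity = 1L,
      t = tt,
      htd_id = paste0("h", herd[i], ".t", findInterval(tt, sched - 15)),
      group_id = paste0("g", group[i]),
      stringsAsFactors = FALSE)
  }
  pheno <- do.call(rbind, rows)
  # findInterval can step outside the schedule at jittered extremes; clamp
  ti <- pmin(pmax(as.integer(sub("^.*\\.t", "", pheno$htd_id)), 1L),
             length(sched))
  pheno$htd_id <- paste0(sub("\\.t.*$", "", pheno$htd_id), ".t", ti)

  Phi_a <- basis_matrix(pheno$t, cfg$add_spec)
  Phi_p <- basis_matrix(pheno$t, cfg$perm_spec)
  Phi_m <- basis_matrix(pheno$t, cfg$mean_spec)
  idx <- match(pheno$animal_id, pop$geno$individual_ids)
  y <- rowSums(Phi_a * Um[idx, , drop = FALSE]) +
    rowSums(Phi_p * Pm[idx, , drop = FALSE]) +
    stats::rnorm(nrow(pheno), 0, sqrt(vc$sigma2_e))
  if (include_groups)
    y <- y + rowSums(Phi_m * cfg$group_curves[group[idx], , drop = FALSE])
  if (include_htd)
    y <- y + htd_eff[pheno$htd_id]
  pheno$y <- unname(y)
  list(pheno = phenotype_table(pheno),
       truth = list(u = Um, p = Pm, htd_effects = htd_eff,
                    group = group, herd = herd))
}

chol_psd <- function(M) {
  eg <- eigen((M + t(M)) / 2, symmetric = TRUE)
  if (min(eg$values) < -1e-8 * max(eg$values, 1))
    stop("matrix is not positive semi-definite")
  eg$vectors %*% (sqrt(pmax(eg$values, 0)) * t(eg$vectors))
}

#' Simulate the time-varying QTN effect trajectory
#'
#' The per-day allele-substitution effect starts at 10.0 on day 5 and
#' performs a random walk with independent U(-1, 1) daily increments
#' through the end of the domain; the trajectory is then read off at the
#' schedule days. Scaling to a target effect size is done separately by
#' [scale_qtn()].
#'
#' @param schedule_days Days at which records exist; must start at the
#'   domain start (day 5).
#' @param seed Integer seed.
#' @param day_grid Full daily grid (default `5:305`).
#' @return Object of class `qtn_effect` with `day_grid`, `daily_effects`
#'   (per day), `schedule_days`, `schedule_effects`.
#' @export
make_qtn_trajectory <- function(schedule_days, seed = 1L, day_grid = 5:305) {
  if (min(schedule_days) != day_grid[1])
    stop("schedule must begin at the first day of the trajectory grid")
  set.seed(seed)
  steps <- stats::runif(length(day_grid) - 1L, -1, 1)
  daily <- 10.0 + c(0, cumsum(steps))
  sched_idx <- match(round(schedule_days), day_grid)
  if (anyNA(sched_idx)) stop("schedule days must lie on the daily grid")
  structure(list(day_grid = day_grid, daily_effects = daily,
                 schedule_days = schedule_days,
                 schedule_effects = daily[sched_idx],
                 k = NA_real_, scaled_effects = NULL),
            class = "qtn_effect")
}

#' Scale a QTN trajectory to a target effect size
#'
#' Rescales the whole trajectory so that its root-mean-square over the
#' schedule days equals `k` phenotypic standard deviations. Under this
#' scaling the phenotypic-variance fraction explained by the QTN matches
#' [qtn_variance_fraction()] exactly in expectation. `method = "mean"`
#' instead matches the time-average effect to `k * phe_sd`.
#'
#' @param traj A `qtn_effect` from [make_qtn_trajectory()].
#' @param k Effect size in phenotypic SD units (>= 0).
#' @param phe_sd Phenotypic standard deviation used as the unit.
#' @param method `"rms"` (default) or `"mean"`.
#' @return The `qtn_effect` with `k` and `scaled_effects` (per schedule
#'   day) filled in, plus `scaled_daily` over the full grid.
#' @export
scale_qtn <- function(traj, k, phe_sd, method = c("rms", "mean")) {
  method <- match.arg(method)
  stopifnot(inherits(traj, "qtn_effect"))
  if (k < 0) stop("k must be non-negative")
  if (phe_sd <= 0) stop("phe_sd must be positive")
  base <- switch(method,
                 rms = sqrt(mean(traj$schedule_effects^2)),
                 mean = mean(traj$schedule_effects))
  if (base == 0) stop("trajectory has zero scale; cannot normalize")
  fac <- k * phe_sd / base
  traj$k <- k
  traj$scaled_effects <- traj$schedule_effects * fac
  traj$scaled_daily <- traj$daily_effects * fac
  traj
}

#' Phenotypic-variance fraction explained by a QTN
#'
#' \deqn{\pi = \frac{2p(1-p)k^2}{1 + 2p(1-p)k^2}}
#' with p the allele frequency and k the allele-substitution effect in
#' phenotypic SD units.
#'
#' @param p Allele frequency in \[0, 1\].
#' @param k Effect size in phenotypic SDs.
#' @return \eqn{\pi} in \[0, 1).
#' @export
qtn_variance_fraction <- function(p, k) {
  if (any(p < 0 | p > 1)) stop("allele frequency must be in [0, 1]")
  v <- 2 * p * (1 - p) * k^2
  v / (1 + v)
}

#' Add a QTN's time-varying effect to the phenotypes
#'
#' For every record of individual n at day t adds
#' `codes[n] * scaled_effect(t)`, reading the scaled trajectory off the
#' daily grid.
#'
#' @param pheno A [phenotype_table()].
#' @param codes Genotype codes (0/1/2) named or ordered by the scan panel.
#' @param animal_ids Panel ids aligned with `codes`.
#' @param traj A scaled `qtn_effect` (see [scale_qtn()]).
#' @return The phenotype table with modified `y`.
#' @export
inject_qtn_effect <- function(pheno, codes, animal_ids, traj) {
  if (is.null(traj$scaled_effects)) stop("trajectory has not been scaled")
  day_idx <- match(round(pheno$t), traj$day_grid)
  if (anyNA(day_idx))
    stop("record day(s) outside the trajectory grid")
  g <- codes[match(pheno$animal_id, animal_ids)]
  pheno$y <- pheno$y + g * traj$scaled_daily[day_idx]
  pheno
}

#' Null-SNP scan: type-I error and p-value uniformity
#'
#' Runs the full rotated scan on phenotypes simulated without any SNP
#' effect and summarizes the null behaviour: the fraction of p-values
#' below `alpha` and the Kolmogorov-Smirnov distance to Uniform(0,1).
#' With `with_polygenic = FALSE` the additive-genetic covariance term is
#' dropped and the permanent-environment and residual variances are
#' re-estimated by REML, reproducing the comparator model that ignores
#' time-varying polygenic effects (and therefore inflates type-I error
#' under family structure).
#'
#' @param pop,phe Outputs of [simulate_population()] /
#'   [simulate_phenotypes()].
#' @param cfg The [sim_config()].
#' @param snp_spec [basis_spec()] of the tested SNP effect (default: the
#'   config's mean spec).
#' @param n_test_snps Number of random SNPs to test (default 1000).
#' @param alpha Nominal level (default 0.05).
#' @param with_polygenic Include the polygenic covariance (default TRUE).
#' @param vc Variance components for the full model (default: the
#'   config's true components, i.e. the known-variance P3D setting).
#' @return List with `p_values`, `rejection_rate`, `ks_stat`, `ks_p`,
#'   `rot` (the rotated system, reusable by [power_study()]), `scan`.
#' @export
null_scan_study <- function(pop, phe, cfg, snp_spec = cfg$mean_spec,
                            n_test_snps = 1000L, alpha = 0.05,
                            with_polygenic = TRUE, vc = cfg$true_vc) {
  design <- build_design(phe$pheno, pop$geno$individual_ids,
                         cfg$mean_spec, cfg$add_spec, cfg$perm_spec)
  if (!with_polygenic) {
    vc_np <- reml_estimate(phe$pheno, K = NULL,
                           mean_spec = cfg$mean_spec,
                           add_spec = cfg$add_spec,
                           perm_spec = cfg$perm_spec,
                           include_genetic = FALSE, tol = 1e-4)
    W <- build_covariance_W(design, K = NULL, vc = vc_np,
                            with_polygenic = FALSE)
    sigma2_e <- vc_np$sigma2_e
  } else {
    W <- build_covariance_W(design, pop$kinship, vc)
    sigma2_e <- vc$sigma2_e
  }
  rot <- rotate_system(W, design, sigma2_e, snp_spec)
  set.seed(cfg$seed + 2L)
  snp_ids <- sample(pop$geno$snp_meta$id,
                    min(n_test_snps, ncol(pop$geno$codes)))
  scan <- scan_snps(rot, pop$geno, snp_ids = snp_ids)
  pv <- scan$p_value[!is.na(scan$p_value)]
  ks <- stats::ks.test(pv, "punif")
  list(p_values = pv, rejection_rate = mean(pv < alpha),
       ks_stat = unname(ks$statistic), ks_p = ks$p.value,
       rot = rot, scan = scan)
}

#' Power study over a grid of QTN effect sizes
#'
#' For each effect size k and each chosen SNP, the scaled time-varying
#' QTN effect is added to the phenotypes, the single SNP is re-tested on
#' the (unchanged) rotated system, and detection is declared when its
#' p-value falls below the empirical threshold -- the 5th percentile of
#' the null p-value distribution, which calibrates all models to the same
#' realized type-I error.
#'
#' @param pop,phe,cfg As in [null_scan_study()].
#' @param null_result Output of [null_scan_study()] (supplies the rotated
#'   system and the null p-values).
#' @param k_grid Effect sizes in phenotypic SDs.
#' @param n_effect_snps SNPs per effect size (default 200).
#' @param fresh_trajectory Draw a new random-walk trajectory per SNP
#'   (default) or reuse one.
#' @return List with `power` (named by k), `threshold`, `detail`
#'   (data.frame of per-SNP p-values), `phe_sd`.
#' @export
power_study <- function(pop, phe, cfg, null_result,
                        k_grid = c(0.04, 0.08, 0.12, 0.16, 0.20),
                        n_effect_snps = 200L, fresh_trajectory = TRUE) {
  rot <- null_result$rot
  threshold <- unname(stats::quantile(null_result$p_values, 0.05, type = 1))
  vc <- cfg$true_vc
  curves <- variance_curves(vc, cfg$add_spec, cfg$perm_spec,
                            cfg$record_schedule)
  phe_sd <- sqrt(mean(curves$phe))
  freqs <- allele_frequencies(pop$geno)

  design <- NULL # rotation is reused; only y changes per injection
  set.seed(cfg$seed + 3L)
  snp_ids <- sample(pop$geno$snp_meta$id, n_effect_snps)
  traj0 <- make_qtn_trajectory(cfg$record_schedule, seed = cfg$seed + 4L)
  detail <- list()
  power <- numeric(length(k_grid))
  names(power) <- as.character(k_grid)
  y0_star <- rot$y_star
  pheno <- phe$pheno
  for (ki in seq_along(k_grid)) {
    k <- k_grid[ki]
    pvals <- numeric(length(snp_ids))
    for (si in seq_along(snp_ids)) {
      traj <- if (fresh_trajectory)
        make_qtn_trajectory(cfg$record_schedule,
                            seed = cfg$seed + 1000L * ki + si)
      else traj0
      traj <- scale_qtn(traj, k, phe_sd)
      m <- match(snp_ids[si], pop$geno$snp_meta$id)
      g <- pop$geno$codes[match(rot$individual_ids,
                                pop$geno$individual_ids), m]
      g[is.na(g)] <- 2 * freqs[m]
      day_idx <- match(round(pheno$t), traj$day_grid)
      inj <- g[rot$record_ind] * traj$scaled_daily[day_idx]
      rot$y_star <- y0_star + drop(crossprod(rot$U, inj))
      sc <- scan_snps(rot, pop$geno, snp_ids = snp_ids[si])
      pvals[si] <- sc$p_value
    }
    power[ki] <- mean(pvals < threshold, na.rm = TRUE)
    detail[[ki]] <- data.frame(k = k, snp_id = snp_ids, p_value = pvals,
                               stringsAsFactors = FALSE)
  }
  rot$y_star <- y0_star
  list(power = power, threshold = threshold,
       detail = do.call(rbind, detail), phe_sd = phe_sd)
}
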