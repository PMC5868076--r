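toy_geno <- function(codes, pos = NULL) {
  codes <- as.matrix(codes)
  meta <- data.frame(id = paste0("s", seq_len(ncol(codes))),
                     chromosome = "1",
                     position = if (is.null(pos)) seq_len(ncol(codes)) * 100 else pos,
                     allele1 = "A", allele2 = "B", stringsAsFactors = FALSE)
  genotype_matrix(codes, meta)
}

test_that("allele frequencies count the coded allele over non-missing calls", {
  g <- toy_geno(cbind(c(0, 1, 2, 2, NA), c(0, 1, 2, 0, 1), c(2, 2, 2, 2, 2)))
  p <- allele_frequencies(g)
  expect_equal(unname(p), c(5 / 8, 0.4, 1.0))
  g2 <- toy_geno(cbind(c(0, 1, 2), c(NA, NA, NA)))
  expect_error(allele_frequencies(g2), "s2")
})

test_that("HWE chi-squared test matches hand-computed values", {
  expect_equal(hwe_test(25, 50, 25), 1.0)
  # p_hat = 0.5, expected (25, 50, 25): chi2 = 1 + 2 + 1 = 4 on 1 df
  expect_equal(hwe_test(30, 40, 30), pchisq(4, 1, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(hwe_test(100, 0, 0), 1.0)
  expect_error(hwe_test(-1, 5, 5), "non-negative")
  # vectorized
  expect_equal(hwe_test(c(25, 100), c(50, 0), c(25, 0)), c(1, 1))
})

test_that("MAF/HWE filtering removes the right SNPs with reasons", {
  n <- 100
  snp_hwe <- c(rep(0, 30), rep(1, 40), rep(2, 30))        # HWE p ~ 0.0455
  snp_rare <- c(rep(1, 4), rep(0, 96))                    # p = 0.02
  snp_ok <- c(rep(0, 25), rep(1, 50), rep(2, 25))         # exact HWE, p = 0.5
  g <- toy_geno(cbind(snp_rare, snp_hwe, snp_ok))
  out <- filter_snps(g, maf_min = 0.03, hwe_p_min = 0.05)
  rep <- attr(out, "filter_report")
  expect_equal(out$snp_meta$id, "s3")
  expect_equal(rep$reason[rep$snp_id == "s1"], "MAF")
  expect_equal(rep$reason[rep$snp_id == "s2"], "HWE")
  expect_equal(rep$value[rep$snp_id == "s2"],
               pchisq(4, 1, lower.tail = FALSE), tolerance = 1e-10)
  # idempotent
  out2 <- filter_snps(out, maf_min = 0.03, hwe_p_min = 0.05)
  expect_equal(out2$codes, out$codes)
})

test_that("VanRaden kinship matches hand computation and is well scaled", {
  # one SNP, p = 0.5: centered code 1, denominator 2 * 0.25
  g1 <- toy_geno(matrix(c(2, 0), ncol = 1))
  K <- vanraden_kinship(g1, freqs = 0.5)
  expect_equal(K$values[1, 1], 2.0)
  expect_equal(K$values[2, 2], 2.0)
  expect_equal(K$values[1, 2], -2.0)

  # duplicate genotype rows are indistinguishable
  set.seed(1)
  cc <- matrix(rbinom(5 * 20, 2, 0.4), 5, 20)
  cc[2, ] <- cc[1, ]
  g2 <- toy_geno(cc)
  K2 <- vanraden_kinship(g2)
  expect_equal(K2$values[1, 2], K2$values[1, 1])
  expect_equal(K2$values[2, 2], K2$values[1, 1])

  # drawing at the centering frequencies gives mean diagonal ~ 1
  set.seed(42)
  p <- runif(500, 0.1, 0.9)
  cc <- sapply(p, function(pp) rbinom(200, 2, pp))
  K3 <- vanraden_kinship(toy_geno(cc), freqs = p)
  expect_equal(mean(diag(K3$values)), 1, tolerance = 0.05)

  # invariant to SNP column order
  g4 <- toy_geno(cc[, c(250:500, 1:249)])
  K4 <- vanraden_kinship(g4, freqs = p[c(250:500, 1:249)])
  expect_equal(K4$values, K3$values, tolerance = 1e-12)

  expect_error(vanraden_kinship(toy_geno(matrix(c(2, 2), ncol = 1)),
                                freqs = 1), "monomorphic")
})

test_that("pairwise r2 matches the hand-computed Pearson correlation", {
  expect_equal(ld_r2(c(0, 1, 2, 2), c(0, 1, 2, 2)), 1.0)
  expect_equal(ld_r2(c(0, 1, 2, 2), c(0, 1, 2, 0)), (1.25 / 2.75)^2,
               tolerance = 1e-12)
  expect_warning(r <- ld_r2(c(1, 1, 1, 1), c(0, 1, 2, 0)), "zero")
  expect_equal(r, 0)
  expect_error(ld_r2(c(0, 1), c(0, 1, 2)), "length")
})

test_that("windowed LD pruning removes one member of each correlated pair", {
  set.seed(7)
  base <- matrix(rbinom(40 * 10, 2, 0.5), 40, 10)
  # make SNPs 4, 5, 6 a perfectly correlated triplet
  base[, 5] <- base[, 4]
  base[, 6] <- base[, 4]
  g <- toy_geno(base)
  kept <- ld_prune(g, window = 10, step = 5, r2_max = 0.5)
  expect_equal(length(kept), 8L)
  expect_length(intersect(c("s4", "s5", "s6"), kept), 1L)

  # duplicated adjacent pair: exactly one survives
  dup <- base[, 1:4]; dup[, 3] <- dup[, 2]
  kept2 <- ld_prune(toy_geno(dup), window = 4, step = 2, r2_max = 0.5)
  expect_equal(length(kept2), 3L)

  # independent SNPs: nothing (or almost nothing) pruned
  set.seed(11)
  ind <- matrix(rbinom(200 * 120, 2, 0.3), 200, 120)
  keep3 <- ld_prune(toy_geno(ind))
  expect_gte(length(keep3), 0.95 * 120)

  # unsorted positions rejected
  g_uns <- toy_geno(base, pos = rev(seq_len(10) * 100))
  expect_error(ld_prune(g_uns), "sort")
})

test_that("Bonferroni threshold is alpha over the effective test count", {
  expect_equal(signif(bonferroni_threshold(0.05, 45573), 4), 1.097e-6)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(bonferroni_threshold(0.01, 100), 1e-4)
  expect_error(bonferroni_threshold(0.05, 0), "positive")
})

test_that("region enrichment coefficient and expected-by-chance count", {
  regions <- interval_set("1", 1, 100, genome_size = 1000)
  pos <- list(chromosome = rep("1", 10),
              position = c(seq(10, 90, length.out = 5), seq(200, 900, length.out = 5)))
  res <- enrichment_coefficient(pos, rep(TRUE, 10), regions)
  expect_equal(res$coefficient, (5 / 100) / (5 / 900))
  expect_equal(res$coefficient, 9.0)

  # the by-chance expectation: 84 significant SNPs, regions = 6.25% of genome
  reg2 <- interval_set("1", 1, 62500, genome_size = 1e6)
  pos2 <- list(chromosome = rep("1", 84), position = rep(5e5, 84))
  res2 <- enrichment_coefficient(pos2, rep(TRUE, 84), reg2)
  expect_equal(res2$region_fraction, 0.0625)
  expect_equal(res2$expected_in_regions_by_chance, 84 * 0.0625)
  expect_equal(round(res2$expected_in_regions_by_chance), 5)

  # uniform placement gives a coefficient near 1
  set.seed(5)
  posu <- list(chromosome = rep("1", 20000),
               position = sample.int(1000, 20000, replace = TRUE))
  resu <- enrichment_coefficient(posu, rep(TRUE, 20000), regions)
  expect_equal(resu$coefficient, 1, tolerance = 0.1)

  # all inside -> infinite enrichment
  resi <- enrichment_coefficient(list(chromosome = "1", position = 50),
                                 TRUE, regions)
  expect_identical(resi$coefficient, Inf)
})

test_that("BED3 regions convert to 1-based inclusive membership", {
  bed <- tempfile(fileext = ".bed")
  writeLines(c("1\t100\t200", "1\t150\t300", "2\t0\t50"), bed)
  regions <- read_bed_regions(bed, genome_size = 10000)
  # overlapping records merged: chr1 101..300 (1-based), chr2 1..50
  expect_equal(sum(GenomicRanges::width(regions$ranges)), 200 + 50)
  expect_true(in_regions("1", 101, regions))
  expect_false(in_regions("1", 100, regions))
  expect_true(in_regions("1", 300, regions))
  expect_false(in_regions("1", 301, regions))
  expect_true(in_regions("2", 1, regions))
})
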