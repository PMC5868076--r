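#' Read a long-format phenotype table
#'
#' Reads a TSV/CSV of test-day records, maps columns, drops rows with
#' missing trait values (count reported), removes animals with too few
#' records (strictly more than `min_records` records are required to be
#' retained), and validates all times against the time domain.
#'
#' @param path Delimited file with one row per animal x test day.
#' @param column_map Named character vector mapping the required names
#'   (`animal_id`, `t`, `htd_id`, `group_id`, `y`, optionally `parity`)
#'   to the file's column names.
#' @param min_records Animals with `<= min_records` records are removed
#'   (default 5, i.e. keep animals with more than five test-day records).
#' @param domain Optional time domain `c(t_min, t_max)` for validation.
#' @return A [phenotype_table()], with attribute `"dropped"`: list with
#'   `missing_y` and `few_records` counts.
#' @export
read_phenotypes <- function(path,
                            column_map = c(animal_id = "animal_id", t = "t",
                                           htd_id = "htd_id",
                                           group_id = "group_id", y = "y"),
                            min_records = 5L, domain = NULL) {
  df <- data.table::fread(path, data.table = FALSE)
  if (!nrow(df)) stop("phenotype file is empty: ", path)
  miss <- setdiff(unname(column_map), names(df))
  if (length(miss))
    stop("phenotype file lacks mapped column(s): ", paste(miss, collapse = ", "))
  out <- df[, unname(column_map), drop = FALSE]
  names(out) <- names(column_map)
  n_missing_y <- sum(is.na(out$y))
  if (n_missing_y) {
    message(n_missing_y, " record(s) with missing y dropped")
    out <- out[!is.na(out$y), , drop = FALSE]
  }
  cnt <- table(out$animal_id)
  drop_animals <- names(cnt)[cnt <= min_records]
  if (length(drop_animals)) {
    message(length(drop_animals), " animal(s) with <= ", min_records,
            " records removed")
    out <- out[!(out$animal_id %in% drop_animals), , drop = FALSE]
  }
  if (!nrow(out)) stop("no records remain after filtering")
  pt <- phenotype_table(out, domain = domain)
  attr(pt, "dropped") <- list(missing_y = n_missing_y,
                              few_records = length(drop_animals))
  pt
}

# ---- PLINK bed/bim/fam codec -------------------------------------------
# 2-bit SNP-major layout; per SNP ceiling(n/4) bytes, individual i in bit
# pair 2*(i mod 4) of byte floor(i/4): 00 = A1/A1 (code 2), 01 = missing,
# 10 = het (code 1), 11 = A2/A2 (code 0).

bed_pair_to_code <- c(`0` = 2, `1` = NA, `2` = 1, `3` = 0)
code_to_bed_pair <- function(code) {
  out <- integer(length(code))
  out[is.na(code)] <- 1L
  out[!is.na(code) & code == 2] <- 0L
  out[!is.na(code) & code == 1] <- 2L
  out[!is.na(code) & code == 0] <- 3L
  out
}

#' Read genotypes from PLINK bed/bim/fam or a plain-text matrix
#'
#' For a PLINK fileset (pass the path prefix or the `.bed` path), codes
#' count copies of the bim A1 allele and individual ids are taken from the
#' fam file. A plain-text file is whitespace-separated, individuals x
#' SNPs, with a header row of SNP ids (optionally a leading `id` column of
#' individual ids) and `NA` for missing.
#'
#' @param path PLINK prefix, `.bed` path, or text-matrix path.
#' @return A [genotype_matrix()].
#' @export
read_genotypes <- function(path) {
  prefix <- sub("\\.bed$", "", path)
  if (file.exists(paste0(prefix, ".bed"))) {
    return(read_plink(prefix))
  }
  if (!file.exists(path)) stop("no such genotype file: ", path)
  df <- data.table::fread(path, data.table = FALSE, header = TRUE)
  first_ids <- !is.numeric(df[[1L]]) || names(df)[1L] %in% c("id", "individual_id")
  if (first_ids) {
    ids <- as.character(df[[1L]])
    df <- df[, -1L, drop = FALSE]
  } else {
    ids <- paste0("ind", seq_len(nrow(df)))
  }
  genotype_matrix(as.matrix(df), individual_ids = ids,
                  snp_meta = data.frame(id = names(df), chromosome = "1",
                                        position = seq_along(df),
                                        allele1 = "A", allele2 = "B",
                                        stringsAsFactors = FALSE))
}

read_plink <- function(prefix) {
  bed_path <- paste0(prefix, ".bed")
  bim_path <- paste0(prefix, ".bim")
  fam_path <- paste0(prefix, ".fam")
  for (f in c(bed_path, bim_path, fam_path))
    if (!file.exists(f)) stop("missing PLINK file: ", f)
  bim <- data.table::fread(bim_path, data.table = FALSE, header = FALSE)
  names(bim)[1:6] <- c("chromosome", "id", "cm", "position", "allele1", "allele2")
  fam <- data.table::fread(fam_path, data.table = FALSE, header = FALSE)
  n_ind <- nrow(fam); n_snp <- nrow(bim)
  raw <- readBin(bed_path, what = "raw", n = file.size(bed_path))
  if (length(raw) < 3L || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b))
    stop("not a PLINK bed file (bad magic number): ", bed_path)
  if (raw[3] != as.raw(0x01))
    stop("only SNP-major bed files are supported: ", bed_path)
  bps <- ceiling(n_ind / 4)
  if (length(raw) - 3L != bps * n_snp)
    stop(sprintf("bed payload is %d bytes but %d SNPs x %d individuals need %d",
                 length(raw) - 3L, n_snp, n_ind, bps * n_snp))
  body <- as.integer(raw[-(1:3)])
  # unpack the four 2-bit pairs of every byte at once
  pairs <- rbind(bitwAnd(body, 3L), bitwAnd(bitwShiftR(body, 2L), 3L),
                 bitwAnd(bitwShiftR(body, 4L), 3L), bitwAnd(bitwShiftR(body, 6L), 3L))
  dim(pairs) <- c(4L * bps, n_snp)
  codes <- matrix(bed_pair_to_code[pairs[seq_len(n_ind), , drop = FALSE] + 1L],
                  n_ind, n_snp)
  genotype_matrix(codes, snp_meta = bim[, c("id", "chromosome", "position",
                                            "allele1", "allele2")],
                  individual_ids = as.character(fam[[2L]]))
}

#' Write genotypes as a PLINK bed/bim/fam fileset
#'
#' @param geno A [genotype_matrix()].
#' @param prefix Output path prefix.
#' @return `prefix`, invisibly.
#' @export
write_plink <- function(geno, prefix) {
  n_ind <- nrow(geno$codes); n_snp <- ncol(geno$codes)
  bps <- ceiling(n_ind / 4)
  pairs <- matrix(1L, 4L * bps, n_snp)  # pad with "missing"
  pairs[seq_len(n_ind), ] <- code_to_bed_pair(geno$codes)
  bytes <- pairs[c(TRUE, FALSE, FALSE, FALSE), , drop = FALSE] +
    bitwShiftL(pairs[c(FALSE, TRUE, FALSE, FALSE), , drop = FALSE], 2L) +
    bitwShiftL(pairs[c(FALSE, FALSE, TRUE, FALSE), , drop = FALSE], 4L) +
    bitwShiftL(pairs[c(FALSE, FALSE, FALSE, TRUE), , drop = FALSE], 6L)
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(as.raw(bytes), con)
  meta <- geno$snp_meta
  bim <- data.frame(meta$chromosome, meta$id, 0, meta$position,
                    meta$allele1, meta$allele2)
  data.table::fwrite(bim, paste0(prefix, ".bim"), sep = "\t",
                     col.names = FALSE)
  fam <- data.frame(geno$individual_ids, geno$individual_ids, 0, 0, 0, -9)
  data.table::fwrite(fam, paste0(prefix, ".fam"), sep = "\t",
                     col.names = FALSE)
  invisible(prefix)
}

#' Write genotypes as a plain-text matrix
#'
#' Whitespace-separated individuals x SNPs with a leading `id` column and
#' a header row of SNP ids; missing as NA.
#' @param geno A [genotype_matrix()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_genotypes_text <- function(geno, path) {
  df <- data.frame(id = geno$individual_ids, geno$codes,
                   check.names = FALSE, stringsAsFactors = FALSE)
  data.table::fwrite(df, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

output_header <- function(config_hash, seed) {
  c(sprintf("# rrgwas %s", as.character(utils::packageVersion("rrgwas"))),
    sprintf("# config_hash: %s", config_hash),
    sprintf("# seed: %s", seed))
}

write_tsv_with_header <- function(df, path, config_hash, seed) {
  writeLines(output_header(config_hash, seed), path)
  suppressWarnings(
    data.table::fwrite(df, path, sep = "\t", append = TRUE,
                       col.names = TRUE, quote = FALSE))
  invisible(path)
}

#' Run the full longitudinal GWAS pipeline
#'
#' Orchestrates QC -> allele frequencies -> VanRaden kinship -> variance
#' components (REML, or read from file: rerunning with an existing
#' variance file skips estimation) -> covariance build -> one eigen
#' rotation -> genome scan -> LD pruning -> Bonferroni threshold ->
#' result files. Every output carries a header comment with the package
#' version, a hash of the configuration and the seed.
#'
#' @param config Path to a YAML file or an equivalent named list with
#'   entries: `pheno` (path, or a `phenotype_table`), `geno` (PLINK
#'   prefix / text path, or a `genotype_matrix`), `out` (output
#'   directory); optional `vc_file` (read components; written there after
#'   estimation when absent), `basis` (list: `family`, `mean_order`,
#'   `snp_order`, `add_order`, `perm_order`, `t_min`, `t_max`,
#'   `normalized`, `wilmink_rate`), `alpha` (0.05), `maf_min` (0.03),
#'   `hwe_p_min` (1e-6), `prune` (list `window`, `step`, `r2_max`),
#'   `min_records` (5), `seed` (1).
#' @return Invisibly, a list with the scan table, threshold, significant
#'   SNP ids, variance components and file paths.
#' @export
run_gwas <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg_hash <- substr(digest_config(config), 1, 12)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  set.seed(seed)
  out_dir <- config$out
  if (is.null(out_dir)) stop("config must name an output directory `out`")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  log_lines <- c(output_header(cfg_hash, seed),
                 sprintf("# started: %s", format(Sys.time())))
  log_add <- function(...) {
    msg <- sprintf(...)
    message(msg)
    log_lines <<- c(log_lines, msg)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  bs <- config$basis
  getd <- function(x, d) if (is.null(x)) d else x
  family <- getd(bs$family, "legendre")
  dom_min <- getd(bs$t_min, 5); dom_max <- getd(bs$t_max, 305)
  normalized <- getd(bs$normalized, TRUE)
  wrate <- getd(bs$wilmink_rate, 0.05)
  mk_spec <- function(order) basis_spec(family, order, dom_min, dom_max,
                                        normalized, wrate)
  mean_spec <- mk_spec(getd(bs$mean_order, 2))
  snp_spec <- mk_spec(getd(bs$snp_order, 2))
  add_spec <- mk_spec(getd(bs$add_order, 2))
  perm_spec <- mk_spec(getd(bs$perm_order, 2))

  pheno <- stage("phenotypes", {
    if (inherits(config$pheno, "phenotype_table")) config$pheno
    else read_phenotypes(config$pheno,
                         min_records = getd(config$min_records, 5L),
                         domain = c(dom_min, dom_max))
  })
  log_add("phenotypes: %d records, %d animals", nrow(pheno),
          length(unique(pheno$animal_id)))

  geno <- stage("genotypes", {
    if (inherits(config$geno, "genotype_matrix")) config$geno
    else read_genotypes(config$geno)
  })
  log_add("genotypes: %d individuals x %d SNPs", nrow(geno$codes),
          ncol(geno$codes))

  geno <- stage("qc", filter_snps(geno, getd(config$maf_min, 0.03),
                                  getd(config$hwe_p_min, 1e-6)))
  rep_qc <- attr(geno, "filter_report")
  log_add("qc: %d SNPs removed (%d MAF, %d HWE), %d retained",
          nrow(rep_qc), sum(rep_qc$reason == "MAF"),
          sum(rep_qc$reason == "HWE"), ncol(geno$codes))
  write_tsv_with_header(rep_qc, file.path(out_dir, "filter_report.tsv"),
                        cfg_hash, seed)

  # records of animals missing from the genotype panel are excluded
  in_panel <- pheno$animal_id %in% geno$individual_ids
  if (any(!in_panel)) {
    log_add("excluded %d record(s) of %d ungenotyped animal(s)",
            sum(!in_panel), length(unique(pheno$animal_id[!in_panel])))
    pheno <- phenotype_table(pheno[in_panel, , drop = FALSE])
  }

  freqs <- stage("frequencies", allele_frequencies(geno))
  K <- stage("kinship", vanraden_kinship(geno, freqs))
  log_add("kinship: mean diagonal %.3f", mean(diag(K$values)))

  vc <- stage("variance components", {
    if (!is.null(config$vc_file) && file.exists(config$vc_file)) {
      log_add("variance components read from %s", config$vc_file)
      read_varcomp(config$vc_file, add_order = add_spec$order,
                   perm_order = perm_spec$order)
    } else {
      v <- reml_estimate(pheno, K, mean_spec, add_spec, perm_spec)
      conv <- attr(v, "convergence")
      log_add("REML: %d iterations, logL %.4f, converged: %s",
              conv$iterations, conv$final_logl, conv$converged)
      if (!is.null(config$vc_file)) write_varcomp(v, config$vc_file)
      v
    }
  })

  design <- stage("design", build_design(pheno, geno$individual_ids,
                                         mean_spec, add_spec, perm_spec))
  W <- stage("covariance", build_covariance_W(design, K, vc))
  rot <- stage("rotation", rotate_system(W, design, vc$sigma2_e, snp_spec))
  scan <- stage("scan", scan_snps(rot, geno, freqs))

  pruned <- stage("prune", {
    pr <- getd(config$prune, list())
    ld_prune(geno, getd(pr$window, 50L), getd(pr$step, 5L),
             getd(pr$r2_max, 0.5))
  })
  m_eff <- length(pruned)
  alpha <- getd(config$alpha, 0.05)
  threshold <- bonferroni_threshold(alpha, m_eff)
  log_add("prune: %d SNPs retained; threshold %.4g = %.3g/%d",
          m_eff, threshold, alpha, m_eff)

  sig <- scan$snp_id[!is.na(scan$p_value) & scan$p_value < threshold]
  log_add("significant: %d SNP(s) at the Bonferroni threshold", length(sig))

  curves <- variance_curves(vc, add_spec, perm_spec,
                            seq(dom_min, dom_max, by = 5))

  paths <- list(scan = file.path(out_dir, "scan.tsv"),
                significant = file.path(out_dir, "significant.tsv"),
                threshold = file.path(out_dir, "threshold.txt"),
                curves = file.path(out_dir, "variance_curves.tsv"),
                log = log_path)
  write_tsv_with_header(scan, paths$scan, cfg_hash, seed)
  write_tsv_with_header(scan[scan$snp_id %in% sig, , drop = FALSE],
                        paths$significant, cfg_hash, seed)
  writeLines(c(output_header(cfg_hash, seed),
               sprintf("alpha\t%g", alpha), sprintf("m_eff\t%d", m_eff),
               sprintf("threshold\t%.6g", threshold)), paths$threshold)
  write_tsv_with_header(curves, paths$curves, cfg_hash, seed)
  log_lines <- c(log_lines, sprintf("# finished: %s", format(Sys.time())))
  writeLines(log_lines, log_path)

  invisible(list(scan = scan, threshold = threshold, m_eff = m_eff,
                 significant = sig, vc = vc, curves = curves,
                 paths = paths))
}

digest_config <- function(config) {
  # order-independent content hash without external digest packages
  canon <- function(x) {
    if (inherits(x, c("phenotype_table", "genotype_matrix", "basis_spec",
                      "variance_components"))) {
      paste0("<object:", class(x)[1], ":", format(object.size(x)), ">")
    } else if (is.list(x)) {
      if (!is.null(names(x))) x <- x[order(names(x))]
      paste0("{", paste(names(x), vapply(x, canon, character(1)),
                        sep = "=", collapse = ";"), "}")
    } else {
      paste(format(x, digits = 15), collapse = ",")
    }
  }
  s <- canon(config)
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}
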