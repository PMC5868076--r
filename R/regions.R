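#' Genomic interval set for region-enrichment tests
#'
#' A set of non-overlapping genomic intervals (e.g. published QTL regions)
#' together with the total genome size, used to ask whether significant
#' SNPs concentrate inside the regions. Coordinates are 1-based inclusive;
#' overlapping or book-ended input intervals are merged with
#' `GenomicRanges::reduce()`.
#'
#' @param chromosome Character vector of chromosome names.
#' @param start,end 1-based inclusive interval bounds, `start <= end`.
#' @param genome_size Total genome length in bp (must exceed the summed
#'   region length).
#' @return An object of class `interval_set` with elements `ranges` (a
#'   merged `GRanges`) and `genome_size`.
#' @export
interval_set <- function(chromosome, start, end, genome_size) {
  if (length(genome_size) != 1L || !is.finite(genome_size) || genome_size <= 0)
    stop("genome_size must be a positive number of bp")
  if (any(start > end)) stop("interval start > end")
  gr <- GenomicRanges::GRanges(
    seqnames = as.character(chromosome),
    ranges = IRanges::IRanges(start = start, end = end))
  gr <- GenomicRanges::reduce(gr)
  total <- sum(GenomicRanges::width(gr))
  if (total >= genome_size)
    stop("summed region length must be smaller than genome_size")
  structure(list(ranges = gr, genome_size = as.numeric(genome_size)),
            class = "interval_set")
}

#' @export
print.interval_set <- function(x, ...) {
  cat(sprintf("<interval_set> %d merged interval(s), %.0f of %.0f bp (%.2f%%)\n",
              length(x$ranges), sum(GenomicRanges::width(x$ranges)),
              x$genome_size,
              100 * sum(GenomicRanges::width(x$ranges)) / x$genome_size))
  invisible(x)
}

#' Read a BED3 file of regions
#'
#' BED intervals are 0-based half-open; import converts them to 1-based
#' inclusive, so a SNP at bp x is inside a BED record `(start, end)` iff
#' `start + 1 <= x <= end`.
#'
#' @param path Path to a 3+ column BED file (no header).
#' @param genome_size Total genome size in bp.
#' @return An [interval_set()].
#' @export
read_bed_regions <- function(path, genome_size) {
  gr <- rtracklayer::import(path, format = "BED")
  interval_set(as.character(GenomicRanges::seqnames(gr)),
               GenomicRanges::start(gr), GenomicRanges::end(gr), genome_size)
}

#' Which SNP positions fall inside an interval set
#' @param chromosome,position Parallel vectors of SNP coordinates (1-based).
#' @param regions An [interval_set()].
#' @return Logical vector.
#' @export
in_regions <- function(chromosome, position, regions) {
  stopifnot(inherits(regions, "interval_set"))
  snps <- GenomicRanges::GRanges(
    seqnames = as.character(chromosome),
    ranges = IRanges::IRanges(start = position, width = 1L))
  GenomicRanges::countOverlaps(snps, regions$ranges) > 0L
}

#' Region-enrichment coefficient for significant SNPs
#'
#' Density ratio of significant SNPs inside versus outside the regions:
#' \deqn{(n_{in}/L_{in}) / (n_{out}/L_{out})}
#' with \eqn{L_{in}} the summed region length and
#' \eqn{L_{out} = genome\_size - L_{in}}. Under uniform placement the
#' coefficient is 1; it is `Inf` when all significant SNPs fall inside.
#' Also reports the count expected inside by chance,
#' `n_sig_total * L_in / genome_size`.
#'
#' @param snp_positions `data.frame` (or list) with `chromosome` and
#'   `position` for every tested SNP.
#' @param significant_flags Logical vector flagging the significant SNPs.
#' @param regions An [interval_set()].
#' @return List with `coefficient`, `expected_in_regions_by_chance`,
#'   `n_sig_in`, `n_sig_out`, `region_fraction`.
#' @export
enrichment_coefficient <- function(snp_positions, significant_flags, regions) {
  stopifnot(inherits(regions, "interval_set"))
  chromosome <- snp_positions$chromosome
  position <- snp_positions$position
  if (length(significant_flags) != length(position))
    stop("significant_flags length does not match the number of SNPs")
  L_in <- sum(GenomicRanges::width(regions$ranges))
  L_out <- regions$genome_size - L_in
  sig <- which(significant_flags)
  inside <- in_regions(chromosome[sig], position[sig], regions)
  n_in <- sum(inside); n_out <- length(sig) - n_in
  coef <- if (n_out == 0 && n_in > 0) Inf
          else if (n_in == 0 && n_out == 0) NA_real_
          else (n_in / L_in) / (n_out / L_out)
  list(coefficient = coef,
       expected_in_regions_by_chance = length(sig) * L_in / regions$genome_size,
       n_sig_in = n_in, n_sig_out = n_out,
       region_fraction = L_in / regions$genome_size)
}
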