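# Per-genotype depth summaries, genome-equivalent coverage, and
# genome-binned MCP/MRD/SNP-density statistics over the concatenated
# reference coordinate system.

#' Summarise mapped read depth for one genotype
#'
#' Mean and standard deviation are computed over covered positions only
#' (depth >= 1); positions absent from the stream are uncovered. The
#' standard deviation is the population form (divide by n), so the
#' maximum-depth cutoff mean + 2*sd is a reproducible descriptive bound.
#'
#' @param observations site observations as returned by [read_pileup()]
#' @param genotype_id optional label; defaults to the genotype recorded in
#'   the observations
#' @return one-row data.frame with `genotype`, `mean_depth`, `sd_depth`,
#'   `max_depth_cutoff` (mean + 2*sd) and `n_covered` (positions with
#'   depth >= 1). An empty stream yields `n_covered` 0 and `NA` moments.
#' @export
depth_summary <- function(observations, genotype_id = NULL) {
  if (is.null(genotype_id)) {
    genotype_id <- if (nrow(observations)) observations$genotype[1] else "sample"
  }
  d <- observations$depth[observations$depth >= 1L]
  n <- length(d)
  if (n == 0L) {
    return(data.frame(genotype = genotype_id, mean_depth = NA_real_,
                      sd_depth = NA_real_, max_depth_cutoff = NA_real_,
                      n_covered = 0L, stringsAsFactors = FALSE))
  }
  m <- mean(d)
  s <- sqrt(mean((d - m)^2))
  data.frame(genotype = genotype_id, mean_depth = m, sd_depth = s,
             max_depth_cutoff = m + 2 * s, n_covered = n,
             stringsAsFactors = FALSE)
}

#' Sequence coverage in genome equivalents
#'
#' Total sequenced bases divided by the (estimated) genome size. The genome
#' size default is the 370 Mbp estimated flax genome; note this is distinct
#' from the length of the loaded reference assembly used as the MCP
#' denominator.
#'
#' @param total_bases total read length in bp
#' @param genome_size genome size in bp
#' @return coverage X as a plain ratio
#' @export
genome_equivalents <- function(total_bases, genome_size = 370e6) {
  if (any(genome_size <= 0)) stop("genome_size must be positive")
  total_bases / genome_size
}

#' Percentage of reads mapped
#' @param n_mapped mapped read count
#' @param n_total total read count
#' @return percentage (0-100)
#' @export
mapping_percentage <- function(n_mapped, n_total) {
  if (any(n_total <= 0)) stop("n_total must be positive")
  100 * n_mapped / n_total
}

# Shared bin scaffold: index, concatenated-coordinate span, true width
# (the last bin may be shorter and is never padded).
bin_frame <- function(reference, bin_size) {
  stopifnot(bin_size >= 1)
  n_bins <- ceiling(reference$total_length / bin_size)
  start <- (seq_len(n_bins) - 1) * bin_size
  end <- pmin(start + bin_size, reference$total_length)
  data.frame(bin_index = seq_len(n_bins) - 1L, start = start, end = end,
             width = end - start)
}

#' Genome-binned coverage statistics (MCP and MRD)
#'
#' Every reference position belongs to exactly one fixed-width bin of the
#' concatenated coordinate system. MCP is the percentage of bin positions
#' covered by at least one read; MRD is the mean depth over covered
#' positions only. A bin with no coverage reports `mrd` 0 with
#' `covered = FALSE`.
#'
#' @param observations site observations for one genotype
#' @param reference a [ref_genome()]
#' @param bin_size bin width in bp (default 0.5 Mbp)
#' @return data.frame with `bin_index`, `start`, `end`, `width`, `mcp`,
#'   `mrd`, `covered`, `n_covered`
#' @export
bin_coverage <- function(observations, reference, bin_size = 500000) {
  bins <- bin_frame(reference, bin_size)
  obs <- observations[observations$depth >= 1L, , drop = FALSE]
  n_cov <- integer(nrow(bins))
  depth_sum <- numeric(nrow(bins))
  if (nrow(obs)) {
    coord <- concat_coord(reference, obs$contig, obs$pos)
    b <- coord %/% bin_size + 1L
    agg_n <- tapply(rep(1L, length(b)), b, sum)
    agg_d <- tapply(obs$depth, b, sum)
    idx <- as.integer(names(agg_n))
    n_cov[idx] <- agg_n
    depth_sum[idx] <- agg_d
  }
  bins$mcp <- 100 * n_cov / bins$width
  bins$mrd <- ifelse(n_cov > 0, depth_sum / n_cov, 0)
  bins$covered <- n_cov > 0
  bins$n_covered <- n_cov
  bins
}

#' Genome-binned SNP counts
#'
#' @param snps data.frame with `contig` and `pos` (1-based, contig-local)
#' @param reference a [ref_genome()]
#' @param bin_size bin width in bp
#' @return data.frame with `bin_index`, `start`, `end`, `width`, `snp_count`;
#'   counts sum to `nrow(snps)`
#' @export
bin_snp_density <- function(snps, reference, bin_size = 500000) {
  bins <- bin_frame(reference, bin_size)
  counts <- integer(nrow(bins))
  if (nrow(snps)) {
    coord <- concat_coord(reference, snps$contig, snps$pos)
    tab <- table(coord %/% bin_size + 1L)
    counts[as.integer(names(tab))] <- as.integer(tab)
  }
  bins$snp_count <- counts
  bins
}

#' Write a combined bin table as TSV
#'
#' @param coverage_bins output of [bin_coverage()]
#' @param snp_bins optional output of [bin_snp_density()] on the same
#'   reference and bin size
#' @param path output path
#' @export
write_bin_table <- function(coverage_bins, snp_bins = NULL, path) {
  out <- coverage_bins
  if (!is.null(snp_bins)) out$snp_count <- snp_bins$snp_count
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
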