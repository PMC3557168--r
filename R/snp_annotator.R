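# Characterization of a filtered SNP set: substitution classes,
# genic/intergenic/CDS partition, cross-genotype sharing, and
# discovery-rate summaries.

#' Classify a substitution as transition or transversion
#'
#' Transitions are the purine<->purine and pyrimidine<->pyrimidine changes
#' (A<->G, C<->T); everything else is a transversion. The classification is
#' symmetric in its arguments. Vectorised.
#'
#' @param ref_allele,alt_allele bases in A/C/G/T, pairwise distinct
#' @return character vector of `"transition"` / `"transversion"`
#' @export
classify_substitution <- function(ref_allele, alt_allele) {
  ref_allele <- toupper(ref_allele); alt_allele <- toupper(alt_allele)
  ok <- ref_allele %in% c("A", "C", "G", "T") &
    alt_allele %in% c("A", "C", "G", "T")
  if (!all(ok)) stop("alleles must be A/C/G/T")
  if (any(ref_allele == alt_allele)) stop("identical alleles")
  purine <- c(A = TRUE, G = TRUE, C = FALSE, T = FALSE)
  unname(ifelse(purine[ref_allele] == purine[alt_allele],
                "transition", "transversion"))
}

#' Transition/transversion summary from class counts
#'
#' @param transitions,transversions counts
#' @return list with `ratio` (Ts/Tv), `transition_pct` and
#'   `transversion_pct`
#' @export
tstv_summary <- function(transitions, transversions) {
  total <- transitions + transversions
  list(ratio = if (transversions > 0) transitions / transversions else NA_real_,
       transition_pct = if (total > 0) 100 * transitions / total else NA_real_,
       transversion_pct = if (total > 0) 100 * transversions / total else NA_real_)
}

# Per-contig sorted interval unions for gene and CDS spans.
region_index <- function(models) {
  list(
    gene = lapply(split(models$genes, models$genes$contig),
                  function(d) interval_union(d$start, d$end)),
    cds = lapply(split(models$cds, models$cds$contig),
                 function(d) interval_union(d$start, d$end))
  )
}

#' Annotate SNPs with region class and CDS flag
#'
#' A SNP is genic iff its position falls inside any gene interval and
#' carries `cds_flag` iff it falls inside any CDS interval; containment is
#' evaluated on 0-based half-open intervals, so a SNP at the exclusive end
#' coordinate of a gene is intergenic. SNPs on contigs absent from the
#' annotation are intergenic (a warning reports how many).
#'
#' @param snps data.frame with `contig` and `pos` (1-based)
#' @param gene_models a [gene_models()] object, or `NULL` for none
#' @return `snps` with `region_class` (`"genic"`/`"intergenic"`) and
#'   logical `cds_flag` columns
#' @export
annotate_region <- function(snps, gene_models = NULL) {
  n <- nrow(snps)
  snps$region_class <- rep("intergenic", n)
  snps$cds_flag <- rep(FALSE, n)
  if (is.null(gene_models) || n == 0L || nrow(gene_models$genes) == 0L) {
    return(snps)
  }
  idx <- region_index(gene_models)
  pos0 <- snps$pos - 1L
  missing_contig <- 0L
  for (ct in unique(snps$contig)) {
    sel <- snps$contig == ct
    gi <- idx$gene[[ct]]
    if (is.null(gi)) {
      missing_contig <- missing_contig + sum(sel)
      next
    }
    snps$region_class[sel][in_intervals(pos0[sel], gi)] <- "genic"
    ci <- idx$cds[[ct]]
    if (!is.null(ci)) snps$cds_flag[sel] <- in_intervals(pos0[sel], ci)
  }
  if (missing_contig > 0L) {
    warning(missing_contig,
            " SNP(s) on contigs absent from the annotation; left intergenic")
  }
  snps
}

#' Cross-genotype sharing histogram
#'
#' @param snps data.frame with an `n_genotypes` column (presence-set size)
#' @param n_genotypes number of genotypes screened (histogram support 1..n)
#' @return integer vector `h` with `h[k]` = number of SNPs present in
#'   exactly `k` genotypes; sums to `nrow(snps)`
#' @export
sharing_profile <- function(snps, n_genotypes) {
  stopifnot(n_genotypes >= 1L)
  k <- snps$n_genotypes
  if (length(k) && any(k < 1L | k > n_genotypes)) {
    stop("presence-set size outside 1..n_genotypes")
  }
  h <- tabulate(k, nbins = n_genotypes)
  stats::setNames(h, as.character(seq_len(n_genotypes)))
}

#' Number of single-genotype SNPs from totals
#' @param total_snps total SNP count
#' @param shared_snps SNPs detected in two or more genotypes
#' @return singleton count
#' @export
singleton_count <- function(total_snps, shared_snps) {
  if (shared_snps > total_snps) stop("shared count exceeds total")
  total_snps - shared_snps
}

#' SNP discovery rate for a region
#'
#' @param snp_count SNPs in the region
#' @param region_length_bp region length (> 0)
#' @return list with `snps_per_kbp` and `bp_per_snp` (`NA` when
#'   `snp_count` is 0)
#' @export
snp_rate <- function(snp_count, region_length_bp) {
  if (any(region_length_bp <= 0)) stop("region length must be positive")
  list(snps_per_kbp = 1000 * snp_count / region_length_bp,
       bp_per_snp = if (snp_count > 0) region_length_bp / snp_count else NA_real_)
}

#' Characterize a SNP set
#'
#' Assembles substitution classes, region partition, sharing histogram,
#' rates, and a per-genotype breakdown (identified / intergenic / genic /
#' CDS). Multi-allelic records (different alternate alleles in different
#' genotypes) are classified by the first genotype's allele and counted.
#' Rate denominators are measured from the loaded reference and the union
#' of the supplied gene intervals (overlapping genes unioned first).
#'
#' @param snps merged SNP records (see [discover_snps()]), with `n_genotypes`
#'   and `alts` columns
#' @param gene_models a [gene_models()] object or `NULL`
#' @param reference a [ref_genome()]
#' @param n_genotypes number of genotypes screened; defaults to the number
#'   of distinct genotype ids seen in `snps`
#' @param partition_lengths optional list with `whole`, `genic`,
#'   `intergenic` lengths in bp overriding the measured denominators
#' @return an object of class `snp_report`; also carries the annotated SNP
#'   frame as `$snps`
#' @export
characterize <- function(snps, gene_models = NULL, reference,
                         n_genotypes = NULL, partition_lengths = NULL) {
  snps <- annotate_region(snps, gene_models)
  total <- nrow(snps)
  gt_sets <- strsplit(snps$genotypes, ",")
  if (is.null(snps$n_genotypes)) {
    snps$n_genotypes <- lengths(gt_sets)   # tables omit the derived column
  }
  if (is.null(n_genotypes)) {
    n_genotypes <- max(1L, length(unique(unlist(gt_sets))))
  }
  if (total > 0L) {
    snps$substitution_class <- classify_substitution(snps$ref, snps$alt)
  } else {
    snps$substitution_class <- character(0)
  }
  ts <- sum(snps$substitution_class == "transition")
  tv <- sum(snps$substitution_class == "transversion")
  genic <- sum(snps$region_class == "genic")
  cds <- sum(snps$cds_flag)
  multi <- if (total > 0L) {
    sum(vapply(strsplit(snps$alts, ","), function(p) {
      length(unique(sub("^.*:", "", p))) > 1L
    }, logical(1)))
  } else 0L

  whole_len <- reference$total_length
  genic_len <- 0
  if (!is.null(gene_models) && nrow(gene_models$genes)) {
    genic_len <- sum(vapply(region_index(gene_models)$gene,
                            function(u) sum(u$end - u$start), numeric(1)))
  }
  if (!is.null(partition_lengths)) {
    whole_len <- partition_lengths$whole %||% whole_len
    genic_len <- partition_lengths$genic %||% genic_len
  }
  intergenic_len <- whole_len - genic_len

  per_genotype <- NULL
  ids <- unique(unlist(gt_sets))
  if (length(ids)) {
    per_genotype <- do.call(rbind, lapply(ids, function(g) {
      sel <- vapply(gt_sets, function(s) g %in% s, logical(1))
      data.frame(genotype = g, identified = sum(sel),
                 intergenic = sum(sel & snps$region_class == "intergenic"),
                 genic = sum(sel & snps$region_class == "genic"),
                 cds = sum(sel & snps$cds_flag), stringsAsFactors = FALSE)
    }))
  }

  structure(list(
    total_snps = total,
    transitions = ts, transversions = tv,
    tstv = tstv_summary(ts, tv),
    genic = genic, intergenic = total - genic, cds = cds,
    cds_pct = if (total > 0) 100 * cds / total else NA_real_,
    genic_pct = if (total > 0) 100 * genic / total else NA_real_,
    multi_allelic = multi,
    sharing = sharing_profile(snps, n_genotypes),
    n_genotypes = n_genotypes,
    lengths = list(whole = whole_len, genic = genic_len,
                   intergenic = intergenic_len),
    rate_whole = snp_rate(total, whole_len),
    rate_genic = if (genic_len > 0) snp_rate(genic, genic_len) else NULL,
    rate_intergenic = if (intergenic_len > 0) {
      snp_rate(total - genic, intergenic_len)
    } else NULL,
    per_genotype = per_genotype,
    snps = snps
  ), class = "snp_report")
}

#' @export
print.snp_report <- function(x, ...) {
  cat(sprintf("<snp_report> %d SNPs across %d genotype(s)\n",
              x$total_snps, x$n_genotypes))
  if (x$total_snps > 0) {
    cat(sprintf("  transitions %d (%.1f%%), transversions %d (Ts/Tv %.2f)\n",
                x$transitions, x$tstv$transition_pct, x$transversions,
                x$tstv$ratio))
    cat(sprintf("  genic %d (%.1f%%), intergenic %d, CDS %d (%.1f%%)\n",
                x$genic, x$genic_pct, x$intergenic, x$cds, x$cds_pct))
    cat(sprintf("  rate %.3g SNPs/Kbp over %s bp\n",
                x$rate_whole$snps_per_kbp,
                format(x$lengths$whole, big.mark = ",")))
    cat("  sharing histogram:",
        paste(sprintf("k=%s:%d", names(x$sharing), x$sharing), collapse = " "),
        "\n")
  }
  invisible(x)
}

#' Serialize a characterization report to JSON
#' @param report a `snp_report`
#' @param path output path
#' @export
write_report_json <- function(report, path) {
  keep <- report[setdiff(names(report), "snps")]
  keep$sharing <- as.list(keep$sharing)
  jsonlite::write_json(keep, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
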