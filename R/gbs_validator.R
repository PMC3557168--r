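# Validation of candidate SNPs by segregation in a recombinant inbred line
# (RIL) population genotyped by sequencing. RIL alleles are called with the
# same depth/ratio/quality criteria as discovery; each candidate locus is
# then classified as validated (both parental alleles segregate), non-
# validated (a quorum of informative lines shows no segregation) or
# ineligible (insufficient informative calls).

#' Call one RIL's allele at one locus
#'
#' The consensus base is accepted as the line's allele when the site meets
#' the caller thresholds (depth, consensus ratio, quality); otherwise the
#' call is missing. The allele may equal the reference base — that is a
#' valid parental call. Residual heterozygous sites fail the ratio
#' criterion and so yield missing calls, consistent with the
#' homozygous-call model for inbred lines.
#'
#' @param site a one-row site observation for the RIL at the locus
#' @param config a [caller_config()]
#' @return single character allele, or `NA` when no confident call
#' @export
call_ril_allele <- function(site, config = caller_config()) {
  stopifnot(nrow(site) == 1L)
  if (!site$ref %in% c("A", "C", "G", "T")) return(NA_character_)
  n_calls <- nchar(site$calls)
  if (n_calls == 0L) return(NA_character_)
  counts <- base_count_matrix(site$calls)[1, ]
  top <- max(counts)
  if (sum(counts == top) > 1L || top == 0L) return(NA_character_)
  allele <- names(counts)[which.max(counts)]
  if (site$depth < config$min_depth) return(NA_character_)
  if (top / n_calls < config$min_consensus_ratio) return(NA_character_)
  cc <- strsplit(site$calls, "", fixed = TRUE)[[1]]
  qq <- phred_ints(site$quals)
  if (mean(qq[cc == allele]) < config$min_quality) return(NA_character_)
  allele
}

#' Build a RIL call matrix from per-line pileups
#'
#' @param ril_pileups named list (one element per RIL) of site-observation
#'   frames or pileup file paths
#' @param loci data.frame with `contig` and `pos` of the candidate loci
#' @param config a [caller_config()]
#' @return character matrix, rows = loci (named `contig:pos`), columns =
#'   RILs; cells are alleles or `NA`
#' @export
ril_call_matrix <- function(ril_pileups, loci, config = caller_config()) {
  stopifnot(!is.null(names(ril_pileups)))
  keys <- paste0(loci$contig, ":", loci$pos)
  m <- matrix(NA_character_, nrow = nrow(loci), ncol = length(ril_pileups),
              dimnames = list(keys, names(ril_pileups)))
  for (r in names(ril_pileups)) {
    obs <- ril_pileups[[r]]
    if (is.character(obs)) obs <- read_pileup(obs, r)
    idx <- match(paste0(obs$contig, ":", obs$pos), keys)
    hit <- which(!is.na(idx))
    for (i in hit) {
      m[idx[i], r] <- call_ril_allele(obs[i, , drop = FALSE], config)
    }
  }
  m
}

#' Classify one candidate locus from RIL allele calls
#'
#' A locus is *validated* when each parental allele is carried by at least
#' `min_minor_lines` RILs (segregation is direct evidence, so no quorum is
#' required); *non-validated* when at least `floor(eligibility_fraction *
#' n_rils_total)` lines are called but only one parental allele reaches
#' `min_minor_lines` (the population does not segregate); and *ineligible*
#' otherwise. Alleles matching neither parent are tallied separately and
#' excluded from the parental counts.
#'
#' @param ril_alleles character vector of per-RIL alleles (`NA`/`"-"` =
#'   missing)
#' @param n_rils_total population size
#' @param parent_alleles length-2 character vector (reference-parent
#'   allele, alternate-parent allele); must be distinct
#' @param eligibility_fraction informative-call quorum for the
#'   non-segregating branch (default 0.9, i.e. 86 of 96 lines)
#' @param min_minor_lines minimum RILs carrying an allele for it to count
#'   as observed (default 2, so a single discordant line is treated as an
#'   artifact)
#' @return list with `status` (`"validated"` / `"non_validated"` /
#'   `"ineligible"`), `n_called`, `n_parent1`, `n_parent2`, `n_other`
#' @export
classify_locus <- function(ril_alleles, n_rils_total,
                           parent_alleles, eligibility_fraction = 0.9,
                           min_minor_lines = 2) {
  stopifnot(length(parent_alleles) == 2L, n_rils_total >= 1L)
  if (parent_alleles[1] == parent_alleles[2]) {
    stop("parental alleles must be distinct")
  }
  a <- ril_alleles
  a[a %in% c("-", "")] <- NA_character_
  called <- !is.na(a)
  n1 <- sum(a[called] == parent_alleles[1])
  n2 <- sum(a[called] == parent_alleles[2])
  n_other <- sum(called) - n1 - n2
  quorum <- floor(eligibility_fraction * n_rils_total)
  seen <- (n1 >= min_minor_lines) + (n2 >= min_minor_lines)
  status <- if (seen == 2L) {
    "validated"
  } else if (sum(called) >= quorum && seen == 1L) {
    "non_validated"
  } else {
    "ineligible"
  }
  list(status = status, n_called = sum(called), n_parent1 = n1,
       n_parent2 = n2, n_other = n_other)
}

#' Validation rate from validated / non-validated counts
#'
#' The rate is over eligible loci only: `100 * v / (v + nv)`.
#'
#' @param n_validated,n_non_validated counts
#' @return percentage, `NA` when no eligible loci
#' @export
validation_rate <- function(n_validated, n_non_validated) {
  eligible <- n_validated + n_non_validated
  if (eligible == 0) return(NA_real_)
  100 * n_validated / eligible
}

#' Validate candidate SNPs against a RIL population
#'
#' @param candidates data.frame with `contig`, `pos`, `ref`, `alt`; the
#'   parental alleles at each locus are (`ref`, `alt`) for a two-parent
#'   comparison where the reference genotype is one parent
#' @param ril_calls character matrix as from [ril_call_matrix()] or
#'   [read_ril_matrix()] (rows `contig:pos`, columns RILs, cells
#'   A/C/G/T/`-`/`NA`), or a named list of per-RIL pileups
#' @param config a [caller_config()] (used when `ril_calls` are pileups)
#' @param eligibility_fraction,min_minor_lines see [classify_locus()]
#' @return an object of class `gbs_validation`: `summary` (counts and
#'   validation rate) and `loci` (per-locus table)
#' @export
validate_snps <- function(candidates, ril_calls, config = caller_config(),
                          eligibility_fraction = 0.9, min_minor_lines = 2) {
  if (is.list(ril_calls) && !is.matrix(ril_calls)) {
    ril_calls <- ril_call_matrix(ril_calls, candidates, config)
  }
  n_rils <- ncol(ril_calls)
  keys <- paste0(candidates$contig, ":", candidates$pos)
  rows <- match(keys, rownames(ril_calls))
  out <- vector("list", nrow(candidates))
  for (i in seq_len(nrow(candidates))) {
    alleles <- if (is.na(rows[i])) rep(NA_character_, n_rils)
               else ril_calls[rows[i], ]
    cl <- classify_locus(alleles, n_rils,
                         c(candidates$ref[i], candidates$alt[i]),
                         eligibility_fraction, min_minor_lines)
    out[[i]] <- data.frame(contig = candidates$contig[i],
                           pos = candidates$pos[i],
                           ref = candidates$ref[i], alt = candidates$alt[i],
                           status = cl$status, n_called = cl$n_called,
                           n_ref_allele = cl$n_parent1,
                           n_alt_allele = cl$n_parent2,
                           n_other = cl$n_other, stringsAsFactors = FALSE)
  }
  loci <- rbind_all(out)
  if (is.null(loci)) {
    loci <- data.frame(contig = character(0), pos = integer(0),
                       ref = character(0), alt = character(0),
                       status = character(0), n_called = integer(0),
                       n_ref_allele = integer(0), n_alt_allele = integer(0),
                       n_other = integer(0), stringsAsFactors = FALSE)
  }
  nv <- sum(loci$status == "validated")
  nn <- sum(loci$status == "non_validated")
  summary <- list(n_candidates = nrow(loci),
                  n_eligible = nv + nn,
                  n_validated = nv,
                  n_non_validated = nn,
                  n_ineligible = sum(loci$status == "ineligible"),
                  validation_rate = validation_rate(nv, nn))
  structure(list(summary = summary, loci = loci, n_rils = n_rils),
            class = "gbs_validation")
}

#' @export
print.gbs_validation <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<gbs_validation> %d candidate loci, %d RILs\n",
              s$n_candidates, x$n_rils))
  cat(sprintf("  validated %d, non-validated %d, ineligible %d\n",
              s$n_validated, s$n_non_validated, s$n_ineligible))
  if (!is.na(s$validation_rate)) {
    cat(sprintf("  validation rate %.1f%% over %d eligible loci\n",
                s$validation_rate, s$n_eligible))
  } else {
    cat("  validation rate undefined (no eligible loci)\n")
  }
  invisible(x)
}

#' Read / write a RIL call matrix
#'
#' The text dialect is a TSV with a `locus` column (`contig:pos`) followed
#' by one column per RIL; cells are A/C/G/T or `-` for missing.
#'
#' @param path file path
#' @return character matrix with locus rownames
#' @export
read_ril_matrix <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d[[1]]
  m[m == "-"] <- NA_character_
  m
}

#' @rdname read_ril_matrix
#' @param calls character matrix (rows = loci, columns = RILs)
#' @export
write_ril_matrix <- function(calls, path) {
  out <- calls
  out[is.na(out)] <- "-"
  d <- data.frame(locus = rownames(out), out, check.names = FALSE,
                  stringsAsFactors = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
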