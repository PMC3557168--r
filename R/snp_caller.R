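# Candidate SNP identification from per-genotype site observations and the
# full filter stack: minimum depth, per-genotype maximum-depth cutoff
# (mean + 2 sd), consensus base ratio, site quality, homopolymer context and
# adjacent-SNP removal. Inbred material is assumed: the ratio filter
# enforces near-fixed alleles and no heterozygous calls are made.

FILTER_FLAGS <- c("low_depth", "high_depth", "low_ratio", "low_quality",
                  "homopolymer", "adjacent")

#' Caller configuration
#'
#' Defaults are the discovery criteria used throughout: minimum mapped read
#' depth 3; maximum depth at each genotype's own mean + 2 sd (`max_depth =
#' NULL`, the "auto" mode) or a fixed value; consensus base ratio >= 0.9;
#' site quality >= 20; homopolymer run length >= 3 for removal; and removal
#' of contiguous candidates separated by a gap < 2 bp.
#'
#' @param min_depth minimum mapped read depth at a site
#' @param max_depth `NULL` for the per-genotype mean + 2 sd cutoff, or a
#'   fixed numeric cutoff
#' @param min_consensus_ratio minimum fraction of calls supporting the
#'   consensus base
#' @param min_quality minimum site quality (Phred scale)
#' @param homopolymer_min_run reference run length at or adjacent to the
#'   site that triggers removal
#' @param min_gap_between_snps minimum gap (intervening bases) between
#'   contiguous candidates; closer pairs are both removed
#' @return a list of class `caller_config`
#' @export
caller_config <- function(min_depth = 3, max_depth = NULL,
                          min_consensus_ratio = 0.9, min_quality = 20,
                          homopolymer_min_run = 3, min_gap_between_snps = 2) {
  stopifnot(min_depth >= 0, min_consensus_ratio >= 0, min_quality >= 0,
            homopolymer_min_run >= 2, min_gap_between_snps >= 0)
  structure(list(min_depth = min_depth, max_depth = max_depth,
                 min_consensus_ratio = min_consensus_ratio,
                 min_quality = min_quality,
                 homopolymer_min_run = homopolymer_min_run,
                 min_gap_between_snps = min_gap_between_snps),
            class = "caller_config")
}

# Vectorised candidate identification over a site-observation frame.
# Returns one row per site whose consensus base differs from the reference
# base: consensus = most frequent base among the calls; ties yield no call;
# sites with a non-ACGT reference base are skipped. The consensus ratio
# denominator is the number of base calls (deletion placeholders already
# excluded at parse time); the depth column keeps the site depth used by
# the depth filters. Quality is the mean Phred base quality of
# consensus-supporting calls, capped by the RMS mapping quality when
# mapping qualities are present.
call_candidates <- function(sites) {
  empty <- data.frame(genotype = character(0), contig = character(0),
                      pos = integer(0), ref = character(0),
                      alt = character(0), depth = integer(0),
                      n_calls = integer(0), ratio = numeric(0),
                      quality = numeric(0), stringsAsFactors = FALSE)
  sites <- sites[sites$ref %in% c("A", "C", "G", "T") & nchar(sites$calls) > 0,
                 , drop = FALSE]
  if (nrow(sites) == 0L) return(empty)
  counts <- base_count_matrix(sites$calls)
  top <- pmax(counts[, 1], counts[, 2], counts[, 3], counts[, 4])
  tied <- rowSums(counts == top) > 1L
  cons <- colnames(counts)[max.col(counts, ties.method = "first")]
  keep <- !tied & top > 0L & cons != sites$ref
  if (!any(keep)) return(empty)
  sites <- sites[keep, , drop = FALSE]
  cons <- cons[keep]
  top <- top[keep]
  n_calls <- nchar(sites$calls)
  quality <- numeric(nrow(sites))
  for (i in seq_len(nrow(sites))) {
    cc <- strsplit(sites$calls[i], "", fixed = TRUE)[[1]]
    qq <- phred_ints(sites$quals[i])
    q <- mean(qq[cc == cons[i]])
    if (!is.na(sites$mapq[i]) && nzchar(sites$mapq[i])) {
      rms <- sqrt(mean(phred_ints(sites$mapq[i])^2))
      q <- min(q, rms)
    }
    quality[i] <- q
  }
  data.frame(genotype = sites$genotype, contig = sites$contig,
             pos = sites$pos, ref = sites$ref, alt = cons,
             depth = sites$depth, n_calls = n_calls,
             ratio = top / n_calls, quality = quality,
             stringsAsFactors = FALSE)
}

#' Identify a candidate SNP at a single site
#'
#' The consensus base is the most frequent base among the calls; a site
#' whose consensus equals the reference base, a tie for the top count, or a
#' non-A/C/G/T reference base yields no candidate.
#'
#' @param site a one-row site observation (see [read_pileup()])
#' @return a one-row candidate data.frame, or `NULL` when no variant is
#'   called
#' @export
call_candidate <- function(site) {
  stopifnot(nrow(site) == 1L)
  out <- call_candidates(site)
  if (nrow(out) == 0L) NULL else out
}

#' Apply the depth, ratio and quality filters to candidates
#'
#' @param candidates candidate frame from [call_candidates()]
#' @param stats per-genotype depth summaries ([depth_summary()] rows); used
#'   for the mean + 2 sd maximum-depth cutoff unless `config$max_depth` is
#'   fixed
#' @param config a [caller_config()]
#' @return the candidates with logical flag columns `low_depth`,
#'   `high_depth`, `low_ratio`, `low_quality`
#' @export
apply_site_filters <- function(candidates, stats, config = caller_config()) {
  n <- nrow(candidates)
  if (is.null(config$max_depth)) {
    i <- match(candidates$genotype, stats$genotype)
    if (anyNA(i) && n > 0L) {
      stop("missing depth stats for genotype: ",
           candidates$genotype[is.na(i)][1])
    }
    cutoff <- stats$max_depth_cutoff[i]
  } else {
    cutoff <- rep(config$max_depth, n)
  }
  candidates$low_depth <- candidates$depth < config$min_depth
  candidates$high_depth <- candidates$depth > cutoff
  candidates$low_ratio <- candidates$ratio < config$min_consensus_ratio
  candidates$low_quality <- candidates$quality < config$min_quality
  candidates
}

# Whole-contig mask: TRUE at positions inside a run of identical bases of
# length >= min_run, or immediately adjacent to one.
contig_homopolymer_mask <- function(sequence, min_run = 3) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  r <- rle(chars)
  mask <- logical(length(chars))
  if (any(r$lengths >= min_run)) {
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$lengths >= min_run)) {
      mask[max(1L, starts[k] - 1L):min(length(chars), ends[k] + 1L)] <- TRUE
    }
  }
  mask
}

# TRUE where the maximal run of identical reference bases containing the
# position, or the run immediately adjacent on either side, has length
# >= min_run. A window of +/- min_run around the position is sufficient to
# decide (a qualifying run always shows at least min_run of its bases
# inside that window).
homopolymer_flag <- function(reference, contig, pos, min_run = 3) {
  n <- length(pos)
  out <- logical(n)
  for (i in seq_len(n)) {
    s <- reference$seq[[contig[i]]]
    if (is.na(s)) stop("unknown contig: ", contig[i])
    len <- reference$lengths[[contig[i]]]
    if (pos[i] < 1L || pos[i] > len) stop("position outside contig")
    w0 <- max(1L, pos[i] - min_run)
    w1 <- min(len, pos[i] + min_run)
    chars <- strsplit(substr(s, w0, w1), "", fixed = TRUE)[[1]]
    r <- rle(chars)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    rel <- pos[i] - w0 + 1L
    k <- which(starts <= rel & ends >= rel)
    hit <- r$lengths[k] >= min_run
    if (!hit && k > 1L) hit <- r$lengths[k - 1L] >= min_run
    if (!hit && k < length(r$lengths)) hit <- r$lengths[k + 1L] >= min_run
    out[i] <- hit
  }
  out
}

#' Flag candidates in or adjacent to reference homopolymer runs
#'
#' A candidate is flagged when the maximal run of identical reference bases
#' that contains the site, or the maximal run immediately abutting it on
#' either side, has length >= `min_run`. Run identity with either allele is
#' not required; the test is on the reference sequence only.
#'
#' @param candidates candidate frame
#' @param reference a [ref_genome()]
#' @param min_run minimum run length that triggers the flag
#' @return candidates with a logical `homopolymer` column
#' @export
filter_homopolymer <- function(candidates, reference, min_run = 3) {
  candidates$homopolymer <- if (nrow(candidates)) {
    homopolymer_flag(reference, candidates$contig, candidates$pos, min_run)
  } else logical(0)
  candidates
}

#' Flag contiguous candidates that are too close together
#'
#' The gap between consecutive same-contig candidates is
#' `pos2 - pos1 - 1`; whenever the gap is below `min_gap` BOTH members of
#' the pair are flagged, so flagging propagates through chains of close
#' candidates. Candidates of one genotype should be supplied together.
#'
#' @param candidates candidate frame, sorted by (contig, pos); unsorted
#'   input is an error
#' @param min_gap minimum intervening bases between kept candidates
#' @return candidates with a logical `adjacent` column
#' @export
filter_adjacent <- function(candidates, min_gap = 2) {
  n <- nrow(candidates)
  flag <- logical(n)
  if (n > 1L) {
    same <- candidates$contig[-1] == candidates$contig[-n]
    d <- candidates$pos[-1] - candidates$pos[-n]
    if (any(same & d <= 0)) stop("candidates must be sorted by (contig, pos)")
    close <- same & (d - 1 < min_gap)
    flag[which(close)] <- TRUE
    flag[which(close) + 1L] <- TRUE
  }
  candidates$adjacent <- flag
  candidates
}

# One genotype through the full stack. Every filter is evaluated
# independently on the complete candidate set (adjacency included), so the
# staged pipeline is equivalent to brute-force per-position evaluation of
# each criterion; a candidate passes iff no flag is set.
filter_genotype <- function(sites, reference, stats, config) {
  cands <- call_candidates(sites)
  o <- order(cands$contig, cands$pos)
  cands <- cands[o, , drop = FALSE]
  cands <- apply_site_filters(cands, stats, config)
  cands <- filter_homopolymer(cands, reference, config$homopolymer_min_run)
  cands <- filter_adjacent(cands, config$min_gap_between_snps)
  cands$pass <- !(cands$low_depth | cands$high_depth | cands$low_ratio |
                    cands$low_quality | cands$homopolymer | cands$adjacent)
  cands
}

#' Discover SNPs across genotypes
#'
#' Runs candidate identification and the full filter stack per genotype,
#' then merges passing candidates across genotypes into records keyed by
#' (contig, position). A record's presence set lists every genotype whose
#' candidate passed; when different genotypes carry different alternate
#' alleles at one location, the record keeps all of them and the first
#' genotype's allele (input order) is the record-level `alt`.
#'
#' @param pileups named list of per-genotype inputs: site-observation
#'   frames from [read_pileup()], or file paths to pileup files
#' @param reference a [ref_genome()]
#' @param config a [caller_config()]
#' @return an object of class `snp_discovery`: list with `snps` (merged
#'   passing records), `candidates` (all candidates with filter flags),
#'   `stats` (per-genotype depth summaries), `filter_counts` (per-genotype
#'   removal tallies) and `config`
#' @export
discover_snps <- function(pileups, reference, config = caller_config()) {
  stopifnot(length(pileups) >= 1L, !is.null(names(pileups)))
  genotype_ids <- names(pileups)
  all_cands <- list()
  all_stats <- list()
  counts <- list()
  for (g in genotype_ids) {
    obs <- pileups[[g]]
    if (is.character(obs)) obs <- read_pileup(obs, g)
    if (nrow(obs) == 0L) {
      warning("genotype ", g, " has no observations; excluded")
      next
    }
    st <- depth_summary(obs, g)
    cands <- filter_genotype(obs, reference, st, config)
    all_stats[[g]] <- st
    all_cands[[g]] <- cands
    counts[[g]] <- data.frame(
      genotype = g, n_sites = nrow(obs), n_candidates = nrow(cands),
      low_depth = sum(cands$low_depth), high_depth = sum(cands$high_depth),
      low_ratio = sum(cands$low_ratio), low_quality = sum(cands$low_quality),
      homopolymer = sum(cands$homopolymer), adjacent = sum(cands$adjacent),
      n_pass = sum(cands$pass), stringsAsFactors = FALSE)
  }
  if (length(all_cands) == 0L) stop("no genotype with observations")
  cands <- rbind_all(all_cands)
  pass <- cands[cands$pass, , drop = FALSE]
  snps <- merge_candidates(pass, genotype_ids)
  structure(list(snps = snps, candidates = cands,
                 stats = rbind_all(all_stats),
                 filter_counts = rbind_all(counts),
                 config = config, genotype_ids = intersect(genotype_ids, names(all_cands))),
            class = "snp_discovery")
}

# Merge passing per-genotype candidates into one record per location.
merge_candidates <- function(pass, genotype_order) {
  cols <- c("contig", "pos", "ref", "alt", "genotypes", "n_genotypes",
            "depth", "ratio", "quality", "alts")
  if (nrow(pass) == 0L) {
    out <- data.frame(contig = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      genotypes = character(0), n_genotypes = integer(0),
                      depth = integer(0), ratio = numeric(0),
                      quality = numeric(0), alts = character(0),
                      stringsAsFactors = FALSE)
    return(out)
  }
  pass$genotype <- factor(pass$genotype, levels = genotype_order)
  o <- order(pass$contig, pass$pos, pass$genotype)
  pass <- pass[o, , drop = FALSE]
  key <- paste(pass$contig, pass$pos)
  first <- !duplicated(key)
  idx <- match(key, key[first])
  out <- pass[first, c("contig", "pos", "ref", "alt", "depth", "ratio",
                       "quality"), drop = FALSE]
  out$genotypes <- vapply(split(as.character(pass$genotype), idx),
                          paste, "", collapse = ",")
  out$n_genotypes <- as.integer(tabulate(idx))
  out$alts <- vapply(split(paste0(pass$genotype, ":", pass$alt), idx),
                     paste, "", collapse = ",")
  rownames(out) <- NULL
  out[, cols]
}

#' Per-nucleotide false-positive rate from a reference self-comparison
#'
#' Mismatch sites obtained by running the caller on the reference
#' genotype's own reads are sequencing/mapping errors by construction;
#' their count divided by the reference length estimates the false-positive
#' rate per nucleotide.
#'
#' @param n_sites number of polymorphic sites called in the self-comparison
#' @param reference_length reference length in bp
#' @return rate per nucleotide
#' @export
estimate_false_positive_rate <- function(n_sites, reference_length) {
  if (any(reference_length <= 0)) stop("reference_length must be positive")
  n_sites / reference_length
}

#' @export
print.snp_discovery <- function(x, ...) {
  cat(sprintf("<snp_discovery> %d SNP record(s) from %d genotype(s)\n",
              nrow(x$snps), length(x$genotype_ids)))
  print(x$filter_counts, row.names = FALSE)
  invisible(x)
}
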