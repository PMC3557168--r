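# Synthetic data generator: random references, implanted genotype variants,
# in-silico restriction digests with fragment size selection, site-level
# pileups under a depth/error model, gene models, and RIL populations.
# Every stage draws from a sub-seed derived from one top-level seed, and
# truth sets are returned for downstream benchmarking.

#' Simulation configuration
#'
#' Defaults emulate the study conditions of a reduced-representation
#' survey of inbred flax genotypes: eight genotypes (the first being the
#' reference line itself, carrying no variants), an MseI digest (TTAA,
#' cut one base into the motif) with 350-425 bp size selection, SNP density
#' 1.7e-4 per bp per genotype (0.17 SNPs/Kbp), and a 96-line F6 RIL
#' population (five selfing generations after F1, residual heterozygosity
#' (1/2)^5 = 3.125% per locus).
#'
#' @param genome_length total reference length in bp
#' @param n_contigs number of contigs (lengths split evenly)
#' @param gc_fraction target GC content (0.39, a typical plant nuclear
#'   genome value)
#' @param n_genotypes genotypes including the reference line
#' @param snp_density substitutions per bp implanted per non-reference
#'   genotype
#' @param transition_prob probability an implanted substitution is the
#'   transition partner of the reference base (0.65, the transition excess
#'   typical of plant SNP surveys); the remainder splits evenly between
#'   the two transversions
#' @param enzyme_motif recognition site (default TTAA = MseI)
#' @param cut_offset bases into the motif where the cut falls (T^TAA = 1)
#' @param fragment_size_range inclusive selected fragment lengths in bp
#' @param mean_depth mean site depth inside selected fragments
#' @param depth_dispersion negative-binomial size parameter; `0` gives
#'   constant depth, `Inf` Poisson
#' @param base_error_rate probability a call flips to a uniformly chosen
#'   different base
#' @param base_quality_mean,base_quality_sd Phred base-quality model
#' @param min_spacing minimum distance (bp) between implanted variants of
#'   one genotype; 3 keeps implants clear of the adjacency filter
#' @param avoid_homopolymer avoid implanting in/next to reference runs >= 3
#' @param restrict_to_fragments implant only inside selected fragments so
#'   truth variants are recoverable by design
#' @param n_rils RIL population size
#' @param selfing_generations selfing generations after F1 (F6 = 5)
#' @param ril_call_prob per-cell probability a RIL yields an informative
#'   call at a locus
#' @param seed top-level seed; all stages derive their streams from it
#' @return list of class `sim_config`
#' @export
sim_config <- function(genome_length = 500000, n_contigs = 5,
                       gc_fraction = 0.39, n_genotypes = 8,
                       snp_density = 1.7e-4, transition_prob = 0.65,
                       enzyme_motif = "TTAA",
                       cut_offset = 1, fragment_size_range = c(350, 425),
                       mean_depth = 10, depth_dispersion = 8,
                       base_error_rate = 0.002, base_quality_mean = 30,
                       base_quality_sd = 3, min_spacing = 3,
                       avoid_homopolymer = TRUE,
                       restrict_to_fragments = TRUE,
                       n_rils = 96, selfing_generations = 5,
                       ril_call_prob = 0.95, seed = 1) {
  stopifnot(genome_length >= n_contigs, gc_fraction >= 0, gc_fraction <= 1,
            n_genotypes >= 1, snp_density >= 0, snp_density <= 1,
            transition_prob >= 0, transition_prob <= 1,
            nchar(enzyme_motif) >= 2, cut_offset >= 0,
            cut_offset < nchar(enzyme_motif),
            fragment_size_range[1] <= fragment_size_range[2],
            mean_depth > 0, base_error_rate >= 0, base_error_rate <= 1,
            n_rils >= 1, selfing_generations >= 1,
            ril_call_prob >= 0, ril_call_prob <= 1)
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate a reference genome
#'
#' I.i.d. bases at the configured GC fraction, split into `n_contigs`
#' contigs of (near-)equal length. Reproducible for identical seeds.
#'
#' @param config a [sim_config()]
#' @return a [ref_genome()]
#' @export
simulate_reference <- function(config = sim_config()) {
  with_seed(stage_seed(config$seed, "reference"), {
    gc <- config$gc_fraction
    p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    base_len <- config$genome_length %/% config$n_contigs
    lens <- rep(base_len, config$n_contigs)
    lens[config$n_contigs] <- lens[config$n_contigs] +
      config$genome_length - sum(lens)
    seqs <- vapply(lens, function(L) {
      paste0(sample(names(p), L, replace = TRUE, prob = p), collapse = "")
    }, character(1))
    names(seqs) <- sprintf("contig%02d", seq_along(seqs))
    ref_genome(seqs)
  })
}

#' In-silico restriction digest with size selection
#'
#' Cuts at every motif occurrence (overlapping occurrences included),
#' `cut_offset` bases into the motif, producing fragments that tile the
#' sequence without overlap; a fragment is selected iff its length falls
#' inside the inclusive size range.
#'
#' @param sequence a single sequence string
#' @param motif recognition site
#' @param cut_offset bases into the motif where the cut falls
#' @param size_range inclusive `c(min, max)` selected lengths
#' @return data.frame with `start`, `end` (0-based half-open), `length`,
#'   `selected`
#' @export
digest_and_select <- function(sequence, motif = "TTAA", cut_offset = 1,
                              size_range = c(350, 425)) {
  L <- nchar(sequence)
  hits <- gregexpr(paste0("(?=", motif, ")"), sequence, perl = TRUE)[[1]]
  cuts <- if (hits[1] == -1L) integer(0) else as.integer(hits) - 1L + cut_offset
  cuts <- cuts[cuts > 0L & cuts < L]
  bounds <- c(0L, sort(unique(cuts)), L)
  start <- bounds[-length(bounds)]
  end <- bounds[-1]
  len <- end - start
  data.frame(start = start, end = end, length = len,
             selected = len >= size_range[1] & len <= size_range[2])
}

#' Digest every contig of a reference
#'
#' @param reference a [ref_genome()]
#' @param config a [sim_config()] supplying motif, cut offset and size
#'   range
#' @return data.frame with `contig`, `start`, `end`, `length`, `selected`
#' @export
digest_reference <- function(reference, config = sim_config()) {
  out <- lapply(names(reference$seq), function(ct) {
    d <- digest_and_select(reference$seq[[ct]], config$enzyme_motif,
                           config$cut_offset, config$fragment_size_range)
    cbind(contig = ct, d, stringsAsFactors = FALSE)
  })
  rbind_all(out)
}

# 0-based positions (per contig) covered by selected fragments.
selected_positions <- function(fragments, contig) {
  f <- fragments[fragments$contig == contig & fragments$selected, ,
                 drop = FALSE]
  if (nrow(f) == 0L) return(integer(0))
  unlist(mapply(function(s, e) seq.int(s, e - 1L), f$start, f$end,
                SIMPLIFY = FALSE), use.names = FALSE)
}

#' Implant substitution variants into genotype copies of a reference
#'
#' Each non-reference genotype receives an independent set of substitution
#' variants at the configured density, subject to the configured
#' constraints: minimum spacing, exclusion of homopolymer contexts, and
#' restriction to selected fragments (so truth variants are recoverable by
#' the caller by design when requested). The truth set records which
#' constraints each variant satisfies.
#'
#' @param reference a [ref_genome()]
#' @param config a [sim_config()]
#' @param fragments optional [digest_reference()] output; computed from the
#'   config when `restrict_to_fragments` is set and `fragments` is `NULL`
#' @return list with `genotypes` (named list of per-contig sequence
#'   vectors) and `truth` (data.frame `genotype`, `contig`, `pos` (1-based),
#'   `ref`, `alt`, `in_homopolymer`, `in_selected_fragment`)
#' @export
implant_variants <- function(reference, config = sim_config(),
                             fragments = NULL) {
  if (config$restrict_to_fragments && is.null(fragments)) {
    fragments <- digest_reference(reference, config)
  }
  genotype_ids <- sprintf("G%02d", seq_len(config$n_genotypes))
  alt_ids <- genotype_ids[-1]            # genotype 1 is the reference line

  eligible <- lapply(names(reference$seq), function(ct) {
    L <- reference$lengths[[ct]]
    pos <- seq_len(L)
    keep <- substring(reference$seq[[ct]], pos, pos) %in% c("A", "C", "G", "T")
    if (config$restrict_to_fragments) {
      sel0 <- selected_positions(fragments, ct)
      keep <- keep & ((pos - 1L) %in% sel0)
    }
    if (config$avoid_homopolymer && any(keep)) {
      keep <- keep & !contig_homopolymer_mask(reference$seq[[ct]], 3)
    }
    pos[keep]
  })
  names(eligible) <- names(reference$seq)

  truth <- list()
  genotypes <- list()
  with_seed(stage_seed(config$seed, "variants"), {
    for (g in alt_ids) {
      rows <- list()
      seqs <- reference$seq
      for (ct in names(reference$seq)) {
        cand <- eligible[[ct]]
        if (length(cand) == 0L) next
        n_target <- stats::rbinom(1, reference$lengths[[ct]],
                                  config$snp_density)
        n_target <- min(n_target, length(cand))
        if (n_target == 0L) next
        pos <- sort(sample(cand, n_target))
        if (config$min_spacing > 1L && length(pos) > 1L) {
          keep <- logical(length(pos))
          last <- -Inf
          for (i in seq_along(pos)) {
            if (pos[i] - last >= config$min_spacing) {
              keep[i] <- TRUE
              last <- pos[i]
            }
          }
          pos <- pos[keep]
        }
        if (length(pos) == 0L) next
        refb <- substring(seqs[[ct]], pos, pos)
        transition_of <- c(A = "G", G = "A", C = "T", T = "C")
        alt <- vapply(refb, function(b) {
          if (stats::runif(1) < config$transition_prob) {
            transition_of[[b]]
          } else {
            sample(setdiff(c("A", "C", "G", "T"), c(b, transition_of[[b]])), 1)
          }
        }, character(1))
        s <- strsplit(seqs[[ct]], "", fixed = TRUE)[[1]]
        s[pos] <- alt
        seqs[[ct]] <- paste0(s, collapse = "")
        rows[[ct]] <- data.frame(
          genotype = g, contig = ct, pos = pos, ref = refb, alt = alt,
          in_homopolymer = homopolymer_flag(reference, rep(ct, length(pos)),
                                            pos, 3),
          in_selected_fragment = if (is.null(fragments)) NA else {
            (pos - 1L) %in% selected_positions(fragments, ct)
          },
          stringsAsFactors = FALSE)
      }
      genotypes[[g]] <- seqs
      truth[[g]] <- rbind_all(rows)
    }
  })
  genotypes <- c(stats::setNames(list(reference$seq), genotype_ids[1]),
                 genotypes)
  truth <- rbind_all(truth)
  if (is.null(truth)) {
    truth <- data.frame(genotype = character(0), contig = character(0),
                        pos = integer(0), ref = character(0),
                        alt = character(0), in_homopolymer = logical(0),
                        in_selected_fragment = logical(0),
                        stringsAsFactors = FALSE)
  }
  rownames(truth) <- NULL
  list(genotypes = genotypes, truth = truth)
}

#' Simulate site-level pileup observations for one genotype
#'
#' Only positions inside selected fragments are covered. Per-site depth is
#' drawn from a negative binomial (mean `mean_depth`, size
#' `depth_dispersion`; 0 = constant, `Inf` = Poisson); zero-depth sites are
#' absent from the stream. Each call is the genotype base, flipped to a
#' uniformly chosen different base with probability `base_error_rate`;
#' base qualities come from a clamped normal model. Reads are not modeled
#' individually: downstream computations consume pileup columns, so the
#' simulator emits site columns directly.
#'
#' @param genotype_id label for the emitted sites
#' @param genotype_seq named per-contig sequence vector for the genotype
#' @param reference the [ref_genome()] the pileup is reported against
#' @param fragments [digest_reference()] output
#' @param config a [sim_config()]
#' @param path optional path; when given, a 6-column samtools-style text
#'   pileup is written
#' @return site-observation data.frame (see [read_pileup()])
#' @export
simulate_pileup <- function(genotype_id, genotype_seq, reference, fragments,
                            config = sim_config(), path = NULL) {
  with_seed(stage_seed(config$seed, paste0("pileup_", genotype_id)), {
    per_contig <- list()
    for (ct in names(reference$seq)) {
      pos0 <- selected_positions(fragments, ct)
      if (length(pos0) == 0L) next
      pos <- sort(pos0) + 1L
      n <- length(pos)
      depth <- if (config$depth_dispersion == 0) {
        rep(max(1L, round(config$mean_depth)), n)
      } else if (is.infinite(config$depth_dispersion)) {
        stats::rpois(n, config$mean_depth)
      } else {
        stats::rnbinom(n, size = config$depth_dispersion,
                       mu = config$mean_depth)
      }
      depth <- as.integer(depth)
      keep <- depth > 0L
      pos <- pos[keep]; depth <- depth[keep]
      if (length(pos) == 0L) next
      true_base <- substring(genotype_seq[[ct]], pos, pos)
      ref_base <- substring(reference$seq[[ct]], pos, pos)
      N <- sum(depth)
      site_of <- rep.int(seq_along(pos), depth)
      calls <- rep.int(true_base, depth)
      if (config$base_error_rate > 0) {
        flip <- which(stats::runif(N) < config$base_error_rate)
        if (length(flip)) {
          calls[flip] <- vapply(calls[flip], function(b) {
            sample(setdiff(c("A", "C", "G", "T"), b), 1)
          }, character(1))
        }
      }
      q <- round(stats::rnorm(N, config$base_quality_mean,
                              config$base_quality_sd))
      q <- pmin(pmax(q, 2L), 41L)
      f <- factor(site_of, levels = seq_along(pos))
      call_str <- vapply(split(calls, f), paste0, "", collapse = "")
      qual_str <- vapply(split(q, f), phred_chars, "")
      per_contig[[ct]] <- data.frame(
        genotype = genotype_id, contig = ct, pos = pos, ref = ref_base,
        depth = depth, calls = unname(call_str), quals = unname(qual_str),
        mapq = NA_character_, stringsAsFactors = FALSE)
    }
    obs <- rbind_all(per_contig)
    if (is.null(obs)) {
      obs <- parse_pileup_lines(character(0), genotype_id)
    }
    if (!is.null(path)) {
      display <- obs$calls
      for (b in c("A", "C", "G", "T", "N")) {
        sel <- obs$ref == b
        display[sel] <- gsub(b, ".", display[sel], fixed = TRUE)
      }
      writeLines(paste(obs$contig, obs$pos, obs$ref, obs$depth, display,
                       obs$quals, sep = "\t"), path)
    }
    obs
  })
}

#' Simulate a RIL population from two parental allele sets
#'
#' Each RIL inherits one parental allele per locus (loci independent, as in
#' an unlinked-marker model); a cell is residual-heterozygous with
#' probability (1/2)^selfing_generations and is emitted as missing in the
#' call matrix (the mask is returned so callers can assert that
#' behaviour), and otherwise informative with probability `ril_call_prob`.
#'
#' @param loci data.frame with `contig`, `pos`, `parent1`, `parent2`
#'   allele columns
#' @param config a [sim_config()]
#' @return list with `calls` (loci x RIL character matrix, `NA` = missing),
#'   `inherited` (parental origin matrix, 1 or 2), `het_mask` and
#'   `missing_mask` logical matrices, and `ril_ids`
#' @export
simulate_ril_population <- function(loci, config = sim_config()) {
  n_loci <- nrow(loci)
  n <- config$n_rils
  ril_ids <- sprintf("RIL%03d", seq_len(n))
  keys <- paste0(loci$contig, ":", loci$pos)
  with_seed(stage_seed(config$seed, "rils"), {
    origin <- matrix(stats::rbinom(n_loci * n, 1, 0.5) + 1L, nrow = n_loci,
                     dimnames = list(keys, ril_ids))
    het_rate <- 0.5^config$selfing_generations
    het <- matrix(stats::runif(n_loci * n) < het_rate, nrow = n_loci,
                  dimnames = list(keys, ril_ids))
    uncalled <- matrix(stats::runif(n_loci * n) >= config$ril_call_prob,
                       nrow = n_loci, dimnames = list(keys, ril_ids))
    alleles <- matrix(ifelse(origin == 1L, loci$parent1, loci$parent2),
                      nrow = n_loci, dimnames = list(keys, ril_ids))
    calls <- alleles
    calls[het | uncalled] <- NA_character_
    list(calls = calls, inherited = origin, het_mask = het,
         missing_mask = uncalled, ril_ids = ril_ids)
  })
}

#' Simulate gene models over a reference
#'
#' Places non-overlapping genes along each contig (mean length ~3 kbp,
#' target genic fraction ~25% of the genome) and 1-4 non-overlapping CDS
#' segments inside each gene covering about half of it. Convenience
#' generator for annotation truth sets; coordinates are 0-based half-open.
#'
#' @param reference a [ref_genome()]
#' @param config a [sim_config()]
#' @param genic_fraction target fraction of the genome inside genes
#' @return a [gene_models()] object
#' @export
simulate_gene_models <- function(reference, config = sim_config(),
                                 genic_fraction = 0.25) {
  with_seed(stage_seed(config$seed, "genes"), {
    genes <- list(); cds <- list(); k <- 0L
    for (ct in names(reference$seq)) {
      L <- reference$lengths[[ct]]
      mean_gene <- 3000
      mean_gap <- mean_gene * (1 - genic_fraction) / genic_fraction
      at <- 0L
      placed <- FALSE
      repeat {
        gap <- stats::rgeom(1, 1 / mean_gap)
        glen <- max(300L, stats::rpois(1, mean_gene))
        start <- at + gap
        end <- start + glen
        if (end > L) {
          if (!placed && L > 2L * glen) {
            # keep every reasonably long contig annotated: first draw
            # overshot, so place the gene at a fixed fraction of the contig
            start <- L %/% 4L
            end <- start + glen
          } else {
            break
          }
        }
        k <- k + 1L
        placed <- TRUE
        gid <- sprintf("gene%04d", k)
        genes[[k]] <- data.frame(gene_id = gid, contig = ct,
                                 start = start, end = end,
                                 stringsAsFactors = FALSE)
        n_exon <- sample(1:4, 1)
        bounds <- sort(sample(seq(start, end - 1L), 2L * n_exon))
        ex_s <- bounds[seq(1, 2 * n_exon, by = 2)]
        ex_e <- bounds[seq(2, 2 * n_exon, by = 2)] + 1L
        ok <- ex_e > ex_s
        if (any(ok)) {
          cds[[length(cds) + 1L]] <- data.frame(
            gene_id = gid, contig = ct, start = ex_s[ok], end = ex_e[ok],
            stringsAsFactors = FALSE)
        }
        at <- end
      }
    }
    gene_models(
      rbind_all(genes) %||%
        data.frame(gene_id = character(0), contig = character(0),
                   start = integer(0), end = integer(0)),
      rbind_all(cds) %||%
        data.frame(gene_id = character(0), contig = character(0),
                   start = integer(0), end = integer(0)))
  })
}

#' Run the whole simulator and write its artifacts
#'
#' Generates the reference, gene models, digest, genotype variants,
#' per-genotype pileups and a RIL population for the two-parent comparison
#' (reference line x genotype 2), writing `ref.fa`, `genes.gff3`,
#' `fragments.tsv`, `<genotype>.pileup`, `truth_variants.tsv`,
#' `ril_calls.tsv` and `ril_truth.tsv` under `outdir`.
#'
#' @param config a [sim_config()]
#' @param outdir output directory (created if needed); `NULL` skips all
#'   file output
#' @return list with `reference`, `gene_models`, `fragments`, `genotypes`,
#'   `truth`, `pileups` (named list of site frames), `ril` (population
#'   object or `NULL` when fewer than two genotypes), `ril_loci`, and
#'   `files`
#' @export
simulate_experiment <- function(config = sim_config(), outdir = NULL) {
  files <- character(0)
  emit <- function(name) {
    if (is.null(outdir)) return(NULL)
    file.path(outdir, name)
  }
  if (!is.null(outdir) && !dir.exists(outdir)) {
    dir.create(outdir, recursive = TRUE)
  }
  reference <- simulate_reference(config)
  models <- simulate_gene_models(reference, config)
  fragments <- digest_reference(reference, config)
  imp <- implant_variants(reference, config, fragments)

  pileups <- list()
  for (g in names(imp$genotypes)) {
    p <- emit(paste0(g, ".pileup"))
    pileups[[g]] <- simulate_pileup(g, imp$genotypes[[g]], reference,
                                    fragments, config, path = p)
    if (!is.null(p)) files <- c(files, p)
  }

  ril <- NULL; ril_loci <- NULL
  if (config$n_genotypes >= 2L) {
    gt2 <- sprintf("G%02d", 2L)
    tr <- imp$truth[imp$truth$genotype == gt2, , drop = FALSE]
    if (nrow(tr)) {
      ril_loci <- data.frame(contig = tr$contig, pos = tr$pos,
                             parent1 = tr$ref, parent2 = tr$alt,
                             stringsAsFactors = FALSE)
      ril <- simulate_ril_population(ril_loci, config)
    }
  }

  if (!is.null(outdir)) {
    f <- emit("ref.fa"); write_reference(reference, f); files <- c(files, f)
    f <- emit("genes.gff3"); write_gene_models(models, f); files <- c(files, f)
    f <- emit("fragments.tsv")
    utils::write.table(fragments, f, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    files <- c(files, f)
    f <- emit("truth_variants.tsv")
    utils::write.table(imp$truth, f, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    files <- c(files, f)
    if (!is.null(ril)) {
      f <- emit("ril_calls.tsv"); write_ril_matrix(ril$calls, f)
      files <- c(files, f)
      f <- emit("ril_truth.tsv")
      truth_out <- data.frame(locus = rownames(ril$inherited),
                              het_fraction = rowMeans(ril$het_mask),
                              stringsAsFactors = FALSE)
      utils::write.table(truth_out, f, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      files <- c(files, f)
    }
  }

  list(reference = reference, gene_models = models, fragments = fragments,
       genotypes = imp$genotypes, truth = imp$truth, pileups = pileups,
       ril = ril, ril_loci = ril_loci, files = files, config = config)
}
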