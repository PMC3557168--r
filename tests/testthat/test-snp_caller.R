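# Candidate calling and the filter stack.

test_that("consensus calling returns the majority base with its ratio", {
  cand <- call_candidate(site_row(ref = "A", calls = "GGGGGGGGGA"))
  expect_identical(cand$alt, "G")
  expect_equal(cand$ratio, 0.9)

  expect_null(call_candidate(site_row(ref = "A", calls = "AAAAAAAAAA")))

  cand <- call_candidate(site_row(ref = "A", calls = "GGGGGGGGTT"))
  expect_identical(cand$alt, "G")
  expect_equal(cand$ratio, 0.8)

  # tie for the top count -> no call; N reference -> skipped
  expect_null(call_candidate(site_row(ref = "A", calls = "GGTT")))
  expect_null(call_candidate(site_row(ref = "N", calls = "GGGG")))
})

test_that("site quality is the mean of consensus-supporting base qualities", {
  # consensus G supported by Q30,Q40 ('?' = 30, 'I' = 40); the A call Q10
  cand <- call_candidate(site_row(ref = "A", calls = "GGA", quals = "?I+"))
  expect_equal(cand$quality, 35)

  # RMS mapping quality caps the base-quality mean when present
  mapq <- intToUtf8(rep(15 + 33, 3))  # RMS 15 < 35
  cand <- call_candidate(site_row(ref = "A", calls = "GGA", quals = "?I+",
                                  mapq = mapq))
  expect_equal(cand$quality, 15)
})

test_that("depth, ratio and quality thresholds flag at the stated bounds", {
  cfg <- caller_config()
  stats <- data.frame(genotype = "G01", mean_depth = 10, sd_depth = 5,
                      max_depth_cutoff = 20, n_covered = 100L)
  mk <- function(depth, ratio = 1, quality = 30) {
    data.frame(genotype = "G01", contig = "c1", pos = 10L, ref = "A",
               alt = "G", depth = depth, n_calls = depth, ratio = ratio,
               quality = quality, stringsAsFactors = FALSE)
  }
  f <- apply_site_filters(mk(3), stats, cfg)
  expect_false(f$low_depth || f$high_depth)        # >= 3 boundary passes
  expect_true(apply_site_filters(mk(2), stats, cfg)$low_depth)
  expect_true(apply_site_filters(mk(21), stats, cfg)$high_depth)
  expect_false(apply_site_filters(mk(20), stats, cfg)$high_depth)
  expect_true(apply_site_filters(mk(10, ratio = 0.89), stats, cfg)$low_ratio)
  expect_false(apply_site_filters(mk(10, ratio = 0.9), stats, cfg)$low_ratio)
  expect_true(apply_site_filters(mk(10, quality = 19.9), stats,
                                 cfg)$low_quality)
  expect_error(apply_site_filters(mk(3), stats[0, ], cfg), "missing")
  # fixed maximum-depth mode ignores the per-genotype cutoff
  cfg2 <- caller_config(max_depth = 15)
  expect_true(apply_site_filters(mk(16), stats, cfg2)$high_depth)
})

test_that("homopolymer flagging covers runs containing or abutting the site", {
  ref <- ref_genome(c(c1 = "GCAAATCGCGTTTAGCACGTAA"))
  cand <- function(pos) data.frame(genotype = "g", contig = "c1",
                                   pos = as.integer(pos), ref = "A",
                                   alt = "G", stringsAsFactors = FALSE)
  # middle of AAA run (positions 3-5)
  expect_true(filter_homopolymer(cand(4), ref, 3)$homopolymer)
  # isolated base in ACGT context (position 17 'A' in GCACGT)
  expect_false(filter_homopolymer(cand(17), ref, 3)$homopolymer)
  # base immediately after TTT run (positions 11-13; 14 abuts it)
  expect_true(filter_homopolymer(cand(14), ref, 3)$homopolymer)
  expect_error(filter_homopolymer(cand(99), ref, 3), "outside")
})

test_that("homopolymer flags agree with a brute-force run scan", {
  set.seed(42)
  seq <- paste0(sample(c("A", "C", "G", "T"), 500, TRUE,
                       prob = c(0.4, 0.1, 0.1, 0.4)), collapse = "")
  ref <- ref_genome(c(c1 = seq))
  chars <- strsplit(seq, "")[[1]]
  brute <- function(p, min_run) {
    run_len <- function(q) {
      if (q < 1 || q > length(chars)) return(0)
      a <- q; b <- q
      while (a > 1 && chars[a - 1] == chars[q]) a <- a - 1
      while (b < length(chars) && chars[b + 1] == chars[q]) b <- b + 1
      b - a + 1
    }
    run_len(p) >= min_run || run_len(p - 1) >= min_run ||
      run_len(p + 1) >= min_run
  }
  pos <- 1:500
  cands <- data.frame(genotype = "g", contig = "c1", pos = pos,
                      stringsAsFactors = FALSE)
  for (min_run in c(2, 3, 4)) {
    got <- filter_homopolymer(cands, ref, min_run)$homopolymer
    expect_identical(got, vapply(pos, brute, logical(1), min_run = min_run))
  }
})

test_that("adjacency flags both members and propagates through chains", {
  mk <- function(pos) data.frame(genotype = "g", contig = "c1",
                                 pos = as.integer(pos),
                                 stringsAsFactors = FALSE)
  expect_equal(filter_adjacent(mk(c(100, 101)), 2)$adjacent, c(TRUE, TRUE))
  expect_equal(filter_adjacent(mk(c(100, 103)), 2)$adjacent, c(FALSE, FALSE))
  expect_equal(filter_adjacent(mk(c(100, 102, 104)), 2)$adjacent,
               rep(TRUE, 3))
  # contig boundary resets the gap
  two <- data.frame(genotype = "g", contig = c("c1", "c2"),
                    pos = c(100L, 101L), stringsAsFactors = FALSE)
  expect_equal(filter_adjacent(two, 2)$adjacent, c(FALSE, FALSE))
  expect_error(filter_adjacent(mk(c(5, 3)), 2), "sorted")
})

test_that("discovery merges passing candidates across genotypes by location", {
  ref <- ref_genome(c(c1 = strrep("ACGTGTCA", 10)))
  clean_site <- function(g, pos, alt) {
    site_row(pos = pos, ref = substr(ref$seq[["c1"]], pos, pos),
             calls = strrep(alt, 10), genotype = g)
  }
  pileups <- list(
    GA = rbind(clean_site("GA", 10, "A"), clean_site("GA", 30, "A")),
    GB = rbind(clean_site("GB", 10, "A"), clean_site("GB", 50, "T"))
  )
  disc <- discover_snps(pileups, ref)
  expect_equal(nrow(disc$snps), 3)
  shared <- disc$snps[disc$snps$pos == 10, ]
  expect_identical(shared$genotypes, "GA,GB")
  expect_identical(shared$n_genotypes, 2L)
  # multi-allelic location keeps one record with per-genotype alleles
  pileups$GB[1, "calls"] <- strrep("T", 10)
  disc <- discover_snps(pileups, ref)
  rec <- disc$snps[disc$snps$pos == 10, ]
  expect_identical(nrow(rec), 1L)
  expect_identical(rec$alt, "A")              # first genotype's allele
  expect_identical(rec$alts, "GA:A,GB:T")
})

test_that("discovery is invariant to genotype and line order", {
  cfg <- sim_config(genome_length = 60000, n_contigs = 2, n_genotypes = 3,
                    seed = 5)
  sim <- simulate_experiment(cfg)
  d1 <- discover_snps(sim$pileups, sim$reference)
  shuffled <- lapply(rev(sim$pileups), function(p) {
    set.seed(1); p[sample(nrow(p)), ]
  })
  d2 <- discover_snps(shuffled, sim$reference)
  k <- function(d) paste(d$snps$contig, d$snps$pos, d$snps$alt)
  expect_setequal(k(d1), k(d2))
  expect_identical(sort(d1$snps$genotypes), sort(d2$snps$genotypes))
})

test_that("staged pipeline equals a brute-force per-position evaluator", {
  set.seed(90)
  for (trial in 1:3) {
    cfg_sim <- sim_config(genome_length = 10000, n_contigs = 2,
                          n_genotypes = 3, snp_density = 2e-3,
                          base_error_rate = 0.01, mean_depth = 6,
                          depth_dispersion = 4, min_spacing = 1,
                          avoid_homopolymer = FALSE,
                          restrict_to_fragments = FALSE,
                          fragment_size_range = c(1, 1e9),
                          seed = 100 + trial)
    sim <- simulate_experiment(cfg_sim)
    cfg <- caller_config(min_depth = sample(2:4, 1),
                         min_consensus_ratio = sample(c(0.7, 0.9), 1),
                         min_quality = sample(c(15, 20), 1),
                         homopolymer_min_run = 3,
                         min_gap_between_snps = sample(1:2, 1))
    disc <- discover_snps(sim$pileups, sim$reference, cfg)
    pass <- disc$candidates[disc$candidates$pass, ]
    got <- paste(pass$genotype, pass$contig, pass$pos)

    want <- character(0)
    for (g in names(sim$pileups)) {
      st <- depth_summary(sim$pileups[[g]], g)
      bf <- brute_force_snps(sim$pileups[[g]], as.list(sim$reference$seq),
                             min_depth = cfg$min_depth,
                             max_depth = st$max_depth_cutoff,
                             min_ratio = cfg$min_consensus_ratio,
                             min_qual = cfg$min_quality,
                             min_run = cfg$homopolymer_min_run,
                             min_gap = cfg$min_gap_between_snps)
      want <- c(want, paste(bf$genotype, bf$contig, bf$pos))
    }
    expect_setequal(got, want)
  }
})

test_that("raising thresholds never grows the passing set", {
  cfg_sim <- sim_config(genome_length = 50000, n_contigs = 2,
                        n_genotypes = 3, base_error_rate = 0.01,
                        mean_depth = 6, depth_dispersion = 3, seed = 9)
  sim <- simulate_experiment(cfg_sim)
  key <- function(disc) {
    p <- disc$candidates[disc$candidates$pass, ]
    paste(p$genotype, p$contig, p$pos)
  }
  base <- key(discover_snps(sim$pileups, sim$reference,
                            caller_config(min_depth = 2,
                                          min_consensus_ratio = 0.7,
                                          min_quality = 10)))
  for (cfg in list(caller_config(min_depth = 4, min_consensus_ratio = 0.7,
                                 min_quality = 10),
                   caller_config(min_depth = 2, min_consensus_ratio = 0.95,
                                 min_quality = 10),
                   caller_config(min_depth = 2, min_consensus_ratio = 0.7,
                                 min_quality = 25))) {
    stricter <- key(discover_snps(sim$pileups, sim$reference, cfg))
    expect_true(all(stricter %in% base))
  }
})

test_that("false-positive rate is the mismatch count per reference base", {
  expect_equal(estimate_false_positive_rate(6072, 318e6), 6072 / 318e6)
  expect_equal(signif(estimate_false_positive_rate(6072, 318e6), 2), 1.9e-5)
  expect_equal(estimate_false_positive_rate(0, 100), 0)
  expect_error(estimate_false_positive_rate(1, 0), "positive")
})

test_that("error-free self-mapping produces zero candidates", {
  cfg <- sim_config(genome_length = 80000, n_contigs = 2, n_genotypes = 1,
                    base_error_rate = 0, seed = 3)
  sim <- simulate_experiment(cfg)
  disc <- discover_snps(sim$pileups, sim$reference)
  expect_identical(nrow(disc$candidates), 0L)
  expect_identical(nrow(disc$snps), 0L)
})
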