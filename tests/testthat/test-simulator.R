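# The synthetic-data generator: determinism, base composition, digest
# arithmetic, depth/error model, and RIL inheritance.

test_that("simulation is deterministic for identical seeds", {
  cfg <- sim_config(genome_length = 30000, n_contigs = 2, n_genotypes = 3,
                    seed = 17)
  r1 <- simulate_reference(cfg)
  r2 <- simulate_reference(cfg)
  expect_identical(r1$seq, r2$seq)
  s1 <- simulate_experiment(cfg)
  s2 <- simulate_experiment(cfg)
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$pileups, s2$pileups)
  expect_identical(s1$ril$calls, s2$ril$calls)
  # a different seed changes the sequence
  r3 <- simulate_reference(sim_config(genome_length = 30000, n_contigs = 2,
                                      seed = 18))
  expect_false(identical(r1$seq, r3$seq))
})

test_that("base composition tracks the configured GC fraction", {
  ref <- simulate_reference(sim_config(genome_length = 1e6, n_contigs = 1,
                                       gc_fraction = 0.5, seed = 2))
  s <- ref$seq[[1]]
  gc <- (count_char(s, "G") + count_char(s, "C")) / nchar(s)
  expect_gt(gc, 0.48)
  expect_lt(gc, 0.52)
  at_only <- simulate_reference(sim_config(genome_length = 5000,
                                           n_contigs = 1, gc_fraction = 0,
                                           seed = 2))
  expect_false(grepl("[GC]", at_only$seq[[1]]))
})

test_that("digest cuts at every motif occurrence with the configured offset", {
  # no motif: one fragment spanning the sequence
  d <- digest_and_select(strrep("C", 50), "TTAA", 1, c(10, 100))
  expect_equal(nrow(d), 1)
  expect_equal(d$length, 50)
  expect_true(d$selected)

  # hand-built 60 bp oracle: motifs at 0-based starts 10 and 34
  s <- paste0(strrep("C", 10), "TTAA", strrep("G", 20), "TTAA",
              strrep("C", 22))
  expect_equal(nchar(s), 60)
  d <- digest_and_select(s, "TTAA", 1, c(1, 100))
  # cuts one base into each motif: 11 and 35 -> lengths 11, 24, 25
  expect_equal(d$length, c(11, 24, 25))
  expect_equal(d$start, c(0, 11, 35))
  expect_equal(sum(d$length), 60)

  # overlapping occurrences: TTTAA contains TTAA at start 1 (0-based)
  d <- digest_and_select(paste0("TTTAA", strrep("G", 15)), "TTAA", 1,
                         c(1, 100))
  expect_equal(d$length, c(2, 18))

  # brute-force all-position scan on a random sequence
  set.seed(8)
  s <- paste0(sample(c("A", "T"), 400, TRUE), collapse = "")
  d <- digest_and_select(s, "TTAA", 1, c(1, 1000))
  starts <- which(vapply(seq_len(nchar(s) - 3),
                         function(i) substr(s, i, i + 3) == "TTAA",
                         logical(1)))
  cuts <- unique(starts - 1 + 1)
  cuts <- cuts[cuts > 0 & cuts < nchar(s)]
  expect_equal(d$start, c(0, sort(cuts)))
  expect_equal(sum(d$length), nchar(s))
})

test_that("fragment size selection is inclusive at both bounds", {
  s <- paste0(strrep("C", 9), "TTAA",      # fragment of length 10
              strrep("G", 16), "TTAA",     # fragment of length 20
              strrep("C", 30))             # tail fragment of length 33
  d <- digest_and_select(s, "TTAA", 1, c(10, 20))
  expect_equal(d$selected, c(TRUE, TRUE, FALSE))
})

test_that("implanted variants respect their constraints and density", {
  cfg <- sim_config(genome_length = 1e5, n_contigs = 2, n_genotypes = 2,
                    snp_density = 1e-3, min_spacing = 3,
                    restrict_to_fragments = FALSE, seed = 12)
  ref <- simulate_reference(cfg)
  imp <- implant_variants(ref, cfg)
  tr <- imp$truth
  expect_gt(nrow(tr), 0)
  expect_true(all(tr$ref != tr$alt))
  # genotype sequence differs from the reference exactly at truth positions
  g2 <- imp$genotypes$G02
  for (ct in names(ref$seq)) {
    diffs <- which(strsplit(g2[[ct]], "")[[1]] !=
                     strsplit(ref$seq[[ct]], "")[[1]])
    expect_setequal(diffs, tr$pos[tr$contig == ct])
  }
  # spacing constraint within each contig
  by_ct <- split(tr$pos, tr$contig)
  expect_true(all(unlist(lapply(by_ct, function(p) diff(sort(p)) >= 3))))
  # none in homopolymer context
  expect_false(any(tr$in_homopolymer))
  # implant count within the Poisson 99% interval of density * length
  lambda <- 1e-3 * 1e5
  expect_gt(nrow(tr), qpois(0.005, lambda) * 0.5)  # spacing thins a little
  expect_lt(nrow(tr), qpois(0.995, lambda))
  # zero density implants nothing
  cfg0 <- sim_config(genome_length = 1e4, n_genotypes = 2, snp_density = 0,
                     seed = 12)
  imp0 <- implant_variants(simulate_reference(cfg0), cfg0)
  expect_identical(nrow(imp0$truth), 0L)
  expect_identical(imp0$genotypes$G02, imp0$genotypes$G01)
})

test_that("pileups cover selected fragments only, with the depth model", {
  cfg <- sim_config(genome_length = 2e5, n_contigs = 1, n_genotypes = 1,
                    base_error_rate = 0, mean_depth = 10,
                    depth_dispersion = 0, seed = 6)
  sim <- simulate_experiment(cfg)
  obs <- sim$pileups$G01
  frag <- sim$fragments
  sel <- frag[frag$selected, ]
  inside <- rep(FALSE, sim$reference$total_length)
  for (i in seq_len(nrow(sel))) inside[(sel$start[i] + 1):sel$end[i]] <- TRUE
  expect_true(all(inside[obs$pos]))
  expect_equal(sum(inside), nrow(obs))          # constant depth: all covered
  expect_true(all(obs$depth == 10))
  # error-free: every call equals the genotype (= reference) base
  expect_true(all(obs$calls == strrep(obs$ref, 10)))
})

test_that("mean depth concentrates near the configured value", {
  cfg <- sim_config(genome_length = 3e5, n_contigs = 1, n_genotypes = 1,
                    mean_depth = 10, depth_dispersion = 8,
                    fragment_size_range = c(100, 1000), seed = 14)
  sim <- simulate_experiment(cfg)
  obs <- sim$pileups$G01
  expect_gt(nrow(obs), 5e4)
  # depth over covered sites: zero-truncated mean is slightly above mu
  expect_lt(abs(mean(obs$depth) - 10) / 10, 0.05)
})

test_that("emitted pileup files reproduce the internal observations", {
  cfg <- sim_config(genome_length = 50000, n_contigs = 2, n_genotypes = 2,
                    base_error_rate = 0.01, seed = 4)
  outdir <- tempfile()
  sim <- simulate_experiment(cfg, outdir)
  for (g in names(sim$pileups)) {
    back <- read_pileup(file.path(outdir, paste0(g, ".pileup")), g)
    expect_identical(back, sim$pileups[[g]])
  }
})

test_that("RIL inheritance is balanced with the configured residual het", {
  cfg <- sim_config(n_rils = 96, selfing_generations = 5,
                    ril_call_prob = 1, seed = 19)
  loci <- data.frame(contig = "c1", pos = seq_len(2000),
                     parent1 = "A", parent2 = "G")
  pop <- simulate_ril_population(loci, cfg)
  # allele frequency ~0.5 per locus, and overall within binomial error
  overall <- mean(pop$inherited == 1L)
  expect_lt(abs(overall - 0.5), 3 * sqrt(0.25 / (2000 * 96)))
  # residual heterozygosity (1/2)^5 = 3.125%
  expect_lt(abs(mean(pop$het_mask) - 0.03125),
            4 * sqrt(0.03125 * (1 - 0.03125) / (2000 * 96)))
  # het cells are emitted as missing calls
  expect_true(all(is.na(pop$calls[pop$het_mask])))
  # every non-missing call is one of the parental alleles
  expect_true(all(pop$calls[!is.na(pop$calls)] %in% c("A", "G")))
})

test_that("selfing generations control the residual het rate", {
  loci <- data.frame(contig = "c1", pos = seq_len(3000),
                     parent1 = "A", parent2 = "G")
  f2 <- simulate_ril_population(loci, sim_config(selfing_generations = 1,
                                                 n_rils = 48, seed = 22))
  f6 <- simulate_ril_population(loci, sim_config(selfing_generations = 5,
                                                 n_rils = 48, seed = 22))
  expect_gt(mean(f2$het_mask), mean(f6$het_mask))
  expect_lt(abs(mean(f2$het_mask) - 0.5), 0.02)
})
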