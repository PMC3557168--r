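# Fixture builders shared across the suite. Everything is generated in
# code; no binary data.

# A one-row site observation, the way read_pileup() lays it out.
site_row <- function(contig = "c1", pos = 10L, ref = "A", calls = "AAAA",
                     quals = NULL, genotype = "G01", depth = NULL,
                     mapq = NA_character_) {
  if (is.null(quals)) quals <- strrep("I", nchar(calls))  # 'I' = Q40
  if (is.null(depth)) depth <- nchar(calls)
  data.frame(genotype = genotype, contig = contig, pos = as.integer(pos),
             ref = ref, depth = as.integer(depth), calls = calls,
             quals = quals, mapq = mapq, stringsAsFactors = FALSE)
}

sites_df <- function(...) do.call(rbind, list(...))

# Write a small FASTA fixture and return its path.
tmp_fasta <- function(seqs) {
  path <- tempfile(fileext = ".fa")
  lines <- unlist(lapply(names(seqs), function(n) c(paste0(">", n), seqs[[n]])))
  writeLines(lines, path)
  path
}

# Independent brute-force re-implementation of the filter stack, used as
# the oracle for staged-pipeline equivalence. Works position by position
# with plain loops and no shared code with the package internals.
brute_force_snps <- function(sites, ref_seqs, min_depth = 3, max_depth = Inf,
                             min_ratio = 0.9, min_qual = 20, min_run = 3,
                             min_gap = 2) {
  cand <- list()
  for (i in seq_len(nrow(sites))) {
    s <- sites[i, ]
    if (!s$ref %in% c("A", "C", "G", "T")) next
    calls <- strsplit(s$calls, "")[[1]]
    if (length(calls) == 0) next
    counts <- sapply(c("A", "C", "G", "T"), function(b) sum(calls == b))
    if (max(counts) == 0 || sum(counts == max(counts)) > 1) next
    cons <- names(counts)[which.max(counts)]
    if (cons == s$ref) next
    quals <- utf8ToInt(s$quals) - 33
    cand[[length(cand) + 1]] <- data.frame(
      genotype = s$genotype, contig = s$contig, pos = s$pos, ref = s$ref,
      alt = cons, depth = s$depth,
      ratio = max(counts) / length(calls),
      quality = mean(quals[calls == cons]), stringsAsFactors = FALSE)
  }
  if (length(cand) == 0) {
    return(data.frame(genotype = character(0), contig = character(0),
                      pos = integer(0)))
  }
  cand <- do.call(rbind, cand)
  # independent homopolymer scan over the full contig
  hp <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    chars <- strsplit(ref_seqs[[cand$contig[i]]], "")[[1]]
    p <- cand$pos[i]
    run_len_at <- function(q) {
      if (q < 1 || q > length(chars)) return(0)
      a <- q; b <- q
      while (a > 1 && chars[a - 1] == chars[q]) a <- a - 1
      while (b < length(chars) && chars[b + 1] == chars[q]) b <- b + 1
      b - a + 1
    }
    hp[i] <- run_len_at(p) >= min_run ||
      run_len_at(p - 1) >= min_run || run_len_at(p + 1) >= min_run
  }
  # all-pairs adjacency within genotype+contig
  adj <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    for (j in seq_len(nrow(cand))) {
      if (i == j) next
      if (cand$genotype[i] == cand$genotype[j] &&
          cand$contig[i] == cand$contig[j] &&
          abs(cand$pos[i] - cand$pos[j]) - 1 < min_gap) {
        adj[i] <- TRUE
      }
    }
  }
  keep <- cand$depth >= min_depth & cand$depth <= max_depth &
    cand$ratio >= min_ratio & cand$quality >= min_qual & !hp & !adj
  cand[keep, c("genotype", "contig", "pos")]
}
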