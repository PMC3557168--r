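# Readers and writers for the external representations the pipeline touches:
# reference FASTA, samtools text pileup, gene models (GFF3/BED-like), and
# SNP tables (TSV/VCF). All internal coordinates are 0-based half-open;
# conversion to/from the native convention of each format happens here and
# only here. Reported positions (pileup, SNP tables) stay 1-based.

## ---- reference genome ----------------------------------------------------

#' Construct a reference genome object from named sequences
#'
#' A `ref_genome` stores ordered contigs plus the offsets that define the
#' concatenated coordinate system used for genome-wide binning: contig `i`
#' starts at the sum of the lengths of contigs `1..i-1`.
#'
#' @param sequences named character vector of contig sequences
#'   (A/C/G/T/N, case-insensitive)
#' @return an object of class `ref_genome` with elements `seq` (named
#'   uppercase character vector), `lengths`, `offsets` (0-based concatenated
#'   start of each contig) and `total_length`
#' @export
ref_genome <- function(sequences) {
  if (length(sequences) == 0L) {
    stop("reference must contain at least one contig")
  }
  ids <- names(sequences)
  if (is.null(ids) || any(!nzchar(ids))) {
    stop("all contigs must be named")
  }
  if (anyDuplicated(ids)) {
    stop("duplicate contig id: ", ids[duplicated(ids)][1])
  }
  seqs <- toupper(as.character(sequences))
  lens <- nchar(seqs)
  if (any(lens == 0L)) {
    stop("empty sequence for contig ", ids[lens == 0L][1])
  }
  bad <- regexpr("[^ACGTN]", seqs)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1]
    stop(sprintf("illegal character in contig %s at offset %d", ids[i], bad[i]))
  }
  offsets <- cumsum(c(0, lens[-length(lens)]))
  names(lens) <- names(offsets) <- ids
  structure(
    list(seq = stats::setNames(seqs, ids), lengths = lens,
         offsets = offsets, total_length = sum(lens)),
    class = "ref_genome"
  )
}

#' Read a reference genome from FASTA
#'
#' Contig order follows file order; lowercase bases are folded to uppercase;
#' characters outside A/C/G/T/N are rejected with the offending contig and
#' offset named.
#'
#' @param path path to a FASTA file (plain or gzipped)
#' @return a [ref_genome()] object
#' @export
read_reference <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- tryCatch(
    Biostrings::readDNAStringSet(path),
    error = function(e) stop("not a readable FASTA file: ", path, " (",
                             conditionMessage(e), ")")
  )
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(set))
  ref_genome(stats::setNames(as.character(set), ids))
}

#' Write a reference genome to FASTA
#' @param reference a [ref_genome()]
#' @param path output path
#' @export
write_reference <- function(reference, path) {
  set <- Biostrings::DNAStringSet(reference$seq)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Concatenated 0-based coordinate of a contig-local position
#'
#' @param reference a [ref_genome()]
#' @param contig contig id(s)
#' @param pos 1-based contig-local position(s)
#' @return 0-based position(s) in the concatenated coordinate system
#' @export
concat_coord <- function(reference, contig, pos) {
  unknown <- setdiff(unique(contig), names(reference$offsets))
  if (length(unknown)) stop("unknown contig: ", unknown[1])
  if (any(pos < 1L | pos > reference$lengths[contig])) {
    stop("position beyond contig end")
  }
  unname(reference$offsets[contig] + pos - 1)
}

#' @export
print.ref_genome <- function(x, ...) {
  cat(sprintf("<ref_genome> %d contig(s), %s bp total\n",
              length(x$seq), format(x$total_length, big.mark = ",")))
  invisible(x)
}

## ---- pileup --------------------------------------------------------------

# Resolve one samtools read-base string that contains structural symbols
# (read starts '^', ends '$', indel runs, deletion placeholders '*').
# Returns calls (ref-resolved, uppercase), the quality substring retained
# for those calls, and the number of '*' placeholders.
parse_base_string <- function(bases, quals, ref) {
  chars <- strsplit(bases, "", fixed = TRUE)[[1]]
  n <- length(chars)
  calls <- character(0)
  keep_qual <- logical(0)   # per quality-consuming token: TRUE = base call
  stars <- 0L
  i <- 1L
  while (i <= n) {
    ch <- chars[i]
    if (ch == "^") {
      i <- i + 2L                     # '^' + mapping-quality char of the read
    } else if (ch == "$") {
      i <- i + 1L
    } else if (ch == "+" || ch == "-") {
      j <- i + 1L
      while (j <= n && chars[j] %in% as.character(0:9)) j <- j + 1L
      len <- as.integer(paste0(chars[(i + 1L):(j - 1L)], collapse = ""))
      i <- j + len                    # skip the inserted/deleted run entirely
    } else if (ch == "*") {
      stars <- stars + 1L
      keep_qual <- c(keep_qual, FALSE)
      i <- i + 1L
    } else if (ch == "." || ch == ",") {
      calls <- c(calls, ref)
      keep_qual <- c(keep_qual, TRUE)
      i <- i + 1L
    } else if (toupper(ch) %in% c("A", "C", "G", "T", "N")) {
      calls <- c(calls, toupper(ch))
      keep_qual <- c(keep_qual, TRUE)
      i <- i + 1L
    } else {
      stop("unexpected pileup symbol '", ch, "'")
    }
  }
  qc <- strsplit(quals, "", fixed = TRUE)[[1]]
  if (length(qc) != length(keep_qual)) {
    stop(sprintf("quality string length %d does not match %d parsed calls",
                 length(qc), length(keep_qual)))
  }
  list(calls = paste0(calls, collapse = ""),
       quals = paste0(qc[keep_qual], collapse = ""),
       stars = stars)
}

#' Read a samtools text pileup into per-site observations
#'
#' Accepts the 6-column text pileup dialect (chrom, 1-based position,
#' reference base, depth, read bases, base qualities) and the 7-column
#' variant with a trailing mapping-quality string. Read-start (`^` plus its
#' mapping-quality character) and read-end (`$`) marks are stripped; indel
#' runs (`+n<seq>` / `-n<seq>`) are skipped entirely; the deletion
#' placeholder `*` counts toward site depth but not toward base calls, and
#' its quality character is dropped. `.`/`,` are resolved to the reference
#' base and lowercase calls are strand-folded to uppercase.
#'
#' @param path path to a pileup file, or a character vector of pileup lines
#' @param genotype_id label recorded on every site
#' @return a data.frame with columns `genotype`, `contig`, `pos` (1-based),
#'   `ref`, `depth` (base calls plus deletion placeholders), `calls`,
#'   `quals` (Phred+33, aligned to `calls`) and `mapq` (Phred+33 string or
#'   `NA` when the input had six columns)
#' @export
read_pileup <- function(path, genotype_id = "sample") {
  lines <- if (length(path) == 1L && file.exists(path)) readLines(path) else path
  parse_pileup_lines(lines, genotype_id)
}

#' @noRd
parse_pileup_lines <- function(lines, genotype_id = "sample") {
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(data.frame(genotype = character(0), contig = character(0),
                      pos = integer(0), ref = character(0), depth = integer(0),
                      calls = character(0), quals = character(0),
                      mapq = character(0), stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "[ \t]+")
  ncols <- lengths(fields)
  if (any(ncols != 6L & ncols != 7L)) {
    stop("pileup line ", which(ncols != 6L & ncols != 7L)[1],
         ": expected 6 or 7 columns, got ", ncols[ncols != 6L & ncols != 7L][1])
  }
  m <- matrix("", nrow = length(fields), ncol = 7L)
  for (i in seq_along(fields)) m[i, seq_len(ncols[i])] <- fields[[i]]
  contig <- m[, 1]
  pos <- suppressWarnings(as.integer(m[, 2]))
  if (anyNA(pos)) stop("pileup line ", which(is.na(pos))[1], ": bad position")
  ref <- toupper(m[, 3])
  bases <- m[, 5]
  quals <- m[, 6]
  mapq <- ifelse(ncols == 7L, m[, 7], NA_character_)

  calls <- character(length(lines))
  kept_quals <- character(length(lines))
  depth <- integer(length(lines))

  simple <- grepl("^[.,ACGTNacgtn]*$", bases)
  if (any(simple)) {
    cs <- toupper(bases[simple])
    rs <- ref[simple]
    for (b in unique(rs)) {
      sel <- rs == b
      cs[sel] <- gsub("[.,]", b, cs[sel])
    }
    nb <- nchar(cs)
    nq <- nchar(quals[simple])
    if (any(nb != nq)) {
      bad <- which(simple)[which(nb != nq)[1]]
      stop("pileup line ", bad, ": quality string length mismatch")
    }
    calls[simple] <- cs
    kept_quals[simple] <- quals[simple]
    depth[simple] <- nb
  }
  for (i in which(!simple)) {
    parsed <- tryCatch(
      parse_base_string(bases[i], quals[i], ref[i]),
      error = function(e) stop("pileup line ", i, ": ", conditionMessage(e))
    )
    calls[i] <- parsed$calls
    kept_quals[i] <- parsed$quals
    depth[i] <- nchar(parsed$calls) + parsed$stars
  }

  data.frame(genotype = genotype_id, contig = contig, pos = pos, ref = ref,
             depth = depth, calls = calls, quals = kept_quals, mapq = mapq,
             stringsAsFactors = FALSE)
}

#' Read an allele-count table as site observations
#'
#' Alternative input dialect for users without pileups: a TSV with columns
#' `contig`, `pos` (1-based), `ref`, `nA`, `nC`, `nG`, `nT`, `meanQ`.
#' Counts are expanded into synthetic call strings with a uniform quality.
#'
#' @inheritParams read_pileup
#' @return the same data.frame layout as [read_pileup()]
#' @export
read_allele_counts <- function(path, genotype_id = "sample") {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("contig", "pos", "ref", "nA", "nC", "nG", "nT", "meanQ")
  if (!all(need %in% names(d))) {
    stop("allele-count table must have columns: ", paste(need, collapse = ", "))
  }
  calls <- mapply(function(a, c, g, t) {
    paste0(strrep("A", a), strrep("C", c), strrep("G", g), strrep("T", t))
  }, d$nA, d$nC, d$nG, d$nT)
  depth <- d$nA + d$nC + d$nG + d$nT
  quals <- mapply(function(n, q) phred_chars(rep(round(q), n)), depth, d$meanQ)
  data.frame(genotype = genotype_id, contig = d$contig, pos = as.integer(d$pos),
             ref = toupper(d$ref), depth = as.integer(depth), calls = calls,
             quals = quals, mapq = NA_character_, stringsAsFactors = FALSE)
}

## ---- gene models ---------------------------------------------------------

#' Construct a gene model set
#'
#' @param genes data.frame with columns `gene_id`, `contig`, `start`, `end`
#'   (0-based half-open)
#' @param cds data.frame with the same columns, one row per CDS segment
#' @return an object of class `gene_models`
#' @export
gene_models <- function(genes, cds) {
  genes <- as.data.frame(genes); cds <- as.data.frame(cds)
  if (nrow(genes) && any(genes$end <= genes$start)) {
    stop("gene interval with end <= start")
  }
  if (nrow(cds)) {
    if (any(cds$end <= cds$start)) stop("CDS interval with end <= start")
    orphan <- !(cds$gene_id %in% genes$gene_id)
    if (any(orphan)) stop("CDS with no parent gene: ", cds$gene_id[orphan][1])
    gi <- match(cds$gene_id, genes$gene_id)
    outside <- cds$start < genes$start[gi] | cds$end > genes$end[gi] |
      cds$contig != genes$contig[gi]
    if (any(outside)) {
      stop("CDS outside its gene span: ", cds$gene_id[outside][1])
    }
  }
  structure(list(genes = genes, cds = cds), class = "gene_models")
}

#' Read gene models from GFF3 or a BED-like table
#'
#' GFF3 coordinates (1-based inclusive) are converted to the internal
#' 0-based half-open convention; CDS features are attached to their parent
#' gene via `Parent`/`ID` attributes. The BED-like dialect is a 5-column
#' table (`contig`, `start`, `end`, `type`, `gene_id`) already 0-based
#' half-open, with `type` in `gene`/`CDS`.
#'
#' @param path input file
#' @param format `"gff3"` or `"bed"`
#' @return a [gene_models()] object
#' @export
read_gene_models <- function(path, format = c("gff3", "bed")) {
  format <- match.arg(format)
  if (format == "gff3") {
    g <- as.data.frame(rtracklayer::readGFF(path))
    if (nrow(g) == 0L) {
      return(gene_models(
        data.frame(gene_id = character(0), contig = character(0),
                   start = integer(0), end = integer(0)),
        data.frame(gene_id = character(0), contig = character(0),
                   start = integer(0), end = integer(0))))
    }
    gn <- g[g$type == "gene", , drop = FALSE]
    cd <- g[g$type == "CDS", , drop = FALSE]
    genes <- data.frame(gene_id = as.character(gn$ID),
                        contig = as.character(gn$seqid),
                        start = gn$start - 1L, end = gn$end,
                        stringsAsFactors = FALSE)
    parent <- vapply(cd$Parent, function(p) as.character(p)[1] %||% NA_character_,
                     character(1))
    cds <- data.frame(gene_id = parent,
                      contig = as.character(cd$seqid),
                      start = cd$start - 1L, end = cd$end,
                      stringsAsFactors = FALSE)
  } else {
    d <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("contig", "start", "end", "type", "gene_id")
    if (!all(need %in% names(d))) {
      stop("BED-like gene table must have columns: ",
           paste(need, collapse = ", "))
    }
    genes <- d[d$type == "gene", c("gene_id", "contig", "start", "end")]
    cds <- d[d$type == "CDS", c("gene_id", "contig", "start", "end")]
  }
  gene_models(genes, cds)
}

#' Write gene models as GFF3
#' @param models a [gene_models()] object
#' @param path output path
#' @export
write_gene_models <- function(models, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  g <- models$genes
  if (nrow(g)) {
    writeLines(sprintf("%s\trrlsnp\tgene\t%d\t%d\t.\t+\t.\tID=%s",
                       g$contig, g$start + 1L, g$end, g$gene_id), con)
  }
  cd <- models$cds
  if (nrow(cd)) {
    writeLines(sprintf("%s\trrlsnp\tCDS\t%d\t%d\t.\t+\t0\tID=%s.cds;Parent=%s",
                       cd$contig, cd$start + 1L, cd$end, cd$gene_id,
                       cd$gene_id), con)
  }
  invisible(path)
}

#' @export
print.gene_models <- function(x, ...) {
  cat(sprintf("<gene_models> %d gene(s), %d CDS segment(s)\n",
              nrow(x$genes), nrow(x$cds)))
  invisible(x)
}

## ---- SNP tables ----------------------------------------------------------

snp_table_columns <- c("contig", "pos", "ref", "alt", "genotypes", "depth",
                       "ratio", "quality", "region_class", "cds_flag",
                       "substitution_class", "alts")

# Fill optional annotation columns so writers can run pre-annotation.
complete_snp_table <- function(snps) {
  snps <- as.data.frame(snps)
  if (is.null(snps$region_class)) snps$region_class <- NA_character_
  if (is.null(snps$cds_flag)) snps$cds_flag <- NA
  if (is.null(snps$substitution_class)) snps$substitution_class <- NA_character_
  if (is.null(snps$alts)) snps$alts <- paste0(sub(",.*$", "", snps$genotypes),
                                              ":", snps$alt)
  snps[, snp_table_columns, drop = FALSE]
}

#' Write a SNP table as TSV or VCF 4.2
#'
#' Positions are contig-local and 1-based in both formats. The VCF encodes
#' the per-genotype alternate alleles in per-sample `GT` fields and the
#' summary statistics (`DP`, `CR`, `SQ`) plus annotation (`RC`, `CDS`, `SC`)
#' in `INFO`; both formats round-trip through [read_snp_table()].
#'
#' @param snps data.frame with columns `contig`, `pos`, `ref`, `alt`,
#'   `genotypes` (comma-separated presence list), `depth`, `ratio`,
#'   `quality`, and optionally `region_class`, `cds_flag`,
#'   `substitution_class`, `alts` (per-genotype `id:base` pairs)
#' @param path output path
#' @param format `"tsv"` or `"vcf"`
#' @param genotype_ids sample column order for VCF; defaults to the
#'   genotypes observed in `snps`
#' @export
write_snp_table <- function(snps, path, format = c("tsv", "vcf"),
                            genotype_ids = NULL) {
  format <- match.arg(format)
  snps <- complete_snp_table(snps)
  if (format == "tsv") {
    out <- snps
    out$ratio <- sprintf("%.6g", out$ratio)
    out$quality <- sprintf("%.6g", out$quality)
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(path))
  }
  if (is.null(genotype_ids)) {
    genotype_ids <- unique(unlist(strsplit(snps$genotypes, ",")))
    genotype_ids <- genotype_ids[nzchar(genotype_ids)]
    if (length(genotype_ids) == 0L) genotype_ids <- "sample"
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=rrlsnp",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##INFO=<ID=CR,Number=1,Type=Float,Description=\"Consensus base ratio\">",
    "##INFO=<ID=SQ,Number=1,Type=Float,Description=\"Site quality\">",
    "##INFO=<ID=RC,Number=1,Type=String,Description=\"Region class\">",
    "##INFO=<ID=CDS,Number=0,Type=Flag,Description=\"Within a CDS\">",
    "##INFO=<ID=SC,Number=1,Type=String,Description=\"Substitution class\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", genotype_ids), collapse = "\t")
  ), con)
  if (nrow(snps)) {
    for (i in seq_len(nrow(snps))) {
      pairs <- strsplit(strsplit(snps$alts[i], ",")[[1]], ":")
      gt_base <- stats::setNames(vapply(pairs, `[`, "", 2),
                                 vapply(pairs, `[`, "", 1))
      alt_alleles <- unique(unname(gt_base))
      gt_field <- vapply(genotype_ids, function(g) {
        if (g %in% names(gt_base)) as.character(match(gt_base[[g]], alt_alleles))
        else "."
      }, character(1))
      info <- sprintf("DP=%d;CR=%.6g;SQ=%.6g", snps$depth[i], snps$ratio[i],
                      snps$quality[i])
      if (!is.na(snps$region_class[i])) {
        info <- paste0(info, ";RC=", snps$region_class[i])
      }
      if (isTRUE(snps$cds_flag[i])) info <- paste0(info, ";CDS")
      if (!is.na(snps$substitution_class[i])) {
        info <- paste0(info, ";SC=", snps$substitution_class[i])
      }
      writeLines(paste(c(snps$contig[i], snps$pos[i], ".", snps$ref[i],
                         paste(alt_alleles, collapse = ","), ".", "PASS",
                         info, "GT", gt_field), collapse = "\t"), con)
    }
  }
  invisible(path)
}

#' Read a SNP table written by [write_snp_table()]
#'
#' @param path input path
#' @param format `"tsv"` or `"vcf"`
#' @return data.frame in the canonical SNP-table layout
#' @export
read_snp_table <- function(path, format = c("tsv", "vcf")) {
  format <- match.arg(format)
  if (format == "tsv") {
    d <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = c(pos = "integer"))
    if (nrow(d) == 0L) {
      d <- d[, snp_table_columns, drop = FALSE]
      return(d)
    }
    d$cds_flag <- as.logical(d$cds_flag)
    return(d[, snp_table_columns, drop = FALSE])
  }
  read_snp_vcf(path)
}

# VCF branch of read_snp_table. Uses vcfR when available, otherwise a
# minimal column scan of the fixed fields (the dialect is the one this
# package writes).
read_snp_vcf <- function(path) {
  empty <- data.frame(contig = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      genotypes = character(0), depth = integer(0),
                      ratio = numeric(0), quality = numeric(0),
                      region_class = character(0), cds_flag = logical(0),
                      substitution_class = character(0), alts = character(0),
                      stringsAsFactors = FALSE)
  if (requireNamespace("vcfR", quietly = TRUE)) {
    v <- suppressWarnings(vcfR::read.vcfR(path, verbose = FALSE))
    fix <- as.data.frame(vcfR::getFIX(v, getINFO = TRUE),
                         stringsAsFactors = FALSE)
    if (nrow(fix) == 0L) return(empty)
    gt <- v@gt
    samples <- colnames(gt)[-1]
    info <- fix$INFO
    chrom <- fix$CHROM; pos <- as.integer(fix$POS)
    ref <- fix$REF; alt_field <- fix$ALT
  } else {
    lines <- readLines(path)
    header <- grep("^#CHROM", lines, value = TRUE)
    samples <- strsplit(header, "\t")[[1]][-(1:9)]
    rows <- lines[!startsWith(lines, "#")]
    if (length(rows) == 0L) return(empty)
    f <- do.call(rbind, strsplit(rows, "\t"))
    gt <- cbind(FORMAT = f[, 9], f[, -(1:9), drop = FALSE])
    colnames(gt) <- c("FORMAT", samples)
    info <- f[, 8]
    chrom <- f[, 1]; pos <- as.integer(f[, 2]); ref <- f[, 4]
    alt_field <- f[, 5]
  }
  get_info <- function(key) {
    m <- regmatches(info, regexpr(paste0("(?:^|;)", key, "=[^;]*"), info))
    out <- rep(NA_character_, length(info))
    hit <- grepl(paste0("(?:^|;)", key, "="), info)
    out[hit] <- sub(paste0("^;?", key, "="), "", m)
    out
  }
  alt_list <- strsplit(alt_field, ",")
  n <- length(chrom)
  genotypes <- character(n); alts <- character(n); alt1 <- character(n)
  for (i in seq_len(n)) {
    calls <- sub(":.*$", "", gt[i, -1])
    present <- which(calls != "." & calls != "")
    ids <- samples[present]
    bases <- alt_list[[i]][as.integer(calls[present])]
    genotypes[i] <- paste(ids, collapse = ",")
    alts[i] <- paste(paste0(ids, ":", bases), collapse = ",")
    alt1[i] <- bases[1]
  }
  data.frame(contig = chrom, pos = pos, ref = ref, alt = alt1,
             genotypes = genotypes,
             depth = as.integer(get_info("DP")),
             ratio = as.numeric(get_info("CR")),
             quality = as.numeric(get_info("SQ")),
             region_class = get_info("RC"),
             cds_flag = grepl("(?:^|;)CDS(?:;|$)", info),
             substitution_class = get_info("SC"),
             alts = alts, stringsAsFactors = FALSE)
}
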