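# Orchestration of the full pipeline: simulate -> discover -> characterize
# -> bins -> validate, with a JSON run manifest capturing the effective
# configuration, input digests and output file list.

#' Run the full pipeline on simulated inputs
#'
#' Executes the stages in dependency order (any stage skippable) starting
#' from a fresh simulation: SNP discovery over the emitted pileup files
#' (read back through the pileup parser, exercising the I/O contract),
#' characterization against the simulated gene models, genome-binned
#' coverage and SNP density, and GBS validation of the discovered
#' two-parent candidates against the simulated RIL population. Outputs are
#' pure functions of (config, seed).
#'
#' @param config a [sim_config()]
#' @param outdir output directory
#' @param caller a [caller_config()]
#' @param bin_size bin width for the coverage/SNP tables (bp)
#' @param stages character subset of
#'   `c("discover", "characterize", "bins", "validate")`
#' @return list with the stage results (`sim`, `discovery`, `report`,
#'   `bins`, `validation`) and the `manifest`
#' @export
run_full_pipeline <- function(config = sim_config(), outdir,
                              caller = caller_config(), bin_size = 50000,
                              stages = c("discover", "characterize", "bins",
                                         "validate")) {
  t0 <- Sys.time()
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  sim <- simulate_experiment(config, outdir)
  outputs <- sim$files
  discovery <- report <- bins <- validation <- NULL

  if ("discover" %in% stages) {
    pileup_files <- file.path(outdir, paste0(names(sim$pileups), ".pileup"))
    names(pileup_files) <- names(sim$pileups)
    discovery <- discover_snps(as.list(pileup_files), sim$reference, caller)
    f <- file.path(outdir, "snps.tsv")
    write_snp_table(discovery$snps, f, "tsv")
    outputs <- c(outputs, f)
    f <- file.path(outdir, "depth_stats.tsv")
    utils::write.table(discovery$stats, f, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    outputs <- c(outputs, f)
  }

  if ("characterize" %in% stages && !is.null(discovery)) {
    report <- characterize(discovery$snps, sim$gene_models, sim$reference,
                           n_genotypes = length(sim$pileups))
    f <- file.path(outdir, "report.json")
    write_report_json(report, f)
    outputs <- c(outputs, f)
    if (!is.null(report$per_genotype)) {
      f <- file.path(outdir, "per_genotype.tsv")
      utils::write.table(report$per_genotype, f, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      outputs <- c(outputs, f)
    }
  }

  if ("bins" %in% stages && !is.null(discovery)) {
    snp_bins <- bin_snp_density(discovery$snps, sim$reference, bin_size)
    bins <- lapply(sim$pileups, bin_coverage, reference = sim$reference,
                   bin_size = bin_size)
    for (g in names(bins)) {
      f <- file.path(outdir, paste0("bins_", g, ".tsv"))
      write_bin_table(bins[[g]], snp_bins, f)
      outputs <- c(outputs, f)
    }
    bins$snp_density <- snp_bins
  }

  if ("validate" %in% stages && !is.null(discovery) && !is.null(sim$ril)) {
    parent2 <- names(sim$pileups)[2]
    cand <- discovery$snps
    cand <- cand[vapply(strsplit(cand$genotypes, ","),
                        function(s) parent2 %in% s, logical(1)), ,
                 drop = FALSE]
    if (nrow(cand)) {
      validation <- validate_snps(cand, sim$ril$calls, caller)
      f <- file.path(outdir, "validation.tsv")
      utils::write.table(validation$loci, f, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      outputs <- c(outputs, f)
      f <- file.path(outdir, "validation_summary.json")
      jsonlite::write_json(validation$summary, f, auto_unbox = TRUE,
                           digits = NA)
      outputs <- c(outputs, f)
    }
  }

  manifest <- list(
    subcommand = "run",
    tool = "rrlsnp",
    version = as.character(utils::packageVersion("rrlsnp")),
    seed = config$seed,
    config = unclass(config),
    caller = unclass(caller),
    stages = stages,
    started = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    outputs = basename(outputs),
    digests = as.list(tools::md5sum(outputs))
  )
  names(manifest$digests) <- basename(outputs)
  mf <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")

  list(sim = sim, discovery = discovery, report = report, bins = bins,
       validation = validation, manifest = manifest)
}
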