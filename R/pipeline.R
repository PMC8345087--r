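# JSON-lines stage log
.log_line <- function(log_path, stage, level, message) {
  line <- jsonlite::toJSON(list(stage = stage, level = level,
                                message = message), auto_unbox = TRUE)
  cat(line, "\n", sep = "", file = log_path, append = TRUE)
}

.md5_of_object <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(as.character(jsonlite::toJSON(x, auto_unbox = TRUE,
                                           digits = NA)), tf)
  unname(tools::md5sum(tf))
}

# fill defaults and validate the pipeline configuration before any compute
.validate_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) .stopf("config file not found: %s", config)
    config <- if (grepl("\\.json$", config))
      jsonlite::read_json(config, simplifyVector = TRUE)
    else if (requireNamespace("yaml", quietly = TRUE))
      yaml::read_yaml(config)
    else .stopf("YAML config requires the yaml package")
  }
  if (!is.list(config)) .stopf("config must be a list or a file path")
  required <- c("manifest", "out_dir")
  missing <- setdiff(required, names(config))
  if (length(missing) > 0)
    .stopf("config schema error: missing field(s) %s",
           paste(missing, collapse = ", "))
  defaults <- list(seed = 1L, cell_lines = .DEFAULT_CELL_LINES,
                   replicates = 3L, depth = 1e5, dispersion = 0.002,
                   read_error_rate = 0.001, activity_multiplier = list(),
                   via_fastq = FALSE, fc_low = 0.8, fc_high = 1.2,
                   alpha = 0.05, test = "student", min_input_count = 10)
  for (nm in names(defaults))
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  if (!file.exists(config$manifest))
    .stopf("config schema error: manifest file %s not found",
           config$manifest)
  if (length(config$cell_lines) < 1)
    .stopf("config schema error: cell_lines must name at least one line")
  config
}

#' Run the reporter-assay pipeline end to end
#'
#' Wires the stages together: load the SNP manifest, design the barcoded
#' construct library, simulate plasmid/cDNA counts from the configured
#' ground truth (optionally rendering paired FASTQ and re-quantifying
#' through merge + demultiplex), normalize to plasmid input and the
#' negative control, and call regulatory SNPs per cell line. All stage
#' tables, a JSON run manifest with input/output digests, a JSON-lines
#' stage log, and a markdown summary are written to the output directory.
#' Reruns with the same config and seed produce byte-identical stage
#' outputs.
#'
#' @param config A named list or path to a YAML/JSON file. Required:
#'   `manifest` (SNP manifest TSV), `out_dir`. Optional (defaults in
#'   parentheses): `seed` (1), `cell_lines` (the 11-line panel),
#'   `replicates` (3), `depth` (1e5), `dispersion` (0.002),
#'   `read_error_rate` (0.001), `activity_multiplier` (named list, empty),
#'   `via_fastq` (FALSE: count columns are used directly; TRUE renders and
#'   re-quantifies FASTQ per sample), `fc_low` (0.8), `fc_high` (1.2),
#'   `alpha` (0.05), `test` ("student"), `min_input_count` (10).
#' @return Invisibly, a list with the stage results: `constructs`,
#'   `counts`, `activity`, `calls`, `fc_matrix`, `out_dir`.
#' @export
run_pipeline <- function(config) {
  config <- .validate_config(config)
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "pipeline.log.jsonl")
  if (file.exists(log_path)) unlink(log_path)

  .log_line(log_path, "design", "info", "loading SNP manifest")
  snps <- load_snp_manifest(config$manifest)
  constructs <- build_constructs(snps)
  write_constructs(constructs, file.path(out_dir, "constructs.tsv"),
                   file.path(out_dir, "inserts.fasta"))
  .log_line(log_path, "design", "info",
            sprintf("%d constructs across %d sub-libraries",
                    nrow(constructs), length(unique(constructs$sublib_tag))))

  mult <- unlist(config$activity_multiplier)
  truth <- simulation_truth(
    activity_multiplier = if (length(mult)) mult else numeric(0),
    replicates = config$replicates, depth = config$depth,
    dispersion = config$dispersion,
    read_error_rate = config$read_error_rate, seed = config$seed)
  .log_line(log_path, "simulate", "info",
            sprintf("simulating counts: depth %g, %d replicates, %d lines",
                    truth$depth, truth$replicates,
                    length(config$cell_lines)))
  counts <- simulate_counts(constructs, truth,
                            cell_lines = config$cell_lines)

  if (isTRUE(config$via_fastq)) {
    .log_line(log_path, "quantify", "info",
              "rendering FASTQ and re-quantifying each sample")
    fq_dir <- file.path(out_dir, "fastq")
    dir.create(fq_dir, showWarnings = FALSE)
    requant <- counts$counts
    for (j in seq_len(ncol(counts$counts))) {
      s <- colnames(counts$counts)[j]
      r1 <- file.path(fq_dir, paste0(s, "_R1.fastq"))
      r2 <- file.path(fq_dir, paste0(s, "_R2.fastq"))
      render_fastq(counts, constructs, s, r1, r2, truth,
                   seed = truth$seed + j)
      q <- quantify_sample(r1, r2, constructs)
      requant[, j] <- q$counts[rownames(requant)]
    }
    counts <- count_table(requant, counts$samples)
  }
  write_count_table(counts, file.path(out_dir, "counts.tsv"),
                    file.path(out_dir, "samples.tsv"))

  .log_line(log_path, "normalize", "info", "plasmid-normalizing activities")
  activity <- normalize_activity(counts,
                                 min_input_count = config$min_input_count)
  act_df <- data.frame(construct_id = rownames(activity$activity),
                       flag = activity$flags[rownames(activity$activity)],
                       activity$activity, check.names = FALSE)
  utils::write.table(act_df, file.path(out_dir, "activity.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  .log_line(log_path, "call", "info", "calling regulatory SNPs")
  cfg <- call_config(config$fc_low, config$fc_high, config$alpha,
                     config$test)
  calls <- call_regulatory_all(activity, constructs, cfg)
  utils::write.table(calls, file.path(out_dir, "calls.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  m <- fc_matrix(calls)
  m_df <- data.frame(rsid = rownames(m), m, check.names = FALSE)
  utils::write.table(m_df, file.path(out_dir, "fc_matrix.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  outputs <- c("constructs.tsv", "inserts.fasta", "counts.tsv",
               "samples.tsv", "activity.tsv", "calls.tsv", "fc_matrix.tsv")
  manifest <- list(
    tool = "dirseq",
    version = as.character(utils::packageVersion("dirseq")),
    timestamp = format(Sys.time(), tz = "UTC"),
    seed = config$seed,
    config = config[setdiff(names(config), "out_dir")],
    config_hash = .md5_of_object(config[setdiff(names(config),
                                                "out_dir")]),
    input_digests = list(manifest = unname(tools::md5sum(config$manifest))),
    output_digests = as.list(tools::md5sum(file.path(out_dir, outputs))))
  names(manifest$output_digests) <- outputs
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  n_called <- table(factor(calls$call, levels = c("down", "up", "none")))
  summary_md <- c(
    "# DiR-seq pipeline summary", "",
    sprintf("- SNPs: %d; constructs: %d (incl. negative control)",
            nrow(snps), nrow(constructs)),
    sprintf("- Samples: %d cDNA across %d cell lines x %d replicates + 1 plasmid input",
            sum(counts$samples$material == "cdna"),
            length(config$cell_lines), config$replicates),
    sprintf("- Low-input constructs excluded: %d",
            sum(activity$flags == "low_input")),
    sprintf("- Regulatory calls: %d down, %d up, %d none (of %d tests)",
            n_called[["down"]], n_called[["up"]], n_called[["none"]],
            attr(calls, "n_tests")),
    sprintf("- Call rule: fc < %g or > %g with p < %g (%s t-test)",
            cfg$fc_low, cfg$fc_high, cfg$alpha, cfg$test))
  writeLines(summary_md, file.path(out_dir, "summary.md"))
  .log_line(log_path, "report", "info", "pipeline complete")

  invisible(list(constructs = constructs, counts = counts,
                 activity = activity, calls = calls, fc_matrix = m,
                 out_dir = out_dir))
}
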