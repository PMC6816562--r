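# Pipeline orchestration ---------------------------------------------------
#
# run_pipeline() chains the stages simulate -> interpret -> frequencies
# -> phenotypes -> faults -> compare -> graph, as requested by a run
# configuration (an R list or a JSON file), writing delimited result
# tables plus a JSON run log with the seed, parameters and package
# version.  cli_main() exposes the same stages as subcommands for
# Rscript use.

#' Read a pipeline run configuration
#'
#' @param path JSON file.  Recognized fields: `steps` (subset of
#'   simulate, interpret, freq, phenotype, faults, compare, graph),
#'   `seed`, `outdir`, `genotype_table` (input path; alternative to
#'   simulating), `cohort` (inline cohort spec as in
#'   [read_cohort_spec()]), `gene_models` (config path; default
#'   catalogue when absent), `standards` (path), `fault_cases` (list of
#'   declarative cases for [evaluate_fault_case()]), `compare`
#'   (`n_breeds_tested`, `mc_resamples`, genes), `ibd_edges` (path),
#'   `carriers`, `disallowed_carriers`.
#' @return the configuration list.
#' @export
read_run_config <- function(path) {
  jsonlite::read_json(path, simplifyVector = FALSE)
}

# normalize the nested JSON lists into the shapes the API expects
.cfg_fault_cases <- function(cfg) {
  lapply(cfg$fault_cases, function(cs) {
    cs$factors <- lapply(cs$factors, function(fc) {
      fc$alleles <- unlist(fc$alleles)
      fc
    })
    cs
  })
}

#' Run the analysis pipeline end to end
#'
#' @param config configuration list (see [read_run_config()]) or a path
#'   to a JSON configuration file.
#' @param outdir output directory override; created if absent.
#' @return invisibly, a named list of output file paths and in-memory
#'   results (`markers`, `calls`, `freqs`, `faults`, `comparisons`,
#'   `graph`, `log`).
#' @export
run_pipeline <- function(config, outdir = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  outdir <- outdir %||% config$outdir %||% tempfile("ctrun")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  steps <- unlist(config$steps %||%
                    list("simulate", "interpret", "freq", "phenotype",
                         "faults", "compare"))
  models <- if (!is.null(config$gene_models))
    read_gene_models(config$gene_models) else default_gene_models()
  seed <- config$seed %||% 1L
  out <- list(outdir = outdir)
  log <- list(package = "caninetraits",
              version = as.character(utils::packageVersion("caninetraits")),
              seed = seed, steps = as.list(steps),
              timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))

  # input genotypes: simulated cohort or an existing table
  markers <- NULL
  if ("simulate" %in% steps) {
    if (is.null(config$cohort))
      stop("step 'simulate' requires a 'cohort' spec in the config")
    spec <- cohort_from_config(config$cohort, seed, models)
    cohort <- generate_cohort(spec)
    markers <- cohort$markers
    out$truth <- cohort$truth
    write_genotype_table(markers, file.path(outdir, "genotypes.tsv"))
  } else if (!is.null(config$genotype_table)) {
    markers <- read_genotype_table(config$genotype_table, models = models)
  }
  if (!is.null(markers)) {
    bad <- is.na(markers$dog_id) | markers$dog_id == "" |
      is.na(markers$breed) | markers$breed == ""
    if (any(bad)) {
      message(sum(bad), " malformed input row(s) skipped")
      log$rows_skipped <- sum(bad)
      markers <- markers[!bad, , drop = FALSE]
    }
    if (!nrow(markers)) stop("no usable dog records in input")
    out$markers <- markers
  }

  if (any(c("interpret", "freq", "phenotype", "faults", "compare") %in%
            steps)) {
    if (is.null(markers)) stop("no genotype input configured")
    calls <- interpret_genotypes(markers, models)
    out$calls <- calls
    utils::write.table(calls, file.path(outdir, "genotype_calls.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       na = "NA")
  }

  if (any(c("freq", "faults", "compare") %in% steps)) {
    freqs <- estimate_frequencies(out$calls, by = c("breed", "population"))
    out$freqs <- freqs
    write_frequency_table(freqs, file.path(outdir, "frequencies.tsv"))
  }

  if ("phenotype" %in% steps) {
    reports <- phenotype_table(out$calls, models,
                               breed_configs = config$breed_configs)
    out$phenotypes <- reports
    utils::write.table(reports, file.path(outdir, "phenotypes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       na = "NA")
  }

  if ("faults" %in% steps) {
    findings <- NULL
    if (!is.null(config$standards)) {
      standards <- read_breed_standards(config$standards)
      findings <- detect_fault_alleles(out$freqs, standards, models)
    }
    cases <- .cfg_fault_cases(config)
    probs <- NULL
    if (length(cases)) {
      evaluated <- lapply(cases, evaluate_fault_case, freqs = out$freqs)
      probs <- data.frame(
        case = vapply(evaluated, `[[`, "", "name"),
        breed = vapply(evaluated, `[[`, "", "breed"),
        probability = vapply(evaluated, `[[`, 0, "probability"),
        stringsAsFactors = FALSE)
    }
    out$faults <- list(findings = findings, probabilities = probs)
    if (!is.null(findings))
      utils::write.table(findings, file.path(outdir, "fault_findings.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(probs))
      utils::write.table(probs, file.path(outdir,
                                          "fault_probabilities.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
  }

  if ("compare" %in% steps) {
    cmp_cfg <- config$compare %||% list()
    n_breeds <- cmp_cfg$n_breeds_tested %||% 30
    genes <- unlist(cmp_cfg$genes %||% as.list(unique(out$calls$gene)))
    breeds <- unique(out$freqs$breed)
    rows <- list()
    for (b in breeds) for (g in genes) {
      res <- suppressWarnings(
        compare_populations(out$freqs, b, g, n_breeds_tested = n_breeds,
                            mc_resamples = cmp_cfg$mc_resamples %||% 1e5,
                            seed = seed))
      rows[[length(rows) + 1L]] <- data.frame(
        breed = b, gene = g, status = res$status,
        test = as.character(res$test), p_value = res$p_value,
        alpha = res$alpha, significant = res$significant,
        stringsAsFactors = FALSE)
    }
    comparisons <- do.call(rbind, rows)
    out$comparisons <- comparisons
    utils::write.table(comparisons, file.path(outdir, "comparisons.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       na = "NA")
  }

  if ("graph" %in% steps) {
    if (is.null(config$ibd_edges) || is.null(config$carriers))
      stop("step 'graph' requires 'ibd_edges' and 'carriers'")
    edges <- read_ibd_edges(config$ibd_edges)
    graph <- connect_carriers(edges, unlist(config$carriers),
                              unlist(config$disallowed_carriers %||%
                                       list()))
    out$graph <- graph
    write_carrier_edges(graph, file.path(outdir, "carrier_edges.tsv"))
    write_carrier_dot(graph, file.path(outdir, "carrier_graph.dot"))
  }

  out$log <- log
  jsonlite::write_json(log, file.path(outdir, "run_log.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out)
}

cohort_from_config <- function(cohort_cfg, seed, models) {
  breeds <- lapply(cohort_cfg$breeds, function(b) list(
    breed = b$breed,
    populations = lapply(b$populations, function(p) list(
      label = p$label, n = p$n,
      freqs = lapply(p$freqs, function(fr) unlist(fr))))))
  cohort_spec(breeds,
              missing_rate = cohort_cfg$missing_rate %||% 0,
              seed = cohort_cfg$seed %||% seed, models = models)
}

#' Predict phenotypes for every dog in an interpreted call table
#'
#' @param calls long table from [interpret_genotypes()].
#' @param models a `gene_catalogue`.
#' @param breed_configs optional named list (breed -> breed_config list
#'   for [predict_phenotype()]).
#' @return `data.frame`, one row per dog, with the report fields as
#'   columns.
#' @export
phenotype_table <- function(calls, models = default_gene_models(),
                            breed_configs = NULL) {
  ids <- unique(calls$dog_id)
  rows <- lapply(ids, function(id) {
    gts <- dog_genotypes(calls, id)
    breed <- calls$breed[calls$dog_id == id][1L]
    bc <- breed_configs[[breed]] %||% list()
    rep_ <- suppressWarnings(predict_phenotype(gts, models,
                                               breed_config = bc))
    flds <- setdiff(names(rep_), "warnings")
    vals <- lapply(rep_[flds], function(v) as.character(v)[1L])
    cbind(data.frame(dog_id = id, breed = breed,
                     stringsAsFactors = FALSE),
          as.data.frame(vals, stringsAsFactors = FALSE))
  })
  do.call(rbind, rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Command-line entry point
#'
#' Subcommands: `simulate`, `interpret`, `freq`, `phenotype`, `faults`,
#' `compare`, `graph`, `run-all`; each takes `--config <path>` and
#' optional `--out <dir>` and `--seed <int>` overrides.  Exit status is
#' nonzero on error or empty output (the wrapper script translates the
#' thrown condition).
#'
#' @param args character vector, default `commandArgs(trailingOnly =
#'   TRUE)`.
#' @return invisibly, the [run_pipeline()] result.
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: caninetraits <subcommand> --config <path> [--out <dir>]",
    "[--seed <int>]\n  subcommands: simulate interpret freq phenotype",
    "faults compare graph run-all")
  if (!length(args)) stop(usage, call. = FALSE)
  sub <- args[1L]; rest <- args[-1L]
  opt <- list()
  i <- 1L
  while (i <= length(rest)) {
    key <- sub("^--", "", rest[i])
    if (i + 1L > length(rest)) stop("missing value for --", key)
    opt[[key]] <- rest[i + 1L]
    i <- i + 2L
  }
  if (is.null(opt$config)) stop(usage, call. = FALSE)
  config <- read_run_config(opt$config)
  if (!is.null(opt$seed)) config$seed <- as.integer(opt$seed)
  step_map <- list(
    simulate = "simulate",
    interpret = c("simulate", "interpret"),
    freq = c("simulate", "interpret", "freq"),
    phenotype = c("simulate", "interpret", "phenotype"),
    faults = c("simulate", "interpret", "freq", "faults"),
    compare = c("simulate", "interpret", "freq", "compare"),
    graph = "graph",
    `run-all` = NULL)
  if (!sub %in% names(step_map)) stop(usage, call. = FALSE)
  if (!identical(sub, "run-all")) {
    steps <- step_map[[sub]]
    if (is.null(config$genotype_table))
      config$steps <- as.list(steps)
    else
      config$steps <- as.list(setdiff(steps, "simulate"))
  }
  run_pipeline(config, outdir = opt$out)
}
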