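#' Per-gene analysis configuration
#'
#' Builds and validates the configuration driving [run_gene()]. All
#' randomness in a run flows from `seed`; two runs with equal configs
#' produce byte-identical reports.
#'
#' @param gene Gene/dataset label used in report rows and file names.
#' @param tree Path to a Newick tree (PAML `#1` foreground labels honoured).
#' @param cds_fasta Path to unaligned in-frame coding sequences (FASTA);
#'   requires `protein_fasta` as back-translation guide.
#' @param protein_fasta Path to the guide protein alignment (FASTA).
#' @param codon_fasta Alternative input: an already-aligned in-frame codon
#'   FASTA (gaps as `-`), bypassing back-translation.
#' @param foreground Optional character vector of tip labels overriding the
#'   tree's own `#1` labels.
#' @param tests Analyses to run: subset of `"branch-site"`, `"clade-model"`,
#'   `"free-ratio"`, `"sitewise"`.
#' @param column_policy Alignment-column policy (see
#'   [drop_unusable_columns()]).
#' @param freq Codon frequency scheme.
#' @param alpha LRT significance threshold.
#' @param posterior_threshold Flagging threshold for divergent-site
#'   posteriors.
#' @param mode Posterior mode `"neb"` or `"beb"`.
#' @param restarts,seed Optimizer restarts and seed.
#' @param outdir Output directory (created if needed).
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(gene = "gene", tree = NULL,
                       cds_fasta = NULL, protein_fasta = NULL,
                       codon_fasta = NULL, foreground = NULL,
                       tests = c("clade-model"),
                       column_policy = "all-gap", freq = "F3x4",
                       alpha = 0.05, posterior_threshold = 0.75,
                       mode = "neb", restarts = 2, seed = 1L,
                       outdir = tempfile("codonsel_run_")) {
  cfg <- list(gene = gene, tree = tree, cds_fasta = cds_fasta,
              protein_fasta = protein_fasta, codon_fasta = codon_fasta,
              foreground = foreground, tests = tests,
              column_policy = column_policy, freq = freq, alpha = alpha,
              posterior_threshold = posterior_threshold, mode = mode,
              restarts = restarts, seed = as.integer(seed), outdir = outdir)
  validate_config(cfg)
  class(cfg) <- "run_config"
  cfg
}

validate_config <- function(cfg) {
  if (is.null(cfg$tree)) stop("config error: a tree path is required")
  paths <- c(tree = cfg$tree, cds_fasta = cfg$cds_fasta,
             protein_fasta = cfg$protein_fasta, codon_fasta = cfg$codon_fasta)
  missing <- paths[!vapply(paths, file.exists, TRUE)]
  if (length(missing))
    stop("config error: missing input file(s): ",
         paste(names(missing), "=", missing, collapse = ", "))
  if (is.null(cfg$codon_fasta) && (is.null(cfg$cds_fasta) || is.null(cfg$protein_fasta)))
    stop("config error: supply codon_fasta, or cds_fasta plus protein_fasta")
  bad <- setdiff(cfg$tests, c("branch-site", "clade-model", "free-ratio", "sitewise"))
  if (length(bad)) stop("config error: unknown test(s): ", paste(bad, collapse = ", "))
  if (cfg$alpha <= 0 || cfg$alpha >= 1 ||
      cfg$posterior_threshold <= 0 || cfg$posterior_threshold >= 1)
    stop("config error: thresholds must lie in (0, 1)")
  invisible(TRUE)
}

#' Load a run configuration from a YAML file
#'
#' Field names follow the arguments of [run_config()]; relative input paths
#' are resolved against the YAML file's directory. Command-line style
#' overrides can be supplied through `...`.
#'
#' @param path YAML file.
#' @param ... Overrides for individual fields.
#' @return A `run_config`.
#' @export
read_run_config <- function(path, ...) {
  raw <- yaml::read_yaml(path)
  over <- list(...)
  raw[names(over)] <- over
  base <- dirname(normalizePath(path))
  for (f in c("tree", "cds_fasta", "protein_fasta", "codon_fasta"))
    if (!is.null(raw[[f]]) && !file.exists(raw[[f]]))
      raw[[f]] <- file.path(base, raw[[f]])
  do.call(run_config, raw)
}

#' Run the full per-gene selection workflow
#'
#' Executes the analysis pipeline on one gene: read inputs, back-translate
#' along the protein guide (if needed), apply the column policy, fit M0
#' (branch lengths and kappa), run the requested selection analyses, and
#' write TSV reports plus a log to the output directory. Any stage failure
#' is reported with its stage name; the startup validation runs before any
#' output is written.
#'
#' @param config A `run_config` (or list accepted by [run_config()], or a
#'   YAML path).
#' @return Invisibly, a list with the fitted objects and report paths.
#' @export
run_gene <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  if (!inherits(config, "run_config")) config <- do.call(run_config, config)
  validate_config(config)
  t0 <- proc.time()[["elapsed"]]
  stages <- character(0)
  timings <- numeric(0)
  stage <- function(name, expr) {
    s <- proc.time()[["elapsed"]]
    out <- tryCatch(force(expr), error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    stages <<- c(stages, name)
    timings <<- c(timings, proc.time()[["elapsed"]] - s)
    out
  }

  inputs <- stage("read-inputs", {
    tree <- read_labeled_tree(file = config$tree)
    if (!is.null(config$foreground))
      tree <- labeled_tree(tree$phylo, foreground = config$foreground)
    aln <- if (!is.null(config$codon_fasta)) {
      codon_alignment(read_fasta(config$codon_fasta, "dna"))
    } else {
      back_translate(read_fasta(config$protein_fasta, "aa"),
                     read_fasta(config$cds_fasta, "dna"))
    }
    list(tree = tree, aln = aln)
  })
  aln <- stage("column-policy",
               drop_unusable_columns(inputs$aln, config$column_policy))
  m0 <- stage("fit-M0",
              fit_codon_model(aln, inputs$tree, "M0", freq = config$freq,
                              restarts = max(config$restarts, 1),
                              seed = config$seed))
  results <- list()
  if ("branch-site" %in% config$tests)
    results$branch_site <- stage("branch-site",
      branch_site_test(aln, inputs$tree, gene = config$gene, m0 = m0,
                       freq = config$freq, alpha = config$alpha,
                       mode = config$mode, restarts = config$restarts,
                       seed = config$seed))
  if ("clade-model" %in% config$tests)
    results$clade_model <- stage("clade-model",
      clade_model_test(aln, inputs$tree, gene = config$gene, m0 = m0,
                       freq = config$freq, alpha = config$alpha,
                       threshold = config$posterior_threshold,
                       mode = config$mode, restarts = config$restarts,
                       seed = config$seed))
  if ("free-ratio" %in% config$tests)
    results$free_ratio <- stage("free-ratio",
      free_ratio(aln, inputs$tree, m0 = m0, freq = config$freq,
                 restarts = config$restarts, seed = config$seed))
  if ("sitewise" %in% config$tests)
    results$sitewise <- stage("sitewise", sitewise_omega(aln, inputs$tree, m0))

  paths <- stage("write-reports", {
    dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
    pre <- file.path(config$outdir, config$gene)
    out <- c(m0 = paste0(pre, "_m0.txt"))
    write_fit_report(m0, out[["m0"]])
    tests <- Filter(function(x) inherits(x, "selection_test"), results)
    if (length(tests)) {
      out["tests"] <- paste0(pre, "_tests.tsv")
      write_test_report(unname(tests), out[["tests"]])
      out["sites"] <- paste0(pre, "_sites.tsv")
      write_site_posteriors(tests[[length(tests)]], out[["sites"]])
    }
    if (!is.null(results$free_ratio)) {
      out["branch_rates"] <- paste0(pre, "_branch_rates.tsv")
      df <- as.data.frame(results$free_ratio)
      write.table(df, out[["branch_rates"]], sep = "\t", quote = FALSE,
                  row.names = FALSE)
      out["tree"] <- paste0(pre, "_annotated.nwk")
      writeLines(c(write_labeled_tree(inputs$tree),
                   "# per-branch dN/dS (child label: omega = dN/dS)",
                   sprintf("# %s: omega=%.4g dN=%.4g dS=%.4g",
                           df$label, df$omega, df$dN, df$dS)),
                 out[["tree"]])
    }
    if (!is.null(results$sitewise)) {
      out["sitewise"] <- paste0(pre, "_sitewise.tsv")
      write.table(results$sitewise, out[["sitewise"]], sep = "\t",
                  quote = FALSE, row.names = FALSE)
    }
    out
  })

  log_path <- file.path(config$outdir, paste0(config$gene, ".log"))
  cfg_chr <- paste(deparse(config[setdiff(names(config), "outdir")]), collapse = "")
  writeLines(c(
    paste0("codonsel version: ", as.character(utils::packageVersion("codonsel"))),
    paste0("config hash: ", config_hash(cfg_chr)),
    paste0("seed: ", config$seed),
    sprintf("stage %-14s %8.2fs", stages, timings),
    sprintf("total %22.2fs", proc.time()[["elapsed"]] - t0)), log_path)
  invisible(list(config = config, m0 = m0, results = results,
                 paths = c(paths, log = log_path)))
}

config_hash <- function(chr) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(chr, tf)
  unname(tools::md5sum(tf))
}

#' Run the spectral-tuning workflow on a species panel
#'
#' Reads an amino-acid FASTA panel, extracts five-sites genotypes against
#' the reference, predicts lambda_max, and writes a TSV report (one row per
#' species; per-sequence failures are collected as annotated rows, not
#' raised).
#'
#' @param panel_fasta Path to the panel FASTA (or named character vector).
#' @param out Output TSV path.
#' @param reference,experimental Passed to [genotype_table()].
#' @return The report data frame, invisibly.
#' @export
run_spectral <- function(panel_fasta, out, reference = NULL,
                         experimental = NULL) {
  panel <- if (is.character(panel_fasta) && length(panel_fasta) == 1L &&
               file.exists(panel_fasta))
    read_fasta(panel_fasta, "aa") else panel_fasta
  df <- genotype_table(panel, reference = reference,
                       experimental = experimental)
  write.table(df, out, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
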