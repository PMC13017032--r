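#' Run configuration for the full pipeline
#'
#' Collects the per-stage settings and the global seed; serialisable to
#' and from YAML. Unknown keys are rejected.
#'
#' @param sim a [sim_config()] (or list of its arguments).
#' @param caller a [caller_config()] (or list of its arguments).
#' @param af_bin_edges AF bin edges for the burden table.
#' @param sc an [sc_filters()] (or list of its arguments).
#' @param seed global seed; each stage derives a child seed from it by a
#'   stable hash of the stage name, so stages are individually
#'   reproducible.
#' @param out_dir output directory.
#' @return list of class `run_config`.
#' @export
run_config <- function(sim = sim_config(), caller = caller_config(),
                       af_bin_edges = c(0.015, 0.05, 0.15, 0.35),
                       sc = sc_filters(), seed = 1L, out_dir = tempfile()) {
  if (is.list(sim) && !inherits(sim, "sim_config"))
    sim <- do.call(sim_config, sim)
  if (is.list(caller) && !inherits(caller, "caller_config"))
    caller <- do.call(caller_config, caller)
  if (is.list(sc) && !inherits(sc, "sc_filters"))
    sc <- do.call(sc_filters, sc)
  sim$seed <- as.integer(seed)
  structure(list(sim = sim, caller = caller, af_bin_edges = af_bin_edges,
                 sc = sc, seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

#' Read / write a run configuration as YAML
#'
#' @param path YAML path.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- c("sim", "caller", "af_bin_edges", "sc", "seed", "out_dir")
  unknown <- setdiff(names(y), known)
  if (length(unknown) > 0)
    .stopf("unknown config key(s): %s", paste(unknown, collapse = ", "))
  args <- list()
  if (!is.null(y$sim)) {
    if (!is.null(y$sim$n_samples)) y$sim$n_samples <-
        unlist(y$sim$n_samples)
    if (!is.null(y$sim$somatic_rate)) y$sim$somatic_rate <-
        unlist(y$sim$somatic_rate)
    if (!is.null(y$sim$vaf_range)) y$sim$vaf_range <- unlist(y$sim$vaf_range)
    args$sim <- y$sim
  }
  if (!is.null(y$caller)) args$caller <- y$caller
  if (!is.null(y$af_bin_edges)) args$af_bin_edges <- unlist(y$af_bin_edges)
  if (!is.null(y$sc)) args$sc <- y$sc
  if (!is.null(y$seed)) args$seed <- y$seed
  if (!is.null(y$out_dir)) args$out_dir <- y$out_dir
  do.call(run_config, args)
}

#' @rdname read_run_config
#' @param config a `run_config`.
#' @export
write_run_config <- function(config, path) {
  y <- list(sim = unclass(config$sim), caller = unclass(config$caller),
            af_bin_edges = config$af_bin_edges, sc = unclass(config$sc),
            seed = config$seed, out_dir = config$out_dir)
  y$sim$n_samples <- as.list(y$sim$n_samples)
  y$sim$somatic_rate <- as.list(y$sim$somatic_rate)
  yaml::write_yaml(y, path)
  invisible(path)
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Chains the stages in dependency order: panel + cohort simulation,
#' per-sample variant calling (consensus pileups are simulated directly at
#' cohort scale), burden table + group enrichment GLM + per-gene ratios,
#' single-cell simulation + cell-type calling + per-cell burden +
#' cell-type contrasts, mutational-signature refit of the pooled somatic
#' calls, and gene-set enrichment. All stage outputs are written as
#' plain-text files under `config$out_dir` and a JSON manifest with file
#' checksums and row counts is written at completion. Identical config and
#' seed reproduce identical outputs.
#'
#' @param config a [run_config()].
#' @param genes panel gene symbols (default the seven-gene demo panel).
#' @param quiet suppress progress messages.
#' @return list with every stage result plus `manifest`.
#' @export
run_pipeline <- function(config = run_config(), genes = DEFAULT_PANEL_GENES,
                         quiet = FALSE) {
  t0 <- Sys.time()
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))
  outf <- function(name) file.path(config$out_dir, name)

  say("stage 1/6: simulate panel + cohort")
  panel <- generate_panel(genes, seed = config$seed)
  meta <- simulate_metadata(config$sim)
  write_fasta(panel$reference, outf("panel.fa"))
  write_bed(panel$targets, outf("targets.bed"))
  write_gene_model(panel$gene_model, outf("gene_model.tsv"))
  write_metadata(meta, outf("metadata.tsv"))

  say("stage 2/6: per-sample calling")
  calls_by_sample <- list()
  truth_by_sample <- list()
  for (i in seq_len(nrow(meta))) {
    sim <- simulate_sample(panel, meta[i, ], config$sim)
    truth_by_sample[[meta$sample_id[i]]] <- sim$truth
    calls <- call_variants(sim$pileup, config$caller, panel$gene_model)
    calls_by_sample[[meta$sample_id[i]]] <- calls
  }
  truth_all <- do.call(rbind, truth_by_sample)
  write_vcf(truth_all, outf("truth.vcf"))
  calls_all <- .rbind_fill(lapply(names(calls_by_sample), function(s) {
    d <- calls_by_sample[[s]]
    d$sample_id <- rep(s, nrow(d))
    d
  }))
  write_vcf(calls_all, outf("calls.vcf"))

  say("stage 3/6: burden table + enrichment GLM")
  burden <- build_burden(calls_by_sample, meta, config$af_bin_edges)
  write.table(burden, outf("burden.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  glm_fit <- burden_test(burden)
  tt <- summary_t_test(burden, "sALS", "control")
  ratios <- gene_burden_ratio(burden, "sALS", "control")
  glm_report <- list(
    coefficients = as.list(coef(glm_fit)),
    se = as.list(glm_fit$se), p_value = as.list(glm_fit$p_value),
    theta = glm_fit$theta, converged = glm_fit$converged,
    t_test = tt[c("mu", "sigma", "t", "p_value")])
  jsonlite::write_json(glm_report, outf("glm_report.json"),
                       auto_unbox = TRUE, digits = NA)
  write.table(ratios, outf("gene_ratios.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)

  say("stage 4/6: single-cell calling + burden")
  cts <- data.frame(
    cell_type = c("excitatory", "inhibitory", "astrocyte", "microglia",
                  "oligodendrocyte", "OPC"),
    n_cells = c(60, 40, 40, 30, 30, 20))
  clones <- data.frame(cell_type = "excitatory", carrier_fraction = 0.25,
                       n_clones = 6)
  sc <- simulate_sc_cohort(cts, clones,
                           list(n_sites = 120, seed = config$seed))
  write_sc_pileup(sc$pileup, outf("sc_pileup.tsv"))
  ctp <- aggregate_by_celltype(sc$pileup, sc$annotations)
  sc_vars <- call_sc_variants(ctp, config$sc)
  write.table(sc_vars, outf("sc_variants.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  cell_burden <- per_cell_burden(sc_vars, sc$pileup, sc$annotations)
  write.table(cell_burden, outf("cell_burden.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  contrasts <- tryCatch(compare_celltype_burden(cell_burden),
                        error = function(e) NULL)

  say("stage 5/6: mutational signatures")
  som <- calls_all[calls_all$classification == "somatic", , drop = FALSE]
  catalog <- synthetic_signature_catalog()
  spectrum <- context_spectrum(som, panel$reference)
  exposure <- fit_signatures(spectrum, catalog)
  write.table(data.frame(channel = names(spectrum),
                         count = as.integer(spectrum)),
              outf("spectrum.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)

  say("stage 6/6: gene-set enrichment")
  tgt <- panel$targets
  weights <- setNames(tgt$end - tgt$start, tgt$name)
  half <- max(1, floor(length(genes) / 2))
  sets <- list(als_core = genes[seq_len(half)])
  if (half < length(genes))
    sets$panel_rest <- genes[(half + 1):length(genes)]
  snv_genes <- som$gene_symbol[!is.na(som$gene_symbol)]
  enrich <- geneset_burden_test(snv_genes, sets, weights,
                                seed = config$seed)
  write.table(enrich, outf("geneset_enrichment.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  files <- list.files(config$out_dir, full.names = TRUE)
  files <- setdiff(files, outf("manifest.json"))
  manifest <- list(
    package_version = as.character(utils::packageVersion("mosaicburden")),
    seed = config$seed,
    n_samples = nrow(meta),
    n_calls = nrow(calls_all),
    n_somatic = nrow(som),
    n_sc_variants = sum(sc_vars$status == "somatic"),
    checksums = as.list(tools::md5sum(sort(files))),
    elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  jsonlite::write_json(manifest, outf("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(list(panel = panel, meta = meta, truth = truth_by_sample,
                 calls = calls_by_sample, burden = burden, glm = glm_fit,
                 t_test = tt, ratios = ratios, sc = sc, sc_variants = sc_vars,
                 cell_burden = cell_burden, contrasts = contrasts,
                 spectrum = spectrum, exposure = exposure, enrich = enrich,
                 manifest = manifest))
}
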