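#' Pipeline configuration
#'
#' Collects everything [run_pipeline] needs: either file paths to an OTU
#' table, environment map and (optionally) chemistry and taxonomy, or a
#' [community_config] to simulate inputs from; plus the analysis knobs. The
#' configuration hash written into every output is the MD5 of the canonical
#' JSON serialization of the config (excluding the output directory), so two
#' runs of the same config and seed are byte-identical.
#'
#' @param otu_table path to an OTU table TSV, or an [otu_table] object.
#' @param env_map path to the environment map TSV, or a named vector
#'   (ignored when `otu_table` is an object carrying labels).
#' @param chemistry optional path to a chemistry TSV or [chemistry_table];
#'   when absent, the correlation stage is skipped with a notice.
#' @param taxonomy optional path to a taxonomy TSV or taxonomy data.frame;
#'   when absent, the core-composition stage is skipped with a notice.
#' @param simulate optional [community_config]; when given, inputs are
#'   generated (and written to `out_dir/data/`) instead of read.
#' @param threshold,abundance_basis see [classify_otus].
#' @param null_method,n_null,n_permutations,alpha see [stochasticity_test].
#' @param rank taxonomic rank for the core composition.
#' @param seed top-level integer seed; per-stage sub-seeds are derived from
#'   it with [derive_seed].
#' @param out_dir output directory (created if needed).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(otu_table = NULL, env_map = NULL, chemistry = NULL,
                            taxonomy = NULL, simulate = NULL,
                            threshold = 0.02,
                            abundance_basis = c("occupied", "all"),
                            null_method = c("regional_multinomial", "row_shuffle"),
                            n_null = 6, n_permutations = 999, alpha = 0.05,
                            rank = "genus", seed = 1, out_dir = "minecore_out") {
  abundance_basis <- match.arg(abundance_basis)
  null_method <- match.arg(null_method)
  if (is.null(simulate) && is.null(otu_table))
    .stopf("either an OTU table or a simulation config is required")
  for (p in c("otu_table", "env_map", "chemistry", "taxonomy")) {
    v <- get(p)
    if (is.character(v) && length(v) == 1 && !file.exists(v))
      .stopf("%s path does not exist: %s", p, v)
  }
  structure(list(otu_table = otu_table, env_map = env_map,
                 chemistry = chemistry, taxonomy = taxonomy,
                 simulate = simulate, threshold = threshold,
                 abundance_basis = abundance_basis,
                 null_method = null_method, n_null = n_null,
                 n_permutations = n_permutations, alpha = alpha, rank = rank,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

.config_hash <- function(cfg) {
  keep <- cfg[setdiff(names(cfg), "out_dir")]
  keep <- lapply(keep, function(x) {
    if (is.character(x) && length(x) == 1 && file.exists(x)) unname(tools::md5sum(x))
    else if (inherits(x, "community_config") || inherits(x, "otu_table"))
      unclass(x)
    else x
  })
  js <- jsonlite::toJSON(keep, auto_unbox = TRUE, digits = NA, force = TRUE,
                         null = "null")
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(as.character(js), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full analysis pipeline
#'
#' Sequences the analysis end-to-end: load or simulate inputs, normalize,
#' classify generalists/specialists per environment, extract the core
#' microbiota and its composition, screen classified OTUs against chemistry,
#' and run the pooled stochasticity test. Writes, per environment,
#' `niche_<env>.tsv`, `core_<env>.tsv`, `core_composition_<env>.tsv` and
#' `correlations_<env>.tsv`; pooled `stochasticity.tsv`; a human-readable
#' `report.md`; a machine-readable `manifest.json` (version, config hash,
#' seed, outputs); and `run.log`. Outputs are deterministic given config and
#' seed (only `run.log` carries timestamps).
#'
#' @param cfg a [pipeline_config].
#' @param quiet suppress console messages.
#' @return (invisibly) a list with all in-memory stage results and the paths
#'   of the written files.
#' @export
run_pipeline <- function(cfg, quiet = FALSE) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(cfg$out_dir, "run.log")
  log_con <- file(log_path, open = "wt")
  on.exit(close(log_con))
  say <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    writeLines(paste0(format(Sys.time(), "%Y-%m-%d %H:%M:%S "), msg), log_con)
    if (!quiet) message(msg)
  }
  hash <- .config_hash(cfg)
  meta <- list(config_hash = hash, seed = cfg$seed)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      say("stage '%s' FAILED: %s", name, conditionMessage(e))
      .stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e))
    })
  }
  say("minecore %s | config hash %s | seed %d", .mc_version(), hash, cfg$seed)

  # ---- inputs ----
  sim <- NULL
  if (!is.null(cfg$simulate)) {
    sim <- stage("simulate",
                 generate_community(cfg$simulate, seed = derive_seed(cfg$seed, 0)))
    ot <- sim$otu
    chem <- sim$chemistry
    tax <- sim$taxonomy
    data_dir <- file.path(cfg$out_dir, "data")
    dir.create(data_dir, showWarnings = FALSE)
    write_table(ot, file.path(data_dir, "otu_table.tsv"), meta)
    write_env_map(ot$environment, file.path(data_dir, "env_map.tsv"), meta)
    write_table(chem, file.path(data_dir, "chemistry.tsv"), meta)
    write_table(sim$truth$labels, file.path(data_dir, "truth_labels.tsv"), meta)
    say("simulated %d OTUs x %d samples", nrow(ot$counts), ncol(ot$counts))
  } else {
    ot <- stage("load", {
      if (inherits(cfg$otu_table, "otu_table")) cfg$otu_table
      else read_otu_table(cfg$otu_table, cfg$env_map)
    })
    chem <- stage("load", {
      if (is.null(cfg$chemistry)) NULL
      else if (inherits(cfg$chemistry, "chemistry_table")) cfg$chemistry
      else read_chemistry(cfg$chemistry)
    })
    tax <- stage("load", {
      if (!is.null(cfg$taxonomy)) {
        if (is.data.frame(cfg$taxonomy)) cfg$taxonomy
        else read_taxonomy(cfg$taxonomy)
      } else attr(ot, "taxonomy")
    })
    say("loaded %d OTUs x %d samples", nrow(ot$counts), ncol(ot$counts))
  }

  envs <- unique(unname(ot$environment))
  results <- list(otu = ot, chemistry = chem, taxonomy = tax, simulated = sim,
                  niche = list(), core = list(), composition = list(),
                  correlations = list())
  files <- character(0)
  report <- c(sprintf("# minecore report"), "",
              sprintf("- version: %s", .mc_version()),
              sprintf("- config hash: %s", hash),
              sprintf("- seed: %d", cfg$seed),
              sprintf("- OTUs: %d, samples: %d", nrow(ot$counts), ncol(ot$counts)),
              "")

  for (env in envs) {
    nc <- stage("classify", classify_otus(ot, env, threshold = cfg$threshold,
                                          abundance_basis = cfg$abundance_basis))
    results$niche[[env]] <- nc
    f <- file.path(cfg$out_dir, sprintf("niche_%s.tsv", env))
    write_table(nc, f, meta); files <- c(files, f)
    n_gen <- sum(nc$label == "generalist")
    n_spec <- sum(nc$label == "specialist")

    core <- stage("core", core_microbiota(ot, env))
    results$core[[env]] <- core
    core_df <- data.frame(otu_id = core$otu_ids,
                          total_counts = as.integer(core$totals),
                          stringsAsFactors = FALSE)
    f <- file.path(cfg$out_dir, sprintf("core_%s.tsv", env))
    write_table(core_df, f, meta); files <- c(files, f)

    comp_line <- "core composition: skipped (no taxonomy supplied)"
    if (!is.null(tax) && core$n_core > 0) {
      comp <- stage("composition", core_composition(ot, core, tax, rank = cfg$rank))
      results$composition[[env]] <- comp
      f <- file.path(cfg$out_dir, sprintf("core_composition_%s.tsv", env))
      write_table(comp, f, meta); files <- c(files, f)
      comp_line <- sprintf("dominant core %s: %s (%.1f%% of core sequences)",
                           cfg$rank, comp$taxon[1], comp$share_pct[1])
    } else say("composition for '%s' skipped: no taxonomy", env)

    corr_line <- "correlations: skipped (no chemistry supplied)"
    if (!is.null(chem)) {
      focal <- nc$otu_id[nc$label != "other"]
      if (length(focal)) {
        co <- stage("correlate",
                    correlate(ot, chem, focal, environment = env,
                              alpha = cfg$alpha))
        results$correlations[[env]] <- co
        f <- file.path(cfg$out_dir, sprintf("correlations_%s.tsv", env))
        write_table(co, f, meta); files <- c(files, f)
        corr_line <- sprintf("correlations: %d of %d (otu, parameter) pairs significant at p < %g",
                             sum(co$significant), nrow(co), cfg$alpha)
      } else {
        corr_line <- "correlations: skipped (no generalist or specialist OTUs)"
        say("correlation for '%s' skipped: nothing classified", env)
      }
    } else say("correlation for '%s' skipped: no chemistry", env)

    say("%s: %d generalists, %d specialists, core %d OTUs",
        env, n_gen, n_spec, core$n_core)
    report <- c(report, sprintf("## %s", env), "",
                sprintf("- generalists: %d", n_gen),
                sprintf("- specialists: %d", n_spec),
                sprintf("- core microbiota: %d OTUs", core$n_core),
                sprintf("- %s", comp_line),
                sprintf("- %s", corr_line), "")
  }

  st <- stage("stochasticity",
              stochasticity_test(ot, n_null = cfg$n_null,
                                 n_permutations = cfg$n_permutations,
                                 alpha = cfg$alpha,
                                 seed = derive_seed(cfg$seed, 9),
                                 method = cfg$null_method))
  results$stochasticity <- st
  st_df <- data.frame(F = st$permdisp$F, p = st$permdisp$p,
                      n_null = st$n_null,
                      n_permutations = st$permdisp$n_permutations,
                      mean_dispersion_observed = unname(st$permdisp$group_means["observed"]),
                      mean_dispersion_null = unname(st$permdisp$group_means["null"]),
                      verdict = st$verdict, seed = cfg$seed,
                      stringsAsFactors = FALSE)
  f <- file.path(cfg$out_dir, "stochasticity.tsv")
  write_table(st_df, f, meta); files <- c(files, f)
  say("stochasticity: F = %.4g, p = %.4g -> %s", st$permdisp$F, st$permdisp$p,
      st$verdict)
  report <- c(report, "## Assembly stochasticity (pooled)", "",
              sprintf("- PERMDISP F = %.4g, p = %.4g (%d null replicates, %d permutations)",
                      st$permdisp$F, st$permdisp$p, st$n_null,
                      st$permdisp$n_permutations),
              sprintf("- verdict at alpha = %g: %s", cfg$alpha, st$verdict), "")

  report_path <- file.path(cfg$out_dir, "report.md")
  writeLines(report, report_path)
  manifest <- list(tool = "minecore", version = .mc_version(),
                   config_hash = hash, seed = cfg$seed,
                   outputs = basename(c(files, report_path)))
  manifest_path <- file.path(cfg$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, pretty = TRUE)
  say("wrote %d result files to %s", length(files) + 2, cfg$out_dir)
  results$files <- c(files, report_path, manifest_path)
  invisible(results)
}
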