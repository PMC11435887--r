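default_pipeline_params <- function() {
  list(
    rare_max_total = 2,
    low_count_min = 4,
    low_count_prevalence = 0.20,
    low_variance_drop = 0.10,
    aggregation_rank = "genus",
    other_threshold_genus = 0.01,
    other_threshold_species = 0.014,
    da_prevalence = 0.30,
    da_winsor = 0.97,
    da_pseudocount = 0.5,
    permutations = 999,
    shannon_base = "e",
    baseline_visit = "endoscopy",
    fdm_convention = "dry_over_wet"
  )
}

#' Load and validate a pipeline configuration
#'
#' The YAML config has exactly one of an `input:` block (paths to
#' `feature_table`, `taxonomy`, `metadata` and optional clinical CSVs) or
#' a `simulate:` block ([trial_sim_config()] fields).  A `params:` block
#' overrides stage parameters; every parameter defaults to the
#' pipeline's standard value (rare-ASV total 2, low-count 4 in 20%, IQR
#' drop 10%, genus aggregation, "Other" at 1%/1.4%, DA prevalence 30%
#' and winsorisation 0.97, 999 permutations).  Unknown keys are
#' rejected so typos surface early.
#'
#' @param path YAML file
#' @return a validated `pipeline_config` list with `mode`
#'   ("input"/"simulate"), `input` or `sim`, `params`, `stages`, `seed`
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("no such config: ", path)
  cfg <- yaml::read_yaml(path)
  known_top <- c("input", "simulate", "params", "stages", "seed")
  unknown <- setdiff(names(cfg), known_top)
  if (length(unknown) > 0)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  has_input <- !is.null(cfg$input)
  has_sim <- !is.null(cfg$simulate)
  if (has_input == has_sim)
    stop("config must have exactly one of 'input' or 'simulate'")
  params <- default_pipeline_params()
  if (!is.null(cfg$params)) {
    unknown <- setdiff(names(cfg$params), names(params))
    if (length(unknown) > 0)
      stop("unknown params key(s): ", paste(unknown, collapse = ", "))
    params[names(cfg$params)] <- cfg$params
  }
  stages_all <- c("composition", "diversity", "differential_abundance",
                  "engraftment", "clinical")
  stages <- cfg$stages %||% stages_all
  unknown <- setdiff(stages, stages_all)
  if (length(unknown) > 0)
    stop("unknown stage(s): ", paste(unknown, collapse = ", "))
  seed <- cfg$seed %||% 1L
  if (has_input) {
    known_in <- c("feature_table", "taxonomy", "metadata", "disposition",
                  "ccecai", "fcs_diary", "fdm", "regression_pairs")
    unknown <- setdiff(names(cfg$input), known_in)
    if (length(unknown) > 0)
      stop("unknown input key(s): ", paste(unknown, collapse = ", "))
    needed <- c("feature_table", "metadata")
    missing <- setdiff(needed, names(cfg$input))
    if (length(missing) > 0)
      stop("input block is missing: ", paste(missing, collapse = ", "))
    structure(list(mode = "input", input = cfg$input, params = params,
                   stages = stages, seed = seed),
              class = "pipeline_config")
  } else {
    sim_args <- cfg$simulate
    ok <- names(formals(trial_sim_config))
    unknown <- setdiff(names(sim_args), ok)
    if (length(unknown) > 0)
      stop("unknown simulate key(s): ", paste(unknown, collapse = ", "))
    if (!is.null(sim_args$relapse_prob))
      sim_args$relapse_prob <- unlist(sim_args$relapse_prob)
    sim_args$seed <- sim_args$seed %||% seed
    sim <- do.call(trial_sim_config, sim_args)
    structure(list(mode = "simulate", sim = sim, params = params,
                   stages = stages, seed = seed),
              class = "pipeline_config")
  }
}

#' Run the analysis pipeline end to end
#'
#' Stages, in order: ingest (read or simulate the dataset), rare-ASV
#' removal, low-count and low-variance filters, taxonomic aggregation,
#' total-sum scaling, then the toggled analysis stages (composition
#' summaries, alpha/beta diversity, differential abundance per arm,
#' donor engraftment, clinical outcomes), and the run report.  All
#' randomness flows from the config seed, so a rerun with the same
#' config reproduces every output bit-exact.
#'
#' @param config a `pipeline_config` from [load_config()], or a path to a
#'   YAML config
#' @param out_dir directory for stage outputs (created if needed)
#' @return a `run_report` list: per-stage output paths, effective
#'   parameters, seed, package version, collected warnings
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- load_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  params <- config$params
  warnings <- character(0)
  note <- function(msg) warnings <<- c(warnings, msg)
  outputs <- list()

  # -- ingest ---------------------------------------------------------
  if (config$mode == "simulate") {
    input_dir <- file.path(out_dir, "input")
    bundle <- make_fixture_dataset(config$sim, out_dir = input_dir)
    table <- bundle$table
    metadata <- bundle$metadata
    clinical <- bundle$clinical
    outputs$input <- input_dir
  } else {
    tx <- if (!is.null(config$input$taxonomy))
      read_taxonomy(config$input$taxonomy) else NULL
    table <- read_asv_table(config$input$feature_table,
                            format = if (grepl("\\.biom$",
                                               config$input$feature_table))
                              "biom" else "tsv",
                            taxonomy = tx)
    metadata <- read_metadata(config$input$metadata)
    clinical <- list(
      disposition = if (!is.null(config$input$disposition))
        read_disposition(config$input$disposition) else NULL,
      regression_pairs = if (!is.null(config$input$regression_pairs))
        utils::read.csv(config$input$regression_pairs) else NULL)
  }
  miss <- setdiff(rownames(table$counts), metadata$sample_id)
  if (length(miss) > 0)
    stop("stage ingest: sample(s) missing from metadata: ",
         paste(miss, collapse = ", "))

  run_stage <- function(name, expr) {
    withCallingHandlers(
      tryCatch(expr, error = function(e)
        stop("stage ", name, ": ", conditionMessage(e), call. = FALSE)),
      warning = function(w) {
        note(paste0(name, ": ", conditionMessage(w)))
        invokeRestart("muffleWarning")
      })
  }

  # -- feature-table processing --------------------------------------
  rare_filtered <- run_stage("rare_filter",
    remove_rare_asvs(table, params$rare_max_total))
  processed <- run_stage("filters", {
    t2 <- low_count_filter(rare_filtered, params$low_count_min,
                           params$low_count_prevalence)
    low_variance_filter(t2, params$low_variance_drop)
  })
  aggregated <- run_stage("aggregate",
    if (!is.null(processed$taxonomy))
      aggregate_taxa(processed, params$aggregation_rank)
    else processed)
  rel <- run_stage("scaling", total_sum_scaling(aggregated))
  write_asv_table(aggregated,
                  file.path(out_dir, "aggregated_counts.tsv"))
  outputs$aggregated <- file.path(out_dir, "aggregated_counts.tsv")

  # -- composition ----------------------------------------------------
  if ("composition" %in% config$stages) {
    thr <- if (params$aggregation_rank == "species")
      params$other_threshold_species else params$other_threshold_genus
    comp <- run_stage("composition", collapse_other(rel, thr))
    f <- file.path(out_dir, "composition.tsv")
    utils::write.table(
      data.frame(sample_id = rownames(comp$proportions),
                 comp$proportions, check.names = FALSE),
      f, sep = "\t", quote = FALSE, row.names = FALSE)
    outputs$composition <- f
  }

  # -- diversity ------------------------------------------------------
  if ("diversity" %in% config$stages) {
    div <- run_stage("diversity", {
      log_base <- if (identical(params$shannon_base, "e")) exp(1)
      else as.numeric(params$shannon_base)
      alpha <- alpha_diversity(rel, base = log_base)
      md <- metadata[match(names(alpha), metadata$sample_id), ]
      groups <- split(alpha, md$group)
      kw <- if (length(groups) >= 2) kruskal_wallis(groups) else NULL
      dm <- bray_curtis_matrix(rel)
      pv <- if (length(unique(md$group)) >= 2 &&
                all(table(md$group) >= 2))
        permanova(dm, md$group, n_permutations = params$permutations,
                  seed = config$seed)
      else NULL
      list(alpha = alpha, kw = kw, dm = dm, permanova = pv)
    })
    f <- file.path(out_dir, "alpha_diversity.tsv")
    utils::write.table(
      data.frame(sample_id = names(div$alpha), shannon = div$alpha),
      f, sep = "\t", quote = FALSE, row.names = FALSE)
    outputs$alpha <- f
    f <- file.path(out_dir, "bray_curtis.tsv")
    utils::write.table(
      data.frame(sample_id = rownames(div$dm$distances),
                 div$dm$distances, check.names = FALSE),
      f, sep = "\t", quote = FALSE, row.names = FALSE)
    outputs$beta <- f
    if (!is.null(div$permanova)) {
      f <- file.path(out_dir, "permanova.tsv")
      utils::write.table(
        data.frame(pseudo_F = div$permanova$pseudo_F,
                   p_value = div$permanova$p_value,
                   n_permutations = div$permanova$n_permutations,
                   seed = div$permanova$seed),
        f, sep = "\t", quote = FALSE, row.names = FALSE)
      outputs$permanova <- f
    }
  }

  # -- differential abundance (per arm, pre vs post) -----------------
  if ("differential_abundance" %in% config$stages) {
    da_out <- run_stage("differential_abundance", {
      cfg <- da_config(prevalence_cutoff = params$da_prevalence,
                       winsor_quantile = params$da_winsor,
                       pseudocount = params$da_pseudocount)
      res <- list()
      for (arm in c("FMT", "placebo")) {
        sids <- metadata$sample_id[metadata$group == arm]
        sids <- intersect(rownames(aggregated$counts), sids)
        if (length(sids) == 0) next
        sub <- asv_table(aggregated$counts[sids, , drop = FALSE])
        sub <- prevalence_filter(sub, cfg$prevalence_cutoff)
        if (ncol(sub$counts) < 3) next
        subrel <- total_sum_scaling(sub)
        fit <- try(fit_da(subrel, metadata, cfg), silent = TRUE)
        if (!inherits(fit, "try-error")) res[[arm]] <- fit
        else note(paste0("differential_abundance: arm ", arm,
                         " skipped (", attr(fit, "condition")$message, ")"))
      }
      res
    })
    for (arm in names(da_out)) {
      f <- file.path(out_dir, paste0("da_", tolower(arm), ".tsv"))
      utils::write.table(da_out[[arm]], f, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      outputs[[paste0("da_", tolower(arm))]] <- f
    }
  }

  # -- engraftment ----------------------------------------------------
  if ("engraftment" %in% config$stages) {
    has_fmt <- any(metadata$group == "FMT")
    has_donor <- any(metadata$group == "donor")
    if (!has_fmt || !has_donor) {
      note(paste0("engraftment: skipped (requires donor and FMT ",
                  "samples)"))
    } else {
      eng <- run_stage("engraftment",
        engraftment_analysis(table, metadata,
                             max_total = params$rare_max_total,
                             baseline_visit = params$baseline_visit))
      f <- file.path(out_dir, "engraftment.tsv")
      utils::write.table(engraftment_table(eng), f, sep = "\t",
                         quote = FALSE, row.names = FALSE)
      outputs$engraftment <- f
      if (!is.null(eng$summary)) {
        freq <- eng$summary$asv_frequency
        f2 <- file.path(out_dir, "engraftment_asv_frequency.tsv")
        utils::write.table(
          data.frame(asv_id = names(freq), n_recipients = freq),
          f2, sep = "\t", quote = FALSE, row.names = FALSE)
        outputs$engraftment_frequency <- f2
      }
      for (dog in names(eng$excluded))
        note(paste0("engraftment: dog ", dog, " excluded (",
                    eng$excluded[dog], ")"))
    }
  }

  # -- clinical -------------------------------------------------------
  if ("clinical" %in% config$stages && !is.null(clinical$disposition)) {
    clin <- run_stage("clinical", {
      po <- phase_outcomes(clinical$disposition)
      reg <- if (!is.null(clinical$regression_pairs))
        fcs_fdm_regression(clinical$regression_pairs$fdm_percent,
                           clinical$regression_pairs$fcs)
      else NULL
      list(outcomes = po, regression = reg)
    })
    f <- file.path(out_dir, "disposition_summary.tsv")
    utils::write.table(clin$outcomes$outcomes, f, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    outputs$disposition <- f
    if (!is.null(clin$regression)) {
      f <- file.path(out_dir, "fcs_fdm_regression.tsv")
      utils::write.table(as.data.frame(clin$regression), f, sep = "\t",
                         quote = FALSE, row.names = FALSE)
      outputs$regression <- f
    }
  }

  report <- structure(list(
    outputs = outputs,
    params = params,
    stages = config$stages,
    seed = config$seed,
    mode = config$mode,
    package_version = as.character(utils::packageVersion("fmtkit")),
    warnings = warnings), class = "run_report")
  write_report(report, file.path(out_dir, "run_report.json"))
  report
}

#' Write a run report as JSON
#'
#' Serialisation is stable: re-serialising an unchanged report is
#' idempotent, so report checksums can certify reproducibility.
#'
#' @param report a `run_report` from [run_pipeline()]
#' @param path destination JSON file
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "run_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(path)
}

#' @export
print.run_report <- function(x, ...) {
  cat("fmtkit run report (seed ", x$seed, ", mode ", x$mode, ")\n",
      sep = "")
  cat("  outputs:\n")
  for (nm in names(x$outputs))
    cat("    ", nm, ": ", x$outputs[[nm]], "\n", sep = "")
  if (length(x$warnings) > 0) {
    cat("  warnings:\n")
    for (w in x$warnings) cat("    - ", w, "\n", sep = "")
  }
  invisible(x)
}
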