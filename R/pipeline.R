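# Subset a pair_features object to a sample-id vector (keeping given order).
subset_samples <- function(features, ids) {
  miss <- setdiff(ids, colnames(features$values))
  if (length(miss) > 0) stop("sample missing from features: ", miss[1])
  new_pair_features(features$pairs, features$values[, ids, drop = FALSE])
}

#' Assemble a pipeline configuration
#'
#' Bundles the data source, stage parameters and output directory for
#' [run_pipeline()]. Defaults follow the method's standard settings:
#' Bonferroni-adjusted screen at `1e-20`, 100 stability repeats with the
#' occurrence threshold at 50 (or tuned over 10, 20, ..., 100), 10-fold
#' cross-validation, 8:2 discovery split, and survival horizons 1, 3, 5.
#'
#' @param synthetic A `pairdx_config` ([synthetic_config()] or a preset)
#'   to simulate from, or `NULL` when reading fixtures.
#' @param input_dir Fixture directory ([write_fixtures()] layout) to read
#'   when `synthetic` is `NULL`.
#' @param out_dir Output directory; stage outputs land in
#'   `<out_dir>/<stage>/`.
#' @param alpha_threshold Screen significance level on adjusted p.
#' @param n_repeats Stability-selection repeats.
#' @param occurrence_threshold Integer threshold, or `"auto"` to tune on
#'   the held-out discovery part over `occurrence_grid`.
#' @param occurrence_grid Grid for `"auto"` tuning.
#' @param cv_folds Cross-validation folds for the penalized fits.
#' @param horizons Survival ROC horizons.
#' @param fraction_train Discovery train fraction.
#' @param seed Master seed; all stage randomness derives from named
#'   substreams of it.
#' @return A `pairdx_pipeline_config` list.
#' @export
pipeline_config <- function(synthetic = NULL, input_dir = NULL, out_dir,
                            alpha_threshold = 1e-20, n_repeats = 100,
                            occurrence_threshold = 50,
                            occurrence_grid = seq(10L, 100L, by = 10L),
                            cv_folds = 10, horizons = c(1, 3, 5),
                            fraction_train = 0.8, seed = 1L) {
  if (is.null(synthetic) && is.null(input_dir))
    stop("provide either a synthetic config or an input directory")
  if (!is.null(synthetic)) stopifnot(inherits(synthetic, "pairdx_config"))
  if (!is.null(input_dir) && !dir.exists(input_dir))
    stop("input directory does not exist: ", input_dir)
  if (!identical(occurrence_threshold, "auto") &&
      occurrence_threshold > n_repeats)
    stop("occurrence_threshold exceeds n_repeats")
  structure(list(synthetic = synthetic, input_dir = input_dir,
                 out_dir = out_dir, alpha_threshold = alpha_threshold,
                 n_repeats = n_repeats,
                 occurrence_threshold = occurrence_threshold,
                 occurrence_grid = occurrence_grid, cv_folds = cv_folds,
                 horizons = horizons, fraction_train = fraction_train,
                 seed = as.integer(seed)),
            class = "pairdx_pipeline_config")
}

#' Run the end-to-end gene-pair pipeline
#'
#' Executes, in order: data (simulate or read) -> candidate pairs ->
#' exact screen -> stability-selected diagnostic model with comparator
#' AUCs -> prognostic Cox model (skipped when no survival table is
#' available) -> gene-set enrichment of the final model's genes. Each
#' stage writes its TSV/model outputs under `<out_dir>/<stage>/`, logs
#' one summary line, and contributes to a JSON run manifest (parameters,
#' seed, per-stage summaries, md5 of every output file). Two runs with
#' the same configuration produce bit-identical outputs and manifests. A
#' stage failure halts the run with the failing stage named.
#'
#' @param config A `pairdx_pipeline_config`, or a path to a YAML file
#'   with fields `preset` (one of `"diagnostic"`, `"prognostic"`,
#'   `"table1"`), `out_dir`, and optionally any [pipeline_config()]
#'   parameter.
#' @param quiet Suppress per-stage log lines.
#' @return The manifest, invisibly (also written to
#'   `<out_dir>/manifest.json`).
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (is.character(config)) config <- config_from_yaml(config)
  stopifnot(inherits(config, "pairdx_pipeline_config"))
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    tool = "pairdx", manifest_version = 1L, seed = config$seed,
    parameters = config[c("alpha_threshold", "n_repeats",
                          "occurrence_threshold", "cv_folds", "horizons",
                          "fraction_train")],
    stages = list())
  log_line <- function(...) if (!quiet) message("[pairdx] ", ...)
  record <- function(name, status, summary = list(), files = character(0)) {
    outputs <- lapply(files, function(f) {
      list(path = f, md5 = unname(tools::md5sum(file.path(out, f))))
    })
    manifest$stages[[name]] <<- list(name = name, status = status,
                                     summary = summary, outputs = outputs)
  }
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      record(name, "failed", list(error = conditionMessage(e)))
      jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  # -- data ----------------------------------------------------------------
  study <- run_stage("data", {
    if (!is.null(config$synthetic)) {
      st <- generate_study(config$synthetic)
      write_fixtures(st, file.path(out, "data"))
    } else {
      st <- read_fixtures(config$input_dir)
    }
    st
  })
  data_files <- if (!is.null(config$synthetic))
    file.path("data", list.files(file.path(out, "data"))) else character(0)
  n_samp <- sum(vapply(study$cohorts, function(co) ncol(co$expr),
                       integer(1)))
  record("data", "completed",
         list(n_cohorts = length(study$cohorts), n_samples = n_samp),
         data_files)
  log_line("data: ", length(study$cohorts), " cohorts, ", n_samp,
           " samples")

  # -- pairs ---------------------------------------------------------------
  common_genes <- Reduce(intersect,
                         lapply(study$cohorts,
                                function(co) rownames(co$expr)))
  pairs <- run_stage("pairs", {
    p <- candidate_pairs(study$sets, common_genes)
    dir.create(file.path(out, "pairs"), showWarnings = FALSE)
    utils::write.table(p, file.path(out, "pairs", "pairs.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    p
  })
  record("pairs", "completed",
         list(n_common_genes = length(common_genes),
              n_candidate_pairs = nrow(pairs)),
         file.path("pairs", "pairs.tsv"))
  log_line("pairs: ", nrow(pairs), " candidate pairs from ",
           length(common_genes), " common genes")

  # -- screen --------------------------------------------------------------
  pooled <- concat_cohorts(study$cohorts, pairs)
  split <- split_discovery(pooled$labels, config$fraction_train,
                           seed = stream_seed(config$seed, "discovery"))
  feats_train <- subset_samples(pooled$features, split$train)
  feats_test <- subset_samples(pooled$features, split$test)
  screen <- run_stage("screen", {
    sc <- screen_pairs(feats_train, pooled$labels,
                       alpha_threshold = config$alpha_threshold)
    dir.create(file.path(out, "screen"), showWarnings = FALSE)
    write_screen_tsv(sc, file.path(out, "screen", "screen.tsv"))
    sc
  })
  n_sig <- sum(screen$significant)
  record("screen", "completed",
         list(n_tested = nrow(screen), n_significant = n_sig,
              n_train = length(split$train), n_test = length(split$test)),
         file.path("screen", "screen.tsv"))
  log_line("screen: ", n_sig, " / ", nrow(screen),
           " pairs significant at adjusted p < ", config$alpha_threshold)

  # -- train ---------------------------------------------------------------
  train_res <- run_stage("train", {
    sig <- screen[screen$significant, c("gene_a", "gene_b"), drop = FALSE]
    if (nrow(sig) < 2)
      stop("fewer than 2 significant pairs; cannot train")
    dfeats_train <- subset_pairs(feats_train, pair_id(sig$gene_a,
                                                      sig$gene_b))
    dfeats_test <- subset_pairs(feats_test, pair_id(sig$gene_a,
                                                    sig$gene_b))
    stab <- stability_select(dfeats_train, pooled$labels,
                             n_repeats = config$n_repeats,
                             fraction_train = config$fraction_train,
                             seed = stream_seed(config$seed, "stability"))
    thr <- config$occurrence_threshold
    if (identical(thr, "auto")) {
      thr <- as.integer(tune_occurrence_threshold(
        stab, dfeats_train, pooled$labels, dfeats_test, pooled$labels,
        grid = config$occurrence_grid, cv_folds = config$cv_folds,
        seed = stream_seed(config$seed, "tune")))
    }
    cand <- select_candidates(stab, thr)
    model <- fit_final_model(dfeats_train, pooled$labels, cand,
                             cv_folds = config$cv_folds,
                             seed = stream_seed(config$seed, "final"))
    comp <- fit_comparators(dfeats_train, pooled$labels, cand,
                            seed = stream_seed(config$seed, "comparators"))
    test_auc <- auc(predict(model, dfeats_test),
                    pooled$labels[dfeats_test$sample_ids])
    train_auc <- auc(predict(model, dfeats_train),
                     pooled$labels[dfeats_train$sample_ids])
    comp_auc <- comparator_aucs(comp, dfeats_test, pooled$labels)
    dir.create(file.path(out, "train"), showWarnings = FALSE)
    write_model(model, file.path(out, "train", "model.txt"))
    report <- data.frame(
      method = c("lasso_logistic", names(comp_auc)),
      eval_auc = c(test_auc, as.numeric(comp_auc)),
      stringsAsFactors = FALSE)
    con <- file(file.path(out, "train", "report.tsv"), "wb")
    writeLines("method\teval_auc", con)
    writeLines(paste(report$method, fmt_num(report$eval_auc), sep = "\t"),
               con)
    close(con)
    list(model = model, threshold = thr, n_candidates = nrow(cand),
         train_auc = train_auc, test_auc = test_auc, report = report)
  })
  record("train", "completed",
         list(occurrence_threshold = train_res$threshold,
              n_candidates = train_res$n_candidates,
              n_model_pairs = nrow(train_res$model$pairs),
              train_auc = train_res$train_auc,
              test_auc = train_res$test_auc),
         file.path("train", c("model.txt", "report.tsv")))
  log_line("train: ", train_res$n_candidates, " candidates -> ",
           nrow(train_res$model$pairs), " model pairs, held-out AUC ",
           round(train_res$test_auc, 4))

  # -- prognosis -----------------------------------------------------------
  if (is.null(study$survival)) {
    record("prognosis", "skipped", list(reason = "no survival table"))
    log_line("prognosis: skipped (no survival table)")
    prog_res <- NULL
  } else {
    prog_res <- run_stage("prognosis", {
      surv <- align_survival(pooled$features, study$survival)
      sfeats <- subset_samples(pooled$features, surv$sample_id)
      filt <- filter_univariate(train_res$model$pairs, sfeats, surv)
      if (nrow(filt) < 2)
        stop("fewer than 2 pairs pass the univariate Cox filter")
      pmodel <- lasso_cox(sfeats, surv, filt,
                          cv_folds = config$cv_folds,
                          seed = stream_seed(config$seed, "cox"))
      scores <- risk_score(pmodel, sfeats)
      strata <- median_split(scores)
      km <- km_logrank(strata, surv)
      td <- vapply(config$horizons, function(h) {
        tryCatch(time_dependent_auc(scores, surv, h),
                 error = function(e) NA_real_)
      }, numeric(1))
      names(td) <- paste0("auc_", config$horizons)
      dir.create(file.path(out, "prognosis"), showWarnings = FALSE)
      write_model(pmodel, file.path(out, "prognosis", "prog_model.txt"))
      con <- file(file.path(out, "prognosis", "km.tsv"), "wb")
      writeLines("group\ttime\tn_risk\tn_event\tsurvival", con)
      writeLines(paste(km$curves$group, fmt_num(km$curves$time),
                       km$curves$n_risk, km$curves$n_event,
                       fmt_num(km$curves$survival), sep = "\t"), con)
      close(con)
      list(model = pmodel, n_filtered = nrow(filt), logrank_p = km$logrank_p,
           td_auc = td)
    })
    record("prognosis", "completed",
           c(list(n_filtered = prog_res$n_filtered,
                  n_model_pairs = nrow(prog_res$model$pairs),
                  logrank_p = prog_res$logrank_p),
             as.list(prog_res$td_auc)),
           file.path("prognosis", c("prog_model.txt", "km.tsv")))
    log_line("prognosis: ", prog_res$n_filtered, " filtered -> ",
             nrow(prog_res$model$pairs), " Cox pairs, log-rank p ",
             signif(prog_res$logrank_p, 3))
  }

  # -- enrich --------------------------------------------------------------
  enr <- run_stage("enrich", {
    genes <- unique(c(train_res$model$pairs$gene_a,
                      train_res$model$pairs$gene_b))
    e <- enrich(genes, study$sets, common_genes)
    dir.create(file.path(out, "enrich"), showWarnings = FALSE)
    con <- file(file.path(out, "enrich", "enrich.tsv"), "wb")
    writeLines(paste(names(e), collapse = "\t"), con)
    writeLines(paste(e$set_name, e$overlap, e$list_size, e$set_size,
                     e$universe_size, fmt_num(e$p_raw), fmt_num(e$p_adj),
                     sep = "\t"), con)
    close(con)
    e
  })
  record("enrich", "completed",
         list(n_sets_tested = nrow(enr),
              top_set = enr$set_name[1]),
         file.path("enrich", "enrich.tsv"))
  log_line("enrich: ", nrow(enr), " sets tested; top set ",
           enr$set_name[1])

  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

write_screen_tsv <- function(screen, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(paste(c("gene_a", "gene_b", "n_case_pos", "n_case_neg",
                     "n_ctrl_pos", "n_ctrl_neg", "p_raw", "p_adj",
                     "direction", "significant"), collapse = "\t"), con)
  writeLines(paste(screen$gene_a, screen$gene_b, screen$n_case_pos,
                   screen$n_case_neg, screen$n_ctrl_pos, screen$n_ctrl_neg,
                   fmt_num(screen$p_raw), fmt_num(screen$p_adj),
                   screen$direction, screen$significant, sep = "\t"), con)
  invisible(path)
}

config_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$out_dir)) stop("YAML config needs an out_dir")
  syn <- NULL
  if (!is.null(y$preset)) {
    seed <- if (is.null(y$seed)) 1L else as.integer(y$seed)
    syn <- switch(y$preset,
                  diagnostic = preset_diagnostic(seed),
                  prognostic = preset_prognostic(seed),
                  table1 = preset_table1(seed),
                  stop("unknown preset: ", y$preset))
  }
  args <- y[intersect(names(y), names(formals(pipeline_config)))]
  args$synthetic <- syn
  do.call(pipeline_config, args)
}

#' Cohort bookkeeping table
#'
#' The per-cohort sample counts of the nine-cohort oral squamous cell
#' carcinoma (OSCC) collection plus the TCGA head-and-neck prognosis
#' cohort that the method was developed on, shipped as a plain TSV
#' (`inst/extdata/cohort_table.tsv`). Useful for bookkeeping checks and
#' as a template for users assembling their own multi-cohort studies:
#' summing its columns reproduces the collection totals (821 samples,
#' 552 cases, 269 controls; 474 discovery, 79 evaluation, 268 external
#' validation).
#'
#' @return `data.frame` with columns `set`, `accession`, `n_case`,
#'   `n_control`, `platform`.
#' @export
cohort_table <- function() {
  path <- system.file("extdata", "cohort_table.tsv", package = "pairdx",
                      mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}
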