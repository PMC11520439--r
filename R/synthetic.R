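#' Configure a synthetic multi-cohort study
#'
#' Describes a generative model for multi-cohort case/control expression
#' data with known ground truth: baseline gene means, per-cohort per-gene
#' additive batch effects, planted gene pairs with controllable
#' group-specific reversal rates, optional per-sample monotone or affine
#' distortions, pathway structure co-locating every planted pair, and
#' exponential proportional-hazards survival for cases driven by the
#' planted pair features.
#'
#' @param n_cohorts Number of cohorts.
#' @param cases_per_cohort,controls_per_cohort Integer counts, recycled to
#'   `n_cohorts` (vectors allowed, so cohorts may be label-imbalanced or
#'   single-class, as real cohort collections often are).
#' @param n_genes Number of genes.
#' @param n_pathways,genes_per_pathway Pathway layout;
#'   `n_pathways * genes_per_pathway` must not exceed `n_genes`.
#' @param planted_pairs `data.frame` with columns `gene_a`, `gene_b`,
#'   `rate_case`, `rate_control` (probability that `gene_a > gene_b` in a
#'   case / control sample) and optional `beta` (log hazard ratio per unit
#'   of the `+1`/`-1` pair feature). Pairs may not share genes.
#' @param batch_shift_sd SD of the per-cohort per-gene additive batch
#'   offset (log2 units), >= 0.
#' @param sample_distortion `"none"`, `"affine"` (per-sample `a*x + b`,
#'   `a ~ U(0.5, 2)`, `b ~ U(-2, 2)`) or `"monotone"` (per-sample strictly
#'   increasing piecewise-linear map with 5 random interior knots). Both
#'   distortions leave every pair feature unchanged.
#' @param survival `NULL`, or `list(baseline_rate = , censor_time_max = )`:
#'   case survival times are `Exponential(baseline_rate * exp(sum beta_p *
#'   r_p))`, censored at `Uniform(0, censor_time_max)`.
#' @param seed Integer master seed; every stage draws from its own named
#'   substream so toggling one stage does not shift the others.
#' @return A validated `pairdx_config` list.
#' @export
synthetic_config <- function(n_cohorts = 3,
                             cases_per_cohort = 50,
                             controls_per_cohort = 50,
                             n_genes = 200,
                             n_pathways = 10,
                             genes_per_pathway = 20,
                             planted_pairs = NULL,
                             batch_shift_sd = 0,
                             sample_distortion = c("none", "affine", "monotone"),
                             survival = NULL,
                             seed = 1L) {
  sample_distortion <- match.arg(sample_distortion)
  stopifnot(n_cohorts >= 1, n_genes >= 2, n_pathways >= 1,
            genes_per_pathway >= 2, batch_shift_sd >= 0)
  cases <- rep_len(as.integer(cases_per_cohort), n_cohorts)
  controls <- rep_len(as.integer(controls_per_cohort), n_cohorts)
  if (any(cases < 0) || any(controls < 0) || any(cases + controls == 0))
    stop("every cohort needs a positive number of samples")
  if (n_pathways * genes_per_pathway > n_genes)
    stop("n_pathways * genes_per_pathway exceeds n_genes")
  gene_ids <- sprintf("G%04d", seq_len(n_genes))
  if (is.null(planted_pairs)) {
    planted_pairs <- data.frame(gene_a = character(0), gene_b = character(0),
                                rate_case = numeric(0), rate_control = numeric(0),
                                beta = numeric(0), stringsAsFactors = FALSE)
  } else {
    stopifnot(is.data.frame(planted_pairs),
              all(c("gene_a", "gene_b", "rate_case", "rate_control") %in%
                    names(planted_pairs)))
    if (!"beta" %in% names(planted_pairs)) planted_pairs$beta <- 0
    # canonical orientation; a swap flips the meaning of "gene_a > gene_b"
    swap <- planted_pairs$gene_a > planted_pairs$gene_b
    if (any(swap)) {
      tmp <- planted_pairs$gene_a[swap]
      planted_pairs$gene_a[swap] <- planted_pairs$gene_b[swap]
      planted_pairs$gene_b[swap] <- tmp
      planted_pairs$rate_case[swap] <- 1 - planted_pairs$rate_case[swap]
      planted_pairs$rate_control[swap] <- 1 - planted_pairs$rate_control[swap]
      planted_pairs$beta[swap] <- -planted_pairs$beta[swap]
    }
    genes_used <- c(planted_pairs$gene_a, planted_pairs$gene_b)
    if (any(planted_pairs$gene_a == planted_pairs$gene_b))
      stop("a planted pair must consist of two distinct genes")
    if (anyDuplicated(genes_used))
      stop("planted pairs may not share genes (rates would interfere)")
    if (!all(genes_used %in% gene_ids))
      stop("planted pair gene not among the generated genes: ",
           setdiff(genes_used, gene_ids)[1])
    rates <- c(planted_pairs$rate_case, planted_pairs$rate_control)
    if (any(rates < 0 | rates > 1)) stop("reversal rates must lie in [0, 1]")
    if (nrow(planted_pairs) > n_pathways * floor(genes_per_pathway / 2))
      stop("planted pair genes not co-assignable to pathways; ",
           "increase n_pathways or genes_per_pathway")
  }
  if (!is.null(survival)) {
    stopifnot(is.list(survival),
              survival$baseline_rate > 0, survival$censor_time_max > 0)
  }
  structure(list(n_cohorts = n_cohorts, cases_per_cohort = cases,
                 controls_per_cohort = controls, n_genes = n_genes,
                 n_pathways = n_pathways,
                 genes_per_pathway = genes_per_pathway,
                 planted_pairs = planted_pairs,
                 batch_shift_sd = batch_shift_sd,
                 sample_distortion = sample_distortion,
                 survival = survival, seed = as.integer(seed),
                 gene_ids = gene_ids),
            class = "pairdx_config")
}

#' Generate a synthetic multi-cohort study
#'
#' Runs the generative model described in [synthetic_config()]:
#' (1) baseline gene means `mu_g ~ N(8, 2)` with per-sample expression
#' `N(mu_g, 1)`; (2) per-cohort per-gene additive batch offsets
#' `N(0, batch_shift_sd)`; (3) planted reversals — for each planted pair
#' and sample the pair state is drawn Bernoulli with the group's rate and
#' imposed with a margin `delta ~ U(0.5, 1.5)` around the genes' current
#' midpoint, so configured rates are realized exactly in expectation in
#' every cohort regardless of batch effects; (4) optional per-sample
#' affine or monotone distortion (pair features unchanged); (5) pathway
#' partition co-locating every planted pair; (6) exponential
#' proportional-hazards survival for cases with uniform censoring.
#'
#' Regenerating with the same config is bit-identical.
#'
#' @param config A `pairdx_config` from [synthetic_config()].
#' @return A `pairdx_study`: list with `cohorts` (named list of
#'   `list(expr, labels)`), `survival` (or `NULL`), `sets` (GMT-style
#'   collection) and `truth` (planted pair table, seed, config).
#' @export
generate_study <- function(config) {
  stopifnot(inherits(config, "pairdx_config"))
  seed <- config$seed
  genes <- config$gene_ids
  n_genes <- config$n_genes
  mu <- with_stream(seed, "means", stats::rnorm(n_genes, 8, 2))

  cohort_ids <- sprintf("C%d", seq_len(config$n_cohorts))
  n_samples <- config$cases_per_cohort + config$controls_per_cohort

  cohorts <- with_stream(seed, "noise", {
    lapply(seq_len(config$n_cohorts), function(ci) {
      n <- n_samples[ci]
      vals <- matrix(stats::rnorm(n_genes * n, mean = mu, sd = 1),
                     nrow = n_genes)
      ids <- sprintf("%s.S%03d", cohort_ids[ci], seq_len(n))
      dimnames(vals) <- list(genes, ids)
      labels <- stats::setNames(
        c(rep(1L, config$cases_per_cohort[ci]),
          rep(0L, config$controls_per_cohort[ci])), ids)
      list(expr = vals, labels = labels)
    })
  })
  names(cohorts) <- cohort_ids

  if (config$batch_shift_sd > 0) {
    cohorts <- with_stream(seed, "batch", {
      lapply(cohorts, function(co) {
        co$expr <- co$expr +
          stats::rnorm(n_genes, 0, config$batch_shift_sd)
        co
      })
    })
  }

  # Planted reversals come after the batch offsets so that the configured
  # reversal rates hold in every cohort's observed data; the truth table
  # would otherwise be scrambled by gene-specific offsets.
  planted <- config$planted_pairs
  pair_states <- NULL  # planted pair feature per (pair, global sample)
  if (nrow(planted) > 0) {
    res <- with_stream(seed, "planted", {
      states <- list()
      for (p in seq_len(nrow(planted))) {
        ga <- planted$gene_a[p]; gb <- planted$gene_b[p]
        st_row <- numeric(0)
        for (ci in seq_along(cohorts)) {
          co <- cohorts[[ci]]
          n <- ncol(co$expr)
          rate <- ifelse(co$labels == 1L, planted$rate_case[p],
                         planted$rate_control[p])
          u <- stats::runif(n)
          delta <- stats::runif(n, 0.5, 1.5)
          state <- ifelse(u < rate, 1L, -1L)
          ctr <- (co$expr[ga, ] + co$expr[gb, ]) / 2
          co$expr[ga, ] <- ctr + state * delta / 2
          co$expr[gb, ] <- ctr - state * delta / 2
          cohorts[[ci]] <- co
          st_row <- c(st_row, stats::setNames(state, colnames(co$expr)))
        }
        states[[pair_id(ga, gb)]] <- st_row
      }
      list(cohorts = cohorts, states = do.call(rbind, states))
    })
    cohorts <- res$cohorts
    pair_states <- res$states
  }

  if (config$sample_distortion != "none") {
    cohorts <- with_stream(seed, "distort", {
      lapply(cohorts, function(co) {
        for (j in seq_len(ncol(co$expr))) {
          v <- co$expr[, j]
          if (config$sample_distortion == "affine") {
            a <- stats::runif(1, 0.5, 2); b <- stats::runif(1, -2, 2)
            co$expr[, j] <- a * v + b
          } else {
            co$expr[, j] <- monotone_map(v)
          }
        }
        co
      })
    })
  }

  sets <- with_stream(seed, "pathway",
                      build_pathways(genes, planted, config$n_pathways,
                                     config$genes_per_pathway))

  survival_tab <- NULL
  if (!is.null(config$survival)) {
    all_labels <- do.call(c, unname(lapply(cohorts, `[[`, "labels")))
    case_ids <- names(all_labels)[all_labels == 1L]
    survival_tab <- with_stream(seed, "survival", {
      lp <- rep(0, length(case_ids))
      if (nrow(planted) > 0 && any(planted$beta != 0))
        lp <- as.numeric(planted$beta %*%
                           pair_states[, case_ids, drop = FALSE])
      rate <- config$survival$baseline_rate * exp(lp)
      t_ev <- stats::rexp(length(case_ids), rate = rate)
      t_cn <- stats::runif(length(case_ids), 0,
                           config$survival$censor_time_max)
      data.frame(sample_id = case_ids,
                 time = pmin(t_ev, t_cn),
                 event = as.integer(t_ev <= t_cn),
                 stringsAsFactors = FALSE)
    })
  }

  structure(list(cohorts = cohorts, survival = survival_tab, sets = sets,
                 truth = list(planted = planted, seed = seed,
                              config = config)),
            class = "pairdx_study")
}

# Strictly increasing piecewise-linear map with 5 random interior knots
# spanning the sample's value range; segment slopes U(0.2, 3).
monotone_map <- function(v) {
  lo <- min(v) - 1e-9; hi <- max(v) + 1e-9
  kx <- c(lo, sort(stats::runif(5, lo, hi)), hi)
  slopes <- stats::runif(6, 0.2, 3)
  ky <- kx[1] + cumsum(c(0, diff(kx) * slopes))
  stats::approx(kx, ky, xout = v)$y
}

# Partition genes into pathways, co-locating each planted pair.
build_pathways <- function(genes, planted, n_pathways, genes_per_pathway) {
  assign <- vector("list", n_pathways)
  if (nrow(planted) > 0) {
    for (p in seq_len(nrow(planted))) {
      slot <- ((p - 1) %% n_pathways) + 1
      if (length(assign[[slot]]) + 2 > genes_per_pathway)
        stop("planted pair genes not co-assignable to a pathway")
      assign[[slot]] <- c(assign[[slot]], planted$gene_a[p],
                          planted$gene_b[p])
    }
  }
  rest <- sample(setdiff(genes, unlist(assign)))
  for (i in seq_len(n_pathways)) {
    need <- genes_per_pathway - length(assign[[i]])
    assign[[i]] <- c(assign[[i]], rest[seq_len(need)])
    rest <- rest[-seq_len(need)]
  }
  names(assign) <- sprintf("PW%02d", seq_len(n_pathways))
  structure(assign,
            description = stats::setNames(
              rep("synthetic pathway", n_pathways), names(assign)))
}

#' @export
print.pairdx_study <- function(x, ...) {
  n <- vapply(x$cohorts, function(co) ncol(co$expr), integer(1))
  cat("pairdx_study:", length(x$cohorts), "cohorts (",
      paste(n, collapse = ", "), "samples ),",
      nrow(x$truth$planted), "planted pairs,",
      if (is.null(x$survival)) "no survival\n" else "with survival\n")
  invisible(x)
}

#' Write a synthetic study to disk as plain-text fixtures
#'
#' Emits one expression TSV per cohort (`expr_<cohort>.tsv`), global
#' `labels.tsv`, `survival.tsv` (when present), `pathways.gmt`, and
#' `truth.json` listing exactly the planted pairs with their rates, betas
#' and the master seed. [read_fixtures()] reads the set back.
#'
#' @param study A `pairdx_study`.
#' @param directory Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_fixtures <- function(study, directory) {
  stopifnot(inherits(study, "pairdx_study"))
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(directory)) stop("cannot create directory: ", directory)
  for (cid in names(study$cohorts)) {
    write_expression(study$cohorts[[cid]]$expr,
                     file.path(directory, paste0("expr_", cid, ".tsv")))
  }
  labels <- do.call(c, lapply(unname(study$cohorts), `[[`, "labels"))
  write_labels(labels, file.path(directory, "labels.tsv"))
  if (!is.null(study$survival))
    write_survival(study$survival, file.path(directory, "survival.tsv"))
  write_gmt(study$sets, file.path(directory, "pathways.gmt"))
  jsonlite::write_json(
    list(planted_pairs = study$truth$planted, seed = study$truth$seed),
    file.path(directory, "truth.json"),
    dataframe = "columns", auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(directory)
}

#' @rdname write_fixtures
#' @export
read_fixtures <- function(directory) {
  files <- list.files(directory, pattern = "^expr_.*\\.tsv$")
  if (length(files) == 0) stop("no expression fixtures in ", directory)
  labels <- read_labels(file.path(directory, "labels.tsv"))
  cohorts <- lapply(files, function(f) {
    cid <- sub("^expr_(.*)\\.tsv$", "\\1", f)
    expr <- read_expression(file.path(directory, f), cohort_id = cid)
    list(expr = expr, labels = labels[colnames(expr)])
  })
  names(cohorts) <- sub("^expr_(.*)\\.tsv$", "\\1", files)
  surv_path <- file.path(directory, "survival.tsv")
  survival_tab <- if (file.exists(surv_path)) read_survival(surv_path) else NULL
  sets <- read_gmt(file.path(directory, "pathways.gmt"))
  truth_path <- file.path(directory, "truth.json")
  truth <- if (file.exists(truth_path)) {
    tj <- jsonlite::read_json(truth_path, simplifyVector = TRUE)
    list(planted = as.data.frame(tj$planted_pairs,
                                 stringsAsFactors = FALSE),
         seed = tj$seed)
  } else NULL
  structure(list(cohorts = cohorts, survival = survival_tab, sets = sets,
                 truth = truth),
            class = "pairdx_study")
}

#' Study presets
#'
#' Fixed study conditions used throughout the package's recovery tests
#' and worked examples.
#'
#' `preset_diagnostic()`: 3 cohorts of 50 cases + 50 controls (150/150
#' pooled), 200 genes in 10 pathways of 20, five planted pairs with
#' reversal rates 0.9 (case) / 0.1 (control), additive batch shifts of SD
#' 2.0 and per-sample affine distortion — a cross-platform case/control
#' collection in which the planted reversal signal must be recovered
#' through substantial technical variation. Planted pairs also carry
#' survival effects so the same preset drives the end-to-end pipeline.
#'
#' `preset_prognostic()`: one cohort of 300 cases + 50 controls, six
#' planted pairs with reversal rate 0.5 in both groups (so the pair
#' feature varies freely among cases) and log hazard ratios
#' (1, -1, 0.9, -0.9, 0.8, -0.8); exponential baseline rate 0.1 with
#' uniform censoring on (0, 20).
#'
#' `preset_table1()`: nine cohorts with the case/control counts of the
#' real cohort collection the method was built on (99/0, 167/62, 40/40,
#' 66/0, 57/22, 57/33, 23/73, 16/34, 27/5).
#'
#' @param seed Master seed.
#' @return A `pairdx_config`.
#' @export
preset_diagnostic <- function(seed = 1L) {
  synthetic_config(
    n_cohorts = 3, cases_per_cohort = 50, controls_per_cohort = 50,
    n_genes = 200, n_pathways = 10, genes_per_pathway = 20,
    planted_pairs = data.frame(
      gene_a = sprintf("G%04d", c(1, 3, 5, 7, 9)),
      gene_b = sprintf("G%04d", c(2, 4, 6, 8, 10)),
      rate_case = 0.9, rate_control = 0.1,
      beta = c(0.8, -0.8, 0.9, -0.9, 0.7),
      stringsAsFactors = FALSE),
    batch_shift_sd = 2.0, sample_distortion = "affine",
    survival = list(baseline_rate = 0.1, censor_time_max = 20),
    seed = seed)
}

#' @rdname preset_diagnostic
#' @export
preset_prognostic <- function(seed = 1L) {
  synthetic_config(
    n_cohorts = 1, cases_per_cohort = 300, controls_per_cohort = 50,
    n_genes = 120, n_pathways = 6, genes_per_pathway = 20,
    planted_pairs = data.frame(
      gene_a = sprintf("G%04d", c(1, 3, 5, 7, 9, 11)),
      gene_b = sprintf("G%04d", c(2, 4, 6, 8, 10, 12)),
      rate_case = 0.5, rate_control = 0.5,
      beta = c(1, -1, 0.9, -0.9, 0.8, -0.8),
      stringsAsFactors = FALSE),
    batch_shift_sd = 0, sample_distortion = "none",
    survival = list(baseline_rate = 0.1, censor_time_max = 20),
    seed = seed)
}

#' @rdname preset_diagnostic
#' @export
preset_table1 <- function(seed = 1L) {
  synthetic_config(
    n_cohorts = 9,
    cases_per_cohort = c(99, 167, 40, 66, 57, 57, 23, 16, 27),
    controls_per_cohort = c(0, 62, 40, 0, 22, 33, 73, 34, 5),
    n_genes = 300, n_pathways = 10, genes_per_pathway = 30,
    planted_pairs = data.frame(
      gene_a = sprintf("G%04d", seq(1, 19, by = 2)),
      gene_b = sprintf("G%04d", seq(2, 20, by = 2)),
      rate_case = 0.85, rate_control = 0.15, beta = 0,
      stringsAsFactors = FALSE),
    batch_shift_sd = 1.5, sample_distortion = "affine",
    seed = seed)
}
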