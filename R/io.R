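#' Read a gene expression matrix from TSV
#'
#' Reads a plain tab-separated expression file: a header row of sample ids,
#' a first column of gene ids, and a numeric body on the log2 scale
#' (genes x samples). Row and column order are preserved exactly as in the
#' file; duplicated ids and non-numeric cells are hard errors, as is an
#' empty file. Missing values are not supported: a cell of `NA` is an
#' error (the intended input is a complete matrix over the genes commonly
#' detected across cohorts).
#'
#' @param path Path to the TSV file.
#' @param cohort_id Cohort tag stored as the `cohort_id` attribute.
#' @param log2_transform If `TRUE`, apply `log2(x + 1)` to raw non-negative
#'   values. Pair features are invariant to monotone transforms, so this
#'   only affects expression-scale diagnostics.
#' @return Numeric matrix (genes x samples) with a `cohort_id` attribute.
#' @seealso [write_expression()]
#' @export
read_expression <- function(path, cohort_id = basename(path),
                            log2_transform = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0) stop("empty expression file: ", path)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character",
                           quote = "", comment.char = "")
  if (nrow(raw) == 0 || ncol(raw) < 2)
    stop("expression file must have a gene id column plus >= 1 sample column: ",
         path)
  genes <- raw[[1]]
  samples <- colnames(raw)[-1]
  if (anyDuplicated(genes))
    stop("duplicate gene id in ", path, ": ", genes[duplicated(genes)][1])
  if (anyDuplicated(samples))
    stop("duplicate sample id in ", path, ": ",
         samples[duplicated(samples)][1])
  body <- as.matrix(raw[, -1, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(body), dim = dim(body)))
  bad <- which(is.na(num), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop("non-numeric or missing value '", body[bad[1, 1], bad[1, 2]],
         "' at row ", bad[1, 1], " (gene ", genes[bad[1, 1]], "), column ",
         bad[1, 2] + 1, " (sample ", samples[bad[1, 2]], ") of ", path)
  }
  dimnames(num) <- list(genes, samples)
  if (log2_transform) {
    if (any(num < 0)) stop("log2 transform requires non-negative values")
    num <- log2(num + 1)
  }
  validate_expression(num, cohort_id = cohort_id)
}

#' Write a gene expression matrix to TSV
#'
#' Inverse of [read_expression()]: emits a header of sample ids (first
#' column `gene_id`) and one row per gene, with full double precision so
#' that a read/write round trip is exact.
#'
#' @param expr Numeric genes x samples matrix with dimnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path) {
  expr <- validate_expression(expr)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(c("gene_id", colnames(expr)), collapse = "\t"), con)
  body <- apply(expr, 1, function(r) paste(fmt_num(r), collapse = "\t"))
  writeLines(paste(rownames(expr), body, sep = "\t"), con)
  invisible(path)
}

#' Read binary sample labels from TSV
#'
#' Two-column TSV (`sample_id`, `label`) with labels in \{0, 1\}
#' (1 = case, 0 = control). Unknown label values and duplicate sample ids
#' are hard errors. File order is preserved.
#'
#' @param path Path to the TSV file.
#' @return Named integer vector of 0/1 labels.
#' @export
read_labels <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, colClasses = "character")
  if (ncol(df) < 2) stop("labels file must have columns sample_id, label")
  lab <- suppressWarnings(as.integer(df[[2]]))
  bad <- is.na(lab) | !(lab %in% c(0L, 1L))
  if (any(bad))
    stop("unknown label value '", df[[2]][which(bad)[1]], "' for sample ",
         df[[1]][which(bad)[1]], " in ", path)
  validate_labels(stats::setNames(lab, df[[1]]))
}

#' @rdname read_labels
#' @param labels Named 0/1 vector.
#' @export
write_labels <- function(labels, path) {
  labels <- validate_labels(labels)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines("sample_id\tlabel", con)
  writeLines(paste(names(labels), labels, sep = "\t"), con)
  invisible(path)
}

#' Read a survival table from TSV
#'
#' Three-column TSV (`sample_id`, `time`, `event`); times must be positive
#' reals in one consistent unit and events 0 (censored) / 1 (event).
#'
#' @param path Path to the TSV file.
#' @return `data.frame` with columns `sample_id`, `time`, `event`.
#' @export
read_survival <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE)
  if (ncol(df) < 3)
    stop("survival file must have columns sample_id, time, event")
  out <- data.frame(sample_id = as.character(df[[1]]),
                    time = as.numeric(df[[2]]),
                    event = as.integer(df[[3]]),
                    stringsAsFactors = FALSE)
  validate_survival(out)
}

#' @rdname read_survival
#' @param surv Survival `data.frame`.
#' @export
write_survival <- function(surv, path) {
  surv <- validate_survival(surv)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines("sample_id\ttime\tevent", con)
  writeLines(paste(surv$sample_id, fmt_num(surv$time), surv$event,
                   sep = "\t"), con)
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' Standard GMT: one set per line, tab-separated fields
#' `name<TAB>description<TAB>member...`. Duplicate members within a line
#' are deduplicated (first occurrence kept); a line with fewer than three
#' fields or a duplicated set name is a hard error. Membership in any
#' particular expression matrix is not required.
#'
#' @param path Path to the GMT file.
#' @return Named list of member-gene character vectors, with a
#'   `description` attribute (named character vector).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) stop("empty GMT file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3)
  if (length(short) > 0)
    stop("GMT line ", short[1], " has fewer than 3 fields in ", path)
  nm <- vapply(fields, `[[`, "", 1)
  if (anyDuplicated(nm))
    stop("duplicate gene set name in ", path, ": ", nm[duplicated(nm)][1])
  desc <- stats::setNames(vapply(fields, `[[`, "", 2), nm)
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- nm
  if (any(lengths(sets) == 0)) stop("gene set with no members in ", path)
  structure(sets, description = desc)
}

#' @rdname read_gmt
#' @param sets Named list of member vectors (optionally with a
#'   `description` attribute).
#' @export
write_gmt <- function(sets, path) {
  desc <- attr(sets, "description")
  if (is.null(desc)) desc <- stats::setNames(rep("na", length(sets)), names(sets))
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (nm in names(sets)) {
    writeLines(paste(c(nm, desc[[nm]], sets[[nm]]), collapse = "\t"), con)
  }
  invisible(path)
}

#' Serialize a fitted pair model to a text file
#'
#' Writes diagnostic (sparse logistic) and prognostic (Cox) pair models in
#' a documented key-value text format with exact decimal representation
#' (`%.17g`), so that `read_model()` then `write_model()` reproduces the
#' file byte for byte.
#'
#' Format: a `# pairdx model v1` header line, then tab-separated
#' `key<TAB>value` lines (`type`, `intercept` for diagnostic models), then
#' one `pair<TAB>gene_a<TAB>gene_b<TAB>coefficient` line per pair.
#'
#' @param model A `pairdx_diag_model` or `pairdx_prog_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (inherits(model, "pairdx_diag_model")) {
    writeLines("# pairdx model v1", con)
    writeLines("type\tdiagnostic", con)
    writeLines(paste0("intercept\t", fmt_num(model$intercept)), con)
  } else if (inherits(model, "pairdx_prog_model")) {
    writeLines("# pairdx model v1", con)
    writeLines("type\tprognostic", con)
  } else stop("unknown model class: ", paste(class(model), collapse = "/"))
  for (i in seq_len(nrow(model$pairs))) {
    writeLines(paste("pair", model$pairs$gene_a[i], model$pairs$gene_b[i],
                     fmt_num(model$coefficients[i]), sep = "\t"), con)
  }
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2 || lines[1] != "# pairdx model v1")
    stop("malformed model file (missing header): ", path)
  fields <- strsplit(lines[-1], "\t", fixed = TRUE)
  keys <- vapply(fields, `[[`, "", 1)
  if (keys[1] != "type") stop("malformed model file (no type line): ", path)
  type <- fields[[1]][2]
  pair_rows <- fields[keys == "pair"]
  if (length(pair_rows) == 0) stop("model file has no pairs: ", path)
  if (any(lengths(pair_rows) != 4))
    stop("malformed pair line in model file: ", path)
  gene_a <- vapply(pair_rows, `[[`, "", 2)
  gene_b <- vapply(pair_rows, `[[`, "", 3)
  coefs <- as.numeric(vapply(pair_rows, `[[`, "", 4))
  if (any(is.na(coefs))) stop("non-numeric coefficient in model file: ", path)
  pairs <- data.frame(gene_a = gene_a, gene_b = gene_b,
                      stringsAsFactors = FALSE)
  if (type == "diagnostic") {
    int_row <- fields[keys == "intercept"]
    if (length(int_row) != 1) stop("diagnostic model needs one intercept: ", path)
    new_diag_model(pairs, coefs, intercept = as.numeric(int_row[[1]][2]))
  } else if (type == "prognostic") {
    new_prog_model(pairs, coefs)
  } else stop("unknown model type '", type, "' in ", path)
}
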