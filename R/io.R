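#' Read a sample-by-metabolite intensity matrix
#'
#' Expects delimited text (tab or comma, sniffed from the header line) with
#' sample ids in the first column and one column per metabolite. Cells equal
#' to \code{missing_token} (default: empty) are below-LOD missing values.
#'
#' @param path file path
#' @param missing_token string denoting a missing (below-LOD) cell
#' @return a raw \code{\link{metab_matrix}}
#' @export
read_matrix <- function(path, missing_token = "") {
  sep <- sniff_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          na.strings = missing_token, check.names = FALSE,
                          colClasses = "character", quote = "\"")
  ids <- df[[1]]
  if (anyDuplicated(ids)) stop("duplicate sample ids in ", path)
  vals <- as.matrix(df[, -1, drop = FALSE])
  suppressWarnings(num <- matrix(as.numeric(vals), nrow(vals), ncol(vals),
                                 dimnames = list(ids, colnames(vals))))
  bad <- which(is.na(num) & !is.na(vals), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("non-numeric intensity at row '%s', column '%s' in %s",
                 ids[bad[1, 1]], colnames(vals)[bad[1, 2]], path))
  metab_matrix(num, is.na(num), state = "raw")
}

#' Write a metabolite matrix as delimited text
#'
#' Missing (below-LOD) cells of a raw matrix are written as
#' \code{missing_token}; processed matrices are written in full.
#'
#' @param matrix a \code{\link{metab_matrix}}
#' @param path output path
#' @param missing_token token for missing cells
#' @param sep field separator
#' @export
write_matrix <- function(matrix, path, missing_token = "", sep = "\t") {
  vals <- matrix$values
  out <- cbind(sample = rownames(vals), as.data.frame(vals, check.names = FALSE))
  utils::write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE,
                     na = missing_token)
  invisible(path)
}

#' Read per-sample covariates
#'
#' Delimited text, sample ids in the first column; character columns become
#' factors downstream via \code{\link{build_design}}. Must include the
#' exposure column (\code{group}, coded 0/1).
#'
#' @param path file path
#' @return data.frame with rownames = sample ids
#' @export
read_covariates <- function(path) {
  sep <- sniff_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE, quote = "\"")
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) stop("duplicate sample ids in ", path)
  out <- df[, -1, drop = FALSE]
  rownames(out) <- ids
  out
}

#' Read a metabolite annotation table
#'
#' Delimited text with columns metabolite, subclass, major_class.
#'
#' @param path file path
#' @return an \code{\link{annotation_table}}
#' @export
read_annotation <- function(path) {
  sep <- sniff_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE, quote = "\"")
  annotation_table(df)
}

#' Read a GMT pathway-set file
#'
#' Standard GMT: one pathway per line, tab-separated — name, description,
#' then member compound ids.
#'
#' @param path file path
#' @return named list of character vectors
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- vapply(parts, length, integer(1)) < 3
  if (any(short)) stop("malformed GMT line(s): ", paste(which(short), collapse = ", "))
  stats::setNames(lapply(parts, function(p) unique(p[-(1:2)])),
                  vapply(parts, `[[`, character(1), 1))
}

#' Read a pathway graph from a two-column edge list
#'
#' @param path whitespace/tab-delimited file, two node ids per line
#' @return an undirected \code{igraph} graph
#' @export
read_pathway_graph <- function(path) {
  df <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("edge list must have two columns: ", path)
  igraph::graph_from_data_frame(df[, 1:2], directed = FALSE)
}

# internal: sniff tab vs comma from the first line
sniff_sep <- function(path) {
  header <- readLines(path, n = 1)
  if (lengths(regmatches(header, gregexpr("\t", header))) > 0) "\t" else ","
}

#' Pipeline configuration
#'
#' @param matrix,covariates,annotation paths to the input tables
#' @param gmt optional path to a GMT pathway-set file (enables ORA)
#' @param graphs optional named list of pathway edge-list paths (topology
#'   impact)
#' @param out_dir output directory (created if absent)
#' @param model a \code{\link{model_spec}}, or the name of a preset from
#'   \code{\link{model_presets}}, or a character vector of covariate names
#' @param fdr_threshold significance threshold on q-values
#' @param B permutation count
#' @param rf an \code{\link{rf_config}}, or NULL to skip the classifier
#' @param subset optional filter expression on the covariate table (e.g.
#'   \code{"substudy != 'Pilot'"}) selecting the analysis subset
#' @param missing_token missing-cell token in the intensity matrix
#' @param seed seed for the permutation machinery
#' @return object of class \code{pipeline_config}
#' @export
pipeline_config <- function(matrix, covariates, annotation, gmt = NULL,
                            graphs = NULL, out_dir = "metabperm_out",
                            model = "full", fdr_threshold = 0.05,
                            B = 1000L, rf = rf_config(), subset = NULL,
                            missing_token = "", seed = 1L) {
  if (fdr_threshold <= 0 || fdr_threshold >= 1)
    stop("fdr_threshold must be in (0, 1)")
  for (p in c(matrix, covariates, annotation, gmt, unlist(graphs)))
    if (!file.exists(p)) stop("input file does not exist: ", p)
  structure(list(matrix = matrix, covariates = covariates,
                 annotation = annotation, gmt = gmt, graphs = graphs,
                 out_dir = out_dir, model = model,
                 fdr_threshold = fdr_threshold, B = as.integer(B), rf = rf,
                 subset = subset, missing_token = missing_token,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Reads the input tables, intersects sample ids, applies the optional
#' subset filter, preprocesses (missingness filter, minimum imputation,
#' median scaling, log), builds the design, runs the per-metabolite
#' differential analysis with permutation Storey q-values, the subclass
#' composite analysis, pathway over-representation of the significant
#' metabolites (when a GMT is supplied) and the random-forest classifier
#' (when configured), and writes all result tables plus permutation
#' diagnostics and a run manifest to the output directory.
#'
#' @param config a \code{\link{pipeline_config}}
#' @return (invisibly) the output directory; side effect: files
#'   \code{differential.tsv}, \code{subclass.tsv}, \code{ora.tsv},
#'   \code{rf_importance.tsv}, \code{permutation_diagnostics.json},
#'   \code{manifest.json}
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  mat <- read_matrix(config$matrix, config$missing_token)
  cov <- read_covariates(config$covariates)
  ann <- read_annotation(config$annotation)

  common <- intersect(sample_ids(mat), rownames(cov))
  dropped <- length(sample_ids(mat)) + nrow(cov) - 2 * length(common)
  if (dropped > 0)
    message(sprintf("run_pipeline: %d sample id(s) not shared between matrix and covariates", dropped))
  if (length(common) == 0) stop("no shared sample ids")
  mat <- subset_samples(mat, match(common, sample_ids(mat)))
  cov <- cov[common, , drop = FALSE]

  if (!is.null(config$subset)) {
    keep <- eval(parse(text = config$subset), envir = cov)
    if (!is.logical(keep) || length(keep) != nrow(cov))
      stop("subset expression must evaluate to one logical per sample")
    message(sprintf("run_pipeline: subset '%s' keeps %d of %d samples",
                    config$subset, sum(keep), length(keep)))
    mat <- subset_samples(mat, which(keep))
    cov <- cov[keep, , drop = FALSE]
  }

  prep <- preprocess(mat)
  spec <- resolve_model(config$model, cov)
  design <- build_design(cov, spec)

  diff_tab <- run_differential(prep$matrix, design, ann,
                               B = config$B, seed = config$seed)
  write_result_tsv(diff_tab, file.path(config$out_dir, "differential.tsv"))

  avg <- subclass_average(subset_samples(prep$matrix,
                                         match(design$rows_kept, sample_ids(prep$matrix))),
                          ann)
  sub_tab <- subclass_test(avg, design, diff_tab, fdr = config$fdr_threshold,
                           B = config$B, seed = config$seed)
  write_result_tsv(sub_tab, file.path(config$out_dir, "subclass.tsv"))

  if (!is.null(config$gmt)) {
    sets <- read_gmt(config$gmt)
    graphs <- if (!is.null(config$graphs))
      lapply(config$graphs, read_pathway_graph) else NULL
    lib <- pathway_library(sets, universe = diff_tab$metabolite, graphs = graphs)
    hits <- diff_tab$metabolite[diff_tab$q < config$fdr_threshold]
    ora_tab <- run_ora(hits, lib)
    write_result_tsv(ora_tab, file.path(config$out_dir, "ora.tsv"))
  }

  if (!is.null(config$rf)) {
    grp <- design$matrix[, design$exposure_index]
    mat_rf <- subset_samples(prep$matrix,
                             match(design$rows_kept, sample_ids(prep$matrix)))
    hold <- train_eval_holdout(mat_rf, grp, config$rf)
    cv <- train_eval_cv(mat_rf, grp, config$rf)
    imp <- data.frame(metabolite = names(hold$importance),
                      importance_mda = unname(hold$importance),
                      importance_gini = unname(cv$importance[names(hold$importance)]),
                      rank_mda = rank(-hold$importance, ties.method = "min"),
                      stringsAsFactors = FALSE)
    write_result_tsv(imp, file.path(config$out_dir, "rf_importance.tsv"))
    rf_summary <- list(accuracy_per_tree_holdout = hold$accuracy,
                       accuracy_cv = cv$accuracy, seed = config$rf$seed,
                       n_trees = config$rf$n_trees)
  } else rf_summary <- NULL

  null <- attr(diff_tab, "perm_null")
  pooled <- abs(as.vector(null$t_null))
  diag <- list(seed = config$seed, B = null$B, df = null$df,
               pi0 = attr(diff_tab, "pi0"),
               pooled_null_abs_t_quantiles = as.list(stats::quantile(
                 pooled, c(0.5, 0.9, 0.95, 0.99))))
  jsonlite::write_json(diag, file.path(config$out_dir, "permutation_diagnostics.json"),
                       auto_unbox = TRUE, digits = NA)

  manifest <- list(
    package_version = as.character(utils::packageVersion("metabperm")),
    r_version = R.version.string,
    config = config[setdiff(names(config), "rf")],
    rf = rf_summary,
    n_samples = nrow(design$matrix),
    n_metabolites_retained = nrow(diff_tab),
    n_metabolites_excluded = length(prep$excluded),
    n_significant = sum(diff_tab$q < config$fdr_threshold))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(config$out_dir)
}

# internal: accept a model_spec, a preset name, or a covariate name vector
resolve_model <- function(model, covariates) {
  if (inherits(model, "model_spec")) return(model)
  if (is.character(model) && length(model) == 1 &&
      model %in% names(model_presets()))
    return(model_presets()[[model]])
  if (is.character(model))
    return(model_spec("custom", model))
  stop("cannot interpret 'model'")
}

# internal: TSV writer used for all result tables
write_result_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
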