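#' Validate an expression matrix
#'
#' camix represents expression data as a plain numeric matrix, genes in
#' rows and samples in columns, on the linear (un-logged) scale. This
#' validator enforces the invariants every module relies on: non-negative
#' finite values and unique gene/sample identifiers.
#'
#' @param values numeric matrix (genes x samples).
#' @param gene_ids,sample_ids optional identifier vectors; default to the
#'   dimnames of `values`.
#' @return the validated matrix with dimnames set.
#' @export
expression_matrix <- function(values, gene_ids = rownames(values),
                              sample_ids = colnames(values)) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("expression data must be a numeric matrix", call. = FALSE)
  if (is.null(gene_ids) || is.null(sample_ids))
    stop("gene and sample identifiers are required", call. = FALSE)
  gene_ids <- as.character(gene_ids)
  sample_ids <- as.character(sample_ids)
  if (length(gene_ids) != nrow(values) || length(sample_ids) != ncol(values))
    stop("identifier lengths do not match matrix dimensions", call. = FALSE)
  if (anyDuplicated(gene_ids))
    stop("duplicate gene id: ", gene_ids[duplicated(gene_ids)][1L],
         call. = FALSE)
  if (anyDuplicated(sample_ids))
    stop("duplicate sample id: ", sample_ids[duplicated(sample_ids)][1L],
         call. = FALSE)
  bad <- which(!is.finite(values))
  if (length(bad)) {
    rc <- arrayInd(bad[1L], dim(values))
    stop(sprintf("non-finite value at gene '%s', sample '%s'",
                 gene_ids[rc[1L]], sample_ids[rc[2L]]), call. = FALSE)
  }
  neg <- which(values < 0)
  if (length(neg)) {
    rc <- arrayInd(neg[1L], dim(values))
    stop(sprintf("negative value %g at gene '%s', sample '%s'",
                 values[neg[1L]], gene_ids[rc[1L]], sample_ids[rc[2L]]),
         call. = FALSE)
  }
  dimnames(values) <- list(gene_ids, sample_ids)
  values
}

#' Read an expression matrix from delimited text or GCT
#'
#' TSV/CSV files must carry sample ids in the header and gene ids in the
#' first column. GCT v1.2 files have the usual two-line preamble and a
#' Description column, which is skipped.
#'
#' @param path file path.
#' @param fmt `"tsv"`, `"csv"` or `"gct"`; default guessed from the file
#'   extension.
#' @param unlog_base if not `NULL`, input values are assumed
#'   log-transformed with this base and are exponentiated before
#'   validation (expression must be linear-scale for convex analysis).
#' @return validated expression matrix (genes x samples).
#' @export
read_expression <- function(path, fmt = NULL, unlog_base = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(fmt)) {
    fmt <- switch(tolower(tools::file_ext(path)),
                  csv = "csv", gct = "gct", "tsv")
  }
  fmt <- match.arg(fmt, c("tsv", "csv", "gct"))
  if (fmt == "gct") {
    hdr <- readLines(path, n = 2L)
    if (!startsWith(hdr[1L], "#1.2"))
      stop("not a GCT v1.2 file: ", path, call. = FALSE)
    df <- read.delim(path, skip = 2L, check.names = FALSE,
                     stringsAsFactors = FALSE)
    gene_ids <- as.character(df[[1L]])
    df <- df[, -c(1L, 2L), drop = FALSE]  # drop Name, Description
  } else {
    reader <- if (fmt == "csv") read.csv else read.delim
    df <- reader(path, check.names = FALSE, stringsAsFactors = FALSE)
    gene_ids <- as.character(df[[1L]])
    df <- df[, -1L, drop = FALSE]
  }
  for (j in seq_along(df)) {
    if (!is.numeric(df[[j]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(df[[j]]))) &
                     !is.na(df[[j]]))[1L]
      stop(sprintf("non-numeric cell at gene '%s', sample '%s'",
                   gene_ids[if (is.na(bad)) 1L else bad],
                   colnames(df)[j]), call. = FALSE)
    }
  }
  values <- as.matrix(df)
  if (!is.null(unlog_base)) values <- unlog_base^values
  expression_matrix(values, gene_ids, colnames(df))
}

#' Write an expression matrix as TSV
#'
#' @param expr expression matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path) {
  df <- data.frame(gene = rownames(expr),
                   apply(expr, 2L, fmt_num),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("gene", colnames(expr))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a plain-text key-value run configuration
#'
#' One `key = value` pair per line; `#` starts a comment. Recognized keys
#' mirror the arguments of [cam_run()] (`k`, `k_min`, `k_max`,
#' `n_clusters`, `filter_low_q`, `filter_high_q`, `reduction`,
#' `target_dim`, `norm`, `damping`, `max_iter`, `stable_iter`,
#' `subset_budget`, `seed`). Values that parse as numbers are returned
#' numeric. Command-line flags override config-file values in the CLI.
#'
#' @param path config file path.
#' @return named list of settings.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  known <- c("k", "k_min", "k_max", "n_clusters", "filter_low_q",
             "filter_high_q", "reduction", "target_dim", "norm",
             "damping", "max_iter", "stable_iter", "subset_budget",
             "seed")
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1L]]
    if (length(kv) != 2L)
      stop("malformed config line (expect 'key = value'): ", ln,
           call. = FALSE)
    key <- trimws(kv[1L]); val <- trimws(kv[2L])
    if (!key %in% known)
      stop("unknown config key: ", key, call. = FALSE)
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (is.na(num)) val else num
  }
  out
}

#' Write deconvolution results to a directory
#'
#' Emits the standard camix output set: `markers.tsv` (gene,
#' subpopulation, cluster id), `proportions.tsv` (samples x
#' subpopulations), `profiles.tsv` (genes x subpopulations), `mdl.tsv`
#' (model-selection curve) and `summary.json` (selected K, configuration
#' echo, seed). Numbers are written with 12 significant digits so that
#' written results reload to within round-off.
#'
#' @param result a `cam_fit` object from [cam_run()].
#' @param outdir output directory, created if absent.
#' @return character vector of the files written.
#' @export
write_results <- function(result, outdir) {
  stopifnot(inherits(result, "cam_fit"))
  if (!dir.exists(outdir))
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outdir)) stop("cannot create ", outdir, call. = FALSE)

  files <- character(0)
  p <- function(f) file.path(outdir, f)

  mk <- result$marker_sets
  marker_df <- data.frame(
    gene = unlist(mk, use.names = FALSE),
    subpopulation = rep(names(mk), lengths(mk)),
    cluster_id = rep(result$model$vertex_idx, lengths(mk)),
    stringsAsFactors = FALSE)
  utils::write.table(marker_df, p("markers.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  files <- c(files, p("markers.tsv"))

  A <- result$A_hat
  prop_df <- data.frame(sample = rownames(A), apply(A, 2L, fmt_num),
                        check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(prop_df, p("proportions.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  files <- c(files, p("proportions.tsv"))

  if (!is.null(result$S_hat)) {
    prof_df <- data.frame(gene = rownames(result$S_hat),
                          apply(result$S_hat, 2L, fmt_num),
                          check.names = FALSE, stringsAsFactors = FALSE)
  } else prof_df <- data.frame(gene = character(0))
  utils::write.table(prof_df, p("profiles.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  files <- c(files, p("profiles.tsv"))

  mdl <- result$mdl
  mdl_out <- data.frame(K = mdl$K,
                        neg_log_likelihood = fmt_num(mdl$neg_log_likelihood),
                        penalty = fmt_num(mdl$penalty),
                        total = fmt_num(mdl$total),
                        selected = mdl$K == result$selected_K)
  utils::write.table(mdl_out, p("mdl.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  files <- c(files, p("mdl.tsv"))

  summary <- list(selected_K = result$selected_K,
                  seed = result$config$seed,
                  config = result$config,
                  fit_error = result$model$fit_error,
                  n_markers = sum(lengths(mk)))
  jsonlite::write_json(summary, p("summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  files <- c(files, p("summary.json"))
  files
}
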