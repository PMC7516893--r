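# Delimited-text readers and writers for the formats the package
# consumes: abundance/probability tables, pairwise matrices, and Gaussian
# embedding sets. Delimiter is auto-detected between tab and comma.

detect_sep <- function(path) {
  first <- readLines(path, n = 1L, warn = FALSE)
  if (grepl("\t", first)) "\t" else ","
}

read_delim_table <- function(path, header) {
  utils::read.table(path, sep = detect_sep(path), header = header,
                    stringsAsFactors = FALSE, check.names = FALSE,
                    comment.char = "")
}

has_header <- function(path) {
  first <- strsplit(readLines(path, n = 1L, warn = FALSE),
                    "[\t,]")[[1]]
  suppressWarnings(any(is.na(as.numeric(first[first != ""]))))
}

#' Read an abundance or probability table as a subsystem ensemble
#'
#' Rows are subsystems (samples), columns are states. An optional header
#' row of state labels and an optional first column of subsystem labels
#' are detected automatically. Counts are normalized row-wise to
#' probabilities; rows summing to zero are rejected by name.
#'
#' @param path delimited text file (tab or comma separated).
#' @param weights optional numeric vector or one-column file of subsystem
#'   weights; defaults to uniform.
#' @return a [subsystem_ensemble()].
#' @export
read_abundance_table <- function(path, weights = NULL) {
  tab <- read_delim_table(path, header = has_header(path))
  labels <- NULL
  if (ncol(tab) > 1 && !is.numeric(tab[[1]])) {
    labels <- as.character(tab[[1]])
    tab <- tab[, -1, drop = FALSE]
  }
  M <- as.matrix(tab)
  if (!is.numeric(M))
    stop("abundance table contains non-numeric entries", call. = FALSE)
  if (any(M < 0)) {
    bad <- which(apply(M, 1L, function(r) any(r < 0)))[1]
    stop(sprintf("negative entries in row %s", row_name(labels, bad)),
         call. = FALSE)
  }
  rs <- rowSums(M)
  if (any(rs == 0)) {
    bad <- which(rs == 0)[1]
    stop(sprintf("row %s sums to zero", row_name(labels, bad)),
         call. = FALSE)
  }
  P <- M / rs
  if (is.character(weights) && length(weights) == 1L)
    weights <- utils::read.table(weights)[[1]]
  e <- subsystem_ensemble(P, w = weights)
  if (!is.null(labels)) rownames(e$P) <- labels
  e
}

row_name <- function(labels, i) {
  if (is.null(labels)) as.character(i) else sprintf("%d (%s)", i, labels[i])
}

#' Read a square pairwise matrix
#'
#' Reads a distance or similarity matrix from delimited text. Asymmetry up
#' to `1e-6` is symmetrized with a warning; beyond that the file is
#' rejected. Kind-specific invariants (zero diagonal for distances, unit
#' diagonal for similarities) are then enforced.
#'
#' @param path delimited text file holding a square numeric table
#'   (optional matching row/column labels).
#' @param kind `"distance"` or `"similarity"`.
#' @return a [distance_matrix()] or [similarity_matrix()].
#' @export
read_matrix <- function(path, kind = c("distance", "similarity")) {
  kind <- match.arg(kind)
  tab <- read_delim_table(path, header = has_header(path))
  if (ncol(tab) > 1 && !is.numeric(tab[[1]]))
    tab <- tab[, -1, drop = FALSE]
  M <- as.matrix(tab)
  if (nrow(M) != ncol(M))
    stop("matrix file is not square", call. = FALSE)
  asym <- max(abs(M - t(M)))
  if (asym > 1e-6)
    stop(sprintf("matrix asymmetric beyond tolerance (max deviation %.3g)",
                 asym), call. = FALSE)
  if (asym > SYM_TOL) {
    warning("small asymmetry symmetrized away", call. = FALSE)
  }
  M <- (M + t(M)) / 2
  dimnames(M) <- NULL
  if (kind == "distance") distance_matrix(M) else similarity_matrix(M)
}

#' Read a Gaussian embedding set from delimited text
#'
#' Expected columns: an optional `id` label column, `mu_1 .. mu_nz`, then
#' either `logvar_1 .. logvar_nz` (diagonal covariances in the
#' variational-encoder convention) or `cov_11 .. cov_nznz` (full
#' covariances in row-major order), and an optional `weight` column.
#'
#' @param path delimited text file with a header row.
#' @return a [gaussian_component_set()].
#' @export
read_gaussian_set <- function(path) {
  tab <- read_delim_table(path, header = TRUE)
  nm <- names(tab)
  mu_cols <- grep("^mu_", nm)
  if (!length(mu_cols))
    stop("no mu_* columns found in embeddings file", call. = FALSE)
  nz <- length(mu_cols)
  mu <- as.matrix(tab[, mu_cols, drop = FALSE])
  w <- if ("weight" %in% nm) tab$weight else NULL
  lv_cols <- grep("^logvar_", nm)
  cov_cols <- grep("^cov_", nm)
  if (length(lv_cols)) {
    if (length(lv_cols) != nz)
      stop("need one logvar_* column per latent dimension", call. = FALSE)
    Sigma <- as.matrix(tab[, lv_cols, drop = FALSE])
    gaussian_component_set(mu, Sigma, w = w, logvar = TRUE)
  } else if (length(cov_cols)) {
    if (length(cov_cols) != nz * nz)
      stop("need nz^2 cov_* columns for full covariances", call. = FALSE)
    C <- as.matrix(tab[, cov_cols, drop = FALSE])
    Sigma <- lapply(seq_len(nrow(C)), function(i)
      matrix(C[i, ], nz, nz, byrow = TRUE))
    gaussian_component_set(mu, Sigma, w = w)
  } else {
    stop("embeddings file needs logvar_* or cov_* columns", call. = FALSE)
  }
}

#' Write a Gaussian embedding set to delimited text
#'
#' Inverse of [read_gaussian_set()], written with full covariances in
#' row-major `cov_*` columns and a `weight` column, at full precision.
#'
#' @param g a [gaussian_component_set()].
#' @param path output file.
#' @param sep field separator (default tab).
#' @return `path`, invisibly.
#' @export
write_gaussian_set <- function(g, path, sep = "\t") {
  stopifnot(inherits(g, "gaussian_component_set"))
  nz <- g$nz
  C <- t(vapply(g$Sigma, function(S) as.numeric(t(S)), numeric(nz * nz)))
  out <- data.frame(id = seq_len(g$N))
  for (j in seq_len(nz)) out[[paste0("mu_", j)]] <- g$mu[, j]
  k <- 1L
  for (r in seq_len(nz)) for (c2 in seq_len(nz)) {
    out[[sprintf("cov_%d%d", r, c2)]] <- C[, k]; k <- k + 1L
  }
  out$weight <- g$w
  utils::write.table(format(out, digits = 17, scientific = NA,
                            trim = TRUE),
                     path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a tidy results table
#'
#' Deterministic column order and full (17 significant digit) precision,
#' as TSV or JSON, so that identical configurations produce byte-identical
#' output.
#'
#' @param table data frame of results.
#' @param path output file.
#' @param format `"tsv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
emit_results <- function(table, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "tsv") {
    fmt <- table
    num <- vapply(fmt, is.numeric, logical(1))
    fmt[num] <- lapply(fmt[num], function(x)
      formatC(x, digits = 17, format = "g"))
    utils::write.table(fmt, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    if (!requireNamespace("jsonlite", quietly = TRUE))
      stop("JSON output requires the jsonlite package", call. = FALSE)
    jsonlite::write_json(table, path, digits = NA, dataframe = "rows")
  }
  invisible(path)
}
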