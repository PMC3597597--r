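#' Expression matrix container
#'
#' Wraps a numeric samples-by-genes matrix of (typically log2) expression
#' values.  Missing measurements are carried as `NA`; downstream
#' operations that require complete data reject or drop them according
#' to an explicit policy.
#'
#' @param values numeric matrix, N samples by G genes.
#' @param sample_ids character vector of N unique sample identifiers.
#'   Defaults to `rownames(values)`.
#' @param gene_ids character vector of G unique gene identifiers.
#'   Defaults to `colnames(values)`.
#'
#' @return An object of class `"expression_matrix"`: the numeric matrix
#'   with sample ids as row names and gene ids as column names.
#' @export
expression_matrix <- function(values, sample_ids = rownames(values),
                              gene_ids = colnames(values)) {
  values <- as.matrix(values)
  if (!is.numeric(values)) {
    stop("expression values must be numeric")
  }
  if (is.null(sample_ids) || is.null(gene_ids)) {
    stop("sample_ids and gene_ids are required (or set as dimnames)")
  }
  sample_ids <- as.character(sample_ids)
  gene_ids <- as.character(gene_ids)
  if (length(sample_ids) != nrow(values)) {
    stop("length(sample_ids) must equal nrow(values)")
  }
  if (length(gene_ids) != ncol(values)) {
    stop("length(gene_ids) must equal ncol(values)")
  }
  if (anyDuplicated(sample_ids)) stop("duplicate sample ids")
  if (anyDuplicated(gene_ids)) stop("duplicate gene ids")
  dimnames(values) <- list(sample_ids, gene_ids)
  class(values) <- c("expression_matrix", class(values))
  values
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf(
    "expression_matrix: %d samples x %d genes (%d missing values)\n",
    nrow(x), ncol(x), sum(is.na(x))
  ))
  invisible(x)
}

#' Read a delimited expression matrix
#'
#' Reads a text file with a header line and one row per gene (the
#' microarray convention: genes in rows, samples in columns) or one row
#' per sample.  Cells equal to `missing_token` become `NA`; any other
#' non-numeric cell is an error.
#'
#' @param path file path.
#' @param delimiter field separator, default tab.
#' @param orientation `"genes_in_rows"` (default) or `"samples_in_rows"`.
#' @param missing_token string standing for a missing value, default `"NA"`.
#'
#' @return An [expression_matrix] (always samples-by-genes internally).
#' @export
read_expression_matrix <- function(path, delimiter = "\t",
                                   orientation = c("genes_in_rows",
                                                   "samples_in_rows"),
                                   missing_token = "NA") {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) stop("expression file needs a header and a body")
  fields <- strsplit(lines, delimiter, fixed = TRUE)
  header <- fields[[1L]]
  body <- fields[-1L]
  widths <- lengths(body)
  if (any(widths != widths[1L])) {
    stop("ragged rows in expression file (row ",
         which(widths != widths[1L])[1L] + 1L, ")")
  }
  # header may or may not carry a label for the id column
  n_data <- widths[1L] - 1L
  if (length(header) == n_data) {
    col_ids <- header
  } else if (length(header) == n_data + 1L) {
    col_ids <- header[-1L]
  } else {
    stop("header width does not match body rows")
  }
  row_ids <- vapply(body, `[`, character(1L), 1L)
  cells <- vapply(body, function(f) f[-1L], character(n_data))
  cells <- matrix(cells, nrow = n_data) # columns = file rows
  vals <- suppressWarnings(as.numeric(cells))
  bad <- is.na(vals) & cells != missing_token
  if (any(bad)) {
    stop("non-numeric cell that is not the missing token: '",
         cells[bad][1L], "'")
  }
  m <- t(matrix(vals, nrow = n_data, ncol = length(body)))
  rownames(m) <- row_ids
  colnames(m) <- col_ids
  if (orientation == "genes_in_rows") m <- t(m)
  expression_matrix(m)
}

#' Gene set
#'
#' @param name gene-set name (single string).
#' @param genes ordered character vector of gene identifiers; nonempty,
#'   no duplicates.  Identifiers are opaque strings and must match the
#'   gene ids of the expression matrix they will be used with.
#'
#' @return An object of class `"gene_set"`.
#' @export
gene_set <- function(name, genes) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  genes <- as.character(genes)
  if (length(genes) == 0L) stop("gene set '", name, "' is empty")
  if (anyDuplicated(genes)) {
    stop("gene set '", name, "' has duplicate identifiers")
  }
  structure(list(name = name, genes = genes), class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("gene_set '%s': %d genes\n", x$name, length(x$genes)))
  invisible(x)
}

#' Gene set collection
#'
#' @param sets list of [gene_set] objects with unique names.
#' @return An object of class `"gene_set_collection"`: a named list of
#'   gene sets, in the given order.
#' @export
gene_set_collection <- function(sets) {
  stopifnot(all(vapply(sets, inherits, logical(1L), "gene_set")))
  nms <- vapply(sets, `[[`, character(1L), "name")
  if (anyDuplicated(nms)) {
    stop("duplicate gene set name: '", nms[duplicated(nms)][1L], "'")
  }
  names(sets) <- nms
  structure(sets, class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("gene_set_collection: %d sets\n", length(x)))
  invisible(x)
}

#' Read / write gene sets in GMT format
#'
#' GMT is the tab-separated format distributed by MSigDB: one set per
#' line as `name<TAB>description<TAB>gene1<TAB>gene2...`.  The
#' description field is discarded on read and written back as `"na"`.
#'
#' @param path file path.
#' @return `read_gmt` returns a [gene_set_collection]; `write_gmt`
#'   returns `path` invisibly.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L) {
      stop("malformed GMT line ", i, ": fewer than 3 tab-separated fields")
    }
    sets[[i]] <- gene_set(f[1L], f[-(1:2)])
  }
  gene_set_collection(sets)
}

#' @rdname read_gmt
#' @param collection a [gene_set_collection].
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "gene_set_collection"))
  lines <- vapply(collection, function(s) {
    paste(c(s$name, "na", s$genes), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Paired gene-set data
#'
#' Aligned predictor / target expression blocks for one gene-set pair:
#' the N-by-p predictor block `X` and the N-by-q target block `Y`, rows
#' aligned by sample.  Blocks are complete (no missing values).
#'
#' @param X numeric matrix N x p.
#' @param Y numeric matrix N x q, same rows as `X`.
#' @param sample_ids character vector of N sample identifiers.
#' @return An object of class `"paired_gene_sets"`.
#' @export
paired_gene_sets <- function(X, Y, sample_ids = rownames(X)) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y)) stop("X and Y must have the same number of rows")
  if (nrow(X) < 2L) stop("need at least 2 samples")
  if (ncol(X) < 1L || ncol(Y) < 1L) stop("empty gene set block")
  if (anyNA(X) || anyNA(Y)) stop("paired blocks must not contain NA")
  if (is.null(sample_ids)) sample_ids <- as.character(seq_len(nrow(X)))
  structure(list(X = X, Y = Y, sample_ids = as.character(sample_ids)),
            class = "paired_gene_sets")
}

#' @export
print.paired_gene_sets <- function(x, ...) {
  cat(sprintf("paired_gene_sets: N=%d, p=%d (predictor), q=%d (target)\n",
              nrow(x$X), ncol(x$X), ncol(x$Y)))
  invisible(x)
}

#' Extract aligned predictor/target blocks for a gene-set pair
#'
#' Pulls the columns of `expr` named by the predictor and target gene
#' sets.  Genes absent from the matrix are dropped (with a message).
#' Missing values are handled by `missing_policy`: `"drop_gene"`
#' removes any gene with a missing value (the usual choice for arrays
#' where only complete probes are analysed), `"drop_sample"` removes
#' samples with a missing value in either block, `"reject"` errors.
#'
#' @param expr an [expression_matrix].
#' @param predictor,target [gene_set] objects.
#' @param missing_policy `"drop_gene"` (default), `"drop_sample"` or
#'   `"reject"`.
#' @param quiet suppress messages about dropped genes.
#'
#' @return A [paired_gene_sets] object; attributes `dropped_predictor`
#'   and `dropped_target` record genes removed as absent or missing.
#' @export
extract_pair <- function(expr, predictor, target,
                         missing_policy = c("drop_gene", "drop_sample",
                                            "reject"),
                         quiet = FALSE) {
  missing_policy <- match.arg(missing_policy)
  stopifnot(inherits(predictor, "gene_set"), inherits(target, "gene_set"))
  take <- function(set) {
    present <- set$genes[set$genes %in% colnames(expr)]
    absent <- setdiff(set$genes, present)
    if (length(absent) && !quiet) {
      message("gene set '", set$name, "': dropping ", length(absent),
              " gene(s) absent from the expression matrix")
    }
    list(block = unclass(expr)[, present, drop = FALSE], absent = absent)
  }
  px <- take(predictor)
  py <- take(target)
  X <- px$block; Y <- py$block
  dropped_x <- px$absent; dropped_y <- py$absent
  if (missing_policy == "reject" && (anyNA(X) || anyNA(Y))) {
    stop("missing values present and missing_policy = 'reject'")
  }
  if (missing_policy == "drop_gene") {
    bad_x <- colnames(X)[colSums(is.na(X)) > 0L]
    bad_y <- colnames(Y)[colSums(is.na(Y)) > 0L]
    if (length(bad_x) && !quiet) {
      message("gene set '", predictor$name, "': dropping ", length(bad_x),
              " gene(s) with missing values")
    }
    if (length(bad_y) && !quiet) {
      message("gene set '", target$name, "': dropping ", length(bad_y),
              " gene(s) with missing values")
    }
    X <- X[, setdiff(colnames(X), bad_x), drop = FALSE]
    Y <- Y[, setdiff(colnames(Y), bad_y), drop = FALSE]
    dropped_x <- c(dropped_x, bad_x)
    dropped_y <- c(dropped_y, bad_y)
  } else if (missing_policy == "drop_sample") {
    keep <- !(rowSums(is.na(X)) > 0L | rowSums(is.na(Y)) > 0L)
    X <- X[keep, , drop = FALSE]
    Y <- Y[keep, , drop = FALSE]
  }
  if (ncol(X) == 0L) stop("empty gene set block: '", predictor$name, "'")
  if (ncol(Y) == 0L) stop("empty gene set block: '", target$name, "'")
  out <- paired_gene_sets(X, Y, rownames(X))
  attr(out, "dropped_predictor") <- dropped_x
  attr(out, "dropped_target") <- dropped_y
  out
}
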