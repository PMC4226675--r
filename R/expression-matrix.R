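#' Construct an expression matrix with sample roles
#'
#' Container for a log2-scale gene-by-sample expression matrix together with
#' the role (`"tumor"` or `"normal"`) of each sample. Gene symbols are
#' upper-cased and must be unique; duplicate-symbol handling belongs to the
#' readers (see [read_expression_tsv()]), not the constructor.
#'
#' @param values numeric matrix, genes in rows (rownames = symbols), samples
#'   in columns (colnames = sample ids).
#' @param roles named character vector mapping every sample id to `"tumor"`
#'   or `"normal"`.
#' @return An object of class `expr_mat`: a list with elements `values` and
#'   `roles`.
#' @export
expression_matrix <- function(values, roles) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("`values` needs gene rownames and sample colnames")
  }
  rownames(values) <- toupper(rownames(values))
  if (anyDuplicated(rownames(values))) {
    stop("duplicate gene symbols in expression matrix")
  }
  if (anyDuplicated(colnames(values))) {
    stop("duplicate sample ids in expression matrix")
  }
  if (!all(colnames(values) %in% names(roles))) {
    stop("every sample needs a role")
  }
  roles <- roles[colnames(values)]
  if (!all(roles %in% c("tumor", "normal"))) {
    stop("roles must be 'tumor' or 'normal'")
  }
  if (!any(roles == "tumor")) {
    stop("expression matrix must contain at least one tumor")
  }
  structure(list(values = values, roles = roles), class = "expr_mat")
}

#' @export
print.expr_mat <- function(x, ...) {
  cat(sprintf(
    "<expr_mat> %d genes x %d samples (%d tumor, %d normal)\n",
    nrow(x$values), ncol(x$values),
    sum(x$roles == "tumor"), sum(x$roles == "normal")
  ))
  invisible(x)
}

#' @export
dim.expr_mat <- function(x) dim(x$values)

#' Sample ids of an expression matrix, optionally restricted by role
#' @param x an `expr_mat`.
#' @param role optional role filter (`"tumor"` or `"normal"`).
#' @return character vector of sample ids.
#' @export
samples_of <- function(x, role = NULL) {
  stopifnot(inherits(x, "expr_mat"))
  ids <- colnames(x$values)
  if (!is.null(role)) ids <- ids[x$roles[ids] == role]
  ids
}

#' Construct a gene set
#'
#' @param name set label.
#' @param genes character vector of gene symbols; upper-cased and
#'   de-duplicated preserving first occurrence.
#' @param description free-text description.
#' @return object of class `gene_set` with elements `name`, `description`,
#'   `genes`.
#' @export
gene_set <- function(name, genes, description = "") {
  genes <- unique(toupper(as.character(genes)))
  if (length(genes) == 0) stop("gene set must be non-empty")
  structure(list(name = name, description = description, genes = genes),
            class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("<gene_set> %s: %d genes\n", x$name, length(x$genes)))
  invisible(x)
}
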