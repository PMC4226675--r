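#' Read a gene-by-sample expression TSV
#'
#' Expects a header row of sample ids and a first column named `gene`
#' holding symbols. Duplicate symbols are collapsed to the max-variance row
#' with a warning; every cell must parse as a finite number, otherwise the
#' offending row/column is named in the error.
#'
#' @param path TSV file path.
#' @param roles named character vector of sample roles; if `NULL`, all
#'   samples are treated as tumors.
#' @return an [expression_matrix()].
#' @export
read_expression_tsv <- function(path, roles = NULL) {
  lines <- readLines(path)
  if (length(lines) < 2) stop("empty expression matrix: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- length(fields[[1]])
  if (ncols < 2) stop("line 1: header needs a gene column and >= 1 sample")
  bad <- which(vapply(fields, length, 1L) != ncols)
  if (length(bad) > 0) {
    stop(sprintf("ragged row at line %d (expected %d fields)", bad[1], ncols))
  }
  samples <- fields[[1]][-1]
  genes <- vapply(fields[-1], `[[`, "", 1L)
  vals <- matrix(NA_real_, nrow = length(genes), ncol = ncols - 1L,
                 dimnames = list(genes, samples))
  for (i in seq_along(genes)) {
    v <- suppressWarnings(as.numeric(fields[[i + 1L]][-1]))
    nf <- which(!is.finite(v))
    if (length(nf) > 0) {
      stop(sprintf(
        "non-numeric or missing value at line %d (gene %s, sample %s)",
        i + 1L, genes[i], samples[nf[1]]
      ))
    }
    vals[i, ] <- v
  }
  rownames(vals) <- toupper(rownames(vals))
  if (anyDuplicated(rownames(vals))) {
    vals <- collapse_duplicate_genes(vals)
  }
  if (is.null(roles)) {
    roles <- stats::setNames(rep("tumor", length(samples)), samples)
  }
  expression_matrix(vals, roles)
}

# keep the max-variance row per duplicated symbol (duplicate-gene policy at
# read time; probe-set collapsing proper is out of scope)
collapse_duplicate_genes <- function(vals) {
  dup <- unique(rownames(vals)[duplicated(rownames(vals))])
  warning(sprintf(
    "collapsed %d duplicated gene symbol(s) to max-variance row: %s",
    length(dup), paste(utils::head(dup, 5), collapse = ", ")
  ))
  keep <- rep(TRUE, nrow(vals))
  for (g in dup) {
    idx <- which(rownames(vals) == g)
    vars <- apply(vals[idx, , drop = FALSE], 1, stats::var)
    keep[setdiff(idx, idx[which.max(vars)])] <- FALSE
  }
  vals[keep, , drop = FALSE]
}

#' Write an expression matrix as TSV
#'
#' First column is `gene`, then one column per sample id; round-trips with
#' [read_expression_tsv()].
#' @param em an `expr_mat`.
#' @param path output path.
#' @export
write_expression_tsv <- function(em, path) {
  stopifnot(inherits(em, "expr_mat"))
  df <- data.frame(gene = rownames(em$values), em$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sample metadata TSV (sample_id, role, time_months, event)
#' @param path TSV path.
#' @return data.frame with those four columns; survival fields are `NA` for
#'   normals.
#' @export
read_metadata_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "role", "time_months", "event")
  if (!all(need %in% names(df))) {
    stop("metadata must have columns: ", paste(need, collapse = ", "))
  }
  df[need]
}

#' Write sample metadata TSV
#' @param metadata data.frame with sample_id, role, time_months, event.
#' @param path output path.
#' @export
write_metadata_tsv <- function(metadata, path) {
  utils::write.table(metadata, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, `name TAB description TAB gene...`.
#' Genes are upper-cased and de-duplicated preserving order.
#'
#' @param path GMT file path.
#' @return named list of [gene_set()] objects (possibly empty, with a
#'   warning, for an empty file).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    warning("empty GMT file: ", path)
    return(stats::setNames(list(), character()))
  }
  sets <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) {
      stop(sprintf("GMT line %d: fewer than 3 tab-separated fields", i))
    }
    sets[[i]] <- gene_set(f[1], f[-(1:2)], description = f[2])
  }
  stats::setNames(sets, vapply(sets, `[[`, "", "name"))
}

#' Write gene sets to a GMT file
#' @param sets a `gene_set` or list of them.
#' @param path output path.
#' @export
write_gmt <- function(sets, path) {
  if (inherits(sets, "gene_set")) sets <- list(sets)
  lines <- vapply(sets, function(s) {
    paste(c(s$name, s$description, s$genes), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' The packaged AR-repressed NF-kB target gene set
#'
#' The 29 published NF-kB target genes with reduced expression in tumors
#' with elevated androgen signaling, shipped as a GMT fixture.
#' @return a [gene_set()] of 29 genes.
#' @export
ar_repressed_nfkb_targets <- function() {
  path <- system.file("extdata", "ar_repressed_nfkb_targets.gmt",
                      package = "arnfkb", mustWork = TRUE)
  read_gmt(path)[[1]]
}
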