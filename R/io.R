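#' Read a GMT gene-set collection
#'
#' Parses the tab-separated GMT dialect used by MSigDB (one set per line:
#' `name <TAB> description <TAB> gene <TAB> gene ...`). Duplicate genes within
#' a line are dropped keeping the first occurrence (with a warning); trailing
#' empty fields are ignored.
#'
#' @param path Path to a GMT file.
#' @return A `gene_set_collection`: a named list of character vectors of gene
#'   ids, with per-set description strings stored in the `"descriptions"`
#'   attribute.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- vector("list", length(lines))
  descs <- character(length(lines))
  nms <- character(length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    # trailing empty fields (from trailing tabs) carry no genes
    while (length(fields) > 0 && !nzchar(fields[length(fields)])) {
      fields <- fields[-length(fields)]
    }
    if (length(fields) < 3) {
      stop("malformed GMT line ", i, ": fewer than 3 tab-separated fields")
    }
    genes <- fields[-(1:2)]
    if (anyDuplicated(genes)) {
      warning("duplicate gene ids in set '", fields[[1]], "' (line ", i,
              "); keeping first occurrence")
      genes <- genes[!duplicated(genes)]
    }
    nms[[i]] <- fields[[1]]
    descs[[i]] <- fields[[2]]
    sets[[i]] <- genes
  }
  if (anyDuplicated(nms)) {
    stop("duplicate set name(s) in GMT: ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "))
  }
  names(sets) <- nms
  names(descs) <- nms
  new_gene_set_collection(sets, descs)
}

new_gene_set_collection <- function(sets, descriptions = NULL) {
  stopifnot(is.list(sets))
  if (is.null(names(sets)) && length(sets) > 0)
    stop("gene sets must be named")
  if (anyDuplicated(names(sets))) stop("duplicate set names")
  if (any(lengths(sets) == 0)) stop("empty gene set(s): ",
    paste(names(sets)[lengths(sets) == 0], collapse = ", "))
  if (is.null(descriptions)) {
    descriptions <- stats::setNames(rep("", length(sets)), names(sets))
  }
  structure(sets, descriptions = descriptions, class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat("gene_set_collection with", length(x), "sets\n")
  if (length(x)) {
    sz <- lengths(x)
    cat("  sizes:", min(sz), "-", max(sz), "genes\n")
    utils::head(names(x), 5) |> paste(collapse = ", ") |> cat("\n")
  }
  invisible(x)
}

#' Write a gene-set collection to GMT
#'
#' Inverse of [read_gmt()]: one tab-separated, newline-terminated line per set.
#'
#' @param collection A `gene_set_collection` (or plain named list of character
#'   vectors).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  descs <- attr(collection, "descriptions")
  lines <- vapply(seq_along(collection), function(i) {
    d <- if (!is.null(descs)) descs[[i]] else ""
    paste(c(names(collection)[[i]], d, collection[[i]]), collapse = "\t")
  }, character(1))
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (length(lines)) writeLines(lines, con, sep = "\n")
  invisible(path)
}

sniff_delimiter <- function(path) {
  header <- readLines(path, n = 1L, warn = FALSE)
  if (grepl("\t", header, fixed = TRUE)) "\t"
  else if (grepl(",", header, fixed = TRUE)) ","
  else "\t"
}

#' Read a delimited expression matrix
#'
#' Reads a TSV/CSV table of log-scale expression values with a gene-identifier
#' column and sample ids in the header. Values must be finite; missing or
#' non-numeric cells are rejected (no imputation policy is implemented).
#'
#' @param path Path to the table.
#' @param gene_column Name of the gene-identifier column (default: first
#'   column).
#' @param delimiter `"auto"` (header sniffing, tab preferred), `"tab"` or
#'   `"comma"`.
#' @param collapse_duplicates If `TRUE`, duplicate gene ids are collapsed with
#'   [collapse_duplicate_genes()] (highest mean expression wins); if `FALSE`
#'   (default) duplicates are an error.
#' @return Numeric matrix, genes x samples, with gene ids as rownames and
#'   sample ids as colnames.
#' @export
read_expression <- function(path, gene_column = NULL,
                            delimiter = c("auto", "tab", "comma"),
                            collapse_duplicates = FALSE) {
  delimiter <- match.arg(delimiter)
  sep <- switch(delimiter, auto = sniff_delimiter(path), tab = "\t", comma = ",")
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "")
  if (is.null(gene_column)) gene_column <- names(df)[[1]]
  if (!gene_column %in% names(df)) {
    stop("gene column '", gene_column, "' not found in header")
  }
  if (anyDuplicated(names(df))) {  # before subsetting: [.data.frame uniquifies
    stop("duplicate sample id(s) in header: ",
         paste(unique(names(df)[duplicated(names(df))]), collapse = ", "))
  }
  gene_ids <- as.character(df[[gene_column]])
  body <- df[-match(gene_column, names(df))]
  for (j in seq_along(body)) {
    if (is.logical(body[[j]]) && all(is.na(body[[j]]))) {
      body[[j]] <- as.numeric(body[[j]])  # all-NA column; rejected below
    }
    if (!is.numeric(body[[j]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(body[[j]]))) &
                     !is.na(body[[j]]))[1]
      stop("non-numeric value in column '", names(body)[[j]], "', row ",
           if (is.na(bad)) "?" else bad)
    }
  }
  m <- as.matrix(body)
  if (anyNA(m) || any(!is.finite(m))) {
    stop("expression matrix contains missing or non-finite values; ",
         "no imputation is performed")
  }
  rownames(m) <- gene_ids
  if (anyDuplicated(gene_ids)) {
    if (!collapse_duplicates) {
      stop("duplicate gene id(s): ",
           paste(utils::head(unique(gene_ids[duplicated(gene_ids)]), 5),
                 collapse = ", "),
           "; re-run with collapse_duplicates = TRUE to keep the row with ",
           "the highest mean expression per gene")
    }
    m <- collapse_duplicate_genes(m)
  }
  validate_expression(m)
}

validate_expression <- function(m) {
  stopifnot(is.matrix(m), is.numeric(m))
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop("expression matrix needs gene rownames and sample colnames")
  if (anyDuplicated(rownames(m))) stop("duplicate gene ids")
  if (anyDuplicated(colnames(m))) stop("duplicate sample ids")
  if (anyNA(m) || any(!is.finite(m))) stop("non-finite expression values")
  m
}

#' Collapse duplicate gene rows by highest mean expression
#'
#' Where several rows (e.g. probesets) share a gene id, keeps exactly the row
#' whose mean across all samples is highest; ties are broken by first
#' occurrence in input order. The mean is computed over all samples,
#' label-agnostically.
#'
#' @param m Numeric matrix with (possibly duplicated) gene ids as rownames.
#' @return Matrix with one row per distinct gene id, input order of first
#'   occurrences preserved.
#' @export
collapse_duplicate_genes <- function(m) {
  stopifnot(is.matrix(m), nrow(m) >= 1)
  ids <- rownames(m)
  means <- rowMeans(m)
  # stable within-gene order => which.max picks the first of tied maxima
  keep <- unlist(lapply(split(seq_len(nrow(m)), factor(ids, levels = unique(ids))),
                        function(idx) idx[which.max(means[idx])]),
                 use.names = FALSE)
  m[sort(keep), , drop = FALSE]
}

#' Read a phenotype (sample-to-group) table
#'
#' @param path Path to a delimited table with one row per sample.
#' @param sample_column,group_column Column names holding sample ids and group
#'   labels.
#' @param delimiter `"auto"`, `"tab"` or `"comma"`.
#' @return Named character vector: group labels named by sample id.
#' @export
read_phenotype <- function(path, sample_column = "sample",
                           group_column = "group",
                           delimiter = c("auto", "tab", "comma")) {
  delimiter <- match.arg(delimiter)
  sep <- switch(delimiter, auto = sniff_delimiter(path), tab = "\t", comma = ",")
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "")
  for (col in c(sample_column, group_column)) {
    if (!col %in% names(df)) stop("column '", col, "' not found in phenotype table")
  }
  ids <- as.character(df[[sample_column]])
  if (anyDuplicated(ids)) {
    stop("duplicate sample id(s) in phenotype table: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  stats::setNames(as.character(df[[group_column]]), ids)
}

#' Resolve a two-group contrast against an expression matrix
#'
#' Checks that both labels exist with at least `min_per_group` samples each and
#' that every selected sample is a column of `expr`.
#'
#' @param expr Expression matrix (genes x samples).
#' @param groups Named character vector of group labels (names = sample ids).
#' @param a,b The two group labels; `a` is the first (reference direction:
#'   metrics are a minus b).
#' @param min_per_group Minimum samples per group (default 2).
#' @return List with character vectors `a_samples`, `b_samples`.
#' @export
resolve_contrast <- function(expr, groups, a, b, min_per_group = 2L) {
  if (identical(a, b)) stop("contrast labels must differ")
  a_samples <- names(groups)[groups == a]
  b_samples <- names(groups)[groups == b]
  if (length(a_samples) == 0) stop("first group '", a, "' empty")
  if (length(b_samples) == 0) stop("second group '", b, "' empty")
  missing <- setdiff(c(a_samples, b_samples), colnames(expr))
  if (length(missing)) {
    stop("phenotype sample(s) absent from expression matrix: ",
         paste(utils::head(missing, 10), collapse = ", "))
  }
  if (length(a_samples) < min_per_group || length(b_samples) < min_per_group) {
    stop("each contrast group needs >= ", min_per_group, " samples (got ",
         length(a_samples), " '", a, "', ", length(b_samples), " '", b, "')")
  }
  list(a_samples = a_samples, b_samples = b_samples)
}

# Shared TSV writer: schema comment line, header, no quoting -- keeps CLI
# outputs byte-reproducible.
write_result_tsv <- function(df, path, schema_comment = NULL) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (!is.null(schema_comment)) {
    writeLines(paste0("# ", schema_comment), con, sep = "\n")
  }
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
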