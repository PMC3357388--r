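#' Read a log2 expression matrix from TSV
#'
#' Expects a header row of sample ids and a first column of gene ids; the
#' body must be fully numeric (log2 scale). Values such as `NA` or text in
#' the body are rejected with the offending cell named, and duplicated gene
#' ids are an error.
#'
#' @param path TSV file path.
#' @return Numeric matrix (genes x samples) with gene-id rownames and
#'   sample-id colnames.
#' @export
read_expression_matrix <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, colClasses = "character")
  if (ncol(df) < 2) stop("expression file needs a gene-id column plus >=1 sample", call. = FALSE)
  genes <- df[[1]]
  if (anyDuplicated(genes)) {
    stop("duplicate gene id(s): ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "), call. = FALSE)
  }
  body <- as.matrix(df[, -1, drop = FALSE])
  vals <- suppressWarnings(array(as.numeric(body), dim = dim(body)))
  bad <- which(!is.finite(vals), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("non-numeric or non-finite value '%s' at gene '%s', sample '%s'",
                 body[bad[1, 1], bad[1, 2]], genes[bad[1, 1]],
                 colnames(body)[bad[1, 2]]), call. = FALSE)
  }
  dimnames(vals) <- list(genes, colnames(body))
  vals
}

#' Write an expression matrix to TSV
#'
#' Inverse of [read_expression_matrix()]; round-trips to full double
#' precision (values serialised with 17 significant digits).
#'
#' @param mat Numeric matrix with rownames (gene ids) and colnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(mat, path) {
  stopifnot(is.matrix(mat), !is.null(rownames(mat)), !is.null(colnames(mat)))
  df <- data.frame(gene_id = rownames(mat),
                   formatC(mat, format = "g", digits = 17),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("gene_id", colnames(mat))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and validate a sample table
#'
#' Requires columns `sample_id`, `condition`, `zt`, `replicate`. ZT values
#' are reduced modulo `period` into `[0, period)`. Validation enforces
#' unique sample ids and, per condition, at least two distinct timepoints
#' (a single timepoint makes rhythm fitting impossible).
#'
#' @param path TSV file path.
#' @param period Period in hours used for the modular reduction (default 24).
#' @return `data.frame` with columns sample_id, condition, zt, replicate.
#' @export
read_sample_table <- function(path, period = 24) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  validate_sample_table(df, period = period)
}

#' @rdname read_sample_table
#' @param df A data.frame already in memory (validated in place).
#' @export
validate_sample_table <- function(df, period = 24) {
  need <- c("sample_id", "condition", "zt", "replicate")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("sample table missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  zt <- suppressWarnings(as.numeric(df$zt))
  if (any(!is.finite(zt))) {
    stop("non-numeric zt value(s): row ",
         paste(which(!is.finite(zt)), collapse = ", "), call. = FALSE)
  }
  df$zt <- zt %% period
  df$sample_id <- as.character(df$sample_id)
  df$condition <- as.character(df$condition)
  df$replicate <- as.integer(df$replicate)
  if (anyDuplicated(df$sample_id)) {
    stop("duplicate sample_id(s): ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "),
         call. = FALSE)
  }
  if (any(df$replicate < 1)) stop("replicate must be a positive integer", call. = FALSE)
  nzt <- tapply(df$zt, df$condition, function(z) length(unique(z)))
  if (any(nzt < 2)) {
    stop("condition(s) with fewer than 2 distinct timepoints: ",
         paste(names(nzt)[nzt < 2], collapse = ", "), call. = FALSE)
  }
  df[, need]
}

#' Write a sample table to TSV
#' @param df Sample table data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sample_table <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' One set per line: name, description, then member gene ids, all
#' tab-separated. Duplicate members within a set are removed; an empty file
#' yields an empty (valid) collection.
#'
#' @param path GMT file path.
#' @return Named list of character vectors of member ids, with a
#'   `"descriptions"` attribute (named character vector).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  desc <- character(0)
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3) {
      stop(sprintf("GMT line %d has %d field(s); need name, description, >=1 member",
                   i, length(fields)), call. = FALSE)
    }
    members <- unique(fields[-(1:2)])
    members <- members[nzchar(members)]
    if (length(members) == 0) {
      stop(sprintf("GMT line %d ('%s') defines an empty set", i, fields[1]),
           call. = FALSE)
    }
    sets[[fields[1]]] <- members
    desc[fields[1]] <- fields[2]
  }
  attr(sets, "descriptions") <- desc
  sets
}

#' Write gene sets in GMT format
#' @param sets Named list of character vectors (see [read_gmt()]).
#' @param path Output path.
#' @param descriptions Optional named character vector of set descriptions.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, descriptions = attr(sets, "descriptions")) {
  lines <- vapply(names(sets), function(nm) {
    d <- if (!is.null(descriptions) && nm %in% names(descriptions)) descriptions[[nm]] else "NA"
    paste(c(nm, d, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

# Shared TSV writer for result tables: deterministic, full precision,
# no row names -- so identical inputs give byte-identical outputs.
write_result_table <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  for (j in which(num)) df[[j]] <- formatC(df[[j]], format = "g", digits = 17)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
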