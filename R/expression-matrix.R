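#' Labelled expression matrix
#'
#' The central container of the package: a genes x samples numeric matrix
#' with unique sample identifiers, optional per-sample binary class labels
#' (0 = normal, 1 = cancer) and a flag recording whether values are on the
#' linear or log2 scale. Gene identifiers may repeat before probe
#' collapsing (probe-level matrices); all supervised operations require
#' labels with both classes present.
#'
#' @param values numeric matrix, genes in rows, samples in columns. Row and
#'   column names are taken as gene and sample identifiers unless
#'   `gene_ids`/`sample_ids` are given.
#' @param gene_ids character vector of row identifiers.
#' @param sample_ids character vector of unique column identifiers.
#' @param labels optional per-sample labels, coerced via [attach_labels()]
#'   semantics (0/1 or "normal"/"cancer").
#' @param scale `"linear"` or `"log2"`.
#' @return An object of class `ExpressionMatrix`: a list with elements
#'   `values` (named numeric matrix), `labels` (integer 0/1 vector or
#'   `NULL`) and `scale`.
#' @examples
#' m <- expression_matrix(matrix(1:6, 3, 2), gene_ids = c("A", "B", "C"),
#'                        sample_ids = c("s1", "s2"))
#' dim(m$values)
#' @export
expression_matrix <- function(values, gene_ids = rownames(values),
                              sample_ids = colnames(values),
                              labels = NULL,
                              scale = c("linear", "log2")) {
  scale <- match.arg(scale)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(gene_ids) || is.null(sample_ids))
    stop("gene_ids and sample_ids are required (row/column names or explicit)")
  gene_ids <- as.character(gene_ids)
  sample_ids <- as.character(sample_ids)
  if (nrow(values) != length(gene_ids))
    stop("row count (", nrow(values), ") != number of gene ids (",
         length(gene_ids), ")")
  if (ncol(values) != length(sample_ids))
    stop("column count (", ncol(values), ") != number of sample ids (",
         length(sample_ids), ")")
  if (anyDuplicated(sample_ids))
    stop("duplicate sample id: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  if (!all(is.finite(values)))
    stop("expression values must all be finite")
  dimnames(values) <- list(gene_ids, sample_ids)
  obj <- structure(list(values = values, labels = NULL, scale = scale),
                   class = "ExpressionMatrix")
  if (!is.null(labels)) obj <- attach_labels(obj, labels)
  obj
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d samples [%s scale]\n",
              nrow(x$values), ncol(x$values), x$scale))
  if (is.null(x$labels)) {
    cat("  labels: <none>\n")
  } else {
    cat(sprintf("  labels: %d normal (0), %d cancer (1)\n",
                sum(x$labels == 0L), sum(x$labels == 1L)))
  }
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

gene_ids <- function(mat) rownames(mat$values)
sample_ids <- function(mat) colnames(mat$values)

is_labelled <- function(mat) !is.null(mat$labels)

check_two_classes <- function(mat) {
  if (!is_labelled(mat))
    stop("matrix has no labels; call attach_labels() first")
  if (length(unique(mat$labels)) < 2L)
    stop("both classes must be present for supervised operations")
  invisible(mat)
}

#' Attach per-sample class labels
#'
#' Labels may be supplied as a vector named by sample id, an unnamed vector
#' in column order, or a two-column data frame (sample_id, label). Accepted
#' label codes are 0/1 or, case-insensitively, "normal"/"cancer".
#'
#' @param mat an [expression_matrix()].
#' @param labels label vector or two-column data frame.
#' @return The matrix with `labels` set (integer 0/1, one per sample).
#' @export
attach_labels <- function(mat, labels) {
  stopifnot(inherits(mat, "ExpressionMatrix"))
  if (is.data.frame(labels)) {
    if (ncol(labels) < 2L)
      stop("label data frame needs columns (sample_id, label)")
    labels <- stats::setNames(labels[[2L]], as.character(labels[[1L]]))
  }
  lab <- coerce_labels(labels)
  sid <- sample_ids(mat)
  if (!is.null(names(lab))) {
    missing <- setdiff(sid, names(lab))
    if (length(missing))
      stop("no label for sample(s): ", paste(missing, collapse = ", "))
    lab <- lab[sid]
  } else if (length(lab) != length(sid)) {
    stop("unnamed label vector length (", length(lab),
         ") != sample count (", length(sid), ")")
  }
  mat$labels <- unname(lab)
  mat
}

coerce_labels <- function(labels) {
  nm <- names(labels)
  if (is.character(labels) || is.factor(labels)) {
    key <- tolower(trimws(as.character(labels)))
    out <- ifelse(key %in% c("1", "cancer", "tumor", "tumour"), 1L,
                  ifelse(key %in% c("0", "normal"), 0L, NA_integer_))
  } else {
    out <- as.integer(labels)
    out[!(out %in% c(0L, 1L))] <- NA_integer_
  }
  if (anyNA(out))
    stop("labels must be 0/1 or normal/cancer; offending value(s): ",
         paste(unique(as.character(labels)[is.na(out)]), collapse = ", "))
  names(out) <- nm
  out
}

#' Read an expression matrix from disk
#'
#' Supports two dialects: plain tab-delimited text (`tsv`; header row of
#' sample ids, first column of gene/probe ids) and the GEO series-matrix
#' table (`series_matrix`; metadata lines prefixed `!`, the numeric table
#' bounded by `!series_matrix_table_begin` / `!series_matrix_table_end`,
#' identifiers possibly double-quoted).
#'
#' Labels are not read here; pair with [read_labels()] and
#' [attach_labels()].
#'
#' @param path file path.
#' @param dialect `"tsv"` or `"series_matrix"`.
#' @return An unlabelled [expression_matrix()] with `scale = "linear"`
#'   (re-flag with [log2_transform()] or construct directly if the file is
#'   already on the log scale).
#' @export
read_matrix <- function(path, dialect = c("tsv", "series_matrix")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (dialect == "series_matrix") {
    begin <- grep("^!series_matrix_table_begin", lines)
    end <- grep("^!series_matrix_table_end", lines)
    if (length(begin) != 1L || length(end) != 1L || end <= begin + 1L)
      stop("series-matrix sentinels not found or table empty in ", path)
    lines <- lines[(begin + 1L):(end - 1L)]
  }
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) stop("no data rows in ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  unquote <- function(x) gsub('^"|"$', "", x)
  header <- unquote(fields[[1L]])
  samples <- header[-1L]
  n_col <- length(header)
  body <- fields[-1L]
  bad <- which(vapply(body, length, 1L) != n_col)
  if (length(bad))
    stop("row ", bad[1L] + 1L, " has ", length(body[[bad[1L]]]),
         " fields, expected ", n_col)
  ids <- unquote(vapply(body, `[[`, "", 1L))
  raw <- vapply(body, function(f) unquote(f[-1L]), character(n_col - 1L))
  raw <- matrix(raw, nrow = n_col - 1L)  # columns = genes at this point
  num <- suppressWarnings(as.numeric(raw))
  if (anyNA(num)) {
    at <- which(is.na(num))[1L]
    g <- (at - 1L) %/% (n_col - 1L) + 1L
    s <- (at - 1L) %% (n_col - 1L) + 1L
    stop("non-numeric value \"", raw[at], "\" at gene '", ids[g],
         "', sample '", samples[s], "'")
  }
  values <- t(matrix(num, nrow = n_col - 1L,
                     dimnames = list(samples, ids)))
  expression_matrix(values, gene_ids = ids, sample_ids = samples)
}

#' Write an expression matrix as tab-delimited text
#'
#' Inverse of [read_matrix()] for the `tsv` dialect (up to floating-point
#' formatting; values are printed at full double precision).
#'
#' @param mat an [expression_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(mat, path) {
  stopifnot(inherits(mat, "ExpressionMatrix"))
  df <- data.frame(gene_id = gene_ids(mat),
                   format(mat$values, digits = 17, trim = TRUE,
                          scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("gene_id", sample_ids(mat))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a two-column label file
#'
#' @param path TSV with columns (sample_id, label); label in 0/1 or
#'   normal/cancer. A header line is detected and skipped if its second
#'   field is not a recognised label code.
#' @return Named integer vector of 0/1 labels.
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, header = FALSE, colClasses = "character")
  if (ncol(df) < 2L) stop("label file needs two tab-separated columns")
  first <- tolower(trimws(df[1L, 2L]))
  if (!first %in% c("0", "1", "normal", "cancer", "tumor", "tumour"))
    df <- df[-1L, , drop = FALSE]
  coerce_labels(stats::setNames(df[[2L]], df[[1L]]))
}

#' Collapse probe-level rows to one representative row per gene
#'
#' Probes are first partitioned into probe groups within each gene: probes
#' sharing a probe-set prefix (the identifier with a trailing
#' \code{.<digits>} member suffix removed) form one group; a probe without
#' such a suffix is its own group. Each group is averaged per sample, and
#' the group with the largest grand mean across samples is taken as the
#' gene's representative row. Probes absent from the map are dropped with a
#' message.
#'
#' @param mat probe-level [expression_matrix()] (row ids are probe ids).
#' @param probe_map data frame with columns `probe_id`, `gene_id`; every
#'   probe maps to exactly one gene.
#' @return An [expression_matrix()] with one row per mapped gene, in order
#'   of first appearance in `mat`.
#' @export
collapse_probes <- function(mat, probe_map) {
  stopifnot(inherits(mat, "ExpressionMatrix"))
  pm <- as.data.frame(probe_map, stringsAsFactors = FALSE)
  if (!all(c("probe_id", "gene_id") %in% colnames(pm)))
    stop("probe_map needs columns 'probe_id' and 'gene_id'")
  if (anyDuplicated(pm$probe_id))
    stop("probe map is not many-probes-to-one-gene: duplicated probe id(s): ",
         paste(unique(pm$probe_id[duplicated(pm$probe_id)]), collapse = ", "))
  probes <- gene_ids(mat)
  keep <- probes %in% pm$probe_id
  if (!any(keep))
    stop("no probe ids in the matrix are present in the probe map")
  n_drop <- sum(!keep)
  if (n_drop > 0L)
    message(n_drop, " unmapped probe(s) dropped")
  vals <- mat$values[keep, , drop = FALSE]
  probes <- probes[keep]
  gene_of <- pm$gene_id[match(probes, pm$probe_id)]
  group_of <- sub("\\.[0-9]+$", "", probes)
  genes <- unique(gene_of)
  out <- matrix(NA_real_, length(genes), ncol(vals),
                dimnames = list(genes, sample_ids(mat)))
  for (g in genes) {
    rows <- which(gene_of == g)
    grp <- split(rows, group_of[rows])
    grp_means <- lapply(grp, function(idx)
      colMeans(vals[idx, , drop = FALSE]))
    best <- which.max(vapply(grp_means, mean, 0))
    out[g, ] <- grp_means[[best]]
  }
  expression_matrix(out, labels = mat$labels, scale = mat$scale)
}

#' Resolve duplicate gene ids in a pre-collapsed matrix
#'
#' When a matrix already carries gene symbols but the same symbol appears on
#' several rows, the row with the largest grand mean across samples is kept
#' (the same "largest representative" convention as [collapse_probes()]); a
#' message reports how many rows were dropped.
#'
#' @param mat an [expression_matrix()].
#' @return The matrix with unique gene ids.
#' @export
resolve_duplicate_genes <- function(mat) {
  stopifnot(inherits(mat, "ExpressionMatrix"))
  ids <- gene_ids(mat)
  if (!anyDuplicated(ids)) return(mat)
  gm <- rowMeans(mat$values)
  ord <- order(-gm)  # best row of each gene comes first
  keep_first <- ord[!duplicated(ids[ord])]
  keep <- sort(keep_first)  # preserve original row order
  message(length(ids) - length(keep), " duplicate gene row(s) dropped")
  expression_matrix(mat$values[keep, , drop = FALSE],
                    labels = mat$labels, scale = mat$scale)
}

#' Log2-transform a linear-scale matrix
#'
#' Replaces every value by `log2(value + offset)` and flags the matrix as
#' log2 scale. Applying the transform twice is an error, as is a
#' non-positive value with `offset = 0` (set `offset = 1` for count-like
#' data containing zeros).
#'
#' @param mat an [expression_matrix()] with `scale = "linear"`.
#' @param offset non-negative constant added before taking logs (default 0).
#' @return The transformed matrix, `scale = "log2"`.
#' @export
log2_transform <- function(mat, offset = 0) {
  stopifnot(inherits(mat, "ExpressionMatrix"))
  if (mat$scale == "log2")
    stop("matrix is already transformed to log2 scale")
  if (offset < 0) stop("offset must be non-negative")
  shifted <- mat$values + offset
  if (any(shifted <= 0)) {
    bad <- which(shifted <= 0, arr.ind = TRUE)[1L, ]
    stop("non-positive value at gene '", gene_ids(mat)[bad[1L]],
         "', sample '", sample_ids(mat)[bad[2L]],
         "' with offset ", offset, "; set a positive offset (commonly 1)")
  }
  mat$values <- log2(shifted)
  mat$scale <- "log2"
  mat
}

#' Restrict a matrix to a subset of samples
#' @noRd
subset_samples <- function(mat, idx) {
  out <- mat
  out$values <- mat$values[, idx, drop = FALSE]
  if (!is.null(mat$labels)) out$labels <- mat$labels[idx]
  out
}
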