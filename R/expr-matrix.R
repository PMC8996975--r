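#' Two-class expression matrix
#'
#' Lightweight container for a probes-or-genes x samples expression matrix
#' with a scale tag and a two-class phenotype. The `linear` scale carries
#' background-corrected intensities (arbitrary units, strictly positive,
#' the MAS5-style track); the `log2` scale carries log2 intensities (the
#' gcRMA-style track).
#'
#' @param values numeric matrix, rows = probes or genes, columns = samples.
#'   Must have unique, non-empty dimnames and finite entries.
#' @param scale `"linear"` or `"log2"`. Linear values must be > 0.
#' @param phenotype character or factor of per-sample class labels, length
#'   `ncol(values)`, with exactly two levels.
#' @return an object of class `expr_matrix`: a list with elements `values`,
#'   `scale` and `phenotype` (a factor aligned to the columns).
#' @export
expr_matrix <- function(values, scale = c("log2", "linear"), phenotype) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must have row and column names")
  if (anyDuplicated(rownames(values)))
    stop("duplicate row IDs in expression matrix")
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample IDs in expression matrix")
  if (!all(is.finite(values)))
    stop("expression values must be finite")
  if (scale == "linear" && any(values <= 0))
    stop("linear-scale expression values must be > 0")
  # preserve the caller's class order: the first level is the disease /
  # positive class throughout the pipeline
  phenotype <- if (is.factor(phenotype)) droplevels(phenotype)
  else factor(phenotype, levels = unique(phenotype))
  if (length(phenotype) != ncol(values))
    stop("phenotype length must equal the number of samples")
  if (nlevels(phenotype) != 2L)
    stop("phenotype must have exactly two classes, got ", nlevels(phenotype))
  structure(list(values = values, scale = scale, phenotype = phenotype),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d rows x %d samples [%s scale]\n",
              nrow(x$values), ncol(x$values), x$scale))
  tab <- table(x$phenotype)
  cat("phenotype:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Subset the rows of an expression matrix
#'
#' @param x an [expr_matrix()].
#' @param rows row IDs or indices to keep (in the given order).
#' @return an [expr_matrix()] with the selected rows; scale and phenotype
#'   are preserved.
#' @export
subset_rows <- function(x, rows) {
  expr_matrix(x$values[rows, , drop = FALSE], scale = x$scale,
              phenotype = x$phenotype)
}

#' Read / write an expression matrix as TSV
#'
#' The on-disk layout is one header line (`id` then sample IDs) and one row
#' per probe/gene; leading `#` lines are treated as comments. The phenotype
#' is carried separately in a CLS file (see [read_cls()]).
#'
#' @param path file path.
#' @param scale scale tag for the matrix read (`"log2"` or `"linear"`).
#' @param phenotype per-sample labels aligned to the file's column order.
#' @return [read_expr_tsv()] returns an `expr_matrix`;
#'   [write_expr_tsv()] returns `path` invisibly.
#' @export
read_expr_tsv <- function(path, scale = c("log2", "linear"), phenotype) {
  scale <- match.arg(scale)
  df <- utils::read.delim(path, header = TRUE, comment.char = "#",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("expression TSV needs an ID column plus samples: ", path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  storage.mode(m) <- "double"
  expr_matrix(m, scale = scale, phenotype = phenotype)
}

#' @rdname read_expr_tsv
#' @param x an `expr_matrix`.
#' @param comments optional character vector written as leading `#` lines.
#' @export
write_expr_tsv <- function(x, path, comments = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(comments))
    writeLines(paste0("# ", comments), con)
  writeLines(paste(c("id", colnames(x$values)), collapse = "\t"), con)
  utils::write.table(data.frame(id = rownames(x$values), x$values,
                                check.names = FALSE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read / write CLS phenotype files
#'
#' The CLS format is three lines: `<n_samples> <n_classes> 1`, then
#' `# <class names>`, then the space-separated per-sample labels. Exactly
#' two classes are enforced for this pipeline.
#'
#' @param path file path.
#' @return [read_cls()] returns a factor of per-sample labels.
#' @export
read_cls <- function(path) {
  ln <- readLines(path, warn = FALSE)
  ln <- ln[nzchar(trimws(ln))]
  if (length(ln) < 3L) stop("CLS file must have 3 lines: ", path)
  hdr <- as.integer(strsplit(trimws(ln[1]), "\\s+")[[1]])
  labels <- strsplit(trimws(ln[3]), "\\s+")[[1]]
  if (length(labels) != hdr[1])
    stop("CLS count line says ", hdr[1], " samples but ", length(labels),
         " labels found")
  classes <- unique(labels)
  if (length(classes) != 2L)
    stop("CLS phenotype must have exactly two classes, got ",
         length(classes))
  if (!is.na(hdr[2]) && hdr[2] != length(classes))
    stop("CLS count line declares ", hdr[2], " classes but labels contain ",
         length(classes))
  factor(labels, levels = classes)
}

#' @rdname read_cls
#' @param phenotype factor or character of per-sample labels (two classes).
#' @export
write_cls <- function(phenotype, path) {
  phenotype <- as.factor(as.character(phenotype))
  if (nlevels(phenotype) != 2L) stop("phenotype must have exactly two classes")
  writeLines(c(
    paste(length(phenotype), nlevels(phenotype), 1),
    paste("#", paste(levels(phenotype), collapse = " ")),
    paste(as.character(phenotype), collapse = " ")
  ), path)
  invisible(path)
}

# deterministic sub-seed derivation: every stage/stream draws its RNG seed
# from the single user seed via a fixed affine map (kept below 2^31 - 1)
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  offs <- sum(utf8ToInt(as.character(stream)))
  as.integer((as.numeric(seed) * 1009 + offs * 7919) %% 2147483647)
}
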