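#' Validate a genes-by-samples expression matrix
#'
#' The package represents expression data as a plain numeric matrix in
#' genes x samples orientation, with unique gene identifiers as row names
#' and unique sample identifiers as column names (log2-scale intensities).
#' This checks the representation invariants and returns the matrix
#' invisibly so it can be used in pipelines.
#'
#' @param m numeric matrix, genes in rows, samples in columns.
#' @param allow_na logical; if `FALSE` (default) any non-finite value is an
#'   error. Preprocessing steps require complete data.
#' @return `m`, invisibly.
#' @export
validate_expression <- function(m, allow_na = FALSE) {
  if (!is.matrix(m) || !is.numeric(m))
    stop("expression data must be a numeric matrix (genes x samples)")
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop("expression matrix needs gene row names and sample column names")
  dup_g <- unique(rownames(m)[duplicated(rownames(m))])
  if (length(dup_g))
    stop("duplicate gene identifiers: ", paste(dup_g, collapse = ", "))
  dup_s <- unique(colnames(m)[duplicated(colnames(m))])
  if (length(dup_s))
    stop("duplicate sample identifiers: ", paste(dup_s, collapse = ", "))
  if (!allow_na && any(!is.finite(m)))
    stop("expression matrix contains non-finite values")
  invisible(m)
}

#' Read an expression matrix from delimited text
#'
#' Reads a TSV/CSV file with a header row and identifier column into a
#' genes x samples matrix. Files stored samples-in-rows are transposed on
#' read so the in-memory orientation is always genes x samples.
#'
#' @param path file path.
#' @param genes_in_rows logical; `TRUE` (default) if rows of the file are
#'   genes, `FALSE` if rows are samples.
#' @param sep field separator; `"\t"` for `.tsv`/`.txt`, `","` for `.csv`
#'   when `NULL`.
#' @return numeric matrix, genes x samples.
#' @export
read_expression <- function(path, genes_in_rows = TRUE, sep = NULL) {
  if (is.null(sep))
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = NULL,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = NA)
  ids <- as.character(df[[1L]])
  body <- df[-1L]
  bad <- !vapply(body, is.numeric, logical(1))
  if (any(bad)) {
    # locate first offending cell for a useful message
    col <- names(body)[which(bad)[1L]]
    v <- suppressWarnings(as.numeric(body[[which(bad)[1L]]]))
    row <- ids[which(is.na(v))[1L]]
    stop("non-numeric value in column '", col, "', row '", row, "'")
  }
  m <- as.matrix(body)
  rownames(m) <- ids
  if (!genes_in_rows) m <- t(m)
  validate_expression(m, allow_na = TRUE)
  m
}

#' Write an expression matrix to delimited text
#'
#' Round-trips with [read_expression()].
#'
#' @param m genes x samples matrix.
#' @param path output path.
#' @param genes_in_rows orientation on disk.
#' @param sep field separator (default tab).
#' @param id_column name for the identifier column.
#' @export
write_expression <- function(m, path, genes_in_rows = TRUE, sep = "\t",
                             id_column = "gene_id") {
  out <- if (genes_in_rows) m else t(m)
  df <- data.frame(id = rownames(out), out, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1L] <- id_column
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Collapse probe-level rows to gene level by the per-sample median
#'
#' Microarray platforms measure several probes per gene; the gene-level
#' expression used throughout the pipeline is the per-sample median over a
#' gene's probes. Probes absent from the map are dropped and counted.
#'
#' @param probe_matrix probes x samples matrix (probe ids as row names).
#' @param probe_to_gene data.frame with columns `probe` and `gene`, or a
#'   named character vector (names = probes, values = genes). Each probe
#'   maps to at most one gene.
#' @return genes x samples matrix with attribute `"unmapped_probes"`
#'   (character vector of dropped probe ids).
#' @export
collapse_probes <- function(probe_matrix, probe_to_gene) {
  validate_expression(probe_matrix, allow_na = TRUE)
  if (is.data.frame(probe_to_gene)) {
    map <- stats::setNames(as.character(probe_to_gene$gene),
                           as.character(probe_to_gene$probe))
  } else {
    map <- probe_to_gene
  }
  if (!length(map)) stop("empty probe-to-gene mapping")
  if (anyDuplicated(names(map)))
    stop("a probe maps to more than one gene: ",
         paste(unique(names(map)[duplicated(names(map))]), collapse = ", "))
  probes <- rownames(probe_matrix)
  mapped <- probes %in% names(map)
  unmapped <- probes[!mapped]
  sub <- probe_matrix[mapped, , drop = FALSE]
  genes <- map[rownames(sub)]
  out <- do.call(rbind, lapply(split(seq_len(nrow(sub)), genes), function(i) {
    apply(sub[i, , drop = FALSE], 2L, stats::median)
  }))
  out <- out[order(rownames(out)), , drop = FALSE]
  colnames(out) <- colnames(probe_matrix)
  attr(out, "unmapped_probes") <- unmapped
  out
}

#' Quantile-normalize the samples of an expression matrix
#'
#' Forces every sample (column) to share the same empirical distribution:
#' the across-sample mean of the order statistics. Tied values within a
#' column receive the mean of the quantile values they span, which makes
#' the operation deterministic and idempotent.
#'
#' @param m genes x samples matrix with no missing values.
#' @return matrix of the same shape, columns identically distributed.
#' @export
quantile_normalize <- function(m) {
  validate_expression(m)
  out <- limma::normalizeQuantiles(m, ties = TRUE)
  dimnames(out) <- dimnames(m)
  out
}

#' Quantile-map one expression matrix onto a reference distribution
#'
#' Applies a monotone transform to the target so that its pooled value
#' distribution matches the reference's pooled distribution (empirical
#' quantile mapping). Rank order within the target is preserved; this is
#' the cross-dataset alignment step applied after per-dataset
#' normalization, with one dataset designated as the reference standard.
#'
#' @param target genes x samples matrix to be transformed.
#' @param reference genes x samples matrix providing the target
#'   distribution.
#' @return transformed target matrix.
#' @export
align_to_reference <- function(target, reference) {
  validate_expression(target)
  if (is.null(reference) || !length(reference)) stop("empty reference matrix")
  validate_expression(reference)
  pool <- as.numeric(target)
  # map each value to its pooled plotting position, then to the matching
  # reference quantile (type-7 interpolation, ties share a position)
  r <- rank(pool, ties.method = "average")
  p <- (r - 1) / (length(pool) - 1)
  if (length(pool) == 1L) p <- 0.5
  mapped <- stats::quantile(as.numeric(reference), probs = p, names = FALSE,
                            type = 7)
  out <- matrix(mapped, nrow = nrow(target), dimnames = dimnames(target))
  out
}

#' Read a per-sample survival/clinical table
#'
#' Expects a delimited file with a header and at least the columns
#' `sample_id`, `time` (years, non-negative) and `event` (0 = censored,
#' 1 = relapse). Optional clinical covariates: `node` (0/1), `er` (0/1),
#' `grade` (1/2/3), `size` (cm), `age` (years); missing values allowed in
#' covariates, not in time/event.
#'
#' @param path file path.
#' @param sep separator (auto from extension when `NULL`).
#' @return validated data.frame.
#' @export
read_survival <- function(path, sep = NULL) {
  if (is.null(sep))
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  validate_survival(df)
}

#' Validate a survival table
#'
#' @param surv data.frame with `sample_id`, `time`, `event` and optional
#'   clinical columns.
#' @return the validated data.frame (sample_id coerced to character).
#' @export
validate_survival <- function(surv) {
  need <- c("sample_id", "time", "event")
  miss <- setdiff(need, names(surv))
  if (length(miss))
    stop("survival table lacks columns: ", paste(miss, collapse = ", "))
  surv$sample_id <- as.character(surv$sample_id)
  if (anyDuplicated(surv$sample_id))
    stop("duplicate sample identifiers in survival table")
  if (any(!is.finite(surv$time)) || any(surv$time < 0))
    stop("time must be finite and non-negative")
  if (!all(surv$event %in% c(0, 1)))
    stop("event must be 0 (censored) or 1 (relapse)")
  if ("node" %in% names(surv) &&
      !all(is.na(surv$node) | surv$node %in% c(0, 1)))
    stop("node must be 0/1 or missing")
  if ("grade" %in% names(surv) &&
      !all(is.na(surv$grade) | surv$grade %in% c(1, 2, 3)))
    stop("grade must be 1/2/3 or missing")
  surv
}

#' Write a survival table (round-trips with [read_survival()])
#' @param surv survival data.frame.
#' @param path output path.
#' @param sep separator.
#' @export
write_survival <- function(surv, path, sep = "\t") {
  utils::write.table(surv, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Check a seed-gene set against an expression matrix
#'
#' Seed genes anchor the co-expression networks. Missing seeds are
#' reported explicitly rather than silently dropped.
#'
#' @param seeds character vector of unique gene identifiers.
#' @param m expression matrix.
#' @param error if `TRUE` (default) missing seeds raise an error; otherwise
#'   they are returned.
#' @return character vector of seeds missing from `m` (empty if none).
#' @export
check_seed_genes <- function(seeds, m, error = TRUE) {
  if (anyDuplicated(seeds))
    stop("duplicate seed gene identifiers")
  missing <- setdiff(seeds, rownames(m))
  if (length(missing) && error)
    stop("seed genes absent from expression matrix: ",
         paste(missing, collapse = ", "))
  missing
}

# Align an expression matrix and survival table on shared samples, in the
# survival table's order. Internal helper used by the modeling layers.
align_samples <- function(m, surv) {
  keep <- intersect(surv$sample_id, colnames(m))
  if (!length(keep)) stop("no shared samples between expression and survival")
  list(m = m[, keep, drop = FALSE],
       surv = surv[match(keep, surv$sample_id), , drop = FALSE])
}
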