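#' Construct a feature-by-sample omics matrix
#'
#' The package represents expression (FPKM) and metabolite concentration
#' tables as plain numeric matrices with feature ids as row names and sample
#' ids as column names. An optional per-feature annotation table (e.g.
#' metabolite class and cuticle fraction) travels along as the
#' `"feature_meta"` attribute.
#'
#' @param values numeric matrix, features in rows, samples in columns.
#' @param feature_ids,sample_ids character vectors; default taken from
#'   `dimnames(values)`.
#' @param feature_meta optional `data.frame` with a `feature` column plus
#'   annotation columns such as `class` and `fraction`.
#' @param nonnegative if `TRUE`, negative entries are an error (expression
#'   matrices are FPKM and must be nonnegative).
#' @return numeric matrix with dimnames and, if given, a `feature_meta`
#'   attribute.
#' @export
omics_matrix <- function(values, feature_ids = rownames(values),
                         sample_ids = colnames(values),
                         feature_meta = NULL, nonnegative = FALSE) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(feature_ids) || is.null(sample_ids)) {
    stop("omics_matrix needs feature and sample ids")
  }
  if (anyDuplicated(feature_ids)) {
    stop("duplicated feature id(s): ",
         paste(unique(feature_ids[duplicated(feature_ids)]), collapse = ", "))
  }
  if (anyDuplicated(sample_ids)) {
    stop("duplicated sample id(s): ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  }
  if (!all(is.finite(values))) stop("omics matrix contains non-finite values")
  if (nonnegative && any(values < 0)) stop("expression matrix must be nonnegative")
  dimnames(values) <- list(feature_ids, sample_ids)
  if (!is.null(feature_meta)) {
    stopifnot(is.data.frame(feature_meta), "feature" %in% names(feature_meta))
    attr(values, "feature_meta") <- feature_meta
  }
  values
}

#' Feature annotations of an omics matrix
#' @param m matrix built by [omics_matrix()].
#' @return the `feature_meta` data.frame, or `NULL`.
#' @export
feature_meta <- function(m) attr(m, "feature_meta")

#' Read a feature-by-sample matrix from TSV/CSV
#'
#' Expects a header row of sample ids and feature ids in the first column.
#' The delimiter is inferred from the file extension (`.csv` means comma,
#' anything else tab).
#'
#' @param path file path.
#' @param kind `"expression"` (missing cells are an error, values must be
#'   nonnegative) or `"metabolite"` (empty cells are treated as 0, i.e.
#'   non-detected, with a warning).
#' @return numeric matrix as from [omics_matrix()].
#' @export
load_matrix <- function(path, kind = c("expression", "metabolite")) {
  kind <- match.arg(kind)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) < 1) stop("empty file: ", path)
  # sentinel keeps trailing empty fields, which strsplit would drop
  fields <- lapply(strsplit(paste0(lines, sep, "\x01"), sep, fixed = TRUE),
                   function(f) f[-length(f)])
  header <- fields[[1]]
  ncol_expected <- length(header)
  sample_ids <- header[-1]
  body <- fields[-1]
  n <- length(body)
  widths <- lengths(body)
  if (any(widths != ncol_expected)) {
    bad <- which(widths != ncol_expected)[1]
    stop(sprintf("ragged row at line %d of %s: %d fields, expected %d",
                 bad + 1L, path, widths[bad], ncol_expected))
  }
  flat <- unlist(body, use.names = FALSE)
  mat_chr <- matrix(flat, nrow = n, byrow = TRUE)
  feature_ids <- mat_chr[, 1]
  cells <- mat_chr[, -1, drop = FALSE]
  empties <- cells == "" | toupper(cells) == "NA"
  if (any(empties)) {
    if (kind == "expression") {
      bad <- which(rowSums(empties) > 0)[1]
      stop(sprintf("missing cell in expression matrix at line %d (feature %s)",
                   bad + 1L, feature_ids[bad]))
    }
    warning(sprintf("%d empty metabolite cell(s) in %s treated as 0 (non-detected)",
                    sum(empties), path))
    cells[empties] <- "0"
  }
  vals <- suppressWarnings(as.numeric(cells))
  if (anyNA(vals)) {
    idx <- which(is.na(matrix(vals, nrow = n)), arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric cell '%s' at line %d, column %d of %s",
                 cells[idx[1], idx[2]], idx[1] + 1L, idx[2] + 1L, path))
  }
  values <- matrix(vals, nrow = n, dimnames = list(feature_ids, sample_ids))
  omics_matrix(values, nonnegative = (kind == "expression"))
}

#' Write a feature-by-sample matrix to TSV/CSV
#'
#' Values are serialized with 17 significant digits so that
#' `load_matrix(write_matrix(m))` round-trips doubles exactly.
#'
#' @param m matrix from [omics_matrix()].
#' @param path output path; `.csv` extension selects comma separation.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(m, path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  header <- paste(c("feature_id", colnames(m)), collapse = sep)
  body <- vapply(seq_len(nrow(m)), function(i) {
    paste(c(rownames(m)[i], sprintf("%.17g", m[i, ])), collapse = sep)
  }, character(1))
  writeLines(c(header, body), path, useBytes = TRUE)
  invisible(path)
}

#' Read or write the sample metadata table
#'
#' Tab-separated with columns `sample_id`, `organ`, `genotype`, `replicate`.
#' @param path file path.
#' @return `data.frame` with factor columns `organ` and `genotype` (level
#'   order = order of first appearance) and integer `replicate`.
#' @export
load_metadata <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "organ", "genotype", "replicate")
  if (!all(need %in% names(df))) {
    stop("metadata must have columns: ", paste(need, collapse = ", "))
  }
  validate_metadata(data.frame(
    sample_id = as.character(df$sample_id),
    organ = factor(df$organ, levels = unique(df$organ)),
    genotype = factor(df$genotype, levels = unique(df$genotype)),
    replicate = as.integer(df$replicate),
    stringsAsFactors = FALSE
  ))
}

#' @rdname load_metadata
#' @param metadata metadata `data.frame`.
#' @export
write_metadata <- function(metadata, path) {
  utils::write.table(metadata, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

validate_metadata <- function(metadata) {
  if (anyDuplicated(metadata$sample_id)) stop("duplicated sample_id in metadata")
  key <- interaction(metadata$organ, metadata$genotype, metadata$replicate, drop = TRUE)
  if (anyDuplicated(key)) stop("duplicated (organ, genotype, replicate) in metadata")
  metadata
}

#' Drop genes expressed in too few samples
#'
#' A gene is kept when it has FPKM > 0 in strictly more than `min_fraction`
#' of the samples (default: expressed in >50% of samples). Survivor order is
#' preserved.
#'
#' @param expr expression matrix (genes x samples).
#' @param min_fraction threshold in `[0, 1)`.
#' @return filtered matrix.
#' @export
filter_low_expression <- function(expr, min_fraction = 0.5) {
  if (!is.numeric(min_fraction) || min_fraction < 0 || min_fraction >= 1) {
    stop("min_fraction must be in [0, 1)")
  }
  frac <- rowMeans(expr > 0)
  keep_meta(expr[frac > min_fraction, , drop = FALSE], expr)
}

keep_meta <- function(sub, orig) {
  fm <- feature_meta(orig)
  if (!is.null(fm)) {
    attr(sub, "feature_meta") <- fm[fm$feature %in% rownames(sub), , drop = FALSE]
  }
  sub
}

#' Standardize features to mean 0, variance 1
#'
#' Each feature row is centered and scaled by its sample standard deviation
#' (n - 1 denominator, matching `scale()`). Constant rows carry no pattern
#' and are dropped with a warning.
#'
#' @param m feature-by-sample matrix.
#' @return standardized matrix (possibly fewer rows).
#' @export
standardize <- function(m) {
  mu <- rowMeans(m)
  s <- apply(m, 1, sd)
  const <- s == 0 | !is.finite(s)
  if (any(const)) {
    warning(sprintf("dropping %d constant feature(s): %s", sum(const),
                    paste(head(rownames(m)[const], 5), collapse = ", ")))
    m <- m[!const, , drop = FALSE]
    mu <- mu[!const]
    s <- s[!const]
  }
  if (nrow(m) == 0) return(m)
  keep_meta((m - mu) / s, m)
}

#' Split genes into high- and low-expression strata
#'
#' The high stratum holds genes whose mean FPKM across all samples exceeds
#' `threshold` (default 100 FPKM); all other expressed genes form the low
#' stratum. The boundary value goes to the low stratum (both inequalities
#' strict).
#'
#' @param expr unstandardized FPKM matrix.
#' @param threshold positive FPKM cutoff.
#' @return list with elements `high` and `low`.
#' @export
stratify_by_expression <- function(expr, threshold = 100) {
  if (!is.numeric(threshold) || threshold <= 0) stop("threshold must be > 0")
  mu <- rowMeans(expr)
  list(high = keep_meta(expr[mu > threshold, , drop = FALSE], expr),
       low = keep_meta(expr[mu <= threshold, , drop = FALSE], expr))
}

#' Align several omics matrices to a common sample order
#'
#' Reorders every matrix's columns to the metadata's sample order. Samples
#' missing from any matrix are dropped from all layers (and from the
#' returned metadata) with a message.
#'
#' @param matrices named list of feature-by-sample matrices.
#' @param metadata sample metadata `data.frame`.
#' @return list with `matrices` (aligned) and `metadata` (possibly reduced).
#' @export
align_samples <- function(matrices, metadata) {
  stopifnot(is.list(matrices), length(matrices) >= 1)
  for (nm in names(matrices)) {
    extra <- setdiff(colnames(matrices[[nm]]), metadata$sample_id)
    if (length(extra)) {
      stop(sprintf("matrix '%s' has samples absent from metadata: %s",
                   nm, paste(head(extra, 5), collapse = ", ")))
    }
  }
  shared <- Reduce(intersect, lapply(matrices, colnames), metadata$sample_id)
  if (length(shared) < 3) stop("fewer than 3 samples shared across all layers")
  keep <- metadata$sample_id[metadata$sample_id %in% shared]
  dropped <- setdiff(metadata$sample_id, keep)
  if (length(dropped)) {
    message(sprintf("align_samples: dropping %d sample(s) missing from some layer",
                    length(dropped)))
  }
  aligned <- lapply(matrices, function(m) m[, keep, drop = FALSE])
  meta <- metadata[match(keep, metadata$sample_id), , drop = FALSE]
  rownames(meta) <- NULL
  list(matrices = aligned, metadata = droplevels(meta))
}
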