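# Feature metadata columns recognized in abundance tables; everything else
# is treated as a sample column.
.meta_cols <- c("feature_id", "gene", "n_unique_peptides", "confidence",
                "protein", "site", "state")

#' Abundance matrix of features by samples
#'
#' The common currency of the pipeline: a non-negative quantification matrix
#' (proteins, peptides, or transcripts in rows; samples in columns) together
#' with per-feature metadata (gene symbol, unique-peptide count, FDR
#' confidence flag, and for methyl peptides the parent protein, site and
#' methyl state).
#'
#' @param values Numeric matrix, features x samples, with unique rownames
#'   (feature ids) and column names (sample ids); all values `>= 0`.
#' @param meta Optional data.frame of feature metadata, one row per feature,
#'   in the same order as `values`.
#' @return An object of class `"abundance_matrix"` with elements `values`
#'   and `meta`.
#' @export
abundance_matrix <- function(values, meta = NULL) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("abundances must be numeric", call. = FALSE)
  if (nrow(values) > 0 && is.null(rownames(values))) {
    stop("values must have feature rownames", call. = FALSE)
  }
  if (is.null(colnames(values))) {
    stop("values must have sample colnames", call. = FALSE)
  }
  if (is.null(rownames(values))) rownames(values) <- character(0)
  dup <- rownames(values)[duplicated(rownames(values))]
  if (length(dup)) {
    stop("duplicated feature id(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  values[is.na(values)] <- 0
  if (any(values < 0)) {
    bad <- which(values < 0, arr.ind = TRUE)[1L, ]
    stop("negative abundance at feature '", rownames(values)[bad[1L]],
         "', sample '", colnames(values)[bad[2L]], "'", call. = FALSE)
  }
  if (is.null(meta)) {
    meta <- data.frame(feature_id = rownames(values),
                       stringsAsFactors = FALSE)
  }
  if (nrow(meta) != nrow(values)) {
    stop("meta must have one row per feature", call. = FALSE)
  }
  meta$feature_id <- rownames(values)
  rownames(meta) <- NULL
  structure(list(values = values, meta = meta), class = "abundance_matrix")
}

#' @export
print.abundance_matrix <- function(x, ...) {
  cat("Abundance matrix:", nrow(x$values), "features x", ncol(x$values),
      "samples\n")
  cat("Metadata columns:", paste(names(x$meta), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.abundance_matrix <- function(x) dim(x$values)

#' Subset an abundance matrix by features and/or samples
#'
#' @param x An [abundance_matrix()].
#' @param i Feature index (logical, integer, or feature ids).
#' @param j Sample index (logical, integer, or sample ids).
#' @param ... Unused.
#' @return An [abundance_matrix()].
#' @export
`[.abundance_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$values))
  if (missing(j)) j <- seq_len(ncol(x$values))
  if (is.character(i)) i <- match(i, rownames(x$values))
  abundance_matrix(x$values[i, j, drop = FALSE],
                   x$meta[i, , drop = FALSE])
}

#' Read / write tab-separated abundance tables
#'
#' Tables are UTF-8 TSV with a mandatory header. The first column is
#' `feature_id`; recognized metadata columns (`gene`, `n_unique_peptides`,
#' `confidence`, `protein`, `site`, `state`) are split off and all remaining
#' columns are parsed as numeric sample abundances. Empty cells are read as
#' missing and treated as 0.
#'
#' @param path File path.
#' @return [read_abundance_table()] returns an [abundance_matrix()];
#'   `write_abundance_table()` returns `path` invisibly.
#' @export
read_abundance_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (!"feature_id" %in% names(df)) {
    stop("missing 'feature_id' column in ", path, call. = FALSE)
  }
  meta_here <- intersect(.meta_cols, names(df))
  sample_cols <- setdiff(names(df), meta_here)
  if (!length(sample_cols)) {
    stop("no sample columns found in ", path, call. = FALSE)
  }
  vals <- as.matrix(df[sample_cols])
  if (!is.numeric(vals)) {
    bad <- sample_cols[!vapply(df[sample_cols], is.numeric, logical(1))]
    stop("non-numeric sample column(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  rownames(vals) <- df$feature_id
  abundance_matrix(vals, df[meta_here])
}

#' @rdname read_abundance_table
#' @param x An [abundance_matrix()].
#' @export
write_abundance_table <- function(x, path) {
  stopifnot(inherits(x, "abundance_matrix"))
  df <- cbind(x$meta, as.data.frame(x$values, check.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write the sample sheet
#'
#' The sample sheet maps each quantification column to its condition
#' (`control` / `treated`), assay (`global` / `pisa`) and replicate index.
#' Every (condition, assay, replicate) triple must be unique and both assays
#' must be present for each (condition, replicate) pair, reflecting that the
#' PISA aliquots and the global aliquot derive from the same cells.
#'
#' @param path File path (TSV with columns `sample_id`, `condition`,
#'   `assay`, `replicate`).
#' @return A validated data.frame.
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_sample_sheet(df)
}

#' @rdname read_sample_sheet
#' @param sheet A sample-sheet data.frame.
#' @export
write_sample_sheet <- function(sheet, path) {
  utils::write.table(validate_sample_sheet(sheet), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname read_sample_sheet
#' @export
validate_sample_sheet <- function(sheet) {
  need <- c("sample_id", "condition", "assay", "replicate")
  miss <- setdiff(need, names(sheet))
  if (length(miss)) {
    stop("sample sheet missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!all(sheet$condition %in% c("control", "treated"))) {
    stop("condition must be 'control' or 'treated'", call. = FALSE)
  }
  if (!all(sheet$assay %in% c("global", "pisa"))) {
    stop("assay must be 'global' or 'pisa'", call. = FALSE)
  }
  key <- paste(sheet$condition, sheet$assay, sheet$replicate)
  if (anyDuplicated(key)) {
    stop("duplicated (condition, assay, replicate) triple: ",
         key[duplicated(key)][1L], call. = FALSE)
  }
  cr <- unique(sheet[c("condition", "replicate")])
  for (k in seq_len(nrow(cr))) {
    have <- sheet$assay[sheet$condition == cr$condition[k] &
                          sheet$replicate == cr$replicate[k]]
    if (!all(c("global", "pisa") %in% have)) {
      stop("both assays required for condition '", cr$condition[k],
           "' replicate ", cr$replicate[k], call. = FALSE)
    }
  }
  sheet
}

# Sample ids for a (condition, assay) cell, ordered by replicate.
sample_ids <- function(sheet, condition, assay) {
  s <- sheet[sheet$condition == condition & sheet$assay == assay, ]
  s$sample_id[order(s$replicate)]
}

#' Read / write gene sets in GMT format
#'
#' One set per line: set name, description, then member gene symbols, all
#' tab-separated. Duplicate members within a set are dropped.
#'
#' @param path File path.
#' @return A named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1L]]
    unique(parts[-(1:2)])
  })
  names(sets) <- vapply(lines, function(l) {
    strsplit(l, "\t", fixed = TRUE)[[1L]][1L]
  }, character(1))
  sets
}

#' @rdname read_gmt
#' @param sets Named list of character vectors.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, nm, unique(sets[[nm]])), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Filter proteins by identification quality
#'
#' Retains proteins identified with high FDR confidence and more than one
#' unique peptide; everything else is removed. Row order is preserved and
#' the operation is idempotent.
#'
#' @param m An [abundance_matrix()] whose metadata contains `confidence`
#'   and `n_unique_peptides`.
#' @return The filtered [abundance_matrix()].
#' @export
filter_proteins <- function(m) {
  stopifnot(inherits(m, "abundance_matrix"))
  miss <- setdiff(c("confidence", "n_unique_peptides"), names(m$meta))
  if (length(miss)) {
    stop("metadata missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  keep <- m$meta$confidence == "High" & m$meta$n_unique_peptides >= 2
  m[which(keep), ]
}

#' Normalize sample columns to equal totals
#'
#' Scales every sample column so that all column sums equal the mean of the
#' original column sums (equal total loading, no further scaling). Ratios of
#' features within a column are unchanged.
#'
#' @param m An [abundance_matrix()].
#' @return The normalized [abundance_matrix()].
#' @export
total_normalize <- function(m) {
  stopifnot(inherits(m, "abundance_matrix"))
  sums <- colSums(m$values)
  if (any(sums <= 0)) {
    stop("zero-sum sample column(s): ",
         paste(colnames(m$values)[sums <= 0], collapse = ", "),
         call. = FALSE)
  }
  m$values <- sweep(m$values, 2, mean(sums) / sums, `*`)
  m
}

#' Add a pseudocount to every abundance
#'
#' Applied after total normalization so that downstream fold changes and
#' log transforms are defined for features missing in some channels.
#'
#' @param m An [abundance_matrix()].
#' @param count Positive constant, default 0.1.
#' @return The shifted [abundance_matrix()].
#' @export
add_pseudocount <- function(m, count = 0.1) {
  stopifnot(inherits(m, "abundance_matrix"))
  if (!is.numeric(count) || length(count) != 1L || count <= 0) {
    stop("pseudocount must be a single positive number", call. = FALSE)
  }
  m$values <- m$values + count
  m
}
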