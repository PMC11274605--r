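# Row-wise Welch t-test on two matrices of replicate columns (one row per
# feature). Degenerate rows follow the documented convention: no variance in
# either group and equal means -> p = 1; no variance but different means ->
# p = 0 (noiseless difference).
row_t_welch <- function(x, y) {
  n1 <- ncol(x); n2 <- ncol(y)
  if (n1 < 2L || n2 < 2L) {
    stop("at least 2 replicates per group are required", call. = FALSE)
  }
  m1 <- rowMeans(x); m2 <- rowMeans(y)
  v1 <- rowSums((x - m1)^2) / (n1 - 1L)
  v2 <- rowSums((y - m2)^2) / (n2 - 1L)
  se2 <- v1 / n1 + v2 / n2
  tstat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1L) + (v2 / n2)^2 / (n2 - 1L))
  p <- 2 * stats::pt(-abs(tstat), df)
  zero <- se2 == 0
  if (any(zero)) {
    eq <- zero & (m1 == m2)
    p[eq] <- 1; tstat[eq] <- 0
    p[zero & !eq] <- 0
    tstat[zero & !eq] <- sign(m1 - m2)[zero & !eq] * Inf
  }
  list(statistic = tstat, p_value = p, df = df)
}

.diff_table <- function(ids, ctrl, trt, alpha, labels, log_input = TRUE) {
  if (log_input) {
    lt <- row_t_welch(log2(trt), log2(ctrl))
  } else {
    lt <- row_t_welch(trt, ctrl)
  }
  fc <- rowMeans(trt) / rowMeans(ctrl)
  call <- rep("unchanged", length(fc))
  call[fc > 1 & lt$p_value < alpha] <- labels[1L]
  call[fc < 1 & lt$p_value < alpha] <- labels[2L]
  data.frame(feature_id = ids, fc = fc, log2fc = log2(fc),
             p_value = lt$p_value, adj_p = NA_real_, call = call,
             stringsAsFactors = FALSE, row.names = NULL)
}

.as_group_matrix <- function(x, what) {
  x <- as.matrix(x)
  if (!is.numeric(x)) stop(what, " must be numeric", call. = FALSE)
  x
}

#' Differential protein abundance between treated and control
#'
#' Per-feature fold change (treated mean over control mean, linear scale)
#' with a two-sample Welch t-test on log2 abundances. A feature is called
#' `up` when FC > 1 and p < `alpha`, `down` when FC < 1 and p < `alpha`;
#' no fold-change magnitude floor is applied and no multiplicity adjustment
#' is performed at this layer.
#'
#' @param ctrl,trt Numeric matrices of replicate columns (same features in
#'   rows, pseudocount already applied).
#' @param alpha Significance threshold on the raw p-value (default 0.05).
#' @return A data.frame with columns `feature_id`, `fc`, `log2fc`,
#'   `p_value`, `adj_p` (NA at this layer), `call`.
#' @export
diff_abundance <- function(ctrl, trt, alpha = 0.05) {
  ctrl <- .as_group_matrix(ctrl, "ctrl"); trt <- .as_group_matrix(trt, "trt")
  stopifnot(nrow(ctrl) == nrow(trt))
  ids <- rownames(ctrl)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(ctrl)))
  .diff_table(ids, ctrl, trt, alpha, c("up", "down"))
}

#' PISA-to-global stability ratios
#'
#' Normalizes the PISA (pooled solubility-integral) abundances to the global
#' abundances to remove treatment-induced protein abundance changes from the
#' thermal-stability readout. Each PISA channel is divided by the global
#' channel of the same condition and replicate — the pair that derives from
#' the same cells. Features absent from either matrix are dropped (recorded
#' in the `"dropped"` attribute).
#'
#' @param pisa,global [abundance_matrix()] objects, already filtered,
#'   normalized and pseudocounted.
#' @param sheet Sample sheet mapping sample ids to condition/assay/replicate.
#' @return An [abundance_matrix()] of ratios with columns
#'   `<condition>_<replicate>`.
#' @export
stability_ratio <- function(pisa, global, sheet) {
  stopifnot(inherits(pisa, "abundance_matrix"),
            inherits(global, "abundance_matrix"))
  sheet <- validate_sample_sheet(sheet)
  shared <- intersect(rownames(pisa$values), rownames(global$values))
  dropped <- union(setdiff(rownames(pisa$values), shared),
                   setdiff(rownames(global$values), shared))
  if (!length(shared)) stop("no shared features", call. = FALSE)
  conds <- c("control", "treated")
  cols <- list()
  for (cond in conds) {
    p_ids <- sample_ids(sheet, cond, "pisa")
    g_ids <- sample_ids(sheet, cond, "global")
    miss <- c(setdiff(p_ids, colnames(pisa$values)),
              setdiff(g_ids, colnames(global$values)))
    if (length(miss)) {
      stop("sample(s) in sheet but not in matrices: ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
    reps <- sort(sheet$replicate[sheet$condition == cond &
                                   sheet$assay == "pisa"])
    for (i in seq_along(p_ids)) {
      cols[[paste(cond, reps[i], sep = "_")]] <-
        pisa$values[shared, p_ids[i]] / global$values[shared, g_ids[i]]
    }
  }
  out <- do.call(cbind, cols)
  rownames(out) <- shared
  res <- abundance_matrix(out, pisa$meta[match(shared, rownames(pisa$values)), ,
                                         drop = FALSE])
  attr(res, "dropped") <- dropped
  res
}

#' Differential thermal stability from PISA/global ratios
#'
#' Welch t-test on the log2 PISA-to-global ratios, treated vs control.
#' Features with a ratio fold change above 1 at p < `alpha` are called
#' `stabilized` (the treatment shifts the melting midpoint up, so more
#' protein survives the gradient); below 1, `destabilized`.
#'
#' @param ratios [abundance_matrix()] from [stability_ratio()] (columns
#'   `control_<r>` / `treated_<r>`).
#' @param alpha Significance threshold (default 0.05).
#' @return A data.frame as in [diff_abundance()] with calls
#'   `stabilized` / `destabilized` / `unchanged`.
#' @export
diff_stability <- function(ratios, alpha = 0.05) {
  stopifnot(inherits(ratios, "abundance_matrix"))
  cn <- colnames(ratios$values)
  ctrl <- ratios$values[, grepl("^control_", cn), drop = FALSE]
  trt <- ratios$values[, grepl("^treated_", cn), drop = FALSE]
  if (!ncol(ctrl) || !ncol(trt)) {
    stop("ratio columns must be named <condition>_<replicate>",
         call. = FALSE)
  }
  .diff_table(rownames(ratios$values), ctrl, trt, alpha,
              c("stabilized", "destabilized"))
}

#' Differential transcript abundance
#'
#' Welch t-test on log2(intensity + pseudocount), Benjamini-Hochberg
#' adjustment across genes, and a call of `up` / `down` only when both the
#' adjusted p-value is below `alpha` and |log2 fold change| exceeds
#' `lfc_cutoff`.
#'
#' @param ctrl,trt Numeric matrices of replicate columns (genes in rows).
#' @param alpha Threshold on the BH-adjusted p-value (default 0.05).
#' @param lfc_cutoff Absolute log2 fold-change cutoff (default 1).
#' @param pseudocount Added before the log transform (default 0.1).
#' @return A data.frame as in [diff_abundance()] with `adj_p` populated.
#' @export
diff_transcripts <- function(ctrl, trt, alpha = 0.05, lfc_cutoff = 1,
                             pseudocount = 0.1) {
  ctrl <- .as_group_matrix(ctrl, "ctrl") + pseudocount
  trt <- .as_group_matrix(trt, "trt") + pseudocount
  stopifnot(nrow(ctrl) == nrow(trt))
  ids <- rownames(ctrl)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(ctrl)))
  res <- .diff_table(ids, ctrl, trt, alpha = 0, c("up", "down"))
  res$adj_p <- stats::p.adjust(res$p_value, method = "BH")
  res$call <- "unchanged"
  res$call[res$adj_p < alpha & res$log2fc > lfc_cutoff] <- "up"
  res$call[res$adj_p < alpha & res$log2fc < -lfc_cutoff] <- "down"
  res
}

#' Transcript-protein fold-change correlation
#'
#' Pearson correlation between protein and transcript log2 fold changes over
#' the genes shared by both result tables.
#'
#' @param prot,rna Differential result data.frames; genes are matched on the
#'   `gene` column if present, else on `feature_id`.
#' @return A list with `r` (Pearson correlation) and `n` (genes compared).
#' @export
protein_rna_correlation <- function(prot, rna) {
  key <- function(d) if ("gene" %in% names(d)) d$gene else d$feature_id
  pk <- key(prot); rk <- key(rna)
  shared <- intersect(pk, rk)
  if (length(shared) < 3L) {
    stop("fewer than 3 shared genes; correlation undefined", call. = FALSE)
  }
  x <- prot$log2fc[match(shared, pk)]
  y <- rna$log2fc[match(shared, rk)]
  r <- if (stats::sd(x) == 0 || stats::sd(y) == 0) NA_real_ else
    stats::cor(x, y, method = "pearson")
  list(r = r, n = length(shared))
}
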