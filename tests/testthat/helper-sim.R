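# Shared fixture builders. Everything is generated in code; configurations
# are scaled-down versions of the full study design unless a test needs the
# full feature counts.

# all effects zero; protein, PISA and transcript layers only
null_config <- function(n = 2000, seed = 1, cv = 0.1, ...) {
  defaults <- list(n_proteins = n, n_detected_extra = 0,
                   n_protein_up = 0, n_protein_down = 0,
                   n_stabilized = 0, n_destabilized = 0,
                   n_genes = n, n_shared_genes = n,
                   n_rna_up = 0, n_rna_down = 0,
                   n_atp_binders = 0, n_methyltransferases = 0,
                   n_known_methylated = 0,
                   n_kme_sites = 0, n_kme_parents = 0,
                   n_kme_up = 0, n_kme_down = 0,
                   n_kme_stabilized = 0, n_kme_destabilized = 0,
                   cv = cv, seed = seed)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

# modest config exercising every layer
small_config <- function(seed = 1, ...) {
  defaults <- list(n_proteins = 300, n_detected_extra = 40,
                   n_protein_up = 30, n_protein_down = 25,
                   n_stabilized = 15, n_destabilized = 10,
                   n_genes = 500, n_shared_genes = 280,
                   n_rna_up = 50, n_rna_down = 60,
                   n_atp_binders = 40, n_methyltransferases = 12,
                   n_known_methylated = 120,
                   n_kme_sites = 30, n_kme_parents = 24,
                   n_kme_up = 4, n_kme_down = 5,
                   n_kme_stabilized = 2, n_kme_destabilized = 2,
                   seed = seed)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

# hand-built abundance matrix: vals is a matrix or vector, meta optional
am <- function(vals, ids = NULL, samples = NULL, ...) {
  vals <- as.matrix(vals)
  if (is.null(ids)) ids <- paste0("f", seq_len(nrow(vals)))
  if (is.null(samples)) samples <- paste0("s", seq_len(ncol(vals)))
  rownames(vals) <- ids
  colnames(vals) <- samples
  meta <- list(...)
  if (length(meta)) {
    abundance_matrix(vals, data.frame(feature_id = ids, meta,
                                      stringsAsFactors = FALSE))
  } else {
    abundance_matrix(vals)
  }
}

# minimal valid sample sheet for n replicates
mini_sheet <- function(n = 4) {
  g <- expand.grid(replicate = seq_len(n), assay = c("global", "pisa"),
                   condition = c("control", "treated"),
                   stringsAsFactors = FALSE)
  g$sample_id <- paste(g$condition, g$assay, g$replicate, sep = "_")
  g[c("sample_id", "condition", "assay", "replicate")]
}

# independent brute-force Pearson chi-square: sum over cells of (O-E)^2/E
brute_chisq <- function(tab) {
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - E)^2 / E)
}

# exhaustive two-sample permutation p-value over all balanced 4v4 splits,
# using |Welch t| as the statistic
perm_p_4v4 <- function(x, y) {
  vals <- c(x, y)
  tstat <- function(a, b) {
    se2 <- stats::var(a) / 4 + stats::var(b) / 4
    abs((mean(a) - mean(b)) / sqrt(se2))
  }
  obs <- tstat(x, y)
  splits <- utils::combn(8, 4)
  stats_all <- apply(splits, 2, function(idx) tstat(vals[idx], vals[-idx]))
  mean(stats_all >= obs - 1e-12)
}
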