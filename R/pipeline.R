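.split_rna <- function(values) {
  cn <- colnames(values)
  list(ctrl = values[, grepl("^control", cn), drop = FALSE],
       trt = values[, grepl("^treated", cn), drop = FALSE])
}

.maybe_read <- function(x) {
  if (is.character(x)) read_abundance_table(x) else x
}

#' Run the full PISA analysis pipeline
#'
#' Executes the complete downstream analysis of a PISA experiment:
#' identification filtering, equal-total normalization, pseudocount,
#' the three differential layers (protein abundance; thermal stability via
#' replicate-matched PISA-to-global ratios; transcripts with BH control),
#' the transcript-protein fold-change correlation, the methyl-lysine site
#' layer (site aggregation, parent-protein and peptide-internal
#' normalization), gene-set chi-square enrichment against the quantified
#' background, and the three-layer overlap classification.
#'
#' @param global,pisa Global and PISA [abundance_matrix()] objects (or TSV
#'   paths).
#' @param sheet Sample sheet data.frame (or TSV path).
#' @param rna Optional transcript [abundance_matrix()] (or path) with
#'   columns named `control_<r>` / `treated_<r>`.
#' @param kme Optional methyl-peptide [abundance_matrix()] (or path).
#' @param sets Optional named list of gene sets (or GMT path).
#' @param alpha Raw p-value threshold for the protein and thermal layers
#'   and adjusted p-value threshold for the transcript layer (default 0.05).
#' @param rna_lfc_cutoff Absolute log2 fold-change cutoff for transcript
#'   calls (default 1).
#' @param pseudocount Added to all normalized abundances (default 0.1).
#' @param filter Apply the identification filter when the metadata carries
#'   `confidence` / `n_unique_peptides` (default `TRUE`).
#' @param n_control_draws Random-set control draws per enrichment test
#'   (0 disables the control).
#' @param seed Optional seed for the random-set control.
#' @return An object of class `"pisa_analysis"` with elements `protein`,
#'   `thermal`, `rna`, `correlation`, `kme_global`, `kme_stability`,
#'   `enrichment`, `overlap`, `overlap_summary`, and `log` (feature counts
#'   per stage plus the thresholds used).
#' @seealso [simulate_experiment()] to generate inputs,
#'   [write_results()] to export the result bundle.
#' @examples
#' sim <- simulate_experiment(sim_config(
#'   n_proteins = 200, n_detected_extra = 20, n_protein_up = 20,
#'   n_protein_down = 15, n_stabilized = 10, n_destabilized = 5,
#'   n_genes = 300, n_shared_genes = 180, n_rna_up = 30, n_rna_down = 30,
#'   n_atp_binders = 30, n_methyltransferases = 10, n_known_methylated = 60,
#'   n_kme_sites = 20, n_kme_parents = 15, n_kme_up = 3, n_kme_down = 3,
#'   n_kme_stabilized = 1, n_kme_destabilized = 1, seed = 1))
#' fit <- pisa_analysis(sim)
#' fit
#' @export
pisa_analysis <- function(global, pisa, sheet, rna = NULL, kme = NULL,
                          sets = NULL, alpha = 0.05, rna_lfc_cutoff = 1,
                          pseudocount = 0.1, filter = TRUE,
                          n_control_draws = 0, seed = NULL) {
  if (inherits(global, "pisa_simulation")) {
    sim <- global
    return(pisa_analysis(sim$global, sim$pisa, sim$sheet, rna = sim$rna,
                         kme = sim$kme,
                         sets = list(
                           ATP_binding =
                             sim$truth$proteins$gene[sim$truth$proteins$atp_binder],
                           methyltransferase_activity =
                             sim$truth$proteins$gene[sim$truth$proteins$methyltransferase],
                           known_Kme_proteins =
                             sim$truth$proteins$gene[sim$truth$proteins$known_methylated]),
                         alpha = alpha, rna_lfc_cutoff = rna_lfc_cutoff,
                         pseudocount = pseudocount, filter = filter,
                         n_control_draws = n_control_draws, seed = seed))
  }
  global <- .maybe_read(global); pisa <- .maybe_read(pisa)
  if (is.character(sheet)) sheet <- read_sample_sheet(sheet)
  sheet <- validate_sample_sheet(sheet)
  if (!is.null(rna)) rna <- .maybe_read(rna)
  if (!is.null(kme)) kme <- .maybe_read(kme)
  if (is.character(sets)) sets <- read_gmt(sets)

  log <- list(alpha = alpha, rna_lfc_cutoff = rna_lfc_cutoff,
              pseudocount = pseudocount, seed = seed,
              n_detected = nrow(global$values))

  ## filter -> normalize -> pseudocount
  can_filter <- filter &&
    all(c("confidence", "n_unique_peptides") %in% names(global$meta))
  if (can_filter) {
    global <- filter_proteins(global)
    pisa <- filter_proteins(pisa)
  }
  log$n_quantified <- nrow(global$values)
  # per-column equal-total factors, kept so the same scaling can be applied
  # to the methyl-peptide columns (the bulk protein total stands in for the
  # total peptide amount)
  col_factors <- function(m) {
    s <- colSums(m$values)
    stats::setNames(mean(s) / s, colnames(m$values))
  }
  fac <- c(col_factors(global), col_factors(pisa))
  prep <- function(m) add_pseudocount(total_normalize(m), pseudocount)
  global <- prep(global); pisa <- prep(pisa)

  ## protein abundance layer
  g_ctrl <- global$values[, sample_ids(sheet, "control", "global"),
                          drop = FALSE]
  g_trt <- global$values[, sample_ids(sheet, "treated", "global"),
                         drop = FALSE]
  protein <- diff_abundance(g_ctrl, g_trt, alpha = alpha)
  if ("gene" %in% names(global$meta)) {
    protein$gene <- global$meta$gene[match(protein$feature_id,
                                           global$meta$feature_id)]
  }
  log$n_protein_up <- sum(protein$call == "up")
  log$n_protein_down <- sum(protein$call == "down")

  ## thermal stability layer
  ratios <- stability_ratio(pisa, global, sheet)
  thermal <- diff_stability(ratios, alpha = alpha)
  if ("gene" %in% names(ratios$meta)) {
    thermal$gene <- ratios$meta$gene[match(thermal$feature_id,
                                           ratios$meta$feature_id)]
  }
  log$n_stabilized <- sum(thermal$call == "stabilized")
  log$n_destabilized <- sum(thermal$call == "destabilized")

  ## transcript layer
  rna_res <- NULL; correlation <- NULL
  if (!is.null(rna)) {
    gr <- .split_rna(rna$values)
    rna_res <- diff_transcripts(gr$ctrl, gr$trt, alpha = alpha,
                                lfc_cutoff = rna_lfc_cutoff,
                                pseudocount = pseudocount)
    rna_res$gene <- rna$meta$gene[match(rna_res$feature_id,
                                        rna$meta$feature_id)]
    log$n_rna_up <- sum(rna_res$call == "up")
    log$n_rna_down <- sum(rna_res$call == "down")
    correlation <- protein_rna_correlation(protein, rna_res)
    log$correlation_r <- correlation$r
    log$correlation_n <- correlation$n
  }

  ## methyl-site layer; the PTM subtable is scaled with the bulk protein
  ## normalization factors rather than its own column totals -- a small
  ## site-focused table's totals are dominated by a few sites whose genuine
  ## occupancy changes would otherwise rescale every site, and using the
  ## bulk factors lets them cancel exactly in the site-to-protein ratio
  kme_global <- NULL; kme_stability <- NULL
  if (!is.null(kme) && nrow(kme$values) > 0) {
    kn <- kme
    shared_cols <- intersect(colnames(kn$values), names(fac))
    kn$values[, shared_cols] <- sweep(kn$values[, shared_cols, drop = FALSE],
                                      2, fac[shared_cols], `*`)
    sites <- aggregate_sites(add_pseudocount(kn, pseudocount))
    log$n_kme_sites <- nrow(sites$values)
    kme_global <- kme_global_differential(sites, global, sheet,
                                          alpha = alpha)
    kme_stability <- kme_stability_differential(sites, sheet, alpha = alpha)
    log$n_kme_up <- sum(kme_global$call == "up")
    log$n_kme_down <- sum(kme_global$call == "down")
    log$n_kme_stabilized <- sum(kme_stability$call == "stabilized")
    log$n_kme_destabilized <- sum(kme_stability$call == "destabilized")
  }

  ## enrichment against the quantified background
  enrichment <- NULL
  if (!is.null(sets) && length(sets)) {
    if (!is.null(seed)) set.seed(seed)
    universe <- if ("gene" %in% names(protein)) protein$gene else
      protein$feature_id
    layers <- list(
      abundance = unique(.result_key(protein)[protein$call != "unchanged"]),
      thermal = unique(.result_key(thermal)[thermal$call != "unchanged"]))
    rows <- list()
    for (set_name in names(sets)) {
      for (layer in names(layers)) {
        r <- chisq_category(sets[[set_name]], layers[[layer]], universe)
        row <- data.frame(set = set_name, layer = layer,
                          in_set_sig = r$table[1, 1],
                          in_set_not = r$table[1, 2],
                          out_set_sig = r$table[2, 1],
                          out_set_not = r$table[2, 2],
                          statistic = r$statistic, p_value = r$p_value,
                          odds_ratio = r$odds_ratio,
                          control_frac_significant = NA_real_,
                          stringsAsFactors = FALSE)
        if (n_control_draws > 0) {
          ctl <- random_control(universe,
                                length(intersect(sets[[set_name]], universe)),
                                layers[[layer]], n_draws = n_control_draws)
          row$control_frac_significant <- ctl$frac_significant
        }
        rows[[paste(set_name, layer)]] <- row
      }
    }
    enrichment <- do.call(rbind, c(rows, make.row.names = FALSE))
  }

  ## three-layer overlap
  overlap <- NULL; overlap_summary <- NULL
  if (!is.null(rna_res)) {
    overlap <- classify_overlap(rna_res, protein, thermal)
    overlap_summary <- summarize_overlap(overlap)
    log$thermal_total <- overlap$summary$thermal_total
    log$thermal_and_any <- overlap$summary$thermal_and_any
    log$thermal_only <- overlap$summary$thermal_only
  }

  structure(list(protein = protein, thermal = thermal, rna = rna_res,
                 correlation = correlation, kme_global = kme_global,
                 kme_stability = kme_stability, enrichment = enrichment,
                 overlap = overlap, overlap_summary = overlap_summary,
                 log = log),
            class = "pisa_analysis")
}

#' @rdname pisa_analysis
#' @param ... Passed to [pisa_analysis()].
#' @export
run_pipeline <- function(...) pisa_analysis(...)

#' @export
print.pisa_analysis <- function(x, ...) {
  l <- x$log
  cat("PISA analysis\n")
  cat(sprintf("  %d proteins detected, %d quantified after filtering\n",
              l$n_detected, l$n_quantified))
  cat(sprintf("  protein abundance: %d up, %d down (p < %g)\n",
              l$n_protein_up, l$n_protein_down, l$alpha))
  cat(sprintf("  thermal stability: %d stabilized, %d destabilized\n",
              l$n_stabilized, l$n_destabilized))
  if (!is.null(x$rna)) {
    cat(sprintf("  transcripts: %d up, %d down (BH adj p < %g, |log2FC| > %g)\n",
                l$n_rna_up, l$n_rna_down, l$alpha, l$rna_lfc_cutoff))
    cat(sprintf("  transcript-protein correlation: R = %.3f (n = %d)\n",
                x$correlation$r, x$correlation$n))
  }
  if (!is.null(x$kme_global)) {
    cat(sprintf("  methyl sites: %d quantified; %d up, %d down; %d stabilized, %d destabilized\n",
                l$n_kme_sites, l$n_kme_up, l$n_kme_down,
                l$n_kme_stabilized, l$n_kme_destabilized))
  }
  if (!is.null(x$overlap_summary) && !x$overlap_summary$undefined) {
    s <- x$overlap_summary
    cat(sprintf("  overlap: %d%% of %d thermally altered also change in RNA or protein; %d thermal-only\n",
                s$pct_overlap_any, s$counts$thermal_total, s$thermal_only))
  }
  invisible(x)
}

#' @export
summary.pisa_analysis <- function(object, ...) {
  print(object)
  if (!is.null(object$enrichment)) {
    cat("\nEnrichment (chi-square vs quantified background):\n")
    print(object$enrichment[c("set", "layer", "statistic", "p_value",
                              "odds_ratio")], row.names = FALSE)
  }
  invisible(object)
}

#' Volcano plot of a differential layer
#'
#' @param x A `pisa_analysis` object.
#' @param layer One of `"protein"`, `"thermal"`, `"rna"`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.pisa_analysis <- function(x, layer = c("thermal", "protein", "rna"),
                               ...) {
  layer <- match.arg(layer)
  d <- x[[layer]]
  if (is.null(d)) stop("layer '", layer, "' not present", call. = FALSE)
  v <- export_volcano(d)
  cols <- c(unchanged = "grey60", up = "firebrick", down = "steelblue",
            stabilized = "firebrick", destabilized = "steelblue")
  graphics::plot(v$log2fc, v$neg_log10_p, pch = 16, cex = 0.5,
                 col = cols[v$call], xlab = "log2 fold change",
                 ylab = "-log10 p", main = paste(layer, "layer"), ...)
  graphics::abline(h = -log10(x$log$alpha), lty = 2)
  invisible(v)
}

#' Plot-ready volcano table
#'
#' One row per feature with the log2 fold change, `-log10` of the p-value
#' (floored at the smallest representable double to avoid infinities), and
#' the categorical call.
#'
#' @param results A differential result data.frame.
#' @return A data.frame with `feature_id`, `log2fc`, `neg_log10_p`, `call`.
#' @export
export_volcano <- function(results) {
  stopifnot(all(c("feature_id", "log2fc", "p_value", "call") %in%
                  names(results)))
  data.frame(feature_id = results$feature_id, log2fc = results$log2fc,
             neg_log10_p = -log10(pmax(results$p_value,
                                       .Machine$double.xmin)),
             call = results$call, stringsAsFactors = FALSE)
}

#' Write the analysis result bundle
#'
#' Emits one TSV per layer (`protein_results.tsv`, `thermal_results.tsv`,
#' `rna_results.tsv`, merged `kme_results.tsv`), the overlap classification
#' (`overlap.tsv`), the enrichment table (`enrichment.tsv`) and a
#' machine-readable run log (`run_log.json`).
#'
#' @param fit A `pisa_analysis` object.
#' @param dir Output directory (created if needed).
#' @return Named character vector of file paths.
#' @export
write_results <- function(fit, dir) {
  stopifnot(inherits(fit, "pisa_analysis"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c()
  wt <- function(df, file) {
    utils::write.table(df, file.path(dir, file), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    file.path(dir, file)
  }
  paths["protein"] <- wt(fit$protein, "protein_results.tsv")
  paths["thermal"] <- wt(fit$thermal, "thermal_results.tsv")
  if (!is.null(fit$rna)) paths["rna"] <- wt(fit$rna, "rna_results.tsv")
  if (!is.null(fit$kme_global)) {
    kg <- fit$kme_global; ks <- fit$kme_stability
    merged <- data.frame(
      protein = kg$protein, site = kg$site, state = kg$state,
      fc_global = kg$fc, p_global = kg$p_value, call_global = kg$call,
      fc_stability = ks$fc[match(kg$feature_id, ks$feature_id)],
      p_stability = ks$p_value[match(kg$feature_id, ks$feature_id)],
      call_stability = ks$call[match(kg$feature_id, ks$feature_id)],
      stringsAsFactors = FALSE)
    paths["kme"] <- wt(merged, "kme_results.tsv")
  }
  if (!is.null(fit$overlap)) {
    paths["overlap"] <- wt(fit$overlap$classes, "overlap.tsv")
  }
  if (!is.null(fit$enrichment)) {
    paths["enrichment"] <- wt(fit$enrichment, "enrichment.tsv")
  }
  jsonlite::write_json(fit$log, file.path(dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  paths["log"] <- file.path(dir, "run_log.json")
  paths
}
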