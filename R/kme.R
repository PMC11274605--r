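#' Aggregate methyl-lysine peptides into site-state records
#'
#' Peptides sharing the same (parent protein, site position, methyl state)
#' are summed per sample, so each record tracks one methylated proteoform
#' site. Different methyl states at the same position stay separate.
#' Peptides lacking site metadata are excluded (count recorded in the
#' `"n_excluded"` attribute).
#'
#' @param kme An [abundance_matrix()] of methyl peptides with metadata
#'   columns `protein`, `site`, `state`.
#' @return An [abundance_matrix()] with one row per site-state record,
#'   feature ids `<protein>_K<site>_<state>`.
#' @export
aggregate_sites <- function(kme) {
  stopifnot(inherits(kme, "abundance_matrix"))
  miss <- setdiff(c("protein", "site", "state"), names(kme$meta))
  if (length(miss)) {
    stop("peptide metadata missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  ok <- !(is.na(kme$meta$protein) | is.na(kme$meta$site) |
            is.na(kme$meta$state))
  n_excluded <- sum(!ok)
  if (n_excluded) {
    warning(n_excluded, " peptide(s) lacking site metadata excluded",
            call. = FALSE)
  }
  m <- kme[which(ok), ]
  key <- paste0(m$meta$protein, "_K", m$meta$site, "_", m$meta$state)
  agg <- rowsum(m$values, group = key, reorder = FALSE)
  first <- !duplicated(key)
  meta <- data.frame(feature_id = key[first],
                     protein = m$meta$protein[first],
                     site = m$meta$site[first],
                     state = m$meta$state[first],
                     stringsAsFactors = FALSE)
  res <- abundance_matrix(agg[meta$feature_id, , drop = FALSE], meta)
  attr(res, "n_excluded") <- n_excluded
  res
}

# per-replicate ratio of site channels to a matched set of denominator
# channels, for one assay; returns ctrl and trt matrices of ratios
.site_ratio_groups <- function(num, den, sheet, assay) {
  out <- list()
  for (cond in c("control", "treated")) {
    ids <- sample_ids(sheet, cond, assay)
    out[[cond]] <- num[, ids, drop = FALSE] / den[, ids, drop = FALSE]
  }
  out
}

#' Differential methyl-site abundance, normalized to the parent protein
#'
#' Each site's global abundance is divided, replicate by replicate, by its
#' parent protein's global abundance so that occupancy changes are measured
#' independently of protein-level changes; a Welch t-test on the log2
#' ratios then calls `up` / `down` sites (FC vs 1, p < `alpha`). Sites whose
#' parent protein is absent from the protein table are skipped (ids in the
#' `"skipped"` attribute).
#'
#' @param sites An [aggregate_sites()] result.
#' @param protein_global An [abundance_matrix()] of global protein
#'   abundances (filtered, normalized, pseudocounted).
#' @param sheet Sample sheet.
#' @param alpha Significance threshold (default 0.05).
#' @return A data.frame as in [diff_abundance()] plus `protein`, `site`,
#'   `state` columns.
#' @export
kme_global_differential <- function(sites, protein_global, sheet,
                                    alpha = 0.05) {
  stopifnot(inherits(sites, "abundance_matrix"),
            inherits(protein_global, "abundance_matrix"))
  sheet <- validate_sample_sheet(sheet)
  have <- sites$meta$protein %in% rownames(protein_global$values)
  skipped <- sites$meta$feature_id[!have]
  s <- sites[which(have), ]
  gids <- c(sample_ids(sheet, "control", "global"),
            sample_ids(sheet, "treated", "global"))
  den <- protein_global$values[s$meta$protein, gids, drop = FALSE]
  rownames(den) <- rownames(s$values)
  gr <- .site_ratio_groups(s$values[, gids, drop = FALSE], den, sheet,
                           "global")
  res <- .diff_table(rownames(s$values), gr$control, gr$treated, alpha,
                     c("up", "down"))
  res <- cbind(res, s$meta[c("protein", "site", "state")])
  attr(res, "skipped") <- skipped
  res
}

#' Differential methyl-site thermal stability
#'
#' Each site's PISA abundance is divided, replicate by replicate, by its own
#' global abundance (peptide-internal normalization: the modified proteoform
#' is its own reference, so no parent protein is needed); a Welch t-test on
#' the log2 ratios calls `stabilized` / `destabilized` sites.
#'
#' @param sites An [aggregate_sites()] result with both assays' columns.
#' @param sheet Sample sheet.
#' @param alpha Significance threshold (default 0.05).
#' @return A data.frame as in [diff_stability()] plus `protein`, `site`,
#'   `state` columns.
#' @export
kme_stability_differential <- function(sites, sheet, alpha = 0.05) {
  stopifnot(inherits(sites, "abundance_matrix"))
  sheet <- validate_sample_sheet(sheet)
  ratios <- list()
  for (cond in c("control", "treated")) {
    p_ids <- sample_ids(sheet, cond, "pisa")
    g_ids <- sample_ids(sheet, cond, "global")
    ratios[[cond]] <- sites$values[, p_ids, drop = FALSE] /
      sites$values[, g_ids, drop = FALSE]
  }
  res <- .diff_table(rownames(sites$values), ratios$control,
                     ratios$treated, alpha,
                     c("stabilized", "destabilized"))
  cbind(res, sites$meta[c("protein", "site", "state")])
}
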