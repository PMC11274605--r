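#' Chi-square test of a gene category against a significance status
#'
#' Pearson chi-square (no continuity correction by default) on the 2x2
#' table of category membership versus significance over a stated universe
#' of analyzed genes. Set members outside the universe are dropped by
#' intersection. The odds ratio uses the Haldane correction (0.5 added to
#' every cell) when any cell is zero.
#'
#' @param members Character vector of category gene ids.
#' @param status Character vector of significant gene ids.
#' @param universe Character vector of all analyzed gene ids (the quantified
#'   background, not the whole genome).
#' @param correct Apply Yates continuity correction (default `FALSE`).
#' @return A list of class `"contingency_result"`: `table` (2x2 counts),
#'   `statistic`, `p_value`, `odds_ratio`, `degenerate`.
#' @export
chisq_category <- function(members, status, universe, correct = FALSE) {
  universe <- unique(universe)
  if (!length(universe)) stop("empty universe", call. = FALSE)
  members <- intersect(unique(members), universe)
  status <- intersect(unique(status), universe)
  in_set <- universe %in% members
  sig <- universe %in% status
  tab <- matrix(c(sum(in_set & sig), sum(in_set & !sig),
                  sum(!in_set & sig), sum(!in_set & !sig)),
                nrow = 2, byrow = TRUE,
                dimnames = list(set = c("in_set", "out_set"),
                                status = c("significant", "not")))
  degenerate <- any(rowSums(tab) == 0) || any(colSums(tab) == 0)
  if (degenerate) {
    stat <- 0; p <- 1
  } else {
    ct <- suppressWarnings(stats::chisq.test(tab, correct = correct))
    stat <- unname(ct$statistic); p <- ct$p.value
  }
  h <- if (any(tab == 0)) 0.5 else 0
  or <- ((tab[1, 1] + h) * (tab[2, 2] + h)) /
    ((tab[1, 2] + h) * (tab[2, 1] + h))
  structure(list(table = tab, statistic = stat, p_value = p,
                 odds_ratio = or, degenerate = degenerate),
            class = "contingency_result")
}

#' @export
print.contingency_result <- function(x, ...) {
  print(x$table)
  cat(sprintf("chi-square = %.4g, p = %.4g, OR = %.3g%s\n", x$statistic,
              x$p_value, x$odds_ratio,
              if (x$degenerate) " (degenerate table)" else ""))
  invisible(x)
}

#' Random-set control for a category enrichment
#'
#' Repeats the chi-square test on randomly drawn gene sets of the same size
#' (without replacement from the universe) to show that an observed
#' enrichment is specific to the annotated category rather than to any set
#' of that size.
#'
#' @param universe Character vector of analyzed gene ids.
#' @param set_size Size of each random set.
#' @param status Character vector of significant gene ids.
#' @param n_draws Number of random draws (>= 100).
#' @param seed Optional integer seed.
#' @param alpha Significance threshold for the summary (default 0.05).
#' @return A list with `draws` (data.frame of per-draw statistic, p-value,
#'   odds ratio) and `frac_significant` (fraction of draws with
#'   p < `alpha`).
#' @export
random_control <- function(universe, set_size, status, n_draws = 1000,
                           seed = NULL, alpha = 0.05) {
  universe <- unique(universe)
  if (set_size > length(universe)) {
    stop("set_size exceeds universe size", call. = FALSE)
  }
  if (n_draws < 100) stop("n_draws must be >= 100", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  draws <- vapply(seq_len(n_draws), function(i) {
    r <- chisq_category(sample(universe, set_size), status, universe)
    c(r$statistic, r$p_value, r$odds_ratio)
  }, numeric(3))
  df <- data.frame(statistic = draws[1, ], p_value = draws[2, ],
                   odds_ratio = draws[3, ])
  list(draws = df, frac_significant = mean(df$p_value < alpha))
}

.result_key <- function(d) if ("gene" %in% names(d)) d$gene else d$feature_id

#' Classify genes by their three-layer significance pattern
#'
#' Assigns every analyzed gene to one of the 8 membership patterns across
#' the transcript, protein-abundance and thermal-stability significance
#' sets (the upset-plot classes). Genes absent from a layer are
#' non-significant there.
#'
#' @param rna,prot,thermal Differential result data.frames (matched on
#'   their `gene` column if present, else `feature_id`); a call other than
#'   `"unchanged"` counts as significant.
#' @return A list with `classes` (per-gene flags and class label), `counts`
#'   (named count per class, summing to the universe size) and `summary`
#'   (thermal-significant total, count also significant at the transcript
#'   or protein level, thermal-only count, and count significant in the
#'   protein layer but not the transcript layer).
#' @export
classify_overlap <- function(rna, prot, thermal) {
  sig_of <- function(d) unique(.result_key(d)[d$call != "unchanged"])
  rna_sig <- sig_of(rna); prot_sig <- sig_of(prot); th_sig <- sig_of(thermal)
  universe <- unique(c(.result_key(rna), .result_key(prot),
                       .result_key(thermal)))
  cls <- data.frame(gene = universe,
                    rna_sig = universe %in% rna_sig,
                    protein_sig = universe %in% prot_sig,
                    thermal_sig = universe %in% th_sig,
                    stringsAsFactors = FALSE)
  lab <- function(r, p, t) {
    parts <- c("rna", "protein", "thermal")[c(r, p, t)]
    if (!length(parts)) "none" else paste(parts, collapse = "+")
  }
  cls$class <- mapply(lab, cls$rna_sig, cls$protein_sig, cls$thermal_sig)
  all_classes <- c("none", "rna", "protein", "thermal", "rna+protein",
                   "rna+thermal", "protein+thermal", "rna+protein+thermal")
  counts <- table(factor(cls$class, levels = all_classes))
  th <- cls[cls$thermal_sig, ]
  summary <- list(
    thermal_total = nrow(th),
    thermal_and_any = sum(th$rna_sig | th$protein_sig),
    thermal_only = sum(!th$rna_sig & !th$protein_sig),
    thermal_protein_only = sum(th$protein_sig & !th$rna_sig))
  list(classes = cls, counts = counts, summary = summary)
}

#' Overlap percentages for the thermal-significance summary
#'
#' Converts overlap counts into the report percentages: the share of
#' thermally altered genes that also change at the transcript or protein
#' level, the share explained solely by protein abundance (protein but not
#' transcript), and the thermal-only count. Percentages are rounded to the
#' nearest integer for report text; raw ratios are retained.
#'
#' @param counts Either the `summary` element of [classify_overlap()] (or
#'   its full return value), or a named list with `thermal_total`,
#'   `thermal_and_any` and `thermal_protein_only`.
#' @return A list with `pct_overlap_any`, `pct_protein_only`,
#'   `thermal_only`, the raw ratios (`ratio_overlap_any`,
#'   `ratio_protein_only`) and the input counts. With `thermal_total = 0`
#'   percentages are `NA` and `undefined` is `TRUE`.
#' @export
summarize_overlap <- function(counts) {
  if (!is.null(counts$summary)) counts <- counts$summary
  need <- c("thermal_total", "thermal_and_any", "thermal_protein_only")
  miss <- setdiff(need, names(counts))
  if (length(miss)) {
    stop("counts missing: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  tot <- counts$thermal_total
  if (!"thermal_only" %in% names(counts)) {
    counts$thermal_only <- tot - counts$thermal_and_any
  }
  if (tot == 0) {
    return(list(pct_overlap_any = NA_real_, pct_protein_only = NA_real_,
                thermal_only = counts$thermal_only,
                ratio_overlap_any = NA_real_, ratio_protein_only = NA_real_,
                counts = counts, undefined = TRUE))
  }
  r1 <- counts$thermal_and_any / tot
  r2 <- counts$thermal_protein_only / tot
  list(pct_overlap_any = round(100 * r1),
       pct_protein_only = round(100 * r2),
       thermal_only = counts$thermal_only,
       ratio_overlap_any = r1, ratio_protein_only = r2,
       counts = counts, undefined = FALSE)
}
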