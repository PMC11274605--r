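#' Configuration for a synthetic PISA experiment
#'
#' Defaults describe the reference study design: a 16-plex TMT layout
#' (4 replicates x 2 conditions x 2 assays), 4890 detected proteins of which
#' 3585 pass the identification filter, 534 abundance-increased and 458
#' abundance-decreased proteins, 91 thermally stabilized and 44 destabilized,
#' a 19051-gene transcriptome sharing 3551 genes with the quantified
#' proteome, 2092 transcript-up and 2611 transcript-down genes, a
#' transcript-protein effect correlation of 0.52, and a quantified
#' methyl-lysine layer of 278 sites on 247 parent proteins with 16
#' occupancy-increased and 24 occupancy-decreased sites, 2 stabilized and 3
#' destabilized methyl proteoforms.
#'
#' @param n_proteins Proteins passing the identification filter.
#' @param n_detected_extra Additional detected proteins that fail the filter
#'   (single unique peptide or sub-High confidence); they carry no effects.
#' @param n_replicates Biological replicates per condition (>= 2).
#' @param n_protein_up,n_protein_down Proteins with increased / decreased
#'   abundance under treatment.
#' @param n_stabilized,n_destabilized Proteins with positive / negative
#'   treatment-induced melting midpoint shifts.
#' @param n_genes Genes in the transcript table.
#' @param n_shared_genes Genes present in both the protein and transcript
#'   tables.
#' @param n_rna_up,n_rna_down Target counts of transcript effects. Genes
#'   whose protein carries an effect receive a transcript effect coupled at
#'   correlation `rho`; the remaining quota is filled with independent
#'   effects on other genes (totals are raised if the coupled effects
#'   already exceed them).
#' @param rho Correlation between protein and transcript log2 effects for
#'   effect-bearing shared genes.
#' @param cv Multiplicative lognormal measurement noise (coefficient of
#'   variation) applied independently to every channel.
#' @param lfc_range Range of |log2 fold change| for abundance effects.
#' @param delta_tm_range Range of |melting midpoint shift| in degrees C.
#' @param tm_range Range of baseline melting midpoints in degrees C.
#' @param slope,plateau Shared melting-curve steepness and residual soluble
#'   fraction.
#' @param baseline_log10_range Log10 range of baseline protein abundances
#'   (default spans 4 orders of magnitude).
#' @param stability_enrich_methylated Sampling-weight multiplier making
#'   known-methylated proteins more likely to receive stability effects.
#' @param abundance_enrich_atp Sampling-weight multiplier making annotated
#'   ATP binders more likely to receive abundance effects.
#' @param n_atp_binders,n_methyltransferases,n_known_methylated Sizes of the
#'   annotated categories among filter-passing proteins.
#' @param n_kme_sites,n_kme_parents Quantified methyl-lysine sites and their
#'   distinct parent proteins.
#' @param kme_state_probs Probabilities of the me1/me2/me3 states.
#' @param occupancy_range Baseline site occupancy range (fraction of protein
#'   copies methylated).
#' @param n_kme_up,n_kme_down Sites with occupancy increases / decreases.
#' @param kme_lfc_range Range of |log2 occupancy change|.
#' @param n_kme_stabilized,n_kme_destabilized Sites whose methylated
#'   proteoform gains / loses thermal stability relative to the parent.
#' @param gradient A [pisa_gradient()].
#' @param seed Integer seed; `NULL` leaves the RNG state alone.
#' @return A validated list of class `"sim_config"`.
#' @export
sim_config <- function(n_proteins = 3585,
                       n_detected_extra = 1305,
                       n_replicates = 4,
                       n_protein_up = 534,
                       n_protein_down = 458,
                       n_stabilized = 91,
                       n_destabilized = 44,
                       n_genes = 19051,
                       n_shared_genes = 3551,
                       n_rna_up = 2092,
                       n_rna_down = 2611,
                       rho = 0.52,
                       cv = 0.1,
                       lfc_range = c(0.5, 2),
                       delta_tm_range = c(1.5, 5),
                       tm_range = c(45, 57),
                       slope = 0.3,
                       plateau = 0.02,
                       baseline_log10_range = c(2, 6),
                       stability_enrich_methylated = 3,
                       abundance_enrich_atp = 3,
                       n_atp_binders = 467,
                       n_methyltransferases = 66,
                       n_known_methylated = 1631,
                       n_kme_sites = 278,
                       n_kme_parents = 247,
                       kme_state_probs = c(me1 = 0.18, me2 = 0.30, me3 = 0.52),
                       occupancy_range = c(0.02, 0.3),
                       n_kme_up = 16,
                       n_kme_down = 24,
                       kme_lfc_range = c(0.5, 1.5),
                       n_kme_stabilized = 2,
                       n_kme_destabilized = 3,
                       gradient = pisa_gradient(),
                       seed = NULL) {
  cfg <- as.list(environment())
  if (n_replicates < 2) stop("n_replicates must be >= 2", call. = FALSE)
  if (cv < 0) stop("cv must be >= 0", call. = FALSE)
  if (n_protein_up + n_protein_down > n_proteins) {
    stop("more abundance effects than proteins", call. = FALSE)
  }
  if (n_stabilized + n_destabilized > n_proteins) {
    stop("more stability effects than proteins", call. = FALSE)
  }
  if (n_rna_up + n_rna_down > n_genes) {
    stop("more transcript effects than genes", call. = FALSE)
  }
  if (n_shared_genes > min(n_proteins, n_genes)) {
    stop("n_shared_genes exceeds protein or gene count", call. = FALSE)
  }
  if (abs(rho) > 1) stop("rho must lie in [-1, 1]", call. = FALSE)
  if (n_kme_parents > max(n_kme_sites, 1) || n_kme_parents > n_proteins) {
    stop("infeasible methyl-site parent count", call. = FALSE)
  }
  if (n_kme_up + n_kme_down > n_kme_sites ||
      n_kme_stabilized + n_kme_destabilized > n_kme_sites) {
    stop("more methyl-site effects than sites", call. = FALSE)
  }
  cfg$kme_state_probs <- kme_state_probs / sum(kme_state_probs)
  cfg$gradient <- pisa_gradient(unclass(gradient))
  structure(cfg, class = "sim_config")
}

# mean soluble fraction over the gradient, vectorized over midpoints
.pool_fraction <- function(tm_eff, slope, plateau, gradient) {
  f <- plateau + (1 - plateau) /
    (1 + exp(slope * outer(-tm_eff, gradient, `+`)))
  rowMeans(f)
}

.noise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

.signed_uniform <- function(n, range, sign) {
  sign * stats::runif(n, range[1], range[2])
}

#' Simulate a complete synthetic PISA experiment
#'
#' Draws ground-truth effects (abundance, melting midpoint shifts,
#' correlated transcript effects, methyl-site occupancy and proteoform
#' shifts), passes unheated abundances through the two-state melting model
#' and the equal-volume solubility-integral pool, and applies multiplicative
#' lognormal measurement noise to every channel. The same seed yields
#' bit-identical output.
#'
#' @param cfg A [sim_config()].
#' @return A list of class `"pisa_simulation"` with elements `truth`
#'   (protein, gene and methyl-site ground truth), `global`, `pisa`, `rna`,
#'   `kme` ([abundance_matrix()] objects), `sheet` (sample sheet) and
#'   `config`.
#' @export
simulate_experiment <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  nrep <- cfg$n_replicates

  ## ---- protein ground truth -------------------------------------------
  n_pass <- cfg$n_proteins
  n_all <- n_pass + cfg$n_detected_extra
  protein_id <- sprintf("P%05d", seq_len(n_all))
  pass <- c(rep(TRUE, n_pass), rep(FALSE, cfg$n_detected_extra))
  # genes: shared genes sit in the transcript table; the remainder get
  # protein-only symbols
  gene <- character(n_all)
  gene[seq_len(cfg$n_shared_genes)] <- sprintf("G%05d",
                                               seq_len(cfg$n_shared_genes))
  extra <- seq_len(n_all)[-seq_len(cfg$n_shared_genes)]
  gene[extra] <- sprintf("GP%05d", extra)

  baseline <- 10^stats::runif(n_all, cfg$baseline_log10_range[1],
                              cfg$baseline_log10_range[2])
  tm <- stats::runif(n_all, cfg$tm_range[1], cfg$tm_range[2])

  # category flags among filter-passing proteins
  flag_draw <- function(n_flag) {
    f <- rep(FALSE, n_all)
    f[sample(seq_len(n_pass), min(n_flag, n_pass))] <- TRUE
    f
  }
  atp <- flag_draw(cfg$n_atp_binders)
  mtase <- flag_draw(cfg$n_methyltransferases)
  methylated <- flag_draw(cfg$n_known_methylated)

  # abundance effects (ATP binders upweighted), filter-passing only
  prot_lfc <- numeric(n_all)
  w_ab <- ifelse(atp[seq_len(n_pass)], cfg$abundance_enrich_atp, 1)
  n_ab <- cfg$n_protein_up + cfg$n_protein_down
  ab_idx <- if (n_ab > 0) {
    sample(seq_len(n_pass), n_ab, prob = w_ab)
  } else integer()
  up_idx <- ab_idx[seq_len(cfg$n_protein_up)]
  down_idx <- setdiff(ab_idx, up_idx)
  prot_lfc[up_idx] <- .signed_uniform(length(up_idx), cfg$lfc_range, 1)
  prot_lfc[down_idx] <- .signed_uniform(length(down_idx), cfg$lfc_range, -1)

  # stability effects (known-methylated proteins upweighted)
  delta_tm <- numeric(n_all)
  w_st <- ifelse(methylated[seq_len(n_pass)],
                 cfg$stability_enrich_methylated, 1)
  n_st <- cfg$n_stabilized + cfg$n_destabilized
  st_idx <- if (n_st > 0) sample(seq_len(n_pass), n_st, prob = w_st) else
    integer()
  stab_idx <- st_idx[seq_len(cfg$n_stabilized)]
  destab_idx <- setdiff(st_idx, stab_idx)
  delta_tm[stab_idx] <- .signed_uniform(length(stab_idx),
                                        cfg$delta_tm_range, 1)
  delta_tm[destab_idx] <- .signed_uniform(length(destab_idx),
                                          cfg$delta_tm_range, -1)

  n_up <- stats::rpois(n_all, 4) + 2L      # unique peptides for passers
  conf <- rep("High", n_all)
  if (cfg$n_detected_extra > 0) {
    fail <- which(!pass)
    one_pep <- stats::runif(length(fail)) < 0.5
    n_up[fail[one_pep]] <- 1L
    conf[fail[!one_pep]] <- "Medium"
  }

  proteins <- data.frame(
    protein_id = protein_id, gene = gene, baseline = baseline,
    prot_lfc = prot_lfc, tm = tm, slope = cfg$slope, plateau = cfg$plateau,
    delta_tm = delta_tm, atp_binder = atp, methyltransferase = mtase,
    known_methylated = methylated, pass_filter = pass,
    n_unique_peptides = n_up, confidence = conf, stringsAsFactors = FALSE)

  ## ---- transcript ground truth ----------------------------------------
  gene_id <- sprintf("G%05d", seq_len(cfg$n_genes))
  rna_lfc <- numeric(cfg$n_genes)
  # coupled effects: genes whose (shared) protein carries an effect
  shared_prot <- which(pass & seq_len(n_all) <= cfg$n_shared_genes)
  coupled <- shared_prot[prot_lfc[shared_prot] != 0]
  if (length(coupled)) {
    e_p <- prot_lfc[coupled]
    eta <- .signed_uniform(length(coupled), cfg$lfc_range,
                           sample(c(-1, 1), length(coupled), replace = TRUE))
    rna_lfc[coupled] <- cfg$rho * e_p + sqrt(1 - cfg$rho^2) * eta
  }
  # independent effects fill the remaining quota
  quota_up <- max(0, cfg$n_rna_up - sum(rna_lfc > 0))
  quota_down <- max(0, cfg$n_rna_down - sum(rna_lfc < 0))
  free <- which(rna_lfc == 0)
  indep <- sample(free, min(quota_up + quota_down, length(free)))
  iu <- indep[seq_len(min(quota_up, length(indep)))]
  idn <- setdiff(indep, iu)
  rna_lfc[iu] <- .signed_uniform(length(iu), cfg$lfc_range, 1)
  rna_lfc[idn] <- .signed_uniform(length(idn), cfg$lfc_range, -1)
  genes_truth <- data.frame(gene = gene_id, rna_lfc = rna_lfc,
                            stringsAsFactors = FALSE)

  ## ---- proteomics matrices --------------------------------------------
  conds <- c("control", "treated")
  sheet <- expand.grid(replicate = seq_len(nrep), assay = c("global", "pisa"),
                       condition = conds, stringsAsFactors = FALSE)
  sheet$sample_id <- paste(sheet$condition, sheet$assay, sheet$replicate,
                           sep = "_")
  sheet <- sheet[c("sample_id", "condition", "assay", "replicate")]

  abund <- function(cond) baseline * 2^(if (cond == "treated") prot_lfc else 0)
  poolfrac <- function(cond) {
    .pool_fraction(tm + if (cond == "treated") delta_tm else 0,
                   cfg$slope, cfg$plateau, cfg$gradient)
  }
  gmat <- matrix(0, n_all, 2 * nrep)
  pmat <- matrix(0, n_all, 2 * nrep)
  gnames <- pnames <- character(2 * nrep)
  k <- 0
  for (cond in conds) {
    a <- abund(cond); pf <- poolfrac(cond)
    for (r in seq_len(nrep)) {
      k <- k + 1
      gmat[, k] <- a * .noise(n_all, cfg$cv)
      pmat[, k] <- a * pf * .noise(n_all, cfg$cv)
      gnames[k] <- paste(cond, "global", r, sep = "_")
      pnames[k] <- paste(cond, "pisa", r, sep = "_")
    }
  }
  colnames(gmat) <- gnames; colnames(pmat) <- pnames
  rownames(gmat) <- rownames(pmat) <- protein_id
  meta <- data.frame(feature_id = protein_id, gene = gene,
                     n_unique_peptides = n_up, confidence = conf,
                     stringsAsFactors = FALSE)
  global <- abundance_matrix(gmat, meta)
  pisa <- abundance_matrix(pmat, meta)

  ## ---- transcript matrix ----------------------------------------------
  rna_base <- 10^stats::runif(cfg$n_genes, 1, 4)
  rmat <- matrix(0, cfg$n_genes, 2 * nrep)
  rnames <- character(2 * nrep)
  k <- 0
  for (cond in conds) {
    a <- rna_base * 2^(if (cond == "treated") rna_lfc else 0)
    for (r in seq_len(nrep)) {
      k <- k + 1
      rmat[, k] <- a * .noise(cfg$n_genes, cfg$cv)
      rnames[k] <- paste(cond, r, sep = "_")
    }
  }
  colnames(rmat) <- rnames; rownames(rmat) <- gene_id
  rna <- abundance_matrix(rmat, data.frame(feature_id = gene_id,
                                           gene = gene_id,
                                           stringsAsFactors = FALSE))

  ## ---- methyl-peptide layer -------------------------------------------
  kme <- .simulate_kme(cfg, proteins, sheet)

  out <- list(truth = list(proteins = proteins, genes = genes_truth,
                           kme_sites = kme$sites, kme_peptides = kme$peptides),
              global = global, pisa = pisa, rna = rna, kme = kme$matrix,
              sheet = sheet, config = cfg)
  class(out) <- "pisa_simulation"
  out
}

# methyl-lysine peptide tables: sites on filter-passing parents, occupancy
# effects, proteoform-specific midpoint shifts, 1-3 peptides per site
.simulate_kme <- function(cfg, proteins, sheet) {
  ns <- cfg$n_kme_sites
  if (ns == 0) {
    empty <- abundance_matrix(
      matrix(numeric(), 0, nrow(sheet),
             dimnames = list(NULL, sheet$sample_id)),
      data.frame(feature_id = character(), protein = character(),
                 site = integer(), state = character(),
                 stringsAsFactors = FALSE))
    return(list(sites = NULL, peptides = NULL, matrix = empty))
  }
  passers <- which(proteins$pass_filter)
  parents <- sample(passers, cfg$n_kme_parents)
  parent_of <- c(parents, sample(parents, ns - cfg$n_kme_parents,
                                 replace = TRUE))
  site_pos <- integer(ns)
  for (p in unique(parent_of)) {
    idx <- which(parent_of == p)
    site_pos[idx] <- sort(sample(5:500, length(idx)))
  }
  state <- sample(names(cfg$kme_state_probs), ns, replace = TRUE,
                  prob = cfg$kme_state_probs)
  occ <- stats::runif(ns, cfg$occupancy_range[1], cfg$occupancy_range[2])
  occ_lfc <- numeric(ns)
  eff <- sample(ns, cfg$n_kme_up + cfg$n_kme_down)
  up <- eff[seq_len(cfg$n_kme_up)]
  dn <- setdiff(eff, up)
  occ_lfc[up] <- .signed_uniform(length(up), cfg$kme_lfc_range, 1)
  occ_lfc[dn] <- .signed_uniform(length(dn), cfg$kme_lfc_range, -1)
  # proteoform midpoint shift: parent's shift unless the site is selected
  pf_delta <- proteins$delta_tm[parent_of]
  st <- sample(setdiff(seq_len(ns), integer()),
               cfg$n_kme_stabilized + cfg$n_kme_destabilized)
  st_up <- st[seq_len(cfg$n_kme_stabilized)]
  st_dn <- setdiff(st, st_up)
  pf_delta[st_up] <- pf_delta[st_up] +
    .signed_uniform(length(st_up), cfg$delta_tm_range, 1)
  pf_delta[st_dn] <- pf_delta[st_dn] +
    .signed_uniform(length(st_dn), cfg$delta_tm_range, -1)

  sites <- data.frame(
    site_id = paste0(proteins$protein_id[parent_of], "_K", site_pos,
                     "_", state),
    protein = proteins$protein_id[parent_of], site = site_pos,
    state = state, occupancy = occ, occ_lfc = occ_lfc,
    proteoform_delta_tm = pf_delta,
    proteoform_stabilized = seq_len(ns) %in% st_up,
    proteoform_destabilized = seq_len(ns) %in% st_dn,
    stringsAsFactors = FALSE)

  npep <- sample(1:3, ns, replace = TRUE, prob = c(0.55, 0.30, 0.15))
  pep_site <- rep(seq_len(ns), npep)
  npe <- length(pep_site)
  ion <- stats::rlnorm(npe, 0, 0.5)   # peptide-specific ionization factor
  peptides <- data.frame(
    peptide_id = paste0(sites$site_id[pep_site], "_pep",
                        unlist(lapply(npep, seq_len))),
    site_id = sites$site_id[pep_site],
    protein = sites$protein[pep_site], site = sites$site[pep_site],
    state = sites$state[pep_site], ion_factor = ion,
    stringsAsFactors = FALSE)

  prot <- proteins[match(sites$protein, proteins$protein_id), ]
  vals <- matrix(0, npe, nrow(sheet))
  colnames(vals) <- sheet$sample_id
  rownames(vals) <- peptides$peptide_id
  for (j in seq_len(nrow(sheet))) {
    treated <- sheet$condition[j] == "treated"
    pa <- prot$baseline * 2^(if (treated) prot$prot_lfc else 0)
    oc <- occ * 2^(if (treated) occ_lfc else 0)
    site_amount <- pa * oc
    if (sheet$assay[j] == "pisa") {
      pf <- .pool_fraction(prot$tm + if (treated) pf_delta else 0,
                           cfg$slope, cfg$plateau, cfg$gradient)
      site_amount <- site_amount * pf
    }
    vals[, j] <- site_amount[pep_site] * ion * .noise(npe, cfg$cv)
  }
  meta <- data.frame(feature_id = peptides$peptide_id,
                     protein = peptides$protein, site = peptides$site,
                     state = peptides$state, stringsAsFactors = FALSE)
  list(sites = sites, peptides = peptides,
       matrix = abundance_matrix(vals, meta))
}

#' @export
print.pisa_simulation <- function(x, ...) {
  tr <- x$truth$proteins
  cat("Synthetic PISA experiment\n")
  cat(sprintf("  %d proteins detected (%d pass filter), %d replicates\n",
              nrow(tr), sum(tr$pass_filter), x$config$n_replicates))
  cat(sprintf("  abundance effects: %d up, %d down; stability: %d / %d\n",
              sum(tr$prot_lfc > 0), sum(tr$prot_lfc < 0),
              sum(tr$delta_tm > 0), sum(tr$delta_tm < 0)))
  cat(sprintf("  transcripts: %d genes (%d with effects)\n",
              nrow(x$truth$genes), sum(x$truth$genes$rna_lfc != 0)))
  if (!is.null(x$truth$kme_sites)) {
    cat(sprintf("  methyl sites: %d on %d parent proteins\n",
                nrow(x$truth$kme_sites),
                length(unique(x$truth$kme_sites$protein))))
  }
  invisible(x)
}

#' Write a simulated experiment to disk
#'
#' Emits the TSV tables consumed by the analysis entry points plus the
#' ground truth and the category gene sets: `global.tsv`, `pisa.tsv`,
#' `rna.tsv`, `kme_peptides.tsv`, `samples.tsv`, `truth.tsv` (protein
#' truth; gene and methyl-site truth in `truth_genes.tsv` /
#' `truth_kme.tsv`), and `sets.gmt`.
#'
#' @param sim A [simulate_experiment()] result.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the file paths written.
#' @export
write_datasets <- function(sim, dir) {
  stopifnot(inherits(sim, "pisa_simulation"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  write_abundance_table(sim$global, p("global.tsv"))
  write_abundance_table(sim$pisa, p("pisa.tsv"))
  write_abundance_table(sim$rna, p("rna.tsv"))
  write_abundance_table(sim$kme, p("kme_peptides.tsv"))
  write_sample_sheet(sim$sheet, p("samples.tsv"))
  utils::write.table(sim$truth$proteins, p("truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth$genes, p("truth_genes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(sim$truth$kme_sites)) {
    utils::write.table(sim$truth$kme_sites, p("truth_kme.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  tr <- sim$truth$proteins
  sets <- list(
    ATP_binding = tr$gene[tr$atp_binder],
    methyltransferase_activity = tr$gene[tr$methyltransferase],
    known_Kme_proteins = tr$gene[tr$known_methylated])
  write_gmt(sets, p("sets.gmt"))
  files <- c(global = p("global.tsv"), pisa = p("pisa.tsv"),
             rna = p("rna.tsv"), kme = p("kme_peptides.tsv"),
             samples = p("samples.tsv"), truth = p("truth.tsv"),
             truth_genes = p("truth_genes.tsv"), sets = p("sets.gmt"))
  if (!is.null(sim$truth$kme_sites)) {
    files["truth_kme"] <- p("truth_kme.tsv")
  }
  files
}
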