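test_that("peptides aggregate additively into site-state records", {
  m <- am(matrix(c(3, 30, 5, 50, 2, 20, 7, 70), 4, 2, byrow = TRUE),
          ids = paste0("pep", 1:4),
          protein = c("P1", "P1", "P1", "P2"),
          site = c(12L, 12L, 12L, 9L),
          state = c("me3", "me3", "me2", "me1"))
  s <- aggregate_sites(m)
  expect_equal(nrow(s$values), 3)  # me2 and me3 at the same site stay apart
  expect_equal(unname(s$values["P1_K12_me3", ]), c(3 + 5, 30 + 50))
  expect_equal(unname(s$values["P1_K12_me2", ]), c(2, 20))
  expect_equal(unname(s$values["P2_K9_me1", ]), c(7, 70))
  # single-peptide sites keep the peptide's values exactly
  expect_equal(unname(s$values["P2_K9_me1", ]), unname(m$values["pep4", ]))
})

test_that("peptides lacking site metadata are excluded with a warning", {
  m <- am(matrix(1, 3, 2), protein = c("P1", "P1", NA),
          site = c(1L, NA, 3L), state = "me1")
  expect_warning(s <- aggregate_sites(m), "2 peptide")
  expect_equal(nrow(s$values), 1)
  expect_equal(attr(s, "n_excluded"), 2)
})

test_that("site record count matches the simulation truth", {
  sim <- simulate_experiment(small_config(seed = 8))
  s <- aggregate_sites(sim$kme)
  expect_equal(nrow(s$values), nrow(sim$truth$kme_sites))
  expect_setequal(rownames(s$values), sim$truth$kme_sites$site_id)
})

test_that("sites tracking their protein are unchanged; occupancy dilution is called down", {
  sheet <- mini_sheet(4)
  gcols <- sheet$sample_id[sheet$assay == "global"]
  treated <- grepl("^treated", gcols)
  # protein doubles under treatment; site A tracks it, site B stays flat
  prot <- am(matrix(rep(ifelse(treated, 200, 100), each = 1), 1, 8),
             ids = "P1", samples = gcols)
  svals <- rbind(A = ifelse(treated, 20, 10), B = rep(10, 8))
  sites <- am(svals, ids = c("P1_K5_me1", "P1_K7_me3"), samples = gcols,
              protein = "P1", site = c(5L, 7L), state = c("me1", "me3"))
  res <- kme_global_differential(sites, prot, sheet)
  expect_equal(res$call, c("unchanged", "down"))
  expect_equal(res$p_value[1], 1)   # ratio cancels exactly
  expect_equal(res$log2fc[2], -1)   # occupancy halves when protein doubles
})

test_that("sites with absent parent proteins are skipped and recorded", {
  sheet <- mini_sheet(2)
  gcols <- sheet$sample_id[sheet$assay == "global"]
  prot <- am(matrix(1, 1, 4), ids = "P1", samples = gcols)
  sites <- am(matrix(1, 2, 4), ids = c("P1_K1_me1", "PX_K2_me1"),
              samples = gcols, protein = c("P1", "PX"),
              site = c(1L, 2L), state = "me1")
  res <- kme_global_differential(sites, prot, sheet)
  expect_equal(res$feature_id, "P1_K1_me1")
  expect_equal(attr(res, "skipped"), "PX_K2_me1")
})

test_that("a stabilized methyl proteoform is called while its parent is not", {
  # the methylated proteoform melts 3 degrees higher under treatment while
  # the unmodified protein is unshifted
  g8 <- pisa_gradient()
  sheet <- mini_sheet(4)
  base <- 1000; occ <- 0.2
  mp0 <- melt_params(50, 0.3, 0.02, delta_tm = 0)
  mp3 <- melt_params(50, 0.3, 0.02, delta_tm = 3)
  cols <- sheet$sample_id
  trt <- grepl("^treated", cols)
  is_pisa <- sheet$assay == "pisa"
  prot_vals <- ifelse(is_pisa, pisa_value(base, mp0, g8), base)
  site_vals <- numeric(16)
  for (j in 1:16) {
    a <- base * occ
    site_vals[j] <- if (is_pisa[j]) {
      pisa_value(a, mp3, g8, treated = trt[j])
    } else a
  }
  gl <- am(matrix(prot_vals[!is_pisa], 1, 8), ids = "P1",
           samples = cols[!is_pisa])
  sites <- am(matrix(site_vals, 1, 16), ids = "P1_K3_me3", samples = cols,
              protein = "P1", site = 3L, state = "me3")
  stab <- kme_stability_differential(sites, sheet)
  expect_equal(stab$call, "stabilized")
  # the parent protein's own thermal layer sees nothing
  pi <- am(matrix(prot_vals[is_pisa], 1, 8), ids = "P1",
           samples = cols[is_pisa])
  parent <- diff_stability(stability_ratio(pi, gl, sheet))
  expect_equal(parent$call, "unchanged")
})

test_that("null sites keep the false-call rate near alpha", {
  cfg <- small_config(seed = 16, n_kme_sites = 200, n_kme_parents = 150,
                      n_kme_up = 0, n_kme_down = 0, n_kme_stabilized = 0,
                      n_kme_destabilized = 0, n_stabilized = 0,
                      n_destabilized = 0)  # parents unshifted too
  sim <- simulate_experiment(cfg)
  fit <- pisa_analysis(sim)
  rate <- mean(fit$kme_stability$call != "unchanged")
  expect_gt(rate, 0)
  expect_lt(rate, 0.12)
})

test_that("occupancy effect recovery is within 20% of the designed counts", {
  cfg <- sim_config(n_proteins = 800, n_detected_extra = 0,
                    n_protein_up = 60, n_protein_down = 60,
                    n_stabilized = 0, n_destabilized = 0,
                    n_genes = 800, n_shared_genes = 800,
                    n_rna_up = 0, n_rna_down = 0,
                    n_atp_binders = 0, n_methyltransferases = 0,
                    n_known_methylated = 0,
                    n_kme_sites = 278, n_kme_parents = 247,
                    n_kme_up = 16, n_kme_down = 24, seed = 17)
  sim <- simulate_experiment(cfg)
  fit <- pisa_analysis(sim)
  truth <- sim$truth$kme_sites
  m <- match(fit$kme_global$feature_id, truth$site_id)
  rec_up <- sum(fit$kme_global$call == "up" & truth$occ_lfc[m] > 0)
  rec_down <- sum(fit$kme_global$call == "down" & truth$occ_lfc[m] < 0)
  expect_gte(rec_up, ceiling(0.8 * 16))
  expect_gte(rec_down, ceiling(0.8 * 24))
})

test_that("site statistics are invariant to rescaling one sample", {
  sim <- simulate_experiment(small_config(seed = 18))
  fit1 <- pisa_analysis(sim)
  sim2 <- sim
  s <- "treated_pisa_2"
  sim2$global$values[, "treated_global_2"] <-
    sim2$global$values[, "treated_global_2"] * 7
  sim2$pisa$values[, s] <- sim2$pisa$values[, s] * 7
  sim2$kme$values[, c(s, "treated_global_2")] <-
    sim2$kme$values[, c(s, "treated_global_2")] * 7
  fit2 <- pisa_analysis(sim2)
  # the fixed pseudocount meets a slightly changed grand total, so the
  # agreement is approximate in p and exact in the calls
  expect_equal(fit2$kme_global$p_value, fit1$kme_global$p_value,
               tolerance = 0.05)
  expect_equal(fit2$kme_stability$p_value, fit1$kme_stability$p_value,
               tolerance = 0.05)
  expect_equal(fit2$kme_global$call, fit1$kme_global$call)
  expect_equal(fit2$kme_stability$call, fit1$kme_stability$call)
})
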