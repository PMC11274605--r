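test_that("chi-square matches independence and the textbook formula", {
  # perfectly independent table: 20 of 60 in set, significance rate 1/3
  # everywhere -> statistic 0, p = 1
  universe <- sprintf("g%02d", 1:60)
  members <- universe[1:20]
  status <- c(universe[1:10], universe[21:30], universe[31:40])
  r0 <- chisq_category(members, status, universe)
  expect_equal(unname(r0$table), matrix(c(10, 10, 20, 20), 2, byrow = TRUE))
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 1)
  # association table [[30,10],[10,30]] has statistic 20 (hand-computed)
  u2 <- sprintf("h%02d", 1:80)
  m2 <- u2[1:40]
  s2 <- c(u2[1:30], u2[41:50])
  r2 <- chisq_category(m2, s2, u2)
  expect_equal(unname(r2$table), matrix(c(30, 10, 10, 30), 2, byrow = TRUE))
  expect_equal(r2$statistic, 20, tolerance = 1e-12)
  expect_equal(r2$statistic, brute_chisq(r2$table), tolerance = 1e-12)
  # transposition symmetry: swapping the roles of set and status
  r2b <- chisq_category(s2, m2, u2)
  expect_equal(r2b$statistic, r2$statistic)
})

test_that("degenerate and zero-cell tables are handled", {
  universe <- sprintf("g%02d", 1:20)
  r <- chisq_category(universe[1:5], character(0), universe)
  expect_true(r$degenerate)
  expect_equal(r$p_value, 1)
  # zero cell -> Haldane-corrected odds ratio is finite
  r2 <- chisq_category(universe[1:5], universe[1:5], universe)
  expect_true(is.finite(r2$odds_ratio))
  expect_gt(r2$odds_ratio, 1)
  expect_error(chisq_category("a", "a", character(0)), "empty universe")
})

test_that("chi-square false-positive rate is near alpha under random status", {
  set.seed(31)
  universe <- sprintf("g%04d", 1:1000)
  members <- sample(universe, 100)
  hits <- replicate(500, {
    status <- universe[runif(1000) < 0.1]
    chisq_category(members, status, universe)$p_value < 0.05
  })
  expect_gt(mean(hits), 0.015)
  expect_lt(mean(hits), 0.09)
})

test_that("random-set control is calibrated, reproducible, and validated", {
  universe <- sprintf("g%04d", 1:500)
  set.seed(32)
  status <- sample(universe, 60)
  a <- random_control(universe, 50, status, n_draws = 200, seed = 7)
  b <- random_control(universe, 50, status, n_draws = 200, seed = 7)
  expect_identical(a, b)
  expect_lt(a$frac_significant, 0.12)
  # degenerate draw: the whole universe every time
  d <- random_control(universe, 500, status, n_draws = 100, seed = 1)
  expect_equal(length(unique(d$draws$statistic)), 1)
  expect_error(random_control(universe, 501, status), "exceeds")
  expect_error(random_control(universe, 10, status, n_draws = 50), ">= 100")
})

test_that("a truly enriched set beats the random-draw distribution", {
  set.seed(33)
  universe <- sprintf("g%04d", 1:1000)
  members <- universe[1:100]
  # members are 4x as likely to be significant
  status <- universe[runif(1000) < ifelse(universe %in% members, 0.4, 0.1)]
  obs <- chisq_category(members, status, universe)
  ctl <- random_control(universe, 100, status, n_draws = 400, seed = 2)
  expect_lt(obs$p_value, 0.05)
  expect_gt(obs$statistic, quantile(ctl$draws$statistic, 0.95))
})

test_that("overlap classification assigns each gene to one of eight classes", {
  mk <- function(ids, sig) data.frame(feature_id = ids,
                                      call = ifelse(sig, "up", "unchanged"))
  rna <- mk(c("a", "b", "c", "d"), c(TRUE, TRUE, FALSE, FALSE))
  prot <- mk(c("a", "b", "c", "e"), c(TRUE, FALSE, FALSE, TRUE))
  therm <- mk(c("a", "c", "d", "e"), c(TRUE, TRUE, FALSE, FALSE))
  ov <- classify_overlap(rna, prot, therm)
  expect_equal(sum(ov$counts), 5)  # universe: a b c d e
  cls <- setNames(ov$classes$class, ov$classes$gene)
  expect_equal(cls[["a"]], "rna+protein+thermal")
  expect_equal(cls[["b"]], "rna")
  expect_equal(cls[["c"]], "thermal")
  expect_equal(cls[["d"]], "none")
  expect_equal(cls[["e"]], "protein")
  expect_equal(ov$summary$thermal_total, 2)
  expect_equal(ov$summary$thermal_and_any, 1)
  expect_equal(ov$summary$thermal_only, 1)
})

test_that("overlap summary reproduces the report arithmetic", {
  s <- summarize_overlap(list(thermal_total = 135, thermal_and_any = 94,
                              thermal_protein_only = 66))
  expect_equal(s$pct_overlap_any, 70)
  expect_equal(s$pct_protein_only, 49)
  expect_equal(s$thermal_only, 41)
  z <- summarize_overlap(list(thermal_total = 135, thermal_and_any = 0,
                              thermal_protein_only = 0))
  expect_equal(z$pct_overlap_any, 0)
  u <- summarize_overlap(list(thermal_total = 0, thermal_and_any = 0,
                              thermal_protein_only = 0))
  expect_true(u$undefined)
  expect_true(is.na(u$pct_overlap_any))
})

test_that("overlap counts from a constructed simulation match the truth", {
  sim <- simulate_experiment(small_config(seed = 34, cv = 0))
  fit <- pisa_analysis(sim)
  # noise-free: every designed effect is recovered, so the corresponding
  # flags must be set (null features may still be flagged because the
  # equal-total normalization shifts them when effects are unbalanced);
  # the transcript layer is not re-normalized, so its flags are exact
  tr <- sim$truth$proteins
  passing <- tr[tr$pass_filter, ]
  genes <- sim$truth$genes
  rna_called <- genes$gene[abs(genes$rna_lfc) > 1]
  cls <- fit$overlap$classes
  j <- match(cls$gene, passing$gene)
  has_prot <- !is.na(j)
  expect_true(all(cls$protein_sig[has_prot][
    passing$prot_lfc[j[has_prot]] != 0]))
  expect_true(all(cls$thermal_sig[has_prot][
    passing$delta_tm[j[has_prot]] != 0]))
  expect_equal(cls$rna_sig, cls$gene %in% rna_called)
  expect_equal(sum(fit$overlap$counts), nrow(cls))
})
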