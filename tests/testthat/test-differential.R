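test_that("identical groups give no change and swap negates the fold change", {
  set.seed(11)
  x <- matrix(rlnorm(40, 5, 0.5), 10, 4,
              dimnames = list(paste0("p", 1:10), paste0("c", 1:4)))
  res <- diff_abundance(x, x)
  expect_true(all(res$log2fc == 0))
  expect_true(all(res$call == "unchanged"))
  expect_true(all(res$p_value == 1))  # zero-variance convention
  y <- x * matrix(rlnorm(40, 0, 0.2), 10, 4)
  ab <- diff_abundance(x, y)
  ba <- diff_abundance(y, x)
  expect_equal(ab$log2fc, -ba$log2fc)
  expect_equal(ab$p_value, ba$p_value)
})

test_that("row-wise Welch t matches stats::t.test", {
  set.seed(12)
  x <- matrix(rnorm(80), 20, 4)
  y <- matrix(rnorm(80, 0.5, 1.3), 20, 4)
  mine <- pisar:::row_t_welch(x, y)
  for (i in 1:20) {
    ref <- t.test(x[i, ], y[i, ])
    expect_equal(mine$p_value[i], ref$p.value, tolerance = 1e-12)
    expect_equal(mine$statistic[i], unname(ref$statistic),
                 tolerance = 1e-12)
  }
  expect_error(pisar:::row_t_welch(x[, 1, drop = FALSE], y), "replicates")
})

test_that("abundance test has power at moderate effects and low noise", {
  set.seed(13)
  n <- 50
  base <- rlnorm(n, 8, 1)
  noise <- function() matrix(rlnorm(n * 4, 0, sqrt(log(1 + 0.05^2))), n, 4)
  ctrl <- base * noise()
  trt <- (base * 2) * noise()  # true log2FC = 1
  rownames(ctrl) <- rownames(trt) <- paste0("p", 1:n)
  res <- diff_abundance(ctrl, trt)
  expect_gte(sum(res$call == "up"), 45)
})

test_that("stability ratios cancel shared abundance changes", {
  sheet <- mini_sheet(2)
  vals <- matrix(rep(c(4, 8), 4), 2, 4)
  ids <- c("P1", "P2")
  cols <- sheet$sample_id
  g <- am(vals, ids = ids, samples = cols[sheet$assay == "global"])
  # identical pisa and global -> all ratios 1
  p <- am(vals, ids = ids, samples = cols[sheet$assay == "pisa"])
  r <- stability_ratio(p, g, sheet)
  expect_true(all(r$values == 1))
  # doubling both assays of one replicate leaves ratios unchanged
  g2 <- g; p2 <- p
  g2$values[, "control_global_1"] <- g2$values[, "control_global_1"] * 2
  p2$values[, "control_pisa_1"] <- p2$values[, "control_pisa_1"] * 2
  expect_equal(stability_ratio(p2, g2, sheet)$values, r$values)
})

test_that("stability ratio drops unshared features and flags orphan samples", {
  sheet <- mini_sheet(2)
  g <- am(matrix(1, 3, 4), ids = c("P1", "P2", "P3"),
          samples = sheet$sample_id[sheet$assay == "global"])
  p <- am(matrix(1, 2, 4), ids = c("P2", "P4"),
          samples = sheet$sample_id[sheet$assay == "pisa"])
  r <- stability_ratio(p, g, sheet)
  expect_equal(rownames(r$values), "P2")
  expect_setequal(attr(r, "dropped"), c("P1", "P3", "P4"))
  bad <- sheet
  bad$sample_id[1] <- "missing_sample"
  expect_error(stability_ratio(p, g, bad), "missing_sample")
})

test_that("a positive midpoint shift raises treated ratios in a noise-free fixture", {
  g8 <- pisa_gradient()
  sheet <- mini_sheet(4)
  base <- 100
  mp <- function(d) melt_params(50, 0.3, 0.02, delta_tm = d)
  gl <- am(matrix(base, 1, 8), ids = "P1",
           samples = sheet$sample_id[sheet$assay == "global"])
  pvals <- c(rep(pisa_value(base, mp(3), g8, treated = FALSE), 4),
             rep(pisa_value(base, mp(3), g8, treated = TRUE), 4))
  pi <- am(matrix(pvals, 1, 8), ids = "P1",
           samples = sheet$sample_id[sheet$assay == "pisa"])
  r <- stability_ratio(pi, gl, sheet)
  trt <- r$values[1, grepl("^treated", colnames(r$values))]
  ctl <- r$values[1, grepl("^control", colnames(r$values))]
  expect_true(all(trt > ctl))
  # frozen oracle: the log2 ratio shift for tm 50 -> 53 over the gradient
  expect_equal(log2(mean(trt) / mean(ctl)), 0.3416706, tolerance = 1e-6)
})

test_that("thermal test on identical matrices yields no significant calls", {
  sheet <- mini_sheet(4)
  set.seed(14)
  v <- matrix(rlnorm(80, 3, 1), 10, 8)
  g <- am(v, samples = sheet$sample_id[sheet$assay == "global"])
  p <- am(v, samples = sheet$sample_id[sheet$assay == "pisa"])
  res <- diff_stability(stability_ratio(p, g, sheet))
  expect_true(all(res$p_value == 1))
  expect_true(all(res$call == "unchanged"))
})

test_that("transcript calls require both significance and fold-change magnitude", {
  # noise-free two-group design: log2FC 0.8 is significant but below the
  # magnitude cutoff; log2FC 1.5 passes both
  ctrl <- matrix(100, 2, 4, dimnames = list(c("g1", "g2"), NULL))
  trt <- rbind(g1 = rep(100 * 2^0.8, 4), g2 = rep(100 * 2^1.5, 4))
  res <- diff_transcripts(ctrl, trt, pseudocount = 0)
  expect_equal(res$call, c("unchanged", "up"))
  expect_lt(res$adj_p[1], 0.05)  # significant yet not called
  res2 <- diff_transcripts(trt, ctrl, pseudocount = 0)
  expect_equal(res2$call[2], "down")
})

test_that("BH control keeps null transcript calls rare", {
  sim <- simulate_experiment(null_config(n = 2000, seed = 15))
  gr <- pisar:::.split_rna(sim$rna$values)
  res <- diff_transcripts(gr$ctrl, gr$trt)
  expect_lte(mean(res$call != "unchanged"), 0.01)
})

test_that("fold-change correlation matches on shared genes and degenerates error", {
  d1 <- data.frame(feature_id = c("a", "b", "c", "d"),
                   log2fc = c(1, 2, -1, 0.5))
  d2 <- data.frame(feature_id = c("c", "b", "a", "e"),
                   log2fc = c(-1, 2, 1, 9))
  r <- protein_rna_correlation(d1, d2)
  expect_equal(r$r, 1)
  expect_equal(r$n, 3)
  d3 <- d2; d3$log2fc <- -d3$log2fc
  expect_equal(protein_rna_correlation(d1, d3)$r, -1)
  expect_error(protein_rna_correlation(d1[1:2, ], d2[1:2, ]), "fewer than 3")
})
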