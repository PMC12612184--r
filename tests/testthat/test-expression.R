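# Relative qPCR quantification and group statistics.

make_strata <- function(folds = c(flat = 1, low = 2, medium = 5, high = 10)) {
  data.frame(cell_type = "keratocyte", gene = "ACTA2",
             condition = names(folds), fold = unname(folds))
}

test_that("ddct reproduces programmed folds exactly in the noise-free limit", {
  tb <- make_ct_table(ct_recipe(make_strata(), noise_sd = 0, seed = 1))
  d <- ddct(tb$ct_table)
  expect_equal(d$fold[match(c("flat", "low", "medium", "high"), d$condition)],
               c(1, 2, 5, 10), tolerance = 1e-12)
  # reference fold is identically 1, ddct identically 0
  expect_identical(d$ddct[d$condition == "flat"], 0)
  expect_identical(d$fold[d$condition == "flat"], 1)
  # ddCt = -1 means fold 2 by closed form
  expect_equal(2^-(-1), 2)
  expect_equal(d$ddct[d$condition == "low"], -1, tolerance = 1e-12)
})

test_that("shifting one condition's target Cts by -1 doubles its fold", {
  tb <- make_ct_table(ct_recipe(make_strata(), noise_sd = 0.3, seed = 2))
  d0 <- ddct(tb$ct_table)
  shifted <- tb$ct_table
  sel <- shifted$condition == "medium" & shifted$gene == "ACTA2"
  shifted$ct[sel] <- shifted$ct[sel] - 1
  d1 <- ddct(shifted)
  expect_equal(d1$fold[d1$condition == "medium"],
               2 * d0$fold[d0$condition == "medium"], tolerance = 1e-12)
  expect_equal(d1$fold[d1$condition == "high"], d0$fold[d0$condition == "high"])
})

test_that("a programmed 10-fold change is recovered across noisy replicates", {
  folds <- vapply(1:20, function(seed) {
    tb <- make_ct_table(ct_recipe(make_strata(), noise_sd = 0.2,
                                  n_replicates = 3, seed = seed))
    d <- ddct(tb$ct_table)
    d$fold[d$condition == "high"]
  }, 0)
  expect_gte(median(folds), 9)
  expect_lte(median(folds), 11)
})

test_that("ct table validation lists the offending strata", {
  tb <- make_ct_table(ct_recipe(make_strata(), noise_sd = 0, seed = 3))$ct_table
  no_hk <- tb[tb$gene != "GAPDH" | tb$sample_id != "keratocyte_low_r1", ]
  expect_error(ddct(no_hk), "keratocyte_low_r1")
  no_ref <- tb[tb$condition != "flat", ]
  expect_error(ddct(no_ref), "reference condition")
  bad_ct <- tb; bad_ct$ct[1] <- 45
  expect_warning(validate_ct_table(bad_ct), "10-40")
  expect_error(validate_ct_table(tb[, -5]), "columns")
})

test_that("anova_scheffe matches reference ANOVA and the k = 2 identity", {
  set.seed(11)
  vals <- c(rnorm(6, 0), rnorm(6, 1), rnorm(6, 1.5))
  grp <- rep(c("a", "b", "c"), each = 6)
  gs <- anova_scheffe(vals, grp)
  ref <- anova(lm(vals ~ grp))
  expect_equal(gs$anova$F, ref$`F value`[1], tolerance = 1e-10)
  expect_equal(gs$anova$p, ref$`Pr(>F)`[1], tolerance = 1e-10)
  expect_equal(gs$anova$mse, ref$`Mean Sq`[2], tolerance = 1e-10)
  # with two groups, Scheffe's pairwise p equals the ANOVA p
  gs2 <- anova_scheffe(vals[1:12], grp[1:12])
  expect_equal(gs2$scheffe$p, gs2$anova$p, tolerance = 1e-10)
  # Scheffe is conservative: pairwise p never below the unadjusted contrast p
  k <- 3; df2 <- length(vals) - k
  for (i in seq_len(nrow(gs$scheffe))) {
    Fs <- gs$scheffe$F[i]
    p_unadj <- pf(Fs * (k - 1), 1, df2, lower.tail = FALSE)
    expect_gte(gs$scheffe$p[i], p_unadj - 1e-12)
  }
  # identical groups: no evidence, no stars
  gs0 <- anova_scheffe(rep(c(1, 2, 3), 4), rep(c("x", "y"), each = 6))
  expect_gt(gs0$anova$p, 0.5)
  expect_true(all(gs0$scheffe$stars == ""))
  expect_error(anova_scheffe(1:5, c("a", "a", "a", "a", "b")), "at least 2")
  expect_identical(signif_stars(c(0.2, 0.04, 0.009, 5e-4)),
                   c("", "*", "**", "***"))
})
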