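test_that("grouped_metric enforces its invariants", {
  expect_error(grouped_metric(list(a = 1:3)), "length")
  expect_error(grouped_metric(list(saline = 1:3, d1 = 5)), "n >= 2")
  expect_error(grouped_metric(list(a = 1:3, b = 1:3), control = "saline"),
               "control")
})

test_that("one-way ANOVA: equal groups give F = 0; F equals t^2 for 2 groups", {
  gm0 <- grouped_metric(list(saline = c(1, 2, 3), d1 = c(1, 2, 3)))
  expect_equal(one_way_anova(gm0)$F, 0)
  set.seed(88)
  for (k in 1:10) {
    a <- rnorm(sample(3:9, 1)); b <- rnorm(sample(3:9, 1), 0.5)
    gm <- grouped_metric(list(saline = a, d1 = b))
    res <- one_way_anova(gm)
    tt <- t.test(a, b, var.equal = TRUE)
    expect_equal(res$F, unname(tt$statistic)^2, tolerance = 1e-9)
    expect_equal(res$p, tt$p.value, tolerance = 1e-9)
  }
})

test_that("one-way ANOVA reproduces the published degrees of freedom", {
  # six groups sized 6, 8, 8, 7, 6, 28 -> F[5, 57]
  set.seed(5)
  sizes <- c(6, 8, 8, 7, 6, 28)
  g <- lapply(sizes, rnorm)
  names(g) <- c(paste0("d", 1:5), "saline")
  res <- one_way_anova(grouped_metric(g))
  expect_equal(res$df_between, 5L)
  expect_equal(res$df_within, 57L)
})

test_that("Dunnett reduces to the t-test for one treatment group", {
  set.seed(31)
  for (k in 1:5) {
    gm <- grouped_metric(list(saline = rnorm(8), d1 = rnorm(6, 0.8)))
    dun <- dunnett_vs_control(gm)
    tt <- t.test(gm$groups$d1, gm$groups$saline, var.equal = TRUE)
    expect_equal(dun$p_adj, tt$p.value, tolerance = 1e-6)
  }
})

test_that("Dunnett adjusted p >= raw p, and matches an independent MC oracle", {
  set.seed(77)
  gm <- grouped_metric(list(saline = rnorm(8), d1 = rnorm(8, 0.4),
                            d2 = rnorm(8, 0.9), d3 = rnorm(8, 1.6)))
  dun <- dunnett_vs_control(gm)
  expect_true(all(dun$p_adj >= dun$p_raw - 1e-12))
  expect_true(all(dun$p_adj <= 1))
  df <- 4 * 8 - 4
  for (i in seq_len(nrow(dun))) {
    ora <- oracle_dunnett_p(abs(dun$t[i]), ns = rep(8, 3), n0 = 8, df = df)
    expect_lt(abs(dun$p_adj[i] - ora), 3e-3) # combined MC error bound

  }
  # determinism of the fixed-seed MC
  expect_identical(dun$p_adj, dunnett_vs_control(gm)$p_adj)
})

test_that("Sidak adjustment follows its closed form", {
  expect_equal(sidak_adjust(0.05, 1), 0.05)
  expect_equal(sidak_adjust(1, 7), 1)
  expect_equal(sidak_adjust(0.01, 5), 1 - 0.99^5)
  expect_equal(sidak_adjust(0, 10), 0)
  expect_error(sidak_adjust(0.5, 0), "m must")
  expect_error(sidak_adjust(1.5, 2), "\\[0, 1\\]")
})

test_that("two-way timecourse: identical group means give p = 1 heatmap", {
  bins <- seq(0, 5100, by = 300)
  base <- data.frame(bin_start = rep(bins, 3),
                     value = rep(c(3, 5, 7), each = length(bins)))
  long <- do.call(rbind, lapply(c("saline", "hal 0.5", "hal 1"), function(g) {
    d <- base
    d$group <- g
    d$session <- paste(g, rep(1:3, each = length(bins)))
    d
  }))
  fit <- two_way_anova_timecourse(long)
  expect_equal(ncol(fit$p_adj), 18L)
  expect_identical(colnames(fit$p_adj), as.character(seq(5, 90, by = 5)))
  expect_true(all(fit$p_adj == 1))
  hm <- pvalue_heatmap(fit)
  expect_true(all(hm <= 0.9999 & hm >= 1e-4))
})

test_that("two-way timecourse detects a planted mid-session effect", {
  set.seed(99)
  bins <- seq(0, 5100, by = 300)
  mk <- function(g, n, shift) {
    do.call(rbind, lapply(1:n, function(i) {
      eff <- ifelse(bins >= 600 & bins < 3600, shift, 0)
      data.frame(session = paste(g, i), group = g, bin_start = bins,
                 value = 10 + eff + rnorm(length(bins)))
    }))
  }
  long <- rbind(mk("saline", 8, 0), mk("hal 1", 8, -6))
  fit <- two_way_anova_timecourse(long)
  inside <- colnames(fit$p_adj)[seq(3, 12)]  # bins ending 15..60 min
  outside <- colnames(fit$p_adj)[c(1, 17, 18)]
  expect_true(all(fit$p_adj["hal 1", inside] < 0.05))
  expect_true(all(fit$p_adj["hal 1", outside] > 0.05))
  # Sidak families: per-table adjustment is at least as conservative
  fit_tab <- two_way_anova_timecourse(long, family = "per_table")
  expect_true(all(fit_tab$p_adj >= fit$p_adj - 1e-12))
})

test_that("missing cells are flagged, not imputed", {
  bins <- seq(0, 900, by = 300)
  long <- rbind(
    data.frame(session = "s1", group = "saline", bin_start = bins, value = 1:4),
    data.frame(session = "s2", group = "saline", bin_start = bins, value = 2:5),
    data.frame(session = "d1", group = "hal 1", bin_start = bins,
               value = c(5, NA, 6, 7)),
    data.frame(session = "d2", group = "hal 1", bin_start = bins,
               value = c(6, NA, 7, 9)))
  fit <- two_way_anova_timecourse(long)
  expect_true(is.na(fit$p_adj["hal 1", 2]))
  expect_false(anyNA(fit$p_adj["hal 1", -2]))
})
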