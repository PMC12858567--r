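test_that("balanced two-way ANOVA reproduces a hand-computed SS oracle", {
  # small integer dataset, n = 3 per cell; balanced, so Type III equals the
  # classical unweighted sums of squares computed here from first principles
  vals <- c(3, 4, 5,  6, 8, 10,  1, 2, 3,
            7, 7, 10,  12, 14, 13,  4, 6, 5)
  tab <- expand.grid(
    rep = 1:3,
    cana = factor(c("NoCana", "Cana"), levels = c("NoCana", "Cana")),
    group = factor(c("ND-Palm", "T1D-Palm", "T1D-Ins"),
                   levels = c("ND-Palm", "T1D-Palm", "T1D-Ins")))
  tab$outcome <- vals
  f <- fit_two_way_anova(tab, "outcome")
  # oracle: classical balanced-design sums of squares
  n <- 3; gm <- mean(vals)
  cm <- tapply(tab$outcome, list(tab$cana, tab$group), mean)
  ss_a <- n * 3 * sum((rowMeans(cm) - gm)^2)
  ss_b <- n * 2 * sum((colMeans(cm) - gm)^2)
  ss_ab <- n * sum((sweep(sweep(cm, 1, rowMeans(cm)), 2, colMeans(cm)) + gm)^2)
  ss_e <- sum((tab$outcome - cm[cbind(as.integer(tab$cana),
                                      as.integer(tab$group))])^2)
  df_e <- 18 - 6
  expect_equal(unname(f$effects$cana["F"]), (ss_a / 1) / (ss_e / df_e))
  expect_equal(unname(f$effects$group["F"]), (ss_b / 2) / (ss_e / df_e))
  expect_equal(unname(f$effects$interaction["F"]),
               (ss_ab / 2) / (ss_e / df_e))
})

test_that("degenerate and malformed cohorts are rejected with named errors", {
  tab <- simulate_cohort_table(n_per_cell = 4, seed = 1)
  bad <- tab[!(tab$cana == "Cana" & tab$group == "T1D-Ins"), ]
  expect_error(fit_two_way_anova(bad, "outcome"), "empty cell: Cana x T1D-Ins")
  const <- tab; const$outcome <- 5
  expect_error(fit_two_way_anova(const, "outcome"), "zero-variance")
  all_tied <- tab; all_tied$outcome <- rep(c(1, 1), length.out = nrow(tab))
  expect_error(art_anova(all_tied, "outcome"), "tied|zero-variance")
})

test_that("exactly additive cell means give zero interaction F", {
  tab <- balanced_cohort(cell_means = c(10, 12, 20, 22, 30, 32), n = 4)
  tab$outcome <- tab$outcome + rep(c(-1, 1), length.out = nrow(tab))
  f <- fit_two_way_anova(tab, "outcome")
  expect_equal(unname(f$effects$interaction["F"]), 0, tolerance = 1e-10)
  expect_equal(unname(f$effects$interaction["p"]), 1, tolerance = 1e-10)
})

test_that("residual diagnostics detect the violations they are built for", {
  # Gaussian homoscedastic: parametric accepted in >= 90% of replicates
  ok <- sapply(1:500, function(s) {
    tab <- simulate_cohort_table(n_per_cell = 10, cell_location = c(1:6) * 10,
                                 cell_scale = 2, seed = s)
    diagnose_residuals(fit_two_way_anova(tab, "outcome"))$parametric_ok
  })
  expect_gte(mean(ok), 0.90)
  # strong heteroscedasticity: sd proportional to the fitted value
  het <- sapply(1:200, function(s) {
    tab <- simulate_cohort_table(n_per_cell = 10,
                                 cell_location = c(10, 40, 90, 15, 50, 100),
                                 cell_scale = 0.15 * c(10, 40, 90, 15, 50, 100),
                                 seed = s)
    diagnose_residuals(fit_two_way_anova(tab, "outcome"))$spearman_p < 0.05
  })
  expect_gte(mean(het), 0.95)
  # symmetric two-point residuals +-1: Anderson-Darling rejects at n = 60
  tab <- balanced_cohort(cell_means = rep(0, 6), n = 10)
  tab$outcome <- rep(c(-1, 1), length.out = nrow(tab))
  d <- diagnose_residuals(fit_two_way_anova(tab, "outcome"))
  expect_lt(d$ad_p, 0.05)
  expect_false(d$parametric_ok)
})

test_that("ART alignment strips off-test effects exactly", {
  tab <- balanced_cohort(cell_means = c(10, 12, 20, 25, 30, 28), n = 4)
  a <- art_anova(tab, "outcome")
  expect_lt(max(unlist(a$alignment_check)), 1e-8)
  tab$outcome <- tab$outcome + rnorm(nrow(tab), 0, 2)
  a2 <- art_anova(tab, "outcome")
  expect_lt(max(unlist(a2$alignment_check)), 1e-8)
  expect_identical(a2$method_used, "ART")
})

test_that("ART and parametric ANOVA agree under monotone transforms", {
  agree <- sapply(1:100, function(s) {
    tb <- simulate_cohort_table(n_per_cell = 10,
                                cell_location = c(0, 1, 2, 0.5, 1.5, 2.5),
                                cell_scale = 1, seed = s)
    pg <- fit_two_way_anova(tb, "outcome")$p_values["group"]
    tb$expy <- exp(tb$outcome)
    pa <- art_anova(tb, "expy")$p_values["group"]
    (pg < 0.05) == (pa < 0.05)
  })
  expect_gte(mean(agree), 0.90)
})

test_that("Holm-Sidak adjustment matches the closed form and is monotone", {
  expect_equal(holm_sidak_adjust(c(0.01, 0.03, 0.04)),
               c(1 - 0.99^3, 1 - 0.97^2, 1 - 0.97^2))
  expect_equal(round(holm_sidak_adjust(c(0.01, 0.03, 0.04)), 4),
               c(0.0297, 0.0591, 0.0591))
  set.seed(1)
  for (i in 1:20) {
    p <- runif(sample(2:6, 1))
    adj <- holm_sidak_adjust(p)
    expect_true(all(adj >= p - 1e-12))
    expect_true(all(adj <= 1))
    o <- order(p)
    expect_true(all(diff(adj[o]) >= -1e-12))
  }
})

test_that("post-hoc families follow the 3+3+3 design and pick the right test", {
  tab <- simulate_cohort_table(n_per_cell = 10,
                               cell_location = c(10, 30, 20, 11, 31, 21),
                               cell_scale = 3, seed = 2)
  fams <- posthoc_families(tab, "outcome")
  expect_named(fams, c("group_within_NoCana", "group_within_Cana",
                       "cana_within_group"))
  expect_true(all(vapply(fams, function(f) nrow(f$comparisons), 0L) == 3L))
  for (f in fams) {
    expect_true(all(f$comparisons$p_adj >= f$comparisons$p_raw - 1e-12))
    expect_true(all(f$comparisons$p_adj <= 1))
  }
  # two identical groups under Dunn: adjusted p = 1 for that pair
  tab2 <- tab
  tab2$outcome[tab2$cana == "NoCana" & tab2$group == "ND-Palm"] <-
    tab2$outcome[tab2$cana == "NoCana" & tab2$group == "T1D-Palm"]
  tab2$outcome <- exp(tab2$outcome / 3)                 # force non-normality
  fams2 <- posthoc_families(tab2, "outcome", diag_alpha = 0.9)
  f1 <- fams2$group_within_NoCana
  expect_identical(f1$test_used, "dunn")
  i <- which(f1$comparisons$level_a == "ND-Palm" &
             f1$comparisons$level_b == "T1D-Palm")
  expect_equal(f1$comparisons$p_adj[i], 1)
  # n < 3 forces Dunn with a warning
  small <- simulate_cohort_table(n_per_cell = c(2, 10, 10, 10, 10, 10),
                                 seed = 3)
  w <- testthat::capture_warnings(
    fams3 <- posthoc_families(small, "outcome"))
  expect_true(any(grepl("n < 3", w)))
  expect_identical(fams3$group_within_NoCana$test_used, "dunn")
})

test_that("the decision tree takes the documented branches", {
  tab <- simulate_cohort_table(n_per_cell = 10,
                               cell_location = c(176, 723, 280, 176, 723, 280),
                               cell_scale = rep(30, 6), seed = 5)
  rep1 <- run_decision_tree(tab, "outcome")
  expect_identical(rep1$branch, "parametric")
  expect_true(all(rep1$posthoc_test == "holm_sidak_t"))
  expect_true(length(rep1$families) >= 2L)              # group gate open
  expect_true(all(c("group_within_NoCana", "group_within_Cana") %in%
                  names(rep1$families)))
  tab2 <- simulate_cohort_table(n_per_cell = 10,
                                cell_scale = c(50, 600, 150, 50, 600, 150),
                                noise_family = "lognormal", seed = 7)
  rep2 <- run_decision_tree(tab2, "outcome")
  expect_identical(rep2$branch, "ART")
  expect_true(all(rep2$posthoc_test == "dunn"))
  # no simulated effect: gates closed, no families emitted
  null_tab <- simulate_cohort_table(n_per_cell = 10, cell_location = 0,
                                    cell_scale = 1, seed = 41)
  rep3 <- run_decision_tree(null_tab, "outcome")
  if (all(rep3$fit$p_values >= 0.05)) expect_length(rep3$families, 0L)
})

test_that("null rejection rates are calibrated for both branches", {
  # moderate replicate count here; the acceptance suite runs the full 2000
  ps <- sapply(1:400, function(s)
    fit_two_way_anova(simulate_cohort_table(n_per_cell = 10,
                                            cell_location = 0, cell_scale = 1,
                                            seed = s), "outcome")$p_values)
  rates <- rowMeans(ps < 0.05)
  expect_true(all(rates > 0.02 & rates < 0.09))
  pa <- sapply(1:400, function(s)
    art_anova(simulate_cohort_table(n_per_cell = 10, cell_location = 0,
                                    cell_scale = 1, seed = s),
              "outcome")$p_values)
  rates_art <- rowMeans(pa < 0.05)
  expect_true(all(rates_art > 0.02 & rates_art < 0.09))
})
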