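check_cohort <- function(table, outcome) {
  if (!all(c("cana", "group") %in% names(table)))
    stop("table must have `cana` and `group` factor columns")
  if (!outcome %in% names(table)) stop("outcome column not found")
  y <- table[[outcome]]
  if (!is.numeric(y)) stop("outcome must be numeric")
  tab <- table(table$cana, table$group)
  if (any(tab == 0L)) {
    emp <- which(tab == 0L, arr.ind = TRUE)[1, ]
    stop(sprintf("empty cell: %s x %s", rownames(tab)[emp[1]],
                 colnames(tab)[emp[2]]))
  }
  if (sum(tab >= 2L) < 5L) stop("need >= 2 observations in >= 5 of 6 cells")
  if (sd(y) == 0) stop("zero-variance outcome")
  invisible(TRUE)
}

# Type III SS by model-matrix column deletion under sum-to-zero contrasts;
# robust to zero-residual (perfect-fit) responses, where F is reported as 0
# for zero-SS effects and Inf otherwise
type3_manual <- function(data, outcome) {
  fml <- stats::as.formula(paste("`", outcome, "` ~ cana * group", sep = ""))
  mf <- stats::model.frame(fml, data)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(fml, mf,
                           contrasts.arg = list(cana = "contr.sum",
                                                group = "contr.sum"))
  asg <- attr(X, "assign")
  rss <- function(M) {
    ft <- stats::lm.fit(M, y)
    sum(ft$residuals^2)
  }
  rss_full <- rss(X)
  df_res <- nrow(X) - ncol(X)
  terms <- c(cana = 1L, group = 2L, interaction = 3L)
  eff <- lapply(terms, function(t) {
    ss <- rss(X[, asg != t, drop = FALSE]) - rss_full
    df <- sum(asg == t)
    tol <- 1e-10 * max(sum(y^2), 1)
    if (rss_full > tol) {
      F <- (ss / df) / (rss_full / df_res)
      p <- stats::pf(F, df, df_res, lower.tail = FALSE)
    } else if (ss <= tol) { F <- 0; p <- 1 } else { F <- Inf; p <- 0 }
    c(F = F, p = p, df = df)
  })
  names(eff) <- names(terms)
  eff
}

# Type III F tests with sum-to-zero contrasts on the 2 x 3 factorial
type3_anova <- function(data, outcome) {
  fml <- stats::as.formula(paste("`", outcome, "` ~ cana * group", sep = ""))
  m <- stats::lm(fml, data = data,
                 contrasts = list(cana = "contr.sum", group = "contr.sum"))
  eff <- tryCatch({
    a <- car::Anova(m, type = 3)
    rn <- rownames(a)
    pick <- function(term) {
      i <- match(term, rn)
      c(F = a[i, "F value"], p = a[i, "Pr(>F)"], df = a[i, "Df"])
    }
    list(cana = pick("cana"), group = pick("group"),
         interaction = pick("cana:group"))
  }, error = function(e) type3_manual(data, outcome))
  list(model = m, effects = eff)
}

#' Two-way factorial ANOVA (parametric branch)
#'
#' Least-squares fit of the canagliflozin x glucose-group factorial with
#' interaction; Type III sums of squares with sum-to-zero contrasts (safe
#' under mild unbalance), as produced by the commercial software the study
#' design mirrors.
#'
#' @param table cohort data frame (see [simulate_cohort_table()]).
#' @param outcome name of the outcome column.
#' @return object of class `factorial_fit`: per-effect F and p
#'   (`cana`, `group`, `interaction`), `residuals`, `fitted`, `cell_means`,
#'   `method_used = "parametric"`.
#' @export
fit_two_way_anova <- function(table, outcome) {
  check_cohort(table, outcome)
  ft <- type3_anova(table, outcome)
  out <- list(effects = ft$effects,
              p_values = vapply(ft$effects, function(e) unname(e["p"]), 0),
              residuals = unname(residuals(ft$model)),
              fitted = unname(fitted(ft$model)),
              cell_means = tapply(table[[outcome]],
                                  list(table$cana, table$group), mean),
              method_used = "parametric", outcome = outcome, table = table)
  class(out) <- "factorial_fit"
  out
}

#' @export
print.factorial_fit <- function(x, ...) {
  cat(sprintf("<factorial_fit> %s ANOVA of %s\n", x$method_used, x$outcome))
  for (e in names(x$effects))
    cat(sprintf("  %-12s F = %8.3f  p = %.4g\n", e,
                x$effects[[e]]["F"], x$effects[[e]]["p"]))
  invisible(x)
}

#' Residual diagnostics for the parametric branch
#'
#' Anderson-Darling normality test on the residuals and Spearman rank
#' correlation of |residual| versus fitted value (heteroscedasticity);
#' the parametric model is accepted when both are non-significant.
#'
#' @param fit a parametric [fit_two_way_anova()] result.
#' @param alpha diagnostic significance level.
#' @return list: `parametric_ok`, `ad_p`, `spearman_p`, `flags`.
#' @export
diagnose_residuals <- function(fit, alpha = 0.05) {
  stopifnot(inherits(fit, "factorial_fit"), fit$method_used == "parametric")
  r <- fit$residuals
  flags <- character()
  if (length(r) < 8L) {
    warning("fewer than 8 residuals: diagnostics unreliable")
    flags <- c(flags, "few_residuals")
  }
  ad <- nortest::ad.test(r)
  sp <- suppressWarnings(cor.test(abs(r), fit$fitted, method = "spearman",
                                  exact = FALSE))
  list(parametric_ok = ad$p.value > alpha && sp$p.value > alpha,
       ad_p = unname(ad$p.value), spearman_p = unname(sp$p.value),
       alpha = alpha, flags = flags)
}

# unweighted cell-mean decomposition of the 2 x 3 design
cell_decomposition <- function(table, outcome) {
  cm <- tapply(table[[outcome]], list(table$cana, table$group), mean)
  mu <- mean(cm)
  a <- rowMeans(cm) - mu                 # cana main effect
  b <- colMeans(cm) - mu                 # group main effect
  ab <- sweep(sweep(cm, 1, rowMeans(cm)), 2, colMeans(cm)) + mu   # interaction
  list(cm = cm, mu = mu, a = a, b = b, ab = ab)
}

#' Aligned-rank-transform factorial ANOVA
#'
#' Non-parametric factorial procedure: for each effect, the response is
#' aligned by stripping (via the unweighted cell-mean decomposition) every
#' estimated effect except the one under test, the aligned values are ranked
#' (mid-ranks for ties), the full factorial ANOVA is run on the ranks, and
#' only the effect under test is read off.  Three aligned fits are run in
#' total.  The published correctness check of the construction — on each
#' aligned (pre-ranking) response the effects *not* under test have F of
#' essentially zero — is exposed via `alignment_check`.
#'
#' @inheritParams fit_two_way_anova
#' @return a `factorial_fit` with `method_used = "ART"` and, per effect, the
#'   rank-ANOVA F and p; `alignment_check` holds the off-test F statistics.
#' @export
art_anova <- function(table, outcome) {
  check_cohort(table, outcome)
  y <- table[[outcome]]
  if (length(unique(y)) == 1L) stop("degenerate ranks: all outcomes tied")
  dec <- cell_decomposition(table, outcome)
  ic <- as.integer(table$cana)
  ig <- as.integer(table$group)
  resid <- y - dec$cm[cbind(ic, ig)]
  aligned <- list(
    cana = resid + dec$a[ic],
    group = resid + dec$b[ig],
    interaction = resid + dec$ab[cbind(ic, ig)])
  effects <- list()
  align_chk <- list()
  tmp <- table
  for (eff in names(aligned)) {
    tmp$.art_rank <- rank(aligned[[eff]])
    ft <- type3_anova(tmp, ".art_rank")
    effects[[eff]] <- ft$effects[[eff]]
    # published correctness check: on the *aligned* (pre-ranking) response
    # the effects not under test must have F ~ 0
    tmp$.art_aligned <- aligned[[eff]]
    chk <- type3_manual(tmp, ".art_aligned")
    align_chk[[eff]] <- vapply(chk[setdiff(names(chk), eff)],
                               function(e) unname(e["F"]), 0)
  }
  out <- list(effects = effects,
              p_values = vapply(effects, function(e) unname(e["p"]), 0),
              residuals = unname(resid), fitted = y - resid,
              cell_means = dec$cm, alignment_check = align_chk,
              method_used = "ART", outcome = outcome, table = table)
  class(out) <- "factorial_fit"
  out
}

#' Holm-Sidak step-down adjustment
#'
#' For raw p-values `p_(1) <= ... <= p_(m)`, the adjusted value of the i-th
#' smallest is `1 - (1 - p_(i))^(m - i + 1)`, enforced monotone
#' non-decreasing in rank and capped at 1.
#'
#' @param p raw p-values.
#' @return adjusted p-values in the original order.
#' @export
holm_sidak_adjust <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- 1 - (1 - p[o])^(m - seq_len(m) + 1)
  adj <- pmin(cummax(adj), 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# Dunn's z statistic for one pair on joint ranks with mid-rank tie correction
dunn_pair <- function(r, g, a, b) {
  n <- length(r)
  ties <- table(r)
  tie_corr <- sum(ties^3 - ties) / (12 * (n - 1))
  va <- (n * (n + 1) / 12 - tie_corr)
  na <- sum(g == a); nb <- sum(g == b)
  z <- (mean(r[g == a]) - mean(r[g == b])) / sqrt(va * (1 / na + 1 / nb))
  c(z = z, p = 2 * pnorm(-abs(z)))
}

#' Family-structured post-hoc comparisons
#'
#' Builds the study's three pre-declared comparison families: the three
#' glucose-group pairs within each canagliflozin arm (two families) and the
#' No-Cana vs Cana contrast within each glucose group (one family).  Within
#' each family, if every involved group passes Shapiro-Wilk normality and
#' the family passes Brown-Forsythe variance homogeneity, pairwise pooled-SD
#' t tests are adjusted by Holm-Sidak step-down; otherwise Dunn's joint-rank
#' z tests are used with the same step-down family size.  Groups with n < 3
#' force the non-parametric branch (Shapiro-Wilk is undefined).
#'
#' @param table cohort data frame.
#' @param outcome outcome column name.
#' @param alpha family-wise significance level (reported, not used to prune).
#' @param diag_alpha significance level of the Shapiro-Wilk / Brown-Forsythe
#'   gates.
#' @return list of `posthoc_family` lists: `family`, `test_used`,
#'   `comparisons` (data frame with levels, estimates, raw and adjusted p).
#' @export
posthoc_families <- function(table, outcome, alpha = 0.05,
                             diag_alpha = 0.05) {
  y <- table[[outcome]]
  fam_specs <- list(
    list(id = "group_within_NoCana", split = "cana", keep = "NoCana",
         factor = "group"),
    list(id = "group_within_Cana", split = "cana", keep = "Cana",
         factor = "group"),
    list(id = "cana_within_group", split = NULL, factor = "cana"))
  out <- list()
  for (fs in fam_specs) {
    if (!is.null(fs$split)) {
      sel <- table[[fs$split]] == fs$keep
      sub <- table[sel, , drop = FALSE]
      g <- droplevels(sub[[fs$factor]])
      ys <- sub[[outcome]]
      lv <- levels(g)
      pairs <- utils::combn(lv, 2, simplify = FALSE)
      groups <- lapply(lv, function(l) ys[g == l])
      names(groups) <- lv
      para <- posthoc_parametric_ok(groups, diag_alpha)
      comp <- lapply(pairs, function(pr) {
        if (para) {
          tt <- t.test(groups[[pr[1]]], groups[[pr[2]]], var.equal = TRUE)
          c(p = unname(tt$p.value), stat = unname(tt$statistic))
        } else {
          r <- rank(ys)
          dp <- dunn_pair(r, g, pr[1], pr[2])
          c(p = unname(dp["p"]), stat = unname(dp["z"]))
        }
      })
      cmp <- data.frame(
        level_a = vapply(pairs, `[`, "", 1),
        level_b = vapply(pairs, `[`, "", 2),
        statistic = vapply(comp, `[[`, 0, "stat"),
        p_raw = vapply(comp, `[[`, 0, "p"))
      cmp$p_adj <- holm_sidak_adjust(cmp$p_raw)
      out[[fs$id]] <- list(family = fs$id,
                           test_used = if (para) "holm_sidak_t" else "dunn",
                           family_alpha = alpha, comparisons = cmp)
    } else {
      # one family of three No-Cana vs Cana contrasts, one per glucose group
      lv <- levels(table$group)
      groups <- list()
      for (gl in lv) for (cl in levels(table$cana))
        groups[[paste(gl, cl, sep = ":")]] <-
          y[table$group == gl & table$cana == cl]
      para <- posthoc_parametric_ok(groups, diag_alpha)
      comp <- lapply(lv, function(gl) {
        ya <- groups[[paste(gl, "NoCana", sep = ":")]]
        yb <- groups[[paste(gl, "Cana", sep = ":")]]
        if (para) {
          tt <- t.test(ya, yb, var.equal = TRUE)
          c(p = unname(tt$p.value), stat = unname(tt$statistic))
        } else {
          sel <- table$group == gl
          r <- rank(y[sel])
          dp <- dunn_pair(r, droplevels(table$cana[sel]), "NoCana", "Cana")
          c(p = unname(dp["p"]), stat = unname(dp["z"]))
        }
      })
      cmp <- data.frame(
        level_a = paste(lv, "NoCana", sep = ":"),
        level_b = paste(lv, "Cana", sep = ":"),
        statistic = vapply(comp, `[[`, 0, "stat"),
        p_raw = vapply(comp, `[[`, 0, "p"))
      cmp$p_adj <- holm_sidak_adjust(cmp$p_raw)
      out[[fs$id]] <- list(family = fs$id,
                           test_used = if (para) "holm_sidak_t" else "dunn",
                           family_alpha = alpha, comparisons = cmp)
    }
  }
  out
}

# Shapiro-Wilk on every group + Brown-Forsythe (median-centered Levene)
# across groups; TRUE -> parametric pairwise tests
posthoc_parametric_ok <- function(groups, diag_alpha) {
  ns <- vapply(groups, length, 0L)
  if (any(ns < 3L)) {
    warning("group with n < 3: Shapiro-Wilk impossible, forcing Dunn")
    return(FALSE)
  }
  sw <- vapply(groups, function(g) {
    if (sd(g) == 0) return(0)          # degenerate: clearly non-normal
    shapiro.test(g)$p.value
  }, 0)
  yy <- unlist(groups, use.names = FALSE)
  gg <- factor(rep(names(groups), ns))
  bf <- car::leveneTest(yy ~ gg, center = median)[1, "Pr(>F)"]
  all(sw > diag_alpha) && bf > diag_alpha
}

#' Run the full statistical decision tree for one outcome
#'
#' Parametric two-way ANOVA, residual diagnostics, aligned-rank-transform
#' fallback when the diagnostics fail, then family-structured post-hoc
#' comparisons: the two within-arm glucose-group families are emitted when
#' the glucose-group or interaction effect is significant, the cross-arm
#' canagliflozin family when the canagliflozin or interaction effect is
#' significant.  Every branch taken is recorded.
#'
#' @inheritParams fit_two_way_anova
#' @param alpha effect significance level gating the post-hoc families.
#' @return list of class `decision_tree_report`: `fit` (the fit used),
#'   `parametric_fit`, `diagnostics`, `branch`, `families`, `gates`.
#' @export
run_decision_tree <- function(table, outcome, alpha = 0.05) {
  pfit <- fit_two_way_anova(table, outcome)
  diag <- diagnose_residuals(pfit, alpha = alpha)
  if (diag$parametric_ok) {
    fit <- pfit
    branch <- "parametric"
  } else {
    fit <- art_anova(table, outcome)
    branch <- "ART"
  }
  p <- fit$p_values
  gate_group <- p["group"] < alpha || p["interaction"] < alpha
  gate_cana <- p["cana"] < alpha || p["interaction"] < alpha
  families <- list()
  if (gate_group || gate_cana) {
    all_fam <- posthoc_families(table, outcome, alpha = alpha)
    if (gate_group)
      families <- c(families, all_fam[c("group_within_NoCana",
                                        "group_within_Cana")])
    if (gate_cana)
      families <- c(families, all_fam["cana_within_group"])
  }
  out <- list(fit = fit, parametric_fit = pfit, diagnostics = diag,
              branch = branch, families = families,
              gates = c(group = unname(gate_group), cana = unname(gate_cana)),
              posthoc_test = if (length(families))
                vapply(families, `[[`, "", "test_used") else character())
  class(out) <- "decision_tree_report"
  out
}

#' @export
print.decision_tree_report <- function(x, ...) {
  cat(sprintf("<decision_tree_report> branch = %s\n", x$branch))
  print(x$fit)
  if (length(x$families))
    for (f in x$families)
      cat(sprintf("  family %s: %s, adjusted p = %s\n", f$family, f$test_used,
                  paste(signif(f$comparisons$p_adj, 3), collapse = ", ")))
  else cat("  no post-hoc families (gates not met)\n")
  invisible(x)
}
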