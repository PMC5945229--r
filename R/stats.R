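# Group comparisons used throughout the pipeline: two-sample t and
# Mann-Whitney U (exact by full enumeration at small combined n), one-way
# ANOVA with Tukey HSD, Kruskal-Wallis with Dunn's post hoc, and the
# significance star convention.

#' Exact Mann-Whitney U by full enumeration
#'
#' Enumerates all `choose(nA + nB, nA)` assignments of the pooled midranks to
#' group A, giving the exact conditional null distribution of U (valid with
#' ties). The two-sided p-value is `min(1, 2 * min(P(U <= u), P(U >= u)))`.
#'
#' @param a,b Numeric samples.
#' @return List with `U` (the smaller of U_A and U_B), `u_a`, and `p`.
#' @export
mann_whitney_exact <- function(a, b) {
  m <- length(a); n <- length(b)
  stopifnot(m >= 1, n >= 1)
  r <- rank(c(a, b))
  u_a <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  cmb <- utils::combn(m + n, m)
  ua_all <- colSums(matrix(r[cmb], nrow = m)) - m * (m + 1) / 2
  p <- min(1, 2 * min(mean(ua_all <= u_a), mean(ua_all >= u_a)))
  list(U = min(u_a, m * n - u_a), u_a = u_a, p = p)
}

# Normal approximation with midranks and tie correction (no continuity
# correction; the exact path covers small samples).
.mann_whitney_approx <- function(a, b) {
  m <- length(a); n <- length(b); N <- m + n
  r <- rank(c(a, b))
  u_a <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  ties <- table(r)
  sigma2 <- m * n / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  if (sigma2 <= 0) return(list(U = min(u_a, m * n - u_a), u_a = u_a, p = 1))
  z <- (u_a - m * n / 2) / sqrt(sigma2)
  list(U = min(u_a, m * n - u_a), u_a = u_a,
       p = min(1, 2 * stats::pnorm(-abs(z))))
}

.stars <- function(p) ifelse(p < 0.001, "***",
                      ifelse(p < 0.01, "**",
                      ifelse(p < 0.05, "*", "ns")))

#' Significance stars
#'
#' The figure-legend convention: `ns` for p > 0.05, `*` for p < 0.05, `**`
#' for p < 0.01, `***` for p < 0.001; boundary values map to the
#' less-significant label.
#'
#' @param p P-values in `[0, 1]`.
#' @return Character vector of labels.
#' @export
star_code <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  .stars(p)
}

.comparison_result <- function(test, statistic, p, sizes, pairwise = NULL) {
  structure(list(test = test, statistic = statistic, p = p,
                 group_sizes = sizes, pairwise = pairwise,
                 stars = .stars(p)),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g (%s); n = %s\n", x$test,
              x$statistic, x$p, x$stars,
              paste(x$group_sizes, collapse = ", ")))
  if (!is.null(x$pairwise)) {
    cat("pairwise comparisons:\n")
    print(x$pairwise, row.names = FALSE)
  }
  invisible(x)
}

#' Compare two groups
#'
#' Parametric mode is the two-sided two-sample Student t test (pooled
#' variance by default, Welch optional); nonparametric mode is the two-sided
#' Mann-Whitney U test, exact by full enumeration when the combined sample
#' size is at most `exact_max` (default 20), otherwise the normal
#' approximation with midranks and tie correction.
#'
#' @param a,b Numeric samples, each of size >= 2.
#' @param mode `"parametric"` or `"nonparametric"`.
#' @param welch Use the Welch t test instead of pooled variance.
#' @param exact_max Largest combined n for the enumerated exact U test.
#' @return A `comparison_result`.
#' @export
compare_two <- function(a, b, mode = c("parametric", "nonparametric"),
                        welch = FALSE, exact_max = 20L) {
  mode <- match.arg(mode)
  stopifnot(length(a) >= 2, length(b) >= 2)
  if (mode == "parametric") {
    if (stats::sd(a) == 0 && stats::sd(b) == 0) {
      if (mean(a) == mean(b))
        return(.comparison_result("Student t test", 0, 1,
                                  c(length(a), length(b))))
      stop("both groups have zero variance: t test undefined", call. = FALSE)
    }
    tt <- stats::t.test(a, b, var.equal = !welch)
    .comparison_result(if (welch) "Welch t test" else "Student t test",
                       unname(tt$statistic), tt$p.value,
                       c(length(a), length(b)))
  } else {
    res <- if (length(a) + length(b) <= exact_max) mann_whitney_exact(a, b)
           else .mann_whitney_approx(a, b)
    .comparison_result("Mann-Whitney U test", res$U, res$p,
                       c(length(a), length(b)))
  }
}

#' Dunn's post hoc test after Kruskal-Wallis
#'
#' Pairwise z statistics from the pooled midranks,
#' `z = (Rbar_i - Rbar_j) / sqrt((N(N+1)/12 - T) (1/n_i + 1/n_j))` with tie
#' term `T = sum(t^3 - t) / (12 (N - 1))`, two-sided normal p-values, and a
#' multiplicity adjustment over all pairs (Bonferroni by default, the
#' Prism-compatible family).
#'
#' @param values Numeric vector of observations.
#' @param groups Grouping factor.
#' @param adjust `"bonferroni"`, `"holm"`, `"sidak"` or `"none"`.
#' @return Data.frame `group1`, `group2`, `z`, `p`, `p_adj`, `stars`.
#' @export
dunn_test <- function(values, groups,
                      adjust = c("bonferroni", "holm", "sidak", "none")) {
  adjust <- match.arg(adjust)
  groups <- factor(groups)
  N <- length(values)
  r <- rank(values)
  rbar <- tapply(r, groups, mean)
  ni <- tapply(r, groups, length)
  ties <- table(r)
  tiecorr <- sum(ties^3 - ties) / (12 * (N - 1))
  g <- levels(groups)
  pairs <- utils::combn(g, 2)
  z <- p <- numeric(ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1, k]; j <- pairs[2, k]
    se <- sqrt((N * (N + 1) / 12 - tiecorr) * (1 / ni[[i]] + 1 / ni[[j]]))
    z[k] <- if (se > 0) (rbar[[i]] - rbar[[j]]) / se else 0
    p[k] <- 2 * stats::pnorm(-abs(z[k]))
  }
  p_adj <- switch(adjust,
                  none = p,
                  sidak = 1 - (1 - p)^ncol(pairs),
                  stats::p.adjust(p, method = adjust))
  p_adj <- pmin(p_adj, 1)
  data.frame(group1 = pairs[1, ], group2 = pairs[2, ], z = z, p = p,
             p_adj = p_adj, stars = .stars(p_adj),
             stringsAsFactors = FALSE)
}

#' Compare three or more groups
#'
#' Parametric mode: one-way ANOVA omnibus with Tukey HSD pairwise
#' comparisons (unadjusted pairwise p-values from pooled-SD t tests are
#' reported alongside). Nonparametric mode: Kruskal-Wallis omnibus with
#' Dunn's pairwise test and multiplicity adjustment.
#'
#' With exactly two groups the parametric omnibus F equals the square of the
#' pooled-variance t statistic.
#'
#' @param values Numeric vector of observations.
#' @param groups Grouping factor (>= 2 levels present; every group n >= 2;
#'   >= 3 groups is the intended use, 2 are accepted for the F = t^2
#'   identity).
#' @param mode `"parametric"` or `"nonparametric"`.
#' @param adjust Dunn adjustment, see [dunn_test()].
#' @return A `comparison_result` whose `pairwise` element is the adjusted
#'   pairwise table.
#' @export
compare_many <- function(values, groups,
                         mode = c("parametric", "nonparametric"),
                         adjust = "bonferroni") {
  mode <- match.arg(mode)
  groups <- droplevels(factor(groups))
  stopifnot(length(values) == length(groups))
  ni <- table(groups)
  if (length(ni) < 2L) stop("need at least two groups", call. = FALSE)
  if (any(ni < 2L))
    stop(sprintf("every group needs n >= 2 (smallest has %d)", min(ni)),
         call. = FALSE)
  if (stats::var(values) == 0) {
    # all observations identical: every statistic is null by definition
    # (avoids 0/0 mean squares in aov)
    pairs <- utils::combn(levels(groups), 2)
    pw <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                     p = 1, p_adj = 1, stars = "ns",
                     stringsAsFactors = FALSE)
    return(.comparison_result(
      if (mode == "parametric") "one-way ANOVA + Tukey HSD"
      else "Kruskal-Wallis + Dunn", 0, 1, as.integer(ni), pw))
  }
  if (mode == "parametric") {
    fit <- stats::aov(values ~ groups)
    sm <- summary(fit)[[1]]
    f <- sm[["F value"]][1]
    p <- sm[["Pr(>F)"]][1]
    if (is.na(f)) { f <- 0; p <- 1 }  # zero residual + zero between variance
    tk <- stats::TukeyHSD(fit)$groups
    cmp <- do.call(rbind, strsplit(rownames(tk), "-", fixed = TRUE))
    punadj <- tryCatch(
      stats::pairwise.t.test(values, groups,
                             p.adjust.method = "none")$p.value,
      error = function(e) NULL)
    pw <- data.frame(group1 = cmp[, 2], group2 = cmp[, 1],
                     diff = -tk[, "diff"], p_adj = tk[, "p adj"],
                     stars = .stars(tk[, "p adj"]),
                     row.names = NULL, stringsAsFactors = FALSE)
    if (!is.null(punadj)) {
      look <- function(i, j) {
        if (i %in% rownames(punadj) && j %in% colnames(punadj))
          punadj[i, j] else NA_real_
      }
      pw$p <- vapply(seq_len(nrow(pw)), function(k) {
        v <- look(pw$group2[k], pw$group1[k])
        if (is.na(v)) look(pw$group1[k], pw$group2[k]) else v
      }, numeric(1))
    }
    .comparison_result("one-way ANOVA + Tukey HSD", f, p, as.integer(ni), pw)
  } else {
    kw <- stats::kruskal.test(values, groups)
    h <- unname(kw$statistic); p <- kw$p.value
    if (is.na(h)) { h <- 0; p <- 1 }  # all observations tied
    pw <- dunn_test(values, groups, adjust = adjust)
    .comparison_result("Kruskal-Wallis + Dunn", h, p, as.integer(ni), pw)
  }
}
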