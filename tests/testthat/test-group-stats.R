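test_that("one-way ANOVA matches hand-computed sums of squares", {
  # {1,2,3} vs {4,5,6}: SSB = 13.5, MSW = 1 -> F = 13.5, df = (1, 4)
  res <- one_way_anova(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
  expect_equal(res$f_value, 13.5)
  expect_equal(res$df_between, 1)
  expect_equal(res$df_within, 4)
  # identical groups: no between-group variance
  res0 <- one_way_anova(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_equal(res0$f_value, 0)
  expect_error(one_way_anova(c(1, 2, 3), c("a", "a", "b")),
               "at least 2")
})

test_that("two-group F equals the squared pooled t statistic", {
  set.seed(5)
  x <- rnorm(8, 0); y <- rnorm(8, 1)
  tt <- t.test(x, y, var.equal = TRUE)
  res <- one_way_anova(c(x, y), rep(c("x", "y"), each = 8))
  expect_equal(res$f_value, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(res$p_value, tt$p.value, tolerance = 1e-10)
})

test_that("F is invariant to constant shifts and group relabeling", {
  set.seed(6)
  g <- rep(letters[1:4], each = 5)
  v <- rnorm(20, as.integer(factor(g)))
  f0 <- one_way_anova(v, g)$f_value
  expect_equal(one_way_anova(v + 100, g)$f_value, f0, tolerance = 1e-10)
  relabel <- c(a = "w", b = "x", c = "y", d = "z")[g]
  expect_equal(one_way_anova(v, relabel)$f_value, f0, tolerance = 1e-12)
})

test_that("Tukey HSD reduces to the plain comparison for two groups", {
  set.seed(7)
  x <- rnorm(6); y <- rnorm(6, 2)
  pw <- tukey_hsd(c(x, y), rep(c("x", "y"), each = 6))
  tt <- t.test(x, y, var.equal = TRUE)
  expect_equal(nrow(pw), 1)
  expect_lt(abs(pw$p_adj - tt$p.value), 1e-8)
})

test_that("identical groups yield adjusted p of 1", {
  v <- rep(c(1, 2, 3, 4), times = 3)
  g <- rep(c("a", "b", "c"), each = 4)
  pw <- tukey_hsd(v, g)
  expect_true(all(pw$p_adj > 1 - 1e-8))
})

test_that("a single shifted group drives exactly its own pairs", {
  set.seed(42)
  g <- rep(paste0("t", 1:7), each = 6)
  v <- rnorm(42, 0, 1)
  v[g == "t7"] <- v[g == "t7"] + 8
  pw <- tukey_hsd(v, g)
  sig <- pw$p_adj < 0.05
  involves_t7 <- pw$group_a == "t7" | pw$group_b == "t7"
  expect_true(all(sig == involves_t7))
})

test_that("compact letters cover the boundary patterns", {
  mk <- function(groups, p) {
    cmb <- t(utils::combn(groups, 2))
    data.frame(group_a = cmb[, 2], group_b = cmb[, 1], p_adj = p)
  }
  # no significant pairs: one shared letter
  all_ns <- compact_letters(mk(c("a", "b", "c"), 0.9))
  expect_true(all(all_ns == all_ns[1]))
  expect_equal(unname(all_ns[1]), "a")
  # all pairs significant: all letters distinct
  all_sig <- compact_letters(mk(c("a", "b", "c"), 0.001))
  expect_equal(length(unique(all_sig)), 3)
  # chain a != c, a = b, b = c
  pw <- data.frame(group_a = c("b", "c", "c"),
                   group_b = c("a", "a", "b"),
                   p_adj = c(0.5, 0.01, 0.6))
  lt <- compact_letters(pw)
  expect_equal(unname(lt["a"]), "a")
  expect_equal(unname(lt["b"]), "ab")
  expect_equal(unname(lt["c"]), "b")
  expect_error(compact_letters(pw[1:2, ]), "incomplete")
})

test_that("letter displays are minimal and consistent on random patterns", {
  set.seed(99)
  for (i in 1:20) {
    k <- sample(3:6, 1)
    groups <- letters[1:k]
    cmb <- t(utils::combn(groups, 2))
    p <- ifelse(runif(nrow(cmb)) < 0.4, 0.01, 0.5)
    pw <- data.frame(group_a = cmb[, 2], group_b = cmb[, 1], p_adj = p)
    lt <- compact_letters(pw, alpha = 0.05)
    expect_true(letters_consistent(lt, pw, 0.05))
    n_used <- length(unique(unlist(strsplit(paste(lt, collapse = ""),
                                            ""))))
    sig_pairs <- pw[pw$p_adj < 0.05, ]
    expect_equal(n_used,
                 min_letters_by_enumeration(groups, sig_pairs))
  }
})

test_that("transform selection prefers the scale whose residuals look normal", {
  set.seed(123)
  g <- rep(letters[1:4], each = 12)
  gauss <- rnorm(48, mean = 10 + as.integer(factor(g)))
  expect_equal(select_transform(gauss, g)$transform, "identity")
  lognorm <- exp(rnorm(48, mean = as.integer(factor(g)), sd = 1.5))
  sel <- select_transform(lognorm, g)
  expect_true(sel$transform %in% c("log", "boxcox"))
  # the winner's residual normality score beats the identity's,
  # recomputed independently
  w_of <- function(vals) {
    shapiro.test(residuals(aov(vals ~ factor(g))))$statistic
  }
  expect_gt(unname(w_of(sel$values)), unname(w_of(lognorm)))
  expect_warning(sel0 <- select_transform(rep(5, 48), g), "constant")
  expect_equal(sel0$transform, "identity")
})

test_that("negative values exclude log-family candidates rather than shifting", {
  set.seed(12)
  g <- rep(c("a", "b"), each = 10)
  v <- rnorm(20, 0, 1)  # straddles zero
  sel <- select_transform(v, g)
  expect_false(any(c("log", "boxcox", "sqrt") %in% names(sel$scores)))
})

test_that("fe_anova bundles transform, ANOVA, Tukey and letters coherently", {
  set.seed(31)
  g <- rep(paste0("t", 1:4), each = 6)
  v <- rnorm(24, c(0, 0, 0, 5)[as.integer(factor(g))])
  res <- fe_anova(v, g, alpha = 0.05)
  expect_equal(res$df_between, 3)
  expect_equal(res$df_within, 20)
  expect_true(letters_consistent(res$group_letters, res$pairwise, 0.05))
  expect_true(is.finite(res$untransformed$f_value))
})

test_that("percent contrasts use the reference magnitude", {
  expect_equal(treatment_contrast_pct(58, 1), 5700)
  expect_equal(treatment_contrast_pct(7, 7), 0)
  expect_equal(treatment_contrast_pct(2.95, 1.0), 195)
  expect_error(treatment_contrast_pct(3, 0), "zero")
})
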