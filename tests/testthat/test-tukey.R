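make_groups <- function(means, n = 8, sd = 1, seed = 1) {
  set.seed(seed)
  tibble::tibble(
    g = rep(sprintf("g%d", seq_along(means)), each = n),
    y = stats::rnorm(n * length(means), rep(means, each = n), sd)
  )
}

test_that("identical groups share a single letter", {
  df <- make_groups(c(0, 0, 0), seed = 2)
  df$y <- rep(df$y[1:8], 3) # literally identical samples
  fit <- anova_tukey(df, y, g)
  expect_equal(fit$f_statistic, 0, tolerance = 1e-12)
  expect_equal(unique(fit$groups$letter), "a")
  expect_false(any(fit$pairs$significant))
})

test_that("two-group Tukey collapses to the pooled t-test", {
  df <- make_groups(c(0, 1), n = 10, seed = 3)
  fit <- anova_tukey(df, y, g)
  tt <- stats::t.test(y ~ g, data = df, var.equal = TRUE)
  expect_equal(fit$pairs$q, sqrt(2) * abs(tt$statistic), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(fit$pairs$p_adj, tt$p.value, tolerance = 1e-9)
  # and the ANOVA F is t squared
  expect_equal(fit$f_statistic, unname(tt$statistic)^2, tolerance = 1e-9)
})

test_that("q statistics match a from-first-principles oracle", {
  set.seed(4)
  ns_in <- c(g1 = 6, g2 = 9, g3 = 7)
  mus <- c(g1 = 0, g2 = 0.8, g3 = 2.5)
  df <- tibble::tibble(
    g = rep(names(ns_in), times = ns_in),
    y = stats::rnorm(sum(ns_in), rep(mus, times = ns_in))
  )
  fit <- anova_tukey(df, y, g)
  # oracle: explicit sums
  sp <- split(df$y, df$g)
  k <- 3
  mse_o <- sum(vapply(sp, function(v) sum((v - mean(v))^2), numeric(1))) /
    (nrow(df) - k)
  means <- vapply(sp, mean, numeric(1))
  ns <- lengths(sp)
  combs <- utils::combn(3, 2)
  q_o <- vapply(seq_len(ncol(combs)), function(i) {
    a <- combs[1, i]; b <- combs[2, i]
    nh <- 2 / (1 / ns[a] + 1 / ns[b])
    abs(means[a] - means[b]) / sqrt(mse_o / nh)
  }, numeric(1))
  expect_equal(fit$pairs$q, q_o, tolerance = 1e-9)
  expect_equal(fit$mse, mse_o, tolerance = 1e-12)
})

test_that("adjusted p-values match a Monte-Carlo studentized-range oracle", {
  df <- make_groups(c(0, 0.9, 1.1), n = 8, seed = 5)
  fit <- anova_tukey(df, y, g)
  k <- 3
  df_err <- 21
  set.seed(99)
  nmc <- 2e5
  z <- matrix(stats::rnorm(nmc * k), ncol = k)
  s <- sqrt(stats::rchisq(nmc, df_err) / df_err)
  q_null <- (apply(z, 1, max) - apply(z, 1, min)) / s
  for (i in seq_len(nrow(fit$pairs))) {
    p_mc <- mean(q_null >= fit$pairs$q[i])
    expect_equal(fit$pairs$p_adj[i], p_mc, tolerance = 0.015)
  }
})

test_that("results agree with the stats::TukeyHSD reference", {
  df <- make_groups(c(0, 1.5, 1.6, 4), n = 6, seed = 6)
  fit <- anova_tukey(df, y, g)
  ref <- stats::TukeyHSD(stats::aov(y ~ g, data = df))$g
  # reference orders pairs differently; match on names
  key <- paste(fit$pairs$group_b, fit$pairs$group_a, sep = "-")
  expect_equal(fit$pairs$p_adj, unname(ref[key, "p adj"]), tolerance = 1e-6)
  expect_equal(-fit$pairs$diff, unname(ref[key, "diff"]), tolerance = 1e-9)
})

test_that("group order does not change the inference or the partition", {
  df <- make_groups(c(0, 1.5, 4), n = 7, seed = 7)
  fit1 <- anova_tukey(df, y, g)
  df2 <- df[rev(seq_len(nrow(df))), ]
  df2$g <- factor(df2$g, levels = c("g3", "g1", "g2"))
  fit2 <- anova_tukey(df2, y, g)
  expect_equal(fit1$f_statistic, fit2$f_statistic, tolerance = 1e-9)
  m1 <- fit1$pairs[order(fit1$pairs$group_a, fit1$pairs$group_b), ]
  m2 <- fit2$pairs
  m2[c("group_a", "group_b")] <- tibble::tibble(
    group_a = pmin(m2$group_a, m2$group_b),
    group_b = pmax(m2$group_a, m2$group_b)
  )
  m2 <- m2[order(m2$group_a, m2$group_b), ]
  expect_equal(m1$p_adj, m2$p_adj, tolerance = 1e-9)
  # same partition into letter classes up to renaming
  part <- function(fit) {
    sp <- split(fit$groups$group, fit$groups$letter)
    unname(lapply(sp[order(vapply(sp, paste, character(1),
                                  collapse = ","))], sort))
  }
  expect_equal(part(fit1), part(fit2))
})

test_that("letters are sound: sharing a letter iff not significant", {
  for (seed in 1:10) {
    df <- make_groups(stats::runif(4, 0, 3), n = 6, seed = seed)
    fit <- anova_tukey(df, y, g, alpha = 0.05)
    lt <- fit$groups$letter[match(fit$groups$group, fit$groups$group)]
    names(lt) <- fit$groups$group
    shares <- function(a, b) {
      any(strsplit(lt[[a]], "")[[1]] %in% strsplit(lt[[b]], "")[[1]])
    }
    for (i in seq_len(nrow(fit$pairs))) {
      expect_equal(shares(fit$pairs$group_a[i], fit$pairs$group_b[i]),
                   !fit$pairs$significant[i],
                   label = sprintf("seed %d pair %d letter consistency",
                                   seed, i))
    }
  }
})

test_that("zero within-group variance with distinct means warns and splits", {
  df <- tibble::tibble(g = rep(c("a", "b"), each = 3),
                       y = rep(c(1, 2), each = 3))
  expect_warning(fit <- anova_tukey(df, y, g), "zero within-group variance")
  expect_true(all(fit$pairs$significant))
  expect_equal(fit$groups$letter, c("b", "a")) # ordered by mean, distinct
})

test_that("the ANOVA maintains its nominal type-I error under the null", {
  set.seed(2024)
  n_sim <- 2000
  rejections <- 0L
  for (i in seq_len(n_sim)) {
    samples <- split(stats::rnorm(30), rep(1:3, each = 10))
    core <- redoxroot:::anova_tukey_core(samples, alpha = 0.05)
    if (core$p_f < 0.05) rejections <- rejections + 1L
  }
  expect_lt(abs(rejections / n_sim - 0.05), 0.015)
})
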