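# One-way ANOVA with Tukey HSD pairwise comparison and a compact letter
# display, the shared statistical backend of the growth, redox and
# cell-cycle comparisons.

# fast vector core (kept free of data-frame overhead so it can be called
# thousands of times in simulation studies)
anova_tukey_core <- function(samples, alpha) {
  k <- length(samples)
  ns <- lengths(samples)
  means <- vapply(samples, mean, numeric(1))
  n_tot <- sum(ns)
  df_err <- n_tot - k
  grand <- sum(ns * means) / n_tot
  ss_between <- sum(ns * (means - grand)^2)
  ss_within <- sum(vapply(samples, function(x) sum((x - mean(x))^2),
                          numeric(1)))
  mse <- ss_within / df_err
  ms_between <- ss_between / (k - 1)
  if (mse > 0) {
    f_stat <- ms_between / mse
    p_f <- stats::pf(f_stat, k - 1, df_err, lower.tail = FALSE)
  } else if (ss_between == 0) {
    f_stat <- 0
    p_f <- 1
  } else {
    f_stat <- Inf
    p_f <- 0
  }

  pairs <- utils::combn(k, 2)
  diff <- means[pairs[1, ]] - means[pairs[2, ]]
  # Tukey-Kramer: studentized range with the harmonic mean of the pair's
  # sample sizes
  n_h <- 2 / (1 / ns[pairs[1, ]] + 1 / ns[pairs[2, ]])
  if (mse > 0) {
    q <- abs(diff) / sqrt(mse / n_h)
    p_adj <- stats::ptukey(q, nmeans = k, df = df_err, lower.tail = FALSE)
  } else {
    q <- ifelse(diff == 0, 0, Inf)
    p_adj <- ifelse(diff == 0, 1, 0)
  }
  list(k = k, ns = ns, means = means, df_err = df_err, mse = mse,
       f_stat = f_stat, p_f = p_f,
       pair_i = pairs[1, ], pair_j = pairs[2, ],
       diff = diff, q = q, p_adj = p_adj,
       significant = p_adj <= alpha)
}

# insert-and-absorb compact letter display: start with one letter holding
# every group; for each significant pair split any letter containing both;
# absorb letters that became subsets.  Non-significant pairs always retain
# a shared letter; significant pairs never do.
cld_letters <- function(k, pair_i, pair_j, significant, order_by) {
  sets <- list(seq_len(k))
  for (p in which(significant)) {
    i <- pair_i[p]; j <- pair_j[p]
    res <- list()
    for (s in sets) {
      if (i %in% s && j %in% s) {
        res <- c(res, list(setdiff(s, i)), list(setdiff(s, j)))
      } else {
        res <- c(res, list(s))
      }
    }
    res <- Filter(length, res)
    keep <- rep(TRUE, length(res))
    for (a in seq_along(res)) {
      for (b in seq_along(res)) {
        if (a != b && keep[b] &&
            all(res[[a]] %in% res[[b]]) &&
            (length(res[[a]]) < length(res[[b]]) || a > b)) {
          keep[a] <- FALSE
          break
        }
      }
    }
    sets <- res[keep]
  }
  # order letters by the best (largest) member mean for conventional display
  set_rank <- vapply(sets, function(s) max(order_by[s]), numeric(1))
  sets <- sets[order(-set_rank)]
  labels <- vapply(seq_len(k), function(g) {
    paste0(letters[which(vapply(sets, function(s) g %in% s, logical(1)))],
           collapse = "")
  }, character(1))
  labels
}

#' One-way ANOVA with Tukey's HSD and a compact letter display
#'
#' Classical one-way ANOVA F test followed by all pairwise comparisons via
#' the studentized range distribution (Tukey-Kramer harmonic-n for
#' unbalanced groups) and letter assignment by insert-and-absorb: groups
#' sharing any letter are not significantly different at `alpha`.
#' With zero within-group variance and distinct means, all pairs are
#' reported significant with a warning (exact separation).
#'
#' @param data A data frame.
#' @param value,group Bare column names of the response and the grouping
#'   variable (>= 2 groups, each with n >= 2).
#' @param alpha Significance level (the study used 0.05 and 0.01).
#' @return An object of class `tukey_hsd`: `groups` (tibble with n, mean,
#'   letter), `pairs` (tibble with diff, q, p_adj, significant),
#'   `f_statistic`, `df`, `p_value`, `mse`, `alpha`.  `tidy()` returns the
#'   pairs, `glance()` the ANOVA row.
#' @examples
#' df <- data.frame(g = rep(c("a", "b", "c"), each = 5),
#'                  y = c(rnorm(5), rnorm(5, 2), rnorm(5, 2)))
#' anova_tukey(df, y, g, alpha = 0.05)
#' @export
anova_tukey <- function(data, value, group, alpha = 0.05) {
  stopifnot(is.data.frame(data), alpha > 0, alpha < 1)
  y <- rlang::eval_tidy(rlang::enquo(value), data)
  g <- rlang::eval_tidy(rlang::enquo(group), data)
  ok <- is.finite(y) & !is.na(g)
  y <- y[ok]
  g <- factor(g)[ok]
  samples <- split(y, g, drop = TRUE)
  if (length(samples) < 2) stop("need at least two groups", call. = FALSE)
  if (any(lengths(samples) < 2)) {
    stop("every group needs at least two observations", call. = FALSE)
  }
  core <- anova_tukey_core(samples, alpha)
  if (core$mse == 0 && any(core$diff != 0)) {
    warning("zero within-group variance with distinct means: ",
            "all unequal pairs reported significant")
  }
  gn <- names(samples)
  letters_ <- cld_letters(core$k, core$pair_i, core$pair_j,
                          core$significant, core$means)
  structure(list(
    groups = tibble::tibble(group = gn, n = as.integer(core$ns),
                            mean = unname(core$means),
                            letter = letters_),
    pairs = tibble::tibble(group_a = gn[core$pair_i],
                           group_b = gn[core$pair_j],
                           diff = unname(core$diff), q = unname(core$q),
                           p_adj = unname(core$p_adj),
                           significant = unname(core$significant)),
    f_statistic = core$f_stat,
    df = c(between = core$k - 1, error = core$df_err),
    p_value = core$p_f,
    mse = core$mse,
    alpha = alpha
  ), class = "tukey_hsd")
}

#' @export
print.tukey_hsd <- function(x, ...) {
  cat(sprintf("<tukey_hsd> F(%d, %d) = %.3f, p = %.3g (alpha = %g)\n",
              x$df[["between"]], x$df[["error"]], x$f_statistic, x$p_value,
              x$alpha))
  print(x$groups)
  invisible(x)
}

#' @export
tidy.tukey_hsd <- function(x, ...) x$pairs

#' @export
glance.tukey_hsd <- function(x, ...) {
  tibble::tibble(f_statistic = x$f_statistic,
                 df_between = x$df[["between"]],
                 df_error = x$df[["error"]],
                 p_value = x$p_value, mse = x$mse, alpha = x$alpha)
}

#' @export
autoplot.tukey_hsd <- function(object, ...) {
  g <- object$groups
  ggplot2::ggplot(g, ggplot2::aes(x = .data$group, y = .data$mean)) +
    ggplot2::geom_col(fill = "grey70") +
    ggplot2::geom_text(ggplot2::aes(label = .data$letter),
                       vjust = -0.4) +
    ggplot2::labs(x = NULL, y = "group mean") +
    ggplot2::theme_minimal()
}
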