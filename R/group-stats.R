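# Rank-based treatment comparison.
#
# The comparison scheme is: an omnibus test chosen by design (two related
# samples -> Wilcoxon signed ranks; two unrelated -> Mann-Whitney U; more
# than two related -> Friedman; more than two unrelated -> Kruskal-Wallis),
# pairwise contrasts with the design-appropriate two-sample test judged at
# the Bonferroni-adapted level alpha_B = alpha / k (k = number of contrasts
# in the family), and a compact letter display.
#
# Ties take mid-ranks with tie-corrected variances throughout. P-values are
# exact permutation probabilities (two-sided by symmetric deviation from the
# null centre; upper tail for the chi-square-type statistics) whenever the
# permutation space is no larger than `exact_limit`, else the large-sample
# approximation is used and flagged in the result.

.perm_cache <- new.env(parent = emptyenv())

cache_get_or <- function(key, compute) {
  if (!exists(key, envir = .perm_cache, inherits = FALSE)) {
    assign(key, compute(), envir = .perm_cache)
  }
  get(key, envir = .perm_cache, inherits = FALSE)
}

midranks <- function(x) rank(x, ties.method = "average")

tie_term <- function(r) {
  t <- table(r)
  sum(t^3 - t)
}

# two-sided permutation p for a statistic symmetric about `center`
two_sided_perm_p <- function(null_values, observed, center, eps = 1e-9) {
  mean(abs(null_values - center) >= abs(observed - center) - eps)
}

#' Mann-Whitney U test (exact permutation or tie-corrected normal)
#'
#' Two-sample rank test for unrelated groups. The statistic is
#' \eqn{U = R_1 - n_1(n_1+1)/2} with \eqn{R_1} the mid-rank sum of the first
#' sample. When `choose(n1+n2, n1) <= exact_limit` the two-sided p-value is
#' the exact permutation probability of a deviation from \eqn{n_1 n_2 / 2}
#' at least as large as observed; otherwise a tie-corrected normal
#' approximation (no continuity correction) is used.
#'
#' @param x,y numeric samples.
#' @param exact_limit largest permutation-space size enumerated exactly.
#' @return list with `name`, `statistic` (U), `p`, `exact` (logical),
#'   `degenerate` (all pooled values identical).
#' @export
mann_whitney_test <- function(x, y, exact_limit = 1e5) {
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  stopifnot(n1 >= 1, n2 >= 1)
  r <- midranks(c(x, y))
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  center <- n1 * n2 / 2
  if (length(unique(c(x, y))) == 1L) {
    return(list(name = "Mann-Whitney U", statistic = u_obs, p = 1,
                exact = TRUE, degenerate = TRUE))
  }
  if (choose(n, n1) <= exact_limit) {
    key <- paste0("mw|", n1, "|", paste(signif(sort(r), 12), collapse = ","))
    null_u <- cache_get_or(key, function() {
      idx <- utils::combn(n, n1)
      colSums(matrix(r[idx], nrow = n1)) - n1 * (n1 + 1) / 2
    })
    p <- two_sided_perm_p(null_u, u_obs, center)
    exact <- TRUE
  } else {
    v <- n1 * n2 / 12 * ((n + 1) - tie_term(r) / (n * (n - 1)))
    p <- 2 * stats::pnorm(-abs(u_obs - center) / sqrt(v))
    exact <- FALSE
  }
  list(name = "Mann-Whitney U", statistic = u_obs, p = min(p, 1),
       exact = exact, degenerate = FALSE)
}

#' Wilcoxon signed ranks test for related pairs
#'
#' Paired rank test. Zero differences are dropped; the statistic is the
#' mid-rank sum of positive differences. When `2^m <= exact_limit` (m =
#' non-zero differences) the two-sided p-value is the exact sign-flip
#' permutation probability; otherwise a tie-corrected normal approximation.
#'
#' @param x,y paired numeric samples of equal length.
#' @inheritParams mann_whitney_test
#' @return list as in [mann_whitney_test()] with statistic V.
#' @export
wilcoxon_signed_rank_test <- function(x, y, exact_limit = 1e5) {
  stopifnot(length(x) == length(y))
  d <- x - y
  d <- d[d != 0]
  m <- length(d)
  if (m == 0) {
    return(list(name = "Wilcoxon signed ranks", statistic = 0, p = 1,
                exact = TRUE, degenerate = TRUE))
  }
  r <- midranks(abs(d))
  v_obs <- sum(r[d > 0])
  center <- sum(r) / 2
  if (2^m <= exact_limit) {
    key <- paste0("wsr|", paste(signif(sort(r), 12), collapse = ","))
    null_v <- cache_get_or(key, function() {
      sums <- 0
      for (ri in r) sums <- c(sums, sums + ri)
      sums
    })
    p <- two_sided_perm_p(null_v, v_obs, center)
    exact <- TRUE
  } else {
    v <- m * (m + 1) * (2 * m + 1) / 24 - tie_term(r) / 48
    p <- 2 * stats::pnorm(-abs(v_obs - center) / sqrt(v))
    exact <- FALSE
  }
  list(name = "Wilcoxon signed ranks", statistic = v_obs, p = min(p, 1),
       exact = exact, degenerate = FALSE)
}

kw_statistic <- function(r, sizes) {
  n <- length(r)
  grp <- rep(seq_along(sizes), sizes)
  rs <- tapply(r, grp, sum)
  h <- 12 / (n * (n + 1)) * sum(rs^2 / sizes) - 3 * (n + 1)
  corr <- 1 - tie_term(r) / (n^3 - n)
  if (corr <= 0) return(NA_real_)
  h / corr
}

# enumerate all partitions of ranks `r` into groups of the given sizes,
# returning the statistic `stat_fn(permuted_r, sizes)` for each
enumerate_group_stats <- function(r, sizes, stat_fn) {
  total <- round(multinomial_count(sizes))
  out <- numeric(total)
  pos <- 0L
  recurse <- function(remaining_idx, size_idx, acc) {
    if (size_idx == length(sizes)) {
      pos <<- pos + 1L
      out[pos] <<- stat_fn(r[c(acc, remaining_idx)], sizes)
      return(invisible())
    }
    k <- sizes[size_idx]
    picks <- utils::combn(length(remaining_idx), k)
    for (j in seq_len(ncol(picks))) {
      sel <- picks[, j]
      recurse(remaining_idx[-sel], size_idx + 1L,
              c(acc, remaining_idx[sel]))
    }
    invisible()
  }
  recurse(seq_along(r), 1L, integer(0))
  out
}

multinomial_count <- function(sizes) {
  exp(lgamma(sum(sizes) + 1) - sum(lgamma(sizes + 1)))
}

#' Kruskal-Wallis H test (exact permutation or chi-square)
#'
#' k-sample rank test for unrelated groups with tie-corrected H. When the
#' number of distinct group assignments `n! / prod(n_i!)` is at most
#' `exact_limit`, the p-value is the exact permutation upper-tail
#' probability of H; otherwise the chi-square approximation on k-1 df.
#'
#' @param samples list of numeric vectors, one per group.
#' @inheritParams mann_whitney_test
#' @return list as in [mann_whitney_test()] with statistic H.
#' @export
kruskal_wallis_test <- function(samples, exact_limit = 1e5) {
  stopifnot(length(samples) >= 2)
  sizes <- lengths(samples)
  pooled <- unlist(samples, use.names = FALSE)
  r <- midranks(pooled)
  h_obs <- kw_statistic(r, sizes)
  if (is.na(h_obs)) {
    return(list(name = "Kruskal-Wallis H", statistic = NA_real_, p = 1,
                exact = TRUE, degenerate = TRUE))
  }
  if (multinomial_count(sizes) <= exact_limit) {
    key <- paste0("kw|", paste(sizes, collapse = "."), "|",
                  paste(signif(sort(r), 12), collapse = ","))
    null_h <- cache_get_or(key, function() {
      enumerate_group_stats(r, sizes, kw_statistic)
    })
    p <- mean(null_h >= h_obs - 1e-9)
    exact <- TRUE
  } else {
    p <- stats::pchisq(h_obs, df = length(samples) - 1, lower.tail = FALSE)
    exact <- FALSE
  }
  list(name = "Kruskal-Wallis H", statistic = h_obs, p = p,
       exact = exact, degenerate = FALSE)
}

friedman_statistic <- function(rank_matrix) {
  b <- nrow(rank_matrix); k <- ncol(rank_matrix)
  rj <- colSums(rank_matrix)
  a <- sum(rank_matrix^2)
  cc <- b * k * (k + 1)^2 / 4
  if (a == cc) return(NA_real_)
  (k - 1) * sum((rj - b * (k + 1) / 2)^2) / (a - cc)
}

#' Friedman test for multiple related samples (exact or chi-square)
#'
#' Rank test over a blocks-by-treatments matrix; within-block mid-ranks and
#' the tie-corrected chi-square-form statistic. When `(k!)^b <= exact_limit`
#' the p-value is exact over all within-block rank permutations; otherwise
#' the chi-square approximation on k-1 df.
#'
#' @param y numeric matrix, rows = blocks (aligned units), columns = groups.
#' @inheritParams mann_whitney_test
#' @return list as in [mann_whitney_test()].
#' @export
friedman_test <- function(y, exact_limit = 1e5) {
  y <- as.matrix(y)
  b <- nrow(y); k <- ncol(y)
  stopifnot(b >= 2, k >= 2)
  rm_obs <- t(apply(y, 1, midranks))
  f_obs <- friedman_statistic(rm_obs)
  if (is.na(f_obs)) {
    return(list(name = "Friedman", statistic = NA_real_, p = 1,
                exact = TRUE, degenerate = TRUE))
  }
  n_perm <- factorial(k)^b
  if (n_perm <= exact_limit) {
    perms <- all_permutations(k)
    np <- nrow(perms)
    grid <- as.matrix(expand.grid(rep(list(seq_len(np)), b)))
    stats_v <- vapply(seq_len(nrow(grid)), function(g) {
      m <- do.call(rbind, lapply(seq_len(b), function(i) {
        rm_obs[i, perms[grid[g, i], ]]
      }))
      friedman_statistic(m)
    }, numeric(1))
    p <- mean(stats_v >= f_obs - 1e-9)
    exact <- TRUE
  } else {
    p <- stats::pchisq(f_obs, df = k - 1, lower.tail = FALSE)
    exact <- FALSE
  }
  list(name = "Friedman", statistic = f_obs, p = p, exact = exact,
       degenerate = FALSE)
}

all_permutations <- function(k) {
  if (k == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(k - 1)
  do.call(rbind, lapply(seq_len(k), function(i) {
    cbind(i, sub + (sub >= i))
  }))
}

#' Omnibus test dispatch by design
#'
#' Chooses the omnibus test from the number of groups and the design:
#' two related samples -> Wilcoxon signed ranks; two unrelated ->
#' Mann-Whitney U; more than two related -> Friedman; more than two
#' unrelated -> Kruskal-Wallis H.
#'
#' @param values numeric observations.
#' @param groups group label per observation.
#' @param design `"unrelated"` (independent groups) or `"related"`
#'   (aligned units; requires `blocks`).
#' @param blocks unit identifier per observation, required for related
#'   designs (every block must appear once per group).
#' @inheritParams mann_whitney_test
#' @return list with `name`, `statistic`, `p`, `exact`, `degenerate`.
#' @export
omnibus_test <- function(values, groups, design = c("unrelated", "related"),
                         blocks = NULL, exact_limit = 1e5) {
  design <- match.arg(design)
  groups <- as.character(groups)
  g_levels <- unique(groups)
  if (length(g_levels) < 2) stop("need at least 2 groups", call. = FALSE)
  if (design == "unrelated") {
    samples <- split(values, factor(groups, levels = g_levels))
    if (length(g_levels) == 2) {
      mann_whitney_test(samples[[1]], samples[[2]], exact_limit)
    } else {
      kruskal_wallis_test(samples, exact_limit)
    }
  } else {
    y <- related_matrix(values, groups, blocks, g_levels)
    if (length(g_levels) == 2) {
      wilcoxon_signed_rank_test(y[, 1], y[, 2], exact_limit)
    } else {
      friedman_test(y, exact_limit)
    }
  }
}

related_matrix <- function(values, groups, blocks, g_levels) {
  if (is.null(blocks)) {
    stop("related design requires `blocks` (aligned units)", call. = FALSE)
  }
  tab <- table(blocks, groups)
  if (any(tab != 1)) {
    stop("related design requires equal group sizes with aligned units",
         call. = FALSE)
  }
  b_levels <- unique(as.character(blocks))
  y <- matrix(NA_real_, length(b_levels), length(g_levels),
              dimnames = list(b_levels, g_levels))
  y[cbind(as.character(blocks), as.character(groups))] <- values
  y
}

#' Bonferroni-adapted pairwise contrasts
#'
#' Tests every unordered pair of groups with the design-appropriate
#' two-sample test (Mann-Whitney U for unrelated, Wilcoxon signed ranks for
#' related pairs) and judges significance at the Bonferroni-adapted level
#' \eqn{\alpha_B = \alpha / k}, where k is the number of contrasts actually
#' performed in this family.
#'
#' @inheritParams omnibus_test
#' @param alpha familywise risk level (default 0.05).
#' @return `data.frame` with one row per pair: `group1, group2, test,
#'   statistic, p, alpha_adjusted, significant, degenerate`; attribute
#'   `alpha_adjusted` carries \eqn{\alpha_B}.
#' @export
bonferroni_contrasts <- function(values, groups,
                                 design = c("unrelated", "related"),
                                 blocks = NULL, alpha = 0.05,
                                 exact_limit = 1e5) {
  design <- match.arg(design)
  stopifnot(alpha > 0, alpha <= 1)
  groups <- as.character(groups)
  g_levels <- unique(groups)
  if (length(g_levels) < 2) stop("need at least 2 groups", call. = FALSE)
  pairs <- utils::combn(g_levels, 2)
  k <- ncol(pairs)
  alpha_b <- alpha / k
  y <- if (design == "related") {
    related_matrix(values, groups, blocks, g_levels)
  }
  rows <- lapply(seq_len(k), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    res <- if (design == "unrelated") {
      mann_whitney_test(values[groups == a], values[groups == b], exact_limit)
    } else {
      wilcoxon_signed_rank_test(y[, a], y[, b], exact_limit)
    }
    data.frame(group1 = a, group2 = b, test = res$name,
               statistic = res$statistic, p = res$p,
               alpha_adjusted = alpha_b,
               significant = res$p <= alpha_b,
               degenerate = res$degenerate,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "alpha_adjusted") <- alpha_b
  out
}

#' Full treatment comparison: omnibus, contrasts, letters
#'
#' Runs the omnibus test, the Bonferroni-adapted pairwise contrasts and the
#' compact letter display in one call.
#'
#' @inheritParams bonferroni_contrasts
#' @return list of class `comparison_result` with elements `omnibus`
#'   (list), `contrasts` (data.frame) and `letters` (named character).
#' @export
compare_groups <- function(values, groups,
                           design = c("unrelated", "related"),
                           blocks = NULL, alpha = 0.05, exact_limit = 1e5) {
  design <- match.arg(design)
  omni <- omnibus_test(values, groups, design, blocks, exact_limit)
  ctr <- bonferroni_contrasts(values, groups, design, blocks, alpha,
                              exact_limit)
  structure(
    list(omnibus = omni, contrasts = ctr, letters = letter_display(ctr)),
    class = "comparison_result"
  )
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("omnibus: %s = %.4g, p = %.4g%s\n", x$omnibus$name,
              x$omnibus$statistic, x$omnibus$p,
              if (x$omnibus$exact) " (exact)" else " (approx.)"))
  cat(sprintf("pairwise contrasts at alpha_B = %.5g:\n",
              attr(x$contrasts, "alpha_adjusted")))
  print(x$contrasts[, c("group1", "group2", "statistic", "p", "significant")],
        row.names = FALSE)
  cat("letters:",
      paste(names(x$letters), x$letters, sep = ": ", collapse = ", "), "\n")
  invisible(x)
}

#' Kendall rank correlation trend check
#'
#' Kendall's tau-b with tie correction, for monotonic-trend checks on
#' ordered series (e.g. an index against year). Exact p-value when the
#' series has no ties and n <= 10; normal approximation otherwise.
#'
#' @param x,y paired numeric vectors, length >= 3.
#' @return list with `tau`, `p`, `n`, `exact`, `degenerate` (constant
#'   series: tau undefined, flagged).
#' @export
kendall_trend <- function(x, y) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 3) stop("kendall_trend needs at least 3 pairs", call. = FALSE)
  if (length(unique(x)) == 1 || length(unique(y)) == 1) {
    warning("constant series: Kendall tau undefined")
    return(list(tau = NA_real_, p = NA_real_, n = n, exact = FALSE,
                degenerate = TRUE))
  }
  has_ties <- anyDuplicated(x) > 0 || anyDuplicated(y) > 0
  use_exact <- !has_ties && n <= 10
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "kendall", exact = use_exact)
  )
  list(tau = unname(ct$estimate), p = ct$p.value, n = n,
       exact = use_exact, degenerate = FALSE)
}
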