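# Independent reference implementations used as oracles. Each works from a
# per-seed event list (or raw permutation enumeration) rather than the
# package's vectorised daily-count formulas.

# All ten indices computed naively from the list of per-seed germination
# days (one entry per germinated seed).
oracle_indices <- function(event_days, total_seeds, duration_days) {
  g <- length(event_days)
  days <- sort(event_days)
  fgp <- 100 * g / total_seeds
  if (g == 0) {
    mgt <- mgr <- fdg <- ldg <- t50 <- cvt <- cvg <- NA_real_
  } else {
    mgt <- mean(days)
    mgr <- 1 / mgt
    fdg <- min(days)
    ldg <- max(days)
    cvg <- 100 * g / sum(days)
    if (g >= 2) {
      s2 <- sum((days - mgt)^2) / (g - 1)
      cvt <- 100 * sqrt(s2) / mgt
    } else {
      cvt <- NA_real_
    }
    # interpolate the cumulative step function at (g+1)/2
    uday <- unique(days)
    cum <- vapply(uday, function(d) sum(days <= d), numeric(1))
    half <- (g + 1) / 2
    if (any(cum == half)) {
      t50 <- uday[which(cum == half)[1]]
    } else if (cum[1] >= half) {
      t50 <- uday[1]
    } else {
      i <- max(which(cum < half))
      t50 <- uday[i] + (half - cum[i]) * (uday[i + 1] - uday[i]) /
        (cum[i + 1] - cum[i])
    }
  }
  gri <- if (g == 0) 0 else sum(100 / total_seeds / days)
  gi <- if (g == 0) 0 else sum(duration_days - days + 1)
  list(fgp = fgp, mgt = mgt, mgr = mgr, fdg = as_num(fdg), ldg = as_num(ldg),
       t50 = as_num(t50), cvt = cvt, cvg = cvg, gri = gri, gi = gi)
}

as_num <- function(x) if (is.na(x)) NA_real_ else as.numeric(x)

# all daily-count vectors of length k with sum <= n_max
enumerate_count_vectors <- function(n_max, k) {
  grow <- function(prefix, remaining, slots) {
    if (slots == 0) return(list(prefix))
    out <- list()
    for (v in 0:remaining) {
      out <- c(out, grow(c(prefix, v), remaining - v, slots - 1))
    }
    out
  }
  grow(integer(0), n_max, k)
}

# Mann-Whitney permutation oracle: U by direct pair counting, two-sided p
# by enumerating every split of the pooled sample.
oracle_mw <- function(x, y) {
  u_of <- function(a, b) {
    sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  }
  pooled <- c(x, y)
  n1 <- length(x)
  center <- n1 * length(y) / 2
  u_obs <- u_of(x, y)
  splits <- utils::combn(length(pooled), n1)
  null_u <- apply(splits, 2, function(idx) {
    u_of(pooled[idx], pooled[-idx])
  })
  list(u = u_obs,
       p = mean(abs(null_u - center) >= abs(u_obs - center) - 1e-9))
}

# Wilcoxon signed-rank sign-flip oracle; mid-ranks computed by position
# averaging rather than rank().
oracle_wsr <- function(x, y) {
  d <- (x - y)[x - y != 0]
  if (!length(d)) return(list(v = 0, p = 1))
  ad <- abs(d)
  r <- vapply(ad, function(v) mean(which(sort(ad) == v)), numeric(1))
  v_obs <- sum(r[d > 0])
  center <- sum(r) / 2
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), length(d))))
  null_v <- as.vector(signs %*% r)
  list(v = v_obs,
       p = mean(abs(null_v - center) >= abs(v_obs - center) - 1e-9))
}

# Kruskal-Wallis oracle: permute the raw observations over all n!
# orderings (each group assignment is counted equally often), recomputing
# H each time with stats::kruskal.test. Only for small n.
oracle_kw <- function(samples) {
  values <- unlist(samples)
  g <- rep(seq_along(samples), lengths(samples))
  h_obs <- unname(stats::kruskal.test(values, g)$statistic)
  perms <- all_perms(length(values))
  null_h <- apply(perms, 1, function(p) {
    unname(stats::kruskal.test(values[p], g)$statistic)
  })
  list(h = h_obs, p = mean(null_h >= h_obs - 1e-9))
}

# Friedman oracle (no ties): classic statistic over all per-block
# permutations of the observed values.
oracle_friedman <- function(y) {
  b <- nrow(y); k <- ncol(y)
  classic <- function(m) {
    r <- t(apply(m, 1, rank))
    12 / (b * k * (k + 1)) * sum(colSums(r)^2) - 3 * b * (k + 1)
  }
  f_obs <- classic(y)
  perms <- all_perms(k)
  grid <- as.matrix(expand.grid(rep(list(seq_len(nrow(perms))), b)))
  null_f <- apply(grid, 1, function(g) {
    classic(do.call(rbind, lapply(seq_len(b), function(i) {
      y[i, perms[g[i], ]]
    })))
  })
  list(f = f_obs, p = mean(null_f >= f_obs - 1e-9))
}

all_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) cbind(i, sub + (sub >= i))))
}

# every symmetric logical matrix on n groups, as a list
all_sig_matrices <- function(n) {
  np <- n * (n - 1) / 2
  lapply(seq_len(2^np) - 1, function(code) {
    bits <- as.logical(bitwAnd(code, 2^(seq_len(np) - 1)))
    m <- matrix(FALSE, n, n,
                dimnames = list(paste0("g", 1:n), paste0("g", 1:n)))
    m[upper.tri(m)] <- bits
    m[lower.tri(m)] <- t(m)[lower.tri(m)]
    m
  })
}

make_schedule <- function(event_days, total_seeds = 20, duration_days = 60,
                          ...) {
  germination_schedule(counts_from_events(event_days, duration_days),
                       total_seeds, duration_days, ...)
}

local_tempdir <- function() {
  d <- tempfile("seedtrends")
  dir.create(d)
  d
}
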