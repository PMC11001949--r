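# Compact letter display by insert-and-absorb.
#
# Two groups share a letter if and only if their pairwise contrast is NOT
# significant. Starting from a single letter covering all groups, each
# significant pair splits every letter set containing both members into two
# reduced copies, and sets contained in another set are absorbed. The
# procedure is deterministic given the input group order.

#' Compact letter display from pairwise significance
#'
#' @param x either a pairwise contrast table (as from
#'   [bonferroni_contrasts()], with columns `group1`, `group2`,
#'   `significant`) or a symmetric logical matrix with group names on both
#'   dimensions, `TRUE` where the pair differs significantly.
#' @return named character vector: for each group, its letters in
#'   alphabetical order (e.g. `"ab"`). Groups share a letter exactly when
#'   their pair is not significant.
#' @examples
#' m <- matrix(FALSE, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
#' m["a", "c"] <- m["c", "a"] <- TRUE
#' letter_display(m)  # a, ab, b
#' @export
letter_display <- function(x) {
  m <- as_significance_matrix(x)
  groups <- rownames(m)
  n <- length(groups)
  sets <- list(seq_len(n))
  pairs <- which(upper.tri(m) & m, arr.ind = TRUE)
  if (nrow(pairs)) {
    # process pairs in input-order: by first group, then second
    pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
  }
  for (pr in seq_len(nrow(pairs))) {
    i <- pairs[pr, 1]; j <- pairs[pr, 2]
    new_sets <- list()
    for (s in sets) {
      if (i %in% s && j %in% s) {
        new_sets <- c(new_sets, list(setdiff(s, i)), list(setdiff(s, j)))
      } else {
        new_sets <- c(new_sets, list(s))
      }
    }
    # absorb sets contained in another set
    keep <- rep(TRUE, length(new_sets))
    for (a in seq_along(new_sets)) {
      for (b in seq_along(new_sets)) {
        if (a != b && keep[a] &&
            all(new_sets[[a]] %in% new_sets[[b]]) &&
            (length(new_sets[[a]]) < length(new_sets[[b]]) || a > b)) {
          keep[a] <- FALSE
        }
      }
    }
    sets <- new_sets[keep]
  }
  # deterministic letter order: by earliest member, then by membership
  ord <- order(vapply(sets, min, numeric(1)),
               vapply(sets, function(s) paste(sort(s), collapse = ","),
                      character(1)))
  sets <- sets[ord]
  out <- vapply(seq_len(n), function(g) {
    paste(sort(letters[which(vapply(sets, function(s) g %in% s, logical(1)))]),
          collapse = "")
  }, character(1))
  names(out) <- groups
  out
}

#' Significance matrix implied by a letter display
#'
#' Inverse view of [letter_display()]: two groups are non-significant iff
#' they share at least one letter.
#'
#' @param letters named character vector of letter strings per group.
#' @return symmetric logical matrix, `TRUE` where the pair is significant.
#' @export
significance_from_letters <- function(letters) {
  groups <- names(letters)
  n <- length(groups)
  sets <- strsplit(letters, "")
  m <- matrix(FALSE, n, n, dimnames = list(groups, groups))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j) m[i, j] <- !any(sets[[i]] %in% sets[[j]])
    }
  }
  m
}

as_significance_matrix <- function(x) {
  if (is.matrix(x)) {
    if (is.null(rownames(x))) {
      dimnames(x) <- list(paste0("g", seq_len(nrow(x))),
                          paste0("g", seq_len(ncol(x))))
    }
    if (!isTRUE(all.equal(x, t(x))) || any(diag(x))) {
      stop("significance matrix must be symmetric with FALSE diagonal",
           call. = FALSE)
    }
    return(x)
  }
  stopifnot(is.data.frame(x),
            all(c("group1", "group2", "significant") %in% names(x)))
  groups <- unique(c(x$group1, x$group2))
  m <- matrix(FALSE, length(groups), length(groups),
              dimnames = list(groups, groups))
  for (r in seq_len(nrow(x))) {
    m[x$group1[r], x$group2[r]] <- x$significant[r]
    m[x$group2[r], x$group1[r]] <- x$significant[r]
  }
  m
}
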