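#' Bray-Curtis dissimilarity matrix
#'
#' `BC(x, y) = sum |x_i - y_i| / sum (x_i + y_i)` after an optional
#' element-wise square-root transform (the standard variance-stabilizing
#' choice for relative abundances). On presence/absence input this equals
#' one minus the Sorensen similarity. A pair of all-zero rows is assigned
#' distance 0 with a warning.
#'
#' @param x Samples x features matrix of non-negative abundances (relative
#'   abundances, counts, or 0/1).
#' @param transform `"sqrt"` or `"none"`.
#' @return A symmetric `dist`-like matrix (class `matrix`) with zero
#'   diagonal and entries in `[0, 1]`.
#' @export
bray_curtis <- function(x, transform = c("sqrt", "none")) {
  transform <- match.arg(transform)
  x <- as.matrix(x)
  if (any(x < 0)) stop("abundances must be non-negative")
  if (transform == "sqrt") x <- sqrt(x)
  n <- nrow(x)
  D <- matrix(0, n, n, dimnames = list(rownames(x), rownames(x)))
  warned <- FALSE
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    denom <- sum(x[i, ] + x[j, ])
    if (denom == 0) {
      if (!warned) { warning("pair of all-zero samples: distance set to 0")
        warned <- TRUE }
      d <- 0
    } else d <- sum(abs(x[i, ] - x[j, ])) / denom
    D[i, j] <- D[j, i] <- d
  }
  D
}

#' Non-metric multidimensional scaling
#'
#' Kruskal stress-1 NMDS via iterative monotone (isotonic) regression
#' ([vegan::monoMDS()]), best of `n_restarts` random starts; deterministic
#' for a fixed seed. Stress below 0.15 conventionally indicates an excellent
#' match between ordination and dissimilarity ranks.
#'
#' @param D Symmetric dissimilarity matrix.
#' @param k Ordination dimension.
#' @param n_restarts Number of random starts.
#' @param seed Integer seed.
#' @return List with `coordinates` (samples x k), `stress`, `n_restarts`,
#'   `seed`, of class `nmds_result`.
#' @export
nmds <- function(D, k = 2, n_restarts = 20, seed = 1) {
  D <- as.matrix(D)
  if (nrow(D) < k + 1) stop("need at least k + 1 samples")
  if (max(D) == min(D)) {
    warning("all distances equal: degenerate ordination, stress 0")
    co <- matrix(0, nrow(D), k, dimnames = list(rownames(D), NULL))
    return(structure(list(coordinates = co, stress = 0,
                          n_restarts = n_restarts, seed = seed),
                     class = "nmds_result"))
  }
  set.seed(seed)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    init <- matrix(rnorm(nrow(D) * k), ncol = k)
    fit <- vegan::monoMDS(stats::as.dist(D), y = init, k = k, model = "global",
                          maxit = 500, smin = 1e-7, sratmax = 1 - 1e-7)
    if (is.null(best) || fit$stress < best$stress) best <- fit
  }
  co <- best$points
  dimnames(co) <- list(rownames(D), paste0("MDS", seq_len(k)))
  structure(list(coordinates = co, stress = best$stress,
                 n_restarts = n_restarts, seed = seed),
            class = "nmds_result")
}

#' @export
print.nmds_result <- function(x, ...) {
  cat(sprintf("NMDS: %d samples, k = %d, stress = %.4f (%s)\n",
              nrow(x$coordinates), ncol(x$coordinates), x$stress,
              if (x$stress < 0.15) "excellent" else "check fit"))
  invisible(x)
}

#' Analysis of similarity (ANOSIM)
#'
#' Rank-based permutation test of whether between-group dissimilarities
#' exceed within-group dissimilarities. All pairwise dissimilarities are
#' ranked (mid-ranks for ties); `R = (r_between - r_within) / (M / 2)` with
#' `M = n (n - 1) / 2`; the p-value counts permuted `R >= observed` under
#' the add-one convention `p = (1 + #{R* >= R}) / (1 + n_perm)`.
#'
#' @param D Symmetric dissimilarity matrix.
#' @param groups Group label per sample (length `nrow(D)`), each group of
#'   size >= 2.
#' @param n_perm Number of label permutations.
#' @param seed Integer seed.
#' @param exhaustive Enumerate all distinct labelings instead of sampling
#'   (exact test; feasible for small designs only). `p` is then the exact
#'   fraction of labelings with `R` at least the observed.
#' @return An `anosim_result`: list with `R`, `p`, `r_between`, `r_within`,
#'   `M`, `n_perm`, `perm_R` (the null statistics).
#' @export
anosim <- function(D, groups, n_perm = 999, seed = 1, exhaustive = FALSE) {
  D <- as.matrix(D)
  groups <- as.character(groups)
  stopifnot(length(groups) == nrow(D))
  tab <- table(groups)
  if (length(tab) < 2) stop("need at least two groups")
  if (any(tab < 2)) stop("group of size 1: ", names(tab)[tab < 2][1L])
  n <- nrow(D)
  lower <- lower.tri(D)
  r <- rank(D[lower]) # mid-ranks for ties
  M <- n * (n - 1) / 2
  pair_i <- row(D)[lower]; pair_j <- col(D)[lower]

  stat <- function(g) {
    between <- g[pair_i] != g[pair_j]
    (mean(r[between]) - mean(r[!between])) / (M / 2)
  }
  R <- stat(groups)
  if (exhaustive) {
    labelings <- .distinct_permutations(groups)
    perm_R <- vapply(labelings, stat, numeric(1))
    p <- mean(perm_R >= R)
    n_perm <- length(labelings)
  } else {
    set.seed(seed)
    perm_R <- vapply(seq_len(n_perm), function(...) stat(sample(groups)),
                     numeric(1))
    p <- (1 + sum(perm_R >= R)) / (1 + n_perm)
  }
  between <- groups[pair_i] != groups[pair_j]
  structure(list(R = R, p = p, r_between = mean(r[between]),
                 r_within = mean(r[!between]), M = M, n_perm = n_perm,
                 perm_R = perm_R),
            class = "anosim_result")
}

#' @export
print.anosim_result <- function(x, ...) {
  cat(sprintf("ANOSIM: R = %.3f, P = %.4g (%d permutations)\n",
              x$R, x$p, x$n_perm))
  invisible(x)
}

#' Pairwise post-hoc ANOSIM
#'
#' Runs [anosim()] on every pair of groups and reports raw and
#' Bonferroni-adjusted p-values.
#'
#' @inheritParams anosim
#' @return data.frame with one row per group pair.
#' @export
anosim_pairwise <- function(D, groups, n_perm = 999, seed = 1) {
  D <- as.matrix(D)
  groups <- as.character(groups)
  gs <- sort(unique(groups))
  prs <- combn(gs, 2)
  out <- do.call(rbind, lapply(seq_len(ncol(prs)), function(k) {
    sel <- groups %in% prs[, k]
    a <- anosim(D[sel, sel, drop = FALSE], groups[sel],
                n_perm = n_perm, seed = seed + k)
    data.frame(group1 = prs[1, k], group2 = prs[2, k], R = a$R, p = a$p)
  }))
  out$p_bonferroni <- pmin(1, out$p * nrow(out))
  out
}

#' Likelihood-ratio G test of independence
#'
#' For an r x c contingency table: `E_ij = row_i * col_j / total`,
#' `G = 2 sum O_ij ln(O_ij / E_ij)` over non-zero cells,
#' `df = (r - 1)(c - 1)`, p from the upper chi-square tail.
#'
#' @param O Count matrix with positive row and column sums.
#' @return A `g_test` object.
#' @export
gtest_independence <- function(O) {
  O <- as.matrix(O)
  if (length(O) == 0 || sum(O) == 0) stop("empty table")
  if (any(rowSums(O) == 0) || any(colSums(O) == 0))
    stop("rows and columns must all have positive sums")
  E <- outer(rowSums(O), colSums(O)) / sum(O)
  nz <- O > 0
  G <- 2 * sum(O[nz] * log(O[nz] / E[nz]))
  df <- (nrow(O) - 1L) * (ncol(O) - 1L)
  structure(list(G = G, df = df, p = pchisq(G, df, lower.tail = FALSE),
                 observed = O, expected = E, type = "independence"),
            class = "g_test")
}
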