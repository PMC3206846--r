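#' Tajima-Nei (1984) pairwise distance
#'
#' Evolutionary distance `d = -b ln(1 - p/b)` for two pre-aligned sequences,
#' where `p` is the proportion of differing sites and `b` accounts for the
#' equilibrium base composition and the observed mismatch-pair spectrum:
#' `b = (1 - sum g_i^2 + p^2 / h) / 2` with `g_i` the average base
#' frequencies over both sequences and
#' `h = sum_{i<j} x_ij^2 / (2 g_i g_j)` over the fractions `x_ij` of sites
#' showing the unordered base pair (i, j). Columns containing gaps or
#' ambiguity codes in either sequence are deleted pairwise. Saturated pairs
#' (`p >= b`) return `Inf` with attribute `saturated = TRUE`.
#'
#' @param a,b Aligned nucleotide strings of equal length.
#' @return Non-negative distance (0 for identical sequences).
#' @export
tajima_nei_distance <- function(a, b) {
  if (nchar(a) != nchar(b)) stop("sequences must be aligned (equal length)")
  av <- strsplit(toupper(a), "")[[1]]
  bv <- strsplit(toupper(b), "")[[1]]
  keep <- av %in% c("A", "C", "G", "T") & bv %in% c("A", "C", "G", "T")
  av <- av[keep]; bv <- bv[keep]
  n <- length(av)
  if (n == 0) stop("no comparable sites after pairwise deletion")
  diff <- av != bv
  p <- mean(diff)
  if (p == 0) return(0)
  bases <- c("A", "C", "G", "T")
  g <- (table(factor(av, bases)) + table(factor(bv, bases))) / (2 * n)
  g <- as.numeric(g)
  # unordered mismatch-pair fractions
  h <- 0
  for (i in 1:3) for (j in (i + 1):4) {
    xij <- sum((av == bases[i] & bv == bases[j]) |
                 (av == bases[j] & bv == bases[i])) / n
    if (xij > 0) h <- h + xij^2 / (2 * g[i] * g[j])
  }
  bb <- (1 - sum(g^2) + p^2 / h) / 2
  if (p >= bb) {
    out <- Inf
    attr(out, "saturated") <- TRUE
    return(out)
  }
  -bb * log(1 - p / bb)
}

#' Tajima-Nei distance matrix
#'
#' @param seqs Named character vector of aligned sequences.
#' @return Symmetric numeric matrix.
#' @export
tajima_nei_matrix <- function(seqs) {
  n <- length(seqs)
  D <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    D[i, j] <- D[j, i] <- tajima_nei_distance(seqs[[i]], seqs[[j]])
  D
}

#' Parsimony length of a discrete character on a tree
#'
#' Minimum number of state changes of an unordered, equal-cost character,
#' computed by the set-intersection dynamic program (Fitch on binary nodes,
#' Hartigan's generalization on multifurcations: at a node with k children,
#' the state set is the set of most-frequent states among child sets and the
#' cost increases by k minus that maximal frequency).
#'
#' @param tree An [ape::phylo] tree.
#' @param states Named character vector: tip label -> state.
#' @return Integer number of changes.
#' @export
parsimony_length <- function(tree, states) {
  if (!all(tree$tip.label %in% names(states)))
    stop("state missing for tip: ",
         setdiff(tree$tip.label, names(states))[1L])
  st <- as.character(states[tree$tip.label])
  lv <- unique(st)
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  sets <- vector("list", ntip + nnode)
  for (i in seq_len(ntip)) sets[[i]] <- st[i]
  tr <- stats::reorder(tree, "postorder")
  cost <- 0L
  for (node in unique(tr$edge[, 1])) {
    children <- tr$edge[tr$edge[, 1] == node, 2]
    cnt <- table(factor(unlist(sets[children]), levels = lv))
    m <- max(cnt)
    sets[[node]] <- lv[cnt == m]
    cost <- cost + length(children) - m
  }
  cost
}

#' Phylogenetic lineage-sorting test (P-test)
#'
#' Tests whether source labels are more clustered on the tree than expected
#' by chance: the observed statistic is the parsimony length of the source
#' character; the null distribution comes from random permutations of tip
#' labels; `p = (1 + #{null <= observed}) / (1 + n_perm)`. With
#' `exhaustive = TRUE` all distinct labelings are enumerated instead
#' (feasible for small trees) and `p` is the exact fraction of labelings
#' with length at most the observed.
#'
#' @param tree An [ape::phylo] tree.
#' @param sources Named character vector: tip label -> source.
#' @param n_perm Number of permutations.
#' @param seed Integer seed.
#' @param exhaustive Enumerate all distinct labelings instead of sampling.
#' @return A `ptest_result`: list with `observed`, `p`, `null` lengths,
#'   `n_perm`.
#' @export
ptest <- function(tree, sources, n_perm = 999, seed = 1, exhaustive = FALSE) {
  if (length(unique(sources)) < 2) stop("need at least two sources")
  obs <- parsimony_length(tree, sources)
  st <- as.character(sources[tree$tip.label])
  if (exhaustive) {
    perms <- .distinct_permutations(st)
    null <- vapply(perms, function(s)
      parsimony_length(tree, setNames(s, tree$tip.label)), integer(1))
    p <- mean(null <= obs)
    n_perm <- length(perms)
  } else {
    set.seed(seed)
    null <- vapply(seq_len(n_perm), function(...)
      parsimony_length(tree, setNames(sample(st), tree$tip.label)),
      integer(1))
    p <- (1 + sum(null <= obs)) / (1 + n_perm)
  }
  structure(list(observed = obs, p = p, null = null, n_perm = n_perm,
                 exhaustive = exhaustive),
            class = "ptest_result")
}

#' @export
print.ptest_result <- function(x, ...) {
  cat(sprintf("P-test: %d observed changes, null mean %.2f, P = %.4g%s\n",
              x$observed, mean(x$null), x$p,
              if (x$exhaustive) " (exhaustive)" else ""))
  invisible(x)
}

# all distinct arrangements of a state multiset (small n only)
.distinct_permutations <- function(st) {
  n <- length(st)
  if (n > 9) stop("exhaustive enumeration limited to 9 tips")
  perm_idx <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      out <- c(out, lapply(perm_idx(v[-i]), function(r) c(v[i], r)))
    out
  }
  all_perms <- perm_idx(seq_len(n))
  arr <- unique(lapply(all_perms, function(ix) st[ix]))
  arr
}

#' Net relatedness and nearest taxon indices (NRI / NTI)
#'
#' Standardized effect sizes of the mean pairwise patristic distance (MPD)
#' and mean nearest-taxon distance (MNTD) of a community against a
#' tip-shuffle null: communities of the same size are drawn at random from
#' the tip pool. Sign convention: phylogenetic clustering (observed distance
#' below the null mean) gives positive NRI/NTI. Results are flagged
#' undefined when the null standard deviation is zero.
#'
#' @param tree An [ape::phylo] tree with branch lengths.
#' @param community Character vector of community tip labels (>= 2).
#' @param pool Character vector of pool tip labels (superset of community).
#' @param n_null Number of null draws.
#' @param seed Integer seed.
#' @param exhaustive Enumerate all subsets of the pool instead of sampling.
#' @return A `dispersion_result`: list with `MPD_obs`, `MNTD_obs`, null
#'   means/sds, `NRI`, `NTI`, `n_null`.
#' @export
nri_nti <- function(tree, community, pool = tree$tip.label, n_null = 999,
                    seed = 1, exhaustive = FALSE) {
  stopifnot(all(community %in% pool), all(pool %in% tree$tip.label),
            length(community) >= 2)
  D <- ape::cophenetic.phylo(tree)[pool, pool]
  mpd <- function(tips) {
    d <- D[tips, tips]
    mean(d[lower.tri(d)])
  }
  mntd <- function(tips) {
    d <- D[tips, tips]
    diag(d) <- Inf
    mean(apply(d, 1, min))
  }
  obs_mpd <- mpd(community); obs_mntd <- mntd(community)
  k <- length(community)
  if (exhaustive) {
    subsets <- combn(pool, k, simplify = FALSE)
    null_mpd <- vapply(subsets, mpd, numeric(1))
    null_mntd <- vapply(subsets, mntd, numeric(1))
    n_null <- length(subsets)
  } else {
    set.seed(seed)
    null_mpd <- numeric(n_null); null_mntd <- numeric(n_null)
    for (i in seq_len(n_null)) {
      tips <- sample(pool, k)
      null_mpd[i] <- mpd(tips); null_mntd[i] <- mntd(tips)
    }
  }
  z <- function(obs, null) {
    s <- sd(null)
    if (is.na(s) || s == 0) NA_real_ else -(obs - mean(null)) / s
  }
  structure(list(MPD_obs = obs_mpd, MNTD_obs = obs_mntd,
                 null_mean_mpd = mean(null_mpd), null_sd_mpd = sd(null_mpd),
                 null_mean_mntd = mean(null_mntd),
                 null_sd_mntd = sd(null_mntd),
                 NRI = z(obs_mpd, null_mpd), NTI = z(obs_mntd, null_mntd),
                 n_null = n_null, null_model = "tip-shuffle"),
            class = "dispersion_result")
}

#' @export
print.dispersion_result <- function(x, ...) {
  cat(sprintf("Phylogenetic dispersion (tip-shuffle null, n = %d):\n",
              x$n_null))
  cat(sprintf("  MPD  = %.3f (null %.3f +/- %.3f)  NRI = %s\n",
              x$MPD_obs, x$null_mean_mpd, x$null_sd_mpd,
              if (is.na(x$NRI)) "undefined" else sprintf("%.2f", x$NRI)))
  cat(sprintf("  MNTD = %.3f (null %.3f +/- %.3f)  NTI = %s\n",
              x$MNTD_obs, x$null_mean_mntd, x$null_sd_mntd,
              if (is.na(x$NTI)) "undefined" else sprintf("%.2f", x$NTI)))
  invisible(x)
}

#' LIBSHUFF comparison of two sequence libraries
#'
#' Compares libraries X and Y through their coverage curves on a distance
#' grid: homologous coverage `C_X(D)` is the fraction of X sequences having
#' another X member within distance `D`; heterologous coverage `C_XY(D)` the
#' fraction having a Y member within `D`. The statistic is the
#' Cramer-von-Mises-type sum `Delta C_XY = sum_grid (C_X - C_XY)^2`,
#' computed in both directions; significance comes from shuffling sequences
#' between the libraries.
#'
#' @param dist Symmetric distance matrix over all sequences (row names are
#'   sequence ids).
#' @param libA,libB Disjoint character vectors of sequence ids, each >= 2.
#' @param grid Distance grid (default 0 to 0.5 step 0.01).
#' @param n_perm Number of shuffles.
#' @param seed Integer seed.
#' @return A `libshuff_result`: per direction, the coverage curves, `deltaC`
#'   and the permutation `p` (add-one convention).
#' @export
libshuff <- function(dist, libA, libB, grid = seq(0, 0.5, by = 0.01),
                     n_perm = 999, seed = 1) {
  if (length(intersect(libA, libB))) stop("libraries must be disjoint")
  stopifnot(length(libA) >= 2, length(libB) >= 2)
  D <- as.matrix(dist)

  coverage <- function(xs, ys, homologous) {
    # per grid point, fraction of xs with a (other-)member of ys within D
    vapply(grid, function(d) {
      covered <- vapply(xs, function(x) {
        others <- setdiff(ys, if (homologous) x else character(0))
        any(D[x, others] <= d)
      }, logical(1))
      mean(covered)
    }, numeric(1))
  }
  deltaC <- function(xs, ys) {
    cx <- coverage(xs, xs, TRUE)
    cxy <- coverage(xs, ys, FALSE)
    list(cx = cx, cxy = cxy, delta = sum((cx - cxy)^2))
  }
  obs_ab <- deltaC(libA, libB)
  obs_ba <- deltaC(libB, libA)
  set.seed(seed)
  all_ids <- c(libA, libB)
  null_ab <- numeric(n_perm); null_ba <- numeric(n_perm)
  for (i in seq_len(n_perm)) {
    sh <- sample(all_ids)
    a <- sh[seq_along(libA)]; b <- sh[-seq_along(libA)]
    null_ab[i] <- deltaC(a, b)$delta
    null_ba[i] <- deltaC(b, a)$delta
  }
  structure(list(
    grid = grid,
    XY = list(C_X = obs_ab$cx, C_XY = obs_ab$cxy, deltaC = obs_ab$delta,
              p = (1 + sum(null_ab >= obs_ab$delta)) / (1 + n_perm)),
    YX = list(C_X = obs_ba$cx, C_XY = obs_ba$cxy, deltaC = obs_ba$delta,
              p = (1 + sum(null_ba >= obs_ba$delta)) / (1 + n_perm)),
    n_perm = n_perm),
    class = "libshuff_result")
}

#' @export
print.libshuff_result <- function(x, ...) {
  cat(sprintf("LIBSHUFF: dCxy = %.4f (P = %.4g), dCyx = %.4f (P = %.4g)\n",
              x$XY$deltaC, x$XY$p, x$YX$deltaC, x$YX$p))
  invisible(x)
}

#' Analysis of molecular variance (AMOVA)
#'
#' Hierarchical decomposition of squared molecular distances into variance
#' among sources, among samples within sources, and within samples
#' (Excoffier-style sums of squares). `F_ST` is the among-source component
#' over the total; significance comes from permuting whole samples among
#' sources (add-one convention). When any source holds a single sample the
#' design degenerates and a two-level decomposition (sources / sequences)
#' is used with a warning.
#'
#' @param dist Symmetric distance matrix over sequences (ids as row names).
#' @param samples Named character vector: sequence id -> sample id.
#' @param sources Named character vector: sample id -> source group.
#' @param n_perm Number of sample permutations.
#' @param seed Integer seed.
#' @return An `amova_result`: variance components, `F_ST`, `p`.
#' @export
amova <- function(dist, samples, sources, n_perm = 1000, seed = 1) {
  D2 <- as.matrix(dist)^2
  ids <- rownames(D2)
  stopifnot(all(ids %in% names(samples)))
  smp <- as.character(samples[ids])
  stopifnot(all(unique(smp) %in% names(sources)))
  if (length(unique(sources[unique(smp)])) < 2)
    stop("need at least two sources")

  ss_within <- function(groups) {
    # sum over groups of (1/n_g) * sum_{i<j in g} d2
    tot <- 0
    for (g in unique(groups)) {
      sel <- which(groups == g)
      if (length(sel) > 1)
        tot <- tot + sum(D2[sel, sel][lower.tri(D2[sel, sel])]) / length(sel)
    }
    tot
  }
  N <- length(ids)
  SS_T <- sum(D2[lower.tri(D2)]) / N

  three_level <- all(table(sources[unique(smp)]) >= 2) &&
    any(table(smp) > 1)
  fst_of <- function(src_of_sample) {
    src <- as.character(src_of_sample[smp])
    if (three_level) {
      SS_WP <- ss_within(smp)                      # within samples
      SS_WG <- ss_within(src)                      # within sources
      SS_SP <- SS_WG - SS_WP                       # among samples in sources
      SS_AG <- SS_T - SS_WG                        # among sources
      S <- length(unique(smp)); G <- length(unique(src))
      df_a <- G - 1; df_b <- S - G; df_w <- N - S
      n_s <- table(smp)
      N_g <- tapply(n_s, src_of_sample[names(n_s)], sum)
      sum_ns2_by_g <- tapply(n_s^2, src_of_sample[names(n_s)], sum)
      n1 <- (N - sum(sum_ns2_by_g / N_g)) / df_b
      n2 <- (sum(sum_ns2_by_g / N_g) - sum(n_s^2) / N) / df_a
      n3 <- (N - sum(N_g^2) / N) / df_a
      MS_w <- if (df_w > 0) SS_WP / df_w else 0
      MS_b <- if (df_b > 0) SS_SP / df_b else 0
      s2_w <- MS_w
      s2_b <- if (n1 > 0) max(0, (MS_b - s2_w) / n1) else 0
      s2_a <- if (n3 > 0) (SS_AG / df_a - s2_w - n2 * s2_b) / n3 else 0
      comps <- c(among_sources = s2_a, among_samples = s2_b, within = s2_w)
    } else {
      SS_WG <- ss_within(src)
      SS_AG <- SS_T - SS_WG
      G <- length(unique(src))
      df_a <- G - 1; df_w <- N - G
      N_g <- table(src)
      n0 <- (N - sum(N_g^2) / N) / df_a
      MS_w <- if (df_w > 0) SS_WG / df_w else 0
      s2_w <- MS_w
      s2_a <- (SS_AG / df_a - s2_w) / n0
      comps <- c(among_sources = s2_a, among_samples = 0, within = s2_w)
    }
    tot <- sum(comps)
    fst <- if (tot <= 0) 0 else comps[["among_sources"]] / tot
    list(fst = fst, comps = comps)
  }

  src_map <- sources[unique(smp)]
  if (!three_level && any(table(smp) > 1))
    warning("a source holds a single sample: two-level AMOVA used")
  obs <- fst_of(src_map)
  set.seed(seed)
  null <- vapply(seq_len(n_perm), function(...) {
    fst_of(setNames(sample(src_map), names(src_map)))$fst
  }, numeric(1))
  p <- (1 + sum(null >= obs$fst)) / (1 + n_perm)
  structure(list(F_ST = obs$fst, components = obs$comps, p = p,
                 degenerate = sum(obs$comps) <= 0,
                 design = if (three_level) "three-level" else "two-level",
                 n_perm = n_perm),
            class = "amova_result")
}

#' @export
print.amova_result <- function(x, ...) {
  cat(sprintf("AMOVA (%s): F_ST = %.3f, P = %.4g (%d permutations)\n",
              x$design, x$F_ST, x$p, x$n_perm))
  comps <- x$components / max(sum(x$components), .Machine$double.eps)
  cat(sprintf("  variance: among sources %.1f%%, among samples %.1f%%, within %.1f%%\n",
              100 * comps[1], 100 * comps[2], 100 * comps[3]))
  invisible(x)
}
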