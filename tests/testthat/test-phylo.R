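quartet <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")

test_that("Tajima-Nei distance obeys identity, symmetry and the formula", {
  s <- random_dna(1, 500)
  expect_equal(tajima_nei_distance(s, s), 0)
  set.seed(67)
  a <- random_dna(1, 1000)
  v <- strsplit(a, "")[[1]]
  pos <- sample(1000, 10)
  for (p in pos) v[p] <- setdiff(c("A", "C", "G", "T"), v[p])[1]
  b <- paste(v, collapse = "")
  expect_equal(tajima_nei_distance(a, b), tajima_nei_oracle(a, b),
               tolerance = 1e-10)
  expect_equal(tajima_nei_distance(a, b), tajima_nei_distance(b, a))
  expect_gt(tajima_nei_distance(a, b), 10 / 1000) # correction exceeds p
  expect_error(tajima_nei_distance("ACGT", "ACG"), "equal length")
})

test_that("gap and ambiguity columns are deleted pairwise", {
  expect_equal(tajima_nei_distance("ACGTN-", "ACGTAA"), 0)
  set.seed(71)
  a <- random_dna(1, 400); b <- random_dna(1, 400)
  a2 <- paste0(a, "NNNN"); b2 <- paste0(b, "ACGT")
  expect_equal(tajima_nei_distance(a, b), tajima_nei_distance(a2, b2))
})

test_that("saturated pairs flag an infinite distance", {
  a <- paste(rep("A", 100), collapse = "")
  b <- paste(rep("C", 100), collapse = "")
  d <- tajima_nei_distance(a, b)
  expect_true(is.infinite(d))
  expect_true(attr(d, "saturated"))
})

test_that("parsimony length matches hand counts and brute-force enumeration", {
  expect_equal(parsimony_length(quartet,
                                c(A = "x", B = "x", C = "y", D = "y")), 1)
  expect_equal(parsimony_length(quartet,
                                c(A = "x", B = "y", C = "x", D = "y")), 2)
  set.seed(73)
  for (i in 1:6) {
    n <- sample(5:8, 1)
    tr <- ape::rtree(n)
    st <- setNames(sample(c("u", "v"), n, replace = TRUE), tr$tip.label)
    if (length(unique(st)) < 2) st[1] <- setdiff(c("u", "v"), st[1])
    expect_equal(parsimony_length(tr, st), parsimony_oracle(tr, st))
  }
  # multifurcating tree handled by the same recurrence
  poly <- ape::read.tree(text = "((A:1,B:1,C:1):1,(D:1,E:1):1);")
  st <- c(A = "x", B = "x", C = "y", D = "y", E = "y")
  expect_equal(parsimony_length(poly, st), parsimony_oracle(poly, st))
})

test_that("parsimony agrees with phangorn on binary trees", {
  skip_if_not_installed("phangorn")
  set.seed(79)
  tr <- ape::rtree(10)
  st <- setNames(sample(c("u", "v", "w"), 10, replace = TRUE), tr$tip.label)
  dat <- phangorn::phyDat(matrix(st, ncol = 1,
                                 dimnames = list(names(st), NULL)),
                          type = "USER", levels = c("u", "v", "w"))
  expect_equal(parsimony_length(tr, st),
               as.integer(phangorn::parsimony(tr, dat, method = "fitch")))
})

test_that("exhaustive P-test reproduces the exact quartet probability", {
  pt <- ptest(quartet, c(A = "s1", B = "s1", C = "s2", D = "s2"),
              exhaustive = TRUE)
  expect_equal(pt$observed, 1)
  expect_equal(pt$p, 2 / 6) # only AB|CD and CD|AB labelings give <= 1 change
  # interleaved labels on a ladder: observed changes are maximal, p near 1
  ladder <- ape::read.tree(text = "(((((A:1,B:1):1,C:1):1,D:1):1,E:1):1,F:1);")
  lab <- setNames(rep(c("x", "y"), 3), c("A", "C", "E", "B", "D", "F"))
  pt2 <- ptest(ladder, lab, exhaustive = TRUE)
  expect_gte(pt2$p, 0.9)
  expect_error(ptest(quartet, c(A = "s", B = "s", C = "s", D = "s")),
               "two sources")
})

test_that("NRI matches the exhaustive two-tip enumeration on the quartet", {
  r <- nri_nti(quartet, c("A", "B"), exhaustive = TRUE)
  expect_equal(r$MPD_obs, 2)
  expect_equal(r$null_mean_mpd, 10 / 3)
  expect_equal(r$NRI, -(2 - 10 / 3) / sd(c(2, 2, 4, 4, 4, 4)))
  expect_equal(r$NRI, 1.2910, tolerance = 1e-4)
  # sampled null converges near the exhaustive value; on a pool of only six
  # subsets the n-1 exhaustive sd exceeds the iid sampling sd by sqrt(6/5),
  # so the two agree only up to that small-pool factor
  rs <- nri_nti(quartet, c("A", "B"), n_null = 4000, seed = 11)
  expect_equal(rs$NRI, r$NRI * sqrt(6 / 5), tolerance = 0.03)
})

test_that("degenerate nulls are flagged undefined", {
  # community = pool: the null is the observed community every time
  r <- nri_nti(quartet, c("A", "B", "C", "D"), exhaustive = TRUE)
  expect_true(is.na(r$NRI))
  # star tree: every pairwise distance equal, null sd zero
  star <- ape::read.tree(text = "(A:1,B:1,C:1,D:1);")
  r2 <- nri_nti(star, c("A", "B"), exhaustive = TRUE)
  expect_true(is.na(r2$NRI))
})

test_that("MPD and MNTD agree with picante", {
  skip_if_not_installed("picante")
  set.seed(83)
  tr <- ape::rtree(12)
  comm <- tr$tip.label[1:5]
  r <- nri_nti(tr, comm, n_null = 9, seed = 1)
  m <- matrix(as.integer(tr$tip.label %in% comm), nrow = 1,
              dimnames = list("c1", tr$tip.label))
  dis <- ape::cophenetic.phylo(tr)
  expect_equal(r$MPD_obs, unname(picante::mpd(m, dis)))
  expect_equal(r$MNTD_obs, unname(picante::mntd(m, dis)))
})

test_that("LIBSHUFF vanishes on duplicated libraries and saturates when far", {
  # identical points within and across libraries: full coverage everywhere
  D <- matrix(0, 6, 6, dimnames = list(paste0("s", 1:6), paste0("s", 1:6)))
  r <- libshuff(D, paste0("s", 1:3), paste0("s", 4:6), n_perm = 9, seed = 1)
  expect_equal(r$XY$deltaC, 0)
  expect_equal(r$YX$deltaC, 0)
  # libraries farther apart than the grid maximum
  D2 <- matrix(1, 8, 8, dimnames = list(paste0("t", 1:8), paste0("t", 1:8)))
  D2[1:4, 1:4] <- 0.02; D2[5:8, 5:8] <- 0.02; diag(D2) <- 0
  grid <- seq(0, 0.5, by = 0.01)
  r2 <- libshuff(D2, paste0("t", 1:4), paste0("t", 5:8), grid = grid,
                 n_perm = 9, seed = 1)
  expect_equal(r2$XY$C_XY, rep(0, length(grid)))
  expect_equal(r2$XY$deltaC, sum(r2$XY$C_X^2))
  expect_error(libshuff(D2, paste0("t", 1:4), paste0("t", 4:8)), "disjoint")
})

test_that("LIBSHUFF coverage curves are monotone and match the oracle", {
  set.seed(89)
  pts <- c(rnorm(10, 0, 0.05), rnorm(10, 0.2, 0.05))
  D <- as.matrix(dist(pts))
  ids <- paste0("q", 1:20)
  rownames(D) <- colnames(D) <- ids
  grid <- seq(0, 0.5, by = 0.01)
  r <- libshuff(D, ids[1:10], ids[11:20], grid = grid, n_perm = 19, seed = 1)
  expect_true(all(diff(r$XY$C_X) >= 0))
  expect_true(all(diff(r$XY$C_XY) >= 0))
  expect_true(all(r$XY$C_X >= 0 & r$XY$C_X <= 1))
  expect_equal(r$XY$deltaC, libshuff_oracle(D, ids[1:10], ids[11:20], grid),
               tolerance = 1e-12)
  expect_equal(r$YX$deltaC, libshuff_oracle(D, ids[11:20], ids[1:10], grid),
               tolerance = 1e-12)
})

test_that("AMOVA recovers the boundary fixed points", {
  ids <- paste0("x", 1:6)
  samples <- setNames(ids, ids) # one sequence per sample: two-level design
  sources <- setNames(rep(c("g1", "g2"), each = 3), ids)
  # all identical sequences
  D0 <- matrix(0, 6, 6, dimnames = list(ids, ids))
  a0 <- amova(D0, samples, sources, n_perm = 49, seed = 1)
  expect_equal(a0$F_ST, 0)
  expect_true(a0$degenerate)
  # complete separation: zero within, positive between
  D1 <- matrix(2, 6, 6, dimnames = list(ids, ids))
  D1[1:3, 1:3] <- 0; D1[4:6, 4:6] <- 0
  a1 <- amova(D1, samples, sources, n_perm = 49, seed = 1)
  expect_equal(a1$F_ST, 1)
  # with 3+3 units only 10 distinct splits exist: exact-test floor ~0.1
  expect_lt(a1$p, 0.25)
})

test_that("two-level AMOVA equals the sums-of-squares oracle", {
  set.seed(97)
  pts <- c(rnorm(3, 0), rnorm(3, 1.5))
  D <- as.matrix(dist(pts))
  ids <- paste0("y", 1:6)
  rownames(D) <- colnames(D) <- ids
  groups <- rep(c("a", "b"), each = 3)
  a <- amova(D, setNames(ids, ids), setNames(groups, ids),
             n_perm = 49, seed = 1)
  expect_equal(a$F_ST, amova_two_level_oracle(D, groups), tolerance = 1e-12)
})

test_that("three-level AMOVA partitions variance and permutes samples", {
  set.seed(101)
  # 2 sources x 3 samples x 3 sequences with planted source separation
  ids <- sprintf("z%02d", 1:18)
  samples <- setNames(rep(sprintf("smp%d", 1:6), each = 3), ids)
  sources <- setNames(rep(c("s1", "s2"), each = 3), sprintf("smp%d", 1:6))
  pts <- rnorm(18, rep(c(0, 3), each = 9), 0.3)
  D <- as.matrix(dist(pts)); rownames(D) <- colnames(D) <- ids
  a <- amova(D, samples, sources, n_perm = 99, seed = 2)
  expect_equal(a$design, "three-level")
  expect_gt(a$F_ST, 0.5)
  expect_lt(a$p, 0.25) # only C(6,3)/2 = 10 distinct sample partitions
  expect_equal(length(a$components), 3)
  expect_true(all(a$components >= 0 | a$components[3] >= 0))
})
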