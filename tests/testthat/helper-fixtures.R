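# shared fixture builders and independent oracles

random_dna <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    character(1))
}

# hand-built otu_table (bypasses clustering) for classification/stats tests
toy_otu_table <- function(counts, sources) {
  metadata <- data.frame(sample_id = colnames(counts), source = sources,
                         stringsAsFactors = FALSE)
  structure(list(counts = counts, representative = NULL, members = NULL,
                 metadata = metadata),
            class = "otu_table")
}

# trf_matrix built directly from bin centers and an abundance matrix
toy_trf_matrix <- function(bins, abundance, mode = "relative") {
  colnames(abundance) <- formatC(bins, format = "f", digits = 2)
  structure(list(bins = bins, abundance = abundance, mode = mode,
                 window = 0.5), class = "trf_matrix")
}

# brute-force first-site oracle: test every window position by hand
scan_first_site <- function(seq, recognition) {
  iupac <- list(A = "A", C = "C", G = "G", T = "T",
                R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                B = c("C", "G", "T"), D = c("A", "G", "T"),
                H = c("A", "C", "T"), V = c("A", "C", "G"),
                N = c("A", "C", "G", "T"))
  sq <- strsplit(seq, "")[[1]]
  rec <- strsplit(recognition, "")[[1]]
  k <- length(rec)
  if (length(sq) < k) return(NA_integer_)
  for (start in seq_len(length(sq) - k + 1L)) {
    hit <- TRUE
    for (j in seq_len(k)) {
      if (!sq[start + j - 1L] %in% iupac[[rec[j]]]) { hit <- FALSE; break }
    }
    if (hit) return(start)
  }
  NA_integer_
}

# exhaustive global-alignment identity oracle for short sequences: enumerate
# every alignment, find the max-score one(s), report the best identity among
# score-optimal alignments
enumerate_identity <- function(a, b, match = 1, mismatch = 0, gap = -1) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  best <- new.env(); best$score <- -Inf; best$ident <- 0
  rec <- function(i, j, cols) {
    if (i > length(av) && j > length(bv)) {
      score <- sum(cols == "M") * match + sum(cols == "X") * mismatch +
        sum(cols == "G") * gap
      lo <- 1; hi <- length(cols)
      while (hi >= lo && cols[hi] == "G") hi <- hi - 1
      while (lo <= hi && cols[lo] == "G") lo <- lo + 1
      denom <- hi - lo + 1
      ident <- if (denom <= 0) 0 else
        sum(cols[lo:hi] == "M") / denom
      if (score > best$score ||
          (score == best$score && ident > best$ident)) {
        best$score <- score; best$ident <- ident
      }
      return(invisible())
    }
    if (i <= length(av) && j <= length(bv))
      rec(i + 1, j + 1, c(cols, if (av[i] == bv[j]) "M" else "X"))
    if (i <= length(av)) rec(i + 1, j, c(cols, "G"))
    if (j <= length(bv)) rec(i, j + 1, c(cols, "G"))
  }
  rec(1, 1, character(0))
  best
}

# independent Tajima-Nei formula computation, coded with explicit loops
tajima_nei_oracle <- function(a, b) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  ok <- av %in% c("A", "C", "G", "T") & bv %in% c("A", "C", "G", "T")
  av <- av[ok]; bv <- bv[ok]
  n <- length(av)
  p <- sum(av != bv) / n
  if (p == 0) return(0)
  bases <- c("A", "C", "G", "T")
  g <- numeric(4)
  for (i in 1:4) g[i] <- (sum(av == bases[i]) + sum(bv == bases[i])) / (2 * n)
  h <- 0
  for (i in 1:3) for (j in (i + 1):4) {
    x <- 0
    for (s in seq_len(n))
      if ((av[s] == bases[i] && bv[s] == bases[j]) ||
          (av[s] == bases[j] && bv[s] == bases[i])) x <- x + 1
    x <- x / n
    if (x > 0) h <- h + x^2 / (2 * g[i] * g[j])
  }
  bb <- 0.5 * (1 - sum(g^2) + p^2 / h)
  -bb * log(1 - p / bb)
}

# brute-force parsimony length: enumerate all internal-node state assignments
parsimony_oracle <- function(tree, states) {
  st <- as.character(states[tree$tip.label])
  lv <- unique(st)
  ntip <- length(tree$tip.label)
  nint <- tree$Nnode
  grid <- as.matrix(expand.grid(rep(list(lv), nint), stringsAsFactors = FALSE))
  best <- Inf
  for (r in seq_len(nrow(grid))) {
    node_state <- c(st, grid[r, ])
    changes <- sum(node_state[tree$edge[, 1]] != node_state[tree$edge[, 2]])
    best <- min(best, changes)
  }
  best
}

# direct-formula LIBSHUFF delta-C oracle
libshuff_oracle <- function(D, libA, libB, grid) {
  cx <- cxy <- numeric(length(grid))
  for (k in seq_along(grid)) {
    d <- grid[k]
    covA <- covAB <- 0
    for (x in libA) {
      if (any(D[x, setdiff(libA, x)] <= d)) covA <- covA + 1
      if (any(D[x, libB] <= d)) covAB <- covAB + 1
    }
    cx[k] <- covA / length(libA)
    cxy[k] <- covAB / length(libA)
  }
  sum((cx - cxy)^2)
}

# two-level AMOVA F_ST from raw sums of squares, coded independently
amova_two_level_oracle <- function(D, groups) {
  N <- nrow(D)
  D2 <- D^2
  SS_T <- sum(D2[lower.tri(D2)]) / N
  SS_W <- 0
  for (g in unique(groups)) {
    sel <- which(groups == g)
    sub <- D2[sel, sel, drop = FALSE]
    SS_W <- SS_W + sum(sub[lower.tri(sub)]) / length(sel)
  }
  SS_A <- SS_T - SS_W
  G <- length(unique(groups))
  df_a <- G - 1; df_w <- N - G
  n0 <- (N - sum(table(groups)^2) / N) / df_a
  MS_w <- SS_W / df_w
  s2_a <- (SS_A / df_a - MS_w) / n0
  s2_a / (s2_a + MS_w)
}
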