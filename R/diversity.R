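#' Alpha diversity of one sample
#'
#' Observed richness, singleton/doubleton counts, Chao1 expected richness,
#' Shannon diversity (natural log) and Pielou evenness `J = H' / ln(S_obs)`.
#' Chao1 uses the classic estimator `S_obs + F1^2 / (2 F2)` when doubletons
#' exist and the bias-corrected form `S_obs + F1 (F1 - 1) / (2 (F2 + 1))`
#' when `F2 = 0`. Evenness is undefined (reported `NA`) when only one OTU
#' is observed.
#'
#' @param counts Non-negative integer vector of per-OTU counts for one
#'   sample (zeros allowed and ignored).
#' @param base Logarithm base for Shannon (default natural log).
#' @return List with `S_obs`, `F1`, `F2`, `S_chao1`, `H_prime`, `J`.
#' @export
alpha_diversity <- function(counts, base = exp(1)) {
  counts <- counts[counts > 0]
  if (length(counts) == 0L) stop("all-zero count vector")
  S <- length(counts)
  F1 <- sum(counts == 1L)
  F2 <- sum(counts == 2L)
  chao1 <- if (F2 > 0) S + F1^2 / (2 * F2) else S + F1 * (F1 - 1) / (2 * (F2 + 1))
  p <- counts / sum(counts)
  H <- -sum(p * log(p, base = base))
  J <- if (S >= 2) H / log(S, base = base) else NA_real_
  list(S_obs = S, F1 = F1, F2 = F2, S_chao1 = chao1, H_prime = H, J = J)
}

#' Alpha diversity for every sample of an OTU table
#'
#' @param table An `otu_table`, or a counts matrix (rows = OTUs).
#' @return data.frame, one row per sample.
#' @export
alpha_diversity_table <- function(table) {
  counts <- if (inherits(table, "otu_table")) table$counts else table
  out <- do.call(rbind, lapply(colnames(counts), function(s) {
    a <- alpha_diversity(counts[, s])
    data.frame(sample_id = s, S_obs = a$S_obs, F1 = a$F1, F2 = a$F2,
               S_chao1 = a$S_chao1, H_prime = a$H_prime, J = a$J)
  }))
  rownames(out) <- NULL
  out
}

#' Analytic rarefaction curve
#'
#' Expected number of OTUs observed in a random subsample of `m` clones,
#' from the hypergeometric expectation
#' `E[S_m] = sum_i (1 - choose(N - N_i, m) / choose(N, m))`.
#'
#' @param counts Non-negative integer vector of per-OTU counts.
#' @param depths Integer subsample sizes, each `<= sum(counts)`.
#' @return Numeric vector of expected richness, one value per depth.
#' @export
rarefaction_curve <- function(counts, depths) {
  counts <- counts[counts > 0]
  N <- sum(counts)
  if (any(depths > N)) stop("rarefaction depth exceeds sample size")
  vapply(depths, function(m) {
    # lchoose avoids overflow; choose(N - Ni, m) = 0 when N - Ni < m
    sum(1 - ifelse(N - counts < m, 0,
                   exp(lchoose(N - counts, m) - lchoose(N, m))))
  }, numeric(1))
}
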