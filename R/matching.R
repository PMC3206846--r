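#' Size-dependent tolerance bins
#'
#' Discrepancies between electrophoretically measured and sequence-predicted
#' fragment sizes (T-RF drift) grow with fragment length, so matching uses an
#' increasing window of size tolerances: by default 1.0 bp for T-RFs up to
#' 200 bp, 1.5 bp for 201-400 bp, and 4.0 bp above 400 bp. Boundary sizes
#' (exactly 200 or 400) take the smaller tolerance.
#'
#' @param rules Two-column matrix or data.frame: upper size bound (bp,
#'   strictly increasing, last may be `Inf`) and tolerance (bp, > 0).
#' @return An object of class `tolerance_bins`.
#' @export
tolerance_bins <- function(rules = cbind(bound = c(200, 400, Inf),
                                         tolerance = c(1.0, 1.5, 4.0))) {
  rules <- as.matrix(rules)
  if (is.unsorted(rules[, 1], strictly = TRUE))
    stop("bounds must be strictly increasing")
  if (any(rules[, 2] <= 0)) stop("tolerances must be positive")
  structure(list(bound = rules[, 1], tolerance = rules[, 2]),
            class = "tolerance_bins")
}

#' @rdname tolerance_bins
#' @param size T-RF size(s) in bp.
#' @param bins A `tolerance_bins` object.
#' @return `tolerance_for`: tolerance (bp) of the first rule whose bound
#'   covers the size.
#' @export
tolerance_for <- function(size, bins = tolerance_bins()) {
  stopifnot(all(size >= 0))
  idx <- vapply(size, function(s) which(bins$bound >= s)[1L], integer(1))
  unname(bins$tolerance[idx])
}

#' Match empirical T-RFs to reference predictions
#'
#' An OTU matches an empirical consensus bin under an enzyme when its
#' predicted T-RF is inside the detection window and the bin center lies
#' within the size-dependent tolerance of the prediction. When several bins
#' qualify, the nearest wins; exact ties go to the smaller size.
#'
#' @param db A `trf_reference` ([build_reference_db()]).
#' @param matrices Named list of `trf_matrix` objects, names = enzyme names
#'   (must all exist in the reference database).
#' @param bins A `tolerance_bins` object.
#' @return An object of class `trf_matches`: list with `matched` (numeric
#'   matrix OTUs x enzymes of matched bin centers, `NA` = unmatched),
#'   `per_trf` (list enzyme -> list bin center -> matching OTU ids) and the
#'   inputs used.
#' @export
match_trfs <- function(db, matrices, bins = tolerance_bins()) {
  stopifnot(inherits(db, "trf_reference"))
  bad <- setdiff(names(matrices), colnames(db$trf))
  if (length(bad)) stop("enzyme absent from reference database: ", bad[1L])
  otus <- rownames(db$trf)
  matched <- matrix(NA_real_, length(otus), length(matrices),
                    dimnames = list(otus, names(matrices)))
  per_trf <- list()
  for (e in names(matrices)) {
    centers <- matrices[[e]]$bins
    hits <- vector("list", length(centers))
    for (o in otus) {
      pred <- db$trf[o, e]
      if (is.na(pred) || !db$in_window[o, e]) next
      tol <- tolerance_for(pred, bins)
      d <- abs(centers - pred)
      cand <- which(d <= tol)
      if (!length(cand)) next
      best <- cand[order(d[cand], centers[cand])][1L]
      matched[o, e] <- centers[best]
      hits[[best]] <- c(hits[[best]], o)
    }
    names(hits) <- formatC(centers, format = "f", digits = 2)
    per_trf[[e]] <- hits
  }
  structure(list(matched = matched, per_trf = per_trf, bins = bins),
            class = "trf_matches")
}

#' Build per-phylotype T-RFLP signatures and classify their resolution
#'
#' A phylotype's T-RFLP signature is the set of matched (enzyme, consensus
#' T-RF) pairs. Its resolution is `unique` when no other phylotype carries
#' the identical set, `shared` when at least one other does, and
#' `undetected` when the set is empty.
#'
#' @param matches A `trf_matches` object.
#' @return An object of class `trf_signatures`: data.frame with one row per
#'   OTU (`otu_id`, `signature` as a canonical string, `n_enzymes_matched`,
#'   `resolution`) plus a `summary` attribute with counts per resolution
#'   class, counts per number of enzymes matched, and the mean +/- SE number
#'   of phylotypes per shared signature.
#' @export
build_signatures <- function(matches) {
  stopifnot(inherits(matches, "trf_matches"))
  m <- matches$matched
  sig <- apply(m, 1L, function(r) {
    hit <- !is.na(r)
    if (!any(hit)) return("")
    paste(colnames(m)[hit], formatC(r[hit], format = "f", digits = 2),
          sep = ":", collapse = ";")
  })
  n_enz <- rowSums(!is.na(m))
  multiplicity <- table(sig[sig != ""])
  resolution <- ifelse(sig == "", "undetected",
                       ifelse(multiplicity[sig] > 1L, "shared", "unique"))
  df <- data.frame(otu_id = rownames(m), signature = sig,
                   n_enzymes_matched = n_enz, resolution = resolution,
                   row.names = NULL, stringsAsFactors = FALSE)
  shared_sizes <- as.integer(multiplicity[multiplicity > 1L])
  summary <- list(
    n_unique = sum(df$resolution == "unique"),
    n_shared = sum(df$resolution == "shared"),
    n_undetected = sum(df$resolution == "undetected"),
    by_n_enzymes = table(factor(df$n_enzymes_matched, levels = 0:ncol(m))),
    otus_per_shared_signature = if (length(shared_sizes))
      c(mean = mean(shared_sizes),
        se = sd(shared_sizes) / sqrt(length(shared_sizes)))
    else c(mean = NA_real_, se = NA_real_)
  )
  attr(df, "summary") <- summary
  class(df) <- c("trf_signatures", "data.frame")
  df
}

#' @export
print.trf_signatures <- function(x, ...) {
  s <- attr(x, "summary")
  n <- nrow(x)
  cat("T-RFLP signatures for", n, "phylotypes:\n")
  cat(sprintf("  unique     %3d (%.1f%%)\n", s$n_unique, 100 * s$n_unique / n))
  cat(sprintf("  shared     %3d (%.1f%%)\n", s$n_shared, 100 * s$n_shared / n))
  cat(sprintf("  undetected %3d (%.1f%%)\n",
              s$n_undetected, 100 * s$n_undetected / n))
  invisible(x)
}

#' Sequence divergence within shared-signature groups
#'
#' For each group of phylotypes carrying an identical non-empty signature,
#' computes the mean pairwise sequence divergence
#' `(1 - pairwise_identity) * 100` over all within-group pairs; reports the
#' grand mean and standard error over group means, overall and stratified by
#' the number of enzymes matched.
#'
#' @param signatures A `trf_signatures` object.
#' @param seqs Named character vector holding a representative sequence per
#'   OTU id.
#' @return List with `overall` (`mean`, `se`, `n_groups`) and `by_n_enzymes`
#'   (data.frame stratified by enzymes matched).
#' @export
shared_signature_divergence <- function(signatures, seqs) {
  sh <- signatures[signatures$resolution == "shared", , drop = FALSE]
  if (!all(sh$otu_id %in% names(seqs)))
    stop("missing representative sequence for shared phylotype")
  groups <- split(sh, sh$signature)
  gmeans <- vapply(groups, function(g) {
    prs <- combn(g$otu_id, 2)
    mean(apply(prs, 2, function(p)
      (1 - pairwise_identity(seqs[[p[1]]], seqs[[p[2]]])) * 100))
  }, numeric(1))
  genz <- vapply(groups, function(g) g$n_enzymes_matched[1L], numeric(1))
  strat <- do.call(rbind, lapply(sort(unique(genz)), function(k) {
    v <- gmeans[genz == k]
    data.frame(n_enzymes = k, n_groups = length(v), mean = mean(v),
               se = if (length(v) > 1) sd(v) / sqrt(length(v)) else NA_real_)
  }))
  list(overall = c(mean = mean(gmeans),
                   se = if (length(gmeans) > 1)
                     sd(gmeans) / sqrt(length(gmeans)) else NA_real_,
                   n_groups = length(gmeans)),
       by_n_enzymes = strat)
}

#' Goodness-of-fit G test for taxonomic recovery bias
#'
#' Compares the taxon frequencies among phylotypes recovered by T-RFLP
#' matching with the frequencies expected from the full clone library:
#' `G = 2 * sum(O * ln(O / E))` with `E` = reference proportions scaled to
#' the matched total; zero observed cells contribute nothing;
#' `df = categories - 1`; p from the upper chi-square tail.
#'
#' @param observed Named integer vector of taxon counts among matched
#'   phylotypes.
#' @param reference Named integer vector of taxon counts in the full library
#'   (same category universe, all > 0).
#' @return A `g_test` object: list with `G`, `df`, `p`, `observed`,
#'   `expected`.
#' @export
taxonomic_bias_gtest <- function(observed, reference) {
  if (!setequal(names(observed), names(reference)))
    stop("observed and reference must share the same category universe")
  reference <- reference[names(observed)]
  if (any(reference <= 0)) stop("reference counts must all be positive")
  n <- sum(observed)
  if (n == 0) stop("no matched phylotypes: G test undefined")
  E <- reference / sum(reference) * n
  nz <- observed > 0
  G <- 2 * sum(observed[nz] * log(observed[nz] / E[nz]))
  df <- length(observed) - 1L
  structure(list(G = G, df = df, p = pchisq(G, df, lower.tail = FALSE),
                 observed = observed, expected = E, type = "goodness-of-fit"),
            class = "g_test")
}

#' @export
print.g_test <- function(x, ...) {
  cat(sprintf("Likelihood-ratio G test (%s): G = %.2f, df = %d, P = %.3g\n",
              x$type, x$G, x$df, x$p))
  invisible(x)
}
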