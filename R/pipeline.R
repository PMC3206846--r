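#' Run the clone-library / T-RFLP profiling workflow
#'
#' Convenience wrapper chaining the analysis stages on in-memory inputs:
#' OTU clustering of the clone sequences, count-table construction,
#' reference T-RF prediction from the OTU representatives, per-enzyme
#' standardization and alignment of the electropherogram peaks, matching of
#' empirical T-RFs against the predictions, and signature construction.
#'
#' @param clones Named character vector of clone sequences.
#' @param sample_of Named character vector: clone id -> sample id.
#' @param metadata Sample metadata data.frame (`sample_id`, `source`, ...).
#' @param peaks Peak data.frame (`sample_id`, `enzyme`, `size_bp`,
#'   `fluorescence`), or `NULL` to skip the fingerprint stages.
#' @param identity OTU identity threshold.
#' @param enzymes Enzyme names for digestion and matching.
#' @param window Detection window in bp.
#' @param align_window T-RF alignment window in bp.
#' @param bins [tolerance_bins()] for matching.
#' @param mode Abundance mode for the aligned matrices.
#' @return List with `clustering`, `table`, `db` and, when peaks are given,
#'   `threshold_pct`, `matrices`, `matches`, `signatures`.
#' @export
profile_communities <- function(clones, sample_of, metadata, peaks = NULL,
                                identity = 0.99,
                                enzymes = c("HaeIII", "MspI", "RsaI"),
                                window = .default_window,
                                align_window = 0.5,
                                bins = tolerance_bins(),
                                mode = "relative") {
  clustering <- cluster_otus(clones, identity)
  table <- build_otu_table(clustering, metadata, sample_of)
  db <- build_reference_db(clustering$representative, enzymes,
                           window = window)
  out <- list(clustering = clustering, table = table, db = db)
  if (!is.null(peaks)) {
    matrices <- list()
    thresholds <- numeric(0)
    for (e in intersect(enzymes, unique(peaks$enzyme))) {
      filt <- variable_threshold_standardize(peaks[peaks$enzyme == e, ],
                                             window = window)
      thresholds[e] <- filt$threshold_pct
      matrices[[e]] <- align_trfs(filt$peaks, window = align_window,
                                  mode = mode,
                                  samples = metadata$sample_id)
    }
    out$threshold_pct <- thresholds
    out$matrices <- matrices
    out$matches <- match_trfs(db, matrices, bins)
    out$signatures <- build_signatures(out$matches)
  }
  out
}
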