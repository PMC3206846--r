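#' Pairwise sequence identity
#'
#' Fraction of identical columns among the aligned columns of a global
#' pairwise alignment (Needleman-Wunsch; match 1, mismatch 0, linear gap -1).
#' Terminal gap columns are excluded from the denominator — the clone
#' sequences are uniformly trimmed, so end overhangs are artifacts — while
#' internal gap columns count as mismatches. Symmetric in its arguments.
#'
#' @param a,b Nucleotide strings.
#' @param match,mismatch,gap Alignment scores.
#' @return Identity fraction in `[0, 1]`.
#' @export
pairwise_identity <- function(a, b, match = 1, mismatch = 0, gap = -1) {
  if (!nzchar(a) || !nzchar(b)) stop("empty sequence")
  if (a == b) return(1)
  .nw_identity_cpp(a, b, match, mismatch, gap)
}

#' Cluster sequences into OTUs by greedy centroid clustering
#'
#' Sequences are dereplicated, then processed in order of decreasing
#' duplicate abundance (ties broken lexicographically by id). Each sequence
#' joins the first existing centroid whose identity with it is at least
#' `threshold`; otherwise it founds a new OTU with itself as representative.
#' Deterministic for a fixed input.
#'
#' @param seqs Named character vector of sequences.
#' @param threshold Identity threshold in `(0, 1]` (default 0.99, the
#'   phylotype definition used throughout the package).
#' @return An object of class `otu_clustering`: list with `otu_ids`,
#'   `representative` (named character vector of centroid sequences),
#'   `assignment` (named character vector: sequence id -> OTU id) and
#'   `members` (list OTU id -> member sequence ids).
#' @export
cluster_otus <- function(seqs, threshold = 0.99) {
  stopifnot(length(seqs) >= 1, threshold > 0, threshold <= 1)
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    stop("sequences must carry unique ids")

  # dereplicate: identical sequences always co-cluster
  uniq <- split(names(seqs), factor(seqs, levels = unique(seqs)))
  rep_id <- vapply(uniq, function(ids) sort(ids)[1L], character(1))
  abund <- lengths(uniq)
  ord <- order(-abund, rep_id)
  useq <- names(uniq)[ord]       # the unique sequences, processing order
  uids <- unname(rep_id[ord])    # id of the lexicographically first carrier

  centroid_seq <- character(0)
  centroid_id <- character(0)
  assign_centroid <- integer(length(useq))
  for (i in seq_along(useq)) {
    hit <- 0L
    for (j in seq_along(centroid_seq)) {
      if (pairwise_identity(useq[i], centroid_seq[j]) >= threshold) {
        hit <- j; break
      }
    }
    if (hit == 0L) {
      centroid_seq <- c(centroid_seq, useq[i])
      centroid_id <- c(centroid_id, uids[i])
      hit <- length(centroid_seq)
    }
    assign_centroid[i] <- hit
  }

  otu_ids <- sprintf("OTU%03d", seq_along(centroid_id))
  assignment <- character(0)
  for (i in seq_along(useq)) {
    ids <- uniq[[which(names(uniq) == useq[i])]]
    assignment[ids] <- otu_ids[assign_centroid[i]]
  }
  assignment <- assignment[names(seqs)] # input order
  members <- split(names(assignment), factor(assignment, levels = otu_ids))
  structure(list(otu_ids = otu_ids,
                 representative = setNames(centroid_seq, otu_ids),
                 representative_id = setNames(centroid_id, otu_ids),
                 assignment = assignment,
                 members = members,
                 threshold = threshold),
            class = "otu_clustering")
}

#' @export
print.otu_clustering <- function(x, ...) {
  cat("OTU clustering:", length(x$assignment), "sequences ->",
      length(x$otu_ids), "OTUs at", x$threshold * 100, "% identity\n")
  invisible(x)
}

#' Build the sample x OTU count table
#'
#' @param clustering An `otu_clustering`.
#' @param metadata Sample metadata data.frame ([read_sample_metadata()]).
#' @param sample_of Named character vector mapping sequence id -> sample id.
#' @return An object of class `otu_table`: list with `counts` (integer
#'   matrix, rows = OTUs, columns = samples), `representative`, `members`
#'   and `metadata`. Row/column conservation: `sum(counts)` equals the
#'   number of clustered sequences and no OTU row is all-zero.
#' @export
build_otu_table <- function(clustering, metadata, sample_of) {
  stopifnot(inherits(clustering, "otu_clustering"))
  ids <- names(clustering$assignment)
  if (!all(ids %in% names(sample_of)))
    stop("sequence(s) without a sample assignment: ",
         setdiff(ids, names(sample_of))[1L])
  smp <- sample_of[ids]
  unknown <- setdiff(unique(smp), metadata$sample_id)
  if (length(unknown))
    stop("sequence mapped to sample absent from metadata: ", unknown[1L])
  counts <- table(factor(clustering$assignment, levels = clustering$otu_ids),
                  factor(smp, levels = metadata$sample_id))
  counts <- matrix(as.integer(counts), nrow = length(clustering$otu_ids),
                   dimnames = list(clustering$otu_ids, metadata$sample_id))
  structure(list(counts = counts,
                 representative = clustering$representative,
                 members = clustering$members,
                 metadata = metadata),
            class = "otu_table")
}

#' @export
print.otu_table <- function(x, ...) {
  cat("OTU table:", nrow(x$counts), "OTUs x", ncol(x$counts), "samples,",
      sum(x$counts), "clones\n")
  src <- table(x$metadata$source)
  cat("Sources:", paste(names(src), src, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Pool OTU counts by source group
#'
#' @param table An `otu_table`.
#' @return Integer matrix, rows = OTUs, columns = source groups.
#' @export
pool_by_source <- function(table) {
  stopifnot(inherits(table, "otu_table"))
  src <- table$metadata$source[match(colnames(table$counts),
                                     table$metadata$sample_id)]
  out <- vapply(unique(src), function(s)
    rowSums(table$counts[, src == s, drop = FALSE]),
    numeric(nrow(table$counts)))
  m <- matrix(as.integer(out), nrow = nrow(table$counts),
              dimnames = list(rownames(table$counts), unique(src)))
  m
}
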