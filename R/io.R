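#' Read a FASTA file of 16S rRNA gene sequences
#'
#' Sequences are uppercased on read and RNA `U` is mapped to `T`, since all
#' downstream operations (restriction digestion, identity clustering) work on
#' the DNA alphabet. Records must have unique, non-empty ids and contain only
#' IUPAC nucleotide codes.
#'
#' @param path Path to a FASTA file.
#' @return A named character vector of sequences; names are record ids, in
#'   file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L || !startsWith(lines[[1L]], ">"))
    stop("not a FASTA file (no '>' header on first line): ", path)
  hdr <- grepl("^>", lines)
  ids <- sub("^>\\s*", "", lines[hdr])
  ids <- sub("\\s.*$", "", ids)
  if (any(!nzchar(ids)))
    stop("empty record id in ", path, " (line ",
         which(hdr)[!nzchar(ids)][1L], ")")
  if (anyDuplicated(ids))
    stop("duplicate record id in ", path, ": ",
         ids[duplicated(ids)][1L])
  grp <- cumsum(hdr)
  seqs <- vapply(split(lines[!hdr], grp[!hdr]),
                 function(x) paste(x, collapse = ""), character(1))
  out <- setNames(character(length(ids)), ids)
  out[as.integer(names(seqs))] <- seqs
  out <- toupper(out)
  out <- chartr("U", "T", out)
  if (any(!nzchar(out)))
    stop("empty sequence for record '", ids[!nzchar(out)][1L], "' in ", path)
  bad <- grepl("[^ACGTRYSWKMBDHVN]", out)
  if (any(bad)) {
    offender <- regmatches(out[bad][1L],
                           regexpr("[^ACGTRYSWKMBDHVN]", out[bad][1L]))
    stop("non-IUPAC character '", offender, "' in record '",
         ids[bad][1L], "' of ", path)
  }
  out
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width in bases.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read a sample metadata table
#'
#' Tab-separated with a header row; `sample_id` and `source` columns are
#' mandatory (`source` is the isolation group, e.g. a host species or
#' `"seawater"`); any further columns (location, clone counts, ...) are kept.
#'
#' @param path Path to a TSV file.
#' @return A data.frame, one row per sample.
#' @export
read_sample_metadata <- function(path) {
  if (!file.exists(path)) stop("metadata file not found: ", path)
  md <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                   fileEncoding = "UTF-8")
  for (col in c("sample_id", "source"))
    if (!col %in% names(md))
      stop("metadata file ", path, " lacks mandatory column '", col, "'")
  if (anyDuplicated(md$sample_id))
    stop("duplicate sample_id in ", path, ": ",
         md$sample_id[duplicated(md$sample_id)][1L])
  if (any(!nzchar(md$source)))
    stop("empty source label in ", path)
  md
}

#' Write a sample metadata table
#' @param metadata data.frame as returned by [read_sample_metadata()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sample_metadata <- function(metadata, path) {
  write.table(metadata, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a T-RFLP peak table
#'
#' Accepts comma- or tab-separated tables (auto-detected from the header
#' line, since electropherogram exports vary) with columns `sample_id`,
#' `enzyme`, `size_bp` and `fluorescence`. Rows are grouped into one profile
#' per (sample, enzyme) and peaks are sorted ascending by size.
#'
#' @param path Path to the peak table.
#' @return A data.frame with columns `sample_id`, `enzyme`, `size_bp`,
#'   `fluorescence`, sorted by sample, enzyme, size.
#' @export
read_peak_table <- function(path) {
  if (!file.exists(path)) stop("peak table not found: ", path)
  hdr <- readLines(path, n = 1L, warn = FALSE, encoding = "UTF-8")
  sep <- if (grepl("\t", hdr)) "\t" else ","
  pk <- read.delim(path, sep = sep, stringsAsFactors = FALSE,
                   fileEncoding = "UTF-8")
  need <- c("sample_id", "enzyme", "size_bp", "fluorescence")
  miss <- setdiff(need, names(pk))
  if (length(miss))
    stop("peak table ", path, " lacks column(s): ",
         paste(miss, collapse = ", "))
  pk$size_bp <- round(as.numeric(pk$size_bp), 2) # 0.01 bp sizing precision
  pk$fluorescence <- as.numeric(pk$fluorescence)
  if (any(!is.finite(pk$size_bp)) || any(pk$size_bp < 0))
    stop("negative or non-numeric size_bp in ", path)
  if (any(!is.finite(pk$fluorescence)) || any(pk$fluorescence < 0))
    stop("negative or non-numeric fluorescence in ", path)
  key <- paste(pk$sample_id, pk$enzyme, pk$size_bp)
  if (anyDuplicated(key))
    stop("duplicate (sample, enzyme, size) row in ", path, ": ",
         key[duplicated(key)][1L])
  pk[order(pk$sample_id, pk$enzyme, pk$size_bp), need]
}

#' Write a T-RFLP peak table (CSV)
#' @param peaks data.frame as returned by [read_peak_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peak_table <- function(peaks, path) {
  write.table(peaks, path, sep = ",", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a newick tree
#'
#' Thin wrapper over [ape::read.tree()] that validates branch lengths and,
#' optionally, tip labels against a known id universe (unknown tips warn but
#' do not fail, so trees built on supersets of the study sequences can be
#' consumed).
#'
#' @param path Path to a newick file.
#' @param ids Optional character vector of known sequence/OTU ids.
#' @return An [ape::phylo] tree.
#' @export
read_newick <- function(path, ids = NULL) {
  if (!file.exists(path)) stop("tree file not found: ", path)
  tree <- tryCatch(ape::read.tree(path),
                   error = function(e) stop("malformed newick in ", path,
                                            ": ", conditionMessage(e)))
  if (is.null(tree)) stop("malformed newick in ", path)
  if (!is.null(tree$edge.length) && any(tree$edge.length < 0))
    stop("negative branch length in ", path)
  if (!is.null(ids)) {
    unknown <- setdiff(tree$tip.label, ids)
    if (length(unknown))
      warning("tree tips absent from the supplied id universe: ",
              paste(utils::head(unknown, 5), collapse = ", "))
  }
  tree
}

#' Write a tree to newick
#' @param tree An [ape::phylo] tree.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Read / write an OTU count table
#'
#' TSV layout: first column `otu_id`, remaining columns one per sample,
#' integer counts.
#'
#' @param path Path to the table.
#' @return Integer matrix, rows = OTUs, columns = samples.
#' @export
read_otu_table <- function(path) {
  tb <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                   fileEncoding = "UTF-8")
  if (names(tb)[1L] != "otu_id") stop("first column must be otu_id: ", path)
  m <- as.matrix(tb[, -1L, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- tb$otu_id
  if (any(m < 0)) stop("negative count in ", path)
  m
}

#' @rdname read_otu_table
#' @param counts Integer matrix, rows = OTUs, columns = samples.
#' @export
write_otu_table <- function(counts, path) {
  df <- data.frame(otu_id = rownames(counts), counts, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}
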