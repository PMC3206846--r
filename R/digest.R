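#' Restriction enzymes
#'
#' Built-in enzyme definitions for the three endonucleases used in the
#' workflow: HaeIII (GG^CC), MspI (C^CGG) and RsaI (GT^AC). `cut_offset` is
#' the number of recognition-site bases retained on the 5'-labeled fragment.
#'
#' @param name Enzyme name. One of the built-ins, or supply `recognition` and
#'   `cut_offset` for a custom enzyme.
#' @param recognition IUPAC recognition sequence (length >= 4).
#' @param cut_offset Integer in `[0, nchar(recognition)]`.
#' @return An object of class `restriction_enzyme`.
#' @export
restriction_enzyme <- function(name, recognition = NULL, cut_offset = NULL) {
  builtin <- list(
    HaeIII = list(recognition = "GGCC", cut_offset = 2L),
    MspI   = list(recognition = "CCGG", cut_offset = 1L),
    RsaI   = list(recognition = "GTAC", cut_offset = 2L)
  )
  if (is.null(recognition)) {
    if (!name %in% names(builtin))
      stop("unknown enzyme '", name,
           "'; supply recognition and cut_offset for custom enzymes")
    recognition <- builtin[[name]]$recognition
    cut_offset <- builtin[[name]]$cut_offset
  }
  recognition <- toupper(recognition)
  if (nchar(recognition) < 4L) stop("recognition site must be >= 4 bases")
  if (cut_offset < 0L || cut_offset > nchar(recognition))
    stop("cut_offset must lie within the recognition site")
  structure(list(name = name, recognition = recognition,
                 cut_offset = as.integer(cut_offset)),
            class = "restriction_enzyme")
}

#' @export
print.restriction_enzyme <- function(x, ...) {
  site <- paste0(substr(x$recognition, 1, x$cut_offset), "^",
                 substr(x$recognition, x$cut_offset + 1, nchar(x$recognition)))
  cat("Restriction enzyme", x$name, " site:", site, "\n")
  invisible(x)
}

# IUPAC expansions for recognition-site bases. Degenerate codes in the
# *sequence* (including N) never match any recognition base: a conservative
# rule that prevents phantom cut sites in ambiguous reads.
.iupac <- list(A = "A", C = "C", G = "G", T = "T",
               R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
               W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
               B = c("C", "G", "T"), D = c("A", "G", "T"),
               H = c("A", "C", "T"), V = c("A", "C", "G"),
               N = c("A", "C", "G", "T"))

.revcomp <- function(s) {
  chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN",
         paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

#' Find the first occurrence of a recognition site
#'
#' Scans the sense strand 5'->3' and returns the 1-based start position of
#' the earliest site match, or `NA` if the sequence carries no site.
#' Degenerate IUPAC codes in the recognition sequence expand; degenerate
#' codes in the scanned sequence never match. All three built-in sites are
#' palindromic, so a sense-strand scan suffices; for non-palindromic custom
#' enzymes both strands are scanned and the earlier labeled-strand cut wins.
#'
#' @param seq A nucleotide string.
#' @param enzyme A [restriction_enzyme()].
#' @return Integer position or `NA_integer_`.
#' @export
find_first_site <- function(seq, enzyme) {
  stopifnot(inherits(enzyme, "restriction_enzyme"))
  pos <- .first_site_one_strand(toupper(seq), enzyme$recognition)
  if (enzyme$recognition != .revcomp(enzyme$recognition)) {
    # non-palindromic: the complementary-strand site cuts the labeled strand
    # at the mirrored offset; report whichever labeled cut comes first
    pos2 <- .first_site_one_strand(toupper(seq), .revcomp(enzyme$recognition))
    if (!is.na(pos2) && (is.na(pos) || pos2 < pos)) pos <- pos2
  }
  pos
}

.first_site_one_strand <- function(seq, recognition) {
  n <- nchar(seq)
  k <- nchar(recognition)
  if (n < k) return(NA_integer_)
  sq <- strsplit(seq, "")[[1]]
  rec <- strsplit(recognition, "")[[1]]
  # per recognition position, logical vector over the sequence of allowed
  # bases; windowed AND vectorized over start positions
  ok <- vapply(rec, function(r) sq %in% .iupac[[r]], logical(n))
  match_all <- rep(TRUE, n - k + 1L)
  for (j in seq_len(k)) match_all <- match_all & ok[(j:(n - k + j)), j]
  w <- which(match_all)
  if (length(w)) w[1L] else NA_integer_
}

#' Predict the 5'-terminal restriction fragment length
#'
#' The labeled fragment runs from the first base of the sequence to the cut
#' position of the earliest recognition site: length =
#' `(site start - 1) + cut_offset + primer_offset`. `primer_offset` shifts
#' predictions into the coordinate frame of the labeled PCR primer when the
#' supplied sequences are trimmed downstream of it (default 0: predict from
#' the first supplied base).
#'
#' @inheritParams find_first_site
#' @param primer_offset Integer bp added to every prediction.
#' @return Integer fragment length in bp, or `NA` when no site exists.
#' @export
predict_trf <- function(seq, enzyme, primer_offset = 0L) {
  pos <- find_first_site(seq, enzyme)
  if (is.na(pos)) return(NA_integer_)
  as.integer(pos - 1L + enzyme$cut_offset + primer_offset)
}

#' Is a predicted T-RF within the accurate sizing range?
#'
#' Capillary sizing against the internal standard is only accurate inside a
#' bounded range (default 100-500 bp, both ends inclusive); `NA` ("no site")
#' is never in-window.
#'
#' @param trf Numeric T-RF length(s) in bp; `NA` allowed.
#' @param window Length-2 numeric `c(min, max)`.
#' @return Logical vector.
#' @export
in_window <- function(trf, window = .default_window) {
  !is.na(trf) & trf >= window[1] & trf <= window[2]
}

#' Build the reference T-RF database
#'
#' Predicts the terminal fragment of every OTU representative for every
#' enzyme, forming the complete OTU x enzyme prediction grid together with
#' in-window flags and per-enzyme summary statistics (how many phylotypes
#' carry an in-window prediction for each enzyme, and for at least one).
#'
#' @param reps Named character vector of OTU representative sequences.
#' @param enzymes Character vector of enzyme names, or a list of
#'   [restriction_enzyme()] objects.
#' @param window Detection window in bp.
#' @param primer_offset Integer bp added to all predictions.
#' @return An object of class `trf_reference` with elements `trf` (integer
#'   matrix OTUs x enzymes, `NA` = no site), `in_window` (logical matrix),
#'   `window`, `primer_offset` and `summary`.
#' @export
build_reference_db <- function(reps, enzymes = c("HaeIII", "MspI", "RsaI"),
                               window = .default_window, primer_offset = 0L) {
  stopifnot(length(reps) >= 1, length(enzymes) >= 1)
  if (anyDuplicated(names(reps)))
    stop("duplicate OTU ids: ", names(reps)[duplicated(names(reps))][1L])
  if (is.character(enzymes)) enzymes <- lapply(enzymes, restriction_enzyme)
  enames <- vapply(enzymes, `[[`, character(1), "name")
  trf <- vapply(enzymes, function(e)
    vapply(reps, predict_trf, integer(1), enzyme = e,
           primer_offset = primer_offset),
    integer(length(reps)))
  trf <- matrix(trf, nrow = length(reps),
                dimnames = list(names(reps), enames))
  inw <- in_window(trf, window)
  dim(inw) <- dim(trf); dimnames(inw) <- dimnames(trf)
  summary <- data.frame(
    enzyme = enames,
    n_in_window = colSums(inw),
    frac_in_window = colSums(inw) / nrow(inw),
    row.names = NULL
  )
  structure(list(trf = trf, in_window = inw, window = window,
                 primer_offset = as.integer(primer_offset),
                 summary = summary,
                 n_any_enzyme = sum(rowSums(inw) > 0),
                 n_no_enzyme = sum(rowSums(inw) == 0)),
            class = "trf_reference")
}

#' @export
print.trf_reference <- function(x, ...) {
  cat("Reference T-RF database:", nrow(x$trf), "phylotypes x",
      ncol(x$trf), "enzymes\n")
  cat("Detection window:", x$window[1], "-", x$window[2], "bp",
      " primer offset:", x$primer_offset, "bp\n")
  print(x$summary, row.names = FALSE)
  cat("In-window for >=1 enzyme:", x$n_any_enzyme, "of", nrow(x$trf),
      sprintf("(%.1f%%)\n", 100 * x$n_any_enzyme / nrow(x$trf)))
  invisible(x)
}

#' Write / read the reference database as JSON
#'
#' Keys are sorted so that identical inputs give byte-identical files.
#'
#' @param db A `trf_reference`.
#' @param path Output path.
#' @return `path` (write) or a `trf_reference` (read).
#' @export
write_reference_db <- function(db, path) {
  ord <- order(rownames(db$trf))
  entries <- lapply(setNames(ord, rownames(db$trf)[ord]), function(i) {
    lapply(setNames(seq_len(ncol(db$trf)), colnames(db$trf)), function(j)
      list(trf = if (is.na(db$trf[i, j])) NULL else unname(db$trf[i, j]),
           in_window = unname(db$in_window[i, j])))
  })
  jsonlite::write_json(
    list(entries = entries,
         params = list(window = db$window,
                       primer_offset = db$primer_offset)),
    path, auto_unbox = TRUE, null = "null", digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_reference_db
#' @export
read_reference_db <- function(path) {
  js <- jsonlite::read_json(path)
  otus <- names(js$entries)
  enames <- names(js$entries[[1L]])
  trf <- matrix(NA_integer_, length(otus), length(enames),
                dimnames = list(otus, enames))
  for (o in otus) for (e in enames) {
    v <- js$entries[[o]][[e]]$trf
    if (!is.null(v)) trf[o, e] <- as.integer(v)
  }
  window <- as.numeric(unlist(js$params$window))
  trf_reference_from_predictions(trf, window,
                                 as.integer(js$params$primer_offset))
}

#' Assemble a reference database from an existing prediction matrix
#'
#' Used by the JSON reader and wherever predicted fragment lengths are
#' already available (e.g. externally digested references).
#'
#' @param trf Integer matrix of predicted T-RF lengths, rows = OTUs,
#'   columns = enzymes; `NA` = no recognition site.
#' @param window Detection window in bp.
#' @param primer_offset Offset recorded with the predictions.
#' @return A `trf_reference`.
#' @export
trf_reference_from_predictions <- function(trf, window = .default_window,
                                           primer_offset = 0L) {
  inw <- in_window(trf, window)
  dim(inw) <- dim(trf); dimnames(inw) <- dimnames(trf)
  structure(list(trf = trf, in_window = inw, window = window,
                 primer_offset = primer_offset,
                 summary = data.frame(enzyme = colnames(trf),
                                      n_in_window = colSums(inw),
                                      frac_in_window = colSums(inw) / nrow(inw),
                                      row.names = NULL),
                 n_any_enzyme = sum(rowSums(inw) > 0),
                 n_no_enzyme = sum(rowSums(inw) == 0)),
            class = "trf_reference")
}
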