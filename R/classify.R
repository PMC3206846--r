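#' Classify one OTU as specialist or generalist symbiont
#'
#' Host-specificity rules: an OTU found in any seawater sample, or whose
#' closest environmental (free-living) GenBank identity exceeds 0.98, is a
#' generalist. Otherwise it is a specialist, sub-classified as dominant
#' (present in every sample of the host and accounting for more than one
#' fourth of the host's clones), common (present in more than one host
#' sample) or rare (a single host sample). An identity of exactly 0.98
#' (2 percent divergence) still counts as specialist. OTUs without an
#' environmental-identity annotation are specialist-eligible and flagged.
#'
#' @param otu_id OTU id (row of the table).
#' @param table An `otu_table`.
#' @param env_identity Closest environmental identity in `[0, 1]`, or `NA`.
#' @param host Source label of the host of interest.
#' @param seawater_source Source label of the seawater samples.
#' @return List with `otu_id`, `host`, `category` (one of
#'   `"dominant specialist"`, `"common specialist"`, `"rare specialist"`,
#'   `"generalist"`) and the supporting fields.
#' @export
classify_otu <- function(otu_id, table, env_identity = NA_real_, host,
                         seawater_source = "seawater") {
  stopifnot(inherits(table, "otu_table"))
  if (!otu_id %in% rownames(table$counts)) stop("unknown OTU: ", otu_id)
  src <- table$metadata$source[match(colnames(table$counts),
                                     table$metadata$sample_id)]
  if (!host %in% src) stop("host source not in metadata: ", host)
  if (!seawater_source %in% src)
    stop("seawater source not in metadata: ", seawater_source)
  row <- table$counts[otu_id, ]
  host_cols <- src == host
  if (sum(row[host_cols]) == 0)
    stop("OTU ", otu_id, " absent from host ", host)
  in_seawater <- sum(row[src == seawater_source]) > 0
  other_hosts <- setdiff(unique(src), c(host, seawater_source))
  multi_host <- any(vapply(other_hosts, function(h)
    sum(row[src == h]) > 0, logical(1)))
  n_present <- sum(row[host_cols] > 0)
  frac <- sum(row[host_cols]) / sum(table$counts[, host_cols])
  env_similar <- !is.na(env_identity) && env_identity > 0.98

  category <- if (in_seawater || env_similar) {
    "generalist"
  } else if (n_present == sum(host_cols) && frac > 0.25) {
    "dominant specialist"
  } else if (n_present >= 2) {
    "common specialist"
  } else {
    "rare specialist"
  }
  list(otu_id = otu_id, host = host, category = category,
       support = list(present_in_all_host_samples = n_present == sum(host_cols),
                      clone_fraction = frac,
                      n_host_samples_present = n_present,
                      shared_with_seawater = in_seawater,
                      env_identity = env_identity,
                      no_annotation = is.na(env_identity),
                      multi_host = multi_host))
}

#' Classify every host-associated OTU and tally categories
#'
#' Applies [classify_otu()] to each OTU present in each host; per host the
#' categories partition the host's OTUs and the category clone fractions sum
#' to one. Singleton OTUs (a single clone in the whole library) are tallied
#' separately with their free-living-relatedness split.
#'
#' @param table An `otu_table`.
#' @param annotations Optional data.frame with columns `otu_id` and
#'   `env_identity` (fractions in `[0, 1]`, `NA` allowed).
#' @param hosts Character vector of host source labels (default: every
#'   non-seawater source in the metadata).
#' @param seawater_source Source label of the seawater samples.
#' @return A `symbiont_classification`: list with `per_otu` (data.frame, one
#'   row per host x OTU), `tally` (per host x category: OTU counts and clone
#'   fractions) and `singletons`.
#' @export
classify_all <- function(table, annotations = NULL, hosts = NULL,
                         seawater_source = "seawater") {
  stopifnot(inherits(table, "otu_table"))
  src <- table$metadata$source[match(colnames(table$counts),
                                     table$metadata$sample_id)]
  hosts <- hosts %||% setdiff(unique(src), seawater_source)
  env <- setNames(rep(NA_real_, nrow(table$counts)), rownames(table$counts))
  if (!is.null(annotations)) {
    stopifnot(all(c("otu_id", "env_identity") %in% names(annotations)))
    env[annotations$otu_id] <- annotations$env_identity
  }
  rows <- list()
  for (h in hosts) {
    present <- rownames(table$counts)[rowSums(
      table$counts[, src == h, drop = FALSE]) > 0]
    for (o in present) {
      cl <- classify_otu(o, table, env[[o]], h, seawater_source)
      rows[[length(rows) + 1L]] <- data.frame(
        host = h, otu_id = o, category = cl$category,
        clone_fraction = cl$support$clone_fraction,
        n_host_samples_present = cl$support$n_host_samples_present,
        shared_with_seawater = cl$support$shared_with_seawater,
        multi_host = cl$support$multi_host,
        stringsAsFactors = FALSE)
    }
  }
  per_otu <- do.call(rbind, rows)
  cats <- c("dominant specialist", "common specialist", "rare specialist",
            "generalist")
  tally <- do.call(rbind, lapply(hosts, function(h) {
    sub <- per_otu[per_otu$host == h, ]
    data.frame(host = h, category = cats,
               n_otus = vapply(cats, function(k)
                 sum(sub$category == k), integer(1)),
               clone_fraction = vapply(cats, function(k)
                 sum(sub$clone_fraction[sub$category == k]), numeric(1)),
               row.names = NULL)
  }))
  singles <- rownames(table$counts)[rowSums(table$counts) == 1L]
  singletons <- list(
    n = length(singles),
    fraction = length(singles) / nrow(table$counts),
    n_free_living_related = sum(!is.na(env[singles]) & env[singles] > 0.98))
  structure(list(per_otu = per_otu, tally = tally, singletons = singletons),
            class = "symbiont_classification")
}

#' @export
print.symbiont_classification <- function(x, ...) {
  cat("Symbiont classification\n")
  for (h in unique(x$tally$host)) {
    sub <- x$tally[x$tally$host == h, ]
    cat(" ", h, ": ",
        paste(sprintf("%s %d (%.1f%% of clones)", sub$category, sub$n_otus,
                      100 * sub$clone_fraction), collapse = "; "), "\n")
  }
  cat(sprintf("  singletons: %d (%.1f%% of OTUs)\n",
              x$singletons$n, 100 * x$singletons$fraction))
  invisible(x)
}
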