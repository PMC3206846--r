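#' Parameters for the synthetic community generator
#'
#' Defaults emulate a replicated clone-library study of two sponge hosts, a
#' tunicate and ambient seawater: 9/3/3/9 replicate samples, 15 clones per
#' sample, one dominant host-specific phylotype per sponge (a third to a
#' half of that host's clones; the tunicate community is even, with no
#' dominant), a generalist fraction drawn from a pool shared with seawater,
#' and a singleton-rich log-series tail. Sequence structure: 600 bp, less
#' than 1 percent divergence within an OTU, at least 2 percent between
#' OTUs, so that clustering at the 99 percent phylotype definition recovers
#' the planted partition exactly. Electropherograms add size-dependent
#' Gaussian T-RF drift (sd `drift_a + drift_b * L`, capped by default at
#' half the applicable tolerance) and uniform baseline noise peaks.
#'
#' @param sources Named integer vector: source group -> number of samples.
#' @param clones_per_sample Clones screened per sample.
#' @param dominant_fraction Named numeric vector: host -> expected clone
#'   fraction of its dominant specialist (0 = no dominant planted).
#' @param generalist_fraction Named numeric vector: host -> probability that
#'   a non-dominant clone is drawn from the seawater (generalist) pool.
#' @param seawater_dominant_fraction Expected clone fraction of the most
#'   abundant seawater phylotype.
#' @param n_specialist_pool,n_seawater_pool Pool sizes behind the abundance
#'   tails.
#' @param logseries_x Log-series parameter in (0, 1) for the host specialist
#'   pools; rank weights `x^k / k` (dominated, low-evenness communities).
#' @param seawater_decay Geometric rank-weight ratio in (0, 1) for the
#'   seawater/generalist pool. Values near 1 give the near-even,
#'   singleton-rich structure of bacterioplankton libraries (high Fisher
#'   alpha), in which nearly every clone drawn is a new phylotype.
#' @param seq_length Sequence length in bp.
#' @param ancestor_divergence Minimum pairwise divergence between OTU
#'   ancestors (fraction).
#' @param within_otu_mutations Maximum substitutions per clone relative to
#'   its OTU ancestor.
#' @param site_prob Probability that an OTU carries an in-window restriction
#'   site for a given enzyme; `site_out_prob` the probability of an
#'   out-of-window site instead.
#' @param drift_a,drift_b T-RF drift model sd = `drift_a + drift_b * L` bp.
#'   Drift is systematic per fragment: one offset per OTU and enzyme,
#'   shared by all samples, emulating the consistent discrepancy between
#'   electrophoretic and sequence-predicted sizes.
#' @param cap_drift Cap the drift sd at half the applicable tolerance.
#' @param jitter_sd Per-sample sizing jitter sd in bp (run-to-run
#'   reproducibility, small relative to the cross-sample alignment window).
#' @param noise_peaks Number of baseline noise peaks per profile.
#' @param total_fluorescence Range of per-profile total fluorescence.
#' @return A list of class `sim_params`.
#' @export
simulation_params <- function(
    sources = c(Hymeniacidon = 9L, Haliclona = 3L, Didemnum = 3L,
                seawater = 9L),
    clones_per_sample = 15L,
    dominant_fraction = c(Hymeniacidon = 0.34, Haliclona = 0.51,
                          Didemnum = 0),
    generalist_fraction = c(Hymeniacidon = 0.22, Haliclona = 0.40,
                            Didemnum = 0.53),
    seawater_dominant_fraction = 0.23,
    n_specialist_pool = 40L,
    n_seawater_pool = 150L,
    logseries_x = 0.9,
    seawater_decay = 0.985,
    seq_length = 600L,
    ancestor_divergence = 0.028,
    within_otu_mutations = 2L,
    site_prob = 0.7,
    site_out_prob = 0.15,
    drift_a = 0.2, drift_b = 0.004, cap_drift = TRUE,
    jitter_sd = 0.15,
    noise_peaks = 5L,
    total_fluorescence = c(20000, 50000)) {
  stopifnot("seawater" %in% names(sources),
            all(dominant_fraction >= 0), all(dominant_fraction <= 0.55),
            all(generalist_fraction >= 0), all(generalist_fraction <= 1),
            logseries_x > 0, logseries_x < 1,
            seawater_decay > 0, seawater_decay < 1,
            # sequences must span the sizing window plus room for
            # out-of-window sites
            seq_length >= 540)
  hosts <- setdiff(names(sources), "seawater")
  stopifnot(all(hosts %in% names(dominant_fraction)),
            all(hosts %in% names(generalist_fraction)))
  structure(as.list(environment()), class = "sim_params")
}

.logseries_weights <- function(n, x) {
  w <- x^seq_len(n) / seq_len(n)
  w / sum(w)
}

#' Simulate a replicated clone-library community
#'
#' Draws the sample x OTU count table under the structure described in
#' [simulation_params()] and records the planted role of every OTU
#' (ground truth for recovery tests).
#'
#' @param params A `sim_params` list.
#' @param seed Integer seed (Mersenne-Twister; all outputs are reproducible
#'   byte for byte given the seed).
#' @return List with `table` (an `otu_table`) and `truth` (data.frame:
#'   `otu_id`, `role` in dominant_specialist / specialist / seawater,
#'   `host`).
#' @export
simulate_community <- function(params = simulation_params(), seed = 1) {
  set.seed(seed)
  hosts <- params$hosts
  # global OTU id universe: per-host dominant + per-host specialist pool +
  # seawater dominant + seawater pool
  ids <- list()
  for (h in hosts) {
    ids[[paste0(h, "_dom")]] <- paste0(h, "_dom")
    ids[[paste0(h, "_sp")]] <- paste0(h, "_sp", seq_len(params$n_specialist_pool))
  }
  sw_ids <- c("sw_dom", paste0("sw", seq_len(params$n_seawater_pool)))
  all_ids <- c(unlist(ids, use.names = FALSE), sw_ids)

  sp_w <- .logseries_weights(params$n_specialist_pool, params$logseries_x)
  # near-even geometric tail for the bacterioplankton pool
  sw_w <- params$seawater_decay^seq_len(params$n_seawater_pool)
  sw_w <- sw_w / sum(sw_w)
  # seawater community: dominant + tail
  sw_p <- c(params$seawater_dominant_fraction,
            (1 - params$seawater_dominant_fraction) * sw_w)
  names(sw_p) <- sw_ids

  samples <- character(0); source_of <- character(0)
  counts <- list()
  for (s in names(params$sources)) {
    for (k in seq_len(params$sources[[s]])) {
      smp <- sprintf("%s_%02d", s, k)
      samples <- c(samples, smp); source_of[smp] <- s
      n <- params$clones_per_sample
      draw <- setNames(integer(length(all_ids)), all_ids)
      if (s == "seawater") {
        # the dominant seawater phylotype is recovered from every sample
        n_dom <- max(1L, rbinom(1L, n, params$seawater_dominant_fraction))
        draw["sw_dom"] <- n_dom
        rest <- sample(paste0("sw", seq_len(params$n_seawater_pool)),
                       n - n_dom, replace = TRUE, prob = sw_w)
        tb <- table(rest); draw[names(tb)] <- draw[names(tb)] + as.integer(tb)
      } else {
        df <- params$dominant_fraction[[s]]
        n_dom <- if (df > 0) max(1L, rbinom(1L, n, df)) else 0L
        if (n_dom > 0) draw[paste0(s, "_dom")] <- n_dom
        n_rest <- n - n_dom
        gen <- runif(n_rest) < params$generalist_fraction[[s]]
        if (any(gen)) {
          g <- sample(sw_ids, sum(gen), replace = TRUE, prob = sw_p)
          tb <- table(g); draw[names(tb)] <- draw[names(tb)] + as.integer(tb)
        }
        if (any(!gen)) {
          spv <- sample(paste0(s, "_sp", seq_len(params$n_specialist_pool)),
                        sum(!gen), replace = TRUE, prob = sp_w)
          tb <- table(spv); draw[names(tb)] <- draw[names(tb)] + as.integer(tb)
        }
      }
      counts[[smp]] <- draw
    }
  }
  m <- do.call(cbind, counts)
  m <- m[rowSums(m) > 0, , drop = FALSE]
  metadata <- data.frame(sample_id = samples,
                         source = unname(source_of[samples]),
                         stringsAsFactors = FALSE)
  role <- ifelse(grepl("_dom$", rownames(m)) & !grepl("^sw", rownames(m)),
                 "dominant_specialist",
                 ifelse(grepl("^sw", rownames(m)), "seawater", "specialist"))
  host <- sub("_(dom|sp[0-9]+)$", "", rownames(m))
  host[role == "seawater"] <- NA
  truth <- data.frame(otu_id = rownames(m), role = role, host = host,
                      stringsAsFactors = FALSE)
  table <- structure(list(counts = m, representative = NULL,
                          members = NULL, metadata = metadata),
                     class = "otu_table")
  list(table = table, truth = truth)
}

# remove every occurrence of the recognition motifs from a sequence vector
# (character vector of single bases), protecting a set of positions
.clear_sites <- function(sq, recognitions, protect = integer(0)) {
  bases <- c("A", "C", "G", "T")
  repeat {
    s <- paste(sq, collapse = "")
    hit <- NULL
    for (rec in recognitions) {
      p <- .first_site_one_strand(s, rec)
      while (!is.na(p)) {
        span <- p:(p + nchar(rec) - 1L)
        if (!any(span %in% protect)) { hit <- span; break }
        # protected occurrence: look past it
        p2 <- .first_site_one_strand(substr(s, p + 1L, nchar(s)), rec)
        p <- if (is.na(p2)) NA_integer_ else p + p2
      }
      if (!is.null(hit)) break
    }
    if (is.null(hit)) return(sq)
    i <- hit[2L] # mutate an interior base of the occurrence
    sq[i] <- sample(setdiff(bases, sq[i]), 1L)
  }
}

#' Simulate clone sequences for a community
#'
#' Builds one ancestor per OTU from a shared root such that ancestors differ
#' pairwise by at least `ancestor_divergence`, then derives each clone from
#' its OTU ancestor with at most `within_otu_mutations` substitutions, so
#' within-OTU divergence stays under 1 percent and between-OTU divergence
#' above 2 percent. Restriction sites are planted per OTU and enzyme (in
#' window with probability `site_prob`, out of window with
#' `site_out_prob`, otherwise no site), after clearing naturally occurring
#' motifs, so predicted T-RFs are controllable.
#'
#' @param community Output of [simulate_community()].
#' @param params A `sim_params` list.
#' @param seed Integer seed.
#' @param enzymes Enzyme names to plant sites for.
#' @return List with `clones` (named character vector, one sequence per
#'   clone, names `<sample>.<k>`), `sample_of` (clone id -> sample id),
#'   `otu_of` (clone id -> planted OTU id) and `ancestors` (per-OTU
#'   ancestral sequences).
#' @export
simulate_sequences <- function(community, params = simulation_params(),
                               seed = 1, enzymes = c("HaeIII", "MspI", "RsaI")) {
  set.seed(seed + 1L)
  bases <- c("A", "C", "G", "T")
  L <- params$seq_length
  otus <- rownames(community$table$counts)
  enz <- lapply(enzymes, restriction_enzyme)
  recs <- vapply(enz, `[[`, character(1), "recognition")
  root <- sample(bases, L, replace = TRUE)

  min_diff <- ceiling(params$ancestor_divergence * L)
  anc <- matrix("", nrow = length(otus), ncol = L,
                dimnames = list(otus, NULL))
  planted <- vector("list", length(otus)); names(planted) <- otus
  for (i in seq_along(otus)) {
    for (try in 1:50) {
      sq <- root
      mut <- sample(L, min_diff + 8L)
      for (p in mut) sq[p] <- sample(setdiff(bases, sq[p]), 1L)
      # choose per-enzyme site plan: target T-RF position or none
      protect <- integer(0)
      plan <- list()
      for (e in seq_along(enz)) {
        u <- runif(1)
        target <- if (u < params$site_prob) {
          sample(110:480, 1L)
        } else if (u < params$site_prob + params$site_out_prob) {
          sample(520:(L - 10L), 1L)
        } else NA_integer_
        plan[[recs[e]]] <- target
      }
      sq <- .clear_sites(sq, recs)
      ok <- TRUE
      for (e in seq_along(enz)) {
        target <- plan[[recs[e]]]
        if (is.na(target)) next
        # site start so that trf = start - 1 + cut_offset = target
        start <- target + 1L - enz[[e]]$cut_offset
        span <- start:(start + nchar(recs[e]) - 1L)
        if (any(span %in% protect)) { ok <- FALSE; break }
        sq[span] <- strsplit(recs[e], "")[[1]]
        protect <- c(protect, span)
      }
      if (!ok) next
      # planting may have spawned a motif across a boundary; clear outside
      # protected spans and verify the plan is realized
      sq <- .clear_sites(sq, recs, protect = protect)
      realized <- vapply(seq_along(enz), function(e)
        predict_trf(paste(sq, collapse = ""), enz[[e]]), integer(1))
      want <- vapply(recs, function(r)
        if (is.na(plan[[r]])) NA_integer_ else plan[[r]], integer(1))
      if (identical(unname(realized), unname(want))) {
        anc[i, ] <- sq
        planted[[i]] <- list(protect = protect, trf = realized)
        break
      }
    }
    if (anc[i, 1] == "") stop("failed to realize site plan for OTU ", otus[i])
  }
  # enforce minimum pairwise ancestor divergence (site planting can only
  # perturb a handful of positions; regenerate rare offenders)
  if (length(otus) > 1) {
    hamming <- function(m) {
      # exact mismatch counts via one-hot cross products
      matches <- Reduce(`+`, lapply(bases, function(b) {
        B <- (m == b) * 1
        tcrossprod(B)
      }))
      ncol(m) - matches
    }
    for (rounds in 1:5) {
      dm <- hamming(anc)
      bad <- which(apply(dm + diag(Inf, nrow(dm)), 1, min) < min_diff)
      if (!length(bad)) break
      for (i in bad) {
        extra <- sample(setdiff(seq_len(L), planted[[i]]$protect), 6L)
        for (p in extra) anc[i, p] <- sample(setdiff(bases, anc[i, p]), 1L)
        anc[i, ] <- .clear_sites(anc[i, ], recs,
                                 protect = planted[[i]]$protect)
      }
    }
  }

  counts <- community$table$counts
  clones <- character(0); sample_of <- character(0); otu_of <- character(0)
  for (smp in colnames(counts)) {
    k <- 0L
    for (o in rownames(counts)) {
      for (rep in seq_len(counts[o, smp])) {
        k <- k + 1L
        id <- sprintf("%s.%02d", smp, k)
        sq <- anc[o, ]
        nmut <- sample(0:params$within_otu_mutations, 1L)
        if (nmut > 0) {
          pos <- sample(setdiff(seq_len(L), planted[[o]]$protect), nmut)
          for (p in pos) sq[p] <- sample(setdiff(bases, sq[p]), 1L)
        }
        clones[id] <- paste(sq, collapse = "")
        sample_of[id] <- smp
        otu_of[id] <- o
      }
    }
  }
  ancestors <- setNames(apply(anc, 1, paste, collapse = ""), otus)
  list(clones = clones, sample_of = sample_of, otu_of = otu_of,
       ancestors = ancestors)
}

#' Simulate T-RFLP electropherograms for a community
#'
#' One profile per sample and enzyme: each OTU present in the sample whose
#' reference prediction is in-window contributes one peak at the predicted
#' size plus its systematic drift — a single Gaussian offset per OTU and
#' enzyme (sd = `drift_a + drift_b * L`, capped at half the applicable
#' tolerance when `cap_drift`), shared by every sample, as electrophoretic
#' drift is reproducible for a given fragment — plus small per-sample
#' sizing jitter (`jitter_sd`). Fluorescence is proportional to the OTU's
#' relative abundance times the profile total; baseline noise peaks (count
#' scaling with total fluorescence, some below the sizing window) are
#' added on top.
#'
#' @param db A `trf_reference` covering the community's OTUs.
#' @param community Output of [simulate_community()] (or any `otu_table` in
#'   its `table` element).
#' @param params A `sim_params` list.
#' @param seed Integer seed.
#' @return Peak data.frame with columns `sample_id`, `enzyme`, `size_bp`,
#'   `fluorescence`.
#' @export
simulate_electropherograms <- function(db, community,
                                       params = simulation_params(),
                                       seed = 1) {
  set.seed(seed + 2L)
  counts <- community$table$counts
  stopifnot(all(rownames(counts) %in% rownames(db$trf)))
  tol <- tolerance_bins()
  # systematic drift: one offset per OTU x enzyme, shared across samples
  drift <- db$trf
  drift[] <- NA_real_
  for (o in rownames(db$trf)) for (e in colnames(db$trf)) {
    if (is.na(db$trf[o, e])) next
    sdv <- params$drift_a + params$drift_b * db$trf[o, e]
    if (params$cap_drift)
      sdv <- min(sdv, tolerance_for(db$trf[o, e], tol) / 2)
    drift[o, e] <- rnorm(1, 0, sdv)
  }
  rows <- list()
  for (smp in colnames(counts)) {
    rel <- counts[, smp] / sum(counts[, smp])
    for (e in colnames(db$trf)) {
      total <- runif(1, params$total_fluorescence[1],
                     params$total_fluorescence[2])
      sz <- numeric(0); fl <- numeric(0)
      for (o in rownames(counts)) {
        if (counts[o, smp] == 0 || !db$in_window[o, e]) next
        sz <- c(sz, db$trf[o, e] + drift[o, e] +
                  rnorm(1, 0, params$jitter_sd))
        fl <- c(fl, rel[o] * total)
      }
      if (params$noise_peaks > 0) {
        # noise-peak count scales with loaded DNA — the dependence the
        # variable-threshold standardization exists to remove
        n_noise <- rpois(1, params$noise_peaks * total /
                           mean(params$total_fluorescence))
        if (n_noise > 0) {
          sz <- c(sz, runif(n_noise, 50, 520))
          fl <- c(fl, runif(n_noise, 0.001, 0.008) * total)
        }
      }
      sz <- round(sz, 2)
      agg <- rowsum(fl, sz) # merge rare size collisions at 0.01 bp
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = smp, enzyme = e,
        size_bp = as.numeric(rownames(agg)), fluorescence = agg[, 1],
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$sample_id, out$enzyme, out$size_bp), ]
}

#' Simulate a phylogeny with planted host clades
#'
#' Coalescent-style random tree in which the specialist OTUs of each host
#' form a clade (planted phylogenetic clustering) while seawater/generalist
#' OTUs scatter across the backbone. With `structured = FALSE` all tips are
#' drawn from one coalescent (no structure; for null calibration).
#'
#' @param truth Truth data.frame from [simulate_community()].
#' @param seed Integer seed.
#' @param structured Plant the host clades?
#' @return An [ape::phylo] tree whose tips are the OTU ids.
#' @export
simulate_tree <- function(truth, seed = 1, structured = TRUE) {
  set.seed(seed + 3L)
  ids <- truth$otu_id
  if (length(ids) < 2) stop("need at least two OTUs")
  if (!structured) {
    tr <- ape::rcoal(length(ids), tip.label = sample(ids))
    return(tr)
  }
  hosts <- unique(truth$host[!is.na(truth$host)])
  clades <- lapply(hosts, function(h)
    truth$otu_id[!is.na(truth$host) & truth$host == h])
  loose <- truth$otu_id[is.na(truth$host)]
  units <- c(as.list(loose), clades[lengths(clades) > 0])
  backbone <- ape::rcoal(length(units),
                         tip.label = paste0("U", seq_along(units)))
  tr <- backbone
  for (u in seq_along(units)) {
    tipname <- paste0("U", u)
    if (length(units[[u]]) == 1L) {
      tr$tip.label[tr$tip.label == tipname] <- units[[u]]
    } else {
      sub <- ape::rcoal(length(units[[u]]), tip.label = units[[u]])
      # graft the host clade onto its backbone tip
      sub$root.edge <- 0.05
      tr <- ape::bind.tree(tr, sub, where = which(tr$tip.label == tipname))
    }
  }
  tr$edge.length <- pmax(tr$edge.length, 1e-6)
  tr
}

#' Simulate a complete study bundle on disk
#'
#' Runs [simulate_community()], [simulate_sequences()],
#' [build_reference_db()] on the planted ancestors,
#' [simulate_electropherograms()] and [simulate_tree()], writing the same
#' file formats the analysis functions read: `seqs.fa`, `samples.tsv`,
#' `peaks.csv`, `tree.nwk`, `truth.tsv` and `clone_map.tsv`.
#'
#' @param dir Output directory (created if absent).
#' @param params A `sim_params` list.
#' @param seed Integer seed.
#' @return Invisibly, the list of generated objects.
#' @export
simulate_dataset <- function(dir, params = simulation_params(), seed = 1) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  com <- simulate_community(params, seed)
  seqs <- simulate_sequences(com, params, seed)
  db <- build_reference_db(seqs$ancestors)
  peaks <- simulate_electropherograms(db, com, params, seed)
  tree <- simulate_tree(com$truth, seed)
  write_fasta(seqs$clones, file.path(dir, "seqs.fa"))
  write_sample_metadata(com$table$metadata, file.path(dir, "samples.tsv"))
  write_peak_table(peaks, file.path(dir, "peaks.csv"))
  write_newick(tree, file.path(dir, "tree.nwk"))
  write.table(com$truth, file.path(dir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(data.frame(clone_id = names(seqs$sample_of),
                         sample_id = unname(seqs$sample_of),
                         otu_id = unname(seqs$otu_of)),
              file.path(dir, "clone_map.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(list(community = com, sequences = seqs, db = db, peaks = peaks,
                 tree = tree))
}
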