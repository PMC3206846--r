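# small study design keeps the generator tests fast; the full 9/3/3/9 design
# is exercised in the acceptance suite
small_params <- function(...) {
  simulation_params(
    sources = c(HostA = 3L, HostB = 2L, seawater = 3L),
    dominant_fraction = c(HostA = 0.34, HostB = 0.51),
    generalist_fraction = c(HostA = 0.25, HostB = 0.40),
    n_specialist_pool = 15L, n_seawater_pool = 20L,
    ...)
}

test_that("community draws conserve clone counts and plant the dominants", {
  p <- small_params()
  com <- simulate_community(p, seed = 3)
  expect_true(all(colSums(com$table$counts) == p$clones_per_sample))
  src <- com$table$metadata$source
  for (h in c("HostA", "HostB")) {
    dom <- paste0(h, "_dom")
    host_cols <- src == h
    expect_true(all(com$table$counts[dom, host_cols] >= 1))
    expect_equal(sum(com$table$counts[dom, !host_cols]), 0) # host-exclusive
  }
  # under the full default design each sponge host's most abundant OTU is
  # its planted dominant (the tunicate community is even, with none)
  def <- simulate_community(simulation_params(), seed = 3)
  dsrc <- def$table$metadata$source
  for (h in c("Hymeniacidon", "Haliclona")) {
    tot <- rowSums(def$table$counts[, dsrc == h, drop = FALSE])
    expect_equal(names(which.max(tot)), paste0(h, "_dom"))
  }
  expect_false("Didemnum_dom" %in% rownames(def$table$counts))
})

test_that("dominant clone counts follow the planted fraction", {
  p <- simulation_params()
  doms <- vapply(1:8, function(s) {
    com <- simulate_community(p, seed = 100 + s)
    src <- com$table$metadata$source
    sum(com$table$counts["Hymeniacidon_dom", src == "Hymeniacidon"])
  }, numeric(1))
  # 135 clones at fraction 0.34: mean within a few binomial sd of 45.9
  expect_gt(mean(doms), 45.9 - 3 * sqrt(135 * 0.34 * 0.66) / sqrt(8))
  expect_lt(mean(doms), 45.9 + 3 * sqrt(135 * 0.34 * 0.66) / sqrt(8))
})

test_that("zero generalist fraction isolates hosts from seawater", {
  p <- small_params()
  p$generalist_fraction[] <- 0
  com <- simulate_community(p, seed = 5)
  src <- com$table$metadata$source
  host <- rowSums(com$table$counts[, src != "seawater", drop = FALSE]) > 0
  sea <- rowSums(com$table$counts[, src == "seawater", drop = FALSE]) > 0
  expect_equal(sum(host & sea), 0)
})

test_that("the generator is deterministic for a fixed seed", {
  p <- small_params()
  c1 <- simulate_community(p, seed = 11)
  c2 <- simulate_community(p, seed = 11)
  expect_identical(c1$table$counts, c2$table$counts)
  s1 <- simulate_sequences(c1, p, seed = 11)
  s2 <- simulate_sequences(c2, p, seed = 11)
  expect_identical(s1$clones, s2$clones)
  db <- build_reference_db(s1$ancestors)
  pk1 <- simulate_electropherograms(db, c1, p, seed = 11)
  pk2 <- simulate_electropherograms(db, c2, p, seed = 11)
  expect_identical(pk1, pk2)
})

test_that("planted divergence structure is respected and re-clusterable", {
  p <- small_params()
  com <- simulate_community(p, seed = 13)
  sq <- simulate_sequences(com, p, seed = 13)
  anc <- sq$ancestors
  # between-OTU ancestors at least 2% divergent
  for (i in 1:min(6, length(anc) - 1)) {
    d <- 1 - pairwise_identity(anc[[i]], anc[[i + 1]])
    expect_gte(d, 0.02)
  }
  # within-OTU clones under 1% from their ancestor
  ids <- sample(names(sq$clones), 10)
  for (id in ids) {
    d <- 1 - pairwise_identity(sq$clones[[id]], anc[[sq$otu_of[[id]]]])
    expect_lt(d, 0.01)
  }
  # re-clustering at 99% recovers the planted partition exactly
  cl <- cluster_otus(sq$clones, 0.99)
  planted <- sq$otu_of[names(cl$assignment)]
  tab <- table(cl$assignment, planted)
  expect_equal(length(unique(cl$assignment)), length(unique(planted)))
  expect_true(all(colSums(tab > 0) == 1) && all(rowSums(tab > 0) == 1))
})

test_that("zero within-OTU mutation yields identical members", {
  p <- small_params(within_otu_mutations = 0L)
  com <- simulate_community(p, seed = 17)
  sq <- simulate_sequences(com, p, seed = 17)
  by_otu <- split(sq$clones, sq$otu_of[names(sq$clones)])
  for (grp in by_otu) expect_equal(length(unique(grp)), 1)
})

test_that("noiseless electropherograms recover the planted in-window set", {
  p <- small_params(drift_a = 0, drift_b = 0, noise_peaks = 0L)
  com <- simulate_community(p, seed = 19)
  sq <- simulate_sequences(com, p, seed = 19)
  db <- build_reference_db(sq$ancestors)
  pk <- simulate_electropherograms(db, com, p, seed = 19)
  mats <- lapply(setNames(nm = c("HaeIII", "MspI", "RsaI")), function(e)
    align_trfs(pk[pk$enzyme == e, ],
               samples = com$table$metadata$sample_id))
  mm <- match_trfs(db, mats)
  present <- rownames(com$table$counts)
  for (e in c("HaeIII", "MspI", "RsaI")) {
    inw <- present[db$in_window[present, e]]
    expect_true(all(!is.na(mm$matched[inw, e])))
  }
})

test_that("electropherogram peaks scale with abundance and carry noise", {
  p <- small_params()
  com <- simulate_community(p, seed = 23)
  sq <- simulate_sequences(com, p, seed = 23)
  db <- build_reference_db(sq$ancestors)
  pk <- simulate_electropherograms(db, com, p, seed = 23)
  one <- pk[pk$sample_id == com$table$metadata$sample_id[1] &
              pk$enzyme == "HaeIII", ]
  n_inw <- sum(db$in_window[
    rownames(com$table$counts)[com$table$counts[, 1] > 0], "HaeIII"])
  # one peak per present in-window OTU, plus a fluorescence-scaled number
  # of noise peaks
  expect_gte(nrow(one), n_inw)
  expect_gt(nrow(pk), 0)
  expect_true(any(pk$size_bp < 100)) # sub-window peaks exercise filtering
})

test_that("planted host clades produce phylogenetic clustering", {
  p <- small_params()
  com <- simulate_community(p, seed = 29)
  tr <- simulate_tree(com$truth, seed = 29)
  expect_setequal(tr$tip.label, com$truth$otu_id)
  expect_true(all(tr$edge.length > 0))
  specialists <- com$truth$otu_id[!is.na(com$truth$host) &
                                    com$truth$host == "HostA"]
  if (length(specialists) >= 2) {
    lab <- setNames(ifelse(tr$tip.label %in% specialists, "in", "out"),
                    tr$tip.label)
    pt <- ptest(tr, lab, n_perm = 199, seed = 1)
    expect_equal(pt$observed, 1) # a planted clade needs a single change
    expect_lt(pt$p, 0.05)
  }
  # unstructured mode scatters labels
  tr0 <- simulate_tree(com$truth, seed = 29, structured = FALSE)
  expect_setequal(tr0$tip.label, com$truth$otu_id)
})

test_that("the on-disk bundle round trips through the package readers", {
  dir <- withr::local_tempdir()
  p <- small_params()
  out <- simulate_dataset(dir, p, seed = 31)
  sq <- read_fasta(file.path(dir, "seqs.fa"))
  expect_identical(sq, out$sequences$clones)
  md <- read_sample_metadata(file.path(dir, "samples.tsv"))
  expect_identical(md$sample_id, out$community$table$metadata$sample_id)
  pk <- read_peak_table(file.path(dir, "peaks.csv"))
  expect_equal(nrow(pk), nrow(out$peaks))
  tr <- read_newick(file.path(dir, "tree.nwk"),
                    ids = out$community$truth$otu_id)
  expect_equal(ape::Ntip(out$tree), ape::Ntip(tr))
  expect_warning(read_newick(file.path(dir, "tree.nwk"), ids = "wrong"),
                 "absent")
})
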