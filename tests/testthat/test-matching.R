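test_that("tolerance rules follow the size-dependent bins", {
  expect_equal(tolerance_for(c(150, 200, 201, 400, 400.1, 450)),
               c(1.0, 1.0, 1.5, 1.5, 4.0, 4.0))
  custom <- tolerance_bins(cbind(c(100, Inf), c(0.5, 2.0)))
  expect_equal(tolerance_for(c(100, 101), custom), c(0.5, 2.0))
  expect_error(tolerance_bins(cbind(c(200, 100), c(1, 1))), "increasing")
  expect_error(tolerance_bins(cbind(c(100, Inf), c(0, 1))), "positive")
})

mk_db <- function(trf_by_enzyme) {
  # trf_by_enzyme: named list enzyme -> named numeric of per-OTU predictions
  otus <- names(trf_by_enzyme[[1]])
  m <- vapply(trf_by_enzyme, function(v) as.integer(v[otus]),
              integer(length(otus)))
  m <- matrix(m, nrow = length(otus),
              dimnames = list(otus, names(trf_by_enzyme)))
  trf_reference_from_predictions(m)
}

test_that("matching applies tolerance arithmetic around predictions", {
  db <- mk_db(list(HaeIII = c(o1 = 150, o2 = 350, o3 = 450)))
  m <- toy_trf_matrix(c(150.8, 351.6, 453.9),
                      matrix(1 / 3, 1, 3, dimnames = list("s1", NULL)))
  res <- match_trfs(db, list(HaeIII = m))
  expect_equal(res$matched["o1", "HaeIII"], 150.8)  # 0.8 <= 1.0
  expect_true(is.na(res$matched["o2", "HaeIII"]))   # 1.6 > 1.5
  expect_equal(res$matched["o3", "HaeIII"], 453.9)  # 3.9 <= 4.0
})

test_that("out-of-window predictions never match and ties pick the smaller bin", {
  db <- mk_db(list(HaeIII = c(lo = 90, mid = 200)))
  m <- toy_trf_matrix(c(90.1, 199.5, 200.5),
                      matrix(1 / 3, 1, 3, dimnames = list("s1", NULL)))
  res <- match_trfs(db, list(HaeIII = m))
  expect_true(is.na(res$matched["lo", "HaeIII"])) # 90 bp is below the window
  expect_equal(res$matched["mid", "HaeIII"], 199.5) # tie at 0.5 -> smaller
  expect_error(match_trfs(db, list(Bogus = m)), "absent")
})

test_that("matching is monotone in the tolerance and self-consistent", {
  set.seed(41)
  for (i in 1:10) {
    preds <- sample(100:500, 8)
    db <- mk_db(list(HaeIII = setNames(preds, paste0("o", 1:8))))
    centers <- sort(round(preds + rnorm(8, 0, 2), 2))
    m <- toy_trf_matrix(centers,
                        matrix(1 / 8, 1, 8, dimnames = list("s1", NULL)))
    small <- match_trfs(db, list(HaeIII = m),
                        tolerance_bins(cbind(c(200, 400, Inf),
                                             c(0.5, 0.75, 2))))
    big <- match_trfs(db, list(HaeIII = m))
    # enlarging every tolerance never removes a match
    expect_true(all(is.na(small$matched) | !is.na(big$matched)))
    # mutual consistency: per-OTU and per-T-RF reports agree
    for (o in rownames(big$matched)) {
      b <- big$matched[o, "HaeIII"]
      if (!is.na(b)) {
        key <- formatC(b, format = "f", digits = 2)
        expect_true(o %in% big$per_trf$HaeIII[[key]])
      }
    }
  }
})

test_that("signature resolution partitions phylotypes", {
  db <- mk_db(list(HaeIII = c(a = 150, b = 150, c = 300, d = NA),
                   MspI   = c(a = NA, b = NA, c = 250, d = NA),
                   RsaI   = c(a = NA, b = NA, c = 410, d = NA)))
  mats <- list(
    HaeIII = toy_trf_matrix(c(150.2, 300.1),
                            matrix(0.5, 1, 2, dimnames = list("s1", NULL))),
    MspI = toy_trf_matrix(250.4,
                          matrix(1, 1, 1, dimnames = list("s1", NULL))),
    RsaI = toy_trf_matrix(411.0,
                          matrix(1, 1, 1, dimnames = list("s1", NULL))))
  sg <- build_signatures(match_trfs(db, mats))
  res <- setNames(sg$resolution, sg$otu_id)
  expect_identical(res[["a"]], "shared")   # a and b share the single bin
  expect_identical(res[["b"]], "shared")
  expect_identical(res[["c"]], "unique")   # all three enzymes, unshared
  expect_identical(res[["d"]], "undetected")
  s <- attr(sg, "summary")
  expect_equal(s$n_unique + s$n_shared + s$n_undetected, 4)
  expect_equal(unname(s$by_n_enzymes["3"]), 1)
})

test_that("shared-signature divergence averages within groups", {
  set.seed(51)
  base <- random_dna(1, 100) # aperiodic, so alignments cannot slide
  mutate_at <- function(s, pos) {
    v <- strsplit(s, "")[[1]]
    for (p in pos) v[p] <- setdiff(c("A", "C", "G", "T"), v[p])[1]
    paste(v, collapse = "")
  }
  # A-B differ by 2, A-C by 4, B-C by 6 -> divergences 2%, 4%, 6%
  seqs <- c(a = base, b = mutate_at(base, 1:2), c = mutate_at(base, 3:6))
  sg <- data.frame(otu_id = c("a", "b", "c"), signature = "HaeIII:150.00",
                   n_enzymes_matched = 1, resolution = "shared",
                   stringsAsFactors = FALSE)
  class(sg) <- c("trf_signatures", "data.frame")
  out <- shared_signature_divergence(sg, seqs)
  expect_equal(unname(out$overall["mean"]), 4)
  # identical pair -> zero divergence
  sg2 <- sg[1:2, ]; sg2$otu_id <- c("x", "y")
  out2 <- shared_signature_divergence(sg2, c(x = base, y = base))
  expect_equal(unname(out2$overall["mean"]), 0)
})

test_that("goodness-of-fit G test matches closed-form arithmetic", {
  expect_equal(taxonomic_bias_gtest(c(a = 20, b = 20), c(a = 50, b = 50))$G, 0)
  g <- taxonomic_bias_gtest(c(a = 30, b = 10), c(a = 50, b = 50))
  expect_equal(g$G, 2 * (30 * log(1.5) + 10 * log(0.5)))
  expect_equal(g$G, 10.46, tolerance = 1e-3)
  # 13 categories -> 12 degrees of freedom
  obs <- setNames(c(5, rep(1, 12)), paste0("t", 1:13))
  ref <- setNames(rep(10, 13), paste0("t", 1:13))
  expect_equal(taxonomic_bias_gtest(obs, ref)$df, 12)
  expect_error(taxonomic_bias_gtest(c(a = 1), c(b = 1)), "universe")
})
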