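rec <- function(n, ...) {
  candidate_records(feature_id = sprintf("f%03d", seq_len(n)), ..., fill = TRUE)
}

test_that("funnel tiers are conjunctions in the documented order", {
  r <- candidate_records(
    feature_id = c("all", "no_cons", "not_pod"),
    expressed = c(TRUE, TRUE, TRUE),
    noncoding = c(TRUE, TRUE, TRUE),
    podocyte_expressed = c(TRUE, TRUE, FALSE),
    tsi_specific = c(TRUE, TRUE, FALSE),
    seq_conserved = c(TRUE, FALSE, FALSE),
    synteny_conserved = c(FALSE, FALSE, FALSE),
    homology_clean = c(TRUE, TRUE, TRUE),
    de_wt1 = c(TRUE, FALSE, FALSE), fill = TRUE)
  f <- build_funnel(r)
  expect_equal(f$tiers$n, c(3L, 2L, 2L, 1L, 1L))
  expect_true("all" %in% f$tiers$members[[5]])
  ## specific but unconserved feature stops at T3
  expect_equal(f$records$tier[f$records$feature_id == "no_cons"], "T3")
})

test_that("missing or NA flags raise errors naming the problem", {
  r <- data.frame(feature_id = "x", level = "transcript", expressed = TRUE)
  expect_error(build_funnel(r), "missing flag")
  r2 <- rec(2, expressed = c(TRUE, NA))
  expect_error(build_funnel(r2), "f002")
})

test_that("tier sizes are non-increasing and upset counts partition T1", {
  set.seed(71)
  for (k in 1:20) {
    n <- 50
    r <- rec(n,
             expressed = stats::runif(n) < 0.8,
             noncoding = stats::runif(n) < 0.8,
             podocyte_expressed = stats::runif(n) < 0.7,
             tsi_specific = stats::runif(n) < 0.4,
             seq_conserved = stats::runif(n) < 0.3,
             synteny_conserved = stats::runif(n) < 0.2,
             homology_clean = stats::runif(n) < 0.9,
             de_wt1 = stats::runif(n) < 0.3,
             de_podocin = stats::runif(n) < 0.3,
             de_adriamycin = stats::runif(n) < 0.3)
    f <- build_funnel(r)
    expect_true(all(diff(f$tiers$n) <= 0))
    expect_equal(sum(f$upset$n), f$tiers$n[1])
  }
})

test_that("planted funnel sizes are recovered exactly on constructed records", {
  ## 100 -> 60 -> 30 -> 20 -> 12 by construction
  n <- 120
  t1 <- seq_len(100); t2 <- seq_len(60); t3 <- seq_len(30)
  t4 <- seq_len(20); t5 <- seq_len(12)
  r <- rec(n,
           expressed = seq_len(n) %in% t1, noncoding = rep(TRUE, n),
           podocyte_expressed = seq_len(n) %in% t2,
           tsi_specific = seq_len(n) %in% t3,
           seq_conserved = seq_len(n) %in% t4,
           homology_clean = rep(TRUE, n),
           de_podocin = seq_len(n) %in% t5)
  expect_equal(build_funnel(r)$tiers$n, c(100L, 60L, 30L, 20L, 12L))
})

test_that("locus rollup ORs transcript evidence and keeps native DE flags", {
  r <- candidate_records(
    feature_id = c("t1", "t2", "t3"),
    expressed = c(TRUE, TRUE, TRUE), noncoding = c(TRUE, TRUE, TRUE),
    podocyte_expressed = c(TRUE, TRUE, FALSE),
    tsi_specific = c(FALSE, FALSE, FALSE),
    seq_conserved = c(TRUE, FALSE, FALSE),
    synteny_conserved = c(FALSE, FALSE, FALSE),
    homology_clean = c(TRUE, TRUE, TRUE), fill = TRUE)
  map <- c(t1 = "locA", t2 = "locA", t3 = "locB")
  de <- data.frame(locus_id = c("locA", "locB"), de_wt1 = c(TRUE, FALSE),
                   de_podocin = FALSE, de_adriamycin = FALSE)
  out <- transcript_to_locus_rollup(r, map, de)
  a <- out[out$feature_id == "locA", ]
  expect_true(a$seq_conserved)             # one conserved member suffices
  expect_true(a$de_wt1)
  b <- out[out$feature_id == "locB", ]
  expect_false(b$podocyte_expressed)
  expect_error(transcript_to_locus_rollup(r, map[1:2]), "without locus")
})

test_that("rollup then funnel equals funnel then rollup on homogeneous loci", {
  set.seed(72)
  n <- 40
  map <- stats::setNames(rep(sprintf("L%02d", 1:20), each = 2),
                         sprintf("f%03d", seq_len(n)))
  flags <- list()
  for (f in c("expressed", "noncoding", "podocyte_expressed", "tsi_specific",
              "seq_conserved", "synteny_conserved", "homology_clean",
              "de_wt1", "de_podocin", "de_adriamycin")) {
    per_locus <- stats::runif(20) < 0.6
    flags[[f]] <- rep(per_locus, each = 2)   # locus-homogeneous
  }
  r <- do.call(candidate_records,
               c(list(feature_id = sprintf("f%03d", seq_len(n)), fill = TRUE),
                 flags))
  lr <- transcript_to_locus_rollup(r, map)
  expect_equal(build_funnel(lr)$tiers$n, build_funnel(r)$tiers$n / 2)
})

test_that("locus tier counts equal brute-force recomputation from transcripts", {
  pl <- get_pipeline()
  r <- pl$records
  map <- locus_map(pl$loci)
  in_l <- r$feature_id %in% names(map)
  brute <- sapply(split(seq_len(nrow(r))[in_l], map[r$feature_id[in_l]]),
                  function(idx) {
    any_f <- function(f) any(r[[f]][idx])
    (any_f("expressed") && any_f("noncoding") && any_f("podocyte_expressed") &&
       any_f("tsi_specific") &&
       (any_f("seq_conserved") || any_f("synteny_conserved")) &&
       any_f("homology_clean"))
  })
  got <- pl$locus_funnel$tiers$members[[4]]
  expect_setequal(got, names(brute)[brute])
})
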