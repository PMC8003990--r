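sim_counts <- function(n, mu, phi, cond_mult = NULL, nrep = 3) {
  cond <- rep(c("control", "disease"), each = nrep)
  m <- matrix(0L, n, 2 * nrep)
  for (i in seq_len(n)) {
    mm <- rep(mu[i], 2 * nrep)
    if (!is.null(cond_mult)) mm[cond == "disease"] <- mm[cond == "disease"] * cond_mult[i]
    m[i, ] <- stats::rnbinom(2 * nrep, size = 1 / phi, mu = mm)
  }
  rownames(m) <- paste0("L", seq_len(n))
  list(counts = m, samples = data.frame(condition = cond))
}

test_that("BH matches its definitional step-up computation", {
  set.seed(404)
  for (k in 1:200) {
    p <- stats::runif(sample(1:50, 1))
    expect_equal(bh_adjust(p), bh_stepup(p))
  }
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.04), 0.04)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  ## NA p-values propagate and are excluded from the family
  q <- bh_adjust(c(0.01, NA, 0.02))
  expect_true(is.na(q[2]))
  expect_equal(q[c(1, 3)], bh_stepup(c(0.01, 0.02)))
  expect_error(bh_adjust(c(0.5, 1.2)), "outside")
})

test_that("dispersion estimation is calibrated on simulated counts", {
  set.seed(88)
  groups <- factor(rep(c("a", "b"), each = 5))
  mu <- exp(stats::rnorm(300, log(100), 0.5))
  pois <- t(vapply(mu, function(m) stats::rpois(10, m), numeric(10)))
  expect_lte(median(estimate_dispersion(pois, groups)), 0.01)
  nb <- t(vapply(mu, function(m) stats::rnbinom(10, size = 10, mu = m),
                 numeric(10)))
  phi_hat <- median(estimate_dispersion(nb, groups))
  expect_gte(phi_hat, 0.05); expect_lte(phi_hat, 0.2)
  ## constant counts hit the floor
  const <- matrix(50L, 5, 10)
  expect_true(all(estimate_dispersion(const, groups) <= 1e-3))
})

test_that("exact nulls give zero fold change and all-zero loci are untestable", {
  counts <- rbind(L1 = rep(100L, 6), L2 = rep(0L, 6))
  ss <- data.frame(condition = rep(c("control", "disease"), each = 3))
  r <- test_de(counts, ss, design = "one_factor")
  expect_equal(r$log2fc[1], 0, tolerance = 1e-6)
  expect_false(r$testable[2])
  expect_equal(r$p[2], 1)
  expect_equal(r$log2fc[2], 0)
})

test_that("swapping condition labels negates log2fc and preserves p", {
  set.seed(31)
  d <- sim_counts(40, exp(stats::rnorm(40, log(80), 0.7)), 0.1,
                  cond_mult = sample(c(1, 4), 40, TRUE))
  r1 <- test_de(d$counts, d$samples, design = "one_factor")
  ss2 <- d$samples
  ss2$condition <- ifelse(ss2$condition == "control", "disease", "control")
  r2 <- test_de(d$counts, ss2, design = "one_factor")
  expect_equal(r2$log2fc, -r1$log2fc, tolerance = 1e-5)
  expect_equal(r2$p, r1$p, tolerance = 1e-5)
})

test_that("library-size normalization absorbs global and per-sample scaling", {
  set.seed(32)
  d <- sim_counts(30, exp(stats::rnorm(30, log(60), 0.5)), 0.1)
  ## a common factor leaves the size factors untouched ...
  expect_equal(size_factors_mor(d$counts * 5L), size_factors_mor(d$counts))
  ## ... and inference is stable (identical p is impossible: multiplying
  ## counts changes the NB mean-variance relation of the data itself)
  r1 <- test_de(d$counts, d$samples, design = "one_factor",
                phi = rep(0.1, 30))
  r2 <- test_de(d$counts * 5L, d$samples, design = "one_factor",
                phi = rep(0.1, 30))
  expect_gt(stats::cor(r1$p, r2$p), 0.99)
  expect_equal(r2$log2fc, r1$log2fc, tolerance = 0.02)
  ## per-sample depth differences are recovered by median-of-ratios:
  ## exact on noiseless data, approximate on sampled counts
  f <- c(1L, 3L, 1L, 2L, 1L, 4L)
  flat <- matrix(rep(c(10L, 40L, 100L), each = 6), 3, 6, byrow = TRUE)
  sf0 <- size_factors_mor(sweep(flat, 2, f, "*"))
  expect_equal(sf0 / sf0[1], f / f[1], tolerance = 1e-9)
  sf <- size_factors_mor(sweep(d$counts, 2, f, "*"))
  expect_equal(sf / sf[1], f / f[1], tolerance = 0.2)
})

test_that("the two-factor design removes the age effect from the condition test", {
  set.seed(33)
  n <- 60
  ss <- data.frame(condition = rep(rep(c("control", "disease"), each = 3), 2),
                   age = rep(c("4w", "12w"), each = 6))
  mu <- exp(stats::rnorm(n, log(100), 0.5))
  counts <- matrix(0L, n, 12)
  for (i in seq_len(n)) {
    mm <- rep(mu[i], 12)
    mm[ss$age == "12w"] <- mm[ss$age == "12w"] * 3   # age effect only
    counts[i, ] <- stats::rnbinom(12, size = 10, mu = mm)
  }
  rownames(counts) <- paste0("L", 1:n)
  r <- test_de(counts, ss, design = "two_factor")
  ## a pure age effect must not masquerade as a condition effect
  expect_lt(sum(r$significant), 0.1 * n)
  expect_lt(median(abs(r$log2fc)), 0.5)
})

test_that("NB-GLM p-values track an independent edgeR analysis", {
  set.seed(34)
  d <- sim_counts(150, exp(stats::rnorm(150, log(100), 0.7)), 0.1,
                  cond_mult = sample(c(1, 1, 4), 150, TRUE))
  mine <- test_de(d$counts, d$samples, design = "one_factor")
  suppressMessages({
    y <- edgeR::DGEList(d$counts, group = d$samples$condition)
    y <- edgeR::calcNormFactors(y)
    y <- edgeR::estimateDisp(y, stats::model.matrix(~ d$samples$condition))
    fit <- edgeR::glmFit(y, stats::model.matrix(~ d$samples$condition))
    lrt <- edgeR::glmLRT(fit)
  })
  expect_gt(stats::cor(mine$p, lrt$table$PValue, method = "spearman"), 0.9)
  expect_gt(stats::cor(mine$log2fc, lrt$table$logFC), 0.95)
})

test_that("cross-model coherence counts joint and concordant loci", {
  mk <- function(ids, sig, lfc) data.frame(locus_id = ids, log2fc = lfc,
                                           p = 0.01, q = 0.01,
                                           significant = sig, testable = TRUE)
  ids <- paste0("L", 1:50)
  a <- mk(ids, ids %in% paste0("L", 1:10), rep(1, 50))
  b <- mk(ids, ids %in% paste0("L", 11:20), rep(1, 50))
  disjoint <- cross_model_summary(list(m1 = a, m2 = b))
  expect_equal(disjoint$n_joint, 0L)
  same <- cross_model_summary(list(m1 = a, m2 = a, m3 = a))
  expect_true(all(same$concordance == 1))
  expect_equal(same$n_joint, rep(10L, 4))
  ## 30 planted shared-direction loci across three models
  sig <- ids %in% paste0("L", 1:30)
  lfc <- ifelse(sig, 2, 0)
  tri <- cross_model_summary(list(wt1 = mk(ids, sig, lfc),
                                  pod = mk(ids, sig, lfc),
                                  adr = mk(ids, sig, lfc)))
  expect_equal(tri$n_joint[tri$models == "wt1+pod+adr"], 30L)
  expect_equal(tri$concordance[tri$models == "wt1+pod+adr"], 1.0)
})

test_that("combine_contrasts ORs significance across time points", {
  mk <- function(sig) data.frame(locus_id = c("a", "b", "c"), log2fc = 1,
                                 p = 0.01, q = 0.01, significant = sig,
                                 testable = TRUE)
  comb <- combine_contrasts(list(mk(c(TRUE, FALSE, FALSE)),
                                 mk(c(FALSE, TRUE, FALSE))))
  expect_equal(comb$significant, c(TRUE, TRUE, FALSE))
})
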