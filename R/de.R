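#' Median-of-ratios library size factors
#'
#' Size factor per sample = median ratio of its counts to the per-locus
#' geometric mean, over loci with all-positive counts; falls back to
#' library-size ratios when no locus qualifies. Factors are scaled to
#' geometric mean 1.
#'
#' @param counts loci x samples integer matrix.
#' @return Numeric vector of size factors, one per sample.
#' @export
size_factors_mor <- function(counts) {
  counts <- as.matrix(counts)
  pos <- rowSums(counts > 0) == ncol(counts)
  if (any(pos)) {
    lg <- log(counts[pos, , drop = FALSE])
    ref <- rowMeans(lg)
    sf <- apply(exp(lg - ref), 2, stats::median)
  } else {
    ls <- colSums(counts)
    sf <- ls / mean(ls)
  }
  sf / exp(mean(log(sf)))
}

#' Moment-based shrunk dispersion estimates
#'
#' Per-locus negative-binomial dispersion by the method of moments on
#' size-factor-normalized counts: phi = max(0, (s^2 - mu)/mu^2), where the
#' within-group sample variances are pooled over the design's groups. Each
#' estimate is shrunk toward a common dispersion with weight
#' `n_prior / (n_prior + df)`, df being the locus' residual degrees of
#' freedom, and floored at 1e-6. The common dispersion is the mean of the
#' per-locus estimates with the upper 5 percent winsorized: the per-locus
#' moment estimator is scale-free but right-skewed (low-count loci can
#' produce wild values), so capping the upper tail stabilizes the mean
#' without the downward bias that symmetric trimming of a skewed
#' distribution would introduce. With single-sample groups only, the
#' common dispersion cannot be estimated and a default of 0.1 is returned
#' for every locus with a warning.
#'
#' @param counts loci x samples matrix.
#' @param groups factor of group membership per sample (one level per
#'   design cell).
#' @param sf size factors (default [size_factors_mor()]).
#' @param n_prior prior weight in pseudo-observations (default 10).
#' @return Numeric vector of dispersions, one per locus.
#' @export
estimate_dispersion <- function(counts, groups, sf = NULL, n_prior = 10) {
  counts <- as.matrix(counts)
  groups <- as.factor(groups)
  if (is.null(sf)) sf <- size_factors_mor(counts)
  y <- sweep(counts, 2, sf, "/")
  df <- ncol(y) - nlevels(groups)
  if (df <= 0) {
    warning("no replicated groups: using a default common dispersion")
    return(rep(0.1, nrow(counts)))
  }
  mom <- t(apply(y, 1, function(v) {
    ss <- 0
    for (g in levels(groups)) {
      vg <- v[groups == g]
      if (length(vg) > 1L) ss <- ss + sum((vg - mean(vg))^2)
    }
    c(mu = mean(v), s2 = ss / df)
  }))
  phi_raw <- ifelse(mom[, "mu"] > 0,
                    pmax(0, (mom[, "s2"] - mom[, "mu"]) / mom[, "mu"]^2), 0)
  common <- mean(pmin(phi_raw, stats::quantile(phi_raw, 0.95)))
  w <- n_prior / (n_prior + df)
  phi <- w * common + (1 - w) * phi_raw
  pmax(phi, 1e-6)
}

## NB log-linear fit by IRLS at fixed dispersion; returns coefficients and
## log-likelihood. X must be full rank.
fit_nb_glm <- function(y, X, offset, phi, maxit = 50, tol = 1e-8) {
  beta <- rep(0, ncol(X))
  beta[1] <- log(mean(pmax(y / exp(offset), 1e-8)))
  eta <- drop(X %*% beta) + offset
  mu <- pmax(exp(eta), 1e-10)
  ll_old <- -Inf
  for (it in seq_len(maxit)) {
    w <- mu / (1 + phi * mu)
    z <- (eta - offset) + (y - mu) / mu
    fit <- stats::lm.wfit(X, z, w)
    beta <- fit$coefficients
    if (anyNA(beta)) stop("design matrix not full rank")
    eta <- drop(X %*% beta) + offset
    eta <- pmin(pmax(eta, -30), 30)
    mu <- pmax(exp(eta), 1e-10)
    ll <- sum(stats::dnbinom(y, size = 1 / phi, mu = mu, log = TRUE))
    if (abs(ll - ll_old) < tol) break
    ll_old <- ll
  }
  list(beta = beta, loglik = ll, mu = mu)
}

#' Per-locus negative-binomial differential expression
#'
#' Fits a per-locus NB log-linear model at fixed (moment-shrunk)
#' dispersion with median-of-ratios size factors as offsets, and tests the
#' condition effect by a 1-df likelihood-ratio chi-square. `log2fc` is the
#' condition (disease vs control) coefficient divided by log(2). Designs:
#' `one_factor` fits `~ condition`; `two_factor` fits `~ age + condition`
#' against `~ age`. All-zero loci are reported untestable with p = 1 and
#' log2fc = 0. q-values are Benjamini-Hochberg over testable loci within
#' the contrast; `significant` means q below `fdr`.
#'
#' @param counts loci x samples matrix.
#' @param samples data.frame with one row per sample (in column order of
#'   `counts`): `condition` (control/disease) and, for the two-factor
#'   design, `age`.
#' @param design `"one_factor"` or `"two_factor"`.
#' @param fdr significance level on q (default 0.05).
#' @param phi optional fixed dispersions (default: estimated).
#' @return data.frame: `locus_id`, `log2fc`, `p`, `q`, `significant`,
#'   `testable`.
#' @export
test_de <- function(counts, samples, design = c("one_factor", "two_factor"),
                    fdr = 0.05, phi = NULL) {
  design <- match.arg(design)
  counts <- as.matrix(counts)
  stopifnot(nrow(samples) == ncol(counts))
  cond <- factor(samples$condition, levels = c("control", "disease"))
  if (anyNA(cond)) stop("condition must be control/disease")
  if (design == "two_factor") {
    age <- factor(samples$age)
    X_full <- stats::model.matrix(~ age + cond)
    X_red <- stats::model.matrix(~ age)
    groups <- interaction(age, cond, drop = TRUE)
  } else {
    X_full <- stats::model.matrix(~ cond)
    X_red <- stats::model.matrix(~ 1, data = data.frame(row.names = seq_along(cond)))
    groups <- cond
  }
  sf <- size_factors_mor(counts)
  offset <- log(sf)
  if (is.null(phi)) phi <- estimate_dispersion(counts, groups, sf = sf)
  cond_col <- ncol(X_full)                 # condition coefficient is last
  n <- nrow(counts)
  log2fc <- numeric(n); p <- numeric(n); testable <- logical(n)
  for (i in seq_len(n)) {
    y <- counts[i, ]
    if (all(y == 0)) { log2fc[i] <- 0; p[i] <- 1; testable[i] <- FALSE; next }
    full <- fit_nb_glm(y, X_full, offset, phi[i])
    red <- fit_nb_glm(y, X_red, offset, phi[i])
    lr <- max(0, 2 * (full$loglik - red$loglik))
    log2fc[i] <- full$beta[cond_col] / log(2)
    p[i] <- stats::pchisq(lr, df = 1, lower.tail = FALSE)
    testable[i] <- TRUE
  }
  q <- rep(NA_real_, n)
  q[testable] <- bh_adjust(p[testable])
  out <- data.frame(locus_id = rownames(counts) %||% as.character(seq_len(n)),
                    log2fc = log2fc, p = p, q = q,
                    significant = !is.na(q) & q < fdr,
                    testable = testable, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up BH with monotonicity enforcement. NaN/NA p-values propagate as
#' NA and are excluded from the family size m.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return q-values of the same length.
#' @export
bh_adjust <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values outside [0, 1]")
  q <- rep(NA_real_, length(p))
  q[ok] <- stats::p.adjust(p[ok], method = "BH")
  q
}

#' Cross-model coherence of differential expression
#'
#' For every pair and the triple of disease models: how many loci are
#' jointly significant, and among those, how many have a concordant sign of
#' log2 fold change in every involved model.
#'
#' @param results named list of [test_de()] results (one combined result
#'   per model; a locus counts as DE if `significant` there).
#' @return data.frame: `models`, `n_joint`, `n_concordant`, `concordance`.
#' @export
cross_model_summary <- function(results) {
  stopifnot(length(results) >= 2L, !is.null(names(results)))
  nm <- names(results)
  combos <- c(utils::combn(nm, 2, simplify = FALSE),
              if (length(nm) >= 3) utils::combn(nm, 3, simplify = FALSE))
  rows <- lapply(combos, function(ms) {
    sig_sets <- lapply(results[ms], function(r) r$locus_id[r$significant])
    joint <- Reduce(intersect, sig_sets)
    conc <- 0L
    if (length(joint)) {
      signs <- vapply(results[ms], function(r)
        sign(r$log2fc[match(joint, r$locus_id)]), numeric(length(joint)))
      signs <- matrix(signs, nrow = length(joint))
      conc <- sum(apply(signs, 1, function(s) all(s == s[1L]) && all(s != 0)))
    }
    data.frame(models = paste(ms, collapse = "+"),
               n_joint = length(joint), n_concordant = conc,
               concordance = if (length(joint)) conc / length(joint) else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Combine contrasts of one model into a per-locus DE call
#'
#' A locus counts as differentially expressed in a model if it is
#' significant in any of the supplied contrasts (e.g. 4-week, 12-week, or
#' the two-factor test). The reported log2fc is taken from the first
#' contrast in the list (by convention the pooled/two-factor one).
#'
#' @param contrasts list of [test_de()] results for one model.
#' @return A single data.frame in [test_de()] layout.
#' @export
combine_contrasts <- function(contrasts) {
  stopifnot(length(contrasts) >= 1L)
  base <- contrasts[[1L]]
  sig <- base$significant
  for (k in seq_along(contrasts)[-1L]) {
    m <- match(base$locus_id, contrasts[[k]]$locus_id)
    sig <- sig | (!is.na(m) & contrasts[[k]]$significant[m])
  }
  base$significant <- sig
  base
}

#' Read a count matrix and sample sheet
#'
#' @param counts_path TSV, first column locus ids, remaining columns
#'   integer counts per sample.
#' @param samples_path TSV with columns `sample`, `model`, `condition` and
#'   optionally `age`.
#' @return List with `counts` (matrix) and `samples` (data.frame, ordered
#'   to match the count columns).
#' @export
read_counts <- function(counts_path, samples_path) {
  df <- utils::read.delim(counts_path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  if (any(m < 0) || any(m != round(m))) stop("counts must be non-negative integers")
  ss <- utils::read.delim(samples_path, stringsAsFactors = FALSE)
  ss <- ss[match(colnames(m), ss$sample), , drop = FALSE]
  if (anyNA(ss$sample)) stop("sample sheet does not cover all count columns")
  list(counts = m, samples = ss)
}
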