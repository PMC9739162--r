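toy_counts <- function(m) {
  tibble::as_tibble(cbind(
    tibble::tibble(feature_id = paste0("f", seq_len(nrow(m)))),
    as.data.frame(m)
  ))
}

test_that("CPM normalises to one million per column and is scale-invariant", {
  m <- toy_counts(cbind(s1 = c(10, 90), s2 = c(50, 50)))
  out <- cpm(m)
  expect_equal(out$s1, c(1e5, 9e5))
  expect_equal(sum(out$s1), 1e6)
  expect_equal(sum(out$s2), 1e6)
  # doubling a column's counts leaves its CPM unchanged
  m2 <- m; m2$s1 <- m$s1 * 2
  expect_equal(cpm(m2)$s1, out$s1)
  # zero library errors
  m3 <- m; m3$s1 <- c(0, 0)
  expect_error(cpm(m3), "Zero library")
})

test_that("the expression filter keeps features at the boundary", {
  # feature f1 reaches 10 CPM in exactly 2 of 3 samples
  m <- toy_counts(rbind(c(1000, 1000, 0), c(99000, 99000, 100000)))
  expect_equal(filter_by_expression(m, min_cpm = 10, min_samples = 2)$feature_id,
               c("f1", "f2"))
  expect_equal(filter_by_expression(m, min_cpm = 10, min_samples = 3)$feature_id,
               "f2")
  expect_equal(nrow(filter_by_expression(m, min_cpm = 0, min_samples = 0)), 2)
  expect_equal(nrow(filter_by_expression(m, min_cpm = Inf, min_samples = 1)), 0)
})

test_that("TMM factors are 1 for identical or depth-scaled columns, geomean 1 always", {
  withr::local_seed(3)
  base <- rnbinom(400, mu = 50, size = 5) + 1
  m <- toy_counts(cbind(s1 = base, s2 = base))
  expect_equal(unname(tmm_factors(m)), c(1, 1))
  # pure depth difference
  m2 <- toy_counts(cbind(s1 = base, s2 = base * 2))
  expect_equal(unname(tmm_factors(m2)), c(1, 1))
  # geometric mean exactly 1 on random matrices
  for (i in 1:10) {
    r <- toy_counts(matrix(rnbinom(300 * 4, mu = 40, size = 2),
                           ncol = 4, dimnames = list(NULL, paste0("s", 1:4))))
    f <- tmm_factors(r)
    expect_equal(exp(mean(log(f))), 1, tolerance = 1e-12)
  }
})

test_that("TMM matches an independent step-by-step recomputation", {
  withr::local_seed(9)
  n <- 200
  base <- rnbinom(n, mu = 100, size = 10) + 1
  m <- cbind(s1 = base, s2 = base + rpois(n, 2), s3 = base + rpois(n, 2))
  m[1:60, "s3"] <- m[1:60, "s3"] * 4   # 30% of features inflated 4-fold
  f <- tmm_factors(toy_counts(m))
  expect_lt(f[["s3"]], 1)

  # independent recomputation, plain loops
  lib <- colSums(m)
  f75 <- apply(m, 2, function(col) quantile(col / sum(col), 0.75))
  ref <- which.min(abs(f75 - mean(f75)))
  raw <- sapply(1:3, function(j) {
    keep <- m[, j] > 0 & m[, ref] > 0
    x <- m[keep, j]; r <- m[keep, ref]
    M <- log2((x / lib[j]) / (r / lib[ref]))
    A <- 0.5 * log2((x / lib[j]) * (r / lib[ref]))
    v <- (lib[j] - x) / (lib[j] * x) + (lib[ref] - r) / (lib[ref] * r)
    if (max(abs(M)) < 1e-6) return(1)
    nn <- length(M)
    loM <- floor(nn * 0.3) + 1; hiM <- nn + 1 - loM
    loA <- floor(nn * 0.05) + 1; hiA <- nn + 1 - loA
    k2 <- rank(M) >= loM & rank(M) <= hiM & rank(A) >= loA & rank(A) <= hiA
    2^(sum(M[k2] / v[k2]) / sum(1 / v[k2]))   # inverse-variance weights
  })
  expected <- raw / exp(mean(log(raw)))
  expect_equal(unname(f), unname(expected), tolerance = 1e-12)
})

test_that("TMM agrees with the reference implementation", {
  withr::local_seed(21)
  m <- matrix(rnbinom(500 * 5, mu = 60, size = 3), ncol = 5,
              dimnames = list(NULL, paste0("s", 1:5)))
  m[m == 0] <- m[m == 0] + rbinom(sum(m == 0), 1, 0.5)  # sparse zeros fine
  f <- tmm_factors(toy_counts(m))
  ref <- edgeR::calcNormFactors(m, method = "TMM")
  expect_equal(unname(f), unname(ref), tolerance = 1e-8)
})

test_that("log-CPM is finite, monotone, and converges to log2(CPM)", {
  m <- toy_counts(cbind(s1 = c(0, 5, 50, 5e6), s2 = c(1, 1, 1, 1e6)))
  lc <- log_cpm(m)
  expect_true(all(is.finite(as.matrix(lc[-1]))))
  expect_true(all(diff(lc$s1) > 0))
  big <- log2(cpm(m)$s1[4])
  expect_equal(lc$s1[4], big, tolerance = 1e-4)
})

test_that("BH adjustment matches the hand-evaluated step-up and its invariants", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.3), 0.3)
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
  withr::local_seed(5)
  p <- runif(50)
  adj <- bh_adjust(p)
  ord <- sample(50)
  expect_equal(bh_adjust(p[ord]), adj[ord])   # permutation-equivariant
  expect_true(all(adj >= p))
  # idempotent on an already-adjusted monotone vector
  expect_equal(bh_adjust(sort(adj)) >= sort(adj), rep(TRUE, 50))
})

sim_logcpm <- function(n_feat, n_per_group, delta = 0, sd = 1) {
  g <- rep(c("control", "case"), each = n_per_group)
  y <- matrix(rnorm(n_feat * 2 * n_per_group, sd = sd), nrow = n_feat)
  y[, g == "case"] <- y[, g == "case"] + delta
  colnames(y) <- paste0("s", seq_along(g))
  list(tbl = tibble::as_tibble(cbind(tibble::tibble(feature_id = paste0("f", 1:n_feat)),
                                     as.data.frame(y))),
       groups = stats::setNames(g, colnames(y)))
}

test_that("moderated t reduces to the ordinary t at d0 = 0", {
  withr::local_seed(2)
  d <- sim_logcpm(50, 6)
  de <- moderated_de(d$tbl, d$groups, prior_df = 0)
  y <- as.matrix(d$tbl[-1])
  tt <- apply(y, 1, function(row) {
    t.test(row[d$groups == "case"], row[d$groups == "control"],
           var.equal = TRUE)$statistic
  })
  expect_equal(de$t_mod, unname(tt), tolerance = 1e-10)
  expect_equal(de$df_total, rep(10, 50))
})

test_that("at d0 = Inf all features share the pooled prior variance", {
  withr::local_seed(2)
  d <- sim_logcpm(50, 6)
  de <- moderated_de(d$tbl, d$groups, prior_df = Inf)
  # shared variance => |t| proportional to |log2fc|
  ratio <- abs(de$t_mod / de$log2fc)
  expect_equal(max(ratio) - min(ratio), 0, tolerance = 1e-10)
})

test_that("moderated t agrees with the reference empirical-Bayes implementation", {
  withr::local_seed(13)
  # heteroskedastic features: per-feature variances from a scaled
  # inverse-chi-square, so the prior df estimate is finite
  n_feat <- 300; n_per <- 5
  g <- rep(c("control", "case"), each = n_per)
  sd_f <- sqrt(4 / rchisq(n_feat, df = 4))
  y <- matrix(rnorm(n_feat * 2 * n_per), nrow = n_feat) * sd_f
  colnames(y) <- paste0("s", seq_along(g)); rownames(y) <- paste0("f", 1:n_feat)
  tbl <- tibble::as_tibble(cbind(tibble::tibble(feature_id = rownames(y)),
                                 as.data.frame(y)))
  groups <- stats::setNames(g, colnames(y))
  de <- moderated_de(tbl, groups)
  design <- cbind(1, group = as.numeric(g == "case"))
  fit <- limma::eBayes(limma::lmFit(y, design))
  expect_true(is.finite(attr(de, "prior_df")))
  expect_equal(attr(de, "prior_df"), fit$df.prior, tolerance = 1e-6)
  expect_equal(attr(de, "prior_var"), fit$s2.prior, tolerance = 1e-6)
  expect_equal(de$t_mod, unname(fit$t[, "group"]), tolerance = 1e-8)
  expect_equal(de$p, unname(fit$p.value[, "group"]), tolerance = 1e-8)

  # homoskedastic features: both approaches fall back to an infinite prior
  d2 <- sim_logcpm(300, 5)
  de2 <- moderated_de(d2$tbl, d2$groups)
  y2 <- as.matrix(d2$tbl[-1])
  fit2 <- limma::eBayes(limma::lmFit(y2, design))
  expect_equal(attr(de2, "prior_df"), fit2$df.prior)
  expect_equal(attr(de2, "prior_var"), fit2$s2.prior, tolerance = 1e-8)
})

test_that("null simulation keeps the type-I error rate near nominal", {
  withr::local_seed(101)
  d <- sim_logcpm(2000, 8)
  de <- moderated_de(d$tbl, d$groups)
  frac <- mean(de$p < 0.05)
  expect_gte(frac, 0.035)
  expect_lte(frac, 0.065)
})

test_that("moderated_de validates degenerate designs", {
  d <- sim_logcpm(5, 2)
  g <- d$groups; g[2] <- "case"  # leaves one control only
  expect_error(moderated_de(d$tbl, g), "at least 2 samples")
})

test_that("variance partition recovers exact and null structure", {
  withr::local_seed(17)
  n <- 24
  # mutually orthogonal covariates, so the order-averaged sequential
  # decomposition has no shared variance to split
  sex <- rep(c("M", "M", "F", "F"), n / 4)
  group <- rep(c("case", "control"), n / 2)
  s <- as.numeric(sex == "F") - 0.5
  g <- as.numeric(group == "case") - 0.5
  q <- qr.Q(qr(cbind(1, s, g, rnorm(n), rnorm(n))))
  cv <- tibble::tibble(RIN = q[, 4] + 7, PMI = q[, 5] * 10 + 15,
                       sex = sex, group = group)
  # response exactly equal to RIN
  y <- tibble::as_tibble(cbind(tibble::tibble(feature_id = "f1"),
                               as.data.frame(matrix(cv$RIN, nrow = 1,
                                                    dimnames = list(NULL, paste0("s", 1:n))))))
  vp <- variance_explained(y, cv)
  expect_equal(vp$RIN, 1, tolerance = 1e-9)
  expect_equal(unname(vp$PMI + vp$sex + vp$group + vp$residual), 0,
               tolerance = 1e-9)

  # pure-noise response: median fractions all small
  y2 <- matrix(rnorm(500 * n), nrow = 500,
               dimnames = list(paste0("f", 1:500), paste0("s", 1:n)))
  vp2 <- variance_explained(
    tibble::as_tibble(cbind(tibble::tibble(feature_id = rownames(y2)),
                            as.data.frame(y2))), cv)
  med <- glance(vp2)
  expect_lt(med$median_RIN, 0.05)
  expect_lt(med$median_PMI, 0.05)
  expect_lt(med$median_sex, 0.05)
  expect_lt(med$median_group, 0.05)
  # fractions sum to one per feature
  sums <- rowSums(as.matrix(vp2[, c("RIN", "PMI", "sex", "group", "residual")]))
  expect_equal(sums, rep(1, 500), ignore_attr = TRUE, tolerance = 1e-9)
})

test_that("variance partition recovers a planted group variance fraction", {
  withr::local_seed(23)
  n <- 26
  meta <- tibble::tibble(
    sample_id = paste0("s", 1:n),
    condition = rep(c("case", "control"), each = n / 2),
    RIN = runif(n, 4, 9), PMI = runif(n, 2, 30),
    sex = sample(c("M", "F"), n, TRUE),
    group = rep(c("case", "control"), each = n / 2)
  )
  counts <- simulate_counts(meta, paste0("f", 1:800), lfc = 0, dispersion = 0.1,
                            covariate_effects = c(group = 0.3))
  vp <- variance_explained(log_cpm(counts),
                           meta[, c("RIN", "PMI", "sex", "group")])
  expect_equal(glance(vp)$median_group, 0.3, tolerance = 0.1)
})

test_that("constant covariates get fraction zero with a warning", {
  withr::local_seed(1)
  n <- 10
  cv <- tibble::tibble(RIN = runif(n), flat = rep(1, n))
  y <- matrix(rnorm(3 * n), nrow = 3,
              dimnames = list(paste0("f", 1:3), paste0("s", 1:n)))
  expect_warning(
    vp <- variance_explained(
      tibble::as_tibble(cbind(tibble::tibble(feature_id = rownames(y)),
                              as.data.frame(y))), cv),
    "Constant")
  expect_equal(vp$flat, rep(0, 3))
})
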