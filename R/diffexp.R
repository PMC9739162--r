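# Expression filtering, TMM normalization, log-CPM and per-feature
# moderated-t differential expression. Count tables are tibbles with a
# feature_id column followed by one numeric column per sample; library
# sizes are always the column sums.

#' Counts per million mapped reads
#'
#' @param counts Count tibble (`feature_id` + sample columns).
#' @param norm_factors Optional named numeric vector of per-sample
#'   normalization factors (e.g. from [tmm_factors()]). With no factors,
#'   each CPM column sums to 1e6.
#' @return CPM tibble with the same shape as `counts`.
#' @export
cpm <- function(counts, norm_factors = NULL) {
  m <- .counts_matrix(counts)
  lib <- colSums(m)
  if (any(lib <= 0)) {
    abort(paste0("Zero library size for sample(s): ",
                 paste(colnames(m)[lib <= 0], collapse = ", ")))
  }
  f <- .match_factors(norm_factors, colnames(m))
  .counts_tibble(sweep(m, 2, lib * f, "/") * 1e6)
}

.match_factors <- function(norm_factors, samples) {
  if (is.null(norm_factors)) return(rep(1, length(samples)))
  if (!is.null(names(norm_factors))) {
    if (!all(samples %in% names(norm_factors))) {
      abort("norm_factors does not cover all samples")
    }
    unname(norm_factors[samples])
  } else {
    stopifnot(length(norm_factors) == length(samples))
    norm_factors
  }
}

#' Filter features on minimum expression
#'
#' Keeps a feature iff its (unnormalized) CPM is at least `min_cpm` in at
#' least `min_samples` samples. With `min_samples = "auto"` the cutoff is
#' `ceiling(0.7 * n)` where `n` is the number of samples in the smallest
#' tissue of `metadata`.
#'
#' @param counts Count tibble.
#' @param min_cpm CPM threshold (default 10).
#' @param min_samples Number of samples required at or above `min_cpm`
#'   (default 9), or `"auto"`.
#' @param metadata Sample metadata; required for `min_samples = "auto"`.
#' @return The filtered count tibble (sample set unchanged).
#' @export
filter_by_expression <- function(counts, min_cpm = 10, min_samples = 9,
                                 metadata = NULL) {
  if (identical(min_samples, "auto")) {
    if (is.null(metadata)) abort("min_samples = 'auto' requires metadata")
    smallest <- min(table(metadata$tissue))
    min_samples <- ceiling(0.7 * smallest)
  }
  n_samp <- ncol(counts) - 1L
  stopifnot(min_samples <= n_samp)
  cm <- .counts_matrix(cpm(counts))
  keep <- rowSums(cm >= min_cpm) >= min_samples
  counts[keep, , drop = FALSE]
}

#' Trimmed mean of M-values normalization factors
#'
#' Estimates a relative scaling factor per sample from doubly trimmed,
#' precision-weighted mean log-ratios against a reference sample (the
#' sample whose 75th-percentile CPM is closest to the mean of those
#' percentiles). Log-ratios (M) and average log-intensities (A) are
#' computed on features with nonzero counts in both sample and reference;
#' the top and bottom `trim_m` of M and `trim_a` of A are discarded and
#' the remaining M are averaged with inverse asymptotic-variance weights
#' `(N - x)/(N x)` summed over sample and reference. Factors are rescaled
#' to have geometric mean exactly 1.
#'
#' @param counts Count tibble with at least two samples.
#' @param trim_m Two-sided trim fraction on M (default 0.3).
#' @param trim_a Two-sided trim fraction on A (default 0.05).
#' @return Named numeric vector of factors, one per sample.
#' @export
tmm_factors <- function(counts, trim_m = 0.3, trim_a = 0.05) {
  m <- .counts_matrix(counts)
  if (ncol(m) < 2) abort("TMM needs at least 2 samples")
  if (any(colSums(m > 0) < 1)) abort("Each sample needs at least one nonzero count")
  lib <- colSums(m)
  f75 <- apply(sweep(m, 2, lib, "/"), 2, stats::quantile, probs = 0.75)
  ref_idx <- which.min(abs(f75 - mean(f75)))
  ref <- m[, ref_idx]
  nref <- lib[ref_idx]
  f <- vapply(seq_len(ncol(m)), function(j) {
    .tmm_pair(m[, j], lib[j], ref, nref, trim_m, trim_a)
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  stats::setNames(f, colnames(m))
}

# One sample vs reference; follows the standard doubly trimmed weighted
# mean of log-ratios with the usual sum-of-binomial-variances weights.
.tmm_pair <- function(obs, nobs, ref, nref, trim_m, trim_a) {
  keep <- obs > 0 & ref > 0
  if (!any(keep)) {
    warn("No features nonzero in both sample and reference; TMM factor set to 1")
    return(1)
  }
  obs <- obs[keep]; ref <- ref[keep]
  M <- log2((obs / nobs) / (ref / nref))
  A <- 0.5 * log2((obs / nobs) * (ref / nref))
  # per-feature asymptotic variance of M; weights are its inverse
  v <- (nobs - obs) / (nobs * obs) + (nref - ref) / (nref * ref)
  if (max(abs(M)) < 1e-6) return(1)
  n <- length(M)
  loM <- floor(n * trim_m) + 1; hiM <- n + 1 - loM
  loA <- floor(n * trim_a) + 1; hiA <- n + 1 - loA
  keep2 <- rank(M) >= loM & rank(M) <= hiM & rank(A) >= loA & rank(A) <= hiA
  if (!any(keep2)) return(1)
  f <- sum(M[keep2] / v[keep2]) / sum(1 / v[keep2])
  if (!is.finite(f)) f <- 0
  2^f
}

#' Log2 counts per million with a prior count
#'
#' `log2((count + prior) / (lib_size * factor + 2 * prior) * 1e6)`;
#' finite everywhere, including zero counts.
#'
#' @param counts Count tibble.
#' @param norm_factors Optional per-sample factors.
#' @param prior_count Positive pseudo-count (default 0.5).
#' @return Log-CPM tibble with the shape of `counts`.
#' @export
log_cpm <- function(counts, norm_factors = NULL, prior_count = 0.5) {
  stopifnot(prior_count > 0)
  m <- .counts_matrix(counts)
  lib <- colSums(m)
  if (any(lib <= 0)) abort("Zero library size")
  f <- .match_factors(norm_factors, colnames(m))
  adj <- lib * f
  .counts_tibble(log2(sweep(m + prior_count, 2, adj + 2 * prior_count, "/") * 1e6))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values in input order: the step-up
#'   `adj_(i) = min_(j >= i) m p_(j) / j`, capped at 1.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    abort("p-values must lie in [0, 1] with no NA")
  }
  stats::p.adjust(p, method = "BH")
}

# Newton solve of trigamma(y) = x, vectorized; standard monotone iteration
# on 1/y which is nearly linear in x.
.trigamma_inverse <- function(x) {
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (max(abs(dif / y)) < 1e-10) break
  }
  y
}

# Empirical-Bayes prior (d0, s0^2) for residual variances s2 on d df, by
# matching the first two moments of log s2 to a scaled inverse chi-square
# prior through digamma/trigamma identities.
.fit_variance_prior <- function(s2, d) {
  ok <- s2 > 0
  if (sum(ok) < 2) return(list(d0 = Inf, s02 = mean(s2)))
  z <- log(s2[ok])
  e <- z - digamma(d / 2) + log(d / 2)
  emean <- mean(e)
  evar <- stats::var(e) - trigamma(d / 2)
  if (!is.finite(evar) || evar <= 0) {
    return(list(d0 = Inf, s02 = mean(s2[ok])))
  }
  d0 <- 2 * .trigamma_inverse(evar)
  s02 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  list(d0 = d0, s02 = s02)
}

#' Moderated-t differential expression on log-CPM
#'
#' Per feature, an ordinary least-squares fit of log-CPM on the
#' case/control contrast (plus optional covariates) is moderated by an
#' empirical-Bayes variance prior shared across features: the prior
#' degrees of freedom and scale are estimated by moment matching on the
#' log residual variances, each feature's variance is shrunk to the
#' posterior `(d0 s0^2 + d s^2) / (d0 + d)`, and the group coefficient is
#' tested against a t distribution with `d0 + d` degrees of freedom.
#'
#' @param logcpm Log-CPM tibble (`feature_id` + sample columns).
#' @param groups Named character/factor vector or tibble mapping samples
#'   to `"case"`/`"control"` (any two labels; `control` is the reference
#'   when present, otherwise the first level).
#' @param covariates Optional tibble of per-sample covariates (rows in
#'   sample order of `logcpm`, or with a `sample_id` column).
#' @param prior_df Override for the prior degrees of freedom `d0`:
#'   `NULL` (estimate; default), `0` (no moderation: ordinary t), or
#'   `Inf` (all features share the pooled prior variance).
#' @return A `sponge_de` tibble: `feature_id`, `log2fc` (case minus
#'   control), `t_mod`, `df_total`, `p`, `adj_p`, `mean_log_cpm`,
#'   ordered as the input, with the prior stored as attributes
#'   `prior_df` and `prior_var`.
#' @export
moderated_de <- function(logcpm, groups, covariates = NULL, prior_df = NULL) {
  y <- .counts_matrix(logcpm)
  samples <- colnames(y)
  g <- .group_vector(groups, samples)
  if (min(table(g)) < 2) abort("Each group needs at least 2 samples")
  x <- .de_design(g, covariates, samples)
  n <- nrow(x); p_cols <- ncol(x)
  d <- n - p_cols
  if (d <= 0) abort("Zero residual degrees of freedom")
  qr_x <- qr(x)
  coefs <- t(qr.coef(qr_x, t(y)))
  resid <- t(qr.resid(qr_x, t(y)))
  s2 <- rowSums(resid^2) / d
  xtx_inv <- chol2inv(qr.R(qr_x))
  se_unit <- sqrt(xtx_inv[2, 2])  # group column is second (after intercept)
  prior <- if (is.null(prior_df)) {
    .fit_variance_prior(s2, d)
  } else if (is.infinite(prior_df)) {
    list(d0 = Inf, s02 = .fit_variance_prior(s2, d)$s02)
  } else if (prior_df == 0) {
    list(d0 = 0, s02 = NA_real_)
  } else {
    list(d0 = prior_df, s02 = .fit_variance_prior(s2, d)$s02)
  }
  s2_post <- if (is.infinite(prior$d0)) {
    rep(prior$s02, length(s2))
  } else if (prior$d0 == 0) {
    s2
  } else {
    (prior$d0 * prior$s02 + d * s2) / (prior$d0 + d)
  }
  beta <- coefs[, 2]
  t_mod <- beta / (se_unit * sqrt(s2_post))
  df_total <- prior$d0 + d  # Inf prior -> normal tail
  p <- 2 * stats::pt(-abs(t_mod), df = df_total)
  out <- tibble::tibble(
    feature_id = rownames(y),
    log2fc = unname(beta),
    t_mod = unname(t_mod),
    df_total = df_total,
    p = unname(p),
    adj_p = bh_adjust(unname(p)),
    mean_log_cpm = unname(rowMeans(y))
  )
  structure(
    out,
    prior_df = prior$d0, prior_var = prior$s02, residual_df = d,
    class = c("sponge_de", class(out))
  )
}

.group_vector <- function(groups, samples) {
  if (is.data.frame(groups)) {
    stopifnot(all(c("sample_id", "condition") %in% names(groups)))
    groups <- stats::setNames(as.character(groups$condition), groups$sample_id)
  }
  if (!is.null(names(groups))) {
    if (!all(samples %in% names(groups))) abort("groups does not cover all samples")
    groups <- groups[samples]
  } else {
    stopifnot(length(groups) == length(samples))
  }
  g <- as.character(groups)
  lev <- unique(g)
  if (length(lev) != 2) abort("Exactly two group labels required")
  if ("control" %in% lev) lev <- c("control", setdiff(lev, "control"))
  factor(g, levels = lev)
}

.de_design <- function(g, covariates, samples) {
  x <- cbind(`(Intercept)` = 1, group = as.numeric(g) - 1)
  if (!is.null(covariates)) {
    cv <- covariates
    if ("sample_id" %in% names(cv)) {
      cv <- cv[match(samples, cv$sample_id), setdiff(names(cv), "sample_id"), drop = FALSE]
    }
    mm <- stats::model.matrix(~ ., data = as.data.frame(cv))[, -1, drop = FALSE]
    x <- cbind(x, mm)
  }
  x
}

#' Per-feature variance explained by sample covariates
#'
#' Fits the fixed-effects model `log-expression ~ RIN + PMI + sex + group`
#' (or any covariate set supplied) per feature and partitions the model
#' sum of squares into per-covariate fractions using sequential sums of
#' squares averaged over all covariate orderings, which removes the order
#' dependence of sequential decomposition. Fractions plus the residual
#' fraction sum to 1 per feature.
#'
#' @param logcpm Log-expression tibble (`feature_id` + sample columns).
#' @param covariates Tibble of per-sample covariates (optionally with a
#'   `sample_id` column); every non-ID column is a term.
#' @return A `sponge_varpart` tibble: `feature_id`, one fraction column
#'   per covariate, and `residual`. `glance()` reports the median
#'   fraction per covariate across features.
#' @export
variance_explained <- function(logcpm, covariates) {
  y <- .counts_matrix(logcpm)
  samples <- colnames(y)
  cv <- covariates
  if ("sample_id" %in% names(cv)) {
    if (!all(samples %in% cv$sample_id)) abort("covariates must cover all samples")
    cv <- cv[match(samples, cv$sample_id), setdiff(names(cv), "sample_id"), drop = FALSE]
  }
  if (anyNA(cv)) abort("covariate table must be complete for all samples")
  terms <- names(cv)
  const <- vapply(cv, function(v) length(unique(v)) < 2, logical(1))
  if (any(const)) {
    warn(paste0("Constant covariate(s) assigned fraction 0: ",
                paste(terms[const], collapse = ", ")))
  }
  active <- terms[!const]
  yc <- y - rowMeans(y)
  tss <- rowSums(yc^2)
  zero_tss <- tss <= 0
  frac <- matrix(0, nrow = nrow(y), ncol = length(terms),
                 dimnames = list(rownames(y), terms))
  if (length(active) > 0 && !all(zero_tss)) {
    # model-matrix columns per term
    mm_cols <- lapply(active, function(tm) {
      stats::model.matrix(~ ., data = as.data.frame(cv[tm]))[, -1, drop = FALSE]
    })
    names(mm_cols) <- active
    orderings <- .permutations(seq_along(active))
    acc <- matrix(0, nrow = nrow(y), ncol = length(active),
                  dimnames = list(NULL, active))
    for (ord in orderings) {
      x <- matrix(1, nrow = length(samples), ncol = 1)
      prev_fit <- rep(0, nrow(y))
      for (k in ord) {
        x <- cbind(x, mm_cols[[k]])
        q <- qr.Q(qr(x))
        fit <- rowSums((y %*% q)^2) - rowSums(y)^2 / length(samples)
        acc[, active[k]] <- acc[, active[k]] + (fit - prev_fit)
        prev_fit <- fit
      }
    }
    acc <- acc / length(orderings)
    frac[!zero_tss, active] <- acc[!zero_tss, , drop = FALSE] / tss[!zero_tss]
    frac[frac < 0 & frac > -1e-12] <- 0
  }
  out <- tibble::as_tibble(frac)
  out$residual <- ifelse(zero_tss, 1, pmax(0, 1 - rowSums(frac)))
  out <- dplyr::bind_cols(tibble::tibble(feature_id = rownames(y)), out)
  structure(out, covariate_terms = terms,
            class = c("sponge_varpart", class(out)))
}

.permutations <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in .permutations(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
  }
  out
}
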