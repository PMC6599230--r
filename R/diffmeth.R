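#' Median-of-ratios size factors
#'
#' Per-sample normalization factor: the median, over peaks with all
#' counts positive, of the ratio of the sample's count to the per-peak
#' geometric mean; the returned factors are rescaled so their geometric
#' mean is 1.
#'
#' @param counts peaks x samples integer matrix, or a `count_matrix`.
#' @param pseudo_reference if `TRUE`, the reference geometric mean is
#'   computed over positive counts only, allowing matrices without any
#'   all-positive peak.
#' @return Named positive numeric vector, one factor per sample.
#' @export
size_factors <- function(counts, pseudo_reference = FALSE) {
  if (inherits(counts, "count_matrix")) counts <- counts$counts
  counts <- as.matrix(counts)
  if (pseudo_reference) {
    log_geo <- apply(counts, 1, function(r) mean(log(r[r > 0])))
    use <- is.finite(log_geo)
  } else {
    use <- rowSums(counts > 0) == ncol(counts)
    if (!any(use))
      stop(paste("no peak with all-positive counts;",
                 "re-run with pseudo_reference = TRUE"))
    log_geo <- rowMeans(log(pmax(counts, 1e-300)))
  }
  sf <- apply(counts[use, , drop = FALSE], 2, function(col) {
    r <- col / exp(log_geo[use])
    stats::median(r[is.finite(r)])
  })
  sf / exp(mean(log(sf)))
}

#' Fit a negative-binomial GLM with log link
#'
#' Iteratively reweighted least squares maximizing the NB log-likelihood
#' at fixed dispersion `alpha` (variance `mu + alpha mu^2`); `alpha = 0`
#' gives the Poisson fit. Standard errors come from the observed
#' information matrix at the optimum. Non-convergence is flagged, not
#' raised.
#'
#' @param y non-negative integer counts.
#' @param X full-rank design matrix (rows match `y`).
#' @param offset per-observation log offset (log size factors).
#' @param alpha NB dispersion (>= 0).
#' @param tol,max_iter convergence control on the deviance-scale change
#'   of the linear predictor.
#' @return List: `beta` (natural-log scale), `se`, `mu`, `converged`,
#'   `iterations`.
#' @export
fit_nb_glm <- function(y, X, offset = 0, alpha = 0, tol = 1e-10,
                       max_iter = 100L) {
  X <- as.matrix(X)
  n <- length(y)
  stopifnot(nrow(X) == n, all(y >= 0), alpha >= 0)
  offset <- rep_len(offset, n)
  if (qr(X)$rank < ncol(X)) stop("design matrix is not full rank")
  beta <- qr.solve(X, log(pmax(y, 0.5)) - offset)
  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta) + offset
    mu <- pmin(exp(eta), 1e12)
    w <- mu / (1 + alpha * mu)           # Fisher weights, log link
    z <- (eta - offset) + (y - mu) / mu
    fit <- stats::lm.wfit(X, z, w)
    delta <- max(abs(fit$coefficients - beta))
    beta <- fit$coefficients
    if (!all(is.finite(beta))) {
      converged <- FALSE
      break
    }
    if (delta < tol * (1 + max(abs(beta)))) {
      converged <- TRUE
      break
    }
  }
  eta <- drop(X %*% beta) + offset
  mu <- pmin(exp(eta), 1e12)
  # observed information for the NB log link
  w_obs <- mu * (1 + alpha * y) / (1 + alpha * mu)^2
  info <- crossprod(X, X * w_obs)
  se <- tryCatch(sqrt(diag(solve(info))),
                 error = function(e) rep(NA_real_, ncol(X)))
  list(beta = unname(beta), se = unname(se), mu = mu,
       converged = converged, iterations = it)
}

nb_loglik <- function(y, mu, alpha) {
  if (alpha <= 0) return(sum(stats::dpois(y, mu, log = TRUE)))
  sum(stats::dnbinom(y, mu = mu, size = 1 / alpha, log = TRUE))
}

#' Per-peak dispersion estimation with trend shrinkage
#'
#' Three-stage estimate in the spirit of count-model packages, kept
#' deliberately simple: (1) raw per-peak dispersion maximizing the NB
#' likelihood given fitted Poisson means; (2) a mean-dispersion trend
#' `alpha(mu) = a0 + a1 / mu` fitted across peaks; (3) the final value,
#' the equal-weight log-space average (geometric mean) of raw and trend,
#' floored at 1e-8.
#'
#' @param counts peaks x samples matrix or `count_matrix`.
#' @param sf per-sample size factors.
#' @param X design matrix.
#' @return Data frame with columns `raw`, `trend`, `final`; the trend
#'   coefficients are attached as attribute `trend_coef` (`a0`, `a1`).
#' @export
estimate_dispersion <- function(counts, sf, X) {
  if (inherits(counts, "count_matrix")) counts <- counts$counts
  counts <- as.matrix(counts)
  X <- as.matrix(X)
  if (nrow(X) - ncol(X) < 2)
    stop("need at least 2 residual degrees of freedom")
  off <- log(sf)
  floor_a <- 1e-8
  base_mean <- rowMeans(sweep(counts, 2, sf, `/`))
  raw <- vapply(seq_len(nrow(counts)), function(i) {
    y <- counts[i, ]
    if (all(y == 0)) return(NA_real_)
    mu <- fit_nb_glm(y, X, offset = off, alpha = 0)$mu
    opt <- stats::optimize(function(la) -nb_loglik(y, mu, exp(la)),
                           interval = log(c(floor_a, 50)))
    a <- exp(opt$minimum)
    # boundary solutions (near-Poisson data) collapse to the floor
    if (-opt$objective <= nb_loglik(y, mu, floor_a) + 1e-8) floor_a else a
  }, numeric(1))
  ok <- !is.na(raw) & base_mean > 0
  # trend on informative peaks only; clamp coefficients to >= 0
  fit_ok <- ok & raw > floor_a
  if (sum(fit_ok) >= 10) {
    co <- stats::coef(stats::lm(raw[fit_ok] ~ I(1 / base_mean[fit_ok])))
    a0 <- max(co[1], floor_a)
    a1 <- max(co[2], 0)
  } else {
    a0 <- max(stats::median(raw[ok], na.rm = TRUE), floor_a)
    a1 <- 0
  }
  trend <- pmax(a0 + a1 / pmax(base_mean, 1e-8), floor_a)
  final <- exp((log(pmax(raw, floor_a)) + log(trend)) / 2)
  final[is.na(raw)] <- trend[is.na(raw)]
  final <- pmax(final, floor_a)
  structure(data.frame(raw = raw, trend = trend, final = final),
            trend_coef = c(a0 = unname(a0), a1 = unname(a1)))
}

#' Two-sided Wald p-values
#'
#' `p = 2 * (1 - Phi(|beta / se|))` for the tested coefficient.
#'
#' @param beta,se coefficient and standard-error vectors.
#' @return Numeric vector of p-values (NA where `se` is not positive).
#' @export
wald_pvalues <- function(beta, se) {
  p <- 2 * stats::pnorm(abs(beta / se), lower.tail = FALSE)
  p[!is.finite(se) | se <= 0] <- NA_real_
  p
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment (monotone, capped at 1).
#'
#' @param p vector of p-values in [0, 1] (NA allowed and propagated).
#' @return Adjusted p-values.
#' @export
bh_adjust <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  stats::p.adjust(p, method = "BH")
}

#' Rejection-maximizing independent filter
#'
#' Scans base-mean quantile thresholds; at each threshold only peaks
#' with `baseMean` >= the threshold are BH-adjusted, and the threshold
#' maximizing the number of adjusted p-values below `alpha_fdr` is
#' chosen (ties broken toward the smallest threshold, retaining the most
#' records). Filtered-out records get `NA` adjusted p-values.
#'
#' @param baseMean,pvalue per-peak mean of normalized counts and raw
#'   p-value (NA p-values are always filtered).
#' @param alpha_fdr FDR level at which rejections are counted.
#' @param quantiles filter-threshold grid, as quantiles of `baseMean`.
#' @return List: `padj`, `threshold` (baseMean cutoff), `quantile`,
#'   `n_rejected`, and the scanned `grid` data frame.
#' @export
independent_filter <- function(baseMean, pvalue, alpha_fdr = 0.05,
                               quantiles = seq(0, 0.95, by = 0.01)) {
  stopifnot(length(baseMean) == length(pvalue))
  if (length(pvalue) == 0)
    return(list(padj = numeric(0), threshold = 0, quantile = 0,
                n_rejected = 0L,
                grid = data.frame(quantile = numeric(0),
                                  threshold = numeric(0),
                                  n_rejected = integer(0))))
  cuts <- stats::quantile(baseMean, quantiles, names = FALSE, na.rm = TRUE)
  n_rej <- vapply(cuts, function(ct) {
    keep <- baseMean >= ct & !is.na(pvalue)
    sum(bh_adjust(pvalue[keep]) < alpha_fdr)
  }, integer(1))
  best <- which.max(n_rej)   # first maximum = smallest threshold
  keep <- baseMean >= cuts[best] & !is.na(pvalue)
  padj <- rep(NA_real_, length(pvalue))
  padj[keep] <- bh_adjust(pvalue[keep])
  list(padj = padj, threshold = cuts[best], quantile = quantiles[best],
       n_rejected = n_rej[best],
       grid = data.frame(quantile = quantiles, threshold = cuts,
                         n_rejected = n_rej))
}

#' Differential-methylation testing of a peak-count matrix
#'
#' Full testing pipeline: median-of-ratios size factors, per-peak
#' dispersion with trend shrinkage, per-peak NB GLM, two-sided Wald test
#' on the non-intercept coefficient, and BH FDR with rejection-maximizing
#' independent filtering. Two designs are supported:
#'
#' * `model = "ptb"`: intercept + group indicator. The reported
#'   `log2FoldChange` is term relative to preterm, so a *positive* value
#'   means higher methylation at term, i.e. the region is
#'   hypo-methylated in preterm placentas (`direction = "hypo"`).
#' * `model = "ga"`: intercept + gestational age in weeks (uncentered);
#'   `log2FoldChange` is the per-week log2 slope, positive when
#'   methylation rises with gestational age.
#'
#' @param cm a `count_matrix` from [summed_counts()] (or a list with
#'   `peaks` and `counts`).
#' @param samples cohort data frame (`sample_id`, `group`,
#'   `gestational_age`) matching the matrix columns.
#' @param model `"ptb"` or `"ga"`.
#' @param alpha_fdr FDR level used by the independent filter.
#' @param independent_filtering set `FALSE` for plain BH on all peaks.
#' @param filter_quantiles quantile grid for the filter scan.
#' @return Results data frame sorted by `padj` (NA last): `location`,
#'   `chrom`, `start`, `end`, `width`, `baseMean`, `log2FoldChange`,
#'   `lfcSE`, `pvalue`, `padj`, `direction`; the chosen filter threshold
#'   is attached as attribute `filter`.
#' @export
run_model <- function(cm, samples, model = c("ptb", "ga"),
                      alpha_fdr = 0.05, independent_filtering = TRUE,
                      filter_quantiles = seq(0, 0.95, by = 0.01)) {
  model <- match.arg(model)
  counts <- cm$counts
  stopifnot(identical(colnames(counts), samples$sample_id))
  if (model == "ptb") {
    if (sum(samples$group == "preterm") < 2 ||
        sum(samples$group == "term") < 2)
      stop("ptb model needs at least 2 samples per group")
    X <- cbind(intercept = 1,
               term = as.numeric(samples$group == "term"))
  } else {
    X <- cbind(intercept = 1, ga = samples$gestational_age)
  }
  sf <- size_factors(counts)
  disp <- estimate_dispersion(counts, sf, X)
  off <- log(sf)
  n <- nrow(counts)
  beta <- se <- rep(NA_real_, n)
  conv <- rep(FALSE, n)
  for (i in seq_len(n)) {
    y <- counts[i, ]
    if (all(y == 0)) next
    f <- fit_nb_glm(y, X, offset = off, alpha = disp$final[i])
    beta[i] <- f$beta[2]
    se[i] <- f$se[2]
    conv[i] <- f$converged
  }
  pvalue <- wald_pvalues(beta, se)
  pvalue[!conv] <- NA_real_
  base_mean <- rowMeans(sweep(counts, 2, sf, `/`))
  if (independent_filtering) {
    fl <- independent_filter(base_mean, pvalue, alpha_fdr,
                             filter_quantiles)
  } else {
    fl <- list(padj = bh_adjust(pvalue), threshold = 0, quantile = 0,
               n_rejected = sum(bh_adjust(pvalue) < alpha_fdr,
                                na.rm = TRUE), grid = NULL)
  }
  res <- data.frame(location = cm$peaks$location %||%
                      format_location(cm$peaks),
                    chrom = cm$peaks$chrom, start = cm$peaks$start,
                    end = cm$peaks$end,
                    width = interval_width(cm$peaks),
                    baseMean = base_mean,
                    log2FoldChange = beta / log(2),
                    lfcSE = se / log(2),
                    pvalue = pvalue, padj = fl$padj,
                    stringsAsFactors = FALSE)
  res$direction <- ifelse(res$log2FoldChange > 0, "hypo", "hyper")
  res <- res[order(res$padj, res$pvalue), , drop = FALSE]
  rownames(res) <- NULL
  structure(res, filter = fl[c("threshold", "quantile", "n_rejected")],
            model = model, size_factors = sf)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Pooled-variance two-sample t-test
#'
#' Student's t-test (equal-variance) comparing cases and controls, as
#' used for the clinical-characteristics table.
#'
#' @param a,b numeric vectors (each of length >= 2).
#' @return List with `t` and two-sided `p`.
#' @export
ttest_groups <- function(a, b) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  if (stats::var(c(a, b)) == 0) return(list(t = 0, p = 1))
  ht <- stats::t.test(a, b, var.equal = TRUE)
  list(t = unname(ht$statistic), p = ht$p.value)
}
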