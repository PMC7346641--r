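# Heavy-tail model fitting for degree distributions.
#
# Degrees are counts, so the default likelihoods are discrete:
#   power law   P(k) = k^-alpha / zeta(alpha, xmin)          (Hurwitz zeta)
#   exponential P(k) = (1-q) q^(k-xmin),  q = exp(-lambda)   (geometric)
#   lognormal+  P(k) ~ dlnorm(k; mu, sigma) renormalized on k >= xmin, mu >= 0
#   weibull     P(k) ~ dweibull(k; shape, scale) renormalized on k >= xmin
# The continuous closed-form power-law MLE is retained as a cross-check mode.

# Hurwitz zeta, sum_{k>=0} (a+k)^-s for s > 1, via Euler-Maclaurin.
# Accurate to ~1e-13 for the s, a ranges arising from degree fits.
hurwitzZeta <- function(s, a) {
  N <- 25
  k <- 0:(N - 1)
  aN <- a + N
  sum((a + k)^(-s)) +
    aN^(1 - s) / (s - 1) +
    0.5 * aN^(-s) +
    s / 12 * aN^(-s - 1) -
    s * (s + 1) * (s + 2) / 720 * aN^(-s - 3)
}

#' Draws from a discrete power law
#'
#' Exact inverse-CDF sampling of `P(k) ~ k^-alpha` on `k >= xmin`, with the
#' support truncated at `cap` (the truncated mass is below 1e-8 for the
#' exponents used anywhere in this package).
#'
#' @param n number of draws.
#' @param alpha exponent (> 1).
#' @param xmin lower bound of the support (integer >= 1).
#' @param cap upper truncation of the support.
#' @return integer vector of draws.
#' @export
rPowerLaw <- function(n, alpha, xmin = 1, cap = 2e5) {
  k <- xmin:cap
  pmf <- k^(-alpha)
  cdf <- cumsum(pmf / sum(pmf))
  xmin + findInterval(runif(n), cdf)
}

# per-observation discrete power-law tail log-likelihood
plLoglikVec <- function(x, alpha, xmin) {
  -alpha * log(x) - log(hurwitzZeta(alpha, xmin))
}

fitAlphaDiscrete <- function(tail, xmin) {
  sl <- sum(log(tail))
  n <- length(tail)
  o <- optimize(function(a) -n * log(hurwitzZeta(a, xmin)) - a * sl,
                c(1.000001, 25), maximum = TRUE, tol = 1e-9)
  list(alpha = o$maximum, loglik = o$objective)
}

ksDistanceDiscrete <- function(alpha, tail, xmin) {
  tail <- sort(tail)
  u <- unique(tail)
  Z <- hurwitzZeta(alpha, xmin)
  Ffit <- 1 - vapply(u, function(k) hurwitzZeta(alpha, k + 1), 0) / Z
  Femp <- cumsum(tabulate(factor(tail, levels = u))) / length(tail)
  max(abs(Femp - Ffit))
}

ksDistanceContinuous <- function(alpha, tail, xmin) {
  tail <- sort(tail)
  u <- unique(tail)
  Ffit <- 1 - (u / xmin)^(1 - alpha)
  Femp <- cumsum(tabulate(factor(tail, levels = u))) / length(tail)
  max(abs(Femp - Ffit))
}

#' Fit a power law to a degree distribution
#'
#' Maximum-likelihood fit of the discrete power law `P(k) ~ k^-alpha` to the
#' degree tail `k >= xmin`.  When `xmin` is not given, all observed degree
#' values leaving at least `minTail` tail points are scanned and the one
#' minimizing the Kolmogorov–Smirnov distance between the empirical and
#' fitted tail CDFs is selected (Clauset-style).
#'
#' Networks with fewer than `minNodes` degrees are rejected — small networks
#' do not carry enough degree data for a stable fit — unless `force = TRUE`
#' (intended for tests and exploration).
#'
#' @param degrees integer node degrees, all >= 1.
#' @param xmin optional fixed lower cutoff; `NULL` (default) scans.
#' @param method `"discrete"` (default) or `"continuous"`, the closed-form
#'   continuous MLE `alpha = 1 + n / sum(log(x/xmin))` kept as an
#'   independent cross-check.
#' @param minNodes minimum number of degrees required (default 100).
#' @param minTail smallest tail size considered during the `xmin` scan.
#' @param force bypass the `minNodes` guard.
#' @return a [PowerLawFit-class].
#' @examples
#' fitPowerLaw(c(2, 4, 8), xmin = 2, method = "continuous", force = TRUE)
#' @export
fitPowerLaw <- function(degrees, xmin = NULL,
                        method = c("discrete", "continuous"),
                        minNodes = 100, minTail = 50, force = FALSE) {
  method <- match.arg(method)
  degrees <- as.numeric(degrees)
  if (any(degrees < 1))
    hgtStop("all degrees must be >= 1", "hgtnet_validation_error")
  if (length(degrees) < minNodes && !force)
    hgtStop(sprintf("need >= %d degrees to fit (got %d); use force = TRUE to override",
                    minNodes, length(degrees)), "hgtnet_insufficient_data")
  if (length(unique(degrees)) == 1L)
    hgtStop("degenerate degree distribution: all degrees identical",
            "hgtnet_degenerate_distribution")
  fitAt <- function(xm) {
    tail <- degrees[degrees >= xm]
    if (method == "discrete") {
      f <- fitAlphaDiscrete(tail, xm)
      ks <- ksDistanceDiscrete(f$alpha, tail, xm)
    } else {
      alpha <- 1 + length(tail) / sum(log(tail / xm))
      ll <- length(tail) * log((alpha - 1) / xm) - alpha * sum(log(tail / xm))
      f <- list(alpha = alpha, loglik = ll)
      ks <- ksDistanceContinuous(f$alpha, tail, xm)
    }
    list(alpha = f$alpha, loglik = f$loglik, ks = ks, nTail = length(tail))
  }
  if (!is.null(xmin)) {
    if (xmin < 1) hgtStop("xmin must be >= 1", "hgtnet_parameter_error")
    best <- fitAt(xmin)
    bestXmin <- xmin
  } else {
    cands <- sort(unique(degrees))
    keep <- vapply(cands, function(xm) sum(degrees >= xm) >= minTail, TRUE)
    cands <- if (any(keep)) cands[keep] else cands[1L]
    best <- NULL; bestXmin <- NA_real_
    for (xm in cands) {
      f <- fitAt(xm)
      if (is.null(best) || f$ks < best$ks) { best <- f; bestXmin <- xm }
    }
  }
  new("PowerLawFit", alpha = best$alpha, xmin = as.numeric(bestXmin),
      ksDistance = best$ks, nTail = as.integer(best$nTail),
      loglik = best$loglik, method = method)
}

# log pmf of a grid-renormalized discretized density on k in [xmin, cap]
gridLogNorm <- function(logf, xmin, cap) {
  k <- xmin:cap
  lf <- logf(k)
  m <- max(lf)
  m + log(sum(exp(lf - m)))
}

altGridCap <- function(tail) max(1e5, 10 * max(tail))

#' Fit an alternative heavy-tailed model to a degree tail
#'
#' Fits one of the comparison families on the same tail (`degrees >= xmin`)
#' used by a power-law fit.  For `"lognormal_positive"` the location is
#' constrained to `mu >= 0` (the median of a degree set is >= 1); when the
#' unconstrained optimum violates it, the model is refit at `mu = 0` and the
#' `constraintBound` slot is set rather than clipping silently.
#'
#' @param degrees integer degrees (the full set; the tail is taken here).
#' @param family `"exponential"`, `"lognormal_positive"` or `"weibull"`.
#' @param xmin tail cutoff, normally taken from [fitPowerLaw()].
#' @return an [AltFit-class].
#' @export
fitAlternative <- function(degrees,
                           family = c("exponential", "lognormal_positive",
                                      "weibull"),
                           xmin = 1) {
  family <- match.arg(family)
  tail <- as.numeric(degrees[degrees >= xmin])
  n <- length(tail)
  if (n < 2L)
    hgtStop("tail too small to fit", "hgtnet_insufficient_data")
  if (length(unique(tail)) == 1L)
    hgtStop(paste0(family, " fit failed: degenerate (constant) tail"),
            "hgtnet_fit_failure")
  if (family == "exponential") {
    # geometric on k - xmin: closed-form MLE
    mbar <- mean(tail - xmin)
    q <- mbar / (1 + mbar)
    lambda <- -log(q)
    ll <- n * log(1 - q) - lambda * sum(tail - xmin)
    return(new("AltFit", family = family, params = c(lambda = lambda),
               loglik = ll, nTail = as.integer(n), logNorm = NA_real_))
  }
  cap <- altGridCap(tail)
  guard <- function(v) if (is.finite(v)) v else 1e10
  if (family == "lognormal_positive") {
    logfFor <- function(p) function(k) dlnorm(k, p[1], p[2], log = TRUE)
    obj <- function(p) {
      lz <- gridLogNorm(logfFor(p), xmin, cap)
      guard(-(sum(dlnorm(tail, p[1], p[2], log = TRUE)) - n * lz))
    }
    init <- c(mean(log(tail)), max(sd(log(tail)), 0.1))
    un <- suppressWarnings(optim(init, obj, method = "L-BFGS-B",
                                 lower = c(-20, 1e-3), upper = c(20, 50)))
    bound <- un$par[1] < 0
    if (bound) {
      # mu >= 0 binds: refit sigma alone at mu = 0 (1-D, reported, not clipped)
      o <- suppressWarnings(optimize(function(s) obj(c(0, s)), c(1e-3, 50)))
      par <- c(0, o$minimum)
    } else {
      if (un$convergence != 0)
        hgtStop(paste0("lognormal_positive fit did not converge: ",
                       un$message), "hgtnet_fit_failure")
      par <- un$par
    }
    lz <- gridLogNorm(logfFor(par), xmin, cap)
    return(new("AltFit", family = family,
               params = c(mu = par[1], sigma = par[2]),
               loglik = -obj(par), nTail = as.integer(n), logNorm = lz,
               constraintBound = bound))
  }
  # weibull
  logfFor <- function(p) function(k) dweibull(k, p[1], p[2], log = TRUE)
  obj <- function(p) {
    lz <- gridLogNorm(logfFor(p), xmin, cap)
    guard(-(sum(dweibull(tail, p[1], p[2], log = TRUE)) - n * lz))
  }
  fit <- suppressWarnings(optim(c(1, mean(tail)), obj, method = "L-BFGS-B",
                                lower = c(1e-2, 1e-2), upper = c(50, 1e6)))
  if (fit$convergence != 0)
    hgtStop(paste0("weibull fit did not converge: ", fit$message),
            "hgtnet_fit_failure")
  lz <- gridLogNorm(logfFor(fit$par), xmin, cap)
  new("AltFit", family = family,
      params = c(shape = fit$par[1], scale = fit$par[2]),
      loglik = -obj(fit$par), nTail = as.integer(n), logNorm = lz)
}

# per-observation log-likelihood of an AltFit evaluated at tail points
altLoglikVec <- function(fit, x, xmin) {
  p <- fit@params
  switch(fit@family,
    exponential = {
      q <- exp(-p[["lambda"]])
      log(1 - q) - p[["lambda"]] * (x - xmin)
    },
    lognormal_positive = dlnorm(x, p[["mu"]], p[["sigma"]], log = TRUE) - fit@logNorm,
    weibull = dweibull(x, p[["shape"]], p[["scale"]], log = TRUE) - fit@logNorm,
    stop("unknown family"))
}

# Vuong-normalized LLR from per-observation log-likelihood vectors;
# antisymmetric in its two arguments.
vuongRatio <- function(llA, llB) {
  d <- llA - llB
  n <- length(d)
  s <- sd(d)
  if (is.na(s) || s == 0) {
    list(ratio = 0, raw = sum(d), p = 1)
  } else {
    r <- sum(d) / (s * sqrt(n))
    list(ratio = r, raw = sum(d), p = 2 * pnorm(-abs(r)))
  }
}

#' Compare the power-law fit against an alternative family
#'
#' Both models are fitted to, and evaluated on, the identical degree tail
#' (`degrees >= xmin` from the power-law fit).  The log-likelihood ratio is
#' normalized per the Vuong construction; a positive ratio means the power
#' law fits better.  Tails smaller than `minTail` are reported as
#' `"undecided"` — the sign of the ratio is noise there.
#'
#' @param degrees integer node degrees.
#' @param family alternative family (see [fitAlternative()]); the degenerate
#'   value `"power_law"` compares the model with itself (ratio 0).
#' @param plFit optional pre-computed [PowerLawFit-class]; fitted here
#'   otherwise (with `force = TRUE`, so callers own the size filter).
#' @param minTail minimum tail size for a decided verdict (default 50).
#' @return an [LLRResult-class].
#' @export
compareFits <- function(degrees,
                        family = c("exponential", "lognormal_positive",
                                   "weibull", "power_law"),
                        plFit = NULL, minTail = 50) {
  family <- match.arg(family)
  if (is.null(plFit)) plFit <- fitPowerLaw(degrees, force = TRUE)
  xmin <- plFit@xmin
  tail <- as.numeric(degrees[degrees >= xmin])
  llPL <- plLoglikVec(tail, plFit@alpha, xmin)
  llAlt <- if (family == "power_law") llPL
           else altLoglikVec(fitAlternative(degrees, family, xmin), tail, xmin)
  v <- vuongRatio(llPL, llAlt)
  winner <- if (length(tail) < minTail || v$ratio == 0) "undecided"
            else if (v$ratio > 0) "power_law" else "alternative"
  new("LLRResult", ratio = v$ratio, rawRatio = v$raw, pValue = v$p,
      winner = winner, family = family, nTail = length(tail))
}

#' Summarize fitted exponents per group with pairwise t-tests
#'
#' @param alphas named list mapping group label to a numeric vector of fitted
#'   exponents (one per network); every group needs >= 2 values.
#' @return data.frame with columns `group`, `n`, `meanAlpha`, `ciLow`,
#'   `ciHigh` (t-based 95% CI of the mean), with a `"pairwise"` attribute
#'   holding all two-sided pooled-variance Student's t-tests between groups.
#' @export
summarizeGroupFits <- function(alphas) {
  if (is.null(names(alphas)) || any(names(alphas) == ""))
    hgtStop("alphas must be a named list of groups", "hgtnet_parameter_error")
  small <- names(alphas)[lengths(alphas) < 2L]
  if (length(small))
    hgtStop(paste0("groups with fewer than 2 fits: ",
                   paste(small, collapse = ", ")), "hgtnet_insufficient_data")
  summ <- do.call(rbind, lapply(names(alphas), function(g) {
    x <- alphas[[g]]
    n <- length(x)
    se <- sd(x) / sqrt(n)
    hw <- qt(0.975, n - 1) * se
    data.frame(group = g, n = n, meanAlpha = mean(x),
               ciLow = mean(x) - hw, ciHigh = mean(x) + hw)
  }))
  pairs <- combn(names(alphas), 2L)
  pw <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(i) {
    a <- alphas[[pairs[1, i]]]; b <- alphas[[pairs[2, i]]]
    tt <- t.test(a, b, var.equal = TRUE)
    data.frame(groupA = pairs[1, i], groupB = pairs[2, i],
               t = unname(tt$statistic), pValue = tt$p.value)
  }))
  attr(summ, "pairwise") <- pw
  summ
}

#' Diameter versus ln(ln(N)) trend across networks
#'
#' In the ultra-small-world regime (degree exponent between 2 and 3) the
#' network diameter grows like `ln(ln(N))`.  Fits a least-squares line of
#' the diameter (of the largest connected component) against `ln(ln(N))`
#' over the supplied networks; only networks with `N >= 3` (so that
#' `ln(ln(N))` is defined) contribute.
#'
#' @param networks list of [HGTNetwork-class] objects.
#' @return list with `points` (data.frame `N`, `d`, `lnlnN`), `slope`,
#'   `intercept` and the Pearson correlation `r`.
#' @export
diameterLnlnTrend <- function(networks) {
  pts <- do.call(rbind, lapply(networks, function(net) {
    g <- networkGraph(net)
    N <- igraph::vcount(g)
    if (N < 3) return(NULL)
    comp <- igraph::components(g)
    keep <- which(comp$membership == which.max(comp$csize))
    sub <- igraph::induced_subgraph(g, keep)
    d <- igraph::diameter(sub, weights = NA)
    data.frame(N = N, d = d, lnlnN = log(log(N)))
  }))
  if (is.null(pts) || nrow(pts) < 3L)
    hgtStop("need >= 3 networks with N >= 3", "hgtnet_insufficient_data")
  if (length(unique(pts$N)) == 1L)
    hgtStop("all networks have the same size: regression degenerate",
            "hgtnet_degenerate_regression")
  fit <- lm(d ~ lnlnN, data = pts)
  list(points = pts, slope = unname(coef(fit)[2]),
       intercept = unname(coef(fit)[1]),
       r = cor(pts$d, pts$lnlnN))
}
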