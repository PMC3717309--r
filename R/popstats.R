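#' Per-sample feature summary (mean and standard deviation)
#'
#' Arithmetic mean and sample standard deviation (n-1 denominator) of each
#' feature over the cells of one sample, plus the cell count; the layout of
#' the per-population summary tables.
#'
#' @param cells data.frame of per-nucleus features (one row per cell).
#' @param features columns to summarise.
#' @return data.frame with \code{feature, mean, sd} and attribute
#'   \code{"nCells"} ("total cells analyzed").
#' @export
summarizeSample <- function(cells,
                            features = c("volume_px", "mean_dapi",
                                         "mean_mec", "lid_pct", "lim_pct",
                                         "cond", "meth", "assoc")) {
  if (nrow(cells) < 2L) stop("need at least 2 cells to summarise")
  features <- intersect(features, names(cells))
  out <- data.frame(
    feature = features,
    mean = vapply(features, function(f) mean(cells[[f]]), numeric(1)),
    sd = vapply(features, function(f) stats::sd(cells[[f]]), numeric(1))
  )
  rownames(out) <- NULL
  attr(out, "nCells") <- nrow(cells)
  out
}

#' Growth rate from doubling time
#'
#' \eqn{g = 1 / t_{doubling}}; senescent samples with infinite doubling
#' time map to growth rate 0 (growth arrest is the natural zero of an
#' inverse-doubling-time axis).
#'
#' @param doublingTimeDays positive doubling times in days; \code{Inf}
#'   allowed.
#' @return growth rates in 1/days.
#' @export
growthRate <- function(doublingTimeDays) {
  stopifnot(all(doublingTimeDays > 0))
  ifelse(is.infinite(doublingTimeDays), 0, 1 / doublingTimeDays)
}

#' Pearson correlation of a feature against growth rate
#'
#' Correlates sample-level feature means against the inverse of doubling
#' time (one point per immunofluorescence sample -- doubling time is a
#' sample-level quantity). Pairs with an undefined feature value are
#' dropped with a message.
#'
#' @param samples data.frame with a \code{doubling_time_days} column and
#'   one column per feature (sample means).
#' @param feature feature column name.
#' @param weights optional per-sample weights (e.g. cell counts);
#'   unweighted by default.
#' @return list with \code{r}, \code{r2} and \code{n}.
#' @export
pearsonVsGrowth <- function(samples, feature, weights = NULL) {
  x <- growthRate(samples$doubling_time_days)
  y <- samples[[feature]]
  ok <- is.finite(x) & is.finite(y)
  if (any(!ok))
    message(sum(!ok), " sample(s) dropped (undefined feature or rate)")
  x <- x[ok]
  y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 samples")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in growth rate or feature")
  r <- if (is.null(weights)) {
    stats::cor(x, y)
  } else {
    w <- weights[ok] / sum(weights[ok])
    mx <- sum(w * x); my <- sum(w * y)
    sum(w * (x - mx) * (y - my)) /
      sqrt(sum(w * (x - mx)^2) * sum(w * (y - my)^2))
  }
  list(r = r, r2 = r^2, n = length(x))
}

.fitResult <- function(model, params, fitted, y, npar, extra = list()) {
  rss <- sum((y - fitted)^2)
  tss <- sum((y - mean(y))^2)
  out <- c(list(model = model, params = params, rss = rss,
                dof = length(y) - npar, npar = npar,
                r2 = if (tss > 0) 1 - rss / tss else NA_real_,
                fitted = fitted, n = length(y)), extra)
  class(out) <- "FitResult"
  out
}

#' @export
print.FitResult <- function(x, ...) {
  cat(sprintf("FitResult [%s]: r2 = %.4f, rss = %.4g, dof = %d\n",
              x$model, x$r2, x$rss, x$dof))
  print(unlist(x$params))
  invisible(x)
}

#' Fit a four-parameter logistic curve
#'
#' Least-squares fit of \eqn{y = b + L / (1 + e^{-k (x - x_0)})} by
#' Levenberg-Marquardt with multi-start initialisation (sign and magnitude
#' grid on \eqn{k}, quantile grid on \eqn{x_0}); the best-RSS start wins.
#' A near-constant response is flagged degenerate (\eqn{k}
#' unidentifiable) instead of fitted.
#'
#' @param x predictor (e.g. growth rates).
#' @param y bounded response (e.g. sample-mean \code{meth}).
#' @return a \code{FitResult} (params \code{L, k, x0, b}); degenerate fits
#'   carry \code{degenerate = TRUE}.
#' @export
fitLogistic <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 5L)
  if (stats::sd(y) < 1e-12 * (abs(mean(y)) + 1))
    return(.fitResult("logistic", list(L = 0, k = NA_real_,
                                       x0 = NA_real_, b = mean(y)),
                      rep(mean(y), length(y)), y, 4L,
                      list(degenerate = TRUE)))
  span <- diff(range(y))
  kmag <- 4 / max(diff(range(x)), 1e-12)  # slope scale from the x-range
  starts <- expand.grid(
    L = c(span, -span),
    k = kmag * c(0.5, 1, 3, 10),
    x0 = stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
  )
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    st <- list(L = starts$L[i], k = starts$k[i], x0 = starts$x0[i],
               b = min(y))
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ b + L / (1 + exp(-k * (x - x0))),
                        start = st,
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss - 1e-12)
      best <- list(fit = fit, rss = rss)
  }
  if (is.null(best))
    stop("logistic fit failed to converge from every start (n = ",
         length(x), ", y-range = ", signif(span, 3), ")")
  cf <- as.list(stats::coef(best$fit))
  # canonical form L > 0: (L, k, x0, b) and (-L, -k, x0, b + L) describe
  # the same curve
  if (cf$L < 0) {
    cf$b <- cf$b + cf$L
    cf$L <- -cf$L
    cf$k <- -cf$k
  }
  .fitResult("logistic", cf[c("L", "k", "x0", "b")],
             stats::fitted(best$fit), y, 4L)
}

.fitCandidate <- function(model, x, y) {
  switch(model,
    linear = {
      f <- stats::lm(y ~ x)
      .fitResult("linear", as.list(stats::coef(f)), stats::fitted(f), y, 2L)
    },
    logarithmic = {
      if (any(x <= 0)) return(NULL)  # undefined at zero growth rate
      f <- stats::lm(y ~ log(x))
      .fitResult("logarithmic", as.list(stats::coef(f)), stats::fitted(f),
                 y, 2L)
    },
    polynomial2 = {
      f <- stats::lm(y ~ x + I(x^2))
      .fitResult("polynomial2", as.list(stats::coef(f)), stats::fitted(f),
                 y, 3L)
    },
    exponential = {
      st <- list(a = diff(range(y)), b = 1 / max(diff(range(x)), 1e-12),
                 c = min(y))
      f <- tryCatch(
        minpack.lm::nlsLM(y ~ a * exp(b * x) + c, start = st,
                          control = minpack.lm::nls.lm.control(maxiter = 200)),
        error = function(e) NULL)
      if (is.null(f)) return(NULL)
      .fitResult("exponential", as.list(stats::coef(f)), stats::fitted(f),
                 y, 3L)
    },
    logistic = tryCatch(fitLogistic(x, y), error = function(e) NULL)
  )
}

.aicc <- function(fit) {
  n <- fit$n
  k <- fit$npar + 1  # + residual variance
  aic <- n * log(fit$rss / n) + 2 * k
  if (n - k - 1 > 0) aic + 2 * k * (k + 1) / (n - k - 1) else Inf
}

# extra-sum-of-squares F-test of a simpler fit against a richer one
.ssF <- function(simple, rich) {
  df1 <- rich$npar - simple$npar
  df2 <- rich$n - rich$npar
  if (df1 <= 0 || df2 <= 0 || rich$rss <= 0) return(NA_real_)
  Fv <- ((simple$rss - rich$rss) / df1) / (rich$rss / df2)
  stats::pf(max(Fv, 0), df1, df2, lower.tail = FALSE)
}

#' Fit candidate growth-response models and select the best
#'
#' Fits linear, logarithmic, quadratic polynomial, exponential and
#' logistic candidates, then selects a winner: the small-sample-corrected
#' information criterion (AICc) ranks all fits, and an
#' extra-sum-of-squares F-test guards parsimony -- a simpler model
#' replaces a more complex AICc winner whenever the F-test does not reject
#' it at \code{alpha} (the F-test requires comparable nesting only for its
#' exact null; here it is the standard curve-fitting comparison on
#' residual sums of squares).
#'
#' @param x,y data (>= 5 points).
#' @param candidates model names to try.
#' @param alpha F-test level.
#' @return the winning \code{FitResult}, with attribute
#'   \code{"comparison"}: a data.frame of all fits (model, npar, rss, r2,
#'   AICc, F-test p vs the AICc winner).
#' @export
selectModel <- function(x, y,
                        candidates = c("linear", "logarithmic",
                                       "polynomial2", "exponential",
                                       "logistic"),
                        alpha = 0.05) {
  stopifnot(length(x) == length(y), length(x) >= 5L)
  fits <- list()
  for (m in candidates) {
    f <- .fitCandidate(m, x, y)
    if (!is.null(f) && is.null(f$degenerate)) fits[[m]] <- f
  }
  if (length(fits) == 0L) stop("all candidate fits failed")
  aicc <- vapply(fits, .aicc, numeric(1))
  bestName <- names(fits)[which.min(aicc)]
  best <- fits[[bestName]]
  # parsimony guard: keep the simplest model not rejected against the winner
  simpler <- fits[vapply(fits, function(f) f$npar < best$npar, TRUE)]
  if (length(simpler)) {
    ord <- order(vapply(simpler, function(f) f$npar, 1L))
    for (f in simpler[ord]) {
      p <- .ssF(f, best)
      if (!is.na(p) && p >= alpha) {
        best <- f
        break
      }
    }
  }
  comparison <- data.frame(
    model = names(fits),
    npar = vapply(fits, function(f) f$npar, 1L),
    rss = vapply(fits, function(f) f$rss, 1),
    r2 = vapply(fits, function(f) f$r2, 1),
    aicc = aicc,
    p_vs_best = vapply(fits, function(f)
      if (f$npar < fits[[bestName]]$npar) .ssF(f, fits[[bestName]])
      else NA_real_, 1)
  )
  rownames(comparison) <- NULL
  attr(best, "comparison") <- comparison
  best
}

#' Welch two-sample t-test between cell classes
#'
#' Unequal-variance (Welch) two-sided t-test; the population tables are
#' plainly heteroscedastic, so the pooled-variance variant is not assumed.
#'
#' @param groupA,groupB numeric vectors (>= 2 values each).
#' @return list with \code{t}, \code{p} and \code{df}.
#' @export
twoSampleTTest <- function(groupA, groupB) {
  stopifnot(length(groupA) >= 2L, length(groupB) >= 2L)
  if (stats::sd(groupA) == 0 && stats::sd(groupB) == 0 &&
      mean(groupA) == mean(groupB))
    return(list(t = 0, p = 1, df = length(groupA) + length(groupB) - 2))
  tt <- stats::t.test(groupA, groupB, var.equal = FALSE)
  list(t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter))
}
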