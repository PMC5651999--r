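#' Within-classroom standardized scores and composite dimensions
#'
#' Computes, per classroom, z-scores of the received counts (`z_pnr`,
#' `z_nnr`), the composite dimensions social preference
#' (`sp = z_pnr - z_nnr`) and social impact (`si = z_pnr + z_nnr`), and
#' their re-standardized forms `z_sp`, `z_si`.  All standardization uses the
#' population SD.  These are the inputs of the standard-score classifier.
#'
#' @param scores a `classroom_scores` object.
#' @return An object of class `standardized_scores` (a data.frame): the
#'   score columns plus `z_pnr`, `z_nnr`, `sp`, `si`, `z_sp`, `z_si`.  The
#'   per-classroom SDs of `sp` and `si` are appended to the `"stats"`
#'   attribute as `sd_sp`, `sd_si`.
#' @export
standardize_scores <- function(scores) {
  stopifnot(inherits(scores, "classroom_scores"))
  stats <- classroom_stats(scores)
  out <- as.data.frame(scores)
  out$z_pnr <- out$z_nnr <- out$sp <- out$si <- out$z_sp <- out$z_si <- NA_real_
  stats$sd_sp <- stats$sd_si <- NA_real_
  for (i in seq_len(nrow(stats))) {
    cl <- stats$classroom[i]
    idx <- which(out$classroom == cl)
    if (stats$sd_pnr[i] == 0 || stats$sd_nnr[i] == 0)
      stop("classroom '", cl, "': zero variance in ",
           if (stats$sd_pnr[i] == 0) "PNR" else "NNR",
           "; the standard-score method is inapplicable")
    zp <- (out$pnr[idx] - stats$m_pnr[i]) / stats$sd_pnr[i]
    zn <- (out$nnr[idx] - stats$m_nnr[i]) / stats$sd_nnr[i]
    sp <- zp - zn
    si <- zp + zn
    sd_sp <- sd_pop(sp); sd_si <- sd_pop(si)
    if (sd_sp == 0 || sd_si == 0)
      stop("classroom '", cl, "': zero variance in ",
           if (sd_sp == 0) "social preference" else "social impact")
    out$z_pnr[idx] <- zp; out$z_nnr[idx] <- zn
    out$sp[idx] <- sp;    out$si[idx] <- si
    # SP and SI have mean 0 within classroom by construction
    out$z_sp[idx] <- sp / sd_sp
    out$z_si[idx] <- si / sd_si
    stats$sd_sp[i] <- sd_sp; stats$sd_si[i] <- sd_si
  }
  structure(out, stats = stats,
            class = c("standardized_scores", "classroom_scores", "data.frame"))
}

#' Distribution diagnostics of a nomination-count dimension
#'
#' For one valence of one classroom, returns the quantities that govern how
#' much a single nomination moves a z-score: the variation coefficient
#' `vc = SD/M`, the z-score at a raw count of zero `z0 = -M/SD = -1/vc`, and
#' the step between consecutive counts' z-scores `step = 1/SD`.  Count
#' distributions with smaller `vc` (hence larger `|z0|`) and larger `M` let
#' each nomination contribute more towards a z-score cutoff.
#'
#' @param scores a `classroom_scores` object.
#' @param valence `"positive"` or `"negative"`.
#' @return data.frame, one row per classroom: `m`, `sd`, `vc`, `z0`, `step`.
#' @export
score_diagnostics <- function(scores, valence = c("positive", "negative")) {
  valence <- match.arg(valence)
  stats <- classroom_stats(scores)
  m <- if (valence == "positive") stats$m_pnr else stats$m_nnr
  s <- if (valence == "positive") stats$sd_pnr else stats$sd_nnr
  if (any(m <= 0))
    stop("classroom '", stats$classroom[which(m <= 0)[1]],
         "': mean of zero, variation coefficient undefined")
  if (any(s <= 0))
    stop("classroom '", stats$classroom[which(s <= 0)[1]],
         "': zero variance, diagnostics undefined")
  data.frame(classroom = stats$classroom, valence = valence,
             m = m, sd = s, vc = s / m, z0 = -m / s, step = 1 / s,
             stringsAsFactors = FALSE)
}

#' Z-score of a raw nomination count given classroom moments
#'
#' For published or hypothetical classrooms where only the mean and SD of a
#' nomination-count distribution are known, converts a raw count to its
#' within-classroom z-score.
#'
#' @param count raw nomination count(s).
#' @param m classroom mean of the dimension.
#' @param sd classroom (population) SD of the dimension.
#' @return numeric z-score(s).
#' @export
count_to_z <- function(count, m, sd) {
  if (sd <= 0) stop("sd must be positive")
  (count - m) / sd
}

#' Distribution diagnostics from printed classroom moments
#'
#' Same quantities as [score_diagnostics()] but computed directly from a
#' mean and either an SD or a variation coefficient, for classrooms known
#' only through their published summary statistics.
#'
#' @param m mean of the nomination-count distribution (must be positive).
#' @param sd population SD of the distribution; derived from `vc` when
#'   missing.
#' @param vc variation coefficient `sd/m`; derived from `sd` when missing.
#' @return list with `m`, `sd`, `vc`, `z0` (z-score at a count of zero,
#'   `-1/vc`) and `step` (z distance between consecutive counts, `1/sd`).
#' @export
moment_diagnostics <- function(m, sd = NULL, vc = NULL) {
  if (m <= 0) stop("mean must be positive; variation coefficient undefined")
  if (is.null(sd)) {
    if (is.null(vc)) stop("supply sd or vc")
    sd <- vc * m
  }
  if (sd <= 0) stop("sd must be positive")
  list(m = m, sd = sd, vc = sd / m, z0 = -m / sd, step = 1 / sd)
}

#' Binomial critical values for received-nomination counts
#'
#' Models the count a child receives as `X ~ Binomial(n_voters, p)` with
#' `p = mean_given / pool`, and finds the scores "rare" at level `alpha`:
#' the upper limit `UL = min{k : P(X >= k) < alpha}` and the lower limit
#' `LL = max{k : P(X <= k) < alpha}` (`NA` when even a count of zero is not
#' rare, or no achievable count is rare on the upper tail).  Because counts
#' are integers the realized tail probabilities are more restrictive than
#' `alpha` itself; they are returned alongside the limits.
#'
#' The default computation is the exact binomial tail sum.  A continuous
#' skewness-corrected normal (Pearson type III / Cornish-Fisher)
#' approximation is available with `method = "salvosa"`; it agrees with the
#' exact limits to within one nomination over the practical range of
#' classroom sizes and is provided for comparison only.
#'
#' @param n_voters number of Bernoulli trials (voters able to nominate the
#'   child, i.e. excluding the child itself).
#' @param mean_given mean nominations given per voter (expansiveness).
#' @param pool number of eligible nominees per voter (group size minus one).
#' @param alpha significance level, default 0.05.
#' @param method `"exact"` (default) or `"salvosa"`.
#' @return An object of class `probability_limits`: list with `ul`, `ll`,
#'   `alpha`, `n_trials`, `p`, `method`, and realized tail probabilities
#'   `p_upper`, `p_lower`.
#' @export
binomial_limits <- function(n_voters, mean_given, pool, alpha = 0.05,
                            method = c("exact", "salvosa")) {
  method <- match.arg(method)
  if (n_voters < 1) stop("n_voters must be at least 1")
  if (mean_given <= 0) stop("mean_given must be positive")
  if (!(alpha > 0 && alpha < 1)) stop("alpha must be in (0, 1)")
  p <- mean_given / pool
  if (p > 1) stop("per-trial probability exceeds 1 (mean_given > pool)")
  n <- as.integer(n_voters)

  if (method == "exact") {
    k <- 0:n
    upper <- rev(cumsum(rev(stats::dbinom(k, n, p))))  # P(X >= k)
    lower <- stats::pbinom(k, n, p)                    # P(X <= k)
    ul <- if (any(upper < alpha)) min(k[upper < alpha]) else NA_integer_
    ll <- if (any(lower < alpha)) max(k[lower < alpha]) else NA_integer_
  } else {
    mu <- n * p
    sigma <- sqrt(n * p * (1 - p))
    skew <- (1 - 2 * p) / sigma
    dev <- function(z) z + skew * (z^2 - 1) / 6
    ul <- as.integer(floor(mu + 0.5 + sigma * dev(stats::qnorm(1 - alpha))) + 1)
    if (ul > n) ul <- NA_integer_
    ll <- as.integer(ceiling(mu - 0.5 + sigma * dev(stats::qnorm(alpha))) - 1)
    if (is.na(ll) || ll < 0) ll <- NA_integer_
  }
  structure(list(
    ul = ul, ll = ll, alpha = alpha, n_trials = n, p = p, method = method,
    p_upper = if (!is.na(ul)) stats::pbinom(ul - 1, n, p, lower.tail = FALSE)
              else NA_real_,
    p_lower = if (!is.na(ll)) stats::pbinom(ll, n, p) else NA_real_),
    class = "probability_limits")
}

#' @export
print.probability_limits <- function(x, ...) {
  cat(sprintf(
    "probability_limits (%s): X ~ Binomial(%d, %.4f), alpha = %g\n",
    x$method, x$n_trials, x$p, x$alpha))
  cat(sprintf("  UL = %s (realized upper tail %s)\n",
              ifelse(is.na(x$ul), "none", x$ul),
              ifelse(is.na(x$ul), "-", format(x$p_upper, digits = 3))))
  cat(sprintf("  LL = %s (realized lower tail %s)\n",
              ifelse(is.na(x$ll), "none", x$ll),
              ifelse(is.na(x$ll), "-", format(x$p_lower, digits = 3))))
  invisible(x)
}

#' Per-classroom probability limits for both valences
#'
#' Applies [binomial_limits()] to each classroom of a score table, once per
#' valence.  The trial count uses only children who actually submitted
#' nominations of that valence (so the limits adjust for non-voters), minus
#' one because a child cannot be nominated by itself; `mean_given` is the
#' realized expansiveness of those voters; the nominee pool is `G - 1`.
#'
#' @param scores a `classroom_scores` object.
#' @param alpha significance level.
#' @param method `"exact"` or `"salvosa"` (see [binomial_limits()]).
#' @return data.frame, one row per classroom: `ul_pnr`, `ll_pnr`, `ul_nnr`,
#'   `ll_nnr`, trial counts and per-trial probabilities, and `alpha`.
#' @export
classroom_limits <- function(scores, alpha = 0.05,
                             method = c("exact", "salvosa")) {
  method <- match.arg(method)
  stats <- classroom_stats(scores)
  out <- lapply(seq_len(nrow(stats)), function(i) {
    st <- stats[i, ]
    lim_of <- function(v_val, expans) {
      n <- max(1L, as.integer(v_val) - 1L)
      binomial_limits(n, expans, pool = st$G - 1, alpha = alpha,
                      method = method)
    }
    lp <- lim_of(st$V_pos, st$expansiveness_pos)
    ln <- lim_of(st$V_neg, st$expansiveness_neg)
    data.frame(classroom = st$classroom,
               ul_pnr = lp$ul, ll_pnr = lp$ll,
               ul_nnr = ln$ul, ll_nnr = ln$ll,
               n_pos = lp$n_trials, p_pos = lp$p,
               n_neg = ln$n_trials, p_neg = ln$p,
               alpha = alpha, method = method, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Curvilinear association between social preference and social impact
#'
#' The standard-score classifier treats social preference (SP) and social
#' impact (SI) as independent dimensions.  This fits, in both directions, a
#' cubic polynomial regression of one dimension on the other
#' (`y ~ x + x^2 + x^3`) and reports the fit statistics, quantifying how far
#' the independence assumption holds in a data set.
#'
#' @param sp,si numeric vectors of the two composite dimensions.
#' @return list with elements `si_on_sp` and `sp_on_si`, each containing
#'   `r_squared`, the overall `F` statistic with its df and p-value, and the
#'   per-term coefficient table.
#' @export
curvilinear_association <- function(sp, si) {
  stopifnot(length(sp) == length(si))
  ok <- stats::complete.cases(sp, si)
  sp <- sp[ok]; si <- si[ok]
  if (length(sp) < 10) stop("need at least 10 observations")
  if (sd_pop(sp) == 0 || sd_pop(si) == 0) stop("constant dimension")
  fit_dir <- function(y, x) {
    fit <- stats::lm(y ~ x + I(x^2) + I(x^3))
    sm <- summary(fit)
    fstat <- sm$fstatistic
    list(r_squared = unname(sm$r.squared),
         f = unname(fstat["value"]),
         df = unname(fstat[c("numdf", "dendf")]),
         p = unname(stats::pf(fstat["value"], fstat["numdf"], fstat["dendf"],
                              lower.tail = FALSE)),
         coefficients = stats::coef(sm))
  }
  list(si_on_sp = fit_dir(si, sp), sp_on_si = fit_dir(sp, si))
}
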