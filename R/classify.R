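.STATUSES <- c("preferred", "rejected", "neglected", "controversial", "average")

.assignment <- function(scores, method, status, rationale) {
  structure(data.frame(classroom = scores$classroom, child = scores$child,
                       pnr = scores$pnr, nnr = scores$nnr,
                       method = method, status = status,
                       rationale = rationale, stringsAsFactors = FALSE),
            class = c("status_assignment", "data.frame"))
}

# Probability-method predicates on a raw (pnr, nnr) pair.  The specific
# criterion is a critical value on one dimension; the supplementary one is
# the side of the other dimension's mean, which makes the four non-average
# predicates pairwise exclusive.
.prob_predicates <- function(pnr, nnr, ul_pnr, ul_nnr, m_pnr, m_nnr,
                             neglected_rule) {
  list(
    preferred     = pnr >= ul_pnr & nnr < m_nnr,
    rejected      = nnr >= ul_nnr & pnr < m_pnr,
    controversial = (pnr >= ul_pnr & nnr >= m_nnr) |
                    (nnr >= ul_nnr & pnr >= m_pnr),
    neglected     = neglected_rule(pnr, nnr))
}

.label_in_order <- function(preds, n) {
  status <- rep("average", n)
  fired <- rep(FALSE, n)
  for (st in c("preferred", "rejected", "controversial", "neglected")) {
    hit <- preds[[st]] & !fired
    status[hit] <- st
    fired <- fired | preds[[st]]
  }
  status
}

#' Standard-score (z-score) sociometric classification
#'
#' Five-way classification from within-classroom standardized scores.  The
#' modified variant (the default) assigns every child: preferred when
#' `z_sp > 1`, `z_pnr > 0`, `z_nnr < 0`; rejected when `z_sp < -1`,
#' `z_pnr < 0`, `z_nnr > 0`; controversial when `z_si > 1` and both z-scores
#' positive; neglected when `z_si < -1` and both z-scores negative; all
#' remaining children are average.  The original variant instead requires
#' `pnr = 0` for neglected, restricts average to `|z_sp|` and `|z_si|`
#' below 0.5, and leaves the remainder `unclassified`.
#'
#' @param std a `standardized_scores` object from [standardize_scores()].
#' @param variant `"modified"` (default) or `"original"`.
#' @return A `status_assignment` data.frame with columns `classroom`,
#'   `child`, `pnr`, `nnr`, `method`, `status`, `rationale`.
#' @export
classify_cd <- function(std, variant = c("modified", "original")) {
  variant <- match.arg(variant)
  stopifnot(inherits(std, "standardized_scores"))
  n <- nrow(std)
  preds <- list(
    preferred     = std$z_sp > 1  & std$z_pnr > 0 & std$z_nnr < 0,
    rejected      = std$z_sp < -1 & std$z_pnr < 0 & std$z_nnr > 0,
    controversial = std$z_si > 1  & std$z_pnr > 0 & std$z_nnr > 0,
    neglected     = if (variant == "modified")
                      std$z_si < -1 & std$z_pnr < 0 & std$z_nnr < 0
                    else
                      std$z_si < -1 & std$pnr == 0)
  status <- .label_in_order(preds, n)
  if (variant == "original") {
    rest <- status == "average"
    avg <- rest & abs(std$z_sp) < 0.5 & abs(std$z_si) < 0.5
    status[rest & !avg] <- "unclassified"
  }
  rationale <- sprintf("z_sp=%.2f z_si=%.2f z_pnr=%.2f z_nnr=%.2f -> %s",
                       std$z_sp, std$z_si, std$z_pnr, std$z_nnr, status)
  .assignment(std, if (variant == "modified") "CD" else "CD_original",
              status, rationale)
}

#' Fixed-cutoff binomial probability classification
#'
#' Five-way classification with the absolute critical value of 7
#' nominations on either dimension, valid for groups of 13-50 children with
#' nominations limited to 3 at a significance level of 0.05: preferred when
#' `pnr >= 7` and `nnr` below the classroom mean; rejected when `nnr >= 7`
#' and `pnr` below its mean; controversial when a dimension reaches 7 and
#' the other is at or above its mean; neglected when the raw impact
#' `pnr + nnr <= 2`; otherwise average.
#'
#' @param scores a `classroom_scores` object.
#' @param cutoff the fixed critical value (7 for limit-3 nominations).
#' @return A `status_assignment` data.frame.
#' @export
classify_nb <- function(scores, cutoff = 7) {
  stopifnot(inherits(scores, "classroom_scores"))
  stats <- classroom_stats(scores)
  if (any(stats$G < 13 | stats$G > 50))
    warning("group size outside the 13-50 window validated for the fixed ",
            "cutoff: ", paste(stats$classroom[stats$G < 13 | stats$G > 50],
                              collapse = ", "))
  if (any(stats$nomination_limit != 3))
    warning("fixed cutoff of 7 is validated for a nomination limit of 3")
  i <- match(scores$classroom, stats$classroom)
  preds <- .prob_predicates(scores$pnr, scores$nnr, cutoff, cutoff,
                            stats$m_pnr[i], stats$m_nnr[i],
                            function(p, n) p + n <= 2)
  status <- .label_in_order(preds, nrow(scores))
  rationale <- sprintf("pair %d-%d vs cutoff %d; M=%.2f/%.2f -> %s",
                       scores$pnr, scores$nnr, cutoff,
                       stats$m_pnr[i], stats$m_nnr[i], status)
  .assignment(scores, "NB", status, rationale)
}

#' Adjusted-probability sociometric classification
#'
#' Five-way classification with per-classroom binomial critical values:
#' preferred when `pnr` reaches the classroom's upper limit for positive
#' nominations and `nnr` is below the mean of negative nominations;
#' rejected symmetrically; controversial when a dimension reaches its upper
#' limit and the other is at or above its mean; neglected when `pnr <= 1`
#' (for limit-3 data; with 5 or unlimited nominations the bound is the
#' larger of the lower limit and 1) and `nnr` below its mean; otherwise
#' average.  The upper limits adjust to each classroom's voter count and
#' expansiveness, so the same raw pair can be classified differently in
#' classrooms with different nomination distributions.
#'
#' @param scores a `classroom_scores` object.
#' @param limits per-classroom limits from [classroom_limits()]; computed at
#'   `alpha` when `NULL`.
#' @param alpha significance level used when `limits` is `NULL`.
#' @param neglected_max_pnr the positive-nomination bound for neglected; 1
#'   for limit-3 data.  Pass `NA` to use `max(ll_pnr, 1)` from the limits
#'   table (intended for data with 5 or unlimited nominations).
#' @return A `status_assignment` data.frame.
#' @export
classify_gb <- function(scores, limits = NULL, alpha = 0.05,
                        neglected_max_pnr = 1) {
  stopifnot(inherits(scores, "classroom_scores"))
  stats <- classroom_stats(scores)
  if (is.null(limits)) limits <- classroom_limits(scores, alpha = alpha)
  i <- match(scores$classroom, stats$classroom)
  j <- match(scores$classroom, limits$classroom)
  if (anyNA(j)) stop("limits table lacks classroom(s): ",
                     paste(unique(scores$classroom[is.na(j)]), collapse = ", "))
  negl_max <- if (is.na(neglected_max_pnr))
    pmax(ifelse(is.na(limits$ll_pnr[j]), 1, limits$ll_pnr[j]), 1)
  else rep(neglected_max_pnr, nrow(scores))
  preds <- .prob_predicates(scores$pnr, scores$nnr,
                            limits$ul_pnr[j], limits$ul_nnr[j],
                            stats$m_pnr[i], stats$m_nnr[i],
                            function(p, n) p <= negl_max & n < stats$m_nnr[i])
  status <- .label_in_order(preds, nrow(scores))
  rationale <- sprintf("pair %d-%d vs UL=%d/%d; M=%.2f/%.2f -> %s",
                       scores$pnr, scores$nnr,
                       limits$ul_pnr[j], limits$ul_nnr[j],
                       stats$m_pnr[i], stats$m_nnr[i], status)
  .assignment(scores, "GB", status, rationale)
}

#' Classify a data set with several methods at once
#'
#' Convenience wrapper: tallies a nomination data set, computes standardized
#' scores and per-classroom limits as needed, runs the requested
#' classifiers, and returns one wide table.
#'
#' @param x a `sociometric_data` object.
#' @param methods subset of `c("CD", "CD_original", "NB", "GB")`.
#' @param alpha significance level for the adjusted-probability limits.
#' @return data.frame with the score and z-score columns plus one
#'   `status_<method>` and `rationale_<method>` column pair per method.
#' @export
classify_all <- function(x, methods = c("CD", "NB", "GB"), alpha = 0.05) {
  stopifnot(inherits(x, "sociometric_data"))
  methods <- match.arg(methods, c("CD", "CD_original", "NB", "GB"),
                       several.ok = TRUE)
  scores <- tally_nominations(x)
  out <- as.data.frame(scores)
  if (any(methods %in% c("CD", "CD_original"))) {
    std <- standardize_scores(scores)
    out <- as.data.frame(std)
  }
  for (m in methods) {
    asg <- switch(m,
      CD          = classify_cd(std, "modified"),
      CD_original = classify_cd(std, "original"),
      NB          = classify_nb(scores),
      GB          = classify_gb(scores, alpha = alpha))
    key <- tolower(m)
    i <- match(paste(out$classroom, out$child),
               paste(asg$classroom, asg$child))
    out[[paste0("status_", key)]] <- asg$status[i]
    out[[paste0("rationale_", key)]] <- asg$rationale[i]
  }
  out
}

#' Enumerate the admissible (PNR, NNR) pairs of a status under a method
#'
#' Characterizes a classifier's region for one status as the exhaustive set
#' of integer nomination pairs that would receive that label in a classroom
#' with the given parameters.  For the probability methods the region is an
#' exact function of the means and critical values.  For the standard-score
#' method the exact region additionally needs the classroom dispersion
#' parameters (`sd_pnr`, `sd_nnr`, `sd_sp`, `sd_si`); when only the means
#' are supplied, the neglected region falls back to its practical
#' characterization (both counts below their means and raw impact at most
#' `si_raw_max`, default 3).
#'
#' @param method `"CD"`, `"NB"` or `"GB"`.
#' @param status one of preferred, rejected, neglected, controversial,
#'   average.
#' @param params named list of classroom parameters: `m_pnr`, `m_nnr`
#'   always; `ul_pnr`, `ul_nnr` for GB; `cutoff` (default 7) for NB;
#'   `sd_pnr`, `sd_nnr`, `sd_sp`, `sd_si` for exact CD regions;
#'   `si_raw_max` (default 3) for the practical CD neglected region;
#'   optionally `V` (voters) to size the grid.
#' @param limit nomination limit per valence.
#' @param max_count upper bound of the pair grid per dimension; defaults to
#'   `limit * V` when `V` is supplied, else `10 * limit`.
#' @return An object of class `pair_region`: data.frame of columns `pnr`,
#'   `nnr`, with the method, status and grid bound as attributes.
#' @export
enumerate_pairs <- function(method = c("CD", "NB", "GB"), status, params,
                            limit = 3, max_count = NULL) {
  method <- match.arg(method)
  status <- match.arg(status, .STATUSES)
  need <- function(keys) {
    miss <- keys[!vapply(keys, function(k)
      !is.null(params[[k]]) && !is.na(params[[k]]), logical(1))]
    if (length(miss))
      stop("missing parameter(s) for ", method, "/", status, ": ",
           paste(miss, collapse = ", "))
  }
  if (is.null(max_count))
    max_count <- if (!is.null(params$V)) limit * params$V else 10L * limit
  grid <- expand.grid(pnr = 0:max_count, nnr = 0:max_count)

  label_of <- function(a, b) {
    if (method == "NB") {
      need(c("m_pnr", "m_nnr"))
      cutoff <- if (is.null(params$cutoff)) 7 else params$cutoff
      preds <- .prob_predicates(a, b, cutoff, cutoff,
                                params$m_pnr, params$m_nnr,
                                function(p, n) p + n <= 2)
    } else if (method == "GB") {
      need(c("m_pnr", "m_nnr", "ul_pnr", "ul_nnr"))
      negl_max <- if (is.null(params$neglected_max_pnr)) 1
                  else params$neglected_max_pnr
      preds <- .prob_predicates(a, b, params$ul_pnr, params$ul_nnr,
                                params$m_pnr, params$m_nnr,
                                function(p, n) p <= negl_max & n < params$m_nnr)
    } else {
      need(c("m_pnr", "m_nnr"))
      exact <- all(c("sd_pnr", "sd_nnr", "sd_sp", "sd_si") %in% names(params))
      if (exact) {
        zp <- (a - params$m_pnr) / params$sd_pnr
        zn <- (b - params$m_nnr) / params$sd_nnr
        z_sp <- (zp - zn) / params$sd_sp
        z_si <- (zp + zn) / params$sd_si
        preds <- list(preferred     = z_sp > 1  & zp > 0 & zn < 0,
                      rejected      = z_sp < -1 & zp < 0 & zn > 0,
                      controversial = z_si > 1  & zp > 0 & zn > 0,
                      neglected     = z_si < -1 & zp < 0 & zn < 0)
      } else {
        if (status != "neglected")
          stop("missing parameter(s) for CD/", status,
               ": sd_pnr, sd_nnr, sd_sp, sd_si (exact z-score region)")
        si_max <- if (is.null(params$si_raw_max)) 3 else params$si_raw_max
        preds <- list(preferred = rep(FALSE, length(a)),
                      rejected = rep(FALSE, length(a)),
                      controversial = rep(FALSE, length(a)),
                      neglected = a < params$m_pnr & b < params$m_nnr &
                                  (a + b) <= si_max)
      }
    }
    .label_in_order(preds, length(a))
  }
  keep <- label_of(grid$pnr, grid$nnr) == status
  region <- grid[keep, , drop = FALSE]
  region <- region[order(region$pnr, region$nnr), , drop = FALSE]
  rownames(region) <- NULL
  structure(region, method = method, status = status, max_count = max_count,
            class = c("pair_region", "data.frame"))
}

#' @export
print.pair_region <- function(x, ...) {
  cat(sprintf("pair_region: %s/%s, %d pair(s) on [0, %d]^2\n",
              attr(x, "method"), attr(x, "status"), nrow(x),
              attr(x, "max_count")))
  if (nrow(x) <= 25)
    cat(" ", paste(sprintf("%d-%d", x$pnr, x$nnr), collapse = ", "), "\n")
  invisible(x)
}

#' Count of reciprocated positive nomination pairs
#'
#' A reciprocated positive pair is two children who nominate each other
#' positively.  Exposed as a helper for audits of the neglected group
#' (children with some positive reciprocity are unlikely true neglected).
#'
#' @param x a `sociometric_data` object.
#' @return data.frame per classroom with the count of reciprocated pairs.
#' @export
reciprocated_positive_pairs <- function(x) {
  stopifnot(inherits(x, "sociometric_data"))
  nom <- x$nominations[x$nominations$valence == "P", , drop = FALSE]
  out <- lapply(split(nom, nom$classroom), function(sub) {
    e <- paste(sub$nominator, sub$nominee, sep = "\r")
    r <- paste(sub$nominee, sub$nominator, sep = "\r")
    data.frame(classroom = sub$classroom[1],
               reciprocated = sum(e %in% r) / 2, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
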