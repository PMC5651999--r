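#' Cohen's kappa between two categorical labelings
#'
#' Chance-corrected agreement `kappa = (p_o - p_e) / (1 - p_e)`, with chance
#' agreement `p_e` from the product of the marginal distributions.  The
#' conventional Landis-Koch verbal band for the value is attached.
#'
#' @param a,b equal-length label vectors over the same children.
#' @return An object of class `cohen_kappa`: list with `kappa`,
#'   `p_observed`, `p_expected`, `band` and the contingency `table`.
#' @export
cohen_kappa <- function(a, b) {
  if (length(a) != length(b)) stop("label vectors differ in length")
  if (!length(a)) stop("empty label vectors")
  lev <- sort(unique(c(as.character(a), as.character(b))))
  fa <- factor(as.character(a), levels = lev)
  fb <- factor(as.character(b), levels = lev)
  tab <- table(fa, fb)
  n <- sum(tab)
  po <- sum(diag(tab)) / n
  pe <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (pe >= 1)
    stop("both labelings are constant and identical; kappa undefined")
  k <- (po - pe) / (1 - pe)
  structure(list(kappa = k, p_observed = po, p_expected = pe,
                 band = landis_koch_band(k), table = tab),
            class = "cohen_kappa")
}

#' @export
print.cohen_kappa <- function(x, ...) {
  cat(sprintf("Cohen's kappa = %.3f (%s); p_o = %.3f, p_e = %.3f\n",
              x$kappa, x$band, x$p_observed, x$p_expected))
  invisible(x)
}

#' Landis-Koch verbal band for a kappa value
#'
#' @param k numeric kappa value(s).
#' @return character: `"poor"` (below 0), `"slight"` (0-0.20), `"fair"`
#'   (0.21-0.40), `"moderate"` (0.41-0.60), `"substantial"` (0.61-0.80) or
#'   `"almost perfect"` (0.81-1).
#' @export
landis_koch_band <- function(k) {
  cut(k, breaks = c(-Inf, -.Machine$double.eps, 0.20, 0.40, 0.60, 0.80, Inf),
      labels = c("poor", "slight", "fair", "moderate", "substantial",
                 "almost perfect"),
      right = TRUE) |> as.character()
}

#' One-vs-rest kappa for a single sociometric type
#'
#' Dichotomizes both labelings as `status` versus everything else and
#' computes [cohen_kappa()] on the resulting binary labels.
#'
#' @param a,b label vectors.
#' @param status the status of interest.
#' @return A `cohen_kappa` object.
#' @export
per_type_kappa <- function(a, b, status) {
  if (!(status %in% a) && !(status %in% b))
    stop("status '", status, "' absent from both labelings; kappa undefined")
  cohen_kappa(ifelse(a == status, status, "other"),
              ifelse(b == status, status, "other"))
}

#' Agreement report across classification methods
#'
#' For every pair of methods: the overall five-way kappa, the one-vs-rest
#' kappa per status (on the full roster by default, or restricted to the
#' union of children either method assigned the status), and the
#' contingency table.  Also partitions children into those labeled
#' identically by all methods and those with at least one disagreement.
#'
#' @param labels data.frame with columns `classroom`, `child` and one label
#'   column per method (e.g. `status_cd`, `status_nb`, `status_gb`), as
#'   produced by [classify_all()].
#' @param methods method label column names; default: every `status_*`
#'   column.
#' @param per_type_scope `"roster"` (default) or `"union"`.
#' @return An object of class `agreement_report`: list with `overall`
#'   (data.frame of pairwise kappas and bands), `per_type` (data.frame),
#'   `crosstabs` (named list), `consistent` and `inconsistent`
#'   (data.frames of children).
#' @export
agreement_report <- function(labels, methods = NULL,
                             per_type_scope = c("roster", "union")) {
  per_type_scope <- match.arg(per_type_scope)
  labels <- as.data.frame(labels)
  if (is.null(methods))
    methods <- grep("^status_", names(labels), value = TRUE)
  if (length(methods) < 2) stop("need at least 2 methods to compare")
  pairs <- utils::combn(methods, 2, simplify = FALSE)
  overall <- do.call(rbind, lapply(pairs, function(pr) {
    ck <- cohen_kappa(labels[[pr[1]]], labels[[pr[2]]])
    data.frame(method_a = pr[1], method_b = pr[2], kappa = ck$kappa,
               band = ck$band, stringsAsFactors = FALSE)
  }))
  statuses <- intersect(.STATUSES, unique(unlist(labels[methods])))
  per_type <- do.call(rbind, lapply(pairs, function(pr) {
    do.call(rbind, lapply(statuses, function(st) {
      a <- labels[[pr[1]]]; b <- labels[[pr[2]]]
      if (per_type_scope == "union") {
        keep <- a == st | b == st
        if (!any(keep)) return(NULL)
        a <- a[keep]; b <- b[keep]
      }
      if (!(st %in% a) && !(st %in% b)) return(NULL)
      ck <- tryCatch(per_type_kappa(a, b, st), error = function(e) NULL)
      if (is.null(ck)) return(NULL)
      data.frame(method_a = pr[1], method_b = pr[2], status = st,
                 kappa = ck$kappa, band = ck$band,
                 n_a = sum(a == st), n_b = sum(b == st),
                 n_agree = sum(a == st & b == st),
                 stringsAsFactors = FALSE)
    }))
  }))
  crosstabs <- lapply(pairs, function(pr)
    cohen_kappa(labels[[pr[1]]], labels[[pr[2]]])$table)
  names(crosstabs) <- vapply(pairs, paste, "", collapse = " vs ")
  agree <- Reduce(`&`, lapply(methods[-1], function(m)
    labels[[m]] == labels[[methods[1]]]))
  structure(list(overall = overall, per_type = per_type,
                 crosstabs = crosstabs,
                 consistent = labels[agree, , drop = FALSE],
                 inconsistent = labels[!agree, , drop = FALSE]),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat("agreement_report:", nrow(x$consistent), "consistent /",
      nrow(x$inconsistent), "inconsistent children\n")
  print(x$overall, row.names = FALSE)
  invisible(x)
}

#' Extract children classified differently by different methods
#'
#' Partitions children into consistent cases (identical label under every
#' method) and inconsistent/discrepant cases, and lists, per method pair,
#' the disagreeing children with their raw nomination pair and the labels
#' each method gave.
#'
#' @inheritParams agreement_report
#' @return list with `consistent`, `inconsistent` (data.frames including
#'   `pnr`/`nnr` when present) and `disagreements`, a named list of
#'   per-method-pair data.frames.
#' @export
extract_discrepancies <- function(labels, methods = NULL) {
  labels <- as.data.frame(labels)
  if (is.null(methods))
    methods <- grep("^status_", names(labels), value = TRUE)
  if (length(methods) < 2) stop("need at least 2 methods")
  agree <- Reduce(`&`, lapply(methods[-1], function(m)
    labels[[m]] == labels[[methods[1]]]))
  keep <- intersect(c("classroom", "child", "pnr", "nnr", methods),
                    names(labels))
  pairs <- utils::combn(methods, 2, simplify = FALSE)
  disagreements <- lapply(pairs, function(pr) {
    d <- labels[labels[[pr[1]]] != labels[[pr[2]]], keep, drop = FALSE]
    rownames(d) <- NULL
    d
  })
  names(disagreements) <- vapply(pairs, paste, "", collapse = " vs ")
  list(consistent = labels[agree, keep, drop = FALSE],
       inconsistent = labels[!agree, keep, drop = FALSE],
       disagreements = disagreements)
}

#' Intra-method variability of raw pairs across classrooms
#'
#' Under a given method, the same raw (PNR, NNR) pair can receive different
#' status labels in different classrooms (because z-scores or adjusted
#' critical values depend on the classroom distribution).  This tabulates,
#' for each observed pair, the labels it received across classrooms and
#' flags pairs with more than one distinct label.
#'
#' @param assignment a `status_assignment` data.frame spanning two or more
#'   classrooms (one method).
#' @return data.frame per observed pair: `pnr`, `nnr`, `n_children`,
#'   `n_classrooms`, `labels` (comma-separated distinct labels with counts)
#'   and logical `flagged`.
#' @export
intra_method_variability <- function(assignment) {
  stopifnot(is.data.frame(assignment))
  if (length(unique(assignment$classroom)) < 2)
    stop("need assignments from at least 2 classrooms")
  key <- paste(assignment$pnr, assignment$nnr, sep = "-")
  out <- do.call(rbind, lapply(split(assignment, key), function(sub) {
    tab <- table(sub$status)
    data.frame(pnr = sub$pnr[1], nnr = sub$nnr[1],
               n_children = nrow(sub),
               n_classrooms = length(unique(sub$classroom)),
               labels = paste(sprintf("%s:%d", names(tab), as.integer(tab)),
                              collapse = ","),
               flagged = length(tab) > 1, stringsAsFactors = FALSE)
  }))
  out <- out[order(-out$pnr, -out$nnr), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Games-Howell pairwise comparisons
#'
#' Post-hoc pairwise tests that do not assume homogeneous variances:
#' Welch-type standard errors and degrees of freedom with p-values from the
#' studentized range distribution.
#'
#' @param values numeric response vector.
#' @param groups group labels.
#' @return data.frame: `group_a`, `group_b`, `diff`, `se`, `t`, `df`, `p`.
#' @export
games_howell <- function(values, groups) {
  groups <- factor(groups)
  lev <- levels(groups)
  k <- length(lev)
  if (k < 2) stop("need at least 2 groups")
  m <- tapply(values, groups, mean)
  v <- tapply(values, groups, stats::var)
  n <- tapply(values, groups, length)
  pairs <- utils::combn(lev, 2, simplify = FALSE)
  out <- do.call(rbind, lapply(pairs, function(pr) {
    i <- pr[1]; j <- pr[2]
    se <- sqrt(v[i] / n[i] + v[j] / n[j])
    tval <- (m[i] - m[j]) / se
    df <- se^4 / ((v[i] / n[i])^2 / (n[i] - 1) + (v[j] / n[j])^2 / (n[j] - 1))
    p <- stats::ptukey(abs(tval) * sqrt(2), nmeans = k, df = df,
                       lower.tail = FALSE)
    data.frame(group_a = i, group_b = j, diff = unname(m[i] - m[j]),
               se = unname(se), t = unname(tval), df = unname(df),
               p = unname(p), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Behavioural validation of a sociometric classification
#'
#' Tests whether the status groups produced by a method differ in social
#' behaviour: one one-way ANOVA per behaviour scale with status as the
#' factor, Levene's test (median-centred) for homogeneity of variances, and
#' post-hoc pairwise comparisons by Tukey's HSD when homogeneity holds or
#' Games-Howell when it does not.  With three scales tested per sample, the
#' Bonferroni-adjusted significance level is 0.05/3 ~ 0.017.
#'
#' @param behavior data.frame of (standardized) behaviour scores with
#'   columns `classroom`, `child` and the scale columns.
#' @param assignment a `status_assignment` data.frame (one method).
#' @param scales scale columns to test; defaults to all non-id columns.
#' @param adjusted_alpha significance level after Bonferroni adjustment.
#' @param homogeneity_alpha level of Levene's test used to pick the
#'   post-hoc procedure.
#' @return An object of class `behavior_validation`: per scale, the group
#'   descriptives, `F`, df, p-value, significance flag, Levene p, the
#'   post-hoc test used and its pairwise p-values.
#' @export
validate_behavior <- function(behavior, assignment, scales = NULL,
                              adjusted_alpha = 0.05 / 3,
                              homogeneity_alpha = 0.05) {
  behavior <- as.data.frame(behavior)
  if (is.null(scales))
    scales <- setdiff(names(behavior), c("classroom", "child"))
  key_b <- if ("classroom" %in% names(behavior))
    paste(behavior$classroom, behavior$child) else behavior$child
  key_a <- paste(assignment$classroom, assignment$child)
  i <- match(key_a, key_b)
  if (anyNA(i)) {
    # fall back to child-only keys (single-classroom behaviour tables)
    i <- match(assignment$child, behavior$child)
    if (anyNA(i)) stop("behaviour scores missing for some children")
  }
  status <- assignment$status
  sizes <- table(status)
  small <- names(sizes)[sizes < 2]
  if (length(small)) {
    warning("dropping status group(s) with fewer than 2 members: ",
            paste(small, collapse = ", "))
    keep <- !(status %in% small)
    status <- status[keep]; i <- i[keep]
  }
  if (length(unique(status)) < 2)
    stop("fewer than 2 status groups with 2+ members; ANOVA impossible")
  status <- factor(status, levels = intersect(c(.STATUSES, "unclassified"),
                                              unique(status)))
  res <- lapply(scales, function(sc) {
    y <- behavior[[sc]][i]
    fit <- stats::aov(y ~ status)
    an <- summary(fit)[[1]]
    lev <- car::leveneTest(y ~ status, center = stats::median)
    homogeneous <- lev[["Pr(>F)"]][1] >= homogeneity_alpha
    if (homogeneous) {
      tk <- stats::TukeyHSD(fit)$status
      posthoc <- data.frame(
        comparison = rownames(tk), diff = tk[, "diff"],
        p = tk[, "p adj"], stringsAsFactors = FALSE)
      test_used <- "Tukey-HSD"
    } else {
      gh <- games_howell(y, status)
      posthoc <- data.frame(
        comparison = paste(gh$group_a, gh$group_b, sep = "-"),
        diff = gh$diff, p = gh$p, stringsAsFactors = FALSE)
      test_used <- "Games-Howell"
    }
    rownames(posthoc) <- NULL
    groups <- data.frame(
      status = levels(status),
      n = as.integer(table(status)),
      mean = as.numeric(tapply(y, status, mean)),
      sd = as.numeric(tapply(y, status, stats::sd)),
      stringsAsFactors = FALSE)
    list(scale = sc, groups = groups,
         f = an[["F value"]][1],
         df = c(an[["Df"]][1], an[["Df"]][2]),
         p = an[["Pr(>F)"]][1],
         significant = an[["Pr(>F)"]][1] < adjusted_alpha,
         levene_p = lev[["Pr(>F)"]][1],
         posthoc_test = test_used, posthoc = posthoc)
  })
  names(res) <- scales
  structure(list(scales = res, adjusted_alpha = adjusted_alpha,
                 method = assignment$method[1],
                 n = length(status)),
            class = "behavior_validation")
}

#' @export
print.behavior_validation <- function(x, ...) {
  cat("behavior_validation (method ", x$method, ", n = ", x$n,
      ", alpha = ", format(x$adjusted_alpha, digits = 3), ")\n", sep = "")
  for (sc in x$scales)
    cat(sprintf("  %-12s F(%d,%d) = %6.2f, p = %.4g %s [%s]\n",
                sc$scale, sc$df[1], sc$df[2], sc$f, sc$p,
                ifelse(sc$significant, "*", " "), sc$posthoc_test))
  invisible(x)
}

#' Flatten a behaviour validation to one row per scale
#'
#' @param x a `behavior_validation` object.
#' @param ... unused.
#' @return data.frame: scale, per-group `n`/`mean`/`sd` columns, `F`, `p`,
#'   the post-hoc test used and one p-value column per pairwise contrast.
#' @export
as.data.frame.behavior_validation <- function(x, ...) {
  do.call(rbind, lapply(x$scales, function(sc) {
    row <- data.frame(scale = sc$scale, stringsAsFactors = FALSE)
    for (g in seq_len(nrow(sc$groups))) {
      st <- sc$groups$status[g]
      row[[paste0("n_", st)]] <- sc$groups$n[g]
      row[[paste0("m_", st)]] <- sc$groups$mean[g]
      row[[paste0("sd_", st)]] <- sc$groups$sd[g]
    }
    row$f <- sc$f; row$p <- sc$p; row$posthoc_test <- sc$posthoc_test
    for (j in seq_len(nrow(sc$posthoc)))
      row[[paste0("p_", gsub("[^a-z]+", "_", sc$posthoc$comparison[j]))]] <-
        sc$posthoc$p[j]
    row
  }))
}
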