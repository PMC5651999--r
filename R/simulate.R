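# Default per-status attraction weights: relative probability of being
# picked as a positive / negative nominee.  Chosen to emulate the canonical
# behavioural repertoires (preferred children widely liked, rejected widely
# disliked, neglected invisible on both dimensions, controversial salient
# on both).  The "strong" preset raises the dominant weights to 10x the
# average child for planted-structure recovery experiments.
.default_weights <- function(separation = c("default", "strong")) {
  separation <- match.arg(separation)
  hi_pos <- if (separation == "strong") 10 else 2.5
  hi_neg <- if (separation == "strong") 10 else 5
  rbind(
    preferred     = c(pos = hi_pos, neg = 0.2),
    rejected      = c(pos = 0.5,    neg = hi_neg),
    neglected     = c(pos = 0.3,    neg = 0.4),
    controversial = c(pos = hi_pos, neg = hi_neg),
    average       = c(pos = 1,      neg = 0.7))
}

# Mean behaviour shifts in SD units (aggression, withdrawal, likeability),
# following the meta-analytic profiles of the five status groups.
.default_behavior_effects <- function() {
  rbind(
    preferred     = c(aggression = -0.5, withdrawal = -0.5, likeability = 1.0),
    rejected      = c(aggression =  1.0, withdrawal =  0.5, likeability = -0.8),
    neglected     = c(aggression = -0.5, withdrawal =  0.5, likeability = -0.4),
    controversial = c(aggression =  0.8, withdrawal =  0.0, likeability = 0.3),
    average       = c(aggression =  0.0, withdrawal =  0.0, likeability = 0.0))
}

#' Configuration of a synthetic classroom simulation
#'
#' Defines one classroom with planted sociometric structure.  Default
#' planted proportions follow meta-analytic base rates (13% preferred, 13%
#' rejected, 15% neglected, 4% controversial, remainder average); each
#' voter gives `limit` distinct positive and `limit` distinct negative
#' nominations, drawn without replacement with probability proportional to
#' the nominee's status attraction weight.
#'
#' @param G classroom size (the probability methods are validated for
#'   13-50).
#' @param limit nominations per valence per voter.
#' @param participation fraction of children who vote (abstainers are drawn
#'   uniformly).
#' @param planted named integer vector of planted counts per status;
#'   computed from `proportions` when `NULL`.
#' @param proportions named proportions for the four non-average statuses.
#' @param weights 5 x 2 matrix of attraction weights (`pos`, `neg` columns,
#'   status rownames); see `separation`.
#' @param separation `"default"` or `"strong"` preset for `weights`.
#' @param behavior_effects 5 x 3 matrix of mean behaviour shifts in SD
#'   units (aggression, withdrawal, likeability).
#' @param disjoint_valences if `TRUE` (default) a voter's positive and
#'   negative nominees do not overlap.
#' @param neg_propensity probability that a voter uses each of its `limit`
#'   negative nomination slots.  Voters always give the full positive quota
#'   but often name fewer "liked least" peers; the default of 0.8 yields a
#'   mean negative expansiveness of 2.4 nominations per voter, reproducing
#'   the empirical pattern that liking counts are more expansive and less
#'   dispersed (lower variation coefficient) than disliking counts.
#' @param seed random seed.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(G = 25, limit = 3, participation = 1,
                       planted = NULL,
                       proportions = c(preferred = 0.13, rejected = 0.13,
                                       neglected = 0.15, controversial = 0.04),
                       weights = NULL,
                       separation = c("default", "strong"),
                       behavior_effects = .default_behavior_effects(),
                       disjoint_valences = TRUE, neg_propensity = 0.8,
                       seed = 1L) {
  separation <- match.arg(separation)
  if (is.null(weights)) weights <- .default_weights(separation)
  if (G < 2) stop("G must be at least 2")
  if (limit >= G) stop("limit must be below G")
  if (is.null(planted)) {
    planted <- round(proportions * G)
  }
  planted <- planted[setdiff(names(planted), "average")]
  if (sum(planted) > G)
    stop("planted counts (", sum(planted), ") exceed classroom size ", G)
  planted <- c(planted, average = G - sum(planted))
  if (any(weights < 0)) stop("attraction weights must be nonnegative")
  if (!(neg_propensity >= 0 && neg_propensity <= 1))
    stop("neg_propensity must be in [0, 1]")
  structure(list(G = as.integer(G), limit = as.integer(limit),
                 participation = participation, planted = planted,
                 weights = weights, behavior_effects = behavior_effects,
                 disjoint_valences = disjoint_valences,
                 neg_propensity = neg_propensity,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config: G =", x$G, ", limit =", x$limit,
      ", participation =", x$participation, ", seed =", x$seed, "\n")
  cat("  planted:", paste(names(x$planted), x$planted, sep = "=",
                          collapse = ", "), "\n")
  invisible(x)
}

.weighted_pick <- function(ids, w, size) {
  size <- min(size, sum(w > 0), length(ids))
  if (size == 0) return(character(0))
  if (length(ids) == 1) return(ids)
  sample(ids, size, prob = w)
}

#' Generate one synthetic classroom
#'
#' Draws nominations and behaviour scores under a `sim_config`: every voter
#' nominates `limit` distinct peers positively and `limit` negatively
#' (disjoint sets by default), with pick probabilities proportional to the
#' nominee's planted-status attraction weights; behaviour scores are the
#' planted mean shift plus unit Gaussian noise, standardized within the
#' classroom.  Output is bit-identical under a fixed seed.
#'
#' @param config a `sim_config`.
#' @param seed overrides `config$seed` when given.
#' @param classroom classroom label.
#' @return list with `data` (a `sociometric_data`), `behavior`
#'   (standardized scores), `truth` (data.frame of planted labels) and the
#'   `config`.
#' @export
generate_classroom <- function(config, seed = NULL, classroom = "sim1") {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(seed)) seed <- config$seed
  set.seed(seed)
  G <- config$G
  children <- sprintf("c%03d", seq_len(G))
  status <- rep(names(config$planted), config$planted)
  truth <- data.frame(classroom = classroom, child = children,
                      status = status, stringsAsFactors = FALSE)

  n_voters <- max(0L, round(config$participation * G))
  voters <- if (n_voters >= G) children else sort(sample(children, n_voters))
  w_pos <- config$weights[status, "pos"]
  w_neg <- config$weights[status, "neg"]
  names(w_pos) <- names(w_neg) <- children

  recs <- vector("list", 2L * length(voters))
  k <- 0L
  for (v in voters) {
    others <- setdiff(children, v)
    pos <- .weighted_pick(others, w_pos[others], config$limit)
    neg_pool <- if (config$disjoint_valences) setdiff(others, pos) else others
    n_neg <- stats::rbinom(1, config$limit, config$neg_propensity)
    neg <- .weighted_pick(neg_pool, w_neg[neg_pool], n_neg)
    if (length(pos)) {
      k <- k + 1L
      recs[[k]] <- data.frame(classroom = classroom, nominator = v,
                              nominee = pos, valence = "P",
                              stringsAsFactors = FALSE)
    }
    if (length(neg)) {
      k <- k + 1L
      recs[[k]] <- data.frame(classroom = classroom, nominator = v,
                              nominee = neg, valence = "N",
                              stringsAsFactors = FALSE)
    }
  }
  nominations <- if (k) do.call(rbind, recs[seq_len(k)]) else
    data.frame(classroom = character(0), nominator = character(0),
               nominee = character(0), valence = character(0))
  roster <- data.frame(classroom = classroom, child = children,
                       stringsAsFactors = FALSE)
  data <- nomination_data(nominations, roster = roster, limit = config$limit)

  eff <- config$behavior_effects[status, , drop = FALSE]
  raw <- data.frame(classroom = classroom, child = children,
                    stringsAsFactors = FALSE)
  for (sc in colnames(config$behavior_effects))
    raw[[sc]] <- eff[, sc] + stats::rnorm(G)
  behavior <- standardize_behavior(raw)

  list(data = data, behavior = behavior, truth = truth, config = config)
}

#' Monte-Carlo comparison of classification methods on planted classrooms
#'
#' Generates `n_replicates` classrooms under one configuration, classifies
#' each with the requested methods, and aggregates planted-status recovery
#' rates and pairwise inter-method kappas.
#'
#' @param config a `sim_config`.
#' @param n_replicates number of classrooms to simulate.
#' @param methods subset of `c("CD", "NB", "GB")`.
#' @param seed base seed; replicate `i` uses `seed + i`.
#' @param alpha significance level for the adjusted-probability limits.
#' @return An object of class `sim_result`: list with `assignments` (one
#'   data.frame over all replicates: replicate, child, pair, true status
#'   and one label column per method), `recovery` (status x method matrix
#'   of pooled recovery rates), `kappa` (mean pairwise kappas) and the
#'   inputs.
#' @export
run_comparison <- function(config, n_replicates, methods = c("CD", "NB", "GB"),
                           seed = config$seed, alpha = 0.05) {
  stopifnot(n_replicates >= 1)
  methods <- match.arg(methods, c("CD", "NB", "GB"), several.ok = TRUE)
  reps <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    sim <- generate_classroom(config, seed = seed + r,
                              classroom = sprintf("r%04d", r))
    scores <- tally_nominations(sim$data)
    tab <- data.frame(replicate = r, classroom = scores$classroom,
                      child = scores$child, pnr = scores$pnr,
                      nnr = scores$nnr,
                      truth = sim$truth$status[match(scores$child,
                                                     sim$truth$child)],
                      stringsAsFactors = FALSE)
    for (m in methods) {
      asg <- switch(m,
        CD = classify_cd(standardize_scores(scores)),
        NB = suppressWarnings(classify_nb(scores)),
        GB = classify_gb(scores, alpha = alpha))
      tab[[paste0("status_", tolower(m))]] <-
        asg$status[match(scores$child, asg$child)]
    }
    reps[[r]] <- tab
  }
  assignments <- do.call(rbind, reps)
  statuses <- names(config$planted)
  recovery <- sapply(methods, function(m) {
    lab <- assignments[[paste0("status_", tolower(m))]]
    vapply(statuses, function(st) {
      planted <- assignments$truth == st
      if (!any(planted)) return(NA_real_)
      mean(lab[planted] == st)
    }, numeric(1))
  })
  recovery <- matrix(recovery, nrow = length(statuses),
                     dimnames = list(statuses, methods))
  kap <- NULL
  if (length(methods) >= 2) {
    prs <- utils::combn(methods, 2, simplify = FALSE)
    kap <- do.call(rbind, lapply(prs, function(pr) {
      data.frame(method_a = pr[1], method_b = pr[2],
                 kappa = cohen_kappa(
                   assignments[[paste0("status_", tolower(pr[1]))]],
                   assignments[[paste0("status_", tolower(pr[2]))]])$kappa,
                 stringsAsFactors = FALSE)
    }))
  }
  structure(list(assignments = assignments, recovery = recovery,
                 kappa = kap, config = config, methods = methods,
                 n_replicates = n_replicates, seed = seed, alpha = alpha),
            class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat("sim_result:", x$n_replicates, "replicates of G =", x$config$G,
      "(seed", x$seed, ")\n")
  cat("pooled recovery of planted status:\n")
  print(round(x$recovery, 3))
  invisible(x)
}

#' Composition of the neglected groups by raw pair
#'
#' Audits which (PNR, NNR) pairs populate each method's neglected group in
#' a simulation result, focussing on the pairs the fixed-cutoff and
#' adjusted methods disagree on: pair 2-0 (neglected under the raw-impact
#' rule only) and pair 1-2 (neglected under the adjusted rule only).
#'
#' @param result a `sim_result` including NB and GB labels.
#' @return list with, per method, a pair-composition table, plus
#'   `frac_nb_20` (share of pair 2-0 among NB-neglected) and `frac_gb_12`
#'   (share of pair 1-2 among GB-neglected); `NA` when a neglected group is
#'   empty.
#' @export
neglected_pair_audit <- function(result) {
  stopifnot(inherits(result, "sim_result"))
  need <- c("status_nb", "status_gb")
  if (!all(need %in% names(result$assignments)))
    stop("result must include NB and GB classifications")
  a <- result$assignments
  comp <- function(col) {
    sub <- a[a[[col]] == "neglected", , drop = FALSE]
    if (!nrow(sub)) return(NULL)
    tab <- table(paste(sub$pnr, sub$nnr, sep = "-"))
    data.frame(pair = names(tab), n = as.integer(tab),
               frac = as.integer(tab) / nrow(sub), stringsAsFactors = FALSE)
  }
  nb <- comp("status_nb"); gb <- comp("status_gb")
  frac_of <- function(tab, pair)
    if (is.null(tab)) NA_real_ else
      if (pair %in% tab$pair) tab$frac[tab$pair == pair] else 0
  list(nb = nb, gb = gb,
       frac_nb_20 = frac_of(nb, "2-0"),
       frac_gb_12 = frac_of(gb, "1-2"))
}
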