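test_that("kappa reproduces hand-computed and degenerate cases", {
  # hand computation from the 2x2 table
  k <- cohen_kappa(c("P", "P", "A", "A"), c("P", "A", "A", "A"))
  expect_equal(k$p_observed, 0.75)
  expect_equal(k$p_expected, 0.5)
  expect_equal(k$kappa, 0.5)
  expect_equal(k$band, "moderate")
  # identical labelings with at least two labels
  expect_equal(cohen_kappa(c("a", "b", "a"), c("a", "b", "a"))$kappa, 1)
  # both raters constant and identical: undefined
  expect_error(cohen_kappa(c("a", "a"), c("a", "a")), "undefined")
  expect_error(cohen_kappa(c("a", "a"), c("a")), "length")
})

test_that("kappa equals independent implementations on random labelings", {
  set.seed(7)
  for (i in 1:200) {
    a <- rand_labels(30)
    b <- rand_labels(30)
    k <- cohen_kappa(a, b)$kappa
    expect_equal(k, kappa_bruteforce(a, b), tolerance = 1e-12)
    # symmetry in the arguments
    expect_equal(cohen_kappa(b, a)$kappa, k, tolerance = 1e-12)
  }
  # cross-check against an established implementation
  a <- rand_labels(200); b <- rand_labels(200)
  ref <- e1071::classAgreement(table(a, b))$kappa
  expect_equal(cohen_kappa(a, b)$kappa, ref, tolerance = 1e-12)
})

test_that("kappa is invariant under a joint relabeling", {
  set.seed(8)
  a <- rand_labels(50); b <- rand_labels(50)
  perm <- setNames(sample(unique(c(a, b))), unique(c(a, b)))
  expect_equal(cohen_kappa(perm[a], perm[b])$kappa,
               cohen_kappa(a, b)$kappa, tolerance = 1e-12)
})

test_that("one-vs-rest kappa matches a brute-force dichotomization", {
  # same single preferred child: perfect agreement
  a <- c("preferred", rep("average", 19))
  expect_equal(per_type_kappa(a, a, "preferred")$kappa, 1)
  # disjoint singleton preferred sets in a class of 20: below chance
  b <- c("average", "preferred", rep("average", 18))
  k <- per_type_kappa(a, b, "preferred")$kappa
  expect_lt(k, 0)
  expect_equal(k, kappa_bruteforce(ifelse(a == "preferred", "p", "o"),
                                   ifelse(b == "preferred", "p", "o")),
               tolerance = 1e-12)
  # all five statuses against the brute-force 2x2 oracle
  set.seed(9)
  for (i in 1:25) {
    x <- rand_labels(40); y <- rand_labels(40)
    for (st in unique(c(x, y)))
      expect_equal(per_type_kappa(x, y, st)$kappa,
                   kappa_bruteforce(ifelse(x == st, st, "o"),
                                    ifelse(y == st, st, "o")),
                   tolerance = 1e-12)
  }
  expect_error(per_type_kappa(a, b, "controversial"), "absent")
})

test_that("agreement report partitions the roster", {
  set.seed(10)
  labels <- data.frame(classroom = "A", child = sprintf("c%02d", 1:40),
                       status_cd = rand_labels(40),
                       status_nb = rand_labels(40),
                       status_gb = rand_labels(40),
                       stringsAsFactors = FALSE)
  rep <- agreement_report(labels)
  expect_equal(nrow(rep$consistent) + nrow(rep$inconsistent), 40)
  expect_true(all(rep$overall$kappa >= -1 & rep$overall$kappa <= 1))
  expect_equal(nrow(rep$overall), 3)
  expect_true(all(sapply(rep$crosstabs, sum) == 40))
  # all methods identical: no inconsistent cases
  same <- labels
  same$status_nb <- same$status_gb <- same$status_cd
  rep2 <- agreement_report(same)
  expect_equal(nrow(rep2$inconsistent), 0)
  disc <- extract_discrepancies(labels)
  expect_equal(nrow(disc$consistent), nrow(rep$consistent))
  expect_true(all(labels$child %in%
                  c(disc$consistent$child, disc$inconsistent$child)))
})

test_that("intra-method variability flags pair 5-0 for z-scores only", {
  # same raw pair (5,0) in two classrooms: preferred under the
  # standard-score method in the homogeneous classroom, average in the
  # dispersed one; the fixed-cutoff method labels it average in both
  mk <- function(pnr, nnr, cl) scores_from_counts(pnr, nnr, classroom = cl)
  sc_a <- mk(c(5, 4, 3, 3, 3, 3, 2, 2, 2, 2, 3, 4),
             c(0, 1, 2, 3, 4, 5, 3, 2, 4, 5, 3, 4), "A")
  sc_b <- mk(c(5, 9, 9, 0, 9, 0, 9, 0, 9, 0, 5, 5),
             c(0, 1, 2, 3, 4, 5, 3, 2, 4, 5, 3, 4), "B")
  cd <- rbind(classify_cd(standardize_scores(sc_a)),
              classify_cd(standardize_scores(sc_b)))
  nb <- rbind(suppressWarnings(classify_nb(sc_a)),
              suppressWarnings(classify_nb(sc_b)))
  v_cd <- intra_method_variability(cd)
  v_nb <- intra_method_variability(nb)
  expect_true(v_cd$flagged[v_cd$pnr == 5 & v_cd$nnr == 0])
  expect_false(v_nb$flagged[v_nb$pnr == 5 & v_nb$nnr == 0])
  expect_error(intra_method_variability(classify_cd(standardize_scores(sc_a))),
               "2 classrooms")
})

test_that("fixed-cutoff labels never vary across classrooms on a mean side", {
  # classrooms sharing the side of the means for every observed pair
  sc_a <- scores_from_counts(c(7, 2, 6, 3, 1, 0, 2, 3, 4, 2, 3, 3, 0),
                             c(1, 0, 2, 3, 4, 5, 2, 1, 3, 2, 4, 3, 1), "A")
  nb_a <- classify_nb(sc_a)
  nb_b <- nb_a
  nb_b$classroom <- "B"
  v <- intra_method_variability(rbind(nb_a, nb_b))
  expect_false(any(v$flagged))
})

test_that("Games-Howell matches an independent reference computation", {
  # three unbalanced heteroscedastic groups; reference p-values computed
  # with an independent statistics library and frozen
  y <- c(0.305, -1.04, 0.75, 0.941, -1.951, -1.302, 0.128, -0.316,
         0.966, -0.706, 2.759, 2.556, 1.132, 3.254, 1.935, -0.719, 1.738,
         -0.918,
         -0.061, -0.525, -0.592, -0.84, 0.111, -0.577, -0.714, -0.676,
         -0.234, -0.317, -0.294, -0.285)
  g <- rep(c("a", "b", "c"), c(8, 10, 12))
  gh <- games_howell(y, g)
  expect_equal(gh$p[gh$group_a == "a" & gh$group_b == "b"], 0.060331,
               tolerance = 1e-4)
  expect_equal(gh$p[gh$group_a == "a" & gh$group_b == "c"], 0.956689,
               tolerance = 1e-4)
  expect_equal(gh$p[gh$group_a == "b" & gh$group_b == "c"], 0.021685,
               tolerance = 1e-4)
})

test_that("behaviour validation detects planted shifts and respects the null", {
  statuses <- c("preferred", "rejected", "neglected", "controversial",
                "average")
  mk_asg <- function(n_per) {
    n <- n_per * 5
    structure(data.frame(
      classroom = "A", child = sprintf("c%03d", 1:n),
      pnr = 0L, nnr = 0L, method = "GB",
      status = rep(statuses, each = n_per), rationale = "",
      stringsAsFactors = FALSE), class = c("status_assignment", "data.frame"))
  }
  # planted +/-1 SD profile: rejected high / preferred low in aggression,
  # preferred high / rejected low in likeability
  hits <- vapply(1:40, function(s) {
    set.seed(3000 + s)
    asg <- mk_asg(30)
    beh <- data.frame(classroom = "A", child = asg$child,
                      aggression = rnorm(150) + (asg$status == "rejected") -
                        (asg$status == "preferred"),
                      likeability = rnorm(150) + (asg$status == "preferred") -
                        (asg$status == "rejected"))
    v <- validate_behavior(beh, asg)
    v$scales$aggression$significant && v$scales$likeability$significant
  }, logical(1))
  expect_gte(mean(hits), 0.95)

  # type-I error under the null stays at the adjusted level
  null_rej <- vapply(1:100, function(s) {
    set.seed(5000 + s)
    asg <- mk_asg(12)
    beh <- data.frame(classroom = "A", child = asg$child,
                      aggression = rnorm(60), withdrawal = rnorm(60),
                      likeability = rnorm(60))
    v <- validate_behavior(beh, asg)
    sum(vapply(v$scales, function(sc) sc$significant, logical(1)))
  }, numeric(1))
  expect_lte(mean(null_rej) / 3, 0.05)
})

test_that("mirrored identical groups give an F of exactly zero", {
  asg <- structure(data.frame(
    classroom = "A", child = sprintf("c%02d", 1:6),
    pnr = 0L, nnr = 0L, method = "GB",
    status = rep(c("preferred", "rejected"), each = 3), rationale = "",
    stringsAsFactors = FALSE), class = c("status_assignment", "data.frame"))
  beh <- data.frame(classroom = "A", child = asg$child,
                    aggression = c(-1, 0, 1, -1, 0, 1))
  v <- suppressWarnings(validate_behavior(beh, asg, scales = "aggression"))
  expect_equal(v$scales$aggression$f, 0, tolerance = 1e-12)
})

test_that("validation report matches the scales-by-contrasts layout", {
  set.seed(11)
  statuses <- c("preferred", "rejected", "neglected", "controversial",
                "average")
  asg <- structure(data.frame(
    classroom = "A", child = sprintf("c%03d", 1:50),
    pnr = 0L, nnr = 0L, method = "GB",
    status = rep(statuses, each = 10), rationale = "",
    stringsAsFactors = FALSE), class = c("status_assignment", "data.frame"))
  beh <- data.frame(classroom = "A", child = asg$child,
                    aggression = rnorm(50), withdrawal = rnorm(50),
                    likeability = rnorm(50))
  v <- validate_behavior(beh, asg)
  tab <- as.data.frame(v)
  expect_equal(nrow(tab), 3)                       # one row per scale
  expect_length(grep("^p_", names(tab)), 10)       # 10 pairwise contrasts
  expect_length(grep("^n_", names(tab)), 5)        # 5 group sizes
  # group Ns sum to the number of labeled children
  expect_equal(sum(v$scales$aggression$groups$n), 50)
  # a status with a single member is dropped with a warning
  asg$status[1:9] <- "average"
  expect_warning(validate_behavior(beh, asg), "fewer than 2")
})
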