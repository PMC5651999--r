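# Shared fixture builders and independent oracles for the test suite.

# Build a sociometric_data object from parallel vectors of records.
toy_data <- function(nominator, nominee, valence, children = NULL,
                     classroom = "A", limit = 3) {
  nom <- data.frame(classroom = classroom, nominator = nominator,
                    nominee = nominee, valence = valence,
                    stringsAsFactors = FALSE)
  roster <- if (is.null(children)) NULL else
    data.frame(classroom = classroom, child = children,
               stringsAsFactors = FALSE)
  nomination_data(nom, roster = roster, limit = limit)
}

# Brute-force Cohen's kappa from first principles: explicit double loop over
# category pairs on the contingency table.  Kept deliberately independent of
# the package implementation.
kappa_bruteforce <- function(a, b) {
  lev <- sort(unique(c(a, b)))
  n <- length(a)
  po <- sum(a == b) / n
  pe <- 0
  for (l in lev) pe <- pe + (sum(a == l) / n) * (sum(b == l) / n)
  (po - pe) / (1 - pe)
}

# Exact binomial upper/lower critical values by direct tail summation,
# written independently of binomial_limits().
ul_oracle <- function(n, p, alpha = 0.05) {
  for (k in 0:n) if (sum(stats::dbinom(k:n, n, p)) < alpha) return(k)
  NA_integer_
}
ll_oracle <- function(n, p, alpha = 0.05) {
  best <- NA_integer_
  for (k in 0:n) if (sum(stats::dbinom(0:k, n, p)) < alpha) best <- k
  best
}

# Random five-way labelings for agreement tests.
rand_labels <- function(n, statuses = c("preferred", "rejected", "neglected",
                                        "controversial", "average")) {
  sample(statuses, n, replace = TRUE)
}
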