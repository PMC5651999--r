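# Canonical internal valence codes
.VALENCES <- c("P", "N")

# Default synonyms accepted in input files, mapped to P/N
.default_valence_map <- function() {
  c(P = "P", POS = "P", POSITIVE = "P", "+" = "P", "1" = "P", LM = "P",
    N = "N", NEG = "N", NEGATIVE = "N", "-" = "N", "-1" = "N", LL = "N")
}

# Population standard deviation: the classroom is the full population of
# interest, so all within-classroom moments divide by N, not N-1.
sd_pop <- function(x) {
  x <- x[!is.na(x)]
  sqrt(mean((x - mean(x))^2))
}

#' Assemble a validated peer-nomination data set
#'
#' Bundles a classroom roster and a long-format nomination table into the
#' container the scoring and classification functions consume.  Validation
#' enforces the nomination protocol: no self-nominations, no duplicated
#' (nominator, nominee, valence) triples, at most `limit` nominations per
#' valence per nominator, and all ids on the roster.
#'
#' @param nominations data.frame with columns `classroom`, `nominator`,
#'   `nominee`, `valence` (valence coded `"P"`/`"N"`).
#' @param roster data.frame with columns `classroom`, `child`; if `NULL` the
#'   roster is inferred as the union of nominators and nominees, with a
#'   warning (non-participating children absent from both sets would be
#'   silently dropped).
#' @param limit maximum nominations per valence a voter may give (the methods
#'   implemented here are validated for `limit = 3`).
#' @return An object of class `sociometric_data`: a list with elements
#'   `roster`, `nominations` and `limit`.
#' @export
nomination_data <- function(nominations, roster = NULL, limit = 3) {
  need <- c("classroom", "nominator", "nominee", "valence")
  miss <- setdiff(need, names(nominations))
  if (length(miss))
    stop("nomination table lacks column(s): ", paste(miss, collapse = ", "))
  nominations <- as.data.frame(nominations)[need]
  for (col in need) nominations[[col]] <- as.character(nominations[[col]])
  if (!all(nominations$valence %in% .VALENCES))
    stop("valence must be coded P or N; got: ",
         paste(unique(setdiff(nominations$valence, .VALENCES)), collapse = ", "))

  if (is.null(roster)) {
    warning("no roster supplied; inferring it from nominators and nominees")
    roster <- unique(data.frame(
      classroom = c(nominations$classroom, nominations$classroom),
      child     = c(nominations$nominator, nominations$nominee),
      stringsAsFactors = FALSE))
  } else {
    roster <- as.data.frame(roster)
    if (!all(c("classroom", "child") %in% names(roster)))
      stop("roster needs columns classroom, child")
    roster <- unique(roster[c("classroom", "child")])
    roster$classroom <- as.character(roster$classroom)
    roster$child <- as.character(roster$child)
  }
  roster <- roster[order(roster$classroom, roster$child), , drop = FALSE]
  rownames(roster) <- NULL
  if (anyDuplicated(roster))
    stop("duplicate child ids in roster")

  .validate_nominations(nominations, roster, limit)
  structure(list(roster = roster, nominations = nominations, limit = limit),
            class = "sociometric_data")
}

.validate_nominations <- function(nom, roster, limit) {
  if (!nrow(nom)) return(invisible(TRUE))
  key <- function(cl, id) paste(cl, id, sep = "\r")
  known <- key(roster$classroom, roster$child)
  bad <- which(!(key(nom$classroom, nom$nominator) %in% known) |
               !(key(nom$classroom, nom$nominee)  %in% known))
  if (length(bad))
    stop("row ", bad[1], ": child id not on the roster of classroom '",
         nom$classroom[bad[1]], "' (",
         nom$nominator[bad[1]], " -> ", nom$nominee[bad[1]], ")")
  self <- which(nom$nominator == nom$nominee)
  if (length(self))
    stop("row ", self[1], ": self-nomination by '", nom$nominator[self[1]],
         "' in classroom '", nom$classroom[self[1]], "'")
  trip <- paste(nom$classroom, nom$nominator, nom$nominee, nom$valence)
  dup <- which(duplicated(trip))
  if (length(dup))
    stop("row ", dup[1], ": duplicated nomination (",
         nom$nominator[dup[1]], " -> ", nom$nominee[dup[1]], ", ",
         nom$valence[dup[1]], ")")
  given <- table(paste(nom$classroom, nom$nominator, nom$valence))
  over <- names(given)[given > limit]
  if (length(over))
    stop("more than ", limit, " nominations of one valence by one voter: ",
         over[1])
  invisible(TRUE)
}

#' @export
print.sociometric_data <- function(x, ...) {
  cat("sociometric_data:",
      length(unique(x$roster$classroom)), "classroom(s),",
      nrow(x$roster), "children,",
      nrow(x$nominations), "nominations (limit", x$limit, "per valence)\n")
  invisible(x)
}

#' Read peer nominations from a delimited text file
#'
#' The canonical file dialect is UTF-8 CSV with header
#' `classroom,nominator,nominee,valence`.  Valence synonyms such as
#' `positive`, `+`, `LM` are normalised to `P`/`N`.
#'
#' @param path nomination file.
#' @param roster_path optional roster file with header `classroom,child`;
#'   when absent the roster is inferred (with a warning).
#' @param sep field separator, `","` by default.
#' @param limit nominations allowed per valence per voter.
#' @param valence_map named character vector mapping input valence spellings
#'   (upper-cased before lookup) to `"P"`/`"N"`.
#' @return A `sociometric_data` object.
#' @export
read_nominations <- function(path, roster_path = NULL, sep = ",", limit = 3,
                             valence_map = .default_valence_map()) {
  if (!file.exists(path)) stop("nomination file not found: ", path)
  nom <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", comment.char = "#",
                           encoding = "UTF-8", stringsAsFactors = FALSE)
  need <- c("classroom", "nominator", "nominee", "valence")
  miss <- setdiff(need, names(nom))
  if (length(miss))
    stop("file ", path, " lacks column(s): ", paste(miss, collapse = ", "))
  v <- valence_map[toupper(trimws(nom$valence))]
  if (anyNA(v))
    stop("unrecognised valence value(s): ",
         paste(unique(nom$valence[is.na(v)]), collapse = ", "))
  nom$valence <- unname(v)
  roster <- NULL
  if (!is.null(roster_path)) {
    if (!file.exists(roster_path)) stop("roster file not found: ", roster_path)
    roster <- utils::read.table(roster_path, header = TRUE, sep = sep,
                                colClasses = "character", comment.char = "#",
                                encoding = "UTF-8", stringsAsFactors = FALSE)
  }
  nomination_data(nom, roster = roster, limit = limit)
}

#' Write a nomination data set to delimited text files
#'
#' Inverse of [read_nominations()]: writes the nomination table to `path` and
#' the roster to `roster_path` in the canonical dialect, so that reading the
#' files back reproduces the object.
#'
#' @param x a `sociometric_data` object.
#' @param path output nomination file.
#' @param roster_path optional output roster file.
#' @param header_lines optional character vector of `#`-prefixed comment
#'   lines (provenance stamps) written before the header.
#' @export
write_nominations <- function(x, path, roster_path = NULL,
                              header_lines = NULL) {
  stopifnot(inherits(x, "sociometric_data"))
  .write_table <- function(df, file) {
    con <- file(file, open = "wt", encoding = "UTF-8")
    on.exit(close(con))
    if (length(header_lines)) writeLines(header_lines, con)
    utils::write.table(df, con, sep = ",", row.names = FALSE, quote = FALSE)
  }
  .write_table(x$nominations, path)
  if (!is.null(roster_path)) .write_table(x$roster, roster_path)
  invisible(x)
}

#' Tally received nominations into per-child score pairs
#'
#' Counts, for every rostered child, the positive and negative nominations
#' received (the PNR/NNR pair), and computes the within-classroom
#' descriptive statistics the classifiers need: means, population SDs,
#' variation coefficients, voter counts and expansiveness per valence.
#' Children never nominated keep the pair (0, 0).
#'
#' @param x a `sociometric_data` object.
#' @return An object of class `classroom_scores`: a data.frame with columns
#'   `classroom`, `child`, `pnr`, `nnr`, carrying the per-classroom summary
#'   table in attribute `"stats"` (accessor [classroom_stats()]).
#' @export
tally_nominations <- function(x) {
  stopifnot(inherits(x, "sociometric_data"))
  roster <- x$roster
  if (!nrow(roster)) stop("empty roster")
  nom <- x$nominations
  key <- paste(roster$classroom, roster$child, sep = "\r")
  cnt <- function(val) {
    sub <- nom[nom$valence == val, , drop = FALSE]
    tab <- table(factor(paste(sub$classroom, sub$nominee, sep = "\r"),
                        levels = key))
    as.integer(tab)
  }
  scores <- data.frame(classroom = roster$classroom, child = roster$child,
                       pnr = cnt("P"), nnr = cnt("N"),
                       stringsAsFactors = FALSE)

  stats <- do.call(rbind, lapply(split(seq_len(nrow(scores)),
                                       scores$classroom), function(idx) {
    cl <- scores$classroom[idx[1]]
    sub <- scores[idx, ]
    nom_cl <- nom[nom$classroom == cl, , drop = FALSE]
    v_of <- function(val) {
      length(unique(nom_cl$nominator[nom_cl$valence == val]))
    }
    n_of <- function(val) sum(nom_cl$valence == val)
    v_pos <- v_of("P"); v_neg <- v_of("N")
    data.frame(
      classroom = cl, G = nrow(sub),
      V = length(unique(nom_cl$nominator)),
      V_pos = v_pos, V_neg = v_neg,
      m_pnr = mean(sub$pnr), m_nnr = mean(sub$nnr),
      sd_pnr = sd_pop(sub$pnr), sd_nnr = sd_pop(sub$nnr),
      vc_pnr = if (mean(sub$pnr) > 0) sd_pop(sub$pnr) / mean(sub$pnr) else NA_real_,
      vc_nnr = if (mean(sub$nnr) > 0) sd_pop(sub$nnr) / mean(sub$nnr) else NA_real_,
      expansiveness_pos = if (v_pos > 0) n_of("P") / v_pos else NA_real_,
      expansiveness_neg = if (v_neg > 0) n_of("N") / v_neg else NA_real_,
      nomination_limit = x$limit,
      stringsAsFactors = FALSE)
  }))
  rownames(stats) <- NULL
  structure(scores, stats = stats, class = c("classroom_scores", "data.frame"))
}

#' Per-classroom descriptive statistics of a score table
#'
#' @param x a `classroom_scores` object from [tally_nominations()] or
#'   [scores_from_counts()].
#' @return data.frame, one row per classroom: group size `G`, voter counts,
#'   means, population SDs, variation coefficients and expansiveness per
#'   valence, and the nomination limit.
#' @export
classroom_stats <- function(x) {
  stopifnot(inherits(x, "classroom_scores"))
  attr(x, "stats")
}

#' Build a score table directly from known (PNR, NNR) pairs
#'
#' Constructs a `classroom_scores` object from raw received counts, for
#' analyses of hypothetical or published classrooms where the underlying
#' nomination records are unavailable.  Voter counts default to full
#' participation (`V = G`); expansiveness is inferred from the totals.
#'
#' @param pnr,nnr nonnegative integer vectors of received counts.
#' @param classroom classroom label.
#' @param children child ids (defaults to `c1..cG`).
#' @param limit nomination limit per valence.
#' @param V number of voters, per valence if length 2 (positive, negative).
#' @export
scores_from_counts <- function(pnr, nnr, classroom = "X", children = NULL,
                               limit = 3, V = NULL) {
  stopifnot(length(pnr) == length(nnr), all(pnr >= 0), all(nnr >= 0))
  G <- length(pnr)
  if (is.null(children))
    children <- sprintf("c%02d", seq_len(G))
  if (is.null(V)) V <- c(G, G)
  if (length(V) == 1) V <- c(V, V)
  scores <- data.frame(classroom = as.character(classroom), child = children,
                       pnr = as.integer(pnr), nnr = as.integer(nnr),
                       stringsAsFactors = FALSE)
  stats <- data.frame(
    classroom = as.character(classroom), G = G, V = max(V),
    V_pos = V[1], V_neg = V[2],
    m_pnr = mean(pnr), m_nnr = mean(nnr),
    sd_pnr = sd_pop(pnr), sd_nnr = sd_pop(nnr),
    vc_pnr = if (mean(pnr) > 0) sd_pop(pnr) / mean(pnr) else NA_real_,
    vc_nnr = if (mean(nnr) > 0) sd_pop(nnr) / mean(nnr) else NA_real_,
    expansiveness_pos = if (V[1] > 0) sum(pnr) / V[1] else NA_real_,
    expansiveness_neg = if (V[2] > 0) sum(nnr) / V[2] else NA_real_,
    nomination_limit = limit, stringsAsFactors = FALSE)
  structure(scores, stats = stats, class = c("classroom_scores", "data.frame"))
}

#' Standardize behaviour scores within classrooms
#'
#' Converts raw behaviour frequencies (aggression, withdrawal, likeability)
#' to z-scores within each classroom, using the population SD.  A scale with
#' zero variance in some classroom cannot be standardized and raises an
#' error naming the scale and classroom.
#'
#' @param behavior data.frame with columns `classroom`, `child` and one or
#'   more numeric scale columns.
#' @param scales scale column names; defaults to every column other than
#'   `classroom`/`child`.
#' @return data.frame of the same shape with scales replaced by
#'   within-classroom z-scores.
#' @export
standardize_behavior <- function(behavior, scales = NULL) {
  behavior <- as.data.frame(behavior)
  if (!all(c("classroom", "child") %in% names(behavior)))
    stop("behavior table needs columns classroom, child")
  if (is.null(scales))
    scales <- setdiff(names(behavior), c("classroom", "child"))
  out <- behavior
  for (cl in unique(behavior$classroom)) {
    idx <- behavior$classroom == cl
    if (sum(idx) < 2)
      stop("classroom '", cl, "' has fewer than 2 children")
    for (sc in scales) {
      v <- behavior[[sc]][idx]
      s <- sd_pop(v)
      if (!is.finite(s) || s == 0)
        stop("zero variance on scale '", sc, "' in classroom '", cl,
             "': cannot standardize")
      out[[sc]][idx] <- (v - mean(v)) / s
    }
  }
  out
}
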