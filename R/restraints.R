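#' Construct a restraint set
#'
#' A restraint set is an ordered table of NOE distance restraints, each
#' pairing two atom selections (possibly pseudoatom wildcards ending in
#' `#`) with a lower and upper distance bound in Angstrom.
#'
#' @param resid_a,resid_b residue numbers (author numbering, 1-based).
#' @param name_a,name_b atom names; a trailing `#` marks a pseudoatom
#'   wildcard standing for a group of equivalent hydrogens.
#' @param lower,upper distance bounds in Angstrom, `0 <= lower <= upper`.
#' @param id integer restraint ids; defaults to file order.
#' @param sel_a,sel_b verbatim selection strings (kept for exact
#'   round-tripping of CNS files); synthesised when missing.
#' @param label one of `"full"`, `"reduced"`, `"random"`, `"custom"`.
#' @return A data frame of class `restraint_set` with one row per
#'   restraint and a `label` attribute.
#' @export
restraint_set <- function(resid_a, name_a, resid_b, name_b, lower, upper,
                          id = seq_along(resid_a), sel_a = NULL,
                          sel_b = NULL, label = "custom") {
  n <- length(resid_a)
  stopifnot(length(name_a) == n, length(resid_b) == n, length(name_b) == n,
            length(lower) == n, length(upper) == n, length(id) == n)
  if (n > 0) {
    if (anyDuplicated(id)) stop("restraint ids must be unique")
    if (any(resid_a < 1) || any(resid_b < 1))
      stop("residue numbers must be >= 1")
    if (any(!nzchar(name_a)) || any(!nzchar(name_b)))
      stop("atom names must be non-empty")
    if (any(lower < 0)) stop("lower bounds must be >= 0")
    if (any(lower > upper)) stop("lower bound exceeds upper bound")
    same <- resid_a == resid_b & name_a == name_b
    if (any(same))
      stop("restraint between a selection and itself (id ",
           paste(id[same], collapse = ", "), ")")
  }
  if (is.null(sel_a)) sel_a <- sprintf("resid %d and name %s", resid_a, name_a)
  if (is.null(sel_b)) sel_b <- sprintf("resid %d and name %s", resid_b, name_b)
  out <- data.frame(id = as.integer(id), resid_a = as.integer(resid_a),
                    name_a = as.character(name_a),
                    resid_b = as.integer(resid_b),
                    name_b = as.character(name_b),
                    lower = as.numeric(lower), upper = as.numeric(upper),
                    sel_a = as.character(sel_a), sel_b = as.character(sel_b),
                    stringsAsFactors = FALSE)
  structure(out, class = c("restraint_set", "data.frame"),
            label = match.arg(label, c("full", "reduced", "random", "custom")))
}

#' @export
print.restraint_set <- function(x, ...) {
  cat(sprintf("Restraint set '%s': %d restraints\n",
              attr(x, "label"), nrow(x)))
  if (nrow(x) > 0) print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("...\n")
  invisible(x)
}

relabel_set <- function(set, label) {
  attr(set, "label") <- label
  set
}

extract_sel_field <- function(sel, pattern) {
  m <- regmatches(sel, regexec(pattern, sel, ignore.case = TRUE))
  vapply(m, function(g) if (length(g) >= 2) g[2] else NA_character_, "")
}

#' Parse a distance-restraint file
#'
#' Reads NOE distance restraints either from an X-PLOR/CNS `assign`
#' block (`dialect = "cns"`) or from a simple tab-separated table
#' (`dialect = "tsv"`, columns `id, resid_a, name_a, resid_b, name_b,
#' lower, upper`).
#'
#' CNS `assign (selA)(selB) d dminus dplus` statements follow the
#' standard X-PLOR NOE convention: `lower = d - dminus`,
#' `upper = d + dplus`. A negative computed lower bound is clamped to 0
#' with a warning. Selection strings are preserved verbatim, including
#' pseudoatom `#` wildcards; only the first `resid`/`name` token of each
#' side is used as the restraint partner identity (ambiguous OR groups
#' collapse to their first member).
#'
#' @param text character: the file content (single string or lines).
#' @param dialect `"cns"` or `"tsv"`.
#' @param label label for the returned set (default `"full"`).
#' @return A [restraint_set()].
#' @export
parse_mr <- function(text, dialect = c("cns", "tsv"), label = "full") {
  dialect <- match.arg(dialect)
  if (length(text) > 1) text <- paste(text, collapse = "\n")
  if (dialect == "tsv") return(parse_mr_tsv(text, label))

  # strip CNS comments
  body <- gsub("!.*?(\n|$)", "\\1", text)
  starts <- gregexpr("(?i)\\bassign\\b", body, perl = TRUE)[[1]]
  if (starts[1] == -1)
    return(restraint_set(integer(0), character(0), integer(0), character(0),
                         numeric(0), numeric(0), label = label))
  ends <- c(starts[-1] - 1, nchar(body))
  stmts <- substring(body, starts, ends)
  lineno <- vapply(starts, function(s)
    1L + lengths(regmatches(substr(body, 1, s), gregexpr("\n", substr(body, 1, s)))),
    1L)

  pat <- paste0("(?is)^assign\\s*\\((.*?)\\)\\s*\\((.*?)\\)\\s*",
                "([-0-9.eE+]+)\\s+([-0-9.eE+]+)\\s+([-0-9.eE+]+)")
  fields <- regmatches(stmts, regexec(pat, stmts, perl = TRUE))
  bad <- which(lengths(fields) < 6)
  if (length(bad) > 0)
    stop("malformed assign statement at line ", lineno[bad[1]], ": ",
         trimws(substr(stmts[bad[1]], 1, 60)))

  sel_a <- trimws(vapply(fields, `[`, "", 2))
  sel_b <- trimws(vapply(fields, `[`, "", 3))
  d <- as.numeric(vapply(fields, `[`, "", 4))
  dminus <- as.numeric(vapply(fields, `[`, "", 5))
  dplus <- as.numeric(vapply(fields, `[`, "", 6))

  resid_a <- as.integer(extract_sel_field(sel_a, "resid(?:ue)?\\s+(\\d+)"))
  resid_b <- as.integer(extract_sel_field(sel_b, "resid(?:ue)?\\s+(\\d+)"))
  name_a <- extract_sel_field(sel_a, "name\\s+([^\\s)]+)")
  name_b <- extract_sel_field(sel_b, "name\\s+([^\\s)]+)")
  miss <- which(is.na(resid_a) | is.na(resid_b) | is.na(name_a) | is.na(name_b))
  if (length(miss) > 0)
    stop("malformed assign statement at line ", lineno[miss[1]],
         ": cannot extract resid/name from selection")

  lower <- d - dminus
  upper <- d + dplus
  if (any(lower < 0)) {
    warning(sum(lower < 0), " restraint(s) with negative computed lower ",
            "bound clamped to 0")
    lower[lower < 0] <- 0
  }
  restraint_set(resid_a, toupper(name_a), resid_b, toupper(name_b),
                lower, upper, sel_a = sel_a, sel_b = sel_b, label = label)
}

parse_mr_tsv <- function(text, label) {
  con <- textConnection(text)
  on.exit(close(con))
  df <- utils::read.table(con, header = TRUE, sep = "\t",
                          comment.char = "",  # '#' is a pseudoatom mark
                          stringsAsFactors = FALSE)
  need <- c("id", "resid_a", "name_a", "resid_b", "name_b", "lower", "upper")
  if (!all(need %in% names(df)))
    stop("tsv restraint table must have columns: ",
         paste(need, collapse = ", "))
  restraint_set(df$resid_a, df$name_a, df$resid_b, df$name_b,
                df$lower, df$upper, id = df$id, label = label)
}

#' Read a restraint file from disk
#'
#' @param file path to a `.mr` (CNS) or `.tsv` restraint file.
#' @inheritParams parse_mr
#' @return A [restraint_set()].
#' @export
read_restraints <- function(file, dialect = c("cns", "tsv"), label = "full") {
  parse_mr(readLines(file, warn = FALSE), dialect = dialect, label = label)
}

#' Write a restraint set
#'
#' Serialises a restraint set so that `parse_mr(write_mr(set))`
#' reproduces bounds to 3 decimals and selection text exactly. In the
#' CNS dialect bounds are written as `d dminus dplus` with
#' `d = (lower + upper) / 2` and symmetric margins.
#'
#' @param set a [restraint_set()].
#' @param dialect `"cns"` or `"tsv"`.
#' @param file optional path; when given the text is also written there.
#' @return The serialised text, invisibly when `file` is given.
#' @export
write_mr <- function(set, dialect = c("cns", "tsv"), file = NULL) {
  dialect <- match.arg(dialect)
  if (dialect == "cns") {
    header <- sprintf("! NOE distance restraints (%d, set '%s')",
                      nrow(set), attr(set, "label"))
    if (nrow(set) == 0) {
      txt <- paste0(header, "\n")
    } else {
      d <- (set$lower + set$upper) / 2
      half <- (set$upper - set$lower) / 2
      lines <- sprintf("assign (%s)(%s) %.3f %.3f %.3f",
                       set$sel_a, set$sel_b, d, half, half)
      txt <- paste(c(header, lines, ""), collapse = "\n")
    }
  } else {
    df <- as.data.frame(set)[, c("id", "resid_a", "name_a", "resid_b",
                                 "name_b", "lower", "upper")]
    df$lower <- sprintf("%.3f", df$lower)
    df$upper <- sprintf("%.3f", df$upper)
    con <- textConnection("txt", "w", local = TRUE)
    utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
    close(con)
    txt <- paste(c(txt, ""), collapse = "\n")
  }
  if (!is.null(file)) {
    writeLines(txt, file, sep = "")
    return(invisible(txt))
  }
  txt
}

#' Build the reduced restraint set
#'
#' Discards the `k` least redundant restraints, i.e. those with the
#' largest unique-information values, from a set. Ties at the k-th
#' largest value are broken by removing the restraint with the smaller
#' id first.
#'
#' @param set a [restraint_set()].
#' @param info an [information_table] covering every restraint in `set`
#'   (see [rank_restraints()]).
#' @param k number of restraints to discard (default 9).
#' @return The surviving restraints, labelled `"reduced"`; bounds are
#'   untouched.
#' @export
make_reduced_set <- function(set, info, k = 9L) {
  k <- as.integer(k)
  if (k >= nrow(set))
    stop("k (", k, ") must be smaller than the set size (", nrow(set), ")")
  if (!all(set$id %in% info$id))
    stop("information table does not cover every restraint in the set")
  if (k == 0) return(relabel_set(set, "reduced"))
  info <- info[match(set$id, info$id), ]
  drop_ids <- info$id[order(-info$i_uni, info$id)][seq_len(k)]
  relabel_set(set[!(set$id %in% drop_ids), , drop = FALSE], "reduced")
}

#' Build a randomly reduced restraint set
#'
#' Discards `k` restraints sampled uniformly without replacement from
#' those whose unique information lies inside `info_range` (by default
#' the low-information window 0 to 0.01).
#'
#' @inheritParams make_reduced_set
#' @param info_range closed interval of eligible unique-information
#'   values.
#' @param seed integer seed; the same seed always removes the same
#'   restraints. The global RNG state is left untouched.
#' @return The surviving restraints, labelled `"random"`.
#' @export
make_random_set <- function(set, info, k = 9L, info_range = c(0, 0.01),
                            seed) {
  k <- as.integer(k)
  if (k >= nrow(set))
    stop("k (", k, ") must be smaller than the set size (", nrow(set), ")")
  if (!all(set$id %in% info$id))
    stop("information table does not cover every restraint in the set")
  info <- info[match(set$id, info$id), ]
  eligible <- info$id[info$i_uni >= info_range[1] &
                      info$i_uni <= info_range[2]]
  if (length(eligible) < k)
    stop("only ", length(eligible), " restraints have unique information ",
         "in [", info_range[1], ", ", info_range[2], "]; need ", k)
  drop_ids <- with_seed(seed, sample(eligible, k))
  relabel_set(set[!(set$id %in% drop_ids), , drop = FALSE], "random")
}

# Run expr under a temporary RNG seed, restoring the global state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}
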