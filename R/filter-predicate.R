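# Boolean filter language over (interaction type, residue) clauses, e.g.
#   PI_PI@TYR56 | HBOND@{ASP122, LYS124, ARG125}
# Grammar: expr := term (('|'|OR) term)* ; term := factor (('&'|AND) factor)*
#          factor := ('!'|NOT) factor | '(' expr ')' | clause
#          clause := TYPE '@' res | TYPE '@{' res (',' res)* '}'
# A residue spec is a residue name with an optional number (TYR56, ASP);
# names match on any chain (key pocket residues exist on both chains of the
# PDL1 dimer). HBOND matches both HBOND_DONOR and HBOND_ACCEPTOR.

#' Parse a key-residue filter predicate
#'
#' @param text Predicate string (see Details in [apply_filter()]).
#' @return A parsed predicate of class `sift_predicate`.
#' @examples
#' parse_predicate("PI_PI@TYR56 | HBOND@{ASP122,LYS124,ARG125}")
#' @export
parse_predicate <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  tokens <- tokenize_predicate(text)
  state <- new.env(parent = emptyenv())
  state$toks <- tokens
  state$pos <- 1L
  node <- parse_or(state)
  if (state$pos <= length(state$toks)) {
    abort(paste0("unexpected token '", state$toks[state$pos],
                 "' in predicate: ", text))
  }
  structure(node, class = "sift_predicate", text = text)
}

tokenize_predicate <- function(text) {
  pat <- "\\{[^}]*\\}|[A-Za-z_][A-Za-z0-9_]*|@|\\(|\\)|\\||&|!|,"
  toks <- unlist(stringr::str_extract_all(text, pat))
  if (length(toks) == 0) abort("empty predicate")
  toks
}

peek <- function(s) if (s$pos <= length(s$toks)) s$toks[s$pos] else NA_character_
eat <- function(s) { t <- peek(s); s$pos <- s$pos + 1L; t }

parse_or <- function(s) {
  left <- parse_and(s)
  args <- list(left)
  while (!is.na(peek(s)) && toupper(peek(s)) %in% c("|", "OR")) {
    eat(s)
    args[[length(args) + 1]] <- parse_and(s)
  }
  if (length(args) == 1) left else list(op = "or", args = args)
}

parse_and <- function(s) {
  left <- parse_not(s)
  args <- list(left)
  while (!is.na(peek(s)) && toupper(peek(s)) %in% c("&", "AND")) {
    eat(s)
    args[[length(args) + 1]] <- parse_not(s)
  }
  if (length(args) == 1) left else list(op = "and", args = args)
}

parse_not <- function(s) {
  if (!is.na(peek(s)) && toupper(peek(s)) %in% c("!", "NOT")) {
    eat(s)
    return(list(op = "not", args = list(parse_not(s))))
  }
  parse_atom(s)
}

parse_atom <- function(s) {
  t <- peek(s)
  if (is.na(t)) abort("predicate ended unexpectedly")
  if (t == "(") {
    eat(s)
    node <- parse_or(s)
    if (!identical(eat(s), ")")) abort("missing ')' in predicate")
    return(node)
  }
  type <- toupper(eat(s))
  known <- c(.interaction_types, "HBOND")
  if (!type %in% known) {
    abort(paste0("unknown interaction type '", type, "'; known: ",
                 paste(known, collapse = ", ")))
  }
  if (!identical(eat(s), "@")) abort("expected '@' after interaction type")
  spec <- eat(s)
  if (is.na(spec)) abort("expected residue spec after '@'")
  raw <- if (startsWith(spec, "{")) {
    unlist(strsplit(gsub("[{}]", "", spec), ","))
  } else spec
  raw <- toupper(trimws(raw))
  raw <- raw[nzchar(raw)]
  if (length(raw) == 0) abort("empty residue list in predicate")
  m <- stringr::str_match(raw, "^([A-Z]{1,3})([0-9]*)$")
  if (any(is.na(m[, 1]))) {
    abort(paste0("bad residue spec: ", paste(raw[is.na(m[, 1])], collapse = ", ")))
  }
  list(op = "clause", type = type,
       residues = tibble(resname = m[, 2],
                         resnum = ifelse(nzchar(m[, 3]),
                                         as.integer(m[, 3]), NA_integer_)))
}

#' @export
print.sift_predicate <- function(x, ...) {
  cat("<sift_predicate>", attr(x, "text"), "\n")
  invisible(x)
}

clause_matches <- function(clause, sift) {
  types <- if (clause$type == "HBOND") c("HBOND_DONOR", "HBOND_ACCEPTOR")
           else clause$type
  rows <- sift[sift$interaction %in% types & sift$count >= 1, , drop = FALSE]
  if (nrow(rows) == 0) return(FALSE)
  any(vapply(seq_len(nrow(clause$residues)), function(i) {
    r <- clause$residues[i, ]
    hit <- rows$resname == r$resname
    if (!is.na(r$resnum)) hit <- hit & rows$resnum == r$resnum
    any(hit)
  }, logical(1)))
}

clause_text <- function(clause) {
  res <- ifelse(is.na(clause$residues$resnum), clause$residues$resname,
                paste0(clause$residues$resname, clause$residues$resnum))
  paste0(clause$type, "@",
         if (length(res) > 1) paste0("{", paste(res, collapse = ","), "}")
         else res)
}

eval_predicate <- function(node, sift, audit) {
  if (identical(node$op, "clause")) {
    sat <- clause_matches(node, sift)
    audit$rows[[length(audit$rows) + 1]] <- tibble(
      clause = clause_text(node), satisfied = sat
    )
    return(sat)
  }
  vals <- vapply(node$args, eval_predicate, logical(1),
                 sift = sift, audit = audit)
  switch(node$op, or = any(vals), and = all(vals), not = !vals[1])
}

#' Apply a key-residue filter predicate to a SIFt matrix
#'
#' Evaluates a boolean expression over (interaction type, residue) clauses
#' against a per-residue interaction table. A clause `TYPE@RES` is satisfied
#' when the matrix holds at least one contact of that type on a matching
#' residue (residue name matches on any chain; appending a number restricts
#' to that residue number). `HBOND` matches donor and acceptor
#' contributions alike.
#'
#' @param sift A `sift_tbl` from [detect_interactions()].
#' @param predicate A string or a [parse_predicate()] object.
#' @return Logical scalar with attribute `matched`, a tibble of the clauses
#'   evaluated and whether each was satisfied.
#' @examples
#' \donttest{
#' sift <- tibble::tibble(chain = "A", resnum = 122, resname = "ASP",
#'                        interaction = "HBOND_DONOR", count = 1L)
#' apply_filter(sift, "HBOND@{ASP122,LYS124,ARG125}")
#' }
#' @export
apply_filter <- function(sift, predicate) {
  if (is.character(predicate)) predicate <- parse_predicate(predicate)
  stopifnot(inherits(predicate, "sift_predicate"))
  audit <- new.env(parent = emptyenv())
  audit$rows <- list()
  pass <- eval_predicate(unclass(predicate), sift, audit)
  structure(pass, matched = bind_rows(audit$rows))
}

#' Shortlist docking poses by interaction filter and score
#'
#' Keeps poses whose SIFt matrix satisfies the predicate, ranks them by
#' best docking score (ascending, i.e. strongest binding first) with id as
#' tie-break, and truncates to the top `n`. Every returned pose carries a
#' `needs_review` flag: the final visual inspection of binding modes is a
#' human step this package does not automate.
#'
#' @param results Tibble with columns `id`, `best_score` and `sift` (a
#'   list-column of `sift_tbl` objects).
#' @param predicate Filter predicate (string or parsed).
#' @param n Maximum shortlist size.
#' @return Tibble `id`, `best_score`, `passes`, `needs_review`, truncated
#'   to `n` rows.
#' @export
shortlist_poses <- function(results, predicate, n = 20) {
  stopifnot(n >= 1, all(c("id", "best_score", "sift") %in% names(results)))
  if (is.character(predicate)) predicate <- parse_predicate(predicate)
  results$passes <- map_lgl(results$sift, ~ as.logical(apply_filter(.x, predicate)))
  out <- results %>%
    filter(.data$passes) %>%
    arrange(.data$best_score, .data$id) %>%
    head(n) %>%
    select(-"sift")
  out$needs_review <- "needs-review"
  out
}
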