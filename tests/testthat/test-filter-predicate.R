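sift_row <- function(resname, resnum, interaction, count = 1L, chain = "A") {
  tibble::tibble(chain = chain, resnum = as.integer(resnum),
                 resname = resname, interaction = interaction,
                 count = as.integer(count))
}

test_that("key-residue clauses match the documented pocket predicate", {
  pred <- parse_predicate("PI_PI@TYR56 | HBOND@{ASP122,LYS124,ARG125}")
  # a single hydrogen bond at Asp122 satisfies the OR
  s1 <- sift_row("ASP", 122, "HBOND_DONOR")
  expect_true(as.logical(apply_filter(s1, pred)))
  # acceptor-side H-bonds count as HBOND too
  s2 <- sift_row("LYS", 124, "HBOND_ACCEPTOR")
  expect_true(as.logical(apply_filter(s2, pred)))
  # stacking on Tyr56 on any chain
  s3 <- sift_row("TYR", 56, "PI_PI", chain = "B")
  expect_true(as.logical(apply_filter(s3, pred)))
  # wrong residue number fails
  s4 <- sift_row("TYR", 123, "PI_PI")
  expect_false(as.logical(apply_filter(s4, pred)))
  # empty matrix fails any non-trivial predicate
  empty <- sift_row("X", 1, "IONIC")[0, ]
  expect_false(as.logical(apply_filter(empty, pred)))
  # audit trail reports both clauses
  m <- attr(apply_filter(s1, pred), "matched")
  expect_equal(nrow(m), 2)
  expect_true(m$satisfied[m$clause == "HBOND@{ASP122,LYS124,ARG125}"])
})

test_that("predicate parsing validates interaction types and syntax", {
  expect_error(parse_predicate("MAGIC@TYR56"), "unknown interaction")
  expect_error(parse_predicate("PI_PI@"), "residue")
  expect_error(parse_predicate("(PI_PI@TYR56"), "\\)")
  expect_s3_class(parse_predicate("!HBOND@ASP & (PI_PI@TYR | IONIC@LYS124)"),
                  "sift_predicate")
  # residue name without a number matches any residue of that name
  pred <- parse_predicate("HBOND@ASP")
  expect_true(as.logical(apply_filter(sift_row("ASP", 9, "HBOND_DONOR"), pred)))
})

test_that("boolean evaluation equals a truth-table oracle", {
  set.seed(8)
  combos <- expand.grid(a = c(TRUE, FALSE), b = c(TRUE, FALSE),
                        c = c(TRUE, FALSE))
  exprs <- list(
    list(text = "PI_PI@TYR56 | HBOND@ASP122 & IONIC@LYS124",
         f = function(a, b, c) a | (b & c)),
    list(text = "(PI_PI@TYR56 | HBOND@ASP122) & !IONIC@LYS124",
         f = function(a, b, c) (a | b) & !c),
    list(text = "!(PI_PI@TYR56 & HBOND@ASP122) | IONIC@LYS124",
         f = function(a, b, c) !(a & b) | c)
  )
  for (e in exprs) {
    pred <- parse_predicate(e$text)
    for (r in seq_len(nrow(combos))) {
      s <- dplyr::bind_rows(
        if (combos$a[r]) sift_row("TYR", 56, "PI_PI"),
        if (combos$b[r]) sift_row("ASP", 122, "HBOND_DONOR"),
        if (combos$c[r]) sift_row("LYS", 124, "IONIC")
      )
      if (is.null(s) || nrow(s) == 0) s <- sift_row("X", 1, "PI_PI")[0, ]
      expect_equal(as.logical(apply_filter(s, pred)),
                   e$f(combos$a[r], combos$b[r], combos$c[r]),
                   info = paste(e$text, r))
    }
  }
})

test_that("shortlisting filters, ranks by score and truncates", {
  set.seed(13)
  n <- 361
  passing <- sort(sample(n, 25))
  results <- tibble::tibble(
    id = sprintf("hit%03d", 1:n),
    best_score = round(runif(n, -12, -6), 1),
    sift = lapply(1:n, function(i) {
      if (i %in% passing) sift_row("TYR", 56, "PI_PI")
      else sift_row("GLY", 10, "HYDROPHOBIC")
    })
  )
  top <- shortlist_poses(results, "PI_PI@TYR56", n = 20)
  expect_equal(nrow(top), 20)
  expect_true(all(top$id %in% results$id[passing]))
  # re-sort oracle: score ascending, id tie-break
  expect_identical(top$id, top$id[order(top$best_score, top$id)])
  expect_true(all(top$needs_review == "needs-review"))
  # the strongest-scoring passing pose leads the shortlist
  pass_tbl <- results[passing, ]
  best <- pass_tbl[order(pass_tbl$best_score, pass_tbl$id), ]
  expect_equal(top$id[1], best$id[1])
  # n larger than the passing set returns all passing poses
  all_pass <- shortlist_poses(results, "PI_PI@TYR56", n = 100)
  expect_equal(nrow(all_pass), 25)
})
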