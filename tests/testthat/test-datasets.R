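test_that("read_library handles valid and malformed records", {
  smi <- tempfile(fileext = ".smi")
  writeLines(c("CCO eth", "c1ccccc1 benz", "CC(=O)O acet"), smi)
  tbl <- read_library(smi)
  expect_equal(nrow(tbl), 3)
  expect_equal(tbl$id, c("eth", "benz", "acet"))
  expect_equal(attr(tbl, "n_dropped"), 0L)

  csv <- tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(
    id = c("a", "b", "c"),
    smiles = c("CCO", "C1CC", "CCN"),  # unclosed ring in record b
    label = c("ACTIVE", "INACTIVE", NA),
    potency_nM = c(12, NA, NA)
  ), csv)
  expect_warning(tbl2 <- read_library(csv), "unparseable")
  expect_equal(nrow(tbl2), 2)
  expect_equal(attr(tbl2, "n_dropped"), 1L)
  expect_equal(tbl2$label, c("ACTIVE", "UNLABELED"))
  expect_equal(tbl2$potency_nM[1], 12)

  expect_error(read_library(tempfile()), "not found")
  bad <- tempfile(fileext = ".smi")
  writeLines("C1CC onlybad", bad)
  expect_error(suppressWarnings(read_library(bad)), "no parseable")
})

test_that("duplicate ids are suffixed deterministically", {
  smi <- tempfile(fileext = ".smi")
  writeLines(c("CCO m", "CCN m", "CCC m"), smi)
  expect_warning(tbl <- read_library(smi), "duplicate")
  expect_equal(tbl$id, c("m", "m_2", "m_3"))
})

test_that("write_library / read_library round-trips id, smiles and label", {
  mols <- tibble::tibble(
    id = c("x1", "x2"), smiles = c("CCO", "c1ccccc1"),
    label = c("ACTIVE", "DECOY"), potency_nM = c(5.5, NA)
  )
  p <- tempfile(fileext = ".csv")
  write_library(mols, p)
  back <- read_library(p)
  expect_equal(back$id, mols$id)
  expect_equal(back$smiles, mols$smiles)
  expect_equal(back$label, mols$label)
  expect_equal(back$potency_nM, mols$potency_nM)
})

test_that("computed properties match hand counts on reference molecules", {
  mols <- tibble::tibble(
    id = c("methane", "ethanol", "acetate", "butane"),
    smiles = c("C", "CCO", "CC(=O)[O-]", "CCCC")
  )
  pr <- compute_properties(mols)
  expect_true(all(pr$prop_ok))
  # methane: no donors, acceptors, rotors or charge
  expect_equal(pr$hbd[1], 0L)
  expect_equal(pr$hba[1], 0L)
  expect_equal(pr$rotb[1], 0L)
  expect_equal(pr$charge[1], 0L)
  # ethanol: one O-H donor on the graph, neutral
  expect_equal(pr$hbd[2], 1L)
  expect_equal(pr$charge[2], 0L)
  # acetate anion: formal-charge sum -1
  expect_equal(pr$charge[3], -1L)
  # butane: one rotatable C-C bond (central), MW ~58
  expect_equal(pr$rotb[4], 1L)
  expect_equal(pr$mw[4], 58.12, tolerance = 0.01)
})

fake_props <- function(id, mw, clogp = 2, hbd = 1, hba = 2, rotb = 3,
                       charge = 0) {
  tibble::tibble(
    id = id, smiles = paste0("SMI_", id), label = "UNLABELED",
    potency_nM = NA_real_, mw = mw, clogp = clogp, hbd = hbd, hba = hba,
    rotb = rotb, charge = charge, cansmi = paste0("SMI_", id),
    prop_ok = TRUE
  )
}

test_that("match_decoys selects within windows, greedily, without leakage", {
  act <- fake_props("A1", mw = 300)
  pool <- fake_props(sprintf("P%02d", 1:10),
                     mw = c(301, 310, 324, 326, 350, 280, 299, 400, 500, 260))
  # windows: mw +/- 25 -> inside: 301,310,324,299,280 and 326? no (26 away)
  dec <- suppressWarnings(match_decoys(act, pool, k = 50))
  inside <- abs(pool$mw - 300) <= 25
  expect_setequal(dec$id, pool$id[inside])
  expect_true(all(dec$label == "DECOY"))

  # exactly 3 inside with brute-force recheck of every selected decoy
  pool2 <- fake_props(sprintf("Q%02d", 1:10),
                      mw = c(300, 310, 320, 330, 340, 350, 360, 370, 380, 390))
  dec2 <- suppressWarnings(match_decoys(act, pool2, k = 50))
  w <- decoy_windows()
  for (i in seq_len(nrow(dec2))) {
    for (p in names(w)) {
      expect_lte(abs(dec2[[p]][i] - act[[p]][1]), w[[p]])
    }
  }
  expect_equal(nrow(dec2), 3)

  # self-match exclusion: pool identical to actives, zero windows
  act3 <- fake_props(c("A1", "A2"), mw = c(100, 200))
  pool3 <- act3
  pool3$id <- c("B1", "B2")
  suppressWarnings(expect_warning(
    dec3 <- match_decoys(act3, pool3, k = 1, windows = decoy_windows() * 0),
    "identical to an active"
  ))
  expect_equal(nrow(dec3), 0)
})

test_that("match_decoys obeys k, assigns each decoy once, monotone in windows", {
  set.seed(11)
  act <- fake_props(sprintf("A%02d", 1:5), mw = runif(5, 250, 350))
  pool <- fake_props(sprintf("P%03d", 1:200), mw = runif(200, 200, 400))
  for (k in c(1, 3, 10)) {
    dec <- suppressWarnings(match_decoys(act, pool, k = k))
    expect_lte(nrow(dec), k * nrow(act))
    expect_false(any(duplicated(dec$id)))
    # brute-force window recheck (oracle equivalence on small pools)
    w <- decoy_windows()
    for (i in seq_len(nrow(dec))) {
      a <- act[act$id == dec$matched_active[i], ]
      ok <- all(vapply(names(w), function(p) {
        if (w[[p]] == 0) dec[[p]][i] == a[[p]] else
          abs(dec[[p]][i] - a[[p]]) <= w[[p]]
      }, logical(1)))
      expect_true(ok)
    }
  }
  # widening every window never shrinks the selection
  n_narrow <- nrow(suppressWarnings(
    match_decoys(act, pool, k = 50, windows = decoy_windows() * 0.5)
  ))
  n_wide <- nrow(suppressWarnings(
    match_decoys(act, pool, k = 50, windows = decoy_windows() * 2)
  ))
  expect_gte(n_wide, n_narrow)
  expect_error(match_decoys(act, pool[0, ], k = 1), "empty")
})

test_that("screening-scale SMI library loads with full record count", {
  base <- small_fx()$library$smiles
  n <- 16191
  smi <- tempfile(fileext = ".smi")
  writeLines(paste(rep_len(base, n), sprintf("cay%05d", seq_len(n))), smi)
  tbl <- read_library(smi)
  expect_equal(nrow(tbl), n)
})

test_that("split_corpus keeps train and test disjoint with paper composition", {
  fx <- small_fx()
  sp <- fx$split
  expect_length(intersect(sp$train$id, sp$test$id), 0)
  expect_setequal(unique(sp$train$label), c("ACTIVE", "INACTIVE"))
  expect_setequal(unique(sp$test$label), c("ACTIVE", "DECOY"))
})
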