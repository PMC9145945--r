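test_that("corpus generation is deterministic and scaffold-faithful", {
  spec <- fixture_spec(n_actives = 40, n_inactives = 12, n_decoy_pool = 200,
                       decoys_per_active = 2, n_library = 40, n_planted = 5)
  fx1 <- suppressWarnings(gen_corpus(spec))
  fx2 <- suppressWarnings(gen_corpus(spec))
  expect_identical(fx1$corpus, fx2$corpus)
  expect_identical(fx1$library, fx2$library)
  expect_identical(fx1$planted_ids, fx2$planted_ids)

  # substructure oracle: every active (and planted library hit) carries the
  # scaffold; no inactive, decoy or background molecule does
  scaffold <- spec$scaffold
  has_scaffold <- function(smiles) {
    sdf <- suppressWarnings(ChemmineR::smiles2sdf(
      setNames(smiles, paste0("m", seq_along(smiles)))
    ))
    unname(ChemmineR::smartsSearchOB(sdf, scaffold) > 0)
  }
  act <- fx1$corpus$smiles[fx1$corpus$label == "ACTIVE"]
  expect_true(all(has_scaffold(act)))
  planted <- fx1$library$smiles[fx1$library$id %in% fx1$planted_ids]
  expect_true(all(has_scaffold(planted)))
  neg <- fx1$corpus$smiles[fx1$corpus$label != "ACTIVE"]
  expect_false(any(has_scaffold(neg)))
  bg <- fx1$library$smiles[!fx1$library$id %in% fx1$planted_ids]
  expect_false(any(has_scaffold(bg)))
  expect_error(gen_corpus(fixture_spec(scaffold = "C1CC")), "parse")
})

test_that("default corpus mirrors the campaign class imbalance", {
  spec <- fixture_spec()
  expect_equal(spec$n_actives / spec$n_inactives, 1581 / 417, tolerance = 0.05)
  expect_equal(spec$seed, 20220516)
})

test_that("all generated molecules re-parse through the package readers", {
  fx <- small_fx()
  p <- tempfile(fileext = ".csv")
  write_library(fx$corpus, p)
  back <- read_library(p)
  expect_equal(nrow(back), nrow(fx$corpus))
  expect_equal(attr(back, "n_dropped"), 0L)

  lib <- tempfile(fileext = ".smi")
  write_library(fx$library, lib)
  expect_equal(nrow(read_library(lib)), nrow(fx$library))
})

test_that("complex recipes honour distances and angles exactly", {
  g <- gen_complex("HBOND", distance = 3.2, angle = 150)
  don <- g$cpx$ligand[g$cpx$ligand$donor, ]
  od1 <- g$cpx$protein[g$cpx$protein$elety == "OD1", ]
  d <- sqrt((don$x - od1$x)^2 + (don$y - od1$y)^2 + (don$z - od1$z)^2)
  expect_equal(d, 3.2, tolerance = 1e-6)
  h <- don$explicit_h[[1]]
  ang <- pdlscreen:::angle_deg(c(don$x, don$y, don$z), h[1, ],
                               c(od1$x, od1$y, od1$z))
  expect_equal(ang, 150, tolerance = 0.1)
  s <- detect_interactions(g$cpx)
  expect_equal(s$interaction, "HBOND_DONOR")
  expect_error(gen_complex("HBOND", distance = -1), "positive")
})

test_that("trajectory modes follow their closed forms", {
  cpx <- gen_complex("HBOND")$cpx
  static <- gen_trajectory(cpx, 100, mode = "static")
  expect_true(all(compute_rmsd(static, "ligand", superpose = FALSE)$rmsd_A == 0))

  detach <- gen_trajectory(cpx, 100, mode = "detach", amplitude = 0.1)
  raw <- compute_rmsd(detach, "ligand", superpose = FALSE)$rmsd_A
  expect_equal(raw[100], 99 * 0.1, tolerance = 1e-9)
  expect_true(all(diff(raw) > 0))

  set.seed(1)
  d1 <- gen_trajectory(cpx, 60, mode = "drift", amplitude = 0.02, seed = 9)
  d2 <- gen_trajectory(cpx, 60, mode = "drift", amplitude = 0.6, seed = 9)
  p1 <- compute_persistence(d1)
  p2 <- compute_persistence(d2)
  v1 <- sum(p1$persistence[p1$category == "HBOND"])
  v2 <- sum(p2$persistence[p2$category == "HBOND"])
  expect_gt(v1, v2) # larger drift amplitude erodes the planted contact
  # determinism
  d1b <- gen_trajectory(cpx, 60, mode = "drift", amplitude = 0.02, seed = 9)
  expect_identical(d1$xyz, d1b$xyz)
})

test_that("synthetic plates reproduce their generating curve on average", {
  plate <- gen_plate(c(x = 25), noise_frac = 0.01, replicates = 6, seed = 2)
  pi <- percent_inhibition(plate)
  truth <- 100 / (1 + (25 / pi$concentration_uM))
  expect_lt(max(abs(pi$pct_inhibition - truth)), 3)
})

test_that("the full funnel runs end to end on generated fixtures", {
  fx <- small_fx()
  hits <- consensus_screen(small_model(), fx$library, k = 1)
  expect_gte(sum(fx$planted_ids %in% hits$id) / length(fx$planted_ids), 0.95)
  # docking triage on the hits via the mock backend, then SIFt shortlist
  score_table <- setNames(seq(-11, -6, length.out = nrow(hits)), hits$id)
  docked <- run_docking(hits, backend = "mock", score_table = score_table)
  sifts <- lapply(seq_len(nrow(docked)), function(i) {
    if (i <= 5) detect_interactions(gen_complex("PI_PI")$cpx)
    else detect_interactions(gen_complex("HBOND", distance = 6)$cpx)
  })
  docked$sift <- sifts
  top <- shortlist_poses(docked, "PI_PI@TYR56 | HBOND@{ASP122,LYS124,ARG125}",
                         n = 3)
  expect_equal(nrow(top), 3)
  expect_true(all(top$id %in% docked$id[1:5]))
})
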