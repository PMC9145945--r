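test_that("each planted geometry triggers exactly its interaction", {
  cases <- list(
    list(type = "HBOND", expect = "HBOND_DONOR"),
    list(type = "PI_PI", expect = "PI_PI"),
    list(type = "HYDROPHOBIC", expect = "HYDROPHOBIC"),
    list(type = "HALOGEN", expect = "HALOGEN"),
    list(type = "IONIC", expect = "IONIC")
  )
  for (cs in cases) {
    g <- gen_complex(cs$type)
    s <- detect_interactions(g$cpx)
    expect_equal(nrow(s), 1, info = cs$type)
    expect_equal(s$interaction, cs$expect, info = cs$type)
    expect_equal(s$count, 1L, info = cs$type)
    expect_equal(s$resname, g$recipe$residue, info = cs$type)
  }
})

test_that("geometry outside the cutoffs yields an empty matrix", {
  expect_equal(nrow(detect_interactions(gen_complex("HBOND", distance = 6)$cpx)), 0)
  expect_equal(nrow(detect_interactions(gen_complex("PI_PI", distance = 6)$cpx)), 0)
  # 45 degrees is neither parallel (<=30) nor T-shaped (60-120)
  expect_equal(nrow(detect_interactions(gen_complex("PI_PI", angle = 45)$cpx)), 0)
  # donor angle below the 120-degree cutoff
  expect_equal(nrow(detect_interactions(gen_complex("HBOND", angle = 90)$cpx)), 0)
  # T-shaped stacking still counts
  s <- detect_interactions(gen_complex("PI_PI", angle = 90)$cpx)
  expect_equal(s$interaction, "PI_PI")
})

test_that("read_complex preserves chains, rings and coordinates", {
  g <- gen_complex("PI_PI")
  cpx <- g$cpx
  expect_length(cpx$lig_rings, 1)
  expect_equal(sum(cpx$ligand$elem != "H"), 6)
  # re-read: identical atom counts, coordinates to 3 decimals
  cpx2 <- read_complex(g$protein_pdb, g$ligand_sdf)
  expect_equal(nrow(cpx2$protein), nrow(cpx$protein))
  expect_equal(as.matrix(cpx2$ligand[, c("x", "y", "z")]),
               as.matrix(cpx$ligand[, c("x", "y", "z")]), tolerance = 1e-3)

  # dimer bookkeeping: same residue number on two chains stays distinct
  pdb <- tempfile(fileext = ".pdb")
  lines <- c(
    pdlscreen:::pdb_atom_line("ATOM", 1, "N", "TYR", "A", 56, 0, 0, 0, "N"),
    pdlscreen:::pdb_atom_line("ATOM", 2, "CA", "TYR", "A", 56, 1.4, 0, 0, "C"),
    pdlscreen:::pdb_atom_line("ATOM", 3, "N", "TYR", "B", 56, 10, 0, 0, "N"),
    pdlscreen:::pdb_atom_line("ATOM", 4, "CA", "TYR", "B", 56, 11.4, 0, 0, "C"),
    "END"
  )
  writeLines(lines, pdb)
  cpx3 <- read_complex(pdb, g$ligand_sdf)
  expect_setequal(unique(cpx3$protein$chain), c("A", "B"))
})

test_that("SIFt is invariant under rigid motion of the whole complex", {
  set.seed(3)
  for (type in c("HBOND", "PI_PI", "IONIC")) {
    cpx <- gen_complex(type)$cpx
    ref <- detect_interactions(cpx)
    for (rep in 1:3) {
      moved <- transform_cpx(cpx, pdlscreen:::random_rigid_motion())
      expect_true(sift_equal(ref, detect_interactions(moved)),
                  info = paste(type, rep))
    }
  }
})

test_that("hydrophobic counts are monotone in the distance cutoff", {
  set.seed(5)
  for (i in 1:10) {
    cpx <- random_micro_cpx()
    counts <- vapply(c(3.5, 4.5, 5.5, 6.5), function(cut) {
      s <- detect_interactions(cpx, sift_criteria(hydrophobic_dist = cut))
      sum(s$count[s$interaction == "HYDROPHOBIC"])
    }, numeric(1))
    expect_true(all(diff(counts) >= 0))
  }
})

test_that("detectors agree with the brute-force oracle on micro-complexes", {
  set.seed(20220516)
  n_match <- 0
  for (i in 1:60) {
    cpx <- random_micro_cpx()
    got <- detect_interactions(cpx)
    want <- oracle_sift(cpx)
    expect_true(sift_equal(got, want), info = paste("micro-complex", i))
    n_match <- n_match + nrow(got)
  }
  expect_gt(n_match, 20) # the fixtures actually exercised the detectors
})

test_that("ligands far from every residue give an empty matrix", {
  cpx <- gen_complex("HBOND")$cpx
  cpx$ligand$x <- cpx$ligand$x + 100
  cpx$ligand$explicit_h <- lapply(cpx$ligand$explicit_h, function(h) {
    if (is.null(h)) NULL else h + matrix(c(100, 0, 0), nrow(h), 3, byrow = TRUE)
  })
  s <- detect_interactions(cpx)
  expect_equal(nrow(s), 0)
  expect_s3_class(s, "sift_tbl")
})
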