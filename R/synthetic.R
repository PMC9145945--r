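# Deterministic synthetic fixtures: separable SMILES corpora with planted
# screening hits, toy protein-ligand complexes with exact interaction
# geometries, toy trajectories, and synthetic HTRF plates. Everything is
# fully determined by the fixture seed so the whole pipeline runs end to
# end with no external data.

#' Fixture generation parameters
#'
#' Defaults mirror the modeled screening campaign's class imbalance
#' (actives:inactives about 1581:417) at desk scale, with a 500-molecule
#' screening library carrying 25 planted actives.
#'
#' @param seed Seed that fully determines all generated fixtures.
#' @param n_actives,n_inactives Corpus class sizes.
#' @param n_decoy_pool Size of the candidate decoy pool.
#' @param decoys_per_active Decoys matched per held-out active.
#' @param n_library,n_planted Screening-library size and planted actives.
#' @param scaffold SMILES of the active-class scaffold (biphenyl).
#' @return A list of class `fixture_spec`.
#' @export
fixture_spec <- function(seed = 20220516, n_actives = 300, n_inactives = 79,
                         n_decoy_pool = 1200, decoys_per_active = 5,
                         n_library = 500, n_planted = 25,
                         scaffold = "c1ccc(-c2ccccc2)cc1") {
  stopifnot(n_actives >= 2, n_inactives >= 1, n_planted <= n_library)
  structure(as.list(environment()), class = "fixture_spec")
}

# Chainable substituent fragments: each is a valid SMILES chain segment
# whose first and last atoms keep a spare valence, so fragments concatenate
# freely as prefixes of a ring system. The active class carries amine/amide
# decorations, the scaffold-free classes ether/ester/thioether/halide ones:
# property profiles overlap (decoy matching stays possible) while every
# fingerprint family, including functional-group keys, sees the class
# difference.
.frags_neutral <- c("C", "CC", "CCC", "CCCC", "C(C)C")
# Active-class decoration: every active carries a nitrile plus a urea or
# guanidine anchor (class signatures visible to functional-group keys as
# well as topological ones) plus amine variety.
.anchors_active <- c("NC(=N)NC(C#N)", "NC(=O)NC(C#N)", "NC(=N)NCC(C#N)",
                     "NC(=O)NCC(C#N)", "C(C#N)NC(=N)N", "C(C#N)NC(=O)N",
                     "C(C#N)CNC(=N)N", "C(C#N)CNC(=O)N")
.variety_active <- c("CN", "NC", "NCC", "CCN", "CNC", "N(C)C", "CCCN",
                     "NCCC", "NC(C)", "NCCN", "CCNC")
# Scaffold-free family: ester anchor plus ether/thioether/halide variety.
.anchors_decoy <- c("C(=O)O", "OC(=O)", "C(=O)OC", "OC(=O)C", "COC(=O)",
                    "CC(=O)O")
.variety_decoy <- c("OC", "CO", "OCC", "CCO", "COC", "OCCC", "SC", "CS",
                    "CCS", "C(Cl)", "C(Br)", "C(F)(F)",
                    # hydroxyl-bearing chains keep the family's HBD/HBA and
                    # clogP ranges overlapping the actives for decoy matching
                    "C(O)", "C(O)C", "CC(O)", "OCC(O)", "C(O)CC(O)")

# Deterministic enumeration of decorated molecules: core ring system with
# one or two fragment prefixes, always including one class-anchor fragment
# so every molecule shows its class to functional-group fingerprints as
# well as to topological ones.
decorate <- function(cores, max_n, anchors, variety,
                     neutrals = .frags_neutral) {
  other <- c(variety, neutrals)
  pairs <- unique(c(
    as.vector(outer(anchors, other, paste0)),
    as.vector(outer(other, anchors, paste0)),
    as.vector(outer(anchors, anchors, paste0))
  ))
  triples <- as.vector(outer(as.vector(outer(pairs, neutrals, paste0)),
                             cores, paste0))
  out <- unique(c(
    as.vector(outer(anchors, cores, paste0)),
    as.vector(outer(pairs, cores, paste0)),
    triples
  ))
  head(out, max_n)
}

.biphenyl_core <- "c1ccc(-c2ccccc2)cc1"
# Scaffold-free decoy chemotypes in the actives' property range (MW, logP,
# HBD/HBA), but without the aryl-aryl bond: one aromatic ring fused or
# linked to saturated carbocycles.
.decoy_cores <- c("c1ccc(C2CCCCC2)cc1",    # phenylcyclohexane
                  "c1ccc2c(c1)CCCC2",      # tetralin
                  "C1CCC(CC2CCCCC2)CC1",   # dicyclohexylmethane
                  "C1CCC(Cc2ccccc2)CC1",   # benzylcyclohexane
                  "c1ccc(C2CCCC2)cc1",     # phenylcyclopentane
                  "c1ccc2c(c1)CCC2")       # indane
.inactive_cores <- c("C1CCCCC1", "c1ccncc1", "C1CCNCC1", "c1ccoc1",
                     "c1ccsc1", "C1CCOCC1", "c1cnccn1", "C1CCCC1")

#' Generate a labeled corpus, split and screening library
#'
#' Actives share the biphenyl scaffold decorated with enumerated
#' substituents; inactives are random non-scaffold heterocycles and chains;
#' the decoy pool holds scaffold-free molecules property-matched to the
#' actives (diphenylmethane, bibenzyl and naphthalene families built from
#' the same substituent set). The screening library mixes decoy-like
#' molecules with freshly decorated (never-trained) planted actives whose
#' ids are recorded. Train/test composition and decoy matching go through
#' [split_corpus()] and [match_decoys()].
#'
#' @param spec A [fixture_spec()].
#' @return List with `corpus` (labeled tibble incl. matched decoys),
#'   `split` (a `corpus_split`), `library` (screening tibble) and
#'   `planted_ids`.
#' @export
gen_corpus <- function(spec = fixture_spec()) {
  stopifnot(inherits(spec, "fixture_spec"))
  chk <- parse_smiles(c(s = spec$scaffold))
  if (chk$n_failed > 0) abort("scaffold SMILES does not parse")

  all_actives <- decorate(.biphenyl_core, spec$n_actives + spec$n_planted,
                          anchors = .anchors_active,
                          variety = .variety_active)
  if (length(all_actives) < spec$n_actives + spec$n_planted) {
    abort("substituent enumeration too small for requested corpus")
  }
  actives <- tibble(
    id = sprintf("ACT%04d", seq_len(spec$n_actives)),
    smiles = all_actives[seq_len(spec$n_actives)],
    label = "ACTIVE",
    potency_nM = with_seed(spec$seed,
                           signif(10^runif(spec$n_actives, log10(0.6), 5), 3))
  )

  # One deterministic shuffle of the scaffold-free enumeration, partitioned
  # into disjoint inactive / decoy-pool / library-background slices so the
  # negative classes share a chemotype (the boundary the models must learn
  # is the scaffold, not an artifact of the negative family).
  decoyish <- with_seed(spec$seed + 1,
                        sample(decorate(.decoy_cores, .Machine$integer.max,
                                        anchors = .anchors_decoy,
                                        variety = .variety_decoy)))
  n_ina_chain <- ceiling(spec$n_inactives / 5)
  n_ina_core <- spec$n_inactives - n_ina_chain
  n_bg <- spec$n_library - spec$n_planted
  if (length(decoyish) < n_ina_core + spec$n_decoy_pool + n_bg) {
    abort("scaffold-free enumeration too small for requested sizes")
  }
  take <- function(n, offset) decoyish[offset + seq_len(n)]
  inactives <- tibble(
    id = sprintf("INA%04d", seq_len(spec$n_inactives)),
    smiles = c(take(n_ina_core, 0),
               with_seed(spec$seed + 5, random_chain_smiles(n_ina_chain))),
    label = "INACTIVE",
    potency_nM = NA_real_
  )
  pool <- tibble(
    id = sprintf("POOL%05d", seq_len(spec$n_decoy_pool)),
    smiles = take(spec$n_decoy_pool, n_ina_core),
    label = "UNLABELED",
    potency_nM = NA_real_
  )

  base <- bind_rows(actives, inactives)
  base_split <- split_corpus(base, seed = spec$seed)
  held_actives <- base_split$test %>% filter(.data$label == "ACTIVE")
  decoys <- suppressWarnings(match_decoys(
    compute_properties(held_actives),
    compute_properties(pool),
    k = spec$decoys_per_active
  ))
  decoys <- decoys[, c("id", "smiles", "label", "potency_nM")]
  corpus <- bind_rows(base, decoys)
  split <- list(
    train = base_split$train,
    test = bind_rows(held_actives, decoys),
    decoys_per_active = spec$decoys_per_active
  )
  class(split) <- c("corpus_split", class(split))

  planted <- tibble(
    id = sprintf("PLANT%03d", seq_len(spec$n_planted)),
    smiles = all_actives[spec$n_actives + seq_len(spec$n_planted)],
    label = "UNLABELED",
    potency_nM = NA_real_
  )
  background <- tibble(
    id = sprintf("LIB%05d", seq_len(n_bg)),
    smiles = take(n_bg, n_ina_core + spec$n_decoy_pool),
    label = "UNLABELED",
    potency_nM = NA_real_
  )
  library_tbl <- with_seed(
    spec$seed + 4,
    dplyr::slice_sample(bind_rows(background, planted), prop = 1)
  )
  list(corpus = corpus, split = split, library = library_tbl,
       planted_ids = planted$id)
}

# Random valid acyclic/heterocyclic SMILES without the biphenyl scaffold.
random_chain_smiles <- function(n) {
  out <- character(n)
  for (i in seq_len(n)) {
    core <- sample(c(.inactive_cores, ""), 1)
    len <- sample(2:5, 1)
    chain <- paste(sample(c("C", "N", "O"), len, replace = TRUE,
                          prob = c(0.7, 0.15, 0.15)), collapse = "")
    frag <- sample(.variety_decoy, 1)
    out[i] <- paste0(frag, chain, core)
  }
  out
}

# ---- toy complexes with exact planted geometries ----

#' Generate a toy complex with one planted interaction
#'
#' Builds a micro protein pocket (the target residue plus a remote glycine
#' spectator) and a minimal ligand placed so that exactly the requested
#' interaction triggers under default [sift_criteria()] - and nothing else.
#' Files are emitted in the package's own formats (PDB + SDF) and re-read
#' through [read_complex()], so the returned object is guaranteed to
#' round-trip.
#'
#' @param type One of `HBOND`, `PI_PI`, `HYDROPHOBIC`, `HALOGEN`, `IONIC`.
#' @param residue Target residue name (defaults per type: ASP for
#'   HBOND/HALOGEN/IONIC, TYR for PI_PI, LEU for HYDROPHOBIC).
#' @param distance Key interaction distance in Angstrom (defaults per type).
#' @param angle Key angle in degrees where applicable (H-bond donor angle,
#'   ring-normal angle for PI_PI; default 180 / 0).
#' @param dir Output directory (default tempdir()); writes `protein.pdb`
#'   and `ligand.sdf`.
#' @return List: `cpx` (complex3d), `protein_pdb`, `ligand_sdf`, `recipe`.
#' @export
gen_complex <- function(type = c("HBOND", "PI_PI", "HYDROPHOBIC", "HALOGEN",
                                 "IONIC"),
                        residue = NULL, distance = NULL, angle = NULL,
                        dir = tempdir()) {
  type <- match.arg(type)
  distance <- distance %||% switch(type, HBOND = 2.9, PI_PI = 3.8,
                                   HYDROPHOBIC = 4.0, HALOGEN = 3.0,
                                   IONIC = 4.0)
  if (distance <= 0) abort("interaction distance must be positive")
  angle <- angle %||% switch(type, HBOND = 180, PI_PI = 0, 180)
  residue <- toupper(residue %||% switch(type, PI_PI = "TYR",
                                         HYDROPHOBIC = "LEU", "ASP"))
  geom <- switch(type,
    HBOND = geom_hbond(residue, distance, angle),
    PI_PI = geom_pipi(residue, distance, angle),
    HYDROPHOBIC = geom_hydrophobic(residue, distance),
    HALOGEN = geom_halogen(residue, distance, angle),
    IONIC = geom_ionic(residue, distance)
  )
  protein_pdb <- file.path(dir, paste0("protein_", tolower(type), ".pdb"))
  ligand_sdf <- file.path(dir, paste0("ligand_", tolower(type), ".sdf"))
  write_micro_pdb(geom$protein, protein_pdb)
  write_sdf(geom$lig_elem, geom$lig_xyz, geom$lig_bonds, geom$lig_charge,
            ligand_sdf)
  cpx <- read_complex(protein_pdb, ligand_sdf)
  list(cpx = cpx, protein_pdb = protein_pdb, ligand_sdf = ligand_sdf,
       recipe = list(type = type, residue = residue, distance = distance,
                     angle = angle))
}

# Residue atom layouts. The target residue sits near the origin with its
# interacting atom AT the origin; a GLY spectator sits 25 A away. Backbone
# atoms are placed >6 A from the ligand so only the planted contact fires.
residue_atoms <- function(resname, side_chain) {
  bb <- tibble(
    elety = c("N", "CA", "C", "O"),
    x = c(-6.0, -5.2, -5.8, -7.0),
    y = c(1.2, 0.0, -1.3, -1.5),
    z = c(0.5, 0.0, -0.5, -0.7),
    elem = c("N", "C", "C", "O")
  )
  res <- bind_rows(bb, side_chain)
  res$resid <- resname
  res$chain <- "A"
  res$resno <- 56L
  spect <- tibble(
    elety = c("N", "CA", "C", "O"),
    x = 25 + c(0, 1, 2, 3), y = c(0, 1, 0, 1), z = c(0, 0, 1, 1),
    elem = c("N", "C", "C", "O"),
    resid = "GLY", chain = "A", resno = 99L
  )
  bind_rows(res, spect)
}

geom_hbond <- function(residue, d, ang) {
  stopifnot(residue == "ASP")
  sc <- tibble(
    elety = c("CB", "CG", "OD1", "OD2"),
    x = c(-3.6, -2.2, 0.0, -2.0),
    y = c(-0.6, -0.4, 0.0, 4.2),
    z = c(0.9, 0.4, 0.0, 0.6),
    elem = c("C", "C", "O", "O")
  )
  # ligand methylamine: N donor at (d,0,0); H placed so angle(N, H, OD1)=ang
  nx <- c(d, 0, 0)
  h <- place_h_for_angle(nx, c(0, 0, 0), ang, bond = 1.0)
  cx <- c(d + 1.0, 0.3, 1.2)
  list(
    protein = residue_atoms(residue, sc),
    lig_elem = c("N", "C", "H"),
    lig_xyz = rbind(nx, cx, h),
    lig_bonds = rbind(c(1, 2, 1), c(1, 3, 1)),
    lig_charge = c(0, 0, 0)
  )
}

# Place an H at bond length from donor D so that the D-H...A angle equals
# `ang` (vertex at H), keeping everything in the xz-plane through D and A.
place_h_for_angle <- function(d_xyz, a_xyz, ang, bond = 1.0) {
  u <- (a_xyz - d_xyz) / vec_norm(a_xyz - d_xyz)
  # perpendicular in a stable plane
  p <- c(-u[2], u[1], 0)
  if (vec_norm(p) < 1e-6) p <- c(0, -u[3], u[2])
  p <- p / vec_norm(p)
  f <- function(alpha) {
    h <- d_xyz + bond * (cos(alpha) * u + sin(alpha) * p)
    angle_deg(d_xyz, h, a_xyz) - ang
  }
  # alpha = 0 puts H on the D->A axis (angle 180)
  if (abs(f(0)) < 1e-9) {
    alpha <- 0
  } else {
    alpha <- stats::uniroot(f, c(1e-6, pi - 1e-3))$root
  }
  d_xyz + bond * (cos(alpha) * u + sin(alpha) * p)
}

geom_pipi <- function(residue, d, ang) {
  stopifnot(residue %in% c("TYR", "PHE"))
  hex <- function(r, z, tilt = 0) {
    th <- seq(0, 2 * pi, length.out = 7)[1:6]
    xyz <- cbind(r * cos(th), r * sin(th), z)
    if (tilt != 0) {
      rot <- matrix(c(cos(tilt), 0, sin(tilt), 0, 1, 0,
                      -sin(tilt), 0, cos(tilt)), 3, 3, byrow = TRUE)
      ctr <- colMeans(xyz)
      xyz <- sweep(sweep(xyz, 2, ctr) %*% t(rot), 2, ctr, "+")
    }
    xyz
  }
  ring <- hex(1.39, 0)
  sc_names <- c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")
  sc <- tibble(
    elety = c(sc_names, "CB", if (residue == "TYR") "OH"),
    x = c(ring[, 1], -4.0, if (residue == "TYR") 4.2),
    y = c(ring[, 2], -0.5, if (residue == "TYR") 0),
    z = c(ring[, 3], -1.5, if (residue == "TYR") -1.2),
    elem = c(rep("C", 7), if (residue == "TYR") "O")
  )
  lig_ring <- hex(1.39, d, tilt = ang * pi / 180)
  bonds <- cbind(1:6, c(2:6, 1), rep(4L, 6))
  bonds[, 3] <- c(2, 1, 2, 1, 2, 1) # kekulized orders
  list(
    protein = residue_atoms(residue, sc),
    lig_elem = rep("C", 6),
    lig_xyz = lig_ring,
    lig_bonds = bonds,
    lig_charge = rep(0, 6)
  )
}

geom_hydrophobic <- function(residue, d) {
  stopifnot(residue == "LEU")
  sc <- tibble(
    elety = c("CB", "CG", "CD1", "CD2"),
    x = c(-2.8, -1.5, 0.0, -2.1),
    y = c(-0.9, 0.2, 0.0, 1.5),
    z = c(1.0, 0.7, 0.0, 1.4),
    elem = rep("C", 4)
  )
  list(
    protein = residue_atoms(residue, sc),
    lig_elem = c("C", "C"),
    lig_xyz = rbind(c(d, 0, 0), c(d + 1.53, 0.4, 1.3)),
    lig_bonds = rbind(c(1, 2, 1)),
    lig_charge = c(0, 0)
  )
}

geom_halogen <- function(residue, d, ang) {
  stopifnot(residue == "ASP")
  sc <- tibble(
    elety = c("CB", "CG", "OD1", "OD2"),
    x = c(-3.6, -2.2, 0.0, -2.0),
    y = c(-0.6, -0.4, 0.0, 4.2),
    z = c(0.9, 0.4, 0.0, 0.6),
    elem = c("C", "C", "O", "O")
  )
  clx <- c(d, 0, 0)
  # carbon placed so that the angle at the halogen, angle(C, Cl, OD1),
  # equals ang: closed form around the Cl vertex
  u <- (c(0, 0, 0) - clx) / vec_norm(c(0, 0, 0) - clx)
  p <- c(-u[2], u[1], 0)
  if (vec_norm(p) < 1e-6) p <- c(0, -u[3], u[2])
  p <- p / vec_norm(p)
  v <- cos(ang * pi / 180) * u + sin(ang * pi / 180) * p
  cx <- clx + 1.77 * v
  list(
    protein = residue_atoms(residue, sc),
    lig_elem = c("Cl", "C"),
    lig_xyz = rbind(clx, cx),
    lig_bonds = rbind(c(1, 2, 1)),
    lig_charge = c(0, 0)
  )
}

geom_ionic <- function(residue, d) {
  stopifnot(residue == "ASP")
  sc <- tibble(
    elety = c("CB", "CG", "OD1", "OD2"),
    x = c(-3.6, -2.2, 0.0, -2.0),
    y = c(-0.6, -0.4, 0.0, 4.2),
    z = c(0.9, 0.4, 0.0, 0.6),
    elem = c("C", "C", "O", "O")
  )
  list(
    protein = residue_atoms(residue, sc),
    lig_elem = c("N", "C"),
    lig_xyz = rbind(c(d, 0, 0), c(d + 1.2, 0.4, 1.0)),
    lig_bonds = rbind(c(1, 2, 1)),
    lig_charge = c(1, 0)
  )
}

write_micro_pdb <- function(atoms, path) {
  lines <- vapply(seq_len(nrow(atoms)), function(i) {
    a <- atoms[i, ]
    pdb_atom_line("ATOM", i, a$elety, a$resid, a$chain, a$resno,
                  a$x, a$y, a$z, a$elem)
  }, character(1))
  writeLines(c(lines, "END"), path)
  invisible(path)
}

# Minimal V2000 SDF writer (atom-field charge codes + M CHG block).
write_sdf <- function(elem, xyz, bonds, charge, path, title = "ligand") {
  n <- length(elem)
  nb <- if (is.null(bonds)) 0L else nrow(bonds)
  code <- vapply(charge, function(q) {
    switch(as.character(q), `3` = 1L, `2` = 2L, `1` = 3L, `0` = 0L,
           `-1` = 5L, `-2` = 6L, `-3` = 7L, 0L)
  }, integer(1))
  lines <- c(
    title, "  pdlscreen", "",
    sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, nb),
    vapply(seq_len(n), function(i) {
      sprintf("%10.4f%10.4f%10.4f %-3s 0  %1d  0  0  0  0  0  0  0  0  0  0",
              xyz[i, 1], xyz[i, 2], xyz[i, 3], elem[i], code[i])
    }, character(1)),
    if (nb > 0) vapply(seq_len(nb), function(k) {
      sprintf("%3d%3d%3d  0  0  0  0", bonds[k, 1], bonds[k, 2], bonds[k, 3])
    }, character(1))
  )
  chg <- which(charge != 0)
  if (length(chg) > 0) {
    lines <- c(lines, paste0(
      sprintf("M  CHG%3d", length(chg)),
      paste0(sprintf(" %3d %3d", chg, charge[chg]), collapse = "")
    ))
  }
  writeLines(c(lines, "M  END", "$$$$"), path)
  invisible(path)
}

# ---- toy trajectories ----

#' Generate a toy trajectory from a complex
#'
#' `static` repeats the input frame; `drift` applies a rigid Gaussian
#' random walk to the ligand (step SD = `amplitude` Angstrom per frame);
#' `detach` translates the ligand away from the protein center by
#' `amplitude` Angstrom per frame (monotone unbinding). The protein never
#' moves.
#'
#' @param cpx A `complex3d`.
#' @param n_frames Number of frames (>= 2).
#' @param mode `"static"`, `"drift"` or `"detach"`.
#' @param amplitude Per-frame ligand displacement scale, Angstrom.
#' @param seed RNG seed (drift mode).
#' @param timestep_ps Frame spacing in ps.
#' @return A trajectory object.
#' @export
gen_trajectory <- function(cpx, n_frames = 100,
                           mode = c("static", "drift", "detach"),
                           amplitude = 0.1, seed = 20220516,
                           timestep_ps = 5.0) {
  mode <- match.arg(mode)
  stopifnot(inherits(cpx, "complex3d"), n_frames >= 2)
  pxyz <- as.matrix(cpx$protein[, c("x", "y", "z")])
  lxyz <- as.matrix(cpx$ligand[, c("x", "y", "z")])
  nl <- nrow(lxyz)
  base <- c(as.vector(t(pxyz)), as.vector(t(lxyz)))
  shift <- switch(mode,
    static = matrix(0, n_frames, 3),
    drift = with_seed(seed, {
      steps <- matrix(rnorm(3 * n_frames, sd = amplitude), ncol = 3)
      steps[1, ] <- 0
      apply(steps, 2, cumsum)
    }),
    detach = {
      dirv <- colMeans(lxyz) - colMeans(pxyz)
      if (vec_norm(dirv) < 1e-9) dirv <- c(1, 0, 0)
      dirv <- dirv / vec_norm(dirv)
      outer((seq_len(n_frames) - 1) * amplitude, dirv)
    }
  )
  xyz <- matrix(rep(base, each = n_frames), nrow = n_frames)
  np3 <- 3 * nrow(pxyz)
  for (f in seq_len(n_frames)) {
    lig <- matrix(xyz[f, -seq_len(np3)], ncol = 3, byrow = TRUE)
    lig <- sweep(lig, 2, shift[f, ], "+")
    xyz[f, -seq_len(np3)] <- as.vector(t(lig))
  }
  as_trajectory(cpx, xyz, timestep_ps)
}

# ---- synthetic HTRF plates ----

#' Generate a synthetic HTRF plate
#'
#' Signals follow `S = S_ctrl - (S_ctrl - S_neg) * %I/100 + noise` where
#' `%I` comes from a 4PL curve with the given parameters; noise is Gaussian
#' with SD `noise_frac` of the assay window. Untreated and no-PD1 control
#' wells are included.
#'
#' @param compounds Named numeric vector: compound id -> true IC50 (uM).
#' @param hill,top,bottom 4PL generating parameters.
#' @param concentrations Tested concentrations in uM (0 rows allowed).
#' @param replicates Wells per (compound, concentration).
#' @param noise_frac Gaussian noise SD as a fraction of the window.
#' @param s_ctrl,s_neg Control and negative mean signals.
#' @param seed RNG seed.
#' @return Plate tibble for [percent_inhibition()] / [fit_plate()].
#' @export
gen_plate <- function(compounds, hill = 1, top = 100, bottom = 0,
                      concentrations = c(0.78125, 1.5625, 3.125, 6.25,
                                         12.5, 25, 50, 100),
                      replicates = 3, noise_frac = 0.05,
                      s_ctrl = 10000, s_neg = 1000, seed = 20220516) {
  stopifnot(length(compounds) >= 1, !is.null(names(compounds)))
  window <- s_ctrl - s_neg
  with_seed(seed, {
    rows <- list()
    for (cid in names(compounds)) {
      for (conc in concentrations) {
        pi_true <- if (conc == 0) bottom
                   else fourpl(conc, bottom, top, compounds[[cid]], hill)
        sig <- s_ctrl - window * pi_true / 100 +
          rnorm(replicates, sd = noise_frac * window)
        rows[[length(rows) + 1]] <- tibble(
          compound_id = cid, concentration_uM = conc,
          signal = pmax(sig, 0), role = "SAMPLE"
        )
      }
    }
    ctrl <- tibble(
      compound_id = "CTRL", concentration_uM = 0,
      signal = pmax(s_ctrl + rnorm(6, sd = noise_frac * window / 2), 0),
      role = "CONTROL_UNTREATED"
    )
    neg <- tibble(
      compound_id = "NEG", concentration_uM = 0,
      signal = pmax(s_neg + rnorm(6, sd = noise_frac * window / 2), 0),
      role = "NEGATIVE_NO_PD1"
    )
    bind_rows(bind_rows(rows), ctrl, neg)
  })
}
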