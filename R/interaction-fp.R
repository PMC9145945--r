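# Structural interaction fingerprints (SIFt) from protein-ligand complexes,
# computed from geometric first principles, plus the key-residue filter
# predicate used to triage docking poses.

# ---- protein chemistry tables (standard residue topologies) ----

.prot_ring_def <- list(
  PHE = list(c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
  TYR = list(c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
  HIS = list(c("CG", "ND1", "CD2", "CE1", "NE2")),
  TRP = list(c("CG", "CD1", "NE1", "CE2", "CD2"),
             c("CD2", "CE2", "CZ2", "CH2", "CZ3", "CE3"))
)

.prot_donor_sc <- list(
  SER = "OG", THR = "OG1", TYR = "OH", CYS = "SG", ASN = "ND2",
  GLN = "NE2", LYS = "NZ", ARG = c("NE", "NH1", "NH2"), TRP = "NE1",
  HIS = c("ND1", "NE2")
)

.prot_acceptor_sc <- list(
  ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"), ASN = "OD1", GLN = "OE1",
  SER = "OG", THR = "OG1", TYR = "OH", HIS = c("ND1", "NE2"), MET = "SD"
)

# Aliphatic C/S atoms bonded only to C, S or H (aromatic ring carbons are
# carried by the PI_PI channel instead; see vignette).
.prot_apolar_sc <- list(
  ALA = "CB", VAL = c("CB", "CG1", "CG2"), LEU = c("CB", "CG", "CD1", "CD2"),
  ILE = c("CB", "CG1", "CG2", "CD1"), MET = c("CB", "CG", "SD", "CE"),
  PRO = c("CB", "CG"), PHE = "CB", TYR = "CB", TRP = "CB",
  LYS = c("CB", "CG", "CD"), ARG = c("CB", "CG"), GLU = c("CB", "CG"),
  GLN = c("CB", "CG"), ASP = "CB", ASN = "CB", HIS = "CB", THR = "CG2",
  CYS = c("CB", "SG")
)

.prot_charge_sc <- list(
  ASP = list(atoms = c("OD1", "OD2"), charge = -1L),
  GLU = list(atoms = c("OE1", "OE2"), charge = -1L),
  LYS = list(atoms = "NZ", charge = 1L),
  ARG = list(atoms = c("NE", "NH1", "NH2"), charge = 1L)
)

.water_resnames <- c("HOH", "WAT", "TIP", "TIP3", "SOL", "H2O")

.interaction_types <- c("HYDROPHOBIC", "HBOND_DONOR", "HBOND_ACCEPTOR",
                        "PI_PI", "HALOGEN", "IONIC")

# ---- complex construction ----

#' Read a protein-ligand complex
#'
#' Builds a `complex3d` object from a protein PDB file and a ligand pose
#' with 3D coordinates (SDF natively; MOL2/PDBQT converted through
#' OpenBabel). Alternate locations keep the highest occupancy; insertion
#' codes are preserved; aromatic rings are perceived on both sides.
#'
#' @param protein Path to a PDB file.
#' @param ligand Path to an SDF/MOL2/PDBQT pose file.
#' @return An object of class `complex3d`.
#' @export
read_complex <- function(protein, ligand) {
  stopifnot(file.exists(protein))
  pdb <- bio3d::read.pdb(protein, verbose = FALSE)
  prot <- protein_table(pdb$atom)
  lig <- read_ligand_pose(ligand)
  new_complex3d(prot, lig$atoms, lig$bonds, lig$rings)
}

protein_table <- function(atom_df) {
  tb <- as_tibble(atom_df)
  tb$insert[is.na(tb$insert)] <- ""
  tb$chain[is.na(tb$chain)] <- "A"
  tb$elem <- ifelse(nzchar(tb$elesy %||% ""), tb$elesy,
                    substr(gsub("[0-9]", "", tb$elety), 1, 1))
  tb$elem[is.na(tb$elem) | !nzchar(tb$elem)] <-
    substr(gsub("[0-9]", "", tb$elety[is.na(tb$elem) | !nzchar(tb$elem)]), 1, 1)
  # altloc: keep the highest-occupancy copy of each atom
  tb$o[is.na(tb$o)] <- 1
  tb <- tb %>%
    group_by(.data$chain, .data$resno, .data$insert, .data$elety) %>%
    arrange(desc(.data$o), .by_group = TRUE) %>%
    slice(1) %>%
    ungroup() %>%
    arrange(.data$eleno)
  tb$is_water <- tb$resid %in% .water_resnames
  tb
}

read_ligand_pose <- function(ligand) {
  stopifnot(file.exists(ligand))
  ext <- tolower(tools::file_ext(ligand))
  sdf_path <- ligand
  if (ext %in% c("mol2", "pdbqt", "pdb")) {
    ob <- Sys.which("obabel")
    if (!nzchar(ob)) abort("converting non-SDF poses requires 'obabel' on PATH")
    sdf_path <- tempfile(fileext = ".sdf")
    system2(ob, c(shQuote(ligand), "-osdf", "-O", shQuote(sdf_path)),
            stdout = FALSE, stderr = FALSE)
  }
  sdfset <- ChemmineR::read.SDFset(sdf_path)
  if (length(sdfset) == 0) abort("no ligand records in pose file")
  g <- mol_graph(sdfset[[1]])
  if (all(g$xyz[, 3] == 0) && all(g$xyz[, 2] %in% range(g$xyz[, 2]))) {
    # purely 2D layouts are suspicious but not fatal; geometry checks below
  }
  if (nrow(g$xyz) == 0) abort("ligand pose has no coordinates")
  ligand_atoms_from_graph(g)
}

ligand_atoms_from_graph <- function(g) {
  n <- length(g$elem)
  total_order <- integer(n)
  if (nrow(g$bonds) > 0) {
    for (k in seq_len(nrow(g$bonds))) {
      total_order[g$bonds$a1[k]] <- total_order[g$bonds$a1[k]] + g$bonds$order[k]
      total_order[g$bonds$a2[k]] <- total_order[g$bonds$a2[k]] + g$bonds$order[k]
    }
  }
  hetero_nb <- vapply(seq_len(n), function(i) {
    any(!g$elem[g$adj[[i]]] %in% c("C", "S", "H"))
  }, logical(1))
  carbon_nb <- vapply(seq_len(n), function(i) {
    any(g$elem[g$adj[[i]]] == "C")
  }, logical(1))
  atoms <- tibble(
    idx = seq_len(n),
    elem = g$elem,
    x = g$xyz[, 1], y = g$xyz[, 2], z = g$xyz[, 3],
    charge = g$charge,
    nH = g$nH,
    aromatic = g$aromatic,
    donor = g$elem %in% c("N", "O") & g$nH >= 1,
    acceptor = (g$elem == "O" & g$charge <= 0) |
      (g$elem == "N" & g$charge <= 0 & total_order + pmax(g$nH - vapply(seq_len(n), function(i) sum(g$elem[g$adj[[i]]] == "H"), integer(1)), 0) <= 3),
    apolar = g$elem %in% c("C", "S") & !g$aromatic & !hetero_nb,
    halogen = g$elem %in% c("Cl", "Br", "I") & carbon_nb,
    explicit_h = map(seq_len(n), function(i) {
      h <- g$adj[[i]][g$elem[g$adj[[i]]] == "H"]
      if (length(h)) g$xyz[h, , drop = FALSE] else NULL
    })
  )
  rings <- keep(g$rings, ~ .x$aromatic && length(.x$atoms) >= 5)
  list(atoms = atoms, bonds = g$bonds, rings = map(rings, "atoms"))
}

new_complex3d <- function(protein, ligand_atoms, ligand_bonds, ligand_rings) {
  heavy <- ligand_atoms[ligand_atoms$elem != "H", , drop = FALSE]
  if (nrow(heavy) == 0) abort("ligand is empty")
  structure(list(
    protein = protein,
    ligand = ligand_atoms,
    lig_bonds = ligand_bonds,
    lig_rings = ligand_rings
  ), class = "complex3d")
}

#' @export
print.complex3d <- function(x, ...) {
  res <- x$protein %>%
    filter(!.data$is_water) %>%
    distinct(.data$chain, .data$resno)
  cat("<complex3d> protein:", nrow(res), "residues (",
      nrow(x$protein), "atoms ), ligand:",
      sum(x$ligand$elem != "H"), "heavy atoms,",
      length(x$lig_rings), "aromatic ring(s)\n")
  invisible(x)
}

# Aromatic rings on the protein side: (chain, resno, resname, coords).
protein_rings <- function(prot) {
  out <- list()
  res <- prot %>%
    filter(.data$resid %in% names(.prot_ring_def)) %>%
    distinct(.data$chain, .data$resno, .data$insert, .data$resid)
  if (nrow(res) == 0) return(out)
  for (i in seq_len(nrow(res))) {
    defs <- .prot_ring_def[[res$resid[i]]]
    for (def in defs) {
      sel <- prot$chain == res$chain[i] & prot$resno == res$resno[i] &
        prot$insert == res$insert[i] & prot$elety %in% def
      if (sum(sel) == length(def)) {
        out[[length(out) + 1]] <- list(
          chain = res$chain[i], resno = res$resno[i], resname = res$resid[i],
          xyz = as.matrix(prot[sel, c("x", "y", "z")])
        )
      }
    }
  }
  out
}

# ---- criteria ----

#' Geometric criteria for interaction detection
#'
#' Community-standard cutoffs, all configurable and recorded in run
#' manifests. Distances in Angstrom, angles in degrees.
#'
#' @param hbond_dist Donor-acceptor heavy-atom distance cutoff.
#' @param hbond_angle Minimum D-H...A angle (applied only when an explicit
#'   hydrogen is available on the donor; otherwise distance-only).
#' @param pipi_dist Ring centroid-centroid cutoff.
#' @param pipi_parallel Maximum inter-normal angle for parallel stacking.
#' @param pipi_tshape Inter-normal angle window for T-shaped stacking.
#' @param hydrophobic_dist Apolar C/S - apolar C/S cutoff.
#' @param halogen_dist X...acceptor cutoff (X = Cl, Br, I).
#' @param halogen_angle Minimum C-X...A angle.
#' @param ionic_dist Opposite-formal-charge distance cutoff.
#' @return A list of class `sift_criteria`.
#' @export
sift_criteria <- function(hbond_dist = 3.5, hbond_angle = 120,
                          pipi_dist = 5.5, pipi_parallel = 30,
                          pipi_tshape = c(60, 120),
                          hydrophobic_dist = 4.5,
                          halogen_dist = 3.5, halogen_angle = 140,
                          ionic_dist = 4.5) {
  structure(as.list(environment()), class = "sift_criteria")
}

# ---- detection ----

#' Detect protein-ligand interactions (SIFt)
#'
#' Computes per-residue counts of six interaction types from a single
#' complex: HYDROPHOBIC (aliphatic C/S pairs), HBOND_DONOR (ligand donates),
#' HBOND_ACCEPTOR (ligand accepts), PI_PI (parallel or T-shaped aromatic
#' stacking), HALOGEN (C-X...acceptor) and IONIC (opposite formal charges).
#' Each interaction instance is attributed to exactly one residue and one
#' type; counts (not booleans) are kept so multiple contacts per residue
#' remain visible. Water residues are ignored here (water bridges belong to
#' trajectory analysis). When a ligand donor carries no explicit hydrogen
#' the donor-angle test is skipped (distance-only), as docking outputs often
#' omit hydrogens.
#'
#' @param cpx A [read_complex()] object.
#' @param criteria A [sift_criteria()].
#' @return A tibble of class `sift_tbl`: `chain`, `resnum`, `resname`,
#'   `interaction`, `count`; only residues with at least one contact appear.
#' @export
detect_interactions <- function(cpx, criteria = sift_criteria()) {
  stopifnot(inherits(cpx, "complex3d"))
  prot <- cpx$protein %>% filter(!.data$is_water)
  lig <- cpx$ligand
  hits <- list()
  add <- function(chain, resno, resname, type, n = 1L) {
    hits[[length(hits) + 1]] <<- tibble(
      chain = chain, resnum = resno, resname = resname,
      interaction = type, count = as.integer(n)
    )
  }
  pxyz <- as.matrix(prot[, c("x", "y", "z")])

  # HYDROPHOBIC
  lap <- lig[lig$apolar, , drop = FALSE]
  pap <- prot[mapply(function(r, a) a %in% (.prot_apolar_sc[[r]] %||% character(0)),
                     prot$resid, prot$elety), , drop = FALSE]
  if (nrow(lap) > 0 && nrow(pap) > 0) {
    d <- cross_dist(as.matrix(lap[, c("x", "y", "z")]),
                    as.matrix(pap[, c("x", "y", "z")]))
    idx <- which(d <= criteria$hydrophobic_dist, arr.ind = TRUE)
    for (r in seq_len(nrow(idx))) {
      p <- pap[idx[r, 2], ]
      add(p$chain, p$resno, p$resid, "HYDROPHOBIC")
    }
  }

  # HBOND: ligand donor -> protein acceptor
  pacc <- prot[prot$elety %in% c("O", "OXT") |
                 mapply(function(r, a) a %in% (.prot_acceptor_sc[[r]] %||% character(0)),
                        prot$resid, prot$elety), , drop = FALSE]
  ldon <- lig[lig$donor, , drop = FALSE]
  if (nrow(ldon) > 0 && nrow(pacc) > 0) {
    d <- cross_dist(as.matrix(ldon[, c("x", "y", "z")]),
                    as.matrix(pacc[, c("x", "y", "z")]))
    idx <- which(d <= criteria$hbond_dist, arr.ind = TRUE)
    for (r in seq_len(nrow(idx))) {
      don <- ldon[idx[r, 1], ]
      acc <- pacc[idx[r, 2], ]
      hxyz <- don$explicit_h[[1]]
      ok <- TRUE
      if (!is.null(hxyz)) {
        angs <- apply(hxyz, 1, function(h) {
          angle_deg(c(don$x, don$y, don$z), h, c(acc$x, acc$y, acc$z))
        })
        ok <- any(angs >= criteria$hbond_angle)
      }
      if (ok) add(acc$chain, acc$resno, acc$resid, "HBOND_DONOR")
    }
  }

  # HBOND: protein donor -> ligand acceptor (distance-only: PDB files
  # usually carry no hydrogens, so the angle test is downgraded)
  pdon <- prot[(prot$elety == "N" & prot$resid != "PRO") |
                 mapply(function(r, a) a %in% (.prot_donor_sc[[r]] %||% character(0)),
                        prot$resid, prot$elety), , drop = FALSE]
  lacc <- lig[lig$acceptor, , drop = FALSE]
  if (nrow(lacc) > 0 && nrow(pdon) > 0) {
    d <- cross_dist(as.matrix(lacc[, c("x", "y", "z")]),
                    as.matrix(pdon[, c("x", "y", "z")]))
    idx <- which(d <= criteria$hbond_dist, arr.ind = TRUE)
    for (r in seq_len(nrow(idx))) {
      p <- pdon[idx[r, 2], ]
      add(p$chain, p$resno, p$resid, "HBOND_ACCEPTOR")
    }
  }

  # PI_PI
  prings <- protein_rings(prot)
  if (length(cpx$lig_rings) > 0 && length(prings) > 0) {
    for (lr in cpx$lig_rings) {
      lxyz <- as.matrix(lig[lig$idx %in% lr, c("x", "y", "z")])
      lc <- colMeans(lxyz)
      ln <- plane_normal(lxyz)
      for (pr in prings) {
        pc <- colMeans(pr$xyz)
        if (vec_norm(lc - pc) > criteria$pipi_dist) next
        ang <- normal_angle(ln, plane_normal(pr$xyz))
        if (ang <= criteria$pipi_parallel ||
            (ang >= criteria$pipi_tshape[1] && ang <= criteria$pipi_tshape[2])) {
          add(pr$chain, pr$resno, pr$resname, "PI_PI")
        }
      }
    }
  }

  # HALOGEN
  lx <- lig[lig$halogen, , drop = FALSE]
  if (nrow(lx) > 0 && nrow(pacc) > 0) {
    d <- cross_dist(as.matrix(lx[, c("x", "y", "z")]),
                    as.matrix(pacc[, c("x", "y", "z")]))
    idx <- which(d <= criteria$halogen_dist, arr.ind = TRUE)
    for (r in seq_len(nrow(idx))) {
      xa <- lx[idx[r, 1], ]
      acc <- pacc[idx[r, 2], ]
      nb <- cpx$lig_bonds
      cnb <- c(nb$a2[nb$a1 == xa$idx], nb$a1[nb$a2 == xa$idx])
      cnb <- cnb[lig$elem[match(cnb, lig$idx)] == "C"]
      if (length(cnb) == 0) next
      cxyz <- as.numeric(lig[lig$idx == cnb[1], c("x", "y", "z")])
      ang <- angle_deg(cxyz, c(xa$x, xa$y, xa$z), c(acc$x, acc$y, acc$z))
      if (ang >= criteria$halogen_angle) {
        add(acc$chain, acc$resno, acc$resid, "HALOGEN")
      }
    }
  }

  # IONIC
  lch <- lig[lig$charge != 0, , drop = FALSE]
  if (nrow(lch) > 0) {
    pch <- list()
    for (rn in names(.prot_charge_sc)) {
      def <- .prot_charge_sc[[rn]]
      sel <- prot$resid == rn & prot$elety %in% def$atoms
      if (any(sel)) {
        q <- prot[sel, ]
        q$pcharge <- def$charge
        pch[[length(pch) + 1]] <- q
      }
    }
    pch <- bind_rows(pch)
    if (!is.null(pch) && nrow(pch) > 0) {
      d <- cross_dist(as.matrix(lch[, c("x", "y", "z")]),
                      as.matrix(pch[, c("x", "y", "z")]))
      idx <- which(d <= criteria$ionic_dist, arr.ind = TRUE)
      for (r in seq_len(nrow(idx))) {
        if (sign(lch$charge[idx[r, 1]]) * sign(pch$pcharge[idx[r, 2]]) < 0) {
          p <- pch[idx[r, 2], ]
          add(p$chain, p$resno, p$resid, "IONIC")
        }
      }
    }
  }

  out <- if (length(hits) == 0) {
    tibble(chain = character(), resnum = integer(), resname = character(),
           interaction = character(), count = integer())
  } else {
    bind_rows(hits) %>%
      group_by(.data$chain, .data$resnum, .data$resname, .data$interaction) %>%
      summarise(count = sum(.data$count), .groups = "drop") %>%
      arrange(.data$chain, .data$resnum, .data$interaction)
  }
  class(out) <- c("sift_tbl", class(out))
  out
}

#' Plot a SIFt matrix as a residue-by-interaction heatmap
#'
#' @param sift A `sift_tbl` from [detect_interactions()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_sift <- function(sift, ...) {
  stopifnot(nrow(sift) > 0)
  sift$res <- paste0(sift$resname, sift$resnum, " (", sift$chain, ")")
  ggplot2::ggplot(sift, ggplot2::aes(x = .data$interaction, y = .data$res,
                                     fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = NULL, y = NULL, fill = "contacts") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.sift_tbl <- function(object, ...) plot_sift(object, ...)
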