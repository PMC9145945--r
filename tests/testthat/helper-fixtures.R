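# Shared fixtures, memoized so expensive corpus generation and ensemble
# training run once per test session.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# Small corpus + ensemble for unit tests.
small_fx <- function() memo("small_fx", {
  suppressWarnings(gen_corpus(fixture_spec(
    n_actives = 60, n_inactives = 60, n_decoy_pool = 400,
    decoys_per_active = 3, n_library = 100, n_planted = 10
  )))
})

small_model <- function() memo("small_model", {
  train_ensemble(small_fx()$split, rf_config(n_estimators = 150))
})

# Study-scale corpus + ensemble (the separable fixture at n = 600, 1:1)
# shared by the ensemble property tests and the acceptance suite.
big_fx <- function() memo("big_fx", {
  suppressWarnings(gen_corpus(fixture_spec(
    n_actives = 300, n_inactives = 300, n_decoy_pool = 1200,
    decoys_per_active = 5, n_library = 500, n_planted = 25
  )))
})

big_model <- function() memo("big_model", {
  train_ensemble(big_fx()$split)
})

big_screen <- function() memo("big_screen", {
  consensus_screen(big_model(), big_fx()$library, k = 1, all = TRUE)
})

# ---- hand-built complexes ----

# Minimal protein atom table in the shape detect_interactions() expects.
make_prot <- function(resname, resno, elety, elem, xyz, chain = "A") {
  tibble::tibble(
    chain = chain, resno = as.integer(resno), insert = "",
    elety = elety, resid = resname, elem = elem,
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    is_water = resname %in% c("HOH", "WAT", "TIP3", "SOL")
  )
}

make_lig <- function(elem, xyz, charge = 0L, nH = 0L, donor = NULL,
                     acceptor = NULL, apolar = NULL, halogen = NULL,
                     aromatic = FALSE, rings = list(),
                     bonds = NULL) {
  n <- length(elem)
  atoms <- tibble::tibble(
    idx = seq_len(n), elem = elem,
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    charge = rep_len(charge, n), nH = rep_len(nH, n),
    aromatic = rep_len(aromatic, n),
    donor = donor %||% (elem %in% c("N", "O") & rep_len(nH, n) >= 1),
    acceptor = acceptor %||% (elem %in% c("N", "O")),
    apolar = apolar %||% (elem %in% c("C", "S") & !rep_len(aromatic, n)),
    halogen = halogen %||% (elem %in% c("Cl", "Br", "I")),
    explicit_h = lapply(seq_len(n), function(i) NULL)
  )
  if (is.null(bonds)) {
    bonds <- tibble::tibble(a1 = integer(), a2 = integer(),
                            order = integer(), in_ring = logical())
  }
  list(atoms = atoms, bonds = bonds, rings = rings)
}

make_cpx <- function(prot, lig) {
  pdlscreen:::new_complex3d(prot, lig$atoms, lig$bonds, lig$rings)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Apply a rigid motion to every coordinate of a complex (protein, ligand
# and any explicit ligand hydrogens).
transform_cpx <- function(cpx, motion) {
  pm <- pdlscreen:::apply_rigid(as.matrix(cpx$protein[, c("x", "y", "z")]),
                                motion)
  cpx$protein$x <- pm[, 1]; cpx$protein$y <- pm[, 2]; cpx$protein$z <- pm[, 3]
  lm <- pdlscreen:::apply_rigid(as.matrix(cpx$ligand[, c("x", "y", "z")]),
                                motion)
  cpx$ligand$x <- lm[, 1]; cpx$ligand$y <- lm[, 2]; cpx$ligand$z <- lm[, 3]
  cpx$ligand$explicit_h <- lapply(cpx$ligand$explicit_h, function(h) {
    if (is.null(h)) NULL else pdlscreen:::apply_rigid(h, motion)
  })
  cpx
}

# ---- independent brute-force SIFt oracle ----
# Plain nested loops and cross-product ring normals: a deliberately
# different computation path from the package's vectorized detectors.

oracle_sift <- function(cpx, criteria = sift_criteria()) {
  prot <- cpx$protein[!cpx$protein$is_water, , drop = FALSE]
  lig <- cpx$ligand
  rows <- list()
  add <- function(chain, resno, resname, type) {
    rows[[length(rows) + 1]] <<- data.frame(
      chain = chain, resnum = resno, resname = resname,
      interaction = type, stringsAsFactors = FALSE
    )
  }
  d3 <- function(a, b) sqrt(sum((a - b)^2))
  pxyz <- function(i) as.numeric(prot[i, c("x", "y", "z")])
  lxyz <- function(i) as.numeric(lig[i, c("x", "y", "z")])
  ang <- function(a, b, c) pdlscreen:::angle_deg(a, b, c)

  apolar_tab <- pdlscreen:::.prot_apolar_sc
  acc_tab <- pdlscreen:::.prot_acceptor_sc
  don_tab <- pdlscreen:::.prot_donor_sc
  chg_tab <- pdlscreen:::.prot_charge_sc

  is_pacc <- function(i) {
    prot$elety[i] %in% c("O", "OXT") ||
      prot$elety[i] %in% (acc_tab[[prot$resid[i]]] %||% character(0))
  }
  for (j in seq_len(nrow(prot))) {
    for (i in seq_len(nrow(lig))) {
      d <- d3(lxyz(i), pxyz(j))
      # hydrophobic
      if (lig$apolar[i] &&
          prot$elety[j] %in% (apolar_tab[[prot$resid[j]]] %||% character(0)) &&
          d <= criteria$hydrophobic_dist) {
        add(prot$chain[j], prot$resno[j], prot$resid[j], "HYDROPHOBIC")
      }
      # ligand donor -> protein acceptor
      if (lig$donor[i] && is_pacc(j) && d <= criteria$hbond_dist) {
        h <- lig$explicit_h[[i]]
        ok <- TRUE
        if (!is.null(h)) {
          ok <- any(apply(h, 1, function(hh) {
            ang(lxyz(i), hh, pxyz(j)) >= criteria$hbond_angle
          }))
        }
        if (ok) add(prot$chain[j], prot$resno[j], prot$resid[j], "HBOND_DONOR")
      }
      # protein donor -> ligand acceptor
      if (lig$acceptor[i] && d <= criteria$hbond_dist &&
          ((prot$elety[j] == "N" && prot$resid[j] != "PRO") ||
           prot$elety[j] %in% (don_tab[[prot$resid[j]]] %||% character(0)))) {
        add(prot$chain[j], prot$resno[j], prot$resid[j], "HBOND_ACCEPTOR")
      }
      # halogen
      if (lig$halogen[i] && is_pacc(j) && d <= criteria$halogen_dist) {
        nb <- cpx$lig_bonds
        cn <- c(nb$a2[nb$a1 == lig$idx[i]], nb$a1[nb$a2 == lig$idx[i]])
        cn <- cn[lig$elem[match(cn, lig$idx)] == "C"]
        if (length(cn) > 0) {
          cx <- as.numeric(lig[lig$idx == cn[1], c("x", "y", "z")])
          if (ang(cx, lxyz(i), pxyz(j)) >= criteria$halogen_angle) {
            add(prot$chain[j], prot$resno[j], prot$resid[j], "HALOGEN")
          }
        }
      }
      # ionic
      if (lig$charge[i] != 0) {
        def <- chg_tab[[prot$resid[j]]]
        if (!is.null(def) && prot$elety[j] %in% def$atoms &&
            sign(def$charge) * sign(lig$charge[i]) < 0 &&
            d <= criteria$ionic_dist) {
          add(prot$chain[j], prot$resno[j], prot$resid[j], "IONIC")
        }
      }
    }
  }
  # pi-pi with cross-product normals
  cross3 <- function(u, v) c(u[2]*v[3]-u[3]*v[2], u[3]*v[1]-u[1]*v[3],
                             u[1]*v[2]-u[2]*v[1])
  ring_normal <- function(xyz) {
    v1 <- xyz[2, ] - xyz[1, ]; v2 <- xyz[3, ] - xyz[1, ]
    n <- cross3(v1, v2); n / sqrt(sum(n^2))
  }
  prings <- pdlscreen:::protein_rings(prot)
  for (lr in cpx$lig_rings) {
    lx <- as.matrix(lig[lig$idx %in% lr, c("x", "y", "z")])
    for (pr in prings) {
      dc <- d3(colMeans(lx), colMeans(pr$xyz))
      if (dc > criteria$pipi_dist) next
      n1 <- ring_normal(lx); n2 <- ring_normal(pr$xyz)
      a <- acos(min(1, abs(sum(n1 * n2)))) * 180 / pi
      if (a <= criteria$pipi_parallel ||
          (a >= criteria$pipi_tshape[1] && a <= criteria$pipi_tshape[2])) {
        add(pr$chain, pr$resno, pr$resname, "PI_PI")
      }
    }
  }
  if (length(rows) == 0) {
    return(tibble::tibble(chain = character(), resnum = integer(),
                          resname = character(), interaction = character(),
                          count = integer()))
  }
  out <- do.call(rbind, rows)
  out <- stats::aggregate(list(count = rep(1L, nrow(out))),
                          by = out[c("chain", "resnum", "resname",
                                     "interaction")], FUN = sum)
  out <- out[order(out$chain, out$resnum, out$interaction), ]
  tibble::as_tibble(out)
}

# Random micro-complex: a handful of residues and ligand atoms thrown into
# a 10 A box, plus (sometimes) a planar aromatic ring pair.
random_micro_cpx <- function() {
  res_defs <- list(
    ASP = list(elety = c("CB", "CG", "OD1", "OD2"), elem = c("C","C","O","O")),
    LEU = list(elety = c("CB", "CG", "CD1", "CD2"), elem = c("C","C","C","C")),
    SER = list(elety = c("CB", "OG"), elem = c("C", "O")),
    LYS = list(elety = c("CB", "CG", "CD", "CE", "NZ"),
               elem = c("C","C","C","C","N")),
    GLN = list(elety = c("CB", "CG", "CD", "OE1", "NE2"),
               elem = c("C","C","C","O","N"))
  )
  n_res <- sample(2:4, 1)
  prot <- list()
  for (r in seq_len(n_res)) {
    nm <- sample(names(res_defs), 1)
    def <- res_defs[[nm]]
    ctr <- runif(3, -5, 5)
    xyz <- sweep(matrix(rnorm(3 * length(def$elety), sd = 1.2), ncol = 3),
                 2, ctr, "+")
    prot[[r]] <- make_prot(nm, r, def$elety, def$elem, xyz)
  }
  rings <- list()
  hex <- NULL
  if (runif(1) < 0.5) {
    # planar TYR ring + planar ligand ring at random separation/orientation
    th <- seq(0, 2 * pi, length.out = 7)[1:6]
    base <- cbind(1.39 * cos(th), 1.39 * sin(th), 0)
    ctr <- runif(3, -2, 2)
    prot[[n_res + 1]] <- make_prot(
      "TYR", n_res + 1,
      c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"), rep("C", 6),
      sweep(base, 2, ctr, "+")
    )
    motion <- pdlscreen:::random_rigid_motion()
    motion$translation <- ctr + runif(3, -4, 4)
    hex <- pdlscreen:::apply_rigid(base, motion)
  }
  prot <- do.call(rbind, prot)

  n_lig <- sample(3:6, 1)
  elem <- sample(c("C", "N", "O", "Cl"), n_lig, replace = TRUE,
                 prob = c(0.5, 0.2, 0.2, 0.1))
  xyz <- matrix(runif(3 * n_lig, -6, 6), ncol = 3)
  charge <- ifelse(runif(n_lig) < 0.15, sample(c(-1L, 1L), n_lig, TRUE), 0L)
  nH <- ifelse(elem %in% c("N", "O"), sample(0:2, n_lig, TRUE), 0L)
  bonds <- NULL
  if (any(elem == "Cl") && n_lig >= 2) {
    cl <- which(elem == "Cl")[1]
    partner <- which(elem == "C")[1]
    if (!is.na(partner)) {
      bonds <- tibble::tibble(a1 = cl, a2 = partner, order = 1L,
                              in_ring = FALSE)
    }
  }
  if (!is.null(hex)) {
    xyz <- rbind(xyz, hex)
    elem <- c(elem, rep("C", 6))
    charge <- c(charge, rep(0L, 6))
    nH <- c(nH, rep(0L, 6))
    rings <- list(n_lig + 1:6)
  }
  lig <- make_lig(elem, xyz, charge = charge, nH = nH,
                  aromatic = c(rep(FALSE, n_lig),
                               rep(TRUE, length(elem) - n_lig)),
                  rings = rings, bonds = bonds)
  make_cpx(prot, lig)
}

sift_equal <- function(a, b) {
  key <- function(x) {
    x <- x[order(x$chain, x$resnum, x$resname, x$interaction), ]
    paste(x$chain, x$resnum, x$resname, x$interaction, x$count,
          collapse = ";")
  }
  identical(key(as.data.frame(a)), key(as.data.frame(b)))
}
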