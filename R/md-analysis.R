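# MD trajectory post-analysis: ligand/backbone RMSD versus the first frame
# and normalized per-residue contact persistence.

#' Construct a trajectory object
#'
#' A trajectory is an ordered set of coordinate frames over the fixed atom
#' set of a [read_complex()] template (protein atoms first, then ligand
#' atoms, in template order).
#'
#' @param cpx `complex3d` template carrying atom metadata and topology.
#' @param xyz Numeric matrix, one row per frame, `3 * n_atoms` columns
#'   (x1, y1, z1, x2, ...).
#' @param timestep_ps Time between stored frames in ps (default 5.0).
#' @return An object of class `trajectory`.
#' @export
as_trajectory <- function(cpx, xyz, timestep_ps = 5.0) {
  stopifnot(inherits(cpx, "complex3d"), timestep_ps > 0)
  n_atoms <- nrow(cpx$protein) + nrow(cpx$ligand)
  xyz <- as.matrix(xyz)
  if (ncol(xyz) != 3 * n_atoms) {
    abort(paste0("xyz must have ", 3 * n_atoms, " columns (3 x atoms), got ",
                 ncol(xyz)))
  }
  structure(list(cpx = cpx, xyz = xyz, timestep_ps = timestep_ps),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("<trajectory>", nrow(x$xyz), "frames x",
      ncol(x$xyz) / 3, "atoms, dt =", x$timestep_ps, "ps\n")
  invisible(x)
}

n_frames <- function(traj) nrow(traj$xyz)

# Column indices (into the frame vector) of the given atom rows.
xyz_cols <- function(atom_rows) {
  as.vector(rbind(3 * atom_rows - 2, 3 * atom_rows - 1, 3 * atom_rows))
}

lig_offset <- function(traj) nrow(traj$cpx$protein)

selection_rows <- function(traj, selection = c("ligand", "backbone", "protein")) {
  selection <- match.arg(selection)
  np <- nrow(traj$cpx$protein)
  rows <- switch(selection,
    ligand = np + which(traj$cpx$ligand$elem != "H"),
    backbone = which(!traj$cpx$protein$is_water &
                       traj$cpx$protein$elety %in% c("N", "CA", "C", "O")),
    protein = which(!traj$cpx$protein$is_water)
  )
  if (length(rows) == 0) abort(paste0("empty selection: ", selection))
  rows
}

frame_coords <- function(traj, f, rows = NULL) {
  v <- traj$xyz[f, ]
  m <- matrix(v, ncol = 3, byrow = TRUE)
  if (!is.null(rows)) m <- m[rows, , drop = FALSE]
  m
}

#' RMSD of a selection versus the first frame
#'
#' `RMSD_t = sqrt(mean_i |x_i(t) - x_i(0)|^2)` over the selected atoms.
#' With `superpose = TRUE` every frame is first least-squares superposed
#' onto frame 1 using the protein backbone (N, CA, C, O), so ligand RMSD
#' measures motion relative to the binding site rather than global drift.
#'
#' @param traj A [as_trajectory()] object with at least 2 frames.
#' @param selection `"ligand"` (heavy atoms), `"backbone"` or `"protein"`.
#' @param superpose Superpose on the protein backbone first (default TRUE).
#' @return Tibble `time_ps`, `rmsd_A`; the first frame has RMSD 0.
#' @export
compute_rmsd <- function(traj, selection = c("ligand", "backbone", "protein"),
                         superpose = TRUE) {
  selection <- match.arg(selection)
  stopifnot(n_frames(traj) >= 2)
  sel <- selection_rows(traj, selection)
  bb <- selection_rows(traj, "backbone")
  ref_sel <- frame_coords(traj, 1, sel)
  ref_bb <- frame_coords(traj, 1, bb)
  vals <- vapply(seq_len(n_frames(traj)), function(f) {
    cur_sel <- frame_coords(traj, f, sel)
    if (superpose) {
      fit <- kabsch(frame_coords(traj, f, bb), ref_bb)
      cur_sel <- apply_kabsch(cur_sel, fit)
    }
    sqrt(mean(rowSums((cur_sel - ref_sel)^2)))
  }, numeric(1))
  tibble(time_ps = (seq_len(n_frames(traj)) - 1) * traj$timestep_ps,
         rmsd_A = vals)
}

#' Full RMSD series for a trajectory
#'
#' Convenience wrapper producing the standard three series: backbone RMSD,
#' backbone-superposed ligand RMSD and raw (unsuperposed) ligand RMSD, all
#' versus the first frame.
#'
#' @param traj A trajectory.
#' @return Tibble `time_ps`, `rmsd_ligand_A`, `rmsd_ligand_raw_A`,
#'   `rmsd_backbone_A`, of class `rmsd_series`.
#' @export
rmsd_series <- function(traj) {
  lig <- compute_rmsd(traj, "ligand", superpose = TRUE)
  lig_raw <- compute_rmsd(traj, "ligand", superpose = FALSE)
  bb <- compute_rmsd(traj, "backbone", superpose = TRUE)
  out <- tibble(
    time_ps = lig$time_ps,
    rmsd_ligand_A = lig$rmsd_A,
    rmsd_ligand_raw_A = lig_raw$rmsd_A,
    rmsd_backbone_A = bb$rmsd_A
  )
  class(out) <- c("rmsd_series", class(out))
  out
}

#' @export
autoplot.rmsd_series <- function(object, ...) {
  long <- tidyr::pivot_longer(object, -"time_ps",
                              names_to = "series", values_to = "rmsd_A")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time_ps, y = .data$rmsd_A,
                                     color = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (ps)", y = "RMSD (Å)", color = NULL) +
    ggplot2::theme_minimal()
}

# Rebuild a complex3d with the coordinates of frame f.
complex_at_frame <- function(traj, f) {
  cpx <- traj$cpx
  np <- nrow(cpx$protein)
  m <- frame_coords(traj, f)
  cpx$protein$x <- m[seq_len(np), 1]
  cpx$protein$y <- m[seq_len(np), 2]
  cpx$protein$z <- m[seq_len(np), 3]
  nl <- nrow(cpx$ligand)
  cpx$ligand$x <- m[np + seq_len(nl), 1]
  cpx$ligand$y <- m[np + seq_len(nl), 2]
  cpx$ligand$z <- m[np + seq_len(nl), 3]
  # explicit-H coordinates move with the frame
  cpx$ligand$explicit_h <- map(seq_len(nl), function(i) {
    adj_h <- which(cpx$ligand$elem == "H" &
                     cpx$ligand$idx %in% c(
                       cpx$lig_bonds$a2[cpx$lig_bonds$a1 == cpx$ligand$idx[i]],
                       cpx$lig_bonds$a1[cpx$lig_bonds$a2 == cpx$ligand$idx[i]]
                     ))
    if (length(adj_h)) as.matrix(cpx$ligand[adj_h, c("x", "y", "z")]) else NULL
  })
  cpx
}

#' Per-residue contact persistence over a trajectory
#'
#' Applies [detect_interactions()] to every frame and normalizes: the
#' persistence of a (residue, category) pair is the summed per-frame contact
#' count divided by the number of frames. A value of 1.0 means one such
#' contact in every frame; values above 1.0 mean multiple simultaneous
#' contacts of the same subtype on that residue. Categories follow the
#' 4-way MD convention: `HBOND` (donor + acceptor), `HYDROPHOBIC`
#' (hydrophobic + aromatic stacking), `IONIC`, and `WATER_BRIDGE` (a water
#' oxygen simultaneously within `hbond_dist` of a ligand N/O and a protein
#' N/O, distance-only).
#'
#' @param traj A trajectory.
#' @param criteria [sift_criteria()], shared with the static SIFt.
#' @return Tibble `chain`, `resnum`, `resname`, `category`, `persistence`,
#'   of class `persistence_tbl`.
#' @export
compute_persistence <- function(traj, criteria = sift_criteria()) {
  stopifnot(n_frames(traj) >= 1)
  per_frame <- map(seq_len(n_frames(traj)), function(f) {
    cpx <- complex_at_frame(traj, f)
    sift <- detect_interactions(cpx, criteria)
    sift$category <- dplyr::case_when(
      sift$interaction %in% c("HBOND_DONOR", "HBOND_ACCEPTOR") ~ "HBOND",
      sift$interaction %in% c("HYDROPHOBIC", "PI_PI") ~ "HYDROPHOBIC",
      sift$interaction == "IONIC" ~ "IONIC",
      TRUE ~ NA_character_
    )
    sift <- sift[!is.na(sift$category), , drop = FALSE]
    wb <- water_bridges(cpx, criteria)
    bind_rows(
      sift %>% group_by(.data$chain, .data$resnum, .data$resname,
                        .data$category) %>%
        summarise(count = sum(.data$count), .groups = "drop"),
      wb
    )
  })
  out <- bind_rows(per_frame) %>%
    group_by(.data$chain, .data$resnum, .data$resname, .data$category) %>%
    summarise(persistence = sum(.data$count) / n_frames(traj),
              .groups = "drop") %>%
    arrange(.data$chain, .data$resnum, .data$category)
  class(out) <- c("persistence_tbl", class(out))
  out
}

# Water-mediated bridges: water O within hbond_dist of both a ligand N/O
# and a protein N/O (distance-only), attributed to the protein residue.
water_bridges <- function(cpx, criteria) {
  empty <- tibble(chain = character(), resnum = integer(),
                  resname = character(), category = character(),
                  count = integer())
  waters <- cpx$protein %>%
    filter(.data$is_water, .data$elem == "O")
  if (nrow(waters) == 0) return(empty)
  lig_no <- cpx$ligand %>% filter(.data$elem %in% c("N", "O"))
  prot_no <- cpx$protein %>%
    filter(!.data$is_water, .data$elem %in% c("N", "O"))
  if (nrow(lig_no) == 0 || nrow(prot_no) == 0) return(empty)
  wxyz <- as.matrix(waters[, c("x", "y", "z")])
  dl <- cross_dist(wxyz, as.matrix(lig_no[, c("x", "y", "z")]))
  dp <- cross_dist(wxyz, as.matrix(prot_no[, c("x", "y", "z")]))
  rows <- list()
  for (w in seq_len(nrow(waters))) {
    if (!any(dl[w, ] <= criteria$hbond_dist)) next
    near <- which(dp[w, ] <= criteria$hbond_dist)
    if (length(near) == 0) next
    res <- prot_no[near, ] %>%
      distinct(.data$chain, .data$resno, .data$resid)
    rows[[length(rows) + 1]] <- tibble(
      chain = res$chain, resnum = res$resno, resname = res$resid,
      category = "WATER_BRIDGE", count = 1L
    )
  }
  if (length(rows) == 0) return(empty)
  bind_rows(rows) %>%
    group_by(.data$chain, .data$resnum, .data$resname, .data$category) %>%
    summarise(count = sum(.data$count), .groups = "drop")
}

#' @export
autoplot.persistence_tbl <- function(object, ...) {
  object$res <- paste0(object$resname, object$resnum)
  ggplot2::ggplot(object, ggplot2::aes(x = .data$res, y = .data$persistence,
                                       fill = .data$category)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "interaction fraction", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

# ---- trajectory I/O ----

#' Write a trajectory as a multi-model PDB
#'
#' Protein atoms are written as ATOM records, ligand atoms as HETATM with
#' residue name `LIG`; one MODEL/ENDMDL block per frame.
#'
#' @param traj A trajectory.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  cpx <- traj$cpx
  np <- nrow(cpx$protein)
  nl <- nrow(cpx$ligand)
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(n_frames(traj))) {
    m <- frame_coords(traj, f)
    writeLines(sprintf("MODEL     %4d", f), con)
    lines <- character(np + nl)
    for (i in seq_len(np)) {
      p <- cpx$protein[i, ]
      lines[i] <- pdb_atom_line("ATOM", i, p$elety, p$resid, p$chain, p$resno,
                                m[i, 1], m[i, 2], m[i, 3], p$elem)
    }
    for (j in seq_len(nl)) {
      l <- cpx$ligand[j, ]
      nm <- paste0(l$elem, j)
      lines[np + j] <- pdb_atom_line("HETATM", np + j, nm, "LIG", "L", 1,
                                     m[np + j, 1], m[np + j, 2], m[np + j, 3],
                                     l$elem)
    }
    writeLines(lines, con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

pdb_atom_line <- function(rec, serial, name, resname, chain, resno,
                          x, y, z, elem) {
  name_fmt <- if (nchar(name) < 4) sprintf(" %-3s", name) else sprintf("%-4s", name)
  sprintf("%-6s%5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          rec, serial %% 100000, name_fmt, resname, chain, resno,
          x, y, z, 1.0, 0.0, elem)
}

#' Read a trajectory from a multi-model PDB or XYZ file
#'
#' For PDB input the atom metadata come from the file itself; ligand atoms
#' are identified by residue name. Providing the original ligand pose SDF
#' restores the full bond graph (donors, rings, apolar typing) for
#' persistence analysis; without it, typing falls back to elements only.
#' XYZ input carries no metadata and therefore requires a `complex3d`
#' template whose atom order matches the file.
#'
#' @param path Multi-model PDB (`.pdb`) or XYZ (`.xyz`) trajectory.
#' @param ligand_resname Residue name of the ligand in PDB input.
#' @param ligand_sdf Optional SDF with the ligand topology (PDB input).
#' @param template `complex3d` template (required for XYZ input).
#' @param timestep_ps Time between stored frames (ps).
#' @return A trajectory object.
#' @export
read_trajectory <- function(path, ligand_resname = "LIG", ligand_sdf = NULL,
                            template = NULL, timestep_ps = 5.0) {
  stopifnot(file.exists(path))
  if (grepl("\\.xyz$", path, ignore.case = TRUE)) {
    if (is.null(template)) abort("XYZ trajectories require a complex3d template")
    xyz <- read_xyz_frames(path)
    return(as_trajectory(template, xyz, timestep_ps))
  }
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  atom <- as_tibble(pdb$atom)
  is_lig <- atom$resid == ligand_resname
  if (!any(is_lig)) abort(paste0("no ligand atoms with resname ", ligand_resname))
  ord <- c(which(!is_lig), which(is_lig))
  prot <- protein_table(pdb$atom[!is_lig, , drop = FALSE])
  lig_rows <- atom[is_lig, , drop = FALSE]

  if (!is.null(ligand_sdf)) {
    lig <- read_ligand_pose(ligand_sdf)
    if (nrow(lig$atoms) != nrow(lig_rows)) {
      abort("ligand SDF atom count does not match trajectory ligand atoms")
    }
    cpx <- new_complex3d(prot, lig$atoms, lig$bonds, lig$rings)
  } else {
    elem <- ifelse(nzchar(lig_rows$elesy), lig_rows$elesy,
                   substr(gsub("[0-9]", "", lig_rows$elety), 1, 1))
    atoms <- tibble(
      idx = seq_len(nrow(lig_rows)), elem = elem,
      x = lig_rows$x, y = lig_rows$y, z = lig_rows$z,
      charge = 0L, nH = 0L, aromatic = FALSE,
      donor = FALSE, acceptor = elem %in% c("N", "O"),
      apolar = elem %in% c("C", "S"), halogen = elem %in% c("Cl", "Br", "I"),
      explicit_h = map(seq_len(nrow(lig_rows)), ~NULL)
    )
    cpx <- new_complex3d(prot, atoms,
                         tibble(a1 = integer(), a2 = integer(),
                                order = integer(), in_ring = logical()),
                         list())
  }
  # frame matrix in template order (protein block then ligand block)
  xyz <- pdb$xyz[, xyz_cols(ord), drop = FALSE]
  as_trajectory(cpx, xyz, timestep_ps)
}

read_xyz_frames <- function(path) {
  lines <- readLines(path, warn = FALSE)
  frames <- list()
  i <- 1
  while (i <= length(lines)) {
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n)) abort("malformed XYZ file")
    block <- lines[(i + 2):(i + 1 + n)]
    parts <- stringr::str_split(trimws(block), "\\s+")
    coords <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
    frames[[length(frames) + 1]] <- as.vector(t(coords))
    i <- i + 2 + n
  }
  do.call(rbind, frames)
}
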