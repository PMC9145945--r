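# Docking adapter: conformer embedding, an AutoDock Vina driver with a
# deterministic mock backend for tests, and a Vina log parser.

#' The PDL1-dimer docking search box
#'
#' Defaults are the published search-space coordinates for the PDL1 dimer
#' tunnel of the 5N2F crystal structure.
#'
#' @param center Box center (x, y, z), Angstrom.
#' @param dims Box edge lengths (x, y, z), Angstrom; must be positive.
#' @return A list of class `docking_box`.
#' @export
docking_box <- function(center = c(31.9429, 12.7403, 133.7878),
                        dims = c(20, 20, 20)) {
  stopifnot(length(center) == 3, length(dims) == 3, all(dims > 0))
  structure(list(center = as.numeric(center), dims = as.numeric(dims)),
            class = "docking_box")
}

#' Embed a 3D conformer for a molecule
#'
#' Generates one 3D conformer through the pluggable conformer backend.
#' The default distance-geometry backend minimizes bond, angle and
#' lower-bound distance constraints from a seeded random start, so the
#' result is fully determined by (molecule, seed). The `obabel` backend
#' shells out to OpenBabel `--gen3d` for force-field-refined geometry; its
#' rotor search is stochastic and not seedable, which is recorded here
#' rather than hidden.
#'
#' @param smiles A single SMILES string.
#' @param seed RNG seed for the distance-geometry start.
#' @param out Optional SDF output path; default a tempfile.
#' @param backend `"dg"` (deterministic distance geometry, default) or
#'   `"obabel"`.
#' @return Path to an SDF file with 3D coordinates and explicit hydrogens,
#'   or `NA` with a warning if embedding fails.
#' @export
embed_conformer <- function(smiles, seed = 20220516, out = NULL,
                            backend = c("dg", "obabel")) {
  backend <- match.arg(backend)
  out <- out %||% tempfile(fileext = ".sdf")
  if (backend == "obabel") {
    ob <- Sys.which("obabel")
    if (!nzchar(ob)) {
      abort("conformer backend unavailable: 'obabel' not found on PATH")
    }
    smi <- tempfile(fileext = ".smi")
    writeLines(paste0(smiles, " conf_seed", seed), smi)
    status <- suppressWarnings(system2(
      ob, c(smi, "-osdf", "-O", shQuote(out), "--gen3d"),
      stdout = FALSE, stderr = FALSE
    ))
    unlink(smi)
    if (status != 0 || !file.exists(out) || file.size(out) == 0) {
      warn(paste0("conformer embedding failed for: ", smiles))
      return(NA_character_)
    }
    return(out)
  }
  parsed <- parse_smiles(c(mol = smiles))
  if (parsed$n_failed > 0) {
    warn(paste0("conformer embedding failed for: ", smiles))
    return(NA_character_)
  }
  g <- mol_graph(parsed$sdf[[1]])
  emb <- dg_embed_graph(g, seed = seed)
  write_sdf(emb$elem, emb$xyz, emb$bonds,
            c(g$charge, rep(0L, length(emb$elem) - length(g$charge))),
            out, title = paste0("conf_seed", seed))
  out
}

#' Run docking through the Vina or mock backend
#'
#' The `vina` backend shells out to an AutoDock Vina binary (box and
#' exhaustiveness passed through; all other parameters left at Vina
#' defaults) and parses its log. The `mock` backend returns scores from an
#' injected `score_table` and exists so the full pipeline is testable
#' without a docking binary.
#'
#' @param ligands Molecule tibble (`id`, `smiles`).
#' @param receptor Receptor file (PDBQT), required for the vina backend.
#' @param box A [docking_box()].
#' @param backend `"mock"` or `"vina"`.
#' @param score_table Named numeric vector id -> best score (kcal/mol) for
#'   the mock backend; ids absent from the table get an error record.
#' @param exhaustiveness Vina exhaustiveness (default 8 = Vina default).
#' @param vina_bin Vina binary name/path.
#' @return Tibble of docking results: `id`, `best_score` (kcal/mol),
#'   `status`, ranked by ascending best score with id tie-break.
#' @export
run_docking <- function(ligands, receptor = NULL, box = docking_box(),
                        backend = c("mock", "vina"), score_table = NULL,
                        exhaustiveness = 8, vina_bin = "vina") {
  backend <- match.arg(backend)
  stopifnot(nrow(ligands) > 0)
  if (backend == "mock") {
    if (is.null(score_table)) abort("mock backend needs a score_table")
    res <- tibble(
      id = ligands$id,
      best_score = unname(score_table[ligands$id]),
      status = ifelse(ligands$id %in% names(score_table), "ok", "error")
    )
  } else {
    if (!nzchar(Sys.which(vina_bin))) {
      abort(paste0(
        "AutoDock Vina binary '", vina_bin, "' not found on PATH. ",
        "Install Vina (https://vina.scripps.edu) or use backend = 'mock'."
      ))
    }
    if (is.null(receptor) || !file.exists(receptor)) {
      abort("vina backend requires an existing receptor file")
    }
    rows <- map(seq_len(nrow(ligands)), function(i) {
      lig_sdf <- embed_conformer(ligands$smiles[i])
      if (is.na(lig_sdf)) {
        return(tibble(id = ligands$id[i], best_score = NA_real_,
                      status = "embed_failed"))
      }
      lig_pdbqt <- tempfile(fileext = ".pdbqt")
      system2("obabel", c(lig_sdf, "-opdbqt", "-O", shQuote(lig_pdbqt)),
              stdout = FALSE, stderr = FALSE)
      log <- tempfile(fileext = ".log")
      args <- c(
        "--receptor", receptor, "--ligand", lig_pdbqt,
        "--center_x", box$center[1], "--center_y", box$center[2],
        "--center_z", box$center[3],
        "--size_x", box$dims[1], "--size_y", box$dims[2],
        "--size_z", box$dims[3],
        "--exhaustiveness", exhaustiveness,
        "--out", tempfile(fileext = ".pdbqt")
      )
      txt <- tryCatch(
        system2(vina_bin, args, stdout = TRUE, stderr = TRUE),
        error = function(e) character(0)
      )
      writeLines(txt, log)
      modes <- tryCatch(parse_vina_log(log), error = function(e) NULL)
      if (is.null(modes) || nrow(modes) == 0) {
        tibble(id = ligands$id[i], best_score = NA_real_,
               status = "parse_failed")
      } else {
        tibble(id = ligands$id[i],
               best_score = modes$affinity_kcal_mol[1], status = "ok")
      }
    })
    res <- bind_rows(rows)
  }
  n_err <- sum(res$status != "ok")
  if (n_err > 0) warn(paste0(n_err, " ligand(s) produced error records"))
  res %>% arrange(.data$best_score, .data$id)
}

#' Parse an AutoDock Vina log
#'
#' Extracts the binding-mode table (`mode | affinity | rmsd l.b. | rmsd
#' u.b.`) from Vina's standard output. Modes are returned sorted ascending
#' by affinity (Vina prints them that way; re-sorted defensively) so the
#' first row is the best pose.
#'
#' @param path Path to a log file, or a character vector of log lines.
#' @return Tibble `mode`, `affinity_kcal_mol`, `rmsd_lb`, `rmsd_ub` with
#'   attribute `best_score`.
#' @export
parse_vina_log <- function(path) {
  lines <- if (length(path) == 1 && file.exists(path))
    readLines(path, warn = FALSE) else path
  hits <- grepl("^\\s*\\d+\\s+-?\\d+(\\.\\d+)?\\s+\\d+(\\.\\d+)?\\s+\\d+(\\.\\d+)?\\s*$",
                lines)
  if (!any(hits)) abort("no Vina binding-mode table found in log")
  fields <- stringr::str_split(trimws(lines[hits]), "\\s+")
  tbl <- tibble(
    mode = map_int(fields, ~ as.integer(.x[1])),
    affinity_kcal_mol = map_dbl(fields, ~ as.numeric(.x[2])),
    rmsd_lb = map_dbl(fields, ~ as.numeric(.x[3])),
    rmsd_ub = map_dbl(fields, ~ as.numeric(.x[4]))
  ) %>% arrange(.data$affinity_kcal_mol, .data$mode)
  attr(tbl, "best_score") <- tbl$affinity_kcal_mol[1]
  tbl
}

#' Write a Vina-style log for a mode table
#'
#' Inverse of [parse_vina_log()], used for round-trip tests and to archive
#' mock results in the format downstream tools expect.
#'
#' @param modes Tibble from [parse_vina_log()] (or same columns).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vina_log <- function(modes, path) {
  header <- c(
    "mode |   affinity | dist from best mode",
    "     | (kcal/mol) | rmsd l.b.| rmsd u.b.",
    "-----+------------+----------+----------"
  )
  body <- sprintf("%4d %11.1f %10.3f %10.3f",
                  modes$mode, modes$affinity_kcal_mol,
                  modes$rmsd_lb, modes$rmsd_ub)
  writeLines(c(header, body), path)
  invisible(path)
}
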