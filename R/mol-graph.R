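# SMILES parsing and molecular-graph extraction on top of the
# ChemmineR/ChemmineOB (OpenBabel) backend. All higher modules go through
# parse_smiles()/mol_graph() so the backend stays swappable in one place.

# Parse a named character vector of SMILES to an SDFset, tolerating
# unparseable records. Returns list(sdf = SDFset of valid records,
# valid = logical mask in input order, n_failed).
# OpenBabel is called in chunks; a failing chunk falls back to per-record
# parsing so one malformed SMILES does not take down its neighbours.
parse_smiles <- function(smiles, chunk = 2000L) {
  stopifnot(length(smiles) > 0)
  ids <- names(smiles) %||% paste0("mol", seq_along(smiles))
  names(smiles) <- ids

  parse_chunk <- function(s) {
    out <- tryCatch(
      suppressWarnings(ChemmineR::smiles2sdf(s)),
      error = function(e) NULL
    )
    if (!is.null(out) && length(out) == length(s) &&
        all(ChemmineR::validSDF(out))) {
      return(out)
    }
    # Per-record fallback: identify the offenders.
    one <- lapply(seq_along(s), function(i) {
      tryCatch({
        x <- suppressWarnings(ChemmineR::smiles2sdf(s[i]))
        if (length(x) == 1 && ChemmineR::validSDF(x)[1]) x[[1]] else NULL
      }, error = function(e) NULL)
    })
    ok <- !vapply(one, is.null, logical(1))
    if (!any(ok)) return(NULL)
    sdfs <- new("SDFset", SDF = one[ok], ID = names(s)[ok])
    sdfs
  }

  idx <- split(seq_along(smiles), ceiling(seq_along(smiles) / chunk))
  parts <- lapply(idx, function(i) parse_chunk(smiles[i]))
  parts <- parts[!vapply(parts, is.null, logical(1))]
  if (length(parts) == 0) {
    return(list(sdf = NULL, valid = rep(FALSE, length(smiles)),
                n_failed = length(smiles)))
  }
  sdf <- if (length(parts) == 1) parts[[1]] else {
    all_sdf <- unlist(lapply(parts, function(p) p@SDF), recursive = FALSE)
    all_id <- unlist(lapply(parts, ChemmineR::sdfid))
    new("SDFset", SDF = all_sdf, ID = all_id)
  }
  got <- ChemmineR::sdfid(sdf)
  valid <- ids %in% got
  list(sdf = sdf, valid = valid, n_failed = sum(!valid))
}

# Standard valences used to infer implicit hydrogen counts on heavy atoms
# when explicit hydrogens are absent (the usual case for OpenBabel SDF
# output from SMILES).
.default_valence <- c(
  C = 4, N = 3, O = 2, S = 2, P = 3, F = 1, Cl = 1, Br = 1, I = 1, B = 3,
  H = 1
)

# Extract a light-weight molecular graph from a single ChemmineR SDF object:
# elements, formal charges, bond list with orders, ring/aromatic flags,
# implicit H counts, degrees, and coordinates.
mol_graph <- function(sdf_mol) {
  ab <- ChemmineR::atomblock(sdf_mol)
  bb <- ChemmineR::bondblock(sdf_mol)
  elem <- gsub("_.*$", "", rownames(ab))
  n <- length(elem)
  charge <- mdl_charge(ab[, "C6"])
  xyz <- unname(ab[, 1:3, drop = FALSE])

  if (is.null(dim(bb)) || nrow(bb) == 0) {
    bonds <- tibble(a1 = integer(), a2 = integer(), order = integer(),
                    in_ring = logical())
  } else {
    bonds <- tibble(
      a1 = as.integer(bb[, 1]), a2 = as.integer(bb[, 2]),
      order = as.integer(bb[, 3])
    )
    bonds$in_ring <- ring_bonds(bonds, n)
  }

  adj <- vector("list", n)
  if (nrow(bonds) > 0) {
    for (k in seq_len(nrow(bonds))) {
      adj[[bonds$a1[k]]] <- c(adj[[bonds$a1[k]]], bonds$a2[k])
      adj[[bonds$a2[k]]] <- c(adj[[bonds$a2[k]]], bonds$a1[k])
    }
  }

  heavy <- elem != "H"
  degree <- vapply(adj, length, integer(1))
  nH_explicit <- vapply(adj, function(nb) sum(elem[nb] == "H"), integer(1))
  # Sum of bond orders at each atom.
  val_used <- integer(n)
  if (nrow(bonds) > 0) {
    for (k in seq_len(nrow(bonds))) {
      val_used[bonds$a1[k]] <- val_used[bonds$a1[k]] + bonds$order[k]
      val_used[bonds$a2[k]] <- val_used[bonds$a2[k]] + bonds$order[k]
    }
  }
  std <- .default_valence[elem]
  std[is.na(std)] <- 0
  nH_implicit <- pmax(0L, as.integer(std + charge * ifelse(elem %in% c("N", "P"), 1L, -1L)) - val_used)
  nH_implicit[!heavy] <- 0L
  nH <- nH_explicit + ifelse(nH_explicit > 0, 0L, nH_implicit)

  # Aromatic perception via ring enumeration (ChemmineR handles the
  # kekulized OpenBabel output).
  arom_atom <- rep(FALSE, n)
  ring_list <- list()
  if (nrow(bonds) > 0 && any(bonds$in_ring)) {
    rr <- tryCatch(
      ChemmineR::rings(sdf_mol, type = "all", arom = TRUE),
      error = function(e) NULL
    )
    if (!is.null(rr) && length(rr$RINGS) > 0) {
      for (j in seq_along(rr$RINGS)) {
        members <- as.integer(gsub("^.*_", "", rr$RINGS[[j]]))
        ring_list[[length(ring_list) + 1]] <- list(
          atoms = members, aromatic = isTRUE(rr$AROMATIC[[j]])
        )
        if (isTRUE(rr$AROMATIC[[j]])) arom_atom[members] <- TRUE
      }
    }
  }

  list(
    elem = elem, charge = charge, xyz = xyz, bonds = bonds, adj = adj,
    degree = degree, nH = nH, heavy = heavy, aromatic = arom_atom,
    rings = ring_list
  )
}

# Which bonds lie in a cycle: a bond is a ring bond iff its endpoints stay
# connected after removing it (BFS per bond; molecules are small).
ring_bonds <- function(bonds, n_atoms) {
  m <- nrow(bonds)
  if (m == 0) return(logical(0))
  out <- logical(m)
  for (k in seq_len(m)) {
    src <- bonds$a1[k]; dst <- bonds$a2[k]
    a1 <- bonds$a1[-k]; a2 <- bonds$a2[-k]
    seen <- rep(FALSE, n_atoms)
    seen[src] <- TRUE
    queue <- src
    while (length(queue) > 0 && !seen[dst]) {
      v <- queue[1]; queue <- queue[-1]
      nb <- unique(c(a2[a1 == v], a1[a2 == v]))
      new <- nb[!seen[nb]]
      seen[new] <- TRUE
      queue <- c(queue, new)
    }
    out[k] <- seen[dst]
  }
  out
}

# Count of rotatable bonds: non-ring single bonds between two heavy atoms
# that each have at least one further heavy-atom neighbour.
count_rotatable <- function(g) {
  if (nrow(g$bonds) == 0) return(0L)
  b <- g$bonds
  heavy_deg <- vapply(seq_along(g$adj), function(i) {
    sum(g$elem[g$adj[[i]]] != "H")
  }, integer(1))
  rot <- b$order == 1 & !b$in_ring &
    g$elem[b$a1] != "H" & g$elem[b$a2] != "H" &
    heavy_deg[b$a1] >= 2 & heavy_deg[b$a2] >= 2
  sum(rot)
}
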