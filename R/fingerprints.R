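# Six 2D fingerprint featurizers. FP2, FP4 and MACCS are delegated to the
# OpenBabel backend (ChemmineOB); Morgan (circular), RDKit-style linear-path
# and Layered path fingerprints are computed natively on the molecular
# graph, hashed into fixed-length bit vectors.

#' Supported fingerprint types
#' @return Character vector of the six fingerprint type names.
#' @export
fp_types <- function() c("FP2", "FP4", "MACCS", "Morgan", "Layered", "RDKit")

#' Fingerprint parameters
#'
#' Bit lengths and walk parameters for the native fingerprints. FP2/FP4 use
#' their backend-native lengths (1024/512); MACCS has the fixed 166 keys.
#'
#' @param n_bits Hash width for Morgan/Layered/RDKit fingerprints.
#' @param morgan_radius Circular-environment radius for Morgan.
#' @param max_path Maximum bond-path length for RDKit/Layered fingerprints.
#' @return A named list, also carrying a short `hash` string identifying the
#'   parameter set in run manifests and caches.
#' @export
fp_params <- function(n_bits = 2048, morgan_radius = 2, max_path = 5) {
  p <- list(n_bits = as.integer(n_bits),
            morgan_radius = as.integer(morgan_radius),
            max_path = as.integer(max_path))
  p$hash <- paste0("nb", p$n_bits, "_r", p$morgan_radius, "_p", p$max_path)
  p
}

.ob_fp_bits <- c(FP2 = 1024L, FP4 = 512L, MACCS = 166L)

#' Compute one fingerprint for one molecule
#'
#' @param smiles A single SMILES string.
#' @param fp_type One of [fp_types()].
#' @param params Parameters from [fp_params()].
#' @return Integer 0/1 vector with attributes `fp_type` and `n_bits`.
#' @examples
#' \donttest{
#' fp <- compute_fingerprint("CCO", "Morgan")
#' sum(fp)
#' }
#' @export
compute_fingerprint <- function(smiles, fp_type, params = fp_params()) {
  check_fp_type(fp_type)
  m <- featurize_library(tibble(id = "m1", smiles = smiles), fp_type, params)
  if (nrow(m) == 0) abort("SMILES failed to parse")
  structure(as.integer(m[1, ]), fp_type = fp_type, n_bits = ncol(m))
}

check_fp_type <- function(fp_type) {
  if (!(length(fp_type) == 1 && fp_type %in% fp_types())) {
    abort(paste0("unsupported fingerprint type '", fp_type,
                 "'; supported: ", paste(fp_types(), collapse = ", ")))
  }
}

#' Featurize a molecule table with one fingerprint type
#'
#' One row per parseable molecule (row names = molecule ids, input order
#' preserved); parse failures are excluded with a warning. Use
#' [featurize_all()] when several fingerprint types are needed, so failures
#' are excluded consistently and the graph extraction is shared.
#'
#' @inheritParams compute_fingerprint
#' @param mols Molecule tibble with `id` and `smiles`.
#' @return 0/1 integer matrix, ids as row names; attributes `fp_type`,
#'   `params`.
#' @export
featurize_library <- function(mols, fp_type, params = fp_params()) {
  featurize_all(mols, fp_type, params)[[fp_type]]
}

#' Featurize a molecule table with several fingerprint types at once
#'
#' @inheritParams featurize_library
#' @param types Character vector of fingerprint types (default all six).
#' @return Named list of 0/1 matrices with identical row ids.
#' @export
featurize_all <- function(mols, types = fp_types(), params = fp_params()) {
  stopifnot(nrow(mols) > 0)
  for (t in types) check_fp_type(t)
  parsed <- parse_smiles(setNames(mols$smiles, mols$id))
  if (is.null(parsed$sdf)) abort("all molecules failed to parse")
  if (parsed$n_failed > 0) {
    warn(paste0(parsed$n_failed, " molecule(s) failed to parse; excluded ",
                "from all fingerprint matrices"))
  }
  sdf <- parsed$sdf
  ids <- ChemmineR::sdfid(sdf)
  out <- list()

  ob_types <- intersect(types, names(.ob_fp_bits))
  for (t in ob_types) {
    m <- ChemmineR::fingerprintOB(sdf, t)@fpma
    # OpenBabel pads MACCS to 256 bits; keep the 166 defined keys.
    m <- m[, seq_len(.ob_fp_bits[[t]]), drop = FALSE]
    storage.mode(m) <- "integer"
    rownames(m) <- ids
    attr(m, "fp_type") <- t
    attr(m, "params") <- params
    out[[t]] <- m
  }

  native <- setdiff(types, ob_types)
  if (length(native) > 0) {
    graphs <- lapply(seq_along(ids), function(i) mol_graph(sdf[[i]]))
    for (t in native) {
      rows <- lapply(graphs, function(g) native_fp(g, t, params))
      m <- do.call(rbind, rows)
      rownames(m) <- ids
      attr(m, "fp_type") <- t
      attr(m, "params") <- params
      out[[t]] <- m
    }
  }
  out[types]
}

native_fp <- function(g, fp_type, params) {
  bits <- switch(fp_type,
    Morgan = morgan_bits(g, params$morgan_radius, params$n_bits),
    RDKit = path_bits(g, params$max_path, params$n_bits, layered = FALSE),
    Layered = path_bits(g, params$max_path, params$n_bits, layered = TRUE)
  )
  v <- integer(params$n_bits)
  v[bits + 1L] <- 1L
  v
}

# Circular (Morgan/ECFP-like) environments: iteratively rehash each heavy
# atom's invariant with its sorted (bond order, neighbour invariant) list;
# every (atom, radius) environment sets one bit.
morgan_bits <- function(g, radius, n_bits) {
  heavy <- which(g$heavy)
  if (length(heavy) == 0) return(integer(0))
  inv <- vapply(heavy, function(i) {
    hash_ints(c(
      match(g$elem[i], c("C", "N", "O", "S", "P", "F", "Cl", "Br", "I", "B"),
            nomatch = 99L),
      g$degree[i], g$nH[i], g$charge[i] + 10L,
      as.integer(g$aromatic[i]),
      as.integer(any(g$bonds$in_ring[g$bonds$a1 == i | g$bonds$a2 == i]))
    ))
  }, numeric(1))
  names(inv) <- heavy
  bits <- inv
  if (radius > 0 && nrow(g$bonds) > 0) {
    border <- g$bonds$order
    for (r in seq_len(radius)) {
      new_inv <- inv
      for (k in seq_along(heavy)) {
        i <- heavy[k]
        bsel <- which(g$bonds$a1 == i | g$bonds$a2 == i)
        nb <- ifelse(g$bonds$a1[bsel] == i, g$bonds$a2[bsel], g$bonds$a1[bsel])
        hv <- g$elem[nb] != "H"
        if (!any(hv)) next
        nb <- nb[hv]; bo <- border[bsel][hv]
        pos <- match(nb, heavy)
        pairs <- cbind(bo, inv[pos])
        ord <- order(pairs[, 1], pairs[, 2])
        new_inv[k] <- hash_ints(c(r, inv[k], as.vector(t(pairs[ord, , drop = FALSE]))))
      }
      inv <- new_inv
      bits <- c(bits, inv)
    }
  }
  unique(as.integer(bits %% n_bits))
}

# Linear bond paths up to max_path bonds, hashed direction-independently.
# layered = TRUE additionally hashes a topology-only and an element-only
# variant of every path (three layers per path).
path_bits <- function(g, max_path, n_bits, layered = FALSE) {
  heavy <- which(g$heavy)
  if (length(heavy) == 0) return(integer(0))
  atom_code <- match(g$elem, c("C", "N", "O", "S", "P", "F", "Cl", "Br", "I", "B"),
                     nomatch = 99L) + 100L * as.integer(g$aromatic)
  bonds <- g$bonds[g$elem[g$bonds$a1] != "H" & g$elem[g$bonds$a2] != "H", ,
                   drop = FALSE]
  bits <- numeric(0)
  # atom layer: single atoms
  bits <- c(bits, vapply(atom_code[heavy], function(a) hash_ints(c(0, a)),
                         numeric(1)))
  if (nrow(bonds) > 0) {
    adj <- vector("list", length(g$elem))
    for (k in seq_len(nrow(bonds))) {
      adj[[bonds$a1[k]]] <- rbind(adj[[bonds$a1[k]]], c(bonds$a2[k], bonds$order[k]))
      adj[[bonds$a2[k]]] <- rbind(adj[[bonds$a2[k]]], c(bonds$a1[k], bonds$order[k]))
    }
    hash_path <- function(atoms, orders) {
      fwd <- c(rbind(atom_code[atoms], c(orders, 0L)))
      fwd <- fwd[-length(fwd)]
      rev_ <- c(rbind(atom_code[rev(atoms)], c(rev(orders), 0L)))
      rev_ <- rev_[-length(rev_)]
      seqv <- if (paste(fwd, collapse = ",") <= paste(rev_, collapse = ","))
        fwd else rev_
      out <- hash_ints(c(1, seqv))
      if (layered) {
        topo <- hash_ints(c(2, orders))
        elems <- if (paste(atoms, collapse = ",") <= paste(rev(atoms), collapse = ","))
          atom_code[atoms] %% 100L else atom_code[rev(atoms)] %% 100L
        out <- c(out, topo, hash_ints(c(3, elems)))
      }
      out
    }
    # DFS over simple paths from each heavy atom.
    walk <- function(path, orders) {
      last <- path[length(path)]
      nbrs <- adj[[last]]
      if (is.null(nbrs)) return(invisible())
      for (r in seq_len(nrow(nbrs))) {
        nxt <- nbrs[r, 1]
        if (nxt %in% path) next
        p2 <- c(path, nxt); o2 <- c(orders, nbrs[r, 2])
        # emit each path once (canonical: first atom <= last atom)
        if (p2[1] <= nxt) bits <<- c(bits, hash_path(p2, o2))
        if (length(o2) < max_path) walk(p2, o2)
      }
    }
    for (a in heavy) walk(a, integer(0))
  }
  unique(as.integer(bits %% n_bits))
}

#' Tanimoto similarity of two bit vectors
#'
#' @param a,b Equal-length 0/1 vectors.
#' @return `|a AND b| / |a OR b|` in `[0, 1]`; 1 when both vectors are empty.
#' @export
tanimoto <- function(a, b) {
  stopifnot(length(a) == length(b))
  a <- as.logical(a); b <- as.logical(b)
  u <- sum(a | b)
  if (u == 0) return(1)
  sum(a & b) / u
}
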