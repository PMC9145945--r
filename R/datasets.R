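#' Read a molecule library from CSV or SMI
#'
#' Reads a labeled molecule table from delimited text (columns `id`,
#' `smiles`, optional `label` and `potency_nM`) or a `.smi` file (one
#' `SMILES id` pair per line). Every SMILES is validated against the
#' cheminformatics backend; unparseable records are dropped with a single
#' summary warning and counted in the `n_dropped` attribute. Duplicate ids
#' are made unique deterministically by suffixing `_2`, `_3`, ...
#'
#' @param path Path to a `.csv`/`.tsv` or `.smi` file.
#' @param format `"auto"` (by extension), `"csv"` or `"smi"`.
#' @param validate Parse every SMILES and drop failures (default `TRUE`).
#' @return A tibble with columns `id`, `smiles`, `label`
#'   (`ACTIVE`/`INACTIVE`/`DECOY`/`UNLABELED`) and `potency_nM`, with
#'   attribute `n_dropped`.
#' @examples
#' \donttest{
#' tf <- tempfile(fileext = ".smi")
#' writeLines(c("CCO mol1", "c1ccccc1 mol2"), tf)
#' read_library(tf)
#' }
#' @export
read_library <- function(path, format = c("auto", "csv", "smi"),
                         validate = TRUE) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    abort(paste0("library file not found: ", path))
  }
  if (format == "auto") {
    format <- if (grepl("\\.smi$", path, ignore.case = TRUE)) "smi" else "csv"
  }
  if (format == "smi") {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    parts <- stringr::str_split_fixed(trimws(lines), "\\s+", 2)
    tbl <- tibble(
      id = ifelse(nzchar(parts[, 2]), parts[, 2],
                  paste0("mol", seq_len(nrow(parts)))),
      smiles = parts[, 1],
      label = "UNLABELED",
      potency_nM = NA_real_
    )
  } else {
    raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
    names(raw) <- tolower(names(raw))
    if (!all(c("id", "smiles") %in% names(raw))) {
      abort("delimited library must have 'id' and 'smiles' columns")
    }
    tbl <- tibble(
      id = as.character(raw$id),
      smiles = as.character(raw$smiles),
      label = if ("label" %in% names(raw)) toupper(as.character(raw$label))
              else "UNLABELED",
      potency_nM = if ("potency_nm" %in% names(raw))
        as.numeric(raw$potency_nm) else NA_real_
    )
    tbl$label[is.na(tbl$label) | !nzchar(tbl$label)] <- "UNLABELED"
  }
  bad_label <- !tbl$label %in% c("ACTIVE", "INACTIVE", "DECOY", "UNLABELED")
  if (any(bad_label)) {
    warn(paste0(sum(bad_label), " unknown labels set to UNLABELED"))
    tbl$label[bad_label] <- "UNLABELED"
  }
  tbl$id <- dedupe_ids(tbl$id)

  n_dropped <- 0L
  if (validate && nrow(tbl) > 0) {
    parsed <- parse_smiles(setNames(tbl$smiles, tbl$id))
    n_dropped <- parsed$n_failed
    if (n_dropped > 0) {
      warn(paste0(n_dropped, " record(s) with unparseable SMILES dropped"))
      tbl <- tbl[parsed$valid, , drop = FALSE]
    }
  }
  if (nrow(tbl) == 0) abort("no parseable records in library")
  attr(tbl, "n_dropped") <- n_dropped
  tbl
}

#' Write a molecule library
#'
#' Inverse of [read_library()]: writes `id`, `smiles`, `label`,
#' `potency_nM` as UTF-8 CSV with a header row, or as `.smi`
#' (`SMILES id` per line, labels not preserved).
#'
#' @param mols Molecule tibble (`id`, `smiles`, at least).
#' @param path Output path; extension `.smi` selects SMI format.
#' @return `path`, invisibly.
#' @export
write_library <- function(mols, path) {
  stopifnot(all(c("id", "smiles") %in% names(mols)))
  if (grepl("\\.smi$", path, ignore.case = TRUE)) {
    writeLines(paste(mols$smiles, mols$id), path)
  } else {
    out <- tibble(
      id = mols$id,
      smiles = mols$smiles,
      label = if ("label" %in% names(mols)) mols$label else "UNLABELED",
      potency_nM = if ("potency_nM" %in% names(mols)) mols$potency_nM
                   else NA_real_
    )
    readr::write_csv(out, path, progress = FALSE)
  }
  invisible(path)
}

dedupe_ids <- function(ids) {
  ids <- as.character(ids)
  dup <- duplicated(ids)
  if (!any(dup)) return(ids)
  warn(paste0(sum(dup), " duplicate id(s) suffixed deterministically"))
  counts <- new.env(parent = emptyenv())
  vapply(ids, function(x) {
    k <- get0(x, envir = counts, ifnotfound = 0L) + 1L
    assign(x, k, envir = counts)
    if (k == 1L) x else paste0(x, "_", k)
  }, character(1), USE.NAMES = FALSE)
}

#' Compute the six decoy-matching physicochemical properties
#'
#' Adds the DUD-E matching properties to a molecule table: molecular weight
#' (`mw`, g/mol), `clogp`, H-bond donors (`hbd`), H-bond acceptors (`hba`),
#' rotatable bonds (`rotb`) and net formal charge (`charge`). MW, clogP,
#' HBD and HBA come from the OpenBabel backend; rotatable bonds and formal
#' charge are derived from the bond graph. Molecules whose property
#' computation fails are flagged `prop_ok = FALSE` and are skipped by
#' [match_decoys()].
#'
#' @param mols Molecule tibble with `id` and `smiles`.
#' @return The input tibble with property columns, canonical SMILES
#'   (`cansmi`) and `prop_ok` appended.
#' @export
compute_properties <- function(mols) {
  stopifnot(nrow(mols) > 0)
  parsed <- parse_smiles(setNames(mols$smiles, mols$id))
  out <- mols
  out$mw <- NA_real_; out$clogp <- NA_real_
  out$hbd <- NA_integer_; out$hba <- NA_integer_
  out$rotb <- NA_integer_; out$charge <- NA_integer_
  out$cansmi <- NA_character_
  out$prop_ok <- FALSE
  if (is.null(parsed$sdf)) {
    warn("property computation failed for all molecules")
    return(out)
  }
  props <- ChemmineR::propOB(parsed$sdf)
  ids <- ChemmineR::sdfid(parsed$sdf)
  idx <- match(ids, out$id)
  out$mw[idx] <- props$MW
  out$clogp[idx] <- props$logP
  out$hbd[idx] <- as.integer(props$HBD)
  out$hba[idx] <- as.integer(props$HBA1)
  out$cansmi[idx] <- props$cansmiNS
  graph_stats <- lapply(seq_along(ids), function(i) {
    g <- mol_graph(parsed$sdf[[i]])
    c(rotb = count_rotatable(g), charge = sum(g$charge))
  })
  out$rotb[idx] <- vapply(graph_stats, `[[`, numeric(1), "rotb")
  out$charge[idx] <- vapply(graph_stats, `[[`, numeric(1), "charge")
  # Molecules the SDF backend cannot represent (e.g. single-atom species
  # like methane carry no bond block) fall back to the OpenBabel CLI.
  missing <- which(is.na(out$mw))
  if (length(missing) > 0 && nzchar(Sys.which("obabel"))) {
    cli <- obabel_props(out$smiles[missing])
    ok <- !is.na(cli$mw)
    out$mw[missing[ok]] <- cli$mw[ok]
    out$clogp[missing[ok]] <- cli$logp[ok]
    out$hbd[missing[ok]] <- cli$hbd[ok]
    out$hba[missing[ok]] <- cli$hba[ok]
    out$cansmi[missing[ok]] <- cli$cansmi[ok]
    out$rotb[missing[ok]] <- 0L
    out$charge[missing[ok]] <- charge_from_smiles(out$smiles[missing[ok]])
  }

  out$prop_ok <- !is.na(out$mw) & is.finite(out$mw) & !is.na(out$rotb)
  if (any(!out$prop_ok)) {
    warn(paste0(sum(!out$prop_ok),
                " molecule(s) flagged: property computation failed"))
  }
  out
}

# Property fallback through the obabel CLI (one call for the batch).
obabel_props <- function(smiles) {
  empty <- tibble(cansmi = NA_character_, mw = NA_real_, logp = NA_real_,
                  hbd = NA_integer_, hba = NA_integer_)[rep(1, length(smiles)), ]
  smi <- tempfile(fileext = ".smi")
  writeLines(paste(smiles, seq_along(smiles)), smi)
  lines <- suppressWarnings(tryCatch(
    system2("obabel", c(smi, "-osmi", "--append", shQuote("MW logP HBD HBA1")),
            stdout = TRUE, stderr = FALSE),
    error = function(e) character(0)
  ))
  unlink(smi)
  lines <- lines[grepl("\\t", lines)]
  if (length(lines) == 0) return(empty)
  for (ln in lines) {
    parts <- strsplit(ln, "[\t ]+")[[1]]
    if (length(parts) < 6) next
    i <- suppressWarnings(as.integer(parts[2]))
    if (is.na(i) || i < 1 || i > length(smiles)) next
    empty$cansmi[i] <- parts[1]
    empty$mw[i] <- as.numeric(parts[3])
    empty$logp[i] <- as.numeric(parts[4])
    empty$hbd[i] <- as.integer(parts[5])
    empty$hba[i] <- as.integer(parts[6])
  }
  empty
}

# Net formal charge from bracket atoms in a SMILES string.
charge_from_smiles <- function(smiles) {
  vapply(smiles, function(s) {
    toks <- regmatches(s, gregexpr("\\[[^]]+\\]", s))[[1]]
    total <- 0L
    for (t in toks) {
      m <- regmatches(t, regexpr("([+-])([0-9]*)", t))
      if (length(m) == 1 && nzchar(m)) {
        sign <- if (substr(m, 1, 1) == "+") 1L else -1L
        num <- suppressWarnings(as.integer(substring(m, 2)))
        total <- total + sign * (if (is.na(num)) 1L else num)
      }
    }
    total
  }, integer(1), USE.NAMES = FALSE)
}

#' Default decoy property-matching windows
#'
#' Tolerances around each active's property inside which a pool molecule
#' qualifies as a candidate decoy: +/-25 g/mol MW, +/-1.0 clogP, +/-1 HBD,
#' +/-1 HBA, +/-2 rotatable bonds, exact net charge.
#'
#' @return Named numeric vector over `mw`, `clogp`, `hbd`, `hba`, `rotb`,
#'   `charge`.
#' @export
decoy_windows <- function() {
  c(mw = 25, clogp = 1.0, hbd = 1, hba = 1, rotb = 2, charge = 0)
}

#' Select property-matched decoys for a set of actives
#'
#' DUD-E style matching: for each active, up to `k` pool molecules are
#' selected whose every property lies within the active's value plus/minus
#' the corresponding window. Selection is greedy by ascending normalized
#' property distance (each absolute difference divided by its window width;
#' zero-width windows require exact equality and contribute 0), with ties
#' broken by lexicographic molecule id. Each pool molecule is assigned to at
#' most one active, and pool molecules identical by canonical SMILES to any
#' active are excluded to prevent label leakage.
#'
#' @param actives Molecule tibble with properties ([compute_properties()]).
#' @param pool Candidate tibble with properties.
#' @param k Decoys per active (default 50).
#' @param windows Named tolerance vector, see [decoy_windows()].
#' @return Tibble of selected pool molecules labeled `DECOY`, with a
#'   `matched_active` column; attribute `shortfall` names actives that
#'   received fewer than `k` decoys.
#' @export
match_decoys <- function(actives, pool, k = 50, windows = decoy_windows()) {
  stopifnot(k >= 1)
  if (nrow(pool) == 0) abort("empty decoy pool")
  props <- names(decoy_windows())
  if (!all(props %in% names(actives)) || !all(props %in% names(pool))) {
    abort("actives and pool must carry computed properties; run compute_properties() first")
  }
  windows <- windows[props]
  pool <- pool[pool$prop_ok %||% TRUE & !is.na(pool$mw), , drop = FALSE]
  act <- actives[actives$prop_ok %||% TRUE & !is.na(actives$mw), , drop = FALSE]

  # Label-leakage guard: drop pool entries identical to any active.
  if ("cansmi" %in% names(pool) && "cansmi" %in% names(act)) {
    leak <- pool$cansmi %in% act$cansmi
  } else {
    leak <- pool$smiles %in% act$smiles
  }
  if (any(leak)) {
    warn(paste0(sum(leak), " pool molecule(s) identical to an active excluded"))
    pool <- pool[!leak, , drop = FALSE]
  }
  if (nrow(pool) == 0) {
    warn("no eligible pool molecules remain")
    out <- pool[0, , drop = FALSE]
    attr(out, "shortfall") <- act$id
    return(out)
  }

  pm <- as.matrix(pool[, props])
  taken <- rep(FALSE, nrow(pool))
  picks <- vector("list", nrow(act))
  shortfall <- character(0)
  # Deterministic order over actives by id.
  act <- act[order(act$id), , drop = FALSE]
  for (i in seq_len(nrow(act))) {
    a <- as.numeric(act[i, props])
    diffs <- abs(sweep(pm, 2, a))
    inside <- rep(TRUE, nrow(pool))
    ndist <- rep(0, nrow(pool))
    for (j in seq_along(props)) {
      w <- windows[j]
      if (w == 0) {
        inside <- inside & diffs[, j] == 0
      } else {
        inside <- inside & diffs[, j] <= w
        ndist <- ndist + diffs[, j] / w
      }
    }
    cand <- which(inside & !taken)
    if (length(cand) > 0) {
      ord <- cand[order(ndist[cand], pool$id[cand])]
      sel <- head(ord, k)
      taken[sel] <- TRUE
      chosen <- pool[sel, , drop = FALSE]
      chosen$matched_active <- act$id[i]
      picks[[i]] <- chosen
    }
    n_got <- if (is.null(picks[[i]])) 0L else nrow(picks[[i]])
    if (n_got < k) shortfall <- c(shortfall, act$id[i])
  }
  out <- bind_rows(picks)
  if (nrow(out) > 0) out$label <- "DECOY"
  if (length(shortfall) > 0) {
    warn(paste0(length(shortfall), " active(s) received fewer than k=", k,
                " decoys"))
  }
  attr(out, "shortfall") <- shortfall
  out
}

#' Split a labeled corpus into training and test sets
#'
#' Composition follows the screening-campaign design: the training set is a
#' fraction of the actives plus all inactives; the test set is the held-out
#' actives plus the decoys. No molecule id appears in both sets.
#'
#' @param mols Labeled molecule tibble (`ACTIVE`/`INACTIVE`/`DECOY`).
#' @param train_fraction Fraction of actives used for training (default 0.8).
#' @param seed RNG seed for the fold assignment.
#' @return A list of class `corpus_split` with tibbles `train` and `test`
#'   and the `decoys_per_active` implied by the corpus.
#' @export
split_corpus <- function(mols, train_fraction = 0.8, seed = 20220516) {
  stopifnot(all(c("id", "smiles", "label") %in% names(mols)))
  act <- mols[mols$label == "ACTIVE", , drop = FALSE]
  ina <- mols[mols$label == "INACTIVE", , drop = FALSE]
  dec <- mols[mols$label == "DECOY", , drop = FALSE]
  if (nrow(act) < 2) abort("need at least two ACTIVE molecules to split")
  n_train <- max(1, round(train_fraction * nrow(act)))
  idx <- with_seed(seed, sample(seq_len(nrow(act)), n_train))
  split <- list(
    train = bind_rows(act[idx, ], ina),
    test = bind_rows(act[-idx, ], dec),
    decoys_per_active = if (nrow(act) - n_train > 0)
      nrow(dec) / (nrow(act) - n_train) else NA_real_
  )
  stopifnot(length(intersect(split$train$id, split$test$id)) == 0)
  class(split) <- c("corpus_split", class(split))
  split
}

#' @export
print.corpus_split <- function(x, ...) {
  cat("<corpus_split>\n")
  cat("  train:", nrow(x$train), "molecules (",
      sum(x$train$label == "ACTIVE"), "ACTIVE /",
      sum(x$train$label == "INACTIVE"), "INACTIVE )\n")
  cat("  test: ", nrow(x$test), "molecules (",
      sum(x$test$label == "ACTIVE"), "ACTIVE /",
      sum(x$test$label == "DECOY"), "DECOY )\n")
  invisible(x)
}
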