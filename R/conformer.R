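# Deterministic distance-geometry conformer embedding.
#
# Coordinates are obtained by minimizing a distance-constraint objective:
# bonded pairs at ideal lengths, 1-3 pairs at the distance implied by the
# central atom's idealized angle, and a soft lower bound between all other
# pairs. Initialization is seeded Gaussian noise, so the result is fully
# determined by (molecule, seed). This is a geometry sketcher adequate for
# docking input and tests, not a force-field minimum.

.bond_len <- function(e1, e2, order) {
  key <- paste(sort(c(e1, e2)), collapse = "-")
  base <- c(
    "C-C" = 1.53, "C-N" = 1.47, "C-O" = 1.43, "C-S" = 1.81, "C-F" = 1.35,
    "C-Cl" = 1.77, "Br-C" = 1.94, "C-I" = 2.14, "N-N" = 1.45, "N-O" = 1.40,
    "O-O" = 1.48, "N-S" = 1.68, "O-S" = 1.57, "S-S" = 2.05,
    "C-H" = 1.09, "H-N" = 1.01, "H-O" = 0.96, "H-S" = 1.34, "H-H" = 0.74
  )
  d <- unname(base[key])
  if (is.na(d)) d <- 1.5
  if (order == 2) d <- d - 0.12
  if (order >= 3) d <- d - 0.20
  d
}

# Embed one molecular graph (mol_graph with implicit-H counts) into 3D.
# Returns list(elem, xyz, bonds) with hydrogens made explicit.
dg_embed_graph <- function(g, seed = 20220516, iters = 1500, step = 0.05) {
  elem <- g$elem
  bonds <- g$bonds[, c("a1", "a2", "order")]
  # make implicit hydrogens explicit
  nH <- g$nH - vapply(seq_along(elem), function(i) {
    sum(g$elem[g$adj[[i]]] == "H")
  }, integer(1))
  for (i in seq_along(g$elem)) {
    for (h in seq_len(max(0, nH[i]))) {
      elem <- c(elem, "H")
      bonds <- rbind(bonds, data.frame(a1 = i, a2 = length(elem), order = 1L))
    }
  }
  n <- length(elem)
  adj <- vector("list", n)
  for (k in seq_len(nrow(bonds))) {
    adj[[bonds$a1[k]]] <- c(adj[[bonds$a1[k]]], bonds$a2[k])
    adj[[bonds$a2[k]]] <- c(adj[[bonds$a2[k]]], bonds$a1[k])
  }
  # constraint lists
  ci <- integer(0); cj <- integer(0); cd <- numeric(0); cw <- numeric(0)
  lo_i <- integer(0); lo_j <- integer(0); lo_d <- numeric(0)
  blen <- numeric(n * n)
  for (k in seq_len(nrow(bonds))) {
    d0 <- .bond_len(elem[bonds$a1[k]], elem[bonds$a2[k]], bonds$order[k])
    ci <- c(ci, bonds$a1[k]); cj <- c(cj, bonds$a2[k])
    cd <- c(cd, d0); cw <- c(cw, 10)
    blen[(bonds$a1[k] - 1) * n + bonds$a2[k]] <- d0
    blen[(bonds$a2[k] - 1) * n + bonds$a1[k]] <- d0
  }
  # angle (1-3) constraints from idealized hybridization at the center
  heavy_deg <- vapply(seq_len(n), function(i) sum(elem[adj[[i]]] != "H"),
                      integer(1))
  order_sum <- integer(n)
  for (k in seq_len(nrow(bonds))) {
    if (bonds$order[k] > 1) {
      order_sum[bonds$a1[k]] <- pmax(order_sum[bonds$a1[k]], bonds$order[k])
      order_sum[bonds$a2[k]] <- pmax(order_sum[bonds$a2[k]], bonds$order[k])
    }
  }
  theta <- ifelse(seq_len(n) <= length(g$aromatic) & c(g$aromatic, rep(FALSE, n - length(g$aromatic))) |
                    order_sum == 2, 120, 109.47)
  theta[order_sum >= 3] <- 180
  for (b in seq_len(n)) {
    nb <- adj[[b]]
    if (length(nb) < 2) next
    th <- theta[b] * pi / 180
    for (p in seq_len(length(nb) - 1)) {
      for (q in (p + 1):length(nb)) {
        i <- nb[p]; j <- nb[q]
        d1 <- blen[(b - 1) * n + i]; d2 <- blen[(b - 1) * n + j]
        d13 <- sqrt(d1^2 + d2^2 - 2 * d1 * d2 * cos(th))
        ci <- c(ci, i); cj <- c(cj, j); cd <- c(cd, d13); cw <- c(cw, 3)
      }
    }
  }
  # lower bounds between all remaining pairs
  bonded_or_13 <- paste(pmin(ci, cj), pmax(ci, cj))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (paste(i, j) %in% bonded_or_13) next
      lo_i <- c(lo_i, i); lo_j <- c(lo_j, j)
      lo_d <- c(lo_d, if (elem[i] == "H" || elem[j] == "H") 1.8 else 2.4)
    }
  }

  x <- with_seed(seed, matrix(rnorm(3 * n, sd = 2), ncol = 3))
  for (it in seq_len(iters)) {
    gmat <- matrix(0, n, 3)
    v <- x[ci, , drop = FALSE] - x[cj, , drop = FALSE]
    d <- sqrt(rowSums(v^2)) + 1e-9
    f <- 2 * cw * (d - cd) / d
    gv <- v * f
    for (ax in 1:3) {
      gmat[, ax] <- gmat[, ax] +
        tapply_sum(gv[, ax], ci, n) - tapply_sum(gv[, ax], cj, n)
    }
    if (length(lo_i) > 0) {
      v2 <- x[lo_i, , drop = FALSE] - x[lo_j, , drop = FALSE]
      d2 <- sqrt(rowSums(v2^2)) + 1e-9
      viol <- d2 < lo_d
      if (any(viol)) {
        f2 <- 2 * (d2 - lo_d) / d2
        f2[!viol] <- 0
        gv2 <- v2 * f2
        for (ax in 1:3) {
          gmat[, ax] <- gmat[, ax] +
            tapply_sum(gv2[, ax], lo_i, n) - tapply_sum(gv2[, ax], lo_j, n)
        }
      }
    }
    # clip the largest per-atom displacement to keep the descent stable
    gn <- sqrt(max(rowSums(gmat^2)))
    if (gn > 1) gmat <- gmat / gn
    x <- x - step * gmat
    if (it == round(iters / 2)) step <- step / 2
  }
  list(elem = elem, xyz = x,
       bonds = as.matrix(bonds[, c("a1", "a2", "order")]))
}

tapply_sum <- function(vals, idx, n) {
  out <- numeric(n)
  s <- tapply(vals, idx, sum)
  out[as.integer(names(s))] <- s
  out
}
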