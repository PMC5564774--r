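# Fixture molecules (all <= 12 heavy atoms) and independent brute-force
# oracles for the descriptor engine. Oracles deliberately use different
# algorithms from the package: Floyd-Warshall distances, combn-based
# subgraph enumeration, closed-form path counts.

FIXTURE_SMILES <- c(
  ethane        = "CC",
  propane       = "CCC",
  butane        = "CCCC",
  isobutane     = "CC(C)C",
  pentane       = "CCCCC",
  neopentane    = "CC(C)(C)C",
  hexane        = "CCCCCC",
  cyclopropane  = "C1CC1",
  cyclohexane   = "C1CCCCC1",
  benzene       = "c1ccccc1",
  toluene       = "Cc1ccccc1",
  phenol        = "c1ccccc1O",
  aniline       = "Nc1ccccc1",
  benzonitrile  = "N#Cc1ccccc1",
  trichlorophenol = "Oc1c(Cl)cc(Cl)cc1Cl",
  nitroaniline  = "Nc1ccc(cc1)[N+](=O)[O-]",
  anhydride     = "CC(=O)OC(=O)C",
  benzaldehyde  = "O=Cc1ccccc1"
)

fixture_graphs <- function(which = names(FIXTURE_SMILES)) {
  lapply(FIXTURE_SMILES[which], parse_smiles)
}

# Build a V2000 MOL record from element/bond specs (explicit H allowed).
make_molfile <- function(elements, bonds, charges = NULL, title = "mol") {
  na <- length(elements); nb <- nrow(bonds)
  lines <- c(title, "  testthat", "",
             sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", na, nb))
  for (el in elements) {
    lines <- c(lines, sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                              0, 0, 0, el))
  }
  for (r in seq_len(nb)) {
    lines <- c(lines, sprintf("%3d%3d%3d  0", bonds$i[r], bonds$j[r], bonds$type[r]))
  }
  if (!is.null(charges)) {
    for (k in seq_along(charges)) {
      if (charges[k] != 0) {
        lines <- c(lines, sprintf("M  CHG  1 %3d %3d", k, charges[k]))
      }
    }
  }
  c(lines, "M  END")
}

# Random atom relabelling of a molgraph.
permute_molgraph <- function(g, perm) {
  inv <- order(perm)  # inv[old] = new position
  atoms <- g$atoms[perm, , drop = FALSE]
  rownames(atoms) <- NULL
  bonds <- data.frame(i = inv[g$bonds$i], j = inv[g$bonds$j], order = g$bonds$order)
  molgraph(atoms, bonds)
}

# Floyd-Warshall all-pairs distances (independent of the package's BFS).
dist_oracle <- function(g) {
  n <- n_atoms(g)
  D <- matrix(Inf, n, n); diag(D) <- 0
  for (r in seq_len(nrow(g$bonds))) {
    D[g$bonds$i[r], g$bonds$j[r]] <- 1
    D[g$bonds$j[r], g$bonds$i[r]] <- 1
  }
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n)) {
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  }
  D
}

wiener_oracle <- function(g) {
  D <- dist_oracle(g)
  sum(D[upper.tri(D)])
}

balaban_oracle <- function(g) {
  D <- dist_oracle(g)
  s <- rowSums(D)
  M <- nrow(g$bonds)
  gamma <- M - n_atoms(g) + 1
  M / (gamma + 1) * sum(1 / sqrt(s[g$bonds$i] * s[g$bonds$j]))
}

graph_degrees <- function(g) {
  n <- n_atoms(g)
  tabulate(c(g$bonds$i, g$bonds$j), n)
}

# Exhaustive chi oracle: all m-subsets of bonds via combn, connectivity by
# iterative frontier expansion, classification by degree sequence.
chi_oracle <- function(g, order, kind, valence = FALSE) {
  delta <- if (valence) qsartox:::.valence_deltas(g) else as.numeric(graph_degrees(g))
  if (order == 0) return(if (kind == "path") sum(1 / sqrt(delta)) else 0)
  nb <- nrow(g$bonds)
  if (nb < order) return(0)
  total <- 0
  combos <- utils::combn(nb, order)
  for (c_idx in seq_len(ncol(combos))) {
    rows <- combos[, c_idx]
    vs <- c(g$bonds$i[rows], g$bonds$j[rows])
    verts <- unique(vs)
    # connectivity of the edge-induced subgraph
    reach <- verts[1L]
    repeat {
      grown <- FALSE
      for (r in rows) {
        bi <- g$bonds$i[r]; bj <- g$bonds$j[r]
        if (bi %in% reach && !(bj %in% reach)) { reach <- c(reach, bj); grown <- TRUE }
        if (bj %in% reach && !(bi %in% reach)) { reach <- c(reach, bi); grown <- TRUE }
      }
      if (!grown) break
    }
    if (length(reach) != length(verts)) next
    is_tree <- length(verts) == order + 1L
    maxdeg <- max(table(vs))
    k <- if (!is_tree) "other"
         else if (maxdeg <= 2) "path"
         else if (order >= 3 && maxdeg == order) "cluster"
         else "path-cluster"
    if (k == kind) total <- total + 1 / sqrt(prod(delta[verts]))
  }
  total
}

# Closed-form path counts: P2 = sum C(d_i, 2); P3 = sum over edges of
# (d_i - 1)(d_j - 1) minus 3 * triangle count (trace(A^3)/6).
path_count_oracle <- function(g, len) {
  d <- graph_degrees(g)
  if (len == 1) return(nrow(g$bonds))
  if (len == 2) return(sum(choose(d, 2)))
  n <- n_atoms(g)
  A <- matrix(0, n, n)
  for (r in seq_len(nrow(g$bonds))) {
    A[g$bonds$i[r], g$bonds$j[r]] <- 1
    A[g$bonds$j[r], g$bonds$i[r]] <- 1
  }
  tri <- sum(diag(A %*% A %*% A)) / 6
  sum((d[g$bonds$i] - 1) * (d[g$bonds$j] - 1)) - 3 * tri
}

kappa_oracle <- function(g, alpha_corrected = FALSE) {
  A <- n_atoms(g)
  al <- if (alpha_corrected) qsartox:::.kier_alpha(g) else 0
  P1 <- path_count_oracle(g, 1); P2 <- path_count_oracle(g, 2); P3 <- path_count_oracle(g, 3)
  Aa <- A + al
  k3 <- if (P3 == 0) 0
        else if (A %% 2 == 1) (Aa - 1) * (Aa - 3)^2 / (P3 + al)^2
        else (Aa - 3) * (Aa - 2)^2 / (P3 + al)^2
  c(Aa * (Aa - 1)^2 / (P1 + al)^2, (Aa - 1) * (Aa - 2)^2 / (P2 + al)^2, k3)
}
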