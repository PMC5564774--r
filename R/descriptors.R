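#' Molecular weight
#'
#' Sum of standard atomic masses over heavy atoms and implicit hydrogens.
#' @param g a [molgraph()].
#' @return mass in g/mol.
#' @examples
#' molecular_weight(parse_smiles("c1ccccc1"))  # benzene, 78.12
#' @export
molecular_weight <- function(g) {
  stopifnot(inherits(g, "molgraph"))
  if (is.null(g$atoms) || nrow(g$atoms) < 1L) {
    stop("molecular graph has no atoms", call. = FALSE)
  }
  info <- .element_info(g$atoms$element)
  sum(info$mass) + sum(g$atoms$hcount) * .ELEMENTS["H", "mass"]
}

#' Wiener index
#'
#' Sum of topological distances over all unordered pairs of heavy atoms.
#' @param g a connected [molgraph()].
#' @return integer-valued Wiener index W.
#' @export
wiener_index <- function(g) {
  D <- .distance_matrix(g)
  sum(D[upper.tri(D)])
}

#' Randic connectivity index (first-order chi)
#'
#' \eqn{^1\chi = \sum_{(i,j) \in E} (\delta_i \delta_j)^{-1/2}} with
#' \eqn{\delta} the heavy-atom degree.
#' @param g a connected [molgraph()] with at least one bond.
#' @return the Randic index.
#' @export
randic_index <- function(g) {
  .assert_connected(g)
  if (nrow(g$bonds) == 0L) stop("Randic index undefined for a single-atom graph", call. = FALSE)
  d <- .degrees(g)
  sum(1 / sqrt(d[g$bonds$i] * d[g$bonds$j]))
}

#' Kier-Hall molecular connectivity index
#'
#' \eqn{^m\chi_t} summed over all connected m-edge subgraphs of the requested
#' kind, each contributing \eqn{\prod_v \delta_v^{-1/2}} over the subgraph's
#' vertices. The valence variant substitutes the Kier-Hall valence delta
#' \eqn{\delta^v = (Z^v - h)/(Z - Z^v - 1)}. Order 0 sums over atoms. If the
#' molecule has no subgraph of the requested kind the index is 0.
#'
#' @param g connected [molgraph()].
#' @param order subgraph edge count, 0 to 4.
#' @param kind `"path"`, `"cluster"` or `"path-cluster"`.
#' @param valence use valence-corrected deltas?
#' @return chi value (0 when no qualifying subgraph exists).
#' @export
chi_index <- function(g, order, kind = c("path", "cluster", "path-cluster"),
                      valence = FALSE) {
  kind <- match.arg(kind)
  stopifnot(order %in% 0:4)
  .assert_connected(g)
  delta <- if (valence) .valence_deltas(g) else as.numeric(.degrees(g))
  if (any(delta <= 0)) {
    # isolated atom (order 0 on single atom) contributes nothing meaningful
    if (order == 0L && n_atoms(g) == 1L) return(0)
  }
  if (order == 0L) {
    if (kind != "path") return(0)
    return(sum(1 / sqrt(delta)))
  }
  subs <- .connected_edge_subgraphs(g, order)
  total <- 0
  for (s in subs) {
    if (.subgraph_kind(g, s) == kind) {
      verts <- unique(c(g$bonds$i[s], g$bonds$j[s]))
      total <- total + 1 / sqrt(prod(delta[verts]))
    }
  }
  total
}

# Enumerate connected m-edge subgraphs (as integer vectors of bond-row
# indices) by recursive frontier growth with string-key deduplication.
.connected_edge_subgraphs <- function(g, m) {
  nb <- nrow(g$bonds)
  if (m < 1L || nb < m) return(list())
  # edges incident to each vertex
  inc <- vector("list", n_atoms(g))
  for (r in seq_len(nb)) {
    inc[[g$bonds$i[r]]] <- c(inc[[g$bonds$i[r]]], r)
    inc[[g$bonds$j[r]]] <- c(inc[[g$bonds$j[r]]], r)
  }
  seen <- new.env(hash = TRUE, parent = emptyenv())
  out <- list()
  grow <- function(edges, verts) {
    if (length(edges) == m) {
      key <- paste(sort(edges), collapse = ",")
      if (is.null(seen[[key]])) {
        seen[[key]] <- TRUE
        out[[length(out) + 1L]] <<- sort(edges)
      }
      return(invisible())
    }
    cand <- setdiff(unique(unlist(inc[verts])), edges)
    for (e in cand) {
      grow(c(edges, e), unique(c(verts, g$bonds$i[e], g$bonds$j[e])))
    }
  }
  for (r in seq_len(nb)) grow(r, c(g$bonds$i[r], g$bonds$j[r]))
  out
}

# Classify a connected m-edge subgraph: trees with max internal degree <= 2
# are paths; stars are clusters; other trees are path-clusters; subgraphs
# containing a cycle (ring/chain type) are "other" and excluded.
.subgraph_kind <- function(g, edge_rows) {
  m <- length(edge_rows)
  vs <- c(g$bonds$i[edge_rows], g$bonds$j[edge_rows])
  verts <- unique(vs)
  if (length(verts) != m + 1L) return("other")  # contains a cycle
  deg <- table(vs)
  maxdeg <- max(deg)
  if (maxdeg <= 2L) return("path")
  if (m >= 3L && maxdeg == m) return("cluster")
  "path-cluster"
}

# Count simple paths with len edges (unordered); len in 1..3.
.count_paths <- function(g, len) {
  if (len == 1L) return(nrow(g$bonds))
  adj <- .adjacency(g)
  n <- n_atoms(g)
  count <- 0L
  walk <- function(path) {
    v <- path[length(path)]
    for (w in adj[[v]]) {
      if (w %in% path) next
      if (length(path) == len) {
        if (w > path[1L]) count <<- count + 1L  # count each unordered path once
      } else {
        walk(c(path, w))
      }
    }
  }
  for (s in seq_len(n)) walk(s)
  count
}

# Kier alpha: sum over heavy atoms of (covalent radius / r(Csp3) - 1).
.kier_alpha <- function(g) {
  hyb <- .hybridisation(g)
  r0 <- .COV_RADII$C[["sp3"]]
  total <- 0
  for (v in seq_len(n_atoms(g))) {
    el <- g$atoms$element[v]
    radii <- .COV_RADII[[el]]
    if (is.null(radii)) stop("no covalent radius for element ", el, call. = FALSE)
    total <- total + radii[[hyb[v]]] / r0 - 1
  }
  total
}

#' Kier kappa shape indices
#'
#' First through third kappa, optionally alpha-corrected for heteroatom
#' covalent radii relative to sp3 carbon:
#' \eqn{^1\kappa = A(A-1)^2/P_1^2}, \eqn{^2\kappa = (A-1)(A-2)^2/P_2^2},
#' \eqn{^3\kappa = (A-1)(A-3)^2/P_3^2} (odd A) or \eqn{(A-3)(A-2)^2/P_3^2}
#' (even A), where \eqn{P_i} counts i-edge paths. The alpha correction adds
#' \eqn{\alpha} to A and every \eqn{P_i}.
#'
#' @param g connected [molgraph()] with at least 3 heavy atoms.
#' @param alpha_corrected return \eqn{\kappa_\alpha} variants?
#' @return named numeric vector `kappa1`, `kappa2`, `kappa3` (suffix `a` when
#'   alpha-corrected). A kappa whose defining path count is zero (e.g. the
#'   third kappa of a 4-atom star, which has no 3-edge path) is reported as 0.
#' @export
kappa_indices <- function(g, alpha_corrected = FALSE) {
  .assert_connected(g)
  A <- n_atoms(g)
  if (A < 3L) stop("kappa indices require at least 3 heavy atoms", call. = FALSE)
  alpha <- if (alpha_corrected) .kier_alpha(g) else 0
  P1 <- .count_paths(g, 1L); P2 <- .count_paths(g, 2L); P3 <- .count_paths(g, 3L)
  kap <- function(num, P) {
    if (P == 0 || P + alpha <= 0) return(0)
    num / (P + alpha)^2
  }
  Aa <- A + alpha
  k1 <- kap(Aa * (Aa - 1)^2, P1)
  k2 <- kap((Aa - 1) * (Aa - 2)^2, P2)
  k3 <- if (A %% 2L == 1L) kap((Aa - 1) * (Aa - 3)^2, P3) else kap((Aa - 3) * (Aa - 2)^2, P3)
  nm <- if (alpha_corrected) c("kappa1a", "kappa2a", "kappa3a") else c("kappa1", "kappa2", "kappa3")
  stats::setNames(c(k1, k2, k3), nm)
}

#' Kier molecular flexibility index
#'
#' \eqn{\Phi = {}^1\kappa_\alpha \cdot {}^2\kappa_\alpha / A}.
#' @param g connected [molgraph()], at least 3 heavy atoms.
#' @return flexibility value (positive).
#' @export
flexibility_phi <- function(g) {
  k <- kappa_indices(g, alpha_corrected = TRUE)
  unname(k["kappa1a"] * k["kappa2a"] / n_atoms(g))
}

#' Balaban distance connectivity index J
#'
#' \eqn{J = \frac{M}{\gamma + 1} \sum_{(i,j) \in E} (s_i s_j)^{-1/2}} with
#' \eqn{s_i} the distance-matrix row sums, M the bond count and \eqn{\gamma}
#' the cyclomatic number.
#' @param g connected [molgraph()].
#' @return Balaban J (0 for a single-atom graph).
#' @export
balaban_index <- function(g) {
  .assert_connected(g)
  M <- nrow(g$bonds)
  if (M == 0L) return(0)
  D <- .distance_matrix(g)
  s <- rowSums(D)
  gamma <- M - n_atoms(g) + 1L
  M / (gamma + 1) * sum(1 / sqrt(s[g$bonds$i] * s[g$bonds$j]))
}

#' Electrotopological state (E-state) indices
#'
#' Kier-Hall intrinsic state \eqn{I_i = ((2/L_i)^2 \delta^v_i + 1)/\delta_i}
#' perturbed over all pairs: \eqn{S_i = I_i + \sum_j (I_i - I_j)/(d_{ij}+1)^2}.
#' @param g connected [molgraph()].
#' @return list with `S` (per-atom E-state values) and `total` (their sum,
#'   the molecular E-state descriptor).
#' @export
estate_indices <- function(g) {
  .assert_connected(g)
  n <- n_atoms(g)
  delta <- as.numeric(.degrees(g))
  if (any(delta == 0) && n > 1L) stop("isolated atom in connected graph?", call. = FALSE)
  if (n == 1L) delta <- 1  # single heavy atom: delta taken as 1
  dv <- .valence_deltas(g)
  L <- .element_info(g$atoms$element)$L
  I <- ((2 / L)^2 * dv + 1) / delta
  D <- if (n > 1L) .distance_matrix(g) else matrix(0, 1, 1)
  S <- I
  for (v in seq_len(n)) {
    S[v] <- I[v] + sum((I[v] - I[-v]) / (D[v, -v] + 1)^2)
  }
  list(S = S, total = sum(S))
}

#' Atom and functional-group counts
#'
#' Element counts (O, N, F, Cl, Br, I), the halogen total, the heteroatom
#' count, and graph-matched functional-group counts. Matching conventions:
#' hydroxyl is an O-H not in a carboxyl; amino is an NH2 on carbon; aldehyde
#' is C(=O)H; nitro matches both the charged and the hypervalent dialect;
#' cyano is a triple C-N bond; acid anhydride is C(=O)-O-C(=O); methyl is a
#' CH3 on any heavy atom.
#' @param g a [molgraph()].
#' @return named integer vector.
#' @export
atom_and_group_counts <- function(g) {
  el <- g$atoms$element
  hc <- g$atoms$hcount
  counts <- c(
    n_O = sum(el == "O"), n_N = sum(el == "N"), n_F = sum(el == "F"),
    n_Cl = sum(el == "Cl"), n_Br = sum(el == "Br"), n_I = sum(el == "I")
  )
  counts["NHal"] <- counts[["n_F"]] + counts[["n_Cl"]] + counts[["n_Br"]] + counts[["n_I"]]
  counts["n_hetero"] <- sum(el != "C")

  has_carbonyl_o <- function(c_idx, exclude = integer(0)) {
    any(vapply(setdiff(.neighbours(g, c_idx), exclude), function(w) {
      el[w] == "O" && identical(.bond_order(g, c_idx, w), 2)
    }, TRUE))
  }

  hydroxyl <- 0L; amino <- 0L; aldehyde <- 0L; nitro <- 0L
  cyano <- 0L; methyl <- 0L; anhydride <- 0L
  for (v in seq_len(n_atoms(g))) {
    nb <- .neighbours(g, v)
    if (el[v] == "O" && hc[v] >= 1L && length(nb) == 1L) {
      c_nb <- nb[1L]
      carboxyl <- el[c_nb] == "C" && has_carbonyl_o(c_nb, exclude = v)
      if (!carboxyl) hydroxyl <- hydroxyl + 1L
    }
    if (el[v] == "N" && hc[v] >= 2L && !g$atoms$aromatic[v] &&
        any(el[nb] == "C")) amino <- amino + 1L
    if (el[v] == "C" && hc[v] >= 1L && has_carbonyl_o(v)) aldehyde <- aldehyde + 1L
    if (el[v] == "N") {
      term_o <- nb[vapply(nb, function(w) el[w] == "O" && length(.neighbours(g, w)) == 1L, TRUE)]
      if (length(term_o) == 2L) {
        ords <- vapply(term_o, function(w) .bond_order(g, v, w), 0)
        if (any(ords == 2) && sum(ords) >= 3) nitro <- nitro + 1L
      }
    }
    if (el[v] == "C" && hc[v] == 3L && length(nb) == 1L) methyl <- methyl + 1L
    if (el[v] == "C") {
      for (w in nb) {
        if (el[w] == "N" && identical(.bond_order(g, v, w), 3) &&
            length(.neighbours(g, w)) == 1L) cyano <- cyano + 1L
      }
    }
    if (el[v] == "O" && length(nb) == 2L && hc[v] == 0L) {
      both <- all(vapply(nb, function(w) {
        el[w] == "C" && identical(.bond_order(g, v, w), 1) && has_carbonyl_o(w, exclude = v)
      }, TRUE))
      if (both) anhydride <- anhydride + 1L
    }
  }
  c(counts,
    n_hydroxyl = hydroxyl, n_amino = amino, n_aldehyde = aldehyde,
    n_nitro = nitro, n_cyano = cyano, n_anhydride = anhydride,
    n_methyl = methyl)
}

#' Hydrogen-bond donor and acceptor counts
#'
#' Donors: heavy atoms that are O or N carrying at least one hydrogen (the
#' heavy-atom convention, not a hydrogen count). Acceptors: O plus N atoms,
#' excluding pyrrole-type aromatic N-H and amide nitrogens.
#' @param g a [molgraph()].
#' @return named integer vector `NHdon`, `NHacc`.
#' @export
hbond_counts <- function(g) {
  el <- g$atoms$element
  hc <- g$atoms$hcount
  don <- sum(el %in% c("O", "N") & hc >= 1L)
  acc <- 0L
  for (v in seq_len(n_atoms(g))) {
    if (!(el[v] %in% c("O", "N"))) next
    if (el[v] == "N") {
      if (g$atoms$aromatic[v] && hc[v] >= 1L) next           # pyrrole-type
      amide <- any(vapply(.neighbours(g, v), function(w) {
        el[w] == "C" && any(vapply(setdiff(.neighbours(g, w), v), function(u) {
          el[u] == "O" && identical(.bond_order(g, w, u), 2)
        }, TRUE))
      }, TRUE))
      if (amide) next
    }
    acc <- acc + 1L
  }
  c(NHdon = don, NHacc = acc)
}

#' Compute the topological descriptor block for a batch of structures
#'
#' Evaluates every graph-computable descriptor of the toolkit for each
#' structure, in a fixed column order. Shape and connectivity indices whose
#' defining subgraphs do not exist in a molecule (e.g. kappa2 for a two-atom
#' graph) are reported as 0 so that the emitted table is always complete.
#'
#' @param structures named list of [molgraph()] objects (names become
#'   compound ids), or a character vector of SMILES strings.
#' @param on_error `"abort"` (default) or `"skip"` unusable structures with
#'   a warning.
#' @return a [descriptor_table()] without a target column.
#' @export
compute_descriptor_block <- function(structures, on_error = c("abort", "skip")) {
  on_error <- match.arg(on_error)
  if (is.character(structures)) {
    nm <- if (!is.null(names(structures))) names(structures)
          else sprintf("mol_%d", seq_along(structures))
    structures <- stats::setNames(lapply(structures, function(s) {
      tryCatch(parse_smiles(s), error = identity)
    }), nm)
  }
  if (length(structures) == 0L) stop("empty structure batch", call. = FALSE)
  if (is.null(names(structures)) || any(!nzchar(names(structures)))) {
    names(structures) <- sprintf("mol_%d", seq_along(structures))
  }
  rows <- list()
  for (id in names(structures)) {
    g <- structures[[id]]
    row <- if (inherits(g, "error")) g else tryCatch(.descriptor_row(g), error = identity)
    if (inherits(row, "error")) {
      if (on_error == "abort") stop("compound ", sQuote(id), ": ", conditionMessage(row), call. = FALSE)
      warning("skipping compound ", sQuote(id), ": ", conditionMessage(row), call. = FALSE)
    } else {
      rows[[id]] <- row
    }
  }
  if (length(rows) == 0L) stop("no computable structures in batch", call. = FALSE)
  mat <- do.call(rbind, rows)
  descriptor_table(values = mat, compound_id = names(rows))
}

.descriptor_row <- function(g) {
  .assert_connected(g)
  A <- n_atoms(g)
  safe <- function(expr) tryCatch(expr, error = function(e) 0)
  chi <- function(m, kind, val) safe(chi_index(g, m, kind, valence = val))
  kap  <- if (A >= 3L) kappa_indices(g, FALSE) else c(kappa1 = 0, kappa2 = 0, kappa3 = 0)
  kapa <- if (A >= 3L) kappa_indices(g, TRUE)  else c(kappa1a = 0, kappa2a = 0, kappa3a = 0)
  out <- c(
    MW = molecular_weight(g),
    chi0 = chi(0L, "path", FALSE), chi1 = chi(1L, "path", FALSE),
    chi2 = chi(2L, "path", FALSE), chi3p = chi(3L, "path", FALSE),
    chi4p = chi(4L, "path", FALSE), chi3c = chi(3L, "cluster", FALSE),
    chi4pc = chi(4L, "path-cluster", FALSE),
    chi0v = chi(0L, "path", TRUE), chi1v = chi(1L, "path", TRUE),
    chi2v = chi(2L, "path", TRUE), chi3pv = chi(3L, "path", TRUE),
    chi3cv = chi(3L, "cluster", TRUE), chi4pcv = chi(4L, "path-cluster", TRUE),
    kap, kapa,
    phi = if (A >= 3L) flexibility_phi(g) else 0,
    wiener = safe(wiener_index(g)),
    balaban = safe(balaban_index(g)),
    estate_sum = safe(estate_indices(g)$total),
    atom_and_group_counts(g),
    hbond_counts(g)
  )
  out
}
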