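#' Hydrogen-suppressed molecular graph
#'
#' Constructs the graph container used by all descriptor computations: heavy
#' atoms with implicit hydrogen counts and formal charges, plus a simple bond
#' list. Aromatic bonds are stored with order 1.5; Kekule single/double/triple
#' bonds with orders 1, 2, 3.
#'
#' @param atoms data.frame with columns `element` (symbol), `hcount`
#'   (implicit hydrogens, integer >= 0), `charge` (formal charge, integer),
#'   `aromatic` (logical).
#' @param bonds data.frame with columns `i`, `j` (1-based atom indices) and
#'   `order` (1, 2, 3 or 1.5 for aromatic). May have zero rows.
#' @return object of class `molgraph`.
#' @examples
#' g <- molgraph(
#'   atoms = data.frame(element = c("C", "C"), hcount = c(3L, 3L),
#'                      charge = 0L, aromatic = FALSE),
#'   bonds = data.frame(i = 1L, j = 2L, order = 1)
#' )
#' n_atoms(g)
#' @export
molgraph <- function(atoms, bonds) {
  stopifnot(is.data.frame(atoms), is.data.frame(bonds))
  if (nrow(atoms) < 1L) stop("molecular graph must contain at least one atom", call. = FALSE)
  atoms <- data.frame(
    element  = as.character(atoms$element),
    hcount   = as.integer(atoms$hcount),
    charge   = as.integer(atoms$charge),
    aromatic = as.logical(atoms$aromatic),
    stringsAsFactors = FALSE
  )
  .element_info(atoms$element)  # validates symbols
  if (any(atoms$hcount < 0L)) stop("negative implicit hydrogen count", call. = FALSE)
  if (nrow(bonds) > 0L) {
    bonds <- data.frame(
      i = as.integer(bonds$i), j = as.integer(bonds$j),
      order = as.numeric(bonds$order), stringsAsFactors = FALSE
    )
    n <- nrow(atoms)
    if (any(bonds$i < 1L | bonds$i > n | bonds$j < 1L | bonds$j > n)) {
      stop("bond references atom index out of range", call. = FALSE)
    }
    if (any(bonds$i == bonds$j)) stop("self-loop bond", call. = FALSE)
    if (!all(bonds$order %in% c(1, 1.5, 2, 3))) {
      stop("bond order must be 1, 2, 3 or 1.5 (aromatic)", call. = FALSE)
    }
    swap <- bonds$i > bonds$j
    tmp <- bonds$i[swap]; bonds$i[swap] <- bonds$j[swap]; bonds$j[swap] <- tmp
    if (anyDuplicated(bonds[, c("i", "j")])) stop("duplicate bond", call. = FALSE)
  } else {
    bonds <- data.frame(i = integer(), j = integer(), order = numeric())
  }
  structure(list(atoms = atoms, bonds = bonds, hydrogen_suppressed = TRUE),
            class = "molgraph")
}

#' @export
print.molgraph <- function(x, ...) {
  cat(sprintf("<molgraph: %d heavy atoms, %d bonds, formula %s>\n",
              n_atoms(x), nrow(x$bonds), .formula_string(x)))
  invisible(x)
}

#' Number of heavy atoms in a molecular graph
#' @param g a `molgraph`.
#' @return integer count.
#' @export
n_atoms <- function(g) nrow(g$atoms)

.formula_string <- function(g) {
  tab <- table(g$atoms$element)
  h <- sum(g$atoms$hcount)
  paste0(paste0(names(tab), ifelse(tab > 1L, tab, "")), collapse = "",
         if (h > 0L) paste0("H", h) else "")
}

# Adjacency list over heavy atoms (bond orders ignored).
.adjacency <- function(g) {
  n <- n_atoms(g)
  adj <- vector("list", n)
  for (r in seq_len(nrow(g$bonds))) {
    i <- g$bonds$i[r]; j <- g$bonds$j[r]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  adj
}

# Heavy-atom degree vector.
.degrees <- function(g) {
  n <- n_atoms(g)
  d <- integer(n)
  if (nrow(g$bonds) > 0L) {
    t1 <- tabulate(g$bonds$i, n); t2 <- tabulate(g$bonds$j, n)
    d <- t1 + t2
  }
  d
}

# Valence delta per Kier-Hall: (Zv - h) / (Z - Zv - 1) with the higher-row
# correction in the denominator; second-row atoms reduce to Zv - h.
.valence_deltas <- function(g) {
  info <- .element_info(g$atoms$element)
  num <- info$Zv - g$atoms$hcount
  den <- info$Z - info$Zv - 1
  ifelse(den <= 0, num, num / den)
}

# Sum of bond orders incident to each atom (aromatic = 1.5).
.bond_order_sums <- function(g) {
  n <- n_atoms(g)
  s <- numeric(n)
  for (r in seq_len(nrow(g$bonds))) {
    s[g$bonds$i[r]] <- s[g$bonds$i[r]] + g$bonds$order[r]
    s[g$bonds$j[r]] <- s[g$bonds$j[r]] + g$bonds$order[r]
  }
  s
}

.is_connected <- function(g) {
  n <- n_atoms(g)
  if (n == 1L) return(TRUE)
  length(.component_of(g, 1L)) == n
}

.component_of <- function(g, start) {
  adj <- .adjacency(g)
  seen <- logical(n_atoms(g))
  queue <- start; seen[start] <- TRUE
  while (length(queue) > 0L) {
    v <- queue[1L]; queue <- queue[-1L]
    for (w in adj[[v]]) if (!seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
  }
  which(seen)
}

.assert_connected <- function(g) {
  if (!.is_connected(g)) {
    stop("disconnected structure: descriptor requires a single connected component",
         call. = FALSE)
  }
  invisible(g)
}

# All-pairs topological distance matrix by breadth-first search.
.distance_matrix <- function(g) {
  .assert_connected(g)
  n <- n_atoms(g)
  adj <- .adjacency(g)
  D <- matrix(0L, n, n)
  for (s in seq_len(n)) {
    dist <- rep(-1L, n); dist[s] <- 0L
    queue <- s
    while (length(queue) > 0L) {
      v <- queue[1L]; queue <- queue[-1L]
      for (w in adj[[v]]) if (dist[w] < 0L) { dist[w] <- dist[v] + 1L; queue <- c(queue, w) }
    }
    D[s, ] <- dist
  }
  D
}

# Hybridisation tag per atom from incident bond orders.
.hybridisation <- function(g) {
  n <- n_atoms(g)
  hyb <- rep("sp3", n)
  for (r in seq_len(nrow(g$bonds))) {
    o <- g$bonds$order[r]
    for (v in c(g$bonds$i[r], g$bonds$j[r])) {
      if (o == 3) hyb[v] <- "sp"
      else if (o %in% c(2, 1.5) && hyb[v] != "sp") hyb[v] <- "sp2"
    }
  }
  hyb
}

# Neighbour indices of atom v.
.neighbours <- function(g, v) {
  b <- g$bonds
  c(b$j[b$i == v], b$i[b$j == v])
}

# Order of the bond between u and v, or NA if absent.
.bond_order <- function(g, u, v) {
  b <- g$bonds
  hit <- (b$i == min(u, v)) & (b$j == max(u, v))
  if (any(hit)) b$order[which(hit)[1L]] else NA_real_
}

# Detect six-membered rings with alternating single/double Kekule bonds and
# mark them aromatic (order 1.5). Deliberately simple: fused systems whose
# every six-ring alternates are caught; exotic aromaticity is not perceived.
.perceive_kekule_aromaticity <- function(g) {
  n <- n_atoms(g)
  if (n < 6L || nrow(g$bonds) < 6L) return(g)
  adj <- .adjacency(g)
  rings <- list()
  # enumerate simple 6-cycles by DFS anchored at their smallest vertex
  dfs <- function(path) {
    v <- path[length(path)]
    for (w in adj[[v]]) {
      if (length(path) == 6L) {
        if (w == path[1L]) rings[[length(rings) + 1L]] <<- path
      } else if (!(w %in% path) && w > path[1L]) {
        dfs(c(path, w))
      }
    }
  }
  for (s in seq_len(n)) dfs(s)
  if (length(rings) == 0L) return(g)
  keys <- vapply(rings, function(r) paste(sort(r), collapse = "-"), "")
  rings <- rings[!duplicated(keys)]
  for (r in rings) {
    ords <- vapply(seq_len(6L), function(k) {
      .bond_order(g, r[k], r[k %% 6L + 1L])
    }, 0)
    alternating <- all(ords %in% c(1, 2)) && sum(ords == 2) == 3L &&
      all(abs(diff(c(ords, ords[1L]))) == 1)
    if (alternating || all(ords == 1.5)) {
      for (k in seq_len(6L)) {
        u <- min(r[k], r[k %% 6L + 1L]); v <- max(r[k], r[k %% 6L + 1L])
        sel <- g$bonds$i == u & g$bonds$j == v
        g$bonds$order[sel] <- 1.5
      }
      g$atoms$aromatic[r] <- TRUE
    }
  }
  g
}
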