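#' Parse a MOL/SDF V2000 record into a molecular graph
#'
#' Reads a single MDL MOL (V2000) record, folds explicit hydrogens into the
#' implicit hydrogen counts of their heavy-atom neighbours, fills remaining
#' valence with implicit hydrogens, and perceives aromaticity on six-membered
#' rings with alternating Kekule bonds (bond type 4 is honoured directly).
#'
#' @param text character scalar (possibly multi-line) or character vector of
#'   lines holding one V2000 record.
#' @param keep_largest if `TRUE`, a multi-fragment record (e.g. a salt) is
#'   reduced to its largest connected component instead of raising an error.
#' @return a [molgraph()].
#' @export
parse_molfile <- function(text, keep_largest = FALSE) {
  lines <- if (length(text) == 1L) strsplit(text, "\n", fixed = TRUE)[[1L]] else text
  if (length(lines) < 4L) stop("malformed MOL record: fewer than 4 lines", call. = FALSE)
  counts <- lines[4L]
  natoms <- suppressWarnings(as.integer(substr(counts, 1L, 3L)))
  nbonds <- suppressWarnings(as.integer(substr(counts, 4L, 6L)))
  if (is.na(natoms) || is.na(nbonds) || natoms < 1L || nbonds < 0L) {
    stop("malformed MOL counts line: ", sQuote(trimws(counts)), call. = FALSE)
  }
  if (length(lines) < 4L + natoms + nbonds) {
    stop("malformed MOL record: truncated atom/bond block", call. = FALSE)
  }
  atom_lines <- lines[5:(4L + natoms)]
  element <- trimws(substr(atom_lines, 32L, 34L))
  if (any(element == "")) stop("malformed MOL atom line: missing element symbol", call. = FALSE)
  charge <- integer(natoms)
  bi <- bj <- integer(0); bo <- numeric(0)
  if (nbonds > 0L) {
    bond_lines <- lines[(5L + natoms):(4L + natoms + nbonds)]
    bi <- suppressWarnings(as.integer(substr(bond_lines, 1L, 3L)))
    bj <- suppressWarnings(as.integer(substr(bond_lines, 4L, 6L)))
    bt <- suppressWarnings(as.integer(substr(bond_lines, 7L, 9L)))
    if (anyNA(bi) || anyNA(bj) || anyNA(bt)) stop("malformed MOL bond line", call. = FALSE)
    if (any(bi < 1L | bi > natoms | bj < 1L | bj > natoms)) {
      stop("MOL bond block references atom index out of range", call. = FALSE)
    }
    if (!all(bt %in% 1:4)) stop("unsupported MOL bond type: ", paste(setdiff(bt, 1:4), collapse = ","),
                                call. = FALSE)
    bo <- ifelse(bt == 4L, 1.5, as.numeric(bt))
  }
  # M  CHG property lines override charge column
  for (ln in grep("^M  CHG", lines, value = TRUE)) {
    toks <- scan(text = substr(ln, 7L, nchar(ln)), what = integer(), quiet = TRUE)
    k <- toks[1L]
    for (e in seq_len(k)) {
      charge[toks[2L * e]] <- toks[2L * e + 1L]
    }
  }

  is_h <- element == "H"
  hx <- integer(natoms)  # explicit H folded onto heavy neighbours
  if (any(is_h)) {
    for (r in seq_along(bi)) {
      if (is_h[bi[r]] && !is_h[bj[r]]) hx[bj[r]] <- hx[bj[r]] + 1L
      if (is_h[bj[r]] && !is_h[bi[r]]) hx[bi[r]] <- hx[bi[r]] + 1L
    }
    keep <- which(!is_h)
    remap <- integer(natoms); remap[keep] <- seq_along(keep)
    sel <- !is_h[bi] & !is_h[bj]
    bi <- remap[bi[sel]]; bj <- remap[bj[sel]]; bo <- bo[sel]
    element <- element[keep]; charge <- charge[keep]; hx <- hx[keep]
    if (length(element) == 0L) stop("record contains only hydrogens", call. = FALSE)
  }

  g <- .finish_graph(element, charge, hx, bi, bj, bo, keep_largest)
  .perceive_kekule_aromaticity(g)
}

#' Parse a multi-record SDF file
#'
#' @param path path to an SDF (V2000) file; records separated by `$$$$`.
#' @inheritParams parse_molfile
#' @param on_error `"abort"` stops at the first bad record; `"skip"` drops it
#'   with a warning naming the record.
#' @return named list of [molgraph()] objects (names from the record title
#'   line, falling back to `mol_<k>`).
#' @export
read_sdf <- function(path, keep_largest = FALSE, on_error = c("abort", "skip")) {
  on_error <- match.arg(on_error)
  lines <- readLines(path, warn = FALSE)
  breaks <- c(0L, which(trimws(lines) == "$$$$"))
  if (length(breaks) == 1L) breaks <- c(0L, length(lines) + 1L)
  out <- list()
  for (k in seq_len(length(breaks) - 1L)) {
    rec <- lines[(breaks[k] + 1L):(breaks[k + 1L] - 1L)]
    rec <- rec[cumsum(nzchar(trimws(rec))) > 0L | seq_along(rec) <= 4L]
    if (!any(nzchar(trimws(rec)))) next
    id <- trimws(rec[1L]); if (!nzchar(id)) id <- sprintf("mol_%d", k)
    g <- tryCatch(parse_molfile(rec, keep_largest = keep_largest), error = identity)
    if (inherits(g, "error")) {
      if (on_error == "abort") stop("record ", sQuote(id), ": ", conditionMessage(g), call. = FALSE)
      warning("skipping record ", sQuote(id), ": ", conditionMessage(g), call. = FALSE)
    } else {
      out[[id]] <- g
    }
  }
  if (length(out) == 0L) stop("no parsable records in ", path, call. = FALSE)
  out
}

#' Parse a SMILES string into a molecular graph
#'
#' Supports the organic subset (`B C N O P S F Cl Br I` and aromatic
#' `b c n o p s`), branches, ring closures (digits and `%nn`), bond symbols
#' `- = # :`, and bracket atoms with explicit hydrogen counts and charges.
#' Stereochemistry and isotopes are not supported.
#'
#' @param s SMILES string.
#' @inheritParams parse_molfile
#' @return a [molgraph()].
#' @export
parse_smiles <- function(s, keep_largest = FALSE) {
  stopifnot(is.character(s), length(s) == 1L)
  chars <- strsplit(s, "", fixed = TRUE)[[1L]]
  element <- character(0); aromatic <- logical(0)
  charge <- integer(0); hfix <- integer(0)      # hfix: bracket H count, NA = derive
  bi <- bj <- integer(0); bo <- numeric(0)
  prev_stack <- integer(0)
  prev <- 0L
  pending <- NA_real_
  ring_open <- list()

  add_atom <- function(sym, arom, chg, hn) {
    element <<- c(element, sym); aromatic <<- c(aromatic, arom)
    charge <<- c(charge, chg); hfix <<- c(hfix, hn)
    idx <- length(element)
    if (prev > 0L) add_bond(prev, idx)
    prev <<- idx
  }
  add_bond <- function(a, b) {
    o <- pending
    if (is.na(o)) o <- if (aromatic[a] && aromatic[b]) 1.5 else 1
    bi <<- c(bi, a); bj <<- c(bj, b); bo <<- c(bo, o)
    pending <<- NA_real_
  }

  i <- 1L; n <- length(chars)
  while (i <= n) {
    ch <- chars[i]
    if (ch == "(") {
      if (prev == 0L) stop("SMILES parse error: branch before any atom", call. = FALSE)
      prev_stack <- c(prev_stack, prev); i <- i + 1L
    } else if (ch == ")") {
      if (length(prev_stack) == 0L) stop("SMILES parse error: unbalanced ')'", call. = FALSE)
      prev <- prev_stack[length(prev_stack)]
      prev_stack <- prev_stack[-length(prev_stack)]; i <- i + 1L
    } else if (ch %in% c("-", "=", "#", ":")) {
      pending <- c("-" = 1, "=" = 2, "#" = 3, ":" = 1.5)[[ch]]; i <- i + 1L
    } else if (ch == "/" || ch == "\\") {
      pending <- 1; i <- i + 1L  # stereo bonds degraded to single
    } else if (grepl("[0-9]", ch) || ch == "%") {
      if (ch == "%") {
        if (i + 2L > n) stop("SMILES parse error: bad %nn ring closure", call. = FALSE)
        key <- paste0(chars[i + 1L], chars[i + 2L]); i <- i + 3L
      } else {
        key <- ch; i <- i + 1L
      }
      if (prev == 0L) stop("SMILES parse error: ring digit before any atom", call. = FALSE)
      if (!is.null(ring_open[[key]])) {
        op <- ring_open[[key]]
        o <- pending
        if (is.na(o)) o <- op$order
        if (is.na(o)) o <- if (aromatic[op$atom] && aromatic[prev]) 1.5 else 1
        bi <- c(bi, op$atom); bj <- c(bj, prev); bo <- c(bo, o)
        pending <- NA_real_
        ring_open[[key]] <- NULL
      } else {
        ring_open[[key]] <- list(atom = prev, order = pending)
        pending <- NA_real_
      }
    } else if (ch == "[") {
      close <- which(chars == "]" & seq_along(chars) > i)[1L]
      if (is.na(close)) stop("SMILES parse error: unbalanced '['", call. = FALSE)
      body <- paste0(chars[(i + 1L):(close - 1L)], collapse = "")
      m <- regmatches(body, regexec(
        "^([0-9]*)([A-Za-z][a-z]?)(H([0-9]?))?([+-][0-9]?|\\+\\+|--)?$", body))[[1L]]
      if (length(m) == 0L) stop("SMILES parse error: bad bracket atom [", body, "]", call. = FALSE)
      sym <- m[3L]
      arom <- sym %in% c("b", "c", "n", "o", "p", "s")
      if (arom) sym <- toupper(sym)
      hn <- if (nzchar(m[4L])) { if (nzchar(m[5L])) as.integer(m[5L]) else 1L } else 0L
      chg <- 0L
      if (nzchar(m[6L])) {
        cc <- m[6L]
        chg <- if (cc == "++") 2L else if (cc == "--") -2L
          else {
            mag <- if (nchar(cc) > 1L) as.integer(substr(cc, 2L, nchar(cc))) else 1L
            if (substr(cc, 1L, 1L) == "+") mag else -mag
          }
      }
      add_atom(sym, arom, chg, hn)
      i <- close + 1L
    } else if (grepl("[A-Za-z]", ch)) {
      two <- if (i < n) paste0(ch, chars[i + 1L]) else ""
      if (two %in% c("Cl", "Br")) {
        add_atom(two, FALSE, 0L, NA_integer_); i <- i + 2L
      } else if (ch %in% c("B", "C", "N", "O", "P", "S", "F", "I")) {
        add_atom(ch, FALSE, 0L, NA_integer_); i <- i + 1L
      } else if (ch %in% c("b", "c", "n", "o", "p", "s")) {
        add_atom(toupper(ch), TRUE, 0L, NA_integer_); i <- i + 1L
      } else {
        stop("SMILES parse error: unexpected symbol ", sQuote(ch), call. = FALSE)
      }
    } else {
      stop("SMILES parse error: unexpected character ", sQuote(ch), call. = FALSE)
    }
  }
  if (length(prev_stack) > 0L) stop("SMILES parse error: unbalanced '('", call. = FALSE)
  if (length(ring_open) > 0L) stop("SMILES parse error: unclosed ring bond", call. = FALSE)
  if (length(element) == 0L) stop("SMILES parse error: empty input", call. = FALSE)

  # derive implicit H for organic-subset atoms from bond-order sums
  bosum <- numeric(length(element))
  for (r in seq_along(bi)) {
    bosum[bi[r]] <- bosum[bi[r]] + bo[r]
    bosum[bj[r]] <- bosum[bj[r]] + bo[r]
  }
  h <- hfix
  derive <- is.na(h)
  if (any(derive)) {
    val <- .effective_valence(element[derive], charge[derive])
    h[derive] <- pmax(0L, as.integer(val - ceiling(bosum[derive] - 1e-9)))
  }
  g <- .finish_graph(element, charge, h, bi, bj, bo, keep_largest,
                     aromatic = aromatic, h_is_total = TRUE)
  g
}

#' Read a SMILES list file
#'
#' One molecule per line: `SMILES` or `SMILES<TAB>id`.
#' @param path file path.
#' @inheritParams read_sdf
#' @return named list of [molgraph()] objects.
#' @export
read_smiles_file <- function(path, on_error = c("abort", "skip")) {
  on_error <- match.arg(on_error)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("no SMILES records in ", path, call. = FALSE)
  out <- list()
  for (k in seq_along(lines)) {
    parts <- strsplit(lines[k], "\t", fixed = TRUE)[[1L]]
    id <- if (length(parts) > 1L && nzchar(trimws(parts[2L]))) trimws(parts[2L])
          else sprintf("mol_%d", k)
    g <- tryCatch(parse_smiles(trimws(parts[1L])), error = identity)
    if (inherits(g, "error")) {
      if (on_error == "abort") stop("record ", sQuote(id), ": ", conditionMessage(g), call. = FALSE)
      warning("skipping record ", sQuote(id), ": ", conditionMessage(g), call. = FALSE)
    } else out[[id]] <- g
  }
  out
}

# Shared tail of both parsers: implicit-H assignment (MOL path), fragment
# handling, container construction.
.finish_graph <- function(element, charge, hx, bi, bj, bo, keep_largest,
                          aromatic = NULL, h_is_total = FALSE) {
  n <- length(element)
  if (is.null(aromatic)) aromatic <- rep(FALSE, n)
  if (!h_is_total) {
    bosum <- numeric(n)
    for (r in seq_along(bi)) {
      bosum[bi[r]] <- bosum[bi[r]] + bo[r]
      bosum[bj[r]] <- bosum[bj[r]] + bo[r]
    }
    val <- .effective_valence(element, charge)
    hx <- hx + pmax(0L, as.integer(val - ceiling(bosum + hx - 1e-9)))
  }
  aromatic <- aromatic | .touches_aromatic_bond(n, bi, bj, bo)
  g <- molgraph(
    atoms = data.frame(element = element, hcount = hx, charge = charge,
                       aromatic = aromatic, stringsAsFactors = FALSE),
    bonds = data.frame(i = bi, j = bj, order = bo)
  )
  if (!.is_connected(g)) {
    if (!keep_largest) {
      stop("disconnected structure (multiple fragments); use keep_largest = TRUE to keep the biggest",
           call. = FALSE)
    }
    g <- .largest_fragment(g)
  }
  g
}

.touches_aromatic_bond <- function(n, bi, bj, bo) {
  a <- logical(n)
  sel <- bo == 1.5
  a[bi[sel]] <- TRUE; a[bj[sel]] <- TRUE
  a
}

.largest_fragment <- function(g) {
  n <- n_atoms(g)
  comp <- integer(n); cid <- 0L
  while (any(comp == 0L)) {
    cid <- cid + 1L
    comp[.component_of_masked(g, which(comp == 0L)[1L])] <- cid
  }
  best <- which.max(tabulate(comp))
  keep <- which(comp == best)
  remap <- integer(n); remap[keep] <- seq_along(keep)
  b <- g$bonds[g$bonds$i %in% keep & g$bonds$j %in% keep, , drop = FALSE]
  molgraph(atoms = g$atoms[keep, , drop = FALSE],
           bonds = data.frame(i = remap[b$i], j = remap[b$j], order = b$order))
}

.component_of_masked <- function(g, start) .component_of(g, start)
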