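# Stem topology: the frame of reference for every analysis. Strands are kept
# in cyclic order (strand s donates its Watson-Crick-edge H-bonds to strand
# s+1); quartet k collects the k-th G of every strand counted 5'->3'.

GUANINE_NAMES <- c("DG", "G", "GUA", "DG5", "DG3")
THYMINE_NAMES <- c("DT", "T", "THY", "DT5", "DT3")
ION_NAMES     <- c("K", "K+", "POT")

# Heavy atoms of the guanine base (no sugar, no phosphate): the ring plus
# exocyclic O6 and N2. Sugar atoms would corrupt planarity.
G_BASE_ATOMS <- c("N9", "C8", "N7", "C5", "C6", "O6", "N1", "C2", "N2", "N3", "C4")
T_BASE_ATOMS <- c("N1", "C2", "O2", "N3", "C4", "O4", "C5", "C7", "C6")

#' Stem topology of a tetrameric parallel G-quadruplex
#'
#' Describes which residues form the G-stem: four strands in cyclic order,
#' each with its guanines 5' to 3' and optional flanking thymines, the
#' quartet membership (level k = k-th G of every strand) and the terminus
#' labels 1-8 (5' end of strand s = label s, 3' end = label s + 4).
#'
#' @param strands list of 4 lists, each with elements `chain` (chain id),
#'   `g_resno` (integer vector, guanine residue numbers 5' to 3'),
#'   `t5_resno`, `t3_resno` (flanking thymine residue numbers or `NA`).
#' @return object of class `"stem_topology"` with fields `n_quartets`,
#'   `strands`, `quartets` (n_quartets x 4 matrix of residue numbers) and
#'   `terminus_labels` (data.frame: label, strand, end, chain, resno).
#' @export
stem_topology <- function(strands) {
  if (length(strands) != 4)
    stop("a tetrameric stem needs exactly 4 strands", call. = FALSE)
  nq <- unique(vapply(strands, function(s) length(s$g_resno), integer(1)))
  if (length(nq) != 1)
    stop("unequal G-tract lengths across strands; supply an explicit topology",
         call. = FALSE)
  if (nq < 2) stop("at least 2 quartets are required", call. = FALSE)
  quartets <- vapply(strands, function(s) as.integer(s$g_resno), integer(nq))
  if (is.null(dim(quartets))) quartets <- matrix(quartets, nrow = nq)

  term <- data.frame(
    label  = 1:8,
    strand = rep(1:4, 2),
    end    = rep(c("5'", "3'"), each = 4),
    chain  = rep(vapply(strands, `[[`, "", "chain"), 2),
    resno  = c(vapply(strands, function(s)
                 if (is.na(s$t5_resno)) s$g_resno[1] else s$t5_resno, numeric(1)),
               vapply(strands, function(s)
                 if (is.na(s$t3_resno)) s$g_resno[length(s$g_resno)] else s$t3_resno,
                 numeric(1))),
    stringsAsFactors = FALSE
  )

  structure(list(n_quartets = nq, strands = strands, quartets = quartets,
                 terminus_labels = term),
            class = "stem_topology")
}

#' Detect the stem topology from an atom table
#'
#' Groups residues by chain, finds four guanine tracts of equal length with
#' optional flanking thymines, and builds the quartet assignment by level.
#' The cyclic strand order (who H-bonds to whom) is taken from the chain
#' order unless reference coordinates are supplied, in which case the donor
#' neighbor of each strand is resolved from the shortest N1-O6 distances in
#' that frame.
#'
#' @param atoms atom table (see [gq_trajectory()]).
#' @param coords optional `n_atoms x 3` matrix of one frame used to resolve
#'   the cyclic strand order.
#' @return a `"stem_topology"`.
#' @export
detect_topology <- function(atoms, coords = NULL) {
  res <- unique(atoms[, c("chain", "resno", "resid")])
  res <- res[order(res$chain, res$resno), ]
  strands <- list()
  for (ch in unique(res$chain)) {
    r <- res[res$chain == ch, ]
    gs <- r$resno[r$resid %in% GUANINE_NAMES]
    if (length(gs) == 0) next
    if (any(diff(gs) != 1))
      stop(sprintf("chain %s: guanine tract is not contiguous", ch), call. = FALSE)
    t5 <- r$resno[r$resid %in% THYMINE_NAMES & r$resno == min(gs) - 1]
    t3 <- r$resno[r$resid %in% THYMINE_NAMES & r$resno == max(gs) + 1]
    strands[[length(strands) + 1]] <-
      list(chain = ch, g_resno = gs,
           t5_resno = if (length(t5)) t5 else NA,
           t3_resno = if (length(t3)) t3 else NA)
  }
  if (length(strands) != 4)
    stop(sprintf("found %d G-tract strand(s), need 4; supply an explicit topology",
                 length(strands)), call. = FALSE)
  lens <- vapply(strands, function(s) length(s$g_resno), integer(1))
  if (length(unique(lens)) != 1)
    stop(sprintf("unequal G-tract lengths (%s); supply an explicit topology",
                 paste(lens, collapse = ",")), call. = FALSE)

  if (!is.null(coords)) strands <- order_strands_cyclic(strands, atoms, coords)
  stem_topology(strands)
}

# Resolve the cyclic (donor -> acceptor) strand order from one frame: the
# Watson-Crick edge (N1) of a strand's first G points at the Hoogsteen edge
# (O6) of its acceptor neighbor's first G.
order_strands_cyclic <- function(strands, atoms, coords) {
  n1 <- lapply(strands, function(s)
    coords[atom_index(atoms, s$chain, s$g_resno[1], "N1"), ])
  o6 <- lapply(strands, function(s)
    coords[atom_index(atoms, s$chain, s$g_resno[1], "O6"), ])
  order_out <- 1L
  used <- 1L
  cur <- 1L
  for (step in 1:3) {
    d <- vapply(1:4, function(j)
      if (j %in% used) Inf else vnorm(o6[[j]] - n1[[cur]]), numeric(1))
    nxt <- which.min(d)
    order_out <- c(order_out, nxt)
    used <- c(used, nxt)
    cur <- nxt
  }
  strands[order_out]
}

# Atom-row indices of the heavy base atoms of the G at (strand s, level k).
g_base_index <- function(atoms, topology, s, k) {
  st <- topology$strands[[s]]
  atom_index(atoms, st$chain, st$g_resno[k], G_BASE_ATOMS)
}

#' Anchor atoms of a terminus
#'
#' The pulling anchors are the geometric centers of the C2, C4 and C6 atoms
#' of the terminal thymine at the labeled strand end.
#'
#' @param topology a `"stem_topology"`.
#' @param label terminus label, 1-8.
#' @param atoms atom table of the trajectory.
#' @return integer atom-row indices of C2, C4, C6 of the anchor thymine.
#' @export
anchor_atoms <- function(topology, label, atoms) {
  t <- topology$terminus_labels
  row <- t[t$label == label, ]
  if (nrow(row) != 1) stop("terminus label must be one of 1..8", call. = FALSE)
  st <- topology$strands[[row$strand]]
  tres <- if (row$end == "5'") st$t5_resno else st$t3_resno
  if (is.na(tres))
    stop(sprintf("terminus %d has no flanking T to anchor", label), call. = FALSE)
  atom_index(atoms, row$chain, tres, c("C2", "C4", "C6"))
}

#' @export
print.stem_topology <- function(x, ...) {
  cat(sprintf("stem_topology: %d quartets x 4 strands (parallel, all-anti)\n",
              x$n_quartets))
  for (s in 1:4) {
    st <- x$strands[[s]]
    cat(sprintf("  strand %d [chain %s]: %s G %s %s\n", s, st$chain,
                if (is.na(st$t5_resno)) "   " else "T +",
                paste(st$g_resno, collapse = ","),
                if (is.na(st$t3_resno)) "" else "+ T"))
  }
  invisible(x)
}
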