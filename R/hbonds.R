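# Quartet hydrogen-bond bookkeeping.
#
# In a parallel quartet each guanine donates two H-bonds from its
# Watson-Crick edge (N1-H...O6, N2-H...N7) to the Hoogsteen edge of the next
# strand's guanine. Strand pair p (p = 1..4) is the ordered pair
# (donor strand p -> acceptor strand p %% 4 + 1). To support register-shifted
# (slip-stranded) states, bonds are evaluated between every donor level and
# every acceptor level of a pair, not just the native diagonal.

DONOR_ATOMS    <- c("N1", "N2")   # Watson-Crick edge of the donor G
ACCEPTOR_ATOMS <- c("O6", "N7")   # Hoogsteen edge of the acceptor G

# Precomputed donor/acceptor atom-row indices: [strand, level, atom(2)].
hb_indices <- function(atoms, topology) {
  nq <- topology$n_quartets
  don <- acc <- array(NA_integer_, c(4, nq, 2))
  for (s in 1:4) for (k in 1:nq) {
    st <- topology$strands[[s]]
    don[s, k, ] <- atom_index(atoms, st$chain, st$g_resno[k], DONOR_ATOMS)
    acc[s, k, ] <- atom_index(atoms, st$chain, st$g_resno[k], ACCEPTOR_ATOMS)
  }
  list(don = don, acc = acc)
}

#' Quartet H-bond state of one frame
#'
#' Evaluates all Watson-Crick-edge to Hoogsteen-edge hydrogen bonds between
#' cyclically adjacent strands, at every level pairing (so strand slippage is
#' visible as off-diagonal bonds). A bond is present when the donor-acceptor
#' distance is at or below `d_cut`; when hydrogens are present in the
#' topology and `use_hydrogens = TRUE`, the donor-H-acceptor angle must also
#' be at least `angle_cut`. The distance-only criterion (default cutoff
#' 3.4 A) is the fallback for hydrogen-free models.
#'
#' @param coords `n_atoms x 3` matrix of one frame.
#' @param atoms atom table.
#' @param topology a `"stem_topology"`.
#' @param d_cut donor-acceptor distance cutoff in A (inclusive). Default
#'   3.4 (distance-only mode); use 3.5 with an angle criterion.
#' @param angle_cut donor-H-acceptor angle cutoff in degrees (default 135).
#' @param use_hydrogens evaluate the angle criterion if hydrogens exist.
#' @param idx optional precomputed atom-index set from an internal helper;
#'   supplied automatically by [hbond_series()].
#' @return object of class `"hbond_state"`: logical array
#'   `[pair, donor_level, acceptor_level, bond]` (bond 1 = N1...O6,
#'   bond 2 = N2...N7), with the distance array as attribute `"distance"`.
#' @export
hbond_state <- function(coords, atoms, topology, d_cut = 3.4,
                        angle_cut = 135, use_hydrogens = FALSE, idx = NULL) {
  nq <- topology$n_quartets
  if (is.null(idx)) idx <- hb_indices(atoms, topology)
  state <- array(FALSE, c(4, nq, nq, 2))
  dist  <- array(NA_real_, c(4, nq, nq, 2))
  for (p in 1:4) {
    sa <- p %% 4 + 1  # acceptor strand
    for (b in 1:2) {
      D <- coords[idx$don[p, , b], , drop = FALSE]
      A <- coords[idx$acc[sa, , b], , drop = FALSE]
      dm <- sqrt(pmax(0, outer(rowSums(D^2), rowSums(A^2), "+") - 2 * D %*% t(A)))
      dist[p, , , b] <- dm
      state[p, , , b] <- dm <= d_cut
    }
  }
  if (use_hydrogens) {
    hn <- list(N1 = "H1", N2 = c("H21", "H22"))
    for (p in 1:4) {
      sa <- p %% 4 + 1
      std <- topology$strands[[p]]
      for (kd in 1:nq) {
        for (b in 1:2) {
          hname <- hn[[DONOR_ATOMS[b]]]
          hidx <- which(atoms$chain == std$chain &
                        atoms$resno == std$g_resno[kd] &
                        atoms$elety %in% hname)
          if (!length(hidx)) next
          for (ka in 1:nq) {
            if (!state[p, kd, ka, b]) next
            dvec <- coords[idx$don[p, kd, b], ]
            avec <- coords[idx$acc[sa, ka, b], ]
            angs <- vapply(hidx, function(i)
              angle_between(dvec - coords[i, ], avec - coords[i, ]), numeric(1))
            state[p, kd, ka, b] <- max(angs) >= angle_cut
          }
        }
      }
    }
  }
  structure(state, distance = dist, class = c("hbond_state", "array"))
}

#' H-bond state series over a trajectory
#'
#' @inheritParams hbond_state
#' @param traj a [gq_trajectory()].
#' @param ... passed to [hbond_state()].
#' @return list of class `"hbond_series"`: `states` (list of per-frame
#'   `"hbond_state"`), `time` and the cutoffs used.
#' @export
hbond_series <- function(traj, topology, ...) {
  idx <- hb_indices(traj$atoms, topology)
  states <- lapply(seq_len(n_frames(traj)), function(i)
    hbond_state(frame_coords(traj, i), traj$atoms, topology, ..., idx = idx))
  structure(list(states = states, time = traj$time, topology = topology),
            class = "hbond_series")
}

# Total bonds the G at (strand s, level k) participates in (donor side on
# pair s, acceptor side on pair s-1), across all level pairings.
g_bond_count <- function(state, s, k) {
  p_acc <- (s + 2) %% 4 + 1  # pair whose acceptor strand is s
  sum(state[s, k, , ]) + sum(state[p_acc, , k, ])
}

# Bonds at the native register within quartet row k, excluding pairs that
# involve strand `exclude` (0 = none).
quartet_row_bonds <- function(state, k, exclude = 0) {
  total <- 0
  for (p in 1:4) {
    sa <- p %% 4 + 1
    if (p == exclude || sa == exclude) next
    total <- total + sum(state[p, k, k, ])
  }
  total
}

# Number of bonds between strand s and each of its two neighbors:
# c(donated to s+1, received from s-1).
strand_pair_bonds <- function(state, s) {
  p_acc <- (s + 2) %% 4 + 1
  c(donated = sum(state[s, , , ]), received = sum(state[p_acc, , , ]))
}

#' Strand register matrix from an H-bond state
#'
#' Register offsets (in quartet levels) of each strand relative to the
#' reference strand (the first strand that still has bonds; strand 1 in a
#' native stem), derived from the level pairings of the inter-strand
#' H-bonds: the modal level shift is propagated around the strand cycle
#' from the anchor over pairs that still have bonds. Strands unreachable
#' through any bonded pair have offset `NA` (detached candidates).
#'
#' @param state an `"hbond_state"` (one frame).
#' @return list with `offsets` (numeric length 4, offset of each strand, NA
#'   if undefined) and `per_residue` (4 x n_quartets matrix of per-G partner
#'   shifts, NA where a G has no bond).
#' @export
register_matrix <- function(state) {
  nq <- dim(state)[2]
  # a bond (kd, ka) on pair p means the two Gs share a geometric level:
  # kd + r_donor = ka + r_acceptor, so ka - kd votes for r_donor - r_acceptor.
  rel <- rep(NA_real_, 4)
  for (p in 1:4) {
    votes <- integer(0)
    for (kd in 1:nq) for (ka in 1:nq)
      if (any(state[p, kd, ka, ])) votes <- c(votes, rep(ka - kd, sum(state[p, kd, ka, ])))
    if (length(votes)) {
      tb <- table(votes)
      rel[p] <- as.numeric(names(tb)[which.max(tb)])
    }
  }
  offsets <- rep(NA_real_, 4)
  # anchor at the best-bonded strand (strand 1 in a native stem; ties keep
  # the lowest index)
  strand_bonds <- vapply(1:4, function(s)
    sum(strand_pair_bonds(state, s)), numeric(1))
  if (all(strand_bonds == 0))
    return(list(offsets = offsets, per_residue = matrix(NA_real_, 4, nq)))
  anchor <- which.max(strand_bonds)
  offsets[anchor] <- 0
  # propagate around the 4-cycle (pair p joins strand p and p %% 4 + 1),
  # well-bonded interfaces first: when incidental contacts of a displaced
  # strand contradict the intact interfaces, the intact ones win
  nb <- vapply(1:4, function(p) sum(state[p, , , ]), numeric(1))
  order_p <- order(-nb)
  repeat {
    changed <- FALSE
    for (p in order_p) {
      sa <- p %% 4 + 1
      if (!is.na(rel[p])) {
        if (!is.na(offsets[p]) && is.na(offsets[sa])) {
          offsets[sa] <- offsets[p] - rel[p]; changed <- TRUE
        } else if (is.na(offsets[p]) && !is.na(offsets[sa])) {
          offsets[p] <- offsets[sa] + rel[p]; changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  per_res <- matrix(NA_real_, 4, nq)
  for (s in 1:4) for (k in 1:nq) {
    p_acc <- (s + 2) %% 4 + 1
    shifts <- c(which(apply(state[s, k, , , drop = FALSE], 3, any)) - k,
                which(apply(state[p_acc, , k, , drop = FALSE], 2, any)) - k)
    if (length(shifts)) {
      tb <- table(shifts)
      per_res[s, k] <- as.numeric(names(tb)[which.max(tb)])
    }
  }
  list(offsets = offsets, per_residue = per_res)
}
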