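#' Joint-position tensor (stream 1 input)
#'
#' Copies a normalized motion sample into the `T x J x C` feature
#' tensor `S` consumed by the joint-position stream, where `C = 3` is
#' the coordinate dimension modelled as channels.
#'
#' @param sample A normalized [motion_sample()].
#' @return A `joint_position_tensor`: list with `S` (T x J x 3 array),
#'   `T`, `J`, `C` and `joint_names`.
#' @export
build_jp <- function(sample) {
  pos <- sample$positions
  S <- array(as.vector(pos), dim(pos))  # value copy, detached from source
  structure(list(S = S, T = dim(pos)[1], J = dim(pos)[2], C = 3L,
                 joint_names = sample$joint_names),
            class = "joint_position_tensor")
}

#' Column index of an ordered joint pair
#'
#' The relative-displacement tensor orders its `J(J-1)` columns grouped
#' by first joint: all pairs `(1, j)` for ascending `j != 1`, then all
#' `(2, j)`, and so on.  Columns `(i-1)(J-1)+1 ... i(J-1)` are thus
#' exactly joint `i`'s displacements to all other joints — the block a
#' width-`(J-1)`, stride-`(J-1)` spatial filter covers in one placement.
#'
#' @param i,j 1-based joint indices, `i != j`.
#' @param J Joint count.
#' @return 1-based column index of pair `(i, j)`.
#' @export
pair_index <- function(i, j, J) {
  if (any(i < 1 | i > J | j < 1 | j > J))
    stopf("joint indices must lie in 1..%d", J)
  if (any(i == j))
    stopf("self-loop pair (%d, %d): pairs connecting a joint to itself are excluded",
          i[i == j][1], i[i == j][1])
  (i - 1L) * (J - 1L) + j - (j > i)
}

#' Ordered joint-pair table
#'
#' @param J Joint count.
#' @return Data frame with columns `i`, `j` listing all `J(J-1)`
#'   ordered pairs in [pair_index()] order.
#' @export
pair_order <- function(J) {
  i <- rep(seq_len(J), each = J - 1L)
  j <- as.vector(vapply(seq_len(J), function(a) seq_len(J)[-a],
                        integer(J - 1L)))
  data.frame(i = i, j = j)
}

#' Relative-joint-displacement tensor (stream 2 input)
#'
#' Builds the `T x D x C` tensor `S'` of displacements between all
#' ordered joint pairs, `D = J(J-1)`:
#' `S'[t, index(i,j), ] = position(i, t) - position(j, t)`.
#' Antisymmetry `S'[t, index(i,j), ] = -S'[t, index(j,i), ]` holds
#' exactly, and the tensor is invariant to whole-body translation.
#'
#' @param sample A normalized [motion_sample()].
#' @return A `relative_displacement_tensor`: list with `S_prime`
#'   (T x D x 3 array), `pair_order` (see [pair_order()]), `T`, `J`,
#'   `D` and `C`.
#' @export
build_rjdp <- function(sample) {
  pos <- sample$positions
  J <- dim(pos)[2]
  if (J < 2) stopf("need at least 2 joints for displacement pairs")
  po <- pair_order(J)
  Sp <- pos[, po$i, , drop = FALSE] - pos[, po$j, , drop = FALSE]
  dimnames(Sp) <- NULL
  structure(list(S_prime = Sp, pair_order = po, T = dim(pos)[1], J = J,
                 D = J * (J - 1L), C = 3L),
            class = "relative_displacement_tensor")
}

# Stream-2 tensor reshaped for the block convolution: T x J x ((J-1)*C),
# where the channel axis stacks the J-1 within-block pair positions for
# each coordinate (pair offset fastest).  Column j of the output holds
# joint j's full correlation block, so a temporal kernel-3 convolution
# over this layout is exactly the paper's F_T x (J-1) x C filter with
# spatial stride J-1.
rjdp_blocked <- function(rjdp) {
  Sp <- rjdp$S_prime
  Tn <- dim(Sp)[1]; J <- rjdp$J; J1 <- J - 1L
  # (T, D, C) -> (T, J1, J, C) -> (T, J, J1, C) -> (T, J, J1*C)
  a <- array(Sp, c(Tn, J1, J, 3))
  a <- aperm(a, c(1, 3, 2, 4))
  array(a, c(Tn, J, J1 * 3L))
}
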