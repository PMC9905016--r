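#' Factorial marginalization of a trial tensor
#'
#' Decomposes the trial tensor `D[t, v, a, r, c]` into the additive
#' components used in factorial ANOVA: a grand mean `M[t, c]` (average over
#' videos, sounds and repeats), a video-related component `V[t, v, c]`
#' (average over sounds and repeats, minus `M`), a sound-related component
#' `A[t, a, c]` (average over videos and repeats, minus `M`), an audiovisual
#' interaction `I[t, v, a, c]` (per-pair average minus the three previous
#' terms) and trial noise `E[t, v, a, r, c]` (deviation of each repeat from
#' its pair average). The decomposition is exact:
#' `D = M + V + A + I + E` (broadcast over missing indices), the factor
#' components sum to zero over their own index, and under the balanced
#' design the components are orthogonal, so their squared norms partition
#' the variance of `D - M`.
#'
#' Applies identically to behavioral-channel tensors.
#'
#' @param D a `trial_tensor` (or plain 5-way array) with no missing values.
#' @return object of class `marginal_components`: list with `M`, `V`, `A`,
#'   `I`, `E` and the tensor's dimensions/attributes.
#' @export
marginalize <- function(D) {
  d <- dim(D)
  if (length(d) != 5L) stop_arg("D must be a 5-way array [t, v, a, r, c]")
  if (anyNA(D)) stop_arg("D contains missing values; the design must be complete")
  nt <- d[1]; nv <- d[2]; na <- d[3]; nr <- d[4]; nc <- d[5]

  # per-pair averages over repeats
  P <- colMeans(aperm(unclass(D), c(4, 1, 2, 3, 5)), dims = 1)   # [t, v, a, c]
  M <- colMeans(aperm(P, c(2, 3, 1, 4)), dims = 2)               # [t, c]
  Va <- colMeans(aperm(P, c(3, 1, 2, 4)), dims = 1)              # [t, v, c]
  Aa <- colMeans(aperm(P, c(2, 1, 3, 4)), dims = 1)              # [t, a, c]
  V <- Va
  for (v in seq_len(nv)) V[, v, ] <- Va[, v, ] - M
  A <- Aa
  for (a in seq_len(na)) A[, a, ] <- Aa[, a, ] - M
  I <- P
  for (v in seq_len(nv)) for (a in seq_len(na))
    I[, v, a, ] <- P[, v, a, ] - M - V[, v, ] - A[, a, ]
  E <- unclass(D)
  for (r in seq_len(nr)) E[, , , r, ] <- array(E[, , , r, ], dim(P)) - P

  structure(list(M = M, V = V, A = A, I = I, E = E,
                 dims = d,
                 bin_size = attr(D, "bin_size"),
                 rel_times = attr(D, "rel_times"),
                 channel_kind = attr(D, "channel_kind"),
                 channel_ids = attr(D, "channel_ids")),
            class = "marginal_components")
}

#' Reconstruct the trial tensor from its marginal components
#'
#' Inverse of [marginalize()]; used to verify exact additivity.
#' @param m a `marginal_components` object.
#' @return the reconstructed 5-way array.
#' @export
recompose <- function(m) {
  d <- m$dims
  out <- array(0, dim = d)
  for (v in seq_len(d[2])) for (a in seq_len(d[3])) {
    slab <- m$M + m$V[, v, ] + m$A[, a, ] + m$I[, v, a, ]
    for (r in seq_len(d[4])) out[, v, a, r, ] <- slab + m$E[, v, a, r, ]
  }
  out
}

#' @export
print.marginal_components <- function(x, ...) {
  d <- x$dims
  ss <- function(z) sum(z^2)
  tot <- ss(x$V) * d[3] * d[4] + ss(x$A) * d[2] * d[4] +
    ss(x$I) * d[4] + ss(x$E)
  cat(sprintf("Marginal components of a %s tensor (%d bins, %d x %d design, %d repeats, %d channels)\n",
              x$channel_kind, d[1], d[2], d[3], d[4], d[5]))
  if (tot > 0)
    cat(sprintf("  share of mean-removed variance: video %.1f%%, sound %.1f%%, interaction %.1f%%, noise %.1f%%\n",
                100 * ss(x$V) * d[3] * d[4] / tot, 100 * ss(x$A) * d[2] * d[4] / tot,
                100 * ss(x$I) * d[4] / tot, 100 * ss(x$E) / tot))
  invisible(x)
}
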