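#' Contact-restraint potential
#'
#' Predicted contacts enter the folding simulation through a smooth
#' piecewise well on the Cb-Cb distance `d`:
#' flat at `-U` for `d <= 8` (satisfied contact), a half-sine rise to 0 at
#' `d2`, a half-sine rise to `+U` at 80, and flat `+U` beyond. `d2` sets the
#' gradient of the well and grows with chain length, from 14 A for short
#' chains to 24 A for long ones.
#'
#' @name contact_potential
NULL

#' Length-dependent well-width parameter d2
#'
#' Clamped linear map over chain lengths 50-350 spanning the 14-24 A range:
#' `d2 = 14 + 10 * clamp((L - 50) / 300, 0, 1)`.
#'
#' @param L chain length (>= 2).
#' @return d2 in Angstrom, within `[14, 24]`.
#' @export
d2_for_length <- function(L) {
  stopifnot(L >= 2)
  14 + 10 * clamp((L - 50) / (350 - 50), 0, 1)
}

#' Restraint parameter set
#'
#' @param d2 well-width parameter in `[14, 24]` A; defaults to
#'   [d2_for_length()] of `L`.
#' @param L chain length used when `d2` is not given.
#' @return a `RestraintParams` list with `d_contact` (8 A), `d_far` (80 A)
#'   and `d2`.
#' @export
restraint_params <- function(d2 = NULL, L = NULL) {
  if (is.null(d2)) {
    if (is.null(L)) cf_abort("cf_domain_error", "need either d2 or L")
    d2 <- d2_for_length(L)
  }
  if (!(d2 > 8 && d2 < 80)) {
    cf_abort("cf_domain_error", "d2 must lie strictly between 8 and 80 A")
  }
  structure(list(d_contact = 8, d_far = 80, d2 = d2),
            class = "RestraintParams")
}

#' Contact-restraint energy of one residue pair
#'
#' Vectorized over `d_ij` and `u_ij` (recycled to a common length).
#'
#' @param d_ij Cb-Cb distance(s) in A (>= 0).
#' @param u_ij contact confidence weight(s) (> 0).
#' @param d2 well-width parameter (8 < d2 < 80).
#' @return energy value(s) in `[-u_ij, u_ij]`.
#' @export
contact_energy <- function(d_ij, u_ij, d2) {
  if (any(d_ij < 0)) cf_abort("cf_domain_error", "distance must be >= 0")
  if (any(u_ij <= 0)) cf_abort("cf_domain_error", "U_ij must be > 0")
  if (!(d2 > 8 && d2 < 80)) {
    cf_abort("cf_domain_error", "d2 must lie strictly between 8 and 80 A")
  }
  n <- max(length(d_ij), length(u_ij))
  d_ij <- rep_len(d_ij, n)
  u_ij <- rep_len(u_ij, n)
  e <- numeric(n)
  b1 <- d_ij <= 8
  b2 <- d_ij > 8 & d_ij <= d2
  b3 <- d_ij > d2 & d_ij < 80
  b4 <- d_ij >= 80
  e[b1] <- -u_ij[b1]
  e[b2] <- -(u_ij[b2] / 2) *
    (1 - sin((d_ij[b2] - (8 + d2) / 2) / (d2 - 8) * pi))
  e[b3] <- (u_ij[b3] / 2) *
    (1 + sin((d_ij[b3] - (80 + d2) / 2) / (80 - d2) * pi))
  e[b4] <- u_ij[b4]
  e
}

#' Total contact-restraint energy of a conformation
#'
#' Sums [contact_energy()] over every consensus contact, using the
#' conformation's virtual-Cb distances.
#'
#' @param conf a `ChainConformation`.
#' @param cs a `ConsensusContactSet`.
#' @param params a [restraint_params()]; defaults to the length-derived d2.
#' @return total restraint energy.
#' @export
restraint_energy <- function(conf, cs,
                             params = restraint_params(L = conf$n_res)) {
  stopifnot(inherits(conf, "ChainConformation"),
            inherits(cs, "ConsensusContactSet"))
  ct <- cs$contacts
  if (nrow(ct) == 0L) return(0)
  if (max(ct$j) > conf$n_res) {
    cf_abort("cf_index_range_error",
             "contact index %d exceeds chain length %d", max(ct$j), conf$n_res)
  }
  dv <- conf$cb[ct$i, , drop = FALSE] - conf$cb[ct$j, , drop = FALSE]
  d <- sqrt(rowSums(dv * dv))
  sum(contact_energy(d, ct$u, params$d2))
}
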