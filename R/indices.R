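#' Index lattice of the 3D Zernike expansion
#'
#' Valid indices are \code{0 <= n <= order_max}, \code{0 <= l <= n} with
#' \code{n - l} even, and (when \code{with_m = TRUE}) \code{0 <= m <= l}.
#' Negative-m coefficients are never stored: for a real-valued density they
#' follow from conjugation symmetry,
#' \eqn{\Omega_{n,l,-m} = (-1)^m \overline{\Omega_{n,l,m}}}.
#'
#' @param order_max maximum expansion order N (non-negative integer).
#' @param with_m if \code{TRUE} return (n, l, m >= 0) triples, otherwise
#'   (n, l) pairs.
#' @return data.frame with columns \code{n}, \code{l} and (optionally)
#'   \code{m}, in canonical order: n ascending, then l, then m.
#' @export
zernike_indices <- function(order_max, with_m = TRUE) {
  stopifnot(length(order_max) == 1, order_max >= 0, order_max == round(order_max))
  rows <- list()
  for (n in 0:order_max) {
    for (l in seq(n %% 2, n, by = 2)) {
      if (with_m) {
        rows[[length(rows) + 1L]] <- data.frame(n = n, l = l, m = 0:l)
      } else {
        rows[[length(rows) + 1L]] <- data.frame(n = n, l = l)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Count valid Zernike indices
#'
#' Number of (n, l) pairs (\code{with_m = FALSE}) or (n, l, m >= 0) triples
#' (\code{with_m = TRUE}) up to order \code{order_max}.  At N = 20 these are
#' 121 and 946 respectively: the lengths of the classical 3DZD invariant
#' vector and of one Canterakis-norm vector.
#'
#' @inheritParams zernike_indices
#' @return integer count.
#' @export
count_indices <- function(order_max, with_m = TRUE) {
  stopifnot(length(order_max) == 1, order_max >= 0, order_max == round(order_max))
  total <- 0L
  for (n in 0:order_max) {
    ls <- seq(n %% 2, n, by = 2)
    total <- total + if (with_m) sum(ls + 1L) else length(ls)
  }
  as.integer(total)
}
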