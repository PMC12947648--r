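# Restricted cubic spline (natural spline) basis, Harrell parameterisation:
# linear tails beyond the boundary knots, k knots -> k-1 columns (the first
# is x itself).  Built in-package; verified in tests against a brute-force
# truncated-power construction.

#' Default knot placement quantiles
#'
#' @param n_knots number of knots (3, 4 or 5).
#' @return Quantile probabilities at which knots are placed.
#' @export
rcs_default_probs <- function(n_knots) {
  switch(as.character(n_knots),
         "3" = c(0.10, 0.50, 0.90),
         "4" = c(0.05, 0.35, 0.65, 0.95),
         "5" = c(0.05, 0.275, 0.50, 0.725, 0.95),
         stop_config("n_knots must be 3, 4 or 5"))
}

#' Restricted cubic spline basis
#'
#' For knots `t_1 < ... < t_k`, column 1 is `x`; column `j+1`
#' (`j = 1..k-2`) is
#' `[(x-t_j)_+^3 - (x-t_{k-1})_+^3 (t_k-t_j)/(t_k-t_{k-1})
#'   + (x-t_k)_+^3 (t_{k-1}-t_j)/(t_k-t_{k-1})] / (t_k-t_1)^2`,
#' which is linear for `x` outside `[t_1, t_k]`.
#'
#' @param x numeric vector.
#' @param knots knot locations (length >= 3), or NULL to place
#'   `n_knots` knots at the default quantiles of `x`.
#' @param n_knots used when `knots` is NULL (default 4).
#' @return Matrix with `length(knots) - 1` columns and attribute `knots`.
#' @export
rcs_basis <- function(x, knots = NULL, n_knots = 4) {
  if (is.null(knots))
    knots <- unname(quantile(x, rcs_default_probs(n_knots), na.rm = TRUE,
                             type = 7))
  knots <- sort(unique(knots))
  k <- length(knots)
  if (k < 3) stop_config("restricted cubic splines need >= 3 distinct knots")
  pos3 <- function(u) pmax(u, 0)^3
  norm <- (knots[k] - knots[1])^2
  B <- matrix(0, length(x), k - 1)
  B[, 1] <- x
  for (j in seq_len(k - 2)) {
    B[, j + 1] <- (pos3(x - knots[j]) -
                     pos3(x - knots[k - 1]) * (knots[k] - knots[j]) /
                     (knots[k] - knots[k - 1]) +
                     pos3(x - knots[k]) * (knots[k - 1] - knots[j]) /
                     (knots[k] - knots[k - 1])) / norm
  }
  colnames(B) <- paste0("rcs", seq_len(k - 1))
  attr(B, "knots") <- knots
  B
}
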