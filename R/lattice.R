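#' The D3Q19 lattice model
#'
#' Nineteen discrete velocities (rest + 6 face + 12 edge directions), their
#' weights (1/3, 1/18, 1/36) and the lattice sound speed `cs^2 = 1/3`.
#' The ordering pairs each direction `i` with its opposite `opp[i]`, which
#' the bounce-back rule relies on.
#'
#' @return list with `e` (19 x 3 integer matrix), `w` (19 weights),
#'   `cs2` (= 1/3) and `opp` (1-based index of the reversed direction).
#' @export
d3q19 <- function() {
  e <- cbind(
    x = c(0, 1, -1, 0, 0, 0, 0, 1, -1, -1, 1, -1, 1, 1, -1, 0, 0, 0, 0),
    y = c(0, 0, 0, 1, -1, 0, 0, 0, 0, -1, 1, 0, 0, -1, 1, -1, 1, -1, 1),
    z = c(0, 0, 0, 0, 0, 1, -1, 1, -1, 0, 0, 1, -1, 0, 0, 1, -1, -1, 1)
  )
  w <- c(1 / 3, rep(1 / 18, 6), rep(1 / 36, 12))
  opp <- integer(19)
  for (i in 1:19) {
    opp[i] <- which(e[, 1] == -e[i, 1] & e[, 2] == -e[i, 2] & e[, 3] == -e[i, 3])
  }
  list(e = e, w = w, cs2 = 1 / 3, opp = opp)
}

#' Equilibrium populations
#'
#' Second-order Maxwell-Boltzmann expansion
#' `feq_i = rho w_i [1 + 3 e.u + 9/2 (e.u)^2 - 3/2 u^2]` (cs^2 = 1/3).
#' Vectorised over sites. This is the reference R implementation; the
#' compiled stepper evaluates the same expression in place.
#'
#' @param rho density, length-n vector.
#' @param u velocity, n x 3 matrix (or length-3 vector for a single site).
#' @param model lattice model from [d3q19()].
#' @return n x 19 matrix of equilibrium populations.
#' @export
equilibrium <- function(rho, u, model = d3q19()) {
  if (is.null(dim(u))) u <- matrix(u, ncol = 3)
  stopifnot(length(rho) == nrow(u))
  eu <- u %*% t(model$e)                      # n x 19
  usq <- rowSums(u^2)
  sweep(1 + 3 * eu + 4.5 * eu^2 - 1.5 * usq, 2, model$w, "*") * rho
}

#' Guo forcing source term
#'
#' Per-direction source
#' `S_i = (1 - 1/(2 tau)) w_i [3 (e_i - u) + 9 (e_i . u) e_i] . F`
#' entering the collision step alongside the half-force velocity shift.
#'
#' @param u velocity, n x 3 matrix (or length-3 vector).
#' @param F body force density, n x 3 matrix (or length-3 vector).
#' @param tau relaxation time.
#' @param model lattice model from [d3q19()].
#' @return n x 19 matrix of source terms.
#' @export
guo_force_term <- function(u, F, tau, model = d3q19()) {
  if (is.null(dim(u))) u <- matrix(u, ncol = 3)
  if (is.null(dim(F))) F <- matrix(F, ncol = 3)
  stopifnot(nrow(u) == nrow(F), tau > 0.5)
  eu <- u %*% t(model$e)                      # n x 19
  eF <- F %*% t(model$e)                      # n x 19
  uF <- rowSums(u * F)                        # n
  pref <- 1 - 1 / (2 * tau)
  sweep(3 * (eF - uF) + 9 * eu * eF, 2, pref * model$w, "*")
}
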