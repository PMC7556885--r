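# Physical constants in the backscattering-friendly unit system:
# energies in micro-eV, frequencies in THz, times in ps.
.PLANCK_UEV_PER_THZ <- 4.135668   # h, ueV per THz
.KB_UEV_PER_K <- 86.17333         # k_B, ueV per K

#' @keywords internal
.assert <- function(cond, msg, class = "hydrosub_error") {
  if (!isTRUE(cond)) {
    stop(structure(class = c(class, "error", "condition"),
                   list(message = msg, call = sys.call(-1))))
  }
  invisible(TRUE)
}

#' Evaluate an expression with a fixed RNG seed, restoring global RNG state
#' @keywords internal
.with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Log-spaced sequence
#'
#' @param from,to positive endpoints
#' @param length.out number of points
#' @return numeric vector, strictly increasing, log-uniformly spaced
#' @export
logspace <- function(from, to, length.out) {
  .assert(from > 0 && to > from, "logspace requires 0 < from < to")
  exp(seq(log(from), log(to), length.out = length.out))
}

# summary.lm warns on exact power-law input; that is a valid case here
.quiet_perfect_fit <- function(expr) {
  withCallingHandlers(expr, warning = function(w) {
    if (grepl("essentially perfect fit", conditionMessage(w)))
      invokeRestart("muffleWarning")
  })
}

# Midpoint-based widths of log(x) spacing, used as quadrature-style weights
# so a linearly spaced frequency grid is weighted uniformly in log-frequency.
.dlog_weights <- function(x) {
  lx <- log(x)
  n <- length(lx)
  if (n == 1L) return(1)
  mid <- (lx[-1] + lx[-n]) / 2
  w <- diff(c(lx[1], mid, lx[n]))
  w / mean(w)
}
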