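# Brute-force nested-bisection equilibrium solver, independent of the
# package's Newton path. Each mass balance T_X_calc is monotone increasing
# in its own free concentration (negative-r species enter T_H as
# -|r| beta .../[H]^|r|, still increasing in [H]), so nested bisection on
# log10 free concentrations is well-founded.

oracle_solve <- function(model, T_M, T_L, T_H, lo = -25, hi = 2, iter = 60) {
  sp <- model$species
  p <- sp$p; q <- sp$q; r <- sp$r; lb <- sp$log_beta

  conc_at <- function(xm, xl, xh) {
    10^(lb + p * conc_guard(xm) + q * conc_guard(xl) + r * conc_guard(xh))
  }
  tm_calc <- function(xm, xl, xh) 10^xm + sum(p * conc_at(xm, xl, xh))
  tl_calc <- function(xm, xl, xh) 10^xl + sum(q * conc_at(xm, xl, xh))
  th_calc <- function(xm, xl, xh) 10^xh + sum(r * conc_at(xm, xl, xh))

  bisect <- function(f, target) {
    a <- lo; b <- hi
    for (i in seq_len(iter)) {
      m <- (a + b) / 2
      if (f(m) > target) b <- m else a <- m
    }
    (a + b) / 2
  }
  solve_l <- function(xm, xh) {
    if (T_L == 0) return(-Inf)
    bisect(function(xl) tl_calc(xm, xl, xh), T_L)
  }
  solve_m <- function(xh) {
    if (T_M == 0) return(-Inf)
    bisect(function(xm) tm_calc(xm, solve_l(xm, xh), xh), T_M)
  }
  xh <- bisect(function(xh) {
    xm <- solve_m(xh)
    th_calc(xm, solve_l(xm, xh), xh)
  }, T_H)
  xm <- solve_m(xh)
  xl <- solve_l(xm, xh)
  free <- 10^c(xm, xl, xh)
  free[!is.finite(free)] <- 0
  free
}

# sanitise -Inf for species evaluation in the oracle
conc_guard <- function(x) ifelse(is.finite(x), x, -500)
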