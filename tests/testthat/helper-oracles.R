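# Independent oracles used to check the numerical simulator.

# Analytic solution of the first-order cascade for piecewise-constant
# promoter activity, via eigen-decomposition of the (triangular) rate matrix.
# segments: data.frame(t_start, f) with t_start[1] == 0.
analytic_cascade <- function(params, segments, times, x0 = c(0, 0, 0)) {
  km <- log(2) / params$mrna_halflife
  kmat <- log(2) / params$maturation_time
  kp <- log(2) / params$protein_halflife
  ktl <- params$translation_rate
  A <- matrix(c(-km, 0, 0,
                ktl, -(kmat + kp), 0,
                0, kmat, -kp), nrow = 3L, byrow = TRUE)
  ev <- eigen(A)
  V <- ev$vectors
  Vi <- solve(V)
  propagate <- function(x, dt) Re(V %*% (exp(ev$values * dt) * (Vi %*% x)))
  out <- matrix(NA_real_, nrow = length(times), ncol = 3L)
  bounds <- c(segments$t_start, Inf)
  x <- x0
  t_cur <- 0
  for (s in seq_len(nrow(segments))) {
    f <- segments$f[s]
    xss <- c(f / km, ktl * f / (km * (kmat + kp)),
             kmat * ktl * f / (km * (kmat + kp) * kp))
    t_next <- min(bounds[s + 1L], max(times))
    idx <- which(times >= bounds[s] - 1e-12 & times <= t_next + 1e-12)
    for (i in idx)
      out[i, ] <- xss + propagate(x - xss, times[i] - t_cur)
    x <- xss + drop(propagate(x - xss, t_next - t_cur))
    t_cur <- t_next
    if (t_cur >= max(times)) break
  }
  colnames(out) <- c("R", "NP", "MP")
  out
}

# Closed-form time for Michaelis-Menten decay from mp0 to mp0/2
# (integrate dX/dt = -Vmax X/(Km+X)).
mm_halving_time <- function(mp0, vmax, km) (mp0 / 2 + km * log(2)) / vmax

# First upward/downward crossing of a threshold, linear interpolation.
cross_time <- function(times, values, target, rising = TRUE) {
  hit <- if (rising) values >= target else values <= target
  if (hit[1L]) return(times[1L])
  i <- which(hit)[1L]
  if (is.na(i)) return(NA_real_)
  y0 <- values[i - 1L]; y1 <- values[i]
  times[i - 1L] + (target - y0) / (y1 - y0) * (times[i] - times[i - 1L])
}
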