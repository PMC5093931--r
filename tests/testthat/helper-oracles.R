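# Independent fine-step explicit-Euler integrator for the illness-death
# system, used as the brute-force oracle against the closed-form stepper.
euler_trajectory <- function(hz, init = c(1, 0), dt = 1e-4) {
  n <- nrow(hz)
  ages <- c(hz$age, max(hz$age) + 1L)
  S <- numeric(n + 1); C <- numeric(n + 1)
  Dd <- numeric(n + 1); Do <- numeric(n + 1)
  S[1] <- init[1]; C[1] <- init[2]
  s <- S[1]; c_ <- C[1]; dd <- 0; do_ <- 0
  for (k in seq_len(n)) {
    i <- hz$i[k]; r <- hz$r[k]; f <- hz$f[k]; m <- hz$m[k]
    nsteps <- round(1 / dt)
    for (step in seq_len(nsteps)) {
      ds <- (-(i + m) * s + r * c_) * dt
      dc <- (i * s - (r + f + m) * c_) * dt
      dd <- dd + f * c_ * dt
      do_ <- do_ + m * (s + c_) * dt
      s <- s + ds; c_ <- c_ + dc
    }
    S[k + 1] <- s; C[k + 1] <- c_; Dd[k + 1] <- dd; Do[k + 1] <- do_
  }
  data.frame(age = ages, S = S, C = C, p = C / (S + C),
             D_disease = Dd, D_other = Do)
}

# random valid hazard schedule for property-style tests
random_hazards <- function(ages = 0:60, scale = c(0.02, 0.05, 0.1, 0.03)) {
  n <- length(ages)
  hazard_schedule(ages,
                  i = runif(n, 0, scale[1]),
                  r = runif(n, 0, scale[2]),
                  f = runif(n, 0, scale[3]),
                  m = runif(n, 0, scale[4]))
}

# smooth zero-remission study inputs on 0:90 built from a logistic
# prevalence curve (analytic derivative available for inversion oracles)
smooth_inputs <- function(L = 0.15, k = 0.1, a0 = 60) {
  age <- 0:90
  p <- L / (1 + exp(-k * (age - a0)))
  dp <- k * p * (1 - p / L)           # analytic dp/da
  m <- 5e-5 * exp(0.088 * age)
  csmr <- 0.04 * p
  list(age = age, p = p, dp = dp, csmr = csmr,
       all_cause = csmr + m,
       # continuous-time inversion at zero remission
       i_oracle = dp / (1 - p) + csmr,
       # same oracle evaluated at interval midpoints a + 1/2
       i_oracle_mid = local({
         am <- age + 0.5
         pm <- L / (1 + exp(-k * (am - a0)))
         dpm <- k * pm * (1 - pm / L)
         dpm / (1 - pm) + 0.04 * pm
       }))
}
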