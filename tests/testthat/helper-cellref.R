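# Independent plain-R coding of the 2004 human ventricular cell model
# (epicardial variant), written directly from the published equations and
# used only as an oracle against the package kernel.  No augmentation.

cellref_init <- function() {
  list(V = -86.2, m = 0, h = 0.75, j = 0.75, xr1 = 0, xr2 = 1, xs = 0,
       r = 0, s = 1, d = 0, f = 1, fca = 1, g = 1,
       Cai = 2e-4, CaSR = 0.2, Nai = 11.6, Ki = 138.3)
}

cellref_step <- function(st, dt, Istim = 0) {
  RTF <- 8314.472 * 310 / 96485.3415
  F <- 96485.3415
  Ko <- 5.4; Nao <- 140; Cao <- 2
  V <- st$V
  ENa <- RTF * log(Nao / st$Nai)
  EK <- RTF * log(Ko / st$Ki)
  EKs <- RTF * log((Ko + 0.03 * Nao) / (st$Ki + 0.03 * st$Nai))
  ECa <- 0.5 * RTF * log(Cao / st$Cai)

  INa <- 14.838 * st$m^3 * st$h * st$j * (V - ENa)
  IbNa <- 0.00029 * (V - ENa)
  z <- 2 * V / RTF
  ICaL <- if (abs(z) < 1e-8) {
    1.75e-4 * st$d * st$f * st$fca * 2 * F * (st$Cai - 0.341 * Cao)
  } else {
    1.75e-4 * st$d * st$f * st$fca * 2 * F *
      (st$Cai * exp(z) - 0.341 * Cao) * z / (exp(z) - 1)
  }
  IbCa <- 0.000592 * (V - ECa)
  Ito <- 0.294 * st$r * st$s * (V - EK)
  IKr <- 0.096 * sqrt(Ko / 5.4) * st$xr1 * st$xr2 * (V - EK)
  IKs <- 0.245 * st$xs^2 * (V - EKs)
  aK1 <- 0.1 / (1 + exp(0.06 * (V - EK - 200)))
  bK1 <- (3 * exp(2e-4 * (V - EK + 100)) + exp(0.1 * (V - EK - 10))) /
         (1 + exp(-0.5 * (V - EK)))
  IK1 <- 5.405 * sqrt(Ko / 5.4) * aK1 / (aK1 + bK1) * (V - EK)
  INaCa <- 1000 * (exp(0.35 * V / RTF) * st$Nai^3 * Cao -
                   exp(-0.65 * V / RTF) * Nao^3 * st$Cai * 2.5) /
           ((87.5^3 + Nao^3) * (1.38 + Cao) *
            (1 + 0.1 * exp(-0.65 * V / RTF)))
  INaK <- 1.362 * Ko * st$Nai /
          ((Ko + 1) * (st$Nai + 40) *
           (1 + 0.1245 * exp(-0.1 * V / RTF) + 0.0353 * exp(-V / RTF)))
  IpCa <- 0.825 * st$Cai / (st$Cai + 5e-4)
  IpK <- 0.0146 * (V - EK) / (1 + exp((25 - V) / 5.98))

  Iion <- INa + IbNa + ICaL + IbCa + Ito + IKr + IKs + IK1 + INaCa + INaK +
          IpCa + IpK

  rl <- function(g0, ginf, tau) ginf + (g0 - ginf) * exp(-dt / tau)
  minf <- 1 / (1 + exp((-56.86 - V) / 9.03))^2
  taum <- (1 / (1 + exp((-60 - V) / 5))) *
          (0.1 / (1 + exp((V + 35) / 5)) + 0.1 / (1 + exp((V - 50) / 200)))
  hinf <- 1 / (1 + exp((V + 71.55) / 7.43))^2
  if (V >= -40) { ah <- 0; bh <- 0.77 / (0.13 * (1 + exp(-(V + 10.66) / 11.1))) }
  else { ah <- 0.057 * exp(-(V + 80) / 6.8)
         bh <- 2.7 * exp(0.079 * V) + 3.1e5 * exp(0.3485 * V) }
  if (V >= -40) { aj <- 0; bj <- 0.6 * exp(0.057 * V) / (1 + exp(-0.1 * (V + 32))) }
  else { aj <- (-2.5428e4 * exp(0.2444 * V) - 6.948e-6 * exp(-0.04391 * V)) *
               (V + 37.78) / (1 + exp(0.311 * (V + 79.23)))
         bj <- 0.02424 * exp(-0.01052 * V) / (1 + exp(-0.1378 * (V + 40.14))) }
  xr1inf <- 1 / (1 + exp((-26 - V) / 7))
  tauxr1 <- 450 / (1 + exp((-45 - V) / 10)) * 6 / (1 + exp((V + 30) / 11.5))
  xr2inf <- 1 / (1 + exp((V + 88) / 24))
  tauxr2 <- 3 / (1 + exp((-60 - V) / 20)) * 1.12 / (1 + exp((V - 60) / 20))
  xsinf <- 1 / (1 + exp((-5 - V) / 14))
  tauxs <- 1100 / sqrt(1 + exp((-10 - V) / 6)) / (1 + exp((V - 60) / 20))
  rinf <- 1 / (1 + exp((20 - V) / 6))
  taur <- 9.5 * exp(-(V + 40)^2 / 1800) + 0.8
  sinf <- 1 / (1 + exp((V + 20) / 5))
  taus <- 85 * exp(-(V + 45)^2 / 320) + 5 / (1 + exp((V - 20) / 5)) + 3
  dinf <- 1 / (1 + exp((-5 - V) / 7.5))
  taud <- (1.4 / (1 + exp((-35 - V) / 13)) + 0.25) *
          (1.4 / (1 + exp((V + 5) / 5))) + 1 / (1 + exp((50 - V) / 20))
  finf <- 1 / (1 + exp((V + 20) / 7))
  tauf <- 1125 * exp(-(V + 27)^2 / 240) + 80 + 165 / (1 + exp((25 - V) / 10))
  afca <- 1 / (1 + (st$Cai / 3.25e-4)^8)
  bfca <- 0.1 / (1 + exp((st$Cai - 5e-4) / 1e-4))
  cfca <- 0.2 / (1 + exp((st$Cai - 7.5e-4) / 8e-4))
  fcainf <- (afca + bfca + cfca + 0.23) / 1.46
  ginf <- if (st$Cai < 3.5e-4) 1 / (1 + (st$Cai / 3.5e-4)^6)
          else 1 / (1 + (st$Cai / 3.5e-4)^16)

  new <- st
  new$m <- rl(st$m, minf, taum)
  new$h <- rl(st$h, hinf, 1 / (ah + bh))
  new$j <- rl(st$j, jinf <- hinf, 1 / (aj + bj))
  new$xr1 <- rl(st$xr1, xr1inf, tauxr1)
  new$xr2 <- rl(st$xr2, xr2inf, tauxr2)
  new$xs <- rl(st$xs, xsinf, tauxs)
  new$r <- rl(st$r, rinf, taur)
  new$s <- rl(st$s, sinf, taus)
  new$d <- rl(st$d, dinf, taud)
  new$f <- rl(st$f, finf, tauf)
  new$fca <- if (fcainf > st$fca && V > -60) st$fca else rl(st$fca, fcainf, 2)
  new$g <- if (ginf > st$g && V > -60) st$g else rl(st$g, ginf, 2)

  Vc <- 0.016404; Vsr <- 0.001094; Cm <- 0.185
  Irel <- (0.016464 * st$CaSR^2 / (0.0625 + st$CaSR^2) + 0.008232) *
          st$d * st$g
  Ileak <- 8e-5 * (st$CaSR - st$Cai)
  Iup <- 4.25e-4 / (1 + (2.5e-4 / st$Cai)^2)
  bufc <- 1 / (1 + 0.15 * 0.001 / (st$Cai + 0.001)^2)
  bufsr <- 1 / (1 + 10 * 0.3 / (st$CaSR + 0.3)^2)
  new$Cai <- st$Cai + dt * bufc *
    (-(ICaL + IbCa + IpCa - 2 * INaCa) / (2 * Vc * F) * Cm +
     Ileak - Iup + Irel)
  new$CaSR <- st$CaSR + dt * bufsr * (Vc / Vsr) * (Iup - Ileak - Irel)
  new$Nai <- st$Nai + dt * (-(INa + IbNa + 3 * INaK + 3 * INaCa) /
                            (Vc * F) * Cm)
  new$Ki <- st$Ki + dt * (-(IK1 + Ito + IKr + IKs + IpK - 2 * INaK - Istim) /
                          (Vc * F) * Cm)
  new$V <- V + dt * (-(Iion - Istim))
  new
}

# paced reference trace (t, Vm) at sampling interval `record_dt`
cellref_trace <- function(t_end, dt = 0.02, stim_amp = 30, stim_dur = 2,
                          bcl = 500, n_beats = 2, record_dt = 1,
                          equilibrate = 1000) {
  st <- cellref_init()
  n_eq <- round(equilibrate / dt)
  for (i in seq_len(n_eq)) st <- cellref_step(st, dt)
  n <- round(t_end / dt)
  rec_every <- round(record_dt / dt)
  tt <- numeric(0); vv <- numeric(0)
  stims <- bcl * (seq_len(n_beats) - 1)
  for (i in 0:(n - 1)) {
    t <- i * dt
    if (i %% rec_every == 0) { tt <- c(tt, t); vv <- c(vv, st$V) }
    Is <- if (any(t >= stims - 1e-9 & t < stims + stim_dur - 1e-9)) stim_amp else 0
    st <- cellref_step(st, dt, Is)
  }
  list(t = tt, Vm = vv)
}
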