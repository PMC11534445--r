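# Independent single-expression transcription of the model equations,
# written directly from the printed forms and kept free of any package
# flux function. Used as the oracle for rhs()/flux_breakdown().
oracle_rhs <- function(state, p) {
  V <- max(state[["V"]], 0); D <- max(state[["D"]], 0)
  B <- max(state[["B"]], 0); S <- max(state[["S"]], 0)
  W <- max(state[["W"]], 0)

  s2 <- D^2 + B^2
  Dpred <- if (s2 > 0) p$r * (D + B) / (p$B_XX + D + B) * D^2 / s2 * W else 0
  Bpred <- if (s2 > 0) p$r * (D + B) / (p$B_XX + D + B) * B^2 / s2 * W else 0
  Dhunt <- if (D <= p$T_D) 0 else (1 - p$T_D / D) * p$H_D * (D - p$T_D)
  Bhunt <- if (B <= p$T_B) 0 else (1 - p$T_B / B) * p$H_B * (B - p$T_B)
  Ddeath <- exp(-p$q * W * (if (s2 > 0) D^2 / s2 else 0)) * p$M_D * D
  Bdeath <- exp(-p$q * W * (if (s2 > 0) B^2 / s2 else 0)) * p$M_B * B

  KD <- Ddeath + Dhunt * p$L_D + Dpred * p$v
  udd <- if (B > 0 && KD > 0) {
    p$u * (KD / (p$A_XB * B)) / (p$B_u + KD / (p$A_XB * B))
  } else 0
  Add <- p$A_XB * (p$C_VB * (1 - p$u_a) + p$C_DB * p$u_a) /
    (p$C_VB * (1 - udd) + p$C_DB * udd)
  Atd <- Add * (V * (1 - udd) + KD * udd) /
    (p$B_XX + V * (1 - udd) + KD * udd)
  KB <- Bdeath + Bhunt * p$L_B + Bpred * p$v
  KDa <- max(KD - Atd * udd * B, 0)
  AddS <- p$A_XS * (V + KDa + KB) / (p$B_XX + V + KDa + KB)

  VconsD <- D * p$A_VD * V / (p$B_XX + V)
  VconsB <- B * Atd * (1 - udd)
  VconsS <- if (V + KDa + KB > 0) S * AddS * V / (KDa + KB + V) else 0

  SgrD <- min(AddS * S, KDa) * p$C_XS
  SgrB <- min(AddS * S, KB) * p$C_XS

  c(
    V = p$R0 * V * (1 - V / p$k0) - VconsD - VconsB - VconsS,
    D = VconsD * p$C_VD - Dpred - Dhunt - Ddeath,
    B = VconsB * p$C_VB + Atd * udd * B * p$C_DB - Bpred - Bhunt - Bdeath,
    S = VconsS * p$C_VS + SgrD + SgrB - p$M_S * S,
    W = Dpred * p$C_XW * (1 - p$v) + Bpred * p$C_XW * (1 - p$v) -
      p$M_W * W
  )
}

# deterministic batch of random valid states spanning typical magnitudes
random_states <- function(n, seed = 42) {
  set.seed(seed)
  m <- cbind(
    V = runif(n, 0, 12),
    D = runif(n, 0, 3),
    B = runif(n, 0, 3),
    S = runif(n, 0, 2),
    W = runif(n, 0, 0.5)
  )
  # sprinkle structural zeros so the guarded limits get exercised
  zero_idx <- seq_len(n) %% 7 == 0
  m[seq_len(n) %% 5 == 0, "W"] <- 0
  m[zero_idx, "B"] <- 0
  m[seq_len(n) %% 11 == 0, c("D", "B")] <- 0
  m
}
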