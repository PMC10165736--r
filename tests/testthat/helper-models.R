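# Analytic fixture models built in code: constant moment arms and linear
# musculotendon length tables, so every mechanical quantity has a closed
# form. Optimal fiber length is reached at phi_opt for every muscle.

simple_elbow_model <- function(F0M_flex = 500, F0M_ext = 400,
                               n_flexors = 1, l0M = 0.1, lST = 0.2,
                               J_flex = 0.03, J_ext = -0.025,
                               alpha0 = 0, phi_opt = 50,
                               F = 0.01, R = 0.005, r_rest = 15) {
  phi <- seq(0, 150, by = 5)
  rad <- pi / 180
  lin_geom <- function(J) {
    # constant moment arm J implies lMT(phi) = lMT(phi_opt) - J*(phi-phi_opt)
    h <- l0M * sin(alpha0)
    proj_opt <- sqrt(l0M^2 - h^2)
    list(phi_deg = phi,
         lMT_m = lST + proj_opt - J * (phi - phi_opt) * rad,
         moment_arm_m = rep(J, length(phi)))
  }
  F0M_flex <- rep_len(F0M_flex, n_flexors)
  names_flex <- if (n_flexors == 1) "flexor1" else paste0("flexor", seq_len(n_flexors))
  rows <- list(); geom <- list()
  for (i in seq_len(n_flexors)) {
    rows[[i]] <- muscle_table(names_flex[i], "flexor", F0M_flex[i], l0M, lST,
                              alpha0, F = F, R = R, r_rest = r_rest)
    geom[[names_flex[i]]] <- lin_geom(J_flex)
  }
  rows[[n_flexors + 1]] <- muscle_table("extensor1", "extensor", F0M_ext, l0M,
                                        lST, alpha0, F = F, R = R,
                                        r_rest = r_rest)
  geom[["extensor1"]] <- lin_geom(J_ext)
  muscles <- do.call(rbind, rows)
  rownames(muscles) <- NULL
  msk_model(muscles, geom, variant = "7M")
}

# brute-force grid search oracle for the 2-muscle load-sharing QP
grid_search_qp <- function(J, Q, lb, ub, w = c(1, 1), step = 1) {
  g1 <- seq(lb[1], ub[1], by = step)
  F2 <- (Q - J[1] * g1) / J[2]
  ok <- F2 >= lb[2] - 1e-9 & F2 <= ub[2] + 1e-9
  obj <- (w[1] * g1)^2 + (w[2] * F2)^2
  obj[!ok] <- Inf
  i <- which.min(obj)
  c(g1[i], F2[i])
}
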