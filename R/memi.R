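# Two-node MEMI heat balance and the PET index.
#
# Steady-state balance over three nodes (core, skin, clothing) per unit
# DuBois area, with Gagge-type vasomotor and sudomotor control:
#
#   core:     m - q_respiration - q_core_to_skin                    = 0
#   skin:     q_core_to_skin - E_skin - q_bare - q_skin_to_clothing = 0
#   clothing: q_skin_to_clothing - q_clothing_to_environment        = 0
#
# The body surface splits into a bare fraction (1 - facl), exchanging
# convection/radiation at skin temperature, and a clothed fraction where heat
# conducts through the clothing resistance before leaving at the clothing
# temperature over the enlarged outer area f_cl. Skin blood flow couples the
# core and skin nodes; regulatory sweating is driven by the mean body
# temperature, capped, and bounded by the evaporative maximum (Lewis
# relation), with a 6% diffusion-wetness floor.
#
# PET is the reference-environment air temperature (T_mrt = T_a,
# v = 0.1 m/s, VP = 12 hPa, same person) at which the body with the *actual*
# core/skin state and skin wetness is again in balance — found by bisection.

SIGMA <- 5.67e-8
C_AIR <- 1010      # J/(kg K)
L_VAP <- 2.42e6    # J/kg
EM_SKIN <- 0.99
EM_CLOTH <- 0.95
F_EFF <- 0.725     # effective radiation area factor, standing/sitting mix
LEWIS_HPA <- 1.65  # K/hPa
P_REF <- 1013.25   # hPa

memi_body <- function(person) {
  w <- person$weight; ht <- person$height
  a_du <- 0.203 * w^0.425 * ht^0.725
  basal <- if (person$sex == "male") {
    3.45 * w^0.75 * (1 + 0.004 * (30 - person$age) +
                       0.010 * (ht * 100 / w^(1 / 3) - 43.4))
  } else {
    3.19 * w^0.75 * (1 + 0.004 * (30 - person$age) +
                       0.018 * (ht * 100 / w^(1 / 3) - 42.1))
  }
  m_total <- person$work + basal       # W
  icl <- person$clo
  facl <- min(1, max(0, (-2.36 + 173.51 * icl - 100.76 * icl^2 +
                           19.28 * icl^3) / 100))
  list(
    a_du = a_du,
    m = m_total / a_du,                # W/m2
    m_total = m_total,
    rtv = 1.44e-6 * m_total,           # respiratory air flow, kg/s
    facl = facl,
    f_cl = 1 + 0.31 * icl,             # clothing area factor
    r_cl = 0.155 * icl                 # clothing resistance, m2 K / W
  )
}

memi_hc <- function(v, p) {
  (2.67 + 6.5 * max(v, 0.1)^0.67) * (p / P_REF)^0.55
}

# respiratory heat loss, W/m2 (positive = loss)
memi_respiration <- function(t_a, vpa, p, body) {
  t_ex <- 0.47 * t_a + 21
  c_res <- C_AIR * (t_ex - t_a) * body$rtv / body$a_du
  e_res <- 0.623 * L_VAP / p *
    (saturation_vapor_pressure(t_ex) - vpa) * body$rtv / body$a_du
  c_res + e_res
}

# skin blood flow (L m-2 h-1) from thermoregulatory signals
memi_blood_flow <- function(t_cr, t_sk) {
  dilat <- max(0, t_cr - 36.6)
  constr <- max(0, 34 - t_sk)
  min(90, max(0.5, (6.3 + 75 * dilat) / (1 + 0.5 * constr)))
}

# heat flux densities at a given node state; t_cl solved internally from
# the clothing balance. All fluxes in W/m2 of DuBois area.
memi_fluxes <- function(t_cr, t_sk, t_a, t_mrt, vpa, hc, body,
                        e_sweat = NULL) {
  rad <- function(t_s, em) {
    em * SIGMA * F_EFF * ((t_s + 273.15)^4 - (t_mrt + 273.15)^4)
  }
  q_bare <- (1 - body$facl) * (hc * (t_sk - t_a) + rad(t_sk, EM_SKIN))
  # clothing temperature from its own balance (monotone in t_cl)
  cl_resid <- function(t_cl) {
    body$facl * (t_sk - t_cl) / body$r_cl -
      body$facl * body$f_cl * (hc * (t_cl - t_a) + rad(t_cl, EM_CLOTH))
  }
  lo <- min(t_sk, t_a, t_mrt) - 5
  hi <- max(t_sk, t_a, t_mrt) + 5
  t_cl <- stats::uniroot(cl_resid, c(lo, hi), tol = 1e-6)$root
  q_cond <- body$facl * (t_sk - t_cl) / body$r_cl

  m_bl <- memi_blood_flow(t_cr, t_sk)
  alpha <- 0.0417737 + 0.7451833 / (m_bl + 0.585417)
  e_max <- LEWIS_HPA * hc * (saturation_vapor_pressure(t_sk) - vpa)
  e_diff <- max(0, 0.06 * e_max)   # passive diffusion (6% wetness floor)
  if (is.null(e_sweat)) {
    t_body <- alpha * t_sk + (1 - alpha) * t_cr
    m_rsw <- min(500, 304.94 * max(0, t_body - 36.6))   # g m-2 h-1
    e_req <- m_rsw * 1e-3 * L_VAP / 3600
    e_sweat <- max(0, min(e_req, e_max - e_diff))
  } else {
    # reference search: regulatory sweat heat flux held at its
    # actual-environment value, bounded by the reference evaporative max
    e_sweat <- min(e_sweat, max(0, e_max - e_diff))
  }
  list(q_bare = q_bare, q_cond = q_cond, t_cl = t_cl,
       q_cr_sk = (5.28 + 1.163 * m_bl) * (t_cr - t_sk),
       e_sk = e_diff + e_sweat, e_sweat = e_sweat)
}

# solve the actual-environment node state by nested bisection:
# inner — core temperature from the core balance (q_core_to_skin is fixed
# at m - q_respiration and strictly increasing in t_cr);
# outer — skin temperature from the skin balance (losses increase in t_sk).
memi_solve <- function(t_a, t_mrt, vpa, v, p, person) {
  body <- memi_body(person)
  hc <- memi_hc(v, p)
  q_target <- body$m - memi_respiration(t_a, vpa, p, body)
  if (q_target <= 0) {
    stop("MEMI: respiratory loss exceeds metabolic heat; ",
         sprintf("inputs t_a=%.1f vpa=%.1f", t_a, vpa))
  }
  t_cr_of <- function(t_sk) {
    f <- function(t_cr) {
      (5.28 + 1.163 * memi_blood_flow(t_cr, t_sk)) * (t_cr - t_sk) - q_target
    }
    stats::uniroot(f, c(t_sk + 1e-9, t_sk + 30), tol = 1e-7)$root
  }
  skin_resid <- function(t_sk) {
    t_cr <- t_cr_of(t_sk)
    fl <- memi_fluxes(t_cr, t_sk, t_a, t_mrt, vpa, hc, body)
    q_target - fl$e_sk - fl$q_bare - fl$q_cond
  }
  lo <- 0; hi <- 43
  r_lo <- skin_resid(lo); r_hi <- skin_resid(hi)
  if (sign(r_lo) == sign(r_hi)) {
    stop(sprintf(paste0("MEMI: no skin-balance root in [%g, %g] degC ",
                        "(residuals %.2f / %.2f W/m2) for t_a=%.1f ",
                        "t_mrt=%.1f vpa=%.1f v=%.2f"),
                 lo, hi, r_lo, r_hi, t_a, t_mrt, vpa, v))
  }
  t_sk <- stats::uniroot(skin_resid, c(lo, hi), tol = 1e-5)$root
  t_cr <- t_cr_of(t_sk)
  fl <- memi_fluxes(t_cr, t_sk, t_a, t_mrt, vpa, hc, body)
  list(t_cr = t_cr, t_sk = t_sk, t_cl = fl$t_cl, e_sweat = fl$e_sweat,
       body = body, q_target = q_target)
}

#' Physiologically equivalent temperature (PET)
#'
#' Solves the two-node MEMI heat balance for the core, skin and clothing
#' temperatures in the actual environment, then searches the standard
#' reference environment (`T_mrt = T_a`, `v = 0.1` m/s, `VP = 12` hPa, same
#' person) by bisection over \[-50, 80\] degC for the air temperature at
#' which the body with that same core/skin state and skin wetness is again
#' in balance. By construction `pet(T, T, 12, 0.1)` returns `T`.
#'
#' Air speed is floored at 0.1 m/s (standard PET convention). The bisection
#' converges to 0.01 K within at most 100 iterations; non-convergence or a
#' reference balance without a sign change raises an error with the
#' offending inputs (never a silent `NA`).
#'
#' @param T_a air temperature (degC).
#' @param T_mrt mean radiant temperature (degC).
#' @param VP vapour pressure (hPa), >= 0.
#' @param v air speed (m/s), >= 0.
#' @param person a [person_parameters()].
#' @param p atmospheric pressure (hPa).
#' @return PET (degC); vectorised over the meteorological inputs.
#' @export
pet <- function(T_a, T_mrt, VP, v, person = person_parameters(),
                p = P_REF) {
  n <- max(length(T_a), length(T_mrt), length(VP), length(v), length(p))
  args <- data.frame(T_a = rep_len(T_a, n), T_mrt = rep_len(T_mrt, n),
                     VP = rep_len(VP, n), v = rep_len(v, n),
                     p = rep_len(p, n))
  if (any(args$VP < 0)) stop("VP must be >= 0")
  vapply(seq_len(n), function(i) {
    pet_one(args$T_a[i], args$T_mrt[i], args$VP[i], args$v[i], args$p[i],
            person)
  }, numeric(1))
}

pet_one <- function(t_a, t_mrt, vpa, v, p, person) {
  st <- memi_solve(t_a, t_mrt, vpa, v, p, person)
  body <- st$body
  hc_ref <- memi_hc(0.1, p)
  resid <- function(t_x) {
    q_avail <- body$m - memi_respiration(t_x, 12, p, body)
    fl <- memi_fluxes(st$t_cr, st$t_sk, t_x, t_x, 12, hc_ref, body,
                      e_sweat = st$e_sweat)
    q_avail - fl$e_sk - fl$q_bare - fl$q_cond
  }
  lo <- -50; hi <- 80
  f_lo <- resid(lo); f_hi <- resid(hi)
  if (sign(f_lo) == sign(f_hi)) {
    stop(sprintf(paste0("PET: no reference-balance root in [%g, %g] degC ",
                        "(residuals %.2f / %.2f W/m2) for t_a=%.1f ",
                        "t_mrt=%.1f vpa=%.1f v=%.2f"),
                 lo, hi, f_lo, f_hi, t_a, t_mrt, vpa, v))
  }
  it <- 0
  while (hi - lo > 0.005 && it < 100) {
    mid <- (lo + hi) / 2
    f_mid <- resid(mid)
    if (sign(f_mid) == sign(f_lo)) {
      lo <- mid; f_lo <- f_mid
    } else {
      hi <- mid
    }
    it <- it + 1
  }
  if (hi - lo > 0.01) {
    stop(sprintf("PET: bisection did not converge (width %.3f K) for t_a=%.1f",
                 hi - lo, t_a))
  }
  (lo + hi) / 2
}
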