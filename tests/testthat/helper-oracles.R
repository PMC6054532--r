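# Independent oracles used across tests. These deliberately avoid the
# package's own code paths for the quantity they check.

# printed rate constants used repeatedly in tests
gleevec_10C_k <- rate_constants(k1 = 0.014, k_m1 = 0.011, k2 = 1.1,
                                k_m2 = 31)
danusertib_k <- rate_constants(k1 = 0.09, k_m1 = 0.06, k2 = 0.4,
                               k_m2 = 6.8, k3 = 16, k_m3 = 7.1e-4)

# mant-ATP: induced-fit pair solved from the printed plateau (21/s) and
# observed off-rate (17.2/s) via the quadratic 17.2^2 - 17.2*(50+21) +
# 50*k_m3 = 0, written out here independently of the package
mant_chain <- local({
  km3 <- (17.2 * (50 + 21) - 17.2^2) / 50
  c(k3 = 21 - km3, k_m3 = km3)
})
mant_atp_k <- rate_constants(k2 = 0.8, k_m2 = 50,
                             k3 = unname(mant_chain["k3"]),
                             k_m3 = unname(mant_chain["k_m3"]))

# slow/fast decay rates of the two-state dissociation subsystem
# (encounter complex <-> tightened complex, escape irreversible) from the
# characteristic polynomial  l^2 - (km2+k3+km3) l + km2*km3 = 0
oracle_dissociation_rates <- function(km2, k3, km3) {
  r <- Re(polyroot(c(km2 * km3, -(km2 + k3 + km3), 1)))
  sort(r)
}

# physical root of the tight-binding quadratic
# x^2 - (I + Et + KD) x + Et I = 0
oracle_bound <- function(I, Et, KD) {
  r <- Re(polyroot(c(Et * I, -(I + Et + KD), 1)))
  min(r)
}

# equilibrium of the three-step chain E_in <-> E_out (+I) <-> EI <-> E*I,
# written out independently: free-ligand root of ligand conservation with
# species expressed through the step constants
oracle_equilibrium_3step <- function(k, Et, Lt) {
  K1 <- k[["k_m1"]] / k[["k1"]]
  K2 <- k[["k_m2"]] / k[["k2"]]
  K3 <- k[["k_m3"]] / k[["k3"]]
  conc <- function(L) {
    # relative to E_out = 1: E_in = K1, EI = L/K2, E*I = L/(K2 K3)
    w <- c(E_in = K1, E_out = 1, EI = L / K2, EsI = L / (K2 * K3))
    ref <- Et / sum(w)
    w * ref
  }
  g <- function(L) {
    cc <- conc(L)
    L + cc[["EI"]] + cc[["EsI"]] - Lt
  }
  L <- uniroot(g, c(0, Lt), tol = 1e-15)$root
  c(conc(L), I = L)
}

# weighted scatter of a vector (for z-score style checks)
zscore <- function(est, truth, se) (est - truth) / se
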