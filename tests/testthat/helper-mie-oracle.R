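# Independent homogeneous-sphere Mie oracle.
#
# Deliberately uses a different algorithm from the package's coated-sphere
# series: the classic logarithmic-derivative formulation (downward recurrence
# for D_n, upward for the Riccati-Bessel functions of the real argument), so
# agreement between the two is a genuine cross-check, not a tautology.
oracle_mie_csca <- function(diameter, wavelength, m_particle, n_medium) {
  x <- pi * diameter * n_medium / wavelength
  m <- m_particle / n_medium
  nmax <- ceiling(x + 4 * x^(1 / 3) + 2)
  mx <- m * x
  nd <- ceiling(max(nmax, Mod(mx))) + 16L
  D <- rep(0 + 0i, nd)  # D[k] = psi_k'(mx)/psi_k(mx)
  for (k in nd:2) {
    D[k - 1L] <- k / mx - 1 / (D[k] + k / mx)
  }
  psi_m1 <- cos(x); psi0 <- sin(x)
  chi_m1 <- -sin(x); chi0 <- cos(x)
  qsum <- 0
  psi_prev <- psi_m1; psi <- psi0
  chi_prev <- chi_m1; chi <- chi0
  for (n in 1:nmax) {
    psi_n <- (2 * n - 1) / x * psi - psi_prev
    chi_n <- (2 * n - 1) / x * chi - chi_prev
    xi_n <- complex(real = psi_n, imaginary = -chi_n)
    xi_nm1 <- complex(real = psi, imaginary = -chi)
    dn <- D[n]
    an <- ((dn / m + n / x) * psi_n - psi) /
      ((dn / m + n / x) * xi_n - xi_nm1)
    bn <- ((dn * m + n / x) * psi_n - psi) /
      ((dn * m + n / x) * xi_n - xi_nm1)
    qsum <- qsum + (2 * n + 1) * (Mod(an)^2 + Mod(bn)^2)
    psi_prev <- psi; psi <- psi_n
    chi_prev <- chi; chi <- chi_n
  }
  qsca <- (2 / x^2) * qsum
  qsca * pi * (diameter / 2)^2
}
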