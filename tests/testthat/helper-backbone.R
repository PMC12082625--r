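# Ideal polypeptide backbone builder (NeRF internal-to-Cartesian),
# used to construct dihedral test inputs with known phi/psi.
place_atom <- function(A, B, C, bond, angle_deg, torsion_deg) {
  ang <- angle_deg * pi / 180
  tor <- torsion_deg * pi / 180
  bc <- C - B; bc <- bc / sqrt(sum(bc^2))
  n <- redoxmap:::pracma_cross(B - A, bc)
  n <- n / sqrt(sum(n^2))
  m <- redoxmap:::pracma_cross(n, bc)
  d <- c(-bond * cos(ang), bond * sin(ang) * cos(tor),
         bond * sin(ang) * sin(tor))
  C + d[1] * bc + d[2] * m + d[3] * n
}

build_backbone <- function(phi, psi, omega = rep(180, length(phi)),
                           cell_edge = 60) {
  nres <- length(phi)
  stopifnot(length(psi) == nres)
  # ideal geometry (lengths A, angles deg)
  bN_CA <- 1.458; bCA_C <- 1.525; bC_N <- 1.329
  aN_CA_C <- 111.2; aCA_C_N <- 116.2; aC_N_CA <- 121.7
  N <- matrix(NA_real_, nres, 3); CA <- N; C <- N
  N[1, ] <- c(10, 10, 10)
  CA[1, ] <- N[1, ] + c(bN_CA, 0, 0)
  ang <- aN_CA_C * pi / 180
  C[1, ] <- CA[1, ] + bCA_C * c(-cos(ang), sin(ang), 0)
  for (i in seq_len(nres - 1)) {
    N[i + 1, ] <- place_atom(N[i, ], CA[i, ], C[i, ], bC_N, aCA_C_N, psi[i])
    CA[i + 1, ] <- place_atom(CA[i, ], C[i, ], N[i + 1, ], bN_CA, aC_N_CA,
                              omega[i])
    C[i + 1, ] <- place_atom(C[i, ], N[i + 1, ], CA[i + 1, ], bCA_C, aN_CA_C,
                             phi[i + 1])
  }
  ord <- as.vector(t(matrix(seq_len(3 * nres), nres, 3)))
  xyz <- rbind(N, CA, C)[ord, ]  # interleave per residue: N, CA, C
  atoms <- tibble::tibble(
    name = rep(c("N", "CA", "C"), nres),
    element = rep(c("N", "C", "C"), nres),
    resname = "ALA",
    resid = rep(seq_len(nres), each = 3),
    chain = "A",
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    occ = 1, b_iso = 20)
  crystal_model(unit_cell(cell_edge, cell_edge, cell_edge), atoms)
}
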