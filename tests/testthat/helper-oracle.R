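# Independent numeric oracles and small fixture builders used across tests.

# Brute-force rigid-superposition RMSD: numeric minimization over ZYZ Euler
# angles (centroids aligned analytically), multi-start Nelder-Mead. Kept
# deliberately independent of kabschFit.
bruteForceRMSD <- function(a, b) {
  A <- sweep(a, 2, colMeans(a))
  B <- sweep(b, 2, colMeans(b))
  obj <- function(ang) {
    R <- FdxBarrel:::rotationFromEuler(ang[1], ang[2], ang[3])
    sqrt(mean(rowSums((A %*% t(R) - B)^2)))
  }
  starts <- as.matrix(expand.grid(a1 = c(0, pi), a2 = c(0.5, 2.5),
                                  a3 = c(0, pi)))
  best <- Inf
  for (s in seq_len(nrow(starts))) {
    fit <- stats::optim(starts[s, ], obj, method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-14))
    if (fit$value < best) best <- fit$value
  }
  best
}

randomRotation <- function(seed) {
  set.seed(seed)
  FdxBarrel:::rotationFromEuler(runif(1, 0, 2 * pi), runif(1, 0, pi),
                                runif(1, 0, 2 * pi))
}

# Apply a rigid transform to every atom of a StructureModel.
transformModel <- function(model, R, t = c(0, 0, 0)) {
  a <- model@atoms
  xyz <- FdxBarrel:::applyRigid(as.matrix(a[, c("x", "y", "z")]), R, t)
  a$x <- xyz[, 1]; a$y <- xyz[, 2]; a$z <- xyz[, 3]
  FdxBarrel:::buildStructureModel(a, id = model@id)
}

# Random-walk coil backbone: per-residue random dihedrals, no repeated
# hydrogen-bonding pattern.
randomCoil <- function(n, seed) {
  set.seed(seed)
  ns <- asNamespace("FdxBarrel")
  N <- CA <- C <- O <- matrix(NA_real_, n, 3)
  N[1, ] <- c(0, 0, 0); CA[1, ] <- c(1.458, 0, 0)
  ang <- (180 - 111.2) * pi / 180
  C[1, ] <- CA[1, ] + 1.525 * c(cos(ang), sin(ang), 0)
  for (i in 2:n) {
    psi <- runif(1, -180, 180); phi <- runif(1, -180, 180)
    N[i, ] <- ns$placeAtom(N[i - 1, ], CA[i - 1, ], C[i - 1, ], 1.329, 116.2, psi)
    CA[i, ] <- ns$placeAtom(CA[i - 1, ], C[i - 1, ], N[i, ], 1.458, 121.7, 180)
    C[i, ] <- ns$placeAtom(C[i - 1, ], N[i, ], CA[i, ], 1.525, 111.2, phi)
  }
  for (i in seq_len(n)) {
    nNext <- if (i < n) N[i + 1, ] else C[i, ] + c(1, 0.5, 0)
    O[i, ] <- C[i, ] - 1.231 * ns$unitv(ns$unitv(nNext - C[i, ]) +
                                        ns$unitv(CA[i, ] - C[i, ]))
  }
  ns$buildStructureModel(
    ns$.backboneAtoms(list(N = N, CA = CA, C = C, O = O), "A"),
    id = "COIL")
}

classifySynthetic <- function(packing, seed, sigma,
                              arrangement = "homodimer") {
  b <- makeBarrel(packing = packing, arrangement = arrangement,
                  noiseSigma = sigma, seed = seed)
  runClassify(model = b$model, annotation = b$truth$annotation)
}
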