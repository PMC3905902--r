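# Shared helpers: random rigid transforms and an independent brute-force
# superposition oracle (direct minimization of RMSD over the rotation
# group, never touching the package's Kabsch path).

rotvec_to_mat <- function(w) {
  th <- sqrt(sum(w^2))
  if (th < 1e-12) return(diag(3))
  u <- w / th
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

random_rotation <- function() {
  rotvec_to_mat(stats::rnorm(3) * pi / 2)
}

apply_rigid <- function(X, R, t) sweep(X %*% t(R), 2, -t)

# minimum RMSD over proper rotations by multi-start Nelder-Mead on the
# axis-angle parameterization (centering handled analytically)
brute_force_rmsd <- function(X, Y, n_starts = 40) {
  Xc <- scale(X, scale = FALSE); Yc <- scale(Y, scale = FALSE)
  f <- function(w) {
    R <- rotvec_to_mat(w)
    sqrt(mean(rowSums((Xc %*% t(R) - Yc)^2)))
  }
  best <- Inf
  for (i in seq_len(n_starts)) {
    o <- stats::optim(stats::rnorm(3) * pi / 2, f, method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-15))
    best <- min(best, o$value)
  }
  best
}

# apply a common rigid transform to every model of a structure
transform_structure <- function(s, R, t) {
  for (k in seq_along(s$models)) {
    co <- apply_rigid(as.matrix(s$models[[k]][, c("x", "y", "z")]), R, t)
    s$models[[k]]$x <- co[, 1]
    s$models[[k]]$y <- co[, 2]
    s$models[[k]]$z <- co[, 3]
  }
  s
}

# independent oracle: exhaustive search over all 10 candidate axial pairs
# with the documented tie rules, reimplemented from scratch
oracle_axial_pair <- function(p, ligands, labels) {
  best <- NULL
  for (i in 1:4) for (j in (i + 1):5) {
    ang <- angle_xyz(ligands[i, ], p, ligands[j, ])
    md <- mean(c(dist_xyz(p, ligands[i, ]), dist_xyz(p, ligands[j, ])))
    lab <- paste(sort(labels[c(i, j)]), collapse = "|")
    cand <- list(pair = c(i, j), ang = ang, md = md, lab = lab)
    if (is.null(best) || cand$ang > best$ang + 1e-12 ||
        (abs(cand$ang - best$ang) <= 1e-12 &&
         (cand$md > best$md + 1e-12 ||
          (abs(cand$md - best$md) <= 1e-12 && cand$lab < best$lab))))
      best <- cand
  }
  best$pair
}

ligand_mapping_es_to_pip <- c(
  "B/201/O5'" = "B/201/O5'", "B/201/O1A" = "B/201/O1A",
  "B/201/O2A" = "B/201/O2A", "B/201/N3A" = "B/201/OW")
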