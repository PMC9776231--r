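# Shared fixtures and independent oracles used across the test files.

# random proper rigid transform (rotation from QR with det +1, translation)
random_rigid <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  list(R = q, t = rnorm(3, sd = 10))
}

apply_rigid <- function(xyz, rt) {
  sweep(xyz %*% rt$R, 2, rt$t, `+`)
}

transform_frame <- function(frame, rt) {
  md_frame(frame$atoms, apply_rigid(frame$xyz, rt), time = frame$time)
}

transform_trajectory <- function(traj, rt) {
  frames <- lapply(seq_len(n_frames(traj)), function(k)
    transform_frame(get_frame(traj, k), rt))
  as_trajectory(frames, frame_interval = traj$frame_interval)
}

# independent superposition oracle: minimise RMSD over Euler angles with
# generic numerical optimisation after centroid alignment (no SVD)
oracle_min_rmsd <- function(mobile, reference) {
  A <- sweep(mobile, 2, colMeans(mobile))
  B <- sweep(reference, 2, colMeans(reference))
  rot <- function(ang) {
    ca <- cos(ang[1]); sa <- sin(ang[1])
    cb <- cos(ang[2]); sb <- sin(ang[2])
    cc <- cos(ang[3]); sc <- sin(ang[3])
    Rz1 <- matrix(c(ca, -sa, 0, sa, ca, 0, 0, 0, 1), 3, 3, byrow = TRUE)
    Ry <- matrix(c(cb, 0, sb, 0, 1, 0, -sb, 0, cb), 3, 3, byrow = TRUE)
    Rz2 <- matrix(c(cc, -sc, 0, sc, cc, 0, 0, 0, 1), 3, 3, byrow = TRUE)
    Rz1 %*% Ry %*% Rz2
  }
  obj <- function(ang) sqrt(mean(rowSums((A %*% rot(ang) - B)^2)))
  starts <- as.matrix(expand.grid(a = c(0, pi), b = c(0.5, 2.5),
                                  c = c(0, pi)))
  best <- Inf
  for (s in seq_len(nrow(starts))) {
    fit <- optim(starts[s, ], obj, method = "Nelder-Mead",
                 control = list(maxit = 2000, reltol = 1e-14))
    best <- min(best, fit$value)
  }
  best
}

# independent enumeration of the four-rule contact rubric on a plain table
# of residue pairs (occurrence %, facing fraction, region ids)
oracle_rubric <- function(pairs, threshold = 85, min_n = 2) {
  keys <- unique(pairs[, c("ra", "rb")])
  out <- character(nrow(keys))
  for (r in seq_len(nrow(keys))) {
    level <- "none"
    n_facing_contact <- 0L
    n_strong <- 0L
    for (i in seq_len(nrow(pairs))) {
      if (pairs$ra[i] != keys$ra[r] || pairs$rb[i] != keys$rb[r]) next
      faces <- pairs$facing[i] >= 0.5            # rule 1
      touched <- pairs$occ[i] > 0                # rule 2 (cutoff already in occ)
      if (faces && touched) {
        n_facing_contact <- n_facing_contact + 1L
        if (pairs$occ[i] >= threshold) n_strong <- n_strong + 1L
      }
    }
    if (n_strong >= min_n) level <- "strong"     # rules 3 + 4
    else if (n_facing_contact > 0L) level <- "weak"
    out[r] <- level
  }
  data.frame(keys, level = out, stringsAsFactors = FALSE)
}

# wrap a plain pair table as an occurrence_map for classify_region_contacts
as_occurrence_map <- function(df, n_frames = 100) {
  out <- data.frame(chain_a = "A", resid_a = df$resid_a, resname_a = "LEU",
                    chain_b = "B", resid_b = df$resid_b, resname_b = "LEU",
                    n_contact_frames = round(df$occ * n_frames / 100),
                    occurrence_pct = df$occ)
  attr(out, "n_frames") <- n_frames
  attr(out, "criterion") <- "hydrophobic"
  class(out) <- c("occurrence_map", "data.frame")
  out
}

# two-residue antiphase oscillator: residues at +/- a on x move radially by
# +/- d in alternate frames, so the optimal superposition stays the identity
# and the oscillating residues have RMSF exactly d
make_oscillator_trajectory <- function(n_res = 10, d = 0.5, n_frames = 8) {
  stopifnot(n_res >= 6, n_frames %% 2 == 0)
  base <- cbind(seq(-10, 10, length.out = n_res),
                rep(c(0, 2), length.out = n_res), 0)
  i1 <- 1L; i2 <- n_res  # end residues, symmetric about the centroid in x
  base[i1, ] <- c(-12, 0, 0); base[i2, ] <- c(12, 0, 0)
  atoms <- data.frame(serial = seq_len(n_res), name = "CA", elem = "C",
                      resname = "GLY", chain = "A", resid = seq_len(n_res))
  frames <- lapply(seq_len(n_frames), function(f) {
    s <- if (f %% 2 == 1) d else -d
    xyz <- base
    xyz[i1, 1] <- xyz[i1, 1] - s   # radial, antiphase
    xyz[i2, 1] <- xyz[i2, 1] + s
    md_frame(atoms, xyz, time = (f - 1) * 10)
  })
  as_trajectory(frames)
}
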