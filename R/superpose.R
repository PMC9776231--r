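#' Optimal rigid-body superposition (Kabsch algorithm)
#'
#' Finds the proper rotation and translation minimising the RMSD between two
#' paired coordinate sets, via SVD of the covariance matrix with the usual
#' sign correction so the rotation determinant is +1 (no reflection).
#'
#' @param mobile,reference numeric n x 3 matrices, n >= 3, rows paired.
#' @return list with `rotation` (3 x 3, det +1), `translation` (length-3
#'   vector) and `rmsd` (Angstrom). The fitted mobile set is
#'   `mobile %*% rotation + translation` (rows as points).
#' @export
kabsch_superpose <- function(mobile, reference) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (ncol(mobile) != 3L || ncol(reference) != 3L)
    stop("coordinate matrices must have 3 columns")
  if (nrow(mobile) != nrow(reference))
    stop("mobile and reference must have equal row counts")
  if (nrow(mobile) < 3L)
    stop("geometry error: need at least 3 points")
  if (!all(is.finite(mobile)) || !all(is.finite(reference)))
    stop("coordinates must be finite")
  cm <- colMeans(mobile); cr <- colMeans(reference)
  A <- sweep(mobile, 2L, cm); B <- sweep(reference, 2L, cr)
  # collinear point sets leave the rotation about the line undetermined
  if (qr(A)$rank < 2L || qr(B)$rank < 2L)
    stop("geometry error: degenerate (collinear) point set")
  if (max(abs(A - B)) == 0) {
    # already coincident after centering: exact identity fit
    return(list(rotation = diag(3), translation = as.numeric(cr - cm),
                rmsd = 0))
  }
  H <- crossprod(A, B)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)   # maps row-vector points: A %*% t(R)... see below
  rot <- t(R)                    # so that fitted = A %*% rot
  fitted <- A %*% rot
  rmsd <- sqrt(mean(rowSums((fitted - B)^2)))
  translation <- as.numeric(cr - cm %*% rot)
  list(rotation = rot, translation = translation, rmsd = rmsd)
}

rmsd_pair <- function(a, b) sqrt(mean(rowSums((a - b)^2)))

# n x 3 coordinate slice of selected atoms in frame k
slice_xyz <- function(traj, idx, k) matrix(traj$xyz[idx, , k], ncol = 3L)

apply_fit <- function(xyz, fit) sweep(xyz %*% fit$rotation, 2L,
                                      fit$translation, `+`)

#' RMSD time series along a trajectory
#'
#' Each frame's selected atoms are superposed onto those of a reference frame
#' and the minimised RMSD recorded, yielding one value per frame. By default
#' the fit and the measurement both use the C-alpha atoms of the selection.
#'
#' @param traj an `md_trajectory`.
#' @param chain chain identifier for the selection.
#' @param first,last inclusive residue range (default: whole chain).
#' @param reference_frame index of the reference frame (default 1).
#' @param atom_names atoms used for fitting and measurement (default `"CA"`).
#' @return data.frame of class `rmsd_series` with columns `time_ps`, `rmsd_A`.
#' @export
rmsd_series <- function(traj, chain, first = NULL, last = NULL,
                        reference_frame = 1L, atom_names = "CA") {
  stopifnot(inherits(traj, "md_trajectory"))
  nf <- n_frames(traj)
  if (reference_frame < 1L || reference_frame > nf)
    stop("index error: reference frame ", reference_frame,
         " outside 1..", nf)
  idx <- atom_select(traj, chain, first, last, atom_names)
  ref <- slice_xyz(traj, idx, reference_frame)
  vals <- vapply(seq_len(nf), function(k) {
    kabsch_superpose(slice_xyz(traj, idx, k), ref)$rmsd
  }, 0)
  out <- data.frame(time_ps = traj$times, rmsd_A = vals)
  class(out) <- c("rmsd_series", "data.frame")
  out
}

#' Per-residue RMSF profile over an analysis window
#'
#' Frames inside the window are superposed onto the mean structure of the
#' window, with the mean recomputed after each superposition pass until it
#' converges (the fluctuation reference is the converged mean, since a single
#' frame would bias the profile). The RMSF of a residue is the root mean
#' squared deviation of its selected atom from its mean position.
#'
#' @param traj an `md_trajectory`.
#' @param chain chain identifier.
#' @param first,last inclusive residue range (default: whole chain).
#' @param window optional `analysis_window`; default all frames.
#' @param atom_names atom carried per residue (default `"CA"`).
#' @param max_iter,tol mean-structure iteration controls.
#' @return data.frame of class `rmsf_profile` with columns `residue`,
#'   `rmsf_A`.
#' @export
rmsf_profile <- function(traj, chain, first = NULL, last = NULL,
                         window = NULL, atom_names = "CA",
                         max_iter = 10L, tol = 1e-6) {
  stopifnot(inherits(traj, "md_trajectory"))
  fr <- window_frames(traj, window)
  if (length(fr) < 2L) stop("window error: RMSF needs at least 2 frames")
  idx <- atom_select(traj, chain, first, last, atom_names)
  coords <- lapply(fr, function(k) slice_xyz(traj, idx, k))
  # a strictly static selection has zero fluctuation by definition; skip the
  # iterative fit so the zeros are exact rather than floating-point noise
  if (all(vapply(coords, function(x) max(abs(x - coords[[1L]])) == 0, TRUE))) {
    out <- data.frame(residue = unique(attr(idx, "resid")),
                      rmsf_A = 0)
    class(out) <- c("rmsf_profile", "data.frame")
    return(out)
  }
  mean_xyz <- coords[[1L]]
  for (it in seq_len(max_iter)) {
    fitted <- lapply(coords, function(x)
      apply_fit(x, kabsch_superpose(x, mean_xyz)))
    new_mean <- Reduce(`+`, fitted) / length(fitted)
    shift <- max(abs(new_mean - mean_xyz))
    mean_xyz <- new_mean
    coords <- fitted
    if (shift < tol) break
  }
  dev2 <- Reduce(`+`, lapply(coords, function(x) rowSums((x - mean_xyz)^2)))
  vals <- sqrt(dev2 / length(coords))
  resid <- attr(idx, "resid")
  if (length(atom_names) > 1L) {
    agg <- tapply(vals^2, resid, mean)
    out <- data.frame(residue = as.integer(names(agg)),
                      rmsf_A = sqrt(as.numeric(agg)))
  } else {
    out <- data.frame(residue = resid, rmsf_A = vals)
  }
  class(out) <- c("rmsf_profile", "data.frame")
  out
}
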