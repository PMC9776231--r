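# Three-state secondary-structure assignment from backbone geometry.
#
# Hydrogen bonds are scored with the classic electrostatic dipole model:
# two partial charges on the donor N-H and two on the acceptor C=O give
#   E = f * (1/d_ON + 1/d_CH - 1/d_OH - 1/d_CN),  f = 27.888 kcal*A/mol,
# and a bond is called when E < -0.5 kcal/mol. Helices are runs of two
# consecutive i -> i+4 bonds; strands are residues in parallel or
# antiparallel bridge patterns. Everything else (turns, bends, 3-10 and
# pi helices not forming i -> i+4 runs) is reported as coil.

HBOND_FACTOR <- 27.888        # kcal*A/mol, q1*q2*332
HBOND_EMAX <- -0.5            # kcal/mol bonding threshold
HBOND_CA_PRESCREEN <- 9.0     # A; donor/acceptor CA pairs farther apart cannot bond

#' Synthesize the backbone amide hydrogen
#'
#' Minimised or coarse trajectory frames often lack amide hydrogens; the H is
#' reconstructed 1.0 Angstrom from N, pointing opposite the bisector of the
#' C(prev)-N-CA angle, the standard planar reconstruction.
#'
#' @param c_prev,n,ca 3-vectors: previous residue's carbonyl C, this
#'   residue's N and CA.
#' @return 3-vector position of the amide H.
#' @export
synthesize_amide_h <- function(c_prev, n, ca) {
  u1 <- c_prev - n; u1 <- u1 / sqrt(sum(u1^2))
  u2 <- ca - n; u2 <- u2 / sqrt(sum(u2^2))
  bis <- u1 + u2
  nb <- sqrt(sum(bis^2))
  if (nb < 1e-8) stop("degenerate backbone geometry at amide H synthesis")
  as.numeric(n - bis / nb)
}

#' Backbone hydrogen-bond energy between a donor and an acceptor residue
#'
#' @param donor list with 3-vector components `N` and `H`.
#' @param acceptor list with 3-vector components `C` and `O`.
#' @return energy in kcal/mol; values below -0.5 count as hydrogen bonded.
#' @export
backbone_hbond_energy <- function(donor, acceptor) {
  d <- function(a, b) sqrt(sum((a - b)^2))
  if (is.null(donor$N) || is.null(donor$H))
    stop("donor must provide backbone N and H")
  if (is.null(acceptor$C) || is.null(acceptor$O))
    stop("acceptor must provide backbone C and O")
  HBOND_FACTOR * (1 / d(acceptor$O, donor$N) + 1 / d(acceptor$C, donor$H) -
                  1 / d(acceptor$O, donor$H) - 1 / d(acceptor$C, donor$N))
}

# Backbone scaffold of one frame: per residue N/CA/C/O (NA rows when absent)
# and the amide H, explicit when present, synthesized otherwise.
backbone_scaffold <- function(frame) {
  a <- frame$atoms
  chains <- unique(a$chain)
  res <- unique(a[c("chain", "resid")])
  res <- res[order(match(res$chain, chains), res$resid), , drop = FALSE]
  R <- nrow(res)
  get_atom <- function(ch, ri, nm) {
    i <- which(a$chain == ch & a$resid == ri & a$name %in% nm)
    if (length(i)) frame$xyz[i[1L], ] else c(NA_real_, NA_real_, NA_real_)
  }
  mat <- function(nm) t(vapply(seq_len(R), function(k)
    get_atom(res$chain[k], res$resid[k], nm), numeric(3)))
  N <- mat("N"); CA <- mat("CA"); C <- mat("C"); O <- mat("O")
  H <- mat(c("H", "HN"))
  pos <- integer(R)
  for (ch in chains) {
    ii <- which(res$chain == ch)
    pos[ii] <- seq_along(ii)
  }
  for (k in seq_len(R)) {
    if (any(is.na(H[k, ])) && pos[k] > 1L) {
      kp <- k - 1L
      if (res$chain[kp] == res$chain[k] && !any(is.na(C[kp, ])) &&
          !any(is.na(N[k, ])) && !any(is.na(CA[k, ])))
        H[k, ] <- synthesize_amide_h(C[kp, ], N[k, ], CA[k, ])
    }
  }
  list(res = res, pos = pos, N = N, CA = CA, C = C, O = O, H = H)
}

# R x R logical matrix: bonded[d, a] is TRUE when residue d's N-H donates to
# residue a's C=O.
hbond_matrix <- function(sc) {
  R <- nrow(sc$res)
  can_donate <- !apply(is.na(sc$N) | is.na(sc$H), 1L, any)
  can_accept <- !apply(is.na(sc$C) | is.na(sc$O), 1L, any)
  bonded <- matrix(FALSE, R, R)
  if (!any(can_donate) || !any(can_accept)) return(bonded)
  ca_ok <- !apply(is.na(sc$CA), 1L, any)
  for (d in which(can_donate)) {
    for (acc in which(can_accept)) {
      if (d == acc) next
      if (sc$res$chain[d] == sc$res$chain[acc] &&
          abs(sc$pos[d] - sc$pos[acc]) <= 1L) next
      if (ca_ok[d] && ca_ok[acc] &&
          sqrt(sum((sc$CA[d, ] - sc$CA[acc, ])^2)) > HBOND_CA_PRESCREEN) next
      e <- backbone_hbond_energy(list(N = sc$N[d, ], H = sc$H[d, ]),
                                 list(C = sc$C[acc, ], O = sc$O[acc, ]))
      bonded[d, acc] <- is.finite(e) && e < HBOND_EMAX
    }
  }
  bonded
}

#' Assign three-state secondary structure to a frame
#'
#' Residues are labeled `H` (alpha helix: inside a run backed by two
#' consecutive i -> i+4 backbone hydrogen bonds), `E` (strand: part of a
#' parallel or antiparallel bridge with another strand segment, possibly on
#' another chain) or `C` (everything else). Chains shorter than 5 residues
#' are labeled all `C`. Helix takes precedence where both patterns match.
#'
#' @param frame an `md_frame` with backbone N, CA, C, O atoms (amide H is
#'   synthesized when absent).
#' @return data.frame of class `ss_assignment` with columns `chain`,
#'   `residue`, `ss`.
#' @export
assign_ss <- function(frame) {
  stopifnot(inherits(frame, "md_frame"))
  sc <- backbone_scaffold(frame)
  R <- nrow(sc$res)
  bonded <- hbond_matrix(sc)
  lab <- rep("C", R)

  same_chain <- outer(sc$res$chain, sc$res$chain, `==`)
  chain_len <- table(sc$res$chain)
  long_chain <- chain_len[sc$res$chain] >= 5L

  # i -> i+4 turns: donor at position p+4 bonds the C=O of position p
  turn4 <- rep(FALSE, R)
  for (i in seq_len(R)) {
    j <- i + 4L
    if (j <= R && same_chain[i, j] && sc$pos[j] == sc$pos[i] + 4L)
      turn4[i] <- bonded[j, i]
  }
  for (i in seq_len(R - 1L)) {
    if (turn4[i] && i > 1L && turn4[i - 1L] &&
        same_chain[i - 1L, min(i + 3L, R)]) {
      span <- i:(i + 3L)
      lab[span[span <= R]] <- "H"
    }
  }

  hb <- function(d, a) d >= 1L && d <= R && a >= 1L && a <= R && bonded[d, a]
  # bridge neighbours must be sequence neighbours on the same chain
  nb <- function(i, step) {
    j <- i + step
    if (j >= 1L && j <= R && same_chain[i, j] && sc$pos[j] == sc$pos[i] + step)
      j else NA_integer_
  }
  is_e <- rep(FALSE, R)
  for (i in seq_len(R)) {
    for (j in seq_len(R)) {
      if (j <= i) next
      if (same_chain[i, j] && abs(sc$pos[i] - sc$pos[j]) < 3L) next
      im <- nb(i, -1L); ip <- nb(i, 1L)
      jm <- nb(j, -1L); jp <- nb(j, 1L)
      par <- (!is.na(im) && !is.na(ip) && hb(j, im) && hb(ip, j)) ||
             (!is.na(jm) && !is.na(jp) && hb(i, jm) && hb(jp, i))
      anti <- (hb(j, i) && hb(i, j)) ||
              (!is.na(im) && !is.na(jp) && !is.na(ip) && !is.na(jm) &&
               hb(jp, im) && hb(ip, jm))
      if (par || anti) { is_e[i] <- TRUE; is_e[j] <- TRUE }
    }
  }
  lab[is_e & lab != "H"] <- "E"
  lab[!long_chain] <- "C"

  out <- data.frame(chain = sc$res$chain, residue = sc$res$resid, ss = lab,
                    stringsAsFactors = FALSE)
  class(out) <- c("ss_assignment", "data.frame")
  out
}

#' Helix and strand percentages over an analysis window
#'
#' Assigns secondary structure to every frame in the window and reports, per
#' residue, the percentage of window frames labeled helix and strand. The
#' whole-chain means (average of the per-residue percentages within each
#' chain) are attached as attribute `chain_mean`.
#'
#' @param traj an `md_trajectory`.
#' @param window optional `analysis_window`; default all frames.
#' @return data.frame of class `ss_percentage_profile` with columns `chain`,
#'   `residue`, `helix_pct`, `strand_pct` and attribute `chain_mean`.
#' @export
ss_percentages <- function(traj, window = NULL) {
  stopifnot(inherits(traj, "md_trajectory"))
  fr <- window_frames(traj, window)
  assigns <- lapply(fr, function(k) assign_ss(get_frame(traj, k)))
  base <- assigns[[1L]][c("chain", "residue")]
  nH <- nE <- numeric(nrow(base))
  for (a in assigns) {
    nH <- nH + (a$ss == "H")
    nE <- nE + (a$ss == "E")
  }
  out <- data.frame(base, helix_pct = 100 * nH / length(fr),
                    strand_pct = 100 * nE / length(fr))
  cm <- aggregate(out[c("helix_pct", "strand_pct")],
                  by = list(chain = out$chain), FUN = mean)
  attr(out, "chain_mean") <- cm
  class(out) <- c("ss_percentage_profile", "data.frame")
  out
}
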