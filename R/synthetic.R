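# Deterministic generators for structures, trajectories and energy sets with
# known ground truth. These emulate the shapes of post-MD analysis inputs
# (two-chain dimer trajectories with prescribed contact occupancy, ideal
# helix/strand backbones, a four-domain open/closed assembly, Gaussian
# conformer energy ensembles) without any force-field dynamics.

with_seed <- function(seed, code) {
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  set.seed(seed)
  code
}

# place atom D from A-B-C with bond |CD|, angle B-C-D (deg) and dihedral
# A-B-C-D (deg): the standard internal-coordinate construction
place_atom <- function(a, b, c, bond, angle, torsion) {
  ang <- angle * pi / 180; tor <- torsion * pi / 180
  bc <- c - b; bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- ab - sum(ab * bc) * bc
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])   # bc x n ... orthonormal frame
  d_local <- c(-bond * cos(ang),
               -bond * sin(ang) * cos(tor),
               -bond * sin(ang) * sin(tor))
  c + d_local[1] * bc + d_local[2] * n + d_local[3] * m
}

build_atom_table <- function(names, elems, resnames, chains, resids) {
  data.frame(serial = seq_along(names), name = names, elem = elems,
             resname = resnames, chain = chains, resid = as.integer(resids),
             stringsAsFactors = FALSE)
}

# poly-alanine backbone from phi/psi via internal coordinates; standard bond
# lengths/angles (N-CA 1.458, CA-C 1.525, C-N 1.329, C=O 1.231)
build_backbone <- function(n, phi, psi, omega = 180) {
  N <- CA <- C <- O <- matrix(0, n, 3L)
  N[1L, ] <- c(0, 0, 0)
  CA[1L, ] <- c(1.458, 0, 0)
  C[1L, ] <- CA[1L, ] + 1.525 * c(cos(pi - 111.2 * pi / 180),
                                  sin(pi - 111.2 * pi / 180), 0)
  for (i in seq_len(n - 1L)) {
    N[i + 1L, ] <- place_atom(N[i, ], CA[i, ], C[i, ], 1.329, 116.2, psi)
    CA[i + 1L, ] <- place_atom(CA[i, ], C[i, ], N[i + 1L, ], 1.458, 121.7,
                               omega)
    C[i + 1L, ] <- place_atom(C[i, ], N[i + 1L, ], CA[i + 1L, ], 1.525,
                              111.2, phi)
  }
  for (i in seq_len(n)) {
    # carbonyl O opposite the next N across the C (dihedral psi + 180)
    O[i, ] <- place_atom(N[i, ], CA[i, ], C[i, ], 1.231, 120.8, psi + 180)
  }
  list(N = N, CA = CA, C = C, O = O)
}

#' Generate an ideal alpha-helical poly-alanine frame
#'
#' Backbone built from helical dihedrals (phi = -57, psi = -47 degrees) with
#' standard bond geometry; the amide hydrogen is present explicitly (placed
#' by the planar reconstruction) so the frame feeds hydrogen-bond based
#' secondary-structure assignment directly.
#'
#' @param n_residues number of residues (at least 5).
#' @param chain chain identifier (default "A").
#' @return an `md_frame`.
#' @export
make_ideal_helix <- function(n_residues, chain = "A") {
  if (n_residues < 5L) stop("size error: an ideal helix needs >= 5 residues")
  backbone_frame(n_residues, phi = -57, psi = -47, chain = chain)
}

# poly-alanine frame at arbitrary backbone dihedrals (helix, extended, ...)
backbone_frame <- function(n_residues, phi, psi, chain = "A") {
  bb <- build_backbone(n_residues, phi = phi, psi = psi)
  names_ <- elems <- resn <- ch <- rid <- list()
  xyz <- list()
  for (i in seq_len(n_residues)) {
    nm <- c("N", "CA", "C", "O"); el <- c("N", "C", "C", "O")
    xs <- rbind(bb$N[i, ], bb$CA[i, ], bb$C[i, ], bb$O[i, ])
    if (i > 1L) {
      nm <- c(nm, "H"); el <- c(el, "H")
      xs <- rbind(xs, synthesize_amide_h(bb$C[i - 1L, ], bb$N[i, ],
                                         bb$CA[i, ]))
    }
    names_[[i]] <- nm; elems[[i]] <- el
    resn[[i]] <- rep("ALA", length(nm)); ch[[i]] <- rep(chain, length(nm))
    rid[[i]] <- rep(i, length(nm)); xyz[[i]] <- xs
  }
  atoms <- build_atom_table(unlist(names_), unlist(elems), unlist(resn),
                            unlist(ch), unlist(rid))
  md_frame(atoms, do.call(rbind, xyz))
}

# one idealized extended strand used by make_ideal_sheet: residues along x
# (spacing 3.3 A), amide H and carbonyl O of residue i pointing along
# side[i] * y, so cross-strand hydrogen bonds can be registered exactly
flat_strand <- function(n, side, chain, reverse = FALSE, origin = c(0, 0, 0)) {
  names_ <- elems <- resn <- ch <- rid <- list()
  xyz <- list()
  dir <- if (reverse) -1 else 1
  for (i in seq_len(n)) {
    x0 <- if (reverse) 3.3 * (n + 1L - i) else 3.3 * i
    s <- side[i]
    CA <- c(x0, 0, 0)
    N <- c(x0 - dir * 1.3, 0.6 * s, 0)
    H <- N + c(0, s, 0)
    C <- c(x0 + dir * 1.3, 0.6 * s, 0)
    O <- C + c(0, 1.23 * s, 0)
    xs <- sweep(rbind(N, CA, C, O, H), 2L, origin, `+`)
    names_[[i]] <- c("N", "CA", "C", "O", "H")
    elems[[i]] <- c("N", "C", "C", "O", "H")
    resn[[i]] <- rep("ALA", 5L); ch[[i]] <- rep(chain, 5L)
    rid[[i]] <- rep(i, 5L); xyz[[i]] <- xs
  }
  list(atoms = build_atom_table(unlist(names_), unlist(elems), unlist(resn),
                                unlist(ch), unlist(rid)),
       xyz = do.call(rbind, xyz))
}

#' Generate an ideal two-strand beta sheet frame
#'
#' Two extended strands on separate chains ("A" and "B"), with amide
#' hydrogens and carbonyl oxygens oriented so the inter-strand hydrogen
#' bonds of the requested sheet sense are registered: in the antiparallel
#' sheet paired residues bond mutually (narrow pairs), in the parallel sheet
#' bonds follow the staggered pattern. The strand separation places donor
#' H to acceptor O at roughly 1.9 Angstrom.
#'
#' @param n_per_strand residues per strand (at least 4; strands of fewer
#'   than 5 residues are below the assignment's minimum chain length).
#' @param orientation `"antiparallel"` or `"parallel"`.
#' @return an `md_frame` with chains "A" and "B".
#' @export
make_ideal_sheet <- function(n_per_strand,
                             orientation = c("antiparallel", "parallel")) {
  orientation <- match.arg(orientation)
  n <- as.integer(n_per_strand)
  if (n < 4L) stop("size error: a strand needs >= 4 residues")
  D <- 5.33  # inter-strand axis separation giving H...O about 1.9 A
  i_all <- seq_len(n)
  if (orientation == "antiparallel") {
    side_a <- ifelse(i_all %% 2L == 0L, 1, -1)
    # strand B runs -x; residue j faces residue n+1-j of A
    side_b <- ifelse((n + 1L - i_all) %% 2L == 0L, -1, 1)
    sa <- flat_strand(n, side_a, "A")
    sb <- flat_strand(n, side_b, "B", reverse = TRUE, origin = c(0, D, 0))
  } else {
    side_a <- ifelse(i_all %% 2L == 1L, 1, -1)
    side_b <- ifelse(i_all %% 2L == 0L, -1, 1)
    sa <- flat_strand(n, side_a, "A")
    sb <- flat_strand(n, side_b, "B", origin = c(-0.7, D, 0))
  }
  atoms <- rbind(sa$atoms, sb$atoms)
  atoms$serial <- seq_len(nrow(atoms))
  md_frame(atoms, rbind(sa$xyz, sb$xyz))
}

#' Per-pair contact schedule for the synthetic dimer trajectory
#'
#' @param resid_a,resid_b residue numbers on chains "A" and "B".
#' @param occupancy target occurrence percentage per pair.
#' @param contact_distance C-alpha distance in contact frames (default 5).
#' @param apart_distance C-alpha distance otherwise (default 15).
#' @param facing whether the pair's pseudo side chains point at each other
#'   (default TRUE).
#' @return data.frame of class `contact_schedule`.
#' @export
contact_schedule <- function(resid_a, resid_b, occupancy,
                             contact_distance = 5, apart_distance = 15,
                             facing = TRUE) {
  df <- data.frame(resid_a = as.integer(resid_a),
                   resid_b = as.integer(resid_b),
                   occupancy = occupancy,
                   contact_distance = contact_distance,
                   apart_distance = apart_distance,
                   facing = facing)
  if (any(df$occupancy < 0 | df$occupancy > 100))
    stop("occupancy must be in [0, 100]")
  if (any(df$contact_distance >= df$apart_distance))
    stop("contact distance must be below apart distance")
  if (anyDuplicated(df$resid_b))
    stop("each chain-B residue may appear in one scheduled pair only")
  class(df) <- c("contact_schedule", "data.frame")
  df
}

#' Generate a two-chain dimer trajectory with prescribed contact occupancy
#'
#' A toy dimer of two poly-leucine chains whose residues carry a C-alpha and
#' a single pseudo side-chain atom (CB). For every scheduled residue pair
#' the chain-B residue sits at the contact distance from its chain-A partner
#' in exactly `round(occupancy * n_frames / 100)` frames (the frames chosen
#' by a seeded permutation, so occurrence percentages are exact rather than
#' binomial) and at the apart distance otherwise. Pseudo side chains point
#' at the partner (or away, when `facing` is FALSE); unscheduled residues
#' stay far from the other chain. Gaussian coordinate noise of `noise_sd`
#' is added to every atom of every frame.
#'
#' @param schedule a `contact_schedule`.
#' @param n_frames number of frames.
#' @param noise_sd Gaussian noise, Angstrom (default 0).
#' @param seed RNG seed driving frame assignment and noise.
#' @return an `md_trajectory` (chains "A" and "B", 10 ps frame spacing),
#'   with attribute `achieved_occupancy` giving the exact per-pair
#'   percentages realised.
#' @export
make_dimer_trajectory <- function(schedule, n_frames, noise_sd = 0,
                                  seed = 1L) {
  stopifnot(inherits(schedule, "contact_schedule"), n_frames >= 1L)
  n_a <- max(10L, schedule$resid_a)
  n_b <- max(10L, schedule$resid_b)
  spacing <- 24  # residue spacing on each chain, keeps unscheduled pairs apart
  far_y <- 80
  zig <- function(i) 0.3 * (-1)^i  # breaks collinearity of the CA trace
  # each residue: CA, pseudo side chain CB, and an HB hydrogen on the CB so
  # hydrogen-bond analysis can run on the toy (the toy has no polar atoms,
  # so hydrogen-bond occurrences are zero by construction)
  mk_chain <- function(n, chain, y, cb_sign) {
    names_ <- rep(c("CA", "CB", "HB"), n)
    elems <- rep(c("C", "C", "H"), n)
    rid <- rep(seq_len(n), each = 3L)
    xyz <- matrix(0, 3L * n, 3L)
    xyz[seq(1L, 3L * n, 3L), ] <- cbind(spacing * seq_len(n), y,
                                        zig(seq_len(n)))
    xyz[seq(2L, 3L * n, 3L), ] <- cbind(spacing * seq_len(n),
                                        y + cb_sign * 1.5, zig(seq_len(n)))
    xyz[seq(3L, 3L * n, 3L), ] <- cbind(spacing * seq_len(n),
                                        y + cb_sign * 2.5, zig(seq_len(n)))
    list(atoms = build_atom_table(names_, elems, rep("LEU", 3L * n),
                                  rep(chain, 3L * n), rid),
         xyz = xyz)
  }
  a <- mk_chain(n_a, "A", 0, +1)
  b <- mk_chain(n_b, "B", far_y, -1)
  atoms <- rbind(a$atoms, b$atoms)
  atoms$serial <- seq_len(nrow(atoms))
  base <- rbind(a$xyz, b$xyz)

  k_contact <- as.integer(round(schedule$occupancy * n_frames / 100))
  achieved <- 100 * k_contact / n_frames
  off <- which(abs(achieved - schedule$occupancy) > 1e-9)
  if (length(off))
    message("make_dimer_trajectory: occupancy rounded to ",
            paste(sprintf("%.4g%%", achieved[off]), collapse = ", "),
            " for pair(s) ", paste(off, collapse = ", "))

  traj <- with_seed(seed, {
    contact_frames <- lapply(seq_len(nrow(schedule)), function(p)
      sample.int(n_frames)[seq_len(k_contact[p])])
    frames <- vector("list", n_frames)
    for (f in seq_len(n_frames)) {
      xyz <- base
      for (p in seq_len(nrow(schedule))) {
        ra <- schedule$resid_a[p]; rb <- schedule$resid_b[p]
        d <- if (f %in% contact_frames[[p]]) schedule$contact_distance[p]
             else schedule$apart_distance[p]
        row_b <- function(nm) which(atoms$chain == "B" & atoms$resid == rb &
                                      atoms$name == nm)
        # partner sits straight above the chain-A residue at distance d
        x_a <- spacing * ra
        z_a <- zig(ra)
        xyz[row_b("CA"), ] <- c(x_a, d, z_a)
        xyz[row_b("CB"), ] <- c(x_a, d - 1.5, z_a)
        xyz[row_b("HB"), ] <- c(x_a, d - 2.5, z_a)
        if (!schedule$facing[p]) {
          row_a <- function(nm) which(atoms$chain == "A" & atoms$resid == ra &
                                        atoms$name == nm)
          # chain-A side chain points away from the partner
          xyz[row_a("CB"), ] <- c(x_a, -1.5, z_a)
          xyz[row_a("HB"), ] <- c(x_a, -2.5, z_a)
        }
      }
      if (noise_sd > 0)
        xyz <- xyz + matrix(stats::rnorm(length(xyz), 0, noise_sd),
                            nrow(xyz), 3L)
      frames[[f]] <- md_frame(atoms, xyz, time = (f - 1) * 10)
    }
    as_trajectory(frames, frame_interval = 10)
  })
  attr(traj, "achieved_occupancy") <- achieved
  traj
}

#' Generate a salt-bridge toy trajectory (lysine/glutamate pair)
#'
#' Real-residue fixture for electrostatic and hydrogen-bond analyses: a
#' lysine on chain "A" and a glutamate on chain "B" whose side-chain tips
#' (NZ and OE1) sit at `contact_distance` in the given frames and at
#' `apart_distance` otherwise. The lysine NZ carries an explicit hydrogen
#' (HZ1) on the NZ-OE1 axis at 1.0 Angstrom, so the H-to-acceptor distance
#' is exactly the NZ-OE1 distance minus 1.
#'
#' @param n_frames number of frames.
#' @param contact_frames integer vector of frames in contact.
#' @param contact_distance NZ-OE1 distance in contact frames (default 3.5).
#' @param apart_distance NZ-OE1 distance otherwise (default 8).
#' @param with_hydrogens include the HZ1 hydrogen (default TRUE).
#' @return an `md_trajectory`.
#' @export
make_salt_bridge_trajectory <- function(n_frames, contact_frames,
                                        contact_distance = 3.5,
                                        apart_distance = 8,
                                        with_hydrogens = TRUE) {
  stopifnot(n_frames >= 1L, all(contact_frames >= 1L),
            all(contact_frames <= n_frames))
  lys_names <- c("N", "CA", "C", "O", "CB", "CG", "CD", "CE", "NZ")
  lys_elem <- c("N", "C", "C", "O", "C", "C", "C", "C", "N")
  lys_xyz <- rbind(c(-1.3, -1.0, 0), c(0, 0, 0), c(1.3, -1.0, 0),
                   c(1.3, -2.23, 0), c(0, 1.5, 0), c(0, 3.0, 0),
                   c(0, 4.5, 0), c(0, 6.0, 0), c(0, 7.5, 0))
  if (with_hydrogens) {
    lys_names <- c(lys_names, "HZ1"); lys_elem <- c(lys_elem, "H")
    lys_xyz <- rbind(lys_xyz, c(0, 8.5, 0))  # on the NZ -> OE1 axis (+y)
  }
  glu_names <- c("N", "CA", "C", "O", "CB", "CG", "CD", "OE1", "OE2")
  glu_elem <- c("N", "C", "C", "O", "C", "C", "C", "O", "O")
  glu_local <- rbind(c(-1.3, 5.0, 0), c(0, 4.0, 0), c(1.3, 5.0, 0),
                     c(1.3, 6.23, 0), c(0, 2.5, 0), c(0, 1.5, 0),
                     c(0, 0.7, 0), c(0, 0, 0), c(1.1, 0.3, 0))
  atoms <- build_atom_table(
    c(lys_names, glu_names), c(lys_elem, glu_elem),
    c(rep("LYS", length(lys_names)), rep("GLU", length(glu_names))),
    c(rep("A", length(lys_names)), rep("B", length(glu_names))),
    c(rep(1L, length(lys_names)), rep(1L, length(glu_names))))
  nz_y <- 7.5
  frames <- lapply(seq_len(n_frames), function(f) {
    d <- if (f %in% contact_frames) contact_distance else apart_distance
    glu_xyz <- sweep(glu_local, 2L, c(0, nz_y + d, 0), `+`)  # OE1 at NZ + d
    md_frame(atoms, rbind(lys_xyz, glu_xyz), time = (f - 1) * 10)
  })
  as_trajectory(frames, frame_interval = 10)
}

TOY_GAUGE_RESIDUES <- data.frame(
  resid = c(134L, 176L, 353L, 403L, 410L, 424L, 614L, 615L, 657L, 721L,
            876L, 884L),
  resname = c("HIS", "GLU", "LYS", "ALA", "VAL", "PHE", "ALA", "GLY", "LYS",
              "SER", "ASP", "LYS"),
  domain = c(1L, 1L, 2L, 2L, 2L, 2L, 3L, 3L, 3L, 3L, 4L, 4L))

#' Generate a four-domain open/closed toy assembly
#'
#' A sparse single-chain frame carrying only the gauge residues of the
#' standard open/closed descriptors (C-alpha atoms), grouped into four rigid
#' pseudo-domains. In the closed state the four domain centers form a
#' compact square; in the open state domains 3 and 4 swing away, so every
#' default distance gauge grows by a factor of at least two and both angle
#' gauges change by more than 20 degrees.
#'
#' @param state `"open"` or `"closed"`.
#' @param chain chain identifier (default "A", matching [ide_gauges()]).
#' @return an `md_frame`.
#' @export
make_open_closed_toy <- function(state = c("closed", "open"), chain = "A") {
  state <- match.arg(state)
  centers <- if (state == "closed")
    rbind(c(0, 0, 0), c(20, 0, 0), c(20, 20, 0), c(0, 20, 0))
  else
    rbind(c(0, 0, 0), c(20, 0, 0), c(40, 40, 0), c(-20, 40, 0))
  g <- TOY_GAUGE_RESIDUES
  # deterministic sub-Angstrom scatter so residues of a domain do not overlap
  offs <- cbind(cos(seq_len(nrow(g))), sin(seq_len(nrow(g))), 0) * 0.8
  xyz <- centers[g$domain, , drop = FALSE] + offs
  atoms <- build_atom_table(rep("CA", nrow(g)), rep("C", nrow(g)),
                            g$resname, rep(chain, nrow(g)), g$resid)
  md_frame(atoms, xyz)
}

#' Specification for a Gaussian conformer energy ensemble
#'
#' @param mean per-conformer mean energies, kcal/mol.
#' @param spread per-conformer standard deviations, kcal/mol (recycled).
#' @param count conformations per conformer (recycled).
#' @param labels conformer labels (default `"C1"`, `"C2"`, ...).
#' @param seed RNG seed.
#' @return list of class `energy_model_spec`.
#' @export
energy_model_spec <- function(mean, spread = 1, count = 500L,
                              labels = NULL, seed = 1L) {
  k <- length(mean)
  spread <- rep_len(spread, k); count <- rep_len(as.integer(count), k)
  if (any(count < 1L)) stop("counts must be >= 1")
  if (any(spread < 0)) stop("spreads must be >= 0")
  if (is.null(labels)) labels <- paste0("C", seq_len(k))
  structure(list(mean = mean, spread = spread, count = count,
                 labels = labels, seed = as.integer(seed)),
            class = "energy_model_spec")
}

#' Default seven-conformer ensemble specification
#'
#' Seven conformers of 500 conformations each, mean energies evenly spanning
#' 3 kcal/mol with a 1 kcal/mol Gaussian spread -- the scale of a typical
#' implicit-solvent conformer comparison.
#'
#' @param seed RNG seed.
#' @return an `energy_model_spec`.
#' @export
default_energy_spec <- function(seed = 1L) {
  energy_model_spec(mean = seq(0, 3, length.out = 7), spread = 1,
                    count = 500L, seed = seed)
}

#' Generate Gaussian conformer energies
#'
#' @param spec an `energy_model_spec`.
#' @return a `conformer_energy_set`; [exact_populations()] of the output is
#'   the recovery target for the Monte Carlo estimator.
#' @export
make_conformer_energies <- function(spec = default_energy_spec()) {
  stopifnot(inherits(spec, "energy_model_spec"))
  with_seed(spec$seed, {
    out <- lapply(seq_along(spec$mean), function(i)
      stats::rnorm(spec$count[i], spec$mean[i], spec$spread[i]))
    names(out) <- spec$labels
    conformer_energy_set(out)
  })
}

#' Write a conformer energy set as a delimited table
#'
#' @param energies a `conformer_energy_set`.
#' @param path output path (CSV with header
#'   `conformer_label,energy_kcal_mol`).
#' @return `path`, invisibly.
#' @export
write_energy_table <- function(energies, path) {
  energies <- conformer_energy_set(energies)
  df <- data.frame(
    conformer_label = rep(names(energies), vapply(energies, length, 0L)),
    energy_kcal_mol = unlist(energies, use.names = FALSE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
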