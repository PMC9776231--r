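#' Interaction criteria for occurrence maps and contact classification
#'
#' Bundles the distance cutoffs and rubric thresholds used throughout the
#' contact analyses: 10 Angstrom between C-alpha atoms for hydrophobic
#' interactions, 4 Angstrom between charged-group atoms for electrostatic
#' interactions, 2.4 Angstrom from donor hydrogen to acceptor for hydrogen
#' bonds, and the strong-contact rubric (at least `min_interactions`
#' qualifying residue pairs with occurrence at or above
#' `strong_occurrence_threshold` percent). All cutoffs are inclusive.
#'
#' @param hydrophobic_ca_cutoff Angstrom, default 10.
#' @param electrostatic_cutoff Angstrom, default 4.
#' @param hbond_cutoff Angstrom, default 2.4.
#' @param strong_occurrence_threshold percent, default 85.
#' @param min_interactions count, default 2.
#' @param facing_angle_cutoff degrees, default 90.
#' @param hydrophobic_residues 3-letter codes counted as hydrophobic.
#' @param his_positive whether histidine counts as positively charged.
#' @return list of class `interaction_criteria`.
#' @export
interaction_criteria <- function(hydrophobic_ca_cutoff = 10,
                                 electrostatic_cutoff = 4,
                                 hbond_cutoff = 2.4,
                                 strong_occurrence_threshold = 85,
                                 min_interactions = 2L,
                                 facing_angle_cutoff = 90,
                                 hydrophobic_residues = c("ALA", "VAL", "LEU",
                                   "ILE", "MET", "PHE", "TRP", "TYR", "PRO"),
                                 his_positive = TRUE) {
  cuts <- c(hydrophobic_ca_cutoff, electrostatic_cutoff, hbond_cutoff,
            facing_angle_cutoff)
  if (any(cuts <= 0)) stop("cutoffs must be positive")
  if (strong_occurrence_threshold <= 0 || strong_occurrence_threshold > 100)
    stop("strong_occurrence_threshold must be in (0, 100]")
  structure(list(hydrophobic_ca_cutoff = hydrophobic_ca_cutoff,
                 electrostatic_cutoff = electrostatic_cutoff,
                 hbond_cutoff = hbond_cutoff,
                 strong_occurrence_threshold = strong_occurrence_threshold,
                 min_interactions = as.integer(min_interactions),
                 facing_angle_cutoff = facing_angle_cutoff,
                 hydrophobic_residues = hydrophobic_residues,
                 his_positive = his_positive),
            class = "interaction_criteria")
}

CHARGED_ATOMS <- list(
  ASP = list(sign = -1, atoms = c("OD1", "OD2")),
  GLU = list(sign = -1, atoms = c("OE1", "OE2")),
  LYS = list(sign = +1, atoms = "NZ"),
  ARG = list(sign = +1, atoms = c("NE", "NH1", "NH2")),
  HIS = list(sign = +1, atoms = c("ND1", "NE2"))
)

BACKBONE_NAMES <- c("N", "CA", "C", "O", "OXT", "H", "HN", "HA")

# residue bookkeeping for a selection spec list(chain=, first=, last=)
resolve_group <- function(traj, group) {
  stopifnot(is.list(group), !is.null(group$chain))
  idx <- atom_select(traj, group$chain, group$first, group$last)
  a <- traj$atoms[idx, , drop = FALSE]
  res <- unique(a[c("chain", "resid", "resname")])
  res[order(res$resid), , drop = FALSE]
}

new_occurrence_map <- function(pairs, counts, n_frames, criterion) {
  out <- data.frame(pairs, n_contact_frames = counts,
                    occurrence_pct = 100 * counts / n_frames)
  attr(out, "n_frames") <- n_frames
  attr(out, "criterion") <- criterion
  class(out) <- c("occurrence_map", "data.frame")
  out
}

# occurrence counting shared by the three map kinds: `hit` is a function
# (frame_xyz) -> logical vector over pair rows
count_pairs <- function(traj, pair_tab, hit) {
  counts <- integer(nrow(pair_tab))
  for (k in seq_len(n_frames(traj)))
    counts <- counts + hit(traj$xyz[, , k, drop = TRUE])
  counts
}

atom_row <- function(atoms, chain, resid, names) {
  which(atoms$chain == chain & atoms$resid == resid & atoms$name %in% names)
}

#' Hydrophobic interaction occurrence map
#'
#' For every pair of hydrophobic residues, one from each group, the map
#' records the percentage of trajectory frames in which the C-alpha to
#' C-alpha distance is within the hydrophobic cutoff (inclusive).
#'
#' @param traj an `md_trajectory`.
#' @param group_a,group_b selection specs: `list(chain =, first =, last =)`
#'   (`first`/`last` optional).
#' @param criteria an `interaction_criteria`.
#' @return data.frame of class `occurrence_map` with one row per hydrophobic
#'   residue pair, attributes `n_frames` and `criterion = "hydrophobic"`.
#' @export
hydrophobic_occurrence_map <- function(traj, group_a, group_b,
                                       criteria = interaction_criteria()) {
  stopifnot(inherits(traj, "md_trajectory"))
  ra <- resolve_group(traj, group_a)
  rb <- resolve_group(traj, group_b)
  ra <- ra[ra$resname %in% criteria$hydrophobic_residues, , drop = FALSE]
  rb <- rb[rb$resname %in% criteria$hydrophobic_residues, , drop = FALSE]
  empty <- nrow(ra) == 0L || nrow(rb) == 0L
  if (empty) {
    warning("no hydrophobic residues in one of the groups; empty map")
    pairs <- data.frame(chain_a = character(), resid_a = integer(),
                        resname_a = character(), chain_b = character(),
                        resid_b = integer(), resname_b = character())
    return(new_occurrence_map(pairs, integer(), n_frames(traj), "hydrophobic"))
  }
  grid <- expand.grid(ia = seq_len(nrow(ra)), ib = seq_len(nrow(rb)))
  pairs <- data.frame(chain_a = ra$chain[grid$ia], resid_a = ra$resid[grid$ia],
                      resname_a = ra$resname[grid$ia],
                      chain_b = rb$chain[grid$ib], resid_b = rb$resid[grid$ib],
                      resname_b = rb$resname[grid$ib],
                      stringsAsFactors = FALSE)
  ca_a <- vapply(seq_len(nrow(ra)), function(i)
    atom_row(traj$atoms, ra$chain[i], ra$resid[i], "CA")[1L], 0L)
  ca_b <- vapply(seq_len(nrow(rb)), function(i)
    atom_row(traj$atoms, rb$chain[i], rb$resid[i], "CA")[1L], 0L)
  ia <- ca_a[grid$ia]; ib <- ca_b[grid$ib]
  cutoff <- criteria$hydrophobic_ca_cutoff
  counts <- count_pairs(traj, pairs, function(xyz) {
    sqrt(rowSums((xyz[ia, , drop = FALSE] - xyz[ib, , drop = FALSE])^2)) <= cutoff
  })
  new_occurrence_map(pairs, counts, n_frames(traj), "hydrophobic")
}

side_chain_rows <- function(atoms, chain, resid) {
  i <- which(atoms$chain == chain & atoms$resid == resid)
  i <- i[!(atoms$name[i] %in% BACKBONE_NAMES) &
           toupper(atoms$elem[i]) != "H"]
  i
}

#' Fraction of frames in which two residues' side chains face each other
#'
#' A residue faces its partner when the vector from its C-alpha to its
#' side-chain heavy-atom centroid makes an angle below the facing cutoff
#' (default 90 degrees) with the vector to the partner's C-alpha. The pair
#' faces when both residues do. Glycine, having no side chain, is taken as
#' always facing.
#'
#' @param traj an `md_trajectory`.
#' @param chain_a,resid_a,chain_b,resid_b the residue pair.
#' @param criteria an `interaction_criteria` (for the angle cutoff).
#' @return fraction in `[0, 1]`.
#' @export
facing_fraction <- function(traj, chain_a, resid_a, chain_b, resid_b,
                            criteria = interaction_criteria()) {
  stopifnot(inherits(traj, "md_trajectory"))
  a <- traj$atoms
  ca_a <- atom_row(a, chain_a, resid_a, "CA")[1L]
  ca_b <- atom_row(a, chain_b, resid_b, "CA")[1L]
  if (is.na(ca_a) || is.na(ca_b)) stop("selection error: missing CA atom")
  sc_a <- side_chain_rows(a, chain_a, resid_a)
  sc_b <- side_chain_rows(a, chain_b, resid_b)
  name_a <- a$resname[ca_a]; name_b <- a$resname[ca_b]
  if (!length(sc_a) && name_a != "GLY")
    stop("geometry error: no side-chain heavy atoms in ",
         name_a, resid_a, " chain ", chain_a)
  if (!length(sc_b) && name_b != "GLY")
    stop("geometry error: no side-chain heavy atoms in ",
         name_b, resid_b, " chain ", chain_b)
  cosmax <- cos(criteria$facing_angle_cutoff * pi / 180)
  faces <- function(xyz, ca_self, sc_self, ca_other) {
    if (!length(sc_self)) return(TRUE)  # glycine: no orientation to violate
    v <- colMeans(xyz[sc_self, , drop = FALSE]) - xyz[ca_self, ]
    w <- xyz[ca_other, ] - xyz[ca_self, ]
    nv <- sqrt(sum(v^2)); nw <- sqrt(sum(w^2))
    if (nv < 1e-8 || nw < 1e-8) return(TRUE)
    sum(v * w) / (nv * nw) > cosmax
  }
  nf <- n_frames(traj)
  hits <- vapply(seq_len(nf), function(k) {
    xyz <- traj$xyz[, , k, drop = TRUE]
    faces(xyz, ca_a, sc_a, ca_b) && faces(xyz, ca_b, sc_b, ca_a)
  }, TRUE)
  mean(hits)
}

#' Facing fractions for every pair of an occurrence map
#' @param traj an `md_trajectory`.
#' @param occ an `occurrence_map`.
#' @param criteria an `interaction_criteria`.
#' @return numeric vector aligned with the rows of `occ`.
#' @export
facing_fractions <- function(traj, occ, criteria = interaction_criteria()) {
  vapply(seq_len(nrow(occ)), function(i)
    facing_fraction(traj, occ$chain_a[i], occ$resid_a[i],
                    occ$chain_b[i], occ$resid_b[i], criteria), 0)
}

#' Electrostatic interaction (salt bridge) occurrence map
#'
#' For every oppositely charged residue pair between the two groups
#' (Asp/Glu carboxylate oxygens against Lys/Arg/His side-chain nitrogens),
#' the map records the percentage of frames in which the minimum distance
#' between charged-group atoms is within the electrostatic cutoff.
#' Like-charged pairs are not reported.
#'
#' @inheritParams hydrophobic_occurrence_map
#' @return data.frame of class `occurrence_map`, `criterion =
#'   "electrostatic"`.
#' @export
electrostatic_occurrence_map <- function(traj, group_a, group_b,
                                         criteria = interaction_criteria()) {
  stopifnot(inherits(traj, "md_trajectory"))
  inventory <- CHARGED_ATOMS
  if (!criteria$his_positive) inventory$HIS <- NULL
  charged <- function(res) res[res$resname %in% names(inventory), , drop = FALSE]
  ra <- charged(resolve_group(traj, group_a))
  rb <- charged(resolve_group(traj, group_b))
  rows <- list(); counts <- integer()
  pairs <- data.frame(chain_a = character(), resid_a = integer(),
                      resname_a = character(), chain_b = character(),
                      resid_b = integer(), resname_b = character(),
                      stringsAsFactors = FALSE)
  if (nrow(ra) && nrow(rb)) {
    grid <- expand.grid(ia = seq_len(nrow(ra)), ib = seq_len(nrow(rb)))
    sign_a <- vapply(ra$resname[grid$ia], function(r) inventory[[r]]$sign, 0)
    sign_b <- vapply(rb$resname[grid$ib], function(r) inventory[[r]]$sign, 0)
    grid <- grid[sign_a * sign_b < 0, , drop = FALSE]
    if (nrow(grid)) {
      pairs <- data.frame(chain_a = ra$chain[grid$ia],
                          resid_a = ra$resid[grid$ia],
                          resname_a = ra$resname[grid$ia],
                          chain_b = rb$chain[grid$ib],
                          resid_b = rb$resid[grid$ib],
                          resname_b = rb$resname[grid$ib],
                          stringsAsFactors = FALSE)
      rows_a <- lapply(seq_len(nrow(pairs)), function(i)
        atom_row(traj$atoms, pairs$chain_a[i], pairs$resid_a[i],
                 inventory[[pairs$resname_a[i]]]$atoms))
      rows_b <- lapply(seq_len(nrow(pairs)), function(i)
        atom_row(traj$atoms, pairs$chain_b[i], pairs$resid_b[i],
                 inventory[[pairs$resname_b[i]]]$atoms))
      cutoff <- criteria$electrostatic_cutoff
      counts <- count_pairs(traj, pairs, function(xyz) {
        vapply(seq_len(nrow(pairs)), function(i) {
          xa <- xyz[rows_a[[i]], , drop = FALSE]
          xb <- xyz[rows_b[[i]], , drop = FALSE]
          if (!nrow(xa) || !nrow(xb)) return(FALSE)
          min(sqrt(pmax(outer(rowSums(xa^2), rowSums(xb^2), `+`) -
                          2 * tcrossprod(xa, xb), 0))) <= cutoff
        }, TRUE)
      })
    }
  }
  if (!length(counts)) counts <- integer(nrow(pairs))
  new_occurrence_map(pairs, counts, n_frames(traj), "electrostatic")
}

#' Hydrogen-bond occurrence map
#'
#' A hydrogen bond between two residues is counted in a frame when any donor
#' hydrogen (an H covalently attached to N or O) of one residue lies within
#' the hydrogen-bond cutoff (default 2.4 Angstrom) of any N or O acceptor of
#' the other, in either donor/acceptor direction. Explicit hydrogens are
#' required; structures without any hydrogens are rejected.
#'
#' @inheritParams hydrophobic_occurrence_map
#' @return data.frame of class `occurrence_map`, `criterion = "hbond"`.
#' @export
hbond_occurrence_map <- function(traj, group_a, group_b,
                                 criteria = interaction_criteria()) {
  stopifnot(inherits(traj, "md_trajectory"))
  a <- traj$atoms
  is_h <- toupper(a$elem) == "H"
  if (!any(is_h))
    stop("no hydrogen atoms in the structure; hydrogen-bond analysis needs ",
         "hydrogen-bearing input")
  xyz1 <- traj$xyz[, , 1L, drop = TRUE]
  # donor hydrogens: H within covalent range of an N/O of the same residue
  polar <- which(a$elem %in% c("N", "O"))
  donor_h <- which(is_h & vapply(seq_len(nrow(a)), function(i) {
    if (!is_h[i]) return(FALSE)
    j <- polar[a$chain[polar] == a$chain[i] & a$resid[polar] == a$resid[i]]
    length(j) > 0L &&
      min(sqrt(rowSums((xyz1[j, , drop = FALSE] -
                          matrix(xyz1[i, ], length(j), 3L, byrow = TRUE))^2))) <= 1.25
  }, TRUE))
  ra <- resolve_group(traj, group_a)
  rb <- resolve_group(traj, group_b)
  grid <- expand.grid(ia = seq_len(nrow(ra)), ib = seq_len(nrow(rb)))
  pairs <- data.frame(chain_a = ra$chain[grid$ia], resid_a = ra$resid[grid$ia],
                      resname_a = ra$resname[grid$ia],
                      chain_b = rb$chain[grid$ib], resid_b = rb$resid[grid$ib],
                      resname_b = rb$resname[grid$ib],
                      stringsAsFactors = FALSE)
  res_rows <- function(ch, ri, set) set[a$chain[set] == ch & a$resid[set] == ri]
  h_a <- lapply(seq_len(nrow(pairs)), function(i)
    res_rows(pairs$chain_a[i], pairs$resid_a[i], donor_h))
  h_b <- lapply(seq_len(nrow(pairs)), function(i)
    res_rows(pairs$chain_b[i], pairs$resid_b[i], donor_h))
  acc_a <- lapply(seq_len(nrow(pairs)), function(i)
    res_rows(pairs$chain_a[i], pairs$resid_a[i], polar))
  acc_b <- lapply(seq_len(nrow(pairs)), function(i)
    res_rows(pairs$chain_b[i], pairs$resid_b[i], polar))
  cutoff <- criteria$hbond_cutoff
  min_d <- function(xyz, ii, jj) {
    if (!length(ii) || !length(jj)) return(Inf)
    xa <- xyz[ii, , drop = FALSE]; xb <- xyz[jj, , drop = FALSE]
    min(sqrt(pmax(outer(rowSums(xa^2), rowSums(xb^2), `+`) -
                    2 * tcrossprod(xa, xb), 0)))
  }
  counts <- count_pairs(traj, pairs, function(xyz) {
    vapply(seq_len(nrow(pairs)), function(i) {
      min_d(xyz, h_a[[i]], acc_b[[i]]) <= cutoff ||
        min_d(xyz, h_b[[i]], acc_a[[i]]) <= cutoff
    }, TRUE)
  })
  new_occurrence_map(pairs, counts, n_frames(traj), "hbond")
}

#' Classify region-pair contacts as strong, weak or none
#'
#' Applies the four-rule rubric to a hydrophobic occurrence map aggregated
#' over region pairs. A residue pair qualifies when its side chains face each
#' other in at least half of the frames (rule 1) and its C-alpha distance
#' fell within the cutoff in at least one frame (rule 2, the map itself).
#' A region pair is `strong` when at least `min_interactions` qualifying
#' pairs reach the strong occurrence threshold (rules 3 and 4; at the exact
#' boundary of 2 interactions at 85 percent the contact counts as strong),
#' `weak` when qualifying pairs exist but the strong condition fails, and
#' `none` when no pair qualifies.
#'
#' @param occ an `occurrence_map` (criterion `"hydrophobic"`).
#' @param facing numeric vector of facing fractions aligned with `occ` rows
#'   (see [facing_fractions()]).
#' @param scheme_a,scheme_b `region_scheme`s for the two sides of the map.
#' @param criteria an `interaction_criteria`.
#' @return data.frame of class `contact_levels` with columns `region_a`,
#'   `region_b`, `n_qualifying`, `n_strong`, `level`.
#' @export
classify_region_contacts <- function(occ, facing, scheme_a, scheme_b,
                                     criteria = interaction_criteria()) {
  stopifnot(inherits(occ, "occurrence_map"))
  if (length(facing) != nrow(occ))
    stop("facing must have one value per occurrence-map row")
  out <- expand.grid(region_a = scheme_a$region, region_b = scheme_b$region,
                     stringsAsFactors = FALSE)
  out$n_qualifying <- 0L; out$n_strong <- 0L; out$level <- "none"
  for (r in seq_len(nrow(out))) {
    sa <- scheme_a[scheme_a$region == out$region_a[r], ]
    sb <- scheme_b[scheme_b$region == out$region_b[r], ]
    in_pair <- occ$chain_a == sa$chain & occ$resid_a >= sa$first &
      occ$resid_a <= sa$last & occ$chain_b == sb$chain &
      occ$resid_b >= sb$first & occ$resid_b <= sb$last
    qual <- in_pair & facing >= 0.5 & occ$occurrence_pct > 0
    strong_n <- sum(qual &
                      occ$occurrence_pct >= criteria$strong_occurrence_threshold)
    out$n_qualifying[r] <- sum(qual)
    out$n_strong[r] <- strong_n
    out$level[r] <- if (strong_n >= criteria$min_interactions) "strong"
      else if (any(qual)) "weak" else "none"
  }
  class(out) <- c("contact_levels", "data.frame")
  out
}
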