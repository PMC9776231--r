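#' @useDynLib postmd, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Construct a single structure frame
#'
#' A frame holds one set of coordinates together with its atom table
#' (topology). The atom table identifies each atom by serial number, atom
#' name, element, residue name, chain identifier and residue sequence number;
#' residue numbering is 1-based as in PDB records.
#'
#' @param atoms data.frame with columns `serial`, `name`, `elem`, `resname`,
#'   `chain`, `resid`.
#' @param xyz numeric matrix, one row per atom, columns x/y/z in Angstrom.
#' @param time frame time in picoseconds (non-negative).
#' @return An object of class `md_frame`.
#' @export
md_frame <- function(atoms, xyz, time = 0) {
  atoms <- validate_atom_table(atoms)
  xyz <- as.matrix(xyz)
  if (!is.numeric(xyz) || ncol(xyz) != 3L)
    stop("xyz must be a numeric matrix with 3 columns")
  if (nrow(xyz) != nrow(atoms))
    stop("xyz has ", nrow(xyz), " rows but atom table has ", nrow(atoms))
  if (!all(is.finite(xyz)))
    stop("coordinates must be finite")
  if (!is.numeric(time) || length(time) != 1L || time < 0)
    stop("time must be a single non-negative number (ps)")
  dimnames(xyz) <- list(NULL, c("x", "y", "z"))
  structure(list(atoms = atoms, xyz = xyz, time = time), class = "md_frame")
}

validate_atom_table <- function(atoms) {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  need <- c("serial", "name", "elem", "resname", "chain", "resid")
  miss <- setdiff(need, names(atoms))
  if (length(miss))
    stop("atom table lacks column(s): ", paste(miss, collapse = ", "))
  if (nrow(atoms) == 0L) stop("atom table is empty")
  if (any(!nzchar(atoms$name))) stop("atom names must be non-empty")
  key <- paste(atoms$chain, atoms$resid)
  dup <- vapply(split(atoms$name, key), anyDuplicated, 0L)
  if (any(dup > 0L))
    stop("duplicated atom name within residue ", names(dup)[dup > 0L][1L])
  atoms[need]
}

#' Construct a trajectory from frames
#'
#' A trajectory is an ordered set of frames sharing one topology. Frame times
#' must be strictly increasing; when frames carry no time metadata, times are
#' assigned as `(frame - 1) * frame_interval` following the saved-frame
#' convention of trajectory snapshots stored every fixed interval.
#'
#' @param frames list of `md_frame` objects with identical atom tables, or a
#'   single `md_frame`.
#' @param frame_interval spacing in ps used when frame times are unset
#'   (default 10 ps).
#' @return An object of class `md_trajectory` holding the shared atom table,
#'   a 3-D coordinate array (atoms x 3 x frames) and a time vector.
#' @export
as_trajectory <- function(frames, frame_interval = 10) {
  if (inherits(frames, "md_trajectory")) return(frames)
  if (inherits(frames, "md_frame")) frames <- list(frames)
  if (!length(frames)) stop("a trajectory needs at least one frame")
  if (!all(vapply(frames, inherits, TRUE, "md_frame")))
    stop("frames must be md_frame objects")
  ref <- frames[[1L]]$atoms
  for (k in seq_along(frames)) {
    if (!identical(unname(as.list(frames[[k]]$atoms)), unname(as.list(ref))))
      stop("topology error: frame ", k, " differs from frame 1 in its atom table")
  }
  times <- vapply(frames, function(f) f$time, 0)
  if (all(times == 0) && length(frames) > 1L)
    times <- (seq_along(frames) - 1) * frame_interval
  if (any(diff(times) <= 0))
    stop("frame times must be strictly increasing")
  xyz <- array(0, dim = c(nrow(ref), 3L, length(frames)))
  for (k in seq_along(frames)) xyz[, , k] <- frames[[k]]$xyz
  structure(list(atoms = ref, xyz = xyz, times = times,
                 frame_interval = frame_interval),
            class = "md_trajectory")
}

#' Number of frames in a trajectory
#' @param traj an `md_trajectory`.
#' @return integer frame count.
#' @export
n_frames <- function(traj) {
  stopifnot(inherits(traj, "md_trajectory"))
  dim(traj$xyz)[3L]
}

#' Extract one frame from a trajectory
#' @param traj an `md_trajectory`.
#' @param i frame index (1-based).
#' @return an `md_frame`.
#' @export
get_frame <- function(traj, i) {
  stopifnot(inherits(traj, "md_trajectory"))
  if (!is.numeric(i) || length(i) != 1L || i < 1L || i > n_frames(traj))
    stop("frame index out of range: ", i)
  md_frame(traj$atoms, traj$xyz[, , i, drop = TRUE], time = traj$times[i])
}

#' @export
print.md_trajectory <- function(x, ...) {
  cat("md_trajectory:", n_frames(x), "frame(s),", nrow(x$atoms), "atoms,",
      length(unique(x$atoms$chain)), "chain(s)\n")
  cat("  time span:", x$times[1], "-", x$times[length(x$times)], "ps\n")
  invisible(x)
}

#' @export
print.md_frame <- function(x, ...) {
  cat("md_frame:", nrow(x$atoms), "atoms,",
      length(unique(x$atoms$chain)), "chain(s), t =", x$time, "ps\n")
  invisible(x)
}

infer_element <- function(name) {
  # strip leading digits (e.g. 1HB), then take leading letters; two-letter
  # elements in proteins are rare (Zn, Fe, ...) and carry both letters in
  # columns 13-14 of the PDB name field
  nm <- sub("^[0-9]+", "", name)
  first <- substr(nm, 1L, 1L)
  toupper(first)
}

#' Read a multi-model PDB file as a trajectory
#'
#' Parses ATOM records of a PDB file into a trajectory with one frame per
#' MODEL (or a single frame when no MODEL records are present). HETATM
#' records, waters and ions are skipped, with a message reporting the count.
#' Alternate locations keep the highest-occupancy conformer; insertion codes
#' are rejected. A missing element column is inferred from the atom name.
#'
#' @param path path to a PDB file.
#' @param frame_interval frame spacing in ps used to assign times
#'   (default 10 ps, the usual save interval of the trajectories analysed
#'   here).
#' @return an `md_trajectory`.
#' @export
read_pdb <- function(path, frame_interval = 10) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1L, 6L)
  is_atom <- rec == "ATOM  "
  n_het <- sum(rec == "HETATM")
  if (n_het > 0L)
    message("read_pdb: skipped ", n_het, " HETATM record(s) (waters/ions/ligands)")
  model_starts <- which(substr(lines, 1L, 5L) == "MODEL")
  atom_idx <- which(is_atom)
  if (!length(atom_idx)) stop("no ATOM records in ", path)

  parse_block <- function(idx) {
    ln <- lines[idx]
    bad <- nchar(ln) < 54L
    if (any(bad))
      stop("malformed ATOM line at line ", idx[bad][1L], " of ", path)
    serial <- suppressWarnings(as.integer(substr(ln, 7L, 11L)))
    name <- trimws(substr(ln, 13L, 16L))
    altloc <- substr(ln, 17L, 17L)
    resname <- trimws(substr(ln, 18L, 20L))
    chain <- substr(ln, 22L, 22L)
    resid <- suppressWarnings(as.integer(substr(ln, 23L, 26L)))
    icode <- substr(ln, 27L, 27L)
    x <- suppressWarnings(as.numeric(substr(ln, 31L, 38L)))
    y <- suppressWarnings(as.numeric(substr(ln, 39L, 46L)))
    z <- suppressWarnings(as.numeric(substr(ln, 47L, 54L)))
    occ <- suppressWarnings(as.numeric(substr(ln, 55L, 60L)))
    occ[is.na(occ)] <- 1
    elem <- trimws(substr(ln, 77L, 78L))
    bad <- is.na(serial) | is.na(resid) | is.na(x) | is.na(y) | is.na(z)
    if (any(bad))
      stop("malformed ATOM line at line ", idx[bad][1L], " of ", path)
    if (any(icode != " "))
      stop("insertion codes are not supported (line ",
           idx[icode != " "][1L], ")")
    df <- data.frame(serial = serial, name = name, elem = elem,
                     resname = resname, chain = chain, resid = resid,
                     altloc = altloc, occ = occ,
                     x = x, y = y, z = z, stringsAsFactors = FALSE)
    # alternate locations: keep highest occupancy per (chain, resid, name)
    if (any(df$altloc != " ")) {
      key <- paste(df$chain, df$resid, df$name)
      keep <- unlist(lapply(split(seq_len(nrow(df)), key)[unique(key)],
                            function(ii) ii[which.max(df$occ[ii])]))
      keep <- sort(keep)
      message("read_pdb: kept highest-occupancy conformer at ",
              length(unique(key[df$altloc != " "])), " alternate-location site(s)")
      df <- df[keep, , drop = FALSE]
    }
    df$elem <- ifelse(nzchar(df$elem), df$elem, infer_element(df$name))
    df
  }

  if (length(model_starts) == 0L) {
    blocks <- list(parse_block(atom_idx))
  } else {
    model_ends <- c(model_starts[-1L] - 1L, length(lines))
    blocks <- vector("list", length(model_starts))
    for (m in seq_along(model_starts)) {
      idx <- atom_idx[atom_idx >= model_starts[m] & atom_idx <= model_ends[m]]
      if (!length(idx)) stop("MODEL ", m, " contains no ATOM records")
      blocks[[m]] <- parse_block(idx)
    }
  }

  ref <- blocks[[1L]][c("serial", "name", "elem", "resname", "chain", "resid")]
  frames <- vector("list", length(blocks))
  for (m in seq_along(blocks)) {
    b <- blocks[[m]]
    topo <- b[c("serial", "name", "elem", "resname", "chain", "resid")]
    if (m > 1L && !identical(unname(as.list(topo[-1L])),
                             unname(as.list(ref[-1L]))))
      stop("topology error: MODEL ", m, " differs from MODEL 1")
    frames[[m]] <- md_frame(ref, as.matrix(b[c("x", "y", "z")]),
                            time = (m - 1) * frame_interval)
  }
  if (length(frames) == 1L) frames[[1L]]$time <- 0
  as_trajectory(frames, frame_interval = frame_interval)
}

format_pdb_name <- function(name, elem) {
  ifelse(nchar(name) >= 4L, sprintf("%-4s", name),
         ifelse(nchar(elem) == 2L, sprintf("%-4s", name),
                sprintf(" %-3s", name)))
}

#' Write a trajectory as a multi-model PDB file
#'
#' Coordinates are written at the fixed-width PDB precision (0.001 A), so a
#' read/write round trip reproduces coordinates to three decimals and
#' topology exactly.
#'
#' @param traj an `md_trajectory` or `md_frame`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(traj, path) {
  if (inherits(traj, "md_frame")) traj <- as_trajectory(traj)
  stopifnot(inherits(traj, "md_trajectory"))
  a <- traj$atoms
  nm <- format_pdb_name(a$name, a$elem)
  nf <- n_frames(traj)
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (m in seq_len(nf)) {
    xyz <- traj$xyz[, , m, drop = TRUE]
    if (is.null(dim(xyz))) xyz <- matrix(xyz, ncol = 3L)
    if (nf > 1L) writeLines(sprintf("MODEL     %4d", m), con)
    body <- sprintf(
      "ATOM  %5d %s %-3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      a$serial %% 100000L, nm, a$resname, a$chain, a$resid,
      xyz[, 1L], xyz[, 2L], xyz[, 3L], 1, 0, a$elem)
    writeLines(body, con)
    last <- nrow(a)
    writeLines(sprintf("TER   %5d      %-3s %s%4d",
                       (a$serial[last] + 1L) %% 100000L,
                       a$resname[last], a$chain[last], a$resid[last]), con)
    if (nf > 1L) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Select atoms by chain, residue range and atom name
#'
#' Returns the indices (rows of the atom table) of the selected atoms, in
#' residue-major order. Selection is validated: the chain must exist, the
#' residue range must be non-empty within the chain, and when `atom_names`
#' is given every selected residue must carry each requested name.
#'
#' @param x an `md_frame` or `md_trajectory`.
#' @param chain chain identifier (single character).
#' @param first,last inclusive residue-number range; default spans the chain.
#' @param atom_names optional character vector of atom names (e.g. `"CA"`).
#' @return integer vector of atom indices with attribute `resid` giving the
#'   residue number of each selected atom.
#' @export
atom_select <- function(x, chain, first = NULL, last = NULL,
                        atom_names = NULL) {
  atoms <- if (inherits(x, "md_frame") || inherits(x, "md_trajectory"))
    x$atoms else stop("x must be an md_frame or md_trajectory")
  in_chain <- atoms$chain == chain
  if (!any(in_chain)) stop("selection error: no chain '", chain, "'")
  if (is.null(first)) first <- min(atoms$resid[in_chain])
  if (is.null(last)) last <- max(atoms$resid[in_chain])
  if (first > last) stop("selection error: first > last")
  sel <- in_chain & atoms$resid >= first & atoms$resid <= last
  if (!any(sel))
    stop("selection error: no residues ", first, "-", last,
         " in chain '", chain, "'")
  idx <- which(sel)
  idx <- idx[order(atoms$resid[idx])]
  if (!is.null(atom_names)) {
    keep <- idx[atoms$name[idx] %in% atom_names]
    per_res <- table(atoms$resid[keep])
    res_all <- unique(atoms$resid[idx])
    missing_res <- res_all[!(res_all %in% names(per_res)) |
                             per_res[as.character(res_all)] < length(atom_names)]
    missing_res <- missing_res[!is.na(missing_res)]
    if (length(missing_res))
      stop("selection error: atom(s) ", paste(atom_names, collapse = ","),
           " absent in residue ", missing_res[1L], " of chain '", chain, "'")
    # residue-major, then in the order of atom_names within each residue
    ord <- order(atoms$resid[keep], match(atoms$name[keep], atom_names))
    idx <- keep[ord]
  }
  structure(idx, resid = atoms$resid[idx])
}

#' Coordinates of a selection in one frame
#'
#' @param frame an `md_frame`.
#' @inheritParams atom_select
#' @return numeric matrix (n x 3) with attribute `resid`.
#' @export
select_coords <- function(frame, chain, first = NULL, last = NULL,
                          atom_names = "CA") {
  stopifnot(inherits(frame, "md_frame"))
  idx <- atom_select(frame, chain, first, last, atom_names)
  structure(frame$xyz[idx, , drop = FALSE], resid = attr(idx, "resid"))
}

#' Named residue-range regions on a chain
#'
#' A region scheme maps region names to inclusive residue ranges on a chain,
#' and is used to aggregate residue-pair results to region pairs (e.g. the
#' four structural domains of insulin-degrading enzyme, or the N-/C-terminal
#' halves of amyloid-beta).
#'
#' @param region character vector of unique region names.
#' @param chain chain identifier per region.
#' @param first,last inclusive residue-number range per region.
#' @return data.frame of class `region_scheme`.
#' @export
region_scheme <- function(region, chain, first, last) {
  df <- data.frame(region = as.character(region), chain = as.character(chain),
                   first = as.integer(first), last = as.integer(last),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df$region)) stop("region names must be unique")
  if (any(df$first > df$last)) stop("region first must be <= last")
  class(df) <- c("region_scheme", "data.frame")
  df
}

#' Standard four-domain scheme of insulin-degrading enzyme
#'
#' Domain 1 spans residues 43-285, domain 2 spans 286-515, domain 3 spans
#' 542-768 and domain 4 spans 769-1016; domains 1-2 form the N-terminal half
#' (IDE-N) and domains 3-4 the C-terminal half (IDE-C).
#'
#' @param chain chain identifier carrying the enzyme (default "A").
#' @param split `"domains"` for the four domains, `"halves"` for IDE-N/IDE-C.
#' @return a `region_scheme`.
#' @export
ide_regions <- function(chain = "A", split = c("domains", "halves")) {
  split <- match.arg(split)
  if (split == "domains")
    region_scheme(c("D1", "D2", "D3", "D4"), chain,
                  c(43L, 286L, 542L, 769L), c(285L, 515L, 768L, 1016L))
  else
    region_scheme(c("IDE-N", "IDE-C"), chain, c(43L, 542L), c(515L, 1016L))
}

#' N-/C-terminal split of the amyloid-beta peptide
#'
#' The 42-residue peptide is split into an N-terminal domain (residues 1-16,
#' D1-K16) and a C-terminal domain (residues 17-42, L17-A42).
#'
#' @param chain chain identifier carrying the peptide.
#' @return a `region_scheme`.
#' @export
abeta_regions <- function(chain = "B") {
  region_scheme(c("Nterm", "Cterm"), chain, c(1L, 17L), c(16L, 42L))
}

#' Time window of a trajectory analysis
#'
#' @param start,end window bounds in ps; `0 <= start < end`.
#' @return numeric vector of class `analysis_window`.
#' @export
analysis_window <- function(start, end) {
  if (!is.numeric(start) || !is.numeric(end) || start < 0 || start >= end)
    stop("window error: need 0 <= start < end")
  structure(c(start = start, end = end), class = "analysis_window")
}

#' Frame indices of a trajectory falling inside a window (inclusive bounds)
#' @param traj an `md_trajectory`.
#' @param window an `analysis_window`, or NULL for all frames.
#' @return integer vector of frame indices.
#' @export
window_frames <- function(traj, window = NULL) {
  stopifnot(inherits(traj, "md_trajectory"))
  if (is.null(window)) return(seq_len(n_frames(traj)))
  idx <- which(traj$times >= window[["start"]] & traj$times <= window[["end"]])
  if (!length(idx)) stop("window error: no frames in [",
                         window[["start"]], ", ", window[["end"]], "] ps")
  idx
}
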