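#' Specify distance and angle gauges of conformational state
#'
#' A gauge spec names inter-residue distances (two residues) and
#' three-residue angles whose traces along a trajectory indicate open versus
#' closed conformations of a multi-domain protein. Each residue entry is
#' `chain:resid` or `chain:resid:atom`; the atom defaults to C-alpha.
#'
#' @param distances list of length-2 character vectors.
#' @param angles list of length-3 character vectors.
#' @return list of class `gauge_spec`.
#' @export
gauge_spec <- function(distances = list(), angles = list()) {
  parse_site <- function(s) {
    p <- strsplit(s, ":", fixed = TRUE)[[1L]]
    if (length(p) < 2L) stop("gauge site must be chain:resid[:atom]: ", s)
    list(chain = p[1L], resid = as.integer(p[2L]),
         atom = if (length(p) >= 3L) p[3L] else "CA")
  }
  d <- lapply(distances, function(x) {
    if (length(x) != 2L) stop("a distance gauge needs exactly 2 sites")
    lapply(x, parse_site)
  })
  an <- lapply(angles, function(x) {
    if (length(x) != 3L) stop("an angle gauge needs exactly 3 sites")
    sites <- lapply(x, parse_site)
    key <- vapply(sites, function(s) paste(s$chain, s$resid), "")
    if (anyDuplicated(key)) stop("angle gauge residues must be distinct")
    sites
  })
  gname <- function(sites) paste(vapply(sites, function(s)
    paste0(s$chain, s$resid), ""), collapse = "-")
  names(d) <- vapply(d, gname, "")
  names(an) <- vapply(an, gname, "")
  structure(list(distances = d, angles = an), class = "gauge_spec")
}

#' Default open/closed gauges of insulin-degrading enzyme
#'
#' Four inter-domain C-alpha distances (H134-K884, F424-G615, V410-A614,
#' K353-K657) and two three-residue angles (E176-A403-S721, A403-S721-D876)
#' that together gauge whether the enzyme's internal chamber is open or
#' closed.
#'
#' @param chain chain identifier carrying the enzyme (default "A").
#' @return a `gauge_spec`.
#' @export
ide_gauges <- function(chain = "A") {
  s <- function(r) paste0(chain, ":", r)
  gauge_spec(
    distances = list(c(s(134), s(884)), c(s(424), s(615)),
                     c(s(410), s(614)), c(s(353), s(657))),
    angles = list(c(s(176), s(403), s(721)), c(s(403), s(721), s(876))))
}

gauge_atom_row <- function(traj, site, gauge_name) {
  i <- atom_row(traj$atoms, site$chain, site$resid, site$atom)[1L]
  if (is.na(i))
    stop("gauge spec error: atom ", site$atom, " of residue ", site$resid,
         " chain ", site$chain, " (gauge ", gauge_name, ") not found")
  i
}

# check that every gauge site resolves to an atom (used by config validation)
gauge_series_sites_exist <- function(traj, spec) {
  for (g in names(spec$distances))
    for (s in spec$distances[[g]]) gauge_atom_row(traj, s, g)
  for (g in names(spec$angles))
    for (s in spec$angles[[g]]) gauge_atom_row(traj, s, g)
  invisible(TRUE)
}

#' Gauge time series along a trajectory
#'
#' @param traj an `md_trajectory`.
#' @param spec a `gauge_spec`; default the standard six gauges of
#'   insulin-degrading enzyme on chain "A".
#' @return data.frame of class `gauge_series`: `time_ps` plus one column per
#'   gauge (distances in Angstrom, angles in degrees, `[0, 180]`).
#' @export
gauge_series <- function(traj, spec = ide_gauges()) {
  stopifnot(inherits(traj, "md_trajectory"), inherits(spec, "gauge_spec"))
  nf <- n_frames(traj)
  out <- data.frame(time_ps = traj$times)
  for (g in names(spec$distances)) {
    sites <- spec$distances[[g]]
    i <- gauge_atom_row(traj, sites[[1L]], g)
    j <- gauge_atom_row(traj, sites[[2L]], g)
    out[[g]] <- vapply(seq_len(nf), function(k)
      sqrt(sum((traj$xyz[i, , k] - traj$xyz[j, , k])^2)), 0)
  }
  for (g in names(spec$angles)) {
    sites <- spec$angles[[g]]
    ijk <- vapply(sites, gauge_atom_row, 0L, traj = traj, gauge_name = g)
    out[[g]] <- vapply(seq_len(nf), function(k) {
      v1 <- traj$xyz[ijk[1L], , k] - traj$xyz[ijk[2L], , k]
      v2 <- traj$xyz[ijk[3L], , k] - traj$xyz[ijk[2L], , k]
      cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
      acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
    }, 0)
  }
  attr(out, "gauges") <- c(names(spec$distances), names(spec$angles))
  attr(out, "kinds") <- c(rep("distance", length(spec$distances)),
                          rep("angle", length(spec$angles)))
  class(out) <- c("gauge_series", "data.frame")
  out
}

#' Mean and standard deviation of each gauge over a window
#'
#' The spread is the population standard deviation (divisor `n`), the
#' descriptive spread of the frames actually in the window.
#'
#' @param series a `gauge_series`.
#' @param window optional `analysis_window` (applied to `time_ps`,
#'   inclusive); default all frames.
#' @return data.frame with columns `gauge`, `kind`, `mean`, `sd`, `n_frames`.
#' @export
summarize_gauges <- function(series, window = NULL) {
  stopifnot(inherits(series, "gauge_series"))
  keep <- if (is.null(window)) rep(TRUE, nrow(series))
    else series$time_ps >= window[["start"]] & series$time_ps <= window[["end"]]
  if (!any(keep)) stop("window error: no frames in the window")
  gauges <- attr(series, "gauges")
  data.frame(
    gauge = gauges,
    kind = attr(series, "kinds"),
    mean = vapply(gauges, function(g) mean(series[[g]][keep]), 0),
    sd = vapply(gauges, function(g) {
      x <- series[[g]][keep]
      sqrt(mean((x - mean(x))^2))
    }, 0),
    n_frames = sum(keep), row.names = NULL)
}
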