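#' Skeletonize the vessel-pore mask into a branch graph
#'
#' Computes a one-voxel-wide, 26-connected curve skeleton by homotopic
#' thinning (simple points removed in order of increasing distance to the
#' pore wall, endpoints preserved), then splits it into branch segments at
#' voxels with three or more skeleton neighbours. Adjacent junction voxels
#' are merged into one node. Each segment carries its polyline, arc length,
#' cord length, mean thickness (2x the distance-transform value along the
#' centerline) and the pore volume attributed to it by nearest-segment
#' propagation.
#'
#' @param vessel logical vessel-pore mask.
#' @param voxel_size_um voxel edge length (um).
#' @param prune drop spur segments: end-terminated branches shorter than
#'   their own mean thickness, which are artefacts of thinning a wide tube
#'   rather than real side branches.
#' @return an object of class `skeleton_graph`: list with `segments` (data
#'   frame), `polylines` (list of um-coordinate matrices), `n_nodes`,
#'   `skeleton` (logical array) and `voxel_size_um`. Empty mask gives an
#'   empty graph.
#' @export
skeletonize_vessels <- function(vessel, voxel_size_um = 1, prune = TRUE) {
  stopifnot_mask(vessel)
  empty <- list(
    segments = data.frame(id = integer(0), n_voxels = integer(0),
                          length_um = numeric(0), cord_length_um = numeric(0),
                          mean_thickness_um = numeric(0),
                          volume_um3 = numeric(0), phi_deg = numeric(0),
                          theta_deg = numeric(0)),
    polylines = list(), n_nodes = 0L, skeleton = vessel,
    voxel_size_um = voxel_size_um)
  class(empty) <- "skeleton_graph"
  if (!any(vessel)) return(empty)

  dm <- dim(vessel)
  dt2 <- edt_sq_cpp(!vessel, dm)           # squared distance to pore wall
  skel <- array(thin_skeleton_cpp(vessel, dm, dt2), dm)

  idx <- which(skel)
  ns <- length(idx)
  pos <- array(0L, dm)
  pos[idx] <- seq_len(ns)
  co <- arrayInd(idx, dm)

  # 26-neighbour ids (0 when absent), ns x 26
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  nbr <- matrix(0L, ns, nrow(offs))
  for (t in seq_len(nrow(offs))) {
    ii <- co[, 1] + offs[t, 1]; jj <- co[, 2] + offs[t, 2]
    kk <- co[, 3] + offs[t, 3]
    ok <- ii >= 1L & ii <= dm[1] & jj >= 1L & jj <= dm[2] &
      kk >= 1L & kk <= dm[3]
    lin <- ii[ok] + dm[1] * (jj[ok] - 1L) + dm[1] * dm[2] * (kk[ok] - 1L)
    v <- integer(ns)
    v[ok] <- pos[lin]
    nbr[, t] <- v
  }
  degree <- rowSums(nbr > 0L)
  is_node <- degree != 2L

  # merge adjacent junction voxels (degree >= 3) into nodes
  cluster <- integer(ns)
  jn <- which(degree >= 3L)
  ncl <- 0L
  for (v in jn) {
    if (cluster[v] != 0L) next
    ncl <- ncl + 1L
    stack <- v; cluster[v] <- ncl
    while (length(stack)) {
      cur <- stack[length(stack)]; stack <- stack[-length(stack)]
      for (nb in nbr[cur, ]) {
        if (nb > 0L && degree[nb] >= 3L && cluster[nb] == 0L) {
          cluster[nb] <- ncl
          stack <- c(stack, nb)
        }
      }
    }
  }
  ends <- which(degree == 1L | degree == 0L)
  for (v in ends) { ncl <- ncl + 1L; cluster[v] <- ncl }

  used <- logical(ns)             # chain voxels consumed
  seg_paths <- list()
  walk_chain <- function(start_node, first) {
    path <- c(start_node, first)
    used[first] <<- TRUE
    prev <- start_node; cur <- first
    while (!is_node[cur]) {
      nbs <- nbr[cur, ]
      nbs <- nbs[nbs > 0L & nbs != prev]
      # prefer unvisited continuation; a degree-2 voxel has exactly one
      nxt <- nbs[1]
      if (is.na(nxt)) break
      if (!is_node[nxt]) {
        if (used[nxt]) break
        used[nxt] <<- TRUE
      }
      path <- c(path, nxt)
      prev <- cur; cur <- nxt
      if (cur == start_node) break  # closed loop
    }
    path
  }
  for (v in which(is_node)) {
    for (nb in nbr[v, ]) {
      if (nb == 0L) next
      if (is_node[nb]) {
        # direct node-node contact: one two-voxel segment across clusters
        if (nb > v && cluster[nb] != cluster[v])
          seg_paths[[length(seg_paths) + 1L]] <- c(v, nb)
      } else if (!used[nb]) {
        seg_paths[[length(seg_paths) + 1L]] <- walk_chain(v, nb)
      }
    }
  }
  # closed loops without any node voxel
  for (v in seq_len(ns)) {
    if (is_node[v] || used[v]) next
    used[v] <- TRUE
    path <- v
    prev <- v; cur <- nbr[v, nbr[v, ] > 0L][1]
    while (!is.na(cur) && cur != v && !used[cur]) {
      used[cur] <- TRUE
      path <- c(path, cur)
      nbs <- nbr[cur, ]; nbs <- nbs[nbs > 0L & nbs != prev]
      prev <- cur; cur <- nbs[1]
    }
    seg_paths[[length(seg_paths) + 1L]] <- c(path, path[1])
  }

  if (!length(seg_paths)) {
    empty$skeleton <- skel
    empty$n_nodes <- ncl
    return(empty)
  }

  dtv <- sqrt(dt2)
  seeds <- array(0L, dm)
  polylines <- vector("list", length(seg_paths))
  rows <- vector("list", length(seg_paths))
  for (s in seq_along(seg_paths)) {
    p <- seg_paths[[s]]
    xyz <- (co[p, , drop = FALSE] - 1) * voxel_size_um
    steps <- diff(xyz)
    len <- sum(sqrt(rowSums(steps^2)))
    cord <- sqrt(sum((xyz[nrow(xyz), ] - xyz[1, ])^2))
    ang <- segment_angles(xyz[nrow(xyz), ] - xyz[1, ])
    sel <- idx[p]
    unclaimed <- seeds[sel] == 0L
    seeds[sel[unclaimed]] <- s
    polylines[[s]] <- xyz
    rows[[s]] <- data.frame(
      id = s, n_voxels = length(p), length_um = len, cord_length_um = cord,
      mean_thickness_um = 2 * mean(dtv[sel]) * voxel_size_um,
      volume_um3 = NA_real_, phi_deg = ang[["phi_deg"]],
      theta_deg = ang[["theta_deg"]])
  }
  segments <- do.call(rbind, rows)

  if (prune && nrow(segments) > 1) {
    # spur = segment with a free end (endpoint voxel shared with no other
    # segment) shorter than its own mean thickness
    endpoints <- unlist(lapply(seg_paths, function(p) c(p[1], p[length(p)])))
    shared <- table(endpoints)
    free_end <- vapply(seg_paths, function(p)
      shared[as.character(p[1])] == 1L ||
        shared[as.character(p[length(p)])] == 1L, TRUE)
    spur <- free_end & segments$length_um < segments$mean_thickness_um
    if (any(spur) && !all(spur)) {
      keep <- which(!spur)
      seg_paths <- seg_paths[keep]
      polylines <- polylines[keep]
      segments <- segments[keep, , drop = FALSE]
      segments$id <- seq_len(nrow(segments))
      seeds <- array(0L, dm)
      for (s in seq_along(seg_paths)) {
        sel <- idx[seg_paths[[s]]]
        unclaimed <- seeds[sel] == 0L
        seeds[sel[unclaimed]] <- s
      }
    }
  }

  seg_lab <- propagate_labels_cpp(as.logical(vessel), as.integer(seeds), dm)
  volumes <- tabulate(seg_lab[seg_lab > 0L], nbins = nrow(segments)) *
    voxel_size_um^3
  segments$volume_um3 <- volumes
  rownames(segments) <- NULL

  structure(list(segments = segments, polylines = polylines, n_nodes = ncl,
                 skeleton = skel, voxel_size_um = voxel_size_um),
            class = "skeleton_graph")
}

#' @export
print.skeleton_graph <- function(x, ...) {
  cat(sprintf("<skeleton_graph> %d segments, %d nodes, total length %.0f um\n",
              nrow(x$segments), x$n_nodes, sum(x$segments$length_um)))
  invisible(x)
}

#' Orientation angles of a branch segment
#'
#' The segment direction is the (undirected) endpoint difference vector.
#' `phi` is the angle to the bone's long axis (`z`): 0 deg means parallel to
#' the long axis. `theta` is the projected angle to the `x` axis in the x-y
#' plane: 0 deg means parallel to the bone surface. Both are folded into
#' \[0, 90\] deg. A segment parallel to `z` has no x-y projection and gets
#' `theta = NA` (excluded from histograms), as does a zero-length segment.
#'
#' @param direction numeric length-3 vector (endpoint difference) or a
#'   polyline matrix whose first/last rows are used.
#' @return named vector `c(phi_deg, theta_deg)`.
#' @examples
#' segment_angles(c(0, 0, 1))   # phi 0, theta NA
#' segment_angles(c(1, 1, 0))   # phi 90, theta 45
#' @export
segment_angles <- function(direction) {
  if (is.matrix(direction))
    direction <- direction[nrow(direction), ] - direction[1, ]
  d <- abs(as.numeric(direction))
  nrm <- sqrt(sum(d^2))
  if (nrm == 0)
    return(c(phi_deg = NA_real_, theta_deg = NA_real_))
  phi <- acos(min(1, d[3] / nrm)) * 180 / pi
  theta <- if (d[1] == 0 && d[2] == 0) NA_real_
           else atan2(d[2], d[1]) * 180 / pi
  c(phi_deg = phi, theta_deg = theta)
}

#' Weighted orientation histograms and the level of alignment (LOA)
#'
#' Bins the segment angles phi and theta over \[0, 90\] deg, weighting each
#' segment by its length, volume or count. The amplitude vector of each
#' histogram is normalized to sum 1; `s_phi` and `s_theta` are the
#' population variances of the two amplitude vectors and
#' `LOA = s_phi * s_theta`. Highly aligned networks concentrate weight in
#' few bins and give a large LOA; uniformly filled histograms give LOA near
#' zero.
#'
#' @param segments a `skeleton_graph` or its `segments` data frame (columns
#'   `phi_deg`, `theta_deg`, `length_um`, `volume_um3`).
#' @param weighting `"length"`, `"volume"` or `"count"`.
#' @param n_bins number of bins over \[0, 90\] deg (>= 2); default 36
#'   (2.5 deg per bin).
#' @return an object of class `orientation_summary` with `hist_phi`,
#'   `hist_theta`, `s_phi`, `s_theta`, `LOA`, `weighting`, `n_bins`.
#' @export
orientation_histogram <- function(segments,
                                  weighting = c("length", "volume", "count"),
                                  n_bins = 36L) {
  weighting <- match.arg(weighting)
  if (inherits(segments, "skeleton_graph")) segments <- segments$segments
  if (n_bins < 2L) stop("`n_bins` must be at least 2", call. = FALSE)
  valid <- !is.na(segments$phi_deg)
  if (!any(valid)) stop("no valid segments (all zero length)", call. = FALSE)
  w_all <- switch(weighting,
                  length = segments$length_um,
                  volume = segments$volume_um3,
                  count = rep(1, nrow(segments)))
  bin_amplitudes <- function(ang, w) {
    keep <- !is.na(ang) & !is.na(w) & w > 0
    if (!any(keep)) stop("no weighted segments to bin", call. = FALSE)
    b <- pmin(n_bins, floor(ang[keep] / (90 / n_bins)) + 1L)
    a <- vapply(seq_len(n_bins), function(i) sum(w[keep][b == i]), 0)
    a / sum(a)
  }
  hist_phi <- bin_amplitudes(segments$phi_deg, w_all)
  hist_theta <- bin_amplitudes(segments$theta_deg, w_all)
  pop_var <- function(a) mean((a - mean(a))^2)
  s_phi <- pop_var(hist_phi)
  s_theta <- pop_var(hist_theta)
  structure(list(hist_phi = hist_phi, hist_theta = hist_theta,
                 s_phi = s_phi, s_theta = s_theta, LOA = s_phi * s_theta,
                 weighting = weighting, n_bins = as.integer(n_bins)),
            class = "orientation_summary")
}

#' @export
print.orientation_summary <- function(x, ...) {
  cat(sprintf("<orientation_summary> %s-weighted, %d bins: s_phi %.3g, s_theta %.3g, LOA %.3g\n",
              x$weighting, x$n_bins, x$s_phi, x$s_theta, x$LOA))
  invisible(x)
}

#' Ratio of donor-site to recipient-site level of alignment
#'
#' @param summary_fb,summary_ab [orientation_histogram()] results (or bare
#'   LOA numbers) for the fibula (donor) and alveolar (recipient) samples of
#'   one patient.
#' @return `LOA_fb / LOA_ab`.
#' @examples
#' loa_ratio(0.70e-5, 5.32e-5)  # 0.13
#' @export
loa_ratio <- function(summary_fb, summary_ab) {
  fb <- if (inherits(summary_fb, "orientation_summary")) summary_fb$LOA
        else as.numeric(summary_fb)
  ab <- if (inherits(summary_ab, "orientation_summary")) summary_ab$LOA
        else as.numeric(summary_ab)
  if (ab <= 0) stop("reference (AB) LOA must be positive", call. = FALSE)
  fb / ab
}
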