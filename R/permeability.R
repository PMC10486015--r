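#' Check whether a pore space percolates along an axis
#'
#' A pore space percolates along a direction when one 6-connected pore
#' component touches both opposing faces.
#'
#' @param pore logical pore mask.
#' @param direction 1, 2 or 3 (x, y, z).
#' @return logical scalar.
#' @export
percolates <- function(pore, direction) {
  stopifnot_mask(pore)
  if (!any(pore)) return(FALSE)
  lab <- label_components(pore, 6L)
  dm <- dim(lab)
  lo <- switch(direction, lab[1, , ], lab[, 1, ], lab[, , 1])
  hi <- switch(direction, lab[dm[1], , ], lab[, dm[2], ], lab[, , dm[3]])
  any(intersect(lo[lo > 0L], hi[hi > 0L]) > 0L)
}

#' Max-pooling downsample of a pore mask
#'
#' Blocks of `factor^3` voxels collapse to one voxel that is pore if any
#' constituent voxel is pore; this preserves percolation paths while
#' reducing the solve grid.
#'
#' @param pore logical mask.
#' @param factor integer block size (>= 1).
#' @return logical mask of the pooled shape.
#' @export
downsample_pore <- function(pore, factor) {
  stopifnot_mask(pore)
  factor <- as.integer(factor)
  if (factor <= 1L) return(pore)
  dm <- dim(pore)
  nd <- dm %/% factor
  if (any(nd < 2L)) stop("downsampling factor too large", call. = FALSE)
  cropped <- pore[seq_len(nd[1] * factor), seq_len(nd[2] * factor),
                  seq_len(nd[3] * factor), drop = FALSE]
  a <- array(cropped, c(factor, nd[1], factor, nd[2], factor, nd[3]))
  out <- apply(a, c(2, 4, 6), any)
  array(out, nd)
}

#' Solve creeping flow through a pore geometry in one direction
#'
#' Steady incompressible viscous flow driven by a uniform body force (the
#' macroscopic pressure gradient) along the requested axis, with no-slip on
#' pore walls and periodic boundaries on all faces, solved with a
#' single-relaxation (BGK) D3Q19 lattice-Boltzmann scheme. The iteration
#' stops when the relative change of the mean velocity drops below
#' `tolerance` or after `max_iter` iterations. The permeability column is
#' `K_j = nu * <u_j> / g` with the superficial (whole-domain) mean velocity,
#' converted to um^2; `K_intrinsic` uses the pore-averaged velocity instead
#' (closed-form channel/tube values refer to that convention when the
#' averaging volume excludes the walls).
#'
#' @param pore logical pore mask (TRUE = fluid).
#' @param direction `"x"`, `"y"` or `"z"`.
#' @param voxel_size_um voxel edge length (um).
#' @param tolerance convergence criterion on the relative mean-velocity
#'   change.
#' @param max_iter iteration cap.
#' @param tau BGK relaxation time; the default 0.933 minimizes the
#'   bounce-back slip error for channel-like geometries.
#' @param force lattice body-force magnitude (small, keeps the flow in the
#'   Stokes regime).
#' @return list with `K_col_um2` (length-3 permeability column),
#'   `K_intrinsic_um2`, `mean_u` (lattice), `porosity`, `converged`,
#'   `iterations`, `residual`, `percolating`.
#' @export
solve_flow <- function(pore, direction = c("x", "y", "z"), voxel_size_um = 1,
                       tolerance = 1e-5, max_iter = 1e6, tau = 0.9330127,
                       force = 1e-6) {
  stopifnot_mask(pore)
  direction <- match.arg(direction)
  ax <- match(direction, c("x", "y", "z"))
  if (!any(pore) || !percolates(pore, ax)) {
    return(list(K_col_um2 = c(0, 0, 0), K_intrinsic_um2 = c(0, 0, 0),
                mean_u = c(0, 0, 0), porosity = mean(pore),
                converged = TRUE, iterations = 0, residual = 0,
                percolating = FALSE))
  }
  g <- c(0, 0, 0)
  g[ax] <- force
  res <- lbm_flow_cpp(as.logical(pore), dim(pore), g, tau, tolerance,
                      max_iter, 50L)
  if (!res$converged && res$iterations >= max_iter)
    warning(sprintf("flow solve stopped at max_iter = %g (residual %.3g)",
                    max_iter, res$residual), call. = FALSE)
  scale <- res$nu / force * voxel_size_um^2
  list(K_col_um2 = as.numeric(res$mean_u) * scale,
       K_intrinsic_um2 = as.numeric(res$mean_u_pore) * scale,
       mean_u = as.numeric(res$mean_u),
       porosity = res$porosity, converged = res$converged,
       iterations = res$iterations, residual = res$residual,
       percolating = TRUE)
}

#' Absolute permeability tensor of a pore space
#'
#' Assembles the 3x3 permeability tensor from three directional creeping-flow
#' solves (force along x, y, z), symmetrizes it as `(K + K') / 2`, and
#' eigen-decomposes it with descending eigenvalues `E1 >= E2 >= E3`.
#' Negative eigenvalues below the numerical floor are clamped to zero with a
#' warning. Geometry larger than `max_dim` voxels per axis is max-pooled
#' first (percolation-preserving).
#'
#' @param pore logical pore mask.
#' @param voxel_size_um voxel edge length (um).
#' @param max_dim largest allowed grid extent for the solve.
#' @param ... passed to [solve_flow()].
#' @return an object of class `permeability_result`: `K_um2`, `eigenvalues`,
#'   `eigenvectors`, `ratio_EV_mean`, `invert`, per-direction convergence
#'   metadata, `percolating` flags.
#' @export
permeability_tensor <- function(pore, voxel_size_um = 1, max_dim = 128L, ...) {
  stopifnot_mask(pore)
  factor <- ceiling(max(dim(pore)) / max_dim)
  if (factor > 1L) {
    pore <- downsample_pore(pore, factor)
    voxel_size_um <- voxel_size_um * factor
  }
  solves <- lapply(c("x", "y", "z"), function(d)
    solve_flow(pore, d, voxel_size_um, ...))
  K <- do.call(cbind, lapply(solves, `[[`, "K_col_um2"))
  Ksym <- (K + t(K)) / 2
  ev <- eigen(Ksym, symmetric = TRUE)
  lam <- ev$values
  floor_val <- 1e-10 * max(abs(lam), 1e-300)
  if (any(lam < -floor_val))
    warning("negative permeability eigenvalue(s) clamped to zero",
            call. = FALSE)
  lam <- pmax(lam, 0)
  res <- structure(list(
    K_um2 = Ksym, K_raw_um2 = K,
    eigenvalues = lam, eigenvectors = ev$vectors,
    percolating = vapply(solves, `[[`, TRUE, "percolating"),
    converged = vapply(solves, `[[`, TRUE, "converged"),
    iterations = vapply(solves, `[[`, 0, "iterations"),
    residual = vapply(solves, `[[`, 0, "residual"),
    voxel_size_um = voxel_size_um), class = "permeability_result")
  an <- anisotropy_summary(res)
  res$ratio_EV_mean <- an$ratio_EV_mean
  res$invert <- an$invert
  res
}

#' Eigenvalue anisotropy summary of a permeability tensor
#'
#' `ratio_EV_mean = ((E2/E1) + (E3/E1)) / 2` summarizes how strongly
#' permeability concentrates along the principal direction; its inverse
#' (`invert`) reads as "flow along the main direction is `invert` times more
#' pronounced than in the orthogonal directions".
#'
#' @param result a `permeability_result`, or a numeric vector of
#'   eigenvalues.
#' @return list with `ratio_EV_mean` and `invert` (both `NA` when `E1 = 0`,
#'   flagged `undefined`).
#' @examples
#' anisotropy_summary(c(4, 2, 1))  # ratio 0.375, invert 2.667
#' @export
anisotropy_summary <- function(result) {
  lam <- if (inherits(result, "permeability_result")) result$eigenvalues
         else sort(as.numeric(result), decreasing = TRUE)
  if (lam[1] <= 0)
    return(list(ratio_EV_mean = NA_real_, invert = NA_real_,
                undefined = TRUE))
  ratio <- (lam[2] / lam[1] + lam[3] / lam[1]) / 2
  list(ratio_EV_mean = ratio, invert = 1 / ratio, undefined = FALSE)
}

#' @export
print.permeability_result <- function(x, ...) {
  cat(sprintf("<permeability_result> @ %g um\n", x$voxel_size_um))
  cat("  K (um^2):\n")
  print(signif(x$K_um2, 4))
  cat(sprintf("  eigenvalues: %s um^2\n",
              paste(signif(x$eigenvalues, 4), collapse = ", ")))
  cat(sprintf("  EV-mean ratio %.4f (invert %.2f); percolating: %s; converged: %s\n",
              x$ratio_EV_mean, x$invert,
              paste(x$percolating, collapse = "/"),
              paste(x$converged, collapse = "/")))
  invisible(x)
}
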