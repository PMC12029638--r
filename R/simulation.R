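#' Coupled fluid-membrane simulation state
#'
#' Bundles an LBM fluid state with a list of membrane meshes and their
#' material parameters. Each coupled step performs one immersed-boundary
#' cycle: membrane forces -> spreading -> LBGK collide/stream with
#' bounce-back -> velocity interpolation -> node advection.
#'
#' Mesh coordinates are kept continuous (unwrapped); periodic wrapping is
#' applied inside the transfer kernels, so membranes may straddle the
#' periodic boundary without tearing.
#'
#' @param fluid an `lbm_state` from [create_fluid()].
#' @param meshes list of [tri_mesh()] (possibly empty).
#' @param params list of [membrane_params()] in lattice units, one per mesh.
#' @param periodic logical length-3; periodic axes for the transfer kernels
#'   (walls are already encoded in the fluid's solid mask).
#' @param bending_form `"tan"` or `"quadratic"`, see [bending_energy()].
#' @param repulsion `NULL` (default: interactions are purely
#'   fluid-mediated), or `list(strength =, gap =)` enabling a short-range
#'   pairwise centroid repulsion that guards against numerical overlap of
#'   membranes: when two particles' surface gap falls below `gap` lattice
#'   units, equal-and-opposite forces of magnitude
#'   `strength * (1 - gap_actual/gap)` are shared uniformly over each
#'   mesh's nodes (momentum-conserving; minimum-image in periodic axes).
#' @param substeps per-mesh membrane force sub-iterations per fluid step
#'   (default 1 = plain explicit coupling). Values > 1 enable the
#'   stiff-membrane scheme: within each fluid step the membrane is relaxed
#'   internally `substeps` times (overdamped, see `mobility`) and the fluid
#'   receives the sub-iteration-averaged force. This raises the stable
#'   stiffness ceiling at the cost of numerical membrane dissipation.
#' @param mobility per-mesh overdamped node mobility (lattice displacement
#'   per unit nodal force per sub-iteration) used when `substeps > 1`.
#'   Stability requires `mobility` times the stiffest nodal spring constant
#'   to stay below ~1; a practical choice is `0.5/(ks + kalpha + kA + kV)`.
#' @return environment of class `ib_lbm_sim`.
#' @export
simulation <- function(fluid, meshes = list(), params = list(),
                       periodic = c(TRUE, TRUE, TRUE),
                       bending_form = "tan", repulsion = NULL,
                       substeps = 1, mobility = 0) {
  stopifnot(inherits(fluid, "lbm_state"), length(meshes) == length(params))
  sim <- new.env(parent = emptyenv())
  sim$fluid <- fluid
  sim$meshes <- meshes
  sim$params <- params
  sim$periodic <- periodic
  sim$bending_form <- bending_form
  sim$repulsion <- repulsion
  sim$substeps <- rep_len(as.integer(substeps), max(1L, length(meshes)))
  sim$mobility <- rep_len(as.numeric(mobility), max(1L, length(meshes)))
  sim$radii <- vapply(meshes, function(m) {
    cen <- colMeans(m$vertices)
    max(sqrt(rowSums(sweep(m$vertices, 2, cen)^2)))
  }, numeric(1))
  sim$t <- 0L
  sim$last_energy <- NULL
  class(sim) <- "ib_lbm_sim"
  sim
}

# pairwise anti-overlap forces; returns list of per-mesh n x 3 matrices
# (or NULL when no pair is within range)
.repulsion_forces <- function(sim) {
  rp <- sim$repulsion
  np <- length(sim$meshes)
  if (is.null(rp) || np < 2) return(NULL)
  dims <- sim$fluid$dims
  cen <- t(vapply(sim$meshes, function(m) colMeans(m$vertices), numeric(3)))
  out <- NULL
  for (i in seq_len(np - 1)) for (j in (i + 1):np) {
    dv <- cen[i, ] - cen[j, ]
    for (d in which(sim$periodic)) {            # minimum image
      dv[d] <- dv[d] - dims[d] * round(dv[d] / dims[d])
    }
    dist <- sqrt(sum(dv^2))
    gap <- dist - sim$radii[i] - sim$radii[j]
    if (gap < rp$gap) {
      if (is.null(out)) out <- vector("list", np)
      mag <- rp$strength * (1 - max(gap, 0) / rp$gap)
      dir <- if (dist > 0) dv / dist else c(1, 0, 0)
      fi <- matrix(mag * dir / nrow(sim$meshes[[i]]$vertices),
                   nrow(sim$meshes[[i]]$vertices), 3, byrow = TRUE)
      fj <- matrix(-mag * dir / nrow(sim$meshes[[j]]$vertices),
                   nrow(sim$meshes[[j]]$vertices), 3, byrow = TRUE)
      out[[i]] <- if (is.null(out[[i]])) fi else out[[i]] + fi
      out[[j]] <- if (is.null(out[[j]])) fj else out[[j]] + fj
    }
  }
  out
}

#' @export
print.ib_lbm_sim <- function(x, ...) {
  cat(sprintf("<ib_lbm_sim> t = %d, %d particle(s)\n", x$t, length(x$meshes)))
  print(x$fluid)
  invisible(x)
}

#' Advance the coupled simulation
#'
#' `coupled_step()` performs `steps` immersed-boundary/LBM cycles. With no
#' particles it reduces exactly to [lbm_step()]. Divergence of either the
#' fluid or a membrane raises an error naming the step.
#'
#' @param sim an `ib_lbm_sim` (modified in place).
#' @param steps number of steps to advance.
#' @return the simulation, invisibly.
#' @export
coupled_step <- function(sim, steps = 1) {
  fl <- sim$fluid
  d <- fl$dims
  per <- as.integer(sim$periodic)
  np <- length(sim$meshes)
  for (k in seq_len(steps)) {
    if (np > 0) {
      fl$Fx[] <- 0; fl$Fy[] <- 0; fl$Fz[] <- 0
      energies <- vector("list", np)
      rep_f <- .repulsion_forces(sim)
      for (p in seq_len(np)) {
        M <- sim$substeps[p]
        if (M <= 1L) {
          mf <- membrane_forces(sim$meshes[[p]], sim$params[[p]],
                                sim$bending_form)
          frc <- mf$forces
        } else {
          # stiff-membrane sub-iteration: relax the nodes internally
          # (overdamped, mobility mu per sub-iteration) and hand the fluid
          # the sub-iteration-averaged force. The internal relaxation acts
          # as membrane dissipation of the stiff modes the explicit
          # coupling cannot follow.
          mu <- sim$mobility[p]
          frc <- 0
          for (m in seq_len(M)) {
            mf <- membrane_forces(sim$meshes[[p]], sim$params[[p]],
                                  sim$bending_form)
            frc <- frc + mf$forces / M
            sim$meshes[[p]]$vertices <- sim$meshes[[p]]$vertices +
              mu * mf$forces
          }
        }
        energies[[p]] <- mf[c("E_S", "E_B", "E_A", "E_V", "area", "volume")]
        if (!is.null(rep_f) && !is.null(rep_f[[p]])) frc <- frc + rep_f[[p]]
        cpp_spread(sim$meshes[[p]]$vertices, frc,
                   fl$Fx, fl$Fy, fl$Fz, d[1], d[2], d[3],
                   per[1], per[2], per[3])
      }
      sim$last_energy <- energies
    }
    lbm_step(fl, 1, check_every = 200)
    if (np > 0) {
      for (p in seq_len(np)) {
        un <- cpp_interp(fl$ux, fl$uy, fl$uz, sim$meshes[[p]]$vertices,
                         d[1], d[2], d[3], per[1], per[2], per[3])
        sim$meshes[[p]]$vertices <- sim$meshes[[p]]$vertices + un
      }
    }
    sim$t <- sim$t + 1L
  }
  invisible(sim)
}

#' Run a coupled simulation with periodic diagnostics recording
#'
#' Advances the simulation, recording per-particle diagnostics every
#' `record_every` steps: radial distance `d` from the vessel centreline
#' (when a vessel is given), normalised Taylor deformation `D`, maximum
#' nodal force magnitude, centroid velocity, and the fluid pressure
#' `cs^2 rho` interpolated at the centroid.
#'
#' @param sim an `ib_lbm_sim`.
#' @param steps total steps to advance.
#' @param record_every recording interval (0 disables recording).
#' @param vessel optional [straight_vessel()]/[curved_vessel()] used for
#'   the distance diagnostic.
#' @param shear_plane length-2 axis pair for the Taylor parameter
#'   (default x-y plane, `c(1, 2)`).
#' @return data frame of the recorded time series (one row per particle and
#'   recording time), invisibly attached to the simulation as `sim$record`.
#' @export
run_simulation <- function(sim, steps, record_every = 100, vessel = NULL,
                           shear_plane = c(1, 2)) {
  rows <- list()
  a0b0 <- lapply(sim$meshes, function(m) {
    ab <- .gyration_radii(m$vertices, shear_plane)
    list(a0 = ab[1], b0 = ab[2])
  })
  nrec <- 0L
  record <- function() {
    fl <- sim$fluid
    for (p in seq_along(sim$meshes)) {
      m <- sim$meshes[[p]]
      cen <- colMeans(m$vertices)
      ab <- .gyration_radii(m$vertices, shear_plane)
      pr <- cpp_interp(fl$rho, fl$rho, fl$rho, matrix(cen %% fl$dims, 1, 3),
                       fl$dims[1], fl$dims[2], fl$dims[3], 1L, 1L, 1L)[1, 1] / 3
      uc <- cpp_interp(fl$ux, fl$uy, fl$uz, matrix(cen %% fl$dims, 1, 3),
                       fl$dims[1], fl$dims[2], fl$dims[3], 1L, 1L, 1L)
      mf <- membrane_forces(m, sim$params[[p]], sim$bending_form)
      maxF <- max(sqrt(rowSums(mf$forces^2)))
      rows[[length(rows) + 1L]] <<- data.frame(
        t = sim$t, particle = p,
        d = if (!is.null(vessel)) distance_d(m, vessel) else NA_real_,
        D = taylor_parameter_normalized(ab[1], ab[2],
                                        a0b0[[p]]$a0, a0b0[[p]]$b0),
        max_force = maxF,
        u_centroid = sqrt(sum(uc^2)),
        pressure = pr)
    }
    nrec <<- nrec + 1L
  }
  if (record_every > 0) record()
  remaining <- steps
  while (remaining > 0) {
    chunk <- if (record_every > 0) min(record_every, remaining) else remaining
    coupled_step(sim, chunk)
    remaining <- remaining - chunk
    if (record_every > 0) record()
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(t = integer(), particle = integer(), d = numeric(),
               D = numeric(), max_force = numeric(), u_centroid = numeric(),
               pressure = numeric())
  sim$record <- out
  invisible(out)
}
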