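# Analytic forward model: potential of a current dipole inside a homogeneous
# conducting sphere, evaluated at surface electrodes, average referenced.
#
# For a monopole current source at b inside an insulated sphere of radius a
# and conductivity sigma, the surface potential admits the closed form
#   K(b) = (1/4*pi*sigma) * [ 2/d + (1/a) log( 2a / (a - (b.r)/a + d) ) ],
# with d = |r - b| (sum of the Legendre series (2n+1)/n (b/a)^n P_n). The
# dipole potential is the directional derivative q . grad_b K(b):
#   V(r) = (1/4*pi*sigma) * [ 2 (q.dv)/d^3
#            + ( (q.r)/a^2 + (q.dv)/(a d) ) / ( a - (r.b)/a + d ) ].
# With positions in mm, conductivity in S/m and |q| = 1, V comes out directly
# in microvolts per picoampere-meter (the 1e-12 A.m moment and the 1e6 V->uV
# factor cancel the mm^2 -> m^2 conversion).

#' Potential of current dipoles in a homogeneous sphere
#'
#' Closed-form surface potential of dipoles at `positions` with moments
#' `moments` (pA*m), evaluated at `electrodes` on the sphere surface.
#' Not average-referenced; the reference is the sphere's "infinity"
#' convention of the analytic solution.
#'
#' @param positions n_src x 3 dipole positions (mm), strictly inside sphere
#' @param moments n_src x 3 dipole moment vectors (pA*m)
#' @param electrodes n_ch x 3 electrode positions on the sphere surface (mm)
#' @param sphere a [sphere_model()]
#' @return n_ch x n_src potential matrix, microvolts
#' @export
dipole_potential <- function(positions, moments, electrodes, sphere) {
  positions <- rbind(positions)
  moments <- rbind(moments)
  electrodes <- rbind(electrodes)
  a <- sphere$scalp_radius
  ctr <- sphere$center
  positions <- sweep(positions, 2, ctr)
  electrodes <- sweep(electrodes, 2, ctr)
  src_r <- sqrt(rowSums(positions^2))
  if (any(src_r >= a - 1e-9)) {
    stop_param("dipole position on or outside the scalp sphere (max radius %.3f of %.3f)",
               max(src_r), a)
  }
  k <- 1 / (4 * pi * sphere$conductivity)
  n_ch <- nrow(electrodes)
  n_src <- nrow(positions)
  out <- matrix(0, n_ch, n_src)
  for (j in seq_len(n_src)) {
    b <- positions[j, ]
    q <- moments[j, ]
    dv <- sweep(electrodes, 2, b) # n_ch x 3
    d <- sqrt(rowSums(dv^2))
    q_dv <- dv %*% q
    q_r <- electrodes %*% q
    f <- a - (electrodes %*% b) / a + d
    out[, j] <- k * (2 * q_dv / d^3 + (q_r / a^2 + q_dv / (a * d)) / f)
  }
  out
}

#' Compute the lead field for a mesh, montage and sphere model
#'
#' One fixed-orientation source per mesh vertex, oriented along the outward
#' vertex normal with unit moment (1 pA*m). Columns are average-referenced,
#' so every source's electrode potentials sum to zero.
#'
#' @param mesh a [build_toy_mesh()] mesh strictly inside the sphere
#' @param montage a [place_electrodes()] montage on the sphere surface
#' @param sphere a [sphere_model()]
#' @return A `lead_field` with `gain` (n_channels x n_sources, uV per pA*m),
#'   plus the `mesh`, `montage` and `sphere` used.
#' @export
compute_lead_field <- function(mesh, montage, sphere = sphere_model()) {
  vr <- sqrt(rowSums(sweep(mesh$vertices, 2, sphere$center)^2))
  if (any(vr >= sphere$scalp_radius - 1e-9)) {
    stop_param("mesh vertices must lie strictly inside the scalp sphere")
  }
  er <- sqrt(rowSums(sweep(montage$positions, 2, sphere$center)^2))
  if (any(abs(er - sphere$scalp_radius) > 1e-6)) {
    stop_param("electrodes must lie on the scalp sphere surface")
  }
  gain <- dipole_potential(mesh$vertices, mesh$normals, montage$positions,
                           sphere)
  gain <- sweep(gain, 2, colMeans(gain)) # average reference
  structure(
    list(gain = gain, mesh = mesh, montage = montage, sphere = sphere,
         units = "uV per pA*m", reference = "average",
         orientation = "fixed-normal"),
    class = "lead_field"
  )
}

#' @export
print.lead_field <- function(x, ...) {
  cat(sprintf(
    "lead_field: %d channels x %d sources (%s, %s reference)\n",
    nrow(x$gain), ncol(x$gain), x$units, x$reference
  ))
  invisible(x)
}
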