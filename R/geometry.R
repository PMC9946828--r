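#' Discretization of the 6D inter-residue geometry space
#'
#' Defines the bins shared by family restraints, predictor outputs and losses.
#' The default mirrors the common distogram discretization: 36 distance bins of
#' 0.5 A over \[2, 20) A plus one no-contact bin; omega and theta dihedrals in
#' 24 bins of 15 deg over (-180, 180\]; the planar angle phi in 12 bins of
#' 15 deg over \[0, 180\]. Every angular channel carries a paired no-contact
#' bin mirroring the distance channel, so that pairs beyond the contact cutoff
#' have a well-defined categorical state in all channels.
#'
#' @param d_edges ascending distance bin edges in Angstrom; the last edge is
#'   the no-contact cutoff.
#' @param omega_edges,theta_edges dihedral bin edges in degrees covering
#'   (-180, 180\].
#' @param phi_edges planar-angle bin edges in degrees covering \[0, 180\].
#' @return an object of class `bin_spec` with per-channel edges and bin counts
#'   (each count includes the trailing no-contact bin).
#' @export
bin_spec <- function(d_edges = seq(2, 20, by = 0.5),
                     omega_edges = seq(-180, 180, by = 15),
                     theta_edges = seq(-180, 180, by = 15),
                     phi_edges = seq(0, 180, by = 15)) {
  chk <- function(e, nm) {
    if (any(!is.finite(e)) || any(diff(e) <= 0)) {
      stop(sprintf("%s edges must be finite and strictly ascending", nm), call. = FALSE)
    }
  }
  chk(d_edges, "distance"); chk(omega_edges, "omega")
  chk(theta_edges, "theta"); chk(phi_edges, "phi")
  if (abs(omega_edges[1] + 180) > 1e-9 || abs(utils::tail(omega_edges, 1) - 180) > 1e-9)
    stop("omega edges must cover (-180, 180] exactly", call. = FALSE)
  if (abs(theta_edges[1] + 180) > 1e-9 || abs(utils::tail(theta_edges, 1) - 180) > 1e-9)
    stop("theta edges must cover (-180, 180] exactly", call. = FALSE)
  if (abs(phi_edges[1]) > 1e-9 || abs(utils::tail(phi_edges, 1) - 180) > 1e-9)
    stop("phi edges must cover [0, 180] exactly", call. = FALSE)
  structure(list(
    edges = list(d = d_edges, omega = omega_edges, theta = theta_edges,
                 phi = phi_edges),
    n_bins = c(d = length(d_edges),            # (len-1) value bins + 1 no-contact
               omega = length(omega_edges),
               theta = length(theta_edges),
               phi = length(phi_edges)),
    cutoff = utils::tail(d_edges, 1)
  ), class = "bin_spec")
}

#' @export
print.bin_spec <- function(x, ...) {
  cat(sprintf("<bin_spec> d:%d omega:%d theta:%d phi:%d bins (incl. no-contact), cutoff %.1f A\n",
              x$n_bins["d"], x$n_bins["omega"], x$n_bins["theta"], x$n_bins["phi"],
              x$cutoff))
  invisible(x)
}

#' Number of bins in a channel (including the no-contact bin)
#' @param spec a `bin_spec`.
#' @param channel one of `"d"`, `"omega"`, `"theta"`, `"phi"`.
#' @return integer bin count.
#' @export
n_bins <- function(spec, channel) {
  stopifnot(inherits(spec, "bin_spec"))
  unname(spec$n_bins[match.arg(channel, c("d", "omega", "theta", "phi"))])
}

#' Map a geometry value to its bin
#'
#' Half-open `[lower, upper)` intervals; distances at or beyond the no-contact
#' cutoff map to the trailing no-contact bin. Angular channels follow the same
#' convention except that the upper seam value (+180 deg for dihedrals,
#' 180 deg for phi) belongs to the final value bin. Angular values of
#' non-contact pairs are assigned the channel's no-contact bin by the callers
#' ([geometry_onehot()], [build_profile()]), not here.
#'
#' @param value numeric vector of finite values (angles pre-wrapped to the
#'   channel's range).
#' @param channel one of `"d"`, `"omega"`, `"theta"`, `"phi"`.
#' @param spec a `bin_spec`.
#' @return integer vector of 1-based bin indices.
#' @export
bin_value <- function(value, channel, spec) {
  channel <- match.arg(channel, c("d", "omega", "theta", "phi"))
  if (any(!is.finite(value))) stop("non-finite value cannot be binned", call. = FALSE)
  e <- spec$edges[[channel]]
  k <- length(e)  # total bins including no-contact
  if (channel == "d") {
    idx <- findInterval(value, e, left.open = FALSE, rightmost.closed = FALSE)
    idx[idx == 0] <- 1L            # below the first edge clamps into bin 1
    idx[idx >= k] <- k             # at/beyond cutoff -> no-contact bin
    if (any(value >= spec$cutoff)) idx[value >= spec$cutoff] <- k
  } else {
    lo <- e[1]; hi <- e[k]
    if (any(value < lo - 1e-9 | value > hi + 1e-9)) {
      stop(sprintf("%s value outside [%g, %g]; wrap first", channel, lo, hi),
           call. = FALSE)
    }
    idx <- findInterval(value, e, left.open = FALSE, rightmost.closed = FALSE)
    idx[idx == 0] <- 1L
    idx[idx >= k] <- k - 1L        # seam value belongs to the last value bin
  }
  as.integer(idx)
}

#' No-contact bin index of a channel
#' @inheritParams n_bins
#' @return integer index of the trailing no-contact bin.
#' @export
no_contact_bin <- function(spec, channel) n_bins(spec, channel)

#' Compute the 6D inter-residue geometry of a backbone
#'
#' For every residue pair: d = Cb_i-Cb_j distance; omega = dihedral
#' (CA_i, CB_i, CB_j, CA_j); theta (directional) = dihedral
#' (N_i, CA_i, CB_i, CB_j); phi (directional) = planar angle
#' (CA_i, CB_i, CB_j). Dihedrals are reported in (-180, 180\], phi in
#' \[0, 180\]. Angular values are defined only where the pair is in contact
#' (d below the no-contact cutoff); elsewhere they are `NA` and the contact
#' mask is `FALSE`.
#'
#' @param x a `backbone` whose residues all carry CB (see [reconstruct_cb()]).
#' @param spec a `bin_spec` providing the contact cutoff.
#' @return an object of class `geometry_map`: list with `length`, symmetric
#'   matrices `d` and `omega`, directional matrices `theta` and `phi` (entry
#'   `[i, j]` is the i->j value), and logical `contact`.
#' @export
compute_geometry <- function(x, spec = bin_spec()) {
  stopifnot(inherits(x, "backbone"))
  if (anyNA(x$coords$CB)) {
    stop("structure lacks CB coordinates; run reconstruct_cb() first", call. = FALSE)
  }
  n <- length(x$resid)
  CB <- x$coords$CB; CA <- x$coords$CA; N <- x$coords$N
  d2 <- outer(rowSums(CB^2), rowSums(CB^2), "+") - 2 * tcrossprod(CB)
  d2[d2 < 0] <- 0
  d <- sqrt(d2)
  diag(d) <- 0
  omega <- matrix(NA_real_, n, n)
  theta <- matrix(NA_real_, n, n)
  phi <- matrix(NA_real_, n, n)
  contact <- d < spec$cutoff
  diag(contact) <- FALSE
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j || !contact[i, j]) next
      if (j > i) {
        omega[i, j] <- wrap_dihedral(dihedral_angle(CA[i, ], CB[i, ], CB[j, ], CA[j, ]))
        omega[j, i] <- omega[i, j]
      }
      theta[i, j] <- wrap_dihedral(dihedral_angle(N[i, ], CA[i, ], CB[i, ], CB[j, ]))
      phi[i, j] <- planar_angle(CA[i, ], CB[i, ], CB[j, ])
    }
  }
  structure(list(length = n, d = d, omega = omega, theta = theta, phi = phi,
                 contact = contact, cutoff = spec$cutoff),
            class = "geometry_map")
}

#' @export
print.geometry_map <- function(x, ...) {
  cat(sprintf("<geometry_map> %d residues, %d contact pairs (cutoff %.1f A)\n",
              x$length, sum(x$contact) / 2, x$cutoff))
  invisible(x)
}

# per-channel value of an ordered pair, already wrapped
gmap_value <- function(gmap, channel, i, j) {
  switch(channel,
         d = gmap$d[i, j],
         omega = gmap$omega[i, j],
         theta = gmap$theta[i, j],
         phi = gmap$phi[i, j])
}

#' Observed bin of an ordered residue pair in each channel
#'
#' Returns the bin index per channel for pair (i, j); non-contact pairs map to
#' the no-contact bin in every channel.
#'
#' @param gmap a `geometry_map`.
#' @param i,j residue indices (1-based), `i != j`.
#' @param spec a `bin_spec`.
#' @return named integer vector with entries `d`, `omega`, `theta`, `phi`
#'   (`theta`/`phi` are the i->j direction).
#' @export
observed_bins <- function(gmap, i, j, spec) {
  if (!gmap$contact[i, j]) {
    return(c(d = no_contact_bin(spec, "d"), omega = no_contact_bin(spec, "omega"),
             theta = no_contact_bin(spec, "theta"), phi = no_contact_bin(spec, "phi")))
  }
  c(d = bin_value(gmap$d[i, j], "d", spec),
    omega = bin_value(gmap$omega[i, j], "omega", spec),
    theta = bin_value(gmap$theta[i, j], "theta", spec),
    phi = bin_value(gmap$phi[i, j], "phi", spec))
}

#' One-hot categorical encoding of a geometry map
#'
#' For every ordered pair (i, j), i != j, each channel holds a distribution
#' with unit mass at the observed bin (the no-contact bin for non-contact
#' pairs).
#'
#' @param gmap a `geometry_map`.
#' @param spec a `bin_spec`.
#' @return a `predicted_geometry` object (see [predicted_geometry()]) whose
#'   distributions are exact one-hots.
#' @export
geometry_onehot <- function(gmap, spec) {
  n <- gmap$length
  arr <- list(
    d = array(0, c(n, n, n_bins(spec, "d"))),
    omega = array(0, c(n, n, n_bins(spec, "omega"))),
    theta = array(0, c(n, n, n_bins(spec, "theta"))),
    phi = array(0, c(n, n, n_bins(spec, "phi")))
  )
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      b <- observed_bins(gmap, i, j, spec)
      for (ch in names(arr)) arr[[ch]][i, j, b[[ch]]] <- 1
    }
  }
  predicted_geometry(n, arr$d, arr$omega, arr$theta, arr$phi, spec)
}

#' Tabulate a geometry map for inspection
#'
#' @param gmap a `geometry_map`.
#' @return data frame with one row per unordered pair i < j and columns
#'   `i`, `j`, `d`, `omega`, `theta_fwd`, `theta_rev`, `phi_fwd`, `phi_rev`
#'   (angular columns `NA` for non-contact pairs).
#' @export
geometry_table <- function(gmap) {
  n <- gmap$length
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  data.frame(
    i = pairs[, 1], j = pairs[, 2],
    d = gmap$d[pairs],
    omega = gmap$omega[pairs],
    theta_fwd = gmap$theta[pairs],
    theta_rev = gmap$theta[pairs[, c(2, 1), drop = FALSE]],
    phi_fwd = gmap$phi[pairs],
    phi_rev = gmap$phi[pairs[, c(2, 1), drop = FALSE]]
  )
}

#' Serialize / restore a bin specification
#'
#' Edges are listed explicitly so a profile file is self-describing.
#' @param spec a `bin_spec`.
#' @return `bin_spec_to_list`: plain list; `bin_spec_from_list`: a `bin_spec`.
#' @export
bin_spec_to_list <- function(spec) {
  list(d_edges = spec$edges$d, omega_edges = spec$edges$omega,
       theta_edges = spec$edges$theta, phi_edges = spec$edges$phi)
}

#' @rdname bin_spec_to_list
#' @param x a plain list as produced by `bin_spec_to_list`.
#' @export
bin_spec_from_list <- function(x) {
  bin_spec(d_edges = as.numeric(x$d_edges), omega_edges = as.numeric(x$omega_edges),
           theta_edges = as.numeric(x$theta_edges), phi_edges = as.numeric(x$phi_edges))
}
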