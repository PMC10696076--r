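#' Distance between two chromophore anchors
#'
#' Inter-bilin distances are measured between anchor atoms (the C10 methine
#' carbon of each bilin). Accepts either one-row chromophore tibbles (as
#' returned inside [read_structure()] models) or bare numeric 3-vectors.
#'
#' @param a,b Chromophore site rows or numeric xyz vectors (Angstrom).
#' @return Euclidean distance in Angstrom.
#' @examples
#' pair_distance(c(0, 0, 0), c(0, 0, 24.3))
#' @export
pair_distance <- function(a, b) {
  pa <- site_coords(a)
  pb <- site_coords(b)
  sqrt(sum((pa - pb)^2))
}

site_coords <- function(s) {
  if (is.numeric(s)) {
    if (length(s) != 3L) abort("coordinate vectors must have length 3")
    if (any(!is.finite(s))) abort("coordinates must be finite")
    return(as.numeric(s))
  }
  if (is.data.frame(s)) {
    if (nrow(s) != 1L) abort("expected a single chromophore site row")
    p <- c(s$x, s$y, s$z)
    if (any(is.na(p))) {
      abort(paste0("site ", s$site_id %||% "?", " has no anchor coordinates"))
    }
    return(as.numeric(p))
  }
  abort("sites must be numeric 3-vectors or one-row data frames")
}

#' All inter-chromophore anchor distances
#'
#' @param model A `pbs_model` or a chromophore tibble with columns `site_id`,
#'   `x`, `y`, `z`.
#' @param cutoff Keep only pairs at or below this distance (Angstrom);
#'   `Inf` keeps all pairs.
#' @return A tibble with one row per unordered pair: `site_a`, `site_b`
#'   (lexicographically ordered within each row), `distance`.
#' @export
pairwise_distances <- function(model, cutoff = Inf) {
  sites <- if (inherits(model, "pbs_model")) chromophores(model) else as_tibble(model)
  bad <- sites$site_id[is.na(sites$x) | is.na(sites$y) | is.na(sites$z)]
  if (length(bad)) {
    abort(paste0("site(s) without anchor coordinates: ",
                 paste(bad, collapse = ", ")))
  }
  n <- nrow(sites)
  if (n < 2L) {
    return(tibble(site_a = character(), site_b = character(),
                  distance = double()))
  }
  d <- as.matrix(stats::dist(as.matrix(sites[, c("x", "y", "z")])))
  idx <- which(upper.tri(d), arr.ind = TRUE)
  out <- tibble(
    site_a = sites$site_id[idx[, 1L]],
    site_b = sites$site_id[idx[, 2L]],
    distance = d[idx])
  swap <- out$site_b < out$site_a
  tmp <- out$site_a[swap]; out$site_a[swap] <- out$site_b[swap]
  out$site_b[swap] <- tmp
  out <- dplyr::filter(out, .data$distance <= cutoff)
  dplyr::arrange(out, round(.data$distance, 6), .data$site_a, .data$site_b)
}

#' Forster orientation factor from dipole vectors
#'
#' Computes the orientation factor between donor and acceptor transition
#' dipoles, kappa = mu_D . mu_A - 3 (mu_D . R)(mu_A . R), where mu_D and mu_A
#' are unit transition-dipole vectors and R is the unit vector from the donor
#' anchor to the acceptor anchor. Also returns kappa^2 (range 0 to 4,
#' isotropic average 2/3), the three angles of the equivalent angular form
#' kappa^2 = (cos theta_tau - 3 cos theta_D cos theta_A)^2, and the
#' donor-acceptor separation.
#'
#' All arguments are vectorized over rows when given as n x 3 matrices.
#'
#' @param origin_d,origin_a Donor/acceptor anchor coordinates (3-vector or
#'   n x 3 matrix, Angstrom).
#' @param mu_d,mu_a Donor/acceptor transition-dipole directions (3-vector or
#'   n x 3 matrix); normalized internally, zero vectors are an error.
#' @return A tibble with columns `kappa`, `kappa_sq`, `theta_tau`, `theta_d`,
#'   `theta_a` (degrees, in \[0, 180\]) and `distance` (Angstrom).
#' @examples
#' orientation_factor(c(0, 0, 0), c(0, 0, 1), c(10, 0, 0), c(0, 0, 1))
#' @export
orientation_factor <- function(origin_d, mu_d, origin_a, mu_a) {
  od <- as_xyz_matrix(origin_d); oa <- as_xyz_matrix(origin_a)
  md <- unitize(as_xyz_matrix(mu_d)); ma <- unitize(as_xyz_matrix(mu_a))
  n <- max(nrow(od), nrow(oa), nrow(md), nrow(ma))
  od <- recycle_rows(od, n); oa <- recycle_rows(oa, n)
  md <- recycle_rows(md, n); ma <- recycle_rows(ma, n)
  r <- oa - od
  dist <- sqrt(rowSums(r^2))
  if (any(dist == 0)) {
    abort("donor and acceptor origins coincide; R-hat is undefined")
  }
  rhat <- r / dist
  dot_da <- rowSums(md * ma)
  dot_dr <- rowSums(md * rhat)
  dot_ar <- rowSums(ma * rhat)
  kappa <- dot_da - 3 * dot_dr * dot_ar
  tibble(
    kappa = kappa,
    kappa_sq = kappa^2,
    theta_tau = safe_acos_deg(dot_da),
    theta_d = safe_acos_deg(dot_dr),
    theta_a = safe_acos_deg(dot_ar),
    distance = dist)
}

as_xyz_matrix <- function(x) {
  if (is.matrix(x)) {
    if (ncol(x) != 3L) abort("coordinate matrices must have 3 columns")
    return(x)
  }
  if (is.numeric(x) && length(x) == 3L) return(matrix(x, nrow = 1L))
  abort("expected a 3-vector or an n x 3 matrix")
}

recycle_rows <- function(m, n) {
  if (nrow(m) == n) m else if (nrow(m) == 1L) m[rep(1L, n), , drop = FALSE]
  else abort("incompatible row counts")
}

unitize <- function(m) {
  nrm <- sqrt(rowSums(m^2))
  if (any(nrm == 0 | !is.finite(nrm))) {
    abort("dipole directions must be non-zero finite vectors")
  }
  m / nrm
}

# arccos with the argument clamped to [-1, 1]; avoids NaN at parallel limits
safe_acos_deg <- function(x) acos(pmin(1, pmax(-1, x))) * 180 / pi

#' Orientation factor squared from the three angles
#'
#' The angular form of the orientation factor,
#' kappa^2 = (cos theta_tau - 3 cos theta_D cos theta_A)^2, where theta_tau is
#' the angle between the two transition dipoles and theta_D, theta_A are the
#' angles each dipole makes with the donor-acceptor line. Agrees with the
#' vector form of [orientation_factor()] when the angles come from the same
#' vectors.
#'
#' @param theta_tau,theta_d,theta_a Angles in degrees, each in \[0, 180\];
#'   vectorized.
#' @return `kappa_sq` values.
#' @examples
#' kappa_sq_from_angles(0, 90, 90)  # parallel dipoles perpendicular to R: 1
#' kappa_sq_from_angles(0, 0, 0)    # collinear head-to-tail: 4
#' @export
kappa_sq_from_angles <- function(theta_tau, theta_d, theta_a) {
  for (ang in list(theta_tau, theta_d, theta_a)) {
    if (any(ang < 0 | ang > 180)) {
      abort("angles must lie in [0, 180] degrees")
    }
  }
  rad <- pi / 180
  (cos(theta_tau * rad) - 3 * cos(theta_d * rad) * cos(theta_a * rad))^2
}

#' Geometric transition-dipole axis of a chromophore
#'
#' Estimates the transition-dipole direction as the first principal axis of
#' the heavy atoms spanning the conjugated system — a geometric stand-in used
#' when quantum-chemically derived dipole vectors are not supplied. The axis
#' sign is ambiguous; it is oriented so that the dot product with the
#' direction from the atom centroid to a reference atom is positive (the sign
#' does not affect kappa^2).
#'
#' @param atoms A data frame of ligand atoms with columns `atom_name`, `x`,
#'   `y`, `z`, or a numeric n x 3 coordinate matrix.
#' @param axis_spec Optional character vector of atom names to use; `NULL`
#'   uses all rows.
#' @param reference_atom Atom name fixing the sign (default: last atom used).
#' @return A unit 3-vector.
#' @export
estimate_dipole_axis <- function(atoms, axis_spec = NULL,
                                 reference_atom = NULL) {
  if (is.matrix(atoms)) {
    coords <- atoms
    ref_point <- coords[nrow(coords), ]
  } else {
    atoms <- as_tibble(atoms)
    if (!is.null(axis_spec)) {
      missing <- setdiff(axis_spec, atoms$atom_name)
      if (length(missing)) {
        abort(paste0("axis atoms absent from ligand: ",
                     paste(missing, collapse = ", ")))
      }
      atoms <- atoms[match(axis_spec, atoms$atom_name), , drop = FALSE]
    }
    coords <- as.matrix(atoms[, c("x", "y", "z")])
    ref_name <- reference_atom %||% atoms$atom_name[nrow(atoms)]
    if (!ref_name %in% atoms$atom_name) {
      abort(paste0("reference atom '", ref_name, "' not among axis atoms"))
    }
    ref_point <- coords[match(ref_name, atoms$atom_name), ]
  }
  if (nrow(coords) < 2L) {
    abort("dipole-axis estimation needs at least 2 atoms")
  }
  centroid <- colMeans(coords)
  axis <- if (nrow(coords) == 2L) {
    coords[2L, ] - coords[1L, ]
  } else {
    stats::prcomp(coords, center = TRUE, scale. = FALSE)$rotation[, 1L]
  }
  axis <- axis / sqrt(sum(axis^2))
  ref_dir <- ref_point - centroid
  if (sum(ref_dir^2) > 0 && sum(axis * ref_dir) < 0) axis <- -axis
  unname(axis)
}

#' Estimate geometric dipole axes for every chromophore in a model
#'
#' Applies [estimate_dipole_axis()] to each site's ligand heavy atoms and
#' stores the resulting unit vectors in the `dx`, `dy`, `dz` columns with
#' `dipole_source = "geometric_axis"`. Sites that already carry supplied
#' dipoles are left untouched unless `overwrite = TRUE`.
#'
#' @param model A `pbs_model`.
#' @param axis_spec Atom names spanning the axis; defaults to the model
#'   config's `ring_atoms` (or all heavy atoms).
#' @param overwrite Replace supplied dipoles as well?
#' @return The model with dipole columns filled.
#' @export
estimate_dipoles <- function(model, axis_spec = NULL, overwrite = FALSE) {
  stopifnot(inherits(model, "pbs_model"))
  axis_spec <- axis_spec %||% model$config$ring_atoms
  ref <- model$config$reference_atom
  sites <- model$chromophores
  for (i in seq_len(nrow(sites))) {
    if (!overwrite && !is.na(sites$dipole_source[i]) &&
        sites$dipole_source[i] == "supplied") next
    at <- model$atoms[model$atoms$site_id == sites$site_id[i], , drop = FALSE]
    spec <- if (!is.null(axis_spec)) intersect(axis_spec, at$atom_name)
    if (!is.null(spec) && length(spec) < 2L) spec <- NULL
    axis <- estimate_dipole_axis(
      at, axis_spec = spec,
      reference_atom = if (!is.null(ref) && ref %in% at$atom_name) ref)
    sites$dx[i] <- axis[1L]; sites$dy[i] <- axis[2L]; sites$dz[i] <- axis[3L]
    sites$dipole_source[i] <- "geometric_axis"
  }
  model$chromophores <- sites
  model
}

#' Attach supplied transition-dipole vectors from a TSV table
#'
#' The table holds one row per site: `site_id`, `dx`, `dy`, `dz` (tab
#' separated, header required). Vectors are normalized to unit length.
#'
#' @param model A `pbs_model`.
#' @param path Path to the dipole table.
#' @return The model with matching sites' dipoles set
#'   (`dipole_source = "supplied"`).
#' @export
apply_dipole_table <- function(model, path) {
  stopifnot(inherits(model, "pbs_model"))
  if (!file.exists(path)) abort(paste0("dipole table not found: ", path))
  tab <- as_tibble(read.delim(path, sep = "\t", stringsAsFactors = FALSE))
  need <- c("site_id", "dx", "dy", "dz")
  if (!all(need %in% names(tab))) {
    abort("dipole table must have columns site_id, dx, dy, dz")
  }
  unknown <- setdiff(tab$site_id, model$chromophores$site_id)
  if (length(unknown)) {
    abort(paste0("dipole table references unknown site(s): ",
                 paste(unknown, collapse = ", ")))
  }
  dirs <- unitize(as.matrix(tab[, c("dx", "dy", "dz")]))
  idx <- match(tab$site_id, model$chromophores$site_id)
  model$chromophores$dx[idx] <- dirs[, 1L]
  model$chromophores$dy[idx] <- dirs[, 2L]
  model$chromophores$dz[idx] <- dirs[, 3L]
  model$chromophores$dipole_source[idx] <- "supplied"
  model
}

#' Forster-style edge weight
#'
#' A relative coupling weight proportional to kappa^2 / D^6 — the geometric
#' part of the Forster rate (no spectral-overlap factor, so not a rate in
#' physical units). When dipoles are unavailable kappa^2 defaults to the
#' isotropic average 2/3.
#'
#' @param distance Donor-acceptor distance(s), Angstrom; must be > 0.
#' @param kappa_sq Orientation factor(s) squared, in \[0, 4\]; default 2/3.
#' @return Numeric weight(s).
#' @examples
#' forster_edge_weight(10) / forster_edge_weight(20)  # 64: D^-6 scaling
#' @export
forster_edge_weight <- function(distance, kappa_sq = 2 / 3) {
  if (any(distance <= 0)) abort("distance must be positive")
  if (any(kappa_sq < 0 | kappa_sq > 4)) abort("kappa_sq must lie in [0, 4]")
  kappa_sq / distance^6
}

#' Pairwise orientation-factor table for a model
#'
#' Computes [orientation_factor()] for every chromophore pair (optionally
#' within a distance cutoff). Sites must carry dipoles (supplied via
#' [apply_dipole_table()] or estimated via [estimate_dipoles()]).
#'
#' @param model A `pbs_model` with dipoles.
#' @param cutoff Distance cutoff in Angstrom (default `Inf`).
#' @return A tibble: `donor_id`, `acceptor_id`, `distance`, `kappa`,
#'   `kappa_sq`, `theta_tau`, `theta_d`, `theta_a`, `dipole_source` (the
#'   less-trusted of the pair's sources).
#' @export
pair_orientation_table <- function(model, cutoff = Inf) {
  sites <- chromophores(model)
  no_dip <- sites$site_id[is.na(sites$dx)]
  if (length(no_dip)) {
    abort(paste0("site(s) without dipole vectors: ",
                 paste(head(no_dip, 5L), collapse = ", "),
                 if (length(no_dip) > 5L) ", ..."))
  }
  pairs <- pairwise_distances(sites, cutoff = cutoff)
  if (nrow(pairs) == 0L) return(pairs)
  ia <- match(pairs$site_a, sites$site_id)
  ib <- match(pairs$site_b, sites$site_id)
  orr <- orientation_factor(
    as.matrix(sites[ia, c("x", "y", "z")]),
    as.matrix(sites[ia, c("dx", "dy", "dz")]),
    as.matrix(sites[ib, c("x", "y", "z")]),
    as.matrix(sites[ib, c("dx", "dy", "dz")]))
  src <- ifelse(sites$dipole_source[ia] == "supplied" &
                  sites$dipole_source[ib] == "supplied",
                "supplied", "geometric_axis")
  tibble(
    donor_id = pairs$site_a, acceptor_id = pairs$site_b,
    distance = pairs$distance,
    kappa = orr$kappa, kappa_sq = orr$kappa_sq,
    theta_tau = orr$theta_tau, theta_d = orr$theta_d, theta_a = orr$theta_a,
    dipole_source = src)
}

#' Write a pairwise orientation table as TSV
#' @param pairs A tibble from [pair_orientation_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pair_table <- function(pairs, path) {
  write.table(pairs, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
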