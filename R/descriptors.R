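#' Conformational descriptor site selection
#'
#' For hexapeptides the two order parameters are the end-to-end distance
#' between the N atom of the first residue and the C atom of the sixth, and
#' the signed dihedral over the C-alpha atoms of residues 1, 3, 4 and 6.
#' `site_selection` generalises this to arbitrary structures by explicit atom
#' indices; `default_site_selection` maps the convention onto a bead chain
#' (first and last bead as the two ends; dihedral sites at fractional
#' positions 0, 2/5, 3/5 and 1 along the chain, mirroring residues 1, 3, 4, 6
#' of a hexapeptide).
#'
#' @param end_a,end_b atom indices of the two ends.
#' @param dihedral_sites four ordered atom indices.
#' @export
site_selection <- function(end_a, end_b, dihedral_sites) {
  stopifnot(length(dihedral_sites) == 4, end_a != end_b,
            !anyDuplicated(dihedral_sites))
  structure(list(end_a = as.integer(end_a), end_b = as.integer(end_b),
                 dihedral_sites = as.integer(dihedral_sites)),
            class = "elcv_site_selection")
}

#' @rdname site_selection
#' @param n_sites number of sites in the chain (>= 6).
#' @export
default_site_selection <- function(n_sites) {
  stopifnot(n_sites >= 6)
  frac <- c(0, 2 / 5, 3 / 5, 1)
  idx <- 1L + as.integer(round(frac * (n_sites - 1)))
  site_selection(1L, n_sites, idx)
}

as_coords3 <- function(coords) {
  if (is.numeric(coords) && is.null(dim(coords))) coords <- coords_matrix(coords, 3L)
  stopifnot(is.matrix(coords), ncol(coords) == 3)
  coords
}

#' End-to-end distance
#' @param coords n x 3 coordinate matrix (or flat vector).
#' @param sel an `elcv_site_selection`.
#' @export
end_to_end <- function(coords, sel) {
  m <- as_coords3(coords)
  if (sel$end_a > nrow(m) || sel$end_b > nrow(m))
    stop("site index out of range", call. = FALSE)
  sqrt(sum((m[sel$end_a, ] - m[sel$end_b, ])^2))
}

#' Signed four-site dihedral (IUPAC convention)
#'
#' Torsion angle in degrees in (-180, 180]; positive for a right-handed twist
#' looking along the middle bond. Errors when the middle bond vanishes or
#' three consecutive sites are collinear (the torsion is then undefined).
#' @inheritParams end_to_end
#' @export
dihedral <- function(coords, sel) {
  m <- as_coords3(coords)
  s <- sel$dihedral_sites
  if (any(s > nrow(m))) stop("site index out of range", call. = FALSE)
  p <- m[s, , drop = FALSE]
  b1 <- p[2, ] - p[1, ]
  b2 <- p[3, ] - p[2, ]
  b3 <- p[4, ] - p[3, ]
  cr <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                         a[3] * b[1] - a[1] * b[3],
                         a[1] * b[2] - a[2] * b[1])
  n1 <- cr(b1, b2)
  n2 <- cr(b2, b3)
  lb2 <- sqrt(sum(b2^2))
  scale <- max(sqrt(sum(b1^2)), lb2, sqrt(sum(b3^2)))
  if (lb2 < 1e-10 || sqrt(sum(n1^2)) < 1e-10 * scale^2 ||
      sqrt(sum(n2^2)) < 1e-10 * scale^2)
    stop("undefined dihedral: collinear or degenerate sites", call. = FALSE)
  y <- sum(cr(n1, n2) * b2) / lb2
  x <- sum(n1 * n2)
  deg <- atan2(y, x) * 180 / pi
  if (deg <= -180) deg <- deg + 360
  deg
}

#' Descriptor extraction configuration
#' @param energy_window energy window above the global minimum (default 2.6,
#'   the dimer-analysis window in kcal/mol for peptide databases).
#' @param restrict_to_contributors restrict records to the feature's
#'   contribution sets?
#' @export
descriptor_config <- function(energy_window = 2.6,
                              restrict_to_contributors = TRUE) {
  stopifnot(energy_window > 0)
  structure(list(energy_window = energy_window,
                 restrict_to_contributors = restrict_to_contributors),
            class = "elcv_descriptor_config")
}

#' Descriptor records for feature-contributing minima
#'
#' One record per minimum in the union of the feature's positive and negative
#' contribution sets (or every minimum when `restrict_to_contributors` is
#' FALSE), restricted to minima within `energy_window` of the global minimum.
#'
#' @param db an `elcv_spdb` with coordinates.
#' @param feature a feature augmented by [feature_contributions()]; may be
#'   NULL when `restrict_to_contributors` is FALSE.
#' @param cfg a `descriptor_config`.
#' @param sel an `elcv_site_selection`.
#' @return data frame with `id`, `energy`, `rel_energy`, `end_to_end`,
#'   `dihedral`, `contributes`.
#' @export
correlation_data <- function(db, feature, cfg = descriptor_config(), sel) {
  if (is.null(db$coords)) stop("database carries no coordinates", call. = FALSE)
  contrib <- if (!is.null(feature))
    sort(unique(c(feature$positive_set$id, feature$negative_set$id)))
  else integer(0)
  ids <- if (cfg$restrict_to_contributors) contrib else seq_len(n_minima(db))
  e_gm <- min(db$minima$energy)
  if (is.finite(cfg$energy_window)) {
    ids <- ids[db$minima$energy[ids] - e_gm <= cfg$energy_window]
  }
  if (!length(ids)) {
    return(data.frame(id = integer(0), energy = numeric(0),
                      rel_energy = numeric(0), end_to_end = numeric(0),
                      dihedral = numeric(0), contributes = logical(0)))
  }
  missing <- ids[vapply(ids, function(i) is.null(db$coords[[i]]), logical(1))]
  if (length(missing))
    stop("missing coordinates for minimum ", missing[1], call. = FALSE)
  data.frame(
    id = ids,
    energy = db$minima$energy[ids],
    rel_energy = db$minima$energy[ids] - e_gm,
    end_to_end = vapply(ids, function(i) end_to_end(db$coords[[i]], sel),
                        numeric(1)),
    dihedral = vapply(ids, function(i) dihedral(db$coords[[i]], sel),
                      numeric(1)),
    contributes = ids %in% contrib)
}

#' Spread statistics of descriptor records
#'
#' A quantitative proxy for the qualitative "spread" of points in the
#' end-to-end distance versus dihedral correlation plot: ranges and standard
#' deviations of both descriptors.
#' @param records data frame with `end_to_end` and `dihedral` columns.
#' @export
spread_statistics <- function(records) {
  if (!nrow(records)) stop("no records", call. = FALSE)
  list(distance_range = diff(range(records$end_to_end)),
       dihedral_range = diff(range(records$dihedral)),
       distance_sd = if (nrow(records) > 1) stats::sd(records$end_to_end) else 0,
       dihedral_sd = if (nrow(records) > 1) stats::sd(records$dihedral) else 0)
}

#' Conformation class from the end-to-end distance
#'
#' Classes in order of increasing end-to-end distance: beta-hairpin
#' (U-shaped), S-shaped (partially helical), question-mark-shaped, W-shaped
#' (almost helical), and extended (Z-shaped). Bins are half-open: a value
#' exactly at a cut point belongs to the upper class.
#'
#' @param end_to_end end-to-end distance(s).
#' @param boundaries four strictly increasing cut points.
#' @export
classify_conformation <- function(end_to_end,
                                  boundaries = c(3, 5, 7, 9)) {
  if (length(boundaries) != 4 || any(diff(boundaries) <= 0))
    stop("boundaries must be 4 strictly increasing cut points", call. = FALSE)
  classes <- c("hairpin", "S_shaped", "question_mark", "W_shaped", "extended")
  idx <- findInterval(end_to_end, boundaries, left.open = FALSE) + 1L
  factor(classes[idx], levels = classes)
}

#' Minimum inter-monomer site distance of a dimer
#'
#' Auxiliary interstrand-separation descriptor for dimer structures.
#' @param coords n x 3 coordinates (or flat vector).
#' @param monomers list of two particle index sets.
#' @export
interstrand_separation <- function(coords, monomers) {
  m <- as_coords3(coords)
  a <- m[monomers[[1]], , drop = FALSE]
  b <- m[monomers[[2]], , drop = FALSE]
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * a %*% t(b)
  sqrt(max(0, min(d2)))
}

#' Feature temperature versus aggregation propensity
#'
#' Rank correlation between first-feature temperatures and externally
#' computed aggregation-propensity scores, plus a per-group report of whether
#' the amyloid-forming member has the lowest feature temperature in its group
#' (sequences from the same source protein). Rows without a feature (NA) are
#' excluded and listed.
#'
#' @param table data frame with columns `label`, `feature_kbt` (NA = no
#'   feature), `propensity`, and optionally `group` and logical `amyloid`.
#' @return list with `rank_correlation`, `per_group` (data frame), `excluded`
#'   (labels), `n_used`.
#' @export
feature_vs_propensity <- function(table) {
  stopifnot(all(c("label", "feature_kbt", "propensity") %in% names(table)))
  usable <- table[!is.na(table$feature_kbt), , drop = FALSE]
  excluded <- table$label[is.na(table$feature_kbt)]
  if (nrow(usable) < 2)
    stop("need at least 2 rows with a detected feature", call. = FALSE)
  rho <- stats::cor(usable$feature_kbt, usable$propensity,
                    method = "spearman")
  per_group <- NULL
  if (!is.null(table$group) && !is.null(table$amyloid)) {
    groups <- unique(usable$group)
    rows <- lapply(groups, function(g) {
      sub <- usable[usable$group == g, , drop = FALSE]
      if (!any(sub$amyloid) || nrow(sub) < 2) return(NULL)
      data.frame(group = g,
                 amyloid_lowest = min(sub$feature_kbt[sub$amyloid]) <
                   min(sub$feature_kbt[!sub$amyloid]))
    })
    per_group <- do.call(rbind, Filter(Negate(is.null), rows))
  }
  list(rank_correlation = rho, per_group = per_group,
       excluded = as.character(excluded), n_used = nrow(usable))
}
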