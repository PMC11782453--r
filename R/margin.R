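#' Residual (unablated) tumor volume
#'
#' Volume of the tumor mask not covered by the ablation-zone mask. A strictly
#' positive value means incomplete tumor coverage at treatment time
#' ("residual tumor", the MAM < 0 mm class).
#'
#' @param tumor,ablation [annotated_volume()]s on the same grid
#'   (post-registration).
#' @return Uncovered tumor volume in mm^3 (0 iff every tumor voxel lies
#'   inside the ablation mask).
#' @export
residual_tumor <- function(tumor, ablation) {
  stop_if_grid_mismatch(tumor, ablation)
  sum(tumor$grid & !ablation$grid) * prod(tumor$spacing)
}

#' Coverage-based minimal ablative margin (safety-margin sweep)
#'
#' The margin definition used by coverage-style confirmation software: for
#' each safety margin r = 1..10 mm the tumor is dilated by r mm and the
#' unablated volume of that envelope (the part outside the ablation zone) is
#' computed. The MAM is the largest r whose envelope is completely ablated
#' (zero unablated voxels); 0 if the tumor itself is fully covered but no
#' 1-mm envelope is; `"residual"` if the tumor is not fully covered. Values
#' above 10 mm are collapsed to 10, the top of the representable range.
#'
#' @param tumor,ablation [annotated_volume()]s on the same grid; `tumor`
#'   must be non-empty.
#' @param radii integer safety margins to sweep, in mm (default 1:10).
#' @return A list with `mam` (`"residual"` or an integer in `0..max(radii)`),
#'   `sentinel` (integer mm for threshold analysis: -1 for residual, else
#'   `mam`), and `unablated_volume_by_margin`, a data.frame with columns
#'   `r_mm` and `unablated_mm3` (non-decreasing in r).
#' @export
mam_coverage <- function(tumor, ablation, radii = 1:10) {
  stop_if_grid_mismatch(tumor, ablation)
  if (!any(tumor$grid)) stop("tumor mask is empty", call. = FALSE)
  radii <- sort(as.integer(radii))
  voxvol <- prod(tumor$spacing)
  d_out <- distance_map(tumor, "outside")$values  # mm to nearest tumor voxel
  uncovered <- !ablation$grid
  unablated <- vapply(radii, function(r)
    sum(d_out <= r + 1e-9 & uncovered) * voxvol, numeric(1))
  residual <- sum(tumor$grid & uncovered) > 0L
  if (residual) {
    mam <- "residual"; sentinel <- -1L
  } else {
    covered <- radii[unablated == 0]
    mam <- if (length(covered)) max(covered) else 0L
    sentinel <- as.integer(mam)
  }
  list(mam = mam, sentinel = sentinel,
       unablated_volume_by_margin = data.frame(r_mm = radii,
                                               unablated_mm3 = unablated))
}

# Ablation-zone boundary: mask voxels with at least one face neighbor outside
# the mask; voxels on the grid edge count as boundary (the outside continues
# beyond the field of view).
boundary_mask <- function(grid) {
  dm <- dim(grid)
  pad <- array(FALSE, dm + 2L)
  pad[2:(dm[1] + 1), 2:(dm[2] + 1), 2:(dm[3] + 1)] <- grid
  core <- pad[2:(dm[1] + 1), 2:(dm[2] + 1), 2:(dm[3] + 1)]
  nb <- pad[1:dm[1], 2:(dm[2] + 1), 2:(dm[3] + 1)] &
    pad[3:(dm[1] + 2), 2:(dm[2] + 1), 2:(dm[3] + 1)] &
    pad[2:(dm[1] + 1), 1:dm[2], 2:(dm[3] + 1)] &
    pad[2:(dm[1] + 1), 3:(dm[2] + 2), 2:(dm[3] + 1)] &
    pad[2:(dm[1] + 1), 2:(dm[2] + 1), 1:dm[3]] &
    pad[2:(dm[1] + 1), 2:(dm[2] + 1), 3:(dm[3] + 2)]
  core & !nb
}

# Signed distance (mm) from every tumor voxel to the ablation-zone boundary:
# positive inside the ablation mask, negative outside. Returns the vector of
# signed distances over tumor voxels plus their indices.
signed_margin_field <- function(tumor, ablation) {
  stop_if_grid_mismatch(tumor, ablation)
  if (!any(tumor$grid)) stop("tumor mask is empty", call. = FALSE)
  if (!any(ablation$grid)) stop("ablation mask is empty", call. = FALSE)
  bnd <- boundary_mask(ablation$grid)
  d2 <- .edt_sq(as.logical(bnd), as.integer(dim(tumor$grid)), tumor$spacing)
  dist <- sqrt(array(d2, dim(tumor$grid)))
  idx <- which(tumor$grid)
  sgn <- ifelse(ablation$grid[idx], 1, -1)
  list(signed = sgn * dist[idx], idx = idx)
}

# Round to nearest integer, halves away from zero.
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Surface-distance minimal ablative margin (signed)
#'
#' The margin definition used by surface-distance confirmation software: the
#' smallest 3D distance between the tumor and the ablation-zone boundary,
#' signed (negative where tumor voxels lie outside the ablation zone, i.e.
#' incomplete coverage) and rounded to the nearest millimeter, halves away
#' from zero.
#'
#' @param tumor,ablation non-empty [annotated_volume()]s on the same grid.
#' @param rounded return the integer-mm value (default) or the raw minimum.
#' @return Signed margin in mm.
#' @export
mam_surface <- function(tumor, ablation, rounded = TRUE) {
  f <- signed_margin_field(tumor, ablation)
  m <- min(f$signed)
  if (rounded) as.integer(round_half_away(m)) else m
}

#' Octant localization of insufficient margins
#'
#' Partitions the tumor voxels into octants by the three anatomical planes
#' (left-right, anterior-posterior, cranio-caudal) through the tumor
#' centroid (center of mass of tumor voxel centers), and reports the minimal
#' signed margin per octant. Octants are keyed by anatomical direction codes
#' (`"RAS"`, `"LPI"`, ...). Octants with a (rounded) margin below the
#' insufficiency threshold are flagged; empty octants are excluded.
#'
#' @inheritParams mam_surface
#' @param threshold insufficiency threshold in mm (default 5, the margin
#'   regarded as the technical-success target).
#' @return A list with `table` (data.frame: `octant`, `n_voxels`,
#'   `min_margin_mm` unrounded, `min_margin_rounded_mm`, `insufficient`),
#'   `insufficient_octants` (character), and `centroid_mm`.
#' @export
octant_margins <- function(tumor, ablation, threshold = 5) {
  f <- signed_margin_field(tumor, ablation)
  idx <- which(tumor$grid, arr.ind = TRUE)
  xyz <- voxel_centers(tumor, idx)
  centroid <- colMeans(xyz)
  # positive side of each anatomical plane gets the R/A/S letter
  lab <- cbind(ifelse(xyz[, 1] > centroid[1], "R", "L"),
               ifelse(xyz[, 2] > centroid[2], "A", "P"),
               ifelse(xyz[, 3] > centroid[3], "S", "I"))
  octant <- paste0(lab[, 1], lab[, 2], lab[, 3])
  all_oct <- as.vector(outer(outer(c("L", "R"), c("P", "A"), paste0),
                             c("I", "S"), paste0))
  mins <- tapply(f$signed, factor(octant, levels = all_oct), min)
  tab <- data.frame(octant = all_oct,
                    n_voxels = as.integer(table(factor(octant,
                                                       levels = all_oct))),
                    min_margin_mm = as.numeric(mins),
                    stringsAsFactors = FALSE)
  tab$min_margin_rounded_mm <- ifelse(is.na(tab$min_margin_mm), NA_integer_,
                                      as.integer(round_half_away(tab$min_margin_mm)))
  tab$insufficient <- !is.na(tab$min_margin_rounded_mm) &
    tab$min_margin_rounded_mm < threshold
  list(table = tab,
       insufficient_octants = tab$octant[tab$insufficient],
       centroid_mm = centroid)
}

#' Full per-tumor margin quantification
#'
#' Composes the whole confirmation workflow for one tumor: optional rigid
#' co-registration from landmarks (with the accuracy audit; an insufficient
#' registration aborts with an exclusion error, mirroring study practice),
#' then residual-tumor volume, both margin definitions, the 1-10 mm
#' safety-margin volume profile, and octant localization.
#'
#' When `landmarks` are supplied the tumor mask is taken to live in the
#' pre-ablation frame: the fitted transform resamples it onto the ablation
#' (post-ablation) grid before any margin is measured.
#'
#' @param tumor pre-ablation tumor mask ([annotated_volume()]).
#' @param ablation post-ablation coagulation-zone mask on the reference grid.
#' @param landmarks optional [landmark_set()] for rigid co-registration.
#' @param threshold octant insufficiency threshold, mm (default 5).
#' @return An object of class `margin_result`: a list with `mam_coverage`,
#'   `mam_surface`, `mam_surface_unrounded`, `sentinel_coverage`,
#'   `sentinel_surface`, `residual_volume_mm3`, `unablated_volume_by_margin`,
#'   `octants`, `insufficient_octants`, and (when registered) `registration`
#'   (transform + audit).
#' @export
quantify <- function(tumor, ablation, landmarks = NULL, threshold = 5) {
  registration <- NULL
  if (!is.null(landmarks)) {
    tf <- fit_rigid(landmarks)
    audit <- audit_registration(landmarks, tf)
    if (!audit$sufficient)
      stop("excluded: failed co-registration (", audit$n_mismatch,
           " landmarks mismatch > ", audit$threshold_mm, " mm)",
           call. = FALSE)
    tumor <- apply_transform(tumor, tf, ablation)
    registration <- list(transform = tf, audit = audit)
  }
  stop_if_grid_mismatch(tumor, ablation)
  cov <- mam_coverage(tumor, ablation)
  surf_raw <- mam_surface(tumor, ablation, rounded = FALSE)
  surf <- as.integer(round_half_away(surf_raw))
  oct <- octant_margins(tumor, ablation, threshold = threshold)
  structure(list(
    mam_coverage = cov$mam,
    mam_surface = surf,
    mam_surface_unrounded = surf_raw,
    sentinel_coverage = cov$sentinel,
    sentinel_surface = surf,
    residual_volume_mm3 = residual_tumor(tumor, ablation),
    unablated_volume_by_margin = cov$unablated_volume_by_margin,
    octants = oct$table,
    insufficient_octants = oct$insufficient_octants,
    registration = registration
  ), class = "margin_result")
}

#' @export
print.margin_result <- function(x, ...) {
  cat("<margin_result>\n")
  cat(sprintf("  coverage MAM : %s mm\n", x$mam_coverage))
  cat(sprintf("  surface MAM  : %+d mm (%.2f mm unrounded)\n",
              x$mam_surface, x$mam_surface_unrounded))
  cat(sprintf("  residual     : %.1f mm^3\n", x$residual_volume_mm3))
  if (length(x$insufficient_octants))
    cat("  insufficient octants:",
        paste(x$insufficient_octants, collapse = ", "), "\n")
  else cat("  insufficient octants: none\n")
  invisible(x)
}

#' Serialize a margin result
#'
#' Writes the result as JSON plus the safety-margin volume profile as CSV
#' (columns `r_mm`, `unablated_mm3`).
#'
#' @param x a `margin_result`.
#' @param json_path,csv_path output file paths (either may be `NULL` to
#'   skip).
#' @return Invisibly, the list that was serialized.
#' @export
write_margin_result <- function(x, json_path = NULL, csv_path = NULL) {
  stopifnot(inherits(x, "margin_result"))
  out <- list(
    mam_coverage = x$mam_coverage,
    mam_surface = x$mam_surface,
    mam_surface_unrounded = x$mam_surface_unrounded,
    sentinel_coverage = x$sentinel_coverage,
    sentinel_surface = x$sentinel_surface,
    residual_volume_mm3 = x$residual_volume_mm3,
    unablated_volume_by_margin = x$unablated_volume_by_margin,
    octants = x$octants,
    insufficient_octants = as.list(x$insufficient_octants)
  )
  if (!is.null(json_path))
    jsonlite::write_json(out, json_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  if (!is.null(csv_path))
    utils::write.csv(x$unablated_volume_by_margin, csv_path, row.names = FALSE)
  invisible(out)
}
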