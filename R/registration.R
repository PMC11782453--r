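#' Paired anatomical landmarks
#'
#' Holds matched point pairs (mm, canonical RAS coordinates) identified in
#' the pre- and post-ablation scans — in practice liver vessel bifurcations
#' near the ablated segment. Used both to fit the rigid co-registration and
#' to audit its local accuracy.
#'
#' @param pre,post n x 3 numeric matrices of mm coordinates (rows are
#'   matched pairs).
#' @param labels optional character vector of unique landmark names.
#' @return An object of class `landmark_set`.
#' @export
landmark_set <- function(pre, post, labels = NULL) {
  pre <- as.matrix(pre); post <- as.matrix(post)
  storage.mode(pre) <- storage.mode(post) <- "double"
  if (ncol(pre) != 3L || ncol(post) != 3L || nrow(pre) != nrow(post))
    stop("`pre` and `post` must be n x 3 matrices with matching rows",
         call. = FALSE)
  if (nrow(pre) < 1L) stop("at least one landmark pair required", call. = FALSE)
  if (is.null(labels)) labels <- paste0("lm", seq_len(nrow(pre)))
  if (anyDuplicated(labels)) stop("landmark labels must be unique", call. = FALSE)
  structure(list(labels = as.character(labels), pre = pre, post = post),
            class = "landmark_set")
}

#' Read landmark pairs from CSV
#'
#' Expects columns `label, pre_x, pre_y, pre_z, post_x, post_y, post_z`
#' (mm, canonical orientation).
#'
#' @param path CSV file path.
#' @return A [landmark_set()].
#' @export
read_landmarks <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("label", "pre_x", "pre_y", "pre_z", "post_x", "post_y", "post_z")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("landmark CSV lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  landmark_set(as.matrix(df[, c("pre_x", "pre_y", "pre_z")]),
               as.matrix(df[, c("post_x", "post_y", "post_z")]),
               labels = df$label)
}

#' Write landmark pairs to CSV
#' @param lm a [landmark_set()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(lm, path) {
  df <- data.frame(label = lm$labels,
                   pre_x = lm$pre[, 1], pre_y = lm$pre[, 2], pre_z = lm$pre[, 3],
                   post_x = lm$post[, 1], post_y = lm$post[, 2],
                   post_z = lm$post[, 3])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Rigid (rotation + translation) transform
#'
#' @param rotation 3 x 3 proper rotation matrix (orthonormal, det +1).
#' @param translation length-3 mm vector.
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  if (!all(dim(rotation) == c(3L, 3L)) || length(translation) != 3L)
    stop("need a 3x3 rotation and a length-3 translation", call. = FALSE)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9)
    stop("rotation is not orthonormal", call. = FALSE)
  if (abs(det(rotation) - 1) > 1e-9)
    stop("rotation must be proper (det +1, no reflection)", call. = FALSE)
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' Apply a rigid transform to points
#' @param t a [rigid_transform()].
#' @param pts n x 3 matrix (or length-3 vector) of mm coordinates.
#' @return Transformed coordinates, same shape.
#' @export
transform_points <- function(t, pts) {
  v <- is.null(dim(pts))
  pts <- matrix(as.numeric(pts), ncol = 3L)
  out <- pts %*% t(t$rotation) + matrix(t$translation, nrow(pts), 3, byrow = TRUE)
  if (v) drop(out) else out
}

#' Invert a rigid transform
#' @param t a [rigid_transform()].
#' @return The inverse [rigid_transform()].
#' @export
invert_transform <- function(t) {
  Rinv <- t(t$rotation)
  rigid_transform(Rinv, -drop(Rinv %*% t$translation))
}

#' Least-squares rigid fit to landmark pairs
#'
#' Closed-form orthogonal Procrustes (Kabsch) solution: the rotation and
#' translation minimizing the sum of squared distances between transformed
#' pre-scan points and their post-scan mates. Reflection solutions are
#' rejected by sign-correcting the smallest singular direction, so the
#' result is always a proper rotation.
#'
#' @param landmarks a [landmark_set()] with at least 3 non-collinear pairs.
#' @return A [rigid_transform()] mapping pre-scan to post-scan coordinates.
#' @export
fit_rigid <- function(landmarks) {
  stopifnot(inherits(landmarks, "landmark_set"))
  P <- landmarks$pre; Q <- landmarks$post
  if (nrow(P) < 3L)
    stop("rigid fit needs at least 3 landmark pairs", call. = FALSE)
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2L, cp); Qc <- sweep(Q, 2L, cq)
  sv <- svd(Pc)
  scale <- max(sv$d[1], 1e-12)
  if (sv$d[2] / scale < 1e-8)
    stop("landmarks are collinear: rotation about their axis is unconstrained",
         call. = FALSE)
  H <- crossprod(Pc, Qc)            # sum of outer products pre x post
  s <- svd(H)
  d <- det(s$v %*% t(s$u))
  R <- s$v %*% diag(c(1, 1, sign(d))) %*% t(s$u)
  rigid_transform(R, cq - drop(R %*% cp))
}

#' Resample a mask through a rigid transform
#'
#' Maps `vol` (pre-ablation frame) through `t` onto the grid of `reference`
#' (post-ablation frame) with nearest-neighbour interpolation, which
#' preserves binarity. Each reference voxel center is pulled back through
#' the inverse transform and takes the value of the nearest source voxel
#' (FALSE outside the source grid).
#'
#' @param vol the [annotated_volume()] to resample.
#' @param t a [rigid_transform()] mapping `vol` coordinates to `reference`
#'   coordinates.
#' @param reference the [annotated_volume()] whose grid defines the output.
#' @return An [annotated_volume()] on the reference grid.
#' @export
apply_transform <- function(vol, t, reference) {
  stopifnot(inherits(vol, "annotated_volume"),
            inherits(t, "rigid_transform"),
            inherits(reference, "annotated_volume"))
  dmref <- dim(reference$grid)
  idx <- as.matrix(expand.grid(i = seq_len(dmref[1]), j = seq_len(dmref[2]),
                               k = seq_len(dmref[3])))
  x_ref <- voxel_centers(reference, idx)
  x_src <- transform_points(invert_transform(t), x_ref)
  src_idx <- round(sweep(sweep(x_src, 2L, vol$origin), 2L, vol$spacing, `/`)) + 1
  dmsrc <- dim(vol$grid)
  inside <- src_idx[, 1] >= 1 & src_idx[, 1] <= dmsrc[1] &
    src_idx[, 2] >= 1 & src_idx[, 2] <= dmsrc[2] &
    src_idx[, 3] >= 1 & src_idx[, 3] <= dmsrc[3]
  out <- logical(nrow(idx))
  out[inside] <- vol$grid[src_idx[inside, , drop = FALSE]]
  annotated_volume(array(out, dmref), spacing = reference$spacing,
                   origin = reference$origin)
}

#' Audit co-registration accuracy at the landmarks
#'
#' Computes the residual distance (mm) at each landmark after applying the
#' fitted transform, and applies the study exclusion rule: registration is
#' sufficient unless more than one landmark mismatches by more than 3 mm
#' (a residual of exactly 3.0 mm does not count as a mismatch).
#'
#' @param landmarks a [landmark_set()].
#' @param t a [rigid_transform()].
#' @param threshold mismatch threshold in mm (default 3).
#' @param max_mismatches largest tolerated number of residuals above the
#'   threshold (default 1).
#' @return A list of class `registration_audit` with elements `residuals`
#'   (named mm vector), `n_mismatch`, and `sufficient`.
#' @export
audit_registration <- function(landmarks, t, threshold = 3,
                               max_mismatches = 1L) {
  stopifnot(inherits(landmarks, "landmark_set"), inherits(t, "rigid_transform"))
  moved <- transform_points(t, landmarks$pre)
  res <- sqrt(rowSums((moved - landmarks$post)^2))
  names(res) <- landmarks$labels
  n_bad <- sum(res > threshold)
  structure(list(residuals = res, n_mismatch = n_bad,
                 threshold_mm = threshold,
                 sufficient = n_bad <= max_mismatches),
            class = "registration_audit")
}

#' @export
print.registration_audit <- function(x, ...) {
  cat(sprintf("<registration_audit> %d landmark(s), %d mismatch(es) > %g mm: %s\n",
              length(x$residuals), x$n_mismatch, x$threshold_mm,
              if (x$sufficient) "sufficient" else "insufficient (exclude)"))
  invisible(x)
}
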