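# Independent brute-force oracles. These deliberately share no code with the
# package internals: neighbor scans are explicit, distances are pairwise.

# Minimum voxel-center distance (mm) from every voxel to the TRUE voxels.
brute_distance_field <- function(mask, spacing) {
  dm <- dim(mask)
  sites <- which(mask, arr.ind = TRUE)
  out <- array(Inf, dm)
  if (nrow(sites) == 0) return(out)
  all_idx <- as.matrix(expand.grid(i = 1:dm[1], j = 1:dm[2], k = 1:dm[3]))
  d2 <- matrix(Inf, nrow(all_idx), 1)
  best <- rep(Inf, nrow(all_idx))
  for (s in seq_len(nrow(sites))) {
    d2s <- ((all_idx[, 1] - sites[s, 1]) * spacing[1])^2 +
      ((all_idx[, 2] - sites[s, 2]) * spacing[2])^2 +
      ((all_idx[, 3] - sites[s, 3]) * spacing[3])^2
    best <- pmin(best, d2s)
  }
  array(sqrt(best), dm)
}

# Ablation boundary by explicit face-neighbor scan (grid edge counts as
# outside), then signed min over tumor voxels.
brute_signed_mam <- function(tumor_grid, ablation_grid, spacing) {
  dm <- dim(ablation_grid)
  is_boundary <- function(i, j, k) {
    if (!ablation_grid[i, j, k]) return(FALSE)
    for (d in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                   c(0, 0, 1), c(0, 0, -1))) {
      ii <- i + d[1]; jj <- j + d[2]; kk <- k + d[3]
      if (ii < 1 || ii > dm[1] || jj < 1 || jj > dm[2] ||
          kk < 1 || kk > dm[3]) return(TRUE)
      if (!ablation_grid[ii, jj, kk]) return(TRUE)
    }
    FALSE
  }
  abl_idx <- which(ablation_grid, arr.ind = TRUE)
  bnd <- abl_idx[apply(abl_idx, 1, function(v) is_boundary(v[1], v[2], v[3])),
                 , drop = FALSE]
  tum <- which(tumor_grid, arr.ind = TRUE)
  if (nrow(tum) == 0 || nrow(bnd) == 0) return(NA_real_)
  vals <- vapply(seq_len(nrow(tum)), function(t) {
    d2 <- ((bnd[, 1] - tum[t, 1]) * spacing[1])^2 +
      ((bnd[, 2] - tum[t, 2]) * spacing[2])^2 +
      ((bnd[, 3] - tum[t, 3]) * spacing[3])^2
    s <- if (ablation_grid[tum[t, 1], tum[t, 2], tum[t, 3]]) 1 else -1
    s * sqrt(min(d2))
  }, numeric(1))
  min(vals)
}

# Tie-aware Mann-Whitney AUC for score = -mam predicting ltp.
brute_auc <- function(mam, ltp) {
  cases <- -mam[ltp == 1]
  controls <- -mam[ltp == 0]
  tot <- 0
  for (x in cases)
    tot <- tot + sum(x > controls) + 0.5 * sum(x == controls)
  tot / (length(cases) * length(controls))
}

# Random blob-ish mask: union of a few random boxes/balls, possibly empty.
rand_mask <- function(dm, p = 0.15) {
  array(runif(prod(dm)) < p, dm)
}

# Random proper rotation via QR of a Gaussian matrix.
rand_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3))
  Q <- qr.Q(qr_)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# Voxelized sphere pair on a shared grid, package-independent construction.
sphere_grid <- function(dm, spacing, center, radius) {
  idx <- as.matrix(expand.grid(i = 1:dm[1], j = 1:dm[2], k = 1:dm[3]))
  xyz <- sweep(idx - 1, 2, spacing, `*`)
  array(rowSums(sweep(xyz, 2, center)^2) <= radius^2, dm)
}
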