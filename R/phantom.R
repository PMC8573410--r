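# Synthetic chiasm phantoms: X-shaped white-matter structure in a T1w-like
# intensity model, with ground-truth masks and corrupted atlas-like masks.

gauss_kernel_matrix <- function(n, sd) {
  if (sd <= 0) return(diag(n))
  r <- max(1L, ceiling(3 * sd))
  k <- stats::dnorm(seq(-r, r), sd = sd)
  K <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- (i - r):(i + r)
    ok <- j >= 1 & j <= n
    K[i, j[ok]] <- k[ok]
    K[i, ] <- K[i, ] / sum(K[i, ])
  }
  K
}

# Separable Gaussian blur with renormalized (truncated) boundaries.
blur3d <- function(arr, sd) {
  if (sd <= 0) return(arr)
  d <- dim(arr)
  arr <- array(gauss_kernel_matrix(d[1], sd) %*% matrix(arr, d[1], d[2] * d[3]), d)
  a <- aperm(arr, c(2, 1, 3))
  a <- array(gauss_kernel_matrix(d[2], sd) %*% matrix(a, d[2], d[1] * d[3]),
             c(d[2], d[1], d[3]))
  arr <- aperm(a, c(2, 1, 3))
  a <- aperm(arr, c(3, 1, 2))
  a <- array(gauss_kernel_matrix(d[3], sd) %*% matrix(a, d[3], d[1] * d[2]),
             c(d[3], d[1], d[2]))
  aperm(a, c(2, 3, 1))
}

#' Parameters of the synthetic chiasm phantom
#'
#' The phantom is an X-shaped white-matter structure: two straight tubular
#' limbs crossing at the grid center in one axial band. `chiasm_width` sets
#' the tube diameter near the crossing, `nerve_width` the diameter of the
#' distal limbs, and `tract_angle` the opening angle (degrees) between the
#' two posterior limbs. Intensities form three tiers
#' (`background < wm < vessel`); Gaussian blur of the tissue fraction
#' emulates partial-volume surface voxels and Gaussian noise the
#' acquisition. `width_jitter` adds seeded per-phantom variability
#' (multiplicative on the widths, additive on the angle) emulating
#' inter-subject anatomy. The malformed preset narrows the chiasm (x 0.5)
#' and nerves (x 0.7) and widens the tract angle (+30 degrees), the
#' direction of the group differences reported for albinism.
#'
#' @param grid_shape integer length-3 grid size in voxels.
#' @param chiasm_width,nerve_width tube diameters in voxels.
#' @param tract_angle opening angle between posterior limbs, degrees,
#'   in (0, 180).
#' @param wm_intensity,background_intensity,vessel_intensity intensity tiers
#'   (arbitrary units), `vessel > wm > background`.
#' @param noise_sd additive Gaussian noise SD.
#' @param blur_sd partial-volume blur SD in voxels.
#' @param width_jitter relative per-phantom geometry variability in
#'   \[0, 0.5\].
#' @param malformed logical; apply the malformation preset.
#' @param seed integer seed; identical seed and parameters give
#'   bit-identical phantoms.
#' @return An object of class `phantom_params`.
#' @export
phantom_params <- function(grid_shape = c(64, 64, 64),
                           chiasm_width = 7, nerve_width = 5,
                           tract_angle = 90,
                           wm_intensity = 0.7, background_intensity = 0.2,
                           vessel_intensity = 1.0,
                           noise_sd = 0.04, blur_sd = 0.7,
                           width_jitter = 0.08,
                           malformed = FALSE, seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 8L))
    stop("grid_shape must be 3 integers >= 8")
  if (chiasm_width <= 0 || nerve_width <= 0) stop("widths must be positive")
  if (tract_angle <= 0 || tract_angle >= 180)
    stop("tract_angle must be in (0, 180)")
  if (!(vessel_intensity > wm_intensity && wm_intensity > background_intensity))
    stop("need vessel_intensity > wm_intensity > background_intensity")
  if (noise_sd < 0 || blur_sd < 0) stop("noise_sd and blur_sd must be >= 0")
  if (width_jitter < 0 || width_jitter > 0.5) stop("width_jitter must be in [0, 0.5]")
  structure(list(grid_shape = grid_shape, chiasm_width = chiasm_width,
                 nerve_width = nerve_width, tract_angle = tract_angle,
                 wm_intensity = wm_intensity,
                 background_intensity = background_intensity,
                 vessel_intensity = vessel_intensity,
                 noise_sd = noise_sd, blur_sd = blur_sd,
                 width_jitter = width_jitter,
                 malformed = isTRUE(malformed), seed = as.integer(seed)),
            class = "phantom_params")
}

# Binary indicator of the X structure (two crossing tubes in the axial
# plane through the grid center).
phantom_indicator <- function(d, chiasm_width, nerve_width, tract_angle) {
  ctr <- (d + 1) / 2
  a2 <- (tract_angle / 2) * pi / 180
  X <- array(rep(seq_len(d[1]), times = d[2] * d[3]), d) - ctr[1]
  Y <- array(rep(rep(seq_len(d[2]), each = d[1]), times = d[3]), d) - ctr[2]
  Z <- array(rep(seq_len(d[3]), each = d[1] * d[2]), d) - ctr[3]
  half_len <- 0.38 * min(d[1], d[2])
  core_len <- 0.095 * min(d[1], d[2])  # axial extent of the chiasm body
  ind <- array(FALSE, d)
  for (sgn in c(-1, 1)) {
    u <- c(sgn * sin(a2), cos(a2))
    tt <- X * u[1] + Y * u[2]
    px <- X - tt * u[1]
    py <- Y - tt * u[2]
    r <- ifelse(abs(tt) <= core_len, chiasm_width / 2, nerve_width / 2)
    ind <- ind | (abs(tt) <= half_len & px^2 + py^2 + Z^2 <= r^2)
  }
  ind
}

#' Generate one synthetic chiasm phantom
#'
#' Builds the X-shaped structure, blurs the tissue indicator into a
#' partial-volume fraction, attaches 1-3 small hyperintense vessel-like
#' blobs to the structure's surface (always outside the ground-truth mask),
#' and adds Gaussian noise. The ground-truth "manual" mask contains the
#' voxels whose pre-noise white-matter fraction exceeds 0.5, emulating a
#' rater labeling majority-white-matter voxels.
#'
#' @param params a [phantom_params()].
#' @return An object of class `chiasm_phantom`: list with `volume`
#'   ([volume()]), `manual_mask` ([binary_mask()]), `label` (`"control"` or
#'   `"malformed"`), `seed` and `params`.
#' @export
make_phantom <- function(params) {
  stopifnot(inherits(params, "phantom_params"))
  p <- params
  d <- p$grid_shape
  out <- with_seed(p$seed, {
    cw <- p$chiasm_width
    nw <- p$nerve_width
    ang <- p$tract_angle
    if (p$width_jitter > 0) {
      cw <- cw * stats::runif(1, 1 - p$width_jitter, 1 + p$width_jitter)
      nw <- nw * stats::runif(1, 1 - p$width_jitter, 1 + p$width_jitter)
      ang <- ang + stats::runif(1, -50 * p$width_jitter, 50 * p$width_jitter)
    }
    if (p$malformed) {
      cw <- cw * 0.5
      nw <- nw * 0.7
      ang <- ang + 30
    }
    ind <- phantom_indicator(d, cw, nw, ang)
    f <- blur3d(ind * 1.0, p$blur_sd)
    manual <- array(as.integer(f > 0.5), d)
    img <- p$background_intensity + (p$wm_intensity - p$background_intensity) * f
    shell <- dilate_mask(binary_mask(manual), "cube26")$data == 1L & manual == 0L
    nv <- sample(1:3, 1)
    centers <- sample(which(shell), min(nv, sum(shell)))
    co <- arrayInd(centers, d)
    vfield <- array(0, d)
    for (i in seq_len(nrow(co))) {
      rng <- lapply(1:3, function(a) max(1, co[i, a] - 2):min(d[a], co[i, a] + 2))
      grid <- as.matrix(expand.grid(rng[[1]], rng[[2]], rng[[3]]))
      dist2 <- rowSums((grid - matrix(co[i, ], nrow(grid), 3, byrow = TRUE))^2)
      vox <- grid[dist2 <= 1.6^2, , drop = FALSE]
      keep <- manual[vox] == 0L
      vfield[vox[keep, , drop = FALSE]] <- 1
    }
    # vessels share the partial-volume model of the tissue boundary
    vfield <- blur3d(vfield, p$blur_sd)
    img <- img + (p$vessel_intensity - p$background_intensity) * vfield
    if (p$noise_sd > 0) img <- img + stats::rnorm(length(img), sd = p$noise_sd)
    list(img = img, manual = manual)
  })
  manual <- out$manual
  if (sum(manual) == 0L) stop("phantom structure does not fit in grid")
  edge <- sum(manual[1, , ]) + sum(manual[d[1], , ]) + sum(manual[, 1, ]) +
    sum(manual[, d[2], ]) + sum(manual[, , 1]) + sum(manual[, , d[3]])
  if (edge > 0) stop("phantom structure does not fit in grid")
  comp <- largest_component(binary_mask(manual), connectivity = 26)
  if (sum(comp$data) != sum(manual))
    stop("internal error: manual mask is not a single component")
  structure(list(volume = volume(array(out$img, d)),
                 manual_mask = binary_mask(manual),
                 label = if (p$malformed) "malformed" else "control",
                 seed = p$seed, params = p),
            class = "chiasm_phantom")
}

#' Corrupt a ground-truth mask into an atlas-like initial mask
#'
#' Emulates the quality of raw atlas-based segmentations by (i) one random
#' global erosion or dilation, (ii) random voxel flips within a 2-voxel
#' shell around the true boundary, and (iii) injection of one contiguous
#' false-positive patch of background/partial-volume voxels adjacent to the
#' mask. The default severity is calibrated so that over many seeds the
#' mean Dice overlap with the ground truth falls near 0.57, the quality
#' level typical of uncorrected atlas masks.
#'
#' @param sample a `chiasm_phantom`.
#' @param corruption_seed integer seed.
#' @param severity corruption strength in (0, 1]; expected overlap decreases
#'   monotonically with severity.
#' @return The corrupted [binary_mask()].
#' @export
corrupt_to_initial <- function(sample, corruption_seed, severity = 0.65) {
  stopifnot(inherits(sample, "chiasm_phantom"))
  if (severity <= 0 || severity > 1) stop("severity must be in (0, 1]")
  manual <- sample$manual_mask$data
  d <- dim(manual)
  m <- with_seed(corruption_seed, {
    m <- manual
    # global erosion or dilation, applied with probability `severity`
    if (stats::runif(1) < severity) {
      if (stats::runif(1) < 0.5) {
        er <- erode_mask(binary_mask(m), "cross6")$data
        m <- if (sum(er) > 0) er else dilate_mask(binary_mask(m), "cross6")$data
      } else {
        m <- dilate_mask(binary_mask(m), "cross6")$data
      }
    }
    outer2 <- dilate_mask(dilate_mask(binary_mask(manual), "cross6"), "cross6")$data
    inner2 <- erode_mask(erode_mask(binary_mask(manual), "cross6"), "cross6")$data
    shell <- which(outer2 == 1L & inner2 == 0L)
    flip <- shell[stats::runif(length(shell)) < 0.45 * severity]
    m[flip] <- 1L - m[flip]
    cand <- which(dilate_mask(binary_mask(manual), "cube26")$data == 1L &
                    manual == 0L)
    ctr <- arrayInd(sample(cand, 1), d)
    rp <- 1.5 + 4.5 * severity
    rr <- ceiling(rp)
    rng <- lapply(1:3, function(a) max(1, ctr[a] - rr):min(d[a], ctr[a] + rr))
    grid <- as.matrix(expand.grid(rng[[1]], rng[[2]], rng[[3]]))
    dist2 <- rowSums((grid - matrix(ctr, nrow(grid), 3, byrow = TRUE))^2)
    patch <- grid[dist2 <= rp^2, , drop = FALSE]
    keep <- manual[patch] == 0L
    m[patch[keep, , drop = FALSE]] <- 1L
    m
  })
  if (sum(m) == 0L)
    stop(sprintf("corruption emptied the mask (seed %d)", corruption_seed))
  binary_mask(m)
}

#' Derive a per-sample seed from a master seed
#'
#' Fixed linear-congruential hash of `(master_seed, index, salt)` modulo
#' `2^31 - 1`, used for all per-sample seed derivation so cohorts and
#' experiments are reproducible from a single master seed.
#'
#' @param master_seed,index,salt integers.
#' @return An integer seed in `[0, 2^31 - 1)`.
#' @export
derive_seed <- function(master_seed, index, salt = 0) {
  s <- (as.double(master_seed) * 48271 + as.double(index) * 16807 +
          as.double(salt) * 69621) %% 2147483647
  as.integer(s)
}

#' Generate a seeded cohort of phantoms
#'
#' Per-sample seeds are derived deterministically from `master_seed`
#' (fixed linear-congruential hash of master seed and sample index), so the
#' same call always reproduces the same cohort. Each sample carries the
#' ground-truth mask and a corrupted atlas-like initial mask. When
#' `out_dir` is given, volumes and masks are written as NIfTI files and a
#' manifest CSV (`id,label,seed,volume_path,manual_mask_path,initial_mask_path`)
#' is written alongside.
#'
#' @param n_control,n_malformed cohort sizes (>= 0).
#' @param base_params a [phantom_params()] shared by all samples (the seed
#'   and malformed fields are overridden per sample).
#' @param master_seed integer master seed.
#' @param out_dir optional output directory for NIfTI files and manifest.
#' @param severity corruption severity passed to [corrupt_to_initial()].
#' @return List of class `chiasm_cohort` with `samples` (each a
#'   `chiasm_phantom` plus `initial_mask` and `id`) and `manifest`
#'   (data.frame).
#' @export
make_cohort <- function(n_control, n_malformed,
                        base_params = phantom_params(), master_seed = 1L,
                        out_dir = NULL, severity = 0.65) {
  stopifnot(n_control >= 0, n_malformed >= 0)
  labels <- c(rep("control", n_control), rep("malformed", n_malformed))
  n <- length(labels)
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  samples <- vector("list", n)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    p <- base_params
    p$seed <- derive_seed(master_seed, i)
    p$malformed <- labels[i] == "malformed"
    s <- make_phantom(p)
    s$initial_mask <- corrupt_to_initial(s, derive_seed(master_seed, i, salt = 1),
                                         severity = severity)
    s$id <- sprintf("sub-%03d", i)
    samples[[i]] <- s
    paths <- c(volume_path = "", manual_mask_path = "", initial_mask_path = "")
    if (!is.null(out_dir)) {
      paths <- c(
        volume_path = file.path(out_dir, sprintf("%s_T1w.nii.gz", s$id)),
        manual_mask_path = file.path(out_dir, sprintf("%s_manual.nii.gz", s$id)),
        initial_mask_path = file.path(out_dir, sprintf("%s_initial.nii.gz", s$id)))
      write_volume(s$volume, paths[["volume_path"]])
      write_mask(s$manual_mask, paths[["manual_mask_path"]], s$volume$spacing)
      write_mask(s$initial_mask, paths[["initial_mask_path"]], s$volume$spacing)
    }
    rows[[i]] <- data.frame(id = s$id, label = s$label, seed = p$seed,
                            volume_path = paths[["volume_path"]],
                            manual_mask_path = paths[["manual_mask_path"]],
                            initial_mask_path = paths[["initial_mask_path"]],
                            stringsAsFactors = FALSE)
  }
  manifest <- if (n > 0) do.call(rbind, rows) else
    data.frame(id = character(), label = character(), seed = integer(),
               volume_path = character(), manual_mask_path = character(),
               initial_mask_path = character(), stringsAsFactors = FALSE)
  if (!is.null(out_dir)) {
    utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                     row.names = FALSE)
  }
  structure(list(samples = samples, manifest = manifest),
            class = "chiasm_cohort")
}
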