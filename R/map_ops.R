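#' Mask / segment a density map
#'
#' Sets voxels outside the mask to zero, optionally cropping the grid to the
#' mask bounding box (the origin is updated so world coordinates are
#' preserved). Masks: a sphere (`centre`, `radius` in Angstrom), a box
#' (`corner`, `extent` in Angstrom), or a density threshold region (`level`).
#'
#' @param map a [density_map()].
#' @param mask a list with `type = "sphere"` (+ `centre`, `radius`),
#'   `type = "box"` (+ `corner`, `extent`), or `type = "threshold"`
#'   (+ `level`).
#' @param crop crop the grid to the mask bounding box?
#' @return A [density_map()].
#' @export
segment_map <- function(map, mask, crop = FALSE) {
  ax <- map_axes(map)
  keep <- switch(mask$type,
    sphere = {
      dx2 <- outer(outer((ax[[1]] - mask$centre[1])^2,
                         (ax[[2]] - mask$centre[2])^2, `+`),
                   (ax[[3]] - mask$centre[3])^2, `+`)
      dx2 <= mask$radius^2
    },
    box = {
      inb <- lapply(1:3, function(k) {
        ax[[k]] >= mask$corner[k] & ax[[k]] <= mask$corner[k] + mask$extent[k]
      })
      outer(outer(inb[[1]], inb[[2]], `&`), inb[[3]], `&`)
    },
    threshold = map$grid >= mask$level,
    stop("unknown mask type: ", mask$type)
  )
  if (!any(keep)) stop("mask does not intersect the map grid")
  grid <- map$grid
  grid[!keep] <- 0
  if (!crop) return(density_map(grid, map$voxel_size, map$origin))
  idx <- which(keep, arr.ind = TRUE)
  lo <- apply(idx, 2, min); hi <- apply(idx, 2, max)
  hi <- pmax(hi, lo + 1L)  # keep >= 2 voxels per axis
  density_map(grid[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE],
              map$voxel_size, map$origin + (lo - 1) * map$voxel_size)
}

#' Pad a cropped map back onto a larger grid
#'
#' Inverse of cropping: places the map's voxels into a zero grid with the
#' given dimensions and origin (which must be grid-commensurate).
#'
#' @param map a [density_map()].
#' @param dims target grid dimensions.
#' @param origin target grid origin (Angstrom).
#' @return A [density_map()].
#' @export
pad_map <- function(map, dims, origin) {
  shift <- (map$origin - origin) / map$voxel_size
  if (max(abs(shift - round(shift))) > 1e-6) {
    stop("origins are not grid-commensurate")
  }
  shift <- as.integer(round(shift))
  grid <- array(0, dim = dims)
  d <- dim(map$grid)
  grid[shift[1] + seq_len(d[1]), shift[2] + seq_len(d[2]),
       shift[3] + seq_len(d[3])] <- map$grid
  density_map(grid, map$voxel_size, origin)
}

# normalized cross-correlation of two equal-size arrays
ncc <- function(a, b) {
  a <- a - mean(a); b <- b - mean(b)
  den <- sqrt(sum(a^2) * sum(b^2))
  if (den == 0) return(NA_real_)
  sum(a * b) / den
}

# resample `moving` onto the grid of `template` under the world-coordinate
# transform x_fixed = R (x - c) + c + t (c = centre of the moving map):
# looks up moving at the inverse-transformed output coordinates
resample_map <- function(moving, template, rotation, translation, center) {
  A <- t(rotation)
  b <- as.numeric(center - A %*% (center + translation))
  vals <- cpp_affine_resample(as.numeric(moving$grid), dim(moving$grid),
                              moving$origin, moving$voxel_size,
                              dim(template$grid), template$origin,
                              A, b)
  density_map(array(vals, dim = dim(template$grid)), template$voxel_size,
              template$origin)
}

#' Rigidly align one density map onto another
#'
#' Maximises the real-space normalised cross-correlation over rigid motions:
#' a coarse exhaustive scan over rotation vectors (all axes, angles up to
#' `max_angle` in steps of `coarse_step`), with the best translation per
#' orientation found by an FFT cross-correlation scan, followed by
#' derivative-free local refinement of all six parameters. Intended for maps
#' that are already roughly oriented (as reconstructions of the same complex
#' are); widen `max_angle` for more divergent inputs.
#'
#' @param moving,fixed [density_map()] objects with the same voxel size.
#' @param coarse_step angular grid spacing of the coarse scan, degrees.
#' @param max_angle largest rotation magnitude scanned, degrees.
#' @param local_refine run Nelder-Mead refinement of the best coarse hit?
#' @return A list of class `map_alignment`: `transform` (the
#'   [rigid_transform()] taking `moving` world coordinates onto `fixed`,
#'   rotation about the moving map's centre), `aligned` (moving resampled
#'   onto the fixed grid), `correlation` (final NCC), `center` (rotation
#'   centre used).
#' @export
align_maps <- function(moving, fixed, coarse_step = 10, max_angle = 30,
                       local_refine = TRUE) {
  if (abs(moving$voxel_size - fixed$voxel_size) > 1e-6) {
    stop("maps must share the same voxel size")
  }
  if (stats::sd(moving$grid) == 0 || stats::sd(fixed$grid) == 0) {
    stop("featureless (constant) map: correlation is undefined")
  }
  vx <- fixed$voxel_size
  nf <- dim(fixed$grid)
  ctr <- moving$origin + (dim(moving$grid) - 1) * vx / 2
  f0 <- fixed$grid - mean(fixed$grid)
  Ff <- stats::fft(f0)
  nrm_f <- sqrt(sum(f0^2))

  steps <- seq(-max_angle, max_angle, by = coarse_step)
  grid_pts <- as.matrix(expand.grid(x = steps, y = steps, z = steps))
  grid_pts <- grid_pts[sqrt(rowSums(grid_pts^2)) <= max_angle + 1e-9, ,
                       drop = FALSE]
  best <- list(cc = -Inf)
  for (g in seq_len(nrow(grid_pts))) {
    R <- rotvec_to_matrix(grid_pts[g, ])
    rs <- resample_map(moving, fixed, R, c(0, 0, 0), ctr)
    m0 <- rs$grid - mean(rs$grid)
    nrm_m <- sqrt(sum(m0^2))
    if (nrm_m == 0) next
    # correlation theorem: cross-correlation over all circular shifts
    cc <- Re(stats::fft(Conj(stats::fft(m0)) * Ff, inverse = TRUE)) /
      (length(m0) * nrm_m * nrm_f)
    k <- which.max(cc)
    if (cc[k] > best$cc) {
      sh <- arrayInd(k, nf) - 1L
      sh <- ifelse(sh > nf / 2, sh - nf, sh)  # wrap to signed shifts
      best <- list(cc = cc[k], rotvec = grid_pts[g, ], shift = sh * vx)
    }
  }
  if (!is.finite(best$cc)) stop("alignment failed: no overlap found")

  par <- c(best$rotvec, best$shift)
  obj <- function(p) {
    rs <- resample_map(moving, fixed, rotvec_to_matrix(p[1:3]), p[4:6], ctr)
    v <- ncc(rs$grid, fixed$grid)
    if (is.na(v)) 1 else -v
  }
  if (local_refine) {
    opt <- stats::optim(par, obj, method = "Nelder-Mead",
                        control = list(maxit = 400, reltol = 1e-8))
    par <- opt$par
  }
  R <- rotvec_to_matrix(par[1:3])
  aligned <- resample_map(moving, fixed, R, par[4:6], ctr)
  transform <- compose_transforms(
    rigid_transform(diag(3), par[4:6]),
    rotation_about_line(if (sqrt(sum(par[1:3]^2)) > 0) par[1:3] else c(0, 0, 1),
                        sqrt(sum(par[1:3]^2)), ctr))
  structure(list(transform = transform, aligned = aligned,
                 correlation = ncc(aligned$grid, fixed$grid), center = ctr),
            class = "map_alignment")
}

#' @export
print.map_alignment <- function(x, ...) {
  ra <- rotation_angle_axis(x$transform)
  cat(sprintf("<map_alignment> rotation %.2f deg, correlation %.4f\n",
              ra$angle, x$correlation))
  invisible(x)
}

#' Average aligned density maps
#'
#' Voxelwise mean and unbiased (N-1) voxelwise variance over a list of maps
#' on identical grids. Averaging boosts signal-to-noise where the maps agree
#' and blurs (raises the variance of) regions where they differ, so the
#' variance map localises conformational heterogeneity.
#'
#' @param maps list of at least two [density_map()] objects with identical
#'   grids.
#' @return A list with `mean` and `variance` [density_map()] objects.
#' @export
average_maps <- function(maps) {
  if (length(maps) < 2) stop("averaging needs at least 2 maps")
  d0 <- dim(maps[[1]]$grid)
  for (m in maps) {
    if (!identical(dim(m$grid), d0) ||
        abs(m$voxel_size - maps[[1]]$voxel_size) > 1e-9) {
      stop("maps must share identical grids")
    }
  }
  n <- length(maps)
  s <- array(0, d0)
  for (m in maps) s <- s + m$grid
  mu <- s / n
  va <- array(0, d0)
  for (m in maps) va <- va + (m$grid - mu)^2
  va <- va / (n - 1)
  list(mean = density_map(mu, maps[[1]]$voxel_size, maps[[1]]$origin),
       variance = density_map(va, maps[[1]]$voxel_size, maps[[1]]$origin))
}

#' Fourier shell correlation of two maps
#'
#' Correlation of the two maps' Fourier coefficients over concentric shells
#' of spatial frequency, the standard agreement/resolution measure for 3D
#' reconstructions.
#'
#' @param map_a,map_b [density_map()] objects on identical grids.
#' @param shell_width shell width in reciprocal-voxel units (default 1 index
#'   step, i.e. `1 / (n * voxel)` per shell).
#' @return An object of class `fsc_curve`: a [tibble::tibble()] with columns
#'   `freq` (shell centre, 1/Angstrom), `fsc`, `n_coef` (Fourier
#'   coefficients per shell), up to the Nyquist frequency.
#' @export
fsc <- function(map_a, map_b, shell_width = 1) {
  if (!identical(dim(map_a$grid), dim(map_b$grid)) ||
      abs(map_a$voxel_size - map_b$voxel_size) > 1e-9) {
    stop("maps must share identical grids")
  }
  d <- dim(map_a$grid)
  Fa <- stats::fft(map_a$grid)
  Fb <- stats::fft(map_b$grid)
  fr <- lapply(1:3, function(k) {
    f <- c(0:(d[k] %/% 2), -((d[k] - d[k] %/% 2 - 1):1)) / d[k]
    f
  })
  r2 <- outer(outer(fr[[1]]^2, fr[[2]]^2, `+`), fr[[3]]^2, `+`)
  ridx <- sqrt(r2) * d[1]  # radius in index units of the first axis
  shell <- floor(ridx / shell_width)
  nyq <- floor((d[1] / 2) / shell_width)
  keep <- shell <= nyq & shell > 0
  sh <- shell[keep]
  num <- Re(Fa[keep] * Conj(Fb[keep]))
  pa <- Mod(Fa[keep])^2
  pb <- Mod(Fb[keep])^2
  t_num <- tapply(num, sh, sum)
  t_pa <- tapply(pa, sh, sum)
  t_pb <- tapply(pb, sh, sum)
  shells <- as.numeric(names(t_num))
  curve <- tibble::tibble(
    freq = (shells + 0.5) * shell_width / (d[1] * map_a$voxel_size),
    fsc = as.numeric(t_num / sqrt(t_pa * t_pb)),
    n_coef = as.integer(table(sh))
  )
  # self-comparison: define the zero shell as 1 by continuity
  structure(curve, class = c("fsc_curve", class(curve)))
}

#' Frequency at which an FSC curve crosses a criterion
#'
#' Reports the first crossing of the given criterion (default 0.143, the
#' conventional independent-half-map resolution cutoff) by linear
#' interpolation between shells, plus the FSC value at a stated check
#' frequency (default 1/10 per Angstrom, a common refinement-band sanity
#' check at medium resolution). Both numbers are reported; neither is chosen
#' silently.
#'
#' @param curve an [fsc()] result.
#' @param criterion FSC level defining the crossing.
#' @param check_freq frequency (1/Angstrom) at which to report the FSC value.
#' @return One-row tibble: `resolution_freq` (1/Angstrom; `NA` if no
#'   crossing), `resolution` (Angstrom), `criterion`, `fsc_at_check`,
#'   `check_freq`.
#' @export
fsc_resolution <- function(curve, criterion = 0.143, check_freq = 0.1) {
  below <- which(curve$fsc < criterion)
  if (length(below) == 0 || below[1] == 1) {
    rf <- NA_real_
  } else {
    i <- below[1]
    f1 <- curve$freq[i - 1]; f2 <- curve$freq[i]
    v1 <- curve$fsc[i - 1]; v2 <- curve$fsc[i]
    rf <- f1 + (criterion - v1) * (f2 - f1) / (v2 - v1)
  }
  fi <- which.min(abs(curve$freq - check_freq))
  tibble::tibble(resolution_freq = rf, resolution = 1 / rf,
                 criterion = criterion,
                 fsc_at_check = curve$fsc[fi], check_freq = check_freq)
}

#' Write an FSC curve as 2-column delimited text
#' @param curve an [fsc()] result.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fsc <- function(curve, path) {
  utils::write.table(curve[, c("freq", "fsc")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an FSC curve
#' @param object an [fsc()] result.
#' @param criterion horizontal reference line (default 0.143).
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.fsc_curve <- function(object, criterion = 0.143, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$freq, y = .data$fsc)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = criterion, linetype = "dashed") +
    ggplot2::labs(x = expression(paste("spatial frequency (", ring(A)^-1, ")")),
                  y = "Fourier shell correlation") +
    ggplot2::theme_minimal()
}

#' Plot per-pair constraint distances of a satisfaction report
#' @param object a [satisfaction()] report.
#' @param ... unused.
#' @return A ggplot object: pair distances vs rank with the threshold line.
#' @export
autoplot.satisfaction_report <- function(object, ...) {
  df <- object$distances[!is.na(object$distances$distance), ]
  df <- df[order(df$distance), ]
  df$rank <- seq_len(nrow(df))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$distance,
                                   colour = .data$satisfied)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = object$threshold, linetype = "dashed") +
    ggplot2::labs(x = "pair (sorted by distance)",
                  y = "CA-CA distance (Å)") +
    ggplot2::theme_minimal()
}

#' Gaussian low-pass filter a density map
#'
#' Convolution with an isotropic Gaussian kernel, computed in Fourier space
#' (multiplication by `exp(-2 pi^2 sigma^2 q^2)`). Standard pre-processing
#' before thresholding or segmenting noisy maps.
#'
#' @param map a [density_map()].
#' @param sigma kernel standard deviation in Angstrom.
#' @return The smoothed [density_map()].
#' @export
smooth_map <- function(map, sigma) {
  if (sigma <= 0) return(map)
  d <- dim(map$grid)
  fr <- lapply(1:3, function(k) {
    c(0:(d[k] %/% 2), -((d[k] - d[k] %/% 2 - 1):1)) / (d[k] * map$voxel_size)
  })
  q2 <- outer(outer(fr[[1]]^2, fr[[2]]^2, `+`), fr[[3]]^2, `+`)
  filt <- exp(-2 * pi^2 * sigma^2 * q2)
  sm <- Re(stats::fft(stats::fft(map$grid) * filt, inverse = TRUE)) /
    length(map$grid)
  density_map(sm, map$voxel_size, map$origin)
}
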