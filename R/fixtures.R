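#' Parameters of one synthetic sperm head
#'
#' Describes a rough-ellipse head: the base ellipse (semi-axes, orientation),
#' a low-order periodic boundary perturbation, interior intensity statistics
#' and an optional tail. All lengths are in pixels, intensities on the 0-255
#' gray scale, angles in radians.
#'
#' @param semi_major,semi_minor ellipse semi-axes; `semi_major >= semi_minor > 0`.
#' @param boundary_roughness amplitude of the periodic radial perturbation as
#'   a fraction of the local ellipse radius, in `[0, 0.5)`. 0 gives an exact
#'   discrete ellipse.
#' @param mean_intensity mean interior gray level; must be darker than the
#'   scene background.
#' @param intensity_noise_sd standard deviation of per-pixel Gaussian
#'   intensity noise inside the head.
#' @param orientation major-axis angle in radians (0 = along image columns).
#' @param tail_length tail length in pixels beyond the head boundary
#'   (0 = no tail).
#' @param axial_contrast peak-to-centre intensity difference of the axial
#'   gradient along the major axis (anterior acrosome brighter, posterior
#'   nucleus darker), in gray levels; 0 gives a flat interior.
#' @param texture_amp amplitude (gray levels) of the band-limited chromatin
#'   texture inside the head — smooth sinusoidal granularity at a 3-7 px
#'   wavelength, the pixel-scale structure a stained nucleus shows; 0 gives
#'   a texture-free interior.
#' @return a `head_params` list.
#' @export
head_params <- function(semi_major = 20, semi_minor = 13,
                        boundary_roughness = 0.02,
                        mean_intensity = 120, intensity_noise_sd = 6,
                        orientation = 0, tail_length = 0,
                        axial_contrast = 20, texture_amp = 12) {
  if (!(semi_major >= semi_minor && semi_minor > 0)) {
    stopf("need semi_major >= semi_minor > 0")
  }
  if (boundary_roughness < 0 || boundary_roughness >= 0.5) {
    stopf("boundary_roughness must lie in [0, 0.5)")
  }
  if (mean_intensity < 0 || mean_intensity > 255) {
    stopf("mean_intensity must lie in [0, 255]")
  }
  structure(list(semi_major = semi_major, semi_minor = semi_minor,
                 boundary_roughness = boundary_roughness,
                 mean_intensity = mean_intensity,
                 intensity_noise_sd = intensity_noise_sd,
                 orientation = orientation, tail_length = tail_length,
                 axial_contrast = axial_contrast, texture_amp = texture_amp),
            class = "head_params")
}

# Radius of the (possibly roughened) head boundary at polar angle theta,
# measured from the head centre. `rough` is a function theta -> [-1, 1].
head_radius <- function(params, theta, rough = NULL) {
  a <- params$semi_major; b <- params$semi_minor
  u <- theta - params$orientation
  r <- a * b / sqrt((b * cos(u))^2 + (a * sin(u))^2)
  if (!is.null(rough) && params$boundary_roughness > 0) {
    r <- r * (1 + params$boundary_roughness * rough(theta))
  }
  r
}

# Normalized low-order harmonic perturbation with seeded random phases.
# Low harmonics (2..5) keep the mask star-convex and connected.
make_roughness_fn <- function() {
  harmonics <- 2:5
  amp <- stats::runif(length(harmonics), 0.3, 1)
  phase <- stats::runif(length(harmonics), 0, 2 * pi)
  peak <- sum(amp)
  function(theta) {
    s <- 0
    for (i in seq_along(harmonics)) {
      s <- s + amp[i] * cos(harmonics[i] * theta + phase[i])
    }
    s / peak
  }
}

#' Render one synthetic sperm (head plus optional tail) on a canvas
#'
#' Draws a rough ellipse `r(theta) = r_ellipse(theta) * (1 + roughness *
#' periodic noise)` filled with noisy dark intensity on a uniform bright
#' background, and attaches a thin curved tail at the rear of the head.
#' Identical `(params, seed)` give bit-identical output.
#'
#' @param params a [head_params()] object.
#' @param canvas `c(height, width)` of the output image in pixels.
#' @param seed integer seed for the boundary-noise phases and intensity noise.
#' @param center head centre `c(row, col)`; defaults to the canvas centre.
#' @param background background gray level (default 230).
#' @return list with `image` (`gray_image`, background everywhere except the
#'   sperm), `mask` (logical matrix, head plus tail, one 8-connected
#'   component) and `head_mask` (logical matrix, head only).
#' @export
generate_head <- function(params, canvas = c(96, 96), seed = 1,
                          center = NULL, background = 230) {
  stopifnot(inherits(params, "head_params"))
  h <- canvas[1]; w <- canvas[2]
  if (is.null(center)) center <- c((h + 1) / 2, (w + 1) / 2)
  if (params$mean_intensity >= background) {
    stopf("mean_intensity (%g) must be below background (%g)",
          params$mean_intensity, background)
  }
  max_r <- params$semi_major * (1 + params$boundary_roughness)
  reach <- max_r + params$tail_length + 6  # bend margin for the tail
  if (center[1] - reach < 1 || center[1] + reach > h ||
      center[2] - reach < 1 || center[2] + reach > w) {
    stopf("head (reach %.1f px from centre) does not fit canvas %dx%d",
          reach, h, w)
  }

  with_seed(seed, {
    rough <- if (params$boundary_roughness > 0) make_roughness_fn() else NULL

    rr <- matrix(seq_len(h), h, w) - center[1]
    cc <- matrix(seq_len(w), h, w, byrow = TRUE) - center[2]
    d <- sqrt(rr^2 + cc^2)
    theta <- atan2(rr, cc)
    head_mask <- d <= head_radius(params, theta, rough)

    mask <- head_mask
    if (params$tail_length > 0) {
      tail_px <- rasterize_tail(params, center, h, w)
      mask[tail_px] <- TRUE
    }

    img <- matrix(background, h, w)
    n_in <- sum(mask)
    # axial acrosome/nucleus gradient: anterior (along +orientation) is
    # brighter, posterior darker, linear in the major-axis coordinate
    axial <- (cc[mask] * cos(params$orientation) +
              rr[mask] * sin(params$orientation)) / params$semi_major
    axial <- pmin(pmax(axial, -1), 1)
    # chromatin texture: a few sinusoidal plane waves, wavelength 3-7 px
    texture <- 0
    if (params$texture_amp > 0) {
      texture <- numeric(n_in)
      for (k in 1:3) {
        ang <- stats::runif(1, 0, pi)
        lambda <- stats::runif(1, 3, 7)
        phase <- stats::runif(1, 0, 2 * pi)
        texture <- texture + sin(2 * pi * (rr[mask] * sin(ang) +
                                           cc[mask] * cos(ang)) / lambda + phase)
      }
      texture <- params$texture_amp * texture / 3
    }
    noisy <- params$mean_intensity + params$axial_contrast * axial + texture +
      stats::rnorm(n_in, 0, params$intensity_noise_sd)
    # clamp so every sperm pixel stays visibly darker than the background
    noisy <- pmin(pmax(noisy, 0), background - 20)
    img[mask] <- noisy
    list(image = as_gray_image(img), mask = mask, head_mask = head_mask)
  })
}

# Pixels of a thin curved tail leaving the head opposite its orientation.
# Width 2-3 px (disc radius 1 stamped along a sinusoidally bent line).
rasterize_tail <- function(params, center, h, w) {
  dir <- params$orientation + pi          # rear of the head
  t_seq <- seq(0, params$tail_length, by = 0.5)
  bend_amp <- stats::runif(1, 0.05, 0.12) * params$tail_length
  bend_phase <- stats::runif(1, 0, 2 * pi)
  # anchor just inside the boundary so the tail is 8-connected to the head
  r0 <- head_radius(params, dir) - 1
  perp <- dir + pi / 2
  rows <- center[1] + (r0 + t_seq) * sin(dir) +
    bend_amp * sin(pi * t_seq / params$tail_length + bend_phase) * sin(perp)
  cols <- center[2] + (r0 + t_seq) * cos(dir) +
    bend_amp * sin(pi * t_seq / params$tail_length + bend_phase) * cos(perp)
  offs <- expand.grid(dr = -1:1, dc = -1:1)
  offs <- offs[offs$dr^2 + offs$dc^2 <= 1, ]   # plus-shaped pen, ~2-3 px wide
  pr <- as.vector(outer(round(rows), offs$dr, `+`))
  pc <- as.vector(outer(round(cols), offs$dc, `+`))
  keep <- pr >= 1 & pr <= h & pc >= 1 & pc <= w
  cbind(pr[keep], pc[keep])
}

#' Default synthetic-scene configuration
#'
#' The generator's stated world: bright background near gray 230 with mild
#' sensor noise; normal heads are smooth ovals with long/short axis ratio
#' uniform in (1.25, 1.75) and mid-dark chromatin; abnormal heads are an
#' equal mixture of too-round (ratio < 1.15), too-slim (ratio > 1.9),
#' irregular-boundary (roughness > 0.25) and abnormal-darkness (too pale or
#' too dark) types. Intensity ranges are free parameters of the generator
#' (no published intensity statistics exist for the source imagery).
#'
#' @param ... overrides of individual defaults.
#' @return a named list of generator settings.
#' @export
scene_config <- function(...) {
  cfg <- list(
    background = 230, background_noise_sd = 2,
    semi_major_range = c(16, 24),
    normal_ratio_range = c(1.25, 1.75),
    normal_roughness_range = c(0, 0.05),
    normal_intensity_range = c(105, 135),
    round_ratio_range = c(1.0, 1.15),
    slim_ratio_range = c(1.9, 2.3),
    rough_roughness_range = c(0.28, 0.40),
    pale_intensity_range = c(190, 208),
    dark_intensity_range = c(20, 60),
    intensity_noise_sd = 6,
    tail_length_range = c(14, 22),
    cell_size = 140, jitter = 5, max_retries = 25
  )
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad)) stopf("unknown scene_config keys: %s", paste(bad, collapse = ", "))
  cfg[names(dots)] <- dots
  cfg
}

draw_normal_params <- function(cfg) {
  a <- stats::runif(1, cfg$semi_major_range[1], cfg$semi_major_range[2])
  ratio <- stats::runif(1, cfg$normal_ratio_range[1], cfg$normal_ratio_range[2])
  head_params(
    semi_major = a, semi_minor = a / ratio,
    boundary_roughness = stats::runif(1, cfg$normal_roughness_range[1],
                                      cfg$normal_roughness_range[2]),
    mean_intensity = stats::runif(1, cfg$normal_intensity_range[1],
                                  cfg$normal_intensity_range[2]),
    intensity_noise_sd = cfg$intensity_noise_sd,
    orientation = stats::runif(1, 0, pi),
    tail_length = stats::runif(1, cfg$tail_length_range[1],
                               cfg$tail_length_range[2])
  )
}

draw_abnormal_params <- function(cfg) {
  kind <- sample(c("round", "slim", "rough", "darkness"), 1)
  a <- stats::runif(1, cfg$semi_major_range[1], cfg$semi_major_range[2])
  ratio <- switch(kind,
    round = stats::runif(1, cfg$round_ratio_range[1], cfg$round_ratio_range[2]),
    slim = stats::runif(1, cfg$slim_ratio_range[1], cfg$slim_ratio_range[2]),
    stats::runif(1, cfg$normal_ratio_range[1], cfg$normal_ratio_range[2])
  )
  roughness <- if (kind == "rough") {
    stats::runif(1, cfg$rough_roughness_range[1], cfg$rough_roughness_range[2])
  } else {
    stats::runif(1, cfg$normal_roughness_range[1], cfg$normal_roughness_range[2])
  }
  intensity <- if (kind == "darkness") {
    if (stats::runif(1) < 0.5) {
      stats::runif(1, cfg$pale_intensity_range[1], cfg$pale_intensity_range[2])
    } else {
      stats::runif(1, cfg$dark_intensity_range[1], cfg$dark_intensity_range[2])
    }
  } else {
    stats::runif(1, cfg$normal_intensity_range[1], cfg$normal_intensity_range[2])
  }
  p <- head_params(
    semi_major = a, semi_minor = a / ratio,
    boundary_roughness = roughness,
    mean_intensity = intensity,
    intensity_noise_sd = cfg$intensity_noise_sd,
    orientation = stats::runif(1, 0, pi),
    tail_length = stats::runif(1, cfg$tail_length_range[1],
                               cfg$tail_length_range[2])
  )
  attr(p, "abnormal_kind") <- kind
  p
}

#' Generate a synthetic micrograph scene with ground truth
#'
#' Places `n_normal + n_abnormal` non-overlapping sperms on a bright noisy
#' canvas, one per cell of a jittered grid, and returns the image together
#' with per-sperm masks, labels and parameters. Fully deterministic given
#' `(n_normal, n_abnormal, seed, config)`.
#'
#' @param n_normal,n_abnormal number of sperms of each class.
#' @param seed integer seed governing every random choice in the scene.
#' @param config a [scene_config()] list.
#' @return a `synthetic_scene` list: `image`, `labels` (character vector
#'   `"normal"`/`"abnormal"`), `params`, `masks` and `head_masks` (lists of
#'   `list(mask, origin)` cropped masks), `label_image` and
#'   `head_label_image` (integer matrices, 0 = background, i = sperm i), and
#'   `seed`.
#' @export
generate_scene <- function(n_normal, n_abnormal, seed = 1,
                           config = scene_config()) {
  if (!is_count(n_normal) || !is_count(n_abnormal)) {
    stopf("counts must be non-negative integers")
  }
  n <- n_normal + n_abnormal
  cfg <- config
  with_seed(seed, {
    if (n == 0L) {
      img <- matrix(cfg$background, 64, 64) +
        stats::rnorm(64 * 64, 0, cfg$background_noise_sd)
      img <- pmin(pmax(img, 0), 255)
      return(structure(list(image = as_gray_image(img), labels = character(),
                            params = list(), masks = list(), head_masks = list(),
                            label_image = matrix(0L, 64, 64),
                            head_label_image = matrix(0L, 64, 64), seed = seed),
                       class = "synthetic_scene"))
    }
    ncol_grid <- ceiling(sqrt(n))
    nrow_grid <- ceiling(n / ncol_grid)
    cs <- cfg$cell_size
    h <- nrow_grid * cs; w <- ncol_grid * cs

    labels <- sample(rep(c("normal", "abnormal"), c(n_normal, n_abnormal)))
    cells <- sample(nrow_grid * ncol_grid, n)

    img <- matrix(cfg$background, h, w)
    label_image <- matrix(0L, h, w)
    head_label_image <- matrix(0L, h, w)
    params <- vector("list", n)
    masks <- vector("list", n)
    head_masks <- vector("list", n)

    for (i in seq_len(n)) {
      cell_r <- (cells[i] - 1) %/% ncol_grid
      cell_c <- (cells[i] - 1) %% ncol_grid
      placed <- FALSE
      for (try in seq_len(cfg$max_retries)) {
        p <- if (labels[i] == "normal") draw_normal_params(cfg) else
          draw_abnormal_params(cfg)
        jit <- stats::runif(2, -cfg$jitter, cfg$jitter)
        center <- c(cell_r * cs + cs / 2 + jit[1],
                    cell_c * cs + cs / 2 + jit[2])
        sub_seed <- sample.int(.Machine$integer.max, 1)
        res <- tryCatch(
          generate_head(p, canvas = c(h, w), seed = sub_seed,
                        center = center, background = cfg$background),
          error = function(e) NULL)
        if (is.null(res)) next
        if (any(label_image[res$mask] != 0L)) next   # overlap: retry
        placed <- TRUE
        label_image[res$mask] <- i
        head_label_image[res$head_mask] <- i
        img[res$mask] <- res$image[res$mask]
        params[[i]] <- p
        masks[[i]] <- crop_logical(res$mask)
        head_masks[[i]] <- crop_logical(res$head_mask)
        break
      }
      if (!placed) stopf("could not place sperm %d without overlap", i)
    }

    bg <- label_image == 0L
    img[bg] <- img[bg] + stats::rnorm(sum(bg), 0, cfg$background_noise_sd)
    img <- pmin(pmax(img, 0), 255)

    structure(list(image = as_gray_image(img), labels = labels,
                   params = params, masks = masks, head_masks = head_masks,
                   label_image = label_image,
                   head_label_image = head_label_image, seed = seed),
              class = "synthetic_scene")
  })
}

# Store a full-canvas logical mask as its bounding-box crop plus origin.
crop_logical <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  r1 <- min(idx[, 1]); r2 <- max(idx[, 1])
  c1 <- min(idx[, 2]); c2 <- max(idx[, 2])
  list(mask = mask[r1:r2, c1:c2, drop = FALSE], origin = c(r1, c1))
}

#' Expand a cropped scene mask back to full-canvas size
#'
#' @param scene a `synthetic_scene`.
#' @param i sperm index.
#' @param head if `TRUE`, the head-only mask; otherwise head plus tail.
#' @return logical matrix the size of `scene$image`.
#' @export
scene_mask <- function(scene, i, head = FALSE) {
  src <- if (head) scene$head_masks[[i]] else scene$masks[[i]]
  out <- matrix(FALSE, nrow(scene$image), ncol(scene$image))
  r <- src$origin[1]; c0 <- src$origin[2]
  out[r:(r + nrow(src$mask) - 1), c0:(c0 + ncol(src$mask) - 1)] <- src$mask
  out
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf("<synthetic_scene> %d x %d px, %d sperms (%d normal, %d abnormal), seed %d\n",
              nrow(x$image), ncol(x$image), length(x$labels),
              sum(x$labels == "normal"), sum(x$labels == "abnormal"), x$seed))
  invisible(x)
}

#' Write a scene to disk as an image plus a CSV manifest
#'
#' @param scene a `synthetic_scene`.
#' @param dir output directory (created if missing).
#' @param format image format, `"pgm"` (default) or `"png"`.
#' @return the manifest data frame, invisibly.
#' @export
write_scene <- function(scene, dir, format = "pgm") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  img_path <- file.path(dir, paste0("scene.", format))
  write_gray_image(scene$image, img_path)
  n <- length(scene$labels)
  manifest <- data.frame(
    image_path = rep(basename(img_path), n),
    sperm_id = seq_len(n),
    label = scene$labels,
    seed = rep(scene$seed, n)
  )
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}
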