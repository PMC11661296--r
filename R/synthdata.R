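# Synthetic phantom generator: scenes with known ground truth emulating the
# experimental inputs of the three imaging pipelines, plus model-based
# binding-curve and rate time-series simulators.

#' Confocal acquisition model for phantom rendering
#'
#' Parameters of the simulated acquisition applied to every phantom scene:
#' Gaussian point-spread-function blur, a low-frequency multiplicative
#' shading gradient, Poisson shot noise on the signal followed by additive
#' Gaussian read noise (the standard EMCCD approximation), and a constant
#' background offset. Rendered images are rounded to non-negative integer
#' camera counts. The same seed and parameters always produce the identical
#' image.
#'
#' @param psf_sigma_px Lateral PSF standard deviation in pixels (>= 0).
#' @param gaussian_noise_sd Additive read-noise standard deviation (>= 0).
#' @param poisson_scale Photons per intensity unit for shot noise; 0 disables
#'   the Poisson component.
#' @param background_level Constant background offset added before noise.
#' @param shading_amplitude Peak-to-peak relative amplitude of a linear
#'   multiplicative shading gradient, in `[0, 1)`.
#' @param seed Integer seed consumed by the scene generators.
#' @return An object of class `acquisition_model`.
#' @export
acquisition_model <- function(psf_sigma_px = 1, gaussian_noise_sd = 2,
                              poisson_scale = 1, background_level = 10,
                              shading_amplitude = 0, seed = 1L) {
  stopifnot(psf_sigma_px >= 0, gaussian_noise_sd >= 0, poisson_scale >= 0,
            background_level >= 0,
            shading_amplitude >= 0, shading_amplitude < 1)
  structure(
    list(psf_sigma_px = psf_sigma_px, gaussian_noise_sd = gaussian_noise_sd,
         poisson_scale = poisson_scale, background_level = background_level,
         shading_amplitude = shading_amplitude, seed = as.integer(seed)),
    class = "acquisition_model"
  )
}

#' Noise-free acquisition (construction checks, oracles)
#' @inheritParams acquisition_model
#' @return An `acquisition_model` with blur and noise disabled.
#' @export
acquisition_clean <- function(background_level = 0, seed = 1L) {
  acquisition_model(psf_sigma_px = 0, gaussian_noise_sd = 0, poisson_scale = 0,
                    background_level = background_level, shading_amplitude = 0,
                    seed = seed)
}

# Render one volume through the acquisition model. RNG must be seeded by the
# calling scene generator; the result is integer camera counts.
apply_acquisition <- function(vol, acq, calibration) {
  vol <- vol + acq$background_level
  if (acq$psf_sigma_px > 0) {
    vol <- gaussian_blur3d(vol, acq$psf_sigma_px, calibration)
  }
  if (acq$shading_amplitude > 0) {
    d <- dim(vol)
    sx <- 1 + acq$shading_amplitude * ((seq_len(d[2]) - 1) / max(1, d[2] - 1) - 0.5)
    vol <- vol * rep(sx, each = d[1])
  }
  if (acq$poisson_scale > 0) {
    vol[] <- stats::rpois(length(vol), pmax(vol, 0) * acq$poisson_scale) / acq$poisson_scale
  }
  if (acq$gaussian_noise_sd > 0) {
    vol <- vol + stats::rnorm(length(vol), sd = acq$gaussian_noise_sd)
  }
  vol[] <- pmax(round(vol), 0)
  vol
}

# Normalized ellipsoid radius field for one z-slice (pixel-centered, 0-based
# physical coordinates), on the anisotropic voxel grid.
rho_slice <- function(ny, nx, z_um, center_um, semi_um, cal) {
  y <- ((seq_len(ny) - 1) * cal$dy - center_um[1]) / semi_um[1]
  x <- ((seq_len(nx) - 1) * cal$dx - center_um[2]) / semi_um[2]
  zz <- ((z_um - center_um[3]) / semi_um[3])^2
  sqrt(outer(y^2, x^2, "+") + zz)
}

#' Ellipsoidal nucleus phantom
#'
#' Geometry and per-frame intensities of one synthetic nucleus: a bright
#' membrane rim of fixed pixel thickness around a dimmer nucleoplasmic
#' interior. The rim/interior amplitude ratio is the ground-truth binding
#' signal.
#'
#' @param center_um Centre (y, x, z) in micrometres.
#' @param semi_um Semi-axes (y, x, z) in micrometres.
#' @param rim_intensity Per-frame rim amplitude (recycled if scalar); > 0.
#' @param interior_intensity Per-frame interior amplitude; > 0.
#' @param rim_thickness_px Rim thickness in pixels (default 5).
#' @param drift_um_per_frame Lateral drift velocity (y, x) in um/frame.
#' @return An object of class `nucleus_phantom`.
#' @export
nucleus_phantom <- function(center_um, semi_um, rim_intensity = 300,
                            interior_intensity = 150, rim_thickness_px = 5,
                            drift_um_per_frame = c(0, 0)) {
  stopifnot(length(center_um) == 3, length(semi_um) == 3, all(semi_um > 0),
            all(rim_intensity > 0), all(interior_intensity > 0),
            rim_thickness_px > 0)
  structure(
    list(center_um = center_um, semi_um = semi_um,
         rim_intensity = rim_intensity, interior_intensity = interior_intensity,
         rim_thickness_px = rim_thickness_px,
         drift_um_per_frame = drift_um_per_frame),
    class = "nucleus_phantom"
  )
}

#' Synthetic GUV scene
#'
#' Renders a single spherical shell (the GUV membrane rim, amplitude
#' `rim_amp`) with a uniform interior amplitude over the background, and
#' records the analytic rim circle per z-slice plus a voxel label volume as
#' ground truth. Without PSF or noise, shell voxels equal
#' `rim_amp + background`.
#'
#' @param radius_um GUV radius in micrometres; must resolve to >= 3 pixels.
#' @param rim_amp Shell amplitude.
#' @param interior_amp Interior amplitude.
#' @param acq An [acquisition_model()].
#' @param calibration A [pixel_calibration()].
#' @param img_px Optional c(Y, X) image size in pixels (auto-sized if NULL).
#' @return List with `stack` ([image_stack()], one probe channel) and
#'   `truth` (label volume, per-slice rim circles, true middle slice).
#' @export
make_guv_scene <- function(radius_um = 10, rim_amp = 100, interior_amp = 5,
                           acq = acquisition_model(),
                           calibration = pixel_calibration(),
                           img_px = NULL) {
  r_px <- radius_um / calibration$dx
  if (r_px < 3) stop("GUV radius below resolvable size (< 3 px)")
  if (is.null(img_px)) {
    n <- 2L * ceiling(r_px * 1.6)
    img_px <- c(n, n)
  }
  ny <- img_px[1]; nx <- img_px[2]
  nz <- max(3L, 2L * ceiling(radius_um / calibration$dz) + 3L)
  center_um <- c((ny - 1) / 2 * calibration$dy, (nx - 1) / 2 * calibration$dx,
                 (nz - 1) / 2 * calibration$dz)
  set.seed(acq$seed)
  vol <- array(0, c(ny, nx, nz))
  labels <- array(0L, c(ny, nx, nz))
  thick_norm <- acq_shell_thickness(radius_um, calibration)
  rim_circles <- data.frame(z = integer(0), center_y_px = numeric(0),
                            center_x_px = numeric(0), radius_px = numeric(0))
  for (z in seq_len(nz)) {
    z_um <- (z - 1) * calibration$dz
    rho <- rho_slice(ny, nx, z_um, center_um, rep(radius_um, 3), calibration)
    sl <- matrix(0, ny, nx)
    sl[rho <= 1 - thick_norm] <- interior_amp
    sl[rho > 1 - thick_norm & rho <= 1] <- rim_amp
    vol[, , z] <- sl
    labels[, , z][rho <= 1] <- 1L
    dz_um <- z_um - center_um[3]
    if (abs(dz_um) < radius_um) {
      rz_um <- sqrt(radius_um^2 - dz_um^2)
      rim_circles <- rbind(rim_circles, data.frame(
        z = z, center_y_px = center_um[1] / calibration$dy + 1,
        center_x_px = center_um[2] / calibration$dx + 1,
        radius_px = rz_um / calibration$dx
      ))
    }
  }
  rendered <- apply_acquisition(vol, acq, calibration)
  stack <- image_stack(to_tczyx(rendered), calibration, channel_roles = "probe")
  truth <- list(labels = labels, rim_circles = rim_circles,
                middle_slice = which.min(abs((seq_len(nz) - 1) * calibration$dz -
                                               center_um[3])),
                center_um = center_um, radius_um = radius_um,
                rim_amp = rim_amp, interior_amp = interior_amp,
                noiseless = vol + acq$background_level)
  list(stack = stack, truth = truth)
}

# shell thickness (normalized radius units) of ~2 px for GUV rendering
acq_shell_thickness <- function(radius_um, cal) {
  2 * cal$dx / radius_um
}

# [y,x,z] volume (or list of volumes as channels / frames) -> T,C,Z,Y,X array
to_tczyx <- function(vol, channels = NULL, frames = NULL) {
  if (is.null(channels) && is.null(frames)) {
    d <- dim(vol)
    arr <- array(0, c(1, 1, d[3], d[1], d[2]))
    arr[1, 1, , , ] <- aperm(vol, c(3, 1, 2))
    return(arr)
  }
  stop("internal: use assemble_stack for multi-frame scenes")
}

#' Synthetic nucleus time lapse
#'
#' Renders a list of non-overlapping [nucleus_phantom()]s over `n_frames`
#' frames in a probe channel, optionally adding a nuclear-envelope reference
#' channel ("lamin") whose rim amplitude is constant over time. Ground truth
#' stores the voxel label volume of every frame and the per-nucleus
#' rim/interior amplitude ratio series.
#'
#' @param phantoms List of [nucleus_phantom()] objects.
#' @param n_frames Number of frames.
#' @param acq An [acquisition_model()].
#' @param calibration A [pixel_calibration()].
#' @param img_px c(Y, X) image size in pixels.
#' @param n_z Number of z-planes.
#' @param lamin_rim_amp Rim amplitude of the reference channel, or NULL to
#'   omit the channel.
#' @return List with `stack` and `truth` (per-frame labels, ratio matrix
#'   phantoms x frames, per-frame centres, track identities).
#' @export
make_nucleus_timelapse <- function(phantoms, n_frames = 10,
                                   acq = acquisition_model(),
                                   calibration = pixel_calibration(),
                                   img_px = c(160, 160), n_z = 9,
                                   lamin_rim_amp = NULL) {
  if (inherits(phantoms, "nucleus_phantom")) phantoms <- list(phantoms)
  stopifnot(length(phantoms) >= 1, n_frames >= 1)
  ny <- img_px[1]; nx <- img_px[2]; nz <- n_z
  np <- length(phantoms)
  set.seed(acq$seed)
  get_amp <- function(v, t) if (length(v) >= n_frames) v[t] else v[1]
  labels <- vector("list", n_frames)
  ratio <- matrix(0, np, n_frames)
  centers <- vector("list", n_frames)
  probe_frames <- vector("list", n_frames)
  lamin_frames <- if (!is.null(lamin_rim_amp)) vector("list", n_frames) else NULL
  for (t in seq_len(n_frames)) {
    lab <- array(0L, c(ny, nx, nz))
    volp <- array(0, c(ny, nx, nz))
    voll <- if (!is.null(lamin_rim_amp)) array(0, c(ny, nx, nz)) else NULL
    ctr <- matrix(0, np, 3)
    for (i in seq_len(np)) {
      ph <- phantoms[[i]]
      c_um <- ph$center_um + c((t - 1) * ph$drift_um_per_frame[1:2], 0)
      ctr[i, ] <- c_um
      t_norm <- ph$rim_thickness_px * calibration$dx / mean(ph$semi_um[1:2])
      rim_a <- get_amp(ph$rim_intensity, t)
      int_a <- get_amp(ph$interior_intensity, t)
      ratio[i, t] <- rim_a / int_a
      for (z in seq_len(nz)) {
        z_um <- (z - 1) * calibration$dz
        rho <- rho_slice(ny, nx, z_um, c_um, ph$semi_um, calibration)
        inside <- rho <= 1
        if (!any(inside)) next
        prev <- lab[, , z]
        clash <- inside & prev > 0L
        if (any(clash)) {
          stop(sprintf("phantom nuclei %d and %d overlap at frame %d",
                       unique(prev[clash])[1], i, t))
        }
        prev[inside] <- i
        lab[, , z] <- prev
        sl <- volp[, , z]
        sl[inside & rho > 1 - t_norm] <- rim_a
        sl[rho <= 1 - t_norm] <- int_a
        volp[, , z] <- sl
        if (!is.null(voll)) {
          sll <- voll[, , z]
          sll[inside & rho > 1 - t_norm] <- lamin_rim_amp
          sll[rho <= 1 - t_norm] <- lamin_rim_amp * 0.2
          voll[, , z] <- sll
        }
      }
    }
    labels[[t]] <- lab
    centers[[t]] <- ctr
    probe_frames[[t]] <- apply_acquisition(volp, acq, calibration)
    if (!is.null(voll)) lamin_frames[[t]] <- apply_acquisition(voll, acq, calibration)
  }
  nc <- if (is.null(lamin_frames)) 1L else 2L
  arr <- array(0, c(n_frames, nc, nz, ny, nx))
  for (t in seq_len(n_frames)) {
    arr[t, 1, , , ] <- aperm(probe_frames[[t]], c(3, 1, 2))
    if (nc == 2L) arr[t, 2, , , ] <- aperm(lamin_frames[[t]], c(3, 1, 2))
  }
  roles <- if (nc == 2L) c("probe", "lamin") else "probe"
  stack <- image_stack(arr, calibration, channel_roles = roles)
  truth <- list(labels = labels, ratio = ratio, centers_um = centers,
                track_ids = seq_len(np))
  list(stack = stack, truth = truth)
}

#' ER phantom description
#'
#' @param mode `"tubular"` (elongated capsule tubules), `"vesiculated"`
#'   (disjoint quasi-spherical vesicles) or `"mixed"`.
#' @param mixed_fraction Fraction of vesicles in mixed mode.
#' @param n_objects Number of objects to place.
#' @param tubule_length_um Range (min, max) of tubule lengths.
#' @param tubule_width_um Tubule width.
#' @param vesicle_radius_um Range (min, max) of vesicle radii.
#' @return An object of class `er_phantom`.
#' @export
er_phantom <- function(mode = c("tubular", "vesiculated", "mixed"),
                       mixed_fraction = 0.5, n_objects = 30,
                       tubule_length_um = c(8, 16), tubule_width_um = 0.48,
                       vesicle_radius_um = c(0.6, 1.3)) {
  mode <- match.arg(mode)
  stopifnot(n_objects >= 1, mixed_fraction >= 0, mixed_fraction <= 1)
  structure(
    list(mode = mode, mixed_fraction = mixed_fraction, n_objects = n_objects,
         tubule_length_um = tubule_length_um, tubule_width_um = tubule_width_um,
         vesicle_radius_um = vesicle_radius_um),
    class = "er_phantom"
  )
}

#' Synthetic ER scene on a 2D analysis plane
#'
#' Places non-overlapping tubules (capsules: rectangles with semicircular
#' caps) and/or vesicles (discs) at random positions and orientations,
#' renders them through the acquisition model, and records per-object
#' analytic area, perimeter and circularity as ground truth. By generator
#' construction the true median circularity of a vesiculated scene exceeds a
#' tubular one's.
#'
#' @param phantom An [er_phantom()].
#' @param acq An [acquisition_model()].
#' @param calibration A [pixel_calibration()].
#' @param img_px c(Y, X) plane size in pixels.
#' @param amplitude Object fluorescence amplitude.
#' @return List with `stack` (single-z [image_stack()]) and `truth`
#'   (label plane and per-object analytic geometry table).
#' @export
make_er_scene <- function(phantom, acq = acquisition_model(),
                          calibration = pixel_calibration(),
                          img_px = c(256, 256), amplitude = 150) {
  stopifnot(inherits(phantom, "er_phantom"))
  ny <- img_px[1]; nx <- img_px[2]
  dx <- calibration$dx
  set.seed(acq$seed)
  types <- switch(phantom$mode,
    tubular = rep("tubule", phantom$n_objects),
    vesiculated = rep("vesicle", phantom$n_objects),
    mixed = ifelse(stats::runif(phantom$n_objects) < phantom$mixed_fraction,
                   "vesicle", "tubule")
  )
  lab <- matrix(0L, ny, nx)
  occupied <- matrix(FALSE, ny, nx) # objects + clearance margin
  yy <- matrix(seq_len(ny), ny, nx)
  xx <- matrix(seq_len(nx), ny, nx, byrow = TRUE)
  margin_px <- 3
  objects <- list()
  id <- 0L
  for (k in seq_along(types)) {
    placed <- FALSE
    for (try in seq_len(200)) {
      if (types[k] == "vesicle") {
        r_um <- stats::runif(1, phantom$vesicle_radius_um[1], phantom$vesicle_radius_um[2])
        r_px <- r_um / dx
        cy <- stats::runif(1, r_px + 2, ny - r_px - 1)
        cx <- stats::runif(1, r_px + 2, nx - r_px - 1)
        dist <- sqrt((yy - cy)^2 + (xx - cx)^2)
        m <- dist <= r_px
        m_marg <- dist <= r_px + margin_px
        geom <- list(type = "vesicle",
                     area_um2 = pi * r_um^2, perimeter_um = 2 * pi * r_um)
      } else {
        L_um <- stats::runif(1, phantom$tubule_length_um[1], phantom$tubule_length_um[2])
        w_um <- phantom$tubule_width_um
        L <- L_um / dx; w <- w_um / dx
        th <- stats::runif(1, 0, pi)
        pad <- L / 2 + w + 2
        cy <- stats::runif(1, pad, ny - pad)
        cx <- stats::runif(1, pad, nx - pad)
        ay <- cy - sin(th) * L / 2; ax <- cx - cos(th) * L / 2
        by <- cy + sin(th) * L / 2; bx <- cx + cos(th) * L / 2
        dist <- dist_to_segment(yy, xx, ay, ax, by, bx)
        m <- dist <= w / 2
        m_marg <- dist <= w / 2 + margin_px
        geom <- list(type = "tubule",
                     area_um2 = L_um * w_um + pi * (w_um / 2)^2,
                     perimeter_um = 2 * L_um + pi * w_um)
      }
      if (!any(m & occupied) && any(m)) {
        id <- id + 1L
        lab[m] <- id
        occupied <- occupied | m_marg
        objects[[id]] <- data.frame(
          id = id, type = geom$type,
          area_um2 = geom$area_um2, perimeter_um = geom$perimeter_um,
          circularity = 4 * pi * geom$area_um2 / geom$perimeter_um^2
        )
        placed <- TRUE
        break
      }
    }
  }
  if (id == 0L) stop("ER phantom produced zero objects")
  objects <- do.call(rbind, objects)
  vol <- array(0, c(ny, nx, 1))
  vol[, , 1][lab > 0L] <- amplitude
  rendered <- apply_acquisition(vol, acq, calibration)
  role <- if (phantom$mode == "tubular") "er_membrane" else "er_luminal"
  stack <- image_stack(to_tczyx(rendered), calibration, channel_roles = role)
  list(stack = stack,
       truth = list(labels = lab, objects = objects, mode = phantom$mode))
}

dist_to_segment <- function(yy, xx, ay, ax, by, bx) {
  vy <- by - ay; vx <- bx - ax
  len2 <- vy^2 + vx^2
  tt <- ((yy - ay) * vy + (xx - ax) * vx) / len2
  tt <- pmin(pmax(tt, 0), 1)
  sqrt((yy - (ay + tt * vy))^2 + (xx - (ax + tt * vx))^2)
}

#' Simulate an equilibrium binding curve
#'
#' Evaluates the Hill-expanded Langmuir isotherm
#' `bound = bmax * c^h / (c^h + kd^h)` at the given concentrations and adds
#' Gaussian noise.
#'
#' @param bmax Saturation amplitude (> 0).
#' @param kd Apparent dissociation constant in nM (> 0).
#' @param h Hill coefficient (> 0).
#' @param concentrations Non-negative concentrations in nM.
#' @param noise_sd Additive Gaussian noise standard deviation.
#' @param seed Integer seed.
#' @return data.frame with columns `concentration`, `bound`.
#' @examples
#' simulate_binding_curve(1, 100, 2, c(0, 50, 100, 500), noise_sd = 0)
#' @export
simulate_binding_curve <- function(bmax, kd, h, concentrations,
                                   noise_sd = 0, seed = 1L) {
  stopifnot(bmax > 0, kd > 0, h > 0)
  if (any(concentrations < 0)) stop("concentrations must be non-negative")
  set.seed(seed)
  mu <- hill_response(concentrations, bmax, kd, h)
  bound <- mu + if (noise_sd > 0) stats::rnorm(length(mu), sd = noise_sd) else 0
  data.frame(concentration = concentrations, bound = bound)
}

#' Hill-Langmuir response function
#' @param conc Concentrations (nM).
#' @param bmax,kd,h Model parameters.
#' @return Bound signal at each concentration.
#' @export
hill_response <- function(conc, bmax, kd, h) {
  ch <- conc^h
  bmax * ch / (ch + kd^h)
}

#' Simulate a piecewise-linear binding-ratio time series
#'
#' Flat baseline, a linear rise of the given slope between the two
#' breakpoints, then a plateau, plus Gaussian noise. The ground-truth slope
#' and window are stored as attributes.
#'
#' @param baseline Baseline ratio value.
#' @param slope Rise per frame (sign unrestricted).
#' @param t_linear_start,t_plateau Breakpoint frames, `0 <= start < plateau
#'   <= n_frames`.
#' @param n_frames Number of frames.
#' @param noise_sd Additive noise SD.
#' @param seed Integer seed.
#' @param dt Minutes per frame.
#' @return A `binding_time_series` data.frame with columns `time`, `ratio`,
#'   `ratio_norm`.
#' @export
simulate_rate_timeseries <- function(baseline = 1, slope = 0.1,
                                     t_linear_start = 5, t_plateau = 15,
                                     n_frames = 20, noise_sd = 0, seed = 1L,
                                     dt = 1) {
  if (!(t_linear_start >= 0 && t_linear_start < t_plateau && t_plateau <= n_frames)) {
    stop("invalid breakpoints: need 0 <= t_linear_start < t_plateau <= n_frames")
  }
  set.seed(seed)
  tt <- seq_len(n_frames) - 1
  y <- baseline + slope * pmin(pmax(tt - t_linear_start, 0), t_plateau - t_linear_start)
  if (noise_sd > 0) y <- y + stats::rnorm(n_frames, sd = noise_sd)
  out <- data.frame(time = tt * dt, ratio = y, ratio_norm = y / y[1])
  attr(out, "true_slope") <- slope
  attr(out, "true_window") <- c(t_linear_start, t_plateau)
  class(out) <- c("binding_time_series", "data.frame")
  out
}
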