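# Seeded phantom generator: bead calibration fields, multi-structure tissue
# phantoms with paired SRS / fluorescence channels, and pre/post-expansion
# pairs, all carrying full ground truth.

# Run code under a fixed seed without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

gaussian_kernel1d <- function(sigma_px) {
  r <- max(1L, ceiling(4 * sigma_px))
  k <- dnorm((-r):r, sd = sigma_px)
  k / sum(k)
}

# Separable Gaussian blur with replicated borders (structure is assumed to
# continue beyond the field, and a uniform image must stay uniform).
# Images smaller than the kernel are replicate-padded up to size first.
blur2d <- function(m, sigma_px) {
  if (sigma_px <= 0) return(m)
  k1 <- gaussian_kernel1d(sigma_px)
  K <- outer(k1, k1)
  py <- max(0L, nrow(K) - nrow(m)); px <- max(0L, ncol(K) - ncol(m))
  if (py > 0 || px > 0) {
    oy <- ceiling(py / 2); ox <- ceiling(px / 2)
    yi <- pmin(pmax(seq_len(nrow(m) + py) - oy, 1L), nrow(m))
    xi <- pmin(pmax(seq_len(ncol(m) + px) - ox, 1L), ncol(m))
    out <- EBImage::filter2(m[yi, xi, drop = FALSE], K,
                            boundary = "replicate")
    return(out[oy + seq_len(nrow(m)), ox + seq_len(ncol(m)), drop = FALSE])
  }
  EBImage::filter2(m, K, boundary = "replicate")
}

#' Noise model specification
#'
#' `"gaussian"` adds zero-mean read noise only; `"poisson_gaussian"`
#' (shot + read) draws photon counts at `photon_scale` counts per intensity
#' unit, divides back, and adds read noise — SRS detection is shot-noise
#' limited, so this is the default for phantoms.
#'
#' @param model `"gaussian"` or `"poisson_gaussian"`.
#' @param read_sigma read-noise standard deviation, intensity units (>= 0).
#' @param photon_scale counts per intensity unit (poisson_gaussian only).
#' @export
noise_spec <- function(model = c("poisson_gaussian", "gaussian"),
                       read_sigma = 0.01, photon_scale = 200) {
  model <- match.arg(model)
  stopifnot(read_sigma >= 0, photon_scale > 0)
  structure(list(model = model, read_sigma = read_sigma,
                 photon_scale = photon_scale), class = "noise_spec")
}

apply_noise <- function(img, noise) {
  if (noise$model == "poisson_gaussian") {
    lam <- pmax(img, 0) * noise$photon_scale
    img <- array(rpois(length(lam), lam), dim(img)) / noise$photon_scale +
      (img - pmax(img, 0))
  }
  if (noise$read_sigma > 0)
    img <- img + array(rnorm(length(img), sd = noise$read_sigma), dim(img))
  img
}

#' Background specification for the SRS forward model
#'
#' Residual spectral crosstalk into the protein CH3 channel: a spatially
#' smooth hydrogel CH2 term and a uniform water O-H term.  Setting both
#' weights to 0 emulates full deuteration of gel and water.
#'
#' @param gel_ch2_weight relative intensity of the smooth hydrogel background.
#' @param water_oh_weight relative intensity of the uniform water background.
#' @export
background_spec <- function(gel_ch2_weight = 0, water_oh_weight = 0) {
  stopifnot(gel_ch2_weight >= 0, water_oh_weight >= 0)
  structure(list(gel_ch2_weight = gel_ch2_weight,
                 water_oh_weight = water_oh_weight), class = "background_spec")
}

structure_kinds <- c("bead", "nucleus", "vessel", "soma", "dendrite",
                     "chromosome_void")

#' Structure specification for tissue phantoms
#'
#' @param kind one of `"nucleus"`, `"vessel"`, `"soma"`, `"dendrite"`,
#'   `"chromosome_void"`, `"bead"`.
#' @param count number of instances to place.
#' @param size_nm characteristic size: radius for nuclei/somata, tube radius
#'   for vessels, half-width for dendrites, blob radius for chromosome
#'   voids, diameter for beads.
#' @param protein_density relative CH3 intensity per voxel (>= 0).  A
#'   chromosome void must be less protein-dense than the nucleus it sits in.
#' @param retention fraction of the structure's protein surviving
#'   homogenization, in `[0, 1]`.
#' @export
structure_spec <- function(kind, count = NULL, size_nm = NULL,
                           protein_density = NULL, retention = 1) {
  kind <- match.arg(kind, structure_kinds)
  def <- list(
    nucleus = list(count = 6, size_nm = 9000, protein_density = 1.0),
    vessel = list(count = 3, size_nm = 1500, protein_density = 1.2),
    soma = list(count = 4, size_nm = 6000, protein_density = 0.8),
    dendrite = list(count = 6, size_nm = 500, protein_density = 0.6),
    chromosome_void = list(count = 4, size_nm = 2500, protein_density = 0.3),
    bead = list(count = 10, size_nm = 100, protein_density = 1.0)
  )[[kind]]
  s <- list(kind = kind,
            count = if (is.null(count)) def$count else count,
            size_nm = if (is.null(size_nm)) def$size_nm else size_nm,
            protein_density = if (is.null(protein_density)) def$protein_density
                              else protein_density,
            retention = retention)
  stopifnot(s$count >= 0, s$size_nm >= 0, s$protein_density >= 0,
            s$retention >= 0, s$retention <= 1)
  structure(s, class = "structure_spec")
}

#' Phantom specification
#'
#' Full description of a synthetic tissue field; a spec plus its `seed` is
#' a pure function of the generated data.  Defaults emulate a desk-scale
#' post-expansion brain-tissue field of view: 0.497 um pixels, stylized
#' nuclei/vessels/somata/dendrites with chromosome-poor voids inside
#' nuclei.
#'
#' @param field_shape integer `(z, y, x)` voxel counts.
#' @param pixel_size_xy nm per pixel in plane.
#' @param z_step nm between slices.
#' @param structures list of [structure_spec()] entries.
#' @param psf_fwhm_xy lateral PSF FWHM, nm (> 0).
#' @param background a [background_spec()].
#' @param noise a [noise_spec()].
#' @param seed integer RNG seed.
#' @export
phantom_spec <- function(field_shape = c(2, 192, 192), pixel_size_xy = 497,
                         z_step = 1000,
                         structures = list(structure_spec("nucleus"),
                                           structure_spec("vessel"),
                                           structure_spec("soma"),
                                           structure_spec("dendrite"),
                                           structure_spec("chromosome_void")),
                         psf_fwhm_xy = 1000,
                         background = background_spec(0.05, 0.02),
                         noise = noise_spec(), seed = 1L) {
  stopifnot(length(field_shape) == 3L, all(field_shape >= 1),
            pixel_size_xy > 0, z_step > 0, psf_fwhm_xy > 0)
  kinds <- vapply(structures, function(s) s$kind, "")
  if (anyDuplicated(kinds)) stop("one structure_spec per kind")
  if ("chromosome_void" %in% kinds) {
    if (!"nucleus" %in% kinds)
      stop("chromosome_void structures need nuclei to sit in")
    dv <- structures[[which(kinds == "chromosome_void")]]$protein_density
    dn <- structures[[which(kinds == "nucleus")]]$protein_density
    if (dv >= dn)
      stop("chromosome_void protein_density must be below the nucleus density")
  }
  structure(list(field_shape = as.integer(field_shape),
                 pixel_size_xy = pixel_size_xy, z_step = z_step,
                 structures = structures, psf_fwhm_xy = psf_fwhm_xy,
                 background = background, noise = noise,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

spec_structure <- function(spec, kind) {
  for (s in spec$structures) if (s$kind == kind) return(s)
  NULL
}

# ---- rasterization helpers (all coordinates in 1-based pixel units) -------

clamp01 <- function(x) pmin(pmax(x, 0), 1)

# Anti-aliased disc: coverage ramps linearly over one pixel at the rim.
add_soft_disk <- function(m, cy, cx, r, value = 1) {
  y0 <- max(1L, floor(cy - r - 1)); y1 <- min(nrow(m), ceiling(cy + r + 1))
  x0 <- max(1L, floor(cx - r - 1)); x1 <- min(ncol(m), ceiling(cx + r + 1))
  if (y0 > y1 || x0 > x1) return(m)
  d <- sqrt(outer((y0:y1 - cy)^2, (x0:x1 - cx)^2, "+"))
  m[y0:y1, x0:x1] <- pmax(m[y0:y1, x0:x1], clamp01(r + 0.5 - d) * value)
  m
}

# Anti-aliased thick segment (capsule) from p0 to p1, radius r.
add_soft_tube <- function(m, p0, p1, r) {
  y0 <- max(1L, floor(min(p0[1], p1[1]) - r - 1))
  y1 <- min(nrow(m), ceiling(max(p0[1], p1[1]) + r + 1))
  x0 <- max(1L, floor(min(p0[2], p1[2]) - r - 1))
  x1 <- min(ncol(m), ceiling(max(p0[2], p1[2]) + r + 1))
  if (y0 > y1 || x0 > x1) return(m)
  yy <- matrix(y0:y1, y1 - y0 + 1, x1 - x0 + 1)
  xx <- matrix(x0:x1, y1 - y0 + 1, x1 - x0 + 1, byrow = TRUE)
  v <- p1 - p0
  L2 <- sum(v^2)
  t <- if (L2 > 0) clamp01(((yy - p0[1]) * v[1] + (xx - p0[2]) * v[2]) / L2)
       else yy * 0
  d <- sqrt((yy - (p0[1] + t * v[1]))^2 + (xx - (p0[2] + t * v[2]))^2)
  m[y0:y1, x0:x1] <- pmax(m[y0:y1, x0:x1], clamp01(r + 0.5 - d))
  m
}

# Bounded-curvature random walk, returning a polyline (n x 2: y, x).
random_walk_path <- function(start, theta, step, n_steps, max_turn, H, W) {
  pts <- matrix(0, n_steps + 1L, 2L)
  pts[1L, ] <- start
  p <- start
  for (i in seq_len(n_steps)) {
    theta <- theta + runif(1, -max_turn, max_turn)
    p <- p + step * c(sin(theta), cos(theta))
    pts[i + 1L, ] <- p
    if (p[1] < 1 || p[1] > H || p[2] < 1 || p[2] > W) return(pts[1:(i + 1L), , drop = FALSE])
  }
  pts
}

rasterize_path <- function(m, pts, r) {
  for (i in seq_len(nrow(pts) - 1L))
    m <- add_soft_tube(m, pts[i, ], pts[i + 1L, ], r)
  m
}

# Per-slice radius of a 3-D ball of radius r_nm centred at slice cz.
slice_radius <- function(z, cz, r_nm, z_step, r_px) {
  dz <- (z - cz) * z_step
  if (abs(dz) >= r_nm) return(0)
  r_px * sqrt(1 - (dz / r_nm)^2)
}

# ---- tissue phantom -------------------------------------------------------

#' Generate a multi-structure tissue phantom
#'
#' Renders the requested structures into per-kind ground-truth density maps
#' (nuclei as ellipsoids, vessels as bounded-curvature random-walk tubes,
#' somata as blobs carrying a nucleus, dendrites as thin branching
#' filaments seeded at somata, chromosome voids as low-density blobs carved
#' out of nuclei), then emits one composite protein-CH3 SRS channel via
#' [srs_forward_model()] and one fluorescence-like channel per structure
#' class: `DAPI` (nuclei), `lectin` (vessels), `MAP2` (somata + dendrites),
#' `NeuN` (somata).
#'
#' @param spec a [phantom_spec()].
#' @return a list of class `vista_phantom`: `channels` (named
#'   [image_volume()] list), `truth` (per-kind maps and parameters),
#'   `spec`.
#' @export
generate_tissue_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  nz <- spec$field_shape[1]; H <- spec$field_shape[2]; W <- spec$field_shape[3]
  px <- spec$pixel_size_xy
  kinds <- vapply(spec$structures, function(s) s$kind, "")
  if ("bead" %in% kinds)
    stop("use generate_bead_stack() for bead calibration fields")
  maps <- list()
  blank <- function() array(0, c(nz, H, W))

  with_seed(spec$seed, {
    # nuclei ----------------------------------------------------------------
    nuc_table <- NULL
    if ("nucleus" %in% kinds) {
      s <- spec_structure(spec, "nucleus")
      maps$nucleus <- blank()
      r_nm <- s$size_nm * runif(s$count, 0.8, 1.2)
      r_px <- r_nm / px
      margin <- pmin(r_px + 2, (min(H, W) - 2) / 2)
      cy <- runif(s$count, 1 + margin, H - margin)
      cx <- runif(s$count, 1 + margin, W - margin)
      cz <- runif(s$count, 1, nz)
      for (i in seq_len(s$count))
        for (z in seq_len(nz)) {
          rs <- slice_radius(z, cz[i], r_nm[i], spec$z_step, r_px[i])
          if (rs > 0)
            maps$nucleus[z, , ] <- add_soft_disk(maps$nucleus[z, , ],
                                                 cy[i], cx[i], rs)
        }
      nuc_table <- data.frame(cy = cy, cx = cx, cz = cz, r_px = r_px,
                              r_nm = r_nm)
    }
    # somata (each carries a nucleus, which also shows in the DAPI map) -----
    soma_table <- NULL
    if ("soma" %in% kinds) {
      s <- spec_structure(spec, "soma")
      maps$soma <- blank()
      r_px <- s$size_nm * runif(s$count, 0.8, 1.2) / px
      margin <- pmin(r_px + 2, (min(H, W) - 2) / 2)
      cy <- runif(s$count, 1 + margin, H - margin)
      cx <- runif(s$count, 1 + margin, W - margin)
      for (i in seq_len(s$count))
        for (z in seq_len(nz)) {
          maps$soma[z, , ] <- add_soft_disk(maps$soma[z, , ], cy[i], cx[i],
                                            r_px[i])
          if (!is.null(maps$nucleus))
            maps$nucleus[z, , ] <- add_soft_disk(maps$nucleus[z, , ],
                                                 cy[i], cx[i], 0.55 * r_px[i])
        }
      soma_table <- data.frame(cy = cy, cx = cx, r_px = r_px)
    }
    # chromosome voids carved out of nuclei ---------------------------------
    if ("chromosome_void" %in% kinds && !is.null(nuc_table) &&
        nrow(nuc_table) > 0) {
      s <- spec_structure(spec, "chromosome_void")
      maps$chromosome_void <- blank()
      host <- sample.int(nrow(nuc_table), s$count, replace = TRUE)
      for (i in seq_len(s$count)) {
        hn <- nuc_table[host[i], ]
        ang <- runif(1, 0, 2 * pi)
        off <- runif(1, 0, 0.45 * hn$r_px)
        vy <- hn$cy + off * sin(ang); vx <- hn$cx + off * cos(ang)
        vr <- min(s$size_nm / px, 0.5 * hn$r_px)
        for (z in seq_len(nz)) {
          void <- add_soft_disk(array(0, c(H, W)), vy, vx, vr)
          nuc_here <- maps$nucleus[z, , ]
          void <- pmin(void, nuc_here)       # voids only exist inside nuclei
          maps$nucleus[z, , ] <- nuc_here - void
          maps$chromosome_void[z, , ] <- pmax(maps$chromosome_void[z, , ], void)
        }
      }
    }
    # vessels: tubes along bounded-curvature random walks --------------------
    if ("vessel" %in% kinds) {
      s <- spec_structure(spec, "vessel")
      maps$vessel <- blank()
      r_px <- s$size_nm / px
      plane <- array(0, c(H, W))
      for (i in seq_len(s$count)) {
        start <- c(runif(1, 1, H), runif(1, 1, W))
        pts <- random_walk_path(start, runif(1, 0, 2 * pi), step = 4,
                                n_steps = 120, max_turn = 0.25, H, W)
        plane <- rasterize_path(plane, pts, r_px)
      }
      for (z in seq_len(nz)) maps$vessel[z, , ] <- plane
    }
    # dendrites: thin branching filaments seeded at somata -------------------
    if ("dendrite" %in% kinds) {
      s <- spec_structure(spec, "dendrite")
      maps$dendrite <- blank()
      r_px <- max(s$size_nm / px, 0.6)
      plane <- array(0, c(H, W))
      for (i in seq_len(s$count)) {
        if (!is.null(soma_table) && nrow(soma_table) > 0) {
          j <- sample.int(nrow(soma_table), 1)
          start <- c(soma_table$cy[j], soma_table$cx[j])
        } else start <- c(runif(1, 1, H), runif(1, 1, W))
        pts <- random_walk_path(start, runif(1, 0, 2 * pi), step = 2.5,
                                n_steps = 45, max_turn = 0.35, H, W)
        plane <- rasterize_path(plane, pts, r_px)
        if (nrow(pts) > 6 && runif(1) < 0.7) {   # one side branch
          k <- sample(3:(nrow(pts) - 2), 1)
          dir0 <- atan2(pts[k, 1] - pts[k - 1, 1], pts[k, 2] - pts[k - 1, 2])
          br <- random_walk_path(pts[k, ], dir0 + sample(c(-1, 1), 1) * runif(1, 0.6, 1.2),
                                 step = 2.5, n_steps = 25, max_turn = 0.35, H, W)
          plane <- rasterize_path(plane, br, r_px)
        }
      }
      for (z in seq_len(nz)) maps$dendrite[z, , ] <- plane
    }

    truth <- structure(list(maps = maps, nuclei = nuc_table,
                            somata = soma_table, expansion = NULL),
                       class = "phantom_truth")
    channels <- list()
    channels[["CH3-2940"]] <- srs_forward_model(truth, spec)
    sigma_px <- spec$psf_fwhm_xy / (2 * sqrt(2 * log(2))) / px
    fl <- list(DAPI = "nucleus", lectin = "vessel", NeuN = "soma")
    make_fluor <- function(map, label) {
      img <- map
      for (z in seq_len(nz)) img[z, , ] <- blur2d(img[z, , ], sigma_px)
      img <- apply_noise(img, spec$noise)
      image_volume(img, pixel_size_xy = px, z_step = spec$z_step,
                   channel_label = label)
    }
    for (lab in names(fl))
      if (!is.null(maps[[fl[[lab]]]]))
        channels[[lab]] <- make_fluor(maps[[fl[[lab]]]], lab)
    if (!is.null(maps$soma) || !is.null(maps$dendrite)) {
      m2 <- blank()
      if (!is.null(maps$soma)) m2 <- pmax(m2, maps$soma)
      if (!is.null(maps$dendrite)) m2 <- pmax(m2, maps$dendrite)
      channels[["MAP2"]] <- make_fluor(m2, "MAP2")
    }
    structure(list(channels = channels, truth = truth, spec = spec),
              class = "vista_phantom")
  })
}

#' SRS forward model: compose the protein-CH3 channel from ground truth
#'
#' `SRS = sum_kind(protein_density * retention * map) + gel background +
#' water background`, then lateral PSF blur, then noise.  The background
#' field and the noise draw are seeded from `spec$seed`, so the composite
#' is reproducible from `truth + spec` alone.
#'
#' @param truth `phantom_truth` (per-kind density maps).
#' @param spec the generating [phantom_spec()].
#' @param intensity_scale multiplier applied before noise (used for
#'   expansion signal dilution).
#' @return an [image_volume()] labeled `"CH3-2940"`.
#' @export
srs_forward_model <- function(truth, spec, intensity_scale = 1) {
  nz <- dim(truth$maps[[1]])[1]
  H <- dim(truth$maps[[1]])[2]; W <- dim(truth$maps[[1]])[3]
  base <- array(0, c(nz, H, W))
  for (s in spec$structures) {
    m <- truth$maps[[s$kind]]
    if (!is.null(m)) base <- base + s$protein_density * s$retention * m
  }
  with_seed(spec$seed + 7919L, {
    bg <- spec$background
    if (bg$gel_ch2_weight > 0) {
      f <- blur2d(matrix(rnorm(H * W), H, W), sigma_px = 8)
      f <- 1 + 0.5 * (f - mean(f)) / max(sd(f), 1e-12)
      f <- pmax(f, 0)
      for (z in seq_len(nz)) base[z, , ] <- base[z, , ] + bg$gel_ch2_weight * f
    }
    base <- base + bg$water_oh_weight
    sigma_px <- spec$psf_fwhm_xy / (2 * sqrt(2 * log(2))) / spec$pixel_size_xy
    for (z in seq_len(nz)) base[z, , ] <- blur2d(base[z, , ], sigma_px)
    base <- apply_noise(base * intensity_scale, spec$noise)
  })
  image_volume(base, pixel_size_xy = spec$pixel_size_xy, z_step = spec$z_step,
               channel_label = "CH3-2940")
}

#' Binary ground-truth mask for selected structure kinds
#'
#' Full-coverage voxels of the requested kinds, optionally eroded so the
#' mask sits strictly inside the structures (away from PSF-blurred rims) —
#' the natural mask for retention quantification on phantoms.
#'
#' @param truth a `phantom_truth`.
#' @param kinds character vector of structure kinds.
#' @param erode_px disc radius (pixels) to erode by; 0 disables.
#' @return logical `(z, y, x)` array.
#' @export
truth_mask <- function(truth, kinds, erode_px = 0) {
  m <- NULL
  for (k in kinds) {
    mk <- truth$maps[[k]]
    if (is.null(mk)) next
    m <- if (is.null(m)) mk else pmax(m, mk)
  }
  if (is.null(m)) stop("no maps for kinds: ", paste(kinds, collapse = ", "))
  mask <- m >= 0.999
  if (erode_px > 0) {
    brush <- EBImage::makeBrush(2 * ceiling(erode_px) + 1, "disc")
    for (z in seq_len(dim(mask)[1]))
      mask[z, , ] <- EBImage::erode(mask[z, , ] * 1, brush) > 0.5
  }
  mask
}

# ---- bead calibration fields ----------------------------------------------

#' Generate a synthetic bead calibration field
#'
#' Sub-resolution beads of known diameter are rendered as uniform circles
#' (area-weighted sub-pixel coverage by `supersample^2` sampling), blurred
#' by an isotropic 2-D Gaussian PSF of the given FWHM, and noised.  A
#' zero-diameter bead degenerates to a point emitter (deposited at the
#' nearest sub-sample, i.e. within `pixel_size / (2*supersample)` of its
#' true center).
#'
#' @param diameter bead diameter, nm (>= 0).
#' @param psf_fwhm Gaussian PSF FWHM, nm.
#' @param pixel_size nm per pixel.
#' @param n_beads number of beads.
#' @param noise a [noise_spec()]; default noiseless.
#' @param seed RNG seed.
#' @param field_shape optional `(z, y, x)`; sized automatically when `NULL`.
#' @param amplitude peak object intensity before blur.
#' @param supersample sub-pixel sampling factor for area weighting.
#' @return `list(volume, truth)`; `truth$beads` holds exact centers
#'   (1-based pixel coordinates) and diameters, `truth$psf_fwhm` the true
#'   PSF width.
#' @export
generate_bead_stack <- function(diameter, psf_fwhm, pixel_size, n_beads = 10,
                                noise = noise_spec("gaussian", read_sigma = 0),
                                seed = 1, field_shape = NULL, amplitude = 1,
                                supersample = 8L) {
  stopifnot(diameter >= 0, psf_fwhm > 0, pixel_size > 0, n_beads >= 1)
  min_sep_px <- 3 * psf_fwhm / pixel_size
  margin_px <- ceiling((2 * psf_fwhm + diameter) / pixel_size) + 2
  if (is.null(field_shape)) {
    ncell <- ceiling(sqrt(n_beads))
    side <- ncell * ceiling(min_sep_px + psf_fwhm / pixel_size) + 2 * margin_px
    field_shape <- c(1L, side, side)
  }
  nz <- field_shape[1]; H <- field_shape[2]; W <- field_shape[3]
  if (H - 2 * margin_px < 1 || W - 2 * margin_px < 1)
    stop("field too small for bead placement")
  with_seed(seed, {
    centers <- matrix(NA_real_, 0, 2)
    tries <- 0L
    while (nrow(centers) < n_beads) {
      if ((tries <- tries + 1L) > 2000L * n_beads)
        stop("field too small to place ", n_beads,
             " beads at >= 3 PSF-FWHM separation")
      p <- c(runif(1, 1 + margin_px, H - margin_px),
             runif(1, 1 + margin_px, W - margin_px))
      if (nrow(centers) == 0 ||
          min(sqrt(colSums((t(centers) - p)^2))) >= min_sep_px)
        centers <- rbind(centers, p)
    }
    img <- matrix(0, H, W)
    ss <- as.integer(supersample)
    r_px <- max((diameter / 2) / pixel_size, 1 / (2 * ss))
    wr <- ceiling(r_px) + 1L
    sub <- ((seq_len(ss) - 0.5) / ss) - 0.5
    for (i in seq_len(n_beads)) {
      cy <- centers[i, 1]; cx <- centers[i, 2]
      ys <- (round(cy) - wr):(round(cy) + wr)
      xs <- (round(cx) - wr):(round(cx) + wr)
      ys <- ys[ys >= 1 & ys <= H]; xs <- xs[xs >= 1 & xs <= W]
      fy <- as.vector(outer(ys, sub, "+"))
      fx <- as.vector(outer(xs, sub, "+"))
      inside <- outer((fy - cy)^2, (fx - cx)^2, "+") <= r_px^2
      cov <- matrix(0, length(ys), length(xs))
      idx_y <- rep(seq_along(ys), times = ss)
      idx_x <- rep(seq_along(xs), times = ss)
      # average the supersampled indicator back onto the pixel grid
      cov <- rowsum(t(rowsum(inside * 1, idx_y)), idx_x) / ss^2
      img[ys, xs] <- img[ys, xs] + amplitude * t(cov)
    }
    sigma_px <- psf_fwhm / (2 * sqrt(2 * log(2))) / pixel_size
    img <- blur2d(img, sigma_px)
    img <- apply_noise(img, noise)
    vox <- array(0, c(nz, H, W))
    for (z in seq_len(nz)) vox[z, , ] <- img
    vol <- image_volume(vox, pixel_size_xy = pixel_size,
                        channel_label = "beads-CH-3050")
    truth <- structure(list(
      maps = NULL,
      beads = data.frame(y_px = centers[, 1], x_px = centers[, 2],
                         diameter_nm = diameter),
      psf_fwhm = psf_fwhm, expansion = NULL), class = "phantom_truth")
    list(volume = vol, truth = truth)
  })
}

# ---- expansion simulation --------------------------------------------------

resize_bilinear <- function(m, new_h, new_w) {
  EBImage::resize(m, w = new_h, h = new_w)   # EBImage dims are (x, y)
}

# Smooth random displacement field with the requested RMS magnitude (px).
distortion_field <- function(H, W, rms_px) {
  f <- function() {
    d <- blur2d(matrix(rnorm(H * W), H, W), sigma_px = max(H, W) / 10)
    d - mean(d)
  }
  dy <- f(); dx <- f()
  mag <- sqrt(mean(dy^2 + dx^2))
  list(dy = dy / mag * rms_px, dx = dx / mag * rms_px)
}

warp_displace <- function(m, dy, dx) {
  H <- nrow(m); W <- ncol(m)
  yy <- matrix(seq_len(H), H, W) + dy
  xx <- matrix(seq_len(W), H, W, byrow = TRUE) + dx
  bilinear_sample(m, yy, xx)
}

# Bilinear lookup with zero outside the grid; `yy`, `xx` are 1-based.
bilinear_sample <- function(m, yy, xx) {
  H <- nrow(m); W <- ncol(m)
  y0 <- floor(yy); x0 <- floor(xx)
  fy <- yy - y0; fx <- xx - x0
  gv <- function(yi, xi) {
    ok <- yi >= 1 & yi <= H & xi >= 1 & xi <= W
    out <- numeric(length(yi))
    out[ok] <- m[cbind(yi[ok], xi[ok])]
    out
  }
  v <- gv(y0, x0) * (1 - fy) * (1 - fx) + gv(y0, x0 + 1) * (1 - fy) * fx +
    gv(y0 + 1, x0) * fy * (1 - fx) + gv(y0 + 1, x0 + 1) * fy * fx
  if (!is.null(dim(yy))) dim(v) <- dim(yy)
  v
}

#' Simulate isotropic sample expansion of a tissue phantom
#'
#' The pre-expansion (unprocessed) channels are the phantom's composites
#' with every retention forced to 1.  Post-expansion channels are rendered
#' from geometry scaled by `ratio` (optionally warped by a smooth random
#' displacement field of the given RMS), with the spec's per-structure
#' retentions applied and conserved signal diluted by `ratio^3` per voxel —
#' linear expansion in three dimensions spreads the same molecules over
#' `ratio^3` the volume.  Both images share the physical pixel size, so a
#' feature of true size L measures `ratio * L` in the post image.
#'
#' @param phantom output of [generate_tissue_phantom()].
#' @param ratio linear expansion factor (>= 1).
#' @param distortion_rms RMS of the random distortion field, nm (0 = none).
#' @param seed RNG seed for post-expansion noise and distortion.
#' @return `list(pre, post, truth)`: two named channel lists and the
#'   post-expansion truth (scaled maps, `ratio`, displacement fields).
#' @export
simulate_expansion <- function(phantom, ratio, distortion_rms = 0, seed = 1) {
  stopifnot(inherits(phantom, "vista_phantom"), ratio >= 1)
  spec <- phantom$spec
  px <- spec$pixel_size_xy
  nz <- spec$field_shape[1]; H <- spec$field_shape[2]; W <- spec$field_shape[3]
  H2 <- round(H * ratio); W2 <- round(W * ratio)
  with_seed(seed, {
    dis <- if (distortion_rms > 0) distortion_field(H2, W2, distortion_rms / px)
    post_maps <- lapply(phantom$truth$maps, function(m) {
      out <- array(0, c(nz, H2, W2))
      for (z in seq_len(nz)) {
        s <- resize_bilinear(m[z, , ], H2, W2)
        if (!is.null(dis)) s <- warp_displace(s, dis$dy, dis$dx)
        out[z, , ] <- s
      }
      out
    })
    truth_post <- structure(list(maps = post_maps, nuclei = NULL, somata = NULL,
                                 expansion = list(ratio = ratio,
                                                  distortion_rms = distortion_rms,
                                                  field = dis)),
                            class = "phantom_truth")
    # pre: unprocessed sample -> retention 1 everywhere
    spec_pre <- spec
    spec_pre$structures <- lapply(spec$structures, function(s) { s$retention <- 1; s })
    pre <- phantom$channels
    pre[["CH3-2940"]] <- srs_forward_model(phantom$truth, spec_pre)

    spec_post <- spec
    spec_post$field_shape <- c(nz, H2, W2)
    post <- list()
    post[["CH3-2940"]] <- srs_forward_model(truth_post, spec_post,
                                            intensity_scale = 1 / ratio^3)
    sigma_px <- spec$psf_fwhm_xy / (2 * sqrt(2 * log(2))) / px
    fl <- list(DAPI = "nucleus", lectin = "vessel", NeuN = "soma")
    for (lab in names(fl)) {
      m <- post_maps[[fl[[lab]]]]
      if (is.null(m) || is.null(phantom$channels[[lab]])) next
      img <- m / ratio^3
      for (z in seq_len(nz)) img[z, , ] <- blur2d(img[z, , ], sigma_px)
      post[[lab]] <- apply_noise(img, spec$noise)
    }
    post <- lapply(post, function(ch) {
      vox <- if (inherits(ch, "vista_volume")) ch$voxels else ch
      image_volume(vox, pixel_size_xy = px, z_step = spec$z_step,
                   channel_label = if (inherits(ch, "vista_volume")) ch$channel_label else "",
                   expansion_state = "expanded", expansion_factor = ratio)
    })
    for (lab in names(post))
      post[[lab]]$channel_label <- lab
    list(pre = pre, post = post, truth = truth_post)
  })
}

#' Add ground-truth degradation noise
#'
#' Adds zero-mean Gaussian noise of the given sigma to a volume — used to
#' build the noise-robustness curve for training-set ground truth.
#'
#' @param v an [image_volume()].
#' @param noise_sigma standard deviation, intensity units (>= 0).
#' @param seed RNG seed.
#' @export
degrade_ground_truth <- function(v, noise_sigma, seed = 1) {
  stopifnot(inherits(v, "vista_volume"), noise_sigma >= 0)
  if (noise_sigma == 0) return(v)
  with_seed(seed, {
    v$voxels <- v$voxels + array(rnorm(length(v$voxels), sd = noise_sigma),
                                 dim(v$voxels))
  })
  v
}
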