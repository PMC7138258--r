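#' Voxel grid specification
#'
#' Default geometry: 64 lateral x 47 depth x 62 scan voxels at 0.6 mm
#' isotropic spacing (38.4 x 28.2 x 37.2 mm). Arrays are indexed `[x, z, y]`
#' with z the depth axis (illumination enters at z = 0) and y the scan axis.
#'
#' @param dims integer triple (x, z, y)
#' @param spacing voxel edge length in mm
#' @export
grid_spec <- function(dims = c(64L, 47L, 62L), spacing = 0.6) {
  dims <- as.integer(dims)
  stopifnot(length(dims) == 3L, all(dims >= 1L), spacing > 0)
  structure(list(dims = dims, spacing = spacing), class = "cepaq_grid")
}

#' Random-walk vessel centerline offsets
#'
#' Generates the per-step offsets \eqn{r_i = r_{i-1} + \eta a_i} of a vessel
#' centerline: the step scale \eqn{\eta} is drawn once per vessel from
#' U(0, 0.2) and each component of \eqn{a_i} is redrawn per step from
#' U(-0.2, 0.2) mm, so no per-component step exceeds 0.04 mm. The phantom
#' builder adds a deterministic scan-axis advance (one voxel per step) on top
#' of these offsets so the vessel spans the volume.
#'
#' @param n_steps number of steps (path has `n_steps + 1` points)
#' @param start_point numeric length-3 starting coordinate in mm (x, z, y)
#' @param seed integer seed
#' @param eta step scale; drawn from U(0, 0.2) when `NULL`
#' @param radius vessel radius in mm (stored on the result)
#' @return object of class `cepaq_vessel_path` with fields `points`
#'   (`(n_steps+1) x 3` matrix, mm), `eta`, `radius`
#' @export
random_walk_vessel <- function(n_steps, start_point = c(0, 0, 0), seed = 1L,
                               eta = NULL, radius = 3) {
  stopifnot(n_steps >= 1, radius > 0, length(start_point) == 3L)
  rng <- local_rng(seed)
  if (is.null(eta)) eta <- rng(1) * 0.2
  stopifnot(eta >= 0, eta < 0.2)
  a <- matrix(rng(3L * n_steps) * 0.4 - 0.2, ncol = 3L)  # U(-0.2, 0.2) mm
  pts <- rbind(start_point,
               sweep(apply(eta * a, 2L, cumsum), 2L, start_point, `+`))
  dimnames(pts) <- NULL
  structure(list(points = pts, eta = eta, radius = radius),
            class = "cepaq_vessel_path")
}

# deterministic local uniform stream that leaves the global RNG untouched
local_rng <- function(seed) {
  env <- new.env()
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  env$state <- get(".Random.seed", globalenv())
  if (is.null(old)) rm(".Random.seed", envir = globalenv())
  else assign(".Random.seed", old, envir = globalenv())
  function(n) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, envir = globalenv())
    x <- runif(n)
    env$state <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
    x
  }
}

#' Rasterize vessel paths into a segmentation label volume
#'
#' A voxel is labelled as vessel when its center lies within the vessel
#' radius of any centerline segment; overlapping vessels merge (the later
#' vessel id wins on contested voxels).
#'
#' @param paths list of [random_walk_vessel()] paths (with radii)
#' @param grid a [grid_spec()]
#' @return integer array `dims(grid)`; 0 = background, v = vessel id
#' @export
rasterize_vessels <- function(paths, grid) {
  d <- grid$dims; h <- grid$spacing
  labels <- array(0L, dim = d)
  if (!length(paths)) return(labels)
  centers <- lapply(d, function(n) (seq_len(n) - 0.5) * h)
  for (vi in seq_along(paths)) {
    p <- paths[[vi]]
    pts <- p$points; r <- p$radius
    touched <- FALSE
    for (s in seq_len(nrow(pts) - 1L)) {
      a <- pts[s, ]; b <- pts[s + 1L, ]
      lo <- pmin(a, b) - r; hi <- pmax(a, b) + r
      ix <- which(centers[[1]] >= lo[1] & centers[[1]] <= hi[1])
      iz <- which(centers[[2]] >= lo[2] & centers[[2]] <= hi[2])
      iy <- which(centers[[3]] >= lo[3] & centers[[3]] <= hi[3])
      if (!length(ix) || !length(iz) || !length(iy)) next
      g <- as.matrix(expand.grid(x = centers[[1]][ix], z = centers[[2]][iz],
                                 y = centers[[3]][iy]))
      ab <- b - a
      len2 <- sum(ab^2)
      t <- if (len2 > 0) pmin(1, pmax(0, (sweep(g, 2L, a) %*% ab) / len2)) else 0
      proj <- sweep(outer(drop(t), ab), 2L, a, `+`)
      inside <- rowSums((g - proj)^2) <= r^2
      if (any(inside)) {
        touched <- TRUE
        sel <- as.matrix(expand.grid(ix, iz, iy))[inside, , drop = FALSE]
        labels[sel] <- vi
      }
    }
    if (!touched)
      warning("vessel ", vi, " lies entirely outside the grid")
  }
  labels
}

#' Assign optical properties to a segmented volume
#'
#' Background and per-vessel absorption coefficients are painted onto the
#' label volume; the ground-truth absorption map is then Gaussian blurred
#' (sigma 0.6 mm, reflective boundaries) to emulate partial-volume effects.
#' Reduced scattering is constant (1.5 cm^-1) and the Grueneisen coefficient
#' is 1 everywhere (it cancels in the relative validation).
#'
#' @param labels integer label array from [rasterize_vessels()]
#' @param vessel_mu_a per-vessel absorption, cm^-1 (recycled over vessel ids)
#' @param bg_mu_a background absorption, cm^-1
#' @param grid a [grid_spec()]
#' @param mu_s_prime reduced scattering coefficient, cm^-1
#' @param gamma Grueneisen coefficient
#' @param blur_sigma blur sigma in mm (0 disables)
#' @return `cepaq_volume`: list with `mu_a`, `mu_s_prime`, `gamma`, `labels`,
#'   `grid`
#' @export
assign_optics <- function(labels, vessel_mu_a, bg_mu_a, grid,
                          mu_s_prime = 1.5, gamma = 1, blur_sigma = 0.6) {
  stopifnot(bg_mu_a >= 0, all(vessel_mu_a >= 0), blur_sigma >= 0, gamma > 0)
  mu_a <- array(bg_mu_a, dim = dim(labels))
  nv <- max(labels)
  if (nv > 0) {
    vmu <- rep(vessel_mu_a, length.out = nv)
    for (v in seq_len(nv)) mu_a[labels == v] <- vmu[v]
  }
  mu_a <- gaussian_blur(mu_a, blur_sigma / grid$spacing)
  structure(list(mu_a = mu_a,
                 mu_s_prime = array(mu_s_prime, dim = dim(labels)),
                 gamma = gamma, labels = labels, grid = grid),
            class = "cepaq_volume")
}

# Table-1 bounds used for validation of user-supplied specs
.ds_table <- list(
  DSbase       = list(radius = c(3, 3),     mu_a = c(4.7, 4.7), count = c(1, 1), bg = c(0.1, 0.1)),
  DSradius     = list(radius = c(0.5, 6),   mu_a = c(4.7, 4.7), count = c(1, 1), bg = c(0.1, 0.1)),
  DSabsorb     = list(radius = c(3, 3),     mu_a = c(1, 12),    count = c(1, 1), bg = c(0.1, 0.1)),
  DSvessel     = list(radius = c(3, 3),     mu_a = c(4.7, 4.7), count = c(1, 7), bg = c(0.1, 0.1)),
  DSbackground = list(radius = c(3, 3),     mu_a = c(4.7, 4.7), count = c(1, 1), bg = c(1e-4, 0.2)),
  DSmulti      = list(radius = c(0.5, 6),   mu_a = c(1, 12),    count = c(1, 7), bg = c(1e-4, 0.2)),
  DSoxy        = list(radius = c(2.3, 4),   mu_a = NULL,        count = c(1, 1), bg = NULL))

#' Experimental dataset specification
#'
#' Seven named designs. The six monospectral designs vary vessel radius,
#' vessel absorption, vessel count and background absorption inside the
#' canonical bounds; `DSoxy` is the multispectral oxygenation design
#' (one carotid-like vessel, homogeneous oxygenation, hemoglobin-based
#' optics at 750/800/850 nm). All ranges are sampled uniformly. Default item
#' counts are 150/25/25 train/val/test (400 training items for `DSmulti`,
#' 240 train / 11 test for `DSoxy`).
#'
#' @param name one of `DSbase`, `DSradius`, `DSabsorb`, `DSvessel`,
#'   `DSbackground`, `DSmulti`, `DSoxy`
#' @param n_train,n_val,n_test item counts (override the defaults)
#' @param vessel_radius_range,vessel_mu_a_range,vessel_count_range,background_mu_a_range
#'   optional overrides; must stay inside the canonical bounds for `name`
#' @export
dataset_spec <- function(name, n_train = NULL, n_val = NULL, n_test = NULL,
                         vessel_radius_range = NULL, vessel_mu_a_range = NULL,
                         vessel_count_range = NULL, background_mu_a_range = NULL) {
  name <- match.arg(name, names(.ds_table))
  tab <- .ds_table[[name]]
  within_bounds <- function(x, b, what) {
    if (is.null(x)) return(b)
    if (is.null(b)) stop(what, " is not configurable for ", name)
    if (x[1] < b[1] || x[2] > b[2])
      stop(what, " range [", x[1], ", ", x[2], "] outside canonical bounds [",
           b[1], ", ", b[2], "] for ", name)
    x
  }
  spec <- list(
    name = name,
    vessel_radius_range = within_bounds(vessel_radius_range, tab$radius, "vessel radius"),
    vessel_mu_a_range = within_bounds(vessel_mu_a_range, tab$mu_a, "vessel mu_a"),
    vessel_count_range = as.integer(within_bounds(vessel_count_range, tab$count, "vessel count")),
    background_mu_a_range = within_bounds(background_mu_a_range, tab$bg, "background mu_a"),
    n_train = as.integer(n_train %||% if (name == "DSmulti") 400L else if (name == "DSoxy") 240L else 150L),
    n_val = as.integer(n_val %||% if (name == "DSoxy") 0L else 25L),
    n_test = as.integer(n_test %||% if (name == "DSoxy") 11L else 25L),
    wavelengths = if (name == "DSoxy") c(750, 800, 850) else NULL)
  stopifnot(spec$n_train >= 0, spec$n_val >= 0, spec$n_test >= 0)
  structure(spec, class = "cepaq_dataset_spec")
}

#' Build a dataset manifest (train/val/test item records)
#'
#' Samples all per-item parameters (vessel count, radii, absorptions,
#' background absorption, oxygenation) from the spec's uniform ranges using a
#' per-item seed hierarchy, so a fixed `(spec, seed)` pair gives a
#' byte-identical manifest. Volumes themselves are realized lazily via
#' [realize_item()] (or eagerly with `materialize = TRUE`).
#'
#' For `DSoxy` the test items carry the fixed oxygenation ladder
#' sO2 = 0%, 10%, ..., 100% (truncated/recycled to `n_test`).
#'
#' @param spec a [dataset_spec()]
#' @param seed integer dataset seed
#' @param grid a [grid_spec()]
#' @param materialize also realize every item volume (memory heavy)
#' @return `cepaq_dataset`: list with `spec`, `grid`, `seed` and manifests
#'   `train`, `val`, `test` (lists of item records)
#' @export
build_dataset <- function(spec, seed, grid = grid_spec(), materialize = FALSE) {
  stopifnot(inherits(spec, "cepaq_dataset_spec"))
  make_items <- function(role, n) {
    if (n == 0L) return(list())
    lapply(seq_len(n), function(i) {
      iseed <- derive_seed(seed, spec$name, role, i)
      rng <- local_rng(iseed)
      cr <- spec$vessel_count_range
      n_vessels <- if (cr[1] == cr[2]) cr[1] else
        cr[1] + floor(rng(1) * (cr[2] - cr[1] + 1L))
      n_vessels <- as.integer(min(n_vessels, cr[2]))
      rr <- spec$vessel_radius_range
      radius <- rr[1] + rng(n_vessels) * (rr[2] - rr[1])
      mu_a <- if (!is.null(spec$vessel_mu_a_range)) {
        mr <- spec$vessel_mu_a_range
        mr[1] + rng(n_vessels) * (mr[2] - mr[1])
      } else rep(NA_real_, n_vessels)
      bg_mu_a <- if (!is.null(spec$background_mu_a_range)) {
        br <- spec$background_mu_a_range
        br[1] + rng(1) * (br[2] - br[1])
      } else NA_real_
      so2 <- if (identical(spec$name, "DSoxy")) {
        if (role == "test") ((i - 1L) %% 11L) / 10 else rng(1)
      } else NA_real_
      # start point uniform in the imaging plane with one-radius margin
      ext <- grid$dims * grid$spacing
      x0 <- z0 <- numeric(n_vessels)
      for (v in seq_len(n_vessels)) {
        mx <- min(radius[v], ext[1] / 2 * 0.99)
        mz <- min(radius[v], ext[2] / 2 * 0.99)
        x0[v] <- mx + rng(1) * (ext[1] - 2 * mx)
        z0[v] <- mz + rng(1) * (ext[2] - 2 * mz)
      }
      list(id = sprintf("%s-%s-%03d", spec$name, role, i), role = role,
           seed = iseed, n_vessels = n_vessels, bg_mu_a = bg_mu_a, so2 = so2,
           vessels = data.frame(radius = radius, mu_a = mu_a, x0 = x0, z0 = z0))
    })
  }
  ds <- structure(list(spec = spec, grid = grid, seed = as.integer(seed),
                       train = make_items("train", spec$n_train),
                       val = make_items("val", spec$n_val),
                       test = make_items("test", spec$n_test)),
                  class = "cepaq_dataset")
  if (materialize)
    for (role in c("train", "val", "test"))
      ds[[role]] <- lapply(ds[[role]], function(it) {
        it$volume <- realize_item(it, ds)
        it
      })
  ds
}

#' Realize one manifest item as a tissue volume
#'
#' Re-derives the vessel random walks from the item seed, rasterizes them,
#' and paints/blurs optical properties. For `DSoxy` items the returned
#' volume's `mu_a` is `NULL`; use [optics_at_wavelength()] to obtain the
#' per-wavelength absorption maps.
#'
#' @param item an item record from a [build_dataset()] manifest
#' @param dataset the `cepaq_dataset` the item belongs to
#' @export
realize_item <- function(item, dataset) {
  grid <- dataset$grid
  spec <- dataset$spec
  n_steps <- grid$dims[3]
  paths <- lapply(seq_len(item$n_vessels), function(v) {
    w <- random_walk_vessel(n_steps,
                            start_point = c(item$vessels$x0[v], item$vessels$z0[v], 0),
                            seed = derive_seed(item$seed, "walk", v),
                            radius = item$vessels$radius[v])
    # scan-axis advance: one voxel per step so the vessel spans the volume
    w$points[, 3] <- w$points[, 3] + (seq_len(nrow(w$points)) - 1L) * grid$spacing
    w
  })
  labels <- rasterize_vessels(paths, grid)
  if (identical(spec$name, "DSoxy")) {
    vol <- structure(list(mu_a = NULL,
                          mu_s_prime = array(1.5, dim = grid$dims),
                          gamma = 1, labels = labels, grid = grid,
                          so2 = item$so2),
                     class = "cepaq_volume")
  } else {
    vol <- assign_optics(labels, item$vessels$mu_a, item$bg_mu_a, grid)
  }
  vol
}

#' Per-wavelength absorption map for an oxygenation-phantom volume
#'
#' Vessel voxels: whole blood (bvf = 1) at the volume's homogeneous
#' oxygenation; background: 0.5% blood volume fraction plus the constant
#' baseline of [background_mu_a_oxy()]. Blurred like the monospectral maps.
#'
#' @param volume a `cepaq_volume` with an `so2` field
#' @param wavelength nm
#' @param model a [blood_optics()] model
#' @param blur_sigma blur sigma in mm
#' @return absorption array, cm^-1
#' @export
optics_at_wavelength <- function(volume, wavelength, model = blood_optics(),
                                 blur_sigma = 0.6) {
  stopifnot(!is.null(volume$so2))
  v_mu <- blood_mu_a(wavelength, volume$so2, model$bvf_vessel, model)
  b_mu <- background_mu_a_oxy(wavelength, volume$so2, model)
  mu_a <- array(b_mu, dim = dim(volume$labels))
  mu_a[volume$labels > 0] <- v_mu
  gaussian_blur(mu_a, blur_sigma / volume$grid$spacing)
}

#' Write a dataset's volumes and manifest to disk
#'
#' One NRRD file per property channel per item plus a JSON manifest with all
#' sampled parameters.
#'
#' @param dataset a `cepaq_dataset`
#' @param dir output directory (created)
#' @param roles which manifests to write
#' @export
write_dataset <- function(dataset, dir, roles = c("train", "val", "test")) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(spec = unclass(dataset$spec), seed = dataset$seed,
                   grid = unclass(dataset$grid), items = list())
  for (role in roles) {
    for (it in dataset[[role]]) {
      vol <- realize_item(it, dataset)
      base <- file.path(dir, it$id)
      write_nrrd(vol$labels + 0, paste0(base, "-labels.nrrd"),
                 spacing = dataset$grid$spacing, meta = c(item = it$id))
      if (!is.null(vol$mu_a))
        write_nrrd(vol$mu_a, paste0(base, "-mua.nrrd"),
                   spacing = dataset$grid$spacing,
                   meta = c(item = it$id, units = "cm^-1"))
      it$vessels <- as.list(it$vessels)
      manifest$items[[it$id]] <- it
    }
  }
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
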