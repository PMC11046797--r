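#' Synthetic nucleus images with known ground truth
#'
#' Generates two-channel (DNA counterstain + epigenetic mark) single-plane
#' images of germ and somatic nuclei with a programmable germ/somatic
#' mark-per-chromatin fold, a programmable germ/somatic chromatin-density
#' fold, optional bright mark foci, and additive Gaussian noise. Nuclei are
#' uniform-intensity discs placed without overlap, so all programmed folds
#' hold exactly before noise.
#'
#' @name sim-image
NULL

run_seeded <- function(seed, fn) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  fn()
}

#' Specification for a synthetic nucleus image
#'
#' @param image_shape Image size in pixels (rows, cols).
#' @param n_germ,n_somatic Nucleus counts (`n_somatic >= 1`, the
#'   normalization reference).
#' @param nucleus_radius_range Disc radius range in pixels.
#' @param germ_mark_fold Programmed germ/somatic mark-per-chromatin ratio.
#' @param germ_density_fold Programmed germ/somatic DNA-per-area ratio.
#' @param foci_per_nucleus Bright Gaussian foci added to the mark channel
#'   of every nucleus.
#' @param focus_sigma Gaussian sigma of a focus in pixels.
#' @param focus_amplitude Focus peak height relative to the nucleus' mark
#'   level.
#' @param noise_sd Additive Gaussian noise SD (intensity units; channels
#'   are clipped at 0).
#' @param dna_base,mark_base Somatic per-pixel intensities of the two
#'   channels (intensity units).
#' @param seed Integer seed; identical seeds give identical output.
#' @return Object of class `image_sim_spec`.
#' @export
image_sim_spec <- function(image_shape = c(512, 512), n_germ = 10,
                           n_somatic = 30, nucleus_radius_range = c(8, 14),
                           germ_mark_fold = 3, germ_density_fold = 0.5,
                           foci_per_nucleus = 0, focus_sigma = 1.5,
                           focus_amplitude = 2, noise_sd = 0,
                           dna_base = 100, mark_base = 40, seed = 1) {
  stopifnot(length(image_shape) == 2L, all(image_shape >= 16))
  if (n_germ < 0 || n_somatic < 1)
    stop("need n_germ >= 0 and n_somatic >= 1")
  if (any(nucleus_radius_range <= 0) || length(nucleus_radius_range) != 2L ||
      nucleus_radius_range[1] > nucleus_radius_range[2])
    stop("invalid nucleus_radius_range")
  if (germ_mark_fold <= 0 || germ_density_fold <= 0)
    stop("folds must be > 0")
  if (foci_per_nucleus < 0 || focus_sigma <= 0 || noise_sd < 0)
    stop("invalid foci or noise parameters")
  structure(list(image_shape = as.integer(image_shape), n_germ = n_germ,
                 n_somatic = n_somatic,
                 nucleus_radius_range = nucleus_radius_range,
                 germ_mark_fold = germ_mark_fold,
                 germ_density_fold = germ_density_fold,
                 foci_per_nucleus = foci_per_nucleus,
                 focus_sigma = focus_sigma,
                 focus_amplitude = focus_amplitude, noise_sd = noise_sd,
                 dna_base = dna_base, mark_base = mark_base,
                 seed = as.integer(seed)),
            class = "image_sim_spec")
}

place_discs <- function(n, shape, radius_range, margin = 2, max_tries = 500) {
  centers <- matrix(numeric(0), ncol = 3)   # row, col, radius
  for (i in seq_len(n)) {
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      r <- stats::runif(1, radius_range[1], radius_range[2])
      row <- stats::runif(1, r + margin + 1, shape[1] - r - margin)
      col <- stats::runif(1, r + margin + 1, shape[2] - r - margin)
      if (nrow(centers) == 0L ||
          all(sqrt((centers[, 1] - row)^2 + (centers[, 2] - col)^2) >
              centers[, 3] + r + margin)) {
        centers <- rbind(centers, c(row, col, r))
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stop("infeasible image spec: could not place nucleus ", i,
           " after ", max_tries, " tries (too many or too large nuclei)")
  }
  centers
}

#' Simulate a two-channel nucleus image
#'
#' Germ nuclei have, before noise, exactly `germ_mark_fold` times the
#' somatic mark/DNA ratio and `germ_density_fold` times the somatic DNA
#' intensity per pixel. Foci are additive Gaussian spots on the mark
#' channel; their centers are recorded in the truth table. Placement
#' failure after bounded retries signals an infeasible spec.
#'
#' @param spec An [image_sim_spec()].
#' @return List with `channels` (named list `dna`, `mark`), `labels`
#'   (integer mask), `classes` (data.frame `nucleus_id`, `class`), `truth`
#'   (list: per-nucleus table with programmed folds and geometry, focus
#'   table) and `spec`.
#' @export
simulate_nuclei_image <- function(spec) {
  stopifnot(inherits(spec, "image_sim_spec"))
  run_seeded(spec$seed, function() {
    n <- spec$n_germ + spec$n_somatic
    shape <- spec$image_shape
    centers <- place_discs(n, shape, spec$nucleus_radius_range)
    class <- sample(c(rep("germ", spec$n_germ),
                      rep("somatic", spec$n_somatic)))
    dna <- matrix(0, shape[1], shape[2])
    mark <- matrix(0, shape[1], shape[2])
    labels <- matrix(0L, shape[1], shape[2])
    dna_val <- ifelse(class == "germ",
                      spec$germ_density_fold * spec$dna_base, spec$dna_base)
    mark_val <- ifelse(class == "germ",
                       spec$germ_mark_fold * spec$germ_density_fold *
                         spec$mark_base, spec$mark_base)
    rows <- row(labels); cols <- col(labels)
    for (i in seq_len(n)) {
      inside <- (rows - centers[i, 1])^2 + (cols - centers[i, 2])^2 <=
        centers[i, 3]^2
      labels[inside] <- i
      dna[inside] <- dna_val[i]
      mark[inside] <- mark_val[i]
    }
    foci <- NULL
    if (spec$foci_per_nucleus > 0) {
      for (i in seq_len(n)) {
        for (k in seq_len(spec$foci_per_nucleus)) {
          ang <- stats::runif(1, 0, 2 * pi)
          rad <- stats::runif(1, 0, 0.6 * centers[i, 3])
          fr <- centers[i, 1] + rad * cos(ang)
          fc <- centers[i, 2] + rad * sin(ang)
          amp <- spec$focus_amplitude * mark_val[i]
          w <- ceiling(3 * spec$focus_sigma)
          rr <- max(1, floor(fr - w)):min(shape[1], ceiling(fr + w))
          cc <- max(1, floor(fc - w)):min(shape[2], ceiling(fc + w))
          g <- outer(rr, cc, function(a, b)
            amp * exp(-((a - fr)^2 + (b - fc)^2) / (2 * spec$focus_sigma^2)))
          mark[rr, cc] <- mark[rr, cc] + g
          foci <- rbind(foci, data.frame(nucleus_id = i, row = fr, col = fc,
                                         sigma = spec$focus_sigma,
                                         amplitude = amp))
        }
      }
    }
    if (spec$noise_sd > 0) {
      dna <- pmax(dna + stats::rnorm(length(dna), 0, spec$noise_sd), 0)
      mark <- pmax(mark + stats::rnorm(length(mark), 0, spec$noise_sd), 0)
      dim(dna) <- dim(mark) <- shape
    }
    nuclei <- data.frame(
      nucleus_id = seq_len(n), class = class,
      center_row = centers[, 1], center_col = centers[, 2],
      radius = centers[, 3],
      true_mark_fold = ifelse(class == "germ", spec$germ_mark_fold, 1),
      true_density_fold = ifelse(class == "germ", spec$germ_density_fold, 1),
      stringsAsFactors = FALSE)
    list(channels = list(dna = dna, mark = mark), labels = labels,
         classes = data.frame(nucleus_id = seq_len(n), class = class,
                              stringsAsFactors = FALSE),
         truth = list(nuclei = nuclei, foci = foci), spec = spec)
  })
}

#' Convert a simulated image to a [labeled_image()]
#'
#' @param sim Result of [simulate_nuclei_image()].
#' @param exclude_border Passed to [labeled_image()].
#' @return A `labeled_image`.
#' @export
as_labeled_image <- function(sim, exclude_border = TRUE) {
  labeled_image(sim$channels, sim$labels,
                stats::setNames(sim$classes$class,
                                as.character(sim$classes$nucleus_id)),
                exclude_border = exclude_border)
}

#' Write a simulated image to disk
#'
#' Emits 16-bit grayscale TIFFs (`dna.tif`, `mark.tif`, rounded to integer
#' intensity units), a 16-bit label TIFF (`labels.tif`), the class table
#' (`classes.csv`) and the ground truth (`truth.json`).
#'
#' @param sim Result of [simulate_nuclei_image()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_nuclei_image <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(dna = file.path(dir, "dna.tif"),
             mark = file.path(dir, "mark.tif"),
             labels = file.path(dir, "labels.tif"),
             classes = file.path(dir, "classes.csv"),
             truth = file.path(dir, "truth.json"))
  write_intensity_image(sim$channels$dna, paths[["dna"]])
  write_intensity_image(sim$channels$mark, paths[["mark"]])
  write_label_image(sim$labels, paths[["labels"]])
  utils::write.csv(sim$classes, paths[["classes"]], row.names = FALSE)
  truth <- sim$truth
  truth$spec <- unclass(sim$spec)
  jsonlite::write_json(truth, paths[["truth"]], digits = NA, auto_unbox = TRUE)
  invisible(paths)
}
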