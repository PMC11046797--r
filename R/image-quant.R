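#' Per-nucleus immunofluorescence quantification
#'
#' Quantification of epigenetic-mark staining in single-plane images of
#' tissue sections or cultured cells. Nuclei are provided as an integer
#' label mask (segmentation is upstream) together with a germ/somatic class
#' per nucleus. Mark level per amount of chromatin is the ratio of total
#' mark to total DNA-counterstain intensity per nucleus; dividing by the
#' mean somatic ratio of the same image yields a normalized intensity that
#' can be pooled across images.
#'
#' @name image-quant
NULL

#' Bundle intensity channels, a label mask and nucleus classes
#'
#' @param channels Named list of numeric matrices (one per channel), all of
#'   the same dimension, finite and >= 0.
#' @param labels Integer matrix of the same dimension; 0 = background,
#'   k > 0 = nucleus k.
#' @param classes Named character vector mapping nucleus id (as character)
#'   to one of `"germ"`, `"somatic"`, `"excluded"`.
#' @param exclude_border Flag nuclei touching the image border as
#'   `excluded` (border truncation biases area and totals).
#' @return Object of class `labeled_image`.
#' @export
labeled_image <- function(channels, labels, classes, exclude_border = TRUE) {
  if (!is.list(channels) || is.null(names(channels)) ||
      any(!nzchar(names(channels))))
    stop("channels must be a named list of matrices")
  dims <- lapply(channels, dim)
  if (length(unique(dims)) != 1L || !identical(dims[[1]], dim(labels)))
    stop("all channels and the label mask must share one shape")
  for (nm in names(channels)) {
    ch <- channels[[nm]]
    if (any(!is.finite(ch)) || any(ch < 0))
      stop("channel '", nm, "' has non-finite or negative intensities")
  }
  ids <- sort(setdiff(unique(as.integer(labels)), 0L))
  if (is.null(names(classes)))
    stop("classes must be named by nucleus id")
  missing_ids <- setdiff(names(classes), as.character(ids))
  if (length(missing_ids))
    stop("class given for nucleus id(s) absent from labels: ",
         paste(utils::head(missing_ids, 5), collapse = ", "))
  if (!all(classes %in% c("germ", "somatic", "excluded")))
    stop("classes must be 'germ', 'somatic' or 'excluded'")
  cls <- stats::setNames(rep("excluded", length(ids)), as.character(ids))
  cls[names(classes)] <- classes
  if (exclude_border && length(ids)) {
    nr <- nrow(labels); nc <- ncol(labels)
    border_ids <- unique(c(labels[1, ], labels[nr, ], labels[, 1], labels[, nc]))
    border_ids <- setdiff(border_ids, 0L)
    cls[as.character(border_ids)] <- "excluded"
  }
  structure(list(channels = channels, labels = labels, classes = cls),
            class = "labeled_image")
}

#' @export
print.labeled_image <- function(x, ...) {
  cat("labeled_image:", paste(dim(x$labels), collapse = " x "), "px,",
      length(x$channels), "channel(s) [",
      paste(names(x$channels), collapse = ", "), "]\n")
  cat("nuclei:", sum(x$classes == "germ"), "germ,",
      sum(x$classes == "somatic"), "somatic,",
      sum(x$classes == "excluded"), "excluded\n")
  invisible(x)
}

nucleus_sums <- function(img, channel) {
  ids <- as.integer(names(img$classes))
  lab <- as.integer(img$labels)
  keep <- lab > 0L
  f <- factor(lab[keep], levels = ids)
  list(ids = ids,
       area = as.numeric(tabulate(f, nbins = length(ids))),
       total = as.numeric(tapply(as.numeric(img$channels[[channel]])[keep],
                                 f, sum, default = 0)))
}

check_channel <- function(img, channel) {
  if (!channel %in% names(img$channels))
    stop("channel '", channel, "' not present in image")
}

#' Quantify mark level per amount of chromatin, somatic-normalized
#'
#' Per non-excluded nucleus: `ratio = mark_total / dna_total`, then
#' `normalized_intensity = ratio / mean(ratio of somatic nuclei in this
#' image)`. Normalization is per image, so records from multiple images can
#' be pooled. Nuclei with `dna_total == 0` are flagged invalid and excluded
#' from the somatic reference mean.
#'
#' For samples without a usable DNA counterstain (e.g. after denaturation),
#' pass `dna_channel = NULL` and a `density_table` giving a chromatin
#' density (intensity per pixel) per nucleus class, measured on matched
#' samples; `dna_total` is then `density * area`.
#'
#' @param img A [labeled_image()].
#' @param mark_channel,dna_channel Channel names.
#' @param density_table Optional data.frame with columns `class`,
#'   `density`, used when `dna_channel` is `NULL`.
#' @return data.frame with one row per non-excluded nucleus: `nucleus_id`,
#'   `class`, `area`, `mark_total`, `dna_total`, `ratio`,
#'   `normalized_intensity`, `valid`.
#' @export
quantify_mark <- function(img, mark_channel, dna_channel = "dna",
                          density_table = NULL) {
  stopifnot(inherits(img, "labeled_image"))
  check_channel(img, mark_channel)
  ms <- nucleus_sums(img, mark_channel)
  if (!is.null(dna_channel)) {
    check_channel(img, dna_channel)
    dna_total <- nucleus_sums(img, dna_channel)$total
  } else {
    if (is.null(density_table) ||
        !all(c("class", "density") %in% names(density_table)))
      stop("without a DNA channel, a density_table (class, density) is required")
    cls <- unname(img$classes[as.character(ms$ids)])
    dens <- density_table$density[match(cls, density_table$class)]
    if (any(is.na(dens) & cls != "excluded"))
      stop("density_table lacks a density for some nucleus class")
    dna_total <- dens * ms$area
  }
  res <- data.frame(nucleus_id = ms$ids,
                    class = unname(img$classes[as.character(ms$ids)]),
                    area = ms$area, mark_total = ms$total,
                    dna_total = dna_total, stringsAsFactors = FALSE)
  res <- res[res$class != "excluded", , drop = FALSE]
  res$valid <- res$dna_total > 0
  res$ratio <- ifelse(res$valid, res$mark_total / res$dna_total, NA_real_)
  ref <- res$ratio[res$class == "somatic" & res$valid]
  if (length(ref) == 0L)
    stop("no normalization reference: image has no valid somatic nucleus")
  res$normalized_intensity <- res$ratio / mean(ref)
  rownames(res) <- NULL
  res
}

#' Quantify chromatin density per unit area, somatic-normalized
#'
#' Per non-excluded nucleus: `density = dna_total / area` (DNA counterstain
#' intensity per pixel), normalized by the mean somatic density of the same
#' image.
#'
#' @param img A [labeled_image()].
#' @param dna_channel DNA counterstain channel name.
#' @return data.frame with `nucleus_id`, `class`, `area`, `dna_total`,
#'   `density`, `normalized_density`.
#' @export
quantify_density <- function(img, dna_channel = "dna") {
  stopifnot(inherits(img, "labeled_image"))
  check_channel(img, dna_channel)
  ds <- nucleus_sums(img, dna_channel)
  res <- data.frame(nucleus_id = ds$ids,
                    class = unname(img$classes[as.character(ds$ids)]),
                    area = ds$area, dna_total = ds$total,
                    stringsAsFactors = FALSE)
  res <- res[res$class != "excluded" & res$area > 0, , drop = FALSE]
  res$density <- res$dna_total / res$area
  ref <- res$density[res$class == "somatic"]
  if (length(ref) == 0L)
    stop("no normalization reference: image has no somatic nucleus")
  res$normalized_density <- res$density / mean(ref)
  rownames(res) <- NULL
  res
}

pad_matrix <- function(m, k, value = 0) {
  out <- matrix(value, nrow(m) + 2 * k, ncol(m) + 2 * k)
  out[(k + 1):(k + nrow(m)), (k + 1):(k + ncol(m))] <- m
  out
}

pad_replicate <- function(m, k) {
  ri <- c(rep(1L, k), seq_len(nrow(m)), rep(nrow(m), k))
  ci <- c(rep(1L, k), seq_len(ncol(m)), rep(ncol(m), k))
  m[ri, ci, drop = FALSE]
}

unpad_matrix <- function(m, k, nr, nc) {
  m[(k + 1):(k + nr), (k + 1):(k + nc), drop = FALSE]
}

# Exact Euclidean distance from each mask pixel to the nearest background
# pixel; the image border counts as background (1-pixel zero pad).
mask_distance <- function(mask) {
  bin <- pad_matrix(ifelse(mask, 1L, 0L), 1L)
  d <- EBImage::distmap(bin, metric = "euclidean")
  unpad_matrix(as.matrix(d), 1L, nrow(mask), ncol(mask))
}

#' Radial signal profile over equal-area concentric shells
#'
#' Implements eroded-volume-fraction analysis on a 2-D nucleus section:
#' pixels are ranked by Euclidean distance to the nucleus boundary and
#' split into `n_shells` quantile bins of equal area (within one pixel;
#' ties broken by pixel linear index). Shell 1 is the outermost
#' (periphery) shell. The profile reports each shell's share of total
#' intensity as a percentage; with equal areas this equals the mean-shell-
#' intensity profile up to the one-pixel discretization.
#'
#' @param intensity Numeric matrix.
#' @param mask Logical (or 0/1) matrix of the same dimension; the nucleus.
#' @param n_shells Number of shells (default 25).
#' @return Object of class `radial_profile`: list with `n_shells`,
#'   `shell_percent` (outermost first, sums to 100), `shell_area`,
#'   `shell_mean` (mean intensity per shell).
#' @export
evf_profile <- function(intensity, mask, n_shells = 25) {
  mask <- mask > 0
  if (!identical(dim(intensity), dim(mask)))
    stop("intensity and mask must share one shape")
  npx <- sum(mask)
  if (npx < n_shells)
    stop("mask has fewer pixels (", npx, ") than shells (", n_shells, ")")
  d <- mask_distance(mask)
  idx <- which(mask)
  idx <- idx[order(d[idx], idx)]          # ties by linear pixel index (documented)
  shell <- floor((seq_along(idx) - 1) * n_shells / npx) + 1L
  vals <- intensity[idx]
  total <- sum(vals)
  if (total <= 0) stop("total intensity in the mask is zero")
  sums <- as.numeric(rowsum(vals, shell)[, 1])
  area <- tabulate(shell, nbins = n_shells)
  structure(list(n_shells = n_shells,
                 shell_percent = 100 * sums / total,
                 shell_area = area,
                 shell_mean = sums / area),
            class = "radial_profile")
}

#' @export
print.radial_profile <- function(x, ...) {
  cat("radial_profile:", x$n_shells,
      "equal-area shells (outermost first)\n")
  print(round(x$shell_percent, 2))
  invisible(x)
}

#' Segment bright foci inside a nucleus
#'
#' White top-hat filtering with a disc structuring element of radius
#' `se_radius` (edge-replicated padding, so a flat image yields no foci),
#' followed by thresholding at `mean + k_sigma * SD` of the top-hat values
#' inside the nucleus, and retention of connected components of at least
#' `min_size` pixels.
#'
#' @param intensity Numeric matrix (the channel carrying the foci).
#' @param mask Logical matrix; the nucleus.
#' @param se_radius Disc structuring-element radius in pixels.
#' @param k_sigma Threshold stringency in SD units.
#' @param min_size Minimum focus size in pixels.
#' @return Object of class `focus_set`: list with `labels` (integer matrix,
#'   0 = none), `n`, `sizes`, and the threshold used. May be empty.
#' @export
segment_foci <- function(intensity, mask, se_radius = 5, k_sigma = 2,
                         min_size = 4) {
  mask <- mask > 0
  if (!any(mask)) stop("empty nucleus mask")
  if (!identical(dim(intensity), dim(mask)))
    stop("intensity and mask must share one shape")
  k <- as.integer(se_radius)
  brush <- EBImage::makeBrush(2L * k + 1L, shape = "disc")
  th <- EBImage::whiteTopHat(pad_replicate(intensity, k), brush)
  th <- unpad_matrix(as.matrix(th), k, nrow(intensity), ncol(intensity))
  vals <- th[mask]
  thr <- mean(vals) + k_sigma * stats::sd(vals)
  fg <- (th > thr) & mask
  if (!any(fg) || !is.finite(thr)) {
    lab <- matrix(0L, nrow(mask), ncol(mask))
    return(structure(list(labels = lab, n = 0L, sizes = integer(0),
                          threshold = thr), class = "focus_set"))
  }
  lab <- EBImage::bwlabel(ifelse(fg, 1L, 0L))
  lab <- matrix(as.integer(lab), nrow(mask), ncol(mask))
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= min_size)
  relab <- integer(length(sizes))
  relab[keep] <- seq_along(keep)
  lab[lab > 0L] <- relab[lab[lab > 0L]]
  structure(list(labels = lab, n = length(keep),
                 sizes = sizes[keep], threshold = thr),
            class = "focus_set")
}

#' @export
print.focus_set <- function(x, ...) {
  cat("focus_set:", x$n, "focus/foci; sizes:",
      paste(x$sizes, collapse = ", "), "\n")
  invisible(x)
}

#' Enrichment of a co-detected channel at segmented foci
#'
#' Per focus: mean intensity of the co-detected channel over the focus,
#' relative to its mean over the whole nucleus.
#'
#' @param foci A [segment_foci()] result.
#' @param codetect Numeric matrix; the co-detected channel.
#' @param mask Logical matrix; the nucleus.
#' @return Numeric vector of per-focus enrichment values (length `foci$n`).
#' @export
focus_enrichment <- function(foci, codetect, mask) {
  stopifnot(inherits(foci, "focus_set"))
  mask <- mask > 0
  if (!identical(dim(codetect), dim(mask)))
    stop("codetect and mask must share one shape")
  nuc_mean <- mean(codetect[mask])
  if (nuc_mean == 0) stop("zero whole-nucleus mean in co-detected channel")
  if (foci$n == 0L) return(numeric(0))
  if (any(foci$labels > 0L & !mask)) stop("foci extend outside the nucleus mask")
  means <- as.numeric(tapply(codetect[foci$labels > 0L],
                             foci$labels[foci$labels > 0L], mean))
  means / nuc_mean
}
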