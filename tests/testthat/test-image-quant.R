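test_that("normalized intensity divides by the somatic mean ratio", {
  img <- toy_image(list(c(10, 20), c(10, 20), c(10, 20), c(10, 60)),
                   c("somatic", "somatic", "somatic", "germ"))
  q <- quantify_mark(img, "mark", "dna")
  expect_equal(q$ratio, c(2, 2, 2, 6))
  expect_equal(q$normalized_intensity, c(1, 1, 1, 3))
  # a single somatic nucleus self-normalizes to 1
  img1 <- toy_image(list(c(7, 13)), "somatic")
  expect_equal(quantify_mark(img1, "mark", "dna")$normalized_intensity, 1)
})

test_that("missing reference and zero-DNA nuclei are handled", {
  img <- toy_image(list(c(10, 20), c(10, 20)), c("germ", "germ"))
  expect_error(quantify_mark(img, "mark", "dna"), "no normalization reference")
  # zero-DNA nucleus flagged invalid and excluded from the somatic mean
  img2 <- toy_image(list(c(10, 20), c(0, 20), c(10, 40)),
                    c("somatic", "somatic", "germ"))
  q <- quantify_mark(img2, "mark", "dna")
  expect_false(q$valid[2])
  expect_true(is.na(q$normalized_intensity[2]))
  expect_equal(q$normalized_intensity[c(1, 3)], c(1, 2))
})

test_that("somatic mean of normalized intensity is 1 on random images", {
  set.seed(5)
  for (case in 1:10) {
    n <- sample(3:8, 1)
    vals <- replicate(n, c(runif(1, 5, 50), runif(1, 5, 50)),
                      simplify = FALSE)
    cls <- c("somatic", sample(c("germ", "somatic"), n - 1, replace = TRUE))
    q <- quantify_mark(toy_image(vals, cls), "mark", "dna")
    expect_equal(mean(q$normalized_intensity[q$class == "somatic"]), 1,
                 tolerance = 1e-9)
  }
})

test_that("normalized quantities are invariant to channel rescaling", {
  img <- toy_image(list(c(10, 20), c(15, 33), c(12, 60)),
                   c("somatic", "somatic", "germ"))
  q0 <- quantify_mark(img, "mark", "dna")
  d0 <- quantify_density(img, "dna")
  img$channels$mark <- img$channels$mark * 7.3
  expect_equal(quantify_mark(img, "mark", "dna")$normalized_intensity,
               q0$normalized_intensity)
  img$channels$dna <- img$channels$dna * 0.21
  expect_equal(quantify_density(img, "dna")$normalized_density,
               d0$normalized_density)
})

test_that("chromatin density is per-pixel intensity normalized to somatic", {
  img <- toy_image(list(c(10, 1), c(10, 1), c(5, 1)),
                   c("somatic", "somatic", "germ"))
  d <- quantify_density(img, "dna")
  expect_equal(d$density, c(10, 10, 5))
  expect_equal(d$normalized_density, c(1, 1, 0.5))
  # uniform intensity everywhere -> all normalized densities 1
  img2 <- toy_image(list(c(4, 1), c(4, 1), c(4, 1)),
                    c("somatic", "germ", "germ"))
  expect_equal(quantify_density(img2, "dna")$normalized_density, c(1, 1, 1))
})

test_that("density-table normalization substitutes for a DNA channel", {
  img <- toy_image(list(c(0, 20), c(0, 20), c(0, 30)),
                   c("somatic", "somatic", "germ"))
  dt <- data.frame(class = c("somatic", "germ"), density = c(10, 5))
  q <- quantify_mark(img, "mark", dna_channel = NULL, density_table = dt)
  # ratios: somatic 20/(10*16), germ 30/(5*16) -> germ fold = 3
  expect_equal(q$normalized_intensity, c(1, 1, 3))
  expect_error(quantify_mark(img, "mark", dna_channel = NULL),
               "density_table")
})

test_that("border-touching nuclei are excluded by default", {
  labels <- matrix(0L, 20, 20)
  labels[1:4, 8:12] <- 1L       # touches the top border
  labels[10:14, 8:12] <- 2L
  ch <- list(dna = matrix(1, 20, 20), mark = matrix(2, 20, 20))
  img <- labeled_image(ch, labels, c("1" = "somatic", "2" = "somatic"))
  expect_equal(quantify_mark(img, "mark", "dna")$nucleus_id, 2L)
  img2 <- labeled_image(ch, labels, c("1" = "somatic", "2" = "somatic"),
                        exclude_border = FALSE)
  expect_equal(quantify_mark(img2, "mark", "dna")$nucleus_id, c(1L, 2L))
})

test_that("EVF of uniform intensity gives flat equal-area shells", {
  mask <- make_disc_mask(120, 50)
  p <- evf_profile(matrix(1, 120, 120), mask, 25)
  expect_equal(sum(p$shell_percent), 100, tolerance = 1e-9)
  expect_true(all(abs(p$shell_percent - 4) <= 0.1))
  expect_lte(max(p$shell_area) - min(p$shell_area), 25)
  # irregular mask too
  mask2 <- mask | (row(mask) > 40 & row(mask) < 80 & col(mask) > 100 &
                     col(mask) < 118)
  p2 <- evf_profile(matrix(1, 120, 120), mask2, 25)
  expect_true(all(abs(p2$shell_percent - 4) <= 0.1))
})

test_that("a point mass at the most interior pixel lands in the last shell", {
  mask <- make_disc_mask(61, 25)
  intensity <- matrix(0, 61, 61)
  intensity[31, 31] <- 1           # unique deepest pixel of the disc
  p <- evf_profile(intensity, mask, 25)
  expect_equal(p$shell_percent[25], 100)
  expect_equal(sum(p$shell_percent[1:24]), 0)
})

test_that("EVF matches the per-pixel brute-force oracle", {
  center <- 51
  mask <- make_disc_mask(101, 50, center)
  intensity <- sqrt((row(mask) - center)^2 + (col(mask) - center)^2)
  p <- evf_profile(intensity, mask, 25)
  expect_equal(p$shell_percent, evf_oracle(intensity, mask, 25))
  # and on an irregular mask with random intensity
  set.seed(9)
  mask2 <- make_disc_mask(80, 30, 40)
  mask2[20:60, 55:75] <- TRUE
  intensity2 <- matrix(runif(80 * 80), 80, 80)
  p2 <- evf_profile(intensity2, mask2, 25)
  expect_equal(p2$shell_percent, evf_oracle(intensity2, mask2, 25))
})

test_that("EVF is invariant to permuting intensities within a shell", {
  set.seed(13)
  mask <- make_disc_mask(60, 25)
  intensity <- matrix(runif(3600, 1, 2), 60, 60)
  p <- evf_profile(intensity, mask, 10)
  # recompute shell assignment exactly as documented, then shuffle in-shell
  d <- pgcquant:::mask_distance(mask)
  idx <- which(mask)
  idx <- idx[order(d[idx], idx)]
  shell <- floor((seq_along(idx) - 1) * 10 / length(idx)) + 1
  for (s in unique(shell)) {
    px <- idx[shell == s]
    intensity[px] <- intensity[sample(px)]
  }
  expect_equal(evf_profile(intensity, mask, 10)$shell_percent,
               p$shell_percent)
})

test_that("EVF rejects masks smaller than the shell count", {
  mask <- matrix(FALSE, 10, 10); mask[1:2, 1:2] <- TRUE
  expect_error(evf_profile(matrix(1, 10, 10), mask, 25), "fewer pixels")
})

test_that("top-hat focus segmentation finds planted spots and nothing flat", {
  mask <- make_disc_mask(80, 30, 40)
  expect_equal(segment_foci(matrix(5, 80, 80), mask)$n, 0)
  spot <- function(m, r, c, amp = 10, sigma = 1.5) {
    m + amp * exp(-((row(m) - r)^2 + (col(m) - c)^2) / (2 * sigma^2))
  }
  one <- spot(matrix(5, 80, 80), 40, 40)
  fs1 <- segment_foci(one, mask, se_radius = 5, k_sigma = 2, min_size = 3)
  expect_equal(fs1$n, 1)
  expect_true(fs1$labels[40, 40] > 0)   # contains the spot peak
  two <- spot(one, 30, 50)
  fs2 <- segment_foci(two, mask, se_radius = 5, k_sigma = 2, min_size = 3)
  expect_equal(fs2$n, 2)
})

test_that("focus enrichment is the focus mean over the nucleus mean", {
  mask <- matrix(TRUE, 40, 40)
  foci_lab <- matrix(0L, 40, 40)
  foci_lab[10:12, 10:12] <- 1L
  fs <- structure(list(labels = foci_lab, n = 1L, sizes = 9L,
                       threshold = 0), class = "focus_set")
  expect_equal(focus_enrichment(fs, matrix(4.2, 40, 40), mask), 1)
  # two-level closed form: focus at 3c, rest at c
  codetect <- matrix(1, 40, 40)
  codetect[foci_lab == 1L] <- 3
  expected <- 3 / ((9 * 3 + (1600 - 9) * 1) / 1600)
  expect_equal(focus_enrichment(fs, codetect, mask), expected)
  expect_error(focus_enrichment(fs, matrix(0, 40, 40), mask),
               "zero whole-nucleus mean")
})

test_that("planted-focus enrichment is recovered from simulated images", {
  spec <- image_sim_spec(n_germ = 0, n_somatic = 6, foci_per_nucleus = 1,
                         focus_amplitude = 3, focus_sigma = 1.5,
                         nucleus_radius_range = c(14, 18),
                         image_shape = c(300, 300), seed = 8)
  sim <- simulate_nuclei_image(spec)
  enr <- unlist(lapply(sim$truth$nuclei$nucleus_id, function(id) {
    mask <- sim$labels == id
    fs <- segment_foci(sim$channels$mark, mask, se_radius = 5,
                       k_sigma = 2, min_size = 3)
    focus_enrichment(fs, sim$channels$mark, mask)
  }))
  expect_gte(length(enr), 4)
  expect_true(all(enr > 1.5))
  # each focus lies near a planted focus center
  for (id in sim$truth$nuclei$nucleus_id) {
    mask <- sim$labels == id
    fs <- segment_foci(sim$channels$mark, mask, se_radius = 5,
                       k_sigma = 2, min_size = 3)
    if (fs$n == 0) next
    f <- sim$truth$foci[sim$truth$foci$nucleus_id == id, ]
    px <- which(fs$labels > 0, arr.ind = TRUE)
    expect_lt(min(sqrt((px[, 1] - f$row)^2 + (px[, 2] - f$col)^2)), 3)
  }
})
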