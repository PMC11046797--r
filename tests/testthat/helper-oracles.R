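# Independent per-base / per-pixel oracles used to validate the interval
# algebra and the radial-profile construction. These deliberately avoid the
# package's own primitives: intervals become boolean occupancy vectors,
# distances are computed by direct minimization.

occ_from_df <- function(df, genome) {
  occ <- lapply(genome, function(len) logical(len))
  for (i in seq_len(nrow(df))) {
    ch <- as.character(df$chrom[i])
    occ[[ch]][(df$start[i] + 1):df$end[i]] <- TRUE
  }
  occ
}

occ_from_set <- function(x, genome) occ_from_df(intervals_df(x), genome)

occ_to_df <- function(occ) {
  out <- NULL
  for (ch in names(occ)) {
    r <- rle(occ[[ch]])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values
    if (any(keep))
      out <- rbind(out, data.frame(chrom = ch, start = starts[keep],
                                   end = ends[keep],
                                   stringsAsFactors = FALSE))
  }
  if (is.null(out))
    data.frame(chrom = character(), start = numeric(), end = numeric(),
               stringsAsFactors = FALSE)
  else out[order(out$chrom, out$start), , drop = FALSE]
}

occ_op <- function(a, b, op) mapply(op, a, b, SIMPLIFY = FALSE)

random_interval_df <- function(genome, n) {
  chrom <- sample(names(genome), n, replace = TRUE)
  len <- unname(genome[chrom])
  start <- floor(runif(n) * (len - 1))
  end <- pmin(len, start + 1 + floor(rexp(n, rate = 1 / (len / 20))))
  data.frame(chrom = chrom, start = start, end = end,
             stringsAsFactors = FALSE)
}

expect_same_intervals <- function(x, df_expected) {
  df <- intervals_df(x)
  rownames(df) <- rownames(df_expected) <- NULL
  df_expected$chrom <- as.character(df_expected$chrom)
  df_expected$start <- as.numeric(df_expected$start)
  df_expected$end <- as.numeric(df_expected$end)
  df$start <- as.numeric(df$start)
  df$end <- as.numeric(df$end)
  expect_equal(df, df_expected)
}

# Direct per-pixel EVF oracle: Euclidean distance of every mask pixel to
# the nearest background pixel (image border counts as background), then
# quantile binning into n equal-area shells, ties by linear pixel index.
evf_oracle <- function(intensity, mask, n_shells) {
  mask <- mask > 0
  nr <- nrow(mask); nc <- ncol(mask)
  fg <- which(mask, arr.ind = TRUE)
  bg <- which(!mask, arr.ind = TRUE)
  # restrict to background pixels that can be nearest: those 8-adjacent to
  # the mask (the nearest background pixel always has a foreground
  # 8-neighbour)
  if (nrow(bg)) {
    adj <- vapply(seq_len(nrow(bg)), function(i) {
      r <- bg[i, 1]; c <- bg[i, 2]
      any(mask[max(1, r - 1):min(nr, r + 1), max(1, c - 1):min(nc, c + 1)])
    }, logical(1))
    bg <- bg[adj, , drop = FALSE]
  }
  d <- vapply(seq_len(nrow(fg)), function(i) {
    r <- fg[i, 1]; c <- fg[i, 2]
    dmin <- min(r, c, nr + 1 - r, nc + 1 - c)   # virtual border background
    if (nrow(bg))
      dmin <- min(dmin, sqrt(min((bg[, 1] - r)^2 + (bg[, 2] - c)^2)))
    dmin
  }, numeric(1))
  lin <- (fg[, 2] - 1) * nr + fg[, 1]
  ord <- order(d, lin)
  npx <- length(ord)
  shell <- floor((seq_len(npx) - 1) * n_shells / npx) + 1
  vals <- intensity[lin[ord]]
  sums <- vapply(seq_len(n_shells), function(s) sum(vals[shell == s]),
                 numeric(1))
  100 * sums / sum(vals)
}

make_disc_mask <- function(size, radius, center = (size + 1) / 2) {
  m <- matrix(FALSE, size, size)
  m[(row(m) - center)^2 + (col(m) - center)^2 <= radius^2] <- TRUE
  m
}

# Tiny hand-built labeled image: nuclei are rectangles with constant
# channel values; value matrices are lists id -> c(dna, mark).
toy_image <- function(values, classes, box = 4, pad = 3) {
  n <- length(values)
  side <- n * (box + pad) + pad
  labels <- matrix(0L, side, side)
  dna <- mark <- matrix(0, side, side)
  for (i in seq_len(n)) {
    r0 <- pad + (i - 1) * (box + pad) + 1
    rows <- r0:(r0 + box - 1)
    cols <- (pad + 1):(pad + box)
    labels[rows, cols] <- i
    dna[rows, cols] <- values[[i]][1]
    mark[rows, cols] <- values[[i]][2]
  }
  labeled_image(list(dna = dna, mark = mark), labels,
                stats::setNames(classes, as.character(seq_len(n))))
}
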