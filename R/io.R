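#' Readers and writers for the formats the pipeline touches
#'
#' All genomic text formats follow the BED convention (tab-separated,
#' 0-based half-open, no header unless noted). Floats are serialized with
#' `%.6g` so that write -> read -> write is byte-stable.
#'
#' @name io-formats
NULL

fmt_num <- function(x) {
  out <- gsub(" ", "", formatC(x, format = "g", digits = 6))
  whole <- is.finite(x) & x == round(x) & abs(x) < 1e15
  out[whole] <- sprintf("%.0f", x[whole])
  out
}

#' Write a data.frame as TSV with stable float formatting
#'
#' @param df data.frame.
#' @param path Output path.
#' @param col.names Write a header line.
#' @return Invisibly, `path`.
#' @export
write_table_tsv <- function(df, path, col.names = TRUE) {
  out <- df
  for (j in seq_along(out))
    if (is.double(out[[j]])) out[[j]] <- fmt_num(out[[j]])
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = col.names)
  invisible(path)
}

read_lines_table <- function(path, n_min, what, header = FALSE,
                             comment = "#") {
  df <- tryCatch(
    utils::read.table(path, sep = "\t", header = header,
                      stringsAsFactors = FALSE, comment.char = comment,
                      quote = ""),
    error = function(e) stop("malformed ", what, " file '", path, "': ",
                             conditionMessage(e)))
  if (ncol(df) < n_min)
    stop(what, " file '", path, "' has ", ncol(df),
         " column(s); expected >= ", n_min)
  df
}

#' Genome file: two-column TSV of chromosome name and length
#'
#' @param path File path.
#' @return Named numeric vector of chromosome lengths.
#' @export
read_genome_file <- function(path) {
  df <- read_lines_table(path, 2, "genome")
  declare_genome(stats::setNames(as.numeric(df[[2]]), as.character(df[[1]])))
}

#' @rdname read_genome_file
#' @param genome Named vector of chromosome lengths.
#' @export
write_genome_file <- function(genome, path) {
  genome <- declare_genome(genome)
  utils::write.table(data.frame(names(genome), fmt_num(unname(genome))),
                     path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

check_bed_coords <- function(df, path) {
  bad <- which(is.na(df$start) | is.na(df$end) | df$end <= df$start)
  if (length(bad))
    stop("malformed interval at line ", bad[1], " of '", path, "'")
  df
}

#' Read and write BED interval files
#'
#' `read_bed()` reads BED3+ (extra columns ignored) into a normalized
#' interval set; `write_bed()` emits BED3. Coordinates outside the declared
#' genome are rejected with the offending line.
#'
#' @param path File path.
#' @param genome Named vector of chromosome lengths.
#' @return `read_bed()`: normalized `GRanges`; `write_bed()`: the path,
#'   invisibly.
#' @export
read_bed <- function(path, genome) {
  df <- read_lines_table(path, 3, "BED")
  names(df)[1:3] <- c("chrom", "start", "end")
  check_bed_coords(df, path)
  interval_set(df$chrom, df$start, df$end, genome)
}

#' @rdname read_bed
#' @param x `GRanges` interval set.
#' @export
write_bed <- function(x, path) {
  df <- intervals_df(x)
  df$start <- fmt_num(df$start)
  df$end <- fmt_num(df$end)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a MACS2 broadPeak file
#'
#' ENCODE broadPeak: BED6 + signalValue, pValue, qValue. Only the interval
#' columns are needed downstream; the rest are kept when present.
#'
#' @param path File path.
#' @return data.frame with `chrom`, `start`, `end` (+ extra columns).
#' @export
read_broadpeak <- function(path) {
  df <- read_lines_table(path, 3, "broadPeak")
  cols <- c("chrom", "start", "end", "name", "score", "strand",
            "signal_value", "p_value", "q_value")
  names(df)[seq_len(min(ncol(df), 9))] <- cols[seq_len(min(ncol(df), 9))]
  check_bed_coords(df, path)
}

#' @rdname read_broadpeak
#' @param peaks data.frame with `chrom`, `start`, `end` (other columns
#'   are generated if absent).
#' @export
write_broadpeak <- function(peaks, path) {
  n <- nrow(peaks)
  out <- data.frame(peaks$chrom, fmt_num(peaks$start), fmt_num(peaks$end),
                    name = sprintf("peak_%d", seq_len(n)),
                    score = 0L, strand = ".",
                    signal = fmt_num(rep(5, n)),
                    p = -1L, q = -1L)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a SICER island table
#'
#' SICER island tables are TSV with the interval in the first three
#' columns and the island false-discovery rate in a version-dependent
#' column; by default the *last* column is taken as the FDR.
#'
#' @param path File path.
#' @param fdr_column Column index holding the FDR; `NULL` = last column.
#' @return data.frame with `chrom`, `start`, `end`, `fdr`.
#' @export
read_sicer_islands <- function(path, fdr_column = NULL) {
  df <- read_lines_table(path, 4, "SICER island")
  if (is.null(fdr_column)) fdr_column <- ncol(df)
  if (fdr_column < 4 || fdr_column > ncol(df))
    stop("fdr_column out of range (file has ", ncol(df), " columns)")
  out <- data.frame(chrom = as.character(df[[1]]), start = df[[2]],
                    end = df[[3]], fdr = as.numeric(df[[fdr_column]]),
                    stringsAsFactors = FALSE)
  bad <- which(is.na(out$fdr) | out$fdr < 0 | out$fdr > 1)
  if (length(bad))
    stop("invalid FDR at line ", bad[1], " of '", path, "'")
  check_bed_coords(out, path)
}

#' @rdname read_sicer_islands
#' @param islands data.frame with `chrom`, `start`, `end`, `fdr`.
#' @export
write_sicer_islands <- function(islands, path) {
  n <- nrow(islands)
  out <- data.frame(islands$chrom, fmt_num(islands$start),
                    fmt_num(islands$end),
                    chip_reads = 100L, control_reads = 10L,
                    p_value = fmt_num(islands$fdr),
                    fold_change = fmt_num(rep(5, n)),
                    fdr = fmt_num(islands$fdr))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read depth tracks
#'
#' `read_bedgraph()` reads 4-column bedGraph runs (track/comment lines
#' skipped); `read_samtools_depth()` reads the 3-column `samtools depth`
#' output (chrom, 1-based position, depth) and converts it to half-open
#' runs, collapsing consecutive positions of equal depth.
#'
#' @param path File path.
#' @return data.frame depth track: `chrom`, `start`, `end`, `depth`.
#' @export
read_bedgraph <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(lines)
  df <- tryCatch(
    utils::read.table(text = paste(lines[keep], collapse = "\n"),
                      sep = "\t", stringsAsFactors = FALSE, quote = ""),
    error = function(e) stop("malformed bedGraph file '", path, "': ",
                             conditionMessage(e)))
  if (ncol(df) < 4)
    stop("bedGraph file '", path, "' has fewer than 4 columns")
  names(df)[1:4] <- c("chrom", "start", "end", "depth")
  check_bed_coords(df, path)
  if (any(is.na(df$depth) | df$depth < 0))
    stop("invalid depth value in '", path, "'")
  df[1:4]
}

#' @rdname read_bedgraph
#' @export
read_samtools_depth <- function(path) {
  df <- read_lines_table(path, 3, "samtools depth")
  names(df)[1:3] <- c("chrom", "pos", "depth")
  df <- df[order(df$chrom, df$pos), ]
  new_run <- c(TRUE, df$chrom[-1] != df$chrom[-nrow(df)] |
                 df$pos[-1] != df$pos[-nrow(df)] + 1 |
                 df$depth[-1] != df$depth[-nrow(df)])
  run <- cumsum(new_run)
  data.frame(chrom = df$chrom[new_run],
             start = df$pos[new_run] - 1,
             end = as.numeric(tapply(df$pos, run, max)),
             depth = df$depth[new_run], stringsAsFactors = FALSE)
}

#' Read annotation and expression tables
#'
#' `read_gene_table()` expects a header with `gene_id`, `chrom`, `strand`,
#' `tss`, `tts`; `read_tpm_table()` a header with `transcript_id`,
#' `gene_id` and replicate TPM columns; `read_repeat_counts()` a header
#' with `element_type`, `repeat_class`, `ip_count`, `input_count`, and
#' applies a configurable repeat-class exclusion list (by default
#' unspecified/unknown/artefact categories and simple repeats except the
#' telomeric repeat).
#'
#' @param path File path.
#' @return data.frame.
#' @export
read_gene_table <- function(path) {
  df <- read_lines_table(path, 5, "gene table", header = TRUE)
  check_gene_table(df)
}

#' @rdname read_gene_table
#' @export
read_tpm_table <- function(path) {
  df <- read_lines_table(path, 3, "TPM table", header = TRUE)
  if (!all(c("transcript_id", "gene_id") %in% names(df)))
    stop("TPM table must have transcript_id and gene_id columns")
  df
}

#' @rdname read_gene_table
#' @param exclude_classes Repeat classes dropped at read time.
#' @param retain_types Element types kept even when their class is
#'   excluded.
#' @export
read_repeat_counts <- function(path,
                               exclude_classes = c("Unspecified", "Unknown",
                                                   "ARTEFACT",
                                                   "Simple_repeat"),
                               retain_types = "(TTAGGG)n") {
  df <- read_lines_table(path, 4, "repeat count", header = TRUE)
  required <- c("element_type", "repeat_class", "ip_count", "input_count")
  if (!all(required %in% names(df)))
    stop("repeat count table must have columns ",
         paste(required, collapse = ", "))
  drop <- df$repeat_class %in% exclude_classes &
    !df$element_type %in% retain_types
  df[!drop, , drop = FALSE]
}

#' Read and write 16-bit grayscale images
#'
#' Intensity and label rasters are stored as 16-bit grayscale TIFF with
#' integer values 0-65535. Writing rounds to integers.
#'
#' @param path File path.
#' @return `read_intensity_image()`: numeric matrix;
#'   `read_label_image()`: integer matrix.
#' @export
read_intensity_image <- function(path) {
  m <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(m)) != 2L) stop("expected a single-plane grayscale image")
  m
}

#' @rdname read_intensity_image
#' @export
read_label_image <- function(path) {
  m <- read_intensity_image(path)
  matrix(as.integer(m), nrow(m), ncol(m))
}

#' @rdname read_intensity_image
#' @param m Numeric (or integer) matrix with values in 0-65535.
#' @export
write_intensity_image <- function(m, path) {
  m <- round(m)
  if (any(m < 0) || any(m > 65535))
    stop("intensity out of 16-bit range")
  tiff::writeTIFF(m / 65535, path, bits.per.sample = 16)
  invisible(path)
}

#' @rdname read_intensity_image
#' @export
write_label_image <- function(m, path) write_intensity_image(m, path)

#' @rdname read_gene_table
#' @export
read_class_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("nucleus_id", "class") %in% names(df)))
    stop("class table must have columns nucleus_id, class")
  df
}
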