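#' Repeat-element enrichment summaries
#'
#' Repressive marks concentrate on the repeated fraction of the genome.
#' Two complementary summaries are provided: the share of sequenced bases
#' falling in the repeat compartment (from a per-base depth track), and
#' per-family IP/input enrichment ratios from read-count tables produced by
#' RepEnrich-style pseudogenome counting.
#'
#' @name repeat-enrichment
NULL

check_depth_track <- function(track) {
  required <- c("chrom", "start", "end", "depth")
  if (!is.data.frame(track) || !all(required %in% names(track)))
    stop("depth track must have columns chrom, start, end, depth")
  if (any(track$end <= track$start)) stop("depth run with end <= start")
  if (any(track$depth < 0)) stop("negative depth")
  invisible(track)
}

#' Fraction of sequenced bases inside a genome compartment
#'
#' Computes (sum of depth over compartment bases) / (sum of depth over all
#' bases) from a run-length encoded depth track, e.g. the proportion of
#' immunoprecipitated DNA lying in the repeated-element compartment.
#'
#' @param track data.frame depth track with `chrom`, `start`, `end`
#'   (0-based half-open runs) and `depth`.
#' @param compartment `interval_set` (e.g. repeats of length >= 50 bp
#'   aggregated with [build_regions()]).
#' @param genome Named vector of chromosome lengths.
#' @return Fraction in \[0, 1\].
#' @export
compartment_fraction <- function(track, compartment, genome) {
  check_depth_track(track)
  genome <- declare_genome(genome)
  if (!identical(genome, genome_of(compartment)))
    stop("compartment is declared on a different genome")
  total <- sum(as.numeric(track$end - track$start) * track$depth)
  if (total == 0) stop("zero genome-wide depth")
  if (nrow(track) == 0L || total_bases(compartment) == 0) return(0)
  ov <- overlap_width_set(as.character(track$chrom), track$start, track$end,
                          compartment)
  sum(ov * track$depth) / total
}

#' IP/input enrichment ratios per repeat type and class
#'
#' Counts are first library-normalized (divided by the library total), then
#' the IP/input ratio is formed per element type, and only then are types
#' grouped into repeat classes. The class value is by default the
#' unweighted mean of its member-type ratios; `weighted = TRUE` weights by
#' input counts instead. Types with a zero input count cannot be ratioed
#' and are dropped with a warning.
#'
#' @param counts data.frame with `element_type`, `repeat_class`,
#'   `ip_count`, `input_count`.
#' @param ip_total,input_total Total read counts of the two libraries.
#' @param weighted Use an input-count-weighted mean per class.
#' @return List with `types` (per-type table incl. `ratio`) and `classes`
#'   (per-class table with `ratio` and `n_types`).
#' @export
family_enrichment <- function(counts, ip_total, input_total,
                              weighted = FALSE) {
  required <- c("element_type", "repeat_class", "ip_count", "input_count")
  if (!is.data.frame(counts) || !all(required %in% names(counts)))
    stop("counts must have columns element_type, repeat_class, ip_count, input_count")
  if (ip_total <= 0 || input_total <= 0) stop("library totals must be > 0")
  if (any(counts$ip_count < 0) || any(counts$input_count < 0))
    stop("negative read counts")
  zero <- counts$input_count == 0
  if (any(zero)) {
    warning("element type(s) with zero input count excluded: ",
            paste(utils::head(counts$element_type[zero], 5), collapse = ", "))
    counts <- counts[!zero, , drop = FALSE]
  }
  counts$ratio <- (counts$ip_count / ip_total) /
    (counts$input_count / input_total)
  cls <- split(counts, counts$repeat_class)
  classes <- do.call(rbind, lapply(names(cls), function(nm) {
    x <- cls[[nm]]
    r <- if (weighted) stats::weighted.mean(x$ratio, x$input_count)
         else mean(x$ratio)
    data.frame(repeat_class = nm, ratio = r, n_types = nrow(x),
               stringsAsFactors = FALSE)
  }))
  list(types = counts, classes = classes)
}

#' Fraction of reads carrying a target repeat
#'
#' Summarizes per-read labels (or pre-tallied counts) of satellite-repeat
#' content, e.g. the percentage of reads containing the pericentric CNM
#' satellite.
#'
#' @param tagged Logical vector of per-read labels, or a tagged-read count.
#' @param total Total read count (required when `tagged` is a count).
#' @return Percentage of reads tagged (0-100).
#' @export
tagged_read_fraction <- function(tagged, total = NULL) {
  if (is.logical(tagged)) {
    if (length(tagged) == 0L) stop("no reads")
    return(100 * mean(tagged))
  }
  if (is.null(total) || total <= 0) stop("total read count must be > 0")
  if (tagged < 0 || tagged > total) stop("tagged count outside [0, total]")
  100 * tagged / total
}
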