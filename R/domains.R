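#' Broad-domain calling and two-cell-type domain comparison
#'
#' Broad repressive histone marks such as H3K9me3 cover the genome in wide
#' domains rather than sharp peaks. Candidate regions come from two callers
#' with complementary strengths: SICER islands (window/gap runs with an FDR
#' per island) and MACS2 broad peaks. The final-domain rule keeps every
#' island with a very small FDR outright, and rescues weaker islands when a
#' broad peak independently supports them.
#'
#' @name domain-calling
NULL

#' Combine SICER islands and MACS2 broad peaks into final domains
#'
#' An island enters the final domain set if its FDR is below `fdr_cut`
#' (strict `<`), or if it is at least partially (>= 1 bp) overlapped by a
#' peak. Peaks only gate inclusion; island coordinates are never trimmed or
#' extended by peaks. The retained islands are then normalized (sorted,
#' overlapping or book-ended islands merged).
#'
#' @param islands data.frame with columns `chrom`, `start`, `end` (0-based
#'   half-open) and `fdr`, as returned by [read_sicer_islands()].
#' @param peaks data.frame with columns `chrom`, `start`, `end` (plus any
#'   others, ignored), as returned by [read_broadpeak()], or an
#'   `interval_set`. May be empty.
#' @param genome Named vector of chromosome lengths.
#' @param fdr_cut FDR threshold below which islands are kept unconditionally.
#' @return Normalized `interval_set` of final domains.
#' @examples
#' gn <- declare_genome(c(chr1 = 10000))
#' isl <- data.frame(chrom = "chr1", start = c(0, 5000), end = c(1000, 6000),
#'                   fdr = c(1e-12, 1e-5))
#' pk <- data.frame(chrom = "chr1", start = 5999, end = 7000)
#' combine_islands_peaks(isl, pk, gn)  # both islands survive
#' @export
combine_islands_peaks <- function(islands, peaks, genome, fdr_cut = 1e-10) {
  stopifnot(is.data.frame(islands))
  required <- c("chrom", "start", "end", "fdr")
  if (!all(required %in% names(islands)))
    stop("islands must have columns chrom, start, end, fdr")
  if (nrow(islands) && (any(!is.finite(islands$fdr)) ||
                        any(islands$fdr < 0) || any(islands$fdr > 1)))
    stop("island FDR values must lie in [0, 1]")
  genome <- declare_genome(genome)
  if (nrow(islands) == 0L)
    return(interval_set(character(), numeric(), numeric(), genome))
  # inclusion is decided per raw island; the survivors are then merged
  keep <- islands$fdr < fdr_cut
  peak_set <- if (inherits(peaks, "interval_set")) peaks
              else interval_set(as.data.frame(peaks), genome = genome)
  if (total_bases(peak_set) > 0)
    keep <- keep | overlaps_any_set(as.character(islands$chrom),
                                    islands$start, islands$end, peak_set)
  interval_set(islands[keep, c("chrom", "start", "end"), drop = FALSE],
               genome = genome)
}

#' Classify domain bases of two cell types
#'
#' Every base inside a domain of either cell type is assigned to one of
#' three classes: *shared core* if it lies in domains of both cell types;
#' *cell-type-specific* if it lies in a domain with zero overlap with any
#' domain of the other cell type; *expansion* otherwise, i.e. the
#' non-shared bases of a domain that does overlap the other cell type
#' somewhere (including bases bridging internal gaps of the other type's
#' coverage).
#'
#' @param dom_a,dom_b Normalized `interval_set` domain sets on the same
#'   genome.
#' @param labels Character vector of length 2 naming the two cell types.
#' @return Object of class `domain_comparison`: a list with the 2 x 3
#'   base-count matrix `counts` (rows = cell types, columns
#'   `shared_core`, `expansion`, `specific`), `total_domain_bases`,
#'   `genome_size` and `genome_percent` (counts as % of the genome).
#' @examples
#' gn <- declare_genome(c(chr1 = 1000))
#' a <- interval_set("chr1", 100, 300, gn)
#' b <- interval_set("chr1", 200, 400, gn)
#' classify_domain_bases(a, b)  # core 100, expansion 100 bases each
#' @export
classify_domain_bases <- function(dom_a, dom_b, labels = c("A", "B")) {
  check_same_genome(dom_a, dom_b)
  stopifnot(length(labels) == 2L)
  genome <- genome_of(dom_a)
  core <- intersect_sets(dom_a, dom_b)
  count_one <- function(self, other) {
    df <- intervals_df(self)
    hit <- overlaps_any_set(df$chrom, df$start, df$end, other)
    specific <- sum(df$end[!hit] - df$start[!hit])
    shared <- total_bases(core)
    total <- total_bases(self)
    c(shared_core = shared, expansion = total - shared - specific,
      specific = specific)
  }
  counts <- rbind(count_one(dom_a, dom_b), count_one(dom_b, dom_a))
  rownames(counts) <- labels
  gs <- genome_size(genome)
  structure(list(counts = counts,
                 total_domain_bases = rowSums(counts),
                 genome_size = gs,
                 genome_percent = counts / gs * 100,
                 labels = labels),
            class = "domain_comparison")
}

#' @export
print.domain_comparison <- function(x, ...) {
  cat("Domain base classification (", paste(x$labels, collapse = " vs "),
      ")\n", sep = "")
  tab <- cbind(x$counts, total = x$total_domain_bases)
  print(tab)
  cat("Genome size:",
      format(x$genome_size, big.mark = ",", scientific = FALSE), "bp\n")
  cat("Genome percent covered:",
      paste(sprintf("%s %.2f%%", x$labels, rowSums(x$genome_percent)),
            collapse = ", "), "\n")
  invisible(x)
}

#' Summary statistics of a domain set
#'
#' @param dom Normalized `interval_set` domain set.
#' @return List with `count`, `sizes` (bp per domain), `total_bases` and
#'   `genome_percent`.
#' @export
domain_stats <- function(dom) {
  df <- intervals_df(dom)
  sizes <- df$end - df$start
  list(count = nrow(df), sizes = sizes, total_bases = sum(sizes),
       genome_percent = sum(sizes) / genome_size(genome_of(dom)) * 100)
}

#' Chi-squared test on the domain class distribution
#'
#' Pearson chi-squared test (no continuity correction) on the 2 cell types
#' x 3 classes table of base counts from [classify_domain_bases()].
#'
#' @param cmp A `domain_comparison`.
#' @return `htest` object from [stats::chisq.test()], df = 2.
#' @export
class_distribution_test <- function(cmp) {
  stopifnot(inherits(cmp, "domain_comparison"))
  tab <- cmp$counts
  if (any(tab < 0)) stop("negative class counts")
  if (any(rowSums(tab) == 0)) stop("a cell type has zero domain bases")
  exp_counts <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(exp_counts == 0))
    stop("expected count of zero in the class table; test undefined")
  suppressWarnings(stats::chisq.test(tab, correct = FALSE))
}
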