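#' Genomic interval algebra
#'
#' All domain, functional-region and coverage computations in pgcquant run
#' on *interval sets*: per chromosome, sorted lists of disjoint half-open
#' intervals in the BED convention (0-based start, exclusive end), tied to
#' a declared genome (chromosome name -> length). Sets are kept
#' *normalized*: sorted, with overlapping or book-ended intervals merged.
#' The algebra is implemented directly on sorted coordinate vectors, which
#' keeps a full set operation at a few microseconds and makes the
#' large randomized oracle comparisons in the test suite cheap.
#'
#' @name interval-algebra
NULL

#' Declare a genome as named chromosome lengths
#'
#' @param lengths Named numeric vector: chromosome name -> length in bp.
#' @return Named numeric vector (validated).
#' @examples
#' gn <- declare_genome(c(chr1 = 10000, chr2 = 5000))
#' @export
declare_genome <- function(lengths) {
  if (is.null(names(lengths)) || any(!nzchar(names(lengths))))
    stop("genome chromosomes must be named")
  if (anyDuplicated(names(lengths)))
    stop("duplicated chromosome names in genome")
  if (any(!is.finite(lengths)) || any(lengths <= 0))
    stop("chromosome lengths must be positive and finite")
  stats::setNames(as.numeric(lengths), names(lengths))
}

#' Genome accessors
#'
#' `genome_of()` returns the genome (named chromosome lengths) an interval
#' set is declared on; `genome_size()` the total genome length in bp.
#'
#' @param x An `interval_set`.
#' @param genome Named vector of chromosome lengths.
#' @return Named numeric vector / total bp.
#' @export
genome_of <- function(x) {
  stopifnot(inherits(x, "interval_set"))
  x$genome
}

#' @rdname genome_of
#' @export
genome_size <- function(genome) sum(as.numeric(genome))

check_same_genome <- function(a, b) {
  if (!identical(genome_of(a), genome_of(b)))
    stop("interval sets are declared on different genomes")
  invisible(TRUE)
}

empty_chrom <- matrix(numeric(0), ncol = 2)

# merge a (start, end) matrix: sort, fuse overlapping/book-ended rows
merge_rows <- function(m) {
  if (nrow(m) <= 1L) return(m)
  m <- m[order(m[, 1], m[, 2]), , drop = FALSE]
  # a row starts a new run when its start exceeds the running max end
  run_end <- cummax(m[, 2])
  new_run <- c(TRUE, m[-1, 1] > run_end[-nrow(m)])
  grp <- cumsum(new_run)
  cbind(m[new_run, 1],
        as.numeric(tapply(m[, 2], grp, max)))
}

new_interval_set <- function(chroms, genome) {
  structure(list(chroms = chroms, genome = genome), class = "interval_set")
}

#' Build a normalized interval set
#'
#' Accepts raw half-open intervals and returns the normalized set: sorted,
#' merged (overlapping and book-ended intervals fused), with the genome
#' attached. Records with `end <= start`, an unknown chromosome, a
#' negative start or an `end` beyond the chromosome length are rejected
#' with the offending record reported.
#'
#' @param chrom Character vector of chromosome names (length-1 values are
#'   recycled), or a data.frame with columns `chrom`, `start`, `end`.
#' @param start,end Numeric vectors, 0-based half-open.
#' @param genome Named vector of chromosome lengths (see
#'   [declare_genome()]).
#' @return An `interval_set`.
#' @examples
#' gn <- declare_genome(c(chr1 = 1000))
#' interval_set("chr1", c(10, 15), c(20, 30), gn)   # merges to [10, 30)
#' @export
interval_set <- function(chrom, start = NULL, end = NULL, genome) {
  if (is.data.frame(chrom)) {
    df <- chrom
    chrom <- as.character(df$chrom); start <- df$start; end <- df$end
  }
  chrom <- as.character(chrom)
  n <- max(length(chrom), length(start))
  if (length(chrom) == 1L) chrom <- rep(chrom, n)
  if (length(chrom) != n || length(start) != n || length(end) != n)
    stop("chrom, start and end must have equal length")
  genome <- declare_genome(genome)
  start <- as.numeric(start); end <- as.numeric(end)
  if (n > 0L) {
    bad <- which(!(chrom %in% names(genome)))
    if (length(bad))
      stop(sprintf("unknown chromosome in record %d: '%s'",
                   bad[1], chrom[bad[1]]))
    bad <- which(is.na(start) | is.na(end) | end <= start)
    if (length(bad))
      stop(sprintf(
        "invalid interval in record %d: start %s, end %s (need start < end)",
        bad[1], format(start[bad[1]]), format(end[bad[1]])))
    bad <- which(start < 0 | end > genome[chrom])
    if (length(bad))
      stop(sprintf("interval out of chromosome bounds in record %d: %s:%s-%s",
                   bad[1], chrom[bad[1]], format(start[bad[1]]),
                   format(end[bad[1]])))
  }
  chroms <- lapply(names(genome), function(ch) {
    sel <- chrom == ch
    if (!any(sel)) empty_chrom
    else merge_rows(cbind(start[sel], end[sel]))
  })
  new_interval_set(stats::setNames(chroms, names(genome)), genome)
}

#' Normalize an interval set (sort + merge)
#'
#' Idempotent; book-ended intervals are fused because base-level set
#' semantics cannot distinguish adjacency from union.
#'
#' @param x An `interval_set`.
#' @return Normalized `interval_set`.
#' @export
normalize_intervals <- function(x) {
  stopifnot(inherits(x, "interval_set"))
  new_interval_set(lapply(x$chroms, merge_rows), x$genome)
}

#' @export
print.interval_set <- function(x, ...) {
  n <- sum(vapply(x$chroms, nrow, integer(1)))
  cat("interval_set:", n, "interval(s),", format(total_bases(x)), "bp on",
      length(x$genome), "chromosome(s)\n")
  if (n > 0) print(utils::head(intervals_df(x), 5))
  invisible(x)
}

intersect_chr <- function(a, b) {
  if (nrow(a) == 0L || nrow(b) == 0L) return(empty_chrom)
  # expand pairs with potential overlap via findInterval on sorted sets
  out_s <- numeric(0); out_e <- numeric(0)
  i <- 1L; j <- 1L
  na <- nrow(a); nb <- nrow(b)
  while (i <= na && j <= nb) {
    s <- max(a[i, 1], b[j, 1])
    e <- min(a[i, 2], b[j, 2])
    if (s < e) { out_s <- c(out_s, s); out_e <- c(out_e, e) }
    if (a[i, 2] < b[j, 2]) i <- i + 1L else j <- j + 1L
  }
  cbind(out_s, out_e, deparse.level = 0)
}

complement_chr <- function(m, len) {
  bounds <- c(0, t(m), len)
  starts <- bounds[seq(1, length(bounds), by = 2)]
  ends <- bounds[seq(2, length(bounds), by = 2)]
  keep <- ends > starts
  cbind(starts[keep], ends[keep], deparse.level = 0)
}

#' Interval-set operations: intersection, difference, complement, union
#'
#' Set semantics over bases; all results are normalized. Binary operations
#' require both sets to be declared on the same genome.
#'
#' @param a,b `interval_set` objects on the same genome.
#' @param ... For `union_sets()`, further interval sets.
#' @return An `interval_set`.
#' @examples
#' gn <- declare_genome(c(chr1 = 100))
#' a <- interval_set("chr1", 0, 10, gn)
#' b <- interval_set("chr1", 5, 15, gn)
#' intervals_df(intersect_sets(a, b))   # [5, 10)
#' @export
intersect_sets <- function(a, b) {
  check_same_genome(a, b)
  new_interval_set(Map(intersect_chr, a$chroms, b$chroms), a$genome)
}

#' @rdname intersect_sets
#' @export
subtract_sets <- function(a, b) {
  check_same_genome(a, b)
  new_interval_set(
    Map(function(ma, mb, len) intersect_chr(ma, complement_chr(mb, len)),
        a$chroms, b$chroms, as.list(a$genome)),
    a$genome)
}

#' @rdname intersect_sets
#' @export
complement_set <- function(a) {
  stopifnot(inherits(a, "interval_set"))
  new_interval_set(Map(complement_chr, a$chroms, as.list(a$genome)),
                   a$genome)
}

#' @rdname intersect_sets
#' @export
union_sets <- function(a, b, ...) {
  rest <- list(...)
  check_same_genome(a, b)
  for (x in rest) check_same_genome(a, x)
  sets <- c(list(a, b), rest)
  new_interval_set(stats::setNames(lapply(names(a$genome), function(ch) {
    merge_rows(do.call(rbind, lapply(sets, function(s) s$chroms[[ch]])))
  }), names(a$genome)), a$genome)
}

#' The whole genome as one interval set
#' @param genome Named vector of chromosome lengths.
#' @return `interval_set` covering every declared chromosome.
#' @export
whole_genome_set <- function(genome) {
  genome <- declare_genome(genome)
  interval_set(names(genome), rep(0, length(genome)), unname(genome), genome)
}

#' Total bases and coverage fraction
#'
#' `total_bases()` is the number of bases in the set; `coverage_fraction()`
#' is the fraction of `target` bases covered by `by`, i.e.
#' `total_bases(intersect(target, by)) / total_bases(target)`.
#'
#' @param a,target,by `interval_set` objects.
#' @return `total_bases()`: numeric bp; `coverage_fraction()`: value in
#'   \[0, 1\].
#' @examples
#' gn <- declare_genome(c(chr1 = 1000))
#' coverage_fraction(interval_set("chr1", 0, 100, gn),
#'                   interval_set("chr1", 0, 50, gn))  # 0.5
#' @export
total_bases <- function(a) {
  stopifnot(inherits(a, "interval_set"))
  sum(vapply(a$chroms, function(m) sum(m[, 2] - m[, 1]), numeric(1)))
}

#' @rdname total_bases
#' @export
coverage_fraction <- function(target, by) {
  check_same_genome(target, by)
  tb <- total_bases(target)
  if (tb == 0) stop("zero-length region: coverage fraction undefined")
  total_bases(intersect_sets(target, by)) / tb
}

# covered bases of `m` (sorted disjoint) in [0, pos) for a vector of pos
covered_before <- function(pos, m) {
  if (nrow(m) == 0L) return(numeric(length(pos)))
  cum <- cumsum(m[, 2] - m[, 1])
  k <- findInterval(pos, m[, 1])
  out <- numeric(length(pos))
  nz <- k > 0
  kk <- k[nz]
  out[nz] <- cum[kk] - pmax(0, m[kk, 2] - pos[nz])
  out
}

# per-query overlap width with a normalized set, vectorized
overlap_width_set <- function(chrom, start, end, set) {
  out <- numeric(length(start))
  for (ch in unique(chrom)) {
    sel <- chrom == ch
    m <- set$chroms[[ch]]
    if (is.null(m)) stop("unknown chromosome '", ch, "'")
    out[sel] <- covered_before(end[sel], m) - covered_before(start[sel], m)
  }
  out
}

# does each query interval overlap the set by >= 1 bp?
overlaps_any_set <- function(chrom, start, end, set) {
  overlap_width_set(chrom, start, end, set) > 0
}

#' Interval set as a BED-convention data.frame
#'
#' @param x An `interval_set`.
#' @return data.frame with `chrom`, `start`, `end` (0-based half-open),
#'   ordered by declared chromosome then start.
#' @export
intervals_df <- function(x) {
  stopifnot(inherits(x, "interval_set"))
  n <- vapply(x$chroms, nrow, integer(1))
  m <- do.call(rbind, x$chroms)
  if (is.null(m)) m <- empty_chrom
  data.frame(chrom = rep(names(x$chroms), n), start = m[, 1], end = m[, 2],
             stringsAsFactors = FALSE)
}
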