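#' Functional regions, gene coverage and expression
#'
#' The genome is partitioned into functional region classes built from gene
#' annotation (promoters, gene bodies, intergenic space, repeats), and each
#' class' coverage by repressive domains is computed. Per-gene coverage over
#' the promoter-extended locus is related to expression (TPM) to quantify
#' the repressive effect of domain coverage.
#'
#' @name annotation-coverage
NULL

check_gene_table <- function(genes) {
  required <- c("gene_id", "chrom", "strand", "tss", "tts")
  if (!is.data.frame(genes) || !all(required %in% names(genes)))
    stop("gene table must have columns gene_id, chrom, strand, tss, tts")
  bad <- !genes$strand %in% c("+", "-")
  if (any(bad))
    stop("unknown strand for gene(s): ",
         paste(utils::head(genes$gene_id[bad], 5), collapse = ", "))
  if (any(genes$tss == genes$tts))
    stop("gene with tss == tts: ",
         paste(utils::head(genes$gene_id[genes$tss == genes$tts], 5),
               collapse = ", "))
  invisible(genes)
}

clip0 <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Build functional genome region classes from annotation
#'
#' Region definitions: `promoters` are windows of `promoter_width` bp
#' centered on the TSS (strand-independent, clipped to the chromosome);
#' `gene_bodies` span TSS to TTS; `intergenic` is the whole genome minus
#' promoters and gene bodies; `repeats` keeps input repeat elements of
#' length >= `min_repeat_length`; `whole_genome` covers every declared
#' chromosome. Promoters and gene bodies may overlap each other; intergenic
#' is disjoint from both.
#'
#' @param genes data.frame with `gene_id`, `chrom`, `strand` (+/-), `tss`,
#'   `tts` (0-based positions; on the - strand `tss > tts`).
#' @param repeats data.frame of repeat elements with `chrom`, `start`,
#'   `end` (element lengths are filtered before normalization).
#' @param genome Named vector of chromosome lengths.
#' @param promoter_width Width in bp of the TSS-centered promoter window.
#' @param min_repeat_length Minimum repeat element length (bp) retained.
#' @return Named list of `interval_set`s: `whole_genome`, `promoters`,
#'   `gene_bodies`, `intergenic`, `repeats`.
#' @export
build_regions <- function(genes, repeats = NULL, genome,
                          promoter_width = 1000, min_repeat_length = 50) {
  check_gene_table(genes)
  genome <- declare_genome(genome)
  half <- promoter_width / 2
  len <- genome[as.character(genes$chrom)]
  prom <- interval_set(genes$chrom,
                       clip0(genes$tss - half, 0, len),
                       clip0(genes$tss + half, 0, len), genome)
  body <- interval_set(genes$chrom,
                       pmin(genes$tss, genes$tts),
                       pmax(genes$tss, genes$tts), genome)
  regions <- list(
    whole_genome = whole_genome_set(genome),
    promoters = prom,
    gene_bodies = body,
    intergenic = complement_set(union_sets(prom, body)))
  if (!is.null(repeats)) {
    stopifnot(is.data.frame(repeats))
    keep <- (repeats$end - repeats$start) >= min_repeat_length
    regions$repeats <- interval_set(repeats[keep, , drop = FALSE],
                                    genome = genome)
  }
  regions
}

#' Coverage of each functional region class by a domain set
#'
#' @param regions Named list of interval sets from [build_regions()].
#' @param domains Normalized `interval_set` domain set.
#' @return data.frame with `region`, `region_bases`, `covered_bases`,
#'   `coverage_fraction`. Empty region classes are omitted.
#' @export
region_coverage <- function(regions, domains) {
  keep <- vapply(regions, function(r) total_bases(r) > 0, logical(1))
  regions <- regions[keep]
  rows <- lapply(names(regions), function(nm) {
    r <- regions[[nm]]
    cov <- total_bases(intersect_sets(r, domains))
    data.frame(region = nm, region_bases = total_bases(r),
               covered_bases = cov,
               coverage_fraction = cov / total_bases(r),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

coverage_class_levels <- c("0%", "(0,25]", "(25,50]", "(50,75]", "(75,100]")

assign_coverage_class <- function(fraction) {
  pct <- fraction * 100
  cls <- as.character(cut(pct, breaks = c(0, 25, 50, 75, 100),
                          labels = coverage_class_levels[-1],
                          include.lowest = FALSE))
  cls[pct == 0] <- "0%"
  factor(cls, levels = coverage_class_levels)
}

#' Per-gene domain coverage over the promoter-extended locus
#'
#' The locus of each gene runs from `upstream` bp upstream of the TSS
#' (strand-oriented) through the TTS; loci reaching past a chromosome end
#' are clipped with a warning. The covered fraction is the proportion of
#' locus bases inside domains, and each gene falls into one of five
#' coverage classes: 0%, (0,25], (25,50], (50,75], (75,100] percent.
#'
#' @param genes data.frame as in [build_regions()].
#' @param domains Normalized `interval_set` domain set.
#' @param genome Named vector of chromosome lengths.
#' @param upstream Strand-oriented promoter extension upstream of the TSS.
#' @return data.frame with `gene_id`, `chrom`, `locus_start`, `locus_end`
#'   (0-based half-open), `covered_fraction`, `coverage_class`.
#' @export
gene_coverage <- function(genes, domains, genome, upstream = 500) {
  check_gene_table(genes)
  genome <- declare_genome(genome)
  if (!identical(genome, genome_of(domains)))
    stop("domains are declared on a different genome")
  lo <- pmin(genes$tss, genes$tts)
  hi <- pmax(genes$tss, genes$tts)
  plus <- genes$strand == "+"
  start <- ifelse(plus, lo - upstream, lo)
  end <- ifelse(plus, hi, hi + upstream)
  len <- unname(genome[as.character(genes$chrom)])
  if (any(start < 0 | end > len))
    warning("gene locus extends past chromosome end; clipped")
  start <- clip0(start, 0, len)
  end <- clip0(end, 0, len)
  ov <- overlap_width_set(as.character(genes$chrom), start, end, domains)
  frac <- ov / (end - start)
  data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
             locus_start = start, locus_end = end,
             covered_fraction = frac,
             coverage_class = assign_coverage_class(frac),
             stringsAsFactors = FALSE)
}

#' Aggregate transcript TPMs to gene level
#'
#' Per replicate, the gene TPM is the sum of the TPMs of its transcripts;
#' the gene's `mean_tpm` is the arithmetic mean over replicates.
#'
#' @param transcripts data.frame with `transcript_id`, `gene_id` and one or
#'   more numeric replicate columns (any other columns are treated as
#'   replicates).
#' @return data.frame with `gene_id`, the summed replicate columns and
#'   `mean_tpm`.
#' @export
aggregate_gene_tpm <- function(transcripts) {
  if (!all(c("transcript_id", "gene_id") %in% names(transcripts)))
    stop("transcript table must have columns transcript_id, gene_id")
  orphan <- is.na(transcripts$gene_id) | !nzchar(as.character(transcripts$gene_id))
  if (any(orphan))
    stop("transcript(s) without a gene: ",
         paste(utils::head(transcripts$transcript_id[orphan], 5), collapse = ", "))
  rep_cols <- setdiff(names(transcripts), c("transcript_id", "gene_id"))
  if (length(rep_cols) == 0L) stop("no replicate TPM columns found")
  if (!all(vapply(transcripts[rep_cols], is.numeric, logical(1))))
    stop("replicate TPM columns must be numeric")
  if (any(as.matrix(transcripts[rep_cols]) < 0, na.rm = TRUE))
    stop("TPM values must be >= 0")
  agg <- stats::aggregate(transcripts[rep_cols],
                          by = list(gene_id = transcripts$gene_id), FUN = sum)
  agg$mean_tpm <- rowMeans(agg[rep_cols])
  agg[order(agg$gene_id), , drop = FALSE]
}

#' Relate gene domain coverage to expression
#'
#' Genes are grouped by their coverage class. With one cell type, the TPM
#' distributions of the classes are compared pairwise; with two cell types,
#' the two TPM distributions are compared within each class (each cell type
#' classified by its own coverage). All comparisons use the two-sided
#' Wilcoxon-Mann-Whitney rank-sum test; groups with fewer than 2 genes are
#' skipped with a warning.
#'
#' @param cov Gene coverage table from [gene_coverage()].
#' @param expr Expression table from [aggregate_gene_tpm()] (`gene_id`,
#'   `mean_tpm`).
#' @param cov2,expr2 Optional second cell type.
#' @param labels Cell-type labels (used in output when two cell types).
#' @return List with `summary` (per class and cell type: n, median and mean
#'   TPM) and `tests` (data.frame of pairwise comparisons with `p_value`).
#' @export
coverage_expression_analysis <- function(cov, expr, cov2 = NULL, expr2 = NULL,
                                         labels = c("A", "B")) {
  tpm_by_class <- function(cov, expr) {
    m <- merge(cov[c("gene_id", "coverage_class")],
               expr[c("gene_id", "mean_tpm")], by = "gene_id")
    split(m$mean_tpm, m$coverage_class)
  }
  ga <- tpm_by_class(cov, expr)
  summarize <- function(groups, label) {
    data.frame(cell_type = label, coverage_class = names(groups),
               n = vapply(groups, length, integer(1)),
               median_tpm = vapply(groups, function(x)
                 if (length(x)) stats::median(x) else NA_real_, numeric(1)),
               mean_tpm = vapply(groups, function(x)
                 if (length(x)) mean(x) else NA_real_, numeric(1)),
               row.names = NULL, stringsAsFactors = FALSE)
  }
  wtest <- function(x, y) {
    suppressWarnings(stats::wilcox.test(x, y, alternative = "two.sided"))$p.value
  }
  if (is.null(cov2)) {
    summary <- summarize(ga, labels[1])
    cls <- names(ga)
    pairs <- utils::combn(seq_along(cls), 2)
    tests <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(k) {
      i <- pairs[1, k]; j <- pairs[2, k]
      if (length(ga[[i]]) < 2 || length(ga[[j]]) < 2) {
        warning(sprintf("class %s or %s has < 2 genes; test skipped",
                        cls[i], cls[j]))
        return(NULL)
      }
      data.frame(group1 = cls[i], group2 = cls[j],
                 p_value = wtest(ga[[i]], ga[[j]]), stringsAsFactors = FALSE)
    }))
  } else {
    gb <- tpm_by_class(cov2, expr2)
    summary <- rbind(summarize(ga, labels[1]), summarize(gb, labels[2]))
    tests <- do.call(rbind, lapply(coverage_class_levels, function(cl) {
      x <- ga[[cl]]; y <- gb[[cl]]
      if (length(x) < 2 || length(y) < 2) {
        warning(sprintf("class %s has < 2 genes in a cell type; test skipped", cl))
        return(NULL)
      }
      data.frame(coverage_class = cl, group1 = labels[1], group2 = labels[2],
                 p_value = wtest(x, y), stringsAsFactors = FALSE)
    }))
  }
  list(summary = summary, tests = tests)
}

#' Select gene sets by domain coverage and repression
#'
#' Three gene lists: list A, genes highly covered (fraction >=
#' `high_cut`) and repressed (TPM at or below the first quartile of the
#' analysis universe) in cell type A; list B, the same for cell type B;
#' list C, genes highly covered in A but weakly covered in B (fraction at
#' or below `low_cut`; strict `<` when `low_inclusive = FALSE`).
#'
#' The first quartile is the linear-interpolation sample quantile
#' ([stats::quantile()] type 7) of each cell type's mean TPM over the gene
#' universe (genes present in both the coverage and expression tables).
#'
#' @param cov_a,cov_b Gene coverage tables from [gene_coverage()].
#' @param expr_a,expr_b Expression tables from [aggregate_gene_tpm()].
#' @param high_cut High-coverage threshold (inclusive).
#' @param low_cut Low-coverage threshold for list C.
#' @param low_inclusive Include genes at exactly `low_cut` in list C.
#' @return List of character vectors `A`, `B`, `C` of gene ids, plus
#'   `q1_a`, `q1_b`, the first-quartile TPM thresholds.
#' @export
select_gene_sets <- function(cov_a, cov_b, expr_a, expr_b,
                             high_cut = 0.75, low_cut = 0.10,
                             low_inclusive = TRUE) {
  ua <- merge(cov_a[c("gene_id", "covered_fraction")],
              expr_a[c("gene_id", "mean_tpm")], by = "gene_id")
  ub <- merge(cov_b[c("gene_id", "covered_fraction")],
              expr_b[c("gene_id", "mean_tpm")], by = "gene_id")
  if (nrow(ua) == 0L || nrow(ub) == 0L)
    stop("empty gene universe after aligning coverage and expression")
  q1a <- unname(stats::quantile(ua$mean_tpm, 0.25, type = 7))
  q1b <- unname(stats::quantile(ub$mean_tpm, 0.25, type = 7))
  list_a <- ua$gene_id[ua$covered_fraction >= high_cut & ua$mean_tpm <= q1a]
  list_b <- ub$gene_id[ub$covered_fraction >= high_cut & ub$mean_tpm <= q1b]
  uc <- merge(ua[c("gene_id", "covered_fraction")],
              ub[c("gene_id", "covered_fraction")],
              by = "gene_id", suffixes = c("_a", "_b"))
  low_ok <- if (low_inclusive) uc$covered_fraction_b <= low_cut
            else uc$covered_fraction_b < low_cut
  list_c <- uc$gene_id[uc$covered_fraction_a >= high_cut & low_ok]
  list(A = sort(list_a), B = sort(list_b), C = sort(list_c),
       q1_a = q1a, q1_b = q1b)
}
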