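#' Synthetic toy genome with two cell types' domain sets
#'
#' Builds a small genome carrying genes, repeat elements and, for two cell
#' types ("A" and "B"), broad repressive domains constructed as shared
#' cores, optional per-cell-type expansions of those cores, and
#' cell-type-specific domains. The domains are re-emitted as SICER-style
#' islands plus MACS2-style broad peaks such that the final-domain rule
#' reconstructs the truth sets exactly, and gene expression is generated so
#' that domain-covered genes are repressed.
#'
#' @name sim-genome
NULL

#' Specification for a synthetic genome
#'
#' @param chrom_lengths Named vector of chromosome lengths (bp).
#' @param n_genes Gene count; gene bodies do not overlap.
#' @param gene_length_range Gene body length range (bp).
#' @param prop_boundary_genes Proportion of genes deliberately placed so
#'   that their locus straddles a domain edge, populating the partial
#'   coverage classes (the remainder are placed uniformly).
#' @param n_repeats Repeat element count.
#' @param repeat_length_range Repeat element length range (bp); ranges
#'   dipping below 50 bp exercise the size filter of [build_regions()].
#' @param n_shared_domains Number of shared domain cores.
#' @param domain_length_range Core length range (bp).
#' @param expansion_prob Per cell type and per core side, the probability
#'   of an expansion.
#' @param expansion_length_range Expansion length range (bp).
#' @param n_specific_per_cell Cell-type-specific domains per cell type.
#' @param n_decoy_islands Low-confidence islands per cell type placed
#'   outside any domain and unsupported by peaks (must be rejected by the
#'   final-domain rule).
#' @param repression_strength Dimensionless link between domain coverage
#'   and expression: log TPM is shifted by `-repression_strength *
#'   covered_fraction`.
#' @param tpm_lognormal_params `c(mu, sigma)` of the gene-baseline log-TPM
#'   (natural log).
#' @param n_replicates Expression replicates per cell type.
#' @param replicate_cv Lognormal replicate noise SD (natural log).
#' @param seed Integer seed; identical seeds give identical output.
#' @return Object of class `genome_sim_spec`.
#' @export
genome_sim_spec <- function(chrom_lengths = c(chr1 = 6e5, chr2 = 4e5),
                            n_genes = 200, gene_length_range = c(400, 1200),
                            prop_boundary_genes = 0.5,
                            n_repeats = 100, repeat_length_range = c(30, 300),
                            n_shared_domains = 40,
                            domain_length_range = c(1000, 5000),
                            expansion_prob = 0.5,
                            expansion_length_range = c(200, 1000),
                            n_specific_per_cell = 10, n_decoy_islands = 10,
                            repression_strength = 2,
                            tpm_lognormal_params = c(mu = 1.5, sigma = 0.5),
                            n_replicates = 3, replicate_cv = 0.1, seed = 1) {
  chrom_lengths <- declare_genome(chrom_lengths)
  ranges <- list(gene_length_range, repeat_length_range, domain_length_range,
                 expansion_length_range)
  for (r in ranges)
    if (length(r) != 2L || any(r <= 0) || r[1] > r[2])
      stop("length ranges must be positive (lo, hi) pairs")
  if (n_genes < 1 || n_repeats < 0 || n_shared_domains < 0 ||
      n_specific_per_cell < 0 || n_decoy_islands < 0)
    stop("feature counts must be non-negative (and n_genes >= 1)")
  if (expansion_prob < 0 || expansion_prob > 1)
    stop("expansion_prob must be a probability")
  if (prop_boundary_genes < 0 || prop_boundary_genes > 1)
    stop("prop_boundary_genes must be a probability")
  if (n_replicates < 1) stop("need at least one replicate")
  structure(list(chrom_lengths = chrom_lengths, n_genes = n_genes,
                 gene_length_range = gene_length_range,
                 prop_boundary_genes = prop_boundary_genes,
                 n_repeats = n_repeats,
                 repeat_length_range = repeat_length_range,
                 n_shared_domains = n_shared_domains,
                 domain_length_range = domain_length_range,
                 expansion_prob = expansion_prob,
                 expansion_length_range = expansion_length_range,
                 n_specific_per_cell = n_specific_per_cell,
                 n_decoy_islands = n_decoy_islands,
                 repression_strength = repression_strength,
                 tpm_lognormal_params = tpm_lognormal_params,
                 n_replicates = n_replicates, replicate_cv = replicate_cv,
                 seed = as.integer(seed)),
            class = "genome_sim_spec")
}

# Rejection-sample n intervals that keep `margin` bp clear of previously
# placed intervals (and of chromosome ends). Errors when the genome is too
# short for the request.
place_intervals <- function(n, len_range, genome, occupied = NULL,
                            margin = 0, max_tries = 1000) {
  chroms <- names(genome)
  if (is.null(occupied))
    occupied <- stats::setNames(rep(list(matrix(numeric(0), ncol = 2)),
                                    length(chroms)), chroms)
  out <- NULL
  for (i in seq_len(n)) {
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      chrom <- sample(chroms, 1, prob = genome)
      len <- round(stats::runif(1, len_range[1], len_range[2]))
      if (genome[chrom] < len + 2 * margin) next
      start <- floor(stats::runif(1, margin, genome[chrom] - len - margin))
      occ <- occupied[[chrom]]
      if (nrow(occ) == 0L ||
          all(occ[, 2] + margin <= start | occ[, 1] >= start + len + margin)) {
        occupied[[chrom]] <- rbind(occ, c(start, start + len))
        out <- rbind(out, data.frame(chrom = chrom, start = start,
                                     end = start + len,
                                     stringsAsFactors = FALSE))
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stop("infeasible genome spec: could not place feature ", i,
           " (chromosomes too short for requested features)")
  }
  list(intervals = out, occupied = occupied)
}

split_into_islands <- function(chrom, start, end, min_piece = 50) {
  len <- end - start
  n_pieces <- if (len >= 3 * min_piece) sample(1:3, 1) else 1L
  if (n_pieces == 1L)
    return(data.frame(chrom = chrom, start = start, end = end,
                      stringsAsFactors = FALSE))
  cuts <- sort(sample(seq(start + min_piece, end - min_piece, by = 1),
                      n_pieces - 1))
  # guard against pieces shorter than min_piece after sampling
  bounds <- c(start, cuts, end)
  if (any(diff(bounds) < min_piece))
    return(data.frame(chrom = chrom, start = start, end = end,
                      stringsAsFactors = FALSE))
  data.frame(chrom = chrom, start = bounds[-length(bounds)],
             end = bounds[-1], stringsAsFactors = FALSE)
}

#' Simulate a toy genome with domains, genes, repeats and expression
#'
#' See [genome_sim_spec()] for the knobs. Construction guarantees:
#' \itemize{
#'   \item A- and B-domains share cores; expansions and specific domains
#'     are separated by margins so no two features touch or merge.
#'   \item Islands tile each truth domain exactly (book-ended pieces).
#'     Pieces get FDR `1e-12` (kept by FDR) or FDR `1e-2` plus a
#'     supporting peak strictly inside the piece (rescued by peak
#'     overlap); decoy islands get FDR `1e-2` and no peak, so
#'     [combine_islands_peaks()] reconstructs the truth set exactly.
#'   \item Per cell type, gene log-TPM is a shared gene baseline minus
#'     `repression_strength * covered_fraction` of that cell type;
#'     transcript TPMs split the gene TPM and replicates add lognormal
#'     noise.
#' }
#'
#' @param spec A [genome_sim_spec()].
#' @return List with `genome`, `genes` (annotation data.frame),
#'   `repeats` (data.frame), per cell type `domains` (`GRanges` truth
#'   sets), `islands` and `peaks` (data.frames per cell type),
#'   `transcripts` (transcript TPM data.frames per cell type), and
#'   `truth` (per-gene programmed coverage and expected TPM per cell
#'   type, plus domain stats).
#' @export
simulate_genome <- function(spec) {
  stopifnot(inherits(spec, "genome_sim_spec"))
  run_seeded(spec$seed, function() {
    genome <- spec$chrom_lengths
    margin <- 2 * spec$expansion_length_range[2] + 100
    # shared cores + specific domains in non-colliding slots
    n_slots <- spec$n_shared_domains + 2 * spec$n_specific_per_cell
    pl <- place_intervals(n_slots, spec$domain_length_range, genome,
                          margin = margin)
    slots <- pl$intervals
    role <- rep(c("core", "specificA", "specificB"),
                c(spec$n_shared_domains, spec$n_specific_per_cell,
                  spec$n_specific_per_cell))
    expand_side <- function(side_len) round(stats::runif(
      1, spec$expansion_length_range[1], spec$expansion_length_range[2]))
    build_cell <- function(cell) {
      rows <- NULL
      for (i in seq_len(nrow(slots))) {
        if (role[i] == "core") {
          s <- slots$start[i]; e <- slots$end[i]
          if (stats::runif(1) < spec$expansion_prob) s <- s - expand_side()
          if (stats::runif(1) < spec$expansion_prob) e <- e + expand_side()
          rows <- rbind(rows, data.frame(chrom = slots$chrom[i], start = s,
                                         end = e, stringsAsFactors = FALSE))
        } else if ((role[i] == "specificA" && cell == "A") ||
                   (role[i] == "specificB" && cell == "B")) {
          rows <- rbind(rows, slots[i, c("chrom", "start", "end")])
        }
      }
      rows
    }
    dom_a_df <- build_cell("A")
    dom_b_df <- build_cell("B")
    dom_a <- interval_set(dom_a_df, genome = genome)
    dom_b <- interval_set(dom_b_df, genome = genome)

    # islands + peaks reconstructing the truth exactly
    make_islands <- function(dom_df, occupied) {
      islands <- NULL; peaks <- NULL
      for (i in seq_len(nrow(dom_df))) {
        pieces <- split_into_islands(dom_df$chrom[i], dom_df$start[i],
                                     dom_df$end[i])
        for (j in seq_len(nrow(pieces))) {
          if (stats::runif(1) < 0.5) {
            fdr <- 1e-12
          } else {
            fdr <- 1e-2
            ps <- pieces$start[j] + 1
            pe <- pieces$end[j] - 1
            peaks <- rbind(peaks, data.frame(chrom = pieces$chrom[j],
                                             start = ps, end = pe,
                                             stringsAsFactors = FALSE))
          }
          islands <- rbind(islands, cbind(pieces[j, , drop = FALSE],
                                          fdr = fdr))
        }
      }
      decoys <- place_intervals(spec$n_decoy_islands, c(200, 800), genome,
                                occupied = occupied, margin = 10)$intervals
      if (!is.null(decoys) && nrow(decoys))
        islands <- rbind(islands, cbind(decoys, fdr = 1e-2))
      list(islands = islands[order(islands$chrom, islands$start), ],
           peaks = peaks)
    }
    # decoys must stay clear of *both* cell types' domains
    occ_all <- stats::setNames(lapply(names(genome), function(ch) {
      rbind(as.matrix(dom_a_df[dom_a_df$chrom == ch, c("start", "end")]),
            as.matrix(dom_b_df[dom_b_df$chrom == ch, c("start", "end")]))
    }), names(genome))
    isl_a <- make_islands(dom_a_df, occ_all)
    isl_b <- make_islands(dom_b_df, occ_all)

    # repeats: unconstrained placement (may overlap anything)
    repeats <- data.frame(chrom = character(), start = numeric(),
                          end = numeric(), stringsAsFactors = FALSE)
    if (spec$n_repeats > 0) {
      chrom <- sample(names(genome), spec$n_repeats, replace = TRUE,
                      prob = genome)
      len <- round(stats::runif(spec$n_repeats, spec$repeat_length_range[1],
                                spec$repeat_length_range[2]))
      start <- floor(stats::runif(spec$n_repeats) * (genome[chrom] - len))
      repeats <- data.frame(chrom = chrom, start = start, end = start + len,
                            stringsAsFactors = FALSE)
      repeats <- repeats[order(repeats$chrom, repeats$start), ]
      rownames(repeats) <- NULL
    }

    # genes: a proportion straddle a domain edge so all coverage classes
    # are populated; gene bodies never overlap
    upstream <- 500
    edges <- rbind(
      data.frame(chrom = dom_a_df$chrom, pos = dom_a_df$start),
      data.frame(chrom = dom_a_df$chrom, pos = dom_a_df$end),
      data.frame(chrom = dom_b_df$chrom, pos = dom_b_df$start),
      data.frame(chrom = dom_b_df$chrom, pos = dom_b_df$end))
    occ_genes <- NULL
    genes <- NULL
    n_boundary <- round(spec$prop_boundary_genes * spec$n_genes)
    gene_margin <- 10
    body_ok <- function(chrom, s, e) {
      s >= upstream + 1 && e <= genome[chrom] - upstream - 1 &&
        (is.null(occ_genes) ||
           !any(occ_genes$chrom == chrom & occ_genes$start < e + gene_margin &
                  occ_genes$end > s - gene_margin))
    }
    add_gene <- function(i, chrom, s, e) {
      strand <- sample(c("+", "-"), 1)
      occ_genes <<- rbind(occ_genes, data.frame(chrom = chrom, start = s,
                                                end = e))
      genes <<- rbind(genes, data.frame(
        gene_id = sprintf("gene%04d", i), chrom = chrom, strand = strand,
        tss = if (strand == "+") s else e,
        tts = if (strand == "+") e else s, stringsAsFactors = FALSE))
    }
    for (i in seq_len(spec$n_genes)) {
      placed <- FALSE
      for (try in seq_len(1000)) {
        len <- round(stats::runif(1, spec$gene_length_range[1],
                                  spec$gene_length_range[2]))
        if (i <= n_boundary && nrow(edges) > 0 && try <= 300) {
          # boundary placement is best-effort: when the edge neighbourhoods
          # saturate, fall back to uniform placement after 300 tries
          # drop the gene body near a domain edge so the promoter-extended
          # locus straddles it with a uniform offset
          k <- sample(nrow(edges), 1)
          chrom_i <- edges$chrom[k]
          locus_len <- len + upstream
          off <- stats::runif(1, 1, locus_len - 1)
          s <- round(edges$pos[k] - off) + upstream
          e <- s + len
        } else {
          chrom_i <- sample(names(genome), 1, prob = genome)
          if (genome[chrom_i] < len + 2 * (upstream + 1)) next
          s <- floor(stats::runif(1, upstream + 1,
                                  genome[chrom_i] - len - upstream - 1))
          e <- s + len
        }
        if (body_ok(chrom_i, s, e)) {
          add_gene(i, chrom_i, s, e)
          placed <- TRUE
          break
        }
      }
      if (!placed)
        stop("infeasible genome spec: could not place gene ", i)
    }
    genes <- genes[order(genes$chrom, pmin(genes$tss, genes$tts)), ]
    rownames(genes) <- NULL

    # programmed coverage and expression
    cov_a <- gene_coverage(genes, dom_a, genome, upstream = upstream)
    cov_b <- gene_coverage(genes, dom_b, genome, upstream = upstream)
    mu <- spec$tpm_lognormal_params[[1]]
    sigma <- spec$tpm_lognormal_params[[2]]
    base_log <- stats::rnorm(nrow(genes), mu, sigma)
    expected_tpm <- list(
      A = exp(base_log - spec$repression_strength * cov_a$covered_fraction),
      B = exp(base_log - spec$repression_strength * cov_b$covered_fraction))
    make_transcripts <- function(gene_tpm) {
      rows <- NULL
      for (g in seq_len(nrow(genes))) {
        n_tx <- sample(1:3, 1)
        w <- stats::runif(n_tx)
        w <- w / sum(w)
        reps <- vapply(seq_len(spec$n_replicates), function(r)
          gene_tpm[g] * exp(stats::rnorm(1, 0, spec$replicate_cv)),
          numeric(1))
        tx <- outer(w, reps)   # transcripts x replicates
        df <- data.frame(
          transcript_id = sprintf("%s.t%d", genes$gene_id[g], seq_len(n_tx)),
          gene_id = genes$gene_id[g], stringsAsFactors = FALSE)
        colnames(tx) <- sprintf("tpm_rep%d", seq_len(spec$n_replicates))
        rows <- rbind(rows, cbind(df, as.data.frame(tx)))
      }
      rows
    }
    transcripts <- list(A = make_transcripts(expected_tpm$A),
                        B = make_transcripts(expected_tpm$B))

    truth <- list(
      genes = data.frame(gene_id = genes$gene_id,
                         covered_fraction_A = cov_a$covered_fraction,
                         covered_fraction_B = cov_b$covered_fraction,
                         expected_tpm_A = expected_tpm$A,
                         expected_tpm_B = expected_tpm$B,
                         stringsAsFactors = FALSE),
      domain_stats = list(A = domain_stats(dom_a)[c("count", "total_bases",
                                                    "genome_percent")],
                          B = domain_stats(dom_b)[c("count", "total_bases",
                                                    "genome_percent")]))
    list(genome = genome, genes = genes, repeats = repeats,
         domains = list(A = dom_a, B = dom_b),
         islands = list(A = isl_a$islands, B = isl_b$islands),
         peaks = list(A = isl_a$peaks, B = isl_b$peaks),
         transcripts = transcripts, truth = truth, spec = spec)
  })
}

#' Write a simulated genome to disk
#'
#' Emits, under `dir`: `genome.tsv` (chrom, length), per cell type
#' `domains_<ct>.bed`, `islands_<ct>.tsv` (SICER-style, FDR in the last
#' column), `peaks_<ct>.broadPeak`, `tpm_<ct>.tsv` (transcript TPM),
#' plus `genes.tsv`, `repeats.bed` and `truth.json`.
#'
#' @param sim Result of [simulate_genome()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_genome_sim <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(genome = file.path(dir, "genome.tsv"),
             genes = file.path(dir, "genes.tsv"),
             repeats = file.path(dir, "repeats.bed"),
             truth = file.path(dir, "truth.json"))
  write_genome_file(sim$genome, paths[["genome"]])
  write_table_tsv(sim$genes, paths[["genes"]])
  write_bed(interval_set(sim$repeats, genome = sim$genome), paths[["repeats"]])
  for (ct in c("A", "B")) {
    p <- file.path(dir, sprintf(c("domains_%s.bed", "islands_%s.tsv",
                                  "peaks_%s.broadPeak", "tpm_%s.tsv"), ct))
    names(p) <- paste0(c("domains_", "islands_", "peaks_", "tpm_"), ct)
    write_bed(sim$domains[[ct]], p[[1]])
    write_sicer_islands(sim$islands[[ct]], p[[2]])
    write_broadpeak(sim$peaks[[ct]], p[[3]])
    write_table_tsv(sim$transcripts[[ct]], p[[4]])
    paths <- c(paths, p)
  }
  truth <- sim$truth
  truth$spec <- unclass(sim$spec)
  jsonlite::write_json(truth, paths[["truth"]], digits = NA,
                       auto_unbox = TRUE, dataframe = "columns")
  invisible(paths)
}

#' Simulate reads with a planted satellite motif
#'
#' Generates random-sequence reads; a fraction carries one exact copy of
#' the satellite motif at a random position. Useful for testing
#' tagged-read-fraction summaries against an exact string-match oracle.
#'
#' @param n_reads Number of reads.
#' @param tagged_fraction Fraction of reads carrying the motif.
#' @param motif Satellite motif string (alphabet ACGT).
#' @param read_length Read length (>= motif length).
#' @param seed Integer seed.
#' @return List with `reads` (character vector) and `tagged` (logical
#'   ground truth).
#' @export
simulate_satellite_reads <- function(n_reads, tagged_fraction,
                                     motif = "ACGTACGTTAGGCC",
                                     read_length = 75, seed = 1) {
  stopifnot(n_reads > 0, tagged_fraction >= 0, tagged_fraction <= 1,
            read_length >= nchar(motif))
  run_seeded(seed, function() {
    n_tag <- round(tagged_fraction * n_reads)
    tagged <- sample(c(rep(TRUE, n_tag), rep(FALSE, n_reads - n_tag)))
    reads <- vapply(seq_len(n_reads), function(i) {
      r <- paste(sample(c("A", "C", "G", "T"), read_length, replace = TRUE),
                 collapse = "")
      if (tagged[i]) {
        pos <- sample(read_length - nchar(motif) + 1, 1)
        substr(r, pos, pos + nchar(motif) - 1) <- motif
      }
      r
    }, character(1))
    list(reads = reads, tagged = tagged)
  })
}
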