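gn10 <- declare_genome(c(chr1 = 10000))

one_gene <- data.frame(gene_id = "g1", chrom = "chr1", strand = "+",
                       tss = 1000, tts = 2000, stringsAsFactors = FALSE)

test_that("region classes follow the promoter/body/intergenic definitions", {
  reg <- build_regions(one_gene, genome = gn10)
  expect_same_intervals(reg$promoters,
                        data.frame(chrom = "chr1", start = 500, end = 1500))
  expect_same_intervals(reg$gene_bodies,
                        data.frame(chrom = "chr1", start = 1000, end = 2000))
  expect_equal(total_bases(reg$intergenic), 10000 - 1500)
  # promoter clipped at the chromosome start
  g2 <- transform(one_gene, tss = 100, tts = 900)
  expect_same_intervals(build_regions(g2, genome = gn10)$promoters,
                        data.frame(chrom = "chr1", start = 0, end = 600))
  expect_error(build_regions(transform(one_gene, strand = "*"),
                             genome = gn10), "strand")
})

test_that("repeats below the size threshold are dropped from the class", {
  reps <- data.frame(chrom = "chr1", start = c(0, 100),
                     end = c(49, 150))   # 49 bp and 50 bp
  reg <- build_regions(one_gene, repeats = reps, genome = gn10)
  expect_same_intervals(reg$repeats,
                        data.frame(chrom = "chr1", start = 100, end = 150))
})

test_that("promoters, bodies and intergenic partition the genome", {
  set.seed(41)
  genes <- data.frame(gene_id = sprintf("g%d", 1:8), chrom = "chr1",
                      strand = sample(c("+", "-"), 8, replace = TRUE),
                      tss = NA, tts = NA, stringsAsFactors = FALSE)
  starts <- sort(sample(seq(600, 9000, by = 100), 8))
  ends <- starts + sample(200:400, 8)
  genes$tss <- ifelse(genes$strand == "+", starts, ends)
  genes$tts <- ifelse(genes$strand == "+", ends, starts)
  reg <- build_regions(genes, genome = gn10)
  covered <- union_sets(reg$promoters, reg$gene_bodies, reg$intergenic)
  expect_equal(total_bases(covered), 10000)
  expect_equal(total_bases(intersect_sets(reg$intergenic, reg$promoters)), 0)
  expect_equal(total_bases(intersect_sets(reg$intergenic, reg$gene_bodies)), 0)
})

test_that("region_coverage reports per-class fractions and skips empty classes", {
  dom <- interval_set("chr1", 500, 1500, gn10)
  reg <- build_regions(one_gene, genome = gn10)
  rc <- region_coverage(reg, dom)
  expect_equal(rc$coverage_fraction[rc$region == "promoters"], 1)
  expect_equal(rc$coverage_fraction[rc$region == "gene_bodies"], 0.5)
  expect_equal(rc$coverage_fraction[rc$region == "whole_genome"], 0.1)
  expect_false("repeats" %in% rc$region)
})

test_that("gene locus coverage uses the strand-oriented 500 bp extension", {
  # + strand: locus [500, 2000); - strand gene with same span: [1000, 2500)
  dom <- interval_set("chr1", 0, 1000, gn10)
  cov_plus <- gene_coverage(one_gene, dom, gn10)
  expect_equal(cov_plus$locus_start, 500)
  expect_equal(cov_plus$locus_end, 2000)
  expect_equal(cov_plus$covered_fraction, 500 / 1500)
  g_minus <- transform(one_gene, strand = "-", tss = 2000, tts = 1000)
  cov_minus <- gene_coverage(g_minus, dom, gn10)
  expect_equal(cov_minus$locus_start, 1000)
  expect_equal(cov_minus$locus_end, 2500)
  expect_equal(cov_minus$covered_fraction, 0)
})

test_that("coverage classes split at 0, 25, 50, 75 percent", {
  expect_equal(as.character(pgcquant:::assign_coverage_class(
    c(0, 0.1, 0.25, 0.4, 0.5, 0.75, 0.76, 1))),
    c("0%", "(0,25]", "(0,25]", "(25,50]", "(25,50]", "(50,75]",
      "(75,100]", "(75,100]"))
  dom_all <- interval_set("chr1", 0, 10000, gn10)
  expect_equal(as.character(gene_coverage(one_gene, dom_all,
                                          gn10)$coverage_class), "(75,100]")
  # 2,500 bp locus with 1,000 bp overlap -> 0.4 -> (25,50]
  g <- transform(one_gene, tss = 1000, tts = 3000)
  dom <- interval_set("chr1", 500, 1500, gn10)
  cov <- gene_coverage(g, dom, gn10)
  expect_equal(cov$covered_fraction, 0.4)
  expect_equal(as.character(cov$coverage_class), "(25,50]")
})

test_that("gene coverage is invariant under coordinate translation", {
  set.seed(43)
  gn_small <- declare_genome(c(chr1 = 20000))
  starts <- seq(1000, 9000, by = 2000)
  genes <- data.frame(gene_id = sprintf("g%d", 1:5), chrom = "chr1",
                      strand = c("+", "-", "+", "-", "+"),
                      tss = starts, tts = starts + 800,
                      stringsAsFactors = FALSE)
  genes$tss[genes$strand == "-"] <- genes$tts[genes$strand == "-"]
  genes$tts[genes$strand == "-"] <- starts[genes$strand == "-"]
  dom_df <- data.frame(chrom = "chr1", start = c(800, 5000),
                       end = c(2000, 7000))
  shift <- 4321
  cov0 <- gene_coverage(genes, interval_set(dom_df, genome = gn_small),
                        gn_small)
  genes2 <- transform(genes, tss = tss + shift, tts = tts + shift)
  dom2 <- transform(dom_df, start = start + shift, end = end + shift)
  cov1 <- gene_coverage(genes2, interval_set(dom2, genome = gn_small),
                        gn_small)
  expect_equal(cov1$covered_fraction, cov0$covered_fraction)
})

test_that("transcript TPMs aggregate to gene sums and replicate means", {
  tx <- data.frame(transcript_id = c("t1", "t2", "t3"),
                   gene_id = c("g1", "g1", "g2"),
                   tpm_rep1 = c(3, 2, 1), tpm_rep2 = c(4, 2, 7))
  expr <- aggregate_gene_tpm(tx)
  expect_equal(expr$tpm_rep1, c(5, 1))
  expect_equal(expr$mean_tpm, c((5 + 6) / 2, (1 + 7) / 2))
  expect_error(aggregate_gene_tpm(transform(tx, gene_id = c("g1", NA, "g2"))),
               "t2")
})

test_that("TPM aggregation conserves mass and matches a group-sum oracle", {
  set.seed(47)
  n_tx <- 200
  tx <- data.frame(transcript_id = sprintf("t%d", 1:n_tx),
                   gene_id = sprintf("g%d", sample(1:60, n_tx, replace = TRUE)),
                   r1 = rexp(n_tx) * 10, r2 = rexp(n_tx) * 10,
                   r3 = rexp(n_tx) * 10)
  expr <- aggregate_gene_tpm(tx)
  for (col in c("r1", "r2", "r3"))
    expect_equal(sum(expr[[col]]), sum(tx[[col]]))
  oracle <- vapply(expr$gene_id, function(g)
    sum(tx$r2[tx$gene_id == g]), numeric(1))
  expect_equal(expr$r2, unname(oracle))
})

# exact two-sided Wilcoxon-Mann-Whitney p by enumeration of assignments
wmw_exact_oracle <- function(x, y) {
  pooled <- c(x, y)
  n <- length(x)
  idx <- utils::combn(length(pooled), n)
  u_of <- function(xi) {
    xs <- pooled[xi]; ys <- pooled[-xi]
    sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
  }
  u_all <- apply(idx, 2, u_of)
  u_obs <- u_of(seq_len(n))
  min(1, 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs)))
}

test_that("rank tests match the exact enumeration oracle", {
  expect_equal(suppressWarnings(
    stats::wilcox.test(c(1, 2, 3), c(10, 20, 30))$p.value), 0.1)
  set.seed(53)
  for (case in 1:8) {
    x <- round(runif(sample(3:6, 1), 0, 100), 3)
    y <- round(runif(sample(3:6, 1), 0, 100), 3)
    expect_equal(stats::wilcox.test(x, y, exact = TRUE)$p.value,
                 wmw_exact_oracle(x, y))
  }
})

test_that("coverage-expression analysis groups by class and tests ranks", {
  set.seed(59)
  n <- 40
  cov <- data.frame(gene_id = sprintf("g%02d", 1:n),
                    coverage_class = pgcquant:::assign_coverage_class(
                      runif(n)), stringsAsFactors = FALSE)
  expr <- data.frame(gene_id = cov$gene_id, mean_tpm = rexp(n, 0.2))
  res <- suppressWarnings(coverage_expression_analysis(cov, expr))
  expect_equal(res$summary$n, as.integer(table(cov$coverage_class)))
  expect_true(all(res$tests$p_value >= 0 & res$tests$p_value <= 1))
  # identical TPM distributions between two cell types: p near 1
  res2 <- suppressWarnings(coverage_expression_analysis(cov, expr, cov, expr))
  expect_true(all(res2$tests$p_value > 0.99))
  suppressWarnings(
    expect_warning(coverage_expression_analysis(cov, expr), "skipped"))
})

test_that("gene set selection honors thresholds, quartile and boundaries", {
  n <- 100
  set.seed(61)
  frac_a <- c(0.75, 0.5, runif(n - 2))
  frac_b <- c(0.10, 0.10, runif(n - 2))
  ids <- sprintf("g%03d", 1:n)
  cov_a <- data.frame(gene_id = ids, covered_fraction = frac_a)
  cov_b <- data.frame(gene_id = ids, covered_fraction = frac_b)
  tpm_a <- rexp(n, 0.1); tpm_b <- rexp(n, 0.1)
  expr_a <- data.frame(gene_id = ids, mean_tpm = tpm_a)
  expr_b <- data.frame(gene_id = ids, mean_tpm = tpm_b)
  sets <- select_gene_sets(cov_a, cov_b, expr_a, expr_b)
  q1a <- unname(quantile(tpm_a, 0.25))
  # brute-force filter oracle
  expect_setequal(sets$A, ids[frac_a >= 0.75 & tpm_a <= q1a])
  expect_setequal(sets$B,
                  ids[frac_b >= 0.75 & tpm_b <= unname(quantile(tpm_b, 0.25))])
  expect_setequal(sets$C, ids[frac_a >= 0.75 & frac_b <= 0.10])
  # boundary gene: fraction exactly 0.75 in A, 0.10 in B -> in C (inclusive)
  expect_true("g001" %in% sets$C)
  strict <- select_gene_sets(cov_a, cov_b, expr_a, expr_b,
                             low_inclusive = FALSE)
  expect_false("g001" %in% strict$C)
  expect_error(select_gene_sets(cov_a[0, ], cov_b, expr_a, expr_b),
               "empty gene universe")
})
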