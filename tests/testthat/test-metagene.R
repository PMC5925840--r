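# a toy annotation with one long gene per strand for profile tests
metagene_gms <- function(body = 3000L, strand = "+") {
  toy_gms(list(gA = list(strand = strand,
                         txs = list(list(c(5001, 5000 + body))))))
}

uniform_reads <- function(from, to, by = 10L, width = 50L, chrom = "chr1") {
  starts <- seq(from, to, by = by)
  as_alignment_set(blocks_to_grl(lapply(starts, function(s)
    rbind(c(s, s + width - 1))), chrom = chrom))
}

test_that("bin means conserve total signal and tile fractional edges", {
  set.seed(31)
  for (rep in 1:5) {
    v <- rpois(sample(c(301, 500, 977, 3000), 1), 4)
    n <- sample(c(100L, 300L), 1)
    bm <- retentionshift:::bin_means(v, n)
    expect_equal(sum(bm) * length(v) / n, sum(v), tolerance = 1e-9)
  }
  # exact division: plain block means
  v <- rep(c(1, 3), each = 150)
  expect_equal(retentionshift:::bin_means(v, 300), v[seq(1, 300, 1)])
})

test_that("profiles have the 100/300/100 layout and exclude short genes", {
  gms <- toy_gms(list(
    gA = list(strand = "+", txs = list(list(c(5001, 8000)))),
    gShort = list(strand = "+", txs = list(list(c(20001, 20400))))))
  chip <- uniform_reads(2001, 11000)
  prof <- bin_coverage(chip, NULL, gms, calibration = "none")
  expect_equal(dim(prof), c(1L, 500L))
  expect_equal(rownames(prof), "gA")
  expect_match(attr(prof, "excluded")[["gShort"]], "500")
})

test_that("pre-normalization bin sums equal per-base coverage totals", {
  gms <- metagene_gms(body = 977L)   # awkward length: fractional bins
  set.seed(32)
  starts <- sample(4500:6200, 300, replace = TRUE)
  chip <- as_alignment_set(blocks_to_grl(lapply(starts, function(s)
    rbind(c(s, s + 49)))))
  prof <- bin_coverage(chip, NULL, gms, calibration = "none", scale_to = 1)
  sc <- 1 / chip$library_size
  cov <- GenomicRanges::coverage(unlist(chip$reads))$chr1
  body_total <- sum(as.numeric(S4Vectors::window(cov, 5001, 5977)))
  expect_equal(sum(prof[1, 101:400]) * 977 / 300 / sc, body_total,
               tolerance = 1e-9)
  flank_total <- sum(as.numeric(S4Vectors::window(cov, 3001, 5000)))
  expect_equal(sum(prof[1, 1:100]) * 20 / sc, flank_total, tolerance = 1e-9)
})

test_that("minus-strand profiles mirror their plus-strand twins", {
  body <- 3000L
  gp <- metagene_gms(body, "+"); gm <- metagene_gms(body, "-")
  # genomically 3'-weighted coverage: denser towards high coordinates
  set.seed(33)
  starts <- 5000 + floor(body * sqrt(runif(800)))
  chip <- as_alignment_set(blocks_to_grl(lapply(starts, function(s)
    rbind(c(s, s + 49)))))
  pp <- bin_coverage(chip, NULL, gp, calibration = "none")
  pm <- bin_coverage(chip, NULL, gm, calibration = "none")
  expect_equal(pm[1, ], rev(pp[1, ]), tolerance = 1e-12)
  # the minus-strand gene sees the dense end as its TSS half
  body_bins <- pm[1, 101:400]
  expect_gt(mean(body_bins[1:150]), mean(body_bins[151:300]))
})

test_that("perfect calibration yields all-zero profiles", {
  gms <- metagene_gms()
  chip <- uniform_reads(2001, 11000)
  prof <- bin_coverage(chip, chip, gms)
  expect_equal(max(abs(prof)), 0)
  # ChIP at 2x input with equal library sizes: flat positive profile
  chip2 <- uniform_reads(2001, 11000, by = 5L)
  chip2$library_size <- chip$library_size   # same normalization scale
  prof2 <- bin_coverage(chip2, chip, gms)
  expect_true(all(prof2[1, 5:495] > 0))
  expect_lt(stats::sd(prof2[1, 101:400]) / mean(prof2[1, 101:400]), 0.2)
  expect_error(bin_coverage(chip, NULL, gms), "input")
})

test_that("aggregate_profile averages element-wise", {
  m <- rbind(a = rep(1, 500), b = rep(-1, 500))
  agg <- aggregate_profile(m)
  expect_equal(as.numeric(agg), rep(0, 500))
  expect_equal(attr(agg, "n_genes"), 2L)
  one <- aggregate_profile(m[1, , drop = FALSE])
  expect_equal(as.numeric(one), rep(1, 500))
  set.seed(34)
  r <- matrix(rnorm(5 * 500), 5)
  expect_equal(as.numeric(aggregate_profile(r)), unname(colMeans(r)))
})

test_that("diff_matrix sorts by red-bin count with deterministic ties", {
  mk <- function(vals) {
    m <- matrix(vals, length(vals), 500,
                dimnames = list(paste0("g", seq_along(vals)), NULL))
    attr(m, "layout") <- c(n_flank = 100L, n_body = 300L)
    m
  }
  mut <- mk(c(0, 1, 0.5)); wt <- mk(c(0, 0, 0))
  d <- diff_matrix(mut, wt)
  expect_equal(rownames(d), c("g2", "g3", "g1"))
  expect_equal(unname(attr(d, "sort_key")), c(300, 300, 0))
  # identical conditions: zero matrix, all keys 0
  d0 <- diff_matrix(mut, mut)
  expect_true(all(d0 == 0))
  expect_true(all(attr(d0, "sort_key") == 0))
  expect_equal(rownames(d0), c("g1", "g2", "g3"))   # tie-break by gene id
  expect_error(diff_matrix(mut[1:2, ], wt), "g3")
  # random matrices: ordering matches an independent counting oracle
  set.seed(35)
  a <- mk(rep(0, 8)); a[] <- rnorm(8 * 500)
  b <- mk(rep(0, 8)); b[] <- rnorm(8 * 500)
  d2 <- diff_matrix(a, b)
  key <- vapply(rownames(d2), function(g)
    sum((a[g, 101:400] - b[g, 101:400]) > 0), numeric(1))
  expect_equal(unname(attr(d2, "sort_key")), unname(key))
  expect_true(all(diff(key) <= 0))
})

test_that("shift caller is exact at the 45-bin boundary", {
  mkrow <- function(n_front_pos, n_rear_neg) {
    r <- rep(0, 500)
    if (n_front_pos > 0) r[100 + seq_len(n_front_pos)] <- 1
    if (n_rear_neg > 0) r[250 + seq_len(n_rear_neg)] <- -1
    r
  }
  expect_true(unname(call_shift(mkrow(150, 150))))
  expect_false(unname(call_shift(rep(0, 500))))
  expect_true(unname(call_shift(mkrow(45, 45))))
  expect_false(unname(call_shift(mkrow(44, 45))))
  expect_false(unname(call_shift(mkrow(45, 44))))
  # flanks are ignored entirely
  r <- mkrow(45, 45); r[1:100] <- -5; r[401:500] <- 5
  expect_true(unname(call_shift(r)))
})

test_that("shift types follow the two-mark contingency", {
  me2 <- c(g1 = TRUE, g2 = FALSE, g3 = TRUE, g4 = FALSE)
  me3 <- c(g1 = FALSE, g2 = TRUE, g3 = TRUE, g4 = FALSE)
  tt <- classify_shift_types(me2, me3)
  expect_equal(setNames(tt$type, tt$gene_id),
               c(g1 = "I", g2 = "II", g3 = "III", g4 = "IV"))
  expect_error(classify_shift_types(me2, me3[1:3]), "gene sets")
})

test_that("signal_at_introns detects a planted 2x group difference", {
  set.seed(36)
  n <- 300
  up <- gr("chr1", seq(1000, by = 400, length.out = n),
           seq(1000, by = 400, length.out = n) + 99)
  down <- GenomicRanges::shift(up, 200)
  mkreads <- function(regions, per_feat) {
    starts <- unlist(lapply(seq_along(regions), function(i)
      GenomicRanges::start(regions)[i] +
        sample(0:50, per_feat[i], replace = TRUE)))
    as_alignment_set(blocks_to_grl(lapply(starts, function(s)
      rbind(c(s, s + 49)))))
  }
  chip <- mkreads(c(up, down), c(rpois(n, 40), rpois(n, 20)))
  res <- signal_at_introns(chip, NULL, list(up = up, down = down))
  expect_gt(res$medians["up"], res$medians["down"])
  expect_lt(res$tests$p_value, 0.01)
  # identical coverage over both groups: p near 1
  res0 <- signal_at_introns(chip, NULL, list(a = up, b = up))
  expect_gt(res0$tests$p_value, 0.9)
  expect_error(signal_at_introns(chip, NULL,
                                 list(a = up, b = up[0])), "non-empty")
})

test_that("signal/expression association behaves at the extremes", {
  set.seed(37)
  f <- setNames(rlnorm(1000, 2, 1), paste0("g", 1:1000))
  # signal identically equal to expression: rho 1
  res1 <- signal_expression_association(f, f)
  expect_equal(res1$spearman_rho, 1)
  expect_true(all(diff(res1$quantile_summary$mean_signal) > 0))
  # independent signal: |rho| small
  s <- setNames(rlnorm(1000, 0, 1), names(f))
  expect_lt(abs(signal_expression_association(s, f)$spearman_rho), 0.1)
  # constant signal: rho defined as 0
  expect_equal(signal_expression_association(
    setNames(rep(1, 1000), names(f)), f)$spearman_rho, 0)
  expect_error(signal_expression_association(s[1:3], f[1:3],
                                             n_quantiles = 5), "quantiles")
})
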