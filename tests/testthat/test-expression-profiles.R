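counts2 <- matrix(c(10, 30, 20, 60), nrow = 2,
                  dimnames = list(c("m1", "m2"), c("a", "b")))

test_that("median-of-ratios size factors match hand computation and equivariance", {
  # two identical samples
  m <- cbind(a = c(5L, 9L, 13L), b = c(5L, 9L, 13L))
  expect_equal(unname(median_of_ratios_size_factors(m)), c(1, 1))

  # geometric means (14.1421, 42.4264): both ratios are sqrt(1/2), sqrt(2)
  sf <- median_of_ratios_size_factors(counts2)
  expect_equal(unname(sf), c(1 / sqrt(2), sqrt(2)), tolerance = 1e-5)

  # scaling one column by c scales its factor by c relative to the others
  # (factors are defined up to the common geometric-mean reference, which
  # the rescaling also moves)
  m2 <- counts2
  m2[, "b"] <- m2[, "b"] * 3L
  sf2 <- median_of_ratios_size_factors(m2)
  expect_equal(sf2[["b"]] / sf2[["a"]], 3 * sf[["b"]] / sf[["a"]])

  norm <- normalize_counts(counts2)
  expect_equal(norm[, "a"], norm[, "b"])

  # all features hit a zero somewhere: reference undefined
  bad <- cbind(a = c(0L, 5L), b = c(3L, 0L))
  expect_error(median_of_ratios_size_factors(bad), "positive counts")
})

test_that("columns that are exact scalar multiples yield those scalars as factors", {
  base <- c(12L, 7L, 30L, 2L)
  scal <- c(1, 2, 4)
  m <- sapply(scal, function(s) as.integer(base * s))
  colnames(m) <- paste0("s", scal)
  sf <- median_of_ratios_size_factors(m)
  # the scalars normalized to geometric mean one
  expect_equal(unname(sf), scal / prod(scal)^(1 / 3))
})

test_that("size factors agree with the reference median-of-ratios implementation", {
  set.seed(77)
  m <- matrix(rpois(60, lambda = rep(c(20, 200, 2000), each = 20)), nrow = 20)
  colnames(m) <- c("s1", "s2", "s3")
  ours <- median_of_ratios_size_factors(m)
  ref <- DESeq2::estimateSizeFactorsForMatrix(m)
  expect_equal(unname(ours), unname(ref), tolerance = 1e-12)
})

test_that("log2 quartile ranking transforms and buckets as documented", {
  expect_equal(log2_quartile_rank(0)$log2, 0)
  expect_equal(log2_quartile_rank(1023)$log2, 10)
  r <- log2_quartile_rank(c(1, 2, 4, 8, 16, 32, 64, 128))
  expect_equal(as.vector(table(r$quartile)), rep(2L, 4))
  expect_true(is.ordered(r$quartile))
  # boundary values fall to the lower quartile
  rq <- log2_quartile_rank(rep(3, 5))
  expect_true(all(rq$quartile == "Q1"))
  expect_error(log2_quartile_rank(numeric(0)), "empty")
})

test_that("RPM and RPKM normalize to the documented scales", {
  m <- matrix(c(5L, 15L), 2, 1, dimnames = list(c("x", "y"), "s"))
  expect_equal(unname(rpm_normalize(m)[, 1]), c(250000, 750000))

  cfg <- matrix(as.integer(c(0, 7, 3, 90, 10, 0)), nrow = 3,
                dimnames = list(NULL, c("a", "b")))
  rpm <- rpm_normalize(cfg)
  expect_equal(unname(colSums(rpm)), c(1e6, 1e6))
  expect_equal(unname(rpm[1, "a"]), 0)

  # duplicating every count leaves RPM unchanged
  expect_equal(rpm_normalize(cfg * 2L), rpm)

  rpkm <- rpkm_normalize(cfg, lengths = c(500, 1000, 2000))
  expect_equal(rpkm[2, ], rpm[2, ])
  expect_equal(rpkm[1, ], rpm[1, ] * 2)

  zero <- matrix(c(1L, 0L), 1, 2, dimnames = list(NULL, c("a", "b")))
  expect_error(rpm_normalize(zero), "library size")
  expect_error(rpkm_normalize(cfg, c(0, 1, 1)), "positive")
})

test_that("compartment ratios divide pseudocount-stabilized RPM means", {
  m <- matrix(as.integer(c(10, 90, 10, 90, 50, 50)), nrow = 2,
              dimnames = list(c("miR-a", "miR-b"),
                              c("cyt1", "cyt2", "nuc1")))
  sheet <- data.frame(sample_id = c("cyt1", "cyt2", "nuc1"),
                      compartment = c("cytoplasm", "cytoplasm", "nucleus"))
  ratio <- compartment_ratio(m, sheet)
  expect_equal(unname(ratio["miR-a"]), (1e5 + 1) / (5e5 + 1))
  # equal RPM in both compartments gives 1
  m2 <- matrix(as.integer(c(10, 90, 10, 90)), nrow = 2,
               dimnames = list(c("miR-a", "miR-b"), c("c", "n")))
  sheet2 <- data.frame(sample_id = c("c", "n"),
                       compartment = c("cytoplasm", "nucleus"))
  expect_equal(unname(compartment_ratio(m2, sheet2)), c(1, 1))
  # swapping numerator and denominator inverts the ratio
  inv <- compartment_ratio(m, sheet, num = "nucleus", den = "cytoplasm")
  expect_equal(unname(inv * ratio), rep(1, 2))
  # extreme case with the stated pseudocount: RPM 1e6 vs 0 -> (1e6+1)/1
  m3 <- matrix(as.integer(c(10, 0, 0, 10)), nrow = 2,
               dimnames = list(c("only-c", "only-n"), c("c", "n")))
  expect_equal(unname(compartment_ratio(m3, sheet2)["only-c"]), 1e6 + 1)
  expect_error(compartment_ratio(m, sheet, den = "nucleolus"), "nucleolus")
})

test_that("Kruskal-Wallis/Dunn reproduces the hand-derived fixture", {
  x <- c(1, 2, 3, 4, 5, 6, 7, 8, 9)
  g <- rep(c("low", "mid", "high"), each = 3)
  kd <- kruskal_dunn(x, g)
  expect_equal(kd$H, 7.2)
  expect_equal(kd$df, 2)
  expect_equal(kd$p_value, pchisq(7.2, 2, lower.tail = FALSE))
  pw <- kd$pairwise
  extreme <- pw[(pw$group_a == "high" & pw$group_b == "low") |
                  (pw$group_a == "low" & pw$group_b == "high"), ]
  expect_equal(abs(extreme$z), 6 / sqrt(5))
  expect_equal(nrow(pw), 3)
  # Bonferroni triples the pairwise p (capped at 1)
  none <- kruskal_dunn(x, g, p_adjust = "none")
  expect_equal(kd$pairwise$p_adj, pmin(none$pairwise$p * 3, 1))
})

test_that("degenerate and invalid group structures are handled", {
  same <- kruskal_dunn(rep(4, 12), rep(c("a", "b", "c"), 4))
  expect_equal(same$H, 0)
  expect_equal(same$p_value, 1)
  expect_equal(same$pairwise$z, rep(0, 3))
  expect_error(kruskal_dunn(1:5, rep("a", 5)), "2 groups")
  expect_error(kruskal_dunn(1:5, c("a", "a", "b", "b", NA)), "missing")
})

test_that("H and p agree with the reference rank test on random tied fixtures", {
  set.seed(123)
  for (i in 1:50) {
    k <- sample(2:4, 1)
    sizes <- sample(3:8, k, replace = TRUE)
    x <- sample(1:6, sum(sizes), replace = TRUE)  # heavy ties
    g <- rep(letters[1:k], sizes)
    kd <- kruskal_dunn(x, g)
    ref <- suppressWarnings(kruskal.test(x, factor(g)))
    expect_equal(kd$H, unname(ref$statistic), tolerance = 1e-9)
    expect_equal(kd$p_value, ref$p.value, tolerance = 1e-6)
  }
})

test_that("only the extreme groups separate under a two-SD location shift", {
  set.seed(99)
  ext <- 0
  adj <- c(0, 0)
  for (s in 1:200) {
    x <- c(rnorm(10, 0), rnorm(10, 1), rnorm(10, 2))
    g <- rep(c("low", "mid", "high"), each = 10)
    pw <- kruskal_dunn(x, g)$pairwise
    key <- paste(pw$group_a, pw$group_b)
    is_ext <- key %in% c("high low", "low high")
    ext <- ext + (pw$p_adj[is_ext] < 0.05)
    adj <- adj + (pw$p_adj[!is_ext] < 0.05)
  }
  expect_gt(ext / 200, 0.8)
  expect_true(all(adj / 200 < 0.2))
})

test_that("count-matrix TSV reader returns counts and optional lengths", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("mirna\ts1\ts2\tlength",
               "miR-1\t10\t20\t22",
               "miR-2\t5\t0\t21"), path)
  cm <- read_count_matrix(path)
  expect_equal(dim(cm$counts), c(2L, 2L))
  expect_equal(cm$counts["miR-1", "s2"], 20)
  expect_equal(cm$lengths, c(22, 21))

  writeLines(c("mirna\ts1", "miR-1\t3"), path)
  expect_null(read_count_matrix(path)$lengths)
  writeLines(c("id\ts1", "miR-1\t3"), path)
  expect_error(read_count_matrix(path), "mirna")
})
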