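check_count_matrix <- function(m) {
  if (!is.matrix(m) || !is.numeric(m)) {
    stop("expected a numeric miRNA x sample count matrix")
  }
  if (any(!is.finite(m)) || any(m < 0) || any(m != round(m))) {
    stop("counts must be non-negative integers")
  }
  if (is.null(colnames(m)) || anyDuplicated(colnames(m))) {
    stop("samples must carry unique column names")
  }
  invisible(m)
}

#' Median-of-ratios size factors
#'
#' Per-sample scaling constants computed with the median-of-ratios formula:
#' for every feature with an all-positive row the geometric mean across
#' samples is taken, and the size factor of sample j is the median over
#' those features of count/geometric-mean. Features containing any zero are
#' excluded from the reference, the standard convention for this estimator.
#'
#' @param m miRNA x sample count matrix with unique column names.
#' @return Named vector of positive size factors, one per sample.
#' @export
#' @examples
#' m <- matrix(c(10, 30, 20, 60), 2, dimnames = list(NULL, c("a", "b")))
#' median_of_ratios_size_factors(m)  # ~ (0.70711, 1.41421)
median_of_ratios_size_factors <- function(m) {
  check_count_matrix(m)
  logm <- log(m)
  ref <- rowMeans(logm)            # log geometric mean; -Inf if any zero
  use <- is.finite(ref)
  if (!any(use)) {
    stop("no feature has positive counts in every sample; ",
         "size factors are undefined")
  }
  sf <- apply(logm[use, , drop = FALSE], 2, function(col) {
    exp(stats::median(col - ref[use]))
  })
  sf
}

#' Normalize counts by median-of-ratios size factors
#' @param m count matrix.
#' @param size_factors optional precomputed factors.
#' @return Matrix of normalized counts (counts divided per-sample factors).
#' @export
normalize_counts <- function(m, size_factors = median_of_ratios_size_factors(m)) {
  sweep(m, 2, size_factors, "/")
}

#' Log2 transform and quartile-rank expression values
#'
#' \code{y = log2(x + pseudocount)} with features labeled Q1 (lowest) to Q4
#' (highest) by the empirical quartiles of \code{y} (linear interpolation;
#' values on a boundary go to the lower quartile).
#'
#' @param x non-negative per-feature expression values (e.g. mean normalized
#'   counts).
#' @param pseudocount added before the log; default 1 read.
#' @return Data frame with columns \code{value, log2, quartile}.
#' @export
log2_quartile_rank <- function(x, pseudocount = 1) {
  if (length(x) == 0) stop("empty input")
  check_nonneg(x, "expression values")
  y <- log2(x + pseudocount)
  q <- stats::quantile(y, c(0.25, 0.5, 0.75), names = FALSE)
  idx <- 1L + (y > q[1]) + (y > q[2]) + (y > q[3])
  data.frame(value = x, log2 = y,
             quartile = factor(paste0("Q", idx),
                               levels = paste0("Q", 1:4), ordered = TRUE))
}

#' Reads-per-million normalization
#' @param m count matrix.
#' @return Matrix of RPM values; each column sums to 1e6.
#' @export
rpm_normalize <- function(m) {
  check_count_matrix(m)
  totals <- colSums(m)
  if (any(totals == 0)) {
    stop("zero library size in sample(s): ",
         paste(colnames(m)[totals == 0], collapse = ", "))
  }
  sweep(m, 2, totals, "/") * 1e6
}

#' Reads-per-kilobase-per-million normalization
#' @param m count matrix.
#' @param lengths positive feature lengths in bases, recycled along rows.
#' @return Matrix of RPKM values.
#' @export
rpkm_normalize <- function(m, lengths) {
  if (any(!is.finite(lengths)) || any(lengths <= 0)) {
    stop("feature lengths must be positive")
  }
  rpm_normalize(m) / (rep_len(lengths, nrow(m)) / 1000)
}

#' Cytoplasm/nuclear (compartment) RPM ratio per miRNA
#'
#' Computes per-feature RPM in two subcellular compartments (averaging RPM
#' across the samples labeled with each compartment) and returns the
#' pseudocount-stabilized ratio; high values indicate predominantly
#' cytoplasmic miRNAs, where repression takes place.
#'
#' @param m count matrix whose columns are compartment libraries.
#' @param sample_sheet data frame with columns \code{sample_id} and
#'   \code{compartment} mapping columns of \code{m} to compartments.
#' @param num,den compartment labels for numerator and denominator; defaults
#'   \code{"cytoplasm"} over \code{"nucleus"}.
#' @param pseudocount RPM added to both terms; default 1.
#' @return Named vector of per-feature ratios.
#' @export
compartment_ratio <- function(m, sample_sheet, num = "cytoplasm",
                              den = "nucleus", pseudocount = 1) {
  stopifnot(is.data.frame(sample_sheet),
            all(c("sample_id", "compartment") %in% names(sample_sheet)))
  rpm <- rpm_normalize(m)
  pick <- function(label) {
    ids <- sample_sheet$sample_id[sample_sheet$compartment == label]
    ids <- intersect(ids, colnames(m))
    if (length(ids) == 0) stop("no samples labeled with compartment '", label, "'")
    rowMeans(rpm[, ids, drop = FALSE])
  }
  (pick(num) + pseudocount) / (pick(den) + pseudocount)
}

#' Kruskal-Wallis test with Dunn's pairwise comparisons
#'
#' Nonparametric one-way comparison across k groups: the tie-corrected
#' Kruskal-Wallis H statistic with a chi-square (k-1 df) p-value, followed
#' by Dunn's z statistics for every group pair,
#' \deqn{z = (\bar R_a - \bar R_b) / \sqrt{\left(\frac{N(N+1)}{12} -
#'   \frac{\sum (t^3 - t)}{12(N-1)}\right)\left(\frac{1}{n_a} +
#'   \frac{1}{n_b}\right)}}
#' with family-wise Bonferroni adjustment over all pairs by default (the
#' behavior of common multiple-comparison software; \code{"none"} is also
#' available).
#'
#' @param x numeric values.
#' @param g group labels (coerced to factor), same length as \code{x}.
#' @param p_adjust \code{"bonferroni"} (default) or \code{"none"}.
#' @return A list of class \code{uta_kw}: \code{H}, \code{df},
#'   \code{p_value}, group summary, and a data frame \code{pairwise} with
#'   columns \code{group_a, group_b, z, p, p_adj}.
#' @export
#' @examples
#' kruskal_dunn(c(1:3, 4:6, 7:9), rep(c("a", "b", "c"), each = 3))
kruskal_dunn <- function(x, g, p_adjust = c("bonferroni", "none")) {
  p_adjust <- match.arg(p_adjust)
  g <- factor(g)
  if (length(x) != length(g)) stop("x and g must have equal length")
  if (anyNA(x) || anyNA(g)) stop("missing values are not supported")
  k <- nlevels(g)
  if (k < 2) stop("need at least 2 groups")
  n_g <- table(g)
  if (any(n_g == 0)) stop("every group must be non-empty")

  N <- length(x)
  rk <- rank(x)
  ties <- table(x)
  tie_sum <- sum(ties^3 - ties)

  rank_sums <- tapply(rk, g, sum)
  H_raw <- 12 / (N * (N + 1)) * sum(rank_sums^2 / n_g) - 3 * (N + 1)
  C <- 1 - tie_sum / (N^3 - N)
  if (C <= 0) {
    H <- 0; p <- 1  # all observations identical
  } else {
    H <- H_raw / C
    p <- stats::pchisq(H, df = k - 1, lower.tail = FALSE)
  }

  rbar <- rank_sums / n_g
  pairs <- utils::combn(levels(g), 2)
  var_term <- N * (N + 1) / 12 - tie_sum / (12 * (N - 1))
  z <- apply(pairs, 2, function(ab) {
    se <- sqrt(var_term * (1 / n_g[[ab[1]]] + 1 / n_g[[ab[2]]]))
    if (se == 0) 0 else (rbar[[ab[1]]] - rbar[[ab[2]]]) / se
  })
  p_pair <- 2 * stats::pnorm(-abs(z))
  p_adj <- if (p_adjust == "bonferroni") pmin(p_pair * ncol(pairs), 1) else p_pair

  structure(list(H = unname(H), df = k - 1, p_value = unname(p),
                 groups = data.frame(group = levels(g),
                                     n = as.integer(n_g),
                                     mean_rank = as.numeric(rbar)),
                 pairwise = data.frame(group_a = pairs[1, ],
                                       group_b = pairs[2, ],
                                       z = as.numeric(z),
                                       p = as.numeric(p_pair),
                                       p_adj = as.numeric(p_adj)),
                 p_adjust = p_adjust),
            class = "uta_kw")
}

#' @export
print.uta_kw <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis: H = %.4g, df = %d, p = %.4g\n",
              x$H, x$df, x$p_value))
  cat(sprintf("Dunn pairwise comparisons (%s adjustment):\n", x$p_adjust))
  print(x$pairwise, row.names = FALSE)
  invisible(x)
}

#' Read a miRNA x sample count matrix from TSV
#'
#' First column \code{mirna}, remaining columns one per sample; an optional
#' \code{length} column supplies feature lengths for RPKM.
#'
#' @param path TSV file path.
#' @return A list with \code{counts} (integer matrix with miRNA rownames)
#'   and \code{lengths} (or NULL).
#' @export
read_count_matrix <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(d)[1] != "mirna") stop("first column must be named 'mirna'")
  lengths <- NULL
  if ("length" %in% names(d)) {
    lengths <- d$length
    d$length <- NULL
  }
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d$mirna
  storage.mode(m) <- "numeric"
  check_count_matrix(m)
  list(counts = m, lengths = lengths)
}
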