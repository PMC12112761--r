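#' Probability of a given co-occurrence count
#'
#' Under the probabilistic co-occurrence model, taxon A occupies a fixed set
#' of \code{incidence_a} samples and taxon B an independent uniform random
#' subset of \code{incidence_b} samples out of \code{n_sites}. The number of
#' shared samples then follows the hypergeometric distribution
#' \deqn{P(j) = \frac{\binom{N_1}{j}\binom{N-N_1}{N_2-j}}{\binom{N}{N_2}}.}
#' Probabilities are accumulated on the log scale (\code{lchoose}) so the
#' computation is stable for site counts in the hundreds.
#'
#' @param j integer vector of co-occurrence counts; values outside the
#'   feasible support return 0.
#' @param n_sites total number of samples N.
#' @param incidence_a,incidence_b the two taxa's incidences N1, N2.
#' @return numeric vector of probabilities, symmetric in
#'   \code{(incidence_a, incidence_b)}.
#' @export
overlap_pmf <- function(j, n_sites, incidence_a, incidence_b) {
  check_margins(n_sites, incidence_a, incidence_b)
  if (any(j != floor(j))) stop("overlap j must be integer-valued")
  lo <- max(0L, incidence_a + incidence_b - n_sites)
  hi <- min(incidence_a, incidence_b)
  p <- numeric(length(j))
  ok <- j >= lo & j <= hi
  p[ok] <- exp(lchoose(incidence_a, j[ok]) +
               lchoose(n_sites - incidence_a, incidence_b - j[ok]) -
               lchoose(n_sites, incidence_b))
  p
}

check_margins <- function(n_sites, incidence_a, incidence_b) {
  if (n_sites < 1) stop("n_sites must be >= 1")
  if (incidence_a < 0 || incidence_b < 0) stop("incidences must be non-negative")
  if (incidence_a > n_sites || incidence_b > n_sites) {
    stop("incidence exceeds number of samples")
  }
  invisible(TRUE)
}

#' Expected co-occurrence under independent placement
#'
#' The mean of the overlap distribution, N1 N2 / N. Pairs whose expected
#' co-occurrence falls below 1 are conventionally excluded from testing.
#'
#' @inheritParams overlap_pmf
#' @return expected number of shared samples (real-valued).
#' @export
expected_overlap <- function(n_sites, incidence_a, incidence_b) {
  check_margins(n_sites, incidence_a, incidence_b)
  incidence_a * incidence_b / n_sites
}

#' Exact two-tailed co-occurrence test for one taxon pair
#'
#' Computes the inclusive tail probabilities of the hypergeometric overlap
#' distribution at the observed co-occurrence count:
#' \code{p_lt} is the probability of an overlap less than or equal to the
#' observed count, \code{p_gt} of an overlap greater than or equal to it.
#' Both tails include the observed value, so
#' \code{p_lt + p_gt = 1 + P(j_obs)} exactly.
#'
#' @inheritParams overlap_pmf
#' @param observed_overlap number of samples containing both taxa; must lie
#'   in the feasible support.
#' @return a list with elements \code{n_sites}, \code{incidence_a},
#'   \code{incidence_b}, \code{observed_overlap}, \code{expected_overlap},
#'   \code{p_lt}, \code{p_gt}.
#' @examples
#' pair_test(38, 8, 11, 8)  # complete overlap of the rarer taxon
#' @export
pair_test <- function(n_sites, incidence_a, incidence_b, observed_overlap) {
  check_margins(n_sites, incidence_a, incidence_b)
  lo <- max(0L, incidence_a + incidence_b - n_sites)
  hi <- min(incidence_a, incidence_b)
  if (observed_overlap < lo || observed_overlap > hi) {
    stop(sprintf("observed overlap %s outside feasible support [%d, %d]",
                 observed_overlap, lo, hi))
  }
  support <- lo:hi
  pmf <- overlap_pmf(support, n_sites, incidence_a, incidence_b)
  list(n_sites = n_sites,
       incidence_a = incidence_a,
       incidence_b = incidence_b,
       observed_overlap = observed_overlap,
       expected_overlap = expected_overlap(n_sites, incidence_a, incidence_b),
       p_lt = min(1, sum(pmf[support <= observed_overlap])),
       p_gt = min(1, sum(pmf[support >= observed_overlap])))
}

#' Classify a taxon pair from its tail probabilities
#'
#' A pair co-occurs negatively if the lower tail is below \code{alpha},
#' positively if the upper tail is, and randomly otherwise. For
#' \code{alpha <= 0.5} the two cannot both trigger, because the inclusive
#' tails always sum to at least 1.
#'
#' @param p_lt,p_gt inclusive lower/upper tail probabilities (vectors).
#' @param alpha significance level in (0, 1).
#' @return character vector: \code{"negative"}, \code{"positive"} or
#'   \code{"random"}.
#' @export
classify_pair <- function(p_lt, p_gt, alpha = 0.05) {
  if (length(alpha) != 1 || is.na(alpha) || alpha <= 0 || alpha >= 1) {
    stop("alpha must be a single value in (0, 1)")
  }
  if (any(p_lt < 0 | p_lt > 1 | p_gt < 0 | p_gt > 1, na.rm = TRUE)) {
    stop("tail probabilities must lie in [0, 1]")
  }
  ifelse(p_lt < alpha, "negative", ifelse(p_gt < alpha, "positive", "random"))
}

#' Pairwise probabilistic co-occurrence analysis
#'
#' Runs the exact hypergeometric co-occurrence test on every unordered pair
#' of taxa in an incidence matrix. Pairs whose expected co-occurrence
#' (N1 N2 / N) is below \code{min_expected} are marked \code{excluded} and
#' carry no classification; the remaining (analyzed) pairs are classified
#' positive, negative or random at level \code{alpha}. No multiple-testing
#' correction is applied: the raw tail probabilities are reported.
#'
#' @param x an \code{\link{incidence_matrix}} (or coercible matrix) with at
#'   least two taxa.
#' @param alpha significance level for classification (default 0.05).
#' @param min_expected exclusion threshold on expected co-occurrence
#'   (default 1; exclusion is strict, i.e. expected < threshold).
#' @return an object of class \code{cooccurrence} with components
#'   \describe{
#'     \item{pairs}{data frame, one row per unordered taxon pair, with
#'       columns \code{taxon_a}, \code{taxon_b}, \code{n_sites},
#'       \code{incidence_a}, \code{incidence_b}, \code{observed_overlap},
#'       \code{expected_overlap}, \code{p_lt}, \code{p_gt}, \code{status},
#'       \code{classification}.}
#'     \item{counts}{named vector: positive / negative / random / excluded
#'       pair counts and the total.}
#'     \item{alpha, min_expected, n_sites}{the settings used.}
#'   }
#' @examples
#' fx <- study_fixture(seed = 1)
#' fit <- cooccurrence_analysis(fx$matrix)
#' fit
#' @export
cooccurrence_analysis <- function(x, alpha = 0.05, min_expected = 1) {
  x <- incidence_matrix(x)
  if (ncol(x) < 2L) stop("pairwise analysis needs at least 2 taxa")
  counts <- incidence_counts(x)
  zero <- names(counts)[counts == 0L]
  if (length(zero)) {
    warning("taxa with zero incidence excluded from testing: ",
            paste(zero, collapse = ", "))
  }
  n <- nrow(x)
  overlap <- crossprod(unclass(x))          # shared-sample counts
  idx <- utils::combn(ncol(x), 2L)
  a <- idx[1L, ]
  b <- idx[2L, ]
  jobs <- overlap[cbind(a, b)]
  exp_ov <- counts[a] * counts[b] / n
  p_lt <- numeric(length(a))
  p_gt <- numeric(length(a))
  analyzed <- exp_ov >= min_expected
  for (k in which(analyzed)) {
    tt <- pair_test(n, counts[a[k]], counts[b[k]], jobs[k])
    p_lt[k] <- tt$p_lt
    p_gt[k] <- tt$p_gt
  }
  status <- ifelse(analyzed, "analyzed", "excluded")
  classification <- rep("none", length(a))
  classification[analyzed] <-
    classify_pair(p_lt[analyzed], p_gt[analyzed], alpha)
  pairs <- data.frame(
    taxon_a = colnames(x)[a],
    taxon_b = colnames(x)[b],
    n_sites = n,
    incidence_a = as.integer(counts[a]),
    incidence_b = as.integer(counts[b]),
    observed_overlap = as.integer(jobs),
    expected_overlap = as.numeric(exp_ov),
    p_lt = ifelse(analyzed, p_lt, NA_real_),
    p_gt = ifelse(analyzed, p_gt, NA_real_),
    status = status,
    classification = classification,
    row.names = NULL, stringsAsFactors = FALSE)
  tallies <- c(positive = sum(classification == "positive"),
               negative = sum(classification == "negative"),
               random   = sum(classification == "random"),
               excluded = sum(!analyzed),
               total    = length(a))
  structure(list(pairs = pairs, counts = tallies, alpha = alpha,
                 min_expected = min_expected, n_sites = n),
            class = "cooccurrence")
}

#' @export
print.cooccurrence <- function(x, ...) {
  cat("Probabilistic co-occurrence analysis\n")
  cat(sprintf("  %d samples, %d taxon pairs (alpha = %g, expected >= %g)\n",
              x$n_sites, x$counts[["total"]], x$alpha, x$min_expected))
  cat(sprintf("  analyzed: %d   excluded: %d\n",
              x$counts[["total"]] - x$counts[["excluded"]],
              x$counts[["excluded"]]))
  cat(sprintf("  positive: %d   negative: %d   random: %d\n",
              x$counts[["positive"]], x$counts[["negative"]],
              x$counts[["random"]]))
  invisible(x)
}

#' @export
summary.cooccurrence <- function(object, ...) {
  sig <- object$pairs[object$pairs$classification %in%
                        c("positive", "negative"), , drop = FALSE]
  out <- list(counts = object$counts, alpha = object$alpha,
              min_expected = object$min_expected,
              significant_pairs = sig[order(sig$p_gt), ])
  class(out) <- "summary.cooccurrence"
  out
}

#' @export
print.summary.cooccurrence <- function(x, ...) {
  cat(sprintf("Pairs: %d total, %d excluded, %d positive, %d negative, %d random\n",
              x$counts[["total"]], x$counts[["excluded"]],
              x$counts[["positive"]], x$counts[["negative"]],
              x$counts[["random"]]))
  if (nrow(x$significant_pairs)) {
    cat("Significant pairs:\n")
    print(x$significant_pairs[, c("taxon_a", "taxon_b", "observed_overlap",
                                  "expected_overlap", "p_lt", "p_gt",
                                  "classification")],
          row.names = FALSE, digits = 3)
  } else {
    cat("No significant pairs.\n")
  }
  invisible(x)
}

#' Write the pair-test table to CSV/TSV
#'
#' @param fit a \code{cooccurrence} object.
#' @param path output file path.
#' @param sep field delimiter.
#' @return \code{path}, invisibly.
#' @export
write_pair_table <- function(fit, path, sep = ",") {
  stopifnot(inherits(fit, "cooccurrence"))
  utils::write.table(fit$pairs, path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
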