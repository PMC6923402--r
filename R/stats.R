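#' Inclusive upper-tail hypergeometric probability
#'
#' Probability of observing at least \code{k} annotated items when drawing
#' \code{n} items without replacement from a universe of \code{N} items of
#' which \code{K} are annotated:
#' \deqn{P(X \ge k) = \sum_{i=k}^{\min(K,n)} \binom{K}{i}\binom{N-K}{n-i} / \binom{N}{n}.}
#' The standard over-representation convention: \code{k = 0} gives 1.
#' Computation is delegated to \code{stats::phyper}, which works in log
#' space internally.
#'
#' @param k observed overlap (non-negative integer); values above
#'   \code{min(K, n)} return 0
#' @param N universe size
#' @param K annotated items in the universe (\code{K <= N})
#' @param n draws (\code{n <= N})
#' @return the tail probability in [0, 1]
#' @export
#' @examples
#' hypergeom_upper_tail(17, 275, 33, 82)  # ~0.004
hypergeom_upper_tail <- function(k, N, K, n) {
  stopifnot(length(k) == 1, length(N) == 1, length(K) == 1, length(n) == 1)
  if (N < 0 || K < 0 || n < 0 || k < 0)
    stop("hypergeometric arguments must be non-negative")
  if (K > N) stop("K must not exceed N")
  if (n > N) stop("n must not exceed N")
  if (k > min(K, n)) return(0)
  if (k <= 0) return(1)
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment; values are clipped to 1,
#' monotonicity is enforced, and input order is preserved. Wraps
#' \code{stats::p.adjust(method = "BH")}.
#'
#' @param pvalues numeric vector of raw p-values in [0, 1]
#' @return adjusted p-values, same length and order
#' @export
bh_adjust <- function(pvalues) {
  if (!length(pvalues)) return(numeric())
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

# round half up (printed percentages use commercial rounding, not banker's)
round_half_up <- function(x, digits = 0) {
  floor(x * 10^digits + 0.5) / 10^digits
}

#' Evaluate a candidate set against a disease annotation
#'
#' Computes confusion counts and metrics of the overlap between a candidate
#' node set and an annotation, with the supplied universe (normally all
#' network nodes) as background. Annotated ids outside the universe are
#' discarded before counting. Significance of the overlap is the inclusive
#' upper-tail hypergeometric probability
#' \code{P(X >= tp | N = |universe|, K, n = |candidates|)}.
#'
#' @param candidates character vector of node ids (or a
#'   \code{\link{node_set}}), must be a subset of \code{universe}
#' @param annotation a \code{\link{disease_annotation}} or character vector
#' @param universe character vector of background node ids
#' @return object of class \code{topcontrol_eval}: list with \code{tp},
#'   \code{fp}, \code{fn}, \code{tn}, \code{universe_n}, \code{disease_k},
#'   \code{candidate_n}, proportions \code{sensitivity}, \code{specificity},
#'   \code{accuracy} (NA when undefined), half-up integer percentages
#'   \code{sensitivity_pct} etc., and \code{hyper_p}
#' @export
#' @examples
#' u <- paste0("n", 1:275)
#' evaluate_candidates(u[1:82], u[c(1:17, 83:98)], u)
evaluate_candidates <- function(candidates, annotation, universe) {
  if (inherits(candidates, "node_set")) candidates <- candidates$members
  if (inherits(annotation, "disease_annotation")) annotation <- annotation$members
  universe <- unique(as.character(universe))
  if (!length(universe)) stop("empty universe")
  candidates <- unique(as.character(candidates))
  if (!all(candidates %in% universe))
    stop("candidates must be a subset of the universe")
  annotated <- intersect(unique(as.character(annotation)), universe)

  N <- length(universe)
  K <- length(annotated)
  n <- length(candidates)
  tp <- length(intersect(candidates, annotated))
  fp <- n - tp
  fn <- K - tp
  tn <- N - K - fp

  sens <- if (K > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  acc  <- (tp + tn) / N
  structure(list(
    tp = tp, fp = fp, fn = fn, tn = tn,
    universe_n = N, disease_k = K, candidate_n = n,
    sensitivity = sens, specificity = spec, accuracy = acc,
    sensitivity_pct = if (is.na(sens)) NA_real_ else round_half_up(100 * sens),
    specificity_pct = if (is.na(spec)) NA_real_ else round_half_up(100 * spec),
    accuracy_pct = round_half_up(100 * acc),
    hyper_p = hypergeom_upper_tail(tp, N, K, n)
  ), class = "topcontrol_eval")
}

#' @export
print.topcontrol_eval <- function(x, ...) {
  cat("Candidate-set evaluation (universe N = ", x$universe_n,
      ", annotated K = ", x$disease_k, ", candidates n = ", x$candidate_n,
      ")\n", sep = "")
  cat(sprintf("  tp=%d fp=%d fn=%d tn=%d\n", x$tp, x$fp, x$fn, x$tn))
  fmt <- function(p) if (is.na(p)) "NA" else sprintf("%d%%", as.integer(p))
  cat("  sensitivity ", fmt(x$sensitivity_pct),
      ", specificity ", fmt(x$specificity_pct),
      ", accuracy ", fmt(x$accuracy_pct), "\n", sep = "")
  cat("  hypergeometric p = ", format(signif(x$hyper_p, 3)), "\n", sep = "")
  invisible(x)
}

#' Serialize an evaluation report to JSON
#' @param x a \code{topcontrol_eval}
#' @param path optional output path; when NULL the JSON string is returned
#' @return the JSON string (invisibly when written to \code{path})
#' @export
eval_to_json <- function(x, path = NULL) {
  obj <- unclass(x)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, na = "null")
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
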