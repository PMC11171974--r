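#' Bin domain scores into cohort quartiles
#'
#' Maps raw EPIC-26 domain scores (0--100) to quartile categories 1 (worst)
#' to 4 (best) using the cohort's empirical 25th/50th/75th percentiles as cut
#' points.  A score equal to a cut point falls in the lower bin, so the
#' mapping is deterministic and monotone non-decreasing in the raw score.
#'
#' @param scores numeric vector of domain scores for one domain across the
#'   cohort, each in `[0, 100]`.
#' @return integer vector of quartile bins in `1:4`.
#' @examples
#' quartile_bin(c(10, 20, 30, 40, 50, 60, 70, 80))
#' @export
quartile_bin <- function(scores) {
  if (length(scores) == 0L) stop("'scores' must be a nonempty vector")
  bad <- which(!is.finite(scores) | scores < 0 | scores > 100)
  if (length(bad) > 0L) {
    stop("domain scores outside [0, 100] (or missing) at positions: ",
         paste(utils::head(bad, 10L), collapse = ", "))
  }
  # empirical percentiles with linear interpolation of order statistics
  q <- stats::quantile(scores, probs = c(0.25, 0.5, 0.75), names = FALSE,
                       type = 7)
  bins <- 1L + (scores > q[1]) + (scores > q[2]) + (scores > q[3])
  as.integer(bins)
}

#' Composite quality-of-life score
#'
#' Sums the five domain quartiles into a composite ranging from 5 (worst) to
#' 20 (best).
#'
#' @param domain_quartiles integer vector of exactly five quartile values,
#'   each in `1:4`.
#' @return integer composite score in `[5, 20]`.
#' @export
composite_score <- function(domain_quartiles) {
  if (length(domain_quartiles) != 5L)
    stop("exactly five domain quartiles are required, got ",
         length(domain_quartiles))
  if (any(!domain_quartiles %in% 1:4))
    stop("domain quartiles must be integers in 1..4")
  as.integer(sum(domain_quartiles))
}

#' Median split of composite scores
#'
#' Dichotomizes composite scores at the cohort median: patients scoring
#' strictly below the median are classed as having poor quality of life;
#' the median itself and above count as good.
#'
#' @param composites integer vector of composite scores in `[5, 20]`.
#' @return list with `poor_qol` (binary vector, 1 = poor) and `median`
#'   (the cut value used).
#' @export
median_split <- function(composites) {
  if (length(composites) == 0L) stop("'composites' must be nonempty")
  if (any(!is.finite(composites) | composites < 5 | composites > 20))
    stop("composite scores must lie in [5, 20]")
  med <- stats::median(composites)
  list(poor_qol = as.integer(composites < med), median = med)
}

#' Derive the binary poor-QoL outcome from domain scores
#'
#' Runs the full outcome derivation on a patient table: per-domain quartile
#' binning across the cohort, composite summation, and a cohort-median split.
#' Patients with any missing or out-of-range domain score are excluded from
#' derivation and reported, never silently dropped.
#'
#' @param records data.frame with a `patient_id` column and the five domain
#'   score columns.
#' @param domain_cols character vector naming the five domain score columns.
#' @return list with `outcomes` (data.frame: patient_id, five quartile
#'   columns, composite, poor_qol), `median` (split value), and `exclusions`
#'   (data.frame: patient_id, reason).
#' @export
derive_poor_qol <- function(records,
                            domain_cols = c("urinary_incontinence",
                                            "urinary_irritative",
                                            "bowel", "sexual", "hormonal")) {
  stopifnot(is.data.frame(records))
  if (!"patient_id" %in% names(records))
    stop("'records' must carry a patient_id column")
  missing_cols <- setdiff(domain_cols, names(records))
  if (length(missing_cols) > 0L)
    stop("missing domain score columns: ", paste(missing_cols, collapse = ", "))
  if (length(domain_cols) != 5L) stop("five domain columns are required")

  sc <- as.matrix(records[, domain_cols, drop = FALSE])
  ok <- rowSums(is.na(sc) | sc < 0 | sc > 100) == 0L
  exclusions <- data.frame(
    patient_id = records$patient_id[!ok],
    reason = rep("missing or out-of-range domain score", sum(!ok)),
    stringsAsFactors = FALSE)
  if (!any(ok)) stop("no patient has a complete set of valid domain scores")

  sc <- sc[ok, , drop = FALSE]
  qmat <- vapply(seq_len(5L), function(d) quartile_bin(sc[, d]),
                 integer(sum(ok)))
  qmat <- matrix(as.integer(qmat), ncol = 5L)
  composite <- as.integer(rowSums(qmat))
  split <- median_split(composite)

  outcomes <- data.frame(patient_id = records$patient_id[ok],
                         stringsAsFactors = FALSE)
  for (d in seq_len(5L)) outcomes[[paste0("q_", domain_cols[d])]] <- qmat[, d]
  outcomes$composite <- composite
  outcomes$poor_qol <- split$poor_qol
  list(outcomes = outcomes, median = split$median, exclusions = exclusions)
}
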