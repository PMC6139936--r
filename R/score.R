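#' Adjusted Rand index between two labelings
#'
#' Pair-counting ARI: 1 for identical partitions, ~0 for independent ones.
#'
#' @param a,b label vectors of equal length
#' @return numeric in `[-1, 1]`
#' @export
adjusted_rand <- function(a, b) {
  stopifnot(length(a) == length(b))
  if (length(a) == 0L) return(NA_real_)
  tab <- table(a, b)
  n <- length(a)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  mx <- (sum_a + sum_b) / 2
  if (mx == expected) return(1)
  (sum_ij - expected) / (mx - expected)
}

#' Score an inferred partition against simulation truth
#'
#' @param inferred named character vector, element id -> inferred subfamily
#'   (e.g. the `assignment` of a `subfamily_tree`)
#' @param truth named character vector, element id -> planted lineage
#' @return list with `ari`, `n`, and `per_subfamily` data.frame (precision
#'   and recall of each planted lineage against its best-matching inferred
#'   subfamily)
#' @export
score_partition <- function(inferred, truth) {
  if (!setequal(names(inferred), names(truth))) {
    stop("element universes differ between inferred partition and truth")
  }
  inferred <- inferred[names(truth)]
  ari <- adjusted_rand(unname(inferred), unname(truth))
  per <- lapply(unique(truth), function(lin) {
    ids <- names(truth)[truth == lin]
    hit <- table(inferred[ids])
    best <- names(hit)[which.max(hit)]
    tp <- max(hit)
    data.frame(lineage = lin, matched = best,
               recall = tp / length(ids),
               precision = tp / sum(inferred == best))
  })
  list(ari = ari, n = length(truth), per_subfamily = do.call(rbind, per))
}

#' Score presence/absence (shared vs lineage-specific) calls
#'
#' @param inferred data.frame with `locus_id` and `call` (e.g.
#'   `"shared"`/`"specific"` or finer history calls)
#' @param truth data.frame with `locus_id` and `call` on the same scheme
#' @return list with overall `accuracy`, `per_class` accuracy, and the
#'   confusion `table`
#' @export
score_presence <- function(inferred, truth) {
  if (!setequal(inferred$locus_id, truth$locus_id)) {
    stop("locus universes differ between inferred calls and truth")
  }
  m <- merge(truth, inferred, by = "locus_id", suffixes = c("_truth", "_inf"))
  acc <- mean(m$call_truth == m$call_inf)
  per <- vapply(split(m, m$call_truth),
                function(d) mean(d$call_truth == d$call_inf), numeric(1))
  list(accuracy = acc, per_class = per,
       table = table(truth = m$call_truth, inferred = m$call_inf))
}
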