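# Segmentation agreement metrics and instance-level precision accounting.

#' Dice similarity coefficient
#'
#' `2|A intersect B| / (|A| + |B|)` over foreground voxels.  Two empty
#' masks agree perfectly (1.0); an empty versus a non-empty mask scores 0.
#'
#' @param a,b [binary_mask()] objects on the same grid.
#' @return Scalar in `[0, 1]`.
#' @export
dsc <- function(a, b) {
  stopifnot(inherits(a, "binary_mask"), inherits(b, "binary_mask"))
  if (!same_grid(a$grid, b$grid)) stop("grid mismatch between masks")
  na <- sum(a$voxels)
  nb <- sum(b$voxels)
  if (na + nb == 0L) return(1.0)
  2 * sum(a$voxels & b$voxels) / (na + nb)
}

# surface voxels: foreground voxels with at least one 6-neighbour outside
# the foreground (volume borders count as outside)
surface_indices <- function(mask) {
  v <- mask$voxels
  d <- dim(v)
  pad <- array(FALSE, d + 2L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- v
  core <- pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] &
    pad[1:d[1], 2:(d[2] + 1), 2:(d[3] + 1)] &
    pad[3:(d[1] + 2), 2:(d[2] + 1), 2:(d[3] + 1)] &
    pad[2:(d[1] + 1), 1:d[2], 2:(d[3] + 1)] &
    pad[2:(d[1] + 1), 3:(d[2] + 2), 2:(d[3] + 1)] &
    pad[2:(d[1] + 1), 2:(d[2] + 1), 1:d[3]] &
    pad[2:(d[1] + 1), 2:(d[2] + 1), 3:(d[3] + 2)]
  idx <- which(v & !core, arr.ind = TRUE)
  storage.mode(idx) <- "integer"
  unname(idx) - 1L
}

min_dists <- function(from_mm, to_mm) {
  # nearest-neighbour distances, blocked to bound memory
  n <- nrow(from_mm)
  out <- numeric(n)
  block <- max(1L, floor(2e7 / max(1L, nrow(to_mm))))
  for (s in seq(1L, n, by = block)) {
    e <- min(n, s + block - 1L)
    d2 <- outer(rowSums(from_mm[s:e, , drop = FALSE]^2), rowSums(to_mm^2), "+") -
      2 * from_mm[s:e, , drop = FALSE] %*% t(to_mm)
    out[s:e] <- sqrt(pmax(apply(d2, 1, min), 0))
  }
  out
}

#' 95th-percentile symmetric surface distance (HD95)
#'
#' Surface voxels are foreground voxels with a 6-connected background
#' neighbour (volume borders count as background); distances are Euclidean
#' mm between voxel centres.  The two directed nearest-surface distance
#' sets are pooled and their 95th percentile taken with linear
#' interpolation ([stats::quantile()] type 7).
#'
#' @param a,b Non-empty [binary_mask()] objects on the same grid.
#' @param probs Percentile in `[0, 1]` (default 0.95; 1 gives the exact
#'   Hausdorff distance).
#' @return Distance in mm.
#' @export
hd95 <- function(a, b, probs = 0.95) {
  stopifnot(inherits(a, "binary_mask"), inherits(b, "binary_mask"))
  if (!same_grid(a$grid, b$grid)) stop("grid mismatch between masks")
  if (sum(a$voxels) == 0L || sum(b$voxels) == 0L) {
    stop("HD95 undefined for empty mask")
  }
  sa <- voxel_to_mm(a$grid, surface_indices(a))
  sb <- voxel_to_mm(b$grid, surface_indices(b))
  pooled <- c(min_dists(sa, sb), min_dists(sb, sa))
  unname(stats::quantile(pooled, probs = probs, type = 7))
}

#' Instance-level error ledger
#'
#' Counts for one structure class (or a whole cohort): total predicted +
#' reported lesion instances `n_instances`, false-positive contours
#' `n_fp`, false-negative report lesions `n_fn`.
#'
#' @param n_instances Positive integer.
#' @param n_fp,n_fn Non-negative integers.
#' @export
error_ledger <- function(n_instances, n_fp, n_fn) {
  stopifnot(n_instances >= 1, n_fp >= 0, n_fn >= 0,
            n_fp + n_fn <= 2 * n_instances)
  structure(list(n_instances = as.integer(n_instances),
                 n_fp = as.integer(n_fp), n_fn = as.integer(n_fn)),
            class = "error_ledger")
}

round_half_up <- function(x, digits = 2) floor(x * 10^digits + 0.5) / 10^digits

#' Precision from an instance ledger
#'
#' With `TP = n_instances - n_fp - n_fn`, precision is `TP / (TP + n_fp)`:
#' the fraction of predicted lesion instances that correspond to a genuine
#' reported lesion.  This is the accounting under which a ledger of
#' 111 instances with 17 FP and 8 FN yields 0.83, and 40/5/0 yields 0.88.
#'
#' @param ledger An [error_ledger()].
#' @return List with `precision` (raw) and `precision_2dp` (rounded
#'   half-up to 2 decimals, the conventional reporting form).
#' @export
precision_from_ledger <- function(ledger) {
  stopifnot(inherits(ledger, "error_ledger"))
  tp <- ledger$n_instances - ledger$n_fp - ledger$n_fn
  if (tp + ledger$n_fp <= 0) stop("no predicted positives")
  p <- tp / (tp + ledger$n_fp)
  list(precision = p, precision_2dp = round_half_up(p, 2))
}

#' Paired (or unpaired) t-test on before/after metric values
#'
#' Compares a metric across the same cases before and after ruling-out.
#' Pairs where either value is missing (e.g. HD95 undefined on an empty
#' mask) are dropped.  When every paired difference is zero the test is
#' degenerate and `p = 1` is returned with a warning.
#'
#' @param before,after Equal-length numeric vectors.
#' @param paired Default `TRUE`: the same cases are compared.
#' @return List with `t`, `p`, `df`, `n`.
#' @export
paired_t_test <- function(before, after, paired = TRUE) {
  stopifnot(length(before) == length(after))
  keep <- is.finite(before) & is.finite(after)
  before <- before[keep]
  after <- after[keep]
  if (length(before) < 2) stop("need at least 2 complete pairs")
  if (paired && all(after - before == 0)) {
    warning("all paired differences are zero; degenerate test, p = 1")
    return(list(t = 0, p = 1, df = length(before) - 1, n = length(before)))
  }
  ht <- stats::t.test(after, before, paired = paired)
  list(t = unname(ht$statistic), p = ht$p.value,
       df = unname(ht$parameter), n = length(before))
}

#' Per-case contour agreement metrics
#'
#' DSC always; HD95 only when both masks are non-empty (otherwise `NA`,
#' the metric being undefined).
#'
#' @param pred,gt Predicted and reference [binary_mask()].
#' @param case_id,structure,phase Bookkeeping labels.
#' @return One-row data.frame: `case_id`, `structure`, `phase`, `dsc`,
#'   `hd95_mm`.
#' @export
case_metrics <- function(pred, gt, case_id = "", structure = "GTVn",
                         phase = "before") {
  h <- if (sum(pred$voxels) > 0L && sum(gt$voxels) > 0L) hd95(pred, gt) else NA_real_
  data.frame(case_id = case_id, structure = structure, phase = phase,
             dsc = dsc(pred, gt), hd95_mm = h, stringsAsFactors = FALSE)
}

#' Summarise a metric column
#'
#' Mean, SD and quartiles over finite values; the summary form used for
#' cohort reporting.
#'
#' @param x Numeric vector.
#' @export
summarize_metric <- function(x) {
  x <- x[is.finite(x)]
  list(n = length(x), mean = mean(x), sd = stats::sd(x),
       q25 = unname(stats::quantile(x, 0.25, type = 7)),
       median = unname(stats::median(x)),
       q75 = unname(stats::quantile(x, 0.75, type = 7)))
}
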