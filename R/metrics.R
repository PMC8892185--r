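#' Overlap metrics for segmentation evaluation
#'
#' The Dice similarity coefficient and intersection-over-union between a
#' reference mask R and a segmentation S:
#' \deqn{DS(R,S) = 2|R \cap S| / (|R| + |S|)}
#' \deqn{IoU(R,S) = |R \cap S| / |R \cup S|}
#' Both are 1 when the masks agree, 0 when nonempty masks are disjoint, and
#' by convention 1 when both masks are empty (perfect agreement on
#' absence); an empty segmentation against a nonempty reference scores 0
#' directly from the formula. Per case the two are linked by
#' `DS = 2 IoU / (1 + IoU)`.
#'
#' @param R reference [mask3d] (or binary array).
#' @param S segmentation [mask3d] (or binary array), same shape.
#' @return a number in \[0, 1\].
#' @examples
#' a <- array(0L, c(3, 3, 1)); a[1:2, 1, 1] <- 1L
#' b <- array(0L, c(3, 3, 1)); b[2:3, 1, 1] <- 1L
#' dice(a, b)
#' iou(a, b)
#' @export
dice <- function(R, S) {
  ab <- mask_pair_counts(R, S)
  if (ab$nR + ab$nS == 0) return(1.0)
  2 * ab$inter / (ab$nR + ab$nS)
}

#' @rdname dice
#' @export
iou <- function(R, S) {
  ab <- mask_pair_counts(R, S)
  un <- ab$nR + ab$nS - ab$inter
  if (un == 0) return(1.0)
  ab$inter / un
}

mask_pair_counts <- function(R, S) {
  r <- if (inherits(R, "vol3d")) R$data else R
  s <- if (inherits(S, "vol3d")) S$data else S
  if (!identical(dim(r), dim(s)))
    stop("shape mismatch between reference and segmentation masks")
  list(nR = sum(r != 0), nS = sum(s != 0), inter = sum(r != 0 & s != 0))
}

#' Per-case evaluation records
#'
#' @param case_id case identifier string.
#' @param method segmentation method name.
#' @param R,S reference and segmentation masks.
#' @return a one-row data.frame with columns `case_id`, `method`, `ds`,
#'   `iou`.
#' @export
eval_record <- function(case_id, method, R, S) {
  data.frame(case_id = as.character(case_id), method = as.character(method),
             ds = dice(R, S), iou = iou(R, S), stringsAsFactors = FALSE)
}

#' Aggregate evaluation records per method
#'
#' Arithmetic mean and sample standard deviation of DS and IoU over cases,
#' one row per method. A single record yields sd 0 by convention.
#'
#' @param records data.frame of evaluation records (rbind of
#'   [eval_record()] rows).
#' @return data.frame with columns `method`, `n`, `ds_mean`, `ds_sd`,
#'   `iou_mean`, `iou_sd`.
#' @export
summarize_eval <- function(records) {
  if (is.null(records) || nrow(records) == 0)
    stop("no evaluation records to summarize")
  sd0 <- function(x) if (length(x) < 2) 0 else stats::sd(x)
  out <- do.call(rbind, lapply(split(records, records$method), function(g) {
    data.frame(method = g$method[1], n = nrow(g),
               ds_mean = mean(g$ds), ds_sd = sd0(g$ds),
               iou_mean = mean(g$iou), iou_sd = sd0(g$iou),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Paired significance test between two methods
#'
#' Two-sided Wilcoxon signed-rank test on per-case metric values of two
#' methods evaluated on the same cases. Exact p-values are used when the
#' sample is small and free of ties/zeros, the normal approximation
#' otherwise. If the two methods agree on every case the p-value is 1.
#'
#' @param records_a,records_b data.frames of evaluation records covering
#'   the same `case_id` sets.
#' @param metric `"ds"` or `"iou"`.
#' @return the two-sided p-value.
#' @export
paired_test <- function(records_a, records_b, metric = c("ds", "iou")) {
  metric <- match.arg(metric)
  a <- records_a[order(records_a$case_id), ]
  b <- records_b[order(records_b$case_id), ]
  if (!identical(a$case_id, b$case_id))
    stop("paired test requires identical case_id sets in both record lists")
  x <- a[[metric]]; y <- b[[metric]]
  d <- x - y
  if (all(d == 0)) return(1.0)
  suppressWarnings(
    stats::wilcox.test(x, y, paired = TRUE, alternative = "two.sided",
                       exact = length(d) < 50 && !any(d == 0) &&
                         !anyDuplicated(abs(d[d != 0])))$p.value)
}

#' Write evaluation results to disk
#'
#' Emits the per-case records as CSV and the per-method summary as JSON.
#'
#' @param records data.frame of evaluation records.
#' @param dir output directory.
#' @return invisibly, the two file paths.
#' @export
write_eval <- function(records, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  csv <- file.path(dir, "per_case.csv")
  utils::write.csv(records, csv, row.names = FALSE)
  js <- file.path(dir, "summary.json")
  jsonlite::write_json(summarize_eval(records), js, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(c(csv, js))
}
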