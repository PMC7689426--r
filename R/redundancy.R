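#' Correlation-matrix redundancy pruning
#'
#' Greedy removal of redundant features among the reliability survivors.
#' Features are visited in order of decreasing mean ICC (ties broken by
#' their order in the report, i.e. registry order); a feature is kept
#' iff its absolute Pearson correlation with every already-kept feature
#' is at or below the threshold (`|r| > threshold` marks redundancy, so
#' a pair at exactly the threshold is kept). A dropped feature records
#' the first kept feature it collided with as its `partner`.
#' Zero-variance features, whose correlation is undefined, are dropped
#' with verdict `drop_degenerate` and a warning.
#'
#' @param table numeric matrix `subjects x features` (the reading used
#'   for the correlation matrix, conventionally reader 1 read 1).
#' @param report a `reliability_report` from [reliability_filter()];
#'   only its `keep` rows enter the sweep.
#' @param r_threshold redundancy threshold on `|r|` (default 0.8).
#' @return The finalized `reliability_report`: surviving features keep
#'   `verdict == "keep"`, pruned ones become `drop_redundant` with a
#'   `partner`.
#' @export
redundancy_prune <- function(table, report, r_threshold = 0.8) {
  stopifnot(nrow(table) >= 3)
  cand <- report$feature[report$verdict == "keep"]
  cand <- cand[cand %in% colnames(table)]
  mean_icc <- (report$icc_inter + report$icc_intra) / 2
  names(mean_icc) <- report$feature
  ord <- cand[order(-mean_icc[cand], match(cand, report$feature))]
  sds <- apply(table[, ord, drop = FALSE], 2, stats::sd)
  degen <- ord[sds == 0]
  for (f in degen) {
    warning("zero-variance feature dropped: ", f)
    report$verdict[report$feature == f] <- "drop_degenerate"
  }
  ord <- setdiff(ord, degen)
  if (!length(ord)) return(report)
  cm <- abs(stats::cor(table[, ord, drop = FALSE]))
  kept <- character(0)
  for (f in ord) {
    hit <- kept[cm[f, kept] > r_threshold]
    if (!length(hit)) {
      kept <- c(kept, f)
    } else {
      i <- report$feature == f
      report$verdict[i] <- "drop_redundant"
      report$partner[i] <- hit[1]
    }
  }
  report
}

#' Features surviving the full selection
#' @param report a finalized `reliability_report`.
#' @return Character vector of kept feature names, in report order.
#' @export
kept_features <- function(report) {
  report$feature[report$verdict == "keep"]
}

#' Write / read a reliability report as CSV
#' @param report a `reliability_report`.
#' @param path output path.
#' @export
write_reliability_report <- function(report, path) {
  utils::write.csv(report, path, row.names = FALSE)
  invisible(path)
}
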