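as_label_vec <- function(x) {
  if (length(x) == 1L && nchar(x[1]) > 1L) strsplit(x, "")[[1]] else
    as.character(x)
}

#' Two-state projection of a labeling
#'
#' @param labels label vector or string.
#' @param tm_labels labels counted as transmembrane.
#' @return Logical vector: `TRUE` for TM positions.
#' @export
project_tm <- function(labels, tm_labels = "M") {
  as_label_vec(labels) %in% tm_labels
}

#' Per-residue two-state accuracy (Q2)
#'
#' Fraction of positions on which reference and prediction agree after
#' projection to \{TM, non-TM\}.
#'
#' @param ref,pred label vectors or strings of equal length.
#' @param tm_labels labels counted as TM.
#' @return Fraction in `[0, 1]`.
#' @export
#' @examples
#' q2("MMMiii", "MMiiii")  # 5/6
q2 <- function(ref, pred, tm_labels = "M") {
  r <- project_tm(ref, tm_labels)
  p <- project_tm(pred, tm_labels)
  if (length(r) != length(p))
    stop("length mismatch: reference ", length(r), ", prediction ",
         length(p))
  mean(r == p)
}

#' Segment overlap score (SOV, 1999 revision)
#'
#' SOV'99 computed on the two-state \{TM, non-TM\} projection and combined
#' over both classes weighted by reference segment lengths. For each pair of
#' overlapping reference/predicted segments of a class the contribution is
#' `len(s_ref) * (minov + delta) / maxov` with
#' `delta = min(maxov - minov, minov, floor(len(s_ref)/2),
#' floor(len(s_pred)/2))`; reference segments with no overlapping partner
#' enter only the normalization. Equals 1 iff the projected segmentations
#' are identical and 0 when no segment pair of either class overlaps.
#'
#' @inheritParams q2
#' @return Value in `[0, 1]`.
#' @export
sov <- function(ref, pred, tm_labels = "M") {
  r <- project_tm(ref, tm_labels)
  p <- project_tm(pred, tm_labels)
  if (length(r) != length(p))
    stop("length mismatch: reference ", length(r), ", prediction ",
         length(p))
  num <- 0
  norm <- 0
  for (cls in c(TRUE, FALSE)) {
    rs <- class_segments(r, cls)
    ps <- class_segments(p, cls)
    if (nrow(rs) == 0L) next
    for (a in seq_len(nrow(rs))) {
      len1 <- rs$end[a] - rs$start[a] + 1L
      overlapped <- FALSE
      if (nrow(ps) > 0L) for (b in seq_len(nrow(ps))) {
        minov <- min(rs$end[a], ps$end[b]) - max(rs$start[a], ps$start[b]) + 1L
        if (minov <= 0L) next
        overlapped <- TRUE
        maxov <- max(rs$end[a], ps$end[b]) - min(rs$start[a], ps$start[b]) + 1L
        len2 <- ps$end[b] - ps$start[b] + 1L
        delta <- min(maxov - minov, minov, len1 %/% 2L, len2 %/% 2L)
        num <- num + len1 * (minov + delta) / maxov
        norm <- norm + len1
      }
      if (!overlapped) norm <- norm + len1
    }
  }
  if (norm == 0) return(0)
  min(num / norm, 1)
}

class_segments <- function(proj, cls) {
  seg <- segments(ifelse(proj, "T", "N"))
  seg[seg$label == (if (cls) "T" else "N"), , drop = FALSE]
}

#' Correct-topology criterion
#'
#' A predicted topology is counted correct when the number of TM segments
#' matches the reference, the k-th predicted TM segment overlaps the k-th
#' reference TM segment by at least `min_overlap` residues for every k, and
#' — in `alpha` mode — the sidedness (in/out) of every connecting loop
#' matches. A loop's sidedness label is its majority non-TM label (first
#' occurring on ties); loops empty in either labeling (a TM segment at a
#' terminus) are skipped. `beta` mode checks counts and in-order overlaps
#' only.
#'
#' @inheritParams q2
#' @param mode `"alpha"` (checks loop sidedness) or `"beta"`.
#' @param min_overlap minimum per-pair overlap in residues.
#' @return Logical.
#' @export
topology_correct <- function(ref, pred, mode = c("alpha", "beta"),
                             tm_labels = "M", min_overlap = 1L) {
  mode <- match.arg(mode)
  r <- as_label_vec(ref)
  p <- as_label_vec(pred)
  if (length(r) != length(p)) stop("length mismatch")
  rs <- class_segments(project_tm(r, tm_labels), TRUE)
  ps <- class_segments(project_tm(p, tm_labels), TRUE)
  if (nrow(rs) != nrow(ps)) return(FALSE)
  if (nrow(rs) > 0L) for (k in seq_len(nrow(rs))) {
    ov <- min(rs$end[k], ps$end[k]) - max(rs$start[k], ps$start[k]) + 1L
    if (ov < min_overlap) return(FALSE)
  }
  if (mode == "beta") return(TRUE)
  loop_label <- function(labels, tm_segs, k, L) {
    # loop k = stretch before TM segment k+1 (k = 0 is the N-terminal loop)
    from <- if (k == 0L) 1L else tm_segs$end[k] + 1L
    to <- if (k == nrow(tm_segs)) L else tm_segs$start[k + 1L] - 1L
    if (from > to) return(NA_character_)
    tab <- table(labels[from:to][!labels[from:to] %in% tm_labels])
    if (length(tab) == 0L) return(NA_character_)
    names(tab)[which.max(tab)]
  }
  for (k in 0:nrow(rs)) {
    lr <- loop_label(r, rs, k, length(r))
    lp <- loop_label(p, ps, k, length(p))
    if (is.na(lr) || is.na(lp)) next
    if (lr != lp) return(FALSE)
  }
  TRUE
}

#' Correct segment (strand) count
#'
#' @inheritParams q2
#' @return `TRUE` iff reference and prediction have the same number of TM
#'   segments.
#' @export
strand_count_correct <- function(ref, pred, tm_labels = "M") {
  r <- class_segments(project_tm(ref, tm_labels), TRUE)
  p <- class_segments(project_tm(pred, tm_labels), TRUE)
  nrow(r) == nrow(p)
}

#' Sensitivity, specificity, and Matthews correlation from a 2x2 table
#'
#' `MCC = (tp*tn - fp*fn) / sqrt((tp+fp)(tp+fn)(tn+fp)(tn+fn))`, set to 0
#' by convention when any denominator factor is 0. Sensitivity or
#' specificity is `NaN` when its own denominator is 0.
#'
#' @param tp,fp,tn,fn nonnegative integer counts (not all zero).
#' @return One-row tibble: `sensitivity`, `specificity`, `mcc`.
#' @export
#' @examples
#' binary_stats(8, 2, 7, 3)
binary_stats <- function(tp, fp, tn, fn) {
  stopifnot(tp >= 0, fp >= 0, tn >= 0, fn >= 0)
  if (tp + fp + tn + fn == 0) stop("all four counts are zero")
  denom <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (denom == 0) 0 else (tp * tn - fp * fn) / sqrt(denom)
  tibble::tibble(sensitivity = tp / (tp + fn),
                 specificity = tn / (tn + fp), mcc = mcc)
}

#' Evaluate predictions against reference labelings
#'
#' Computes the per-protein topology metrics (Q2, SOV, topology-correct,
#' segment-count-correct) and their aggregates.
#'
#' @param refs list of labeled sequences (the references).
#' @param preds list of `prediction` objects or label vectors, aligned with
#'   `refs`.
#' @param mode topology criterion mode, see [topology_correct()].
#' @param tm_labels labels counted as TM.
#' @return Tibble of class `eval_report`, one row per protein (`id`,
#'   `length`, `q2`, `sov`, `topology_correct`, `count_correct`), with
#'   attribute `aggregate` (one-row tibble of means/counts; `q2_residue` is
#'   the residue-weighted mean Q2).
#' @export
evaluate_predictions <- function(refs, preds, mode = c("alpha", "beta"),
                                 tm_labels = "M") {
  mode <- match.arg(mode)
  stopifnot(length(refs) == length(preds))
  rows <- lapply(seq_along(refs), function(j) {
    ref <- refs[[j]]$labels
    pl <- preds[[j]]
    if (inherits(pl, "prediction")) pl <- pl$labels
    tibble::tibble(
      id = refs[[j]]$id, length = length(ref),
      q2 = q2(ref, pl, tm_labels), sov = sov(ref, pl, tm_labels),
      topology_correct = topology_correct(ref, pl, mode, tm_labels),
      count_correct = strand_count_correct(ref, pl, tm_labels))
  })
  rep <- do.call(rbind, rows)
  agg <- tibble::tibble(
    n = nrow(rep), q2 = mean(rep$q2),
    q2_residue = sum(rep$q2 * rep$length) / sum(rep$length),
    sov = mean(rep$sov),
    n_topology_correct = sum(rep$topology_correct),
    n_count_correct = sum(rep$count_correct))
  attr(rep, "aggregate") <- agg
  class(rep) <- c("eval_report", class(rep))
  rep
}

#' Aggregate summary of an evaluation report
#'
#' @param x an `eval_report` from [evaluate_predictions()].
#' @param ... unused.
#' @return One-row tibble of aggregate metrics.
#' @export
glance.eval_report <- function(x, ...) attr(x, "aggregate")

#' Write an evaluation report as TSV
#'
#' One row per protein plus an aggregate summary block.
#'
#' @param report an `eval_report`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_eval_report <- function(report, path) {
  con <- file(path, "w")
  on.exit(close(con))
  utils::write.table(as.data.frame(report), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  writeLines("", con)
  writeLines("# aggregate", con)
  utils::write.table(as.data.frame(attr(report, "aggregate")), con,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
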