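# qPCR relative quantification and the rescue screen: U6-normalized 2^-ddCt
# over a miRNome panel, selection of miRNAs downregulated in disease and
# restored to control level upon knockdown of the driver, and the plain
# 2^-dCt quantification used for circularization RT-qPCR of adenylated
# miRNAs.

#' Construct a Ct table
#'
#' @param ct numeric matrix of cycle thresholds, targets (including the
#'   internal control) x samples. NA marks undetermined wells.
#' @param groups named character vector, sample id -> group label.
#' @param internal_control row id of the internal control (e.g. `"U6"`).
#' @return object of class `ct_table`.
#' @export
ct_table <- function(ct, groups, internal_control = "U6") {
  stopifnot(is.matrix(ct), !is.null(rownames(ct)), !is.null(colnames(ct)))
  if (!internal_control %in% rownames(ct))
    stop("internal control '", internal_control, "' not in Ct table")
  if (any(!is.na(ct) & ct <= 0))
    stop("Ct values must be positive")
  bad <- colnames(ct)[is.na(ct[internal_control, ])]
  if (length(bad))
    stop("missing internal-control Ct in sample(s): ",
         paste(bad, collapse = ", "))
  if (!all(colnames(ct) %in% names(groups)))
    stop("every sample needs a group label")
  structure(list(ct = ct, groups = groups[colnames(ct)],
                 internal_control = internal_control),
            class = "ct_table")
}

#' @export
print.ct_table <- function(x, ...) {
  cat(sprintf("ct_table: %d targets x %d samples (internal control: %s)\n",
              nrow(x$ct) - 1L, ncol(x$ct), x$internal_control))
  invisible(x)
}

#' Relative expression by the 2^-ddCt method
#'
#' For every target and sample: dCt = Ct_target - Ct_internal-control; the
#' dCt values of the control samples are averaged per target
#' (dCt_control-averaged); ddCt = dCt - dCt_control-averaged; fold =
#' 2^-ddCt. Missing target Ct values propagate to missing folds.
#'
#' @param ct a [ct_table].
#' @param control_samples sample ids defining the control average (>= 1).
#' @return object of class `fold_table`: matrices `delta_ct`, `delta_delta_ct`
#'   and `fold` (targets x samples, internal-control row dropped), the per-
#'   target `control_avg_delta_ct`, plus `groups` and `control_samples`.
#' @export
delta_delta_ct <- function(ct, control_samples) {
  stopifnot(inherits(ct, "ct_table"))
  if (length(control_samples) < 1L) stop("need >= 1 control sample")
  missing_s <- setdiff(control_samples, colnames(ct$ct))
  if (length(missing_s))
    stop("control sample(s) not in Ct table: ",
         paste(missing_s, collapse = ", "))
  ic <- ct$ct[ct$internal_control, ]
  targets <- setdiff(rownames(ct$ct), ct$internal_control)
  dct <- sweep(ct$ct[targets, , drop = FALSE], 2L, ic, `-`)
  ctrl_avg <- rowMeans(dct[, control_samples, drop = FALSE])
  ddct <- sweep(dct, 1L, ctrl_avg, `-`)
  structure(list(delta_ct = dct, delta_delta_ct = ddct, fold = 2^(-ddct),
                 control_avg_delta_ct = ctrl_avg,
                 groups = ct$groups, control_samples = control_samples),
            class = "fold_table")
}

#' Relative levels by the 2^-dCt method (no internal-control normalization)
#'
#' Used for circularization RT-qPCR of adenylated miRNAs: per target,
#' dCt = Ct - mean(Ct over control samples) and relative level = 2^-dCt.
#' The geometric mean of the control samples' relative levels is 1 by
#' construction.
#'
#' @param ct numeric matrix (targets x samples) or vector of Ct values.
#' @param control_samples sample ids (or indices) averaged per target.
#' @return matrix (or vector) of relative levels.
#' @export
rel_quant_delta_ct <- function(ct, control_samples) {
  if (length(control_samples) < 1L) stop("need >= 1 control sample")
  vec <- !is.matrix(ct)
  if (vec) ct <- matrix(ct, 1L, dimnames = list("target", names(ct)))
  if (is.character(control_samples)) {
    missing_s <- setdiff(control_samples, colnames(ct))
    if (length(missing_s))
      stop("control sample(s) not found: ", paste(missing_s, collapse = ", "))
  }
  avg <- rowMeans(ct[, control_samples, drop = FALSE])
  rel <- 2^(-sweep(ct, 1L, avg, `-`))
  if (vec) rel[1L, ] else rel
}

#' Screen for miRNAs downregulated in disease and restored on knockdown
#'
#' Selects panel targets whose group-mean fold in the disease group is at
#' most `down_threshold` times the control level AND whose group-mean fold
#' in the knockdown group lies within `restore_range` of the control level
#' ("restored to normal"). Group means of per-sample folds are arithmetic by
#' default (option: geometric).
#'
#' @param folds a [fold_table] from [delta_delta_ct()].
#' @param group_roles named character vector of length 3 mapping roles to
#'   group labels: `c(control = ..., disease = ..., knockdown = ...)`.
#' @param down_threshold maximum disease/control fold to call "down".
#' @param restore_range numeric pair: knockdown/control fold interval that
#'   counts as restored (default 0.8 to 1.25).
#' @param mean_type `"arithmetic"` (default) or `"geometric"` group summary.
#' @return list with `selected` (character vector of ids), `verdicts` (per
#'   target: group-mean folds, `down`, `restored`, `selected`), and
#'   `thresholds` (echoed parameters; written into output headers by
#'   [write_screen_verdicts()]).
#' @export
screen_restored <- function(folds, group_roles,
                            down_threshold = 0.8,
                            restore_range = c(0.8, 1.25),
                            mean_type = c("arithmetic", "geometric")) {
  stopifnot(inherits(folds, "fold_table"))
  mean_type <- match.arg(mean_type)
  roles <- c("control", "disease", "knockdown")
  if (!all(roles %in% names(group_roles)))
    stop("group_roles must name control, disease and knockdown groups")
  missing_g <- setdiff(unname(group_roles[roles]), unique(folds$groups))
  if (length(missing_g))
    stop("group(s) absent from fold table: ", paste(missing_g, collapse = ", "))
  gmean <- function(x) exp(mean(log(x)))
  summarize <- if (mean_type == "arithmetic") function(x) mean(x) else gmean
  fm <- folds$fold
  grp_mean <- sapply(roles, function(r) {
    cols <- names(folds$groups)[folds$groups == group_roles[[r]]]
    apply(fm[, cols, drop = FALSE], 1L, summarize)
  })
  if (is.null(dim(grp_mean)))
    grp_mean <- matrix(grp_mean, nrow = 1L,
                       dimnames = list(rownames(fm), roles))
  # folds are already relative to the control average; express disease and
  # knockdown relative to the realized control group mean to be safe
  rel_dis <- grp_mean[, "disease"] / grp_mean[, "control"]
  rel_kd <- grp_mean[, "knockdown"] / grp_mean[, "control"]
  down <- rel_dis <= down_threshold
  restored <- rel_kd >= restore_range[1L] & rel_kd <= restore_range[2L]
  selected <- down & restored
  verdicts <- data.frame(mirna_id = rownames(fm),
                         fold_control = grp_mean[, "control"],
                         fold_disease = grp_mean[, "disease"],
                         fold_knockdown = grp_mean[, "knockdown"],
                         down = down, restored = restored,
                         selected = selected,
                         stringsAsFactors = FALSE)
  rownames(verdicts) <- NULL
  list(selected = verdicts$mirna_id[selected],
       verdicts = verdicts,
       thresholds = list(down_threshold = down_threshold,
                         restore_range = restore_range,
                         mean_type = mean_type,
                         group_roles = as.list(group_roles[roles])))
}

#' Write screen verdicts with a threshold provenance header
#'
#' @param screen result of [screen_restored()].
#' @param path output TSV; the selection thresholds are recorded in `#`
#'   comment lines at the top.
#' @return invisibly, `path`.
#' @export
write_screen_verdicts <- function(screen, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  th <- screen$thresholds
  writeLines(c(
    sprintf("# down_threshold=%g", th$down_threshold),
    sprintf("# restore_range=[%g,%g]", th$restore_range[1L],
            th$restore_range[2L]),
    sprintf("# mean_type=%s", th$mean_type),
    sprintf("# groups: control=%s disease=%s knockdown=%s",
            th$group_roles$control, th$group_roles$disease,
            th$group_roles$knockdown)), con)
  utils::write.table(screen$verdicts, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Export a log2-fold heat-map matrix
#'
#' Writes the log2 folds of a selection of targets as CSV, row-ordered by
#' input order or by hierarchical clustering of fold profiles, ready for any
#' plotting tool.
#'
#' @param folds a [fold_table].
#' @param selection character vector of target ids (non-empty).
#' @param path output CSV file, or NULL to return the matrix only.
#' @param order `"input"` (default) or `"hclust"` (complete linkage on
#'   Euclidean distance of log2-fold profiles).
#' @return the log2-fold matrix (invisibly when written to file).
#' @export
export_heatmap_matrix <- function(folds, selection, path = NULL,
                                  order = c("input", "hclust")) {
  stopifnot(inherits(folds, "fold_table"))
  order <- match.arg(order)
  if (length(selection) == 0L) stop("selection must be non-empty")
  missing_t <- setdiff(selection, rownames(folds$fold))
  if (length(missing_t))
    stop("selection not in fold table: ", paste(missing_t, collapse = ", "))
  m <- log2(folds$fold[selection, , drop = FALSE])
  if (order == "hclust" && nrow(m) > 2L) {
    hc <- stats::hclust(stats::dist(m))
    m <- m[hc$order, , drop = FALSE]
  }
  if (!is.null(path)) {
    utils::write.csv(data.frame(mirna_id = rownames(m), m,
                                check.names = FALSE), path,
                     row.names = FALSE, quote = FALSE)
    return(invisible(m))
  }
  m
}

#' Write a fold table as TSV
#'
#' @param folds a [fold_table].
#' @param path output TSV (targets x samples of 2^-ddCt folds).
#' @return invisibly, `path`.
#' @export
write_fold_table <- function(folds, path) {
  utils::write.table(data.frame(mirna_id = rownames(folds$fold), folds$fold,
                                check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
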