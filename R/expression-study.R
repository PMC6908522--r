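#' Construct an ExpressionStudy
#'
#' The unit of per-study analysis: a feature-by-sample expression matrix
#' together with sample group labels (`control` vs `case`), the study's
#' disease class (`LC` lung cancer, `LD` other lung disease) and the scale
#' the values live on (`raw` scanner intensities or `glog2` after
#' variance stabilization).
#'
#' @param study_id character study identifier.
#' @param disease_class `"LC"` or `"LD"`.
#' @param values numeric matrix, features in rows, samples in columns;
#'   dimnames are used as feature and sample labels.
#' @param group character/factor of length `ncol(values)` with levels
#'   `control` and `case`.
#' @param scale `"raw"` or `"glog2"`.
#' @return an object of class `ExpressionStudy`.
#' @export
expression_study <- function(study_id, disease_class, values, group,
                             scale = c("raw", "glog2")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    stop_format("values must be a numeric matrix")
  feats <- rownames(values)
  samps <- colnames(values)
  if (is.null(feats) || is.null(samps))
    stop_format("values must carry feature rownames and sample colnames")
  if (anyDuplicated(feats))
    stop_format("duplicate feature labels: %s",
                paste(unique(feats[duplicated(feats)]), collapse = ", "))
  if (anyDuplicated(samps))
    stop_format("duplicate sample labels: %s",
                paste(unique(samps[duplicated(samps)]), collapse = ", "))
  group <- as.character(group)
  if (length(group) != ncol(values))
    stop_format("group has length %d but study has %d samples",
                length(group), ncol(values))
  if (!all(group %in% c("control", "case")))
    stop_format("group labels must be 'control' or 'case'")
  if (any(table(factor(group, levels = c("control", "case"))) < 2))
    stop_format("study '%s': fewer than 2 samples in a group", study_id)
  if (!disease_class %in% c("LC", "LD"))
    stop_format("disease_class must be 'LC' or 'LD'")
  if (scale == "glog2" && !all(is.finite(values)))
    stop_format("non-finite values not allowed on the glog2 scale")
  structure(
    list(study_id = as.character(study_id), disease_class = disease_class,
         values = values, group = stats::setNames(group, samps),
         scale = scale),
    class = "ExpressionStudy"
  )
}

#' @export
print.ExpressionStudy <- function(x, ...) {
  cat(sprintf(
    "ExpressionStudy '%s' (%s): %d features x %d samples (%d control / %d case), scale=%s\n",
    x$study_id, x$disease_class, nrow(x$values), ncol(x$values),
    sum(x$group == "control"), sum(x$group == "case"), x$scale))
  invisible(x)
}

#' @export
dim.ExpressionStudy <- function(x) dim(x$values)

study_features <- function(study) rownames(study$values)
study_samples  <- function(study) colnames(study$values)

## split columns by group, in study order
group_columns <- function(study) {
  list(control = which(unname(study$group) == "control"),
       case    = which(unname(study$group) == "case"))
}
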