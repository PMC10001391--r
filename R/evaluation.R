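# Segmentation metrics over the three clinically reported tumor regions:
# whole tumor (WT), tumor core (TC) and enhancing tumor (EnT).

#' Derive the clinical region masks from a label map
#'
#' Internal class codes: 0 background, 1 necrotic core, 2 edema/non-enhancing,
#' 3 enhancing.  The regions follow the BraTS convention:
#' WT = \{1, 2, 3\}, TC = \{1, 3\}, EnT = \{3\}.
#'
#' @param labels integer label matrix/array with internal codes 0..3.
#' @return named list of logical masks `WT`, `TC`, `EnT` (EnT ⊆ TC ⊆ WT).
#' @export
region_masks <- function(labels) {
  bad <- setdiff(unique(as.vector(labels)), 0:3)
  if (length(bad))
    stop("unexpected label values: ", paste(bad, collapse = ", "))
  list(WT = array(labels %in% 1:3, dim(labels)),
       TC = array(labels %in% c(1, 3), dim(labels)),
       EnT = array(labels == 3, dim(labels)))
}

check_same_shape <- function(G, S) {
  if (!identical(dim(G), dim(S)))
    stop("mask shapes differ: ", paste(dim(G), collapse = "x"), " vs ",
         paste(dim(S), collapse = "x"))
}

#' Dice similarity coefficient of two binary masks
#'
#' `2|G∩S| / (|G| + |S|)`; when both masks are empty the overlap is perfect
#' by convention and 1 is returned.
#'
#' @param G,S logical (or 0/1) arrays of one shape.
#' @return scalar in \[0, 1\].
#' @export
dsc <- function(G, S) {
  check_same_shape(G, S)
  g <- sum(G != 0); s <- sum(S != 0)
  if (g + s == 0) return(1)
  2 * sum(G != 0 & S != 0) / (g + s)
}

#' Intersection over union (Jaccard index) of two binary masks
#'
#' `|G∩S| / |G∪S|`; both masks empty gives 1 by convention.  Related to the
#' Dice coefficient by `IoU = DSC / (2 - DSC)` for any mask pair.
#'
#' @inheritParams dsc
#' @return scalar in \[0, 1\].
#' @export
iou <- function(G, S) {
  check_same_shape(G, S)
  u <- sum(G != 0 | S != 0)
  if (u == 0) return(1)
  sum(G != 0 & S != 0) / u
}

# boundary pixels: mask pixels with at least one 4-connected background
# neighbour (image border counts as background); 1-pixel masks fall back to
# the full mask
mask_boundary <- function(M) {
  M <- M != 0
  n <- nrow(M); p <- ncol(M)
  pad <- matrix(FALSE, n + 2, p + 2)
  pad[2:(n + 1), 2:(p + 1)] <- M
  inner <- pad[2:(n + 1), 2:(p + 1)] &
    pad[1:n, 2:(p + 1)] & pad[3:(n + 2), 2:(p + 1)] &
    pad[2:(n + 1), 1:p] & pad[2:(n + 1), 3:(p + 2)]
  b <- M & !inner
  if (!any(b)) M else b
}

#' 95th-percentile Hausdorff distance between two masks
#'
#' Boundary points of each mask are extracted (4-connectivity); for each
#' boundary point of one mask the Euclidean distance to the nearest boundary
#' point of the other is computed, the 95th percentile is taken in each
#' direction, and the maximum of the two directed values is returned.
#' Distances are in mm via `spacing`.
#'
#' @param T_mask,P_mask logical arrays of one shape (ground truth and
#'   prediction).
#' @param spacing pixel spacing in mm (length 2, default `c(1, 1)`).
#' @param percentile distance percentile (default 0.95; 1 gives the classical
#'   sup-inf Hausdorff distance).
#' @return distance in mm; 0 when both masks are empty, `NA` (undefined)
#'   when exactly one is empty.
#' @export
hausdorff95 <- function(T_mask, P_mask, spacing = c(1, 1),
                        percentile = 0.95) {
  check_same_shape(T_mask, P_mask)
  et <- sum(T_mask != 0) == 0
  ep <- sum(P_mask != 0) == 0
  if (et && ep) return(0)
  if (et || ep) return(NA_real_)
  bt <- which(mask_boundary(T_mask), arr.ind = TRUE)
  bp <- which(mask_boundary(P_mask), arr.ind = TRUE)
  pt <- sweep(bt, 2, spacing[1:2], "*")
  pp <- sweep(bp, 2, spacing[1:2], "*")
  d2 <- outer(pt[, 1], pp[, 1], "-")^2 + outer(pt[, 2], pp[, 2], "-")^2
  dtp <- sqrt(apply(d2, 1, min))   # T -> nearest P
  dpt <- sqrt(apply(d2, 2, min))   # P -> nearest T
  max(stats::quantile(dtp, percentile, names = FALSE),
      stats::quantile(dpt, percentile, names = FALSE))
}

#' Pixel-level confusion metrics of two binary masks
#'
#' @inheritParams dsc
#' @return named list: `accuracy`, `precision`, `recall`, `f1`, plus
#'   `degenerate`, TRUE when a zero denominator forced a metric to 0.
#' @export
pixel_metrics <- function(G, S) {
  check_same_shape(G, S)
  g <- G != 0; s <- S != 0
  tp <- sum(g & s); tn <- sum(!g & !s)
  fp <- sum(!g & s); fn <- sum(g & !s)
  total <- tp + tn + fp + fn
  degenerate <- FALSE
  div <- function(num, den) {
    if (den == 0) { degenerate <<- TRUE; 0 } else num / den
  }
  precision <- div(tp, tp + fp)
  recall <- div(tp, tp + fn)
  f1 <- div(2 * precision * recall, precision + recall)
  list(accuracy = div(tp + tn, total), precision = precision,
       recall = recall, f1 = f1, degenerate = degenerate)
}

region_metric_row <- function(Gm, Sm, spacing) {
  pm <- pixel_metrics(Gm, Sm)
  c(dsc = dsc(Gm, Sm), iou = iou(Gm, Sm),
    hd95 = hausdorff95(Gm, Sm, spacing),
    precision = pm$precision, recall = pm$recall, f1 = pm$f1,
    accuracy = pm$accuracy)
}

#' Evaluate predicted label maps against ground truth
#'
#' Computes per-case WT/TC/EnT metrics and aggregates them by the mean over
#' cases; cases where HD95 is undefined (exactly one empty mask) are excluded
#' from the HD95 mean only.
#'
#' @param pred list of predicted label matrices (internal codes 0..3).
#' @param gt list of ground-truth label matrices, same length and shapes.
#' @param spacing pixel spacing in mm.
#' @return data.frame with one row per region and columns
#'   `region, dsc, iou, hd95, precision, recall, f1, accuracy`.
#' @export
evaluate_predictions <- function(pred, gt, spacing = c(1, 1)) {
  stopifnot(length(pred) == length(gt), length(gt) > 0)
  regions <- c("WT", "TC", "EnT")
  acc <- array(NA_real_, c(length(pred), 7, 3),
               dimnames = list(NULL,
                               c("dsc", "iou", "hd95", "precision", "recall",
                                 "f1", "accuracy"), regions))
  for (i in seq_along(pred)) {
    gm <- region_masks(gt[[i]])
    sm <- region_masks(pred[[i]])
    for (r in regions)
      acc[i, , r] <- region_metric_row(gm[[r]], sm[[r]], spacing)
  }
  out <- data.frame(region = regions)
  for (m in dimnames(acc)[[2]])
    out[[m]] <- vapply(regions, function(r)
      mean(acc[, m, r], na.rm = (m == "hd95")), numeric(1))
  out
}

#' Predict and evaluate a dataset split with a trained model
#'
#' Runs the model on every pair of the split, takes the per-pixel argmax
#' labels and calls [evaluate_predictions()].
#'
#' @param model a model from [build_model()].
#' @param dataset list of `list(x = slice, y = labels)` pairs.
#' @param spacing pixel spacing in mm.
#' @return data.frame as in [evaluate_predictions()].
#' @export
evaluate_split <- function(model, dataset, spacing = c(1, 1)) {
  if (!length(dataset)) stop("empty dataset")
  if (any(vapply(dataset, function(p) is.null(p$y), logical(1))))
    stop("evaluation requires ground-truth labels for every case")
  pred <- lapply(dataset, function(p) predict_labels(model, p$x))
  gt <- lapply(dataset, function(p) p$y)
  evaluate_predictions(pred, gt, spacing)
}
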