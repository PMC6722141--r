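#' Dice overlap of one label between two masks
#'
#' `Dice = 2 |A intersect B| / (|A| + |B|)` for the voxel sets carrying the
#' given label. When the label is absent from both masks the overlap is
#' undefined and `NA` is returned (never silently 1).
#'
#' @param a,b [hg_labels] on a common grid.
#' @param label positive integer label value.
#' @return Scalar in `[0, 1]`, or `NA_real_` when undefined.
#' @export
dice <- function(a, b, label) {
  check_same_grid(a, b)
  in_a <- a$labels == label
  in_b <- b$labels == label
  na <- sum(in_a)
  nb <- sum(in_b)
  if (na + nb == 0) return(NA_real_)
  2 * sum(in_a & in_b) / (na + nb)
}

#' Size-weighted overall Dice
#'
#' Weighted mean of per-label Dice values with weights proportional to the
#' (mean) region sizes, so large structures dominate the summary the way
#' they dominate the image.
#'
#' @param per_label data.frame with columns `dice` and `size` (one row per
#'   label; rows with `NA` dice are dropped).
#' @return Scalar in `[0, 1]`.
#' @export
weighted_overall_dice <- function(per_label) {
  stopifnot(is.data.frame(per_label), nrow(per_label) > 0)
  keep <- !is.na(per_label$dice)
  if (!any(keep)) stop("all labels undefined: no Dice values to weight")
  d <- per_label$dice[keep]
  w <- per_label$size[keep]
  sum(d * w) / sum(w)
}

#' Majority-vote group label map
#'
#' Per-voxel modal label across the input masks; ties are broken by the
#' smallest label value (including background 0).
#'
#' @param label_maps non-empty list of [hg_labels] on a common grid.
#' @return An [hg_labels].
#' @export
majority_vote <- function(label_maps) {
  stopifnot(length(label_maps) >= 1)
  if (length(label_maps) == 1) return(label_maps[[1]])
  for (m in label_maps[-1]) check_same_grid(label_maps[[1]], m)
  d <- grid_dim(label_maps[[1]])
  vals <- sort(unique(unlist(lapply(label_maps,
                                    function(m) unique(as.vector(m$labels))))))
  best_count <- array(-1, dim = d)
  best_label <- array(0, dim = d)
  for (v in vals) {  # ascending: strict > keeps the smallest label on ties
    cnt <- Reduce(`+`, lapply(label_maps, function(m) (m$labels == v) * 1))
    sel <- cnt > best_count
    best_label[sel] <- v
    best_count[sel] <- cnt[sel]
  }
  hg_labels(best_label, label_maps[[1]]$spacing, label_maps[[1]]$affine)
}

#' Sharpness of an image (mean gradient magnitude)
#'
#' Reported for group-mean images: a sharper mean (better-aligned
#' population) has larger average gradient magnitude. A qualitative
#' diagnostic only, never an acceptance gate.
#'
#' @param img an [hg_volume].
#' @return Non-negative scalar.
#' @export
sharpness <- function(img) {
  g <- cpp_gradient(img$data)
  d <- dim(img$data)
  n <- prod(d)
  mag <- sqrt(g[seq_len(n)]^2 + g[n + seq_len(n)]^2 + g[2 * n + seq_len(n)]^2)
  mean(mag)
}

#' Evaluate a groupwise registration run against label masks
#'
#' Warps each input mask by its final deformation (nearest-neighbour),
#' builds the majority-vote group label map, and computes per-label and
#' size-weighted overall Dice of every warped mask against the group label
#' map, plus the sharpness of the group-mean image. With `psi = NULL` the
#' masks are evaluated unwarped, giving the pre-registration baseline.
#'
#' @param result an `hg_registration_result`, or `NULL` when `psi` given.
#' @param label_masks list of [hg_labels], one per input image.
#' @param psi optional explicit list of displacement fields overriding
#'   `result$psi` (use `NULL` entries / `NULL` for identity).
#' @return An `hg_eval_report`: `per_image` data.frame (`image`, `label`,
#'   `dice`, `size`; label `"overall"` rows carry the weighted Dice),
#'   `overall` (mean over images of the weighted Dice), `group_labels`,
#'   `sharpness` (of the group-mean image when available).
#' @export
evaluate_run <- function(result, label_masks, psi = NULL) {
  n <- length(label_masks)
  if (n == 0) stop("no label masks supplied")
  if (is.null(psi) && !is.null(result)) psi <- result$psi
  warped_masks <- lapply(seq_len(n), function(i) {
    if (is.null(psi) || is.null(psi[[i]])) label_masks[[i]]
    else warp_labels(label_masks[[i]], psi[[i]])
  })
  group_lab <- majority_vote(warped_masks)
  labels <- sort(setdiff(unique(as.vector(group_lab$labels)), 0))
  if (length(labels) == 0)
    labels <- sort(setdiff(unique(unlist(lapply(warped_masks, function(m)
      unique(as.vector(m$labels))))), 0))
  rows <- list()
  overall_by_image <- numeric(n)
  for (i in seq_len(n)) {
    per_label <- data.frame(
      label = labels,
      dice = vapply(labels, function(l)
        dice(warped_masks[[i]], group_lab, l), numeric(1)),
      size = vapply(labels, function(l)
        mean(c(sum(warped_masks[[i]]$labels == l),
               sum(group_lab$labels == l))), numeric(1)))
    ov <- weighted_overall_dice(per_label)
    overall_by_image[i] <- ov
    rows[[i]] <- rbind(
      data.frame(image = i, label = as.character(per_label$label),
                 dice = per_label$dice, size = per_label$size),
      data.frame(image = i, label = "overall", dice = ov,
                 size = sum(per_label$size)))
  }
  sharp <- if (!is.null(result) && !is.null(result$group_center))
    sharpness(result$group_center) else NA_real_
  structure(list(per_image = do.call(rbind, rows),
                 overall = mean(overall_by_image),
                 group_labels = group_lab, sharpness = sharp),
            class = "hg_eval_report")
}

#' @export
print.hg_eval_report <- function(x, ...) {
  cat("<hg_eval_report> overall weighted Dice = ",
      sprintf("%.4f", x$overall),
      if (!is.na(x$sharpness))
        sprintf(", group-mean sharpness = %.4f", x$sharpness),
      "\n", sep = "")
  invisible(x)
}

#' Write an evaluation report to CSV + JSON
#'
#' @param report an `hg_eval_report`.
#' @param dir output directory (`dice_report.csv`, `report.json`).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$per_image, file.path(dir, "dice_report.csv"),
                   row.names = FALSE)
  jsonlite::write_json(list(overall_weighted_dice = report$overall,
                            sharpness = report$sharpness),
                       file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
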