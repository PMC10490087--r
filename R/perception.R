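#' Load a hierarchical food taxonomy
#'
#' The taxonomy is a three-level tree (fine inside middle inside coarse),
#' shipped as a TSV with columns `fine`, `middle`, `coarse`. Every fine
#' label must have exactly one middle and one coarse ancestor. A miniature
#' fixture taxonomy (5 coarse / 8 middle / 20 fine) is bundled with the
#' package for tests and demos; real deployments substitute their own table
#' (the study-scale instance has 18 coarse, 34 middle and 301 fine
#' categories).
#'
#' @param path TSV file; defaults to the bundled miniature taxonomy.
#' @return A `food_taxonomy` tibble (fine, middle, coarse) with attribute
#'   `levels` reporting the level sizes.
#' @export
load_taxonomy <- function(path = system.file("extdata", "taxonomy_mini.tsv",
                                             package = "mealmetry")) {
  tax <- readr::read_tsv(path, col_types = "ccc")
  if (!all(c("fine", "middle", "coarse") %in% names(tax))) {
    abort("taxonomy must have columns fine, middle, coarse")
  }
  dup <- tax |> count(fine) |> filter(n > 1)
  if (nrow(dup) > 0) {
    abort(sprintf("fine categories mapped more than once: %s",
                  paste(dup$fine, collapse = ", ")))
  }
  amb <- tax |> distinct(middle, coarse) |> count(middle) |> filter(n > 1)
  if (nrow(amb) > 0) {
    abort(sprintf("middle categories with multiple coarse parents: %s",
                  paste(amb$middle, collapse = ", ")))
  }
  attr(tax, "levels") <- c(coarse = dplyr::n_distinct(tax$coarse),
                           middle = dplyr::n_distinct(tax$middle),
                           fine = nrow(tax))
  class(tax) <- c("food_taxonomy", class(tax))
  tax
}

#' Roll a fine label up the taxonomy
#'
#' @param fine_label Fine category name.
#' @param taxonomy A `food_taxonomy`.
#' @return Named list with `middle` and `coarse`.
#' @export
roll_up <- function(fine_label, taxonomy) {
  row <- taxonomy[taxonomy$fine == fine_label, ]
  if (nrow(row) == 0) {
    abort(sprintf("unknown fine category '%s'", fine_label),
          class = "mealmetry_unknown_category")
  }
  list(middle = row$middle[1], coarse = row$coarse[1])
}

roll_up_vec <- function(labels, taxonomy, level) {
  if (level == "fine") return(labels)
  i <- match(labels, taxonomy$fine)
  if (anyNA(i)) {
    abort(sprintf("unknown fine category '%s'", labels[which(is.na(i))[1]]),
          class = "mealmetry_unknown_category")
  }
  taxonomy[[level]][i]
}

#' Baseline segmentation of a synthetic render
#'
#' Desk-scale stand-in for a learned instance segmenter, for end-to-end
#' tests only: it reads the renderer's per-item index channel and returns
#' one mask per connected component of each index. Touching items with
#' distinct indices stay separated. Real segmentation masks enter the
#' pipeline through the same list-of-masks contract.
#'
#' @param index Integer matrix (0 = background, k = item k), as in
#'   `render_output$index`.
#' @return List of logical masks, pairwise disjoint, ordered by item index.
#' @export
baseline_segment <- function(index) {
  stopifnot(is.matrix(index))
  ids <- sort(unique(index[!is.na(index) & index > 0]))
  masks <- list()
  for (id in ids) {
    comp <- label_components(!is.na(index) & index == id)
    for (lab in seq_len(max(comp))) {
      masks[[length(masks) + 1]] <- comp == lab
    }
  }
  masks
}

#' Build an oracle prediction ranking
#'
#' Test-harness classifier: returns a ranking over fine categories with the
#' ground-truth label placed at a configurable rank, filled with decoys
#' drawn deterministically from the taxonomy. Stands in for a trained
#' recognition network in end-to-end tests; external model rankings enter
#' through the same structure.
#'
#' @param gt_fine Ground-truth fine label.
#' @param taxonomy A `food_taxonomy`.
#' @param gt_rank Rank at which the truth appears (1-based).
#' @param n_ranked Total length of the ranking.
#' @return A `prediction` tibble with columns `fine` and `score`
#'   (descending).
#' @export
oracle_prediction <- function(gt_fine, taxonomy, gt_rank = 1, n_ranked = 5) {
  stopifnot(gt_rank >= 1, gt_rank <= n_ranked)
  if (!gt_fine %in% taxonomy$fine) {
    abort(sprintf("unknown fine category '%s'", gt_fine),
          class = "mealmetry_unknown_category")
  }
  decoys <- setdiff(taxonomy$fine, gt_fine)
  labels <- append(head(decoys, n_ranked - 1), gt_fine, after = gt_rank - 1)
  out <- tibble(fine = labels,
                score = round(seq(0.9, 0.1, length.out = length(labels)), 6))
  class(out) <- c("prediction", class(out))
  out
}

#' Apply the top-5 user-selection rule
#'
#' Mirrors app usage: the user is shown the five highest-scored categories
#' and picks the true one when it is offered; otherwise the system's top
#' guess stands.
#'
#' @param prediction A `prediction` tibble (columns `fine`, `score`,
#'   descending scores).
#' @param gt_fine Ground-truth fine label.
#' @return The chosen fine label.
#' @export
top5_select <- function(prediction, gt_fine) {
  stopifnot(nrow(prediction) >= 1)
  if (gt_fine %in% head(prediction$fine, 5)) gt_fine else prediction$fine[1]
}

#' Intersection over union of two masks
#'
#' `|A intersect B| / |A union B|`; defined as 1 when both masks are empty.
#'
#' @param mask_a,mask_b Logical matrices of equal shape.
#' @return Number in `[0, 1]`.
#' @export
iou <- function(mask_a, mask_b) {
  if (!all(dim(mask_a) == dim(mask_b))) {
    abort("masks must have the same shape")
  }
  u <- sum(mask_a | mask_b)
  if (u == 0) return(1)
  sum(mask_a & mask_b) / u
}

#' Top-k classification accuracy at a taxonomy level
#'
#' Each item's ranked fine predictions are rolled up to `level`; duplicate
#' labels after roll-up collapse (so two fine guesses sharing a parent
#' consume a single slot), and the item counts as correct when its rolled-up
#' ground truth appears among the first `k` distinct rolled-up labels.
#'
#' @param predictions List of `prediction` tibbles (one per item).
#' @param gt_labels Character vector of ground-truth fine labels.
#' @param k Number of distinct guesses allowed.
#' @param level `"fine"`, `"middle"`, or `"coarse"`.
#' @param taxonomy A `food_taxonomy`.
#' @return Accuracy as a percentage in `[0, 100]`.
#' @export
top_k_accuracy <- function(predictions, gt_labels, k, level = "fine",
                           taxonomy) {
  stopifnot(length(predictions) == length(gt_labels), k >= 1,
            level %in% c("fine", "middle", "coarse"))
  hits <- map2_lgl(predictions, gt_labels, function(pred, gt) {
    ranked <- roll_up_vec(pred$fine, taxonomy, level)
    ranked <- ranked[!duplicated(ranked)]
    gt_lvl <- roll_up_vec(gt, taxonomy, level)
    gt_lvl %in% head(ranked, k)
  })
  100 * mean(hits)
}
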