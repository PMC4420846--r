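# The central experiment: classification performance as a function of the
# number of receptor conformations included in the SIFt profile.

#' Rank receptor conformations by centroid-screening AUROC
#'
#' Pre-evaluation step: each conformation is scored by the AUROC with
#' which its docking scores separate active from inactive cluster
#' centroids.
#'
#' @param centroid_scores Named list, one element per conformation, each a
#'   list with numeric vectors `pos` (actives) and `neg` (inactives).
#' @return Object of class `conformation_ranking`: named numeric vector of
#'   AUROC values, in input order, with the ranking order (descending
#'   AUROC) as attribute `order`.
#' @export
rank_conformations <- function(centroid_scores) {
  if (length(centroid_scores) == 0) stop("no conformations to rank")
  auroc <- vapply(centroid_scores, function(s) {
    if (length(s$pos) == 0 || length(s$neg) == 0)
      stop("every conformation needs scores for both classes")
    compute_auroc(s$pos, s$neg)
  }, numeric(1))
  structure(auroc, class = "conformation_ranking",
            order = names(auroc)[order(-auroc)])
}

#' @export
print.conformation_ranking <- function(x, ...) {
  cat("Conformation AUROC ranking:\n")
  ord <- order(-unclass(x))
  for (i in ord) cat(sprintf("  %s  %.4f\n", names(x)[i], x[i]))
  invisible(x)
}

#' Sweep the ensemble size from `min_size` conformations upwards
#'
#' For every size s = `min_size` .. N, profiles are built on the first s
#' conformations of `ensemble_order` (one-by-one prefix addition),
#' cross-validated over the C grid, and the best pooled MCC is recorded.
#' Per-step MCC differences, the best and worst sizes (ties to the
#' smaller, cheaper ensemble) and - when a [rank_conformations()] result
#' is supplied - the step at which the top-AUROC conformation enters the
#' profile are summarised in the result.
#'
#' @param collection A `sift_collection` (per-conformation fingerprints
#'   with labels), e.g. from [simulate_fingerprints()] or
#'   [as_sift_collection()].
#' @param ensemble_order Conformation ids in addition order; defaults to
#'   the collection's input order. Pass
#'   `attr(ranking, "order")` to add conformations by descending AUROC.
#' @param min_size Smallest ensemble size evaluated (default 3).
#' @param C_grid,k_folds,seed Cross-validation settings, see
#'   [cross_validate()].
#' @param denominator Missing-pose policy, see [build_profile()].
#' @param ranking Optional `conformation_ranking` used to mark the entry
#'   step of the top-AUROC conformation.
#' @return Object of class `sift_sweep`: list with `ensemble_order`,
#'   `sizes`, `mcc_by_size`, `auroc_by_size`, `best_C_by_size`,
#'   `delta_mcc` (size s minus size s-1, defined from `min_size + 1`),
#'   `best_size`, `worst_size`, and when ranked,
#'   `best_auroc_conformation` / `best_auroc_step`.
#' @export
run_sweep <- function(collection, ensemble_order = collection$conformation_ids,
                      min_size = 3, C_grid = default_C_grid(), k_folds = 10,
                      seed = 1L, denominator = c("ensemble", "poses"),
                      ranking = NULL) {
  denominator <- match.arg(denominator)
  if (length(ensemble_order) < min_size)
    stop("need at least ", min_size, " conformations")
  sizes <- seq.int(min_size, length(ensemble_order))
  mcc <- auroc <- bestC <- stats::setNames(numeric(length(sizes)), sizes)
  for (si in seq_along(sizes)) {
    fm <- collection_profiles(collection, ensemble_order[seq_len(sizes[si])],
                              denominator = denominator)
    cv <- cross_validate(fm, C_grid = C_grid, k_folds = k_folds, seed = seed)
    mcc[si] <- cv$best_mcc
    bestC[si] <- cv$best_C
    auroc[si] <- cv$per_C$auroc_pooled[cv$per_C$C == cv$best_C]
  }
  delta <- diff(mcc)
  names(delta) <- sizes[-1]
  pick <- function(v) sizes[v][which.min(sizes[v])]
  res <- list(ensemble_order = ensemble_order, sizes = sizes,
              mcc_by_size = mcc, auroc_by_size = auroc,
              best_C_by_size = bestC, delta_mcc = delta,
              best_size = pick(mcc == max(mcc)),
              worst_size = pick(mcc == min(mcc)),
              min_size = min_size, seed = seed, k_folds = k_folds)
  if (!is.null(ranking)) {
    top <- attr(ranking, "order")[1]
    res$best_auroc_conformation <- top
    step <- match(top, ensemble_order)
    res$best_auroc_step <- if (is.na(step)) NA_integer_
                           else max(step, min_size)
  }
  structure(res, class = "sift_sweep")
}

#' @export
print.sift_sweep <- function(x, ...) {
  cat(sprintf("Ensemble-size sweep: %d..%d conformations\n",
              min(x$sizes), max(x$sizes)))
  tab <- data.frame(size = x$sizes, mcc = round(x$mcc_by_size, 4),
                    auroc = round(x$auroc_by_size, 4),
                    best_C = x$best_C_by_size)
  print(tab, row.names = FALSE)
  cat(sprintf("best size %d (MCC %.4f), worst size %d (MCC %.4f)\n",
              x$best_size, x$mcc_by_size[as.character(x$best_size)],
              x$worst_size, x$mcc_by_size[as.character(x$worst_size)]))
  if (!is.null(x$best_auroc_conformation))
    cat(sprintf("top-AUROC conformation %s enters at size %s\n",
                x$best_auroc_conformation, x$best_auroc_step))
  invisible(x)
}

#' @export
summary.sift_sweep <- function(object, ...) {
  data.frame(
    best_size = object$best_size,
    mcc_best = unname(object$mcc_by_size[as.character(object$best_size)]),
    worst_size = object$worst_size,
    mcc_worst = unname(object$mcc_by_size[as.character(object$worst_size)]),
    mcc_first = unname(object$mcc_by_size[1]),
    mcc_last = unname(object$mcc_by_size[length(object$mcc_by_size)]))
}

#' @export
plot.sift_sweep <- function(x, ...) {
  graphics::plot(x$sizes, x$mcc_by_size, type = "b", pch = 16,
                 xlab = "conformations in profile", ylab = "pooled CV MCC",
                 ...)
  graphics::abline(v = x$best_size, lty = 2, col = "grey40")
  invisible(x)
}

#' Tabulate several sweeps (one row per screening scenario)
#'
#' @param results Named list of `sift_sweep` objects, e.g. the
#'   actives/true-inactives, actives/DUD-like and actives/random-decoy
#'   scenarios.
#' @return data.frame with scenario, optimal and worst ensemble size and
#'   the MCC at each.
#' @export
summarize_sweeps <- function(results) {
  if (length(results) == 0) stop("no sweep results to summarise")
  if (is.null(names(results)))
    names(results) <- paste0("scenario", seq_along(results))
  rows <- lapply(names(results), function(nm) {
    cbind(scenario = nm, summary(results[[nm]]))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Convert a list of per-conformation SIFts into a collection
#'
#' Groups `sift` objects by compound, verifies position compatibility and
#' packs them into the array form used by [collection_profiles()] and
#' [run_sweep()].
#'
#' @param sifts List of `sift` objects.
#' @param labels Named vector (by compound id): `"active"`,
#'   `"inactive"` or `"decoy"`.
#' @param conformation_ids Ensemble order; defaults to the order of first
#'   appearance in `sifts`.
#' @return A `sift_collection`.
#' @export
as_sift_collection <- function(sifts, labels, conformation_ids = NULL) {
  stopifnot(length(sifts) >= 1)
  cid <- vapply(sifts, attr, character(1), "compound_id")
  kid <- vapply(sifts, attr, character(1), "conformation_id")
  if (is.null(conformation_ids)) conformation_ids <- unique(kid)
  if (!all(kid %in% conformation_ids))
    stop("SIFt conformation id missing from conformation_ids")
  lens <- vapply(sifts, length, integer(1))
  if (length(unique(lens)) != 1) stop("SIFts have differing lengths")
  compounds <- unique(cid)
  if (!all(compounds %in% names(labels)))
    stop("missing label for some compounds")
  bits <- array(0L, dim = c(length(compounds), length(conformation_ids),
                            lens[1]),
                dimnames = list(compounds, NULL, NULL))
  pose <- matrix(FALSE, length(compounds), length(conformation_ids),
                 dimnames = list(compounds, NULL))
  for (s in seq_along(sifts)) {
    i <- match(cid[s], compounds)
    j <- match(kid[s], conformation_ids)
    if (pose[i, j]) stop("duplicate SIFt for (", cid[s], ", ", kid[s], ")")
    bits[i, j, ] <- as.integer(sifts[[s]])
    pose[i, j] <- TRUE
  }
  structure(list(bits = bits, pose = pose,
                 labels = labels[compounds],
                 conformation_ids = conformation_ids,
                 residue_labels = attr(sifts[[1]], "residue_labels"),
                 signal_positions = integer(0)),
            class = "sift_collection")
}
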