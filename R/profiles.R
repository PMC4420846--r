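# Per-ligand SIFt profiles: binary fingerprints averaged over an ensemble
# of receptor conformations.

#' Build a per-ligand SIFt profile over a conformation ensemble
#'
#' Averages the binary fingerprints of one compound position-wise over the
#' conformations of an ensemble. Conformations in which the compound
#' received no pose contribute zero vectors under the default
#' `denominator = "ensemble"` mode (each value is the sum of bits divided
#' by the full ensemble size); `denominator = "poses"` instead divides by
#' the number of conformations with a pose, renormalising the profile.
#' The two modes coincide when every conformation has a pose.
#'
#' @param sifts List of `sift` objects, all for the same compound, at most
#'   one per conformation.
#' @param ensemble_ids Ordered character vector of conformation ids
#'   defining the ensemble.
#' @param denominator `"ensemble"` (default) or `"poses"`.
#' @return Object of class `sift_profile`: numeric vector in `[0, 1]` with
#'   attributes `compound_id`, `ensemble_ids`, `n_poses`.
#' @export
build_profile <- function(sifts, ensemble_ids,
                          denominator = c("ensemble", "poses")) {
  denominator <- match.arg(denominator)
  if (length(sifts) == 0)
    stop("no SIFts supplied; compounds without poses must be dropped upstream")
  lens <- vapply(sifts, length, integer(1))
  if (length(unique(lens)) != 1) stop("SIFts have differing lengths")
  cids <- unique(vapply(sifts, attr, character(1), "compound_id"))
  if (length(cids) != 1) stop("SIFts belong to several compounds")
  conf <- vapply(sifts, attr, character(1), "conformation_id")
  if (anyDuplicated(conf)) stop("multiple SIFts for one conformation")
  if (!all(conf %in% ensemble_ids))
    stop("SIFt conformation id not in ensemble_ids")
  acc <- Reduce(`+`, lapply(sifts, as.numeric))
  denom <- if (denominator == "ensemble") length(ensemble_ids)
           else length(sifts)
  structure(acc / denom, class = "sift_profile",
            compound_id = cids, ensemble_ids = ensemble_ids,
            n_poses = length(sifts),
            residue_labels = attr(sifts[[1]], "residue_labels"))
}

#' @export
print.sift_profile <- function(x, ...) {
  cat(sprintf("SIFt profile %s: %d positions over %d conformations (%d with a pose)\n",
              attr(x, "compound_id"), length(x),
              length(attr(x, "ensemble_ids")), attr(x, "n_poses")))
  invisible(x)
}

#' Assemble profiles into a labelled feature matrix
#'
#' Stacks per-ligand profiles into the machine-learning input: one row per
#' compound instance, one column per bit position, labels coded
#' active = +1, inactive/decoy = -1. All profiles must have been built on
#' the same ensemble (same conformation ids, same order).
#'
#' @param profiles List of `sift_profile` objects.
#' @param labels Named vector (by compound id) with values interpreted as
#'   +1 for `"active"`/`1` and -1 for `"inactive"`/`"decoy"`/`-1`.
#' @param groups Optional named vector mapping compound instance ids to
#'   parent-compound ids for leakage-safe cross-validation; defaults to the
#'   instance ids themselves.
#' @return Object of class `feature_matrix`: list with `x` (numeric
#'   matrix), `y` (+1/-1), `groups`.
#' @export
profile_matrix <- function(profiles, labels, groups = NULL) {
  stopifnot(length(profiles) >= 1)
  ens <- lapply(profiles, attr, "ensemble_ids")
  if (!all(vapply(ens, identical, logical(1), ens[[1]])))
    stop("profiles were built on different ensembles")
  ids <- vapply(profiles, attr, character(1), "compound_id")
  x <- do.call(rbind, lapply(profiles, as.numeric))
  rownames(x) <- ids
  labs <- attr(profiles[[1]], "residue_labels")
  if (!is.null(labs)) colnames(x) <- sift_colnames(labs)
  y <- normalize_labels(labels[ids], ids)
  if (is.null(groups)) groups <- stats::setNames(ids, ids)
  feature_matrix(x, y, groups[ids])
}

#' @noRd
normalize_labels <- function(lab, ids) {
  if (any(is.na(lab)))
    stop("no label for compound(s): ",
         paste(utils::head(ids[is.na(lab)], 5), collapse = ", "))
  y <- ifelse(lab %in% c("active", "+1", "1", 1), 1L,
              ifelse(lab %in% c("inactive", "decoy", "-1", -1), -1L, NA))
  if (any(is.na(y))) stop("labels must be active/inactive/decoy or +-1")
  as.integer(y)
}

#' Construct a feature matrix for screening
#'
#' @param x Numeric matrix, rows are compound instances.
#' @param y Labels in \{-1, +1\}.
#' @param groups Parent-compound ids (same length as rows) used to keep
#'   instances of one compound in one cross-validation fold.
#' @return Object of class `feature_matrix`.
#' @export
feature_matrix <- function(x, y, groups = rownames(x)) {
  x <- as.matrix(x)
  if (anyNA(x) || any(!is.finite(x))) stop("feature matrix has missing values")
  y <- as.integer(y)
  if (!all(y %in% c(-1L, 1L))) stop("labels must be -1 or +1")
  if (length(y) != nrow(x)) stop("label length does not match rows")
  if (is.null(groups)) groups <- as.character(seq_len(nrow(x)))
  structure(list(x = x, y = y, groups = as.character(groups)),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("Feature matrix: %d instances x %d positions (%d positive, %d negative)\n",
              nrow(x$x), ncol(x$x), sum(x$y == 1), sum(x$y == -1)))
  invisible(x)
}

#' Write profiles to a delimited text file
#'
#' @param profiles List of `sift_profile` objects on one ensemble.
#' @param path Output TSV.
#' @return `path`, invisibly.
#' @export
write_profiles <- function(profiles, path) {
  mat <- do.call(rbind, lapply(profiles, as.numeric))
  labs <- attr(profiles[[1]], "residue_labels")
  if (!is.null(labs)) colnames(mat) <- sift_colnames(labs)
  out <- data.frame(
    compound_id = vapply(profiles, attr, character(1), "compound_id"),
    n_poses = vapply(profiles, attr, integer(1), "n_poses"),
    mat, check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
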