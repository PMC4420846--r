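# Compound-set curation: activity labelling, clustering with centroid
# picking, and simplified property-matched decoy selection.

#' Label compounds as active / inactive / excluded from affinity data
#'
#' IC50 measurements are converted to Ki by halving (the conventional
#' competitive-binding approximation Ki = IC50 / 2) before thresholding.
#' A compound is active when its Ki is strictly below 100 nM and inactive
#' when strictly above 1000 nM; the 100-1000 nM band (and the boundary
#' values themselves) is excluded. Replicate measurements of one compound
#' are merged by the geometric mean of their Ki values, the natural mean
#' for log-scaled affinities.
#'
#' @param records data.frame with columns `compound_id`, `measure`
#'   (`"Ki"` or `"IC50"`) and `value_nM` (> 0); a `smiles` column is
#'   carried through if present.
#' @param active_below,inactive_above Thresholds in nM.
#' @return data.frame with columns `compound_id`, `ki_nM`, `label`
#'   (factor: active/inactive/excluded), one row per compound, ordered by
#'   compound id.
#' @export
label_compounds <- function(records, active_below = 100,
                            inactive_above = 1000) {
  need <- c("compound_id", "measure", "value_nM")
  if (!all(need %in% names(records)))
    stop("records must have columns: ", paste(need, collapse = ", "))
  if (any(records$value_nM <= 0)) stop("activity values must be positive")
  if (!all(records$measure %in% c("Ki", "IC50")))
    stop("measure must be 'Ki' or 'IC50'")
  ki <- ifelse(records$measure == "IC50", records$value_nM / 2,
               records$value_nM)
  agg <- tapply(ki, records$compound_id, function(v) exp(mean(log(v))))
  ids <- sort(names(agg))
  ki_nM <- as.numeric(agg[ids])
  label <- ifelse(ki_nM < active_below, "active",
                  ifelse(ki_nM > inactive_above, "inactive", "excluded"))
  out <- data.frame(compound_id = ids, ki_nM = ki_nM,
                    label = factor(label,
                                   levels = c("active", "inactive", "excluded")),
                    stringsAsFactors = FALSE)
  if ("smiles" %in% names(records)) {
    sm <- tapply(records$smiles, records$compound_id, `[`, 1)
    out$smiles <- as.character(sm[ids])
  }
  rownames(out) <- NULL
  out
}

#' Number of clusters for a compound set
#'
#' Approximately 30 percent of the set size: `floor(0.3 * n)`, at least 1.
#'
#' @param n_compounds Number of compounds (>= 1).
#' @return Integer cluster count.
#' @export
cluster_count <- function(n_compounds) {
  stopifnot(n_compounds >= 1)
  max(1L, as.integer(floor(0.3 * n_compounds)))
}

#' Tanimoto similarity between binary fingerprint rows
#'
#' @param fp Binary (0/1) matrix, one fingerprint per row.
#' @return Symmetric similarity matrix; two all-zero fingerprints have
#'   similarity 1.
#' @export
tanimoto_matrix <- function(fp) {
  fp <- as.matrix(fp) > 0
  common <- fp %*% t(fp)
  ones <- rowSums(fp)
  union <- outer(ones, ones, "+") - common
  sim <- ifelse(union == 0, 1, common / union)
  dimnames(sim) <- list(rownames(fp), rownames(fp))
  sim
}

#' Cluster compounds and pick cluster centroids
#'
#' Hierarchical average-linkage clustering on Tanimoto distance
#' (1 - similarity) of 2D binary fingerprints, cut into `k` clusters. The
#' centroid of a cluster is the member with the minimal mean distance to
#' the other members; ties are broken by lexicographic compound id. The
#' procedure is deterministic; `seed` is only used to subsample inputs
#' larger than `max_n`.
#'
#' @param fingerprints Binary matrix with compound ids as row names.
#' @param k Number of clusters (1 <= k <= number of compounds).
#' @param seed Integer seed for optional subsampling.
#' @param max_n Inputs larger than this are subsampled to `max_n` rows
#'   before clustering.
#' @return Character vector of `k` centroid compound ids, in cluster order.
#' @export
cluster_and_pick_centroids <- function(fingerprints, k, seed = 1L,
                                       max_n = 5000L) {
  fp <- as.matrix(fingerprints)
  if (nrow(fp) == 0) stop("no compounds to cluster")
  if (is.null(rownames(fp))) rownames(fp) <- as.character(seq_len(nrow(fp)))
  if (nrow(fp) > max_n) {
    set.seed(seed)
    fp <- fp[sort(sample(nrow(fp), max_n)), , drop = FALSE]
  }
  if (k > nrow(fp)) stop("k exceeds the number of compounds")
  dmat <- 1 - tanimoto_matrix(fp)
  cl <- if (k == nrow(fp)) seq_len(nrow(fp)) else {
    hc <- stats::hclust(stats::as.dist(dmat), method = "average")
    stats::cutree(hc, k = k)
  }
  vapply(seq_len(k), function(ci) {
    member <- which(cl == ci)
    if (length(member) == 1) return(rownames(fp)[member])
    meand <- rowMeans(dmat[member, member, drop = FALSE]) *
      length(member) / (length(member) - 1)  # exclude self-distance
    best <- member[meand == min(meand)]
    sort(rownames(fp)[best])[1]
  }, character(1))
}

#' Select property-matched decoys for an active set
#'
#' A simplified Directory-of-Useful-Decoys style selection: a candidate
#' survives when its physicochemical properties fall inside the window of
#' at least one active (molecular weight within 25 Da, logP within 1.0,
#' hydrogen-bond donors and acceptors within 1, rotatable bonds within 2)
#' while its 2D fingerprint Tanimoto similarity to every active stays
#' below 0.6 (topologically dissimilar). Survivors are down-sampled
#' uniformly at random to `n` with the given seed.
#'
#' @param candidates data.frame with columns `compound_id`, `mw`, `logp`,
#'   `hbd`, `hba`, `rotb`.
#' @param candidate_fp Binary fingerprint matrix with candidate compound
#'   ids as row names.
#' @param actives data.frame with the same property columns for actives.
#' @param active_fp Binary fingerprint matrix for the actives.
#' @param n Number of decoys to return.
#' @param seed Integer seed for the down-sampling.
#' @param mw_win,logp_win,hbd_win,hba_win,rotb_win,tanimoto_max
#'   Property windows and the similarity ceiling.
#' @return Character vector of `n` decoy compound ids.
#' @export
select_decoys <- function(candidates, candidate_fp, actives, active_fp, n,
                          seed = 1L, mw_win = 25, logp_win = 1.0,
                          hbd_win = 1, hba_win = 1, rotb_win = 2,
                          tanimoto_max = 0.6) {
  need <- c("compound_id", "mw", "logp", "hbd", "hba", "rotb")
  if (!all(need %in% names(candidates)) || !all(need %in% names(actives)))
    stop("candidates and actives need columns: ", paste(need, collapse = ", "))
  in_window <- vapply(seq_len(nrow(candidates)), function(i) {
    any(abs(candidates$mw[i] - actives$mw) <= mw_win &
        abs(candidates$logp[i] - actives$logp) <= logp_win &
        abs(candidates$hbd[i] - actives$hbd) <= hbd_win &
        abs(candidates$hba[i] - actives$hba) <= hba_win &
        abs(candidates$rotb[i] - actives$rotb) <= rotb_win)
  }, logical(1))
  cfp <- as.matrix(candidate_fp)[candidates$compound_id, , drop = FALSE] > 0
  afp <- as.matrix(active_fp) > 0
  common <- cfp %*% t(afp)
  union <- outer(rowSums(cfp), rowSums(afp), "+") - common
  sim <- ifelse(union == 0, 1, common / union)
  dissimilar <- apply(sim, 1, max) < tanimoto_max
  keep <- candidates$compound_id[in_window & dissimilar &
                                   !(candidates$compound_id %in%
                                       actives$compound_id)]
  if (length(keep) < n)
    stop("only ", length(keep), " candidates survive the filters; ", n,
         " requested")
  set.seed(seed)
  sort(sample(keep, n))
}
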