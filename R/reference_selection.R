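# Cosine-similarity computations and reference-compound selection.
#
# References are the known potent inhibitors whose latent vectors anchor
# the generator drift. A molecule qualifies as a reference for a target
# when it (i) binds tighter than the activity cut-off (delta G strictly
# below -9.54 kcal/mol, i.e. Ki below 0.1 uM), (ii) passes Lipinski's rule
# of five, and (iii) sits centrally in its dataset's latent cloud (average
# cosine similarity strictly above 0.40).

#' Cosine similarity between two latent vectors
#'
#' `dot(u, v) / (|u| |v|)`. Both vectors must be nonzero; a zero-norm
#' vector has no direction and raises a domain error rather than
#' returning 0 or NaN.
#'
#' @param u,v equal-length numeric vectors.
#' @return similarity in `[-1, 1]`.
#' @export
cosine_similarity <- function(u, v) {
  u <- check_latent(u, "u"); v <- check_latent(v, "v")
  if (length(u) != length(v)) stop_domain("dimension mismatch")
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) stop_domain("cosine similarity undefined for zero vector")
  s <- sum(u * v) / (nu * nv)
  min(1, max(-1, s))
}

#' Cosine-similarity matrix between two sets of latent vectors
#'
#' @param query numeric matrix, one latent vector per row.
#' @param dataset numeric matrix, one latent vector per row.
#' @return `nrow(query) x nrow(dataset)` matrix of similarities.
#' @export
similarity_matrix <- function(query, dataset) {
  query <- as.matrix(query); dataset <- as.matrix(dataset)
  if (ncol(query) != ncol(dataset)) stop_domain("dimension mismatch")
  qn <- sqrt(rowSums(query^2)); dn <- sqrt(rowSums(dataset^2))
  if (any(qn == 0) || any(dn == 0)) {
    stop_domain("cosine similarity undefined for zero vector")
  }
  s <- (query %*% t(dataset)) / outer(qn, dn)
  pmax(pmin(s, 1), -1)
}

#' Average cosine similarity of a candidate to a dataset
#'
#' Arithmetic mean of the cosine similarities between `candidate` and every
#' dataset member. Rows identical to the candidate vector are excluded
#' (self-comparison would inflate every average), and an error is raised if
#' nothing remains.
#'
#' @param candidate latent vector.
#' @param dataset numeric matrix of latent vectors (rows).
#' @return mean similarity in `[-1, 1]`.
#' @export
avg_similarity <- function(candidate, dataset) {
  candidate <- check_latent(candidate, "candidate")
  dataset <- as.matrix(dataset)
  if (nrow(dataset) == 0L) stop_domain("empty dataset")
  self <- apply(dataset, 1L, function(r) isTRUE(all(r == candidate)))
  dataset <- dataset[!self, , drop = FALSE]
  if (nrow(dataset) == 0L) {
    stop_domain("dataset contains only the candidate itself")
  }
  mean(similarity_matrix(matrix(candidate, nrow = 1L), dataset))
}

#' Count dataset members above a similarity threshold
#'
#' Strict comparison: members with similarity exactly at the threshold are
#' not counted.
#'
#' @inheritParams avg_similarity
#' @param threshold similarity threshold in `[-1, 1]`.
#' @return integer count.
#' @export
count_above <- function(candidate, dataset, threshold) {
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold < -1 || threshold > 1) {
    stop_domain("threshold must be a scalar in [-1, 1]")
  }
  sims <- similarity_matrix(matrix(check_latent(candidate, "candidate"),
                                   nrow = 1L), as.matrix(dataset))
  sum(sims > threshold)
}

#' Select reference compounds for a target
#'
#' Filters the molecules annotated with `target` down to those with
#' binding free energy strictly below `affinity_cut`, a Lipinski rule-of-
#' five pass, and average cosine similarity to the target's latent cloud
#' strictly above `min_avg_sim`; survivors are ranked by average similarity
#' (descending), then by more negative binding free energy, then by id.
#'
#' @param mols molecule data.frame with columns `id`, `smiles`, `target`,
#'   `delta_g` and the Lipinski descriptors `mw`, `logp`, `nhd`, `nha`.
#' @param latents numeric matrix of latent vectors, rows aligned with
#'   `mols`.
#' @param target target name, e.g. `"DAT"`.
#' @param affinity_cut activity cut-off in kcal/mol (default -9.54, the
#'   Ki = 0.1 uM threshold).
#' @param min_avg_sim minimum average cosine similarity (default 0.40).
#' @return data.frame of surviving records with an `avg_sc` column, ranked.
#' @export
select_references <- function(mols, latents, target,
                              affinity_cut = -9.54, min_avg_sim = 0.40) {
  validate_molecules(mols)
  need <- c("target", "delta_g", "mw", "logp", "nhd", "nha")
  miss <- setdiff(need, names(mols))
  if (length(miss) > 0L) {
    stop_data("molecule table lacks column(s): ", paste(miss, collapse = ", "))
  }
  latents <- as.matrix(latents)
  if (nrow(latents) != nrow(mols)) {
    stop_data("latent rows (", nrow(latents), ") do not align with molecules (",
              nrow(mols), ")")
  }
  in_target <- mols$target == target
  sub <- mols[in_target, , drop = FALSE]
  zs <- latents[in_target, , drop = FALSE]
  if (nrow(sub) == 0L) stop_data("no records for target '", target, "'")
  sub$avg_sc <- vapply(seq_len(nrow(sub)),
                       function(i) avg_similarity(zs[i, ], zs), numeric(1))
  lip <- lipinski_filter(sub)$pass
  keep <- sub$delta_g < affinity_cut & lip & sub$avg_sc > min_avg_sim
  out <- sub[keep, , drop = FALSE]
  out[order(-out$avg_sc, out$delta_g, out$id), , drop = FALSE]
}
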