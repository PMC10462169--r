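# Shared helpers: tiny codecs and brute-force oracles kept deliberately
# independent of the package's own implementations.

tiny_molecules <- function(n, prefix = "M") {
  data.frame(id = sprintf("%s%03d", prefix, seq_len(n)),
             smiles = vapply(seq_len(n),
                             function(i) paste(rep("C", i), collapse = ""),
                             character(1)),
             stringsAsFactors = FALSE)
}

# Exhaustive nearest-neighbour scan (Euclidean), ties by lowest index.
brute_nearest <- function(z, centers) {
  d2 <- apply(centers, 1L, function(cc) sum((z - cc)^2))
  which.min(d2)
}

brute_cosine <- function(u, v) {
  sum(u * v) / (sqrt(sum(u^2)) * sqrt(sum(v^2)))
}

# Independent three-criterion reference scan (affinity, Lipinski, average
# similarity), no ranking.
brute_reference_ids <- function(mols, latents, target) {
  rows <- which(mols$target == target)
  zs <- latents[rows, , drop = FALSE]
  keep <- logical(length(rows))
  for (i in seq_along(rows)) {
    r <- mols[rows[i], ]
    sims <- vapply(seq_along(rows)[-i],
                   function(j) brute_cosine(zs[i, ], zs[j, ]), numeric(1))
    keep[i] <- r$delta_g < -9.54 &&
      r$mw <= 500 && r$logp <= 5 && r$nhd <= 5 && r$nha <= 10 &&
      mean(sims) > 0.40
  }
  mols$id[rows[keep]]
}

# Independent property classifier written directly from the screening
# ranges: closed excellent intervals, medium (0.3, 0.7], strict one-sided
# bounds.
brute_classify <- function(p) {
  score <- function(x) {
    if (x >= 0 && x <= 0.3) "excellent"
    else if (x > 0.3 && x <= 0.7) "medium"
    else "fail"
  }
  c(caco2 = if (p$caco2 > -5.15) "excellent" else "fail",
    f20 = score(p$f20), pgp_sub = score(p$pgp_sub),
    pgp_inh = score(p$pgp_inh),
    vd = if (p$vd >= 0.04 && p$vd <= 20) "excellent" else "fail",
    t_half = score(p$t_half), fdamdd = score(p$fdamdd),
    sas = if (p$sas < 6) "excellent" else "fail",
    logp = if (p$logp >= 0 && p$logp <= 3) "excellent" else "fail",
    logs = if (p$logs >= -4 && p$logs <= 0.5) "excellent" else "fail")
}
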