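# Synthetic fixture generator. Produces toy datasets with the statistical
# structure the pipeline assumes — per-target latent clusters, planted
# linear affinity labels, descriptor columns inside drug-like ranges and
# property profiles with known classes — so every stage is testable
# without external downloads. All outputs are pure functions of
# (spec, seed).

#' Specification of a synthetic dataset
#'
#' @param n_per_target molecules per target (default 50).
#' @param d latent dimension (default 16; the full pipeline default of 512
#'   is unnecessary for fixtures).
#' @param targets target names; default `c("DAT", "NET", "SERT", "hERG")`.
#' @param cluster_spread per-coordinate standard deviation of a target's
#'   latent cloud around its center (default 0.3, small against typical
#'   center norms so within-cluster cosine similarity is high, as in real
#'   inhibitor sets).
#' @param intercepts named kcal/mol intercepts of the planted affinity
#'   maps; transporters default to -11 (well inside the active region),
#'   hERG to -6 (weak binding).
#' @param weight_norms named Euclidean norms of the planted linear weight
#'   vectors; transporters default to 5 (label SD ~1.5 kcal/mol at the
#'   default spread), hERG to 0.5.
#' @param noise_sd label noise standard deviation in kcal/mol (default
#'   0.5).
#' @param descriptor_ranges list of `c(lo, hi)` sampling intervals for
#'   `mw`, `logp`, `nhd`, `nha`.
#' @param class_fractions named fractions (`excellent`, `medium`, `fail`)
#'   used when planting property classes; for properties without a medium
#'   range the medium mass folds into excellent.
#' @param seed integer seed.
#' @return an object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_per_target = 50L, d = 16L,
                           targets = c("DAT", "NET", "SERT", "hERG"),
                           cluster_spread = 0.3,
                           intercepts = NULL, weight_norms = NULL,
                           noise_sd = 0.5,
                           descriptor_ranges = list(
                             mw = c(200, 480), logp = c(0.5, 4.5),
                             nhd = c(0, 4), nha = c(1, 8)),
                           class_fractions = c(excellent = 0.6,
                                               medium = 0.25, fail = 0.15),
                           seed = 1L) {
  n_per_target <- as.integer(n_per_target)
  d <- as.integer(d)
  if (is.na(n_per_target) || n_per_target < 1L) {
    stop_config("n_per_target must be positive")
  }
  if (is.na(d) || d < 1L) stop_config("d must be positive")
  if (length(targets) < 1L || anyDuplicated(targets) > 0L) {
    stop_config("targets must be distinct names")
  }
  if (!is.numeric(cluster_spread) || cluster_spread < 0) {
    stop_config("cluster_spread must be >= 0")
  }
  if (!is.numeric(noise_sd) || noise_sd < 0) stop_config("noise_sd must be >= 0")
  default_b <- ifelse(targets == "hERG", -6, -11)
  names(default_b) <- targets
  default_w <- ifelse(targets == "hERG", 0.5, 5)
  names(default_w) <- targets
  if (!is.null(intercepts)) default_b[names(intercepts)] <- intercepts
  if (!is.null(weight_norms)) default_w[names(weight_norms)] <- weight_norms
  cf <- class_fractions / sum(class_fractions)
  if (any(cf < 0) || !all(c("excellent", "medium", "fail") %in% names(cf))) {
    stop_config("class_fractions needs non-negative excellent/medium/fail")
  }
  structure(list(n_per_target = n_per_target, d = d, targets = targets,
                 cluster_spread = cluster_spread, intercepts = default_b,
                 weight_norms = default_w, noise_sd = noise_sd,
                 descriptor_ranges = descriptor_ranges,
                 class_fractions = cf, seed = as.integer(seed)),
            class = "synthetic_spec")
}

# Unique, syntactically valid SMILES: a linear chain over the C/N/O
# alphabet encoding the molecule index in base 3, prefixed with C.
.synthetic_smiles <- function(i) {
  vapply(i, function(k) {
    digits <- character(0)
    k0 <- k
    repeat {
      digits <- c(c("C", "N", "O")[k0 %% 3L + 1L], digits)
      k0 <- k0 %/% 3L
      if (k0 == 0L) break
    }
    paste0("C", paste(digits, collapse = ""))
  }, character(1))
}

#' Generate a synthetic latent dataset with planted affinity labels
#'
#' Draws each target's molecules around a target-specific latent center
#' (centers are standard normal in d dimensions, drawn once per spec),
#' labels them with a planted linear affinity map
#' `delta_g = b_t + w_t . (x - c_t) + noise`, and samples Lipinski
#' descriptors uniformly inside the spec's ranges. The planted truth
#' (centers, weights, intercepts) is returned alongside so tests can
#' assert recovery.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `molecules` (data.frame: `id`, `smiles`, `target`,
#'   `delta_g`, `mw`, `logp`, `nhd`, `nha`), `latents` (matrix, rows
#'   aligned) and `truth` (centers, weights, intercepts, noise_sd).
#' @export
make_latent_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(derive_seed(spec$seed, "latent-dataset"), {
    k <- length(spec$targets)
    n <- spec$n_per_target
    centers <- matrix(rnorm(k * spec$d), k, spec$d,
                      dimnames = list(spec$targets, NULL))
    weights <- matrix(rnorm(k * spec$d), k, spec$d,
                      dimnames = list(spec$targets, NULL))
    weights <- weights / sqrt(rowSums(weights^2)) * spec$weight_norms[spec$targets]
    latents <- matrix(NA_real_, k * n, spec$d)
    delta_g <- numeric(k * n)
    target_col <- rep(spec$targets, each = n)
    for (ti in seq_len(k)) {
      rows <- (ti - 1L) * n + seq_len(n)
      x <- matrix(rnorm(n * spec$d, sd = spec$cluster_spread), n, spec$d)
      x <- sweep(x, 2L, centers[ti, ], "+")
      latents[rows, ] <- x
      centered <- sweep(x, 2L, centers[ti, ])
      delta_g[rows] <- spec$intercepts[spec$targets[ti]] +
        as.numeric(centered %*% weights[ti, ]) +
        if (spec$noise_sd > 0) rnorm(n, sd = spec$noise_sd) else 0
    }
    dr <- spec$descriptor_ranges
    total <- k * n
    mols <- data.frame(
      id = sprintf("MOL%05d", seq_len(total)),
      smiles = .synthetic_smiles(seq_len(total)),
      target = target_col,
      delta_g = delta_g,
      mw = runif(total, dr$mw[1], dr$mw[2]),
      logp = runif(total, dr$logp[1], dr$logp[2]),
      nhd = sample(seq.int(dr$nhd[1], dr$nhd[2]), total, replace = TRUE),
      nha = sample(seq.int(dr$nha[1], dr$nha[2]), total, replace = TRUE),
      stringsAsFactors = FALSE)
    list(molecules = mols, latents = latents,
         truth = list(centers = centers, weights = weights,
                      intercepts = spec$intercepts, noise_sd = spec$noise_sd))
  })
}

# Per-property sampling intervals for each planted class, chosen strictly
# inside (or strictly outside) the default range table so boundary rounding
# can never flip a planted class.
.class_regions <- list(
  caco2 = list(excellent = c(-5.0, -4.0), fail = c(-6.5, -5.3)),
  f20 = list(excellent = c(0.02, 0.28), medium = c(0.35, 0.68),
             fail = c(0.72, 0.95)),
  pgp_sub = list(excellent = c(0.02, 0.28), medium = c(0.35, 0.68),
                 fail = c(0.72, 0.95)),
  pgp_inh = list(excellent = c(0.02, 0.28), medium = c(0.35, 0.68),
                 fail = c(0.72, 0.95)),
  vd = list(excellent = c(0.1, 15), fail = c(21, 30)),
  t_half = list(excellent = c(0.02, 0.28), medium = c(0.35, 0.68),
                fail = c(0.72, 0.95)),
  fdamdd = list(excellent = c(0.02, 0.28), medium = c(0.35, 0.68),
                fail = c(0.72, 0.95)),
  sas = list(excellent = c(1.5, 5.5), fail = c(6.2, 8.0)),
  logp = list(excellent = c(0.2, 2.8), fail = c(3.3, 5.0)),
  logs = list(excellent = c(-3.5, 0.3), fail = c(-6.0, -4.3)))

#' Generate synthetic property profiles with planted classes
#'
#' For each molecule and each of the ten screened properties, a class is
#' drawn from the spec's class fractions and a value is sampled strictly
#' inside that class's region of the default range table. The planted
#' class of every value is returned as ground truth.
#'
#' @param ids character vector of molecule ids.
#' @param spec a [synthetic_spec()].
#' @return list with `profiles` (data.frame `id` + ten property columns)
#'   and `truth` (data.frame of planted classes, same shape).
#' @export
make_property_profiles <- function(ids, spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  ids <- as.character(ids)
  with_seed(derive_seed(spec$seed, "property-profiles"), {
    n <- length(ids)
    profiles <- data.frame(id = ids, stringsAsFactors = FALSE)
    truth <- data.frame(id = ids, stringsAsFactors = FALSE)
    for (p in .property_names) {
      regions <- .class_regions[[p]]
      fr <- spec$class_fractions
      if (!"medium" %in% names(regions)) {
        fr["excellent"] <- fr["excellent"] + fr["medium"]
        fr <- fr[c("excellent", "fail")]
      }
      cls <- sample(names(fr), n, replace = TRUE, prob = fr)
      lo <- vapply(cls, function(cc) regions[[cc]][1], numeric(1))
      hi <- vapply(cls, function(cc) regions[[cc]][2], numeric(1))
      profiles[[p]] <- runif(n, lo, hi)
      truth[[p]] <- cls
    }
    list(profiles = profiles, truth = truth)
  })
}

#' Build a complete synthetic fixture for the generation pipeline
#'
#' Produces a codebook codec over a synthetic dataset, selects one
#' reference compound per transporter target with [select_references()],
#' takes the centroid of the reference latents as the seed vector, and
#' attaches property profiles for every molecule.
#'
#' @param spec a [synthetic_spec()].
#' @param transporters targets used for reference selection (default the
#'   spec targets minus `"hERG"`).
#' @return list with `codec`, `refs` (a [reference_set()], uniform
#'   weights), `ref_table` (the selected reference records), `seed_vector`,
#'   `molecules`, `latents`, `profiles`, `profile_truth` and `truth`.
#' @export
make_codebook_fixture <- function(spec,
                                  transporters = setdiff(spec$targets, "hERG")) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (length(transporters) < 1L) stop_config("need at least one transporter")
  data <- make_latent_dataset(spec)
  codec <- codebook_codec(data$molecules, data$latents)
  ref_rows <- lapply(transporters, function(t) {
    sel <- select_references(data$molecules, data$latents, t)
    if (nrow(sel) == 0L) {
      stop_config("no molecule qualifies as a reference for target '", t, "'")
    }
    sel[1L, , drop = FALSE]
  })
  ref_table <- do.call(rbind, ref_rows)
  ref_latents <- data$latents[match(ref_table$id, data$molecules$id), ,
                              drop = FALSE]
  refs <- reference_set(ref_latents)
  props <- make_property_profiles(data$molecules$id, spec)
  list(codec = codec, refs = refs, ref_table = ref_table,
       seed_vector = colMeans(ref_latents),
       molecules = data$molecules, latents = data$latents,
       profiles = props$profiles, profile_truth = props$truth,
       truth = data$truth)
}
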